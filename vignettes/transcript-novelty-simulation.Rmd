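---
title: "Simulating controlled transcript novelty for long-read RNA-seq benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating controlled transcript novelty for long-read RNA-seq benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novelsim)
library(data.table)
```

## The problem

Transcript discovery from long-read RNA-seq (PacBio, Oxford Nanopore) is
hard to benchmark: real samples contain genuinely novel isoforms, but
nobody knows which ones, so sensitivity and precision of reconstruction
pipelines cannot be measured directly. `novelsim` manufactures a ground
truth by *controlled removal*: reference transcripts are classified by the
structural category they would fall into if they were absent from the
annotation, a user-chosen number per category is removed to form a
"reduced" annotation, reads are simulated from the *complete* annotation,
and a reconstruction run against the reduced annotation can then be scored
exactly — every removed transcript is a known novel isoform, everything
else a known annotated one.

The structural vocabulary is the SQANTI3 category scheme used across the
field: FSM (full splice match), ISM (incomplete splice match), NIC (novel
in catalog), NNC (novel not in catalog), plus genic-genomic, antisense,
fusion and intergenic.

## Classification model

Each transcript is compared against the other transcripts of its gene
group, *never against itself* — a self-comparison would always return FSM.
Concretely, the comparison group of a candidate is the set of transcripts
belonging to genes whose span (recomputed without the candidate) overlaps
the candidate on the same strand. Using actual overlap rather than
`gene_id` labels means that removal-induced categories (intergenic,
antisense) reflect what remains on the genome, not bookkeeping.

For multi-exon candidates the cascade is, first match wins:

1. **FSM** — junction chain identical to a comparison transcript;
2. **ISM** — chain is a strictly shorter *contiguous* subchain (junctions
   missing at the 5' and/or 3' end only);
3. **FUSION** — exons overlap two or more distinct same-strand genes;
4. **NIC** — every donor and acceptor is in the gene catalog, but the
   chain is not a subchain of any reference;
5. **NNC** — at least one donor or acceptor is absent from the catalog;
6. no same-strand overlap: **ANTISENSE** if an opposite-strand gene
   overlaps, otherwise **INTERGENIC**.

Mono-exon candidates use a separate, deterministic rule set: FSM when
another mono-exon transcript of the group overlaps reciprocally by at
least 80%; ISM when contained within a single exon of a multi-exon
transcript; otherwise the fusion/antisense/intergenic checks, defaulting
to GENIC_GENOMIC when a same-strand gene overlaps. The 80% reciprocal
threshold and the single-exon containment rule are this package's own
choices — the mono-exon case is underdetermined in the category scheme —
and both are pinned by tests, including agreement with an independent
brute-force classifier that rebuilds each candidate's catalog from
scratch.

Ties for the associated transcript (an ISM chain contained in several
references) resolve to the reference with the most junctions, then the
lexicographically smallest id, so the index file is reproducible.

## Design stage

`select_novel()` draws the requested number of candidates per category
uniformly at random (seeded) among *eligible* transcripts: category
matches and length at least `min_length` (default 200 nt, avoiding small
RNAs). A shortfall is a hard error naming the category and the available
versus requested numbers — never silent under-delivery.

`reduce_annotation()` removes the selected transcripts and then
*verifies* the contract that makes the simulation a ground truth:
re-classifying each removed transcript against the reduced annotation
must return its designated category. Removal can break a designation
(e.g. removing both an ISM and the only reference carrying its parent
chain), so violators are swapped for fresh eligible candidates, with a
retry budget of 10 times the requested count per category; exhaustion is
an error listing the unverifiable designations. The synthetic fixtures
(below) are built so that constructs do not interfere, and the
benchmark-scale experiments verify with zero swaps.

Known transcripts are not removed; when `n_known` is given, that many
potential-FSM transcripts are additionally selected for expression, which
mirrors how the validation designs state their "known" counts.

### Expression

Three modes assign read counts to the simulated (expressed) transcripts:

* **equal** — identical counts up to ±1 from integer rounding;
* **custom** — negative binomial draws with separate `(size, prob)` pairs
  for known and novel transcripts;
* **sample** — inverse-transform sampling from an empirical count
  distribution: per transcript draw `u ~ Uniform(0,1)` and take the
  smallest support value whose cumulative probability reaches `u`.

The known/novel expression bias of sample mode uses
`u' = u^(1 + diff_exp)` for novel transcripts. This functional form is a
package choice (the bias is only described qualitatively in the
literature this tool follows): it is monotone in `diff_exp`, recovers the
unbiased sampler at 0, and gives stochastic dominance — for the same `u`
a larger `diff_exp` never yields a larger count — which the tests check
directly.

Raw draws are scaled to the requested total with largest-remainder
rounding, so counts sum *exactly* to `total_long_reads`; every simulated
transcript keeps at least one read (zero-read "simulated" transcripts
would be undetectable by construction). TPM is counts normalized to 1e6.

With `iso_complex`, the known transcripts to express are chosen gene by
gene, with the number of expressed isoforms per gene drawn by inverse
transform from an empirical per-gene isoform-count multiset (capped at
the gene's transcript count). We place this in the known-selection step
because the novel partition is already fixed by the category request.

## Read simulation

### Long reads

The internal engine draws each read from the spliced transcript sequence
(complete annotation — novel transcripts are sequenced; that is the
point), optionally truncates at the 5' end, then mutates. The per-base
event model treats deletion and substitution as mutually exclusive
(probabilities `del` and `sub`; their sum is below 1), with insertion as
an independent Bernoulli after each position. An alternative would be to
draw substitution independently of deletion, but a substitution on a
deleted base is undefined, and the exclusive form makes the realized
substitution fraction per source base an unbiased estimator of the
configured rate — which is exactly what the rate-recovery checks measure.

Presets carry the platform default rates: PacBio Sequel (substitution
1.731%, deletion 1.090%, insertion 2.204%), ONT cDNA (2.8 / 1.9 / 3.5%)
and ONT dRNA (3.6 / 3.0 / 5.7%). Truncation defaults to off
(`trunc_prob = 0`); when enabled, the truncated fraction is
Uniform(0, `trunc_max`) at the 5' end, a qualitative stand-in for cDNA
degradation. FASTQ qualities are a constant Q20 placeholder: nothing
downstream of this package reads them, and realistic quality-string
models belong to the dedicated read simulators this engine stands in for
at desk scale (an adapter around those tools is a documented extension
point, not implemented here).

### Short reads

Paired-end mates of 100 nt with a uniform 0.5% per-base substitution
error (the conventional defaults for matched Illumina simulation). Pairs
are allocated across transcripts by a single multinomial draw with
weights TPM × length, fragments are Normal(300, 30) clipped to the
transcript, mate 2 is reverse-complemented. Coverage for downstream
feature computation is projected from the simulation *truth* through the
exon structure — no aligner is involved, which removes a heavyweight
dependency while preserving the feature definitions exactly.

### CAGE peaks

TSS support is modeled by logistic regression on two features: the TSS
ratio (coverage in the 100-bp window downstream of the TSS over the
100-bp window upstream, both sums pseudocounted by +1 so the log is
finite at zero coverage) and the TSS coverage proportion (read starts in
the 20-bp downstream window over total reads). The fit is maximum
likelihood via IRLS (tolerance 1e-8) with k-fold (default 10)
cross-validated accuracy at threshold 0.5; complete separation falls back
to a ridge-stabilized fit with a warning. The coverage proportion can be
exactly zero, so the model stores a pseudocount (default 1e-4) applied
inside its log transform at both fit and prediction time.

Peak placement draws (length, center distance) *jointly* — resampling
rows of the empirical sample rather than independent marginals — because
length and distance are dependent in real CAGE data; distances are
strand-aware (positive = downstream). Non-supporting peaks are added
until they make up the requested fraction of all peaks, anchored at
randomly chosen TSS with draws from the non-supporting sample; no
exclusion zone is enforced around other TSS, since "non-supporting" is
defined by the drawn distance distribution itself.

## Evaluation

A reconstructed multi-exon model is **TP** for a simulated transcript
when the junction chains match exactly and both ends are within 50 nt;
**PTP** when the chain matches but an end is further away ("within 50" is
read strictly: an offset of exactly 50 is TP, 51 is PTP, and a sweep test
pins the boundary); otherwise **FP**. Simulated transcripts with no TP
are **FN**. Mono-exon models, which have no chain, match by both ends
within tolerance. When several models would be TP for one simulated
transcript, the first in input order wins and later duplicates are FP —
redundant models are penalized deterministically. FP models are assigned
a structural category by classifying them against the *reduced*
annotation, mirroring how a QC tool would see them.

Metrics use the printed formulas: `Sn = TP/(TP+FN)`, `Pr = TP/(TP+FP)`,
`F1 = TP/(TP + (FP+FN)/2)`, `PDR = (TP+PTP)/(TP+FN)`,
`FDR = FP/(TP+PTP+FP)`; zero denominators give NA. PTP enters only PDR
and FDR. Note that PDR can exceed 1 when redundant PTP models outnumber
missed transcripts; it is reported as computed. Gene-level detection
counts a simulated gene as found when at least one of its simulated
transcripts is TP or PTP.

## Synthetic fixtures

The generator plants one selectable candidate per construct, each next to
an FSM backbone pair whose members can never be selected as novel (FSM
wins the cascade before anything else), so candidate removals are
independent across constructs:

| category | construct |
|---|---|
| FSM | two transcripts with identical chains, jittered ends |
| ISM | 4-exon backbone pair + 3-exon prefix candidate |
| NIC | backbone pair + exon-skipping candidate (known sites, novel junction) |
| NNC | backbone pair + candidate with a donor shifted 12 nt |
| GENIC_GENOMIC | mono-exon straddling an exon/intron boundary |
| ANTISENSE | mono-exon gene nested in an opposite-strand host |
| FUSION | transcript spanning two adjacent 2-exon genes |
| INTERGENIC | isolated mono-exon single-transcript gene |

Constructs are shuffled along contigs with random gaps and alternating
strands; canonical GT..AG motifs (strand-aware) are physically written
into the random genomic background at every intron, so junction
canonicity is meaningful rather than vacuous. Fixtures are
byte-deterministic under a fixed seed, and the generator's promise is
closed-loop tested: the classifier itself verifies the planted quotas.

What the fixtures deliberately do *not* emulate: realistic human gene
architecture (exon/intron length distributions are uniform within narrow
ranges), overlapping isoform-dense loci, repeat elements, alternative
TSS/TTS clusters, or sequence-dependent error structure. Passing tests
on these fixtures demonstrates correctness of the classification, design
and evaluation machinery under controlled conditions, not performance of
any pipeline on real tissue data.

## Problem sizes and numerical choices

The validation experiments in the test suite and acceptance script use a
fixture with 3000 eligible candidates per novel category (three times the
1000-per-category request) and 44,000 potential-FSM transcripts for the
43,000-known design, about 65,000 transcripts in total; the
benchmark-scale design uses 15,000 eligible candidates per main category
(~135,000 transcripts) and requests 5000 ISM/NIC/NNC. Error-rate
recovery uses 1e5 read pairs (2e7 bases) for the short-read engine and
~1e6 transcript bases for the long-read engine, with agreement judged
within three binomial standard deviations of the configured rate.

Other numerical conventions: internal coordinates are 0-based half-open
with conversion at the GTF boundary (this removes every off-by-one from
the algorithms; the converters are pinned by hand-worked examples);
strand "." in input GTF is tolerated as "+" with a warning; largest
remainder ties break by index order; all stage seeds derive from one
global seed through named substreams, so `full-sim` equals the
composition of its stages byte for byte.

## Limitations

The classifier implements the widely used category semantics but not the
full QC attribute set of dedicated tools (no RT-switching, intrapriming
or coding prediction, and no subcategory labels). The internal read
engine is a rate-faithful stand-in, not a platform error-model emulator:
no homopolymer effects, no quality model, no multi-pass consensus.
Orthogonal data simulation assumes the TSS-support logistic model is an
adequate summary of CAGE evidence; with sparse short-read coverage its
features degenerate toward the pseudocount. Expression modes draw
per-transcript counts independently, so co-expression structure within
genes is not modeled beyond the optional isoform-complexity constraint.
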