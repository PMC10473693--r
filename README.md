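# novelsim

Controlled transcript-novelty simulation for benchmarking long-read
RNA-seq transcriptome reconstruction.

## The problem

Long-read RNA-seq (PacBio, ONT) routinely discovers transcripts missing
from even the best reference annotations, but there is no way to score a
reconstruction pipeline's novel calls on real data — the truth is unknown.
`novelsim` builds the truth instead of guessing it:

1. **classif** — every reference transcript is assigned the *potential*
   structural category it would fall into if it were missing from the
   annotation, by comparison against the other transcripts of its
   (overlapping, same-strand) gene group, excluding itself. Categories
   follow the SQANTI3 scheme: FSM, ISM, NIC, NNC, genic-genomic,
   antisense, fusion, intergenic.
2. **design** — a requested number of transcripts per category (length ≥
   200 bp) is removed, producing a *reduced* annotation; each removed
   transcript is re-classified against the reduced annotation to verify it
   really presents as its designated category. Expression is assigned by
   `equal`, `custom` (two negative binomials) or `sample` mode
   (inverse-transform sampling from an empirical count distribution, with
   a `diff_exp` knob biasing novel transcripts toward lower expression).
3. **sim** — long reads are simulated from the *complete* annotation with
   platform error presets (PacBio Sequel 1.731% sub / 1.090% del /
   2.204% ins; ONT cDNA and dRNA presets), plus matched paired-end short
   reads (100 nt, 0.5% uniform error) and CAGE peaks driven by a logistic
   TSS-support model
   `logit(pi) = b0 + b1*log(TSS ratio) + b2*log(TSS coverage proportion)`.
4. **eval** — a reconstruction (GTF) is scored against the simulated
   truth: TP (junction chain match, both ends within 50 nt), PTP (chain
   match, an end beyond 50 nt), FP (not simulated), FN (simulated, not
   recovered), with `Sn = TP/(TP+FN)`, `Pr = TP/(TP+FP)`,
   `F1 = TP/(TP+(FP+FN)/2)`, `PDR = (TP+PTP)/(TP+FN)`,
   `FDR = FP/(TP+PTP+FP)`, overall, per novelty status and per category.

A seeded synthetic genome/annotation generator plants verifiable
candidates of every category, so the whole pipeline runs and is tested
without any downloads.

## Worked example

```r
library(novelsim)

spec <- fixture_spec(quota = c(ISM = 20, NIC = 20, NNC = 20),
                     n_fsm_genes = 30, seed = 42)
fx  <- synth_fixture(spec)
idx <- classify_annotation(fx$annotation)
table(idx$category)
#> FSM ISM NIC NNC
#> 180  20  20  20

req <- novelty_request(ism = 10, nic = 10, nnc = 10, n_known = 40)
des <- select_novel(idx, req, seed = 42)
red <- reduce_annotation(fx$annotation, des, idx)
all(red$verification$designated == red$verification$observed)
#> TRUE

des <- assign_expression(red$design, expression_equal(), 5000, seed = 42)
tr  <- simulate_long_reads(des, fx$annotation, fx$genome,
                           error_profile("ont-cdna"), "demo.fastq", seed = 42)
nrow(tr); mean(tr$n_sub)
#> 5000
#> 14.91

# pretend reconstruction: the first 60 of the 70 simulated transcripts
recon <- subset_annotation(fx$annotation, des$transcript_id[1:60])
m <- match_models(recon, des, fx$annotation, red$reduced)
compute_metrics(m$counts)[stratum %in% c("all", "known", "novel")]
#>    stratum TP PTP FP FN sensitivity precision        F1
#> 1:     all 60   0  0 10   0.8571429         1 0.9230769
#> 2:   known 30   0  0 10   0.7500000         1 0.8571429
#> 3:   novel 30   0  0  0   1.0000000         1 1.0000000
```

Reading the output: all 30 removed (novel) transcripts were classified
into their designated categories after reduction (`TRUE`), the 5000
requested ONT cDNA reads carry about 15 substitutions each (2.8% of a
~530 nt transcript), and dropping 10 known transcripts from the
"reconstruction" costs exactly 10 FN with known-stratum sensitivity 0.75
while precision stays 1.

A command-line wrapper with the same stages is installed at
`system.file("scripts", "novelsim", package = "novelsim")`, e.g.

```sh
Rscript $(Rscript -e 'cat(system.file("scripts","novelsim",package="novelsim"))') \
  full-sim --gtf ref.gtf --genome ref.fa --ism 1000 --nic 1000 --nnc 1000 \
  --n_known 43000 --long_count 100000 --ont --out_dir sim_out --seed 1
```

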