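# Shared helpers: hand-built annotations and an independent brute-force
# structural classifier used as oracle for the vectorized implementation.

library(data.table)

# Build an annotation from a compact transcript list:
# list(list(id=, gene=, strand=, exons=list(c(s,e), ...), contig=), ...)
mk_ann <- function(txs, contig = "chr1") {
  rows <- lapply(txs, function(t) {
    ex <- do.call(rbind, t$exons)
    data.table(transcript_id = t$id, gene_id = t$gene,
               contig = if (!is.null(t$contig)) t$contig else contig,
               strand = if (!is.null(t$strand)) t$strand else "+",
               start = as.integer(ex[, 1]), end = as.integer(ex[, 2]))
  })
  annotation(rbindlist(rows))
}

# uniform random genome for hand-built annotations
mk_genome <- function(ann, pad = 100L, seed = 1L) {
  set.seed(seed)
  out <- vapply(split(ann$exons, ann$exons$contig), function(ex) {
    L <- max(ex$end) + pad
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  out
}

# small all-category synthetic fixture used across tests
tiny_fixture <- function(seed = 7L, per_cat = 4L, n_fsm = 4L, sequence = TRUE) {
  spec <- fixture_spec(
    quota = c(ISM = per_cat, NIC = per_cat, NNC = per_cat,
              GENIC_GENOMIC = per_cat, ANTISENSE = per_cat,
              FUSION = per_cat, INTERGENIC = per_cat),
    n_fsm_genes = n_fsm, seed = seed)
  synth_fixture(spec, sequence = sequence)
}

# ---- independent brute-force classifier -----------------------------------
# Per-candidate loops; rebuilds the comparison catalog from scratch for every
# candidate. Used only as a test oracle.

bf_chain <- function(ex) {
  ex <- ex[order(ex$start), ]
  if (nrow(ex) < 2) return(character(0))
  paste(ex$end[-nrow(ex)], ex$start[-1], sep = "-")
}

bf_sites <- function(chain_tokens, strand) {
  if (length(chain_tokens) == 0) return(character(0))
  m <- do.call(rbind, strsplit(chain_tokens, "-", fixed = TRUE))
  lo <- m[, 1]; hi <- m[, 2]
  if (strand == "+") c(paste0("d", lo), paste0("a", hi))
  else c(paste0("d", hi), paste0("a", lo))
}

bf_is_subchain <- function(sub, full) {
  ns <- length(sub); nf <- length(full)
  if (ns == 0 || ns >= nf) return(FALSE)
  for (o in 0:(nf - ns)) {
    if (all(full[(o + 1):(o + ns)] == sub)) return(TRUE)
  }
  FALSE
}

brute_classify_one <- function(ann, cand_id, cand_ann = NULL) {
  src <- if (is.null(cand_ann)) ann else cand_ann
  me_tx <- src$transcripts[src$transcripts$transcript_id == cand_id, ]
  me_ex <- as.data.frame(src$exons[src$exons$transcript_id == cand_id, ])
  my_chain <- bf_chain(me_ex)
  # every reference transcript except the candidate itself
  rtx <- as.data.frame(ann$transcripts)
  rtx <- rtx[rtx$transcript_id != cand_id, ]
  rtx <- rtx[rtx$contig == me_tx$contig, ]
  # gene spans from remaining transcripts
  genes <- list()
  for (g in unique(rtx$gene_id)) {
    mem <- rtx[rtx$gene_id == g, ]
    genes[[g]] <- list(start = min(mem$tx_start), end = max(mem$tx_end),
                       strand = mem$strand[1])
  }
  overl <- function(gs, ge) gs < me_tx$tx_end && ge > me_tx$tx_start
  S <- names(genes)[vapply(genes, function(g)
    g$strand == me_tx$strand && overl(g$start, g$end), logical(1))]
  A <- names(genes)[vapply(genes, function(g)
    g$strand != me_tx$strand && overl(g$start, g$end), logical(1))]
  comp <- rtx[rtx$gene_id %in% S, ]
  comp_chains <- lapply(comp$transcript_id, function(id)
    bf_chain(as.data.frame(ann$exons[ann$exons$transcript_id == id, ])))
  # fusion: candidate exons overlapping >= 2 distinct same-strand genes
  fus_genes <- unique(unlist(lapply(S, function(g) {
    gg <- genes[[g]]
    hit <- any(me_ex$start < gg$end & me_ex$end > gg$start)
    if (hit) g else NULL
  })))
  is_fusion <- length(fus_genes) >= 2
  if (me_tx$n_exons > 1) {
    fsm <- any(vapply(comp_chains, function(cc)
      length(cc) == length(my_chain) && all(cc == my_chain), logical(1)))
    if (fsm) return("FSM")
    ism <- any(vapply(comp_chains, function(cc)
      bf_is_subchain(my_chain, cc), logical(1)))
    if (ism) return("ISM")
    if (is_fusion) return("FUSION")
    if (length(S) > 0) {
      catalog <- unique(unlist(mapply(bf_sites, comp_chains, comp$strand,
                                      SIMPLIFY = FALSE)))
      mine <- bf_sites(my_chain, me_tx$strand)
      return(if (all(mine %in% catalog)) "NIC" else "NNC")
    }
    if (length(A) > 0) return("ANTISENSE")
    return("INTERGENIC")
  }
  # mono-exon cascade
  mono_comp <- comp[comp$n_exons == 1, ]
  if (nrow(mono_comp) > 0) {
    for (i in seq_len(nrow(mono_comp))) {
      ov <- min(me_tx$tx_end, mono_comp$tx_end[i]) -
            max(me_tx$tx_start, mono_comp$tx_start[i])
      if (ov >= 0.8 * (me_tx$tx_end - me_tx$tx_start) &&
          ov >= 0.8 * (mono_comp$tx_end[i] - mono_comp$tx_start[i]))
        return("FSM")
    }
  }
  multi_comp <- comp[comp$n_exons > 1, ]
  for (id in multi_comp$transcript_id) {
    ex <- as.data.frame(ann$exons[ann$exons$transcript_id == id, ])
    if (any(ex$start <= me_tx$tx_start & ex$end >= me_tx$tx_end)) return("ISM")
  }
  if (is_fusion) return("FUSION")
  if (length(S) > 0) return("GENIC_GENOMIC")
  if (length(A) > 0) return("ANTISENSE")
  "INTERGENIC"
}

brute_classify <- function(ann, ids = NULL) {
  if (is.null(ids)) ids <- ann$transcripts$transcript_id
  vapply(ids, function(id) brute_classify_one(ann, id), character(1))
}
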