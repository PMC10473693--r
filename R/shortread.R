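#' Short-read simulation parameters
#'
#' @param n_pairs number of read pairs to simulate.
#' @param read_length mate length in nt (default 100).
#' @param error_rate uniform per-base substitution error rate (default 0.005).
#' @param frag_mean,frag_sd fragment-length Normal parameters (nt).
#' @return a `short_read_params` list.
#' @export
short_read_params <- function(n_pairs, read_length = 100L, error_rate = 0.005,
                              frag_mean = 300, frag_sd = 30) {
  if (read_length < 20L) stop("read_length must be at least 20 nt")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must lie in [0, 1)")
  structure(list(n_pairs = as.integer(n_pairs), read_length = as.integer(read_length),
                 error_rate = error_rate, frag_mean = frag_mean, frag_sd = frag_sd),
            class = "short_read_params")
}

# substitute bases at random positions; returns modified reads
apply_uniform_errors <- function(reads, n_err) {
  idx <- which(n_err > 0L)
  base_raw <- charToRaw("ACGT")
  for (i in idx) {
    r <- charToRaw(reads[i])
    pos <- sample.int(length(r), n_err[i])
    cur <- match(r[pos], base_raw)
    shift <- sample.int(3L, length(pos), replace = TRUE)
    r[pos] <- base_raw[((cur - 1L + shift) %% 4L) + 1L]
    reads[i] <- rawToChar(r)
  }
  reads
}

#' Simulate paired-end short reads matched to the long-read expression
#'
#' Expected pairs per transcript are proportional to TPM times transcript
#' length (one multinomial draw totaling `n_pairs`). Fragment lengths are
#' Normal(`frag_mean`, `frag_sd`) clipped to the transcript; mates of
#' exactly `read_length` nt are taken from the fragment ends, mate 2
#' reverse-complemented; independent uniform per-base substitution errors
#' are applied at `error_rate`. Transcripts shorter than `read_length` are
#' excluded with a warning.
#'
#' @param design a `simulation_design` with TPM.
#' @param ann the complete `annotation`.
#' @param genome named character vector of contig sequences.
#' @param params a [short_read_params()].
#' @param prefix output path prefix; writes `<prefix>_R1.fasta` and
#'   `<prefix>_R2.fasta`.
#' @param seed integer seed.
#' @return truth data.table: `read_id, transcript_id, frag_start, frag_end`
#'   (transcript coordinates, 0-based half-open), `n_err1, n_err2`.
#' @export
simulate_short_reads <- function(design, ann, genome, params, prefix,
                                 seed = 1L) {
  stopifnot(inherits(params, "short_read_params"))
  if (!"TPM" %in% names(design))
    stop("design lacks TPM; run assign_expression() first")
  set.seed(stage_seed(seed, "short_reads"))
  rl <- params$read_length
  des <- copy(design)
  short <- des$length < rl
  if (any(short)) {
    warning(sum(short), " transcript(s) shorter than read length excluded")
    des <- des[!short]
  }
  if (nrow(des) == 0) stop("no transcript long enough for short reads")
  w <- des$TPM * des$length
  cnt <- as.integer(rmultinom(1, params$n_pairs, w))
  seqs <- spliced_sequence(genome, ann, des$transcript_id)
  tx_id <- rep(des$transcript_id, cnt)
  tx_len <- rep(des$length, cnt)
  tx_seq <- rep(seqs, cnt)
  n <- length(tx_id)
  frag <- as.integer(pmin(pmax(round(rnorm(n, params$frag_mean, params$frag_sd)), rl), tx_len))
  fs <- as.integer(floor(runif(n, 0, tx_len - frag + 1)))
  m1 <- substring(tx_seq, fs + 1L, fs + rl)
  m2 <- revcomp(substring(tx_seq, fs + frag - rl + 1L, fs + frag))
  ne1 <- rbinom(n, rl, params$error_rate)
  ne2 <- rbinom(n, rl, params$error_rate)
  m1 <- apply_uniform_errors(m1, ne1)
  m2 <- apply_uniform_errors(m2, ne2)
  rid <- sprintf("SR%07d_%s", seq_len(n), tx_id)
  writeLines(as.vector(rbind(paste0(">", rid, "/1"), m1)),
             paste0(prefix, "_R1.fasta"))
  writeLines(as.vector(rbind(paste0(">", rid, "/2"), m2)),
             paste0(prefix, "_R2.fasta"))
  data.table(read_id = rid, transcript_id = tx_id,
             frag_start = fs, frag_end = fs + frag,
             n_err1 = ne1, n_err2 = ne2)
}

# Transcript-space chunks of each transcript: tx interval [c0, c1) maps to
# genomic [g_s, g_e) on `contig`; chunks are in transcript (5'->3') order.
transcript_chunks <- function(ann, ids) {
  ex <- ann$exons[transcript_id %in% ids]
  tx <- ann$transcripts[transcript_id %in% ids, .(transcript_id, strand)]
  ex <- ex[tx, on = "transcript_id"]
  setorder(ex, transcript_id, start)
  ex[, ord := if (strand[1L] == "+") seq_len(.N) else rev(seq_len(.N)),
     by = transcript_id]
  setorder(ex, transcript_id, ord)
  ex[, width := end - start]
  ex[, c1 := cumsum(width), by = transcript_id]
  ex[, c0 := c1 - width]
  ex[, .(transcript_id, contig, strand, c0, c1, g_s = start, g_e = end)]
}

# Map transcript-space intervals [a, b) to genomic intervals.
map_tx_intervals <- function(chunks, dt) {
  j <- merge(dt, chunks, by = "transcript_id", allow.cartesian = TRUE)
  j <- j[a < c1 & b > c0]
  j[, `:=`(x0 = pmax(a, c0), x1 = pmin(b, c1))]
  j[, `:=`(gs = ifelse(strand == "+", g_s + (x0 - c0), g_e - (x1 - c0)),
           ge = ifelse(strand == "+", g_s + (x1 - c0), g_e - (x0 - c0)))]
  j[, .(id, transcript_id, contig, strand, gs = as.integer(gs), ge = as.integer(ge))]
}

#' Genomic coverage and read starts from a short-read truth table
#'
#' Projects each mate onto the genome through its transcript's exon
#' structure and accumulates per-base coverage and 5'-read-start counts per
#' contig. This is the coverage used for TSS feature computation; it comes
#' directly from the simulation truth, so no aligner is involved.
#'
#' @param truth table from [simulate_short_reads()].
#' @param ann the `annotation` the reads were simulated from.
#' @param genome named character vector (defines contig lengths).
#' @param read_length mate length used in the simulation.
#' @return list with `cov` and `starts`: named lists of integer vectors
#'   (one per contig, length = contig length), and `total_reads`.
#' @export
short_read_coverage <- function(truth, ann, genome, read_length = 100L) {
  rl <- read_length
  ids <- unique(truth$transcript_id)
  chunks <- transcript_chunks(ann, ids)
  mates <- rbind(
    truth[, .(id = paste0(read_id, "/1"), transcript_id,
              a = frag_start, b = frag_start + rl, first = TRUE)],
    truth[, .(id = paste0(read_id, "/2"), transcript_id,
              a = frag_end - rl, b = frag_end, first = FALSE)])
  iv <- map_tx_intervals(chunks, mates[, .(id, transcript_id, a, b)])
  clen <- vapply(genome, nchar, integer(1))
  cov <- lapply(clen, function(L) integer(L))
  for (ctg in unique(iv$contig)) {
    L <- clen[[ctg]]
    delta <- integer(L + 1L)
    sub <- iv[contig == ctg]
    add <- tabulate(sub$gs + 1L, nbins = L + 1L) -
           tabulate(pmin(sub$ge, L) + 1L, nbins = L + 1L)
    cov[[ctg]] <- cumsum(add)[seq_len(L)]
  }
  # 5' genomic start of mate 1 (transcript-orientation start)
  m1 <- mates[first == TRUE]
  pt <- map_tx_intervals(chunks, m1[, .(id, transcript_id, a, b = a + 1L)])
  starts <- lapply(clen, function(L) integer(L))
  for (ctg in unique(pt$contig)) {
    L <- clen[[ctg]]
    starts[[ctg]] <- tabulate(pt[contig == ctg, gs] + 1L, nbins = L)
  }
  list(cov = cov, starts = starts, total_reads = nrow(truth))
}
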