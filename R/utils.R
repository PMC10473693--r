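#' @import data.table
#' @importFrom stats binomial plogis rbinom rnbinom rnorm runif rmultinom
#'   glm.fit glm.control median quantile
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".I", ".SD", ".GRP", "transcript_id", "gene_id", "contig",
  "strand", "start", "end", "tx_start", "tx_end", "n_exons", "chain",
  "g_start", "g_end", "n_tx", "category", "status", "i.strand", "i.start",
  "i.end", "i.transcript_id", "i.gene_id", "cand_id", "ref_id", "own",
  "site", "type", "known", "len", "requested_reads", "TPM", "label",
  "assoc", "width", "ord", "s", "e", "tss", "count", "supporting",
  "distance", "peak_len", "n_sub", "n_ins", "n_del", "read_id"
))

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of sequences over A/C/G/T/N (case preserved).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

# Derive a per-stage RNG seed from a global seed and a stage name.
# Deterministic, stays below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

# Largest-remainder rounding of non-negative weights to integers summing to
# `total`. Ties broken by index order. Optionally force every count >= 1.
largest_remainder <- function(w, total, min_one = FALSE) {
  stopifnot(all(w >= 0), total >= 0)
  n <- length(w)
  if (n == 0L) return(integer(0))
  if (sum(w) == 0) w <- rep(1, n)
  q <- total * w / sum(w)
  fl <- floor(q)
  rem <- as.integer(total - sum(fl))
  cnt <- as.integer(fl)
  if (rem > 0L) {
    idx <- order(q - fl, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
    cnt[idx[seq_len(rem)]] <- cnt[idx[seq_len(rem)]] + 1L
  }
  if (min_one && any(cnt == 0L) && total >= n) {
    # bump zero counts to 1, taking from the largest counts
    while (any(cnt == 0L)) {
      z <- which(cnt == 0L)
      don <- order(cnt, decreasing = TRUE)
      take <- head(don[cnt[don] > 1L], length(z))
      k <- min(length(z), length(take))
      cnt[z[seq_len(k)]] <- 1L
      cnt[take[seq_len(k)]] <- cnt[take[seq_len(k)]] - 1L
    }
  }
  stopifnot(sum(cnt) == total)
  cnt
}

# write a TSV deterministically
write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}
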