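#' Long-read error profiles
#'
#' Per-base substitution, insertion and deletion rates plus a 5' truncation
#' model (probability of truncation; when triggered, the truncated fraction
#' is Uniform(0, `trunc_max`)). Named presets carry the default error rates
#' of the platforms they emulate: PacBio Sequel (substitution 1.731%,
#' deletion 1.090%, insertion 2.204%), ONT cDNA (mismatch 2.8%, insertion
#' 1.9%, deletion 3.5%) and ONT dRNA (mismatch 3.6%, insertion 3.0%,
#' deletion 5.7%).
#'
#' @param preset one of `"pacbio-sequel"`, `"ont-cdna"`, `"ont-drna"`, or
#'   `NULL` for custom rates.
#' @param sub,ins,del custom per-base rates in `[0, 1)`; `sub + del` must be
#'   below 1.
#' @param trunc_prob probability that a read is 5'-truncated (default 0:
#'   full-length reads).
#' @param trunc_max maximum truncated fraction of the transcript.
#' @return an `error_profile` list.
#' @export
error_profile <- function(preset = NULL, sub = 0, ins = 0, del = 0,
                          trunc_prob = 0, trunc_max = 0.5) {
  if (!is.null(preset)) {
    rates <- switch(preset,
      "pacbio-sequel" = c(sub = 0.01731, del = 0.01090, ins = 0.02204),
      "ont-cdna"      = c(sub = 0.028,   ins = 0.019,   del = 0.035),
      "ont-drna"      = c(sub = 0.036,   ins = 0.030,   del = 0.057),
      stop("unknown preset: ", preset))
    sub <- rates[["sub"]]; ins <- rates[["ins"]]; del <- rates[["del"]]
  }
  if (any(c(sub, ins, del) < 0) || any(c(sub, ins, del) >= 1))
    stop("rates must lie in [0, 1)")
  if (sub + del >= 1) stop("sub + del must be below 1")
  structure(list(sub = sub, ins = ins, del = del,
                 trunc_prob = trunc_prob, trunc_max = trunc_max),
            class = "error_profile")
}

# integer codes <-> bases
seq_to_int <- function(s) {
  x <- utf8ToInt(s)
  out <- integer(length(x))
  out[x == 65L] <- 1L; out[x == 67L] <- 2L
  out[x == 71L] <- 3L; out[x == 84L] <- 4L
  out
}
int_to_seq <- function(v) {
  paste(DNA_BASES[v], collapse = "")
}

#' Introduce sequencing errors into a sequence
#'
#' Per-base events: each base is deleted with probability `del`, substituted
#' (to a uniformly chosen different base) with probability `sub`, or kept;
#' independently, a uniformly random base is inserted after each position
#' with probability `ins`. Exact edit counts are returned.
#'
#' @param seq a non-empty nucleotide string.
#' @param profile an [error_profile()].
#' @return list with `read` (mutated string), `n_sub`, `n_ins`, `n_del`.
#' @export
mutate_sequence <- function(seq, profile) {
  x <- seq_to_int(seq)
  n <- length(x)
  if (n == 0L) stop("empty sequence")
  u <- runif(n)
  del <- u < profile$del
  sub <- !del & u < profile$del + profile$sub
  ins <- runif(n) < profile$ins
  y <- x
  if (any(sub)) {
    # uniform among the three other bases
    shift <- sample.int(3L, sum(sub), replace = TRUE)
    y[sub] <- ((x[sub] - 1L + shift) %% 4L) + 1L
  }
  keep <- !del
  n_ins <- sum(ins)
  if (n_ins > 0L) {
    ins_base <- sample.int(4L, n_ins, replace = TRUE)
    key <- c(which(keep), which(ins) + 0.5)
    vals <- c(y[keep], ins_base)
    out <- vals[order(key)]
  } else {
    out <- y[keep]
  }
  list(read = int_to_seq(out), n_sub = sum(sub), n_ins = n_ins, n_del = sum(del))
}

#' Simulate long reads with a ground-truth table
#'
#' Emits exactly `requested_reads` reads per design transcript, drawn from
#' the spliced transcript sequence over the complete annotation (novel
#' transcripts included), optionally 5'-truncated, then mutated according
#' to the error profile. FASTQ qualities are a constant placeholder
#' (Q20, `"5"`); downstream evaluation never uses them.
#'
#' @param design a `simulation_design` with `requested_reads`.
#' @param ann the complete `annotation`.
#' @param genome named character vector of contig sequences.
#' @param profile an [error_profile()].
#' @param fastq output FASTQ path.
#' @param seed integer seed; the same seed gives byte-identical FASTQ.
#' @return data.table truth table `read_id, transcript_id, n_sub, n_ins,
#'   n_del, trunc5, trunc3`, one row per read.
#' @export
simulate_long_reads <- function(design, ann, genome, profile, fastq,
                                seed = 1L) {
  if (!"requested_reads" %in% names(design))
    stop("design lacks requested_reads; run assign_expression() first")
  missing <- setdiff(design$transcript_id, ann$transcripts$transcript_id)
  if (length(missing) > 0)
    stop("design transcript(s) absent from annotation: ",
         paste(head(missing, 5), collapse = ", "))
  set.seed(stage_seed(seed, "long_reads"))
  des <- design[requested_reads > 0]
  seqs <- spliced_sequence(genome, ann, des$transcript_id)
  total <- sum(des$requested_reads)
  fq <- vector("list", total)
  truth <- vector("list", total)
  k <- 0L
  for (i in seq_len(nrow(des))) {
    s <- seqs[[i]]
    slen <- nchar(s)
    for (r in seq_len(des$requested_reads[i])) {
      k <- k + 1L
      trunc5 <- 0L
      src <- s
      if (profile$trunc_prob > 0 && runif(1) < profile$trunc_prob) {
        trunc5 <- as.integer(floor(runif(1, 0, profile$trunc_max) * slen))
        if (trunc5 >= slen) trunc5 <- slen - 1L
        if (trunc5 > 0L) src <- substring(s, trunc5 + 1L, slen)
      }
      m <- mutate_sequence(src, profile)
      rid <- sprintf("LR%06d_%s", k, des$transcript_id[i])
      fq[[k]] <- c(paste0("@", rid), m$read, "+",
                   strrep("5", nchar(m$read)))
      truth[[k]] <- data.table(read_id = rid,
                               transcript_id = des$transcript_id[i],
                               n_sub = m$n_sub, n_ins = m$n_ins,
                               n_del = m$n_del, trunc5 = trunc5, trunc3 = 0L)
    }
  }
  writeLines(unlist(fq), fastq)
  rbindlist(truth)
}

#' Write a long-read truth table
#' @param truth table from [simulate_long_reads()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) write_tsv(truth, path)
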