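NOVEL_CATEGORIES <- c("ISM", "NIC", "NNC", "GENIC_GENOMIC", "ANTISENSE",
                      "FUSION", "INTERGENIC")

#' Novelty request
#'
#' Per-category counts of transcripts to be removed from the annotation and
#' simulated as novel, plus the number of known (FSM) transcripts to express.
#' Only transcripts at least `min_length` nt long are eligible, to avoid
#' simulating small RNAs.
#'
#' @param ism,nic,nnc,genic_genomic,antisense,fusion,intergenic requested
#'   counts per novel structural category.
#' @param n_known number of known transcripts (potential FSM) selected for
#'   expression; `NA` expresses every remaining transcript.
#' @param min_length minimum eligible transcript length in nt (default 200).
#' @return a `novelty_request` list.
#' @export
novelty_request <- function(ism = 0, nic = 0, nnc = 0, genic_genomic = 0,
                            antisense = 0, fusion = 0, intergenic = 0,
                            n_known = NA_integer_, min_length = 200) {
  counts <- c(ISM = ism, NIC = nic, NNC = nnc, GENIC_GENOMIC = genic_genomic,
              ANTISENSE = antisense, FUSION = fusion, INTERGENIC = intergenic)
  if (any(counts < 0)) stop("requested counts must be non-negative")
  if (min_length < 0) stop("min_length must be non-negative")
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, n_known = n_known,
                 min_length = min_length), class = "novelty_request")
}

eligible_pool <- function(index, cat, min_length) {
  index[category == cat & length >= min_length, transcript_id]
}

#' Select novel transcripts per requested category
#'
#' Uniformly random (seeded) choice of the requested number of transcripts
#' per category among eligible candidates (matching category, length at
#' least `min_length`). The remaining transcripts are known; of these,
#' `n_known` potential-FSM transcripts are selected for expression (all
#' known transcripts when `n_known` is `NA`).
#'
#' @param index classification table from [classify_annotation()].
#' @param request a [novelty_request()].
#' @param seed integer seed; the same seed reproduces the same selection.
#' @param iso_dist optional integer multiset of expressed-isoforms-per-gene
#'   counts; when supplied, the known transcripts to express are chosen gene
#'   by gene with the per-gene number of expressed isoforms drawn from this
#'   empirical distribution (capped at the gene's transcript count).
#' @return a `simulation_design` data.table with columns `transcript_id`,
#'   `gene_id`, `status` (known/novel), `category`, `length`, `n_exons`;
#'   one row per simulated (expressed) transcript. The request and seed are
#'   kept as attributes for the reduction stage.
#' @export
select_novel <- function(index, request, seed = 1L, iso_dist = NULL) {
  stopifnot(inherits(request, "novelty_request"))
  set.seed(stage_seed(seed, "select_novel"))
  novel <- vector("list", length(NOVEL_CATEGORIES))
  names(novel) <- NOVEL_CATEGORIES
  for (cat in NOVEL_CATEGORIES) {
    k <- request$counts[[cat]]
    if (k == 0L) { novel[[cat]] <- character(0); next }
    pool <- eligible_pool(index, cat, request$min_length)
    if (length(pool) < k)
      stop(sprintf("category %s: requested %d but only %d eligible candidates (length >= %d)",
                   cat, k, length(pool), request$min_length))
    novel[[cat]] <- sample(pool, k)
  }
  novel_ids <- unlist(novel, use.names = FALSE)
  known_idx <- index[!transcript_id %in% novel_ids]
  if (is.na(request$n_known)) {
    known_ids <- known_idx$transcript_id
  } else {
    pool <- known_idx[category == "FSM" & length >= request$min_length]
    if (nrow(pool) < request$n_known)
      stop(sprintf("known (FSM): requested %d but only %d eligible candidates",
                   request$n_known, nrow(pool)))
    known_ids <- if (is.null(iso_dist)) sample(pool$transcript_id, request$n_known)
                 else select_known_by_complexity(pool, request$n_known, iso_dist)
  }
  des <- rbind(
    index[match(novel_ids, transcript_id),
          .(transcript_id, gene_id, status = "novel", category, length, n_exons)],
    index[match(known_ids, transcript_id),
          .(transcript_id, gene_id, status = "known", category, length, n_exons)])
  setattr(des, "request", request)
  setattr(des, "seed", seed)
  setattr(des, "class", c("simulation_design", class(des)))
  des
}

# Gene-by-gene known-transcript selection reproducing an empirical
# expressed-isoforms-per-gene distribution.
select_known_by_complexity <- function(pool, n_known, iso_dist) {
  e <- empirical_ecdf(iso_dist)
  genes <- pool[, .(ids = list(transcript_id)), by = gene_id]
  genes <- genes[sample(.N)]
  draws <- ecdf_quantile(e, runif(nrow(genes)))
  picked <- character(0)
  for (i in seq_len(nrow(genes))) {
    ids <- genes$ids[[i]]
    k <- min(length(ids), draws[i])
    if (k > 0L) picked <- c(picked, sample(ids, k))
    if (length(picked) >= n_known) break
  }
  if (length(picked) < n_known) {
    rest <- setdiff(pool$transcript_id, picked)
    picked <- c(picked, sample(rest, n_known - length(picked)))
  }
  picked[seq_len(n_known)]
}

#' Remove novel transcripts and verify their designated categories
#'
#' Produces the reduced annotation lacking every designated-novel transcript
#' and verifies, by re-classifying each removed transcript against the
#' reduced annotation, that it still yields its designated category (the
#' ground-truth contract of the simulation). Violators are swapped for
#' fresh eligible candidates (seeded, bounded retries); genes left without
#' transcripts are dropped.
#'
#' @param ann the full `annotation`.
#' @param design a `simulation_design` from [select_novel()].
#' @param index the classification table used for the selection.
#' @param max_retry_factor retry budget: `max_retry_factor` times the
#'   requested count per category; exhaustion is an error, never silent
#'   under-delivery.
#' @return list with elements `reduced` (annotation), `design` (possibly
#'   with swapped novel transcripts) and `verification` (per removed
#'   transcript, its designated and re-classified category).
#' @export
reduce_annotation <- function(ann, design, index, max_retry_factor = 10L) {
  request <- attr(design, "request")
  seed <- attr(design, "seed")
  if (is.null(request)) stop("design lacks its novelty request attribute")
  set.seed(stage_seed(seed, "reduce_swap"))
  des <- copy(design)
  burned <- des[status == "novel", transcript_id]
  budget <- pmax(attr(design, "request")$counts, 0L) * max_retry_factor
  names(budget) <- NOVEL_CATEGORIES
  repeat {
    novel <- des[status == "novel"]
    reduced <- subset_annotation(ann, novel$transcript_id, keep = FALSE)
    recls <- classify_transcripts(subset_annotation(ann, novel$transcript_id),
                                  reduced, self_exclude = FALSE)
    ver <- merge(novel[, .(transcript_id, designated = category)],
                 recls[, .(transcript_id, observed = category)],
                 by = "transcript_id")
    bad <- ver[designated != observed]
    if (nrow(bad) == 0L) {
      ver <- ver[match(novel$transcript_id, transcript_id)]
      return(list(reduced = reduced, design = des, verification = ver))
    }
    for (i in seq_len(nrow(bad))) {
      cat <- bad[i, ]
      dcat <- novel[transcript_id == cat$transcript_id, category]
      if (budget[[dcat]] <= 0L)
        stop("retry budget exhausted; unverifiable designation(s): ",
             paste(bad$transcript_id, collapse = ", "))
      pool <- setdiff(eligible_pool(index, dcat, request$min_length), burned)
      if (length(pool) == 0L)
        stop(sprintf("category %s: no replacement candidates left for %s",
                     dcat, cat$transcript_id))
      repl <- sample(pool, 1L)
      burned <- c(burned, repl)
      budget[[dcat]] <- budget[[dcat]] - 1L
      des[transcript_id == cat$transcript_id,
          `:=`(transcript_id = repl,
               gene_id = index[transcript_id == repl, gene_id],
               length = index[transcript_id == repl, length],
               n_exons = index[transcript_id == repl, n_exons])]
    }
  }
}

#' Empirical cumulative distribution over observed counts
#'
#' @param counts numeric vector of observed values (at least one positive).
#' @return an `empirical_ecdf` list with sorted support `values` and
#'   nondecreasing cumulative `probs` ending at 1.
#' @export
empirical_ecdf <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0 || all(counts <= 0))
    stop("ECDF requires at least one positive count")
  tab <- table(counts)
  values <- as.numeric(names(tab))
  probs <- cumsum(as.numeric(tab)) / sum(tab)
  structure(list(values = values, probs = probs), class = "empirical_ecdf")
}

#' Inverse-transform quantile of an empirical ECDF
#'
#' Returns the smallest support value whose cumulative probability is at
#' least `u`; nondecreasing in `u`.
#'
#' @param ecdf an [empirical_ecdf()].
#' @param u numeric vector of probabilities in `[0, 1]`.
#' @return numeric vector of support values.
#' @export
ecdf_quantile <- function(ecdf, u) {
  stopifnot(inherits(ecdf, "empirical_ecdf"))
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  idx <- findInterval(u, ecdf$probs, left.open = TRUE) + 1L
  idx <- pmin(idx, length(ecdf$values))
  ecdf$values[idx]
}

#' Expression models
#'
#' Three computation modes for assigning expression to simulated
#' transcripts: `equal` gives every transcript the same count; `custom`
#' draws from two negative binomial distributions (one for known, one for
#' novel transcripts, parameterized by `size` and `prob`); `sample` draws
#' by inverse-transform sampling from an empirical count distribution, with
#' the novel-transcript quantile biased by `diff_exp` (novel transcripts
#' use `u' = u^(1 + diff_exp)`, so larger values push novel expression
#' down; 0 recovers the unbiased sampler).
#'
#' @param size_known,prob_known,size_novel,prob_novel negative binomial
#'   parameters (`size > 0`, `0 < prob <= 1`).
#' @param counts observed raw counts defining the empirical distribution.
#' @param diff_exp non-negative bias between known and novel expression.
#' @param iso_complex logical flag recorded for the design stage.
#' @return an `expression_model` list.
#' @name expression_model
NULL

#' @rdname expression_model
#' @export
expression_equal <- function() {
  structure(list(mode = "equal"), class = "expression_model")
}

#' @rdname expression_model
#' @export
expression_custom <- function(size_known, prob_known, size_novel, prob_novel) {
  ok <- function(s, p) is.finite(s) && s > 0 && is.finite(p) && p > 0 && p <= 1
  if (!ok(size_known, prob_known) || !ok(size_novel, prob_novel))
    stop("invalid negative binomial parameters: need size > 0 and 0 < prob <= 1")
  structure(list(mode = "custom", known = c(size = size_known, prob = prob_known),
                 novel = c(size = size_novel, prob = prob_novel)),
            class = "expression_model")
}

#' @rdname expression_model
#' @export
expression_sample <- function(counts, diff_exp = 0, iso_complex = FALSE) {
  if (diff_exp < 0) stop("diff_exp must be non-negative")
  structure(list(mode = "sample", ecdf = empirical_ecdf(counts),
                 diff_exp = diff_exp, iso_complex = iso_complex,
                 counts = counts),
            class = "expression_model")
}

#' Assign read counts and TPM to a simulation design
#'
#' Draws per-transcript expression according to the model, then scales to
#' exactly `total_long_reads` reads by largest-remainder rounding (every
#' simulated transcript keeps at least one read). TPM is derived from the
#' final counts normalized to 1e6.
#'
#' @param design a `simulation_design`.
#' @param model an expression model (see [expression_equal()]).
#' @param total_long_reads total number of long reads to distribute.
#' @param seed integer seed.
#' @return the design with `requested_reads` and `TPM` columns added.
#' @export
assign_expression <- function(design, model, total_long_reads, seed = 1L) {
  stopifnot(inherits(model, "expression_model"))
  n <- nrow(design)
  if (total_long_reads < n)
    stop("total_long_reads must be at least the number of simulated transcripts")
  set.seed(stage_seed(seed, "expression"))
  des <- copy(design)
  w <- switch(model$mode,
    equal = rep(1, n),
    custom = {
      is_novel <- des$status == "novel"
      w <- numeric(n)
      w[!is_novel] <- rnbinom(sum(!is_novel), size = model$known[["size"]],
                              prob = model$known[["prob"]])
      w[is_novel] <- rnbinom(sum(is_novel), size = model$novel[["size"]],
                             prob = model$novel[["prob"]])
      pmax(w, 0.5)  # keep zero draws selectable before integer repair
    },
    sample = {
      u <- runif(n)
      is_novel <- des$status == "novel"
      u[is_novel] <- u[is_novel]^(1 + model$diff_exp)
      ecdf_quantile(model$ecdf, u)
    },
    stop("unknown expression mode"))
  counts <- largest_remainder(w, total_long_reads, min_one = TRUE)
  des[, requested_reads := counts]
  des[, TPM := counts / sum(counts) * 1e6]
  setattr(des, "class", class(design))
  des
}

#' Write / read a design table
#'
#' Tab-separated `transcript_id status category requested_reads TPM` (plus
#' `gene_id`, `length`, `n_exons` kept for the evaluation stage).
#'
#' @param design a `simulation_design`.
#' @param path file path.
#' @return `path` (write) or a data.table (read).
#' @export
write_design <- function(design, path) {
  cols <- intersect(c("transcript_id", "status", "category", "requested_reads",
                      "TPM", "gene_id", "length", "n_exons"), names(design))
  write_tsv(design[, cols, with = FALSE], path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  fread(path, sep = "\t")
}
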