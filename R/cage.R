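#' TSS support features from short-read coverage
#'
#' For each transcript's TSS, computes the two features of the logistic
#' TSS-support model: `tss_ratio`, the ratio of short-read coverage in the
#' 100-bp window downstream (into the transcript body) over the 100-bp
#' window upstream of the TSS, with a pseudocount of +1 added to both
#' window sums; and `tss_cov_prop`, the number of reads starting in the
#' 20-bp window downstream of the TSS divided by the total number of reads.
#' Windows are strand-aware and clipped (and flagged) at contig edges.
#'
#' @param ann an `annotation`.
#' @param transcript_ids transcripts whose TSS to profile.
#' @param coverage list from [short_read_coverage()].
#' @return data.table `transcript_id, tss, tss_ratio, tss_cov_prop, clipped`.
#' @export
tss_features <- function(ann, transcript_ids, coverage) {
  tx <- ann$transcripts[match(transcript_ids, transcript_id)]
  if (anyNA(tx$gene_id)) stop("unknown transcript id(s)")
  total <- coverage$total_reads
  out <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    ctg <- tx$contig[i]
    cv <- coverage$cov[[ctg]]
    st <- coverage$starts[[ctg]]
    if (is.null(cv)) stop("no coverage for contig ", ctg)
    L <- length(cv)
    plus <- tx$strand[i] == "+"
    tss <- if (plus) tx$tx_start[i] else tx$tx_end[i] - 1L
    # downstream = into the transcript body
    if (plus) {
      dwn <- c(tss, tss + 100L); ups <- c(tss - 100L, tss); w20 <- c(tss, tss + 20L)
    } else {
      dwn <- c(tss - 99L, tss + 1L); ups <- c(tss + 1L, tss + 101L); w20 <- c(tss - 19L, tss + 1L)
    }
    clipped <- dwn[1] < 0L || ups[1] < 0L || dwn[2] > L || ups[2] > L
    wsum <- function(v, w) {
      lo <- max(w[1], 0L); hi <- min(w[2], L)
      if (hi <= lo) 0L else sum(v[(lo + 1L):hi])
    }
    ratio <- (wsum(cv, dwn) + 1) / (wsum(cv, ups) + 1)
    prop <- if (total > 0) wsum(st, w20) / total else 0
    out[[i]] <- data.table(transcript_id = tx$transcript_id[i], tss = tss,
                           tss_ratio = ratio, tss_cov_prop = prop,
                           clipped = clipped)
  }
  rbindlist(out)
}

cage_design_matrix <- function(features, pseudo) {
  cbind(log(features$tss_ratio), log(features$tss_cov_prop + pseudo))
}

#' Fit the logistic TSS-support model
#'
#' Maximum-likelihood logistic regression of CAGE-peak presence at a TSS on
#' the log-transformed TSS ratio and log-transformed TSS coverage
#' proportion, fitted by iteratively reweighted least squares (gradient
#' tolerance 1e-8), with k-fold cross-validated accuracy at threshold 0.5.
#' Complete separation triggers a ridge-stabilized fit (glmnet, alpha = 0)
#' with a warning. A pseudocount (default 1e-4) keeps the log of a zero
#' coverage proportion finite; it is stored in the model and reused at
#' prediction time.
#'
#' @param features data.table with `tss_ratio` and `tss_cov_prop`.
#' @param labels logical/0-1 vector: CAGE peak present at the TSS.
#' @param k number of cross-validation folds (default 10).
#' @param pseudo pseudocount added to `tss_cov_prop` before log transform.
#' @param seed seed for fold assignment.
#' @return a `cage_model` list with `beta` (intercept, log tss_ratio
#'   coefficient, log tss_cov_prop coefficient), `cv_accuracy`, `pseudo`.
#' @export
fit_cage_model <- function(features, labels, k = 10L, pseudo = 1e-4,
                           seed = 1L) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  n <- length(y)
  if (n < k) stop("need at least k observations")
  X <- cage_design_matrix(features, pseudo)
  fit_one <- function(X, y) {
    sep <- FALSE
    fit <- withCallingHandlers(
      glm.fit(cbind(1, X), y, family = binomial(),
              control = glm.control(epsilon = 1e-8, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    beta <- fit$coefficients
    if (sep || anyNA(beta) || any(abs(beta) > 1e3)) {
      warning("separation detected; using ridge-stabilized logistic fit")
      g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = 1e-3, standardize = FALSE)
      beta <- as.numeric(c(g$a0, as.matrix(g$beta)))
    }
    beta
  }
  beta <- fit_one(X, y)
  set.seed(stage_seed(seed, "cage_cv"))
  fold <- sample(rep(seq_len(k), length.out = n))
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) return(NA_real_)
    b <- suppressWarnings(fit_one(X[tr, , drop = FALSE], y[tr]))
    p <- plogis(cbind(1, X[!tr, , drop = FALSE]) %*% b)
    mean((p >= 0.5) == (y[!tr] == 1L))
  }, numeric(1))
  structure(list(beta = unname(beta), cv_accuracy = mean(acc, na.rm = TRUE),
                 pseudo = pseudo), class = "cage_model")
}

#' Constant-probability TSS support model
#'
#' A degenerate model assigning the same support probability to every TSS;
#' useful for fully controlled simulations.
#' @param p support probability.
#' @return a `cage_model`.
#' @export
cage_model_constant <- function(p) {
  stopifnot(p >= 0, p <= 1)
  structure(list(beta = NULL, constant = p, cv_accuracy = NA_real_,
                 pseudo = 1e-4), class = "cage_model")
}

#' Predict TSS support probability
#'
#' `pi = plogis(beta0 + beta1 * log(tss_ratio) + beta2 * log(tss_cov_prop))`
#' (with the model's stored pseudocount inside the second log).
#'
#' @param model a `cage_model`.
#' @param features data.table with `tss_ratio`, `tss_cov_prop`.
#' @return numeric vector of probabilities.
#' @export
predict_tss_support <- function(model, features) {
  stopifnot(inherits(model, "cage_model"))
  if (!is.null(model$constant)) return(rep(model$constant, nrow(features)))
  X <- cage_design_matrix(features, model$pseudo)
  as.numeric(plogis(cbind(1, X) %*% model$beta))
}

#' Profile CAGE peaks against annotated TSS
#'
#' For each peak, its length and the signed distance from the peak center
#' to the nearest annotated TSS (strand-aware: positive = downstream of
#' that TSS), and whether the peak interval overlaps any TSS. The
#' supporting and non-supporting rows form the two empirical bivariate
#' (length, distance) distributions used by the peak simulator.
#'
#' @param peaks data.table with `contig, start, end` (0-based half-open).
#' @param ann an `annotation`.
#' @return data.table `contig, start, end, peak_len, distance, supporting`.
#' @export
cage_profile <- function(peaks, ann) {
  pk <- as.data.table(peaks)[, .(contig = as.character(contig),
                                 start = as.integer(start), end = as.integer(end))]
  if (any(pk$end <= pk$start)) stop("peak with non-positive width")
  tx <- ann$transcripts
  tsstab <- tx[, .(contig, strand,
                   tss = ifelse(strand == "+", tx_start, tx_end - 1L))]
  tsstab <- unique(tsstab)
  pk[, peak_len := end - start]
  pk[, center := start + peak_len %/% 2L]
  res <- vector("list", nrow(pk))
  for (i in seq_len(nrow(pk))) {
    cand <- tsstab[contig == pk$contig[i]]
    if (nrow(cand) == 0) {
      res[[i]] <- data.table(distance = NA_integer_, supporting = FALSE)
      next
    }
    d_gen <- pk$center[i] - cand$tss
    j <- which.min(abs(d_gen))
    dist <- if (cand$strand[j] == "+") d_gen[j] else -d_gen[j]
    sup <- any(cand$tss >= pk$start[i] & cand$tss < pk$end[i])
    res[[i]] <- data.table(distance = as.integer(dist), supporting = sup)
  }
  cbind(pk[, .(contig, start, end, peak_len)], rbindlist(res))
}

#' Simulate CAGE peaks
#'
#' For each expressed transcript TSS, support is drawn Bernoulli(pi) from
#' the model; supported TSS receive one peak whose (length, center
#' distance) is drawn jointly - as a paired row, preserving the empirical
#' dependence - from the supporting bivariate sample. Additional
#' non-supporting peaks, with (length, distance) from the non-supporting
#' sample and anchored at randomly chosen TSS, are added until they make up
#' `false_fraction` of all peaks. Distances are strand-aware (positive =
#' downstream). Output is 0-based half-open, BED-ready.
#'
#' @param design a `simulation_design`.
#' @param ann the complete `annotation`.
#' @param model a `cage_model` (fitted or constant).
#' @param ecdfs list with data.tables `supporting` and `nonsupporting`,
#'   each with columns `peak_len` and `distance` (e.g. from
#'   [cage_profile()], split on `supporting`).
#' @param false_fraction requested fraction of peaks not supporting any
#'   TSS, in `[0, 1)`.
#' @param features optional TSS features aligned to `design` rows (needed
#'   unless the model is constant).
#' @param seed integer seed.
#' @return data.table of peaks: `contig, start, end, name, score, strand,
#'   supports_tss`.
#' @export
simulate_cage_peaks <- function(design, ann, model, ecdfs, false_fraction = 0,
                                features = NULL, seed = 1L) {
  if (false_fraction < 0 || false_fraction >= 1)
    stop("false_fraction must lie in [0, 1)")
  if (nrow(ecdfs$supporting) == 0) stop("empty supporting (length, distance) sample")
  set.seed(stage_seed(seed, "cage_peaks"))
  tx <- ann$transcripts[match(design$transcript_id, transcript_id)]
  tsspos <- ifelse(tx$strand == "+", tx$tx_start, tx$tx_end - 1L)
  pi_hat <- if (!is.null(model$constant)) rep(model$constant, nrow(tx)) else {
    if (is.null(features)) stop("features required for a fitted model")
    predict_tss_support(model, features)
  }
  sup <- runif(nrow(tx)) < pi_hat
  place <- function(tss, strand, smp) {
    d <- ifelse(strand == "+", smp$distance, -smp$distance)
    center <- tss + d
    start <- pmax(center - smp$peak_len %/% 2L, 0L)
    data.table(start = as.integer(start),
               end = as.integer(start + smp$peak_len))
  }
  n_true <- sum(sup)
  peaks <- list()
  if (n_true > 0) {
    smp <- ecdfs$supporting[sample(.N, n_true, replace = TRUE)]
    p <- place(tsspos[sup], tx$strand[sup], smp)
    peaks$true <- data.table(contig = tx$contig[sup], p, supports_tss = TRUE)
  }
  n_false <- if (false_fraction > 0)
    as.integer(round(false_fraction * n_true / (1 - false_fraction))) else 0L
  if (n_false > 0) {
    if (nrow(ecdfs$nonsupporting) == 0) stop("empty non-supporting sample")
    anchor <- sample(length(tsspos), n_false, replace = TRUE)
    smp <- ecdfs$nonsupporting[sample(.N, n_false, replace = TRUE)]
    p <- place(tsspos[anchor], tx$strand[anchor], smp)
    peaks$false <- data.table(contig = tx$contig[anchor], p, supports_tss = FALSE)
  }
  out <- rbindlist(peaks)
  if (nrow(out) == 0) return(data.table(contig = character(0), start = integer(0),
                                        end = integer(0), name = character(0),
                                        score = integer(0), strand = character(0),
                                        supports_tss = logical(0)))
  out[, `:=`(name = sprintf("peak%06d", .I), score = 0L, strand = ".")]
  out[, .(contig, start, end, name, score, strand, supports_tss)]
}

#' Write peaks as BED6
#' @param peaks table from [simulate_cage_peaks()] or with compatible columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  data.table::fwrite(peaks[, .(contig, start, end, name, score, strand)],
                     path, sep = "\t", quote = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a BED file (first six columns)
#' @param path BED path (0-based half-open).
#' @return data.table with `contig, start, end` (+ name/score/strand if present).
#' @export
read_bed <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE)
  setnames(dt, seq_len(min(6L, ncol(dt))),
           c("contig", "start", "end", "name", "score", "strand")[seq_len(min(6L, ncol(dt)))])
  dt
}
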