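#' Match reconstructed transcript models against the simulated ground truth
#'
#' A reconstructed multi-exon model is a true positive (TP) for a simulated
#' transcript S when its junction chain matches S exactly and both its ends
#' lie within `end_tolerance` nt of S's ends; a partial true positive (PTP)
#' when the chain matches but an end exceeds the tolerance; otherwise a
#' false positive (FP). Mono-exon models are matched by both ends within
#' tolerance to a simulated mono-exon transcript. Every simulated
#' transcript claimed by no TP is a false negative (FN). When several
#' models would be TP for the same S, the first in input order is the TP
#' and later duplicates are FP.
#'
#' @param recon reconstructed `annotation` (e.g. [read_gtf()] of a
#'   pipeline's output).
#' @param design design table listing every simulated transcript with
#'   `status` and `category`.
#' @param full the complete `annotation` (source of simulated coordinates).
#' @param reduced the reduced `annotation` (used to assign a structural
#'   category to FP models).
#' @param end_tolerance nt tolerance on TSS/TTS (default 50).
#' @return list with `labels` (per reconstructed model: label, matched
#'   simulated transcript, category), `fn` (per simulated transcript:
#'   detected flag) and `counts` (an `eval_counts` table by stratum).
#' @export
match_models <- function(recon, design, full, reduced, end_tolerance = 50L) {
  sim <- full$transcripts[match(design$transcript_id, transcript_id)]
  if (anyNA(sim$gene_id))
    stop("design transcript(s) absent from the full annotation")
  sim <- cbind(sim, design[, .(status, sim_category = category)])
  rec <- copy(recon$transcripts)
  known_contigs <- unique(sim$contig)
  if (nrow(rec) > 0 && any(!rec$contig %in% known_contigs))
    warning("reconstructed transcript(s) on unknown contig treated as FP")

  simkey <- sim[, .(transcript_id, contig, strand, chain, tx_start, tx_end,
                    n_exons, status, sim_category)]
  claimed <- new.env(parent = emptyenv())
  labels <- character(nrow(rec))
  matched <- character(nrow(rec))
  mcat <- character(nrow(rec))
  # candidate chain matches for all reconstructed models at once
  rec[, rid := seq_len(.N)]
  multi <- rec[n_exons > 1L]
  cand_multi <- merge(multi[, .(rid, contig, strand, chain, r_s = tx_start, r_e = tx_end)],
                      simkey[n_exons > 1L],
                      by = c("contig", "strand", "chain"), allow.cartesian = TRUE)
  mono <- rec[n_exons == 1L]
  cand_mono <- merge(mono[, .(rid, contig, strand, r_s = tx_start, r_e = tx_end)],
                     simkey[n_exons == 1L],
                     by = c("contig", "strand"), allow.cartesian = TRUE)
  cand_mono <- cand_mono[abs(r_s - tx_start) <= end_tolerance &
                           abs(r_e - tx_end) <= end_tolerance]
  cand <- rbind(cand_multi, cand_mono, fill = TRUE)
  if (nrow(cand) > 0) {
    cand[, within := abs(r_s - tx_start) <= end_tolerance &
                     abs(r_e - tx_end) <= end_tolerance]
    setorder(cand, rid)
  }
  cand_by_rid <- if (nrow(cand) > 0) split(cand, by = "rid") else list()
  for (i in seq_len(nrow(rec))) {
    cc <- cand_by_rid[[as.character(i)]]
    if (is.null(cc) || nrow(cc) == 0) { labels[i] <- "FP"; next }
    hit <- cc[within == TRUE]
    if (nrow(hit) > 0) {
      free <- hit[!vapply(hit$transcript_id, exists, logical(1), envir = claimed)]
      if (nrow(free) > 0) {
        s <- free[1L]
        assign(s$transcript_id, TRUE, envir = claimed)
        labels[i] <- "TP"; matched[i] <- s$transcript_id; mcat[i] <- s$sim_category
      } else {
        labels[i] <- "FP"  # duplicate of an already-claimed TP match
      }
    } else {
      s <- cc[1L]
      labels[i] <- "PTP"; matched[i] <- s$transcript_id; mcat[i] <- s$sim_category
    }
  }
  # categorize FP models against the reduced annotation
  fp_idx <- which(labels == "FP")
  if (length(fp_idx) > 0) {
    fp_ids <- rec$transcript_id[fp_idx]
    onref <- rec$contig[fp_idx] %in% names_or_empty(reduced)
    if (any(onref)) {
      cls <- classify_candidate(subset_annotation(recon, fp_ids[onref]), reduced)
      mcat[fp_idx[onref]] <- cls[match(fp_ids[onref], cls$transcript_id), category]
    }
    mcat[fp_idx[!onref]] <- "INTERGENIC"
  }
  lab <- data.table(transcript_id = rec$transcript_id, label = labels,
                    matched = ifelse(nzchar(matched), matched, NA_character_),
                    category = mcat)
  det <- vapply(simkey$transcript_id, exists, logical(1), envir = claimed)
  ptp_of <- unique(lab[label == "PTP" & !is.na(matched), matched])
  fn <- data.table(transcript_id = simkey$transcript_id,
                   status = simkey$status, category = simkey$sim_category,
                   detected = det, ptp_detected = simkey$transcript_id %in% ptp_of)
  list(labels = lab, fn = fn,
       counts = tally_counts(lab, fn))
}

names_or_empty <- function(ann) unique(ann$exons$contig)

# Tally TP/PTP/FP/FN by stratum: overall, known/novel, and per category.
tally_counts <- function(labels, fn) {
  novel_cats <- setdiff(STRUCTURAL_CATEGORIES, "FSM")
  strata <- c("all", "known", "novel", STRUCTURAL_CATEGORIES)
  res <- lapply(strata, function(s) {
    if (s == "all") {
      lsel <- rep(TRUE, nrow(labels)); fsel <- rep(TRUE, nrow(fn))
    } else if (s == "known") {
      lsel <- labels$category == "FSM"; fsel <- fn$status == "known"
    } else if (s == "novel") {
      lsel <- labels$category %in% novel_cats; fsel <- fn$status == "novel"
    } else {
      lsel <- labels$category == s; fsel <- fn$category == s
    }
    data.table(stratum = s,
               TP = sum(labels$label[lsel] == "TP"),
               PTP = sum(labels$label[lsel] == "PTP"),
               FP = sum(labels$label[lsel] == "FP"),
               FN = sum(fsel & !fn$detected))
  })
  rbindlist(res)
}

#' Accuracy metrics from TP/PTP/FP/FN counts
#'
#' Sensitivity `Sn = TP / (TP + FN)`, precision `Pr = TP / (TP + FP)`,
#' `F1 = TP / (TP + (FP + FN) / 2)` (the harmonic mean of Sn and Pr),
#' positive detection rate `PDR = (TP + PTP) / (TP + FN)` and false
#' discovery rate `FDR = FP / (TP + PTP + FP)`. Zero denominators give NA.
#'
#' @param counts data.table with columns `TP`, `PTP`, `FP`, `FN` (extra
#'   columns such as `stratum` are carried through).
#' @return the table with `sensitivity, precision, F1, PDR, FDR` appended.
#' @export
compute_metrics <- function(counts) {
  ct <- as.data.table(counts)
  if (any(ct[, .(TP, PTP, FP, FN)] < 0)) stop("negative counts")
  safe <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  ct[, sensitivity := safe(TP, TP + FN)]
  ct[, precision := safe(TP, TP + FP)]
  ct[, F1 := safe(TP, TP + (FP + FN) / 2)]
  ct[, PDR := safe(TP + PTP, TP + FN)]
  ct[, FDR := safe(FP, TP + PTP + FP)]
  ct[]
}

#' Canonical splice-junction flags
#'
#' A junction is canonical when its intron motif, read strand-aware, is
#' GT..AG, GC..AG or AT..AC. A transcript is canonical when all of its
#' junctions are (mono-exon transcripts vacuously so).
#'
#' @param ann an `annotation`.
#' @param genome named character vector of contig sequences.
#' @param transcript_id a single transcript id.
#' @return list with `junctions` (logical per junction) and `all_canonical`.
#' @export
junction_canonicity <- function(ann, genome, transcript_id) {
  id <- transcript_id
  tx <- ann$transcripts[transcript_id == id]
  if (nrow(tx) == 0) stop("unknown transcript id: ", id)
  jc <- junction_chain(ann, id)
  if (nrow(jc) == 0) return(list(junctions = logical(0), all_canonical = TRUE))
  ctg <- genome[[tx$contig]]
  lo <- substring(ctg, jc$start + 1L, jc$start + 2L)
  hi <- substring(ctg, jc$end - 1L, jc$end)
  motif <- if (tx$strand == "+") paste0(lo, "..", hi)
           else paste0(revcomp(hi), "..", revcomp(lo))
  ok <- motif %in% c("GT..AG", "GC..AG", "AT..AC")
  list(junctions = ok, all_canonical = all(ok))
}

#' Write the evaluation report
#'
#' Produces `<prefix>_labels.tsv` (per reconstructed model),
#' `<prefix>_metrics.tsv` (per-stratum counts and metrics) and
#' `<prefix>_summary.txt` (plain-text overview including descriptive
#' strata: length, exon counts, simulated reads, canonical junctions,
#' gene-level detection and, when given, orthogonal support tables).
#'
#' @param match result of [match_models()].
#' @param design design table with `requested_reads` when available.
#' @param prefix output path prefix.
#' @param genome optional genome for canonical-junction tallies.
#' @param recon optional reconstructed annotation (needed with `genome`).
#' @param support optional named list of extra tables appended to the
#'   summary (e.g. SJ short-read coverage, CAGE TSS support).
#' @return named character vector of the written paths, invisibly.
#' @export
evaluation_report <- function(match, design, prefix, genome = NULL,
                              recon = NULL, support = NULL) {
  labels_path <- paste0(prefix, "_labels.tsv")
  metrics_path <- paste0(prefix, "_metrics.tsv")
  summary_path <- paste0(prefix, "_summary.txt")
  write_tsv(match$labels, labels_path)
  met <- compute_metrics(match$counts)
  write_tsv(met, metrics_path)
  lines <- c("transcriptome reconstruction evaluation", "")
  ov <- met[stratum == "all"]
  lines <- c(lines, sprintf(
    "reconstructed models: %d (TP %d, PTP %d, FP %d); simulated: %d (FN %d)",
    nrow(match$labels), ov$TP, ov$PTP, ov$FP, nrow(match$fn), ov$FN))
  lines <- c(lines, sprintf(
    "sensitivity %.4f  precision %.4f  F1 %.4f  PDR %.4f  FDR %.4f",
    ov$sensitivity, ov$precision, ov$F1, ov$PDR, ov$FDR), "")
  # gene level: a simulated gene is detected iff >= 1 of its simulated
  # transcripts is TP or PTP
  gd <- merge(match$fn, design[, .(transcript_id, gene_id)], by = "transcript_id")
  gl <- gd[, .(det = any(detected | ptp_detected)), by = gene_id]
  lines <- c(lines, sprintf("gene-level detection: %d / %d simulated genes (%.4f)",
                            sum(gl$det), nrow(gl), mean(gl$det)), "")
  # descriptive strata over simulated transcripts
  ds <- merge(match$fn, design, by = c("transcript_id", "status", "category"))
  ds[, outcome := ifelse(detected, "TP", ifelse(ptp_detected, "PTP", "FN"))]
  strata_stat <- ds[, .(n = .N, median_length = as.numeric(median(length)),
                        median_exons = as.numeric(median(n_exons)),
                        median_reads = if ("requested_reads" %in% names(ds))
                          as.numeric(median(requested_reads)) else NA_real_),
                    by = outcome][order(outcome)]
  lines <- c(lines, "simulated transcripts by outcome:",
             utils::capture.output(print(strata_stat, row.names = FALSE)), "")
  if (!is.null(genome) && !is.null(recon) && nrow(recon$transcripts) > 0) {
    can <- vapply(recon$transcripts$transcript_id, function(id)
      junction_canonicity(recon, genome, id)$all_canonical, logical(1))
    lines <- c(lines, sprintf(
      "reconstructed models with all-canonical junctions: %d / %d",
      sum(can), length(can)), "")
  }
  if (!is.null(support)) {
    for (nm in names(support)) {
      lines <- c(lines, paste0(nm, ":"),
                 utils::capture.output(print(support[[nm]])), "")
    }
  }
  writeLines(lines, summary_path)
  invisible(c(labels = labels_path, metrics = metrics_path, summary = summary_path))
}
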