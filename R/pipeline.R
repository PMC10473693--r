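#' Pipeline stages over files
#'
#' Thin file-level wrappers chaining the package's stages in pipeline
#' order: `classif` (annotation -> index), `design` (index + request ->
#' reduced GTF + design table with expression), `sim` (design -> long
#' reads, optional short reads), and `eval` (reconstruction vs ground
#' truth). `full_sim()` chains classif, design and sim in one call. Every
#' stage writes a JSON run manifest recording inputs, parameters, seed and
#' output MD5 hashes; a single global seed drives per-stage substreams, so
#' a full run and the composition of its stages produce identical outputs.
#'
#' @param gtf reference annotation GTF path.
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed.
#' @return invisibly, a named list of output paths.
#' @name pipeline
NULL

write_manifest <- function(out_dir, stage, inputs, params, seed, outputs) {
  man <- list(stage = stage, inputs = inputs, params = params, seed = seed,
              outputs = as.list(tools::md5sum(unlist(outputs))))
  jsonlite::write_json(man, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' @rdname pipeline
#' @export
run_classif <- function(gtf, out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- read_gtf(gtf)
  index <- classify_annotation(ann)
  out <- file.path(out_dir, "index.tsv")
  write_index(index, out)
  write_manifest(out_dir, "classif", list(gtf = gtf), list(), seed,
                 list(index = out))
  invisible(list(index = out))
}

#' @rdname pipeline
#' @param index index TSV from [run_classif()].
#' @param request a [novelty_request()].
#' @param model an expression model.
#' @param long_count total long reads to distribute.
#' @export
run_design <- function(gtf, index, request, out_dir, seed = 1L,
                       model = expression_equal(), long_count = 10000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- read_gtf(gtf)
  idx <- read_index(index)
  des <- select_novel(idx, request, seed = seed)
  red <- reduce_annotation(ann, des, idx)
  des <- assign_expression(red$design, model, long_count, seed = seed)
  gtf_out <- file.path(out_dir, "reduced.gtf")
  des_out <- file.path(out_dir, "design.tsv")
  write_gtf(red$reduced, gtf_out)
  write_design(des, des_out)
  write_manifest(out_dir, "design", list(gtf = gtf, index = index),
                 list(counts = as.list(request$counts),
                      n_known = request$n_known,
                      min_length = request$min_length,
                      mode = model$mode, long_count = long_count),
                 seed, list(reduced = gtf_out, design = des_out))
  invisible(list(reduced = gtf_out, design = des_out))
}

#' @rdname pipeline
#' @param genome_fa genome FASTA path.
#' @param design design TSV from [run_design()].
#' @param profile an [error_profile()].
#' @param short_pairs if positive, also simulate this many short-read pairs.
#' @export
run_sim <- function(gtf, genome_fa, design, out_dir, seed = 1L,
                    profile = error_profile("pacbio-sequel"),
                    short_pairs = 0L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- read_gtf(gtf)
  genome <- read_genome(genome_fa)
  des <- read_design(design)
  fq <- file.path(out_dir, "long_reads.fastq")
  truth <- simulate_long_reads(des, ann, genome, profile, fq, seed = seed)
  truth_out <- file.path(out_dir, "long_truth.tsv")
  write_truth(truth, truth_out)
  outs <- list(fastq = fq, truth = truth_out)
  if (short_pairs > 0L) {
    sp <- short_read_params(n_pairs = short_pairs)
    st <- simulate_short_reads(des, ann, genome, sp,
                               file.path(out_dir, "short"), seed = seed)
    souts <- list(short_R1 = file.path(out_dir, "short_R1.fasta"),
                  short_R2 = file.path(out_dir, "short_R2.fasta"),
                  short_truth = file.path(out_dir, "short_truth.tsv"))
    write_tsv(st, souts$short_truth)
    outs <- c(outs, souts)
  }
  write_manifest(out_dir, "sim",
                 list(gtf = gtf, genome = genome_fa, design = design),
                 list(sub = profile$sub, ins = profile$ins, del = profile$del,
                      short_pairs = short_pairs),
                 seed, outs)
  invisible(outs)
}

#' @rdname pipeline
#' @param recon reconstructed transcriptome GTF.
#' @param reduced reduced GTF from [run_design()].
#' @export
run_eval <- function(recon, design, reduced, gtf, out_dir, seed = 1L,
                     genome_fa = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- read_gtf(recon)
  des <- read_design(design)
  red <- read_gtf(reduced)
  full <- read_gtf(gtf)
  m <- match_models(rec, des, full, red)
  genome <- if (!is.null(genome_fa)) read_genome(genome_fa) else NULL
  prefix <- file.path(out_dir, "evaluation")
  paths <- evaluation_report(m, des, prefix, genome = genome, recon = rec)
  write_manifest(out_dir, "eval",
                 list(recon = recon, design = design, reduced = reduced,
                      gtf = gtf),
                 list(), seed, as.list(paths))
  invisible(as.list(paths))
}

#' @rdname pipeline
#' @export
full_sim <- function(gtf, genome_fa, request, out_dir, seed = 1L,
                     model = expression_equal(), long_count = 10000L,
                     profile = error_profile("pacbio-sequel"),
                     short_pairs = 0L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  o1 <- run_classif(gtf, out_dir, seed = seed)
  o2 <- run_design(gtf, o1$index, request, out_dir, seed = seed,
                   model = model, long_count = long_count)
  o3 <- run_sim(gtf, genome_fa, o2$design, out_dir, seed = seed,
                profile = profile, short_pairs = short_pairs)
  invisible(c(o1, o2, o3))
}

#' @rdname pipeline
#' @param quota,n_fsm_genes fixture parameters, see [fixture_spec()].
#' @export
run_fixtures <- function(out_dir, quota, n_fsm_genes = 2L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- fixture_spec(quota = quota, n_fsm_genes = n_fsm_genes, seed = seed)
  fx <- synth_fixture(spec)
  gtf <- file.path(out_dir, "fixture.gtf")
  fa <- file.path(out_dir, "fixture.fasta")
  man <- file.path(out_dir, "fixture_manifest.tsv")
  write_gtf(fx$annotation, gtf)
  write_genome(fx$genome, fa)
  write_tsv(fx$manifest, man)
  write_manifest(out_dir, "fixtures", list(),
                 list(quota = as.list(quota), n_fsm_genes = n_fsm_genes),
                 seed, list(gtf = gtf, fasta = fa, manifest = man))
  invisible(list(gtf = gtf, fasta = fa, manifest = man))
}
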