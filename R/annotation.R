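#' Genomic annotation model
#'
#' An `annotation` object is the package's in-memory transcriptome model.
#' All internal coordinates are 0-based, half-open; GTF input and output
#' convert at the boundary. It holds three keyed data.tables:
#' \describe{
#'   \item{exons}{`transcript_id, gene_id, contig, strand, start, end`,
#'     one row per exon, sorted by transcript then start.}
#'   \item{transcripts}{per-transcript span, exon count, spliced length and
#'     the intron ("junction") chain encoded as a string `"d-a;d-a;..."`.}
#'   \item{genes}{per-gene span (union of member exon spans) and member count.}
#' }
#'
#' @param exons data.frame/data.table with columns `transcript_id`, `gene_id`,
#'   `contig`, `strand`, `start`, `end` in 0-based half-open coordinates.
#' @return object of class `annotation`.
#' @export
annotation <- function(exons) {
  ex <- as.data.table(exons)[, .(transcript_id = as.character(transcript_id),
                                 gene_id = as.character(gene_id),
                                 contig = as.character(contig),
                                 strand = as.character(strand),
                                 start = as.integer(start),
                                 end = as.integer(end))]
  if (nrow(ex) > 0) {
    if (any(ex$end <= ex$start)) stop("exon with non-positive width")
    if (!all(ex$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    setorder(ex, transcript_id, start)
    # per-transcript sanity: one contig/strand/gene, disjoint sorted exons
    chk <- ex[, .(ncont = uniqueN(contig), nstr = uniqueN(strand),
                  ngene = uniqueN(gene_id),
                  ovl = any(head(end, -1) > tail(start, -1))),
              by = transcript_id]
    bad <- chk[ncont > 1 | nstr > 1 | ngene > 1 | ovl]
    if (nrow(bad) > 0)
      stop("inconsistent transcript(s): ", paste(head(bad$transcript_id, 5), collapse = ", "))
  }
  tx <- ex[, .(gene_id = gene_id[1L], contig = contig[1L], strand = strand[1L],
               tx_start = start[1L], tx_end = end[.N], n_exons = .N,
               length = sum(end - start),
               chain = if (.N == 1L) "" else
                 paste(head(end, -1L), tail(start, -1L), sep = "-", collapse = ";")),
           by = transcript_id]
  genes <- if (nrow(tx) == 0)
    data.table(gene_id = character(), contig = character(), strand = character(),
               g_start = integer(), g_end = integer(), n_tx = integer())
  else tx[, .(contig = contig[1L], strand = strand[1L],
              g_start = min(tx_start), g_end = max(tx_end), n_tx = .N),
          by = gene_id]
  obj <- list(exons = ex, transcripts = tx, genes = genes)
  class(obj) <- "annotation"
  obj
}

#' @export
print.annotation <- function(x, ...) {
  cat("annotation:", nrow(x$transcripts), "transcripts,",
      nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      uniqueN(x$exons$contig), "contig(s)\n")
  invisible(x)
}

#' Number of transcripts in an annotation
#' @param ann an `annotation`.
#' @return integer count.
#' @export
n_transcripts <- function(ann) nrow(ann$transcripts)

#' Subset an annotation by transcript ids
#'
#' @param ann an `annotation`.
#' @param ids transcript ids to keep (`keep = TRUE`) or drop.
#' @param keep logical; keep (default) or drop `ids`.
#' @return a new `annotation`. Genes left without transcripts disappear.
#' @export
subset_annotation <- function(ann, ids, keep = TRUE) {
  sel <- ann$exons$transcript_id %in% ids
  if (!keep) sel <- !sel
  annotation(ann$exons[sel])
}

#' Read a GTF file into an annotation
#'
#' Accepts the Ensembl/GENCODE GTF dialect: 9 tab-separated columns with
#' `gene_id "X"; transcript_id "Y";` attributes. Transcript models are
#' synthesized from `exon` feature lines sharing a `transcript_id`, so
#' explicit `transcript` feature lines are optional. 1-based inclusive GTF
#' coordinates are converted to internal 0-based half-open. Strand `"."` is
#' tolerated and treated as `"+"` with a warning.
#'
#' @param path path to a GTF file.
#' @return an `annotation`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) return(annotation(empty_exon_table()))
  meaningful <- !startsWith(lines, "#") & nzchar(trimws(lines))
  if (!any(meaningful)) return(annotation(empty_exon_table()))
  ntab <- stringi::stri_count_fixed(lines[meaningful], "\t")
  if (any(ntab != 8L)) {
    bad <- which(meaningful)[which(ntab != 8L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields")
  }
  dt <- fread(text = lines[meaningful], sep = "\t", header = FALSE, quote = "",
              col.names = c("contig", "source", "feature", "start", "end",
                            "score", "strand", "frame", "attrs"),
              colClasses = list(character = c(1, 2, 3, 6, 7, 8, 9)))
  lineno <- which(meaningful)
  if (anyNA(dt$start) || anyNA(dt$end)) {
    bad <- lineno[which(is.na(dt$start) | is.na(dt$end))[1L]]
    stop("malformed GTF line ", bad, ": non-numeric coordinates")
  }
  gid <- stringi::stri_match_first_regex(dt$attrs, 'gene_id\\s+"([^"]*)"')[, 2]
  tid <- stringi::stri_match_first_regex(dt$attrs, 'transcript_id\\s+"([^"]*)"')[, 2]
  need_tid <- dt$feature %in% c("exon", "transcript")
  if (anyNA(gid[need_tid]) || anyNA(tid[need_tid])) {
    bad <- lineno[which(need_tid & (is.na(gid) | is.na(tid)))[1L]]
    stop("malformed GTF line ", bad, ": missing gene_id/transcript_id attribute")
  }
  if (any(dt$strand == ".")) {
    warning("strand '.' treated as '+'")
    dt[strand == ".", strand := "+"]
  }
  dt[, `:=`(gene_id = gid, transcript_id = tid)]
  ex <- dt[feature == "exon",
           .(transcript_id, gene_id, contig, strand,
             start = start - 1L, end = end)]
  # transcripts declared but with zero exon lines are rejected by id
  declared <- unique(tid[dt$feature == "transcript"])
  orphans <- setdiff(declared, unique(ex$transcript_id))
  if (length(orphans) > 0)
    stop("transcript(s) without exon lines: ", paste(head(orphans, 5), collapse = ", "))
  annotation(ex)
}

empty_exon_table <- function() {
  data.table(transcript_id = character(), gene_id = character(),
             contig = character(), strand = character(),
             start = integer(), end = integer())
}

#' Write an annotation as GTF
#'
#' Emits `gene`, `transcript` and `exon` features with `gene_id` and
#' `transcript_id` attributes, converting internal 0-based half-open
#' coordinates to 1-based inclusive. Record order is deterministic:
#' genes by (contig, start, gene_id), transcripts within genes by
#' (start, transcript_id), exons ascending. Two writes of the same
#' annotation are byte-identical.
#'
#' @param ann an `annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  g <- copy(ann$genes)[order(contig, g_start, gene_id)]
  tx <- copy(ann$transcripts)
  ex <- copy(ann$exons)
  if (nrow(g) == 0) { writeLines(character(0), path); return(invisible(path)) }
  g[, ord := .I]
  tx <- tx[g[, .(gene_id, ord)], on = "gene_id"][order(ord, tx_start, transcript_id)]
  tx[, txord := .I]
  ex <- ex[tx[, .(transcript_id, txord)], on = "transcript_id"][order(txord, start)]
  gl <- g[, sprintf('%s\tnovelsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                    contig, g_start + 1L, g_end, strand, gene_id)]
  tl <- tx[, sprintf('%s\tnovelsim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                     contig, tx_start + 1L, tx_end, strand, gene_id, transcript_id)]
  el <- ex[, sprintf('%s\tnovelsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                     contig, start + 1L, end, strand, gene_id, transcript_id)]
  # interleave: gene line, then its transcript lines each followed by exon lines
  tx_first_ex <- ex[, .(i0 = .I[1L], i1 = .I[.N]), by = txord]
  g_first_tx <- tx[, .(t0 = .I[1L], t1 = .I[.N]), by = ord]
  out <- vector("list", nrow(g))
  for (gi in seq_len(nrow(g))) {
    trange <- g_first_tx$t0[gi]:g_first_tx$t1[gi]
    blocks <- lapply(trange, function(ti)
      c(tl[ti], el[tx_first_ex$i0[ti]:tx_first_ex$i1[ti]]))
    out[[gi]] <- c(gl[gi], unlist(blocks))
  }
  writeLines(unlist(out), path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @return named character vector of upper-case sequences, one per contig.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) stop("duplicate contig names in ", path)
  g
}

#' Write a genome FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Spliced transcript sequence
#'
#' Concatenates exon substrings in ascending genomic order and
#' reverse-complements the result for minus-strand transcripts, so the
#' returned string is in transcript (5' to 3') orientation.
#'
#' @param genome named character vector of contig sequences.
#' @param ann an `annotation`.
#' @param transcript_id one or more transcript ids.
#' @return character vector of spliced sequences, named by transcript id.
#' @export
spliced_sequence <- function(genome, ann, transcript_id) {
  ids <- transcript_id
  tx <- ann$transcripts[match(ids, ann$transcripts$transcript_id)]
  if (anyNA(tx$gene_id)) stop("unknown transcript id(s)")
  out <- vapply(seq_len(nrow(tx)), function(i) {
    id <- tx$transcript_id[i]
    ctg <- tx$contig[i]
    if (!ctg %in% names(genome)) stop("contig absent from genome: ", ctg)
    clen <- nchar(genome[[ctg]])
    ex <- ann$exons[transcript_id == id]
    if (any(ex$start < 0L) || any(ex$end > clen))
      stop("exon out of contig bounds for ", id)
    s <- paste(substring(genome[[ctg]], ex$start + 1L, ex$end), collapse = "")
    if (tx$strand[i] == "-") revcomp(s) else s
  }, character(1))
  names(out) <- tx$transcript_id
  out
}

#' Junction chain of a transcript
#'
#' Introns as (donor_pos, acceptor_pos) pairs in genomic coordinates,
#' 0-based half-open: intron i spans `[exon_i end, exon_{i+1} start)`.
#' Mono-exon transcripts have an empty chain.
#'
#' @param ann an `annotation`.
#' @param transcript_id a single transcript id.
#' @return data.table with columns `start`, `end`, one row per intron.
#' @export
junction_chain <- function(ann, transcript_id) {
  id <- transcript_id
  ex <- ann$exons[transcript_id == id]
  if (nrow(ex) == 0) stop("unknown transcript id: ", id)
  if (nrow(ex) == 1L) return(data.table(start = integer(0), end = integer(0)))
  data.table(start = head(ex$end, -1L), end = tail(ex$start, -1L))
}
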