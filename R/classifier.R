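#' Structural categories
#'
#' The eight structural categories used throughout the package, in cascade
#' priority order for multi-exon transcripts: FSM (chain identical to a
#' same-gene reference), ISM (chain is a strictly shorter contiguous
#' subchain), FUSION (exons span two or more same-strand genes), NIC (all
#' donors/acceptors annotated but the chain is not a subchain of any
#' reference), NNC (at least one unannotated donor or acceptor), then the
#' overlap-driven categories GENIC_GENOMIC, ANTISENSE and INTERGENIC.
#' @export
STRUCTURAL_CATEGORIES <- c("FSM", "ISM", "NIC", "NNC", "GENIC_GENOMIC",
                           "ANTISENSE", "FUSION", "INTERGENIC")

# Split a chain string "d-a;d-a" into a long table of strand-aware splice
# sites keyed "d:<pos>" / "a:<pos>".
chain_sites <- function(ids, chains, strands) {
  keep <- nzchar(chains)
  if (!any(keep)) return(data.table(id = character(0), site = character(0)))
  ids <- ids[keep]; chains <- chains[keep]; strands <- strands[keep]
  introns <- stringi::stri_split_fixed(chains, ";")
  n <- lengths(introns)
  flat <- stringi::stri_split_fixed(unlist(introns), "-", simplify = TRUE)
  lo <- flat[, 1]; hi <- flat[, 2]
  str <- rep(strands, n)
  # donor = 5' intron boundary in transcript orientation
  donor <- ifelse(str == "+", lo, hi)
  accep <- ifelse(str == "+", hi, lo)
  per_intron <- rep(ids, n)
  data.table(id = c(per_intron, per_intron),
             site = c(paste0("d:", donor), paste0("a:", accep)))
}

# Leave-one-out gene spans: for each (gene, transcript) pair, the gene span
# recomputed without that transcript. Returns per-gene order statistics.
gene_loo_stats <- function(tx) {
  if (nrow(tx) == 0)
    return(data.table(gene_id = character(), s1 = integer(), s1n = integer(),
                      s2 = integer(), e1 = integer(), e1n = integer(),
                      e2 = integer(), n_tx = integer()))
  tx[, .(s1 = sort(tx_start, partial = 1)[1L],
         s1n = sum(tx_start == min(tx_start)),
         s2 = if (.N > 1L) sort(tx_start, partial = 2)[2L] else NA_integer_,
         e1 = max(tx_end),
         e1n = sum(tx_end == max(tx_end)),
         e2 = if (.N > 1L) -sort(-tx_end, partial = 2)[2L] else NA_integer_,
         n_tx = .N),
     by = gene_id]
}

# Core batched classifier: assigns each candidate transcript its structural
# category relative to a reference annotation. When `self_exclude` is TRUE
# (candidates are members of `ref`), the candidate's own contribution to the
# reference - its splice sites and its effect on its own gene's span - is
# removed before comparison, so a transcript is never compared to itself.
classify_transcripts <- function(cand, ref, self_exclude) {
  ctx <- copy(cand$transcripts)
  rtx <- ref$transcripts
  res <- ctx[, .(transcript_id, gene_id, length, n_exons)]
  if (nrow(ctx) == 0) {
    res[, `:=`(category = character(0), associated_transcript = character(0),
               associated_gene = character(0))]
    return(res[, .(transcript_id, gene_id, category, associated_transcript,
                   associated_gene, length, n_exons)])
  }

  loo <- gene_loo_stats(rtx)
  gdt <- ref$genes[loo, on = "gene_id"][, .(
    contig, gene_id, g_strand = strand, gs = g_start, ge = g_end - 1L,
    s1, s1n, s2, e1, e1n, e2, n_tx)]
  setkey(gdt, contig, gs, ge)

  cdt <- ctx[, .(contig, s = tx_start, e = tx_end - 1L,
                 cand_id = transcript_id, cand_gene = gene_id,
                 cand_strand = strand)]
  ov <- foverlaps(cdt, gdt, by.x = c("contig", "s", "e"),
                  type = "any", nomatch = NULL)
  if (self_exclude && nrow(ov) > 0) {
    # own-gene rows: replace the gene span by its leave-one-out span
    ownrow <- ov$cand_gene == ov$gene_id
    if (any(ownrow)) {
      o <- ov[ownrow]
      keep <- o$n_tx > 1L
      los <- ifelse(o$s == o$s1 & o$s1n == 1L, o$s2, o$s1)
      loe <- ifelse (o$e + 1L == o$e1 & o$e1n == 1L, o$e2, o$e1)
      keep <- keep & !is.na(los) & !is.na(loe) & los <= o$e & (loe - 1L) >= o$s
      ov <- rbind(ov[!ownrow], o[keep])
    }
  }

  same <- ov[cand_strand == g_strand, .(cand_id, gene_id)]
  anti <- ov[cand_strand != g_strand, .(cand_id, gene_id)]
  has_S <- res$transcript_id %in% same$cand_id
  has_A <- res$transcript_id %in% anti$cand_id

  # candidate x comparison-transcript pairs
  rsub <- rtx[, .(gene_id, ref_id = transcript_id, r_start = tx_start,
                  r_end = tx_end, r_nex = n_exons, r_chain = chain)]
  pairs <- merge(same, rsub, by = "gene_id", allow.cartesian = TRUE)
  if (self_exclude) pairs <- pairs[cand_id != ref_id]
  pairs <- merge(pairs,
                 ctx[, .(cand_id = transcript_id, c_start = tx_start,
                         c_end = tx_end, c_nex = n_exons, c_chain = chain)],
                 by = "cand_id")

  fsm_dt <- ism_dt <- data.table(cand_id = character(0), assoc = character(0))
  if (nrow(pairs) > 0) {
    mm <- pairs$c_nex > 1L & pairs$r_nex > 1L
    fsm <- mm & pairs$c_chain == pairs$r_chain
    ism <- logical(nrow(pairs))
    cand_sub <- which(mm & !fsm)
    if (length(cand_sub) > 0) {
      ism[cand_sub] <- stringi::stri_detect_fixed(
        paste0(";", pairs$r_chain[cand_sub], ";"),
        paste0(";", pairs$c_chain[cand_sub], ";"))
    }
    # mono-exon candidate vs mono-exon reference: reciprocal overlap >= 80%
    mono2 <- pairs$c_nex == 1L & pairs$r_nex == 1L
    ovw <- pmin(pairs$c_end, pairs$r_end) - pmax(pairs$c_start, pairs$r_start)
    fsm_m <- mono2 & ovw >= 0.8 * (pairs$c_end - pairs$c_start) &
      ovw >= 0.8 * (pairs$r_end - pairs$r_start)
    # mono-exon candidate contained in a single exon of a multi-exon reference
    ism_m <- logical(nrow(pairs))
    mm1 <- which(pairs$c_nex == 1L & pairs$r_nex > 1L)
    if (length(mm1) > 0) {
      pm <- pairs[mm1, .(idx = mm1, cand_id, ref_id, c_start, c_end)]
      rex <- ref$exons[, .(ref_id = transcript_id, ex_s = start, ex_e = end)]
      j <- merge(pm, rex, by = "ref_id", allow.cartesian = TRUE)
      hit <- j[ex_s <= c_start & ex_e >= c_end, unique(idx)]
      ism_m[hit] <- TRUE
    }
    pick_assoc <- function(sel) {
      if (!any(sel)) return(data.table(cand_id = character(0), assoc = character(0)))
      pairs[sel][order(cand_id, -r_nex, ref_id),
                 .(assoc = ref_id[1L]), by = cand_id]
    }
    fsm_dt <- pick_assoc(fsm | fsm_m)
    ism_dt <- pick_assoc(ism | ism_m)
  }

  # fusion: candidate exons overlap >= 2 distinct same-strand genes
  fus_dt <- data.table(cand_id = character(0), genes = character(0), ng = integer(0))
  if (nrow(same) > 0) {
    cex <- cand$exons[transcript_id %in% unique(same$cand_id),
                      .(cand_id = transcript_id, contig, s = start, e = end - 1L)]
    gsp <- gdt[, .(contig, gs, ge, gene_id)]
    setkey(gsp, contig, gs, ge)
    eov <- foverlaps(cex, gsp, by.x = c("contig", "s", "e"),
                     type = "any", nomatch = NULL)
    eov <- unique(eov[, .(cand_id, gene_id)])[same, on = c("cand_id", "gene_id"), nomatch = NULL]
    fus_dt <- eov[order(cand_id, gene_id),
                  .(genes = paste(unique(gene_id), collapse = "_"),
                    ng = uniqueN(gene_id)), by = cand_id]
  }

  # splice-site catalogs (union over comparison transcripts, self excluded)
  nnc_ids <- character(0)
  multi_cand <- ctx[n_exons > 1L, transcript_id]
  if (nrow(pairs) > 0 && length(multi_cand) > 0) {
    ref_sites <- chain_sites(rtx$transcript_id, rtx$chain, rtx$strand)
    setnames(ref_sites, "id", "ref_id")
    cat_sites <- unique(merge(pairs[cand_id %in% multi_cand, .(cand_id, ref_id)],
                              ref_sites, by = "ref_id",
                              allow.cartesian = TRUE)[, .(cand_id, site)])
    own_sites <- chain_sites(ctx$transcript_id, ctx$chain, ctx$strand)
    setnames(own_sites, "id", "cand_id")
    own_sites <- own_sites[cand_id %in% multi_cand]
    miss <- own_sites[!cat_sites, on = c("cand_id", "site")]
    nnc_ids <- unique(miss$cand_id)
  }

  anti_assoc <- if (nrow(anti) > 0)
    anti[order(cand_id, gene_id), .(agene = gene_id[1L]), by = cand_id]
  else data.table(cand_id = character(0), agene = character(0))

  res[, `:=`(category = NA_character_, associated_transcript = "novel",
             associated_gene = gene_id)]
  res[fsm_dt, on = c(transcript_id = "cand_id"),
      `:=`(category = "FSM", associated_transcript = assoc)]
  res[is.na(category) & transcript_id %in% ism_dt$cand_id, category := "ISM"]
  res[ism_dt, on = c(transcript_id = "cand_id"),
      associated_transcript := ifelse(category == "ISM", assoc, associated_transcript)]
  fus2 <- fus_dt[ng >= 2L]
  res[is.na(category) & transcript_id %in% fus2$cand_id, category := "FUSION"]
  res[fus2, on = c(transcript_id = "cand_id"),
      associated_gene := ifelse(category == "FUSION", genes, associated_gene)]
  res[is.na(category) & n_exons > 1L & has_S,
      category := ifelse(transcript_id %in% nnc_ids, "NNC", "NIC")]
  res[is.na(category) & n_exons == 1L & has_S, category := "GENIC_GENOMIC"]
  res[is.na(category) & has_A, category := "ANTISENSE"]
  res[anti_assoc, on = c(transcript_id = "cand_id"),
      associated_gene := ifelse(category == "ANTISENSE", agene, associated_gene)]
  res[is.na(category), `:=`(category = "INTERGENIC", associated_gene = "novel")]
  res[, .(transcript_id, gene_id, category, associated_transcript,
          associated_gene, length, n_exons)]
}

#' Classify every transcript of an annotation
#'
#' Assigns each transcript its potential structural category when compared
#' to the other transcripts of overlapping same-strand genes, excluding the
#' transcript itself from the comparison (a self-comparison would always
#' yield FSM). The result is the index table used by the design and
#' evaluation stages.
#'
#' @param ann an `annotation`.
#' @return data.table with columns `transcript_id`, `gene_id`, `category`,
#'   `associated_transcript` (the matched reference for FSM/ISM, otherwise
#'   `"novel"`), `associated_gene`, `length`, `n_exons`; one row per
#'   transcript, in input order.
#' @export
classify_annotation <- function(ann) {
  idx <- classify_transcripts(ann, ann, self_exclude = TRUE)
  idx[match(ann$transcripts$transcript_id, idx$transcript_id)]
}

#' Classify one or more candidate transcripts against a reference
#'
#' Candidates may be external to the reference (e.g. removed transcripts
#' re-classified against a reduced annotation). If a candidate id is present
#' in the reference, set `self_exclude = TRUE` to remove it from its own
#' comparison catalog.
#'
#' @param cand an `annotation` holding the candidate transcript model(s).
#' @param ref the reference `annotation` to compare against.
#' @param self_exclude logical; exclude candidates from their own catalogs.
#' @return classification table as in [classify_annotation()].
#' @export
classify_candidate <- function(cand, ref, self_exclude = FALSE) {
  classify_transcripts(cand, ref, self_exclude = self_exclude)
}

#' Build the splice-site catalog seen by one transcript
#'
#' The set of annotated donor sites, acceptor sites and junctions collected
#' from all transcripts of the same (overlapping, same-strand) gene group,
#' excluding the given transcript itself.
#'
#' @param ann an `annotation`.
#' @param exclude_id transcript id excluded from the catalog (the candidate).
#' @return list with character vectors `donors`, `acceptors` (strand-aware
#'   positions) and `junctions` (`"d-a"` chain tokens).
#' @export
build_catalog <- function(ann, exclude_id) {
  tx <- ann$transcripts
  if (!exclude_id %in% tx$transcript_id) stop("unknown transcript id: ", exclude_id)
  me <- tx[transcript_id == exclude_id]
  g <- ann$genes[contig == me$contig & strand == me$strand]
  # leave-one-out span of the candidate's own gene
  others <- tx[gene_id == me$gene_id & transcript_id != exclude_id]
  g <- g[gene_id != me$gene_id]
  if (nrow(others) > 0)
    g <- rbind(g, data.table(gene_id = me$gene_id, contig = me$contig,
                             strand = me$strand, g_start = min(others$tx_start),
                             g_end = max(others$tx_end), n_tx = nrow(others)))
  g <- g[g_start < me$tx_end & g_end > me$tx_start]
  members <- tx[gene_id %in% g$gene_id & transcript_id != exclude_id]
  sites <- chain_sites(members$transcript_id, members$chain, members$strand)
  juncs <- unique(unlist(stringi::stri_split_fixed(
    members$chain[nzchar(members$chain)], ";")))
  list(donors = unique(sub("^d:", "", sites$site[startsWith(sites$site, "d:")])),
       acceptors = unique(sub("^a:", "", sites$site[startsWith(sites$site, "a:")])),
       junctions = if (length(juncs)) juncs else character(0))
}

#' Write a classification index file
#'
#' Tab-separated with header `transcript_id gene_id category
#' associated_transcript length n_exons`, one row per transcript in
#' classification order.
#'
#' @param index table from [classify_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  write_tsv(index[, .(transcript_id, gene_id, category, associated_transcript,
                      length, n_exons)], path)
}

#' Read a classification index file
#' @param path path written by [write_index()].
#' @return data.table.
#' @export
read_index <- function(path) {
  fread(path, sep = "\t", colClasses = list(
    character = c("transcript_id", "gene_id", "category", "associated_transcript")))
}
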