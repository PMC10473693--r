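#' Synthetic fixture specification
#'
#' Describes a seeded synthetic genome + annotation pair guaranteeing
#' eligible candidate transcripts of every structural category. Each
#' requested candidate is planted by a small, self-contained gene
#' construct: FSM as duplicated-chain transcript pairs; ISM as truncated
#' chains next to an FSM backbone pair; NIC by re-pairing known donor and
#' acceptor sites (exon skipping); NNC by shifting a donor site; genic
#' genomic as intron-overlapping mono-exons; antisense as single-transcript
#' genes nested in an opposite-strand gene; fusion as transcripts spanning
#' two same-strand genes; intergenic as isolated single-transcript genes.
#' Backbone pairs classify as FSM, so each construct contributes exactly
#' one selectable novel candidate and constructs do not interfere when
#' candidates are removed. Canonical GT..AG motifs are written into the
#' genome at every intron.
#'
#' @param quota named integer vector of candidate quotas per novel category
#'   (names among ISM, NIC, NNC, GENIC_GENOMIC, ANTISENSE, FUSION,
#'   INTERGENIC).
#' @param n_fsm_genes additional FSM-pair genes beyond the backbones the
#'   novel constructs already contain (each gene contributes 2 FSM
#'   candidates).
#' @param seed integer seed; fixtures are byte-identical under a fixed seed.
#' @param exon_range,intron_range,gap_range exon length, intron length and
#'   inter-construct gap ranges in nt.
#' @param gc GC fraction of the random genomic background.
#' @param genes_per_contig constructs placed per contig.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(quota = c(ISM = 0, NIC = 0, NNC = 0,
                                   GENIC_GENOMIC = 0, ANTISENSE = 0,
                                   FUSION = 0, INTERGENIC = 0),
                         n_fsm_genes = 2, seed = 1L,
                         exon_range = c(100L, 200L),
                         intron_range = c(150L, 400L),
                         gap_range = c(200L, 500L),
                         gc = 0.5, genes_per_contig = 2000L) {
  full <- c(ISM = 0L, NIC = 0L, NNC = 0L, GENIC_GENOMIC = 0L,
            ANTISENSE = 0L, FUSION = 0L, INTERGENIC = 0L)
  if (length(quota) > 0) {
    if (is.null(names(quota)) || !all(names(quota) %in% names(full)))
      stop("quota names must be novel structural categories")
    full[names(quota)] <- as.integer(quota)
  }
  if (any(full < 0) || n_fsm_genes < 0) stop("quotas must be non-negative")
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)")
  structure(list(quota = full, n_fsm_genes = as.integer(n_fsm_genes),
                 seed = as.integer(seed), exon_range = as.integer(exon_range),
                 intron_range = as.integer(intron_range),
                 gap_range = as.integer(gap_range), gc = gc,
                 genes_per_contig = as.integer(genes_per_contig)),
            class = "fixture_spec")
}

runif_int <- function(n, range) {
  if (n == 0L) return(integer(0))
  as.integer(floor(runif(n, range[1], range[2] + 1)))
}

# Exon-start scaffold for n constructs with m exons: local coordinates.
scaffold <- function(n, m, spec, min_e2 = NULL) {
  EL <- matrix(runif_int(n * m, spec$exon_range), n, m)
  if (!is.null(min_e2) && m >= 2L) EL[, 2] <- pmax(EL[, 2], min_e2)
  IL <- if (m > 1L) matrix(runif_int(n * (m - 1L), spec$intron_range), n, m - 1L)
        else matrix(integer(0), n, 0)
  S <- matrix(0L, n, m)
  if (m > 1L) for (k in 2:m) S[, k] <- S[, k - 1L] + EL[, k - 1L] + IL[, k - 1L]
  list(EL = EL, IL = IL, S = S, E = S + EL)
}

# assemble exon rows for transcripts defined by (exon subset, start/end tweaks)
exon_rows <- function(uid, tx_suffix, gene_suffix, S, E, cols, ds = 0L, de = 0L) {
  n <- length(uid)
  m <- length(cols)
  s <- S[, cols, drop = FALSE]
  e <- E[, cols, drop = FALSE]
  s[, 1] <- s[, 1] + ds
  e[, m] <- e[, m] + de
  data.table(uid = rep(uid, m),
             tx = rep(paste0(tx_suffix), n * m),
             gene = rep(paste0(gene_suffix), n * m),
             s = as.integer(s), e = as.integer(e))
}

build_constructs <- function(spec) {
  q <- spec$quota
  types <- c(rep("FSM", spec$n_fsm_genes), rep("ISM", q[["ISM"]]),
             rep("NIC", q[["NIC"]]), rep("NNC", q[["NNC"]]),
             rep("GEN", q[["GENIC_GENOMIC"]]), rep("ANT", q[["ANTISENSE"]]),
             rep("FUS", q[["FUSION"]]), rep("INT", q[["INTERGENIC"]]))
  n_all <- length(types)
  if (n_all == 0L) stop("empty fixture specification")
  parts <- list()
  cands <- list()
  add <- function(type, rows, cand = NULL) {
    parts[[type]] <<- rows
    if (!is.null(cand)) cands[[type]] <<- cand
  }
  uid_of <- function(type) sprintf("%s%06d", type, which(types == type))
  dlt <- function(n) runif_int(n, c(0L, 20L))

  # FSM extra genes: 3-exon duo with identical chains
  nf <- spec$n_fsm_genes
  if (nf > 0) {
    uid <- uid_of("FSM")
    sc <- scaffold(nf, 3L, spec)
    add("FSM", rbind(
      exon_rows(uid, "T1", "G", sc$S, sc$E, 1:3),
      exon_rows(uid, "T2", "G", sc$S, sc$E, 1:3, ds = dlt(nf), de = -dlt(nf))))
  }
  # ISM: 4-exon backbone pair + prefix candidate (exons 1-3)
  ni <- q[["ISM"]]
  if (ni > 0) {
    uid <- uid_of("ISM")
    sc <- scaffold(ni, 4L, spec)
    add("ISM", rbind(
      exon_rows(uid, "T1", "G", sc$S, sc$E, 1:4),
      exon_rows(uid, "T2", "G", sc$S, sc$E, 1:4, ds = dlt(ni)),
      exon_rows(uid, "T3", "G", sc$S, sc$E, 1:3)),
      cand = data.table(uid = uid, tx = "T3", category = "ISM"))
  }
  # NIC: backbone pair + exon-skipping candidate (known sites, novel junction)
  nn <- q[["NIC"]]
  if (nn > 0) {
    uid <- uid_of("NIC")
    sc <- scaffold(nn, 4L, spec)
    add("NIC", rbind(
      exon_rows(uid, "T1", "G", sc$S, sc$E, 1:4),
      exon_rows(uid, "T2", "G", sc$S, sc$E, 1:4, ds = dlt(nn)),
      exon_rows(uid, "T3", "G", sc$S, sc$E, c(1L, 3L, 4L))),
      cand = data.table(uid = uid, tx = "T3", category = "NIC"))
  }
  # NNC: backbone pair + candidate with donor of intron 2 shifted +12
  nc <- q[["NNC"]]
  if (nc > 0) {
    uid <- uid_of("NNC")
    sc <- scaffold(nc, 4L, spec)
    E2 <- sc$E; E2[, 2] <- E2[, 2] + 12L
    add("NNC", rbind(
      exon_rows(uid, "T1", "G", sc$S, sc$E, 1:4),
      exon_rows(uid, "T2", "G", sc$S, sc$E, 1:4, ds = dlt(nc)),
      exon_rows(uid, "T3", "G", sc$S, E2, 1:4)),
      cand = data.table(uid = uid, tx = "T3", category = "NNC"))
  }
  # GENIC_GENOMIC: backbone pair + mono-exon straddling the exon2/intron2
  # boundary (partly exonic, partly intronic; not inside any single exon)
  ng <- q[["GENIC_GENOMIC"]]
  if (ng > 0) {
    uid <- uid_of("GEN")
    sc <- scaffold(ng, 4L, spec, min_e2 = 170L)
    mono <- data.table(uid = uid, tx = "T3", gene = "G",
                       s = as.integer(sc$E[, 2] - 150L),
                       e = as.integer(sc$E[, 2] + 60L))
    add("GEN", rbind(
      exon_rows(uid, "T1", "G", sc$S, sc$E, 1:4),
      exon_rows(uid, "T2", "G", sc$S, sc$E, 1:4, ds = dlt(ng)),
      mono),
      cand = data.table(uid = uid, tx = "T3", category = "GENIC_GENOMIC"))
  }
  # ANTISENSE: host FSM pair; opposite-strand mono-exon gene nested inside
  na <- q[["ANTISENSE"]]
  if (na > 0) {
    uid <- uid_of("ANT")
    sc <- scaffold(na, 3L, spec)
    mono <- data.table(uid = uid, tx = "T3", gene = "GA",
                       s = as.integer(sc$E[, 1] + 10L),
                       e = as.integer(sc$E[, 1] + 260L))
    add("ANT", rbind(
      exon_rows(uid, "T1", "G", sc$S, sc$E, 1:3),
      exon_rows(uid, "T2", "G", sc$S, sc$E, 1:3, ds = dlt(na)),
      mono),
      cand = data.table(uid = uid, tx = "T3", category = "ANTISENSE"))
  }
  # FUSION: two adjacent 2-exon FSM-pair genes + a gene-spanning candidate
  nu <- q[["FUSION"]]
  if (nu > 0) {
    uid <- uid_of("FUS")
    g1 <- scaffold(nu, 2L, spec)
    g2 <- scaffold(nu, 2L, spec)
    off <- g1$E[, 2] + 150L
    S2 <- g2$S + off; E2 <- g2$E + off
    fus_s <- cbind(g1$S, S2); fus_e <- cbind(g1$E, E2)
    add("FUS", rbind(
      exon_rows(uid, "T1", "G1", g1$S, g1$E, 1:2),
      exon_rows(uid, "T2", "G1", g1$S, g1$E, 1:2, ds = dlt(nu)),
      exon_rows(uid, "T3", "G2", S2, E2, 1:2),
      exon_rows(uid, "T4", "G2", S2, E2, 1:2, ds = dlt(nu)),
      exon_rows(uid, "T5", "GF", fus_s, fus_e, 1:4)),
      cand = data.table(uid = uid, tx = "T5", category = "FUSION"))
  }
  # INTERGENIC: isolated mono-exon single-transcript gene
  nx <- q[["INTERGENIC"]]
  if (nx > 0) {
    uid <- uid_of("INT")
    add("INT", data.table(uid = uid, tx = "T1", gene = "G",
                          s = 0L, e = 250L),
        cand = data.table(uid = uid, tx = "T1", category = "INTERGENIC"))
  }
  ex <- rbindlist(parts)
  list(exons = ex, candidates = rbindlist(cands), types = types)
}

#' Generate a synthetic fixture
#'
#' Plans the construct layout (deterministic under the spec's seed), places
#' constructs along contigs in seeded-shuffled order with random gaps,
#' alternating strands, and optionally generates the genomic sequence with
#' canonical GT..AG (strand-aware) motifs written at every intron.
#'
#' @param spec a [fixture_spec()].
#' @param sequence logical; generate the genome sequence (can be skipped
#'   for classification/design work that only needs coordinates).
#' @return list with `annotation`, `genome` (named character vector or
#'   `NULL`), and `manifest` (planted candidate table: `transcript_id`,
#'   `category`).
#' @export
synth_fixture <- function(spec, sequence = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(stage_seed(spec$seed, "fixture_plan"))
  built <- build_constructs(spec)
  ex <- built$exons
  # construct-level placement
  cons <- ex[, .(w = max(e)), by = uid]
  cons <- cons[sample(.N)]  # shuffle construct order along the genome
  n <- nrow(cons)
  cons[, gap := runif_int(n, spec$gap_range)]
  cons[, contig := sprintf("ctg%03d", (seq_len(n) - 1L) %/% spec$genes_per_contig + 1L)]
  cons[, offset := {
    o <- cumsum(as.numeric(w + gap)) - (w + gap)
    as.integer(o)
  }, by = contig]
  cons[, strand := c("+", "-")[(seq_len(n) %% 2L) + 1L]]
  ex <- ex[cons[, .(uid, contig, offset, strand)], on = "uid"]
  ex[, `:=`(s = s + offset, e = e + offset)]
  # antisense candidate genes sit on the strand opposite their host
  anti <- ex$gene == "GA"
  if (any(anti)) ex$strand[anti] <- ifelse(ex$strand[anti] == "+", "-", "+")
  exon_tab <- ex[, .(transcript_id = paste0(uid, "_", tx),
                     gene_id = paste0(uid, "_", gene),
                     contig, strand, start = s, end = e)]
  ann <- annotation(exon_tab)
  manifest <- built$candidates[, .(transcript_id = paste0(uid, "_", tx), category)]
  genome <- NULL
  if (sequence) genome <- fixture_genome(ann, cons, spec)
  list(annotation = ann, genome = genome, manifest = manifest)
}

# random background at the requested GC with canonical intron motifs patched in
fixture_genome <- function(ann, cons, spec) {
  set.seed(stage_seed(spec$seed, "fixture_seq"))
  clen <- cons[, .(len = max(offset + w + gap)), by = contig]
  p <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
  genome <- vapply(seq_len(nrow(clen)), function(i) {
    rawToChar(charToRaw("ACGT")[sample.int(4L, clen$len[i], replace = TRUE, prob = p)])
  }, character(1))
  names(genome) <- clen$contig
  # patch strand-aware canonical motifs at every annotated intron
  introns <- ann$transcripts[n_exons > 1L, {
    iv <- stringi::stri_split_fixed(chain, ";")[[1]]
    m <- stringi::stri_split_fixed(iv, "-", simplify = TRUE)
    .(istart = as.integer(m[, 1]), iend = as.integer(m[, 2]))
  }, by = .(transcript_id, contig, strand)]
  introns <- unique(introns[, .(contig, strand, istart, iend)])
  for (ctg in unique(introns$contig)) {
    r <- charToRaw(genome[[ctg]])
    sub <- introns[contig == ctg]
    plus <- sub$strand == "+"
    don <- charToRaw("GT"); acc <- charToRaw("AG")
    donm <- charToRaw("CT"); accm <- charToRaw("AC")
    if (any(plus)) {
      r[sub$istart[plus] + 1L] <- don[1]; r[sub$istart[plus] + 2L] <- don[2]
      r[sub$iend[plus] - 1L] <- acc[1]; r[sub$iend[plus]] <- acc[2]
    }
    if (any(!plus)) {
      r[sub$istart[!plus] + 1L] <- donm[1]; r[sub$istart[!plus] + 2L] <- donm[2]
      r[sub$iend[!plus] - 1L] <- accm[1]; r[sub$iend[!plus]] <- accm[2]
    }
    genome[[ctg]] <- rawToChar(r)
  }
  genome
}

#' @rdname synth_fixture
#' @export
synth_genome <- function(spec) synth_fixture(spec, sequence = TRUE)$genome

#' @rdname synth_fixture
#' @export
synth_annotation <- function(spec) {
  fx <- synth_fixture(spec, sequence = FALSE)
  fx[c("annotation", "manifest")]
}
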