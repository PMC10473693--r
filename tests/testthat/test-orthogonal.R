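# short-read and CAGE-peak simulation

mini_design <- function(seed = 81, per_cat = 2, n_fsm = 4, reads = 400) {
  fx <- tiny_fixture(seed = seed, per_cat = per_cat, n_fsm = n_fsm)
  idx <- classify_annotation(fx$annotation)
  des <- select_novel(idx, novelty_request(ism = per_cat, n_known = 2 * n_fsm),
                      seed = seed)
  des <- assign_expression(des, expression_equal(), reads, seed = seed)
  list(fx = fx, des = des)
}

test_that("short-read pair totals are conserved and mates have the configured length", {
  md <- mini_design()
  p <- short_read_params(n_pairs = 3000)
  pre <- tempfile()
  st <- simulate_short_reads(md$des, md$fx$annotation, md$fx$genome, p, pre, seed = 4)
  expect_equal(nrow(st), 3000L)
  r1 <- readLines(paste0(pre, "_R1.fasta"))
  r2 <- readLines(paste0(pre, "_R2.fasta"))
  expect_equal(length(r1), 6000L)
  expect_true(all(nchar(r1[seq(2, 6000, 2)]) == 100L))
  expect_true(all(nchar(r2[seq(2, 6000, 2)]) == 100L))
  expect_error(short_read_params(n_pairs = 10, read_length = 10), "20")
})

test_that("zero error rate reproduces fragment substrings exactly; mate 2 is reverse-complemented", {
  md <- mini_design(seed = 83)
  p <- short_read_params(n_pairs = 500, error_rate = 0)
  pre <- tempfile()
  st <- simulate_short_reads(md$des, md$fx$annotation, md$fx$genome, p, pre, seed = 5)
  seqs <- spliced_sequence(md$fx$genome, md$fx$annotation, st$transcript_id)
  r1 <- readLines(paste0(pre, "_R1.fasta"))[seq(2, 1000, 2)]
  r2 <- readLines(paste0(pre, "_R2.fasta"))[seq(2, 1000, 2)]
  expect_equal(r1, unname(substring(seqs, st$frag_start + 1, st$frag_start + 100)))
  expect_equal(r2, unname(revcomp(substring(seqs, st$frag_end - 99, st$frag_end))))
})

test_that("pairs are allocated proportionally to TPM x length", {
  md <- mini_design(seed = 87, n_fsm = 6, reads = 1200)
  p <- short_read_params(n_pairs = 20000)
  st <- simulate_short_reads(md$des, md$fx$annotation, md$fx$genome, p,
                             tempfile(), seed = 6)
  obs <- st[, .N, by = transcript_id][md$des, on = "transcript_id"]
  obs[is.na(N), N := 0L]
  w <- md$des$TPM * md$des$length
  chi <- suppressWarnings(chisq.test(obs$N, p = w / sum(w)))
  expect_gt(chi$p.value, 0.01)
})

test_that("TSS features behave under symmetric, empty and scaled coverage", {
  a <- mk_ann(list(list(id = "t", gene = "g", exons = list(c(500, 900)))),
              contig = "ctg")
  mkcov <- function(cov_vec, starts_vec, total) {
    list(cov = list(ctg = cov_vec), starts = list(ctg = starts_vec),
         total_reads = total)
  }
  L <- 2000L
  # uniform coverage on both sides: ratio exactly 1
  f1 <- tss_features(a, "t", mkcov(rep(5L, L), rep(0L, L), 100))
  expect_equal(f1$tss_ratio, 1)
  # zero coverage: pseudocounted ratio 1, proportion 0
  f0 <- tss_features(a, "t", mkcov(rep(0L, L), rep(0L, L), 100))
  expect_equal(f0$tss_ratio, 1)
  expect_equal(f0$tss_cov_prop, 0)
  # doubling downstream coverage doubles the unpseudocounted ratio
  cv <- rep(0L, L); cv[501:600] <- 10L   # downstream window of the + TSS at 500
  fA <- tss_features(a, "t", mkcov(cv, rep(0L, L), 100))
  cv2 <- cv * 2L
  fB <- tss_features(a, "t", mkcov(cv2, rep(0L, L), 100))
  expect_equal((fB$tss_ratio - 1) * 1, (fA$tss_ratio - 1) * 2, tolerance = 1e-9)
  # proportion counts starts in the 20-bp downstream window
  stv <- rep(0L, L); stv[501:520] <- 1L; stv[521:540] <- 1L
  fS <- tss_features(a, "t", mkcov(rep(0L, L), stv, 100))
  expect_equal(fS$tss_cov_prop, 20 / 100)
  # minus-strand transcript: downstream points left of the TSS
  am <- mk_ann(list(list(id = "t", gene = "g", strand = "-",
                         exons = list(c(500, 900)))), contig = "ctg")
  cvm <- rep(0L, L); cvm[800:899] <- 4L  # inside the body, downstream of TSS at 899
  fm <- tss_features(am, "t", mkcov(cvm, rep(0L, L), 100))
  expect_gt(fm$tss_ratio, 1)
  # TSS near the contig edge is clipped and flagged
  ae <- mk_ann(list(list(id = "t", gene = "g", exons = list(c(10, 300)))),
               contig = "ctg")
  fe <- tss_features(ae, "t", mkcov(rep(1L, L), rep(0L, L), 10))
  expect_true(fe$clipped)
})

test_that("coverage from simulated truth concentrates on exons", {
  md <- mini_design(seed = 91)
  p <- short_read_params(n_pairs = 2000)
  st <- simulate_short_reads(md$des, md$fx$annotation, md$fx$genome, p,
                             tempfile(), seed = 7)
  cov <- short_read_coverage(st, md$fx$annotation, md$fx$genome)
  expect_equal(cov$total_reads, 2000L)
  # total covered bases = 2 mates x 100 nt x pairs
  expect_equal(sum(vapply(cov$cov, sum, numeric(1))), 2000 * 200)
  # exonic positions of an expressed transcript get coverage, intron interior none
  id <- md$des[status == "known"][which.max(requested_reads), transcript_id]
  tx <- md$fx$annotation$transcripts[transcript_id == id]
  ex <- md$fx$annotation$exons[transcript_id == id]
  cv <- cov$cov[[tx$contig]]
  expect_gt(sum(cv[(ex$start[1] + 1):ex$end[1]]), 0)
})

test_that("logistic fit recovers known coefficients within 3 SEs", {
  set.seed(11)
  n <- 5000
  x1 <- rnorm(n); x2 <- rnorm(n)
  beta <- c(-1, 2, 3)
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x1 + beta[3] * x2))
  ft <- data.table(tss_ratio = exp(x1), tss_cov_prop = exp(x2))
  m <- fit_cage_model(ft, y, k = 10, pseudo = 0)
  fit <- glm(y ~ x1 + x2, family = binomial())
  se <- summary(fit)$coefficients[, "Std. Error"]
  expect_true(all(abs(m$beta - beta) < 3 * se))
  # the closed-form predictor matches an independent evaluation
  set.seed(12)
  for (i in 1:100) {
    b <- rnorm(3); f <- data.table(tss_ratio = exp(rnorm(1)), tss_cov_prop = exp(rnorm(1)))
    mm <- structure(list(beta = b, pseudo = 0), class = "cage_model")
    expect_equal(predict_tss_support(mm, f),
                 1 / (1 + exp(-(b[1] + b[2] * log(f$tss_ratio) +
                                  b[3] * log(f$tss_cov_prop)))))
  }
})

test_that("separable data reach perfect CV accuracy; null labels fall to the base rate", {
  set.seed(13)
  n <- 600
  x1 <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
  ft <- data.table(tss_ratio = exp(x1), tss_cov_prop = exp(rnorm(n)))
  y <- as.integer(x1 > 0)
  m <- suppressWarnings(fit_cage_model(ft, y, k = 5, pseudo = 0))
  expect_equal(m$cv_accuracy, 1.0)
  # labels independent of features: accuracy near the majority-class fraction
  y2 <- rbinom(n, 1, 0.7)
  m2 <- fit_cage_model(data.table(tss_ratio = exp(rnorm(n)),
                                  tss_cov_prop = exp(rnorm(n))), y2, k = 5)
  expect_lt(abs(m2$cv_accuracy - mean(y2 == 1)), 0.05)
  expect_error(fit_cage_model(ft, rep(1, n)), "single class")
})

test_that("simulated CAGE peaks land at TSS with the drawn length and distance", {
  # hand-built 3-transcript case with a forced-support model
  a <- mk_ann(list(
    list(id = "t1", gene = "g1", exons = list(c(1000, 1400))),
    list(id = "t2", gene = "g2", exons = list(c(3000, 3400))),
    list(id = "t3", gene = "g3", strand = "-", exons = list(c(5000, 5400)))))
  des <- data.table(transcript_id = c("t1", "t2", "t3"),
                    gene_id = c("g1", "g2", "g3"), status = "known",
                    category = "FSM", length = 400L, n_exons = 1L)
  ec <- list(supporting = data.table(peak_len = 20L, distance = 6L),
             nonsupporting = data.table(peak_len = 30L, distance = 500L))
  pk <- simulate_cage_peaks(des, a, cage_model_constant(1), ec,
                            false_fraction = 0, seed = 3)
  expect_equal(nrow(pk), 3L)
  expect_true(all(pk$supports_tss))
  # center = TSS + strand-aware distance; length as drawn
  expect_equal(pk$end - pk$start, rep(20L, 3))
  centers <- pk$start + 10L
  expect_equal(sort(centers), sort(c(1000L + 6L, 3000L + 6L, 5399L - 6L)))
  expect_error(simulate_cage_peaks(des, a, cage_model_constant(1), ec,
                                   false_fraction = 1), "false_fraction")
})

test_that("requested non-supporting fraction is recovered within 3 binomial SDs", {
  fx <- tiny_fixture(seed = 97, per_cat = 1, n_fsm = 1500, sequence = FALSE)
  idx <- classify_annotation(fx$annotation)
  des <- select_novel(idx, novelty_request(n_known = 2500), seed = 4)
  set.seed(20)
  ec <- list(supporting = data.table(peak_len = sample(20:60, 400, TRUE),
                                     distance = sample(-20:20, 400, TRUE)),
             nonsupporting = data.table(peak_len = sample(30:90, 400, TRUE),
                                        distance = sample(300:3000, 400, TRUE)))
  f <- 0.25
  pk <- simulate_cage_peaks(des, fx$annotation, cage_model_constant(1), ec,
                            false_fraction = f, seed = 21)
  expect_gte(nrow(pk), 2000L)
  sd3 <- 3 * sqrt(f * (1 - f) / nrow(pk))
  expect_lt(abs(mean(!pk$supports_tss) - f), sd3 + 1 / nrow(pk))
  # marginals of the drawn (length, distance) match the training multiset
  sup <- pk[pk$supports_tss == TRUE]
  ksl <- suppressWarnings(ks.test(sup$end - sup$start, ec$supporting$peak_len))
  expect_gt(ksl$p.value, 0.01)
})

test_that("cage_profile measures length, center distance and TSS overlap", {
  a <- mk_ann(list(list(id = "t", gene = "g", exons = list(c(1000, 1500)))))
  pk <- data.table(contig = "chr1",
                   start = c(990L, 1200L), end = c(1010L, 1240L))
  pr <- cage_profile(pk, a)
  expect_equal(pr$peak_len, c(20L, 40L))
  expect_equal(pr$supporting, c(TRUE, FALSE))
  expect_equal(pr$distance, c(0L, 220L))  # centers 1000 and 1220 vs TSS 1000
})
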