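test_that("ECDF quantile is the generalized inverse of the empirical CDF", {
  e <- empirical_ecdf(c(2, 2, 8))
  expect_equal(ecdf_quantile(e, 0.5), 2)   # P(X <= 2) = 2/3 >= 0.5
  expect_equal(ecdf_quantile(e, 2/3), 2)
  expect_equal(ecdf_quantile(e, 0.7), 8)
  expect_equal(ecdf_quantile(e, 1), 8)     # maximum support value
  expect_equal(ecdf_quantile(e, 0), 2)
  expect_error(ecdf_quantile(e, 1.1), "0, 1")
  # monotone in u
  u <- sort(runif(200))
  q <- ecdf_quantile(empirical_ecdf(rpois(100, 5) + 1), u)
  expect_true(all(diff(q) >= 0))
  expect_error(empirical_ecdf(c(0, 0)), "positive")
})

test_that("select_novel honors forced choices, shortfalls and the length filter", {
  fx <- tiny_fixture(seed = 41, per_cat = 3, n_fsm = 3, sequence = FALSE)
  idx <- classify_annotation(fx$annotation)
  # forced choice: request every eligible ISM
  n_ism <- idx[category == "ISM" & length >= 200, .N]
  des <- select_novel(idx, novelty_request(ism = n_ism), seed = 1)
  expect_setequal(des[status == "novel", transcript_id],
                  idx[category == "ISM" & length >= 200, transcript_id])
  # shortfall names the category and the numbers
  expect_error(select_novel(idx, novelty_request(nic = 1000), seed = 1),
               "NIC.*1000")
  # candidates below min_length are ineligible
  short_idx <- copy(idx)[category == "NIC", length := 150L]
  expect_error(select_novel(short_idx, novelty_request(nic = 1), seed = 1),
               "NIC")
  # determinism: same seed, same selection
  d1 <- select_novel(idx, novelty_request(ism = 2, nnc = 2), seed = 9)
  d2 <- select_novel(idx, novelty_request(ism = 2, nnc = 2), seed = 9)
  expect_equal(d1$transcript_id, d2$transcript_id)
})

test_that("novel and known partition the simulated set", {
  fx <- tiny_fixture(seed = 43, per_cat = 3, n_fsm = 4, sequence = FALSE)
  idx <- classify_annotation(fx$annotation)
  req <- novelty_request(ism = 2, nic = 2, nnc = 2, antisense = 2,
                         fusion = 2, intergenic = 2, genic_genomic = 2,
                         n_known = 6)
  des <- select_novel(idx, req, seed = 3)
  expect_equal(des[status == "novel", .N], 14L)
  expect_equal(des[status == "known", .N], 6L)
  expect_length(intersect(des[status == "novel", transcript_id],
                          des[status == "known", transcript_id]), 0)
  expect_true(all(des[status == "known", category] == "FSM"))
})

test_that("reduction removes novel transcripts and verifies designations", {
  fx <- tiny_fixture(seed = 47, per_cat = 3, n_fsm = 3, sequence = FALSE)
  idx <- classify_annotation(fx$annotation)
  req <- novelty_request(ism = 2, nic = 2, nnc = 2, antisense = 2,
                         fusion = 2, intergenic = 2, genic_genomic = 2)
  des <- select_novel(idx, req, seed = 5)
  red <- reduce_annotation(fx$annotation, des, idx)
  novel <- red$design[status == "novel", transcript_id]
  expect_length(intersect(novel, red$reduced$transcripts$transcript_id), 0)
  expect_equal(red$verification$designated, red$verification$observed)
  # re-classification counts per category equal the request
  tab <- red$verification[, .N, by = designated]
  expect_true(all(tab$N == 2L))
})

test_that("an unverifiable designation is swapped or reported, never silent", {
  # gene with A (junctions J1 J2) and B (J1): removing both cannot leave
  # B as ISM because its reference partner is gone
  ann <- mk_ann(list(
    list(id = "A", gene = "g", exons = list(c(0, 100), c(200, 300), c(400, 500))),
    list(id = "B", gene = "g", exons = list(c(0, 100), c(200, 280)))))
  idx <- classify_annotation(ann)
  expect_equal(idx[transcript_id == "B", category], "ISM")
  des <- select_novel(idx, novelty_request(ism = 1, nnc = 1, min_length = 0), seed = 1)
  # both transcripts are now designated novel; no replacements exist
  expect_error(reduce_annotation(ann, des, idx), "replacement|budget")
})

test_that("equal mode splits the total evenly and conserves it", {
  fx <- tiny_fixture(seed = 53, per_cat = 2, n_fsm = 3, sequence = FALSE)
  idx <- classify_annotation(fx$annotation)
  des <- select_novel(idx, novelty_request(ism = 2, n_known = 8), seed = 2)
  ex <- assign_expression(des, expression_equal(), 1000, seed = 2)
  expect_equal(sum(ex$requested_reads), 1000L)
  expect_true(all(ex$requested_reads == 100L))
  # non-divisible totals differ by at most one read
  ex2 <- assign_expression(des, expression_equal(), 1003, seed = 2)
  expect_equal(sum(ex2$requested_reads), 1003L)
  expect_lte(diff(range(ex2$requested_reads)), 1L)
  # TPM normalizes to 1e6
  expect_equal(sum(ex$TPM), 1e6)
})

test_that("custom mode draws from two negative binomials and validates them", {
  expect_error(expression_custom(0, 0.5, 1, 0.5), "size")
  expect_error(expression_custom(1, 0, 1, 0.5), "size|prob")
  fx <- tiny_fixture(seed = 59, per_cat = 3, n_fsm = 6, sequence = FALSE)
  idx <- classify_annotation(fx$annotation)
  des <- select_novel(idx, novelty_request(ism = 3, n_known = 12), seed = 4)
  m <- expression_custom(5, 0.05, 2, 0.5)  # novel mean far below known mean
  ex <- assign_expression(des, m, 5000, seed = 4)
  expect_equal(sum(ex$requested_reads), 5000L)
  expect_gt(median(ex[status == "known", requested_reads]),
            median(ex[status == "novel", requested_reads]))
})

test_that("sample mode reproduces the empirical distribution and diff_exp biases it", {
  set.seed(1)
  counts <- rnbinom(5000, size = 0.8, mu = 50) + 1
  # large design: half known, half novel
  idx <- data.table(
    transcript_id = sprintf("t%05d", 1:4000),
    gene_id = sprintf("g%05d", 1:4000),
    category = rep(c("FSM", "ISM"), each = 2000),
    length = 1000L, n_exons = 2L)
  des <- select_novel(idx, novelty_request(ism = 2000, n_known = 2000), seed = 6)
  # diff_exp = 0: known and novel counts from the same distribution
  ex0 <- assign_expression(des, expression_sample(counts, diff_exp = 0),
                           400000, seed = 6)
  ks <- suppressWarnings(ks.test(ex0[status == "known", requested_reads],
                                 ex0[status == "novel", requested_reads]))
  expect_gt(ks$p.value, 0.01)
  # diff_exp = 2: novel expression is pushed down
  ex2 <- assign_expression(des, expression_sample(counts, diff_exp = 2),
                           400000, seed = 6)
  expect_lt(median(ex2[status == "novel", requested_reads]),
            median(ex2[status == "known", requested_reads]))
  expect_equal(sum(ex2$requested_reads), 400000L)
  # stochastic ordering of the sampler: for the same u, a larger diff_exp
  # never yields a larger novel count (ECDF dominance)
  e <- empirical_ecdf(counts)
  u <- runif(5000)
  expect_true(all(ecdf_quantile(e, u^(1 + 2)) <= ecdf_quantile(e, u^(1 + 0.5))))
  # every simulated transcript gets at least one read
  expect_gte(min(ex2$requested_reads), 1L)
})

test_that("iso_complex known selection tracks the per-gene isoform distribution", {
  # many genes with 4 FSM candidates each; ask for 2 per gene on average
  txs <- list()
  for (g in 1:80) for (i in 1:4) {
    base <- g * 2000
    txs[[length(txs) + 1]] <- list(
      id = sprintf("g%03d_t%d", g, i), gene = sprintf("g%03d", g),
      exons = list(c(base + i * 10, base + 300), c(base + 500, base + 800)))
  }
  ann <- mk_ann(txs)
  idx <- classify_annotation(ann)
  expect_true(all(idx$category == "FSM"))
  des <- select_novel(idx, novelty_request(n_known = 160), seed = 8,
                      iso_dist = rep(2L, 50))
  per_gene <- des[, .N, by = gene_id]
  # most selected genes express exactly 2 isoforms
  expect_gte(mean(per_gene$N == 2L), 0.8)
  expect_equal(nrow(des), 160L)
})

test_that("design table round-trips through the TSV format", {
  fx <- tiny_fixture(seed = 61, per_cat = 2, n_fsm = 2, sequence = FALSE)
  idx <- classify_annotation(fx$annotation)
  des <- select_novel(idx, novelty_request(ism = 1, n_known = 4), seed = 1)
  des <- assign_expression(des, expression_equal(), 500, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_design(des, f)
  d2 <- read_design(f)
  expect_equal(d2$transcript_id, des$transcript_id)
  expect_equal(d2$requested_reads, des$requested_reads)
  expect_equal(names(d2)[1:5],
               c("transcript_id", "status", "category", "requested_reads", "TPM"))
})
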