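test_that("tau matches hand-evaluated cases and boundary rules", {
  m <- expression_matrix(rbind(
    single = c(1, 0, 0, 0, 0),
    uniform = c(3, 3, 3, 3, 3),
    graded = c(10, 2, 1, 1, 1),
    weak = c(0.5, 0.2, 0, 0, 0),   # max < tpm_min -> excluded
    zero = c(0, 0, 0, 0, 0)
  ))
  colnames(m$tpm) <- paste0("t", 1:5)
  r <- compute_tau(m)
  expect_setequal(r$feature, c("single", "uniform", "graded"))
  expect_equal(r$tau[r$feature == "single"], 1)
  expect_equal(r$tau[r$feature == "uniform"], 0)
  expect_equal(r$tau[r$feature == "graded"], 0.875)
  expect_true(r$is_tra[r$feature == "graded"])
  expect_false(r$is_tra[r$feature == "uniform"])
  expect_equal(r$expressing_tissues[r$feature == "single"], "t1")
  expect_true(all(nzchar(r$expressing_tissues)))

  one_col <- expression_matrix(matrix(1, 1, 1, dimnames = list("g", "t")))
  expect_error(compute_tau(one_col), "2 tissue")
})

test_that("tau is invariant to column permutation and row scaling", {
  set.seed(14)
  tpm <- matrix(rexp(60, 0.2), 10, 6,
                dimnames = list(sprintf("g%02d", 1:10), paste0("t", 1:6)))
  base <- compute_tau(expression_matrix(tpm))
  perm <- compute_tau(expression_matrix(tpm[, sample(6)]))
  expect_equal(perm$tau[match(base$feature, perm$feature)], base$tau)
  scaled <- compute_tau(expression_matrix(tpm * 7))
  expect_equal(scaled$tau[match(base$feature, scaled$feature)], base$tau)
  # tau = 0 iff all retained values equal; tau = 1 iff one nonzero tissue
  expect_true(all(base$tau[apply(tpm, 1, function(v) sum(v > 0) == 1)] == 1))
})

test_that("binarization picks the largest gap, conservatively on ties", {
  expect_equal(unname(binarize_tissues(c(a = 0.1, b = 0.1, c = 0.2, d = 5))), 4L)
  expect_equal(sort(unname(binarize_tissues(c(5, 5, 0.1)))), c(1L, 2L))
  expect_equal(sort(unname(binarize_tissues(c(3, 3, 3)))), 1:3)
  # equal gaps: 1,2,3 has gaps (1,1); tie resolves to the higher gap -> {3}
  expect_equal(unname(binarize_tissues(c(1, 2, 3))), 3L)
  expect_error(binarize_tissues(numeric(0)), "empty")
})

test_that("expressed fractions are exact and monotone in the threshold", {
  m <- expression_matrix(matrix(c(2, 1.2, 1, 0.4), 4, 1,
                                dimnames = list(paste0("g", 1:4), "t1")))
  r <- expressed_fraction(m, thresholds = 1)
  expect_equal(r$fraction, 0.75)
  expect_equal(expressed_fraction(m, thresholds = 99)$fraction, 0)
  multi <- expressed_fraction(m, thresholds = c(0.5, 1, 2))
  expect_true(all(diff(multi$fraction) <= 0))
  expect_error(expressed_fraction(m, thresholds = 0), "> 0")
  expect_error(expressed_fraction(m, thresholds = 1, feature_set = "gX"),
               "intersect")
})

test_that("splicing entropy matches closed forms and is scale-invariant", {
  tpm <- rbind(ga.1 = c(1, 10), ga.2 = c(1, 10), ga.3 = c(1, 10), ga.4 = c(1, 10),
               gb.1 = c(2, 4), gb.2 = c(1, 2), gb.3 = c(1, 2),
               gc.1 = c(5, 0))
  colnames(tpm) <- c("s1", "s2")
  map <- setNames(c(rep("ga", 4), rep("gb", 3), "gc"), rownames(tpm))
  m <- expression_matrix(tpm, level = "transcript", tx2gene = map)
  r <- splicing_entropy(m)
  pg <- r$per_gene
  expect_equal(pg$entropy[pg$gene == "ga" & pg$column == "s1"], 2)
  expect_equal(pg$entropy[pg$gene == "gb" & pg$column == "s1"], 1.5)
  # single expressed isoform -> ineligible
  expect_true(is.na(pg$entropy[pg$gene == "gc" & pg$column == "s1"]))
  # scale invariance: s2 is s1 with per-gene multipliers
  expect_equal(pg$entropy[pg$column == "s2"][1:2], c(2, 1.5))
  expect_equal(unname(r$column_medians["s1"]), median(c(2, 1.5)))
  # bounds
  eligible <- pg[!is.na(pg$entropy), ]
  expect_true(all(eligible$entropy >= 0))
  expect_true(all(eligible$entropy <= log2(eligible$n_expressed_isoforms) + 1e-12))

  gene_level <- expression_matrix(tpm, level = "gene")
  expect_error(splicing_entropy(gene_level), "transcript-level")
  nomap <- expression_matrix(tpm, level = "transcript")
  expect_error(splicing_entropy(nomap), "map")
})

test_that("transcripts~genes regression is exact on a perfect line", {
  # summary.lm warns on an exactly perfect fit; irrelevant to the contract
  fit <- suppressWarnings(
    transcripts_vs_genes_fit(data.frame(n_genes = 1:3,
                                        n_transcripts = c(2, 4, 6)),
                             query_points = 4))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-9)
  expect_equal(fit$predictions$predicted, 8, tolerance = 1e-9)
  expect_true(all(fit$predictions$ci_half_width >= 0))

  expect_error(transcripts_vs_genes_fit(data.frame(n_genes = c(1, 2),
                                                   n_transcripts = c(1, 2))),
               ">= 3")
  expect_error(transcripts_vs_genes_fit(data.frame(n_genes = c(2, 2, 2),
                                                   n_transcripts = 1:3)),
               "variance")
})

test_that("noisy regression CI covers the mean response", {
  set.seed(19)
  x <- seq(100, 1000, length.out = 12)
  y <- 50 + 1.8 * x + rnorm(12, 0, 20)
  fit <- transcripts_vs_genes_fit(data.frame(n_genes = x, n_transcripts = y),
                                  query_points = 550)
  expect_gt(fit$predictions$ci_half_width, 0)
  expect_lt(abs(fit$slope - 1.8), 0.2)
})

test_that("aggregate_tissues takes per-tissue medians", {
  tpm <- matrix(c(1, 3, 5, 2, 4, 6), 1, dimnames = list("g", paste0("s", 1:6)))
  m <- expression_matrix(tpm)
  agg <- aggregate_tissues(m, setNames(rep(c("A", "B"), each = 3),
                                       paste0("s", 1:6)))
  expect_equal(unname(agg$tpm["g", ]), c(3, 4))
})
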