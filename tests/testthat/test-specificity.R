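five_five_design <- function() {
  sample_group_design(c(paste0("hi_", 1:5), paste0("lo_", 1:5)),
                      rep(c("hi", "lo"), each = 5), rep(1:5, 2))
}

presence_matrix <- function(hi, lo) {
  m <- matrix(c(hi, lo), nrow = length(hi) / 5, byrow = FALSE)
  m <- matrix(as.logical(c(hi, lo)), ncol = 10,
              dimnames = list(sprintf("t%02d", seq_len(length(hi) / 5)),
                              c(paste0("hi_", 1:5), paste0("lo_", 1:5))))
  m
}

test_that("population-specific classification follows the two-sample rule", {
  pres <- rbind(
    t1 = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),  # >=2 hi, 0 lo -> hi_specific
    t2 = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0),  # 1 hi only -> unreplicated
    t3 = c(1, 1, 0, 0, 0, 1, 0, 0, 0, 0),  # both groups -> shared
    t4 = c(0, 0, 0, 0, 0, 1, 1, 0, 0, 0),  # lo_specific
    t5 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0)   # absent -> unreplicated
  ) == 1
  colnames(pres) <- c(paste0("hi_", 1:5), paste0("lo_", 1:5))
  lab <- classify_population_specific(pres, five_five_design())
  expect_equal(lab$label,
               c("hi_specific", "unreplicated", "shared", "lo_specific",
                 "unreplicated"))
  # labels partition the set; hi_specific with lo presence is impossible
  expect_true(all(table(lab$id) == 1))
  expect_error(classify_population_specific(
    pres[, 1:6], sample_group_design(colnames(pres)[1:6],
                                     c(rep("hi", 5), "lo"), c(1:5, 1))),
    "samples")
})

test_that("classification never calls hi_specific with any lo presence", {
  set.seed(4)
  for (rep in 1:20) {
    pres <- matrix(runif(200) < 0.3, ncol = 10,
                   dimnames = list(sprintf("t%02d", 1:20),
                                   c(paste0("hi_", 1:5), paste0("lo_", 1:5))))
    lab <- classify_population_specific(pres, five_five_design())
    hi <- lab$id[lab$label == "hi_specific"]
    expect_true(all(rowSums(pres[hi, 6:10, drop = FALSE]) == 0))
    lo <- lab$id[lab$label == "lo_specific"]
    expect_true(all(rowSums(pres[lo, 1:5, drop = FALSE]) == 0))
  }
})

test_that("paired t-test reproduces the worked example and degenerate cases", {
  res <- paired_t_test(c(0, 0, 0, 0, 0), c(100, 100, 100, 0, 0))
  expect_equal(res$t, 2.449, tolerance = 1e-3)
  expect_equal(res$df, 4L)
  expect_equal(res$p, 0.0705, tolerance = 1e-3)
  expect_equal(round(res$p, 2), 0.07)
  # cross-check against the reference implementation
  expect_equal(res$p, t.test(c(100, 100, 100, 0, 0), c(0, 0, 0, 0, 0),
                             paired = TRUE)$p.value, tolerance = 1e-12)

  expect_error(paired_t_test(1:5, 1:5), "degenerate")
  res2 <- paired_t_test(c(0, 0), c(1, -1))
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
})

test_that("paired t-test is antisymmetric", {
  set.seed(8)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    a <- paired_t_test(x, y); b <- paired_t_test(y, x)
    expect_equal(a$t, -b$t)
    expect_equal(a$p, b$p)
  }
})

test_that("Fisher odds ratios match enumeration and hand-worked tables", {
  r <- fisher_or(20, 80, 10, 90)
  expect_equal(r$odds_ratio, 2.25)
  expect_equal(r$p, fisher_p_enumeration(20, 80, 10, 90), tolerance = 1e-12)

  r2 <- fisher_or(1, 0, 0, 1)
  expect_equal(r2$p, 1.0)
  expect_equal(r2$odds_ratio, 9)  # Haldane-corrected

  r3 <- fisher_or(5, 5, 5, 5)
  expect_equal(r3$odds_ratio, 1)
  expect_equal(r3$p, 1)

  set.seed(12)
  for (rep in 1:20) {
    cells <- sample(0:40, 4, replace = TRUE)
    if (sum(cells) == 0) next
    r <- fisher_or(cells[1], cells[2], cells[3], cells[4])
    expect_equal(r$p, fisher_p_enumeration(cells[1], cells[2], cells[3],
                                           cells[4]), tolerance = 1e-9)
    # swapping group rows inverts the OR and preserves p
    rs <- fisher_or(cells[3], cells[4], cells[1], cells[2])
    expect_equal(rs$p, r$p, tolerance = 1e-12)
    if (all(cells > 0)) expect_equal(rs$odds_ratio, 1 / r$odds_ratio)
    if (all(cells > 0)) {
      expect_lte(r$ci_low, r$odds_ratio)
      expect_gte(r$ci_high, r$odds_ratio)
    }
  }
})

test_that("enrichment_odds_ratio builds the table from labels and membership", {
  lab <- data.frame(id = sprintf("t%02d", 1:8),
                    label = c(rep("hi_specific", 4), rep("lo_specific", 3),
                              "shared"))
  member <- setNames(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
                     lab$id)
  r <- enrichment_odds_ratio(lab, member)
  expect_equal(unname(r$table), c(3, 1, 1, 2))
  expect_equal(r$odds_ratio, 6)
  expect_error(enrichment_odds_ratio(lab[lab$label != "lo_specific", ], member),
               "lo_specific")
})

test_that("Mann-Whitney exact enumeration handles ties and known cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 / choose(6, 3)
  expect_equal(mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 2, 3))$p, 1)
  # agreement with wilcox.test when there are no ties
  set.seed(3)
  x <- rnorm(6); y <- rnorm(7)
  expect_equal(mann_whitney_u(x, y)$p,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("tsrs_per_gene counts genes and compares populations", {
  lab <- data.frame(id = sprintf("t%02d", 1:6),
                    label = c(rep("hi_specific", 3), rep("lo_specific", 3)))
  ann <- data.frame(id = lab$id,
                    category = "promoter",
                    nearest_gene_id = c("g1", "g1", "g2", "g3", "g4", "g5"))
  pres <- matrix(TRUE, 6, 10,
                 dimnames = list(lab$id,
                                 c(paste0("hi_", 1:5), paste0("lo_", 1:5))))
  r <- tsrs_per_gene(lab, ann, pres, five_five_design())
  expect_equal(r$mean_hi, 1.5)   # genes g1 (2 TSRs) and g2 (1)
  expect_equal(r$mean_lo, 1)
  expect_true(r$test$p > 0 && r$test$p <= 1)
})

test_that("gene-set fractions and mis-initiation rates use per-sample denominators", {
  design <- five_five_design()
  ids <- sprintf("t%02d", 1:10)
  lab <- data.frame(id = ids, label = c(rep("hi_specific", 5),
                                        rep("lo_specific", 5)))
  pres <- matrix(FALSE, 10, 10, dimnames = list(ids, design$sample_id))
  pres[1:5, 1:5] <- TRUE    # all hi-specific TSRs present in every hi sample
  pres[6:10, 6:10] <- TRUE
  ann <- data.frame(id = ids,
                    category = c("promoter", "promoter", "promoter", "intron",
                                 "promoter", rep("promoter", 5)),
                    nearest_gene_id = c("g1", "g2", "g3", "g4", "g5",
                                        "g6", "g7", "g8", "g9", "g10"))
  gf <- suppressWarnings(geneset_fractions(lab, ann, pres, design, gene_set = c("g1", "g2")))
  expect_equal(gf$fractions$fraction[gf$fractions$group == "hi"], rep(0.4, 5))
  expect_equal(gf$fractions$fraction[gf$fractions$group == "lo"], rep(0, 5))

  mr <- suppressWarnings(misinitiation_rates(ann, lab, pres, design))
  expect_equal(mr$rates$rate[mr$rates$group == "hi"], rep(0.2, 5))
  expect_equal(mr$rates$rate[mr$rates$group == "lo"], rep(0, 5))
  expect_equal(unname(mr$enrichment$table), c(1, 4, 0, 5))
  # grouping 5' UTR with promoters removes a reclassified mis-initiation
  ann2 <- ann; ann2$category[4] <- "five_utr"
  mr2 <- suppressWarnings(misinitiation_rates(ann2, lab, pres, design,
                             promoter_like = c("promoter", "five_utr")))
  expect_equal(mr2$rates$rate[mr2$rates$group == "hi"], rep(0, 5))
  # gene level: a gene with {promoter, intergenic} TSRs counts as mis-initiated
  ann3 <- ann
  ann3$nearest_gene_id[1:2] <- "g1"
  ann3$category[1] <- "promoter"; ann3$category[2] <- "intergenic"
  mr3 <- suppressWarnings(misinitiation_rates(ann3, lab, pres, design, level = "gene"))
  hi_rates <- mr3$rates$rate[mr3$rates$group == "hi"]
  expect_equal(hi_rates, rep(2 / 4, 5))  # g1 (intergenic TSR) + g4 (intron) of 4 genes
})

test_that("leave-one-out reproduces the 3-tissue hand example", {
  pres <- rbind(t1 = c(1, 0, 0), t2 = c(1, 0, 1),
                t3 = c(0, 1, 0), t4 = c(0, 1, 1)) == 1
  colnames(pres) <- c("T1", "T2", "T3")
  r <- leave_one_out_specificity(pres)
  expect_equal(r$F["T1", ], c(T1 = NA, T2 = 0, T3 = 0.5))
  expect_equal(r$F["T2", ], c(T1 = 0, T2 = NA, T3 = 0.5))
  expect_equal(r$F["T3", ], c(T1 = 1, T2 = 1, T3 = NA))
  expect_equal(unname(r$Z["T1", c("T2", "T3")]), c(-1, 1))
  # defined rows are centered with unit population SD
  for (u in rownames(r$Z)) {
    z <- r$Z[u, !is.na(r$Z[u, ])]
    if (length(z) >= 2 && sd(z) > 0) {
      expect_equal(mean(z), 0, tolerance = 1e-12)
      expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-12)
    }
  }
  expect_error(leave_one_out_specificity(pres[, 1:2]), ">= 3")

  # permuting tissues permutes rows/columns consistently
  perm <- c("T3", "T1", "T2")
  r2 <- leave_one_out_specificity(pres[, perm])
  expect_equal(r2$F[perm, perm], r$F[perm, perm])

  # fully shared TSRs -> everything undefined
  allshare <- matrix(TRUE, 4, 3, dimnames = list(rownames(pres), colnames(pres)))
  expect_true(all(is.na(leave_one_out_specificity(allshare)$F)))
})
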