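test_that("sim_config validates its invariants", {
  expect_error(sim_config(zipf_exponent = 1), "zipf_exponent")
  expect_error(sim_config(detection_prob = 0), "detection_prob")
  expect_error(sim_config(frac_hi_specific = 0.7, frac_lo_specific = 0.7),
               "sum")
  expect_error(sim_config(noise_tags_per_kb = -1), "noise")
  expect_error(sim_config(dirichlet_alpha = 0), "dirichlet")
  expect_error(sim_config(isoforms_per_gene_range = c(0, 3)), "isoforms")
  expect_error(sim_config(genome = c(100, 200)), "named")
})

test_that("generation is seed-deterministic, bit for bit", {
  cfg <- small_config(seed = 5L)
  a <- gen_tss_dataset(cfg); b <- gen_tss_dataset(cfg)
  expect_identical(a, b)
  expect_identical(gen_expression_matrix(cfg), gen_expression_matrix(cfg))
  expect_identical(gen_isoform_profiles(cfg), gen_isoform_profiles(cfg))
  expect_identical(gen_annotation(cfg, a$truth), gen_annotation(cfg, a$truth))
  # a different seed changes the data
  expect_false(identical(a$tracks, gen_tss_dataset(small_config(seed = 6L))$tracks))
})

test_that("planted group structure is strict: no cross-population tags", {
  cfg <- small_config(seed = 2L, noise_tags_per_kb = 0)
  ds <- gen_tss_dataset(cfg)
  pr <- ds$truth$promoters
  hi_prom <- pr[pr$group == "hi_specific", ]
  expect_equal(nrow(hi_prom), round(0.2 * cfg$n_promoters))
  lo_samples <- grep("^lo_", colnames(ds$truth$activity), value = TRUE)
  expect_true(all(!ds$truth$activity[hi_prom$promoter_id, lo_samples]))
  # with zero background, no tag of any lo sample falls near a hi promoter
  w <- cfg$promoter_width_bp
  for (s in lo_samples) {
    d <- ds$tracks[[s]]$data
    for (r in seq_len(nrow(hi_prom))) {
      near <- d$chrom == hi_prom$chrom[r] & d$strand == hi_prom$strand[r] &
        abs(d$pos - hi_prom$center[r]) <= w
      expect_equal(sum(d$value[near]), 0)
    }
  }
})

test_that("per-sample tag totals are conserved", {
  cfg <- small_config(seed = 9L)
  ds <- gen_tss_dataset(cfg)
  expected_noise <- cfg$noise_tags_per_kb * sum(cfg$genome) / 1000
  rounding_slack <- cfg$n_promoters / 2
  for (trk in ds$tracks) {
    total <- track_total(trk)
    expect_gte(total, cfg$total_tags_per_sample - rounding_slack)
    expect_lte(total, cfg$total_tags_per_sample + rounding_slack +
                 expected_noise + 5 * sqrt(expected_noise + 1))
  }
})

test_that("promoter placement respects spacing and rejects infeasible configs", {
  cfg <- small_config(seed = 1L)
  ds <- gen_tss_dataset(cfg)
  pr <- ds$truth$promoters
  for (ch in unique(pr$chrom)) {
    centers <- sort(pr$center[pr$chrom == ch])
    if (length(centers) > 1) {
      expect_true(all(diff(centers) > 4 * cfg$promoter_width_bp + 40))
    }
  }
  expect_error(gen_tss_dataset(sim_config(genome = c(c1 = 2000L),
                                          n_promoters = 1000L)),
               "placement")
})

test_that("per-promoter totals re-fit to the planted power-law exponent", {
  alphas <- vapply(11:13, function(seed) {
    # noise-free so the reconstructed totals are purely promoter-derived; many
    # promoters so the totals span enough distinct values for a stable refit
    cfg <- sim_config(seed = seed, genome = c(chr1 = 3000000L),
                      n_promoters = 20000L, n_genes = 100L,
                      total_tags_per_sample = 50000L, noise_tags_per_kb = 0)
    ds <- gen_tss_dataset(cfg)
    # reconstruct per-promoter totals of one sample from its tag track
    w <- cfg$promoter_width_bp
    pr <- ds$truth$promoters
    d <- ds$tracks$hi_1$data
    totals <- numeric(nrow(pr))
    for (key in split(seq_len(nrow(pr)), paste(pr$chrom, pr$strand))) {
      ord <- order(pr$center[key])
      centers <- pr$center[key][ord]
      dd <- d[d$chrom == pr$chrom[key[1]] & d$strand == pr$strand[key[1]], ]
      if (nrow(dd) == 0) next
      idx <- findInterval(dd$pos, centers - w - 0.5)
      ok <- idx >= 1 & idx <= length(centers)
      ok[ok] <- abs(dd$pos[ok] - centers[idx[ok]]) <= w
      sums <- tapply(dd$value[ok], idx[ok], sum)
      totals[key[ord][as.integer(names(sums))]] <- sums
    }
    totals <- totals[totals > 0]
    trk <- build_track(data.frame(chrom = "x", pos = seq_along(totals),
                                  strand = "+", count = as.integer(totals)))
    fit_power_law(trk)$alpha
  }, numeric(1))
  expect_lt(abs(mean(alphas) - 1.5), 0.15)
  expect_true(all(abs(alphas - 1.5) < 0.3))
})

test_that("annotation places canonical promoters at gene starts", {
  cfg <- small_config(seed = 3L)
  ds <- gen_tss_dataset(cfg)
  ann <- gen_annotation(cfg, ds$truth)
  g <- ann$annotation$genes
  gt <- ann$gene_truth
  centers <- ds$truth$promoters$center[match(gt$promoter_id,
                                             ds$truth$promoters$promoter_id)]
  expect_true(all(abs(g$tss[match(gt$gene_id, g$gene_id)] - centers) <= 10))
  # TSS inside the gene span; exons within the gene; CDS only in coding genes
  expect_true(all(g$tss >= g$start & g$tss <= g$end))
  ex <- ann$annotation$exons
  expect_true(all(ex$start <= ex$end))
  coding <- g$gene_id[g$biotype == "coding"]
  expect_true(all(ann$annotation$cds$gene_id %in% coding))
  # gene sets: TRA and housekeeping disjoint; AIRE/FEZF2 subsets of TRA
  gs <- ann$gene_sets
  expect_length(intersect(gs$tra, gs$housekeeping), 0)
  expect_length(intersect(gs$aire_like, gs$fezf2_like), 0)
  expect_true(all(gs$aire_like %in% gs$tra))
  expect_true(all(gs$fezf2_like %in% gs$tra))
  # TRA genes sit on hi-specific promoters (the planted pGE bias)
  tra_prom <- gt$promoter_id[gt$class == "tra"]
  expect_true(all(ds$truth$promoters$group[
    match(tra_prom, ds$truth$promoters$promoter_id)] == "hi_specific"))
})

test_that("expression truth plants the advertised tau classes", {
  cfg <- small_config(seed = 4L)
  em <- gen_expression_matrix(cfg)
  expect_true(all(em$matrix$tpm >= 0))
  tau <- compute_tau(em$matrix)
  merged <- merge(tau, em$truth, by.x = "feature", by.y = "gene_id")
  expect_true(mean(merged$tau[merged$class == "tra"] >= 0.8) >= 0.95)
  expect_true(all(merged$tau[merged$class == "housekeeping"] < 0.5))
  # zero-jitter, zero-background single-tissue TRAs give exact tau of 1
  cfg0 <- small_config(seed = 4L, tpm_jitter = 0, background_tpm = 0)
  em0 <- gen_expression_matrix(cfg0)
  tau0 <- compute_tau(em0$matrix)
  m0 <- merge(tau0, em0$truth, by.x = "feature", by.y = "gene_id")
  single <- m0$class == "tra" & !grepl(",", m0$tissues)
  expect_true(all(m0$tau[single] == 1))
  expect_true(all(m0$tau[m0$class == "housekeeping"] == 0))
  expect_error(gen_expression_matrix(small_config(tra_foreground_tpm = 0.1)),
               "exceed")
})

test_that("isoform truth entropy is exact and bounded", {
  cfg <- small_config(seed = 6L)
  iso <- gen_isoform_profiles(cfg)
  tr <- iso$truth
  expect_true(all(tr$entropy_bits >= 0))
  expect_true(all(tr$entropy_bits <= log2(pmax(tr$n_isoforms, 2)) + 1e-12))
  expect_true(all(tr$entropy_bits[tr$n_isoforms == 1] == 0))
  # usage vectors sum to 1 and reproduce the recorded entropy
  for (r in sample(nrow(tr), 10)) {
    u <- as.numeric(strsplit(tr$usage[r], ",")[[1]])
    expect_equal(sum(u), 1, tolerance = 1e-9)
    expect_equal(-sum(ifelse(u > 0, u * log2(u), 0)), tr$entropy_bits[r],
                 tolerance = 1e-9)
  }
  # computed entropy from the matrix equals the truth wherever defined
  ent <- splicing_entropy(iso$matrix)
  pg <- ent$per_gene[!is.na(ent$per_gene$entropy), ]
  expect_true(all(abs(pg$entropy -
                        tr$entropy_bits[match(pg$gene, tr$gene_id)]) < 1e-9))
})

test_that("mean Dirichlet(1,1) two-isoform entropy matches numeric integration", {
  cfg <- sim_config(seed = 13L, n_genes = 1000L, n_tra = 0L,
                    n_housekeeping = 0L, isoforms_per_gene_range = c(2L, 2L),
                    dirichlet_alpha = 1)
  iso <- gen_isoform_profiles(cfg)
  expected <- dirichlet2_entropy_expectation()
  expect_equal(expected, 1 / (2 * log(2)), tolerance = 1e-8)
  expect_lt(abs(mean(iso$truth$entropy_bits) - expected), 0.03)
})
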