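#' Configuration of the synthetic-data generator
#'
#' Collects, with validation, every knob of the seeded generator that emulates
#' the statistical structure of 5' tag and tissue-expression data: a small
#' genome; promoters whose per-promoter tag totals follow a discrete power law
#' and whose tags spread geometrically around the center; a paired hi/lo sample
#' design with planted group-specific promoters and per-sample stochastic
#' dropout; uniform singleton background tags; and gene/transcript TPM
#' matrices with planted tissue-restricted, housekeeping and multi-isoform
#' genes.
#'
#' @param seed integer seed; identical configs give bit-identical output.
#' @param genome named integer vector of chromosome lengths (bp).
#' @param n_promoters number of planted promoters.
#' @param promoter_width_bp half-width of the tag spread (truncation bound of
#'   the symmetric geometric offset distribution).
#' @param zipf_exponent tail exponent (>1) of the reverse-cumulative
#'   distribution of per-promoter tag totals.
#' @param total_tags_per_sample promoter-derived tags allocated per sample.
#' @param n_hi_samples,n_lo_samples samples per population (paired by index).
#' @param frac_hi_specific,frac_lo_specific fractions of promoters planted as
#'   active only in the hi (resp. lo) population.
#' @param detection_prob per-sample probability that an allowed promoter is
#'   active (models cross-sample dropout).
#' @param noise_tags_per_kb uniform background singleton-tag rate.
#' @param n_genes,n_tissues,n_tra,n_housekeeping gene/tissue counts for the
#'   expression matrices.
#' @param tra_foreground_tpm,background_tpm planted TRA expression inside and
#'   outside its tissue subset.
#' @param housekeeping_tpm planted uniform housekeeping expression.
#' @param tpm_jitter fractional lognormal jitter band applied to planted TPMs
#'   (0.2 means values typically within about +-20% of the target, a
#'   two-sigma multiplicative band); 0 disables jitter.
#' @param isoforms_per_gene_range integer min/max isoforms per gene.
#' @param dirichlet_alpha symmetric Dirichlet concentration of isoform usage.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome = c(chr1 = 1000000L, chr2 = 1000000L),
                       n_promoters = 200L,
                       promoter_width_bp = 5L,
                       zipf_exponent = 1.5,
                       total_tags_per_sample = 50000L,
                       n_hi_samples = 5L, n_lo_samples = 5L,
                       frac_hi_specific = 0.2, frac_lo_specific = 0.2,
                       detection_prob = 0.6,
                       noise_tags_per_kb = 0.05,
                       n_genes = 150L, n_tissues = 12L,
                       n_tra = 30L, n_housekeeping = 30L,
                       tra_foreground_tpm = 100, background_tpm = 0.5,
                       housekeeping_tpm = 50,
                       tpm_jitter = 0.2,
                       isoforms_per_gene_range = c(1L, 5L),
                       dirichlet_alpha = 1) {
  cfg <- list(seed = as.integer(seed), genome = genome,
              n_promoters = as.integer(n_promoters),
              promoter_width_bp = as.integer(promoter_width_bp),
              zipf_exponent = zipf_exponent,
              total_tags_per_sample = as.integer(total_tags_per_sample),
              n_hi_samples = as.integer(n_hi_samples),
              n_lo_samples = as.integer(n_lo_samples),
              frac_hi_specific = frac_hi_specific,
              frac_lo_specific = frac_lo_specific,
              detection_prob = detection_prob,
              noise_tags_per_kb = noise_tags_per_kb,
              n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
              n_tra = as.integer(n_tra),
              n_housekeeping = as.integer(n_housekeeping),
              tra_foreground_tpm = tra_foreground_tpm,
              background_tpm = background_tpm,
              housekeeping_tpm = housekeeping_tpm,
              tpm_jitter = tpm_jitter,
              isoforms_per_gene_range = as.integer(isoforms_per_gene_range),
              dirichlet_alpha = dirichlet_alpha)
  if (cfg$zipf_exponent <= 1) stop("zipf_exponent must exceed 1")
  if (any(cfg$genome <= 0) || is.null(names(cfg$genome))) {
    stop("genome must be a named vector of positive chromosome lengths")
  }
  probs <- c(cfg$frac_hi_specific, cfg$frac_lo_specific, cfg$detection_prob)
  if (any(probs < 0 | probs > 1) || cfg$detection_prob == 0) {
    stop("fractions must lie in [0,1] and detection_prob in (0,1]")
  }
  if (cfg$frac_hi_specific + cfg$frac_lo_specific > 1) {
    stop("specific fractions sum to more than 1")
  }
  if (cfg$noise_tags_per_kb < 0) stop("noise_tags_per_kb must be >= 0")
  counts <- c(cfg$n_promoters, cfg$total_tags_per_sample, cfg$n_hi_samples,
              cfg$n_lo_samples, cfg$n_genes, cfg$n_tissues, cfg$n_tra,
              cfg$n_housekeeping)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (cfg$isoforms_per_gene_range[1] < 1 ||
      cfg$isoforms_per_gene_range[2] < cfg$isoforms_per_gene_range[1]) {
    stop("isoforms_per_gene_range must satisfy 1 <= min <= max")
  }
  if (cfg$dirichlet_alpha <= 0) stop("dirichlet_alpha must be > 0")
  structure(cfg, class = "sim_config")
}

sim_sample_ids <- function(config) {
  c(sprintf("hi_%d", seq_len(config$n_hi_samples)),
    sprintf("lo_%d", seq_len(config$n_lo_samples)))
}

#' Paired sample design implied by a simulation config
#'
#' hi_i and lo_i are treated as the two populations of individual i.
#'
#' @param config a `sim_config`.
#' @return a `sample_group_design`.
#' @export
sim_design <- function(config) {
  sample_group_design(
    sample_id = sim_sample_ids(config),
    group = rep(c("hi", "lo"), c(config$n_hi_samples, config$n_lo_samples)),
    individual_id = c(seq_len(config$n_hi_samples), seq_len(config$n_lo_samples))
  )
}

# discrete power law on integers 1..1e6: P(X >= x) = x^(-exponent)
rpowerlaw <- function(n, exponent) {
  x <- floor(stats::runif(n)^(-1 / exponent))
  pmin(pmax(x, 1), 1e6)
}

# symmetric geometric offset truncated at +-width
r_truncgeom_offset <- function(n, width, prob = 0.5) {
  mag <- stats::qgeom(stats::runif(n) * stats::pgeom(width, prob), prob)
  sign <- ifelse(stats::runif(n) < 0.5, -1L, 1L)
  as.integer(sign * mag)
}

#' Generate a seeded synthetic 5' tag dataset with ground truth
#'
#' Plants `n_promoters` promoters on non-overlapping slots (pairwise distance
#' greater than `4 * promoter_width_bp + 40`), splits them into hi-specific,
#' lo-specific and shared groups, and simulates each sample: allowed promoters
#' are active with probability `detection_prob`; `total_tags_per_sample` tags
#' are allocated across active promoters proportionally to power-law
#' per-promoter weights; each tag lands at a truncated-geometric offset from
#' the promoter center; uniform background singleton tags are added at
#' `noise_tags_per_kb`. Hi-specific promoters have zero planted activity in
#' every lo sample, and vice versa.
#'
#' @param config a `sim_config`.
#' @return list with `tracks` (list of raw `tss_track`, one per sample) and
#'   `truth` (list with `promoters` data.frame and `activity` logical matrix
#'   promoters x samples).
#' @export
gen_tss_dataset <- function(config) {
  with_seed(config$seed, {
    w <- config$promoter_width_bp
    spacing <- 4L * w + 41L
    slots <- do.call(rbind, lapply(names(config$genome), function(ch) {
      len <- config$genome[[ch]]
      k <- floor((len - 2 * spacing) / spacing)
      if (k < 1) return(NULL)
      data.frame(chrom = ch, center = spacing + spacing * seq_len(k))
    }))
    if (is.null(slots) || nrow(slots) < config$n_promoters) {
      stop("infeasible promoter placement: genome too small for n_promoters")
    }
    pick <- sort(sample.int(nrow(slots), config$n_promoters))
    promoters <- slots[pick, , drop = FALSE]
    promoters$strand <- ifelse(stats::runif(config$n_promoters) < 0.5, "+", "-")
    n_hi <- round(config$frac_hi_specific * config$n_promoters)
    n_lo <- round(config$frac_lo_specific * config$n_promoters)
    grp <- rep("shared", config$n_promoters)
    grp[seq_len(n_hi)] <- "hi_specific"
    if (n_lo > 0) grp[n_hi + seq_len(n_lo)] <- "lo_specific"
    promoters$group <- grp[sample.int(config$n_promoters)]
    promoters$promoter_id <- sprintf("prom_%04d", seq_len(config$n_promoters))
    promoters <- promoters[, c("promoter_id", "chrom", "strand", "center", "group")]
    rownames(promoters) <- NULL

    samples <- sim_sample_ids(config)
    is_hi_sample <- grepl("^hi_", samples)
    allowed <- outer(promoters$group, is_hi_sample, function(g, hi) {
      ifelse(g == "hi_specific", hi, ifelse(g == "lo_specific", !hi, TRUE))
    })
    activity <- allowed &
      matrix(stats::runif(length(allowed)) < config$detection_prob,
             nrow = nrow(allowed))
    dimnames(activity) <- list(promoters$promoter_id, samples)

    strength <- rpowerlaw(config$n_promoters, config$zipf_exponent)
    genome_kb <- sum(config$genome) / 1000
    chrom_prob <- config$genome / sum(config$genome)

    tracks <- lapply(seq_along(samples), function(s) {
      act <- which(activity[, s])
      recs <- NULL
      if (length(act) > 0L) {
        # proportional allocation of the tag budget preserves the power-law
        # shape of per-promoter totals exactly (up to rounding)
        counts <- as.integer(round(config$total_tags_per_sample *
                                     strength[act] / sum(strength[act])))
        act <- act[counts > 0L]; counts <- counts[counts > 0L]
        idx <- rep(act, counts)
        offs <- r_truncgeom_offset(length(idx), w)
        recs <- data.frame(chrom = promoters$chrom[idx],
                           pos = promoters$center[idx] + offs,
                           strand = promoters$strand[idx],
                           count = 1L)
      }
      n_noise <- stats::rpois(1, config$noise_tags_per_kb * genome_kb)
      if (n_noise > 0L) {
        ch <- sample(names(config$genome), n_noise, replace = TRUE,
                     prob = chrom_prob)
        noise <- data.frame(chrom = ch,
                            pos = as.integer(floor(stats::runif(n_noise) *
                                                     config$genome[ch])),
                            strand = ifelse(stats::runif(n_noise) < 0.5, "+", "-"),
                            count = 1L)
        recs <- rbind(recs, noise)
      }
      build_track(recs, samples[s])
    })
    names(tracks) <- samples
    list(tracks = tracks,
         truth = list(promoters = promoters, activity = activity,
                      strength = stats::setNames(strength, promoters$promoter_id)))
  })
}

#' Planted gene classes (deterministic in the config)
#'
#' Gene ids are `gene_0001` ... and classes are assigned by index: the first
#' `n_tra` genes are tissue-restricted, the next `n_housekeeping` are
#' housekeeping, the rest are unclassified. Shared across the annotation and
#' expression generators so that their truths agree.
#'
#' @param config a `sim_config`.
#' @return data.frame `gene_id`, `class`.
#' @export
planted_gene_classes <- function(config) {
  if (config$n_tra + config$n_housekeeping > config$n_genes) {
    stop("n_tra + n_housekeeping exceeds n_genes")
  }
  cls <- rep("other", config$n_genes)
  cls[seq_len(config$n_tra)] <- "tra"
  cls[config$n_tra + seq_len(config$n_housekeeping)] <- "housekeeping"
  data.frame(gene_id = sprintf("gene_%04d", seq_len(config$n_genes)),
             class = cls, stringsAsFactors = FALSE)
}

#' Generate gene models and gene-set lists around the planted promoters
#'
#' The first `n_genes` promoters (in a biased deterministic pairing: TRA genes
#' take hi-specific promoters first, housekeeping genes take shared promoters
#' first) become canonical gene starts: each gene's annotated TSS sits exactly
#' at its promoter center, with 2-8 sequential exons, an internal CDS for
#' coding genes, and strand-aware extent. Remaining promoters fall wherever
#' they were planted (gene bodies or intergenic space), emulating
#' mis-initiation. Gene-set lists (TRA, housekeeping, AIRE-like, FEZF2-like)
#' are consistent with [planted_gene_classes()]; the AIRE-like and FEZF2-like
#' lists are disjoint subsets of the TRA list.
#'
#' @param config a `sim_config`.
#' @param truth the `truth` element of [gen_tss_dataset()] output.
#' @return list with `annotation` (a `genomic_annotation`), `gene_sets` (list
#'   of id vectors: `tra`, `housekeeping`, `aire_like`, `fezf2_like`) and
#'   `gene_truth` (data.frame `gene_id`, `class`, `promoter_id`).
#' @export
gen_annotation <- function(config, truth) {
  promoters <- truth$promoters
  if (config$n_genes > nrow(promoters)) {
    stop("infeasible: n_genes exceeds the number of planted promoters")
  }
  classes <- planted_gene_classes(config)
  with_seed(config$seed + 1L, {
    # pair genes to promoters: TRA -> hi_specific first, housekeeping -> shared
    ord <- c(which(promoters$group == "hi_specific"),
             which(promoters$group == "shared"),
             which(promoters$group == "lo_specific"))
    gene_rank <- order(match(classes$class, c("tra", "housekeeping", "other")))
    prom_idx <- integer(config$n_genes)
    prom_idx[gene_rank] <- ord[seq_len(config$n_genes)]

    genes <- exons <- cds <- NULL
    gl <- vector("list", config$n_genes); el <- vector("list", config$n_genes)
    cl <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      p <- promoters[prom_idx[i], ]
      gid <- classes$gene_id[i]
      n_ex <- sample(2:8, 1)
      ex_w <- sample(100:500, n_ex, replace = TRUE)
      in_w <- if (n_ex > 1) sample(200:1000, n_ex - 1, replace = TRUE) else integer(0)
      # block offsets downstream of the TSS in gene orientation
      starts_rel <- cumsum(c(0L, as.integer(ex_w[-n_ex] + in_w)))
      ends_rel <- starts_rel + ex_w - 1L
      glen <- ends_rel[n_ex] + 1L
      chrom_len <- config$genome[[p$chrom]]
      if (p$strand == "+") {
        g_start <- p$center
        ex_s <- g_start + starts_rel; ex_e <- g_start + ends_rel
      } else {
        g_start <- p$center - glen + 1L
        ex_e <- p$center - starts_rel; ex_s <- p$center - ends_rel
      }
      ex_s <- pmax(ex_s, 0L); ex_e <- pmin(ex_e, chrom_len - 1L)
      ok <- ex_s <= ex_e
      ex_s <- ex_s[ok]; ex_e <- ex_e[ok]
      g_lo <- min(ex_s); g_hi <- max(ex_e)
      biotype <- if (stats::runif(1) < 0.85) "coding" else "noncoding"
      tid <- paste0(gid, ".t1")
      gl[[i]] <- data.frame(gene_id = gid, chrom = p$chrom, strand = p$strand,
                            start = g_lo, end = g_hi,
                            tss = if (p$strand == "+") g_lo else g_hi,
                            tts = if (p$strand == "+") g_hi else g_lo,
                            biotype = biotype)
      el[[i]] <- data.frame(gene_id = gid, transcript_id = tid,
                            start = ex_s, end = ex_e)
      if (biotype == "coding" && length(ex_s) >= 1L) {
        # CDS spans from 30 bp into the first exon to 30 bp before the last
        cds_lo <- min(g_lo + 30L, g_hi); cds_hi <- max(g_hi - 30L, g_lo)
        cs <- pmax(ex_s, cds_lo); ce <- pmin(ex_e, cds_hi)
        keep <- cs <= ce
        if (any(keep)) {
          cl[[i]] <- data.frame(gene_id = gid, transcript_id = tid,
                                start = cs[keep], end = ce[keep])
        }
      }
    }
    genes <- do.call(rbind, gl)
    exons <- do.call(rbind, el)
    cds <- do.call(rbind, cl[!vapply(cl, is.null, logical(1))])
    if (is.null(cds)) cds <- data.frame(gene_id = character(),
                                        transcript_id = character(),
                                        start = integer(), end = integer())
    ann <- genomic_annotation(genes, exons, cds)
    tra_ids <- classes$gene_id[classes$class == "tra"]
    hk_ids <- classes$gene_id[classes$class == "housekeeping"]
    n_aire <- floor(length(tra_ids) / 3)
    n_fezf2 <- floor(length(tra_ids) / 6)
    gene_sets <- list(tra = tra_ids, housekeeping = hk_ids,
                      aire_like = tra_ids[seq_len(n_aire)],
                      fezf2_like = tra_ids[n_aire + seq_len(n_fezf2)])
    gene_truth <- data.frame(gene_id = classes$gene_id, class = classes$class,
                             promoter_id = promoters$promoter_id[prom_idx],
                             stringsAsFactors = FALSE)
    list(annotation = ann, gene_sets = gene_sets, gene_truth = gene_truth)
  })
}

# `band` is the fractional jitter band (0.2 = "about +-20%"), interpreted as
# a two-sigma multiplicative lognormal band: sdlog = log(1 + band) / 2.
lognormal_jitter <- function(n, target, band) {
  if (band == 0 || target == 0) return(rep(target, n))
  sdlog <- log(1 + band) / 2
  target * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a gene-level tissue TPM matrix with planted specificity classes
#'
#' Planted TRA genes express `tra_foreground_tpm` (with lognormal jitter) in a
#' random subset of 1-3 tissues and `background_tpm` elsewhere; housekeeping
#' genes express `housekeeping_tpm` in every tissue; other genes get an
#' intermediate uniform level. The truth records the planted tissue set and
#' the expected tau class (`high` for TRAs, `low` for housekeeping).
#'
#' @param config a `sim_config`.
#' @return list with `matrix` (gene-level `expression_matrix`) and `truth`
#'   (data.frame `gene_id`, `class`, `tissues`, `expected_tau_class`).
#' @export
gen_expression_matrix <- function(config) {
  if (config$n_tissues < 3L) stop("need at least 3 tissues")
  if (config$tra_foreground_tpm <= config$background_tpm) {
    stop("tra_foreground_tpm must exceed background_tpm (planted tau class unattainable)")
  }
  classes <- planted_gene_classes(config)
  tissues <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  with_seed(config$seed + 2L, {
    tpm <- matrix(0, config$n_genes, config$n_tissues,
                  dimnames = list(classes$gene_id, tissues))
    planted_tissues <- character(config$n_genes)
    for (i in seq_len(config$n_genes)) {
      if (classes$class[i] == "tra") {
        k <- sample(1:3, 1)
        fg <- sample.int(config$n_tissues, k)
        row <- lognormal_jitter(config$n_tissues, config$background_tpm,
                                config$tpm_jitter)
        row[fg] <- lognormal_jitter(k, config$tra_foreground_tpm,
                                    config$tpm_jitter)
        planted_tissues[i] <- paste(tissues[fg], collapse = ",")
      } else {
        level <- if (classes$class[i] == "housekeeping") {
          config$housekeeping_tpm
        } else {
          (config$housekeeping_tpm + config$background_tpm) / 2
        }
        row <- lognormal_jitter(config$n_tissues, level, config$tpm_jitter)
        planted_tissues[i] <- paste(tissues, collapse = ",")
      }
      tpm[i, ] <- row
    }
    truth <- data.frame(gene_id = classes$gene_id, class = classes$class,
                        tissues = planted_tissues,
                        expected_tau_class = ifelse(classes$class == "tra", "high",
                                             ifelse(classes$class == "housekeeping",
                                                    "low", "other")),
                        stringsAsFactors = FALSE)
    list(matrix = expression_matrix(tpm, level = "gene"), truth = truth)
  })
}

#' Generate transcript-level isoform profiles with known usage and entropy
#'
#' Per gene, the isoform count is uniform on `isoforms_per_gene_range` and the
#' usage vector is drawn from a symmetric Dirichlet; transcript TPM is the
#' gene TPM times usage, so computed splicing entropy should match the truth
#' entropy `-sum(p log2 p)` exactly wherever the gene is expressed.
#'
#' @param config a `sim_config`.
#' @param gene_matrix optional gene-level `expression_matrix`; defaults to
#'   `gen_expression_matrix(config)$matrix`.
#' @return list with `matrix` (transcript-level `expression_matrix` carrying
#'   `tx2gene`), `tx2gene`, and `truth` (data.frame `gene_id`, `n_isoforms`,
#'   `usage` (comma-joined), `entropy_bits`).
#' @export
gen_isoform_profiles <- function(config, gene_matrix = NULL) {
  if (is.null(gene_matrix)) gene_matrix <- gen_expression_matrix(config)$matrix
  g_tpm <- gene_matrix$tpm
  rng <- config$isoforms_per_gene_range
  with_seed(config$seed + 3L, {
    rows <- list(); usage_truth <- list()
    for (i in seq_len(nrow(g_tpm))) {
      gid <- rownames(g_tpm)[i]
      k <- if (rng[2] > rng[1]) sample(rng[1]:rng[2], 1) else rng[1]
      u <- stats::rgamma(k, shape = config$dirichlet_alpha)
      u <- u / sum(u)
      tx <- sprintf("%s.t%d", gid, seq_len(k))
      rows[[i]] <- list(tx = tx, gene = gid, tpm = outer(u, g_tpm[i, ]))
      usage_truth[[i]] <- data.frame(
        gene_id = gid, n_isoforms = k,
        usage = paste(formatC(u, digits = 12, format = "g"), collapse = ","),
        entropy_bits = -sum(u * log2(u)), stringsAsFactors = FALSE)
    }
    tx_tpm <- do.call(rbind, lapply(rows, `[[`, "tpm"))
    rownames(tx_tpm) <- unlist(lapply(rows, `[[`, "tx"))
    colnames(tx_tpm) <- colnames(g_tpm)
    tx2gene <- stats::setNames(rep(vapply(rows, `[[`, character(1), "gene"),
                                   vapply(rows, function(r) length(r$tx), integer(1))),
                               rownames(tx_tpm))
    list(matrix = expression_matrix(tx_tpm, level = "transcript",
                                    tx2gene = tx2gene),
         tx2gene = tx2gene,
         truth = do.call(rbind, usage_truth))
  })
}
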