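#' Sample group design for paired hi/lo population comparisons
#'
#' @param sample_id character vector of sample names.
#' @param group `"hi"` or `"lo"` per sample (mature vs immature population).
#' @param individual_id pairing key; each individual contributes at most one
#'   sample per group.
#' @return a `sample_group_design` data.frame.
#' @export
sample_group_design <- function(sample_id, group, individual_id) {
  stopifnot(length(sample_id) == length(group),
            length(sample_id) == length(individual_id))
  if (!all(group %in% c("hi", "lo"))) stop("group must be 'hi' or 'lo'")
  d <- data.frame(sample_id = as.character(sample_id), group = as.character(group),
                  individual_id = as.character(individual_id),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample_id)) stop("duplicate sample ids in design")
  if (anyDuplicated(d[, c("group", "individual_id")])) {
    stop("an individual may contribute at most one sample per group")
  }
  class(d) <- c("sample_group_design", "data.frame")
  d
}

#' Classify consensus TSRs as population-specific
#'
#' A TSR is hi-specific when it is present in at least `min_support` hi samples
#' and in no lo sample (lo-specific symmetrically); shared when present in at
#' least one sample of each group; unreplicated otherwise. The empirical rule
#' replaces differential testing, which is underpowered for the sparse,
#' dropout-prone presence patterns typical of 5' tag data.
#'
#' @param presence logical matrix, TSR x sample (consensus presence).
#' @param design a `sample_group_design` covering the presence columns.
#' @param min_support minimum supporting samples within the specific group.
#' @return data.frame `id`, `label` with
#'   label in hi_specific / lo_specific / shared / unreplicated.
#' @export
classify_population_specific <- function(presence, design, min_support = 2) {
  design <- design[match(colnames(presence), design$sample_id), , drop = FALSE]
  if (any(is.na(design$sample_id))) stop("presence columns missing from design")
  hi_cols <- design$group == "hi"
  lo_cols <- design$group == "lo"
  if (sum(hi_cols) < min_support || sum(lo_cols) < min_support) {
    stop(sprintf("each group needs >= %d samples for classification", min_support))
  }
  n_hi <- rowSums(presence[, hi_cols, drop = FALSE])
  n_lo <- rowSums(presence[, lo_cols, drop = FALSE])
  label <- rep("unreplicated", nrow(presence))
  label[n_hi >= min_support & n_lo == 0] <- "hi_specific"
  label[n_lo >= min_support & n_hi == 0] <- "lo_specific"
  label[n_hi >= 1 & n_lo >= 1] <- "shared"
  ids <- rownames(presence)
  if (is.null(ids)) ids <- sprintf("tsr_%05d", seq_len(nrow(presence)))
  data.frame(id = ids, label = label, stringsAsFactors = FALSE)
}

#' Two-sided paired t-test
#'
#' Classical paired t on differences `y - x`: `t = mean(d) / (sd(d) / sqrt(n))`
#' with the n−1 sample standard deviation and n−1 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, paired by individual.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("paired t-test needs >= 2 complete pairs")
  d <- y - x
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("degenerate paired t-test: all differences identical")
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(t = t_stat, df = n - 1L, p = 2 * stats::pt(-abs(t_stat), df = n - 1L))
}

# samples x labels bookkeeping shared by the per-sample fraction analyses:
# for sample s in group g, the denominator is the set of g-specific TSRs
# present in s.
specific_present_sets <- function(labels, presence, design) {
  design <- design[match(colnames(presence), design$sample_id), , drop = FALSE]
  lab <- labels$label[match(rownames(presence), labels$id)]
  lapply(seq_len(nrow(design)), function(s) {
    want <- if (design$group[s] == "hi") "hi_specific" else "lo_specific"
    rownames(presence)[lab == want & presence[, s]]
  })
}

#' Per-sample gene-set fractions of population-specific TSRs
#'
#' For each sample of group g, the fraction of g-specific TSRs present in that
#' sample whose nearest gene belongs to `gene_set`, plus the paired hi-vs-lo
#' t-test over individuals.
#'
#' @param labels output of [classify_population_specific()].
#' @param annotation output of [annotate_tsrs()] (needs `nearest_gene_id`).
#' @param presence logical TSR x sample matrix.
#' @param design a `sample_group_design`.
#' @param gene_set character vector of gene ids.
#' @return list with `fractions` (data.frame `sample_id`, `group`,
#'   `individual_id`, `n_specific`, `n_in_set`, `fraction`) and `test`
#'   (paired t result, or NULL with a warning when degenerate/incomplete).
#' @export
geneset_fractions <- function(labels, annotation, presence, design, gene_set) {
  design <- design[match(colnames(presence), design$sample_id), , drop = FALSE]
  sets <- specific_present_sets(labels, presence, design)
  in_set <- annotation$nearest_gene_id %in% gene_set
  names(in_set) <- annotation$id
  rows <- lapply(seq_len(nrow(design)), function(s) {
    ids <- sets[[s]]
    n <- length(ids)
    k <- sum(in_set[ids], na.rm = TRUE)
    data.frame(sample_id = design$sample_id[s], group = design$group[s],
               individual_id = design$individual_id[s],
               n_specific = n, n_in_set = k,
               fraction = if (n > 0) k / n else NA_real_)
  })
  fractions <- do.call(rbind, rows)
  if (any(is.na(fractions$fraction))) {
    warning("samples with zero group-specific TSRs present were excluded from the paired test")
  }
  test <- tryCatch(paired_fraction_test(fractions), error = function(e) {
    warning(conditionMessage(e)); NULL
  })
  list(fractions = fractions, test = test)
}

# pair hi/lo fractions by individual and run the paired t-test (lo as x, hi as y)
paired_fraction_test <- function(fractions) {
  hi <- fractions[fractions$group == "hi", ]
  lo <- fractions[fractions$group == "lo", ]
  ind <- intersect(hi$individual_id, lo$individual_id)
  x <- lo$fraction[match(ind, lo$individual_id)]
  y <- hi$fraction[match(ind, hi$individual_id)]
  paired_t_test(x, y)
}

#' Fisher-exact enrichment of a TSR property in hi- vs lo-specific TSRs
#'
#' Builds the 2x2 table (hi-specific vs lo-specific) x (member vs non-member).
#' The odds ratio is the sample `ad/bc`; the two-sided p sums all
#' hypergeometric table probabilities not exceeding the observed one (at fixed
#' margins); the 95% CI uses the Woolf logit method, with a Haldane–Anscombe
#' 0.5 correction applied to all cells iff any cell is zero.
#'
#' @param labels output of [classify_population_specific()].
#' @param membership named logical vector (TSR id -> property).
#' @return an `enrichment_result` list: `table` (a, b, c, d), `odds_ratio`,
#'   `ci_low`, `ci_high`, `p`, `test`.
#' @export
enrichment_odds_ratio <- function(labels, membership) {
  hi <- labels$id[labels$label == "hi_specific"]
  lo <- labels$id[labels$label == "lo_specific"]
  if (length(hi) == 0L || length(lo) == 0L) {
    stop("need at least one hi_specific and one lo_specific TSR")
  }
  a <- sum(membership[hi], na.rm = TRUE); b <- length(hi) - a
  c_ <- sum(membership[lo], na.rm = TRUE); d <- length(lo) - c_
  fisher_or(a, b, c_, d)
}

#' Fisher exact test and odds ratio for a 2x2 table
#'
#' @param a,b,c_,d table cells (row 1: a, b; row 2: c_, d).
#' @return an `enrichment_result` (see [enrichment_odds_ratio()]).
#' @export
fisher_or <- function(a, b, c_, d) {
  if (a + b + c_ + d < 1) stop("empty 2x2 table")
  # two-sided exact p: sum of hypergeometric probabilities <= P(observed)
  m <- a + b; n2 <- c_ + d; k <- a + c_
  lo_a <- max(0L, k - n2); hi_a <- min(m, k)
  support <- lo_a:hi_a
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c_)
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or_ci <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(0.975)
  structure(list(table = c(a = a, b = b, c = c_, d = d),
                 odds_ratio = if (is.finite(or)) or else or_ci,
                 ci_low = exp(log(or_ci) - z * se),
                 ci_high = exp(log(or_ci) + z * se),
                 p = p, test = "two-sided Fisher exact"),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("OR = %.3g [%.3g, %.3g], p = %.3g (%s); table a=%d b=%d c=%d d=%d\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p, x$test,
              x$table["a"], x$table["b"], x$table["c"], x$table["d"]))
  invisible(x)
}

#' Exact two-sided Mann-Whitney U test with mid-rank ties
#'
#' Exact enumeration of all group assignments when both groups have at most
#' `exact_max` observations; normal approximation with continuity correction
#' otherwise. Ties are handled by mid-ranks in both modes.
#'
#' @param x,y numeric vectors.
#' @param exact_max enumeration cutoff per group.
#' @return list with `U` (statistic of `x`), `p` (two-sided), `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 10) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pooled <- c(x, y)
  rk <- rank(pooled)           # mid-ranks
  u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, u_of)
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
    list(U = u_obs, p = p, method = "exact enumeration, mid-ranks")
  } else {
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    list(U = u_obs, p = min(1, 2 * stats::pnorm(-max(z, 0))),
         method = "normal approximation, continuity-corrected")
  }
}

#' TSRs per gene by population
#'
#' Counts, per population, how many TSRs map to each distinct nearest gene
#' (genes with at least one TSR), and compares the per-gene count vectors with
#' the two-sided Mann-Whitney U test. `scope = "population"` uses the
#' population-specific TSR sets; `scope = "all"` uses every TSR present in at
#' least one sample of the population.
#'
#' @param labels output of [classify_population_specific()].
#' @param annotation output of [annotate_tsrs()].
#' @param presence logical TSR x sample matrix.
#' @param design a `sample_group_design`.
#' @param scope `"population"` or `"all"`.
#' @return list with `hi_counts`, `lo_counts` (named per-gene integer vectors),
#'   `mean_hi`, `mean_lo`, `test` (Mann-Whitney result).
#' @export
tsrs_per_gene <- function(labels, annotation, presence, design,
                          scope = c("population", "all")) {
  scope <- match.arg(scope)
  design <- design[match(colnames(presence), design$sample_id), , drop = FALSE]
  gene_of <- annotation$nearest_gene_id[match(labels$id, annotation$id)]
  pick <- function(grp) {
    ids <- if (scope == "population") {
      labels$id[labels$label == paste0(grp, "_specific")]
    } else {
      labels$id[rowSums(presence[labels$id, design$group == grp, drop = FALSE]) >= 1]
    }
    genes <- gene_of[match(ids, labels$id)]
    genes <- genes[!is.na(genes)]
    if (length(genes) == 0L) stop("no genes with TSRs in group ", grp)
    table(genes)
  }
  hi_counts <- pick("hi"); lo_counts <- pick("lo")
  list(hi_counts = hi_counts, lo_counts = lo_counts,
       mean_hi = mean(hi_counts), mean_lo = mean(lo_counts),
       test = mann_whitney_u(as.numeric(hi_counts), as.numeric(lo_counts)))
}

#' Mis-initiation rates of population-specific TSRs
#'
#' A TSR is mis-initiated when its genomic category falls outside
#' `promoter_like` (default: outside annotated promoter windows; set
#' `promoter_like = c("promoter", "five_utr")` to also exempt 5' UTRs). At
#' `level = "tsr"` the per-sample rate is the fraction of group-specific TSRs
#' present in the sample that are mis-initiated; at `level = "gene"` it is the
#' fraction of their nearest genes with at least one mis-initiated TSR. Also
#' returns the paired hi-vs-lo t-test and the pooled hi-vs-lo Fisher odds
#' ratio over population-specific TSRs.
#'
#' @param annotation output of [annotate_tsrs()].
#' @param labels output of [classify_population_specific()].
#' @param presence logical TSR x sample matrix.
#' @param design a `sample_group_design`.
#' @param gene_set optional gene-id restriction (by nearest gene).
#' @param promoter_like categories counted as canonical initiation.
#' @param level `"tsr"` or `"gene"`.
#' @return list with `rates` (per-sample data.frame), `test` (paired t or
#'   NULL), `enrichment` (pooled `enrichment_result`).
#' @export
misinitiation_rates <- function(annotation, labels, presence, design,
                                gene_set = NULL,
                                promoter_like = "promoter",
                                level = c("tsr", "gene")) {
  level <- match.arg(level)
  design <- design[match(colnames(presence), design$sample_id), , drop = FALSE]
  mis <- !(annotation$category %in% promoter_like)
  names(mis) <- annotation$id
  gene_of <- annotation$nearest_gene_id
  names(gene_of) <- annotation$id
  eligible <- annotation$id
  if (!is.null(gene_set)) {
    eligible <- annotation$id[annotation$nearest_gene_id %in% gene_set]
  }
  sets <- specific_present_sets(labels, presence, design)
  rows <- lapply(seq_len(nrow(design)), function(s) {
    ids <- intersect(sets[[s]], eligible)
    rate <- if (level == "tsr") {
      if (length(ids) > 0) mean(mis[ids]) else NA_real_
    } else {
      genes <- unique(gene_of[ids])
      genes <- genes[!is.na(genes)]
      if (length(genes) == 0L) NA_real_ else {
        mean(vapply(genes, function(gg) any(mis[ids][gene_of[ids] == gg]), logical(1)))
      }
    }
    data.frame(sample_id = design$sample_id[s], group = design$group[s],
               individual_id = design$individual_id[s], rate = rate)
  })
  rates <- do.call(rbind, rows)
  if (any(is.na(rates$rate))) warning("samples with empty denominators yield missing rates")
  test <- tryCatch({
    hi <- rates[rates$group == "hi", ]; lo <- rates[rates$group == "lo", ]
    ind <- intersect(hi$individual_id, lo$individual_id)
    paired_t_test(lo$rate[match(ind, lo$individual_id)],
                  hi$rate[match(ind, hi$individual_id)])
  }, error = function(e) { warning(conditionMessage(e)); NULL })
  lab <- labels$label[match(eligible, labels$id)]
  hi_ids <- eligible[lab == "hi_specific"]; lo_ids <- eligible[lab == "lo_specific"]
  enrichment <- if (length(hi_ids) > 0 && length(lo_ids) > 0) {
    fisher_or(sum(mis[hi_ids]), sum(!mis[hi_ids]), sum(mis[lo_ids]), sum(!mis[lo_ids]))
  } else NULL
  list(rates = rates, test = test, enrichment = enrichment)
}

#' Leave-one-out tissue-specificity of TSR usage
#'
#' For each held-out tissue t, the TSRs present in exactly one remaining
#' tissue u form the tissue-unique set U_u(t); `F[u, t]` is the fraction of
#' U_u(t) also present in t (NA when U_u(t) is empty). `Z` is the row-wise
#' z-score of F across defined held-out tissues using the population SD, and
#' `column_means` averages each column of Z over its defined entries.
#'
#' @param presence logical matrix, TSR x tissue.
#' @return a `loo_matrix` list: `F`, `Z` (tissue u x held-out tissue t
#'   matrices, NA diagonal), `column_means`.
#' @export
leave_one_out_specificity <- function(presence) {
  tissues <- colnames(presence)
  if (is.null(tissues)) tissues <- sprintf("T%d", seq_len(ncol(presence)))
  k <- length(tissues)
  if (k < 3L) stop("leave-one-out analysis needs >= 3 tissues")
  Fm <- matrix(NA_real_, k, k, dimnames = list(tissues, tissues))
  for (t in seq_len(k)) {
    rest <- setdiff(seq_len(k), t)
    sub <- presence[, rest, drop = FALSE]
    n_present <- rowSums(sub)
    for (u_idx in seq_along(rest)) {
      u <- rest[u_idx]
      unique_u <- n_present == 1L & sub[, u_idx]
      if (any(unique_u)) Fm[u, t] <- mean(presence[unique_u, t])
    }
  }
  Z <- t(apply(Fm, 1, function(row) {
    ok <- !is.na(row)
    if (sum(ok) >= 2L) {
      s <- sqrt(mean((row[ok] - mean(row[ok]))^2))  # population SD
      # constant rows carry no ranking information: z undefined, not zero
      if (s > 0) row <- (row - mean(row[ok])) / s else row[ok] <- NA_real_
    }
    row
  }))
  dimnames(Z) <- dimnames(Fm)
  structure(list(F = Fm, Z = Z,
                 column_means = colMeans(Z, na.rm = TRUE)),
            class = "loo_matrix")
}

#' @export
print.loo_matrix <- function(x, ...) {
  cat("leave-one-out tissue-specificity matrix (rows: unique-in tissue, columns: held out)\n")
  print(round(x$F, 3))
  invisible(x)
}
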