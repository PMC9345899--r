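#' Expression matrix container
#'
#' Feature-by-tissue (or sample) TPM table at gene or transcript level, with an
#' optional transcript-to-gene map for transcript-level matrices.
#'
#' @param tpm numeric matrix, features x columns, nonnegative, unique rownames.
#' @param level `"gene"` or `"transcript"`.
#' @param tx2gene named character vector mapping transcript id -> gene id
#'   (required for entropy analyses at transcript level).
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(tpm, level = c("gene", "transcript"), tx2gene = NULL) {
  level <- match.arg(level)
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm)) || anyDuplicated(rownames(tpm))) {
    stop("tpm needs unique rownames (feature ids)")
  }
  if (any(tpm < 0)) stop("TPM values must be nonnegative")
  structure(list(tpm = tpm, level = level, tx2gene = tx2gene),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s level): %d features x %d columns\n",
              x$level, nrow(x$tpm), ncol(x$tpm)))
  invisible(x)
}

#' Tissue-specificity index tau with TRA calling and tissue binarization
#'
#' For each feature with maximum tissue TPM at least `tpm_min`, expression is
#' max-normalized (`xhat_i = x_i / max_i x_i`) and
#' `tau = sum(1 - xhat_i) / (n - 1)` over the n tissues. tau is 0 for uniform
#' expression and 1 for strict single-tissue expression; features with
#' `tau >= tau_min` are called tissue-restricted antigens (TRAs). Expressing
#' tissues are assigned by [binarize_tissues()].
#'
#' @param mat an `expression_matrix` with one column per tissue.
#' @param tpm_min minimum maximum-tissue TPM for a feature to be scored.
#' @param tau_min TRA threshold on tau.
#' @return data.frame `feature`, `tau`, `is_tra`, `expressing_tissues`
#'   (comma-separated tissue names), one row per retained feature.
#' @export
compute_tau <- function(mat, tpm_min = 1, tau_min = 0.8) {
  tpm <- mat$tpm
  n <- ncol(tpm)
  if (n < 2L) stop("tau needs >= 2 tissue columns")
  mx <- apply(tpm, 1, max)
  keep <- mx >= tpm_min & mx > 0
  tpm <- tpm[keep, , drop = FALSE]
  mx <- mx[keep]
  xhat <- tpm / mx
  tau <- rowSums(1 - xhat) / (n - 1)
  expressing <- vapply(seq_len(nrow(tpm)), function(i) {
    paste(colnames(tpm)[binarize_tissues(tpm[i, ])], collapse = ",")
  }, character(1))
  data.frame(feature = rownames(tpm), tau = unname(tau),
             is_tra = unname(tau >= tau_min),
             expressing_tissues = expressing,
             stringsAsFactors = FALSE)
}

#' Assign expressing tissues by the largest gap in sorted expression
#'
#' Sorts the expression vector ascending, locates the largest difference
#' between consecutive values, and declares all tissues strictly above the
#' lower edge of that gap as expressing. Ties between equal-size gaps resolve
#' toward the gap at higher expression (the smaller, more conservative
#' expressing set). An all-equal vector returns every tissue.
#'
#' @param expression numeric vector over tissues (names preserved).
#' @return integer indices (or names, if named) of expressing tissues.
#' @export
binarize_tissues <- function(expression) {
  if (length(expression) == 0L) stop("empty expression vector")
  if (length(expression) == 1L) return(seq_along(expression))
  ord <- sort(expression)
  gaps <- diff(ord)
  if (all(gaps == 0)) return(seq_along(expression))
  best <- max(which(gaps == max(gaps)))   # highest-expression gap on ties
  cutoff <- ord[best]
  which(expression > cutoff)
}

#' Fraction of features expressed per column at TPM thresholds
#'
#' @param mat an `expression_matrix`.
#' @param thresholds positive TPM thresholds.
#' @param feature_set optional feature-id restriction.
#' @return data.frame `column`, `threshold`, `n_expressed`, `fraction`.
#' @export
expressed_fraction <- function(mat, thresholds = c(0.5, 1, 2),
                               feature_set = NULL) {
  if (any(thresholds <= 0)) stop("thresholds must be > 0")
  tpm <- mat$tpm
  if (!is.null(feature_set)) {
    tpm <- tpm[rownames(tpm) %in% feature_set, , drop = FALSE]
    if (nrow(tpm) == 0L) stop("feature_set does not intersect the matrix")
  }
  out <- expand.grid(column = colnames(tpm), threshold = thresholds,
                     stringsAsFactors = FALSE)
  out$n_expressed <- mapply(function(col, thr) sum(tpm[, col] >= thr),
                            out$column, out$threshold)
  out$fraction <- out$n_expressed / nrow(tpm)
  out
}

#' Splicing entropy of isoform usage
#'
#' Per gene and column, isoform usage `P_i = TPM_i / sum(TPM)` over the gene's
#' isoforms gives the Shannon entropy `H = -sum(P_i log2 P_i)` in bits (with
#' `0 log 0 := 0`). Genes are eligible in a column when at least
#' `min_expressed_isoforms` isoforms have TPM > 0; the column summary is the
#' median entropy over eligible genes.
#'
#' @param mat a transcript-level `expression_matrix` with `tx2gene`.
#' @param min_expressed_isoforms eligibility cutoff (default 2: multi-isoform
#'   genes only).
#' @return an `entropy_result` list: `per_gene` (data.frame `gene`, `column`,
#'   `n_expressed_isoforms`, `entropy`; NA entropy for ineligible gene-column
#'   pairs), `column_medians` (named numeric), `eligibility`.
#' @export
splicing_entropy <- function(mat, min_expressed_isoforms = 2) {
  if (mat$level != "transcript") stop("splicing entropy needs a transcript-level matrix")
  if (is.null(mat$tx2gene)) stop("transcript->gene map required")
  tpm <- mat$tpm
  genes <- mat$tx2gene[rownames(tpm)]
  if (any(is.na(genes))) stop("transcripts missing from the tx2gene map")
  gene_levels <- unique(genes)
  per <- do.call(rbind, lapply(gene_levels, function(gg) {
    sub <- tpm[genes == gg, , drop = FALSE]
    ent <- apply(sub, 2, function(v) {
      k <- sum(v > 0)
      if (k < min_expressed_isoforms) return(NA_real_)
      p <- v[v > 0] / sum(v)
      -sum(p * log2(p))
    })
    data.frame(gene = gg, column = colnames(tpm),
               n_expressed_isoforms = apply(sub, 2, function(v) sum(v > 0)),
               entropy = unname(ent), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  med <- tapply(per$entropy, per$column, stats::median, na.rm = TRUE)
  structure(list(per_gene = per,
                 column_medians = med[colnames(tpm)],
                 eligibility = sprintf(">= %d isoforms with TPM > 0",
                                       min_expressed_isoforms)),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat("splicing entropy (bits); column medians over eligible genes:\n")
  print(round(x$column_medians, 4))
  invisible(x)
}

#' Linear fit of expressed transcripts against expressed genes
#'
#' Ordinary least squares `transcripts = a + b * genes` over reference tissue
#' points, with 95% mean-response confidence intervals from the t
#' distribution, evaluated at query gene counts.
#'
#' @param reference_points data.frame with `n_genes`, `n_transcripts`.
#' @param query_points numeric vector of gene counts to predict at.
#' @return a `tg_fit` list: `slope`, `intercept`, `residual_sd`, `predictions`
#'   (data.frame `n_genes`, `predicted`, `ci_low`, `ci_high`, `ci_half_width`).
#' @export
transcripts_vs_genes_fit <- function(reference_points, query_points = numeric(0)) {
  rp <- as.data.frame(reference_points)
  if (nrow(rp) < 3L) stop("regression needs >= 3 reference points")
  if (stats::var(rp$n_genes) == 0) stop("zero variance in gene counts")
  fit <- stats::lm(n_transcripts ~ n_genes, data = rp)
  preds <- if (length(query_points) > 0L) {
    ci <- stats::predict(fit, newdata = data.frame(n_genes = query_points),
                         interval = "confidence", level = 0.95)
    data.frame(n_genes = query_points, predicted = ci[, "fit"],
               ci_low = ci[, "lwr"], ci_high = ci[, "upr"],
               ci_half_width = (ci[, "upr"] - ci[, "lwr"]) / 2)
  } else {
    data.frame(n_genes = numeric(0), predicted = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               ci_half_width = numeric(0))
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = summary(fit)$sigma,
                 predictions = preds, lm = fit),
            class = "tg_fit")
}

#' @export
print.tg_fit <- function(x, ...) {
  cat(sprintf("transcripts ~ genes: slope %.4g, intercept %.4g, residual SD %.4g\n",
              x$slope, x$intercept, x$residual_sd))
  invisible(x)
}

#' Aggregate replicate columns to one column per tissue by median TPM
#'
#' @param mat an `expression_matrix`.
#' @param tissue_of named character vector: column name -> tissue.
#' @return an `expression_matrix` with one median column per tissue.
#' @export
aggregate_tissues <- function(mat, tissue_of) {
  tissues <- unique(tissue_of[colnames(mat$tpm)])
  agg <- matrix(0, nrow(mat$tpm), length(tissues),
                dimnames = list(rownames(mat$tpm), tissues))
  for (t in tissues) {
    cols <- colnames(mat$tpm)[tissue_of[colnames(mat$tpm)] == t]
    agg[, t] <- apply(mat$tpm[, cols, drop = FALSE], 1, stats::median)
  }
  expression_matrix(agg, level = mat$level, tx2gene = mat$tx2gene)
}

#' Read an expression matrix from TSV (feature id in the first column)
#' @param path TSV path.
#' @param level `"gene"` or `"transcript"`.
#' @param tx2gene optional named map (see [expression_matrix()]).
#' @return an `expression_matrix`.
#' @export
read_expression_tsv <- function(path, level = "gene", tx2gene = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, level = level, tx2gene = tx2gene)
}

#' Write an expression matrix as TSV
#' @param mat an `expression_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat$tpm), mat$tpm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
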