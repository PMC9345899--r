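#' Fit a power law to the reverse-cumulative tag-count distribution
#'
#' 5' tag counts of capped transcripts characteristically follow a power law:
#' the number of genomic positions with at least `x` tags falls off as
#' `R(x) = c * x^-alpha`. The fit is an ordinary least-squares regression of
#' `log10 R(x)` on `log10 x` over the distinct observed count values inside
#' `[fit_min, fit_max]` (unweighted: one point per distinct value).
#'
#' @param track a raw `tss_track`.
#' @param fit_min,fit_max bounds on the count values entering the fit. The
#'   default `[1, 1000]` excludes the saturated extreme tail.
#' @param ref_alpha,ref_total slope and total signal of the common reference
#'   power law used later by [normalize_to_reference()]; defaults 1.25 and
#'   1e6 ("tags per million").
#' @return A `power_law_fit`: list with `alpha` (positive slope magnitude),
#'   `log10_c` (intercept, log10 of the fitted reverse cumulative at count 1),
#'   `fit_min`, `fit_max`, `n_points`, `r2`, `ref_alpha`, `ref_total`.
#' @export
fit_power_law <- function(track, fit_min = 1, fit_max = 1000,
                          ref_alpha = 1.25, ref_total = 1e6) {
  if (track$kind != "raw") stop("fit_power_law expects a raw track")
  v <- track$data$value
  xs <- sort(unique(v))
  xs <- xs[xs >= fit_min & xs <= fit_max]
  if (length(xs) < 2L) stop("power-law fit needs >= 2 distinct count values in range")
  rev_cum <- vapply(xs, function(x) sum(v >= x), numeric(1))
  lx <- log10(xs)
  ly <- log10(rev_cum)
  fit <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) stop("power-law fit failed: non-decreasing tail")
  r2 <- if (stats::var(ly) == 0) 1 else summary(fit)$r.squared
  structure(list(alpha = -slope, log10_c = unname(stats::coef(fit)[1]),
                 fit_min = fit_min, fit_max = fit_max, n_points = length(xs),
                 r2 = r2, ref_alpha = ref_alpha, ref_total = ref_total),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: alpha=%.4f log10_c=%.4f (n=%d, r2=%.4f), reference beta=%.3g T=%.3g\n",
              x$alpha, x$log10_c, x$n_points, x$r2, x$ref_alpha, x$ref_total))
  invisible(x)
}

#' Normalize a raw track to a common reference power law
#'
#' Each raw count `x` is mapped onto the value `y` at which the reference
#' power law `R_ref(y) = c' * y^-beta` (with `c' = T * (beta - 1)`, the
#' continuous-total normalization so that the reference integrates to `T`
#' tags) has the same reverse-cumulative height as the sample's fitted law at
#' `x`:
#'
#'   y = (c * x^-alpha / c')^(-1/beta)
#'
#' The mapping is strictly increasing in `x`, so positions and value ranks are
#' preserved; only the value scale changes.
#'
#' @param track raw `tss_track`.
#' @param fit `power_law_fit` obtained from this track.
#' @return a normalized `tss_track` on the same positions.
#' @export
normalize_to_reference <- function(track, fit) {
  if (track$kind != "raw") stop("normalize_to_reference expects a raw track")
  beta <- fit$ref_alpha
  if (beta <= 1) stop("reference alpha must exceed 1 (reference total undefined)")
  c_fit <- 10^fit$log10_c
  c_ref <- fit$ref_total * (beta - 1)
  x <- track$data$value
  y <- (c_fit * x^(-fit$alpha) / c_ref)^(-1 / beta)
  out <- track$data
  out$value <- y
  new_tss_track(out, track$sample_id, "normalized")
}

#' TSS discovery saturation curve by tag subsampling
#'
#' For each proportion `p`, individual tags (each position's count expanded to
#' that many tags) are subsampled without replacement down to
#' `round(p * total)` tags, and the number of distinct positions retaining at
#' least one tag is counted.
#'
#' @param track raw `tss_track`.
#' @param proportions numeric vector in (0, 1].
#' @param seed integer seed for the subsampling.
#' @return data.frame with columns `proportion`, `n_distinct_tss`.
#' @export
saturation_curve <- function(track, proportions = c(0.1, 0.25, 0.5, 0.75, 1),
                             seed = 1L) {
  if (track$kind != "raw") stop("saturation_curve expects a raw track")
  if (any(proportions <= 0 | proportions > 1)) {
    stop("proportions must lie in (0, 1]")
  }
  counts <- as.integer(round(track$data$value))
  total <- sum(counts)
  n_pos <- nrow(track$data)
  # one fixed random tag order per call: nested subsamples => monotone curve
  tag_owner <- rep.int(seq_len(n_pos), counts)
  perm <- with_seed(seed, sample.int(length(tag_owner)))
  ordered_owner <- tag_owner[perm]
  n_distinct <- vapply(proportions, function(p) {
    k <- round(p * total)
    if (k <= 0) 0L else length(unique(ordered_owner[seq_len(k)]))
  }, integer(1))
  data.frame(proportion = proportions, n_distinct_tss = n_distinct)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
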