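#' Density-based hierarchical clustering of TSS positions
#'
#' Clusters the sites of one chromosome strand into a nested hierarchy of
#' candidate transcription start regions. A segment of sites is a cluster at
#' density `d` when it is maximal under the score `total - d * span`; each
#' reported cluster carries the half-open density interval
#' `[min_density, max_density)` over which it is maximal. The decomposition is
#' recursive: for a segment, the break density is the minimum over all prefix
#' densities `sum(i..k) / (p[k+1] - p[i])` and suffix densities
#' `sum(k..j) / (p[j] - p[k-1])`; the weakest prefix (or suffix; ties resolved
#' prefixes first, shorter first) is split off and both parts are decomposed
#' further with inherited density `max(d_in, break)`. Clusters whose density
#' interval is empty (`min >= max`) are never maximal and are suppressed.
#'
#' @param sites data.frame with strictly increasing `pos` (integer) and
#'   positive `value` columns, all on one chromosome and strand.
#' @return data.frame of clusters: `start`, `end` (0-based inclusive site
#'   positions), `n_sites`, `total`, `span`, `min_density`, `max_density`,
#'   ordered by `start` then decreasing span. Returns zero rows for empty
#'   input.
#' @examples
#' paraclu_hierarchy(data.frame(pos = c(1L, 2L, 50L), value = c(4, 4, 2)))
#' @export
paraclu_hierarchy <- function(sites) {
  sites <- as.data.frame(sites)
  n <- nrow(sites)
  cols <- c("start", "end", "n_sites", "total", "span", "min_density", "max_density")
  if (n == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), 7L), cols))
    out$start <- integer(0); out$end <- integer(0); out$n_sites <- integer(0)
    out$span <- integer(0)
    return(out)
  }
  pos <- as.integer(sites$pos)
  val <- as.numeric(sites$value)
  if (n > 1L && any(diff(pos) <= 0L)) {
    stop("site positions must be strictly increasing (sorted, no duplicates)")
  }
  if (any(val <= 0)) stop("site values must be > 0")
  csum <- c(0, cumsum(val))
  range_sum <- function(i, j) csum[j + 1L] - csum[i]

  res_start <- integer(0); res_end <- integer(0); res_n <- integer(0)
  res_total <- numeric(0); res_min <- numeric(0); res_max <- numeric(0)
  emit <- function(i, j, d_in, d_break) {
    res_start <<- c(res_start, pos[i]); res_end <<- c(res_end, pos[j])
    res_n <<- c(res_n, j - i + 1L); res_total <<- c(res_total, range_sum(i, j))
    res_min <<- c(res_min, d_in); res_max <<- c(res_max, d_break)
  }

  # explicit stack; segments are (i, j, d_in)
  stack <- list(list(i = 1L, j = n, d_in = 0))
  while (length(stack) > 0L) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg$i; j <- seg$j; d_in <- seg$d_in
    if (i == j) {
      if (d_in < val[i]) emit(i, j, d_in, val[i])
      next
    }
    # candidate break densities: prefixes (shorter first), then suffixes
    ks_pre <- i:(j - 1L)
    d_pre <- (csum[ks_pre + 1L] - csum[i]) / (pos[ks_pre + 1L] - pos[i])
    ks_suf <- j:(i + 1L)                       # shorter suffixes first
    d_suf <- (csum[j + 1L] - csum[ks_suf]) / (pos[j] - pos[ks_suf - 1L])
    cand <- c(d_pre, d_suf)
    best <- which.min(cand)                    # first minimum: prefix-first, shorter-first
    d_break <- cand[best]
    if (d_in < d_break) emit(i, j, d_in, d_break)
    d_child <- max(d_in, d_break)
    if (best <= length(ks_pre)) {
      k <- ks_pre[best]
      stack[[length(stack) + 1L]] <- list(i = i, j = k, d_in = d_child)
      stack[[length(stack) + 1L]] <- list(i = k + 1L, j = j, d_in = d_child)
    } else {
      k <- ks_suf[best - length(ks_pre)]
      stack[[length(stack) + 1L]] <- list(i = i, j = k - 1L, d_in = d_child)
      stack[[length(stack) + 1L]] <- list(i = k, j = j, d_in = d_child)
    }
  }
  out <- data.frame(start = res_start, end = res_end, n_sites = res_n,
                    total = res_total, span = res_end - res_start + 1L,
                    min_density = res_min, max_density = res_max)
  out <- out[order(out$start, -out$span), cols]
  rownames(out) <- NULL
  out
}

#' Run the density hierarchy across a whole track
#'
#' Splits a normalized (or raw) track by chromosome and strand, clusters each
#' part with [paraclu_hierarchy()], and returns the combined table.
#'
#' @param track a `tss_track`.
#' @return data.frame of clusters with additional `chrom` and `strand` columns.
#' @export
paraclu_track <- function(track) {
  d <- track$data
  if (nrow(d) == 0L) {
    out <- paraclu_hierarchy(data.frame(pos = integer(), value = numeric()))
    out$chrom <- character(0); out$strand <- character(0)
    return(out[, c("chrom", "strand", setdiff(names(out), c("chrom", "strand")))])
  }
  parts <- split(d, list(d$chrom, d$strand), drop = TRUE)
  res <- lapply(parts, function(p) {
    p <- p[order(p$pos), ]
    h <- paraclu_hierarchy(data.frame(pos = p$pos, value = p$value))
    if (nrow(h) > 0L) {
      h$chrom <- p$chrom[1L]
      h$strand <- p$strand[1L]
    } else {
      h$chrom <- character(0); h$strand <- character(0)
    }
    h
  })
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$strand, out$start, -out$span), ]
  rownames(out) <- NULL
  out[, c("chrom", "strand", "start", "end", "n_sites", "total", "span",
          "min_density", "max_density")]
}
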