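#' Select transcription start regions from a cluster hierarchy
#'
#' Applies the TSR filters to the density hierarchy of one sample: minimum
#' total signal (2 tags per million by default), maximum cluster length (20 bp
#' by default) and, optionally, a minimum density stability
#' `max_density / min_density`. Among nested clusters that all pass, only the
#' outermost is kept, so the result is non-overlapping per chromosome strand.
#'
#' @param hierarchy cluster table from [paraclu_track()] (or
#'   [paraclu_hierarchy()] with `chrom`/`strand` columns added).
#' @param sample_id sample name recorded on the result.
#' @param min_signal minimum cluster total (normalized tags).
#' @param max_span maximum cluster length in bp.
#' @param min_stability minimum `max_density / min_density`; the default 1
#'   disables the filter (a zero `min_density` is floored at 1e-9).
#' @return a `tsr_set`: list with `sample_id` and `clusters` (the retained,
#'   pairwise disjoint cluster rows).
#' @export
select_tsrs <- function(hierarchy, sample_id = "sample", min_signal = 2,
                        max_span = 20, min_stability = 1) {
  if (min_signal <= 0) stop("min_signal must be > 0")
  if (max_span < 1) stop("max_span must be >= 1")
  h <- as.data.frame(hierarchy)
  if (!all(c("chrom", "strand") %in% names(h))) {
    stop("hierarchy must carry chrom and strand columns (see paraclu_track)")
  }
  keep <- h$total >= min_signal & h$span <= max_span &
    (h$max_density / pmax(h$min_density, 1e-9)) >= min_stability
  cand <- h[keep, , drop = FALSE]
  if (nrow(cand) > 0L) {
    # outermost-first within each chrom/strand; drop candidates nested in a keeper
    cand <- cand[order(cand$chrom, cand$strand, cand$start, -cand$span), ]
    sel <- logical(nrow(cand))
    last_chrom <- ""; last_strand <- ""; last_end <- -1L
    for (r in seq_len(nrow(cand))) {
      if (cand$chrom[r] != last_chrom || cand$strand[r] != last_strand ||
          cand$start[r] > last_end) {
        sel[r] <- TRUE
        last_chrom <- cand$chrom[r]; last_strand <- cand$strand[r]
        last_end <- cand$end[r]
      }
    }
    cand <- cand[sel, , drop = FALSE]
    rownames(cand) <- NULL
  }
  structure(list(sample_id = sample_id, clusters = cand), class = "tsr_set")
}

#' @export
print.tsr_set <- function(x, ...) {
  cat(sprintf("tsr_set '%s': %d TSRs\n", x$sample_id, nrow(x$clusters)))
  invisible(x)
}

#' Merge per-sample TSRs into strand-specific consensus TSRs
#'
#' Sample TSRs (inclusive cluster coordinates) are converted to half-open
#' intervals and merged transitively, per chromosome and strand, whenever the
#' gap between two intervals is at most `merge_gap` bp (20 bp by default, the
#' proximity used for consensus calling). Consensus ids are assigned
#' deterministically in (chrom, start, strand) order.
#'
#' @param tsr_sets list of `tsr_set` objects (one per sample).
#' @param merge_gap maximum bp gap bridged when merging.
#' @return a `consensus_tsr_set`: list with `tsrs` (data.frame `id`, `chrom`,
#'   `strand`, `start`, `end`; half-open 0-based intervals), `samples`
#'   (character vector), `contributors` (per-consensus list of contributing
#'   sample TSR keys), and empty `presence`/`expression` matrices to be filled
#'   by [score_presence()].
#' @export
merge_consensus <- function(tsr_sets, merge_gap = 20) {
  if (length(tsr_sets) == 0L) stop("merge_consensus needs at least one tsr_set")
  samples <- vapply(tsr_sets, function(s) s$sample_id, character(1))
  if (anyDuplicated(samples)) stop("duplicate sample ids among tsr_sets")
  all_tsrs <- do.call(rbind, lapply(tsr_sets, function(s) {
    cl <- s$clusters
    if (nrow(cl) == 0L) return(NULL)
    data.frame(sample_id = s$sample_id, chrom = cl$chrom, strand = cl$strand,
               start = cl$start, end = cl$end + 1L,  # half-open
               total = cl$total, stringsAsFactors = FALSE)
  }))
  if (is.null(all_tsrs) || nrow(all_tsrs) == 0L) {
    tsrs <- data.frame(id = character(), chrom = character(), strand = character(),
                       start = integer(), end = integer())
    return(structure(list(tsrs = tsrs, samples = samples,
                          contributors = list(),
                          presence = matrix(FALSE, 0, length(samples),
                                            dimnames = list(NULL, samples)),
                          expression = matrix(0, 0, length(samples),
                                              dimnames = list(NULL, samples))),
                     class = "consensus_tsr_set"))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = all_tsrs$chrom,
    ranges = IRanges::IRanges(start = all_tsrs$start, end = all_tsrs$end - 1L),
    strand = all_tsrs$strand
  )
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L,
                                  ignore.strand = FALSE)
  md <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                   strand = as.character(GenomicRanges::strand(merged)),
                   start = GenomicRanges::start(merged),
                   end = GenomicRanges::end(merged) + 1L)
  ord <- order(md$chrom, md$start, md$strand)
  md <- md[ord, ]
  merged <- merged[ord]
  md$id <- sprintf("ctsr_%05d", seq_len(nrow(md)))
  hits <- GenomicRanges::findOverlaps(gr, merged)
  contrib <- split(paste0(all_tsrs$sample_id[S4Vectors::queryHits(hits)], ":",
                          all_tsrs$chrom[S4Vectors::queryHits(hits)], ":",
                          all_tsrs$start[S4Vectors::queryHits(hits)]),
                   factor(S4Vectors::subjectHits(hits), levels = seq_len(nrow(md))))
  tsrs <- md[, c("id", "chrom", "strand", "start", "end")]
  rownames(tsrs) <- NULL
  structure(list(tsrs = tsrs, samples = samples,
                 contributors = unname(as.list(contrib)),
                 presence = matrix(FALSE, nrow(tsrs), length(samples),
                                   dimnames = list(tsrs$id, samples)),
                 expression = matrix(0, nrow(tsrs), length(samples),
                                     dimnames = list(tsrs$id, samples))),
            class = "consensus_tsr_set")
}

#' @export
print.consensus_tsr_set <- function(x, ...) {
  cat(sprintf("consensus_tsr_set: %d TSRs across %d samples\n",
              nrow(x$tsrs), length(x$samples)))
  invisible(x)
}

#' Score per-sample presence and expression of consensus TSRs
#'
#' A consensus TSR is present in a sample when one of that sample's filtered
#' TSRs overlaps it by at least 1 bp on the same strand. Its expression in the
#' sample is the sum of the sample's normalized signal at positions inside the
#' consensus interval (same strand), which can be positive even when presence
#' is false (signal below the TSR filters).
#'
#' @param consensus a `consensus_tsr_set`.
#' @param tsr_sets list of per-sample `tsr_set` objects.
#' @param tracks list of normalized `tss_track` objects, same samples.
#' @return the `consensus_tsr_set` with `presence` and `expression` filled.
#' @export
score_presence <- function(consensus, tsr_sets, tracks) {
  set_ids <- vapply(tsr_sets, function(s) s$sample_id, character(1))
  trk_ids <- vapply(tracks, function(t) t$sample_id, character(1))
  if (!setequal(set_ids, consensus$samples) || !setequal(trk_ids, consensus$samples)) {
    stop("samples of tsr_sets/tracks do not match the consensus set")
  }
  tsr_sets <- tsr_sets[match(consensus$samples, set_ids)]
  tracks <- tracks[match(consensus$samples, trk_ids)]
  ct <- consensus$tsrs
  if (nrow(ct) == 0L) return(consensus)
  cons_gr <- GenomicRanges::GRanges(ct$chrom,
                                    IRanges::IRanges(ct$start, ct$end - 1L),
                                    strand = ct$strand)
  presence <- matrix(FALSE, nrow(ct), length(consensus$samples),
                     dimnames = list(ct$id, consensus$samples))
  expression <- matrix(0, nrow(ct), length(consensus$samples),
                       dimnames = list(ct$id, consensus$samples))
  for (s in seq_along(consensus$samples)) {
    cl <- tsr_sets[[s]]$clusters
    if (nrow(cl) > 0L) {
      gr <- GenomicRanges::GRanges(cl$chrom, IRanges::IRanges(cl$start, cl$end),
                                   strand = cl$strand)
      hit <- GenomicRanges::countOverlaps(cons_gr, gr) > 0L
      presence[hit, s] <- TRUE
    }
    td <- tracks[[s]]$data
    if (nrow(td) > 0L) {
      pos_gr <- GenomicRanges::GRanges(td$chrom, IRanges::IRanges(td$pos, td$pos),
                                       strand = td$strand)
      hits <- GenomicRanges::findOverlaps(pos_gr, cons_gr)
      if (length(hits) > 0L) {
        sums <- tapply(td$value[S4Vectors::queryHits(hits)],
                       factor(S4Vectors::subjectHits(hits), levels = seq_len(nrow(ct))),
                       sum)
        sums[is.na(sums)] <- 0
        expression[, s] <- as.numeric(sums)
      }
    }
  }
  consensus$presence <- presence
  consensus$expression <- expression
  consensus
}

#' Write a TSR or consensus set as BED6
#'
#' Scores are `min(1000, round(total))`; consensus rows without totals score 0.
#'
#' @param x a `tsr_set` or `consensus_tsr_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsr_bed <- function(x, path) {
  if (inherits(x, "tsr_set")) {
    cl <- x$clusters
    if (nrow(cl) == 0L) {
      writeLines(character(0), path); return(invisible(path))
    }
    df <- data.frame(chrom = cl$chrom, start = cl$start, end = cl$end + 1L,
                     name = sprintf("%s_tsr_%04d", x$sample_id, seq_len(nrow(cl))),
                     score = pmin(1000, round(cl$total)), strand = cl$strand)
  } else if (inherits(x, "consensus_tsr_set")) {
    ct <- x$tsrs
    tot <- if (nrow(x$expression) == nrow(ct)) rowSums(x$expression) else rep(0, nrow(ct))
    df <- data.frame(chrom = ct$chrom, start = ct$start, end = ct$end,
                     name = ct$id, score = pmin(1000, round(tot)),
                     strand = ct$strand)
  } else stop("x must be a tsr_set or consensus_tsr_set")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
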