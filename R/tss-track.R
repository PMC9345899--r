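#' TSS track: strand-specific per-position 5' tag signal for one sample
#'
#' A `tss_track` stores, for a single sample, the tag signal observed at each
#' genomic position where transcription initiation was detected: one value per
#' unique (chromosome, strand, position) key. Positions are 0-based. Raw tracks
#' hold positive integer tag counts; normalized tracks hold strictly positive
#' real tags-per-million values.
#'
#' @param records data.frame with columns `chrom`, `pos`, `strand`, `count`
#'   (one row per observed tag batch; duplicate keys are summed).
#' @param sample_id character scalar naming the sample.
#' @return An object of class `tss_track`: a list with elements `sample_id`,
#'   `data` (data.frame `chrom`, `pos`, `strand`, `value`, sorted by
#'   chromosome, strand, position) and `kind` (`"raw"` or `"normalized"`).
#' @examples
#' trk <- build_track(data.frame(chrom = "chr1", pos = c(100L, 100L, 105L),
#'                               strand = "+", count = c(3L, 2L, 1L)), "s1")
#' trk$data
#' @export
build_track <- function(records, sample_id = "sample") {
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    return(new_tss_track(empty_track_data(), sample_id, "raw"))
  }
  records <- as.data.frame(records)
  required <- c("chrom", "pos", "strand", "count")
  if (!all(required %in% names(records))) {
    stop("CTSS records need columns: ", paste(required, collapse = ", "))
  }
  if (any(!records$strand %in% c("+", "-"))) {
    stop("malformed strand; must be '+' or '-'")
  }
  if (any(records$count <= 0) || any(records$count != round(records$count))) {
    stop("tag counts must be positive integers")
  }
  if (any(records$pos < 0)) stop("positions must be >= 0")
  agg <- stats::aggregate(
    list(value = as.numeric(records$count)),
    by = list(chrom = as.character(records$chrom),
              strand = as.character(records$strand),
              pos = as.integer(records$pos)),
    FUN = sum
  )
  agg <- agg[order(agg$chrom, agg$strand, agg$pos), c("chrom", "pos", "strand", "value")]
  rownames(agg) <- NULL
  new_tss_track(agg, sample_id, "raw")
}

new_tss_track <- function(data, sample_id, kind) {
  stopifnot(kind %in% c("raw", "normalized"))
  structure(list(sample_id = sample_id, data = data, kind = kind),
            class = "tss_track")
}

empty_track_data <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             value = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.tss_track <- function(x, ...) {
  cat(sprintf("tss_track '%s' (%s): %d positions, total signal %.6g\n",
              x$sample_id, x$kind, nrow(x$data), sum(x$data$value)))
  invisible(x)
}

#' Total signal of a track
#' @param track a `tss_track`.
#' @return Sum of the track's values (tag count for raw tracks, normalized
#'   tags for normalized tracks).
#' @export
track_total <- function(track) sum(track$data$value)

#' Read a CTSS table
#'
#' CTSS files are tab-separated with columns chrom, position, strand, value and
#' optional `#`-prefixed comment lines. Positions are 0-based by default; pass
#' `one_based = TRUE` for dialects counting from 1.
#'
#' @param path file path.
#' @param sample_id sample name; defaults to the file's base name.
#' @param kind `"raw"` (integer counts) or `"normalized"` (TPM values).
#' @param one_based logical; convert 1-based input positions to 0-based.
#' @return a `tss_track`.
#' @export
read_ctss <- function(path, sample_id = NULL, kind = c("raw", "normalized"),
                      one_based = FALSE) {
  kind <- match.arg(kind)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                          col.names = c("chrom", "pos", "strand", "value"),
                          colClasses = c("character", "integer", "character", "numeric"))
  if (one_based) df$pos <- df$pos - 1L
  if (kind == "raw") {
    build_track(data.frame(chrom = df$chrom, pos = df$pos, strand = df$strand,
                           count = df$value), sample_id)
  } else {
    if (any(df$value <= 0)) stop("normalized values must be > 0")
    df <- df[order(df$chrom, df$strand, df$pos), c("chrom", "pos", "strand", "value")]
    rownames(df) <- NULL
    new_tss_track(df, sample_id, "normalized")
  }
}

#' Write a CTSS table
#'
#' Raw counts are written as integers; normalized values at 6 significant
#' digits. A comment header records the sample and kind.
#'
#' @param track a `tss_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ctss <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ctss sample=%s kind=%s", track$sample_id, track$kind), con)
  if (nrow(track$data) > 0L) {
    val <- if (track$kind == "raw") {
      format(as.integer(round(track$data$value)), trim = TRUE, scientific = FALSE)
    } else {
      formatC(track$data$value, digits = 6, format = "g")
    }
    writeLines(paste(track$data$chrom, track$data$pos, track$data$strand, val,
                     sep = "\t"), con)
  }
  invisible(path)
}
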