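#' Genomic annotation container
#'
#' Minimal gene-model annotation used for TSR categorization: one transcript
#' model per gene, with exons and (for coding genes) a CDS. All coordinates are
#' 0-based inclusive internally; GTF I/O converts to the 1-based convention.
#'
#' @param genes data.frame: `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss`, `tts`, `biotype` (`"coding"` or `"noncoding"`).
#' @param exons data.frame: `gene_id`, `transcript_id`, `start`, `end`.
#' @param cds data.frame: `gene_id`, `transcript_id`, `start`, `end` (rows only
#'   for coding genes).
#' @return a `genomic_annotation` object.
#' @export
genomic_annotation <- function(genes, exons, cds) {
  genes <- as.data.frame(genes); exons <- as.data.frame(exons)
  cds <- as.data.frame(cds)
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end", "tss", "tts",
                  "biotype") %in% names(genes)))
  if (any(genes$tss < genes$start | genes$tss > genes$end)) {
    stop("gene TSS must lie inside the gene span")
  }
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "genomic_annotation")
}

#' @export
print.genomic_annotation <- function(x, ...) {
  cat(sprintf("genomic_annotation: %d genes (%d coding), %d exons\n",
              nrow(x$genes), sum(x$genes$biotype == "coding"), nrow(x$exons)))
  invisible(x)
}

#' Write the minimal GTF dialect
#'
#' Emits gene, exon and CDS features with `gene_id`/`transcript_id` attributes,
#' converting internal 0-based inclusive coordinates to 1-based GTF.
#'
#' @param annotation a `genomic_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  g <- annotation$genes
  lines <- character(0)
  fmt <- function(chrom, feat, start, end, strand, attrs) {
    sprintf("%s\ttsrdiv\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, start + 1L, end + 1L, strand, attrs)
  }
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    attrs <- sprintf('gene_id "%s"; biotype "%s";', gid, g$biotype[i])
    lines <- c(lines, fmt(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i], attrs))
    ex <- annotation$exons[annotation$exons$gene_id == gid, , drop = FALSE]
    for (k in seq_len(nrow(ex))) {
      lines <- c(lines, fmt(g$chrom[i], "exon", ex$start[k], ex$end[k], g$strand[i],
                            sprintf('gene_id "%s"; transcript_id "%s";', gid,
                                    ex$transcript_id[k])))
    }
    cd <- annotation$cds[annotation$cds$gene_id == gid, , drop = FALSE]
    for (k in seq_len(nrow(cd))) {
      lines <- c(lines, fmt(g$chrom[i], "CDS", cd$start[k], cd$end[k], g$strand[i],
                            sprintf('gene_id "%s"; transcript_id "%s";', gid,
                                    cd$transcript_id[k])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read the minimal GTF dialect
#'
#' @param path GTF file with gene/exon/CDS features and `gene_id`,
#'   `transcript_id` and (on gene rows) `biotype` attributes.
#' @return a `genomic_annotation`.
#' @export
read_gtf <- function(path) {
  raw <- utils::read.table(path, sep = "\t", comment.char = "#", quote = "",
                           col.names = c("chrom", "source", "feature", "start",
                                         "end", "score", "strand", "frame", "attr"),
                           colClasses = c("character", "character", "character",
                                          "integer", "integer", "character",
                                          "character", "character", "character"))
  raw$start <- raw$start - 1L
  raw$end <- raw$end - 1L
  get_attr <- function(attr, key) {
    m <- regmatches(attr, regexec(sprintf('%s "([^"]*)"', key), attr))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
  }
  raw$gene_id <- get_attr(raw$attr, "gene_id")
  raw$transcript_id <- get_attr(raw$attr, "transcript_id")
  gr <- raw[raw$feature == "gene", , drop = FALSE]
  genes <- data.frame(gene_id = gr$gene_id, chrom = gr$chrom, strand = gr$strand,
                      start = gr$start, end = gr$end,
                      tss = ifelse(gr$strand == "+", gr$start, gr$end),
                      tts = ifelse(gr$strand == "+", gr$end, gr$start),
                      biotype = get_attr(gr$attr, "biotype"))
  ex <- raw[raw$feature == "exon", , drop = FALSE]
  cd <- raw[raw$feature == "CDS", , drop = FALSE]
  genomic_annotation(
    genes,
    data.frame(gene_id = ex$gene_id, transcript_id = ex$transcript_id,
               start = ex$start, end = ex$end),
    data.frame(gene_id = cd$gene_id, transcript_id = cd$transcript_id,
               start = cd$start, end = cd$end)
  )
}

#' Categorize consensus TSRs against gene models
#'
#' Each consensus TSR is assigned exactly one genomic category by its interval
#' midpoint, with priority promoter > TTS > 5' UTR > 3' UTR > coding exon >
#' noncoding exon > intron > intergenic. The promoter and TTS windows are
#' strand-aware around the annotated gene TSS/TTS (defaults: promoter −1000 to
#' +100 bp, TTS −100 to +1000 bp, in gene orientation). The nearest gene is the
#' one whose annotated TSS minimizes the absolute midpoint distance on the same
#' chromosome (any strand); the distance is reported signed in the gene's
#' orientation (positive downstream of the TSS).
#'
#' @param consensus a `consensus_tsr_set`.
#' @param annotation a `genomic_annotation`.
#' @param promoter_window,tts_window numeric length-2 windows in gene
#'   orientation around TSS and TTS.
#' @return data.frame `id`, `category`, `nearest_gene_id`, `tss_distance`.
#' @export
annotate_tsrs <- function(consensus, annotation,
                          promoter_window = c(-1000, 100),
                          tts_window = c(-100, 1000)) {
  if (nrow(annotation$genes) == 0L) stop("annotation has no genes")
  ct <- consensus$tsrs
  g <- annotation$genes
  exons <- annotation$exons
  cds <- annotation$cds
  cds_span <- if (nrow(cds) > 0L) {
    do.call(rbind, lapply(split(cds, cds$gene_id), function(d) {
      data.frame(gene_id = d$gene_id[1], cds_start = min(d$start), cds_end = max(d$end))
    }))
  } else data.frame(gene_id = character(), cds_start = integer(), cds_end = integer())

  n <- nrow(ct)
  category <- rep("intergenic", n)
  nearest_gene <- rep(NA_character_, n)
  tss_distance <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    mid <- floor((ct$start[r] + ct$end[r] - 1L) / 2)
    on_chrom <- g[g$chrom == ct$chrom[r], , drop = FALSE]
    if (nrow(on_chrom) == 0L) next
    # orientation-signed offset of the midpoint from each gene's TSS / TTS
    sgn <- ifelse(on_chrom$strand == "+", 1, -1)
    off_tss <- sgn * (mid - on_chrom$tss)
    off_tts <- sgn * (mid - on_chrom$tts)
    ni <- which.min(abs(off_tss))
    nearest_gene[r] <- on_chrom$gene_id[ni]
    tss_distance[r] <- off_tss[ni]

    in_prom <- off_tss >= promoter_window[1] & off_tss <= promoter_window[2]
    in_tts <- off_tts >= tts_window[1] & off_tts <= tts_window[2]
    in_gene <- mid >= on_chrom$start & mid <= on_chrom$end
    gene_ids <- on_chrom$gene_id
    in_exon <- vapply(gene_ids, function(gid) {
      e <- exons[exons$gene_id == gid, , drop = FALSE]
      any(mid >= e$start & mid <= e$end)
    }, logical(1)) & in_gene
    cs <- cds_span[match(gene_ids, cds_span$gene_id), , drop = FALSE]
    coding <- on_chrom$biotype == "coding" & !is.na(cs$cds_start)
    before_cds <- coding & ifelse(on_chrom$strand == "+",
                                  mid < cs$cds_start, mid > cs$cds_end)
    after_cds <- coding & ifelse(on_chrom$strand == "+",
                                 mid > cs$cds_end, mid < cs$cds_start)
    category[r] <-
      if (any(in_prom)) "promoter"
      else if (any(in_tts)) "tts"
      else if (any(in_exon & before_cds)) "five_utr"
      else if (any(in_exon & after_cds)) "three_utr"
      else if (any(in_exon & coding)) "exon"
      else if (any(in_exon & !coding)) "noncoding"
      else if (any(in_gene)) "intron"
      else "intergenic"
  }
  data.frame(id = ct$id, category = category, nearest_gene_id = nearest_gene,
             tss_distance = tss_distance, stringsAsFactors = FALSE)
}

#' Distance from each consensus TSR to the nearest feature interval
#'
#' Strand-agnostic, intra-chromosomal edge-to-edge distance: 0 when the TSR
#' overlaps a feature, `NA` when the TSR's chromosome carries no feature.
#'
#' @param consensus a `consensus_tsr_set`.
#' @param features data.frame of half-open intervals: `chrom`, `start`, `end`
#'   (BED3-style, 0-based).
#' @return data.frame `id`, `distance`.
#' @export
nearest_feature_distance <- function(consensus, features) {
  ct <- consensus$tsrs
  features <- as.data.frame(features)
  dist <- rep(NA_real_, nrow(ct))
  if (nrow(features) > 0L && nrow(ct) > 0L) {
    tsr_gr <- GenomicRanges::GRanges(ct$chrom, IRanges::IRanges(ct$start, ct$end - 1L))
    feat_gr <- GenomicRanges::GRanges(features$chrom,
                                      IRanges::IRanges(features$start, features$end - 1L))
    nearest <- GenomicRanges::distanceToNearest(tsr_gr, feat_gr, ignore.strand = TRUE)
    dist[S4Vectors::queryHits(nearest)] <- S4Vectors::mcols(nearest)$distance
  }
  data.frame(id = ct$id, distance = dist, stringsAsFactors = FALSE)
}

#' Read BED3 feature intervals
#' @param path BED file (chrom, start, end; 0-based half-open).
#' @return data.frame `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          colClasses = c("character", "integer", "integer"))[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df
}
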