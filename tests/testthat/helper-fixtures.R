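# Shared fixtures, built in code.

# reduced-scale config for fast unit tests (acceptance tests use defaults)
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             genome = c(chrA = 300000L, chrB = 300000L),
             n_promoters = 60L, total_tags_per_sample = 8000L,
             n_genes = 40L, n_tra = 10L, n_housekeeping = 10L,
             n_tissues = 12L, ...)
}

make_track <- function(pos, count, chrom = "c1", strand = "+", sample_id = "s1") {
  build_track(data.frame(chrom = chrom, pos = as.integer(pos),
                         strand = strand, count = as.integer(count)),
              sample_id)
}

# raw track whose per-position counts follow P(X >= x) = x^-exponent
zipf_track <- function(n_sites, exponent, seed = 1L, sample_id = "zipf") {
  set.seed(seed)
  counts <- pmin(pmax(floor(runif(n_sites)^(-1 / exponent)), 1), 1e6)
  build_track(data.frame(chrom = "c1", pos = seq_len(n_sites) * 10L,
                         strand = "+", count = as.integer(counts)), sample_id)
}

# tiny two-gene annotation on one chromosome:
#   gene_a: + strand, TSS 10000, exons [10000,10400] and [12000,12500],
#           CDS [10200,12300] (so 5' UTR before 10200, 3' UTR after 12300)
#   gene_b: - strand, noncoding, TSS 50000, single exon [49000,50000]
tiny_annotation <- function() {
  genomic_annotation(
    genes = data.frame(
      gene_id = c("gene_a", "gene_b"), chrom = "c1", strand = c("+", "-"),
      start = c(10000L, 49000L), end = c(12500L, 50000L),
      tss = c(10000L, 50000L), tts = c(12500L, 49000L),
      biotype = c("coding", "noncoding")),
    exons = data.frame(
      gene_id = c("gene_a", "gene_a", "gene_b"),
      transcript_id = c("gene_a.t1", "gene_a.t1", "gene_b.t1"),
      start = c(10000L, 12000L, 49000L), end = c(10400L, 12500L, 50000L)),
    cds = data.frame(
      gene_id = c("gene_a", "gene_a"),
      transcript_id = c("gene_a.t1", "gene_a.t1"),
      start = c(10200L, 12000L), end = c(10400L, 12300L))
  )
}

# consensus set built directly from intervals (half-open), for interval tests
make_consensus <- function(chrom, start, end, strand, samples = c("s1", "s2")) {
  tsrs <- data.frame(id = sprintf("ctsr_%05d", seq_along(start)),
                     chrom = chrom, strand = strand,
                     start = as.integer(start), end = as.integer(end))
  structure(list(tsrs = tsrs, samples = samples, contributors = list(),
                 presence = matrix(FALSE, nrow(tsrs), length(samples),
                                   dimnames = list(tsrs$id, samples)),
                 expression = matrix(0, nrow(tsrs), length(samples),
                                     dimnames = list(tsrs$id, samples))),
            class = "consensus_tsr_set")
}

make_tsr_set <- function(sample_id, chrom, start, end, strand, total = 10) {
  structure(list(sample_id = sample_id,
                 clusters = data.frame(chrom = chrom, strand = strand,
                                       start = as.integer(start),
                                       end = as.integer(end),
                                       n_sites = 1L, total = total,
                                       span = as.integer(end - start + 1L),
                                       min_density = 0, max_density = Inf)),
            class = "tsr_set")
}
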