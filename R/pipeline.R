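#' Read a pipeline configuration
#'
#' Configurations are JSON (key-value, nested sections per stage). Relative
#' paths are resolved against the config file's directory. A list passes
#' through unchanged (paths then resolved against `base` or the working
#' directory).
#'
#' @param config path to a JSON file, or a list.
#' @param base directory for resolving relative paths when `config` is a list.
#' @return the configuration list, with an attached `base` attribute.
#' @export
read_pipeline_config <- function(config, base = NULL) {
  if (is.character(config) && length(config) == 1L) {
    base <- dirname(normalizePath(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(base)) base <- attr(config, "base", exact = TRUE)
  attr(config, "base") <- if (is.null(base)) "." else base
  config
}

cfg_path <- function(config, key, required = TRUE) {
  val <- config[[key]]
  if (is.null(val)) {
    if (required) stop(sprintf("config error: missing required key '%s'", key))
    return(NULL)
  }
  base <- attr(config, "base", exact = TRUE)
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  if (is.list(val)) lapply(val, resolve) else resolve(val)
}

cfg_param <- function(config, key, default) {
  p <- config$params
  if (!is.null(p[[key]])) p[[key]] else default
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[tsrdiv:%s] %s", stage, paste0(...)))
}

stage_guard <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Read / write a sample design TSV (sample_id, group, individual_id)
#' @param path TSV path.
#' @return a `sample_group_design`.
#' @export
read_design <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  sample_group_design(df$sample_id, df$group, df$individual_id)
}

#' @rdname read_design
#' @param design a `sample_group_design`.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-set list (one id per line, `#` comments allowed)
#' @param path file path.
#' @return character vector of ids.
#' @export
read_gene_set <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

write_matrix_tsv <- function(m, path, row_label = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_manifest <- function(config, inputs, outputs, log_path = NA_character_) {
  sum_of <- function(paths) {
    paths <- unlist(paths, use.names = FALSE)
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  list(tool = "tsrdiv",
       version = as.character(utils::packageVersion("tsrdiv")),
       config_hash = unname(tools::md5sum(
         local({
           tmp <- tempfile()
           jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
           tmp
         }))),
       inputs = sum_of(inputs), outputs = sum_of(outputs),
       log_path = log_path)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Produces per-sample CTSS files, the paired sample design, the minimal GTF
#' annotation, gene-set lists, gene- and transcript-level TPM matrices, the
#' transcript-to-gene map, the truth tables, and a ready-to-run pipeline
#' config (`config.json`).
#'
#' @param config a `sim_config`.
#' @param outdir output directory (created if needed).
#' @return the path of the written pipeline config, invisibly.
#' @export
simulate_to_dir <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- gen_tss_dataset(config)
  ann <- gen_annotation(config, ds$truth)
  expr <- gen_expression_matrix(config)
  iso <- gen_isoform_profiles(config, expr$matrix)

  ctss_paths <- list()
  for (trk in ds$tracks) {
    p <- file.path(outdir, paste0(trk$sample_id, ".ctss.tsv"))
    write_ctss(trk, p)
    ctss_paths[[trk$sample_id]] <- basename(p)
  }
  write_design(sim_design(config), file.path(outdir, "design.tsv"))
  write_gtf(ann$annotation, file.path(outdir, "annotation.gtf"))
  set_paths <- list()
  for (nm in names(ann$gene_sets)) {
    p <- file.path(outdir, paste0("geneset_", nm, ".txt"))
    writeLines(ann$gene_sets[[nm]], p)
    set_paths[[nm]] <- basename(p)
  }
  write_expression_tsv(expr$matrix, file.path(outdir, "gene_tpm.tsv"))
  write_expression_tsv(iso$matrix, file.path(outdir, "transcript_tpm.tsv"))
  utils::write.table(data.frame(transcript_id = names(iso$tx2gene),
                                gene_id = unname(iso$tx2gene)),
                     file.path(outdir, "tx2gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth$promoters, file.path(outdir, "truth_promoters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(ds$truth$activity * 1L,
                   file.path(outdir, "truth_activity.tsv"), "promoter_id")
  utils::write.table(expr$truth, file.path(outdir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(iso$truth, file.path(outdir, "truth_isoforms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pipeline_cfg <- list(
    seed = config$seed,
    ctss = ctss_paths,
    design = "design.tsv",
    annotation = "annotation.gtf",
    gene_sets = set_paths,
    gene_matrix = "gene_tpm.tsv",
    transcript_matrix = "transcript_tpm.tsv",
    tx2gene = "tx2gene.tsv",
    outdir = "results",
    params = list()
  )
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(pipeline_cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(cfg_path)
}

#' Run the full TSR pipeline
#'
#' Chains CTSS loading, power-law normalization, density clustering, TSR
#' selection, consensus merging, presence/expression scoring, genomic
#' annotation, population-specific classification, gene-set enrichment,
#' mis-initiation rates and the leave-one-out analysis, writing all outputs
#' plus a checksummed run manifest.
#'
#' @param config JSON path or list (see [read_pipeline_config()]); requires
#'   keys `ctss` (named sample -> path), `design`, `annotation`, `outdir`;
#'   optional `gene_sets`, `features`, `params`.
#' @return the run manifest, invisibly.
#' @export
run_tsr_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  ctss <- cfg_path(config, "ctss")
  design_path <- cfg_path(config, "design")
  ann_path <- cfg_path(config, "annotation")
  outdir <- file.path(attr(config, "base"),
                      if (is.null(config$outdir)) "results" else config$outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  design <- stage_guard("design", read_design(design_path))
  pipeline_log("load", sprintf("%d CTSS inputs", length(ctss)))
  tracks <- stage_guard("build_track", {
    out <- lapply(names(ctss), function(s) read_ctss(ctss[[s]], sample_id = s))
    names(out) <- names(ctss)
    out
  })

  outputs <- list()
  norm_tracks <- stage_guard("normalize", lapply(tracks, function(trk) {
    fit <- fit_power_law(trk,
                         fit_min = cfg_param(config, "fit_min", 1),
                         fit_max = cfg_param(config, "fit_max", 1000),
                         ref_alpha = cfg_param(config, "ref_alpha", 1.25),
                         ref_total = cfg_param(config, "ref_total", 1e6))
    normalize_to_reference(trk, fit)
  }))
  for (trk in norm_tracks) {
    p <- file.path(outdir, paste0(trk$sample_id, ".normalized.ctss.tsv"))
    write_ctss(trk, p); outputs <- c(outputs, p)
  }

  pipeline_log("call-tsr", "clustering per sample")
  tsr_sets <- stage_guard("call_tsr", lapply(norm_tracks, function(trk) {
    select_tsrs(paraclu_track(trk), sample_id = trk$sample_id,
                min_signal = cfg_param(config, "min_signal", 2),
                max_span = cfg_param(config, "max_span", 20),
                min_stability = cfg_param(config, "min_stability", 1))
  }))
  for (ts in tsr_sets) {
    p <- file.path(outdir, paste0(ts$sample_id, ".tsr.bed"))
    write_tsr_bed(ts, p); outputs <- c(outputs, p)
  }

  consensus <- stage_guard("consensus",
    merge_consensus(tsr_sets, merge_gap = cfg_param(config, "merge_gap", 20)))
  consensus <- stage_guard("presence", score_presence(consensus, tsr_sets, norm_tracks))
  p <- file.path(outdir, "consensus.bed"); write_tsr_bed(consensus, p)
  outputs <- c(outputs, p)
  p <- file.path(outdir, "presence.tsv")
  write_matrix_tsv(consensus$presence * 1L, p); outputs <- c(outputs, p)
  p <- file.path(outdir, "expression.tsv")
  write_matrix_tsv(round(consensus$expression, 6), p); outputs <- c(outputs, p)
  pipeline_log("consensus", sprintf("%d consensus TSRs", nrow(consensus$tsrs)))

  annotation <- stage_guard("annotate", {
    ann <- read_gtf(ann_path)
    annotate_tsrs(consensus, ann,
                  promoter_window = unlist(cfg_param(config, "promoter_window",
                                                     c(-1000, 100))),
                  tts_window = unlist(cfg_param(config, "tts_window",
                                                c(-100, 1000))))
  })
  p <- file.path(outdir, "tsr_annotation.tsv")
  utils::write.table(annotation, p, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, p)

  labels <- stage_guard("classify",
    classify_population_specific(consensus$presence, design,
                                 min_support = cfg_param(config, "min_support", 2)))
  p <- file.path(outdir, "labels.tsv")
  utils::write.table(labels, p, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, p)
  pipeline_log("classify", sprintf("%d hi-specific, %d lo-specific",
                                   sum(labels$label == "hi_specific"),
                                   sum(labels$label == "lo_specific")))

  gene_set_paths <- cfg_path(config, "gene_sets", required = FALSE)
  if (!is.null(gene_set_paths)) {
    enrich_rows <- lapply(names(gene_set_paths), function(nm) {
      gs <- read_gene_set(gene_set_paths[[nm]])
      membership <- stats::setNames(annotation$nearest_gene_id %in% gs,
                                    annotation$id)
      er <- stage_guard("enrich", enrichment_odds_ratio(labels, membership))
      data.frame(gene_set = nm, a = er$table["a"], b = er$table["b"],
                 c = er$table["c"], d = er$table["d"],
                 odds_ratio = er$odds_ratio, ci_low = er$ci_low,
                 ci_high = er$ci_high, p = er$p)
    })
    p <- file.path(outdir, "enrichment.tsv")
    utils::write.table(do.call(rbind, enrich_rows), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p)
  }

  mis <- stage_guard("misinitiation", withCallingHandlers(
    misinitiation_rates(annotation, labels, consensus$presence, design,
                        promoter_like = unlist(cfg_param(config, "promoter_like",
                                                         "promoter"))),
    warning = function(w) {
      pipeline_log("misinitiation", "warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  p <- file.path(outdir, "misinitiation_rates.tsv")
  utils::write.table(mis$rates, p, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, p)

  loo <- stage_guard("loo", leave_one_out_specificity(consensus$presence))
  p <- file.path(outdir, "loo_fractions.tsv")
  write_matrix_tsv(round(loo$F, 6), p, "tissue"); outputs <- c(outputs, p)
  p <- file.path(outdir, "loo_zscores.tsv")
  write_matrix_tsv(round(loo$Z, 6), p, "tissue"); outputs <- c(outputs, p)

  manifest <- run_manifest(config,
                           inputs = c(ctss, design_path, ann_path,
                                      if (!is.null(gene_set_paths)) gene_set_paths),
                           outputs = outputs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log("done", sprintf("%d outputs in %s", length(outputs), outdir))
  invisible(manifest)
}

#' Run the expression-diversity pipeline
#'
#' Chains tau scoring with tissue binarization, expressed-fraction curves,
#' splicing entropy, and the transcripts-versus-genes regression; writes
#' outputs and a checksummed manifest.
#'
#' @param config JSON path or list; requires `gene_matrix`,
#'   `transcript_matrix`, `tx2gene`, `outdir`; optional `params`
#'   (`tpm_min`, `tau_min`, `thresholds`, `min_expressed_isoforms`).
#' @return the run manifest, invisibly.
#' @export
run_expression_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  gene_path <- cfg_path(config, "gene_matrix")
  tx_path <- cfg_path(config, "transcript_matrix")
  map_path <- cfg_path(config, "tx2gene")
  outdir <- file.path(attr(config, "base"),
                      if (is.null(config$outdir)) "results" else config$outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  gene_mat <- stage_guard("load", read_expression_tsv(gene_path, level = "gene"))
  map_df <- stage_guard("load", utils::read.table(map_path, header = TRUE,
                                                  sep = "\t",
                                                  colClasses = "character"))
  tx2gene <- stats::setNames(map_df$gene_id, map_df$transcript_id)
  tx_mat <- stage_guard("load", read_expression_tsv(tx_path, level = "transcript",
                                                    tx2gene = tx2gene))
  outputs <- list()

  tau <- stage_guard("tau", compute_tau(gene_mat,
                                        tpm_min = cfg_param(config, "tpm_min", 1),
                                        tau_min = cfg_param(config, "tau_min", 0.8)))
  p <- file.path(outdir, "tau.tsv")
  utils::write.table(tau, p, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, p)
  pipeline_log("tau", sprintf("%d features scored, %d TRAs", nrow(tau),
                              sum(tau$is_tra)))

  thresholds <- unlist(cfg_param(config, "thresholds", c(0.5, 1, 2)))
  ef_gene <- stage_guard("expressed_fraction",
                         expressed_fraction(gene_mat, thresholds))
  ef_tx <- stage_guard("expressed_fraction",
                       expressed_fraction(tx_mat, thresholds))
  ef_gene$level <- "gene"; ef_tx$level <- "transcript"
  p <- file.path(outdir, "expressed_fraction.tsv")
  utils::write.table(rbind(ef_gene, ef_tx), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outputs <- c(outputs, p)

  ent <- stage_guard("entropy", splicing_entropy(
    tx_mat, min_expressed_isoforms = cfg_param(config, "min_expressed_isoforms", 2)))
  p <- file.path(outdir, "splicing_entropy.tsv")
  utils::write.table(ent$per_gene, p, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, p)
  p <- file.path(outdir, "entropy_medians.tsv")
  utils::write.table(data.frame(column = names(ent$column_medians),
                                median_entropy_bits = as.numeric(ent$column_medians)),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, p)

  fit_threshold <- cfg_param(config, "fit_threshold", 1)
  ref <- stage_guard("tg_fit", {
    eg <- expressed_fraction(gene_mat, fit_threshold)
    et <- expressed_fraction(tx_mat, fit_threshold)
    data.frame(n_genes = eg$n_expressed[match(colnames(gene_mat$tpm), eg$column)],
               n_transcripts = et$n_expressed[match(colnames(gene_mat$tpm),
                                                    et$column)])
  })
  fit <- stage_guard("tg_fit",
                     transcripts_vs_genes_fit(ref, query_points = ref$n_genes))
  p <- file.path(outdir, "transcripts_vs_genes.tsv")
  utils::write.table(cbind(column = colnames(gene_mat$tpm), ref,
                           fit$predictions[, -1]),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, p)
  pipeline_log("tg_fit", sprintf("slope %.3f intercept %.1f", fit$slope,
                                 fit$intercept))

  manifest <- run_manifest(config, inputs = list(gene_path, tx_path, map_path),
                           outputs = outputs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest_expr.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
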