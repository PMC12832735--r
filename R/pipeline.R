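#' Build an analysis configuration
#'
#' A validated bag of paths and parameters driving the pipeline stages.
#' Configurations may also be loaded from a YAML file with the same keys.
#'
#' @param counts_a,counts_b paths to the two cohorts' count tables.
#' @param gmt path to the gene-set collection (GMT).
#' @param annotation optional path to the feature annotation table.
#' @param ct,mirna optional paths to the qPCR Ct table and miRNA panel.
#' @param mapping optional path to the mapping-stats table.
#' @param k top-K cutoff (default 1000).
#' @param detect_threshold detection threshold for composition summaries.
#' @param ct_min,ct_max qPCR calling window (defaults 18, 35).
#' @param mirna_cutoff miRNA low-expression cutoff (default 100).
#' @param out_dir output directory for reports.
#' @param source_a,source_b cohort labels.
#' @return a list of class `ev_config`.
#' @export
analysis_config <- function(counts_a = NULL, counts_b = NULL, gmt = NULL,
                            annotation = NULL, ct = NULL, mirna = NULL,
                            mapping = NULL, k = 1000L,
                            detect_threshold = 1, ct_min = 18, ct_max = 35,
                            mirna_cutoff = 100, out_dir = ".",
                            source_a = "salEV", source_b = "bEV") {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  cfg <- list(counts_a = counts_a, counts_b = counts_b, gmt = gmt,
              annotation = annotation, ct = ct, mirna = mirna,
              mapping = mapping, k = as.integer(k),
              detect_threshold = detect_threshold,
              ct_min = ct_min, ct_max = ct_max,
              mirna_cutoff = mirna_cutoff, out_dir = out_dir,
              source_a = source_a, source_b = source_b)
  for (key in c("counts_a", "counts_b", "gmt", "annotation", "ct", "mirna",
                "mapping")) {
    path <- cfg[[key]]
    if (!is.null(path) && !file.exists(path))
      stop("config path for '", key, "' does not exist: ", path,
           call. = FALSE)
  }
  class(cfg) <- "ev_config"
  cfg
}

#' @rdname analysis_config
#' @param path YAML file whose keys match the `analysis_config()` arguments.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

log_msg <- function(...) message(sprintf(...))

config_provenance <- function(config) {
  prov <- unclass(config)
  prov[vapply(prov, is.null, logical(1L))] <- NULL
  prov
}

#' Run the cross-source comparison pipeline
#'
#' Reads both count tables and the gene-set collection, harmonizes IDs,
#' computes per-source mean log abundances and top-K sets, and writes the
#' representation table (`representation.tsv` + `representation.json`),
#' the ranked top-K sets, and a dropped-ID report. Each report embeds the
#' configuration used.
#'
#' @param config an [analysis_config()] object with `counts_a`,
#'   `counts_b` and `gmt` set.
#' @return the `ev_representation` table, invisibly.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "ev_config"))
  for (key in c("counts_a", "counts_b", "gmt"))
    if (is.null(config[[key]]))
      stop("run_compare requires config key '", key, "'", call. = FALSE)
  gs <- stage("read_gmt", read_gmt(config$gmt))
  ann <- if (!is.null(config$annotation))
    stage("read_annotation", read_annotation(config$annotation)) else NULL
  ca <- stage("read_counts_a",
              read_count_matrix(config$counts_a, config$source_a))
  cb <- stage("read_counts_b",
              read_count_matrix(config$counts_b, config$source_b))
  log_msg("compare: %d x %d (%s) vs %d x %d (%s), K = %d",
          nrow(ca$counts), ncol(ca$counts), ca$source_label,
          nrow(cb$counts), ncol(cb$counts), cb$source_label, config$k)
  drop_a <- harmonize_ids(rownames(ca$counts), ann)$n_dropped
  drop_b <- harmonize_ids(rownames(cb$counts), ann)$n_dropped
  if (drop_a + drop_b > 0)
    log_msg("compare: dropped IDs during harmonization: %d (%s), %d (%s)",
            drop_a, config$source_a, drop_b, config$source_b)
  rep <- stage("compare_topk",
               compare_topk(ca, cb, gs, ann, k = config$k))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_representation(rep, p("representation.tsv"),
                       p("representation.json"))
  tk <- attr(rep, "topk")
  write_topk(tk$a, p(sprintf("topk_%s.tsv", config$source_a)))
  write_topk(tk$b, p(sprintf("topk_%s.tsv", config$source_b)))
  jsonlite::write_json(
    list(config = config_provenance(config),
         dropped_ids = list(a = drop_a, b = drop_b),
         table = as.data.frame(rep)),
    p("compare_report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}

#' Run the presence-calling pipeline
#'
#' Runs qPCR presence calling and/or miRNA background filtering, whichever
#' inputs the configuration provides, and writes TSV reports plus a
#' combined `presence_report.json` embedding the configuration. At least
#' one of `ct` or `mirna` must be configured.
#'
#' @param config an [analysis_config()] object.
#' @return a list with `presence`, `summary`, `mirna` (those that ran),
#'   invisibly.
#' @export
run_presence <- function(config) {
  stopifnot(inherits(config, "ev_config"))
  if (is.null(config$ct) && is.null(config$mirna))
    stop("run_presence requires a Ct table and/or a miRNA table",
         call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  out <- list()
  report <- list(config = config_provenance(config))
  if (!is.null(config$ct)) {
    ct <- stage("read_ct_table", read_ct_table(config$ct))
    pres <- stage("qpcr_presence_call",
                  qpcr_presence_call(ct, config$ct_min, config$ct_max))
    smry <- presence_summary(pres)
    log_msg("presence: %d genes x %d samples; %d present in >= 1 sample",
            nrow(pres), ncol(pres), smry$n_genes[smry$min_samples == 1L])
    write_presence(pres, p("presence.tsv"))
    out$presence <- pres
    out$summary <- smry
    report$qpcr <- list(universe = attr(smry, "universe"),
                        ct_window = c(config$ct_min, config$ct_max),
                        thresholds = as.data.frame(smry))
  }
  if (!is.null(config$mirna)) {
    tab <- stage("read_mirna_table", read_mirna_table(config$mirna))
    expr <- stage("mirna_expression_filter",
                  mirna_expression_filter(tab, config$mirna_cutoff))
    log_msg("presence: %d of %d miRNAs above background %.1f",
            expr$n_expressed, nrow(expr$table), expr$background)
    write_mirna_report(expr, p("mirna_report.tsv"))
    out$mirna <- expr
    report$mirna <- list(n_assayed = nrow(expr$table),
                         n_expressed = expr$n_expressed,
                         background = expr$background,
                         low_cutoff = expr$low_cutoff,
                         top = expr$top)
  }
  jsonlite::write_json(report, p("presence_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
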