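#' Per-sample transcript-biotype composition
#'
#' A feature is detected in a sample when its count reaches
#' `detect_threshold` (default 1 read). Detected features are tallied by
#' biotype per sample; per-sample percentages are then averaged across the
#' cohort. Features missing from the annotation are binned as "other" and
#' counted in the `n_unannotated` attribute with a warning.
#'
#' Two cohort-level conventions are reported because they genuinely differ:
#' `mean_percent` (mean of per-sample percentages) and `pooled_percent`
#' (ratio of summed counts). The mean of per-sample ratios need not equal
#' the ratio of means.
#'
#' @param counts an [count_matrix()] object.
#' @param annotation an [feature_annotation()] object.
#' @param detect_threshold minimum count for a feature to be called
#'   detected in a sample (default 1).
#' @return a list of class `ev_composition`: `per_sample` (data.frame:
#'   sample, biotype, n_detected, percent — percent is `NA` for an
#'   all-zero sample), `totals` (named vector of per-sample detected
#'   totals), and `summary` (data.frame: biotype, mean_n, mean_percent,
#'   pooled_percent), plus `mean_total`.
#' @export
biotype_composition <- function(counts, annotation, detect_threshold = 1) {
  stopifnot(inherits(counts, "ev_counts"),
            inherits(annotation, "ev_annotation"))
  m <- counts$counts
  bt <- annotation$biotype[match(rownames(m), annotation$feature_id)]
  n_unannot <- sum(is.na(bt))
  if (n_unannot > 0L) {
    warning(n_unannot, " unannotated feature(s) binned as 'other'",
            call. = FALSE)
    bt[is.na(bt)] <- "other"
  }
  bt <- factor(bt, levels = BIOTYPE_VOCAB)
  det <- m >= detect_threshold
  per <- do.call(rbind, lapply(colnames(m), function(s) {
    tab <- tapply(det[, s], bt, sum)
    tab[is.na(tab)] <- 0L
    tot <- sum(tab)
    data.frame(sample = s, biotype = BIOTYPE_VOCAB,
               n_detected = as.integer(tab[BIOTYPE_VOCAB]),
               percent = if (tot > 0) 100 * as.numeric(tab[BIOTYPE_VOCAB]) / tot
                         else rep(NA_real_, length(BIOTYPE_VOCAB)),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  totals <- tapply(per$n_detected, per$sample, sum)[colnames(m)]
  pooled <- tapply(per$n_detected, per$biotype, sum)[BIOTYPE_VOCAB]
  smry <- data.frame(
    biotype = BIOTYPE_VOCAB,
    mean_n = as.numeric(tapply(per$n_detected, per$biotype,
                               mean)[BIOTYPE_VOCAB]),
    mean_percent = as.numeric(tapply(per$percent, per$biotype, mean,
                                     na.rm = TRUE)[BIOTYPE_VOCAB]),
    pooled_percent = if (sum(pooled) > 0)
      100 * as.numeric(pooled) / sum(pooled) else NA_real_,
    stringsAsFactors = FALSE)
  structure(list(per_sample = per, totals = totals, summary = smry,
                 mean_total = mean(totals), n_unannotated = n_unannot,
                 detect_threshold = detect_threshold),
            class = "ev_composition")
}

#' @export
print.ev_composition <- function(x, ...) {
  cat(sprintf("Biotype composition: %d samples, mean %.0f detected features\n",
              length(x$totals), x$mean_total))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write composition TSV (sample, biotype, count, percent) + summary JSON
#' @param x an `ev_composition` object.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @export
write_composition <- function(x, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(x$per_sample, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(mean_total = x$mean_total, detect_threshold = x$detect_threshold,
           summary = x$summary),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(x)
}

#' Total-mapped read summary
#'
#' Total mapped percent per sample is the sum of uniquely-mapped and
#' multi-mapped percents (reads mapping anywhere in the genome). In
#' raw-count mode percentages are derived from the category counts first.
#'
#' @param stats an `ev_mapstats` object (see [mapping_stats()]).
#' @return a list of class `ev_mapping_summary`: `per_sample` (data.frame:
#'   sample, unique_pct, multi_pct, total_pct) and `mean` (named vector
#'   with the three cohort averages).
#' @export
mapping_summary <- function(stats) {
  stopifnot(inherits(stats, "ev_mapstats"))
  if (attr(stats, "mode") == "counts") {
    tot <- stats$unique_reads + stats$multi_reads + stats$unmapped_reads
    if (any(tot == 0))
      stop("sample with zero total reads: ",
           stats$sample[tot == 0][1L], call. = FALSE)
    uq <- 100 * stats$unique_reads / tot
    mu <- 100 * stats$multi_reads / tot
  } else {
    uq <- stats$unique_pct
    mu <- stats$multi_pct
  }
  per <- data.frame(sample = stats$sample, unique_pct = uq, multi_pct = mu,
                    total_pct = uq + mu, stringsAsFactors = FALSE)
  structure(list(per_sample = per,
                 mean = c(unique_pct = mean(uq), multi_pct = mean(mu),
                          total_pct = mean(uq + mu))),
            class = "ev_mapping_summary")
}

#' @export
print.ev_mapping_summary <- function(x, ...) {
  cat(sprintf(
    "Read mapping over %d samples: mean %.1f%% unique + %.1f%% multi = %.1f%% mapped\n",
    nrow(x$per_sample), x$mean["unique_pct"], x$mean["multi_pct"],
    x$mean["total_pct"]))
  invisible(x)
}
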