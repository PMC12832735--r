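#' Presence calls from duplicate-run qPCR Ct values
#'
#' A gene is called present in a sample when its cycle-threshold value
#' falls inside the assay's dynamic range (default Ct in \[18, 35\],
#' inclusive) in *both* duplicate runs. A missing replicate — including
#' "Undetermined" wells, stored as `NA` — makes the call absent.
#'
#' @param ct an `ev_ct` table (see [ct_table()]).
#' @param ct_min,ct_max inclusive dynamic-range bounds (defaults 18 and 35).
#' @return a logical gene-by-sample matrix of class `ev_presence`, defined
#'   for every gene and sample occurring in the input; attributes record
#'   the Ct window used.
#' @export
qpcr_presence_call <- function(ct, ct_min = 18, ct_max = 35) {
  stopifnot(inherits(ct, "ev_ct"))
  if (ct_min > ct_max) stop("ct_min must not exceed ct_max", call. = FALSE)
  genes <- sort(unique(ct$gene))
  samples <- sort(unique(ct$sample))
  ok <- !is.na(ct$ct) & ct$ct >= ct_min & ct$ct <= ct_max
  # a (gene, sample) is present iff both replicate wells exist and pass
  pass <- matrix(0L, length(genes), length(samples),
                 dimnames = list(genes, samples))
  idx <- cbind(match(ct$gene, genes), match(ct$sample, samples))
  for (i in which(ok)) pass[idx[i, 1L], idx[i, 2L]] <-
      pass[idx[i, 1L], idx[i, 2L]] + 1L
  pres <- pass == 2L
  structure(pres, ct_min = ct_min, ct_max = ct_max,
            class = c("ev_presence", class(pres)))
}

#' Summarize presence calls across samples
#'
#' For each threshold m, the number and percent of genes called present in
#' at least m samples, over the full assay universe (all genes on the
#' array). Display percents are rounded to the nearest integer.
#'
#' @param p an `ev_presence` matrix (see [qpcr_presence_call()]), or any
#'   logical gene-by-sample matrix.
#' @param thresholds integer vector of minimum-sample thresholds
#'   (default `c(1, 10)`).
#' @return a data.frame of class `ev_presence_summary` with columns
#'   `min_samples`, `n_genes`, `percent` (full precision),
#'   `percent_display`; attribute `universe` holds the gene universe size.
#' @export
presence_summary <- function(p, thresholds = c(1L, 10L)) {
  if (!is.matrix(p) || !is.logical(p))
    stop("p must be a logical gene-by-sample matrix", call. = FALSE)
  thresholds <- as.integer(thresholds)
  n_per_gene <- rowSums(p)
  universe <- nrow(p)
  n <- vapply(thresholds, function(m) sum(n_per_gene >= m), integer(1L))
  pct <- if (universe > 0) 100 * n / universe else rep(0, length(n))
  structure(data.frame(min_samples = thresholds, n_genes = n,
                       percent = pct, percent_display = round(pct),
                       stringsAsFactors = FALSE),
            universe = universe,
            class = c("ev_presence_summary", "data.frame"))
}

#' @export
print.ev_presence_summary <- function(x, ...) {
  cat(sprintf("Assay universe: %d genes\n", attr(x, "universe")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  detected in >= %d sample(s): %d genes (%d%%)\n",
                x$min_samples[i], x$n_genes[i], x$percent_display[i]))
  invisible(x)
}

#' Background filtering of a miRNA count panel
#'
#' Hybridization panels carry negative-control probes that define the
#' technical background. The background threshold is mean + 2*SD of the
#' control counts within each sample, averaged across samples; a miRNA is
#' called expressed when its mean count across samples exceeds that
#' threshold (strictly). Expressed miRNAs whose mean count does not exceed
#' `low_cutoff` are additionally flagged as low-expression.
#'
#' @param x an `ev_mirna` table (see [mirna_table()]).
#' @param low_cutoff low-expression cutoff on the mean count (default 100;
#'   a mean strictly above it clears the flag).
#' @param n_top number of top expressed miRNAs in the ranked report
#'   (default 20).
#' @return a list of class `ev_mirna_expressed`: `table` (data.frame: id,
#'   mean_count, expressed, low_flag, rank — rank by mean count among
#'   expressed miRNAs, `NA` otherwise), `background` (the averaged
#'   threshold), `per_sample_background`, `n_expressed`, and `top`
#'   (the head of the expressed ranking).
#' @export
mirna_expression_filter <- function(x, low_cutoff = 100, n_top = 20L) {
  stopifnot(inherits(x, "ev_mirna"))
  ctrl <- x$counts[x$is_control, , drop = FALSE]
  bg_per_sample <- apply(ctrl, 2L, function(v) mean(v) + 2 * stats::sd(v))
  if (nrow(ctrl) == 1L) bg_per_sample <- colMeans(ctrl)  # sd undefined
  background <- mean(bg_per_sample)
  assay <- x$counts[!x$is_control, , drop = FALSE]
  mean_count <- rowMeans(assay)
  expressed <- mean_count > background
  low_flag <- expressed & mean_count <= low_cutoff
  rank <- rep(NA_integer_, length(mean_count))
  ord <- order(-mean_count[expressed], names(mean_count)[expressed],
               method = "radix")
  rank[which(expressed)[ord]] <- seq_len(sum(expressed))
  tab <- data.frame(id = names(mean_count), mean_count = unname(mean_count),
                    expressed = unname(expressed),
                    low_flag = unname(low_flag), rank = rank,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  top <- tab[!is.na(tab$rank), , drop = FALSE]
  top <- top[order(top$rank), , drop = FALSE][seq_len(min(n_top, nrow(top))), ,
                                              drop = FALSE]
  structure(list(table = tab, background = background,
                 per_sample_background = bg_per_sample,
                 n_expressed = sum(expressed), low_cutoff = low_cutoff,
                 top = top),
            class = "ev_mirna_expressed")
}

#' @export
print.ev_mirna_expressed <- function(x, ...) {
  cat(sprintf(
    "miRNA panel: %d of %d assayed miRNAs expressed above background (%.1f)\n",
    x$n_expressed, nrow(x$table), x$background))
  if (nrow(x$top) > 0L) {
    cat(sprintf("top %d mean count: %.1f\n", nrow(x$top),
                mean(x$top$mean_count)))
  }
  invisible(x)
}

#' Write presence and miRNA reports
#'
#' @param p an `ev_presence` matrix.
#' @param path output TSV path (gene-by-sample 0/1 table).
#' @export
write_presence <- function(p, path) {
  df <- data.frame(gene = rownames(p), unclass(p) + 0L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence
#' @param x an `ev_mirna_expressed` result.
#' @export
write_mirna_report <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
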