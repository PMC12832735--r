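#' Per-feature mean log abundance
#'
#' The ranking statistic for cross-source comparison: for feature g with
#' counts x_g1..x_gn over the cohort's n samples,
#' mu_g = (1/n) * sum_i log(x_gi + 1). Natural log by default; the induced
#' ranking is invariant to the log base. Scores are zero exactly for
#' features with zero counts in every sample.
#'
#' @param counts an [count_matrix()] object.
#' @param base log base (default `exp(1)`; ranking is base-invariant).
#' @param normalize if `TRUE`, counts are first scaled per sample to the
#'   mean library size. Off by default: raw counts enter the statistic.
#' @return an object of class `ev_abundance`: a list with `scores` (named
#'   numeric, one per feature), `n_samples`, and `source_label`.
#' @examples
#' m <- matrix(c(1, 3, 7), nrow = 1, dimnames = list("g1", paste0("s", 1:3)))
#' log_mean_abundance(count_matrix(m))$scores  # ln(2*4*8)/3 = ln 4
#' @export
log_mean_abundance <- function(counts, base = exp(1), normalize = FALSE) {
  stopifnot(inherits(counts, "ev_counts"))
  m <- counts$counts
  if (ncol(m) == 0L) stop("no samples", call. = FALSE)
  if (normalize) {
    libs <- colSums(m)
    if (any(libs == 0))
      stop("cannot library-size normalize a sample with zero total counts",
           call. = FALSE)
    m <- sweep(m, 2L, libs / mean(libs), "/")
  }
  # row sum then double-precision division: bit-reproducible against a
  # plain per-feature sum(log(x + 1)) / n, so equal count multisets tie
  scores <- rowSums(log(m + 1, base = base)) / ncol(m)
  structure(list(scores = scores, n_samples = ncol(m),
                 source_label = counts$source_label),
            class = "ev_abundance")
}

#' @export
print.ev_abundance <- function(x, ...) {
  cat(sprintf("Mean log abundance [%s]: %d features over %d samples\n",
              x$source_label, length(x$scores), x$n_samples))
  invisible(x)
}

#' Top-K highly-represented feature set
#'
#' The K features with largest mean log abundance in one source. Ties at
#' the boundary are broken by lexicographic feature ID (ascending, C
#' collation) so results are identical across platforms.
#'
#' @param scores an [log_mean_abundance()] result, or a named numeric
#'   vector of scores.
#' @param k number of features to keep (default 1000); if fewer features
#'   exist, all are returned.
#' @return a data.frame of class `ev_topk` with columns `rank`,
#'   `feature_id`, `score`, and attributes `k` and `source_label`.
#' @export
top_k_features <- function(scores, k = 1000L) {
  src <- "unlabeled"
  if (inherits(scores, "ev_abundance")) {
    src <- scores$source_label
    scores <- scores$scores
  }
  if (is.null(names(scores))) stop("scores must be named", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  ord <- order(-scores, names(scores), method = "radix")
  keep <- ord[seq_len(min(k, length(scores)))]
  structure(data.frame(rank = seq_along(keep),
                       feature_id = names(scores)[keep],
                       score = unname(scores[keep]),
                       stringsAsFactors = FALSE),
            k = k, source_label = src, class = c("ev_topk", "data.frame"))
}

#' Write a ranked top-K set as TSV (rank, feature_id, score)
#' @param topk an `ev_topk` object.
#' @param path output path.
#' @export
write_topk <- function(topk, path) {
  utils::write.table(as.data.frame(topk), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Cross-sample top-K recurrence within a biotype
#'
#' For each sample separately, features of the requested biotype are ranked
#' by that sample's raw count (ties broken lexicographically by ID); a
#' feature is recurrent when it falls in the per-sample top K in at least
#' `min_fraction` of samples. This reproduces analyses of the form "16
#' lncRNAs were among the top 20 in at least half of the samples".
#'
#' @param counts an [count_matrix()] object.
#' @param annotation an [feature_annotation()] object.
#' @param biotype one of the biotype vocabulary entries.
#' @param k per-sample rank cutoff (default 20).
#' @param min_fraction minimum fraction of samples (in (0, 1\]) in whose
#'   top K the feature must appear (default 0.5).
#' @return a data.frame with columns `feature_id`, `n_topk` (samples in
#'   whose top K the feature appears), `fraction`, `recurrent`; ordered by
#'   decreasing fraction then ID, restricted to features seen in at least
#'   one sample's top K.
#' @export
topk_recurrence <- function(counts, annotation, biotype, k = 20L,
                            min_fraction = 0.5) {
  stopifnot(inherits(counts, "ev_counts"),
            inherits(annotation, "ev_annotation"))
  if (!biotype %in% BIOTYPE_VOCAB)
    stop("unknown biotype: ", biotype, call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must lie in (0, 1]", call. = FALSE)
  keep <- annotation$feature_id[annotation$biotype == biotype]
  m <- counts$counts[rownames(counts$counts) %in% keep, , drop = FALSE]
  if (nrow(m) == 0L)
    return(data.frame(feature_id = character(0), n_topk = integer(0),
                      fraction = numeric(0), recurrent = logical(0)))
  hits <- integer(nrow(m))
  names(hits) <- rownames(m)
  for (j in seq_len(ncol(m))) {
    ord <- order(-m[, j], rownames(m), method = "radix")
    top <- rownames(m)[ord[seq_len(min(k, nrow(m)))]]
    hits[top] <- hits[top] + 1L
  }
  frac <- hits / ncol(m)
  res <- data.frame(feature_id = names(hits), n_topk = unname(hits),
                    fraction = unname(frac),
                    recurrent = unname(frac >= min_fraction),
                    stringsAsFactors = FALSE)
  res <- res[res$n_topk > 0L, , drop = FALSE]
  res <- res[order(-res$fraction, res$feature_id, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
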