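# Fixtures built in code; no files shipped.

toy_counts <- function(values = c(0, 1, 2, 3, 4, 5), nrow = 3,
                       source_label = "salEV") {
  m <- matrix(values, nrow = nrow, byrow = TRUE)
  rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  count_matrix(m, source_label)
}

random_counts <- function(n_feat, n_samp, source_label = "x",
                          lambda = 20) {
  m <- matrix(stats::rpois(n_feat * n_samp, lambda), n_feat, n_samp)
  rownames(m) <- sprintf("f%03d", seq_len(n_feat))
  colnames(m) <- sprintf("s%02d", seq_len(n_samp))
  count_matrix(m, source_label)
}

toy_annotation <- function(ids, biotypes = NULL) {
  if (is.null(biotypes))
    biotypes <- rep_len(c("protein_coding", "lncRNA"), length(ids))
  feature_annotation(ids, biotypes, paste0("SYM_", ids))
}

# a top-K set built directly from a character vector (bypasses scoring)
as_topk <- function(ids, k = length(ids), source_label = "A") {
  structure(data.frame(rank = seq_along(ids), feature_id = ids,
                       score = rev(seq_along(ids)),
                       stringsAsFactors = FALSE),
            k = as.integer(k), source_label = source_label,
            class = c("ev_topk", "data.frame"))
}

toy_genesets <- function(sets, names = NULL) {
  if (is.null(names)) names <- stats::setNames(names(sets), names(sets))
  structure(sets, pathway_names = names, class = "ev_genesets")
}

# independent exact-test oracle: exhaustive hypergeometric enumeration of
# 2x2 tables with fixed margins (row totals k, k; column total m)
fisher_oracle <- function(count_a, count_b, k) {
  m <- count_a + count_b
  xs <- max(0L, m - k):min(k, m)
  logp <- lchoose(k, xs) + lchoose(k, m - xs) - lchoose(2 * k, m)
  p <- exp(logp)
  p_obs <- p[xs == count_a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}
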