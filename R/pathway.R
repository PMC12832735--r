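#' Pathway members inside a top-K set
#'
#' Size of the intersection between one source's top-K feature set and a
#' pathway gene set, after harmonizing both to a common namespace.
#'
#' @param topk an `ev_topk` object (see [top_k_features()]) or a character
#'   vector of feature IDs.
#' @param geneset character vector of pathway member genes (non-empty).
#' @param annotation optional [feature_annotation()] used to map both sides
#'   to gene symbols via [harmonize_ids()].
#' @return integer count of pathway members in the top-K set.
#' @export
members_in_topk <- function(topk, geneset, annotation = NULL) {
  if (inherits(topk, "ev_topk")) topk <- topk$feature_id
  geneset <- unique(as.character(geneset))
  if (length(geneset) == 0L) stop("empty gene set", call. = FALSE)
  ids <- harmonize_ids(topk, annotation)$ids
  gs <- harmonize_ids(geneset, annotation = NULL)$ids
  length(intersect(unique(ids), unique(gs)))
}

percent_of <- function(count, size) 100 * count / size

## one-decimal display rounding; R's round() is round-half-even
format_pct1 <- function(p) round(p, 1L)

#' Representation of gene sets in two sources' top-K sets
#'
#' The core cross-source comparison: for each pathway of size k, the number
#' and percent of its genes found in each source's top-K set. Because
#' absolute expression levels are not comparable across cohorts profiled
#' under different conditions, only top-K *composition* is contrasted.
#'
#' @param topk_a,topk_b `ev_topk` objects for the two sources, built with
#'   the same K.
#' @param genesets an `ev_genesets` collection (see [read_gmt()]).
#' @param annotation optional [feature_annotation()] for symbol mapping.
#' @param universe_a,universe_b optional character vectors of all measured
#'   feature IDs per source, used to report how many pathway members were
#'   measurable at all ("measured members"); percentages always use the
#'   full pathway size as denominator.
#' @return a data.frame of class `ev_representation` with columns
#'   `pathway_id`, `pathway_name`, `count_a`, `percent_a`, `count_b`,
#'   `percent_b`, `pathway_size`, `measured_a`, `measured_b`. Percent
#'   columns hold full precision; [print()] displays them rounded to one
#'   decimal. Attributes: `k`, `source_a`, `source_b`.
#' @export
representation_table <- function(topk_a, topk_b, genesets,
                                 annotation = NULL,
                                 universe_a = NULL, universe_b = NULL) {
  ka <- attr(topk_a, "k"); kb <- attr(topk_b, "k")
  if (!is.null(ka) && !is.null(kb) && ka != kb)
    stop("top-K sets built with different K (", ka, " vs ", kb, ")",
         call. = FALSE)
  harmo <- function(x) if (is.null(x)) NULL else
    unique(harmonize_ids(x, annotation)$ids)
  ua <- harmo(universe_a); ub <- harmo(universe_b)
  rows <- lapply(names(genesets), function(pid) {
    gs <- harmonize_ids(genesets[[pid]])$ids
    size <- length(unique(gs))
    ca <- members_in_topk(topk_a, genesets[[pid]], annotation)
    cb <- members_in_topk(topk_b, genesets[[pid]], annotation)
    data.frame(pathway_id = pid,
               pathway_name = unname(attr(genesets, "pathway_names")[pid]),
               count_a = ca, percent_a = percent_of(ca, size),
               count_b = cb, percent_b = percent_of(cb, size),
               pathway_size = size,
               measured_a = if (is.null(ua)) NA_integer_ else
                 length(intersect(unique(gs), ua)),
               measured_b = if (is.null(ub)) NA_integer_ else
                 length(intersect(unique(gs), ub)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            k = if (is.null(ka)) kb else ka,
            source_a = attr(topk_a, "source_label") %||% "A",
            source_b = attr(topk_b, "source_label") %||% "B",
            class = c("ev_representation", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare the top-K cargo composition of two cohorts
#'
#' High-level entry point: computes each source's mean log abundance,
#' extracts the top-K sets, and tabulates gene-set representation. This is
#' the full cross-source pipeline over validated in-memory objects.
#'
#' @param counts_a,counts_b [count_matrix()] objects for the two sources.
#' @param genesets an `ev_genesets` collection.
#' @param annotation optional [feature_annotation()].
#' @param k top-K cutoff (default 1000).
#' @param normalize optional per-sample library-size scaling before the
#'   log-mean (off by default; raw counts match the published statistic).
#' @return an `ev_representation` table (see [representation_table()]);
#'   attribute `topk` holds the two `ev_topk` sets.
#' @examples
#' sim <- simulate_study(simulation_config(n_genes = 300, seed = 1))
#' fit <- compare_topk(sim$counts_a, sim$counts_b, sim$genesets,
#'                     sim$annotation, k = 50)
#' print(fit)
#' @export
compare_topk <- function(counts_a, counts_b, genesets, annotation = NULL,
                         k = 1000L, normalize = FALSE) {
  ta <- top_k_features(log_mean_abundance(counts_a, normalize = normalize), k)
  tb <- top_k_features(log_mean_abundance(counts_b, normalize = normalize), k)
  rep <- representation_table(ta, tb, genesets, annotation,
                              universe_a = rownames(counts_a$counts),
                              universe_b = rownames(counts_b$counts))
  attr(rep, "topk") <- list(a = ta, b = tb)
  rep
}

#' @export
print.ev_representation <- function(x, ...) {
  cat(sprintf("Top-%s gene-set representation: %s vs %s\n",
              attr(x, "k") %||% "K", attr(x, "source_a"), attr(x, "source_b")))
  df <- data.frame(
    pathway = x$pathway_id, name = x$pathway_name,
    a = sprintf("%d (%.1f)", x$count_a, format_pct1(x$percent_a)),
    b = sprintf("%d (%.1f)", x$count_b, format_pct1(x$percent_b)),
    size = x$pathway_size, stringsAsFactors = FALSE)
  names(df)[3:4] <- c(paste0(attr(x, "source_a"), " (%)"),
                      paste0(attr(x, "source_b"), " (%)"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ev_representation <- function(object, ...) {
  d <- object$percent_a - object$percent_b
  cat(sprintf("%d gene sets; K = %s\n", nrow(object), attr(object, "k")))
  cat(sprintf("percent difference (%s - %s): mean %.1f, range [%.1f, %.1f]\n",
              attr(object, "source_a"), attr(object, "source_b"),
              mean(d), min(d), max(d)))
  cat(sprintf("sets more represented in %s: %d of %d\n",
              attr(object, "source_a"), sum(d > 0), nrow(object)))
  invisible(object)
}

#' @export
plot.ev_representation <- function(x, ...) {
  m <- t(as.matrix(x[, c("percent_a", "percent_b")]))
  graphics::barplot(m, beside = TRUE, names.arg = x$pathway_id,
                    ylab = "% of pathway in top-K",
                    legend.text = c(attr(x, "source_a"), attr(x, "source_b")),
                    las = 2, ...)
  invisible(x)
}

#' Write a representation table (display TSV + full-precision JSON)
#'
#' The TSV mirrors the published column order: pathway ID, name, source-A
#' "count (percent)", source-B "count (percent)", pathway size. The JSON
#' twin carries unrounded percents plus the measured-members columns.
#'
#' @param x an `ev_representation` object.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_representation <- function(x, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- data.frame(
      pathway_id = x$pathway_id, pathway_name = x$pathway_name,
      source_a = sprintf("%d (%.1f)", x$count_a, format_pct1(x$percent_a)),
      source_b = sprintf("%d (%.1f)", x$count_b, format_pct1(x$percent_b)),
      pathway_size = x$pathway_size, stringsAsFactors = FALSE)
    names(df)[3:4] <- c(attr(x, "source_a"), attr(x, "source_b"))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(k = attr(x, "k"), source_a = attr(x, "source_a"),
           source_b = attr(x, "source_b"),
           table = as.data.frame(x)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(x)
}

#' Exact test for a difference in top-K representation
#'
#' An extension beyond the published descriptive comparison (and off by
#' default in pipeline reports): Fisher's exact test on the 2x2 table of
#' pathway members in/out of the top-K set in each source, plus the raw
#' difference in proportions.
#'
#' @param count_a,count_b pathway members in the top-K set per source.
#' @param k pathway size (> 0); both counts must lie in \[0, k\].
#' @return list with `difference` (prop_a - prop_b) and `p_value`
#'   (two-sided).
#' @export
proportion_test <- function(count_a, count_b, k) {
  if (k <= 0) stop("pathway size k must be positive", call. = FALSE)
  if (count_a < 0 || count_a > k || count_b < 0 || count_b > k)
    stop("counts must lie in [0, k]", call. = FALSE)
  tab <- matrix(c(count_a, k - count_a, count_b, k - count_b), nrow = 2L,
                byrow = TRUE)
  list(difference = (count_a - count_b) / k,
       p_value = stats::fisher.test(tab)$p.value)
}
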