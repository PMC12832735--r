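#' @keywords internal
"_PACKAGE"

## Controlled biotype vocabulary. Features outside it are binned as "other".
BIOTYPE_VOCAB <- c("protein_coding", "lncRNA", "pseudogene", "other")

#' Construct a validated count matrix
#'
#' A count matrix holds non-negative (possibly fractional, e.g. after
#' multi-mapping reassignment) feature-by-sample counts for one EV source
#' (cohort), e.g. saliva-derived ("salEV") or blood-derived ("bEV") vesicles.
#'
#' @param counts numeric matrix, features in rows, samples in columns; must
#'   carry unique rownames (feature IDs) and unique colnames (sample IDs).
#' @param source_label free-text cohort label, e.g. `"salEV"`.
#' @return an object of class `ev_counts`: a list with elements `counts`
#'   (the validated matrix) and `source_label`.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' count_matrix(m, "salEV")
#' @export
count_matrix <- function(counts, source_label = "unlabeled") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix", call. = FALSE)
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("count matrix must have at least one feature and one sample", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have feature rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop("duplicate feature ID: ", dup, call. = FALSE)
  }
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ID: ",
         colnames(counts)[duplicated(colnames(counts))][1L], call. = FALSE)
  if (anyNA(counts))
    stop("count matrix contains missing values", call. = FALSE)
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 rownames(counts)[neg[1L, 1L]], colnames(counts)[neg[1L, 2L]]),
         call. = FALSE)
  structure(list(counts = counts, source_label = as.character(source_label)[1L]),
            class = "ev_counts")
}

#' @export
print.ev_counts <- function(x, ...) {
  cat(sprintf("EV count matrix [%s]: %d features x %d samples\n",
              x$source_label, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.ev_counts <- function(x) dim(x$counts)

#' Read a featureCounts-style count table
#'
#' Expects a tab-delimited file whose first column holds feature IDs and
#' remaining columns per-sample counts. Comment lines starting with `#`
#' (featureCounts writes a command-line header) are skipped.
#'
#' @param path file path.
#' @param source_label cohort label attached to the result.
#' @return an [count_matrix()] object.
#' @export
read_count_matrix <- function(path, source_label = "unlabeled") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("empty or malformed count file: ", path,
                             call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or malformed count file: ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric count column in ", path, call. = FALSE)
  rownames(m) <- ids
  count_matrix(m, source_label)
}

#' Write a count matrix as a featureCounts-style table
#'
#' @param x an `ev_counts` object.
#' @param path output path (tab-delimited, UTF-8).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "ev_counts"))
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' GMT is the standard tab-delimited gene-set format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are collapsed (set semantics).
#'
#' @param path file path.
#' @return an object of class `ev_genesets`: a named list of character
#'   vectors with a `pathway_names` attribute mapping set ID to description.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d fields (need >= 3)", i, length(f)),
           call. = FALSE)
    ids[i] <- f[1L]
    nms[i] <- f[2L]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(ids))
    stop("duplicate gene-set ID: ", ids[duplicated(ids)][1L], call. = FALSE)
  names(sets) <- ids
  names(nms) <- ids
  structure(sets, pathway_names = nms, class = "ev_genesets")
}

#' Write a gene-set collection in GMT format
#'
#' @param gs an `ev_genesets` object (or named list of character vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gs, path) {
  nms <- attr(gs, "pathway_names")
  if (is.null(nms)) nms <- stats::setNames(names(gs), names(gs))
  lines <- vapply(names(gs), function(id)
    paste(c(id, nms[[id]], gs[[id]]), collapse = "\t"), character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a feature annotation table
#'
#' Maps feature IDs to a transcript biotype (closed vocabulary:
#' `protein_coding`, `lncRNA`, `pseudogene`, `other`) and a gene symbol.
#'
#' @param feature_id,biotype,symbol character vectors of equal length.
#' @return a data.frame of class `ev_annotation`.
#' @export
feature_annotation <- function(feature_id, biotype, symbol) {
  feature_id <- as.character(feature_id)
  biotype <- as.character(biotype)
  symbol <- as.character(symbol)
  stopifnot(length(biotype) == length(feature_id),
            length(symbol) == length(feature_id))
  if (anyDuplicated(feature_id))
    stop("duplicate feature ID in annotation: ",
         feature_id[duplicated(feature_id)][1L], call. = FALSE)
  bad <- setdiff(unique(biotype), BIOTYPE_VOCAB)
  if (length(bad) > 0L)
    stop("biotype outside vocabulary (", paste(BIOTYPE_VOCAB, collapse = ", "),
         "): ", bad[1L], call. = FALSE)
  structure(data.frame(feature_id = feature_id, biotype = biotype,
                       symbol = symbol, stringsAsFactors = FALSE),
            class = c("ev_annotation", "data.frame"))
}

#' Read a feature annotation table (feature_id, biotype, symbol)
#' @param path tab-delimited file with columns feature_id, biotype, symbol.
#' @return an [feature_annotation()] object.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("feature_id", "biotype", "symbol")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  feature_annotation(df$feature_id, df$biotype, df$symbol)
}

#' @rdname read_annotation
#' @param ann an `ev_annotation` object.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Comma-separated with columns `gene`, `sample`, `replicate`, `ct`. Each
#' assay is run in duplicate, so replicate must be 1 or 2; a missing or
#' "Undetermined" well is stored as `NA`.
#'
#' @param path CSV path.
#' @return a data.frame of class `ev_ct` with columns gene, sample,
#'   replicate, ct.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$ct <- suppressWarnings(as.numeric(ifelse(
    is.character(df$ct) & tolower(trimws(df$ct)) %in%
      c("undetermined", "na", ""), NA, df$ct)))
  ct_table(df$gene, df$sample, df$replicate, df$ct)
}

#' @rdname read_ct_table
#' @param gene,sample,replicate,ct vectors defining one well each.
#' @export
ct_table <- function(gene, sample, replicate, ct) {
  replicate <- as.integer(replicate)
  if (!all(replicate %in% c(1L, 2L)))
    stop("replicate index must be 1 or 2", call. = FALSE)
  ct <- as.numeric(ct)
  if (any(!is.na(ct) & ct <= 0))
    stop("Ct values must be positive when present", call. = FALSE)
  df <- data.frame(gene = as.character(gene), sample = as.character(sample),
                   replicate = replicate, ct = ct, stringsAsFactors = FALSE)
  key <- paste(df$gene, df$sample, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, sample, replicate) well in Ct table", call. = FALSE)
  structure(df, class = c("ev_ct", "data.frame"))
}

#' @rdname read_ct_table
#' @export
write_ct_table <- function(ct, path) {
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read a miRNA count table with flagged negative-control rows
#'
#' Tab-delimited: a `mirna_id` column, a logical/0-1 `control` column
#' flagging negative-control probes, and one column per sample. At least
#' one control row is required (it defines the background level).
#'
#' @param path file path.
#' @return a list of class `ev_mirna` with elements `counts` (matrix,
#'   miRNA x sample) and `is_control` (logical vector along rows).
#' @export
read_mirna_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "control") %in% names(df)))
    stop("miRNA file must have columns mirna_id and control", call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("mirna_id", "control")),
                    drop = FALSE])
  rownames(m) <- df$mirna_id
  mirna_table(m, as.logical(df$control))
}

#' @rdname read_mirna_table
#' @param counts numeric miRNA-by-sample matrix with rownames.
#' @param is_control logical vector marking negative-control rows.
#' @export
mirna_table <- function(counts, is_control) {
  if (!is.matrix(counts) || !is.numeric(counts) || is.null(rownames(counts)))
    stop("miRNA counts must be a numeric matrix with rownames", call. = FALSE)
  if (length(is_control) != nrow(counts))
    stop("is_control length must match row count", call. = FALSE)
  if (any(counts < 0, na.rm = TRUE))
    stop("miRNA counts must be non-negative", call. = FALSE)
  if (!any(is_control))
    stop("at least one negative-control row is required", call. = FALSE)
  structure(list(counts = counts, is_control = as.logical(is_control)),
            class = "ev_mirna")
}

#' @rdname read_mirna_table
#' @param x an `ev_mirna` object.
#' @export
write_mirna_table <- function(x, path) {
  df <- data.frame(mirna_id = rownames(x$counts),
                   control = as.integer(x$is_control), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample read-mapping statistics
#'
#' Two layouts are accepted: percent mode with columns `sample`,
#' `unique_pct`, `multi_pct` (each in \[0, 100\]), or raw-count mode with
#' columns `sample`, `unique_reads`, `multi_reads`, `unmapped_reads`.
#'
#' @param path tab-delimited file.
#' @return a data.frame of class `ev_mapstats` with an attribute
#'   `mode` of `"percent"` or `"counts"`.
#' @export
read_mapping_stats <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  mapping_stats(df)
}

#' @rdname read_mapping_stats
#' @param df a data.frame in one of the two accepted layouts.
#' @export
mapping_stats <- function(df) {
  if (all(c("unique_pct", "multi_pct") %in% names(df))) {
    pct <- c(df$unique_pct, df$multi_pct)
    if (any(pct < 0 | pct > 100))
      stop("mapping percentages must lie in [0, 100]", call. = FALSE)
    mode <- "percent"
  } else if (all(c("unique_reads", "multi_reads", "unmapped_reads") %in%
                 names(df))) {
    cnt <- c(df$unique_reads, df$multi_reads, df$unmapped_reads)
    if (any(cnt < 0)) stop("read counts must be non-negative", call. = FALSE)
    mode <- "counts"
  } else {
    stop("mapping stats need unique_pct/multi_pct or *_reads columns",
         call. = FALSE)
  }
  if (!"sample" %in% names(df))
    stop("mapping stats need a sample column", call. = FALSE)
  structure(df, mode = mode, class = c("ev_mapstats", "data.frame"))
}

#' Harmonize feature identifiers across sources
#'
#' Strips Ensembl-style version suffixes (the text after the final `.` when
#' the prefix matches an `ENS...` accession pattern), then optionally maps
#' IDs to gene symbols through an annotation table. Unmapped IDs are
#' excluded and counted — never silently dropped. The operation is
#' idempotent.
#'
#' @param ids character vector of feature IDs.
#' @param annotation optional [feature_annotation()]; when given, IDs are
#'   replaced by their gene symbol and unmappable IDs are dropped.
#' @return a list with `ids` (harmonized vector), `n_dropped`, and
#'   `dropped_ids`.
#' @examples
#' harmonize_ids(c("ENSG00000123456.7", "ENSG00000000001"))
#' @export
harmonize_ids <- function(ids, annotation = NULL) {
  ids <- as.character(ids)
  versioned <- grepl("^ENS[A-Z]*[0-9]+\\.[0-9]+$", ids)
  ids[versioned] <- sub("\\.[0-9]+$", "", ids[versioned])
  dropped <- character(0)
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "ev_annotation"))
    idx <- match(ids, annotation$feature_id)
    sym <- annotation$symbol[idx]
    # an ID already given as a known symbol passes through unchanged
    known_sym <- is.na(idx) & ids %in% annotation$symbol
    sym[known_sym] <- ids[known_sym]
    dropped <- ids[is.na(sym)]
    ids <- sym[!is.na(sym)]
  }
  list(ids = ids, n_dropped = length(dropped), dropped_ids = dropped)
}
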