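#' Configuration for a synthetic two-cohort EV study
#'
#' Defines the generative model used to emulate a two-source EV RNA study:
#' negative-binomial gene counts with log-normal baseline means and
#' per-sample log-normal library-size factors, cohort sizes matching a
#' small saliva-EV cohort (15) against a large public blood-EV cohort
#' (117), source-specific structural zeros, a biotype label per gene, a
#' planted pathway enrichment (fold-factor applied to gene means in one
#' source), a duplicate-Ct qPCR panel, and a miRNA count panel with
#' negative-control probes. The seed is mandatory: simulated studies are
#' reproducible by construction.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_samples integer vector of length 2: cohort sizes for sources
#'   A and B (default `c(15, 117)`).
#' @param meanlog,sdlog log-normal parameters of baseline gene means
#'   (defaults 3 and 1.8, spanning the dynamic range typical of bulk
#'   RNA-seq).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2; default 0.4).
#' @param libsize_sdlog log-normal sd of per-sample library factors
#'   (default 0.3).
#' @param biotype_prop named proportions over the biotype vocabulary
#'   (default 0.62/0.17/0.13/0.08 for protein_coding/lncRNA/pseudogene/
#'   other).
#' @param n_pathways,pathway_size number and size of simulated gene sets
#'   (defaults 3 and 50); alternatively pass `pathways`, a named list of
#'   gene-symbol vectors, to use explicit sets.
#' @param pathways optional explicit named list of symbol vectors; every
#'   member must be a simulated gene symbol.
#' @param enrich_pathway ID of the pathway whose genes are boosted
#'   (default `"P1"`; `NA` plants no signal).
#' @param fold_factor mean fold-change applied to enriched-pathway genes
#'   in the enriched source (>= 1; default 8).
#' @param enrich_source which source carries the enrichment (`"A"` or
#'   `"B"`; default `"A"`).
#' @param zero_fraction fraction of genes structurally zero per source,
#'   drawn independently per source (default 0.05); when a fold > 1
#'   signal is planted, never applied to the enriched pathway's genes in
#'   the enriched source.
#' @param qpcr_genes,qpcr_samples qPCR panel dimensions (defaults 94, 15).
#' @param qpcr_present_prob probability a panel gene is present in a given
#'   sample (default 0.55).
#' @param ct_mean,ct_sd Ct distribution for present genes (defaults 26.5,
#'   2.5), truncated away from the window edges.
#' @param n_mirna,n_mirna_expressed,n_mirna_controls,mirna_samples miRNA
#'   panel layout (defaults 827 assayed, 286 expressed, 6 controls, 6
#'   samples).
#' @param mirna_bg_mean,mirna_bg_sd negative-control background law
#'   (defaults 20, 5).
#' @param seed integer random seed; mandatory, no default.
#' @return a validated list of class `ev_simconfig`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_samples = c(15L, 117L),
                              meanlog = 3, sdlog = 1.8,
                              dispersion = 0.4,
                              libsize_sdlog = 0.3,
                              biotype_prop = c(protein_coding = 0.62,
                                               lncRNA = 0.17,
                                               pseudogene = 0.13,
                                               other = 0.08),
                              n_pathways = 3L, pathway_size = 50L,
                              pathways = NULL,
                              enrich_pathway = "P1", fold_factor = 8,
                              enrich_source = "A",
                              zero_fraction = 0.05,
                              qpcr_genes = 94L, qpcr_samples = 15L,
                              qpcr_present_prob = 0.55,
                              ct_mean = 26.5, ct_sd = 2.5,
                              n_mirna = 827L, n_mirna_expressed = 286L,
                              n_mirna_controls = 6L, mirna_samples = 6L,
                              mirna_bg_mean = 20, mirna_bg_sd = 5,
                              seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_genes >= 10, length(n_samples) == 2L, all(n_samples >= 1),
            meanlog > -Inf, sdlog > 0, dispersion > 0, libsize_sdlog >= 0,
            fold_factor >= 1, zero_fraction >= 0, zero_fraction < 1,
            enrich_source %in% c("A", "B"))
  if (!setequal(names(biotype_prop), BIOTYPE_VOCAB))
    stop("biotype_prop must be named over the full biotype vocabulary",
         call. = FALSE)
  biotype_prop <- biotype_prop / sum(biotype_prop)
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              meanlog = meanlog, sdlog = sdlog, dispersion = dispersion,
              libsize_sdlog = libsize_sdlog, biotype_prop = biotype_prop,
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size), pathways = pathways,
              enrich_pathway = enrich_pathway, fold_factor = fold_factor,
              enrich_source = enrich_source, zero_fraction = zero_fraction,
              qpcr_genes = as.integer(qpcr_genes),
              qpcr_samples = as.integer(qpcr_samples),
              qpcr_present_prob = qpcr_present_prob,
              ct_mean = ct_mean, ct_sd = ct_sd,
              n_mirna = as.integer(n_mirna),
              n_mirna_expressed = as.integer(n_mirna_expressed),
              n_mirna_controls = as.integer(n_mirna_controls),
              mirna_samples = as.integer(mirna_samples),
              mirna_bg_mean = mirna_bg_mean, mirna_bg_sd = mirna_bg_sd,
              seed = as.integer(seed))
  class(cfg) <- "ev_simconfig"
  cfg
}

sim_gene_ids <- function(n) sprintf("ENSG%011d", seq_len(n))
sim_symbols <- function(n) sprintf("GENE%05d", seq_len(n))

sim_pathways <- function(config, symbols) {
  if (!is.null(config$pathways)) {
    unknown <- setdiff(unlist(config$pathways), symbols)
    if (length(unknown) > 0L)
      stop("pathway references unknown genes: ", unknown[1L], call. = FALSE)
    gs <- config$pathways
  } else {
    if (config$n_pathways * config$pathway_size > length(symbols))
      stop("pathways exceed gene universe", call. = FALSE)
    pick <- sample(symbols, config$n_pathways * config$pathway_size)
    gs <- split(pick, rep(seq_len(config$n_pathways),
                          each = config$pathway_size))
    names(gs) <- paste0("P", seq_len(config$n_pathways))
  }
  structure(gs,
            pathway_names = stats::setNames(
              paste("simulated pathway", names(gs)), names(gs)),
            class = "ev_genesets")
}

#' Simulate two cohorts of EV RNA-seq counts
#'
#' Draws gene counts from a negative-binomial law with mean
#' `baseline * library-factor * fold-factor` (the fold applied only to
#' enriched-pathway genes in the enriched source), applies source-specific
#' structural zeros, and returns annotated matrices plus gene sets and the
#' ground-truth record. Deterministic given the config seed.
#'
#' @param config an [simulation_config()] object.
#' @return list with `counts_a`, `counts_b` ([count_matrix()] objects),
#'   `annotation`, `genesets`, and `truth` (enriched pathway, source,
#'   fold, per-source structural-zero genes, baseline means).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "ev_simconfig"))
  set.seed(config$seed)
  ids <- sim_gene_ids(config$n_genes)
  syms <- sim_symbols(config$n_genes)
  biotypes <- sample(names(config$biotype_prop), config$n_genes,
                     replace = TRUE, prob = config$biotype_prop)
  ann <- feature_annotation(ids, biotypes, syms)
  gs <- sim_pathways(config, syms)
  baseline <- stats::rlnorm(config$n_genes, config$meanlog, config$sdlog)
  names(baseline) <- ids
  enriched_syms <- if (!is.na(config$enrich_pathway) &&
                       config$enrich_pathway %in% names(gs))
    gs[[config$enrich_pathway]] else character(0)
  enriched_ids <- ids[syms %in% enriched_syms]
  size <- 1 / config$dispersion
  draw_source <- function(n_s, label, enriched_here) {
    mu_g <- baseline
    if (enriched_here) mu_g[enriched_ids] <- mu_g[enriched_ids] *
        config$fold_factor
    # structural zeros spare planted-enrichment genes only when a signal
    # is actually planted, so the fold = 1 null stays symmetric
    protect <- enriched_here && config$fold_factor > 1
    zero_ids <- sample(setdiff(ids, if (protect) enriched_ids
                               else character(0)),
                       round(config$zero_fraction * config$n_genes))
    mu_g[zero_ids] <- 0
    lib <- stats::rlnorm(n_s, 0, config$libsize_sdlog)
    m <- matrix(0, config$n_genes, n_s,
                dimnames = list(ids, sprintf("%s_s%03d", label,
                                             seq_len(n_s))))
    nz <- mu_g > 0
    for (j in seq_len(n_s))
      m[nz, j] <- stats::rnbinom(sum(nz), mu = mu_g[nz] * lib[j],
                                 size = size)
    list(cm = count_matrix(m, label), zero_ids = zero_ids)
  }
  a <- draw_source(config$n_samples[1L], "salEV",
                   config$enrich_source == "A")
  b <- draw_source(config$n_samples[2L], "bEV",
                   config$enrich_source == "B")
  list(counts_a = a$cm, counts_b = b$cm, annotation = ann, genesets = gs,
       truth = list(enrich_pathway = config$enrich_pathway,
                    enrich_source = config$enrich_source,
                    fold_factor = config$fold_factor,
                    zero_ids_a = a$zero_ids, zero_ids_b = b$zero_ids,
                    baseline_mean = baseline))
}

#' Simulate a duplicate-run qPCR Ct panel
#'
#' Present (gene, sample) pairs draw both replicate Ct values from a
#' normal law truncated one cycle inside the \[18, 35\] calling window;
#' absent pairs draw either a missing replicate or an out-of-window value,
#' so the planted truth is recoverable exactly.
#'
#' @param config an [simulation_config()] object.
#' @return list with `ct` (an `ev_ct` table) and `truth` (logical
#'   gene-by-sample presence matrix).
#' @export
generate_ct_table <- function(config) {
  stopifnot(inherits(config, "ev_simconfig"))
  set.seed(config$seed + 1L)
  genes <- sprintf("ADG%03d", seq_len(config$qpcr_genes))
  samples <- sprintf("qs%02d", seq_len(config$qpcr_samples))
  truth <- matrix(stats::runif(length(genes) * length(samples)) <
                    config$qpcr_present_prob,
                  length(genes), length(samples),
                  dimnames = list(genes, samples))
  draw_in <- function(n) pmin(34, pmax(19, stats::rnorm(n, config$ct_mean,
                                                        config$ct_sd)))
  rows <- expand.grid(gene = genes, sample = samples, replicate = 1:2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pres <- truth[cbind(rows$gene, rows$sample)]
  ct <- numeric(nrow(rows))
  ct[pres] <- draw_in(sum(pres))
  # absent pairs: half get an out-of-window Ct on replicate 1 and a valid
  # replicate 2, half get a missing replicate 2
  ct[!pres] <- ifelse(rows$replicate[!pres] == 1L,
                      stats::runif(sum(!pres), 36, 40), NA_real_)
  mode_b <- stats::runif(nrow(rows)) < 0.5
  swap <- !pres & mode_b & rows$replicate == 2L
  ct[swap] <- draw_in(sum(swap))  # missing-mode becomes out-of-window mode 1
  list(ct = ct_table(rows$gene, rows$sample, rows$replicate, ct),
       truth = truth)
}

#' Simulate a miRNA count panel with negative controls
#'
#' Expressed miRNAs draw counts well above the control background
#' (log-normal means >= 200); non-expressed miRNAs and negative controls
#' draw from the low-mean background law.
#'
#' @param config an [simulation_config()] object.
#' @return list with `mirna` (an `ev_mirna` table) and `truth` (character
#'   vector of planted expressed miRNA IDs).
#' @export
generate_mirna_table <- function(config) {
  stopifnot(inherits(config, "ev_simconfig"))
  set.seed(config$seed + 2L)
  n <- config$n_mirna
  n_expr <- config$n_mirna_expressed
  stopifnot(n_expr <= n)
  ids <- sprintf("hsa-miR-%04d", seq_len(n))
  ctrl_ids <- sprintf("NEG_%s", LETTERS[seq_len(config$n_mirna_controls)])
  samples <- sprintf("ns%02d", seq_len(config$mirna_samples))
  expr_ids <- if (n_expr > 0) sample(ids, n_expr) else character(0)
  bg_draw <- function(nr) matrix(pmax(0, round(stats::rnorm(
    nr * length(samples), config$mirna_bg_mean, config$mirna_bg_sd))),
    nrow = nr)
  counts <- bg_draw(n)
  rownames(counts) <- ids
  colnames(counts) <- samples
  if (n_expr > 0) {
    mu <- 200 * (1 + stats::rlnorm(n_expr, 0, 0.7))  # means >= 200
    counts[expr_ids, ] <- matrix(stats::rnbinom(
      n_expr * length(samples), mu = rep(mu, length(samples)), size = 10),
      nrow = n_expr)
  }
  ctrl <- bg_draw(length(ctrl_ids))
  rownames(ctrl) <- ctrl_ids
  colnames(ctrl) <- samples
  all_counts <- rbind(counts, ctrl)
  list(mirna = mirna_table(all_counts,
                           c(rep(FALSE, n), rep(TRUE, length(ctrl_ids)))),
       truth = sort(expr_ids))
}

#' Simulate per-sample read-mapping statistics
#' @param config an [simulation_config()] object.
#' @return an `ev_mapstats` object in percent mode for the source-A cohort.
#' @export
generate_mapping_stats <- function(config) {
  stopifnot(inherits(config, "ev_simconfig"))
  set.seed(config$seed + 3L)
  n <- config$n_samples[1L]
  uq <- pmin(95, pmax(5, stats::rnorm(n, 44.1, 5)))
  mu <- pmin(100 - uq, pmax(0.5, stats::rnorm(n, 4.3, 1)))
  mapping_stats(data.frame(sample = sprintf("salEV_s%03d", seq_len(n)),
                           unique_pct = uq, multi_pct = mu,
                           stringsAsFactors = FALSE))
}

#' Simulate a complete two-cohort EV study
#'
#' Bundles [generate_counts()], [generate_ct_table()],
#' [generate_mirna_table()] and [generate_mapping_stats()] into one study
#' object with a full ground-truth record. Every component is
#' deterministic given the config seed.
#'
#' @param config an [simulation_config()] object.
#' @return a list of class `ev_study` with elements `counts_a`,
#'   `counts_b`, `annotation`, `genesets`, `ct`, `mirna`, `mapping`,
#'   `truth`, and `config`.
#' @export
simulate_study <- function(config) {
  cm <- generate_counts(config)
  qp <- generate_ct_table(config)
  mi <- generate_mirna_table(config)
  mp <- generate_mapping_stats(config)
  structure(list(counts_a = cm$counts_a, counts_b = cm$counts_b,
                 annotation = cm$annotation, genesets = cm$genesets,
                 ct = qp$ct, mirna = mi$mirna, mapping = mp,
                 truth = c(cm$truth, list(qpcr_presence = qp$truth,
                                          mirna_expressed = mi$truth)),
                 config = config),
            class = "ev_study")
}

#' @export
print.ev_study <- function(x, ...) {
  cat(sprintf(
    "Simulated EV study (seed %d): %d genes; cohorts %s (n=%d) and %s (n=%d)\n",
    x$config$seed, x$config$n_genes,
    x$counts_a$source_label, ncol(x$counts_a$counts),
    x$counts_b$source_label, ncol(x$counts_b$counts)))
  cat(sprintf("  qPCR panel %dx%d; miRNA panel %d (+%d controls) x %d\n",
              x$config$qpcr_genes, x$config$qpcr_samples, x$config$n_mirna,
              x$config$n_mirna_controls, x$config$mirna_samples))
  invisible(x)
}

#' Write a simulated study to a directory of plain-text files
#'
#' Emits `counts_A.tsv`, `counts_B.tsv`, `annotation.tsv`,
#' `pathways.gmt`, `ct.csv`, `mirna.tsv`, `mapping.tsv` and `truth.json`.
#' Every file is readable by the corresponding package reader.
#'
#' @param study an `ev_study` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ev_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_count_matrix(study$counts_a, p("counts_A.tsv"))
  write_count_matrix(study$counts_b, p("counts_B.tsv"))
  write_annotation(study$annotation, p("annotation.tsv"))
  write_gmt(study$genesets, p("pathways.gmt"))
  write_ct_table(study$ct, p("ct.csv"))
  write_mirna_table(study$mirna, p("mirna.tsv"))
  utils::write.table(as.data.frame(study$mapping), p("mapping.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = study$config$seed,
         enrich_pathway = study$truth$enrich_pathway,
         enrich_source = study$truth$enrich_source,
         fold_factor = study$truth$fold_factor,
         mirna_expressed = study$truth$mirna_expressed,
         qpcr_presence = apply(study$truth$qpcr_presence, 1L, which)),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
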