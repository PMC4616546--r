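# One reproducible run: screen, then optional IHC diagnostics and
# methylation association for the screened markers, with a JSON manifest
# capturing version and parameters.

#' Pipeline run configuration
#'
#' Collects input paths and stage parameters and fails fast if any
#' referenced file is missing, before any computation starts. The IHC and
#' methylation stages are optional: leave their paths `NULL` to skip them.
#'
#' @param expression Path to the expression matrix (TSV/CSV).
#' @param annotation Path to the sample annotation CSV.
#' @param target_subtype Subtype whose markers are screened for.
#' @param outdir Output directory (created if absent).
#' @param ihc Optional path to an IHC grading CSV.
#' @param methylation Optional path to a beta-value matrix; requires
#'   `probe_gene_map`.
#' @param probe_gene_map Optional path to a two-column probe-to-gene CSV.
#' @param criteria A [screen_criteria()]; defaults to the standard operating
#'   point for `target_subtype`.
#' @param rules Positivity rule names evaluated in the IHC stage.
#' @param delta_threshold Median beta gap for the hypomethylation flag.
#' @param ihc_types Optional tumor types entering sensitivity/specificity
#'   (default: every type in the records).
#' @return An object of class `run_config`.
#' @export
run_config <- function(expression, annotation, target_subtype, outdir,
                       ihc = NULL, methylation = NULL, probe_gene_map = NULL,
                       criteria = screen_criteria(target_subtype),
                       rules = c("strict", "lenient"),
                       delta_threshold = 0.25, ihc_types = NULL) {
  paths <- c(expression = expression, annotation = annotation,
             ihc = ihc, methylation = methylation,
             probe_gene_map = probe_gene_map)
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0)
    stop("input file(s) not found: ",
         paste(sprintf("%s (%s)", absent, names(absent)), collapse = ", "))
  if (!is.null(methylation) && is.null(probe_gene_map))
    stop("methylation stage needs a probe_gene_map file")
  stopifnot(inherits(criteria, "screen_criteria"),
            identical(criteria$target_subtype, target_subtype))
  structure(list(expression = expression, annotation = annotation,
                 target_subtype = target_subtype, outdir = outdir,
                 ihc = ihc, methylation = methylation,
                 probe_gene_map = probe_gene_map, criteria = criteria,
                 rules = rules, delta_threshold = delta_threshold,
                 ihc_types = ihc_types),
            class = "run_config")
}

#' Run the full marker-discovery pipeline
#'
#' Executes the screen and writes `hits.csv`; if an IHC table is configured,
#' computes sensitivity/specificity for every screened marker present in it
#' under each configured rule (`metrics.csv`); if a beta table is
#' configured, runs the methylation association restricted to probes mapped
#' to screened genes (`cpg_assoc.csv`). A `run.json` manifest records the
#' package version, all parameters, and the files written; the timestamp
#' lives only there, so the CSV outputs are byte-identical across reruns of
#' the same configuration.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the screen table, optional metrics and
#'   association tables, and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  expr <- read_expression(cfg$expression)
  ann <- read_annotation(cfg$annotation)
  nm <- normalize_by_reference(expr, cfg$criteria$reference_gene)
  s <- summarize_by_subtype(nm, ann, q = cfg$criteria$percentile,
                            method = cfg$criteria$method)
  hits <- apply_screen(s, cfg$criteria)
  params <- list(target = cfg$target_subtype,
                 median_min = cfg$criteria$median_min,
                 q = cfg$criteria$percentile,
                 q_max = cfg$criteria$background_q_max,
                 ref = cfg$criteria$reference_gene,
                 method = cfg$criteria$method)
  files <- list(hits = file.path(cfg$outdir, "hits.csv"))
  write_table(hits, files$hits, params = params)
  hit_genes <- hits$gene_id[hits$hit]
  msg("screen: %d hit(s) of %d genes", length(hit_genes), nrow(hits))

  metrics <- NULL
  if (!is.null(cfg$ihc)) {
    records <- read_ihc(cfg$ihc)
    markers <- intersect(unique(records$marker), hit_genes)
    if (length(markers) == 0)
      msg("IHC stage: no screened marker present in the grading table")
    metrics <- do.call(rbind, lapply(markers, function(mk) {
      do.call(rbind, lapply(cfg$rules, function(rn) {
        counts <- tabulate_ihc(records, mk, cfg$target_subtype,
                               positivity_rule(rn), types = cfg$ihc_types)
        diagnostic_metrics(counts)
      }))
    }))
    if (is.null(metrics))
      metrics <- diagnostic_metrics_empty()
    files$metrics <- file.path(cfg$outdir, "metrics.csv")
    write_table(metrics, files$metrics,
                params = c(params, list(rules = paste(cfg$rules,
                                                      collapse = "+"))))
  }

  assoc <- NULL
  if (!is.null(cfg$methylation)) {
    beta <- read_methylation(cfg$methylation)
    map <- utils::read.csv(cfg$probe_gene_map, stringsAsFactors = FALSE,
                           comment.char = "#", colClasses = "character")
    map <- map[map$gene_id %in% hit_genes, , drop = FALSE]
    if (nrow(map) == 0) {
      msg("methylation stage: no probe maps to a screened gene")
      assoc <- NULL
    } else {
      assoc <- associate_methylation(beta, nm, ann, map,
                                     cfg$target_subtype,
                                     cfg$delta_threshold)
      files$cpg_assoc <- file.path(cfg$outdir, "cpg_assoc.csv")
      write_table(assoc, files$cpg_assoc,
                  params = c(params,
                             list(delta_threshold = cfg$delta_threshold)))
    }
  }

  manifest <- list(
    tool = "markerscreen",
    version = as.character(utils::packageVersion("markerscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = c(params, list(delta_threshold = cfg$delta_threshold,
                                rules = cfg$rules)),
    inputs = list(expression = cfg$expression, annotation = cfg$annotation,
                  ihc = cfg$ihc, methylation = cfg$methylation,
                  probe_gene_map = cfg$probe_gene_map),
    outputs = lapply(files, normalizePath),
    n_hits = length(hit_genes),
    hits = hit_genes)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(hits = hits, metrics = metrics, cpg_assoc = assoc,
                 manifest = manifest))
}

# Zero-row metrics table with the standard columns, so a run whose grading
# table contains none of the screened markers still writes a well-formed file.
diagnostic_metrics_empty <- function() {
  data.frame(marker = character(0), target_type = character(0),
             rule = character(0), tp = integer(0), fn = integer(0),
             fp = integer(0), tn = integer(0), sensitivity = numeric(0),
             sens_pct = numeric(0), sens_lo = numeric(0),
             sens_hi = numeric(0), specificity = numeric(0),
             spec_pct = numeric(0), spec_lo = numeric(0),
             spec_hi = numeric(0), stringsAsFactors = FALSE)
}

#' Write a simulated cohort bundle to disk
#'
#' Materializes one synthetic cohort in the standard file formats the
#' pipeline consumes: `expression.tsv`, `annotation.csv`, `beta.tsv`,
#' `probe_gene_map.csv`, `ihc.csv`, and `truth.csv` (the planted marker
#' table).
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if absent).
#' @return Named list of the paths written, invisibly.
#' @export
write_simulated_bundle <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_expression(cfg)
  meth <- simulate_methylation(cfg, sim$expression, sim$annotation)
  records <- simulate_ihc(cfg)
  paths <- list(
    expression = file.path(outdir, "expression.tsv"),
    annotation = file.path(outdir, "annotation.csv"),
    beta = file.path(outdir, "beta.tsv"),
    probe_gene_map = file.path(outdir, "probe_gene_map.csv"),
    ihc = file.path(outdir, "ihc.csv"),
    truth = file.path(outdir, "truth.csv"))
  params <- list(seed = cfg$seed)
  write_table(sim$expression, paths$expression, params, id_col = "gene_id")
  write_table(sim$annotation, paths$annotation, params)
  write_table(meth$beta, paths$beta, params, id_col = "probe_id")
  write_table(meth$probe_gene_map, paths$probe_gene_map, params)
  write_table(records, paths$ihc, params)
  write_table(sim$truth, paths$truth, params)
  invisible(paths)
}
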