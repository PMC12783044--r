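#' Default pipeline configuration
#'
#' All tunables of the screen-analysis pipeline with their standard values:
#' the 700-read coverage cutoff, 3-guide minimum, 0.6 median-correlation
#' consistency threshold, detection limit 1 for zero imputation, MCD scoring,
#' and 60 pseudo-controls. Fields can be overridden via `...` or supplied as
#' a YAML/JSON file through [read_run_config()].
#'
#' @param ... named overrides of any default field.
#' @return list of class `run_config`.
#' @export
#' @examples
#' run_config(min_total = 500, n_pseudo_controls = 30)
run_config <- function(...) {
  cfg <- list(
    events = NULL,            # path to an event-level TSV, or
    counts = NULL,            # path to a count TSV, or
    simulate = NULL,          # list of simulation_config() overrides
    min_total = 700,
    min_guides = 3,
    min_median_r = 0.6,
    recheck_min_guides = TRUE,
    dl = 1,
    method = "mcd",
    support_fraction = NULL,
    n_pseudo_controls = 60,
    pseudo_control_mode = "unified",
    jsd_base = 2,
    seed = 1,
    out_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML (or JSON) file of config fields.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full screen-analysis pipeline
#'
#' Executes the stages in order — obtain counts (read an event or count
#' table, or simulate), preprocess (coverage, guide-count and consistency
#' filters plus zero imputation), aggregate gene spectra, score genes
#' (ILR + robust Mahalanobis, unified across targets), select
#' pseudo-controls — and optionally writes every intermediate with a manifest
#' recording the configuration, seeds and package version. Identical configs
#' produce identical artifacts.
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @return list with `counts` (filtered, imputed), `filter_report`,
#'   `spectra`, `scores` (gene score table with `is_pseudo_control`),
#'   `pseudo_controls` (gene ids), `truth` (when simulated), `manifest`.
#' @export
#' @examples
#' res <- run_pipeline(run_config(simulate = list(n_genes = 60, n_outliers = 3,
#'                                                n_targets = 1),
#'                                seed = 7, n_pseudo_controls = 10))
#' head(res$scores[order(res$scores$rank), c("gene", "unified_score", "rank")])
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    stop("config must come from run_config() or read_run_config()")
  }
  src <- c(events = !is.null(config$events), counts = !is.null(config$counts),
           simulate = !is.null(config$simulate))
  if (sum(src) != 1) {
    stop("exactly one input source required: events, counts or simulate")
  }

  truth <- NULL
  if (src[["events"]]) {
    message("stage=input source=events file=", config$events)
    raw <- build_count_table(read_events(config$events))
  } else if (src[["counts"]]) {
    message("stage=input source=counts file=", config$counts)
    raw <- read_counts(config$counts)
  } else {
    sim_args <- config$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sim <- simulate_screen(do.call(simulation_config, sim_args))
    message("stage=input source=simulate rows=", nrow(sim$counts))
    raw <- sim$counts
    truth <- sim$truth
  }

  message("stage=preprocess rows_in=", nrow(raw))
  pre <- preprocess_counts(raw, min_total = config$min_total,
                           min_guides = config$min_guides,
                           min_median_r = config$min_median_r,
                           dl = config$dl, seed = config$seed,
                           recheck_min_guides = config$recheck_min_guides)
  message("stage=preprocess rows_out=", nrow(pre$counts),
          " removed=", nrow(pre$report))
  if (!nrow(pre$counts)) {
    warning("no rows survive preprocessing; downstream tables are empty")
    return(list(counts = pre$counts, filter_report = pre$report,
                spectra = NULL, scores = NULL, pseudo_controls = character(0),
                truth = truth, manifest = pipeline_manifest(config)))
  }

  spectra <- aggregate_gene_spectra(pre$counts)
  message("stage=spectra gene_targets=", nrow(spectra))

  scores <- score_screen(spectra, seed = config$seed, method = config$method,
                         support_fraction = config$support_fraction)
  n_pc <- min(config$n_pseudo_controls, nrow(scores))
  scores <- select_pseudo_controls(scores, n = n_pc,
                                   mode = config$pseudo_control_mode)
  message("stage=score genes=", nrow(scores), " pseudo_controls=",
          sum(scores$is_pseudo_control))

  result <- list(counts = pre$counts, filter_report = pre$report,
                 spectra = spectra, scores = scores,
                 pseudo_controls = scores$gene[scores$is_pseudo_control],
                 truth = truth,
                 manifest = pipeline_manifest(config))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(result$counts, file.path(config$out_dir, "filtered_counts.tsv"))
    write_tsv(result$filter_report,
              file.path(config$out_dir, "filter_report.tsv"))
    write_tsv(result$spectra, file.path(config$out_dir, "spectra.tsv"))
    write_tsv(result$scores, file.path(config$out_dir, "gene_scores.tsv"))
    writeLines(result$pseudo_controls,
               file.path(config$out_dir, "pseudo_controls.txt"))
    if (!is.null(truth)) {
      write_tsv(truth, file.path(config$out_dir, "simulation_truth.tsv"))
    }
    jsonlite::write_json(result$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    message("stage=write out_dir=", config$out_dir)
  }
  result
}

pipeline_manifest <- function(config) {
  cfg <- unclass(config)
  cfg_json <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                               null = "null", digits = NA)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(package = "spectrascreen",
       version = as.character(utils::packageVersion("spectrascreen")),
       config = cfg, config_md5 = hash,
       ilr_basis = "gram-schmidt sequential binary partition",
       category_order = analysis_categories())
}
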