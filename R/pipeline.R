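#' Configuration for a full pipeline run
#'
#' @param pssm_dir directory of per-protein PSSM files (`<id>.pssm` ASCII
#'   or `<id>.tsv`).
#' @param pairs_file TSV of labeled pairs (id_a, id_b, label).
#' @param out_dir directory the artifacts are written to.
#' @param olpp an [olpp_config()].
#' @param rof a [rof_config()].
#' @param folds cross-validation folds.
#' @param seed fold-assignment seed (the Rotation Forest seed lives in
#'   `rof`).
#' @param log_level `"info"` for stage messages on stderr, `"quiet"` for
#'   none.
#' @return List of class `run_config`.
#' @export
run_config <- function(pssm_dir, pairs_file, out_dir,
                       olpp = olpp_config(), rof = rof_config(),
                       folds = 5L, seed = 1L, log_level = "info") {
  structure(list(pssm_dir = pssm_dir, pairs_file = pairs_file,
                 out_dir = out_dir, olpp = olpp, rof = rof,
                 folds = as.integer(folds), seed = as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

pipeline_log <- function(config, stage, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, paste0(...)))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(config)), f)
  unname(tools::md5sum(f))
}

#' Run the complete prediction pipeline
#'
#' Executes feature extraction, OLPP embedding, pair-feature
#' construction, Rotation Forest training and cross-validated evaluation
#' from files on disk, and writes the artifacts: `report.json` (per-fold
#' and aggregate metrics plus the fully resolved configuration, its hash
#' and the seed), `roc.tsv` (per-fold ROC points) and
#' `descriptors.tsv`. Stage progress goes to stderr; results never do.
#'
#' @param config a [run_config()].
#' @return The [cross_validate()] report, invisibly, with the artifact
#'   paths attached as attribute `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$pssm_dir)) stop("pssm_dir not found: ", config$pssm_dir)
  if (!file.exists(config$pairs_file)) stop("pairs file not found: ", config$pairs_file)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  pipeline_log(config, "featurize", "reading pairs from ", config$pairs_file)
  pairs <- read_pairs(config$pairs_file)
  ids <- unique(c(pairs$id_a, pairs$id_b))
  pipeline_log(config, "featurize", length(ids), " proteins, ",
               nrow(pairs), " pairs")
  descriptors <- descriptors_from_dir(config$pssm_dir, ids)

  desc_path <- file.path(config$out_dir, "descriptors.tsv")
  utils::write.table(data.frame(id = rownames(descriptors), descriptors,
                                check.names = FALSE),
                     desc_path, sep = "\t", quote = FALSE, row.names = FALSE)

  pipeline_log(config, "evaluate", config$folds, "-fold cross-validation")
  report <- cross_validate(pairs, descriptors, config$olpp, config$rof,
                           k_folds = config$folds, seed = config$seed)
  report$config$run <- list(pssm_dir = config$pssm_dir,
                            pairs_file = config$pairs_file,
                            seed = config$seed,
                            config_hash = config_hash(config))

  report_path <- file.path(config$out_dir, "report.json")
  roc_path <- file.path(config$out_dir, "roc.tsv")
  write_report(report, report_path, roc_path)
  pipeline_log(config, "done", "report written to ", report_path)
  attr(report, "paths") <- list(report = report_path, roc = roc_path,
                                descriptors = desc_path)
  invisible(report)
}
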