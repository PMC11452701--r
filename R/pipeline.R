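#' Write / read a cohort CSV
#'
#' One row per patient, header names exactly the patient-record field names.
#' Reading validates every row; errors name the row and column.
#'
#' @param cohort a `uf_cohort`
#' @param path file path
#' @return `read_cohort_csv` returns a validated `uf_cohort`
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("read_cohort_csv: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- names(empty_cohort())
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("read_cohort_csv: missing column(s): ",
         paste(missing, collapse = ", "))
  num_cols <- setdiff(req, c("id", "group"))
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1]
      stop("read_cohort_csv: non-numeric value in column '", cc,
           "', row ", bad)
    }
  }
  df <- df[, req]
  class(df) <- c("uf_cohort", "data.frame")
  validate_cohort(df)
  df
}

#' Export simulated waveforms to CSV
#'
#' One file per requested site with columns time_s, P_mmHg, Q_mL_per_s,
#' U_cm_per_s.
#'
#' @param result a `uf_simresult`
#' @param dir output directory
#' @param sites site names (default: all)
#' @return written paths, invisibly
#' @export
write_waveform_csv <- function(result, dir, sites = names(result$sites)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in sites) {
    s <- result$sites[[nm]]
    df <- data.frame(time_s = result$time, P_mmHg = pa_to_mmhg(s$P),
                     Q_mL_per_s = 1e6 * s$Q, U_cm_per_s = 100 * s$U)
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: cohort source (spec or CSV
#' path), solver settings, calibration controls, classification config and
#' the global seed. Serialisable to JSON for provenance.
#'
#' @param cohort_spec a [cohort_spec()] (ignored when `cohort_csv` given)
#' @param cohort_csv optional path to an existing cohort CSV
#' @param settings [solver_settings()]
#' @param max_iter,rel_tol,topology calibration controls
#' @param eval_config classification config (see [supervised_eval()])
#' @param out_dir output directory (`NULL` = write nothing)
#' @param seed global seed; flows into cohort generation and classification
#' @return a `uf_pipeline_config`
#' @export
pipeline_config <- function(cohort_spec = uteroflow::cohort_spec(),
                            cohort_csv = NULL,
                            settings = solver_settings(),
                            max_iter = 12L, rel_tol = 0.03,
                            topology = "full",
                            eval_config = list(n_repeats = 5L,
                                               holdout_size = 2L,
                                               cv_folds = 2L),
                            out_dir = NULL, seed = 1L) {
  if (!is.null(cohort_csv) && !file.exists(cohort_csv))
    stop("pipeline_config: cohort_csv does not exist: ", cohort_csv)
  structure(list(cohort_spec = cohort_spec, cohort_csv = cohort_csv,
                 settings = settings, max_iter = as.integer(max_iter),
                 rel_tol = rel_tol, topology = topology,
                 eval_config = eval_config, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "uf_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' synth -> calibrate -> simulate -> biomarkers -> classify. Generates (or
#' loads) the cohort, calibrates a digital twin per patient, assembles the
#' feature table, and evaluates every classifier column. Deterministic for a
#' fixed `config$seed`. When `config$out_dir` is set, writes `cohort.csv`,
#' `features.csv`, `twins.json` (per-patient parameters and convergence
#' logs) and `report.json`.
#'
#' @param config a [pipeline_config()]
#' @return a `uf_report` list: `cohort`, `features`, `report` (per-feature
#'   metrics data frame), `excluded`, `seed`, `provenance`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "uf_pipeline_config"))
    stop("run_pipeline: 'config' must be a uf_pipeline_config")
  cohort <- if (!is.null(config$cohort_csv)) read_cohort_csv(config$cohort_csv)
  else {
    spec <- config$cohort_spec
    spec$seed <- config$seed
    generate_cohort(spec)
  }
  # write stage outputs as they are produced so a downstream failure leaves
  # the upstream artifacts intact
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(cohort, file.path(config$out_dir, "cohort.csv"))
  }
  if (length(unique(cohort$group)) < 2)
    stop("run_pipeline: classification needs both groups present ",
         "(single-class cohort)")
  twins <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    twins[[i]] <- suppressWarnings(
      calibrate(measurement_targets(cohort[i, ], rel_tol = config$rel_tol),
                settings = config$settings, max_iter = config$max_iter,
                topology = config$topology))
  }
  features <- feature_table(cohort, twins = twins)
  if (!is.null(config$out_dir)) {
    utils::write.csv(as.data.frame(features),
                     file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    twin_json <- lapply(seq_along(twins), function(i) {
      t <- twins[[i]]
      list(id = cohort$id[i], converged = t$converged,
           iterations = t$iterations,
           R_periph = t$R_periph, C_syst = t$C_syst, k_beta = t$k_beta,
           R_ut = as.list(t$R_ut), A = t$A, PWV_model = t$PWV_model,
           residuals = as.list(t$residuals), log = t$log)
    })
    jsonlite::write_json(twin_json,
                         file.path(config$out_dir, "twins.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  if (length(unique(features$group)) < 2)
    stop("run_pipeline: classification needs both groups present ",
         "(single-class feature table after exclusions)")
  ev <- config$eval_config
  ev$seed <- config$seed
  rep_df <- feature_report(features[, feature_columns()], features$group, ev)
  conv <- data.frame(
    id = cohort$id,
    converged = vapply(twins, function(t) isTRUE(t$converged), TRUE),
    iterations = vapply(twins, function(t) as.integer(t$iterations), 1L),
    max_residual = vapply(twins, function(t) max(t$residuals), 1)
  )
  out <- structure(list(cohort = cohort, features = features,
                        report = rep_df, convergence = conv,
                        excluded = attr(features, "excluded"),
                        seed = config$seed,
                        provenance = list(
                          package_version =
                            as.character(utils::packageVersion("uteroflow")),
                          topology = config$topology,
                          rel_tol = config$rel_tol,
                          timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
                   class = "uf_report")
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(list(report = rep_df, convergence = conv,
                              excluded = out$excluded, seed = config$seed,
                              provenance = out$provenance),
                         file.path(config$out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.uf_report <- function(x, ...) {
  cat("uteroflow pipeline report\n")
  cat("  patients:", nrow(x$cohort), " converged:", nrow(x$features), "\n")
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n\n")
  print(x$report, digits = 3)
  invisible(x)
}
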