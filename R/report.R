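#' Write assessment reports
#'
#' Writes two files to \code{dir}: \code{report.json}, the full-precision
#' record of every pipeline intermediate (normalized matrix, entropies,
#' entropy/subsystem/combined weights, AHP consistency, per-plot scores,
#' flags in effect), and \code{summary.csv}, one row per plot with V, S,
#' V/S, C, D and the class labels rounded the way assessment tables print
#' them (4 decimals for C, 2 for the rest).
#'
#' @param fit a [ccd()] fit.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(fit, dir) {
  stopifnot(inherits(fit, "ccd"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  norm <- fit$normalized
  report <- list(
    options = list(alpha = fit$alpha, beta = fit$beta,
                   literal_d = fit$literal,
                   class_digits = fit$class_digits),
    systems = fit$index$systems,
    normalized = stats::setNames(
      lapply(rownames(norm), function(p) as.list(norm[p, ])),
      rownames(norm)),
    entropies = as.list(fit$weights$entropies),
    entropy_weights = as.list(fit$weights$entropy_weights),
    subsystem_weights = lapply(fit$weights$subsystem_weights, as.list),
    consistency = fit$weights$consistency,
    combined_weights = as.list(fit$weights$combined_weights),
    scores = fit$scores)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  s <- fit$scores
  csv <- data.frame(plot = s$plot,
                    V = round(s$V, 2), S = round(s$S, 2),
                    ratio = round(s$ratio, 2),
                    C = round(s$C, 4), D = round(s$D, 2),
                    coordination_class = s$coordination_class,
                    lag_class = s$lag_class,
                    stringsAsFactors = FALSE)
  csv_path <- file.path(dir, "summary.csv")
  utils::write.table(csv, csv_path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' Run the full pipeline from file inputs and write reports
#'
#' Thin composition used by the command-line interface: read the index
#' system and data table, fit the assessment with [ccd()], write JSON and
#' CSV reports plus a plain-text log of the options in effect.
#'
#' @param data_path CSV/TSV plot-by-indicator table.
#' @param index_path index-system YAML/JSON config.
#' @param ahp_path subsystem-weight YAML/JSON config.
#' @param out_dir output directory.
#' @param scheme_path optional classification-scheme config.
#' @inheritParams ccd
#' @return the \code{ccd} fit, invisibly.
#' @export
run_pipeline <- function(data_path, index_path, ahp_path, out_dir,
                         alpha = 0.5, beta = 0.5, cr_max = 0.1,
                         cr_action = "warn", literal = FALSE,
                         scheme_path = NULL, class_digits = 2,
                         exclude_plots = NULL) {
  scheme <- if (is.null(scheme_path)) classification_scheme()
            else read_classification_scheme(scheme_path)
  fit <- ccd(data_path, index_path, ahp_path, alpha = alpha, beta = beta,
             cr_max = cr_max, cr_action = cr_action, literal = literal,
             scheme = scheme, class_digits = class_digits,
             exclude_plots = exclude_plots)
  paths <- write_report(fit, out_dir)
  log_lines <- c(
    "ccdeval run",
    paste0("data: ", data_path),
    paste0("index: ", index_path),
    paste0("ahp: ", ahp_path),
    paste0("alpha: ", alpha, "  beta: ", beta),
    paste0("cr_max: ", cr_max, "  cr_action: ", cr_action),
    paste0("literal_eq_d: ", literal),
    paste0("class_digits: ", class_digits),
    paste0("outputs: ", paste(paths, collapse = ", ")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(fit)
}

#' Validate configuration files
#'
#' Reads and validates an index-system config and, optionally, an AHP
#' config and a data table against it. Raises on the first violation;
#' returns TRUE invisibly when everything checks out.
#'
#' @param index_path index-system config path.
#' @param ahp_path optional AHP config path.
#' @param data_path optional data table path.
#' @return TRUE, invisibly.
#' @export
validate_inputs <- function(index_path, ahp_path = NULL, data_path = NULL) {
  index <- read_index_system(index_path)
  if (!is.null(ahp_path))
    subsystem_weights(ahp_path, index)
  if (!is.null(data_path))
    read_indicator_matrix(data_path, index)
  invisible(TRUE)
}
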