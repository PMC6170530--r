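#' Synthetic survey scenarios
#'
#' A scenario describes how to generate a raw plot-by-indicator matrix
#' with known ground truth. Targets are specified on the normalized scale
#' and inverted through the min-max transform: raw = low + x' (high - low)
#' for benefit columns (reflected for cost columns), so normalizing the
#' generated matrix reproduces the targets exactly. For the inversion to
#' round-trip, every target column must attain an exact 0 and an exact 1
#' (the column extrema pin the raw min and max). Without targets, values
#' are drawn uniformly within the column ranges with optional Gaussian
#' jitter, reproducibly from \code{seed}.
#'
#' @param index an \code{index_system}.
#' @param n_plots number of plots (>= 2) when drawing random values;
#'   ignored when \code{target_normalized} is given.
#' @param column_ranges named list/vector mapping indicator id to
#'   \code{c(low, high)} raw bounds with low < high; defaults to (0, 1)
#'   for every indicator.
#' @param target_normalized optional plots x indicators matrix of values
#'   in [0, 1] with plot row names; each column must contain 0 and 1.
#' @param noise_sd nonnegative raw-scale jitter standard deviation,
#'   applied only when targets are absent.
#' @param seed integer seed for the random draws.
#' @return an object of class \code{synthetic_scenario}.
#' @seealso [generate_matrix()], [scenario_from_scores()]
#' @export
synthetic_scenario <- function(index, n_plots = 5L, column_ranges = NULL,
                               target_normalized = NULL, noise_sd = 0,
                               seed = 1L) {
  ids <- indicator_ids(index)
  if (is.null(column_ranges))
    column_ranges <- stats::setNames(rep(list(c(0, 1)), length(ids)), ids)
  missing_rng <- setdiff(ids, names(column_ranges))
  if (length(missing_rng))
    stop("column_ranges lack indicator(s): ",
         paste(missing_rng, collapse = ", "), call. = FALSE)
  for (id in ids) {
    r <- column_ranges[[id]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1L] >= r[2L])
      stop("range for '", id, "' must be c(low, high) with low < high",
           call. = FALSE)
  }
  if (!is.null(target_normalized)) {
    target_normalized <- as.matrix(target_normalized)
    if (is.null(rownames(target_normalized)))
      rownames(target_normalized) <-
        paste0("plot", seq_len(nrow(target_normalized)))
    if (is.null(colnames(target_normalized)))
      colnames(target_normalized) <- ids
    if (!identical(colnames(target_normalized), ids))
      target_normalized <- target_normalized[, ids, drop = FALSE]
    if (any(target_normalized < 0) || any(target_normalized > 1))
      stop("target values must lie in [0, 1]", call. = FALSE)
    n_plots <- nrow(target_normalized)
  }
  if (n_plots < 2L)
    stop("scenario needs at least 2 plots", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(
    list(index = index, n_plots = as.integer(n_plots),
         column_ranges = column_ranges,
         target_normalized = target_normalized,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_scenario")
}

# Run expr with a locally seeded RNG, restoring any pre-existing global
# RNG state afterwards (no global side effects).
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a raw matrix from a synthetic scenario
#'
#' With targets: exact affine inversion of min-max normalization, so
#' \code{minmax_normalize(generate_matrix(s), s$index)} equals
#' \code{s$target_normalized} (up to floating-point representation).
#' Without targets: uniform draws within ranges plus Gaussian jitter,
#' deterministic given the scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a raw-scale indicator matrix.
#' @export
generate_matrix <- function(scenario) {
  idx <- scenario$index
  ids <- indicator_ids(idx)
  dir <- stats::setNames(idx$indicators$direction, ids)
  if (!is.null(scenario$target_normalized)) {
    tgt <- scenario$target_normalized
    bad <- ids[vapply(ids, function(id)
      !(any(tgt[, id] == 0) && any(tgt[, id] == 1)), logical(1))]
    if (length(bad))
      stop("target column(s) lack an exact 0 or 1 (inversion would not ",
           "round-trip): ", paste(bad, collapse = ", "), call. = FALSE)
    raw <- tgt
    for (id in ids) {
      r <- scenario$column_ranges[[id]]
      x <- if (dir[id] == "benefit") tgt[, id] else 1 - tgt[, id]
      raw[, id] <- r[1L] + x * (r[2L] - r[1L])
    }
    return(indicator_matrix(raw, scale = "raw"))
  }
  raw <- with_local_seed(scenario$seed, {
    m <- scenario$n_plots
    vals <- sapply(ids, function(id) {
      r <- scenario$column_ranges[[id]]
      v <- stats::runif(m, r[1L], r[2L])
      if (scenario$noise_sd > 0)
        v <- v + stats::rnorm(m, 0, scenario$noise_sd)
      v
    })
    matrix(vals, nrow = m,
           dimnames = list(paste0("plot", seq_len(m)), ids))
  })
  indicator_matrix(raw, scale = "raw")
}

#' Scenario engineered to reproduce given system scores
#'
#' Builds target normalized values in which every column of the first
#' system equals V_i for plot i and every column of the second system
#' equals S_i. Because each system's combined weights sum to 1, the
#' weighted sum over a constant row returns the constant: the pipeline
#' recovers exactly (V_i, S_i) for these plots under ANY valid weight
#' set. Two anchor plots (all-0 and all-1 rows) are appended whenever the
#' targets alone do not pin every column's extrema, so the min-max
#' inversion of [generate_matrix()] stays exact; exclude them from
#' reports via the \code{"anchor_plots"} attribute.
#'
#' @param V,S named numeric vectors of target scores in [0, 1], one entry
#'   per plot (same names/order).
#' @param index an \code{index_system} with exactly two systems.
#' @param column_ranges optional raw-scale ranges, as in
#'   [synthetic_scenario()].
#' @return a \code{synthetic_scenario} whose \code{"anchor_plots"}
#'   attribute names any appended anchor plots.
#' @examples
#' sc <- scenario_from_scores(V = c(RP = 0.57), S = c(RP = 0.74),
#'                            index = pingshuo_index())
#' attr(sc, "anchor_plots")
#' @export
scenario_from_scores <- function(V, S, index, column_ranges = NULL) {
  if (length(index$systems) != 2L)
    stop("score-targeted scenarios need exactly two systems", call. = FALSE)
  if (length(V) != length(S))
    stop("V and S must have one entry per plot", call. = FALSE)
  if (any(V < 0 | V > 1) || any(S < 0 | S > 1))
    stop("target scores must lie in [0, 1]", call. = FALSE)
  plots <- names(V)
  if (is.null(plots)) plots <- paste0("plot", seq_along(V))
  ids <- indicator_ids(index)
  veg_cols <- subsystem_indicators(index, index$systems[1L])
  soil_cols <- subsystem_indicators(index, index$systems[2L])
  tgt <- matrix(0, nrow = length(V), ncol = length(ids),
                dimnames = list(plots, ids))
  tgt[, veg_cols] <- V
  tgt[, soil_cols] <- S
  anchors <- character(0)
  pinned <- all(apply(tgt, 2L, function(col)
    any(col == 0) && any(col == 1)))
  if (!pinned) {
    anchors <- c("anchor_lo", "anchor_hi")
    tgt <- rbind(tgt,
                 anchor_lo = rep(0, length(ids)),
                 anchor_hi = rep(1, length(ids)))
  }
  sc <- synthetic_scenario(index, column_ranges = column_ranges,
                           target_normalized = tgt)
  attr(sc, "anchor_plots") <- anchors
  sc
}

#' Write a synthetic matrix and its ground truth
#'
#' Generates the scenario's matrix, writes it as CSV, and writes a JSON
#' sidecar with the ground-truth normalized targets (if any), the column
#' ranges and the seed.
#'
#' @param scenario a \code{synthetic_scenario}.
#' @param dir output directory (created if needed).
#' @param basename file stem (default \code{"synthetic"}).
#' @return invisibly, the paths written.
#' @export
write_synthetic <- function(scenario, dir, basename = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- generate_matrix(scenario)
  csv <- file.path(dir, paste0(basename, "_matrix.csv"))
  write_indicator_matrix(mat, csv)
  truth <- list(
    seed = scenario$seed,
    noise_sd = scenario$noise_sd,
    column_ranges = scenario$column_ranges,
    anchor_plots = attr(scenario, "anchor_plots"),
    target_normalized = if (is.null(scenario$target_normalized)) NULL else {
      t_ <- scenario$target_normalized
      stats::setNames(lapply(rownames(t_), function(p) as.list(t_[p, ])),
                      rownames(t_))
    })
  js <- file.path(dir, paste0(basename, "_truth.json"))
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(matrix = csv, truth = js))
}
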