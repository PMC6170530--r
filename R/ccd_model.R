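#' Per-plot comprehensive evaluation scores
#'
#' The comprehensive evaluation function of a system is the weighted sum
#' of its normalized indicators: V_i = sum_j w_j x'_ij over the vegetation
#' indicators and S_i = sum_j w_j x'_ij over the soil indicators (and
#' likewise for any other declared system). With weights summing to 1 per
#' system and normalized values in [0, 1], each score lies in [0, 1].
#'
#' @param normalized a normalized-scale indicator matrix.
#' @param weights named vector of combined indicator weights (summing to 1
#'   within each system), e.g. from [combine_weights()].
#' @param index the \code{index_system}.
#' @return numeric matrix, plots x systems, of comprehensive scores.
#' @export
system_scores <- function(normalized, weights, index) {
  if (matrix_scale(normalized) != "normalized")
    stop("system_scores expects a normalized matrix", call. = FALSE)
  ids <- indicator_ids(index)
  missing_w <- setdiff(colnames(normalized), names(weights))
  missing_w <- intersect(missing_w, ids)
  if (length(missing_w))
    stop("indicator(s) lack weights: ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  out <- sapply(index$systems, function(sys) {
    cols <- subsystem_indicators(index, sys)
    drop(normalized[, cols, drop = FALSE] %*% weights[cols])
  })
  out <- matrix(out, nrow = nrow(normalized),
                dimnames = list(rownames(normalized), index$systems))
  out
}

#' Coupling degree of two system scores
#'
#' C = sqrt(V S / (V + S)^2), a symmetric measure of interaction intensity
#' between two systems. In this two-system form C is at most 0.5, attained
#' exactly when V = S > 0. When both scores are zero the coupling is
#' undefined; it is set to 0 and flagged via the \code{"degenerate"}
#' attribute.
#'
#' @param V,S nonnegative system scores (vectorized).
#' @return coupling degree(s) in [0, 0.5], with a logical
#'   \code{"degenerate"} attribute marking V + S = 0 cases.
#' @examples
#' coupling_degree(0.57, 0.74)  # 0.4958
#' @export
coupling_degree <- function(V, S) {
  if (any(V < 0) || any(S < 0))
    stop("system scores must be nonnegative", call. = FALSE)
  tot <- V + S
  degenerate <- tot == 0
  C <- ifelse(degenerate, 0, sqrt((V * S) / ifelse(degenerate, 1, tot^2)))
  attr(C, "degenerate") <- degenerate
  C
}

#' Coupling coordination degree
#'
#' D = sqrt(C T) with the composite development term T = alpha V + beta S.
#' The radical couples interaction intensity (C) with overall development
#' level (T); with alpha = beta = 0.5 it reduces to the closed form
#' D = (V S)^(1/4) / sqrt(2). The radical-free variant D = C T is
#' available via \code{literal = TRUE} for comparison studies; see the
#' methods vignette for why the radical form is the default.
#'
#' @param C coupling degree(s) from [coupling_degree()].
#' @param V,S system scores.
#' @param alpha,beta contribution coefficients of the two systems; must be
#'   nonnegative and sum to 1 (default 0.5 each: equal importance).
#' @param literal if TRUE, compute D = C T without the square root.
#' @return coordination degree(s) in [0, 1].
#' @examples
#' C <- coupling_degree(0.57, 0.74)
#' coordination_degree(C, 0.57, 0.74)  # 0.57
#' @export
coordination_degree <- function(C, V, S, alpha = 0.5, beta = 0.5,
                                literal = FALSE) {
  if (alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-12)
    stop("contribution coefficients must be nonnegative and sum to 1 ",
         "(alpha = ", alpha, ", beta = ", beta, ")", call. = FALSE)
  T_ <- alpha * V + beta * S
  if (literal) as.numeric(C) * T_ else sqrt(as.numeric(C) * T_)
}

#' Vegetation-to-soil lag ratio
#'
#' The ratio V/S diagnoses which system lags behind the other (the "short
#' plank" of the plot). When S = 0 the ratio is undefined: NA is returned,
#' flagged via the \code{"undefined"} attribute, and classified downstream
#' as extreme soil lag (V > 0) or degenerate (V = 0).
#'
#' @param V,S system scores (vectorized).
#' @return ratio(s), NA where S = 0, with an \code{"undefined"} attribute.
#' @export
lag_ratio <- function(V, S) {
  undefined <- S == 0
  r <- ifelse(undefined, NA_real_, V / ifelse(undefined, 1, S))
  attr(r, "undefined") <- undefined
  r
}

# -- classification -----------------------------------------------------------

make_bands <- function(lower, upper, label) {
  stopifnot(length(lower) == length(upper), length(upper) == length(label))
  o <- order(lower)
  b <- data.frame(lower = lower[o], upper = upper[o], label = label[o],
                  stringsAsFactors = FALSE)
  if (anyDuplicated(b$label))
    stop("band labels must be unique", call. = FALSE)
  if (nrow(b) > 1L && any(b$lower[-1L] != b$upper[-nrow(b)]))
    stop("bands must be contiguous and non-overlapping", call. = FALSE)
  b
}

#' Coordination classification scheme
#'
#' Bands are half-open on the left, (lower, upper], following the
#' convention 0 < D <= 0.2 etc. The default scheme classifies D as
#' low (0, 0.2], primary (0.2, 0.4], intermediate (0.4, 0.6], well
#' (0.6, 0.8] or high (0.8, 1] coordination, and V/S as vegetation
#' lagging behind (0, 0.8], synchronous development (0.8, 1.2] or soil
#' lagging behind (1.2, Inf).
#'
#' Note that with two systems C never exceeds 0.5, so D never exceeds
#' sqrt(0.5) ~ 0.707 when alpha = beta = 0.5; the bands above that value
#' exist for completeness and for other coefficient choices.
#'
#' @param d_bands,ratio_bands data frames with columns \code{lower},
#'   \code{upper}, \code{label}; contiguous, non-overlapping.
#' @return an object of class \code{ccd_scheme}.
#' @export
classification_scheme <- function(
    d_bands = data.frame(
      lower = c(0, 0.2, 0.4, 0.6, 0.8),
      upper = c(0.2, 0.4, 0.6, 0.8, 1),
      label = c("low coordination", "primary coordination",
                "intermediate coordination", "well coordination",
                "high coordination")),
    ratio_bands = data.frame(
      lower = c(0, 0.8, 1.2),
      upper = c(0.8, 1.2, Inf),
      label = c("vegetation lagging behind", "synchronous development",
                "soil lagging behind"))) {
  structure(
    list(d_bands = make_bands(d_bands$lower, d_bands$upper, d_bands$label),
         ratio_bands = make_bands(ratio_bands$lower, ratio_bands$upper,
                                  ratio_bands$label)),
    class = "ccd_scheme")
}

#' Read a classification scheme from YAML/JSON
#'
#' Config keys \code{d_bands} and \code{ratio_bands}, each a list of
#' records with \code{lower}, \code{upper} (\code{.inf} allowed in YAML)
#' and \code{label}. Missing keys fall back to the defaults of
#' [classification_scheme()].
#'
#' @param path config file path.
#' @return a \code{ccd_scheme}.
#' @export
read_classification_scheme <- function(path) {
  cfg <- read_config(path)
  to_df <- function(recs) {
    do.call(rbind, lapply(recs, function(r)
      data.frame(lower = as.numeric(r$lower), upper = as.numeric(r$upper),
                 label = as.character(r$label), stringsAsFactors = FALSE)))
  }
  defaults <- classification_scheme()
  classification_scheme(
    d_bands = if (is.null(cfg$d_bands)) defaults$d_bands
              else to_df(cfg$d_bands),
    ratio_bands = if (is.null(cfg$ratio_bands)) defaults$ratio_bands
                  else to_df(cfg$ratio_bands))
}

band_label <- function(value, bands) {
  vapply(value, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == bands$lower[1L]) return(bands$label[1L])  # include left edge
    hit <- which(v > bands$lower & v <= bands$upper)
    if (!length(hit)) return(NA_character_)
    bands$label[hit[1L]]
  }, character(1))
}

#' Classify coordination degree and lag ratio
#'
#' Maps D onto the coordination bands and V/S onto the lag bands of a
#' [classification_scheme()] (boundaries right-closed). Published
#' assessment tables band the values at their printed precision, so by
#' default D and the ratio are rounded to \code{digits} decimals before
#' banding; set \code{digits = NULL} to band at full precision.
#'
#' An undefined ratio (S = 0) is labelled \code{"soil lagging behind
#' (extreme)"} when V > 0 and \code{"degenerate"} when V = 0.
#'
#' @param D coordination degree(s) in [0, 1].
#' @param ratio lag ratio(s), possibly NA from [lag_ratio()].
#' @param scheme a \code{ccd_scheme}.
#' @param digits decimals used for banding (default 2, matching reporting
#'   precision), or NULL for none.
#' @param V optional vegetation scores, used only to resolve undefined
#'   ratios.
#' @return list with character vectors \code{coordination_class} and
#'   \code{lag_class}.
#' @examples
#' classify(0.57, 0.77)  # intermediate coordination, vegetation lagging
#' @export
classify <- function(D, ratio, scheme = classification_scheme(),
                     digits = 2, V = NULL) {
  if (any(D < 0 | D > 1))
    stop("coordination degree outside [0, 1]", call. = FALSE)
  Db <- if (is.null(digits)) D else round(D, digits)
  rb <- if (is.null(digits)) ratio else round(ratio, digits)
  coord <- band_label(Db, scheme$d_bands)
  lag <- band_label(rb, scheme$ratio_bands)
  und <- is.na(ratio)
  if (any(und)) {
    v <- if (is.null(V)) rep(1, length(ratio)) else V
    lag[und & v > 0] <- "soil lagging behind (extreme)"
    lag[und & v == 0] <- "degenerate"
  }
  list(coordination_class = coord, lag_class = lag)
}

# -- the assessment fit -------------------------------------------------------

#' Fit a coupling coordination assessment
#'
#' Runs the full evaluation pipeline on a raw plot-by-indicator matrix:
#' min-max normalization over the index system, entropy weights per
#' subsystem, subsystem weights from the AHP config, multiplicative weight
#' combination, per-plot comprehensive scores (V, S), coupling degree C,
#' coupling coordination degree D, lag ratio V/S, and band classification.
#' Every intermediate is retained on the returned object so each stage is
#' inspectable.
#'
#' @param data raw-scale indicator matrix (see [indicator_matrix()]), or a
#'   path to a CSV/TSV table read with [read_indicator_matrix()].
#' @param index an \code{index_system}, or a path to its YAML/JSON config.
#'   Must declare exactly two systems: the first plays the role of V
#'   (vegetation), the second of S (soil).
#' @param ahp subsystem-weight config: path or list accepted by
#'   [subsystem_weights()].
#' @param alpha,beta contribution coefficients of the two systems
#'   (nonnegative, summing to 1; default 0.5 each).
#' @param cr_max,cr_action AHP consistency-ratio policy.
#' @param literal use the radical-free D = C T variant (default FALSE).
#' @param scheme a [classification_scheme()].
#' @param class_digits decimals at which D and V/S are banded (default 2,
#'   the reporting precision); NULL bands at full precision.
#' @param exclude_plots plot labels dropped from the score table (but not
#'   from normalization), e.g. synthetic anchor plots.
#' @return an object of class \code{ccd}: a list with the call, the index
#'   system, raw and normalized matrices, the \code{weight_set}, and
#'   \code{scores}, a data frame with one row per plot (V, S, ratio, C, T,
#'   D, coordination_class, lag_class).
#' @examples
#' idx <- pingshuo_index()
#' sc <- scenario_from_scores(
#'   V = c(RP = 0.57), S = c(RP = 0.74), index = idx)
#' fit <- ccd(generate_matrix(sc), idx, pingshuo_ahp(),
#'            exclude_plots = attr(sc, "anchor_plots"))
#' fit$scores
#' @seealso [coupling_degree()], [coordination_degree()], [classify()]
#' @export
ccd <- function(data, index, ahp, alpha = 0.5, beta = 0.5,
                cr_max = 0.1, cr_action = c("warn", "error"),
                literal = FALSE, scheme = classification_scheme(),
                class_digits = 2, exclude_plots = NULL) {
  cr_action <- match.arg(cr_action)
  cl <- match.call()
  if (is.character(index)) index <- read_index_system(index)
  if (length(index$systems) != 2L)
    stop("coupling requires exactly two systems; index declares ",
         length(index$systems), call. = FALSE)
  if (is.character(data)) data <- read_indicator_matrix(data, index)
  data <- validate_indicator_matrix(data)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  if (nrow(data) < 2L)
    stop("[entropy] entropy weights need at least 2 plots", call. = FALSE)
  normalized <- if (matrix_scale(data) == "raw")
    stage("normalize", minmax_normalize(data, index)) else data
  ws <- stage("weighting",
              compute_weight_set(normalized, index, ahp,
                                 cr_max = cr_max, cr_action = cr_action))
  sc <- stage("scores",
              system_scores(normalized, ws$combined_weights, index))
  V <- sc[, 1L]; S <- sc[, 2L]
  C <- stage("coupling", coupling_degree(V, S))
  D <- stage("coordination",
             coordination_degree(C, V, S, alpha = alpha, beta = beta,
                                 literal = literal))
  r <- lag_ratio(V, S)
  cls <- stage("classify",
               classify(D, r, scheme = scheme, digits = class_digits, V = V))
  scores <- data.frame(
    plot = rownames(sc), V = V, S = S, ratio = as.numeric(r),
    C = as.numeric(C), T = alpha * V + beta * S, D = D,
    coordination_class = cls$coordination_class,
    lag_class = cls$lag_class,
    degenerate = attr(C, "degenerate"),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(exclude_plots))
    scores <- scores[!scores$plot %in% exclude_plots, , drop = FALSE]
  structure(
    list(call = cl, index = index, raw = data, normalized = normalized,
         weights = ws, scores = scores, alpha = alpha, beta = beta,
         literal = literal, scheme = scheme, class_digits = class_digits),
    class = "ccd")
}

#' @export
print.ccd <- function(x, ...) {
  cat("Coupling coordination assessment:",
      nrow(x$scores), "plots,",
      nrow(x$index$indicators), "indicators (",
      paste(x$index$systems, collapse = " vs "), ")\n")
  if (x$literal) cat("  (radical-free D = C*T variant)\n")
  tab <- x$scores
  tab$V <- round(tab$V, 2); tab$S <- round(tab$S, 2)
  tab$ratio <- round(tab$ratio, 2)
  tab$C <- round(tab$C, 4); tab$D <- round(tab$D, 2)
  tab$T <- NULL; tab$degenerate <- NULL
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ccd <- function(object, ...) {
  structure(list(fit = object), class = "summary.ccd")
}

#' @export
print.summary.ccd <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\n")
  print(fit$weights)
  cat("\nEntropies (e_j):\n")
  print(round(fit$weights$entropies, 4))
  invisible(x)
}

#' @export
coef.ccd <- function(object, ...) object$weights$combined_weights

#' @export
fitted.ccd <- function(object, ...) {
  stats::setNames(object$scores$D, object$scores$plot)
}

#' Scores table of a fitted assessment
#' @param object a \code{ccd} fit.
#' @return the per-plot score data frame (full precision).
#' @export
scores <- function(object) UseMethod("scores")

#' @export
scores.ccd <- function(object) object$scores

#' @export
plot.ccd <- function(x, ...) {
  s <- x$scores
  lim <- c(0, max(1, s$V, s$S))
  graphics::plot(s$V, s$S, xlim = lim, ylim = lim,
                 xlab = paste("V:", x$index$systems[1L], "score"),
                 ylab = paste("S:", x$index$systems[2L], "score"),
                 pch = 19, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::abline(0, 1 / 0.8, lty = 3, col = "grey70")
  graphics::abline(0, 1 / 1.2, lty = 3, col = "grey70")
  graphics::text(s$V, s$S, labels = paste0(s$plot, " (D=", round(s$D, 2), ")"),
                 pos = 3, cex = 0.8)
  invisible(x)
}
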