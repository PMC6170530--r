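#' Entropy weights for a block of indicator columns
#'
#' Objective weighting by the entropy weight method. For each indicator j
#' over m plots, the share of plot i is P_ij = x'_ij / sum_i x'_ij, its
#' information entropy is e_j = -(1/ln m) sum_i P_ij ln P_ij (with the
#' convention 0 ln 0 = 0), and the weight is w_j = (1 - e_j) /
#' sum_j (1 - e_j) over the indicators of the block. Uniform columns have
#' e_j = 1 and receive zero weight; a column whose values sum to 0 carries
#' no share information and is likewise assigned e_j = 1. If every column
#' of the block is uninformative, equal weights are assigned with a
#' warning.
#'
#' @param normalized a normalized-scale indicator matrix.
#' @param columns indicator ids forming the block (typically one
#'   subsystem); weights are normalized to sum 1 within the block.
#' @return list with \code{entropies} and \code{weights}, both named
#'   numeric vectors over \code{columns}.
#' @examples
#' idx <- index_system("s", list(s = "a"),
#'   data.frame(id = c("X1", "X2"), name = c("x", "y"), system = "s",
#'              subsystem = "a", direction = "benefit"))
#' m <- indicator_matrix(cbind(X1 = c(0, 1), X2 = c(0.5, 0.5)),
#'                       plot_ids = c("p1", "p2"), scale = "normalized")
#' entropy_weights(m, c("X1", "X2"))  # X1 carries all the weight
#' @export
entropy_weights <- function(normalized, columns) {
  if (matrix_scale(normalized) != "normalized")
    stop("entropy_weights expects a normalized matrix", call. = FALSE)
  missing_id <- setdiff(columns, colnames(normalized))
  if (length(missing_id))
    stop("column(s) absent from matrix: ",
         paste(missing_id, collapse = ", "), call. = FALSE)
  m <- nrow(normalized)
  if (m < 2L)
    stop("entropy weights need at least 2 plots (ln m = 0 for m = 1)",
         call. = FALSE)
  e <- vapply(columns, function(id) {
    col <- normalized[, id]
    tot <- sum(col)
    if (tot == 0) return(1)        # no share information
    p <- col / tot
    terms <- ifelse(p > 0, p * log(p), 0)   # 0 * ln 0 := 0
    -sum(terms) / log(m)
  }, numeric(1))
  # clamp tiny negative round-off; e_j is in [0, 1] by construction
  e <- pmin(pmax(e, 0), 1)
  d <- 1 - e
  if (sum(d) == 0) {
    warning("all columns in block are uninformative (e_j = 1); ",
            "assigning equal weights", call. = FALSE)
    w <- rep(1 / length(columns), length(columns))
  } else {
    w <- d / sum(d)
  }
  names(w) <- columns
  list(entropies = e, weights = w)
}

# Saaty's random consistency index, k = 1..10
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

validate_pcm <- function(a, tol = 1e-9) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a))
    stop("pairwise comparison matrix must be square", call. = FALSE)
  if (any(!is.finite(a)) || any(a <= 0))
    stop("pairwise comparison matrix must be positive and finite",
         call. = FALSE)
  if (any(abs(diag(a) - 1) > tol))
    stop("pairwise comparison matrix must have unit diagonal", call. = FALSE)
  rel <- abs(a * t(a) - 1)
  if (any(rel > tol * pmax(1, a * t(a))))
    stop("pairwise comparison matrix is not reciprocal (a_ji != 1/a_ij)",
         call. = FALSE)
  a
}

#' AHP priority vector with consistency check
#'
#' Computes the principal right eigenvector of a reciprocal pairwise
#' comparison matrix by power iteration, normalized to sum 1, together
#' with the principal eigenvalue lambda_max, the consistency index
#' CI = (lambda_max - k)/(k - 1) and the consistency ratio CR = CI/RI(k)
#' using Saaty's random-index table (defined for k <= 10). A CR above
#' \code{cr_max} triggers a warning, or an error when
#' \code{cr_action = "error"}.
#'
#' @param pcm square positive reciprocal matrix (unit diagonal); row/column
#'   names, if present, label the weights.
#' @param cr_max consistency-ratio threshold (default 0.1).
#' @param cr_action \code{"warn"} (default) or \code{"error"} when CR
#'   exceeds \code{cr_max}.
#' @param tol,max_iter power-iteration convergence tolerance and cap.
#' @return list with \code{weights} (sums to 1), \code{lambda_max},
#'   \code{CI} and \code{CR}.
#' @examples
#' ahp_priority(matrix(c(1, 1/3, 3, 1), 2, 2))$weights  # 0.75, 0.25
#' @export
ahp_priority <- function(pcm, cr_max = 0.1, cr_action = c("warn", "error"),
                         tol = 1e-12, max_iter = 10000L) {
  cr_action <- match.arg(cr_action)
  a <- validate_pcm(pcm)
  k <- nrow(a)
  if (k > length(saaty_ri))
    stop("random-index table covers k <= ", length(saaty_ri), call. = FALSE)
  labels <- rownames(a)
  if (k == 1L) {
    w <- stats::setNames(1, labels)
    return(list(weights = w, lambda_max = 1, CI = 0, CR = 0))
  }
  w <- rep(1 / k, k)
  lambda <- k
  for (it in seq_len(max_iter)) {
    aw <- drop(a %*% w)
    w_new <- aw / sum(aw)
    lambda <- sum(aw) # since sum(w) == 1, Rayleigh-type estimate
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  lambda <- sum(drop(a %*% w)) / sum(w)
  ci <- (lambda - k) / (k - 1)
  cr <- if (saaty_ri[k] > 0) ci / saaty_ri[k] else 0
  if (cr > cr_max) {
    msg <- sprintf("consistency ratio %.4f exceeds %.2f", cr, cr_max)
    if (cr_action == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  names(w) <- labels
  list(weights = w, lambda_max = lambda, CI = ci, CR = cr)
}

#' Geometric-mean (logarithmic least squares) AHP weights
#'
#' Row geometric means of the pairwise matrix, normalized to sum 1.
#' Coincides with the eigenvector solution on perfectly consistent
#' matrices; provided as an independent cross-check of [ahp_priority()].
#'
#' @inheritParams ahp_priority
#' @return named numeric weight vector summing to 1.
#' @export
ahp_geomean <- function(pcm) {
  a <- validate_pcm(pcm)
  g <- apply(a, 1L, function(r) exp(mean(log(r))))
  stats::setNames(g / sum(g), rownames(a))
}

#' Subsystem weights from an AHP config
#'
#' The config gives, per system, either a \code{pairwise} judgment matrix
#' over its subsystems (solved by [ahp_priority()]) or
#' \code{direct_weights} (normalized to sum 1). Used by [ccd()] to obtain
#' the subjective layer of the combined weighting scheme.
#'
#' @param config path to a YAML/JSON file, or an equivalent named list
#'   keyed by system name.
#' @param index the \code{index_system}; every system must be covered and
#'   every subsystem weighted.
#' @param cr_max,cr_action consistency-ratio policy passed to
#'   [ahp_priority()].
#' @return list with \code{subsystem_weights} (per system, a named vector
#'   over its subsystems summing to 1) and \code{consistency} (per system,
#'   NULL for direct weights).
#' @export
subsystem_weights <- function(config, index, cr_max = 0.1,
                              cr_action = c("warn", "error")) {
  cr_action <- match.arg(cr_action)
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  weights <- list()
  consistency <- list()
  for (sys in index$systems) {
    subs <- index$subsystems[[sys]]
    entry <- config[[sys]]
    if (is.null(entry))
      stop("AHP config lacks an entry for system '", sys, "'",
           call. = FALSE)
    if (!is.null(entry$pairwise)) {
      a <- do.call(rbind, lapply(entry$pairwise, as.numeric))
      if (nrow(a) != length(subs))
        stop("pairwise matrix for '", sys, "' is ", nrow(a), "x", ncol(a),
             " but the system has ", length(subs), " subsystems",
             call. = FALSE)
      rownames(a) <- colnames(a) <- subs
      res <- ahp_priority(a, cr_max = cr_max, cr_action = cr_action)
      weights[[sys]] <- res$weights
      consistency[[sys]] <- res[c("lambda_max", "CI", "CR")]
    } else if (!is.null(entry$direct_weights)) {
      w <- unlist(entry$direct_weights)
      missing_sub <- setdiff(subs, names(w))
      if (length(missing_sub))
        stop("direct weights for '", sys, "' lack subsystem(s): ",
             paste(missing_sub, collapse = ", "), call. = FALSE)
      w <- w[subs]
      if (any(w < 0) || sum(w) <= 0)
        stop("direct weights for '", sys, "' must be nonnegative with a ",
             "positive sum", call. = FALSE)
      weights[[sys]] <- w / sum(w)
      consistency[sys] <- list(NULL)
    } else {
      stop("system '", sys, "' needs either 'pairwise' or 'direct_weights'",
           call. = FALSE)
    }
  }
  list(subsystem_weights = weights, consistency = consistency)
}

#' Combine subsystem and entropy weights
#'
#' The combined weight of an indicator is the product of its subsystem's
#' AHP weight and its within-subsystem entropy weight. Because subsystem
#' weights sum to 1 per system and entropy weights sum to 1 per subsystem,
#' the products sum to 1 within each system with no renormalization.
#'
#' @param subsys_w list per system of named subsystem weight vectors
#'   (each summing to 1).
#' @param entropy_w named vector of entropy weights over all indicators
#'   (summing to 1 within each subsystem).
#' @param index the \code{index_system}.
#' @return named numeric vector of combined weights, one per indicator in
#'   index order.
#' @export
combine_weights <- function(subsys_w, entropy_w, index) {
  ind <- index$indicators
  w <- numeric(nrow(ind))
  for (i in seq_len(nrow(ind))) {
    sw <- subsys_w[[ind$system[i]]][ind$subsystem[i]]
    ew <- entropy_w[ind$id[i]]
    if (is.null(sw) || is.na(sw))
      stop("no subsystem weight for indicator '", ind$id[i], "' (",
           ind$system[i], "/", ind$subsystem[i], ")", call. = FALSE)
    if (is.na(ew))
      stop("no entropy weight for indicator '", ind$id[i], "'",
           call. = FALSE)
    w[i] <- sw * ew
  }
  stats::setNames(w, ind$id)
}

# Full weighting stage over a normalized matrix: entropy weights per
# subsystem, subsystem weights from config, multiplicative combination.
# Returns the WeightSet used by ccd().
compute_weight_set <- function(normalized, index, ahp_config,
                               cr_max = 0.1, cr_action = "warn") {
  ent <- numeric(0)
  ew <- numeric(0)
  for (sys in index$systems) {
    for (sub in index$subsystems[[sys]]) {
      ids <- subsystem_indicators(index, sys, sub)
      res <- entropy_weights(normalized, ids)
      ent <- c(ent, res$entropies)
      ew <- c(ew, res$weights)
    }
  }
  sw <- subsystem_weights(ahp_config, index, cr_max = cr_max,
                          cr_action = cr_action)
  cw <- combine_weights(sw$subsystem_weights, ew, index)
  structure(
    list(entropies = ent[indicator_ids(index)],
         entropy_weights = ew[indicator_ids(index)],
         subsystem_weights = sw$subsystem_weights,
         combined_weights = cw,
         consistency = sw$consistency),
    class = "weight_set")
}

#' @export
print.weight_set <- function(x, digits = 4, ...) {
  cat("Weight set (", length(x$combined_weights), " indicators)\n", sep = "")
  cat("Subsystem weights:\n")
  for (sys in names(x$subsystem_weights)) {
    w <- round(x$subsystem_weights[[sys]], digits)
    cat("  ", sys, ": ",
        paste(names(w), "=", format(w), collapse = ", "), "\n", sep = "")
    cons <- x$consistency[[sys]]
    if (!is.null(cons))
      cat("    (lambda_max = ", format(round(cons$lambda_max, digits)),
          ", CR = ", format(round(cons$CR, digits)), ")\n", sep = "")
  }
  cat("Combined indicator weights:\n")
  print(round(x$combined_weights, digits))
  invisible(x)
}
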