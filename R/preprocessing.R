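#' Min-max normalization of a raw indicator matrix
#'
#' Rescales each indicator column to [0, 1] over the plots. Benefit
#' indicators use (x - min) / (max - min); cost indicators use the
#' reflection (max - x) / (max - min), so that higher normalized values
#' are always better. The extrema are taken per column, across plots.
#'
#' A constant column (max == min) carries no ranking information; it is
#' mapped to all zeros with a warning rather than raising, so the entropy
#' stage downstream assigns it zero weight.
#'
#' @param x a raw-scale indicator matrix (see [indicator_matrix()]).
#' @param index an \code{index_system} supplying per-indicator direction;
#'   columns of \code{x} must match its indicator ids.
#' @return a normalized-scale indicator matrix of the same shape.
#' @examples
#' idx <- index_system("s", list(s = "a"),
#'   data.frame(id = "X1", name = "x", system = "s", subsystem = "a",
#'              direction = "benefit"))
#' m <- indicator_matrix(matrix(c(1, 3, 5), ncol = 1),
#'                       plot_ids = c("p1", "p2", "p3"),
#'                       indicator_ids = "X1", scale = "raw")
#' minmax_normalize(m, idx)   # 0, 0.5, 1
#' @export
minmax_normalize <- function(x, index) {
  if (matrix_scale(x) != "raw")
    stop("minmax_normalize expects a raw-scale matrix", call. = FALSE)
  ids <- indicator_ids(index)
  if (!identical(colnames(x), ids)) {
    missing_id <- setdiff(ids, colnames(x))
    if (length(missing_id))
      stop("matrix lacks indicator column(s): ",
           paste(missing_id, collapse = ", "), call. = FALSE)
    x <- x[, ids, drop = FALSE]
  }
  dir <- index$indicators$direction
  out <- x
  constant <- character(0)
  for (j in seq_along(ids)) {
    col <- x[, j]
    lo <- min(col); hi <- max(col)
    if (hi == lo) {
      out[, j] <- 0
      constant <- c(constant, ids[j])
    } else if (dir[j] == "benefit") {
      out[, j] <- (col - lo) / (hi - lo)
    } else {
      out[, j] <- (hi - col) / (hi - lo)
    }
  }
  if (length(constant))
    warning("constant column(s) normalized to 0 (no information): ",
            paste(constant, collapse = ", "), call. = FALSE)
  attr(out, "scale") <- "normalized"
  validate_indicator_matrix(out)
}
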