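#' Hierarchical indicator systems
#'
#' An index system is a two-level hierarchy: systems (e.g. \code{vegetation}
#' and \code{soil}) are divided into subsystems (e.g. tree/herb/litter), and
#' each subsystem holds one or more measured indicators. The hierarchy fixes
#' the column order of every indicator matrix downstream and carries, per
#' indicator, the normalization direction (\code{benefit}: larger raw values
#' score higher; \code{cost}: smaller raw values score higher).
#'
#' @param systems character vector of system names, in order.
#' @param subsystems named list mapping each system to its ordered subsystem
#'   names.
#' @param indicators data frame with columns \code{id}, \code{name},
#'   \code{system}, \code{subsystem}, \code{direction} and optionally
#'   \code{units}; row order defines indicator (column) order everywhere.
#' @return An object of class \code{index_system}: a list with elements
#'   \code{systems}, \code{subsystems} and \code{indicators}.
#' @examples
#' idx <- index_system(
#'   systems    = c("vegetation", "soil"),
#'   subsystems = list(vegetation = "tree", soil = "basic"),
#'   indicators = data.frame(
#'     id = c("X1", "X2"), name = c("canopy density", "pH"),
#'     system = c("vegetation", "soil"), subsystem = c("tree", "basic"),
#'     direction = "benefit"))
#' indicator_ids(idx)
#' @seealso [read_index_system()], [pingshuo_index()]
#' @export
index_system <- function(systems, subsystems, indicators) {
  indicators <- as.data.frame(indicators, stringsAsFactors = FALSE)
  if (is.null(indicators$units)) indicators$units <- ""
  indicators <- indicators[, c("id", "name", "system", "subsystem",
                               "direction", "units")]
  obj <- structure(
    list(systems = as.character(systems),
         subsystems = subsystems,
         indicators = indicators),
    class = "index_system")
  validate_index_system(obj)
}

validate_index_system <- function(x) {
  ind <- x$indicators
  required <- c("id", "name", "system", "subsystem", "direction")
  missing_col <- setdiff(required, names(ind))
  if (length(missing_col))
    stop("indicator table lacks column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ind$id))
    stop("duplicate indicator id: ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(x$systems))
    stop("duplicate system name", call. = FALSE)
  if (!setequal(names(x$subsystems), x$systems))
    stop("subsystem map must declare exactly the systems: ",
         paste(x$systems, collapse = ", "), call. = FALSE)
  for (sys in x$systems) {
    if (length(x$subsystems[[sys]]) < 1L)
      stop("system '", sys, "' declares no subsystem", call. = FALSE)
  }
  bad_sys <- setdiff(ind$system, x$systems)
  if (length(bad_sys))
    stop("indicator(s) reference undeclared system: ",
         paste(bad_sys, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(ind))) {
    if (!ind$subsystem[i] %in% x$subsystems[[ind$system[i]]])
      stop("indicator '", ind$id[i], "' references subsystem '",
           ind$subsystem[i], "' not declared under system '",
           ind$system[i], "'", call. = FALSE)
  }
  # every declared subsystem must own at least one indicator
  for (sys in x$systems) for (sub in x$subsystems[[sys]]) {
    if (!any(ind$system == sys & ind$subsystem == sub))
      stop("subsystem '", sub, "' of system '", sys,
           "' has no indicators", call. = FALSE)
  }
  bad_dir <- setdiff(unique(ind$direction), c("benefit", "cost"))
  if (length(bad_dir))
    stop("direction must be 'benefit' or 'cost', got: ",
         paste(bad_dir, collapse = ", "), call. = FALSE)
  x
}

#' @export
print.index_system <- function(x, ...) {
  cat("Index system:", length(x$systems), "systems,",
      sum(lengths(x$subsystems)), "subsystems,",
      nrow(x$indicators), "indicators\n")
  for (sys in x$systems) {
    cat("  ", sys, ":\n", sep = "")
    for (sub in x$subsystems[[sys]]) {
      ids <- x$indicators$id[x$indicators$system == sys &
                             x$indicators$subsystem == sub]
      cat("    ", sub, ": ", paste(ids, collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' @rdname index_system
#' @param index an \code{index_system} object.
#' @export
indicator_ids <- function(index) index$indicators$id

#' Indicator ids belonging to one subsystem (or one system)
#'
#' @param index an \code{index_system}.
#' @param system system name.
#' @param subsystem subsystem name; if omitted, all indicators of the system.
#' @return character vector of indicator ids, in index order.
#' @export
subsystem_indicators <- function(index, system, subsystem = NULL) {
  ind <- index$indicators
  keep <- ind$system == system
  if (!is.null(subsystem)) keep <- keep & ind$subsystem == subsystem
  ind$id[keep]
}

#' Read or write an index system as YAML/JSON
#'
#' The config declares \code{systems} (list of names), \code{subsystems}
#' (map system -> names) and \code{indicators} (list of records with
#' \code{id}, \code{name}, \code{system}, \code{subsystem},
#' \code{direction}, \code{units}). Format is inferred from the file
#' extension (\code{.yaml}/\code{.yml} or \code{.json}).
#'
#' @param path file path.
#' @return \code{read_index_system} returns a validated
#'   \code{index_system}; \code{write_index_system} returns \code{path}
#'   invisibly.
#' @export
read_index_system <- function(path) {
  cfg <- read_config(path)
  for (key in c("systems", "subsystems", "indicators")) {
    if (is.null(cfg[[key]]))
      stop("index-system config lacks key '", key, "'", call. = FALSE)
  }
  ind <- do.call(rbind, lapply(cfg$indicators, function(rec) {
    for (f in c("id", "name", "system", "subsystem", "direction")) {
      if (is.null(rec[[f]]))
        stop("indicator record ",
             if (!is.null(rec$id)) paste0("'", rec$id, "' ") else "",
             "lacks field '", f, "'", call. = FALSE)
    }
    data.frame(id = rec$id, name = rec$name, system = rec$system,
               subsystem = rec$subsystem, direction = rec$direction,
               units = if (is.null(rec$units)) "" else rec$units,
               stringsAsFactors = FALSE)
  }))
  subs <- lapply(cfg$subsystems, function(s) as.character(unlist(s)))
  index_system(as.character(unlist(cfg$systems)), subs, ind)
}

#' @rdname read_index_system
#' @param index an \code{index_system} to serialize.
#' @export
write_index_system <- function(index, path) {
  ind_records <- lapply(seq_len(nrow(index$indicators)), function(i)
    as.list(index$indicators[i, ]))
  cfg <- list(systems = as.list(index$systems),
              subsystems = lapply(index$subsystems, as.list),
              indicators = ind_records)
  write_config(cfg, path)
  invisible(path)
}

# -- indicator matrices -------------------------------------------------------

#' Plot-by-indicator matrices
#'
#' An indicator matrix is a base numeric matrix with plot labels as row
#' names, indicator ids as column names (in index order), and a
#' \code{"scale"} attribute, either \code{"raw"} or \code{"normalized"}.
#' All entries must be finite; normalized entries must lie in [0, 1].
#'
#' @param values numeric matrix (plots x indicators) or object coercible
#'   to one.
#' @param plot_ids row labels; defaults to existing row names.
#' @param indicator_ids column labels; defaults to existing column names.
#' @param scale \code{"raw"} or \code{"normalized"}.
#' @return a validated numeric matrix with the \code{"scale"} attribute set.
#' @export
indicator_matrix <- function(values, plot_ids = rownames(values),
                             indicator_ids = colnames(values),
                             scale = c("raw", "normalized")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- plot_ids
  colnames(values) <- indicator_ids
  attr(values, "scale") <- scale
  validate_indicator_matrix(values)
}

validate_indicator_matrix <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("indicator matrix needs plot row names and indicator column names",
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate plot label: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(x)))
    stop("indicator matrix contains missing or non-finite values",
         call. = FALSE)
  scl <- attr(x, "scale")
  if (is.null(scl) || !scl %in% c("raw", "normalized"))
    stop("indicator matrix must carry scale 'raw' or 'normalized'",
         call. = FALSE)
  if (scl == "normalized" && (min(x) < 0 || max(x) > 1))
    stop("normalized matrix has values outside [0, 1]", call. = FALSE)
  x
}

#' Scale of an indicator matrix
#' @param x an indicator matrix.
#' @return \code{"raw"} or \code{"normalized"}.
#' @export
matrix_scale <- function(x) attr(x, "scale")

#' Read or write a plot-by-indicator table
#'
#' The delimited table (CSV, or TSV by extension) has a first column of
#' plot labels and one column per indicator id. Columns are reordered to
#' follow the index; extra columns are ignored with a message.
#'
#' @param path file path (\code{.csv} or \code{.tsv}).
#' @param index an \code{index_system} defining the expected columns and
#'   their order.
#' @return \code{read_indicator_matrix}: a raw-scale indicator matrix.
#' @export
read_indicator_matrix <- function(path, index) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("matrix table needs a plot-label column plus indicator columns",
         call. = FALSE)
  ids <- indicator_ids(index)
  missing_id <- setdiff(ids, names(tab)[-1L])
  if (length(missing_id))
    stop("matrix table lacks indicator column(s): ",
         paste(missing_id, collapse = ", "), call. = FALSE)
  plots <- as.character(tab[[1L]])
  vals <- tab[, ids, drop = FALSE]
  non_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(non_num))
    stop("non-numeric values in column(s): ",
         paste(non_num, collapse = ", "), call. = FALSE)
  indicator_matrix(as.matrix(vals), plot_ids = plots,
                   indicator_ids = ids, scale = "raw")
}

#' @rdname read_indicator_matrix
#' @param x an indicator matrix to serialize.
#' @export
write_indicator_matrix <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- data.frame(plot = rownames(x), as.data.frame(unclass(x)),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# -- config helpers -----------------------------------------------------------

read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

write_config <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Bundled Pingshuo opencast-mine index system
#'
#' The two-system, five-subsystem, eighteen-indicator hierarchy used to
#' assess soil-vegetation co-development on reclaimed mine dumps:
#' vegetation (tree, herb, litter layers; X1-X9) and soil (basic and
#' nutrient properties; X10-X18). All indicators default to benefit
#' direction so that published composite scores are reproduced; pH and
#' bulk density can be switched to cost in a custom config.
#'
#' @return an \code{index_system} with 18 indicators.
#' @export
pingshuo_index <- function() {
  read_index_system(system.file("extdata", "pingshuo_index.yaml",
                                package = "ccdeval", mustWork = TRUE))
}

#' Bundled subsystem-weight config for the Pingshuo index system
#'
#' Direct subsystem weights (tree/herb/litter within vegetation and
#' basic/nutrient within soil) matching the published per-system weight
#' blocks. The original pairwise judgment matrices were not published, so
#' the fixture carries the implied subsystem weights directly.
#'
#' @return path to the YAML config, for use as the \code{ahp} argument of
#'   [ccd()].
#' @export
pingshuo_ahp <- function() {
  system.file("extdata", "pingshuo_ahp.yaml",
              package = "ccdeval", mustWork = TRUE)
}

#' Published per-plot comprehensive scores for the Pingshuo plots
#'
#' The reported vegetation (V) and soil (S) comprehensive evaluation
#' scores of the five study plots (four 23-year reclaimed mine-dump
#' plots, RUA/RP/RM/PM, plus the undisturbed reference OP). Useful as
#' targets for [scenario_from_scores()] to rebuild an executable fixture
#' when the underlying survey table is unavailable.
#'
#' @return data frame with columns \code{plot}, \code{V}, \code{S}.
#' @export
pingshuo_scores <- function() {
  utils::read.csv(system.file("extdata", "pingshuo_scores.csv",
                              package = "ccdeval", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
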