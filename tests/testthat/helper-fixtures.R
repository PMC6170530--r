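# Small index systems and matrices built in code for the tests.

# one system, one subsystem, configurable indicator count/directions
tiny_index <- function(n = 1L, direction = "benefit", system = "s",
                       subsystem = "a") {
  index_system(
    systems = system,
    subsystems = stats::setNames(list(subsystem), system),
    indicators = data.frame(
      id = paste0("X", seq_len(n)), name = paste0("ind", seq_len(n)),
      system = system, subsystem = subsystem,
      direction = rep_len(direction, n), stringsAsFactors = FALSE))
}

# two systems ("veg", "soil"), one subsystem each, n indicators per system
two_system_index <- function(n_per_system = 2L) {
  n <- n_per_system
  index_system(
    systems = c("veg", "soil"),
    subsystems = list(veg = "a", soil = "b"),
    indicators = data.frame(
      id = paste0("X", seq_len(2L * n)),
      name = paste0("ind", seq_len(2L * n)),
      system = rep(c("veg", "soil"), each = n),
      subsystem = rep(c("a", "b"), each = n),
      direction = "benefit", stringsAsFactors = FALSE))
}

norm_matrix <- function(values, ids, plots = NULL) {
  values <- as.matrix(values)
  if (is.null(plots)) plots <- paste0("p", seq_len(nrow(values)))
  indicator_matrix(values, plot_ids = plots, indicator_ids = ids,
                   scale = "normalized")
}

raw_matrix <- function(values, ids, plots = NULL) {
  values <- as.matrix(values)
  if (is.null(plots)) plots <- paste0("p", seq_len(nrow(values)))
  indicator_matrix(values, plot_ids = plots, indicator_ids = ids,
                   scale = "raw")
}

# reciprocal pairwise matrix built from a weight vector: a_ij = w_i / w_j
consistent_pcm <- function(w) {
  outer(w, w, "/")
}

# fit the published five-plot scores through the whole pipeline
fit_pingshuo <- function(...) {
  idx <- pingshuo_index()
  t5 <- pingshuo_scores()
  sc <- scenario_from_scores(stats::setNames(t5$V, t5$plot),
                             stats::setNames(t5$S, t5$plot), idx)
  ccd(generate_matrix(sc), idx, pingshuo_ahp(),
      exclude_plots = attr(sc, "anchor_plots"), ...)
}
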