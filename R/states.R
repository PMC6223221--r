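#' Methylation-state thresholds
#'
#' Two cut points discretising a methylation fraction into hypo, moderate and
#' hyper states. Values at or below `hypo_max` are hypo-methylated, values at
#' or above `hyper_min` hyper-methylated, everything between moderate. The
#' defaults (0.3 / 0.7) are conventional WGBS cut-offs; both are echoed into
#' pipeline output metadata because downstream counts depend on them.
#'
#' @param hypo_max upper bound (inclusive) of the hypo-methylated state.
#' @param hyper_min lower bound (inclusive) of the hyper-methylated state.
#' @return List of class `state_thresholds`.
#' @export
state_thresholds <- function(hypo_max = 0.3, hyper_min = 0.7) {
  if (!is.numeric(hypo_max) || !is.numeric(hyper_min) ||
      hypo_max < 0 || hyper_min > 1 || hypo_max >= hyper_min) {
    stop("need 0 <= hypo_max < hyper_min <= 1")
  }
  structure(list(hypo_max = hypo_max, hyper_min = hyper_min),
            class = "state_thresholds")
}

#' The three methylation state labels, in increasing order
#' @return `c("hypo", "moderate", "hyper")`
#' @export
state_levels <- function() c("hypo", "moderate", "hyper")

#' Classify methylation values into hypo/moderate/hyper states
#'
#' Works on whole-gene methylation as well as on any single region or bin
#' slice of a `stage_summary`. Missing values stay unclassified (`NA`).
#'
#' @param values numeric vector of methylation fractions (may contain `NA`);
#'   names are preserved.
#' @param thresholds a [state_thresholds()] object.
#' @return Factor over `hypo < moderate < hyper`, `NA` for missing input.
#' @export
classify_states <- function(values, thresholds = state_thresholds()) {
  stopifnot(inherits(thresholds, "state_thresholds"))
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    stop("methylation values must lie in [0, 1]")
  }
  st <- ifelse(is.na(values), NA_character_,
               ifelse(values <= thresholds$hypo_max, "hypo",
                      ifelse(values >= thresholds$hyper_min, "hyper",
                             "moderate")))
  out <- factor(st, levels = state_levels())
  names(out) <- names(values)
  out
}

#' Count methylation-state transitions between two stages
#'
#' Cross-tabulates per-gene states at two stages over the genes classified in
#' both; genes unclassified in either stage are excluded and counted.
#' Headline aggregates (hypo to hyper, maintained hypo, hyper to hypo) are
#' reported alongside the full 3 x 3 matrix.
#'
#' @param states_a,states_b named factors from [classify_states()] over the
#'   same gene universe (the name sets must intersect).
#' @return List of class `transition_counts` with elements `counts` (3 x 3
#'   integer matrix, rows = state at stage A, columns = state at stage B),
#'   `excluded` (genes unclassified in either stage), `hypo_to_hyper`,
#'   `maintained_hypo` and `hyper_to_hypo`.
#' @export
transitions <- function(states_a, states_b) {
  if (is.null(names(states_a)) || is.null(names(states_b))) {
    stop("states must be named by gene")
  }
  common <- intersect(names(states_a), names(states_b))
  if (length(common) == 0L) {
    stop("the two state vectors share no genes")
  }
  a <- factor(as.character(states_a[common]), levels = state_levels())
  b <- factor(as.character(states_b[common]), levels = state_levels())
  both <- !is.na(a) & !is.na(b)
  counts <- table(from = a[both], to = b[both])
  counts <- matrix(as.integer(counts), nrow = 3, ncol = 3,
                   dimnames = list(from = state_levels(),
                                   to = state_levels()))
  structure(list(
    counts = counts,
    excluded = sum(!both),
    hypo_to_hyper = counts["hypo", "hyper"],
    maintained_hypo = counts["hypo", "hypo"],
    hyper_to_hypo = counts["hyper", "hypo"]
  ), class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  print(x$counts)
  cat("hypo->hyper:", x$hypo_to_hyper,
      " maintained hypo:", x$maintained_hypo,
      " hyper->hypo:", x$hyper_to_hypo,
      " excluded:", x$excluded, "\n")
  invisible(x)
}
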