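#' Current-clamp input-output (excitability) curve
#'
#' Action-potential counts evoked by depolarizing current steps of
#' increasing amplitude (500 ms steps from a -60 mV holding potential by
#' convention).
#'
#' @param current_steps strictly increasing injected currents (pA).
#' @param ap_counts AP counts per step (may be non-integer for averaged
#'   curves).
#' @param step_duration current step duration (s).
#' @param holding_potential holding potential (mV).
#' @return an object of class \code{excitability_curve}.
#' @export
excitability_curve <- function(current_steps, ap_counts, step_duration = 0.5,
                               holding_potential = -60) {
  if (length(current_steps) != length(ap_counts)) {
    stop("'current_steps' and 'ap_counts' must have equal length", call. = FALSE)
  }
  if (any(diff(current_steps) <= 0)) {
    stop("'current_steps' must be strictly increasing", call. = FALSE)
  }
  if (any(ap_counts < 0)) stop("'ap_counts' must be >= 0", call. = FALSE)
  structure(list(current_steps = as.numeric(current_steps),
                 ap_counts = as.numeric(ap_counts),
                 step_duration = step_duration,
                 holding_potential = holding_potential),
            class = "excitability_curve")
}

#' Cohort-averaged excitability curve
#'
#' Resamples every cell's curve onto the union current grid by linear
#' interpolation within its observed span (no extrapolation) and averages
#' AP counts pointwise across contributing cells.
#'
#' @param curves list of \code{\link{excitability_curve}} objects.
#' @return an object of class \code{cohort_curve} with the common grid,
#'   mean AP counts and per-step n.
#' @export
cohort_curve <- function(curves) {
  if (!length(curves)) stop("empty cohort", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, logical(1), "excitability_curve")))
  grid <- sort(unique(unlist(lapply(curves, `[[`, "current_steps"))))
  mat <- vapply(curves, function(cv) {
    if (length(cv$current_steps) == 1L) {
      ifelse(grid == cv$current_steps, cv$ap_counts, NA_real_)
    } else {
      approx(cv$current_steps, cv$ap_counts, xout = grid, rule = 1)$y
    }
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  n <- rowSums(!is.na(mat))
  structure(list(current_grid = grid,
                 mean_counts = rowMeans(mat, na.rm = TRUE),
                 n = n),
            class = "cohort_curve")
}

#' Rheobase from a cohort-averaged excitability curve
#'
#' Averages AP counts pointwise across cells and returns the current at the
#' first upward crossing of mean count = 1, linearly interpolated between
#' the bracketing current steps. If the first grid point already has mean
#' >= 1, that grid point is returned. When the averaged curve never reaches
#' 1 AP the result carries \code{rheobase = NA} (a no-rheobase outcome,
#' distinct from 0 pA).
#'
#' @param curves list of \code{\link{excitability_curve}} objects (or a
#'   single curve).
#' @return an object of class \code{rheobase_estimate} with elements
#'   \code{rheobase} (pA or \code{NA}) and \code{curve} (the
#'   \code{\link{cohort_curve}}).
#' @export
rheobase_from_cohort <- function(curves) {
  if (inherits(curves, "excitability_curve")) curves <- list(curves)
  cc <- cohort_curve(curves)
  keep <- cc$n >= 1L
  grid <- cc$current_grid[keep]
  m <- cc$mean_counts[keep]
  rheo <- NA_real_
  if (length(m) && any(m >= 1)) {
    k <- which(m >= 1)[1]
    rheo <- if (k == 1L) {
      grid[1]
    } else {
      grid[k - 1L] + (1 - m[k - 1L]) / (m[k] - m[k - 1L]) * (grid[k] - grid[k - 1L])
    }
  }
  structure(list(rheobase = rheo, curve = cc), class = "rheobase_estimate")
}

#' @export
print.rheobase_estimate <- function(x, ...) {
  if (is.na(x$rheobase)) {
    cat("<rheobase_estimate> averaged curve never reaches 1 AP (no rheobase)\n")
  } else {
    cat(sprintf("<rheobase_estimate> %.3f pA (1-AP crossing of the cohort-averaged curve)\n",
                x$rheobase))
  }
  invisible(x)
}

#' Classify a neuron as spontaneously active
#'
#' A cell is spontaneously active when at least one action potential is
#' observed within the observation window at zero holding current.
#'
#' @param ap_count APs observed in the window.
#' @param window observation window (s).
#' @param holding_current holding current (pA); the convention is 0.
#' @return logical.
#' @export
classify_spontaneous <- function(ap_count, window = 60, holding_current = 0) {
  stopifnot_scalar(window, "window", positive = TRUE)
  ap_count >= 1
}
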