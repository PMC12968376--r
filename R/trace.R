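#' Per-revolution sprint trace
#'
#' The unit of all fitting: an ordered set of per-revolution observations
#' (1-based stroke index, end-of-revolution time stamp, cadence, mean pedal
#' force, mean power), with the protocol metadata needed to interpret it.
#' Time stamps are the cumulative sum of revolution durations, so the model
#' equations are evaluated at end-of-revolution times throughout.
#'
#' @param revolutions Data frame with columns `index_n` (1-based, consecutive),
#'   `t_s` (strictly increasing), `cadence_rpm`, `force_N`, `power_W`.
#' @param target_cadence_rpm Enforced isokinetic cadence (rpm).
#' @param geometry A [crank_geometry()].
#' @param protocol `"isokinetic_45s"` or `"motoric_6s"`.
#' @param meta Optional named list of extra metadata (seed, truth parameters).
#' @return An object of class `sprint_trace`.
#' @export
sprint_trace <- function(revolutions, target_cadence_rpm,
                         geometry = crank_geometry(),
                         protocol = c("isokinetic_45s", "motoric_6s"),
                         meta = list()) {
  protocol <- match.arg(protocol)
  req <- c("index_n", "t_s", "cadence_rpm", "force_N", "power_W")
  missing_cols <- setdiff(req, names(revolutions))
  if (length(missing_cols)) {
    stop("trace is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(revolutions) == 0L) stop("trace has no revolutions", call. = FALSE)
  if (any(diff(revolutions$t_s) <= 0)) stop("times must be increasing", call. = FALSE)
  if (any(diff(revolutions$index_n) != 1L)) {
    stop("index_n must increase by 1", call. = FALSE)
  }
  structure(list(revolutions = revolutions,
                 target_cadence_rpm = target_cadence_rpm,
                 geometry = geometry, protocol = protocol, meta = meta),
            class = "sprint_trace")
}

#' @export
print.sprint_trace <- function(x, ...) {
  r <- x$revolutions
  cat(sprintf("Sprint trace (%s): %d revolutions over %.1f s, target %g rpm\n",
              x$protocol, nrow(r), max(r$t_s), x$target_cadence_rpm))
  cat(sprintf("  peak power %.0f W, final power %.0f W\n",
              max(r$power_W), r$power_W[nrow(r)]))
  invisible(x)
}

#' Cadence series of a trace
#'
#' Builds the [cadence_series()] implied by a trace for stroke/time
#' conversion, anchored at t = 0 with the first revolution's cadence held
#' constant back to the start (stationary-start ramp is inside revolution 1).
#'
#' @param trace A [sprint_trace()].
#' @return A [cadence_series()].
#' @export
trace_cadence_series <- function(trace) {
  r <- trace$revolutions
  cadence_series(c(0, r$t_s), c(r$cadence_rpm[1], r$cadence_rpm))
}

#' Indices of at-target (isokinetic) revolutions
#'
#' Revolutions from the first at/above the target cadence to the end of the
#' trace; the common scoring window for all model variants.
#'
#' @param trace A [sprint_trace()].
#' @param tol Relative tolerance on reaching the target (default 0.5%).
#' @return Integer row indices.
#' @export
isokinetic_window <- function(trace, tol = 0.005) {
  r <- trace$revolutions
  first <- which(r$cadence_rpm >= trace$target_cadence_rpm * (1 - tol))[1]
  if (is.na(first)) stop("trace never reaches the target cadence", call. = FALSE)
  seq.int(first, nrow(r))
}
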