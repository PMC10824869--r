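#' Parameters of the rubble accumulation decision tree
#'
#' Bundles the four tunable quantities the moving-window classifier uses and
#' validates their invariants. Defaults are the base case used throughout:
#' a 50-m half-window (5 samples at 10-m spacing), a 0.5-m problematic rubble
#' thickness, a 5-m relief limit beyond which rubble rolls away, and a 0.5-m
#' depth variation still considered flat.
#'
#' @param moving_window_m Half-width, in metres, of the along-track window
#'   centred on the focal point over which local relief is evaluated.
#' @param rubble_height_m Minimum thickness (m) of an accumulated rubble layer
#'   that is problematic for coral recovery; also the depth by which a
#'   depression must exceed its flanks to trap such a layer.
#' @param roll_depth_range_m Depth range (m) within the window at or beyond
#'   which the focal point is on or near a steep slope and rubble rolls off.
#' @param flat_depth_change_m Maximum depth variation (m) within the window
#'   for the neighbourhood to count as flat.
#' @return An object of class `rubble_params`.
#' @examples
#' rubble_params()                      # base case
#' rubble_params(moving_window_m = 60)  # widened window
#' @export
rubble_params <- function(moving_window_m = 50,
                          rubble_height_m = 0.5,
                          roll_depth_range_m = 5,
                          flat_depth_change_m = 0.5) {
  vals <- c(moving_window_m = moving_window_m,
            rubble_height_m = rubble_height_m,
            roll_depth_range_m = roll_depth_range_m,
            flat_depth_change_m = flat_depth_change_m)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all rubble parameters must be finite and > 0", call. = FALSE)
  }
  if (flat_depth_change_m >= roll_depth_range_m) {
    stop("flat_depth_change_m must be smaller than roll_depth_range_m",
         call. = FALSE)
  }
  structure(
    list(moving_window_m = moving_window_m,
         rubble_height_m = rubble_height_m,
         roll_depth_range_m = roll_depth_range_m,
         flat_depth_change_m = flat_depth_change_m),
    class = "rubble_params"
  )
}

#' @export
print.rubble_params <- function(x, ...) {
  cat("Rubble accumulation parameters:\n")
  cat(sprintf("  moving window (half-width): %g m (%d samples each side)\n",
              x$moving_window_m, window_half_width(x$moving_window_m)))
  cat(sprintf("  rubble height:              %g m\n", x$rubble_height_m))
  cat(sprintf("  roll depth range:           %g m\n", x$roll_depth_range_m))
  cat(sprintf("  flat depth change:          %g m\n", x$flat_depth_change_m))
  invisible(x)
}

#' Window half-width in samples
#'
#' Converts the moving-window half-width from metres to a number of 10-m
#' samples, rounding to the nearest sample so that perturbed windows (e.g.
#' 40 m or 60 m from a +/-20% sensitivity scenario) map onto the sampling
#' lattice.
#'
#' @param moving_window_m Half-width in metres.
#' @param spacing_m Along-track sample spacing (default 10 m).
#' @return Integer number of samples each side of the focal point.
#' @export
window_half_width <- function(moving_window_m, spacing_m = 10) {
  h <- as.integer(round(moving_window_m / spacing_m))
  max(h, 1L)
}

#' Scale one parameter of a base case
#'
#' Helper for one-at-a-time sensitivity scenarios: returns a copy of `params`
#' with a single named parameter multiplied by `factor`. Invalid results
#' (violating the parameter invariants) raise the same errors as
#' [rubble_params()].
#'
#' @param params A `rubble_params` object.
#' @param name One of `"moving_window_m"`, `"rubble_height_m"`,
#'   `"roll_depth_range_m"`, `"flat_depth_change_m"`.
#' @param factor Multiplicative perturbation (e.g. 0.8 or 1.2).
#' @return A new `rubble_params` object.
#' @export
scale_param <- function(params, name, factor) {
  stopifnot(inherits(params, "rubble_params"))
  name <- match.arg(name, names(unclass(params)))
  vals <- unclass(params)
  vals[[name]] <- vals[[name]] * factor
  do.call(rubble_params, vals)
}
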