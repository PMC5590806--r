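#' Position where a profile falls to half its maximum
#'
#' Scans the profile from the ventral end and returns the first position
#' (linear interpolation between nodes) where the value drops to half of the
#' profile maximum. Profiles that never cross half-maximum (e.g. constants)
#' return the axis length.
#'
#' @param profile Per-node values, ventral to dorsal; `max(profile) > 0`.
#' @param x Node positions; defaults to an even grid over `axis_length`.
#' @param axis_length Axis length used when `x` is not given (default 700).
#' @return Position in micrometres from the ventral end.
#' @export
half_max_position <- function(profile, x = NULL, axis_length = 700) {
  if (max(profile) <= 0) abort("`profile` must have a positive maximum.")
  n <- length(profile)
  if (is.null(x)) x <- seq(0, axis_length, length.out = n)
  half <- max(profile) / 2
  below <- which(profile < half)
  if (length(below) == 0) return(x[n])
  j <- below[1]
  if (j == 1) return(x[1])
  # linear interpolation between node j-1 (>= half) and node j (< half)
  x[j - 1] + (x[j] - x[j - 1]) * (profile[j - 1] - half) /
    (profile[j - 1] - profile[j])
}

#' Classify the gradient-forming mechanism of one fitted solution
#'
#' Assigns exactly one label to a solution that passed the wild-type gate, in
#' fixed precedence order:
#'
#' 1. **shuttling** -- the ventral-most BMP level in the Chordin null is at
#'    least `shuttling_drop` (20%) lower than in wild type: Chordin was moving
#'    ligand into the ventral peak.
#' 2. **transcriptional** -- at least `transcriptional_fraction` (80%) of the
#'    BMP produced in its production region is degraded there or accumulates
#'    there: the gradient mirrors transcription.
#' 3. **source_sink** -- more BMP leaves the production region by net
#'    diffusion than is bound there by Chordin; otherwise
#'    **counter_gradient**.
#'
#' Solutions with zero production are `unclassified`.
#'
#' @param balance A [mass_balance()] row computed over the BMP production
#'   region of the wild-type simulation.
#' @param B_wt,B_chd_null Per-node final BMP profiles of the wild-type and
#'   Chordin-null simulations.
#' @param cfg A [fit_config()].
#' @return One of `"shuttling"`, `"transcriptional"`, `"source_sink"`,
#'   `"counter_gradient"`, `"unclassified"`.
#' @export
classify_mechanism <- function(balance, B_wt, B_chd_null, cfg = fit_config()) {
  if (balance$produced <= 0) return("unclassified")
  if (B_wt[1] > 0 &&
      B_chd_null[1] <= (1 - cfg$shuttling_drop) * B_wt[1]) {
    return("shuttling")
  }
  if ((balance$decayed + balance$accumulated) / balance$produced >=
      cfg$transcriptional_fraction) {
    return("transcriptional")
  }
  if (balance$net_diffused_out > balance$net_bound_chd) {
    "source_sink"
  } else {
    "counter_gradient"
  }
}

#' Does a solution reproduce Drosophila-like dorsoventral patterning?
#'
#' A solution is Drosophila-like iff (a) its wild-type gradient reaches
#' half-maximum within `droso_halfmax_fraction` (10%) of the axis, (b) the
#' ventral peak of the Chordin null is at least `droso_peak_drop` (50%) lower
#' than wild type, and (c) net BMP-Noggin binding is below
#' `droso_max_nog_bound_fraction` (5%) of produced BMP (flies have no noggin).
#' This track is independent of the wild-type data gate.
#'
#' @inheritParams classify_mechanism
#' @param axis_length Axis length in micrometres.
#' @return Logical flag.
#' @export
drosophila_like <- function(balance, B_wt, B_chd_null, cfg = fit_config(),
                            axis_length = 700) {
  if (max(B_wt) <= 0 || balance$produced <= 0) return(FALSE)
  hm <- half_max_position(B_wt, axis_length = axis_length)
  steep <- hm / axis_length < cfg$droso_halfmax_fraction
  drop <- B_wt[1] > 0 &&
    B_chd_null[1] <= (1 - cfg$droso_peak_drop) * B_wt[1]
  nog_ok <- balance$net_bound_nog / balance$produced <
    cfg$droso_max_nog_bound_fraction
  isTRUE(steep && drop && nog_ok)
}

#' Robustness of a fitted solution to ubiquitous Chordin production
#'
#' A solution retains a wild-type BMP gradient under uniform Chordin
#' production iff the NRMSD between its scaled uniform-Chordin BMP profile
#' and the wild-type target is at most the gate threshold, using the
#' wild-type-derived scale factor (boundary inclusive).
#'
#' @param B_chd_uniform Per-node final BMP profile of the `chd_uniform`
#'   simulation.
#' @param target_wt Per-node wild-type target.
#' @param s Scale factor fitted on the wild-type pair.
#' @param cfg A [fit_config()].
#' @return Logical flag.
#' @export
uniform_chd_robust <- function(B_chd_uniform, target_wt, s,
                               cfg = fit_config()) {
  if (is.null(B_chd_uniform)) {
    abort("A `chd_uniform` simulation is required for the robustness test.")
  }
  if (is.na(s)) return(FALSE)
  nrmsd(s * B_chd_uniform, target_wt) <= cfg$nrmsd_threshold
}
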