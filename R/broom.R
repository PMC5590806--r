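#' Tidy a simulation result into long format
#'
#' @param x A `dv_sim` from [simulate_gradient()].
#' @param ... Unused.
#' @return A tibble with columns `node`, `x`, `species`, `concentration`.
#' @method tidy dv_sim
#' @export
tidy.dv_sim <- function(x, ...) {
  if (!x$success) return(tibble(node = integer(), x = numeric(),
                                species = character(),
                                concentration = numeric()))
  tidyr::pivot_longer(x$final, cols = c("B", "C", "N", "BC", "BN"),
                      names_to = "species", values_to = "concentration")
}

#' One-row summary of a simulation
#'
#' @param x A `dv_sim`.
#' @param ... Unused.
#' @return A tibble with the genotype, success flag, tolerance, peak free-BMP
#'   concentration and the minimum concentration seen (non-negativity check).
#' @method glance dv_sim
#' @export
glance.dv_sim <- function(x, ...) {
  tibble(
    genotype = x$genotype, success = x$success, rtol = x$rtol,
    peak_B = if (x$success) max(x$final$B) else NA_real_,
    min_conc = if (x$success) x$min_conc else NA_real_
  )
}

#' Per-start results of a diffusivity fit
#'
#' @param x A `frap_fit` from [estimate_diffusivity()].
#' @param ... Unused.
#' @return A tibble with one row per optimizer start: starting value `D0`,
#'   fitted `D`, objective, convergence flag and iteration count.
#' @method tidy frap_fit
#' @export
tidy.frap_fit <- function(x, ...) x$starts

#' One-row summary of a diffusivity fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return A tibble with `D_hat` (um^2/s), the objective at the optimum, the
#'   number of converged starts and the number of data points fitted.
#' @method glance frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(
    D_hat = x$D_hat, objective = x$objective,
    n_starts = nrow(x$starts), n_converged = sum(x$starts$converged),
    n_obs = sum(!is.na(x$curve$intensity))
  )
}

#' Summary counts of a screen store
#'
#' @param x A `dv_screen`.
#' @param ... Unused.
#' @return A tibble with completed/total sample counts and solver failures.
#' @method glance dv_screen
#' @export
glance.dv_screen <- function(x, ...) {
  tibble(
    n = x$manifest$n,
    completed = x$manifest$last_completed,
    seed = x$manifest$seed,
    solver_failures = if (is.null(x$flags)) 0L else sum(!x$flags$success)
  )
}

#' Label counts of a classified screen
#'
#' @param x A `dv_classification` from [classify_screen()].
#' @param ... Unused.
#' @return A one-row tibble: gated counts, per-label counts among solutions
#'   passing all gates, and the Drosophila-like count.
#' @method glance dv_classification
#' @export
glance.dv_classification <- function(x, ...) {
  fitted <- x[x$pass_all, , drop = FALSE]
  tibble(
    n = nrow(x),
    n_pass_wt = sum(x$pass_wt),
    n_pass_all = nrow(fitted),
    source_sink = sum(fitted$label == "source_sink"),
    counter_gradient = sum(fitted$label == "counter_gradient"),
    transcriptional = sum(fitted$label == "transcriptional"),
    shuttling = sum(fitted$label == "shuttling"),
    drosophila_like = sum(x$droso, na.rm = TRUE)
  )
}
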