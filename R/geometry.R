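#' Embryo axis geometry for the 1D reaction-diffusion model
#'
#' The zebrafish gastrula margin is reduced to a one-dimensional
#' half-circumference running from the ventral-most point (`x = 0`) to the
#' dorsal-most point (`x = axis_length`). Expression domains of *chordin* and
#' *noggin* are anchored at the dorsal end, the Tolloid activity domain at the
#' ventral end. The axis is discretized into `n_nodes` equidistant node points;
#' spatial integrals use trapezoidal weights so that the discrete zero-flux
#' Laplacian conserves mass exactly.
#'
#' @param axis_length Half-circumference in micrometres (default 700).
#' @param n_nodes Number of finite-difference nodes (default 36).
#' @param chd_domain_length Chordin production domain, micrometres measured
#'   from the dorsal end (default 145).
#' @param nog_domain_length Noggin production domain, micrometres from the
#'   dorsal end (default 78).
#' @param tld_domain_length Tolloid activity domain, micrometres from the
#'   ventral end (default 400).
#' @param t_final Length of the simulated developmental window in seconds
#'   (default 7800 s = 130 min, roughly 3.5 to 5.7 hpf).
#'
#' @return An object of class `dv_geometry`: a list with the arguments above
#'   plus `x` (node positions, ventral to dorsal), `dx` (node spacing) and
#'   `weights` (trapezoidal quadrature weights, micrometres).
#' @examples
#' geom <- dv_geometry()
#' geom$dx # 20 um
#' @export
dv_geometry <- function(axis_length = 700, n_nodes = 36,
                        chd_domain_length = 145, nog_domain_length = 78,
                        tld_domain_length = 400, t_final = 7800) {
  if (!is.numeric(axis_length) || length(axis_length) != 1 || axis_length <= 0) {
    abort("`axis_length` must be a single positive number.")
  }
  if (!is.numeric(n_nodes) || length(n_nodes) != 1 || n_nodes < 3 ||
      n_nodes != round(n_nodes)) {
    abort("`n_nodes` must be an integer >= 3.")
  }
  for (nm in c("chd_domain_length", "nog_domain_length", "tld_domain_length")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > axis_length) {
      abort(sprintf("`%s` must lie in [0, axis_length].", nm))
    }
  }
  if (t_final <= 0) abort("`t_final` must be positive.")
  n_nodes <- as.integer(n_nodes)
  dx <- axis_length / (n_nodes - 1)
  w <- rep(dx, n_nodes)
  w[c(1, n_nodes)] <- dx / 2
  structure(
    list(
      axis_length = axis_length, n_nodes = n_nodes,
      chd_domain_length = chd_domain_length,
      nog_domain_length = nog_domain_length,
      tld_domain_length = tld_domain_length,
      t_final = t_final,
      x = seq(0, axis_length, length.out = n_nodes),
      dx = dx, weights = w
    ),
    class = "dv_geometry"
  )
}

#' @export
print.dv_geometry <- function(x, ...) {
  cat(sprintf(
    "<dv_geometry> %g um axis, %d nodes (dx = %.3g um), t_final = %g s\n",
    x$axis_length, x$n_nodes, x$dx, x$t_final
  ))
  cat(sprintf(
    "  domains: chd %g um (dorsal), nog %g um (dorsal), tld %g um (ventral)\n",
    x$chd_domain_length, x$nog_domain_length, x$tld_domain_length
  ))
  invisible(x)
}
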