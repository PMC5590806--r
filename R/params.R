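#' Biophysical parameter vector for the five-species model
#'
#' Collects the production, decay, diffusion, binding and Tolloid-cleavage
#' rates of one model instance. Dissociation constants are held fixed
#' (`Kd_BC` = 1 nM, `Kd_BN` = 0.1 nM) and the off-rates are always derived as
#' `koff = Kd * kon`, so only the on-rates are free.
#'
#' @param eta_B,eta_C,eta_N Production rates, nM/s.
#' @param dec_B,dec_C,dec_N,dec_BC,dec_BN First-order decay rates, 1/s.
#' @param D_B,D_C,D_N,D_BC,D_BN Diffusivities, um^2/s.
#' @param lambda_C,lambda_BC Tolloid cleavage rates of free and BMP-bound
#'   Chordin, 1/s.
#' @param kon_BC,kon_BN Binding on-rates, 1/(nM s).
#' @param Kd_BC,Kd_BN Dissociation constants, nM (fixed by default).
#'
#' @return A named numeric vector of class `dv_params` including the derived
#'   `koff_BC` and `koff_BN`.
#' @examples
#' p <- dv_params(D_B = 4.4)
#' p[["koff_BC"]] / p[["kon_BC"]] # Kd_BC = 1 nM
#' @export
dv_params <- function(eta_B = 0.1, eta_C = 0.1, eta_N = 0.01,
                      dec_B = 1e-4, dec_C = 1e-4, dec_N = 1e-4,
                      dec_BC = 1e-4, dec_BN = 1e-4,
                      D_B = 1, D_C = 1, D_N = 1, D_BC = 1, D_BN = 1,
                      lambda_C = 0.01, lambda_BC = 0.01,
                      kon_BC = 0.01, kon_BN = 0.01,
                      Kd_BC = 1, Kd_BN = 0.1) {
  p <- c(
    eta_B = eta_B, eta_C = eta_C, eta_N = eta_N,
    dec_B = dec_B, dec_C = dec_C, dec_N = dec_N,
    dec_BC = dec_BC, dec_BN = dec_BN,
    D_B = D_B, D_C = D_C, D_N = D_N, D_BC = D_BC, D_BN = D_BN,
    lambda_C = lambda_C, lambda_BC = lambda_BC,
    kon_BC = kon_BC, kon_BN = kon_BN,
    Kd_BC = Kd_BC, Kd_BN = Kd_BN
  )
  if (any(!is.finite(p)) || any(p < 0)) {
    abort("All rates must be finite and non-negative.")
  }
  p <- c(p, koff_BC = unname(Kd_BC * kon_BC), koff_BN = unname(Kd_BN * kon_BN))
  structure(p, class = "dv_params")
}

#' Coerce a one-row data frame or named list to a `dv_params` vector
#'
#' @param x A named list, one-row data frame (e.g. a row of the tibble from
#'   [sample_parameters()]), or `dv_params` object. Extra columns such as
#'   `sample` are ignored.
#' @return A `dv_params` vector.
#' @export
as_dv_params <- function(x) {
  if (inherits(x, "dv_params")) return(x)
  x <- as.list(x)
  keep <- intersect(names(x), names(formals(dv_params)))
  do.call(dv_params, x[keep])
}

#' @export
print.dv_params <- function(x, ...) {
  cat("<dv_params>\n")
  print(unclass(x))
  invisible(x)
}

#' Parameter ranges of the computational screen
#'
#' Lower and upper sampling bounds for every varied parameter. Production,
#' decay, diffusion and Tolloid-cleavage ranges each span four orders of
#' magnitude. No published range exists for the binding on-rates; they are
#' sampled over four orders of magnitude as well (default 1e-4 to 1 per nM
#' per s), with off-rates derived from the fixed dissociation constants.
#'
#' @param kon_lower,kon_upper Bounds for both binding on-rates, 1/(nM s).
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @examples
#' param_ranges()
#' @export
param_ranges <- function(kon_lower = 1e-4, kon_upper = 1) {
  tibble(
    parameter = c(
      "eta_B", "eta_C", "eta_N",
      "dec_B", "dec_C", "dec_N", "dec_BC", "dec_BN",
      "D_B", "D_C", "D_N", "D_BC", "D_BN",
      "lambda_C", "lambda_BC",
      "kon_BC", "kon_BN"
    ),
    lower = c(rep(1e-2, 3), rep(1e-5, 5), rep(1e-2, 5), rep(1e-4, 2),
              rep(kon_lower, 2)),
    upper = c(rep(1e2, 3), rep(1e-1, 5), rep(1e2, 5), rep(1e0, 2),
              rep(kon_upper, 2))
  )
}

# Deterministic per-sample substream: the parameter vector drawn for sample i
# depends only on (seed, i), so interrupted, resumed and re-run screens see
# identical streams regardless of batching.
sample_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Draw random parameter vectors for the screen
#'
#' Each varied parameter is drawn independently from a uniform distribution in
#' log10 space between its bounds. Off-rates are derived from the fixed
#' dissociation constants. Sampling is counter-based: sample `i` uses an RNG
#' substream derived from `(seed, i)`, so the stream is reproducible and
#' restart-invariant.
#'
#' @param ranges Tibble from [param_ranges()] (or a compatible data frame).
#' @param n Number of parameter vectors to draw.
#' @param seed Integer seed driving all substreams.
#' @return A tibble with a `sample` index column (0-based, matching store
#'   record indices) and one column per parameter, including derived
#'   `koff_BC`/`koff_BN` and fixed `Kd_BC`/`Kd_BN`.
#' @examples
#' sample_parameters(param_ranges(), n = 3, seed = 1)
#' @export
sample_parameters <- function(ranges = param_ranges(), n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort("`n` must be >= 1.")
  if (any(ranges$lower > ranges$upper)) abort("ranges: lower > upper.")
  if (any(ranges$lower <= 0)) {
    abort("ranges: bounds must be positive for log-space sampling.")
  }
  n <- as.integer(n)
  lo <- log10(ranges$lower)
  hi <- log10(ranges$upper)
  k <- nrow(ranges)
  draws <- matrix(0, nrow = n, ncol = k, dimnames = list(NULL, ranges$parameter))
  for (i in seq_len(n)) {
    old <- .Random.seed_save()
    set.seed(sample_seed(seed, i - 1L))
    draws[i, ] <- 10^(lo + runif(k) * (hi - lo))
    .Random.seed_restore(old)
  }
  out <- as_tibble(draws)
  out$koff_BC <- 1.0 * out$kon_BC
  out$koff_BN <- 0.1 * out$kon_BN
  out$Kd_BC <- 1.0
  out$Kd_BN <- 0.1
  dplyr::bind_cols(tibble(sample = seq_len(n) - 1L), out)
}

# save/restore the global RNG state so samplers do not perturb user streams
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
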