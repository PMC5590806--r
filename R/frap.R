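#' FRAP bleach-region geometry
#'
#' Geometry of the square photobleached region and its finite-difference
#' grid. The bleach is modeled as 2D diffusion in the bleach plane: interior
#' concentration 0 at `t = 0`, the surround held at the pre-bleach plateau
#' (normalized to `boundary`). The grid is cell-centered (one node per image
#' pixel), so the spatial mean of the model field and the pixel mean of an
#' image frame are the same functional.
#'
#' @param side Side length of the square bleach region, micrometres
#'   (default 160.4).
#' @param resolution Target grid spacing, micrometres per pixel (default
#'   `side / 40`, a 40 x 40 pixel grid). Must be at most `side / 10`.
#' @param sampling Sampling interval of the recovery series, seconds
#'   (default 10).
#' @param boundary Boundary concentration (normalized pre-bleach plateau,
#'   default 1).
#' @param mask_threshold Extracellular mask threshold as a fraction of the
#'   image maximum (default 0.01).
#' @return A list of class `frap_geometry` with the pixel count per side
#'   `n_pixels`.
#' @export
frap_geometry <- function(side = 160.4, resolution = side / 40,
                          sampling = 10, boundary = 1,
                          mask_threshold = 0.01) {
  if (side <= 0) abort("`side` must be positive.")
  if (resolution > side / 10) abort("`resolution` must be at most side/10.")
  n_pixels <- max(10L, as.integer(round(side / resolution)))
  n_pixels <- n_pixels + n_pixels %% 2L # even: all odd sine modes carry weight
  structure(
    list(side = side, resolution = side / n_pixels, n_pixels = n_pixels,
         sampling = sampling, boundary = boundary,
         mask_threshold = mask_threshold),
    class = "frap_geometry"
  )
}

# Modal solution of the cell-centered Dirichlet diffusion problem on M
# pixels: deficit w (1 at t = 0, boundary value 0 half a cell beyond the
# outer pixels) evolves on sine modes sin((j - 1/2) k pi / M); only odd k
# carry weight for a uniform initial condition.
frap_modes <- function(D, side, M) {
  h <- side / M
  k <- seq(1, M - 1, by = 2)
  list(
    M = M,
    lambda = -(4 * D / h^2) * sin(k * pi / (2 * M))^2,
    S = 1 / sin(k * pi / (2 * M)), # row sum of mode k
    k = k
  )
}

# pixel mean of the 1D deficit at the requested times
frap_mean_deficit_1d <- function(modes, times) {
  vapply(times, function(t) {
    (2 / modes$M^2) * sum(modes$S^2 * exp(modes$lambda * t))
  }, numeric(1))
}

# grid fine enough to resolve the boundary layer sqrt(D * t) at the first
# sampled time; capped to keep the modal sums cheap
frap_refined_M <- function(D, geom, times) {
  tpos <- times[times > 0]
  if (length(tpos) == 0) return(geom$n_pixels)
  M <- max(geom$n_pixels,
           min(640L, ceiling(geom$side / (0.2 * sqrt(D * min(tpos))))))
  M + M %% 2L
}

#' Simulate fluorescence recovery in the square bleach region
#'
#' Solves the 2D diffusion equation on the square with zero initial interior
#' concentration and the surround held at the plateau level, using the exact
#' modal solution of the cell-centered finite-difference discretization (the
#' Dirichlet eigenmodes of the 5-point Laplacian are separable, so time
#' integration is exact and unconditionally stable). Returns the pixel mean
#' over the bleach region: monotone non-decreasing in time and in `D`,
#' approaching the plateau.
#'
#' When `refine = TRUE` the grid is refined internally so that the diffusion
#' boundary layer at the earliest sampled time is resolved (agreement with
#' the continuum Fourier-series solution to about 1e-3); `refine = FALSE`
#' evaluates on the geometry's own pixel grid, matching the pixel mean of
#' frames generated by [synth_frap_frames()] exactly.
#'
#' @param D Diffusivity, um^2/s (positive).
#' @param geom A [frap_geometry()].
#' @param times Sampling times in seconds (default 0 to 1800 s at the
#'   geometry's sampling interval).
#' @param refine Refine the grid for early-time accuracy (default TRUE).
#' @return A tibble of class `frap_curve` with columns `time`, `intensity`;
#'   attribute `plateau` records the boundary level.
#' @examples
#' curve <- simulate_recovery(4.4)
#' time_to_recovery(curve, 0.9) / 60 # minutes
#' @export
simulate_recovery <- function(D, geom = frap_geometry(),
                              times = seq(0, 1800, by = geom$sampling),
                              refine = TRUE) {
  if (!is.numeric(D) || length(D) != 1 || D <= 0) {
    abort("`D` must be a single positive diffusivity.")
  }
  M <- if (refine) frap_refined_M(D, geom, times) else geom$n_pixels
  m1 <- frap_mean_deficit_1d(frap_modes(D, geom$side, M), times)
  out <- tibble(time = times, intensity = geom$boundary * (1 - m1^2))
  attr(out, "plateau") <- geom$boundary
  attr(out, "geom") <- geom
  class(out) <- c("frap_curve", class(out))
  out
}

# full 2D pixel field at the requested times (list of n_pixels x n_pixels
# matrices), on the geometry's own grid
frap_field <- function(D, geom, times) {
  M <- geom$n_pixels
  modes <- frap_modes(D, geom$side, M)
  j <- seq_len(M)
  phi <- sin(outer(j - 0.5, modes$k) * pi / M)   # phi[j, k]
  ck <- (2 / M) * modes$S
  lapply(times, function(t) {
    w1 <- as.numeric(phi %*% (ck * exp(modes$lambda * t)))
    geom$boundary * (1 - outer(w1, w1))
  })
}

#' Extract a recovery curve from image frames
#'
#' Rescales 8-bit frames to `[0, 1]`, builds a per-frame extracellular mask
#' (pixels at or above `mask_threshold` times the series maximum; static dark
#' intracellular pixels never enter the mask) and returns the masked pixel
#' mean within the bleach box per frame. Frames with an empty mask give a
#' masked (`NA`) time point. Note that in early frames the mask also excludes
#' still-dark extracellular pixels, biasing the masked mean upward relative
#' to the plain pixel mean; the bias vanishes once the dimmest pixel clears
#' the threshold.
#'
#' @param frames List of numeric matrices (identical dimensions), one per
#'   time point. Values above 1.5 are treated as 8-bit and divided by 255.
#' @param times Frame times in seconds (default multiples of
#'   `geom$sampling`).
#' @param geom A [frap_geometry()] (supplies the mask threshold).
#' @param box Optional list with `rows`, `cols` index vectors delimiting the
#'   bleach box; default: the whole frame.
#' @return A `frap_curve` tibble with columns `time`, `intensity`.
#' @export
extract_recovery <- function(frames, times = NULL, geom = frap_geometry(),
                             box = NULL) {
  if (length(frames) == 0) abort("`frames` is empty.")
  dims <- dim(frames[[1]])
  if (any(!vapply(frames, function(f) identical(dim(f), dims), logical(1)))) {
    abort("All frames must share the same dimensions.")
  }
  if (is.null(times)) times <- (seq_along(frames) - 1) * geom$sampling
  if (is.null(box)) box <- list(rows = seq_len(dims[1]), cols = seq_len(dims[2]))
  if (min(box$rows) < 1 || max(box$rows) > dims[1] ||
      min(box$cols) < 1 || max(box$cols) > dims[2]) {
    abort("`box` must lie inside the frame.")
  }
  gmax <- max(vapply(frames, max, numeric(1)))
  scale <- if (gmax > 1.5) 255 else 1
  thr <- geom$mask_threshold * gmax / scale
  vals <- vapply(frames, function(f) {
    f <- f[box$rows, box$cols, drop = FALSE] / scale
    keep <- f >= thr
    if (!any(keep)) return(NA_real_)
    mean(f[keep])
  }, numeric(1))
  out <- tibble(time = times, intensity = vals)
  class(out) <- c("frap_curve", class(out))
  out
}

#' Estimate an effective diffusivity from a recovery curve
#'
#' Fits the finite-difference recovery model to a measured curve by
#' minimizing the sum of squared residuals over `log D`, using steepest
#' descent (central-difference gradient, backtracking line search) from
#' multiple log-uniform random starts. The best converged start wins.
#' Intensities are normalized by the plateau before fitting, so the estimate
#' is invariant to joint rescaling of curve and plateau.
#'
#' @param curve A `frap_curve` (needs at least 5 non-masked time points).
#' @param geom A [frap_geometry()].
#' @param n_starts Number of random starts (default 8).
#' @param seed Seed for the starts.
#' @param d_range Range of starting diffusivities, um^2/s (default
#'   `c(0.01, 100)`).
#' @param plateau Plateau level used to normalize intensities; defaults to
#'   the curve's `plateau` attribute or its maximum intensity.
#' @return An object of class `frap_fit`: `D_hat` (um^2/s), `objective`,
#'   per-start results and convergence flags. See [tidy.frap_fit()] and
#'   [glance.frap_fit()].
#' @examples
#' curve <- simulate_recovery(5)
#' fit <- estimate_diffusivity(curve, n_starts = 4, seed = 1)
#' glance(fit)
#' @export
estimate_diffusivity <- function(curve, geom = frap_geometry(),
                                 n_starts = 8, seed = 1,
                                 d_range = c(0.01, 100), plateau = NULL) {
  ok <- !is.na(curve$intensity)
  tt <- curve$time[ok]
  yy <- curve$intensity[ok]
  if (length(yy) < 5) abort("Insufficient data: need at least 5 time points.")
  plateau <- plateau %||% attr(curve, "plateau") %||% max(yy)
  if (plateau <= 0) abort("`plateau` must be positive.")
  yy <- yy / plateau

  # one fixed grid for the whole fit (fine enough for the smallest candidate
  # D) keeps the objective smooth in D; a D-dependent grid would introduce
  # spurious jumps that break the finite-difference gradient
  M_fit <- frap_refined_M(d_range[1], geom, tt)
  objective <- function(logD) {
    pred <- 1 -
      frap_mean_deficit_1d(frap_modes(exp(logD), geom$side, M_fit), tt)^2
    sum((pred - yy)^2)
  }

  old <- .Random.seed_save()
  set.seed(as.integer(seed))
  starts <- exp(runif(n_starts, log(d_range[1]), log(d_range[2])))
  .Random.seed_restore(old)

  fit_one <- function(D0) {
    x <- log(D0)
    fx <- objective(x)
    converged <- FALSE
    iters <- 0L
    for (it in seq_len(100)) {
      iters <- it
      h <- 1e-5
      g <- (objective(x + h) - objective(x - h)) / (2 * h)
      if (abs(g) < 1e-8 * (1 + abs(fx))) { converged <- TRUE; break }
      step <- 1
      repeat {
        xn <- x - step * g
        fn <- objective(xn)
        if (fn <= fx - 1e-4 * step * g^2 || step < 1e-12) break
        step <- step / 2
      }
      if (step < 1e-12) { converged <- TRUE; break } # no descent possible
      improvement <- fx - fn
      x <- xn
      fx <- fn
      if (improvement < 1e-12 * (1 + abs(fx))) { converged <- TRUE; break }
    }
    tibble(D0 = D0, D = exp(x), objective = fx, converged = converged,
           iterations = iters)
  }
  res <- dplyr::bind_rows(lapply(starts, fit_one))
  ok_res <- res[is.finite(res$objective), , drop = FALSE]
  if (nrow(ok_res) == 0) {
    abort(paste0("All starts failed; objectives: ",
                 paste(signif(res$objective, 4), collapse = ", ")))
  }
  best <- ok_res[which.min(ok_res$objective), ] # best of all starts
  structure(
    list(D_hat = best$D, objective = best$objective, starts = res,
         curve = curve, geom = geom, plateau = plateau),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> D = %.4g um^2/s (SSE %.3g; %d/%d starts converged)\n",
    x$D_hat, x$objective, sum(x$starts$converged), nrow(x$starts)
  ))
  invisible(x)
}

#' Time for a recovery curve to reach a fraction of its plateau
#'
#' First time (linear interpolation between samples) at which the mean
#' intensity reaches `fraction` times the plateau level. Returns `Inf` when
#' the curve never reaches it (e.g. fraction 1 on an asymptotic curve).
#'
#' @param curve A `frap_curve`.
#' @param fraction Fraction of the plateau in (0, 1].
#' @param plateau Plateau level; defaults to the curve's `plateau` attribute
#'   or its maximum intensity.
#' @return Time in seconds (possibly `Inf`).
#' @export
time_to_recovery <- function(curve, fraction, plateau = NULL) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  ok <- !is.na(curve$intensity)
  tt <- curve$time[ok]
  yy <- curve$intensity[ok]
  plateau <- plateau %||% attr(curve, "plateau") %||% max(yy)
  thr <- fraction * plateau
  at_or_above <- which(yy >= thr)
  if (length(at_or_above) == 0) return(Inf)
  j <- at_or_above[1]
  if (j == 1) return(tt[1])
  tt[j - 1] + (tt[j] - tt[j - 1]) * (thr - yy[j - 1]) / (yy[j] - yy[j - 1])
}
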