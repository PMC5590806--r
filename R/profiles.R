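#' Profile-construction configuration
#'
#' @param band_thickness Thickness of the marginal cell band, micrometres
#'   (default 40).
#' @param bin_width Angular bin width in degrees (default 10, i.e. 36 bins
#'   around the full margin).
#' @param dividing_threshold Nuclei with DNA intensity above this multiple of
#'   the mean DNA intensity are considered dividing and removed (default 1.40).
#' @param shell_fraction Fraction of nuclei removed at each of the inner and
#'   outer radial extremes (enveloping layer / yolk syncytial layer proxies;
#'   default 0.15).
#' @param alpha Significance level for profile comparisons (default 0.05).
#' @return A list of class `profile_config`.
#' @export
profile_config <- function(band_thickness = 40, bin_width = 10,
                           dividing_threshold = 1.40, shell_fraction = 0.15,
                           alpha = 0.05) {
  if (band_thickness < 0 || bin_width <= 0 || dividing_threshold <= 0 ||
      alpha <= 0) {
    abort("All profile-config values must be positive.")
  }
  if (shell_fraction < 0 || shell_fraction >= 0.5) {
    abort("`shell_fraction` must lie in [0, 0.5).")
  }
  structure(
    list(band_thickness = band_thickness, bin_width = bin_width,
         dividing_threshold = dividing_threshold,
         shell_fraction = shell_fraction, alpha = alpha),
    class = "profile_config"
  )
}

#' Least-squares sphere fit to a nucleus cloud
#'
#' Fits centre and radius by the algebraic least-squares method (linear in
#' the centre coordinates). Degenerate clouds (coplanar or too few points)
#' raise an error.
#'
#' @param cloud Data frame with columns `x`, `y`, `z` (micrometres).
#' @return List with `center` (length-3) and `radius`.
#' @export
fit_sphere <- function(cloud) {
  if (nrow(cloud) < 10) abort("Need at least 10 nuclei for a sphere fit.")
  P <- as.matrix(cloud[, c("x", "y", "z")])
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  qr_A <- qr(A)
  if (qr_A$rank < 4) abort("Degenerate (coplanar) cloud: sphere fit failed.")
  theta <- unname(qr.coef(qr_A, b))
  center <- theta[1:3]
  r2 <- theta[4] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0) abort("Sphere fit failed.")
  list(center = unname(center), radius = sqrt(r2))
}

#' Remove dividing cells and inner/outer shell nuclei
#'
#' Two filters, applied in fixed order per embryo: (1) nuclei with DNA
#' intensity above `dividing_threshold` times the mean DNA intensity
#' (condensed chromatin of dividing cells) are removed; (2) the
#' `shell_fraction` of nuclei with the smallest and the largest radial
#' distance from the fitted sphere centre are removed (enveloping-layer and
#' yolk-syncytial-layer proxies). The thresholds actually used are recorded
#' on the result, and are reused when the function is applied to its own
#' output, making the filter idempotent.
#'
#' @param cloud Tibble with columns `x`, `y`, `z`, `dna`, `signal` and
#'   optionally `embryo`.
#' @param cfg A [profile_config()].
#' @return The filtered cloud (attributes `dividing_cutoff`,
#'   `shell_cutoffs` record the thresholds).
#' @export
filter_nuclei <- function(cloud, cfg = profile_config()) {
  cloud <- as_tibble(cloud)
  div_cut <- attr(cloud, "dividing_cutoff") %||%
    (cfg$dividing_threshold * mean(cloud$dna))
  keep <- cloud$dna <= div_cut
  out <- cloud[keep, , drop = FALSE]

  shell <- attr(cloud, "shell_cutoffs")
  if (is.null(shell)) {
    sph <- fit_sphere(out)
    r <- sqrt(colSums((t(as.matrix(out[, c("x", "y", "z")])) - sph$center)^2))
    shell <- quantile(r, c(cfg$shell_fraction, 1 - cfg$shell_fraction),
                      names = FALSE, type = 7)
    attr(shell, "center") <- sph$center
  } else {
    r <- sqrt(colSums((t(as.matrix(out[, c("x", "y", "z")])) -
                         attr(shell, "center"))^2))
  }
  out <- out[r >= shell[1] & r <= shell[2], , drop = FALSE]
  attr(out, "dividing_cutoff") <- div_cut
  attr(out, "shell_cutoffs") <- shell
  out
}

#' Restrict a cloud to the marginal band
#'
#' Keeps nuclei within `band_thickness` of the margin plane on the animal
#' side. The margin plane is supplied (synthetic embryos know their
#' equatorial plane; imported clouds must provide one) as a point and a unit
#' normal pointing to the animal pole.
#'
#' @param cloud Nucleus tibble.
#' @param band_thickness Band thickness, micrometres.
#' @param plane List with `point` (length-3) and `normal` (length-3, animal
#'   side positive). Default: plane z = 0 with normal +z.
#' @return The subset of `cloud` within the band.
#' @export
marginal_band <- function(cloud, band_thickness = 40,
                          plane = list(point = c(0, 0, 0),
                                       normal = c(0, 0, 1))) {
  nrm <- plane$normal / sqrt(sum(plane$normal^2))
  d <- as.matrix(cloud[, c("x", "y", "z")]) %*% nrm -
    sum(plane$point * nrm)
  out <- cloud[d >= 0 & d <= band_thickness, , drop = FALSE]
  if (nrow(out) == 0) {
    warn("Marginal band is empty; downstream profiles will be empty.")
  }
  attr(out, "plane") <- list(point = plane$point, normal = nrm)
  out
}

# azimuth (degrees in [0, 360)) of nuclei in the margin plane; 0 = ventral
# reference direction
margin_angle <- function(cloud, plane, ventral = c(1, 0, 0)) {
  nrm <- plane$normal / sqrt(sum(plane$normal^2))
  e1 <- ventral - sum(ventral * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    nrm[2] * e1[3] - nrm[3] * e1[2],
    nrm[3] * e1[1] - nrm[1] * e1[3],
    nrm[1] * e1[2] - nrm[2] * e1[1]
  )
  P <- sweep(as.matrix(cloud[, c("x", "y", "z")]), 2, plane$point)
  ang <- atan2(P %*% e2, P %*% e1) * 180 / pi
  as.numeric((ang + 360) %% 360)
}

#' Bin marginal nuclei into an angular intensity profile
#'
#' Groups nuclei of the marginal band into `bin_width`-degree intervals
#' around the full margin (36 bins at the default 10 degrees) and reports the
#' mean, standard deviation and count of the signal intensity per bin. Empty
#' bins are kept with `n = 0` and masked (`NA`) mean.
#'
#' @param band Output of [marginal_band()] (must carry its `plane`
#'   attribute, or supply `plane`).
#' @param cfg A [profile_config()].
#' @param plane Margin plane, defaulting to the attribute set by
#'   [marginal_band()].
#' @param ventral Direction of the ventral reference (angle 0).
#' @return A tibble of class `dv_profile` with columns `angle` (bin centre,
#'   degrees), `mean`, `sd`, `n`.
#' @export
bin_profile <- function(band, cfg = profile_config(),
                        plane = attr(band, "plane"),
                        ventral = c(1, 0, 0)) {
  if (is.null(plane)) abort("No margin plane available.")
  breaks <- seq(0, 360, by = cfg$bin_width)
  centers <- head(breaks, -1) + cfg$bin_width / 2
  ang <- margin_angle(band, plane, ventral)
  idx <- findInterval(ang, breaks, rightmost.closed = TRUE)
  out <- tibble(
    angle = centers,
    mean = NA_real_, sd = NA_real_, n = 0L
  )
  for (b in seq_along(centers)) {
    v <- band$signal[idx == b]
    out$n[b] <- length(v)
    if (length(v) > 0) out$mean[b] <- mean(v)
    if (length(v) > 1) out$sd[b] <- sd(v)
  }
  class(out) <- c("dv_profile", class(out))
  out
}

#' Fold a 36-bin margin profile into an 18-bin ventral-to-dorsal profile
#'
#' Averages the left and right sides of the margin: the bin at angle `theta`
#' is combined with the bin at `360 - theta` by an n-weighted mean. Total
#' weighted intensity (`sum(mean * n)`) is conserved.
#'
#' @param profile36 A 36-bin (or any even-bin) [bin_profile()] output with
#'   ventral at angle 0.
#' @return A `dv_profile` tibble with bins ordered ventral (0) to dorsal
#'   (180 degrees).
#' @export
fold_profile <- function(profile36) {
  nb <- nrow(profile36)
  if (nb %% 2 != 0) abort("Folding requires an even number of bins.")
  if (!all(abs(sort(profile36$angle) - profile36$angle) < 1e-9)) {
    abort("Bins must be ordered by angle.")
  }
  half <- nb / 2
  left <- profile36[seq_len(half), ]
  right <- profile36[seq(nb, half + 1), ] # mirrored order: 360-theta pairs
  n <- left$n + right$n
  wmean <- ifelse(
    n > 0,
    (dplyr::coalesce(left$mean * left$n, 0) +
       dplyr::coalesce(right$mean * right$n, 0)) / n,
    NA_real_
  )
  # pooled sd of the combined group from per-side moments
  pooled_sd <- rep(NA_real_, half)
  for (b in seq_len(half)) {
    nl <- left$n[b]; nr <- right$n[b]
    if (nl + nr > 1) {
      ml <- if (nl > 0) left$mean[b] else 0
      mr <- if (nr > 0) right$mean[b] else 0
      sl <- if (nl > 1) left$sd[b] else 0
      sr <- if (nr > 1) right$sd[b] else 0
      mm <- wmean[b]
      ss <- (if (nl > 0) (nl - 1) * sl^2 + nl * (ml - mm)^2 else 0) +
        (if (nr > 0) (nr - 1) * sr^2 + nr * (mr - mm)^2 else 0)
      pooled_sd[b] <- sqrt(ss / (nl + nr - 1))
    }
  }
  out <- tibble(angle = left$angle, mean = wmean, sd = pooled_sd, n = n)
  class(out) <- c("dv_profile", class(out))
  out
}

#' Batch normalization scalars from shared wild-type controls
#'
#' Embryo sets stained and imaged on different days are normalized by a
#' single per-set scalar chosen to minimize the sum of squared differences
#' between that set's wild-type control mean profile and the reference set's:
#' `s = sum(ref * batch) / sum(batch^2)`.
#'
#' @param controls Tibble with columns `batch`, `angle`, `value` (mean
#'   wild-type control profile per batch; several control embryos should be
#'   averaged beforehand or supplied per embryo, in which case they are
#'   averaged per angle here).
#' @param reference Batch id used as the reference (default: first batch).
#' @return Tibble with columns `batch`, `scalar`; the reference batch has
#'   scalar 1.
#' @export
normalize_batches <- function(controls, reference = NULL) {
  if (!all(c("batch", "angle", "value") %in% names(controls))) {
    abort("`controls` needs columns batch, angle, value.")
  }
  means <- controls |>
    dplyr::group_by(.data$batch, .data$angle) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  batches <- unique(means$batch)
  if (is.null(reference)) reference <- batches[1]
  if (!reference %in% batches) abort("Reference batch not found.")
  ref <- means[means$batch == reference, ]
  ref <- ref[order(ref$angle), ]
  out <- lapply(batches, function(b) {
    cur <- means[means$batch == b, ]
    cur <- cur[order(cur$angle), ]
    if (!isTRUE(all.equal(cur$angle, ref$angle))) {
      abort(sprintf("Batch \"%s\" has a different bin structure.", b))
    }
    tibble(batch = b, scalar = sum(ref$value * cur$value) / sum(cur$value^2))
  })
  dplyr::bind_rows(out)
}

#' Per-bin comparison of two groups of embryo profiles
#'
#' Welch two-sample two-tailed t-tests per angular bin, flagged at the given
#' significance level. No multiple-testing correction is applied. Bins with
#' fewer than two embryos in either group are masked.
#'
#' @param group_a,group_b Tibbles with columns `embryo`, `angle`, `value`
#'   (one value per embryo per bin).
#' @param alpha Significance level (default 0.05).
#' @return Tibble with columns `angle`, `n_a`, `n_b`, `p`, `significant`.
#' @export
compare_profiles <- function(group_a, group_b, alpha = 0.05) {
  for (g in list(group_a, group_b)) {
    if (!all(c("embryo", "angle", "value") %in% names(g))) {
      abort("Groups need columns embryo, angle, value.")
    }
  }
  angles <- sort(unique(c(group_a$angle, group_b$angle)))
  out <- lapply(angles, function(a) {
    va <- group_a$value[group_a$angle == a]
    vb <- group_b$value[group_b$angle == a]
    if (length(va) < 2 || length(vb) < 2 ||
        (sd(va) == 0 && sd(vb) == 0)) {
      if (length(va) >= 2 && length(vb) >= 2 &&
          isTRUE(all.equal(mean(va), mean(vb)))) {
        # identical degenerate groups: no evidence of difference
        return(tibble(angle = a, n_a = length(va), n_b = length(vb),
                      p = 1, significant = FALSE))
      }
      return(tibble(angle = a, n_a = length(va), n_b = length(vb),
                    p = NA_real_, significant = NA))
    }
    p <- t.test(va, vb, var.equal = FALSE)$p.value
    tibble(angle = a, n_a = length(va), n_b = length(vb), p = p,
           significant = p < alpha)
  })
  dplyr::bind_rows(out)
}

#' Smoothed slope of a folded profile
#'
#' Locally weighted (lowess) smoothing of the profile followed by centred
#' finite differences, reporting which bins exceed a slope threshold
#' (gradient steepness in a.u. per degree).
#'
#' @param profile A `dv_profile` (folded, ventral to dorsal).
#' @param span Lowess span as a fraction of the data (default 0.4).
#' @param threshold High-slope threshold in a.u./degree (default 0.5).
#' @return Tibble with columns `angle`, `smoothed`, `slope`, `high_slope`
#'   (absolute slope above threshold).
#' @export
profile_slope <- function(profile, span = 0.4, threshold = 0.5) {
  ok <- !is.na(profile$mean)
  ang <- profile$angle[ok]
  val <- profile$mean[ok]
  if (length(val) < 5) abort("Need at least 5 bins for a slope estimate.")
  if (span * length(val) < 3) abort("`span` must cover at least 3 points.")
  sm <- lowess(ang, val, f = span)
  slope <- rep(NA_real_, length(sm$y))
  h <- diff(sm$x)
  slope[1] <- (sm$y[2] - sm$y[1]) / h[1]
  nl <- length(sm$y)
  slope[nl] <- (sm$y[nl] - sm$y[nl - 1]) / h[nl - 1]
  for (i in seq(2, nl - 1)) {
    slope[i] <- (sm$y[i + 1] - sm$y[i - 1]) / (sm$x[i + 1] - sm$x[i - 1])
  }
  tibble(angle = sm$x, smoothed = sm$y, slope = slope,
         high_slope = abs(slope) > threshold)
}

#' Resample a folded profile onto the model grid
#'
#' Maps bin centres from degrees (0 ventral, 180 dorsal) to axis positions
#' (0 to `axis_length`) and linearly interpolates the mean intensity onto the
#' model node positions, extending the end values beyond the outermost bin
#' centres.
#'
#' @param profile A folded `dv_profile` (or any tibble with `angle`, `mean`).
#' @param geom A [dv_geometry()].
#' @return A numeric per-node target vector.
#' @export
resample_to_model_grid <- function(profile, geom) {
  ok <- !is.na(profile$mean)
  if (sum(ok) < 2) abort("Need at least 2 valid bins to resample.")
  pos <- profile$angle[ok] / 180 * geom$axis_length
  approx(pos, profile$mean[ok], xout = geom$x, rule = 2)$y
}
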