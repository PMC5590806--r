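#' Synthetic ventral-to-dorsal target signaling profile
#'
#' Generates an 18-bin folded marginal intensity profile with the qualitative
#' structure of measured P-Smad5 gradients: ventrally peaked, monotone
#' non-increasing towards dorsal, half-maximum near 40% of the axis,
#' embryo-to-embryo amplitude variability and per-bin noise. The underlying
#' mean curve is a logistic sigmoid of the angle. Genotype variants encode
#' the measured relationships as constraints: the Chordin null gains
#' intensity laterally and never loses it anywhere (ventral peak preserved);
#' the heterozygote is indistinguishable from wild type.
#'
#' @param genotype `"wt"`, `"chd_null"` or `"chd_het"`.
#' @param amplitude Peak amplitude above baseline, a.u.
#' @param halfmax_deg Angle of the sigmoid midpoint, degrees (default 72, 40%
#'   of the 180-degree folded axis).
#' @param steepness Sigmoid steepness, 1/degree (default 0.1: flat ventral
#'   plateau over roughly the ventral-most 30 degrees, near-baseline tail
#'   dorsal of about 110 degrees).
#' @param baseline Dorsal baseline intensity, a.u.
#' @param cv Embryo-to-embryo amplitude coefficient of variation
#'   (default 0.1).
#' @param noise_sd Per-bin additive noise standard deviation, a.u.
#' @param n_embryos Number of synthetic embryos averaged (default 10).
#' @param lateral_shift Dorsalward shift (degrees) of the Chordin-null
#'   sigmoid midpoint (default 40).
#' @param seed Integer seed (deterministic output).
#' @return A `dv_profile` tibble (`angle`, `mean`, `sd`, `n`) with attributes
#'   `genotype` and `truth` (the noiseless mean curve).
#' @examples
#' p <- synth_target_profile("wt", seed = 1)
#' all(diff(attr(p, "truth")) <= 0)
#' @export
synth_target_profile <- function(genotype = c("wt", "chd_null", "chd_het"),
                                 amplitude = 1, halfmax_deg = 72,
                                 steepness = 0.1, baseline = 0.05,
                                 cv = 0.1, noise_sd = 0.02, n_embryos = 10,
                                 lateral_shift = 40, seed = 1) {
  genotype <- match.arg(genotype)
  if (amplitude <= baseline || baseline < 0 || cv < 0 || noise_sd < 0) {
    abort("Need amplitude > baseline >= 0, cv >= 0, noise_sd >= 0.")
  }
  angle <- seq(5, 175, by = 10)
  sig <- function(theta, mid) 1 / (1 + exp(-(mid - theta) * steepness))
  truth <- baseline + amplitude * sig(angle, halfmax_deg)
  if (genotype == "chd_null") {
    # lateral gain only: the gain of the dorsally-shifted sigmoid, windowed to
    # vanish at the ventral-most bin (the peak itself does not change)
    gain <- amplitude * (sig(angle, halfmax_deg + lateral_shift) -
                           sig(angle, halfmax_deg))
    window <- pmin(1, pmax(0, (angle - angle[1]) / 30))
    truth <- truth + window * gain
  }
  old <- .Random.seed_save()
  set.seed(as.integer(seed))
  emb <- vapply(seq_len(n_embryos), function(i) {
    amp_i <- max(0, 1 + cv * rnorm(1))
    baseline + amp_i * (truth - baseline) + rnorm(length(angle), 0, noise_sd)
  }, numeric(length(angle)))
  .Random.seed_restore(old)
  out <- tibble(
    angle = angle,
    mean = rowMeans(emb),
    sd = apply(emb, 1, sd),
    n = n_embryos
  )
  attr(out, "genotype") <- genotype
  attr(out, "truth") <- truth
  class(out) <- c("dv_profile", class(out))
  out
}

#' Synthetic embryo nucleus cloud with ground-truth labels
#'
#' Places nuclei on a blastoderm-like spherical cap (animal pole down to just
#' below the equatorial margin), assigns DNA intensities by class (deep,
#' dividing with condensed-chromatin-bright DNA, outer enveloping-layer and
#' inner yolk-syncytial-layer shells) and draws the signal intensity of each
#' nucleus from a folded target profile evaluated at the nucleus azimuth,
#' plus Gaussian noise. The margin plane is the equatorial plane `z = 0`
#' (animal side `z > 0`), ventral at azimuth 0 along `+x`.
#'
#' @param profile A folded `dv_profile` supplying the angular mean signal.
#' @param n_cells Number of nuclei (default 8000).
#' @param radius Embryo sphere radius, micrometres (default 350).
#' @param dividing_fraction Fraction of deep cells that are dividing
#'   (default 0.05).
#' @param evl_fraction,ysl_fraction Fractions of outer/inner shell nuclei
#'   (default 0.1 each).
#' @param dna_sd DNA intensity standard deviation within a class
#'   (default 0.08 around a mean of 1).
#' @param dividing_dna_factor DNA intensity multiple for dividing cells
#'   (default 2).
#' @param signal_noise_sd Per-nucleus signal noise, a.u. (default 0.05).
#' @param seed Integer seed.
#' @return A tibble with columns `x`, `y`, `z`, `dna`, `signal`, `embryo`,
#'   and the ground-truth `class` (`deep`, `dividing`, `evl`, `ysl`).
#' @export
synth_embryo_cloud <- function(profile, n_cells = 8000, radius = 350,
                               dividing_fraction = 0.05, evl_fraction = 0.1,
                               ysl_fraction = 0.1, dna_sd = 0.08,
                               dividing_dna_factor = 2,
                               signal_noise_sd = 0.05, seed = 1) {
  if (evl_fraction + ysl_fraction + dividing_fraction >= 1) {
    abort("Class fractions must sum to less than 1.")
  }
  old <- .Random.seed_save()
  set.seed(as.integer(seed))

  n_evl <- round(n_cells * evl_fraction)
  n_ysl <- round(n_cells * ysl_fraction)
  n_body <- n_cells - n_evl - n_ysl
  n_div <- round(n_body * dividing_fraction)
  class <- c(rep("deep", n_body - n_div), rep("dividing", n_div),
             rep("evl", n_evl), rep("ysl", n_ysl))

  # blastoderm cap: colatitude from the animal pole down to 105 degrees
  u <- runif(n_cells, cos(105 * pi / 180), 1)
  colat <- acos(u)
  az <- runif(n_cells, 0, 2 * pi)
  r <- radius - 25 + rnorm(n_cells, 0, 5)
  r[class == "evl"] <- radius + 8 + rnorm(n_evl, 0, 3)
  r[class == "ysl"] <- radius - 70 + rnorm(n_ysl, 0, 5)

  # margin plane z = 0: animal pole at +z
  x <- r * sin(colat) * cos(az)
  y <- r * sin(colat) * sin(az)
  z <- r * cos(colat)

  dna <- 1 + rnorm(n_cells, 0, dna_sd)
  dna[class == "dividing"] <- dividing_dna_factor +
    rnorm(n_div, 0, dna_sd)

  angle <- (atan2(y, x) * 180 / pi + 360) %% 360
  folded <- pmin(angle, 360 - angle)
  mu <- approx(profile$angle, profile$mean, xout = folded, rule = 2)$y
  signal <- pmax(0, mu + rnorm(n_cells, 0, signal_noise_sd))
  signal[class %in% c("evl", "ysl")] <-
    pmax(0, 0.2 * signal[class %in% c("evl", "ysl")])

  .Random.seed_restore(old)
  tibble(x = x, y = y, z = z, dna = dna, signal = signal,
         embryo = 1L, class = class)
}

#' Synthetic FRAP image frames with ground truth
#'
#' Builds image frames from the finite-difference recovery field at the true
#' diffusivity, adds i.i.d. Gaussian pixel noise and stamps a static
#' intracellular zero pattern (randomly placed dark pixels emulating cell
#' interiors excluded by the extracellular mask).
#'
#' @param D_true True diffusivity, um^2/s.
#' @param geom A [frap_geometry()].
#' @param times Frame times, seconds.
#' @param noise_sd Pixel noise standard deviation (default 0.02).
#' @param intracellular_fraction Fraction of interior pixels set to zero in
#'   every frame (default 0.15; 0 disables the pattern).
#' @param seed Integer seed.
#' @return List with `frames` (list of matrices), `times`, `true_curve` (the
#'   noiseless [simulate_recovery()] curve) and `intracellular` (logical
#'   matrix of the zero pattern).
#' @export
synth_frap_frames <- function(D_true = 4.4, geom = frap_geometry(),
                              times = seq(0, 1800, by = geom$sampling),
                              noise_sd = 0.02,
                              intracellular_fraction = 0.15, seed = 1) {
  if (D_true <= 0) abort("`D_true` must be positive.")
  old <- .Random.seed_save()
  set.seed(as.integer(seed))
  fields <- frap_field(D_true, geom, times)
  ng <- geom$n_pixels
  cells <- matrix(FALSE, ng, ng)
  if (intracellular_fraction > 0) {
    interior <- as.matrix(expand.grid(seq_len(ng), seq_len(ng)))
    pick <- sample(nrow(interior),
                   round(intracellular_fraction * nrow(interior)))
    cells[interior[pick, , drop = FALSE]] <- TRUE
  }
  frames <- lapply(fields, function(u) {
    if (noise_sd > 0) u <- u + matrix(rnorm(ng * ng, 0, noise_sd), ng, ng)
    u[cells] <- 0
    pmax(u, 0)
  })
  .Random.seed_restore(old)
  list(frames = frames, times = times,
       true_curve = simulate_recovery(D_true, geom, times, refine = FALSE),
       intracellular = cells)
}

#' Hand-tuned parameter vectors that exemplify each mechanism
#'
#' Returns a frozen parameter vector (within the screen ranges) and BMP
#' production shape whose wild-type simulation, fitted against a target
#' generated from its own output, classifies as the requested mechanism.
#' Used as classifier fixtures:
#' * `source_sink`: fast, stable BMP diffusing from the ventral source to the
#'   restricted dorsal Chordin sink.
#' * `counter_gradient`: slow BMP bound in place by abundant, fast-diffusing,
#'   stable Chordin spreading ventrally.
#' * `transcriptional`: near-immobile BMP with negligible antagonist binding,
#'   production shaped like the target itself.
#' * `shuttling`: fast-diffusing BMP captured by abundant Chordin into a
#'   mobile, decay-protected complex that is carried ventrally and slowly
#'   released by Tolloid cleavage, so removing Chordin drops the ventral peak
#'   by more than 20%.
#'
#' @param mechanism One of `"source_sink"`, `"counter_gradient"`,
#'   `"transcriptional"`, `"shuttling"`.
#' @return List with `params` (a [dv_params()]) and `bmp_shape` (preset name).
#' @export
synth_mechanism_vector <- function(mechanism = c("source_sink",
                                                 "counter_gradient",
                                                 "transcriptional",
                                                 "shuttling")) {
  mechanism <- match.arg(mechanism)
  switch(mechanism,
    source_sink = list(
      params = dv_params(
        eta_B = 0.05, eta_C = 1, eta_N = 0.01,
        dec_B = 1e-5, dec_C = 1e-4, dec_N = 1e-4,
        dec_BC = 1e-3, dec_BN = 1e-3,
        D_B = 20, D_C = 0.5, D_N = 1, D_BC = 0.1, D_BN = 0.1,
        lambda_C = 1e-4, lambda_BC = 1e-4,
        kon_BC = 0.1, kon_BN = 1e-3
      ),
      bmp_shape = "graded_default"
    ),
    counter_gradient = list(
      params = dv_params(
        eta_B = 0.05, eta_C = 0.5, eta_N = 0.01,
        dec_B = 1e-4, dec_C = 1e-5, dec_N = 1e-4,
        dec_BC = 1e-3, dec_BN = 1e-3,
        D_B = 0.05, D_C = 20, D_N = 1, D_BC = 0.05, D_BN = 0.1,
        lambda_C = 1e-4, lambda_BC = 1e-4,
        kon_BC = 0.1, kon_BN = 1e-3
      ),
      bmp_shape = "graded_default"
    ),
    transcriptional = list(
      params = dv_params(
        eta_B = 0.05, eta_C = 0.01, eta_N = 0.01,
        dec_B = 1e-3, dec_C = 1e-4, dec_N = 1e-4,
        dec_BC = 1e-3, dec_BN = 1e-3,
        D_B = 0.01, D_C = 0.1, D_N = 0.1, D_BC = 0.05, D_BN = 0.05,
        lambda_C = 1e-4, lambda_BC = 1e-4,
        kon_BC = 1e-4, kon_BN = 1e-4
      ),
      bmp_shape = "match_target"
    ),
    shuttling = list(
      params = dv_params(
        eta_B = 0.015, eta_C = 4, eta_N = 0.01,
        dec_B = 1e-3, dec_C = 1e-5, dec_N = 1e-4,
        dec_BC = 2e-5, dec_BN = 1e-3,
        D_B = 70, D_C = 6, D_N = 1, D_BC = 50, D_BN = 0.1,
        lambda_C = 0.05, lambda_BC = 3.5e-3,
        kon_BC = 0.5, kon_BN = 1e-3
      ),
      bmp_shape = "graded_default"
    )
  )
}
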