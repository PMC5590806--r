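test_that("target profiles are deterministic and carry the assumed shape", {
  a <- synth_target_profile("wt", seed = 3)
  b <- synth_target_profile("wt", seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, synth_target_profile("wt", seed = 4)))
  # noiseless truth: ventrally peaked, monotone non-increasing
  truth <- attr(a, "truth")
  expect_gt(truth[1], 0)
  expect_true(all(diff(truth) <= 0))
})

test_that("the noiseless profile is an exact sigmoid with the set half-max", {
  p <- synth_target_profile("wt", baseline = 0, cv = 0, noise_sd = 0,
                            halfmax_deg = 72, steepness = 0.1, seed = 1)
  expect_equal(p$mean,
               1 / (1 + exp(-(72 - p$angle) * 0.1)), tolerance = 1e-12)
  # half of the maximum is reached at ~40% of the folded axis (72 degrees)
  hm <- approx(p$mean, p$angle, xout = max(p$mean) / 2)$y
  expect_equal(hm, 72, tolerance = 1.5)
  # steepness -> infinity approaches a step profile
  st <- synth_target_profile("wt", baseline = 0, cv = 0, noise_sd = 0,
                             steepness = 50, seed = 1)
  expect_equal(st$mean[st$angle < 72], rep(1, sum(st$angle < 72)))
  expect_equal(st$mean[st$angle > 72], rep(0, sum(st$angle > 72)))
})

test_that("genotype variants encode the measured constraints", {
  wt <- attr(synth_target_profile("wt", cv = 0, noise_sd = 0), "truth")
  cn <- attr(synth_target_profile("chd_null", cv = 0, noise_sd = 0), "truth")
  ch <- attr(synth_target_profile("chd_het", cv = 0, noise_sd = 0), "truth")
  expect_true(all(cn >= wt))          # no decrease anywhere in the gradient
  expect_equal(cn[1], wt[1])          # ventral peak preserved
  expect_gt(max(cn - wt), 0.2)        # clear lateral gain
  expect_identical(ch, wt)            # heterozygote indistinguishable
})

test_that("embryo clouds expose ground truth the filters can recover", {
  prof <- synth_target_profile("wt", seed = 5)
  cloud <- synth_embryo_cloud(prof, seed = 5)
  expect_identical(cloud, synth_embryo_cloud(prof, seed = 5))
  expect_equal(nrow(cloud), 8000)
  filt <- filter_nuclei(cloud)
  # dividing nuclei: >= 95% removed at the default 140% threshold
  dividing_kept <- dplyr::semi_join(cloud[cloud$class == "dividing", ], filt,
                                    by = c("x", "y", "z"))
  expect_lt(nrow(dividing_kept) / sum(cloud$class == "dividing"), 0.05)
  # zero dividing fraction: the dividing filter removes almost nothing
  c0 <- synth_embryo_cloud(prof, dividing_fraction = 0, seed = 6)
  cut <- 1.4 * mean(c0$dna)
  expect_lt(mean(c0$dna > cut), 0.01)
})

test_that("the end-to-end profile pipeline recovers the generator truth", {
  prof <- synth_target_profile("wt", seed = 7)
  cloud <- synth_embryo_cloud(prof, seed = 7)
  p18 <- cloud |>
    filter_nuclei() |>
    marginal_band(40) |>
    bin_profile() |>
    fold_profile()
  truth <- approx(prof$angle, prof$mean, xout = p18$angle, rule = 2)$y
  ok <- p18$n > 1
  # 2 SEM is a ~95% band per bin; demand nominal coverage across the 18 bins
  covered <- abs(p18$mean[ok] - truth[ok]) <= 2 * p18$sd[ok] / sqrt(p18$n[ok])
  expect_gte(sum(covered), sum(ok) - 2)
  # uniform profile: folded output flat within noise
  uprof <- synth_target_profile("wt", cv = 0, noise_sd = 0, seed = 1)
  uprof$mean <- rep(1, 18)
  ucloud <- synth_embryo_cloud(uprof, seed = 8)
  u18 <- ucloud |> filter_nuclei() |> marginal_band(40) |>
    bin_profile() |> fold_profile()
  expect_lt(max(abs(u18$mean - 1), na.rm = TRUE), 0.05)
})

test_that("synthetic FRAP frames carry exact ground truth", {
  geom <- frap_geometry()
  sf <- synth_frap_frames(4.4, geom, noise_sd = 0,
                          intracellular_fraction = 0, seed = 2)
  expect_length(sf$frames, length(sf$times))
  # all-masked (all-zero) first frame is reported as a masked point
  ex <- extract_recovery(sf$frames, geom = geom)
  expect_true(is.na(ex$intensity[1]))
  # noisy frames with an intracellular pattern still support estimation
  sf2 <- synth_frap_frames(4.4, geom, noise_sd = 0.02,
                           intracellular_fraction = 0.15, seed = 3)
  expect_equal(sum(sf2$intracellular), round(0.15 * 40 * 40))
  ex2 <- extract_recovery(sf2$frames, geom = geom)
  fit <- estimate_diffusivity(ex2, geom, n_starts = 4, seed = 4, plateau = 1)
  expect_equal(fit$D_hat, 4.4, tolerance = 0.10)
})

test_that("mechanism fixtures stay within the screen ranges", {
  r <- param_ranges()
  for (mech in c("source_sink", "counter_gradient", "transcriptional",
                 "shuttling")) {
    p <- synth_mechanism_vector(mech)$params
    for (i in seq_len(nrow(r))) {
      v <- p[[r$parameter[i]]]
      expect_gte(v, r$lower[i])
      expect_lte(v, r$upper[i])
    }
  }
})
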