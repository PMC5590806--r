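# Shared lazy fixtures: computed once per test run, reused across files.
.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx, inherits = FALSE)) {
    assign(key, force(expr), envir = .fx)
  }
  get(key, envir = .fx)
}

# default geometry and synthetic targets resampled onto the model grid
fx_geom <- function() memo("geom", dv_geometry())

fx_targets <- function() memo("targets", {
  g <- fx_geom()
  list(
    WT = resample_to_model_grid(synth_target_profile("wt", seed = 101), g),
    chd_null = resample_to_model_grid(
      synth_target_profile("chd_null", seed = 102), g),
    chd_het = resample_to_model_grid(
      synth_target_profile("chd_het", seed = 103), g)
  )
})

# one simulated battery of the four mechanism fixtures (used by several files)
fx_mechanism_runs <- function() memo("mech_runs", {
  g <- fx_geom()
  tw <- fx_targets()$WT
  lapply(
    stats::setNames(
      c("source_sink", "counter_gradient", "transcriptional", "shuttling"),
      c("source_sink", "counter_gradient", "transcriptional", "shuttling")
    ),
    function(mech) {
      fx <- synth_mechanism_vector(mech)
      f <- production_fields(g, fx$params, fx$bmp_shape,
                             target = if (fx$bmp_shape == "match_target") tw)
      sim_wt <- simulate_gradient(fx$params, f)
      sim_cn <- simulate_gradient(fx$params, apply_genotype(f, "chd_null"),
                                  n_save = 2)
      list(
        fixture = fx, fields = f,
        wt = sim_wt, chd_null = sim_cn,
        balance = mass_balance(sim_wt, production_region(f))
      )
    }
  )
})

store_files <- c("manifest.json", "params.csv", "profiles.csv",
                 "balance.csv", "flags.csv")

expect_identical_stores <- function(dir_a, dir_b) {
  for (f in store_files) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)),
                     label = paste("store file", f))
  }
}
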