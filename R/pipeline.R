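pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    geometry = list(axis_length = 700, n_nodes = 36, chd_domain_length = 145,
                    nog_domain_length = 78, tld_domain_length = 400,
                    t_final = 7800),
    ranges = list(kon_lower = 1e-4, kon_upper = 1),
    screen = list(n_samples = 100, batch_size = 500, bmp_shape = "graded_default",
                  genotypes = c("WT", "chd_null", "chd_het", "nog_null"),
                  rtol = 1e-9, n_save = 201, species = "B"),
    fit = list(nrmsd_threshold = 0.08, shuttling_drop = 0.20,
               transcriptional_fraction = 0.80, het_chd_factor = 0.5,
               droso_halfmax_fraction = 0.10, droso_peak_drop = 0.50,
               droso_max_nog_bound_fraction = 0.05,
               nog_consistency_threshold = 0.08, normalization = "peak"),
    targets = list(amplitude = 1, halfmax_deg = 72, steepness = 0.1,
                   baseline = 0.05, cv = 0.1, noise_sd = 0.02,
                   n_embryos = 10, lateral_shift = 40,
                   use_chd_targets = TRUE),
    profile = list(band_thickness = 40, bin_width = 10,
                   dividing_threshold = 1.40, shell_fraction = 0.15,
                   alpha = 0.05),
    frap = list(side = 160.4, sampling = 10, boundary = 1,
                mask_threshold = 0.01)
  )
}

check_keys <- function(cfg, defaults, path = "") {
  extra <- setdiff(names(cfg), names(defaults))
  if (length(extra) > 0) {
    abort(sprintf("Unknown configuration key(s): %s",
                  paste0(path, extra, collapse = ", ")))
  }
  for (nm in names(cfg)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(cfg[[nm]])) {
        abort(sprintf("Configuration block \"%s%s\" must be a mapping.",
                      path, nm))
      }
      check_keys(cfg[[nm]], defaults[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(defaults, cfg) {
  for (nm in names(cfg)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], cfg[[nm]])
    } else {
      defaults[[nm]] <- cfg[[nm]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  if (cfg$fit$nrmsd_threshold <= 0 || cfg$fit$nrmsd_threshold > 1) {
    abort("fit.nrmsd_threshold must lie in (0, 1].")
  }
  if (cfg$screen$n_samples < 1) abort("screen.n_samples must be >= 1.")
  if (cfg$frap$side <= 0) abort("frap.side must be positive.")
  if (cfg$geometry$axis_length <= 0) abort("geometry.axis_length must be positive.")
  if (any(unlist(cfg$ranges) <= 0)) abort("ranges bounds must be positive.")
  invisible(cfg)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration with blocks `geometry`, `ranges`, `screen`,
#' (note: the sample count key is `n_samples` -- a bare `n` is a boolean in
#' YAML 1.1),
#' `fit`, `targets`, `profile`, `frap` plus top-level `seed` and `out_dir`,
#' fills in documented defaults, and rejects unknown keys. An empty file
#' yields all defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such config file: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defaults <- pipeline_defaults()
  check_keys(cfg, defaults)
  out <- validate_config(merge_config(defaults, cfg))
  structure(out, class = c("pipeline_config", "list"))
}

#' Run the full screen-and-classify pipeline
#'
#' Generates synthetic target profiles per genotype, resamples them onto the
#' model grid, runs the parameter screen, gates and classifies every
#' solution, and writes `labels.csv`, `summary.json` and an echo of the
#' effective configuration to the output directory. Re-running with the same
#' configuration reproduces the summary exactly.
#'
#' @param config A `pipeline_config` from [load_config()] (or the default
#'   configuration when omitted).
#' @param out_dir Output directory (overrides `config$out_dir`; required if
#'   neither is set).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the store, the classification tibble and
#'   the summary list.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, quiet = TRUE) {
  cfg <- config %||% structure(pipeline_defaults(),
                               class = c("pipeline_config", "list"))
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) abort("An output directory is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  geom <- do.call(dv_geometry, cfg$geometry)
  tg <- cfg$targets
  seed <- as.integer(cfg$seed)
  mk_target <- function(genotype, offset) {
    synth_target_profile(
      genotype, amplitude = tg$amplitude, halfmax_deg = tg$halfmax_deg,
      steepness = tg$steepness, baseline = tg$baseline, cv = tg$cv,
      noise_sd = tg$noise_sd, n_embryos = tg$n_embryos,
      lateral_shift = tg$lateral_shift, seed = seed + offset
    )
  }
  prof_wt <- mk_target("wt", 101L)
  targets <- list(WT = resample_to_model_grid(prof_wt, geom))
  if (isTRUE(tg$use_chd_targets)) {
    targets$chd_null <- resample_to_model_grid(mk_target("chd_null", 102L), geom)
    targets$chd_het <- resample_to_model_grid(mk_target("chd_het", 103L), geom)
  }

  sc <- cfg$screen
  store <- run_screen(
    n = sc$n_samples, seed = seed, geom = geom,
    ranges = do.call(param_ranges, cfg$ranges),
    bmp_shape = sc$bmp_shape,
    target = if (identical(sc$bmp_shape, "match_target")) targets$WT,
    genotypes = sc$genotypes,
    store_dir = file.path(out_dir, "store"),
    batch_size = sc$batch_size, species = sc$species,
    rtol = sc$rtol, n_save = sc$n_save, quiet = quiet
  )

  fitcfg <- do.call(fit_config, cfg$fit)
  labels <- classify_screen(store, targets, fitcfg)
  readr::write_csv(labels, file.path(out_dir, "labels.csv"), progress = FALSE)

  fitted <- labels[labels$pass_all, , drop = FALSE]
  summary <- list(
    seed = seed, n = sc$n_samples, bmp_shape = sc$bmp_shape,
    n_solver_failures = if (is.null(store$flags)) 0L else
      sum(!store$flags$success),
    n_pass_wt = sum(labels$pass_wt),
    n_pass_all = nrow(fitted),
    labels = as.list(table(fitted$label)),
    n_drosophila_like = sum(labels$droso, na.rm = TRUE)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_echo.yaml"))

  invisible(list(store = store, classification = labels, summary = summary))
}
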