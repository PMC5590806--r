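#' Run the random-parameter computational screen
#'
#' Draws `n` parameter vectors (log-uniform within the screen ranges) and
#' simulates each one under every requested genotype, changing only the
#' production fields between genotypes. Final concentration profiles, solver
#' flags and the wild-type BMP mass balance over the production region are
#' appended to a plain-text store that is checkpointed every `batch_size`
#' samples, so interrupted jobs restart at the last completed index with an
#' identical random stream (see [resume_screen()]).
#'
#' @param n Number of parameter vectors to screen.
#' @param seed Integer seed; drives the counter-based per-sample substreams.
#' @param geom A [dv_geometry()].
#' @param ranges Parameter ranges, see [param_ranges()].
#' @param bmp_shape BMP production shape preset or per-node vector, see
#'   [production_fields()].
#' @param target Per-node target profile, required for
#'   `bmp_shape = "match_target"`.
#' @param genotypes Genotypes simulated for every vector (default `WT`,
#'   `chd_null`, `chd_het`, `nog_null`; add `chd_uniform` for the robustness
#'   test).
#' @param store_dir Directory for the store (created if missing). `NULL`
#'   keeps the store in memory only.
#' @param batch_size Checkpoint interval in samples (default 500).
#' @param species Which final concentration fields to record (default all
#'   five; `"B"` alone suffices for fitting and classification).
#' @param rtol Relative solver tolerance (default 1e-9).
#' @param n_save Saved time points for the wild-type run (mass-balance
#'   quadrature; default 201). Mutant runs save only the final state.
#' @param stop_after Stop (checkpoint cleanly) after this many samples;
#'   used to exercise interruption/resume. `NULL` runs to completion.
#' @param quiet Suppress progress messages.
#' @return An object of class `dv_screen` (the store).
#' @examples
#' \donttest{
#' geom <- dv_geometry()
#' st <- run_screen(5, seed = 1, geom = geom, species = "B")
#' glance(st)
#' }
#' @export
run_screen <- function(n, seed, geom = dv_geometry(),
                       ranges = param_ranges(),
                       bmp_shape = "graded_default", target = NULL,
                       genotypes = c("WT", "chd_null", "chd_het", "nog_null"),
                       store_dir = NULL, batch_size = 500,
                       species = c("B", "C", "N", "BC", "BN"),
                       rtol = 1e-9, n_save = 201,
                       stop_after = NULL, quiet = TRUE) {
  species <- match.arg(species, several.ok = TRUE)
  if (!"WT" %in% genotypes) abort("`genotypes` must include \"WT\".")
  samples <- sample_parameters(ranges, n, seed)
  store <- new_screen_store(
    dir = store_dir, n = n, seed = seed, geom = geom, ranges = ranges,
    bmp_shape = bmp_shape, target = target, genotypes = genotypes,
    species = species, rtol = rtol, n_save = n_save, batch_size = batch_size
  )
  screen_loop(store, samples, from = 0L, stop_after = stop_after,
              quiet = quiet)
}

#' Resume an interrupted screen from its store
#'
#' Reloads the manifest and completed records, regenerates the parameter
#' stream from the persisted seed, verifies that the regenerated vectors match
#' the stored ones over the completed range (refusing to touch a store that
#' fails this integrity check) and continues from the last completed index.
#' A resumed store is identical to one produced by an uninterrupted run.
#'
#' @param store A `dv_screen` object or the path to a store directory.
#' @param stop_after,quiet See [run_screen()].
#' @return The completed (or further advanced) `dv_screen` store.
#' @export
resume_screen <- function(store, stop_after = NULL, quiet = TRUE) {
  if (is.character(store)) store <- read_screen(store)
  stopifnot(inherits(store, "dv_screen"))
  m <- store$manifest
  done <- m$last_completed
  if (done >= m$n) return(store)
  samples <- sample_parameters(ranges_from_manifest(m), m$n, m$seed)
  if (done > 0) {
    stored <- store$params[store$params$sample < done, , drop = FALSE]
    regen <- samples[samples$sample < done, names(stored), drop = FALSE]
    if (!isTRUE(all.equal(as.data.frame(stored), as.data.frame(regen),
                          tolerance = 1e-12))) {
      abort("Store integrity check failed: stored parameters do not match the regenerated stream; refusing to overwrite.")
    }
  }
  screen_loop(store, samples, from = done, stop_after = stop_after,
              quiet = quiet)
}

#' Read a screen store from disk
#'
#' @param dir Store directory written by [run_screen()].
#' @return A `dv_screen` object.
#' @export
read_screen <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("No manifest.json under \"%s\".", dir))
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  # base read.csv parses doubles with correctly-rounded strtod, which the
  # byte-identical round-trip contract needs
  read_tbl <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) as_tibble(utils::read.csv(p)) else NULL
  }
  structure(
    list(
      dir = dir, manifest = m,
      params = read_tbl("params.csv"),
      profiles = read_tbl("profiles.csv"),
      balance = read_tbl("balance.csv"),
      flags = read_tbl("flags.csv")
    ),
    class = "dv_screen"
  )
}

#' @export
print.dv_screen <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<dv_screen> %d/%d samples completed (seed %d, shape %s)%s\n",
    m$last_completed, m$n, m$seed, m$bmp_shape_label,
    if (is.null(x$dir)) " [in memory]" else paste0(" at ", x$dir)
  ))
  invisible(x)
}

# ---- internals --------------------------------------------------------------

new_screen_store <- function(dir, n, seed, geom, ranges, bmp_shape, target,
                             genotypes, species, rtol, n_save, batch_size) {
  shape_label <- if (is.character(bmp_shape)) bmp_shape else "custom"
  manifest <- list(
    format = "bmpgrad-screen-1", n = as.integer(n), seed = as.integer(seed),
    last_completed = 0L, batch_size = as.integer(batch_size),
    genotypes = genotypes, species = species,
    bmp_shape_label = shape_label,
    bmp_shape_vector = if (is.numeric(bmp_shape)) as.numeric(bmp_shape) else NULL,
    target = if (!is.null(target)) as.numeric(target) else NULL,
    rtol = rtol, n_save = as.integer(n_save),
    geometry = geom[c("axis_length", "n_nodes", "chd_domain_length",
                      "nog_domain_length", "tld_domain_length", "t_final")],
    ranges = as.data.frame(ranges)
  )
  structure(
    list(dir = dir, manifest = manifest, params = NULL, profiles = NULL,
         balance = NULL, flags = NULL),
    class = "dv_screen"
  )
}

ranges_from_manifest <- function(m) as_tibble(as.data.frame(m$ranges))

geometry_from_manifest <- function(m) do.call(dv_geometry, as.list(m$geometry))

fields_from_manifest <- function(m, params, geom) {
  shape <- switch(m$bmp_shape_label,
    custom = as.numeric(m$bmp_shape_vector),
    match_target = "match_target",
    m$bmp_shape_label
  )
  production_fields(geom, params, bmp_shape = shape,
                    target = if (!is.null(m$target)) as.numeric(m$target))
}

screen_loop <- function(store, samples, from, stop_after, quiet) {
  m <- store$manifest
  geom <- geometry_from_manifest(m)
  n_nodes <- geom$n_nodes
  upto <- if (is.null(stop_after)) m$n else min(m$n, from + stop_after)
  if (upto <= from) return(store)

  prof_rows <- list()
  bal_rows <- list()
  flag_rows <- list()
  k <- 0L

  flush <- function(completed) {
    store$manifest$last_completed <<- as.integer(completed)
    store$params <<- dplyr::bind_rows(
      store$params, samples[samples$sample >= from & samples$sample < completed, ]
    ) |> dplyr::distinct(.data$sample, .keep_all = TRUE)
    if (length(prof_rows) > 0) {
      store$profiles <<- dplyr::bind_rows(store$profiles,
                                          dplyr::bind_rows(prof_rows))
      prof_rows <<- list()
    }
    if (length(bal_rows) > 0) {
      store$balance <<- dplyr::bind_rows(store$balance,
                                         dplyr::bind_rows(bal_rows))
      bal_rows <<- list()
    }
    if (length(flag_rows) > 0) {
      store$flags <<- dplyr::bind_rows(store$flags,
                                       dplyr::bind_rows(flag_rows))
      flag_rows <<- list()
    }
    write_screen(store)
  }

  for (i in seq(from, upto - 1L)) {
    row <- samples[samples$sample == i, , drop = FALSE]
    params <- as_dv_params(row)
    fields <- fields_from_manifest(m, params, geom)
    region <- production_region(fields)
    for (g in m$genotypes) {
      gf <- apply_genotype(fields, g)
      sim <- simulate_gradient(params, gf, rtol = m$rtol,
                               n_save = if (g == "WT") m$n_save else 2L)
      k <- k + 1L
      flag_rows[[k]] <- tibble(sample = i, genotype = g,
                               success = sim$success)
      if (sim$success) {
        fin <- sim$final
        for (sp in m$species) {
          v <- as.list(fin[[sp]])
          names(v) <- paste0("v", seq_len(n_nodes))
          prof_rows[[length(prof_rows) + 1L]] <- as_tibble(
            c(list(sample = i, genotype = g, species = sp), v)
          )
        }
        if (g == "WT" && length(region) > 0 && m$n_save >= 3) {
          bal <- mass_balance(sim, region)
          bal_rows[[length(bal_rows) + 1L]] <- dplyr::bind_cols(
            tibble(sample = i), as_tibble(bal)
          )
        }
      }
    }
    done <- i + 1L
    if (done %% m$batch_size == 0 || done == upto) flush(done)
    if (!quiet && done %% 100 == 0) {
      message(sprintf("screen: %d/%d", done, m$n))
    }
  }
  store
}

write_screen <- function(store) {
  if (is.null(store$dir)) return(invisible(store))
  dir.create(store$dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(store$manifest, file.path(store$dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  # doubles are serialized at full precision ("%.17g") so that a store read
  # back from CSV and rewritten is byte-identical (round-trip contract)
  wr <- function(tbl, name) {
    if (is.null(tbl)) return(invisible(NULL))
    tbl <- dplyr::mutate(tbl, dplyr::across(
      dplyr::where(is.double),
      function(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
    ))
    readr::write_csv(tbl, file.path(store$dir, name), progress = FALSE)
  }
  wr(store$params, "params.csv")
  wr(store$profiles, "profiles.csv")
  wr(store$balance, "balance.csv")
  wr(store$flags, "flags.csv")
  invisible(store)
}

# final-profile matrix (samples x nodes) of one species/genotype, row-named
# by sample index; samples with failed solves are absent
profile_matrix <- function(store, genotype, species = "B") {
  pr <- store$profiles
  pr <- pr[pr$genotype == genotype & pr$species == species, , drop = FALSE]
  vm <- as.matrix(pr[, grepl("^v\\d+$", names(pr)), drop = FALSE])
  rownames(vm) <- pr$sample
  vm
}

#' Fit, gate and classify every record of a screen store
#'
#' Applies [gate_solution()] to every screened sample against per-genotype
#' targets, classifies wild-type-gated solutions with [classify_mechanism()],
#' and flags Drosophila-like solutions and (when a `chd_uniform` genotype was
#' simulated) robustness to uniform Chordin production.
#'
#' @param store A `dv_screen` store.
#' @param targets Named list of per-node target vectors: `WT` mandatory,
#'   `chd_null`, `chd_het` optional (their gates are skipped when absent).
#' @param cfg A [fit_config()].
#' @return A tibble of class `dv_classification`: one row per sample with the
#'   scale factor, NRMSDs, gate flags, mechanism `label`, `droso` flag and
#'   `uniform_chd` flag (NA when not simulated).
#' @export
classify_screen <- function(store, targets, cfg = fit_config()) {
  stopifnot(inherits(store, "dv_screen"))
  if (is.null(targets$WT)) abort("A wild-type target is required.")
  m <- store$manifest
  n_done <- m$last_completed
  mats <- lapply(stats::setNames(m$genotypes, m$genotypes),
                 function(g) profile_matrix(store, g, "B"))
  bal <- store$balance
  has_unif <- "chd_uniform" %in% m$genotypes

  rows <- vector("list", n_done)
  for (i in seq_len(n_done)) {
    id <- as.character(i - 1L)
    profs <- lapply(mats, function(vm) {
      if (id %in% rownames(vm)) vm[id, ] else NULL
    })
    ok <- !is.null(profs$WT)
    gate <- gate_solution(profs, targets, cfg, success = ok)
    label <- "unclassified"
    droso <- FALSE
    unif <- NA
    if (ok && !is.null(profs$chd_null) && !is.null(bal) &&
        (i - 1L) %in% bal$sample) {
      b <- bal[bal$sample == i - 1L, , drop = FALSE]
      if (isTRUE(gate$pass_wt)) {
        label <- classify_mechanism(b, profs$WT, profs$chd_null, cfg)
      }
      droso <- drosophila_like(b, profs$WT, profs$chd_null, cfg,
                               axis_length = m$geometry$axis_length)
      if (has_unif && !is.null(profs$chd_uniform) && !is.na(gate$s)) {
        unif <- uniform_chd_robust(profs$chd_uniform, targets$WT, gate$s, cfg)
      }
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble(sample = i - 1L), gate,
      tibble(label = label, droso = droso, uniform_chd = unif)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dv_classification", class(out))
  out
}
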