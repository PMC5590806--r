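#' Per-node production fields and Tolloid activity indicator
#'
#' Maps the expression-domain geometry onto the finite-difference grid:
#' Chordin production on the dorsal-most `chd_domain_length` um, Noggin on the
#' dorsal-most `nog_domain_length` um, Tolloid activity on the ventral-most
#' `tld_domain_length` um, and a graded BMP production profile. A node belongs
#' to a domain iff its centre lies within the domain interval.
#'
#' The BMP production shape presets are:
#' * `"graded_default"`: linear ramp from 1 at the ventral end to 0 at 500 um,
#'   0 dorsal of that -- a broad ventrally-graded transcription profile.
#' * `"match_target"`: proportional to a supplied target signaling profile
#'   (already resampled to the model grid, see [resample_to_model_grid()]),
#'   for the alternative scenario in which *bmp* expression mirrors the
#'   measured signaling gradient.
#' * a numeric per-node weight vector (non-negative, length `n_nodes`).
#'
#' Shapes are normalized to maximum 1 before scaling by `eta_B`.
#'
#' @param geom A [dv_geometry()].
#' @param params A [dv_params()] vector supplying `eta_B`, `eta_C`, `eta_N`.
#' @param bmp_shape `"graded_default"`, `"match_target"`, or a numeric vector.
#' @param target Per-node target profile, required when
#'   `bmp_shape = "match_target"`.
#' @return An object of class `dv_fields`: list with per-node `eta_B`,
#'   `eta_C`, `eta_N` (nM/s), the 0/1 `tld` indicator, the `shape` used, and
#'   the geometry.
#' @examples
#' geom <- dv_geometry()
#' f <- production_fields(geom, dv_params())
#' range(geom$x[f$eta_C > 0]) # dorsal-most 145 um
#' @export
production_fields <- function(geom, params, bmp_shape = "graded_default",
                              target = NULL) {
  stopifnot(inherits(geom, "dv_geometry"))
  params <- as_dv_params(params)
  x <- geom$x
  n <- geom$n_nodes
  if (is.character(bmp_shape)) {
    shape <- switch(bmp_shape,
      graded_default = pmax(0, 1 - x / 500),
      match_target = {
        if (is.null(target)) {
          abort("bmp_shape = \"match_target\" requires `target`.")
        }
        if (length(target) != n || any(target < 0)) {
          abort("`target` must be a non-negative per-node vector.")
        }
        as.numeric(target)
      },
      abort(sprintf("Unknown bmp_shape preset \"%s\".", bmp_shape))
    )
    shape_label <- bmp_shape
  } else {
    if (!is.numeric(bmp_shape) || length(bmp_shape) != n) {
      abort("Custom `bmp_shape` must be a numeric vector of length n_nodes.")
    }
    if (any(bmp_shape < 0)) abort("Custom `bmp_shape` must be non-negative.")
    shape <- as.numeric(bmp_shape)
    shape_label <- "custom"
  }
  if (max(shape) > 0) shape <- shape / max(shape)

  chd_on <- x >= geom$axis_length - geom$chd_domain_length
  nog_on <- x >= geom$axis_length - geom$nog_domain_length
  tld_on <- x <= geom$tld_domain_length

  structure(
    list(
      eta_B = unname(params[["eta_B"]]) * shape,
      eta_C = unname(params[["eta_C"]]) * as.numeric(chd_on),
      eta_N = unname(params[["eta_N"]]) * as.numeric(nog_on),
      tld = as.numeric(tld_on),
      shape = shape, shape_label = shape_label,
      genotype = "WT",
      geom = geom
    ),
    class = "dv_fields"
  )
}

#' Genotype perturbations of the production fields
#'
#' Re-simulation of a parameter vector under a mutant condition changes only
#' the production fields: `chd_null` removes Chordin production, `chd_het`
#' halves it (heterozygotes are assumed to have half the wild-type Chordin
#' level), `nog_null` removes Noggin production, and `chd_uniform` produces
#' Chordin at the wild-type per-node rate on every node (ubiquitous
#' production, used for the robustness test).
#'
#' @param fields A `dv_fields` object from [production_fields()].
#' @param genotype One of `"WT"`, `"chd_null"`, `"chd_het"`, `"nog_null"`,
#'   `"chd_uniform"`.
#' @return A modified `dv_fields` object with the `genotype` label updated.
#' @examples
#' f <- production_fields(dv_geometry(), dv_params())
#' all(apply_genotype(f, "chd_null")$eta_C == 0)
#' @export
apply_genotype <- function(fields, genotype) {
  stopifnot(inherits(fields, "dv_fields"))
  if (!is.character(genotype) || length(genotype) != 1) {
    abort("`genotype` must be a single string.")
  }
  out <- fields
  switch(genotype,
    WT = NULL,
    chd_null = { out$eta_C <- out$eta_C * 0 },
    chd_het = { out$eta_C <- out$eta_C * 0.5 },
    nog_null = { out$eta_N <- out$eta_N * 0 },
    chd_uniform = {
      rate <- max(fields$eta_C)
      out$eta_C <- rep(rate, fields$geom$n_nodes)
    },
    abort(sprintf("Unknown genotype \"%s\".", genotype))
  )
  out$genotype <- genotype
  out
}

#' @export
print.dv_fields <- function(x, ...) {
  cat(sprintf(
    "<dv_fields> genotype %s, bmp shape %s; nonzero nodes: eta_B %d, eta_C %d, eta_N %d, tld %d\n",
    x$genotype, x$shape_label, sum(x$eta_B > 0), sum(x$eta_C > 0),
    sum(x$eta_N > 0), sum(x$tld > 0)
  ))
  invisible(x)
}
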