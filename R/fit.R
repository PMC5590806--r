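#' Fitting and classification configuration
#'
#' Thresholds and modes used to score screened solutions against target
#' profiles and to classify their gradient-forming mechanism.
#'
#' @param nrmsd_threshold Pass gate on the normalized root-mean-squared
#'   deviation between scaled model and target (default 0.08, i.e. 8%).
#' @param shuttling_drop Minimum relative decrease of the ventral-most BMP
#'   level in the Chordin null compared to wild type that defines shuttling
#'   (default 0.20).
#' @param transcriptional_fraction Minimum fraction of produced BMP that is
#'   degraded or accumulates at its site of production for the transcriptional
#'   label (default 0.80).
#' @param het_chd_factor Chordin level of heterozygotes relative to wild type
#'   (default 0.5).
#' @param droso_halfmax_fraction Half-maximum position as a fraction of the
#'   axis below which a wild-type gradient counts as Drosophila-steep
#'   (default 0.10).
#' @param droso_peak_drop Minimum ventral peak drop in the Chordin null for a
#'   Drosophila-like solution (default 0.50).
#' @param droso_max_nog_bound_fraction Maximum net BMP-Noggin binding as a
#'   fraction of produced BMP (Drosophila has no noggin; default 0.05).
#' @param nog_consistency_threshold NRMSD between wild-type and Noggin-null
#'   model profiles above which a solution is eliminated (default 0.08).
#' @param normalization `"peak"` (default: match peak levels) or
#'   `"least_squares"` (normal-equation scale).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(nrmsd_threshold = 0.08, shuttling_drop = 0.20,
                       transcriptional_fraction = 0.80, het_chd_factor = 0.5,
                       droso_halfmax_fraction = 0.10, droso_peak_drop = 0.50,
                       droso_max_nog_bound_fraction = 0.05,
                       nog_consistency_threshold = 0.08,
                       normalization = c("peak", "least_squares")) {
  normalization <- match.arg(normalization)
  fr <- c(
    nrmsd_threshold = nrmsd_threshold, shuttling_drop = shuttling_drop,
    transcriptional_fraction = transcriptional_fraction,
    het_chd_factor = het_chd_factor,
    droso_halfmax_fraction = droso_halfmax_fraction,
    droso_peak_drop = droso_peak_drop,
    droso_max_nog_bound_fraction = droso_max_nog_bound_fraction,
    nog_consistency_threshold = nog_consistency_threshold
  )
  if (any(fr <= 0 | fr > 1)) abort("All fractions must lie in (0, 1].")
  structure(
    c(as.list(fr), list(normalization = normalization)),
    class = "fit_config"
  )
}

#' Amplitude scale between a model BMP profile and a target profile
#'
#' The model works in nM while targets are fluorescence intensities (a.u.),
#' so a single scale factor `s` is fitted on the wild-type pair and then
#' applied unchanged to every mutant profile of the same parameter vector.
#' `"peak"` mode matches peak levels, `s = max(target) / max(model)`;
#' `"least_squares"` mode solves the normal equation
#' `s = sum(model * target) / sum(model^2)`.
#'
#' @param model_B Per-node model BMP profile (nM), wild type.
#' @param target Per-node target profile (a.u.), same grid.
#' @param mode `"peak"` or `"least_squares"`.
#' @return The scale factor, or `NA_real_` (unfit) when the model profile is
#'   identically zero.
#' @export
normalize_scale <- function(model_B, target, mode = c("peak", "least_squares")) {
  mode <- match.arg(mode)
  if (length(model_B) != length(target)) {
    abort("model and target must have equal length.")
  }
  if (max(model_B) <= 0) return(NA_real_)
  if (mode == "peak") {
    max(target) / max(model_B)
  } else {
    sum(model_B * target) / sum(model_B^2)
  }
}

#' Normalized root-mean-squared deviation
#'
#' RMSD between a scaled model profile and a target, divided by the maximum of
#' the target, so a constant offset of 8% of the target peak gives exactly
#' 0.08. Scale-invariant: multiplying both profiles by the same factor leaves
#' it unchanged.
#'
#' @param scaled_model Per-node scaled model profile.
#' @param target Per-node target profile; `max(target)` must be positive.
#' @return The NRMSD as a fraction.
#' @export
nrmsd <- function(scaled_model, target) {
  if (length(scaled_model) != length(target)) {
    abort("model and target must have equal length.")
  }
  m <- max(target)
  if (m <= 0) abort("`target` must have a positive maximum.")
  sqrt(mean((scaled_model - target)^2)) / m
}

#' Gate a screened solution against per-genotype targets
#'
#' A solution passes the wild-type gate iff the NRMSD between the scaled model
#' BMP profile and the wild-type target is at most `nrmsd_threshold`. Mutant
#' gates reuse the wild-type scale factor. The Noggin-consistency gate
#' eliminates solutions whose Noggin-null BMP profile deviates from the
#' wild-type model profile by more than `nog_consistency_threshold` (loss of
#' Noggin does not affect dorsoventral patterning).
#'
#' @param profiles Named list of per-node model BMP profiles; must contain
#'   `WT`, optionally `chd_null`, `chd_het`, `nog_null`.
#' @param targets Named list of per-node target vectors; `WT` mandatory,
#'   `chd_null` and `chd_het` optional.
#' @param cfg A [fit_config()].
#' @param success Solver success flag; failed records fail every gate.
#' @return A one-row tibble: scale `s`, per-genotype NRMSDs, pass flags and
#'   the overall `pass_all`.
#' @export
gate_solution <- function(profiles, targets, cfg = fit_config(),
                          success = TRUE) {
  if (is.null(targets$WT)) abort("A wild-type target is required.")
  na_row <- tibble(
    s = NA_real_, nrmsd_wt = NA_real_, nrmsd_chd_null = NA_real_,
    nrmsd_chd_het = NA_real_, nrmsd_nog = NA_real_,
    pass_wt = FALSE, pass_chd_null = FALSE, pass_chd_het = FALSE,
    pass_nog = FALSE, pass_all = FALSE
  )
  if (!isTRUE(success) || is.null(profiles$WT)) return(na_row)
  s <- normalize_scale(profiles$WT, targets$WT, cfg$normalization)
  if (is.na(s)) return(na_row)

  nr_wt <- nrmsd(s * profiles$WT, targets$WT)
  pass_wt <- nr_wt <= cfg$nrmsd_threshold

  gate_mut <- function(genotype) {
    if (is.null(targets[[genotype]]) || is.null(profiles[[genotype]])) {
      return(list(nr = NA_real_, pass = TRUE)) # gate not requested
    }
    nr <- nrmsd(s * profiles[[genotype]], targets[[genotype]])
    list(nr = nr, pass = nr <= cfg$nrmsd_threshold)
  }
  g_cn <- gate_mut("chd_null")
  g_ch <- gate_mut("chd_het")

  if (!is.null(profiles$nog_null)) {
    nr_nog <- nrmsd(s * profiles$nog_null, s * profiles$WT)
    pass_nog <- nr_nog <= cfg$nog_consistency_threshold
  } else {
    nr_nog <- NA_real_
    pass_nog <- TRUE
  }

  tibble(
    s = s, nrmsd_wt = nr_wt, nrmsd_chd_null = g_cn$nr,
    nrmsd_chd_het = g_ch$nr, nrmsd_nog = nr_nog,
    pass_wt = pass_wt, pass_chd_null = g_cn$pass, pass_chd_het = g_ch$pass,
    pass_nog = pass_nog,
    pass_all = pass_wt && g_cn$pass && g_ch$pass && pass_nog
  )
}
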