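# Observation model: fluorescence observables are model species scaled from
# nM into arbitrary units (a.u.). The membrane GFP region of interest
# contains free and Epo-bound receptor; the cytoplasmic Cy5.5 signal is the
# sum of intact and degraded label because the dye survives proteolysis.

.OBS_EPO <- c("EpoR_GFP_mem", "EpoR_GFP_ves", "EpoR_GFP_Cy55ves",
              "Epo_Cy55_mem", "Epo_Cy55_cpl")
.OBS_RED <- c("EpoR_GFP_mem", "EpoR_GFP_ves")

#' Observable names per condition
#'
#' Epo-stimulated cells have five observables (membrane GFP, vesicular GFP
#' without Epo, GFP in Epo-Cy5.5 vesicles, membrane Cy5.5, cytoplasmic
#' Cy5.5); bleach/CHX cells only the two GFP observables.
#'
#' @param condition `"epo"`, `"bleach"` or `"chx"`.
#' @return Character vector of observable names.
#' @export
observables <- function(condition = "epo") {
  condition <- match.arg(condition, c("epo", "bleach", "chx"))
  if (condition == "epo") .OBS_EPO else .OBS_RED
}

#' Map model states to fluorescence observables
#'
#' Linear readout: `EpoR_GFP_mem = scale * (EpoR_m + EpoRstar_m)`,
#' `EpoR_GFP_ves = scale * EpoR_i`, `EpoR_GFP_Cy55ves = scale * EpoRstar_RE`,
#' `Epo_Cy55_mem = scale * EpoRstar_m`,
#' `Epo_Cy55_cpl = scale * (EpoRstar_RE + Epo_deg_i)`. Dark/degraded receptor
#' pools of the reduced models are excluded from the GFP observables.
#'
#' @param states A trajectory matrix from [simulate_cell()] or a single named
#'   state vector.
#' @param condition Condition whose observable set to produce.
#' @param scales Named vector of scaling factors (a.u. per nM) per
#'   observable; defaults to 1 for each.
#' @return Matrix (times x observables) in a.u. (or a named vector for a
#'   single state).
#' @export
observe <- function(states, condition = "epo", scales = NULL) {
  single <- is.null(dim(states))
  if (single) states <- matrix(states, 1, dimnames = list(NULL, names(states)))
  obs_names <- observables(condition)
  if (is.null(scales)) scales <- setNames(rep(1, length(obs_names)), obs_names)
  unknown <- setdiff(names(scales), obs_names)
  if (length(unknown) > 0)
    stop("unknown observable name(s): ", paste(unknown, collapse = ", "))
  sc <- setNames(rep(1, length(obs_names)), obs_names)
  sc[names(scales)] <- scales
  if (any(sc <= 0)) stop("scales must be > 0")
  out <- matrix(0, nrow(states), length(obs_names),
                dimnames = list(NULL, obs_names))
  out[, "EpoR_GFP_mem"] <- states[, "EpoR_m"] +
    if (condition == "epo") states[, "EpoRstar_m"] else 0
  out[, "EpoR_GFP_ves"] <- states[, "EpoR_i"]
  if (condition == "epo") {
    out[, "EpoR_GFP_Cy55ves"] <- states[, "EpoRstar_RE"]
    out[, "Epo_Cy55_mem"] <- states[, "EpoRstar_m"]
    out[, "Epo_Cy55_cpl"] <- states[, "EpoRstar_RE"] + states[, "Epo_deg_i"]
  }
  out <- sweep(out, 2, sc[obs_names], `*`)
  if (single) out[1, ] else out
}

#' Measurement-error model and weighted squared residual
#'
#' The standard deviation of a measured point is
#' `sigma = sigma_rel * max(predicted, floor) + sigma_abs`; the chi-square
#' contribution of one point is `((observed - predicted) / sigma)^2`.
#'
#' @param observed,predicted Values in a.u. (vectorized).
#' @param sigma_rel Relative error component (unitless, default 0.1).
#' @param sigma_abs Absolute error component (a.u.).
#' @param floor Lower bound on the prediction entering the relative part,
#'   guarding against vanishing weights near zero signal.
#' @return `chi2_contribution`: unitless squared weighted residual;
#'   `obs_sigma`: the standard deviation in a.u.
#' @export
chi2_contribution <- function(observed, predicted, sigma_rel = 0.1,
                              sigma_abs = 0, floor = 0) {
  s <- obs_sigma(predicted, sigma_rel, sigma_abs, floor)
  if (any(s <= 0)) stop("error model gives sigma <= 0; set sigma_abs or floor")
  ((observed - predicted) / s)^2
}

#' @rdname chi2_contribution
#' @export
obs_sigma <- function(predicted, sigma_rel = 0.1, sigma_abs = 0, floor = 0) {
  stopifnot(sigma_rel >= 0, sigma_abs >= 0)
  sigma_rel * pmax(predicted, floor) + sigma_abs
}

# Per-observable error-model defaults derived from the data: absolute floor
# at 1% of each observable's data maximum, keeping weights finite where the
# signal vanishes; imaging pipelines rarely report a calibrated error model.
default_error_model <- function(data, sigma_rel = 0.1, abs_frac = 0.01) {
  mx <- tapply(data$value_au, data$observable, max)
  list(sigma_rel = sigma_rel,
       sigma_abs = setNames(abs_frac * as.numeric(mx), names(mx)),
       floor = setNames(abs_frac * as.numeric(mx), names(mx)))
}
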