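# The trafficking ODE system, reduced bleach/CHX models and solvers.
#
# Species (nM): EpoR_i (intracellular free receptor), EpoR_m (membrane free
# receptor), EpoRstar_m (membrane Epo-EpoR complex), EpoRstar_RE (complex in
# the recycling-endosome compartment), Epo_deg_i (cumulative intracellular
# degraded Epo), Epo_deg_ext (cumulative exported degraded Epo). A seventh
# bookkeeping column "pool" tracks, per condition, intact Epo released via
# part A (epo), the bleached receptor pool (bleach) or cumulative degraded
# receptor (chx). Extracellular Epo is a constant input, not a state.

.cond_code <- function(condition)
  match(condition, c("epo", "bleach", "chx")) - 1L

#' Right-hand side of the trafficking ODE system
#'
#' Time derivatives of the six model species for a given variant, kinetic
#' parameters and constant extracellular Epo concentration. All reactions are
#' first order; Epo binding is pseudo-first-order because the medium is not
#' depleted.
#'
#' @param variant Model variant (name or `epor_variant`).
#' @param params Named kinetic parameters of the variant's Epo-condition
#'   model (see [kinetic_param_names()]). Supplying a parameter the variant
#'   excludes is an error.
#' @param state Named state vector with components `EpoR_i`, `EpoR_m`,
#'   `EpoRstar_m`, `EpoRstar_RE`, `Epo_deg_i`, `Epo_deg_ext`.
#' @param epo Extracellular Epo concentration (nM, >= 0).
#' @return Named vector of derivatives (nM/min) of the six species.
#' @export
epor_rhs <- function(variant, params, state, epo) {
  stopifnot(epo >= 0)
  p <- as_param_vector(params, variant, "epo")
  s <- state[.STATE_NAMES]
  if (any(is.na(s))) stop("state must contain: ",
                          paste(.STATE_NAMES, collapse = ", "))
  d_Ri <- p["k_EpoR_syn"] - (p["k_EpoR_deg"] + p["k_EpoR_ItoM"]) * s["EpoR_i"] +
    p["k_EpoR_MtoI"] * s["EpoR_m"] + p["k_EpoRstar_REtoI"] * s["EpoRstar_RE"]
  d_Rm <- p["k_EpoR_ItoM"] * s["EpoR_i"] - p["k_EpoR_MtoI"] * s["EpoR_m"] -
    p["k_on_Epo"] * epo * s["EpoR_m"] + p["k_off_Epo"] * s["EpoRstar_m"] +
    p["k_EpoRstar_REtoM"] * s["EpoRstar_RE"]
  d_Sm <- p["k_on_Epo"] * epo * s["EpoR_m"] -
    (p["k_off_Epo"] + p["k_EpoRstar_MtoRE"]) * s["EpoRstar_m"]
  exit <- p["k_EpoRstar_REtoM"] + p["k_EpoRstar_REtoI"] +
    p["k_EpoRstar_deg_REtoEx"] + p["k_EpoRstar_deg_REtoI"]
  d_Sre <- p["k_EpoRstar_MtoRE"] * s["EpoRstar_m"] - exit * s["EpoRstar_RE"]
  d_Di <- (p["k_EpoRstar_REtoI"] + p["k_EpoRstar_deg_REtoI"]) * s["EpoRstar_RE"]
  d_Dx <- p["k_EpoRstar_deg_REtoEx"] * s["EpoRstar_RE"]
  setNames(as.numeric(c(d_Ri, d_Rm, d_Sm, d_Sre, d_Di, d_Dx)), .STATE_NAMES)
}

#' Pre-stimulus steady state of free receptor
#'
#' Without ligand the complexes vanish and receptor turnover settles to
#' `EpoR_i = k_syn / k_deg` and `EpoR_m = (k_ItoM / k_MtoI) * EpoR_i`; the
#' membrane fraction of total receptor is `k_ItoM / (k_ItoM + k_MtoI)`.
#'
#' @param params Named parameters containing at least `k_EpoR_syn`,
#'   `k_EpoR_deg`, `k_EpoR_ItoM`, `k_EpoR_MtoI` (deg and MtoI must be > 0).
#' @return Named vector `c(EpoR_i =, EpoR_m =)` in nM.
#' @export
prestimulus_steady_state <- function(params) {
  need <- c("k_EpoR_syn", "k_EpoR_deg", "k_EpoR_ItoM", "k_EpoR_MtoI")
  p <- params[need]
  if (any(is.na(p))) stop("params must contain: ", paste(need, collapse = ", "))
  if (p["k_EpoR_deg"] <= 0 || p["k_EpoR_MtoI"] <= 0)
    stop("k_EpoR_deg and k_EpoR_MtoI must be > 0 for a steady state")
  ri <- unname(p["k_EpoR_syn"] / p["k_EpoR_deg"])
  rm_ <- unname(p["k_EpoR_ItoM"] / p["k_EpoR_MtoI"]) * ri
  c(EpoR_i = ri, EpoR_m = rm_)
}

#' Membrane fraction of total receptor at the pre-stimulus steady state
#' @inheritParams prestimulus_steady_state
#' @return `k_ItoM / (k_ItoM + k_MtoI)` (unitless).
#' @export
membrane_fraction <- function(params)
  unname(params["k_EpoR_ItoM"] /
           (params["k_EpoR_ItoM"] + params["k_EpoR_MtoI"]))

#' Reduced models for the auxiliary experiments
#'
#' Describes the variant-independent models used for photobleached and
#' CHX-treated cells: 3 state equations each, with 5 (bleach) or 3 (chx)
#' kinetic parameters. Bleaching is a first-order loss of fluorescent
#' receptor into a dark pool, active only during the pulse window; CHX sets
#' synthesis to zero from the treatment time.
#'
#' @param condition `"bleach"` or `"chx"`.
#' @return List with `states`, `kinetic_params`, `n_odes`, `n_kinetic`.
#' @export
reduced_model <- function(condition = c("bleach", "chx")) {
  condition <- match.arg(condition)
  if (condition == "bleach")
    list(condition = "bleach",
         states = c("EpoR_i", "EpoR_m", "EpoR_bleached"),
         kinetic_params = kinetic_param_names(condition = "bleach"),
         n_odes = 3L, n_kinetic = 5L)
  else
    list(condition = "chx",
         states = c("EpoR_i", "EpoR_m", "EpoR_degraded"),
         kinetic_params = kinetic_param_names(condition = "chx"),
         n_odes = 3L, n_kinetic = 3L)
}

# Default initial state: free receptor at its pre-stimulus steady state, no
# complexes, empty bookkeeping pools.
default_init <- function(params) {
  ss <- prestimulus_steady_state(params)
  c(EpoR_i = unname(ss["EpoR_i"]), EpoR_m = unname(ss["EpoR_m"]),
    EpoRstar_m = 0, EpoRstar_RE = 0, Epo_deg_i = 0, Epo_deg_ext = 0,
    pool = 0)
}

#' Simulate a single cell under a stimulus protocol
#'
#' Solves the trafficking system at the protocol's sample times. Because the
#' system is linear for piecewise-constant inputs, the default method solves
#' each protocol segment exactly through an eigendecomposition (compiled
#' code); `method = "lsoda"` integrates the same system with
#' [deSolve::lsoda()], restarting at event times, and serves as the
#' independent numerical route.
#'
#' @param variant Model variant; ignored for bleach/chx protocols (pass e.g.
#'   `""`).
#' @param params Named kinetic parameters for the protocol's condition model.
#' @param protocol An [epo_protocol()], [bleach_protocol()] or
#'   [chx_protocol()].
#' @param init Optional named initial state (length 6 or 7, see Details);
#'   defaults to the pre-stimulus steady state with zero complexes. The
#'   state refers to the first sample time.
#' @param method `"analytic"` (default) or `"lsoda"`.
#' @param rtol,atol Integration tolerances for the lsoda route.
#' @return Matrix (times x 7) with columns `EpoR_i`, `EpoR_m`, `EpoRstar_m`,
#'   `EpoRstar_RE`, `Epo_deg_i`, `Epo_deg_ext`, `pool`; attributes `times`,
#'   `protocol`, `variant`. The `pool` column is condition bookkeeping:
#'   intact Epo released via part A (epo), bleached receptor (bleach),
#'   degraded receptor (chx).
#' @export
simulate_cell <- function(variant, params, protocol, init = NULL,
                          method = c("analytic", "lsoda"),
                          rtol = 1e-10, atol = 1e-12) {
  method <- match.arg(method)
  stopifnot(inherits(protocol, "epor_protocol"))
  cond <- protocol$condition
  p <- as_param_vector(params, variant, cond)
  if (is.null(init)) init <- default_init(p)
  if (length(init) == 6) init <- c(init, pool = 0)
  if (any(init < 0) || any(!is.finite(init)))
    stop("initial state must be nonnegative and finite")
  y0 <- as.numeric(init[1:4])
  cum0 <- as.numeric(init[5:7])
  times <- protocol$sample_times

  if (method == "analytic") {
    sol <- solve_traffic_cpp(times, y0, cum0, unname(p), .cond_code(cond),
                             protocol$epo_conc,
                             protocol$add_time %||% 0,
                             protocol$bleach_start %||% -1,
                             protocol$bleach_end %||% -1,
                             protocol$chx_time %||% -1)
    if (!sol$ok) {
      return(simulate_cell(variant, params, protocol, init, "lsoda",
                           rtol, atol))
    }
    out <- sol$states
  } else {
    out <- .simulate_lsoda(p, cond, protocol, c(y0, cum0), rtol, atol)
  }
  if (any(!is.finite(out)))
    stop("integration failure (condition ", cond, ", variant '",
         epor_variant(if (cond == "epo") variant else "")$name, "')")
  dimnames(out) <- list(NULL, c(.STATE_NAMES, "pool"))
  structure(out, times = times, protocol = protocol,
            variant = if (cond == "epo") epor_variant(variant)$name else NULL,
            class = c("epor_traj", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deSolve route: same piecewise-constant system, integration restarted at
# every event boundary rather than switching inside the right-hand side.
.simulate_lsoda <- function(p, cond, protocol, y0, rtol, atol) {
  times <- protocol$sample_times
  events <- switch(cond,
                   epo = protocol$add_time,
                   bleach = c(protocol$bleach_start, protocol$bleach_end),
                   chx = protocol$chx_time)
  bounds <- sort(unique(c(times[1], events[events > times[1] &
                                            events < max(times)], max(times))))
  full_rhs <- function(t, y, parms) {
    epo <- parms$epo
    kb <- parms$kb
    syn <- parms$syn
    d1 <- syn - (p[4] + p[5] + kb) * y[1] + p[6] * y[2] + p[9] * y[4]
    d2 <- p[5] * y[1] - (p[6] + p[1] * epo + kb) * y[2] + p[2] * y[3] +
      p[8] * y[4]
    d3 <- p[1] * epo * y[2] - (p[2] + p[7]) * y[3]
    d4 <- p[7] * y[3] - (p[8] + p[9] + p[10] + p[11]) * y[4]
    d5 <- (p[9] + p[11]) * y[4]
    d6 <- p[10] * y[4]
    d7 <- switch(cond, epo = p[8] * y[4], bleach = kb * (y[1] + y[2]),
                 chx = p[4] * y[1])
    list(c(d1, d2, d3, d4, d5, d6, d7))
  }
  out <- matrix(NA_real_, length(times), 7)
  it <- which(times <= bounds[1])
  for (i in it) out[i, ] <- y0
  y <- y0
  for (s in seq_len(length(bounds) - 1)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1]
    tm <- (t0 + t1) / 2
    parms <- list(
      epo = if (cond == "epo" && tm > protocol$add_time) protocol$epo_conc else 0,
      kb = if (cond == "bleach" && tm > protocol$bleach_start &&
                 tm < protocol$bleach_end) p[12] else 0,
      syn = if (cond == "chx" && tm > protocol$chx_time) 0 else p[3])
    sel <- which(times > t0 & times <= t1)
    tt <- sort(unique(c(t0, times[sel], t1)))
    sol <- deSolve::lsoda(y, tt, full_rhs, parms, rtol = rtol, atol = atol)
    if (length(sel) > 0)
      out[sel, ] <- sol[match(times[sel], sol[, 1]), -1, drop = FALSE]
    y <- as.numeric(sol[nrow(sol), -1])
  }
  out
}

#' @export
print.epor_traj <- function(x, ...) {
  pr <- attr(x, "protocol")
  cat("Simulated trajectory (", pr$condition, "), ",
      nrow(x), " time points, t in [", min(attr(x, "times")), ", ",
      max(attr(x, "times")), "] min\n", sep = "")
  print(utils::head(cbind(time = attr(x, "times"), unclass(x)), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}
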