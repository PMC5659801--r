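# Synthetic single-cell trajectory generator. Per-cell kinetic parameters
# are drawn from a correlated multivariate log-normal; each cell starts at
# its pre-stimulus steady state, is simulated under its protocol, observed
# with unit scales and corrupted by multiplicative log-normal noise.

.SAMPLED_TYPES <- c("k_EpoR_syn", "k_EpoR_deg", "k_EpoR_ItoM", "k_EpoR_MtoI",
                    "k_EpoRstar_MtoRE", "k_EpoRstar_REtoM",
                    "k_EpoRstar_REtoI", "k_EpoRstar_deg_REtoEx",
                    "k_EpoRstar_deg_REtoI", "k_bleach")
.TRANSPORT_TYPES <- c("k_EpoR_ItoM", "k_EpoR_MtoI", "k_EpoRstar_MtoRE",
                      "k_EpoRstar_REtoM")

#' Default generating parameter distribution
#'
#' Log10 medians and SDs of the per-cell kinetic parameters. Medians are
#' calibrated so the population reproduces the imaging study's emergent
#' statistics: mean membrane receptor fraction 7.6% with SD ~2.1 percentage
#' points, total receptor ~43 nM, free-receptor cycling of ~1% of the total
#' per minute before stimulation, an Epo-EpoR internalization flux of
#' ~0.8 nM/min with recycling back to the membrane of similar magnitude to
#' the free-receptor transport flux, degradation mostly with export of the
#' consumed ligand, and 5-h output CVs in the 0.2-0.5 band.
#'
#' @return Data frame with columns `name`, `log10_mean`, `log10_sd`.
#' @export
default_parameter_table <- function() {
  data.frame(
    name = .SAMPLED_TYPES,
    log10_mean = log10(c(0.6, 0.015, 0.0104125, 0.1313, 0.26, 0.12,
                         0.06, 0.08, 0.03, 3)),
    log10_sd = c(0.10, 0.10, 0.165, 0.165, 0.165, 0.165,
                 0.15, 0.15, 0.15, 0.15))
}

#' Configuration of the synthetic-data generator
#'
#' Defines the simulated study: 16 Epo-stimulated cells with five
#' observables, 10 photobleached and 7 CHX-treated cells with two
#' observables each, per-cell parameters from a correlated multivariate
#' log-normal (pairwise correlation `rho_transport` among the four transport
#' parameters, zero elsewhere), Epo at 4.2 nM, the imaging grid (5-min steps
#' to 30 min, then 10-min steps to 300 min) and multiplicative log-normal
#' measurement noise.
#'
#' @param n_epo_cells,n_bleach_cells,n_chx_cells Cells per condition.
#' @param true_variant Generating model variant (default `"ACD"`).
#' @param param_table Data frame as [default_parameter_table()].
#' @param rho_transport Pairwise log-scale correlation among
#'   `k_EpoR_ItoM`, `k_EpoR_MtoI`, `k_EpoRstar_MtoRE`, `k_EpoRstar_REtoM`.
#' @param k_on_Epo,k_off_Epo Global Epo binding/unbinding rates shared by
#'   all cells (per-nM-per-min, per-min).
#' @param epo_conc Epo concentration (nM).
#' @param sample_times Sampling grid (min).
#' @param sigma_rel Log-normal noise SD (relative scale).
#' @param seed Default seed used when none is passed to the sampling
#'   functions.
#' @return An object of class `epor_genconfig`.
#' @export
generator_config <- function(n_epo_cells = 16, n_bleach_cells = 10,
                             n_chx_cells = 7, true_variant = "ACD",
                             param_table = default_parameter_table(),
                             rho_transport = 0.7,
                             k_on_Epo = 0.5, k_off_Epo = 0.1,
                             epo_conc = 4.2,
                             sample_times = default_grid(),
                             sigma_rel = 0.1, seed = 1L) {
  stopifnot(n_epo_cells >= 1, n_bleach_cells >= 0, n_chx_cells >= 0,
            sigma_rel >= 0, rho_transport > -1, rho_transport < 1)
  stopifnot(all(.SAMPLED_TYPES %in% param_table$name))
  cfg <- structure(
    list(n_epo_cells = n_epo_cells, n_bleach_cells = n_bleach_cells,
         n_chx_cells = n_chx_cells,
         true_variant = epor_variant(true_variant)$name,
         param_table = param_table, rho_transport = rho_transport,
         k_on_Epo = k_on_Epo, k_off_Epo = k_off_Epo, epo_conc = epo_conc,
         sample_times = sample_times, sigma_rel = sigma_rel,
         seed = as.integer(seed)),
    class = "epor_genconfig")
  ev <- eigen(generator_correlation(cfg), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("correlation structure is not positive semidefinite")
  cfg
}

# Log-scale correlation matrix over the sampled parameter types.
generator_correlation <- function(config) {
  k <- length(.SAMPLED_TYPES)
  R <- diag(k)
  dimnames(R) <- list(.SAMPLED_TYPES, .SAMPLED_TYPES)
  idx <- match(.TRANSPORT_TYPES, .SAMPLED_TYPES)
  R[idx, idx] <- config$rho_transport
  diag(R) <- 1
  R
}

#' Draw per-cell kinetic parameters and initial states
#'
#' Samples one full kinetic parameter vector per cell from the generator's
#' multivariate log-normal and places each cell at its pre-stimulus steady
#' state. Deterministic given the seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with `params` (cells x parameter types, natural scale),
#'   `init` (cells x `EpoR_i`, `EpoR_m`), `condition` (per-cell condition)
#'   and `cell_id`.
#' @export
sample_cells <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "epor_genconfig"))
  set.seed(seed)
  n <- config$n_epo_cells + config$n_bleach_cells + config$n_chx_cells
  tab <- config$param_table[match(.SAMPLED_TYPES, config$param_table$name), ]
  sd_ln <- tab$log10_sd * log(10)
  mu_ln <- tab$log10_mean * log(10)
  R <- generator_correlation(config)
  Sigma <- diag(sd_ln) %*% R %*% diag(sd_ln)
  Z <- MASS::mvrnorm(n, mu = mu_ln, Sigma = Sigma)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  params <- exp(Z)
  colnames(params) <- .SAMPLED_TYPES
  condition <- rep(c("epo", "bleach", "chx"),
                   c(config$n_epo_cells, config$n_bleach_cells,
                     config$n_chx_cells))
  cell_id <- sprintf("%s_%02d", condition,
                     stats::ave(seq_len(n), condition, FUN = seq_along))
  init <- t(apply(params, 1, prestimulus_steady_state))
  colnames(init) <- c("EpoR_i", "EpoR_m")
  list(params = params, init = init, condition = condition,
       cell_id = cell_id)
}

#' Generate a synthetic single-cell trajectory dataset
#'
#' Simulates every sampled cell under its condition protocol (Epo added
#' after the first frame; bleach pulse at t = 5 min; CHX at t = 0), applies
#' the observation model with unit scales and multiplies by log-normal noise
#' `exp(N(0, sigma_rel^2))`. The ground truth (parameters, initial states,
#' configuration) travels with the result.
#'
#' @inheritParams sample_cells
#' @return An object of class `epor_dataset`: list with `trajectories`
#'   (long-format data frame with columns `cell_id`, `condition`,
#'   `observable`, `time_min`, `value_au`) and `truth` (list of `params`,
#'   `init`, `condition`, `cell_id`, `config`, `seed`).
#' @export
generate_dataset <- function(config = generator_config(),
                             seed = config$seed) {
  cells <- sample_cells(config, seed)
  n <- length(cells$cell_id)
  grids <- list(
    epo = epo_protocol(config$epo_conc, 0, config$sample_times),
    bleach = bleach_protocol(sample_times = config$sample_times),
    chx = chx_protocol(0, config$sample_times))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cond <- cells$condition[i]
    pr <- grids[[cond]]
    pars <- cell_truth_params(cells$params[i, ], cond, config)
    init <- c(EpoR_i = unname(cells$init[i, "EpoR_i"]),
              EpoR_m = unname(cells$init[i, "EpoR_m"]),
              EpoRstar_m = 0, EpoRstar_RE = 0, Epo_deg_i = 0,
              Epo_deg_ext = 0)
    traj <- simulate_cell(config$true_variant, pars, pr, init = init)
    obs <- observe(traj, cond)
    nt <- length(pr$sample_times)
    rows[[i]] <- data.frame(
      cell_id = cells$cell_id[i], condition = cond,
      observable = rep(colnames(obs), each = nt),
      time_min = rep(pr$sample_times, ncol(obs)),
      value_au = as.numeric(obs), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (config$sigma_rel > 0)
    tab$value_au <- tab$value_au *
      exp(rnorm(nrow(tab), 0, config$sigma_rel))
  structure(list(trajectories = tab,
                 truth = c(cells, list(config = config, seed = seed))),
            class = "epor_dataset")
}

# Subset a sampled full parameter vector to the condition model, adding the
# global binding rates for Epo cells.
cell_truth_params <- function(row, condition, config) {
  if (condition == "epo") {
    nm <- kinetic_param_names(config$true_variant, "epo")
    out <- c(k_on_Epo = config$k_on_Epo, k_off_Epo = config$k_off_Epo,
             row[setdiff(nm, c("k_on_Epo", "k_off_Epo"))])
  } else {
    nm <- kinetic_param_names(condition = condition)
    out <- row[nm]
  }
  out
}

#' @export
print.epor_dataset <- function(x, ...) {
  tab <- x$trajectories
  cat("Synthetic single-cell dataset:", length(unique(tab$cell_id)),
      "cells,", nrow(tab), "data points\n")
  print(table(unique(tab[c("cell_id", "condition")])$condition))
  invisible(x)
}

#' Convert molecule counts to concentration
#'
#' `n / (N_A * volume)` expressed in nM for a volume in picolitres
#' (1 nM in 1 pl is ~602 molecules).
#'
#' @param n_molecules Molecule count (>= 0).
#' @param volume_pl Cell volume in picolitres (> 0).
#' @return Concentration in nM.
#' @examples
#' molecules_to_concentration(142000, 5.47) # ~43.1 nM
#' @export
molecules_to_concentration <- function(n_molecules, volume_pl) {
  if (any(volume_pl <= 0)) stop("volume must be > 0")
  n_molecules / (volume_pl * .MOLECULES_PER_NM_PL)
}

#' Fraction of medium ligand internalized by the cell population
#'
#' Bounds the depletion of labelled Epo from the medium: with a per-cell
#' internalization flux (nM/min referred to the cell volume), the fraction
#' of the well's ligand taken up is
#' `flux * cell_volume * duration * n_cells / (epo_conc * well_volume)`
#' (Avogadro's number cancels). Used to justify the constant-Epo model
#' assumption.
#'
#' @param flux_nM_min Internalization flux per cell (nM/min).
#' @param cell_volume_pl Cell volume (pl).
#' @param duration_min Experiment duration (min).
#' @param n_cells Number of cells in the well.
#' @param well_volume_ul Medium volume (microlitres).
#' @param epo_conc_nM Ligand concentration in the medium (nM).
#' @return Percentage of the well's ligand internalized.
#' @examples
#' fraction_ligand_internalized(0.8, 5.47, 300, 4e4, 400, 4.2) # ~3%
#' @export
fraction_ligand_internalized <- function(flux_nM_min, cell_volume_pl,
                                         duration_min, n_cells,
                                         well_volume_ul, epo_conc_nM) {
  stopifnot(cell_volume_pl > 0, duration_min >= 0, n_cells >= 0,
            well_volume_ul > 0, epo_conc_nM > 0)
  well_pl <- well_volume_ul * 1e6
  100 * (flux_nM_min * cell_volume_pl * duration_min * n_cells) /
    (epo_conc_nM * well_pl)
}
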