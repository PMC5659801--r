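# Post-fit biology: reaction fluxes, concentration control coefficients,
# parameter variability statistics, correlation analyses, and the
# covariance-removal experiment probing how correlated transport kinetics
# buffer cell-to-cell variability.

.STAR_TRANSPORT <- c("k_EpoRstar_MtoRE", "k_EpoRstar_REtoM",
                     "k_EpoRstar_deg_REtoEx", "k_EpoRstar_deg_REtoI")

#' Reaction fluxes along a trajectory
#'
#' Every reaction is first order, so its flux is the rate constant times the
#' source species concentration (nM/min), evaluated at each sample time.
#' Fluxes of reactions absent from the variant are identically zero.
#'
#' @param variant Model variant.
#' @param params Named kinetic parameters (Epo-condition model).
#' @param traj Trajectory from [simulate_cell()].
#' @return Matrix (times x fluxes) with columns `F_deg`, `F_ItoM`, `F_MtoI`,
#'   `F_Epo_on`, `F_Epo_off`, `F_EpoRstar_MtoRE`, `F_EpoRstar_REtoM`,
#'   `F_EpoRstar_REtoI`, `F_EpoRstar_deg_REtoEx`, `F_EpoRstar_deg_REtoI`;
#'   attribute `times`.
#' @export
fluxes <- function(variant, params, traj) {
  p <- as_param_vector(params, variant, "epo")
  pr <- attr(traj, "protocol")
  times <- attr(traj, "times")
  epo <- if (!is.null(pr) && pr$condition == "epo")
    ifelse(times > pr$add_time, pr$epo_conc, 0) else 0
  out <- cbind(
    F_deg = p["k_EpoR_deg"] * traj[, "EpoR_i"],
    F_ItoM = p["k_EpoR_ItoM"] * traj[, "EpoR_i"],
    F_MtoI = p["k_EpoR_MtoI"] * traj[, "EpoR_m"],
    F_Epo_on = p["k_on_Epo"] * epo * traj[, "EpoR_m"],
    F_Epo_off = p["k_off_Epo"] * traj[, "EpoRstar_m"],
    F_EpoRstar_MtoRE = p["k_EpoRstar_MtoRE"] * traj[, "EpoRstar_m"],
    F_EpoRstar_REtoM = p["k_EpoRstar_REtoM"] * traj[, "EpoRstar_RE"],
    F_EpoRstar_REtoI = p["k_EpoRstar_REtoI"] * traj[, "EpoRstar_RE"],
    F_EpoRstar_deg_REtoEx = p["k_EpoRstar_deg_REtoEx"] * traj[, "EpoRstar_RE"],
    F_EpoRstar_deg_REtoI = p["k_EpoRstar_deg_REtoI"] * traj[, "EpoRstar_RE"])
  structure(out, times = times)
}

#' Concentration control coefficients
#'
#' Normalized sensitivities `r_k = (k / X(t)) dX(t)/dk` of a target species
#' concentration at time `t` with respect to every kinetic parameter of the
#' cell (global binding rates and synthesis included), computed by central
#' finite differences with a relative step. The initial state — by default
#' the cell's pre-stimulus steady state at the unperturbed parameters — is
#' held fixed across perturbations, mirroring an experiment whose starting
#' concentrations are measured constants; the synthesis coefficient is
#' therefore strictly below one at finite times. In the long-time limit the
#' memory of the initial state decays and the coefficients sum to zero:
#' scaling all first-order rates and the synthesis rate jointly rescales
#' time but not the stationary concentrations.
#'
#' @param variant Model variant.
#' @param params Named kinetic parameters (Epo-condition model).
#' @param target `"EpoRstar_m"` or `"EpoRstar_RE"`.
#' @param t Evaluation time (min, > 0).
#' @param protocol Stimulus protocol (default: Epo at 4.2 nM from t = 0).
#' @param rel_step Relative finite-difference step (default 1%).
#' @param init Optional fixed initial state; defaults to the pre-stimulus
#'   steady state at the unperturbed parameters.
#' @return Named vector of unitless control coefficients.
#' @export
control_coefficients <- function(variant, params,
                                 target = c("EpoRstar_m", "EpoRstar_RE"),
                                 t = 300, protocol = NULL, rel_step = 0.01,
                                 init = NULL) {
  target <- match.arg(target)
  stopifnot(t > 0, rel_step > 0)
  if (is.null(protocol))
    protocol <- epo_protocol(sample_times = c(0, t))
  if (!t %in% protocol$sample_times)
    protocol <- epo_protocol(protocol$epo_conc, protocol$add_time,
                             sort(unique(c(protocol$sample_times, t))))
  if (is.null(init)) {
    p0 <- as_param_vector(params, variant, "epo")
    init <- default_init(p0)
  }
  value_at <- function(pp) {
    traj <- simulate_cell(variant, pp, protocol, init = init)
    traj[match(t, attr(traj, "times")), target]
  }
  x0 <- value_at(params)
  if (x0 == 0) stop("target concentration is zero at t = ", t)
  nm <- kinetic_param_names(variant, "epo")
  r <- setNames(numeric(length(nm)), nm)
  for (k in nm) {
    up <- params; up[k] <- params[k] * (1 + rel_step)
    dn <- params; dn[k] <- params[k] * (1 - rel_step)
    r[k] <- (value_at(up) - value_at(dn)) / (2 * rel_step * x0)
  }
  r
}

#' Pearson correlation matrix with t-test p-values
#'
#' Correlations between per-cell quantities (columns), on log10 scale for
#' kinetic parameters (their distributions are log-normal) or linear scale
#' for concentrations/amounts. Significance from the t statistic
#' `rho * sqrt(n - 2) / sqrt(1 - rho^2)` (two-sided).
#'
#' @param x Matrix or data frame, cells in rows, quantities in columns.
#' @param log Correlate log10-transformed values?
#' @return List with `r` (correlation matrix), `p` (two-sided p-values),
#'   `n` (number of cells).
#' @export
correlation_analysis <- function(x, log = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 cells")
  if (log) {
    if (any(x <= 0)) stop("log-scale correlation requires positive values")
    x <- log10(x)
  }
  if (any(apply(x, 2, sd) == 0))
    stop("zero-variance input column(s): ",
         paste(colnames(x)[apply(x, 2, sd) == 0], collapse = ", "))
  k <- ncol(x)
  r <- diag(k)
  p <- matrix(0, k, k)
  dimnames(r) <- dimnames(p) <- list(colnames(x), colnames(x))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ct <- cor.test(x[, i], x[, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = nrow(x))
}

#' Cell-to-cell parameter variability statistics
#'
#' Per-parameter-type mean, SD and CV across cells, the log10-scale Pearson
#' correlation matrix with p-values, and the fitted multivariate log-normal
#' (log10 mean vector and covariance matrix) that generates the ensemble's
#' parameter distribution. A covariance that is not positive semidefinite
#' (possible after estimation on few cells) is repaired to the nearest PSD
#' matrix and flagged.
#'
#' @param params Matrix of per-cell kinetic parameters (cells x types,
#'   natural scale, all positive).
#' @return Class `epor_param_stats` with fields `summary`, `cor`, `cor_p`,
#'   `n_cells`, `log10_mean`, `log10_cov`, `psd_repaired`.
#' @export
parameter_stats <- function(params) {
  params <- as.matrix(params)
  if (any(params <= 0)) stop("kinetic parameters must be positive")
  if (nrow(params) < 3) stop("need at least 3 cells")
  L <- log10(params)
  ca <- correlation_analysis(params, log = TRUE)
  cv <- apply(params, 2, sd) / colMeans(params)
  smry <- data.frame(parameter = colnames(params),
                     mean = colMeans(params),
                     sd = apply(params, 2, sd), cv = cv)
  rownames(smry) <- NULL
  cov_l <- stats::cov(L)
  repaired <- FALSE
  ev <- eigen(cov_l, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    cov_l <- as.matrix(Matrix::nearPD(cov_l)$mat)
    repaired <- TRUE
  }
  structure(list(summary = smry, cor = ca$r, cor_p = ca$p,
                 n_cells = nrow(params),
                 log10_mean = colMeans(L), log10_cov = cov_l,
                 psd_repaired = repaired),
            class = "epor_param_stats")
}

#' @export
print.epor_param_stats <- function(x, ...) {
  cat("Single-cell parameter distribution (", x$n_cells, " cells)\n",
      sep = "")
  print(transform(x$summary, mean = signif(mean, 4), sd = signif(sd, 4),
                  cv = signif(cv, 3)), row.names = FALSE)
  if (x$psd_repaired) cat("note: log-covariance repaired to nearest PSD\n")
  invisible(x)
}

#' Multivariate log-normal of the generator defaults
#'
#' The exact log10 mean vector and covariance matrix of the synthetic-data
#' generator's parameter distribution, as an [parameter_stats()]-compatible
#' object (for use with [covariance_experiment()]).
#'
#' @param config A [generator_config()].
#' @return Class `epor_param_stats` (distribution fields only).
#' @export
generator_stats <- function(config = generator_config()) {
  tab <- config$param_table[match(.SAMPLED_TYPES, config$param_table$name), ]
  R <- generator_correlation(config)
  S <- diag(tab$log10_sd) %*% R %*% diag(tab$log10_sd)
  dimnames(S) <- list(.SAMPLED_TYPES, .SAMPLED_TYPES)
  structure(list(summary = NULL, cor = R, cor_p = NULL, n_cells = NA,
                 log10_mean = setNames(tab$log10_mean, .SAMPLED_TYPES),
                 log10_cov = S, psd_repaired = FALSE),
            class = "epor_param_stats")
}

#' Covariance-removal variability experiment
#'
#' Samples parameter vectors from a multivariate log-normal, simulates each
#' virtual cell from its pre-stimulus steady state through 5 h of Epo
#' stimulation and reports the coefficient of variation of the membrane and
#' endosomal Epo-receptor complex concentrations. With `reduced = TRUE` all
#' covariances involving the four EpoR* transport parameters
#' (`k_EpoRstar_MtoRE`, `k_EpoRstar_REtoM`, `k_EpoRstar_deg_REtoEx`,
#' `k_EpoRstar_deg_REtoI`) are set to zero before sampling, removing the
#' correlations through which opposing transport processes buffer
#' variability.
#'
#' @param stats An `epor_param_stats` (from [parameter_stats()] or
#'   [generator_stats()]).
#' @param n_samples Number of sampled parameter vectors (default 1000).
#' @param seed Integer seed (sampling is deterministic given the seed).
#' @param reduced Zero the EpoR*-transport covariances before sampling?
#' @param variant Model variant simulated (default `"ACD"`).
#' @param k_on_Epo,k_off_Epo Global binding rates (not part of the sampled
#'   distribution).
#' @param epo_conc Epo concentration (nM).
#' @param t Evaluation time (min; 5 h = 300 min).
#' @param boot Bootstrap resamples for the Monte-Carlo standard error of
#'   the CVs.
#' @return Class `epor_covexp`: list with `cv` (named: `EpoRstar_m`,
#'   `EpoRstar_RE`), `cv_se`, `values` (samples x 2), `reduced`,
#'   `psd_repaired`, `n_samples`, `seed`.
#' @export
covariance_experiment <- function(stats, n_samples = 1000, seed = 1,
                                  reduced = FALSE, variant = "ACD",
                                  k_on_Epo = 0.5, k_off_Epo = 0.1,
                                  epo_conc = 4.2, t = 300, boot = 200) {
  stopifnot(inherits(stats, "epor_param_stats"), n_samples >= 2)
  variant <- epor_variant(variant)
  need <- setdiff(kinetic_param_names(variant, "epo"),
                  c("k_on_Epo", "k_off_Epo"))
  miss <- setdiff(need, names(stats$log10_mean))
  if (length(miss) > 0) stop("distribution lacks parameter(s): ",
                             paste(miss, collapse = ", "))
  mu <- stats$log10_mean[need]
  S <- stats$log10_cov[need, need, drop = FALSE]
  repaired <- FALSE
  if (reduced) {
    z <- intersect(.STAR_TRANSPORT, need)
    for (a in z) {
      S[a, setdiff(need, a)] <- 0
      S[setdiff(need, a), a] <- 0
    }
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    S <- as.matrix(Matrix::nearPD(S)$mat)
    repaired <- TRUE
    warning("covariance repaired to nearest PSD after reduction")
  }
  set.seed(seed)
  Z <- MASS::mvrnorm(n_samples, mu, S)
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = length(mu),
                                   dimnames = list(NULL, names(mu)))
  colnames(Z) <- need
  pr <- epo_protocol(epo_conc, 0, c(0, t))
  vals <- matrix(NA_real_, n_samples, 2,
                 dimnames = list(NULL, c("EpoRstar_m", "EpoRstar_RE")))
  for (i in seq_len(n_samples)) {
    pars <- c(k_on_Epo = k_on_Epo, k_off_Epo = k_off_Epo, 10^Z[i, ])
    traj <- simulate_cell(variant, pars, pr)
    vals[i, ] <- traj[nrow(traj), c("EpoRstar_m", "EpoRstar_RE")]
  }
  cv <- apply(vals, 2, function(v) sd(v) / mean(v))
  cv_se <- apply(vals, 2, function(v) {
    sd(vapply(seq_len(boot), function(b) {
      s <- v[sample.int(length(v), replace = TRUE)]
      sd(s) / mean(s)
    }, 0))
  })
  structure(list(cv = cv, cv_se = cv_se, values = vals, reduced = reduced,
                 psd_repaired = repaired, n_samples = n_samples,
                 seed = seed),
            class = "epor_covexp")
}

#' @export
print.epor_covexp <- function(x, ...) {
  cat("Covariance-", if (x$reduced) "removal" else "retaining",
      " sampling experiment (", x$n_samples, " virtual cells)\n", sep = "")
  cat(sprintf("  CV [EpoR*_m](5h)  = %.3f (MC SE %.3f)\n",
              x$cv["EpoRstar_m"], x$cv_se["EpoRstar_m"]))
  cat(sprintf("  CV [EpoR*_RE](5h) = %.3f (MC SE %.3f)\n",
              x$cv["EpoRstar_RE"], x$cv_se["EpoRstar_RE"]))
  invisible(x)
}

#' Data-level correlations of single-cell observables
#'
#' Model-free correlations computed directly from a trajectory table of
#' Epo-stimulated cells: per-cell fold changes (value divided by the
#' population mean) of membrane vs vesicular GFP concentration at the first
#' frame, of total GFP concentration vs membrane Cy5.5 concentration at the
#' end of the experiment, and of the corresponding absolute amounts
#' (concentration times cell volume). Fold changes are scale-free, so
#' rescaling the table leaves all statistics unchanged.
#'
#' @param tab Long-format trajectory table with Epo-condition cells.
#' @param volumes Optional named per-cell volumes (pl) for the amount-level
#'   comparison; equal volumes assumed when omitted.
#' @param t_end End time (min; default: last common time point).
#' @return List of three tests (`mem_vs_ves_conc`, `tot_vs_epo_mem_conc`,
#'   `tot_vs_epo_mem_amount`), each with `rho`, `p`, `n`, `degenerate`
#'   flag, and the per-cell fold changes.
#' @export
data_level_correlations <- function(tab, volumes = NULL, t_end = NULL) {
  tab <- tab[tab$condition == "epo", ]
  if (nrow(tab) == 0) stop("no Epo-condition cells in table")
  t0 <- min(tab$time_min)
  if (is.null(t_end)) t_end <- max(tab$time_min)
  ids <- unique(tab$cell_id)
  pull <- function(obs, tt) {
    v <- vapply(ids, function(id) {
      w <- tab$value_au[tab$cell_id == id & tab$observable == obs &
                          tab$time_min == tt]
      if (length(w) != 1) NA_real_ else w
    }, 0)
    if (any(is.na(v))) stop("missing time point t=", tt, " for ", obs)
    v
  }
  mem0 <- pull("EpoR_GFP_mem", t0)
  ves0 <- pull("EpoR_GFP_ves", t0)
  tot0 <- mem0 + ves0 + pull("EpoR_GFP_Cy55ves", t0)
  epo_end <- pull("Epo_Cy55_mem", t_end)
  if (is.null(volumes)) volumes <- setNames(rep(1, length(ids)), ids)
  vol <- volumes[ids]
  one <- function(x, y) {
    fx <- x / mean(x)
    fy <- y / mean(y)
    if (sd(fx) == 0 || sd(fy) == 0)
      return(list(rho = NA_real_, p = NA_real_, n = length(x),
                  degenerate = TRUE, fold_x = fx, fold_y = fy))
    ct <- cor.test(fx, fy, method = "pearson")
    list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
         degenerate = FALSE, fold_x = fx, fold_y = fy)
  }
  list(mem_vs_ves_conc = one(mem0, ves0),
       tot_vs_epo_mem_conc = one(tot0, epo_end),
       tot_vs_epo_mem_amount = one(tot0 * vol, epo_end * vol))
}
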