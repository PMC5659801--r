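# Cell-ensemble fitting: one trafficking model per cell sharing structure,
# global Epo binding/unbinding rates, shared per-observable scaling factors,
# per-cell kinetic rates and initial concentrations, and distribution
# constraints tying the log-parameter means/variances of the condition
# groups together. All parameters are optimized in log10 space with box
# bounds; local refinement is bounded Levenberg-Marquardt (minpack.lm) on
# the residual vector, multi-started from Latin-hypercube points.

.default_control <- function(n_starts) {
  list(
    cellwise_passes = 1L,    # block passes of per-cell refinement per start
    cellwise_maxit = 15L,    # LM iterations per cell block
    shared_maxit = 10L,      # LM iterations of the globals+scales block
    joint_maxit = 50L,       # LM iterations of the joint refinement
    refine_top = max(3L, ceiling(0.15 * n_starts)), # starts refined jointly
    polish_cycles = 3L,      # block/joint alternations on the incumbent
    screen = NULL,           # run block refinement only on this many starts
    extra_starts = NULL,     # named log10 vectors injected as warm starts
    extra_fill = "midpoint", # unmatched warm-start entries: midpoint/lower
    rate_bounds = c(1e-6, 1e3),      # natural scale
    init_bounds = c(1e-3, 1e3),
    scale_bounds = c(1e-3, 1e3),
    rate_start_range = c(1e-4, 1e1), # LHS start box (natural scale)
    init_start_range = c(1e-1, 3e2),
    scale_start_range = c(1e-1, 1e1),
    ftol = 1e-8, ptol = 1e-8)
}

# ---- context construction ---------------------------------------------------

# Assemble everything the objective needs: per-cell data blocks, the theta
# index map, bounds, and the constraint index lists.
build_ensemble <- function(data, variant, conditions, constraint_weight,
                           fit_scales, error_model, protocols, control,
                           scale_scheme = "fluorophore") {
  data <- validate_trajectories(data[, .TRAJ_COLS])
  data <- data[data$condition %in% conditions, , drop = FALSE]
  if (nrow(data) == 0) stop("no data for conditions: ",
                            paste(conditions, collapse = ", "))
  variant <- epor_variant(variant)
  if (is.null(error_model)) error_model <- default_error_model(data)
  if (is.null(protocols))
    protocols <- list(epo = epo_protocol(), bleach = bleach_protocol(),
                      chx = chx_protocol())

  ids <- unique(data$cell_id)
  cells <- vector("list", length(ids))
  theta_names <- character(0)
  kind <- character(0)        # "rate", "init" or "scale" per theta entry

  has_epo <- "epo" %in% data$condition
  idx_global <- integer(0)
  if (has_epo) {
    theta_names <- c("k_on_Epo", "k_off_Epo")
    kind <- c("rate", "rate")
    idx_global <- 1:2
  }

  for (j in seq_along(ids)) {
    sub <- data[data$cell_id == ids[j], ]
    cond <- sub$condition[1]
    if (length(unique(sub$condition)) > 1)
      stop("cell ", ids[j], " appears under multiple conditions")
    times <- sort(unique(sub$time_min))
    obs <- observables(cond)
    Y <- matrix(NA_real_, length(times), length(obs),
                dimnames = list(NULL, obs))
    ii <- cbind(match(sub$time_min, times), match(sub$observable, obs))
    Y[ii] <- sub$value_au
    pr <- protocols[[cond]]

    kin_names <- setdiff(kinetic_param_names(variant, cond),
                         c("k_on_Epo", "k_off_Epo"))
    own_names <- paste0(ids[j], ".", c(kin_names, "EpoR_i0", "EpoR_m0"))
    own_idx <- length(theta_names) + seq_along(own_names)
    theta_names <- c(theta_names, own_names)
    kind <- c(kind, rep("rate", length(kin_names)), "init", "init")

    cells[[j]] <- list(
      id = ids[j], condition = cond, cond_code = .cond_code(cond),
      times = times, Y = Y, mask = which(!is.na(Y)),
      obs = obs,
      epo_conc = pr$epo_conc %||% 0, add_time = pr$add_time %||% 0,
      bleach_start = pr$bleach_start %||% -1,
      bleach_end = pr$bleach_end %||% -1,
      chx_time = pr$chx_time %||% -1,
      kin_names = kin_names,
      mask0 = which(!is.na(Y)) - 1L,
      kin_slots = match(kin_names, .PARAM_NAMES),
      kin_theta = own_idx[seq_along(kin_names)],
      init_theta = own_idx[length(kin_names) + 1:2],
      own_theta = own_idx,
      sigma_abs = error_model$sigma_abs[obs],
      floor = error_model$floor[obs])
    # data-informed starting guesses for the initial concentrations: the
    # first-frame vesicular/membrane GFP signals at unit scale
    first_val <- function(col) {
      v <- Y[, col]
      v <- v[!is.na(v)]
      if (length(v) == 0) 10 else max(v[1], 1e-2)
    }
    cells[[j]]$init_guess <- log10(c(first_val("EpoR_GFP_ves"),
                                     first_val("EpoR_GFP_mem")))
  }

  # shared scaling factors. Default scheme: one factor per fluorophore per
  # condition group (the factor converts fluorescence to concentration for
  # a dye under fixed imaging settings, so all observables of one dye share
  # it); "observable" grants each observable its own factor. The epo-group
  # GFP scale (or the first group's, if no epo cells) is the fixed unit
  # reference.
  scale_id <- function(cd, obs) {
    if (scale_scheme == "observable") return(paste0("scale.", cd, ".", obs))
    paste0("scale.", cd, ".",
           ifelse(startsWith(obs, "Epo_Cy55"), "Cy55", "GFP"))
  }
  conds_present <- intersect(c("epo", "bleach", "chx"),
                             unique(data$condition))
  scale_names_all <- unique(unlist(lapply(conds_present, function(cd)
    scale_id(cd, observables(cd)))))
  reference <- scale_id(conds_present[1], "EpoR_GFP_mem")
  free_scales <- switch(fit_scales,
                        none = character(0),
                        free = setdiff(scale_names_all, reference),
                        all = scale_names_all)
  idx_scale <- length(theta_names) + seq_along(free_scales)
  theta_names <- c(theta_names, free_scales)
  kind <- c(kind, rep("scale", length(free_scales)))
  names(idx_scale) <- free_scales

  # per-cell scale lookup: fixed values and theta positions
  for (j in seq_along(cells)) {
    cd <- cells[[j]]$condition
    snm <- scale_id(cd, cells[[j]]$obs)
    fixed <- setNames(rep(1, length(snm)), cells[[j]]$obs)
    free <- snm %in% free_scales
    cells[[j]]$scale_fixed <- fixed
    cells[[j]]$scale_free <- which(free)
    cells[[j]]$scale_theta <- unname(idx_scale[snm[free]])
  }

  # distribution constraints: shared kinetic types across condition groups
  constraints <- list()
  if (constraint_weight > 0 && length(conds_present) > 1) {
    groups <- lapply(conds_present, function(cd)
      which(vapply(cells, function(cl) cl$condition == cd, TRUE)))
    names(groups) <- conds_present
    type_of <- lapply(cells, function(cl) cl$kin_names)
    combos <- utils::combn(conds_present, 2, simplify = FALSE)
    for (pair in combos) {
      t1 <- unique(unlist(type_of[groups[[pair[1]]]]))
      t2 <- unique(unlist(type_of[groups[[pair[2]]]]))
      for (ty in intersect(t1, t2)) {
        pos <- function(g) unlist(lapply(groups[[g]], function(i) {
          k <- match(ty, cells[[i]]$kin_names)
          if (is.na(k)) NULL else cells[[i]]$kin_theta[k]
        }))
        constraints[[length(constraints) + 1L]] <-
          list(type = ty, groups = pair, idx1 = pos(pair[1]),
               idx2 = pos(pair[2]))
      }
    }
  }

  lower <- ifelse(kind == "rate", log10(control$rate_bounds[1]),
                  ifelse(kind == "init", log10(control$init_bounds[1]),
                         log10(control$scale_bounds[1])))
  upper <- ifelse(kind == "rate", log10(control$rate_bounds[2]),
                  ifelse(kind == "init", log10(control$init_bounds[2]),
                         log10(control$scale_bounds[2])))
  s_lower <- ifelse(kind == "rate", log10(control$rate_start_range[1]),
                    ifelse(kind == "init", log10(control$init_start_range[1]),
                           log10(control$scale_start_range[1])))
  s_upper <- ifelse(kind == "rate", log10(control$rate_start_range[2]),
                    ifelse(kind == "init", log10(control$init_start_range[2]),
                           log10(control$scale_start_range[2])))

  list(cells = cells, idx_global = idx_global, idx_scale = idx_scale,
       theta_names = theta_names, kind = kind,
       lower = lower, upper = upper,
       start_lower = s_lower, start_upper = s_upper,
       constraints = constraints, weight = constraint_weight,
       sigma_rel = error_model$sigma_rel, error_model = error_model,
       variant = variant, conditions = conditions,
       n_data = sum(vapply(cells, function(cl) length(cl$mask), 0L)),
       control = control, data = data, protocols = protocols,
       fit_scales = fit_scales)
}

# ---- residuals --------------------------------------------------------------

.predict_cell <- function(cell, kin12, init2, scales) {
  sol <- solve_traffic_cpp(cell$times, c(init2, 0, 0), numeric(3), kin12,
                           cell$cond_code, cell$epo_conc, cell$add_time,
                           cell$bleach_start, cell$bleach_end, cell$chx_time)
  S <- sol$states
  if (!sol$ok || any(!is.finite(S))) return(NULL)
  if (cell$cond_code == 0L) {
    pred <- cbind(S[, 2] + S[, 3], S[, 1], S[, 4], S[, 3], S[, 4] + S[, 5])
  } else {
    pred <- cbind(S[, 2], S[, 1])
  }
  sweep(pred, 2, scales, `*`)
}

.cell_resid <- function(ctx, i, theta) {
  cell <- ctx$cells[[i]]
  kin <- numeric(12)
  kin[cell$kin_slots] <- 10^theta[cell$kin_theta]
  if (cell$cond_code == 0L) kin[1:2] <- 10^theta[ctx$idx_global]
  sc <- cell$scale_fixed
  if (length(cell$scale_free) > 0)
    sc[cell$scale_free] <- 10^theta[cell$scale_theta]
  cell_resid_cpp(cell$times, 10^theta[cell$init_theta], kin, cell$cond_code,
                 cell$epo_conc, cell$add_time, cell$bleach_start,
                 cell$bleach_end, cell$chx_time, cell$Y, cell$mask0,
                 unname(sc), ctx$sigma_rel, unname(cell$floor),
                 unname(cell$sigma_abs))
}

.constraint_resid <- function(ctx, theta) {
  if (length(ctx$constraints) == 0) return(numeric(0))
  sw <- sqrt(ctx$weight)
  unlist(lapply(ctx$constraints, function(cn) {
    a <- theta[cn$idx1]
    b <- theta[cn$idx2]
    out <- sw * (mean(a) - mean(b))
    if (length(a) >= 2 && length(b) >= 2)
      out <- c(out, sw * (var(a) - var(b)))
    out
  }), use.names = FALSE)
}

.full_resid <- function(ctx, theta) {
  c(unlist(lapply(seq_along(ctx$cells), function(i)
    .cell_resid(ctx, i, theta)), use.names = FALSE),
    .constraint_resid(ctx, theta))
}

.objective <- function(ctx, theta) sum(.full_resid(ctx, theta)^2)

# Forward-difference Jacobian exploiting the block structure: cell-specific
# parameters only touch their own cell's residuals (plus constraint rows).
.full_jac <- function(ctx, theta, h = 1e-6) {
  r0_cells <- lapply(seq_along(ctx$cells), function(i)
    .cell_resid(ctx, i, theta))
  len <- vapply(r0_cells, length, 0L)
  off <- cumsum(c(0L, len))
  r0_con <- .constraint_resid(ctx, theta)
  m <- sum(len) + length(r0_con)
  J <- matrix(0, m, length(theta))
  con_rows <- if (length(r0_con) > 0) sum(len) + seq_along(r0_con) else integer(0)

  shared <- c(ctx$idx_global, unname(ctx$idx_scale))
  for (j in shared) {
    th <- theta
    th[j] <- th[j] + h
    for (i in seq_along(ctx$cells))
      J[off[i] + seq_len(len[i]), j] <- (.cell_resid(ctx, i, th) -
                                           r0_cells[[i]]) / h
  }
  for (i in seq_along(ctx$cells)) {
    rows <- off[i] + seq_len(len[i])
    for (j in ctx$cells[[i]]$own_theta) {
      th <- theta
      th[j] <- th[j] + h
      J[rows, j] <- (.cell_resid(ctx, i, th) - r0_cells[[i]]) / h
    }
  }
  if (length(con_rows) > 0) {
    kin_idx <- unique(unlist(lapply(ctx$constraints,
                                    function(cn) c(cn$idx1, cn$idx2))))
    for (j in kin_idx) {
      th <- theta
      th[j] <- th[j] + h
      J[con_rows, j] <- (.constraint_resid(ctx, th) - r0_con) / h
    }
  }
  J
}

# ---- optimization -----------------------------------------------------------

.lhs_starts <- function(ctx, n_starts) {
  p <- length(ctx$theta_names)
  U <- lhs::randomLHS(n_starts, p)
  starts <- t(apply(U, 1, function(u)
    ctx$start_lower + u * (ctx$start_upper - ctx$start_lower)))
  if (n_starts == 1) starts <- matrix(starts, 1)
  # anchor initial concentrations at the data-derived guesses (log10 jitter
  # +-0.5 from the LHS coordinate) and start synthesis consistent with
  # turnover (k_syn ~ k_deg * EpoR_i0)
  for (cl in ctx$cells) {
    it <- cl$init_theta
    jit <- (starts[, it, drop = FALSE] -
              rep((ctx$start_lower[it] + ctx$start_upper[it]) / 2,
                  each = n_starts)) /
      rep(ctx$start_upper[it] - ctx$start_lower[it], each = n_starts)
    starts[, it] <- rep(cl$init_guess, each = n_starts) + jit
    ks <- match(paste0(cl$id, ".k_EpoR_syn"), ctx$theta_names)
    kd <- match(paste0(cl$id, ".k_EpoR_deg"), ctx$theta_names)
    if (!is.na(ks) && !is.na(kd))
      starts[, ks] <- starts[, kd] + starts[, it[1]]
  }
  starts <- pmin(pmax(starts, rep(ctx$lower, each = n_starts)),
                 rep(ctx$upper, each = n_starts))
  starts
}

.cellwise_pass <- function(ctx, theta) {
  ctrl <- minpack.lm::nls.lm.control(
    maxiter = ctx$control$cellwise_maxit, ftol = 1e-6, ptol = 1e-6)
  for (pass in seq_len(ctx$control$cellwise_passes)) {
    for (i in seq_along(ctx$cells)) {
      own <- ctx$cells[[i]]$own_theta
      fn <- function(x) {
        th <- theta
        th[own] <- x
        .cell_resid(ctx, i, th)
      }
      res <- try(minpack.lm::nls.lm(theta[own], lower = ctx$lower[own],
                                    upper = ctx$upper[own], fn = fn,
                                    control = ctrl), silent = TRUE)
      if (!inherits(res, "try-error")) theta[own] <- res$par
    }
  }
  theta
}

.joint_refine <- function(ctx, theta, maxiter = NULL) {
  ctrl <- minpack.lm::nls.lm.control(
    maxiter = maxiter %||% ctx$control$joint_maxit,
    ftol = ctx$control$ftol, ptol = ctx$control$ptol)
  res <- try(minpack.lm::nls.lm(
    theta, lower = ctx$lower, upper = ctx$upper,
    fn = function(x) .full_resid(ctx, x),
    jac = function(x, ...) .full_jac(ctx, x),
    control = ctrl), silent = TRUE)
  if (inherits(res, "try-error")) theta else res$par
}

.shared_stage <- function(ctx, theta) {
  sh <- c(ctx$idx_global, unname(ctx$idx_scale))
  if (length(sh) == 0) return(theta)
  fn <- function(x) {
    th <- theta
    th[sh] <- x
    .full_resid(ctx, th)
  }
  res <- try(minpack.lm::nls.lm(
    theta[sh], lower = ctx$lower[sh], upper = ctx$upper[sh], fn = fn,
    control = minpack.lm::nls.lm.control(
      maxiter = ctx$control$shared_maxit, ftol = 1e-7, ptol = 1e-7)),
    silent = TRUE)
  if (!inherits(res, "try-error")) theta[sh] <- res$par
  theta
}

# Multi-start schedule: Latin-hypercube starts (plus any injected warm
# starts), optional screening by raw objective, per-cell block refinement,
# then for the best starts an alternation of shared-parameter, per-cell and
# full joint Levenberg-Marquardt refinement.
.multistart_fit <- function(ctx, n_starts, seed) {
  set.seed(seed)
  starts <- .lhs_starts(ctx, n_starts)
  if (!is.null(ctx$control$extra_starts)) {
    ex <- ctx$control$extra_starts
    if (is.matrix(ex))
      ex <- lapply(seq_len(nrow(ex)), function(r) ex[r, ])
    if (!is.list(ex)) ex <- list(ex)
    fills <- rep(ctx$control$extra_fill %||% "midpoint", length.out = length(ex))
    embed <- function(v, fill) {
      base <- (ctx$start_lower + ctx$start_upper) / 2
      # nested-model embeddings for entries the source fit does not carry:
      # "lower" switches the reaction off exactly (preserves the source's
      # chi-square, but is stationary in log space), "active" puts the rate
      # at a small active value so refinement keeps a live gradient
      if (fill == "lower") base[ctx$kind == "rate"] <- ctx$lower[ctx$kind == "rate"]
      if (fill == "active") base[ctx$kind == "rate"] <- -2
      names(base) <- ctx$theta_names
      common <- intersect(names(v), ctx$theta_names)
      j <- match(common, ctx$theta_names)
      base[j] <- pmin(pmax(v[common], ctx$lower[j]), ctx$upper[j])
      base
    }
    rows <- t(mapply(embed, ex, fills))
    starts <- rbind(rows, starts)[seq_len(max(n_starts, nrow(rows))), ,
                                  drop = FALSE]
  }
  n_total <- nrow(starts)
  obj <- vapply(seq_len(n_total), function(s) .objective(ctx, starts[s, ]), 0)
  thetas <- lapply(seq_len(n_total), function(s) starts[s, ])
  keep <- seq_len(n_total)
  if (!is.null(ctx$control$screen) && ctx$control$screen < n_total)
    keep <- order(obj)[seq_len(ctx$control$screen)]
  for (s in keep) {
    th <- .cellwise_pass(ctx, starts[s, ])
    o <- .objective(ctx, th)
    if (is.finite(o) && o < obj[s]) {
      thetas[[s]] <- th
      obj[s] <- o
    }
  }
  top <- intersect(order(obj), keep)
  top <- top[seq_len(min(ctx$control$refine_top, length(top)))]
  for (s in top) {
    th <- .shared_stage(ctx, thetas[[s]])
    th <- .cellwise_pass(ctx, th)
    th <- .joint_refine(ctx, th)
    o <- .objective(ctx, th)
    if (is.finite(o) && o < obj[s]) {
      thetas[[s]] <- th
      obj[s] <- o
    }
  }
  # final polish of the incumbent: alternate block and joint refinement
  best <- order(obj)[1]
  th <- thetas[[best]]
  o_prev <- obj[best]
  for (cyc in seq_len(ctx$control$polish_cycles)) {
    th2 <- .cellwise_pass(ctx, th)
    th2 <- .shared_stage(ctx, th2)
    th2 <- .joint_refine(ctx, th2)
    o <- .objective(ctx, th2)
    if (is.finite(o) && o < o_prev) {
      th <- th2
      if (o > o_prev - max(1e-4 * o_prev, 1e-8)) { o_prev <- o; break }
      o_prev <- o
    } else break
  }
  thetas[[best]] <- th
  obj[best] <- o_prev
  ord <- order(obj)
  list(theta = thetas[[ord[1]]], objective = obj[ord[1]],
       starts = data.frame(start = ord, objective = obj[ord],
                           refined = ord %in% top),
       thetas = thetas[ord])
}

# ---- user-facing fitting ----------------------------------------------------

#' Fit a cell-ensemble trafficking model
#'
#' Jointly estimates, for one model variant, the global Epo binding and
#' unbinding rates, per-cell kinetic rates and initial receptor
#' concentrations, and shared per-observable scaling factors, by weighted
#' least squares over all cells and conditions. Quadratic penalties on the
#' differences of log10-parameter means and variances between condition
#' groups (Epo / bleach / CHX) keep the single-cell parameter distributions
#' consistent across experiments. Optimization is multi-start: Latin
#' hypercube points in log10 space, per-cell block refinement for every
#' start, full joint Levenberg-Marquardt refinement for the best starts.
#'
#' @param data Long-format trajectory table (see [read_trajectories()]) or
#'   an `epor_dataset` from [generate_dataset()].
#' @param variant Model variant for the Epo-condition cells.
#' @param conditions Condition groups to fit (`data` is filtered to these).
#' @param n_starts Number of Latin-hypercube starts.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param constraint_weight Weight of the distribution-constraint penalty
#'   (0 disables it). The default 100 is likelihood-scaled: of the order of
#'   the inverse sampling variance of a condition group's log10-parameter
#'   mean for typical group sizes and spreads (`n/(2 sigma^2)` is 100-300
#'   for 4-16 cells with log10 spreads of 0.1-0.2), so matching the group
#'   distributions carries real statistical weight against the data term.
#' @param fit_scales `"free"` (estimate all scaling factors except the
#'   epo-group membrane-GFP reference, which is fixed at 1), `"none"` (all
#'   fixed at 1) or `"all"`.
#' @param error_model Optional list with `sigma_rel`, `sigma_abs`, `floor`
#'   (per observable); defaults to `sigma_rel = 0.1` and absolute floor at
#'   1% of each observable's data maximum.
#' @param protocols Optional named list of protocols per condition; sample
#'   times are taken from the data.
#' @param control List overriding optimizer settings (iteration caps, box
#'   bounds, start ranges, number of jointly refined starts).
#' @return An object of class `epor_fit`; see [summary.epor_fit()],
#'   [coef.epor_fit()], [profile.epor_fit()], [simulate.epor_fit()].
#' @export
epor_fit <- function(data, variant = "ACD",
                     conditions = c("epo", "bleach", "chx"),
                     n_starts = 100, seed = 1,
                     constraint_weight = 100,
                     fit_scales = c("free", "none", "all"),
                     scale_scheme = c("fluorophore", "observable"),
                     error_model = NULL, protocols = NULL,
                     control = list()) {
  cl <- match.call()
  if (inherits(data, "epor_dataset")) data <- data$trajectories
  fit_scales <- match.arg(fit_scales)
  scale_scheme <- match.arg(scale_scheme)
  stopifnot(n_starts >= 1)
  ctrl <- modifyList(.default_control(n_starts), control)
  ctx <- build_ensemble(data, variant, conditions, constraint_weight,
                        fit_scales, error_model, protocols, ctrl,
                        scale_scheme)
  ms <- .multistart_fit(ctx, n_starts, seed)
  .as_epor_fit(ctx, ms, cl, n_starts, seed)
}

.as_epor_fit <- function(ctx, ms, call, n_starts, seed, extra = list()) {
  theta <- setNames(ms$theta, ctx$theta_names)
  data_res <- unlist(lapply(seq_along(ctx$cells), function(i)
    .cell_resid(ctx, i, theta)), use.names = FALSE)
  chi2 <- sum(data_res^2)
  penalty <- sum(.constraint_resid(ctx, theta)^2)
  n_par <- length(theta)
  out <- structure(c(list(
    call = call, variant = ctx$variant$name, conditions = ctx$conditions,
    theta = theta, objective = ms$objective, chi2 = chi2, penalty = penalty,
    n_data = ctx$n_data, n_params = n_par,
    aicc = aicc(ms$objective, n_par, ctx$n_data),
    starts = ms$starts, start_thetas = ms$thetas,
    n_starts = n_starts, seed = seed,
    cell_ids = vapply(ctx$cells, `[[`, "", "id"),
    cell_conditions = vapply(ctx$cells, `[[`, "", "condition"),
    ctx = ctx), extra),
    class = "epor_fit")
  out
}

#' Corrected Akaike information criterion
#'
#' `AICc = chi2 + 2 k + 2 k (k + 1) / (n - k - 1)`, with the weighted
#' residual sum of squares playing the role of -2 log-likelihood up to a
#' data-dependent constant, `k` estimated parameters and `n` fitted data
#' points.
#'
#' @param chi2 Objective value (weighted residual sum of squares, including
#'   any constraint penalty).
#' @param n_params Number of estimated parameters.
#' @param n_data Number of fitted data points (must exceed `n_params + 1`).
#' @return The AICc value.
#' @examples
#' aicc(50, 10, 100) # 72.47191
#' @export
aicc <- function(chi2, n_params, n_data) {
  if (n_data <= n_params + 1)
    stop("AICc undefined: n_data must exceed n_params + 1")
  chi2 + 2 * n_params + 2 * n_params * (n_params + 1) / (n_data - n_params - 1)
}

#' Retain the best fraction of multi-start fits
#'
#' @param fit An `epor_fit` (or its `starts` data frame).
#' @param frac Fraction of starts to keep (default 0.5%), ordered by
#'   objective; at least one is kept.
#' @return The retained rows of the starts table.
#' @export
keep_best <- function(fit, frac = 0.005) {
  starts <- if (inherits(fit, "epor_fit")) fit$starts else fit
  n <- max(1L, round(frac * nrow(starts)))
  utils::head(starts[order(starts$objective), ], n)
}

# ---- model discrimination ---------------------------------------------------

#' Model discrimination by corrected AIC
#'
#' Fits every candidate variant to the dataset and reports AICc differences
#' to the best variant. In `"ensemble"` mode one joint cell-ensemble fit per
#' variant is performed on the conditions selected by `data_combo`; in
#' `"single_cell"` mode each Epo-condition cell is fitted independently
#' (per-cell binding rates, no distribution constraints) and per-cell
#' AICc differences with medians are reported.
#'
#' @param data Trajectory table or `epor_dataset`.
#' @param variants List of variants (default: all 16).
#' @param mode `"ensemble"` or `"single_cell"`.
#' @param data_combo `"epo"`, `"epo+bleach"` or `"epo+bleach+chx"`.
#' @param n_starts,seed,... Passed to [epor_fit()].
#' @param control Optimizer control list passed to [epor_fit()].
#' @param warm_from In ensemble mode, `"union"` first fits the union of all
#'   candidate parts thoroughly and injects its optimum (restricted to each
#'   candidate's parameters) as one warm start into every candidate's
#'   multi-start schedule -- the standard nested-model warm-starting that
#'   keeps the chi-square ordering of nested variants consistent;
#'   `"none"` fits every variant from scratch.
#' @return Class `epor_selection`: in ensemble mode a data frame with one
#'   row per variant (`variant`, `objective`, `n_params`, `aicc`,
#'   `delta_aicc`), sorted by AICc; in single-cell mode additionally the
#'   per-cell delta matrix and medians.
#' @export
select_variant <- function(data, variants = epor_variants(),
                           mode = c("ensemble", "single_cell"),
                           data_combo = "epo+bleach+chx",
                           n_starts = 25, seed = 1, control = list(),
                           warm_from = c("union", "none"), ...) {
  mode <- match.arg(mode)
  warm_from <- match.arg(warm_from)
  if (inherits(data, "epor_dataset")) data <- data$trajectories
  if (mode == "single_cell") data_combo <- "epo"
  conditions <- strsplit(data_combo, "+", fixed = TRUE)[[1]]
  stopifnot(all(conditions %in% c("epo", "bleach", "chx")))
  if (!all(conditions %in% unique(data$condition)))
    stop("dataset lacks conditions required by data_combo '", data_combo, "'")
  vnames <- vapply(lapply(variants, epor_variant), `[[`, "", "name")

  if (mode == "ensemble") {
    # nested continuation: fit variants from fewest to most parts; each
    # variant's multi-start schedule is seeded with the embedded optima of
    # its already-fitted sub-variants (absent rates at the lower bound), so
    # a superset variant never ends above a subset (nesting-consistent
    # chi-square ordering)
    ord_v <- order(nchar(vnames), vnames)
    fits <- vector("list", length(vnames))
    for (k in ord_v) {
      ctl <- control
      if (warm_from == "union") {
        parts_k <- strsplit(vnames[k], "")[[1]]
        subs <- Filter(function(f) !is.null(f) &&
                         all(strsplit(f$variant, "")[[1]] %in% parts_k) &&
                         f$variant != vnames[k], fits)
        if (length(subs) > 0) {
          best <- subs[order(vapply(subs, `[[`, 0, "objective"))]
          warm <- lapply(utils::head(best, 2), `[[`, "theta")
          # each sub-optimum enters twice: exact embedding (nesting) and
          # active embedding (gradient for the added reactions)
          ctl$extra_starts <- rep(warm, each = 2)
          ctl$extra_fill <- rep(c("lower", "active"), length(warm))
          if (is.null(ctl$screen))
            ctl$screen <- max(6L, ceiling(n_starts / 3))
          # both embeddings of the best sub-fit must reach joint refinement
          ctl$refine_top <- max(ctl$refine_top %||% 0L, 3L)
        }
      }
      fit <- try(epor_fit(data, vnames[k], conditions, n_starts = n_starts,
                          seed = seed, control = ctl, ...), silent = TRUE)
      if (inherits(fit, "try-error")) {
        warning("fit failed for variant '", vnames[k], "'; excluded")
        fits[k] <- list(NULL)
      } else fits[[k]] <- fit
    }
    rows <- lapply(seq_along(vnames), function(k) {
      fit <- fits[[k]]
      if (is.null(fit)) return(NULL)
      data.frame(variant = vnames[k], objective = fit$objective,
                 n_params = fit$n_params, aicc = fit$aicc,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$delta_aicc <- tab$aicc - min(tab$aicc)
    tab <- tab[order(tab$aicc), ]
    rownames(tab) <- NULL
    return(structure(list(mode = mode, data_combo = data_combo, table = tab),
                     class = "epor_selection"))
  }

  # single-cell mode: each Epo cell fitted on its own
  epo_ids <- unique(data$cell_id[data$condition == "epo"])
  delta <- matrix(NA_real_, length(epo_ids), length(vnames),
                  dimnames = list(epo_ids, vnames))
  for (ci in seq_along(epo_ids)) {
    sub <- data[data$cell_id == epo_ids[ci] & data$condition == "epo", ]
    a <- vapply(vnames, function(v) {
      fit <- try(epor_fit(sub, v, "epo", n_starts = n_starts,
                          seed = seed + ci, constraint_weight = 0,
                          fit_scales = "none", control = control, ...),
                 silent = TRUE)
      if (inherits(fit, "try-error")) NA_real_ else fit$aicc
    }, 0)
    delta[ci, ] <- a - min(a, na.rm = TRUE)
  }
  med <- apply(delta, 2, median, na.rm = TRUE)
  tab <- data.frame(variant = vnames, median_delta_aicc = med,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$median_delta_aicc), ]
  rownames(tab) <- NULL
  structure(list(mode = mode, data_combo = "epo", table = tab,
                 per_cell_delta = delta),
            class = "epor_selection")
}

#' @export
print.epor_selection <- function(x, ...) {
  cat("Model discrimination (", x$mode, " mode, data: ", x$data_combo,
      ")\n", sep = "")
  print(x$table, digits = 5)
  invisible(x)
}

# ---- parameter-fixing ladder ------------------------------------------------

#' Sequential parameter-fixing ladder
#'
#' Greedily turns cell-specific kinetic parameter types into single global
#' values shared by all cells, refitting after each fixing and recording the
#' AICc increase relative to the unrestricted fit. At each step the
#' candidate whose fixing causes the smallest (`direction = "min"`) or
#' largest (`"max"`) AICc increase is fixed next; ties break
#' lexicographically on the parameter name. `k_EpoR_syn` always stays
#' cell-specific to carry the cells' different receptor levels.
#'
#' @param fit An `epor_fit` of the unrestricted model.
#' @param direction `"min"` or `"max"`.
#' @param joint_maxit LM iteration cap for the warm-started refits.
#' @return Class `epor_ladder`: data frame with one row per fixing step
#'   (`step`, `parameter`, `aicc`, `delta_aicc`).
#' @export
fixing_ladder <- function(fit, direction = c("min", "max"),
                          joint_maxit = 40) {
  direction <- match.arg(direction)
  stopifnot(inherits(fit, "epor_fit"))
  ctx <- fit$ctx
  types <- sort(unique(unlist(lapply(ctx$cells, `[[`, "kin_names"))))
  candidates <- setdiff(types, "k_EpoR_syn")
  tied <- character(0)
  theta_warm <- fit$theta
  rows <- list()
  for (step in seq_along(candidates)) {
    remaining <- sort(setdiff(candidates, tied))
    trial <- lapply(remaining, function(ty)
      .fit_tied(ctx, c(tied, ty), theta_warm, joint_maxit))
    a <- vapply(trial, `[[`, 0, "aicc")
    pick <- if (direction == "min") which.min(a) else which.max(a)
    tied <- c(tied, remaining[pick])
    theta_warm <- .expand_tied(ctx, trial[[pick]]$theta_tied, tied)
    rows[[step]] <- data.frame(step = step, parameter = remaining[pick],
                               aicc = a[pick],
                               delta_aicc = a[pick] - fit$aicc,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(list(direction = direction, base_aicc = fit$aicc, table = out),
            class = "epor_ladder")
}

#' @export
print.epor_ladder <- function(x, ...) {
  cat("Parameter-fixing ladder (direction:", x$direction, ")\n")
  print(x$table, digits = 5)
  invisible(x)
}

# Refit with the given kinetic types tied to a single shared value across
# cells, warm-started from a full theta. The tied theta keeps the full
# layout minus the redundant per-cell entries.
.fit_tied <- function(ctx, tied, theta_full, joint_maxit) {
  map <- .tie_map(ctx, tied)
  theta_t <- .collapse_tied(ctx, theta_full, tied, map)
  fn <- function(x) .full_resid(ctx, x[map$expand])
  res <- try(minpack.lm::nls.lm(
    theta_t, lower = ctx$lower[map$rep_idx], upper = ctx$upper[map$rep_idx],
    fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = joint_maxit,
                                         ftol = 1e-8, ptol = 1e-8)),
    silent = TRUE)
  theta_t <- if (inherits(res, "try-error")) theta_t else res$par
  obj <- .objective(ctx, theta_t[map$expand])
  list(theta_tied = theta_t, objective = obj,
       aicc = aicc(obj, length(theta_t), ctx$n_data), tied = tied)
}

# Index plumbing for tied refits: rep_idx picks one representative full-theta
# position per tied-theta entry; expand maps each full-theta position to its
# tied-theta entry.
.tie_map <- function(ctx, tied) {
  p <- length(ctx$theta_names)
  group <- seq_len(p)
  for (ty in tied) {
    pos <- unlist(lapply(ctx$cells, function(cl) {
      k <- match(ty, cl$kin_names)
      if (is.na(k)) NULL else cl$kin_theta[k]
    }))
    group[pos] <- pos[1]
  }
  rep_idx <- sort(unique(group))
  expand <- match(group, rep_idx)
  list(rep_idx = rep_idx, expand = expand)
}

.collapse_tied <- function(ctx, theta_full, tied, map = .tie_map(ctx, tied)) {
  out <- theta_full[map$rep_idx]
  for (ty in tied) {
    pos <- unlist(lapply(ctx$cells, function(cl) {
      k <- match(ty, cl$kin_names)
      if (is.na(k)) NULL else cl$kin_theta[k]
    }))
    out[match(pos[1], map$rep_idx)] <- mean(theta_full[pos])
  }
  out
}

.expand_tied <- function(ctx, theta_tied, tied) {
  map <- .tie_map(ctx, tied)
  setNames(theta_tied[map$expand], ctx$theta_names)
}
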