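# Profile-likelihood estimation (PLE): per-parameter objective profiles
# with re-optimization of all remaining parameters, defining pointwise
# confidence intervals where the profile crosses the best objective plus a
# threshold (default delta-chi2 = 1, i.e. 1-sigma pointwise).

#' Profile a residual-based objective along one coordinate
#'
#' Generic PLE engine: steps coordinate `which` of the parameter vector up
#' and down from its optimum with an adaptive step (targeting roughly
#' `0.1 * threshold` objective increase per step), re-optimizing all other
#' coordinates by bounded Levenberg-Marquardt at each grid point, and
#' locates the crossing of `best objective + threshold` by linear
#' interpolation. A profile that reaches a box bound before crossing is
#' flagged open on that side.
#'
#' @param resid_fn Function mapping the full parameter vector to a residual
#'   vector; the objective is its sum of squares.
#' @param theta Optimum of the full parameter vector.
#' @param which Index (or name) of the profiled coordinate.
#' @param lower,upper Box bounds on `theta`.
#' @param threshold Objective increase defining the confidence interval
#'   (default 1, pointwise 1-sigma for a chi-square objective).
#' @param step_init Initial step size in the profiled coordinate.
#' @param max_steps Maximum grid points per direction.
#' @param reopt_maxit LM iteration cap per re-optimization.
#' @param jac_fn Optional Jacobian `function(theta)` of the residuals.
#' @return List with `grid` (data frame: `value`, `objective`), `ci_lower`,
#'   `ci_upper` (in the profiled coordinate's own scale), `lower_open`,
#'   `upper_open`, `best`, `objective0`.
#' @export
ple_profile <- function(resid_fn, theta, which, lower, upper,
                        threshold = 1, step_init = 0.05, max_steps = 50,
                        reopt_maxit = 30, jac_fn = NULL) {
  p <- length(theta)
  if (is.character(which)) which <- match(which, names(theta))
  stopifnot(length(which) == 1, which >= 1, which <= p)
  free <- setdiff(seq_len(p), which)
  obj <- function(th) sum(resid_fn(th)^2)
  f0 <- obj(theta)
  target <- 0.1 * threshold
  ctrl <- minpack.lm::nls.lm.control(maxiter = reopt_maxit, ftol = 1e-8,
                                     ptol = 1e-8)

  reopt <- function(th) {
    if (length(free) == 0) return(list(theta = th, value = obj(th)))
    fn <- function(x) { th[free] <- x; resid_fn(th) }
    args <- list(par = th[free], lower = lower[free], upper = upper[free],
                 fn = fn, control = ctrl)
    if (!is.null(jac_fn))
      args$jac <- function(x, ...) {
        th[free] <- x
        jac_fn(th)[, free, drop = FALSE]
      }
    res <- try(do.call(minpack.lm::nls.lm, args), silent = TRUE)
    if (inherits(res, "try-error")) return(list(theta = th, value = NA_real_))
    th[free] <- res$par
    list(theta = th, value = obj(th))
  }

  walk <- function(dir) {
    th <- theta
    val <- f0
    delta <- step_init
    grid_v <- numeric(0)
    grid_o <- numeric(0)
    ci <- NA_real_
    open <- FALSE
    prev_v <- theta[which]
    prev_o <- f0
    for (s in seq_len(max_steps)) {
      nxt <- th[which] + dir * delta
      at_bound <- FALSE
      if (nxt <= lower[which]) { nxt <- lower[which]; at_bound <- TRUE }
      if (nxt >= upper[which]) { nxt <- upper[which]; at_bound <- TRUE }
      th[which] <- nxt
      r <- reopt(th)
      if (is.na(r$value)) {        # re-optimization failure: flag and skip
        grid_v <- c(grid_v, nxt)
        grid_o <- c(grid_o, NA_real_)
        if (at_bound) { open <- TRUE; break }
        next
      }
      th <- r$theta
      grid_v <- c(grid_v, nxt)
      grid_o <- c(grid_o, r$value)
      if (r$value > f0 + threshold) {
        ci <- unname(prev_v + (nxt - prev_v) *
                       (f0 + threshold - prev_o) / (r$value - prev_o))
        break
      }
      if (at_bound) { open <- TRUE; break }
      inc <- r$value - val
      delta <- delta * min(2, max(0.5, target / max(inc, target / 4)))
      prev_v <- nxt
      prev_o <- r$value
      val <- r$value
      if (s == max_steps) open <- TRUE
    }
    list(grid_v = grid_v, grid_o = grid_o, ci = ci, open = open)
  }

  up <- walk(+1)
  dn <- walk(-1)
  grid <- data.frame(
    value = unname(c(rev(dn$grid_v), theta[which], up$grid_v)),
    objective = unname(c(rev(dn$grid_o), f0, up$grid_o)))
  list(grid = grid,
       ci_lower = if (dn$open) NA_real_ else dn$ci,
       ci_upper = if (up$open) NA_real_ else up$ci,
       lower_open = dn$open, upper_open = up$open,
       best = unname(theta[which]), objective0 = f0)
}

#' Profile-likelihood confidence intervals of a fitted ensemble
#'
#' Runs PLE for the selected parameters of an [epor_fit()]: each parameter
#' is stepped in log10 space while all remaining parameters are
#' re-optimized. A lower interval end at the box bound is flagged "includes
#' zero", an upper end at the bound "infinite"; confidence intervals are
#' reported on the natural parameter scale together with their size
#' relative to the best-fit value.
#'
#' @param fitted An `epor_fit`.
#' @param which Parameter names to profile (`"kinetic"`: all kinetic
#'   entries, the default; `"all"`: every estimated parameter; or a
#'   character vector of theta names).
#' @param threshold Delta-objective defining the interval (default 1).
#' @param max_steps,reopt_maxit,step_init Engine settings, see
#'   [ple_profile()].
#' @param ... Unused.
#' @return Class `epor_profiles`: data frame (`parameter`, `best`,
#'   `ci_lower`, `ci_upper`, `includes_zero`, `infinite_upper`,
#'   `relative_ci`) with the per-parameter grids as attribute `profiles`.
#' @export
profile.epor_fit <- function(fitted, which = "kinetic", threshold = 1,
                             max_steps = 50, reopt_maxit = 30,
                             step_init = 0.05, ...) {
  ctx <- fitted$ctx
  theta <- fitted$theta
  nm <- names(theta)
  if (identical(which, "all")) which <- nm
  if (identical(which, "kinetic"))
    which <- nm[ctx$kind == "rate"]
  bad <- setdiff(which, nm)
  if (length(bad) > 0) stop("unknown parameter(s): ",
                            paste(bad, collapse = ", "))
  resid_fn <- function(th) .full_resid(ctx, th)
  jac_fn <- function(th) .full_jac(ctx, th)
  rows <- list()
  grids <- list()
  for (w in which) {
    pr <- ple_profile(resid_fn, theta, w, ctx$lower, ctx$upper,
                      threshold = threshold, step_init = step_init,
                      max_steps = max_steps, reopt_maxit = reopt_maxit,
                      jac_fn = jac_fn)
    best_nat <- 10^pr$best
    lo <- if (pr$lower_open) 0 else 10^pr$ci_lower
    hi <- if (pr$upper_open) Inf else 10^pr$ci_upper
    rows[[w]] <- data.frame(
      parameter = w, best = best_nat, ci_lower = lo, ci_upper = hi,
      includes_zero = pr$lower_open, infinite_upper = pr$upper_open,
      relative_ci = (hi - lo) / best_nat, stringsAsFactors = FALSE)
    grids[[w]] <- pr$grid
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, profiles = grids, threshold = threshold,
            class = c("epor_profiles", "data.frame"))
}

#' @export
print.epor_profiles <- function(x, ...) {
  cat("Profile-likelihood 1-sigma confidence intervals (",
      nrow(x), " parameters, threshold ", attr(x, "threshold"), ")\n",
      sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
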