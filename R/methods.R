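# S3 methods for fitted cell-ensemble models.

#' @export
print.epor_fit <- function(x, ...) {
  v <- if (nzchar(x$variant)) x$variant else "basic"
  cat("Cell-ensemble trafficking model fit (variant ", v, ")\n", sep = "")
  cat("  conditions: ", paste(x$conditions, collapse = " + "),
      " | cells: ", length(x$cell_ids),
      " | data points: ", x$n_data, "\n", sep = "")
  cat(sprintf("  objective %.4g (data chi2 %.4g + penalty %.4g), %d parameters, AICc %.4g\n",
              x$objective, x$chi2, x$penalty, x$n_params, x$aicc))
  cat("  multi-start: best of", x$n_starts, "starts, seed", x$seed, "\n")
  invisible(x)
}

#' Extract fitted parameters
#'
#' @param object An `epor_fit`.
#' @param type `"all"` for the full named vector (natural scale),
#'   `"cells"` for a cells x kinetic-parameter matrix (plus initial
#'   concentrations), `"global"` or `"scales"`.
#' @param ... Unused.
#' @return Named numeric vector or matrix on the natural parameter scale.
#' @export
coef.epor_fit <- function(object, type = c("all", "cells", "global",
                                           "scales"), ...) {
  type <- match.arg(type)
  full <- 10^object$theta
  if (type == "all") return(full)
  ctx <- object$ctx
  if (type == "global")
    return(full[ctx$idx_global])
  if (type == "scales") {
    sc <- full[unname(ctx$idx_scale)]
    names(sc) <- names(ctx$idx_scale)
    return(sc)
  }
  cols <- sort(unique(unlist(lapply(ctx$cells, `[[`, "kin_names"))))
  cols <- c(cols, "EpoR_i0", "EpoR_m0")
  out <- matrix(NA_real_, length(ctx$cells), length(cols),
                dimnames = list(vapply(ctx$cells, `[[`, "", "id"), cols))
  for (i in seq_along(ctx$cells)) {
    cl <- ctx$cells[[i]]
    out[i, cl$kin_names] <- full[cl$kin_theta]
    out[i, c("EpoR_i0", "EpoR_m0")] <- full[cl$init_theta]
  }
  out
}

#' Summarize a cell-ensemble fit
#'
#' @param object An `epor_fit`.
#' @param ... Unused.
#' @return Class `summary.epor_fit` with per-parameter-type means, SDs and
#'   CVs across cells, global parameters, scales, and fit statistics.
#' @export
summary.epor_fit <- function(object, ...) {
  cells <- coef(object, "cells")
  stats <- data.frame(
    parameter = colnames(cells),
    mean = colMeans(cells, na.rm = TRUE),
    sd = apply(cells, 2, sd, na.rm = TRUE))
  stats$cv <- stats$sd / stats$mean
  structure(list(fit = object, cell_params = cells, type_stats = stats,
                 global = coef(object, "global"),
                 scales = coef(object, "scales")),
            class = "summary.epor_fit")
}

#' @export
print.summary.epor_fit <- function(x, ...) {
  print(x$fit)
  cat("\nGlobal parameters:\n")
  print(signif(x$global, 4))
  if (length(x$scales) > 0) {
    cat("\nScaling factors (a.u./nM):\n")
    print(signif(x$scales, 4))
  }
  cat("\nSingle-cell parameter distribution across cells:\n")
  print(transform(x$type_stats, mean = signif(mean, 4), sd = signif(sd, 4),
                  cv = signif(cv, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
logLik.epor_fit <- function(object, ...) {
  structure(-object$objective / 2, df = object$n_params,
            nobs = object$n_data, class = "logLik")
}

#' Model predictions for the fitted data
#'
#' @param object An `epor_fit`.
#' @param ... Unused.
#' @return `fitted()`: the data table with an extra `fitted_au` column;
#'   `residuals()`: weighted residuals `(observed - fitted) / sigma` in the
#'   same row order.
#' @export
fitted.epor_fit <- function(object, ...) {
  ctx <- object$ctx
  theta <- object$theta
  rows <- lapply(seq_along(ctx$cells), function(i) {
    cell <- ctx$cells[[i]]
    kin <- numeric(12)
    kin[cell$kin_slots] <- 10^theta[cell$kin_theta]
    if (cell$cond_code == 0L) kin[1:2] <- 10^theta[ctx$idx_global]
    sc <- cell$scale_fixed
    if (length(cell$scale_free) > 0)
      sc[cell$scale_free] <- 10^theta[cell$scale_theta]
    pred <- .predict_cell(cell, kin, 10^theta[cell$init_theta], sc)
    idx <- arrayInd(cell$mask, dim(cell$Y))
    data.frame(cell_id = cell$id, condition = cell$condition,
               observable = cell$obs[idx[, 2]],
               time_min = cell$times[idx[, 1]],
               value_au = cell$Y[cell$mask],
               fitted_au = pred[cell$mask],
               sigma_au = (ctx$sigma_rel *
                             pmax(pred, rep(cell$floor, each = nrow(pred))) +
                             rep(cell$sigma_abs, each = nrow(pred)))[cell$mask],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname fitted.epor_fit
#' @export
residuals.epor_fit <- function(object, ...) {
  f <- fitted(object)
  (f$value_au - f$fitted_au) / f$sigma_au
}

#' Simulate trajectories from a fitted ensemble
#'
#' Re-simulates every fitted cell from its estimated parameters and initial
#' concentrations, optionally adding multiplicative log-normal measurement
#' noise with the fit's relative error.
#'
#' @param object An `epor_fit`.
#' @param nsim Number of noisy replicate tables (ignored if `noise = FALSE`).
#' @param seed Optional seed for the noise draws.
#' @param noise Add measurement noise?
#' @param ... Unused.
#' @return A long-format trajectory table (list of tables if `nsim > 1`).
#' @export
simulate.epor_fit <- function(object, nsim = 1, seed = NULL, noise = FALSE,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- fitted(object)
  base <- f[, c("cell_id", "condition", "observable", "time_min")]
  base$value_au <- f$fitted_au
  if (!noise) return(base)
  out <- lapply(seq_len(nsim), function(k) {
    b <- base
    b$value_au <- b$value_au *
      exp(rnorm(nrow(b), 0, object$ctx$sigma_rel))
    b
  })
  if (nsim == 1) out[[1]] else out
}

#' Plot fit against data
#'
#' One panel per observable of the chosen condition, data as points and
#' model trajectories as lines, colored by cell.
#'
#' @param x An `epor_fit`.
#' @param condition Condition to display.
#' @param cells Optional subset of cell ids.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.epor_fit <- function(x, condition = "epo", cells = NULL, ...) {
  f <- fitted(x)
  f <- f[f$condition == condition, ]
  if (!is.null(cells)) f <- f[f$cell_id %in% cells, ]
  if (nrow(f) == 0) stop("no fitted data for condition ", condition)
  obs <- unique(f$observable)
  ids <- unique(f$cell_id)
  cols <- grDevices::rainbow(length(ids))
  old <- par(mfrow = c(ceiling(length(obs) / 2), 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (o in obs) {
    sub <- f[f$observable == o, ]
    plot(sub$time_min, sub$value_au, col = cols[match(sub$cell_id, ids)],
         pch = 1, cex = 0.6, xlab = "time (min)", ylab = "a.u.",
         main = o, ...)
    for (id in ids) {
      s2 <- sub[sub$cell_id == id, ]
      lines(s2$time_min[order(s2$time_min)],
            s2$fitted_au[order(s2$time_min)], col = cols[match(id, ids)])
    }
  }
  invisible(x)
}
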