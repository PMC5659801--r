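test_that("AICc formula and small-sample penalty behave as documented", {
  expect_equal(aicc(50, 10, 100), 50 + 20 + 220 / 89)
  expect_equal(aicc(50, 10, 100), 72.472, tolerance = 1e-4)
  # equal fit, fewer parameters: smaller AICc
  expect_lt(aicc(80, 5, 200), aicc(80, 9, 200))
  expect_error(aicc(10, 10, 11), "n_data must exceed")
})

test_that("the best 0.5% of 1000 multi-starts keeps 5 fits", {
  starts <- data.frame(start = 1:1000, objective = rnorm(1000) + 100)
  kept <- keep_best(starts, frac = 0.005)
  expect_identical(nrow(kept), 5L)
  expect_identical(kept$objective, sort(starts$objective)[1:5])
  expect_identical(nrow(keep_best(starts[1:10, ], 0.005)), 1L)
})

test_that("constraint penalty vanishes for identical group distributions", {
  ds <- tiny_dataset()
  ctx <- epoRtraffic:::build_ensemble(
    ds$trajectories, epor_variant("ACD"), c("epo", "bleach", "chx"),
    constraint_weight = 1, fit_scales = "none", error_model = NULL,
    protocols = NULL, control = epoRtraffic:::.default_control(5))
  th <- setNames(rep(-1, length(ctx$theta_names)), ctx$theta_names)
  expect_equal(sum(epoRtraffic:::.constraint_resid(ctx, th)^2), 0)
  # shared types across all three groups plus k_syn for epo/bleach
  types <- vapply(ctx$constraints, `[[`, "", "type")
  expect_setequal(unique(types),
                  c("k_EpoR_deg", "k_EpoR_ItoM", "k_EpoR_MtoI",
                    "k_EpoR_syn"))
  expect_identical(sum(types == "k_EpoR_syn"), 1L)   # epo-bleach pair only
})

test_that("group log-means one decade apart cost weight x 1 per shared type", {
  ds <- tiny_dataset()
  ctx <- epoRtraffic:::build_ensemble(
    ds$trajectories, epor_variant("ACD"), c("epo", "bleach"),
    constraint_weight = 1, fit_scales = "none", error_model = NULL,
    protocols = NULL, control = epoRtraffic:::.default_control(5))
  th <- setNames(rep(1, length(ctx$theta_names)), ctx$theta_names)
  bleach_kin <- grep("^bleach.*k_", names(th))
  th[bleach_kin] <- 2
  pen <- sum(epoRtraffic:::.constraint_resid(ctx, th)^2)
  expect_equal(pen, length(unique(vapply(ctx$constraints, `[[`, "",
                                         "type"))))
})

test_that("zero constraint weight reduces the objective to weighted least squares", {
  ds <- tiny_dataset()
  mk <- function(w) epoRtraffic:::build_ensemble(
    ds$trajectories, epor_variant("ACD"), c("epo", "bleach", "chx"),
    constraint_weight = w, fit_scales = "none", error_model = NULL,
    protocols = NULL, control = epoRtraffic:::.default_control(5))
  ctx0 <- mk(0)
  ctx1 <- mk(1)
  set.seed(1)
  th <- epoRtraffic:::.lhs_starts(ctx1, 1)[1, ]
  data_chi2 <- sum(unlist(lapply(seq_along(ctx0$cells), function(i)
    epoRtraffic:::.cell_resid(ctx0, i, th)))^2)
  expect_equal(epoRtraffic:::.objective(ctx0, th), data_chi2)
  expect_gte(epoRtraffic:::.objective(ctx1, th), data_chi2)
})

test_that("objective is invariant under permutation of cell order", {
  ds <- tiny_dataset()
  tab <- ds$trajectories
  perm <- tab[order(rev(tab$cell_id), tab$observable, tab$time_min), ]
  mk <- function(d) epoRtraffic:::build_ensemble(
    d, epor_variant("ACD"), c("epo", "bleach", "chx"),
    constraint_weight = 1, fit_scales = "free", error_model = NULL,
    protocols = NULL, control = epoRtraffic:::.default_control(5))
  ctx_a <- mk(tab)
  ctx_b <- mk(perm)
  th_a <- setNames(seq(-2, 1, length.out = length(ctx_a$theta_names)),
                   ctx_a$theta_names)
  th_b <- th_a[ctx_b$theta_names]
  expect_equal(epoRtraffic:::.objective(ctx_a, th_a),
               epoRtraffic:::.objective(ctx_b, th_b), tolerance = 1e-10)
})

test_that("a noise-free single cell is recovered essentially exactly", {
  ds <- noisefree_cell()
  fit <- cached("nf_fit", {
    suppressWarnings(epor_fit(ds, variant = "", conditions = "epo",
                              n_starts = 30, seed = 2, fit_scales = "none",
                              constraint_weight = 0))
  })
  expect_lt(fit$objective, 1e-8)
  est <- coef(fit, "cells")[1, ]
  truth <- ds$truth
  pars <- epoRtraffic:::cell_truth_params(truth$params[1, ], "epo",
                                          truth$config)
  for (nm in setdiff(names(pars), c("k_on_Epo", "k_off_Epo")))
    expect_equal(unname(est[nm]), unname(pars[nm]), tolerance = 0.01)
  expect_equal(unname(est["EpoR_i0"]), unname(truth$init[1, "EpoR_i"]),
               tolerance = 0.01)
  expect_equal(unname(coef(fit, "global")), unname(pars[c("k_on_Epo",
                                                          "k_off_Epo")]),
               tolerance = 0.01)
})

test_that("fits are deterministic given the seed", {
  ds <- noisefree_cell()
  f1 <- suppressWarnings(epor_fit(ds, "", "epo", n_starts = 4, seed = 31,
                                  fit_scales = "none",
                                  control = list(refine_top = 1,
                                                 polish_cycles = 1)))
  f2 <- suppressWarnings(epor_fit(ds, "", "epo", n_starts = 4, seed = 31,
                                  fit_scales = "none",
                                  control = list(refine_top = 1,
                                                 polish_cycles = 1)))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$starts$objective, f2$starts$objective)
  expect_identical(f1$aicc, f2$aicc)
})

test_that("fit object methods are coherent", {
  fit <- cached("nf_fit", {
    suppressWarnings(epor_fit(noisefree_cell(), variant = "",
                              conditions = "epo", n_starts = 30, seed = 2,
                              fit_scales = "none", constraint_weight = 0))
  })
  expect_s3_class(fit, "epor_fit")
  expect_identical(fit$n_data, 170L)
  expect_equal(as.numeric(logLik(fit)), -fit$objective / 2)
  expect_identical(attr(logLik(fit), "df"), fit$n_params)
  f <- fitted(fit)
  expect_identical(nrow(f), fit$n_data)
  expect_equal(sum(residuals(fit)^2), fit$chi2, tolerance = 1e-10)
  sim <- simulate(fit)
  expect_identical(nrow(sim), fit$n_data)
  expect_equal(sim$value_au, f$fitted_au)
  s <- summary(fit)
  expect_s3_class(s, "summary.epor_fit")
  expect_true(all(c("k_EpoR_deg", "EpoR_i0") %in%
                    colnames(s$cell_params)))
})

test_that("a superset variant never fits worse than its nested sub-variant", {
  ds <- tiny_dataset()
  fsub <- cached("tiny_AD", {
    suppressWarnings(epor_fit(tiny_dataset(), "AD", n_starts = 8, seed = 3,
                              control = list(refine_top = 2,
                                             polish_cycles = 1)))
  })
  fsup <- suppressWarnings(epor_fit(
    ds, "ACD", n_starts = 8, seed = 3,
    control = list(refine_top = 2, polish_cycles = 1,
                   extra_starts = fsub$theta, extra_fill = "lower")))
  expect_lte(fsup$objective, fsub$objective * (1 + 1e-6))
  expect_gt(fsup$n_params, fsub$n_params)
})
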