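test_that("fluxes are rate times source and stationary before stimulation", {
  p <- paper_like_params("ACD")
  p["k_on_Epo"] <- 0                       # no binding: resting turnover
  tr <- simulate_cell("ACD", p, epo_protocol())
  fl <- fluxes("ACD", p, tr)
  expect_equal(fl[, "F_ItoM"], fl[, "F_MtoI"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(fl[1, "F_deg"]), unname(p["k_EpoR_syn"]),
               tolerance = 1e-10)
  # empty RE compartment: every exit flux is zero
  expect_equal(max(fl[, c("F_EpoRstar_REtoM", "F_EpoRstar_deg_REtoEx",
                          "F_EpoRstar_deg_REtoI")]), 0)
})

test_that("recycling flux reaches the order of the free-receptor transport flux", {
  p <- paper_like_params("ACD")
  tr <- simulate_cell("ACD", p, epo_protocol())
  fl <- fluxes("ACD", p, tr)
  i <- nrow(fl)
  ratio <- fl[i, "F_EpoRstar_REtoM"] / fl[i, "F_ItoM"]
  expect_gt(ratio, 0.1)
  expect_lt(ratio, 10)
})

test_that("control coefficients: decoupled parameters score zero, all |r| < 1, sum ~ 0", {
  p <- paper_like_params("")
  p["k_EpoR_ItoM"] <- 0          # intracellular pool decoupled from membrane
  init <- c(EpoR_i = 30, EpoR_m = 3, EpoRstar_m = 0, EpoRstar_RE = 0,
            Epo_deg_i = 0, Epo_deg_ext = 0)
  r0 <- control_coefficients("", p, "EpoRstar_m", t = 100, init = init)
  expect_equal(unname(r0["k_EpoR_deg"]), 0, tolerance = 1e-8)
  expect_equal(unname(r0["k_EpoR_syn"]), 0, tolerance = 1e-8)

  p2 <- paper_like_params("ACD")
  r <- control_coefficients("ACD", p2, "EpoRstar_m", t = 300)
  expect_true(all(abs(r) < 1))
  # at steady state the coefficients over all rates plus synthesis cancel
  r_ss <- control_coefficients("ACD", p2, "EpoRstar_m", t = 2e4)
  expect_equal(unname(sum(r_ss)), 0, tolerance = 1e-3)
  r_ss2 <- control_coefficients("ACD", p2, "EpoRstar_RE", t = 2e4)
  expect_equal(unname(sum(r_ss2)), 0, tolerance = 1e-3)
})

test_that("Pearson correlations carry the exact t-test p-values", {
  set.seed(3)
  n <- 16
  x <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x))
  y <- 0.8 * scale(x)[, 1] + sqrt(1 - 0.8^2) * scale(z)[, 1]
  m <- cbind(a = exp(x), b = exp(y))          # log-scale correlation 0.8
  ca <- correlation_analysis(m, log = TRUE)
  expect_equal(ca$r["a", "b"], 0.8, tolerance = 1e-10)
  t_stat <- 0.8 * sqrt(n - 2) / sqrt(1 - 0.8^2)
  expect_equal(ca$p["a", "b"], 2 * pt(-t_stat, n - 2), tolerance = 1e-10)
  expect_equal(t_stat, 4.99, tolerance = 1e-3)
  expect_equal(ca$p["a", "b"], 2.1e-4, tolerance = 0.02)
  # perfect correlation and degenerate input
  expect_error(correlation_analysis(cbind(a = rep(2, 5), b = 1:5),
                                    log = FALSE), "zero-variance")
  ph <- correlation_analysis(cbind(a = 1:8, b = (1:8) * 3), log = FALSE)
  expect_equal(ph$r["a", "b"], 1)
})

test_that("parameter statistics summarize the ensemble and fit a log-normal", {
  cells <- sample_cells(generator_config(n_epo_cells = 60,
                                         n_bleach_cells = 0,
                                         n_chx_cells = 0, seed = 4))
  st <- parameter_stats(cells$params)
  expect_s3_class(st, "epor_param_stats")
  expect_true(all(st$summary$cv > 0))
  expect_equal(st$cor, t(st$cor))
  expect_equal(unname(diag(st$cor)), rep(1, ncol(cells$params)))
  ev <- eigen(st$log10_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  # transport parameters sampled with rho = 0.7 are strongly correlated
  expect_gt(st$cor["k_EpoR_ItoM", "k_EpoR_MtoI"], 0.4)
})

test_that("covariance experiment: sampling obeys the log-normal closed form", {
  st <- generator_stats(generator_config())
  cx <- covariance_experiment(st, n_samples = 400, seed = 2)
  expect_named(cx$cv, c("EpoRstar_m", "EpoRstar_RE"))
  expect_true(all(is.finite(cx$cv)) && all(cx$cv > 0))
  expect_true(all(cx$cv_se > 0))
  # univariate marginal check: one free parameter, all others pinned
  tab <- default_parameter_table()
  tab$log10_sd[] <- 0
  tab$log10_sd[tab$name == "k_EpoR_syn"] <- 0.43
  cfg1 <- generator_config(param_table = tab, rho_transport = 0)
  s1 <- sample_cells(generator_config(n_epo_cells = 3000,
                                      n_bleach_cells = 0, n_chx_cells = 0,
                                      param_table = tab, rho_transport = 0),
                     seed = 8)
  sig <- 0.43 * log(10)
  expect_equal(sd(s1$params[, "k_EpoR_syn"]) / mean(s1$params[, "k_EpoR_syn"]),
               sqrt(exp(sig^2) - 1), tolerance = 0.1)
})

test_that("with a diagonal covariance the reduced experiment changes nothing", {
  st <- generator_stats(generator_config(rho_transport = 0))
  a <- covariance_experiment(st, n_samples = 200, seed = 3, reduced = FALSE)
  b <- covariance_experiment(st, n_samples = 200, seed = 3, reduced = TRUE)
  expect_equal(a$cv, b$cv, tolerance = 1e-12)
})

test_that("removing transport covariances inflates membrane-complex variability", {
  st <- generator_stats(generator_config())
  full <- covariance_experiment(st, n_samples = 600, seed = 4)
  red <- covariance_experiment(st, n_samples = 600, seed = 4, reduced = TRUE)
  expect_gt(red$cv["EpoRstar_m"], full$cv["EpoRstar_m"])
})

test_that("data-level correlations are scale-free and flag degenerate input", {
  ds <- cached("dlc16", {
    generate_dataset(generator_config(n_epo_cells = 16, n_bleach_cells = 0,
                                      n_chx_cells = 0, seed = 6))
  })
  tab <- ds$trajectories
  out <- data_level_correlations(tab)
  expect_named(out, c("mem_vs_ves_conc", "tot_vs_epo_mem_conc",
                      "tot_vs_epo_mem_amount"))
  # correlated transport kinetics induce a positive membrane-vesicle
  # concentration correlation
  expect_gt(out$mem_vs_ves_conc$rho, 0)
  tab2 <- tab
  tab2$value_au <- tab2$value_au * 37.5
  out2 <- data_level_correlations(tab2)
  expect_equal(out2$mem_vs_ves_conc$rho, out$mem_vs_ves_conc$rho,
               tolerance = 1e-12)
  expect_equal(out2$tot_vs_epo_mem_conc$p, out$tot_vs_epo_mem_conc$p,
               tolerance = 1e-12)
  # identical cells: fold changes all one, correlation undefined but flagged
  one <- tab[tab$cell_id == "epo_01", ]
  clones <- do.call(rbind, lapply(1:4, function(k) {
    x <- one
    x$cell_id <- paste0("epo_0", k)
    x
  }))
  outc <- data_level_correlations(clones)
  expect_true(outc$mem_vs_ves_conc$degenerate)
  expect_true(is.na(outc$mem_vs_ves_conc$rho))
  expect_equal(unname(outc$mem_vs_ves_conc$fold_x), rep(1, 4))
})
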