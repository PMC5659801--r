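state0 <- function(...) {
  s <- c(EpoR_i = 0, EpoR_m = 0, EpoRstar_m = 0, EpoRstar_RE = 0,
         Epo_deg_i = 0, Epo_deg_ext = 0)
  args <- c(...)
  s[names(args)] <- args
  s
}

test_that("rhs matches the hand-evaluated derivative for variant ACD", {
  p <- setNames(rep(1, 10), kinetic_param_names("ACD"))
  s <- state0(EpoR_i = 1, EpoR_m = 1, EpoRstar_m = 1, EpoRstar_RE = 1,
              Epo_deg_i = 1, Epo_deg_ext = 1)
  d <- epor_rhs("ACD", p, s, epo = 1)
  expect_equal(unname(d), c(0, 1, -1, -2, 1, 1))
})

test_that("without ligand and complexes the system is two-compartment turnover", {
  p <- paper_like_params("ACD")
  s <- state0(EpoR_i = 5, EpoR_m = 2)
  d <- epor_rhs("ACD", p, s, epo = 0)
  expect_equal(unname(d[c("EpoRstar_m", "EpoRstar_RE", "Epo_deg_i",
                          "Epo_deg_ext")]), rep(0, 4))
  expect_equal(unname(d["EpoR_i"]),
               unname(p["k_EpoR_syn"] - (p["k_EpoR_deg"] + p["k_EpoR_ItoM"]) * 5 +
                        p["k_EpoR_MtoI"] * 2))
})

test_that("receptor mass balance holds symbolically for every variant", {
  set.seed(1)
  for (v in epor_variants()) {
    nm <- kinetic_param_names(v)
    p <- setNames(10^runif(length(nm), -2, 0), nm)
    s <- state0(EpoR_i = runif(1, 0, 50), EpoR_m = runif(1, 0, 5),
                EpoRstar_m = runif(1, 0, 5), EpoRstar_RE = runif(1, 0, 10))
    d <- epor_rhs(v, p, s, epo = 4.2)
    lhs <- sum(d[c("EpoR_i", "EpoR_m", "EpoRstar_m", "EpoRstar_RE")])
    deg_re <- sum(p[c("k_EpoRstar_deg_REtoEx", "k_EpoRstar_deg_REtoI")],
                  na.rm = TRUE)
    rhs <- unname(p["k_EpoR_syn"] - p["k_EpoR_deg"] * s["EpoR_i"] -
                    deg_re * s["EpoRstar_RE"])
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("pre-stimulus steady state has the closed form and is a fixed point", {
  p <- c(k_EpoR_syn = 1, k_EpoR_deg = 0.1, k_EpoR_ItoM = 0.1, k_EpoR_MtoI = 1)
  ss <- prestimulus_steady_state(p)
  expect_equal(unname(ss), c(10, 1))
  # independent oracle: long-time integration without ligand converges there
  pp <- c(k_on_Epo = 0, k_off_Epo = 0.1, p, k_EpoRstar_MtoRE = 0.2)
  pr <- epo_protocol(epo_conc = 1e-12, sample_times = c(0, 5000))
  tr <- simulate_cell("", pp, pr,
                      init = state0(EpoR_i = 30, EpoR_m = 4), method = "lsoda")
  expect_equal(unname(tr[2, c("EpoR_i", "EpoR_m")]), c(10, 1),
               tolerance = 1e-6)
  expect_equal(unname(prestimulus_steady_state(
    c(k_EpoR_syn = 0, k_EpoR_deg = 0.1, k_EpoR_ItoM = 3, k_EpoR_MtoI = 1))),
    c(0, 0))
  expect_equal(membrane_fraction(c(k_EpoR_ItoM = 0.3, k_EpoR_MtoI = 0.3)), 0.5)
  expect_error(prestimulus_steady_state(
    c(k_EpoR_syn = 1, k_EpoR_deg = 0, k_EpoR_ItoM = 1, k_EpoR_MtoI = 1)),
    "must be > 0")
})

test_that("reduced bleach/CHX models have 3 ODEs with 5 and 3 parameters", {
  b <- reduced_model("bleach")
  expect_identical(b$n_odes, 3L)
  expect_identical(b$n_kinetic, 5L)
  expect_length(b$states, 3)
  ch <- reduced_model("chx")
  expect_identical(ch$n_odes, 3L)
  expect_identical(ch$n_kinetic, 3L)
})

test_that("analytic solver matches the 2x2 matrix-exponential closed form", {
  # basic variant, no ligand, no synthesis/degradation: pure linear exchange
  p <- c(k_on_Epo = 0, k_off_Epo = 0.1, k_EpoR_syn = 0, k_EpoR_deg = 0,
         k_EpoR_ItoM = 0.07, k_EpoR_MtoI = 0.21, k_EpoRstar_MtoRE = 0.1)
  times <- c(0, 2, 7, 31, 120)
  pr <- epo_protocol(epo_conc = 1e-12, sample_times = times)
  y0 <- c(12, 3)
  tr <- simulate_cell("", p, pr, init = state0(EpoR_i = 12, EpoR_m = 3))
  A <- matrix(c(-0.07, 0.07, 0.21, -0.21), 2, 2)
  for (k in seq_along(times)) {
    ref <- as.numeric(Matrix::expm(A * times[k]) %*% y0)
    expect_equal(unname(tr[k, c("EpoR_i", "EpoR_m")]), ref, tolerance = 1e-10)
  }
})

test_that("analytic and lsoda routes agree and satisfy state invariants", {
  cfg <- generator_config()
  p <- paper_like_params("ABCD")
  pr <- epo_protocol()
  tr1 <- simulate_cell("ABCD", p, pr)
  tr2 <- simulate_cell("ABCD", p, pr, method = "lsoda")
  expect_equal(unclass(tr1), unclass(tr2), tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_true(all(tr1 >= -1e-10))
  # cumulative bookkeeping states never decrease
  expect_true(all(diff(tr1[, "Epo_deg_i"]) >= -1e-10))
  expect_true(all(diff(tr1[, "Epo_deg_ext"]) >= -1e-10))
})

test_that("no binding means no complexes; steady-state start stays constant", {
  p <- paper_like_params("ACD")
  p["k_on_Epo"] <- 0
  tr <- simulate_cell("ACD", p, epo_protocol())
  expect_equal(max(abs(tr[, "EpoRstar_m"])), 0)
  expect_equal(max(abs(tr[, "EpoRstar_RE"])), 0)
  p2 <- paper_like_params("ACD")
  p2["k_on_Epo"] <- 0
  tr2 <- simulate_cell("ACD", p2, epo_protocol())
  expect_equal(unname(diff(range(tr2[, "EpoR_i"]))), 0, tolerance = 1e-8)
  expect_equal(unname(diff(range(tr2[, "EpoR_m"]))), 0, tolerance = 1e-8)
})

test_that("steady state under Epo: direct linear solve matches long integration", {
  p <- paper_like_params("ACD")
  full <- epoRtraffic:::as_param_vector(p, "ACD", "epo")
  # linear-solve oracle for the 4 core species with constant Epo
  epo <- 4.2
  K <- matrix(0, 4, 4)
  K[1, 1] <- -(full["k_EpoR_deg"] + full["k_EpoR_ItoM"])
  K[1, 2] <- full["k_EpoR_MtoI"]
  K[2, 1] <- full["k_EpoR_ItoM"]
  K[2, 2] <- -(full["k_EpoR_MtoI"] + full["k_on_Epo"] * epo)
  K[2, 3] <- full["k_off_Epo"]
  K[2, 4] <- full["k_EpoRstar_REtoM"]
  K[3, 2] <- full["k_on_Epo"] * epo
  K[3, 3] <- -(full["k_off_Epo"] + full["k_EpoRstar_MtoRE"])
  K[4, 3] <- full["k_EpoRstar_MtoRE"]
  K[4, 4] <- -(full["k_EpoRstar_REtoM"] + full["k_EpoRstar_deg_REtoEx"] +
                 full["k_EpoRstar_deg_REtoI"])
  ss <- solve(K, -c(full["k_EpoR_syn"], 0, 0, 0))
  pr <- epo_protocol(sample_times = c(0, 2e5))
  tr <- simulate_cell("ACD", p, pr)
  expect_equal(unname(tr[2, 1:4]), unname(ss), tolerance = 1e-8)
})

test_that("Cy5.5 label bookkeeping is conserved along the trajectory", {
  p <- paper_like_params("ACD")
  pr <- epo_protocol(sample_times = seq(0, 300, by = 0.1))
  tr <- simulate_cell("ACD", p, pr)
  times <- attr(tr, "times")
  # internalized label either sits in the RE pool, was degraded (internal or
  # exported) or left intact via part A; influx is the endocytosis flux
  influx <- p["k_EpoRstar_MtoRE"] * tr[, "EpoRstar_m"]
  cum_influx <- cumsum(c(0, diff(times) *
                           (head(influx, -1) + tail(influx, -1)) / 2))
  label <- tr[, "EpoRstar_RE"] + tr[, "Epo_deg_i"] + tr[, "Epo_deg_ext"] +
    tr[, "pool"]
  expect_lt(max(abs(label - cum_influx)) / max(label), 1e-4)
})

test_that("bleach pulse removes fluorescent receptor only during the window", {
  pb <- c(k_EpoR_syn = 0.6, k_EpoR_deg = 0.015, k_EpoR_ItoM = 0.0104,
          k_EpoR_MtoI = 0.1313, k_bleach = 3)
  tr <- simulate_cell("", pb, bleach_protocol(start = 5, duration = 0.5))
  expect_equal(unname(tr[2, "pool"]), 0)          # t = 5: pre-pulse
  expect_gt(tr[3, "pool"], 0)                     # t = 10: after pulse
  expect_equal(tr[3, "pool"], tr[34, "pool"], tolerance = 1e-10)
  # null pulse reproduces plain turnover
  pb0 <- pb
  pb0["k_bleach"] <- 0
  tr0 <- simulate_cell("", pb0, bleach_protocol())
  pc <- c(k_EpoR_syn = 0.6, k_EpoR_deg = 0.015, k_EpoR_ItoM = 0.0104,
          k_EpoR_MtoI = 0.1313, k_on_Epo = 0, k_off_Epo = 0,
          k_EpoRstar_MtoRE = 0)
  trt <- simulate_cell("", pc, epo_protocol(epo_conc = 1e-12,
                                            sample_times = default_grid()),
                       init = tr0[1, 1:6])
  expect_equal(tr0[, c("EpoR_i", "EpoR_m")], trt[, c("EpoR_i", "EpoR_m")],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("CHX switches synthesis off and the receptor pool decays", {
  pc <- c(k_EpoR_deg = 0.015, k_EpoR_ItoM = 0.0104, k_EpoR_MtoI = 0.1313)
  init <- state0(EpoR_i = 40, EpoR_m = 3.2)
  tr <- simulate_cell("", pc, chx_protocol(), init = init)
  tot <- tr[, "EpoR_i"] + tr[, "EpoR_m"]
  expect_true(all(diff(tot) < 0))
  # degraded receptor accounts exactly for the loss
  expect_equal(tot + tr[, "pool"], rep(43.2, nrow(tr)), tolerance = 1e-8,
               ignore_attr = TRUE)
})
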