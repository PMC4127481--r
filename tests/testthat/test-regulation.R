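p <- defaultParams()
pv <- param(p)
la <- pv[["Lp"]] * pv[["A_osm"]]

test_that("water-side coefficients recover a constructed single-difference
           pair: only media osmotic pressure differs", {
  t <- seq(0, 500, by = 0.1)
  mk <- function(pi_o_const)
    syntheticTrajectory(p, t,
                        pi_i = 1.25e6 + 2e4 * sin(2 * pi * t / 50),
                        pi_o = rep(pi_o_const, length(t)),
                        P = 2.14e5 + 500 * sin(2 * pi * t / 50 + 1))
  trA <- mk(0.89e6); trB <- mk(0.45e6)
  w <- c(100, 200)   # two exact periods: sine averages vanish
  r <- waterRegulationCoefficients(trA, trB, windowO1 = w, windowO2 = w)
  expect_equal(r$R_pi_o_w, 1, tolerance = 1e-9)
  expect_equal(r$R_pi_i_w, 0, tolerance = 1e-9)
  expect_equal(r$R_P_w, 0, tolerance = 1e-9)
  expect_equal(r$water_sum, 1, tolerance = 1e-12)
})

test_that("water-side coefficients match hand-computed values for a general
           pair and are invariant under swapping the states", {
  t <- seq(0, 400, by = 0.1)
  mk <- function(ci, co, cp)
    syntheticTrajectory(p, t,
                        pi_i = ci + 1e4 * sin(2 * pi * t / 40),
                        pi_o = rep(co, length(t)),
                        P = cp + 300 * cos(2 * pi * t / 40))
  trA <- mk(1.25e6, 0.89e6, 2.10e5)
  trB <- mk(1.29e6, 0.52e6, 2.35e5)
  w <- c(80, 160)
  r <- waterRegulationCoefficients(trA, trB, windowO1 = w, windowO2 = w)
  dd <- la * ((1.25e6 - 0.89e6 - 2.10e5) - (1.29e6 - 0.52e6 - 2.35e5))
  expect_equal(r$R_pi_i_w, la * (1.25e6 - 1.29e6) / dd, tolerance = 1e-9)
  expect_equal(r$R_pi_o_w, -la * (0.89e6 - 0.52e6) / dd, tolerance = 1e-9)
  expect_equal(r$R_P_w, -la * (2.10e5 - 2.35e5) / dd, tolerance = 1e-9)
  expect_equal(r$water_sum, 1, tolerance = 1e-12)
  rs <- waterRegulationCoefficients(trB, trA, windowO1 = w, windowO2 = w)
  expect_equal(rs$R_pi_o_w, r$R_pi_o_w, tolerance = 1e-12)
  expect_equal(rs$R_P_w, r$R_P_w, tolerance = 1e-12)
})

test_that("comparing a state with itself is a degenerate comparison", {
  t <- seq(0, 300, by = 0.1)
  tr <- syntheticTrajectory(p, t,
                            pi_i = 1.25e6 + 1e4 * sin(2 * pi * t / 50),
                            pi_o = rep(0.89e6, length(t)),
                            P = rep(2.14e5, length(t)))
  w <- c(100, 200)
  expect_error(waterRegulationCoefficients(tr, tr, w, w), "degenerate")
})

test_that("wall-side coefficients match the closed-form log decomposition
           for steady states and flag P <= Pc", {
  t <- seq(0, 300, by = 0.1)
  mkc <- function(ci, cp) syntheticTrajectory(p, t,
    pi_i = rep(ci, length(t)), pi_o = rep(0.89e6, length(t)),
    P = rep(cp, length(t)))
  trA <- mkc(1.25e6, 2.14e5)
  trB <- mkc(1.20e6, 2.25e5)
  w <- c(50, 250)
  r <- wallRegulationCoefficients(trA, trB, windowO1 = w, windowO2 = w)
  gA <- la * (1.25e6 - 0.89e6 - 2.14e5)
  gB <- la * (1.20e6 - 0.89e6 - 2.25e5)
  Pc <- pv[["Pc"]]
  dd <- log(gA) - log(gB)
  # phi is implied by the chamber identity; log(v_ext phi) difference is
  # dd minus the turgor-term difference
  expect_equal(r$R_P_c, (log(2.14e5 - Pc) - log(2.25e5 - Pc)) / dd,
               tolerance = 1e-9)
  expect_equal(r$R_O_c, 0, tolerance = 1e-9)
  expect_equal(r$R_phi_c, 1 - r$R_P_c, tolerance = 1e-9)
  expect_equal(r$wall_sum, 1, tolerance = 1e-12)
  trLow <- mkc(1.05e6, 1.9e5)   # P below critical turgor
  expect_error(wallRegulationCoefficients(trA, trLow, w, w), "Pc")
})

test_that("automatic exact-period windows give the same sums", {
  t <- seq(0, 600, by = 0.1)
  mk <- function(co) syntheticTrajectory(p, t,
    pi_i = 1.25e6 + 3e4 * sin(2 * pi * t / 50),
    pi_o = rep(co, length(t)),
    P = 2.14e5 + 200 * sin(2 * pi * t / 50 - 0.4))
  r <- waterRegulationCoefficients(mk(0.89e6), mk(0.6e6))
  expect_equal(r$water_sum, 1, tolerance = 1e-12)
  expect_gt(r$R_pi_o_w, 0.9)
})

test_that("regulation report bundles both sides with audit averages", {
  t <- seq(0, 500, by = 0.1)
  mk <- function(ci, cp) syntheticTrajectory(p, t,
    pi_i = ci + 2e4 * sin(2 * pi * t / 50),
    pi_o = rep(0.89e6, length(t)),
    P = rep(cp, length(t)))
  rep_ <- regulationReport(mk(1.25e6, 2.14e5), mk(1.31e6, 2.26e5),
                           labels = c("A", "B"))
  expect_s4_class(rep_, "RegulationReport")
  expect_equal(unname(rep_@water["water_sum"]), 1, tolerance = 1e-9)
  expect_equal(unname(rep_@wall["wall_sum"]), 1, tolerance = 1e-6)
  expect_equal(nrow(rep_@averages), 2L)
})
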