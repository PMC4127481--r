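pc <- physicalConstants()

test_that("ohmic current follows g*(V - E)", {
  expect_equal(ohmicCurrent(1, -0.1, -0.1), 0)
  expect_equal(ohmicCurrent(0, 0.3, -0.2), 0)
  expect_equal(ohmicCurrent(2, -0.1, -0.15), 0.1)
})

test_that("GHK current reverses at the Nernst potential and collapses for
           equal concentrations", {
  for (z in c(1, 2, -1)) {
    ci <- 0.05; ce <- 0.002
    E <- pc$Vref / z * log(ce / ci)
    expect_equal(ghkCurrent(3, E, z, ci, ce, pc$Vref), 0, tolerance = 1e-10)
  }
  # ci = ce = c: I = g*V*c for any V
  V <- seq(-0.2, 0.2, by = 0.013)
  expect_equal(ghkCurrent(2, V, 1, 0.1, 0.1, pc$Vref), 2 * V * 0.1,
               tolerance = 1e-12)
})

test_that("GHK small-voltage limit matches the series expansion", {
  # independent oracle: evaluate the full expression just outside the
  # switch-over and compare with the analytic limit g*Vref*(ci-ce)/z
  for (z in c(1, 2, -1)) {
    lim <- 1 * pc$Vref * (0.1 - 0.003) / z
    for (V in c(-1e-9, 1e-9)) {
      full <- ghkCurrent(1, V, z, 0.1, 0.003, pc$Vref)
      expect_equal(full, lim, tolerance = 1e-6)
    }
    expect_equal(ghkCurrent(1, 1e-12, z, 0.1, 0.003, pc$Vref), lim,
                 tolerance = 1e-9)
  }
})

test_that("GHK current has the sign of the concentration driving force", {
  # outward for ci > ce*exp(-zV/Vref) at V > 0 (cation)
  expect_gt(ghkCurrent(1, 0.05, 1, 0.1, 0.001, pc$Vref), 0)
  expect_lt(ghkCurrent(1, -0.15, 2, 1e-7, 1e-3, pc$Vref), 0)
  expect_error(ghkCurrent(1, 0.1, 0, 0.1, 0.1), "valence")
  expect_error(ghkCurrent(1, 0.1, 1, -0.1, 0.1), "non-negative")
})

test_that("stretch gate rates: kOC constant, kCO exponential in turgor", {
  r0 <- stretchGateRates(0, kOC0 = 1.5, kCO0 = 0.2, ka = 1e-5)
  expect_equal(r0$kOC, 1.5)
  expect_equal(r0$kCO, 0.2)
  rflat <- stretchGateRates(c(0, 2e5, 5e5), 1.5, 0.2, ka = 0)
  expect_equal(rflat$kCO, rep(0.2, 3))
  # ratio identity kCO(P2)/kCO(P1) = exp(ka*(P2-P1))
  P1 <- 1e5; P2 <- 3.7e5; ka <- 1.3e-5
  r1 <- stretchGateRates(P1, 1, 1e-3, ka)
  r2 <- stretchGateRates(P2, 1, 1e-3, ka)
  expect_equal(r2$kCO / r1$kCO, exp(ka * (P2 - P1)), tolerance = 1e-12)
})

test_that("gate kinetics relax to kCO/(kCO + kOC) and equilibrium opening
           increases with turgor", {
  expect_equal(gateRhs(0.2 / (0.2 + 0.8), kOC = 0.8, kCO = 0.2), 0)
  expect_equal(gateRhs(0, kOC = 0, kCO = 3), 3)
  expect_error(gateRhs(1.2, 1, 1), "0, 1")
  P <- seq(0, 5e5, length.out = 40)
  r <- stretchGateRates(P, kOC0 = 1, kCO0 = 1e-3, ka = 2e-5)
  p_inf <- r$kCO / (r$kCO + r$kOC)
  expect_true(all(diff(p_inf) > 0))
})

test_that("stretch currents vanish with closed gates and at reversal, and
           scale linearly in conductance", {
  p <- fastParams(g_Ca_sa = 1000, g_K_sa = 500)
  st <- list(V = -0.12, Ca_i = 1e-6, K_i = 0.1, Cl_i = 0.01,
             Ca_o = 1e-3, H_o = 2e-6, H_i = 1e-7, K_o = 1e-3, Cl_o = 3e-3,
             p_open_Ca = 0, p_open_K = 0)
  expect_equal(unname(stretchCurrents(st, p)[c("I_sa1", "I_sa2")]), c(0, 0))
  st$p_open_Ca <- 0.7; st$p_open_K <- 0.4
  E_Ca <- p@constants$Vref / 2 * log(st$Ca_o / st$Ca_i)
  st2 <- st; st2$V <- E_Ca
  expect_equal(unname(stretchCurrents(st2, p)["I_sa1"]), 0,
               tolerance = 1e-12)
  I1 <- stretchCurrents(st, p)["I_sa1"]
  I2 <- stretchCurrents(st, setParams(p, g_Ca_sa = 2000))["I_sa1"]
  expect_equal(unname(I2 / I1), 2, tolerance = 1e-12)
})

test_that("voltage-gated currents all vanish with zero conductances and GHK
           kernels reverse at their Nernst potentials", {
  p0 <- fastParams(g_vg1 = 0, g_vg2 = 0, g_vg3 = 0, I_pump_max = 0,
                   g_vg5 = 0, g_vg6 = 0)
  st <- list(V = -0.08, Ca_i = 1e-6, H_i = 1e-7, K_i = 0.1, Cl_i = 0.01,
             Ca_o = 1e-3, H_o = 2e-6, K_o = 1e-3, Cl_o = 3e-3)
  expect_equal(unname(voltageGatedCurrents(st, p0)), rep(0, 6))
  p <- fastParams()
  Vref <- p@constants$Vref
  st$V <- Vref / 2 * log(st$Ca_o / st$Ca_i)     # Ca Nernst
  expect_equal(unname(voltageGatedCurrents(st, p)["I_vg3"]), 0,
               tolerance = 1e-12)
  st$V <- -Vref * log(st$Cl_o / st$Cl_i)        # Cl Nernst (z = -1)
  expect_equal(unname(voltageGatedCurrents(st, p)["I_vg6"]), 0,
               tolerance = 1e-12)
})

test_that("symporter stoichiometry feeds H+ twice as strongly as Cl-", {
  p <- fastParams(g_vg1 = 0, g_vg2 = 0, g_vg3 = 0, I_pump_max = 0,
                  g_vg6 = 0, g_Ca_sa = 0, g_K_sa = 0,
                  k_relax_Ca = 0, k_relax_H = 0, k_relax_K = 0,
                  k_relax_Cl = 0)
  st <- list(V = -0.15, Ca_i = 1e-6, H_i = 1e-7, K_i = 0.1, Cl_i = 0.01,
             Ca_o = 1e-3, H_o = 2e-6, K_o = 1e-3, Cl_o = 3e-3)
  cur <- c(voltageGatedCurrents(st, p),
           stretchCurrents(c(st, p_open_Ca = 0, p_open_K = 0), p))
  d <- ionRhs(list(Ca_i = st$Ca_i, H_i = st$H_i, K_i = st$K_i,
                   Cl_i = st$Cl_i),
              cur, OV = 4e5, F = p@constants$F, rel_vol_rate = 0, params = p)
  expect_gt(abs(d[["H_i"]]), 0)
  expect_equal(unname(d[["H_i"]] / d[["Cl_i"]]), 2, tolerance = 1e-12)
})

test_that("membrane potential balance is charge conservation over Cm", {
  expect_equal(membranePotentialRhs(c(0, 0, 0), 0.01), 0)
  expect_equal(membranePotentialRhs(c(0.2, -0.2), 0.01), 0)
  expect_equal(membranePotentialRhs(0.1, 0.02),
               membranePotentialRhs(0.1, 0.01) / 2)
})
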