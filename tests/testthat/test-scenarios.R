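p <- calibratedParams()

test_that("unknown scenario names list the valid options", {
  expect_error(buildScenario("nosuch", params = p), "isotonic")
})

test_that("osmotic shift scenarios encode media course and radius ramps", {
  hypo <- buildScenario("hypotonic_018", params = p)
  ext0 <- protocolAt(hypo$protocol, 7000)
  ext1 <- protocolAt(hypo$protocol, 7300)
  tot <- function(e) e$Ca_o + e$H_o + e$K_o + e$Cl_o + e$Osm_o
  expect_equal(tot(ext0), 0.36, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(tot(ext1), 0.18, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(protocolAt(hypo$protocol, 9000)$r, 5.5e-6,
               ignore_attr = TRUE)
  expect_equal(protocolAt(hypo$protocol, 8100)$drdt, 0.5e-6 / 1800,
               ignore_attr = TRUE)
  hyper <- buildScenario("hypertonic_116", params = p)
  expect_equal(tot(protocolAt(hyper$protocol, 7300)), 1.16,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(protocolAt(hyper$protocol, 9500)$r, 3.5e-6,
               ignore_attr = TRUE)
})

test_that("viscosity ramp follows the staged schedule at 0.18 Osm", {
  vr <- buildScenario("viscosity_ramp", params = p)
  at <- function(t) protocolAt(vr$protocol, t)$eta_eq
  expect_equal(at(5000), 25e6)
  expect_equal(at(7000), 75e6)     # midway 25 -> 125
  expect_equal(at(9000), 125e6)
  expect_equal(at(11000), 175e6)   # midway 125 -> 225
  expect_equal(at(13000), 225e6)
  e <- protocolAt(vr$protocol, 100)
  expect_equal(e$Ca_o + e$H_o + e$K_o + e$Cl_o + e$Osm_o, 0.18,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("raba4d scenario reduces the fusion-rate scale 100-fold at the
           mutant radius", {
  rb <- buildScenario("raba4d", params = p)
  e <- protocolAt(rb$protocol, 1000)
  expect_equal(e$fusion_scale, 0.01, ignore_attr = TRUE)
  expect_equal(e$r, 12e-6, ignore_attr = TRUE)
})

test_that("media calcium and pH shifts step to the cited levels and back", {
  ca <- buildScenario("calcium_shift", params = p)
  expect_equal(protocolAt(ca$protocol, 7000)$Ca_o, 0.13e-3,
               ignore_attr = TRUE)
  expect_equal(protocolAt(ca$protocol, 9000)$Ca_o, 1.3e-3,
               ignore_attr = TRUE)
  expect_equal(protocolAt(ca$protocol, 12000)$Ca_o, 0.13e-3,
               ignore_attr = TRUE)
  ph <- buildScenario("ph_shift", params = p)
  expect_equal(-log10(protocolAt(ph$protocol, 7000)$H_o), 5.7,
               ignore_attr = TRUE)
  expect_equal(-log10(protocolAt(ph$protocol, 9000)$H_o), 5.1,
               ignore_attr = TRUE)
})

test_that("oil injection ramps cellular osmolyte up and resets it", {
  oi <- buildScenario("oil_injection", params = p)
  base <- param(p, "Osm_i")
  expect_equal(protocolAt(oi$protocol, 7000)$Osm_i, base,
               ignore_attr = TRUE)
  expect_equal(protocolAt(oi$protocol, 8200)$Osm_i, base + 0.25,
               ignore_attr = TRUE)
  expect_equal(protocolAt(oi$protocol, 8500)$Osm_i, base,
               ignore_attr = TRUE)
})

test_that("qualitative scenario behaviours match the reported directions", {
  init <- calibratedInit()
  run <- function(name, t_end, overrides = list()) {
    sc <- buildScenario(name, params = p, t_end = t_end,
                        overrides = overrides)
    runSimulation(sc$params, sc$protocol, init = init,
                  solver = solverSettings(sample_dt = 0.5))
  }
  # raba4d: reduced fusion => slower elongation than a same-radius control
  wt <- run("isotonic", 1800, overrides = list(radius = 12e-6))
  mut <- run("raba4d", 1800)
  Lwt <- trajectoryData(wt)$L
  Lmu <- trajectoryData(mut)$L
  expect_gt(Lwt[length(Lwt)], Lmu[length(Lmu)])
  # raised media calcium keeps the tube growing and oscillating
  pCa <- setParams(p, Ca_o_ref = 1.3e-3,
                   Osm_o_ref = param(p, "Osm_o_ref") - 0.3e-3)
  scCa <- buildScenario("isotonic", params = pCa, t_end = 2000)
  hiCa <- runSimulation(scCa$params, scCa$protocol, init = init,
                        solver = solverSettings(sample_dt = 0.5))
  oHi <- oscillationOf(hiCa, "growth_um_min")
  expect_true(oHi@oscillatory)
  expect_gt(mean(trajectoryData(hiCa)$growth_um_min), 0)
})
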