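calP <- calibratedParams()
calInit <- calibratedInit()

test_that("compiled and reference right-hand sides agree at random states", {
  set.seed(42)
  sc <- buildScenario("isotonic", params = calP, t_end = 100)
  st0 <- initState(calP)
  for (k in 1:12) {
    st <- st0 * exp(runif(length(st0), -0.25, 0.25))
    st["V"] <- -0.15 + runif(1, -0.08, 0.1)
    st[c("p_Ca", "p_K", "n_K")] <- runif(3)
    names(st) <- names(st0)
    t <- runif(1, 1, 99)
    rref <- cellRhs(t, st, calP, sc$protocol)
    cc <- deSolve::DLLfunc(
      func = "ptube_derivs", times = t, y = st,
      parms = pollentube:::.packParams(calP), dllname = "pollentube",
      initfunc = "ptube_init", initforc = "ptube_forc",
      forcings = pollentube:::.protocolForcings(sc$protocol),
      nout = 23L, outnames = pollentube:::.outNames())
    expect_equal(unname(cc$dy), unname(rref[[1]]), tolerance = 1e-12)
    expect_equal(unname(cc$var), unname(rref[[2]]), tolerance = 1e-12)
  }
})

test_that("two runs with identical inputs are bitwise identical", {
  sc <- buildScenario("isotonic", params = calP, t_end = 300)
  t1 <- runSimulation(sc$params, sc$protocol, init = calInit,
                      solver = solverSettings(sample_dt = 0.5))
  t2 <- runSimulation(sc$params, sc$protocol, init = calInit,
                      solver = solverSettings(sample_dt = 0.5))
  expect_identical(trajectoryData(t1), trajectoryData(t2))
})

test_that("with frozen ions and wall, turgor converges to the closed-form
           steady state", {
  # all transporters off and no secretion; relaxation pins the ions so the
  # osmotic pressures and extensibility are effectively frozen
  p <- setParams(calP, g_vg1 = 0, g_vg2 = 0, g_vg3 = 0, I_pump_max = 0,
                 g_vg5 = 0, g_vg6 = 0, g_Ca_sa = 0, g_K_sa = 0, k2a = 0,
                 k_relax_Ca = 1e3, k_relax_H = 1e3, k_relax_K = 1e3,
                 k_relax_Cl = 1e3)
  sc <- buildScenario("isotonic", params = p, t_end = 800)
  st <- initState(p)
  st["P"] <- 1.5e5                      # start away from the fixed point
  # with secretion off the wall thins to its numerical guard; that is the
  # expected degenerate-input warning
  expect_warning(
    tr <- runSimulation(p, sc$protocol, init = st,
                        solver = solverSettings(sample_dt = 0.5)),
    "1 nm guard")
  d <- trajectoryData(tr)
  n <- nrow(d)
  P_expect <- steadyTurgor(d$pi_i[n], d$pi_o[n], d$phi[n], p)
  expect_equal(d$P[n], unname(P_expect), tolerance = 1e-6)
  expect_gt(d$P[n], d$P[1])
})

test_that("flux-balance residual vanishes along trajectories (constitutive
           identity behind the turgor equation)", {
  for (name in c("isotonic", "viscosity_ramp")) {
    sc <- buildScenario(name, params = calP, t_end = 400)
    tr <- runSimulation(sc$params, sc$protocol, init = calInit,
                        solver = solverSettings(sample_dt = 0.5))
    d <- trajectoryData(tr)
    eps <- param(calP, "eps")
    resid <- eps * (d$net_water / d$v - d$wall_yield_rate / d$v) - d$dP_dt
    expect_lt(max(abs(resid)), 1e-8 * eps)
    # Ortega identity: water and chamber volume rates coincide
    expect_lt(max(abs(d$wall_chamber_rate - d$net_water)),
              1e-8 * max(abs(d$net_water)))
  }
})

test_that("scaling OV up and conductances down leaves ion trajectories
           unchanged", {
  # pointwise comparison across the sharp voltage transitions is dominated
  # by solver phase jitter, so the invariance is checked on the dynamics:
  # oscillation period and pool statistics must agree
  gnames <- c("g_vg1", "g_vg2", "g_vg3", "I_pump_max", "g_vg5", "g_vg6",
              "g_Ca_sa", "g_K_sa")
  sc0 <- buildScenario("isotonic", params = calP, t_end = 600)
  ref <- runSimulation(sc0$params, sc0$protocol, init = calInit,
                       solver = solverSettings(sample_dt = 0.5))
  oref <- oscillationOf(ref, "K_i")
  dref <- trajectoryData(ref)
  for (cfac in c(0.5, 2, 10)) {
    repl <- as.list(param(calP, gnames) / cfac)
    names(repl) <- gnames
    # the membrane charge balance scales with its conductances, so the
    # capacitive loading is scaled identically; the concentration equations
    # then depend only on the invariant products OV * g
    p2 <- do.call(setParams, c(list(calP), repl,
                               list(ov_scale = cfac,
                                    Cm = param(calP, "Cm") / cfac)))
    sc2 <- buildScenario("isotonic", params = p2, t_end = 600)
    tr2 <- runSimulation(sc2$params, sc2$protocol, init = calInit,
                         solver = solverSettings(sample_dt = 0.5))
    o2 <- oscillationOf(tr2, "K_i")
    d2 <- trajectoryData(tr2)
    expect_equal(o2@period, oref@period, tolerance = 1e-3)
    for (col in c("Ca_i", "H_i", "K_i", "Cl_i", "V")) {
      expect_equal(mean(d2[[col]]), mean(dref[[col]]), tolerance = 1e-3)
      expect_equal(range(d2[[col]]), range(dref[[col]]), tolerance = 5e-3)
    }
  }
})

test_that("water-permeable whole surface or uniform extensibility give
           exponential volume growth", {
  # degenerate configuration 1: A_osm proportional to v
  pv <- param(calP)
  a <- pv[["A_osm"]] / 3.9e-14
  rhs1 <- function(t, y, parms) {
    w <- waterVolumeRate(y[1], 2.0e5, 1.32e6, 0.89e6, pv[["Lp"]],
                         a * y[1])
    list(w$net_water)
  }
  sol1 <- deSolve::ode(c(v = 3.9e-14), seq(0, 4e4, 100), rhs1, NULL,
                       rtol = 1e-10, atol = 1e-28)
  fit1 <- stats::lm(log(sol1[, "v"]) ~ sol1[, "time"])
  expect_gt(summary(fit1)$r.squared, 0.9999)
  expect_gt(stats::coef(fit1)[2L], 0)
  # degenerate configuration 2: extensibility uniform over the cell
  rhs2 <- function(t, y, parms)
    list(wallChamberRate(y[1], y[1], 4.5e-8, 2.14e5, 2.0e5, pv[["eps"]], 0))
  sol2 <- deSolve::ode(c(v = 3.9e-14), seq(0, 4e4, 100), rhs2, NULL,
                       rtol = 1e-10, atol = 1e-28)
  fit2 <- stats::lm(log(sol2[, "v"]) ~ sol2[, "time"])
  expect_gt(summary(fit2)$r.squared, 0.9999)
})

test_that("the isotonic limit cycle is reached from perturbed initial
           conditions with the same period", {
  sc <- buildScenario("isotonic", params = calP, t_end = 2600)
  ref <- oscillationOf(
    runSimulation(sc$params, sc$protocol, init = calInit,
                  solver = solverSettings(sample_dt = 0.5)),
    "growth_um_min")
  set.seed(7)
  st <- calInit * exp(runif(length(calInit), -0.1, 0.1))
  st["V"] <- calInit[["V"]] * 0.9
  names(st) <- names(calInit)
  pert <- oscillationOf(
    runSimulation(sc$params, sc$protocol, init = st,
                  solver = solverSettings(sample_dt = 0.5)),
    "growth_um_min")
  expect_true(ref@oscillatory && pert@oscillatory)
  expect_equal(pert@period, ref@period, tolerance = 0.01)
})

test_that("halving solver tolerances leaves the reported period essentially
           unchanged", {
  sc <- buildScenario("isotonic", params = calP, t_end = 1500)
  o1 <- oscillationOf(
    runSimulation(sc$params, sc$protocol, init = calInit,
                  solver = solverSettings(rtol = 1e-8, sample_dt = 0.25)),
    "growth_um_min")
  o2 <- oscillationOf(
    runSimulation(sc$params, sc$protocol, init = calInit,
                  solver = solverSettings(rtol = 5e-9, sample_dt = 0.25)),
    "growth_um_min")
  expect_equal(o1@period, o2@period, tolerance = 0.005)
})

test_that("integration failures surface as diagnostic errors", {
  sc <- buildScenario("isotonic", params = calP, t_end = 2000)
  sv <- solverSettings(sample_dt = 1000)
  sv$maxsteps <- 10            # starve the integrator
  expect_error(
    suppressWarnings(
      runSimulation(calP, sc$protocol, init = initState(calP),
                    solver = sv)),
    "integration failed")
})
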