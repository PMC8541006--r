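test_that("the depot-blood-tissue system is closed: mass conserved always", {
  set.seed(11)
  for (i in 1:10) {
    r <- runif(8, 0, 0.05)
    params <- kineticParams(r[1], r[2], r[3], r[4], r[5], r[6], r[7], r[8],
                            trapping = i %% 2 == 0)
    sim <- simulateTracerKinetics(params, dose = 4)
    total <- rowSums(amounts(sim)[, c("P", "B", "gut", "visceral_fat",
                                      "liver", "loss")])
    expect_lt(max(abs(total - 4)), 1e-8)
  }
})

test_that("zero dose gives identically zero curves; removed routes deliver 0", {
  sim0 <- simulateTracerKinetics(dose = 0)
  for (tc in tacs(sim0)) expect_identical(unique(tc@activities), 0)

  noPre <- kineticParams(kPG = 0, kPV = 0, kPL = 0)
  simNP <- simulateTracerKinetics(noPre, dose = 4)
  expect_equal(unname(deliveredPreSystemic(simNP, 10)["total"]), 0)
})

test_that("matrix-exponential solution matches closed form and an ODE solver", {
  params <- kineticParams()
  sim <- simulateTracerKinetics(params, dose = 4)
  an <- analyticAmounts(params, 4, sim@times)
  for (nm in names(an))
    expect_lt(max(abs(amounts(sim)[, nm] - an[[nm]])), 1e-9)

  skip_if_not_installed("deSolve")
  # independent route: stiff ODE integration of the same vector field
  r <- kineticRates(params)
  rhs <- function(t, y, p) {
    K <- sum(r[c("kPA", "kPG", "kPV", "kPL")])
    kB <- sum(r[c("kBG", "kBV", "kBL", "kLoss")])
    list(c(-K * y[1],
           r[["kPA"]] * y[1] - kB * y[2],
           r[["kPG"]] * y[1] + r[["kBG"]] * y[2],
           r[["kPV"]] * y[1] + r[["kBV"]] * y[2],
           r[["kPL"]] * y[1] + r[["kBL"]] * y[2],
           r[["kLoss"]] * y[2]))
  }
  ode <- deSolve::lsoda(c(4, 0, 0, 0, 0, 0), sim@times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(ode[, 2:7] -
                    amounts(sim)[, c("P", "B", "gut", "visceral_fat",
                                     "liver", "loss")])), 1e-6)
})

test_that("default kinetics reproduce the arrival-fraction calibration", {
  sim <- simulateTracerKinetics(kineticParams(), dose = 4)
  blood <- tacs(sim)$blood
  frac <- integrateWindow(blood, t0 = 0, t1 = 10) /
    integrateWindow(blood, t0 = 0, t1 = 60)
  expect_gt(frac, 0.03); expect_lt(frac, 0.05)
  gv <- deliveredPreSystemic(sim, 10)[["total"]] / 4
  expect_gte(gv, 0.15); expect_lte(gv, 0.20)
})

test_that("raising blood-to-VF extraction strictly raises VF post AUC", {
  aucs <- vapply(seq(5e-4, 5e-3, length.out = 6), function(kbv) {
    sim <- simulateTracerKinetics(kineticParams(kBV = kbv), dose = 4)
    integrateWindow(tacs(sim)$visceral_fat, t0 = 10, t1 = 60)
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("invalid parameters and grids are rejected", {
  expect_error(kineticParams(kPA = -0.01), "negative")
  expect_error(kineticParams(kPA = 0, kPG = 0, kPV = 0, kPL = 0),
               "peritoneal outflow")
  expect_error(simulateTracerKinetics(grid = seq(0, 30, 0.5)), "60")
  expect_error(simulateTracerKinetics(grid = seq(5, 65, 0.5)), "start at 0")
})
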