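# Basquin/SWT fatigue-life mapping: closed forms, inverses, gating.

test_that("sigma_L calibration matches the yield-point anchor", {
  # beta = 0: exponent vanishes
  expect_equal(calibrate_sigma_L(60, 20, 0), 40)
  # direct arithmetic
  expect_equal(calibrate_sigma_L(60, 20, 0.1), 10^0.3 * 40, tolerance = 1e-12)
  # Basquin curve evaluated at N = 1e3 returns the yield point exactly,
  # for a spread of valid triples
  for (tr in list(c(60, 24, 0.1), c(80, 30, 0.07), c(55, 5, 0.25))) {
    fp <- fatigue_params(tr[1], tr[2], tr[3], confirmed = TRUE)
    expect_equal(basquin_stress(1e3, fp), tr[1], tolerance = 1e-14)
    # calibration identity to machine precision
    expect_equal(fp$sigma_f + fp$sigma_L * 10^(-3 * fp$beta), fp$sigma_02,
                 tolerance = 1e-14)
  }
  expect_error(calibrate_sigma_L(20, 60, 0.1), "yield point")
})

test_that("Basquin curve and its inverse agree", {
  fp <- fatigue_params(60, 20, 0.1, confirmed = TRUE)
  expect_equal(basquin_stress(1, fp), fp$sigma_f + fp$sigma_L)
  expect_equal(basquin_stress(1e6, fp), 20 + 10^0.3 * 40 * 10^(-0.6),
               tolerance = 1e-12)
  expect_equal(basquin_stress(1e6, fp), 40.04749, tolerance = 1e-6)
  # strictly decreasing, approaching the fatigue limit
  N <- 10^seq(0, 9, by = 0.5)
  expect_true(all(diff(basquin_stress(N, fp)) < 0))
  expect_lt(basquin_stress(1e40, fp) - fp$sigma_f, 1e-2)
  # anchors of the inverse
  expect_equal(basquin_cycles(fp$sigma_02, fp), 1e3, tolerance = 1e-10)
  expect_equal(basquin_cycles(fp$sigma_f + fp$sigma_L, fp), 1)
  expect_equal(basquin_cycles(fp$sigma_f, fp), fp$n_max)
  expect_equal(basquin_cycles(0.5 * fp$sigma_f, fp), fp$n_max)
  # round trips to 6 significant digits
  for (N0 in c(10, 1e3, 1e6))
    expect_equal(basquin_cycles(basquin_stress(N0, fp), fp), N0,
                 tolerance = 1e-6)
  expect_error(basquin_stress(0.5, fp), ">= 1")
})

test_that("SWT equivalent stress implements the Macaulay bracket", {
  expect_equal(swt_equivalent(-10, 5), 0)   # compression: no crack opening
  expect_equal(swt_equivalent(0, 5), 0)
  sa <- 7.5
  expect_equal(swt_equivalent(sa, 2 * sa), sa)          # fully reversed
  expect_equal(swt_equivalent(sa, sa), sa / sqrt(2))    # pulsating 0 -> s
  expect_error(swt_equivalent(5, -1), ">= 0")
})

test_that("SWT cycle solver inverts the SWT fatigue curve", {
  fp <- fatigue_params(60, 20, 0.1, swt_sigma_u = 18, swt_beta = 0.12,
                       confirmed = TRUE)
  expect_equal(swt_cycles(fp$swt_sigma_u, fp), fp$n_max)
  expect_equal(swt_cycles(0.1, fp), fp$n_max)
  expect_equal(swt_cycles(fp$swt_sigma_u + fp$swt_sigma_V, fp), 1)
  N0 <- 1e4
  sw <- fp$swt_sigma_u + fp$swt_sigma_V * N0^(-fp$swt_beta)
  expect_equal(swt_cycles(sw, fp), N0, tolerance = 1e-6)
})

test_that("cycles convert to years by the mastication schedule", {
  expect_equal(cycles_to_years(0), 0)
  expect_equal(cycles_to_years(1.0950e6, 3, 1000), 1.0, tolerance = 1e-12)
  # linear in N at fixed schedule
  expect_equal(cycles_to_years(7e6), 7 * cycles_to_years(1e6))
})

fake_stress_field <- function(s1, vm = abs(s1)) {
  n <- length(s1)
  structure(list(nodal = data.frame(sxx = s1, syy = 0, szz = 0, sxy = 0,
                                    syz = 0, szx = 0, von_mises = vm,
                                    s1 = s1, s2 = 0, s3 = pmin(s1, 0))),
            class = "stress_field")
}

test_that("life fields classify hazard zones consistently", {
  fp <- fatigue_params(confirmed = TRUE)
  # uniform field at the yield point -> N = 1e3 everywhere, all red
  lf <- life_field(fake_stress_field(rep(fp$sigma_02, 5)), fp,
                   criterion = "basquin-mises")
  expect_equal(lf$N, rep(1e3, 5), tolerance = 1e-9)
  expect_true(all(lf$hazard == "red"))
  # uniform field below the fatigue limit -> capped, non-hazardous
  lf2 <- life_field(fake_stress_field(rep(0.5 * fp$sigma_f, 4)), fp,
                    criterion = "basquin-mises")
  expect_true(all(lf2$N == fp$n_max))
  expect_true(all(lf2$hazard == "non-hazardous"))
  # monotonicity: the more stressed node never lives longer
  lf3 <- life_field(fake_stress_field(c(50, 30)), fp,
                    criterion = "basquin-mises")
  expect_lte(lf3$N[1], lf3$N[2])
  # years consistent with the schedule
  expect_equal(lf3$years,
               lf3$N / (fp$meals_per_day * fp$chews_per_meal * 365))
})

test_that("pure compression yields the cycle cap under SWT", {
  fp <- fatigue_params(confirmed = TRUE)
  s1 <- -runif(20, 1, 100)    # all principal stresses compressive
  lf <- life_field(fake_stress_field(s1, vm = abs(s1)), fp,
                   criterion = "swt-principal")
  expect_true(all(lf$N == fp$n_max))
  expect_true(all(lf$hazard == "non-hazardous"))
})

test_that("life is monotone under stress scaling", {
  set.seed(42)
  fp <- fatigue_params(confirmed = TRUE)
  s1 <- runif(30, 5, 80)
  for (crit in c("swt-principal", "basquin-mises")) {
    base <- life_field(fake_stress_field(s1), fp, criterion = crit)
    for (alpha in c(0, 0.5, 1.3, 2.5)) {
      sc <- life_field(fake_stress_field(alpha * s1), fp, criterion = crit)
      if (alpha >= 1) expect_true(all(sc$N <= base$N)) else
        expect_true(all(sc$N >= base$N))
    }
  }
})

test_that("disjoint hazard zones are counted by mesh connectivity", {
  m <- mesh_box(c(4, 1, 1), n = c(4, 1, 1))
  fp <- fatigue_params(confirmed = TRUE)
  # two hot spots at opposite ends of the bar, cold middle
  hot <- fp$sigma_02 + 5
  s1 <- ifelse(m$nodes[, 1] < 0.5, hot,
               ifelse(m$nodes[, 1] > 3.5, hot, 1))
  lf <- life_field(fake_stress_field(s1), fp, criterion = "basquin-mises")
  expect_equal(hazard_zones(m, lf), 2L)
  # no hazardous nodes -> zero zones
  lf0 <- life_field(fake_stress_field(rep(1, nrow(m$nodes))), fp,
                    criterion = "basquin-mises")
  expect_equal(hazard_zones(m, lf0), 0L)
})
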