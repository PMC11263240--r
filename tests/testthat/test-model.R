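test_that("derivatives reproduce the disposition equations", {
  p <- male_params()
  # zero state -> zero rates
  expect_equal(pk_derivatives(rep(0, 6), p), setNames(rep(0, 6), NULL),
               ignore_attr = TRUE)
  # all drug central: dA1/dt is minus the sum of the outflow rate constants
  d <- pk_derivatives(c(100, 0, 0, 0, 0, 0), p)
  expect_equal(d[["A1"]], -(3.60 + 2.14 + 17.6 + 9.37 + 0.081) * 100)
  expect_equal(d[["A1"]], -3279.1)
  expect_equal(d[["Aelim"]], 3.60 * 100)
})

test_that("disposition rates cancel: sum of compartment rates is -kel*A1", {
  # independent term-by-term oracle coded directly from the model equations
  rates_by_hand <- function(A, p) {
    c(p$k21 * A[2] + p$k31 * A[3] + p$k41 * A[4] + p$k51 * A[5] -
        (p$kel + p$k12 + p$k13 + p$k14 + p$k15) * A[1] +
        p$kPgp * A[3] + p$kPgp * A[4],
      p$k12 * A[1] - p$k21 * A[2],
      p$k13 * A[1] + p$k53 * A[5] - (p$k31 + p$k35 + p$kPgp) * A[3],
      p$k14 * A[1] + p$k54 * A[5] - (p$k41 + p$k45 + p$kPgp) * A[4],
      p$k15 * A[1] + p$k35 * A[3] + p$k45 * A[4] -
        (p$k51 + p$k53 + p$k54) * A[5])
  }
  set.seed(11)
  for (i in 1:20) {
    p <- random_params()
    A <- c(stats::runif(5, 0, 100), 0)
    d <- pk_derivatives(A, p)
    expect_equal(unname(d[1:5]), rates_by_hand(A, p), tolerance = 1e-12)
    expect_equal(sum(d[1:5]), -p$kel * A[1], tolerance = 1e-10)
  }
})

test_that("zero dose gives identically zero concentrations", {
  prof <- simulate_profiles(male_params(), "WT", dose_event(0),
                            times = c(0.1, 0.5, 1))
  expect_true(all(prof$conc == 0))
})

test_that("one-compartment limit matches the closed form", {
  p <- pk_parameters(V1 = 17.5, kel = 3.60, k12 = 1e-12, k21 = 1,
                     k13 = 1e-12, k31 = 1, k14 = 1e-12, k41 = 1,
                     k15 = 1e-12, k51 = 1, k35 = 1e-12, k53 = 1, kPgp = 0)
  tt <- seq(0.1, 1, by = 0.1)
  for (m in c("analytic", "lsoda")) {
    prof <- simulate_profiles(p, "WT", dose_event(1750), tt, method = m)
    plasma <- prof$conc[prof$matrix == "plasma"]
    expect_equal(plasma, 1750 / 17.5 * exp(-3.60 * tt), tolerance = 1e-6)
    expect_equal(plasma[tt == 0.5], 100 * exp(-1.8), tolerance = 1e-6)
    cns <- prof$conc[prof$matrix != "plasma"]
    expect_true(all(cns < 1e-8))
  }
})

test_that("mass balance and non-negativity hold at every output time", {
  dose <- male_dose()
  tt <- seq(0.01, 2.5, by = 0.01)
  for (g in c("WT", "KO", "OT")) {
    for (m in c("analytic", "lsoda")) {
      A <- simulate_amounts(effective_params(male_params(), g), dose, tt,
                            method = m)
      expect_lt(max(abs(rowSums(A) - dose$amount)) / dose$amount, 1e-6)
      expect_true(all(A >= -1e-12))
    }
  }
  set.seed(21)
  for (i in 1:10) {
    A <- simulate_amounts(random_params(), dose_event(1000), c(0.5, 1, 3))
    expect_lt(max(abs(rowSums(A) - 1000)) / 1000, 1e-6)
    expect_true(all(A >= -1e-12))
  }
})

test_that("analytic propagator agrees with the stiff integrator", {
  set.seed(31)
  tt <- c(0.05, 0.25, 1, 2.5)
  for (i in 1:10) {
    p <- random_params()
    a <- simulate_amounts(p, dose_event(3250), tt, method = "analytic")
    l <- simulate_amounts(p, dose_event(3250), tt, method = "lsoda")
    expect_equal(unclass(a), unclass(l), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("the model is linear in dose", {
  tt <- c(0.1, 0.5, 1, 2)
  p1 <- simulate_profiles(male_params(), "WT", dose_event(1000), tt)
  p2 <- simulate_profiles(male_params(), "WT", dose_event(2000), tt)
  expect_equal(p2$conc, 2 * p1$conc, tolerance = 1e-12)
})

test_that("knockout equals wild type with the efflux term removed", {
  p <- male_params()
  p0 <- p
  p0$kPgp <- 0
  tt <- seq(0.05, 2.5, by = 0.05)
  ko <- simulate_profiles(p, "KO", male_dose(), tt)
  wt0 <- simulate_profiles(p0, "WT", male_dose(), tt)
  expect_equal(ko$conc, wt0$conc, tolerance = 1e-12)
})

test_that("CNS exposure is monotone non-increasing in the efflux rate", {
  p <- male_params()
  tt <- c(0.25, 0.5, 1, 2)
  grid <- c(0, 10, 40, 81.9, 150)
  prev <- NULL
  for (k in grid) {
    pk <- p
    pk$kPgp <- k
    prof <- simulate_profiles(pk, "WT", male_dose(), tt)
    cns <- prof$conc[prof$matrix %in% c("brain", "spinal_cord")]
    if (!is.null(prev)) expect_true(all(cns <= prev + 1e-10))
    prev <- cns
  }
})

test_that("bolus at a later dose time shifts the profile", {
  p <- male_params()
  a <- simulate_amounts(p, dose_event(3250, time = 0), c(0.5, 1))
  b <- simulate_amounts(p, dose_event(3250, time = 0.5), c(1, 1.5))
  expect_equal(unclass(a), unclass(b), tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(simulate_amounts(p, dose_event(3250, time = 2), c(1, 3)),
               ">= dose time")
  expect_error(simulate_amounts(p, dose_event(3250), c(1, 1)),
               "strictly increasing")
})
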