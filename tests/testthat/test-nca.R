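test_that("trapezoidal AUC matches hand arithmetic and closed forms", {
  expect_equal(auc_trapezoid(c(0, 1, 2), c(10, 5, 2.5)), 11.25)
  # rectangle
  expect_equal(auc_trapezoid(c(0, 3), c(7, 7)), 21)
  # dense exponential grid vs analytic integral
  tt <- seq(0, 5, by = 0.001)
  expect_equal(auc_trapezoid(tt, 10 * exp(-2 * tt)),
               10 / 2 * (1 - exp(-10)), tolerance = 1e-4)
  expect_error(auc_trapezoid(1, 5), "at least 2")
  expect_error(auc_trapezoid(c(0, 1), c(-1, 1)), ">= 0")
})

test_that("AUC is additive over subintervals and monotone in concentration", {
  set.seed(41)
  for (i in 1:10) {
    tt <- sort(stats::runif(9, 0, 4))
    cc <- stats::runif(9, 0, 20)
    expect_equal(auc_trapezoid(tt, cc),
                 auc_trapezoid(tt[1:5], cc[1:5]) +
                   auc_trapezoid(tt[5:9], cc[5:9]), tolerance = 1e-12)
    cc2 <- cc
    j <- sample(9, 1)
    cc2[j] <- cc2[j] + 1
    expect_gte(auc_trapezoid(tt, cc2), auc_trapezoid(tt, cc))
  }
})

test_that("missing (censored) points are bridged, not zeroed", {
  tt <- c(0, 1, 2)
  cc <- c(10, NA, 2.5)
  expect_equal(auc_trapezoid(tt, cc), 2 * (10 + 2.5) / 2)
})

test_that("log-linear-down AUC is exact on a declining exponential", {
  tt <- seq(0, 2, by = 0.5)
  cc <- 10 * exp(-1.5 * tt)
  expect_equal(auc_trapezoid(tt, cc, method = "linear-log"),
               10 / 1.5 * (1 - exp(-3)), tolerance = 1e-12)
  # linear trapezoid overestimates a convex decline
  expect_gt(auc_trapezoid(tt, cc), auc_trapezoid(tt, cc, method = "linear-log"))
})

test_that("terminal slope recovers exponential rates", {
  tt <- c(1, 2, 3)
  lz <- terminal_slope(tt, 10 * exp(-0.693 * tt))
  expect_equal(lz$lambda_z, 0.693, tolerance = 1e-10)
  expect_equal(lz$t_half, log(2) / 0.693, tolerance = 1e-10)
  expect_equal(lz$r2, 1, tolerance = 1e-10)

  # bi-exponential sampled in its terminal phase: slow rate within 1%
  tt <- seq(3, 6, by = 0.5)
  cc <- 10 * exp(-5 * tt) + 1 * exp(-0.5 * tt)
  lz <- terminal_slope(tt, cc, n_points = length(tt))
  expect_equal(lz$lambda_z, 0.5, tolerance = 0.01)

  expect_error(terminal_slope(c(1, 2, 3), c(5, 5, 5)), "lambda_z")
  expect_error(terminal_slope(c(1, 2), c(5, 4)), ">= 3")
})

test_that("NCA summary matches one-compartment closed forms", {
  kel <- 3.60
  tt <- seq(0, 4, by = 0.01)
  cc <- 1750 / 17.5 * exp(-kel * tt)
  res <- nca_summary(tt, cc, dose = dose_event(1750), matrix = "plasma",
                     n_lambda = 5)
  expect_equal(res$cl, 63.0, tolerance = 0.01)       # kel * V1
  expect_equal(res$vss, 17.5, tolerance = 0.01)
  expect_equal(res$mrt, 1 / kel, tolerance = 0.01)
  expect_equal(res$t_half, log(2) / kel, tolerance = 0.01)
  expect_false(res$extrap_warning)
})

test_that("NCA summary recovers Vss = V1 + V2 for a two-compartment bolus", {
  # analytic bi-exponential oracle, independent of the simulator
  V1 <- 10; k12 <- 2; k21 <- 1; kel <- 1
  s <- kel + k12 + k21
  alpha <- (s + sqrt(s^2 - 4 * kel * k21)) / 2
  beta <- (s - sqrt(s^2 - 4 * kel * k21)) / 2
  D <- 1000
  tt <- seq(0, 40, by = 0.005)
  cc <- D / V1 * ((alpha - k21) / (alpha - beta) * exp(-alpha * tt) +
                    (k21 - beta) / (alpha - beta) * exp(-beta * tt))
  res <- nca_summary(tt, cc, dose = dose_event(D), n_lambda = 10)
  expect_equal(res$vss, V1 * (1 + k12 / k21), tolerance = 0.01)
  expect_equal(res$cl, kel * V1, tolerance = 0.01)
  expect_equal(res$lambda_z, beta, tolerance = 0.001)
})

test_that("NCA rejects degenerate profiles and flags heavy extrapolation", {
  expect_error(nca_summary(1, 5), "at least 2")
  # sampling stops early: most of the AUC is extrapolated
  tt <- c(0.1, 0.2, 0.3)
  res <- nca_summary(tt, 10 * exp(-0.5 * tt), dose = dose_event(100))
  expect_true(res$extrap_warning)
  expect_gt(res$extrap_fraction, 0.2)
})

test_that("partition coefficients reproduce the published arithmetic", {
  expect_equal(partition_coefficient(22.0, 6.13)$kp, 3.59, tolerance = 0.002)
  expect_equal(partition_coefficient(15.0, 6.13, "spinal_cord")$kp, 2.45,
               tolerance = 0.002)
  expect_equal(partition_coefficient(5, 5)$kp, 1.0)
  expect_error(partition_coefficient(0, 5), "> 0")
  expect_error(partition_coefficient(5, -1), "> 0")
})

test_that("dataset-level NCA mirrors the reporting conventions", {
  p <- male_params()
  ds <- generate_dataset(p, study_design(groups = c("WT", "OT"), sexes = "M"),
                         var_p = 0, seed = 3)
  res <- nca_dataset(ds, dose_map = c(M = 3250))
  expect_setequal(unique(res$matrix), c("plasma", "brain", "spinal_cord", "CSF"))
  # CL/Vss are plasma-only concepts
  expect_true(all(is.na(res$cl[res$matrix != "plasma"])))
  expect_true(all(!is.na(res$cl[res$matrix == "plasma"])))
  # Kp only for tissues, and OT tissues show higher partition than WT
  expect_true(all(is.na(res$kp[res$matrix == "plasma"])))
  kp_wt <- res$kp[res$group == "WT" & res$matrix == "brain"]
  kp_ot <- res$kp[res$group == "OT" & res$matrix == "brain"]
  expect_gt(kp_ot, kp_wt)
})

test_that("round-trip with the simulator: NCA clearance matches direct integration", {
  p <- male_params()
  tt <- seq(0, 8, by = 0.002)
  prof <- simulate_profiles(p, "WT", dose_event(3250), tt)
  pl <- prof[prof$matrix == "plasma", ]
  res <- nca_summary(pl$time, pl$conc, dose = dose_event(3250), n_lambda = 10)
  cl_direct <- 3250 / (auc_trapezoid(pl$time, pl$conc) +
                         pl$conc[nrow(pl)] / res$lambda_z)
  expect_equal(res$cl, cl_direct, tolerance = 0.01)
})
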