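test_that("the proportional-error NLL matches hand arithmetic", {
  p <- male_params()
  dm <- c(M = 3250)
  ds <- generate_dataset(p, study_design(sexes = "M"), var_p = 0, seed = 1)
  # perfect fit: residual term vanishes, only the normalization remains
  pred <- predict_dataset(p, ds, dm)$pred
  keep <- !ds$censored
  expect_equal(objective_nll(p, 0.05, ds, dm),
               0.5 * sum(log(2 * pi * 0.05 * pred[keep]^2)),
               tolerance = 1e-10)

  # single record, hand arithmetic: obs 1.1, pred 1.0, var_P 0.05
  one <- data.frame(group = "WT", sex = "M", matrix = "plasma", time = 1,
                    mean_conc = 1.1, sd = 0, n = 1, censored = FALSE)
  p1 <- pk_parameters(V1 = 10, kel = 1, k12 = 1e-12, k21 = 1, k13 = 1e-12,
                      k31 = 1, k14 = 1e-12, k41 = 1, k15 = 1e-12, k51 = 1,
                      k35 = 1e-12, k53 = 1, kPgp = 0)
  # dose such that plasma prediction at t=1 equals 1.0 exactly
  dose_amt <- 10 / exp(-1)
  nll <- objective_nll(p1, 0.05, one, c(M = dose_amt))
  expect_equal(nll, 0.5 * (log(2 * pi * 0.05) + 0.1^2 / 0.05),
               tolerance = 1e-8)
  expect_error(objective_nll(p1, 0, one, c(M = dose_amt)), "> 0")
})

test_that("NLL decreases along a segment toward the generating values", {
  p <- male_params()
  dm <- c(M = 3250)
  ds <- generate_dataset(p, study_design(sexes = "M"), var_p = 0, seed = 2)
  est <- estimable_parameters()
  truth <- log(unlist(p[est]))
  start <- truth + log(2)
  nlls <- vapply(c(0, 0.5, 0.9, 1), function(w) {
    th <- exp((1 - w) * start + w * truth)
    names(th) <- est
    pw <- cnspk:::.update_params(p, th)
    objective_nll(pw, 0.05, ds, dm)
  }, 0)
  expect_true(all(diff(nlls) < 0))
})

test_that("NLL is exactly invariant to dataset row order", {
  p <- male_params()
  dm <- c(M = 3250)
  ds <- generate_dataset(p, study_design(sexes = "M"), var_p = 0.05, seed = 5)
  set.seed(6)
  shuffled <- ds[sample(nrow(ds)), ]
  expect_identical(objective_nll(p, 0.05, ds, dm),
                   objective_nll(p, 0.05, shuffled, dm))
})

test_that("log transform round-trips", {
  th <- c(V1 = 17.5, kel = 3.6, kPgp = 81.9, kPgp_TRQ = 0.0021)
  expect_equal(untransform(log_transform(th)), th, tolerance = 1e-12)
})

test_that("noise-free self-consistency: fit from the truth stays at the truth", {
  p <- male_params()
  dm <- c(M = 3250)
  ds <- generate_dataset(p, study_design(sexes = "M"), var_p = 0, seed = 7)
  fs <- fit_spec(ds, init = p, dose_map = dm, n_starts = 1, maxit = 200)
  fit <- fit_pooled(fs, compute_cv = FALSE)
  expect_true(fit$converged)
  truth <- unlist(p[estimable_parameters()])
  expect_true(all(abs(fit$estimates - truth) / truth < 1e-3))
})

test_that("fit specification validates estimability and coverage", {
  p <- male_params()
  ds <- generate_dataset(p, study_design(groups = "WT", sexes = "M"),
                         var_p = 0, seed = 8)
  expect_error(fit_spec(ds, init = p, estimate = c("V1", "Vbrain"),
                        dose_map = c(M = 3250)), "not estimable")
  expect_error(fit_spec(ds, init = p, estimate = c("V1", "kel_TRQ"),
                        dose_map = c(M = 3250)), "requires OT records")
  ko_only <- ds
  ko_only$group <- "KO"
  expect_error(fit_spec(ko_only, init = p, estimate = "kPgp",
                        dose_map = c(M = 3250)), "requires WT records")
  expect_error(fit_spec(ds, init = p, estimate = "V1",
                        dose_map = c(M = 3250), n_starts = 3),
               "requires a seed")
})

test_that("fixing the efflux term at zero worsens the fit to efflux-bearing data", {
  p <- male_params()
  dm <- c(M = 3250)
  ds <- generate_dataset(p, study_design(groups = "WT", sexes = "M"),
                         var_p = 0, seed = 9)
  nll_truth <- objective_nll(p, 0.05, ds, dm)
  p0 <- p
  p0$kPgp <- 0
  expect_gt(objective_nll(p0, 0.05, ds, dm), nll_truth)
})

test_that("predictions cover the design and respect the covariate structure", {
  p <- male_params()
  dm <- c(M = 3250)
  empty <- data.frame(group = character(), sex = character(),
                      matrix = character(), time = numeric())
  expect_identical(nrow(predict_dataset(p, empty, dm)), 0L)

  tt <- c(0.25, 0.5, 1, 2)
  design <- expand.grid(group = c("WT", "KO"), sex = "M",
                        matrix = c("plasma", "brain"), time = tt,
                        stringsAsFactors = FALSE)
  pred <- predict_dataset(p, design, dm)
  # knockout brain exposure dominates wild type at every design time
  ko <- pred$pred[pred$group == "KO" & pred$matrix == "brain"]
  wt <- pred$pred[pred$group == "WT" & pred$matrix == "brain"]
  expect_true(all(ko >= wt))

  # OT plasma predictions use the tariquidar covariate parameters
  ot <- predict_dataset(p, data.frame(group = "OT", sex = "M",
                                      matrix = "plasma", time = tt), dm)
  pe <- p
  pe$V1 <- p$V1_TRQ
  pe$kel <- p$kel_TRQ
  pe$kPgp <- p$kPgp_TRQ
  manual <- simulate_profiles(pe, NULL, dose_event(3250), tt)
  expect_equal(ot$pred, manual$conc[manual$matrix == "plasma"],
               tolerance = 1e-10)
})

test_that("Hessian CV% agrees with a parametric bootstrap within a factor of 2", {
  p <- male_params()
  dm <- c(M = 3250)
  est6 <- c("V1", "V1_TRQ", "kel", "kel_TRQ", "k12", "k21")
  design <- study_design(groups = c("WT", "OT"), sexes = "M")
  ds <- generate_dataset(p, design, var_p = 0.05, seed = 42)
  ds <- ds[ds$matrix == "plasma", ]
  fs <- fit_spec(ds, init = p, estimate = est6, dose_map = dm,
                 n_starts = 1, maxit = 300)
  fit <- fit_pooled(fs, compute_cv = TRUE)
  expect_true(all(is.finite(fit$cv_percent[est6])))

  # parametric bootstrap: one draw per design point at the fitted
  # mean-profile variance reproduces the fitted observation noise
  bdesign <- study_design(groups = c("WT", "OT"), sexes = "M",
                          n_terminal = 1, n_sequential = 1)
  boot <- vapply(seq_len(200), function(i) {
    dsb <- generate_dataset(fit$params, bdesign, var_p = fit$var_p,
                            seed = 5000 + i)
    dsb <- dsb[dsb$matrix == "plasma", ]
    fsb <- fit_spec(dsb, init = fit$params, estimate = est6, dose_map = dm,
                    n_starts = 1, maxit = 300, stages = "lm")
    fit_pooled(fsb, compute_cv = FALSE)$estimates[est6]
  }, setNames(numeric(6), est6))
  cv_boot <- 100 * apply(log(boot), 1, stats::sd)
  ratio <- fit$cv_percent[est6] / cv_boot
  expect_true(all(ratio > 0.5 & ratio < 2))
})
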