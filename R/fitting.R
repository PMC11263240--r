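#' Estimable parameter names
#'
#' The structural parameters the pooled fitter can estimate. Under the tied
#' parameterization, \code{k35} carries \code{k45} and \code{k53} carries
#' \code{k54}. The physiological volumes are never estimable.
#'
#' @return character vector of parameter names
#' @export
estimable_parameters <- function() {
  c("V1", "V1_TRQ", "kel", "kel_TRQ", "k12", "k21", "k13", "k31",
    "k14", "k41", "k15", "k51", "k35", "k53", "kPgp", "kPgp_TRQ")
}

# write a named vector of estimated values into a parameter object,
# propagating the tie constraints
.update_params <- function(base, theta) {
  for (nm in names(theta)) base[[nm]] <- unname(theta[nm])
  if (isTRUE(attr(base, "tie_csf_exchange"))) {
    base$k45 <- base$k35
    base$k54 <- base$k53
  }
  base
}

# split a dataset into per-(group, sex) prediction designs so one simulation
# per group serves all matrices
.fit_design <- function(dataset) {
  dataset <- validate_dataset(dataset)
  dataset <- dataset[!dataset$censored & !is.na(dataset$mean_conc), ]
  if (nrow(dataset) == 0) stop("no uncensored observations to fit", call. = FALSE)
  cells <- unique(dataset[, c("group", "sex")])
  lapply(seq_len(nrow(cells)), function(i) {
    d <- dataset[dataset$group == cells$group[i] & dataset$sex == cells$sex[i], ]
    times <- sort(unique(d$time))
    col_of <- c(plasma = 1L, brain = 3L, spinal_cord = 4L, CSF = 5L)
    list(group = cells$group[i], sex = cells$sex[i],
         times = times,
         row = match(d$time, times),
         col = col_of[d$matrix],
         obs = d$mean_conc)
  })
}

.predict_cells <- function(params, cells, dose_map, method) {
  unlist(lapply(cells, function(cell) {
    pe <- effective_params(params, cell$group)
    dose <- dose_event(dose_map[[cell$sex]])
    A <- simulate_amounts(pe, dose, cell$times, method = method)
    vol <- c(pe$V1, NA, pe$Vbrain, pe$Vspinal, pe$VCSF)
    A[cbind(cell$row, cell$col)] / vol[cell$col]
  }), use.names = FALSE)
}

# fitting-time prediction: a parameter vector the solver cannot handle maps
# to floor predictions (huge residuals) instead of an error, so optimizers
# can step back from pathological regions
.predict_cells_safe <- function(params, cells, dose_map, method, n_obs) {
  pred <- tryCatch(.predict_cells(params, cells, dose_map, method),
                   error = function(e) NULL)
  if (is.null(pred) || any(!is.finite(pred))) return(rep(1e-12, n_obs))
  pmax(pred, 1e-12)
}

#' Proportional-error negative log-likelihood
#'
#' The pooled objective: with predictions f from the group-effective model at
#' every uncensored record, NLL = 1/2 * sum over records of
#' ln(2*pi*var_P*f^2) + (obs - f)^2 / (var_P * f^2). One shared var_P covers
#' all matrices and groups of a sex, matching the single reported residual
#' variance. Non-positive predictions at an observation time are floored at a
#' machine-small positive value.
#'
#' @param params shared \code{pk_parameters}
#' @param var_p proportional-error variance (> 0)
#' @param dataset a concentration dataset; censored rows are excluded
#' @param dose_map named numeric of dose amounts (ug) by sex
#' @param method simulation backend
#' @return the negative log-likelihood (scalar)
#' @export
objective_nll <- function(params, var_p, dataset, dose_map,
                          method = "analytic") {
  if (var_p <= 0) stop("var_p must be > 0", call. = FALSE)
  cells <- .fit_design(dataset)
  obs <- unlist(lapply(cells, `[[`, "obs"), use.names = FALSE)
  pred <- pmax(.predict_cells(params, cells, dose_map, method), 1e-12)
  0.5 * sum(log(2 * pi * var_p * pred^2) + (obs - pred)^2 / (var_p * pred^2))
}

#' Fit specification
#'
#' Bundles everything \code{\link{fit_pooled}} needs: the dataset, which
#' parameters to estimate, initial values, dosing, and optimizer settings.
#'
#' @param dataset a concentration dataset covering the groups whose
#'   covariate parameters are estimated
#' @param init a \code{pk_parameters} object supplying initial values for the
#'   estimated parameters and fixed values for the rest
#' @param estimate names of parameters to estimate (subset of
#'   \code{\link{estimable_parameters}})
#' @param dose_map named numeric of dose amounts (ug) by sex
#' @param n_starts number of optimizer starts (first start = \code{init},
#'   the rest log-normally jittered)
#' @param start_jitter log-scale SD of the multi-start jitter
#' @param seed seed for the multi-start jitter (mandatory when
#'   \code{n_starts > 1})
#' @param maxit iteration cap per optimizer stage
#' @param method simulation backend
#' @param kpgp_trq_floor lower bound (1/h) guarding the weakly identified
#'   residual efflux term
#' @param stages optimizer stages to run, in order: "lm"
#'   (Levenberg-Marquardt on the proportional residuals), "bfgs" and "nm"
#'   (refinement of the profiled NLL); the default runs all three
#' @param lower,upper named numeric overrides of the plausibility box
#'   constraints (defaults: rate constants in [1e-6, 1e4] 1/h, volumes in
#'   [0.1, 1e4] mL); estimates are clamped to the box, and parameters ending
#'   on a limit are flagged
#' @return an object of class \code{fit_spec}
#' @export
fit_spec <- function(dataset, init, estimate = estimable_parameters(),
                     dose_map, n_starts = 5, start_jitter = 0.4, seed = NULL,
                     maxit = 500, method = "analytic",
                     kpgp_trq_floor = 1e-6, stages = c("lm", "bfgs", "nm"),
                     lower = NULL, upper = NULL) {
  stages <- match.arg(stages, c("lm", "bfgs", "nm"), several.ok = TRUE)
  vols <- c("V1", "V1_TRQ")
  lo <- ifelse(estimate %in% vols, 0.1, 1e-6)
  hi <- rep(1e4, length(estimate))
  names(lo) <- names(hi) <- estimate
  if ("kPgp_TRQ" %in% estimate) lo["kPgp_TRQ"] <- kpgp_trq_floor
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  bad <- setdiff(estimate, estimable_parameters())
  if (length(bad) > 0)
    stop("not estimable: ", paste(bad, collapse = ", "),
         " (volumes are fixed by design)", call. = FALSE)
  validate_pk_parameters(init)
  groups <- unique(validate_dataset(dataset)$group)
  need_ot <- c("V1_TRQ", "kel_TRQ", "kPgp_TRQ")
  if (any(need_ot %in% estimate) && !"OT" %in% groups)
    stop("estimating ", paste(intersect(need_ot, estimate), collapse = ", "),
         " requires OT records in the dataset", call. = FALSE)
  if ("kPgp" %in% estimate && !"WT" %in% groups)
    stop("estimating kPgp requires WT records in the dataset", call. = FALSE)
  if (n_starts > 1 && is.null(seed))
    stop("multi-start fitting requires a seed", call. = FALSE)
  structure(list(dataset = dataset, init = init, estimate = estimate,
                 dose_map = dose_map, n_starts = n_starts,
                 start_jitter = start_jitter, seed = seed, maxit = maxit,
                 method = method, kpgp_trq_floor = kpgp_trq_floor,
                 stages = stages, lower = lo, upper = hi),
            class = "fit_spec")
}

#' Naive-pooled maximum-likelihood fit
#'
#' Simultaneously fits the shared parameter vector to mean concentration
#' profiles of all groups and matrices in the dataset (one sex at a time) by
#' minimizing the proportional-error negative log-likelihood over
#' log-transformed parameters. The residual variance var_P is profiled out
#' analytically (its conditional MLE is the mean squared proportional
#' residual), a gradient-based stage (BFGS) is followed by a Nelder-Mead
#' refinement, and multiple seeded starts guard against local minima. CV\%
#' per estimate comes from the inverse observed-information matrix on the log
#' scale (delta method: CV\% = 100 * log-scale SE).
#'
#' @param spec a \code{\link{fit_spec}}
#' @param compute_cv compute the Hessian-based CV\% (skip for speed in
#'   simulation studies)
#' @return an object of class \code{fit_result}: a list with
#'   \code{params} (fitted \code{pk_parameters}), \code{estimates} (named
#'   vector), \code{var_p}, \code{cv_percent}, \code{nll}, \code{converged},
#'   \code{at_bound}, \code{n_obs}, \code{starts} (per-start objective
#'   values) and \code{residuals} (observed vs predicted table)
#' @export
fit_pooled <- function(spec, compute_cv = TRUE) {
  stopifnot(inherits(spec, "fit_spec"))
  cells <- .fit_design(spec$dataset)
  obs <- unlist(lapply(cells, `[[`, "obs"), use.names = FALSE)
  n_obs <- length(obs)
  est <- spec$estimate
  floor_trq <- spec$kpgp_trq_floor

  lo <- spec$lower[est]
  hi <- spec$upper[est]
  lo_l <- log(lo)
  hi_l <- log(hi)
  pen_w <- 1e4  # smooth log-scale barrier outside the plausibility box
  theta_of <- function(lp) {
    th <- exp(pmin(pmax(lp, -45), 45))
    names(th) <- est
    th
  }
  resid_terms <- function(lp) {
    p <- .update_params(spec$init, theta_of(lp))
    pred <- .predict_cells_safe(p, cells, spec$dose_map, spec$method, n_obs)
    list(pred = pred, R = sum((obs - pred)^2 / pred^2))
  }
  pen2 <- function(lp) sum(pmax(lp - hi_l, 0)^2 + pmax(lo_l - lp, 0)^2)
  # var_P profiled out: conditional MLE is R / n
  profiled_nll <- function(lp) {
    rt <- resid_terms(lp)
    R <- max(rt$R, 1e-300)
    n_obs / 2 * log(2 * pi * R / n_obs) + sum(log(rt$pred)) + n_obs / 2 +
      pen_w * pen2(lp)
  }

  init_lp <- log(unlist(spec$init[est]))
  if ("kPgp_TRQ" %in% est)
    init_lp["kPgp_TRQ"] <- log(max(spec$init$kPgp_TRQ, floor_trq))
  starts <- list(init_lp)
  if (spec$n_starts > 1) {
    set.seed(as.integer(spec$seed))
    for (i in seq_len(spec$n_starts - 1))
      starts[[i + 1]] <- init_lp +
        stats::rnorm(length(init_lp), 0, spec$start_jitter)
  }

  # proportional residual vector; its sum of squares dominates the profiled
  # NLL, so Levenberg-Marquardt on it is the gradient-based stage
  prop_resid <- function(lp) {
    p <- .update_params(spec$init, theta_of(lp))
    pred <- .predict_cells_safe(p, cells, spec$dose_map, spec$method, n_obs)
    c((obs - pred) / pred,
      sqrt(pen_w) * c(pmax(lp - hi_l, 0), pmax(lo_l - lp, 0)))
  }
  stages <- if (is.null(spec$stages)) c("lm", "bfgs", "nm") else spec$stages
  best <- NULL
  start_vals <- numeric(length(starts))
  for (i in seq_along(starts)) {
    lp <- starts[[i]]
    cand <- list(par = lp, value = profiled_nll(lp), convergence = 1)
    ok <- FALSE
    if ("lm" %in% stages) {
      lm <- tryCatch(
        minpack.lm::nls.lm(lp, fn = prop_resid,
                           control = minpack.lm::nls.lm.control(
                             maxiter = min(spec$maxit, 1024), ftol = 1e-14,
                             ptol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(lm)) {
        lp <- lm$par
        ok <- ok || lm$info %in% 1:4
        v <- profiled_nll(lp)
        if (v < cand$value) cand <- list(par = lp, value = v)
      }
    }
    if ("bfgs" %in% stages) {
      o1 <- stats::optim(lp, profiled_nll, method = "BFGS",
                         control = list(maxit = spec$maxit, reltol = 1e-12))
      ok <- ok || o1$convergence == 0
      if (o1$value < cand$value) cand <- list(par = o1$par, value = o1$value)
      lp <- o1$par
    }
    if ("nm" %in% stages) {
      o2 <- stats::optim(lp, profiled_nll, method = "Nelder-Mead",
                         control = list(maxit = spec$maxit, reltol = 1e-12))
      ok <- ok || o2$convergence == 0
      if (o2$value < cand$value) cand <- list(par = o2$par, value = o2$value)
    }
    cand$converged <- ok
    start_vals[i] <- cand$value
    if (is.null(best) || cand$value < best$value) best <- cand
  }

  theta <- pmin(pmax(theta_of(best$par), lo), hi)
  params <- .update_params(spec$init, theta)
  rt <- resid_terms(log(theta))
  var_p <- max(rt$R / n_obs, 1e-300)
  nll <- objective_nll(params, var_p, spec$dataset, spec$dose_map,
                       method = spec$method)
  at_limit <- theta <= lo * (1 + 1e-6) | theta >= hi * (1 - 1e-6)
  at_bound <- "kPgp_TRQ" %in% est && isTRUE(unname(at_limit["kPgp_TRQ"]))

  cv <- rep(NA_real_, length(est) + 1)
  names(cv) <- c(est, "var_P")
  if (compute_cv) {
    full_nll <- function(lpv) {
      lp <- lpv[seq_along(est)]
      vp <- exp(lpv[length(lpv)])
      rt <- resid_terms(lp)
      0.5 * sum(log(2 * pi * vp * rt$pred^2)) + rt$R / (2 * vp)
    }
    H <- tryCatch(pracma::hessian(full_nll, c(best$par, log(var_p))),
                  error = function(e) NULL)
    if (!is.null(H)) {
      Sigma <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Sigma)) {
        dg <- diag(Sigma)
        cv[dg > 0] <- 100 * sqrt(dg[dg > 0])
      }
    }
    if (at_bound) cv["kPgp_TRQ"] <- NA_real_  # unreliable at the bound
  }

  resid_tab <- data.frame(obs = obs, pred = rt$pred,
                          prop_resid = (obs - rt$pred) / rt$pred)
  structure(list(params = params, estimates = theta, var_p = var_p,
                 cv_percent = cv, nll = nll, converged = best$converged,
                 at_bound = at_bound, at_limit = at_limit, n_obs = n_obs,
                 starts = start_vals, residuals = resid_tab),
            class = "fit_result")
}

#' Model predictions over a dataset design
#'
#' Returns one predicted concentration per design record (group, sex, matrix,
#' time), using the group-effective parameters.
#'
#' @param params shared \code{pk_parameters}
#' @param design a data.frame with columns group, sex, matrix, time (extra
#'   columns are preserved)
#' @param dose_map named numeric of dose amounts (ug) by sex
#' @param method simulation backend
#' @return \code{design} with a \code{pred} column appended
#' @export
predict_dataset <- function(params, design, dose_map, method = "analytic") {
  need <- c("group", "sex", "matrix", "time")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols) > 0)
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  design <- as.data.frame(design)
  design$pred <- numeric(nrow(design))
  if (nrow(design) == 0) return(design)
  cells <- unique(design[, c("group", "sex")])
  for (i in seq_len(nrow(cells))) {
    sel <- design$group == cells$group[i] & design$sex == cells$sex[i]
    d <- design[sel, ]
    pe <- effective_params(params, cells$group[i])
    dose <- dose_event(dose_map[[cells$sex[i]]])
    times <- sort(unique(d$time))
    A <- simulate_amounts(pe, dose, times, method = method)
    vol <- c(pe$V1, NA, pe$Vbrain, pe$Vspinal, pe$VCSF)
    col_of <- c(plasma = 1L, brain = 3L, spinal_cord = 4L, CSF = 5L)
    cl <- col_of[d$matrix]
    design$pred[sel] <- A[cbind(match(d$time, times), cl)] / vol[cl]
  }
  design
}

#' Log-parameter transform
#'
#' Bijective transform used by the fitter.
#'
#' @param theta named positive parameter vector
#' @return log-transformed vector
#' @export
log_transform <- function(theta) log(theta)

#' @rdname log_transform
#' @param ltheta log-scale vector
#' @export
untransform <- function(ltheta) exp(ltheta)
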