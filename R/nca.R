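#' Trapezoidal area under the curve
#'
#' Linear trapezoidal AUC from the first to the last sampling time. The
#' log-linear-down variant uses the log-trapezoid on intervals where the
#' concentration declines (both endpoints positive) and the linear trapezoid
#' elsewhere. Missing concentrations (NA, e.g. censored records) are skipped:
#' the trapezoid spans bridge them.
#'
#' @param times sampling times (h), strictly increasing
#' @param conc concentrations (ug/mL), non-negative; NA allowed
#' @param method "linear" (default) or "linear-log" (log-linear down)
#' @return AUC in h*ug/mL
#' @export
auc_trapezoid <- function(times, conc, method = c("linear", "linear-log")) {
  method <- match.arg(method)
  keep <- !is.na(conc)
  times <- as.numeric(times)[keep]
  conc <- as.numeric(conc)[keep]
  if (length(times) < 2L)
    stop("AUC requires at least 2 non-missing points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  dt <- diff(times)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  seg <- dt * (c1 + c2) / 2
  if (method == "linear-log") {
    dn <- c2 < c1 & c2 > 0 & c1 > 0
    seg[dn] <- dt[dn] * (c1[dn] - c2[dn]) / log(c1[dn] / c2[dn])
  }
  sum(seg)
}

# trapezoid of t*C(t), for AUMC
.aumc_trapezoid <- function(times, conc) {
  keep <- !is.na(conc)
  auc_trapezoid(times[keep], times[keep] * conc[keep])
}

#' Terminal elimination rate constant
#'
#' Least-squares regression of log concentration on time over the last
#' \code{n_points} positive, non-missing observations. With
#' \code{auto = TRUE} the number of terminal points (3 up to all points after
#' Cmax) is chosen by best adjusted fit (highest r-squared).
#'
#' @param times sampling times (h)
#' @param conc concentrations (ug/mL)
#' @param n_points number of terminal points for the regression (default 3)
#' @param auto select n_points automatically by best r-squared
#' @return a list with \code{lambda_z} (1/h), \code{t_half} (h), \code{r2}
#'   and \code{n_points}
#' @export
terminal_slope <- function(times, conc, n_points = 3, auto = FALSE) {
  ok <- !is.na(conc) & conc > 0
  times <- as.numeric(times)[ok]
  conc <- as.numeric(conc)[ok]
  fit_n <- function(n) {
    if (n < 3 || n > length(times)) return(NULL)
    idx <- seq.int(length(times) - n + 1L, length(times))
    f <- stats::lm.fit(cbind(1, times[idx]), log(conc[idx]))
    slope <- f$coefficients[2]
    ss_res <- sum(f$residuals^2)
    y <- log(conc[idx])
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
    list(lambda_z = -unname(slope), r2 = r2, n_points = n)
  }
  res <- if (auto) {
    cands <- Filter(Negate(is.null), lapply(3:length(times), fit_n))
    cands <- Filter(function(x) is.finite(x$r2) && x$lambda_z > 0, cands)
    if (length(cands) == 0) NULL else cands[[which.max(vapply(cands, `[[`, 0, "r2"))]]
  } else fit_n(n_points)
  if (is.null(res))
    stop("terminal slope requires >= 3 positive concentrations", call. = FALSE)
  if (!is.finite(res$lambda_z) || res$lambda_z <= 1e-12 ||
      !is.finite(res$r2))
    stop("terminal phase is not declining (lambda_z <= 0); cannot estimate ",
         "half-life", call. = FALSE)
  res$t_half <- log(2) / res$lambda_z
  res[c("lambda_z", "t_half", "r2", "n_points")]
}

#' Noncompartmental summary of one profile
#'
#' Computes the standard IV-bolus exposure metrics from a mean
#' concentration-time profile: AUC to the last sample and extrapolated to
#' infinity (observed last concentration / lambda_z), AUMC to infinity, the
#' terminal slope and half-life, mean residence time, and - when a dose is
#' supplied and the profile is plasma - clearance and steady-state volume of
#' distribution. Tissue profiles report exposure and half-life only.
#'
#' @param times,conc the profile; NA concentrations (censored) are skipped in
#'   the AUC and excluded from the terminal regression
#' @param dose a \code{dose_event}, required for CL and Vss
#' @param matrix profile matrix ("plasma", "brain", "spinal_cord", "CSF")
#' @param n_lambda terminal points for \code{\link{terminal_slope}}
#' @param auto_lambda choose terminal points by best r-squared
#' @param auc_method passed to \code{\link{auc_trapezoid}}
#' @return a one-row data.frame (class \code{nca_result}) with columns
#'   matrix, auc_last, auc_inf, aumc_inf, lambda_z, t_half, mrt, cl, vss,
#'   n_lambda_points, lambda_r2, extrap_fraction, extrap_warning
#' @export
nca_summary <- function(times, conc, dose = NULL, matrix = "plasma",
                        n_lambda = 3, auto_lambda = FALSE,
                        auc_method = "linear") {
  keep <- !is.na(conc)
  if (sum(keep) < 2L)
    stop("NCA requires at least 2 non-missing observations", call. = FALSE)
  lz <- terminal_slope(times, conc, n_points = n_lambda, auto = auto_lambda)
  auc_last <- auc_trapezoid(times, conc, method = auc_method)
  aumc_last <- .aumc_trapezoid(times, conc)
  t_obs <- times[keep]; c_obs <- conc[keep]
  c_last <- c_obs[length(c_obs)]
  t_last <- t_obs[length(t_obs)]
  auc_inf <- auc_last + c_last / lz$lambda_z
  aumc_inf <- aumc_last + c_last * t_last / lz$lambda_z +
    c_last / lz$lambda_z^2
  mrt <- aumc_inf / auc_inf
  extrap <- (auc_inf - auc_last) / auc_inf
  is_plasma <- identical(matrix, "plasma")
  cl <- vss <- NA_real_
  if (is_plasma && !is.null(dose)) {
    cl <- dose$amount / auc_inf
    vss <- cl * mrt
  }
  out <- data.frame(
    matrix = matrix, auc_last = auc_last, auc_inf = auc_inf,
    aumc_inf = aumc_inf, lambda_z = lz$lambda_z, t_half = lz$t_half,
    mrt = mrt, cl = cl, vss = vss,
    n_lambda_points = lz$n_points, lambda_r2 = lz$r2,
    extrap_fraction = extrap, extrap_warning = extrap > 0.2,
    stringsAsFactors = FALSE)
  class(out) <- c("nca_result", class(out))
  out
}

#' Tissue-to-plasma partition coefficient
#'
#' Kp = AUC_tissue / AUC_plasma, the exposure ratio used to quantify CNS
#' penetration.
#'
#' @param auc_tissue,auc_plasma exposures (h*ug/mL), both > 0
#' @param tissue tissue label
#' @return a one-row data.frame with columns tissue and kp
#' @export
partition_coefficient <- function(auc_tissue, auc_plasma, tissue = "brain") {
  if (!is.finite(auc_tissue) || auc_tissue <= 0)
    stop("auc_tissue must be > 0", call. = FALSE)
  if (!is.finite(auc_plasma) || auc_plasma <= 0)
    stop("auc_plasma must be > 0", call. = FALSE)
  data.frame(tissue = tissue, kp = auc_tissue / auc_plasma,
             stringsAsFactors = FALSE)
}

#' NCA over a concentration dataset
#'
#' Runs \code{\link{nca_summary}} per (group, sex, matrix) cell of a
#' long-format dataset of mean concentrations, then appends tissue partition
#' coefficients against the matching plasma exposure. Censored records enter
#' as missing (skipped in AUC spans, excluded from the terminal regression).
#'
#' @param dataset a concentration dataset (see \code{\link{read_dataset}})
#' @param dose_map named numeric of dose amounts (ug) by sex, e.g.
#'   \code{c(M = 3250, F = 2650)}; NULL suppresses CL/Vss
#' @param ... passed to \code{\link{nca_summary}}
#' @return a data.frame with one row per group/sex/matrix plus a \code{kp}
#'   column (NA for plasma)
#' @export
nca_dataset <- function(dataset, dose_map = NULL, ...) {
  dataset <- validate_dataset(dataset)
  cells <- unique(dataset[, c("group", "sex", "matrix")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    d <- dataset[dataset$group == cell$group & dataset$sex == cell$sex &
                   dataset$matrix == cell$matrix, ]
    d <- d[order(d$time), ]
    conc <- ifelse(d$censored, NA_real_, d$mean_conc)
    dose <- if (!is.null(dose_map) && cell$sex %in% names(dose_map))
      dose_event(dose_map[[cell$sex]]) else NULL
    res <- nca_summary(d$time, conc, dose = dose, matrix = cell$matrix, ...)
    cbind(group = cell$group, sex = cell$sex, res)
  })
  out <- do.call(rbind, rows)
  out$kp <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (out$matrix[i] == "plasma") next
    j <- which(out$group == out$group[i] & out$sex == out$sex[i] &
                 out$matrix == "plasma")
    if (length(j) == 1L)
      out$kp[i] <- out$auc_inf[i] / out$auc_inf[j]
  }
  rownames(out) <- NULL
  out
}
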