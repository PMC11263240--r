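#' Pgp-inhibition scan specification
#'
#' Defines a forward-simulation experiment varying the extent of Pgp
#' inhibition: the wild-type efflux rate constant is scaled to
#' (1 - f) * kPgp for each inhibition fraction f, all other parameters held
#' fixed. The systemic set chooses whether the central volume and elimination
#' constant are the ondansetron-alone (WT) or the tariquidar-co-dosed (OT)
#' values; the ratio at a given fraction is always taken against the f = 0
#' baseline of the same systemic set, so systemic covariate effects cancel.
#'
#' @param params shared \code{pk_parameters}
#' @param systemic "WT" (default, the context of the reported fold changes)
#'   or "OT"
#' @param fractions inhibition fractions in [0, 1]; the baseline f = 0 is
#'   always included
#' @param times simulation grid (h)
#' @param dose a \code{dose_event}
#' @param method simulation backend
#' @return an object of class \code{scan_spec}
#' @export
scan_spec <- function(params, systemic = c("WT", "OT"),
                      fractions = c(0, 0.5, 0.9, 1),
                      times = seq(0, 2.5, by = 0.01),
                      dose = dose_from_weight(10, default_body_weight("M")),
                      method = "analytic") {
  systemic <- match.arg(systemic)
  validate_pk_parameters(params)
  fractions <- as.numeric(fractions)
  if (length(fractions) == 0) stop("fractions must be non-empty", call. = FALSE)
  if (any(fractions < 0 | fractions > 1))
    stop("inhibition fractions must lie in [0, 1]", call. = FALSE)
  fractions <- sort(unique(c(0, fractions)))
  structure(list(params = params, systemic = systemic, fractions = fractions,
                 times = as.numeric(times), dose = dose, method = method),
            class = "scan_spec")
}

# effective parameters for one scan point: WT or OT systemic set, efflux
# scaled to (1 - f) of the wild-type value
.scan_params <- function(spec, fraction) {
  p <- spec$params
  if (spec$systemic == "OT") {
    p$V1 <- p$V1_TRQ
    p$kel <- p$kel_TRQ
  }
  p$kPgp <- (1 - fraction) * spec$params$kPgp
  p
}

#' Run an inhibition scan
#'
#' One full simulation per inhibition fraction, on the specification's time grid.
#'
#' @param spec a \code{\link{scan_spec}}
#' @return a tidy data.frame with columns fraction, matrix, time, conc and
#'   ratio (concentration relative to the f = 0 baseline at the same time;
#'   NA where the baseline is below the numeric floor)
#' @export
inhibition_scan <- function(spec) {
  stopifnot(inherits(spec, "scan_spec"))
  times <- spec$times
  runs <- lapply(spec$fractions, function(f) {
    prof <- simulate_profiles(.scan_params(spec, f), group = NULL,
                              dose = spec$dose, times = times,
                              method = spec$method)
    prof$fraction <- f
    prof
  })
  base <- runs[[1]]
  out <- do.call(rbind, runs)
  base_conc <- base$conc[match(paste(out$matrix, out$time),
                               paste(base$matrix, base$time))]
  out$ratio <- ifelse(base_conc > 1e-300, out$conc / base_conc, NA_real_)
  out[, c("fraction", "matrix", "time", "conc", "ratio")]
}

#' Fold change in CNS exposure under partial Pgp inhibition
#'
#' The concentration ratio in a tissue at one time point between a simulation
#' with kPgp reduced to (1 - fraction) of its wild-type value and the
#' unreduced baseline.
#'
#' @param spec a \code{\link{scan_spec}}
#' @param tissue "brain", "spinal_cord" or "CSF"
#' @param time time point (h)
#' @param fraction inhibition fraction in [0, 1]
#' @return a one-row data.frame with columns tissue, time, fraction, ratio
#' @export
fold_change <- function(spec, tissue, time, fraction) {
  stopifnot(inherits(spec, "scan_spec"))
  tissue <- match.arg(tissue, c("brain", "spinal_cord", "CSF"))
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  conc_at <- function(f) {
    prof <- simulate_profiles(.scan_params(spec, f), group = NULL,
                              dose = spec$dose, times = time,
                              method = spec$method)
    prof$conc[prof$matrix == tissue]
  }
  base <- conc_at(0)
  if (base <= 1e-300)
    stop("baseline concentration below the numeric floor at t = ", time,
         call. = FALSE)
  data.frame(tissue = tissue, time = time, fraction = fraction,
             ratio = conc_at(fraction) / base, stringsAsFactors = FALSE)
}
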