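#' Model parameter vector
#'
#' Constructs the full parameter set of the semi-physiological model of
#' ondansetron disposition: a central and a peripheral systemic compartment
#' plus brain, spinal cord and CSF, with first-order passive exchange and a
#' first-order P-glycoprotein (Pgp) efflux term acting from brain and spinal
#' cord back to the central compartment. Tariquidar co-administration (the
#' "OT" condition) is a categorical covariate carried by three dedicated
#' fields (\code{V1_TRQ}, \code{kel_TRQ}, \code{kPgp_TRQ}); see
#' \code{\link{effective_params}}.
#'
#' Units are fixed package-wide: amounts in ug, volumes in mL, time in h,
#' concentrations in ug/mL.
#'
#' @param V1 central volume of distribution (mL)
#' @param kel first-order systemic elimination rate constant (1/h)
#' @param k12,k21 central <-> peripheral distribution rate constants (1/h)
#' @param k13,k31 central <-> brain rate constants (1/h)
#' @param k14,k41 central <-> spinal cord rate constants (1/h)
#' @param k15,k51 central <-> CSF rate constants (1/h)
#' @param k35,k45 brain -> CSF and spinal cord -> CSF rate constants (1/h)
#' @param k53,k54 CSF -> brain and CSF -> spinal cord rate constants (1/h)
#' @param kPgp Pgp-mediated efflux rate constant, brain and spinal cord ->
#'   central (1/h); set to zero in knockout animals
#' @param V1_TRQ central volume under tariquidar co-administration (mL)
#' @param kel_TRQ elimination rate constant under tariquidar (1/h)
#' @param kPgp_TRQ residual Pgp efflux under tariquidar (1/h)
#' @param Vbrain,Vspinal,VCSF fixed physiological volumes (mL); never
#'   estimated
#' @param tie_csf_exchange logical; when TRUE (default) enforce the reduced
#'   parameterization k35 == k45 and k53 == k54 used in the final model
#' @return an object of class \code{pk_parameters} (a named list)
#' @export
pk_parameters <- function(V1, kel, k12, k21, k13, k31, k14, k41, k15, k51,
                          k35, k53, k45 = k35, k54 = k53,
                          kPgp = 0,
                          V1_TRQ = V1, kel_TRQ = kel, kPgp_TRQ = 0,
                          Vbrain = 1.8, Vspinal = 0.6, VCSF = 0.25,
                          tie_csf_exchange = TRUE) {
  p <- list(V1 = V1, V1_TRQ = V1_TRQ, kel = kel, kel_TRQ = kel_TRQ,
            k12 = k12, k21 = k21, k13 = k13, k31 = k31, k14 = k14, k41 = k41,
            k15 = k15, k51 = k51, k35 = k35, k45 = k45, k53 = k53, k54 = k54,
            kPgp = kPgp, kPgp_TRQ = kPgp_TRQ,
            Vbrain = Vbrain, Vspinal = Vspinal, VCSF = VCSF)
  p <- lapply(p, as.numeric)
  attr(p, "tie_csf_exchange") <- tie_csf_exchange
  class(p) <- "pk_parameters"
  validate_pk_parameters(p)
  p
}

#' Validate a parameter vector
#'
#' Checks positivity (all rate constants and volumes strictly positive, the
#' two Pgp efflux terms allowed to be zero) and, when the tied
#' parameterization is selected, the k35 == k45 and k53 == k54 constraints.
#'
#' @param p a \code{pk_parameters} object
#' @return \code{p}, invisibly, or an error describing the violated invariant
#' @export
validate_pk_parameters <- function(p) {
  stopifnot(inherits(p, "pk_parameters"))
  nonneg <- c("kPgp", "kPgp_TRQ")
  for (nm in names(unclass(p))) {
    v <- p[[nm]]
    if (length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (nm %in% nonneg) {
      if (v < 0) stop("parameter '", nm, "' must be >= 0", call. = FALSE)
    } else if (v <= 0) {
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
    }
  }
  if (isTRUE(attr(p, "tie_csf_exchange"))) {
    if (p$k35 != p$k45)
      stop("tied parameterization requires k35 == k45", call. = FALSE)
    if (p$k53 != p$k54)
      stop("tied parameterization requires k53 == k54", call. = FALSE)
  }
  invisible(p)
}

#' Group specification
#'
#' @param strain one of \code{"WT"} (wild type, ondansetron alone),
#'   \code{"KO"} (Pgp knockout) or \code{"OT"} (wild type, ondansetron +
#'   tariquidar)
#' @param sex \code{"M"} or \code{"F"}
#' @return an object of class \code{group_spec}
#' @export
group_spec <- function(strain, sex = "M") {
  strain <- match.arg(toupper(strain), c("WT", "KO", "OT"))
  sex <- match.arg(toupper(sex), c("M", "F"))
  structure(list(strain = strain, sex = sex), class = "group_spec")
}

#' Group-effective parameters
#'
#' Maps the shared parameter vector to the effective parameters of one study
#' group: wild-type animals use the base vector unchanged; knockout animals
#' have the Pgp efflux term set to zero; tariquidar-co-dosed animals use the
#' covariate central volume and elimination rate constant and the residual
#' efflux term. All other parameters are shared across groups.
#'
#' @param base a \code{pk_parameters} object (the shared vector)
#' @param group a \code{group_spec}, or a strain string ("WT", "KO", "OT")
#' @return a \code{pk_parameters} object with group-effective values
#' @export
effective_params <- function(base, group) {
  validate_pk_parameters(base)
  strain <- if (inherits(group, "group_spec")) group$strain else as.character(group)
  if (!strain %in% c("WT", "KO", "OT"))
    stop("unknown strain '", strain, "': must be one of WT, KO, OT",
         call. = FALSE)
  p <- base
  if (strain == "KO") {
    p$kPgp <- 0
  } else if (strain == "OT") {
    p$V1 <- base$V1_TRQ
    p$kel <- base$kel_TRQ
    p$kPgp <- base$kPgp_TRQ
  }
  p
}

# Map between internal field names and the published symbol names used in
# parameter files.
.param_symbol_map <- c(
  V1 = "V_1", V1_TRQ = "V_1,TRQ", kel = "k_el", kel_TRQ = "k_el,TRQ",
  k12 = "k_12", k21 = "k_21", k13 = "k_13", k31 = "k_31",
  k14 = "k_14", k41 = "k_41", k15 = "k_15", k51 = "k_51",
  k35 = "k_35=45", k53 = "k_53=54",
  kPgp = "k_Pgp", kPgp_TRQ = "k_Pgp,TRQ",
  Vbrain = "V_brain", Vspinal = "V_spinal", VCSF = "V_CSF")

#' Read a parameter file
#'
#' Parameter files are flat YAML maps keyed by the published symbol names
#' (\code{V_1}, \code{k_el}, \code{k_35=45}, \code{k_Pgp,TRQ}, ...), each
#' entry carrying an \code{estimate} and optionally \code{cv_percent}; the
#' physiological volumes are flagged \code{fixed: true} and are never
#' estimable. The residual proportional-error variance travels under
#' \code{var_P}.
#'
#' @param path path to a YAML parameter file
#' @return a list with elements \code{params} (a \code{pk_parameters}),
#'   \code{var_P} (numeric), and \code{cv_percent} (named numeric, on the
#'   internal field names)
#' @export
read_pk_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  pars <- y$parameters
  if (is.null(pars)) stop("parameter file has no 'parameters' block", call. = FALSE)
  est <- cv <- numeric(0)
  for (internal in names(.param_symbol_map)) {
    sym <- .param_symbol_map[[internal]]
    ent <- pars[[sym]]
    if (is.null(ent)) stop("parameter file is missing key '", sym, "'", call. = FALSE)
    est[internal] <- as.numeric(ent$estimate)
    cv[internal] <- if (is.null(ent$cv_percent)) NA_real_ else as.numeric(ent$cv_percent)
  }
  varp <- pars[["var_P"]]
  p <- pk_parameters(
    V1 = est["V1"], kel = est["kel"], k12 = est["k12"], k21 = est["k21"],
    k13 = est["k13"], k31 = est["k31"], k14 = est["k14"], k41 = est["k41"],
    k15 = est["k15"], k51 = est["k51"], k35 = est["k35"], k53 = est["k53"],
    kPgp = est["kPgp"], V1_TRQ = est["V1_TRQ"], kel_TRQ = est["kel_TRQ"],
    kPgp_TRQ = est["kPgp_TRQ"], Vbrain = est["Vbrain"],
    Vspinal = est["Vspinal"], VCSF = est["VCSF"])
  list(params = p,
       var_P = if (is.null(varp)) NA_real_ else as.numeric(varp$estimate),
       cv_percent = cv,
       sex = y$sex)
}

#' Write a parameter file
#'
#' Inverse of \code{\link{read_pk_parameters}}; emits the canonical YAML
#' dialect with published symbol keys.
#'
#' @param p a \code{pk_parameters} object
#' @param path output path
#' @param var_P residual proportional-error variance to record
#' @param cv_percent optional named numeric of CV\% values (internal names)
#' @param sex optional sex tag ("M"/"F") recorded in the file header
#' @return \code{path}, invisibly
#' @export
write_pk_parameters <- function(p, path, var_P = NA_real_,
                                cv_percent = NULL, sex = NULL) {
  validate_pk_parameters(p)
  fixed <- c("Vbrain", "Vspinal", "VCSF")
  pars <- list()
  for (internal in names(.param_symbol_map)) {
    ent <- list(estimate = p[[internal]])
    if (!is.null(cv_percent) && !is.na(cv_percent[internal]))
      ent$cv_percent <- unname(cv_percent[internal])
    if (internal %in% fixed) ent$fixed <- TRUE
    pars[[.param_symbol_map[[internal]]]] <- ent
  }
  pars[["var_P"]] <- list(estimate = var_P)
  out <- list(sex = sex, parameters = pars)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Packaged default parameter sets
#'
#' Returns the final-model estimates shipped with the package for the male or
#' female pooled fit (WT + KO + OT). The number parsing of a few entries
#' (\code{k_15}, \code{k_51}, \code{var_P}) is provisional, as flagged in the
#' shipped files.
#'
#' @param sex "male"/"M" or "female"/"F"
#' @return as \code{\link{read_pk_parameters}}
#' @export
default_parameters <- function(sex = c("male", "female")) {
  sex <- match.arg(tolower(substr(sex, 1, 1)), c("m", "f"))
  file <- system.file("extdata",
                      if (sex == "m") "params_male.yaml" else "params_female.yaml",
                      package = "cnspk", mustWork = TRUE)
  read_pk_parameters(file)
}

#' Intravenous bolus dose event
#'
#' @param amount dose amount (ug), administered into the central compartment
#' @param time dose time (h)
#' @return an object of class \code{dose_event}
#' @export
dose_event <- function(amount, time = 0) {
  amount <- as.numeric(amount); time <- as.numeric(time)
  if (amount < 0) stop("dose amount must be >= 0", call. = FALSE)
  if (time < 0) stop("dose time must be >= 0", call. = FALSE)
  structure(list(amount = amount, time = time, compartment = "central"),
            class = "dose_event")
}

#' Default rat body weight
#'
#' Midpoints of the study's weight ranges: 300-350 g for males, 250-280 g for
#' females.
#'
#' @param sex "M" or "F"
#' @return body weight in kg
#' @export
default_body_weight <- function(sex = "M") {
  sex <- match.arg(toupper(substr(sex, 1, 1)), c("M", "F"))
  if (sex == "M") 0.325 else 0.265
}

#' Dose amount from body weight
#'
#' @param mg_per_kg dose level (mg/kg); the study used 10 mg/kg
#' @param body_weight_kg body weight (kg)
#' @param time dose time (h)
#' @return a \code{dose_event} with amount in ug
#' @export
dose_from_weight <- function(mg_per_kg = 10, body_weight_kg = 0.325, time = 0) {
  dose_event(mg_per_kg * body_weight_kg * 1000, time = time)
}
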