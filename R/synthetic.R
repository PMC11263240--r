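#' Study design
#'
#' Encodes the sampling design of the rat study: an IV bolus of ondansetron
#' (10 mg/kg) with serial plasma sampling at 5, 10, 15, 30 and 45 min and 1,
#' 1.5, 2, 2.5, 3 and 4 h, and destructive terminal sampling of plasma and
#' CNS tissues (brain, spinal cord, CSF) in separate animal groups at 0.16,
#' 0.25, 0.5, 1, 1.5, 2 and 2.5 h.
#'
#' @param plasma_times sequential plasma schedule (h)
#' @param terminal_times terminal (destructive) schedule (h)
#' @param n_terminal animals per terminal time point (study used 4-6)
#' @param n_sequential animals in the sequential plasma arm
#' @param dose_mg_per_kg dose level (mg/kg)
#' @param groups character vector of strains to generate (subset of WT, KO,
#'   OT)
#' @param sexes character vector of sexes ("M", "F")
#' @param body_weight_kg named numeric of body weights by sex; defaults to
#'   the midpoints of the study weight ranges
#' @return an object of class \code{study_design}
#' @export
study_design <- function(plasma_times = c(c(5, 10, 15, 30, 45) / 60,
                                          1, 1.5, 2, 2.5, 3, 4),
                         terminal_times = c(0.16, 0.25, 0.5, 1, 1.5, 2, 2.5),
                         n_terminal = 5,
                         n_sequential = 5,
                         dose_mg_per_kg = 10,
                         groups = c("WT", "KO", "OT"),
                         sexes = "M",
                         body_weight_kg = c(M = 0.325, F = 0.265)) {
  plasma_times <- sort(as.numeric(plasma_times))
  terminal_times <- sort(as.numeric(terminal_times))
  if (any(plasma_times <= 0) || any(terminal_times <= 0))
    stop("sampling times must be positive", call. = FALSE)
  if (anyDuplicated(plasma_times) || anyDuplicated(terminal_times))
    stop("sampling schedules must be strictly increasing", call. = FALSE)
  if (n_terminal < 1 || n_sequential < 1) stop("n must be >= 1", call. = FALSE)
  groups <- match.arg(toupper(groups), c("WT", "KO", "OT"), several.ok = TRUE)
  sexes <- match.arg(toupper(sexes), c("M", "F"), several.ok = TRUE)
  structure(list(plasma_times = plasma_times, terminal_times = terminal_times,
                 n_terminal = as.integer(n_terminal),
                 n_sequential = as.integer(n_sequential),
                 dose_mg_per_kg = dose_mg_per_kg, groups = groups,
                 sexes = sexes, body_weight_kg = body_weight_kg),
            class = "study_design")
}

#' Assay detection limits
#'
#' @param plasma plasma limit of detection (ug/mL; assay LOD 10 ng/mL)
#' @param cns CNS tissue limit of detection (ug/mL; assay LOD 50 ng/mL)
#' @return an object of class \code{lod_spec}
#' @export
lod_spec <- function(plasma = 0.010, cns = 0.050) {
  if (plasma <= 0 || cns <= 0) stop("LODs must be > 0", call. = FALSE)
  structure(list(plasma = plasma, cns = cns), class = "lod_spec")
}

# design points of one group/sex: plasma at union of sequential and terminal
# schedules (terminal animals contribute a plasma sample too), tissues at the
# terminal schedule only
.design_points <- function(design) {
  plasma_t <- sort(unique(c(design$plasma_times, design$terminal_times)))
  n_plasma <- ifelse(plasma_t %in% design$plasma_times,
                     design$n_sequential, 0L) +
    ifelse(plasma_t %in% design$terminal_times, design$n_terminal, 0L)
  rbind(
    data.frame(matrix = "plasma", time = plasma_t, n = n_plasma,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(c("brain", "spinal_cord", "CSF"), function(m)
      data.frame(matrix = m, time = design$terminal_times,
                 n = design$n_terminal, stringsAsFactors = FALSE)))
  )
}

#' Generate a synthetic concentration dataset
#'
#' Simulates the study design from a parameter set and draws replicate
#' observations with proportional Gaussian noise, obs = pred * (1 + e),
#' e ~ N(0, var_P), truncated at zero (negative draws are resampled).
#' Replicates below the matrix-appropriate detection limit are censored;
#' each dataset row carries the mean, SD and count of the uncensored
#' replicates at that design point, or a censored flag when none remain.
#'
#' @param params shared \code{pk_parameters}
#' @param design a \code{\link{study_design}}
#' @param var_p proportional-error variance (0 gives noise-free means equal
#'   to the model predictions)
#' @param lod a \code{\link{lod_spec}}
#' @param seed integer seed; mandatory, recorded in the result's
#'   \code{"seed"} attribute
#' @param method simulation backend (see \code{\link{simulate_amounts}})
#' @return a validated concentration dataset with attributes \code{seed} and
#'   \code{dose} (named ug amounts by sex)
#' @export
generate_dataset <- function(params, design = study_design(),
                             var_p = 0.05, lod = lod_spec(), seed,
                             method = "analytic") {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is mandatory for dataset generation", call. = FALSE)
  if (var_p < 0) stop("var_p must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  pts <- .design_points(design)
  sdnoise <- sqrt(var_p)
  rows <- list()
  doses <- c()
  for (sex in design$sexes) {
    dose <- dose_from_weight(design$dose_mg_per_kg,
                             design$body_weight_kg[[sex]])
    doses[sex] <- dose$amount
    for (grp in design$groups) {
      prof <- simulate_profiles(params, group_spec(grp, sex), dose,
                                sort(unique(pts$time)), method = method)
      for (i in seq_len(nrow(pts))) {
        if (pts$n[i] == 0) next
        pred <- prof$conc[prof$matrix == pts$matrix[i] &
                            prof$time == pts$time[i]]
        reps <- if (sdnoise == 0) rep(pred, pts$n[i]) else {
          r <- pred * (1 + stats::rnorm(pts$n[i], 0, sdnoise))
          while (any(r < 0))
            r[r < 0] <- pred * (1 + stats::rnorm(sum(r < 0), 0, sdnoise))
          r
        }
        lim <- if (pts$matrix[i] == "plasma") lod$plasma else lod$cns
        keep <- reps >= lim
        rows[[length(rows) + 1L]] <- data.frame(
          group = grp, sex = sex, matrix = pts$matrix[i], time = pts$time[i],
          mean_conc = if (any(keep)) mean(reps[keep]) else NA_real_,
          sd = if (sum(keep) > 1) stats::sd(reps[keep]) else
            if (any(keep)) 0 else NA_real_,
          n = if (any(keep)) sum(keep) else pts$n[i],
          censored = !any(keep),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- validate_dataset(do.call(rbind, rows))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "dose") <- doses
  out
}

#' Apply detection-limit censoring
#'
#' Flags rows whose mean concentration falls below the matrix-appropriate
#' detection limit. Censoring is idempotent and never drops rows.
#'
#' @param dataset a concentration dataset
#' @param lod a \code{\link{lod_spec}}
#' @return the dataset with the \code{censored} flag updated
#' @export
censor_lod <- function(dataset, lod = lod_spec()) {
  dataset <- validate_dataset(dataset)
  if (nrow(dataset) == 0) return(dataset)
  lim <- ifelse(dataset$matrix == "plasma", lod$plasma, lod$cns)
  below <- !is.na(dataset$mean_conc) & dataset$mean_conc < lim
  dataset$censored <- dataset$censored | below
  dataset
}
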