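#' Run the analysis pipeline
#'
#' Orchestrates the workflow stages over one configuration: \code{simulate}
#' (model profiles on a dense grid), \code{generate} (synthetic study
#' dataset), \code{fit} (naive-pooled estimation), \code{nca}
#' (noncompartmental summary of the dataset) and \code{scan} (Pgp-inhibition
#' scan). Every output is written under \code{out_dir} together with a
#' manifest (JSON: package version, config, seed) and a plain-text run log.
#' Any stage failure stops the run with a diagnostic naming the stage.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{stages}{character vector from simulate, generate, fit, nca, scan}
#'     \item{sex}{"M" or "F" (selects the packaged parameter set and dose)}
#'     \item{param_file}{optional path to a parameter YAML (default: packaged
#'       set for \code{sex})}
#'     \item{dataset}{optional path to an existing dataset CSV (otherwise the
#'       generate stage must precede fit/nca)}
#'     \item{seed}{integer; mandatory when any stochastic stage is requested}
#'     \item{var_p}{generator noise variance (default: packaged var_P)}
#'     \item{n_starts}{fit multi-start count (default 1)}
#'     \item{maxit}{fit iteration cap (default 500)}
#'     \item{times}{simulation grid for simulate/scan (default 0-2.5 h)}
#'     \item{fractions}{scan inhibition fractions (default 0, 0.5, 0.9, 1)}
#'   }
#' @param out_dir output directory (created if absent)
#' @return invisibly, a list of the produced artifact paths
#' @export
run_pipeline <- function(config, out_dir = "results") {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stages <- match.arg(config$stages,
                      c("simulate", "generate", "fit", "nca", "scan"),
                      several.ok = TRUE)
  sex <- if (is.null(config$sex)) "M" else toupper(config$sex)
  seed <- config$seed
  stochastic <- "generate" %in% stages ||
    ("fit" %in% stages && !is.null(config$n_starts) && config$n_starts > 1)
  if (stochastic && is.null(seed))
    stop("config must provide a seed when a stochastic stage is requested",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    writeLines(msg, log_con)
    message(msg)
  }
  stage <- function(name, expr) {
    say("stage ", name, " started")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  pf <- if (!is.null(config$param_file)) read_pk_parameters(config$param_file)
        else default_parameters(sex)
  params <- pf$params
  var_p <- if (!is.null(config$var_p)) config$var_p else pf$var_P
  dose <- dose_from_weight(10, default_body_weight(sex))
  dose_map <- stats::setNames(dose$amount, sex)
  times <- if (is.null(config$times)) seq(0, 2.5, by = 0.01)
           else as.numeric(config$times)
  if (!is.null(seed)) say("seed: ", seed)
  artifacts <- list()

  dataset <- NULL
  if (!is.null(config$dataset)) dataset <- read_dataset(config$dataset)

  if ("simulate" %in% stages) {
    stage("simulate", {
      prof <- do.call(rbind, lapply(c("WT", "KO", "OT"), function(g) {
        d <- simulate_profiles(params, group_spec(g, sex), dose,
                               times[times > 0])
        cbind(group = g, sex = sex, d)
      }))
      path <- file.path(out_dir, "simulated_profiles.csv")
      utils::write.csv(prof, path, row.names = FALSE)
      artifacts$simulate <- path
      say("simulate: wrote ", nrow(prof), " rows")
    })
  }
  if ("generate" %in% stages) {
    stage("generate", {
      design <- study_design(sexes = sex)
      dataset <- generate_dataset(params, design, var_p = var_p, seed = seed)
      path <- file.path(out_dir, "synthetic_dataset.csv")
      write_dataset(dataset, path)
      artifacts$generate <- path
      say("generate: ", nrow(dataset), " rows, seed ", seed)
    })
  }
  if ("fit" %in% stages) {
    stage("fit", {
      if (is.null(dataset))
        stop("fit requires a dataset (path in config or a generate stage)")
      n_starts <- if (is.null(config$n_starts)) 1 else config$n_starts
      maxit <- if (is.null(config$maxit)) 500 else config$maxit
      fs <- fit_spec(dataset, init = params, dose_map = dose_map,
                     n_starts = n_starts, seed = seed, maxit = maxit)
      fit <- fit_pooled(fs)
      tab <- data.frame(parameter = c(names(fit$estimates), "var_P"),
                        estimate = c(unname(fit$estimates), fit$var_p),
                        cv_percent = unname(fit$cv_percent))
      path <- file.path(out_dir, "fit_result.csv")
      utils::write.csv(tab, path, row.names = FALSE)
      artifacts$fit <- path
      say("fit: NLL ", format(fit$nll), ", converged ", fit$converged,
          ", starts ", n_starts)
    })
  }
  if ("nca" %in% stages) {
    stage("nca", {
      if (is.null(dataset))
        stop("nca requires a dataset (path in config or a generate stage)")
      res <- nca_dataset(dataset, dose_map = dose_map)
      path <- file.path(out_dir, "nca_results.csv")
      utils::write.csv(res, path, row.names = FALSE)
      artifacts$nca <- path
      say("nca: ", nrow(res), " rows")
    })
  }
  if ("scan" %in% stages) {
    stage("scan", {
      fractions <- if (is.null(config$fractions)) c(0, 0.5, 0.9, 1)
                   else as.numeric(config$fractions)
      sc <- scan_spec(params, fractions = fractions, times = times,
                      dose = dose)
      res <- inhibition_scan(sc)
      path <- file.path(out_dir, "scan_results.csv")
      utils::write.csv(res, path, row.names = FALSE)
      artifacts$scan <- path
      say("scan: fractions ", paste(fractions, collapse = ", "))
    })
  }

  manifest <- list(
    package = "cnspk",
    version = as.character(utils::packageVersion("cnspk")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config[setdiff(names(config), "stages")],
    stages = stages,
    artifacts = lapply(artifacts, basename))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  artifacts$manifest <- manifest_path
  artifacts$log <- log_path
  say("pipeline complete")
  invisible(artifacts)
}
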