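#' Validate a concentration dataset
#'
#' The canonical long format is one row per (group, sex, matrix, time) with
#' the across-animal mean concentration, its SD and the number of uncensored
#' replicates. Group, sex and matrix labels are case-folded to the canonical
#' vocabularies (WT/KO/OT, M/F, plasma/brain/spinal_cord/CSF). Censored rows
#' (all replicates below the detection limit) carry \code{censored = TRUE}
#' and may have a missing mean; they are never silently dropped.
#'
#' @param dataset a data.frame with columns group, sex, matrix, time,
#'   mean_conc, sd, n, censored
#' @return the validated, case-folded dataset
#' @export
validate_dataset <- function(dataset) {
  required <- c("group", "sex", "matrix", "time", "mean_conc", "sd", "n",
                "censored")
  missing_cols <- setdiff(required, names(dataset))
  if (length(missing_cols) > 0)
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dataset <- as.data.frame(dataset)[, required]
  if (nrow(dataset) == 0) return(dataset)

  dataset$group <- toupper(trimws(as.character(dataset$group)))
  bad <- setdiff(unique(dataset$group), c("WT", "KO", "OT"))
  if (length(bad) > 0)
    stop("unknown group value(s): ", paste(bad, collapse = ", "), call. = FALSE)

  dataset$sex <- toupper(trimws(as.character(dataset$sex)))
  bad <- setdiff(unique(dataset$sex), c("M", "F"))
  if (length(bad) > 0)
    stop("unknown sex value(s): ", paste(bad, collapse = ", "), call. = FALSE)

  mx <- tolower(trimws(as.character(dataset$matrix)))
  mx[mx == "csf"] <- "CSF"
  dataset$matrix <- mx
  bad <- setdiff(unique(mx), c("plasma", "brain", "spinal_cord", "CSF"))
  if (length(bad) > 0)
    stop("unknown matrix value(s): ", paste(bad, collapse = ", "), call. = FALSE)

  dataset$time <- as.numeric(dataset$time)
  dataset$mean_conc <- as.numeric(dataset$mean_conc)
  dataset$sd <- as.numeric(dataset$sd)
  dataset$n <- as.integer(dataset$n)
  dataset$censored <- as.logical(dataset$censored)

  if (any(dataset$time < 0)) stop("time must be >= 0", call. = FALSE)
  bad_conc <- !dataset$censored &
    (is.na(dataset$mean_conc) | dataset$mean_conc < 0)
  if (any(bad_conc))
    stop("mean_conc must be >= 0 (or the row censored); offending row(s): ",
         paste(which(bad_conc), collapse = ", "), call. = FALSE)
  if (any(!is.na(dataset$sd) & dataset$sd < 0))
    stop("sd must be >= 0", call. = FALSE)
  if (any(dataset$n < 1)) stop("n must be >= 1", call. = FALSE)

  key <- paste(dataset$group, dataset$sex, dataset$matrix, dataset$time)
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (group, sex, matrix, time) key(s): ",
         paste(unique(key[dup]), collapse = "; "), call. = FALSE)
  dataset
}

#' Read a concentration dataset
#'
#' Reads the canonical CSV dialect (comma separated, dot decimal, UTF-8,
#' header required) and validates it. Times are hours internally; a file
#' sampled in minutes is converted on read either through
#' \code{time_units = "min"} or through an explicit per-row \code{time_units}
#' column holding \code{"h"} or \code{"min"}.
#'
#' @param path CSV file path
#' @param time_units default time units of the file ("h" or "min")
#' @return a validated dataset (times in hours)
#' @export
read_dataset <- function(path, time_units = "h") {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  # read everything as character: an all-"F" sex column must not collapse to
  # logical; validate_dataset does the typed coercion
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if ("time" %in% names(d)) d$time <- as.numeric(d$time)
  if ("time_units" %in% names(d)) {
    u <- tolower(trimws(d$time_units))
    bad <- setdiff(unique(u), c("h", "min"))
    if (length(bad) > 0)
      stop("unknown time_units value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    d$time <- ifelse(u == "min", d$time / 60, d$time)
    d$time_units <- NULL
  } else if (identical(time_units, "min")) {
    d$time <- d$time / 60
  } else if (!identical(time_units, "h")) {
    stop("time_units must be 'h' or 'min'", call. = FALSE)
  }
  validate_dataset(d)
}

#' Write a concentration dataset
#'
#' Emits the canonical CSV dialect. Writing a dataset read from a
#' canonical-form file reproduces it byte for byte.
#'
#' @param dataset a validated dataset
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
write_dataset <- function(dataset, path) {
  dataset <- validate_dataset(dataset)
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE,
                   na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
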