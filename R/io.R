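#' Read an individual (morphometric) table from CSV
#'
#' Expects a UTF-8, "."-decimal CSV with a header row and columns `id`,
#' `transect`, `group` plus the measurements in [MORPHO_VARS].  Records
#' are validated: duplicate ids, unknown group labels, missing columns and
#' non-positive lengths are rejected with the offending rows named.
#'
#' @param path path to the CSV file.
#' @return validated data frame of morphometric records.
#' @export
read_individuals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_individuals(read.csv(path, stringsAsFactors = FALSE))
}

#' Write an individual table to CSV
#' @param individuals data frame of morphometric records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_individuals <- function(individuals, path) {
  individuals <- validate_individuals(individuals)
  write.csv(individuals, path, row.names = FALSE)
  invisible(path)
}

#' Read a transect (microhabitat) table from CSV
#'
#' Expects `transect`, the variables in [ENV_VARS], and optionally
#' per-group count columns `n_juvenile`, `n_male`, `n_female`.
#'
#' @param path path to the CSV file.
#' @return validated data frame of transects.
#' @export
read_transects <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_transects(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a transect table to CSV
#' @param transects data frame of transects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transects <- function(transects, path) {
  transects <- validate_transects(transects)
  write.csv(transects, path, row.names = FALSE)
  invisible(path)
}

validate_transects <- function(transects) {
  transects <- as.data.frame(transects)
  need <- c("transect", ENV_VARS)
  miss <- setdiff(need, names(transects))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  transects$transect <- as.character(transects$transect)
  if (anyDuplicated(transects$transect)) {
    stop("duplicate transect id(s): ",
         paste(unique(transects$transect[duplicated(transects$transect)]),
               collapse = ", "))
  }
  for (v in ENV_VARS) {
    if (!is.numeric(transects[[v]])) stop("column ", v, " must be numeric")
    if (any(!is.finite(transects[[v]]))) {
      stop("non-finite ", v, " in row(s) ",
           paste(which(!is.finite(transects[[v]])), collapse = ", "))
    }
  }
  for (v in c("AH", "SH", "RC", "BSC", "CGC")) {
    bad <- which(transects[[v]] < 0 | transects[[v]] > 100)
    if (length(bad)) {
      stop("coverage/humidity ", v, " outside [0, 100] in row(s) ",
           paste(bad, collapse = ", "))
    }
  }
  for (v in grep("^n_", names(transects), value = TRUE)) {
    bad <- which(transects[[v]] < 0 | transects[[v]] != round(transects[[v]]))
    if (length(bad)) {
      stop("count column ", v, " must hold nonnegative integers (row(s) ",
           paste(bad, collapse = ", "), ")")
    }
  }
  transects
}
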