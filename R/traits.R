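#' Morphometric column names expected in an individual table
#'
#' `M` is body mass in grams; the remaining ten are linear measurements in
#' millimetres: interocular distance (IO), mouth width (MW), head length
#' (HL), head height (HH), head width (HW), forelimb length (FLL), hindlimb
#' length (HLL), tail length (TAL), abdominal maximum width (AMW) and
#' snout-vent length (SVL).
#' @export
MORPHO_VARS <- c("M", "IO", "MW", "HL", "HH", "HW", "FLL", "HLL", "TAL", "AMW", "SVL")

#' Names of the nine unitless functional traits
#' @export
TRAIT_NAMES <- c("Mass", "EP", "MS", "HS", "RFL", "RHL", "LR", "RTL", "RAW")

#' Allowed group labels for individuals
#' @export
GROUP_LEVELS <- c("juvenile", "male", "female")

#' Compute functional traits from raw morphometrics
#'
#' Converts raw measurements into the nine unitless functional traits used
#' to build the functional space:
#' \describe{
#'   \item{Mass}{`log10(M + 1)` -- overall size / muscle mass (the log base
#'     is configurable via `log_base`).}
#'   \item{EP}{`IO / HW` -- eye position, prey detection.}
#'   \item{MS}{`MW / HW` -- mouth shape, size of ingestible prey.}
#'   \item{HS}{`(HW * HL * HH)^(1/3)` -- head size, bite performance.}
#'   \item{RFL}{`FLL / SVL` -- relative forelimb length.}
#'   \item{RHL}{`HLL / SVL` -- relative hindlimb length.}
#'   \item{LR}{`FLL / HLL` -- limb ratio, coordination.}
#'   \item{RTL}{`TAL / SVL` -- relative tail length, balance.}
#'   \item{RAW}{`AMW / SVL` -- relative abdominal width, fecundity.}
#' }
#'
#' All ratios are scale-free; `Mass` and `HS` deliberately retain absolute
#' size information.
#'
#' @param records data frame of individuals with columns `id`, `transect`,
#'   `group` and the measurements in [MORPHO_VARS].
#' @param log_base base of the logarithm applied to `M + 1` (default 10).
#' @return an object of class `trait_matrix`: a list with the `traits`
#'   matrix (individuals x 9, rownames = ids), per-individual `meta`
#'   (id, group, transect), and a `standardized` flag.
#' @examples
#' ind <- generate_individuals(simulation_config(seed = 1))
#' tm <- compute_traits(ind)
#' head(tm$traits)
#' @export
compute_traits <- function(records, log_base = 10) {
  records <- validate_individuals(records)
  denoms <- c("HW", "SVL", "HLL")
  for (v in denoms) {
    bad <- which(records[[v]] <= 0)
    if (length(bad)) {
      stop(
        "non-positive denominator ", v, " for record(s) ",
        paste(records$id[bad], collapse = ", ")
      )
    }
  }
  tr <- cbind(
    Mass = log(records$M + 1, base = log_base),
    EP  = records$IO / records$HW,
    MS  = records$MW / records$HW,
    HS  = (records$HW * records$HL * records$HH)^(1 / 3),
    RFL = records$FLL / records$SVL,
    RHL = records$HLL / records$SVL,
    LR  = records$FLL / records$HLL,
    RTL = records$TAL / records$SVL,
    RAW = records$AMW / records$SVL
  )
  rownames(tr) <- records$id
  structure(
    list(
      traits = tr,
      meta = data.frame(
        id = records$id, group = records$group, transect = records$transect,
        stringsAsFactors = FALSE
      ),
      standardized = FALSE,
      center = NULL,
      scale = NULL,
      log_base = log_base
    ),
    class = "trait_matrix"
  )
}

#' Standardize a trait matrix to zero mean and unit standard deviation
#'
#' Each trait column is centred and scaled by its sample standard deviation
#' (`n - 1` denominator).  The centring and scaling constants are stored so
#' the transformation can be inverted with [unstandardize_traits()].
#'
#' @param tm a `trait_matrix` from [compute_traits()].
#' @return a standardized `trait_matrix`.
#' @export
standardize_traits <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  if (isTRUE(tm$standardized)) return(tm)
  x <- tm$traits
  if (nrow(x) < 2) stop("standardization needs at least 2 individuals")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  const <- which(scl <= .Machine$double.eps^0.5 * pmax(abs(ctr), 1))
  if (length(const)) {
    stop("constant trait column(s): ", paste(colnames(x)[const], collapse = ", "))
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  tm$traits <- z
  tm$standardized <- TRUE
  tm$center <- ctr
  tm$scale <- scl
  tm
}

#' Invert the standardization of a trait matrix
#'
#' @param tm a standardized `trait_matrix`.
#' @return the `trait_matrix` on the original trait scale.
#' @export
unstandardize_traits <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"), isTRUE(tm$standardized))
  x <- sweep(sweep(tm$traits, 2, tm$scale, "*"), 2, tm$center, "+")
  tm$traits <- x
  tm$standardized <- FALSE
  tm$center <- NULL
  tm$scale <- NULL
  tm
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(
    "Functional trait matrix:", nrow(x$traits), "individuals x",
    ncol(x$traits), "traits",
    if (isTRUE(x$standardized)) "(standardized)" else "(raw)", "\n"
  )
  cat("Groups:", paste(sprintf(
    "%s=%d", names(table(x$meta$group)), as.integer(table(x$meta$group))
  ), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.trait_matrix <- function(x, ...) {
  cbind(x$meta, as.data.frame(x$traits))
}

# validation shared by compute_traits() and read_individuals()
validate_individuals <- function(records) {
  records <- as.data.frame(records)
  need <- c("id", "transect", "group", MORPHO_VARS)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  records$id <- as.character(records$id)
  records$transect <- as.character(records$transect)
  records$group <- as.character(records$group)
  if (anyDuplicated(records$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  badg <- which(!records$group %in% GROUP_LEVELS)
  if (length(badg)) {
    stop(
      "unknown group label(s) in row(s) ", paste(badg, collapse = ", "),
      "; allowed labels: ", paste(GROUP_LEVELS, collapse = ", ")
    )
  }
  for (v in MORPHO_VARS) {
    if (!is.numeric(records[[v]])) stop("column ", v, " must be numeric")
    if (any(!is.finite(records[[v]]))) {
      stop("non-finite ", v, " in row(s) ",
           paste(which(!is.finite(records[[v]])), collapse = ", "))
    }
  }
  lens <- setdiff(MORPHO_VARS, "M")
  for (v in lens) {
    bad <- which(records[[v]] <= 0)
    if (length(bad)) {
      stop("non-positive length ", v, " in row(s) ", paste(bad, collapse = ", "))
    }
  }
  if (any(records$M < 0)) {
    stop("negative body mass in row(s) ",
         paste(which(records$M < 0), collapse = ", "))
  }
  records
}
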