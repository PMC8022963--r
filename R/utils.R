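# Internal helpers shared across modules.

#' Round half-up with a floor of one
#'
#' Cohort scaling multiplies every cohort size and selection count by a factor
#' in (0,1]; sizes are rounded half-up and never drop below one individual.
#'
#' @param n numeric vector of counts.
#' @param scale scaling factor in (0, 1].
#' @return integer vector of scaled counts.
#' @export
scaleCount <- function(n, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) ||
      scale <= 0 || scale > 1) {
    stop("'scale' must be a single number in (0, 1]")
  }
  as.integer(pmax(1, floor(n * scale + 0.5)))
}

# Deterministic per-node child seeds below 2^31, derived from one master seed.
deriveSeeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(master_seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

# sample() that never falls into the 1:x interpretation for length-1 input.
resample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Named-list getter with default.
lget <- function(x, name, default = NULL) {
  if (!is.null(x) && !is.null(x[[name]])) x[[name]] else default
}

isCount <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

isProportion <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# Check a matrix is a valid correlation matrix (symmetric, unit diagonal, PSD).
checkCorrelation <- function(m, label) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    return(sprintf("%s must be a square matrix", label))
  }
  if (max(abs(m - t(m))) > 1e-8) {
    return(sprintf("%s must be symmetric", label))
  }
  if (max(abs(diag(m) - 1)) > 1e-8) {
    return(sprintf("%s must have a unit diagonal", label))
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    return(sprintf("%s must be positive semi-definite", label))
  }
  NULL
}
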