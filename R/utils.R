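# Shared helpers: unit constants, optical density, local RNG scope.

# One conversion constant between the object scale (um^2) and the
# cortex scale (mm^2), used everywhere areas change units.
UM2_PER_MM2 <- 1e6

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Optical density transform
#'
#' Converts transmitted intensity in \[0, 1\] to optical density
#' \code{-log(I)}. Intensities are floored at \code{eps} so fully dark
#' pixels stay finite. Ratios of optical densities are invariant to a
#' global stain-intensity multiplier, which is what makes the detector
#' robust to staining level.
#'
#' @param x numeric array of intensities in \[0, 1\].
#' @param eps floor applied before the logarithm.
#' @return array of the same shape, optical densities (>= 0).
#' @keywords internal
optical_density <- function(x, eps = 0.02) {
  -log(pmax(x, eps))
}

# Evaluate `expr` under a private RNG stream seeded with `seed`,
# restoring the caller's .Random.seed afterwards. Keeps generator
# output a pure function of (spec, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Sample skewness g1 = m3 / m2^(3/2); returns NA for constant input.
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

# Truncated normal draws by inversion; mean/sd are the untruncated
# parameters, bounds are honoured exactly.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, pl, pu)
  stats::qnorm(u, mean, sd)
}
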