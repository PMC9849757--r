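# Ecoenzymatic stoichiometry: vector length/angle and reflection transforms.

#' Microbial nutrient-limitation vectors from extracellular enzyme activities
#'
#' Summarises the relative investment in carbon-, nitrogen- and
#' phosphorus-acquiring extracellular enzymes as a vector in the plane:
#' with \code{a = T(bg)}, \code{n = T(nag) + T(lap)}, \code{p = T(acp)}
#' (\code{T} identity or natural log), the coordinates are
#' \code{x = a/(a + p)} and \code{y = a/(a + n)}. Vector length
#' \code{sqrt(x^2 + y^2)} indexes microbial carbon limitation; the vector
#' angle (degrees, via the two-argument arctangent of \code{x} against
#' \code{y}) indexes the nitrogen/phosphorus balance: angle < 45 means
#' relatively greater N-acquisition investment (N limitation), angle > 45
#' P limitation, 45 exactly co-limitation.
#'
#' @param bg,nag,lap,acp numeric vectors of equal length: activities of
#'   beta-1,4-glucosidase, N-acetyl-glucosaminidase, leucine aminopeptidase
#'   and acid phosphatase (one value per sample, same activity units).
#' @param trans \code{"ln"} (default) log-transforms each activity before
#'   forming the ratios (all activities must then be > 1 is not required,
#'   but they must be positive); \code{"raw"} uses activities as-is.
#' @return A data.frame with columns \code{length}, \code{angle} (degrees in
#'   [0, 90]) and \code{limitation} (factor: \code{"N"}, \code{"P"},
#'   \code{"co-limited"}).
#' @examples
#' vector_limitation(bg = 1, nag = 0.5, lap = 0.5, acp = 1, trans = "raw")
#' @export
vector_limitation <- function(bg, nag, lap, acp, trans = c("ln", "raw")) {
  trans <- match.arg(trans)
  n <- length(bg)
  if (!all(lengths(list(nag, lap, acp)) == n))
    stop("bg, nag, lap, acp must have equal length", call. = FALSE)
  act <- cbind(bg = bg, nag = nag, lap = lap, acp = acp)
  if (anyNA(act)) stop("enzyme activities contain missing values", call. = FALSE)
  if (trans == "ln") {
    if (any(act <= 0))
      stop("all enzyme activities must be positive for trans = 'ln'",
           call. = FALSE)
    act <- log(act)
  } else if (any(act < 0)) {
    stop("enzyme activities must be non-negative", call. = FALSE)
  }
  a <- act[, "bg"]
  nn <- act[, "nag"] + act[, "lap"]
  p <- act[, "acp"]
  if (any(a + p == 0) || any(a + nn == 0))
    stop("degenerate activity sums: a + p and a + n must be nonzero",
         call. = FALSE)
  x <- a / (a + p)
  y <- a / (a + nn)
  if (any(x == 0 & y == 0))
    stop("vector angle undefined: both components zero", call. = FALSE)
  len <- sqrt(x^2 + y^2)
  ang <- atan2(x, y) * 180 / pi   # x > y => angle > 45 (P limitation)
  cls <- ifelse(ang < 45, "N", ifelse(ang > 45, "P", "co-limited"))
  data.frame(length = len, angle = ang,
             limitation = factor(cls, levels = c("N", "P", "co-limited")))
}

#' Reflect a "bad-is-high" soil function so that high values are desirable
#'
#' Applies \code{r(f) = -f + max(f)}: the maximum maps to 0, the order is
#' reversed, and all outputs are non-negative. Used for carbon limitation,
#' soil hardness and bulk density before multifunctionality scoring.
#'
#' @param values non-empty numeric vector.
#' @return Numeric vector of the same length.
#' @examples
#' reflect_negative(c(1, 3, 5))  # 4 2 0
#' @export
reflect_negative <- function(values) {
  if (length(values) == 0L || !is.numeric(values))
    stop("values must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(values)) stop("values contain missing entries", call. = FALSE)
  -values + max(values)
}

#' Fold vector angles about the 45-degree co-limitation line
#'
#' Maps an angle x (degrees, in [0, 90]) to \code{x - 45} below 45 and
#' \code{-x + 45} above 45 (0 at 45 exactly), i.e. \code{-|x - 45|}: the
#' closer a community sits to balanced N/P co-limitation the higher
#' (less negative) the score.
#'
#' @param angles numeric vector of angles in degrees, each in [0, 90].
#' @return Numeric vector, all values <= 0.
#' @examples
#' reflect_angle(c(30, 45, 60))  # -15 0 -15
#' @export
reflect_angle <- function(angles) {
  if (length(angles) == 0L || !is.numeric(angles))
    stop("angles must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(angles)) stop("angles contain missing entries", call. = FALSE)
  if (any(angles < 0 | angles > 90))
    stop("angles must lie in [0, 90] degrees", call. = FALSE)
  -abs(angles - 45)
}
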