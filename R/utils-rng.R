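#' @importFrom withr with_seed
NULL

# Derive a 31-bit sub-seed from a master seed and a substream name, so each
# generator modality draws from its own reproducible stream and adding a new
# modality never shifts another's draws.
subSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((abs(seed) * 48271 + h) %% 2147483647L)
}

withSubstream <- function(seed, name, code) {
  withr::with_seed(subSeed(seed, name), code)
}

#' Sample angles from a von Mises distribution
#'
#' Best--Fisher rejection sampler for the von Mises distribution with mean
#' direction \code{mu} (radians) and concentration \code{kappa}. Used by the
#' synthetic orientation generator, where nematic angles \eqn{\theta} are
#' drawn with \eqn{2\theta \sim \mathrm{vM}(2\mu, \kappa)}.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration parameter, \eqn{\kappa \ge 0}; \code{0} gives
#'   the uniform distribution on the circle.
#' @return numeric vector of angles in \eqn{[-\pi, \pi)}.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa == 0) {
    th <- stats::runif(n, -pi, pi)
    return(((th + mu + pi) %% (2 * pi)) - pi)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- stats::runif(1)
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  ((out + mu + pi) %% (2 * pi)) - pi
}

# Ratio of modified Bessel functions I1(k)/I0(k): the expected resultant
# length of a von Mises sample, i.e. the expected nematic order parameter
# when doubled angles are von Mises distributed.
besselRatio <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Concentration giving a target mean order parameter
#'
#' Inverts the Bessel ratio \eqn{E[Q] = I_1(\kappa)/I_0(\kappa)} by
#' root-finding, so a synthetic orientation fixture can be generated with a
#' prescribed expected nematic order parameter (e.g. the low/medium/high
#' density values 0.18, 0.51, 0.87).
#'
#' @param Q target expected order parameter in \code{[0, 1)}.
#' @return concentration \eqn{\kappa \ge 0}.
#' @export
kappaForOrder <- function(Q) {
  stopifnot(Q >= 0, Q < 1)
  if (Q == 0) return(0)
  stats::uniroot(function(k) besselRatio(k) - Q,
                 lower = 1e-8, upper = 1e4, tol = 1e-10)$root
}
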