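# Spheroid and ellipse geometry shared by the rounding generator and the
# dissipation diagnostic.
#
# Convention (matching the morphometry anisotropy convention): the cluster is
# a spheroid with in-plane major semi-axis `a` and minor semi-axis `c`, the
# minor axis being the doubly-degenerate one, so that
#   eps = (c - a)/(c + a)  in (-1, 0]  and  r = (2a + c)/3.
# Volume is V = (4/3) pi a c^2 and is conserved during rounding.

# semi-axes (a, c) of the spheroid with anisotropy eps and volume V
spheroidAxes <- function(eps, V) {
  stopifnot(abs(eps) < 1, V > 0)
  q <- (1 + eps) / (1 - eps)        # c / a
  a <- (3 * V / (4 * pi * q^2))^(1 / 3)
  c(a = a, c = a * q)
}

spheroidVolume <- function(a, c) 4 / 3 * pi * a * c^2

# mean radius r = (2a + c)/3 for a given anisotropy at fixed volume
spheroidMeanRadius <- function(eps, V) {
  ax <- spheroidAxes(eps, V)
  (2 * ax["a"] + ax["c"]) / 3
}

# Exact surface area of the spheroid with distinct semi-axis `a` and repeated
# semi-axis `c` (prolate when a > c, oblate when a < c).
spheroidArea <- function(a, c) {
  stopifnot(a > 0, c > 0)
  if (abs(a - c) < 1e-12 * max(a, c)) return(4 * pi * a^2)
  if (a > c) {                       # prolate about the long axis a
    e <- sqrt(1 - c^2 / a^2)
    2 * pi * c^2 + 2 * pi * a * c * asin(e) / e
  } else {                           # oblate
    e <- sqrt(1 - a^2 / c^2)
    2 * pi * c^2 + pi * a^2 / e * log((1 + e) / (1 - e))
  }
}

# dS/deps at constant volume, central finite differences
spheroidAreaDeriv <- function(eps, V, h = 1e-6) {
  axp <- spheroidAxes(eps + h, V)
  axm <- spheroidAxes(eps - h, V)
  (spheroidArea(axp["a"], axp["c"]) - spheroidArea(axm["a"], axm["c"])) /
    (2 * h)
}

# Exact perimeter of an ellipse with semi-axes a, b via the complete
# elliptic integral of the second kind.
ellipsePerimeter <- function(a, b) {
  hi <- pmax(a, b); lo <- pmin(a, b)
  m <- 1 - (lo / hi)^2
  4 * hi * pracma::ellipke(m)$e
}
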