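# Shared fixture builders; everything is generated in code at test time.

# seven default rounding tracks with the given noise, distinct substreams
makeRoundingTracks <- function(n = 7L, noise = 2, seed = 1, ...) {
  lapply(seq_len(n), function(i)
    simulateRoundingTrack(axisNoiseSD_um = noise, seed = seed * 100 + i,
                          objectId = i, ...))
}

# circular mean of nematic angles (radians in [0, pi))
nematicMean <- function(field) {
  w <- if (length(field@weight)) field@weight else rep(1, length(field@theta))
  (atan2(sum(w * sin(2 * field@theta)),
         sum(w * cos(2 * field@theta))) / 2) %% pi
}

# closed form of dN/dt = p1 - a(t) p2 N, a = min(t/ts, 1), N(0) = 0:
# on t <= ts the linear ODE has integrating factor exp(p2 t^2 / (2 ts))
# (imaginary-error-function solution); beyond ts it is the constant-
# coefficient relaxation toward p1/p2. Independent oracle for the RK4 model.
populationClosedForm <- function(t, p1, p2, ts) {
  b <- p2 / (2 * ts)
  ramp <- function(tt) {
    # N(t) = p1 * exp(-b t^2) * int_0^t exp(b s^2) ds
    #      = p1 * exp(-b t^2) * erfi(sqrt(b) t) * sqrt(pi) / (2 sqrt(b))
    p1 * exp(-b * tt^2) * pracma::erfi(sqrt(b) * tt) * sqrt(pi) /
      (2 * sqrt(b))
  }
  out <- numeric(length(t))
  low <- t <= ts
  out[low] <- ramp(t[low])
  if (any(!low)) {
    Nts <- ramp(ts)
    out[!low] <- p1 / p2 + (Nts - p1 / p2) * exp(-p2 * (t[!low] - ts))
  }
  out
}
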