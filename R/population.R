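# Cluster population dynamics: dN/dt = p1 - alpha(t) p2 N with a linear
# ramp alpha(t) = min(t/ts, 1) on the fusion-driven reduction rate.
# The forward model is classical fixed-step RK4; the constant-coefficient
# (ts -> 0) closed form (p1/p2)(1 - exp(-p2 t)) is kept in the test suite as
# an independent oracle.

#' Solve the cluster population ODE
#'
#' Fixed-step RK4 integration of
#' \eqn{dN/dt = p_1 - \min(t/t_s, 1)\, p_2 N}, \eqn{N(0) = 0}.
#'
#' @param p1 formation rate (clusters/day).
#' @param p2 relative reduction rate (1/day); 0 is allowed (pure growth).
#' @param ts_day ramp stabilization time (day).
#' @param horizon_day integration horizon (day).
#' @param dt_day RK4 step (day); at most 0.01 for reference accuracy.
#' @param times_day optional output times (day); default the RK4 grid.
#' @return data.frame with columns \code{t_day}, \code{N}.
#' @export
simulatePopulation <- function(p1, p2, ts_day, horizon_day, dt_day = 1e-3,
                               times_day = NULL) {
  stopifnot(p1 > 0, p2 >= 0, ts_day > 0, horizon_day > 0, dt_day > 0)
  nstep <- max(1L, ceiling(horizon_day / dt_day))
  h <- horizon_day / nstep
  f <- function(t, N) p1 - min(t / ts_day, 1) * p2 * N
  tt <- numeric(nstep + 1); NN <- numeric(nstep + 1)
  for (i in seq_len(nstep)) {
    t0 <- tt[i]; y <- NN[i]
    k1 <- f(t0, y)
    k2 <- f(t0 + h / 2, y + h / 2 * k1)
    k3 <- f(t0 + h / 2, y + h / 2 * k2)
    k4 <- f(t0 + h, y + h * k3)
    NN[i + 1] <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    tt[i + 1] <- i * h
  }
  if (is.null(times_day)) return(data.frame(t_day = tt, N = NN))
  data.frame(t_day = times_day,
             N = stats::approx(tt, NN, xout = times_day, rule = 2)$y)
}

#' Align count series on their onset
#'
#' Sets \eqn{t = 0} at the onset of cluster formation for each condition:
#' the last zero-count sample before the first strictly positive count (the
#' population law starts from \eqn{N(0) = 0}, so the first positive count
#' belongs at one sampling step after the origin). A series that is zero
#' until day 3 is shifted by 3 days — the uniform shift applied to the low
#' and medium seeding densities — and a series already starting at day 0
#' gets shift 0. Re-aligning an already aligned series is a no-op.
#'
#' @param series a \code{CountSeries} or list of them.
#' @return list of shifted \code{CountSeries} with \code{onsetDay} recorded;
#'   all-zero series are dropped with a warning.
#' @export
alignOnsets <- function(series) {
  if (is(series, "CountSeries")) series <- list(series)
  out <- list()
  for (s in series) {
    d <- s@data
    for (cond in unique(d$condition)) {
      dc <- d[d$condition == cond, , drop = FALSE]
      pos <- which(dc$N > 0)
      if (!length(pos)) {
        warning(sprintf("condition '%s' has no positive counts: excluded",
                        cond))
        next
      }
      onset <- if (pos[1] > 1) dc$t_day[pos[1] - 1] else dc$t_day[1]
      prior <- if (!is.na(s@onsetDay)) s@onsetDay else 0
      dc$t_day <- dc$t_day - onset
      dc <- dc[dc$t_day >= 0, , drop = FALSE]
      out[[length(out) + 1L]] <- new("CountSeries", data = dc,
                                     onsetDay = prior + onset)
    }
  }
  out
}

# pooled (t, N) table from CountSeries input
.poolCounts <- function(series) {
  if (is(series, "CountSeries")) series <- list(series)
  do.call(rbind, lapply(series, function(s) s@data[, c("t_day", "N")]))
}

#' Fit the cluster population dynamics
#'
#' Least squares over \eqn{(p_1, p_2, t_s)} with the RK4 forward model,
#' jointly over all supplied (onset-aligned) series, so one master curve
#' runs through all densities. A coarse multi-start grid
#' (\eqn{p_1 \in [1, 200]}, \eqn{p_2 \in [0.1, 5]}, \eqn{t_s \in [1, 20]})
#' guards against local minima; the best starts are polished by Nelder-Mead
#' on log-parameters. SEs by bootstrap over time points.
#'
#' @param series a \code{CountSeries} or list of them (already shifted; use
#'   \code{\link{alignOnsets}} first when onsets differ).
#' @param nBoot bootstrap resamples for SEs (0 to skip).
#' @param dt_day RK4 step used inside the objective.
#' @param nPolish number of best grid starts refined by Nelder-Mead.
#' @param seed seed for the bootstrap.
#' @return a \code{PopulationFit}.
#' @export
fitPopulation <- function(series, nBoot = 200L, dt_day = 0.01,
                          nPolish = 3L, seed = 1) {
  d <- .poolCounts(series)
  if (nrow(d) < 8) stop("need at least 8 time points to fit")
  horizon <- max(d$t_day)
  sse <- function(logp, dat) {
    p <- exp(logp)
    if (p[1] > 1e4 || p[2] > 1e3 || p[3] > 1e3) return(1e12)
    mod <- simulatePopulation(p[1], p[2], p[3], horizon, dt_day,
                              times_day = dat$t_day)
    sum((dat$N - mod$N)^2)
  }
  fitOnce <- function(dat, starts) {
    vals <- vapply(starts, function(s) sse(log(s), dat), numeric(1))
    best <- order(vals)[seq_len(min(nPolish, length(starts)))]
    res <- lapply(best, function(i)
      stats::optim(log(starts[[i]]), sse, dat = dat,
                   method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-10)))
    res <- res[[which.min(vapply(res, `[[`, numeric(1), "value"))]]
    if (res$convergence != 0)
      warning("population fit: optimizer did not report convergence")
    list(par = exp(res$par), value = res$value)
  }
  starts <- expand.grid(p1 = c(5, 50, 150), p2 = c(0.2, 1, 4),
                        ts = c(2, 8, 16))
  starts <- split(as.matrix(starts), row(starts)[, 1])
  fit <- fitOnce(d, starts)
  p <- fit$par
  resid <- d$N - simulatePopulation(p[1], p[2], p[3], horizon, dt_day,
                                    times_day = d$t_day)$N
  se <- c(p1 = NA_real_, p2 = NA_real_, ts_day = NA_real_)
  if (nBoot > 0) {
    bs <- withSubstream(seed, "population-boot", {
      vapply(seq_len(nBoot), function(b) {
        idx <- sample.int(nrow(d), replace = TRUE)
        fb <- tryCatch(fitOnce(d[idx, , drop = FALSE], list(p)),
                       error = function(e) NULL)
        if (is.null(fb)) rep(NA_real_, 3) else fb$par
      }, numeric(3))
    })
    se <- apply(bs, 1, stats::sd, na.rm = TRUE)
    names(se) <- c("p1", "p2", "ts_day")
  }
  new("PopulationFit", p1 = p[1], p2 = p[2], ts_day = p[3], se = se,
      residualSD = stats::sd(resid), plateau = p[1] / p[2])
}
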