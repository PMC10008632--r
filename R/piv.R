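# Minimal multi-pass cross-correlation PIV: per-window FFT phase-free
# correlation of mean-subtracted windows, three-point Gaussian subpixel peak,
# later passes warp the search window by the previous pass's (integer)
# displacement. Defaults replicate the study settings: three passes to a
# final 32 px window, 0.5 overlap.

# cross-correlation displacement of two equal square windows; returns
# c(u, v) or NA for degenerate (flat) windows
.windowDisplacement <- function(w1, w2) {
  w1 <- w1 - mean(w1); w2 <- w2 - mean(w2)
  if (stats::sd(w1) == 0 || stats::sd(w2) == 0) return(c(NA_real_, NA_real_))
  n <- nrow(w1)
  cc <- Re(stats::fft(Conj(stats::fft(w1)) * stats::fft(w2),
                      inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # wrap to signed displacement
  sgn <- function(i) if (i - 1 > n / 2) i - 1 - n else i - 1
  du <- sgn(pk[1]); dv <- sgn(pk[2])
  # 3-point Gaussian subpixel interpolation (log-parabola), cyclic indexing
  cyc <- function(i) ((i - 1) %% n) + 1
  sub <- function(cm, c0, cp) {
    if (cm <= 0 || c0 <= 0 || cp <= 0) {
      den <- cm - 2 * c0 + cp
      if (den == 0) return(0)
      return(0.5 * (cm - cp) / den)            # parabolic fallback
    }
    den <- 2 * (log(cm) + log(cp) - 2 * log(c0))
    if (den == 0) return(0)
    (log(cm) - log(cp)) / den
  }
  c0 <- cc[pk[1], pk[2]]
  dui <- sub(cc[cyc(pk[1] - 1), pk[2]], c0, cc[cyc(pk[1] + 1), pk[2]])
  dvi <- sub(cc[pk[1], cyc(pk[2] - 1)], c0, cc[pk[1], cyc(pk[2] + 1)])
  c(du + dui, dv + dvi)
}

#' Multi-pass PIV on an image pair
#'
#' @param frame1,frame2 equal-size grayscale matrices indexed \code{[x, y]}.
#' @param passes number of passes; window sizes halve per pass down to
#'   \code{finalWindow} (first pass \code{finalWindow * 2^(passes-1)}).
#' @param finalWindow final interrogation window (px).
#' @param overlap window overlap fraction of the final pass grid.
#' @param dt_s frame interval (s), carried into the result for unit
#'   conversion.
#' @param pixelSize um per pixel, carried into the result.
#' @return a \code{VelocityField} with displacements in px/frame; vectors
#'   from degenerate (flat) windows are marked invalid. Borders without a
#'   full window carry no vector.
#' @export
pivPair <- function(frame1, frame2, passes = 3L, finalWindow = 32L,
                    overlap = 0.5, dt_s = 300, pixelSize = 0.65) {
  stopifnot(all(dim(frame1) == dim(frame2)), passes >= 1,
            finalWindow >= 8, overlap > 0, overlap < 1)
  nx <- nrow(frame1); ny <- ncol(frame1)
  prev <- NULL   # data.frame x, y, u, v from the previous pass
  for (p in seq_len(passes)) {
    W <- finalWindow * 2^(passes - p)
    if (W > min(nx, ny)) next
    step <- max(1L, round(W * (1 - overlap)))
    x0 <- seq(1L, nx - W + 1L, by = step)
    y0 <- seq(1L, ny - W + 1L, by = step)
    res <- expand.grid(x0 = x0, y0 = y0)
    res$xc <- res$x0 + W / 2 - 1  # 0-based window center
    res$yc <- res$y0 + W / 2 - 1
    res$u <- NA_real_; res$v <- NA_real_
    for (k in seq_len(nrow(res))) {
      xs <- res$x0[k]:(res$x0[k] + W - 1L)
      ys <- res$y0[k]:(res$y0[k] + W - 1L)
      shift <- c(0L, 0L)
      if (!is.null(prev)) {
        i <- which.min((prev$xc - res$xc[k])^2 + (prev$yc - res$yc[k])^2)
        if (length(i) && is.finite(prev$u[i]))
          shift <- round(c(prev$u[i], prev$v[i]))
      }
      xs2 <- xs + shift[1]; ys2 <- ys + shift[2]
      if (min(xs2) < 1 || max(xs2) > nx || min(ys2) < 1 || max(ys2) > ny) {
        xs2 <- pmin(pmax(xs2, 1L), nx); ys2 <- pmin(pmax(ys2, 1L), ny)
      }
      d <- .windowDisplacement(frame1[xs, ys], frame2[xs2, ys2])
      res$u[k] <- d[1] + shift[1]
      res$v[k] <- d[2] + shift[2]
    }
    prev <- res
  }
  if (is.null(prev)) stop("image smaller than the first interrogation window")
  out <- data.frame(x_px = prev$xc, y_px = prev$yc, u = prev$u, v = prev$v,
                    valid = is.finite(prev$u) & is.finite(prev$v))
  out$u[!out$valid] <- NA_real_; out$v[!out$valid] <- NA_real_
  new("VelocityField", data = out, dt_s = dt_s, pixelSize = pixelSize,
      vrms_um_h = NA_real_, removedFraction = NA_real_)
}

#' Filter spurious vectors and summarize a velocity field
#'
#' Invalidates vectors whose magnitude exceeds their local mean (3x3 grid
#' neighborhood, center excluded) by three times the standard deviation of
#' magnitudes over the whole field. The field-wide SD makes the rule robust
#' to clustered outliers: two adjacent spurious vectors inflate a 3x3
#' neighborhood SD enough to shield each other, while the global spread
#' still exposes both. Then computes the root-mean-square speed over the
#' remaining valid vectors in um/h using the field's pixel size and frame
#' interval.
#'
#' @param field a \code{VelocityField} from \code{\link{pivPair}}.
#' @param nSD outlier threshold in SDs (default 3).
#' @return the field with updated validity, \code{vrms_um_h} and
#'   \code{removedFraction}; an error if no valid vectors remain.
#' @export
filterVelocityField <- function(field, nSD = 3) {
  d <- seriesData(field)
  if (!any(d$valid)) stop("no valid vectors to summarize")
  nInitial <- sum(d$valid)
  xs <- sort(unique(d$x_px)); ys <- sort(unique(d$y_px))
  ix <- match(d$x_px, xs); iy <- match(d$y_px, ys)
  magAll <- sqrt(d$u^2 + d$v^2)
  mag <- matrix(NA_real_, length(xs), length(ys))
  mag[cbind(ix, iy)] <- ifelse(d$valid, magAll, NA)
  sdGlobal <- stats::sd(magAll[d$valid])
  bad <- logical(nrow(d))
  for (k in seq_len(nrow(d))) {
    if (!d$valid[k]) next
    ii <- max(1, ix[k] - 1):min(length(xs), ix[k] + 1)
    jj <- max(1, iy[k] - 1):min(length(ys), iy[k] + 1)
    nb <- mag[ii, jj]
    nb[ix[k] - ii[1] + 1, iy[k] - jj[1] + 1] <- NA   # exclude self
    nb <- nb[!is.na(nb)]
    if (length(nb) < 3) next
    if (magAll[k] > mean(nb) + nSD * sdGlobal) bad[k] <- TRUE
  }
  d$valid <- d$valid & !bad
  d$u[!d$valid] <- NA_real_; d$v[!d$valid] <- NA_real_
  if (!any(d$valid)) stop("outlier filter removed all vectors")
  toUmH <- field@pixelSize * 3600 / field@dt_s
  speeds <- sqrt(d$u[d$valid]^2 + d$v[d$valid]^2) * toUmH
  new("VelocityField", data = d, dt_s = field@dt_s,
      pixelSize = field@pixelSize,
      vrms_um_h = sqrt(mean(speeds^2)),
      removedFraction = 1 - sum(d$valid) / nInitial)
}
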