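# Mask-based morphometry: connected components (8-connectivity),
# moments-based ellipse metrics, subpixel contour perimeters,
# nearest-centroid tracking, hole width and fusion-neck measurement.
# This module consumes binary masks; it does not segment grayscale images.

#' Label a binary mask with 8-connectivity
#'
#' EBImage's \code{bwlabel} uses 4-connectivity; diagonal-adjacent labels are
#' merged afterwards (union-find) so diagonally touching pixels form one
#' object.
#'
#' @param mask numeric 0/1 matrix indexed \code{[x, y]}.
#' @return integer label matrix (0 = background).
#' @export
labelMask8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- min(ri, rj) # no-op guard
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nx <- nrow(lab); ny <- ncol(lab)
  # diagonal neighbor pairs with different nonzero labels
  a <- lab[-nx, -ny]; b <- lab[-1, -1]
  w <- which(a > 0 & b > 0 & a != b)
  for (i in w) union(a[i], b[i])
  a <- lab[-1, -ny]; b <- lab[-nx, -1]
  w <- which(a > 0 & b > 0 & a != b)
  for (i in w) union(a[i], b[i])
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

# circular moving-average smoothing of a closed polygon, then arc length;
# subpixel marching-squares contours of a binary mask overestimate smooth
# perimeters by ~6% from staircasing, smoothing removes the bias
.contourPerimeter <- function(submask, k = 5L) {
  cl <- grDevices::contourLines(x = seq_len(nrow(submask)),
                                y = seq_len(ncol(submask)),
                                z = submask, levels = 0.5)
  if (!length(cl)) return(NA_real_)
  lens <- vapply(cl, function(cc) length(cc$x), integer(1))
  cc <- cl[[which.max(lens)]]               # outer boundary
  x <- cc$x[-1]; y <- cc$y[-1]              # closed: first == last
  n <- length(x)
  kk <- max(0L, min(k, (n - 1L) %/% 3L))
  if (kk > 0) {
    sm <- function(v) {
      vv <- c(utils::tail(v, kk), v, utils::head(v, kk))
      as.numeric(stats::filter(vv, rep(1 / (2 * kk + 1), 2 * kk + 1)))[
        (kk + 1):(kk + n)]
    }
    x <- sm(x); y <- sm(y)
  }
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# subpixel outer contour of one object (0-based pixel coordinates)
.objectContour <- function(mask01) {
  cl <- grDevices::contourLines(x = seq_len(nrow(mask01)),
                                y = seq_len(ncol(mask01)),
                                z = mask01, levels = 0.5)
  if (!length(cl)) return(NULL)
  lens <- vapply(cl, function(cc) length(cc$x), integer(1))
  cc <- cl[[which.max(lens)]]
  cbind(x = cc$x - 1, y = cc$y - 1)
}

# Shape metrics for the pixels of one labeled object. Second central moments
# (plus the 1/12 unit-square pixel term) give the ellipse semi-axes:
# semi-axis = 2*sqrt(eigenvalue), exact for an ideal ellipse.
.shapeMetrics <- function(lab, l, pixelSize) {
  idx <- which(lab == l, arr.ind = TRUE)
  x <- idx[, 1] - 1; y <- idx[, 2] - 1
  npx <- length(x)
  cx <- mean(x); cy <- mean(y)
  mxx <- mean((x - cx)^2) + 1 / 12
  myy <- mean((y - cy)^2) + 1 / 12
  mxy <- mean((x - cx) * (y - cy))
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2), symmetric = TRUE)
  major_px <- 2 * sqrt(max(ev$values))
  minor_px <- 2 * sqrt(max(min(ev$values), 0))
  theta <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  # perimeter on a padded crop for the subpixel contour
  pad <- 2L
  xr <- range(idx[, 1]); yr <- range(idx[, 2])
  sub <- matrix(0, diff(xr) + 1 + 2 * pad, diff(yr) + 1 + 2 * pad)
  sub[cbind(idx[, 1] - xr[1] + 1 + pad, idx[, 2] - yr[1] + 1 + pad)] <- 1
  P_px <- .contourPerimeter(sub)
  list(area_px = npx, cx_px = cx, cy_px = cy, major_px = major_px,
       minor_px = minor_px, theta = theta, perim_px = P_px,
       area_um2 = npx * pixelSize^2, perimeter_um = P_px * pixelSize,
       major_um = major_px * pixelSize, minor_um = minor_px * pixelSize,
       cx_um = cx * pixelSize, cy_um = cy * pixelSize)
}

# circularity with the digitization allowance: (1, 1.02] clamps to 1,
# beyond 1.02 is a measurement failure (NA + flag)
.circularity <- function(area_um2, perimeter_um) {
  circ <- 4 * pi * area_um2 / perimeter_um^2
  flag <- character(0)
  if (is.na(circ)) return(list(circ = NA_real_, flag = "no contour"))
  if (circ > 1.02) {
    flag <- sprintf("circularity %.3f > 1.02: measurement failure", circ)
    circ <- NA_real_
  } else if (circ > 1) {
    flag <- sprintf("circularity %.4f clamped to 1", circ)
    circ <- 1
  }
  list(circ = circ, flag = flag)
}

#' Label and track objects through a mask stack
#'
#' Per frame: 8-connected components, components below \code{minArea_um2}
#' dropped, ellipse metrics from second central moments, perimeter from the
#' smoothed subpixel contour. Frames are linked by nearest centroid within a
#' gate of three times the median per-frame displacement (floored at 3 px);
#' when two candidates fall inside the gate the smaller area change wins and
#' the ambiguity is flagged on the track. Empty frames yield gaps, not
#' failures.
#'
#' @param stack list of 0/1 matrices indexed \code{[x, y]} (or one matrix).
#' @param minArea_um2 minimum object area kept (default 100).
#' @param pixelSize um per pixel (default 0.65).
#' @param dt_s frame interval in seconds (default 1200).
#' @return list of \code{ShapeTrack}.
#' @export
labelAndTrack <- function(stack, minArea_um2 = 100, pixelSize = 0.65,
                          dt_s = 1200) {
  if (is.matrix(stack)) stack <- list(stack)
  perFrame <- lapply(seq_along(stack), function(i) {
    lab <- labelMask8(stack[[i]])
    ls <- setdiff(sort(unique(as.vector(lab))), 0L)
    rows <- list()
    for (l in ls) {
      m <- .shapeMetrics(lab, l, pixelSize)
      if (m$area_um2 < minArea_um2) next
      cc <- .circularity(m$area_um2, m$perimeter_um)
      rows[[length(rows) + 1L]] <- c(m, circ = cc$circ,
                                     flag = list(cc$flag))
    }
    rows
  })
  tracks <- list()   # each: list(id, rows=list, lastC=c(x,y), lastA, flags)
  nextId <- 1L
  for (i in seq_along(perFrame)) {
    objs <- perFrame[[i]]
    t_s <- (i - 1) * dt_s
    if (!length(objs)) next
    oc <- t(vapply(objs, function(o) c(o$cx_px, o$cy_px), numeric(2)))
    active <- which(vapply(tracks, function(tr) tr$lastFrame == i - 1L,
                           logical(1)))
    assigned <- rep(FALSE, length(objs))
    if (length(active)) {
      tc <- t(vapply(tracks[active], function(tr) tr$lastC, numeric(2)))
      D <- sqrt(outer(tc[, 1], oc[, 1], "-")^2 +
                outer(tc[, 2], oc[, 2], "-")^2)
      nearest <- apply(D, 1, min)
      gate <- max(3 * stats::median(nearest), 3)
      ord <- order(D)
      usedT <- rep(FALSE, length(active))
      for (k in ord) {
        ti <- (k - 1) %% length(active) + 1
        oi <- (k - 1) %/% length(active) + 1
        if (D[ti, oi] > gate) break
        if (usedT[ti] || assigned[oi]) next
        cand <- which(D[ti, ] <= gate & !assigned)
        oi2 <- oi
        if (length(cand) > 1) {
          dA <- abs(vapply(objs[cand], `[[`, numeric(1), "area_um2") -
                      tracks[[active[ti]]]$lastA)
          oi2 <- cand[which.min(dA)]
          tracks[[active[ti]]]$flags <- c(
            tracks[[active[ti]]]$flags,
            sprintf("frame %d: ambiguous link, resolved by area", i))
        }
        usedT[ti] <- TRUE; assigned[oi2] <- TRUE
        tr <- tracks[[active[ti]]]
        tr$rows[[length(tr$rows) + 1L]] <- c(objs[[oi2]], t_s = t_s)
        tr$lastC <- c(objs[[oi2]]$cx_px, objs[[oi2]]$cy_px)
        tr$lastA <- objs[[oi2]]$area_um2
        tr$lastFrame <- i
        tracks[[active[ti]]] <- tr
      }
    }
    for (oi in which(!assigned)) {
      tracks[[length(tracks) + 1L]] <- list(
        id = nextId, rows = list(c(objs[[oi]], t_s = t_s)),
        lastC = c(objs[[oi]]$cx_px, objs[[oi]]$cy_px),
        lastA = objs[[oi]]$area_um2, lastFrame = i, flags = character(0))
      nextId <- nextId + 1L
    }
  }
  lapply(tracks, function(tr) {
    d <- do.call(rbind, lapply(tr$rows, function(r) {
      a <- r$major_um; c. <- r$minor_um
      data.frame(t_s = r$t_s, area_um2 = r$area_um2,
                 perimeter_um = r$perimeter_um, circ = r$circ,
                 major_um = a, minor_um = c.,
                 eps = (c. - a) / (c. + a), r_um = (2 * a + c.) / 3,
                 cx_um = r$cx_um, cy_um = r$cy_um)
    }))
    flags <- unique(c(tr$flags,
                      unlist(lapply(tr$rows, `[[`, "flag"))))
    new("ShapeTrack", objectId = as.integer(tr$id), data = d,
        pixelSize = pixelSize, flags = flags)
  })
}

#' Measure an enclosed hole through a mask stack
#'
#' The hole is the largest background component fully enclosed by the
#' foreground sheet (border-touching background is outside). Width is the
#' extent of the hole perpendicular to its long axis: the full minor ellipse
#' axis of the hole component from second moments. Optionally extracts
#' tip-profile points from the subpixel contour within a caliper window
#' around the advancing end, rotated into the propagation frame (x measured
#' backwards from the tip, x >= 0).
#'
#' @param stack list of 0/1 sheet masks (1 = cells), or one matrix.
#' @param pixelSize um per pixel.
#' @param dt_s frame interval (s).
#' @param profileFrame frame index from which to extract the tip profile
#'   (NULL for none; "last" for the final frame with a hole).
#' @param axisHint propagation direction in radians (NULL: the hole's major
#'   axis, positive end).
#' @param caliper_px half-window behind the tip for profile points.
#' @param minArea_px smallest background component considered a hole.
#' @return a \code{HoleSeries}; frames without an enclosed hole contribute
#'   width 0 before the first hole and are dropped after it.
#' @export
measureHole <- function(stack, pixelSize = 0.65, dt_s = 300,
                        profileFrame = NULL, axisHint = NULL,
                        caliper_px = 40, minArea_px = 9) {
  if (is.matrix(stack)) stack <- list(stack)
  if (identical(profileFrame, "last")) profileFrame <- length(stack)
  widths <- numeric(0); times <- numeric(0)
  profile <- data.frame(x_um = numeric(0), y_um = numeric(0))
  for (i in seq_along(stack)) {
    m <- stack[[i]]
    bg <- 1 - m
    lab <- labelMask8(bg)
    if (max(lab) == 0) { widths <- c(widths, 0)
                         times <- c(times, (i - 1) * dt_s); next }
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                       lab[, ncol(lab)]))
    inner <- setdiff(seq_len(max(lab)), c(0L, border))
    sizes <- vapply(inner, function(l) sum(lab == l), numeric(1))
    inner <- inner[sizes >= minArea_px]
    sizes <- sizes[sizes >= minArea_px]
    if (!length(inner)) {
      # no enclosed hole: width 0 (intact sheet); a frame with no sheet at
      # all contributes nothing
      if (sum(m) > 0) { widths <- c(widths, 0)
                        times <- c(times, (i - 1) * dt_s) }
      next
    }
    l <- inner[which.max(sizes)]
    met <- .shapeMetrics(lab, l, pixelSize)
    widths <- c(widths, 2 * met$minor_um)
    times <- c(times, (i - 1) * dt_s)
    if (!is.null(profileFrame) && i == profileFrame) {
      hole01 <- matrix(0, nrow(lab), ncol(lab)); hole01[lab == l] <- 1
      ct <- .objectContour(hole01)
      if (!is.null(ct)) {
        phi <- if (is.null(axisHint)) met$theta else axisHint
        ax <- c(cos(phi), sin(phi))
        proj <- ct %*% ax
        perp <- ct %*% c(-ax[2], ax[1])
        tip <- which.max(proj)
        xb <- as.numeric(proj[tip] - proj)       # px behind the tip
        yb <- as.numeric(perp - perp[tip])
        keep <- xb >= 0 & xb <= caliper_px
        profile <- data.frame(x_um = xb[keep] * pixelSize,
                              y_um = yb[keep] * pixelSize)
      }
    }
  }
  if (!any(widths > 0))
    return(new("HoleSeries", pixelSize = pixelSize))
  new("HoleSeries", data = data.frame(t_s = times, width_um = widths),
      profile = profile, pixelSize = pixelSize)
}

#' Measure the fusion neck of a cluster doublet
#'
#' The neck radius is half the minimal cross-width of the object along scan
#' lines perpendicular to the centroid--centroid axis, restricted to the
#' inter-centroid span. Initial areas are taken from the last frame where
#' the lobes are separate components; when they touch from the first frame,
#' the first frame is split at the minimal cross-section instead.
#'
#' @param stack list of 0/1 doublet masks.
#' @param centers 2x2 matrix of lobe centers (rows; 0-based px), e.g. the
#'   \code{"centers_px"} attribute of \code{\link{simulateFusionSeries}}.
#'   NULL: taken from the two largest components of the first frame (or the
#'   split halves when already fused).
#' @param pixelSize um per pixel.
#' @param dt_s frame interval (s).
#' @return a \code{FusionSeries}; an error if any frame holds more than two
#'   lobes.
#' @export
measureNeck <- function(stack, centers = NULL, pixelSize = 0.65,
                        dt_s = 1200) {
  if (is.matrix(stack)) stack <- list(stack)
  first <- stack[[1]]
  lab1 <- labelMask8(first)
  ncomp1 <- max(lab1)
  if (is.null(centers)) {
    if (ncomp1 >= 2) {
      sizes <- vapply(seq_len(ncomp1), function(l) sum(lab1 == l),
                      numeric(1))
      top <- order(sizes, decreasing = TRUE)[1:2]
      centers <- t(vapply(top, function(l) {
        idx <- which(lab1 == l, arr.ind = TRUE)
        c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
      }, numeric(2)))
    } else {
      stop("centers are required when the lobes touch from the first frame")
    }
  }
  centers <- as.matrix(centers)
  ax <- centers[2, ] - centers[1, ]
  L <- sqrt(sum(ax^2)); ax <- ax / L
  crossWidths <- function(mask) {
    idx <- which(mask > 0, arr.ind = TRUE)
    x <- idx[, 1] - 1; y <- idx[, 2] - 1
    u <- (x - centers[1, 1]) * ax[1] + (y - centers[1, 2]) * ax[2]
    v <- -(x - centers[1, 1]) * ax[2] + (y - centers[1, 2]) * ax[1]
    inside <- u > 2 & u < L - 2     # strictly between the centroids
    if (!any(inside)) return(0)
    bin <- floor(u[inside])
    ext <- tapply(v[inside], bin, function(vv) diff(range(vv)) + 1)
    full <- setdiff(seq(3, floor(L) - 3), as.integer(names(ext)))
    if (length(full)) return(0)     # a gap: lobes not in contact
    min(ext)
  }
  rho <- numeric(length(stack)); nlob <- integer(length(stack))
  for (i in seq_along(stack)) {
    lab <- labelMask8(stack[[i]])
    big <- sum(vapply(seq_len(max(lab)), function(l) sum(lab == l),
                      numeric(1)) >= 9)
    nlob[i] <- big
    if (big > 2) stop(sprintf("frame %d holds %d lobes (expected <= 2)",
                              i, big))
    rho[i] <- if (big == 2) 0 else crossWidths(stack[[i]]) / 2 * pixelSize
  }
  # initial areas from the last pre-contact frame, else split frame 1
  pre <- which(nlob == 2)
  if (length(pre)) {
    lab <- labelMask8(stack[[max(pre)]])
    sizes <- sort(vapply(seq_len(max(lab)), function(l) sum(lab == l),
                         numeric(1)), decreasing = TRUE)[1:2]
    A1 <- sizes[1] * pixelSize^2; A2 <- sizes[2] * pixelSize^2
  } else {
    idx <- which(first > 0, arr.ind = TRUE)
    u <- (idx[, 1] - 1 - centers[1, 1]) * ax[1] +
      (idx[, 2] - 1 - centers[1, 2]) * ax[2]
    # split at the minimal cross-section
    usplit <- L / 2
    A1 <- sum(u < usplit) * pixelSize^2
    A2 <- sum(u >= usplit) * pixelSize^2
  }
  new("FusionSeries",
      data = data.frame(t_s = (seq_along(stack) - 1) * dt_s, rho_um = rho),
      A1_um2 = A1, A2_um2 = A2, R0_um = sqrt((A1 + A2) / (2 * pi)))
}
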