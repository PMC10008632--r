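# Mask rendering. One fixed raster dialect everywhere: masks are numeric 0/1
# matrices indexed [x, y] (EBImage convention), pixel centers at integer
# coordinates, origin top-left, x right, y down, 0-based. TIFF I/O transposes
# to the row-major layout the format expects.

pixelGrid <- function(shape) {
  list(x = matrix(rep(0:(shape[1] - 1), shape[2]), shape[1], shape[2]),
       y = matrix(rep(0:(shape[2] - 1), each = shape[1]),
                  shape[1], shape[2]))
}

#' Render an ellipse mask
#'
#' @param shape image size in pixels, \code{c(nx, ny)}.
#' @param cx,cy center in pixel coordinates (0-based).
#' @param a,b semi-axes in pixels along the (rotated) x and y directions.
#' @param phi rotation of the a-axis in radians (counterclockwise in pixel
#'   coordinates).
#' @return numeric 0/1 matrix indexed \code{[x, y]}.
#' @export
renderEllipseMask <- function(shape, cx, cy, a, b, phi = 0) {
  stopifnot(a > 0, b > 0, length(shape) == 2)
  g <- pixelGrid(shape)
  dx <- g$x - cx; dy <- g$y - cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  storage.mode(mask) <- "numeric"
  mask
}

#' Render a disc mask
#'
#' @inheritParams renderEllipseMask
#' @param r radius in pixels.
#' @export
renderDiscMask <- function(shape, cx, cy, r)
  renderEllipseMask(shape, cx, cy, r, r)

#' Render a coalescing-doublet mask
#'
#' Two discs at fixed centers joined by a tangent-capped bridge of half-width
#' \code{rho} spanning the inter-center segment. The minimal cross-section of
#' the object perpendicular to the center axis equals \code{2 rho} whenever
#' \code{rho} is below both disc radii.
#'
#' @param shape image size \code{c(nx, ny)}.
#' @param c1,c2 centers, each \code{c(x, y)} in 0-based pixel coordinates.
#' @param R1,R2 disc radii in pixels.
#' @param rho neck half-width in pixels (0 for detached discs).
#' @export
renderDoubletMask <- function(shape, c1, c2, R1, R2, rho = 0) {
  stopifnot(R1 > 0, R2 > 0, rho >= 0)
  g <- pixelGrid(shape)
  m1 <- (g$x - c1[1])^2 + (g$y - c1[2])^2 <= R1^2
  m2 <- (g$x - c2[1])^2 + (g$y - c2[2])^2 <= R2^2
  mask <- m1 | m2
  if (rho > 0) {
    ax <- c2 - c1; L <- sqrt(sum(ax^2)); ax <- ax / L
    u <- (g$x - c1[1]) * ax[1] + (g$y - c1[2]) * ax[2]
    v <- -(g$x - c1[1]) * ax[2] + (g$y - c1[2]) * ax[1]
    mask <- mask | (u >= 0 & u <= L & abs(v) <= rho)
  }
  storage.mode(mask) <- "numeric"
  mask
}

#' Render a sheet-with-hole mask
#'
#' Foreground sheet (1) covering the frame with an enclosed elliptical hole
#' (0); used by the hole-opening generator.
#'
#' @param shape image size \code{c(nx, ny)}.
#' @param cx,cy hole center (0-based pixels).
#' @param halfLength semi-axis along the propagation direction (px).
#' @param halfWidth semi-axis across it (px); 0 yields an intact sheet.
#' @param phi propagation direction in radians.
#' @export
renderHoleMask <- function(shape, cx, cy, halfLength, halfWidth, phi = 0) {
  sheet <- matrix(1, shape[1], shape[2])
  if (halfWidth > 0 && halfLength > 0)
    sheet <- sheet * (1 - renderEllipseMask(shape, cx, cy, halfLength,
                                            halfWidth, phi))
  sheet
}

#' Render line-segment fiber texture
#'
#' Draws bright oriented segments on a dark background, one per supplied
#' angle, at random positions. Serves as a fixture for structure-tensor
#' orientation estimation.
#'
#' @param theta segment angles in radians (nematic, mod pi).
#' @param shape image size \code{c(nx, ny)}.
#' @param length segment length in pixels.
#' @param width segment half-width in pixels.
#' @param seed RNG seed for segment placement.
#' @return numeric matrix in \code{[0, 1]} indexed \code{[x, y]}.
#' @export
renderFiberTexture <- function(theta, shape = c(256, 256), length = 31,
                               width = 1, seed = 1) {
  img <- matrix(0, shape[1], shape[2])
  withSubstream(seed, "fiber-texture", {
    cx <- stats::runif(base::length(theta), length, shape[1] - 1 - length)
    cy <- stats::runif(base::length(theta), length, shape[2] - 1 - length)
    for (i in seq_along(theta)) {
      tseq <- seq(-length / 2, length / 2, by = 0.25)
      for (w in seq(-width, width, by = 0.25)) {
        px <- cx[i] + tseq * cos(theta[i]) - w * sin(theta[i])
        py <- cy[i] + tseq * sin(theta[i]) + w * cos(theta[i])
        # bilinear splat: subpixel positions anti-aliased onto the grid
        x0 <- floor(px); y0 <- floor(py)
        fx <- px - x0; fy <- py - y0
        for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
          xi <- x0 + corner[1] + 1; yi <- y0 + corner[2] + 1
          wt <- abs(corner[1] - (1 - fx)) * abs(corner[2] - (1 - fy))
          ok <- xi >= 1 & xi <= shape[1] & yi >= 1 & yi <= shape[2]
          idx <- cbind(xi[ok], yi[ok])
          img[idx] <- img[idx] + 0.25 * wt[ok]
        }
      }
    }
  })
  pmin(img, 1)
}

#' Write a mask or image stack as multi-page TIFF
#'
#' Masks are written 8-bit with foreground 255; grayscale textures 16-bit.
#'
#' @param stack a matrix or list of matrices indexed \code{[x, y]}.
#' @param path output file.
#' @param bits 8 (masks) or 16 (textures).
#' @export
writeMaskStack <- function(stack, path, bits = 8L) {
  if (is.matrix(stack)) stack <- list(stack)
  pages <- lapply(stack, function(m) t(pmin(pmax(m, 0), 1)))
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file.
#' @return list of numeric matrices indexed \code{[x, y]} with values in
#'   \code{[0, 1]}.
#' @export
readMaskStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    t(p)
  })
}
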