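#' Image sequence container
#'
#' A `tag_sequence` holds T frames of a scalar image sampled on a regular 2D
#' grid, together with the pixel spacing, the frame interval and the
#' acquisition start time. The coordinate convention used throughout the
#' package is pixel-center, 0-based: pixel `[i, j]` (1-based R indices) sits
#' at physical position `((i - 1) * spacing[1], (j - 1) * spacing[2])` in mm,
#' with the first array dimension along x1 and the second along x2.
#'
#' @param frames numeric array `nx x ny x T` (a matrix is promoted to a
#'   single frame).
#' @param spacing pixel spacing in mm, scalar or length-2 vector.
#' @param dt frame interval in seconds.
#' @param t0 time of the first frame in seconds (reference time,
#'   end-diastole by convention).
#' @return An object of class `tag_sequence`.
#' @export
tag_sequence <- function(frames, spacing = 1, dt = 1, t0 = 0) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            all(spacing > 0), dt > 0)
  structure(
    list(frames = frames, spacing = rep_len(as.numeric(spacing), 2L),
         dt = as.numeric(dt), t0 = as.numeric(t0)),
    class = "tag_sequence"
  )
}

#' @export
print.tag_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("tag_sequence: %d x %d pixels, %d frames, spacing %g x %g mm, dt %g s, t0 %g s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$dt, x$t0))
  invisible(x)
}

n_frames <- function(seq) dim(seq$frames)[3]

frame_times <- function(seq) seq$t0 + (seq_len(n_frames(seq)) - 1L) * seq$dt

#' Physical coordinates of all pixel centers
#'
#' @param nx,ny grid size in pixels.
#' @param spacing pixel spacing in mm (scalar or length 2).
#' @return List with matrices `x1`, `x2` (each `nx x ny`, mm).
#' @export
pixel_coords <- function(nx, ny, spacing = 1) {
  spacing <- rep_len(spacing, 2L)
  list(x1 = matrix((seq_len(nx) - 1) * spacing[1], nx, ny),
       x2 = matrix((seq_len(ny) - 1) * spacing[2], nx, ny, byrow = TRUE))
}

#' Annular region-of-interest mask
#'
#' Logical mask selecting pixels whose distance from `center` lies in
#' `[r_inner, r_outer]` (mm), used as the myocardial ROI on phantom data.
#'
#' @param nx,ny grid size in pixels.
#' @param spacing pixel spacing in mm.
#' @param center annulus center in mm (length 2).
#' @param r_inner,r_outer inner and outer radii in mm.
#' @return Logical `nx x ny` matrix.
#' @export
annulus_mask <- function(nx, ny, spacing, center, r_inner, r_outer) {
  xc <- pixel_coords(nx, ny, spacing)
  r <- sqrt((xc$x1 - center[1])^2 + (xc$x2 - center[2])^2)
  r >= r_inner & r <= r_outer
}

## Bilinear interpolation of an image at physical positions (2 x m matrix).
## Returns NA outside the grid. `validity`: logical matrix; a query whose
## four neighbors are not all valid returns NA.
bilinear <- function(img, pts, spacing, validity = NULL) {
  spacing <- rep_len(spacing, 2L)
  n1 <- nrow(img); n2 <- ncol(img)
  u <- pts[1, ] / spacing[1] # 0-based continuous index
  v <- pts[2, ] / spacing[2]
  i0 <- floor(u); j0 <- floor(v)
  fu <- u - i0; fv <- v - j0
  # queries exactly on the far edge are clamped into the last cell
  atx <- u == n1 - 1; aty <- v == n2 - 1
  i0[atx] <- n1 - 2; fu[atx] <- 1
  j0[aty] <- n2 - 2; fv[aty] <- 1
  ok <- (i0 >= 0 & i0 <= n1 - 2) & (j0 >= 0 & j0 <= n2 - 2)
  out <- rep(NA_real_, length(u))
  if (any(ok)) {
    ii <- i0[ok] + 1L; jj <- j0[ok] + 1L
    a <- fu[ok]; b <- fv[ok]
    v00 <- img[cbind(ii, jj)];     v10 <- img[cbind(ii + 1L, jj)]
    v01 <- img[cbind(ii, jj + 1L)]; v11 <- img[cbind(ii + 1L, jj + 1L)]
    out[ok] <- (1 - a) * (1 - b) * v00 + a * (1 - b) * v10 +
               (1 - a) * b * v01 + a * b * v11
    if (!is.null(validity)) {
      good <- validity[cbind(ii, jj)] & validity[cbind(ii + 1L, jj)] &
              validity[cbind(ii, jj + 1L)] & validity[cbind(ii + 1L, jj + 1L)]
      out[ok][!good] <- NA_real_
    }
  }
  out
}
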