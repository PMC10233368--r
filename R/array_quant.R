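#' Fit the dot lattice on a membrane image
#'
#' Detects spots in either channel by thresholding at the channel median
#' plus `detect_k` robust SDs (MAD), labels connected components, and fits
#' a least-squares affine lattice (origin, per-axis spacing, rotation) to
#' the component centroids.  The initial rotation estimate is the median
#' orientation of nearest-neighbour spot pairs; index assignment and the
#' affine fit are then iterated so that small rotations (a few degrees)
#' and missing spots are handled.  This replaces interactive gridding of
#' the membrane with an automatic, testable fit.
#'
#' @param image Two-channel membrane: `list(signal =, control =)` numeric
#'   matrices, as produced by [generate_screen()] or [read_membrane_tiff()].
#' @param rows,cols Expected grid dimensions.
#' @param detect_k Detection threshold in MADs above the median
#'   (default 5).
#' @param min_spot_px Minimum component area in pixels (default 4).
#' @param max_residual Gridding fails if the RMS residual of detected
#'   centroids about the fitted lattice exceeds this fraction of the
#'   spacing (default 0.25).
#' @return Object of class `array_grid`: list with `origin` (pixel
#'   coordinates `c(x, y)` of grid position row 1, col 1), `spacing`
#'   (`c(dx, dy)` pixels), `rotation` (radians), `rows`, `cols`,
#'   `roi_radius` (0.4 x min spacing), `residual_rms` (pixels) and
#'   `n_spots` used in the fit.
#' @export
fit_grid <- function(image, rows, cols, detect_k = 5, min_spot_px = 4L,
                     max_residual = 0.25) {
  stopifnot(is.list(image), !is.null(image$signal), !is.null(image$control))
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < 4L) stop("rows * cols must be >= 4")
  cent <- detect_spot_centroids(image, detect_k, min_spot_px)
  if (nrow(cent) < 4L) stop("no spots detected: cannot fit grid")

  # robust spacing estimate from nearest-neighbour distances
  d <- as.matrix(stats::dist(cent))
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  sp0 <- stats::median(nn)

  # rotation from the orientation of axially adjacent spot pairs, folded to
  # [-45, 45) degrees so horizontal and vertical neighbours agree; the band
  # stays below sqrt(2) x spacing so diagonal pairs cannot contaminate it
  adj <- which(d > 0.8 * sp0 & d < 1.25 * sp0, arr.ind = TRUE)
  adj <- adj[adj[, 1L] < adj[, 2L], , drop = FALSE]
  ang <- atan2(cent$y[adj[, 2L]] - cent$y[adj[, 1L]],
               cent$x[adj[, 2L]] - cent$x[adj[, 1L]]) * 180 / pi
  ang <- ang - 90 * round(ang / 90)
  th0 <- stats::median(ang) * pi / 180

  # derotate, assign integer lattice indices, then iterate affine fits
  cx <- mean(cent$x); cy <- mean(cent$y)
  xr <- cos(-th0) * (cent$x - cx) - sin(-th0) * (cent$y - cy)
  yr <- sin(-th0) * (cent$x - cx) + cos(-th0) * (cent$y - cy)
  ix <- round((xr - min(xr)) / sp0)
  iy <- round((yr - min(yr)) / sp0)
  fit <- NULL
  for (it in 1:3) {
    fx <- stats::lm.fit(cbind(1, ix, iy), cent$x)
    fy <- stats::lm.fit(cbind(1, ix, iy), cent$y)
    A <- rbind(c(fx$coefficients[2L], fx$coefficients[3L]),
               c(fy$coefficients[2L], fy$coefficients[3L]))
    o <- c(fx$coefficients[1L], fy$coefficients[1L])
    inv <- solve(A)
    ij <- t(inv %*% rbind(cent$x - o[1L], cent$y - o[2L]))
    ix <- pmin(pmax(round(ij[, 1L]), 0L), cols - 1L)
    iy <- pmin(pmax(round(ij[, 2L]), 0L), rows - 1L)
    fit <- list(A = A, o = o)
  }
  pred_x <- fit$o[1L] + fit$A[1L, 1L] * ix + fit$A[1L, 2L] * iy
  pred_y <- fit$o[2L] + fit$A[2L, 1L] * ix + fit$A[2L, 2L] * iy
  res <- sqrt(mean((cent$x - pred_x)^2 + (cent$y - pred_y)^2))
  dx <- sqrt(sum(fit$A[, 1L]^2)); dy <- sqrt(sum(fit$A[, 2L]^2))
  if (res > max_residual * min(dx, dy))
    stop(sprintf("grid fit failed: residual RMS %.2f px exceeds %.2f px",
                 res, max_residual * min(dx, dy)))
  structure(list(origin = c(x = unname(fit$o[1L]), y = unname(fit$o[2L])),
                 spacing = c(dx = dx, dy = dy),
                 rotation = atan2(fit$A[2L, 1L], fit$A[1L, 1L]),
                 rows = rows, cols = cols,
                 roi_radius = 0.4 * min(dx, dy),
                 residual_rms = res, n_spots = nrow(cent)),
            class = "array_grid")
}

detect_spot_centroids <- function(image, detect_k, min_spot_px) {
  mask <- matrix(FALSE, nrow(image$signal), ncol(image$signal))
  for (ch in c("signal", "control")) {
    m <- image[[ch]]
    thr <- stats::median(m) + detect_k * stats::mad(m)
    mask <- mask | (m > thr)
  }
  if (!any(mask)) return(data.frame(x = numeric(0), y = numeric(0)))
  lab <- EBImage::bwlabel(mask * 1)
  idx <- which(lab > 0)
  l <- lab[idx]
  yy <- (idx - 1L) %% nrow(lab) + 1L
  xx <- (idx - 1L) %/% nrow(lab) + 1L
  area <- tabulate(l)
  keep <- which(area >= min_spot_px)
  sel <- l %in% keep
  data.frame(x = as.numeric(tapply(xx[sel], l[sel], mean)),
             y = as.numeric(tapply(yy[sel], l[sel], mean)))
}

#' Predicted dot centers of a fitted grid
#'
#' @param grid An `array_grid` from [fit_grid()].
#' @return Data frame `row, col, x, y` in row-major order (1-based grid
#'   indices, pixel coordinates).
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "array_grid"))
  g <- expand.grid(col = seq_len(grid$cols), row = seq_len(grid$rows))
  th <- grid$rotation
  A <- rbind(c(cos(th) * grid$spacing["dx"], -sin(th) * grid$spacing["dy"]),
             c(sin(th) * grid$spacing["dx"],  cos(th) * grid$spacing["dy"]))
  data.frame(row = g$row, col = g$col,
             x = grid$origin["x"] + A[1L, 1L] * (g$col - 1) +
               A[1L, 2L] * (g$row - 1),
             y = grid$origin["y"] + A[2L, 1L] * (g$col - 1) +
               A[2L, 2L] * (g$row - 1),
             row.names = NULL)
}

#' @export
print.array_grid <- function(x, ...) {
  cat(sprintf("array_grid: %d x %d, origin (%.1f, %.1f), spacing (%.2f, %.2f) px, rotation %.3f deg\n",
              x$rows, x$cols, x$origin["x"], x$origin["y"],
              x$spacing["dx"], x$spacing["dy"], x$rotation * 180 / pi))
  cat(sprintf("  fit: %d spots, residual RMS %.3f px; ROI radius %.2f px\n",
              x$n_spots, x$residual_rms, x$roi_radius))
  invisible(x)
}

#' Measure every dot of a gridded membrane
#'
#' For each grid position, sums pixel intensities over a disk ROI of
#' radius `grid$roi_radius` in each channel, estimates the local
#' background per channel as the median of an annulus around the ROI, and
#' reports the background-subtracted sum, clipped at zero (intensities
#' are physical nonnegatives and downstream ratios must not change sign).
#' ROIs that extend past the image border are measured on the available
#' pixels and flagged `truncated_roi` rather than dropped.
#'
#' @param image Two-channel membrane (`list(signal =, control =)`).
#' @param grid An `array_grid` from [fit_grid()].
#' @param annulus Background annulus radii as fractions of the minimum
#'   spacing, `c(inner, outer)` (default `c(0.45, 0.5)`, just outside the
#'   ROI and inside the neighbouring dots at standard 1,536 density).
#' @return Data frame in row-major grid order, one row per position:
#'   `row, col, x, y, signal_raw, control_raw, signal_bg, control_bg,
#'   signal_corrected, control_corrected, flags` (per-pixel background
#'   estimates; `*_corrected = max(raw - bg * area, 0)`).
#' @export
quantify_dots <- function(image, grid, annulus = c(0.45, 0.5)) {
  stopifnot(inherits(grid, "array_grid"))
  ctr <- grid_centers(grid)
  sp <- min(grid$spacing)
  r_roi <- grid$roi_radius
  r_in <- annulus[1L] * sp
  r_out <- annulus[2L] * sp
  h <- nrow(image$signal); w <- ncol(image$signal)
  n <- nrow(ctr)
  out <- data.frame(ctr,
                    signal_raw = numeric(n), control_raw = numeric(n),
                    signal_bg = numeric(n), control_bg = numeric(n),
                    signal_corrected = numeric(n),
                    control_corrected = numeric(n),
                    flags = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cx <- ctr$x[i]; cy <- ctr$y[i]
    px <- seq.int(max(1L, floor(cx - r_out)), min(w, ceiling(cx + r_out)))
    py <- seq.int(max(1L, floor(cy - r_out)), min(h, ceiling(cy + r_out)))
    d2 <- outer((py - cy)^2, (px - cx)^2, `+`)
    in_roi <- d2 <= r_roi^2
    in_ann <- d2 >= r_in^2 & d2 <= r_out^2
    flags <- character(0)
    full_px <- (floor(cx - r_out) >= 1 && ceiling(cx + r_out) <= w &&
                floor(cy - r_out) >= 1 && ceiling(cy + r_out) <= h)
    if (!full_px) flags <- c(flags, "truncated_roi")
    area <- sum(in_roi)
    for (ch in c("signal", "control")) {
      sub <- image[[ch]][py, px, drop = FALSE]
      raw <- sum(sub[in_roi])
      bg <- stats::median(sub[in_ann])
      corr <- max(raw - bg * area, 0)
      out[[paste0(ch, "_raw")]][i] <- raw
      out[[paste0(ch, "_bg")]][i] <- bg
      out[[paste0(ch, "_corrected")]][i] <- corr
    }
    out$flags[i] <- paste(flags, collapse = ";")
  }
  out
}
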