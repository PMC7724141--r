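#' Stimulus aperture movies
#'
#' A `stimulus_movie` holds the binary aperture of the retinotopic mapping
#' stimulus, one frame per TR, in visual-field coordinates. Frames are stored
#' as a TR x height x width array; pixel (i, j) of a frame sits at the center
#' of a square cell, with x increasing with j (left to right) and y increasing
#' with i (bottom of the visual field to top).
#'
#' @name stimulus_movie
NULL

# Pixel-center coordinates for a square grid covering [-extent, extent].
pixel_grid <- function(grid_size, extent_deg) {
  cell <- 2 * extent_deg / grid_size
  -extent_deg + (seq_len(grid_size) - 0.5) * cell
}

new_stimulus_movie <- function(frames, extent_deg, tr_s) {
  stopifnot(length(dim(frames)) == 3)
  structure(
    list(frames = frames, extent_deg = extent_deg, tr_s = tr_s),
    class = "stimulus_movie"
  )
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "stimulus_movie: %d frames of %d x %d pixels, extent +/-%g deg, TR %g s\n",
    d[1], d[2], d[3], x$extent_deg, x$tr_s
  ))
  invisible(x)
}

#' Generate a bar-sweep retinotopy aperture movie
#'
#' Renders the aperture of a sweeping-bar mapping stimulus: an 8 degree wide
#' bar, oriented perpendicular to its direction of motion, sweeps the full
#' display in 30 s (20 TRs at TR = 1.5 s), once per direction, with 12 s
#' (8 TR) mean-luminance blanks at the start and end of the run. The bar
#' center moves linearly from -extent to +extent (one position per TR, at
#' sweep-step midpoints), so the bar enters and exits at the display edges.
#'
#' @param sweep_order character vector of directions, each one of
#'   `"L2R"`, `"R2L"`, `"T2B"`, `"B2T"` (default the four in that order).
#' @param grid_size number of pixels per side of the square rendering grid
#'   (>= 32; default 101).
#' @param tr_s repetition time in seconds (default 1.5).
#' @param extent_deg half-width of the modeled field of view in degrees
#'   (default 16).
#' @param bar_width_deg full width of the bar in degrees (default 8).
#' @param sweep_s duration of one sweep in seconds (default 30).
#' @param blank_s duration of each blank period in seconds (default 12).
#' @return a [stimulus_movie] with `4 * 20 + 2 * 8 = 96` frames under the
#'   defaults.
#' @examples
#' mov <- make_bar_aperture_sequence()
#' dim(mov$frames)  # 96 x 101 x 101
#' @export
make_bar_aperture_sequence <- function(sweep_order = c("L2R", "R2L", "T2B", "B2T"),
                                       grid_size = 101, tr_s = 1.5,
                                       extent_deg = 16, bar_width_deg = 8,
                                       sweep_s = 30, blank_s = 12) {
  stopifnot(grid_size >= 32)
  known <- c("L2R", "R2L", "T2B", "B2T")
  bad <- setdiff(sweep_order, known)
  if (length(bad) > 0) {
    stop("unknown sweep direction(s): ", paste(bad, collapse = ", "),
         "; use one of ", paste(known, collapse = ", "))
  }
  n_sweep_tr <- round(sweep_s / tr_s)
  n_blank_tr <- round(blank_s / tr_s)
  n_tr <- length(sweep_order) * n_sweep_tr + 2 * n_blank_tr

  coords <- pixel_grid(grid_size, extent_deg)
  frames <- array(0, dim = c(n_tr, grid_size, grid_size))
  half <- bar_width_deg / 2
  # bar-center positions at sweep-step midpoints across [-extent, extent]
  centers <- -extent_deg + (seq_len(n_sweep_tr) - 0.5) / n_sweep_tr * 2 * extent_deg

  t0 <- n_blank_tr
  for (s in seq_along(sweep_order)) {
    dir <- sweep_order[s]
    for (k in seq_len(n_sweep_tr)) {
      ctr <- switch(dir,
        L2R = centers[k], R2L = -centers[k],
        B2T = centers[k], T2B = -centers[k]
      )
      in_bar <- abs(coords - ctr) <= half
      fr <- matrix(0, grid_size, grid_size)
      if (dir %in% c("L2R", "R2L")) {
        fr[, in_bar] <- 1  # vertical bar: band of x (columns)
      } else {
        fr[in_bar, ] <- 1  # horizontal bar: band of y (rows)
      }
      frames[t0 + (s - 1) * n_sweep_tr + k, , ] <- fr
    }
  }
  new_stimulus_movie(frames, extent_deg, tr_s)
}

#' Spatially downsample a stimulus movie by bilinear interpolation
#'
#' Used to build the low-resolution "effective stimulus" for the coarse grid
#' stage of pRF fitting; the default target is 5% of the original resolution.
#' Downsampled frames are continuous in [0, 1].
#'
#' @param movie a [stimulus_movie].
#' @param factor target resolution as a fraction of the original (default
#'   0.05); the result has `max(2, round(grid_size * factor))` pixels per side.
#' @return a [stimulus_movie] on the coarser grid.
#' @export
downsample_movie <- function(movie, factor = 0.05) {
  stopifnot(inherits(movie, "stimulus_movie"), factor > 0, factor <= 1)
  d <- dim(movie$frames)
  new_size <- max(2L, as.integer(round(d[2] * factor)))
  old <- pixel_grid(d[2], movie$extent_deg)
  new <- pixel_grid(new_size, movie$extent_deg)
  frames <- array(0, dim = c(d[1], new_size, new_size))
  for (t in seq_len(d[1])) {
    fr <- movie$frames[t, , ]
    # separable bilinear: interpolate rows (y), then columns (x)
    tmp <- apply(fr, 2, function(col) {
      stats::approx(old, col, xout = new, rule = 2)$y
    })
    frames[t, , ] <- t(apply(tmp, 1, function(row) {
      stats::approx(old, row, xout = new, rule = 2)$y
    }))
  }
  new_stimulus_movie(frames, movie$extent_deg, movie$tr_s)
}

# Flatten frames to a TR x n_pixels matrix plus matching pixel coordinates.
# Pixel order is column-major over (y, x), consistent with as.vector of a
# height x width matrix. When every frame is (numerically) rank 1 -- true for
# bar apertures, which are outer products of a row mask and a column mask --
# the factors are stored so the Gaussian overlap can be computed separably.
movie_matrix <- function(movie) {
  d <- dim(movie$frames)
  n_tr <- d[1]; h <- d[2]; w <- d[3]
  m <- matrix(aperm(movie$frames, c(2, 3, 1)), nrow = h * w, ncol = n_tr)
  ys <- pixel_grid(h, movie$extent_deg)
  xs <- pixel_grid(w, movie$extent_deg)
  out <- list(
    mat = t(m),                          # TR x pixels
    x = rep(xs, each = h),
    y = rep(ys, times = w),
    xs = xs, ys = ys
  )
  R <- matrix(0, n_tr, h)                # row (y) factors
  C <- matrix(0, n_tr, w)                # column (x) factors
  sep <- TRUE
  for (t in seq_len(n_tr)) {
    fr <- movie$frames[t, , ]
    mx <- max(abs(fr))
    if (mx < 1e-12) next                 # blank frame: zero factors
    sv <- svd(fr, nu = 1, nv = 1)
    if (sum(sv$d[-1]^2) > 1e-20 * sv$d[1]^2) {
      sep <- FALSE
      break
    }
    u <- sv$u[, 1] * sqrt(sv$d[1])
    v <- sv$v[, 1] * sqrt(sv$d[1])
    if (sum(u) < 0) { u <- -u; v <- -v }
    R[t, ] <- u
    C[t, ] <- v
  }
  if (sep) {
    out$sep_R <- R
    out$sep_C <- C
  }
  out
}
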