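#' Angle utilities
#'
#' Polar angle is measured counterclockwise from the positive horizontal axis
#' (right horizontal meridian = 0 degrees) and kept in [0, 360). Cartesian
#' y > 0 is the upper visual field. All public functions take and return
#' degrees.
#'
#' @name angles
#' @keywords internal
NULL

deg2rad <- function(d) d * pi / 180

rad2deg <- function(r) r * 180 / pi

#' Wrap angles into [0, 360)
#' @param theta_deg numeric vector of angles in degrees.
#' @return angles wrapped to [0, 360).
#' @export
wrap_angle <- function(theta_deg) theta_deg %% 360

#' Signed circular difference a - b in (-180, 180]
#' @param a,b angles in degrees.
#' @return signed difference in degrees.
#' @export
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Absolute circular distance between two angles, in [0, 180]
#' @param a,b angles in degrees.
#' @return absolute angular distance in degrees.
#' @export
circ_dist <- function(a, b) abs(circ_diff(a, b))

#' Circular mean of angles in degrees
#' @param theta_deg angles in degrees.
#' @return mean direction in [0, 360); NA for an empty or cancelling set.
#' @export
circ_mean_deg <- function(theta_deg) {
  s <- mean(sin(deg2rad(theta_deg)))
  c <- mean(cos(deg2rad(theta_deg)))
  if (sqrt(s^2 + c^2) < .Machine$double.eps^0.5) return(NA_real_)
  wrap_angle(rad2deg(atan2(s, c)))
}

#' Convert Cartesian visual-field coordinates to polar
#' @param x_deg,y_deg Cartesian coordinates in degrees of visual angle.
#' @return list with `angle_deg` in [0, 360) and `ecc_deg` >= 0.
#' @export
cart2polar <- function(x_deg, y_deg) {
  list(
    angle_deg = wrap_angle(rad2deg(atan2(y_deg, x_deg))),
    ecc_deg = sqrt(x_deg^2 + y_deg^2)
  )
}

#' Convert polar visual-field coordinates to Cartesian
#' @param angle_deg polar angle in degrees.
#' @param ecc_deg eccentricity in degrees of visual angle.
#' @return list with `x_deg` and `y_deg`.
#' @export
polar2cart <- function(angle_deg, ecc_deg) {
  list(
    x_deg = ecc_deg * cos(deg2rad(angle_deg)),
    y_deg = ecc_deg * sin(deg2rad(angle_deg))
  )
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards. seed = NULL runs unseeded.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
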