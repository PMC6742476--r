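#' Dimensionless surface-to-volume prefactor of a sphere
#'
#' The constant \eqn{\gamma_{sphere} = 6^{2/3}\pi^{1/3} \approx 4.836}, the
#' value of \eqn{S/V^{2/3}} for a sphere. Every closed convex shape family
#' implemented here (spherocylinders, prolate spheroids) has
#' \eqn{\gamma \ge \gamma_{sphere}}, with equality at aspect ratio 1.
#'
#' @format A length-one numeric.
#' @export
gamma_sphere <- 6^(2 / 3) * pi^(1 / 3)

.check_rod <- function(length, width) {
  if (any(!is.finite(length)) || any(!is.finite(width))) {
    stop("rod dimensions must be finite numbers", call. = FALSE)
  }
  if (any(width <= 0)) stop("cell width must be positive", call. = FALSE)
  if (any(length < width)) {
    stop("pole-to-pole length must be >= width (L = w is a sphere)",
      call. = FALSE
    )
  }
  invisible(NULL)
}

.check_spheroid <- function(a, c) {
  if (any(!is.finite(a)) || any(!is.finite(c))) {
    stop("spheroid semi-axes must be finite numbers", call. = FALSE)
  }
  if (any(a <= 0)) stop("minor semi-axis must be positive", call. = FALSE)
  if (any(c < a)) stop("major semi-axis must be >= minor semi-axis", call. = FALSE)
  invisible(NULL)
}

#' Spherocylinder surface area and volume
#'
#' Closed-form surface area \eqn{S = \pi w L} and volume
#' \eqn{V = (\pi/4) w^2 L - (\pi/12) w^3} of a spherocylinder: a cylinder of
#' diameter `width` capped by two hemispheres, with `length` the pole-to-pole
#' length (caps included). At `length == width` the shape degenerates to a
#' sphere and both formulas reduce to the sphere values.
#'
#' Width means cell **diameter** throughout this package, never radius;
#' mixing the two silently corrupts the scaling prefactor \eqn{\gamma}.
#'
#' @param length Pole-to-pole length, um. Vectorised.
#' @param width Cell width (diameter), um. Vectorised.
#' @return Numeric vector of areas (um^2) or volumes (um^3).
#' @examples
#' rod_surface(4, 1)            # 4*pi
#' rod_volume(4, 1)             # pi - pi/12
#' rod_volume(1, 1)             # pi/6, the unit-diameter sphere
#' @export
rod_surface <- function(length, width) {
  .check_rod(length, width)
  pi * width * length
}

#' @rdname rod_surface
#' @export
rod_volume <- function(length, width) {
  .check_rod(length, width)
  (pi / 4) * width^2 * length - (pi / 12) * width^3
}

#' Scaling prefactor of a spherocylinder from its aspect ratio
#'
#' For a spherocylinder with aspect ratio \eqn{\eta = L/w}, the dimensionless
#' prefactor of the scaling law \eqn{S = \gamma V^{2/3}} is
#' \deqn{\gamma(\eta) = \eta \pi \left(\frac{\eta\pi}{4} -
#'   \frac{\pi}{12}\right)^{-2/3}.}
#' \eqn{\gamma} is scale-free, equals [gamma_sphere] at \eqn{\eta = 1}, and
#' increases strictly with \eqn{\eta}: a population with constant \eqn{\gamma}
#' is a population with constant aspect ratio.
#'
#' @param eta Aspect ratio, length/width, >= 1. Vectorised.
#' @return Dimensionless prefactor \eqn{\gamma}.
#' @seealso [eta_from_gamma_rod()] for the inverse map,
#'   [gamma_from_eta_spheroid()] for coccoid cells.
#' @examples
#' gamma_from_eta_rod(1)     # sphere, 6^(2/3) pi^(1/3)
#' gamma_from_eta_rod(4.14)  # about 6.27, close to the 2*pi of rod bacteria
#' @export
gamma_from_eta_rod <- function(eta) {
  if (any(!is.finite(eta)) || any(eta < 1)) {
    stop("aspect ratio must be finite and >= 1 for a spherocylinder",
      call. = FALSE
    )
  }
  eta * pi * (eta * pi / 4 - pi / 12)^(-2 / 3)
}

#' Aspect ratio of a spherocylinder from its scaling prefactor
#'
#' Numerically inverts [gamma_from_eta_rod()] by bracketed root finding
#' (Brent's method on \eqn{[1, 10^4]}, tolerance 1e-12). The inverse exists
#' and is unique because \eqn{\gamma(\eta)} is strictly increasing.
#'
#' @param gamma Dimensionless prefactor, >= [gamma_sphere] (a small numerical
#'   tolerance below the sphere value is treated as the sphere). Vectorised.
#' @return Aspect ratio \eqn{\eta \ge 1}.
#' @examples
#' eta_from_gamma_rod(6.24)          # about 4.1
#' eta_from_gamma_rod(gamma_sphere)  # 1
#' @export
eta_from_gamma_rod <- function(gamma) {
  if (any(!is.finite(gamma))) stop("gamma must be finite", call. = FALSE)
  if (any(gamma < gamma_sphere * (1 - 1e-9))) {
    stop("gamma below the sphere value ", format(gamma_sphere),
      ": no spherocylinder solution",
      call. = FALSE
    )
  }
  vapply(gamma, function(g) {
    if (g <= gamma_sphere) {
      return(1)
    }
    stats::uniroot(
      function(eta) gamma_from_eta_rod(eta) - g,
      interval = c(1, 1e4), tol = 1e-12
    )$root
  }, numeric(1))
}

#' Prolate spheroid surface area and volume
#'
#' Closed-form surface area and volume of a prolate spheroid with minor
#' semi-axis `a` and major semi-axis `c` (both semi-axes, not diameters):
#' \deqn{S = 2\pi a^2 + \frac{2\pi a c^2}{\sqrt{c^2 - a^2}}
#'   \arcsin\!\left(\frac{\sqrt{c^2 - a^2}}{c}\right), \quad
#'   V = \frac{4\pi}{3} a^2 c.}
#' The surface formula has a removable singularity at \eqn{c = a}; below a
#' relative eccentricity of 1e-8 the sphere formula \eqn{4\pi a^2} is
#' returned instead, giving a continuous limit.
#'
#' @param a Minor semi-axis, um. Vectorised.
#' @param c Major semi-axis, um, `c >= a`. Vectorised.
#' @return Numeric vector of areas (um^2) or volumes (um^3).
#' @examples
#' spheroid_surface(1, 1)     # 4*pi, the unit sphere
#' spheroid_surface(1, 1.38)  # about 15.85
#' @export
spheroid_surface <- function(a, c) {
  .check_spheroid(a, c)
  n <- max(length(a), length(c))
  a <- rep_len(a, n)
  c <- rep_len(c, n)
  out <- 4 * pi * a^2
  ecc <- (c - a) / a > 1e-8
  if (any(ecc)) {
    ae <- a[ecc]
    ce <- c[ecc]
    f <- sqrt(ce^2 - ae^2)
    out[ecc] <- 2 * pi * ae^2 + 2 * pi * ae * ce^2 / f * asin(f / ce)
  }
  out
}

#' @rdname spheroid_surface
#' @export
spheroid_volume <- function(a, c) {
  .check_spheroid(a, c)
  (4 * pi / 3) * a^2 * c
}

#' Scaling prefactor of a prolate spheroid from its aspect ratio
#'
#' \eqn{S/V^{2/3}} for a prolate spheroid of aspect ratio
#' \eqn{\eta = c/a \ge 1}, evaluated from the closed-form spheroid surface
#' and volume. Scale-free: the result is the same for any absolute size.
#' Coccoid cells such as *S. aureus* follow this curve at low aspect ratio.
#'
#' @param eta Aspect ratio (major/minor axis), >= 1. Vectorised.
#' @return Dimensionless prefactor \eqn{\gamma}.
#' @examples
#' gamma_from_eta_spheroid(1)     # sphere
#' gamma_from_eta_spheroid(1.38)  # 4.92 to three significant figures
#' @export
gamma_from_eta_spheroid <- function(eta) {
  if (any(!is.finite(eta)) || any(eta < 1)) {
    stop("aspect ratio must be finite and >= 1 for a prolate spheroid",
      call. = FALSE
    )
  }
  spheroid_surface(1, eta) / spheroid_volume(1, eta)^(2 / 3)
}

#' Spherocylinder dimensions from volume and aspect ratio
#'
#' Inverts the spherocylinder volume at fixed aspect ratio: solves
#' \eqn{w^3 (\pi\eta/4 - \pi/12) = V} in closed form and returns
#' \eqn{(L = \eta w, w)}. This is the exact inversion; see
#' [rod_volume_eta4_approx()] for the commonly quoted approximate relation.
#'
#' @param volume Cell volume, um^3, > 0. Vectorised.
#' @param eta Aspect ratio, >= 1. Vectorised (recycled against `volume`).
#' @return A data.frame with columns `length` and `width` (um).
#' @examples
#' rod_dimensions_from_volume(11 * pi / 12, 4)  # L = 4, w = 1
#' @export
rod_dimensions_from_volume <- function(volume, eta) {
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("volume must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(eta)) || any(eta < 1)) {
    stop("aspect ratio must be finite and >= 1", call. = FALSE)
  }
  n <- max(length(volume), length(eta))
  volume <- rep_len(volume, n)
  eta <- rep_len(eta, n)
  width <- (volume / (pi * eta / 4 - pi / 12))^(1 / 3)
  data.frame(length = eta * width, width = width)
}

#' Approximate volume-width relation for aspect-ratio-4 rods
#'
#' The relation \eqn{V \approx 8 w^3} sometimes quoted for rods of aspect
#' ratio about 4. It is **inconsistent** with the exact spherocylinder
#' geometry, which at \eqn{\eta = 4} gives
#' \eqn{V = (11\pi/12) w^3 \approx 2.88 w^3} (and with
#' \eqn{S \approx 4\pi w^2} combined with \eqn{S = 2\pi V^{2/3}}, which force
#' \eqn{V = \sqrt{8}\, w^3 \approx 2.83 w^3}) — consistent with a dropped
#' radical. The function is provided for comparison only; all package
#' computations use the exact geometry via [rod_volume()] and
#' [rod_dimensions_from_volume()].
#'
#' @param width Cell width, um.
#' @return Approximate volume \eqn{8 w^3}, um^3.
#' @export
rod_volume_eta4_approx <- function(width) {
  if (any(!is.finite(width)) || any(width <= 0)) {
    stop("width must be positive and finite", call. = FALSE)
  }
  8 * width^3
}
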