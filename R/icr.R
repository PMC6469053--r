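#' Per-plane centre of rotation from two contact normals
#'
#' The centre of rotation of one sagittal plane model is the intersection of
#' the inward normal lines at the phalanx contact (A) and the sesamoid contact
#' (B or C). When the two normals are parallel within tolerance -- the regime
#' in which the on-ridge and in-groove contact normals coincide -- no unique
#' intersection exists and the status records it; the sweep layer interprets
#' that as "centre unchanged at the spherical centre".
#'
#' @param normal_A,normal_B [line2] contact normals.
#' @param plane label: `"tibial"`, `"fibular"`, or `"generic"`.
#' @param parallel_tol parallelism tolerance in radians.
#' @return A `plane_cr` list: `plane`, `point` (length-2 or `NA`), `status`
#'   (`"unique"` or `"parallel-normals"`).
#' @export
plane_cr <- function(normal_A, normal_B, plane = "generic", parallel_tol = 1e-8) {
  pt <- intersect_lines(normal_A, normal_B, parallel_tol, on_parallel = "na")
  structure(list(plane = plane, point = pt,
                 status = if (anyNA(pt)) "parallel-normals" else "unique"),
            class = "plane_cr")
}

## A 3D line: point p (length 3) and unit direction d (length 3).
line3 <- function(p, d) list(p = as.numeric(p), d = unitize(as.numeric(d)))

#' Least-squares common centre of three contact normals in 3D
#'
#' Combines the phalanx normal and the two sesamoid-plane normals (each lying
#' in its own parallel sagittal plane at its z-offset) into the shared
#' instantaneous centre: the point minimising the sum of squared distances to
#' the three lines, via the closed-form normal equations. The residual is zero
#' exactly when the normals are concurrent -- the instantaneous sphere of
#' rotation of a perfectly spherical head.
#'
#' @param lines a list of three (or more) lines, each `list(p = , d = )` with
#'   3D point and direction.
#' @return An `icr_result`: `point3`, `rms_residual` (mm).
#' @export
icr_3d <- function(lines) {
  stopifnot(length(lines) >= 2)
  M <- matrix(0, 3, 3); b <- numeric(3)
  for (l in lines) {
    d <- unitize(l$d)
    Pm <- diag(3) - outer(d, d)
    M <- M + Pm
    b <- b + as.numeric(Pm %*% l$p)
  }
  if (rcond(M) < 1e-12) {
    abort("degenerate geometry: normal lines are (near) all parallel",
          class = "mpsjc_degenerate_geometry")
  }
  x <- as.numeric(solve(M, b))
  d2 <- vapply(lines, function(l) {
    v <- x - l$p
    d <- unitize(l$d)
    ## |v x d|^2: numerically stable for v nearly parallel to d
    cr <- c(v[2] * d[3] - v[3] * d[2],
            v[3] * d[1] - v[1] * d[3],
            v[1] * d[2] - v[2] * d[1])
    sum(cr^2)
  }, numeric(1))
  structure(list(point3 = x, rms_residual = sqrt(mean(pmax(d2, 0)))),
            class = "icr_result")
}

#' Metatarsal declination angle from the phalanx contact normal
#'
#' The declination angle is subtended between the normal line at contact
#' point A and the longitudinal axis of the metatarsal, reported in
#' `[0, 90]` degrees.
#'
#' @param normal_A the [line2] contact normal at A.
#' @param long_axis_world unit length-2 metatarsal long-axis direction in the
#'   platform frame.
#' @return Angle in degrees.
#' @export
declination_angle <- function(normal_A, long_axis_world) {
  line_angle_deg(normal_A$direction, long_axis_world)
}

#' Surface speed of a material point about a centre of rotation
#'
#' `speed = omega * |point - cr|` with `omega` converted from deg/s. A distal
#' shift of the centre of rotation lowers the surface speed of the distal
#' metatarsal edge while slightly raising it at the proximal end.
#'
#' @param point material point `c(x, y)` (mm).
#' @param cr centre of rotation `c(x, y)` (mm).
#' @param omega angular speed, degrees per second (>= 0; comparisons are
#'   ratios, so the default 1 deg/s is sufficient).
#' @return Speed in mm/s.
#' @export
surface_speed <- function(point, cr, omega = 1) {
  stopifnot(omega >= 0)
  deg2rad(omega) * vnorm(point - cr)
}

#' Obliquity of the trans-sesamoid x-axis
#'
#' The joint's transverse x-axis runs through the two sesamoid contact points.
#' When the tibial contact sits more distal than the fibular (the normal
#' arrangement), this axis is oblique to the perpendicular of the metatarsal
#' long axis and the shared centre is displaced slightly lateral-proximal.
#'
#' @param contact_tibial,contact_fibular 3D contact points `c(x, y, z)`.
#' @param long_axis_world unit in-plane long-axis direction (length 2 or 3).
#' @return A list: `obliquity_deg` (signed; positive when the tibial contact
#'   is more distal) and `icr_displacement_label`
#'   (`"lateral-proximal"`, `"medial-distal"`, or `"none"`).
#' @export
x_axis_obliquity <- function(contact_tibial, contact_fibular, long_axis_world) {
  v <- contact_tibial - contact_fibular
  if (vnorm(v) < 1e-9) {
    abort("degenerate geometry: coincident sesamoid contacts",
          class = "mpsjc_degenerate_geometry")
  }
  a3 <- if (length(long_axis_world) == 2) c(long_axis_world, 0) else long_axis_world
  ang <- 90 - line_angle_deg3(v, a3)
  dx <- contact_tibial[1] - contact_fibular[1]
  obl <- abs(ang) * sign(dx)
  label <- if (abs(obl) < 1e-6) "none" else if (obl > 0) "lateral-proximal" else "medial-distal"
  list(obliquity_deg = obl, icr_displacement_label = label)
}

line_angle_deg3 <- function(u, v) {
  d <- abs(sum(unitize(u) * unitize(v)))
  rad2deg(acos(min(1, d)))
}
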