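#' Articular profiles built from circular and elliptical arcs
#'
#' A composite profile models one sagittal section of the distal metatarsal
#' articular surface: a convex chain of implicit-conic arcs (circle and
#' groove ellipse segments) that join with matching position and tangent
#' (C1). Profiles are star-shaped about the head-circle centre, so points are
#' addressed by the polar angle `psi` (degrees, measured about that centre,
#' 0 = distal, -90 = plantar).
#'
#' @name composite_profile
NULL

new_profile <- function(center, radius, arcs, span) {
  structure(list(center = as.numeric(center), radius = radius,
                 arcs = arcs, span = span),
            class = "composite_profile")
}

#' Build a pure-circle profile
#'
#' @param radius circle radius (mm).
#' @param center circle centre, default origin of the bone frame.
#' @param span angular domain in degrees `c(from, to)`.
#' @return A `composite_profile` with a single circular arc.
#' @export
profile_circle <- function(radius, center = c(0, 0), span = c(-160, 80)) {
  stopifnot(radius > 0, span[2] > span[1], span[2] - span[1] <= 360)
  arcs <- list(list(type = "circle", q = conic_circle(center, radius),
                    span = span, label = "head"))
  new_profile(center, radius, arcs, span)
}

#' Build a head profile with one sesamoid groove
#'
#' The groove is a flattened (elliptical) region of the plantar articular
#' surface between its proximal inception and distal termination angles. It is
#' realised as two double-contact conic sub-arcs meeting C1 at the trough, so
#' the profile stays convex for every admissible flattening and the trough can
#' sit asymmetrically within the groove. At the depths used here the steep
#' wall is where the contact normals deviate most from the radial direction:
#' a trough near the inception (tibial type, the surface curving up almost
#' immediately) tilts the inward normals proximal and shifts the centre of
#' rotation proximally, while a trough near the termination (fibular type,
#' whose proximal flattened stretch runs nearly parallel to the metatarsal
#' long axis) alters the normals at the distal portion of the groove and
#' shifts the centre distally.
#'
#' @param radius head-circle radius (mm).
#' @param inception,termination groove limits, polar angles in degrees
#'   (inception proximal, i.e. smaller angle).
#' @param flattening dimensionless in `[0, 1)`: trough depth as a fraction of
#'   the maximal convex-compatible depth for the groove's geometry; 0
#'   degenerates to the pure circle.
#' @param trough_frac position of the trough within the groove, in (0, 1).
#' @param face_tilt tilt of the trough face in degrees away from the
#'   perpendicular-to-radial default (positive tilts the face normal distally).
#' @param bulge conic fullness parameter in (0, 0.5), see details.
#' @param center,span as in [profile_circle()].
#' @return A `composite_profile` with `head`/`groove` labelled arcs.
#' @export
profile_groove <- function(radius, inception, termination, flattening,
                           trough_frac = 0.5, face_tilt = 0, bulge = 0.35,
                           center = c(0, 0), span = c(-160, 80)) {
  stopifnot(radius > 0, termination > inception,
            flattening >= 0, flattening < 1,
            trough_frac > 0, trough_frac < 1,
            span[1] < inception, termination < span[2])
  if (flattening < 1e-12) {
    return(profile_circle(radius, center, span))
  }
  ## A convex arc that leaves a flat trough and rejoins the circle after a
  ## wall of angular width w can be at most R(1 - cos w) deep; the trough
  ## depth is therefore the flattening times the smaller of the two walls'
  ## limits, so every flattening < 1 yields a convex profile.
  w_prox <- deg2rad(trough_frac * (termination - inception))
  w_dist <- deg2rad((1 - trough_frac) * (termination - inception))
  d_max <- radius * min(1 - cos(w_prox), 1 - cos(w_dist))
  depth <- flattening * d_max
  psi_t <- inception + trough_frac * (termination - inception)
  dir_at <- function(psi) c(cos(deg2rad(psi)), sin(deg2rad(psi)))
  P_i <- center + radius * dir_at(inception)
  P_t <- center + (radius - depth) * dir_at(psi_t)
  P_e <- center + radius * dir_at(termination)
  n_t <- dir_at(psi_t + face_tilt)   # trough face outward normal
  cp <- conic_two_tangent(P_i, dir_at(inception), P_t, n_t, bulge)
  cd <- conic_two_tangent(P_t, n_t, P_e, dir_at(termination), bulge)
  qc <- conic_circle(center, radius)
  arcs <- list(
    list(type = "circle", q = qc, span = c(span[1], inception), label = "head"),
    list(type = "conic", q = cp$q, chord = cp$chord, side = cp$side,
         span = c(inception, psi_t), label = "groove"),
    list(type = "conic", q = cd$q, chord = cd$chord, side = cd$side,
         span = c(psi_t, termination), label = "groove"),
    list(type = "circle", q = qc, span = c(termination, span[2]), label = "head")
  )
  new_profile(center, radius, arcs, span)
}

#' @export
print.composite_profile <- function(x, ...) {
  cat(sprintf("<composite_profile> R = %.4g mm, %d arc(s), psi in [%.4g, %.4g] deg\n",
              x$radius, length(x$arcs), x$span[1], x$span[2]))
  invisible(x)
}

active_arc <- function(profile, psi) {
  if (psi < profile$span[1] - 1e-9 || psi > profile$span[2] + 1e-9) {
    abort(sprintf("profile parameter %.6g outside domain [%g, %g]",
                  psi, profile$span[1], profile$span[2]),
          class = "mpsjc_domain_error")
  }
  for (a in profile$arcs) {
    if (psi <= a$span[2] + 1e-12 && psi >= a$span[1] - 1e-12) return(a)
  }
  profile$arcs[[length(profile$arcs)]]
}

#' Evaluate a profile point at polar angle `psi`
#'
#' @param profile a `composite_profile`.
#' @param psi polar angle(s), degrees.
#' @return A matrix of points (one row per `psi`).
#' @export
profile_point <- function(profile, psi) {
  out <- vapply(psi, function(p) {
    a <- active_arc(profile, p)
    r <- conic_ray_radius(a$q, profile$center, p, profile$radius,
                          a$chord, a$side %||% 0)
    profile$center + r * c(cos(deg2rad(p)), sin(deg2rad(p)))
  }, numeric(2))
  t(out)
}

#' Radial distance from the profile centre at polar angle `psi`
#'
#' Vectorised over `psi` (the ray-conic solve is done arc-wise in closed
#' form).
#'
#' @inheritParams profile_point
#' @return Numeric vector of radii (mm).
#' @export
profile_radius <- function(profile, psi) {
  if (any(psi < profile$span[1] - 1e-9) || any(psi > profile$span[2] + 1e-9)) {
    abort(sprintf("profile parameter outside domain [%g, %g]",
                  profile$span[1], profile$span[2]),
          class = "mpsjc_domain_error")
  }
  out <- rep(NA_real_, length(psi))
  ctr <- profile$center; ref <- profile$radius
  done <- rep(FALSE, length(psi))
  for (a in profile$arcs) {
    sel <- !done & psi >= a$span[1] - 1e-12 & psi <= a$span[2] + 1e-12
    if (!any(sel)) next
    th <- deg2rad(psi[sel])
    dx <- cos(th); dy <- sin(th)
    q <- a$q
    A11 <- q[1]; A12 <- q[2] / 2; A22 <- q[3]
    alpha <- A11 * dx^2 + 2 * A12 * dx * dy + A22 * dy^2
    beta <- 2 * (ctr[1] * (A11 * dx + A12 * dy) + ctr[2] * (A12 * dx + A22 * dy)) +
      q[4] * dx + q[5] * dy
    gamma <- conic_eval(q, ctr)
    disc <- beta^2 - 4 * alpha * gamma
    disc[disc < 0] <- NA
    sq <- sqrt(disc)
    r1 <- (-beta - sq) / (2 * alpha)
    r2 <- (-beta + sq) / (2 * alpha)
    lin <- abs(alpha) < 1e-14
    if (any(lin)) { r1[lin] <- -gamma / beta[lin]; r2[lin] <- r1[lin] }
    r1[r1 <= 0] <- NA; r2[r2 <= 0] <- NA
    if (!is.null(a$chord) && !is.null(a$side) && a$side != 0) {
      m1 <- (ctr[1] + r1 * dx) * a$chord$n[1] + (ctr[2] + r1 * dy) * a$chord$n[2] - a$chord$s
      m2 <- (ctr[1] + r2 * dx) * a$chord$n[1] + (ctr[2] + r2 * dy) * a$chord$n[2] - a$chord$s
      tol <- -1e-9 * max(1, ref)
      bad1 <- !is.na(r1) & !is.na(r2) & (a$side * m1 < tol) & (a$side * m2 >= tol)
      bad2 <- !is.na(r1) & !is.na(r2) & (a$side * m2 < tol) & (a$side * m1 >= tol)
      r1[bad1] <- NA; r2[bad2] <- NA
    }
    pick <- ifelse(is.na(r1), r2,
                   ifelse(is.na(r2), r1,
                          ifelse(abs(r1 - ref) <= abs(r2 - ref), r1, r2)))
    out[sel] <- pick
    done[sel] <- TRUE
  }
  if (anyNA(out)) abort("ray does not meet conic")
  out
}

#' Unit tangent of a profile at `psi`
#'
#' Oriented for counterclockwise traversal (increasing `psi`).
#'
#' @inheritParams profile_point
#' @return Unit length-2 vector.
#' @export
tangent_at <- function(profile, psi) {
  stopifnot(length(psi) == 1)
  a <- active_arc(profile, psi)
  X <- drop(profile_point(profile, psi))
  perp(unitize(conic_grad(a$q, X)))
}

#' Inward normal line of a profile at `psi`
#'
#' The line through the profile point directed towards the bone interior; the
#' intersection of two such contact normals locates a centre of rotation.
#'
#' @inheritParams profile_point
#' @return A [line2] with origin on the profile and inward unit direction.
#' @export
normal_line_at <- function(profile, psi) {
  stopifnot(length(psi) == 1)
  a <- active_arc(profile, psi)
  X <- drop(profile_point(profile, psi))
  line2(X, -unitize(conic_grad(a$q, X)))
}

## Outward normal angle (deg, unwrapped monotone reference) at psi.
outward_normal_angle <- function(profile, psi) {
  a <- active_arc(profile, psi)
  X <- drop(profile_point(profile, psi))
  g <- unitize(conic_grad(a$q, X))
  rad2deg(atan2(g[2], g[1]))
}

#' Check profile invariants: C1 junctions and convexity
#'
#' @param profile a `composite_profile`.
#' @param n number of samples for the convexity scan.
#' @return A list with `junction_position_error` (mm),
#'   `junction_tangent_error` (radians), and `convex` (logical).
#' @export
profile_check <- function(profile, n = 720) {
  pos_err <- 0; tan_err <- 0
  if (length(profile$arcs) > 1) {
    for (i in seq_len(length(profile$arcs) - 1)) {
      psi <- profile$arcs[[i]]$span[2]
      a1 <- profile$arcs[[i]]; a2 <- profile$arcs[[i + 1]]
      r1 <- conic_ray_radius(a1$q, profile$center, psi, profile$radius,
                             a1$chord, a1$side %||% 0)
      r2 <- conic_ray_radius(a2$q, profile$center, psi, profile$radius,
                             a2$chord, a2$side %||% 0)
      pos_err <- max(pos_err, abs(r1 - r2))
      X <- profile$center + r1 * c(cos(deg2rad(psi)), sin(deg2rad(psi)))
      g1 <- unitize(conic_grad(a1$q, X)); g2 <- unitize(conic_grad(a2$q, X))
      tan_err <- max(tan_err, acos(min(1, sum(g1 * g2))))
    }
  }
  eps <- 1e-6
  psis <- seq(profile$span[1] + eps, profile$span[2] - eps, length.out = n)
  ang <- vapply(psis, function(p) outward_normal_angle(profile, p), numeric(1))
  ang <- ang + 360 * cumsum(c(0, diff(ang) < -180)) - 360 * cumsum(c(0, diff(ang) > 180))
  convex <- all(diff(ang) > -1e-6)
  list(junction_position_error = pos_err, junction_tangent_error = tan_err,
       convex = convex)
}

#' Serialise a profile to a plain list (JSON-ready)
#'
#' Conic groove arcs are reported with their reduced ellipse parameters
#' (centre, semi-axes, orientation, flattening) alongside the implicit
#' coefficients used computationally.
#'
#' @param profile a `composite_profile`.
#' @return A list mirroring the profile structure.
#' @export
profile_to_list <- function(profile) {
  arcs <- lapply(profile$arcs, function(a) {
    out <- list(type = a$type, span = a$span, label = a$label,
                coefficients = as.numeric(a$q))
    if (!is.null(a$chord)) {
      out$chord <- list(n = as.numeric(a$chord$n), s = a$chord$s)
      out$side <- a$side
    }
    if (a$type == "conic" && conic_is_ellipse(a$q)) {
      out$ellipse <- conic_reduce(a$q)
    }
    out
  })
  list(center = profile$center, radius = profile$radius,
       span = profile$span, arcs = arcs)
}

profile_from_list <- function(x) {
  arcs <- lapply(x$arcs, function(a) {
    arc <- list(type = a$type, q = as.numeric(a$coefficients),
                span = as.numeric(a$span), label = a$label)
    if (!is.null(a$chord)) {
      arc$chord <- list(n = as.numeric(a$chord$n), s = a$chord$s)
      arc$side <- a$side
    }
    arc
  })
  new_profile(as.numeric(x$center), x$radius, arcs, as.numeric(x$span))
}

## Rigidly transform a profile (used by equivariance checks).
profile_transform <- function(profile, g) {
  ## Conic Q(X) -> Q(g^-1 X): transform coefficients.
  arcs <- lapply(profile$arcs, function(a) {
    A <- matrix(c(a$q[1], a$q[2] / 2, a$q[2] / 2, a$q[3]), 2, 2)
    bv <- c(a$q[4], a$q[5]); f0 <- a$q[6]
    Rm <- g$R; tv <- g$t
    A2 <- Rm %*% A %*% t(Rm)
    b2 <- as.numeric(Rm %*% bv) - 2 * as.numeric(A2 %*% tv)
    f2 <- as.numeric(t(tv) %*% A2 %*% tv) - sum((Rm %*% bv) * tv) + f0
    ang <- rad2deg(atan2(Rm[2, 1], Rm[1, 1]))
    arc <- list(type = a$type, q = c(A2[1, 1], 2 * A2[1, 2], A2[2, 2], b2, f2),
                span = a$span + ang, label = a$label)
    if (!is.null(a$chord)) {
      n2c <- as.numeric(Rm %*% a$chord$n)
      arc$chord <- list(n = n2c, s = a$chord$s + sum(n2c * tv))
      arc$side <- a$side
    }
    arc
  })
  ang <- rad2deg(atan2(g$R[2, 1], g$R[1, 1]))
  new_profile(rigid_apply(g, profile$center), profile$radius, arcs,
              profile$span + ang)
}
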