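## Fast internal arc lookup (no domain checks; psi assumed in span).
arc_at <- function(profile, psi) {
  for (a in profile$arcs) {
    if (psi <= a$span[2] + 1e-12 && psi >= a$span[1] - 1e-12) return(a)
  }
  profile$arcs[[length(profile$arcs)]]
}

## Fast internal radius lookup (no domain checks; psi assumed in span).
.radius_at <- function(profile, psi) {
  for (a in profile$arcs) {
    if (psi <= a$span[2] + 1e-12 && psi >= a$span[1] - 1e-12) {
      return(conic_ray_radius(a$q, profile$center, psi, profile$radius,
                              a$chord, a$side %||% 0))
    }
  }
  a <- profile$arcs[[length(profile$arcs)]]
  conic_ray_radius(a$q, profile$center, psi, profile$radius,
                   a$chord, a$side %||% 0)
}

## Distance from an exterior point C to the profile, minimised over the polar
## parameter in a window about the ray direction. Returns psi*, point, dist.
closest_on_profile <- function(profile, C, window = 30) {
  psi_c <- rad2deg(atan2(C[2] - profile$center[2], C[1] - profile$center[1]))
  lo <- max(profile$span[1], psi_c - window)
  hi <- min(profile$span[2], psi_c + window)
  if (lo >= hi) {
    abort("body lies outside the profile's angular domain",
          class = "mpsjc_contact_failure")
  }
  dfun <- function(p) {
    r <- .radius_at(profile, p)
    X <- profile$center + r * c(cos(deg2rad(p)), sin(deg2rad(p)))
    sqrt(sum((X - C)^2))
  }
  op <- optimize(dfun, c(lo, hi), tol = 1e-8)
  psi <- op$minimum
  ## Secant polish on the normal-foot condition: (C - X) parallel to the
  ## outward conic gradient. Brent alone leaves ~1e-7 tangential error.
  hfun <- function(p) {
    r <- .radius_at(profile, p)
    X <- profile$center + r * c(cos(deg2rad(p)), sin(deg2rad(p)))
    g <- conic_grad(arc_at(profile, p)$q, X)
    (C[1] - X[1]) * g[2] - (C[2] - X[2]) * g[1]
  }
  p0 <- psi; p1 <- psi + 1e-5
  h0 <- hfun(p0); h1 <- hfun(p1)
  for (it in seq_len(40)) {
    if (!is.finite(h1) || h1 == h0) break
    p2 <- p1 - h1 * (p1 - p0) / (h1 - h0)
    p2 <- min(max(p2, lo), hi)
    if (abs(p2 - p1) < 1e-13) { p1 <- p2; break }
    p0 <- p1; h0 <- h1
    p1 <- p2; h1 <- hfun(p1)
  }
  if (is.finite(p1) && abs(p1 - psi) < 0.5) psi <- p1
  r <- .radius_at(profile, psi)
  X <- profile$center + r * c(cos(deg2rad(psi)), sin(deg2rad(psi)))
  list(psi = psi, point = X, dist = sqrt(sum((X - C)^2)))
}

#' Resolve the contact between a convex profile and a circular body
#'
#' Finds the unique profile point whose inward normal line passes through the
#' body's centre (equivalently the closest profile point for a convex profile
#' and exterior body), returning the contact point and the shared normal line.
#'
#' @param profile a posed `composite_profile` (platform frame).
#' @param center body centre `c(x, y)` (sesamoid or phalanx support).
#' @param radius body radius (0 for a point support).
#' @param window half-width (deg) of the angular search window about the ray
#'   from the profile centre to the body.
#' @return A list: `point` (contact, length-2), `normal` (a [line2] through the
#'   contact directed inward), `psi` (profile parameter, deg), `distance`
#'   (centre-to-contact distance), `gap` (`distance - radius`; zero at
#'   tangency).
#' @export
resolve_contact <- function(profile, center, radius = 0, window = 90) {
  co <- closest_on_profile(profile, center, window)
  r_ray <- tryCatch(.radius_at(profile, co$psi), error = function(e) NA_real_)
  if (is.finite(r_ray) &&
      vnorm(center - profile$center) < vnorm(co$point - profile$center) - 1e-9) {
    abort("contact failure: body centre lies inside the articular surface",
          class = "mpsjc_contact_failure")
  }
  nrm <- if (co$dist > 1e-12) unitize(co$point - center) else {
    ## body centre on the surface (point support at tangency): use profile normal
    normal_line_at(profile, co$psi)$direction
  }
  list(point = co$point, normal = line2(co$point, nrm), psi = co$psi,
       distance = co$dist, gap = co$dist - radius)
}

## Head-centre position for the sphere-only tangency closure: c satisfies
## |c - P| = R + r_p and |c - S| = R + r_s. Picks the solution nearest `near`.
sphere_pose_center <- function(P, rp, S, rs, R, near = c(0, 0)) {
  d1 <- R + rp; d2 <- R + rs
  u <- S - P; L <- vnorm(u)
  a <- (d1^2 - d2^2 + L^2) / (2 * L)
  h2 <- d1^2 - a^2
  if (h2 < 0) abort("no tangency achievable: supports too far apart",
                    class = "mpsjc_contact_failure")
  base <- P + a * u / L
  off <- sqrt(h2) * perp(u / L)
  c1 <- base + off; c2 <- base - off
  if (sum((c1 - near)^2) <= sum((c2 - near)^2)) c1 else c2
}

## Solve the rigid pose of the metatarsal in one sagittal plane at declination
## theta: rotation is fixed (-theta, bone to platform), the translation closes
## simultaneous tangency to the phalanx support (contact A always on the
## dorsal circular arc, so |c - P| = R + r_p exactly) and to the plane's
## sesamoid (profile tangency, solved as a 1-D root in the angle of the head
## centre about the phalanx centre).
##
## profile: bone-frame profile (head centre at origin). Returns pose and
## contact data in the platform frame.
solve_plane_pose <- function(profile, theta, S, rs, P, rp, phi_hint = NULL) {
  R <- profile$radius
  Rb2p <- rot2(-theta)   # bone -> platform rotation
  Rp2b <- rot2(theta)
  c_sphere <- sphere_pose_center(P, rp, S, rs, R)
  phi0 <- atan2(c_sphere[2] - P[2], c_sphere[1] - P[1])
  if (!is.null(phi_hint)) phi0 <- phi_hint
  d1 <- R + rp
  gap <- function(phi) {
    cc <- P + d1 * c(cos(phi), sin(phi))
    Sb <- as.numeric(Rp2b %*% (S - cc))
    closest_on_profile(profile, Sb)$dist - rs
  }
  ## Bracket the tangency root about the spherical solution.
  w <- deg2rad(1)
  g_lo <- gap(phi0 - w); g_hi <- gap(phi0 + w)
  tries <- 0
  while (g_lo * g_hi > 0 && tries < 12) {
    w <- w * 1.8
    g_lo <- gap(phi0 - w); g_hi <- gap(phi0 + w)
    tries <- tries + 1
  }
  if (g_lo * g_hi > 0) {
    abort(sprintf("contact failure at theta = %.3f deg: no tangency closure", theta),
          class = "mpsjc_contact_failure")
  }
  phi <- uniroot(gap, c(phi0 - w, phi0 + w), tol = 1e-13)$root
  cc <- P + d1 * c(cos(phi), sin(phi))
  Sb <- as.numeric(Rp2b %*% (S - cc))
  co <- closest_on_profile(profile, Sb)
  X_platform <- as.numeric(Rb2p %*% co$point) + cc
  A <- cc + R * unitize(P - cc)
  list(center = cc, phi = phi, theta = theta,
       A = A, A_normal = line2(A, unitize(cc - P)),
       contact = X_platform,
       contact_normal = line2(X_platform, unitize(X_platform - S)),
       contact_psi_bone = co$psi,
       tangency_gap = co$dist - rs)
}
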