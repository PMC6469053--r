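## Implicit conics: q = c(a, b, c, d, e, f) encodes
##   Q(x, y) = a x^2 + b x y + c y^2 + d x + e y + f.
## Convention: on every articular arc the gradient of Q points OUTWARD
## (away from the bone interior), matching the circle form |X - c|^2 - R^2.

conic_eval <- function(q, xy) {
  if (!is.matrix(xy)) xy <- matrix(xy, ncol = 2)
  x <- xy[, 1]; y <- xy[, 2]
  q[1] * x^2 + q[2] * x * y + q[3] * y^2 + q[4] * x + q[5] * y + q[6]
}

conic_grad <- function(q, p) {
  c(2 * q[1] * p[1] + q[2] * p[2] + q[4],
    q[2] * p[1] + 2 * q[3] * p[2] + q[5])
}

conic_circle <- function(center, radius) {
  c(1, 0, 1, -2 * center[1], -2 * center[2], sum(center^2) - radius^2)
}

## Linear form l(X) = n . X - s with unit normal n, zero on the line through
## `point` with normal `normal`.
line_form <- function(point, normal) {
  n <- unitize(normal)
  list(n = n, s = sum(n * point))
}

line_form_eval <- function(l, xy) {
  if (!is.matrix(xy)) xy <- matrix(xy, ncol = 2)
  xy[, 1] * l$n[1] + xy[, 2] * l$n[2] - l$s
}

## Conic coefficients of the product of two linear forms.
conic_from_line_product <- function(l1, l2) {
  u <- l1$n; v <- l2$n
  c(u[1] * v[1],
    u[1] * v[2] + u[2] * v[1],
    u[2] * v[2],
    -(u[1] * l2$s + v[1] * l1$s),
    -(u[2] * l2$s + v[2] * l1$s),
    l1$s * l2$s)
}

## Double-contact conic: tangent to the line with outward normal n1 at P1 and
## to the line with outward normal n2 at P2. The one-parameter pencil
##   Q = k * m^2 - l1 * l2   (m = chord line through P1, P2)
## is navigated by `bulge` in (0, 1): the fraction along the segment from the
## chord midpoint towards the tangent-line vertex at which the arc crosses.
## bulge < 0.5 yields an ellipse; the defaults stay well inside that range.
conic_two_tangent <- function(P1, n1, P2, n2, bulge = 0.35) {
  stopifnot(bulge > 0, bulge < 1)
  l1 <- line_form(P1, n1)
  l2 <- line_form(P2, n2)
  ## Orient each tangent form negative at the opposite contact point so the
  ## product is positive outside the arc.
  if (line_form_eval(l1, P2) > 0) l1 <- list(n = -l1$n, s = -l1$s)
  if (line_form_eval(l2, P1) > 0) l2 <- list(n = -l2$n, s = -l2$s)
  chord <- line_form(P1, perp(P2 - P1))
  A <- cbind(l1$n, l2$n)
  if (abs(det(A)) < 1e-12) {
    abort("tangent lines are parallel: degenerate groove construction")
  }
  V <- solve(t(A), c(l1$s, l2$s))
  M <- (P1 + P2) / 2
  B <- M + bulge * (V - M)
  k <- (line_form_eval(l1, B) * line_form_eval(l2, B)) / line_form_eval(chord, B)^2
  q <- k * conic_from_line_product(chord, chord) - conic_from_line_product(l1, l2)
  q <- q / max(abs(q))   # normalise for conditioning near-degenerate grooves
  ## Ensure outward gradient at P1 (n1 passed as outward normal there).
  if (sum(conic_grad(q, P1) * n1) < 0) q <- -q
  ## The chord through the tangency points splits the conic into the arc
  ## (vertex side) and the remainder; callers use it to select ray roots.
  list(q = q, chord = chord, side = sign(line_form_eval(chord, B)))
}

conic_discriminant <- function(q) q[2]^2 - 4 * q[1] * q[3]

conic_is_ellipse <- function(q) conic_discriminant(q) < -1e-12

## Reduce a central conic to centre / semi-axes / orientation (degrees).
conic_reduce <- function(q) {
  A <- matrix(c(q[1], q[2] / 2, q[2] / 2, q[3]), 2, 2)
  bv <- c(q[4], q[5])
  ctr <- solve(2 * A, -bv)
  gamma <- conic_eval(q, ctr)
  ev <- eigen(A, symmetric = TRUE)
  ax <- sqrt(pmax(0, -gamma / ev$values))
  ord <- order(ax, decreasing = TRUE)
  list(center = as.numeric(ctr),
       semi_major = ax[ord[1]], semi_minor = ax[ord[2]],
       orientation = rad2deg(atan2(ev$vectors[2, ord[1]], ev$vectors[1, ord[1]])) %% 180,
       flattening = 1 - ax[ord[2]] / ax[ord[1]])
}

## Radius along the ray from `center` at polar angle psi (deg) to the conic.
## For double-contact groove arcs the admissible root must lie on the arc
## side of the tangency chord (`chord`/`side`); among admissible roots the
## one nearest `ref` (the expected articular radius) is returned.
conic_ray_radius <- function(q, center, psi_deg, ref, chord = NULL, side = 0) {
  d <- c(cos(deg2rad(psi_deg)), sin(deg2rad(psi_deg)))
  A <- matrix(c(q[1], q[2] / 2, q[2] / 2, q[3]), 2, 2)
  bv <- c(q[4], q[5])
  alpha <- sum(d * (A %*% d))
  beta <- 2 * sum(center * (A %*% d)) + sum(bv * d)
  gamma <- conic_eval(q, center)
  if (abs(alpha) < 1e-14) {
    t <- -gamma / beta
    if (!is.finite(t) || t <= 0) abort("ray does not meet conic")
    return(t)
  }
  disc <- beta^2 - 4 * alpha * gamma
  if (disc < 0) abort("ray does not meet conic")
  r <- (-beta + c(-1, 1) * sqrt(disc)) / (2 * alpha)
  r <- r[r > 0]
  if (!length(r)) abort("ray does not meet conic")
  if (!is.null(chord) && side != 0 && length(r) > 1) {
    m <- vapply(r, function(t) line_form_eval(chord, center + t * d), numeric(1))
    keep <- side * m >= -1e-9 * max(1, ref)
    if (any(keep)) r <- r[keep]
  }
  r[which.min(abs(r - ref))]
}
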