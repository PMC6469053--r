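#' Least-squares circle fit
#'
#' Fits a circle to digitised contour points by geometric least squares:
#' an algebraic (Kasa) solve seeds a Levenberg-Marquardt refinement of the
#' radial residuals \eqn{r_i = |p_i - c| - R}. This reproduces, computationally,
#' the superimposition of a circle over the distal metatarsal edge from which
#' the head radius and centre of rotation are read.
#'
#' @param points a two-column matrix or data frame of `x, y` coordinates (mm),
#'   at least 3 non-collinear points.
#' @return A list with `center` (length-2), `radius`, and `rms_residual` (the
#'   root-mean-square radial deviation, mm).
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 40)
#' fit_circle(cbind(cos(th), sin(th)))
fit_circle <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (nrow(pts) < 3) abort("need at least 3 points to fit a circle")
  x <- pts[, 1]; y <- pts[, 2]
  X <- cbind(x, y, 1)
  qrX <- qr(cbind(x - mean(x), y - mean(y)))
  if (qrX$rank < 2) {
    abort("degenerate circle fit: points are collinear", class = "mpsjc_degenerate_fit")
  }
  sol <- tryCatch(qr.solve(X, x^2 + y^2), error = function(e) NULL)
  if (is.null(sol)) {
    abort("degenerate circle fit: points are collinear", class = "mpsjc_degenerate_fit")
  }
  c0 <- sol[1:2] / 2
  r0 <- sqrt(max(sol[3] + sum(c0^2), .Machine$double.eps))
  resid_fn <- function(p) sqrt((x - p[1])^2 + (y - p[2])^2) - p[3]
  fit <- minpack.lm::nls.lm(par = c(c0, r0), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-15, ptol = 1e-15, maxiter = 200))
  p <- fit$par
  if (p[3] <= 0 || !all(is.finite(p))) {
    abort("degenerate circle fit", class = "mpsjc_degenerate_fit")
  }
  res <- resid_fn(p)
  list(center = as.numeric(p[1:2]), radius = p[3],
       rms_residual = sqrt(mean(res^2)))
}

#' Fit a composite head-plus-groove profile to one section contour
#'
#' Given a template declaring the groove's angular placement, recovers the
#' head-circle centre and radius together with the groove flattening by
#' geometric least squares on the radial residuals. A single-arc template
#' degenerates to [fit_circle()].
#'
#' @param points a two-column matrix / data frame of contour points (mm).
#' @param template a list: `arcs = 1` for a pure circle, or `arcs = 3` with
#'   `inception`, `termination` (deg), `trough_frac`, and optionally
#'   `face_tilt`, `bulge` fixing the groove placement (the free parameters are
#'   the circle centre/radius and the flattening).
#' @param init optional starting values `list(center=, radius=, flattening=)`.
#' @return A list with the fitted `profile`, `center`, `radius`, `flattening`,
#'   `rms_residual`, and `arc_residuals` (per-arc rms, mm).
#' @export
fit_profile <- function(points, template = list(arcs = 1), init = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (is.null(template$arcs)) template$arcs <- if (is.null(template$inception)) 1 else 3
  cf <- fit_circle(pts)
  if (template$arcs == 1) {
    prof <- profile_circle(cf$radius, cf$center,
                           span = contour_span(pts, cf$center))
    return(list(profile = prof, center = cf$center, radius = cf$radius,
                flattening = 0, rms_residual = cf$rms_residual,
                arc_residuals = c(head = cf$rms_residual)))
  }
  stopifnot(!is.null(template$inception), !is.null(template$termination))
  tf <- template$trough_frac %||% 0.5
  free_tf <- isTRUE(template$fit_trough_frac)
  ft <- template$face_tilt %||% 0
  bu <- template$bulge %||% 0.35
  f0 <- if (!is.null(init$flattening)) init$flattening else 0.05
  c0 <- init$center %||% cf$center
  r0 <- init$radius %||% cf$radius
  build <- function(p) {
    profile_groove(radius = p[3], inception = template$inception,
                   termination = template$termination,
                   flattening = min(max(p[4], 0), 0.999),
                   trough_frac = if (free_tf && length(p) >= 5) {
                     min(max(p[5], 0.02), 0.98)
                   } else tf,
                   face_tilt = ft, bulge = bu,
                   center = p[1:2], span = c(-179.9, 179.9))
  }
  resid_fn <- function(p) {
    tryCatch({
      prof <- build(p)
      psi <- rad2deg(atan2(pts[, 2] - p[2], pts[, 1] - p[1]))
      sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) - profile_radius(prof, psi)
    }, error = function(e) rep(1e3, nrow(pts)))
  }
  lm_fit <- function(par0, lower, upper, maxiter = 400) {
    tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = maxiter)),
      error = function(e) abort(paste0("profile fit failed to converge: ",
                                       conditionMessage(e)),
                                class = "mpsjc_fit_failure"))
  }
  if (!free_tf) {
    fit <- lm_fit(c(c0, r0, f0), c(-Inf, -Inf, 1e-6, 0), c(Inf, Inf, Inf, 0.999))
    fit <- lm_fit(fit$par, c(-Inf, -Inf, 1e-6, 0), c(Inf, Inf, Inf, 0.999))
    p <- c(fit$par, tf)
  } else {
    ## The residual surface is multimodal and kinked in the trough position
    ## (moving the trough relocates the steep groove wall across sample
    ## points), so the trough fraction is handled by grid + golden-section
    ## search with the smooth parameters refit exactly at each node.
    tf_init <- tf
    rng <- template$trough_frac_range %||% c(0.02, 0.98)
    start <- c(c0, r0, f0)
    inner <- function(tfc, st) {
      tf <<- tfc
      ft <- lm_fit(st, c(-Inf, -Inf, 1e-6, 0), c(Inf, Inf, Inf, 0.985),
                   maxiter = 150)
      list(par = ft$par, rss = sum(resid_fn(ft$par)^2))
    }
    cands <- sort(unique(round(c(tf_init, seq(0.12, 0.88, by = 0.08)), 3)))
    cands <- pmin(pmax(cands, rng[1]), rng[2])
    cands <- sort(unique(cands))
    best <- NULL
    for (tfc in cands) {
      r <- inner(tfc, start)   # fresh start: a pegged node must not seed the next
      if (is.null(best) || r$rss < best$rss) best <- c(r, list(tf = tfc))
    }
    op <- optimize(function(tfc) {
      r <- inner(tfc, start)
      if (r$rss < best$rss) best <<- c(r, list(tf = tfc))
      r$rss
    }, c(max(rng[1], best$tf - 0.15), min(rng[2], best$tf + 0.15)), tol = 1e-4)
    r_fin <- inner(op$minimum, start)
    if (r_fin$rss <= best$rss) best <- c(r_fin, list(tf = op$minimum))
    tf <- best$tf
    p <- c(best$par, best$tf)
  }
  res <- resid_fn(p)
  prof <- build(p)
  psi <- rad2deg(atan2(pts[, 2] - p[2], pts[, 1] - p[1]))
  in_groove <- psi >= template$inception & psi <= template$termination
  arc_res <- c(head = sqrt(mean(res[!in_groove]^2)),
               groove = if (any(in_groove)) sqrt(mean(res[in_groove]^2)) else NA_real_)
  list(profile = prof, center = as.numeric(p[1:2]), radius = p[3],
       flattening = p[4],
       trough_frac = if (free_tf && length(p) >= 5) min(max(p[5], 0.02), 0.98) else tf,
       rms_residual = sqrt(mean(res^2)),
       arc_residuals = arc_res)
}

## Angular span (deg) covered by contour points about a centre, padded.
contour_span <- function(pts, center) {
  psi <- rad2deg(atan2(pts[, 2] - center[2], pts[, 1] - center[1]))
  c(min(psi) - 1, max(psi) + 1)
}
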