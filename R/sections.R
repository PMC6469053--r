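#' Specification for a synthetic sagittal section stack
#'
#' Emulates a sequential series of 0.5-mm sagittal sections through the
#' metatarsal head of a normal specimen: a near-circular inter-sesamoidal
#' ridge (crista) section midway through the head, a tibial groove trough
#' medial of it, and a fibular groove trough lateral of it (fibular index <
#' crista index < tibial index under the +z-medial convention). Ground truth
#' is retained so every fitting and kinematic stage is testable.
#'
#' @param n_sections number of sections (0.5-mm spacing).
#' @param crista_index,tibial_trough_index,fibular_trough_index landmark
#'   section indices; must satisfy fibular < crista < tibial.
#' @param head_radius sagittal crista radius (mm).
#' @param transverse_radius dorsal-dome radius controlling how section radii
#'   shrink away from the crista (mm).
#' @param tibial_flattening,fibular_flattening groove flattenings at the
#'   trough sections.
#' @param tibial_trough_frac,fibular_trough_frac in-plane trough positions.
#' @param groove_halfwidth transverse extent of each groove, in sections.
#' @param flare_base,flare_slope amplitude (mm) of the non-articular
#'   proximal-margin flare added to every non-crista section.
#' @param noise_sigma isotropic Gaussian point noise (mm).
#' @param n_points contour points per section.
#' @param span angular extent of each contour (deg).
#' @param seed RNG seed (stacks are deterministic given the seed).
#' @return A `stack_gen_spec` list.
#' @export
stack_gen_spec <- function(n_sections = 48, crista_index = 23,
                           tibial_trough_index = 31, fibular_trough_index = 15,
                           head_radius = 11, transverse_radius = 13,
                           tibial_flattening = 0.65, fibular_flattening = 0.65,
                           tibial_trough_frac = 0.35, fibular_trough_frac = 0.65,
                           tibial_groove = c(-70, -20), fibular_groove = c(-75, -25),
                           groove_halfwidth = 7,
                           flare_base = 0.6, flare_slope = 0.03,
                           noise_sigma = 0.005 * head_radius,
                           n_points = 150, span = c(-110, 60), seed = 1L) {
  if (!(fibular_trough_index < crista_index && crista_index < tibial_trough_index)) {
    abort("landmark ordering must satisfy fibular < crista < tibial",
          class = "mpsjc_spec_error")
  }
  stopifnot(n_sections >= tibial_trough_index, fibular_trough_index >= 1,
            head_radius > 0, transverse_radius > 0, noise_sigma >= 0)
  structure(as.list(environment()), class = "stack_gen_spec")
}

## Section in-plane radius at out-of-plane offset z: the dorsal dome of
## radius Rt drops the section radius away from the crista plane.
section_radius <- function(R, Rt, z) {
  R - Rt + sqrt(pmax(Rt^2 - z^2, 0.25))
}

## Transverse groove taper: flattening fraction at `delta` sections from the
## trough (cosine-squared bump, zero beyond the halfwidth).
groove_taper <- function(delta, halfwidth) {
  ifelse(abs(delta) >= halfwidth, 0, cos(pi * delta / (2 * halfwidth))^2)
}

#' Generate a synthetic section stack
#'
#' @param spec a [stack_gen_spec()].
#' @return An `mpsjc_stack`: `sections` (tibble with `section`, `z`, `x`, `y`)
#'   and `ground_truth` (the generating spec plus landmark indices).
#' @export
generate_stack <- function(spec = stack_gen_spec()) {
  stopifnot(inherits(spec, "stack_gen_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)
  psis <- seq(spec$span[1], spec$span[2], length.out = spec$n_points)
  ## cubic flare ramp over the proximal non-articular tail, clear of the
  ## groove inceptions
  ramp_hi <- min(spec$span[1] + 0.25 * diff(spec$span), -85)
  ramp <- ifelse(psis < ramp_hi,
                 ((ramp_hi - psis) / (ramp_hi - spec$span[1]))^3, 0)
  rows <- lapply(seq_len(spec$n_sections), function(k) {
    z <- (k - spec$crista_index) * 0.5
    Rs <- section_radius(spec$head_radius, spec$transverse_radius, z)
    side <- if (k > spec$crista_index) "tibial" else "fibular"
    trough_k <- if (side == "tibial") spec$tibial_trough_index else spec$fibular_trough_index
    f_k <- (if (side == "tibial") spec$tibial_flattening else spec$fibular_flattening) *
      groove_taper(k - trough_k, spec$groove_halfwidth)
    groove <- if (side == "tibial") spec$tibial_groove else spec$fibular_groove
    tf <- if (side == "tibial") spec$tibial_trough_frac else spec$fibular_trough_frac
    prof <- if (f_k < 1e-12) {
      profile_circle(Rs, span = spec$span + c(-1, 1))
    } else {
      profile_groove(Rs, groove[1], groove[2], f_k, tf,
                     span = spec$span + c(-1, 1))
    }
    r <- profile_radius(prof, psis)
    amp <- if (k == spec$crista_index) 0 else {
      spec$flare_base + spec$flare_slope * abs(k - spec$crista_index)
    }
    r <- r + amp * ramp
    x <- r * cos(deg2rad(psis)) + rnorm(spec$n_points, 0, spec$noise_sigma)
    y <- r * sin(deg2rad(psis)) + rnorm(spec$n_points, 0, spec$noise_sigma)
    tibble::tibble(section = k, z = z, x = x, y = y)
  })
  structure(list(sections = dplyr::bind_rows(rows),
                 ground_truth = list(
                   spec = unclass(spec),
                   crista_index = spec$crista_index,
                   tibial_trough_index = spec$tibial_trough_index,
                   fibular_trough_index = spec$fibular_trough_index)),
            class = "mpsjc_stack")
}

#' @export
print.mpsjc_stack <- function(x, ...) {
  ns <- length(unique(x$sections$section))
  cat(sprintf("<mpsjc_stack> %d sections at 0.5-mm spacing, %d points each\n",
              ns, nrow(x$sections) / ns))
  invisible(x)
}

## Dorsal-arc reference for one section's contour, about a common head-axis
## centre (the crista section's fitted centre). Fitting a circle to the short
## dorsal arc alone is ill-conditioned (radius errors far exceed groove
## depth); with the centre known, the dorsal radius is just a trimmed mean of
## radial distances over the distal-dorsal window, which carries neither
## groove nor proximal flare.
dorsal_reference <- function(pts, center, window = c(-10, 45)) {
  psi <- rad2deg(atan2(pts[, 2] - center[2], pts[, 1] - center[1]))
  sel <- psi >= window[1] & psi <= window[2]
  if (sum(sel) < 10) sel <- rep(TRUE, nrow(pts))
  r <- sqrt((pts[sel, 1] - center[1])^2 + (pts[sel, 2] - center[2])^2)
  list(center = center, radius = mean(r, trim = 0.1))
}

## Plantar groove deficit of one section: radial deficit below the dorsal
## reference circle within the plantar window, smoothed with a short running
## mean. The trough is the argmax of the smoothed curve (a top-quantile mean
## would be biased towards the gentle flank of an asymmetric groove).
groove_deficit <- function(pts, ref, window = c(-80, -15), smooth_n = 7L) {
  psi <- rad2deg(atan2(pts[, 2] - ref$center[2], pts[, 1] - ref$center[1]))
  sel <- psi >= window[1] & psi <= window[2]
  if (sum(sel) < smooth_n) {
    return(list(depth = 0, psi_at = NA_real_, psi = numeric(0),
                deficit = numeric(0), smoothed = numeric(0)))
  }
  ps <- psi[sel]
  d <- ref$radius - sqrt((pts[sel, 1] - ref$center[1])^2 + (pts[sel, 2] - ref$center[2])^2)
  ord <- order(ps)
  ps <- ps[ord]; d <- d[ord]
  sm <- stats::filter(d, rep(1 / smooth_n, smooth_n), sides = 2)
  sm[is.na(sm)] <- d[is.na(sm)]
  sm <- as.numeric(sm)
  at <- which.max(sm)
  ## mean deficit over the window: lower-variance localisation statistic
  ## (scales with the groove's cross-sectional relief like the peak depth)
  list(depth = sm[at], area = mean(d), psi_at = ps[at],
       psi = ps, deficit = d, smoothed = sm)
}

## Parabolic vertex refinement of a discrete argmax.
refine_peak <- function(idx, val, at, halfwin = 3L) {
  sel <- which(abs(idx - idx[at]) <= halfwin)
  if (length(sel) < 3) return(idx[at])
  fit <- stats::lm(val[sel] ~ poly(idx[sel], 2, raw = TRUE))
  b <- unname(coef(fit))
  if (!is.finite(b[3]) || b[3] >= 0) return(as.integer(idx[at]))
  v <- -b[2] / (2 * b[3])
  out <- as.integer(round(v))
  if (out < min(idx[sel]) || out > max(idx[sel])) as.integer(idx[at]) else out
}

#' Locate the crista and groove-trough sections of a stack
#'
#' The crista is the section whose contour is most circular (minimum
#' circle-fit rms residual); each trough is the section with maximal plantar
#' groove deficit (deviation below the dorsal reference circle) on its side of
#' the crista, with a parabolic refinement across neighbouring sections.
#'
#' @param stack an `mpsjc_stack` or a sections tibble with
#'   `section`, `x`, `y`.
#' @param depth_factor troughs must exceed `depth_factor` times the crista
#'   residual (noise floor) to count as detected.
#' @return A list: `crista_index`, `tibial_trough_index`,
#'   `fibular_trough_index`, plus per-section diagnostics in `details`.
#' @export
locate_landmarks <- function(stack, depth_factor = 4) {
  secs <- if (inherits(stack, "mpsjc_stack")) stack$sections else stack
  ks <- sort(unique(secs$section))
  if (length(ks) < 5) abort("need at least 5 sections", class = "mpsjc_spec_error")
  fits <- lapply(ks, function(k) {
    fit_circle(as.matrix(secs[secs$section == k, c("x", "y")]))
  })
  rms <- vapply(fits, `[[`, numeric(1), "rms_residual")
  crista <- ks[which.min(rms)]
  c_ref <- fits[[which.min(rms)]]$center
  per <- lapply(seq_along(ks), function(i) {
    pts <- as.matrix(secs[secs$section == ks[i], c("x", "y")])
    ref <- dorsal_reference(pts, c_ref)
    gd <- groove_deficit(pts, ref)
    tibble::tibble(section = ks[i], rms = rms[i], depth = gd$depth,
                   area = gd$area, ref_radius = ref$radius,
                   ref_cx = ref$center[1], ref_cy = ref$center[2],
                   deficit_psi = gd$psi_at)
  })
  det <- dplyr::bind_rows(per)
  noise_floor <- max(det$rms[det$section == crista], 1e-7)
  find_trough <- function(side_sections) {
    if (!length(side_sections)) {
      abort("missing landmark: no sections on one side of the crista",
            class = "mpsjc_missing_landmark")
    }
    sub <- det[det$section %in% side_sections, ]
    if (max(sub$depth) < depth_factor * noise_floor) {
      abort("missing landmark: groove deficit below the detection threshold",
            class = "mpsjc_missing_landmark")
    }
    ## normalise by the section's dorsal radius: section radii shrink away
    ## from the crista and would otherwise tilt the peak towards it
    a_norm <- sub$area / sub$ref_radius
    at <- which.max(a_norm)
    refine_peak(sub$section, a_norm, at, halfwin = 6L)
  }
  tib <- find_trough(ks[ks > crista])
  fib <- find_trough(ks[ks < crista])
  list(crista_index = as.integer(crista), tibial_trough_index = as.integer(tib),
       fibular_trough_index = as.integer(fib), details = det)
}

#' Reconstruct a metatarsal head model from a section stack
#'
#' Fits the crista section with a circle (head radius and centre), derives
#' each groove's angular template from its trough section's deficit profile,
#' fits the composite head-plus-groove profile in each trough plane, and
#' estimates the transverse dome radius from the dorsal-arc radii of sections
#' flanking the crista.
#'
#' @param stack an `mpsjc_stack`.
#' @param landmarks optionally, the result of [locate_landmarks()].
#' @return A list: `head` (a [metatarsal_head()]), `crista_fit`,
#'   `tibial_fit`, `fibular_fit`, `landmarks`.
#' @export
stack_to_model <- function(stack, landmarks = locate_landmarks(stack)) {
  secs <- if (inherits(stack, "mpsjc_stack")) stack$sections else stack
  get_pts <- function(k) as.matrix(secs[secs$section == k, c("x", "y")])
  crista_fit <- tryCatch(fit_circle(get_pts(landmarks$crista_index)),
                         error = function(e) {
                           abort(sprintf("crista fit failed at section %d: %s",
                                         landmarks$crista_index, conditionMessage(e)),
                                 class = "mpsjc_fit_failure")
                         })
  noise_floor <- max(crista_fit$rms_residual, 1e-7)
  restrict <- function(pp, articular_window = c(-82, 52)) {
    ps <- rad2deg(atan2(pp[, 2] - crista_fit$center[2],
                        pp[, 1] - crista_fit$center[1]))
    pp[ps >= articular_window[1] & ps <= articular_window[2], , drop = FALSE]
  }
  all_ks <- sort(unique(secs$section))
  fit_trough <- function(k, side, articular_window = c(-82, 52)) {
    pts <- restrict(get_pts(k))
    ref <- dorsal_reference(pts, crista_fit$center)
    ## Average the deficit curves of the trough section and its neighbours
    ## (they share the groove's angular geometry and carry nearly the full
    ## flattening), boosting the signal-to-noise of the template estimate.
    pool <- intersect(k + (-3:3), all_ks)
    grid_psi <- seq(-79, -16, by = 1.5)
    curves <- vapply(pool, function(kk) {
      pp <- restrict(get_pts(kk))
      rr <- dorsal_reference(pp, crista_fit$center)
      g <- groove_deficit(pp, rr)
      stats::approx(g$psi, g$smoothed, xout = grid_psi, rule = 2)$y
    }, numeric(length(grid_psi)))
    gd <- list(psi = grid_psi, smoothed = rowMeans(curves),
               deficit = rowMeans(curves))
    gd$depth <- max(gd$smoothed)
    gd$psi_at <- grid_psi[which.max(gd$smoothed)]
    at <- which.max(gd$smoothed)
    ## Parabola-refined trough angle over a +/- 6 degree neighbourhood.
    nb <- which(abs(gd$psi - gd$psi[at]) <= 6)
    a_psi <- gd$psi[at]
    if (length(nb) >= 5) {
      co <- coef(stats::lm(gd$smoothed[nb] ~ poly(gd$psi[nb], 2, raw = TRUE)))
      if (is.finite(co[3]) && co[3] < 0) {
        v <- -co[2] / (2 * co[3])
        if (abs(v - gd$psi[at]) <= 6) a_psi <- v
      }
    }
    ## The deficit returns to zero at the groove junctions, so each window
    ## edge is the zero intercept of a line through two flank crossings
    ## (robust against the noise floor right at the junction).
    flank_zero <- function(side) {
      thr1 <- 0.12 * gd$depth; thr2 <- 0.35 * gd$depth
      cross <- function(thr) {
        if (side == "prox") {
          i <- which(gd$smoothed[seq_len(at)] >= thr)[1]
          if (is.na(i) || i < 2) return(NA_real_)
          x0 <- gd$psi[i - 1]; x1 <- gd$psi[i]
          d0 <- gd$smoothed[i - 1]; d1 <- gd$smoothed[i]
        } else {
          idx <- at:length(gd$smoothed)
          j <- which(gd$smoothed[idx] <= thr)[1]
          if (is.na(j) || j < 2) return(NA_real_)
          x0 <- gd$psi[idx[j - 1]]; x1 <- gd$psi[idx[j]]
          d0 <- gd$smoothed[idx[j - 1]]; d1 <- gd$smoothed[idx[j]]
        }
        if (abs(d1 - d0) < 1e-12) return(x1)
        x0 + (thr - d0) * (x1 - x0) / (d1 - d0)
      }
      c1 <- cross(thr1); c2 <- cross(thr2)
      if (is.na(c1) || is.na(c2) || abs(c2 - c1) < 1e-9) return(c1)
      c1 - thr1 * (c2 - c1) / (thr2 - thr1)   # extrapolate to zero deficit
    }
    inception <- flank_zero("prox"); termination <- flank_zero("dist")
    if (is.na(inception)) inception <- a_psi - 22
    if (is.na(termination)) termination <- a_psi + 22
    if (termination - inception < 10) {
      abort(sprintf("groove fit failed at section %d: no groove extent detected", k),
            class = "mpsjc_fit_failure")
    }
    inception <- max(inception, -80)
    termination <- min(termination, -16)
    ## The deficit argmax sits at the conic's radius minimum, which lies a few
    ## degrees inside the wide sub-arc of an asymmetric groove; it seeds the
    ## trough search but the profile fit decides the position over the full
    ## admissible range.
    tf <- min(max((a_psi - inception) / (termination - inception), 0.08), 0.92)
    ## Fit the averaged deficit curve against the groove family directly:
    ## for each candidate trough fraction, the window, flattening, and a
    ## baseline offset are optimised on the 1-D curve, whose pooled noise is
    ## low enough to identify the trough side that a single section cannot.
    R_ref <- ref$radius
    deficit_rss <- function(par, tfc) {
      inc <- par[1]; term <- par[2]; f <- par[3]; b <- par[4]
      if (inc < -80 || term > -15 || term - inc < 12 ||
          f < 0.02 || f > 0.98) return(1e6)
      prof <- tryCatch(profile_groove(R_ref, inc, term, f, tfc,
                                      span = c(-170, 170)),
                       error = function(e) NULL)
      if (is.null(prof)) return(1e6)
      dm <- R_ref - profile_radius(prof, gd$psi)
      sum((gd$smoothed - dm - b)^2)
    }
    f0 <- min(max(gd$depth / (R_ref * (1 - cos(deg2rad(
      min(tf, 1 - tf) * (termination - inception))))), 0.05), 0.9)
    best <- NULL
    for (tfc in seq(0.15, 0.85, by = 0.1)) {
      o <- optim(c(inception, termination, f0, 0), deficit_rss, tfc = tfc,
                 method = "Nelder-Mead",
                 control = list(maxit = 150, reltol = 1e-7))
      if (is.null(best) || o$value < best$value) best <- c(o, list(tf = tfc))
    }
    op <- optimize(function(tfc) {
      o <- optim(best$par, deficit_rss, tfc = tfc, method = "Nelder-Mead",
                 control = list(maxit = 150, reltol = 1e-7))
      if (o$value < best$value) best <<- c(o, list(tf = tfc))
      o$value
    }, c(max(0.05, best$tf - 0.1), min(0.95, best$tf + 0.1)), tol = 5e-3)
    inception <- best$par[1]; termination <- best$par[2]
    tf_best <- best$tf
    fit <- tryCatch(
      fit_profile(pts, template = list(arcs = 3, inception = inception,
                                       termination = termination,
                                       trough_frac = tf_best)),
      error = function(e) {
        abort(sprintf("profile fit failed at section %d (%s plane): %s",
                      k, side, conditionMessage(e)),
              class = "mpsjc_fit_failure")
      })
    fit$template <- list(inception = inception, termination = termination,
                         trough_frac = tf_best)
    fit
  }
  tib <- fit_trough(landmarks$tibial_trough_index, "tibial")
  fib <- fit_trough(landmarks$fibular_trough_index, "fibular")
  ## The tibial groove commences more distally than the fibular; window
  ## estimates from noisy sections can cross this ordering marginally, so the
  ## tibial inception is nudged distal of the fibular one when they conflict.
  if (tib$template$inception <= fib$template$inception) {
    tib$template$inception <- fib$template$inception + 0.5
  }
  ## Transverse dome radius from dorsal radii of flanking sections.
  ks <- sort(unique(secs$section))
  flank <- ks[abs(ks - landmarks$crista_index) >= 3 & abs(ks - landmarks$crista_index) <= 7]
  Rt <- crista_fit$radius * 1.1
  if (length(flank) >= 3) {
    rz <- vapply(flank, function(k) {
      dorsal_reference(get_pts(k), crista_fit$center)$radius
    }, numeric(1))
    zz <- (flank - landmarks$crista_index) * 0.5
    obj <- function(Rt) {
      sum((rz - section_radius(crista_fit$radius, Rt, zz))^2)
    }
    Rt <- optimize(obj, c(crista_fit$radius, 4 * crista_fit$radius))$minimum
  }
  head <- metatarsal_head(
    radius = crista_fit$radius,
    transverse_radius = max(Rt, crista_fit$radius),
    tibial_groove = groove_spec(tib$template$inception, tib$template$termination,
                                min(tib$flattening, 0.95), tib$template$trough_frac),
    fibular_groove = groove_spec(fib$template$inception, fib$template$termination,
                                 min(fib$flattening, 0.95), fib$template$trough_frac))
  list(head = head, crista_fit = crista_fit, tibial_fit = tib,
       fibular_fit = fib, landmarks = landmarks)
}

#' Build a full joint model around a reconstructed head
#'
#' Combines a head recovered by [stack_to_model()] with the default platform
#' (sesamoid and phalanx placements scaled to the recovered radius).
#'
#' @param recovered result of [stack_to_model()].
#' @param ... overrides passed to [default_model()].
#' @return An `mpsjc_model`.
#' @export
recovered_joint_model <- function(recovered, ...) {
  h <- recovered$head
  m <- default_model(head_radius = h$radius,
                     transverse_radius = h$transverse_radius, ...)
  m$head <- h
  m
}

#' Write / read a stack as per-section CSV contour files
#'
#' Sections are written as `section_XX.csv` files with an `x,y` header (mm),
#' plus a `ground_truth.json` sidecar for synthetic stacks.
#'
#' @param stack an `mpsjc_stack`.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_stack_csv <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in sort(unique(stack$sections$section))) {
    sub <- stack$sections[stack$sections$section == k, c("x", "y")]
    p <- file.path(dir, sprintf("section_%02d.csv", k))
    writeLines(c("x,y", sprintf("%.9g,%.9g", sub$x, sub$y)), p)
  }
  if (!is.null(stack$ground_truth)) {
    gt <- stack$ground_truth
    gt$spec$span <- as.numeric(gt$spec$span)
    writeLines(as.character(jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA,
                                             pretty = TRUE)),
               file.path(dir, "ground_truth.json"))
  }
  invisible(dir)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(dir) {
  files <- sort(list.files(dir, pattern = "^section_[0-9]+\\.csv$", full.names = TRUE))
  if (!length(files)) abort("no section CSV files found", class = "mpsjc_io_error")
  rows <- lapply(files, function(f) {
    k <- as.integer(sub("^section_0*([0-9]+)\\.csv$", "\\1", basename(f)))
    d <- utils::read.csv(f)
    if (!all(c("x", "y") %in% names(d))) {
      abort(sprintf("%s: contour CSV must have an x,y header", basename(f)),
            class = "mpsjc_io_error")
    }
    tibble::tibble(section = k, z = NA_real_, x = d$x, y = d$y)
  })
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::fromJSON(gt_path, simplifyVector = TRUE) else NULL
  secs <- dplyr::bind_rows(rows)
  if (!is.null(gt$crista_index)) {
    secs$z <- (secs$section - gt$crista_index) * 0.5
  }
  structure(list(sections = secs, ground_truth = gt), class = "mpsjc_stack")
}
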