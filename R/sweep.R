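#' Sweep the declination angle and track centres of rotation
#'
#' Poses the metatarsal at each declination angle of the sweep grid, resolves
#' the phalanx and sesamoid contacts in the tibial and fibular sagittal
#' planes, intersects the contact normals into per-plane centres of rotation,
#' and combines the three normals (phalanx + two sesamoids, each at its
#' z-offset) into the three-dimensional shared instantaneous centre.
#'
#' The normal at contact A is treated as functionally fixed across the sweep
#' for shift attribution; it is recomputed at every step and its drift from
#' the initial direction is asserted to stay below `drift_tol`.
#'
#' @param model an `mpsjc_model`.
#' @param sweep a [sweep_spec()]; defaults to the model's.
#' @param drift_tol maximum tolerated drift (deg) of the A-normal direction.
#' @return An `mpsjc_sweep` object; `tidy()` returns the trajectory tibble
#'   (one row per step and plane), `glance()` a one-row summary.
#' @export
#' @examples
#' sw <- sweep_joint(default_model(), sweep_spec(15, 70, 40, warn = FALSE))
#' glance(sw)
sweep_joint <- function(model, sweep = model$sweep, drift_tol = 5) {
  viol <- validate_model(model)
  if (nrow(viol)) {
    abort(paste0("invalid model: ", paste(viol$invariant, collapse = ", ")))
  }
  thetas <- seq(sweep$theta0, sweep$thetaM, length.out = sweep$n_steps)
  prof <- list(tibial = head_profile(model$head, "tibial"),
               fibular = head_profile(model$head, "fibular"))
  ses <- list(tibial = model$tibial, fibular = model$fibular)
  P <- model$phalanx$center; rp <- model$phalanx$radius
  R <- model$head$radius
  hints <- list(tibial = NULL, fibular = NULL)
  rows <- vector("list", length(thetas))
  A0_dir <- NULL
  for (i in seq_along(thetas)) {
    th <- thetas[i]
    axis <- c(-cos(deg2rad(th)), sin(deg2rad(th)))
    st <- lapply(c(tibial = "tibial", fibular = "fibular"), function(pl) {
      ps <- tryCatch(
        solve_plane_pose(prof[[pl]], th, ses[[pl]]$center, ses[[pl]]$radius,
                         P, rp, hints[[pl]]),
        error = function(e) {
          abort(sprintf("sweep failed at step %d (theta = %.3f deg, %s plane): %s",
                        i, th, pl, conditionMessage(e)),
                class = "mpsjc_contact_failure")
        })
      hints[[pl]] <<- ps$phi
      ps
    })
    if (is.null(A0_dir)) A0_dir <- st$tibial$A_normal$direction
    drift <- line_angle_deg(st$tibial$A_normal$direction, A0_dir)
    if (drift > drift_tol) {
      warn(sprintf("A-normal drift %.2f deg exceeds drift_tol at theta = %.2f", drift, th))
    }
    cbar <- (st$tibial$center + st$fibular$center) / 2
    A_common <- cbar + R * unitize(P - cbar)
    nA <- unitize(cbar - P)
    ## Embed each sesamoid plane's normal in 3D: the line runs from the 3D
    ## contact point towards that plane's own centre of rotation placed in
    ## the inter-sesamoid mid-plane. For a spherical head every such line
    ## passes through the 3D sphere centre, so the three normals concur.
    z_mid <- (ses$tibial$z + ses$fibular$z) / 2
    cr_pt <- lapply(c(tibial = "tibial", fibular = "fibular"), function(pl) {
      cr <- plane_cr(st[[pl]]$A_normal, st[[pl]]$contact_normal, plane = pl)
      if (cr$status == "unique") cr$point else st[[pl]]$center
    })
    lines <- list(
      line3(c(A_common, 0), c(nA, 0)),
      line3(c(st$tibial$contact, ses$tibial$z),
            c(cr_pt$tibial, z_mid) - c(st$tibial$contact, ses$tibial$z)),
      line3(c(st$fibular$contact, ses$fibular$z),
            c(cr_pt$fibular, z_mid) - c(st$fibular$contact, ses$fibular$z)))
    icr <- icr_3d(lines)
    rows[[i]] <- dplyr::bind_rows(lapply(c("tibial", "fibular"), function(pl) {
      ps <- st[[pl]]
      cr <- plane_cr(ps$A_normal, ps$contact_normal, plane = pl)
      pt <- if (cr$status == "unique") cr$point else ps$center
      tibble::tibble(
        step = i, theta_deg = th, plane = pl,
        cr_x = pt[1], cr_y = pt[2], cr_status = cr$status,
        center_x = ps$center[1], center_y = ps$center[2],
        contact_x = ps$contact[1], contact_y = ps$contact[2],
        contact_psi_bone = ps$contact_psi_bone,
        A_x = ps$A[1], A_y = ps$A[2],
        declination_deg = declination_angle(ps$A_normal, axis),
        icr_x = icr$point3[1], icr_y = icr$point3[2], icr_z = icr$point3[3],
        icr_residual = icr$rms_residual,
        a_normal_drift_deg = drift)
    }))
  }
  structure(list(trajectory = dplyr::bind_rows(rows), model = model,
                 sweep = sweep, excursion_tol = 0.005 * R),
            class = "mpsjc_sweep")
}

#' @export
print.mpsjc_sweep <- function(x, ...) {
  cat(sprintf("<mpsjc_sweep> %d steps, theta %g-%g deg; mean ICR residual %.3g mm\n",
              x$sweep$n_steps, x$sweep$theta0, x$sweep$thetaM,
              mean(x$trajectory$icr_residual)))
  invisible(x)
}

#' @rdname sweep_joint
#' @param x an `mpsjc_sweep`.
#' @param ... unused.
#' @export
tidy.mpsjc_sweep <- function(x, ...) x$trajectory

#' @rdname sweep_joint
#' @export
glance.mpsjc_sweep <- function(x, ...) {
  cls <- dplyr::bind_rows(classify_shift(x, "tibial"), classify_shift(x, "fibular"))
  tibble::tibble(
    theta0 = x$sweep$theta0, thetaM = x$sweep$thetaM, n_steps = x$sweep$n_steps,
    tibial_direction = cls$direction[1], fibular_direction = cls$direction[2],
    tibial_max_excursion = cls$max_excursion[1],
    fibular_max_excursion = cls$max_excursion[2],
    max_icr_residual = max(x$trajectory$icr_residual),
    max_a_normal_drift = max(x$trajectory$a_normal_drift_deg))
}

#' Classify the centre-of-rotation shift of one plane over a sweep
#'
#' A proximal shift is a decrease in the centre's x-coordinate relative to its
#' initial (spherical) position beyond `excursion_tol`; distal the reverse.
#' The classification reports the dominant direction, the onset angle (first
#' step beyond tolerance), the return angle (first step after the excursion
#' peak back within tolerance of the initial value), and the peak excursion.
#'
#' @param sweep an `mpsjc_sweep` from [sweep_joint()].
#' @param plane `"tibial"` or `"fibular"`.
#' @param excursion_tol length tolerance (mm); default `0.005 * head radius`.
#' @return A one-row tibble: `plane`, `direction` (`proximal`/`distal`/`none`),
#'   `onset_theta`, `return_theta`, `max_excursion`.
#' @export
classify_shift <- function(sweep, plane = c("tibial", "fibular"),
                           excursion_tol = NULL) {
  plane <- match.arg(plane)
  tol <- excursion_tol %||% sweep$excursion_tol
  tr <- sweep$trajectory[sweep$trajectory$plane == plane, ]
  dx <- tr$cr_x - tr$cr_x[1]
  over <- abs(dx) > tol
  if (!any(over)) {
    return(tibble::tibble(plane = plane, direction = "none",
                          onset_theta = NA_real_, return_theta = NA_real_,
                          max_excursion = max(abs(dx))))
  }
  ipk <- which.max(abs(dx))
  direction <- if (dx[ipk] < 0) "proximal" else "distal"
  onset <- tr$theta_deg[which(over)[1]]
  after <- which(seq_along(dx) > ipk & abs(dx) < tol)
  ret <- if (length(after)) tr$theta_deg[after[1]] else NA_real_
  tibble::tibble(plane = plane, direction = direction, onset_theta = onset,
                 return_theta = ret, max_excursion = abs(dx[ipk]))
}

#' Order of the tibial vs fibular shift onsets
#'
#' The tibial centre of rotation shifts earlier in propulsion than the
#' fibular one when the tibial groove engages its sesamoid first.
#'
#' @inheritParams classify_shift
#' @return A list: `tibial_first` (logical; `NA` on a tie),
#'   `onset_tibial`, `onset_fibular`, `tie` (onsets within one grid step).
#' @export
shift_ordering <- function(sweep, excursion_tol = NULL) {
  ct <- classify_shift(sweep, "tibial", excursion_tol)
  cf <- classify_shift(sweep, "fibular", excursion_tol)
  if (ct$direction == "none" || cf$direction == "none") {
    abort("shift ordering undefined: at least one plane shows no shift",
          class = "mpsjc_undefined_ordering")
  }
  step <- (sweep$sweep$thetaM - sweep$sweep$theta0) / (sweep$sweep$n_steps - 1)
  tie <- abs(ct$onset_theta - cf$onset_theta) <= step
  list(tibial_first = if (tie) NA else ct$onset_theta < cf$onset_theta,
       onset_tibial = ct$onset_theta, onset_fibular = cf$onset_theta,
       tie = tie)
}

#' Impose a small transverse-plane rotation on the platform
#'
#' Rotates the platform elements about the dorsal-plantar (y) axis through the
#' head centre by `angle_deg`, emulating the transverse-plane metatarsal
#' abduction the joint accommodates (about 2 degrees).
#'
#' @param model an `mpsjc_model`.
#' @param angle_deg rotation about the y-axis, degrees.
#' @return The perturbed model.
#' @export
transverse_perturbation <- function(model, angle_deg) {
  ca <- cos(deg2rad(angle_deg)); sa <- sin(deg2rad(angle_deg))
  rot_xz <- function(x, z) c(x * ca + z * sa, -x * sa + z * ca)
  for (s in c("tibial", "fibular")) {
    xz <- rot_xz(model[[s]]$center[1], model[[s]]$z)
    model[[s]]$center[1] <- xz[1]
    model[[s]]$z <- xz[2]
  }
  pz <- rot_xz(model$phalanx$center[1], 0)
  model$phalanx$center[1] <- pz[1]
  model
}

#' Evert the sesamoid-phalanx platform about the long axis
#'
#' An everted metatarsal position is represented by counter-rotating the
#' platform about the distal-proximal (x) axis through the head centre:
#' eversion of the bone by `angle_deg` rotates the sesamoid pair's (y, z)
#' coordinates the opposite way.
#'
#' @param model an `mpsjc_model`.
#' @param angle_deg metatarsal eversion angle, degrees.
#' @return The perturbed model.
#' @export
evert_platform <- function(model, angle_deg) {
  ca <- cos(deg2rad(angle_deg)); sa <- sin(deg2rad(angle_deg))
  for (s in c("tibial", "fibular")) {
    y <- model[[s]]$center[2]; z <- model[[s]]$z
    model[[s]]$center[2] <- y * ca + z * sa
    model[[s]]$z <- -y * sa + z * ca
  }
  model
}
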