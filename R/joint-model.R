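#' Default model constants
#'
#' Numeric defaults for the metatarso-phalangeal-sesamoid joint model.
#' The declination range (15-70 degrees within the published 12-20 / 65-75
#' bounds) and the landmark ordering (tibial sesamoid and groove inception
#' more distal, fibular more proximal) are morphology the model must honour;
#' the remaining magnitudes (head radius 11 mm, sesamoid radii 3.5 mm, groove
#' flattening 0.75 of the convex-compatible depth, about 0.1-0.2 mm of
#' relief, placement angles) are illustrative values chosen to be
#' anatomically plausible, not measurements.
#'
#' @format A named list.
#' @export
mpsjc_defaults <- list(
  head_radius = 11,          # sagittal (crista) radius, mm -- illustrative
  transverse_radius = 12,    # dorsal-view radius, slightly longer, mm
  sesamoid_radius = 3.5,     # mm -- illustrative
  phalanx_radius = 6,        # circular support for contact A, mm
  phalanx_angle = 0,         # platform polar angle of the phalanx centre, deg
  tibial_angle = -88,        # platform polar angle of tibial sesamoid centre
  fibular_angle = -100,      # fibular sesamoid sits more proximal
  tibial_z = 4,              # mm, medial (+z) of the crista plane
  fibular_z = -4,            # mm, lateral
  tibial_groove = list(inception = -62, termination = -22,
                       flattening = 0.75, trough_frac = 0.30, face_tilt = 0),
  fibular_groove = list(inception = -69, termination = -33,
                        flattening = 0.75, trough_frac = 0.70, face_tilt = 0),
  bulge = 0.35,
  profile_span = c(-160, 80),
  theta0 = 15, thetaM = 70, n_steps = 200
)

#' Sesamoid body in the platform frame
#'
#' @param label `"tibial"` or `"fibular"`.
#' @param center in-plane centre `c(x, y)` (mm, platform frame).
#' @param z out-of-plane offset (mm; +z medial, so tibial > fibular).
#' @param radius sesamoid radius (mm, > 0).
#' @return A `sesamoid_body` list.
#' @export
sesamoid_body <- function(label = c("tibial", "fibular"), center, z, radius) {
  label <- match.arg(label)
  stopifnot(length(center) == 2, is.finite(z), radius > 0)
  structure(list(label = label, center = as.numeric(center), z = z,
                 radius = radius), class = "sesamoid_body")
}

#' Phalanx contact support
#'
#' The proximal phalanx is modelled as a circular support whose contact with
#' the metatarsal head is contact point A; radius 0 gives a point support.
#'
#' @param center centre `c(x, y)` (mm, platform frame).
#' @param radius support radius (mm, >= 0).
#' @export
phalanx_contact <- function(center, radius = 0) {
  stopifnot(length(center) == 2, radius >= 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "phalanx_contact")
}

#' Sesamoid groove specification
#'
#' @param inception,termination groove limits as polar angles (deg) on the
#'   sagittal profile; inception is the proximal inception point (T or F).
#' @param flattening trough depth as a fraction of the maximal
#'   convex-compatible depth for the groove's geometry, in `[0, 1)`.
#' @param trough_frac trough position within the groove (0 = at inception).
#' @param face_tilt optional tilt of the trough face (deg).
#' @export
groove_spec <- function(inception, termination, flattening,
                        trough_frac = 0.5, face_tilt = 0) {
  stopifnot(inception < termination, flattening >= 0, flattening < 1,
            trough_frac > 0, trough_frac < 1)
  structure(list(inception = inception, termination = termination,
                 flattening = flattening, trough_frac = trough_frac,
                 face_tilt = face_tilt), class = "groove_spec")
}

#' Orientation of a groove relative to the metatarsal long axis
#'
#' Reports the angle (deg, in `[0, 90]`) between the trough face line and the
#' metatarsal long axis in the bone frame. Small values mean the flattened
#' surface runs nearly parallel to the long axis (fibular-type), large values
#' that it curves towards perpendicular (tibial-type).
#'
#' @param groove a [groove_spec()].
#' @return Angle in degrees.
#' @export
groove_orientation <- function(groove) {
  psi_t <- groove$inception + groove$trough_frac * (groove$termination - groove$inception)
  face_dir <- psi_t + groove$face_tilt + 90  # trough tangent direction, deg
  line_angle_deg(c(cos(deg2rad(face_dir)), sin(deg2rad(face_dir))), c(-1, 0))
}

#' Metatarsal head geometry
#'
#' Holds the sagittal head radius (crista section), the slightly longer
#' transverse radius, and the two sesamoid groove specifications. Per-plane
#' profiles are built on demand with [head_profile()].
#'
#' @param radius sagittal head-circle radius (mm).
#' @param transverse_radius dorsal-view radius (mm, >= `radius`).
#' @param tibial_groove,fibular_groove [groove_spec()] objects.
#' @param span angular domain of the articular profiles (deg).
#' @param bulge conic fullness for groove arcs.
#' @export
metatarsal_head <- function(radius, transverse_radius, tibial_groove,
                            fibular_groove, span = c(-160, 80), bulge = 0.35) {
  stopifnot(radius > 0, transverse_radius > 0)
  structure(list(radius = radius, transverse_radius = transverse_radius,
                 tibial_groove = tibial_groove, fibular_groove = fibular_groove,
                 span = span, bulge = bulge), class = "metatarsal_head")
}

#' Sagittal profile of the head in a named plane
#'
#' @param head a [metatarsal_head()].
#' @param plane `"crista"` (pure circle), `"tibial"` or `"fibular"` (grooved).
#' @return A `composite_profile` in the bone frame (head centre at origin).
#' @export
head_profile <- function(head, plane = c("crista", "tibial", "fibular")) {
  plane <- match.arg(plane)
  if (plane == "crista") {
    return(profile_circle(head$radius, span = head$span))
  }
  g <- if (plane == "tibial") head$tibial_groove else head$fibular_groove
  profile_groove(head$radius, g$inception, g$termination, g$flattening,
                 g$trough_frac, g$face_tilt, head$bulge, span = head$span)
}

#' Sweep specification over the declination angle
#'
#' @param theta0 initial declination angle (deg); the published initial range
#'   is 12-20 degrees.
#' @param thetaM terminal declination angle (deg); published range 65-75.
#' @param n_steps number of sweep steps (>= 2).
#' @param warn warn when the bounds fall outside the published ranges.
#' @export
sweep_spec <- function(theta0 = 15, thetaM = 70, n_steps = 200, warn = TRUE) {
  stopifnot(n_steps >= 2, thetaM > theta0)
  if (warn && (theta0 < 12 || theta0 > 20 || thetaM < 65 || thetaM > 75)) {
    warn("sweep bounds outside the published declination ranges (12-20, 65-75 deg)")
  }
  structure(list(theta0 = theta0, thetaM = thetaM, n_steps = n_steps),
            class = "sweep_spec")
}

#' Assemble a full joint model
#'
#' @param head a [metatarsal_head()].
#' @param tibial,fibular [sesamoid_body()] objects.
#' @param phalanx a [phalanx_contact()].
#' @param sweep a [sweep_spec()].
#' @return An `mpsjc_model`.
#' @export
joint_model <- function(head, tibial, fibular, phalanx, sweep = sweep_spec()) {
  structure(list(head = head, tibial = tibial, fibular = fibular,
                 phalanx = phalanx, sweep = sweep, schema_version = 1L),
            class = "mpsjc_model")
}

#' The default joint model
#'
#' A fully specified metatarso-phalangeal-sesamoid model: spherical head of
#' sagittal radius 11 mm with tibial and fibular grooves, tibial sesamoid more
#' distal and medial, fibular more proximal and lateral, circular phalanx
#' support distally, and a 15-70 degree declination sweep.
#'
#' @param ... named overrides of entries in [mpsjc_defaults].
#' @return An `mpsjc_model`.
#' @export
#' @examples
#' m <- default_model()
#' m$sweep$theta0
default_model <- function(...) {
  d <- modifyList(mpsjc_defaults, list(...))
  standoff <- function(ang) {
    (d$head_radius + d$sesamoid_radius) *
      c(cos(deg2rad(ang)), sin(deg2rad(ang)))
  }
  head <- metatarsal_head(
    radius = d$head_radius, transverse_radius = d$transverse_radius,
    tibial_groove = do.call(groove_spec, d$tibial_groove),
    fibular_groove = do.call(groove_spec, d$fibular_groove),
    span = d$profile_span, bulge = d$bulge)
  joint_model(
    head = head,
    tibial = sesamoid_body("tibial", standoff(d$tibial_angle), d$tibial_z,
                           d$sesamoid_radius),
    fibular = sesamoid_body("fibular", standoff(d$fibular_angle), d$fibular_z,
                            d$sesamoid_radius),
    phalanx = phalanx_contact(c(d$head_radius + d$phalanx_radius, 0),
                              d$phalanx_radius),
    sweep = sweep_spec(d$theta0, d$thetaM, d$n_steps, warn = FALSE))
}

#' @export
print.mpsjc_model <- function(x, ...) {
  cat(sprintf(paste0("<mpsjc_model> head R = %.3g mm (transverse %.3g), ",
                     "sweep %g-%g deg in %d steps\n"),
              x$head$radius, x$head$transverse_radius,
              x$sweep$theta0, x$sweep$thetaM, x$sweep$n_steps))
  invisible(x)
}

#' Validate a joint model against its structural invariants
#'
#' Violations are returned as data, not raised: each row names the invariant
#' and the offending field.
#'
#' @param model an `mpsjc_model`.
#' @return A tibble with columns `invariant`, `field`, `message`; zero rows
#'   for a valid model.
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(invariant, field, message) {
    v[[length(v) + 1]] <<- tibble::tibble(invariant = invariant, field = field,
                                          message = message)
  }
  h <- model$head
  if (h$transverse_radius < h$radius) {
    add("transverse-radius-ordering", "head$transverse_radius",
        "transverse (dorsal-view) radius must be at least the sagittal crista radius")
  }
  if (model$tibial$radius <= 0) add("positive-radius", "tibial$radius", "sesamoid radius must be > 0")
  if (model$fibular$radius <= 0) add("positive-radius", "fibular$radius", "sesamoid radius must be > 0")
  if (model$phalanx$radius < 0) add("nonnegative-radius", "phalanx$radius", "phalanx support radius must be >= 0")
  if (model$tibial$z <= model$fibular$z) {
    add("sesamoid-z-order", "tibial$z",
        "tibial sesamoid must be medial (+z) of the fibular under the +z-medial convention")
  }
  if (model$tibial$center[1] <= model$fibular$center[1]) {
    add("sesamoid-order", "tibial$center",
        "tibial sesamoid must sit more distal (larger x) than the fibular sesamoid")
  }
  for (side in c("tibial", "fibular")) {
    g <- h[[paste0(side, "_groove")]]
    if (g$inception >= g$termination) {
      add("groove-extent", paste0("head$", side, "_groove"),
          "groove inception must precede its termination")
    }
    if (g$flattening < 0 || g$flattening >= 1) {
      add("groove-flattening", paste0("head$", side, "_groove$flattening"),
          "flattening must lie in [0, 1)")
    }
  }
  if (h$tibial_groove$inception <= h$fibular_groove$inception) {
    add("groove-inception-order", "head$tibial_groove$inception",
        "tibial groove inception must be more distal than the fibular inception")
  }
  for (plane in c("crista", "tibial", "fibular")) {
    chk <- tryCatch(profile_check(head_profile(h, plane), n = 360),
                    error = function(e) NULL)
    if (is.null(chk)) {
      add("profile-constructible", paste0("head (", plane, ")"),
          "profile construction failed")
    } else {
      if (chk$junction_position_error > 1e-9 || chk$junction_tangent_error > 1e-6) {
        add("profile-c1", paste0("head (", plane, ")"),
            "arc junctions are not C1 within tolerance")
      }
      if (!chk$convex) {
        add("profile-convex", paste0("head (", plane, ")"),
            "profile is not convex (outward normal not monotone)")
      }
    }
  }
  if (model$sweep$theta0 < 12 || model$sweep$theta0 > 20) {
    add("theta0-range", "sweep$theta0", "theta0 outside the published 12-20 deg range")
  }
  if (model$sweep$thetaM < 65 || model$sweep$thetaM > 75) {
    add("thetaM-range", "sweep$thetaM", "thetaM outside the published 65-75 deg range")
  }
  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(invariant = character(), field = character(), message = character())
  }
}

model_to_list <- function(model) {
  g2l <- function(g) list(inception = g$inception, termination = g$termination,
                          flattening = g$flattening, trough_frac = g$trough_frac,
                          face_tilt = g$face_tilt)
  s2l <- function(s) list(label = s$label, center = s$center, z = s$z,
                          radius = s$radius)
  list(schema_version = model$schema_version,
       units = list(length = "mm", angle = "deg"),
       head = list(radius = model$head$radius,
                   transverse_radius = model$head$transverse_radius,
                   tibial_groove = g2l(model$head$tibial_groove),
                   fibular_groove = g2l(model$head$fibular_groove),
                   span = model$head$span, bulge = model$head$bulge),
       tibial = s2l(model$tibial), fibular = s2l(model$fibular),
       phalanx = list(center = model$phalanx$center, radius = model$phalanx$radius),
       sweep = list(theta0 = model$sweep$theta0, thetaM = model$sweep$thetaM,
                    n_steps = model$sweep$n_steps))
}

#' Serialise a model to canonical JSON
#'
#' Field order and numeric formatting are fixed, so
#' serialise-deserialise-serialise round trips are byte-identical.
#'
#' @param model an `mpsjc_model`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
model_to_json <- function(model, path = NULL) {
  js <- jsonlite::toJSON(model_to_list(model), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param input a file path or JSON string produced by [model_to_json()].
#' @return An `mpsjc_model`.
#' @export
model_from_json <- function(input) {
  x <- jsonlite::fromJSON(input, simplifyVector = TRUE)
  need <- c("head", "tibial", "fibular", "phalanx", "sweep")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("model JSON is missing required field(s): %s",
                  paste(miss, collapse = ", ")),
          class = "mpsjc_schema_error")
  }
  head <- metatarsal_head(
    radius = x$head$radius, transverse_radius = x$head$transverse_radius,
    tibial_groove = do.call(groove_spec, x$head$tibial_groove),
    fibular_groove = do.call(groove_spec, x$head$fibular_groove),
    span = as.numeric(x$head$span), bulge = x$head$bulge)
  joint_model(
    head = head,
    tibial = sesamoid_body("tibial", as.numeric(x$tibial$center), x$tibial$z,
                           x$tibial$radius),
    fibular = sesamoid_body("fibular", as.numeric(x$fibular$center), x$fibular$z,
                            x$fibular$radius),
    phalanx = phalanx_contact(as.numeric(x$phalanx$center), x$phalanx$radius),
    sweep = sweep_spec(x$sweep$theta0, x$sweep$thetaM, x$sweep$n_steps,
                       warn = FALSE))
}

## Rigidly transform the platform elements of a model (equivariance checks).
model_transform <- function(model, g) {
  model$tibial$center <- rigid_apply(g, model$tibial$center)
  model$fibular$center <- rigid_apply(g, model$fibular$center)
  model$phalanx$center <- rigid_apply(g, model$phalanx$center)
  attr(model, "platform_transform") <- g
  model
}
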