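test_that("plane_cr intersects contact normals and flags parallel normals", {
  circ <- profile_circle(11, span = c(-179, 179))
  cr <- plane_cr(normal_line_at(circ, 0), normal_line_at(circ, -88), "tibial")
  expect_identical(cr$status, "unique")
  expect_close(cr$point, c(0, 0), 1e-9)

  par <- plane_cr(line2(c(0, 0), c(0, 1)), line2(c(1, 0), c(0, 1)))
  expect_identical(par$status, "parallel-normals")
  expect_true(anyNA(par$point))
})

test_that("groove contact shifts the plane CR in the morphology's direction", {
  ## tibial-type groove (steep wall right after inception): on the wall the
  ## inward normals point proximal, so the CR x drops below the spherical
  ## centre -- the tangent angle with A turning more obtuse
  tib <- profile_groove(11, -62, -22, 0.75, 0.3)
  nA <- line2(c(11, 0), c(-1, 0))
  crT <- plane_cr(nA, normal_line_at(tib, -55), "tibial")
  expect_lt(crT$point[1], 0)

  ## fibular-type groove (steep wall at the distal portion): normals there
  ## point distal, CR x above the spherical centre
  fib <- profile_groove(11, -69, -33, 0.75, 0.7)
  crF <- plane_cr(nA, normal_line_at(fib, -38), "fibular")
  expect_gt(crF$point[1], 0)
})

test_that("icr_3d returns concurrent-line centres exactly", {
  mk <- function(p, d) list(p = p, d = d)
  lines <- list(mk(c(1, 0, 0), c(-1, 0, 0)),
                mk(c(0, 2, 0), c(0, -1, 0)),
                mk(c(0, 0, 3), c(0, 0, -1)))
  r <- icr_3d(lines)
  expect_close(r$point3, c(0, 0, 0), 1e-12)
  expect_lt(r$rms_residual, 1e-12)
})

test_that("icr_3d matches a numerical minimiser on perturbed line triples", {
  set.seed(77)
  for (i in 1:20) {
    lines <- lapply(1:3, function(j) {
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      list(p = rnorm(3, sd = 5) + runif(3, -0.1, 0.1), d = d)
    })
    r <- icr_3d(lines)
    obj <- function(x) {
      sum(vapply(lines, function(l) {
        v <- x - l$p
        sum(v^2) - sum(v * l$d)^2
      }, numeric(1)))
    }
    o <- optim(c(0, 0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
    expect_close(r$point3, o$par, 1e-5)
  }
})

test_that("icr_3d rejects near-parallel degenerate line sets", {
  lines <- list(list(p = c(0, 0, 0), d = c(1, 0, 0)),
                list(p = c(0, 1, 0), d = c(1, 0, 0)),
                list(p = c(0, 0, 1), d = c(1, 1e-9, 0)))
  expect_error(icr_3d(lines), class = "mpsjc_degenerate_geometry")
})

test_that("the 3D centre lies between the plane centres when one plane grooves", {
  ## two spherical normals through the origin plus a tilted tibial groove normal
  l_A <- list(p = c(11, 0, 0), d = c(-1, 0, 0))
  l_F <- list(p = c(0, -11, -4), d = c(0.05, 1, -0.36))  # near-concurrent
  tib <- profile_groove(11, -62, -22, 0.6, 0.7)
  nl <- normal_line_at(tib, -50)
  cr <- intersect_lines(line2(c(11, 0), c(-1, 0)), nl)
  l_T <- list(p = c(nl$origin, 4), d = c(cr - nl$origin, -4))
  r <- icr_3d(list(l_A, l_F, l_T))
  expect_gt(r$point3[1], min(cr[1], 0) - 1e-9)
  expect_lt(r$point3[1], max(cr[1], 0) + 1e-9)
})

test_that("declination_angle equals the line angle to the long axis", {
  ## default model posed at the initial stance: exactly theta0
  m <- default_model()
  prof <- head_profile(m$head, "tibial")
  ps <- mpsjc:::solve_plane_pose(prof, 15, m$tibial$center, m$tibial$radius,
                                 m$phalanx$center, m$phalanx$radius)
  axis <- c(-cos(15 * pi / 180), sin(15 * pi / 180))
  expect_close(declination_angle(ps$A_normal, axis), 15, 1e-6)

  ## long axis parallel to the A-normal gives zero
  expect_close(declination_angle(line2(c(0, 0), c(1, 0)), c(-1, 0)), 0, 1e-12)

  ## random poses: arccos of the absolute dot product
  set.seed(9)
  for (i in 1:20) {
    nd <- runif(2, -1, 1); ad <- runif(2, -1, 1)
    nd <- nd / sqrt(sum(nd^2)); ad <- ad / sqrt(sum(ad^2))
    expect_close(declination_angle(line2(c(0, 0), nd), ad),
                 acos(abs(sum(nd * ad))) * 180 / pi, 1e-9)
  }
})

test_that("surface speed responds to CR shifts as the geometry dictates", {
  expect_identical(surface_speed(c(3, 2), c(3, 2)), 0)
  distal_edge <- c(11, 0); proximal_end <- c(-25, 2)
  cr0 <- c(0, 0); cr_shifted <- c(2, 0)   # distal CR shift
  expect_lt(surface_speed(distal_edge, cr_shifted), surface_speed(distal_edge, cr0))
  expect_gt(surface_speed(proximal_end, cr_shifted), surface_speed(proximal_end, cr0))
  ## speeds scale linearly in omega
  expect_close(surface_speed(distal_edge, cr0, 30), 30 * surface_speed(distal_edge, cr0), 1e-12)
})

test_that("x-axis obliquity is zero for level contacts and signed by tibial offset", {
  axis <- c(-1, 0)
  lev <- x_axis_obliquity(c(1, -10, 4), c(1, -10, -4), axis)
  expect_close(lev$obliquity_deg, 0, 1e-9)
  expect_identical(lev$icr_displacement_label, "none")

  obl <- x_axis_obliquity(c(2, -10, 4), c(-1, -10, -4), axis)
  expect_gt(obl$obliquity_deg, 0)
  expect_identical(obl$icr_displacement_label, "lateral-proximal")

  mir <- x_axis_obliquity(c(-1, -10, 4), c(2, -10, -4), axis)
  expect_close(mir$obliquity_deg, -obl$obliquity_deg, 1e-9)

  expect_error(x_axis_obliquity(c(1, 1, 1), c(1, 1, 1), axis),
               class = "mpsjc_degenerate_geometry")
})
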