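test_that("tangents and inward normals of canonical arcs are correct", {
  circ <- profile_circle(1)
  expect_close(tangent_at(circ, 0), c(0, 1), 1e-12)
  nl <- normal_line_at(circ, 0)
  expect_close(nl$origin, c(1, 0), 1e-12)
  expect_close(nl$direction, c(-1, 0), 1e-12)

  ## circle normals are radial: any normal passes through the centre
  circ2 <- profile_circle(7, center = c(2, -3), span = c(-170, 170))
  for (psi in c(-120, -45, 10, 88)) {
    nl <- normal_line_at(circ2, psi)
    expect_lt(mpsjc:::point_line_distance(c(2, -3), nl), 1e-9)
  }
})

test_that("profile tangents agree with central finite differences", {
  prof <- profile_groove(11, -62, -22, 0.4, 0.7)
  h <- 1e-4
  for (psi in c(-100, -55, -40, -24, 30)) {
    tg <- tangent_at(prof, psi)
    fd <- (drop(profile_point(prof, psi + h)) -
             drop(profile_point(prof, psi - h)))
    expect_close(tg, fd / sqrt(sum(fd^2)), 1e-6)
  }
})

test_that("groove-arc normals match the implicit-conic gradient numerically", {
  prof <- profile_groove(11, -60, -25, 0.5, 0.3)
  for (psi in c(-55, -49, -40, -28)) {
    X <- drop(profile_point(prof, psi))
    nl <- normal_line_at(prof, psi)
    ## numerical gradient of the active conic
    a <- mpsjc:::active_arc(prof, psi)
    h <- 1e-6
    g <- c(mpsjc:::conic_eval(a$q, X + c(h, 0)) - mpsjc:::conic_eval(a$q, X - c(h, 0)),
           mpsjc:::conic_eval(a$q, X + c(0, h)) - mpsjc:::conic_eval(a$q, X - c(0, h)))
    g <- g / sqrt(sum(g^2))
    expect_close(nl$direction, -g, 1e-6)
  }
})

test_that("parameters outside the profile domain raise a domain error", {
  prof <- profile_circle(5, span = c(-90, 90))
  expect_error(tangent_at(prof, 120), class = "mpsjc_domain_error")
  expect_error(normal_line_at(prof, -95), class = "mpsjc_domain_error")
})

test_that("intersect_lines solves the 2x2 system and flags parallels", {
  ## normals of the unit circle at two angles meet at the centre
  circ <- profile_circle(1, span = c(-170, 170))
  p <- intersect_lines(normal_line_at(circ, 10), normal_line_at(circ, 80))
  expect_close(p, c(0, 0), 1e-12)

  expect_error(intersect_lines(line2(c(0, 0), c(1, 0)), line2(c(0, 1), c(1, 0))),
               class = "mpsjc_parallel_lines")

  ## random pairs against an explicit linear solve
  set.seed(11)
  for (i in 1:25) {
    o1 <- runif(2, -5, 5); o2 <- runif(2, -5, 5)
    a1 <- runif(1, 0, 2 * pi); a2 <- a1 + runif(1, 0.3, pi - 0.3)
    l1 <- line2(o1, c(cos(a1), sin(a1)))
    l2 <- line2(o2, c(cos(a2), sin(a2)))
    p <- intersect_lines(l1, l2)
    ## oracle: solve [d1 -d2] t = o2 - o1
    t12 <- solve(cbind(l1$direction, -l2$direction), o2 - o1)
    expect_close(p, o1 + t12[1] * l1$direction, 1e-9)
    expect_lt(mpsjc:::point_line_distance(p, l1), 1e-9)
    expect_lt(mpsjc:::point_line_distance(p, l2), 1e-9)
  }
})

test_that("tangent/normal/intersection are equivariant under rigid motions", {
  set.seed(21)
  prof <- profile_groove(11, -62, -22, 0.4, 0.7)
  for (i in 1:10) {
    g <- random_rigid()
    profT <- mpsjc:::profile_transform(prof, g)
    ang <- mpsjc:::rad2deg(atan2(g$R[2, 1], g$R[1, 1]))
    for (psi in c(-50, -30, 20)) {
      X <- drop(profile_point(prof, psi))
      XT <- drop(profile_point(profT, psi + ang))
      expect_close(XT, mpsjc:::rigid_apply(g, X), 1e-9)
      nl <- normal_line_at(prof, psi)
      nlT <- normal_line_at(profT, psi + ang)
      expect_close(nlT$direction, as.numeric(g$R %*% nl$direction), 1e-9)
    }
  }
})

test_that("circle-normal concurrency holds for random circles (circle oracle)", {
  set.seed(31)
  for (i in 1:50) {
    ctr <- runif(2, -10, 10)
    R <- runif(1, 1, 20)
    circ <- profile_circle(R, ctr, span = c(-179, 179))
    psis <- sort(runif(2, -170, 170))
    if (diff(psis) < 5) psis[2] <- psis[1] + 10
    cr <- intersect_lines(normal_line_at(circ, psis[1]),
                          normal_line_at(circ, psis[2]))
    expect_close(cr, ctr, 1e-9 * R)
  }
})
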