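#' Construct a 2D line from an origin point and a direction
#'
#' Lines carry a point on the line (`origin`) and a unit `direction`. They are
#' used for the tangent and inward-normal lines of articular profiles; two
#' contact normals intersected give a centre of rotation.
#'
#' @param origin numeric length-2, a point on the line (mm).
#' @param direction numeric length-2, direction; normalised internally.
#' @return An object of class `line2`.
#' @export
#' @examples
#' line2(c(1, 0), c(-1, 0))
line2 <- function(origin, direction) {
  stopifnot(is.numeric(origin), length(origin) == 2, all(is.finite(origin)),
            is.numeric(direction), length(direction) == 2, all(is.finite(direction)))
  structure(list(origin = as.numeric(origin), direction = unitize(as.numeric(direction))),
            class = "line2")
}

#' @export
print.line2 <- function(x, ...) {
  cat(sprintf("<line2> through (%.6g, %.6g) along (%.6g, %.6g)\n",
              x$origin[1], x$origin[2], x$direction[1], x$direction[2]))
  invisible(x)
}

#' Intersect two 2D lines
#'
#' Solves the 2x2 linear system for the intersection point. When the lines are
#' parallel within `parallel_tol` (an angle in radians) no unique intersection
#' exists; for centre-of-rotation sweeps this is the regime in which the two
#' contact normals coincide and the centre is unchanged, so the caller decides
#' how to interpret it via `on_parallel`.
#'
#' @param l1,l2 `line2` objects.
#' @param parallel_tol angle in radians below which the lines count as parallel.
#' @param on_parallel `"error"` (default) or `"na"` to return `c(NA, NA)`.
#' @return Numeric length-2 intersection point.
#' @export
#' @examples
#' intersect_lines(line2(c(0, -1), c(0, 1)), line2(c(-1, 0), c(1, 0)))
intersect_lines <- function(l1, l2, parallel_tol = 1e-8, on_parallel = c("error", "na")) {
  on_parallel <- match.arg(on_parallel)
  stopifnot(inherits(l1, "line2"), inherits(l2, "line2"))
  s <- abs(l1$direction[1] * l2$direction[2] - l1$direction[2] * l2$direction[1])
  if (s < sin(parallel_tol)) {
    if (on_parallel == "na") return(c(NA_real_, NA_real_))
    abort("no unique intersection: lines are parallel within tolerance",
          class = "mpsjc_parallel_lines")
  }
  A <- cbind(l1$direction, -l2$direction)
  t <- solve(A, l2$origin - l1$origin)
  l1$origin + t[1] * l1$direction
}

## Distance from a point to a line2.
point_line_distance <- function(p, l) {
  d <- p - l$origin
  abs(d[1] * l$direction[2] - d[2] * l$direction[1])
}

## Apply a rigid transform g = list(R = 2x2 rotation, t = translation) to
## points (rows or length-2) / line2 objects.
rigid_apply <- function(g, x) {
  if (inherits(x, "line2")) {
    return(line2(as.numeric(g$R %*% x$origin) + g$t, as.numeric(g$R %*% x$direction)))
  }
  if (is.matrix(x)) return(t(g$R %*% t(x)) + matrix(g$t, nrow(x), 2, byrow = TRUE))
  as.numeric(g$R %*% x) + g$t
}
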