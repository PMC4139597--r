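## Small row-wise vector helpers for n x 3 coordinate matrices.

row_norm <- function(m) sqrt(rowSums(m * m))

row_unit <- function(m) {
  n <- row_norm(m)
  if (any(n < 1e-12)) stop("zero-length vector encountered while normalising")
  m / n
}

row_dot <- function(a, b) rowSums(a * b)

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## clamp into [-1, 1] before acos
clamp1 <- function(x) pmin(1, pmax(-1, x))

as_mat3 <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("expected an n x 3 coordinate matrix")
  storage.mode(x) <- "double"
  x
}

## deterministic orthonormal frame completing a single unit vector u:
## returns list(e1, e2) with {e1, e2, u} right-handed orthonormal.
perp_frame <- function(u) {
  ref <- diag(3)[, which.min(abs(u))]
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

## signed dihedral angle of point rows (p1,p2,p3,p4), IUPAC convention:
## cis = 0, trans = pi, right-handed positive. Vectorised over rows.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  m1 <- row_cross(n1, b2 / row_norm(b2))
  atan2(row_dot(m1, n2), row_dot(n1, n2))
}

## interior angle at p2 for rows (p1,p2,p3)
bend_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(clamp1(row_dot(u, v) / (row_norm(u) * row_norm(v))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## wrap angle into (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}
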