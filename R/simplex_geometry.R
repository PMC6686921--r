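# Row-wise cross product of two n x 3 matrices.
rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Build the anchor-group triangle in distance space
#'
#' Each anchor group (E = European, F = African, A = East Asian) is placed at
#' the 3-space point whose coordinates are its expected distances to the first
#' three reference populations. Connecting the three points gives the triangle
#' whose barycentric coordinates define ancestry proportions.
#'
#' @param d_E,d_F,d_A length-3 numeric expected-distance triples.
#' @return object of class `triadmix_triangle`: a 3 x 3 matrix with rows
#'   `E`, `F`, `A`.
#' @export
build_triangle <- function(d_E, d_F, d_A) {
  V <- rbind(E = as.numeric(d_E), F = as.numeric(d_F), A = as.numeric(d_A))
  if (!all(is.finite(V)) || ncol(V) != 3L) {
    stop("vertex triples must be finite length-3 numerics")
  }
  a <- V["A", ] - V["F", ]
  e <- V["E", ] - V["F", ]
  area2 <- sqrt(sum(rowcross(rbind(a), rbind(e))^2))
  per <- sqrt(sum(a^2)) + sqrt(sum(e^2)) + sqrt(sum((a - e)^2))
  if (area2 <= 1e-12 * max(per^2, .Machine$double.xmin)) {
    stop("degenerate triangle: anchor-group points are collinear")
  }
  structure(V, class = c("triadmix_triangle", "matrix", "array"))
}

#' Rigidly map a triangle (and subject points) onto the z = 0 plane
#'
#' Applies the fixed rigid transform: origin at vertex F, the F-to-A side
#' along the positive x-axis, vertex E in the upper half plane (y > 0), and
#' the out-of-plane axis given by the right-handed normal
#' \eqn{(V_A - V_F) \times (V_E - V_F)}. The transform is a rotation plus
#' translation, so all pairwise distances are preserved; the signed z
#' coordinate of a transformed subject point is its out-of-plane score.
#'
#' @param tri a `triadmix_triangle`.
#' @param points optional n x 3 matrix of subject points to transform with the
#'   triangle.
#' @return object of class `triadmix_frame`: list with `vertices2d` (3 x 2,
#'   rows E/F/A), `origin`, `axes` (3 x 3, rows u/v/w), `detT` (twice the
#'   signed triangle area), `perimeter`, and — when `points` is supplied —
#'   `points` (n x 3 matrix of in-frame x, y and out-of-plane z).
#' @export
planarize <- function(tri, points = NULL) {
  stopifnot(inherits(tri, "triadmix_triangle"))
  V <- unclass(tri)
  a <- V["A", ] - V["F", ]
  e <- V["E", ] - V["F", ]
  an <- sqrt(sum(a^2))
  u <- a / an
  w0 <- as.numeric(rowcross(rbind(a), rbind(e)))
  wn <- sqrt(sum(w0^2))
  per <- an + sqrt(sum(e^2)) + sqrt(sum((a - e)^2))
  if (wn <= 1e-12 * max(per^2, .Machine$double.xmin)) {
    stop("degenerate triangle: cannot planarize")
  }
  w <- w0 / wn
  v <- as.numeric(rowcross(rbind(w), rbind(u)))
  vertices2d <- rbind(E = c(sum(e * u), sum(e * v)),
                      F = c(0, 0),
                      A = c(an, 0))
  colnames(vertices2d) <- c("x", "y")
  frame <- structure(
    list(vertices2d = vertices2d,
         origin = V["F", ],
         axes = rbind(u = u, v = v, w = w),
         detT = an * vertices2d["E", "y"],
         perimeter = per),
    class = "triadmix_frame"
  )
  if (!is.null(points)) {
    frame$points <- frame_project(frame, points)
  }
  frame
}

#' Project 3-space points into a planar frame
#'
#' @param frame a `triadmix_frame`.
#' @param points n x 3 matrix (or length-3 vector) of points.
#' @return n x 3 matrix with columns `x`, `y` (in-plane) and `z`
#'   (out-of-plane, signed).
#' @export
frame_project <- function(frame, points) {
  stopifnot(inherits(frame, "triadmix_frame"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  d <- sweep(points, 2L, frame$origin)
  out <- d %*% t(frame$axes)
  colnames(out) <- c("x", "y", "z")
  out
}

# TRUE when the frame's barycentric solve is numerically unreliable.
frame_unstable <- function(frame, tol = 1e-9) {
  abs(frame$detT) < tol * frame$perimeter^2
}

# Signed double area of triangle (q, b, c): det [[1 xq yq][1 xb yb][1 xc yc]].
det3 <- function(qx, qy, bx, by, cx, cy) {
  (bx - qx) * (cy - qy) - (cx - qx) * (by - qy)
}

#' Barycentric coordinates of in-plane points
#'
#' Solves for the unique affine weights (lambda_e, lambda_f, lambda_a) with
#' \eqn{Q = \lambda_e V_E + \lambda_f V_F + \lambda_a V_A} and
#' \eqn{\sum \lambda = 1}, using the ratio-of-determinants form: each lambda
#' is the 3 x 3 determinant obtained by replacing the corresponding vertex row
#' of \eqn{T = [[1, x_e, y_e], [1, x_f, y_f], [1, x_a, y_a]]} with the query
#' point, divided by det(T). Coordinates are signed; points outside the
#' triangle get negative entries.
#'
#' @param frame a `triadmix_frame`.
#' @param q n x 2 matrix (or length-2 vector) of in-plane points.
#' @return n x 3 matrix with columns `lambda_e`, `lambda_f`, `lambda_a`,
#'   rows summing to 1.
#' @export
barycentric <- function(frame, q) {
  stopifnot(inherits(frame, "triadmix_frame"))
  if (frame_unstable(frame)) {
    stop("unstable frame: triangle too close to degenerate for barycentric solve")
  }
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  V <- frame$vertices2d
  dT <- frame$detT
  le <- det3(q[, 1], q[, 2], V["F", 1], V["F", 2], V["A", 1], V["A", 2]) / dT
  lf <- det3(V["E", 1], V["E", 2], q[, 1], q[, 2], V["A", 1], V["A", 2]) / dT
  la <- det3(V["E", 1], V["E", 2], V["F", 1], V["F", 2], q[, 1], q[, 2]) / dT
  cbind(lambda_e = le, lambda_f = lf, lambda_a = la)
}

#' Ancestry proportions from barycentric coordinates
#'
#' Inside the triangle the proportions are the barycentric coordinates
#' themselves. Points falling outside (some lambda < 0) are clamped:
#' \deqn{P_m = \max(0, \lambda_m) / \sum_r \max(0, \lambda_r)}
#'
#' @param lambda n x 3 matrix (or length-3 vector) of barycentric coordinates,
#'   rows summing to 1.
#' @return n x 3 matrix with columns `P_e`, `P_f`, `P_a`; entries in
#'   \code{[0, 1]}, rows summing to 1.
#' @export
ancestry_proportions <- function(lambda) {
  if (is.null(dim(lambda))) lambda <- matrix(lambda, nrow = 1L)
  stopifnot(ncol(lambda) == 3L)
  if (any(abs(rowSums(lambda) - 1) > 1e-6)) {
    stop("barycentric coordinates must sum to 1")
  }
  lp <- pmax(lambda, 0)
  tot <- rowSums(lp)
  tot[tot <= 0] <- NA_real_  # cannot occur when rows sum to 1; guarded anyway
  out <- lp / tot
  colnames(out) <- c("P_e", "P_f", "P_a")
  out
}

#' Map barycentric coordinates back to Cartesian coordinates of a frame
#'
#' Re-expresses coordinates computed against one triangle on another
#' (typically the full-panel reference triangle):
#' \eqn{x = \lambda_e x_e + \lambda_f x_f + \lambda_a x_a} and likewise for y.
#' Composed with [barycentric()] on the same frame this is the identity.
#'
#' @param lambda n x 3 matrix (or length-3 vector) of barycentric coordinates.
#' @param frame the target `triadmix_frame`.
#' @return n x 2 matrix of `x`, `y` coordinates in the target frame.
#' @export
barycentric_to_cartesian <- function(lambda, frame) {
  stopifnot(inherits(frame, "triadmix_frame"))
  if (is.null(dim(lambda))) lambda <- matrix(lambda, nrow = 1L)
  out <- lambda %*% frame$vertices2d  # rows E, F, A match lambda order
  colnames(out) <- c("x", "y")
  out
}

#' @export
print.triadmix_frame <- function(x, ...) {
  cat("planar triangle frame (rows E/F/A):\n")
  print(round(x$vertices2d, 6))
  invisible(x)
}
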