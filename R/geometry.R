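## Planar geometry helpers shared by the hullset and metrics layers.
## All coordinates are metres in the local projection; areas are returned
## in m^2 by the low-level helpers and converted to km^2 at the API surface.

#' Convex hull of a point set
#'
#' Thin wrapper around [grDevices::chull()] returning the hull vertices in
#' counter-clockwise order, with degeneracy detection. A point set with
#' fewer than 3 distinct, non-collinear points yields a degenerate hull
#' (zero area).
#'
#' @param x,y Numeric coordinate vectors (metres).
#' @return List with `x`, `y` (hull vertices, CCW), `area` (m^2) and
#'   logical `degenerate`.
#' @keywords internal
convex_hull <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) {
    return(list(x = pts[, 1], y = pts[, 2], area = 0, degenerate = TRUE))
  }
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[idx, 1]
  hy <- pts[idx, 2]
  a <- polygon_area(hx, hy)
  if (a < 0) { # chull returns clockwise; enforce CCW
    hx <- rev(hx)
    hy <- rev(hy)
    a <- -a
  }
  list(x = hx, y = hy, area = a, degenerate = a <= 0)
}

#' Signed polygon area (shoelace)
#' @keywords internal
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Polygon perimeter
#' @keywords internal
polygon_perimeter <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  j <- c(n, seq_len(n - 1))
  sum(sqrt((x - x[j])^2 + (y - y[j])^2))
}

#' Union of a list of polygons
#'
#' Merges polygons (each a list with `x`, `y`) into a single region using
#' Clipper (nonzero fill) via \pkg{polyclip}. Returns the union paths with
#' total area (holes subtract) and total boundary length.
#'
#' @param polys List of polygons, each `list(x=, y=)` in metres.
#' @return List with `paths` (list of x/y rings), `area` (m^2),
#'   `perimeter` (m).
#' @keywords internal
polygon_union <- function(polys) {
  polys <- Filter(function(p) length(p$x) >= 3, polys)
  if (length(polys) == 0) {
    return(list(paths = list(), area = 0, perimeter = 0))
  }
  paths <- lapply(polys, function(p) list(x = p$x, y = p$y))
  u <- polyclip::polyclip(paths, paths[1], op = "union",
                          fillA = "nonzero", fillB = "nonzero",
                          closed = TRUE)
  area <- sum(vapply(u, function(p) polygon_area(p$x, p$y), numeric(1)))
  per <- sum(vapply(u, function(p) polygon_perimeter(p$x, p$y), numeric(1)))
  list(paths = u, area = abs(area), perimeter = per)
}

#' Points inside (or on the boundary of) a polygon
#'
#' Boundary-inclusive membership test; relies on
#' [sp::point.in.polygon()], whose return codes 1 (interior), 2 (edge)
#' and 3 (vertex) all count as inside.
#'
#' @param px,py Query points (metres).
#' @param poly Polygon `list(x=, y=)`.
#' @return Logical vector.
#' @keywords internal
points_in_polygon <- function(px, py, poly) {
  if (length(poly$x) < 3) return(rep(FALSE, length(px)))
  sp::point.in.polygon(px, py, poly$x, poly$y) > 0
}

#' Points inside a union of polygons (any-hull membership)
#' @keywords internal
points_in_any <- function(px, py, polys) {
  inside <- rep(FALSE, length(px))
  for (p in polys) {
    todo <- which(!inside)
    if (length(todo) == 0) break
    ## bounding-box prefilter keeps large hullsets affordable
    bb <- todo[px[todo] >= min(p$x) & px[todo] <= max(p$x) &
                 py[todo] >= min(p$y) & py[todo] <= max(p$y)]
    if (length(bb) == 0) next
    inside[bb] <- points_in_polygon(px[bb], py[bb], p)
  }
  inside
}

#' Minimum-area enclosing ellipse (Khachiyan iteration)
#'
#' Computes the Loewner-John ellipse of a planar point set by the standard
#' barycentric-coordinate ascent. Used for hull eccentricity.
#'
#' @param x,y Point coordinates.
#' @param tol Convergence tolerance on the barycentric update (default
#'   1e-7).
#' @param max_iter Iteration cap.
#' @return List with `center` (length-2), `shape` (2x2 matrix A such that
#'   (p-c)' A (p-c) <= 1 on the ellipse), `axes` (semi-axes, descending).
#' @keywords internal
min_enclosing_ellipse <- function(x, y, tol = 1e-7, max_iter = 5000) {
  P <- unique(cbind(x, y))
  n <- nrow(P)
  stopifnot(n >= 2)
  d <- 2
  Q <- rbind(t(P), rep(1, n)) # 3 x n lifted points
  u <- rep(1 / n, n)
  ## Frank-Wolfe with away steps (Todd-Yildirim): far faster than the
  ## plain Khachiyan ascent once the support set has been found
  for (it in seq_len(max_iter)) {
    X <- Q %*% (u * t(Q))
    Xi <- tryCatch(solve(X), error = function(e) NULL)
    if (is.null(Xi)) break # collinear: fall through to degenerate handling
    M <- colSums(Q * (Xi %*% Q)) # Mahalanobis distances
    jp <- which.max(M)
    gap_plus <- M[jp] - (d + 1)
    pos <- which(u > 0)
    jm <- pos[which.min(M[pos])]
    gap_minus <- (d + 1) - M[jm]
    if (gap_plus < (d + 1) * tol && gap_minus < (d + 1) * tol) break
    if (gap_plus >= gap_minus) {
      lam <- gap_plus / ((d + 1) * (M[jp] - 1))
      if (!is.finite(lam) || lam <= 0) break
      u <- (1 - lam) * u
      u[jp] <- u[jp] + lam
    } else {
      lam <- min(gap_minus / ((d + 1) * (M[jm] - 1)),
                 u[jm] / (1 - u[jm]))
      if (!is.finite(lam) || lam <= 0) break
      u <- (1 + lam) * u
      u[jm] <- u[jm] - lam
      u[u < 0] <- 0
      u <- u / sum(u)
    }
  }
  c0 <- as.numeric(t(P) %*% u)
  Pc <- sweep(P, 2, c0)
  S <- crossprod(Pc * sqrt(u)) # sum u_i (p_i-c)(p_i-c)'
  A <- tryCatch(solve(S) / d, error = function(e) NULL)
  if (is.null(A)) {
    ## collinear set: degenerate ellipse, minor axis 0
    ev <- eigen(S, symmetric = TRUE)$values
    len <- sqrt(pmax(ev, 0) * d)
    return(list(center = c0, shape = NULL, axes = sort(len, decreasing = TRUE)))
  }
  ev <- eigen(A, symmetric = TRUE)$values
  axes <- sort(1 / sqrt(ev), decreasing = TRUE)
  list(center = c0, shape = A, axes = axes)
}
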