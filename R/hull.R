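# Convex hull over anchor atoms.  The anchor sets this method uses (the
# alpha-carbons enclosing a binding region) are small, so the hull is built
# by exhaustive enumeration of supporting planes: a triple of points spans a
# facet plane iff all remaining points lie on one side.  Containment is then
# a closed half-space test, and the volume follows from the facet polygons
# via the divergence theorem.

#' Build the convex hull of a set of 3D anchor points
#'
#' @param anchor_points `n x 3` matrix of coordinates (Angstrom); `n >= 4`,
#'   not all coplanar
#' @return object of class `hull_region`: outward unit `normals` (`m x 3`),
#'   plane `offsets` (point `p` is inside iff `normals %*% p <= offsets`
#'   within tolerance), `volume`, `vertices` (indices of anchor points on
#'   the hull) and the anchors themselves
#' @export
build_hull <- function(anchor_points) {
  P <- as.matrix(anchor_points)
  if (ncol(P) != 3L) stop("anchor points must be n x 3", call. = FALSE)
  n <- nrow(P)
  if (n < 4L) stop("need at least 4 anchor points", call. = FALSE)
  scale <- max(apply(P, 2, function(col) diff(range(col))), 1e-9)
  tol <- 1e-9 * scale
  ctr <- colMeans(P)
  if (qr(sweep(P, 2, ctr))$rank < 3L) {
    stop("degenerate anchors: points are coplanar or collinear",
         call. = FALSE)
  }
  triples <- combn(n, 3L)
  normals <- list(); offsets <- numeric(0)
  keys <- character(0)
  on_hull <- logical(n)
  for (t in seq_len(ncol(triples))) {
    i <- triples[1, t]; j <- triples[2, t]; k <- triples[3, t]
    v1 <- P[j, ] - P[i, ]; v2 <- P[k, ] - P[i, ]
    nv <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    nn <- sqrt(sum(nv^2))
    if (nn < tol * scale) next
    nv <- nv / nn
    d <- sum(nv * P[i, ])
    side <- P %*% nv - d
    if (all(side <= tol)) {
      # outward already
    } else if (all(side >= -tol)) {
      nv <- -nv; d <- -d; side <- -side
    } else next
    key <- paste(round(c(nv, d / scale), 7), collapse = "/")
    if (key %in% keys) {
      on_hull[abs(side) <= tol] <- TRUE
      next
    }
    keys <- c(keys, key)
    normals[[length(normals) + 1L]] <- nv
    offsets <- c(offsets, d)
    on_hull[abs(side) <= tol] <- TRUE
  }
  N <- do.call(rbind, normals)
  # volume: sum over facet polygons of area * distance(centroid, plane) / 3
  vol <- 0
  for (f in seq_len(nrow(N))) {
    nv <- N[f, ]; d <- offsets[f]
    side <- as.vector(P %*% nv) - d
    verts <- which(abs(side) <= tol)
    if (length(verts) < 3L) next
    # orthonormal in-plane basis
    a <- if (abs(nv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * nv) * nv; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nv[2] * e1[3] - nv[3] * e1[2],
            nv[3] * e1[1] - nv[1] * e1[3],
            nv[1] * e1[2] - nv[2] * e1[1])
    uv <- cbind(P[verts, , drop = FALSE] %*% e1,
                P[verts, , drop = FALSE] %*% e2)
    h <- grDevices::chull(uv[, 1], uv[, 2])
    poly <- uv[h, , drop = FALSE]
    m <- nrow(poly)
    area <- abs(sum(poly[, 1] * poly[c(2:m, 1), 2] -
                    poly[c(2:m, 1), 1] * poly[, 2])) / 2
    vol <- vol + area * (d - sum(nv * ctr)) / 3
  }
  structure(list(anchor_points = P, normals = N, offsets = offsets,
                 vertices = which(on_hull), volume = vol, tol = tol),
            class = "hull_region")
}

#' @export
print.hull_region <- function(x, ...) {
  cat("<hull_region> ", nrow(x$anchor_points), " anchors, ",
      nrow(x$normals), " facet planes, volume ", signif(x$volume, 5),
      " A^3\n", sep = "")
  invisible(x)
}

#' Closed containment test against a hull
#'
#' Points on the hull surface count as inside.
#'
#' @param hull a [build_hull()] object
#' @param points vector of length 3 or `n x 3` matrix
#' @param tol containment tolerance (defaults to the hull's build tolerance
#'   scaled up for robustness)
#' @return logical vector
#' @export
hull_contains <- function(hull, points, tol = NULL) {
  stopifnot(inherits(hull, "hull_region"))
  tol <- tol %||% (hull$tol * 100)
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  S <- pts %*% t(hull$normals)
  apply(sweep(S, 2, hull$offsets) <= tol, 1L, all)
}
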