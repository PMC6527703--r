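# Incremental 3D convex hull.  Used as the fallback exposed surface when no
# smooth envelope mesh is supplied: the hull of the pial vertex cloud is a
# closed genus-0 surface, so its angle deficits sum to 4*pi by construction.

hull_face_planes <- function(points, faces) {
  a <- points[faces[, 1], , drop = FALSE]
  b <- points[faces[, 2], , drop = FALSE]
  c <- points[faces[, 3], , drop = FALSE]
  n <- cross3(b - a, c - a)
  list(normal = n, offset = rowSums(n * a))
}

#' Convex hull of a 3D point set as a triangulated surface
#'
#' Incremental construction: starting from an extreme tetrahedron, each
#' remaining point outside the current hull replaces its visible faces with a
#' fan to the horizon.  The result is a closed, convex, outward-oriented
#' triangulation (\code{topology_report()$is_closed} is \code{TRUE}).
#'
#' @param points numeric matrix (n x 3), n >= 4, not all coplanar.
#' @param name name for the resulting surface.
#' @return a \code{triangulated_surface} of the hull, vertices restricted to
#'   hull vertices.
#' @export
convex_hull_surface <- function(points, name = "convex_hull") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (nrow(points) < 4L) stop("convex hull needs at least 4 points")
  scale <- max(apply(points, 2, function(z) diff(range(z))))
  if (scale <= 0) stop("degenerate input: all points coincide")
  eps <- 1e-10 * scale

  # extreme initial tetrahedron
  i1 <- which.min(points[, 1]); i2 <- which.max(points[, 1])
  if (sqrt(sum((points[i1, ] - points[i2, ])^2)) < eps)
    stop("degenerate input: points collapse to a point along x")
  ab <- points[i2, ] - points[i1, ]
  rel <- sweep(points, 2, points[i1, ])
  d_line <- row_norm(cross3(rel, matrix(ab, nrow(points), 3, byrow = TRUE)))
  i3 <- which.max(d_line)
  if (d_line[i3] < eps * sqrt(sum(ab^2)))
    stop("degenerate input: points are collinear")
  nrm <- cross3(matrix(ab, 1), matrix(points[i3, ] - points[i1, ], 1))[1, ]
  d_plane <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(d_plane)
  if (d_plane[i4] < eps)
    stop("degenerate input: points are coplanar")

  faces <- rbind(c(i1, i2, i3), c(i1, i3, i4), c(i1, i4, i2), c(i2, i4, i3))
  # orient outward: every face normal must point away from the centroid
  centroid <- colMeans(points[c(i1, i2, i3, i4), , drop = FALSE])
  pl <- hull_face_planes(points, faces)
  flip <- (pl$normal %*% centroid)[, 1] - pl$offset > 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]

  remaining <- setdiff(seq_len(nrow(points)), c(i1, i2, i3, i4))
  for (p in remaining) {
    pl <- hull_face_planes(points, faces)
    nn <- row_norm(pl$normal)
    vis <- ((pl$normal %*% points[p, ])[, 1] - pl$offset) > eps * nn
    if (!any(vis)) next
    visible <- faces[vis, , drop = FALSE]
    he <- rbind(visible[, c(1, 2)], visible[, c(2, 3)], visible[, c(3, 1)])
    ukey <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
    horizon <- he[ukey %in% names(which(table(ukey) == 1L)), , drop = FALSE]
    faces <- rbind(faces[!vis, , drop = FALSE],
                   cbind(horizon, p))
  }

  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(points)); remap[used] <- seq_along(used)
  triangulated_surface(points[used, , drop = FALSE],
                       matrix(remap[faces], ncol = 3), name = name)
}
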