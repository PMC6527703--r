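# Geometric and topological primitives on triangulated surfaces.
# Discrete Gaussian curvature is concentrated at vertices as the angle
# deficit 2*pi - sum(incident corner angles); on a closed mesh the deficits
# sum to 2*pi*chi (Gauss-Bonnet), i.e. 4*pi for genus 0.

triangle_corner_vectors <- function(surface) {
  v <- surface$vertices
  t <- surface$triangles
  list(a = v[t[, 1], , drop = FALSE],
       b = v[t[, 2], , drop = FALSE],
       c = v[t[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

row_norm <- function(m) sqrt(rowSums(m * m))

#' Per-triangle areas
#'
#' @param surface a \code{triangulated_surface}.
#' @return numeric vector of triangle areas (mm^2).
#' @export
triangle_areas <- function(surface) {
  co <- triangle_corner_vectors(surface)
  0.5 * row_norm(cross3(co$b - co$a, co$c - co$a))
}

#' Total surface area
#'
#' Sum of triangle areas; for a pial surface this is the total area
#' \eqn{A_t}, for the exposed envelope the exposed area \eqn{A_e}.
#'
#' @param surface a \code{triangulated_surface}.
#' @return total area (mm^2), strictly positive.
#' @export
surface_area <- function(surface) {
  a <- sum(triangle_areas(surface))
  if (!is.finite(a) || a <= 0) stop("degenerate mesh: non-positive total area")
  a
}

# corner angles of every triangle, m x 3, angle j at vertex triangles[, j].
# atan2 of cross/dot is robust near collapsed corners.
corner_angles <- function(surface) {
  co <- triangle_corner_vectors(surface)
  ang1 <- atan2(row_norm(cross3(co$b - co$a, co$c - co$a)),
                rowSums((co$b - co$a) * (co$c - co$a)))
  ang2 <- atan2(row_norm(cross3(co$c - co$b, co$a - co$b)),
                rowSums((co$c - co$b) * (co$a - co$b)))
  ang3 <- atan2(row_norm(cross3(co$a - co$c, co$b - co$c)),
                rowSums((co$a - co$c) * (co$b - co$c)))
  cbind(ang1, ang2, ang3)
}

undirected_edges <- function(surface) {
  t <- surface$triangles
  e <- rbind(t[, c(1, 2)], t[, c(2, 3)], t[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

boundary_vertex_indices <- function(surface) {
  e <- undirected_edges(surface)
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  if (any(cnt > 2L)) {
    bad <- names(cnt)[cnt > 2L][1]
    stop("non-manifold edge (", sub(" ", "-", bad), ") with ",
         max(cnt), " incident triangles")
  }
  boundary <- e[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  sort(unique(as.vector(boundary)))
}

#' Vertex angle deficits (discrete Gaussian curvature)
#'
#' The deficit at an interior vertex is \eqn{2\pi} minus the sum of the
#' corner angles of the triangles incident on it.  On an almost-closed mesh
#' (e.g. a hemisphere cut by the corpus callosum), vertices lying on a
#' boundary edge are assigned deficit 0 and reported through the
#' \code{boundary_vertices} attribute, so that partition sums exclude them.
#'
#' @param surface a \code{triangulated_surface}; every vertex must have at
#'   least one incident triangle.
#' @return a \code{vertex_field} of deficits (steradians) with attributes
#'   \code{boundary_vertices} (indices) and \code{n_boundary}.
#' @export
vertex_angle_deficits <- function(surface) {
  nv <- nrow(surface$vertices)
  t <- surface$triangles
  used <- tabulate(as.vector(t), nbins = nv)
  if (any(used == 0L))
    stop("vertex with no incident triangle: ",
         paste(utils::head(which(used == 0L), 5L), collapse = ", "))
  ang <- corner_angles(surface)
  angle_sum <- rep(0, nv)
  for (j in 1:3) {
    acc <- rowsum(ang[, j], group = t[, j], reorder = FALSE)
    angle_sum[as.integer(rownames(acc))] <-
      angle_sum[as.integer(rownames(acc))] + acc[, 1]
  }
  deficits <- 2 * pi - angle_sum
  bnd <- boundary_vertex_indices(surface)
  deficits[bnd] <- 0
  out <- vertex_field(deficits, surface)
  attr(out, "boundary_vertices") <- bnd
  attr(out, "n_boundary") <- length(bnd)
  out
}

#' Integrated Gaussian curvature
#'
#' Sum of vertex angle deficits over a vertex subset (default: all).  For a
#' closed genus-0 mesh the total is the topological invariant \eqn{4\pi};
#' for a torus it is 0.
#'
#' @param surface a \code{triangulated_surface}.
#' @param vertex_subset optional integer vector of 1-based vertex indices.
#' @param deficits optional precomputed result of
#'   \code{vertex_angle_deficits} (avoids recomputation in loops).
#' @return integrated curvature \eqn{I_G} (steradians).
#' @export
integrated_curvature <- function(surface, vertex_subset = NULL,
                                 deficits = NULL) {
  if (is.null(deficits)) deficits <- vertex_angle_deficits(surface)
  if (is.null(vertex_subset)) sum(deficits) else sum(deficits[vertex_subset])
}

#' Barycentric vertex areas
#'
#' One third of the summed areas of the triangles incident on each vertex.
#' These weights partition the surface exactly, so they are used for
#' area-weighted mean thickness per region.
#'
#' @param surface a \code{triangulated_surface}.
#' @return a \code{vertex_field} of areas (mm^2) summing to
#'   \code{surface_area(surface)}.
#' @export
vertex_areas <- function(surface) {
  nv <- nrow(surface$vertices)
  t <- surface$triangles
  third <- triangle_areas(surface) / 3
  va <- rep(0, nv)
  for (j in 1:3) {
    acc <- rowsum(third, group = t[, j], reorder = FALSE)
    va[as.integer(rownames(acc))] <- va[as.integer(rownames(acc))] + acc[, 1]
  }
  vertex_field(va, surface)
}

#' Topological diagnostics of a mesh
#'
#' Euler characteristic \eqn{\chi = V - E + F}, boundary-edge count,
#' closedness, and the total angle deficit so callers can quantify the
#' deviation from \eqn{4\pi} on almost-closed hemispheres.
#'
#' @param surface a \code{triangulated_surface}.
#' @return a list of class \code{topology_report} with fields
#'   \code{euler_characteristic}, \code{boundary_edge_count},
#'   \code{is_closed}, \code{total_angle_deficit}.
#' @export
topology_report <- function(surface) {
  e <- undirected_edges(surface)
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  if (any(cnt > 2L)) {
    bad <- names(cnt)[cnt > 2L][1]
    stop("non-manifold edge (", sub(" ", "-", bad), ") with ",
         max(cnt), " incident triangles")
  }
  n_edges <- length(cnt)
  n_boundary <- sum(cnt == 1L)
  chi <- nrow(surface$vertices) - n_edges + nrow(surface$triangles)
  structure(
    list(euler_characteristic = as.integer(chi),
         boundary_edge_count = as.integer(n_boundary),
         is_closed = n_boundary == 0L,
         total_angle_deficit = integrated_curvature(surface)),
    class = "topology_report"
  )
}

#' @export
print.topology_report <- function(x, ...) {
  cat("topology_report: chi =", x$euler_characteristic,
      "| boundary edges =", x$boundary_edge_count,
      "| closed =", x$is_closed,
      "| total deficit =", format(x$total_angle_deficit), "sr",
      sprintf("(%.4f x 4pi)\n", x$total_angle_deficit / (4 * pi)))
  invisible(x)
}
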