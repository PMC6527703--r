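#' Construct a triangulated surface
#'
#' A triangulated surface is the computational representation of one cortical
#' sheet: either the folded (pial) surface whose area is the total area
#' \eqn{A_t}, or the smooth exposed envelope whose area is \eqn{A_e}.
#' Coordinates are in millimetres.
#'
#' Validation enforces that every triangle refers to an existing vertex and
#' that no triangle is degenerate (area below \code{area_tol}).  Winding
#' consistency (orientability) is checked by requiring that no directed edge
#' is used twice; an inconsistent mesh is accepted but flagged via the
#' \code{oriented} attribute and a warning.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param triangles integer matrix, one row per triangle, three 1-based
#'   vertex indices per row.
#' @param name free-text identifier carried through outputs.
#' @param area_tol triangles with area below this (mm^2) abort validation.
#' @return an object of class \code{triangulated_surface} with fields
#'   \code{vertices}, \code{triangles}, \code{name} and attribute
#'   \code{oriented}.
#' @export
triangulated_surface <- function(vertices, triangles, name = "surface",
                                 area_tol = 1e-12) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (nrow(vertices) < 3L) stop("a surface needs at least 3 vertices")
  if (nrow(triangles) < 1L) stop("a surface needs at least 1 triangle")
  if (anyNA(vertices) || anyNA(triangles)) stop("NA in vertices or triangles")
  if (min(triangles) < 1L || max(triangles) > nrow(vertices))
    stop("triangle index out of range: vertices are 1..", nrow(vertices))

  s <- structure(
    list(vertices = vertices, triangles = triangles, name = as.character(name)[1]),
    class = "triangulated_surface"
  )
  areas <- triangle_areas(s)
  if (any(areas < area_tol))
    stop("degenerate triangle(s) with area < ", area_tol, " mm^2 at row(s) ",
         paste(utils::head(which(areas < area_tol), 5L), collapse = ", "))

  # consistent winding <=> each directed edge appears at most once
  he <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  oriented <- !anyDuplicated(he)
  if (!oriented)
    warning("inconsistent triangle winding; surface flagged as unoriented")
  attr(s, "oriented") <- oriented
  s
}

#' @export
print.triangulated_surface <- function(x, ...) {
  cat("triangulated_surface '", x$name, "': ",
      nrow(x$vertices), " vertices, ", nrow(x$triangles), " triangles\n",
      sep = "")
  invisible(x)
}

#' Construct a per-vertex scalar field
#'
#' Holds one scalar per mesh vertex: cortical thickness (mm), vertex angle
#' deficits (steradians) or barycentric vertex areas (mm^2), depending on
#' role.
#'
#' @param values numeric vector, one value per vertex.
#' @param surface optional \code{triangulated_surface}; when given, length is
#'   checked against its vertex count.
#' @param role one of "generic", "thickness"; thickness must be non-negative.
#' @return numeric vector of class \code{vertex_field}.
#' @export
vertex_field <- function(values, surface = NULL, role = c("generic", "thickness")) {
  role <- match.arg(role)
  values <- as.double(values)
  if (anyNA(values)) stop("NA in vertex field")
  if (!is.null(surface) && length(values) != nrow(surface$vertices))
    stop("field length ", length(values), " != vertex count ",
         nrow(surface$vertices))
  if (role == "thickness" && any(values < 0))
    stop("thickness values must be non-negative")
  structure(values, class = "vertex_field", role = role)
}

#' Construct a per-vertex integer label field
#'
#' @param labels integer vector, one non-negative label id per vertex.
#' @param label_table optional data.frame with columns \code{label_id},
#'   \code{region} naming each id.
#' @param surface optional surface for length checking.
#' @return integer vector of class \code{label_field} with attribute
#'   \code{label_table}.
#' @export
label_field <- function(labels, label_table = NULL, surface = NULL) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("NA label")
  if (any(labels < 0L)) stop("label ids must be non-negative")
  if (!is.null(surface) && length(labels) != nrow(surface$vertices))
    stop("label length != vertex count")
  if (!is.null(label_table)) {
    stopifnot(all(c("label_id", "region") %in% names(label_table)))
    missing_ids <- setdiff(unique(labels), label_table$label_id)
    if (length(missing_ids))
      stop("labels absent from label_table: ",
           paste(missing_ids, collapse = ", "))
  }
  structure(labels, class = "label_field", label_table = label_table)
}

region_names <- function(labels) {
  tab <- attr(labels, "label_table")
  ids <- sort(unique(as.integer(labels)))
  if (is.null(tab)) {
    stats::setNames(as.character(ids), ids)
  } else {
    stats::setNames(tab$region[match(ids, tab$label_id)], ids)
  }
}
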