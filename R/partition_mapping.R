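# Mapping parcellation labels between the folded (pial) surface and the
# smooth exposed envelope, and aggregating raw per-partition morphology.
# The exposed surface carries the partition of the integrated curvature:
# each exposed vertex inherits the label of its nearest pial vertex, and
# I_G per partition is the sum of exposed-vertex angle deficits.

bounding_boxes_disjoint <- function(a, b) {
  ra <- apply(a$vertices, 2, range)
  rb <- apply(b$vertices, 2, range)
  any(ra[2, ] < rb[1, ] | rb[2, ] < ra[1, ])
}

#' Transfer vertex labels from the pial surface to the exposed surface
#'
#' Each exposed vertex receives the label of its Euclidean-nearest pial
#' vertex.  Ties at exactly equal distance resolve to the lowest label id.
#' The search is an exact chunked exhaustive scan, so the result is
#' deterministic and identical to any spatial-index implementation.
#'
#' @param pial folded \code{triangulated_surface}.
#' @param pial_labels \code{label_field} over the pial vertices.
#' @param exposed exposed \code{triangulated_surface} in the same
#'   coordinate frame (mm); disjoint bounding boxes abort, since they
#'   indicate mismatched files.
#' @param chunk_size exposed vertices processed per distance block.
#' @return a \code{label_field} over the exposed vertices (label table
#'   carried over).
#' @export
transfer_labels <- function(pial, pial_labels, exposed, chunk_size = 512L) {
  stopifnot(inherits(pial, "triangulated_surface"),
            inherits(exposed, "triangulated_surface"))
  if (length(pial_labels) != nrow(pial$vertices))
    stop("pial_labels must cover every pial vertex")
  if (bounding_boxes_disjoint(pial, exposed))
    stop("pial and exposed bounding boxes are disjoint; ",
         "meshes appear to be in different coordinate frames")
  pv <- pial$vertices
  ev <- exposed$vertices
  lab <- as.integer(pial_labels)
  p_sq <- rowSums(pv * pv)
  out <- integer(nrow(ev))
  for (start in seq(1L, nrow(ev), by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, nrow(ev))
    ch <- ev[idx, , drop = FALSE]
    # squared distances: |p|^2 - 2 p.e + |e|^2; |e|^2 constant per row
    d2 <- outer(rep(1, length(idx)), p_sq) - 2 * ch %*% t(pv)
    dmin <- d2[cbind(seq_along(idx), max.col(-d2, ties.method = "first"))]
    for (r in seq_along(idx)) {
      cand <- which(d2[r, ] <= dmin[r])
      out[idx[r]] <- min(lab[cand])
    }
  }
  label_field(out, label_table = attr(pial_labels, "label_table"),
              surface = exposed)
}

#' Per-triangle labels by majority vote
#'
#' Areas are summed per face while labels live on vertices: each triangle
#' takes the majority label of its three vertices; a three-way tie resolves
#' to the lowest label id.
#'
#' @param surface a \code{triangulated_surface}.
#' @param labels a \code{label_field} over its vertices.
#' @return integer vector, one label per triangle.
#' @export
face_labels <- function(surface, labels) {
  if (length(labels) != nrow(surface$vertices))
    stop("labels must cover every vertex")
  lv <- matrix(as.integer(labels)[surface$triangles], ncol = 3)
  srt <- t(apply(lv, 1, sort))
  ifelse(srt[, 1] == srt[, 2] | srt[, 2] == srt[, 3], srt[, 2], srt[, 1])
}

#' Aggregate raw per-partition morphology
#'
#' For each label: total (pial) area from pial faces, exposed area from
#' exposed faces, vertex-area-weighted mean thickness over pial vertices,
#' and integrated Gaussian curvature as the sum of angle deficits over
#' exposed vertices.  The per-partition quantities conserve the whole-mesh
#' totals: areas sum to the respective surface areas and I_G sums to the
#' exposed surface's total deficit.
#'
#' @param pial folded surface; \code{thickness} and \code{pial_labels} live
#'   on its vertices.
#' @param thickness \code{vertex_field} of cortical thickness (mm).
#' @param pial_labels \code{label_field} on the pial vertices.
#' @param exposed exposed surface.
#' @param exposed_labels \code{label_field} on the exposed vertices,
#'   normally from \code{\link{transfer_labels}}.
#' @param weighted_thickness use vertex-area weights for mean thickness
#'   (default); \code{FALSE} gives the unweighted vertex mean.
#' @param renormalize_curvature rescale all \code{I_G} by
#'   \code{4*pi / sum(I_G)} so partition curvatures sum exactly to
#'   \eqn{4\pi}.  Off by default: for a closed exposed surface the sum is
#'   already \eqn{4\pi}, and for an almost-closed hemisphere the raw
#'   deficits keep the correction literal.  The deviation of the raw sum
#'   from \eqn{4\pi} is reported in the \code{total_deficit} attribute
#'   either way.
#' @return data.frame with columns \code{partition} (region name),
#'   \code{label_id}, \code{A_t}, \code{A_e}, \code{T}, \code{I_G},
#'   \code{n_vertices_exposed}.  Labels with no pial faces are omitted with
#'   a warning.
#' @export
aggregate_partitions <- function(pial, thickness, pial_labels, exposed,
                                 exposed_labels, weighted_thickness = TRUE,
                                 renormalize_curvature = FALSE) {
  stopifnot(length(thickness) == nrow(pial$vertices),
            length(pial_labels) == nrow(pial$vertices),
            length(exposed_labels) == nrow(exposed$vertices))
  pf_lab <- face_labels(pial, pial_labels)
  ef_lab <- face_labels(exposed, exposed_labels)
  pf_area <- triangle_areas(pial)
  ef_area <- triangle_areas(exposed)
  deficits <- vertex_angle_deficits(exposed)
  va <- if (weighted_thickness) as.double(vertex_areas(pial))
        else rep(1, nrow(pial$vertices))

  ids <- sort(unique(c(as.integer(pial_labels), as.integer(exposed_labels))))
  nm <- region_names(pial_labels)
  rows <- lapply(ids, function(id) {
    A_t <- sum(pf_area[pf_lab == id])
    if (A_t == 0) return(NULL)
    vsel <- as.integer(pial_labels) == id
    esel <- as.integer(exposed_labels) == id
    data.frame(
      partition = if (as.character(id) %in% names(nm)) nm[[as.character(id)]]
                  else as.character(id),
      label_id = id,
      A_t = A_t,
      A_e = sum(ef_area[ef_lab == id]),
      T = sum(thickness[vsel] * va[vsel]) / sum(va[vsel]),
      I_G = sum(deficits[esel]),
      n_vertices_exposed = sum(esel),
      stringsAsFactors = FALSE)
  })
  dropped <- ids[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("label(s) with zero pial face area omitted: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  total_deficit <- sum(deficits)
  if (renormalize_curvature) out$I_G <- out$I_G * (4 * pi / total_deficit)
  attr(out, "total_deficit") <- total_deficit
  out
}

#' Read a region-to-lobe mapping
#'
#' Two-column CSV (\code{region}, \code{lobe}), \code{#} comments allowed.
#' Lobes must come from frontal / parietal / temporal / occipital /
#' excluded.  The packaged default (\code{system.file("extdata",
#' "dk_lobe_map.csv", package = "foldscale")}) maps the Desikan-Killiany
#' regions to the four lobes following the FreeSurfer lobe assignment, with
#' the cingulate divided between the frontal and parietal lobes and the
#' insula, medial wall and corpus callosum excluded.
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{region}, \code{lobe}.
#' @export
read_lobe_map <- function(path) {
  lm_df <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           strip.white = TRUE)
  stopifnot(all(c("region", "lobe") %in% names(lm_df)))
  allowed <- c(lobe_names, "excluded")
  bad <- setdiff(unique(lm_df$lobe), allowed)
  if (length(bad))
    stop("unknown lobe name(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  if (anyDuplicated(lm_df$region))
    stop("duplicate region(s) in lobe map")
  lm_df[, c("region", "lobe")]
}

#' Group region partitions into lobes
#'
#' Component-wise sums of \code{A_t}, \code{A_e}, \code{I_G} and exposed
#' vertex counts over the member regions of each lobe; thickness is
#' recomputed as the \code{A_t}-weighted mean of member thicknesses.
#' Regions mapped to \code{excluded} are dropped; their summed quantities
#' are reported in the \code{excluded_totals} attribute so conservation can
#' be checked over retained + excluded.
#'
#' @param partitions data.frame from \code{\link{aggregate_partitions}}.
#' @param lobe_map data.frame (\code{region}, \code{lobe}) as returned by
#'   \code{\link{read_lobe_map}}.
#' @return data.frame with one row per lobe (frontal, parietal, temporal,
#'   occipital) and the same morphology columns.
#' @export
group_to_lobes <- function(partitions, lobe_map) {
  stopifnot(is.data.frame(partitions), is.data.frame(lobe_map))
  unmapped <- setdiff(partitions$partition, lobe_map$region)
  if (length(unmapped))
    stop("partition(s) not in lobe map: ", paste(unmapped, collapse = ", "))
  lobe <- lobe_map$lobe[match(partitions$partition, lobe_map$region)]
  keep <- lobe != "excluded"
  excl <- partitions[!keep, , drop = FALSE]
  excluded_totals <- c(A_t = sum(excl$A_t), A_e = sum(excl$A_e),
                       I_G = sum(excl$I_G))
  retained <- partitions[keep, , drop = FALSE]
  lobe <- lobe[keep]
  target <- intersect(lobe_names, unique(lobe_map$lobe))
  empty <- setdiff(target, unique(lobe))
  if (length(empty))
    stop("lobe(s) with no member regions: ", paste(empty, collapse = ", "))
  rows <- lapply(intersect(lobe_names, unique(lobe)), function(L) {
    m <- retained[lobe == L, , drop = FALSE]
    data.frame(partition = L,
               A_t = sum(m$A_t), A_e = sum(m$A_e),
               T = sum(m$T * m$A_t) / sum(m$A_t),
               I_G = sum(m$I_G),
               n_vertices_exposed = sum(m$n_vertices_exposed),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded_totals") <- excluded_totals
  out
}
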