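#' Skeletal segments and skeleton models
#'
#' A segment is a named functional unit of a skeleton (trunk, thigh, neck
#' part 1, ...) holding the point cloud to be hulled. A skeleton model is a
#' set of segments belonging to one specimen; its total convex-hull volume
#' is the sum of the per-segment hull volumes.
#'
#' @param name functional-unit label, e.g. `"trunk"`.
#' @param cloud a [pointcloud].
#' @param part_index integer part number (>= 1) for units that were
#'   subdivided to keep the hull tight (long necks, tails).
#' @return `segment()` returns an object of class `segment`;
#'   `skeleton_model()` an object of class `skeleton_model`.
#' @export
segment <- function(name, cloud, part_index = 1L) {
  stopifnot(inherits(cloud, "pointcloud"))
  part_index <- as.integer(part_index)
  if (is.na(part_index) || part_index < 1L) stop("part_index must be >= 1")
  structure(list(name = as.character(name)[1], cloud = cloud,
                 part_index = part_index), class = "segment")
}

#' @rdname segment
#' @param segments list of `segment` objects with unique (name, part_index).
#' @param specimen optional specimen label or a row of a calibration table.
#' @export
skeleton_model <- function(segments, specimen = NULL) {
  if (inherits(segments, "segment")) segments <- list(segments)
  if (!length(segments) || !all(vapply(segments, inherits, TRUE, "segment")))
    stop("`segments` must be a non-empty list of segment objects")
  key <- vapply(segments, function(s) paste(s$name, s$part_index), "")
  if (anyDuplicated(key))
    stop("duplicate segment (name, part_index): ", key[duplicated(key)][1])
  structure(list(segments = segments, specimen = specimen),
            class = "skeleton_model")
}

#' Convex hull of a 3D point cloud
#'
#' Computes the minimum convex polytope enclosing the cloud with an
#' incremental Quickhull and returns its volume by the divergence theorem:
#' signed tetrahedra are summed over the outward-oriented triangular facets
#' against the centroid of the hull vertices. The volume is therefore exact
#' for polytopes, invariant under rigid motion, and scales with the cube of
#' any linear rescaling.
#'
#' Input clouds must span three dimensions. Rank is assessed from the
#' singular values of the centred cloud; any singular value below `1e-9`
#' of the largest marks the cloud as degenerate (collinear or coplanar).
#'
#' @param cloud a [pointcloud] with at least 4 points of full affine rank.
#' @return An object of class `hull_result`: list with `volume` (m^3),
#'   `area` (m^2), `hull_vertex_count`, `hull_facet_count`, `vertices`
#'   (indices into the cloud), `faces` (triangle index matrix, outward
#'   orientation) and `segment_name`.
#' @examples
#' cube <- pointcloud(as.matrix(expand.grid(0:1, 0:1, 0:1)))
#' compute_hull(cube)$volume  # 1
#' @export
compute_hull <- function(cloud) {
  stopifnot(inherits(cloud, "pointcloud"))
  p <- cloud$points
  if (nrow(p) < 4L)
    stop(sprintf("degenerate cloud '%s': %d point(s), need >= 4 (rank %d)",
                 cloud$label, nrow(p), .cloud_rank(p)))
  rk <- .cloud_rank(p)
  if (rk < 3L)
    stop(sprintf("degenerate cloud '%s': affine rank %d (points are %s)",
                 cloud$label, rk, c("identical", "collinear", "coplanar")[rk + 1]))
  res <- .qhull3d(p)
  if (!is.null(res$error))
    stop(sprintf("degenerate cloud '%s': affine rank %d", cloud$label, res$rank))
  structure(list(segment_name = cloud$label,
                 volume = res$volume,
                 area = res$area,
                 hull_vertex_count = length(res$vertices),
                 hull_facet_count = nrow(res$faces),
                 vertices = res$vertices,
                 faces = res$faces),
            class = "hull_result")
}

.cloud_rank <- function(p) {
  ctr <- sweep(p, 2, colMeans(p))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  sum(sv > 1e-9 * max(sv, .Machine$double.xmin))
}

#' @export
print.hull_result <- function(x, ...) {
  cat(sprintf("<hull> %s: volume %.6g m^3, %d vertices, %d facets\n",
              x$segment_name, x$volume, x$hull_vertex_count,
              x$hull_facet_count))
  invisible(x)
}

#' Total convex-hull volume of a skeleton
#'
#' The total `vol_CH` of a skeleton is the sum of the convex-hull volumes of
#' its segments, mirroring the segment-wise hulling workflow used on scanned
#' museum mounts.
#'
#' @param skeleton a [skeleton_model()].
#' @return List with `total` (m^3) and `breakdown`, a data.frame of
#'   per-segment volumes (`segment`, `part`, `volume`) summing exactly to
#'   `total`.
#' @export
total_volume <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_model"))
  rows <- lapply(skeleton$segments, function(s) {
    h <- tryCatch(compute_hull(s$cloud), error = function(e)
      stop(sprintf("segment '%s' (part %d): %s", s$name, s$part_index,
                   conditionMessage(e)), call. = FALSE))
    data.frame(segment = s$name, part = s$part_index, volume = h$volume)
  })
  breakdown <- do.call(rbind, rows)
  list(total = sum(breakdown$volume), breakdown = breakdown)
}

#' Subdivide a segment along an axis
#'
#' Curved functional units (long necks, tails) are cut into parts before
#' hulling so that each part's hull fits tightly; the parts partition the
#' points into equal-count quantile slabs along the chosen axis. For a
#' convex (straight) unit, the part volumes sum back to the unsplit hull
#' volume up to discretisation error; for a curved unit the sum is strictly
#' smaller, which is the entire point of subdividing.
#'
#' @param seg a [segment()].
#' @param n_parts number of parts (>= 1); `1` returns the segment unchanged.
#' @param axis `"principal"` (first principal component of the cloud, the
#'   default) or a coordinate axis `"x"`, `"y"`, `"z"`.
#' @return List of `segment` objects with `part_index` 1..n_parts.
#' @export
subdivide_segment <- function(seg, n_parts, axis = c("principal", "x", "y", "z")) {
  stopifnot(inherits(seg, "segment"))
  axis <- match.arg(axis)
  n_parts <- as.integer(n_parts)
  if (is.na(n_parts) || n_parts < 1L) stop("n_parts must be >= 1")
  if (n_parts == 1L) return(list(seg))
  p <- seg$cloud$points
  proj <- switch(axis,
    principal = {
      ctr <- sweep(p, 2, colMeans(p))
      drop(ctr %*% svd(ctr, nu = 0, nv = 1)$v)
    },
    x = p[, 1], y = p[, 2], z = p[, 3])
  # equal-count slabs: rank-based cut is robust to non-uniform scan density
  cut_id <- ceiling(rank(proj, ties.method = "first") * n_parts / length(proj))
  out <- vector("list", n_parts)
  for (k in seq_len(n_parts)) {
    pk <- p[cut_id == k, , drop = FALSE]
    if (nrow(pk) < 4L || .cloud_rank(pk) < 3L)
      stop(sprintf(
        "subdividing '%s' into %d parts leaves part %d degenerate; use fewer parts",
        seg$name, n_parts, k))
    out[[k]] <- segment(seg$name,
                        pointcloud(pk, label = sprintf("%s_part_%d", seg$name, k)),
                        part_index = k)
  }
  out
}

#' Randomly subsample a point cloud
#'
#' Draws `n` points uniformly without replacement, emulating the
#' down-sampling applied to LiDAR trunk clouds so that all specimens have
#' comparable point counts. Reproducible for a fixed seed; the global RNG
#' state is left untouched.
#'
#' @param cloud a [pointcloud].
#' @param n number of points to keep (1 <= n <= point count).
#' @param seed integer RNG seed.
#' @return A [pointcloud] of `n` points.
#' @export
subsample_pointcloud <- function(cloud, n, seed) {
  stopifnot(inherits(cloud, "pointcloud"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > npoints(cloud))
    stop("n must be between 1 and the point count (", npoints(cloud), ")")
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(npoints(cloud), n, replace = FALSE))
  pointcloud(cloud$points[idx, , drop = FALSE], label = cloud$label)
}

#' Export a hull as a triangulated OBJ mesh
#'
#' Writes the hull's vertices and outward-oriented triangular facets as a
#' Wavefront OBJ, re-indexed to the hull vertices.
#'
#' @param hull a `hull_result` from [compute_hull()].
#' @param cloud the [pointcloud] the hull was computed from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hull_obj <- function(hull, cloud, path) {
  stopifnot(inherits(hull, "hull_result"), inherits(cloud, "pointcloud"))
  vid <- hull$vertices
  remap <- integer(npoints(cloud))
  remap[vid] <- seq_along(vid)
  p <- cloud$points[vid, , drop = FALSE]
  f <- matrix(remap[hull$faces], ncol = 3)
  writeLines(c(sprintf("v %.17g %.17g %.17g", p[, 1], p[, 2], p[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  invisible(path)
}
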