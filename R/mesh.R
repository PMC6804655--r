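#' Triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix, mm coordinates.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param vertex_radius optional numeric vector, one positive radius (mm)
#'   per vertex (distance to the vessel centerline).
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, vertex_radius = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("surface_mesh: face indices out of range")
  if (!is.null(vertex_radius)) {
    if (length(vertex_radius) != nrow(vertices))
      stop("surface_mesh: vertex_radius must have one value per vertex")
    if (nrow(vertices) && any(vertex_radius <= 0))
      stop("surface_mesh: vertex_radius values must be positive")
  }
  structure(list(vertices = vertices, faces = faces,
                 vertex_radius = vertex_radius),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces", if (!is.null(x$vertex_radius)) ", with vertex radii", "\n",
      sep = "")
  invisible(x)
}

#' Empty mesh
#' @export
empty_mesh <- function() surface_mesh(matrix(numeric(0), 0, 3),
                                      matrix(integer(0), 0, 3))

is_empty_mesh <- function(m) nrow(m$faces) == 0

#' Total surface area of a mesh (mm^2)
#' @param mesh a `surface_mesh`.
#' @export
mesh_area <- function(mesh) {
  if (is_empty_mesh(mesh)) return(0)
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# per-face unit normals (orientation as stored)
face_normals <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Connected-component labels of mesh vertices
#' @param mesh a `surface_mesh`.
#' @return integer vector, component id per vertex (isolated vertices get
#'   their own components).
#' @export
mesh_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  if (nv == 0) return(integer(0))
  if (nrow(mesh$faces) == 0) return(seq_len(nv))
  edges <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nv - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(nv)]
}

# keep the given vertices; drop faces touching removed vertices; reindex
subset_mesh_vertices <- function(mesh, keep) {
  keep <- which(keep)
  map <- integer(nrow(mesh$vertices))
  map[keep] <- seq_along(keep)
  f <- mesh$faces
  ok <- map[f[, 1]] > 0 & map[f[, 2]] > 0 & map[f[, 3]] > 0
  f <- cbind(map[f[ok, 1]], map[f[ok, 2]], map[f[ok, 3]])
  surface_mesh(mesh$vertices[keep, , drop = FALSE], f,
               if (!is.null(mesh$vertex_radius)) mesh$vertex_radius[keep])
}

#' Remove small unconnected mesh components
#'
#' Deletes every connected component with fewer than `min_vertices`
#' vertices; surviving geometry is unchanged. This is the cleanup step that
#' discards speckle left by thresholding a noisy vesselness image.
#'
#' @param mesh a `surface_mesh`.
#' @param min_vertices minimum component size to keep (0 = identity).
#' @export
remove_small_components <- function(mesh, min_vertices = 30) {
  stopifnot(min_vertices >= 0)
  if (min_vertices == 0 || nrow(mesh$vertices) == 0) return(mesh)
  comp <- mesh_components(mesh)
  sizes <- tabulate(comp)
  subset_mesh_vertices(mesh, sizes[comp] >= min_vertices)
}

#' Prune a radius-annotated mesh by vessel diameter
#'
#' Removes every vertex whose local diameter (`2 * vertex_radius`) is
#' strictly below the threshold, along with incident faces. Threshold 0 is
#' the identity. The strict-below convention means a vessel of diameter
#' exactly equal to the threshold survives.
#'
#' @param mesh a `surface_mesh` with `vertex_radius` populated.
#' @param threshold_mm diameter cutoff, mm.
#' @export
prune_by_diameter <- function(mesh, threshold_mm) {
  if (threshold_mm == 0) return(mesh)
  if (is.null(mesh$vertex_radius))
    stop("prune_by_diameter: mesh has no vertex_radius")
  subset_mesh_vertices(mesh, 2 * mesh$vertex_radius >= threshold_mm)
}

#' Extract a vessel isosurface from a vesselness (or any scalar) volume
#'
#' Marching-tetrahedra isosurface at a user-chosen intensity threshold, with
#' vertex coordinates in mm (grid origin and voxel size applied). The
#' interactive threshold of clinical practice becomes a scalar here;
#' [otsu_threshold()] supplies an unattended default.
#'
#' @param vesselness a `seeg_volume`.
#' @param threshold iso value; must lie within the image intensity range.
#' @return a `surface_mesh` (empty, with a warning, if nothing crosses the
#'   threshold).
#' @export
extract_vessel_surface <- function(vesselness, threshold) {
  rng <- range(vesselness$data)
  if (threshold < rng[1] || threshold > rng[2])
    stop(sprintf("threshold %g outside image intensity range [%g, %g]",
                 threshold, rng[1], rng[2]))
  # pad with sub-threshold background so structures touching the volume
  # boundary yield closed (capped) surfaces
  d <- dim(vesselness$data)
  padded <- array(min(rng[1], threshold) - 1, d + 2)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vesselness$data
  res <- cpp_marching_tetra(as.numeric(padded), d + 2L,
                            threshold, vesselness$voxdim,
                            vesselness$origin - vesselness$voxdim)
  if (nrow(res$faces) == 0) {
    warning("extract_vessel_surface: empty isosurface")
    return(empty_mesh())
  }
  surface_mesh(res$vertices, res$faces)
}

#' Otsu threshold of the positive values of a volume
#'
#' Default unattended stand-in for an interactively chosen vesselness
#' threshold: Otsu's criterion on a 256-bin histogram of the nonzero voxels.
#'
#' @param vol a `seeg_volume`.
#' @param nbins histogram bins.
#' @export
otsu_threshold <- function(vol, nbins = 256) {
  x <- vol$data[vol$data > 0]
  if (!length(x)) stop("otsu_threshold: no positive voxels")
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- -Inf; thr <- mids[1]
  csum <- cumsum(w); cmean <- cumsum(w * mids); mu <- cmean[length(cmean)]
  for (t in seq_len(nbins - 1)) {
    w0 <- csum[t]; w1 <- 1 - w0
    if (w0 < 1e-12 || w1 < 1e-12) next
    m0 <- cmean[t] / w0; m1 <- (mu - cmean[t]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; thr <- (mids[t] + mids[t + 1]) / 2 }
  }
  thr
}

#' Minimum distance from points to a mesh surface
#'
#' Exact Euclidean distance from each query point to the nearest point on
#' any triangle of the mesh. Empty meshes give `Inf`.
#'
#' @param pts n x 3 matrix of mm points.
#' @param mesh a `surface_mesh` or list of meshes (minimum over all).
#' @param method `"grid"` (uniform-grid accelerated, default) or `"brute"`
#'   (exhaustive scan over triangles; the independent reference used in
#'   tests).
#' @export
point_mesh_distance <- function(pts, mesh, method = c("grid", "brute")) {
  method <- match.arg(method)
  pts <- rbind(pts)
  meshes <- if (inherits(mesh, "surface_mesh")) list(mesh) else mesh
  out <- rep(Inf, nrow(pts))
  for (m in meshes) {
    if (is_empty_mesh(m)) next
    d <- if (method == "grid")
      cpp_point_mesh_dist_grid(pts, m$vertices, m$faces)
    else cpp_point_mesh_dist(pts, m$vertices, m$faces)
    out <- pmin(out, as.numeric(d))
  }
  out
}

#' Does an electrode cylinder around each segment touch a mesh?
#'
#' `TRUE` where the minimum distance from the segment to any triangle is at
#' most `radius` (grid-accelerated with early exit).
#'
#' @param p0,p1 segment endpoints (mm), vectors or n x 3 matrices.
#' @param mesh a `surface_mesh` or list of meshes.
#' @param radius cylinder radius, mm.
#' @export
segment_mesh_collides <- function(p0, p1, mesh, radius) {
  p0 <- rbind(p0); p1 <- rbind(p1)
  meshes <- if (inherits(mesh, "surface_mesh")) list(mesh) else mesh
  out <- rep(FALSE, nrow(p0))
  for (m in meshes) {
    if (is_empty_mesh(m)) next
    todo <- which(!out)
    if (!length(todo)) break
    out[todo] <- as.logical(cpp_segment_mesh_within(
      p0[todo, , drop = FALSE], p1[todo, , drop = FALSE],
      m$vertices, m$faces, radius))
  }
  out
}

#' Minimum distance from a line segment to a mesh surface
#'
#' @param p0,p1 segment endpoints (mm), vectors or n x 3 matrices.
#' @param mesh a `surface_mesh` or list of meshes.
#' @param early_stop optional distance at which the per-segment search may
#'   stop early (used for collision tests); `NULL` for exact minima.
#' @export
segment_mesh_distance <- function(p0, p1, mesh, early_stop = NULL) {
  p0 <- rbind(p0); p1 <- rbind(p1)
  meshes <- if (inherits(mesh, "surface_mesh")) list(mesh) else mesh
  out <- rep(Inf, nrow(p0))
  for (m in meshes) {
    if (is_empty_mesh(m)) next
    out <- pmin(out, as.numeric(cpp_segment_mesh_dist(
      p0, p1, m$vertices, m$faces,
      if (is.null(early_stop)) -1 else early_stop)))
  }
  out
}
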