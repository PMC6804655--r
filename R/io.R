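#' Read and write volumes as NIfTI-1
#'
#' Voxel size round-trips through pixdim; the origin is carried in the
#' sform/qform translation.
#'
#' @param vol a `seeg_volume`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data, pixdim = vol$voxdim)
  M <- diag(4)
  diag(M)[1:3] <- vol$voxdim
  M[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(M, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("read_volume: malformed NIfTI at ",
                                           path, ": ", conditionMessage(e)))
  M <- RNifti::xform(img)
  voxdim <- sqrt(colSums(M[1:3, 1:3]^2))
  new_volume(array(as.numeric(img), dim(img)), voxdim, M[1:3, 4])
}

#' Write a mesh as ASCII STL or PLY
#'
#' PLY carries `vertex_radius` as a per-vertex `radius` property; STL cannot
#' hold attributes, so radii go to a JSON sidecar (`<path>.radius.json`).
#'
#' @param mesh a `surface_mesh`.
#' @param path file path ending in `.stl` or `.ply`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    if (nrow(mesh$faces)) {
      n <- face_normals(mesh)
      for (f in seq_len(nrow(mesh$faces))) {
        writeLines(sprintf("facet normal %.9g %.9g %.9g",
                           n[f, 1], n[f, 2], n[f, 3]), con)
        writeLines("  outer loop", con)
        for (v in mesh$faces[f, ])
          writeLines(sprintf("    vertex %.9g %.9g %.9g",
                             mesh$vertices[v, 1], mesh$vertices[v, 2],
                             mesh$vertices[v, 3]), con)
        writeLines("  endloop", con)
        writeLines("endfacet", con)
      }
    }
    writeLines("endsolid mesh", con)
    if (!is.null(mesh$vertex_radius))
      jsonlite::write_json(list(vertex_radius = mesh$vertex_radius),
                           paste0(path, ".radius.json"), digits = NA)
  } else if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    has_r <- !is.null(mesh$vertex_radius)
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(mesh$vertices)),
                 "property double x", "property double y", "property double z",
                 if (has_r) "property double radius",
                 paste("element face", nrow(mesh$faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    if (nrow(mesh$vertices)) {
      vm <- if (has_r) cbind(mesh$vertices, mesh$vertex_radius) else mesh$vertices
      writeLines(apply(vm, 1, function(r) paste(sprintf("%.9g", r),
                                                collapse = " ")), con)
    }
    if (nrow(mesh$faces))
      writeLines(paste("3", mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                       mesh$faces[, 3] - 1), con)
  } else stop("write_mesh: unsupported extension: ", ext)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("read_mesh: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    ln <- readLines(path)
    vl <- grep("^\\s*vertex ", ln, value = TRUE)
    if (!length(vl)) return(empty_mesh())
    vm <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    # weld identical vertices
    key <- apply(vm, 1, paste, collapse = "|")
    uk <- !duplicated(key)
    map <- match(key, key[uk])
    verts <- vm[uk, , drop = FALSE]
    faces <- matrix(map, ncol = 3, byrow = TRUE)
    vr <- NULL
    side <- paste0(path, ".radius.json")
    if (file.exists(side)) {
      vr <- as.numeric(jsonlite::read_json(side,
                                           simplifyVector = TRUE)$vertex_radius)
      if (length(vr) != nrow(verts)) vr <- NULL
    }
    surface_mesh(verts, faces, vr)
  } else if (ext == "ply") {
    ln <- readLines(path)
    hdr_end <- match("end_header", ln)
    if (is.na(hdr_end)) stop("read_mesh: malformed PLY (no end_header)")
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", ln, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", ln, value = TRUE)))
    props <- grep("^property (double|float)", ln[seq_len(hdr_end)],
                  value = TRUE)
    has_r <- any(grepl("radius", props))
    vrows <- ln[(hdr_end + 1):(hdr_end + nv)]
    vm <- do.call(rbind, lapply(strsplit(trimws(vrows), "\\s+"), as.numeric))
    frows <- if (nf > 0) ln[(hdr_end + nv + 1):(hdr_end + nv + nf)] else character(0)
    fm <- if (nf > 0)
      do.call(rbind, lapply(strsplit(trimws(frows), "\\s+"), function(p)
        as.integer(p[2:4]) + 1L)) else matrix(integer(0), 0, 3)
    surface_mesh(vm[, 1:3, drop = FALSE], fm,
                 if (has_r) vm[, 4] else NULL)
  } else stop("read_mesh: unsupported extension: ", ext)
}

#' Serialize an affine transform to JSON (matrix plus decomposition)
#' @param t an [affine_transform()].
#' @param path file path.
#' @export
write_transform_json <- function(t, path) {
  jsonlite::write_json(list(matrix = t$matrix, rotation = t$rotation,
                            translation = t$translation, scale = t$scale,
                            center = t$center), path, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- affine_transform(rotation = x$rotation, translation = x$translation,
                          scale = x$scale, center = x$center)
  out$matrix <- matrix(unlist(x$matrix), 4, 4)
  out
}

#' Export a plan as CSV (one row per electrode)
#' @param plan a `seeg_plan`.
#' @param path file path.
#' @export
write_plan_csv <- function(plan, path) {
  write.csv(plan_table(plan), path, row.names = FALSE)
  invisible(path)
}

#' Read or write a study configuration as YAML
#'
#' Round-trips the scalar settings of [study_config()]; profile and
#' parameter objects are rebuilt through their constructors so defaults and
#' validation apply.
#'
#' @param config a [study_config()].
#' @param path file path.
#' @export
write_config_yaml <- function(config, path) {
  flat <- list(
    n_phantoms = config$n_phantoms,
    phantom = config$phantom[setdiff(names(config$phantom),
                                     c("profiles", "tree_params"))],
    tree_params = config$phantom$tree_params,
    profiles = lapply(config$phantom$profiles, unclass),
    prune_thresholds = config$prune_thresholds,
    constraints = unclass(config$constraints),
    risk = unclass(config$cfg),
    electrode = unclass(config$electrode),
    weights = config$weights,
    use_sulci = config$use_sulci,
    imaged_arm = config$imaged_arm,
    n_candidates = config$n_candidates)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  profiles <- lapply(y$profiles, function(p) do.call(modality_profile, p))
  ph <- do.call(phantom_config,
                c(y$phantom, list(tree_params = y$tree_params %||% list(),
                                  profiles = profiles)))
  study_config(n_phantoms = y$n_phantoms, phantom = ph,
               prune_thresholds = y$prune_thresholds,
               constraints = do.call(plan_constraints,
                                     y$constraints[!vapply(y$constraints,
                                                           is.null, TRUE)]),
               cfg = do.call(risk_config, y$risk),
               electrode = do.call(electrode_spec, y$electrode),
               weights = do.call(plan_weights, y$weights),
               use_sulci = isTRUE(y$use_sulci),
               imaged_arm = isTRUE(y$imaged_arm),
               n_candidates = y$n_candidates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
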