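#' Scalar or label volume on a regular grid
#'
#' Light container for 3-D volumes: a numeric (or logical) array plus the
#' voxel size and the world position of the first voxel center, both in mm.
#' Voxel `(i, j, k)` (1-based) has its center at
#' `origin + (c(i, j, k) - 1) * voxdim`.
#'
#' @param data 3-D array.
#' @param voxdim numeric length-3 voxel size in mm (scalar recycled).
#' @param origin numeric length-3 world coordinate (mm) of the first voxel
#'   center.
#' @return an object of class `seeg_volume`.
#' @export
new_volume <- function(data, voxdim = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  voxdim <- rep_len(as.numeric(voxdim), 3)
  origin <- rep_len(as.numeric(origin), 3)
  if (any(voxdim <= 0)) stop("voxel dimensions must be positive")
  structure(list(data = data, voxdim = voxdim, origin = origin),
            class = "seeg_volume")
}

#' @export
print.seeg_volume <- function(x, ...) {
  cat("<seeg_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$voxdim, 3), collapse = " x "),
      " mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' Grid specification of a volume
#' @param vol a `seeg_volume`.
#' @return list with `dim`, `voxdim`, `origin`.
#' @export
vol_grid <- function(vol) {
  list(dim = dim(vol$data), voxdim = vol$voxdim, origin = vol$origin)
}

#' Create an empty volume from a grid specification
#' @param grid list with `dim`, `voxdim`, `origin`.
#' @param value fill value.
#' @export
empty_volume <- function(grid, value = 0) {
  new_volume(array(value, dim = grid$dim), grid$voxdim, grid$origin)
}

same_grid <- function(a, b, tol = 1e-8) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$voxdim - b$voxdim) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World coordinates of voxel centers
#'
#' @param vol a `seeg_volume`.
#' @param mask optional logical array selecting voxels; default all.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_centers <- function(vol, mask = NULL) {
  d <- dim(vol$data)
  if (is.null(mask)) {
    idx <- arrayInd(seq_len(prod(d)), d)
  } else {
    idx <- which(array(as.logical(mask), d), arr.ind = TRUE)
  }
  sweep(sweep(idx - 1, 2, vol$voxdim, "*"), 2, vol$origin, "+")
}

#' Nearest-voxel lookup of mm points
#'
#' @param vol a `seeg_volume`.
#' @param pts n x 3 matrix of mm points.
#' @param outside value for points outside the grid.
#' @return vector of voxel values.
#' @export
lookup_volume <- function(vol, pts, outside = 0) {
  pts <- rbind(pts)
  d <- dim(vol$data)
  ijk <- round(sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$voxdim, "/")) + 1
  ok <- ijk[, 1] >= 1 & ijk[, 2] >= 1 & ijk[, 3] >= 1 &
    ijk[, 1] <= d[1] & ijk[, 2] <= d[2] & ijk[, 3] <= d[3]
  out <- rep(outside, nrow(pts))
  if (any(ok)) {
    lin <- (ijk[ok, 1]) + d[1] * (ijk[ok, 2] - 1) + d[1] * d[2] * (ijk[ok, 3] - 1)
    out[ok] <- as.numeric(vol$data)[lin]
  }
  out
}

#' Trilinear sampling of a volume at mm points
#' @inheritParams lookup_volume
#' @export
sample_volume <- function(vol, pts, outside = 0) {
  pts <- rbind(pts)
  as.numeric(cpp_trilinear(as.numeric(vol$data), dim(vol$data), vol$voxdim,
                           vol$origin, pts, outside))
}

#' Euclidean distance map to a foreground mask
#'
#' Distance (mm) from every voxel center to the nearest `TRUE` voxel center,
#' honoring anisotropic voxel sizes. Voxels inside the foreground get 0.
#'
#' @param mask a `seeg_volume` with logical/0-1 data.
#' @return a `seeg_volume` of distances in mm.
#' @export
distance_map <- function(mask) {
  fg <- as.logical(mask$data)
  if (!any(fg)) stop("distance_map: mask is empty")
  d <- cpp_edt3d(fg, dim(mask$data), mask$voxdim)
  new_volume(array(d, dim(mask$data)), mask$voxdim, mask$origin)
}

#' Gaussian smoothing of a volume
#' @param vol a `seeg_volume`.
#' @param sigma_mm standard deviation in mm (scalar or length 3).
#' @export
gaussian_smooth <- function(vol, sigma_mm) {
  sigma_vox <- rep_len(sigma_mm, 3) / vol$voxdim
  out <- cpp_gauss_blur3d(as.numeric(vol$data), dim(vol$data), sigma_vox)
  new_volume(array(out, dim(vol$data)), vol$voxdim, vol$origin)
}

#' Zero an image outside an intracranial mask
#'
#' Voxels outside the mask are set to 0; voxels inside are unchanged. Used to
#' drop extracranial structures before vessel surface extraction.
#'
#' @param image a `seeg_volume`.
#' @param mask a `seeg_volume` on the same grid, logical/0-1.
#' @return masked `seeg_volume`.
#' @export
apply_intracranial_mask <- function(image, mask) {
  if (!same_grid(image, mask))
    stop("apply_intracranial_mask: image and mask grids differ")
  out <- image
  out$data <- image$data * array(as.logical(mask$data) * 1, dim(image$data))
  out
}

#' Erode a binary mask with a ball structuring element
#'
#' A voxel survives when its distance to the nearest background voxel exceeds
#' the erosion radius (Euclidean, in mm).
#'
#' @param mask a `seeg_volume`, logical/0-1.
#' @param radius_mm erosion radius in mm; 0 is the identity.
#' @export
erode_mask <- function(mask, radius_mm) {
  stopifnot(radius_mm >= 0)
  m <- as.logical(mask$data)
  out <- mask
  if (radius_mm == 0) {
    out$data <- array(m, dim(mask$data))
    return(out)
  }
  bg <- !m
  if (!any(bg)) stop("erode_mask: mask has no background")
  d <- array(cpp_edt3d(bg, dim(mask$data), mask$voxdim), dim(mask$data))
  out$data <- array(m & (d > radius_mm), dim(mask$data))
  out
}

#' Downsample a volume by 2 (smooth then decimate)
#' @param vol a `seeg_volume`.
#' @keywords internal
downsample2 <- function(vol) {
  sm <- gaussian_smooth(vol, vol$voxdim)
  d <- dim(sm$data)
  ix <- seq(1, d[1], by = 2); iy <- seq(1, d[2], by = 2); iz <- seq(1, d[3], by = 2)
  new_volume(sm$data[ix, iy, iz, drop = FALSE], vol$voxdim * 2, vol$origin)
}
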