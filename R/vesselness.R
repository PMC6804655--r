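#' Multiscale vesselness filter parameters
#'
#' Parameters of the Hessian line filter used to enhance bright tubular
#' structures: per voxel and per scale, the Gaussian-smoothed Hessian
#' eigenvalues `l1 >= l2 >= l3` feed the line measure of Sato's formulation;
#' the response is the maximum over scales of the sigma^2-normalized
#' measure. Bright tubes have `l2, l3` strongly negative and `l1` near 0.
#'
#' @param scales Gaussian scales (sigma) in mm, nonempty, all positive.
#' @param alpha asymmetry weight for positive `l1` (eccentric cross
#'   sections); 0 < alpha <= 1.
#' @param gamma12 exponent on the `l1`/`l2` factor.
#' @param gamma23 exponent on the `l2`/`l3` factor.
#' @export
vesselness_params <- function(scales = c(0.5, 1, 2, 3), alpha = 0.25,
                              gamma12 = 1, gamma23 = 1) {
  if (!length(scales) || any(scales <= 0))
    stop("vesselness_params: scales must be nonempty and positive")
  structure(list(scales = scales, alpha = alpha, gamma12 = gamma12,
                 gamma23 = gamma23), class = "vesselness_params")
}

# shift array with edge replication
shift_arr <- function(a, s, axis) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + s, 1), d[axis])
  if (axis == 1) a[idx, , , drop = FALSE]
  else if (axis == 2) a[, idx, , drop = FALSE]
  else a[, , idx, drop = FALSE]
}

# second derivatives by central differences (spacing h per axis, mm)
hessian_components <- function(a, h) {
  d2 <- function(ax) (shift_arr(a, 1, ax) - 2 * a + shift_arr(a, -1, ax)) / h[ax]^2
  dd <- function(ax1, ax2) {
    (shift_arr(shift_arr(a, 1, ax1), 1, ax2) -
       shift_arr(shift_arr(a, 1, ax1), -1, ax2) -
       shift_arr(shift_arr(a, -1, ax1), 1, ax2) +
       shift_arr(shift_arr(a, -1, ax1), -1, ax2)) / (4 * h[ax1] * h[ax2])
  }
  list(xx = d2(1), yy = d2(2), zz = d2(3),
       xy = dd(1, 2), xz = dd(1, 3), yz = dd(2, 3))
}

# eigenvalues of symmetric 3x3 fields, returned sorted l1 >= l2 >= l3
sym3_eigenvalues <- function(H) {
  a11 <- H$xx; a22 <- H$yy; a33 <- H$zz
  a12 <- H$xy; a13 <- H$xz; a23 <- H$yz
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  safe_p <- pmax(p, 1e-300)
  b11 <- (a11 - q) / safe_p; b22 <- (a22 - q) / safe_p; b33 <- (a33 - q) / safe_p
  b12 <- a12 / safe_p; b13 <- a13 / safe_p; b23 <- a23 / safe_p
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  degenerate <- p2 < 1e-30
  if (any(degenerate)) {
    e1[degenerate] <- q[degenerate]
    e2[degenerate] <- q[degenerate]
    e3[degenerate] <- q[degenerate]
  }
  list(l1 = e1, l2 = e2, l3 = e3)
}

#' Multiscale Hessian vesselness of a 3-D image
#'
#' For each scale sigma the image is Gaussian-smoothed, the Hessian is
#' formed by central differences and normalized by sigma^2, and the
#' bright-line measure is evaluated from its sorted eigenvalues
#' `l1 >= l2 >= l3`:
#' zero unless `l3 <= l2 < 0`; otherwise
#' `|l3| * (l2/l3)^gamma23 * w(l1)` with `w` rewarding `l1` near zero
#' (`(1 + l1/|l2|)^gamma12` for `l1 <= 0`,
#' `(1 - alpha*l1/|l2|)^gamma12` for small positive `l1`, 0 beyond).
#' The returned response is the per-voxel maximum over scales; it is
#' nonnegative and vanishes on constant images. Input must use the
#' bright-vessel convention (vessels brighter than background).
#'
#' @param image a `seeg_volume` (3-D).
#' @param params a [vesselness_params()].
#' @return a `seeg_volume` of filter responses.
#' @export
sato_vesselness <- function(image, params = vesselness_params()) {
  if (!inherits(image, "seeg_volume") || length(dim(image$data)) != 3)
    stop("sato_vesselness: need a 3-D seeg_volume")
  best <- array(0, dim(image$data))
  for (sg in params$scales) {
    sm <- gaussian_smooth(image, sg)
    H <- hessian_components(sm$data, image$voxdim)
    H <- lapply(H, function(x) x * sg^2)   # scale normalization
    ev <- sym3_eigenvalues(H)
    l1 <- ev$l1; l2 <- ev$l2; l3 <- ev$l3
    resp <- array(0, dim(image$data))
    tube <- l2 < 0 & l3 < 0
    if (any(tube)) {
      l1t <- l1[tube]; l2t <- l2[tube]; l3t <- l3[tube]
      base <- abs(l3t) * (l2t / l3t)^params$gamma23
      w <- numeric(length(l1t))
      neg <- l1t <= 0
      w[neg] <- (1 + l1t[neg] / abs(l2t[neg]))^params$gamma12
      pos <- !neg & (l1t < abs(l2t) / params$alpha)
      w[pos] <- (1 - params$alpha * l1t[pos] / abs(l2t[pos]))^params$gamma12
      w[w < 0 | !is.finite(w)] <- 0
      resp[tube] <- base * w
    }
    best <- pmax(best, resp)
  }
  new_volume(best, image$voxdim, image$origin)
}
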