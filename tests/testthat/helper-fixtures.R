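# Shared fixtures: analytic volumes and meshes built in code, plus a
# session-cached cohort study so the expensive end-to-end results are
# computed once and reused across test files.

sphere_volume <- function(n = 40, center = rep((n - 1) / 2, 3), radius = 12,
                          voxdim = 1) {
  ax <- (seq_len(n) - 1) * voxdim
  r2 <- outer(outer((ax - center[1])^2, (ax - center[2])^2, "+"),
              (ax - center[3])^2, "+")
  new_volume((sqrt(r2) <= radius) * 1, voxdim = voxdim)
}

# axis-aligned cylinder along z, axis through (cx, cy)
cylinder_volume <- function(n = 40, cx = (n - 1) / 2, cy = (n - 1) / 2,
                            radius = 2, voxdim = 1) {
  ax <- (seq_len(n) - 1) * voxdim
  lat <- outer((ax - cx)^2, (ax - cy)^2, "+")
  data <- array(rep((sqrt(lat) <= radius) * 1, times = n), dim = rep(n, 3))
  new_volume(data, voxdim = voxdim)
}

smooth_surface <- function(vol, iso = 0.5) {
  extract_vessel_surface(gaussian_smooth(vol, 0.5 * min(vol$voxdim)), iso)
}

# two parallel tubes of the given radii along z, centers x = x1, x2
two_tube_tree <- function(radii = c(0.5, 1.5), x = c(25, 55), len = c(10, 70)) {
  segs <- data.frame(x0 = x, y0 = 40, z0 = len[1],
                     x1 = x, y1 = 40, z1 = len[2],
                     radius = radii, parent = 0L, generation = 1L,
                     branch = seq_along(radii))
  structure(list(segments = segs, roots = cbind(x, 40, len[1]),
                 params = list(), seed = 0L),
            class = "vascular_tree")
}

# three-branch tree with diameters 1, 3 and 5 mm for pruning tests
three_branch_tree <- function() {
  segs <- data.frame(
    x0 = c(20, 40, 60), y0 = c(40, 40, 40), z0 = c(15, 15, 15),
    x1 = c(20, 40, 60), y1 = c(40, 40, 40), z1 = c(65, 65, 65),
    radius = c(0.5, 1.5, 2.5), parent = 0L, generation = 1L,
    branch = 1:3)
  structure(list(segments = segs, roots = cbind(segs$x0, segs$y0, segs$z0),
                 params = list(), seed = 0L),
            class = "vascular_tree")
}

grid80 <- function(voxdim = 1) list(dim = rep(80, 3), voxdim = rep(voxdim, 3),
                                    origin = c(0, 0, 0))

# cohort study cache (computed on first use; ~10 min)
.seegplan_test_cache <- new.env(parent = emptyenv())

cached_study <- function() {
  if (is.null(.seegplan_test_cache$study))
    .seegplan_test_cache$study <- run_study(42L, study_config())
  .seegplan_test_cache$study
}

cached_phantom <- function() {
  if (is.null(.seegplan_test_cache$phantom))
    .seegplan_test_cache$phantom <- make_phantom(7L)
  .seegplan_test_cache$phantom
}

# gold-model plan on the cached phantom, shared by evaluation and io tests
cached_gold_plan <- function() {
  if (is.null(.seegplan_test_cache$gold_plan)) {
    ph <- cached_phantom()
    gold <- truth_vessel_model(ph)
    .seegplan_test_cache$gold_plan <-
      list(gold = gold, plan = plan_electrodes(ph, list(gold), seed = 11))
  }
  .seegplan_test_cache$gold_plan
}

# asymmetric three-tube image (two parallel + one oblique) so no affine
# degree of freedom is degenerate; shared by registration unit tests and
# the registration-recovery acceptance block
reg_image <- function(noise = 0) {
  segs <- data.frame(x0 = c(25, 50, 15), y0 = c(40, 40, 18),
                     z0 = c(12, 12, 20),
                     x1 = c(25, 50, 60), y1 = c(40, 40, 62),
                     z1 = c(64, 64, 58),
                     radius = c(1.5, 3, 2), parent = 0L, generation = 1L,
                     branch = 1:3)
  tree <- structure(list(segments = segs,
                         roots = cbind(segs$x0, segs$y0, segs$z0),
                         params = list(), seed = 0L),
                    class = "vascular_tree")
  prof <- modality_profile("reg", 0, blur_sigma = 1, noise_sd = noise)
  render_modality(tree, prof, grid80(), seed = 3)
}
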