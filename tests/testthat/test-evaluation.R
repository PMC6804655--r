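# frozen two-electrode plan used across re-evaluation tests
fixed_plan <- function() {
  es <- electrode_spec()
  mk <- function(entry, target) {
    tr <- trajectory(entry, target, es)
    list(trajectory = tr,
         metrics = list(rs = NA, md = NA, length = traj_length_of(tr),
                        angle = NA, gm_ratio = NA, collision = FALSE))
  }
  structure(list(electrodes = list(A = mk(c(10, 20, 40), c(35, 35, 40)),
                                   B = mk(c(70, 60, 40), c(48, 48, 40))),
                 constraints = plan_constraints(), weights = plan_weights()),
            class = "seeg_plan")
}

traj_length_of <- function(t) sqrt(sum((t$target - t$entry)^2))

test_that("self-evaluation reproduces the planning-time metrics", {
  gp <- cached_gold_plan()
  gold <- gp$gold; pl <- gp$plan
  rows <- recompute_plan_metrics(pl, gold)
  for (i in seq_along(pl$electrodes)) {
    expect_equal(rows$rs[i], pl$electrodes[[rows$electrode[i]]]$metrics$rs)
    expect_equal(rows$md[i], pl$electrodes[[rows$electrode[i]]]$metrics$md)
  }
})

test_that("a distant extra structure leaves RS unchanged and can only shrink MD", {
  tube <- smooth_surface(cylinder_volume(80, cx = 40, cy = 40, radius = 2))
  pl <- fixed_plan()
  base <- recompute_plan_metrics(pl, tube)
  # extra tube > 10 mm beyond every node of both trajectories
  far <- smooth_surface(cylinder_volume(80, cx = 5, cy = 75, radius = 2))
  both <- surface_mesh(rbind(tube$vertices, far$vertices),
                       rbind(tube$faces, far$faces + nrow(tube$vertices)))
  aug <- recompute_plan_metrics(pl, both)
  expect_equal(aug$rs, base$rs, tolerance = 1e-12)
  expect_true(all(aug$md <= base$md + 1e-12))
})

test_that("true risk dominates apparent risk for nested models", {
  ph <- cached_phantom()
  gold <- truth_vessel_model(ph)
  degraded <- prune_by_diameter(gold, 4)
  pl <- plan_electrodes(ph, list(degraded), seed = 13)
  apparent <- recompute_plan_metrics(pl, degraded)
  true <- recompute_plan_metrics(pl, gold)
  expect_true(all(apparent$rs <= true$rs + 1e-12))
  expect_true(all(apparent$md >= true$md - 1e-12))
})

test_that("diameter sweep is monotone and anchored at threshold zero", {
  gp <- cached_gold_plan()
  gold <- gp$gold; pl <- gp$plan
  sw <- diameter_sweep(pl, gold, thresholds = c(0, 1, 2, 3, 4))
  base <- recompute_plan_metrics(pl, gold)
  t0 <- sw[sw$threshold == 0, ]
  expect_equal(t0$rs, base$rs)
  expect_equal(t0$md, base$md)
  for (el in unique(sw$electrode)) {
    s <- sw[sw$electrode == el, ]
    s <- s[order(s$threshold), ]
    expect_true(all(diff(s$rs) <= 1e-12))
    expect_true(all(diff(s$md) >= -1e-12))
  }
  noradius <- surface_mesh(gold$vertices, gold$faces)
  expect_error(diameter_sweep(pl, noradius), "vertex_radius")
})

test_that("vessel region classification matches a voxel-membership oracle", {
  ph <- cached_phantom()
  masks <- list(sulcal = sulcal_mask(ph$gm_mask, ph$intracranial_mask, 5),
                gm = ph$gm_mask, intracranial = ph$intracranial_mask)
  gold <- truth_vessel_model(ph)
  # identical to the reference: all vertices present
  p1 <- classify_vessel_regions(gold, masks, gold)
  expect_equal(unname(p1["present_in_reference"]), 1)
  expect_equal(sum(p1), 1)
  # a tube fully inside the sulcal mask with an empty reference
  fold_pts <- voxel_centers(masks$sulcal, masks$sulcal$data > 0)
  ctr <- fold_pts[which.max(rowSums(fold_pts)), ]  # a deep fold voxel
  tiny <- icosphere(ctr, 0.4, 1)   # small enough to stay in one voxel
  p2 <- classify_vessel_regions(tiny, masks, empty_mesh())
  expect_equal(unname(p2["sulcal"]), 1)
  # mixed case: proportions equal brute-force point-in-mask counts
  mixed <- prune_by_diameter(gold, 2)
  p3 <- classify_vessel_regions(mixed, masks, prune_by_diameter(gold, 3),
                                tol = 1, cortical_depth = 3)
  V <- mixed$vertices
  dref <- point_mesh_distance(V, prune_by_diameter(gold, 3), method = "brute")
  in_sulc <- lookup_volume(masks$sulcal, V, outside = 0) > 0.5
  depth_vol <- distance_map(new_volume((masks$intracranial$data <= 0.5) * 1,
                                       ph$grid$voxdim, ph$grid$origin))
  depth <- sample_volume(depth_vol, V)
  lab <- rep("intracerebral", nrow(V))
  lab[depth <= 3] <- "cortical_surface"
  lab[in_sulc] <- "sulcal"
  lab[dref <= 1] <- "present_in_reference"
  expect_equal(unname(p3["present_in_reference"]),
               mean(lab == "present_in_reference"))
  expect_equal(unname(p3["sulcal"]), mean(lab == "sulcal"))
  expect_equal(sum(p3), 1)
})

test_that("a small cohort study has the advertised structure and determinism", {
  cfg <- study_config(
    n_phantoms = 2,
    phantom = phantom_config(n = 64, brain_radius = 26, skull_radius = 29,
                             roi_depth = 12, n_target_rois = 3,
                             tree_params = list(max_generation = 5)),
    imaged_arm = FALSE, n_candidates = 6)
  st <- run_study(3, cfg)
  ev <- st$evaluation
  # one apparent and one true row per electrode, phantom and planning model
  expect_equal(nrow(ev), 2 * 3 * 3 * 2)
  expect_true(all(ev$rs >= 0 & ev$rs <= 2))
  expect_equal(nrow(st$sweep), 2 * 3 * 4)
  expect_true(all(vapply(st$checks, function(c) c$ok, logical(1))))
  # determinism: same seed reproduces the tables exactly
  st2 <- run_study(3, cfg)
  expect_identical(st$evaluation, st2$evaluation)
  expect_identical(st$sweep, st2$sweep)
  # different seed gives a different cohort (one phantom suffices)
  cfg1 <- cfg; cfg1$n_phantoms <- 1
  st3 <- run_study(5, cfg1)
  expect_false(identical(st$evaluation$rs[seq_len(nrow(st3$evaluation))],
                         st3$evaluation$rs))
})
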