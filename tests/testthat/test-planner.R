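test_that("entry sampling covers a sphere at the requested density", {
  skull <- icosphere(center = c(0, 0, 0), radius = 80)
  ec <- with_seed(2, sample_entry_candidates(skull, spacing = 5))
  expected <- 4 * pi * 80^2 / 5^2
  expect_lt(abs(nrow(ec$points) - expected) / expected, 0.2)
  # outward normals align with the radial direction on a sphere
  rad <- ec$points / sqrt(rowSums(ec$points^2))
  expect_gt(min(rowSums(ec$normals * rad)), 0.99)
  # huge spacing still returns at least one point
  ec2 <- with_seed(2, sample_entry_candidates(skull, spacing = 500))
  expect_gte(nrow(ec2$points), 1)
})

test_that("target candidates respect the safety margin", {
  g <- grid80()
  roi <- empty_volume(g)
  roi$data[36:44, 36:44, 36:44] <- 1
  # far vessel: everything survives
  far <- smooth_surface(cylinder_volume(80, cx = 5, cy = 5, radius = 2))
  pts <- sample_target_candidates(new_volume(roi$data), list(far), margin = 3)
  expect_equal(nrow(pts), sum(roi$data))
  # vessel bisecting the ROI: excluded corridor matches a distance oracle
  mid <- smooth_surface(cylinder_volume(80, cx = 40, cy = 40, radius = 2))
  pts2 <- sample_target_candidates(new_volume(roi$data), list(mid), margin = 3)
  all_pts <- voxel_centers(roi, roi$data > 0)
  oracle_d <- point_mesh_distance(all_pts, mid, method = "brute")
  expect_equal(nrow(pts2), sum(oracle_d >= 3))
  expect_true(all(point_mesh_distance(pts2, mid, method = "brute") >= 3))
  # margin beyond the ROI extent: nothing survives
  expect_warning(
    pts3 <- sample_target_candidates(new_volume(roi$data), list(mid),
                                     margin = 60),
    "no candidate")
  expect_equal(nrow(pts3), 0)
})

test_that("hard-constraint filtering matches a per-constraint oracle", {
  ph <- cached_phantom()
  vessels <- truth_vessel_model(ph)
  es <- electrode_spec()
  entries <- with_seed(4, sample_entry_candidates(ph$skull_mesh, 8))
  roi <- ph$target_rois; roi$data <- (roi$data == 1) * 1
  targets <- sample_target_candidates(roi, list(vessels), 3, es$diameter / 2)
  cons <- plan_constraints(max_length = 60, max_angle_to_normal = 25)
  pairs <- with_seed(5, cbind(sample.int(nrow(entries$points), 100, TRUE),
                              sample.int(nrow(targets), 100, TRUE)))
  surv <- filter_candidates(entries, targets, pairs = pairs,
                            constraints = cons, critical = list(vessels),
                            electrode = es)
  # oracle: evaluate every constraint independently per pair
  keep_oracle <- vapply(seq_len(nrow(pairs)), function(i) {
    e <- entries$points[pairs[i, 1], ]; nrm <- entries$normals[pairs[i, 1], ]
    t <- targets[pairs[i, 2], ]
    len <- sqrt(sum((t - e)^2))
    ang <- acos(sum((t - e) / len * (-nrm))) * 180 / pi
    clear <- segment_mesh_distance(e, t, list(vessels)) > es$diameter / 2
    len <= cons$max_length && ang <= cons$max_angle_to_normal && clear
  }, logical(1))
  expect_setequal(paste(surv$entry, surv$target),
                  paste(pairs[keep_oracle, 1], pairs[keep_oracle, 2]))
})

test_that("obvious rejections: collision and near-tangent drilling angles", {
  g <- grid80()
  tube <- smooth_surface(cylinder_volume(80, radius = 3))
  entries <- list(points = rbind(c(10, 40, 40)),
                  normals = rbind(c(-1, 0, 0)))
  # through the tube: removed
  surv <- filter_candidates(entries, rbind(c(70, 40, 40)),
                            critical = list(tube))
  expect_equal(nrow(surv), 0)
  # nearly tangent to the skull normal: removed at 30 degrees
  surv2 <- filter_candidates(entries, rbind(c(11, 40 + 57, 40)),
                             critical = list())
  expect_equal(nrow(surv2), 0)
})

test_that("gray-matter contact ratio counts contact centers in the mask", {
  g <- grid80()
  gm <- empty_volume(g)
  gm$data[, , ] <- 1
  es <- electrode_spec(n_contacts = 10, contact_spacing = 5)
  tr <- trajectory(c(10, 40, 40), c(70, 40, 40), es)
  expect_equal(gm_contact_ratio(tr, gm), 1.0)
  expect_equal(gm_contact_ratio(tr, empty_volume(g)), 0.0)
  # slab covering contacts 1-4 only (deepest contact sits on the target)
  gm2 <- empty_volume(g)
  gm2$data[53:78, , ] <- 1   # x in [52, 77] mm; contacts at x = 70,65,..,25
  expect_equal(gm_contact_ratio(tr, gm2), 0.4)
  # contacts beyond the entry count as outside
  tr2 <- trajectory(c(60, 40, 40), c(70, 40, 40), es)
  gm3 <- empty_volume(g); gm3$data[, , ] <- 1
  expect_equal(gm_contact_ratio(tr2, gm3), 0.3)  # 70, 65, 60 only
})

test_that("plan combination is optimal on small instances", {
  es <- electrode_spec()
  mk <- function(entry, target, rs, gm = 0, len = 50) {
    tr <- trajectory(entry, target, es)
    list(trajectory = tr,
         metrics = list(rs = rs, md = 5, length = len, angle = 10,
                        gm_ratio = gm, collision = FALSE))
  }
  # dominance: lower RS wins
  cands <- list(E1 = list(mk(c(0, 0, 0), c(0, 0, 50), 0.6),
                          mk(c(20, 0, 0), c(20, 0, 50), 0.2)))
  plan <- optimize_plan(cands)
  expect_equal(plan$electrodes$E1$metrics$rs, 0.2)

  # two electrodes whose individually-best choices are 5 mm apart: one must
  # switch to honor the 10 mm spacing (verified by exhaustive search)
  cands2 <- list(
    A = list(mk(c(0, 0, 0), c(0, 0, 50), 0.1),
             mk(c(30, 0, 0), c(30, 0, 50), 0.5)),
    B = list(mk(c(5, 0, 0), c(5, 0, 50), 0.1),
             mk(c(15, 0, 0), c(15, 0, 50), 0.3)))
  plan2 <- optimize_plan(cands2)
  d <- trajectory_distance(plan2$electrodes$A$trajectory,
                           plan2$electrodes$B$trajectory)
  expect_gte(d, 10)
  expect_false(plan2$electrodes$A$metrics$rs == 0.1 &&
                 plan2$electrodes$B$metrics$rs == 0.1)

  # randomized small instances match exhaustive search cost
  wts <- plan_weights()
  cons <- plan_constraints()
  reps <- with_seed(21, lapply(1:10, function(r) {
    k <- sample(2:3, 1)
    cands <- lapply(seq_len(k), function(e) {
      lapply(seq_len(sample(3:8, 1)), function(c) {
        x <- runif(1, 0, 80); y <- runif(1, 0, 80)
        mk(c(x, y, 0), c(x + runif(1, -10, 10), y + runif(1, -10, 10), 60),
           rs = runif(1, 0, 1), gm = runif(1), len = runif(1, 40, 80))
      })
    })
    names(cands) <- paste0("E", seq_len(k))
    cands
  }))
  for (cands in reps) {
    cost_of <- function(choice) {
      sel <- Map(function(cl, i) cl[[i]], cands, choice)
      trs <- lapply(sel, `[[`, "trajectory")
      k <- length(trs)
      for (i in seq_len(k - 1)) for (j in (i + 1):k)
        if (trajectory_distance(trs[[i]], trs[[j]]) < cons$min_pairwise)
          return(NA_real_)
      sum(vapply(sel, function(s)
        s$metrics$rs * wts$rs - s$metrics$gm_ratio * wts$gm +
          s$metrics$length / cons$max_length * wts$len, numeric(1)))
    }
    grid <- do.call(expand.grid, lapply(cands, seq_along))
    costs <- apply(grid, 1, function(ch) cost_of(as.integer(ch)))
    plan <- tryCatch(optimize_plan(cands, cons, wts), error = function(e) NULL)
    if (all(is.na(costs))) {
      expect_null(plan)
    } else {
      expect_false(is.null(plan))
      got <- sum(vapply(plan$electrodes, function(e)
        e$metrics$rs * wts$rs - e$metrics$gm_ratio * wts$gm +
          e$metrics$length / cons$max_length * wts$len, numeric(1)))
      # small instances are solved exhaustively: true optimum expected
      expect_equal(got, min(costs, na.rm = TRUE), tolerance = 1e-9)
      ck <- vapply(seq_along(plan$electrodes), function(i)
        all(vapply(seq_along(plan$electrodes), function(j)
          i == j || trajectory_distance(plan$electrodes[[i]]$trajectory,
                                        plan$electrodes[[j]]$trajectory) >=
            cons$min_pairwise, logical(1))), logical(1))
      expect_true(all(ck))
    }
  }
})
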