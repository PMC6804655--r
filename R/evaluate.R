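#' Segment a vessel model from a modality image
#'
#' The canonical model-generation pipeline: multiscale vesselness
#' enhancement, intracranial masking, vessel detection by thresholding the
#' vesselness (Otsu by default), then surface extraction from the intensity
#' image restricted to the grown detection mask at half the vessel
#' intensity (the full-width-half-maximum criterion, which places the
#' surface at the unblurred tube boundary and so keeps estimated radii
#' unbiased), and removal of small unconnected components.
#'
#' @param image modality `seeg_volume`.
#' @param icv_mask intracranial binary `seeg_volume`.
#' @param params a [vesselness_params()].
#' @param threshold vesselness detection threshold; `NULL` uses
#'   [otsu_threshold()] of the masked vesselness.
#' @param surface_iso intensity iso value for the surface; `NULL` uses half
#'   the median detected vessel intensity.
#' @param min_component minimum vertices per connected component.
#' @return a `surface_mesh`; attributes `"threshold"` and `"surface_iso"`
#'   record the values used.
#' @export
segment_vessel_model <- function(image, icv_mask,
                                 params = vesselness_params(),
                                 threshold = NULL, surface_iso = NULL,
                                 min_component = 30) {
  v <- sato_vesselness(image, params)
  v <- apply_intracranial_mask(v, icv_mask)
  if (is.null(threshold)) threshold <- otsu_threshold(v)
  segment_from_vesselness(image, v, icv_mask, threshold, surface_iso,
                          min_component)
}

# detection + FWHM surface extraction given a precomputed vesselness
segment_from_vesselness <- function(image, v, icv_mask, threshold,
                                    surface_iso = NULL, min_component = 30) {
  det <- v
  det$data <- (v$data >= threshold) * 1
  if (!any(det$data > 0)) {
    warning("segment_vessel_model: nothing detected above threshold")
    return(empty_mesh())
  }
  if (is.null(surface_iso))
    surface_iso <- 0.5 * median(image$data[det$data > 0 &
                                             icv_mask$data > 0.5])
  grown <- distance_map(det)
  keep <- grown
  keep$data <- (grown$data <= 1.5) * 1
  img_m <- apply_intracranial_mask(image, icv_mask)
  img_m$data <- img_m$data * keep$data
  mesh <- suppressWarnings(extract_vessel_surface(img_m, surface_iso))
  mesh <- remove_small_components(mesh, min_component)
  attr(mesh, "threshold") <- threshold
  attr(mesh, "surface_iso") <- surface_iso
  mesh
}

#' Ground-truth radius of the nearest tree segment, per mesh vertex
#'
#' Ownership is decided by distance to the tube surface (not the axis), so
#' vertices at junctions belong to the vessel whose wall they sit on.
#'
#' @param mesh a `surface_mesh`.
#' @param tree the generating `vascular_tree`.
#' @return numeric vector of true radii (mm), one per vertex.
#' @export
tree_vertex_radii <- function(mesh, tree) {
  segs <- tree$segments
  nv <- nrow(mesh$vertices)
  if (nv == 0 || nrow(segs) == 0) return(numeric(0))
  best <- rep(Inf, nv)
  rad <- rep(NA_real_, nv)
  V <- mesh$vertices
  for (s in seq_len(nrow(segs))) {
    p0 <- c(segs$x0[s], segs$y0[s], segs$z0[s])
    v <- c(segs$x1[s] - p0[1], segs$y1[s] - p0[2], segs$z1[s] - p0[3])
    vv <- sum(v^2)
    w1 <- V[, 1] - p0[1]; w2 <- V[, 2] - p0[2]; w3 <- V[, 3] - p0[3]
    t <- if (vv > 0) pmin(1, pmax(0, (w1 * v[1] + w2 * v[2] + w3 * v[3]) / vv)) else 0
    d2 <- (w1 - t * v[1])^2 + (w2 - t * v[2])^2 + (w3 - t * v[3])^2
    # distance to the tube surface, not the axis, decides ownership
    ds <- sqrt(d2) - segs$radius[s]
    upd <- ds < best
    best[upd] <- ds[upd]
    rad[upd] <- segs$radius[s]
  }
  rad
}

#' Ground-truth vessel model of a phantom
#'
#' Surface of the full-visibility tube rasterization with per-vertex radii
#' taken from the generating tree segment (the phantom's ground truth).
#' Pruning this mesh at a visibility cutoff reproduces, by construction,
#' the geometry a noiseless modality with that cutoff would show.
#'
#' @param phantom a `seeg_phantom`.
#' @return a `surface_mesh` with `vertex_radius` populated from the truth.
#' @export
truth_vessel_model <- function(phantom) {
  m <- phantom$truth$mask
  sm <- gaussian_smooth(m, 0.5 * min(m$voxdim))
  mesh <- extract_vessel_surface(sm, 0.5)
  mesh$vertex_radius <- tree_vertex_radii(mesh, phantom$tree)
  mesh
}

#' Re-evaluate a frozen plan against an alternative vessel model
#'
#' Trajectories are kept exactly as planned; only the critical-structure
#' model changes. This separates the "apparent" risk (metrics against the
#' model used for planning) from the "true" risk (metrics against the
#' reference model).
#'
#' @param plan a `seeg_plan`.
#' @param vessels evaluation vessel `surface_mesh`.
#' @param sulci optional sulcal `surface_mesh` added to the critical set.
#' @param cfg a [risk_config()].
#' @return data.frame: `electrode`, `rs`, `md`.
#' @export
recompute_plan_metrics <- function(plan, vessels, sulci = NULL,
                                   cfg = risk_config()) {
  critical <- c(list(vessels), if (!is.null(sulci)) list(sulci))
  do.call(rbind, lapply(names(plan$electrodes), function(nm) {
    tr <- plan$electrodes[[nm]]$trajectory
    d <- node_distances(tr, critical)
    data.frame(electrode = nm,
               rs = risk_score(as.numeric(d), cfg),
               md = min(attr(d, "raw")))
  }))
}

#' Metrics of a frozen plan under iterative diameter pruning
#'
#' Recomputes RS and MD for each electrode against the reference model
#' pruned at each diameter threshold, emulating the iterative removal of
#' small vessels from the gold standard.
#'
#' @param plan a `seeg_plan`.
#' @param gold reference `surface_mesh` with `vertex_radius` populated.
#' @param thresholds mm diameters (default 1, 2, 3, 4).
#' @param cfg a [risk_config()].
#' @return data.frame: `threshold`, `electrode`, `rs`, `md`.
#' @export
diameter_sweep <- function(plan, gold, thresholds = c(1, 2, 3, 4),
                           cfg = risk_config()) {
  if (is.null(gold$vertex_radius))
    stop("diameter_sweep: reference mesh has no vertex_radius")
  do.call(rbind, lapply(thresholds, function(th) {
    pruned <- prune_by_diameter(gold, th)
    rows <- recompute_plan_metrics(plan, pruned, cfg = cfg)
    cbind(threshold = th, rows)
  }))
}

#' Classify vessel-model vertices by anatomical region
#'
#' Each vertex of `vessels` is labeled, in priority order:
#' `present_in_reference` (within `tol` of the reference model), `sulcal`
#' (inside the sulcal mask), `cortical_surface` (within `cortical_depth` of
#' the intracranial boundary), else `intracerebral`.
#'
#' @param vessels `surface_mesh` to classify.
#' @param masks list with `sulcal`, `gm`, `intracranial` binary
#'   `seeg_volume`s on one grid.
#' @param reference reference `surface_mesh` (may be empty).
#' @param tol mm for presence in the reference.
#' @param cortical_depth mm shell treated as cortical surface.
#' @return named numeric proportions summing to 1.
#' @export
classify_vessel_regions <- function(vessels, masks, reference,
                                    tol = 1, cortical_depth = 3) {
  V <- vessels$vertices
  n <- nrow(V)
  labs <- character(n)
  dref <- if (!is_empty_mesh(reference))
    point_mesh_distance(V, reference) else rep(Inf, n)
  in_sulcal <- lookup_volume(masks$sulcal, V, outside = 0) > 0.5
  depth_vol <- distance_map(new_volume((masks$intracranial$data <= 0.5) * 1,
                                       masks$intracranial$voxdim,
                                       masks$intracranial$origin))
  depth <- sample_volume(depth_vol, V)
  labs[] <- "intracerebral"
  labs[depth <= cortical_depth] <- "cortical_surface"
  labs[in_sulcal] <- "sulcal"
  labs[dref <= tol] <- "present_in_reference"
  out <- table(factor(labs, levels = c("present_in_reference", "sulcal",
                                       "intracerebral", "cortical_surface")))
  as.numeric(out) / n -> p
  stats::setNames(p, names(out))
}

#' Study configuration
#'
#' Conditions of the synthetic cohort study: phantom settings, the cohort
#' size, planning constraints and weights, and the risk-score constants.
#'
#' @param n_phantoms cohort size (default 10).
#' @param phantom a [phantom_config()].
#' @param prune_thresholds mm sweep thresholds.
#' @param constraints a [plan_constraints()].
#' @param cfg a [risk_config()].
#' @param electrode an [electrode_spec()].
#' @param weights a [plan_weights()].
#' @param use_sulci include the sulcal model among critical structures.
#' @param imaged_arm also run the image-based segmentation arm.
#' @param n_candidates exact-stage candidates per electrode.
#' @export
study_config <- function(n_phantoms = 10, phantom = phantom_config(),
                         prune_thresholds = c(1, 2, 3, 4),
                         constraints = plan_constraints(),
                         cfg = risk_config(), electrode = electrode_spec(),
                         weights = plan_weights(), use_sulci = FALSE,
                         imaged_arm = TRUE, n_candidates = 8) {
  list(n_phantoms = n_phantoms, phantom = phantom,
       prune_thresholds = prune_thresholds, constraints = constraints,
       cfg = cfg, electrode = electrode, weights = weights,
       use_sulci = use_sulci, imaged_arm = imaged_arm,
       n_candidates = n_candidates)
}

#' Run the full synthetic cohort study
#'
#' For every phantom in the cohort: build the ground-truth vessel model and
#' its visibility-degraded versions (truth-pruned, i.e. exactly nested), plan
#' one implantation per model, cross-evaluate every frozen plan against its
#' own model ("apparent") and the gold model ("true"), sweep pruning
#' diameters on the gold plan, and - in the imaged arm - re-derive the
#' models from the rendered modality images through the segmentation
#' pipeline and test the statistical equivalence of the degraded model with
#' the gold model pruned at the matching diameter. Paired statistics use
#' the Shapiro-Wilk-gated test with Bonferroni correction over 3
#' comparisons.
#'
#' @param seed integer master seed.
#' @param config a [study_config()].
#' @return list of class `seeg_study`: `evaluation` (long table of
#'   per-electrode RS/MD across models), `sweep`, `plans`, `checks`,
#'   `stats`, `r2`, `equivalence`, `config`, `seed`.
#' @export
run_study <- function(seed, config = study_config()) {
  cc <- config
  profiles <- cc$phantom$profiles
  deltas <- vapply(profiles, function(p) p$min_visible_diameter, numeric(1))
  gold_name <- names(deltas)[which.min(deltas)]
  sub_seeds <- with_seed(seed, sample.int(1e8L, cc$n_phantoms))

  eval_rows <- list(); sweep_rows <- list(); equiv_rows <- list()
  plans <- list(); checks <- list()

  for (i in seq_len(cc$n_phantoms)) {
    ph <- make_phantom(sub_seeds[i], cc$phantom)
    gold <- truth_vessel_model(ph)
    models <- lapply(deltas, function(d) prune_by_diameter(gold, d))
    sulci <- if (cc$use_sulci)
      extract_sulcal_model(ph$gm_mask, ph$intracranial_mask, 5) else NULL

    phplans <- list()
    for (nm in names(models)) {
      critical <- c(list(models[[nm]]), if (!is.null(sulci)) list(sulci))
      pl <- plan_electrodes(ph, critical, constraints = cc$constraints,
                            cfg = cc$cfg, electrode = cc$electrode,
                            weights = cc$weights,
                            n_candidates = cc$n_candidates,
                            seed = sub_seeds[i] + match(nm, names(models)))
      attr(pl, "critical_model") <- critical
      phplans[[nm]] <- pl
      apparent <- recompute_plan_metrics(pl, models[[nm]], sulci, cc$cfg)
      true <- recompute_plan_metrics(pl, models[[gold_name]], sulci, cc$cfg)
      eval_rows[[length(eval_rows) + 1]] <- data.frame(
        phantom = i, arm = "nested", planning_model = nm,
        evaluation_model = nm, threshold = NA_real_,
        electrode = apparent$electrode, rs = apparent$rs, md = apparent$md,
        kind = "apparent")
      eval_rows[[length(eval_rows) + 1]] <- data.frame(
        phantom = i, arm = "nested", planning_model = nm,
        evaluation_model = gold_name, threshold = NA_real_,
        electrode = true$electrode, rs = true$rs, md = true$md,
        kind = "true")
    }
    plans[[i]] <- phplans
    checks[[i]] <- check_plan(phplans[[gold_name]],
                              c(list(models[[gold_name]]),
                                if (!is.null(sulci)) list(sulci)),
                              cc$constraints)
    sw <- diameter_sweep(phplans[[gold_name]], gold, cc$prune_thresholds,
                         cc$cfg)
    sweep_rows[[length(sweep_rows) + 1]] <- cbind(phantom = i, sw)

    if (cc$imaged_arm) {
      # one extraction threshold for all modalities of a phantom (identical
      # acquisition contrast), so surface offsets do not differ by modality
      vgold <- apply_intracranial_mask(
        sato_vesselness(ph$modality_images[[gold_name]]),
        ph$intracranial_mask)
      thr <- otsu_threshold(vgold)
      iso <- 0.5 * median(ph$modality_images[[gold_name]]$data[
        vgold$data >= thr & ph$intracranial_mask$data > 0.5])
      imeshes <- lapply(names(profiles), function(nm) {
        if (nm == gold_name)
          segment_from_vesselness(ph$modality_images[[nm]], vgold,
                                  ph$intracranial_mask, thr, iso)
        else
          segment_vessel_model(ph$modality_images[[nm]], ph$intracranial_mask,
                               threshold = thr, surface_iso = iso)
      })
      names(imeshes) <- names(profiles)
      # two pruning bases for the segmented gold mesh: ground-truth radii
      # (membership matches the visibility cutoff exactly; isolates noise)
      # and centerline-measured radii with partial-volume correction (the
      # fully image-driven readout, which carries measurement bias)
      igold_truth <- imeshes[[gold_name]]
      igold_truth$vertex_radius <- pmax(tree_vertex_radii(igold_truth,
                                                          ph$tree), 0.05)
      igold_meas <- extract_centerline_radii(imeshes[[gold_name]], ph$grid)
      igold_meas <- deblur_radii(igold_meas,
                                 profiles[[gold_name]]$blur_sigma)
      ref_plan <- phplans[[gold_name]]
      for (nm in names(profiles)) {
        d <- deltas[[nm]]
        if (d <= 0) next
        m_delta <- recompute_plan_metrics(ref_plan, imeshes[[nm]],
                                          cfg = cc$cfg)
        pr_t <- remove_small_components(prune_by_diameter(igold_truth, d), 30)
        pr_m <- remove_small_components(prune_by_diameter(igold_meas, d), 30)
        m_pt <- recompute_plan_metrics(ref_plan, pr_t, cfg = cc$cfg)
        m_pm <- recompute_plan_metrics(ref_plan, pr_m, cfg = cc$cfg)
        equiv_rows[[length(equiv_rows) + 1]] <- data.frame(
          phantom = i, delta = d, electrode = m_delta$electrode,
          rs_delta = m_delta$rs, md_delta = m_delta$md,
          rs_pruned = m_pt$rs, md_pruned = m_pt$md,
          rs_pruned_meas = m_pm$rs, md_pruned_meas = m_pm$md)
      }
    }
  }

  evaluation <- do.call(rbind, eval_rows)
  sweep <- do.call(rbind, sweep_rows)
  equivalence <- if (length(equiv_rows)) do.call(rbind, equiv_rows) else NULL

  # paired comparisons: true RS of degraded-model plans vs gold-model plans
  true_rs <- function(nm) {
    sub <- evaluation[evaluation$kind == "true" &
                        evaluation$planning_model == nm, ]
    sub <- sub[order(sub$phantom, sub$electrode), ]
    sub$rs
  }
  degraded <- setdiff(names(deltas), gold_name)
  stats_list <- lapply(degraded, function(nm)
    paired_compare(true_rs(nm), true_rs(gold_name),
                   label = paste0("true RS: plan on ", nm, " vs ", gold_name),
                   n_comparisons = 3))
  names(stats_list) <- degraded

  equiv_tests <- NULL
  if (!is.null(equivalence)) {
    equiv_tests <- lapply(sort(unique(equivalence$delta)), function(d) {
      sub <- equivalence[equivalence$delta == d, ]
      list(delta = d,
           rs = paired_compare(sub$rs_delta, sub$rs_pruned,
                               label = sprintf("RS equivalence at %g mm", d),
                               n_comparisons = 3),
           md = paired_compare(sub$md_delta, sub$md_pruned,
                               label = sprintf("MD equivalence at %g mm", d),
                               n_comparisons = 3),
           rs_measured = paired_compare(
             sub$rs_delta, sub$rs_pruned_meas,
             label = sprintf("RS equivalence at %g mm (measured radii)", d),
             n_comparisons = 3),
           md_measured = paired_compare(
             sub$md_delta, sub$md_pruned_meas,
             label = sprintf("MD equivalence at %g mm (measured radii)", d),
             n_comparisons = 3))
    })
  }

  # apparent-vs-true correlation per visibility cutoff
  r2 <- do.call(rbind, lapply(names(deltas), function(nm) {
    app <- evaluation[evaluation$kind == "apparent" &
                        evaluation$planning_model == nm, ]
    tru <- evaluation[evaluation$kind == "true" &
                        evaluation$planning_model == nm, ]
    app <- app[order(app$phantom, app$electrode), ]
    tru <- tru[order(tru$phantom, tru$electrode), ]
    data.frame(model = nm, delta = deltas[[nm]],
               r2 = if (sd(app$rs) == 0 || sd(tru$rs) == 0) NA_real_
               else pearson_r2(app$rs, tru$rs))
  }))

  structure(list(evaluation = evaluation, sweep = sweep,
                 equivalence = equivalence, plans = plans, checks = checks,
                 stats = stats_list, equivalence_tests = equiv_tests,
                 r2 = r2, config = cc, seed = seed,
                 gold_model = gold_name, deltas = deltas),
            class = "seeg_study")
}

#' @export
print.seeg_study <- function(x, ...) {
  cat("<seeg_study> ", x$config$n_phantoms, " phantoms, ",
      length(x$plans[[1]]), " models, seed ", x$seed, "\n", sep = "")
  cat("R^2(apparent, true) by visibility cutoff:\n")
  print(x$r2, row.names = FALSE)
  invisible(x)
}
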