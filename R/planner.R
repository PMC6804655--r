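#' Electrode specification
#'
#' Generic depth-electrode geometry; any manufacturer's electrode fits by
#' supplying its dimensions.
#'
#' @param diameter shaft diameter mm.
#' @param n_contacts number of contacts.
#' @param contact_length mm per contact.
#' @param contact_spacing center-to-center spacing mm.
#' @export
electrode_spec <- function(diameter = 1.3, n_contacts = 10,
                           contact_length = 2.4, contact_spacing = 5) {
  stopifnot(diameter > 0, n_contacts > 0, contact_length > 0,
            contact_spacing > 0)
  structure(list(diameter = diameter, n_contacts = n_contacts,
                 contact_length = contact_length,
                 contact_spacing = contact_spacing),
            class = "electrode_spec")
}

#' Risk-score configuration
#'
#' The two distance constants of the cumulative risk score: beyond
#' `safety_distance` (10 mm) a node contributes nothing; any node within
#' `margin` (3 mm) switches the trajectory into the high-risk regime.
#'
#' @param safety_distance mm, default 10.
#' @param margin mm, default 3; must be below `safety_distance`.
#' @param n_nodes nodes sampled along a trajectory, default 128.
#' @export
risk_config <- function(safety_distance = 10, margin = 3, n_nodes = 128) {
  if (!(safety_distance > margin && margin > 0))
    stop("risk_config: need safety_distance > margin > 0")
  structure(list(safety_distance = safety_distance, margin = margin,
                 n_nodes = as.integer(n_nodes)), class = "risk_config")
}

#' Hard constraints of the plan search
#'
#' @param max_length mm maximum entry-target length.
#' @param max_angle_to_normal degrees from the inward skull normal
#'   (drilling-angle limit).
#' @param min_target_margin mm clearance required of candidate target
#'   points, default 3.
#' @param min_pairwise mm minimum distance between trajectories in one
#'   plan, default 10.
#' @param entry_roi optional label of an entry region the trajectory must
#'   traverse.
#' @export
plan_constraints <- function(max_length = 90, max_angle_to_normal = 30,
                             min_target_margin = 3, min_pairwise = 10,
                             entry_roi = NULL) {
  stopifnot(max_length > 0, max_angle_to_normal > 0, min_target_margin > 0,
            min_pairwise > 0)
  structure(list(max_length = max_length,
                 max_angle_to_normal = max_angle_to_normal,
                 min_target_margin = min_target_margin,
                 min_pairwise = min_pairwise, entry_roi = entry_roi),
            class = "plan_constraints")
}

#' Straight electrode trajectory
#'
#' @param entry,target mm points.
#' @param electrode an [electrode_spec()].
#' @param n_nodes nodes sampled uniformly from entry to target (default
#'   128); `nodes[1]` is the entry and `nodes[n]` the target.
#' @export
trajectory <- function(entry, target, electrode = electrode_spec(),
                       n_nodes = 128) {
  entry <- as.numeric(entry); target <- as.numeric(target)
  s <- seq(0, 1, length.out = n_nodes)
  nodes <- cbind(entry[1] + s * (target[1] - entry[1]),
                 entry[2] + s * (target[2] - entry[2]),
                 entry[3] + s * (target[3] - entry[3]))
  structure(list(entry = entry, target = target, electrode = electrode,
                 nodes = nodes, n_nodes = as.integer(n_nodes)),
            class = "seeg_trajectory")
}

#' @export
print.seeg_trajectory <- function(x, ...) {
  cat("<trajectory> length ", signif(traj_length(x), 4), " mm, ",
      x$n_nodes, " nodes\n", sep = "")
  invisible(x)
}

traj_length <- function(t) sqrt(sum((t$target - t$entry)^2))

#' Node clearances of a trajectory from critical structures
#'
#' For each of the N sampled nodes: Euclidean distance to the nearest point
#' on any critical mesh, minus the electrode radius, floored at 0. The raw
#' (unfloored, surface-to-shaft) distances are attached as attribute
#' `"raw"`. An empty critical set yields `Inf` at every node.
#'
#' @param t a [trajectory()].
#' @param critical a `surface_mesh` or list of meshes.
#' @return numeric vector of length N (attribute `"raw"` holds the
#'   unfloored values).
#' @export
node_distances <- function(t, critical) {
  d <- point_mesh_distance(t$nodes, critical)
  raw <- d - t$electrode$diameter / 2
  out <- pmax(raw, 0)
  attr(out, "raw") <- raw
  out
}

#' Cumulative risk score of a trajectory
#'
#' Piecewise score over the N node clearances `Dist(i)`, with distances
#' clamped at the safety distance (10 mm) so far nodes contribute zero:
#' if every node keeps `Dist > 3`,
#' `RS = sum_i (10 - min(Dist(i), 10)) / (N * (10 - 3))`;
#' if any node comes within the 3 mm margin, the trajectory is scored in
#' the high-risk regime `RS = 1 + sum_{Dist(i) <= 3} (3 - Dist(i)) / (3 N)`.
#' The score is continuous at the 3 mm boundary and always lies in [0, 2]:
#' 0 when all nodes are at least 10 mm clear, 1 when uniformly at 3 mm,
#' 2 when the shaft touches a structure along its whole length.
#'
#' @param distances node clearances (mm), length `cfg$n_nodes`.
#' @param cfg a [risk_config()].
#' @export
risk_score <- function(distances, cfg = risk_config()) {
  n <- cfg$n_nodes
  if (length(distances) != n)
    stop(sprintf("risk_score: expected %d distances, got %d", n,
                 length(distances)))
  s <- cfg$safety_distance; m <- cfg$margin
  d <- pmin(distances, s)
  if (all(distances > m)) {
    sum(s - d) / (n * (s - m))
  } else {
    risky <- distances <= m
    1 + sum(m - distances[risky]) / (m * n)
  }
}

#' Minimum node distance of a trajectory
#' @param distances node distances from [node_distances()].
#' @export
min_distance <- function(distances) {
  if (!length(distances)) stop("min_distance: empty input")
  min(distances)
}

#' Full metric set of one trajectory
#'
#' @param t a [trajectory()].
#' @param critical list of critical meshes.
#' @param gm gray-matter `seeg_volume` (or NULL).
#' @param cfg a [risk_config()].
#' @param angle drilling angle (degrees) if known.
#' @return list: `rs`, `md` (mm, unfloored shaft clearance, so collision
#'   shows as negative down to minus the electrode radius), `length`,
#'   `angle`, `gm_ratio`, `collision`.
#' @export
trajectory_metrics <- function(t, critical, gm = NULL, cfg = risk_config(),
                               angle = NA_real_) {
  d <- node_distances(t, critical)
  raw <- attr(d, "raw")
  list(rs = risk_score(as.numeric(d), cfg),
       md = min(raw),
       length = traj_length(t),
       angle = angle,
       gm_ratio = if (is.null(gm)) NA_real_ else gm_contact_ratio(t, gm),
       collision = is.finite(min(raw)) && min(raw) <= 0)
}

#' Candidate target points inside an ROI with a safety margin
#'
#' Returns the ROI voxel centers whose distance to every critical mesh is at
#' least `margin` plus the electrode radius (so the margin is measured to
#' the electrode surface, not its axis).
#'
#' @param roi binary or label `seeg_volume` (nonzero voxels are the ROI).
#' @param critical list of `surface_mesh`.
#' @param margin mm safety margin (default 3).
#' @param electrode_radius mm added to the margin.
#' @return n x 3 matrix of mm points (0 rows, with a warning, if no
#'   candidate survives).
#' @export
sample_target_candidates <- function(roi, critical, margin = 3,
                                     electrode_radius = 0) {
  m <- roi$data > 0
  if (!any(m)) stop("sample_target_candidates: empty ROI")
  pts <- voxel_centers(roi, m)
  d <- point_mesh_distance(pts, critical)
  keep <- d >= margin + electrode_radius
  if (!any(keep)) warning("sample_target_candidates: no candidate target survives")
  pts[keep, , drop = FALSE]
}

#' Entry candidates on the skull surface
#'
#' Approximately uniform sampling of the skull mesh at the requested
#' spacing: a dense area-weighted random pool is thinned by farthest-point
#' sampling down to `round(area / spacing^2)` points. Each point carries the
#' outward unit normal of its source triangle.
#'
#' @param skull a `surface_mesh`.
#' @param spacing mm target spacing.
#' @return list: `points` (n x 3), `normals` (n x 3, outward, unit length).
#' @export
sample_entry_candidates <- function(skull, spacing = 5) {
  if (is_empty_mesh(skull)) stop("sample_entry_candidates: empty skull mesh")
  area <- mesh_area(skull)
  n <- max(1L, as.integer(round(area / spacing^2)))
  pool_n <- max(4L * n, 200L)
  a <- skull$vertices[skull$faces[, 1], , drop = FALSE]
  b <- skull$vertices[skull$faces[, 2], , drop = FALSE]
  cc <- skull$vertices[skull$faces[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  fa <- sqrt(rowSums(cr^2)) / 2
  fidx <- sample.int(nrow(skull$faces), pool_n, replace = TRUE,
                     prob = fa / sum(fa))
  r1 <- sqrt(runif(pool_n)); r2 <- runif(pool_n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  pool <- w1 * a[fidx, , drop = FALSE] + w2 * b[fidx, , drop = FALSE] +
    w3 * cc[fidx, , drop = FALSE]
  nrm <- face_normals(skull)[fidx, , drop = FALSE]
  ctr <- colMeans(skull$vertices)
  flip <- rowSums(nrm * sweep(pool, 2, ctr)) < 0
  nrm[flip, ] <- -nrm[flip, ]

  # farthest-point thinning
  sel <- integer(n)
  sel[1] <- 1L
  mind <- rowSums(sweep(pool, 2, pool[1, ])^2)
  if (n > 1) for (k in 2:n) {
    sel[k] <- which.max(mind)
    mind <- pmin(mind, rowSums(sweep(pool, 2, pool[sel[k], ])^2))
  }
  list(points = pool[sel, , drop = FALSE], normals = nrm[sel, , drop = FALSE])
}

# does segment entry->target pass through the nonzero part of `roi`?
traverses_roi <- function(entry, target, roi, step = 1) {
  len <- sqrt(sum((target - entry)^2))
  s <- seq(0, 1, length.out = max(2, ceiling(len / step)))
  pts <- cbind(entry[1] + s * (target[1] - entry[1]),
               entry[2] + s * (target[2] - entry[2]),
               entry[3] + s * (target[3] - entry[3]))
  any(lookup_volume(roi, pts, outside = 0) > 0)
}

#' Filter entry-target pairs by the hard constraints
#'
#' Survivors satisfy all of: intracerebral length within `max_length`, the
#' drilling angle (between the trajectory and the inward skull normal at
#' the entry) within `max_angle_to_normal`, traversal of the entry ROI when
#' one is specified, and no collision of the electrode cylinder with any
#' critical mesh.
#'
#' @param entries list from [sample_entry_candidates()].
#' @param targets n x 3 matrix of target points.
#' @param pairs 2-column matrix (entry index, target index); default all
#'   combinations.
#' @param constraints a [plan_constraints()].
#' @param critical list of critical meshes.
#' @param electrode an [electrode_spec()].
#' @param entry_roi optional `seeg_volume` the trajectory must traverse.
#' @return data.frame of survivors: entry/target indices, `length`, `angle`.
#' @export
filter_candidates <- function(entries, targets, pairs = NULL,
                              constraints = plan_constraints(),
                              critical = list(),
                              electrode = electrode_spec(),
                              entry_roi = NULL) {
  ne <- nrow(entries$points); nt <- nrow(targets)
  if (is.null(pairs))
    pairs <- cbind(rep(seq_len(ne), times = nt),
                   rep(seq_len(nt), each = ne))
  ep <- entries$points[pairs[, 1], , drop = FALSE]
  en <- entries$normals[pairs[, 1], , drop = FALSE]
  tp <- targets[pairs[, 2], , drop = FALSE]
  dvec <- tp - ep
  len <- sqrt(rowSums(dvec^2))
  dirn <- dvec / pmax(len, 1e-12)
  # drilling angle to the inward normal
  cosang <- rowSums(dirn * (-en))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  keep <- len <= constraints$max_length & ang <= constraints$max_angle_to_normal
  if (!is.null(entry_roi) && any(keep)) {
    ki <- which(keep)
    trav <- vapply(ki, function(i) traverses_roi(ep[i, ], tp[i, ], entry_roi),
                   logical(1))
    keep[ki] <- trav
  }
  if (any(keep) && length(critical)) {
    ki <- which(keep)
    hit <- segment_mesh_collides(ep[ki, , drop = FALSE],
                                 tp[ki, , drop = FALSE], critical,
                                 electrode$diameter / 2)
    keep[ki] <- !hit
  }
  data.frame(entry = pairs[keep, 1], target = pairs[keep, 2],
             length = len[keep], angle = ang[keep])
}

#' Fraction of electrode contacts inside gray matter
#'
#' Contacts are placed from the target backwards along the shaft at the
#' specified spacing (the deepest contact centered on the target); contacts
#' extending beyond the entry count as outside.
#'
#' @param t a [trajectory()].
#' @param gm gray-matter binary `seeg_volume`.
#' @export
gm_contact_ratio <- function(t, gm) {
  sp <- t$electrode
  len <- traj_length(t)
  dirn <- (t$entry - t$target) / len
  offs <- (seq_len(sp$n_contacts) - 1) * sp$contact_spacing
  centers <- cbind(t$target[1] + offs * dirn[1],
                   t$target[2] + offs * dirn[2],
                   t$target[3] + offs * dirn[3])
  inside <- lookup_volume(gm, centers, outside = 0) > 0.5
  inside[offs > len] <- FALSE
  mean(inside)
}

#' Minimum distance between two trajectories (3-D segments)
#' @param t1,t2 [trajectory()] objects.
#' @export
trajectory_distance <- function(t1, t2) {
  cpp_seg_seg_dist(t1$entry, t1$target, t2$entry, t2$target)
}

candidate_cost <- function(rs, gm_ratio, len, max_length,
                           weights = plan_weights()) {
  gmr <- ifelse(is.na(gm_ratio), 0, gm_ratio)
  weights$rs * rs - weights$gm * gmr + weights$len * (len / max_length)
}

#' Cost weights of the per-plan optimization
#' @param rs weight on the risk score.
#' @param gm weight (reward) on the gray-matter contact ratio.
#' @param len weight on normalized trajectory length.
#' @export
plan_weights <- function(rs = 1, gm = 0.3, len = 0.1) {
  list(rs = rs, gm = gm, len = len)
}

#' Combine per-electrode candidates into a valid plan
#'
#' Greedy assignment in order of ascending candidate count with
#' backtracking: electrodes with the fewest options commit first; each
#' electrode takes its cheapest candidate compatible with all previous
#' choices (pairwise trajectory distance at least `min_pairwise`), undoing
#' earlier choices when an electrode runs out of options. Deterministic:
#' ties break by lower cost, then lexicographic candidate order.
#'
#' @param per_electrode_candidates named list; each element a list of
#'   candidates, each candidate a list with `trajectory` (a
#'   [trajectory()]) and `metrics` (from [trajectory_metrics()]).
#' @param constraints a [plan_constraints()].
#' @param weights a [plan_weights()].
#' @return object of class `seeg_plan`: `electrodes` (named list with
#'   `trajectory` and `metrics`) and the constraint set.
#' @export
optimize_plan <- function(per_electrode_candidates,
                          constraints = plan_constraints(),
                          weights = plan_weights()) {
  nm <- names(per_electrode_candidates)
  if (is.null(nm)) nm <- paste0("E", seq_along(per_electrode_candidates))
  counts <- vapply(per_electrode_candidates, length, integer(1))
  if (any(counts == 0))
    stop("optimize_plan: electrode '", nm[which(counts == 0)[1]],
         "' has no feasible candidate")
  ord <- order(counts, seq_along(counts))

  cand_sorted <- lapply(per_electrode_candidates, function(cands) {
    cost <- vapply(cands, function(cd)
      candidate_cost(cd$metrics$rs, cd$metrics$gm_ratio, cd$metrics$length,
                     constraints$max_length, weights), numeric(1))
    cands[order(cost)]
  })

  # all pairwise trajectory separations are precomputed once (a few
  # thousand segment pairs), so the combination searches below only do
  # table lookups
  k <- length(cand_sorted)
  sizes <- vapply(cand_sorted, length, integer(1))
  offs <- c(0L, cumsum(sizes))
  n_all <- sum(sizes)
  allt <- vector("list", n_all)
  for (e in seq_len(k))
    for (c in seq_len(sizes[e]))
      allt[[offs[e] + c]] <- cand_sorted[[e]][[c]]$trajectory
  compatible <- matrix(TRUE, n_all, n_all)
  for (a in seq_len(n_all - 1))
    for (b in (a + 1):n_all) {
      okp <- trajectory_distance(allt[[a]], allt[[b]]) >=
        constraints$min_pairwise
      compatible[a, b] <- okp
      compatible[b, a] <- okp
    }
  gi <- function(e, c) offs[e] + c

  # small instances: exhaustive search over all combinations, so the
  # returned plan is a true optimum of the summed cost
  if (prod(counts) <= 4096) {
    combos <- as.matrix(do.call(expand.grid, lapply(sizes, seq_len)))
    best_cost <- Inf; best_sel <- NULL
    for (r in seq_len(nrow(combos))) {
      idx <- vapply(seq_len(k), function(e) gi(e, combos[r, e]), integer(1))
      feasible <- TRUE
      if (k > 1) for (i in seq_len(k - 1)) {
        if (!all(compatible[idx[i], idx[(i + 1):k]])) { feasible <- FALSE; break }
      }
      if (!feasible) next
      sel <- lapply(seq_len(k), function(e) cand_sorted[[e]][[combos[r, e]]])
      cost <- sum(vapply(sel, function(cd)
        candidate_cost(cd$metrics$rs, cd$metrics$gm_ratio, cd$metrics$length,
                       constraints$max_length, weights), numeric(1)))
      if (cost < best_cost - 1e-12) { best_cost <- cost; best_sel <- sel }
    }
    if (is.null(best_sel))
      stop("optimize_plan: no compatible combination; electrode '",
           nm[ord[length(ord)]], "' cannot be placed")
    electrodes <- stats::setNames(best_sel, nm)
    return(structure(list(electrodes = electrodes, constraints = constraints,
                          weights = weights),
                     class = "seeg_plan"))
  }

  # larger instances: greedy value order (candidates are cost-sorted) under
  # forward-checking search with dynamic most-constrained-first electrode
  # ordering; domains shrink as assignments commit, so dead branches are
  # pruned before they are entered
  steps <- 0L
  solve <- function(domains, assigned) {
    steps <<- steps + 1L
    if (steps > 2e4L)
      stop("optimize_plan: combination search budget exhausted")
    un <- which(vapply(assigned, is.na, logical(1)))
    if (!length(un)) return(assigned)
    e <- un[which.min(vapply(domains[un], length, integer(1)))]
    if (!length(domains[[e]]))
      stop("optimize_plan: no compatible combination; electrode '",
           nm[e], "' cannot be placed")
    for (ci in domains[[e]]) {
      g <- gi(e, ci)
      nd <- domains
      dead <- FALSE
      for (e2 in setdiff(un, e)) {
        nd[[e2]] <- nd[[e2]][compatible[offs[e2] + nd[[e2]], g]]
        if (!length(nd[[e2]])) { dead <- TRUE; break }
      }
      if (dead) next
      a2 <- assigned
      a2[e] <- ci
      res <- tryCatch(solve(nd, a2), error = function(err) err)
      if (!inherits(res, "error")) return(res)
      if (grepl("budget", conditionMessage(res))) stop(res)
    }
    stop("optimize_plan: no compatible combination; electrode '",
         nm[e], "' cannot be placed")
  }
  assigned <- solve(lapply(sizes, seq_len), rep(NA_integer_, k))
  choice <- assigned
  ord <- seq_len(k)

  electrodes <- stats::setNames(vector("list", k), nm)
  for (q in seq_len(k))
    electrodes[[ord[q]]] <- cand_sorted[[ord[q]]][[choice[q]]]
  structure(list(electrodes = electrodes, constraints = constraints,
                 weights = weights),
            class = "seeg_plan")
}

#' @export
print.seeg_plan <- function(x, ...) {
  cat("<seeg_plan> ", length(x$electrodes), " electrodes; RS ",
      paste(signif(vapply(x$electrodes, function(e) e$metrics$rs, numeric(1)), 3),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plan metrics as a data.frame
#' @param plan a `seeg_plan`.
#' @export
plan_table <- function(plan) {
  do.call(rbind, lapply(names(plan$electrodes), function(nm) {
    e <- plan$electrodes[[nm]]
    data.frame(electrode = nm,
               entry_x = e$trajectory$entry[1], entry_y = e$trajectory$entry[2],
               entry_z = e$trajectory$entry[3],
               target_x = e$trajectory$target[1],
               target_y = e$trajectory$target[2],
               target_z = e$trajectory$target[3],
               rs = e$metrics$rs, md = e$metrics$md,
               length = e$metrics$length, angle = e$metrics$angle,
               gm_ratio = e$metrics$gm_ratio,
               collision = e$metrics$collision)
  }))
}

#' Independent validity check of a plan
#'
#' Re-verifies, from scratch and without reusing any cached metric: no
#' electrode collides with a critical structure, every target keeps the
#' margin, trajectories are pairwise separated, and length/angle limits
#' hold.
#'
#' @param plan a `seeg_plan`.
#' @param critical list of critical meshes.
#' @param constraints a [plan_constraints()].
#' @return list `ok` plus per-check logical fields.
#' @export
check_plan <- function(plan, critical, constraints = plan_constraints()) {
  el <- plan$electrodes
  coll <- vapply(el, function(e) {
    segment_mesh_collides(e$trajectory$entry, e$trajectory$target, critical,
                          e$trajectory$electrode$diameter / 2)
  }, logical(1))
  tmar <- vapply(el, function(e) {
    point_mesh_distance(rbind(e$trajectory$target), critical) >=
      constraints$min_target_margin
  }, logical(1))
  lenok <- vapply(el, function(e) traj_length(e$trajectory) <=
                    constraints$max_length, logical(1))
  n <- length(el)
  pair_ok <- TRUE
  min_pair <- Inf
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- trajectory_distance(el[[i]]$trajectory, el[[j]]$trajectory)
    min_pair <- min(min_pair, d)
    if (d < constraints$min_pairwise) pair_ok <- FALSE
  }
  list(ok = !any(coll) && all(tmar) && all(lenok) && pair_ok,
       no_collision = !any(coll), target_margin = all(tmar),
       length_ok = all(lenok), pairwise_ok = pair_ok,
       min_pairwise = min_pair)
}

#' Plan a multi-electrode implantation on a phantom
#'
#' The full planning pipeline against one critical-structure model:
#' entry sampling on the skull, per-ROI target candidates with the safety
#' margin, hard-constraint filtering of all entry-target combinations, a
#' fast distance-field pre-ranking of survivors, exact metrics for the best
#' `n_candidates` per electrode, and per-plan combination under the
#' pairwise-spacing constraint.
#'
#' @param phantom a `seeg_phantom`.
#' @param critical list of critical meshes (vessel model, optionally the
#'   sulcal model).
#' @param electrodes named integer vector mapping electrode names to target
#'   ROI labels; default one electrode per ROI.
#' @param constraints a [plan_constraints()].
#' @param cfg a [risk_config()].
#' @param electrode an [electrode_spec()].
#' @param weights a [plan_weights()].
#' @param entry_spacing mm skull sampling pitch.
#' @param n_candidates exact-stage candidates per electrode.
#' @param seed integer seed (entry sampling).
#' @return a `seeg_plan`; attribute `"n_pairs_prefilter"` counts the raw
#'   entry-by-target combinations considered.
#' @export
plan_electrodes <- function(phantom, critical,
                            electrodes = NULL,
                            constraints = plan_constraints(),
                            cfg = risk_config(),
                            electrode = electrode_spec(),
                            weights = plan_weights(),
                            entry_spacing = 5, n_candidates = 8, seed = 1) {
  if (is.null(electrodes)) {
    k <- max(phantom$target_rois$data)
    electrodes <- stats::setNames(seq_len(k), paste0("E", seq_len(k)))
  }
  entries <- with_seed(seed, sample_entry_candidates(phantom$skull_mesh,
                                                     entry_spacing))
  # fast clearance field: EDT to the voxelized critical surfaces
  dfield <- critical_distance_field(critical, phantom$grid)

  n_pairs <- 0
  cand <- list()
  for (nm in names(electrodes)) {
    lab <- electrodes[[nm]]
    roi <- phantom$target_rois
    roi$data <- (roi$data == lab) * 1
    targets <- sample_target_candidates(roi, critical,
                                        margin = constraints$min_target_margin,
                                        electrode_radius = electrode$diameter / 2)
    if (nrow(targets) == 0)
      stop("plan_electrodes: no target candidates for electrode '", nm, "'")
    n_pairs <- n_pairs + nrow(entries$points) * nrow(targets)
    # conservative entry prescreen: an entry whose angle to the ROI centroid
    # exceeds the drilling limit by more than the worst-case spread across
    # the ROI cannot serve any target in it
    tc <- colMeans(targets)
    dvec <- matrix(tc, nrow(entries$points), 3, byrow = TRUE) - entries$points
    dl <- sqrt(rowSums(dvec^2))
    cosang <- rowSums(dvec / pmax(dl, 1e-12) * (-entries$normals))
    ang_c <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    spread <- max(sqrt(rowSums(sweep(targets, 2, tc)^2)))
    slack <- asin(pmin(spread / pmax(min(dl), 1e-6), 1)) * 180 / pi
    ekeep <- which(ang_c <= constraints$max_angle_to_normal + slack + 1)
    if (!length(ekeep)) ekeep <- seq_len(nrow(entries$points))
    pairs <- cbind(rep(ekeep, times = nrow(targets)),
                   rep(seq_len(nrow(targets)), each = length(ekeep)))
    surv <- filter_candidates(entries, targets, pairs = pairs,
                              constraints = constraints,
                              critical = list(), electrode = electrode)
    if (nrow(surv) == 0)
      stop("plan_electrodes: no trajectory satisfies the geometric constraints for '",
           nm, "'")
    # distance-field pre-ranking (approximate RS on sparsely sampled nodes);
    # stride-subsample very large survivor sets first
    if (nrow(surv) > 30000) {
      stride <- ceiling(nrow(surv) / 30000)
      surv <- surv[seq(1, nrow(surv), by = stride), , drop = FALSE]
    }
    ep <- entries$points[surv$entry, , drop = FALSE]
    tp <- targets[surv$target, , drop = FALSE]
    approx <- approx_risk(ep, tp, dfield, electrode, cfg)
    clear <- approx$clear
    if (!any(clear)) clear <- approx$mins > 0  # drop the safety buffer
    surv <- surv[clear, , drop = FALSE]
    rs_a <- approx$rs[clear]
    if (nrow(surv) == 0)
      stop("plan_electrodes: every candidate for '", nm,
           "' grazes a critical structure")
    ord <- order(rs_a, surv$length)
    # diversify by entry point so the plan combiner has real alternatives
    sel <- integer(0)
    for (i in ord) {
      if (length(sel) >= n_candidates * 3L) break
      epi <- entries$points[surv$entry[i], ]
      tpi <- targets[surv$target[i], ]
      if (length(sel)) {
        prev_e <- entries$points[surv$entry[sel], , drop = FALSE]
        prev_t <- targets[surv$target[sel], , drop = FALSE]
        sep_e <- min(sqrt(rowSums(sweep(prev_e, 2, epi)^2)))
        sep_t <- min(sqrt(rowSums(sweep(prev_t, 2, tpi)^2)))
        if (sep_e < 4 && sep_t < 2.5) next
      }
      sel <- c(sel, i)
    }
    if (length(sel) < n_candidates)
      sel <- unique(c(sel, head(ord, n_candidates * 3L)))
    take <- sel
    # exact stage: collision then metrics
    ep <- entries$points[surv$entry[take], , drop = FALSE]
    tp <- targets[surv$target[take], , drop = FALSE]
    hit <- segment_mesh_collides(ep, tp, critical, electrode$diameter / 2)
    ok <- which(!hit)
    if (!length(ok))
      stop("plan_electrodes: all pre-ranked candidates for '", nm,
           "' collide with a critical structure")
    cand[[nm]] <- lapply(ok, function(i)
      list(entry = ep[i, ], target = tp[i, ], angle = surv$angle[take[i]]))
  }
  # exact metrics are computed lazily: the cheap head slice first, the full
  # collision-free pool only if the pairwise spacing cannot be satisfied
  with_metrics <- function(cands) lapply(cands, function(cd) {
    tr <- trajectory(cd$entry, cd$target, electrode, cfg$n_nodes)
    list(trajectory = tr,
         metrics = trajectory_metrics(tr, critical, phantom$gm_mask, cfg,
                                      angle = cd$angle))
  })
  plan <- tryCatch(
    optimize_plan(lapply(cand, function(x) with_metrics(head(x, n_candidates))),
                  constraints, weights),
    error = function(e) optimize_plan(lapply(cand, with_metrics),
                                      constraints, weights))
  attr(plan, "n_pairs_prefilter") <- n_pairs
  plan
}

# EDT-based clearance field (mm to nearest critical surface voxel)
critical_distance_field <- function(critical, grid) {
  meshes <- if (inherits(critical, "surface_mesh")) list(critical) else critical
  surf <- array(FALSE, grid$dim)
  for (m in meshes) {
    if (is_empty_mesh(m)) next
    surf <- surf | array(cpp_voxelize_surface(m$vertices, m$faces, grid$dim,
                                              grid$voxdim, grid$origin),
                         grid$dim)
  }
  if (!any(surf)) return(NULL)
  new_volume(array(cpp_edt3d(surf, grid$dim, grid$voxdim), grid$dim),
             grid$voxdim, grid$origin)
}

# vectorized approximate risk over many segments via the clearance field
approx_risk <- function(ep, tp, dfield, electrode, cfg, n_nodes = 16) {
  n <- nrow(ep)
  if (is.null(dfield))
    return(list(rs = rep(0, n), clear = rep(TRUE, n)))
  s <- seq(0, 1, length.out = n_nodes)
  rs <- numeric(n); clear <- logical(n)
  pts <- matrix(0, n * n_nodes, 3)
  for (a in 1:3)
    pts[, a] <- rep(ep[, a], each = n_nodes) +
      rep(s, times = n) * (rep(tp[, a], each = n_nodes) - rep(ep[, a], each = n_nodes))
  dv <- sample_volume(dfield, pts, outside = cfg$safety_distance) -
    electrode$diameter / 2
  dm <- matrix(dv, nrow = n_nodes)
  sset <- cfg$safety_distance; mm <- cfg$margin
  mins <- apply(dm, 2, min)
  clear <- mins > 0.5  # keep a half-voxel buffer before the exact check
  dcl <- pmin(dm, sset)
  safe_rs <- colSums(sset - dcl) / (n_nodes * (sset - mm))
  risky_pen <- colSums((mm - dm) * (dm <= mm)) / (mm * n_nodes)
  rs <- ifelse(mins > mm, safe_rs, 1 + risky_pen)
  list(rs = rs, clear = clear, mins = mins)
}
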