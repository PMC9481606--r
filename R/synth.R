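# Seeded synthetic-data generators.  These stand in for the molecular
# dynamics the full method consumes: labelled two-state descriptor data for
# CV training, and water trajectories with planted long-lived "reservoir"
# molecules inside a protein-like hull plus transient bulk waters.

#' Two labelled Gaussian descriptor clouds
#'
#' Emulates descriptor data collected from unbiased runs in the bound (B)
#' and unbound (U) states: `n_per_state` draws per state from multivariate
#' normals with the requested means and covariances.  The default dimension
#' is 18, mirroring a (G, H, V_1..V_16) water-coordination descriptor set.
#'
#' @param n_per_state samples per state
#' @param mean_B,mean_U state means (length `dim`); defaults separate the
#'   states along the first axis
#' @param cov_B,cov_U symmetric positive-definite covariances (default
#'   identity)
#' @param dim descriptor dimension (used only when means are defaulted)
#' @param seed integer seed
#' @return data.frame with a `state` factor (`"B"`/`"U"`) and descriptor
#'   columns `d1..ddim`
#' @export
synth_two_state_descriptors <- function(n_per_state, mean_B = NULL,
                                        mean_U = NULL, cov_B = NULL,
                                        cov_U = NULL, dim = 18L,
                                        seed = 1L) {
  if (is.null(mean_B)) mean_B <- c(2, rep(0, dim - 1L))
  if (is.null(mean_U)) mean_U <- c(-2, rep(0, dim - 1L))
  if (length(mean_B) != length(mean_U)) stop("mean dimensions differ",
                                             call. = FALSE)
  d <- length(mean_B)
  cov_B <- cov_B %||% diag(d)
  cov_U <- cov_U %||% diag(d)
  for (S in list(cov_B, cov_U)) {
    if (!isSymmetric(unname(S), tol = 1e-8) ||
        min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("covariances must be symmetric positive-definite", call. = FALSE)
    }
    if (nrow(S) != d) stop("covariance dimension mismatch", call. = FALSE)
  }
  X <- with_seed(derive_seed(seed, 1L), {
    rbind(MASS::mvrnorm(n_per_state, mean_B, cov_B),
          MASS::mvrnorm(n_per_state, mean_U, cov_U))
  })
  out <- as.data.frame(X)
  names(out) <- paste0("d", seq_len(d))
  out <- cbind(state = factor(rep(c("B", "U"), each = n_per_state)), out)
  out
}

#' Deterministic protein-like anchor envelope
#'
#' A Fibonacci-sphere point set of pseudo alpha-carbons, usable as the
#' anchor set of a convex hull enclosing a binding region.
#'
#' @param n number of anchors
#' @param radius envelope radius (Angstrom)
#' @param center centre of the envelope
#' @return `n x 3` matrix
#' @export
anchor_envelope <- function(n = 30L, radius = 12, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + radius * sin(phi) * cos(theta),
        center[2] + radius * sin(phi) * sin(theta),
        center[3] + radius * cos(phi))
}

#' Specify a synthetic water scene
#'
#' Defines a trajectory containing planted long-lived waters jittering
#' around fixed interior spots (teleport-swapping identity with a bulk
#' water when their lifetime expires) plus bulk waters random-walking
#' outside the hull with brief scripted incursions.
#'
#' @param anchor_points hull anchors (default [anchor_envelope()])
#' @param planted_spots `k x 3` matrix of spot centres (default: 5 spots
#'   with mutual spacing >= 4 Angstrom, well inside the default envelope)
#' @param lifetimes per-spot occupant lifetime (ps); must exceed
#'   `filter_threshold`
#' @param n_bulk_waters transient bulk waters
#' @param box full box lengths (Angstrom), centred on the origin
#' @param frame_interval trajectory spacing (ps)
#' @param n_frames frames
#' @param seed integer seed
#' @param jitter_sd Gaussian jitter of planted occupants (Angstrom)
#' @param bulk_incursion_max maximal duration of a bulk incursion (ps);
#'   kept strictly below `filter_threshold`
#' @param filter_threshold the residence filter (ps) the planted waters are
#'   meant to pass and the bulk waters to fail
#' @return object of class `water_scene_spec`
#' @export
water_scene_spec <- function(anchor_points = anchor_envelope(),
                             planted_spots = NULL, lifetimes = 500,
                             n_bulk_waters = 30L, box = c(40, 40, 40),
                             frame_interval = 10, n_frames = 50L,
                             seed = 1L, jitter_sd = 0.5,
                             bulk_incursion_max = 30,
                             filter_threshold = 100) {
  if (is.null(planted_spots)) {
    planted_spots <- rbind(c(0, 0, 0), c(5, 0, 0), c(-2.5, 4.5, 0),
                           c(0, -3, 4.5), c(-2, -1, -5))
  }
  planted_spots <- as.matrix(planted_spots)
  k <- nrow(planted_spots)
  lifetimes <- rep_len(lifetimes, k)
  if (any(lifetimes <= filter_threshold)) {
    stop("planted lifetimes must exceed the filter threshold",
         call. = FALSE)
  }
  if (bulk_incursion_max >= filter_threshold) {
    stop("bulk incursions must stay below the filter threshold",
         call. = FALSE)
  }
  hull <- build_hull(anchor_points)
  if (!all(hull_contains(hull, planted_spots, tol = -1e-6))) {
    stop("every planted spot must lie strictly inside the anchor hull",
         call. = FALSE)
  }
  structure(list(anchor_points = as.matrix(anchor_points),
                 planted_spots = planted_spots, lifetimes = lifetimes,
                 n_bulk_waters = as.integer(n_bulk_waters), box = box,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), seed = seed,
                 jitter_sd = jitter_sd,
                 bulk_incursion_max = bulk_incursion_max,
                 filter_threshold = filter_threshold, hull = hull),
            class = "water_scene_spec")
}

#' Generate a synthetic water trajectory
#'
#' Planted occupants jitter around their spot centre (resampled until the
#' position stays inside the hull) for their stated lifetime, then swap
#' identity with a randomly chosen bulk water; bulk waters random-walk in
#' the box outside the hull, with brief scripted incursions shorter than
#' the residence filter.  The generator is bitwise reproducible under a
#' fixed seed.
#'
#' @param scene a [water_scene_spec()]
#' @return list with `frames` (list of `n_waters x 3` matrices; waters
#'   `1..k` start as spot occupants), `scene`, `hull`, and `truth` (planted
#'   spot centres, the per-frame occupant of each spot, and the scripted
#'   incursion table)
#' @export
synth_water_scene <- function(scene) {
  stopifnot(inherits(scene, "water_scene_spec"))
  k <- nrow(scene$planted_spots)
  nb <- scene$n_bulk_waters
  nw <- k + nb
  nf <- scene$n_frames
  hull <- scene$hull
  half <- scene$box / 2
  with_seed(derive_seed(scene$seed, 2L), {
    draw_outside <- function() {
      repeat {
        p <- runif(3, -half, half)
        if (!hull_contains(hull, p)) return(p)
      }
    }
    draw_near <- function(center, sd) {
      repeat {
        p <- center + rnorm(3, 0, sd)
        if (hull_contains(hull, p)) return(p)
      }
    }
    pos <- matrix(0, nw, 3)
    for (s in seq_len(k)) pos[s, ] <- draw_near(scene$planted_spots[s, ],
                                                scene$jitter_sd)
    for (b in seq_len(nb)) pos[k + b, ] <- draw_outside()
    occupant <- seq_len(k)            # water id currently at each spot
    entry_frame <- rep(1L, k)
    life_frames <- pmax(1L, round(scene$lifetimes / scene$frame_interval))
    # scripted bulk incursions: ~30% of bulk waters make one brief visit
    max_in_frames <- max(0L, floor(scene$bulk_incursion_max /
                                     scene$frame_interval))
    incursions <- data.frame(water_id = integer(0), start = integer(0),
                             len = integer(0))
    if (max_in_frames > 0L && nf > 4L) {
      for (b in seq_len(nb)) {
        if (runif(1) < 0.3) {
          len <- sample.int(max_in_frames, 1L)
          start <- sample.int(max(1L, nf - len - 1L), 1L) + 1L
          incursions <- rbind(incursions, data.frame(
            water_id = k + b, start = start, len = len))
        }
      }
    }
    interior_pt <- colMeans(scene$planted_spots)
    occupant_trace <- matrix(0L, nf, k)
    frames <- vector("list", nf)
    for (f in seq_len(nf)) {
      if (f > 1L) {
        # planted occupants jitter, bulk waters walk
        for (s in seq_len(k)) {
          pos[occupant[s], ] <- draw_near(scene$planted_spots[s, ],
                                          scene$jitter_sd)
        }
        for (wid in setdiff(seq_len(nw), occupant)) {
          inc <- incursions[incursions$water_id == wid, ]
          if (nrow(inc) == 1L && f >= inc$start &&
              f < inc$start + inc$len) {
            pos[wid, ] <- draw_near(interior_pt, 1.0)
          } else {
            cand <- pos[wid, ] + rnorm(3, 0, 1.0)
            cand <- pmin(pmax(cand, -half), half)
            if (hull_contains(hull, cand)) cand <- draw_outside()
            pos[wid, ] <- cand
          }
        }
        # lifetime bookkeeping: swap identity with a bulk water
        for (s in seq_len(k)) {
          if (f - entry_frame[s] >= life_frames[s]) {
            bulk_ids <- setdiff(seq_len(nw), occupant)
            if (length(bulk_ids) == 0L) next
            new_id <- bulk_ids[sample.int(length(bulk_ids), 1L)]
            old_id <- occupant[s]
            tmp <- pos[new_id, ]
            pos[new_id, ] <- pos[old_id, ]
            pos[old_id, ] <- tmp
            occupant[s] <- new_id
            entry_frame[s] <- f
          }
        }
      }
      occupant_trace[f, ] <- occupant
      frames[[f]] <- pos
    }
    list(frames = frames, scene = scene, hull = hull,
         truth = list(spot_centers = scene$planted_spots,
                      occupant = occupant_trace,
                      incursions = incursions,
                      lifetimes = scene$lifetimes))
  })
}

#' Write a water scene to disk (XYZ trajectory + anchor PDB)
#'
#' @param ws output of [synth_water_scene()]
#' @param traj_path XYZ trajectory path (water oxygens, element `O`)
#' @param anchors_path PDB path for the anchor pseudo alpha-carbons
#' @export
write_water_scene <- function(ws, traj_path, anchors_path) {
  write_xyz(ws$frames, traj_path,
            names = rep("O", nrow(ws$frames[[1]])),
            comment = sprintf("frame interval %g ps",
                              ws$scene$frame_interval))
  write_ca_pdb(ws$scene$anchor_points, anchors_path)
  invisible(ws)
}
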