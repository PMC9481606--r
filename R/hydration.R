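# Long-lived hydration spots: the four-step method.
#   1. select anchor (alpha-carbon) atoms enclosing the region of interest,
#   2. build their convex hull,
#   3. collect positions of waters resident inside the hull longer than a
#      lifetime threshold (default 100 ps),
#   4. cluster the pooled positions with K-means; the centres are the
#      hydration spots, chosen so their spacing falls in a 2-3 A band.

#' Track water residences inside a hull
#'
#' Computes, per water, the contiguous intervals of frames spent inside the
#' hull (closed containment; a single-frame exit splits the interval) and
#' keeps the intervals whose duration exceeds the lifetime threshold.
#'
#' @param trajectory list of `n_waters x 3` coordinate matrices (one per
#'   frame, consistent row order = persistent water identity), or the
#'   `frames` element of [synth_water_scene()] output
#' @param hull a [build_hull()] region
#' @param frame_interval time between frames (ps)
#' @param lifetime_threshold minimal residence duration (ps, exclusive);
#'   the four-step method uses 100 ps
#' @return list with `records` (data.frame: `water_id`, `entry_frame`,
#'   `exit_frame`, `duration`) and `pooled` (matrix of all positions stored
#'   during the retained residences)
#' @export
track_residences <- function(trajectory, hull, frame_interval,
                             lifetime_threshold = 100) {
  if (is.list(trajectory) && !is.null(trajectory$frames)) {
    trajectory <- trajectory$frames
  }
  n_frames <- length(trajectory)
  if (n_frames == 0L) stop("trajectory has zero frames", call. = FALSE)
  assert_scalar_pos(frame_interval, "frame_interval")
  n_w <- nrow(trajectory[[1]])
  inside <- vapply(trajectory, function(fr) hull_contains(hull, fr),
                   logical(n_w))                      # n_w x n_frames
  if (n_w == 1L) inside <- matrix(inside, nrow = 1L)
  recs <- list()
  pooled <- list()
  for (w in seq_len(n_w)) {
    r <- rle(inside[w, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      duration <- (ends[i] - starts[i]) * frame_interval
      if (duration > lifetime_threshold) {
        recs[[length(recs) + 1L]] <- data.frame(
          water_id = w, entry_frame = starts[i], exit_frame = ends[i],
          duration = duration)
        pos <- t(vapply(starts[i]:ends[i],
                        function(f) trajectory[[f]][w, ], numeric(3)))
        pooled[[length(pooled) + 1L]] <- pos
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(water_id = integer(0), entry_frame = integer(0),
               exit_frame = integer(0), duration = numeric(0))
  list(records = records,
       pooled = if (length(pooled)) do.call(rbind, pooled) else
         matrix(numeric(0), 0, 3))
}

# minimum pairwise and maximum nearest-neighbour distance between centres
.spacing_stats <- function(centers) {
  k <- nrow(centers)
  if (k < 2L) return(list(min_pair = Inf, max_nn = Inf))
  D <- as.matrix(dist(centers))
  diag(D) <- Inf
  list(min_pair = min(D), max_nn = max(apply(D, 1L, min)))
}

#' Cluster pooled long-lived water positions into hydration spots
#'
#' K-means with multiple restarts under a fixed seed.  With `k = "auto"`
#' the cluster count is swept upward from 1 and the largest `k` is kept
#' whose minimum inter-centre distance stays at or above the lower edge of
#' the spacing band (the "centres 2-3 Angstrom apart" rule); both the
#' minimum pairwise and the maximum nearest-neighbour spacing are reported.
#'
#' @param pooled_positions `n x 3` matrix from [track_residences()]
#' @param k integer cluster count, or `"auto"`
#' @param spacing_band numeric length 2 (Angstrom), the target band for
#'   inter-centre spacing used by the auto rule
#' @param seed seed for the K-means restarts
#' @param n_restarts K-means restarts
#' @param k_max upper bound of the auto sweep
#' @return object of class `hydration_spots`: `centers`, `k`,
#'   `min_pair_distance`, `max_nearest_neighbor_distance`, `member_counts`,
#'   `spacing_band`, `in_band` flags
#' @export
cluster_spots <- function(pooled_positions, k = "auto",
                          spacing_band = c(2, 3), seed = 1L,
                          n_restarts = 10L, k_max = 30L) {
  X <- as.matrix(pooled_positions)
  if (nrow(X) == 0L) stop("no pooled positions to cluster", call. = FALSE)
  run_k <- function(kk) {
    with_seed(derive_seed(seed, kk), {
      if (kk == 1L) {
        list(centers = matrix(colMeans(X), 1L), size = nrow(X))
      } else {
        km <- kmeans(X, centers = kk, nstart = n_restarts, iter.max = 100L)
        list(centers = km$centers, size = km$size)
      }
    })
  }
  if (identical(k, "auto")) {
    chosen <- run_k(1L); chosen_k <- 1L
    upper <- min(k_max, nrow(unique(X)))
    for (kk in seq.int(2L, max(2L, upper))) {
      if (kk > upper) break
      cand <- run_k(kk)
      st <- .spacing_stats(cand$centers)
      if (st$min_pair < spacing_band[1]) break
      chosen <- cand; chosen_k <- kk
    }
  } else {
    k <- as.integer(k)
    if (nrow(X) < k) stop("fewer points than clusters", call. = FALSE)
    chosen <- run_k(k); chosen_k <- k
  }
  st <- .spacing_stats(chosen$centers)
  centers <- unname(as.matrix(chosen$centers))
  structure(list(centers = centers, k = chosen_k,
                 min_pair_distance = st$min_pair,
                 max_nearest_neighbor_distance = st$max_nn,
                 member_counts = chosen$size,
                 spacing_band = spacing_band,
                 in_band = c(min_pair = st$min_pair >= spacing_band[1] &&
                               st$min_pair <= spacing_band[2],
                             max_nn = st$max_nn >= spacing_band[1] &&
                               st$max_nn <= spacing_band[2])),
            class = "hydration_spots")
}

#' @export
print.hydration_spots <- function(x, ...) {
  cat("<hydration_spots> k = ", x$k,
      ", min pair distance = ", signif(x$min_pair_distance, 4),
      " A, max nearest-neighbour = ",
      signif(x$max_nearest_neighbor_distance, 4), " A\n", sep = "")
  invisible(x)
}

#' Smooth coordination number around a centre
#'
#' Rational switching count of water oxygens,
#' `sum_j (1 - (r_j/r0)^n) / (1 - (r_j/r0)^m)`, with the removable
#' singularity at `r_j = r0` taking its limit `n/m`.  The functional form is
#' the standard rational switching used by enhanced-sampling engines; the
#' defaults `(n, m, r0) = (6, 12, 3.5 A)` are a package choice (see the
#' methods vignette).
#'
#' @param center numeric length-3 centre
#' @param oxygen_positions `n x 3` matrix of water oxygen coordinates (may
#'   have zero rows: the sum is then 0)
#' @param r0 switching radius (Angstrom)
#' @param n,m switching exponents, `n < m`
#' @return numeric coordination number
#' @export
coordination <- function(center, oxygen_positions, r0 = 3.5, n = 6L,
                         m = 12L) {
  assert_scalar_pos(r0, "r0")
  if (n >= m) stop("'n' must be smaller than 'm'", call. = FALSE)
  X <- as.matrix(oxygen_positions)
  if (nrow(X) == 0L) return(0)
  r <- sqrt(rowSums(sweep(X, 2, center)^2))
  x <- r / r0
  out <- numeric(length(x))
  at_one <- abs(x - 1) < 1e-9
  out[at_one] <- n / m
  xs <- x[!at_one]
  out[!at_one] <- (1 - xs^n) / (1 - xs^m)
  sum(out)
}

#' Define the water-descriptor configuration
#'
#' The descriptor vector of a frame is
#' `d = (G, H, V_1, ..., V_k)`: the water coordination of the ligand anchor
#' atom (amidine-carbon analogue), of the binding-site anchor atom
#' (carboxylate-carbon analogue), and of each hydration spot.  Its length is
#' `2 + k` (18 in a configuration with 16 spots).
#'
#' @param ligand_atom,site_atom atom selectors: either a length-3 coordinate
#'   (fixed anchor) or a single row index into the frame coordinate matrix
#' @param spots a [cluster_spots()] object
#' @param r0,n,m switching parameters passed to [coordination()]
#' @return object of class `descriptor_spec`
#' @export
descriptor_spec <- function(ligand_atom, site_atom, spots, r0 = 3.5,
                            n = 6L, m = 12L) {
  stopifnot(inherits(spots, "hydration_spots"))
  assert_scalar_pos(r0, "r0")
  if (n >= m) stop("'n' must be smaller than 'm'", call. = FALSE)
  structure(list(ligand_atom = ligand_atom, site_atom = site_atom,
                 spots = spots, r0 = r0, n = n, m = m,
                 names = c("G", "H", paste0("V", seq_len(spots$k)))),
            class = "descriptor_spec")
}

.resolve_atom <- function(sel, frame) {
  if (length(sel) == 3L && is.numeric(sel)) return(as.numeric(sel))
  if (length(sel) == 1L && is.numeric(sel)) {
    if (sel < 1 || sel > nrow(frame)) {
      stop("atom selector index out of range", call. = FALSE)
    }
    return(frame[sel, ])
  }
  stop("atom selector must be a coordinate triple or a row index",
       call. = FALSE)
}

#' Evaluate the water-descriptor vector for one frame
#'
#' @param waters `n x 3` matrix of water oxygen positions in the frame
#' @param spec a [descriptor_spec()]
#' @param frame optional full coordinate matrix, required when the spec's
#'   atom selectors are row indices
#' @return named numeric vector `(G, H, V_1 ... V_k)` of length `2 + k`;
#'   invariant under permutation of the water rows
#' @export
descriptor_vector <- function(waters, spec, frame = NULL) {
  stopifnot(inherits(spec, "descriptor_spec"))
  waters <- as.matrix(waters)
  lig <- .resolve_atom(spec$ligand_atom, frame)
  sit <- .resolve_atom(spec$site_atom, frame)
  vals <- c(
    coordination(lig, waters, spec$r0, spec$n, spec$m),
    coordination(sit, waters, spec$r0, spec$n, spec$m),
    vapply(seq_len(spec$spots$k), function(i) {
      coordination(spec$spots$centers[i, ], waters, spec$r0, spec$n, spec$m)
    }, numeric(1)))
  setNames(vals, spec$names)
}

#' Write hydration spots as PDB pseudo-atoms plus a JSON summary
#'
#' @param spots a [cluster_spots()] object
#' @param prefix output path prefix; writes `<prefix>.pdb` (HETATM pseudo
#'   atoms) and `<prefix>.json` (centres and spacing statistics)
#' @export
write_spots <- function(spots, prefix) {
  stopifnot(inherits(spots, "hydration_spots"))
  pdb_path <- paste0(prefix, ".pdb")
  con <- file(pdb_path, "w")
  for (i in seq_len(spots$k)) {
    writeLines(sprintf(
      "HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
      i, i, spots$centers[i, 1], spots$centers[i, 2], spots$centers[i, 3]),
      con)
  }
  writeLines("END", con)
  close(con)
  jsonlite::write_json(
    list(k = spots$k, centers = spots$centers,
         min_pair_distance = spots$min_pair_distance,
         max_nearest_neighbor_distance =
           spots$max_nearest_neighbor_distance,
         member_counts = spots$member_counts,
         spacing_band = spots$spacing_band),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Emit an equivalent PLUMED coordination stanza (text only)
#'
#' Generates the text of PLUMED `COORDINATION` actions matching a
#' descriptor spec, for users who want to evaluate the same descriptors in
#' an MD engine.
#'
#' @param spec a [descriptor_spec()]
#' @param water_group PLUMED group label for the water oxygens
#' @return character vector of PLUMED input lines
#' @export
plumed_stanza <- function(spec, water_group = "water_O") {
  sw <- sprintf("SWITCH={RATIONAL R_0=%.3f NN=%d MM=%d}", spec$r0,
                as.integer(spec$n), as.integer(spec$m))
  c("# water coordination descriptors (G, H, V_i)",
    sprintf("G: COORDINATION GROUPA=ligand_anchor GROUPB=%s %s",
            water_group, sw),
    sprintf("H: COORDINATION GROUPA=site_anchor GROUPB=%s %s",
            water_group, sw),
    vapply(seq_len(spec$spots$k), function(i) {
      sprintf("V%d: COORDINATION GROUPA=spot%d GROUPB=%s %s", i, i,
              water_group, sw)
    }, character(1)))
}
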