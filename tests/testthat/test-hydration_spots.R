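# The four-step trapped-water method: hull, residence filter, clustering,
# coordination descriptors.

test_that("convex hull has exact volume and closed containment", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  h <- build_hull(tet)
  expect_equal(h$volume, 1 / 6, tolerance = 1e-12)
  expect_true(hull_contains(h, colMeans(tet)))
  expect_true(all(hull_contains(h, tet)))            # boundary is inside
  expect_true(hull_contains(h, c(0.5, 0.5, 0)))      # face point
  expect_false(hull_contains(h, c(0.5, 0.5, 0.5)))
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(build_hull(cube)$volume, 1, tolerance = 1e-12)
  expect_error(build_hull(cbind(runif(5), runif(5), 0)), "degenerate")
  expect_error(build_hull(tet[1:3, ]), "at least 4")
})

test_that("containment agrees with the brute-force half-space oracle", {
  env <- anchor_envelope(30, 12)
  h <- build_hull(env)
  set.seed(22)
  pts <- matrix(runif(3000, -15, 15), ncol = 3)
  fast <- hull_contains(h, pts)
  oracle <- apply(pts, 1, function(p) {
    all(h$normals %*% p - h$offsets <= 1e-7)
  })
  expect_equal(mean(fast == oracle), 1)
})

test_that("residence bookkeeping is exact on a hand-built micro-trajectory", {
  box <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  h <- build_hull(box)
  inside <- c(0, 0, 0); outside <- c(5, 5, 5)
  # water 1: in, out for one frame, in again -> two separate intervals
  # water 2: inside the whole time
  traj <- list(
    rbind(inside, inside), rbind(inside, inside), rbind(outside, inside),
    rbind(inside, inside), rbind(inside, inside))
  res <- track_residences(traj, h, frame_interval = 10,
                          lifetime_threshold = 5)
  r1 <- res$records[res$records$water_id == 1, ]
  expect_equal(nrow(r1), 2L)
  expect_equal(r1$duration, c(10, 10))        # (2-1)*10 and (5-4)*10
  r2 <- res$records[res$records$water_id == 2, ]
  expect_equal(r2$duration, 40)               # (5-1)*10
  # a stricter threshold drops the split intervals but keeps water 2
  res2 <- track_residences(traj, h, 10, lifetime_threshold = 15)
  expect_equal(res2$records$water_id, 2)
  expect_error(track_residences(list(), h, 10), "zero frames")
})

test_that("the residence filter keeps exactly the planted waters", {
  ws <- synth_water_scene(water_scene_spec(seed = 30))
  res <- track_residences(ws$frames, ws$hull, frame_interval = 10,
                          lifetime_threshold = 100)
  expect_equal(nrow(res$records), 5L)
  expect_setequal(res$records$water_id, 1:5)
  res600 <- track_residences(ws$frames, ws$hull, 10,
                             lifetime_threshold = 600)
  expect_equal(nrow(res600$records), 0L)
  # all pooled positions are inside the hull
  expect_true(all(hull_contains(ws$hull, res$pooled)))
})

test_that("k-means spots recover the planted centres", {
  ws <- synth_water_scene(water_scene_spec(seed = 33))
  res <- track_residences(ws$frames, ws$hull, 10, 100)
  sp <- cluster_spots(res$pooled, k = 5, seed = 2)
  truth <- ws$truth$spot_centers
  D <- as.matrix(dist(rbind(sp$centers, truth)))
  D <- D[1:5, 5 + 1:5]
  expect_lt(sqrt(mean(apply(D, 2, min)^2)), 0.5)
  # k = 1 is the centroid
  sp1 <- cluster_spots(res$pooled, k = 1, seed = 2)
  expect_equal(sp1$centers[1, ], unname(colMeans(res$pooled)),
               tolerance = 1e-12)
  expect_error(cluster_spots(res$pooled[1:3, ], k = 5), "fewer points")
  expect_error(cluster_spots(res$pooled[0, , drop = FALSE], k = 1),
               "no pooled")
  expect_identical(cluster_spots(res$pooled, k = 5, seed = 2)$centers,
                   sp$centers)
})

test_that("auto-k matches an exhaustive sweep against the spacing rule", {
  ws <- synth_water_scene(water_scene_spec(seed = 35))
  pooled <- track_residences(ws$frames, ws$hull, 10, 100)$pooled
  band <- c(2, 3)
  sp <- cluster_spots(pooled, k = "auto", spacing_band = band, seed = 7)
  expect_gte(sp$min_pair_distance, band[1])
  # oracle: largest k whose min inter-centre spacing stays >= band lower
  # bound, k swept exhaustively with the same seeds
  ok <- integer(0)
  for (kk in 1:8) {
    cand <- cluster_spots(pooled, k = kk, seed = 7)
    if (cand$min_pair_distance >= band[1]) ok <- c(ok, kk) else break
  }
  expect_equal(sp$k, max(ok))
  expect_equal(sp$k, 5L)   # the planted scene has 5 well-separated spots
})

test_that("coordination has the switching limits and stays smooth at r0", {
  expect_equal(coordination(c(0, 0, 0), matrix(numeric(0), 0, 3)), 0)
  expect_equal(coordination(c(0, 0, 0), matrix(c(3.5, 0, 0), 1)), 0.5)
  near <- matrix(rnorm(9, 0, 0.02), 3)
  expect_equal(coordination(c(0, 0, 0), near), 3, tolerance = 1e-4)
  # finite-difference continuity across the removable singularity
  r <- seq(3.5 - 1e-3, 3.5 + 1e-3, length.out = 201)
  v <- sapply(r, function(ri) coordination(c(0, 0, 0),
                                           matrix(c(ri, 0, 0), 1)))
  expect_lt(max(abs(diff(v))), 1e-4)
  expect_error(coordination(c(0, 0, 0), near, n = 12, m = 6), "smaller")
})

test_that("descriptor vectors have length 2 + k and permutation symmetry", {
  ws <- synth_water_scene(water_scene_spec(seed = 33))
  pooled <- track_residences(ws$frames, ws$hull, 10, 100)$pooled
  sp <- cluster_spots(pooled, k = 5, seed = 2)
  spec <- descriptor_spec(c(0, 0, 8), c(0, 0, -8), sp)
  waters <- ws$frames[[7]]
  d <- descriptor_vector(waters, spec)
  expect_length(d, 2 + 5)
  expect_named(d, c("G", "H", paste0("V", 1:5)))
  set.seed(1)
  expect_equal(descriptor_vector(waters[sample(nrow(waters)), ], spec), d)
  expect_equal(descriptor_vector(matrix(numeric(0), 0, 3), spec),
               setNames(rep(0, 7), names(d)))
  # a 16-spot configuration gives the 18-component descriptor set
  sp16 <- sp; sp16$k <- 16L
  sp16$centers <- matrix(rnorm(48), 16)
  d16 <- descriptor_vector(waters, descriptor_spec(c(0, 0, 8), c(0, 0, -8),
                                                   sp16))
  expect_length(d16, 18)
})

test_that("spots serialise to PDB pseudo-atoms plus JSON", {
  ws <- synth_water_scene(water_scene_spec(seed = 33))
  pooled <- track_residences(ws$frames, ws$hull, 10, 100)$pooled
  sp <- cluster_spots(pooled, k = 5, seed = 2)
  prefix <- tempfile()
  write_spots(sp, prefix)
  at <- read_structure(paste0(prefix, ".pdb"))
  expect_equal(nrow(at), 5)
  expect_equal(unname(as.matrix(at[, c("x", "y", "z")])), sp$centers,
               tolerance = 1e-3)
  js <- jsonlite::fromJSON(paste0(prefix, ".json"))
  expect_equal(js$k, 5)
  stanza <- plumed_stanza(descriptor_spec(c(0, 0, 8), c(0, 0, -8), sp))
  expect_true(any(grepl("COORDINATION", stanza)))
  expect_length(grep("^V", stanza), 5)
})
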