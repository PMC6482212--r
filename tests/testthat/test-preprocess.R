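# Superposition, box scaling, target scaling and the TR/TE split.

test_that("self-superposition is the identity with zero RMSD", {
  a <- matrix(runif(30), 10, 3)
  s <- kabsch_superpose(a, a)
  expect_equal(s$rotation, diag(3), tolerance = 1e-10)
  expect_equal(s$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(s$rmsd_after, 1e-12)
  expect_lt(max(abs(crossprod(s$rotation) - diag(3))), 1e-10)
  expect_equal(det(s$rotation), 1, tolerance = 1e-10)
})

test_that("a pure rigid motion is removed exactly and inverted", {
  set.seed(7)
  target <- matrix(runif(24), 8, 3)
  rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)   # 90 deg about z
  mobile <- sweep(target %*% rz, 2, c(1, 0, 0), "+")
  s <- kabsch_superpose(mobile, target)
  expect_lt(s$rmsd_after, 1e-12)
  expect_equal(s$rotation, t(rz), tolerance = 1e-10)   # inverse of the motion
  expect_lt(max(abs(apply_superposition(s, mobile) - target)), 1e-10)
})

test_that("the minimised RMSD matches an independent rotation search", {
  set.seed(21)
  target <- matrix(runif(30), 10, 3)
  mobile <- random_rigid(target + matrix(rnorm(30, sd = 0.05), 10, 3))
  s <- kabsch_superpose(mobile, target)
  expect_lte(s$rmsd_after, rmsd_of(mobile, target))
  expect_equal(s$rmsd_after, grid_rmsd(mobile, target), tolerance = 1e-3)
  # cross-check against bio3d's least-squares rotation
  pc <- sweep(mobile, 2, colMeans(mobile))
  qc <- sweep(target, 2, colMeans(target))
  r_b <- bio3d::rot.lsq(as.vector(t(pc)), as.vector(t(qc)))
  fitted_b <- matrix(r_b, ncol = 3, byrow = TRUE)
  expect_equal(s$rmsd_after, sqrt(mean(rowSums((fitted_b - qc)^2))),
               tolerance = 1e-8)
})

test_that("superposition never increases RMSD (property sweep)", {
  for (sd_ in c(0.01, 0.1, 0.5)) {
    for (rep in 1:5) {
      set.seed(100 * sd_ + rep)
      target <- matrix(runif(18), 6, 3)
      mobile <- random_rigid(target + matrix(rnorm(18, sd = sd_), 6, 3))
      s <- kabsch_superpose(mobile, target)
      expect_lte(s$rmsd_after, rmsd_of(mobile, target) + 1e-12)
    }
  }
})

test_that("collinear point sets are flagged as degenerate", {
  line <- cbind(seq(0, 1, length.out = 5), 0, 0)
  expect_warning(kabsch_superpose(line, line + 0.01), "degenerate")
  expect_error(kabsch_superpose(matrix(0, 3, 3), matrix(0, 4, 3)), "equal N")
})

test_that("fit_and_scale reproduces the reference row and removes rigid motion", {
  ens <- tiny_cloud()
  ref <- ens$reference
  one <- structure(list(frame_count = 1L,
                        coords = array(ref$coords, c(1, ref$atom_count, 3)),
                        source_format = "synthetic"), class = "trajectory")
  x <- fit_and_scale(one, ref)
  expect_equal(dim(x), c(1L, 3L * ref$atom_count))
  expect_equal(x[1, ], as.vector(t(ref$coords)), tolerance = 1e-10)

  moved <- structure(list(frame_count = 1L,
                          coords = array(random_rigid(ref$coords),
                                         c(1, ref$atom_count, 3)),
                          source_format = "synthetic"), class = "trajectory")
  x2 <- fit_and_scale(moved, ref)
  expect_lt(max(abs(x2 - x)), 1e-8)
})

test_that("features are rotation-invariant and stay inside [0,1]", {
  ens <- tiny_cloud()
  x <- fit_and_scale(ens$trajectory, ens$reference)
  expect_true(all(x >= -1e-9 & x <= 1 + 1e-9))
  set.seed(5)
  moved <- ens$trajectory
  for (fr in seq_len(moved$frame_count)) {
    moved$coords[fr, , ] <- random_rigid(moved$coords[fr, , ])
  }
  expect_lt(max(abs(fit_and_scale(moved, ens$reference) - x)), 1e-8)
})

test_that("a frame the box cannot hold is an error naming frame, atom and axis", {
  ref_coords <- matrix(runif(15, 0.3, 0.7), 5, 3)
  ref <- structure(list(atom_count = 5L, atom_serials = 1:5,
                        coords = ref_coords, box = box_spec(1, 1, 1),
                        atom = NULL), class = "reference_structure")
  bad <- ref_coords
  bad[2, 2] <- 6.2   # fitted y far beyond ly
  traj <- structure(list(frame_count = 1L, coords = array(bad, c(1, 5, 3)),
                         source_format = "synthetic"), class = "trajectory")
  expect_error(fit_and_scale(traj, ref, nofit = TRUE),
               "box too small: frame 1, atom 2, axis y")
})

test_that("target scaling maps endpoints to [0,1] and inverts exactly", {
  ts <- scale_targets(c(2, 4, 6))
  expect_equal(ts$scaling$cv_min, 2)
  expect_equal(ts$scaling$cv_max, 6)
  expect_equal(ts$scaled, c(0, 0.5, 1))
  expect_equal(scale_targets(c(0, 1))$scaled, c(0, 1))
  v <- rnorm(50)
  ts2 <- scale_targets(v)
  expect_equal(unscale_targets(ts2$scaling, ts2$scaled), v, tolerance = 1e-12)
  expect_error(scale_targets(rep(3, 10)), "degenerate")
})

test_that("the TR/TE split honours fraction, floor, minimum and shuffling", {
  expect_equal(sum(split_dataset(10, 0.1, TRUE, 1) == "TE"), 1L)
  expect_equal(sum(split_dataset(8375, 0.1, TRUE, 1) == "TE"), 837L)
  expect_equal(sum(split_dataset(5, 0.01, TRUE, 1) == "TE"), 1L)  # min 1
  expect_equal(which(split_dataset(10, 0.2, shuffle = FALSE) == "TE"),
               c(9L, 10L))
  l1 <- split_dataset(200, 0.1, TRUE, seed = 33)
  expect_identical(l1, split_dataset(200, 0.1, TRUE, seed = 33))
  expect_false(identical(l1, split_dataset(200, 0.1, TRUE, seed = 34)))
  expect_true(all(l1 %in% c("TR", "TE")))
  expect_equal(length(l1), 200L)
  expect_error(split_dataset(100, 0), "between 0 and 1")
  expect_error(split_dataset(100, 1), "between 0 and 1")
})
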