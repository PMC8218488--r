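test_that("QT-RMSD clustering recovers planted binding modes", {
  dir <- withr::local_tempdir()
  one <- generate_toy_trajectory(10, dir = dir, two_state = FALSE, seed = 81)
  t1 <- load_trajectory(one$topology, one$coords, "resname LIG", "protein")
  a1 <- qt_rmsd_cluster(t1, cutoff = 2.0)
  expect_equal(a1$labels, rep(0L, 10))

  two <- generate_toy_trajectory(50, dir = dir, two_state = TRUE, seed = 82)
  t2 <- load_trajectory(two$topology, two$coords, "resname LIG", "protein")
  a2 <- qt_rmsd_cluster(t2, cutoff = 2.0)
  expect_equal(length(unique(a2$labels)), 2L)
  expect_true(all(a2$labels >= 0L))
  # clusters coincide with the planted poses (up to label swap)
  expect_equal(length(unique(a2$labels[two$pose == 0])), 1L)
  expect_equal(length(unique(a2$labels[two$pose == 1])), 1L)
})

test_that("QT-RMSD matches a per-pair recursive oracle on small trajectories", {
  dir <- withr::local_tempdir()
  for (seed in c(91, 92, 93)) {
    toy <- generate_toy_trajectory(8, dir = dir, two_state = (seed %% 2 == 0),
                                   jitter = 0.8, seed = seed)
    traj <- load_trajectory(toy$topology, toy$coords, "resname LIG", "protein")
    for (cutoff in c(0.5, 1.5, 3.0)) {
      got <- qt_rmsd_cluster(traj, cutoff = cutoff)$labels
      pidx <- bio3d::atom2xyz(traj$protein)
      fitted <- bio3d::fit.xyz(fixed = traj$xyz[1, ], mobile = traj$xyz,
                               fixed.inds = pidx, mobile.inds = pidx)
      want <- qt_oracle(fitted, traj$ligand, cutoff)
      expect_identical(got, want)
    }
  }
})

test_that("zero cutoff on distinct frames yields singletons; cluster cap leaves noise", {
  dir <- withr::local_tempdir()
  toy <- generate_toy_trajectory(6, dir = dir, jitter = 0.3, seed = 94)
  traj <- load_trajectory(toy$topology, toy$coords, "resname LIG", "protein")
  a <- qt_rmsd_cluster(traj, cutoff = 0)
  expect_equal(sort(a$labels), 0:5)

  two <- generate_toy_trajectory(10, dir = dir, two_state = TRUE, seed = 95)
  t2 <- load_trajectory(two$topology, two$coords, "resname LIG", "protein")
  capped <- qt_rmsd_cluster(t2, cutoff = 2.0, max_clusters = 1)
  expect_equal(sum(capped$labels == -1L), 5L)
})

test_that("size series counts frames per label with noise as singletons", {
  expect_equal(size_series(c(0L, 0L, 1L, -1L))$sizes, c(2L, 2L, 1L, 1L))
  expect_equal(size_series(rep(0L, 10))$sizes, rep(10L, 10))
  expect_equal(size_series(rep(c(0L, 1L), each = 5))$sizes, rep(5L, 10))
  # invariant under relabeling
  expect_equal(size_series(c(7L, 7L, 3L, -1L))$sizes, c(2L, 2L, 1L, 1L))
  # distinct cluster sizes plus noise count = T
  set.seed(96)
  labels <- sample(c(-1L, 0L, 1L, 2L), 40, replace = TRUE)
  sz <- size_series(labels)$sizes
  expect_equal(sum(unique(data.frame(labels, sz)[labels >= 0, ])$sz) +
                 sum(labels == -1L), 40L)
})

test_that("stability requires strictly more than the persistence threshold", {
  # 2500 frames x 20 ps = 50 ns exactly: not strictly longer
  expect_false(is_stable(size_series(rep(0L, 2500)), 20, 50))
  expect_true(is_stable(size_series(rep(0L, 3000)), 20, 50))
  expect_false(is_stable(size_series(seq_len(100) * 0 - 1), 20, 50))  # all noise
  expect_error(is_stable(size_series(rep(0L, 10)), 0, 50))
})

test_that("assignments round-trip through the frame,label CSV format", {
  a <- moietyrank:::new_cluster_assignment(c(0L, 1L, -1L, 0L), "latent")
  f <- withr::local_tempfile(fileext = ".csv")
  write_assignment(a, f)
  back <- read_assignment(f)
  expect_equal(back$labels, a$labels)
  expect_equal(back$source, "external")
})
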