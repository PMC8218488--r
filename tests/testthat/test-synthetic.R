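test_that("generation is seed-reproducible and shape-consistent", {
  spec <- synthetic_spec(T_ = 50, M = 20, seed = 121)
  a <- generate_contact_system(spec)
  b <- generate_contact_system(spec)
  expect_identical(a$contacts$values, b$contacts$values)
  expect_identical(a$reference$labels, b$reference$labels)
  expect_equal(dim(a$contacts$values), c(50L, 10L, 20L))
  expect_equal(a$malicious_subtypes, 2L)
  expect_equal(length(a$atom_to_subtype), 10L)
})

test_that("zero-rate stable blocks are time-constant with zero dynamism", {
  blocks <- data.frame(subtype_id = 0:1, n_atoms = 2L,
                       behavior = "stable", density = 0.4, rate = 0)
  sys <- generate_contact_system(synthetic_spec(T_ = 30, M = 15, blocks = blocks,
                                                seed = 122))
  dyn <- build_dynamism(sys$contacts, delta = 5)
  expect_true(all(dyn$values[, 2, , ] == 0L))
  expect_equal(length(unique(asplit(sys$contacts$values, 1))), 1L)
})

test_that("flicker flips the planted fraction of cells between consecutive frames", {
  blocks <- data.frame(subtype_id = 0L, n_atoms = 4L,
                       behavior = "flicker", density = 0.5, rate = 0.5)
  sys <- generate_contact_system(synthetic_spec(T_ = 400, M = 40, blocks = blocks,
                                                seed = 123))
  v <- sys$contacts$values
  frac <- mean(v[-1, , ] != v[-400, , ])
  expect_equal(frac, 0.5, tolerance = 0.02)     # binomial tolerance

  blocks$rate <- 0.1
  sys2 <- generate_contact_system(synthetic_spec(T_ = 400, M = 40, blocks = blocks,
                                                 seed = 124))
  v2 <- sys2$contacts$values
  expect_equal(mean(v2[-1, , ] != v2[-400, , ]), 0.1, tolerance = 0.02)
})

test_that("intermittent blocks alternate detached stretches and fresh episodes", {
  blocks <- data.frame(subtype_id = 0L, n_atoms = 2L,
                       behavior = "intermittent", density = 0.3, rate = 0.05)
  sys <- generate_contact_system(synthetic_spec(T_ = 600, M = 30, blocks = blocks,
                                                seed = 125))
  occ <- apply(sys$contacts$values, 1, sum)
  expect_true(any(occ == 0))                    # detached frames exist
  expect_true(any(occ > 0))                     # attached frames exist
  att <- which(occ > 0)
  pats <- unique(asplit(sys$contacts$values[att, , , drop = FALSE], 1))
  expect_gt(length(pats), 3)                    # several distinct episode patterns
})

test_that("switching blocks drive the whole-molecule regime labels", {
  blocks <- data.frame(subtype_id = 0:1, n_atoms = 2L,
                       behavior = c("stable", "switching"),
                       density = 0.3, rate = c(0, 0))
  sys <- generate_contact_system(synthetic_spec(T_ = 100, M = 20, blocks = blocks,
                                                switch_every = 25, seed = 126))
  expect_equal(unique(sys$reference$labels[1:25]), 0L)
  expect_equal(unique(sys$reference$labels[26:50]), 1L)
  expect_equal(sys$reference$labels[1:50], sys$reference$labels[51:100])
})

test_that("toy trajectories honor frame counts and planted pose geometry", {
  dir <- withr::local_tempdir()
  toy <- generate_toy_trajectory(5, dir = dir, two_state = TRUE, seed = 127)
  expect_equal(toy$pose, c(0L, 1L, 0L, 1L, 0L))
  traj <- load_trajectory(toy$topology, toy$coords, "resname LIG", "protein")
  expect_equal(n_frames(traj), 5L)
  # poses are > 5 A apart in ligand RMSD after protein superposition
  li <- bio3d::atom2xyz(traj$ligand)
  r <- bio3d::rmsd(traj$xyz[1, li], traj$xyz[2, li], fit = FALSE)
  expect_gt(r, 5)
})
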