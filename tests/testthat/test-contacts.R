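# hand-built two-frame trajectory with exact distances
exact_traj <- function() {
  # atom 1 (ligand) at origin; protein atoms at 3.0, 4.5 and 6.0 A along x
  xyz <- rbind(
    c(0, 0, 0,  3, 0, 0,  4.5, 0, 0,  6, 0, 0),
    c(0, 0, 0,  3, 0, 0,  4.5, 0, 0,  100, 0, 0)
  )
  atoms <- data.frame(name = c("C1", "CA", "CB", "CC"),
                      type = c("C1", "CA", "CB", "CC"),
                      resid = c("LIG", "ALA", "ALA", "ALA"),
                      resno = c(2L, 1L, 1L, 1L), chain = "A", segid = "")
  moietyrank:::new_trajectory(xyz, atoms, ligand = 1L, protein = 2:4)
}

test_that("contacts use a closed cutoff comparison", {
  cs <- compute_contact_series(exact_traj(), cutoff = 4.5)
  expect_equal(dim(cs$values), c(2L, 1L, 3L))
  expect_equal(cs$values[1, 1, ], c(1L, 1L, 0L))   # 3.0 in, 4.5 boundary in, 6.0 out
  expect_equal(cs$values[2, 1, ], c(1L, 1L, 0L))
})

test_that("contact series are monotone in cutoff", {
  toy <- generate_toy_trajectory(4, dir = withr::local_tempdir(), seed = 7)
  traj <- load_trajectory(toy$topology, toy$coords, "resname LIG", "protein")
  a <- compute_contact_series(traj, cutoff = 3.0)
  b <- compute_contact_series(traj, cutoff = 6.0)
  expect_true(all(a$values <= b$values))
})

test_that("permuting protein columns permutes contact columns identically", {
  traj <- exact_traj()
  perm <- c(3L, 1L, 2L)
  traj2 <- traj
  traj2$protein <- traj$protein[perm]
  a <- compute_contact_series(traj, 4.5)$values
  b <- compute_contact_series(traj2, 4.5)$values
  expect_equal(b[, , seq_along(perm)], a[, , perm])
})

test_that("subtype aggregation is logical OR over member rows", {
  set.seed(21)
  vals <- random_contacts(5, 4, 10)
  cs <- moietyrank:::new_contact_series(vals, cutoff = 4.5)
  map <- c(0L, 0L, 1L, 2L)

  both <- aggregate_by_subtype(cs, map, 0L)
  expect_equal(dim(both$values), c(5L, 1L, 10L))
  expect_equal(both$values[, 1, ], pmax(vals[, 1, ], vals[, 2, ]))

  single <- aggregate_by_subtype(cs, map, 1L)
  expect_equal(single$values[, 1, ], vals[, 3, ])   # one atom: identity

  zero <- moietyrank:::new_contact_series(array(0L, c(3, 2, 4)), 4.5)
  agg0 <- aggregate_by_subtype(zero, c(0L, 0L), 0L)
  expect_true(all(agg0$values == 0L))

  expect_error(aggregate_by_subtype(cs, map, 7L), "no ligand atoms")

  # OR-aggregated rows jointly cover every 1 of the original matrix
  cover <- Reduce(`+`, lapply(unique(map), function(s)
    aggregate_by_subtype(cs, map, s)$values[, 1, ]))
  expect_true(all((apply(vals, c(1, 3), max) == 1) == (cover >= 1)))
})

test_that("contact series round-trip through the array container + sidecar", {
  set.seed(22)
  cs <- moietyrank:::new_contact_series(random_contacts(4, 2, 6), cutoff = 4.0,
                                        ligand_labels = c("a", "b"),
                                        protein_labels = letters[1:6])
  path <- withr::local_tempfile(fileext = ".rds")
  write_contact_series(cs, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_contact_series(path)
  expect_equal(back$values, cs$values)
  expect_equal(back$cutoff, cs$cutoff)
  expect_equal(back$ligand_labels, cs$ligand_labels)
})
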