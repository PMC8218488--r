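toy_prm <- c(
  "* toy parameter file",
  "NONBONDED nbxmod 5 atom cdiel",
  "CG331    0.0  -0.0780  2.0500",
  "CG321    0.0  -0.0560  2.0100",
  "HGA3     0.0  -0.0240  1.3400",
  "OG311    0.0  -0.1921  1.7650",
  "END"
)

test_that("CHARMM nonbonded rows parse with sign and column conventions", {
  p <- parse_nonbonded_params(toy_prm)
  expect_equal(nrow(p), 4L)
  expect_equal(p$epsilon[p$type_name == "CG331"], 0.0780)
  expect_equal(p$size[p$type_name == "CG331"], 2.0500)
  expect_true(all(p$epsilon >= 0))

  expect_error(parse_nonbonded_params(c("BONDS", "CG331 0 -0.1 2.0")), "NONBONDED")
  expect_error(parse_nonbonded_params(c("NONBONDED", "CG331 0.0 abc 2.05")), "non-numeric")
  expect_warning(
    dup <- parse_nonbonded_params(c("NONBONDED", "X 0 -0.1 1.0", "X 0 -0.2 2.0")),
    "duplicate")
  expect_equal(dup$epsilon, 0.2)  # last wins
})

test_that("grouping follows pairwise 10% compatibility with transitive closure", {
  two_same <- tibble::tibble(type_name = c("A", "B"), epsilon = c(0.1, 0.1),
                             size = c(1.5, 1.5))
  expect_equal(length(group_subtypes(two_same)$members), 1L)

  far <- tibble::tibble(type_name = c("A", "B"), epsilon = c(0.1, 0.1),
                        size = c(1.0, 2.0))
  expect_equal(length(group_subtypes(far)$members), 2L)

  # 1.00 ~ 1.09 and 1.09 ~ 1.18 chain into one component even though
  # 1.00 vs 1.18 alone fails the 10% test
  chain <- tibble::tibble(type_name = c("A", "B", "C"), epsilon = 0.1,
                          size = c(1.00, 1.09, 1.18))
  expect_equal(length(group_subtypes(chain)$members), 1L)

  # zero-epsilon types pair with each other but not with nonzero epsilon
  zeros <- tibble::tibble(type_name = c("A", "B", "C"), epsilon = c(0, 0, 0.1),
                          size = 1.0)
  tab <- group_subtypes(zeros)
  expect_equal(tab$subtype_of[["A"]], tab$subtype_of[["B"]])
  expect_false(tab$subtype_of[["A"]] == tab$subtype_of[["C"]])
})

test_that("grouping equals a DFS connected-components oracle on random tables", {
  set.seed(401)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    params <- tibble::tibble(
      type_name = sprintf("T%02d", seq_len(n)),
      epsilon = round(stats::runif(n, 0, 0.3), 3),
      size = round(stats::runif(n, 1, 2.5), 3)
    )
    tol <- sample(c(0.05, 0.10, 0.25), 1)
    got <- group_subtypes(params, tol)$subtype_of[params$type_name]
    want <- cc_oracle(params, tol)
    expect_true(same_partition(unname(got), want))
  }
})

test_that("subtype count is monotone in tolerance and order-invariant", {
  set.seed(402)
  params <- tibble::tibble(
    type_name = sprintf("T%02d", 1:15),
    epsilon = round(stats::runif(15, 0, 0.3), 3),
    size = round(stats::runif(15, 1, 2.5), 3)
  )
  tols <- c(0, 0.05, 0.1, 0.2, 0.5, 2, 1e6)
  counts <- vapply(tols, function(tl) length(group_subtypes(params, tl)$members), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 15L)          # all parameters distinct at tol 0
  expect_equal(counts[length(counts)], 1L)

  perm <- params[sample(nrow(params)), ]
  a <- group_subtypes(params, 0.1)$subtype_of
  b <- group_subtypes(perm, 0.1)$subtype_of
  expect_equal(a[sort(names(a))], b[sort(names(b))])
})

test_that("ligand atoms map to subtypes through their force-field types", {
  toy <- generate_toy_trajectory(2, dir = withr::local_tempdir(), seed = 5)
  traj <- load_trajectory(toy$topology, toy$coords,
                          ligand_selection = "resname LIG",
                          protein_selection = "protein")
  types <- unique(traj$atoms$type[traj$ligand])
  params <- tibble::tibble(type_name = types,
                           epsilon = seq(0.05, by = 0.05, length.out = length(types)),
                           size = seq(1, by = 0.3, length.out = length(types)))
  tab <- group_subtypes(params, tolerance = 0)
  m <- map_ligand_atoms(traj, tab)
  expect_length(m, length(traj$ligand))
  # atoms sharing a type share a subtype
  expect_equal(length(unique(m[names(m) == types[1]])), 1L)

  tab2 <- group_subtypes(params[-1, ], tolerance = 0)
  expect_error(map_ligand_atoms(traj, tab2), types[1])
})
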