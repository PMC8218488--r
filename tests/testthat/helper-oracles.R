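# Independent oracles used across the suite. Each re-derives its quantity by
# the most literal route available (explicit loops, graph search, pairwise
# bio3d RMSD) so it shares no code path with the implementation it checks.

# explicit-summation metric oracles
brute_cos <- function(a, s) {
  num <- 0; da <- 0; ds <- 0
  for (t in seq_along(a)) {
    num <- num + a[t] * s[t]
    da <- da + a[t]^2
    ds <- ds + s[t]^2
  }
  num / (sqrt(da) * sqrt(ds))
}

brute_avg <- function(a, s) {
  acc <- 0
  for (t in seq_along(a)) acc <- acc + (a[t] - s[t])
  acc / length(a)
}

# connected components of the pairwise LJ-compatibility graph, by DFS over an
# explicitly built edge list
cc_oracle <- function(params, tolerance) {
  n <- nrow(params)
  pair_ok <- function(i, j) {
    abs(params$size[i] - params$size[j]) <= tolerance * max(params$size[i], params$size[j]) &&
      abs(params$epsilon[i] - params$epsilon[j]) <= tolerance * max(params$epsilon[i], params$epsilon[j])
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    stack <- start
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      for (u in seq_len(n)) if (is.na(comp[u]) && pair_ok(v, u)) stack <- c(stack, u)
    }
  }
  comp
}

# same-partition comparison, label-permutation invariant
same_partition <- function(a, b) {
  identical(as.integer(match(a, unique(a))), as.integer(match(b, unique(b))))
}

# greedy QT clustering re-derived with per-pair bio3d::rmsd calls on the raw
# (already superposed) coordinates; set semantics, no distance matrix reuse
qt_oracle <- function(xyz_fitted, ligand, cutoff) {
  T_ <- nrow(xyz_fitted)
  li <- bio3d::atom2xyz(ligand)
  prmsd <- function(i, j) {
    bio3d::rmsd(xyz_fitted[i, li], xyz_fitted[j, li], fit = FALSE)
  }
  labels <- rep(-1L, T_)
  remaining <- seq_len(T_)
  k <- 0L
  while (length(remaining) > 0L) {
    counts <- vapply(remaining, function(c0) {
      sum(vapply(remaining, function(j) prmsd(c0, j) <= cutoff + 1e-9, TRUE))
    }, 0L)
    center <- remaining[which.max(counts)]   # first max = lowest frame index
    members <- remaining[vapply(remaining, function(j) prmsd(center, j) <= cutoff + 1e-9, TRUE)]
    labels[members] <- k
    remaining <- setdiff(remaining, members)
    k <- k + 1L
  }
  labels
}

# small binary dynamism fixture helpers
random_contacts <- function(T_, N, M, p = 0.3) {
  array(stats::rbinom(T_ * N * M, 1L, p), dim = c(T_, N, M))
}
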