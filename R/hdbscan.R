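#' Hierarchical density-based clustering (HDBSCAN)
#'
#' Density clustering over a point cloud: core distances at `min_samples`
#' neighbors, mutual-reachability distances, a minimum spanning tree, the
#' condensed cluster tree at `min_cluster_size`, and excess-of-mass cluster
#' extraction. Points not assigned to any extracted cluster are labeled noise
#' (-1). Inputs smaller than `min_cluster_size` (or `min_samples`) cannot form
#' a cluster and come back all noise.
#'
#' Unlike some implementations this extraction allows the tree root itself to
#' be returned as a cluster by default (`allow_single_cluster = TRUE`):
#' conformational analysis of a stably bound molecule expects a single
#' dominant state, and discarding the root would mislabel a perfectly stable
#' trajectory as pure noise.
#'
#' @param X Numeric matrix, one row per observation.
#' @param min_cluster_size Smallest cluster size that may be returned (>= 2).
#' @param min_samples Neighborhood size for core distances; defaults to
#'   `min_cluster_size` (the common convention). The distance to the
#'   `min_samples`-th nearest neighbor counts the point itself.
#' @param allow_single_cluster Allow the root cluster as a result.
#' @return Integer vector of labels, `-1` for noise, clusters numbered from 0.
#' @export
hdbscan <- function(X, min_cluster_size = 50, min_samples = NULL,
                    allow_single_cluster = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(min_cluster_size >= 2)
  if (is.null(min_samples)) min_samples <- min_cluster_size
  if (n < min_cluster_size || n < min_samples || n < 2L) {
    return(rep(-1L, n))
  }
  D <- as.matrix(stats::dist(X))
  core <- apply(D, 1L, function(r) sort(r, partial = min_samples)[min_samples])
  MR <- pmax(D, outer(core, rep(1, n)), outer(rep(1, n), core))

  ## ---- minimum spanning tree over mutual reachability (Prim) ----
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  best <- MR[1L, ]
  best_from <- rep(1L, n)
  e_from <- integer(n - 1L); e_to <- integer(n - 1L); e_w <- numeric(n - 1L)
  cand <- best; cand[1L] <- Inf
  for (k in seq_len(n - 1L)) {
    j <- which.min(cand)
    e_from[k] <- best_from[j]; e_to[k] <- j; e_w[k] <- best[j]
    in_tree[j] <- TRUE
    cand[j] <- Inf
    upd <- which(!in_tree & MR[j, ] < best)
    best[upd] <- MR[j, upd]
    best_from[upd] <- j
    cand[upd] <- best[upd]
  }

  ## ---- single-linkage dendrogram via union-find over sorted edges ----
  ord <- order(e_w)
  parent <- seq_len(2L * n - 1L)           # union-find over points + internal nodes
  find <- function(v) {
    while (parent[v] != v) v <- parent[v]
    v
  }
  node_of <- seq_len(n)                    # component root -> dendrogram node id
  n_size <- c(rep(1L, n), integer(n - 1L))
  n_left <- integer(n - 1L); n_right <- integer(n - 1L); n_dist <- numeric(n - 1L)
  nxt <- n
  for (k in ord) {
    ra <- find(e_from[k]); rb <- find(e_to[k])
    na_ <- node_of[ra]; nb <- node_of[rb]
    nxt <- nxt + 1L
    n_left[nxt - n] <- na_; n_right[nxt - n] <- nb
    n_dist[nxt - n] <- e_w[k]
    n_size[nxt] <- n_size[na_] + n_size[nb]
    parent[ra] <- nxt; parent[rb] <- nxt
    parent[nxt] <- nxt
    node_of[nxt] <- nxt
  }
  root <- 2L * n - 1L
  lam <- function(d) 1 / pmax(d, 1e-12)

  points_under <- function(v) {
    out <- integer(0); stack <- v
    while (length(stack) > 0L) {
      u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (u <= n) out <- c(out, u)
      else stack <- c(stack, n_left[u - n], n_right[u - n])
    }
    out
  }

  ## ---- condensed tree ----
  max_cl <- n
  cl_parent <- integer(max_cl); cl_birth <- numeric(max_cl)
  cl_stab <- numeric(max_cl); cl_children <- vector("list", max_cl)
  K <- 1L
  cl_parent[1L] <- 0L; cl_birth[1L] <- 0
  pt_cluster <- integer(n); pt_lambda <- numeric(n)
  stack <- list(c(root, 1L))
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- fr[1L]; cc <- fr[2L]
    if (v <= n) {                           # bare point as a cluster root: falls out immediately
      pt_cluster[v] <- cc; pt_lambda[v] <- Inf
      next
    }
    l <- n_left[v - n]; r <- n_right[v - n]
    lv <- lam(n_dist[v - n])
    sl <- n_size[l]; sr <- n_size[r]
    big_l <- sl >= min_cluster_size; big_r <- sr >= min_cluster_size
    if (big_l && big_r) {
      cl_stab[cc] <- cl_stab[cc] + (sl + sr) * (lv - cl_birth[cc])
      for (ch in list(l, r)) {
        K <- K + 1L
        cl_parent[K] <- cc; cl_birth[K] <- lv
        cl_children[[cc]] <- c(cl_children[[cc]], K)
        stack[[length(stack) + 1L]] <- c(ch, K)
      }
    } else if (big_l || big_r) {
      small <- if (big_l) r else l
      big <- if (big_l) l else r
      ssmall <- n_size[small]
      cl_stab[cc] <- cl_stab[cc] + ssmall * (lv - cl_birth[cc])
      pts <- points_under(small)
      pt_cluster[pts] <- cc; pt_lambda[pts] <- lv
      stack[[length(stack) + 1L]] <- c(big, cc)
    } else {
      cl_stab[cc] <- cl_stab[cc] + (sl + sr) * (lv - cl_birth[cc])
      pts <- points_under(v)
      pt_cluster[pts] <- cc; pt_lambda[pts] <- lv
    }
  }

  ## ---- excess-of-mass extraction ----
  sel <- logical(K); total <- numeric(K)
  deselect_descendants <- function(cc) {
    for (ch in cl_children[[cc]]) {
      sel[ch] <<- FALSE
      deselect_descendants(ch)
    }
  }
  for (cc in rev(seq_len(K))) {
    kids <- cl_children[[cc]]
    if (length(kids) == 0L) {
      sel[cc] <- TRUE; total[cc] <- cl_stab[cc]
    } else {
      cs <- sum(total[kids])
      if (cl_stab[cc] > cs && (cc != 1L || allow_single_cluster)) {
        sel[cc] <- TRUE; total[cc] <- cl_stab[cc]
        deselect_descendants(cc)
      } else {
        sel[cc] <- FALSE; total[cc] <- cs
      }
    }
  }
  if (!allow_single_cluster) sel[1L] <- FALSE

  ## ---- labels ----
  sel_ids <- which(sel)
  label_of_cluster <- rep(-1L, K)
  label_of_cluster[sel_ids] <- seq_along(sel_ids) - 1L
  labels <- rep(-1L, n)
  for (p in seq_len(n)) {
    cc <- pt_cluster[p]
    while (cc != 0L) {
      if (sel[cc]) { labels[p] <- label_of_cluster[cc]; break }
      cc <- cl_parent[cc]
    }
  }
  labels
}
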