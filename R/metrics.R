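#' Cosine similarity between two cluster-size series
#'
#' `sum(A*S) / (sqrt(sum(A^2)) * sqrt(sum(S^2)))`. For positive size series
#' the value lies in (0, 1]; values near 1 mean the per-frame stability
#' profile of the subtype tracks the whole-molecule reference.
#'
#' @param A,S Numeric vectors of equal length (cluster-size series), or
#'   `cluster_size_series` objects.
#' @return A single number.
#' @export
cosine_similarity <- function(A, S) {
  A <- as_sizes(A); S <- as_sizes(S)
  if (length(A) != length(S)) {
    stop("series lengths differ (", length(A), " vs ", length(S), ")", call. = FALSE)
  }
  if (all(A == 0) || all(S == 0)) {
    stop("cosine similarity undefined for an all-zero series", call. = FALSE)
  }
  sum(A * S) / (sqrt(sum(A^2)) * sqrt(sum(S^2)))
}

#' Average difference between two cluster-size series
#'
#' `sum(A - S) / T`, in frames. Negative values mean the subtype sits in
#' smaller clusters than the whole molecule, i.e. it is less stable than the
#' reference.
#'
#' @inheritParams cosine_similarity
#' @return A single number.
#' @export
average_difference <- function(A, S) {
  A <- as_sizes(A); S <- as_sizes(S)
  if (length(A) != length(S)) {
    stop("series lengths differ (", length(A), " vs ", length(S), ")", call. = FALSE)
  }
  sum(A - S) / length(A)
}

as_sizes <- function(x) {
  if (inherits(x, "cluster_size_series")) x$sizes else as.numeric(x)
}

#' Center per-subtype metric values by their mean over subtypes
#'
#' The normalized metrics are `nCosSim = CosSim - Avg(CosSim)` and
#' `nAvgDiff = AvgDiff - Avg(AvgDiff)`, with the unweighted mean taken over
#' the subtypes present in the ligand. Negative normalized values flag
#' subtypes less stable than the molecule's average.
#'
#' @param values Numeric vector of per-subtype metric values.
#' @return Numeric vector of the same length, summing to zero.
#' @export
normalize_metrics <- function(values) {
  stopifnot(length(values) >= 1L)
  values - mean(values)
}

#' Aggregate per-model metrics over the autoencoder ensemble
#'
#' @param per_model Numeric vector (or matrix with one row per model) of
#'   metric values for one subtype across ensemble members.
#' @return Named numeric vector with `mean` and population `sd` (divisor n,
#'   fixed for reproducibility; with a single model the sd is 0). A small sd
#'   means the ensemble members agree and the suggestion is well grounded.
#' @export
aggregate_ensemble <- function(per_model) {
  x <- as.numeric(per_model)
  stopifnot(length(x) >= 1L)
  m <- mean(x)
  c(mean = m, sd = sqrt(mean((x - m)^2)))
}

#' Compare every subtype's cluster-size series with the reference
#'
#' Computes CosSim and AvgDiff per subtype and ensemble member, centers the
#' ensemble means across subtypes, and returns a tidy per-subtype table.
#'
#' @param subtype_sizes Nested list: `subtype_sizes[[s]][[m]]` is the
#'   cluster-size series (numeric vector or `cluster_size_series`) of subtype
#'   s under ensemble member m. Names of the outer list are subtype ids.
#' @param reference Reference (whole-molecule) cluster-size series.
#' @return Tibble with one row per subtype: `subtype_id`, `cos_sim`,
#'   `cos_sim_sd`, `avg_diff`, `avg_diff_sd`, `n_cos_sim`, `n_avg_diff`.
#' @export
compare_subtypes <- function(subtype_sizes, reference) {
  stopifnot(length(subtype_sizes) >= 1L)
  ids <- names(subtype_sizes)
  if (is.null(ids)) ids <- as.character(seq_along(subtype_sizes) - 1L)
  rows <- lapply(seq_along(subtype_sizes), function(s) {
    per_model_cos <- vapply(subtype_sizes[[s]], cosine_similarity, 0.0, S = reference)
    per_model_avg <- vapply(subtype_sizes[[s]], average_difference, 0.0, S = reference)
    cs <- aggregate_ensemble(per_model_cos)
    ad <- aggregate_ensemble(per_model_avg)
    tibble::tibble(subtype_id = ids[s],
                   cos_sim = cs[["mean"]], cos_sim_sd = cs[["sd"]],
                   avg_diff = ad[["mean"]], avg_diff_sd = ad[["sd"]])
  })
  out <- do.call(rbind, rows)
  out$n_cos_sim <- normalize_metrics(out$cos_sim)
  out$n_avg_diff <- normalize_metrics(out$avg_diff)
  out
}

#' Rank atom subtypes from most to least "malicious"
#'
#' Each subtype is ranked by `n_cos_sim` (ascending) and by `n_avg_diff`
#' (ascending); the final rank orders subtypes by the average of those two
#' ranks, ties broken by ascending subtype id. Rank 1 is the subtype whose
#' clustering behavior deviates most below the whole-molecule reference — the
#' top candidate for chemical modification. The malicious-atom reading is only
#' valid when the whole-molecule simulation is itself stable; when
#' `stable = FALSE` a prominent warning is emitted (low metric values then no
#' longer single out destabilizing moieties) but ranks are still returned.
#'
#' @param metrics Tibble from [compare_subtypes()] (needs `subtype_id`,
#'   `n_cos_sim`, `n_avg_diff`; extra columns are carried through).
#' @param stable Logical stability flag from [is_stable()].
#' @return Object of class `subtype_ranking`: tibble sorted by `rank` with
#'   added columns `rank_cos`, `rank_avg`, `rank`, plus attribute `stable`.
#' @export
rank_subtypes <- function(metrics, stable = TRUE) {
  stopifnot(nrow(metrics) >= 1L)
  if (!isTRUE(stable)) {
    warning("whole-molecule binding mode is NOT stable: low comparison metrics do not ",
            "identify malicious atoms in an unstable simulation; interpret ranks with care",
            call. = FALSE)
  }
  r1 <- rank(metrics$n_cos_sim, ties.method = "average")
  r2 <- rank(metrics$n_avg_diff, ties.method = "average")
  composite <- (r1 + r2) / 2
  ord <- order(composite, metrics$subtype_id)
  out <- metrics[ord, , drop = FALSE]
  out$rank_cos <- r1[ord]
  out$rank_avg <- r2[ord]
  out$rank <- seq_len(nrow(out))
  structure(tibble::as_tibble(out), class = c("subtype_ranking", class(tibble::tibble())),
            stable = isTRUE(stable))
}

#' @export
#' @importFrom generics tidy
tidy.subtype_ranking <- function(x, ...) {
  tibble::as_tibble(unclass_ranking(x))
}

#' @export
#' @importFrom generics glance
glance.subtype_ranking <- function(x, ...) {
  tibble::tibble(
    n_subtypes = nrow(x),
    stable = isTRUE(attr(x, "stable")),
    top_subtype = x$subtype_id[x$rank == 1][1],
    top_n_cos_sim = x$n_cos_sim[x$rank == 1][1],
    top_n_avg_diff = x$n_avg_diff[x$rank == 1][1]
  )
}

unclass_ranking <- function(x) {
  class(x) <- setdiff(class(x), "subtype_ranking")
  x
}
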