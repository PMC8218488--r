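#' Build the two-channel dynamism series from a contact series
#'
#' Pairs the contact matrix at each frame t (channel 1) with the absolute
#' elementwise difference between the contacts at t and at t - delta
#' (channel 2). Because the series is binary the absolute difference equals
#' XOR, so channel 2 marks cells whose contact state changed over the lag —
#' 1 for a new or lost contact, 0 for a stable cell — independent of the
#' direction of the change. Frames with t <= delta compare against frame 1
#' (clamped lag) so the output keeps length T and stays aligned with the
#' reference clustering series.
#'
#' @param contacts A `contact_series` (T x R x M; R = N whole molecule, 1 for
#'   an aggregated subtype).
#' @param delta Lag in frames, >= 0. Default 500 frames (10 ns at the default
#'   20 ps snapshot spacing).
#' @return Object of class `dynamism_series`: list with `values`
#'   (T x 2 x R x M integer array), `delta`, `frame_interval_ps`.
#' @export
build_dynamism <- function(contacts, delta = 500) {
  stopifnot(inherits(contacts, "contact_series"))
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  delta <- as.integer(delta)
  v <- contacts$values
  d <- dim(v)
  T_ <- d[1]
  lag_idx <- pmax(seq_len(T_) - delta, 1L)
  out <- array(0L, dim = c(T_, 2L, d[2], d[3]))
  out[, 1L, , ] <- v
  out[, 2L, , ] <- abs(v - v[lag_idx, , , drop = FALSE])
  structure(list(values = out, delta = delta,
                 frame_interval_ps = contacts$frame_interval_ps),
            class = "dynamism_series")
}

#' @export
print.dynamism_series <- function(x, ...) {
  d <- dim(x$values)
  cat("<dynamism_series> T=", d[1], ", channels=2, R=", d[3], ", M=", d[4],
      ", delta=", x$delta, " frames\n", sep = "")
  invisible(x)
}

#' Flatten a whole-molecule dynamism series to per-frame 2N x M matrices
#'
#' Concatenates the two channels along the atom axis: rows 1..N are the
#' contacts at t, rows N+1..2N the temporal-change channel. This single-channel
#' 2N x M layout is the input of the whole-molecule reference autoencoder.
#'
#' @param dyn A `dynamism_series` with R = N rows.
#' @return A `dynamism_series` whose `values` have dimensions
#'   T x 1 x 2N x M (one channel, stacked rows).
#' @export
flatten_whole_molecule <- function(dyn) {
  stopifnot(inherits(dyn, "dynamism_series"))
  d <- dim(dyn$values)
  T_ <- d[1]; N <- d[3]; M <- d[4]
  out <- array(0L, dim = c(T_, 1L, 2L * N, M))
  out[, 1L, seq_len(N), ] <- dyn$values[, 1L, , ]
  out[, 1L, N + seq_len(N), ] <- dyn$values[, 2L, , ]
  structure(list(values = out, delta = dyn$delta,
                 frame_interval_ps = dyn$frame_interval_ps),
            class = "dynamism_series")
}
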