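make_constant_dyn <- function(T_ = 200, M = 128, seed = 51) {
  set.seed(seed)
  pat <- stats::rbinom(M, 1, 0.3)
  vals <- array(0L, dim = c(T_, 1, M))
  for (t in seq_len(T_)) vals[t, 1, ] <- pat
  build_dynamism(moietyrank:::new_contact_series(vals, cutoff = 4.5), delta = 10)
}

test_that("architecture validates the protein-axis length at build time", {
  cfg <- cvae_config(filters = 32, latent_dim = 5)
  m <- build_cvae(cfg, c(2, 1, 256))
  expect_equal(m$shape_trace, c(256L, 125L, 60L, 27L, 11L))
  expect_error(build_cvae(cfg, c(2, 1, 20)), "M >= 91")
  expect_silent(build_cvae(cfg, c(2, 1, 91)))   # smallest legal input
  expect_error(build_cvae(cfg, c(2, 1, 90)), "M >= 91")
})

test_that("encoder emits d-dimensional codes and the decoder restores the input shape", {
  cfg <- cvae_config(filters = 32, latent_dim = 5, seed = 3)
  model <- build_cvae(cfg, c(2, 1, 256))
  set.seed(8)
  x <- array(rbinom(4 * 2 * 256, 1, 0.3), dim = c(4, 2, 1, 256))
  z <- encode(model, x)
  expect_equal(dim(z), c(4L, 5L))
  r <- reconstruct(model, x)
  expect_equal(dim(r), dim(x))
  expect_true(all(r > 0 & r < 1))             # sigmoid output

  cfg3 <- cvae_config(filters = 8, latent_dim = 3, seed = 3)
  m3 <- build_cvae(cfg3, c(2, 1, 128))
  set.seed(9)
  x3 <- array(rbinom(3 * 2 * 128, 1, 0.5), dim = c(3, 2, 1, 128))
  expect_equal(dim(encode(m3, x3)), c(3L, 3L))
})

test_that("training reduces reconstruction loss on a constant series and is seed-reproducible", {
  dyn <- make_constant_dyn()
  cfg <- cvae_config(filters = 8, latent_dim = 3, max_epochs = 30, seed = 11)
  emb <- train_cvae(build_cvae(cfg, dim(dyn$values)[2:4]), dyn)
  lh <- emb$loss_history
  expect_lt(lh$bce[nrow(lh)], lh$bce[1])
  expect_true(all(is.finite(lh$total)))
  expect_true(all(lh$kl >= 0))

  emb2 <- train_cvae(build_cvae(cfg, dim(dyn$values)[2:4]), dyn)
  expect_identical(emb$loss_history, emb2$loss_history)   # bit-for-bit
  expect_identical(emb$z, emb2$z)

  cfg2 <- cvae_config(filters = 8, latent_dim = 3, max_epochs = 30, seed = 12)
  emb3 <- train_cvae(build_cvae(cfg2, dim(dyn$values)[2:4]), dyn)
  expect_false(identical(emb$loss_history$total, emb3$loss_history$total))
})

test_that("training rejects non-binary input", {
  dyn <- make_constant_dyn(T_ = 10)
  bad <- dyn$values * 0.5
  cfg <- cvae_config(filters = 8, latent_dim = 3, max_epochs = 2)
  model <- build_cvae(cfg, dim(dyn$values)[2:4])
  expect_error(train_cvae(model, bad), "binary")
})

test_that("two planted states separate in latent space", {
  set.seed(61)
  M <- 128; T_ <- 300
  p1 <- rbinom(M, 1, 0.3); p2 <- rbinom(M, 1, 0.3)
  state <- rep(c(0L, 1L), each = T_ / 2)
  vals <- array(0L, dim = c(T_, 1, M))
  for (t in seq_len(T_)) vals[t, 1, ] <- if (state[t] == 0) p1 else p2
  dyn <- build_dynamism(moietyrank:::new_contact_series(vals, cutoff = 4.5), 10)
  cfg <- cvae_config(filters = 32, latent_dim = 3, max_epochs = 40, seed = 21)
  emb <- train_cvae(build_cvae(cfg, dim(dyn$values)[2:4]), dyn)
  z <- emb$z
  c0 <- colMeans(z[state == 0, ]); c1 <- colMeans(z[state == 1, ])
  between <- sqrt(sum((c0 - c1)^2))
  within <- mean(c(sqrt(rowSums((z[state == 0, ] - rep(c0, each = sum(state == 0)))^2)),
                   sqrt(rowSums((z[state == 1, ] - rep(c1, each = sum(state == 1)))^2))))
  expect_gt(between, within)
})

test_that("the hyperparameter ensemble trains one member per grid point", {
  dyn <- make_constant_dyn(T_ = 60)
  embs <- suppressWarnings(     # short-series advisory is expected at T = 60
    build_ensemble(dyn, filters_grid = c(8, 16), latent_grid = c(2, 3),
                   base_seed = 5, max_epochs = 4))
  expect_named(embs, c("f8_d2", "f8_d3", "f16_d2", "f16_d3"))
  expect_equal(vapply(embs, function(e) ncol(e$z), 0L),
               c(f8_d2 = 2L, f8_d3 = 3L, f16_d2 = 2L, f16_d3 = 3L))
  expect_true(all(vapply(embs, function(e) nrow(e$z), 0L) == 60L))
  expect_equal(length(suppressWarnings(build_ensemble(dyn, 8, 2, max_epochs = 2))), 1L)
  # default grids give the 6-member ensemble
  g <- expand.grid(d = c(3, 5, 10), f = c(32, 64))
  expect_equal(nrow(g), 6L)
})
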