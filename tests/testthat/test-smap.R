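# Helpers to build small mixed embeddings from simulated composites.
smap_fixture <- function(seed = 1L, n_donors = 1L, E = 3L, m = 12L) {
  set.seed(seed)
  rec <- as_composite(replicate(m, rlnorm(10, 1, 0.8), simplify = FALSE) |> unname(),
                      taxon = "rec", ln = TRUE)
  donors <- lapply(seq_len(n_donors), function(i) {
    as_composite(replicate(m, rlnorm(10, 1, 0.8), simplify = FALSE) |> unname(),
                 taxon = paste0("d", i), ln = TRUE)
  })
  names(donors) <- paste0("d", seq_len(n_donors))
  build_mixed_embedding(rec, donors, E)
}

test_that("mixed embeddings follow the lag-substitution rule", {
  # E = 5, 3 donors -> {R_t, R_t-1, D1, D2, D3}
  e1 <- smap_fixture(1, n_donors = 3L, E = 5L)
  expect_equal(colnames(e1$X), c("R_lag0", "R_lag1", "d1", "d2", "d3"))
  # E = 2, 4 donors -> dimension 5 with a single recipient column
  e2 <- smap_fixture(2, n_donors = 4L, E = 2L)
  expect_equal(colnames(e2$X), c("R_lag0", "d1", "d2", "d3", "d4"))
  # E = 3, 1 donor -> {R_t, R_t-1, D1}
  e3 <- smap_fixture(3, n_donors = 1L, E = 3L)
  expect_equal(colnames(e3$X), c("R_lag0", "R_lag1", "d1"))
  # no donors is not S-mappable
  set.seed(4)
  rec <- as_composite(list(rnorm(10), rnorm(10)))
  expect_error(build_mixed_embedding(rec, list(), 3L), "no donors")
})

test_that("the response is within-fragment per-capita growth", {
  sim <- simulate_community(synthetic_config(), seed = 2L)
  cs <- preprocess(sim$panel)
  emb <- build_mixed_embedding(cs$rotifers, cs["phytoplankton"], 3L)
  # rows per fragment = len - max(lags, 1 for the response)
  expect_equal(nrow(emb$X), 24L * (10L - 2L))
  g <- growth_series(cs$rotifers)
  expect_equal(emb$y, g[emb$t])
  expect_false(anyNA(emb$y))
})

test_that("regularized S-map matches the explicit normal-equations oracle", {
  for (seed in 1:10) {
    emb <- smap_fixture(seed, n_donors = sample(1:3, 1), E = sample(2:4, 1),
                        m = 8L)
    theta <- sample(c(0, 0.5, 2, 4), 1)
    lambda <- sample(c(0, 0.01, 0.5), 1)
    got <- regularized_smap(emb, theta, lambda)
    want <- oracle_smap(emb$X, emb$y, theta, lambda, exclude_self = TRUE)
    expect_equal(unname(got$coefficients), unname(want), tolerance = 1e-8)
  }
})

test_that("theta = 0, lambda = 0 reduces to global least squares", {
  emb <- smap_fixture(11, n_donors = 2L, E = 3L)
  fit <- regularized_smap(emb, 0, 0, exclude_self = FALSE)
  ols <- unname(coef(lm(emb$y ~ emb$X)))
  for (p in c(1L, 5L, nrow(emb$X))) {
    expect_equal(unname(fit$coefficients[p, ]), ols, tolerance = 1e-8)
  }
})

test_that("a heavy ridge penalty shrinks slopes towards zero", {
  emb <- smap_fixture(12, n_donors = 2L, E = 3L)
  fit <- regularized_smap(emb, 0, 1e8)
  slopes <- fit$coefficients[, -1L]
  expect_lt(max(abs(slopes)), 1e-4)
  # intercept approaches the mean response
  expect_equal(mean(fit$coefficients[, 1L]), mean(emb$y), tolerance = 0.05)
})

test_that("S-map recovers a linear system's coefficients at every row", {
  set.seed(20)
  m <- 20L
  x1 <- replicate(m, rlnorm(10), simplify = FALSE)
  x2 <- replicate(m, rlnorm(10), simplify = FALSE)
  rec <- as_composite(replicate(m, rlnorm(10), simplify = FALSE) |> unname(),
                      ln = TRUE)
  donors <- list(d1 = as_composite(unname(x1), taxon = "d1", ln = TRUE),
                 d2 = as_composite(unname(x2), taxon = "d2", ln = TRUE))
  emb <- build_mixed_embedding(rec, donors, 2L)
  emb$y <- 2 * emb$X[, "d1"] - emb$X[, "d2"] + rnorm(nrow(emb$X), 0, 0.01)
  fit <- regularized_smap(emb, 1, 0.001)
  expect_true(all(abs(fit$coefficients[, "d1"] - 2) < 0.05))
  expect_true(all(abs(fit$coefficients[, "d2"] + 1) < 0.05))
})

test_that("coefficients are invariant to row permutation", {
  emb <- smap_fixture(13, n_donors = 1L, E = 3L)
  fit1 <- regularized_smap(emb, 2, 0.01)
  set.seed(1)
  perm <- sample(nrow(emb$X))
  emb2 <- emb
  emb2$X <- emb$X[perm, , drop = FALSE]
  emb2$y <- emb$y[perm]
  emb2$t <- emb$t[perm]
  fit2 <- regularized_smap(emb2, 2, 0.01)
  expect_equal(fit2$coefficients[order(perm), ], fit1$coefficients,
               tolerance = 1e-10)
})

test_that("grid tuning minimizes LOOCV RMSE with the documented tie-break", {
  emb <- smap_fixture(14, n_donors = 2L, E = 3L, m = 8L)
  tn <- tune_smap(emb)
  expect_equal(nrow(tn$surface), 11L * 8L)
  expect_equal(min(tn$surface$rmse), tn$rmse)
  # chosen rmse equals a direct refit at the chosen parameters
  refit <- regularized_smap(emb, tn$theta, tn$lambda)
  expect_equal(refit$rmse, tn$rmse, tolerance = 1e-10)
  # tie rule: identical rmse everywhere picks (theta 0, lambda 0)
  tn2 <- tn
  tn2$surface$rmse <- 1
  cand <- tn2$surface[order(tn2$surface$lambda, tn2$surface$theta), ]
  expect_equal(cand$theta[1], 0)
  expect_equal(cand$lambda[1], 0)
})

test_that("a globally linear stochastic system selects small theta", {
  set.seed(30)
  m <- 24L
  rec_frags <- replicate(m, exp(as.numeric(arima.sim(list(ar = 0.6), 10))),
                         simplify = FALSE)
  rec <- as_composite(unname(rec_frags), ln = TRUE)
  don <- as_composite(replicate(m, rlnorm(10), simplify = FALSE) |> unname(),
                      taxon = "d1", ln = TRUE)
  emb <- build_mixed_embedding(rec, list(d1 = don), 2L)
  emb$y <- 0.5 * emb$X[, "R_lag0"] + 0.3 * emb$X[, "d1"] +
    rnorm(nrow(emb$X), 0, 0.2)
  tn <- tune_smap(emb)
  expect_lte(tn$theta, 1)
})

test_that("interaction series map coefficients back to panel keys", {
  sim <- simulate_community(synthetic_config(), seed = 2L)
  cs <- preprocess(sim$panel)
  links <- data.frame(donor = c("phytoplankton", "phytophilous_pred"),
                      recipient = c("rotifers", "rotifers"))
  E <- c(rotifers = 4L)
  its <- interaction_timeseries(links, cs, E, theta = 1, lambda = 0.01)
  ser <- its$series
  expect_setequal(unique(ser$donor), links$donor)
  # one coefficient per link per valid time point: lags use 2 recipient
  # columns, so 8 rows per fragment
  expect_equal(nrow(ser), 2L * 24L * 8L)
  expect_true(all(ser$census %in% 1:9))
  expect_true(all(is.finite(ser$coefficient)))
  # links absent from the accepted set produce no series
  expect_false(any(ser$donor == "molluscs"))
  # both donors share the single recipient model
  expect_equal(its$models$recipient, "rotifers")
})

test_that("a constant donor column shrinks to zero under ridge", {
  emb <- smap_fixture(15, n_donors = 1L, E = 2L)
  emb$X[, "d1"] <- 0.7     # constant column
  fit <- regularized_smap(emb, 0.5, 0.5)
  expect_lt(max(abs(fit$coefficients[, "d1"])), 1e-6)
})
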