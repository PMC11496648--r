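test_that("cross mapping is asymmetric for unidirectionally coupled maps", {
  sim <- simulate_coupled_logistic(seed = 3)
  # x drives y: y's manifold recovers x (skill grows with library size)
  cv_true <- ccm_convergence(sim$y, sim$x, 2L, n_samples = 300L, seed = 11)
  cv_false <- ccm_convergence(sim$x, sim$y, 2L, n_samples = 300L, seed = 12)
  expect_true(cv_true$pass)
  expect_gt(cv_true$rho_max, 0.8)
  expect_gt(cv_true$delta_rho, 0.5)
  expect_lt(cv_false$rho_max, 0.4)
  expect_false(cv_false$pass)
  expect_equal(cv_true$Lmin, 3L)
  expect_equal(cv_true$Lmax, 24L * (10L - 1L))
})

test_that("independent noise pairs show no cross-map skill at any library size", {
  a <- noise_composite(seed = 31, taxon = "a")
  b <- noise_composite(seed = 32, taxon = "b")
  for (L in c(20L, 100L, 216L)) {
    rho <- mean(cross_map(a, b, 2L, L = L, n_samples = 50L, seed = 4),
                na.rm = TRUE)
    expect_lt(abs(rho), 0.25)
  }
})

test_that("cross_map is reproducible and validates library bounds", {
  sim <- simulate_coupled_logistic(seed = 5)
  r1 <- cross_map(sim$y, sim$x, 2L, L = 30L, n_samples = 20L, seed = 99)
  r2 <- cross_map(sim$y, sim$x, 2L, L = 30L, n_samples = 20L, seed = 99)
  expect_identical(r1, r2)
  # full library is deterministic regardless of sampling
  rfull <- cross_map(sim$y, sim$x, 2L, L = 216L, n_samples = 1L, seed = 1)
  rfull2 <- cross_map(sim$y, sim$x, 2L, L = 216L, n_samples = 3L, seed = 77)
  expect_equal(rep(rfull, 3), rfull2)
  expect_error(cross_map(sim$y, sim$x, 2L, L = 2L), "below minimum")
  expect_error(cross_map(sim$y, sim$x, 2L, L = 1000L), "exceeds available")
})

test_that("library-subsample summaries are stable within Monte-Carlo error", {
  sim <- simulate_coupled_logistic(seed = 8)
  r1 <- cross_map(sim$y, sim$x, 2L, L = 20L, n_samples = 400L, seed = 1)
  r2 <- cross_map(sim$y, sim$x, 2L, L = 20L, n_samples = 800L, seed = 2)
  se <- sd(r1) / sqrt(length(r1))
  expect_lt(abs(mean(r1) - mean(r2)), 3 * se + 3 * sd(r2) / sqrt(length(r2)))
})

test_that("seasonal surrogates preserve the cyclic mean and permute anomalies", {
  sim <- simulate_community(synthetic_config(), seed = 4L)
  cs <- preprocess(sim$panel)$rotifers
  su <- seasonal_surrogate(cs, n = 50L, seed = 9)
  pos <- ((cs$census - 1L) %% 10L) + 1L
  orig_prof <- tapply(cs$values, pos, mean)
  for (j in c(1L, 25L, 50L)) {
    s <- su$surrogates[, j]
    expect_equal(as.numeric(tapply(s, pos, mean)), as.numeric(orig_prof),
                 tolerance = 1e-12)
    prof_at <- as.numeric(orig_prof[as.character(pos)])
    expect_equal(sort(s - prof_at), sort(cs$values - prof_at),
                 tolerance = 1e-12)
  }
})

test_that("a zero-anomaly series is a fixed point of surrogate generation", {
  prof <- sin(2 * pi * (0:9) / 10) * 2 + 0.5
  cs <- as_composite(rep(list(prof), 6))
  su <- seasonal_surrogate(cs, n = 20L, seed = 3)
  expect_true(all(abs(su$surrogates - cs$values) < 1e-12))
})

test_that("surrogates with 9-point fragments use available positions", {
  sim <- simulate_community(synthetic_config(), seed = 1L)
  p <- sim$panel
  drop <- p$taxon == "macrophytes" & p$year == 3L & p$census == 10L
  cs <- preprocess(community_panel(p[!drop, ]))$macrophytes
  su <- seasonal_surrogate(cs, n = 10L, seed = 2)
  expect_equal(dim(su$surrogates), c(232L, 10L))
  pos <- ((cs$census - 1L) %% 10L) + 1L
  expect_equal(as.numeric(table(pos))[10], 16)  # position 10 seen in 16 fragments
  prof <- tapply(cs$values, pos, mean)
  expect_equal(as.numeric(tapply(su$surrogates[, 5], pos, mean)),
               as.numeric(prof), tolerance = 1e-12)
})

test_that("the add-one permutation p-value follows the rank formula", {
  expect_equal(permutation_pvalue(2, rep(1, 1000)), 1 / 1001)
  null <- as.numeric(1:999)
  expect_equal(permutation_pvalue(500, null), (1 + 500) / 1000)
  expect_gt(permutation_pvalue(Inf, null), 0)  # never exactly zero
})

test_that("surrogate test accepts a true causal link and its p is calibrated", {
  sim <- simulate_coupled_logistic(seed = 13)
  su <- seasonal_surrogate(sim$x, n = 1000L, seed = 21)
  st <- surrogate_test(sim$y, sim$x, 2L, su)
  expect_lt(st$p, 0.05)
  expect_equal(st$rho_obs,
               cross_map(sim$y, sim$x, 2L, L = 216L, n_samples = 1L),
               tolerance = 1e-12)
  # a noise "donor" is not significant against its own surrogates
  nz <- noise_composite(seed = 77)
  sun <- seasonal_surrogate(nz, n = 200L, seed = 22)
  stn <- surrogate_test(sim$y, nz, 2L, sun)
  expect_gt(stn$p, 0.05)
})

test_that("lagged CCM screens false positives and breaks ties as documented", {
  sim <- simulate_coupled_logistic(seed = 3)
  lc <- lagged_ccm(sim$y, sim$x, 2L, seed = 5)
  expect_true(lc$optimal_lag <= 0L)
  expect_true(lc$pass)
  expect_named(lc$rho_by_lag, as.character(-2:2))

  # tie-break: smallest |lag| first, then the more negative lag
  fake <- c(`-2` = 0.5, `-1` = 0.7, `0` = 0.7, `1` = 0.2, `2` = 0.1)
  best <- max(fake)
  cand <- as.integer(names(fake))[fake == best]
  cand <- cand[order(abs(cand), cand)]
  expect_equal(cand[1], 0L)
})

test_that("the criterion cascade short-circuits and flags decisions", {
  set.seed(42)
  # two noise series: expect convergence failures with NA surrogate p,
  # proving criterion 2 never ran for pairs failing criterion 1
  comps <- list(a = noise_composite(seed = 51, taxon = "a"),
                b = noise_composite(seed = 52, taxon = "b"))
  E <- c(a = 2L, b = 2L)
  scan <- detect_links(comps, E, n_samples = 100L, n_surrogates = 50L,
                       lag_samples = 10L, seed = 7)
  expect_equal(nrow(scan$table), 2L)
  failed_conv <- scan$table$criterion_failed == "convergence"
  expect_true(all(is.na(scan$table$p_surrogate[failed_conv])))
  expect_true(all(is.na(scan$table$opt_lag[failed_conv])))

  # coupled maps: the true direction is accepted, the false one is not
  sim <- simulate_coupled_logistic(seed = 3)
  comps2 <- list(x = sim$x, y = sim$y)
  scan2 <- detect_links(comps2, c(x = 2L, y = 2L), n_samples = 300L,
                        n_surrogates = 300L, lag_samples = 20L, seed = 8)
  tab <- scan2$table
  xy <- tab[tab$donor == "x" & tab$recipient == "y", ]
  yx <- tab[tab$donor == "y" & tab$recipient == "x", ]
  expect_equal(xy$decision, "accept")
  expect_equal(yx$decision, "reject")
  # reruns with the same seed are bit-identical
  scan2b <- detect_links(comps2, c(x = 2L, y = 2L), n_samples = 300L,
                         n_surrogates = 300L, lag_samples = 20L, seed = 8)
  expect_identical(scan2$table, scan2b$table)
})

test_that("a known 5-link web is recovered at moderate noise with FP reporting", {
  web5 <- data.frame(
    donor = c("phytoplankton", "rotifers", "benthic_pred", "macrophytes",
              "neustonic_pred"),
    recipient = c("rotifers", "phytoplankton", "molluscs", "herbivores",
                  "molluscs"),
    a = c(0.9, -0.9, -0.9, 0.9, -0.7), b = c(0.2, -0.2, -0.25, -0.2, 0))
  cfg <- synthetic_config(web = web5, process_sd = 0.1, season_amp = 0.15,
                          self_reg = 0.7,
                          disturbance = list(C = numeric(0), I = numeric(0),
                                             H = numeric(0), IH = numeric(0)))
  sim <- simulate_community(cfg, seed = 31L)
  cs <- preprocess(sim$panel)
  E <- select_embeddings(cs)
  scan <- detect_links(cs, E, n_samples = 300L, n_surrogates = 500L,
                       lag_samples = 30L, seed = 31L)
  lk <- function(d) paste(d$donor, d$recipient)
  acc <- scan$table[scan$table$decision %in% c("accept", "marginal"), ]
  n_true <- sum(lk(acc) %in% lk(web5))
  expect_gte(n_true, 3L)                       # majority of the 5 true links
  # false-positive rate is computable from the scan (detections beyond the
  # direct links include net/indirect effects)
  fp_rate <- mean(!(lk(acc) %in% lk(web5)))
  expect_true(is.finite(fp_rate) && fp_rate >= 0 && fp_rate <= 1)
})

test_that("a fully decoupled community accepts about alpha * 90 pairs", {
  cfg <- synthetic_config(web = default_web()[0, ],
                          disturbance = list(C = numeric(0), I = numeric(0),
                                             H = numeric(0), IH = numeric(0)))
  sim <- simulate_community(cfg, seed = 21L)
  cs <- preprocess(sim$panel)
  E <- select_embeddings(cs)
  scan <- detect_links(cs, E, n_samples = 200L, n_surrogates = 500L,
                       lag_samples = 30L, seed = 9L)
  n_acc <- sum(scan$table$decision == "accept")
  # expectation alpha * 90 = 4.5; allow generous binomial slack
  expect_lte(n_acc, 12L)
})
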