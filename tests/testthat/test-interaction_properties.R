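# Build a coefficient series over a recipient composite with a chosen
# functional dependence on the recipient's standardized density.
coef_series <- function(recipient_cs, f, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  keys <- composite_keys(recipient_cs)
  data.frame(donor = "d", recipient = recipient_cs$taxon,
             tank_id = keys$tank_id, treatment = keys$treatment,
             year = keys$year, census = keys$census,
             coefficient = f(recipient_cs$values) +
               rnorm(length(recipient_cs$values), 0, noise_sd),
             stringsAsFactors = FALSE)
}

control_composite <- function(seed = 1L, m = 6L) {
  set.seed(seed)
  keys <- data.frame(tank_id = rep(c("C1", "C2"), each = m / 2),
                     treatment = "C",
                     year = rep(1:(m / 2), times = 2))
  as_composite(replicate(m, rlnorm(10), simplify = FALSE) |> unname(),
               taxon = "rec", ln = TRUE, keys = keys)
}

test_that("IDD regression recovers exact linear density-dependence", {
  cs <- control_composite(1)
  ser <- coef_series(cs, function(z) -0.5 * z + 0.2)
  reg <- idd_regression(ser, cs)
  expect_equal(reg$slope, -0.5, tolerance = 1e-10)
  expect_equal(reg$intercept, 0.2, tolerance = 1e-10)
  expect_equal(reg$direction, "negative")
  expect_false(reg$degenerate)

  pos <- idd_regression(coef_series(cs, function(z) 0.3 * z), cs)
  expect_equal(pos$direction, "positive")

  flat <- idd_regression(coef_series(cs, function(z) rep(0.1, length(z))), cs)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$direction, "negative")  # zero slope -> negative by convention
  expect_true(flat$degenerate)
})

test_that("IDD slope equals the closed-form covariance/variance ratio", {
  cs <- control_composite(2)
  ser <- coef_series(cs, function(z) 0.4 * z, noise_sd = 0.3, seed = 5)
  reg <- idd_regression(ser, cs)
  dat_slope <- cov(cs$values, ser$coefficient) / var(cs$values)
  expect_equal(reg$slope, dat_slope, tolerance = 1e-12)
})

test_that("density-independent variability is classified against the permutation null", {
  cs <- control_composite(3)
  # coefficients independent of density: inside the null band
  ind <- coef_series(cs, function(z) rep(0, length(z)), noise_sd = 0.3,
                     seed = 7)
  cl <- classify_idd(ind, cs, seed = 11)
  expect_equal(cl$class, "density_independent")
  # strong dependence: classified by sign
  neg <- coef_series(cs, function(z) -0.5 * z, noise_sd = 0.05, seed = 8)
  expect_equal(classify_idd(neg, cs, seed = 12)$class, "negative")
  pos <- coef_series(cs, function(z) 0.5 * z, noise_sd = 0.05, seed = 9)
  expect_equal(classify_idd(pos, cs, seed = 13)$class, "positive")
})

test_that("link summaries decouple mean strength from temporal variability", {
  cells <- expand.grid(tank_id = c("C1", "C2"), year = 1:3)
  base <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(tank_id = cells$tank_id[i], treatment = "C",
               year = cells$year[i], census = 1:10,
               coefficient = NA_real_)
  }))

  # constant coefficient: strength |c|, zero variability
  cc <- base; cc$coefficient <- -0.7
  sm <- summarize_link(cc)
  expect_equal(sm$mean_strength, 0.7)
  expect_equal(sm$temporal_variability, 0)
  expect_equal(sm$n_cells, 6L)

  # alternating +a/-a: per-cell mean 0, sd = a * sqrt(n/(n-1))
  a <- 0.4
  alt <- base; alt$coefficient <- rep(c(a, -a), length.out = nrow(base))
  sm2 <- summarize_link(alt)
  expect_equal(sm2$mean_strength, 0, tolerance = 1e-12)
  expect_equal(sm2$temporal_variability, a * sqrt(10 / 9), tolerance = 1e-10)

  # a single-point cell is dropped with a warning
  onep <- rbind(cc[cc$tank_id == "C1" | cc$year > 1, ],
                cc[cc$tank_id == "C2" & cc$year == 1 & cc$census == 1, ])
  expect_warning(sm3 <- summarize_link(onep), "cell")
  expect_equal(sm3$n_cells, 5L)
  expect_equal(sm3$mean_strength, 0.7)

  # non-control records are ignored
  mix <- rbind(cc, transform(cc, treatment = "I", coefficient = 5))
  expect_equal(summarize_link(mix)$mean_strength, 0.7)
})

test_that("mean strength is invariant to census order within cells", {
  cc <- data.frame(tank_id = "C1", treatment = "C", year = 1L, census = 1:10,
                   coefficient = rnorm(10))
  shuf <- cc[sample(10), ]
  expect_equal(summarize_link(cc)$mean_strength,
               summarize_link(shuf)$mean_strength)
})

test_that("the consistency ANOVA attributes variance to the right terms", {
  grid <- expand.grid(tank_id = c("1", "2"), treatment = c("C", "I"),
                      year = 1, census = 1:5)
  # treatment-only signal: treatment SS > 0, census SS = 0
  g1 <- transform(grid, coefficient = ifelse(treatment == "C", 1, 2))
  a1 <- anova_consistency(g1)
  expect_gt(a1$table$sum_sq[a1$table$term == "treatment"], 0)
  expect_equal(a1$table$sum_sq[a1$table$term == "census"], 0,
               tolerance = 1e-12)

  # census-driven signal dominates the residual
  set.seed(3)
  g2 <- transform(grid, coefficient = as.numeric(census) * 0.5 +
                    rnorm(nrow(grid), 0, 0.05))
  a2 <- anova_consistency(g2)
  expect_gt(a2$table$sum_sq[a2$table$term == "census"],
            10 * a2$table$sum_sq[a2$table$term == "Residuals"])

  # pure noise: F near 1 on average over replicates
  fs <- replicate(30, {
    g <- transform(grid, coefficient = rnorm(nrow(grid)))
    tb <- anova_consistency(g)$table
    tb$F[tb$term == "treatment"]
  })
  expect_lt(abs(mean(fs) - 1), 0.6)

  # unreplicated interaction is flagged
  g3 <- g1[g1$tank_id == "1", ]
  expect_warning(a3 <- anova_consistency(g3), "confounded")
  expect_true(a3$interaction_confounded)
})

test_that("link_properties assembles the per-link property table", {
  sim <- simulate_community(synthetic_config(), seed = 2L)
  cs <- preprocess(sim$panel)
  links <- data.frame(donor = c("phytoplankton", "rotifers"),
                      recipient = c("rotifers", "phytoplankton"))
  E <- c(rotifers = 4L, phytoplankton = 4L)
  its <- interaction_timeseries(links, cs, E, theta = 2, lambda = 0.01)
  pr <- link_properties(its, cs)
  expect_equal(nrow(pr), 2L)
  expect_true(all(pr$idd_magnitude == abs(pr$idd_slope)))
  expect_true(all(pr$mean_strength >= 0))
  expect_true(all(pr$temporal_variability >= 0))
  expect_true(all(pr$idd_direction %in% c("negative", "positive")))
})
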