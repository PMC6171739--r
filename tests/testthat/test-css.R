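test_that("stimulus maps place the disc at the polar location", {
  s <- make_stimulus_map(45)
  expect_equal(unname(s$center), rep(7 * cos(pi / 4), 2), tolerance = 1e-12)
  # pixel area of the disc approximates pi r^2
  area <- sum(s$grid) * s$px_area
  expect_lt(abs(area - pi * 4) / (pi * 4), 0.02)
  # antipodal maps are point reflections of each other
  s2 <- make_stimulus_map(225)
  expect_equal(s2$grid, s$grid[rev(seq_len(nrow(s$grid))),
                               rev(seq_len(ncol(s$grid)))])
  expect_error(make_stimulus_map(45, eccentricity = 10), "clipped")
})

test_that("a full-field stimulus returns the gain exactly (unit volume)", {
  u <- data.frame(x0_deg = 0, y0_deg = 0.5, sigma_deg = 1.8, gain = 2,
                  exponent = 0.2)
  r <- css_response(u, full_field_map())
  expect_equal(r, 2, tolerance = 1e-6)
  # empty stimulus gives zero response
  empty <- make_stimulus_map(45)
  empty$grid[] <- 0
  expect_equal(css_response(u, empty), 0)
})

test_that("responses scale linearly in gain and match adaptive quadrature", {
  skip_if_not_installed("pracma")
  set.seed(7)
  st_cache <- list()
  for (i in 1:10) {
    loc <- runif(1, 0, 360)
    u <- data.frame(x0_deg = runif(1, -6, 6), y0_deg = runif(1, -6, 6),
                    sigma_deg = runif(1, 0.8, 4), gain = runif(1, 0.5, 3),
                    exponent = 0.2)
    st <- make_stimulus_map(loc, resolution = 40)
    r <- css_response(u, st)
    cx <- st$center[1]; cy <- st$center[2]
    f <- function(rho, phi) {
      rho * exp(-((cx + rho * cos(phi) - u$x0_deg)^2 +
                    (cy + rho * sin(phi) - u$y0_deg)^2) /
                  (2 * u$sigma_deg^2)) / (2 * pi * u$sigma_deg^2)
    }
    a <- pracma::integral2(f, 0, 2, 0, 2 * pi, reltol = 1e-10)$Q
    expect_equal(r, u$gain * a^0.2, tolerance = 1e-3)
    # homogeneous in gain
    u2 <- u; u2$gain <- 2 * u$gain
    expect_equal(css_response(u2, st), 2 * r, tolerance = 1e-12)
  }
})

test_that("decodable activations are stable under grid refinement", {
  pool <- generate_prf_population(prf_spec("IOG", n_units = 200), seed = 3)
  r10 <- vapply(c(45, 135, 225, 315), function(l)
    css_response(pool, make_stimulus_map(l, resolution = 10)),
    numeric(nrow(pool)))
  r20 <- vapply(c(45, 135, 225, 315), function(l)
    css_response(pool, make_stimulus_map(l, resolution = 20)),
    numeric(nrow(pool)))
  # clearly stimulus-driven units (3x the default noise SD): < 1% relative
  keep <- r20 > 0.3
  expect_lt(max(abs(r10[keep] - r20[keep]) / r20[keep]), 0.01)
  # all units: the discretization wobble is a negligible fraction of the
  # trial noise (SD 0.1), so it cannot move the decoder
  expect_lt(max(abs(r10 - r20)), 0.1 * 0.1)
})

test_that("population responses mix identities linearly", {
  units <- make_two_units(x0 = c(4.9, -4.9), y0 = c(4.9, -4.9))
  st <- make_stimulus_map(45)
  resp <- css_response(units, st)
  # m = 0: b-preferring units respond at noise level only
  set.seed(1)
  x0 <- population_response(units, 0, resp, noise_sd = 0, n_trials = 1)
  expect_equal(unname(x0[1, ]), c(resp[1], 0))
  # m = 50: each unit at half its full response
  x50 <- population_response(units, 50, resp, noise_sd = 0, n_trials = 1)
  expect_equal(unname(x50[1, ]), resp / 2)
  # noiseless linearity at m = 25
  x25 <- population_response(units, 25, resp, noise_sd = 0, n_trials = 1)
  expect_equal(unname(x25[1, ]), c(0.75 * resp[1], 0.25 * resp[2]))
})

test_that("noise scales with unit gain (amplified output, not cleaner signal)", {
  units <- make_two_units(x0 = c(4.9, -4.9), y0 = c(4.9, -4.9),
                          gain = c(4, 1))
  st <- make_stimulus_map(45)
  resp <- css_response(units, st)
  set.seed(2)
  x <- population_response(units, 50, resp, noise_sd = 0.1, n_trials = 4000)
  sds <- apply(x, 2, sd)
  expect_equal(sds[1] / sds[2], 4, tolerance = 0.2)
})

test_that("noise-free distinct patterns are learned perfectly", {
  units <- make_two_units(x0 = c(4.9, -4.9), y0 = c(4.9, -4.9))
  cfg <- css_config(ratio = 1, noise_sd = 0)
  dec <- run_learning_phase(units, cfg)
  expect_equal(dec$accuracy, 1)
  expect_equal(dec$n_train, 80)
})

test_that("learning accuracy beats chance on sampled populations", {
  pool <- generate_prf_population(prf_spec("IOG"), seed = 4)
  cfg <- css_config(ratio = 1)
  set.seed(5)
  units <- sample_population(pool, cfg)
  dec <- run_learning_phase(units, cfg)
  # binomial test at 80 training samples: > 0.5 at alpha = 0.01 needs 0.64
  expect_gt(dec$accuracy, 0.64)
})

test_that("decoder decisions are invariant to unit order", {
  pool <- generate_prf_population(prf_spec("pFus", n_units = 50), seed = 6)
  cfg <- css_config(ratio = 3)
  set.seed(7)
  units <- sample_population(pool, cfg)
  res1 <- run_css_experiment(units, cfg, seed = 8)
  perm <- c(3, 1, 4, 2)
  res2 <- run_css_experiment(units[perm, ], cfg, seed = 8)
  # same seed, same units (reordered): the noise draws differ in unit
  # assignment, so compare the deterministic noise-free decisions instead
  cfg0 <- css_config(ratio = 3, noise_sd = 0)
  r1 <- run_css_experiment(units, cfg0, seed = 9)
  r2 <- run_css_experiment(units[perm, ], cfg0, seed = 9)
  expect_equal(r1$pse_by_location, r2$pse_by_location, tolerance = 1e-8)
  expect_s3_class(res1, "css_result")
  expect_s3_class(res2, "css_result")
})

test_that("a noise-free symmetric population has exactly zero bias", {
  units <- make_two_units(x0 = c(2, 2), y0 = c(1, 1))
  res <- run_css_experiment(units, css_config(ratio = 1, noise_sd = 0),
                            seed = 1)
  expect_true(res$identifiable)
  expect_equal(unname(res$pse_by_location), rep(50, 4), tolerance = 1e-6)
  expect_lt(res$pse_variance, 1e-10)
})

test_that("the bias is invariant to relabeling the identities", {
  units <- make_two_units(x0 = c(4.9, 2), y0 = c(4.9, -1),
                          sigma = c(1.5, 2))
  cfg <- css_config(ratio = 1, noise_sd = 0)
  res <- run_css_experiment(units, cfg, seed = 1)
  swapped <- units
  swapped$identity_pref <- rev(units$identity_pref)
  res2 <- run_css_experiment(swapped, cfg, seed = 1)
  expect_equal(res2$pse_by_location, 100 - res$pse_by_location,
               tolerance = 1e-6)
  expect_equal(res2$pse_variance, res$pse_variance, tolerance = 1e-6)
})

test_that("coverage follows the 2-sigma intersection geometry", {
  # tiny receptive fields at fixation cannot reach the 7-degree stimuli
  u <- data.frame(x0_deg = 0, y0_deg = 0, sigma_deg = 0.5, gain = 1,
                  exponent = 0.2)
  expect_equal(coverage_proportion(u), 0)
  # a unit centered exactly on one stimulus covers that location
  u2 <- data.frame(x0_deg = 7 * cos(pi / 4), y0_deg = 7 * sin(pi / 4),
                   sigma_deg = 0.5, gain = 1, exponent = 0.2)
  expect_equal(coverage_proportion(u2, locations = 45), 1)
  # calibrated pools: fewer IOG units reach the stimuli than pFus units
  iog <- generate_prf_population(prf_spec("IOG"), seed = 10)
  pfus <- generate_prf_population(prf_spec("pFus"), seed = 10)
  expect_lt(coverage_proportion(iog), coverage_proportion(pfus))
})

test_that("population sampling applies the manipulations to a-units only", {
  pool <- generate_prf_population(prf_spec("IOG", n_units = 50), seed = 1)
  cfg <- css_config(ratio = 4, gain_a = 2, rf_inflation_a = 0.5)
  set.seed(2)
  units <- sample_population(pool, cfg)
  expect_equal(nrow(units), 5)
  expect_equal(sum(units$identity_pref == "a"), 4)
  expect_true(all(units$gain[units$identity_pref == "a"] == 2))
  expect_true(all(units$gain[units$identity_pref == "b"] == 1))
  expect_error(sample_population(pool[1:3, ], css_config(ratio = 9)),
               "pool too small")
})
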