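test_that("Pearson report carries r, t and combinatorial df", {
  x <- rnorm(10)
  r <- pearson_with_test(x, x)
  expect_equal(r$r, 1)
  expect_equal(r$df, 8)
  # 4 subjects x 8 locations of paired deviations
  set.seed(1)
  a <- rnorm(32); b <- a + rnorm(32)
  r2 <- pearson_with_test(a, b)
  expect_equal(r2$df, 30)
  expect_equal(r2$t_stat, r2$r * sqrt(r2$df / (1 - r2$r^2)),
               tolerance = 1e-10)
  expect_error(pearson_with_test(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_with_test(1:2, 2:3), "at least 3")
})

test_that("null correlations at n = 120 rarely exceed 0.3", {
  set.seed(42)
  r <- replicate(1000, cor(rnorm(120), rnorm(120)))
  expect_gte(mean(abs(r) < 0.3), 0.99)
})

test_that("BCa interval collapses for constant data and warns", {
  expect_warning(ci <- bca_ci(rep(2, 10), mean, n_boot = 200, seed = 1),
                 "degenerate")
  expect_equal(as.numeric(ci), c(2, 2))
  expect_true(attr(ci, "collapsed"))
})

test_that("BCa equals the percentile interval when z0 and acceleration vanish", {
  set.seed(3)
  v <- rnorm(40)
  x <- c(v, -v)  # sign-symmetric sample: skewness and acceleration vanish
  ci <- bca_ci(x, mean, n_boot = 4000, seed = 7)
  expect_lt(abs(attr(ci, "z0")), 0.06)
  expect_lt(abs(attr(ci, "acceleration")), 1e-12)
  # regenerate the identical bootstrap draws for the percentile oracle
  boots <- retbias:::with_seed(7, vapply(1:4000, function(b)
    mean(x[sample.int(80, 80, replace = TRUE)]), numeric(1)))
  perc <- quantile(boots, c(0.025, 0.975), names = FALSE, type = 6)
  expect_lt(max(abs(as.numeric(ci) - perc)), 0.03 * sd(x))
})

test_that("BCa agrees with the boot-package reference implementation", {
  skip_if_not_installed("boot")
  set.seed(9)
  x <- rexp(40)  # skewed, so bias correction and acceleration matter
  ci <- bca_ci(x, mean, n_boot = 6000, seed = 11)
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 6000)
  ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  expect_equal(as.numeric(ci), ref, tolerance = 0.08 * sd(x))
})

test_that("within/between difference is zero under exchangeable patterns", {
  pat <- c(3, -1, 4, -2, 0, 1, -3, 2)
  pse <- expand.grid(subject_id = sprintf("s%02d", 1:4),
                     location_deg = seq(0, 315, 45), session = 1:2,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pse$delta_pse <- pat[match(pse$location_deg, seq(0, 315, 45))]
  wb <- suppressWarnings(within_between_difference(pse, n_boot = 200,
                                                   seed = 1))
  expect_equal(wb$difference, 0, tolerance = 1e-12)
})

test_that("orthogonal stable patterns give within 1, between <= 0", {
  prof <- generate_subject_profiles(4, c(ab = 5),
                                    locations = seq(0, 315, 45),
                                    orthogonal = TRUE, seed = 2)
  base <- prof[, c("subject_id", "location_deg")]
  base$delta_pse <- prof$true_pse - 50
  pse <- rbind(transform(base, session = 1), transform(base, session = 2))
  wb <- suppressWarnings(within_between_difference(pse, n_boot = 200,
                                                   seed = 3))
  expect_equal(wb$within_r, 1, tolerance = 1e-9)
  expect_lte(wb$between_r, 1e-9)
  expect_gte(wb$difference, 1 - 1e-9)
})

test_that("the difference is invariant to session-wide constant shifts", {
  study <- make_exp1_study(n_subjects = 4, seed = 31)
  stage <- fit_psychometrics_stage(study$trials, estimator = "fixed")
  wb1 <- within_between_difference(stage$pse, n_boot = 500, seed = 5)
  shifted <- stage$pse
  shifted$delta_pse[shifted$session == 1] <-
    shifted$delta_pse[shifted$session == 1] + 7
  wb2 <- within_between_difference(shifted, n_boot = 500, seed = 5)
  expect_equal(wb1$difference, wb2$difference, tolerance = 1e-12)
})

test_that("interaction ANOVA matches a brute-force sums-of-squares oracle", {
  set.seed(6)
  d <- expand.grid(subject_id = sprintf("s%02d", 1:5),
                   location_deg = c(45, 135, 225, 315), rep = 1:3,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$pse <- rnorm(nrow(d), 50, 5)
  a <- interaction_anova(d)
  o <- anova_interaction_oracle(d$subject_id, d$location_deg, d$pse)
  expect_equal(a$F, o$F, tolerance = 1e-10)
  expect_equal(a$df1, o$df1)
  expect_equal(a$df2, o$df2)
})

test_that("additive noise-free tables give a vanishing interaction", {
  d <- expand.grid(subject_id = sprintf("s%02d", 1:4),
                   location_deg = c(45, 135), rep = 1:2,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # cell means exactly additive; replicate noise sums to zero in each cell
  d$pse <- 50 + as.integer(factor(d$subject_id)) * 2 +
    as.integer(factor(d$location_deg)) * 3 + c(-1, 1)[d$rep]
  a <- interaction_anova(d)
  expect_lt(abs(a$F), 1e-10)
})

test_that("10 subjects x 4 locations with 4 replicates give df 27 and 120", {
  set.seed(8)
  d <- expand.grid(subject_id = sprintf("s%02d", 1:10),
                   location_deg = c(45, 135, 225, 315), rep = 1:4,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$pse <- rnorm(nrow(d), 50, 5)
  a <- interaction_anova(d)
  expect_equal(a$df1, 27)
  expect_equal(a$df2, 120)
  expect_error(interaction_anova(d[-1, ]), "balanced")
})

test_that("identity alignment flips PSEs of pairs led by the target identity", {
  tab <- data.frame(subject_id = "s01", morph_pair = c("ab", "bc", "ac"),
                    location_deg = 45, pse = c(40, 60, 70))
  out <- align_pse_identity(tab, "b")
  expect_setequal(out$morph_pair, c("ab", "bc"))
  expect_equal(out$pse[out$morph_pair == "ab"], 40)   # b is second: kept
  expect_equal(out$pse[out$morph_pair == "bc"], 40)   # b is first: 100 - 60
})
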