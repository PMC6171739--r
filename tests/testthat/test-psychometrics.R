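make_fit <- function(beta0, beta_loc, z) {
  structure(list(beta0 = beta0, beta_loc = beta_loc, z = z,
                 z_variance = 0, morph_pair = "ab",
                 n_locations = length(beta_loc),
                 locations = as.numeric(names(beta_loc)),
                 subjects = rownames(z), n_trials = 0,
                 estimator = "fixed", converged = TRUE, model = NULL),
            class = "psyfit")
}

test_that("third-identity trials are removed and counted", {
  tr <- data.frame(morph_pair = c("ab", "ab", "ac"),
                   response = c("c", "a", "a"))
  out <- filter_third_identity(tr)
  expect_equal(out$removed, 1L)
  expect_equal(nrow(out$trials), 2L)
  expect_true(all(mapply(function(r, p) r %in% strsplit(p, "")[[1]],
                         out$trials$response, out$trials$morph_pair)))
  empty <- filter_third_identity(tr[0, ])
  expect_equal(empty$removed, 0L)
  expect_equal(nrow(empty$trials), 0L)
})

test_that("PSE decomposition follows the closed-form identities", {
  z <- matrix(c(0, -0.5), nrow = 2, dimnames = list(c("s01", "s02"), "45"))
  fit <- make_fit(0.1, c(`45` = -5), z)
  tab <- pse_table(fit)
  expect_equal(tab$pse[tab$subject_id == "s01"], 50)
  expect_equal(tab$pse[tab$subject_id == "s02"], 55)
  expect_equal(tab$delta_pse[tab$subject_id == "s02"], 5)
  expect_equal(tab$pse_pop, c(50, 50))
  # exact algebraic identity
  expect_equal(max(abs(tab$pse - (tab$pse_pop + tab$delta_pse))), 0)
})

test_that("a zero slope makes the PSE undefined", {
  z <- matrix(0, 1, 1, dimnames = list("s01", "45"))
  expect_error(pse_table(make_fit(0, c(`45` = -5), z)), "undefined")
})

test_that("single-subject fits match a plain logistic regression oracle", {
  trials <- make_single_subject_trials(c(`45` = 45, `135` = 55), seed = 3)
  fit <- fit_psychometric(trials, estimator = "mixed")  # auto-falls to fixed
  expect_equal(fit$estimator, "fixed")
  d <- trials
  d$y <- as.integer(d$response == "b")
  d$loc <- factor(d$location_deg)
  oracle <- glm(y ~ 0 + loc + morph_pct, data = d, family = binomial())
  expect_equal(fit$beta0, unname(coef(oracle)["morph_pct"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$beta_loc),
               unname(coef(oracle)[c("loc45", "loc135")]), tolerance = 1e-6)
  expect_true(all(fit$z == 0))
})

test_that("single-subject PSEs recover the generating map", {
  truth <- c(`45` = 45, `135` = 55, `225` = 50, `315` = 60)
  trials <- make_single_subject_trials(truth, reps = 10, seed = 5)
  tab <- pse_table(fit_psychometric(trials))
  rec <- setNames(tab$pse, tab$location_deg)[names(truth)]
  expect_lt(max(abs(rec - truth)), 2)
})

test_that("identical response patterns across locations give equal effects", {
  # same deterministic outcome sequence at every location
  base <- expand.grid(morph_pct = c(0, 17, 33, 50, 67, 83, 100),
                      rep = 1:10, location_deg = c(45, 135, 225))
  base$response <- ifelse(base$morph_pct > 50, "b",
                          ifelse(base$morph_pct < 50, "a",
                                 rep(c("a", "b"), length.out = nrow(base))[
                                   seq_len(nrow(base))]))
  # enforce exactly the same pattern per location
  base <- base[order(base$location_deg, base$morph_pct, base$rep), ]
  one_loc <- base[base$location_deg == 45, "response"]
  base$response <- rep(one_loc, 3)
  base$subject_id <- "s01"
  base$morph_pair <- "ab"
  fit <- fit_psychometric(base)
  expect_lt(diff(range(fit$beta_loc)), 1e-6)
  expect_true(all(abs(pse_table(fit)$delta_pse) < 1e-6))
})

test_that("flipping response labels mirrors PSEs about 50", {
  study <- make_exp1_study(n_subjects = 3, seed = 13)
  trials <- study$trials[study$trials$session == 1, ]
  fit <- fit_psychometric(trials, estimator = "fixed")
  # renaming the identities flips both the response labels and the
  # morph axis (morph % is measured toward the second identity)
  flipped <- trials
  flipped$response <- ifelse(trials$response == "a", "b", "a")
  flipped$morph_pct <- 100 - trials$morph_pct
  fit2 <- fit_psychometric(flipped, estimator = "fixed")
  t1 <- pse_table(fit)
  t2 <- pse_table(fit2)
  expect_equal(t2$pse, 100 - t1$pse, tolerance = 1e-8)
  expect_equal(t2$delta_pse, -t1$delta_pse, tolerance = 1e-8)
})

test_that("mixed and fixed estimators agree on the decomposition", {
  prof <- generate_subject_profiles(4, c(ab = 8),
                                    locations = c(45, 135, 225, 315),
                                    seed = 2)
  trials <- do.call(rbind, lapply(sprintf("s%02d", 1:4), function(s) {
    stubs <- generate_design(2, subject_id = s, seed = 3)
    stubs <- stubs[stubs$morph_pair == "ab", ]
    simulate_responses(stubs, prof, seed = match(s, sprintf("s%02d", 1:4)))
  }))
  fm <- fit_psychometric(trials, estimator = "mixed")
  ff <- fit_psychometric(trials, estimator = "fixed")
  expect_equal(fm$estimator, "mixed")
  expect_gt(cor(as.vector(fm$z), as.vector(ff$z)), 0.98)
  expect_equal(fm$beta0, ff$beta0, tolerance = 0.05)
  expect_gt(fm$z_variance, 0)
})

test_that("responses outside the morph pair are rejected before fitting", {
  tr <- data.frame(subject_id = "s01", morph_pair = "ab",
                   morph_pct = c(0, 100), location_deg = 45,
                   response = c("c", "b"))
  expect_error(fit_psychometric(tr), "filter_third_identity")
})

test_that("predict and simulate methods follow the fitted curves", {
  z <- matrix(c(0, -0.5), 2, 1, dimnames = list(c("s01", "s02"), "45"))
  fit <- make_fit(0.1, c(`45` = -5), z)
  nd <- data.frame(subject_id = c("s01", "s02"), location_deg = 45,
                   morph_pct = 50)
  p <- predict(fit, nd)
  expect_equal(p[1], 0.5)
  expect_equal(p[2], plogis(-0.5))
  sims <- simulate(fit, nsim = 3, seed = 1, newdata = nd)
  expect_equal(dim(sims), c(2L, 3L))
  expect_true(all(unlist(sims) %in% c("a", "b")))
})

test_that("bias statistic is the sum of squared deviations", {
  expect_equal(bias_variance(c(0, 0, 0, 0)), 0)
  expect_equal(bias_variance(c(1, -1, 2, -2)), 10)
  # with generator SD 5 over 4 locations the expected bias is 4 * 25 = 100
  p <- generate_subject_profiles(200, c(ab = 5),
                                 locations = c(45, 135, 225, 315), seed = 8)
  p$delta_pse <- p$true_pse - 50
  b <- aggregate(delta_pse ~ subject_id, p, bias_variance)
  expect_gt(mean(b$delta_pse), 79)
  expect_lt(mean(b$delta_pse), 121)
})

test_that("bias_scores aggregates per subject and morph", {
  tab <- data.frame(subject_id = rep(c("s01", "s02"), each = 2),
                    morph_pair = "ab", delta_pse = c(1, -1, 2, -2))
  b <- bias_scores(tab)
  expect_equal(b$bias, c(2, 8))
})

test_that("per-location logistic readout recovers and flags appropriately", {
  # symmetric deterministic outcomes about 50
  m <- rep(c(0, 17, 33, 50, 67, 83, 100), each = 10)
  y <- ifelse(m < 50, 0L, ifelse(m > 50, 1L, rep(c(0L, 1L), 5)))
  f <- fit_simple_logit(m, y)
  expect_equal(f$pse, 50, tolerance = 1e-6)
  # recovery from a generating logistic at large n
  set.seed(10)
  m2 <- sample(c(0, 17, 33, 50, 67, 83, 100), 10000, replace = TRUE)
  y2 <- rbinom(10000, 1, plogis(0.15 * (m2 - 40)))
  f2 <- fit_simple_logit(m2, y2)
  expect_gt(f2$pse, 39)
  expect_lt(f2$pse, 41)
  expect_false(f2$degenerate)
  # one outcome class: degenerate, no silent number
  f3 <- fit_simple_logit(m, rep(1L, length(m)))
  expect_true(f3$degenerate)
  expect_false(f3$ok)
  expect_true(is.na(f3$pse))
  # at-chance outcomes: statistically indeterminate PSE is flagged
  set.seed(11)
  f4 <- fit_simple_logit(m2, rbinom(10000, 1, 0.5))
  expect_true(f4$indeterminate)
})
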