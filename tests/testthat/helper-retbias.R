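# Shared fixtures, all generated in code.

# One experiment-1-style study: trials for both sessions of n subjects.
make_exp1_study <- function(n_subjects = 4, bias_sd = 5, seed = 1,
                            orthogonal = FALSE) {
  simulate_behavior(1, n_subjects = n_subjects,
                    bias_sd_by_morph = c(ab = bias_sd),
                    orthogonal = orthogonal, seed = seed)
}

# Single-subject trials with a known PSE map, `reps` copies of the
# experiment-1 design per session (10 * reps trials per morph level and
# location).
make_single_subject_trials <- function(true_pse_by_loc, slope = 0.1,
                                       reps = 1, seed = 1) {
  locs <- as.numeric(names(true_pse_by_loc))
  prof <- data.frame(subject_id = "s01", morph_pair = "ab",
                     location_deg = locs,
                     true_pse = unname(true_pse_by_loc))
  attr(prof, "slope") <- slope
  attr(prof, "lapse_third") <- 0
  class(prof) <- c("subject_profiles", "data.frame")
  seeds <- retbias:::split_seed(seed, reps)
  do.call(rbind, lapply(seq_len(reps), function(r) {
    stubs <- generate_design(1, subject_id = "s01", seed = seeds[r])
    stubs <- stubs[stubs$location_deg %in% locs, , drop = FALSE]
    simulate_responses(stubs, prof, seed = seeds[r] + 1L)
  }))
}

# Brute-force two-way ANOVA with interaction (textbook sums of squares),
# independent of stats::aov.
anova_interaction_oracle <- function(subject, location, y) {
  s <- factor(subject); l <- factor(location)
  gm <- mean(y)
  cell <- tapply(y, list(s, l), mean)
  ms <- tapply(y, s, mean)
  ml <- tapply(y, l, mean)
  n_rep <- length(y) / (nlevels(s) * nlevels(l))
  ss_int <- n_rep * sum((cell - outer(ms, rep(1, nlevels(l))) -
                           outer(rep(1, nlevels(s)), ml) + gm)^2)
  fitted_cell <- cell[cbind(as.integer(s), as.integer(l))]
  ss_err <- sum((y - fitted_cell)^2)
  df1 <- (nlevels(s) - 1) * (nlevels(l) - 1)
  df2 <- length(y) - nlevels(s) * nlevels(l)
  list(F = (ss_int / df1) / (ss_err / df2), df1 = df1, df2 = df2)
}

# A tiny two-unit population with explicit parameters.
make_two_units <- function(x0, y0, sigma = 1.5, gain = 1) {
  data.frame(roi = "test", x0_deg = x0, y0_deg = y0, sigma_deg = sigma,
             gain = gain, exponent = 0.2,
             size_deg = sigma / sqrt(0.2),
             identity_pref = c("a", "b"), stringsAsFactors = FALSE)
}
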