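#' Simulate a complete behavioral study
#'
#' Generates ground-truth observer profiles and two sessions of trial data
#' for every subject at the full design scale of the chosen experiment.
#' Profiles are shared across sessions, so any across-session stability in
#' the fitted estimates reflects the generative idiosyncrasy, not reuse of
#' noise.
#'
#' @param experiment 1 (two identities, 8 locations, 560 trials/session) or
#'   2 (three morph pairs, 4 locations, 840 trials/session).
#' @param n_subjects Number of observers (paper-scale defaults: 4 for
#'   experiment 1, 10 for experiment 2 — pass explicitly to change).
#' @param bias_sd_by_morph Named per-pair SD of the true per-location PSE
#'   deviations (morph-%).
#' @param slope True logistic slope per morph-%.
#' @param lapse_third Third-identity lapse probability (experiment 2).
#' @param orthogonal Generate exactly orthogonal subject deviation patterns
#'   (see [generate_subject_profiles()]).
#' @param seed Integer seed fanned out to per-stage child seeds.
#' @return List: `trials` (both sessions, all subjects), `profiles`,
#'   `experiment`, `seed`.
#' @export
simulate_behavior <- function(experiment, n_subjects = if (experiment == 1) 4L else 10L,
                              bias_sd_by_morph = NULL, slope = 0.1,
                              lapse_third = if (experiment == 1) 0 else 0.02,
                              orthogonal = FALSE, seed = 1L) {
  if (is.null(bias_sd_by_morph)) {
    bias_sd_by_morph <- if (experiment == 1) c(ab = 5) else
      c(ab = 3, ac = 5, bc = 7)
  }
  locations <- if (experiment == 1) seq(0, 315, by = 45) else
    c(45, 135, 225, 315)
  seeds <- split_seed(seed, 1L + 2L * n_subjects)
  profiles <- generate_subject_profiles(
    n_subjects, bias_sd_by_morph, locations = locations, slope = slope,
    lapse_third = lapse_third, orthogonal = orthogonal, seed = seeds[1L])
  subjects <- unique(profiles$subject_id)
  trials <- do.call(rbind, lapply(seq_along(subjects), function(k) {
    do.call(rbind, lapply(1:2, function(sess) {
      s_seed <- seeds[1L + 2L * (k - 1L) + sess]
      stubs <- generate_design(experiment, subject_id = subjects[k],
                               session = sess, seed = s_seed)
      simulate_responses(stubs, profiles, seed = s_seed + 1L)
    }))
  }))
  rownames(trials) <- NULL
  list(trials = trials, profiles = profiles, experiment = experiment,
       seed = seed)
}

#' Fit the psychometric model per session and morph pair
#'
#' Removes third-identity lapses, then fits [fit_psychometric()] separately
#' for each session and morph pair (sessions are fit independently so that
#' across-session correlations compare genuinely separate estimates), and
#' stacks the resulting [pse_table()]s.
#'
#' @param trials Trial data frame covering one experiment.
#' @param estimator Passed to [fit_psychometric()].
#' @return List: `pse` (stacked PSE tables with a `session` column),
#'   `fits` (named list of `psyfit` objects), `removed` (lapse trials
#'   dropped).
#' @export
fit_psychometrics_stage <- function(trials, estimator = c("mixed", "fixed")) {
  estimator <- match.arg(estimator)
  filt <- filter_third_identity(trials)
  trials <- filt$trials
  pairs <- sort(unique(trials$morph_pair))
  sessions <- sort(unique(trials$session))
  fits <- list()
  tabs <- list()
  for (sess in sessions) {
    for (mp in pairs) {
      d <- trials[trials$session == sess & trials$morph_pair == mp, ,
                  drop = FALSE]
      fit <- fit_psychometric(d, morph = mp, estimator = estimator)
      tab <- pse_table(fit)
      tab$session <- sess
      key <- paste0(mp, "_s", sess)
      fits[[key]] <- fit
      tabs[[key]] <- tab
    }
  }
  pse <- do.call(rbind, tabs)
  rownames(pse) <- NULL
  list(pse = pse, fits = fits, removed = filt$removed)
}

#' Across-session stability and idiosyncrasy report
#'
#' For each morph pair: the across-session Pearson correlations of the
#' subject-level PSEs and of the delta-PSEs (with BCa CIs), and the
#' within- minus between-subject correlation difference of the delta-PSE
#' profiles. Also reports the across-session delta-PSE correlation pooled
#' over all morph pairs (the single-row-per-experiment convention, df =
#' subjects x locations x pairs - 2) and the correlation of the
#' population-level PSEs.
#'
#' @param pse Stacked PSE table from [fit_psychometrics_stage()].
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return List of class `reliability_report`.
#' @export
reliability_report <- function(pse, n_boot = 10000L, seed = 1L) {
  pairs <- sort(unique(pse$morph_pair))
  seeds <- split_seed(seed, 3L * length(pairs) + 1L)
  per_pair <- list()
  all1 <- NULL; all2 <- NULL
  for (i in seq_along(pairs)) {
    mp <- pairs[i]
    d1 <- pse[pse$morph_pair == mp & pse$session == 1, , drop = FALSE]
    d2 <- pse[pse$morph_pair == mp & pse$session == 2, , drop = FALSE]
    key <- paste(d1$subject_id, d1$location_deg)
    ord <- match(key, paste(d2$subject_id, d2$location_deg))
    d2 <- d2[ord, , drop = FALSE]
    all1 <- rbind(all1, d1); all2 <- rbind(all2, d2)
    delta <- pearson_with_test(d1$delta_pse, d2$delta_pse)
    dd <- cbind(x = d1$delta_pse, y = d2$delta_pse)
    delta$ci <- as.numeric(suppressWarnings(bca_ci(
      dd, function(m) cor(m[, 1L], m[, 2L]), n_boot = n_boot,
      seed = seeds[3L * i - 2L])))
    full <- pearson_with_test(d1$pse, d2$pse)
    pp <- cbind(x = d1$pse, y = d2$pse)
    full$ci <- as.numeric(suppressWarnings(bca_ci(
      pp, function(m) cor(m[, 1L], m[, 2L]), n_boot = n_boot,
      seed = seeds[3L * i - 1L])))
    wb <- within_between_difference(
      rbind(d1, d2), n_boot = n_boot, seed = seeds[3L * i])
    per_pair[[mp]] <- list(delta_pse = delta, pse = full,
                           within_between = wb)
  }
  # delta-PSE stability pooled over morph pairs (n = subjects x locations
  # x pairs, as in a single correlation table row per experiment)
  pooled <- pearson_with_test(all1$delta_pse, all2$delta_pse)
  pd <- cbind(x = all1$delta_pse, y = all2$delta_pse)
  pooled$ci <- as.numeric(suppressWarnings(bca_ci(
    pd, function(m) cor(m[, 1L], m[, 2L]), n_boot = n_boot,
    seed = seeds[length(seeds)] + 1L)))

  # population PSE stability: one value per location (x pair)
  p1 <- aggregate(pse_pop ~ location_deg + morph_pair, all1, mean)
  p2 <- aggregate(pse_pop ~ location_deg + morph_pair, all2, mean)
  ord <- match(paste(p1$location_deg, p1$morph_pair),
               paste(p2$location_deg, p2$morph_pair))
  pop <- pearson_with_test(p1$pse_pop, p2$pse_pop[ord])
  mpp <- cbind(x = p1$pse_pop, y = p2$pse_pop[ord])
  pop$ci <- as.numeric(suppressWarnings(bca_ci(
    mpp, function(m) cor(m[, 1L], m[, 2L]), n_boot = n_boot,
    seed = seeds[length(seeds)])))
  structure(list(per_pair = per_pair, delta_pse_pooled = pooled,
                 population_pse = pop, n_boot = n_boot, seed = seed),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  for (mp in names(x$per_pair)) {
    p <- x$per_pair[[mp]]
    cat("Morph '", mp, "':\n  delta-PSE  ", sep = "")
    print(p$delta_pse)
    cat("  PSE        ")
    print(p$pse)
    cat("  ")
    print(p$within_between)
  }
  cat("delta-PSE pooled over pairs ")
  print(x$delta_pse_pooled)
  cat("Population PSE ")
  print(x$population_pse)
  invisible(x)
}

#' Familiarity stage: composite scores and bias regressions
#'
#' Averages each subject's delta-PSE across sessions, computes the bias
#' statistic per subject x morph pair, builds composite familiarity and
#' contact scores, and runs the nested regressions of
#' [bias_regressions()].
#'
#' @param pse Stacked PSE table (both sessions).
#' @param ratings Questionnaire ratings data frame.
#' @param session_average `"delta"` (default: average delta-PSE across
#'   sessions, then square-and-sum) or `"bias"` (average the per-session
#'   bias scores).
#' @param n_boot,seed Passed to [bias_regressions()].
#' @return List of class `familiarity_report`: `scores`, `bias`,
#'   `regressions`, `scale_correlations`.
#' @export
familiarity_report <- function(pse, ratings,
                               session_average = c("delta", "bias"),
                               n_boot = 10000L, seed = 1L) {
  session_average <- match.arg(session_average)
  if (session_average == "delta") {
    avg <- aggregate(delta_pse ~ subject_id + morph_pair + location_deg,
                     data = pse, FUN = mean)
    bias <- bias_scores(avg)
  } else {
    per_sess <- lapply(split(pse, pse$session), bias_scores)
    stacked <- do.call(rbind, per_sess)
    bias <- aggregate(bias ~ subject_id + morph_pair, data = stacked,
                      FUN = mean)
  }
  scores <- composite_scores(ratings,
                             morph_pairs = sort(unique(bias$morph_pair)))
  reg <- bias_regressions(bias, scores, n_boot = n_boot, seed = seed)
  structure(list(scores = scores, bias = bias, regressions = reg,
                 scale_correlations = scale_intercorrelations(ratings)),
            class = "familiarity_report")
}

#' @export
print.familiarity_report <- function(x, ...) {
  cat(sprintf("Scale intercorrelations: min r = %.2f, max r = %.2f\n",
              x$scale_correlations$min, x$scale_correlations$max))
  print(x$regressions)
  invisible(x)
}

#' End-to-end seeded replica run
#'
#' Chains every stage at the chosen scale: synthetic behavioral generation
#' for both experiments, per-session psychometric fits, reliability and
#' familiarity reports, and a reduced ratio sweep of the neural-population
#' simulation. All randomness derives from one seed via deterministic
#' child seeds, and the configuration is echoed in the bundle.
#'
#' @param seed Integer master seed.
#' @param n_subjects_exp1,n_subjects_exp2 Study sizes.
#' @param estimator Psychometric estimator (see [fit_psychometric()]).
#' @param familiarity_link Scaling from familiarity to the generative
#'   delta-PSE SD: `sd = link_base - link_slope * familiarity` (clamped at
#'   0.5), encoding the familiarity-dependent shrinkage of the bias.
#' @param n_boot Bootstrap replicates for the report CIs.
#' @param sweep_experiments Experiments per ratio condition in the reduced
#'   css sweep (0 skips the sweep).
#' @param sweep_values Ratio conditions for the sweep.
#' @param prf_pool_size Units in the IOG-like parameter pool.
#' @return List of class `replica_bundle` with every stage's output and a
#'   `provenance` record (seed, child seeds, parameters).
#' @export
full_replica <- function(seed = 1L, n_subjects_exp1 = 4L,
                         n_subjects_exp2 = 10L,
                         estimator = "mixed",
                         familiarity_link = c(base = 9, slope = 1.2),
                         n_boot = 2000L, sweep_experiments = 50L,
                         sweep_values = c(1L, 9L), prf_pool_size = 2000L) {
  seeds <- split_seed(seed, 8L)
  exp1 <- simulate_behavior(1, n_subjects = n_subjects_exp1,
                            seed = seeds[1L])
  stage1 <- fit_psychometrics_stage(exp1$trials, estimator = estimator)
  rel1 <- reliability_report(stage1$pse, n_boot = n_boot, seed = seeds[2L])

  # questionnaires first: familiarity determines the generative bias SD
  q <- generate_questionnaires(n_subjects_exp2,
                               familiarity_means = c(a = 5.5, b = 4.5, c = 3),
                               seed = seeds[3L])
  sc <- composite_scores(q$ratings, morph_pairs = c("ab", "ac", "bc"))
  sd_map <- sc$by_morph[, c("subject_id", "morph_pair")]
  sd_map$sd <- pmax(0.5, familiarity_link[["base"]] -
                      familiarity_link[["slope"]] * sc$by_morph$familiarity)
  exp2 <- simulate_behavior(2, n_subjects = n_subjects_exp2,
                            bias_sd_by_morph = sd_map, seed = seeds[4L])
  stage2 <- fit_psychometrics_stage(exp2$trials, estimator = estimator)
  rel2 <- reliability_report(stage2$pse, n_boot = n_boot, seed = seeds[5L])
  fam <- familiarity_report(stage2$pse, q$ratings, n_boot = n_boot,
                            seed = seeds[6L])

  sweep <- NULL
  if (sweep_experiments > 0L) {
    pool <- generate_prf_population(prf_spec("IOG", n_units = prf_pool_size),
                                    seed = seeds[7L])
    sweep <- sweep_bias(pool, axis = "ratio", values = sweep_values,
                        n_experiments = sweep_experiments, seed = seeds[8L])
  }
  structure(list(
    exp1 = list(trials = exp1$trials, pse = stage1$pse, reliability = rel1,
                removed = stage1$removed),
    exp2 = list(trials = exp2$trials, pse = stage2$pse, reliability = rel2,
                removed = stage2$removed, familiarity = fam,
                questionnaires = q$ratings),
    css_sweep = sweep,
    provenance = list(seed = seed, child_seeds = seeds,
                      estimator = estimator, n_boot = n_boot,
                      familiarity_link = familiarity_link,
                      generated = "synthetic")
  ), class = "replica_bundle")
}

#' Write the tabular pieces of a replica bundle to CSV
#'
#' @param bundle A [full_replica()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    trials_exp1 = file.path(dir, "trials_exp1.csv"),
    trials_exp2 = file.path(dir, "trials_exp2.csv"),
    pse_exp1 = file.path(dir, "pse_exp1.csv"),
    pse_exp2 = file.path(dir, "pse_exp2.csv"),
    questionnaires = file.path(dir, "questionnaires.csv")
  )
  write.csv(bundle$exp1$trials, paths["trials_exp1"], row.names = FALSE)
  write.csv(bundle$exp2$trials, paths["trials_exp2"], row.names = FALSE)
  write.csv(bundle$exp1$pse, paths["pse_exp1"], row.names = FALSE)
  write.csv(bundle$exp2$pse, paths["pse_exp2"], row.names = FALSE)
  write.csv(bundle$exp2$questionnaires, paths["questionnaires"],
            row.names = FALSE)
  if (!is.null(bundle$css_sweep)) {
    p <- file.path(dir, "css_sweep.csv")
    write.csv(as.data.frame(bundle$css_sweep), p, row.names = FALSE)
    paths <- c(paths, css_sweep = p)
  }
  invisible(paths)
}
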