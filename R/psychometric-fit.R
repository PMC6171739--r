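#' Fit the location-indexed logit psychometric model
#'
#' Fits the group-level psychometric curve for one morph continuum: the
#' probability of reporting the second identity of the pair is modeled as
#' `logit^-1(beta0 * morph_pct + beta_i + z_ik)` with a shared slope `beta0`
#' per morph-%, a fixed effect `beta_i` per angular location `i`, and a
#' random intercept `z_ik` per subject `k` x location (a single shared
#' variance component). From this model each subject's point of subjective
#' equality (PSE) at each location decomposes exactly into a
#' population-level PSE and a subject-specific deviation; see [pse_table()].
#'
#' Two estimators are available. `"mixed"` (the default for two or more
#' subjects) maximizes the Laplace-approximate marginal likelihood via
#' [lme4::glmer()]. `"fixed"` replaces the random intercepts by
#' subject-by-location fixed intercepts in an ordinary logistic regression
#' with shared slope; deviations are then centered across subjects within
#' each location. The fixed estimator is exact for a single subject (where
#' the random effect is degenerate and `z` is fixed at 0) and is the fast
#' path for large simulation studies; the decomposition contract is
#' identical.
#'
#' @param trials Data frame of trials (as from [generate_design()] +
#'   [simulate_responses()]): columns `subject_id`, `morph_pair`,
#'   `morph_pct`, `location_deg`, `response`. Responses must belong to the
#'   morph pair — remove third-identity lapses first with
#'   [filter_third_identity()].
#' @param morph Morph pair to fit (required when several are present).
#' @param estimator `"mixed"` (lme4 Laplace) or `"fixed"` (shared-slope
#'   logistic regression with subject x location intercepts).
#' @param nAGQ Integration accuracy passed to [lme4::glmer()] (0 = fast
#'   penalized-likelihood approximation, 1 = Laplace).
#' @param max_iter Optimizer iteration cap.
#' @return An object of class `psyfit` with components `beta0`, `beta_loc`
#'   (named by location), `z` (subjects x locations matrix of deviations),
#'   `z_variance`, `morph_pair`, `estimator`, `converged`, `model` (the
#'   underlying fit) and bookkeeping fields. Non-convergence is an error
#'   carrying the optimizer diagnostics, never a silent fallback.
#' @examples
#' prof <- generate_subject_profiles(3, c(ab = 5), locations = c(45, 135, 225, 315),
#'                                   seed = 2)
#' trials <- do.call(rbind, lapply(sprintf("s%02d", 1:3), function(s)
#'   simulate_responses(generate_design(2, subject_id = s, seed = 3),
#'                      prof, seed = match(s, sprintf("s%02d", 1:3)))))
#' trials <- filter_third_identity(trials)$trials
#' fit <- fit_psychometric(trials, morph = "ab", estimator = "fixed")
#' head(pse_table(fit))
#' @seealso [pse_table()], [bias_scores()], [fit_simple_logit()]
#' @export
fit_psychometric <- function(trials, morph = NULL,
                             estimator = c("mixed", "fixed"),
                             nAGQ = 1L, max_iter = 500L) {
  estimator <- match.arg(estimator)
  pairs <- unique(trials$morph_pair)
  if (is.null(morph)) {
    if (length(pairs) > 1L) {
      stop("several morph pairs present (", paste(pairs, collapse = ", "),
           "); pick one with `morph`")
    }
    morph <- pairs
  }
  d <- trials[trials$morph_pair == morph, , drop = FALSE]
  if (nrow(d) == 0L) stop("no trials for morph pair '", morph, "'")
  ids <- pair_identities(morph)[[1L]]
  bad <- !d$response %in% ids
  if (any(bad)) {
    stop(sum(bad), " trial(s) have responses outside morph pair '", morph,
         "'; run filter_third_identity() first")
  }
  d$y <- as.integer(d$response == ids[2L])
  if (length(unique(d$morph_pct[d$y == 1L])) < 1L ||
      length(unique(d$morph_pct)) < 2L) {
    stop("need at least two morph levels with both responses represented")
  }
  locs <- sort(unique(d$location_deg))
  subjects <- sort(unique(d$subject_id))
  d$loc <- factor(d$location_deg, levels = locs)
  if (length(subjects) == 1L && estimator == "mixed") estimator <- "fixed"

  if (estimator == "mixed") {
    d$subj_loc <- interaction(d$subject_id, d$loc, drop = TRUE, sep = ":")
    ctrl <- lme4::glmerControl(
      optimizer = "bobyqa",
      optCtrl = list(maxfun = max_iter * 100L),
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)
    )
    fit <- lme4::glmer(y ~ 0 + loc + morph_pct + (1 | subj_loc),
                       data = d, family = binomial(), nAGQ = nAGQ,
                       control = ctrl)
    msgs <- fit@optinfo$conv$lme4$messages
    failed <- any(grepl("failed to converge", msgs %||% character()))
    if (failed) {
      stop(structure(class = c("retbias_fit_error", "error", "condition"),
                     list(message = paste0(
                       "mixed logit did not converge for morph '", morph,
                       "': ", paste(msgs, collapse = "; ")),
                       call = sys.call(-1))))
    }
    fe <- lme4::fixef(fit)
    beta0 <- unname(fe["morph_pct"])
    beta_loc <- setNames(unname(fe[paste0("loc", locs)]), locs)
    re <- lme4::ranef(fit)$subj_loc
    z <- matrix(0, nrow = length(subjects), ncol = length(locs),
                dimnames = list(subjects, locs))
    key <- do.call(rbind, strsplit(rownames(re), ":", fixed = TRUE))
    z[cbind(match(key[, 1L], subjects), match(key[, 2L], as.character(locs)))] <-
      re[["(Intercept)"]]
    z_variance <- as.numeric(lme4::VarCorr(fit)$subj_loc[1L, 1L])
    converged <- TRUE
  } else {
    d$subj_loc <- interaction(d$subject_id, d$loc, drop = TRUE, sep = ":")
    fit <- withCallingHandlers(
      glm(y ~ 0 + subj_loc + morph_pct, data = d, family = binomial(),
          control = list(maxit = max_iter)),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!fit$converged) {
      stop(structure(class = c("retbias_fit_error", "error", "condition"),
                     list(message = paste0(
                       "fixed-intercept logit did not converge for morph '",
                       morph, "'"), call = sys.call(-1))))
    }
    cf <- coef(fit)
    beta0 <- unname(cf["morph_pct"])
    cells <- matrix(NA_real_, nrow = length(subjects), ncol = length(locs),
                    dimnames = list(subjects, locs))
    for (s in subjects) for (l in as.character(locs)) {
      nm <- paste0("subj_loc", s, ":", l)
      if (nm %in% names(cf)) cells[s, l] <- cf[nm]
    }
    if (anyNA(cells)) stop("incomplete subject x location design")
    beta_loc <- setNames(colMeans(cells), locs)
    z <- sweep(cells, 2L, beta_loc)
    z_variance <- if (length(subjects) > 1L) mean(apply(z, 2L, var)) else 0
    converged <- TRUE
  }

  structure(list(
    beta0 = beta0, beta_loc = beta_loc, z = z, z_variance = z_variance,
    morph_pair = morph, n_locations = length(locs), locations = locs,
    subjects = subjects, n_trials = nrow(d), estimator = estimator,
    converged = converged, model = fit, call = match.call()
  ), class = "psyfit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.psyfit <- function(x, ...) {
  cat("Logit psychometric fit (", x$estimator, ") for morph '",
      x$morph_pair, "'\n", sep = "")
  cat("  ", length(x$subjects), " subject(s), ", x$n_locations,
      " locations, ", x$n_trials, " trials\n", sep = "")
  cat("  slope beta0 =", format(x$beta0, digits = 4),
      "per morph-%;  random-intercept variance =",
      format(x$z_variance, digits = 4), "\n")
  pp <- -x$beta_loc / x$beta0
  cat("  population PSE by location:\n")
  print(round(pp, 2))
  invisible(x)
}

#' @export
coef.psyfit <- function(object, ...) {
  c(setNames(object$beta0, "morph_pct"),
    setNames(object$beta_loc, paste0("loc", object$locations)))
}

#' @export
summary.psyfit <- function(object, ...) {
  tab <- pse_table(object)
  out <- list(
    morph_pair = object$morph_pair, estimator = object$estimator,
    beta0 = object$beta0, z_variance = object$z_variance,
    pse_pop = setNames(-object$beta_loc / object$beta0, object$locations),
    delta_pse_sd = sd(tab$delta_pse), n_subjects = length(object$subjects),
    n_trials = object$n_trials
  )
  class(out) <- "summary.psyfit"
  out
}

#' @export
print.summary.psyfit <- function(x, ...) {
  cat("Morph '", x$morph_pair, "': beta0 = ", format(x$beta0, digits = 4),
      ", z variance = ", format(x$z_variance, digits = 4), "\n", sep = "")
  cat("Population PSE (morph-%):\n")
  print(round(x$pse_pop, 2))
  cat("SD of subject delta-PSE:", format(x$delta_pse_sd, digits = 4), "\n")
  invisible(x)
}

#' Predict response probabilities from a psychometric fit
#'
#' @param object A [fit_psychometric()] object.
#' @param newdata Data frame with `morph_pct`, `location_deg` and (for
#'   subject-level predictions) `subject_id`; unknown subjects get the
#'   population curve (`z = 0`).
#' @param type `"response"` for probabilities of reporting the second
#'   identity, `"link"` for the linear predictor.
#' @param ... Unused.
#' @export
predict.psyfit <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  li <- match(as.character(newdata$location_deg),
              as.character(object$locations))
  if (anyNA(li)) stop("unknown location in `newdata`")
  z <- rep(0, nrow(newdata))
  if (!is.null(newdata$subject_id)) {
    si <- match(newdata$subject_id, object$subjects)
    known <- !is.na(si)
    z[known] <- object$z[cbind(si[known], li[known])]
  }
  eta <- object$beta0 * newdata$morph_pct + object$beta_loc[li] + z
  if (type == "link") unname(eta) else unname(plogis(eta))
}

#' Simulate identity responses from a fitted psychometric model
#'
#' Draws Bernoulli responses at the fitted subject-level probabilities for
#' a given trial design, returning identity labels — the model-based twin
#' of [simulate_responses()].
#'
#' @param object A `psyfit`.
#' @param nsim Number of simulated response sets.
#' @param seed Optional integer seed.
#' @param newdata Trial design data frame (defaults must be supplied by the
#'   caller; columns as in [predict.psyfit()]).
#' @param ... Unused.
#' @return A data frame with `nsim` columns of identity labels.
#' @export
simulate.psyfit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  p <- predict(object, newdata)
  ids <- pair_identities(object$morph_pair)[[1L]]
  sims <- with_seed(seed, replicate(nsim, ifelse(runif(length(p)) < p,
                                                 ids[2L], ids[1L]),
                                    simplify = FALSE))
  out <- as.data.frame(sims, stringsAsFactors = FALSE)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot fitted psychometric curves by location
#'
#' Draws the population-level psychometric curve for each angular location
#' over the morph axis.
#'
#' @param x A `psyfit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.psyfit <- function(x, ...) {
  m <- seq(0, 100, by = 1)
  curves <- vapply(seq_along(x$locations), function(i)
    plogis(x$beta0 * m + x$beta_loc[i]), numeric(length(m)))
  graphics::matplot(m, curves, type = "l", lty = 1,
                    xlab = "morph (% toward second identity)",
                    ylab = "P(second identity)",
                    main = paste0("Morph '", x$morph_pair,
                                  "': population curves by location"), ...)
  graphics::abline(h = 0.5, lty = 3)
  graphics::legend("topleft", legend = paste0(x$locations, "°"),
                   col = seq_along(x$locations), lty = 1, cex = 0.7,
                   bty = "n")
  invisible(x)
}
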