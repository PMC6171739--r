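#' Binary contrast map for a disc stimulus at a polar location
#'
#' Builds the contrast map of a circular stimulus: a disc of ones on a
#' square visual-field window of zeros. Cell values are evaluated at pixel
#' centers (midpoint rule).
#'
#' @param location_deg Polar angle of the stimulus center, degrees.
#' @param eccentricity Eccentricity of the stimulus center, degrees.
#' @param diameter Stimulus diameter, degrees.
#' @param extent Window side length, degrees (window is centered at
#'   fixation).
#' @param resolution Pixels per degree.
#' @return List of class `stimulus_map`: `grid` (matrix), `xs`, `ys`
#'   (pixel-center coordinates), `px_area`, `center` (stimulus center),
#'   plus the input parameters.
#' @examples
#' s <- make_stimulus_map(45)
#' s$center                       # ~ (4.95, 4.95)
#' @export
make_stimulus_map <- function(location_deg, eccentricity = 7, diameter = 4,
                              extent = 21, resolution = 10) {
  if (eccentricity + diameter / 2 > extent / 2) {
    stop("stimulus disc would be clipped by the window; enlarge `extent`")
  }
  h <- 1 / resolution
  n <- round(extent * resolution)
  xs <- -extent / 2 + h * (seq_len(n) - 0.5)
  ys <- xs
  theta <- location_deg * pi / 180
  cx <- eccentricity * cos(theta)
  cy <- eccentricity * sin(theta)
  gx <- matrix(xs, n, n)
  gy <- matrix(ys, n, n, byrow = TRUE)
  grid <- (gx - cx)^2 + (gy - cy)^2 <= (diameter / 2)^2
  structure(list(grid = grid * 1, xs = xs, ys = ys, px_area = h^2,
                 center = c(x = cx, y = cy), location_deg = location_deg,
                 eccentricity = eccentricity, diameter = diameter,
                 extent = extent, resolution = resolution),
            class = "stimulus_map")
}

#' Full-field stimulus map (constant contrast 1)
#'
#' Useful as the normalization anchor: a unit-volume Gaussian receptive
#' field fully inside the window integrates to 1, so the CSS response to a
#' full-field stimulus equals the unit's gain.
#'
#' @inheritParams make_stimulus_map
#' @export
full_field_map <- function(extent = 21, resolution = 10) {
  s <- make_stimulus_map(0, eccentricity = 0, diameter = 0,
                         extent = extent, resolution = resolution)
  s$grid[] <- 1
  s$center <- c(x = 0, y = 0)
  s
}

#' Compressive spatial summation (CSS) response
#'
#' Response of a receptive-field unit to a contrast map: the stimulus is
#' integrated under a unit-volume 2-D isotropic Gaussian centered at the
#' receptive-field position (`a`), then passed through a compressive power
#' law, `r = gain * a^n` with exponent `n < 1` producing subadditive
#' spatial summation. The integral is a midpoint Riemann sum with
#' pixel-area weighting over the nonzero stimulus pixels.
#'
#' @param units A `prf_units` data frame (or any data frame with `x0_deg`,
#'   `y0_deg`, `sigma_deg`, `gain`, `exponent`).
#' @param stim A [make_stimulus_map()] object.
#' @return Numeric vector of nonnegative responses, one per unit.
#' @export
css_response <- function(units, stim) {
  stopifnot(inherits(stim, "stimulus_map"))
  if (any(units$sigma_deg <= 0)) stop("sigma must be positive")
  idx <- which(stim$grid != 0)
  if (length(idx) == 0L) return(numeric(nrow(units)) * units$gain)
  n <- length(stim$xs)
  px <- stim$xs[(idx - 1L) %% n + 1L]
  py <- stim$ys[(idx - 1L) %/% n + 1L]
  sv <- stim$grid[idx]
  a <- vapply(seq_len(nrow(units)), function(u) {
    s2 <- units$sigma_deg[u]^2
    dens <- exp(-((px - units$x0_deg[u])^2 + (py - units$y0_deg[u])^2) /
                  (2 * s2)) / (2 * pi * s2)
    sum(dens * sv) * stim$px_area
  }, numeric(1))
  units$gain * a^units$exponent
}

#' Configuration of one simulated identification experiment
#'
#' Collects every tunable parameter of the neural-population simulation:
#' the ratio of units preferring identity a to identity b (`N_b` is fixed
#' at 1), gain and receptive-field-size manipulations of the a-units,
#' trial counts, stimulus geometry and noise level.
#'
#' @param ratio Integer >= 1, number of a-units per b-unit.
#' @param gain_a Gain multiplier applied to a-units (b-units keep gain 1).
#' @param rf_inflation_a Fractional increase of a-unit sigma (0-0.5).
#' @param noise_sd SD of the i.i.d. Gaussian response noise per unit and
#'   trial.
#' @param learn_trials Trials per identity x location in the learning
#'   phase.
#' @param test_trials Trials per location x morph level in the test phase.
#' @param locations Angular stimulus locations (degrees).
#' @param morph_levels Morph percentages presented.
#' @param eccentricity,diameter,extent,resolution Stimulus-map geometry
#'   (see [make_stimulus_map()]).
#' @param max_resample Maximum fresh-noise resamples of an experiment whose
#'   per-location psychometric fit fails.
#' @return List of class `css_config`.
#' @export
css_config <- function(ratio = 1L, gain_a = 1, rf_inflation_a = 0,
                       noise_sd = 0.1, learn_trials = 10L, test_trials = 10L,
                       locations = c(45, 135, 225, 315),
                       morph_levels = c(0, 17, 33, 50, 67, 83, 100),
                       eccentricity = 7, diameter = 4, extent = 21,
                       resolution = 10, max_resample = 20L) {
  stopifnot(ratio >= 1, gain_a > 0, rf_inflation_a >= 0, noise_sd >= 0,
            learn_trials >= 1, test_trials >= 1)
  structure(as.list(environment()), class = "css_config")
}

#' Assemble the unit population for one simulated experiment
#'
#' Samples `ratio + 1` units without replacement from a parameter pool,
#' assigns the first `ratio` to identity a and one to identity b, and
#' applies the gain / receptive-field manipulations to the a-units.
#'
#' @param pool A `prf_units` pool (see [generate_prf_population()]).
#' @param config A [css_config()].
#' @return `prf_units` data frame with an `identity_pref` column.
#' @export
sample_population <- function(pool, config) {
  n <- config$ratio + 1L
  if (nrow(pool) < n) {
    stop("parameter pool too small: need ", n, " units, have ", nrow(pool))
  }
  units <- pool[sample.int(nrow(pool), n, replace = FALSE), , drop = FALSE]
  units$identity_pref <- c(rep("a", config$ratio), "b")
  is_a <- units$identity_pref == "a"
  units$gain[is_a] <- units$gain[is_a] * config$gain_a
  units$sigma_deg[is_a] <- units$sigma_deg[is_a] * (1 + config$rf_inflation_a)
  rownames(units) <- NULL
  units
}

#' Noisy population response to a morphed stimulus
#'
#' A morph `m`% of the way toward identity b drives each unit at a fraction
#' of its full-identity CSS response: weight `1 - m/100` for a-preferring
#' units and `m/100` for b-preferring units (linear morph-response
#' assumption). I.i.d. Gaussian noise is added per unit and trial; each
#' unit's noise SD is `noise_sd * gain`, because a gain modulation
#' amplifies the unit's whole output — the stimulus-driven response and the
#' unit's intrinsic variability alike — and therefore cannot add
#' information that the spatial sampling does not contain.
#'
#' @param units Population with `identity_pref` (see
#'   [sample_population()]).
#' @param morph_pct Morph percentage toward identity b, in `[0, 100]`.
#' @param responses Vector of per-unit CSS responses to the stimulus at the
#'   presented location (from [css_response()]).
#' @param noise_sd Baseline noise SD (per unit of gain).
#' @param n_trials Number of trials to draw.
#' @return Matrix `n_trials` x `n_units` of noisy activations.
#' @export
population_response <- function(units, morph_pct, responses, noise_sd,
                                n_trials = 1L) {
  stopifnot(morph_pct >= 0, morph_pct <= 100,
            length(responses) == nrow(units))
  m <- morph_pct / 100
  w <- ifelse(units$identity_pref == "b", m, 1 - m)
  mu <- w * responses
  sds <- rep(noise_sd * units$gain, each = n_trials)
  noise <- matrix(rnorm(n_trials * length(mu), 0, sds), nrow = n_trials)
  sweep(noise, 2L, mu, `+`)
}

# Per-unit CSS responses to each stimulus location (units x locations).
location_responses <- function(units, config) {
  maps <- lapply(config$locations, make_stimulus_map,
                 eccentricity = config$eccentricity,
                 diameter = config$diameter, extent = config$extent,
                 resolution = config$resolution)
  vapply(maps, function(s) css_response(units, s), numeric(nrow(units)))
}

#' Train the identity decoder on full-identity responses
#'
#' Learning phase: noisy population responses to the unmorphed identities a
#' and b at every stimulus location (`learn_trials` per identity x
#' location) train a linear support vector machine (cost 1) to classify the
#' reported identity from the activation pattern. Features are standardized
#' before training (the SVM default) whenever the configuration is noisy;
#' noise-free configurations skip scaling, where it is undefined for
#' constant features.
#'
#' @param units Population with `identity_pref`.
#' @param config A [css_config()].
#' @param loc_resp Optional precomputed [location_responses] matrix.
#' @return List of class `css_decoder`: `model` (e1071 svm), `accuracy`
#'   (training accuracy), `n_train`.
#' @export
run_learning_phase <- function(units, config, loc_resp = NULL) {
  if (is.null(loc_resp)) loc_resp <- location_responses(units, config)
  X <- NULL; labels <- character()
  for (l in seq_along(config$locations)) {
    for (id in c("a", "b")) {
      m <- if (id == "a") 0 else 100
      X <- rbind(X, population_response(units, m, loc_resp[, l],
                                        config$noise_sd,
                                        config$learn_trials))
      labels <- c(labels, rep(id, config$learn_trials))
    }
  }
  if (all(apply(X, 2L, function(col) length(unique(col)) == 1L)) ||
      nrow(unique(X)) == 1L) {
    stop("degenerate training set: all patterns identical")
  }
  model <- e1071::svm(x = X, y = factor(labels, levels = c("a", "b")),
                      kernel = "linear", cost = 1,
                      scale = config$noise_sd > 0)
  acc <- mean(decode_labels(model, X) == labels)
  structure(list(model = model, accuracy = acc, n_train = nrow(X)),
            class = "css_decoder")
}

# Hard labels from SVM decision values with a deterministic alternating
# tie-break at decision values that are zero to numerical precision
# (relevant only for noise-free symmetric configurations, where it
# preserves the analytic 50% anchor).
decode_labels <- function(model, X, tie_tol = 1e-10) {
  pr <- predict(model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  positive <- strsplit(colnames(dv), "/", fixed = TRUE)[[1L]]
  lab <- ifelse(dv[, 1L] > 0, positive[1L], positive[2L])
  ties <- which(abs(dv[, 1L]) <= tie_tol)
  if (length(ties)) {
    lab[ties] <- ifelse(seq_along(ties) %% 2L == 1L, positive[1L],
                        positive[2L])
  }
  unname(lab)
}

#' Run one simulated identification experiment
#'
#' Learning phase ([run_learning_phase()]), then `test_trials` noisy
#' responses per location x morph level are decoded to identity labels and
#' each location's labels are fit with a per-location logistic regression
#' ([fit_simple_logit()]) to estimate a PSE. The experiment's bias is the
#' sum over locations of squared PSE deviations from 50%. Experiments in
#' which any per-location fit is degenerate or fails get fresh noise —
#' learning phase included — counted in `failed_fits`, up to
#' `config$max_resample` times. A population for which some location stays
#' unidentifiable under every redraw cannot measure identity there at all:
#' its bias is unbounded, and the result carries `pse_variance = Inf` with
#' `identifiable = FALSE` (medians and bootstrap CIs across experiments
#' remain well defined).
#'
#' @param units Population with `identity_pref` (see
#'   [sample_population()]).
#' @param config A [css_config()].
#' @param seed Optional integer seed.
#' @return List of class `css_result`: `pse_by_location`, `pse_variance`,
#'   `decoder_accuracy_learning`, `failed_fits`, `identifiable`.
#' @export
run_css_experiment <- function(units, config, seed = NULL) {
  with_seed(seed, {
    loc_resp <- location_responses(units, config)
    failed <- 0L
    repeat {
      # the whole experiment (learning included) is redrawn on failure
      decoder <- run_learning_phase(units, config, loc_resp)
      pses <- rep(NA_real_, length(config$locations))
      ok <- TRUE
      for (l in seq_along(config$locations)) {
        X <- NULL
        morphs <- rep(config$morph_levels, each = config$test_trials)
        for (m in config$morph_levels) {
          X <- rbind(X, population_response(units, m, loc_resp[, l],
                                            config$noise_sd,
                                            config$test_trials))
        }
        y <- as.integer(decode_labels(decoder$model, X) == "b")
        fit <- fit_simple_logit(morphs, y)
        if (!fit$ok) { ok <- FALSE; break }
        pses[l] <- fit$pse
      }
      if (ok) break
      failed <- failed + 1L
      if (failed > config$max_resample) break
    }
    structure(list(
      pse_by_location = setNames(pses, config$locations),
      pse_variance = if (ok) sum((pses - 50)^2) else Inf,
      decoder_accuracy_learning = decoder$accuracy,
      failed_fits = failed, identifiable = ok
    ), class = "css_result")
  })
}

#' @export
print.css_result <- function(x, ...) {
  cat("Simulated experiment: PSE by location (morph-%):\n")
  print(round(x$pse_by_location, 2))
  cat(sprintf("PSE variance about 50%%: %.2f; learning accuracy %.2f; %d resample(s)\n",
              x$pse_variance, x$decoder_accuracy_learning, x$failed_fits))
  invisible(x)
}

#' Proportion of units whose receptive field covers the stimuli
#'
#' A unit covers a stimulus location when the stimulus disc intersects the
#' circle of radius `radius_multiplier * sigma` around the unit's center.
#' Returns the mean over locations of the covered fraction of units.
#'
#' @param units A `prf_units` data frame.
#' @param locations Angular stimulus locations (degrees).
#' @param eccentricity,diameter Stimulus geometry.
#' @param radius_multiplier Receptive-field radius in units of sigma
#'   (default 2).
#' @return Scalar in `[0, 1]`.
#' @export
coverage_proportion <- function(units, locations = c(45, 135, 225, 315),
                                eccentricity = 7, diameter = 4,
                                radius_multiplier = 2) {
  stopifnot(nrow(units) >= 1L)
  theta <- locations * pi / 180
  cx <- eccentricity * cos(theta)
  cy <- eccentricity * sin(theta)
  cover <- vapply(seq_along(locations), function(l) {
    d <- sqrt((units$x0_deg - cx[l])^2 + (units$y0_deg - cy[l])^2)
    mean(d <= radius_multiplier * units$sigma_deg + diameter / 2)
  }, numeric(1))
  mean(cover)
}
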