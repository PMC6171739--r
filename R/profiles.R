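#' Generate ground-truth psychometric observer profiles
#'
#' Each simulated observer has a true point of subjective equality (PSE) for
#' every (morph pair, angular location) cell: `true_pse = 50 + delta`, with
#' `delta` drawn independently per subject x location from a zero-mean
#' Gaussian whose SD is set per morph pair. The SD is the generative knob for
#' idiosyncratic retinotopic bias: a smaller SD plays the role of higher
#' familiarity with the identities of that pair. Profiles are constant across
#' sessions — stability of the bias is the generative assumption.
#'
#' @param n_subjects Number of observers (>= 1).
#' @param bias_sd_by_morph Either a named numeric vector mapping morph pair
#'   (e.g. `c(ab = 5)`) to the SD (in morph-%) of the per-location PSE
#'   deviations, or a data frame `subject_id`, `morph_pair`, `sd` giving a
#'   subject-specific SD (e.g. derived from that subject's familiarity with
#'   the identities of the pair); subject ids must then be
#'   `sprintf("s%02d", 1:n_subjects)`.
#' @param locations Angular locations in degrees.
#' @param slope Logistic slope per morph-% (shared across cells).
#' @param lapse_third Probability of responding with the uninvolved third
#'   identity (three-identity experiments only); in `[0, 0.2]`.
#' @param orthogonal If `TRUE`, the subjects' deviation patterns within
#'   each morph pair are Gram-Schmidt orthogonalized across locations (and
#'   rescaled to the target SD), giving exactly uncorrelated idiosyncratic
#'   patterns — useful for power analyses of the within- versus
#'   between-subject contrast. Requires `n_subjects <= length(locations)`
#'   and a positive SD.
#' @param seed Integer seed; identical seeds give identical profiles.
#' @return A data frame of class `subject_profiles` with one row per
#'   subject x morph pair x location (`subject_id`, `morph_pair`,
#'   `location_deg`, `true_pse`) and attributes `slope` and `lapse_third`.
#' @examples
#' p <- generate_subject_profiles(2, c(ab = 5), locations = c(45, 135), seed = 1)
#' @export
generate_subject_profiles <- function(n_subjects, bias_sd_by_morph,
                                      locations, slope = 0.1,
                                      lapse_third = 0, orthogonal = FALSE,
                                      seed = NULL) {
  if (n_subjects < 1) stop("`n_subjects` must be at least 1")
  if (lapse_third < 0 || lapse_third > 0.2) {
    stop("`lapse_third` must lie in [0, 0.2]")
  }
  subjects <- sprintf("s%02d", seq_len(n_subjects))
  per_subject <- is.data.frame(bias_sd_by_morph)
  if (per_subject) {
    stopifnot(all(c("subject_id", "morph_pair", "sd") %in%
                    names(bias_sd_by_morph)))
    pairs <- sort(unique(bias_sd_by_morph$morph_pair))
  } else {
    if (is.null(names(bias_sd_by_morph)) ||
        any(!nzchar(names(bias_sd_by_morph)))) {
      stop("`bias_sd_by_morph` must be named by morph pair")
    }
    pairs <- names(bias_sd_by_morph)
  }
  grid <- expand.grid(
    location_deg = locations, morph_pair = pairs,
    subject_id = subjects, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("subject_id", "morph_pair", "location_deg")]
  sds <- if (per_subject) {
    i <- match(paste(grid$subject_id, grid$morph_pair),
               paste(bias_sd_by_morph$subject_id,
                     bias_sd_by_morph$morph_pair))
    if (anyNA(i)) stop("`bias_sd_by_morph` must cover every subject x pair")
    bias_sd_by_morph$sd[i]
  } else {
    unname(bias_sd_by_morph[grid$morph_pair])
  }
  if (any(sds < 0)) stop("`bias_sd_by_morph` must be >= 0")
  delta <- with_seed(seed, rnorm(nrow(grid), mean = 0, sd = sds))
  if (orthogonal) {
    if (per_subject) stop("`orthogonal` needs a single SD per morph pair")
    if (n_subjects >= length(locations)) {
      stop("orthogonal patterns need n_subjects < number of locations")
    }
    for (mp in pairs) {
      sel <- grid$morph_pair == mp
      m <- matrix(delta[sel], nrow = length(locations))  # locations x subjects
      # orthogonalize against the constant vector too, so the patterns are
      # exactly uncorrelated, and rescale to the target SD
      qr_m <- qr.Q(qr(cbind(1, m)))[, 1L + seq_len(n_subjects), drop = FALSE]
      m <- sweep(qr_m, 2L, apply(qr_m, 2L, sd), `/`) *
        bias_sd_by_morph[[mp]]
      delta[sel] <- as.vector(m)
    }
  }
  grid$true_pse <- pmin(pmax(50 + delta, 0), 100)
  rownames(grid) <- NULL
  structure(grid,
            slope = slope, lapse_third = lapse_third,
            class = c("subject_profiles", "data.frame"))
}

#' Simulate categorical identity responses for a trial design
#'
#' The generative twin of the psychometric model: the probability of
#' reporting the *second* identity of a pair is
#' `plogis(slope * (morph_pct - true_pse))`. In three-identity designs a
#' trial's response is replaced, with probability `lapse_third`, by the
#' identity not involved in the morph pair.
#'
#' @param stubs Trial design as returned by [generate_design()] (the
#'   `subject_id` column selects each trial's profile).
#' @param profiles A `subject_profiles` object covering every
#'   (subject, morph_pair, location) present in `stubs`.
#' @param seed Integer seed; the same design, profiles and seed give
#'   identical responses.
#' @return `stubs` with the `response` column filled with identity labels.
#' @export
simulate_responses <- function(stubs, profiles, seed = NULL) {
  key <- function(d) paste(d$subject_id, d$morph_pair, d$location_deg, sep = "|")
  idx <- match(key(stubs), key(profiles))
  if (anyNA(idx)) {
    missing <- unique(key(stubs)[is.na(idx)])
    stop("no profile for (subject|morph_pair|location): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  slope <- attr(profiles, "slope")
  lapse <- attr(profiles, "lapse_third")
  true_pse <- profiles$true_pse[idx]
  p_second <- plogis(slope * (stubs$morph_pct - true_pse))
  ids <- pair_identities(stubs$morph_pair)
  first <- vapply(ids, `[`, character(1), 1L)
  second <- vapply(ids, `[`, character(1), 2L)
  out <- stubs
  with_seed(seed, {
    pick_second <- runif(nrow(stubs)) < p_second
    out$response <- ifelse(pick_second, second, first)
    if (lapse > 0) {
      lapsed <- runif(nrow(stubs)) < lapse
      if (any(lapsed)) {
        out$response[lapsed] <- third_identity(stubs$morph_pair[lapsed])
      }
    }
  })
  out
}
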