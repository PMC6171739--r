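#' Remove trials whose response names an identity outside the morph pair
#'
#' In three-identity experiments observers occasionally report the third
#' identity (e.g. respond `c` to an `ab` morph); such trials are removed
#' before fitting.
#'
#' @param trials Trial data frame with `morph_pair` and `response`.
#' @return A list with `trials` (the kept rows) and `removed` (count).
#' @export
filter_third_identity <- function(trials) {
  if (nrow(trials) == 0L) return(list(trials = trials, removed = 0L))
  ids <- pair_identities(trials$morph_pair)
  ok <- mapply(function(r, p) r %in% p, trials$response, ids,
               USE.NAMES = FALSE)
  list(trials = trials[ok, , drop = FALSE], removed = sum(!ok))
}

#' Decompose a psychometric fit into PSE components
#'
#' The PSE of subject `k` at location `i` is the morph percentage at which
#' the fitted probability of reporting the second identity is 0.5:
#' `PSE_ik = -(beta_i + z_ik) / beta0`. It splits exactly into a
#' population-level PSE `-beta_i / beta0` and a subject deviation
#' `delta_pse = -z_ik / beta0`, so `pse = pse_pop + delta_pse` holds
#' row-wise as an algebraic identity.
#'
#' @param fit A [fit_psychometric()] object with nonzero slope.
#' @return Data frame of class `pse_table`: `subject_id`, `morph_pair`,
#'   `location_deg`, `pse`, `pse_pop`, `delta_pse`.
#' @export
pse_table <- function(fit) {
  stopifnot(inherits(fit, "psyfit"))
  if (!is.finite(fit$beta0) || fit$beta0 == 0) {
    stop("PSE is undefined: fitted slope beta0 is zero")
  }
  pse_pop <- -fit$beta_loc / fit$beta0
  grid <- expand.grid(location_deg = fit$locations, subject_id = fit$subjects,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  li <- match(grid$location_deg, fit$locations)
  si <- match(grid$subject_id, fit$subjects)
  delta <- -fit$z[cbind(si, li)] / fit$beta0
  out <- data.frame(
    subject_id = grid$subject_id, morph_pair = fit$morph_pair,
    location_deg = grid$location_deg,
    pse = unname(pse_pop[li] + delta), pse_pop = unname(pse_pop[li]),
    delta_pse = delta, stringsAsFactors = FALSE
  )
  structure(out, class = c("pse_table", "data.frame"))
}

#' Retinotopic bias statistic: summed squared PSE deviations
#'
#' The bias of one subject for one morph continuum is the sum over angular
#' locations of the squared subject-level PSE deviations,
#' `sum_i delta_pse_i^2` (in squared morph-%). Being proportional to the
#' variance of the deviations about zero it is also called the delta-PSE
#' variance.
#'
#' @param delta_pse Numeric vector of per-location deviations.
#' @return A single nonnegative number.
#' @examples
#' bias_variance(c(1, -1, 2, -2))  # 10
#' @export
bias_variance <- function(delta_pse) {
  stopifnot(length(delta_pse) >= 1L, is.numeric(delta_pse))
  sum(delta_pse^2)
}

#' Per-subject bias scores from a PSE table
#'
#' Applies [bias_variance()] to each subject x morph pair of one or more
#' stacked [pse_table()] results.
#'
#' @param pse A `pse_table` (or stacked rows of several).
#' @return Data frame `subject_id`, `morph_pair`, `bias`.
#' @export
bias_scores <- function(pse) {
  agg <- aggregate(delta_pse ~ subject_id + morph_pair, data = pse,
                   FUN = bias_variance)
  names(agg)[names(agg) == "delta_pse"] <- "bias"
  agg[order(agg$subject_id, agg$morph_pair), , drop = FALSE]
}

#' Per-location logistic fit without random effects
#'
#' Plain logistic regression of a binary outcome on morph percentage for a
#' single location, as used to read out the simulated decoder's responses.
#' The PSE is `-intercept / slope` on the morph axis. Degenerate inputs
#' (one outcome class) and complete-separation fits are flagged rather than
#' silently returning a number, and at-chance data whose slope is not
#' statistically distinguishable from zero carry an `indeterminate` flag
#' (the PSE ratio is then unstable).
#'
#' @param morph_pct Numeric morph percentages.
#' @param y Binary outcomes (1 = second identity reported).
#' @return List of class `simple_logit`: `intercept`, `slope`, `pse`,
#'   `degenerate`, `separated`, `indeterminate`, `converged`, `ok`
#'   (usable PSE).
#' @export
fit_simple_logit <- function(morph_pct, y) {
  stopifnot(length(morph_pct) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    out <- list(intercept = NA_real_, slope = NA_real_, pse = NA_real_,
                degenerate = TRUE, separated = FALSE, indeterminate = TRUE,
                converged = FALSE, ok = FALSE)
    class(out) <- "simple_logit"
    return(out)
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ morph_pct, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  pse <- -cf[[1L]] / cf[[2L]]
  slope_z <- cf[[2L]] / sqrt(vcov(fit)[2L, 2L])
  out <- list(intercept = cf[[1L]], slope = cf[[2L]], pse = unname(pse),
              degenerate = FALSE, separated = separated,
              indeterminate = !is.finite(slope_z) || abs(slope_z) < 2,
              converged = fit$converged,
              ok = fit$converged && is.finite(pse))
  class(out) <- "simple_logit"
  out
}

#' @export
print.simple_logit <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate logistic fit: only one outcome class; PSE undefined\n")
  } else {
    cat("Logistic fit: slope ", format(x$slope, digits = 4), ", PSE ",
        format(x$pse, digits = 4), if (x$separated) " (separation)" else "",
        "\n", sep = "")
  }
  invisible(x)
}
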