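#' Sweep a simulation parameter and summarize the retinotopic bias
#'
#' Runs many simulated experiments per condition along one axis — the
#' a:b unit ratio (1..9), the gain of a-units (1..4 in 0.5 steps) or their
#' receptive-field inflation (0..50% in 10% steps) — drawing a fresh unit
#' sample from the pool for every experiment, and summarizes each
#' condition's PSE variance by its median with a bootstrap percentile CI.
#'
#' @param pool A `prf_units` parameter pool ([generate_prf_population()]).
#' @param axis `"ratio"`, `"gain"` or `"rf"`.
#' @param values Conditions along the axis; defaults are `1:9` (ratio),
#'   `seq(1, 4, 0.5)` (gain) and `seq(0, 0.5, 0.1)` (rf inflation).
#' @param n_experiments Experiments per condition (500 by default).
#' @param config Baseline [css_config()]; the swept field is overridden.
#' @param n_boot Bootstrap replicates for the median CI.
#' @param level CI level.
#' @param seed Integer seed.
#' @return Data frame of class `css_sweep`: `roi`, `axis`, `condition`,
#'   `median_variance`, `ci_low`, `ci_high`, `n_experiments`,
#'   `failed_fits` (noise resamples) and `unidentifiable` (experiments
#'   whose bias is unbounded because some location's PSE stayed
#'   unidentifiable; they enter the median as `Inf`); the per-experiment
#'   variances are kept in the `"variances"` attribute (a list per
#'   condition).
#' @export
sweep_bias <- function(pool, axis = c("ratio", "gain", "rf"), values = NULL,
                       n_experiments = 500L, config = css_config(),
                       n_boot = 1000L, level = 0.95, seed = NULL) {
  axis <- match.arg(axis)
  if (is.null(values)) {
    values <- switch(axis, ratio = 1:9, gain = seq(1, 4, by = 0.5),
                     rf = seq(0, 0.5, by = 0.1))
  }
  seeds <- split_seed(seed %||% 1L, length(values))
  rows <- vector("list", length(values))
  all_var <- vector("list", length(values))
  for (i in seq_along(values)) {
    cfg <- config
    if (axis == "ratio") cfg$ratio <- as.integer(values[i])
    if (axis == "gain") cfg$gain_a <- values[i]
    if (axis == "rf") cfg$rf_inflation_a <- values[i]
    res <- with_seed(seeds[i], {
      vapply(seq_len(n_experiments), function(e) {
        units <- sample_population(pool, cfg)
        out <- run_css_experiment(units, cfg)
        c(out$pse_variance, out$failed_fits, !out$identifiable)
      }, numeric(3))
    })
    v <- res[1L, ]
    ci <- with_seed(seeds[i] + 1L, {
      meds <- vapply(seq_len(n_boot), function(b)
        median(v[sample.int(length(v), replace = TRUE)]), numeric(1))
      quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    })
    rows[[i]] <- data.frame(
      roi = pool$roi[1L], axis = axis, condition = values[i],
      median_variance = median(v), ci_low = ci[1L], ci_high = ci[2L],
      n_experiments = n_experiments, failed_fits = sum(res[2L, ]),
      unidentifiable = sum(res[3L, ]),
      stringsAsFactors = FALSE)
    all_var[[i]] <- v
  }
  out <- do.call(rbind, rows)
  names(all_var) <- as.character(values)
  structure(out, variances = all_var,
            class = c("css_sweep", "data.frame"))
}

#' Plot a bias sweep
#'
#' Median PSE variance per condition with its bootstrap CI.
#'
#' @param x A [sweep_bias()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.css_sweep <- function(x, ...) {
  graphics::plot(x$condition, x$median_variance, type = "b", pch = 19,
                 ylim = range(c(x$ci_low, x$ci_high)),
                 xlab = x$axis[1L],
                 ylab = "median PSE variance about 50% (morph-%^2)",
                 main = paste0(x$roi[1L], ": ", x$axis[1L], " sweep"), ...)
  graphics::arrows(x$condition, x$ci_low, x$condition, x$ci_high,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Bootstrap trend of a bias sweep
#'
#' Slope of a least-squares line through (condition, median PSE variance),
#' with a percentile bootstrap CI obtained by resampling experiments within
#' each condition and recomputing the medians. A flat sweep has a slope CI
#' containing zero; a bias-reducing manipulation has an entirely negative
#' CI.
#'
#' @param sweep A [sweep_bias()] result (its `"variances"` attribute is
#'   used).
#' @param n_boot Bootstrap replicates.
#' @param level CI level.
#' @param seed Integer seed.
#' @return List: `slope`, `ci` (length 2), `n_boot`.
#' @export
sweep_trend <- function(sweep, n_boot = 1000L, level = 0.95, seed = NULL) {
  v <- attr(sweep, "variances")
  stopifnot(!is.null(v))
  x <- sweep$condition
  slope_of <- function(meds) {
    keep <- is.finite(meds)
    if (sum(keep) < 2L) return(NA_real_)
    unname(coef(lm(meds[keep] ~ x[keep]))[2L])
  }
  slope <- slope_of(vapply(v, median, numeric(1)))
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    meds <- vapply(v, function(vi)
      median(vi[sample.int(length(vi), replace = TRUE)]), numeric(1))
    slope_of(meds)
  }, numeric(1)))
  boots <- boots[is.finite(boots)]
  ci <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE)
  list(slope = slope, ci = ci, n_boot = n_boot)
}
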