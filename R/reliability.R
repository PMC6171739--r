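#' Pearson correlation with t test
#'
#' @param x,y Paired numeric vectors (n >= 3, finite, nonconstant).
#' @return List of class `correlation_report`: `r`, `t_stat`, `df`
#'   (= n - 2), `p`, `n`.
#' @export
pearson_with_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), t_stat = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value, n = length(x)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("r = %.3f", x$r))
  if (!is.null(x$ci)) cat(sprintf(" [%.3f, %.3f]", x$ci[1], x$ci[2]))
  cat(sprintf(", t(%d) = %.2f, p = %.3g\n", x$df, x$t_stat, x$p))
  invisible(x)
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Nonparametric bootstrap interval with bias-correction constant
#' `z0 = qnorm(#\{theta* < theta_hat\} / B)` and jackknife-estimated
#' acceleration. When both corrections vanish the interval equals the
#' percentile interval. Resampling is deterministic under `seed`.
#'
#' @param data A vector, or a data frame / matrix resampled by rows.
#' @param statistic Function mapping a resampled `data` to a scalar.
#' @param n_boot Bootstrap replicates (10,000 by default).
#' @param level Coverage level.
#' @param seed Integer seed.
#' @return Numeric `c(low, high)` with attributes `z0`, `acceleration`,
#'   `theta` (point estimate) and `collapsed` (`TRUE` when all resampled
#'   statistics were identical, in which case the interval is a point and a
#'   warning is raised).
#' @examples
#' bca_ci(rnorm(30), mean, n_boot = 2000, seed = 1)
#' @export
bca_ci <- function(data, statistic, n_boot = 10000L, level = 0.95,
                   seed = NULL) {
  take <- if (is.null(dim(data))) {
    n <- length(data); function(i) data[i]
  } else {
    n <- nrow(data); function(i) data[i, , drop = FALSE]
  }
  if (n < 3L) stop("need at least 3 observations")
  theta <- statistic(data)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(b) statistic(take(sample.int(n, n, replace = TRUE))),
           numeric(1))
  })
  boots <- boots[is.finite(boots)]
  if (length(boots) < 2L || length(unique(boots)) == 1L) {
    warning("degenerate bootstrap distribution; interval collapsed")
    ci <- c(theta, theta)
    return(structure(ci, z0 = 0, acceleration = 0, theta = theta,
                     collapsed = TRUE))
  }
  z0 <- qnorm((sum(boots < theta) + 0.5 * sum(boots == theta)) /
                length(boots))
  jack <- vapply(seq_len(n), function(i) statistic(take(-i)), numeric(1))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)
  alpha <- (1 + c(-1, 1) * level) / 2
  zalpha <- qnorm(alpha)
  adj <- pnorm(z0 + (z0 + zalpha) / (1 - a * (z0 + zalpha)))
  ci <- unname(quantile(boots, adj, names = FALSE, type = 6))
  structure(ci, z0 = z0, acceleration = a, theta = theta, collapsed = FALSE)
}

#' Within- versus between-subject correlation of PSE deviations
#'
#' Quantifies idiosyncrasy: each subject's session-1 delta-PSE profile
#' across locations is correlated with their own session-2 profile
#' (within), and with every other subject's session-2 profile (between,
#' all ordered cross-subject pairs). Correlations are pooled by averaging
#' on the Fisher-z scale by default. The difference within - between gets a
#' BCa confidence interval by resampling subjects (the claim is about
#' subject-level idiosyncrasy, so the subject is the exchangeable unit).
#'
#' @param pse Stacked per-session PSE rows: columns `subject_id`,
#'   `location_deg`, `session`, `delta_pse` (one morph pair at a time).
#' @param n_boot Bootstrap replicates for the difference CI.
#' @param level CI level.
#' @param pooling `"fisher"` (average on the z scale) or `"raw"` (average
#'   the correlations directly).
#' @param seed Integer seed.
#' @return List of class `wb_difference`: `within_r`, `between_r`,
#'   `difference`, `ci`, `n_subjects`, `n_locations`.
#' @export
within_between_difference <- function(pse, n_boot = 10000L, level = 0.95,
                                      pooling = c("fisher", "raw"),
                                      seed = NULL) {
  pooling <- match.arg(pooling)
  subjects <- sort(unique(pse$subject_id))
  locs <- sort(unique(pse$location_deg))
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  if (length(locs) < 2L) stop("correlation undefined with a single location")
  if (!all(c(1, 2) %in% pse$session)) stop("both sessions must be present")
  mat <- function(sess) {
    d <- pse[pse$session == sess, , drop = FALSE]
    m <- matrix(NA_real_, length(subjects), length(locs),
                dimnames = list(subjects, locs))
    m[cbind(match(d$subject_id, subjects), match(d$location_deg, locs))] <-
      d$delta_pse
    if (anyNA(m)) stop("incomplete subject x location table in session ", sess)
    m
  }
  m1 <- mat(1); m2 <- mat(2)
  pool <- function(r) {
    if (pooling == "fisher") tanh(mean(fisher_z(r))) else mean(r)
  }
  stat <- function(idx) {
    w <- vapply(idx, function(k) cor(m1[k, ], m2[k, ]), numeric(1))
    # positions, not labels: duplicated resampled subjects stay distinct
    pos <- expand.grid(i1 = seq_along(idx), i2 = seq_along(idx))
    pos <- pos[pos$i1 != pos$i2, , drop = FALSE]
    b <- mapply(function(i1, i2) cor(m1[idx[i1], ], m2[idx[i2], ]),
                pos$i1, pos$i2)
    pool(w) - pool(b)
  }
  idx0 <- seq_along(subjects)
  within_r <- pool(vapply(idx0, function(k) cor(m1[k, ], m2[k, ]),
                          numeric(1)))
  pos <- expand.grid(i1 = idx0, i2 = idx0)
  pos <- pos[pos$i1 != pos$i2, , drop = FALSE]
  between_r <- pool(mapply(function(i1, i2) cor(m1[i1, ], m2[i2, ]),
                           pos$i1, pos$i2))
  ci <- suppressWarnings(
    bca_ci(idx0, stat, n_boot = n_boot, level = level, seed = seed))
  structure(list(within_r = within_r, between_r = between_r,
                 difference = within_r - between_r, ci = as.numeric(ci),
                 n_subjects = length(subjects), n_locations = length(locs)),
            class = "wb_difference")
}

#' @export
print.wb_difference <- function(x, ...) {
  cat(sprintf(
    "within r = %.3f, between r = %.3f, difference = %.3f [%.3f, %.3f]\n",
    x$within_r, x$between_r, x$difference, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Two-way participant x location ANOVA on PSE estimates
#'
#' Tests whether the spatial PSE profile differs across participants via
#' the participant-by-location interaction of a balanced two-way ANOVA with
#' replicates (sessions and/or identity-aligned morphs).
#'
#' @param pse Data frame with `subject_id`, `location_deg`, `pse` and one
#'   or more replicate rows per cell.
#' @return List of class `anova_report`: `F`, `df1`, `df2`, `p` for the
#'   interaction term.
#' @export
interaction_anova <- function(pse) {
  d <- data.frame(subject = factor(pse$subject_id),
                  location = factor(pse$location_deg), pse = pse$pse)
  counts <- table(d$subject, d$location)
  if (length(unique(as.vector(counts))) != 1L || any(counts < 2L)) {
    stop("subject x location table must be balanced with >= 2 replicates")
  }
  fit <- aov(pse ~ subject * location, data = d)
  tab <- summary(fit)[[1L]]
  i <- grep("subject:location", rownames(tab))
  structure(list(F = tab[i, "F value"], df1 = tab[i, "Df"],
                 df2 = tab[nrow(tab), "Df"], p = tab[i, "Pr(>F)"]),
            class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("participant x location interaction: F(%d, %d) = %.3f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Re-express PSEs with respect to a common identity
#'
#' PSEs are measured toward the *second* identity of a morph pair. To
#' compare continua sharing an identity, PSEs of pairs in which the target
#' identity comes first are flipped (`100 - pse`), and pairs not containing
#' the identity are dropped.
#'
#' @param pse A [pse_table()]-style data frame.
#' @param identity Single identity label (e.g. `"b"`).
#' @return The filtered data frame with aligned `pse` values.
#' @export
align_pse_identity <- function(pse, identity) {
  ids <- pair_identities(pse$morph_pair)
  pos <- vapply(ids, function(p) {
    w <- match(identity, p)
    if (is.na(w)) 0L else w
  }, integer(1))
  out <- pse[pos > 0L, , drop = FALSE]
  flip <- pos[pos > 0L] == 1L
  out$pse[flip] <- 100 - out$pse[flip]
  out
}
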