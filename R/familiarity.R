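#' Composite familiarity and contact scores
#'
#' Per subject x identity: SCI is the mean of its two items, the familiarity
#' score is the mean of IOS, SCI and the We-scale (all on 1-7), and the
#' contact score is the sum of the six binary contact items (0-6). Per
#' subject x morph pair, both scores are the arithmetic mean of the two
#' identities making up the pair.
#'
#' @param ratings Questionnaire data frame as produced by
#'   [generate_questionnaires()]`$ratings` (columns `subject_id`,
#'   `identity`, `ios`, `sci_1`, `sci_2`, `we`, `contact_1`..`contact_6`).
#' @param morph_pairs Character vector of pairs to score (e.g.
#'   `c("ab", "ac", "bc")`); defaults to all pairs of observed identities.
#' @return List of class `familiarity_scores` with `by_identity`
#'   (`subject_id`, `identity`, `familiarity`, `contact`) and `by_morph`
#'   (`subject_id`, `morph_pair`, `familiarity`, `contact`).
#' @export
composite_scores <- function(ratings, morph_pairs = NULL) {
  items <- c("ios", "sci_1", "sci_2", "we", paste0("contact_", 1:6))
  for (it in items) {
    if (!it %in% names(ratings)) stop("missing questionnaire column: ", it)
    if (anyNA(ratings[[it]])) {
      i <- which(is.na(ratings[[it]]))[1L]
      stop("missing item '", it, "' for subject ", ratings$subject_id[i],
           ", identity ", ratings$identity[i])
    }
  }
  sci <- (ratings$sci_1 + ratings$sci_2) / 2
  fam <- (ratings$ios + sci + ratings$we) / 3
  contact <- rowSums(ratings[paste0("contact_", 1:6)])
  by_id <- data.frame(subject_id = ratings$subject_id,
                      identity = ratings$identity,
                      familiarity = fam, contact = contact,
                      stringsAsFactors = FALSE)
  ids <- sort(unique(by_id$identity))
  if (is.null(morph_pairs)) {
    morph_pairs <- if (length(ids) >= 2L)
      apply(utils::combn(ids, 2L), 2L, paste, collapse = "") else character()
  }
  key <- paste(by_id$subject_id, by_id$identity)
  rows <- lapply(morph_pairs, function(mp) {
    p <- pair_identities(mp)[[1L]]
    subjects <- unique(by_id$subject_id)
    i1 <- match(paste(subjects, p[1L]), key)
    i2 <- match(paste(subjects, p[2L]), key)
    if (anyNA(i1) || anyNA(i2)) stop("identities of pair '", mp,
                                     "' not rated by every subject")
    data.frame(subject_id = subjects, morph_pair = mp,
               familiarity = (by_id$familiarity[i1] + by_id$familiarity[i2]) / 2,
               contact = (by_id$contact[i1] + by_id$contact[i2]) / 2,
               stringsAsFactors = FALSE)
  })
  by_morph <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), morph_pair = character(),
               familiarity = numeric(), contact = numeric())
  structure(list(by_identity = by_id, by_morph = by_morph),
            class = "familiarity_scores")
}

#' Pairwise correlations among the three rating scales
#'
#' Pearson correlations among IOS, SCI (item mean) and the We-scale over
#' subject x identity rows; constant scales are flagged and their pairs
#' skipped.
#'
#' @param ratings Questionnaire data frame (see [composite_scores()]).
#' @return List with `r` (named vector of pairwise correlations), `min`,
#'   `max` and `skipped` (pairs dropped for zero variance).
#' @export
scale_intercorrelations <- function(ratings) {
  scales <- data.frame(ios = ratings$ios,
                       sci = (ratings$sci_1 + ratings$sci_2) / 2,
                       we = ratings$we)
  if (nrow(scales) < 3L) stop("need at least 3 subject x identity rows")
  combs <- utils::combn(names(scales), 2L)
  r <- numeric(0); skipped <- character(0)
  for (i in seq_len(ncol(combs))) {
    a <- combs[1L, i]; b <- combs[2L, i]
    nm <- paste(a, b, sep = "-")
    if (sd(scales[[a]]) == 0 || sd(scales[[b]]) == 0) {
      skipped <- c(skipped, nm)
    } else {
      r[nm] <- cor(scales[[a]], scales[[b]])
    }
  }
  if (length(skipped)) warning("zero-variance scale(s); skipped: ",
                               paste(skipped, collapse = ", "))
  list(r = r, min = if (length(r)) min(r) else NA_real_,
       max = if (length(r)) max(r) else NA_real_, skipped = skipped)
}

#' Nested regressions of the retinotopic bias on familiarity and contact
#'
#' Fits two ordinary least-squares models of the per subject x morph bias
#' score: model 1 on familiarity alone, model 2 on familiarity plus
#' contact. Reports R^2, adjusted R^2, model F tests, per-coefficient t and
#' partial eta^2, the chi-square(1) log-likelihood-ratio statistic between
#' the nested models, the zero-order bias-familiarity correlation, and both
#' partial correlations (each predictor adjusted for the other), all with
#' BCa confidence intervals from row resampling.
#'
#' @param bias Data frame with `subject_id`, `morph_pair`, `bias` (see
#'   [bias_scores()]).
#' @param scores A [composite_scores()] result (its `by_morph` table is
#'   merged on subject and morph pair).
#' @param n_boot BCa replicates for the correlation CIs.
#' @param level CI level.
#' @param seed Integer seed.
#' @return List of class `bias_regression_report`; see Details in the
#'   package vignette. Key fields: `model1`, `model2` (each with
#'   `r_squared`, `adj_r_squared`, `F`, `df`, `p`, `coefficients` with t,
#'   p and partial eta^2), `lrt` (`chisq`, `df`, `p`), `cor_familiarity`,
#'   `partial_familiarity`, `partial_contact` (each r with `ci`), `n`.
#' @export
bias_regressions <- function(bias, scores, n_boot = 10000L, level = 0.95,
                             seed = NULL) {
  stopifnot(inherits(scores, "familiarity_scores"))
  d <- merge(bias, scores$by_morph, by = c("subject_id", "morph_pair"))
  if (nrow(d) < 4L) stop("need at least 4 subject x morph observations")
  if (length(unique(d$familiarity)) < 3L) {
    stop("need at least 3 distinct familiarity values")
  }
  if (sd(d$contact) > 0 && abs(cor(d$familiarity, d$contact)) == 1) {
    stop("familiarity and contact are perfectly collinear")
  }
  m1 <- lm(bias ~ familiarity, data = d)
  m2 <- lm(bias ~ familiarity + contact, data = d)

  describe <- function(m) {
    s <- summary(m)
    cf <- s$coefficients
    dfres <- m$df.residual
    eta <- cf[, "t value"]^2 / (cf[, "t value"]^2 + dfres)
    list(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
         F = unname(s$fstatistic[1L]),
         df = unname(s$fstatistic[2:3]),
         p = pf_from_summary(s),
         coefficients = data.frame(beta = cf[, "Estimate"],
                                   t = cf[, "t value"],
                                   p = cf[, "Pr(>|t|)"],
                                   partial_eta2 = eta))
  }
  lrt_stat <- as.numeric(2 * (logLik(m2) - logLik(m1)))
  lrt <- list(chisq = lrt_stat, df = 1L,
              p = pchisq(lrt_stat, df = 1L, lower.tail = FALSE))

  pcor <- function(dd, xvar, adjust) {
    rx <- residuals(lm(stats::reformulate(adjust, xvar), data = dd))
    ry <- residuals(lm(stats::reformulate(adjust, "bias"), data = dd))
    cor(rx, ry)
  }
  seeds <- split_seed(seed %||% 20231L, 3L)
  r0 <- pearson_with_test(d$familiarity, d$bias)
  r0$ci <- as.numeric(suppressWarnings(bca_ci(
    d, function(dd) cor(dd$familiarity, dd$bias),
    n_boot = n_boot, level = level, seed = seeds[1L])))
  partial <- function(xvar, adjust, sd_ok, seed) {
    if (!sd_ok) return(list(r = NA_real_, ci = c(NA_real_, NA_real_)))
    r <- pcor(d, xvar, adjust)
    ci <- as.numeric(suppressWarnings(bca_ci(
      d, function(dd) pcor(dd, xvar, adjust),
      n_boot = n_boot, level = level, seed = seed)))
    list(r = r, ci = ci)
  }
  structure(list(
    model1 = describe(m1), model2 = describe(m2), lrt = lrt,
    cor_familiarity = r0,
    partial_familiarity = partial("familiarity", "contact",
                                  sd(d$contact) > 0, seeds[2L]),
    partial_contact = partial("contact", "familiarity", TRUE, seeds[3L]),
    lm1 = m1, lm2 = m2, n = nrow(d)
  ), class = "bias_regression_report")
}

pf_from_summary <- function(s) {
  f <- s$fstatistic
  unname(stats::pf(f[1L], f[2L], f[3L], lower.tail = FALSE))
}

#' @export
print.bias_regression_report <- function(x, ...) {
  cat(sprintf("Model 1 (familiarity): R2 = %.3f (adj %.3f), F(%d,%d) = %.2f, p = %.3g\n",
              x$model1$r_squared, x$model1$adj_r_squared, x$model1$df[1],
              x$model1$df[2], x$model1$F, x$model1$p))
  cat(sprintf("Model 2 (+ contact):   R2 = %.3f (adj %.3f), F(%d,%d) = %.2f, p = %.3g\n",
              x$model2$r_squared, x$model2$adj_r_squared, x$model2$df[1],
              x$model2$df[2], x$model2$F, x$model2$p))
  cat(sprintf("LRT: chi2(1) = %.2f, p = %.3g\n", x$lrt$chisq, x$lrt$p))
  cat(sprintf("bias ~ familiarity: r = %.3f [%.3f, %.3f]\n",
              x$cor_familiarity$r, x$cor_familiarity$ci[1],
              x$cor_familiarity$ci[2]))
  if (is.finite(x$partial_familiarity$r))
    cat(sprintf("partial (familiarity | contact): r = %.3f [%.3f, %.3f]\n",
                x$partial_familiarity$r, x$partial_familiarity$ci[1],
                x$partial_familiarity$ci[2]))
  invisible(x)
}
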