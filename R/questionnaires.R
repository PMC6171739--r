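#' Generate questionnaire ratings of familiarity and contact
#'
#' For each subject x target identity a latent closeness value drives three
#' correlated 1-7 rating scales — IOS (inclusion of other in the self), SCI
#' (subjective closeness inventory; two items), and the We-scale — plus six
#' binary contact items (seen at an event, shared a meal, texted, ...). Each
#' scale is `mean + scale_sd * (sqrt(r) * Z + sqrt(1 - r) * e)` with `Z` the
#' shared latent and `e` scale-specific noise, so every pair of raw scales
#' correlates at `inter_scale_r`; raw values are then rounded and clamped to
#' the 1-7 range. The probability of each contact item increases with the
#' same latent closeness.
#'
#' @param n_subjects Number of subjects.
#' @param familiarity_means Named numeric vector, one mean (on the 1-7
#'   scale) per target identity, e.g. `c(a = 5.5, b = 4, c = 3)`.
#' @param inter_scale_r Latent correlation between the rating scales, in
#'   `[0, 1]`.
#' @param scale_sd SD of the raw (pre-discretization) scale values.
#' @param seed Integer seed.
#' @return A list with `ratings` (one row per subject x identity:
#'   `subject_id`, `identity`, `ios`, `sci_1`, `sci_2`, `we`,
#'   `contact_1`..`contact_6`) and `latent` (the raw continuous scale values
#'   before discretization, useful for calibration checks).
#' @export
generate_questionnaires <- function(n_subjects, familiarity_means,
                                    inter_scale_r = 0.9, scale_sd = 1.5,
                                    seed = NULL) {
  if (inter_scale_r < 0 || inter_scale_r > 1) {
    stop("`inter_scale_r` must lie in [0, 1]")
  }
  if (any(familiarity_means < 1 | familiarity_means > 7)) {
    stop("`familiarity_means` must lie within the 1-7 scale range")
  }
  if (is.null(names(familiarity_means))) {
    stop("`familiarity_means` must be named by identity")
  }
  subjects <- sprintf("s%02d", seq_len(n_subjects))
  grid <- expand.grid(identity = names(familiarity_means),
                      subject_id = subjects,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("subject_id", "identity")]
  n <- nrow(grid)
  mu <- familiarity_means[grid$identity]
  r <- inter_scale_r
  with_seed(seed, {
    z <- rnorm(n)
    raw <- function() mu + scale_sd * (sqrt(r) * z + sqrt(1 - r) * rnorm(n))
    ios_raw <- raw(); sci1_raw <- raw(); sci2_raw <- raw(); we_raw <- raw()
    # contact probability rises with the latent closeness and the identity's
    # baseline familiarity
    p_contact <- plogis(z + (mu - 4) / 1.5)
    contact <- matrix(rbinom(6L * n, 1L, rep(p_contact, each = 6L)),
                      nrow = n, ncol = 6L, byrow = TRUE)
  })
  disc <- function(x) pmin(7L, pmax(1L, as.integer(round(x))))
  ratings <- data.frame(
    grid,
    ios = disc(ios_raw), sci_1 = disc(sci1_raw), sci_2 = disc(sci2_raw),
    we = disc(we_raw), stringsAsFactors = FALSE
  )
  colnames(contact) <- paste0("contact_", 1:6)
  ratings <- cbind(ratings, as.data.frame(contact))
  latent <- data.frame(grid, ios = ios_raw, sci_1 = sci1_raw,
                       sci_2 = sci2_raw, we = we_raw,
                       stringsAsFactors = FALSE)
  list(ratings = ratings, latent = latent)
}
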