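#' Generate the factorial trial design of a morph-identification experiment
#'
#' Builds the trial list (stubs without responses) for one session of one
#' subject. Experiment 1 presents morphs between two identities (`ab`) at
#' eight angular locations; each of the 7 morph levels appears twice per
#' location in each of 5 blocks (8 x 7 x 2 = 112 trials/block, 560 total, 70
#' per location). Experiment 2 presents three morph continua (`ab`, `ac`,
#' `bc`) at four angular locations; each (location, pair, level) cell appears
#' once per block across 10 blocks of 84 trials (840 total, 10 per cell).
#'
#' @param experiment Integer, 1 or 2.
#' @param subject_id Subject identifier stamped on every trial.
#' @param session Session number (1 or 2).
#' @param seed Optional integer seed; trial order within each block is
#'   shuffled deterministically under it. `NULL` leaves the factorial order.
#' @return A data frame with columns `subject_id`, `session`, `block`,
#'   `trial`, `morph_pair`, `morph_pct`, `location_deg` and an all-`NA`
#'   `response` column, one row per trial.
#' @examples
#' d <- generate_design(1, seed = 1)
#' nrow(d)                      # 560
#' table(d$location_deg)[1]     # 70 per location
#' @export
generate_design <- function(experiment, subject_id = "s01", session = 1L,
                            seed = NULL) {
  if (length(experiment) != 1L || !experiment %in% c(1, 2)) {
    stop("`experiment` must be 1 or 2, got: ", deparse(experiment))
  }
  morphs <- morph_levels_default
  if (experiment == 1) {
    locations <- seq(0L, 315L, by = 45L)
    pairs <- "ab"
    n_blocks <- 5L
    reps <- 2L
  } else {
    locations <- c(45L, 135L, 225L, 315L)
    pairs <- c("ab", "ac", "bc")
    n_blocks <- 10L
    reps <- 1L
  }
  block_cells <- expand.grid(
    morph_pct = morphs, location_deg = locations, morph_pair = pairs,
    rep = seq_len(reps), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  seeds <- if (is.null(seed)) rep(list(NULL), n_blocks) else
    as.list(split_seed(seed, n_blocks))
  blocks <- lapply(seq_len(n_blocks), function(b) {
    ord <- with_seed(seeds[[b]], sample.int(nrow(block_cells)))
    cells <- block_cells[ord, , drop = FALSE]
    data.frame(
      subject_id = subject_id, session = as.integer(session), block = b,
      trial = seq_len(nrow(cells)),
      morph_pair = cells$morph_pair,
      morph_pct = cells$morph_pct,
      location_deg = cells$location_deg,
      response = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
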