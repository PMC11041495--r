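# Independent oracles and small fixture builders shared across tests.

# Brute-force LLR: evaluate the stacked 2d-dimensional Gaussian densities of
# (enrolled, probe) under the same-speaker and different-speaker hypotheses
# directly. Independent of the block-inversion path used by score_llr.
brute_force_llr <- function(model, enrolled, n_averaged, probe) {
  A <- model$between_cov + model$within_cov / n_averaged
  B <- model$between_cov + model$within_cov
  C <- model$between_cov
  same <- rbind(cbind(A, C), cbind(C, B))
  diff <- rbind(cbind(A, 0 * C), cbind(0 * C, B))
  z <- c(enrolled - model$mean, probe - model$mean)
  ld <- function(S) {
    -length(z) / 2 * log(2 * pi) -
      0.5 * as.numeric(determinant(S, logarithm = TRUE)$modulus) -
      0.5 * drop(z %*% solve(S, z))
  }
  ld(same) - ld(diff)
}

# Minimal plda_model without fitting, for scoring tests.
toy_plda_model <- function(mean, between, within) {
  structure(list(mean = mean, between_cov = as.matrix(between),
                 within_cov = as.matrix(within), dim = length(mean),
                 length_norm = FALSE, fit_log = numeric(0)),
            class = "plda_model")
}

random_psd <- function(d, scale = 1) {
  m <- matrix(rnorm(d * d), d)
  crossprod(m) / d * scale
}

# Exhaustive-grid minimum of the detection cost function: evaluates the cost
# on an evenly spaced grid spanning beyond the score range.
grid_min_dcf <- function(scores, labels, spec, n_grid = 1e4) {
  grid <- seq(min(scores) - 1, max(scores) + 1, length.out = n_grid)
  min(detection_cost(scores, labels, grid, spec))
}

# Tiny deterministic cohort: n_speakers x recs recordings of dimension d.
toy_cohort <- function(n_speakers = 12, recs = 3, d = 4, seed = 1,
                       within = 0.25, tasks = NULL) {
  cfg <- generator_config(
    n_speakers = n_speakers, dim = d,
    tasks = tasks %||% speech_tasks("speech", recordings = recs),
    between = 1, within = within, seed = seed)
  generate_cohort(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap an accept_matches table as a match_table tied to a hand-built split,
# so count_outcomes can be exercised on enumerated toys.
as_match_table <- function(tab, probe_speaker_of, split) {
  tab$probe_speaker <- probe_speaker_of[tab$probe_id]
  tab <- tab[, c("probe_id", "probe_speaker", "known_speaker", "score", "rank", "accepted")]
  attr(tab, "n_known") <- length(split$known_speakers)
  attr(tab, "n_probes") <- nrow(split$unknown_probes)
  class(tab) <- c("match_table", "data.frame")
  tab
}

hand_split <- function(known, probes_df, overlap = character(0), seed = 0L) {
  structure(list(known_speakers = known,
                 enrollment = data.frame(speaker_id = known,
                                         recording_id = paste0("enr_", known),
                                         stringsAsFactors = FALSE),
                 unknown_probes = probes_df,
                 overlap_speakers = overlap,
                 unknown_only_speakers = setdiff(probes_df$speaker_id, overlap),
                 shortfall = 0L, seed = seed,
                 probe_task = NULL, enroll_task = NULL),
            class = "speaker_split")
}
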