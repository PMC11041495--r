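# Acceptance-threshold calibration: detection cost function (minDCF), the
# EER alternative, and bootstrap averaging over random speaker subsets.

#' Detection cost parameters
#'
#' Cost of the two verification errors and the prior probability of a target
#' (same-speaker) trial, as used by the detection cost function
#' `DCF = C_FR * FR * prior + C_FA * FA * (1 - prior)`.
#'
#' Two presets are provided: `threshold_preset("default")` penalises both
#' errors equally (`C_FA = 1, C_FR = 1, prior = 0.01`) and
#' `threshold_preset("strict")` penalises false acceptances heavily
#' (`C_FA = 10, C_FR = 0.1, prior = 0.001`), reflecting an adversary for
#' whom precision matters more than recall.
#'
#' @param C_FA cost of a false acceptance (> 0).
#' @param C_FR cost of a false rejection (> 0).
#' @param prior_target prior probability of a target trial, strictly in (0, 1).
#' @param mode `"rates"` (FR/FA are miss and false-accept rates; the default,
#'   matching standard minDCF implementations and making the prior term
#'   meaningful) or `"counts"` (raw error counts).
#' @return an object of class `threshold_spec`.
#' @export
threshold_spec <- function(C_FA = 1, C_FR = 1, prior_target = 0.01,
                           mode = c("rates", "counts")) {
  mode <- match.arg(mode)
  if (!(C_FA > 0) || !(C_FR > 0)) rr_validation_error("costs C_FA and C_FR must be positive")
  if (!(prior_target > 0 && prior_target < 1)) {
    rr_validation_error("prior_target must lie strictly inside (0, 1)")
  }
  structure(list(C_FA = C_FA, C_FR = C_FR, prior_target = prior_target, mode = mode),
            class = "threshold_spec")
}

#' @rdname threshold_spec
#' @param name preset name.
#' @export
threshold_preset <- function(name = c("default", "strict")) {
  switch(match.arg(name),
         default = threshold_spec(C_FA = 1, C_FR = 1, prior_target = 0.01),
         strict = threshold_spec(C_FA = 10, C_FR = 0.1, prior_target = 0.001))
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> C_FA=%g, C_FR=%g, prior=%g, mode=%s\n",
              x$C_FA, x$C_FR, x$prior_target, x$mode))
  invisible(x)
}

check_trials <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(scores) != length(labels)) rr_validation_error("scores and labels must have equal length")
  if (!all(labels %in% c("genuine", "impostor"))) {
    rr_validation_error("labels must be 'genuine' or 'impostor'")
  }
  if (!any(labels == "genuine")) rr_degenerate_error("no genuine trials in the input")
  if (!any(labels == "impostor")) rr_degenerate_error("no impostor trials in the input")
  labels
}

# Error counts at one or more thresholds. Acceptance is score >= threshold
# (ties at the threshold are accepted). Vectorised over thresholds via
# sorted cumulative counts.
error_counts <- function(scores, labels, thresholds) {
  g <- sort(scores[labels == "genuine"])
  i <- sort(scores[labels == "impostor"])
  fr <- findInterval(thresholds, g, left.open = TRUE)       # genuine < t
  fa <- length(i) - findInterval(thresholds, i, left.open = TRUE)  # impostor >= t
  list(fr = fr, fa = fa, n_genuine = length(g), n_impostor = length(i))
}

#' Detection cost of a threshold
#'
#' `C_FR * FR * prior + C_FA * FA * (1 - prior)`, with FR/FA either error
#' rates (miss rate among genuine trials, false-accept rate among impostor
#' trials) or raw counts depending on the spec's `mode`.
#'
#' @param scores numeric trial scores (LLRs).
#' @param labels `"genuine"`/`"impostor"` per trial; both classes required.
#' @param threshold acceptance threshold (accept when score >= threshold).
#' @param spec a [threshold_spec()].
#' @return the detection cost (scalar).
#' @export
detection_cost <- function(scores, labels, threshold, spec = threshold_preset("default")) {
  labels <- check_trials(scores, labels)
  ec <- error_counts(scores, labels, threshold)
  fr <- ec$fr; fa <- ec$fa
  if (spec$mode == "rates") {
    fr <- fr / ec$n_genuine; fa <- fa / ec$n_impostor
  }
  spec$C_FR * fr * spec$prior_target + spec$C_FA * fa * (1 - spec$prior_target)
}

# Candidate thresholds: midpoints of adjacent sorted unique scores plus one
# sentinel below and one above all scores. The error counts are piecewise
# constant between adjacent scores, so this set is exhaustive. The sentinels
# stand in for the infinite tails; they are placed half a median
# inter-score gap outside the data so that a run whose optimum lies in the
# accept-nothing region returns a finite threshold on the scale of the
# scores (these thresholds are averaged across bootstrap runs).
threshold_candidates <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1L) return(c(u - 1, u + 1))
  gaps <- diff(u)
  g <- stats::median(gaps) / 2
  if (g <= 0) g <- 1
  mids <- (u[-1L] + u[-length(u)]) / 2
  c(u[1L] - g, mids, u[length(u)] + g)
}

#' Threshold minimising the detection cost function
#'
#' Searches the candidate set of midpoints between adjacent sorted unique
#' scores (plus sentinels below and above all scores, standing in for the
#' infinite tails); the cost function is piecewise constant between
#' adjacent scores so this search is exhaustive. Ties in cost are broken
#' toward the largest threshold (the most conservative choice for the
#' adversary).
#'
#' @inheritParams detection_cost
#' @return list with `threshold` and the minimal `cost`.
#' @export
min_dcf_threshold <- function(scores, labels, spec = threshold_preset("default")) {
  labels <- check_trials(scores, labels)
  cand <- threshold_candidates(scores)
  cost <- detection_cost(scores, labels, cand, spec)
  best <- max(which(cost == min(cost)))
  list(threshold = cand[best], cost = cost[best])
}

#' Equal-error-rate threshold
#'
#' Returns the candidate threshold minimising `|FAR - FRR|` and the EER
#' `(FAR + FRR) / 2` at that point; ties are broken toward the largest
#' threshold.
#'
#' @inheritParams detection_cost
#' @return list with `threshold` and `eer`.
#' @export
eer_threshold <- function(scores, labels) {
  labels <- check_trials(scores, labels)
  cand <- threshold_candidates(scores)
  ec <- error_counts(scores, labels, cand)
  frr <- ec$fr / ec$n_genuine; far <- ec$fa / ec$n_impostor
  gap <- abs(far - frr)
  best <- max(which(gap == min(gap)))
  list(threshold = cand[best], eer = (far[best] + frr[best]) / 2)
}

#' Bootstrap-averaged minDCF threshold over speaker subsets
#'
#' Mirrors calibrating on subsets of the training (known) speakers: each run
#' draws two independent subsets of `subset_size` speakers (without
#' replacement within a subset, independently across subsets and runs, so
#' the two subsets may overlap). Subset A speakers are enrolled by averaging
#' all their recordings; one randomly held recording per subset B speaker
#' serves as a probe (withheld from the enrollment average when the speaker
#' is in both subsets and has another recording). All A x B pairs are
#' scored, labelled genuine iff same speaker, and fed to
#' [min_dcf_threshold()]. Runs without a single genuine trial (disjoint
#' subsets) are discarded; the calibrated threshold is the arithmetic mean
#' over retained runs.
#'
#' @param known_cohort an [embedding_cohort()] of training speakers
#'   (>= `subset_size` speakers).
#' @param model a fitted [fit_plda()] model.
#' @param spec a [threshold_spec()].
#' @param subset_size speakers per subset (default 100).
#' @param runs number of bootstrap runs attempted (default 200).
#' @param seed integer seed.
#' @param converge_tol optional early stop: halt when the running mean
#'   threshold has changed by less than this over the last 25 retained runs
#'   (`NULL` disables).
#' @return a `calibrated_threshold`: list with `value`, `method`,
#'   `per_run_thresholds`, `runs_attempted`, `runs_used`, `runs_discarded`,
#'   and the `spec`.
#' @export
bootstrap_threshold <- function(known_cohort, model, spec = threshold_preset("default"),
                                subset_size = 100L, runs = 200L, seed = 1L,
                                converge_tol = NULL) {
  stopifnot(inherits(known_cohort, "embedding_cohort"), inherits(model, "plda_model"))
  if (runs < 1L) rr_validation_error("runs must be >= 1")
  speakers <- unique(known_cohort$records$speaker_id)
  if (length(speakers) < subset_size) {
    rr_validation_error(sprintf(
      "known cohort has %d speakers but subsets of %d were requested",
      length(speakers), subset_size))
  }
  rec_sp <- factor(known_cohort$records$speaker_id, levels = speakers)
  sums <- rowsum(known_cohort$embeddings, rec_sp, reorder = FALSE)
  counts <- as.vector(table(rec_sp))
  rec_by_sp <- split(seq_len(nrow(known_cohort$records)), rec_sp)

  per_run <- numeric(0)
  discarded <- 0L
  attempted <- 0L
  for (r in seq_len(runs)) {
    attempted <- attempted + 1L
    res <- with_seed(derive_seed(seed, r, "bootstrap"), {
      ia <- sample.int(length(speakers), subset_size)
      ib <- sample.int(length(speakers), subset_size)
      if (length(intersect(ia, ib)) == 0L) NULL else {
        probe_rec <- vapply(rec_by_sp[ib], function(ids) {
          ids[sample.int(length(ids), 1L)]
        }, integer(1))
        # enrollment averages for A, withholding the held probe where possible
        E <- sums[ia, , drop = FALSE]
        n_avg <- counts[ia]
        in_b <- match(ia, ib)
        for (k in which(!is.na(in_b))) {
          if (counts[ia[k]] >= 2L) {
            E[k, ] <- E[k, ] - known_cohort$embeddings[probe_rec[in_b[k]], ]
            n_avg[k] <- n_avg[k] - 1L
          }
        }
        enr <- structure(list(speaker_id = speakers[ia],
                              vectors = E / n_avg, n_averaged = n_avg),
                         class = "enrollment_table")
        P <- known_cohort$embeddings[probe_rec, , drop = FALSE]
        sc <- score_matrix(model, enr, P)
        lab <- ifelse(outer(speakers[ib], speakers[ia], "=="), "genuine", "impostor")
        if (!any(lab == "genuine")) NULL
        else min_dcf_threshold(as.vector(sc), as.vector(lab), spec)$threshold
      }
    })
    if (is.null(res)) discarded <- discarded + 1L else per_run <- c(per_run, res)
    if (!is.null(converge_tol) && length(per_run) >= 26L) {
      m_now <- mean(per_run)
      m_prev <- mean(per_run[seq_len(length(per_run) - 25L)])
      if (abs(m_now - m_prev) < converge_tol) break
    }
  }
  if (length(per_run) == 0L) {
    rr_degenerate_error(paste(
      "every bootstrap run was discarded (the two speaker subsets never overlapped);",
      "increase subset_size or runs"))
  }
  structure(list(value = mean(per_run), method = "minDCF",
                 per_run_thresholds = per_run,
                 runs_attempted = attempted,
                 runs_used = length(per_run),
                 runs_discarded = discarded,
                 spec = spec, subset_size = as.integer(subset_size),
                 seed = as.integer(seed)),
            class = "calibrated_threshold")
}

#' @export
print.calibrated_threshold <- function(x, ...) {
  cat(sprintf("<calibrated_threshold> %s = %.4f (runs: %d used, %d discarded of %d)\n",
              x$method, x$value, x$runs_used, x$runs_discarded, x$runs_attempted))
  invisible(x)
}

#' Write a calibration report as JSON
#'
#' @param calibrated a `calibrated_threshold` from [bootstrap_threshold()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(calibrated, path) {
  stopifnot(inherits(calibrated, "calibrated_threshold"))
  jsonlite::write_json(list(
    method = calibrated$method,
    value = calibrated$value,
    spec = unclass(calibrated$spec),
    subset_size = calibrated$subset_size,
    runs_attempted = calibrated$runs_attempted,
    runs_used = calibrated$runs_used,
    runs_discarded = calibrated$runs_discarded,
    per_run_thresholds = calibrated$per_run_thresholds
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
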