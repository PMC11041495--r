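# Marketer-attack execution: score every probe against every enrolled known
# speaker, apply the acceptance rule, and tabulate risk outcomes.

#' Apply an acceptance rule to a score matrix
#'
#' Variants: `"all"` accepts every pair scoring at or above the threshold;
#' `"rank1"` accepts at most the top-ranked known speaker per probe (and
#' only if it clears the threshold); `"topN"` keeps the `N` highest-scoring
#' pairs among all threshold-clearing pairs across all probes (an adversary
#' who knows the overlap size). Ranks are per probe by descending score,
#' ties broken by known-speaker id; score ties at the global top-N boundary
#' are broken the same way, for determinism.
#'
#' @param scores probes x known LLR matrix with probe ids as row names and
#'   known speaker ids as column names.
#' @param threshold acceptance threshold (accept when score >= threshold).
#' @param variant `"all"`, `"rank1"` or `"topN"`.
#' @param N for `"topN"`: the number of matches kept (>= 1). If fewer pairs
#'   clear the threshold, all of them are kept.
#' @return a data frame with one row per probe-known pair: `probe_id`,
#'   `known_speaker`, `score`, `rank`, `accepted`.
#' @export
accept_matches <- function(scores, threshold, variant = c("all", "rank1", "topN"),
                           N = NULL) {
  variant <- match.arg(variant)
  if (!is.finite(threshold)) {
    if (!is.infinite(threshold)) rr_validation_error("threshold must be numeric")
  }
  if (variant == "topN" && (is.null(N) || N < 1L)) {
    rr_validation_error("variant 'topN' requires N >= 1")
  }
  m <- nrow(scores); k <- ncol(scores)
  probe_ids <- rownames(scores) %||% as.character(seq_len(m))
  known_ids <- colnames(scores) %||% as.character(seq_len(k))
  # per-probe ranks: descending score, ties by known speaker id
  rank_mat <- t(apply(scores, 1L, function(row) {
    ord <- order(-row, known_ids)
    r <- integer(k); r[ord] <- seq_len(k); r
  }))
  if (m == 1L) rank_mat <- matrix(rank_mat, nrow = 1L)
  tab <- data.frame(
    probe_id = rep(probe_ids, times = k),
    known_speaker = rep(known_ids, each = m),
    score = as.vector(scores),
    rank = as.vector(rank_mat),
    stringsAsFactors = FALSE)
  above <- tab$score >= threshold
  accepted <- switch(variant,
    all = above,
    rank1 = above & tab$rank == 1L,
    topN = {
      idx <- which(above)
      if (length(idx) > N) {
        ord <- idx[order(-tab$score[idx], tab$known_speaker[idx], tab$probe_id[idx])]
        keep <- ord[seq_len(N)]
        seq_len(nrow(tab)) %in% keep
      } else above
    })
  tab$accepted <- accepted
  attr(tab, "threshold") <- threshold
  attr(tab, "variant") <- variant
  attr(tab, "N") <- N
  tab
}

#' Run the marketer attack on a split
#'
#' Enrolls the split's known speakers (speaker-averaged embeddings,
#' honouring probe withholding), scores every probe against every
#' enrollment under the PLDA model, and applies the acceptance rule.
#'
#' @param model a fitted [fit_plda()] model.
#' @param split a [make_split()] result.
#' @param cohort the [embedding_cohort()] the split was drawn from.
#' @param threshold acceptance LLR threshold (finite, or `Inf`/`-Inf`).
#' @param variant,N acceptance rule, see [accept_matches()].
#' @param pool_probes if `TRUE`, each unknown speaker's probe is replaced by
#'   the mean embedding of all that speaker's recordings across tasks
#'   (an adversary able to link the shared recordings per speaker).
#' @return a `match_table`: the [accept_matches()] data frame augmented with
#'   `probe_speaker`, carrying the split's bookkeeping as attributes.
#' @export
run_attack <- function(model, split, cohort, threshold,
                       variant = c("all", "rank1", "topN"), N = NULL,
                       pool_probes = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(model, "plda_model"), inherits(split, "speaker_split"),
            inherits(cohort, "embedding_cohort"))
  if (nrow(split$unknown_probes) == 0L) rr_validation_error("the split has no probes")
  if (ncol(cohort$embeddings) != model$dim) {
    rr_validation_error("model dimension does not match the cohort")
  }
  enr <- enroll(cohort, split$enrollment)
  if (pool_probes) {
    P <- t(vapply(split$unknown_probes$speaker_id, function(s) {
      idx <- which(cohort$records$speaker_id == s)
      colMeans(cohort$embeddings[idx, , drop = FALSE])
    }, numeric(model$dim)))
    rownames(P) <- split$unknown_probes$recording_id
  } else {
    P <- cohort$embeddings[match(split$unknown_probes$recording_id,
                                 cohort$records$recording_id), , drop = FALSE]
  }
  sc <- score_matrix(model, enr, P)
  tab <- accept_matches(sc, threshold, variant, N)
  tab$probe_speaker <- split$unknown_probes$speaker_id[
    match(tab$probe_id, split$unknown_probes$recording_id)]
  tab <- tab[, c("probe_id", "probe_speaker", "known_speaker", "score", "rank", "accepted")]
  attr(tab, "threshold") <- threshold
  attr(tab, "variant") <- variant
  attr(tab, "N") <- N
  attr(tab, "n_known") <- length(enr$speaker_id)
  attr(tab, "n_probes") <- nrow(split$unknown_probes)
  class(tab) <- c("match_table", "data.frame")
  tab
}

#' Tabulate attack outcomes as a risk summary
#'
#' Counts true acceptances (accepted pairs whose probe and known speaker
#' coincide) and false acceptances, and derives precision, the
#' false-acceptance rate `FA / (comparisons - genuine_pairs)` (impostor
#' comparisons as the base), and the FA/TA ratio. TAs and FAs are the
#' true/false positives of the reidentification attack. Precision is `NA`
#' (undefined, not 0) when nothing was accepted; FA/TA is `Inf` when
#' `FA > 0 = TA` and `NA` when both are zero.
#'
#' @param table a `match_table` from [run_attack()].
#' @param split the `speaker_split` the table was produced from.
#' @return a one-row data frame (class `risk_summary`): `TA`, `FA`,
#'   `comparisons`, `genuine_pairs`, `precision`, `FAR`, `fa_ta_ratio`,
#'   plus the split descriptor columns `n_known`, `n_unknown`, `n_overlap`,
#'   `shortfall`, `seed`.
#' @export
count_outcomes <- function(table, split) {
  stopifnot(inherits(table, "match_table"), inherits(split, "speaker_split"))
  n_known <- attr(table, "n_known")
  n_probes <- attr(table, "n_probes")
  if (n_probes != nrow(split$unknown_probes) ||
      n_known != length(split$known_speakers) ||
      !setequal(unique(table$probe_speaker), split$unknown_probes$speaker_id)) {
    rr_validation_error("match table does not correspond to this split")
  }
  comparisons <- n_probes * n_known
  genuine_pairs <- length(split$overlap_speakers)
  acc <- table[table$accepted, , drop = FALSE]
  TA <- sum(acc$probe_speaker == acc$known_speaker)
  FA <- nrow(acc) - TA
  precision <- if (TA + FA > 0) TA / (TA + FA) else NA_real_
  fa_ta <- if (TA > 0) FA / TA else if (FA > 0) Inf else NA_real_
  out <- data.frame(
    TA = TA, FA = FA, comparisons = comparisons, genuine_pairs = genuine_pairs,
    precision = precision, FAR = FA / (comparisons - genuine_pairs),
    fa_ta_ratio = fa_ta,
    n_known = n_known, n_unknown = n_probes,
    n_overlap = genuine_pairs, shortfall = split$shortfall, seed = split$seed)
  class(out) <- c("risk_summary", "data.frame")
  out
}

#' Search-space size and stratification arithmetic
#'
#' The attack search space is `n_known * n_unknown` comparisons. When the
#' adversary can stratify both sets (e.g. by gender, keeping fractions
#' `f_k` and `f_u` of each), the stratum search space is
#' `(f_k n_known) * (f_u n_unknown)` and the reduction is
#' `100 * (1 - f_k * f_u)` percent: a 50:50 split on both sides removes 75%
#' of the comparisons.
#'
#' @param n_known,n_unknown set sizes (non-negative).
#' @param stratum_fraction_known,stratum_fraction_unknown optional fractions
#'   in (0, 1].
#' @return list with `comparisons` and (when fractions are given)
#'   `reduction_pct`.
#' @export
search_space <- function(n_known, n_unknown,
                         stratum_fraction_known = NULL,
                         stratum_fraction_unknown = NULL) {
  if (n_known < 0 || n_unknown < 0) rr_validation_error("set sizes must be non-negative")
  have_frac <- !is.null(stratum_fraction_known) || !is.null(stratum_fraction_unknown)
  fk <- stratum_fraction_known %||% 1
  fu <- stratum_fraction_unknown %||% 1
  if (fk <= 0 || fk > 1 || fu <= 0 || fu > 1) {
    rr_validation_error("stratum fractions must lie in (0, 1]")
  }
  if (have_frac) {
    list(comparisons = (fk * n_known) * (fu * n_unknown),
         reduction_pct = 100 * (1 - fk * fu))
  } else {
    list(comparisons = n_known * n_unknown, reduction_pct = NULL)
  }
}
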