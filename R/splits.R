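# Sampling of attack speaker sets: known (identified, enrolled), unknown
# (shared, de-identified probes), and their overlap. One probe recording per
# unknown speaker; for overlap speakers the probe is withheld from the
# enrollment recordings.

#' Sample one attack split
#'
#' Samples `n_known` known speakers uniformly from those eligible for the
#' enrollment task, draws `n_overlap` overlap speakers uniformly from the
#' known set (among those with a usable probe recording), and
#' `n_unknown - n_overlap` unknown-only speakers from the remaining
#' probe-eligible speakers. Each unknown speaker gets exactly one randomly
#' chosen probe recording; for overlap speakers that recording is excluded
#' from their enrollment recordings. Known speakers are enrolled on all
#' their eligible recordings.
#'
#' If fewer than `n_known` speakers are eligible, all eligible speakers are
#' used and the shortfall is recorded in the split (mirrors task-limited
#' designs where a nominal known-set size exceeds the available speakers).
#'
#' @param cohort an [embedding_cohort()].
#' @param n_known,n_unknown,n_overlap set sizes;
#'   `0 <= n_overlap <= min(n_known, n_unknown)`.
#' @param probe_task optional task label restricting probe recordings.
#' @param enroll_task optional task label restricting enrollment recordings.
#' @param exclude_recordings recording ids never used for enrollment (e.g. a
#'   sentence held out for probing).
#' @param seed integer seed.
#' @return a `speaker_split`: list with `known_speakers`, `enrollment`
#'   (data frame speaker_id, recording_id), `unknown_probes` (data frame
#'   speaker_id, recording_id), `overlap_speakers`, `unknown_only_speakers`,
#'   `shortfall`, `seed`, and the task filters.
#' @export
make_split <- function(cohort, n_known, n_unknown, n_overlap,
                       probe_task = NULL, enroll_task = NULL,
                       exclude_recordings = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "embedding_cohort"))
  n_known <- as.integer(n_known); n_unknown <- as.integer(n_unknown)
  n_overlap <- as.integer(n_overlap)
  if (n_known < 1L || n_unknown < 1L) rr_validation_error("n_known and n_unknown must be >= 1")
  if (n_overlap < 0L || n_overlap > min(n_known, n_unknown)) {
    rr_validation_error("n_overlap must satisfy 0 <= n_overlap <= min(n_known, n_unknown)")
  }
  rec <- cohort$records
  enroll_ok <- !(rec$recording_id %in% exclude_recordings) &
    (if (is.null(enroll_task)) TRUE else rec$task == enroll_task)
  probe_ok <- if (is.null(probe_task)) rep(TRUE, nrow(rec)) else rec$task == probe_task

  enroll_recs <- split(rec$recording_id[enroll_ok], rec$speaker_id[enroll_ok])
  probe_recs <- split(rec$recording_id[probe_ok], rec$speaker_id[probe_ok])
  known_eligible <- names(enroll_recs)
  # overlap speakers need a probe whose withholding leaves >= 1 enrollment
  # recording: either a probe outside the enrollment set, or >= 2 enrollment
  # recordings
  overlap_usable <- function(s) {
    pr <- probe_recs[[s]]
    if (is.null(pr) || length(pr) == 0L) return(FALSE)
    er <- enroll_recs[[s]]
    any(!(pr %in% er)) || length(er) >= 2L
  }

  with_seed(seed, {
    if (length(known_eligible) < n_known) {
      known <- sort(known_eligible)
      shortfall <- n_known - length(known)
    } else {
      known <- sort(sample(known_eligible, n_known))
      shortfall <- 0L
    }
    if (n_overlap > 0L) {
      cand <- known[vapply(known, overlap_usable, logical(1))]
      if (length(cand) < n_overlap) {
        rr_validation_error(sprintf(
          paste("only %d known speakers have a probe recording of the requested task",
                "that can be withheld from enrollment; %d overlap speakers requested"),
          length(cand), n_overlap))
      }
      overlap <- sort(sample(cand, n_overlap))
    } else overlap <- character(0)

    uo_pool <- setdiff(names(probe_recs)[lengths(probe_recs) > 0L], known)
    n_uo <- n_unknown - n_overlap
    if (length(uo_pool) < n_uo) {
      rr_validation_error(sprintf(
        "only %d speakers outside the known set have recordings of the probe task; %d unknown-only speakers requested",
        length(uo_pool), n_uo))
    }
    unknown_only <- sort(if (n_uo > 0L) sample(uo_pool, n_uo) else character(0))

    pick_probe <- function(s, must_leave_enrollment) {
      pr <- probe_recs[[s]]
      if (must_leave_enrollment) {
        er <- enroll_recs[[s]]
        # prefer any probe; restrict to ones that leave enrollment non-empty
        ok <- !(pr %in% er) | (length(er) >= 2L)
        pr <- pr[ok]
      }
      pr[sample.int(length(pr), 1L)]
    }
    unknown <- c(overlap, unknown_only)
    probes <- data.frame(
      speaker_id = unknown,
      recording_id = vapply(unknown, function(s) {
        pick_probe(s, must_leave_enrollment = s %in% overlap)
      }, character(1)),
      stringsAsFactors = FALSE, row.names = NULL)

    enrollment <- do.call(rbind, lapply(known, function(s) {
      er <- enroll_recs[[s]]
      if (s %in% overlap) er <- setdiff(er, probes$recording_id[probes$speaker_id == s])
      data.frame(speaker_id = rep(s, length(er)), recording_id = er,
                 stringsAsFactors = FALSE)
    }))
    structure(list(known_speakers = known, enrollment = enrollment,
                   unknown_probes = probes, overlap_speakers = overlap,
                   unknown_only_speakers = unknown_only,
                   shortfall = shortfall, seed = as.integer(seed),
                   probe_task = probe_task, enroll_task = enroll_task),
              class = "speaker_split")
  })
}

#' @export
print.speaker_split <- function(x, ...) {
  cat(sprintf("<speaker_split> known %d (shortfall %d), unknown %d = %d overlap + %d unknown-only, seed %d\n",
              length(x$known_speakers), x$shortfall, nrow(x$unknown_probes),
              length(x$overlap_speakers), length(x$unknown_only_speakers), x$seed))
  invisible(x)
}

#' Sample a series of attack splits
#'
#' Generates `splits_per_size` independent splits for each requested size
#' triple, with per-split seeds derived deterministically from the master
#' seed.
#'
#' @param cohort an [embedding_cohort()].
#' @param sizes a list of `c(n_known, n_unknown, n_overlap)` triples.
#' @param splits_per_size splits per triple.
#' @param seed master seed.
#' @inheritParams make_split
#' @return a list of `speaker_split` objects
#'   (`length(sizes) * splits_per_size` of them, sizes in order).
#' @export
make_split_series <- function(cohort, sizes, splits_per_size = 20L,
                              probe_task = NULL, enroll_task = NULL,
                              exclude_recordings = NULL, seed = 1L) {
  if (!is.list(sizes) || length(sizes) == 0L) rr_validation_error("sizes must be a non-empty list of triples")
  out <- vector("list", length(sizes) * splits_per_size)
  k <- 0L
  for (i in seq_along(sizes)) {
    sz <- sizes[[i]]
    if (length(sz) != 3L) rr_validation_error("each size entry must be c(n_known, n_unknown, n_overlap)")
    for (j in seq_len(splits_per_size)) {
      k <- k + 1L
      out[[k]] <- make_split(cohort, sz[1L], sz[2L], sz[3L],
                             probe_task = probe_task, enroll_task = enroll_task,
                             exclude_recordings = exclude_recordings,
                             seed = series_seed(seed, i, j))
    }
  }
  out
}

# per-split seed within a series; shared by make_split_series and
# run_experiment so both walk identical random streams
series_seed <- function(master, size_index, split_index) {
  derive_seed(master, size_index * 100000L + split_index, "split")
}

# Internal: assert all structural invariants of a split against its cohort.
# Used by tests and by run_experiment's consistency checks.
validate_split <- function(split, cohort) {
  stopifnot(inherits(split, "speaker_split"))
  unknown <- split$unknown_probes$speaker_id
  stopifnot(
    setequal(unknown, union(split$overlap_speakers, split$unknown_only_speakers)),
    length(intersect(split$overlap_speakers, split$unknown_only_speakers)) == 0L,
    length(intersect(split$unknown_only_speakers, split$known_speakers)) == 0L,
    all(split$overlap_speakers %in% split$known_speakers),
    anyDuplicated(unknown) == 0L,
    all(split$known_speakers %in% unique(split$enrollment$speaker_id))
  )
  # withheld probes never appear among that speaker's enrollment recordings
  for (s in split$overlap_speakers) {
    pr <- split$unknown_probes$recording_id[split$unknown_probes$speaker_id == s]
    stopifnot(!(pr %in% split$enrollment$recording_id[split$enrollment$speaker_id == s]))
  }
  invisible(TRUE)
}
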