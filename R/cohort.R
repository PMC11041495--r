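# The embedding cohort container: labelled recordings with fixed-dimension
# embedding vectors. This is the universe both attacker (known set) and
# defender (shared unknown set) sample from.

#' Construct an embedding cohort
#'
#' @param recording_id unique character ids, one per recording.
#' @param speaker_id character speaker labels.
#' @param task character task labels.
#' @param embeddings numeric matrix, one row per recording; all entries
#'   must be finite.
#' @param provenance a [generator_config()] or a character tag describing an
#'   external source.
#' @return an object of class `embedding_cohort`: a list with `records`
#'   (data frame of recording_id, speaker_id, task), `embeddings` (matrix
#'   with recording ids as row names) and `provenance`.
#' @export
embedding_cohort <- function(recording_id, speaker_id, task, embeddings,
                             provenance = "external") {
  embeddings <- as.matrix(embeddings)
  n <- length(recording_id)
  if (length(task) == 1L) task <- rep(task, n)
  if (length(speaker_id) != n || length(task) != n || nrow(embeddings) != n) {
    rr_validation_error("recording_id, speaker_id, task and embeddings must have matching lengths")
  }
  if (n == 0L) rr_validation_error("a cohort must contain at least one recording")
  if (anyDuplicated(recording_id)) rr_validation_error("recording_ids must be unique")
  if (!all(is.finite(embeddings))) rr_validation_error("all embeddings must be finite")
  rownames(embeddings) <- recording_id
  structure(list(
    records = data.frame(recording_id = as.character(recording_id),
                         speaker_id = as.character(speaker_id),
                         task = as.character(task),
                         stringsAsFactors = FALSE),
    embeddings = embeddings,
    provenance = provenance
  ), class = "embedding_cohort")
}

#' @export
print.embedding_cohort <- function(x, ...) {
  cat(sprintf("<embedding_cohort> %d recordings, %d speakers, %d task(s), dim %d\n",
              nrow(x$records), length(unique(x$records$speaker_id)),
              length(unique(x$records$task)), ncol(x$embeddings)))
  invisible(x)
}

#' Subset a cohort by recording ids
#'
#' @param cohort an [embedding_cohort()].
#' @param recording_ids ids to keep (order preserved).
#' @return an `embedding_cohort` restricted to the requested recordings.
#' @export
cohort_subset <- function(cohort, recording_ids) {
  idx <- match(recording_ids, cohort$records$recording_id)
  if (anyNA(idx)) {
    rr_validation_error(sprintf("unknown recording ids: %s",
                                paste(head(recording_ids[is.na(idx)], 3), collapse = ", ")))
  }
  embedding_cohort(cohort$records$recording_id[idx],
                   cohort$records$speaker_id[idx],
                   cohort$records$task[idx],
                   cohort$embeddings[idx, , drop = FALSE],
                   provenance = cohort$provenance)
}

#' Write a cohort as TSV plus a JSON sidecar
#'
#' The TSV has columns `recording_id`, `speaker_id`, `task`,
#' `e_0 ... e_{dim-1}` (UTF-8, "." decimal point, 17 significant digits so
#' values round-trip exactly). The sidecar `<path>.json` stores provenance:
#' the full generator configuration and seed when the cohort is synthetic.
#'
#' @param cohort an [embedding_cohort()].
#' @param path output TSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  d <- ncol(cohort$embeddings)
  num <- apply(cohort$embeddings, 2L, function(col) sprintf("%.17g", col))
  df <- cbind(cohort$records,
              as.data.frame(num, stringsAsFactors = FALSE))
  names(df) <- c("recording_id", "speaker_id", "task", paste0("e_", seq_len(d) - 1L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  jsonlite::write_json(provenance_json(cohort$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

provenance_json <- function(prov) {
  if (inherits(prov, "generator_config")) {
    list(source = "synthetic",
         generator = list(dim = prov$dim, n_speakers = prov$n_speakers,
                          tasks = prov$tasks,
                          between = cov_spec_json(prov$between),
                          within = cov_spec_json(prov$within),
                          channel_noise_sd = prov$channel_noise_sd,
                          seed = prov$seed))
  } else {
    list(source = as.character(prov))
  }
}

cov_spec_json <- function(spec) {
  if (is.numeric(spec) && length(spec) == 1L) list(type = "isotropic", variance = spec)
  else list(type = "full", matrix = as.matrix(spec))
}

provenance_from_json <- function(js) {
  if (identical(js$source, "synthetic") && !is.null(js$generator)) {
    g <- js$generator
    cov_in <- function(cs) {
      if (identical(cs$type, "isotropic")) cs$variance
      else matrix(unlist(cs$matrix), nrow = g$dim, byrow = FALSE)
    }
    tasks <- as.data.frame(g$tasks, stringsAsFactors = FALSE)
    generator_config(n_speakers = g$n_speakers, dim = g$dim,
                     tasks = speech_tasks(tasks$task, tasks$recordings,
                                          tasks$theta, tasks$sigma, tasks$offset),
                     between = cov_in(g$between), within = cov_in(g$within),
                     channel_noise_sd = g$channel_noise_sd, seed = g$seed)
  } else {
    js$source %||% "external"
  }
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path TSV path; the JSON sidecar `<path>.json` is read when present.
#' @return an [embedding_cohort()].
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character",
                   fileEncoding = "UTF-8")
  ecols <- grep("^e_[0-9]+$", names(df), value = TRUE)
  if (length(ecols) == 0L) rr_validation_error("no embedding columns e_0 ... found")
  ecols <- ecols[order(as.integer(sub("^e_", "", ecols)))]
  emb <- vapply(df[ecols], as.numeric, numeric(nrow(df)))
  if (nrow(df) == 1L) emb <- matrix(emb, nrow = 1L)
  sidecar <- paste0(path, ".json")
  prov <- if (file.exists(sidecar)) {
    provenance_from_json(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  } else "external"
  embedding_cohort(df$recording_id, df$speaker_id, df$task, emb, provenance = prov)
}
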