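# Two-covariance Gaussian PLDA.
#
# Model: x_si = mu + y_s + e_si with y_s ~ N(0, Phi_b) (speaker identity) and
# e_si ~ N(0, Phi_w) (within-speaker/channel variation). Verification scores
# are exact log-likelihood ratios of the same-speaker vs different-speaker
# hypotheses under this model. The full-rank two-covariance flavour is used:
# it is exactly scoreable and sufficient at the scales considered here.

#' Fit a two-covariance PLDA model by EM
#'
#' The global mean is the grand mean of the data. `Phi_b` and `Phi_w` are
#' initialised from the one-way ANOVA moment estimates and refined by EM on
#' the exact marginal likelihood; the per-iteration log-likelihood is
#' recorded and is non-decreasing. When `Phi_w` becomes ill-conditioned a
#' ridge `lambda * I` with `lambda = 1e-6 * mean(diag(Phi_w))` is added and
#' the model is flagged as regularised.
#'
#' @param embeddings numeric matrix (recordings x dim) or list of vectors.
#' @param speaker_labels speaker label per recording; at least 2 speakers.
#' @param max_iter maximum EM iterations.
#' @param tol stop when the log-likelihood gain drops below `tol`.
#' @param length_norm if `TRUE`, rows are scaled to unit Euclidean norm
#'   before fitting and the same normalisation is applied at scoring time.
#' @param center if `TRUE` (default) the model mean is the grand mean;
#'   otherwise the mean is fixed at zero.
#' @return an object of class `plda_model` with elements `mean`,
#'   `between_cov`, `within_cov`, `fit_log`, `iterations`, `converged`,
#'   `regularized`.
#' @export
fit_plda <- function(embeddings, speaker_labels, max_iter = 50L, tol = 1e-4,
                     length_norm = FALSE, center = TRUE) {
  X <- if (is.list(embeddings) && !is.matrix(embeddings)) {
    do.call(rbind, lapply(embeddings, as.numeric))
  } else as.matrix(embeddings)
  if (!all(is.finite(X))) rr_validation_error("embeddings must be finite")
  sp <- factor(speaker_labels)
  if (length(sp) != nrow(X)) rr_validation_error("speaker_labels must match the number of embeddings")
  S <- nlevels(sp)
  if (S < 2L) rr_degenerate_error("cannot estimate the between-speaker covariance from a single speaker")
  d <- ncol(X); N <- nrow(X)
  if (length_norm) {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0)) rr_validation_error("length normalisation undefined for zero vectors")
    X <- X / nrm
  }
  mu <- if (center) colSums(X) / N else numeric(d)
  Xc <- sweep(X, 2L, mu)

  ns <- as.vector(table(sp))
  means <- rowsum(Xc, sp) / ns                 # speaker means (S x d)
  SW <- crossprod(Xc - means[as.integer(sp), , drop = FALSE])

  regularized <- FALSE
  regularize <- function(W) {
    ev <- eigen(sym(W), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / min(ev) > 1e10) {
      regularized <<- TRUE
      W <- W + diag(1e-6 * mean(diag(W)), d)
    }
    sym(W)
  }

  # ANOVA moment initialisation (deterministic)
  Phiw <- regularize(SW / max(N - S, 1L))
  n0 <- (N - sum(ns^2) / N) / (S - 1)
  grand0 <- colSums(Xc) / N
  dm <- sweep(means, 2L, grand0)
  MSB <- crossprod(dm * sqrt(ns)) / (S - 1)
  Phib <- sym((MSB - Phiw) / n0)
  eb <- eigen(Phib, symmetric = TRUE)
  Phib <- sym(eb$vectors %*% (pmax(eb$values, 1e-4 * mean(diag(Phiw))) * t(eb$vectors)))

  groups <- split(seq_len(S), ns)              # speakers grouped by n_s
  fit_log <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Wi <- chol_inv(Phiw)
    ldW <- chol_logdet(Phiw)
    ll <- -0.5 * sum(Wi * SW) - 0.5 * (N - S) * ldW - 0.5 * N * d * log(2 * pi)
    Bacc <- matrix(0, d, d); Wacc <- SW; Macc <- 0
    for (g in names(groups)) {
      idx <- groups[[g]]; n <- as.integer(g)
      Vn <- sym(n * Phib + Phiw)               # cov of sqrt-n-scaled speaker mean part
      Vni <- chol_inv(Vn)
      Mg <- means[idx, , drop = FALSE]
      ll <- ll - 0.5 * length(idx) * chol_logdet(Vn) -
        0.5 * n * sum((Mg %*% Vni) * Mg)
      # E-step: posterior of y_s given the data, T = (Phib^-1 + n Phiw^-1)^-1,
      # computed stably as Phib - n Phib (n Phib + Phiw)^-1 Phib
      Tn <- sym(Phib - n * Phib %*% Vni %*% Phib)
      Ms <- n * (Mg %*% Wi %*% Tn)             # posterior means E[y_s]
      Bacc <- Bacc + crossprod(Ms) + length(idx) * Tn
      R <- Mg - Ms
      Wacc <- Wacc + n * crossprod(R) + length(idx) * n * Tn
    }
    fit_log <- c(fit_log, ll)
    if (iter > 1L && (ll - fit_log[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
    if (iter == max_iter) break  # keep parameters matching the last recorded ll
    Phib <- sym(Bacc / S)
    Phiw <- regularize(Wacc / N)
  }

  structure(list(mean = mu, between_cov = sym(Phib), within_cov = sym(Phiw),
                 fit_log = fit_log, iterations = length(fit_log),
                 converged = converged, regularized = regularized,
                 dim = d, n_speakers = S, length_norm = length_norm),
            class = "plda_model")
}

#' @export
print.plda_model <- function(x, ...) {
  cat(sprintf("<plda_model> dim %d, fitted on %d speakers, %d EM iterations%s%s\n",
              x$dim, x$n_speakers, x$iterations,
              if (x$converged) " (converged)" else "",
              if (x$regularized) ", within-cov regularised" else ""))
  invisible(x)
}

#' Enroll speakers by averaging their embeddings
#'
#' Each known speaker is represented by the arithmetic mean of their
#' enrollment embeddings; the number averaged is recorded because the
#' enrolled vector's within-speaker covariance shrinks as `Phi_w / n`.
#'
#' @param cohort an [embedding_cohort()] containing the enrollment
#'   recordings (e.g. via [cohort_subset()]).
#' @param recordings optional data frame with columns `speaker_id`,
#'   `recording_id` restricting which recordings enter each average (used by
#'   splits to honour probe withholding); default: all recordings in
#'   `cohort`, grouped by speaker.
#' @return an `enrollment_table`: list with `speaker_id`, `vectors`
#'   (speakers x dim matrix) and `n_averaged`.
#' @export
enroll <- function(cohort, recordings = NULL) {
  stopifnot(inherits(cohort, "embedding_cohort"))
  if (is.null(recordings)) {
    recordings <- cohort$records[, c("speaker_id", "recording_id")]
  }
  if (nrow(recordings) == 0L) rr_validation_error("no enrollment recordings given")
  idx <- match(recordings$recording_id, cohort$records$recording_id)
  if (anyNA(idx)) rr_validation_error("enrollment recording ids missing from cohort")
  sp <- factor(recordings$speaker_id, levels = unique(recordings$speaker_id))
  n_averaged <- as.vector(table(sp))
  if (any(n_averaged < 1L)) rr_validation_error("every enrolled speaker needs >= 1 recording")
  vec <- rowsum(cohort$embeddings[idx, , drop = FALSE], sp, reorder = FALSE) / n_averaged
  structure(list(speaker_id = levels(sp), vectors = unname(vec),
                 n_averaged = n_averaged),
            class = "enrollment_table")
}

#' @export
print.enrollment_table <- function(x, ...) {
  cat(sprintf("<enrollment_table> %d speakers, dim %d, recordings averaged: %s\n",
              length(x$speaker_id), ncol(x$vectors),
              paste(range(x$n_averaged), collapse = "-")))
  invisible(x)
}

# Precompute scoring matrices for a given enrollment average size n.
# With A = Phib + Phiw/n, B = Phib + Phiw, C = Phib, the joint covariance of
# (enrolled, probe) is [[A, C], [C, B]] under H_same and diag(A, B) under
# H_diff, and (with S = B - C A^-1 C the Schur complement)
#   LLR = 0.5 (log|B| - log|S|) - 0.5 e'Me + e'Hp - 0.5 p'Gp
# on centred vectors, where M = A^-1 C S^-1 C A^-1, H = A^-1 C S^-1,
# G = S^-1 - B^-1.
plda_score_params <- function(model, n_averaged) {
  A <- sym(model$between_cov + model$within_cov / n_averaged)
  B <- sym(model$between_cov + model$within_cov)
  C <- model$between_cov
  Ai <- chol_inv(A)
  Sc <- sym(B - C %*% Ai %*% C)
  Si <- chol_inv(Sc)
  H <- Ai %*% C %*% Si
  list(c0 = 0.5 * (chol_logdet(B) - chol_logdet(Sc)),
       M = sym(H %*% C %*% Ai), H = H, G = sym(Si - chol_inv(B)))
}

#' Score a probe against an enrolled speaker
#'
#' Exact log-likelihood ratio of the same-speaker vs different-speaker
#' hypotheses under the two-covariance model; the enrolled vector's
#' within-speaker covariance is scaled by `1/n_averaged` because it is an
#' average of `n_averaged` recordings.
#'
#' @param model a fitted [fit_plda()] model.
#' @param enrolled enrolled (averaged) embedding vector.
#' @param n_averaged number of recordings averaged into `enrolled`.
#' @param probe probe embedding vector.
#' @return a finite scalar LLR; positive favours a same-speaker match.
#' @export
score_llr <- function(model, enrolled, n_averaged = 1L, probe) {
  stopifnot(inherits(model, "plda_model"))
  enrolled <- as.numeric(enrolled); probe <- as.numeric(probe)
  if (length(enrolled) != model$dim || length(probe) != model$dim) {
    rr_validation_error(sprintf("vectors must have the model dimension %d", model$dim))
  }
  if (model$length_norm) {
    enrolled <- enrolled / sqrt(sum(enrolled^2))
    probe <- probe / sqrt(sum(probe^2))
  }
  p <- plda_score_params(model, n_averaged)
  e <- enrolled - model$mean; q <- probe - model$mean
  drop(p$c0 - 0.5 * e %*% p$M %*% e + e %*% p$H %*% q - 0.5 * q %*% p$G %*% q)
}

#' Score every probe against every enrolled speaker
#'
#' @param model a fitted [fit_plda()] model.
#' @param enrollments an `enrollment_table` from [enroll()].
#' @param probes a numeric matrix (probes x dim) with probe ids as row
#'   names, or a named list of vectors.
#' @return an `n_probes x n_known` matrix of LLRs; entry `(i, j)` equals
#'   `score_llr` for probe i vs enrolled speaker j.
#' @export
score_matrix <- function(model, enrollments, probes) {
  stopifnot(inherits(model, "plda_model"), inherits(enrollments, "enrollment_table"))
  P <- if (is.list(probes) && !is.matrix(probes)) {
    do.call(rbind, lapply(probes, as.numeric))
  } else as.matrix(probes)
  if (nrow(P) == 0L || length(enrollments$speaker_id) == 0L) {
    rr_validation_error("score_matrix requires at least one probe and one enrollment")
  }
  if (ncol(P) != model$dim || ncol(enrollments$vectors) != model$dim) {
    rr_validation_error(sprintf("vectors must have the model dimension %d", model$dim))
  }
  if (model$length_norm) P <- P / sqrt(rowSums(P^2))
  Pc <- sweep(P, 2L, model$mean)
  E <- if (model$length_norm) {
    enrollments$vectors / sqrt(rowSums(enrollments$vectors^2))
  } else enrollments$vectors
  Ec <- sweep(E, 2L, model$mean)
  out <- matrix(NA_real_, nrow(P), nrow(Ec),
                dimnames = list(rownames(P), enrollments$speaker_id))
  for (n in unique(enrollments$n_averaged)) {
    j <- which(enrollments$n_averaged == n)
    par <- plda_score_params(model, n)
    qE <- rowSums((Ec[j, , drop = FALSE] %*% par$M) * Ec[j, , drop = FALSE])
    qP <- rowSums((Pc %*% par$G) * Pc)
    cross <- Pc %*% t(par$H) %*% t(Ec[j, , drop = FALSE])  # p' H' e = e' H p
    out[, j] <- par$c0 + cross - 0.5 * outer(qP, qE, "+")
  }
  if (!all(is.finite(out))) rr_stop("non-finite scores produced; check the model covariances")
  out
}
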