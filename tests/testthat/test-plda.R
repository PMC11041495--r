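# Two-covariance PLDA: EM fit, enrollment averaging, and exact LLR scoring
# checked against independent oracles.

test_that("EM on the balanced 1-D toy reaches the closed-form ML fixed point", {
  X <- matrix(c(0, 2, 10, 12), ncol = 1)
  lab <- c("A", "A", "B", "B")
  m <- fit_plda(X, lab, max_iter = 500, tol = 1e-12)
  # ML closed form for the balanced one-way model (grand mean 6):
  # sigma_w^2 = SSW / (N - S) = 2; v = mean((m_s - mu)^2) = 25;
  # sigma_b^2 = v - sigma_w^2 / n = 24
  expect_equal(drop(m$mean), 6)
  expect_equal(drop(m$within_cov), 2, tolerance = 1e-4)
  expect_equal(drop(m$between_cov), 24, tolerance = 1e-4)
  # independent check: direct numeric maximisation of the marginal likelihood
  nll <- function(par) {
    sw <- exp(par[1]); sb <- exp(par[2])
    v <- sb + sw / 2
    -(sum(-0.5 * log(2 * pi * v) - (c(1, 11) - 6)^2 / (2 * v)) +
        sum(-0.5 * log(2 * pi * sw) - c(2, 2) / (2 * sw)))
  }
  o <- optim(c(0, 0), nll)
  expect_equal(drop(m$within_cov), exp(o$par[1]), tolerance = 1e-2)
  expect_equal(drop(m$between_cov), exp(o$par[2]), tolerance = 1e-2)
})

test_that("the per-iteration log-likelihood is non-decreasing", {
  for (seed in 1:3) {
    coh <- toy_cohort(n_speakers = 40, recs = 4, d = 6, seed = seed, within = 0.7)
    m <- fit_plda(coh$embeddings, coh$records$speaker_id, max_iter = 30, tol = 0)
    expect_true(all(diff(m$fit_log) >= -1e-8))
  }
})

test_that("fitting requires at least two speakers", {
  X <- matrix(rnorm(10), 5)
  expect_error(fit_plda(X, rep("only", 5)), class = "reidrisk_degenerate_error")
})

test_that("rank-deficient data triggers reported within-covariance regularisation", {
  # embeddings confined to a 1-D subspace of a 3-D space
  base <- matrix(rnorm(40), 40, 1) %*% t(c(1, 1, 1))
  lab <- rep(letters[1:10], each = 4)
  m <- fit_plda(base, lab)
  expect_true(m$regularized)
  expect_true(all(is.finite(m$within_cov)))
  expect_no_error(chol(m$within_cov))
})

test_that("enrollment averages embeddings and records the count", {
  X <- rbind(c(0, 0), c(2, 2), c(5, 1))
  coh <- embedding_cohort(c("r1", "r2", "r3"), c("A", "A", "B"), "t", X)
  enr <- enroll(coh)
  expect_equal(enr$vectors[enr$speaker_id == "A", ], c(1, 1))
  expect_equal(enr$n_averaged[enr$speaker_id == "A"], 2L)
  expect_equal(enr$vectors[enr$speaker_id == "B", ], c(5, 1))  # single recording
  expect_error(enroll(coh, data.frame(speaker_id = character(0),
                                      recording_id = character(0))),
               class = "reidrisk_validation_error")
})

test_that("withheld probe recordings never enter the enrollment average", {
  coh <- toy_cohort(n_speakers = 15, recs = 3, d = 3, seed = 11)
  split <- make_split(coh, n_known = 10, n_unknown = 6, n_overlap = 4, seed = 21)
  enr <- enroll(coh, split$enrollment)
  for (s in split$overlap_speakers) {
    probe <- split$unknown_probes$recording_id[split$unknown_probes$speaker_id == s]
    kept <- setdiff(coh$records$recording_id[coh$records$speaker_id == s], probe)
    manual <- colMeans(coh$embeddings[kept, , drop = FALSE])
    expect_equal(enr$vectors[enr$speaker_id == s, ], manual)
    expect_equal(enr$n_averaged[enr$speaker_id == s], length(kept))
  }
})

test_that("LLR matches hand values and degenerates correctly", {
  m1 <- toy_plda_model(0, matrix(1), matrix(1))
  expect_equal(score_llr(m1, 0, 1, 0), 0.5 * log(4 / 3))
  # no between-speaker variance: hypotheses coincide, LLR identically zero
  m0 <- toy_plda_model(c(0, 0), matrix(0, 2, 2), diag(2))
  for (i in 1:5) {
    expect_equal(score_llr(m0, rnorm(2), 1, rnorm(2)), 0)
  }
  expect_error(score_llr(m1, c(0, 0), 1, 0), class = "reidrisk_validation_error")
})

test_that("LLR equals the brute-force stacked-Gaussian evaluation", {
  set.seed(31)
  for (i in 1:25) {
    d <- sample(1:4, 1)
    m <- toy_plda_model(rnorm(d), random_psd(d), random_psd(d) + diag(0.5, d))
    n <- sample(1:6, 1)
    e <- rnorm(d); p <- rnorm(d)
    expect_equal(score_llr(m, e, n, p), brute_force_llr(m, e, n, p),
                 tolerance = 1e-10)
  }
})

test_that("the LLR is symmetric in its arguments for single-recording enrollment", {
  set.seed(8)
  m <- toy_plda_model(rnorm(3), random_psd(3), random_psd(3) + diag(3))
  e <- rnorm(3); p <- rnorm(3)
  expect_equal(score_llr(m, e, 1, p), score_llr(m, p, 1, e), tolerance = 1e-10)
})

test_that("score_matrix agrees with elementwise score_llr", {
  set.seed(13)
  d <- 3
  m <- toy_plda_model(rnorm(d), random_psd(d), random_psd(d) + diag(d))
  E <- matrix(rnorm(3 * d), 3); n_avg <- c(1L, 4L, 2L)
  enr <- structure(list(speaker_id = c("k1", "k2", "k3"), vectors = E,
                        n_averaged = n_avg), class = "enrollment_table")
  P <- matrix(rnorm(2 * d), 2, dimnames = list(c("p1", "p2"), NULL))
  sc <- score_matrix(m, enr, P)
  expect_equal(dim(sc), c(2L, 3L))
  for (i in 1:2) for (j in 1:3) {
    expect_equal(sc[i, j], score_llr(m, E[j, ], n_avg[j], P[i, ]), tolerance = 1e-10)
  }
  # single pair reduces to score_llr
  one <- score_matrix(m, structure(list(speaker_id = "k", vectors = E[1, , drop = FALSE],
                                        n_averaged = 1L), class = "enrollment_table"),
                      P[1, , drop = FALSE])
  expect_equal(drop(one), score_llr(m, E[1, ], 1, P[1, ]))
  expect_error(score_matrix(m, enr, P[0, , drop = FALSE]),
               class = "reidrisk_validation_error")
})

test_that("a large probe-by-enrollment score matrix is finite throughout", {
  set.seed(77)
  d <- 16
  m <- toy_plda_model(rnorm(d), random_psd(d), random_psd(d) + diag(0.3, d))
  enr <- structure(list(speaker_id = sprintf("k%04d", 1:6000),
                        vectors = matrix(rnorm(6000 * d), 6000),
                        n_averaged = sample(1:6, 6000, replace = TRUE)),
                   class = "enrollment_table")
  sc <- score_matrix(m, enr, matrix(rnorm(163 * d), 163))
  expect_equal(dim(sc), c(163L, 6000L))
  expect_true(all(is.finite(sc)))
})

test_that("genuine pairs outscore impostor pairs when speakers dominate the variance", {
  diffs <- vapply(1:20, function(seed) {
    coh <- toy_cohort(n_speakers = 25, recs = 3, d = 5, seed = seed, within = 0.3)
    m <- fit_plda(coh$embeddings, coh$records$speaker_id)
    enr <- enroll(coh, coh$records[!duplicated(coh$records$speaker_id),
                                   c("speaker_id", "recording_id")])
    probes_idx <- which(duplicated(coh$records$speaker_id))
    P <- coh$embeddings[probes_idx, , drop = FALSE]
    sc <- score_matrix(m, enr, P)
    lab <- outer(coh$records$speaker_id[probes_idx], enr$speaker_id, "==")
    mean(sc[lab]) - mean(sc[!lab])
  }, numeric(1))
  expect_gt(min(diffs), 0)
  expect_lt(t.test(diffs, alternative = "greater")$p.value, 1e-6)
})

test_that("covariance recovery from a generated cohort is accurate", {
  # moderate size here; the full-scale recovery is exercised in the
  # acceptance suite
  Phib <- diag(seq(0.5, 1.5, length.out = 4))
  coh_cfg <- generator_config(n_speakers = 300, dim = 4,
                              tasks = speech_tasks("t", recordings = 8),
                              between = Phib, within = 0.4, seed = 17)
  coh <- generate_cohort(coh_cfg)
  m <- fit_plda(coh$embeddings, coh$records$speaker_id)
  expect_lt(norm(m$between_cov - Phib, "F") / norm(Phib, "F"), 0.2)
  expect_lt(norm(m$within_cov - diag(0.4, 4), "F") / norm(diag(0.4, 4), "F"), 0.2)
})
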