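# Attack execution: acceptance variants on enumerable score matrices,
# outcome counting, search-space arithmetic and monotonicity properties.

toy_matrix <- matrix(c(1.2, 0.1, -0.5,
                       0.9, 0.95, -1.0),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(c("p1", "p2"), c("k1", "k2", "k3")))

test_that("acceptance variants reproduce the enumerated toy", {
  all_acc <- accept_matches(toy_matrix, 0.9, "all")
  acc <- all_acc[all_acc$accepted, c("probe_id", "known_speaker")]
  expect_setequal(paste(acc$probe_id, acc$known_speaker),
                  c("p1 k1", "p2 k1", "p2 k2"))
  top2 <- accept_matches(toy_matrix, 0.9, "topN", N = 2)
  acc2 <- top2[top2$accepted, c("probe_id", "known_speaker")]
  expect_setequal(paste(acc2$probe_id, acc2$known_speaker), c("p1 k1", "p2 k2"))
  # N beyond the accepted count keeps everything accepted
  top9 <- accept_matches(toy_matrix, 0.9, "topN", N = 9)
  expect_equal(sum(top9$accepted), 3)
  r1 <- accept_matches(toy_matrix, 0.9, "rank1")
  accr <- r1[r1$accepted, ]
  expect_setequal(paste(accr$probe_id, accr$known_speaker), c("p1 k1", "p2 k2"))
  expect_true(all(accr$rank == 1L))
  # ranks are a permutation of 1..n_known per probe
  for (p in c("p1", "p2")) expect_setequal(all_acc$rank[all_acc$probe_id == p], 1:3)
  expect_equal(sum(accept_matches(toy_matrix, Inf, "all")$accepted), 0)
  expect_error(accept_matches(toy_matrix, 0, "topN"), class = "reidrisk_validation_error")
})

test_that("outcome counting reproduces hand-enumerated summaries", {
  probes <- data.frame(speaker_id = c("k1", "x2"),
                       recording_id = c("p1", "p2"), stringsAsFactors = FALSE)
  split <- hand_split(known = c("k1", "k2", "k3"), probes_df = probes,
                      overlap = "k1")
  tab <- as_match_table(accept_matches(toy_matrix, 0.9, "all"),
                        c(p1 = "k1", p2 = "x2"), split)
  s <- count_outcomes(tab, split)
  expect_equal(s$TA, 1)          # (p1, k1)
  expect_equal(s$FA, 2)          # (p2, k1), (p2, k2)
  expect_equal(s$precision, 1 / 3)
  expect_equal(s$comparisons, 6)
  expect_equal(s$genuine_pairs, 1)
  expect_equal(s$FAR, 2 / 5)
  expect_equal(s$fa_ta_ratio, 2)
})

test_that("degenerate outcome counts follow the definitional conventions", {
  probes <- data.frame(speaker_id = c("k1", "k2"),
                       recording_id = c("p1", "p2"), stringsAsFactors = FALSE)
  split <- hand_split(known = c("k1", "k2", "k3"), probes_df = probes,
                      overlap = c("k1", "k2"))
  m <- matrix(c(5, -9, -9, -9, 5, -9), 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("k1", "k2", "k3")))
  s <- count_outcomes(as_match_table(accept_matches(m, 0, "all"),
                                     c(p1 = "k1", p2 = "k2"), split), split)
  expect_equal(s$TA, 2); expect_equal(s$FA, 0)
  expect_equal(s$precision, 1)
  expect_equal(s$fa_ta_ratio, 0)
  # nothing accepted: precision undefined, not zero
  s0 <- count_outcomes(as_match_table(accept_matches(m, 10, "all"),
                                      c(p1 = "k1", p2 = "k2"), split), split)
  expect_true(is.na(s0$precision))
  expect_true(is.na(s0$fa_ta_ratio))
  # only false acceptances: zero precision, infinite FA/TA
  m2 <- matrix(c(-9, -9, 5, -9, -9, 5), 2, byrow = TRUE,
               dimnames = dimnames(m))
  s2 <- count_outcomes(as_match_table(accept_matches(m2, 0, "all"),
                                      c(p1 = "k1", p2 = "k2"), split), split)
  expect_equal(s2$TA, 0); expect_equal(s2$FA, 2)
  expect_equal(s2$precision, 0)
  expect_equal(s2$fa_ta_ratio, Inf)
  expect_equal(s2$FAR, 2 / (6 - 2))
})

test_that("raising the threshold never increases acceptances of either kind", {
  set.seed(12)
  probes <- data.frame(speaker_id = sprintf("u%d", 1:6),
                       recording_id = sprintf("p%d", 1:6), stringsAsFactors = FALSE)
  probes$speaker_id[1:2] <- c("k1", "k2")
  split <- hand_split(known = sprintf("k%d", 1:8), probes_df = probes,
                      overlap = c("k1", "k2"))
  speaker_of <- setNames(probes$speaker_id, probes$recording_id)
  m <- matrix(rnorm(48), 6, 8,
              dimnames = list(probes$recording_id, sprintf("k%d", 1:8)))
  prev_ta <- Inf; prev_fa <- Inf
  for (thr in seq(-2, 2, by = 0.25)) {
    s <- count_outcomes(as_match_table(accept_matches(m, thr, "all"),
                                       speaker_of, split), split)
    expect_lte(s$TA, prev_ta); expect_lte(s$FA, prev_fa)
    prev_ta <- s$TA; prev_fa <- s$FA
  }
})

test_that("rank1 and topN acceptances are nested within the accept-all set", {
  set.seed(23)
  for (i in 1:10) {
    m <- matrix(rnorm(35), 5, 7,
                dimnames = list(paste0("p", 1:5), paste0("k", 1:7)))
    thr <- rnorm(1)
    key <- function(tab) paste(tab$probe_id, tab$known_speaker)[tab$accepted]
    all_k <- key(accept_matches(m, thr, "all"))
    r1 <- accept_matches(m, thr, "rank1")
    expect_true(all(key(r1) %in% all_k))
    expect_lte(max(table(r1$probe_id[r1$accepted])), 1)
    n <- sample(1:6, 1)
    topn <- key(accept_matches(m, thr, "topN", N = n))
    expect_true(all(topn %in% all_k))
    expect_lte(length(topn), n)
  }
})

test_that("run_attack wires enrollment, scoring and acceptance together", {
  coh <- toy_cohort(n_speakers = 20, recs = 3, d = 4, seed = 31, within = 0.2)
  split <- make_split(coh, 12, 6, 3, seed = 7)
  model <- fit_plda(coh$embeddings, coh$records$speaker_id)
  tab <- run_attack(model, split, coh, threshold = 0, variant = "all")
  expect_s3_class(tab, "match_table")
  expect_equal(nrow(tab), 6 * 12)
  s <- count_outcomes(tab, split)
  expect_equal(s$comparisons, 72)
  expect_lte(s$TA, s$genuine_pairs)
  # manual rescore of one accepted pair
  row <- tab[which(tab$accepted)[1], ]
  enr <- enroll(coh, split$enrollment)
  j <- match(row$known_speaker, enr$speaker_id)
  probe <- coh$embeddings[row$probe_id, ]
  expect_equal(row$score,
               score_llr(model, enr$vectors[j, ], enr$n_averaged[j], probe))
  expect_equal(sum(run_attack(model, split, coh, Inf)$accepted), 0)
})

test_that("probe pooling replaces probes by speaker-mean embeddings", {
  coh <- toy_cohort(n_speakers = 16, recs = 3, d = 4, seed = 41, within = 0.2)
  split <- make_split(coh, 10, 5, 2, seed = 3)
  model <- fit_plda(coh$embeddings, coh$records$speaker_id)
  pooled <- run_attack(model, split, coh, threshold = -Inf, pool_probes = TRUE)
  enr <- enroll(coh, split$enrollment)
  s1 <- split$unknown_probes$speaker_id[1]
  mean_vec <- colMeans(coh$embeddings[coh$records$speaker_id == s1, , drop = FALSE])
  j <- 1
  row <- pooled[pooled$probe_speaker == s1 & pooled$known_speaker == enr$speaker_id[j], ]
  expect_equal(row$score,
               score_llr(model, enr$vectors[j, ], enr$n_averaged[j], mean_vec))
})

test_that("search-space arithmetic matches the worked examples", {
  expect_equal(search_space(6000, 1000)$comparisons, 6e6)
  strat <- search_space(6000, 1000, 0.5, 0.5)
  expect_equal(strat$comparisons, 1.5e6)
  expect_equal(strat$reduction_pct, 75)
  expect_equal(search_space(6000, 0)$comparisons, 0)
  expect_error(search_space(10, 10, 0, 1), class = "reidrisk_validation_error")
})
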