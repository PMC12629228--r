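test_that("top-quantile votes follow the ceiling rule and tie-break by id", {
  set.seed(1)
  s <- 100
  ids <- sprintf("S%03d", 1:s)
  scores <- rnorm(s)
  v <- method_votes(scores, ids, "positive", 0.05)
  expect_identical(sum(v), 5L)
  expect_setequal(ids[v == 1L], ids[order(-scores)][1:5])

  # negative direction votes for the most negative scores
  vn <- method_votes(scores, ids, "negative", 0.05)
  expect_setequal(ids[vn == 1L], ids[order(scores)][1:5])

  # S = 10, quantile 0.05 -> ceiling(0.5) = 1 voted (degenerate, warns)
  expect_warning(v10 <- method_votes(rnorm(10), sprintf("T%02d", 1:10),
                                     "positive", 0.05),
                 "degenerate")
  expect_identical(sum(v10), 1L)

  # p-values dominate the ranking when supplied
  p <- rep(0.5, s); p[7] <- 0.001
  vp <- method_votes(scores, ids, "positive", 0.01, p = p)
  expect_identical(which(vp == 1L), 7L)

  # ineligible references never vote
  elig <- rep(TRUE, s); elig[order(-scores)[1]] <- FALSE
  ve <- method_votes(scores, ids, "positive", 0.05, eligible = elig)
  expect_identical(ve[order(-scores)[1]], 0L)
  expect_identical(sum(ve), 5L)
})

test_that("meta-score is the sum of exactly six binary votes", {
  expect_identical(meta_score(rep(1L, 6)), 6L)
  expect_identical(meta_score(rep(0L, 6)), 0L)
  expect_identical(meta_score(c(1, 1, 1, 0, 0, 0)), 3L)
  expect_error(meta_score(rep(1L, 5)), "six votes")
  expect_error(meta_score(c(1, 1, 1, 0, 0, 2)), "0 or 1")
})

test_that("the WTCS gate admits references significant by any of the five
          other methods", {
  flags <- cbind(c(TRUE, FALSE, FALSE), c(FALSE, FALSE, FALSE),
                 c(FALSE, FALSE, FALSE), c(FALSE, FALSE, FALSE),
                 c(FALSE, FALSE, TRUE))
  expect_identical(wtcs_gate(flags), c(TRUE, FALSE, TRUE))
  expect_identical(wtcs_gate(matrix(TRUE, 4, 5)), rep(TRUE, 4))
  expect_error(wtcs_gate(matrix(TRUE, 4, 4)), "5 methods")
})

test_that("a positive screen ranks an exact planted copy of the query first
          with meta-score 6", {
  fx <- small_screen_fixture(n_genes = 150, n_sigs = 81, seed = 17,
                             planted = list(list(kind = "mimic", alpha = 1,
                                                 noise_sd = 0)))
  cfg <- screen_config(K = 15, n_perm = 300, direction = "positive",
                       seed = 17)
  rep <- run_screen(fx$query, fx$repo, cfg)
  top <- rep$results[1, ]
  expect_identical(top$sig_id, fx$truth$sig_id)
  expect_identical(top$rank, 1L)
  expect_identical(top$meta_score, 6L)
  # ranks are 1..S with no gaps; meta equals the vote sum everywhere
  expect_identical(rep$results$rank, seq_len(nrow(rep$results)))
  vote_cols <- paste0("vote_", c("pearson", "spearman", "cosine", "wtcs",
                                 "css", "xsum"))
  expect_identical(rep$results$meta_score,
                   as.integer(rowSums(rep$results[, vote_cols])))
  # every reference receiving a non-WTCS vote is in the gated set
  non_wtcs <- rowSums(rep$results[, setdiff(vote_cols, "vote_wtcs")]) > 0
  expect_true(all(rep$results$gated_wtcs[non_wtcs]))
  # ungated references carry no WTCS value and no WTCS vote
  expect_true(all(is.na(rep$results$wtcs[!rep$results$gated_wtcs])))
  expect_true(all(rep$results$vote_wtcs[!rep$results$gated_wtcs] == 0L))
})

test_that("a negative screen recovers a planted reversal at rank 1, and the
          flipped direction does not", {
  fx <- small_screen_fixture(n_genes = 200, n_sigs = 101, seed = 23,
                             planted = list(list(kind = "reversal", alpha = 1,
                                                 noise_sd = 0.3)))
  cfg <- screen_config(K = 20, n_perm = 300, direction = "negative",
                       seed = 23)
  rep_neg <- run_screen(fx$query, fx$repo, cfg)
  expect_identical(rep_neg$results$sig_id[1], fx$truth$sig_id)
  expect_gte(rep_neg$results$meta_score[1], 5L)

  cfg_pos <- screen_config(K = 20, n_perm = 300, direction = "positive",
                           seed = 23)
  rep_pos <- run_screen(fx$query, fx$repo, cfg_pos)
  expect_false(rep_pos$results$sig_id[1] == fx$truth$sig_id)
})

test_that("screens are bit-identical across repeat runs and worker counts", {
  fx <- small_screen_fixture(n_genes = 100, n_sigs = 41, seed = 31)
  cfg1 <- screen_config(K = 10, n_perm = 150, direction = "negative",
                        seed = 31, threads = 1L)
  cfg4 <- screen_config(K = 10, n_perm = 150, direction = "negative",
                        seed = 31, threads = 4L)
  r1 <- run_screen(fx$query, fx$repo, cfg1)
  r2 <- run_screen(fx$query, fx$repo, cfg1)
  r4 <- run_screen(fx$query, fx$repo, cfg4)
  expect_identical(r1$results, r2$results)
  r4$config <- r1$config  # threads is the only permitted difference
  expect_identical(r1$results, r4$results)
})

test_that("reversal duality: negating the query and flipping the direction
          reproduces the ranking", {
  fx <- small_screen_fixture(n_genes = 100, n_sigs = 41, seed = 37)
  cfg_pos <- screen_config(K = 10, n_perm = 200, direction = "positive",
                           seed = 37)
  cfg_neg <- screen_config(K = 10, n_perm = 200, direction = "negative",
                           seed = 37)
  q_neg <- signature_record(fx$query$sig_id, fx$query$gene_ids, -fx$query$z)
  r1 <- run_screen(fx$query, fx$repo, cfg_pos)
  r2 <- run_screen(q_neg, fx$repo, cfg_neg)
  expect_identical(r1$results$sig_id, r2$results$sig_id)
  expect_identical(r1$results$meta_score, r2$results$meta_score)
})

test_that("mean meta-score over a null repository approximates six times the
          vote quantile", {
  means <- vapply(1:6, function(seed) {
    fx <- small_screen_fixture(n_genes = 80, n_sigs = 100, seed = 100 + seed)
    cfg <- screen_config(K = 8, n_perm = 100, direction = "negative",
                         seed = 100 + seed)
    mean(run_screen(fx$query, fx$repo, cfg)$results$meta_score)
  }, numeric(1))
  # each method votes exactly ceil(0.05 * 100) = 5 of 100 -> mean meta = 0.3
  expect_equal(mean(means), 6 * 0.05, tolerance = 0.01)
  expect_true(all(abs(means - 0.3) < 1e-12))
})

test_that("screens accept precomputed background stores and reject stale or
          missing coverage", {
  fx <- small_screen_fixture(n_genes = 80, n_sigs = 25, seed = 41)
  dir <- withr::local_tempdir()
  build_background_store(fx$repo, K_values = 8L, n_perm = 120, seed = 41,
                         dir = dir)
  cfg <- screen_config(K = 8, n_perm = 120, direction = "negative", seed = 41)
  r_store <- run_screen(fx$query, fx$repo, cfg, backgrounds = dir)
  r_fly <- run_screen(fx$query, fx$repo, cfg, backgrounds = NULL)
  # same seed derivation: on-the-fly and stored backgrounds agree exactly
  expect_identical(r_store$results, r_fly$results)

  cfg_stale <- screen_config(K = 8, n_perm = 999, direction = "negative",
                             seed = 41)
  expect_error(run_screen(fx$query, fx$repo, cfg_stale, backgrounds = dir),
               "stale")
  cfg_missing <- screen_config(K = 9, n_perm = 120, direction = "negative",
                               seed = 41)
  expect_error(run_screen(fx$query, fx$repo, cfg_missing, backgrounds = dir),
               "no stored")
})
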