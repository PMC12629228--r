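test_that("full-vector similarities reproduce closed-form values", {
  expect_equal(pearson_score(c(1, 2, 3), c(1, 2, 4)), 9 / (2 * sqrt(21)),
               tolerance = 1e-12)
  expect_equal(pearson_score(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_score(c(1, 2, 3), c(-1, -2, -3)), -1)
  expect_error(pearson_score(c(1, 1, 1), c(1, 2, 3)), "zero-variance")

  # hand rank computation: d = (0, -1, 1, 0), 1 - 6*2/(4*15) = 0.8
  expect_equal(spearman_score(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # rank invariance under monotone transforms
  x <- c(0.3, -1.2, 2.5, 0.9, -0.4)
  expect_equal(spearman_score(x, exp(x)), 1)
  expect_equal(spearman_score(x, -x^3), -1)

  expect_equal(cosine_score(c(1, 0), c(1, 1)), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cosine_score(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_score(c(1, 2, 3), 7 * c(1, 2, 3)), 1)
  expect_error(cosine_score(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("enrichment score reproduces the 4-gene hand computation and
          enforces preconditions", {
  ref <- signature_record("r", paste0("g", 1:4), c(2, 1, -1, -2))
  expect_equal(enrichment_score("g1", ref), 1)
  expect_equal(enrichment_score("g4", ref), -1)
  expect_error(enrichment_score(paste0("g", 1:4), ref), "disallowed")
  expect_error(enrichment_score("absent", ref), "absent from reference")
})

test_that("enrichment score matches the position-by-position running-sum
          oracle on random instances", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(6:30, 1)
    genes <- sprintf("g%02d", seq_len(n))
    z <- rnorm(n)
    m <- sample(1:(n - 1), 1)
    gene_set <- sample(genes, m)
    ref <- signature_record("r", genes, z)
    expect_equal(enrichment_score(gene_set, ref),
                 oracle_es(gene_set, genes, z),
                 tolerance = 1e-12)
  }
})

test_that("WTCS combines opposite-sign enrichment components and is zero
          otherwise", {
  ref <- signature_record("r", paste0("g", 1:4), c(2, 1, -1, -2))
  q <- signature_record("q", paste0("g", 1:4), c(2, 1, -1, -2))
  ex <- select_extreme_genes(q, 1)
  w <- wtcs(ex, ref)
  expect_equal(w$value, 1)        # (1 - (-1)) / 2
  expect_equal(w$es_up, 1)
  expect_equal(w$es_down, -1)

  # swapping up and down negates the score
  swapped <- ex
  swapped$up <- ex$down; swapped$down <- ex$up
  swapped$up_z <- ex$down_z; swapped$down_z <- ex$up_z
  expect_equal(wtcs(swapped, ref)$value, -1)

  # both components sharing a sign forces 0: up and down both enriched at top
  ref2 <- signature_record("r2", paste0("g", 1:6), c(3, 2.5, 2, -1, -2, -3))
  ex2 <- list(up = "g1", down = "g2", up_z = 5, down_z = -4, K = 1L)
  class(ex2) <- "extreme_gene_set"
  w2 <- wtcs(ex2, ref2)
  expect_gt(w2$es_up * w2$es_down, 0)
  expect_identical(w2$value, 0)
})

test_that("CSS reproduces the six-gene worked example and its extremes", {
  ref <- signature_record("r", paste0("g", 1:6), c(3, 2, 1, -1.5, -2.5, -3.5))
  # R_ref = (+5, +3, +1, -2, -4, -6); c = 5*2 + 6 = 16, c_max = 12 + 5 = 17
  ex <- list(up = "g1", down = "g6", up_z = 2, down_z = -1, K = 1L)
  class(ex) <- "extreme_gene_set"
  expect_equal(css(ex, ref)$value, 16 / 17, tolerance = 1e-12)

  # extremes exactly the reference's own strongest genes, matching signs and
  # importance order, attain c_max by construction
  ref2 <- signature_record("r2", paste0("g", 1:6), c(3, 2, 1, -1, -2, -2.5))
  # strongest |z|: g1 (+3, signed rank +6), g6 (-2.5, signed rank -5)
  ex1 <- list(up = "g1", down = "g6", up_z = 2, down_z = -1, K = 1L)
  class(ex1) <- "extreme_gene_set"
  expect_equal(css(ex1, ref2)$value, 1)
  # flipping all query signs gives exactly -1
  ex_fl <- ex1; ex_fl$up_z <- -2; ex_fl$down_z <- 1
  expect_equal(css(ex_fl, ref2)$value, -1)
})

test_that("XSum reproduces the hand enumeration and zeroes non-extreme
          reference genes", {
  ref <- signature_record("r", paste0("g", 1:6), c(3, 2, 1, -1, -2, -3))
  ex <- list(up = c("g1", "g3"), down = c("g6", "g4"),
             up_z = c(3, 1), down_z = c(-3, -1), K = 2L)
  class(ex) <- "extreme_gene_set"
  expect_equal(xsum(ex, ref, ref_extreme_n = 2)$value, 6)

  # all query extremes outside the reference extremes -> 0
  ex_mid <- list(up = "g3", down = "g4", up_z = 1, down_z = -1, K = 1L)
  class(ex_mid) <- "extreme_gene_set"
  expect_equal(xsum(ex_mid, ref, ref_extreme_n = 1)$value, 0)

  # swapping up and down negates
  ex_sw <- ex; ex_sw$up <- ex$down; ex_sw$down <- ex$up
  ex_sw$up_z <- ex$down_z; ex_sw$down_z <- ex$up_z
  expect_equal(xsum(ex_sw, ref, ref_extreme_n = 2)$value, -6)
})

test_that("CSS and XSum match naive brute-force evaluators on >= 100 small
          random instances", {
  count <- 0
  for (seed in 1:120) {
    set.seed(seed)
    n <- sample(6:12, 1)
    k <- sample(1:3, 1)
    inst <- random_instance(n, k, seed)
    ex <- inst$extremes
    expect_equal(css(ex, inst$ref)$value,
                 oracle_css(ex$up, ex$down, ex$up_z, ex$down_z,
                            inst$ref$gene_ids, inst$ref$z),
                 tolerance = 1e-12)
    m <- sample(1:(n %/% 2), 1)
    expect_equal(xsum(ex, inst$ref, ref_extreme_n = m)$value,
                 oracle_xsum(ex$up, ex$down, inst$ref$gene_ids, inst$ref$z, m),
                 tolerance = 1e-12)
    count <- count + 1
  }
  expect_gte(count, 100)
})

test_that("all six methods are antisymmetric in the query and the bounded
          methods stay in [-1, 1]", {
  for (seed in 1:100) {
    inst <- random_instance(30, 4, seed)
    q <- inst$query; ref <- inst$ref
    cfg <- screen_config(K = 4, seed = 1)
    s_pos <- score_pair(q, ref, cfg)
    q_neg <- signature_record("qneg", q$gene_ids, -q$z)
    s_neg <- score_pair(q_neg, ref, cfg)
    for (m in c("pearson", "spearman", "cosine", "wtcs", "css", "xsum")) {
      v1 <- s_pos$value[s_pos$method == m]
      v2 <- s_neg$value[s_neg$method == m]
      expect_equal(v2, -v1, tolerance = 1e-12, label = m)
      if (m != "xsum") expect_lte(abs(v1), 1 + 1e-12)
    }
  }
})

test_that("scores are invariant under simultaneous reordering of stored
          gene/value pairs", {
  for (seed in 1:20) {
    inst <- random_instance(25, 3, seed)
    set.seed(seed + 1000)
    perm <- sample(25)
    ref2 <- signature_record("ref", inst$ref$gene_ids[perm], inst$ref$z[perm])
    q2 <- signature_record("q", inst$query$gene_ids[perm], inst$query$z[perm])
    cfg <- screen_config(K = 3)
    s1 <- score_pair(inst$query, inst$ref, cfg)
    s2 <- score_pair(q2, ref2, cfg)
    expect_equal(s2$value, s1$value, tolerance = 1e-12)
  }
})

test_that("score_pair dispatch agrees with the standalone operations and
          honors method subsets", {
  inst <- random_instance(50, 5, 7)
  cfg <- screen_config(K = 5)
  all6 <- score_pair(inst$query, inst$ref, cfg)
  expect_identical(all6$method,
                   c("pearson", "spearman", "cosine", "wtcs", "css", "xsum"))
  shared_q <- inst$query$z; shared_r <- inst$ref$z
  expect_equal(all6$value[all6$method == "pearson"],
               pearson_score(shared_q, shared_r))
  expect_equal(all6$value[all6$method == "spearman"],
               spearman_score(shared_q, shared_r))
  expect_equal(all6$value[all6$method == "cosine"],
               cosine_score(shared_q, shared_r))
  expect_equal(all6$value[all6$method == "wtcs"],
               wtcs(inst$extremes, inst$ref)$value)
  expect_equal(all6$value[all6$method == "css"],
               css(inst$extremes, inst$ref)$value)
  expect_equal(all6$value[all6$method == "xsum"],
               xsum(inst$extremes, inst$ref, 5)$value)

  one <- score_pair(inst$query, inst$ref, cfg, methods = "pearson")
  expect_identical(nrow(one), 1L)

  # self-comparison maximizes every bounded method
  self <- score_pair(inst$query, inst$query, cfg)
  expect_equal(self$value[self$method %in% c("pearson", "spearman", "cosine")],
               rep(1, 3), tolerance = 1e-12)
  expect_equal(self$value[self$method == "wtcs"], 1, tolerance = 1e-12)
  expect_gt(self$value[self$method == "xsum"], 0)
})
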