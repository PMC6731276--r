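test_that("enrichment score matches the brute-force oracle on random instances", {
  set.seed(11)
  for (i in 1:200) {
    N <- sample(5:50, 1)
    k <- sample(1:min(10, N - 1), 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    sig <- make_signature(scores)
    hit_idx <- sort(sample.int(N, k))
    gene_set <- sig$feature[hit_idx]
    es <- enrichment_score(sig, gene_set)$es
    hits <- seq_len(N) %in% hit_idx
    if (brute_es_tied(scores, hits)) {
      # both extrema have equal magnitude: only |ES| is determined
      expect_equal(abs(es), abs(brute_es(scores, hits)), tolerance = 1e-12)
    } else {
      expect_equal(es, brute_es(scores, hits), tolerance = 1e-12)
    }
  }
})

test_that("enrichment score agrees with fgsea's statistic", {
  set.seed(12)
  for (i in 1:40) {
    N <- sample(20, 1) + 10
    scores <- sort(rnorm(N), decreasing = TRUE)
    sig <- make_signature(scores)
    idx <- sort(sample.int(N, 5))
    es <- enrichment_score(sig, sig$feature[idx])$es
    ref <- fgsea::calcGseaStat(scores, idx, gseaParam = 1)
    expect_equal(es, ref, tolerance = 1e-9)
  }
})

test_that("enrichment score handles the forced extreme cases", {
  sig <- make_signature(c(3, 2, 1), c("A", "B", "C"))
  top <- enrichment_score(sig, "A")
  expect_equal(top$es, 1)
  expect_equal(top$leading_edge, "A")

  # set = all signature genes: no miss decrements, es = 1
  expect_equal(enrichment_score(sig, c("A", "B", "C"))$es, 1)

  # bottom gene: extrema are 0 (end) and -1 (before the hit)
  bottom <- enrichment_score(sig, "C")
  expect_equal(bottom$es, brute_es(c(3, 2, 1), c(FALSE, FALSE, TRUE)))
  expect_equal(bottom$es, -1)
  expect_equal(bottom$leading_edge, "C")

  expect_error(enrichment_score(sig, "ZZZ"), "no overlap")
  zero <- make_signature(c(1, 0, 0, -1), c("A", "B", "C", "D"))
  expect_error(enrichment_score(zero, c("B", "C")), "zero")
})

test_that("absolute signature collapses the tails and preserves ties", {
  sig <- make_signature(c(3, -5, 1), c("GA", "GB", "GC"))
  a <- absolute_signature(sig)
  expect_equal(a$feature, c("GB", "GA", "GC"))
  expect_equal(a$score, c(5, 3, 1))

  pos <- make_signature(c(4, 3, 2))
  expect_equal(absolute_signature(pos)$feature, pos$feature)

  flipped <- make_signature(-c(3, -5, 1), c("GA", "GB", "GC"))
  expect_equal(absolute_signature(flipped)$feature, a$feature)
  expect_equal(absolute_signature(flipped)$score, a$score)

  # absolute-mode ES invariant under global sign flip
  set.seed(3)
  sc <- rnorm(30)
  s1 <- absolute_signature(make_signature(sc))
  s2 <- absolute_signature(make_signature(-sc))
  gs <- s1$feature[c(2, 5, 9)]
  expect_equal(enrichment_score(s1, gs)$es, enrichment_score(s2, gs)$es)
})

test_that("permutation NES/p is seeded, bounded and extreme at the top", {
  set.seed(21)
  sig <- make_signature(sort(rnorm(200), decreasing = TRUE))
  gs <- sig$feature[c(3, 10, 17)]
  r1 <- nes_pvalue(sig, gs, n_perm = 200, seed = 99)
  r2 <- nes_pvalue(sig, gs, n_perm = 200, seed = 99)
  expect_identical(r1$nes, r2$nes)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 201)
  expect_equal(sign(r1$nes), sign(r1$es))

  # a set at the exact top of a strongly graded signature: no permutation
  # can beat it, so p sits at its floor given the matching-sign count
  graded <- make_signature(seq(10, 0.1, length.out = 300))
  top <- nes_pvalue(graded, graded$feature[1:10], n_perm = 500, seed = 5)
  nulls <- pathchemo:::null_es(abs(graded$score), 10, 500, 5)
  expect_equal(top$p, 1 / (sum(nulls > 0) + 1))
  expect_lt(top$p, 0.01)
  expect_gt(top$nes, 1)
  expect_error(nes_pvalue(sig, gs, n_perm = 50), "n_perm")
})

test_that("collection enrichment reports skips and flags ineligible results", {
  set.seed(31)
  sig <- make_signature(rnorm(60))
  col <- pathway_collection(list(P1 = sig$feature[1:8],
                                 P2 = sig$feature[30:40],
                                 P3 = c("ZZ1", "ZZ2")))
  res <- enrich_collection(sig, col, "signed", n_perm = 150, seed = 4)
  expect_equal(nrow(res), 2)
  expect_equal(attr(res, "skipped"), "P3")
  expect_true(all(res$eligible))
  res2 <- enrich_collection(sig, col, "signed", n_perm = 150, seed = 4)
  expect_identical(res$nes, res2$nes)

  resa <- enrich_collection(sig, col, "absolute", n_perm = 150, seed = 4)
  expect_identical(resa$eligible, resa$nes > 0)
})

test_that("composite integration applies the min-p rule with
           negative-absolute exclusion over all four cases", {
  cases <- list(
    # signed wins on p
    list(s = fake_enr("P", -1.9, 0.004, "signed"),
         a = fake_enr("P", 1.5, 0.2, "absolute"),
         nes = -1.9, p = 0.004, mode = "signed"),
    # absolute ineligible (negative NES) despite smaller p
    list(s = fake_enr("P", 1.1, 0.4, "signed"),
         a = fake_enr("P", -2.0, 0.001, "absolute"),
         nes = 1.1, p = 0.4, mode = "signed"),
    # eligible absolute wins on p
    list(s = fake_enr("P", 1.2, 0.30, "signed"),
         a = fake_enr("P", 2.2, 0.01, "absolute"),
         nes = 2.2, p = 0.01, mode = "absolute"),
    # exact tie resolves toward signed
    list(s = fake_enr("P", 1.3, 0.05, "signed"),
         a = fake_enr("P", 1.4, 0.05, "absolute"),
         nes = 1.3, p = 0.05, mode = "signed"))
  for (cs in cases) {
    comp <- composite_integration(cs$s, cs$a)
    expect_equal(comp$nes, cs$nes)
    expect_equal(comp$p, cs$p)
    expect_equal(comp$source_mode, cs$mode)
    # composite p equals the minimum eligible input p by construction
    elig <- c(cs$s$p, if (cs$a$nes > 0) cs$a$p)
    expect_equal(comp$p, min(elig))
  }
  # pathway with no eligible result is dropped with a warning
  expect_warning(
    expect_error(
      composite_integration(fake_enr("P", 1, 0.5, "signed")[0, ],
                            fake_enr("P", -2, 0.001, "absolute")),
      "no pathway"),
    "dropped")
})

test_that("a fully null signature yields few significant composite pathways", {
  # with the add-one, sign-conditioned estimator the attainable p floor is
  # ~2/n_perm, so significance is checked at 0.01 with 400 permutations
  set.seed(91)
  counts <- vapply(1:10, function(r) {
    sig <- make_signature(rnorm(600))
    sets <- split(sample(sig$feature, 500), rep(1:100, each = 5))
    names(sets) <- sprintf("P%03d", 1:100)
    col <- pathway_collection(sets)
    s <- enrich_collection(sig, col, "signed", n_perm = 400, seed = 900 + r)
    a <- enrich_collection(sig, col, "absolute", n_perm = 400, seed = 1900 + r)
    comp <- suppressWarnings(composite_integration(s, a))
    sum(comp$p < 0.01)
  }, numeric(1))
  expect_gte(sum(counts <= 5), 9)
})
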