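test_that("ROC-AUC equals pair counting and the U identity, with and without ties", {
  e_top <- toy_edges(c(4, 3, 2, 1), c(1, 1, 0, 0))
  expect_equal(roc_auc(e_top)$auc, 1)
  e_bot <- toy_edges(c(4, 3, 2, 1), c(0, 0, 1, 1))
  expect_equal(roc_auc(e_bot)$auc, 0)

  # tie-aware midpoint counting: pos {3,1}, neg {3,0}
  e_tie <- toy_edges(c(3, 1, 3, 0), c(1, 1, 0, 0))
  expect_equal(roc_auc(e_tie)$auc, 0.625)
  expect_equal(roc_auc(e_tie)$auc, brute_auc(e_tie$ftERC, e_tie$label))

  expect_error(roc_auc(toy_edges(1:3, c(1, 1, 1))), "ROC undefined")

  set.seed(13)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    scores <- sample(round(stats::rnorm(n), 1)) # rounding forces ties
    labels <- integer(n)
    labels[sample(n, sample(seq_len(n - 1), 1))] <- 1L
    e <- toy_edges(scores, labels)
    res <- roc_auc(e)
    expect_equal(res$auc, brute_auc(scores, labels), tolerance = 1e-12)
    expect_equal(res$auc, res$U / (res$n_pos * res$n_neg), tolerance = 1e-12)
    # curve is a valid monotone path from (0,0) to (1,1)
    expect_equal(res$curve$FPR[1], 0)
    expect_equal(res$curve$TPR[1], 0)
    expect_equal(utils::tail(res$curve$FPR, 1), 1)
    expect_equal(utils::tail(res$curve$TPR, 1), 1)
    expect_true(all(diff(res$curve$FPR) >= 0))
    expect_true(all(diff(res$curve$TPR) >= 0))
    # AUC invariant to monotone transform of the scores
    e2 <- toy_edges(exp(scores / 2), labels)
    expect_equal(roc_auc(e2)$auc, res$auc, tolerance = 1e-12)
  }
})

test_that("one-tailed Mann-Whitney p matches exhaustive enumeration for small n", {
  # 2 positives on top of 4: p = 1 / choose(4,2) = 1/6
  e <- toy_edges(c(4, 3, 2, 1), c(1, 1, 0, 0))
  expect_equal(mann_whitney_one_tailed(e), 1 / 6, tolerance = 1e-12)
  # n1 = n0 = 1, positive on top: p = 1/2
  e1 <- toy_edges(c(2, 1), c(1, 0))
  expect_equal(mann_whitney_one_tailed(e1), 0.5, tolerance = 1e-12)

  # enumeration oracle: p = P(U_perm >= U_obs) over all label placements
  set.seed(14)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    scores <- stats::rnorm(n)
    labels <- integer(n)
    labels[sample(n, sample(2:(n - 2), 1))] <- 1L
    p <- mann_whitney_one_tailed(toy_edges(scores, labels))
    obs_auc <- brute_auc(scores, labels)
    placements <- utils::combn(n, sum(labels))
    null_aucs <- apply(placements, 2, function(idx) {
      l <- integer(n)
      l[idx] <- 1L
      brute_auc(scores, l)
    })
    expect_equal(p, mean(null_aucs >= obs_auc - 1e-12), tolerance = 1e-12)
  }
})

test_that("exact and approximate Mann-Whitney agree for moderate tie-free samples", {
  set.seed(15)
  for (i in 1:10) {
    pos <- stats::rnorm(8, mean = 0.3)
    neg <- stats::rnorm(9)
    p_exact <- stats::wilcox.test(pos, neg, alternative = "greater", exact = TRUE)$p.value
    p_approx <- stats::wilcox.test(pos, neg,
      alternative = "greater", exact = FALSE, correct = TRUE
    )$p.value
    # the normal approximation is only advertised away from the extreme tails
    if (p_exact > 0.05 && p_exact < 0.95) {
      expect_lt(abs(p_approx - p_exact) / p_exact, 0.1)
    }
  }
})

test_that("AUC label permutation has null centre 0.5 and converges to enumeration", {
  set.seed(16)
  scores <- stats::rnorm(10)
  labels <- c(rep(1, 5), rep(0, 5))[rank(-scores)] # positives = top 5
  e <- toy_edges(scores, labels)
  perm <- permute_complex_auc(e, B = 1000, seed = 4)
  expect_equal(perm$observed, 1)
  expect_lt(perm$p, 0.01)
  expect_equal(mean(perm$null), 0.5, tolerance = 3 * stats::sd(perm$null) / sqrt(1000))

  # exhaustive: C(10,5) = 252 placements
  p_exact <- exact_auc_perm_p(scores, labels)
  se <- sqrt(p_exact * (1 - p_exact) / 1000)
  expect_lt(abs(perm$p - p_exact), 2 * se + 2 / 1000)

  expect_identical(
    permute_complex_auc(e, B = 100, seed = 9)$null,
    permute_complex_auc(e, B = 100, seed = 9)$null
  )
  expect_error(permute_complex_auc(e, B = 0), "B must be")
  expect_error(
    permute_complex_auc(toy_edges(1:4, rep(1, 4)), B = 10),
    "ROC undefined"
  )
})

test_that("study-wide average AUC test matches joint enumeration on two tiny complexes", {
  s1 <- c(3, 2, 1)
  l1 <- c(1, 0, 0)
  s2 <- c(4, 3, 2, 1)
  l2 <- c(0, 1, 1, 0)
  e1 <- toy_edges(s1, l1, "cx1")
  e2 <- toy_edges(s2, l2, "cx2")
  res <- global_average_auc_test(list(e1, e2), B = 4000, seed = 6)
  expect_equal(res$observed, mean(c(brute_auc(s1, l1), brute_auc(s2, l2))))

  # product-space oracle over all 3 x 6 joint label placements
  auc1 <- apply(utils::combn(3, 1), 2, function(idx) {
    l <- integer(3); l[idx] <- 1L
    brute_auc(s1, l)
  })
  auc2 <- apply(utils::combn(4, 2), 2, function(idx) {
    l <- integer(4); l[idx] <- 1L
    brute_auc(s2, l)
  })
  joint <- outer(auc1, auc2, function(a, b) (a + b) / 2)
  p_exact <- mean(joint >= res$observed - 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p - p_exact), 3 * se + 2 / 4000)

  expect_error(global_average_auc_test(list(e1), B = 10), "at least 2")
})

test_that("proportional rank hits its anchors and the tie-aware pair score", {
  expect_equal(proportional_rank(1, 11), 1)
  expect_equal(proportional_rank(11, 11), 0)
  expect_equal(proportional_rank(3, 11), 0.8)
  expect_error(proportional_rank(1, 1), "fewer than 2")
  expect_error(proportional_rank(5, 4), "out of range")

  # single physical among T = 2, physical on top
  e <- toy_edges(c(2, 1), c(1, 0))
  expect_equal(protein_pair_prop_rank(e)$score, 1)

  # two physical pairs at ranks 1 and T average to 0.5
  e2 <- toy_edges(c(5, 4, 3, 2, 1), c(1, 0, 0, 0, 1))
  expect_equal(protein_pair_prop_rank(e2)$score, 0.5)

  # 3x2 domain grid with one ftERC tie: average-rank oracle
  scores <- c(9, 7, 7, 5, 3, 1)
  labels <- c(0, 1, 0, 0, 0, 0) # physical is one of the tied pair
  pr <- protein_pair_prop_rank(toy_edges(scores, labels))
  expect_equal(pr$physical_ranks, 2.5) # ranks 2 and 3 share midrank 2.5
  expect_equal(pr$score, (6 - 2.5) / 5)

  # no physical pair: not evaluated; all physical: undefined
  expect_null(protein_pair_prop_rank(toy_edges(c(2, 1), c(0, 0))))
  expect_error(protein_pair_prop_rank(toy_edges(c(2, 1), c(1, 1))), "undefined")
})

test_that("complex proportional-rank permutation matches the joint placement oracle", {
  # single pair, 1 physical among T = 11: null expectation 0.5
  set.seed(17)
  scores <- stats::rnorm(11)
  labels <- integer(11)
  labels[which.max(scores)] <- 1L
  res1 <- complex_prop_rank_test(list(p1 = toy_edges(scores, labels)), B = 1000, seed = 7)
  expect_equal(mean(res1$null), 0.5, tolerance = 3 * stats::sd(res1$null) / sqrt(1000))
  expect_equal(res1$observed, 1)
  # null replicates redraw the top rank with probability 1/11, which ties the
  # observed score of 1 and is counted by the >= convention
  se1 <- sqrt((1 / 11) * (10 / 11) / 1000)
  expect_lt(abs(res1$p - 1 / 11), 3 * se1 + 2 / 1000)

  # 2 pairs with T = 3 each: exhaustive 3 x 3 joint null
  sA <- c(3, 2, 1); lA <- c(1, 0, 0)
  sB <- c(6, 5, 4); lB <- c(0, 1, 0)
  pairs <- list(pA = toy_edges(sA, lA), pB = toy_edges(sB, lB))
  res <- complex_prop_rank_test(pairs, B = 4000, seed = 8)
  obs <- mean(c(1, 0.5))
  expect_equal(res$observed, obs)
  joint <- outer(c(1, 0.5, 0), c(1, 0.5, 0), function(a, b) (a + b) / 2)
  p_exact <- mean(joint >= obs - 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p - p_exact), 3 * se + 2 / 4000)
})

test_that("complex edge lists split into physically interacting protein pairs only", {
  cx <- complex_definition(
    "split",
    tibble::tibble(
      protein_id = c("P1", "P1", "P2", "P2", "P3"),
      domain_id = c("P1:a", "P1:b", "P2:a", "P2:b", "P3:a")
    ),
    physical_domain_pairs = data.frame(a = "P1:a", b = "P2:a")
  )
  ids <- cx$domains$domain_id
  pairs <- utils::combn(ids, 2)
  erc <- tibble::tibble(
    gene_a = pairs[1, ], gene_b = pairs[2, ],
    r = 0.1, n_branches = 30L, n_shared_species = 20L,
    ftERC = seq_len(ncol(pairs)), filter_reason = NA_character_
  )
  edges <- build_domain_edge_list(erc, cx)
  pp <- complex_protein_pairs(edges, cx)
  # only P1-P2 share a physical interaction; P3 pairs are not evaluated
  expect_equal(names(pp), "P1-P2")
  expect_equal(nrow(pp[["P1-P2"]]), 4)
})

test_that("binomial tail matches the closed form", {
  expect_equal(binomial_tail(12, 17), sum(stats::dbinom(12:17, 17, 0.5)), tolerance = 1e-12)
  expect_equal(binomial_tail(0, 5), 1)
})
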