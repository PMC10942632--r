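edge_scores_labels <- function(edges) {
  stopifnot(all(c("ftERC", "label") %in% names(edges)))
  list(scores = edges$ftERC, labels = as.integer(edges$label))
}

# Mann-Whitney U of positives over negatives via midranks; equals
# #{pos > neg} + 0.5 * #{pos = neg}.
u_statistic <- function(scores, labels) {
  n1 <- sum(labels == 1)
  rk <- rank(scores)         # ascending midranks
  sum(rk[labels == 1]) - n1 * (n1 + 1) / 2
}

#' ROC analysis of a ranked domain edge list
#'
#' The AUC is computed tie-aware as `U / (n0 * n1)`, i.e. the probability
#' that a random physical (label 1) pair outranks a random non-physical
#' (label 0) pair, counting ties as one half; this equals the trapezoidal
#' area under the tie-aware ROC curve.  A one-tailed Mann-Whitney p-value
#' (alternative: physical pairs rank higher) is attached.
#'
#' @param edges Edge list with `ftERC` and `label` columns (e.g. from
#'   [build_domain_edge_list()]).
#' @return Object of class `erc_roc`: `complex_id`, `auc`, `U`, `n_pos`,
#'   `n_neg`, `p_mw`, and `curve` (tibble of FPR/TPR points from (0,0) to
#'   (1,1)).
#' @export
roc_auc <- function(edges) {
  sl <- edge_scores_labels(edges)
  n1 <- sum(sl$labels == 1)
  n0 <- sum(sl$labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("ROC undefined: need at least one positive and one negative", call. = FALSE)
  }
  U <- u_statistic(sl$scores, sl$labels)
  # tie-aware curve: one step per distinct score, descending
  ord <- order(sl$scores, decreasing = TRUE)
  s <- sl$scores[ord]; l <- sl$labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(tapply(l, grp, sum))
  fp <- cumsum(tapply(1 - l, grp, sum))
  curve <- tibble::tibble(
    FPR = c(0, unname(fp) / n0),
    TPR = c(0, unname(tp) / n1)
  )
  structure(
    list(
      complex_id = attr(edges, "complex_id"),
      auc = U / (n0 * n1), U = U, n_pos = n1, n_neg = n0,
      p_mw = mann_whitney_one_tailed(edges), curve = curve
    ),
    class = "erc_roc"
  )
}

#' @export
print.erc_roc <- function(x, ...) {
  cat(
    "<erc_roc>", if (!is.null(x$complex_id)) x$complex_id else "",
    " AUC =", signif(x$auc, 4),
    " (", x$n_pos, "pos /", x$n_neg, "neg ), one-tailed MW p =",
    signif(x$p_mw, 4), "\n"
  )
  invisible(x)
}

#' One-tailed Mann-Whitney test that physical pairs rank higher
#'
#' Exact enumeration (no ties, `n0 + n1 <= 12`) or normal approximation with
#' tie and continuity corrections otherwise, as provided by
#' [stats::wilcox.test()].
#'
#' @inheritParams roc_auc
#' @return One-tailed p-value.
#' @export
mann_whitney_one_tailed <- function(edges) {
  sl <- edge_scores_labels(edges)
  pos <- sl$scores[sl$labels == 1]
  neg <- sl$scores[sl$labels == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("Mann-Whitney undefined: need both classes", call. = FALSE)
  }
  n <- length(pos) + length(neg)
  ties <- anyDuplicated(c(pos, neg)) > 0
  use_exact <- n <= 12 && !ties
  suppressWarnings(
    stats::wilcox.test(
      pos, neg,
      alternative = "greater", exact = use_exact, correct = TRUE
    )$p.value
  )
}

perm_result <- function(observed, null, B, seed, statistic) {
  structure(
    list(
      statistic = statistic, observed = observed, null = null,
      B = B, seed = seed,
      p = (1 + sum(null >= observed)) / (1 + B)
    ),
    class = "erc_perm"
  )
}

#' @export
print.erc_perm <- function(x, ...) {
  cat(
    "<erc_perm>", x$statistic, ": observed =", signif(x$observed, 4),
    ", null mean =", signif(mean(x$null), 4),
    ", p =", signif(x$p, 4), " (B =", x$B, ")\n"
  )
  invisible(x)
}

#' Permutation null for one complex's ROC-AUC
#'
#' Keeps the ranked list fixed and reassigns the positive labels to a uniform
#' random subset of positions `B` times, recomputing the AUC each time.  The
#' p-value uses the add-one convention.
#'
#' @inheritParams roc_auc
#' @param B Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @return Object of class `erc_perm` (`observed`, `null`, `B`, `seed`, `p`).
#' @export
permute_complex_auc <- function(edges, B = 1000, seed = 1L) {
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  sl <- edge_scores_labels(edges)
  n1 <- sum(sl$labels == 1)
  n0 <- sum(sl$labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("ROC undefined: need at least one positive and one negative", call. = FALSE)
  }
  obs <- u_statistic(sl$scores, sl$labels) / (n0 * n1)
  rk <- rank(sl$scores)
  n <- length(rk)
  set.seed(seed)
  null <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n1)
    (sum(rk[idx]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  }, numeric(1))
  perm_result(obs, null, B, seed, "auc")
}

#' Study-wide average-AUC permutation test
#'
#' Each complex contributes `B` permuted AUCs (from [permute_complex_auc()]
#' with a complex-specific seed derived from `seed`); replicate `b`'s
#' statistic is the mean over complexes of their `b`-th permuted AUC, and the
#' observed statistic is the mean of the observed AUCs.
#'
#' @param edge_lists List of per-complex edge lists.
#' @param B Permutations per complex (default 1000).
#' @param seed Integer seed.
#' @return `erc_perm` object with an extra `per_complex` tibble
#'   (`complex_id`, `auc`).
#' @export
global_average_auc_test <- function(edge_lists, B = 1000, seed = 1L) {
  if (length(edge_lists) < 2) stop("need at least 2 complexes", call. = FALSE)
  seeds <- derive_seeds(seed, length(edge_lists))
  perms <- purrr::map2(edge_lists, seeds, ~ permute_complex_auc(.x, B = B, seed = .y))
  obs_aucs <- vapply(perms, function(p) p$observed, numeric(1))
  null_mat <- matrix(vapply(perms, function(p) p$null, numeric(B)), nrow = B)
  out <- perm_result(mean(obs_aucs), rowMeans(null_mat), B, seed, "mean_auc")
  out$per_complex <- tibble::tibble(
    complex_id = purrr::map_chr(
      edge_lists,
      ~ attr(.x, "complex_id") %||% NA_character_
    ),
    auc = obs_aucs
  )
  out
}

#' Proportional rank of a physical domain pair
#'
#' `(T - rank) / (T - 1)`: 1 when the physical pair is ranked first among the
#' `T` domain pairs of a protein pair, 0 when it is ranked last.
#'
#' @param rank Rank position(s), 1 = highest ERC (average ranks for ties are
#'   allowed, so non-integer values are accepted).
#' @param n_pairs Total number of domain pairs `T` (>= 2).
#' @return Score(s) in `[0, 1]`.
#' @export
proportional_rank <- function(rank, n_pairs) {
  if (any(n_pairs < 2)) stop("proportional rank undefined for fewer than 2 pairs", call. = FALSE)
  if (any(rank < 1 | rank > n_pairs)) stop("rank out of range", call. = FALSE)
  (n_pairs - rank) / (n_pairs - 1)
}

#' Proportional-rank score for one protein pair
#'
#' Ranks all `T` inter-protein domain pairs of the two proteins by ftERC
#' (descending; ties get average ranks) and averages the proportional rank
#' over the physically interacting pairs.
#'
#' @param edges Edge list restricted to one protein pair, with `ftERC` and
#'   `label` columns.
#' @param protein_a,protein_b Optional labels carried into the result.
#' @return Object of class `prop_rank`: `protein_a`, `protein_b`, `T`,
#'   `physical_ranks`, `score`.  Returns `NULL` (pair not evaluated) when
#'   there is no physical pair; errors when `T < 2` or all pairs are
#'   physical, where the statistic is undefined.
#' @export
protein_pair_prop_rank <- function(edges, protein_a = NA_character_,
                                   protein_b = NA_character_) {
  sl <- edge_scores_labels(edges)
  T_ <- length(sl$scores)
  if (sum(sl$labels == 1) == 0) return(NULL)
  if (T_ < 2) stop("proportional rank undefined for fewer than 2 domain pairs", call. = FALSE)
  if (all(sl$labels == 1)) {
    stop("proportional rank undefined when all domain pairs are physical", call. = FALSE)
  }
  rk <- rank(-sl$scores)  # descending, average ranks for ties
  phys <- rk[sl$labels == 1]
  structure(
    list(
      protein_a = protein_a, protein_b = protein_b,
      T = T_, physical_ranks = unname(phys),
      score = mean(proportional_rank(phys, T_))
    ),
    class = "prop_rank"
  )
}

#' @export
print.prop_rank <- function(x, ...) {
  cat(
    "<prop_rank>", x$protein_a, "-", x$protein_b,
    ": score =", signif(x$score, 4), " over T =", x$T, "domain pairs\n"
  )
  invisible(x)
}

#' Split a complex edge list into physically interacting protein pairs
#'
#' Domains of one protein are only contrasted with domains of another protein
#' when the two proteins share an annotated physical interaction.  Pairs with
#' fewer than 2 domain pairs, no physical domain pair between them, or only
#' physical pairs are excluded (tallied in the `excluded` attribute).
#'
#' @param edges Complex edge list from [build_domain_edge_list()].
#' @param cx The [complex_definition()].
#' @return Named list of per-protein-pair edge tibbles.
#' @export
complex_protein_pairs <- function(edges, cx) {
  pp_id <- pair_id(edges$protein_a, edges$protein_b)
  keep_pp <- intersect(unique(pp_id), cx$physical_protein_pairs)
  out <- list()
  excluded <- character(0)
  for (pp in keep_pp) {
    sub <- edges[pp_id == pp, ]
    label <- paste(strsplit(pp, "\r", fixed = TRUE)[[1]], collapse = "-")
    if (nrow(sub) < 2 || all(sub$label == 1) || all(sub$label == 0)) {
      excluded <- c(excluded, label)
      next
    }
    out[[label]] <- sub
  }
  attr(out, "excluded") <- excluded
  out
}

#' Nested permutation test for a complex's mean proportional rank
#'
#' For each evaluated protein pair, a null distribution of `B` scores is
#' drawn by placing that pair's physical labels uniformly at random among its
#' `T` rank positions.  A complex-level null replicate averages one draw per
#' pair; the observed statistic is the mean of the observed pair scores.
#'
#' @param pair_edges Named list of per-protein-pair edge lists (see
#'   [complex_protein_pairs()]).
#' @param B Permutations (default 1000).
#' @param seed Integer seed.
#' @return `erc_perm` object with an extra `pairs` tibble (`pair`, `T`,
#'   `n_physical`, `score`).
#' @export
complex_prop_rank_test <- function(pair_edges, B = 1000, seed = 1L) {
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  if (length(pair_edges) < 1) stop("no evaluated protein pair", call. = FALSE)
  results <- purrr::imap(pair_edges, function(e, nm) {
    pr <- protein_pair_prop_rank(e, nm, nm)
    if (is.null(pr)) stop("protein pair without physical domain pair: ", nm, call. = FALSE)
    pr
  })
  set.seed(seed)
  null_mat <- vapply(names(results), function(nm) {
    pr <- results[[nm]]
    rk <- rank(-pair_edges[[nm]]$ftERC)
    n_phys <- length(pr$physical_ranks)
    vapply(seq_len(B), function(b) {
      mean(proportional_rank(sample(rk, n_phys), pr$T))
    }, numeric(1))
  }, numeric(B))
  null_mat <- matrix(null_mat, nrow = B)
  observed <- mean(vapply(results, function(pr) pr$score, numeric(1)))
  out <- perm_result(observed, rowMeans(null_mat), B, seed, "mean_prop_rank")
  out$pairs <- tibble::tibble(
    pair = names(results),
    T = purrr::map_int(results, "T"),
    n_physical = purrr::map_int(results, ~ length(.x$physical_ranks)),
    score = purrr::map_dbl(results, "score")
  )
  out
}

#' Upper-tail binomial probability
#'
#' Convenience wrapper: probability of observing `k` or more successes out of
#' `n` under success probability `p0`.
#'
#' @param k Observed count.
#' @param n Trials.
#' @param p0 Null success probability (default 0.5).
#' @return Upper-tail probability.
#' @export
binomial_tail <- function(k, n, p0 = 0.5) {
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}
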