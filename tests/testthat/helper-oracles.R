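# Independent oracles and small fixture builders used across the suite.

# Pair-counting AUC: P(pos > neg) + 0.5 * P(pos = neg), by explicit loops.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# Sort-and-replace winsorization oracle.
winsor_oracle <- function(v, k) {
  s <- sort(v)
  lo <- s[k + 1]
  hi <- s[length(v) - k]
  out <- v
  out[out < lo] <- lo
  out[out > hi] <- hi
  out
}

# Exact permutation p-value for the AUC under uniform label placement:
# enumerate every assignment of n1 positive labels to positions.
exact_auc_perm_p <- function(scores, labels) {
  n <- length(scores)
  n1 <- sum(labels == 1)
  obs <- brute_auc(scores, labels)
  placements <- utils::combn(n, n1)
  aucs <- apply(placements, 2, function(idx) {
    lab <- integer(n)
    lab[idx] <- 1L
    brute_auc(scores, lab)
  })
  mean(aucs >= obs - 1e-12)
}

# Build an edge-list tibble for rank statistics tests.
toy_edges <- function(scores, labels, complex_id = "toy") {
  e <- tibble::tibble(
    domain_a = sprintf("a%02d", seq_along(scores)),
    domain_b = sprintf("b%02d", seq_along(scores)),
    protein_a = "P1", protein_b = "P2",
    ftERC = scores, label = as.integer(labels)
  )
  attr(e, "complex_id") <- complex_id
  e
}

# RER matrix with explicit species identities: `ns` singleton (species)
# columns named sp01.. plus `ni` internal-branch columns.  Values filled from
# `fill` (a function of n) row by row.
toy_rer_matrix <- function(n_genes, ns, ni = 0, fill = stats::rnorm,
                           genes = sprintf("g%02d", seq_len(n_genes))) {
  cols <- c(
    sprintf("sp%02d", seq_len(ns)),
    if (ni > 0) {
      vapply(seq_len(ni), function(i) {
        paste(sprintf("sp%02d", c(i, i + 1)), collapse = ";")
      }, character(1))
    }
  )
  M <- matrix(fill(n_genes * (ns + ni)), n_genes, ns + ni,
    dimnames = list(genes, cols)
  )
  M
}

# A small fixed master tree on 5 species used across tree tests.
master5 <- function() {
  read_newick("(((A:1,B:2):1,C:1.5):0.5,(D:2,E:1):1);")
}

# Named lengths by branch key, via the package keying (for comparing pruned
# trees' merged lengths).
lengths_by_key <- function(tree, master) {
  bk <- branch_keys(tree, master)
  stats::setNames(bk$length, bk$key)
}
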