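#' Branch-length matrix over canonical branch keys
#'
#' Rows are genes, columns are master branch keys; a cell holds the length of
#' the gene-tree branch matched to that master branch, or `NA` where the gene
#' tree (after taxon loss) has no such branch.  Column order follows the
#' master tree's edge order.
#'
#' @param trees A [tree_set()].
#' @return Numeric matrix with gene rownames and branch-key colnames.
#' @export
build_branch_length_matrix <- function(trees) {
  stopifnot(inherits(trees, "tree_set"))
  master_keys <- vapply(edge_clades(trees$master), key_string, character(1))
  genes <- names(trees$gene_trees)
  M <- matrix(
    NA_real_,
    nrow = length(genes), ncol = length(master_keys),
    dimnames = list(genes, master_keys)
  )
  for (g in genes) {
    bk <- branch_keys(trees$gene_trees[[g]], trees$master)
    M[g, bk$key] <- bk$length
  }
  M
}

RER_EPS <- 1e-9

# Per-gene scale factor against reference branch lengths m: for each gene the
# ratio of its total length to the total reference length over the branches it
# actually has.
gene_scales <- function(M, m) {
  obs <- !is.na(M)
  num <- rowSums(M, na.rm = TRUE)
  den <- (obs %*% m)[, 1]
  if (any(den <= 0)) stop("gene with zero total reference length", call. = FALSE)
  num / den
}

#' Genome-wide expected branch lengths
#'
#' Estimates the "average" branch length for every master branch from the
#' branch-length matrix.  A provisional per-branch mean is used to put each
#' gene on a common scale (fast genes are shrunk, slow genes stretched), then
#' the per-branch mean is recomputed from the rescaled lengths — one
#' refinement pass, which keeps the estimate deterministic and is already
#' very close to the fixed point of the scale/mean alternation.
#'
#' @param M Branch-length matrix from [build_branch_length_matrix()].
#' @return Named numeric vector of positive lengths, one per branch key.
#' @export
estimate_master_lengths <- function(M) {
  stopifnot(is.matrix(M))
  empty <- colSums(!is.na(M)) == 0
  if (any(empty)) {
    stop(
      "no gene covers branch(es): ",
      paste(colnames(M)[empty], collapse = ", "),
      call. = FALSE
    )
  }
  M[!is.na(M) & M == 0] <- RER_EPS
  m0 <- colMeans(M, na.rm = TRUE)
  s <- gene_scales(M, m0)
  m <- colMeans(M / s, na.rm = TRUE)
  pmax(m, RER_EPS)
}

#' Relative evolutionary rates
#'
#' Converts branch lengths into branch-specific relative evolutionary rates
#' (RERs): how fast each gene evolves on each branch relative to the
#' genome-wide expectation for that branch, after removing the gene's overall
#' rate.  Two interchangeable methods are provided:
#'
#' * `"log-ratio"` (default): `log((l + eps) / (s_g * m_b + eps))`, centred
#'   per gene; exactly zero for a gene whose tree is proportional to the
#'   master, and exactly invariant to rescaling a gene's lengths.
#' * `"residual"`: per-gene residuals of `sqrt(l)` regressed on
#'   `sqrt(s_g * m_b)`, divided by the square root of the gene scale and
#'   centred per gene; a square-root variance-stabilized regression in the
#'   spirit of commonly used RER software.  The scale normalization keeps
#'   this method's output shrinking to zero as branch-length noise vanishes,
#'   in agreement with the log-ratio method in the null.
#'
#' Missing branches stay missing; nothing is imputed.
#'
#' @param M Branch-length matrix.
#' @param m Master lengths from [estimate_master_lengths()].
#' @param method `"log-ratio"` or `"residual"`.
#' @return Matrix of RERs with the same dimensions and missingness as `M`,
#'   with attribute `method`.
#' @export
compute_rer <- function(M, m, method = c("log-ratio", "residual")) {
  method <- match.arg(method)
  stopifnot(is.matrix(M))
  if (!all(colnames(M) %in% names(m))) {
    stop("master lengths do not cover all branch columns", call. = FALSE)
  }
  m <- m[colnames(M)]
  s <- gene_scales(M, m)
  expected <- s %o% m
  if (method == "log-ratio") {
    # pseudo-length floors only affect zero branches, so rescaling a gene's
    # positive lengths leaves its RERs exactly unchanged
    R <- log(pmax(M, RER_EPS) / pmax(expected, RER_EPS))
  } else {
    R <- M * NA_real_
    for (g in seq_len(nrow(M))) {
      obs <- which(!is.na(M[g, ]))
      y <- sqrt(M[g, obs])
      x <- sqrt(expected[g, obs])
      fit <- stats::lm(y ~ x)
      # residuals scale with sqrt(gene scale); dividing by it makes the
      # method exactly invariant to rescaling a gene's lengths
      R[g, obs] <- stats::residuals(fit) / sqrt(s[g])
    }
  }
  R <- sweep(R, 1, rowMeans(R, na.rm = TRUE))
  attr(R, "method") <- method
  R
}

#' Species present in each gene's tree, recovered from the RER/branch matrix
#'
#' A gene's species are exactly the singleton branch keys at which it has a
#' value (pendant branches always match the master's own pendant branch).
#'
#' @param M Branch-length or RER matrix keyed by branch keys.
#' @return Named list of character vectors, one per gene.
#' @export
matrix_gene_species <- function(M) {
  singleton <- !grepl(";", colnames(M), fixed = TRUE)
  sp <- colnames(M)[singleton]
  obs <- !is.na(M[, singleton, drop = FALSE])
  lapply(seq_len(nrow(M)), function(i) sp[obs[i, ]]) |>
    stats::setNames(rownames(M))
}

#' Write / read a branch-keyed matrix as TSV
#'
#' Column headers are the semicolon-joined descendant leaf sets; the first
#' column holds gene ids.
#'
#' @param M Matrix with gene rownames and branch-key colnames.
#' @param path Output path.
#' @return `read_branch_matrix_tsv()` returns the matrix.
#' @export
write_branch_matrix_tsv <- function(M, path) {
  df <- tibble::as_tibble(M, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_branch_matrix_tsv
#' @export
read_branch_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  M <- as.matrix(df[, -1])
  storage.mode(M) <- "double"
  rownames(M) <- df$gene_id
  M
}
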