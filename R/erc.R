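#' Winsorize a vector of rates
#'
#' Condenses the `k` most extreme values in each tail to the (k+1)-th most
#' extreme, by value (ties at the boundary are clamped together regardless of
#' position).  Element order and missingness are preserved.  This damps
#' correlations driven by one or a few outlier branches.
#'
#' @param x Numeric vector, possibly with `NA`s.
#' @param k Values condensed per tail (default 3).
#' @return Winsorized vector, same length and order as `x`.
#' @examples
#' winsorize(1:10, k = 3)
#' @export
winsorize <- function(x, k = 3) {
  obs <- which(!is.na(x))
  n <- length(obs)
  if (n <= 2 * k) {
    stop(
      "cannot winsorize ", n, " values with k = ", k,
      " (need more than ", 2 * k, ")",
      call. = FALSE
    )
  }
  if (k == 0) return(x)
  v <- sort(x[obs])
  lo <- v[k + 1]
  hi <- v[n - k]
  x[obs] <- pmin(pmax(x[obs], lo), hi)
  x
}

#' Fisher transformation of a correlation, normalized for branch count
#'
#' `ftERC = atanh(r) * sqrt(n - 3)`, with `r` clamped to `1 - 1e-12` in
#' magnitude so the statistic stays finite at `r = +/-1`.  Dividing the
#' Fisher z by its null standard error `1/sqrt(n - 3)` puts gene pairs with
#' different numbers of shared branches on a common scale with null mean 0
#' and variance about 1.
#'
#' @param r Pearson correlation(s), `|r| <= 1`.
#' @param n Number of shared branches contributing to `r` (`n >= 4`).
#' @return ftERC value(s).
#' @examples
#' fisher_transform(0.5, 103)
#' @export
fisher_transform <- function(r, n) {
  if (any(n < 4)) {
    stop("fisher_transform undefined for n < 4 branches", call. = FALSE)
  }
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    stop("|r| must not exceed 1", call. = FALSE)
  }
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  atanh(r) * sqrt(n - 3)
}

# Core of the pairwise computation, on two aligned RER vectors (NAs mark
# missing branches) plus the two genes' species sets.  Returns a plain list;
# the exported wrappers shape it into tibbles.
erc_pair_core <- function(ra, rb, n_shared_species,
                          min_shared_species = 15, winsor_k = 3) {
  shared <- which(!is.na(ra) & !is.na(rb))
  n_branches <- length(shared)
  out <- list(
    r = NA_real_, n_branches = n_branches,
    n_shared_species = n_shared_species,
    ftERC = NA_real_, filter_reason = NA_character_
  )
  if (n_shared_species < min_shared_species) {
    out$filter_reason <- "min_species"
    return(out)
  }
  if (n_branches <= 2 * winsor_k || n_branches < 4) {
    out$filter_reason <- "too_few_branches"
    return(out)
  }
  va <- winsorize(ra[shared], winsor_k)
  vb <- winsorize(rb[shared], winsor_k)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    out$filter_reason <- "zero_variance"
    return(out)
  }
  out$r <- stats::cor(va, vb)
  out$ftERC <- fisher_transform(out$r, n_branches)
  out
}

#' ERC between one pair of genes
#'
#' Restricts both genes' RER vectors to the branches present in both,
#' winsorizes each restricted vector, computes the Pearson correlation, and
#' Fisher-transforms it with `n` = number of shared branches.  Pairs sharing
#' fewer than `min_shared_species` species, or too few branches, or with a
#' constant winsorized vector are *filtered* (returned with a
#' `filter_reason`), not errors.
#'
#' @param rer RER matrix from [compute_rer()].
#' @param a,b Gene ids (rownames of `rer`).
#' @param min_shared_species Minimum species shared by the two gene trees
#'   (default 15).
#' @param winsor_k Winsorization depth per tail (default 3).
#' @return One-row tibble: `gene_a`, `gene_b`, `r`, `n_branches`,
#'   `n_shared_species`, `ftERC`, `filter_reason`.
#' @export
pairwise_erc <- function(rer, a, b, min_shared_species = 15, winsor_k = 3) {
  stopifnot(a %in% rownames(rer), b %in% rownames(rer))
  sp <- matrix_gene_species(rer[c(a, b), , drop = FALSE])
  core <- erc_pair_core(
    rer[a, ], rer[b, ],
    n_shared_species = length(intersect(sp[[1]], sp[[2]])),
    min_shared_species = min_shared_species, winsor_k = winsor_k
  )
  tibble::tibble(
    gene_a = a, gene_b = b,
    r = core$r, n_branches = core$n_branches,
    n_shared_species = core$n_shared_species,
    ftERC = core$ftERC, filter_reason = core$filter_reason
  )
}

#' ERC for all gene pairs
#'
#' Runs [pairwise_erc()] over every unordered pair of the requested genes and
#' returns the edge list.  Filtered pairs are kept in the table with their
#' `filter_reason` so downstream tallies can account for them.
#'
#' @param rer RER matrix.
#' @param genes Optional subset of gene ids (default: all rows).
#' @inheritParams pairwise_erc
#' @return Tibble edge list, one row per unordered pair, class `erc_tbl`.
#' @export
all_pairs_erc <- function(rer, genes = NULL, min_shared_species = 15,
                          winsor_k = 3) {
  if (is.null(genes)) genes <- rownames(rer)
  genes <- as.character(genes)
  if (length(genes) < 2) stop("need at least 2 genes", call. = FALSE)
  if (!all(genes %in% rownames(rer))) {
    stop("unknown gene id(s): ",
      paste(setdiff(genes, rownames(rer)), collapse = ", "),
      call. = FALSE
    )
  }
  species <- matrix_gene_species(rer[genes, , drop = FALSE])
  np <- length(genes) * (length(genes) - 1) / 2
  gene_a <- character(np); gene_b <- character(np)
  r <- numeric(np); nb <- integer(np); ns <- integer(np)
  ft <- numeric(np); reason <- character(np)
  idx <- 0L
  for (i in seq_along(genes)[-length(genes)]) {
    ri <- rer[genes[i], ]
    for (j in seq((i + 1), length(genes))) {
      idx <- idx + 1L
      core <- erc_pair_core(
        ri, rer[genes[j], ],
        n_shared_species = length(intersect(species[[i]], species[[j]])),
        min_shared_species = min_shared_species, winsor_k = winsor_k
      )
      gene_a[idx] <- genes[i]; gene_b[idx] <- genes[j]
      r[idx] <- core$r; nb[idx] <- core$n_branches
      ns[idx] <- core$n_shared_species; ft[idx] <- core$ftERC
      reason[idx] <- if (is.na(core$filter_reason)) NA_character_ else core$filter_reason
    }
  }
  out <- tibble::tibble(
    gene_a = gene_a, gene_b = gene_b, r = r, n_branches = nb,
    n_shared_species = ns, ftERC = ft, filter_reason = reason
  )
  class(out) <- c("erc_tbl", class(out))
  out
}

#' Symmetric gene-by-gene matrix of an ERC edge-list column
#'
#' @param erc Edge list from [all_pairs_erc()].
#' @param value Column to spread (default `"ftERC"`).
#' @param genes Optional gene universe fixing row/column order.
#' @return Symmetric matrix with `NA` diagonal and `NA` for filtered pairs.
#' @export
erc_matrix <- function(erc, value = "ftERC", genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(c(erc$gene_a, erc$gene_b)))
  M <- matrix(
    NA_real_, length(genes), length(genes),
    dimnames = list(genes, genes)
  )
  keep <- is.na(erc$filter_reason) &
    erc$gene_a %in% genes & erc$gene_b %in% genes
  e <- erc[keep, ]
  M[cbind(e$gene_a, e$gene_b)] <- e[[value]]
  M[cbind(e$gene_b, e$gene_a)] <- e[[value]]
  M
}

#' Write / read an ERC edge list as TSV
#'
#' @param erc Edge list tibble.
#' @param path File path.
#' @return `read_erc_tsv()` returns the edge list (class `erc_tbl`).
#' @export
write_erc_tsv <- function(erc, path) {
  readr::write_tsv(erc, path)
  invisible(path)
}

#' @rdname write_erc_tsv
#' @export
read_erc_tsv <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_a = "c", gene_b = "c", r = "d", n_branches = "i",
      n_shared_species = "i", ftERC = "d", filter_reason = "c"
    )
  )
  class(out) <- c("erc_tbl", class(out))
  out
}
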