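normalize_pairs <- function(pairs) {
  if (is.null(pairs) || (is.data.frame(pairs) && nrow(pairs) == 0)) {
    return(character(0))
  }
  if (is.data.frame(pairs)) {
    a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  } else {
    a <- vapply(pairs, function(p) as.character(p[[1]]), character(1))
    b <- vapply(pairs, function(p) as.character(p[[2]]), character(1))
  }
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

pair_id <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Mean ERC of a gene set
#'
#' Arithmetic mean of ftERC over the unordered in-set pairs, excluding pairs
#' filtered upstream (too few shared species, zero variance) and, optionally,
#' a list of masked pairs — e.g. physically interacting members of a pathway,
#' so the co-functional signal can be measured free of physical pairs.
#'
#' @param erc ERC edge list from [all_pairs_erc()].
#' @param members Character vector of gene ids.
#' @param mask Optional pairs to exclude: a two-column data frame or a list
#'   of length-2 vectors.
#' @return List with `mean` and `n_pairs_used`.
#' @export
set_mean_erc <- function(erc, members, mask = NULL) {
  members <- unique(as.character(members))
  if (length(members) < 2) stop("need at least 2 members", call. = FALSE)
  keep <- erc$gene_a %in% members & erc$gene_b %in% members &
    is.na(erc$filter_reason)
  if (!is.null(mask)) {
    keep <- keep & !(pair_id(erc$gene_a, erc$gene_b) %in% normalize_pairs(mask))
  }
  if (!any(keep)) stop("no usable pairs in set", call. = FALSE)
  list(mean = mean(erc$ftERC[keep]), n_pairs_used = sum(keep))
}

# Mean of the upper triangle of a symmetric value matrix over `idx`, NA-aware.
submatrix_mean <- function(M, idx) {
  sub <- M[idx, idx, drop = FALSE]
  vals <- sub[upper.tri(sub)]
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Permutation test of a gene set's mean ERC against size-matched random sets
#'
#' The null distribution is built from `B` random gene sets of the same size,
#' sampled uniformly without replacement from the gene universe (all genes
#' with computed RERs).  Null means obey the same filtering and masking rules
#' as the observed statistic; a null replicate with zero usable pairs is
#' resampled (and counted).  The p-value uses the add-one convention
#' `p = (1 + #\{null >= observed\}) / (1 + B)`, so it is never zero and the
#' smallest attainable value at `B = 1000` is `1/1001` (reported "<0.001").
#'
#' @param erc ERC edge list.
#' @param members Gene ids of the set.
#' @param universe Gene ids to sample null sets from.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param mask Optional masked pairs (see [set_mean_erc()]).
#' @param set_id Optional label carried into the result.
#' @return Object of class `erc_set_test`: `set_id`, `mean_erc`,
#'   `n_pairs_used`, `B`, `null_means`, `p`, `seed`, `n_resampled`.
#' @export
size_matched_permutation_test <- function(erc, members, universe, B = 1000,
                                          seed = 1L, mask = NULL,
                                          set_id = NA_character_) {
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  members <- unique(as.character(members))
  universe <- unique(as.character(universe))
  if (length(universe) <= length(members)) {
    stop("universe must be larger than the set", call. = FALSE)
  }
  M <- erc_matrix(erc, "ftERC", genes = universe)
  if (!is.null(mask)) {
    masked <- normalize_pairs(mask)
    all_ids <- outer(universe, universe, pair_id)
    M[all_ids %in% masked] <- NA_real_
  }
  obs_idx <- match(members, universe)
  if (anyNA(obs_idx)) stop("set member(s) outside the universe", call. = FALSE)
  observed <- submatrix_mean(M, obs_idx)
  if (is.na(observed)) stop("no usable pairs in set", call. = FALSE)
  n_pairs <- sum(!is.na(M[obs_idx, obs_idx][upper.tri(diag(length(obs_idx)))]))
  set.seed(seed)
  k <- length(members)
  nu <- length(universe)
  null_means <- numeric(B)
  n_resampled <- 0L
  for (b in seq_len(B)) {
    repeat {
      val <- submatrix_mean(M, sample.int(nu, k))
      if (!is.na(val)) break
      n_resampled <- n_resampled + 1L
    }
    null_means[b] <- val
  }
  structure(
    list(
      set_id = set_id, mean_erc = observed, n_pairs_used = n_pairs,
      B = B, null_means = null_means,
      p = (1 + sum(null_means >= observed)) / (1 + B),
      seed = seed, n_resampled = n_resampled
    ),
    class = "erc_set_test"
  )
}

#' @export
print.erc_set_test <- function(x, ...) {
  cat(
    "<erc_set_test>", if (!is.na(x$set_id)) x$set_id else "",
    " mean ftERC =", signif(x$mean_erc, 4),
    " over", x$n_pairs_used, "pairs; p =", signif(x$p, 4),
    " (B =", x$B, ")\n"
  )
  invisible(x)
}

#' Run the size-matched permutation test over a manifest of gene sets
#'
#' Sets are first pared down to members present in the universe; sets with
#' more than `member_min - 1` members (default: more than four) are tested,
#' smaller ones are dropped with a reason.
#'
#' @param erc ERC edge list.
#' @param sets Tibble with columns `set_id`, `kind`, `member`.
#' @param universe Gene universe for null sampling; defaults to all genes in
#'   `erc`.
#' @param member_min Minimum set size after intersection (default 5).
#' @inheritParams size_matched_permutation_test
#' @return Tibble with one row per tested set: `set_id`, `kind`, `n_members`,
#'   `mean_erc`, `n_pairs_used`, `B`, `p`, plus a `null_means` list column.
#' @export
set_permutation_tests <- function(erc, sets, universe = NULL, B = 1000,
                                  seed = 1L, mask = NULL, member_min = 5) {
  stopifnot(all(c("set_id", "kind", "member") %in% names(sets)))
  if (is.null(universe)) universe <- unique(c(erc$gene_a, erc$gene_b))
  sets <- dplyr::filter(sets, .data$member %in% universe)
  counts <- dplyr::count(sets, .data$set_id, name = "n_members")
  keep_ids <- counts$set_id[counts$n_members >= member_min]
  sets <- dplyr::filter(sets, .data$set_id %in% keep_ids)
  if (nrow(sets) == 0) stop("no set passes the size filter", call. = FALSE)
  split_sets <- split(sets, sets$set_id)
  seeds <- derive_seeds(seed, length(split_sets))
  purrr::imap_dfr(split_sets, function(df, id) {
    res <- size_matched_permutation_test(
      erc, df$member, universe,
      B = B, seed = seeds[[match(id, names(split_sets))]],
      mask = mask, set_id = id
    )
    tibble::tibble(
      set_id = id, kind = df$kind[1], n_members = nrow(df),
      mean_erc = res$mean_erc, n_pairs_used = res$n_pairs_used,
      B = res$B, p = res$p, null_means = list(res$null_means)
    )
  })
}

# Deterministic child seeds below 2^31, derived from one parent seed.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Read a gene-set manifest TSV (`set_id`, `kind`, `member`)
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_gene_sets_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(set_id = "c", kind = "c", member = "c")
  )
}
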