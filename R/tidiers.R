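#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data %||%
NULL

#' Tidy a permutation-test result into its null sample
#'
#' @param x An `erc_perm` object.
#' @param ... Unused.
#' @return Tibble with `replicate` and `value` (one row per null draw).
#' @method tidy erc_perm
#' @export
tidy.erc_perm <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null), value = x$null)
}

#' One-row summary of a permutation test
#'
#' @param x An `erc_perm` object.
#' @param ... Unused.
#' @return Tibble: `statistic`, `observed`, `null_mean`, `B`, `p`, `seed`.
#' @method glance erc_perm
#' @export
glance.erc_perm <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, observed = x$observed,
    null_mean = mean(x$null), B = x$B, p = x$p, seed = x$seed
  )
}

#' ROC curve points of a ROC result
#'
#' @param x An `erc_roc` object.
#' @param ... Unused.
#' @return Tibble of `FPR`, `TPR` points.
#' @method tidy erc_roc
#' @export
tidy.erc_roc <- function(x, ...) x$curve

#' One-row summary of a ROC result
#'
#' @param x An `erc_roc` object.
#' @param ... Unused.
#' @return Tibble: `complex_id`, `auc`, `U`, `n_pos`, `n_neg`, `p_mw`.
#' @method glance erc_roc
#' @export
glance.erc_roc <- function(x, ...) {
  tibble::tibble(
    complex_id = x$complex_id %||% NA_character_,
    auc = x$auc, U = x$U, n_pos = x$n_pos, n_neg = x$n_neg, p_mw = x$p_mw
  )
}

#' Null sample of a gene-set permutation test
#'
#' @param x An `erc_set_test` object.
#' @param ... Unused.
#' @return Tibble with `replicate` and `null_mean`.
#' @method tidy erc_set_test
#' @export
tidy.erc_set_test <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null_means), null_mean = x$null_means)
}

#' One-row summary of a gene-set permutation test
#'
#' @param x An `erc_set_test` object.
#' @param ... Unused.
#' @return Tibble: `set_id`, `mean_erc`, `n_pairs_used`, `B`, `p`, `seed`.
#' @method glance erc_set_test
#' @export
glance.erc_set_test <- function(x, ...) {
  tibble::tibble(
    set_id = x$set_id, mean_erc = x$mean_erc,
    n_pairs_used = x$n_pairs_used, B = x$B, p = x$p, seed = x$seed
  )
}

#' Per-complex summary table of a full run
#'
#' @param x An `erc_run` object.
#' @param ... Unused.
#' @return The per-complex summary tibble.
#' @method tidy erc_run
#' @export
tidy.erc_run <- function(x, ...) x$summary

#' One-row overview of a full run
#'
#' @param x An `erc_run` object.
#' @param ... Unused.
#' @return Tibble of run-level tallies and the study-wide AUC test.
#' @method glance erc_run
#' @export
glance.erc_run <- function(x, ...) {
  tibble::tibble(
    n_genes = x$manifest$n_genes,
    n_branches = x$manifest$n_branches,
    n_pairs = x$manifest$n_pairs,
    n_filtered_min_species = x$manifest$n_filtered_min_species,
    n_sets_tested = x$manifest$n_sets_tested,
    n_complexes = x$manifest$n_complexes,
    mean_auc = if (is.null(x$global_auc)) NA_real_ else x$global_auc$observed,
    p_global_auc = if (is.null(x$global_auc)) NA_real_ else x$global_auc$p
  )
}
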