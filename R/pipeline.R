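#' Analysis parameters for a full study run
#'
#' Surfaces every pipeline threshold in one place: the 15-shared-species
#' filter, winsorization depth, permutation count, and the minimum gene-set
#' size ("greater than four members").
#'
#' @param min_shared_species Minimum species shared by a gene pair (default 15).
#' @param winsor_k Winsorization depth per tail (default 3).
#' @param B Permutations for every permutation test (default 1000).
#' @param member_min Minimum gene-set size after intersection with the
#'   dataset (default 5).
#' @param rer_method RER method, `"log-ratio"` or `"residual"`.
#' @param include_intra_protein Include same-protein domain pairs as ROC
#'   negatives (default `FALSE`).
#' @param mask Optional gene pairs excluded from set means (e.g. physically
#'   interacting pathway members).
#' @param seed Integer seed; every stage derives its own stream from it.
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(min_shared_species = 15, winsor_k = 3, B = 1000,
                            member_min = 5, rer_method = "log-ratio",
                            include_intra_protein = FALSE, mask = NULL,
                            seed = 1L) {
  structure(
    list(
      min_shared_species = min_shared_species, winsor_k = winsor_k, B = B,
      member_min = member_min, rer_method = rer_method,
      include_intra_protein = include_intra_protein, mask = mask,
      seed = as.integer(seed)
    ),
    class = "pipeline_params"
  )
}

#' Run the full ERC analysis on a study
#'
#' Executes every stage in order: branch-length matrix and RERs, all-pairs
#' ERC, gene-set permutation tests, per-complex domain edge lists with
#' ROC-AUC / Mann-Whitney / AUC-permutation tests, the study-wide average-AUC
#' permutation test, and per-complex proportional-rank tests.  Complexes
#' whose edge list is degenerate (no positive or no negative class with ERC
#' values) are skipped and listed in the manifest.  Given the same study and
#' parameters, the run is fully deterministic.
#'
#' @param study An `erc_study` (from [simulate_study()] or [read_study()]).
#' @param params A [pipeline_params()].
#' @return Object of class `erc_run` with components `rer`, `master_lengths`,
#'   `erc`, `set_results`, `edges` (per-complex edge lists), `roc`,
#'   `auc_perm`, `global_auc`, `prop_rank`, `summary` (per-complex table),
#'   and `manifest` (stage tallies).
#' @export
run_full_study <- function(study, params = pipeline_params()) {
  stopifnot(inherits(study, "erc_study"))
  seeds <- derive_seeds(params$seed, 3 + length(study$complexes) * 2)
  blm <- build_branch_length_matrix(study$trees)
  m <- estimate_master_lengths(blm)
  rer <- compute_rer(blm, m, method = params$rer_method)
  erc <- all_pairs_erc(
    rer,
    min_shared_species = params$min_shared_species,
    winsor_k = params$winsor_k
  )
  filter_tally <- table(erc$filter_reason, useNA = "no")

  set_results <- NULL
  if (nrow(study$sets) > 0) {
    set_results <- tryCatch(
      set_permutation_tests(
        erc, study$sets,
        universe = rownames(rer), B = params$B, seed = seeds[1],
        mask = params$mask, member_min = params$member_min
      ),
      error = function(e) NULL
    )
  }

  edges <- list(); roc <- list(); auc_perm <- list(); prop_rank <- list()
  skipped <- character(0)
  cx_ids <- names(study$complexes)
  for (i in seq_along(cx_ids)) {
    cid <- cx_ids[i]
    e <- tryCatch(
      build_domain_edge_list(
        erc, study$complexes[[cid]],
        include_intra_protein = params$include_intra_protein
      ),
      error = function(err) NULL
    )
    if (is.null(e)) {
      skipped <- c(skipped, cid)
      next
    }
    edges[[cid]] <- e
    roc[[cid]] <- roc_auc(e)
    auc_perm[[cid]] <- permute_complex_auc(e, B = params$B, seed = seeds[3 + i])
    pp <- complex_protein_pairs(e, study$complexes[[cid]])
    if (length(pp) > 0) {
      prop_rank[[cid]] <- complex_prop_rank_test(
        pp,
        B = params$B, seed = seeds[3 + length(cx_ids) + i]
      )
    }
  }

  global_auc <- NULL
  if (length(edges) >= 2) {
    global_auc <- global_average_auc_test(edges, B = params$B, seed = seeds[2])
  }

  summary <- purrr::imap_dfr(edges, function(e, cid) {
    phys <- e$ftERC[e$label == 1]
    nonphys <- e$ftERC[e$label == 0]
    pr <- prop_rank[[cid]]
    tibble::tibble(
      complex_id = cid,
      n_proteins = length(unique(c(e$protein_a, e$protein_b))),
      n_domains = length(unique(c(e$domain_a, e$domain_b))),
      n_edges = nrow(e),
      n_dropped = attr(e, "n_dropped"),
      mean_erc = mean(e$ftERC),
      mean_physical_erc = mean(phys),
      mean_nonphysical_erc = mean(nonphys),
      auc = roc[[cid]]$auc,
      p_mw = roc[[cid]]$p_mw,
      p_auc_perm = auc_perm[[cid]]$p,
      prop_rank = if (is.null(pr)) NA_real_ else pr$observed,
      p_prop_rank = if (is.null(pr)) NA_real_ else pr$p
    )
  })

  manifest <- list(
    seed = params$seed,
    params = unclass(params),
    n_genes = nrow(rer),
    n_branches = ncol(rer),
    n_pairs = nrow(erc),
    n_filtered_min_species = sum(erc$filter_reason %in% "min_species"),
    n_filtered_too_few_branches = sum(erc$filter_reason %in% "too_few_branches"),
    n_filtered_zero_variance = sum(erc$filter_reason %in% "zero_variance"),
    filter_tally = filter_tally,
    n_sets_tested = if (is.null(set_results)) 0L else nrow(set_results),
    n_complexes = length(edges),
    skipped_complexes = skipped
  )

  structure(
    list(
      rer = rer, master_lengths = m, erc = erc, set_results = set_results,
      edges = edges, roc = roc, auc_perm = auc_perm, global_auc = global_auc,
      prop_rank = prop_rank, summary = summary, manifest = manifest
    ),
    class = "erc_run"
  )
}

#' @export
print.erc_run <- function(x, ...) {
  cat(
    "<erc_run>", x$manifest$n_genes, "genes,",
    x$manifest$n_pairs, "ERC pairs (",
    x$manifest$n_filtered_min_species, "filtered by species ),",
    x$manifest$n_sets_tested, "sets tested,",
    x$manifest$n_complexes, "complexes analysed\n"
  )
  if (!is.null(x$global_auc)) {
    cat(
      "  study-wide mean AUC =", signif(x$global_auc$observed, 4),
      ", permutation p =", signif(x$global_auc$p, 4), "\n"
    )
  }
  invisible(x)
}

#' Write the main tables of a run to a directory
#'
#' Emits `rer.tsv`, `erc.tsv`, `set_results.tsv`, `summary.tsv` and
#' `roc_curves.tsv`.
#'
#' @param run An `erc_run`.
#' @param dir Output directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_branch_matrix_tsv(run$rer, file.path(dir, "rer.tsv"))
  write_erc_tsv(run$erc, file.path(dir, "erc.tsv"))
  if (!is.null(run$set_results)) {
    readr::write_tsv(
      dplyr::select(run$set_results, -"null_means"),
      file.path(dir, "set_results.tsv")
    )
  }
  if (nrow(run$summary) > 0) {
    readr::write_tsv(run$summary, file.path(dir, "summary.tsv"))
    curves <- purrr::imap_dfr(run$roc, function(r, cid) {
      dplyr::mutate(r$curve, complex_id = cid, .before = 1)
    })
    readr::write_tsv(curves, file.path(dir, "roc_curves.tsv"))
  }
  invisible(dir)
}
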