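#' Configuration for a synthetic ERC study
#'
#' Describes a complete synthetic study: a master species tree, background
#' genes, co-functional modules (complexes/pathways at the set level) whose
#' members share a latent rate factor with loading `rho_mod`, and
#' domain-resolved complexes in which designated "physically interacting"
#' domain pairs share an additional pair factor with loading `rho_phys`.
#' Under this model the population correlation between two units' true RERs
#' is `rho_mod` (same module) plus `rho_phys` (physical pair), which is what
#' the ERC estimator should recover.
#'
#' @param S Number of species (>= 20, so the 15-shared-species filter is a
#'   live constraint rather than a vacuous one).
#' @param n_background_genes Unrelated genes with no shared factor.
#' @param modules Tibble with `module_id`, `kind` (`"complex"`/`"pathway"`),
#'   `n_members`, `rho_mod`; or `NULL`.
#' @param complexes Tibble with `complex_id`, `n_proteins`,
#'   `n_physical_pairs`, `rho_mod`, `rho_phys`; or `NULL`.
#' @param n_domains_per_protein Length-2 integer range; each complex protein
#'   gets a uniform draw from it.
#' @param sigma_noise Multiplicative log-normal noise scale on branch
#'   lengths: a unit's length on branch `b` is
#'   `m_b * exp(sigma_noise * RER)`.
#' @param dropout Per-species, per-gene probability of being absent from a
#'   gene tree.
#' @param birth_rate Yule speciation rate of the master tree.
#' @param seed Integer master seed; all randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(S = 40, n_background_genes = 100, modules = NULL,
                       complexes = NULL, n_domains_per_protein = c(2, 3),
                       sigma_noise = 0.3, dropout = 0.1, birth_rate = 1,
                       seed = 1L) {
  stopifnot(S >= 20, n_background_genes >= 0, sigma_noise > 0)
  stopifnot(dropout >= 0, dropout < 1, birth_rate > 0)
  if (!is.null(modules)) {
    stopifnot(all(c("module_id", "kind", "n_members", "rho_mod") %in% names(modules)))
    stopifnot(all(modules$rho_mod >= 0 & modules$rho_mod < 1))
  }
  if (!is.null(complexes)) {
    stopifnot(all(
      c("complex_id", "n_proteins", "n_physical_pairs", "rho_mod", "rho_phys") %in%
        names(complexes)
    ))
    stopifnot(all(complexes$rho_mod + complexes$rho_phys < 1))
    stopifnot(all(complexes$rho_phys >= 0), all(complexes$rho_mod >= 0))
    stopifnot(all(complexes$n_proteins >= 2))
  }
  structure(
    list(
      S = S, n_background_genes = n_background_genes, modules = modules,
      complexes = complexes, n_domains_per_protein = n_domains_per_protein,
      sigma_noise = sigma_noise, dropout = dropout, birth_rate = birth_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a rooted Yule master tree
#'
#' Pure-birth simulation: starting from two lineages, each of the `k` current
#' lineages waits an `Exp(k * birth_rate)` epoch before one (chosen uniformly)
#' splits, until `S` lineages exist; one final `Exp(S * birth_rate)` epoch is
#' then appended so all pendant branches have positive length.  Total tree
#' length therefore has expectation `S / birth_rate`.
#'
#' @param S Number of species (>= 3).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed; same seed, same newick string.
#' @return Rooted binary `phylo` with tips `s001 ... s<S>`.
#' @export
simulate_master_tree <- function(S, birth_rate = 1, seed = 1L) {
  stopifnot(S >= 3, birth_rate > 0)
  set.seed(seed)
  n_nodes <- 1L # node 1 is the root
  par <- integer(0); child <- integer(0); len <- numeric(0)
  lin_parent <- c(1L, 1L)
  lin_len <- c(0, 0)
  k <- 2L
  while (k < S) {
    lin_len <- lin_len + stats::rexp(1, k * birth_rate)
    i <- sample.int(k, 1)
    n_nodes <- n_nodes + 1L
    par <- c(par, lin_parent[i]); child <- c(child, n_nodes); len <- c(len, lin_len[i])
    lin_parent[i] <- n_nodes; lin_len[i] <- 0
    lin_parent <- c(lin_parent, n_nodes); lin_len <- c(lin_len, 0)
    k <- k + 1L
  }
  lin_len <- lin_len + stats::rexp(1, S * birth_rate)
  labels <- character(n_nodes + S)
  for (i in seq_len(S)) {
    n_nodes <- n_nodes + 1L
    par <- c(par, lin_parent[i]); child <- c(child, n_nodes); len <- c(len, lin_len[i])
    labels[n_nodes] <- sprintf("s%03d", i)
  }
  kids <- split(seq_along(par), par)
  build <- function(node) {
    e <- kids[[as.character(node)]]
    if (is.null(e)) return(labels[node])
    paste0(
      "(",
      paste(
        vapply(e, function(ed) {
          paste0(build(child[ed]), ":", format(len[ed], digits = 15))
        }, character(1)),
        collapse = ","
      ),
      ")"
    )
  }
  read_newick(paste0(build(1L), ";"))
}

# Expand a sim_config into the unit table (one row per gene/domain) and the
# physical-pair truth table.  Deterministic given `seed`.
build_sim_units <- function(config, seed) {
  set.seed(seed)
  units <- list()
  pairs <- list()
  if (config$n_background_genes > 0) {
    units[[length(units) + 1]] <- tibble::tibble(
      unit_id = sprintf("bg%04d", seq_len(config$n_background_genes)),
      protein_id = sprintf("bg%04d", seq_len(config$n_background_genes)),
      set_id = NA_character_, kind = NA_character_, rho_mod = 0
    )
  }
  if (!is.null(config$modules)) {
    for (i in seq_len(nrow(config$modules))) {
      m <- config$modules[i, ]
      ids <- sprintf("%s_g%02d", m$module_id, seq_len(m$n_members))
      units[[length(units) + 1]] <- tibble::tibble(
        unit_id = ids, protein_id = ids,
        set_id = m$module_id, kind = m$kind, rho_mod = m$rho_mod
      )
    }
  }
  if (!is.null(config$complexes)) {
    rng <- config$n_domains_per_protein
    for (i in seq_len(nrow(config$complexes))) {
      cx <- config$complexes[i, ]
      doms <- list()
      for (p in seq_len(cx$n_proteins)) {
        prot <- sprintf("%s_p%d", cx$complex_id, p)
        nd <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
        doms[[p]] <- tibble::tibble(
          unit_id = sprintf("%s_d%d", prot, seq_len(nd)),
          protein_id = prot
        )
      }
      doms <- dplyr::bind_rows(doms)
      units[[length(units) + 1]] <- dplyr::mutate(
        doms,
        set_id = cx$complex_id, kind = "domain_complex", rho_mod = cx$rho_mod
      )
      # physical pairs: distinct protein pairs, one not-yet-paired domain from
      # each side, so no domain carries more than one pair factor
      if (cx$n_physical_pairs > 0) {
        prot_ids <- unique(doms$protein_id)
        combos <- utils::combn(prot_ids, 2)
        pick <- sample(ncol(combos), min(cx$n_physical_pairs, ncol(combos)))
        used <- character(0)
        for (ci in pick) {
          free_a <- setdiff(doms$unit_id[doms$protein_id == combos[1, ci]], used)
          free_b <- setdiff(doms$unit_id[doms$protein_id == combos[2, ci]], used)
          if (length(free_a) == 0 || length(free_b) == 0) next
          da <- if (length(free_a) == 1) free_a else sample(free_a, 1)
          db <- if (length(free_b) == 1) free_b else sample(free_b, 1)
          used <- c(used, da, db)
          pairs[[length(pairs) + 1]] <- tibble::tibble(
            domain_a = da, domain_b = db,
            set_id = cx$complex_id, rho_phys = cx$rho_phys,
            expected_cor = cx$rho_mod + cx$rho_phys
          )
        }
      }
    }
  }
  units <- dplyr::bind_rows(units)
  if (anyDuplicated(units$unit_id)) stop("duplicate unit ids in config", call. = FALSE)
  pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else tibble::tibble(
    domain_a = character(0), domain_b = character(0),
    set_id = character(0), rho_phys = numeric(0), expected_cor = numeric(0)
  )
  list(units = units, pairs = pairs)
}

#' Simulate true relative evolutionary rates with latent-factor structure
#'
#' Draws, independently per master branch, a standard-normal module factor
#' per module, a pair factor per physical domain pair, and idiosyncratic
#' noise per unit, and combines them as
#' `RER = sqrt(rho_mod) * f_module + sqrt(rho_phys) * g_pair +
#' sqrt(1 - rho_mod - rho_phys) * e`, giving every cell unit variance and
#' every unit pair the population correlation recorded in the truth table.
#'
#' @param master Master tree.
#' @param config A [sim_config()].
#' @return List: `rer` (units x branch-keys matrix), `truth` (list of
#'   `units` and `pairs` tibbles).
#' @export
simulate_rers <- function(master, config) {
  stopifnot(inherits(config, "sim_config"))
  ds <- derive_seeds(config$seed, 4)
  sim <- build_sim_units(config, ds[2])
  units <- sim$units
  pairs <- sim$pairs
  keys <- vapply(edge_clades(master), key_string, character(1))
  nb <- length(keys)
  n_units <- nrow(units)
  set.seed(ds[3])
  set_ids <- unique(stats::na.omit(units$set_id))
  f <- matrix(stats::rnorm(length(set_ids) * nb), length(set_ids), nb,
    dimnames = list(set_ids, NULL)
  )
  g <- if (nrow(pairs) > 0) {
    matrix(stats::rnorm(nrow(pairs) * nb), nrow(pairs), nb)
  } else {
    matrix(numeric(0), 0, nb)
  }
  E <- matrix(stats::rnorm(n_units * nb), n_units, nb)
  unit_pair <- rep(NA_integer_, n_units)
  if (nrow(pairs) > 0) {
    for (pi in seq_len(nrow(pairs))) {
      unit_pair[match(c(pairs$domain_a[pi], pairs$domain_b[pi]), units$unit_id)] <- pi
    }
  }
  R <- matrix(0, n_units, nb, dimnames = list(units$unit_id, keys))
  for (u in seq_len(n_units)) {
    rho_m <- units$rho_mod[u]
    rho_p <- if (is.na(unit_pair[u])) 0 else pairs$rho_phys[unit_pair[u]]
    row <- sqrt(1 - rho_m - rho_p) * E[u, ]
    if (!is.na(units$set_id[u]) && rho_m > 0) {
      row <- row + sqrt(rho_m) * f[units$set_id[u], ]
    }
    if (!is.na(unit_pair[u]) && rho_p > 0) {
      row <- row + sqrt(rho_p) * g[unit_pair[u], ]
    }
    R[u, ] <- row
  }
  list(rer = R, truth = list(units = units, pairs = pairs))
}

#' Turn true RERs into gene trees with noise and taxon dropout
#'
#' Unit `u`'s length on branch `b` is `m_b * exp(sigma_noise * RER[u, b])`
#' where `m_b` is the master branch length; species are then dropped
#' independently with probability `dropout` and the tree pruned (collapsed
#' path lengths summed).  A draw leaving fewer than 2 species is redrawn.
#'
#' @param master Master tree.
#' @param rers True RER matrix from [simulate_rers()].
#' @param sigma_noise,dropout See [sim_config()].
#' @param seed Integer seed (per-gene streams are derived from it, so a
#'   gene's tree does not depend on how many genes precede it).
#' @return A [tree_set()].
#' @export
emit_gene_trees <- function(master, rers, sigma_noise, dropout, seed = 1L) {
  keys <- vapply(edge_clades(master), key_string, character(1))
  stopifnot(setequal(colnames(rers), keys))
  m_b <- master$edge.length
  units <- rownames(rers)
  seeds <- derive_seeds(seed, length(units))
  trees <- vector("list", length(units))
  names(trees) <- units
  n_redrawn <- 0L
  for (u in seq_along(units)) {
    tr <- master
    tr$edge.length <- unname(m_b * exp(sigma_noise * rers[units[u], keys]))
    if (dropout > 0) {
      set.seed(seeds[u])
      repeat {
        keep <- master$tip.label[stats::runif(length(master$tip.label)) >= dropout]
        if (length(keep) >= 2) break
        n_redrawn <- n_redrawn + 1L
      }
      if (length(keep) < length(master$tip.label)) tr <- prune_to_species(tr, keep)
    }
    trees[[u]] <- tr
  }
  out <- tree_set(master, trees)
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' Simulate a complete synthetic study
#'
#' Master tree, true RERs, noisy gene/domain trees, gene-set manifests and
#' domain-resolved complex definitions, all from one seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `erc_study`: `master`, `trees` (a `tree_set`),
#'   `sets` (tibble `set_id`, `kind`, `member`), `complexes` (named list of
#'   [complex_definition()]s), `truth`, `true_rers`, `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ds <- derive_seeds(config$seed, 4)
  master <- simulate_master_tree(config$S, config$birth_rate, seed = ds[1])
  sim <- simulate_rers(master, config)
  trees <- emit_gene_trees(
    master, sim$rer, config$sigma_noise, config$dropout,
    seed = ds[4]
  )
  units <- sim$truth$units
  sets <- dplyr::filter(units, !is.na(.data$set_id) & .data$kind != "domain_complex") |>
    dplyr::transmute(set_id = .data$set_id, kind = .data$kind, member = .data$unit_id)
  complexes <- list()
  if (!is.null(config$complexes)) {
    for (cid in config$complexes$complex_id) {
      cx_units <- units[!is.na(units$set_id) & units$set_id == cid, ]
      cx_pairs <- sim$truth$pairs[sim$truth$pairs$set_id == cid, ]
      if (nrow(cx_pairs) == 0) next
      complexes[[cid]] <- complex_definition(
        cid,
        domains = tibble::tibble(
          protein_id = cx_units$protein_id, domain_id = cx_units$unit_id
        ),
        physical_domain_pairs = cx_pairs[, c("domain_a", "domain_b")]
      )
    }
  }
  structure(
    list(
      master = master, trees = trees, sets = sets, complexes = complexes,
      truth = sim$truth, true_rers = sim$rer, config = config
    ),
    class = "erc_study"
  )
}

#' @export
print.erc_study <- function(x, ...) {
  cat(
    "<erc_study>", length(x$master$tip.label), "species,",
    length(x$trees$gene_trees), "gene/domain trees,",
    length(unique(x$sets$set_id)), "gene sets,",
    length(x$complexes), "domain-resolved complexes\n"
  )
  invisible(x)
}

#' Write / read a synthetic study directory
#'
#' Layout: `master.nwk`, `trees/<unit>.nwk`, `sets.tsv`, `complexes.tsv`
#' (`complex_id`, `protein_id`, `domain_id`), `physical_protein_pairs.tsv`,
#' `physical_domain_pairs.tsv`, and `truth/units.tsv`, `truth/pairs.tsv`.
#'
#' @param study An `erc_study`.
#' @param dir Output directory (created if needed).
#' @return `read_study()` returns an `erc_study` (without `true_rers`).
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "trees"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_newick(study$master, file.path(dir, "master.nwk"))
  for (g in names(study$trees$gene_trees)) {
    write_newick(study$trees$gene_trees[[g]], file.path(dir, "trees", paste0(g, ".nwk")))
  }
  readr::write_tsv(study$sets, file.path(dir, "sets.tsv"))
  if (length(study$complexes) > 0) {
    cx_rows <- purrr::imap_dfr(study$complexes, function(cx, cid) {
      dplyr::mutate(cx$domains, complex_id = cid, .before = 1)
    })
    readr::write_tsv(cx_rows, file.path(dir, "complexes.tsv"))
    split_pair <- function(ids) {
      parts <- strsplit(ids, "\r", fixed = TRUE)
      tibble::tibble(
        a = vapply(parts, `[[`, character(1), 1),
        b = vapply(parts, `[[`, character(1), 2)
      )
    }
    pp <- purrr::imap_dfr(study$complexes, function(cx, cid) {
      dplyr::mutate(split_pair(cx$physical_protein_pairs), complex_id = cid, .before = 1)
    })
    names(pp) <- c("complex_id", "protein_a", "protein_b")
    readr::write_tsv(pp, file.path(dir, "physical_protein_pairs.tsv"))
    pd <- purrr::imap_dfr(study$complexes, function(cx, cid) {
      dplyr::mutate(split_pair(cx$physical_domain_pairs), complex_id = cid, .before = 1)
    })
    names(pd) <- c("complex_id", "domain_a", "domain_b")
    readr::write_tsv(pd, file.path(dir, "physical_domain_pairs.tsv"))
  }
  readr::write_tsv(study$truth$units, file.path(dir, "truth", "units.tsv"))
  readr::write_tsv(study$truth$pairs, file.path(dir, "truth", "pairs.tsv"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  trees <- read_tree_dir(dir)
  sets <- read_gene_sets_tsv(file.path(dir, "sets.tsv"))
  complexes <- list()
  cx_rows <- NULL
  if (file.exists(file.path(dir, "complexes.tsv"))) {
    cx_rows <- readr::read_tsv(file.path(dir, "complexes.tsv"), show_col_types = FALSE)
    pd <- readr::read_tsv(file.path(dir, "physical_domain_pairs.tsv"), show_col_types = FALSE)
    pp <- readr::read_tsv(file.path(dir, "physical_protein_pairs.tsv"), show_col_types = FALSE)
  }
  for (cid in unique(cx_rows$complex_id)) {
    complexes[[cid]] <- complex_definition(
      cid,
      domains = cx_rows[cx_rows$complex_id == cid, c("protein_id", "domain_id")],
      physical_domain_pairs = pd[pd$complex_id == cid, c("domain_a", "domain_b")],
      physical_protein_pairs = pp[pp$complex_id == cid, c("protein_a", "protein_b")]
    )
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth", "units.tsv"))) {
    truth <- list(
      units = readr::read_tsv(file.path(dir, "truth", "units.tsv"), show_col_types = FALSE),
      pairs = readr::read_tsv(file.path(dir, "truth", "pairs.tsv"), show_col_types = FALSE)
    )
  }
  structure(
    list(
      master = trees$master, trees = trees, sets = sets, complexes = complexes,
      truth = truth, true_rers = NULL, config = NULL
    ),
    class = "erc_study"
  )
}
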