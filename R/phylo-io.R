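#' Read a rooted phylogeny from newick text or file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the pipeline relies on: unique leaf labels, branch lengths present
#' on every non-root edge, and no negative lengths.  Zero-length branches are
#' allowed; downstream rate computations apply a pseudo-length.
#'
#' @param text Newick string (with trailing semicolon).
#' @param file Path to a newick file; exactly one of `text`/`file` is given.
#' @return An object of class `phylo` (rooted, as written).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`", call. = FALSE)
  }
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("newick parse failure: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tr)) stop("newick parse failure: input did not yield a tree", call. = FALSE)
  validate_phylo(tr)
  tr
}

#' Write a phylogeny as newick text
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @return The newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

validate_phylo <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    dup <- tree$tip.label[duplicated(tree$tip.label)][1]
    stop("duplicate leaf label: '", dup, "'", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("branch lengths are required on all non-root edges", call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    stop("missing branch length on at least one edge", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    bad <- min(tree$edge.length)
    stop("negative branch length: ", bad, call. = FALSE)
  }
  invisible(tree)
}

#' Restrict a tree to a subset of species
#'
#' Drops all leaves not in `keep` and collapses the resulting unary paths,
#' summing their branch lengths, so the output topology equals the input
#' topology restricted to `keep`.
#'
#' @param tree A `phylo`.
#' @param keep Character vector of leaf labels to retain (at least 2 present).
#' @return A pruned `phylo`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' write_newick(prune_to_species(tr, c("A", "C")))
#' @export
prune_to_species <- function(tree, keep) {
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) < 2) {
    stop("degenerate tree: fewer than 2 retained species", call. = FALSE)
  }
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

# Descendant leaf labels for each edge (row of tree$edge), via one postorder
# sweep.  Returned as a list parallel to the edge matrix.
edge_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- vector("list", nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  clade <- vector("list", nnode)
  for (i in seq_len(ntip)) clade[[i]] <- tree$tip.label[i]
  for (r in seq_len(nrow(po$edge))) {
    par <- po$edge[r, 1]
    ch <- po$edge[r, 2]
    clade[[par]] <- c(clade[[par]], clade[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(r) clade[[tree$edge[r, 2]]])
}

key_string <- function(leaves) paste(sort(leaves), collapse = ";")

key_species <- function(key) strsplit(key, ";", fixed = TRUE)

#' Canonical branch keys for a (possibly pruned) gene tree
#'
#' Each branch of a gene tree pruned from the master is matched to the
#' *minimal* master branch whose descendant set, restricted to the gene
#' tree's leaves, equals the branch's own descendant set.  The branch key is
#' the full (unrestricted) descendant leaf set of that master branch, written
#' as a sorted semicolon-joined string.  This keying is injective and reduces
#' to the identity when the gene tree carries all master species; it is what
#' lets "the same branch" be identified across gene trees with different
#' missing taxa.
#'
#' @param tree Gene tree (`phylo`), leaves a subset of the master's.
#' @param master Master species tree (`phylo`).
#' @return Tibble with one row per gene-tree edge: `edge` (row index in
#'   `tree$edge`), `key` (master branch key), `length`.
#' @export
branch_keys <- function(tree, master) {
  if (!all(tree$tip.label %in% master$tip.label)) {
    missing <- setdiff(tree$tip.label, master$tip.label)[1]
    stop("leaf '", missing, "' not present in the master tree", call. = FALSE)
  }
  m_clades <- edge_clades(master)
  m_sizes <- lengths(m_clades)
  ord <- order(m_sizes)
  leaves <- tree$tip.label
  restricted <- vapply(
    m_clades[ord],
    function(cl) key_string(intersect(cl, leaves)),
    character(1)
  )
  g_keys <- vapply(edge_clades(tree), key_string, character(1))
  # first match in size order is the minimal master branch
  idx <- match(g_keys, restricted)
  if (anyNA(idx)) {
    bad <- g_keys[which(is.na(idx))[1]]
    stop(
      "topology inconsistency: no master branch matches descendant set {",
      bad, "}",
      call. = FALSE
    )
  }
  keys <- vapply(m_clades[ord][idx], key_string, character(1))
  if (anyDuplicated(keys)) {
    stop("topology inconsistency: branch keys are not unique", call. = FALSE)
  }
  tibble::tibble(
    edge = seq_along(g_keys),
    key = keys,
    length = tree$edge.length
  )
}

#' Bundle a master tree with its gene trees
#'
#' Validates that every gene tree's leaves are a subset of the master's and
#' that each gene tree's topology equals the master topology pruned to the
#' gene's species (checked by requiring an injective branch-key matching).
#'
#' @param master Master species tree (`phylo`).
#' @param gene_trees Named list of `phylo` objects.
#' @return An object of class `tree_set`.
#' @export
tree_set <- function(master, gene_trees) {
  validate_phylo(master)
  if (is.null(names(gene_trees)) || any(names(gene_trees) == "")) {
    stop("gene_trees must be a named list", call. = FALSE)
  }
  for (g in names(gene_trees)) {
    tr <- gene_trees[[g]]
    validate_phylo(tr)
    tryCatch(
      branch_keys(tr, master),
      error = function(e) {
        stop("gene '", g, "': ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  structure(
    list(master = master, gene_trees = gene_trees),
    class = "tree_set"
  )
}

#' @export
print.tree_set <- function(x, ...) {
  cat(
    "<tree_set> master:", length(x$master$tip.label), "species;",
    length(x$gene_trees), "gene trees\n"
  )
  invisible(x)
}

#' Read a directory of newick trees as a tree set
#'
#' Expects `master.nwk` plus one `<gene_id>.nwk` per gene under `dir/trees/`
#' (or directly under `dir` if there is no `trees/` subdirectory).
#'
#' @param dir Study directory.
#' @return A `tree_set`.
#' @export
read_tree_dir <- function(dir) {
  master_path <- file.path(dir, "master.nwk")
  if (!file.exists(master_path)) stop("no master.nwk under ", dir, call. = FALSE)
  tree_dir <- if (dir.exists(file.path(dir, "trees"))) file.path(dir, "trees") else dir
  files <- list.files(tree_dir, pattern = "\\.nwk$", full.names = TRUE)
  files <- files[basename(files) != "master.nwk"]
  genes <- sub("\\.nwk$", "", basename(files))
  trees <- lapply(files, function(f) read_newick(file = f))
  names(trees) <- genes
  tree_set(read_newick(file = master_path), trees)
}
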