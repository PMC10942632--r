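#' Parse InterProScan-style TSV domain annotations
#'
#' Reads the standard headerless InterProScan TSV layout (protein accession,
#' sequence md5, sequence length, analysis, signature accession, signature
#' description, start, stop, score, status, date, ...).  Coordinates are
#' 1-based inclusive.  Rows failing basic coordinate sanity checks raise an
#' error naming the offending line.
#'
#' @param path TSV path.
#' @return Tibble with `protein_id`, `domain_id`, `start`, `stop`, `source`.
#'   Domain ids repeated within one protein are suffixed `.2`, `.3`, ... so
#'   they stay unique per protein.
#' @export
parse_interpro_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      protein_id = character(0), domain_id = character(0),
      start = integer(0), stop = integer(0), source = character(0)
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(f, lineno) {
    if (length(f) < 8) {
      stop("line ", lineno, ": expected at least 8 tab-separated fields", call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[[7]]))
    stop_ <- suppressWarnings(as.integer(f[[8]]))
    if (is.na(start) || is.na(stop_)) {
      stop("line ", lineno, ": non-integer coordinates", call. = FALSE)
    }
    if (start < 1 || start > stop_) {
      stop("line ", lineno, ": invalid interval [", start, ", ", stop_, "]", call. = FALSE)
    }
    len <- suppressWarnings(as.integer(f[[3]]))
    if (!is.na(len) && stop_ > len) {
      stop("line ", lineno, ": stop ", stop_, " exceeds protein length ", len, call. = FALSE)
    }
    tibble::tibble(
      protein_id = f[[1]], domain_id = f[[5]],
      start = start, stop = stop_, source = f[[4]]
    )
  }
  out <- purrr::imap_dfr(fields, parse_row)
  dplyr::mutate(
    dplyr::group_by(out, .data$protein_id, .data$domain_id),
    domain_id = if (dplyr::n() > 1) {
      paste0(.data$domain_id, c("", paste0(".", seq_len(dplyr::n() - 1) + 1)))
    } else {
      .data$domain_id
    }
  ) |> dplyr::ungroup()
}

#' Merge or keep overlapping domain intervals
#'
#' With `policy = "merge"`, overlapping (or touching) intervals on the same
#' protein are unioned into one domain whose id concatenates the originals;
#' with `"keep"` (the default elsewhere in the pipeline) annotations pass
#' through unchanged.
#'
#' @param annots Tibble as returned by [parse_interpro_tsv()].
#' @param policy `"keep"` or `"merge"`.
#' @return Tibble in the same shape.
#' @export
merge_overlaps <- function(annots, policy = c("keep", "merge")) {
  policy <- match.arg(policy)
  if (policy == "keep" || nrow(annots) == 0) return(annots)
  merge_one <- function(df) {
    df <- dplyr::arrange(df, .data$start, .data$stop)
    out <- df[0, ]
    cur <- df[1, ]
    ids <- cur$domain_id
    for (i in seq_len(nrow(df))[-1]) {
      row <- df[i, ]
      if (row$start <= cur$stop) {
        cur$stop <- max(cur$stop, row$stop)
        ids <- c(ids, row$domain_id)
      } else {
        cur$domain_id <- paste(ids, collapse = "+")
        out <- dplyr::bind_rows(out, cur)
        cur <- row
        ids <- row$domain_id
      }
    }
    cur$domain_id <- paste(ids, collapse = "+")
    dplyr::bind_rows(out, cur)
  }
  dplyr::group_modify(
    dplyr::group_by(annots, .data$protein_id),
    ~ merge_one(.x)
  ) |> dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(names(annots)))
}

#' Define a protein complex with domain decomposition and physical labels
#'
#' @param complex_id Identifier.
#' @param domains Tibble with `protein_id`, `domain_id` (domain ids must be
#'   globally unique here, e.g. `"P1:PF00001"`).
#' @param physical_domain_pairs Two-column data frame (or list of length-2
#'   vectors) of physically contacting domain pairs.
#' @param physical_protein_pairs Optional; defaults to the protein pairs
#'   implied by the domain pairs.  Every physical domain pair's proteins must
#'   form a physical protein pair.
#' @return Object of class `complex_def`.
#' @export
complex_definition <- function(complex_id, domains, physical_domain_pairs,
                               physical_protein_pairs = NULL) {
  stopifnot(all(c("protein_id", "domain_id") %in% names(domains)))
  if (anyDuplicated(domains$domain_id)) {
    stop("domain ids must be unique within a complex", call. = FALSE)
  }
  dom2prot <- stats::setNames(domains$protein_id, domains$domain_id)
  pd <- normalize_pairs(physical_domain_pairs)
  if (length(pd) == 0) stop("at least one physical domain pair is required", call. = FALSE)
  pd_dom <- strsplit(pd, "\r", fixed = TRUE)
  for (p in pd_dom) {
    if (!all(p %in% names(dom2prot))) {
      stop("physical domain pair references unknown domain: ",
        paste(setdiff(p, names(dom2prot)), collapse = ", "),
        call. = FALSE
      )
    }
    if (dom2prot[[p[1]]] == dom2prot[[p[2]]]) {
      stop("physical domain pair within one protein: ", p[1], " - ", p[2], call. = FALSE)
    }
  }
  implied_pp <- unique(vapply(
    pd_dom, function(p) pair_id(dom2prot[[p[1]]], dom2prot[[p[2]]]), character(1)
  ))
  if (is.null(physical_protein_pairs)) {
    pp <- implied_pp
  } else {
    pp <- unique(normalize_pairs(physical_protein_pairs))
    if (!all(implied_pp %in% pp)) {
      stop("a physical domain pair spans proteins not annotated as physically interacting",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      complex_id = complex_id,
      domains = tibble::as_tibble(domains[, c("protein_id", "domain_id")]),
      physical_domain_pairs = pd,
      physical_protein_pairs = pp
    ),
    class = "complex_def"
  )
}

#' @export
print.complex_def <- function(x, ...) {
  cat(
    "<complex_def>", x$complex_id, "-",
    length(unique(x$domains$protein_id)), "proteins (",
    nrow(x$domains), "domains ),",
    length(x$physical_domain_pairs), "physical domain pair(s)\n"
  )
  invisible(x)
}

#' Ranked domain-vs-domain ERC edge list for a complex
#'
#' Enumerates all inter-protein domain pairs of the complex (intra-protein
#' pairs are excluded by default: same-protein domains share trivial rate
#' structure and would dilute the negative class), attaches each pair's ftERC
#' and its physical label, and sorts by ftERC descending with a stable
#' `(ftERC desc, domain_a, domain_b)` tie-break.  Pairs filtered during ERC
#' computation (or absent from the edge list) are dropped and counted in the
#' `n_dropped` attribute.
#'
#' @param erc ERC edge list over domain ids.
#' @param cx A [complex_definition()].
#' @param include_intra_protein Also include same-protein domain pairs as
#'   negatives (default `FALSE`).
#' @return Tibble of class `domain_edges`: `domain_a`, `domain_b`,
#'   `protein_a`, `protein_b`, `ftERC`, `label` (1 physical / 0 not), with
#'   attributes `complex_id` and `n_dropped`.
#' @export
build_domain_edge_list <- function(erc, cx, include_intra_protein = FALSE) {
  stopifnot(inherits(cx, "complex_def"))
  doms <- cx$domains
  cmb <- utils::combn(nrow(doms), 2)
  a <- doms$domain_id[cmb[1, ]]
  b <- doms$domain_id[cmb[2, ]]
  pa <- doms$protein_id[cmb[1, ]]
  pb <- doms$protein_id[cmb[2, ]]
  if (!include_intra_protein) {
    inter <- pa != pb
    a <- a[inter]; b <- b[inter]; pa <- pa[inter]; pb <- pb[inter]
  }
  ids <- pair_id(a, b)
  erc_ok <- erc[is.na(erc$filter_reason), ]
  ft <- stats::setNames(erc_ok$ftERC, pair_id(erc_ok$gene_a, erc_ok$gene_b))
  vals <- unname(ft[ids])
  dropped <- is.na(vals)
  edges <- tibble::tibble(
    domain_a = a[!dropped], domain_b = b[!dropped],
    protein_a = pa[!dropped], protein_b = pb[!dropped],
    ftERC = vals[!dropped],
    label = as.integer(ids[!dropped] %in% cx$physical_domain_pairs)
  )
  n_pos <- sum(edges$label == 1)
  n_neg <- sum(edges$label == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop(
      "degenerate complex '", cx$complex_id, "': needs at least one physical and one ",
      "non-physical domain pair with ERC values (has ", n_pos, " / ", n_neg, ")",
      call. = FALSE
    )
  }
  edges <- dplyr::arrange(edges, dplyr::desc(.data$ftERC), .data$domain_a, .data$domain_b)
  attr(edges, "complex_id") <- cx$complex_id
  attr(edges, "n_dropped") <- sum(dropped)
  class(edges) <- c("domain_edges", class(edges))
  edges
}
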