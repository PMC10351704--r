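## Rooted, ranked taxonomy: the container behind taxonomic binning and the
## synthetic community generator. Stored as a plain node table plus
## precomputed depth; all queries are parent-pointer walks.

TAX_RANKS <- c("root", "domain", "phylum", "class", "order",
               "family", "genus", "species")

#' Construct a ranked taxonomy tree
#'
#' Builds the rooted, ranked tree used for weighted-LCA binning and for
#' structuring synthetic communities. Nodes carry an opaque `taxon_id`, a
#' parent pointer, one of the eight canonical ranks (root, domain, phylum,
#' class, order, family, genus, species) and a display name.
#'
#' @param nodes data.frame with columns `taxon_id`, `parent_id` (NA for the
#'   root), `rank`, `name`.
#' @return An object of class `taxonomy_tree`.
#' @details Invariants enforced: exactly one root; every non-root parent
#'   exists; no cycles; rank strictly deepens along every root-to-node path.
#' @seealso [build_taxonomy()], [weighted_lca()]
#' @export
taxonomy_tree <- function(nodes) {
  req <- c("taxon_id", "parent_id", "rank", "name")
  if (!is.data.frame(nodes) || !all(req %in% names(nodes)))
    stop_arg("nodes must be a data.frame with columns ",
             paste(req, collapse = ", "))
  nodes <- as.data.frame(nodes[req], stringsAsFactors = FALSE)
  nodes$taxon_id <- as.character(nodes$taxon_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$rank <- as.character(nodes$rank)
  if (anyDuplicated(nodes$taxon_id))
    stop_arg("duplicate taxon_id in taxonomy")
  if (!all(nodes$rank %in% TAX_RANKS))
    stop_arg("unknown rank(s): ",
             paste(setdiff(nodes$rank, TAX_RANKS), collapse = ", "))
  is_root <- is.na(nodes$parent_id)
  if (sum(is_root) != 1L) stop_arg("taxonomy must have exactly one root")
  if (nodes$rank[is_root] != "root") stop_arg("root node must have rank 'root'")
  idx <- match(nodes$parent_id, nodes$taxon_id)
  if (any(is.na(idx) & !is_root)) stop_arg("parent_id not found for some nodes")

  ## depth by pointer walking also proves acyclicity
  n <- nrow(nodes)
  depth <- rep(NA_integer_, n)
  depth[is_root] <- 0L
  for (i in seq_len(n)) {
    if (!is.na(depth[i])) next
    path <- i
    j <- i
    while (is.na(depth[j])) {
      j <- idx[j]
      if (j %in% path || length(path) > n) stop_arg("cycle in taxonomy")
      path <- c(path, j)
    }
    d <- depth[j]
    for (k in rev(seq_len(length(path) - 1L)))
      depth[path[k]] <- (d <- d + 1L)
  }
  rk <- match(nodes$rank, TAX_RANKS)
  bad <- which(!is_root & rk <= match(nodes$rank[idx], TAX_RANKS))
  if (length(bad))
    stop_arg("rank must deepen from parent to child (offending: ",
             paste(utils::head(nodes$taxon_id[bad], 3L), collapse = ", "), ")")
  structure(
    list(nodes = nodes, depth = depth,
         parent = stats::setNames(nodes$parent_id, nodes$taxon_id),
         rank = stats::setNames(nodes$rank, nodes$taxon_id)),
    class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", nrow(x$nodes), "nodes,",
      sum(x$rank == "species"), "species\n")
  invisible(x)
}

tax_exists <- function(tree, id) id %in% names(tree$parent)

#' Root-to-taxon lineage
#'
#' @param tree a [taxonomy_tree()]
#' @param taxon_id node id
#' @return Character vector of taxon ids from the root down to `taxon_id`.
#' @export
tax_lineage <- function(tree, taxon_id) {
  if (!tax_exists(tree, taxon_id)) stop_arg("unknown taxon: ", taxon_id)
  out <- character(0)
  id <- taxon_id
  while (!is.na(id)) {
    out <- c(id, out)
    id <- tree$parent[[id]]
  }
  out
}

#' Ancestor of a taxon at a given rank
#'
#' @inheritParams tax_lineage
#' @param rank one of the eight canonical ranks
#' @return The ancestor's taxon id, `taxon_id` itself when already at `rank`,
#'   or `NA` when the node is shallower than `rank`.
#' @export
tax_ancestor_at_rank <- function(tree, taxon_id, rank) {
  if (!rank %in% TAX_RANKS) stop_arg("unknown rank: ", rank)
  lin <- tax_lineage(tree, taxon_id)
  hit <- lin[tree$rank[lin] == rank]
  if (length(hit)) hit else NA_character_
}

#' Lowest common ancestor of a set of taxa
#'
#' @inheritParams tax_lineage
#' @param taxon_ids character vector of node ids
#' @return The deepest taxon id ancestral to (or equal to) all inputs.
#' @export
tax_lca <- function(tree, taxon_ids) {
  taxon_ids <- unique(taxon_ids)
  if (!length(taxon_ids)) stop_arg("need at least one taxon")
  lin <- tax_lineage(tree, taxon_ids[1L])
  for (id in taxon_ids[-1L]) {
    l2 <- tax_lineage(tree, id)
    m <- min(length(lin), length(l2))
    eq <- which(lin[seq_len(m)] == l2[seq_len(m)])
    lin <- lin[seq_len(max(eq))]
  }
  lin[length(lin)]
}

#' Species leaves of a taxonomy
#'
#' @inheritParams tax_lineage
#' @return Character vector of species-rank taxon ids.
#' @export
tax_species <- function(tree) {
  tree$nodes$taxon_id[tree$nodes$rank == "species"]
}

#' Generate a balanced ranked taxonomy
#'
#' Deterministically lays out one domain holding `n_phyla` phylum subtrees,
#' each branching `children_per_node`-fold at every rank down to species.
#' The `seed` participates only in name generation and is recorded so a
#' fixture's provenance is reproducible; the topology is a function of the
#' size arguments alone.
#'
#' @param seed integer; recorded, and kept for signature symmetry with the
#'   stochastic generators.
#' @param n_phyla number of phylum subtrees (>= 1)
#' @param children_per_node branching factor below phylum (>= 1)
#' @return A [taxonomy_tree()]. With `n_phyla = 1, children_per_node = 1` this
#'   is the 8-node root-to-species path.
#' @examples
#' tr <- build_taxonomy(1, n_phyla = 2, children_per_node = 2)
#' length(tax_species(tr))
#' @export
build_taxonomy <- function(seed = 1L, n_phyla = 3L, children_per_node = 2L) {
  check_number(n_phyla, "n_phyla", min = 1)
  check_number(children_per_node, "children_per_node", min = 1)
  n_phyla <- as.integer(n_phyla)
  k <- as.integer(children_per_node)
  rows <- list(
    data.frame(taxon_id = "r", parent_id = NA_character_, rank = "root",
               name = "root", stringsAsFactors = FALSE),
    data.frame(taxon_id = "d1", parent_id = "r", rank = "domain",
               name = "Bacteria", stringsAsFactors = FALSE))
  prev <- data.frame(taxon_id = paste0("p", seq_len(n_phyla)),
                     parent_id = "d1", rank = "phylum",
                     name = paste0("Phylum_", seq_len(n_phyla)),
                     stringsAsFactors = FALSE)
  rows <- c(rows, list(prev))
  abbrev <- c(class = "c", order = "o", family = "f",
              genus = "g", species = "s")
  for (rank in names(abbrev)) {
    parent <- rep(prev$taxon_id, each = k)
    id <- paste0(parent, ".", abbrev[[rank]], rep(seq_len(k), length(prev$taxon_id)))
    prev <- data.frame(taxon_id = id, parent_id = parent, rank = rank,
                       name = paste0(toupper(abbrev[[rank]]), "_", id),
                       stringsAsFactors = FALSE)
    rows <- c(rows, list(prev))
  }
  tree <- taxonomy_tree(do.call(rbind, rows))
  attr(tree, "seed") <- as.integer(seed)
  tree
}

#' Write / read a taxonomy as TSV
#'
#' Four tab-separated columns: `taxon_id`, `parent_id` (empty for the root),
#' `rank`, `name`.
#'
#' @param tree a [taxonomy_tree()]
#' @param path output file
#' @return `write_taxonomy` returns `path` invisibly; `read_taxonomy` returns
#'   a [taxonomy_tree()].
#' @export
write_taxonomy <- function(tree, path) {
  df <- tree$nodes
  df$parent_id[is.na(df$parent_id)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  df$parent_id[df$parent_id == ""] <- NA_character_
  taxonomy_tree(df)
}

#' Export a taxonomy as a Newick string
#'
#' @inheritParams tax_lineage
#' @param path optional file; when given the string is written there.
#' @return The Newick string (invisibly when `path` is given).
#' @export
tax_newick <- function(tree, path = NULL) {
  kids <- split(tree$nodes$taxon_id[!is.na(tree$nodes$parent_id)],
                tree$nodes$parent_id[!is.na(tree$nodes$parent_id)])
  rec <- function(id) {
    ch <- kids[[id]]
    if (is.null(ch)) return(id)
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")", id)
  }
  root <- tree$nodes$taxon_id[is.na(tree$nodes$parent_id)]
  s <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
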