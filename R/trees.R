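# Tree I/O and indexing: a rooted species tree with one WGD-annotated
# branch, and rooted binary gene trees with (species, gene) leaf labels.

#' Construct a WGD-annotated species tree
#'
#' @param phy A rooted `ape::phylo` object (polytomies allowed).
#' @param wgd Either the internal node number at the child end of the WGD
#'   branch, or a character vector of species whose most recent common
#'   ancestor sits at the child end of the WGD branch.
#' @return An object of class `species_tree_wgd` wrapping the tree, with
#'   `wgd_node` (node number below the WGD branch). The WGD branch itself is
#'   the edge ending in `wgd_node`; all species descending from `wgd_node`
#'   carry the duplication.
#' @export
species_tree_wgd <- function(phy, wgd) {
  assert_that(inherits(phy, "phylo"), "phy must be an ape phylo tree")
  assert_that(ape::is.rooted(phy), "species tree must be rooted")
  if (is.character(wgd)) {
    miss <- setdiff(wgd, phy$tip.label)
    if (length(miss) > 0)
      stop2("WGD clade species not in tree: ", paste(miss, collapse = ", "))
    wgd <- if (length(wgd) == 1) match(wgd, phy$tip.label)
           else ape::getMRCA(phy, wgd)
  }
  wgd <- as.integer(wgd)
  assert_that(length(wgd) == 1 && wgd >= 1 &&
                wgd <= ape::Ntip(phy) + phy$Nnode,
              "wgd must name one node of the tree")
  assert_that(wgd != ape::Ntip(phy) + 1L,
              "the WGD branch cannot be above the root")
  structure(list(phy = phy, wgd_node = wgd), class = "species_tree_wgd")
}

#' @export
print.species_tree_wgd <- function(x, ...) {
  cat(sprintf("<species_tree_wgd> %d species; WGD branch above node %d (%s)\n",
              ape::Ntip(x$phy), x$wgd_node,
              paste(clade_species(x, x$wgd_node), collapse = ",")))
  invisible(x)
}

#' Species descending from a species-tree node
#' @param st A [species_tree_wgd()].
#' @param node Node number (tip or internal).
#' @export
clade_species <- function(st, node) {
  phy <- st$phy
  if (node <= ape::Ntip(phy)) return(phy$tip.label[node])
  kids <- phangorn_free_descendants(phy, node)
  phy$tip.label[kids]
}

# Tip numbers below an internal node (iterative stack; no phangorn dep).
phangorn_free_descendants <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  out <- integer(0)
  stack <- node
  children <- split(phy$edge[, 2], phy$edge[, 1])
  while (length(stack) > 0) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= ntip) out <- c(out, v)
    else stack <- c(stack, children[[as.character(v)]])
  }
  sort(out)
}

#' Read a Newick tree (species tree or gene tree)
#'
#' A species tree is recognized by an internal-node label containing
#' `wgd_token` (the WGD-branch mark); the token labels the node at the child
#' end of the WGD branch. A gene tree is recognized by `|` in every tip
#' label (`species|gene`), and must be rooted and fully binary.
#'
#' @param path Newick file.
#' @param wgd_token Label token marking the WGD branch (default `"WGD"`).
#' @return A `species_tree_wgd` or a `phylo` gene tree (class
#'   `c("gene_tree", "phylo")`).
#' @export
read_tree <- function(path, wgd_token = "WGD") {
  phy <- ape::read.tree(path)
  assert_that(inherits(phy, "phylo"), "file must contain a single Newick tree")
  if (!is.null(phy$node.label) && any(grepl(wgd_token, phy$node.label, fixed = TRUE))) {
    hit <- which(grepl(wgd_token, phy$node.label, fixed = TRUE))
    if (length(hit) > 1) stop2("exactly one WGD branch is allowed per analysis")
    return(species_tree_wgd(phy, ape::Ntip(phy) + hit))
  }
  if (all(grepl("|", phy$tip.label, fixed = TRUE)))
    return(as_gene_tree(phy))
  stop2("tree is neither WGD-annotated (no '", wgd_token,
        "' node label) nor a gene tree (tips lack 'species|gene' labels)")
}

#' Validate and class a gene tree
#'
#' @param phy Rooted binary `phylo`; tips labelled `species|gene`.
#' @export
as_gene_tree <- function(phy) {
  assert_that(inherits(phy, "phylo"), "gene tree must be an ape phylo object")
  assert_that(ape::is.rooted(phy), "gene tree must be rooted")
  if (ape::Ntip(phy) > 1 && !ape::is.binary(phy))
    stop2("gene tree must be fully binary (no polytomies)")
  if (anyDuplicated(phy$tip.label))
    stop2("duplicate gene-tree leaf labels")
  if (!all(grepl("|", phy$tip.label, fixed = TRUE)))
    stop2("gene-tree tips must be labelled 'species|gene'")
  class(phy) <- c("gene_tree", "phylo")
  phy
}

#' Write a tree to Newick
#'
#' Round-trips with [read_tree()] up to whitespace: the WGD token is kept in
#' the node label of a species tree.
#' @param tree `species_tree_wgd` or `phylo`.
#' @param path Output file.
#' @param wgd_token Token written on the WGD node of a species tree.
#' @export
write_tree <- function(tree, path, wgd_token = "WGD") {
  if (inherits(tree, "species_tree_wgd")) {
    phy <- tree$phy
    nlab <- phy$node.label %||% rep("", phy$Nnode)
    idx <- tree$wgd_node - ape::Ntip(phy)
    if (!grepl(wgd_token, nlab[idx], fixed = TRUE)) nlab[idx] <- wgd_token
    phy$node.label <- nlab
    ape::write.tree(phy, file = path)
  } else {
    ape::write.tree(tree, file = path)
  }
  invisible(path)
}

#' Species and gene ids from gene-tree tip labels
#' @param labels Character vector of `species|gene` labels.
#' @return Data frame with columns `species_id`, `gene_id`.
#' @export
split_leaf_labels <- function(labels) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop2("malformed leaf label(s): ",
                      paste(labels[bad], collapse = ", "))
  data.frame(species_id = vapply(parts, `[`, "", 1),
             gene_id = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
}

# --- species-tree index used by reconciliation, Dollo mapping, simulation ---

# Precomputes parent pointers, ancestor paths (self -> root), per-node leaf
# sets and node depths for O(1)-ish LCA queries.
index_species_tree <- function(st) {
  phy <- st$phy
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  parent <- integer(nnode); parent[] <- NA_integer_
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ntip + 1L
  depth <- integer(nnode)
  # ape guarantees parents precede children in a preorder of node numbers
  # only for cladewise ordering; compute depths by walking parents.
  anc <- vector("list", nnode)
  for (v in seq_len(nnode)) {
    path <- v
    p <- parent[v]
    while (!is.na(p)) { path <- c(path, p); p <- parent[p] }
    anc[[v]] <- path
    depth[v] <- length(path) - 1L
  }
  leaves <- vector("list", nnode)
  for (v in seq_len(nnode))
    leaves[[v]] <- if (v <= ntip) v else phangorn_free_descendants(phy, v)
  list(phy = phy, ntip = ntip, nnode = nnode, root = root, parent = parent,
       depth = depth, ancestors = anc, leaves = leaves,
       tip_of = stats::setNames(seq_len(ntip), phy$tip.label),
       wgd_node = st$wgd_node)
}

# LCA of a set of node numbers under a species-tree index.
st_lca <- function(ix, nodes) {
  nodes <- unique(nodes)
  if (length(nodes) == 1) return(nodes)
  cand <- ix$ancestors[[nodes[1]]]
  for (v in nodes[-1]) cand <- cand[cand %in% ix$ancestors[[v]]]
  cand[1]
}

# TRUE if node a equals or is an ancestor of node b.
st_is_ancestor <- function(ix, a, b) a %in% ix$ancestors[[b]]
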