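# Core inference: classify each family's duplication history into
# ohnologue / ancient tandem / recent tandem / single-copy categories by
# combining gene-tree/species-tree reconciliation (the primary, timing
# criterion) with chromosomal linkage (the secondary criterion), and map
# ohnologue losses onto the species tree by Dollo parsimony.

#' Classify the linkage relation of two genes
#'
#' Genes on different chromosomes are `dispersed`; on one chromosome they
#' are `linked`, and additionally `clustered` when at most
#' `max_cluster_gap_genes` genes intervene and the intergenic distance
#' (downstream start minus upstream end) is at most `max_cluster_gap_bp`.
#'
#' @param gene_a,gene_b Gene ids (distinct) of one species.
#' @param genome The species' [species_genome()].
#' @param max_cluster_gap_genes,max_cluster_gap_bp Clustering bounds
#'   (defaults 10 genes, 1 Mb).
#' @return List: `relation` (`clustered`/`linked`/`dispersed`),
#'   `intervening_gene_count`, `distance_bp` (NA when dispersed).
#' @export
classify_linkage <- function(gene_a, gene_b, genome,
                             max_cluster_gap_genes = 10,
                             max_cluster_gap_bp = 1e6) {
  assert_that(!identical(gene_a, gene_b), "the two genes must differ")
  g <- genome$genes
  ra <- g[g$gene_id == gene_a, , drop = FALSE]
  rb <- g[g$gene_id == gene_b, , drop = FALSE]
  assert_that(nrow(ra) == 1 && nrow(rb) == 1, "genes not found in genome")
  if (ra$chromosome_id != rb$chromosome_id)
    return(list(relation = "dispersed", intervening_gene_count = NA_integer_,
                distance_bp = NA_integer_))
  on_chr <- g[g$chromosome_id == ra$chromosome_id, , drop = FALSE]
  ia <- which(on_chr$gene_id == gene_a)
  ib <- which(on_chr$gene_id == gene_b)
  n_between <- abs(ia - ib) - 1L
  dist <- intergenic_distance(ra, rb)
  clustered <- n_between <= max_cluster_gap_genes && dist <= max_cluster_gap_bp
  list(relation = if (clustered) "clustered" else "linked",
       intervening_gene_count = n_between, distance_bp = dist)
}

# Precomputed per-species lookup for fast linkage queries (genes are
# stored sorted by chromosome then start, so within-chromosome rank is a
# running index).
linkage_index <- function(genomes) {
  lapply(genomes, function(g) {
    gg <- g$genes
    rank_in_chr <- stats::ave(seq_len(nrow(gg)), gg$chromosome_id,
                              FUN = seq_along)
    list(chr = stats::setNames(gg$chromosome_id, gg$gene_id),
         rank = stats::setNames(rank_in_chr, gg$gene_id),
         start = stats::setNames(gg$start, gg$gene_id),
         end = stats::setNames(gg$end, gg$gene_id))
  })
}

linkage_relation_fast <- function(ixsp, a, b, gap_genes, gap_bp) {
  if (ixsp$chr[[a]] != ixsp$chr[[b]]) return("dispersed")
  n_between <- abs(ixsp$rank[[a]] - ixsp$rank[[b]]) - 1L
  dist <- if (ixsp$start[[a]] <= ixsp$start[[b]])
    ixsp$start[[b]] - ixsp$end[[a]] else ixsp$start[[a]] - ixsp$end[[b]]
  if (n_between <= gap_genes && dist <= gap_bp) "clustered" else "linked"
}

#' Reconcile a gene tree with the species tree (LCA mapping)
#'
#' Each gene-tree node maps to the most recent common ancestor of its
#' leaves' species. A node is a duplication when its mapping equals the
#' mapping of one of its children; otherwise it is a speciation. A
#' duplication mapping to the node at the child end of the WGD branch is
#' tagged WGD-compatible.
#'
#' @param gene_tree A rooted binary gene tree (`species|gene` tips).
#' @param species_tree A [species_tree_wgd()].
#' @return Data frame, one row per gene-tree node (tips included):
#'   `node`, `is_leaf`, `type` (`speciation`/`duplication`/`leaf`),
#'   `mapped_node`, `mapped_species` (label of the mapped species-tree
#'   node), `wgd_compatible`.
#' @export
reconcile <- function(gene_tree, species_tree) {
  ix <- index_species_tree(species_tree)
  gt <- gene_tree
  ntip <- ape::Ntip(gt)
  nn <- ntip + gt$Nnode
  leaves <- split_leaf_labels(gt$tip.label)
  miss <- setdiff(leaves$species_id, ix$phy$tip.label)
  if (length(miss) > 0)
    stop2("gene-tree species not in species tree: ",
          paste(unique(miss), collapse = ", "))
  map <- integer(nn)
  map[seq_len(ntip)] <- unname(ix$tip_of[leaves$species_id])
  kids <- split(gt$edge[, 2], gt$edge[, 1])
  is_dup <- rep(NA, nn)
  # postorder edge ordering lists every child edge before its parent edge,
  # so first appearance of each internal node is deepest-first
  ord <- unique(ape::reorder.phylo(gt, "postorder")$edge[, 1])
  for (v in ord) {
    ch <- kids[[as.character(v)]]
    map[v] <- st_lca(ix, map[ch])
    is_dup[v] <- any(map[ch] == map[v])
  }
  lab <- function(s) {
    if (s <= ix$ntip) ix$phy$tip.label[s]
    else {
      l <- if (!is.null(ix$phy$node.label)) ix$phy$node.label[s - ix$ntip] else ""
      if (!is.na(l) && nzchar(l)) l else paste0("n", s)
    }
  }
  data.frame(
    node = seq_len(nn), is_leaf = seq_len(nn) <= ntip,
    type = ifelse(seq_len(nn) <= ntip, "leaf",
                  ifelse(is_dup, "duplication", "speciation")),
    mapped_node = map,
    mapped_species = vapply(map, lab, ""),
    wgd_compatible = !is.na(is_dup) & is_dup & map == ix$wgd_node,
    stringsAsFactors = FALSE)
}

# Tip indices (gene-tree) below each node, as a list.
gt_leafsets <- function(gt) {
  ntip <- ape::Ntip(gt)
  nn <- ntip + gt$Nnode
  out <- vector("list", nn)
  for (i in seq_len(ntip)) out[[i]] <- i
  ord <- unique(ape::reorder.phylo(gt, "postorder")$edge[, 1])
  kids <- split(gt$edge[, 2], gt$edge[, 1])
  for (v in ord) out[[v]] <- sort(unlist(out[kids[[as.character(v)]]]))
  out
}

#' Classify one family's duplication history
#'
#' Combines the reconciliation of the family's gene tree with per-species
#' linkage of paralogue pairs. Duplication nodes mapping strictly above the
#' WGD node are pre-WGD (ancient tandem candidates); nodes mapping to the
#' WGD node are the WGD itself, unless both their children already contain
#' WGD-mapped duplications (then the upper node must predate the single
#' WGD and is treated as pre-WGD) or an ancestral node was already
#' designated the WGD (then they are post-WGD); all other duplications are
#' post-WGD/outgroup (recent tandem candidates). Where the majority linkage
#' relation contradicts the reconciliation timing, the reconciliation wins
#' and a conflict is recorded. Pseudogene leaves are pruned first.
#'
#' @param family_id Family to classify.
#' @param genomes Named list of [species_genome()] with family assignments.
#' @param gene_tree The family's gene tree, or `NULL` when fewer than two
#'   genes survive.
#' @param species_tree A [species_tree_wgd()].
#' @param clades Named species sets for loss refinement (default: resolved
#'   from species-tree node labels, see [resolve_clades()]).
#' @param majority_fraction Fraction of species votes required to call a
#'   majority linkage relation (default 0.7).
#' @param max_cluster_gap_genes,max_cluster_gap_bp Passed to
#'   [classify_linkage()].
#' @return A `family_call` list: `family_id`, `category` (`O`, `AT`, `RT`,
#'   `SC`, `SOL`, `EOL`, `LOSS_other`, `EXTINCT`), `duplication_branch`,
#'   `copy_counts`, and an `evidence` list (per-duplication-node linkage
#'   votes, conflicts, WGD lineage membership, Dollo loss branches).
#' @export
classify_family <- function(family_id, genomes, gene_tree, species_tree,
                            clades = resolve_clades(species_tree),
                            majority_fraction = 0.7,
                            max_cluster_gap_genes = 10,
                            max_cluster_gap_bp = 1e6,
                            linkage_ix = linkage_index(genomes)) {
  ix <- index_species_tree(species_tree)
  wgd_species <- clade_species(species_tree, species_tree$wgd_node)
  fam_genes <- do.call(rbind, lapply(genomes, function(g)
    g$genes[g$genes$family_id == family_id, , drop = FALSE]))
  if (!is.null(fam_genes)) rownames(fam_genes) <- NULL
  live <- fam_genes[!fam_genes$pseudogene, , drop = FALSE]
  copy_counts <- table(factor(live$species_id, levels = ix$phy$tip.label))
  present_wgd <- any(live$species_id %in% wgd_species)
  extant <- nrow(live) > 0

  finish <- function(category, duplication_branch, evidence) {
    structure(list(family_id = family_id, category = category,
                   duplication_branch = duplication_branch,
                   copy_counts = copy_counts, evidence = evidence),
              class = "family_call")
  }

  # prune pseudogene leaves (gene ids recur across species: match both)
  gt <- gene_tree
  if (!is.null(gt)) {
    pseudo_keys <- paste(fam_genes$species_id[fam_genes$pseudogene],
                         fam_genes$gene_id[fam_genes$pseudogene])
    lv <- split_leaf_labels(gt$tip.label)
    drop <- gt$tip.label[paste(lv$species_id, lv$gene_id) %in% pseudo_keys]
    if (length(drop) > 0 && ape::Ntip(gt) - length(drop) >= 2)
      gt <- as_gene_tree(ape::drop.tip(gt, drop))
    else if (length(drop) > 0) gt <- NULL
  }
  if (is.null(gt) || ape::Ntip(gt) < 2) {
    cat_ <- combine_family_category(FALSE, character(), FALSE, present_wgd,
                                    extant)
    return(finish(cat_, NA_character_, list(n_dup_nodes = 0L)))
  }

  rec <- reconcile(gt, species_tree)
  leafsets <- gt_leafsets(gt)
  leaf_sp <- split_leaf_labels(gt$tip.label)
  kids <- split(gt$edge[, 2], gt$edge[, 1])
  dup_nodes <- rec$node[rec$type == "duplication"]
  crown <- ix$wgd_node

  # linkage vote per duplication node: one vote per species carrying genes
  # from both child lineages
  node_linkage <- function(v) {
    ch <- kids[[as.character(v)]]
    la <- leafsets[[ch[1]]]; lb <- leafsets[[ch[2]]]
    votes <- character()
    for (sp in intersect(leaf_sp$species_id[la], leaf_sp$species_id[lb])) {
      ga <- leaf_sp$gene_id[la][leaf_sp$species_id[la] == sp]
      gb <- leaf_sp$gene_id[lb][leaf_sp$species_id[lb] == sp]
      rels <- character()
      for (x in ga) for (y in gb)
        rels <- c(rels, linkage_relation_fast(linkage_ix[[sp]], x, y,
                                              max_cluster_gap_genes,
                                              max_cluster_gap_bp))
      votes[sp] <- if ("clustered" %in% rels) "clustered"
                   else if ("linked" %in% rels) "linked" else "dispersed"
    }
    if (length(votes) == 0) return("none")
    fr_disp <- mean(votes == "dispersed")
    fr_link <- mean(votes != "dispersed")
    if (fr_disp >= majority_fraction) "dispersed"
    else if (fr_link >= majority_fraction) {
      if (sum(votes == "clustered") >= sum(votes == "linked")) "clustered"
      else "linked"
    } else "mixed"
  }

  # designate duplication nodes: pre / wgd / post
  crown_dups <- dup_nodes[rec$mapped_node[dup_nodes] == crown]
  # a node u is below v iff its leafset is a strict subset of v's
  below <- function(u, v) u != v && all(leafsets[[u]] %in% leafsets[[v]])
  designation <- stats::setNames(rep(NA_character_, length(dup_nodes)),
                                 dup_nodes)
  # preorder over dup nodes (largest leafset first)
  dup_ord <- dup_nodes[order(-lengths(leafsets[dup_nodes]))]
  wgd_designated <- integer(0)
  for (v in dup_ord) {
    mv <- rec$mapped_node[v]
    if (mv == crown) {
      ch <- kids[[as.character(v)]]
      nested <- vapply(ch, function(c_) any(vapply(crown_dups, function(u)
        u == c_ || below(u, c_), TRUE)), TRUE)
      if (all(nested)) designation[as.character(v)] <- "pre"
      else if (any(vapply(wgd_designated, function(u) below(v, u), TRUE)))
        designation[as.character(v)] <- "post"
      else {
        designation[as.character(v)] <- "wgd"
        wgd_designated <- c(wgd_designated, v)
      }
    } else if (mv != crown && st_is_ancestor(ix, mv, crown)) {
      designation[as.character(v)] <- "pre"
    } else {
      designation[as.character(v)] <- "post"
    }
  }

  linkage <- stats::setNames(vapply(dup_nodes, node_linkage, ""), dup_nodes)
  conflicts <- character()
  for (v in dup_nodes) {
    d <- designation[as.character(v)]
    l <- linkage[as.character(v)]
    if (d == "wgd" && l %in% c("clustered", "linked"))
      conflicts <- c(conflicts, sprintf("node %d: WGD-compatible but %s", v, l))
    if (d %in% c("pre", "post") && l == "dispersed")
      conflicts <- c(conflicts, sprintf("node %d: %s-WGD but dispersed", v, d))
  }

  # WGD lineages and their Dollo loss placements
  pair_labs <- character()
  lineages <- list()
  loss_branches <- character()
  for (v in wgd_designated) {
    ch <- kids[[as.character(v)]]
    pres_a <- unique(leaf_sp$species_id[leafsets[[ch[1]]]])
    pres_b <- unique(leaf_sp$species_id[leafsets[[ch[2]]]])
    sa <- lineage_status(pres_a, clades, wgd_species)
    sb <- lineage_status(pres_b, clades, wgd_species)
    pair_labs <- c(pair_labs, pair_category(pres_a, pres_b, ix, clades,
                                            wgd_species))
    lineages[[length(lineages) + 1L]] <- list(
      node = v,
      a = leaf_sp$gene_id[leafsets[[ch[1]]]],
      b = leaf_sp$gene_id[leafsets[[ch[2]]]],
      species_a = pres_a, species_b = pres_b,
      status_a = sa, status_b = sb)
    for (pres in list(pres_a, pres_b))
      loss_branches <- c(loss_branches,
                         dollo_losses(pres, species_tree, crown)$branches)
  }

  has_at <- any(designation == "pre")
  has_rt <- any(designation == "post")
  category <- combine_family_category(has_at, pair_labs, has_rt, present_wgd,
                                      extant)
  branch_lab <- function(v) rec$mapped_species[match(v, rec$node)]
  dup_branch <- switch(category,
    O = , SOL = , EOL = "WGD",
    AT = branch_lab(dup_nodes[designation == "pre"][1]),
    RT = branch_lab(dup_nodes[designation == "post"][1]),
    NA_character_)
  finish(category, dup_branch,
         list(n_dup_nodes = length(dup_nodes),
              designation = designation, linkage = linkage,
              conflicts = conflicts, wgd_lineages = lineages,
              loss_branches = unique(loss_branches)))
}

#' @export
print.family_call <- function(x, ...) {
  cat(sprintf("<family_call> %s: %s (branch %s; %d genes)\n", x$family_id,
              x$category, x$duplication_branch %||% "NA",
              sum(x$copy_counts)))
  invisible(x)
}

#' Dollo-parsimony loss placement for one presence pattern
#'
#' Assuming a single gain at `gain_node` (the WGD), finds the minimum
#' number of losses explaining the presence/absence pattern over the
#' species below the gain: one loss on every branch whose subtree contains
#' no present species while its parent's does.
#'
#' @param present_species Species with the character present.
#' @param species_tree A [species_tree_wgd()].
#' @param gain_node Node under which the character was gained (default the
#'   WGD node).
#' @return List: `n_losses`, `branches` (labels of loss-branch child
#'   nodes).
#' @export
dollo_losses <- function(present_species, species_tree,
                         gain_node = species_tree$wgd_node) {
  ix <- index_species_tree(species_tree)
  sub_tips <- ix$leaves[[gain_node]]
  pres_tips <- unname(ix$tip_of[intersect(present_species,
                                          ix$phy$tip.label[sub_tips])])
  state <- vapply(seq_len(ix$nnode), function(v)
    any(ix$leaves[[v]] %in% pres_tips), TRUE)
  if (!state[gain_node])
    return(list(n_losses = 1L, branches = node_label_of(ix, gain_node)))
  losses <- character()
  for (e in seq_len(nrow(ix$phy$edge))) {
    u <- ix$phy$edge[e, 1]; v <- ix$phy$edge[e, 2]
    if (!st_is_ancestor(ix, gain_node, u)) next  # edge outside the gain clade
    if (state[u] && !state[v]) losses <- c(losses, node_label_of(ix, v))
  }
  list(n_losses = length(losses), branches = unique(losses))
}

node_label_of <- function(ix, v) {
  if (v <= ix$ntip) return(ix$phy$tip.label[v])
  l <- if (!is.null(ix$phy$node.label)) ix$phy$node.label[v - ix$ntip] else ""
  if (!is.na(l) && nzchar(l)) l else paste0("n", v)
}

#' Infer ohnologue losses from a presence matrix
#'
#' Applies Dollo parsimony (single gain at the WGD, multiple losses) to
#' each row of a family-by-species presence matrix and refines the loss
#' pattern into stem-loss categories: `SOL` when the character is absent
#' from every spider but present elsewhere in the WGD clade, `EOL` when
#' absent from every entelegyne but present in a non-entelegyne spider,
#' otherwise `none` (no losses) or `LOSS_other`.
#'
#' @param presence Matrix or data frame (families x species) of copy
#'   counts or logical presence.
#' @param species_tree A [species_tree_wgd()].
#' @param clades Named clade species sets (see [resolve_clades()]).
#' @return Data frame: `family_id`, `n_losses`, `branches`
#'   (semicolon-joined), `pattern`.
#' @export
infer_losses <- function(presence, species_tree,
                         clades = resolve_clades(species_tree)) {
  m <- as.matrix(presence) > 0
  wgd_species <- clade_species(species_tree, species_tree$wgd_node)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    pres <- colnames(m)[m[i, ]]
    dl <- dollo_losses(pres, species_tree)
    status <- lineage_status(pres, clades, wgd_species)
    pattern <- if (dl$n_losses == 0) "none"
               else if (status %in% c("SOL", "EOL")) status else "LOSS_other"
    data.frame(family_id = rownames(m)[i] %||% as.character(i),
               n_losses = dl$n_losses,
               branches = paste(dl$branches, collapse = ";"),
               pattern = pattern, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify every family of a multi-species dataset
#'
#' @param genomes Named list of [species_genome()] with family assignments.
#' @param gene_trees Named list (by family) of gene trees (`NULL` entries
#'   allowed).
#' @param species_tree A [species_tree_wgd()].
#' @param ... Passed to [classify_family()].
#' @return Data frame of calls (one row per family) with the per-call
#'   `family_call` objects in the `calls` attribute.
#' @export
classify_all_families <- function(genomes, gene_trees, species_tree, ...) {
  fams <- c_sort(unique(unlist(lapply(genomes, function(g)
    setdiff(g$genes$family_id, "UNASSIGNED")))))
  lk <- linkage_index(genomes)
  calls <- lapply(stats::setNames(fams, fams), function(f)
    classify_family(f, genomes, gene_trees[[f]], species_tree,
                    linkage_ix = lk, ...))
  df <- do.call(rbind, lapply(calls, function(cl)
    data.frame(family_id = cl$family_id, category = cl$category,
               duplication_branch = cl$duplication_branch %||% NA_character_,
               n_conflicts = length(cl$evidence$conflicts %||% character()),
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  attr(df, "calls") <- calls
  df
}

#' Per-species repertoire summary
#'
#' Mirrors a per-species summary table: total genes (excluding
#' pseudogenes), families present, families with ancient / recent tandem
#' paralogues retained in that species, single-copy families, and families
#' with retained ohnologues (two or more copies of an ohnologue-bearing
#' family). Also derives the ratio of mean totals in WGD versus non-WGD
#' species (rounded to 1 dp) and the min/max of the retained-ohnologue row
#' over WGD species.
#'
#' @param genomes Named list of [species_genome()].
#' @param calls Data frame from [classify_all_families()].
#' @param species_tree A [species_tree_wgd()].
#' @return List: `table` (one row per species), `ratio`, `min_retained`,
#'   `max_retained`.
#' @export
summarize_repertoire <- function(genomes, calls, species_tree) {
  wgd_species <- clade_species(species_tree, species_tree$wgd_node)
  cat_of <- stats::setNames(calls$category, calls$family_id)
  rows <- lapply(names(genomes), function(sp) {
    g <- genomes[[sp]]$genes
    live <- g[!g$pseudogene & g$family_id != "UNASSIGNED", , drop = FALSE]
    cnt <- table(live$family_id)
    fams <- names(cnt)
    catf <- cat_of[fams]
    data.frame(
      species_id = sp, wgd = sp %in% wgd_species,
      total_genes = nrow(g[!g$pseudogene, , drop = FALSE]),
      families_present = length(fams),
      at_families = sum(!is.na(catf) & catf == "AT" & cnt >= 2),
      rt_families = sum(!is.na(catf) & catf == "RT" & cnt >= 2),
      single_copy_families = sum(cnt == 1),
      retained_ohnologue_families =
        sum(!is.na(catf) & catf %in% c("O", "SOL", "EOL") & cnt >= 2),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ratio <- if (any(tab$wgd) && any(!tab$wgd) && sum(tab$total_genes) > 0)
    round(mean(tab$total_genes[tab$wgd]) / mean(tab$total_genes[!tab$wgd]), 1)
  else NA_real_
  ret <- tab$retained_ohnologue_families[tab$wgd]
  list(table = tab, ratio = ratio,
       min_retained = if (length(ret) > 0) min(ret) else NA_integer_,
       max_retained = if (length(ret) > 0) max(ret) else NA_integer_)
}
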