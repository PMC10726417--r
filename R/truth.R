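# Ground-truth category labels derived from the simulation event log, the
# event-log replay oracle, and fixture output.
#
# The truth labeller and the classifier share one category vocabulary and
# one set of decision rules (lineage presence patterns, precedence between
# event types); they differ only in their evidence. Truth reads the event
# genealogy; the classifier reads reconciled gene trees and chromosomal
# linkage. Mismatches therefore measure information genuinely lost to
# extinction and rearrangement, not definitional drift.

# ---- shared category rules -------------------------------------------------

#' Resolve named clades from species-tree node labels
#'
#' Internal-node labels (e.g. `spiders`, `entelegynes`) become named species
#' sets; used to refine ohnologue losses into stem-loss categories.
#' @param st A [species_tree_wgd()].
#' @return Named list of character vectors of species ids.
#' @export
resolve_clades <- function(st) {
  phy <- st$phy
  labs <- phy$node.label
  out <- list()
  if (is.null(labs)) return(out)
  for (i in seq_along(labs)) {
    if (!is.na(labs[i]) && nzchar(labs[i]))
      out[[labs[i]]] <- clade_species(st, ape::Ntip(phy) + i)
  }
  out
}

# Status of one ohnologue lineage from its species-presence pattern.
# "SOL": absent from every species of clades$spiders but present elsewhere
# in the WGD clade; "EOL": absent from every entelegyne but present in a
# non-entelegyne spider; "dead": absent from the whole WGD clade.
lineage_status <- function(presence, clades, wgd_species) {
  p <- intersect(presence, wgd_species)
  if (length(p) == 0) return("dead")
  spi <- clades[["spiders"]]
  ent <- clades[["entelegynes"]]
  if (!is.null(spi) && length(intersect(p, spi)) == 0 &&
      length(setdiff(p, spi)) > 0) return("SOL")
  if (!is.null(ent) && !is.null(spi) && length(intersect(p, ent)) == 0 &&
      length(intersect(p, setdiff(spi, ent))) > 0) return("EOL")
  "retained"
}

# Category of one WGD gene pair from the species-presence sets of its two
# lineages. The categories are observational: a stem loss is only called
# when the surviving pattern still reveals the duplication (the paper's
# spider-ohnologue-loss families are those with BOTH ohnologues retained in
# the scorpion). Under LCA reconciliation the duplication node is visible
# iff the LCA of the combined presence equals the LCA of one lineage; a
# reciprocally eroded pair is indistinguishable from a single-copy family
# and is classed SC, and a pair whose combined span has shrunk below the
# WGD node is indistinguishable from a post-WGD dispersed duplication (RT
# with a conflict flag on the inference side).
pair_category <- function(pres_a, pres_b, ix, clades, wgd_species) {
  pa <- intersect(pres_a, wgd_species)
  pb <- intersect(pres_b, wgd_species)
  if (length(pa) == 0 && length(pb) == 0) return("NONE")
  if (length(pa) == 0 || length(pb) == 0) return("SC")
  nodes <- function(sp) unname(ix$tip_of[sp])
  l_ab <- st_lca(ix, nodes(union(pa, pb)))
  l_a <- st_lca(ix, nodes(pa))
  l_b <- st_lca(ix, nodes(pb))
  if (l_ab != l_a && l_ab != l_b) return("SC")     # hidden paralogy
  if (l_ab != ix$wgd_node) return("RT")            # looks post-WGD
  sa <- lineage_status(pa, clades, wgd_species)
  sb <- lineage_status(pb, clades, wgd_species)
  if ("SOL" %in% c(sa, sb)) return("SOL")
  if ("EOL" %in% c(sa, sb)) return("EOL")
  "O"
}

# Single family category from the assembled evidence, with one precedence
# shared by truth and inference: AT > (O > SOL > EOL) > RT > SC.
combine_family_category <- function(has_at, pair_labels, has_rt,
                                    present_in_wgd_clade, extant_anywhere) {
  if (!extant_anywhere) return("EXTINCT")
  if (has_at) return("AT")
  for (lab in c("O", "SOL", "EOL"))
    if (lab %in% pair_labels) return(lab)
  if (has_rt || "RT" %in% pair_labels) return("RT")
  if (present_in_wgd_clade || "SC" %in% pair_labels) return("SC")
  "LOSS_other"
}

# ---- truth labels ----------------------------------------------------------

#' True per-family duplication categories from the event log
#'
#' Recomputes, for every simulated family, the category a perfect observer
#' of the full event genealogy would assign: `O` (both WGD copies retained),
#' `SOL`/`EOL` (one copy lost on the spider / entelegyne stem), `SC` (one
#' WGD copy retained), `AT`/`RT` (surviving pre-/post-WGD small-scale
#' duplication), `LOSS_other` (family absent from the whole WGD clade),
#' `EXTINCT`. Pseudogenes do not count as presence.
#'
#' @param sim A `hoxwgd_sim` object.
#' @return Data frame: `family_id`, `category`, `n_pre_dups`, `n_post_dups`,
#'   `n_wgd_pairs`.
#' @export
truth_labels <- function(sim) {
  st <- sim$species_tree
  ix <- index_species_tree(st)
  clades <- resolve_clades(st)
  wgd_species <- clade_species(st, st$wgd_node)
  reg <- sim$registry
  parent_map <- stats::setNames(reg$dup_parent, reg$gene_id)
  created_node <- stats::setNames(reg$created_node, reg$gene_id)
  created_time <- stats::setNames(reg$created_time, reg$gene_id)
  fam_of <- stats::setNames(reg$family_id, reg$gene_id)

  # extant non-pseudogene genes and their duplication-ancestry chains
  ext <- do.call(rbind, lapply(sim$genomes, function(g) {
    gg <- g$genes[!g$genes$pseudogene, c("gene_id", "species_id"), drop = FALSE]
    gg
  }))
  rownames(ext) <- NULL
  chain_cache <- new.env(parent = emptyenv())
  chain_of <- function(id) {
    if (!is.null(chain_cache[[id]])) return(chain_cache[[id]])
    ch <- id
    p <- parent_map[[id]]
    while (!is.na(p)) { ch <- c(ch, p); p <- parent_map[[p]] }
    chain_cache[[id]] <- ch
    ch
  }
  ext$family <- unname(fam_of[ext$gene_id])

  wgd_rows <- sim$event_log[sim$event_log$type == "wgd", , drop = FALSE]
  wgd_pairs <- if (nrow(wgd_rows) == 1) {
    prs <- strsplit(strsplit(wgd_rows$extra, ";", fixed = TRUE)[[1]], ">",
                    fixed = TRUE)
    data.frame(parent = vapply(prs, `[`, "", 1),
               child = vapply(prs, `[`, "", 2), stringsAsFactors = FALSE)
  } else data.frame(parent = character(), child = character())
  t_wgd <- sim$wgd_time
  v_wgd <- st$wgd_node

  dup_rows <- sim$event_log[sim$event_log$type %in%
                              c("tandem_dup", "dispersed_dup"), , drop = FALSE]

  wgd_clade_set <- clade_species(st, v_wgd)

  # does extant gene g (in species sp) descend through gene p at or after
  # time tE on the branch into node vE, without passing the event child c?
  descends_stay <- function(g, sp, p, c, vE, tE) {
    ch <- chain_of(g)
    if (c %in% ch) return(FALSE)
    k <- match(p, ch)
    if (is.na(k)) return(FALSE)
    if (k == 1) return(sp %in% ix$phy$tip.label[ix$leaves[[vE]]])
    q <- ch[k - 1]
    qn <- created_node[[q]]; qt <- created_time[[q]]
    (qn == vE && qt > tE) || (qn != vE && st_is_ancestor(ix, vE, qn))
  }

  event_lineages <- function(p, c, vE, tE, family) {
    fg <- ext[ext$family == family, , drop = FALSE]
    if (nrow(fg) == 0) return(list(stay = character(), copy = character()))
    copy <- unique(fg$species_id[vapply(fg$gene_id, function(g)
      c %in% chain_of(g), TRUE)])
    stay <- unique(fg$species_id[mapply(descends_stay, fg$gene_id,
                                        fg$species_id,
                                        MoreArgs = list(p = p, c = c,
                                                        vE = vE, tE = tE))])
    list(stay = stay, copy = copy)
  }

  fams <- sim$catalog$family_id
  out <- lapply(fams, function(f) {
    fg <- ext[ext$family == f, , drop = FALSE]
    extant_anywhere <- nrow(fg) > 0
    present_wgd <- any(fg$species_id %in% wgd_clade_set)

    has_at <- FALSE; has_rt <- FALSE
    n_pre <- 0L; n_post <- 0L
    dr <- dup_rows[!is.na(fam_of[dup_rows$child_gene]) &
                     fam_of[dup_rows$child_gene] == f, , drop = FALSE]
    if (nrow(dr) > 0) {
      for (i in seq_len(nrow(dr))) {
        vE <- dr$branch_node[i]; tE <- dr$time[i]
        pre <- !is.na(t_wgd) &&
          ((vE == v_wgd && tE < t_wgd) ||
             (vE != v_wgd && st_is_ancestor(ix, vE, v_wgd)))
        lin <- event_lineages(dr$parent_gene[i], dr$child_gene[i], vE, tE, f)
        survives <- length(lin$stay) > 0 && length(lin$copy) > 0
        if (survives && pre) { has_at <- TRUE; n_pre <- n_pre + 1L }
        if (survives && !pre) { has_rt <- TRUE; n_post <- n_post + 1L }
      }
    }

    labs <- character()
    wp <- wgd_pairs[!is.na(fam_of[wgd_pairs$child]) &
                      fam_of[wgd_pairs$child] == f, , drop = FALSE]
    if (nrow(wp) > 0) {
      for (i in seq_len(nrow(wp))) {
        lin <- event_lineages(wp$parent[i], wp$child[i], v_wgd, t_wgd, f)
        labs <- c(labs, pair_category(lin$stay, lin$copy, ix, clades,
                                      wgd_species))
      }
    }
    data.frame(family_id = f,
               category = combine_family_category(has_at, labs, has_rt,
                                                  present_wgd, extant_anywhere),
               n_pre_dups = n_pre, n_post_dups = n_post,
               n_wgd_pairs = nrow(wp), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- replay oracle ---------------------------------------------------------

#' Replay the event log from the root genome
#'
#' Re-applies every logged event down the species tree and rebuilds each
#' leaf genome's structure (chromosomes, gene order, strands, pseudogene
#' flags). Serves as the structural oracle: the replayed genomes must match
#' the simulated ones exactly.
#' @param sim A `hoxwgd_sim`.
#' @return Named list (by species) of [species_genome()] objects; sequences
#'   are carried over from the parent at duplication and are not replayed.
#' @export
replay_event_log <- function(sim) {
  st <- sim$species_tree
  phy <- st$phy
  log <- sim$event_log
  config <- sim$config
  children_edges <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  genomes <- list()

  apply_branch <- function(state, v) {
    rows <- log[log$branch_node == v & log$type != "speciation", , drop = FALSE]
    if (nrow(rows) == 0) return(state)
    rows <- rows[order(rows$event_id), , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      state <- switch(r$type,
        tandem_dup = {
          at <- gs_find(state, r$parent_gene)
          gs_insert(state, at$chr, at$idx + 1L, r$child_gene,
                    unname(state$strand[r$parent_gene]),
                    unname(state$fam[r$parent_gene]),
                    unname(state$cds[r$parent_gene]),
                    unname(state$pseudo[r$parent_gene]))
        },
        dispersed_dup = gs_insert(state, r$chromosome_id2, r$position,
                                  r$child_gene, r$extra,
                                  unname(state$fam[r$parent_gene]),
                                  unname(state$cds[r$parent_gene]),
                                  unname(state$pseudo[r$parent_gene])),
        loss = gs_remove(state, r$parent_gene),
        inversion = gs_invert(state, r$chromosome_id, r$span_from, r$span_to),
        translocation = gs_translocate(state, r$chromosome_id, r$span_from,
                                       r$span_to, r$chromosome_id2, r$position),
        fusion = gs_fuse(state, r$chromosome_id, r$chromosome_id2, r$extra),
        fission = {
          parts <- strsplit(r$extra, "|", fixed = TRUE)[[1]]
          gs_fission(state, r$chromosome_id, r$position, parts[1], parts[2])
        },
        wgd = {
          prs <- strsplit(strsplit(r$extra, ";", fixed = TRUE)[[1]], ">",
                          fixed = TRUE)
          map <- stats::setNames(vapply(prs, `[`, "", 2),
                                 vapply(prs, `[`, "", 1))
          gs_wgd(state, map)
        },
        pseudogenize = { state$pseudo[r$parent_gene] <- TRUE; state },
        state)
    }
    state
  }

  rec <- function(v, state) {
    kid_edges <- children_edges[[as.character(v)]]
    if (is.null(kid_edges)) {
      genomes[[phy$tip.label[v]]] <<- materialize_genome(phy$tip.label[v],
                                                         state, config)
      return(invisible(NULL))
    }
    for (ei in kid_edges) {
      child <- phy$edge[ei, 2]
      rec(child, apply_branch(state, child))
    }
  }
  rec(ape::Ntip(phy) + 1L, sim$root_state)
  genomes[phy$tip.label]
}

# ---- fixture output --------------------------------------------------------

#' Write a simulation to plain-text fixture files
#'
#' Emits, under `dir`: one GFF3 and two FASTA files (homeodomain protein,
#' CDS) per species, all gene trees and the species tree as Newick, the
#' family catalog, truth labels and event log as TSV. Deterministic for a
#' given simulation object.
#' @param sim A `hoxwgd_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$genomes)) {
    g <- sim$genomes[[sp]]
    write_gene_table(g, file.path(dir, paste0(sp, ".gff3")), "gff3")
    gg <- g$genes
    if (nrow(gg) > 0) {
      hd <- Biostrings::AAStringSet(stats::setNames(gg$homeodomain_seq,
                                                    gg$gene_id))
      Biostrings::writeXStringSet(hd, file.path(dir, paste0(sp, "_hd.faa")))
      cds <- Biostrings::DNAStringSet(stats::setNames(gg$cds_seq, gg$gene_id))
      Biostrings::writeXStringSet(cds, file.path(dir, paste0(sp, "_cds.fna")))
    }
  }
  write_tree(sim$species_tree, file.path(dir, "species_tree.nwk"))
  gt_dir <- file.path(dir, "gene_trees")
  dir.create(gt_dir, showWarnings = FALSE)
  for (f in names(sim$gene_trees)) {
    if (!is.null(sim$gene_trees[[f]]))
      ape::write.tree(sim$gene_trees[[f]], file.path(gt_dir, paste0(f, ".nwk")))
  }
  utils::write.table(sim$catalog, file.path(dir, "catalog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$event_log, file.path(dir, "event_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
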