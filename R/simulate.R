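# Forward simulator of genome evolution along a WGD-bearing species tree.
#
# The simulator is the test bed for every inference stage: it produces
# labelled leaf genomes, the true gene tree of every family, a replayable
# event log, and per-family truth categories in the same vocabulary the
# classifier uses (O / AT / RT / SC / SOL / EOL / LOSS_other).
#
# Modelling choices:
#  * one global random stream, seeded; events within a branch are applied in
#    draw (time) order, so a seed fixes the full output;
#  * the WGD duplicates every chromosome and gene simultaneously at the
#    midpoint of the marked branch (new chromosome ids suffixed "_w");
#  * gene coordinates live on a fixed spacing grid (default 10 kb) and are
#    re-spaced after insertions, keeping intergenic distances deterministic;
#  * gene loss is fractionation-biased: copies whose family currently has
#    more than one (non-pseudogene) copy in the genome are lost at an
#    elevated rate, so most post-WGD redundancy resolves near the WGD, as
#    observed in real WGD descendants;
#  * pseudogenization writes one internal stop codon into the homeodomain
#    and freezes the sequence.

#' Simulation configuration
#'
#' All rates are per branch-length unit. Duplication and loss rates are per
#' gene; inversion and translocation rates are per genome; fusion/fission
#' are per-branch probabilities. `pseudogenize_prob` is a per-gene,
#' per-branch probability and may be a named vector keyed by branch (tip or
#' node label) with a `.default` entry.
#'
#' @param seed Integer seed fixing the full output byte-for-byte.
#' @param n_chromosomes Chromosomes in the root genome.
#' @param n_families Total gene families in the root genome (one root gene
#'   each); must cover the cluster templates.
#' @param cluster_templates Named list of character vectors: each template's
#'   member families in canonical order (instantiated at the root as a
#'   contiguous run with alternating strands).
#' @param tandem_duplication,dispersed_duplication Per-gene duplication
#'   rates.
#' @param gene_loss Background per-gene loss rate.
#' @param redundant_loss Additional per-gene loss rate applied to copies of
#'   families with >1 copy in the genome (post-duplication fractionation).
#' @param inversion,translocation Per-genome rearrangement rates.
#' @param fusion_prob,fission_prob Per-branch probabilities of a chromosome
#'   fusion / fission.
#' @param codon_substitution_rate Per-nucleotide substitution rate for CDS
#'   evolution.
#' @param aa_substitution_rate Per-residue rate for genes that carry a
#'   homeodomain but no CDS (unused by the simulator's own genes, whose
#'   homeodomains are CDS translations).
#' @param ts_tv_ratio Transition/transversion rate ratio (kappa).
#' @param pseudogenize_prob Per-gene, per-branch pseudogenization
#'   probability.
#' @param n_hd_codons Homeodomain length in codons (CDS length = 3x this).
#' @param tandem_offset_bp Admissible intergenic offset range for tandem
#'   copies; with grid re-spacing this is informational and recorded in the
#'   config only.
#' @param gene_length_bp,spacing_bp Gene span and grid spacing used when
#'   materializing coordinates.
#' @param max_genes Abort threshold on total gene count.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 20231103L,
                       n_chromosomes = 8L,
                       n_families = 200L,
                       cluster_templates = default_cluster_templates(),
                       tandem_duplication = 0.008,
                       dispersed_duplication = 0.001,
                       gene_loss = 0.02,
                       redundant_loss = 0.35,
                       inversion = 0.5,
                       translocation = 0.2,
                       fusion_prob = 0.02,
                       fission_prob = 0.02,
                       codon_substitution_rate = 0.02,
                       aa_substitution_rate = 0.0,
                       ts_tv_ratio = 2.0,
                       pseudogenize_prob = 0.002,
                       n_hd_codons = 60L,
                       tandem_offset_bp = c(1000L, 20000L),
                       gene_length_bp = 2000L,
                       spacing_bp = 10000L,
                       max_genes = 1e6) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              n_families = as.integer(n_families),
              cluster_templates = cluster_templates,
              tandem_duplication = tandem_duplication,
              dispersed_duplication = dispersed_duplication,
              gene_loss = gene_loss, redundant_loss = redundant_loss,
              inversion = inversion, translocation = translocation,
              fusion_prob = fusion_prob, fission_prob = fission_prob,
              codon_substitution_rate = codon_substitution_rate,
              aa_substitution_rate = aa_substitution_rate,
              ts_tv_ratio = ts_tv_ratio,
              pseudogenize_prob = pseudogenize_prob,
              n_hd_codons = as.integer(n_hd_codons),
              tandem_offset_bp = tandem_offset_bp,
              gene_length_bp = as.integer(gene_length_bp),
              spacing_bp = as.integer(spacing_bp),
              max_genes = max_genes)
  rates <- c("tandem_duplication", "dispersed_duplication", "gene_loss",
             "redundant_loss", "inversion", "translocation",
             "codon_substitution_rate", "aa_substitution_rate")
  for (r in rates)
    assert_that(all(is.finite(cfg[[r]])) && all(cfg[[r]] >= 0),
                paste0(r, " must be finite and >= 0"))
  n_cluster_genes <- sum(lengths(cluster_templates))
  assert_that(cfg$n_families >= n_cluster_genes,
              "n_families must cover all cluster template members")
  structure(cfg, class = "sim_config")
}

#' Default homeobox-style cluster templates
#'
#' Six templates mirroring the conserved bilaterian homeobox clusters
#' (Hox, NK, NK2, HRO, Irx, SINE) with their member counts; members are
#' named by template and canonical position.
#' @export
default_cluster_templates <- function() {
  sizes <- c(Hox = 10L, NK = 6L, NK2 = 4L, HRO = 3L, Irx = 3L, SINE = 3L)
  lapply(stats::setNames(names(sizes), names(sizes)), function(nm)
    sprintf("%s%02d", nm, seq_len(sizes[[nm]])))
}

#' Default 14-taxon species tree with one WGD branch
#'
#' Nine species descend from the WGD (a scorpion-like outgroup `Cscu` plus
#' eight spider-like taxa), five do not (`Dmel`, `Tcas`, `Smar`, `Isca`,
#' `Popi`). Internal nodes `spiders` and `entelegynes` name the clades used
#' for loss refinement. Branch lengths are ultrametric with root depth 3.
#' @return A [species_tree_wgd()].
#' @export
default_species_tree <- function() {
  nwk <- paste0(
    "(((Dmel:1.2,Tcas:1.2)insects:0.8,Smar:2.0)mandibulates:1.0,",
    "(Isca:2.2,(Popi:1.8,(Cscu:1.3,(Dsil:1.0,(Dpla:0.8,((Lele:0.4,",
    "Ptep:0.4)theridiids:0.3,(Hgra:0.55,(Abru:0.3,(Tant:0.2,Tcla:0.2)",
    "trichonephila:0.1)araneids:0.25)hgraclade:0.15)araneoidea:0.1)",
    "entelegynes:0.2)spiders:0.3)WGD:0.5)popiclade:0.4)chelicerates:0.8)",
    "root;")
  phy <- ape::read.tree(text = nwk)
  species_tree_wgd(phy, ape::Ntip(phy) + which(phy$node.label == "WGD"))
}

# ---- genome state ----------------------------------------------------------

gs_new <- function() {
  list(chr_ids = character(), genes_by_chr = list(),
       strand = character(), fam = character(), cds = character(),
       pseudo = logical())
}

gs_n_genes <- function(state) sum(lengths(state$genes_by_chr))

gs_all_ids <- function(state) unlist(state$genes_by_chr, use.names = FALSE)

gs_find <- function(state, id) {
  for (ch in state$chr_ids) {
    i <- match(id, state$genes_by_chr[[ch]])
    if (!is.na(i)) return(list(chr = ch, idx = i))
  }
  stop2("gene not in genome state: ", id)
}

gs_insert <- function(state, chr, pos, id, strand, fam, cds, pseudo) {
  v <- state$genes_by_chr[[chr]]
  state$genes_by_chr[[chr]] <- append(v, id, after = pos - 1L)
  state$strand[id] <- strand; state$fam[id] <- fam
  state$cds[id] <- cds; state$pseudo[id] <- pseudo
  state
}

gs_remove <- function(state, id) {
  at <- gs_find(state, id)
  v <- state$genes_by_chr[[at$chr]]
  state$genes_by_chr[[at$chr]] <- v[v != id]
  state$strand <- state$strand[names(state$strand) != id]
  state$fam <- state$fam[names(state$fam) != id]
  state$cds <- state$cds[names(state$cds) != id]
  state$pseudo <- state$pseudo[names(state$pseudo) != id]
  state
}

gs_invert <- function(state, chr, from, to) {
  v <- state$genes_by_chr[[chr]]
  seg <- v[from:to]
  state$genes_by_chr[[chr]][from:to] <- rev(seg)
  state$strand[seg] <- ifelse(state$strand[seg] == "+", "-", "+")
  state
}

gs_translocate <- function(state, chr, from, to, dest_chr, dest_pos) {
  v <- state$genes_by_chr[[chr]]
  seg <- v[from:to]
  state$genes_by_chr[[chr]] <- v[-(from:to)]
  w <- state$genes_by_chr[[dest_chr]]
  state$genes_by_chr[[dest_chr]] <- append(w, seg, after = dest_pos - 1L)
  state
}

gs_fuse <- function(state, c1, c2, new_id) {
  state$genes_by_chr[[new_id]] <- c(state$genes_by_chr[[c1]],
                                    state$genes_by_chr[[c2]])
  state$genes_by_chr[[c1]] <- NULL
  state$genes_by_chr[[c2]] <- NULL
  state$chr_ids <- c(setdiff(state$chr_ids, c(c1, c2)), new_id)
  state
}

gs_fission <- function(state, chr, after_idx, new1, new2) {
  v <- state$genes_by_chr[[chr]]
  state$genes_by_chr[[new1]] <- v[seq_len(after_idx)]
  state$genes_by_chr[[new2]] <- v[(after_idx + 1L):length(v)]
  state$genes_by_chr[[chr]] <- NULL
  state$chr_ids <- c(setdiff(state$chr_ids, chr), new1, new2)
  state
}

# Duplicate every chromosome and gene; gene_map is named: old id -> new id.
gs_wgd <- function(state, gene_map, chr_suffix = "_w") {
  for (ch in state$chr_ids) {
    old <- state$genes_by_chr[[ch]]
    new <- unname(gene_map[old])
    nch <- paste0(ch, chr_suffix)
    state$genes_by_chr[[nch]] <- new
    state$strand[new] <- unname(state$strand[old])
    state$fam[new] <- unname(state$fam[old])
    state$cds[new] <- unname(state$cds[old])
    state$pseudo[new] <- unname(state$pseudo[old])
  }
  state$chr_ids <- c(state$chr_ids, paste0(state$chr_ids, chr_suffix))
  state
}

# Genes of families with >1 non-pseudogene copy in the genome.
gs_redundant_ids <- function(state) {
  ids <- gs_all_ids(state)
  ids <- ids[!state$pseudo[ids]]
  fams <- state$fam[ids]
  ids[fams %in% names(which(table(fams) > 1))]
}

# ---- the simulator ---------------------------------------------------------

#' Simulate genome evolution along a WGD-bearing species tree
#'
#' Runs the forward model from a root genome down every branch of the
#' species tree: tandem and dispersed duplications, fractionation-biased
#' gene loss, inversions, translocations, chromosome fusions/fissions, one
#' WGD at the midpoint of the marked branch, codon-level sequence evolution,
#' and pseudogenization. Every structural event is logged; the true gene
#' tree of each family is built from the recorded genealogy.
#'
#' @param species_tree A [species_tree_wgd()] with branch lengths.
#' @param config A [sim_config()].
#' @return A `hoxwgd_sim` list: `genomes` (named list of
#'   [species_genome()]), `gene_trees` (named list of gene trees; `NULL`
#'   for families with fewer than two surviving genes), `event_log`,
#'   `registry` (per-gene origin records), `catalog` (the family catalog of
#'   root consensus homeodomains), `truth` (per-family true categories),
#'   `species_tree`, `config`.
#' @export
simulate_genomes <- function(species_tree, config = sim_config()) {
  assert_that(inherits(species_tree, "species_tree_wgd"),
              "species_tree must be a species_tree_wgd")
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  ix <- index_species_tree(species_tree)
  phy <- ix$phy
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))

  env <- new.env(parent = emptyenv())
  env$gene_n <- 0L
  env$log <- list()
  env$reg <- list()
  env$wgd_time <- NA_real_

  new_gene_id <- function() {
    env$gene_n <- env$gene_n + 1L
    sprintf("g%06d", env$gene_n)
  }
  node_label <- function(v) {
    if (v <= ix$ntip) return(phy$tip.label[v])
    lab <- if (!is.null(phy$node.label)) phy$node.label[v - ix$ntip] else ""
    if (!is.na(lab) && nzchar(lab)) lab else paste0("n", v)
  }
  log_event <- function(type, branch_node, time, parent_gene = NA, child_gene = NA,
                        chromosome_id = NA, chromosome_id2 = NA, position = NA,
                        span_from = NA, span_to = NA, extra = NA) {
    env$log[[length(env$log) + 1L]] <- data.frame(
      event_id = length(env$log) + 1L, type = type,
      branch_node = branch_node, branch = node_label(branch_node),
      time = time, parent_gene = as.character(parent_gene),
      child_gene = as.character(child_gene),
      chromosome_id = as.character(chromosome_id),
      chromosome_id2 = as.character(chromosome_id2),
      position = as.integer(position), span_from = as.integer(span_from),
      span_to = as.integer(span_to), extra = as.character(extra),
      stringsAsFactors = FALSE)
  }
  register_gene <- function(id, family, node, time, dup_parent, origin) {
    env$reg[[id]] <- data.frame(gene_id = id, family_id = family,
                                created_node = node, created_time = time,
                                dup_parent = as.character(dup_parent),
                                origin = origin, stringsAsFactors = FALSE)
  }

  # --- root genome -----------------------------------------------------
  templates <- config$cluster_templates
  cluster_fams <- unlist(templates, use.names = FALSE)
  n_single <- config$n_families - length(cluster_fams)
  single_fams <- if (n_single > 0) sprintf("fam%03d", seq_len(n_single)) else character()
  families <- c(cluster_fams, single_fams)
  classes <- c("ANTP", "PRD", "LIM", "SINE", "TALE", "POU", "HNF", "CUT",
               "ZF", "CERS", "PROS", "SIX")
  fam_class <- stats::setNames(rep_len(classes, length(families)), families)

  root_cds <- stats::setNames(
    vapply(families, function(f) random_cds(config$n_hd_codons), ""), families)

  state <- gs_new()
  chrs <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  state$chr_ids <- chrs
  for (ch in chrs) state$genes_by_chr[[ch]] <- character()
  root_node <- ix$root
  root_gene_of <- character()
  # cluster templates: contiguous runs in canonical order, alternating strand
  ti <- 0L
  for (nm in names(templates)) {
    ti <- ti + 1L
    ch <- chrs[(ti - 1L) %% length(chrs) + 1L]
    for (k in seq_along(templates[[nm]])) {
      f <- templates[[nm]][k]
      id <- new_gene_id()
      state <- gs_insert(state, ch, length(state$genes_by_chr[[ch]]) + 1L,
                         id, if (k %% 2 == 1) "+" else "-", f, root_cds[[f]], FALSE)
      register_gene(id, f, root_node, 0, NA, "root")
      root_gene_of[f] <- id
    }
  }
  for (k in seq_along(single_fams)) {
    f <- single_fams[k]
    ch <- chrs[(k - 1L) %% length(chrs) + 1L]
    id <- new_gene_id()
    state <- gs_insert(state, ch, length(state$genes_by_chr[[ch]]) + 1L,
                       id, if (k %% 2 == 0) "+" else "-", f, root_cds[[f]], FALSE)
    register_gene(id, f, root_node, 0, NA, "root")
    root_gene_of[f] <- id
  }

  catalog <- data.frame(
    family_id = families, class = unname(fam_class[families]),
    consensus = vapply(families, function(f) translate_cds(root_cds[[f]]), ""),
    diagnostics = "",
    cluster = c(rep(names(templates), lengths(templates)),
                rep("none", length(single_fams))),
    cluster_order = c(unlist(lapply(templates, seq_along), use.names = FALSE),
                      rep(NA_integer_, length(single_fams))),
    stringsAsFactors = FALSE)

  root_state <- state  # snapshot for event-log replay

  # --- per-branch simulation -------------------------------------------
  pseu_prob <- function(branch_lab) {
    p <- config$pseudogenize_prob
    if (is.null(names(p))) return(unname(p[1]))
    if (branch_lab %in% names(p)) return(unname(p[[branch_lab]]))
    if (".default" %in% names(p)) return(unname(p[[".default"]]))
    0
  }

  apply_segment <- function(state, v, t0, L, lab) {
    # structural events over one time segment of the branch into node v
    n0 <- gs_n_genes(state)
    if (n0 == 0 || L <= 0) return(state)
    nred0 <- length(gs_redundant_ids(state))
    counts <- c(
      tandem = stats::rpois(1, config$tandem_duplication * L * n0),
      dispersed = stats::rpois(1, config$dispersed_duplication * L * n0),
      loss = stats::rpois(1, config$gene_loss * L * n0),
      rloss = stats::rpois(1, config$redundant_loss * L * nred0),
      inversion = stats::rpois(1, config$inversion * L),
      translocation = stats::rpois(1, config$translocation * L))
    types <- rep(names(counts), counts)
    if (length(types) == 0) return(state)
    times <- t0 + sort(stats::runif(length(types), 0, L))
    types <- sample(types)
    for (k in seq_along(types)) {
      if (gs_n_genes(state) == 0) break
      tk <- times[k]
      switch(types[k],
        tandem = {
          ids <- gs_all_ids(state)
          p <- ids[sample.int(length(ids), 1)]
          at <- gs_find(state, p)
          cid <- new_gene_id()
          state <- gs_insert(state, at$chr, at$idx + 1L, cid,
                             unname(state$strand[p]), unname(state$fam[p]),
                             unname(state$cds[p]), unname(state$pseudo[p]))
          register_gene(cid, unname(state$fam[p]), v, tk, p, "tandem")
          log_event("tandem_dup", v, tk, parent_gene = p, child_gene = cid,
                    chromosome_id = at$chr, position = at$idx)
        },
        dispersed = {
          ids <- gs_all_ids(state)
          p <- ids[sample.int(length(ids), 1)]
          dch <- state$chr_ids[sample.int(length(state$chr_ids), 1)]
          dpos <- sample.int(length(state$genes_by_chr[[dch]]) + 1L, 1)
          cid <- new_gene_id()
          cstrand <- sample(c("+", "-"), 1)
          state <- gs_insert(state, dch, dpos, cid, cstrand,
                             unname(state$fam[p]),
                             unname(state$cds[p]), unname(state$pseudo[p]))
          register_gene(cid, unname(state$fam[p]), v, tk, p, "dispersed")
          log_event("dispersed_dup", v, tk, parent_gene = p, child_gene = cid,
                    chromosome_id2 = dch, position = dpos, extra = cstrand)
        },
        loss = {
          ids <- gs_all_ids(state)
          g <- ids[sample.int(length(ids), 1)]
          state <- gs_remove(state, g)
          log_event("loss", v, tk, parent_gene = g)
        },
        rloss = {
          ids <- gs_redundant_ids(state)
          if (length(ids) > 0) {
            g <- ids[sample.int(length(ids), 1)]
            state <- gs_remove(state, g)
            log_event("loss", v, tk, parent_gene = g, extra = "redundant")
          }
        },
        inversion = {
          nonempty <- state$chr_ids[lengths(state$genes_by_chr[state$chr_ids]) >= 2]
          if (length(nonempty) > 0) {
            ch <- nonempty[sample.int(length(nonempty), 1)]
            n <- length(state$genes_by_chr[[ch]])
            ends <- sort(sample.int(n, 2))
            state <- gs_invert(state, ch, ends[1], ends[2])
            log_event("inversion", v, tk, chromosome_id = ch,
                      span_from = ends[1], span_to = ends[2])
          }
        },
        translocation = {
          nonempty <- state$chr_ids[lengths(state$genes_by_chr[state$chr_ids]) >= 1]
          if (length(nonempty) >= 2) {
            ch <- nonempty[sample.int(length(nonempty), 1)]
            n <- length(state$genes_by_chr[[ch]])
            run <- min(n, sample.int(3L, 1))
            from <- sample.int(n - run + 1L, 1)
            dest_choices <- setdiff(state$chr_ids, ch)
            dch <- dest_choices[sample.int(length(dest_choices), 1)]
            dpos <- sample.int(length(state$genes_by_chr[[dch]]) + 1L, 1)
            state <- gs_translocate(state, ch, from, from + run - 1L, dch, dpos)
            log_event("translocation", v, tk, chromosome_id = ch,
                      chromosome_id2 = dch, span_from = from,
                      span_to = from + run - 1L, position = dpos)
          }
        })
      if (gs_n_genes(state) > config$max_genes)
        stop2("simulation exceeded max_genes (", config$max_genes, ")")
    }
    state
  }

  # Simulate the branch into node v; returns exit state plus the branch's
  # duplication/loss records needed for gene-tree assembly.
  sim_branch <- function(state, edge_i) {
    v <- phy$edge[edge_i, 2]
    L <- phy$edge.length[edge_i]
    lab <- node_label(v)
    entry_ids <- gs_all_ids(state)
    branch_dups <- list()
    note_dup <- function(p, c, t) branch_dups[[length(branch_dups) + 1L]] <<-
      list(parent = p, child = c, time = t)
    n_log0 <- length(env$log)

    # per-branch fusion / fission draws (applied at branch start)
    if (stats::runif(1) < config$fusion_prob && length(state$chr_ids) >= 2) {
      cs <- sample(state$chr_ids, 2)
      newid <- paste(cs, collapse = "+")
      state <- gs_fuse(state, cs[1], cs[2], newid)
      log_event("fusion", v, 0, chromosome_id = cs[1],
                chromosome_id2 = cs[2], extra = newid)
    }
    if (stats::runif(1) < config$fission_prob) {
      big <- state$chr_ids[lengths(state$genes_by_chr[state$chr_ids]) >= 2]
      if (length(big) > 0) {
        ch <- big[sample.int(length(big), 1)]
        n <- length(state$genes_by_chr[[ch]])
        cut <- sample.int(n - 1L, 1)
        n1 <- paste0(ch, ".1"); n2 <- paste0(ch, ".2")
        state <- gs_fission(state, ch, cut, n1, n2)
        log_event("fission", v, 0, chromosome_id = ch, position = cut,
                  extra = paste(n1, n2, sep = "|"))
      }
    }

    is_wgd <- (v == ix$wgd_node)
    if (is_wgd) {
      state <- apply_segment(state, v, 0, L / 2, lab)
      ids <- gs_all_ids(state)
      gene_map <- stats::setNames(vapply(ids, function(i) new_gene_id(), ""), ids)
      t_wgd <- L / 2
      env$wgd_time <- t_wgd
      for (p in ids)
        register_gene(unname(gene_map[p]), unname(state$fam[p]), v, t_wgd, p, "wgd")
      chr_map <- paste0(state$chr_ids, "_w")
      log_event("wgd", v, t_wgd,
                extra = paste(paste0(ids, ">", unname(gene_map[ids])), collapse = ";"),
                chromosome_id = paste(state$chr_ids, collapse = ";"),
                chromosome_id2 = paste(chr_map, collapse = ";"))
      state <- gs_wgd(state, gene_map)
      state <- apply_segment(state, v, L / 2, L / 2, lab)
    } else {
      state <- apply_segment(state, v, 0, L, lab)
    }

    # sequence evolution over the full branch (all surviving genes)
    ids <- gs_all_ids(state)
    live <- ids[!state$pseudo[ids]]
    for (g in live) {
      r <- evolve_cds_branch(state$cds[[g]], L, config$codon_substitution_rate,
                             config$ts_tv_ratio)
      state$cds[g] <- r$seq
    }
    # pseudogenization draws (per gene, per branch)
    pp <- pseu_prob(lab)
    if (pp > 0 && length(live) > 0) {
      hit <- live[stats::runif(length(live)) < pp]
      for (g in hit) {
        state$cds[g] <- pseudogenize_cds(state$cds[[g]])
        state$pseudo[g] <- TRUE
        log_event("pseudogenize", v, L, parent_gene = g)
      }
    }

    # collect the branch's duplications (chronological) from the log tail
    new_rows <- if (length(env$log) > n_log0)
      env$log[(n_log0 + 1L):length(env$log)] else list()
    for (row in new_rows) {
      if (row$type %in% c("tandem_dup", "dispersed_dup"))
        note_dup(row$parent_gene, row$child_gene, row$time)
      if (row$type == "wgd") {
        pairs <- strsplit(strsplit(row$extra, ";", fixed = TRUE)[[1]], ">", fixed = TRUE)
        for (pr in pairs) note_dup(pr[1], pr[2], row$time)
      }
    }
    ord <- order(vapply(branch_dups, function(d) d$time, 0))
    list(state = state, entry_ids = entry_ids, dups = branch_dups[ord])
  }

  # --- gene-tree assembly over the species tree ------------------------
  # mini-trees: leaf = gene id (character); node = list(a, b)
  build_mini_trees <- function(entry_ids, dups, exit_ids) {
    exit_set <- exit_ids
    sub_replace <- function(tree, target, repl) {
      if (is.character(tree)) {
        if (tree == target) repl else tree
      } else {
        tree[[1]] <- sub_replace(tree[[1]], target, repl)
        tree[[2]] <- sub_replace(tree[[2]], target, repl)
        tree
      }
    }
    prune <- function(tree) {
      if (is.character(tree)) return(if (tree %in% exit_set) tree else NULL)
      a <- prune(tree[[1]]); b <- prune(tree[[2]])
      if (is.null(a)) return(b)
      if (is.null(b)) return(a)
      list(a, b)
    }
    out <- list()
    for (e in entry_ids) {
      members <- e
      tree <- e
      for (d in dups) {
        if (d$parent %in% members) {
          tree <- sub_replace(tree, d$parent, list(d$parent, d$child))
          members <- c(members, d$child)
        }
      }
      out[[e]] <- prune(tree)
    }
    out
  }

  substitute_leaves <- function(tree, map) {
    if (is.null(tree)) return(NULL)
    if (is.character(tree)) return(map[[tree]])
    a <- substitute_leaves(tree[[1]], map)
    b <- substitute_leaves(tree[[2]], map)
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    list(a, b)
  }

  genomes <- list()
  children_edges <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])

  rec_node <- function(v, state) {
    # returns map: gene id in `state` -> final subtree (leaves "sp|gene")
    kid_edges <- children_edges[[as.character(v)]]
    if (is.null(kid_edges)) {  # tip
      sp <- phy$tip.label[v]
      genomes[[sp]] <<- materialize_genome(sp, state, config)
      ids <- gs_all_ids(state)
      return(stats::setNames(as.list(paste0(sp, "|", ids)), ids))
    }
    maps <- list()
    for (ei in kid_edges) {
      br <- sim_branch(state, ei)
      log_event("speciation", phy$edge[ei, 2], 0)
      below <- rec_node(phy$edge[ei, 2], br$state)
      mt <- build_mini_trees(br$entry_ids, br$dups, gs_all_ids(br$state))
      maps[[length(maps) + 1L]] <-
        stats::setNames(lapply(br$entry_ids, function(e)
          substitute_leaves(mt[[e]], below)), br$entry_ids)
    }
    ids <- gs_all_ids(state)
    out <- stats::setNames(vector("list", length(ids)), ids)
    for (g in ids) {
      subs <- Filter(Negate(is.null), lapply(maps, function(m) m[[g]]))
      out[[g]] <- if (length(subs) == 0) NULL
                  else Reduce(function(a, b) list(a, b), subs)
    }
    out
  }

  root_map <- rec_node(ix$root, state)

  tree_to_newick <- function(tree) {
    rec <- function(x) if (is.character(x)) x
      else paste0("(", rec(x[[1]]), ",", rec(x[[2]]), ")")
    paste0(rec(tree), ";")
  }
  n_leaves <- function(tree) {
    if (is.null(tree)) 0L
    else if (is.character(tree)) 1L
    else n_leaves(tree[[1]]) + n_leaves(tree[[2]])
  }
  gene_trees <- lapply(stats::setNames(families, families), function(f) {
    tr <- root_map[[root_gene_of[[f]]]]
    if (n_leaves(tr) < 2) return(NULL)
    as_gene_tree(ape::read.tree(text = tree_to_newick(tr)))
  })

  event_log <- do.call(rbind, env$log)
  registry <- do.call(rbind, env$reg)
  rownames(event_log) <- rownames(registry) <- NULL

  sim <- structure(list(species_tree = species_tree, config = config,
                        genomes = genomes[phy$tip.label],
                        gene_trees = gene_trees, event_log = event_log,
                        registry = registry, catalog = catalog,
                        root_gene_of = root_gene_of, root_state = root_state,
                        wgd_time = env$wgd_time, truth = NULL),
                   class = "hoxwgd_sim")
  sim$truth <- truth_labels(sim)
  sim
}

# Materialize a leaf genome: grid coordinates, translated homeodomains,
# pseudogene flags carried from the genome state (set at pseudogenization;
# sequence evolution never introduces stops otherwise).
materialize_genome <- function(sp, state, config) {
  rows <- list()
  for (ch in c_sort(state$chr_ids)) {
    ids <- state$genes_by_chr[[ch]]
    if (length(ids) == 0) next
    start <- (seq_along(ids) - 1L) * config$spacing_bp
    hd <- vapply(ids, function(g) translate_cds(state$cds[[g]]), "")
    rows[[ch]] <- data.frame(
      gene_id = ids, chromosome_id = ch, start = start,
      end = start + config$gene_length_bp,
      strand = unname(state$strand[ids]), family_id = unname(state$fam[ids]),
      pseudogene = unname(state$pseudo[ids]),
      homeodomain_seq = unname(hd), cds_seq = unname(state$cds[ids]),
      stringsAsFactors = FALSE)
  }
  genes <- if (length(rows) > 0) do.call(rbind, rows) else empty_gene_table()
  chrom <- data.frame(
    chromosome_id = c_sort(state$chr_ids),
    length = vapply(c_sort(state$chr_ids), function(ch)
      max(1L, length(state$genes_by_chr[[ch]]) * config$spacing_bp), 1L),
    stringsAsFactors = FALSE)
  species_genome(sp, genes, chrom)
}

#' @export
print.hoxwgd_sim <- function(x, ...) {
  cat(sprintf("<hoxwgd_sim> %d species, %d families, %d events, seed %d\n",
              length(x$genomes), x$config$n_families, nrow(x$event_log),
              x$config$seed))
  invisible(x)
}
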