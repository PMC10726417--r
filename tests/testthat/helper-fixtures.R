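# Shared builders and independent brute-force oracles.

# ---- builders --------------------------------------------------------------

mk_genes <- function(chr, families, start0 = 0L, step = 100000L,
                     width = 2000L, strand = "+", ids = NULL) {
  n <- length(families)
  data.frame(
    gene_id = ids %||% sprintf("%s_g%02d", chr, seq_len(n)),
    chromosome_id = chr,
    start = start0 + (seq_len(n) - 1L) * step,
    end = start0 + (seq_len(n) - 1L) * step + width,
    strand = rep_len(strand, n), family_id = families,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_species_tree <- function() {
  phy <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)root;")
  species_tree_wgd(phy, c("A", "B"))
}

small_sim_config <- function(seed = 11L, ...) {
  sim_config(seed = seed, n_families = 35L, n_chromosomes = 3L, ...)
}

toy_catalog <- function(consensus, classes = NULL, diagnostics = NULL) {
  data.frame(family_id = names(consensus),
             class = classes %||% rep("ANTP", length(consensus)),
             consensus = unname(consensus),
             diagnostics = diagnostics %||% rep("", length(consensus)),
             stringsAsFactors = FALSE)
}

random_aa <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# ---- oracle: LCA reconciliation -------------------------------------------

# Independent route: clade tip sets via ape::extract.clade; mapping = the
# smallest-clade species-tree node covering the leaf species; duplication
# iff the two children's mappings are ancestrally comparable.
oracle_reconcile <- function(gene_tree, species_tree) {
  sp <- species_tree$phy
  nsp <- ape::Ntip(sp) + sp$Nnode
  clade_of <- lapply(seq_len(nsp), function(v) {
    if (v <= ape::Ntip(sp)) sp$tip.label[v]
    else ape::extract.clade(sp, v)$tip.label
  })
  map_set <- function(species) {
    cover <- which(vapply(clade_of, function(cl) all(species %in% cl), TRUE))
    cover[which.min(lengths(clade_of[cover]))]
  }
  gt <- gene_tree
  ngt <- ape::Ntip(gt) + gt$Nnode
  species_below <- function(v) {
    labs <- if (v <= ape::Ntip(gt)) gt$tip.label[v]
            else ape::extract.clade(gt, v)$tip.label
    unique(vapply(strsplit(labs, "|", fixed = TRUE), `[`, "", 1))
  }
  res <- data.frame(node = seq_len(ngt), type = NA_character_,
                    mapped_node = NA_integer_)
  for (v in seq_len(ngt)) {
    res$mapped_node[v] <- map_set(species_below(v))
    if (v <= ape::Ntip(gt)) { res$type[v] <- "leaf"; next }
    ch <- gt$edge[gt$edge[, 1] == v, 2]
    m1 <- map_set(species_below(ch[1]))
    m2 <- map_set(species_below(ch[2]))
    comparable <- all(clade_of[[m2]] %in% clade_of[[m1]]) ||
      all(clade_of[[m1]] %in% clade_of[[m2]])
    res$type[v] <- if (comparable) "duplication" else "speciation"
  }
  res
}

random_gene_tree <- function(n_tips, species_pool) {
  phy <- ape::rtree(n_tips, rooted = TRUE, br = NULL)
  phy$tip.label <- paste0(sample(species_pool, n_tips, replace = TRUE),
                          "|g", seq_len(n_tips))
  as_gene_tree(phy)
}

# ---- oracle: Dollo losses --------------------------------------------------

# Exhaustive minimum over all subsets of loss branches.
oracle_dollo_min <- function(present_species, species_tree) {
  phy <- species_tree$phy
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  edges <- seq_len(nrow(phy$edge))
  tips_below_edge <- lapply(edges, function(e) {
    v <- phy$edge[e, 2]
    if (v <= ntip) phy$tip.label[v] else ape::extract.clade(phy, v)$tip.label
  })
  parent_edges_of_tip <- lapply(phy$tip.label, function(tp)
    which(vapply(tips_below_edge, function(s) tp %in% s, TRUE)))
  names(parent_edges_of_tip) <- phy$tip.label
  best <- Inf
  for (mask in 0:(2^length(edges) - 1)) {
    losses <- which(bitwAnd(mask, 2^(edges - 1)) > 0)
    if (length(losses) >= best) next
    ok <- TRUE
    for (tp in phy$tip.label) {
      hit <- any(losses %in% parent_edges_of_tip[[tp]])
      want_absent <- !(tp %in% present_species)
      if (hit != want_absent) { ok <- FALSE; break }
    }
    if (ok) best <- length(losses)
  }
  best
}

# ---- oracle: collinear chain length ---------------------------------------

oracle_best_chain_len <- function(og_x, og_y, max_gap) {
  ms <- expand.grid(i = seq_along(og_x), j = seq_along(og_y))
  ms <- ms[og_x[ms$i] == og_y[ms$j], , drop = FALSE]
  n <- nrow(ms)
  if (n == 0) return(0L)
  memo <- new.env(parent = emptyenv())
  longest_from <- function(k, dir) {
    key <- paste(k, dir)
    if (!is.null(memo[[key]])) return(memo[[key]])
    len <- 1L
    for (l in seq_len(n)) {
      ok <- ms$i[l] > ms$i[k] &&
        (if (dir > 0) ms$j[l] > ms$j[k] else ms$j[l] < ms$j[k]) &&
        (ms$i[l] - ms$i[k] - 1L) <= max_gap &&
        (abs(ms$j[l] - ms$j[k]) - 1L) <= max_gap
      if (ok) len <- max(len, 1L + longest_from(l, dir))
    }
    memo[[key]] <- len
    len
  }
  best <- 0L
  for (k in seq_len(n)) for (dir in c(1, -1))
    best <- max(best, longest_from(k, dir))
  best
}

# ---- oracle: cluster membership via adjacency components -------------------

oracle_clusters <- function(genome, template, max_gap_genes, max_gap_bp) {
  g <- genome$genes
  out <- list()
  for (ch in unique(g$chromosome_id)) {
    on_chr <- g[g$chromosome_id == ch, , drop = FALSE]
    mem <- which(on_chr$family_id %in% template & !on_chr$pseudogene)
    if (length(mem) == 0) next
    comp <- seq_along(mem)
    if (length(mem) > 1) {
      for (k in 2:length(mem)) {
        gap_genes <- mem[k] - mem[k - 1] - 1L
        gap_bp <- on_chr$start[mem[k]] - on_chr$end[mem[k - 1]]
        if (gap_genes <= max_gap_genes && gap_bp <= max_gap_bp)
          comp[k] <- comp[k - 1]
      }
    }
    for (cc in unique(comp))
      out[[length(out) + 1L]] <- sort(on_chr$gene_id[mem[comp == cc]])
  }
  out[order(vapply(out, `[`, "", 1))]
}

# ---- oracle: NG86 pathway counts ------------------------------------------

all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

oracle_codon_paths <- function(a, b) {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  walks <- lapply(all_perms(pos), function(ord) {
    cur <- ca; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- cb[p]
      if (gc[paste(nxt, collapse = "")] == "*") blocked <- TRUE
      if (gc[paste(nxt, collapse = "")] == gc[paste(cur, collapse = "")])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, blocked)
  })
  w <- do.call(rbind, walks)
  use <- if (any(w[, 3] == 0)) w[w[, 3] == 0, , drop = FALSE] else w
  c(sd = mean(use[, 1]), nd = mean(use[, 2]))
}

oracle_codon_syn_sites <- function(codon) {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  ch <- strsplit(codon, "")[[1]]
  total <- 0
  for (p in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), ch[p])
    aa <- vapply(alts, function(b) {
      x <- ch; x[p] <- b; gc[paste(x, collapse = "")]
    }, "")
    sense <- aa[aa != "*"]
    if (length(sense) > 0)
      total <- total + mean(sense == gc[codon])
  }
  total
}
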