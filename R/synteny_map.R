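# Macrosynteny: chromosome-level orthology from shared orthogroup content,
# collinear chain detection by dynamic-programming chaining, and placement
# of named clusters on orthologous blocks.

#' Chromosome orthology between two genomes
#'
#' Builds the contingency table of shared orthogroups per chromosome pair
#' (content-based: gene order is irrelevant) and assigns each chromosome of
#' `genome_x` its best-supported partner in `genome_y`, greedily by
#' descending shared count with ties broken by chromosome id. Pairs sharing
#' fewer than `min_shared` orthogroups stay unassigned. Fusions and
#' fissions surface as 2:1 / 1:2 assignments and are reported.
#'
#' @param genome_x,genome_y [species_genome()] objects.
#' @param orthogroups Data frame with columns `species_id`, `gene_id`,
#'   `orthogroup`; for simulated data, family ids serve as orthogroups
#'   (see [family_orthogroups()]).
#' @param min_shared Minimum shared orthogroups to assign (default 10).
#' @return List: `table` (chromosomes of x by chromosomes of y),
#'   `assignment` (data frame `chr_x`, `chr_y`, `shared`; `chr_y` NA when
#'   unassigned), `relations` (data frame `chr_y`, `n_partners`,
#'   `relation` like `"2:1"`).
#' @export
chromosome_orthology <- function(genome_x, genome_y, orthogroups,
                                 min_shared = 10) {
  og_of <- function(genome) {
    og <- orthogroups[orthogroups$species_id == genome$species_id, ,
                      drop = FALSE]
    idx <- match(genome$genes$gene_id, og$gene_id)
    data.frame(chromosome_id = genome$genes$chromosome_id,
               orthogroup = og$orthogroup[idx],
               stringsAsFactors = FALSE)[!is.na(idx), , drop = FALSE]
  }
  gx <- og_of(genome_x); gy <- og_of(genome_y)
  chrs_x <- c_sort(unique(genome_x$genes$chromosome_id))
  chrs_y <- c_sort(unique(genome_y$genes$chromosome_id))
  tab <- matrix(0L, length(chrs_x), length(chrs_y),
                dimnames = list(chrs_x, chrs_y))
  shared_og <- intersect(gx$orthogroup, gy$orthogroup)
  for (og in shared_og) {
    cx <- unique(gx$chromosome_id[gx$orthogroup == og])
    cy <- unique(gy$chromosome_id[gy$orthogroup == og])
    tab[cx, cy] <- tab[cx, cy] + 1L
  }
  assignment <- data.frame(chr_x = chrs_x, chr_y = NA_character_,
                           shared = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(chrs_x)) {
    if (ncol(tab) == 0) break
    best <- which.max(tab[i, ])
    if (tab[i, best] >= min_shared) {
      assignment$chr_y[i] <- chrs_y[best]
      assignment$shared[i] <- tab[i, best]
    }
  }
  assigned <- assignment$chr_y[!is.na(assignment$chr_y)]
  relations <- if (length(assigned) > 0) {
    part <- table(assigned)
    data.frame(chr_y = names(part), n_partners = as.integer(part),
               relation = paste0(as.integer(part), ":1"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chr_y = character(), n_partners = integer(),
               relation = character(), stringsAsFactors = FALSE)
  }
  list(table = tab, assignment = assignment, relations = relations)
}

#' Orthogroup table from family assignments
#'
#' For simulated or pre-classified data the family labels are the
#' orthogroups; this flattens a genome list into the orthogroup table
#' consumed by [chromosome_orthology()] and [collinear_chains()].
#' @param genomes Named list of [species_genome()].
#' @param exclude_unassigned Drop `UNASSIGNED` genes (default TRUE).
#' @export
family_orthogroups <- function(genomes, exclude_unassigned = TRUE) {
  out <- do.call(rbind, lapply(genomes, function(g) {
    gg <- g$genes
    data.frame(species_id = gg$species_id, gene_id = gg$gene_id,
               orthogroup = gg$family_id, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (exclude_unassigned)
    out <- out[out$orthogroup != "UNASSIGNED", , drop = FALSE]
  out
}

#' Collinear chains between two ordered gene lists
#'
#' Chains matches (positions sharing an orthogroup) that are monotone in
#' both genomes - increasing in both (forward) or increasing in x and
#' decreasing in y (reversed) - with positional gaps of at most `max_gap`
#' on either side between consecutive matches. Chains are extracted
#' best-first (dynamic programming, deterministic tie-breaks); chains
#' shorter than `min_chain` are discarded.
#'
#' @param og_x,og_y Character vectors: orthogroup ids of the genes of one
#'   chromosome in genomic order.
#' @param min_chain Minimum reported chain length (default 5).
#' @param max_gap Maximum positional gap between consecutive chain members
#'   (default 25).
#' @return List of chains; each is a list with `orientation`
#'   (`"forward"`/`"reversed"`) and `matches` (data frame `pos_x`, `pos_y`,
#'   `orthogroup`).
#' @export
collinear_chains <- function(og_x, og_y, min_chain = 5, max_gap = 25) {
  matches <- which(outer(og_x, og_y, "=="), arr.ind = TRUE)
  if (length(matches) == 0) return(list())
  m <- data.frame(i = matches[, 1], j = matches[, 2])
  m <- m[order(m$i, m$j), , drop = FALSE]
  rownames(m) <- NULL
  chains <- list()
  active <- rep(TRUE, nrow(m))
  best_chain <- function(reversed) {
    idx <- which(active)
    if (length(idx) == 0) return(NULL)
    mi <- m$i[idx]
    mj <- if (reversed) -m$j[idx] else m$j[idx]
    n <- length(idx)
    score <- rep(1L, n)
    prev <- rep(NA_integer_, n)
    for (a in seq_len(n)) {
      for (b in seq_len(a - 1L)) {
        ok <- mi[b] < mi[a] && mj[b] < mj[a] &&
          (mi[a] - mi[b] - 1L) <= max_gap &&
          (abs(mj[a] - mj[b]) - 1L) <= max_gap
        if (ok && score[b] + 1L > score[a]) {
          score[a] <- score[b] + 1L
          prev[a] <- b
        }
      }
    }
    end <- which.max(score)
    path <- end
    while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
    list(len = score[end], members = idx[path])
  }
  repeat {
    fwd <- best_chain(FALSE)
    rev_ <- best_chain(TRUE)
    if (is.null(fwd)) break
    pick <- if ((rev_$len %||% 0) > fwd$len) list(rev_, "reversed")
            else list(fwd, "forward")
    if (pick[[1]]$len < min_chain) break
    mem <- pick[[1]]$members
    chains[[length(chains) + 1L]] <- list(
      orientation = pick[[2]],
      matches = data.frame(pos_x = m$i[mem], pos_y = m$j[mem],
                           orthogroup = og_x[m$i[mem]],
                           stringsAsFactors = FALSE))
    active[mem] <- FALSE
  }
  chains
}

#' Place named clusters on macrosynteny blocks
#'
#' Joins labelled cluster reports with chromosome orthology maps to a
#' reference species and flags relocations: a cluster whose chromosome
#' maps to a different reference chromosome than the chromosome carrying
#' the same cluster (template + label) in the reference species.
#'
#' @param clusters Data frame with columns `species_id`, `template`,
#'   `label`, `chromosome_id` (e.g. flattened from scored, paired
#'   reports).
#' @param ortho_maps Named list (by species) of assignment data frames from
#'   [chromosome_orthology()] computed against the reference species.
#' @param reference_species Reference species id.
#' @return `clusters` with `ref_chromosome` (mapped block),
#'   `ref_cluster_chromosome` (where the reference carries the same-label
#'   cluster) and `relocated` added. A cluster is flagged relocated when
#'   its chromosome maps to a reference block on which the reference
#'   species carries no cluster of that template at all: ohnologous (A/B)
#'   blocks share most gene content, so the per-copy labels - assigned by
#'   intactness within each species - cannot distinguish homologous copies
#'   across species, and comparing against either template block avoids
#'   spurious flags from label swaps.
#' @export
locate_clusters <- function(clusters, ortho_maps, reference_species) {
  ref <- clusters[clusters$species_id == reference_species, , drop = FALSE]
  ref_chr_of <- stats::setNames(ref$chromosome_id,
                                paste(ref$template, ref$label))
  ref_chrs_of_tpl <- split(ref$chromosome_id, ref$template)
  n <- nrow(clusters)
  clusters$ref_chromosome <- NA_character_
  clusters$ref_cluster_chromosome <-
    unname(ref_chr_of[paste(clusters$template, clusters$label)])
  for (i in seq_len(n)) {
    sp <- clusters$species_id[i]
    if (sp == reference_species) {
      clusters$ref_chromosome[i] <- clusters$chromosome_id[i]
      next
    }
    amap <- ortho_maps[[sp]]
    if (is.null(amap)) next
    hit <- match(clusters$chromosome_id[i], amap$chr_x)
    if (!is.na(hit)) clusters$ref_chromosome[i] <- amap$chr_y[hit]
  }
  clusters$relocated <- vapply(seq_len(n), function(i) {
    rc <- clusters$ref_chromosome[i]
    tpl_chrs <- ref_chrs_of_tpl[[clusters$template[i]]]
    !is.na(rc) && length(tpl_chrs) > 0 && !(rc %in% tpl_chrs) &&
      clusters$species_id[i] != reference_species
  }, TRUE)
  clusters
}
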