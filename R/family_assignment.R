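# Homeobox family assignment from homeodomain sequences: similarity plus
# diagnostic residues against a family catalog, pseudogene flagging, and
# detection of lineage-spanning novel ("un") families.

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

check_aa <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(ch), AA_ALPHABET)
  if (length(bad) > 0)
    stop2("non-amino-acid character(s) in sequence: ",
          paste(bad, collapse = ", "))
  ch
}

# Best ungapped fit of query against a reference of length L: slide the
# shorter sequence along the longer; returns matches at the best offset and
# the aligned query (padded with X) of length L.
best_ungapped_fit <- function(query, ref) {
  q <- check_aa(query)
  r <- strsplit(ref, "")[[1]]
  L <- length(r)
  n <- length(q)
  best <- list(matches = -1L, aligned = NULL)
  offsets <- if (n >= L) 0:(n - L) else -(0:(L - n))
  for (off in offsets) {
    aligned <- if (off >= 0) q[(off + 1):(off + L)]
    else c(rep("X", -off), q, rep("X", L - n + off))[1:L]
    m <- sum(aligned == r & aligned != "X" & aligned != "*")
    if (m > best$matches) best <- list(matches = m, aligned = aligned)
  }
  best
}

parse_diagnostics <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) return(list())
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    list(pos = as.integer(kv[1]),
         allowed = strsplit(kv[2], "|", fixed = TRUE)[[1]])
  })
}

#' Score a homeodomain sequence against a family catalog
#'
#' Similarity is ungapped identity over the 60-column homeodomain (the
#' query, 55-65 aa, is slid to its best ungapped fit against each
#' consensus). A family's diagnostic residues must all match for
#' `diagnostic_pass`; a family without diagnostics passes vacuously.
#' Ranking is by (diagnostic_pass desc, similarity desc, family_id asc).
#'
#' @param hd_seq Homeodomain amino-acid sequence, 55-65 residues. `X` and
#'   `*` are allowed and never match.
#' @param catalog Family catalog data frame with columns `family_id`,
#'   `consensus` (60 aa) and optionally `diagnostics`
#'   (`"pos:AA|AA;pos:AA"`).
#' @return Data frame ranked best-first: `family_id`, `similarity`,
#'   `diagnostic_pass`.
#' @export
score_family <- function(hd_seq, catalog) {
  n <- nchar(hd_seq)
  assert_that(n >= 55 && n <= 65,
              "homeodomain sequence must be 55-65 residues")
  check_aa(hd_seq)
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    cons <- catalog$consensus[i]
    fit <- best_ungapped_fit(hd_seq, cons)
    L <- nchar(cons)
    diags <- parse_diagnostics(if ("diagnostics" %in% names(catalog))
      catalog$diagnostics[i] else "")
    pass <- all(vapply(diags, function(d) fit$aligned[d$pos] %in% d$allowed,
                       TRUE))
    data.frame(family_id = catalog$family_id[i],
               similarity = fit$matches / L,
               diagnostic_pass = pass, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[c_order(!out$diagnostic_pass, -out$similarity, out$family_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign genes to families by homeodomain similarity
#'
#' Every gene with a homeodomain sequence is labelled with the top-ranked
#' catalog family, or `UNASSIGNED` when the best similarity falls below
#' `min_similarity`. Deterministic and independent of gene order.
#'
#' @param genome A [species_genome()] whose genes carry `homeodomain_seq`.
#' @param catalog Family catalog (see [score_family()]).
#' @param min_similarity Assignment threshold on similarity (default 0.55).
#' @return The genome with `family_id` replaced by the assignments.
#' @export
assign_families <- function(genome, catalog, min_similarity = 0.55) {
  g <- genome$genes
  # fast path: fixed-width sequences compare against the consensus matrix
  # column-wise; equivalent to score_family (single zero offset)
  L <- unique(nchar(catalog$consensus))
  cons_mat <- if (length(L) == 1)
    vapply(catalog$consensus, function(s) strsplit(s, "")[[1]],
           character(L)) else NULL
  diags <- lapply(if ("diagnostics" %in% names(catalog))
    catalog$diagnostics else rep("", nrow(catalog)), parse_diagnostics)
  ord3 <- function(pass, sim) c_order(!pass, -sim, catalog$family_id)[1]
  for (i in seq_len(nrow(g))) {
    hd <- g$homeodomain_seq[i]
    if (is.na(hd)) { g$family_id[i] <- "UNASSIGNED"; next }
    if (!is.null(cons_mat) && nchar(hd) == L) {
      q <- check_aa(hd)
      informative <- q != "X" & q != "*"
      sims <- colSums((q == cons_mat) & informative) / L
      pass <- vapply(seq_along(diags), function(j)
        all(vapply(diags[[j]], function(d) q[d$pos] %in% d$allowed, TRUE)),
        TRUE)
      best <- ord3(pass, sims)
      g$family_id[i] <- if (sims[best] >= min_similarity)
        catalog$family_id[best] else "UNASSIGNED"
    } else {
      sc <- score_family(hd, catalog)
      g$family_id[i] <- if (sc$similarity[1] >= min_similarity)
        sc$family_id[1] else "UNASSIGNED"
    }
  }
  genome$genes <- g
  genome
}

#' Flag pseudogenes by internal stop codons in the homeodomain
#'
#' A gene is a pseudogene when an internal stop codon falls within the
#' homeodomain-encoding span: the CDS translation (or, failing that, the
#' homeodomain sequence itself) contains `*` before its final position.
#' A terminal stop alone does not flag. Pseudogenes are retained in the
#' genome but excluded from repertoire counts downstream.
#'
#' @param genome A [species_genome()].
#' @return The genome with the `pseudogene` column set.
#' @export
flag_pseudogenes <- function(genome) {
  g <- genome$genes
  for (i in seq_len(nrow(g))) {
    aa <- if (!is.na(g$cds_seq[i])) {
      if (nchar(g$cds_seq[i]) %% 3 == 0) translate_cds(g$cds_seq[i])
      else g$homeodomain_seq[i]
    } else g$homeodomain_seq[i]
    if (is.na(aa)) next
    internal <- substr(aa, 1, nchar(aa) - 1)
    g$pseudogene[i] <- grepl("*", internal, fixed = TRUE)
  }
  genome$genes <- g
  genome
}

# Symmetric pairwise similarity between two homeodomain-scale sequences:
# best ungapped overlap, matches / max(length).
pairwise_hd_similarity <- function(a, b) {
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
  fit <- best_ungapped_fit(b, a)
  fit$matches / nchar(a)
}

#' Detect novel families among unassigned genes
#'
#' Groups `UNASSIGNED` genes across species by single-linkage clustering on
#' pairwise homeodomain similarity. Groups spanning at least `min_species`
#' species become new families named `<CLASS>-un<K>` after the class of the
#' nearest catalog consensus; single-species groups stay unclassified.
#'
#' @param genomes Named list of [species_genome()] objects (>= 2 species).
#' @param catalog Family catalog with `class` and `consensus` columns.
#' @param min_species Minimum species spanned by a new family (default 2).
#' @param cross_similarity Single-linkage threshold (default 0.8).
#' @return Data frame: `gene_id`, `species_id`, `new_family`
#'   (`"unclassified"` for residual singletons/groups).
#' @export
detect_new_families <- function(genomes, catalog, min_species = 2,
                                cross_similarity = 0.8) {
  assert_that(length(genomes) >= 2, "need at least two species")
  un <- do.call(rbind, lapply(genomes, function(g) {
    gg <- g$genes[g$genes$family_id == "UNASSIGNED" &
                    !is.na(g$genes$homeodomain_seq), , drop = FALSE]
    gg[, c("gene_id", "species_id", "homeodomain_seq")]
  }))
  if (is.null(un) || nrow(un) == 0)
    return(data.frame(gene_id = character(), species_id = character(),
                      new_family = character(), stringsAsFactors = FALSE))
  rownames(un) <- NULL
  un <- un[c_order(un$species_id, un$gene_id), , drop = FALSE]
  n <- nrow(un)
  # single-linkage components on the similarity graph (union-find)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (pairwise_hd_similarity(un$homeodomain_seq[i],
                                 un$homeodomain_seq[j]) >= cross_similarity) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  un$new_family <- "unclassified"
  counter <- integer(0)
  for (r in unique(roots)) {
    idx <- which(roots == r)
    if (length(unique(un$species_id[idx])) < min_species) next
    # class of the nearest catalog consensus over group members
    sims <- vapply(seq_len(nrow(catalog)), function(ci)
      max(vapply(idx, function(i)
        pairwise_hd_similarity(un$homeodomain_seq[i], catalog$consensus[ci]),
        0)), 0)
    cls <- catalog$class[which.max(sims)]
    counter[cls] <- (if (cls %in% names(counter)) counter[[cls]] else 0L) + 1L
    un$new_family[idx] <- sprintf("%s-un%d", cls, counter[[cls]])
  }
  un[, c("gene_id", "species_id", "new_family")]
}
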