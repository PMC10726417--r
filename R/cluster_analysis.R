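# Homeobox cluster detection and integrity scoring: completeness of the
# template gene complement, order conservation (reversal-tolerant longest
# common subsequence against the canonical order), strand coherence, and
# A/B asymmetry between ohnologous cluster copies.

#' Detect clusters of template-family genes
#'
#' Finds maximal runs of template-family genes on one chromosome where no
#' two consecutive members are separated by more than `max_gap_genes`
#' intervening (non-template) genes or more than `max_gap_bp` of intergenic
#' distance. Non-template genes never break a cluster; they only count
#' toward the gap limits. Singleton members are reported as size-1
#' clusters. Pseudogenes are not counted as members.
#'
#' @param genome A [species_genome()] with family assignments.
#' @param template_families Character vector of the template's member
#'   families.
#' @param max_gap_genes,max_gap_bp Gap bounds (defaults 10 genes, 5 Mb).
#' @param template_name Optional template label carried into the reports.
#' @return List of unscored cluster reports; each is a list with
#'   `species_id`, `chromosome_id`, `template`, `members` (data frame in
#'   genomic order), `span_bp`.
#' @export
detect_clusters <- function(genome, template_families, max_gap_genes = 10,
                            max_gap_bp = 5e6, template_name = NA_character_) {
  g <- genome$genes
  out <- list()
  for (ch in unique(g$chromosome_id)) {
    on_chr <- g[g$chromosome_id == ch, , drop = FALSE]  # already sorted
    mem_idx <- which(on_chr$family_id %in% template_families &
                       !on_chr$pseudogene)
    if (length(mem_idx) == 0) next
    run <- mem_idx[1]
    flush <- function(run) {
      members <- on_chr[run, c("gene_id", "family_id", "start", "end",
                               "strand"), drop = FALSE]
      rownames(members) <- NULL
      out[[length(out) + 1L]] <<- structure(
        list(species_id = genome$species_id, chromosome_id = ch,
             template = template_name, members = members,
             span_bp = max(members$end) - min(members$start),
             label = NA_character_),
        class = "cluster_report")
    }
    if (length(mem_idx) > 1) {
      for (k in 2:length(mem_idx)) {
        i_prev <- run[length(run)]
        i_cur <- mem_idx[k]
        gap_genes <- i_cur - i_prev - 1L
        gap_bp <- on_chr$start[i_cur] - on_chr$end[i_prev]
        if (gap_genes <= max_gap_genes && gap_bp <= max_gap_bp) {
          run <- c(run, i_cur)
        } else {
          flush(run)
          run <- i_cur
        }
      }
    }
    flush(run)
  }
  out
}

#' @export
print.cluster_report <- function(x, ...) {
  sc <- if (!is.null(x$completeness))
    sprintf(" completeness %.2f order %.2f orientation %.2f",
            x$completeness, x$order_score, x$orientation_score) else ""
  cat(sprintf("<cluster_report> %s %s [%s%s]: %s%s\n", x$species_id,
              x$chromosome_id, x$template %||% "?",
              if (!is.na(x$label %||% NA)) paste0("/", x$label) else "",
              paste(x$members$family_id, collapse = "-"), sc))
  invisible(x)
}

# Longest common subsequence length (dynamic programming).
lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0L)
  dp <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m))
    dp[i + 1, j + 1] <- if (a[i] == b[j]) dp[i, j] + 1L
                        else max(dp[i, j + 1], dp[i + 1, j])
  dp[n + 1, m + 1]
}

#' Score cluster integrity against a canonical template order
#'
#' Completeness is the fraction of template families present. The order
#' score is the longest common subsequence between the observed family
#' order (or its reversal, whichever is longer; whole-cluster inversions
#' are organization-preserving) and the canonical order, divided by the
#' number of members present. The orientation score is the largest fraction
#' of members sharing one strand.
#'
#' @param cluster A cluster report from [detect_clusters()].
#' @param canonical_order Template families in canonical order.
#' @return The cluster report with `completeness`, `order_score`,
#'   `orientation_score` added.
#' @export
score_integrity <- function(cluster, canonical_order) {
  m <- cluster$members
  assert_that(!is.null(m) && nrow(m) > 0, "cannot score an empty cluster")
  obs <- m$family_id
  cluster$completeness <-
    length(intersect(unique(obs), canonical_order)) / length(canonical_order)
  cluster$order_score <- max(lcs_length(obs, canonical_order),
                             lcs_length(rev(obs), canonical_order)) /
    length(obs)
  cluster$orientation_score <- max(table(m$strand)) / nrow(m)
  cluster
}

#' Pair ohnologous cluster copies and report their asymmetry
#'
#' Clusters of one template within one species are paired when their
#' members are mutual ohnologues (maximal mutual-ohnologue count, greedy,
#' deterministic); leftovers stay unpaired with a warning when more than
#' two candidates exist. Within a pair, the more intact copy (higher
#' completeness, then order score; ties broken by chromosome id) receives
#' `intact_label` ("A" by default; pass "B" to follow conventions in which
#' B denotes the intact copy).
#'
#' @param clusters List of scored cluster reports (one template, one
#'   species).
#' @param ohnologue_pairs Data frame with columns `gene_a`, `gene_b`:
#'   gene-level ohnology from the family calls.
#' @param intact_label `"A"` or `"B"`: label given to the more intact copy.
#' @return List of pair reports: `cluster_a`, `cluster_b` (labelled),
#'   `delta_completeness`, `delta_order`, `more_intact` (label); plus
#'   `unpaired` clusters.
#' @export
pair_ohnologous_clusters <- function(clusters, ohnologue_pairs,
                                     intact_label = "A") {
  assert_that(intact_label %in% c("A", "B"), "intact_label must be A or B")
  other_label <- setdiff(c("A", "B"), intact_label)
  n <- length(clusters)
  if (n < 2) return(list(pairs = list(), unpaired = clusters))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ohno <- unique(key(ohnologue_pairs$gene_a, ohnologue_pairs$gene_b))
  count_mutual <- function(ci, cj) {
    ga <- clusters[[ci]]$members$gene_id
    gb <- clusters[[cj]]$members$gene_id
    sum(outer(ga, gb, key) %in% ohno)
  }
  cand <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cnt <- count_mutual(i, j)
    if (cnt > 0) cand[[length(cand) + 1L]] <- c(i = i, j = j, cnt = cnt)
  }
  used <- logical(n)
  pairs <- list()
  if (length(cand) > 0) {
    ord <- order(-vapply(cand, `[[`, 0, "cnt"),
                 vapply(cand, `[[`, 0, "i"), vapply(cand, `[[`, 0, "j"))
    for (k in ord) {
      i <- cand[[k]][["i"]]; j <- cand[[k]][["j"]]
      if (used[i] || used[j]) next
      used[i] <- used[j] <- TRUE
      a <- clusters[[i]]; b <- clusters[[j]]
      intact_first <-
        if (a$completeness != b$completeness) a$completeness > b$completeness
        else if (a$order_score != b$order_score) a$order_score > b$order_score
        else a$chromosome_id <= b$chromosome_id
      if (!intact_first) { tmp <- a; a <- b; b <- tmp }
      a$label <- intact_label
      b$label <- other_label
      pairs[[length(pairs) + 1L]] <- list(
        cluster_a = a, cluster_b = b,
        delta_completeness = abs(a$completeness - b$completeness),
        delta_order = abs(a$order_score - b$order_score),
        more_intact = a$label)
    }
  }
  if (n - 2L * length(pairs) > 0 && n > 2)
    warning("unpaired cluster(s) remain after mutual-ohnologue pairing")
  for (i in which(!used)) clusters[[i]]$label <- "unpaired"
  list(pairs = pairs, unpaired = clusters[!used])
}
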