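# Pairwise dN/dS by the Nei-Gojobori (1986) counting method with
# Jukes-Cantor correction.
#
# Site counts: at each codon position, the synonymous fraction of the
# sense single-nucleotide changes (changes to stop codons are excluded
# from the denominator), so each codon contributes exactly 3 sites and
# S + N = 3L. Differences: codons differing at d positions are resolved by
# averaging the synonymous/nonsynonymous step counts over all d! orderings
# of single-nucleotide steps whose intermediates are sense codons; if every
# ordering passes through a stop codon, all orderings are averaged with
# stop steps counted as nonsynonymous (rare fallback, noted in the result).

# Per-codon synonymous site count (sum over 3 positions of the synonymous
# fraction among sense changes).
codon_syn_sites <- function(codon) {
  aa_tab <- codon_aa()
  aa0 <- aa_tab[[codon]]
  s <- 0
  ch <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    syn <- 0L; sense <- 0L
    for (b in BASES[BASES != ch[pos]]) {
      alt <- ch; alt[pos] <- b
      aa1 <- aa_tab[[paste(alt, collapse = "")]]
      if (aa1 == "*") next
      sense <- sense + 1L
      if (aa1 == aa0) syn <- syn + 1L
    }
    if (sense > 0) s <- s + syn / sense
  }
  s
}

.ng_cache <- NULL
ng_tables <- function() {
  if (!is.null(.ng_cache)) return(.ng_cache)
  sense <- sense_codons()
  sites <- vapply(sense, codon_syn_sites, 0)
  utils::assignInMyNamespace(".ng_cache",
                             list(sites = sites,
                                  diffs = new.env(parent = emptyenv())))
  .ng_cache
}

# Average (syn, nonsyn) step counts between two codons over mutational
# pathways; memoized. Returns c(sd, nd, fallback).
codon_path_counts <- function(a, b) {
  tabs <- ng_tables()
  key <- paste(a, b)
  hit <- tabs$diffs[[key]]
  if (!is.null(hit)) return(hit)
  aa_tab <- codon_aa()
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  d <- length(pos)
  if (d == 0) {
    res <- c(sd = 0, nd = 0, fallback = 0)
  } else {
    perms <- if (d == 1) list(pos)
    else if (d == 2) list(pos, rev(pos))
    else list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
              pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
    walk <- function(order_) {
      cur <- ca
      sd <- 0; nd <- 0; blocked <- FALSE
      for (p in order_) {
        nxt <- cur; nxt[p] <- cb[p]
        aa0 <- aa_tab[[paste(cur, collapse = "")]]
        aa1 <- aa_tab[[paste(nxt, collapse = "")]]
        if (aa1 == "*") blocked <- TRUE
        if (aa1 == aa0) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd, blocked = as.numeric(blocked))
    }
    all_counts <- vapply(perms, walk, c(sd = 0, nd = 0, blocked = 0))
    ok <- all_counts["blocked", ] == 0
    use <- if (any(ok)) all_counts[, ok, drop = FALSE] else all_counts
    res <- c(sd = mean(use["sd", ]), nd = mean(use["nd", ]),
             fallback = as.numeric(!any(ok)))
  }
  tabs$diffs[[key]] <- res
  res
}

split_codons <- function(seq) {
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Pairwise dN/dS by Nei-Gojobori (1986) counting
#'
#' @param cds_a,cds_b Aligned coding sequences of equal length (multiple
#'   of 3), no internal stop codons, standard genetic code.
#' @return A `dnds_result` list: synonymous/nonsynonymous site counts `S`
#'   and `N` (averaged over the two sequences; `S + N = 3L`), observed
#'   differences `Sd`, `Nd` (pathway-averaged), proportions `pS`, `pN`,
#'   Jukes-Cantor-corrected rates `dS`, `dN`, and `omega` = dN/dS.
#'   `omega` is `NA` (never infinite) when `dS` is 0 or a proportion is
#'   saturated; `omega_reason` says why.
#' @export
ng86 <- function(cds_a, cds_b) {
  assert_that(nchar(cds_a) == nchar(cds_b),
              "sequences must be aligned to equal length")
  assert_that(nchar(cds_a) %% 3 == 0, "length must be a multiple of 3")
  assert_that(nchar(cds_a) >= 3, "need at least one codon")
  cod_a <- split_codons(cds_a)
  cod_b <- split_codons(cds_b)
  if (any(cod_a %in% STOP_CODONS) || any(cod_b %in% STOP_CODONS))
    stop2("internal stop codon in input")
  tabs <- ng_tables()
  bad <- c(cod_a, cod_b)[!(c(cod_a, cod_b) %in% names(tabs$sites))]
  if (length(bad) > 0)
    stop2("non-ACGT codon(s): ", paste(unique(bad), collapse = ", "))
  L <- length(cod_a)
  S_a <- sum(tabs$sites[cod_a]); S_b <- sum(tabs$sites[cod_b])
  S <- (S_a + S_b) / 2
  N <- 3 * L - S
  counts <- vapply(seq_len(L), function(i)
    codon_path_counts(cod_a[i], cod_b[i]), c(sd = 0, nd = 0, fallback = 0))
  Sd <- sum(counts["sd", ]); Nd <- sum(counts["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) return(NA_real_)
    -3 / 4 * log(arg)
  }
  dS <- jc(pS); dN <- jc(pN)
  omega <- NA_real_; reason <- NA_character_
  if (is.na(dS) || is.na(dN)) reason <- "saturation (Jukes-Cantor undefined)"
  else if (dS == 0) reason <- if (dN == 0) "0/0 (identical)" else "dS = 0"
  else omega <- dN / dS
  structure(list(n_codons = L, S = S, N = N, Sd = Sd, Nd = Nd, pS = pS,
                 pN = pN, dS = dS, dN = dN, omega = omega,
                 omega_reason = reason,
                 n_path_fallbacks = sum(counts["fallback", ])),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf(paste0("<dnds_result> %d codons: S=%.2f N=%.2f Sd=%.2f ",
                     "Nd=%.2f dS=%s dN=%s omega=%s%s\n"),
              x$n_codons, x$S, x$N, x$Sd, x$Nd,
              format(x$dS, digits = 4), format(x$dN, digits = 4),
              format(x$omega, digits = 4),
              if (!is.na(x$omega_reason)) paste0(" (", x$omega_reason, ")")
              else ""))
  invisible(x)
}

#' Back-translate a protein alignment pair into a codon alignment
#'
#' Each aligned residue expands to its codon; columns containing a gap in
#' either sequence or an ambiguous (non-ACGT) base are dropped. The
#' ungapped protein must equal the CDS translation.
#'
#' @param prot_a,prot_b Aligned protein sequences (equal length, `-` gaps).
#' @param cds_a,cds_b Unaligned coding sequences.
#' @return List `a`, `b`: codon-aligned sequences of equal length
#'   (multiple of 3).
#' @export
backtranslate_align <- function(prot_a, prot_b, cds_a, cds_b) {
  assert_that(nchar(prot_a) == nchar(prot_b),
              "protein alignment rows must have equal length")
  check_one <- function(prot, cds, who) {
    ungapped <- gsub("-", "", prot, fixed = TRUE)
    n_cod <- nchar(cds) %/% 3
    assert_that(nchar(cds) %% 3 == 0,
                paste0("CDS ", who, " length not divisible by 3"))
    tr <- translate_cds(cds)
    tr <- sub("\\*$", "", tr)  # tolerate one terminal stop
    if (nchar(tr) != nchar(ungapped))
      stop2("CDS ", who, " translates to ", nchar(tr),
            " residues but alignment has ", nchar(ungapped))
    mism <- which(strsplit(tr, "")[[1]] != strsplit(ungapped, "")[[1]])
    if (length(mism) > 0)
      stop2("translation mismatch for ", who, " at residue ", mism[1])
  }
  check_one(prot_a, cds_a, "a")
  check_one(prot_b, cds_b, "b")
  pa <- strsplit(prot_a, "")[[1]]; pb <- strsplit(prot_b, "")[[1]]
  cod_a <- split_codons(cds_a); cod_b <- split_codons(cds_b)
  # drop a terminal stop codon if present
  if (length(cod_a) > 0 && cod_a[length(cod_a)] %in% STOP_CODONS)
    cod_a <- cod_a[-length(cod_a)]
  if (length(cod_b) > 0 && cod_b[length(cod_b)] %in% STOP_CODONS)
    cod_b <- cod_b[-length(cod_b)]
  ia <- 0L; ib <- 0L
  keep_a <- character(); keep_b <- character()
  for (col in seq_along(pa)) {
    ga <- pa[col] == "-"; gb <- pb[col] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga || gb) next
    ca <- cod_a[ia]; cb <- cod_b[ib]
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    keep_a <- c(keep_a, ca); keep_b <- c(keep_b, cb)
  }
  list(a = paste(keep_a, collapse = ""), b = paste(keep_b, collapse = ""))
}

#' Pairwise dN/dS scan over specified gene pairs
#'
#' Computes [ng86()] for each requested pair, labelling rows with their
#' relationship category (`1-1` direct orthologues, `1-2` single-copy
#' versus each of two ohnologues, `O` between ohnologues, `T` between
#' tandem paralogues). Pairs with a missing CDS, unequal CDS lengths (no
#' aligner is invoked) or internal stops are skipped with a warning.
#'
#' @param pairs Data frame: `species_a`, `gene_a`, `species_b`, `gene_b`,
#'   `category`.
#' @param genomes Named list of [species_genome()] carrying `cds_seq`.
#' @return Data frame: pair columns plus `S`, `N`, `Sd`, `Nd`, `dS`, `dN`,
#'   `omega`.
#' @export
pairwise_scan <- function(pairs, genomes) {
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    get_cds <- function(sp, id) {
      g <- genomes[[sp]]$genes
      g$cds_seq[match(id, g$gene_id)]
    }
    ca <- get_cds(p$species_a, p$gene_a)
    cb <- get_cds(p$species_b, p$gene_b)
    if (is.na(ca) || is.na(cb) || nchar(ca) != nchar(cb)) {
      warning(sprintf("pair %s/%s skipped (missing or unalignable CDS)",
                      p$gene_a, p$gene_b))
      next
    }
    res <- tryCatch(ng86(ca, cb), error = function(e) NULL)
    if (is.null(res)) {
      warning(sprintf("pair %s/%s skipped (internal stop)", p$gene_a,
                      p$gene_b))
      next
    }
    rows[[length(rows) + 1L]] <- cbind(
      p, data.frame(S = res$S, N = res$N, Sd = res$Sd, Nd = res$Nd,
                    dS = res$dS, dN = res$dN, omega = res$omega,
                    stringsAsFactors = FALSE))
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    cbind(pairs[0, , drop = FALSE],
          data.frame(S = numeric(), N = numeric(), Sd = numeric(),
                     Nd = numeric(), dS = numeric(), dN = numeric(),
                     omega = numeric()))
  rownames(out) <- NULL
  out
}

#' Derive Table-3-style comparison pairs for one family
#'
#' Builds the comparison set between a non-WGD outgroup species and a WGD
#' species from a family call: `1-1` when both are single-copy, `1-2` when
#' the WGD species retains two ohnologues, `O` between the two ohnologues,
#' and `T` between tandem paralogues within either species.
#'
#' @param call A `family_call` from [classify_family()].
#' @param genomes Named list of [species_genome()].
#' @param outgroup_species,wgd_species_id The two species compared.
#' @return Pairs data frame for [pairwise_scan()].
#' @export
family_pairs <- function(call, genomes, outgroup_species, wgd_species_id) {
  fam <- call$family_id
  genes_of <- function(sp) {
    g <- genomes[[sp]]$genes
    c_sort(g$gene_id[g$family_id == fam & !g$pseudogene])
  }
  ga <- genes_of(outgroup_species)
  gb <- genes_of(wgd_species_id)
  rows <- list()
  add <- function(sa, a, sb, b, cat) rows[[length(rows) + 1L]] <<-
    data.frame(species_a = sa, gene_a = a, species_b = sb, gene_b = b,
               category = cat, stringsAsFactors = FALSE)
  # ohnologue membership in the WGD species, if any
  lin <- call$evidence$wgd_lineages
  ohno_sets <- if (length(lin) > 0)
    list(intersect(lin[[1]]$a, gb), intersect(lin[[1]]$b, gb))
  else list(gb, character())
  if (length(ga) >= 1 && length(gb) >= 1) {
    both <- lengths(ohno_sets) >= 1
    cat_ab <- if (all(both)) "1-2" else "1-1"
    for (b in gb) add(outgroup_species, ga[1], wgd_species_id, b, cat_ab)
  }
  if (all(lengths(ohno_sets) >= 1))
    add(wgd_species_id, ohno_sets[[1]][1], wgd_species_id,
        ohno_sets[[2]][1], "O")
  for (sp in c(outgroup_species, wgd_species_id)) {
    gs <- genes_of(sp)
    for (side in if (sp == wgd_species_id) ohno_sets else list(gs)) {
      if (length(side) >= 2)
        add(sp, side[1], sp, side[2], "T")
    }
  }
  if (length(rows) == 0)
    return(data.frame(species_a = character(), gene_a = character(),
                      species_b = character(), gene_b = character(),
                      category = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
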