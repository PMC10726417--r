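# Codon machinery and sequence evolution along branches.
#
# CDS sequences evolve under a per-site nucleotide substitution process with
# a transition/transversion ratio (kappa); substitutions that would create a
# premature stop codon are suppressed unless the gene is being
# pseudogenized, in which case exactly one internal stop is written into the
# homeodomain-encoding span. Homeodomain amino-acid sequences are the
# translation of the CDS (the simulator keeps CDS = the 60-codon
# homeodomain ORF). A plain amino-acid process is available for inputs that
# carry a homeodomain but no CDS.

BASES <- c("A", "C", "G", "T")

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}
.CODON_AA <- NULL
codon_aa <- function() {
  if (is.null(.CODON_AA)) {
    tab <- codon_table()
    utils::assignInMyNamespace(".CODON_AA", tab)
  }
  .CODON_AA
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() setdiff(names(codon_table()), STOP_CODONS)

#' Translate a coding sequence (standard genetic code)
#' @param cds Nucleotide string, length divisible by 3. Stop codons
#'   translate to `*`.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  assert_that(nchar(cds) %% 3 == 0, "CDS length must be divisible by 3")
  if (nchar(cds) == 0) return("")
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- codon_aa()[cods]
  if (anyNA(aa)) stop2("CDS contains non-ACGT codon(s): ",
                       paste(unique(cods[is.na(aa)]), collapse = ", "))
  paste(aa, collapse = "")
}

is_transition <- function(from, to) {
  (from %in% c("A", "G") & to %in% c("A", "G")) |
    (from %in% c("C", "T") & to %in% c("C", "T"))
}

# One branch of CDS evolution. Proposed substitutions: Poisson(rate*t*L)
# events, site uniform, target base with transition weight kappa. Proposals
# creating an internal stop are suppressed (never applied, not counted)
# unless `allow_stop`. Returns list(seq, n_sub = applied substitutions).
evolve_cds_branch <- function(cds, t, rate, kappa = 2, allow_stop = FALSE) {
  L <- nchar(cds)
  n_ev <- stats::rpois(1, rate * t * L)
  if (n_ev == 0 || L == 0) return(list(seq = cds, n_sub = 0L))
  s <- strsplit(cds, "")[[1]]
  aa_tab <- codon_aa()
  n_app <- 0L
  for (k in seq_len(n_ev)) {
    site <- sample.int(L, 1)
    from <- s[site]
    others <- BASES[BASES != from]
    w <- ifelse(is_transition(from, others), kappa, 1)
    to <- sample(others, 1, prob = w)
    ci <- (site - 1L) %/% 3L
    cod <- s[(ci * 3L + 1L):(ci * 3L + 3L)]
    cod[(site - 1L) %% 3L + 1L] <- to
    new_aa <- aa_tab[paste(cod, collapse = "")]
    if (!allow_stop && identical(unname(new_aa), "*")) next
    s[site] <- to
    n_app <- n_app + 1L
  }
  list(seq = paste(s, collapse = ""), n_sub = n_app)
}

# Amino-acid branch process: Poisson(rate*t*L) substitutions, site uniform,
# replacement uniform over the other 19 residues.
evolve_aa_branch <- function(aa, t, rate) {
  L <- nchar(aa)
  n_ev <- stats::rpois(1, rate * t * L)
  if (n_ev == 0 || L == 0) return(list(seq = aa, n_sub = 0L))
  AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  s <- strsplit(aa, "")[[1]]
  for (k in seq_len(n_ev)) {
    site <- sample.int(L, 1)
    s[site] <- sample(AA[AA != s[site]], 1)
  }
  list(seq = paste(s, collapse = ""), n_sub = n_ev)
}

# Write exactly one internal stop codon into the homeodomain span
# (codons 2..(n-1) of the span) of a CDS.
pseudogenize_cds <- function(cds, hd_from_codon = 1L,
                             hd_n_codons = nchar(cds) %/% 3) {
  n <- nchar(cds) %/% 3
  lo <- hd_from_codon + 1L
  hi <- min(hd_from_codon + hd_n_codons - 2L, n - 1L)
  if (hi < lo) lo <- hi <- max(2L, min(n - 1L, hd_from_codon))
  ci <- if (hi > lo) sample(lo:hi, 1) else lo
  stop_cod <- sample(STOP_CODONS, 1)
  paste0(substr(cds, 1, (ci - 1) * 3), stop_cod,
         substr(cds, ci * 3 + 1, nchar(cds)))
}

# Random sense-codon CDS of n codons.
random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

#' Evolve sequences down a species tree
#'
#' Evolves a set of root CDS sequences independently along every branch of
#' a rooted tree and returns the per-leaf sequences. Used by the genome
#' simulator and directly testable: with rate 0 the leaves equal the root;
#' expected substitution counts scale as rate x branch length x sites.
#'
#' @param root_seqs Named character vector of root CDS sequences (lengths
#'   divisible by 3).
#' @param phy Rooted `ape::phylo` with branch lengths.
#' @param rate Substitutions per nucleotide site per branch-length unit.
#' @param kappa Transition/transversion rate ratio.
#' @return Named list (by leaf label) of named character vectors of leaf
#'   sequences, with attribute `n_sub`: total substitutions applied.
#' @export
evolve_sequences <- function(root_seqs, phy, rate, kappa = 2) {
  assert_that(inherits(phy, "phylo") && ape::is.rooted(phy),
              "phy must be a rooted tree")
  assert_that(all(nchar(root_seqs) %% 3 == 0),
              "root CDS lengths must be divisible by 3")
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  out <- vector("list", ntip)
  names(out) <- phy$tip.label
  total <- 0L
  recurse <- function(node, seqs) {
    for (ei in children[[as.character(node)]] %||% integer(0)) {
      child <- phy$edge[ei, 2]
      t <- phy$edge.length[ei] %||% 1
      evolved <- vapply(seqs, function(s) {
        r <- evolve_cds_branch(s, t, rate, kappa)
        total <<- total + r$n_sub
        r$seq
      }, "")
      if (child <= ntip) out[[phy$tip.label[child]]] <<- evolved
      else recurse(child, evolved)
    }
  }
  recurse(root, root_seqs)
  attr(out, "n_sub") <- total
  out
}

#' Simulate a diverged codon-sequence pair under mutation-selection
#'
#' Evolves two copies of a random sense-codon ancestor, each for `t/2`
#' expected substitutions per site: nucleotide proposals with
#' transition/transversion ratio `kappa`; nonsynonymous proposals accepted
#' with probability `omega`; stop-creating proposals always rejected. The
#' null harness for the dN/dS counting method (`omega = 1`: neutral;
#' `omega` well below 1: purifying).
#'
#' @param n_codons Sequence length in codons.
#' @param t Total expected proposals per nucleotide site across the pair.
#' @param omega Acceptance probability of nonsynonymous proposals.
#' @param kappa Transition/transversion rate ratio.
#' @return List `a`, `b`: the two diverged coding sequences.
#' @export
simulate_codon_pair <- function(n_codons, t, omega = 1, kappa = 1) {
  anc <- random_cds(n_codons)
  aa_tab <- codon_aa()
  evolve_sel <- function(cds, tt) {
    L <- nchar(cds)
    n_ev <- stats::rpois(1, tt * L)
    s <- strsplit(cds, "")[[1]]
    for (k in seq_len(n_ev)) {
      site <- sample.int(L, 1)
      from <- s[site]
      others <- BASES[BASES != from]
      w <- ifelse(is_transition(from, others), kappa, 1)
      to <- sample(others, 1, prob = w)
      ci <- (site - 1L) %/% 3L
      cod <- s[(ci * 3L + 1L):(ci * 3L + 3L)]
      old_aa <- unname(aa_tab[paste(cod, collapse = "")])
      cod[(site - 1L) %% 3L + 1L] <- to
      new_aa <- unname(aa_tab[paste(cod, collapse = "")])
      if (new_aa == "*") next
      if (new_aa != old_aa && stats::runif(1) > omega) next
      s[site] <- to
    }
    paste(s, collapse = "")
  }
  list(a = evolve_sel(anc, t / 2), b = evolve_sel(anc, t / 2))
}
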