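test_that("similarity scoring ranks consensus matches and honors diagnostics", {
  set.seed(101)
  cons <- c(famA = random_aa(60), famB = random_aa(60))
  cat_ <- toy_catalog(cons)
  sc <- score_family(cons[["famA"]], cat_)
  expect_equal(sc$family_id[1], "famA")
  expect_equal(sc$similarity[1], 1.0)

  # 6/60 mismatches avoiding diagnostic sites -> similarity 0.9, pass TRUE
  cat_d <- toy_catalog(cons["famA"],
                       diagnostics = sprintf("1:%s;2:%s",
                                             substr(cons[["famA"]], 1, 1),
                                             substr(cons[["famA"]], 2, 2)))
  q <- strsplit(cons[["famA"]], "")[[1]]
  alt <- function(a) setdiff(c("A", "C", "D", "E"), a)[1]
  for (p in 10:15) q[p] <- alt(q[p])
  sc2 <- score_family(paste(q, collapse = ""), cat_d)
  expect_equal(sc2$similarity, 0.9)
  expect_true(sc2$diagnostic_pass)

  # equidistant from two consensuses: the diagnostic-passing family wins
  base <- strsplit(cons[["famA"]], "")[[1]]
  c2 <- base; c2[5] <- alt(base[5])  # famC differs at a site famB-diag fails
  cons3 <- c(famA = cons[["famA"]], famC = paste(c2, collapse = ""))
  q3 <- base; q3[30] <- alt(base[30])
  # query differs from famA by 1 (site 30) and from famC by 2 (5, 30)
  cat3 <- toy_catalog(cons3,
                      diagnostics = c(sprintf("5:%s", alt(base[5])), ""))
  # famA fails its diagnostic at site 5, famC passes vacuously
  sc3 <- score_family(paste(q3, collapse = ""), cat3)
  expect_equal(sc3$family_id[1], "famC")
  expect_true(sc3$diagnostic_pass[1])
  expect_false(sc3$diagnostic_pass[2])

  expect_error(score_family(paste(rep("J", 60), collapse = ""), cat_),
               "non-amino-acid")
  expect_error(score_family(random_aa(40), cat_), "55-65")
})

test_that("assignment labels all consensus sequences and rejects noise", {
  set.seed(11)
  cons <- stats::setNames(vapply(1:20, function(i) random_aa(60), ""),
                          sprintf("fam%02d", 1:20))
  cat_ <- toy_catalog(cons)
  genes <- mk_genes("c1", rep("UNASSIGNED", 20))
  genes$homeodomain_seq <- unname(cons)
  g <- assign_families(species_genome("s", genes), cat_)
  expect_equal(g$genes$family_id, names(cons)[match(g$genes$homeodomain_seq,
                                                    cons)])
  # random sequences sit near background identity (~1/20) and stay
  # unassigned at the 0.55 threshold
  genes2 <- mk_genes("c2", rep("x", 10), ids = sprintf("r%02d", 1:10))
  genes2$family_id <- "UNASSIGNED"
  genes2$homeodomain_seq <- vapply(1:10, function(i) random_aa(60), "")
  g2 <- assign_families(species_genome("s2", genes2), cat_)
  expect_true(all(g2$genes$family_id == "UNASSIGNED"))
})

test_that("assignment is order-invariant and monotone in the threshold", {
  set.seed(12)
  cons <- stats::setNames(vapply(1:10, function(i) random_aa(60), ""),
                          sprintf("fam%02d", 1:10))
  cat_ <- toy_catalog(cons)
  genes <- mk_genes("c1", rep("UNASSIGNED", 10))
  genes$homeodomain_seq <- vapply(seq_len(10), function(i) {
    q <- strsplit(cons[[i]], "")[[1]]
    flip <- sample(60, sample(0:35, 1))
    for (p in flip) q[p] <- sample(setdiff(LETTERS[LETTERS %in%
      strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]], q[p]), 1)
    paste(q, collapse = "")
  }, "")
  g1 <- assign_families(species_genome("s", genes), cat_)
  perm <- sample(nrow(genes))
  g2 <- assign_families(species_genome("s", genes[perm, ]), cat_)
  expect_identical(g1$genes, g2$genes)
  for (thr in c(0.3, 0.5, 0.7, 0.9)) {
    lo <- assign_families(species_genome("s", genes), cat_, thr)
    hi <- assign_families(species_genome("s", genes), cat_, thr + 0.1)
    expect_true(sum(hi$genes$family_id != "UNASSIGNED") <=
                  sum(lo$genes$family_id != "UNASSIGNED"))
  }
})

test_that("simulated families are recovered exactly at zero divergence and >=99% at default", {
  st <- default_species_tree()
  cfg0 <- sim_config(seed = 8L, n_families = 40L, n_chromosomes = 3L,
                     codon_substitution_rate = 0, pseudogenize_prob = 0)
  sim0 <- simulate_genomes(st, cfg0)
  for (sp in c("Dmel", "Ptep")) {
    g <- assign_families(sim0$genomes[[sp]], sim0$catalog)
    expect_equal(g$genes$family_id, sim0$genomes[[sp]]$genes$family_id)
  }
  sim <- simulate_genomes(st, sim_config(seed = 8L, n_families = 40L,
                                         n_chromosomes = 3L))
  hits <- 0L; tot <- 0L
  for (sp in names(sim$genomes)) {
    g <- assign_families(flag_pseudogenes(sim$genomes[[sp]]), sim$catalog)
    live <- !g$genes$pseudogene
    hits <- hits + sum(g$genes$family_id[live] ==
                         sim$genomes[[sp]]$genes$family_id[live])
    tot <- tot + sum(live)
  }
  expect_gte(hits / tot, 0.99)
})

test_that("pseudogene flagging requires an internal homeodomain stop", {
  genes <- mk_genes("c1", c("f1", "f2", "f3"))
  ok <- hoxwgd:::random_cds(20)
  internal <- paste0(substr(ok, 1, 30), "TAA", substr(ok, 34, 60))
  terminal <- paste0(substr(ok, 1, 57), "TAA")
  genes$cds_seq <- c(ok, internal, terminal)
  genes$pseudogene <- FALSE
  g <- flag_pseudogenes(species_genome("s", genes))
  expect_equal(g$genes$pseudogene, c(FALSE, TRUE, FALSE))
})

test_that("simulator-pseudogenized genes are all flagged", {
  st <- toy_species_tree()
  cfg <- sim_config(seed = 14L, n_families = 30L, n_chromosomes = 2L,
                    pseudogenize_prob = 0.2)
  sim <- simulate_genomes(st, cfg)
  n_pseudo <- 0L
  for (sp in names(sim$genomes)) {
    truth_flag <- sim$genomes[[sp]]$genes$pseudogene
    g <- sim$genomes[[sp]]
    g$genes$pseudogene <- FALSE
    called <- flag_pseudogenes(g)$genes$pseudogene
    expect_equal(called, truth_flag, info = sp)
    n_pseudo <- n_pseudo + sum(truth_flag)
  }
  expect_gt(n_pseudo, 0L)
})

test_that("novel families need two species; grouping equals brute-force components", {
  set.seed(33)
  cons <- stats::setNames(vapply(1:5, function(i) random_aa(60), ""),
                          sprintf("fam%02d", 1:5))
  cat_ <- toy_catalog(cons, classes = c("ANTP", "PRD", "LIM", "SINE",
                                        "TALE"))
  novel <- random_aa(60)
  novel2 <- {
    q <- strsplit(novel, "")[[1]]; q[1:3] <- c("A", "A", "A")
    paste(q, collapse = "")
  }
  lone <- random_aa(60)
  mk <- function(sp, seqs, ids) {
    genes <- mk_genes("c1", rep("UNASSIGNED", length(seqs)), ids = ids)
    genes$homeodomain_seq <- seqs
    species_genome(sp, genes)
  }
  gA <- mk("spA", c(novel, lone), c("a1", "a2"))
  gB <- mk("spB", novel2, "b1")
  res <- detect_new_families(list(spA = gA, spB = gB), cat_)
  grp <- res$new_family[match(c("a1", "b1"), res$gene_id)]
  expect_equal(length(unique(grp)), 1L)
  expect_match(grp[1], "-un1$")
  expect_equal(res$new_family[res$gene_id == "a2"], "unclassified")

  # oracle: single-linkage groups = connected components of the >=0.8 graph
  set.seed(34)
  seqs <- c(vapply(1:4, function(i) random_aa(60), ""))
  seqs <- c(seqs, vapply(seqs, function(s) {
    q <- strsplit(s, "")[[1]]; q[1:5] <- "G"; paste(q, collapse = "")
  }, ""))
  ids <- sprintf("g%02d", seq_along(seqs))
  gs <- list(s1 = mk("s1", seqs[1:4], ids[1:4]),
             s2 = mk("s2", seqs[5:8], ids[5:8]))
  res2 <- detect_new_families(gs, cat_, cross_similarity = 0.8)
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n)
    adj[i, j] <- hoxwgd:::pairwise_hd_similarity(seqs[i], seqs[j]) >= 0.8
  comp <- seq_len(n)
  repeat {
    new <- vapply(1:n, function(i) min(comp[adj[i, ]]), 1)
    if (identical(new, comp)) break
    comp <- new
  }
  got <- res2$new_family[match(ids, res2$gene_id)]
  for (i in 1:n) for (j in 1:n) {
    if (got[i] == "unclassified" || got[j] == "unclassified") next
    expect_equal(comp[i] == comp[j], got[i] == got[j])
  }
})
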