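test_that("linkage relations follow the chromosome/gap/distance rules", {
  genes <- rbind(mk_genes("c1", c("f1", "x", "f2"), step = 25000L),
                 mk_genes("c1", "f3", start0 = 40e6, ids = "far1"),
                 mk_genes("c2", "f4"))
  g <- species_genome("s", genes)
  ids <- g$genes$gene_id[match(c("f1", "f2", "f3", "f4"),
                               g$genes$family_id)]
  adj <- classify_linkage(ids[1], ids[2], g)
  expect_equal(adj$relation, "clustered")
  expect_equal(adj$intervening_gene_count, 1L)
  far <- classify_linkage(ids[1], ids[3], g)
  expect_equal(far$relation, "linked")  # ~40 Mb apart: linked, not clustered
  expect_gt(far$distance_bp, 1e6)
  expect_equal(classify_linkage(ids[1], ids[4], g)$relation, "dispersed")
  expect_error(classify_linkage(ids[1], ids[1], g), "differ")
})

test_that("reconciliation marks duplications and WGD compatibility on worked cases", {
  st <- toy_species_tree()  # ((A,B)WGD,(C,D))
  gt <- as_gene_tree(ape::read.tree(text = "((A|g1,B|g1),(A|g2,B|g2));"))
  rec <- reconcile(gt, st)
  root_row <- rec[!rec$is_leaf & rec$node == ape::Ntip(gt) + 1L, ]
  expect_equal(root_row$type, "duplication")
  expect_true(root_row$wgd_compatible)
  inner <- rec[!rec$is_leaf & rec$node != ape::Ntip(gt) + 1L, ]
  expect_true(all(inner$type == "speciation"))

  # congruent single-copy topology: all speciations
  gt2 <- as_gene_tree(ape::read.tree(
    text = "((A|g1,B|g1),(C|g1,D|g1));"))
  rec2 <- reconcile(gt2, st)
  expect_true(all(rec2$type[!rec2$is_leaf] == "speciation"))

  expect_error(
    reconcile(as_gene_tree(ape::read.tree(text = "(A|g1,Z|g1);")), st),
    "not in species tree")
})

test_that("reconciliation equals the brute-force LCA oracle on random gene trees", {
  st <- default_species_tree()
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    gt <- random_gene_tree(n, st$phy$tip.label)
    got <- reconcile(gt, st)
    want <- oracle_reconcile(gt, st)
    expect_identical(got$type, want$type)
    expect_identical(got$mapped_node, want$mapped_node)
  }
})

test_that("worked family classifications: O, AT, SC", {
  st <- default_species_tree()
  wgd_sp <- clade_species(st, st$wgd_node)
  out_sp <- setdiff(st$phy$tip.label, wgd_sp)

  mk_genome <- function(sp, fams, chrs) {
    genes <- do.call(rbind, lapply(seq_along(fams), function(i)
      mk_genes(chrs[i], fams[i], ids = sprintf("%s_%d", sp, i))))
    species_genome(sp, genes)
  }

  # O: two dispersed copies in every WGD leaf, one elsewhere
  genomes <- c(
    lapply(stats::setNames(wgd_sp, wgd_sp), function(sp)
      mk_genome(sp, c("famO", "famO"), c("c1", "c2"))),
    lapply(stats::setNames(out_sp, out_sp), function(sp)
      mk_genome(sp, "famO", "c1")))
  tips_a <- paste0(wgd_sp, "|", wgd_sp, "_1")
  tips_b <- paste0(wgd_sp, "|", wgd_sp, "_2")
  prune_to <- function(tips) {
    sp_of <- sub("\\|.*", "", tips)
    tr <- ape::keep.tip(st$phy, sp_of)
    tr$tip.label <- tips[match(tr$tip.label, sp_of)]
    tr$node.label <- NULL
    tr$edge.length <- NULL
    tr
  }
  chop <- function(tr) sub(";$", "", ape::write.tree(tr))
  nwk <- sprintf("((%s,%s),%s);", chop(prune_to(tips_a)),
                 chop(prune_to(tips_b)),
                 paste0(out_sp[1], "|", out_sp[1], "_1"))
  gt <- as_gene_tree(ape::read.tree(text = nwk))
  call <- classify_family("famO", genomes, gt, st)
  expect_equal(call$category, "O")
  expect_equal(call$duplication_branch, "WGD")

  # SC: one copy everywhere, congruent tree
  genomes_sc <- lapply(stats::setNames(st$phy$tip.label, st$phy$tip.label),
                       function(sp) mk_genome(sp, "famS", "c1"))
  tipsS <- paste0(st$phy$tip.label, "|", st$phy$tip.label, "_1")
  call_sc <- classify_family("famS", genomes_sc,
                             as_gene_tree(prune_to(tipsS)), st)
  expect_equal(call_sc$category, "SC")

  # AT: duplication in the harvestman+arachnopulmonate ancestor, copies
  # clustered in the carriers
  at_sp <- c("Popi", wgd_sp)
  genomes_at <- c(
    lapply(stats::setNames(at_sp, at_sp), function(sp) {
      genes <- mk_genes("c1", c("famT", "famT"), step = 60000L,
                        ids = paste0(sp, "_", 1:2))
      species_genome(sp, genes)
    }),
    lapply(stats::setNames(setdiff(out_sp, "Popi"),
                           setdiff(out_sp, "Popi")), function(sp)
      mk_genome(sp, "famT", "c1")))
  t1 <- paste0(at_sp, "|", at_sp, "_1")
  t2 <- paste0(at_sp, "|", at_sp, "_2")
  gt_at <- as_gene_tree(ape::read.tree(text = sprintf(
    "((%s,%s),%s);", chop(prune_to(t1)), chop(prune_to(t2)),
    "Isca|Isca_1")))
  call_at <- classify_family("famT", genomes_at, gt_at, st)
  expect_equal(call_at$category, "AT")
  expect_equal(call_at$duplication_branch, "popiclade")
})

test_that("Dollo loss mapping places stem losses and matches the exhaustive oracle", {
  st <- default_species_tree()
  wgd_sp <- clade_species(st, st$wgd_node)
  # present everywhere below the WGD: no losses
  expect_equal(dollo_losses(wgd_sp, st)$n_losses, 0L)
  # present only in the scorpion among WGD taxa: one loss on the spider stem
  dl <- dollo_losses("Cscu", st)
  expect_equal(dl$n_losses, 1L)
  expect_equal(dl$branches, "spiders")
  # absent only from entelegynes: one loss on the entelegyne stem
  dl2 <- dollo_losses(c("Cscu", "Dsil"), st)
  expect_equal(dl2$n_losses, 1L)
  expect_equal(dl2$branches, "entelegynes")

  # exhaustive check over all 63 nonempty patterns on a 6-leaf tree
  phy6 <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):2)r;")
  st6 <- species_tree_wgd(phy6, c("a", "b"))
  tips <- phy6$tip.label
  root <- ape::Ntip(phy6) + 1L
  for (mask in 1:63) {
    pres <- tips[bitwAnd(mask, 2^(0:5)) > 0]
    got <- dollo_losses(pres, st6, gain_node = root)$n_losses
    expect_equal(got, oracle_dollo_min(pres, st6), info = mask)
  }
})

test_that("infer_losses refines presence patterns into SOL/EOL", {
  st <- default_species_tree()
  wgd_sp <- clade_species(st, st$wgd_node)
  species <- st$phy$tip.label
  m <- matrix(0L, 3, length(species), dimnames = list(
    c("all", "sol", "eol"), species))
  m["all", wgd_sp] <- 1L
  m["sol", "Cscu"] <- 1L
  m["eol", c("Cscu", "Dsil")] <- 1L
  res <- infer_losses(m, st)
  expect_equal(res$pattern, c("none", "SOL", "EOL"))
  expect_equal(res$n_losses, c(0L, 1L, 1L))
})

test_that("classification is deterministic under gene-row permutations", {
  st <- default_species_tree()
  sim <- simulate_genomes(st, small_sim_config(seed = 55L))
  genomes <- lapply(sim$genomes, function(g)
    assign_families(flag_pseudogenes(g), sim$catalog))
  calls1 <- classify_all_families(genomes, sim$gene_trees, st)
  set.seed(1)
  genomes2 <- lapply(genomes, function(g)
    species_genome(g$species_id, g$genes[sample(nrow(g$genes)), ],
                   g$chromosomes))
  calls2 <- classify_all_families(genomes2, sim$gene_trees, st)
  expect_identical(calls1[, c("family_id", "category")],
                   calls2[, c("family_id", "category")])
})

test_that("repertoire summaries count categories consistently", {
  st <- default_species_tree()
  sim <- simulate_genomes(st, small_sim_config(seed = 77L))
  genomes <- lapply(sim$genomes, function(g)
    assign_families(flag_pseudogenes(g), sim$catalog))
  calls <- classify_all_families(genomes, sim$gene_trees, st)
  s <- summarize_repertoire(genomes, calls, st)
  expect_equal(nrow(s$table), 14L)
  for (i in seq_len(nrow(s$table))) {
    r <- s$table[i, ]
    g <- genomes[[r$species_id]]$genes
    live <- g[!g$pseudogene & g$family_id != "UNASSIGNED", , drop = FALSE]
    expect_lte(r$single_copy_families + r$retained_ohnologue_families,
               r$families_present)
    expect_equal(r$families_present, length(unique(live$family_id)))
    expect_gte(r$total_genes, r$families_present)
  }
  # empty genomes: ratio undefined -> NA
  empty <- lapply(genomes, function(g)
    species_genome(g$species_id, hoxwgd:::empty_gene_table()))
  s0 <- summarize_repertoire(empty, calls[0, ], st)
  expect_true(is.na(s0$ratio))
  expect_true(all(s0$table$total_genes == 0))
})
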