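quiet_cfg <- function(...) small_sim_config(...)

zero_rates <- function(seed = 3L, pseudogenize_prob = 0, ...) {
  sim_config(seed = seed, n_families = 12L, n_chromosomes = 2L,
             cluster_templates = list(Hox = sprintf("Hox%02d", 1:4)),
             tandem_duplication = 0, dispersed_duplication = 0,
             gene_loss = 0, redundant_loss = 0, inversion = 0,
             translocation = 0, fusion_prob = 0, fission_prob = 0,
             codon_substitution_rate = 0,
             pseudogenize_prob = pseudogenize_prob, ...)
}

test_that("with all rates zero, non-WGD leaves equal the root and the WGD doubles", {
  st <- toy_species_tree()  # WGD above (A,B)
  sim <- simulate_genomes(st, zero_rates())
  expect_setequal(unique(sim$event_log$type), c("speciation", "wgd"))
  # outgroup leaves: identical to the root complement
  for (sp in c("C", "D")) {
    g <- sim$genomes[[sp]]$genes
    expect_equal(nrow(g), 12L)
    expect_equal(length(unique(g$chromosome_id)), 2L)
  }
  expect_identical(sim$genomes$C$genes$cds_seq, sim$genomes$D$genes$cds_seq)
  # WGD leaves: exactly 2F genes on 2x chromosomes, every family twice
  for (sp in c("A", "B")) {
    g <- sim$genomes[[sp]]$genes
    expect_equal(nrow(g), 24L)
    expect_equal(length(unique(g$chromosome_id)), 4L)
    expect_true(all(table(g$family_id) == 2))
  }
  expect_true(all(sim$truth$category == "O"))
})

test_that("a fixed seed reproduces the simulation byte-for-byte; seeds differ", {
  st <- toy_species_tree()
  s1 <- simulate_genomes(st, small_sim_config(seed = 21L))
  s2 <- simulate_genomes(st, small_sim_config(seed = 21L))
  s3 <- simulate_genomes(st, small_sim_config(seed = 22L))
  expect_identical(s1$event_log, s2$event_log)
  expect_identical(lapply(s1$genomes, `[[`, "genes"),
                   lapply(s2$genomes, `[[`, "genes"))
  expect_false(identical(s1$event_log, s3$event_log))
})

test_that("replaying the event log reconstructs every leaf genome exactly", {
  st <- default_species_tree()
  sim <- simulate_genomes(st, small_sim_config(seed = 13L))
  rg <- replay_event_log(sim)
  cols <- c("gene_id", "chromosome_id", "start", "end", "strand",
            "pseudogene")
  for (sp in names(sim$genomes))
    expect_identical(rg[[sp]]$genes[, cols], sim$genomes[[sp]]$genes[, cols],
                     info = sp)
})

test_that("leaf gene counts equal root + duplications - losses per the log", {
  st <- toy_species_tree()
  sim <- simulate_genomes(st, small_sim_config(seed = 17L))
  ev <- sim$event_log
  # count per leaf by walking the branch path
  ix <- hoxwgd:::index_species_tree(st)
  for (sp in names(sim$genomes)) {
    tip <- ix$tip_of[[sp]]
    path_nodes <- ix$ancestors[[tip]]
    on_path <- ev[ev$branch_node %in% path_nodes, , drop = FALSE]
    n_dup <- sum(on_path$type %in% c("tandem_dup", "dispersed_dup"))
    n_wgd_children <- sum(vapply(seq_len(nrow(on_path)), function(i)
      if (on_path$type[i] == "wgd")
        length(strsplit(on_path$extra[i], ";", fixed = TRUE)[[1]]) else 0L,
      1L))
    n_loss <- sum(on_path$type == "loss")
    expect_equal(nrow(sim$genomes[[sp]]$genes),
                 sim$config$n_families + n_dup + n_wgd_children - n_loss,
                 info = sp)
  }
})

test_that("without dispersal or rearrangement, tandem children stay on the parent chromosome", {
  st <- toy_species_tree()
  cfg <- sim_config(seed = 5L, n_families = 30L, n_chromosomes = 3L,
                    tandem_duplication = 0.1, dispersed_duplication = 0,
                    inversion = 0, translocation = 0, fusion_prob = 0,
                    fission_prob = 0)
  sim <- simulate_genomes(st, cfg)
  td <- sim$event_log[sim$event_log$type == "tandem_dup", , drop = FALSE]
  for (sp in names(sim$genomes)) {
    g <- sim$genomes[[sp]]$genes
    chr_of <- stats::setNames(g$chromosome_id, g$gene_id)
    for (i in seq_len(nrow(td))) {
      p <- td$parent_gene[i]; ch <- td$child_gene[i]
      if (p %in% names(chr_of) && ch %in% names(chr_of))
        expect_equal(unname(chr_of[p]), unname(chr_of[ch]))
    }
  }
})

test_that("true gene trees are consistent with the event log", {
  st <- toy_species_tree()
  sim <- simulate_genomes(st, small_sim_config(seed = 29L))
  # every gene-tree leaf is an extant gene of that species and family
  for (f in names(sim$gene_trees)) {
    gt <- sim$gene_trees[[f]]
    if (is.null(gt)) next
    lv <- split_leaf_labels(gt$tip.label)
    for (k in seq_len(nrow(lv))) {
      g <- sim$genomes[[lv$species_id[k]]]$genes
      expect_true(lv$gene_id[k] %in% g$gene_id)
      expect_equal(g$family_id[g$gene_id == lv$gene_id[k]], f)
    }
  }
  # a logged tandem duplication with both children extant appears as an
  # internal node: the child's leaves must be a clade-mate subset
  td <- sim$event_log[sim$event_log$type == "tandem_dup", , drop = FALSE]
  reg <- sim$registry
  fam_of <- stats::setNames(reg$family_id, reg$gene_id)
  parent_map <- stats::setNames(reg$dup_parent, reg$gene_id)
  descends_from <- function(gid, anc) {
    repeat {
      if (gid == anc) return(TRUE)
      p <- parent_map[[gid]]
      if (is.na(p)) return(FALSE)
      gid <- p
    }
  }
  for (i in seq_len(nrow(td))) {
    f <- fam_of[[td$child_gene[i]]]
    gt <- sim$gene_trees[[f]]
    if (is.null(gt)) next
    lv <- split_leaf_labels(gt$tip.label)
    kids <- vapply(lv$gene_id, descends_from, TRUE, anc = td$child_gene[i])
    if (!any(kids)) next
    expect_true(sum(kids) == length(gt$tip.label) ||
                  ape::is.monophyletic(gt, gt$tip.label[kids]))
  }
})

test_that("sequence evolution matches its expectation and respects rate 0", {
  phy <- ape::read.tree(text = "(X:1,Y:1);")
  seqs <- stats::setNames(vapply(1:3, function(i) hoxwgd:::random_cds(60), ""),
                          paste0("s", 1:3))
  set.seed(2)
  out0 <- evolve_sequences(seqs, phy, rate = 0)
  expect_identical(out0$X, seqs)
  expect_identical(out0$Y, seqs)
  # Monte-Carlo: total applied substitutions over replicates close to
  # rate x branch length x sites (slightly below: stop-creating proposals
  # are suppressed)
  set.seed(7)
  rate <- 0.05; L <- 180; reps <- 100
  tot <- sum(replicate(reps, attr(evolve_sequences(seqs[1], phy, rate), "n_sub")))
  expected <- rate * 2 * L * reps  # two branches of length 1
  expect_lt(abs(tot - expected), 3 * sqrt(expected) + 0.05 * expected)
})

test_that("pseudogenization probability 1 on a branch stops all that leaf's genes", {
  st <- toy_species_tree()
  cfg <- zero_rates(seed = 9L,
                    pseudogenize_prob = c(C = 1, .default = 0))
  sim <- simulate_genomes(st, cfg)
  gC <- sim$genomes$C$genes
  expect_true(all(gC$pseudogene))
  expect_true(all(grepl("\\*", substr(gC$homeodomain_seq, 2,
                                      nchar(gC$homeodomain_seq) - 1))))
  expect_false(any(sim$genomes$D$genes$pseudogene))
})

test_that("fixtures round-trip and are deterministic for a seed", {
  st <- toy_species_tree()
  sim <- simulate_genomes(st, small_sim_config(seed = 31L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(sim, d1)
  write_fixture(simulate_genomes(st, small_sim_config(seed = 31L)), d2)
  for (f in list.files(d1, recursive = TRUE))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  back <- read_gene_table(file.path(d1, "A.gff3"), "gff3", "A")
  cols <- c("gene_id", "chromosome_id", "start", "end", "strand",
            "family_id", "pseudogene")
  expect_identical(back$genes[, cols], sim$genomes$A$genes[, cols])
  st_back <- read_tree(file.path(d1, "species_tree.nwk"))
  expect_setequal(clade_species(st_back, st_back$wgd_node), c("A", "B"))
  sim3 <- simulate_genomes(st, small_sim_config(seed = 32L))
  expect_false(identical(sim3$event_log, sim$event_log))
})

test_that("rate blow-ups abort with a size error", {
  st <- toy_species_tree()
  cfg <- sim_config(seed = 1L, n_families = 50L, n_chromosomes = 2L,
                    tandem_duplication = 30, gene_loss = 0,
                    redundant_loss = 0, max_genes = 500)
  expect_error(simulate_genomes(st, cfg), "max_genes")
})
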