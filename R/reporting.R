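# Orchestration and packaged reference numbers: the per-species repertoire
# summary table for the 14 arthropod genomes, summary statistics, the
# truth-versus-call recovery harness, and the end-to-end pipeline.

#' Packaged per-species homeobox summary table
#'
#' The published per-species summary for five non-WGD arthropods (fruit
#' fly, beetle, centipede, tick, harvestman) and nine arachnopulmonates
#' (scorpion plus eight spiders): total homeobox genes, families present,
#' families with ancient/recent tandem paralogues, single-copy families,
#' and families with retained ohnologues (WGD species only).
#'
#' @return Data frame, one row per species, with a logical `wgd` column.
#' @export
table2_fixture <- function() {
  species <- c("Dmel", "Tcas", "Smar", "Isca", "Popi", "Cscu", "Dsil",
               "Dpla", "Lele", "Ptep", "Hgra", "Abru", "Tant", "Tcla")
  data.frame(
    species_id = species,
    wgd = c(rep(FALSE, 5), rep(TRUE, 9)),
    total_genes = c(103L, 104L, 114L, 110L, 108L, 161L, 143L, 150L, 152L,
                    151L, 176L, 149L, 147L, 152L),
    families_present = c(83L, 85L, 90L, 89L, 91L, 90L, 79L, 87L, 89L, 91L,
                         86L, 88L, 87L, 89L),
    at_families = c(5L, 5L, 6L, 7L, 8L, 7L, 7L, 8L, 8L, 8L, 8L, 8L, 8L, 8L),
    rt_families = c(9L, 9L, 13L, 8L, 5L, 4L, 8L, 3L, 6L, 4L, 23L, 3L, 2L,
                    5L),
    single_copy_families = c(71L, 71L, 74L, 76L, 81L, 41L, 35L, 41L, 46L,
                             44L, 42L, 45L, 44L, 45L),
    retained_ohnologue_families = c(NA, NA, NA, NA, NA, 46L, 41L, 44L, 41L,
                                    44L, 37L, 40L, 40L, 40L),
    stringsAsFactors = FALSE)
}

#' Summary statistics of a per-species repertoire table
#'
#' @param tab A table shaped like [table2_fixture()] (or the `table`
#'   element of [summarize_repertoire()]).
#' @return List: `ratio` (mean total in WGD species over mean total in
#'   non-WGD species, rounded to 1 dp; `NA` when a group is empty or all
#'   zero), `min_retained`, `max_retained` over WGD species.
#' @export
table2_statistics <- function(tab) {
  ratio <- if (any(tab$wgd) && any(!tab$wgd) && sum(tab$total_genes) > 0)
    round(mean(tab$total_genes[tab$wgd]) /
            mean(tab$total_genes[!tab$wgd]), 1) else NA_real_
  ret <- tab$retained_ohnologue_families[tab$wgd]
  ret <- ret[!is.na(ret)]
  list(ratio = ratio,
       min_retained = if (length(ret) > 0) min(ret) else NA_integer_,
       max_retained = if (length(ret) > 0) max(ret) else NA_integer_)
}

#' Truth-versus-call recovery of a simulation
#'
#' Joins simulator truth labels with classifier calls and reports overall
#' category recovery (over families whose truth is O/AT/RT/SC), stem-loss
#' recovery (over SOL/EOL families), the O-to-RT confusion rate, and the
#' full confusion matrix.
#'
#' @param truth Truth data frame from the simulator (`family_id`,
#'   `category`).
#' @param calls Calls data frame from [classify_all_families()].
#' @return List: `category_recovery`, `sol_eol_recovery`,
#'   `o_rt_confusion`, `n_families`, `confusion` (table).
#' @export
category_recovery <- function(truth, calls) {
  merged <- merge(truth[, c("family_id", "category")],
                  calls[, c("family_id", "category")],
                  by = "family_id", suffixes = c("_truth", "_call"),
                  all.x = TRUE)
  merged <- merged[merged$category_truth != "EXTINCT", , drop = FALSE]
  merged$category_call[is.na(merged$category_call)] <- "ABSENT"
  core <- merged[merged$category_truth %in% c("O", "AT", "RT", "SC"), ,
                 drop = FALSE]
  stem <- merged[merged$category_truth %in% c("SOL", "EOL"), , drop = FALSE]
  conf <- table(truth = merged$category_truth, call = merged$category_call)
  o_rt <- sum(merged$category_truth == "O" & merged$category_call == "RT") +
    sum(merged$category_truth == "RT" & merged$category_call == "O")
  list(
    category_recovery = if (nrow(core) > 0)
      mean(core$category_truth == core$category_call) else NA_real_,
    sol_eol_recovery = if (nrow(stem) > 0)
      mean(stem$category_truth == stem$category_call) else NA_real_,
    o_rt_confusion = o_rt / max(1L, nrow(merged)),
    n_families = nrow(merged),
    confusion = conf)
}

#' Run the full inference pipeline on a simulation
#'
#' Stages, in dependency order: pseudogene flagging, family assignment
#' against the simulator's catalog, per-family duplication typing,
#' repertoire summary, cluster detection/scoring/pairing for every cluster
#' template, chromosome orthology against a reference species, cluster
#' placement, and the truth-recovery report. When `out` is given, each
#' stage writes a TSV stamped with the seed.
#'
#' @param sim A `hoxwgd_sim` from [simulate_genomes()], or `NULL` to
#'   simulate with `species_tree` and `config`.
#' @param species_tree,config Used when `sim` is `NULL`.
#' @param reference_species Reference for macrosynteny (default the first
#'   WGD-clade species in tip order).
#' @param out Optional output directory for TSVs.
#' @return List: `genomes` (reassigned), `calls`, `summary`, `clusters`,
#'   `cluster_pairs`, `synteny`, `located`, `recovery`.
#' @export
run_pipeline <- function(sim = NULL, species_tree = default_species_tree(),
                         config = sim_config(), reference_species = NULL,
                         out = NULL) {
  if (is.null(sim)) sim <- simulate_genomes(species_tree, config)
  st <- sim$species_tree
  wgd_sp <- clade_species(st, st$wgd_node)
  if (is.null(reference_species))
    reference_species <- intersect(st$phy$tip.label, wgd_sp)[2] %||%
      wgd_sp[1]

  # stage 1-2: pseudogene flagging + family assignment from sequence
  genomes <- lapply(sim$genomes, function(g)
    assign_families(flag_pseudogenes(g), sim$catalog))

  # stage 3: duplication typing
  calls <- classify_all_families(genomes, sim$gene_trees, st)

  # stage 4: repertoire summary
  summary <- summarize_repertoire(genomes, calls, st)

  # stage 5: clusters per template, scored and paired per species
  templates <- sim$config$cluster_templates
  call_objs <- attr(calls, "calls")
  ohno_pairs_of <- function(sp) {
    rows <- list()
    for (cl in call_objs) {
      for (lin in cl$evidence$wgd_lineages %||% list()) {
        ga <- lin$a; gb <- lin$b
        g <- genomes[[sp]]$genes
        ga <- intersect(ga, g$gene_id); gb <- intersect(gb, g$gene_id)
        for (x in ga) for (y in gb)
          rows[[length(rows) + 1L]] <- data.frame(gene_a = x, gene_b = y,
                                                  stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0)
      data.frame(gene_a = character(), gene_b = character())
    else do.call(rbind, rows)
  }
  clusters <- list()
  cluster_pairs <- list()
  cluster_rows <- list()
  for (sp in names(genomes)) {
    op <- NULL
    for (tpl in names(templates)) {
      cls <- detect_clusters(genomes[[sp]], templates[[tpl]],
                             template_name = tpl)
      cls <- lapply(cls, score_integrity, canonical_order = templates[[tpl]])
      clusters[[sp]][[tpl]] <- cls
      if (length(cls) >= 2 && sp %in% wgd_sp) {
        if (is.null(op)) op <- ohno_pairs_of(sp)
        pr <- pair_ohnologous_clusters(cls, op)
        cluster_pairs[[sp]][[tpl]] <- pr
        for (p in pr$pairs) for (side in c("cluster_a", "cluster_b"))
          cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
            species_id = sp, template = tpl, label = p[[side]]$label,
            chromosome_id = p[[side]]$chromosome_id,
            completeness = p[[side]]$completeness,
            order_score = p[[side]]$order_score, stringsAsFactors = FALSE)
      } else if (length(cls) >= 1) {
        best <- cls[[which.max(vapply(cls, function(x) x$completeness, 0))]]
        cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
          species_id = sp, template = tpl, label = "unpaired",
          chromosome_id = best$chromosome_id,
          completeness = best$completeness, order_score = best$order_score,
          stringsAsFactors = FALSE)
      }
    }
  }
  cluster_tab <- if (length(cluster_rows) > 0) do.call(rbind, cluster_rows)
    else data.frame(species_id = character(), template = character(),
                    label = character(), chromosome_id = character(),
                    completeness = numeric(), order_score = numeric())

  # stage 6: macrosynteny against the reference species
  og <- family_orthogroups(genomes)
  ortho_maps <- list()
  for (sp in setdiff(names(genomes), reference_species))
    ortho_maps[[sp]] <- chromosome_orthology(genomes[[sp]],
                                             genomes[[reference_species]],
                                             og)$assignment
  located <- locate_clusters(cluster_tab, ortho_maps, reference_species)

  # stage 7: recovery against truth
  recovery <- category_recovery(sim$truth, calls)

  res <- list(sim = sim, genomes = genomes, calls = calls,
              summary = summary, clusters = clusters,
              cluster_pairs = cluster_pairs, synteny = ortho_maps,
              located = located, recovery = recovery,
              reference_species = reference_species)

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    stamp <- sprintf("# seed=%d", sim$config$seed)
    wtsv <- function(df, name) {
      path <- file.path(out, name)
      writeLines(stamp, path)
      suppressWarnings(utils::write.table(df, path, sep = "\t",
                                          quote = FALSE, row.names = FALSE,
                                          append = TRUE))
      path
    }
    wtsv(calls, "calls.tsv")
    wtsv(summary$table, "summary.tsv")
    wtsv(located, "clusters.tsv")
    wtsv(as.data.frame(recovery$confusion), "confusion.tsv")
    for (sp in names(genomes))
      write_gene_table(genomes[[sp]],
                       file.path(out, paste0(sp, "_assigned.tsv")),
                       "bed_tsv")
  }
  res
}
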