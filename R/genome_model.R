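# Core data model: per-species gene tables and genome containers.
#
# Coordinates are 0-based, half-open throughout the package; GFF3 I/O
# converts at the boundary (GFF3 is 1-based, inclusive). Strand must be
# "+" or "-": orientation scoring downstream needs a defined strand.

#' Construct a species genome
#'
#' Bundles one species' gene records with its chromosome table. Genes are
#' validated and stored sorted by (chromosome, start, gene_id) so that all
#' downstream order-dependent computations (cluster detection, collinearity)
#' see a canonical order regardless of input order.
#'
#' @param species_id Single species identifier.
#' @param genes Data frame with columns `gene_id`, `chromosome_id`, `start`,
#'   `end`, `strand`; optionally `family_id`, `pseudogene`,
#'   `homeodomain_seq`, `cds_seq`. `start`/`end` are 0-based half-open.
#' @param chromosomes Optional data frame with columns `chromosome_id`,
#'   `length`. When omitted, each chromosome's length defaults to the
#'   maximum gene end observed on it (annotations often omit lengths).
#' @return An object of class `species_genome`: a list with elements
#'   `species_id`, `chromosomes`, `genes`.
#' @export
species_genome <- function(species_id, genes, chromosomes = NULL) {
  assert_that(is.character(species_id) && length(species_id) == 1,
              "species_id must be a single string")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  for (col in setdiff(GENE_TABLE_COLS, names(genes))) {
    genes[[col]] <- rep(switch(col,
      species_id = species_id,
      family_id = "UNASSIGNED",
      pseudogene = FALSE,
      NA_character_
    ), nrow(genes))
  }
  genes <- genes[, GENE_TABLE_COLS]
  genes$species_id <- rep(species_id, nrow(genes))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$pseudogene <- as.logical(genes$pseudogene)
  validate_gene_table(genes)
  genes <- genes[c_order(genes$chromosome_id, genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL

  if (is.null(chromosomes)) {
    if (nrow(genes) > 0) {
      len <- tapply(genes$end, genes$chromosome_id, max)
      chromosomes <- data.frame(chromosome_id = names(len),
                                length = as.integer(len),
                                stringsAsFactors = FALSE)
    } else {
      chromosomes <- data.frame(chromosome_id = character(),
                                length = integer(), stringsAsFactors = FALSE)
    }
  } else {
    chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
    assert_that(all(c("chromosome_id", "length") %in% names(chromosomes)),
                "chromosomes needs columns chromosome_id, length")
    missing_chr <- setdiff(genes$chromosome_id, chromosomes$chromosome_id)
    if (length(missing_chr) > 0)
      stop2("genes reference unknown chromosome(s): ",
            paste(missing_chr, collapse = ", "))
    idx <- match(genes$chromosome_id, chromosomes$chromosome_id)
    bad <- genes$end > chromosomes$length[idx]
    if (any(bad))
      stop2("gene interval exceeds chromosome length: ",
            paste(genes$gene_id[bad], collapse = ", "))
  }
  chromosomes <- chromosomes[c_order(chromosomes$chromosome_id), , drop = FALSE]
  rownames(chromosomes) <- NULL

  structure(list(species_id = species_id, chromosomes = chromosomes,
                 genes = genes), class = "species_genome")
}

validate_gene_table <- function(genes) {
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0)
    stop2("duplicate gene_id within species: ",
          paste(unique(dup), collapse = ", "))
  bad <- !(genes$strand %in% c("+", "-"))
  if (any(bad))
    stop2("strand must be '+' or '-' (got '",
          paste(unique(genes$strand[bad]), collapse = "','"),
          "' for ", paste(genes$gene_id[bad], collapse = ", "), ")")
  bad <- !(genes$start >= 0 & genes$start < genes$end)
  if (any(bad))
    stop2("invalid interval (need 0 <= start < end) for: ",
          paste(genes$gene_id[bad], collapse = ", "))
  has_cds <- !is.na(genes$cds_seq)
  bad <- has_cds & !genes$pseudogene & nchar(genes$cds_seq) %% 3 != 0
  if (any(bad))
    stop2("cds_seq length not divisible by 3 for non-pseudogene: ",
          paste(genes$gene_id[bad], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.species_genome <- function(x, ...) {
  cat(sprintf("<species_genome> %s: %d genes on %d chromosome(s)\n",
              x$species_id, nrow(x$genes), nrow(x$chromosomes)))
  invisible(x)
}

#' Read a per-species gene table
#'
#' Supports two dialects. `gff3`: standard 9-column GFF3 restricted to
#' feature type `gene` with an `ID` attribute; coordinates are converted
#' from 1-based inclusive to the internal 0-based half-open convention.
#' `bed_tsv`: a headered tab-separated table with columns
#' `species, gene_id, chromosome, start, end, strand, family` (already
#' 0-based half-open), and optionally `pseudogene`.
#'
#' @param path File path.
#' @param format `"gff3"` or `"bed_tsv"`.
#' @param species_id Species id; required for `gff3` (GFF3 has no species
#'   column), ignored for `bed_tsv` when the file names one.
#' @return A [species_genome()].
#' @export
read_gene_table <- function(path, format = c("gff3", "bed_tsv"),
                            species_id = NULL) {
  format <- match.arg(format)
  if (format == "gff3") {
    assert_that(!is.null(species_id), "species_id is required for GFF3 input")
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    rows <- which(keep)
    if (length(rows) == 0) return(species_genome(species_id, empty_gene_table()))
    recs <- lapply(rows, function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) != 9)
        stop2("malformed GFF3 line ", i, ": expected 9 tab-separated fields, got ",
              length(f))
      if (f[3] != "gene") return(NULL)
      start1 <- suppressWarnings(as.integer(f[4]))
      end1 <- suppressWarnings(as.integer(f[5]))
      if (is.na(start1) || is.na(end1))
        stop2("malformed GFF3 line ", i, ": non-numeric coordinates")
      id <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", f[9])
      if (identical(id, f[9]) && !grepl("^ID=", f[9]))
        stop2("malformed GFF3 line ", i, ": no ID attribute")
      fam <- if (grepl("(^|;)family=", f[9]))
        sub(".*(?:^|;)family=([^;]+).*", "\\1", f[9]) else "UNASSIGNED"
      pse <- grepl("(^|;)pseudogene=(true|1)", f[9])
      data.frame(gene_id = id, chromosome_id = f[1],
                 start = start1 - 1L, end = end1, strand = f[7],
                 family_id = fam, pseudogene = pse, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, recs)
    if (is.null(tab)) return(species_genome(species_id, empty_gene_table()))
    return(species_genome(species_id, tab))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("species", "gene_id", "chromosome", "start", "end", "strand",
            "family")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop2("bed_tsv is missing column(s): ", paste(miss, collapse = ", "))
  sp <- unique(tab$species)
  if (length(sp) > 1)
    stop2("bed_tsv contains multiple species: ", paste(sp, collapse = ", "))
  if (length(sp) == 0) sp <- species_id %||% "unknown"
  genes <- data.frame(gene_id = tab$gene_id, chromosome_id = tab$chromosome,
                      start = as.integer(tab$start), end = as.integer(tab$end),
                      strand = tab$strand, family_id = tab$family,
                      stringsAsFactors = FALSE)
  if ("pseudogene" %in% names(tab))
    genes$pseudogene <- tab$pseudogene %in% c("TRUE", "true", "1")
  species_genome(sp, genes)
}

#' Write a per-species gene table
#'
#' Inverse of [read_gene_table()]; a write/read round trip reproduces the
#' gene records field by field (sequences are carried by FASTA, not here).
#'
#' @inheritParams read_gene_table
#' @param genome A [species_genome()].
#' @export
write_gene_table <- function(genome, path, format = c("gff3", "bed_tsv")) {
  format <- match.arg(format)
  g <- genome$genes
  if (format == "gff3") {
    attrs <- sprintf("ID=%s;family=%s%s", g$gene_id, g$family_id,
                     ifelse(g$pseudogene, ";pseudogene=true", ""))
    lines <- c("##gff-version 3",
               if (nrow(g) > 0)
                 sprintf("%s\thoxwgd\tgene\t%d\t%d\t.\t%s\t.\t%s",
                         g$chromosome_id, g$start + 1L, g$end, g$strand, attrs))
    writeLines(lines, path)
  } else {
    out <- data.frame(species = g$species_id, gene_id = g$gene_id,
                      chromosome = g$chromosome_id, start = g$start,
                      end = g$end, strand = g$strand, family = g$family_id,
                      pseudogene = g$pseudogene, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Intergenic distance between two gene records
#'
#' Defined as `downstream.start - upstream.end` (0 for abutting genes;
#' negative for overlapping genes). Both genes must lie on one chromosome.
#' @param a,b Single-row gene records (rows of a gene table).
#' @export
intergenic_distance <- function(a, b) {
  assert_that(a$chromosome_id == b$chromosome_id,
              "intergenic distance is defined on one chromosome only")
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  as.integer(b$start - a$end)
}
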