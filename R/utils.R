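#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

# Deterministic, locale-independent string ordering (C collation).
c_order <- function(...) order(..., method = "radix")
c_sort <- function(x) sort(x, method = "radix")

# Empty gene table with the canonical column set and types.
empty_gene_table <- function() {
  data.frame(
    gene_id = character(),
    species_id = character(),
    chromosome_id = character(),
    start = integer(),
    end = integer(),
    strand = character(),
    family_id = character(),
    pseudogene = logical(),
    homeodomain_seq = character(),
    cds_seq = character(),
    stringsAsFactors = FALSE
  )
}

GENE_TABLE_COLS <- names(empty_gene_table())
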