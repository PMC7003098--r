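HOMOLOGY_RELATIONS <- c("ortholog_one2one", "ortholog_one2many",
                        "ortholog_many2many", "within_species_paralog")

#' Construct a Compara-style homology table
#'
#' A homology table holds pairwise homology records in the style of
#' EnsemblCompara exports: each row relates two genes, gives the relation
#' type, and — for within-species paralogs — the taxonomic level (a
#' species-tree node name) of the duplication that separates them. Records
#' are stored once per unordered pair; semantics are symmetric (the
#' one2many relation reads left-to-right and is flipped on reversal).
#'
#' @param df data.frame with columns `gene_a`, `species_a`, `gene_b`,
#'   `species_b`, `relation`, `duplication_level`.
#' @return a `homology_table` (data.frame subclass).
#' @export
homology_table <- function(df) {
  need <- c("gene_a", "species_a", "gene_b", "species_b",
            "relation", "duplication_level")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[need]
  bad <- setdiff(unique(df$relation), HOMOLOGY_RELATIONS)
  if (length(bad))
    stop("unknown relation(s): ", paste(bad, collapse = ", "), call. = FALSE)
  is_par <- df$relation == "within_species_paralog"
  if (any(is_par & (is.na(df$duplication_level) | !nzchar(df$duplication_level))))
    stop("within_species_paralog records need a duplication_level", call. = FALSE)
  if (any(!is_par & nzchar(df$duplication_level)))
    stop("duplication_level must be empty unless relation is within_species_paralog",
         call. = FALSE)
  if (any(is_par & df$species_a != df$species_b))
    stop("within_species_paralog records must relate genes of one species",
         call. = FALSE)
  class(df) <- c("homology_table", "data.frame")
  df
}

#' Read / write homology tables as TSV
#'
#' Tab-separated, header row, UTF-8; empty `duplication_level` for ortholog
#' records.
#'
#' @param path file path.
#' @return [read_homology_table()]: a `homology_table`.
#' @export
read_homology_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          fileEncoding = "UTF-8")
  df$duplication_level[is.na(df$duplication_level)] <- ""
  homology_table(df)
}

#' @rdname read_homology_table
#' @param table a `homology_table`.
#' @export
write_homology_table <- function(table, path) {
  stopifnot(inherits(table, "homology_table"))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Symmetric closure of a homology table
#'
#' Returns the table with both orientations of every record; one2many
#' relations are flipped to many2... semantics by swapping the gene columns
#' (the relation string is kept, read from the first gene's side).
#'
#' @param table a `homology_table`.
#' @return a `homology_table` with both orientations.
#' @export
symmetrize_homology <- function(table) {
  rev <- table
  rev[c("gene_a", "species_a", "gene_b", "species_b")] <-
    table[c("gene_b", "species_b", "gene_a", "species_a")]
  out <- unique(rbind(as.data.frame(table), as.data.frame(rev)))
  homology_table(out)
}

# all genes of a species mentioned anywhere in the table
genes_of_species <- function(table, species) {
  unique(c(table$gene_a[table$species_a == species],
           table$gene_b[table$species_b == species]))
}

#' Is a homology relation an ortholog relation?
#'
#' @param relation character vector of relation strings.
#' @return logical vector.
#' @export
is_ortholog_relation <- function(relation) startsWith(relation, "ortholog")
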