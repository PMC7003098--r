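#' Clade scheme: species-to-phylum mapping for early-animal analyses
#'
#' A clade scheme assigns every species to one of the phylum-level labels
#' used throughout the package: `B` (Bilateria), `Cn` (Cnidaria), `Pl`
#' (Placozoa), `Ct` (Ctenophora), `Po` (Porifera, sponges),
#' `Choanoflagellatea` (the choanoflagellate outgroup within Choanozoa) and
#' `Outgroup` (anything deeper, e.g. fungi). Eumetazoa is, by default,
#' Bilateria + Cnidaria + Placozoa.
#'
#' @param phylum_of named character vector: names are species, values are
#'   clade labels.
#' @param eumetazoa labels counted as eumetazoan phyla.
#' @return an object of class `clade_scheme`.
#' @examples
#' sch <- clade_scheme(c(B1 = "B", Cn1 = "Cn", Pl1 = "Pl", Ct1 = "Ct", Po1 = "Po"))
#' phylum_of(sch, c("Ct1", "B1"))
#' @export
clade_scheme <- function(phylum_of, eumetazoa = c("B", "Cn", "Pl")) {
  valid <- c("B", "Cn", "Pl", "Ct", "Po", "Choanoflagellatea", "Outgroup")
  if (is.null(names(phylum_of)) || any(!nzchar(names(phylum_of))))
    stop("`phylum_of` must be a named vector (names = species)", call. = FALSE)
  bad <- setdiff(unique(phylum_of), valid)
  if (length(bad))
    stop("unknown clade label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(phylum_of)))
    stop("duplicated species in clade scheme", call. = FALSE)
  if (!all(eumetazoa %in% valid))
    stop("eumetazoa labels must be valid clade labels", call. = FALSE)
  structure(list(phylum_of = phylum_of, eumetazoa = eumetazoa),
            class = "clade_scheme")
}

#' Look up the phylum label of species
#'
#' @param scheme a [clade_scheme()].
#' @param species character vector of species names.
#' @return character vector of clade labels.
#' @export
phylum_of <- function(scheme, species) {
  stopifnot(inherits(scheme, "clade_scheme"))
  out <- scheme$phylum_of[species]
  if (anyNA(out))
    stop("species not in clade scheme: ",
         paste(unique(species[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}

#' @export
print.clade_scheme <- function(x, ...) {
  cat("<clade_scheme>", length(x$phylum_of), "species;",
      "eumetazoa =", paste(x$eumetazoa, collapse = "+"), "\n")
  print(table(x$phylum_of))
  invisible(x)
}

# phyla of gene-tree leaves labelled "Species|gene"
leaf_phyla <- function(labels, scheme) {
  phylum_of(scheme, split_leaf_labels(labels)$species)
}
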