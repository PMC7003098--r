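AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Construct a rectangular amino-acid alignment
#'
#' Sequences are stored as an upper-case character matrix (one row per
#' sequence, one column per alignment column) over the 20 amino acids plus
#' the gap character `-` and the unknown-residue character `X`.
#'
#' @param seqs named character vector of aligned sequences (strings), or a
#'   character matrix of single residues with rownames.
#' @return object of class `aa_alignment` (a character matrix).
#' @examples
#' aln <- aa_alignment(c(s1 = "ACDE", s2 = "AC-E"))
#' alignment_columns(aln)
#' @export
aa_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("sequences must be named", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      ref <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
      bad <- names(seqs)[lens != ref]
      stop("alignment is not rectangular; offending row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("row ids must be present and unique", call. = FALSE)
  bad <- setdiff(unique(as.vector(m)), c(AA_ALPHABET, "-", "X"))
  if (length(bad))
    stop("unknown residue symbol(s): ", paste(bad, collapse = " "),
         call. = FALSE)
  class(m) <- c("aa_alignment", class(m))
  m
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment>", nrow(x), "sequences x", ncol(x), "columns\n")
  invisible(x)
}

#' Read a protein multiple sequence alignment
#'
#' Reads FASTA or NEXUS (DATA block; sequential or interleaved matrices) into
#' an [aa_alignment()]. Rectangularity and the residue alphabet are enforced
#' at read time; ragged input is a format error naming the offending row.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"nexus"`; default guesses from the extension.
#' @return an [aa_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("nex", "nexus", "nxs")) "nexus" else "fasta"
  }
  seqs <- if (format == "fasta") {
    x <- ape::read.FASTA(path, type = "AA")
    vapply(as.character(x), paste, "", collapse = "")
  } else {
    x <- ape::read.nexus.data(path)
    lens <- lengths(x)
    if (length(unique(lens)) > 1L) {
      ref <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
      stop("alignment is not rectangular; offending row(s): ",
           paste(names(x)[lens != ref], collapse = ", "), call. = FALSE)
    }
    vapply(x, paste, "", collapse = "")
  }
  # NEXUS '?' missing states are treated as unknown residues
  seqs <- gsub("?", "X", seqs, fixed = TRUE)
  aa_alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln an [aa_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Number of alignment columns
#'
#' @param aln an [aa_alignment()].
#' @return integer column count (the common row length).
#' @export
alignment_columns <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  ncol(aln)
}

as_residue_vector <- function(x, aln = NULL) {
  if (!is.null(aln) && is.character(x) && length(x) == 1L &&
      x %in% rownames(aln)) return(aln[x, ])
  if (is.character(x) && length(x) == 1L) return(strsplit(toupper(x), "")[[1]])
  toupper(as.vector(x))
}

#' Gap-normalized percent amino-acid identity
#'
#' Percent identity between two aligned rows, normalized to the columns both
#' rows actually share: 100 x identical-residue columns / columns where
#' neither row has a gap. Columns where either residue is the unknown
#' character `X` contribute to neither numerator nor denominator. The
#' alternative convention that divides by all alignment columns is exposed
#' via `denominator = "all_columns"`.
#'
#' @param row_a,row_b aligned sequences: strings, residue vectors, or row ids
#'   into `aln`.
#' @param aln optional [aa_alignment()] in which to look up row ids.
#' @param denominator `"shared"` (default; shared non-gap columns) or
#'   `"all_columns"`.
#' @return percentage in `[0, 100]`.
#' @examples
#' gap_normalized_identity("AC-GT", "ACAGT")  # 100
#' gap_normalized_identity("ACGT", "ACGA")    # 75
#' @export
gap_normalized_identity <- function(row_a, row_b, aln = NULL,
                                    denominator = c("shared", "all_columns")) {
  denominator <- match.arg(denominator)
  a <- as_residue_vector(row_a, aln)
  b <- as_residue_vector(row_b, aln)
  if (length(a) != length(b))
    stop("rows have different lengths (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  usable <- a != "-" & b != "-" & a != "X" & b != "X"
  ident <- sum(a[usable] == b[usable])
  denom <- if (denominator == "shared") sum(usable) else length(a)
  if (denom == 0L)
    stop("undefined identity: no shared non-gap columns", call. = FALSE)
  100 * ident / denom
}

#' Amino-acid composition of one or more rows
#'
#' Pooled residue frequencies over the 20 amino acids; gaps and `X` are
#' excluded.
#'
#' @param rows sequences: an [aa_alignment()], a character matrix, or a
#'   (possibly named) character vector of sequence strings.
#' @return named numeric vector of length 20 summing to 1.
#' @export
aa_composition <- function(rows) {
  res <- if (is.matrix(rows)) as.vector(rows) else
    unlist(strsplit(toupper(rows), ""), use.names = FALSE)
  res <- res[res %in% AA_ALPHABET]
  if (!length(res)) stop("no residues (all-gap input)", call. = FALSE)
  counts <- table(factor(res, levels = AA_ALPHABET))
  as.vector(counts / sum(counts)) |> stats::setNames(AA_ALPHABET)
}

#' Pooled residue counts (internal)
#' @noRd
aa_counts <- function(rows) {
  res <- if (is.matrix(rows)) as.vector(rows) else
    unlist(strsplit(toupper(rows), ""), use.names = FALSE)
  res <- res[res %in% AA_ALPHABET]
  table(factor(res, levels = AA_ALPHABET))
}
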