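#' Fetch the published supplementary sequence archive
#'
#' Downloads and unpacks the curated alignment archive for the cornichon,
#' TMC, and MLX/MLXIP gene families (figshare DOI
#' `10.25387/g3.11444400`) into a local directory, returning the extracted
#' file paths. Requires network access; the archive is never bundled with
#' the package.
#'
#' @param dest directory to download into (default a session temp dir).
#' @param quiet suppress download progress.
#' @return character vector of extracted file paths.
#' @export
fetch_supplementary_archive <- function(dest = file.path(tempdir(),
                                                         "dupliphy_suppl"),
                                        quiet = TRUE) {
  dir.create(dest, showWarnings = FALSE, recursive = TRUE)
  api <- "https://api.figshare.com/v2/articles?doi=10.25387/g3.11444400"
  meta_file <- file.path(dest, "article.json")
  utils::download.file(api, meta_file, quiet = quiet)
  meta <- jsonlite::read_json(meta_file)
  if (!length(meta)) stop("figshare article not found", call. = FALSE)
  art <- jsonlite::read_json(file.path(dest, "article.json"))
  id <- art[[1]]$id
  files <- jsonlite::read_json(
    sprintf("https://api.figshare.com/v2/articles/%s/files", id))
  out <- character()
  for (f in files) {
    path <- file.path(dest, f$name)
    if (!file.exists(path))
      utils::download.file(f$download_url, path, mode = "wb", quiet = quiet)
    if (grepl("\\.zip$", path, ignore.case = TRUE)) {
      out <- c(out, utils::unzip(path, exdir = dest))
    } else out <- c(out, path)
  }
  out
}

#' Column counts of the curated supplementary alignments
#'
#' Given the extracted supplementary files, locates the trimmed TMC,
#' MLX/MLXIP, and cornichon alignments by filename and reports their
#' alignment column counts.
#'
#' @param paths file paths from [fetch_supplementary_archive()].
#' @return named integer vector (`tmc`, `mlx`, `cornichon`); families whose
#'   alignment cannot be located are `NA`.
#' @export
supplementary_column_counts <- function(paths) {
  find1 <- function(pattern) {
    hits <- paths[grepl(pattern, basename(paths), ignore.case = TRUE) &
                    grepl("\\.(nexus|nex|fas|fasta|masx)$", paths,
                          ignore.case = TRUE)]
    if (!length(hits)) return(NA_integer_)
    counts <- suppressWarnings(vapply(hits, function(p)
      tryCatch(alignment_columns(read_alignment(p)),
               error = function(e) NA_integer_), 1L))
    if (all(is.na(counts))) NA_integer_ else max(counts, na.rm = TRUE)
  }
  c(tmc = find1("tmc"), mlx = find1("mlx|mondo"),
    cornichon = find1("cni|cornichon"))
}
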