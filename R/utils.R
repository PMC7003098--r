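#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the R random number generator seeded at `seed`, then
#' restores the caller's RNG state, so seeded package functions never
#' perturb the user's random stream.
#'
#' @param seed integer seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for stage `index` derived from a global seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647)
}

#' Split "Species|gene" leaf labels
#'
#' Gene-tree leaves are self-describing: the species name precedes the first
#' `|`, the gene identifier follows it. Labels without `|` are treated as
#' bare species names (as in species trees).
#'
#' @param labels character vector of leaf labels.
#' @return data.frame with columns `species` and `gene`.
#' @export
split_leaf_labels <- function(labels) {
  has_bar <- grepl("|", labels, fixed = TRUE)
  species <- ifelse(has_bar, sub("\\|.*$", "", labels), labels)
  gene <- ifelse(has_bar, sub("^[^|]*\\|", "", labels), labels)
  data.frame(label = labels, species = species, gene = gene,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
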