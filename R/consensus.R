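#' Cross-study co-DEG consensus
#'
#' Given the up/down signatures of several independent studies of the same
#' category, identifies the co-deregulated genes (co-DEGs): genes appearing
#' in the up lists of at least `min_support` studies (co-up), or analogously
#' in the down lists (co-down). Genes supported in only a single study are
#' filtered out. A gene reaching `min_support` in *both* directions is
#' flagged `"conflicting"` and excluded from both consensus sets, keeping the
#' downstream enrichment direction-pure.
#'
#' @param signatures List of at least two [signature_from_cd()] results, all
#'   of the same category.
#' @param min_support Minimum number of supporting studies (default 2,
#'   i.e. "at least two independent studies").
#' @return An object of class `CoDEGSet`: `category`, `co_up`, `co_down`,
#'   `conflicting` (character vectors), `support` (data.frame gene/n_up/
#'   n_down), `min_support`, `n_studies`.
#' @export
compute_codegs <- function(signatures, min_support = 2L) {
  if (length(signatures) < 2) stop("need at least 2 signatures")
  stopifnot(all(vapply(signatures, inherits, TRUE, "GeneSignature")))
  cats <- unique(vapply(signatures, `[[`, "", "category"))
  if (length(cats) != 1)
    stop("signatures mix categories: ", paste(cats, collapse = ", "))
  if (min_support < 1) stop("min_support must be >= 1")

  up_counts <- table(unlist(lapply(signatures, `[[`, "up_genes")))
  down_counts <- table(unlist(lapply(signatures, `[[`, "down_genes")))
  genes <- sort(unique(c(names(up_counts), names(down_counts))))
  n_up <- as.integer(up_counts[genes]); n_up[is.na(n_up)] <- 0L
  n_down <- as.integer(down_counts[genes]); n_down[is.na(n_down)] <- 0L

  up_ok <- n_up >= min_support
  down_ok <- n_down >= min_support
  conflicting <- genes[up_ok & down_ok]
  structure(
    list(category = cats,
         co_up = genes[up_ok & !down_ok],
         co_down = genes[down_ok & !up_ok],
         conflicting = conflicting,
         support = data.frame(gene = genes, n_up = n_up, n_down = n_down,
                              stringsAsFactors = FALSE),
         min_support = as.integer(min_support),
         n_studies = length(signatures)),
    class = "CoDEGSet"
  )
}

#' @export
print.CoDEGSet <- function(x, ...) {
  cat(sprintf(
    "CoDEGSet [%s]: %d co-up, %d co-down, %d conflicting (support >= %d of %d studies)\n",
    x$category, length(x$co_up), length(x$co_down), length(x$conflicting),
    x$min_support, x$n_studies))
  invisible(x)
}

#' Per-gene support table for a CoDEGSet
#'
#' One row per gene seen in any study's signature, with its up/down study
#' counts and a status (`co_up`, `co_down`, `conflicting`, or `single` for
#' genes below the support threshold), sorted by maximum support descending
#' then symbol ascending.
#'
#' @param codegs A `CoDEGSet`.
#' @param path Optional path; if given the table is also written as TSV.
#' @return A data.frame with columns `gene`, `n_up`, `n_down`, `status`.
#' @export
support_table <- function(codegs, path = NULL) {
  stopifnot(inherits(codegs, "CoDEGSet"))
  s <- codegs$support
  status <- rep("single", nrow(s))
  status[s$gene %in% codegs$co_up] <- "co_up"
  status[s$gene %in% codegs$co_down] <- "co_down"
  status[s$gene %in% codegs$conflicting] <- "conflicting"
  s$status <- status
  ord <- order(-pmax(s$n_up, s$n_down), s$gene)
  s <- s[ord, , drop = FALSE]
  rownames(s) <- NULL
  if (!is.null(path))
    write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  s
}
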