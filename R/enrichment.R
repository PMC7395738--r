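#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing an overlap of at least `k_overlap` genes between
#' a random query of `query_size` genes and a term of `term_size` genes,
#' drawn without replacement from a universe of `universe_size` genes:
#' `P(X >= k)` for `X ~ Hypergeometric(universe, term, query)` (equivalently
#' the one-sided Fisher exact test of the 2x2 overlap table).
#'
#' @param k_overlap Observed overlap count.
#' @param query_size,term_size,universe_size Set sizes.
#' @return The p-value in \[0, 1\].
#' @export
hypergeom_pvalue <- function(k_overlap, query_size, term_size, universe_size) {
  if (any(k_overlap < 0) || any(term_size > universe_size) ||
      any(query_size > universe_size) ||
      any(k_overlap > pmin(query_size, term_size)))
    stop("inconsistent counts: need 0 <= k <= min(query, term) <= universe")
  phyper(k_overlap - 1, term_size, universe_size - term_size, query_size,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment with monotonicity enforcement;
#' the output preserves the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Combined enrichment score
#'
#' The ranking statistic used throughout the pipeline: the absolute natural
#' log of the BH-adjusted Fisher/hypergeometric p-value multiplied by the
#' z-score of the term's deviation from its expected rank,
#' `c = |ln(p_adj)| * z`.
#'
#' @param p_adj BH-adjusted p-value(s).
#' @param z Rank-deviation z-score(s) (positive = ranked better than
#'   expected under random queries).
#' @return Numeric combined score(s).
#' @export
combined_score <- function(p_adj, z) {
  abs(log(p_adj)) * z
}

#' Null expected-rank model for a gene-set library
#'
#' Ranks of a term (by ascending hypergeometric p) vary with query size and
#' library composition even for random queries. This builds, per term, the
#' mean and standard deviation of its rank across `n_random` random queries
#' (uniform draws without replacement from the universe) at each requested
#' query size, pooled over sizes. These moments feed the rank-deviation
#' z-score in [enrich()]. Ranks use average tie handling so exchangeable
#' terms receive identical expected ranks.
#'
#' @param library A `GeneSetLibrary`.
#' @param query_sizes Integer vector of query sizes to simulate.
#' @param n_random Random queries per query size (>= 10; default 1000).
#' @param seed Integer seed; the model is reproducible given the seed.
#' @param universe Optional explicit universe (defaults to the library
#'   universe). Queries are drawn from it and term sizes restricted to it.
#' @return An object of class `NullRankModel`: `library_name`, `terms`,
#'   `mean_rank`, `sd_rank` (named numerics, sd floored at 1e-6),
#'   `n_random`, `query_sizes`, `seed`.
#' @export
build_null_rank_model <- function(library, query_sizes, n_random = 1000L,
                                  seed, universe = NULL) {
  stopifnot(inherits(library, "GeneSetLibrary"))
  if (!length(library$terms)) stop("library is empty")
  if (n_random < 10) stop("n_random must be >= 10")
  if (missing(seed)) stop("seed is required")
  universe <- unique(toupper(universe %||% library$universe))
  query_sizes <- unique(pmin(as.integer(query_sizes), length(universe)))
  if (any(query_sizes < 1)) stop("query sizes must be >= 1")

  # term x gene indicator over the universe
  M <- vapply(library$terms,
              function(g) as.numeric(universe %in% g),
              numeric(length(universe)))        # genes x terms
  term_sizes <- colSums(M)
  U <- length(universe)

  ranks <- with_seed(seed, {
    out <- vector("list", length(query_sizes) * n_random)
    i <- 0L
    for (q in query_sizes) {
      for (r in seq_len(n_random)) {
        idx <- sample.int(U, q)
        k <- colSums(M[idx, , drop = FALSE])
        p <- phyper(k - 1, term_sizes, U - term_sizes, q, lower.tail = FALSE)
        i <- i + 1L
        out[[i]] <- rank(p, ties.method = "average")
      }
    }
    do.call(rbind, out)
  })
  mu <- colMeans(ranks)
  sdev <- pmax(apply(ranks, 2, sd), 1e-6)
  names(mu) <- names(sdev) <- names(library$terms)
  structure(
    list(library_name = library$name, terms = names(library$terms),
         mean_rank = mu, sd_rank = sdev,
         n_random = as.integer(n_random), query_sizes = query_sizes,
         seed = as.integer(seed)),
    class = "NullRankModel"
  )
}

#' @export
print.NullRankModel <- function(x, ...) {
  cat(sprintf("NullRankModel for '%s': %d terms, %d random queries/size (sizes: %s), seed %d\n",
              x$library_name, length(x$terms), x$n_random,
              paste(x$query_sizes, collapse = ","), x$seed))
  invisible(x)
}

#' Over-representation analysis with combined scores
#'
#' Tests a query gene set against every term of a library over a fixed gene
#' universe. Per term: the overlap `k`, the upper-tail hypergeometric
#' p-value, the BH-adjusted p across all the library's (universe-restricted)
#' terms, the rank-deviation z-score
#' `z = (expected_rank - observed_rank) / sd_rank` from `null_model`
#' (positive = enriched beyond expectation), and the combined score
#' `|ln(p_adj)| * z`. Only terms with `k >= 1` are returned, sorted by
#' combined score descending (ties by term ID).
#'
#' @param query Character vector of query genes; genes outside `universe`
#'   are dropped with a warning.
#' @param library A `GeneSetLibrary`.
#' @param universe Character vector: the gene universe. Typically the
#'   library universe intersected with the genes actually measured in the
#'   contributing studies; pass the full genome list to reproduce a
#'   whole-genome background instead.
#' @param null_model A [build_null_rank_model()] for the same library, or
#'   `NULL` to skip z-scores (then `z` and `combined_score` are `NA` and
#'   rows are sorted by p ascending).
#' @return A data.frame with columns `term`, `overlap` (comma-separated
#'   genes), `k`, `query_size`, `term_size`, `universe_size`, `p`, `p_adj`,
#'   `z`, `combined_score`.
#' @export
enrich <- function(query, library, universe, null_model = NULL) {
  stopifnot(inherits(library, "GeneSetLibrary"))
  query <- unique(toupper(query))
  universe <- unique(toupper(universe))
  if (!length(query)) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  if (!length(query)) stop("empty query after universe restriction")
  if (!is.null(null_model) && !setequal(null_model$terms, names(library$terms)))
    warning("null model terms do not match the library's terms")

  terms <- lapply(library$terms, intersect, universe)
  term_sizes <- vapply(terms, length, 1L)
  keep <- term_sizes >= 1L
  terms <- terms[keep]; term_sizes <- term_sizes[keep]
  if (!length(terms))
    return(empty_enrichment())
  overlaps <- lapply(terms, intersect, query)
  k <- vapply(overlaps, length, 1L)
  U <- length(universe); q <- length(query)
  p <- phyper(k - 1, term_sizes, U - term_sizes, q, lower.tail = FALSE)
  p_adj <- bh_adjust(p)
  obs_rank <- rank(p, ties.method = "average")

  z <- rep(NA_real_, length(terms))
  if (!is.null(null_model)) {
    idx <- match(names(terms), names(null_model$mean_rank))
    ok <- !is.na(idx)
    z[ok] <- (null_model$mean_rank[idx[ok]] - obs_rank[ok]) /
      null_model$sd_rank[idx[ok]]
  }
  cs <- combined_score(p_adj, z)

  res <- data.frame(
    term = names(terms),
    overlap = vapply(overlaps, function(g) paste(sort(g), collapse = ","), ""),
    k = k, query_size = q, term_size = term_sizes, universe_size = U,
    p = p, p_adj = p_adj, z = z, combined_score = cs,
    stringsAsFactors = FALSE)
  res <- res[res$k >= 1L, , drop = FALSE]
  ord <- if (all(is.na(res$combined_score))) {
    order(res$p, res$term)
  } else {
    order(-res$combined_score, res$term)
  }
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_enrichment <- function() {
  data.frame(term = character(), overlap = character(), k = integer(),
             query_size = integer(), term_size = integer(),
             universe_size = integer(), p = numeric(), p_adj = numeric(),
             z = numeric(), combined_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Write an enrichment table as TSV
#'
#' @param result Data.frame from [enrich()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  out <- result
  for (col in c("p", "p_adj", "z", "combined_score"))
    out[[col]] <- format_num(out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
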