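#' Construct a drug signature library
#'
#' @param drugs Named list; each element a list with `up` and `down`
#'   character vectors (disjoint per drug, uppercased on construction).
#' @param universe Character vector of all assayable genes.
#' @param name Library name.
#' @return An object of class `DrugSignatureLibrary`.
#' @export
drug_signature_library <- function(drugs, universe, name = "drugs") {
  stopifnot(is.list(drugs), length(names(drugs)) == length(drugs))
  drugs <- lapply(drugs, function(d) {
    d$up <- unique(toupper(d$up)); d$down <- unique(toupper(d$down))
    if (length(intersect(d$up, d$down)))
      stop("drug up/down sets overlap: ",
           paste(intersect(d$up, d$down), collapse = ", "))
    d[c("up", "down")]
  })
  structure(list(name = name, drugs = drugs,
                 universe = unique(toupper(universe))),
            class = "DrugSignatureLibrary")
}

#' @export
print.DrugSignatureLibrary <- function(x, ...) {
  cat(sprintf("DrugSignatureLibrary '%s': %d drugs over %d genes\n",
              x$name, length(x$drugs), length(x$universe)))
  invisible(x)
}

#' Read a drug library from paired GMT files
#'
#' Term IDs may carry `__up` / `__down` suffixes (stripped to form the drug
#' name) or be plain drug names, with the direction given by which file the
#' term came from. A drug must appear in both files.
#'
#' @param up_path GMT of per-drug up-regulated gene sets.
#' @param down_path GMT of per-drug down-regulated gene sets.
#' @param universe Optional explicit universe; defaults to the union of all
#'   genes in both files.
#' @return A `DrugSignatureLibrary`.
#' @export
read_drug_library <- function(up_path, down_path, universe = NULL) {
  up_lib <- read_gmt(up_path); down_lib <- read_gmt(down_path)
  strip <- function(x) sub("__(up|down)$", "", x, ignore.case = TRUE)
  names(up_lib$terms) <- strip(names(up_lib$terms))
  names(down_lib$terms) <- strip(names(down_lib$terms))
  common <- intersect(names(up_lib$terms), names(down_lib$terms))
  if (!length(common)) stop("no drug appears in both GMT files")
  drugs <- setNames(lapply(common, function(d) {
    list(up = up_lib$terms[[d]], down = down_lib$terms[[d]])
  }), common)
  drug_signature_library(
    drugs, universe %||% union(up_lib$universe, down_lib$universe))
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Signed-Jaccard connectivity score
#'
#' Scores the similarity between a query up/down signature and a drug
#' perturbation signature on set inputs:
#' `score = ((J(q_up, d_up) + J(q_down, d_down)) - (J(q_up, d_down) + J(q_down, d_up))) / 2`
#' with `J` the Jaccard index. The score lies in \[-1, +1\]: +1 iff the drug
#' exactly mimics the query signature (a perturbation that would push cells
#' further toward the disease state) and -1 iff it exactly reverses it (a
#' repurposing candidate). A hypergeometric association p-value is the
#' minimum upper-tail p over the four quadrant overlaps, Bonferroni-adjusted
#' by 4 and capped at 1.
#'
#' @param query_up,query_down Non-empty, disjoint query gene sets.
#' @param drug_up,drug_down Disjoint drug signature gene sets.
#' @param universe Background gene universe.
#' @param drug Optional drug identifier carried into the result.
#' @return An object of class `ConnectivityResult`: `drug`, `score`,
#'   `p_value`, and `overlap_genes` (list of the four quadrant overlaps:
#'   `up_up`, `down_down`, `up_down`, `down_up`).
#' @export
connectivity_score <- function(query_up, query_down, drug_up, drug_down,
                               universe, drug = NA_character_) {
  query_up <- unique(toupper(query_up)); query_down <- unique(toupper(query_down))
  drug_up <- unique(toupper(drug_up)); drug_down <- unique(toupper(drug_down))
  if (!length(query_up) || !length(query_down))
    stop("query up and down sets must both be non-empty")
  if (length(intersect(query_up, query_down)))
    stop("query up/down sets must be disjoint")
  if (length(intersect(drug_up, drug_down)))
    stop("drug up/down sets must be disjoint")
  universe <- unique(toupper(universe))

  score <- ((jaccard(query_up, drug_up) + jaccard(query_down, drug_down)) -
              (jaccard(query_up, drug_down) + jaccard(query_down, drug_up))) / 2

  quads <- list(up_up = list(query_up, drug_up),
                down_down = list(query_down, drug_down),
                up_down = list(query_up, drug_down),
                down_up = list(query_down, drug_up))
  overlaps <- lapply(quads, function(q) intersect(q[[1]], q[[2]]))
  U <- length(universe)
  ps <- vapply(names(quads), function(nm) {
    a <- quads[[nm]][[1]]; b <- quads[[nm]][[2]]
    if (!length(b)) return(1)
    phyper(length(overlaps[[nm]]) - 1, length(b), U - length(b), length(a),
           lower.tail = FALSE)
  }, 1)
  p <- min(1, 4 * min(ps))

  structure(list(drug = drug, score = score, p_value = p,
                 overlap_genes = overlaps),
            class = "ConnectivityResult")
}

#' @export
print.ConnectivityResult <- function(x, ...) {
  cat(sprintf("ConnectivityResult%s: score %.4f, p = %.3g\n",
              if (is.na(x$drug)) "" else paste0(" [", x$drug, "]"),
              x$score, x$p_value))
  invisible(x)
}

#' Rank a drug library against a query signature
#'
#' Scores every drug with [connectivity_score()] and emits two tables:
#' `reversers` sorted by score ascending (most negative = strongest
#' signature reversal, the repurposing candidates) and `mimics` sorted
#' descending. Ties are broken by p-value then drug name.
#'
#' @param query_up,query_down Query signature gene sets.
#' @param library A `DrugSignatureLibrary` (non-empty).
#' @return A list with data.frames `reversers` and `mimics`, each with
#'   columns `drug`, `score`, `p_value`, `k_up_up`, `k_down_down`,
#'   `k_up_down`, `k_down_up`.
#' @export
rank_drugs <- function(query_up, query_down, library) {
  stopifnot(inherits(library, "DrugSignatureLibrary"))
  if (!length(library$drugs)) stop("drug library is empty")
  rows <- lapply(names(library$drugs), function(d) {
    sig <- library$drugs[[d]]
    r <- connectivity_score(query_up, query_down, sig$up, sig$down,
                            library$universe, drug = d)
    data.frame(drug = d, score = r$score, p_value = r$p_value,
               k_up_up = length(r$overlap_genes$up_up),
               k_down_down = length(r$overlap_genes$down_down),
               k_up_down = length(r$overlap_genes$up_down),
               k_down_up = length(r$overlap_genes$down_up),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rev_tab <- tab[order(tab$score, tab$p_value, tab$drug), , drop = FALSE]
  mim_tab <- tab[order(-tab$score, tab$p_value, tab$drug), , drop = FALSE]
  rownames(rev_tab) <- rownames(mim_tab) <- NULL
  list(reversers = rev_tab, mimics = mim_tab)
}
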