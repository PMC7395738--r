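#' Construct an ExpressionStudy
#'
#' An `ExpressionStudy` holds one study's log2-scale expression matrix
#' (genes x samples) together with its case/control sample assignment and a
#' study category. Gene symbols are uppercased and must be unique; case and
#' control sample sets must be disjoint and non-empty.
#'
#' @param study_id Character scalar identifying the study.
#' @param values Numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample IDs). Log2 expression units.
#' @param case_samples,control_samples Character vectors of sample IDs.
#' @param category One of `"cancer_vs_normal"`, `"gene_perturbation"`,
#'   `"drug_perturbation"`.
#' @return An object of class `ExpressionStudy`.
#' @export
expression_study <- function(study_id, values, case_samples, control_samples,
                             category = "cancer_vs_normal") {
  category <- match.arg(category, STUDY_CATEGORIES)
  stopifnot(is.matrix(values), is.numeric(values))
  genes <- toupper(rownames(values))
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(genes))
    stop("duplicate gene symbols after uppercasing: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (length(case_samples) == 0 || length(control_samples) == 0)
    stop("case and control sample sets must both be non-empty")
  overlap <- intersect(case_samples, control_samples)
  if (length(overlap))
    stop("case and control sample sets overlap: ", paste(overlap, collapse = ", "))
  missing <- setdiff(c(case_samples, control_samples), samples)
  if (length(missing))
    stop("sample ID(s) not present in the matrix: ", paste(missing, collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values")
  rownames(values) <- genes
  structure(
    list(study_id = study_id, genes = genes, samples = samples,
         values = values, case_samples = case_samples,
         control_samples = control_samples, category = category),
    class = "ExpressionStudy"
  )
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy '%s' [%s]: %d genes x %d samples (%d case / %d control)\n",
              x$study_id, x$category, length(x$genes), length(x$samples),
              length(x$case_samples), length(x$control_samples)))
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' Reads a genes x samples TSV (first column gene symbols, header row sample
#' IDs) into a validated [expression_study()]. Symbols are uppercased and rows
#' sharing a symbol after uppercasing are collapsed by their arithmetic mean.
#'
#' @param path Path to the TSV file.
#' @param case_ids,control_ids Sample IDs of the two classes; every ID must
#'   appear in the header.
#' @param study_id Study identifier (defaults to the file name).
#' @param category Study category, see [expression_study()].
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to the values (for
#'   matrices supplied on the raw intensity scale). Default `FALSE`: values
#'   are assumed to be log2 already.
#' @return An `ExpressionStudy`.
#' @export
read_expression_matrix <- function(path, case_ids, control_ids,
                                   study_id = basename(path),
                                   category = "cancer_vs_normal",
                                   log2_transform = FALSE) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression matrix needs a gene column and >=1 sample column")
  sample_ids <- colnames(raw)[-1]
  missing <- setdiff(c(case_ids, control_ids), sample_ids)
  if (length(missing))
    stop("sample ID(s) not found in header of '", path, "': ",
         paste(missing, collapse = ", "))
  symbols <- toupper(trimws(raw[[1]]))
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !(is.na(col) | col %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of '%s'",
                   col[bad[1]], bad[1], sample_ids[j], path))
    vals[, j] <- num
  }
  # collapse duplicate symbols by mean
  if (anyDuplicated(symbols)) {
    vals <- rowsum(vals, group = symbols, reorder = FALSE) /
      as.vector(table(factor(symbols, levels = unique(symbols))))
    symbols <- unique(symbols)
  }
  rownames(vals) <- symbols
  if (log2_transform) vals <- log2(vals + 1)
  expression_study(study_id, vals, case_ids, control_ids, category)
}

#' Write an ExpressionStudy back to TSV
#'
#' @param study An `ExpressionStudy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(study, path) {
  df <- data.frame(gene = study$genes, study$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a GeneSetLibrary
#'
#' @param terms Named list mapping term IDs to character vectors of gene
#'   symbols (uppercased, de-duplicated on construction).
#' @param name Library name.
#' @return An object of class `GeneSetLibrary` with fields `name`, `terms`
#'   and `universe` (union of all term genes).
#' @export
gene_set_library <- function(terms, name = "library") {
  stopifnot(is.list(terms))
  terms <- lapply(terms, function(g) unique(toupper(g)))
  empty <- vapply(terms, length, 1L) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty term(s): ",
            paste(names(terms)[empty], collapse = ", "))
    terms <- terms[!empty]
  }
  structure(
    list(name = name, terms = terms,
         universe = unique(unlist(terms, use.names = FALSE)) %||% character()),
    class = "GeneSetLibrary"
  )
}

#' @export
print.GeneSetLibrary <- function(x, ...) {
  cat(sprintf("GeneSetLibrary '%s': %d terms over %d genes\n",
              x$name, length(x$terms), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set library
#'
#' Parses the Broad GMT dialect: one term per line,
#' `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`. Genes are
#' uppercased and de-duplicated; terms left empty are dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @param name Library name (defaults to the file name).
#' @return A `GeneSetLibrary`.
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_library(list(), name = name))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3))
    stop("GMT line ", which(nf < 3)[1], " of '", path,
         "' has fewer than 3 tab-separated fields")
  terms <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g[nzchar(trimws(g))]
  })
  names(terms) <- vapply(fields, `[[`, "", 1L)
  gene_set_library(terms, name = name)
}

#' Write a GeneSetLibrary as GMT
#'
#' @param library A `GeneSetLibrary`.
#' @param path Output path.
#' @param descriptions Optional named character vector of term descriptions;
#'   defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path, descriptions = NULL) {
  lines <- vapply(names(library$terms), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions))
      descriptions[[id]] else "na"
    paste(c(id, desc, library$terms[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a PPINetwork
#'
#' A simple undirected protein-protein interaction network: self-loops are
#' removed and duplicate / reversed edges collapsed. Nodes isolated after
#' self-loop removal are retained.
#'
#' @param edges Two-column character matrix or data.frame of interacting
#'   symbol pairs.
#' @param nodes Optional additional node symbols to retain as isolated nodes.
#' @return An object of class `PPINetwork` with fields `nodes` (character)
#'   and `edges` (data.frame with columns `from`, `to`, canonically ordered).
#' @export
ppi_network <- function(edges, nodes = character()) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2) stop("edges must have two columns")
  a <- toupper(as.character(edges[, 1])); b <- toupper(as.character(edges[, 2]))
  nodes <- unique(c(toupper(nodes), a, b))
  keep <- a != b
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep])
  key <- paste(a2, b2, sep = "\r")
  uniq <- !duplicated(key)
  structure(
    list(nodes = sort(nodes),
         edges = data.frame(from = a2[uniq], to = b2[uniq],
                            stringsAsFactors = FALSE)),
    class = "PPINetwork"
  )
}

#' @export
print.PPINetwork <- function(x, ...) {
  cat(sprintf("PPINetwork: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a PPI edge list
#'
#' Accepts a two-column whitespace/tab-separated edge list or the SIF dialect
#' (`A pp B`). Self-loops are dropped (their nodes retained as isolated) and
#' duplicate or reversed edges are de-duplicated.
#'
#' @param path Path to the edge-list file.
#' @return A `PPINetwork`.
#' @export
read_ppi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(ppi_network(matrix(character(), 0, 2)))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- vapply(fields, length, 1L)
  bad <- which(!(nf == 2 | nf == 3))
  if (length(bad))
    stop("malformed edge at line ", bad[1], " of '", path,
         "': expected 2 columns or SIF 'A pp B'")
  pairs <- t(vapply(fields, function(f) {
    if (length(f) == 3) c(f[1], f[3]) else f
  }, character(2)))
  ppi_network(pairs)
}

#' Write a PPINetwork as a two-column edge list
#'
#' Only edges are written; isolated nodes survive a round trip by passing
#' them to [ppi_network()] via its `nodes` argument.
#'
#' @param network A `PPINetwork`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Signature-integrity QC for a study
#'
#' Applies the two signature-integrity rules used when curating case/control
#' comparisons: a study whose case and control sample sets share an ID is
#' rejected outright, and gene symbols absent from a supplied valid-symbol
#' list (e.g. an HGNC snapshot) are flagged for removal.
#'
#' @param study An `ExpressionStudy`.
#' @param valid_symbols Non-empty character vector of acceptable gene symbols
#'   (case-insensitive).
#' @return A list of class `signature_qc` with fields `study_id`, `status`
#'   (`"accepted"`/`"rejected"`), `overlapping_samples`, `invalid_symbols`,
#'   `n_dropped`, and `retained_genes`.
#' @export
validate_signature_metadata <- function(study, valid_symbols) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (length(valid_symbols) == 0) stop("valid_symbols must be non-empty")
  valid_symbols <- toupper(valid_symbols)
  overlap <- intersect(study$case_samples, study$control_samples)
  invalid <- setdiff(study$genes, valid_symbols)
  structure(
    list(study_id = study$study_id,
         status = if (length(overlap)) "rejected" else "accepted",
         overlapping_samples = overlap,
         invalid_symbols = invalid,
         n_dropped = length(invalid),
         retained_genes = setdiff(study$genes, invalid)),
    class = "signature_qc"
  )
}

#' @export
print.signature_qc <- function(x, ...) {
  cat(sprintf("QC for '%s': %s; %d invalid symbol(s) dropped\n",
              x$study_id, x$status, x$n_dropped))
  if (length(x$overlapping_samples))
    cat("  case/control overlap: ",
        paste(x$overlapping_samples, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write one-symbol-per-line gene lists
#'
#' @param path File path.
#' @return `read_gene_list` returns an uppercased character vector.
#' @export
read_gene_list <- function(path) {
  g <- toupper(trimws(readLines(path, warn = FALSE)))
  g[nzchar(g)]
}

#' @rdname read_gene_list
#' @param genes Character vector of symbols.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
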