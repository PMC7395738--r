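#' Characteristic Direction differential expression
#'
#' Computes the Characteristic Direction (CD) for a two-class expression
#' study: the unit vector `b` that best separates case from control samples
#' under a shrunken pooled within-class covariance,
#' `b` proportional to `solve(gamma * S + (1 - gamma) * nu * I, mu_case - mu_control)`,
#' where `S` is the pooled within-class covariance and `nu` the mean of its
#' diagonal (the average within-class gene variance). The per-gene components
#' of `b` rank genes by their contribution to the class separation; positive
#' components indicate genes higher in cases.
#'
#' When genes outnumber samples the solve is carried out inside the PCA
#' subspace of the gene-centered data and mapped back to gene space; with
#' `n_components` at least the data rank this is algebraically identical to
#' the full gene-space solve, because the mean difference has no component
#' outside the data's row space.
#'
#' The orientation of `b` is fixed deterministically: among genes whose raw
#' case-minus-control mean difference is positive, the gene with the largest
#' absolute coefficient must have a positive coefficient (falling back to the
#' globally largest coefficient matching its mean-difference sign when no
#' gene is up in cases).
#'
#' @param study An [expression_study()] with at least 2 samples per class and
#'   at least 2 genes.
#' @param gamma Shrinkage weight in (0, 1]; `gamma = 1` uses the raw pooled
#'   covariance, small values approach the scaled-identity (mean-difference)
#'   direction. Default 0.5.
#' @param n_components `"auto"` (the default, `min(n_samples - 2, 30)`), an
#'   integer PCA dimension, or `"full"` to use the complete data rank.
#' @return An object of class `CDResult`: list with `study_id`,
#'   `coefficients` (named numeric, unit L2 norm), `gamma`, `n_components`.
#' @export
characteristic_direction <- function(study, gamma = 0.5, n_components = "auto") {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (!(gamma > 0 && gamma <= 1)) stop("gamma must be in (0, 1]")
  X <- study$values
  if (nrow(X) < 2) stop("need at least 2 genes")
  case <- X[, study$case_samples, drop = FALSE]
  ctrl <- X[, study$control_samples, drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2)
    stop("each class needs at least 2 samples (got ", n1, " case, ", n2, " control)")

  # per-gene pooled within-class variance; nu is its mean (gene-space trace
  # of S divided by the gene count, so it is subspace-independent)
  v_case <- apply(case, 1, var)
  v_ctrl <- apply(ctrl, 1, var)
  pooled_var <- ((n1 - 1) * v_case + (n2 - 1) * v_ctrl) / (n1 + n2 - 2)
  if (sum(pooled_var) <= 0 && sum(apply(X, 1, var)) <= 0)
    stop("degenerate input: zero total variance")
  nu <- mean(pooled_var)

  d_gene <- rowMeans(case) - rowMeans(ctrl)
  if (sqrt(sum(d_gene^2)) < 1e-12 * max(1, sqrt(sum(X^2))))
    stop("degenerate input: case and control means coincide, no discriminating direction")

  # PCA of the gene-centered data (samples as points in gene space)
  Xc <- X - rowMeans(X)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  k <- if (identical(n_components, "auto")) {
    min(ncol(X) - 2L, 30L, rank)
  } else if (identical(n_components, "full")) {
    rank
  } else {
    min(as.integer(n_components), rank)
  }
  if (k < 1) stop("degenerate input: data rank below 1")
  U <- sv$u[, seq_len(k), drop = FALSE]              # genes x k basis

  # reduced coordinates of each sample: t(U) %*% Xc
  Z <- t(U) %*% Xc
  z_case <- Z[, study$case_samples, drop = FALSE]
  z_ctrl <- Z[, study$control_samples, drop = FALSE]
  d_z <- rowMeans(z_case) - rowMeans(z_ctrl)
  cc <- z_case - rowMeans(z_case)
  gg <- z_ctrl - rowMeans(z_ctrl)
  S_z <- (cc %*% t(cc) + gg %*% t(gg)) / (n1 + n2 - 2)

  M <- gamma * S_z + (1 - gamma) * nu * diag(k)
  b_z <- solve(M, d_z)
  b <- as.vector(U %*% b_z)
  nrm <- sqrt(sum(b^2))
  if (nrm < 1e-300) stop("degenerate input: zero direction")
  b <- b / nrm
  names(b) <- study$genes

  # deterministic sign orientation
  up <- which(d_gene > 0)
  anchor <- if (length(up)) up[which.max(abs(b[up]))] else which.max(abs(b))
  target_sign <- if (length(up)) 1 else sign(d_gene[anchor])
  if (sign(b[anchor]) != 0 && sign(b[anchor]) != target_sign) b <- -b

  structure(
    list(study_id = study$study_id, coefficients = b, gamma = gamma,
         n_components = k, category = study$category),
    class = "CDResult"
  )
}

#' @export
print.CDResult <- function(x, ...) {
  cat(sprintf("CDResult '%s': %d genes, gamma=%g, %d PCA components\n",
              x$study_id, length(x$coefficients), x$gamma, x$n_components))
  invisible(x)
}

#' Fixed-size up/down signature from a CD result
#'
#' Ranks genes by absolute CD coefficient (descending, ties broken
#' lexicographically by symbol) and keeps the top `cutoff` genes overall,
#' splitting them by coefficient sign into ordered up- and down-regulated
#' lists. Genes with exactly zero coefficient never enter either list. With
#' `per_direction = TRUE` the cutoff is instead applied within each direction.
#'
#' @param cd A `CDResult`.
#' @param cutoff Maximum number of signature genes (total across both
#'   directions unless `per_direction`). Default 500.
#' @param per_direction Apply `cutoff` to each direction separately.
#' @return An object of class `GeneSignature`: `study_id`, `up_genes`,
#'   `down_genes` (rank-ordered), `scores` (named coefficients of retained
#'   genes), `category`, `cutoff`.
#' @export
signature_from_cd <- function(cd, cutoff = 500L, per_direction = FALSE) {
  stopifnot(inherits(cd, "CDResult"))
  if (cutoff < 1) stop("cutoff must be >= 1")
  b <- cd$coefficients
  if (cutoff > length(b))
    warning("cutoff (", cutoff, ") exceeds gene count (", length(b),
            "); using all genes")
  ord <- order(-abs(b), names(b))
  ranked <- b[ord]
  ranked <- ranked[ranked != 0]
  if (per_direction) {
    up <- head(ranked[ranked > 0], cutoff)
    down <- head(ranked[ranked < 0], cutoff)
    kept <- c(up, down)
  } else {
    kept <- head(ranked, cutoff)
    up <- kept[kept > 0]
    down <- kept[kept < 0]
  }
  structure(
    list(study_id = cd$study_id,
         up_genes = names(up), down_genes = names(down),
         scores = kept, category = cd$category, cutoff = as.integer(cutoff)),
    class = "GeneSignature"
  )
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s' [%s]: %d up, %d down (cutoff %d)\n",
              x$study_id, x$category, length(x$up_genes),
              length(x$down_genes), x$cutoff))
  invisible(x)
}

#' Write a signature to disk
#'
#' Produces `<study>.cd.tsv` (gene, coefficient), `<study>.up.txt` and
#' `<study>.down.txt` in `dir`.
#'
#' @param signature A `GeneSignature`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the three paths written, invisibly.
#' @export
write_signature <- function(signature, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, signature$study_id)
  cd_path <- paste0(base, ".cd.tsv")
  write.table(
    data.frame(gene = names(signature$scores),
               coefficient = format_num(signature$scores),
               stringsAsFactors = FALSE),
    cd_path, sep = "\t", quote = FALSE, row.names = FALSE)
  up_path <- paste0(base, ".up.txt"); down_path <- paste0(base, ".down.txt")
  write_gene_list(signature$up_genes, up_path)
  write_gene_list(signature$down_genes, down_path)
  invisible(c(cd_path, up_path, down_path))
}

# fixed-width scientific formatting so reruns are byte-identical
format_num <- function(x, digits = 10) {
  formatC(x, digits = digits, format = "g")
}
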