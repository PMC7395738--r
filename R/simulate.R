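#' Simulation configuration
#'
#' Parameters of the synthetic multi-study generator. Defaults emulate a
#' small meta-analysis of independent case/control microarray studies on a
#' shared platform: log2-scale Gaussian expression with per-gene baselines
#' drawn from Uniform(6, 12), within-class standard deviation `base_sd`,
#' a set of co-deregulated genes shifted in the cases of *every* study, and
#' per-study private (noise) DEGs shifted in exactly one study. Planted
#' upstream regulators (TFs wired to the co-DEGs, kinases wired to the TFs,
#' a hub protein connecting the TFs in the PPI) and a planted
#' signature-reversing drug give every downstream stage a known truth.
#'
#' @param seed Integer root seed (mandatory); all randomness in the
#'   generator flows from it through a fixed splitting scheme.
#' @param n_studies Number of independent studies (default 3).
#' @param n_genes Genes per study (default 1000).
#' @param n_case,n_control Samples per class per study (default 10 each).
#' @param n_co_up,n_co_down Planted shared co-up / co-down genes
#'   (default 50 each).
#' @param n_private Study-specific noise DEGs per study (default 30).
#' @param effect_size Case shift of planted DEGs, in units of `base_sd`
#'   (default 2).
#' @param base_sd Within-class standard deviation on the log2 scale
#'   (default 0.5, a typical array-noise level).
#' @param n_tfs,targets_per_tf Planted TFs and co-DEG targets per TF
#'   (defaults 10 and 30).
#' @param n_kinases,substrates_per_kinase Planted kinases and substrates per
#'   kinase, drawn from the TFs and the hub (defaults 10 and 5).
#' @param ppi_extra_edges Random background PPI edges beyond the planted
#'   hub-TF star (default 50).
#' @param n_decoy_tfs,n_decoy_kinases,n_decoy_drugs Decoy terms per library
#'   (defaults 40, 40, 20).
#' @return An object of class `SimulationConfig` (a validated list).
#' @export
simulation_config <- function(seed, n_studies = 3L, n_genes = 1000L,
                              n_case = 10L, n_control = 10L,
                              n_co_up = 50L, n_co_down = 50L,
                              n_private = 30L, effect_size = 2,
                              base_sd = 0.5, n_tfs = 10L,
                              targets_per_tf = 30L, n_kinases = 10L,
                              substrates_per_kinase = 5L,
                              ppi_extra_edges = 50L, n_decoy_tfs = 40L,
                              n_decoy_kinases = 40L, n_decoy_drugs = 20L) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_studies = as.integer(n_studies),
              n_genes = as.integer(n_genes), n_case = as.integer(n_case),
              n_control = as.integer(n_control),
              n_co_up = as.integer(n_co_up), n_co_down = as.integer(n_co_down),
              n_private = as.integer(n_private),
              effect_size = effect_size, base_sd = base_sd,
              n_tfs = as.integer(n_tfs),
              targets_per_tf = as.integer(targets_per_tf),
              n_kinases = as.integer(n_kinases),
              substrates_per_kinase = as.integer(substrates_per_kinase),
              ppi_extra_edges = as.integer(ppi_extra_edges),
              n_decoy_tfs = as.integer(n_decoy_tfs),
              n_decoy_kinases = as.integer(n_decoy_kinases),
              n_decoy_drugs = as.integer(n_decoy_drugs))
  counts <- unlist(cfg[setdiff(names(cfg), c("effect_size", "base_sd", "seed"))])
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$n_co_up + cfg$n_co_down + cfg$n_studies * cfg$n_private > cfg$n_genes)
    stop("infeasible counts: planted DEGs exceed the gene count")
  if (cfg$base_sd <= 0) stop("base_sd must be positive")
  structure(cfg, class = "SimulationConfig")
}

#' Simulate multi-study case/control expression data
#'
#' Draws per-gene log2 baselines once (shared across studies), then per
#' study a genes x samples Gaussian matrix; planted co-up (co-down) genes
#' are shifted by `+effect_size * base_sd` (`-`) in the cases of every
#' study, and each study's private DEGs by a random sign in that study only.
#'
#' @param config A [simulation_config()].
#' @return A list with `studies` (list of `ExpressionStudy`) and `truth`
#'   (class `GroundTruth`: `genes`, `co_up`, `co_down`, `private` — a named
#'   sign vector per study — and, once the library generators have run,
#'   `tf_targets`, `kinase_substrates`, `hub`, `reverser_drug`).
#' @export
simulate_expression_studies <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  width <- max(4L, nchar(as.character(cfg$n_genes)))
  genes <- sprintf(paste0("G%0", width, "d"), seq_len(cfg$n_genes))
  with_seed(derive_seed(cfg$seed, 1L), {
    perm <- sample(genes)
    co_up <- sort(perm[seq_len(cfg$n_co_up)])
    co_down <- sort(perm[cfg$n_co_up + seq_len(cfg$n_co_down)])
    used <- cfg$n_co_up + cfg$n_co_down
    private <- list()
    for (s in seq_len(cfg$n_studies)) {
      g <- perm[used + seq_len(cfg$n_private)]
      used <- used + cfg$n_private
      private[[paste0("study", s)]] <-
        setNames(sample(c(1, -1), cfg$n_private, replace = TRUE), g)
    }
    mu <- runif(cfg$n_genes, 6, 12)
    shift <- cfg$effect_size * cfg$base_sd
    studies <- lapply(seq_len(cfg$n_studies), function(s) {
      id <- paste0("study", s)
      ns <- cfg$n_case + cfg$n_control
      X <- matrix(rnorm(cfg$n_genes * ns, mean = mu, sd = cfg$base_sd),
                  nrow = cfg$n_genes, ncol = ns)
      case_cols <- seq_len(cfg$n_case)
      X[genes %in% co_up, case_cols] <- X[genes %in% co_up, case_cols] + shift
      X[genes %in% co_down, case_cols] <- X[genes %in% co_down, case_cols] - shift
      priv <- private[[id]]
      for (g in names(priv))
        X[genes == g, case_cols] <- X[genes == g, case_cols] + priv[[g]] * shift
      rownames(X) <- genes
      colnames(X) <- c(paste0(id, "_case", case_cols),
                       paste0(id, "_ctrl", seq_len(cfg$n_control)))
      expression_study(id, X,
                       case_samples = colnames(X)[case_cols],
                       control_samples = colnames(X)[-case_cols],
                       category = "cancer_vs_normal")
    })
    truth <- structure(
      list(genes = genes, co_up = co_up, co_down = co_down,
           private = private, tf_targets = NULL, kinase_substrates = NULL,
           hub = NULL, reverser_drug = NULL),
      class = "GroundTruth")
    list(studies = studies, truth = truth)
  })
}

#' Simulate TF / kinase libraries and a background PPI
#'
#' Each planted TF's gene set is a sample of the planted co-DEGs (its
#' targets) padded with decoy non-DEG genes; decoy TFs get size-matched
#' all-non-DEG sets, so their enrichment against a co-DEG query is null.
#' Planted kinases phosphorylate random subsets of the TFs and hub; decoy
#' kinase terms are drawn from genes outside the regulatory layer. The PPI
#' is a star connecting every planted TF through one hub protein (so the hub
#' lies on a length-2 path between every TF pair) plus `ppi_extra_edges`
#' random background edges.
#'
#' @param truth `GroundTruth` from [simulate_expression_studies()].
#' @param config The same [simulation_config()].
#' @return A list with `tf_library`, `kinase_library` (both
#'   `GeneSetLibrary`), `ppi` (`PPINetwork`) and the updated `truth`.
#' @export
simulate_regulator_libraries <- function(truth, config) {
  stopifnot(inherits(truth, "GroundTruth"), inherits(config, "SimulationConfig"))
  cfg <- config
  codegs <- c(truth$co_up, truth$co_down)
  deg_all <- c(codegs, unlist(lapply(truth$private, names), use.names = FALSE))
  nondeg <- setdiff(truth$genes, deg_all)
  tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  hub <- "HUB1"
  kinases <- sprintf("KIN%02d", seq_len(cfg$n_kinases))
  n_pad <- max(1L, round(cfg$targets_per_tf / 2))

  with_seed(derive_seed(cfg$seed, 2L), {
    tf_terms <- setNames(lapply(tfs, function(tf) {
      targets <- sample(codegs, min(cfg$targets_per_tf, length(codegs)))
      c(targets, sample(nondeg, min(n_pad, length(nondeg))))
    }), tfs)
    decoy_size <- cfg$targets_per_tf + n_pad
    decoy_tfs <- setNames(lapply(seq_len(cfg$n_decoy_tfs), function(i) {
      sample(nondeg, min(decoy_size, length(nondeg)))
    }), sprintf("DTF%02d", seq_len(cfg$n_decoy_tfs)))
    tf_library <- gene_set_library(c(tf_terms, decoy_tfs), name = "tf_targets")

    pool <- c(tfs, hub)
    kin_terms <- setNames(lapply(kinases, function(k) {
      sample(pool, min(cfg$substrates_per_kinase, length(pool)))
    }), kinases)
    decoy_kin <- setNames(lapply(seq_len(cfg$n_decoy_kinases), function(i) {
      sample(nondeg, min(cfg$substrates_per_kinase, length(nondeg)))
    }), sprintf("DKIN%02d", seq_len(cfg$n_decoy_kinases)))
    kinase_library <- gene_set_library(c(kin_terms, decoy_kin),
                                       name = "kinase_substrates")

    star <- cbind(hub, tfs)
    all_symbols <- c(truth$genes, tfs, hub)
    extra <- if (cfg$ppi_extra_edges > 0) {
      t(replicate(cfg$ppi_extra_edges, sample(all_symbols, 2)))
    } else matrix(character(), 0, 2)
    ppi <- ppi_network(rbind(star, extra))

    truth$tf_targets <- lapply(tf_terms, intersect, codegs)
    truth$kinase_substrates <- kin_terms
    truth$hub <- hub
    list(tf_library = tf_library, kinase_library = kinase_library,
         ppi = ppi, truth = truth)
  })
}

#' Simulate a drug perturbation-signature library
#'
#' One planted reverser drug whose up set is an 80% sample of the planted
#' co-down genes and whose down set is an 80% sample of the co-up genes
#' (i.e. it flips the disease signature), plus size-matched decoy drugs with
#' random gene sets.
#'
#' @param truth `GroundTruth` with planted co-DEGs.
#' @param config The [simulation_config()].
#' @param n_decoy_drugs Number of decoy drugs (defaults to the config
#'   value).
#' @return A list with `drug_library` (`DrugSignatureLibrary`) and the
#'   updated `truth` (field `reverser_drug`).
#' @export
simulate_drug_library <- function(truth, config,
                                  n_decoy_drugs = config$n_decoy_drugs) {
  stopifnot(inherits(truth, "GroundTruth"), inherits(config, "SimulationConfig"))
  with_seed(derive_seed(config$seed, 3L), {
    n_up <- ceiling(0.8 * length(truth$co_down))
    n_down <- ceiling(0.8 * length(truth$co_up))
    drugs <- list(RX_REVERSER = list(up = sample(truth$co_down, n_up),
                                     down = sample(truth$co_up, n_down)))
    for (i in seq_len(n_decoy_drugs)) {
      pick <- sample(truth$genes, n_up + n_down)
      drugs[[sprintf("DRUG%02d", i)]] <-
        list(up = pick[seq_len(n_up)], down = pick[n_up + seq_len(n_down)])
    }
    truth$reverser_drug <- "RX_REVERSER"
    list(drug_library = drug_signature_library(drugs, truth$genes,
                                               name = "sim_drugs"),
         truth = truth)
  })
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf(
    "GroundTruth: %d co-up, %d co-down genes; %d studies with private DEGs; hub=%s; reverser=%s\n",
    length(x$co_up), length(x$co_down), length(x$private),
    x$hub %||% "<unset>", x$reverser_drug %||% "<unset>"))
  invisible(x)
}
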