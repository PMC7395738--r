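#' Run the full co-DEG meta-analysis pipeline
#'
#' Orchestrates every stage end to end and writes the report tables to
#' `out_dir`: per-study Characteristic Direction signatures, the cross-study
#' co-DEG consensus, TF enrichment per direction, the G2N-expanded
#' regulatory networks with kinases attached, hub detection, and drug
#' connectivity ranking. With a [simulation_config()] the inputs are
#' simulated with known ground truth; alternatively pass pre-built `inputs`
#' (e.g. loaded with [read_expression_matrix()], [read_gmt()],
#' [read_ppi()], [read_drug_library()]).
#'
#' All report tables are written with fixed numeric formatting, so a rerun
#' with the same seed is byte-identical.
#'
#' @param config A `SimulationConfig`, or `NULL` when `inputs` is given.
#' @param inputs Optional list with elements `studies` (list of
#'   `ExpressionStudy`), `tf_library`, `kinase_library` (`GeneSetLibrary`),
#'   `ppi` (`PPINetwork`), `drug_library` (`DrugSignatureLibrary`).
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the enrichment null models when running from
#'   `inputs`; ignored if `config` is given (its seed is used).
#' @param gamma,cutoff,min_support,top_tfs,top_kinases,top_hubs,n_null
#'   Stage parameters: CD shrinkage, signature size, co-DEG support,
#'   regulators kept per layer, hubs flagged per network, random queries per
#'   null model.
#' @return Invisibly, a list with all intermediate objects (`studies`,
#'   `truth`, `cd`, `signatures`, `codegs`, `tf_enrichment`, `networks`,
#'   `hub_tables`, `hubs`, `drug_ranking`, `manifest`, `out_dir`).
#' @export
run_full_pipeline <- function(config = NULL, inputs = NULL, out_dir,
                              seed = NULL, gamma = 0.5, cutoff = 500L,
                              min_support = 2L, top_tfs = 10L,
                              top_kinases = 10L, top_hubs = 3L,
                              n_null = 1000L) {
  if (is.null(config) && is.null(inputs))
    stop("provide either a simulation config or prepared inputs")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (!is.null(config)) config$seed else
    seed %||% stop("seed is required when running from prepared inputs")
  stages <- character()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  truth <- NULL
  if (!is.null(config)) {
    sim <- stage("simulate", {
      ex <- simulate_expression_studies(config)
      reg <- simulate_regulator_libraries(ex$truth, config)
      drg <- simulate_drug_library(reg$truth, config)
      list(studies = ex$studies, tf_library = reg$tf_library,
           kinase_library = reg$kinase_library, ppi = reg$ppi,
           drug_library = drg$drug_library, truth = drg$truth)
    })
    studies <- sim$studies; truth <- sim$truth
    tf_library <- sim$tf_library; kinase_library <- sim$kinase_library
    ppi <- sim$ppi; drug_library <- sim$drug_library
  } else {
    stage("load", {
      studies <- inputs$studies %||% stop("inputs$studies is missing")
      tf_library <- inputs$tf_library %||% stop("inputs$tf_library is missing")
      kinase_library <- inputs$kinase_library %||%
        stop("inputs$kinase_library is missing")
      ppi <- inputs$ppi; drug_library <- inputs$drug_library
    })
  }

  cd <- stage("chdir", lapply(studies, characteristic_direction, gamma = gamma))
  signatures <- stage("signatures", {
    sigs <- lapply(cd, signature_from_cd, cutoff = cutoff)
    for (sig in sigs) write_signature(sig, file.path(out_dir, "signatures"))
    sigs
  })
  codegs <- stage("codegs", {
    cdg <- compute_codegs(signatures, min_support = min_support)
    support_table(cdg, path = file.path(out_dir, "codegs.tsv"))
    write_gene_list(cdg$co_up, file.path(out_dir, "co_up.txt"))
    write_gene_list(cdg$co_down, file.path(out_dir, "co_down.txt"))
    cdg
  })

  measured <- sort(Reduce(union, lapply(studies, `[[`, "genes")))
  tf_universe <- intersect(tf_library$universe, measured)

  tf_enrichment <- stage("tf_enrichment", {
    queries <- list(up = codegs$co_up, down = codegs$co_down)
    sizes <- pmax(1L, vapply(queries,
                             function(q) length(intersect(q, tf_universe)), 1L))
    null_tf <- build_null_rank_model(tf_library, query_sizes = sizes,
                                     n_random = n_null,
                                     seed = derive_seed(seed, 10L),
                                     universe = tf_universe)
    enr <- lapply(names(queries), function(dir) {
      e <- suppressWarnings(enrich(queries[[dir]], tf_library, tf_universe,
                                   null_tf))
      write_enrichment(e, file.path(out_dir,
                                    paste0("tf_enrichment_", dir, ".tsv")))
      e
    })
    names(enr) <- names(queries)
    enr
  })

  networks <- stage("network", {
    if (is.null(ppi)) stop("PPI network input is missing")
    nets <- lapply(names(tf_enrichment), function(dir) {
      tfs <- top_regulators(tf_enrichment[[dir]], n = top_tfs)
      net <- g2n_expand(tfs, ppi, provenance = paste0("co_", dir))
      kin_universe <- sort(union(kinase_library$universe, net$nodes$symbol))
      null_kin <- build_null_rank_model(
        kinase_library, query_sizes = max(1L, nrow(net$nodes)),
        n_random = n_null, seed = derive_seed(seed, 20L),
        universe = kin_universe)
      net <- kinase_enrich_and_attach(net, kinase_library, kin_universe,
                                      null_kin, n = top_kinases)
      write_network(net,
                    sif_path = file.path(out_dir, paste0("network_", dir, ".sif")),
                    graphml_path = file.path(out_dir,
                                             paste0("network_", dir, ".graphml")))
      net
    })
    names(nets) <- names(tf_enrichment)
    nets
  })

  hub_results <- stage("hubs", {
    tabs <- lapply(names(networks), function(dir) {
      ht <- select_hubs(hub_table(networks[[dir]]), top_k = top_hubs)
      ht$direction <- dir
      ht
    })
    combined <- do.call(rbind, tabs)
    out <- combined
    out$betweenness <- format_num(out$betweenness)
    write.table(out, file.path(out_dir, "hubs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    names(tabs) <- names(networks)
    tabs
  })

  drug_ranking <- stage("connectivity", {
    if (is.null(drug_library)) stop("drug library input is missing")
    rk <- rank_drugs(codegs$co_up, codegs$co_down, drug_library)
    for (nm in names(rk)) {
      out <- rk[[nm]]
      out$score <- format_num(out$score)
      out$p_value <- format_num(out$p_value)
      write.table(out, file.path(out_dir, paste0("drugs_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    rk
  })

  manifest <- list(
    package = "codegnet",
    version = as.character(packageVersion("codegnet")),
    seed = seed,
    parameters = list(gamma = gamma, cutoff = cutoff,
                      min_support = min_support, top_tfs = top_tfs,
                      top_kinases = top_kinases, top_hubs = top_hubs,
                      n_null = n_null,
                      simulation = if (!is.null(config)) unclass(config)),
    stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(studies = studies, truth = truth, cd = cd,
                 signatures = signatures, codegs = codegs,
                 tf_enrichment = tf_enrichment, networks = networks,
                 hub_tables = hub_results,
                 hubs = lapply(hub_results, function(h) attr(h, "hubs") %||%
                                 h$symbol[h$is_hub]),
                 drug_ranking = drug_ranking, manifest = manifest,
                 out_dir = out_dir))
}
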