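test_that("top regulators are ordered by combined score with lexicographic ties", {
  enr <- data.frame(term = c("Z", "B", "A"), combined_score = c(9.2, 4.1, 4.1),
                    p = c(0.001, 0.01, 0.01), stringsAsFactors = FALSE)
  expect_equal(top_regulators(enr, 2), c("Z", "A"))
  expect_equal(top_regulators(enr, 10), c("Z", "A", "B"))
  expect_error(top_regulators(enr, 0), "n must be")
})

test_that("G2N expansion collects shortest-path connectors between seeds", {
  ppi <- ppi_network(rbind(c("T1", "I1"), c("I1", "T2")))
  net <- g2n_expand(c("T1", "T2"), ppi)
  expect_setequal(net$nodes$symbol, c("T1", "T2", "I1"))
  expect_equal(net$nodes$role[net$nodes$symbol == "I1"], "intermediate")
  expect_equal(sort(net$nodes$role[net$nodes$symbol != "I1"]), c("tf", "tf"))
  expect_equal(nrow(net$edges), 2)

  direct <- g2n_expand(c("T1", "T2"), ppi_network(rbind(c("T1", "T2"))))
  expect_setequal(direct$nodes$symbol, c("T1", "T2"))
  expect_equal(nrow(direct$edges), 1)

  apart <- ppi_network(rbind(c("T1", "X"), c("T2", "Y")))
  iso <- g2n_expand(c("T1", "T2"), apart, max_path_length = 1)
  expect_setequal(iso$nodes$symbol, c("T1", "T2"))
  expect_equal(nrow(iso$edges), 0)
})

test_that("G2N output is a subgraph of the background PPI plus isolated seeds", {
  for (seed in 1:10) {
    edges <- random_edge_graph(9, 0.3, seed = 400 + seed)
    ppi <- ppi_network(edges, nodes = LETTERS[1:9])
    seeds <- sample(c(LETTERS[1:9], "ZZ"), 3)
    net <- g2n_expand(seeds, ppi)
    bg_keys <- paste(ppi$edges$from, ppi$edges$to)
    expect_true(all(paste(net$edges$from, net$edges$to) %in% bg_keys))
    expect_true(all(toupper(seeds) %in% net$nodes$symbol))
  }
})

test_that("kinases attach through substrate intersection", {
  net <- regulatory_network(
    data.frame(symbol = c("T1", "I1"), role = c("tf", "intermediate")),
    data.frame(from = "I1", to = "T1", kind = "ppi"))
  klib <- gene_set_library(list(K1 = c("T1", "I1", "X")), name = "kin")
  out <- kinase_enrich_and_attach(net, klib, universe = c("T1", "I1", "X", "Y"))
  expect_true("K1" %in% out$nodes$symbol)
  expect_equal(out$nodes$role[out$nodes$symbol == "K1"], "kinase")
  ph <- out$edges[out$edges$kind == "phosphorylation", ]
  expect_equal(nrow(ph), 2)
  expect_true(all(ph$from == "K1" | ph$to == "K1"))

  klib_miss <- gene_set_library(list(K2 = c("AA", "BB")), name = "kin")
  expect_warning(unchanged <- kinase_enrich_and_attach(
    net, klib_miss, universe = c("T1", "I1", "AA", "BB")), "unchanged|overlap")
  expect_equal(unchanged$nodes, net$nodes)
})

test_that("betweenness matches hand-computed small graphs", {
  path3 <- as_regnet(data.frame(from = c("A", "B"), to = c("B", "C")),
                     c("A", "B", "C"))
  b <- betweenness(path3)
  expect_equal(b[["B"]], 1)
  expect_equal(b[["A"]], 0)
  expect_equal(b[["C"]], 0)

  cyc <- as_regnet(data.frame(from = c("A", "B", "C", "D"),
                              to = c("B", "C", "D", "A")),
                   LETTERS[1:4])
  expect_equal(unname(betweenness(cyc)), rep(0.5, 4))

  star <- as_regnet(data.frame(from = "Z", to = c("A", "B", "C", "D")),
                    c("Z", LETTERS[1:4]))
  expect_equal(betweenness(star)[["Z"]], choose(4, 2))
})

test_that("betweenness and k-core match brute-force oracles on random graphs", {
  for (seed in 1:30) {
    n <- sample(4:9, 1)
    edges <- random_edge_graph(n, 0.4, seed = 500 + seed)
    net <- as_regnet(edges, LETTERS[1:n])
    expect_equal(betweenness(net)[LETTERS[1:n]],
                 oracle_betweenness(edges, LETTERS[1:n]), tolerance = 1e-12)
    expect_equal(as.integer(kcore(net)[LETTERS[1:n]]),
                 unname(oracle_kcore(edges, LETTERS[1:n])),
                 ignore_attr = TRUE)
  }
})

test_that("k-core peeling on canonical graphs", {
  tri_pendant <- as_regnet(
    data.frame(from = c("A", "B", "C", "C"), to = c("B", "C", "A", "P")),
    c("A", "B", "C", "P"))
  core <- kcore(tri_pendant)
  expect_equal(unname(core[c("A", "B", "C")]), rep(2, 3))
  expect_equal(core[["P"]], 1)

  lonely <- as_regnet(data.frame(from = character(), to = character()),
                      c("A", "B"))
  expect_equal(unname(kcore(lonely)), c(0, 0))

  k5 <- t(utils::combn(LETTERS[1:5], 2))
  complete <- as_regnet(data.frame(from = k5[, 1], to = k5[, 2]), LETTERS[1:5])
  expect_equal(unname(kcore(complete)), rep(4, 5))
})

test_that("hub selection ranks by kcore, betweenness, degree, symbol", {
  star <- as_regnet(data.frame(from = "Z", to = c("A", "B", "C", "D")),
                    c("Z", LETTERS[1:4]))
  ht <- select_hubs(hub_table(star), top_k = 1)
  expect_equal(attr(ht, "hubs"), "Z")
  expect_true(ht$is_hub[ht$symbol == "Z"])
  expect_true(all(ht$kcore <= ht$degree))
  # leaves have zero betweenness
  expect_true(all(ht$betweenness[ht$degree == 1] == 0))

  # equal k-core everywhere (a path): betweenness breaks the tie
  path4 <- as_regnet(data.frame(from = c("A", "B", "C"), to = c("B", "C", "D")),
                     LETTERS[1:4])
  ht2 <- select_hubs(hub_table(path4), top_k = 2)
  expect_setequal(attr(ht2, "hubs"), c("B", "C"))

  all_of_them <- select_hubs(hub_table(path4), top_k = 10)
  expect_true(all(all_of_them$is_hub))
  expect_error(select_hubs(hub_table(path4), top_k = 0), "top_k")
})

test_that("networks export to SIF and GraphML", {
  net <- regulatory_network(
    data.frame(symbol = c("T1", "I1", "K1", "LONER"),
               role = c("tf", "intermediate", "kinase", "tf")),
    data.frame(from = c("T1", "K1"), to = c("I1", "T1"),
               kind = c("ppi", "phosphorylation")))
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, sif_path = sif, graphml_path = gml)
  lines <- readLines(sif)
  expect_length(lines, 3)            # 2 edges + 1 isolated node
  expect_true("LONER" %in% lines)
  expect_true(any(grepl("\tph\t", lines)))
  expect_true(any(grepl("graphml", readLines(gml)[1:3])))
})
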