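# In-code fixture builders shared across test files.

fixture_store <- function() {
  drug_store(
    tibble::tibble(
      drug_id = c("dA", "dB", "dC"),
      name = c("alpha", "beta", "gamma"),
      smiles = c("CC(=O)OC1=CC=CC=C1C(=O)O", "CC(=O)NC1=CC=C(C=C1)O", NA),
      atc = list(c("L01XE07"), c("L01XA01", "N02BA01"), character())),
    diseases = tibble::tibble(
      drug_id = c("dA", "dA", "dA", "dB", "dB", "dB"),
      disease_id = c("d1", "d2", "d3", "d2", "d3", "d4")),
    adrs = tibble::tibble(
      drug_id = c("dA", "dA", "dA", "dB", "dB", "dB"),
      adr_id = c("a1", "a2", "a3", "a3", "a4", "a5")),
    targets = tibble::tibble(
      drug_id = c("dA", "dB", "dC"),
      target_id = c("P1", "P2", "P3"),
      sign = c(1, -1, 1)))
}

write_fixture_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("drug_id\tname\tsmiles\tatc_codes",
               "dA\talpha\tCCO\tL01XE07",
               "dB\tbeta\tc1ccccc1\tN02BA01|L01XA01"),
             file.path(dir, "drugs.tsv"))
  writeLines(c("drug_id\tdisease_id", "dA\td1", "dA\td2", "dB\td2"),
             file.path(dir, "drug_disease.tsv"))
  writeLines(c("drug_id\tadr_id", "dA\ta1", "dB\ta1", "dB\ta2"),
             file.path(dir, "drug_adr.tsv"))
  writeLines(c("drug_id\ttarget_id\taction",
               "dA\tP1\tactivate", "dB\tP2\tinhibit"),
             file.path(dir, "drug_target.tsv"))
  dir
}

# random signed directed graph as an edge data frame + igraph twin
random_signed_graph <- function(n_nodes, p = 0.25) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  grid <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  keep <- runif(nrow(grid)) < p
  edges <- grid[keep, , drop = FALSE]
  edges$sign <- sample(c(-1, 1), nrow(edges), replace = TRUE)
  rownames(edges) <- NULL
  list(edges = edges,
       graph = if (nrow(edges) == 0) {
         igraph::make_empty_graph(directed = TRUE) |>
           igraph::add_vertices(n_nodes, name = nodes)
       } else {
         g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                            vertices = nodes)
         g
       },
       nodes = nodes)
}

# random undirected graph (Erdos-Renyi) as edge data frame + igraph twin
random_ppi <- function(n_nodes, p = 0.15) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      stringsAsFactors = FALSE)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, n_nodes, name = nodes)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  }
  list(edges = edges, graph = g, nodes = nodes)
}

# small labeled feature table with planted signal on two named features
planted_dataset <- function(n = 200, beta = c(adrid = 3, bps = -3),
                            sigma = 0.3, seed = 42) {
  set.seed(seed)
  feats <- tibble::as_tibble(setNames(
    lapply(feature_names(), function(f) runif(n)), feature_names()))
  z <- scale(as.matrix(feats))
  full <- setNames(rep(0, length(feature_names())), feature_names())
  full[names(beta)] <- beta
  eta <- as.numeric(z %*% full) + rnorm(n, 0, sigma)
  feats$label <- ifelse(runif(n) < plogis(eta), "synergistic",
                        "antagonistic")
  feats$drug_a <- sprintf("dx%03d", seq_len(n))
  feats$drug_b <- sprintf("dy%03d", seq_len(n))
  feats
}
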