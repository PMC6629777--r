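# Seeded synthetic-fixture generators. They emulate, at toy scale, every
# input the pipeline consumes - drug annotation tables, the signed
# directed protein network, the undirected PPI network, a GO BP DAG with
# protein annotations, pathway gene sets and labeled pairs - with a label
# model whose feature-label association is known by construction:
#   label ~ Bernoulli(logistic(sum_f beta_f * z_f + eps)),
# z the within-fixture standardized features (missing -> 0 contribution),
# eps ~ Normal(0, sigma). Defaults plant signal on the ADR-overlap
# (positive) and biological-process-similarity (negative) features, the
# two strongest class differences seen in curated synergy data.

# Valid drug-like SMILES pool for the chemical-similarity feature
# (common small-molecule drugs; structure, not identity, is what matters).
.smiles_pool <- c(
  "CC(=O)OC1=CC=CC=C1C(=O)O",            # aspirin
  "CC(C)CC1=CC=C(C=C1)C(C)C(=O)O",       # ibuprofen
  "CC(=O)NC1=CC=C(C=C1)O",               # paracetamol
  "CN1C=NC2=C1C(=O)N(C(=O)N2C)C",        # caffeine
  "C1=CC=C(C=C1)C(=O)O",                 # benzoic acid
  "C1=CC=C2C(=C1)C=CC=C2O",              # naphthol
  "CN(C)CCC1=CNC2=C1C=C(C=C2)CC(=O)O",   # indole acid
  "CC1=CC=C(C=C1)S(=O)(=O)N",            # tosylamide
  "NC1=CC=C(C=C1)S(=O)(=O)NC2=NC=CC=N2", # sulfadiazine
  "CC(N)CC1=CC=CC=C1",                   # amphetamine
  "OC(=O)CCC(=O)O",                      # succinic acid
  "OCC(O)C(O)C(O)C(O)CO",                # sorbitol
  "CN1CCC[C@H]1C2=CN=CC=C2",             # nicotine
  "ClC1=CC=CC=C1Cl",                     # dichlorobenzene
  "CC(=O)C1=CC=CC=C1",                   # acetophenone
  "NCCC1=CC=C(O)C(O)=C1",                # dopamine
  "OC1=CC=CC=C1C(=O)O",                  # salicylic acid
  "CCN(CC)CCNC(=O)C1=CC=C(N)C=C1",       # procainamide
  "CC1=CN=C(C=N1)C",                     # dimethylpyrazine
  "COC1=CC=C(CCN)C=C1"                   # methoxyphenethylamine
)

.atc_letters <- strsplit("ABCDGHJLMNPRSV", "")[[1]]

#' Configuration of the synthetic study generator
#'
#' All sizes, rates and the label model in one serializable list; the
#' same configuration (same seed included) always yields byte-identical
#' fixtures.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_drugs Number of drugs.
#' @param n_diseases,disease_rate Disease vocabulary size and mean
#'   indications per drug.
#' @param n_adrs,adr_rate ADR vocabulary size and mean ADRs per drug.
#' @param n_proteins Protein universe size (shared by both networks).
#' @param targets_per_drug Inclusive range of signed targets per drug.
#' @param signed_density Directed edge probability of the signed network.
#' @param sign_balance Probability that a signed edge is promotive (+1).
#' @param ppi_density Edge probability of the undirected PPI network.
#' @param go_depth,go_branching Depth and branching of the GO BP tree.
#' @param part_of_rate Probability a DAG edge is `part_of` (else `is_a`).
#' @param annotation_rate Mean GO terms per protein.
#' @param n_pathways,pathway_size Number and size of pathway gene sets.
#' @param n_pairs Number of labeled drug pairs.
#' @param beta Named log-odds coefficients on the standardized features.
#' @param intercept Log-odds offset of the label model; the default (2.5)
#'   puts the realized synergistic prevalence near the roughly 3:1
#'   synergistic-to-antagonistic ratio typical of curated combination
#'   datasets, once the spread of the planted signal is taken into
#'   account.
#' @param sigma SD of the latent Gaussian noise in the label model.
#' @param missing_rate Per-feature probability of masking a computed
#'   feature value (exercises the complete-case path).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_drugs = 40, n_diseases = 60,
                       disease_rate = 6, n_adrs = 80, adr_rate = 8,
                       n_proteins = 60, targets_per_drug = c(1, 4),
                       signed_density = 0.05, sign_balance = 0.5,
                       ppi_density = 0.06, go_depth = 3, go_branching = 3,
                       part_of_rate = 0.2, annotation_rate = 2,
                       n_pathways = 15, pathway_size = 8, n_pairs = 400,
                       beta = c(did = 0, adrid = 3, bps = -3, sma = 0,
                                ss = 0, chem = 0, atc = 0),
                       intercept = 2.5, sigma = 0.5, missing_rate = 0) {
  if (signed_density > 1 || ppi_density > 1 || signed_density < 0 ||
      ppi_density < 0) {
    abort("network densities must lie in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1)")
  }
  full_beta <- setNames(rep(0, 7), feature_names())
  full_beta[names(beta)] <- beta
  structure(list(seed = seed, n_drugs = n_drugs, n_diseases = n_diseases,
                 disease_rate = disease_rate, n_adrs = n_adrs,
                 adr_rate = adr_rate, n_proteins = n_proteins,
                 targets_per_drug = targets_per_drug,
                 signed_density = signed_density,
                 sign_balance = sign_balance, ppi_density = ppi_density,
                 go_depth = go_depth, go_branching = go_branching,
                 part_of_rate = part_of_rate,
                 annotation_rate = annotation_rate,
                 n_pathways = n_pathways, pathway_size = pathway_size,
                 n_pairs = n_pairs, beta = full_beta, intercept = intercept,
                 sigma = sigma, missing_rate = missing_rate),
            class = "sim_config")
}

.sim_go <- function(config) {
  terms <- "GO:1"
  edges <- list()
  frontier <- "GO:1"
  counter <- 1L
  for (d in seq_len(config$go_depth)) {
    nxt <- character()
    for (parent in frontier) {
      for (b in seq_len(config$go_branching)) {
        counter <- counter + 1L
        child <- sprintf("GO:%d", counter)
        rel <- if (runif(1) < config$part_of_rate) "part_of" else "is_a"
        edges[[length(edges) + 1]] <- c(child, parent, rel)
        nxt <- c(nxt, child)
      }
    }
    terms <- c(terms, nxt)
    frontier <- nxt
  }
  m <- do.call(rbind, edges)
  go_dag(terms, tibble::tibble(child = m[, 1], parent = m[, 2],
                               relation = m[, 3]))
}

#' Generate a complete synthetic study
#'
#' Draws the drug store, both protein networks, the GO DAG and
#' annotations, pathway gene sets and `n_pairs` labeled drug pairs whose
#' labels follow the configured logistic model on the computed features.
#'
#' @param config A [sim_config()].
#' @return A `sim_study` list: `config`, `store`, `signed_graph`, `ppi`,
#'   `annotations`, `dag`, `pathways`, `pairs`, `dataset` (feature table
#'   with labels).
#' @export
sim_study <- function(config = sim_config()) {
  set.seed(config$seed)
  drug_ids <- sprintf("D%03d", seq_len(config$n_drugs))
  proteins <- sprintf("P%03d", seq_len(config$n_proteins))
  diseases_vocab <- sprintf("DIS%03d", seq_len(config$n_diseases))
  adr_vocab <- sprintf("ADR%03d", seq_len(config$n_adrs))

  draw_links <- function(ids, vocab, rate, col) {
    rows <- lapply(ids, function(id) {
      n <- min(stats::rpois(1, rate), length(vocab))
      if (n == 0) return(NULL)
      tibble::tibble(drug_id = id, !!col := sample(vocab, n))
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) {
      out <- tibble::tibble(drug_id = character(), !!col := character())
    }
    out
  }
  diseases <- draw_links(drug_ids, diseases_vocab, config$disease_rate,
                         "disease_id")
  adrs <- draw_links(drug_ids, adr_vocab, config$adr_rate, "adr_id")
  targets <- dplyr::bind_rows(lapply(drug_ids, function(id) {
    n <- sample(seq(config$targets_per_drug[1], config$targets_per_drug[2]), 1)
    tibble::tibble(drug_id = id, target_id = sample(proteins, n),
                   sign = sample(c(-1, 1), n, replace = TRUE))
  }))
  atc <- lapply(drug_ids, function(id) {
    n <- sample(1:2, 1)
    unique(replicate(n, sprintf(
      "%s%02d%s%s%02d", sample(.atc_letters, 1), sample(0:9, 1),
      sample(LETTERS, 1), sample(LETTERS, 1), sample(0:9, 1))))
  })
  drugs <- tibble::tibble(
    drug_id = drug_ids, name = paste0("drug_", tolower(drug_ids)),
    smiles = sample(.smiles_pool, config$n_drugs, replace = TRUE),
    atc = atc)
  store <- drug_store(drugs, diseases, adrs, targets)

  signed_graph <- .sim_signed_graph(proteins, config)
  ppi <- igraph::sample_gnp(config$n_proteins, config$ppi_density)
  igraph::V(ppi)$name <- proteins

  dag <- .sim_go(config)
  annotations <- dplyr::bind_rows(lapply(proteins, function(p) {
    n <- min(1 + stats::rpois(1, config$annotation_rate - 1),
             length(dag$terms))
    tibble::tibble(protein_id = p, go_term = sample(dag$terms, n))
  }))
  pathways <- setNames(lapply(seq_len(config$n_pathways), function(i) {
    sample(proteins, min(config$pathway_size, length(proteins)))
  }), sprintf("PW%03d", seq_len(config$n_pathways)))

  all_pairs <- t(combn(drug_ids, 2))
  take <- sample(nrow(all_pairs), min(config$n_pairs, nrow(all_pairs)))
  pairs <- tibble::tibble(drug_a = all_pairs[take, 1],
                          drug_b = all_pairs[take, 2],
                          label = NA_character_)

  dataset <- build_dataset(pairs, store, signed_graph, ppi, annotations, dag)
  feats <- as.matrix(dataset[, feature_names()])
  z <- scale(feats)
  z[!is.finite(z)] <- 0  # missing or constant features contribute nothing
  eta <- config$intercept + as.numeric(z %*% config$beta) +
    rnorm(nrow(dataset), 0, config$sigma)
  lab <- rbinom(nrow(dataset), 1, plogis(eta))
  dataset$label <- ifelse(lab == 1, "synergistic", "antagonistic")

  if (config$missing_rate > 0) {
    for (f in feature_names()) {
      mask <- runif(nrow(dataset)) < config$missing_rate
      dataset[[f]][mask] <- NA_real_
    }
  }
  pairs$label <- dataset$label

  structure(list(config = config, store = store, signed_graph = signed_graph,
                 ppi = ppi, annotations = annotations, dag = dag,
                 pathways = pathways, pairs = pairs, dataset = dataset),
            class = "sim_study")
}

.sim_signed_graph <- function(proteins, config) {
  g <- igraph::sample_gnp(length(proteins), config$signed_density,
                          directed = TRUE)
  igraph::V(g)$name <- proteins
  igraph::E(g)$sign <- ifelse(
    runif(igraph::ecount(g)) < config$sign_balance, 1, -1)
  g
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "<sim_study> seed %d: %d drugs, %d proteins, %d pairs (%d synergistic)\n",
    x$config$seed, x$config$n_drugs, x$config$n_proteins,
    nrow(x$dataset), sum(x$dataset$label == "synergistic")))
  invisible(x)
}

#' Write a synthetic study to the package's plain-text formats
#'
#' Emits the four drug-store tables, `signed_network.tsv`, `ppi.tsv`,
#' `go.obo`, `annotations.tsv`, `pathways.gmt`, `pairs.tsv`,
#' `features.csv` and `config.json`; every file reads back through the
#' corresponding reader.
#'
#' @param study A `sim_study`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_sim_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_drug_store(study$store, dir)
  write_signed_network(study$signed_graph, file.path(dir, "signed_network.tsv"))
  write_ppi_network(study$ppi, file.path(dir, "ppi.tsv"))
  write_obo_dag(study$dag, file.path(dir, "go.obo"))
  readr::write_tsv(study$annotations, file.path(dir, "annotations.tsv"),
                   progress = FALSE)
  write_gmt(study$pathways, file.path(dir, "pathways.gmt"))
  write_pairs(study$pairs, file.path(dir, "pairs.tsv"))
  write_features(study$dataset, file.path(dir, "features.csv"))
  cfg <- unclass(study$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Hand-checkable worked examples for the graph and ontology features
#'
#' A bundle of micro-fixtures whose expected values were derived by hand
#' (sign propagation on two-node signed graphs, BFS on a path graph, Wang
#' S-value arithmetic on a three-term DAG), each carrying its expected
#' value and a one-line derivation.
#'
#' @return Named list of cases; each case has `inputs`, `expected` and
#'   `derivation`.
#' @export
worked_examples <- function() {
  two_drug_store <- function(sign_a, sign_b) {
    drug_store(
      tibble::tibble(drug_id = c("a", "b")),
      targets = tibble::tibble(drug_id = c("a", "b"),
                               target_id = c("Ta", "Tb"),
                               sign = c(sign_a, sign_b)))
  }
  path_graph <- igraph::make_graph(~ P1 - P2 - P3 - P4 - P5)
  pair_graph <- igraph::make_graph(~ u - v)
  dag3 <- go_dag(c("R", "C1", "C2"),
                 tibble::tibble(child = c("C1", "C2"), parent = c("R", "R"),
                                relation = c("is_a", "is_a")))
  list(
    sign_rules = list(
      inputs = tibble::tribble(
        ~x_on_y, ~y_on_z, ~x_on_z,
        1, 1, 1,    # promote of promote is promote
        1, -1, -1,  # promote of inhibit is inhibit
        -1, -1, 1   # inhibit of inhibit is promote
      ),
      expected = NULL,
      derivation = "composition of action signs is their product"
    ),
    sma_opposite = list(
      inputs = list(
        store = two_drug_store(sign_a = -1, sign_b = 1),
        graph = signed_network("Tb", "Ta", 1)),
      expected = -1,
      derivation = paste(
        "b promotes Tb, Tb promotes Ta => propagated mode promote;",
        "a inhibits Ta => c = -1; no reverse path; SMA = -1/1")
    ),
    sma_agree = list(
      inputs = list(
        store = two_drug_store(sign_a = 1, sign_b = 1),
        graph = signed_network(c("Tb", "Ta"), c("Ta", "Tb"), c(1, 1))),
      expected = 1,
      derivation = "both propagated modes match the direct modes; SMA = 2/2"
    ),
    sma_balanced = list(
      inputs = list(
        store = drug_store(
          tibble::tibble(drug_id = c("a", "b")),
          targets = tibble::tibble(drug_id = c("a", "b", "b"),
                                   target_id = c("Ta", "T1", "T2"),
                                   sign = c(1, 1, 1))),
        graph = signed_network(c("T1", "T2"), c("Ta", "Ta"), c(1, -1))),
      expected = NA_real_,
      derivation = paste(
        "two equal-length paths to Ta with opposite signs average to 0;",
        "denominator 0 => undefined")
    ),
    ss_path = list(
      inputs = list(graph = path_graph, targets_a = "P1", targets_b = "P5"),
      expected = 4,
      derivation = "singletons: d_aa = d_bb = 0; d_ab = 4 hops; s = 4 - 0"
    ),
    ss_overlap = list(
      inputs = list(graph = pair_graph, targets_a = c("u", "v"),
                    targets_b = c("u", "v")),
      expected = -1,
      derivation = "d_aa = d_bb = 1 (nearest other member); d_ab = 0; s = 0 - 1"
    ),
    wang_parent_child = list(
      inputs = list(dag = dag3, t1 = "C1", t2 = "R"),
      expected = 1.8 / 2.8,
      derivation = "S_C1 = {C1: 1, R: 0.8}, S_R = {R: 1}; (0.8 + 1)/(1.8 + 1)"
    ),
    wang_siblings = list(
      inputs = list(dag = dag3, t1 = "C1", t2 = "C2"),
      expected = 1.6 / 3.6,
      derivation = "shared ancestor R only: (0.8 + 0.8)/(1.8 + 1.8)"
    )
  )
}

#' Write the worked-example bundle to disk
#'
#' Emits the micro-fixtures in the package's standard formats plus an
#' `expected.json` sidecar with each case's expected value and
#' derivation note.
#'
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_worked_examples <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- worked_examples()
  for (nm in c("sma_opposite", "sma_agree", "sma_balanced")) {
    sub <- file.path(dir, nm)
    write_drug_store(ex[[nm]]$inputs$store, sub)
    write_signed_network(ex[[nm]]$inputs$graph,
                         file.path(sub, "signed_network.tsv"))
  }
  write_ppi_network(ex$ss_path$inputs$graph, file.path(dir, "ss_path.tsv"))
  write_ppi_network(ex$ss_overlap$inputs$graph,
                    file.path(dir, "ss_overlap.tsv"))
  write_obo_dag(ex$wang_parent_child$inputs$dag, file.path(dir, "go3.obo"))
  sidecar <- lapply(ex, function(case) {
    list(expected = case$expected, derivation = case$derivation)
  })
  jsonlite::write_json(sidecar, file.path(dir, "expected.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
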