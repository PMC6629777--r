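# Synthetic study generator: determinism, round-trips through the
# readers, and the planted label model.

small_config <- function(seed = 1, n_pairs = 60, ...) {
  sim_config(seed = seed, n_drugs = 18, n_diseases = 25, n_adrs = 30,
             n_proteins = 25, n_pairs = n_pairs, ...)
}

test_that("the generator is deterministic given the configuration", {
  s1 <- sim_study(small_config(seed = 42))
  s2 <- sim_study(small_config(seed = 42))
  expect_identical(s1$dataset, s2$dataset)
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(igraph::as_data_frame(s1$signed_graph),
                   igraph::as_data_frame(s2$signed_graph))
  s3 <- sim_study(small_config(seed = 43))
  expect_false(identical(s1$dataset, s3$dataset))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_sim_study(s1, dir1); write_sim_study(s2, dir2)
  for (f in c("drugs.tsv", "pairs.tsv", "features.csv", "go.obo")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("every generated artifact round-trips through the readers", {
  study <- sim_study(small_config(seed = 7))
  dir <- withr::local_tempdir()
  expect_no_warning(write_sim_study(study, dir))
  store <- read_drug_store(file.path(dir, "drugs.tsv"),
                           file.path(dir, "drug_disease.tsv"),
                           file.path(dir, "drug_adr.tsv"),
                           file.path(dir, "drug_target.tsv"))
  expect_equal(store$targets, study$store$targets)
  expect_equal(store$drugs, study$store$drugs)
  g <- read_signed_network(file.path(dir, "signed_network.tsv"))
  expect_equal(igraph::ecount(g), igraph::ecount(study$signed_graph))
  ppi <- read_ppi_network(file.path(dir, "ppi.tsv"))
  expect_equal(igraph::ecount(ppi), igraph::ecount(study$ppi))
  dag <- read_obo_dag(file.path(dir, "go.obo"))
  expect_setequal(dag$terms, study$dag$terms)
  expect_equal(dplyr::arrange(dag$edges, child),
               dplyr::arrange(study$dag$edges, child))
  ann <- read_annotations(file.path(dir, "annotations.tsv"), dag)
  expect_equal(nrow(ann), nrow(study$annotations))
  sets <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_equal(sets, study$pathways)
  pairs <- read_pairs(file.path(dir, "pairs.tsv"))
  expect_equal(pairs, study$pairs)
  # feature table re-read matches to serialization precision
  feats <- read_features(file.path(dir, "features.csv"))
  expect_equal(as.data.frame(feats), as.data.frame(study$dataset),
               tolerance = 1e-12)
})

test_that("label model responds to the planted coefficients", {
  # zero effects: labels follow the intercept alone and features carry no
  # signal, so CV accuracy collapses to the majority rate
  null <- sim_study(small_config(seed = 5, beta = c(did = 0),
                                 intercept = 0, n_pairs = 120))
  prev <- mean(null$dataset$label == "synergistic")
  expect_lt(abs(prev - 0.5), 0.15)
  # strong planted effect separates the classes
  strong <- sim_study(sim_config(seed = 6, n_drugs = 25, n_proteins = 30,
                                 n_pairs = 250,
                                 beta = c(adrid = 3, bps = -3),
                                 sigma = 0.3))
  cv <- repeated_cv(strong$dataset, feature_names(),
                    cv_config(5, 3, seed = 2), nrounds = 40)
  expect_gt(mean(cv$metrics$accuracy), 0.75)
  imp <- tidy(syn_train(strong$dataset, seed = 2))
  expect_true(all(c("adrid", "bps") %in% imp$feature[1:3]))
})

test_that("missingness injection exercises the complete-case filter", {
  study <- sim_study(small_config(seed = 9, missing_rate = 0.2))
  d <- study$dataset
  expect_true(anyNA(d[feature_names()]))
  cc <- complete_cases(d)
  expect_lt(nrow(cc), nrow(d))
  expect_false(anyNA(cc[feature_names()]))
  expect_error(sim_config(missing_rate = 1.2), "missing_rate")
  expect_error(sim_config(ppi_density = 2), "densities")
})

test_that("the worked-example bundle matches its sidecar expectations", {
  dir <- withr::local_tempdir()
  write_worked_examples(dir)
  sidecar <- jsonlite::read_json(file.path(dir, "expected.json"))
  expect_equal(sidecar$sma_opposite$expected, -1)
  expect_equal(sidecar$ss_path$expected, 4)
  expect_equal(sidecar$wang_parent_child$expected, 1.8 / 2.8)
  # files re-read and re-evaluated reproduce the expectations
  store <- read_drug_store(
    file.path(dir, "sma_opposite", "drugs.tsv"),
    target_tsv = file.path(dir, "sma_opposite", "drug_target.tsv"))
  g <- read_signed_network(file.path(dir, "sma_opposite",
                                     "signed_network.tsv"))
  expect_equal(sma(store, "a", "b", g)$value, -1)
  dag <- read_obo_dag(file.path(dir, "go3.obo"))
  expect_equal(wang_term_similarity("C1", "R", dag), 1.8 / 2.8)
  ppi <- read_ppi_network(file.path(dir, "ss_path.tsv"))
  expect_equal(separation_score_sets("P1", "P5", ppi)$value, 4)
})
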