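# Assembly of the seven-feature vector per drug pair and of labeled
# feature tables. Missing features are carried as NA (first-class, never
# silently 0); the boosted-tree learner consumes them natively while
# baseline classifiers see complete cases only.

#' Compute the seven-feature vector of one drug pair
#'
#' Features, in canonical order: `did` (indication Jaccard), `adrid` (ADR
#' Jaccard), `bps` (GO BP Wang/BMA similarity of target annotations),
#' `sma` (signed-path mode-of-action similarity), `ss` (PPI separation
#' score), `chem` (fingerprint Tanimoto), `atc` (ATC-code similarity).
#' Every feature is symmetric in the two drugs, so the result is
#' order-invariant.
#'
#' @param store A `drug_store`.
#' @param drug_a,drug_b Drug ids in the store.
#' @param signed_graph Signed directed `igraph` for `sma` (`NULL` leaves
#'   it `NA`).
#' @param ppi Undirected `igraph` for `ss` (`NULL` leaves it `NA`).
#' @param annotations,dag GO annotations and DAG for `bps` (`NULL` leaves
#'   it `NA`).
#' @param fingerprint Fingerprint backend for `chem`
#'   (see [chemical_similarity()]).
#' @return One-row tibble with the seven feature columns (NA = missing).
#' @export
featurize_pair <- function(store, drug_a, drug_b, signed_graph = NULL,
                           ppi = NULL, annotations = NULL, dag = NULL,
                           fingerprint = fp_path_ob) {
  .stopifnot_store(store)
  .require_drug(store, drug_a); .require_drug(store, drug_b)
  ra <- drug_record(store, drug_a)
  rb <- drug_record(store, drug_b)
  tibble::tibble(
    did = did(store, drug_a, drug_b),
    adrid = adrid(store, drug_a, drug_b),
    bps = if (is.null(annotations) || is.null(dag)) NA_real_ else
      bps(store, drug_a, drug_b, annotations, dag),
    sma = if (is.null(signed_graph)) NA_real_ else
      sma(store, drug_a, drug_b, signed_graph)$value,
    ss = if (is.null(ppi)) NA_real_ else
      separation_score(store, drug_a, drug_b, ppi)$value,
    chem = chemical_similarity(ra$smiles, rb$smiles, fingerprint),
    atc = atc_similarity(ra$atc, rb$atc)
  )
}

#' Build a labeled feature table for a set of drug pairs
#'
#' @param pairs Tibble `drug_a`, `drug_b`, `label`
#'   (see [read_pairs()]).
#' @inheritParams featurize_pair
#' @return Tibble: `drug_a`, `drug_b`, the seven feature columns in
#'   canonical order, `label`.
#' @export
build_dataset <- function(pairs, store, signed_graph = NULL, ppi = NULL,
                          annotations = NULL, dag = NULL,
                          fingerprint = fp_path_ob) {
  fp_cache <- new.env(parent = emptyenv())
  cached_fp <- function(smiles) {
    if (is.null(fp_cache[[smiles]])) fp_cache[[smiles]] <- fingerprint(smiles)
    fp_cache[[smiles]]
  }
  feats <- purrr::map2_dfr(pairs$drug_a, pairs$drug_b, function(a, b) {
    featurize_pair(store, a, b, signed_graph, ppi, annotations, dag,
                   cached_fp)
  })
  dplyr::bind_cols(pairs[c("drug_a", "drug_b")], feats,
                   tibble::tibble(label = pairs$label))
}

#' Keep only drug pairs with no missing value among the named features
#'
#' Mirrors the complete-case filter used before comparing classifiers
#' that cannot handle missing inputs. Row order is preserved.
#'
#' @param dataset A feature table from [build_dataset()].
#' @param features Feature columns that must be non-missing; an empty
#'   vector returns the dataset unchanged.
#' @return The filtered tibble.
#' @export
complete_cases <- function(dataset, features = feature_names()) {
  if (length(features) == 0) return(dataset)
  missing_cols <- setdiff(features, names(dataset))
  if (length(missing_cols) > 0) {
    abort(sprintf("unknown feature column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  dataset[complete.cases(dataset[features]), , drop = FALSE]
}

#' Write / read a feature table as CSV
#'
#' Missing feature values are serialized as empty cells.
#'
#' @param dataset A feature table.
#' @param path CSV path.
#' @return `write_features` the path; `read_features` the tibble.
#' @export
write_features <- function(dataset, path) {
  readr::write_csv(dataset, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    drug_a = readr::col_character(),
    drug_b = readr::col_character(),
    label = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}
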