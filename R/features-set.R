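# Set-overlap and string-based pair features: indication overlap (DID),
# ADR overlap (ADRID), ATC-code similarity and chemical Tanimoto similarity.
# An empty comparison (no evidence on either side) yields NA, never 0:
# absence of annotation is lack of evidence, not evidence of dissimilarity.

#' Jaccard similarity with explicit counts
#'
#' Computes |A ∩ B| / |A ∪ B| on two finite token sets. When both sets are
#' empty the ratio is undefined and the value is `NA`.
#'
#' @param set_a,set_b Character vectors (treated as sets).
#' @return One-row tibble with `value`, `n_intersection`, `n_union`.
#' @export
jaccard_similarity <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  n_int <- length(intersect(set_a, set_b))
  n_un <- length(union(set_a, set_b))
  tibble::tibble(
    value = if (n_un == 0) NA_real_ else n_int / n_un,
    n_intersection = n_int,
    n_union = n_un
  )
}

#' Disease intersection degree (DID) of a drug pair
#'
#' Jaccard overlap of the two drugs' indication (disease) sets: the
#' proportion of shared indications. `NA` when neither drug has any
#' recorded indication.
#'
#' @param store A `drug_store`.
#' @param drug_a,drug_b Drug ids in the store.
#' @return Numeric scalar in \[0, 1\] or `NA`.
#' @export
did <- function(store, drug_a, drug_b) {
  .stopifnot_store(store)
  .require_drug(store, drug_a); .require_drug(store, drug_b)
  jaccard_similarity(
    store$diseases$disease_id[store$diseases$drug_id == drug_a],
    store$diseases$disease_id[store$diseases$drug_id == drug_b])$value
}

#' Adverse drug reaction intersection degree (ADRID) of a drug pair
#'
#' Jaccard overlap of the two drugs' ADR sets.
#'
#' @inheritParams did
#' @return Numeric scalar in \[0, 1\] or `NA`.
#' @export
adrid <- function(store, drug_a, drug_b) {
  .stopifnot_store(store)
  .require_drug(store, drug_a); .require_drug(store, drug_b)
  jaccard_similarity(
    store$adrs$adr_id[store$adrs$drug_id == drug_a],
    store$adrs$adr_id[store$adrs$drug_id == drug_b])$value
}

# Prefix lengths of the five ATC levels: anatomical main group (1),
# therapeutic subgroup (3), pharmacological subgroup (4), chemical
# subgroup (5), chemical substance (7).
.atc_levels <- c(1L, 3L, 4L, 5L, 7L)

#' ATC-code similarity of two drugs
#'
#' For one pair of codes the score is k/5, where k is the number of
#' leading ATC levels (prefix lengths 1, 3, 4, 5, 7) on which both codes
#' agree; comparison stops at the shorter code's level. The drug-level
#' similarity is the maximum over all cross pairs of the two drugs' code
#' sets. `NA` when either drug has no ATC code.
#'
#' @param codes_a,codes_b Character vectors of ATC codes (lengths 1, 3, 4,
#'   5 or 7).
#' @return Numeric scalar in \{0, 0.2, 0.4, 0.6, 0.8, 1\} or `NA`.
#' @export
atc_similarity <- function(codes_a, codes_b) {
  codes_a <- .check_atc(unique(codes_a))
  codes_b <- .check_atc(unique(codes_b))
  if (length(codes_a) == 0 || length(codes_b) == 0) return(NA_real_)
  best <- 0L
  for (a in codes_a) {
    for (b in codes_b) {
      lv <- .atc_levels[.atc_levels <= min(nchar(a), nchar(b))]
      k <- sum(substring(a, 1, lv) == substring(b, 1, lv))
      if (k > best) best <- k
    }
  }
  best / 5
}

#' Chemical structure similarity of two drugs
#'
#' Tanimoto coefficient |F_a ∩ F_b| / |F_a ∪ F_b| on binary molecular
#' fingerprints of the two SMILES strings. The default backend is a hashed
#' linear-path fingerprint (Open Babel FP2: paths of length 1-7 hashed
#' into 1024 bits); any function mapping a SMILES string to a logical bit
#' vector (or `NULL` on failure) can be plugged in. The value is `NA` when
#' either SMILES is absent or unparseable, or both fingerprints are empty.
#'
#' @param smiles_a,smiles_b SMILES strings (or `NA`).
#' @param fingerprint Fingerprint backend function; default [fp_path_ob()].
#' @return Numeric scalar in \[0, 1\] or `NA`.
#' @export
chemical_similarity <- function(smiles_a, smiles_b, fingerprint = fp_path_ob) {
  fa <- .fingerprint_or_null(smiles_a, fingerprint)
  fb <- .fingerprint_or_null(smiles_b, fingerprint)
  if (is.null(fa) || is.null(fb)) return(NA_real_)
  tanimoto(fa, fb)
}

.fingerprint_or_null <- function(smiles, fingerprint) {
  if (is.null(smiles) || length(smiles) != 1 || is.na(smiles) || smiles == "") {
    return(NULL)
  }
  tryCatch(fingerprint(smiles), error = function(e) NULL)
}

#' Tanimoto coefficient of two binary fingerprints
#'
#' @param fp_a,fp_b Logical vectors of equal length.
#' @return |A ∩ B| / |A ∪ B|; `NA` if the union is empty.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) abort("fingerprint lengths differ")
  un <- sum(fp_a | fp_b)
  if (un == 0) return(NA_real_)
  sum(fp_a & fp_b) / un
}

#' Hashed path fingerprint backend (Open Babel FP2)
#'
#' Linear fragments of length 1-7 hashed into a 1024-bit vector.
#'
#' @param smiles A single SMILES string.
#' @return Logical vector of length 1024; errors on unparseable SMILES.
#' @export
fp_path_ob <- function(smiles) {
  bits <- ChemmineOB::fingerprint_OB(
    ChemmineOB::forEachMol("SMILES", smiles, identity), "FP2")
  as.logical(as.numeric(bits))
}
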