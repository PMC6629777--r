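# Model interpretation: which drug pairs the classifier gets consistently
# right or wrong across CV repetitions, whether that consistency clusters
# in particular ATC anatomical main groups (Fisher's exact test), and
# which pathways the targets of consistently-classified pairs enrich
# (hypergeometric test, Bonferroni).

#' Partition pairs by prediction consistency across CV repetitions
#'
#' @param cv_record The `cv_record` tibble of a [repeated_cv()] result
#'   (`pair_id`, `run`, `correct`).
#' @return List of character vectors: `always_correct`, `always_wrong`,
#'   `correct_at_least_once`, `wrong_at_least_once`.
#' @export
consistent_pairs <- function(cv_record) {
  counts <- cv_record |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     .groups = "drop")
  if (length(unique(counts$n)) > 1) {
    abort("pairs have unequal numbers of CV repetitions")
  }
  list(
    always_correct = counts$pair_id[counts$n_correct == counts$n],
    always_wrong = counts$pair_id[counts$n_correct == 0],
    correct_at_least_once = counts$pair_id[counts$n_correct > 0],
    wrong_at_least_once = counts$pair_id[counts$n_correct < counts$n]
  )
}

.pair_drugs <- function(pair_ids) {
  unlist(strsplit(pair_ids, "|", fixed = TRUE), use.names = FALSE)
}

#' Applicability domain over ATC anatomical main groups
#'
#' Drugs occurring in always-correct and always-wrong pairs are tallied
#' per ATC first letter (a drug in k pairs contributes k; drugs without
#' an ATC code fall into an `unclassified` bucket excluded from testing).
#' Each group gets a 2x2 table (group vs other drugs, correct vs wrong
#' pairs), a two-sided Fisher's exact p-value, the classic cross-product
#' odds ratio, and the proportion-ratio variant
#' (share of the group among correct-pair drugs divided by its share
#' among wrong-pair drugs). Groups absent from both sides are omitted.
#'
#' @param always_correct,always_wrong Character vectors of pair ids
#'   (see [consistent_pairs()] and [pair_id()]).
#' @param store A `drug_store` supplying ATC codes.
#' @return A tibble: `atc_group`, `n_group_correct`, `n_other_correct`,
#'   `n_group_wrong`, `n_other_wrong`, `odds_ratio`, `prop_ratio`,
#'   `fisher_p`.
#' @export
atc_domain_test <- function(always_correct, always_wrong, store) {
  .stopifnot_store(store)
  groups_of <- function(pair_ids) {
    drugs <- .pair_drugs(pair_ids)
    codes <- store$drugs$atc[match(drugs, store$drugs$drug_id)]
    vapply(codes, function(x) {
      if (is.null(x) || length(x) == 0) "unclassified" else {
        paste(sort(unique(substr(x, 1, 1))), collapse = "")
      }
    }, "")
  }
  # a drug annotated in several main groups contributes to each of them
  expand <- function(pair_ids) {
    g <- groups_of(pair_ids)
    unlist(strsplit(g[g != "unclassified"], ""), use.names = FALSE)
  }
  gc <- expand(always_correct)
  gw <- expand(always_wrong)
  groups <- sort(unique(c(gc, gw)))
  purrr::map_dfr(groups, function(g) {
    a <- sum(gc == g); c_ <- length(gc) - a
    b <- sum(gw == g); d <- length(gw) - b
    p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                     alternative = "two.sided")$p.value
    tibble::tibble(
      atc_group = g,
      n_group_correct = a, n_other_correct = c_,
      n_group_wrong = b, n_other_wrong = d,
      odds_ratio = if (b * c_ == 0) NA_real_ else (a * d) / (b * c_),
      prop_ratio = if (a + c_ == 0 || b + d == 0 || b == 0) NA_real_ else
        (a / (a + c_)) / (b / (b + d)),
      fisher_p = p
    )
  })
}

#' Hypergeometric pathway enrichment of a target set
#'
#' Upper-tail hypergeometric p-value per pathway (probability of at least
#' the observed overlap when drawing the target set from the background),
#' Bonferroni-adjusted across the tested pathways; pathways with adjusted
#' p below `alpha` are flagged significant. The background defaults to
#' the union of all pathway gene sets.
#'
#' @param targets Character vector of gene/protein ids.
#' @param pathways Named list of gene sets (see [read_gmt()]).
#' @param background Gene universe; targets outside it are dropped.
#' @param alpha Significance cutoff on the adjusted p-value.
#' @return A tibble: `pathway`, `n_hits`, `n_pathway`, `n_targets`,
#'   `p_value`, `p_adjusted`, `significant`; zero rows for an empty
#'   target set.
#' @export
pathway_enrichment <- function(targets, pathways, background = NULL,
                               alpha = 0.01) {
  if (is.null(background)) background <- unique(unlist(pathways))
  targets <- intersect(unique(targets), background)
  if (length(targets) == 0) {
    return(tibble::tibble(pathway = character(), n_hits = integer(),
                          n_pathway = integer(), n_targets = integer(),
                          p_value = double(), p_adjusted = double(),
                          significant = logical()))
  }
  n_bg <- length(background)
  n_draw <- length(targets)
  rows <- purrr::map_dfr(names(pathways), function(nm) {
    pw <- intersect(unique(pathways[[nm]]), background)
    k <- length(intersect(targets, pw))
    # P(X >= k), X ~ Hypergeom(#pathway, #background - #pathway, #draw)
    p <- phyper(k - 1, length(pw), n_bg - length(pw), n_draw,
                lower.tail = FALSE)
    tibble::tibble(pathway = nm, n_hits = k, n_pathway = length(pw),
                   n_targets = n_draw, p_value = p)
  })
  rows$p_adjusted <- pmin(1, rows$p_value * nrow(rows))
  rows$significant <- rows$p_adjusted < alpha
  dplyr::arrange(rows, .data$p_value)
}

#' Pathways significant in one enrichment but not another
#'
#' @param rows_first,rows_second Enrichment tables from
#'   [pathway_enrichment()].
#' @return Character vector of pathway ids significant in the first
#'   table only.
#' @export
exclusive_pathways <- function(rows_first, rows_second) {
  setdiff(rows_first$pathway[rows_first$significant],
          rows_second$pathway[rows_second$significant])
}
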