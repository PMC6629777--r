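# Biological-process similarity (BPS): Wang's graph-based GO semantic
# similarity with best-match-average (BMA) set combining. A term's
# semantic profile is the set of its ancestors (self included), each with
# an S-value: 1 for the term itself, and for each ancestor the maximum
# over paths of the product of edge weights (is_a 0.8, part_of 0.6).

.wang_weights <- c(is_a = 0.8, part_of = 0.6)

#' Wang S-value profile of a GO term
#'
#' @param term Term id present in the DAG.
#' @param dag A `go_dag`.
#' @return Named numeric vector: ancestor (and self) term -> S-value in
#'   (0, 1\].
#' @export
go_svalues <- function(term, dag) {
  if (!term %in% dag$terms) abort(sprintf("unknown term '%s'", term))
  if (!is.null(dag$cache) && !is.null(dag$cache[[term]])) {
    return(dag$cache[[term]])
  }
  g <- dag$graph
  anc <- igraph::V(g)$name[as.integer(
    igraph::subcomponent(g, term, mode = "out"))]
  sub <- dag$edges[dag$edges$child %in% anc & dag$edges$parent %in% anc, ]
  s <- setNames(rep(-Inf, length(anc)), anc)
  s[term] <- 1
  # edges run child -> parent, so a topological order of the ancestor
  # subgraph visits each child before its parents
  sg <- igraph::induced_subgraph(g, anc)
  ord <- igraph::V(sg)$name[as.integer(igraph::topo_sort(sg, mode = "out"))]
  for (v in ord) {
    e <- sub[sub$child == v, ]
    if (nrow(e) == 0) next
    w <- .wang_weights[e$relation] * s[v]
    for (i in seq_len(nrow(e))) {
      p <- e$parent[i]
      if (w[i] > s[p]) s[p] <- w[i]
    }
  }
  s <- s[is.finite(s)]
  if (!is.null(dag$cache)) dag$cache[[term]] <- s
  s
}

#' Wang semantic similarity of two GO terms
#'
#' Sim(t1, t2) = sum over shared ancestors of (S1 + S2), divided by the
#' sum of all S-values of both terms. Equal terms score 1.
#'
#' @param t1,t2 Term ids in the DAG.
#' @param dag A `go_dag`.
#' @return Numeric scalar in \[0, 1\].
#' @export
wang_term_similarity <- function(t1, t2, dag) {
  s1 <- go_svalues(t1, dag)
  s2 <- go_svalues(t2, dag)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

#' Best-match-average similarity of two GO term sets
#'
#' (sum over t in set1 of its best match in set2 + sum over u in set2 of
#' its best match in set1) / (|set1| + |set2|). `NA` when either set is
#' empty.
#'
#' @param set1,set2 Character vectors of term ids.
#' @param dag A `go_dag`.
#' @return Numeric scalar in \[0, 1\] or `NA`.
#' @export
termset_similarity_bma <- function(set1, set2, dag) {
  set1 <- unique(set1); set2 <- unique(set2)
  if (length(set1) == 0 || length(set2) == 0) return(NA_real_)
  m <- matrix(0, length(set1), length(set2))
  for (i in seq_along(set1)) {
    for (j in seq_along(set2)) {
      m[i, j] <- wang_term_similarity(set1[i], set2[j], dag)
    }
  }
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) /
    (length(set1) + length(set2))
}

#' Biological-process similarity (BPS) of a drug pair
#'
#' Each drug's term set is the union of GO BP annotations over its
#' protein interactants (targets); the similarity of the two unions is
#' the Wang/BMA set similarity. `NA` when either union is empty (drug
#' without targets, or targets without annotation).
#'
#' @param store A `drug_store`.
#' @param drug_a,drug_b Drug ids.
#' @param annotations Tibble `protein_id`, `go_term`
#'   (see [read_annotations()]).
#' @param dag A `go_dag`.
#' @return Numeric scalar in \[0, 1\] or `NA`.
#' @export
bps <- function(store, drug_a, drug_b, annotations, dag) {
  .stopifnot_store(store)
  .require_drug(store, drug_a); .require_drug(store, drug_b)
  terms_of <- function(id) {
    tg <- names(drug_record(store, id)$targets)
    unique(annotations$go_term[annotations$protein_id %in% tg])
  }
  termset_similarity_bma(terms_of(drug_a), terms_of(drug_b), dag)
}
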