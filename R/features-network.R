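# Graph-algorithmic pair features on protein networks.
#
# Similarity of mode of action (SMA): how a drug's promotive (+1) or
# inhibitory (-1) influence propagates to the partner drug's targets along
# ALL shortest paths of a signed directed protein network. A path's sign is
# the product of its edge signs, so promote-of-promote is promote,
# promote-of-inhibit is inhibit, and inhibit-of-inhibit is promote.
#
# Separation score (SS): network separation of the two drugs' target
# modules on an undirected PPI network,
#   s_ab = <d_ab> - (<d_aa> + <d_bb>) / 2,
# negative values meaning overlapping modules.

.virtual <- ".drug."

.augment_with_drug <- function(graph, sources) {
  # attach a virtual drug node with signed edges to its targets; targets
  # absent from the network are added as isolated vertices first so the
  # direct virtual edge still exists
  nodes <- igraph::V(graph)$name
  add <- setdiff(names(sources), nodes)
  if (length(add) > 0) graph <- igraph::add_vertices(graph, length(add), name = add)
  graph <- igraph::add_vertices(graph, 1, name = .virtual)
  graph <- igraph::add_edges(
    graph,
    rbind(rep(.virtual, length(sources)), names(sources)),
    sign = unname(sources))
  graph
}

.path_sign <- function(graph, vpath) {
  eids <- igraph::get_edge_ids(
    graph, rbind(vpath[-length(vpath)], vpath[-1]))
  prod(igraph::E(graph)$sign[eids])
}

#' All shortest signed paths from a drug to a protein
#'
#' The drug is represented as a virtual node with one signed edge per
#' direct target (the drug's own action sign on it). All minimum-length
#' directed paths from the virtual node to `target` are returned, each
#' with the product of edge signs along it (the virtual action edge
#' included).
#'
#' @param graph Directed `igraph` with `sign` edge attribute (+1/-1).
#' @param sources Named numeric vector: protein id -> initial action sign.
#' @param target Protein id. Unreachable or absent targets give zero rows.
#' @return Tibble with list-column `nodes` (protein path, virtual node
#'   omitted), `sign` and `length` (edge count including the virtual edge).
#' @export
all_shortest_signed_paths <- function(graph, sources, target) {
  if (length(sources) == 0) abort("at least one signed source is required")
  if (!all(sources %in% c(-1, 1))) abort("source signs must be +1 or -1")
  g <- .augment_with_drug(graph, sources)
  if (!target %in% igraph::V(g)$name || target == .virtual) {
    return(tibble::tibble(nodes = list(), sign = double(), length = integer()))
  }
  res <- suppressWarnings(igraph::all_shortest_paths(
    g, from = .virtual, to = target, mode = "out"))
  paths <- res$vpaths %||% res$res
  if (length(paths) == 0) {
    return(tibble::tibble(nodes = list(), sign = double(), length = integer()))
  }
  tibble::tibble(
    nodes = lapply(paths, function(p) igraph::V(g)$name[as.integer(p)][-1]),
    sign = vapply(paths, function(p) .path_sign(g, as.integer(p)), 0),
    length = vapply(paths, function(p) length(p) - 1L, 1L)
  )
}

#' Similarity of mode of action (SMA) of a drug pair
#'
#' For each target t of drug a, every shortest signed path from drug b
#' (virtual node over b's signed targets) to t carries a propagated mode;
#' the path coefficient is +1 when that mode equals drug a's own action
#' sign on t and -1 otherwise. Per-target coefficients are averaged over
#' the tied shortest paths; the score is the sum of per-target means (both
#' directions) divided by the sum of their absolute values, giving a value
#' in \[-1, 1\]: +1 when the partner reproduces every direct mode, -1 when
#' it opposes every one. Targets with no path are excluded from both sums;
#' the value is `NA` when no target has a path or all path evidence is
#' balanced.
#'
#' @param store A `drug_store`.
#' @param drug_a,drug_b Drug ids with at least one signed target each.
#' @param graph Signed directed `igraph` (see [read_signed_network()]).
#' @return An `sma_breakdown`: list with `value`, `numerator`,
#'   `denominator`, `reason` (when `NA`) and `terms` (tibble: `direction`,
#'   `target`, `n_paths`, `mean_c`).
#' @export
sma <- function(store, drug_a, drug_b, graph) {
  .stopifnot_store(store)
  .require_drug(store, drug_a); .require_drug(store, drug_b)
  ta <- drug_record(store, drug_a)$targets
  tb <- drug_record(store, drug_b)$targets
  if (length(ta) == 0 || length(tb) == 0) {
    missing_side <- if (length(ta) == 0) drug_a else drug_b
    return(.sma_breakdown(NULL, reason = sprintf(
      "drug '%s' has no signed targets", missing_side)))
  }
  terms <- dplyr::bind_rows(
    .sma_direction(graph, sources = tb, targets = ta, direction = "b_to_a"),
    .sma_direction(graph, sources = ta, targets = tb, direction = "a_to_b")
  )
  .sma_breakdown(terms)
}

.sma_direction <- function(graph, sources, targets, direction) {
  purrr::map_dfr(names(targets), function(t) {
    paths <- all_shortest_signed_paths(graph, sources, t)
    if (nrow(paths) == 0) {
      return(tibble::tibble(direction = direction, target = t,
                            n_paths = 0L, mean_c = NA_real_))
    }
    cc <- ifelse(paths$sign == targets[[t]], 1, -1)
    tibble::tibble(direction = direction, target = t,
                   n_paths = nrow(paths), mean_c = mean(cc))
  })
}

.sma_breakdown <- function(terms, reason = NULL) {
  if (is.null(terms)) {
    terms <- tibble::tibble(direction = character(), target = character(),
                            n_paths = integer(), mean_c = double())
  }
  used <- terms$mean_c[!is.na(terms$mean_c)]
  num <- sum(used)
  den <- sum(abs(used))
  value <- if (length(used) == 0 || den == 0) NA_real_ else num / den
  if (is.na(value) && is.null(reason)) {
    reason <- if (length(used) == 0) "no shortest path to any target" else
      "all path evidence balanced (denominator 0)"
  }
  structure(list(value = value, numerator = num, denominator = den,
                 reason = if (is.na(value)) reason else NULL, terms = terms),
            class = "sma_breakdown")
}

#' @export
print.sma_breakdown <- function(x, ...) {
  cat(sprintf("<sma_breakdown> value = %s (%d target terms, %d with paths)\n",
              format(x$value, digits = 4), nrow(x$terms),
              sum(!is.na(x$terms$mean_c))))
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

.mapped <- function(targets, ppi) intersect(unique(targets), igraph::V(ppi)$name)

#' Mean within-module distance of a target set on a PPI network
#'
#' Average, over the set's mapped members, of the shortest-path hop count
#' to the NEAREST other member of the same set; a singleton set has
#' distance 0. Members absent from the network or unreachable from every
#' other member are excluded from the average and counted.
#'
#' @param targets Character vector of protein ids.
#' @param ppi Undirected `igraph`.
#' @return One-row tibble `value` (`NA` if nothing mapped), `n_used`,
#'   `n_excluded`.
#' @export
mean_within_distance <- function(targets, ppi) {
  targets <- unique(targets)
  mapped <- .mapped(targets, ppi)
  off <- length(targets) - length(mapped)
  if (length(mapped) == 0) {
    return(tibble::tibble(value = NA_real_, n_used = 0L, n_excluded = off))
  }
  if (length(mapped) == 1) {
    return(tibble::tibble(value = 0, n_used = 1L, n_excluded = off))
  }
  d <- igraph::distances(ppi, v = mapped, to = mapped)
  diag(d) <- Inf
  nearest <- apply(d, 1, min)
  ok <- is.finite(nearest)
  tibble::tibble(
    value = if (any(ok)) mean(nearest[ok]) else NA_real_,
    n_used = sum(ok),
    n_excluded = off + sum(!ok)
  )
}

#' Mean cross-module distance of two target sets on a PPI network
#'
#' Average, over all mapped members of A and of B, of the shortest-path
#' hop count to the nearest member of the opposite set; a protein present
#' in both sets has cross distance 0. Unmapped or unreachable members are
#' excluded and counted.
#'
#' @param targets_a,targets_b Character vectors of protein ids.
#' @param ppi Undirected `igraph`.
#' @return One-row tibble `value`, `n_used`, `n_excluded`.
#' @export
mean_cross_distance <- function(targets_a, targets_b, ppi) {
  a <- .mapped(targets_a, ppi)
  b <- .mapped(targets_b, ppi)
  off <- (length(unique(targets_a)) - length(a)) +
    (length(unique(targets_b)) - length(b))
  if (length(a) == 0 || length(b) == 0) {
    return(tibble::tibble(value = NA_real_, n_used = 0L, n_excluded = off))
  }
  d <- igraph::distances(ppi, v = a, to = b)
  nearest <- c(apply(d, 1, min), apply(d, 2, min))
  ok <- is.finite(nearest)
  tibble::tibble(
    value = if (any(ok)) mean(nearest[ok]) else NA_real_,
    n_used = sum(ok),
    n_excluded = off + sum(!ok)
  )
}

#' Separation score (SS) of a drug pair's target modules
#'
#' Network separation s_ab = <d_ab> - (<d_aa> + <d_bb>) / 2 of the two
#' drugs' target sets on an undirected PPI network. Negative values mean
#' the modules overlap; `NA` when either side has no target mapped on the
#' network.
#'
#' @param store A `drug_store`.
#' @param drug_a,drug_b Drug ids.
#' @param ppi Undirected `igraph` (see [read_ppi_network()]).
#' @return A `separation_breakdown`: list with `value`, `d_aa`, `d_bb`,
#'   `d_ab`, `n_excluded`.
#' @export
separation_score <- function(store, drug_a, drug_b, ppi) {
  .stopifnot_store(store)
  .require_drug(store, drug_a); .require_drug(store, drug_b)
  ta <- names(drug_record(store, drug_a)$targets)
  tb <- names(drug_record(store, drug_b)$targets)
  separation_score_sets(ta, tb, ppi)
}

#' Separation score of two explicit protein sets
#'
#' @param targets_a,targets_b Character vectors of protein ids.
#' @param ppi Undirected `igraph`.
#' @return A `separation_breakdown` (see [separation_score()]).
#' @export
separation_score_sets <- function(targets_a, targets_b, ppi) {
  w_a <- mean_within_distance(targets_a, ppi)
  w_b <- mean_within_distance(targets_b, ppi)
  x <- mean_cross_distance(targets_a, targets_b, ppi)
  value <- if (is.na(w_a$value) || is.na(w_b$value) || is.na(x$value)) {
    NA_real_
  } else {
    x$value - (w_a$value + w_b$value) / 2
  }
  structure(list(value = value, d_aa = w_a$value, d_bb = w_b$value,
                 d_ab = x$value,
                 n_excluded = w_a$n_excluded + w_b$n_excluded + x$n_excluded),
            class = "separation_breakdown")
}

#' @export
print.separation_breakdown <- function(x, ...) {
  cat(sprintf(
    "<separation_breakdown> s = %s (d_ab = %s, d_aa = %s, d_bb = %s, %d excluded)\n",
    format(x$value, digits = 4), format(x$d_ab, digits = 4),
    format(x$d_aa, digits = 4), format(x$d_bb, digits = 4), x$n_excluded))
  invisible(x)
}

#' Serialize a feature breakdown as JSON (debug aid)
#'
#' @param x An `sma_breakdown` or `separation_breakdown`.
#' @param path Output JSON path.
#' @export
write_breakdown_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
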