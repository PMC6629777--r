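# Independent brute-force oracles. Deliberately written without igraph or
# any package internals so they can arbitrate the implementations.

# adjacency list from an edge data frame (directed when directed = TRUE)
oracle_adj <- function(edges, directed = FALSE) {
  adj <- list()
  push <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
  }
  for (i in seq_len(nrow(edges))) {
    push(edges$from[i], edges$to[i])
    if (!directed) push(edges$to[i], edges$from[i])
  }
  adj
}

# BFS hop distances from one node; unreachable nodes are absent
oracle_bfs <- function(adj, from) {
  dist <- setNames(0L, from)
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!w %in% names(dist)) {
        dist[w] <- dist[[v]] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# every simple path from any signed source to target, by exhaustive DFS;
# keeps only minimum-length ones. sources: named sign vector (the virtual
# drug edge counts one hop and multiplies the sign in).
oracle_signed_paths <- function(edges, sources, target) {
  adj <- list(); sgn <- list()
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
    sgn[[paste(edges$from[i], edges$to[i])]] <- edges$sign[i]
  }
  found <- list()
  dfs <- function(v, seen, sign, hops) {
    if (v == target) {
      found[[length(found) + 1]] <<- list(sign = sign, length = hops,
                                          nodes = seen)
      return()
    }
    for (w in adj[[v]]) {
      if (!w %in% seen) dfs(w, c(seen, w), sign * sgn[[paste(v, w)]], hops + 1)
    }
  }
  for (s in names(sources)) dfs(s, s, sources[[s]], 1)
  if (length(found) == 0) return(found)
  lens <- vapply(found, `[[`, 0, "length")
  found[lens == min(lens)]
}

# separation score by BFS: edges undirected data frame from/to
oracle_separation <- function(edges, set_a, set_b) {
  adj <- oracle_adj(edges, directed = FALSE)
  nodes <- unique(c(edges$from, edges$to))
  set_a <- intersect(unique(set_a), nodes)
  set_b <- intersect(unique(set_b), nodes)
  if (length(set_a) == 0 || length(set_b) == 0) return(NA_real_)
  nearest <- function(v, others) {
    d <- oracle_bfs(adj, v)
    hits <- d[intersect(names(d), others)]
    if (length(hits) == 0) NA_real_ else min(hits)
  }
  within <- function(set) {
    if (length(set) == 1) return(0)
    vals <- vapply(set, function(v) nearest(v, setdiff(set, v)), 0)
    mean(vals[!is.na(vals)])
  }
  cross_vals <- c(vapply(set_a, function(v) nearest(v, set_b), 0),
                  vapply(set_b, function(v) nearest(v, set_a), 0))
  cross <- mean(cross_vals[!is.na(cross_vals)])
  cross - (within(set_a) + within(set_b)) / 2
}

# two-sided Fisher p by full hypergeometric enumeration
# (conditional-probability method)
oracle_fisher <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, 0)
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# confusion-matrix tallier
oracle_metrics <- function(y, prob, threshold = 0.5) {
  pred <- ifelse(prob > threshold, 1, 0)
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(y)) {
    if (pred[i] == 1 && y[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && y[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && y[i] == 0) tn <- tn + 1
    if (pred[i] == 0 && y[i] == 1) fn <- fn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# AUC by direct pair counting (ties count half)
oracle_auc <- function(y, prob) {
  pos <- prob[y == 1]; neg <- prob[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
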