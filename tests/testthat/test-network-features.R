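# Signed-path mode-of-action similarity and separation score, checked
# against exhaustive path enumeration and BFS oracles.

test_that("sign propagation reproduces the promote/inhibit rule table", {
  rules <- worked_examples()$sign_rules$inputs
  for (i in seq_len(nrow(rules))) {
    g <- signed_network(c("X", "Y"), c("Y", "Z"),
                        c(rules$x_on_y[i], rules$y_on_z[i]))
    paths <- all_shortest_signed_paths(g, c(X = 1), "Z")
    expect_equal(nrow(paths), 1)
    expect_equal(paths$sign, rules$x_on_z[i])
  }
})

test_that("shortest signed paths include the drug's own action sign", {
  # drug b promotes Tb; Tb promotes Ta: one path of 2 hops, positive
  g <- signed_network("Tb", "Ta", 1)
  paths <- all_shortest_signed_paths(g, c(Tb = 1), "Ta")
  expect_equal(nrow(paths), 1)
  expect_equal(paths$sign, 1)
  expect_equal(paths$length, 2)
  # inhibit of inhibit is promote, carried through the initial sign
  g2 <- signed_network(c("Tb", "Y"), c("Y", "Ta"), c(-1, -1))
  paths2 <- all_shortest_signed_paths(g2, c(Tb = 1), "Ta")
  expect_equal(paths2$sign, 1)
  # unreachable target -> zero rows, not an error
  g3 <- signed_network("A", "B", 1)
  expect_equal(nrow(all_shortest_signed_paths(g3, c(A = 1), "Zzz")), 0)
})

test_that("all shortest signed paths agree with exhaustive enumeration", {
  set.seed(101)
  n_checked <- 0
  for (i in 1:40) {
    rg <- random_signed_graph(sample(4:8, 1), p = 0.3)
    if (nrow(rg$edges) == 0) next
    sources <- setNames(sample(c(-1, 1), 2, replace = TRUE),
                        sample(rg$nodes, 2))
    target <- sample(setdiff(rg$nodes, names(sources)), 1)
    got <- all_shortest_signed_paths(rg$graph, sources, target)
    want <- oracle_signed_paths(rg$edges, sources, target)
    # oracle counts the virtual hop too (it starts each walk at hop 1)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(sort(got$sign), sort(vapply(want, `[[`, 0, "sign")))
      expect_equal(got$length[1], want[[1]]$length)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 10)
})

test_that("sma reproduces the hand-derived two-node extremes", {
  ex <- worked_examples()
  opp <- sma(ex$sma_opposite$inputs$store, "a", "b",
             ex$sma_opposite$inputs$graph)
  expect_equal(opp$value, -1)
  expect_equal(opp$numerator, -1)
  expect_equal(opp$denominator, 1)
  agree <- sma(ex$sma_agree$inputs$store, "a", "b",
               ex$sma_agree$inputs$graph)
  expect_equal(agree$value, 1)
  bal <- sma(ex$sma_balanced$inputs$store, "a", "b",
             ex$sma_balanced$inputs$graph)
  expect_true(is.na(bal$value))
  expect_match(bal$reason, "balanced")
  # a drug without targets is undefined with a reason
  store <- drug_store(tibble::tibble(drug_id = c("a", "b")),
                      targets = tibble::tibble(drug_id = "a",
                                               target_id = "T", sign = 1))
  expect_true(is.na(sma(store, "a", "b", ex$sma_agree$inputs$graph)$value))
})

test_that("sma is symmetric, bounded, and flips under global sign flip", {
  set.seed(77)
  done <- 0
  for (i in 1:30) {
    rg <- random_signed_graph(sample(5:9, 1), p = 0.25)
    if (nrow(rg$edges) < 2) next
    store <- drug_store(
      tibble::tibble(drug_id = c("a", "b")),
      targets = tibble::tibble(
        drug_id = c("a", "a", "b", "b"),
        target_id = c(sample(rg$nodes, 2), sample(rg$nodes, 2)),
        sign = sample(c(-1, 1), 4, replace = TRUE)))
    v_ab <- sma(store, "a", "b", rg$graph)$value
    v_ba <- sma(store, "b", "a", rg$graph)$value
    expect_equal(v_ab, v_ba)
    if (!is.na(v_ab)) {
      expect_lte(abs(v_ab), 1)
      done <- done + 1
      # flipping drug a's own action signs on its targets flips every
      # coefficient that involves drug a's modes an odd number of times
      # only in the b->a direction; the clean invariant is on single
      # targets: flipping ALL edge signs of odd-length paths is covered
      # by the rule-table test, so here check the direct-sign flip on a
      # one-target construction instead
    }
  }
  expect_gte(done, 5)
  # direct sign flip on a single-target pair flips the score
  g <- signed_network("Tb", "Ta", 1)
  mk <- function(sa) drug_store(
    tibble::tibble(drug_id = c("a", "b")),
    targets = tibble::tibble(drug_id = c("a", "b"),
                             target_id = c("Ta", "Tb"), sign = c(sa, 1)))
  expect_equal(sma(mk(1), "a", "b", g)$value,
               -sma(mk(-1), "a", "b", g)$value)
})

test_that("within/cross distances match the stated conventions", {
  ex <- worked_examples()
  path_g <- ex$ss_path$inputs$graph
  expect_equal(mean_within_distance("P1", path_g)$value, 0)
  expect_equal(mean_cross_distance("P1", "P5", path_g)$value, 4)
  pair_g <- ex$ss_overlap$inputs$graph
  expect_equal(mean_within_distance(c("u", "v"), pair_g)$value, 1)
  expect_equal(mean_cross_distance(c("u", "v"), c("u", "v"), pair_g)$value, 0)
  # off-network protein excluded and counted
  r <- mean_within_distance(c("u", "v", "ghost"), pair_g)
  expect_equal(r$value, 1)
  expect_equal(r$n_excluded, 1)
})

test_that("separation score matches the BFS oracle on random graphs", {
  ex <- worked_examples()
  expect_equal(separation_score_sets("P1", "P5", ex$ss_path$inputs$graph)$value, 4)
  expect_equal(separation_score_sets(c("u", "v"), c("u", "v"),
                                     ex$ss_overlap$inputs$graph)$value, -1)
  set.seed(303)
  n_checked <- 0
  while (n_checked < 100) {
    rp <- random_ppi(sample(6:30, 1), p = runif(1, 0.08, 0.3))
    if (nrow(rp$edges) == 0) next
    a <- sample(rp$nodes, sample(1:4, 1))
    b <- sample(rp$nodes, sample(1:4, 1))
    got <- separation_score_sets(a, b, rp$graph)$value
    want <- oracle_separation(rp$edges, a, b)
    # oracle works on nodes incident to an edge only; restrict comparison
    if (is.na(want) || is.na(got)) next
    au <- intersect(a, unique(c(rp$edges$from, rp$edges$to)))
    bu <- intersect(b, unique(c(rp$edges$from, rp$edges$to)))
    if (length(au) < length(a) || length(bu) < length(b)) next
    expect_equal(got, want)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 100)
})

test_that("separation score is symmetric and honours the store interface", {
  store <- fixture_store()
  g <- igraph::make_graph(~ P1 - P2 - P3)
  s_ab <- separation_score(store, "dA", "dB", g)
  s_ba <- separation_score(store, "dB", "dA", g)
  expect_equal(s_ab$value, s_ba$value)
  expect_equal(s_ab$value, 1 - 0)  # singletons one hop apart
  # unmappable side -> missing
  store2 <- drug_store(tibble::tibble(drug_id = c("a", "b")),
                       targets = tibble::tibble(drug_id = c("a", "b"),
                                                target_id = c("P1", "QQ"),
                                                sign = c(1, 1)))
  expect_true(is.na(separation_score(store2, "a", "b", g)$value))
})
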