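test_that("selection scores decompose as node weight plus context", {
  thr <- mk_thr(c("A", "B"))
  net <- mk_net(tibble::tibble(family_a = "A", family_b = "B", score = 3),
                families = c("A", "B"))

  solo <- selection_score(mk_hits("A", 1, 50, score = 23), thr, network = net)
  expect_equal(solo$selection_score, 3) # H - T, no partners

  pair <- selection_score(mk_hits(c("A", "B"), c(1, 100), c(50, 150),
                                  score = c(19, 25)), thr, network = net)
  expect_equal(pair$selection_score, c(-1 + 3, 5 + 3))

  # allowed-nested overlapping partner contributes no context term
  rules <- nesting_rules(tibble::tibble(family_a = "A", family_b = "B"))
  nested <- selection_score(mk_hits(c("A", "B"), c(1, 10), c(50, 40),
                                    score = c(19, 25)), thr, rules, net)
  expect_equal(nested$selection_score, c(-1, 5))
})

test_that("total score counts each context edge once (or twice on request)", {
  thr <- mk_thr(c("A", "B"))
  net <- mk_net(tibble::tibble(family_a = "A", family_b = "B", score = 3),
                families = c("A", "B"))
  empty <- mk_hits(character(0), integer(0), integer(0), numeric(0))
  expect_equal(total_score(empty, thr), 0)

  two <- mk_hits(c("A", "B"), c(1, 100), c(50, 150), score = c(19, 19))
  expect_equal(total_score(two, thr, network = net), 1)                       # -1 -1 +3
  expect_equal(total_score(two, thr, network = net,
                           objective_mode = "edge_twice"), 4)                 # -1 -1 +6
})

test_that("context boosts weak domains and removes negative-context ones", {
  thr <- mk_thr(c("A", "B"))
  boost <- mk_net(tibble::tibble(family_a = "A", family_b = "B", score = 3),
                  families = c("A", "B"))
  weak <- mk_hits(c("A", "B"), c(1, 100), c(50, 150), score = c(19, 19))
  s <- solve_exact(weak, thr, network = boost)
  expect_identical(nrow(s$selected), 2L)
  expect_equal(s$total_score, 1)
  expect_true(all(s$selected$selection_score >= 0))

  # unobserved-pair penalty -4: keeping both would push the +2 domain to -2
  punish <- mk_net(penalty = -4, c_total = 15, families = c("A", "B"))
  strong <- mk_hits(c("A", "B"), c(1, 100), c(50, 150), score = c(22, 25))
  s2 <- solve_exact(strong, thr, network = punish)
  expect_identical(s2$selected$family, "B")
  expect_equal(s2$total_score, 5)
})

test_that("with an all-zero network the optimizer reduces to the standard filter", {
  for (seed in 1:10) {
    spec <- sim_spec(seed = seed, n_proteins = 30, n_families = 12)
    thr <- simulate_thresholds(spec)
    cand <- simulate_candidates(simulate_architectures(spec), thr, spec)
    dp <- predict_domains(cand$hits, thr, network = NULL, evalue_cutoff = Inf)
    std <- standard_filter(cand$hits, thr)
    expect_identical(
      sort(paste(dp$protein, dp$hit_id)),
      sort(paste(std$protein, std$hit_id))
    )
  }
})

test_that("solver equals the brute-force oracle on random instances", {
  for (seed in 1:80) {
    pb <- rand_problem(m = (seed %% 12) + 1, seed = 1000 + seed)
    a <- solve_exact(pb$hits, pb$thresholds, pb$rules, pb$network, pb$mode)
    b <- brute_force_oracle(pb$hits, pb$thresholds, pb$rules, pb$network, pb$mode)
    expect_equal(a$total_score, b$total_score, tolerance = 1e-9)
    expect_identical(sort(a$selected$hit_id), sort(b$selected$hit_id))
    expect_identical(nrow(validate_selection(a$selected, pb$thresholds,
                                             pb$rules, pb$network)), 0L)
  }
})

test_that("oracle handles the degenerate sizes and rejects huge ones", {
  thr <- mk_thr("A")
  empty <- mk_hits(character(0), integer(0), integer(0), numeric(0))
  s0 <- brute_force_oracle(empty, thr)
  expect_identical(nrow(s0$selected), 0L)
  expect_equal(s0$total_score, 0)

  at_thr <- mk_hits("A", 1, 50, score = 20) # H = T: boundary, selected
  expect_identical(nrow(brute_force_oracle(at_thr, thr)$selected), 1L)

  big <- mk_hits(rep("A", 26), seq(1, by = 100, length.out = 26),
                 seq(50, by = 100, length.out = 26), score = 25)
  expect_error(brute_force_oracle(big, thr), class = "dpucr_too_large")
})

test_that("candidate elimination is safe and reaches a fixed point", {
  thr <- mk_thr(c("A", "B"))
  net <- mk_net(tibble::tibble(family_a = "A", family_b = "B", score = 4),
                families = c("A", "B"))
  h <- mk_hits(c("A", "B"), c(1, 100), c(50, 150), score = c(10, 21))
  kept <- eliminate_candidates(h, thr, network = net)
  expect_identical(kept$family, "B") # H-T = -10 cannot be rescued by +4

  pos <- mk_hits("A", 1, 50, score = 21)
  expect_identical(nrow(eliminate_candidates(pos, thr, network = net)), 1L)

  for (seed in 1:25) {
    pb <- rand_problem(m = 10, seed = 2000 + seed)
    with_elim <- solve_exact(pb$hits, pb$thresholds, pb$rules, pb$network,
                             pb$mode, eliminate = TRUE)
    without <- solve_exact(pb$hits, pb$thresholds, pb$rules, pb$network,
                           pb$mode, eliminate = FALSE)
    expect_equal(with_elim$total_score, without$total_score, tolerance = 1e-9)
  }
})

test_that("raising a context edge never lowers the optimal total", {
  for (seed in 1:15) {
    pb <- rand_problem(m = 8, seed = 3000 + seed)
    base <- solve_exact(pb$hits, pb$thresholds, pb$rules, pb$network)$total_score
    net2 <- pb$network
    if (nrow(net2$scores) == 0) next
    k <- (seed %% nrow(net2$scores)) + 1
    net2$scores$score[k] <- net2$scores$score[k] + 2.5
    raised <- solve_exact(pb$hits, pb$thresholds, pb$rules, net2)$total_score
    expect_gte(raised, base - 1e-9)
  }
})

test_that("selection is deterministic for identical inputs", {
  pb <- rand_problem(m = 11, seed = 555)
  a <- solve_exact(pb$hits, pb$thresholds, pb$rules, pb$network, pb$mode)
  b <- solve_exact(pb$hits, pb$thresholds, pb$rules, pb$network, pb$mode)
  expect_identical(a$selected, b$selected)
  expect_identical(a$total_score, b$total_score)
})

test_that("the sequence-level threshold hook gates whole families", {
  thr <- mk_thr(c("A", "B"))
  h <- mk_hits(c("A", "A", "B"), c(1, 100, 200), c(50, 150, 250),
               score = c(21, 22, 30))
  base <- solve_exact(h, thr)
  expect_identical(nrow(base$selected), 3L)
  # disabled hook changes nothing
  expect_identical(solve_exact(h, thr, seq_thresholds = NULL)$selected,
                   base$selected)
  # family A sums to 43 bits: a 50-bit sequence threshold removes both hits
  seq_thr <- tibble::tibble(family = "A", seq_threshold = 50)
  gated <- solve_exact(h, thr, seq_thresholds = seq_thr)
  expect_identical(gated$selected$family, "B")
  # a reachable sequence threshold keeps the family
  ok <- solve_exact(h, thr, seq_thresholds = tibble::tibble(
    family = "A", seq_threshold = 40))
  expect_identical(nrow(ok$selected), 3L)
})

test_that("tidy and glance expose the selection decomposition", {
  pb <- rand_problem(m = 6, seed = 77)
  s <- solve_exact(pb$hits, pb$thresholds, pb$rules, pb$network)
  td <- tidy(s)
  expect_true(all(c("normalized", "context", "selection_score") %in% names(td)))
  expect_equal(td$selection_score, td$normalized + td$context)
  g <- glance(s)
  expect_identical(g$n_selected, nrow(td))
})
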