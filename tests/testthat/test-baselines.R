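test_that("standard filter keeps exactly the threshold passers, overlap-legally", {
  thr <- mk_thr(c("A", "B", "C"))
  h <- mk_hits(c("A", "B"), c(1, 100), c(50, 150), score = c(20.1, 19.9))
  kept <- standard_filter(h, thr)
  expect_identical(kept$family, "A")

  # two disallowed-overlapping passers: higher H - T wins
  clash <- mk_hits(c("A", "B"), c(1, 20), c(50, 70), score = c(22, 25))
  expect_identical(standard_filter(clash, thr)$family, "B")

  # allowed nesting keeps both
  rules <- nesting_rules(tibble::tibble(family_a = "A", family_b = "B"))
  expect_identical(nrow(standard_filter(clash, thr, rules)), 2L)

  # all filters return overlap-legal sets
  withr::with_seed(8, {
    for (k in 1:10) {
      pb <- rand_problem(m = 10, seed = 4000 + k)
      out <- standard_filter(pb$hits, pb$thresholds, pb$rules)
      expect_identical(nrow(validate_selection(
        dplyr::select(out, -dplyr::any_of(c("normalized", "method"))),
        pb$thresholds, pb$rules)), 0L)
    }
  })
})

test_that("extended GA filter is antitone in the shift", {
  thr <- mk_thr(c("A", "B"))
  h <- mk_hits(c("A", "B", "A"), c(1, 100, 200), c(50, 150, 250),
               score = c(21, 23, 18))
  expect_identical(extended_ga_filter(h, thr, 0)$hit_id,
                   standard_filter(h, thr)$hit_id)
  d0 <- extended_ga_filter(h, thr, 0)
  d5 <- extended_ga_filter(h, thr, 5)
  expect_true(all(d5$hit_id %in% d0$hit_id))
  expect_identical(nrow(extended_ga_filter(h, thr, -100)), 3L)
})

test_that("E-value filter keeps the cutoff passers by ascending E-value", {
  h <- mk_hits(c("A", "B", "C"), c(1, 100, 20), c(50, 150, 70),
               score = c(10, 11, 12), evalue = c(0.5, 1e-4, 1e-3))
  expect_identical(nrow(evalue_filter(h, 1e-6)), 0L)
  all_kept <- evalue_filter(h, Inf)
  # A [1,50] and C [20,70] clash: C has the better E-value
  expect_identical(sort(all_kept$family), c("B", "C"))
  rules <- nesting_rules(tibble::tibble(family_a = "A", family_b = "C"))
  expect_identical(nrow(evalue_filter(h, Inf, rules)), 3L)
})

test_that("CODD transfers candidates with positive context to trusted domains", {
  pos <- tibble::tibble(family_a = "A", family_b = "B")
  G <- mk_hits("A", 1, 50, score = 25)
  D <- mk_hits("B", 100, 150, score = 15, evalue = 0.5)
  out <- codd_filter(G, D, pos)
  expect_identical(sort(out$family), c("A", "B"))

  # empty G: no candidate can have context with G
  emptyG <- mk_hits(character(0), integer(0), integer(0), numeric(0))
  expect_identical(nrow(codd_filter(emptyG, D, pos)), 0L)

  # two mutually-contextual weak candidates cannot rescue each other via
  # CODD (contrast: the optimizer can select both)
  weak2 <- mk_hits(c("A", "B"), c(1, 100), c(50, 150), score = c(19, 19))
  expect_identical(nrow(codd_filter(emptyG, weak2, pos)), 0L)
  thr <- mk_thr(c("A", "B"))
  net <- mk_net(tibble::tibble(family_a = "A", family_b = "B", score = 3),
                families = c("A", "B"))
  expect_identical(nrow(solve_exact(weak2, thr, network = net)$selected), 2L)

  # output is always a superset of a legal G
  expect_true(all(G$hit_id %in% out$hit_id))

  # transfer respects overlaps with the growing prediction set
  D2 <- mk_hits(c("B", "B"), c(100, 120), c(150, 170), score = c(15, 14),
                evalue = c(0.1, 0.5))
  out2 <- codd_filter(G, D2, pos)
  expect_identical(nrow(out2), 2L) # second B clashes with the first
})

test_that("nCODD also removes members paired only by never-observed context", {
  thr <- mk_thr(c("A", "B", "C"))
  pos <- tibble::tibble(family_a = "A", family_b = "B")
  net <- mk_net(tibble::tibble(family_a = "A", family_b = "B",
                               count = 2, score = 3),
                penalty = -4, families = c("A", "B", "C"))
  # no unobserved pairs among members: identical to codd
  G <- mk_hits(c("A", "B"), c(1, 100), c(50, 150), score = c(25, 24))
  D <- mk_hits(character(0), integer(0), integer(0), numeric(0))
  expect_identical(ncodd_filter(G, D, pos, net, thr)$hit_id,
                   codd_filter(G, D, pos)$hit_id)

  # C never co-occurs with A; the weaker of the two is removed, even from G
  G2 <- mk_hits(c("A", "C"), c(1, 100), c(50, 150), score = c(25, 22))
  out <- ncodd_filter(G2, D, pos, net, thr)
  expect_identical(out$family, "A")

  # nCODD never adds anything codd would not
  out_c <- codd_filter(G2, D, pos)
  expect_true(all(out$hit_id %in% out_c$hit_id))
})

test_that("baseline_predict drives all modes over multiple proteins", {
  spec <- sim_spec(seed = 5, n_proteins = 20, n_families = 10)
  thr <- simulate_thresholds(spec)
  db <- simulate_architectures(spec)
  cand <- simulate_candidates(db, thr, spec)
  net <- build_context_network(db)
  std <- baseline_predict(cand$hits, "standard", thr)
  expect_identical(unique(std$method), "standard")
  codd <- baseline_predict(cand$hits, "codd", thr, network = net)
  expect_true(all(std$hit_id %in% codd$hit_id)) # codd extends the trusted set
  nc <- baseline_predict(cand$hits, "ncodd", thr, network = net)
  expect_true(all(nc$hit_id %in% codd$hit_id))  # ncodd only removes
  ev <- baseline_predict(cand$hits, "evalue", cutoff = 1e-4)
  expect_true(all(ev$evalue <= 1e-4))
})
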