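test_that("architecture filtering removes single-sequence architectures", {
  solo <- mk_db(c("A", "B"))
  expect_identical(nrow(filter_architectures(solo)), 0L)

  mixed <- mk_db(c("A", "B"), c("A", "B"), "C")
  kept <- filter_architectures(mixed)
  expect_identical(nrow(kept), 2L)
  expect_true(all(vapply(kept$architecture, paste, "", collapse = ",") == "A,B"))

  # fixed point: filtering twice changes nothing
  expect_identical(filter_architectures(kept), kept)

  # exact ordered lists: [A,B] and [B,A] are different architectures
  perm <- mk_db(c("A", "B"), c("B", "A"))
  expect_identical(nrow(filter_architectures(perm)), 0L)
})

test_that("pair counts follow the normalized-count construction", {
  # one protein [A,B]: c_AB = 1 per orientation, total mass e_p = 2
  pc <- pair_counts(mk_db(c("A", "B")))
  expect_equal(pc$count, 1)
  expect_equal(attr(pc, "c_total"), 2)

  # one protein [A,A]: self pair c_AA = 2*1/1 = 2 = e_p
  pc2 <- pair_counts(mk_db(c("A", "A")))
  expect_identical(pc2$family_a, pc2$family_b)
  expect_equal(pc2$count, 2)
  expect_equal(attr(pc2, "c_total"), 2)

  # one protein [A,B,C]: each heterologous orientation gets 0.5, mass 3
  pc3 <- pair_counts(mk_db(c("A", "B", "C")))
  expect_equal(pc3$count, rep(0.5, 3))
  expect_equal(attr(pc3, "c_total"), 3)

  # single-domain proteins contribute nothing
  pc4 <- pair_counts(mk_db(c("A", "B"), "C", "D"))
  expect_equal(attr(pc4, "c_total"), 2)
  expect_identical(attr(pc4, "n"), 4L) # but they widen the family universe
})

test_that("every multidomain protein contributes exactly e_p counts", {
  for (seed in 1:5) {
    spec <- sim_spec(seed = seed, n_proteins = 60, n_families = 12)
    db <- simulate_architectures(spec)
    e_p <- lengths(db$architecture)
    expected <- sum(e_p[e_p >= 2])
    pc <- pair_counts(db)
    expect_equal(attr(pc, "c_total"), expected, tolerance = 1e-9)
    # and per protein: its own corpus of one protein carries mass e_p
    one <- architecture_db(db[which.max(e_p), ])
    expect_equal(attr(pair_counts(one), "c_total"), max(e_p), tolerance = 1e-12)
  }
})

test_that("pair probabilities are regularized and normalized", {
  # no multidomain proteins: every p_ij is the uniform 1/n^2
  pc <- pair_counts(mk_db("A", "B"))
  pp <- pair_probability(pc, alpha = 1)
  expect_equal(attr(pp, "p_unobserved"), 1 / 4)

  # unobserved pair with c = 3, alpha = 1, n = 2 -> 0.25/4
  pc2 <- structure(tibble::tibble(family_a = "A", family_b = "A", count = 3),
                   n = 2L, c_total = 3, families = c("A", "B"),
                   class = c("pair_counts", "tbl_df", "tbl", "data.frame"))
  expect_equal(attr(pair_probability(pc2, alpha = 1), "p_unobserved"), 0.0625)

  # ordered-pair probabilities sum to 1
  for (seed in 1:4) {
    spec <- sim_spec(seed = seed, n_proteins = 80, n_families = 15)
    pc <- pair_counts(simulate_architectures(spec))
    pp <- pair_probability(pc)
    n <- attr(pp, "n")
    self <- pp$family_a == pp$family_b
    observed_ordered <- sum(self) + 2 * sum(!self)
    total <- sum(pp$prob[self]) + 2 * sum(pp$prob[!self]) +
      (n^2 - observed_ordered) * attr(pp, "p_unobserved")
    expect_equal(total, 1, tolerance = 1e-12)
  }

  expect_error(pair_probability(structure(tibble::tibble(), n = 0L, c_total = 0)),
               class = "dpucr_empty_corpus")
})

test_that("context scores use the closed-form penalty and zero-flooring", {
  # c = 3, alpha = 1, b = 2: every unobserved pair scores -log2(4) = -2
  pc <- structure(tibble::tibble(family_a = "A", family_b = "B", count = 3),
                  n = 5L, c_total = 3, families = LETTERS[1:5],
                  class = c("pair_counts", "tbl_df", "tbl", "data.frame"))
  net <- context_network(pc, alpha = 1, b = 2)
  expect_equal(net$unobserved_penalty, -2)
  expect_equal(context_lookup(net, "C", "D"), -2)

  # empty corpus (c = 0): penalty is log of 1, all lookups are 0
  pc0 <- pair_counts(mk_db("A", "B"))
  net0 <- context_network(pc0)
  expect_equal(net0$unobserved_penalty, 0)
  expect_equal(context_lookup(net0, "A", "B"), 0)

  # an observed pair with negative raw log-odds is floored to zero and is
  # never penalized, but it is not a positive pair either
  pcf <- structure(
    tibble::tibble(family_a = c("A", "A", "B"), family_b = c("A", "B", "B"),
                   count = c(5, 0.2, 5)),
    n = 2L, c_total = 10.4, families = c("A", "B"),
    class = c("pair_counts", "tbl_df", "tbl", "data.frame")
  )
  netf <- context_network(pcf)
  raw_ab <- log2((0.2 + 1 / 4) * 4 / (10.4 + 1))
  expect_lt(raw_ab, 0)
  expect_equal(context_lookup(netf, "A", "B"), 0)
  pos <- positive_pair_set(netf)
  expect_false(any(pos$family_a == "A" & pos$family_b == "B"))
})

test_that("raising a pair's count never lowers its score", {
  base <- function(cnt) {
    pc <- structure(
      tibble::tibble(family_a = c("A", "C"), family_b = c("B", "D"),
                     count = c(cnt, 4)),
      n = 6L, c_total = 2 * (cnt + 4), families = LETTERS[1:6],
      class = c("pair_counts", "tbl_df", "tbl", "data.frame")
    )
    context_lookup(context_network(pc), "A", "B")
  }
  grid <- seq(0.1, 20, by = 0.5)
  scores <- vapply(grid, base, 0)
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("shuffling positive scores preserves the multiset, deterministically", {
  spec <- sim_spec(seed = 3, n_proteins = 120, n_families = 15)
  net <- build_context_network(simulate_architectures(spec))
  s1 <- shuffle_positive_scores(net, seed = 99)
  s2 <- shuffle_positive_scores(net, seed = 99)
  expect_identical(s1$scores$score, s2$scores$score)
  expect_equal(sort(s1$scores$score), sort(net$scores$score))
  expect_identical(s1$unobserved_penalty, net$unobserved_penalty)
  expect_false(identical(s1$scores$score, net$scores$score)) # actually permuted

  one <- mk_net(tibble::tibble(family_a = "A", family_b = "B", score = 2))
  expect_identical(shuffle_positive_scores(one, 1)$scores, one$scores)
})

test_that("positive pair set excludes floored and (optionally) self pairs", {
  expect_identical(nrow(positive_pair_set(mk_net())), 0L)
  net <- mk_net(tibble::tibble(family_a = c("A", "A", "B"),
                               family_b = c("A", "B", "C"),
                               score = c(1.5, 2, 0)))
  expect_identical(nrow(positive_pair_set(net)), 2L)
  expect_identical(nrow(positive_pair_set(net, include_self = FALSE)), 1L)
})

test_that("planted pairs score above random observed pairs", {
  spec <- sim_spec(seed = 21)
  net <- build_context_network(simulate_architectures(spec))
  planted_scores <- context_lookup(net, spec$planted_pairs$family_a,
                                   spec$planted_pairs$family_b)
  key_p <- paste(spec$planted_pairs$family_a, spec$planted_pairs$family_b)
  key_all <- paste(net$scores$family_a, net$scores$family_b)
  other <- net$scores$score[!key_all %in% key_p]
  expect_gt(mean(planted_scores), mean(other))
})
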