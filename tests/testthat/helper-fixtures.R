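# Shared in-code fixtures: tiny hit tables, hand-built context networks and
# a random selection-problem generator used by the property suites.

mk_hits <- function(family, start, end, score, evalue = 0.5, protein = "p") {
  domain_hits(tibble::tibble(
    protein = protein, family = family, start = start, end = end,
    score = score, evalue = evalue
  ))
}

mk_thr <- function(families, value = 20) {
  threshold_table(tibble::tibble(family = families, threshold = value))
}

# hand-built context network (bypasses corpus counting)
mk_net <- function(pairs = NULL, penalty = -2, n = 10, c_total = 3,
                   alpha = 1, b = 2, families = sprintf("F%02d", 1:10)) {
  if (is.null(pairs)) {
    pairs <- tibble::tibble(family_a = character(0), family_b = character(0),
                            count = double(0), score = double(0))
  } else {
    pairs <- tibble::as_tibble(pairs)
    if (!"count" %in% names(pairs)) pairs$count <- 1
  }
  structure(list(scores = pairs, unobserved_penalty = penalty, n = n,
                 c_total = c_total, alpha = alpha, b = b, families = families),
            class = "context_network")
}

mk_db <- function(...) {
  archs <- list(...)
  architecture_db(tibble::tibble(
    protein = sprintf("p%03d", seq_along(archs)), architecture = archs
  ))
}

# the four-protein coherence worked example: a conserved family U in all
# members, a family shared by the two in-paralogs only (S), and two
# unmatched domains (Y overlaps S's columns but differs in family; Z
# overlaps nothing)
mk_coherence_fixture <- function() {
  members <- c("Pf1", "Pf2", "Pv1", "Pc1")
  aln <- setNames(rep(strrep("A", 120), 4), members)
  preds <- domain_hits(tibble::tibble(
    protein = c("Pf1", "Pf1", "Pf2", "Pf2", "Pv1", "Pv1", "Pc1", "Pc1"),
    family  = c("U",   "S",   "U",   "S",   "U",   "Y",   "U",   "Z"),
    start   = c(1,     60,    1,     70,    1,     60,    1,     90),
    end     = c(40,    100,   40,    110,   40,    100,   40,    119),
    score = 25, evalue = 1e-5
  ))
  list(groups = tibble::tibble(group = "OG1", protein = members),
       alignments = list(OG1 = aln), preds = preds)
}

# random selection problem: mixed positive/negative context, overlaps and one
# allowed nesting pair; used by the oracle-equivalence property suites
rand_problem <- function(m, seed) {
  withr::with_seed(seed, {
    fams <- sprintf("F%02d", 1:8)
    st <- sample(1:250, m, replace = TRUE)
    hits <- domain_hits(tibble::tibble(
      protein = "p", family = sample(fams, m, replace = TRUE),
      start = st, end = st + sample(20:70, m, replace = TRUE),
      score = 20 + rnorm(m, 1, 4), evalue = runif(m)
    ))
    pairs <- t(utils::combn(fams, 2))
    keep <- runif(nrow(pairs)) < 0.4
    net <- mk_net(
      tibble::tibble(family_a = pairs[keep, 1], family_b = pairs[keep, 2],
                     count = runif(sum(keep), 1, 5),
                     score = runif(sum(keep), 0, 6)),
      penalty = -runif(1, 1, 5), n = 8, c_total = 10, families = fams
    )
    list(hits = hits, thresholds = mk_thr(fams),
         rules = nesting_rules(tibble::tibble(family_a = "F01", family_b = "F02")),
         network = net,
         mode = sample(c("edge_once", "edge_twice"), 1))
  })
}
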