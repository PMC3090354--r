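# Context scoring: domain-architecture corpus -> normalized pair counts ->
# regularized probabilities -> log-odds context network (bits).

#' Build a domain-architecture database
#'
#' The architecture of a protein is its ordered list of domain families,
#' including repeats. This is the training corpus for pair counts.
#'
#' @param x A data frame with a `protein` column and either an `architecture`
#'   list-column of character vectors or a character column of comma-separated
#'   family lists.
#' @return A tibble with columns `protein` (unique) and `architecture`
#'   (list of non-empty character vectors).
#' @export
architecture_db <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("protein", "architecture") %in% names(x))) {
    abort("architecture db needs columns `protein` and `architecture`",
          class = "dpucr_bad_architectures")
  }
  if (!is.list(x$architecture)) {
    x$architecture <- strsplit(as.character(x$architecture), ",", fixed = TRUE)
  }
  if (anyDuplicated(x$protein)) {
    abort("duplicate protein in architecture db", class = "dpucr_bad_architectures")
  }
  if (nrow(x) > 0 && any(lengths(x$architecture) == 0)) {
    abort("empty architecture list", class = "dpucr_bad_architectures")
  }
  dplyr::select(x, "protein", "architecture")
}

#' Remove architectures observed in only one sequence
#'
#' Architectures (as exact ordered family lists) seen on a single protein are
#' more likely to be erroneous and are dropped before counting; the family
#' universe is recomputed from the survivors. Idempotent.
#'
#' @param db Architecture database ([architecture_db()]).
#' @return Filtered architecture database.
#' @export
filter_architectures <- function(db) {
  db <- architecture_db(db)
  key <- vapply(db$architecture, paste, "", collapse = ",")
  keep <- key %in% key[duplicated(key)]
  db[keep, , drop = FALSE]
}

# family universe of a db (sorted for determinism)
.family_universe <- function(db) {
  sort(unique(unlist(db$architecture, use.names = FALSE)))
}

#' Normalized domain-family pair counts from an architecture corpus
#'
#' For each multidomain protein `p` with `e_ip` domains of family `i` and
#' `e_p` domains in total, heterologous pairs contribute
#' `c_ij += e_ip * e_jp / (e_p - 1)` and self pairs
#' `c_ii += e_ip * (e_ip - 1) / (e_p - 1)`. Single-domain proteins are
#' skipped (zero denominator). The normalization stops domains counting
#' themselves while each protein contributes exactly `e_p` counts in total
#' over all ordered pairs, compensating for proteins with many domains.
#'
#' @param db Architecture database, already filtered
#'   ([filter_architectures()]).
#' @return A `pair_counts` object: tibble of canonical unordered pairs
#'   (`family_a`, `family_b`, `count`) with attributes `n` (family universe
#'   size), `c_total` (total count mass over ordered pairs) and `families`.
#'   A stored row with `family_a == family_b` is a self pair; every other
#'   stored count is the per-orientation value `c_ij` (which the ordered-pair
#'   total counts twice).
#' @export
pair_counts <- function(db) {
  db <- architecture_db(db)
  fams <- .family_universe(db)
  acc <- new.env(parent = emptyenv())
  for (arch in db$architecture) {
    e_p <- length(arch)
    if (e_p < 2) next
    tab <- table(arch)
    f <- names(tab)
    e <- as.numeric(tab)
    for (i in seq_along(f)) {
      for (j in i:length(f)) {
        if (i == j) {
          val <- e[i] * (e[i] - 1) / (e_p - 1)
          if (val == 0) next
        } else {
          val <- e[i] * e[j] / (e_p - 1)
        }
        key <- .pair_key(f[i], f[j])
        acc[[key]] <- (acc[[key]] %||% 0) + val
      }
    }
  }
  keys <- ls(acc)
  if (length(keys) > 0) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    counts <- tibble::tibble(
      family_a = vapply(parts, `[[`, "", 1L),
      family_b = vapply(parts, `[[`, "", 2L),
      count = unname(vapply(keys, function(k) acc[[k]], 0))
    )
    counts <- dplyr::arrange(counts, .data$family_a, .data$family_b)
  } else {
    counts <- tibble::tibble(family_a = character(0), family_b = character(0),
                             count = double(0))
  }
  # ordered-pair mass: off-diagonal canonical rows count twice
  self <- counts$family_a == counts$family_b
  c_total <- sum(counts$count[self]) + 2 * sum(counts$count[!self])
  structure(counts,
            n = length(fams), c_total = c_total, families = fams,
            class = c("pair_counts", class(counts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regularized pair probabilities
#'
#' `p_ij = (c_ij + alpha / n^2) / (c + alpha)` over all ordered family pairs
#' (including self pairs), where `c` is the total count mass and `n` the
#' family universe size. By construction the ordered-pair probabilities sum
#' to 1; with no counts at all they reduce to the uniform `1 / n^2`.
#'
#' @param counts A [pair_counts()] object.
#' @param alpha Regularization pseudocount mass (default 1).
#' @return Tibble of canonical unordered pairs with columns `count`, `prob`
#'   (the per-ordered-pair probability) plus attributes `n`, `c_total`,
#'   `alpha`, `p_unobserved` (shared probability of any zero-count pair).
#' @export
pair_probability <- function(counts, alpha = 1) {
  stopifnot(alpha > 0)
  n <- attr(counts, "n")
  c_total <- attr(counts, "c_total")
  if (is.null(n) || n < 1) {
    abort("empty corpus: no domain families observed", class = "dpucr_empty_corpus")
  }
  out <- tibble::as_tibble(counts)
  out$prob <- (out$count + alpha / n^2) / (c_total + alpha)
  structure(out,
            n = n, c_total = c_total, alpha = alpha,
            p_unobserved = (alpha / n^2) / (c_total + alpha),
            class = c("pair_probability", class(out)))
}

#' Build the log-odds context network
#'
#' Context scores are log-odds in base `b` against a uniform null
#' `q_ij = 1 / n^2` (random hits under permissive E-value thresholds land
#' approximately uniformly over families):
#' `s_ij = log_b(p_ij / q_ij)`. Every unobserved pair (`c_ij = 0`) gets the
#' same closed-form penalty `-log_b(1 + c / alpha)`; observed pairs with
#' negative raw scores are floored to 0, so observed pairs are never
#' penalized. Self pairs are first-class: repeats of a family provide context
#' to each other through `C_ff`.
#'
#' @param counts A [pair_counts()] object.
#' @param alpha Regularization pseudocount (default 1).
#' @param b Logarithm base (default 2, bit scores).
#' @return A `context_network` object.
#' @export
context_network <- function(counts, alpha = 1, b = 2) {
  stopifnot(alpha > 0, b > 1)
  pp <- pair_probability(counts, alpha = alpha)
  n <- attr(pp, "n")
  c_total <- attr(pp, "c_total")
  scores <- tibble::as_tibble(pp)
  scores$score <- pmax(0, log(scores$prob * n^2, base = b))
  scores <- dplyr::select(scores, "family_a", "family_b", "count", "score")
  structure(list(
    scores = scores,
    unobserved_penalty = -log(1 + c_total / alpha, base = b),
    n = n, c_total = c_total, alpha = alpha, b = b,
    families = attr(counts, "families")
  ), class = "context_network")
}

#' @export
print.context_network <- function(x, ...) {
  cat(sprintf(
    "<context_network> %d observed pairs over %d families (c = %.4g, alpha = %g, b = %g)\n",
    nrow(x$scores), x$n, x$c_total, x$alpha, x$b
  ))
  cat(sprintf("  unobserved-pair penalty: %.6g bits\n", x$unobserved_penalty))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.context_network <- function(x, ...) {
  tibble::as_tibble(x$scores)
}

#' @exportS3Method generics::glance
glance.context_network <- function(x, ...) {
  tibble::tibble(
    n_families = x$n, n_observed_pairs = nrow(x$scores),
    c_total = x$c_total, alpha = x$alpha, b = x$b,
    unobserved_penalty = x$unobserved_penalty
  )
}

#' Build a context network straight from an architecture corpus
#'
#' Convenience pipeline: [filter_architectures()] then [pair_counts()] then
#' [context_network()].
#'
#' @inheritParams context_network
#' @param db Architecture database.
#' @param filter Drop single-sequence architectures first? (default TRUE)
#' @return A `context_network`.
#' @export
build_context_network <- function(db, alpha = 1, b = 2, filter = TRUE) {
  db <- architecture_db(db)
  if (filter) db <- filter_architectures(db)
  if (nrow(db) == 0 || length(.family_universe(db)) == 0) {
    abort("empty corpus after architecture filtering", class = "dpucr_empty_corpus")
  }
  context_network(pair_counts(db), alpha = alpha, b = b)
}

#' Look up context scores for family pairs
#'
#' Symmetric lookup: any pair not stored (never observed in the corpus) gets
#' the shared unobserved-pair penalty. Vectorised over pairs.
#'
#' @param net A `context_network`.
#' @param family_a,family_b Character vectors of families (recycled).
#' @return Numeric vector of context scores (bits).
#' @export
context_lookup <- function(net, family_a, family_b) {
  keys <- .pair_key(family_a, family_b)
  idx <- match(keys, .pair_key(net$scores$family_a, net$scores$family_b))
  out <- net$scores$score[idx]
  out[is.na(idx)] <- net$unobserved_penalty
  out
}

#' Shuffle the observed-pair scores of a network
#'
#' Keeps the multiset of observed-pair scores but reassigns them to a uniform
#' random permutation of the observed pairs; the unobserved penalty is
#' untouched. This is the control showing that which pair carries which score
#' matters, not just the score distribution.
#'
#' @param net A `context_network`.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return A `context_network` with permuted observed scores.
#' @export
shuffle_positive_scores <- function(net, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  out <- net
  k <- nrow(net$scores)
  if (k > 1) {
    perm <- withr::with_seed(as.integer(seed), sample.int(k))
    out$scores$score <- net$scores$score[perm]
  }
  out
}

#' Family pairs with strictly positive context score
#'
#' The positive-pair input to the CODD-style filters. Pairs floored to zero
#' are excluded. Optionally mimics the published CODD network: drop self
#' pairs, and drop pairs whose counts are not significantly enriched under a
#' hypergeometric draw of co-occurrences.
#'
#' @param net A `context_network`.
#' @param include_self Keep same-family pairs? (default TRUE; the published
#'   CODD network lacks them)
#' @param hypergeom_p Optional p-value cutoff: keep a pair only if its count
#'   is higher than expected by chance at this level (upper-tail
#'   hypergeometric on rounded counts). NULL (default) disables the filter.
#' @return Tibble of canonical pairs (`family_a`, `family_b`, `score`).
#' @export
positive_pair_set <- function(net, include_self = TRUE, hypergeom_p = NULL) {
  out <- dplyr::filter(net$scores, .data$score > 0)
  if (!include_self) {
    out <- dplyr::filter(out, .data$family_a != .data$family_b)
  }
  if (!is.null(hypergeom_p)) {
    c_tot <- round(net$c_total)
    fam_mass <- .family_mass(net)
    m_a <- round(fam_mass[out$family_a])
    m_b <- round(fam_mass[out$family_b])
    # P(X >= c_ij) for X ~ Hypergeom(drawing m_a of c_tot, m_b marked)
    pv <- stats::phyper(round(out$count) - 1, m_b, pmax(0, c_tot - m_b), m_a,
                        lower.tail = FALSE)
    out <- out[pv <= hypergeom_p, , drop = FALSE]
  }
  dplyr::select(out, "family_a", "family_b", "score")
}

# per-family total count mass (self pairs count once, others per orientation)
.family_mass <- function(net) {
  sc <- net$scores
  mass <- setNames(numeric(net$n), net$families)
  for (k in seq_len(nrow(sc))) {
    a <- sc$family_a[k]; b <- sc$family_b[k]
    mass[a] <- mass[a] + sc$count[k]
    if (a != b) mass[b] <- mass[b] + sc$count[k]
  }
  mass
}
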