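# Non-context baselines (gathering thresholds, shifted thresholds, E-value
# cutoffs) and the CODD-style positive / positive+negative context filters.

# greedy overlap resolution: walk hits in `priority` order, keep a hit iff it
# has no disallowed overlap with anything already kept
.greedy_legal <- function(hits, rules, priority) {
  m <- nrow(hits)
  if (m == 0) return(hits)
  ov <- .overlap_matrix(hits)
  allowed <- .allowed_matrix(hits, rules)
  disallowed <- ov & !allowed
  kept <- logical(m)
  for (i in priority) {
    if (!any(disallowed[i, kept])) kept[i] <- TRUE
  }
  hits[kept, , drop = FALSE]
}

#' Standard gathering-threshold filter
#'
#' Keeps hits with `H >= T` for their family; disallowed overlaps among the
#' passers are resolved greedily by descending normalized score (`H - T`),
#' breaking ties by canonical hit order. This is the classical single-point
#' baseline every context method is compared against. Overlap resolution
#' order is configurable to ascending E-value.
#'
#' @param hits Candidate hit table (any number of proteins).
#' @param thresholds Threshold table.
#' @param rules Nesting rules.
#' @param resolve `"score"` (descending `H - T`, default) or `"evalue"`
#'   (ascending E-value) greedy priority.
#' @return The kept hits, with `normalized` and `method` columns.
#' @export
standard_filter <- function(hits, thresholds, rules = nesting_rules(),
                            resolve = c("score", "evalue")) {
  resolve <- match.arg(resolve)
  hits <- domain_hits(hits)
  hits$normalized <- normalized_score(hits, thresholds)
  hits <- dplyr::filter(hits, .data$normalized >= 0)
  if (nrow(hits) == 0) return(dplyr::mutate(hits, method = character(0)))
  hits <- hits |>
    dplyr::group_split(.data$protein) |>
    purrr::map(function(h) {
      pr <- if (resolve == "score") order(-h$normalized, h$hit_id) else order(h$evalue, h$hit_id)
      .greedy_legal(h, rules, pr)
    }) |>
    purrr::list_rbind()
  dplyr::mutate(domain_hits_keep_extras(hits), method = "standard")
}

# re-sort canonically but keep extra columns such as `normalized`
domain_hits_keep_extras <- function(hits) {
  dplyr::arrange(hits, .data$protein, .data$start, .data$end,
                 .data$family, dplyr::desc(.data$score))
}

#' Extended gathering-threshold filter
#'
#' [standard_filter()] with every family threshold shifted by a constant
#' `delta` (bits), tracing out a signal/noise curve around the curated
#' thresholds. Antitone in `delta`: a larger shift keeps a subset.
#'
#' @inheritParams standard_filter
#' @param delta Threshold shift in bits (finite; may be negative).
#' @return Kept hits with `method = "extended_ga"`.
#' @export
extended_ga_filter <- function(hits, thresholds, delta,
                               rules = nesting_rules(),
                               resolve = c("score", "evalue")) {
  stopifnot(is.finite(delta))
  shifted <- dplyr::mutate(thresholds, threshold = .data$threshold + delta)
  out <- standard_filter(hits, shifted, rules, resolve)
  dplyr::mutate(out, method = "extended_ga")
}

#' E-value filter
#'
#' Keeps hits with `evalue <= cutoff`; disallowed overlaps resolved greedily
#' by ascending E-value (then canonical hit order). Thresholds are ignored.
#'
#' @inheritParams standard_filter
#' @param cutoff Positive E-value cutoff.
#' @return Kept hits with `method = "evalue"`.
#' @export
evalue_filter <- function(hits, cutoff, rules = nesting_rules()) {
  stopifnot(cutoff > 0)
  hits <- domain_hits(hits)
  hits <- dplyr::filter(hits, .data$evalue <= cutoff)
  if (nrow(hits) == 0) return(dplyr::mutate(hits, method = character(0)))
  hits <- hits |>
    dplyr::group_split(.data$protein) |>
    purrr::map(function(h) .greedy_legal(h, rules, order(h$evalue, h$hit_id))) |>
    purrr::list_rbind()
  dplyr::mutate(hits, method = "evalue")
}

#' CODD-style positive-context filter
#'
#' Starting from the trusted set `G` (hits passing the gathering thresholds,
#' no disallowed overlaps), candidates `D` are processed in ascending E-value
#' (ties by `hit_id`): a candidate is transferred into the prediction set iff
#' it has positive context with some member of the original `G` (not with
#' previously transferred candidates) and no disallowed overlap with anything
#' already in the prediction set. Weak domains can therefore only be rescued
#' by trusted domains, never by each other.
#'
#' @param G Trusted hit table for one protein (no disallowed overlaps).
#' @param D Candidate hit table for the same protein (hits already in `G`
#'   are ignored).
#' @param positive_pairs Tibble of positive family pairs
#'   ([positive_pair_set()]).
#' @param rules Nesting rules.
#' @return The prediction set (superset of `G`).
#' @export
codd_filter <- function(G, D, positive_pairs, rules = nesting_rules()) {
  G <- domain_hits(G)
  D <- domain_hits(D)
  # membership in G is decided on hit identity, not on id strings, so G and
  # D may come from independently constructed tables
  hkey <- function(h) paste(h$protein, h$family, h$start, h$end, h$score)
  D <- D[!hkey(D) %in% hkey(G), , drop = FALSE]
  clash <- D$hit_id %in% G$hit_id
  D$hit_id[clash] <- paste0(D$hit_id[clash], ":d")
  pos_keys <- .pair_key(positive_pairs$family_a, positive_pairs$family_b)
  P <- G
  for (k in order(D$evalue, D$hit_id)) {
    d <- D[k, , drop = FALSE]
    has_context <- nrow(G) > 0 && any(.pair_key(d$family, G$family) %in% pos_keys)
    if (!has_context) next
    legal <- nrow(P) == 0 ||
      all(vapply(seq_len(nrow(P)), function(i)
        overlap_allowed(d, P[i, , drop = FALSE], rules), logical(1)))
    if (legal) P <- dplyr::bind_rows(P, d)
  }
  dplyr::mutate(domain_hits_keep_extras(P), method = "codd")
}

#' Double positive-and-negative context filter (nCODD variant)
#'
#' Applies [codd_filter()], then iteratively removes members (including
#' trusted ones) that form a never-observed family pair with a
#' non-overlapping member of strictly higher normalized score, until a fixed
#' point. The published rule lives in unavailable supplementary material;
#' this variant implements the stated "double positive and negative"
#' semantics and is not byte-compatible with the original.
#'
#' @inheritParams codd_filter
#' @param thresholds Threshold table (for the `H - T` ordering).
#' @param network Context network providing the never-observed predicate.
#' @return The filtered prediction set with `method = "ncodd"`.
#' @export
ncodd_filter <- function(G, D, positive_pairs, network, thresholds,
                         rules = nesting_rules()) {
  P <- codd_filter(G, D, positive_pairs, rules)
  if (nrow(P) == 0) return(dplyr::mutate(P, method = "ncodd"))
  obs_keys <- .pair_key(network$scores$family_a, network$scores$family_b)
  repeat {
    m <- nrow(P)
    if (m < 2) break
    norm <- normalized_score(P, thresholds)
    ov <- .overlap_matrix(P)
    keys <- outer(P$family, P$family, .pair_key)
    unobs <- matrix(!(keys %in% obs_keys), m, m) & !ov
    diag(unobs) <- FALSE
    stronger <- outer(norm, norm, FUN = function(a, b) b > a + .dpucr_tol)
    flagged <- which(rowSums(unobs & stronger) > 0)
    if (length(flagged) == 0) break
    victim <- flagged[order(norm[flagged], P$hit_id[flagged])][1]
    P <- P[-victim, , drop = FALSE]
  }
  dplyr::mutate(P, method = "ncodd")
}

#' Run a baseline method over a multi-protein hit table
#'
#' One entry point for the comparison curves. For the context filters the
#' trusted set is the per-protein [standard_filter()] result and the
#' candidate set is everything under the permissive E-value cutoff.
#'
#' @param hits Candidate hit table.
#' @param mode One of `"standard"`, `"extended_ga"`, `"evalue"`, `"codd"`,
#'   `"ncodd"`.
#' @param thresholds,rules As elsewhere.
#' @param delta Shift for `extended_ga`.
#' @param cutoff E-value cutoff for `evalue`.
#' @param network Context network (needed for `codd`/`ncodd`).
#' @param positive_pairs Positive pair set; defaults to
#'   [positive_pair_set()] of `network`.
#' @param evalue_cutoff Candidate pool cutoff for the context filters.
#' @return Tibble of kept hits with a `method` column.
#' @export
baseline_predict <- function(hits, mode = c("standard", "extended_ga", "evalue",
                                            "codd", "ncodd"),
                             thresholds = NULL, rules = nesting_rules(),
                             delta = 0, cutoff = 1, network = NULL,
                             positive_pairs = NULL, evalue_cutoff = 1) {
  mode <- match.arg(mode)
  hits <- domain_hits(hits)
  if (mode == "evalue") return(evalue_filter(hits, cutoff, rules))
  if (is.null(thresholds)) abort("thresholds required", class = "dpucr_usage")
  if (mode == "standard") return(standard_filter(hits, thresholds, rules))
  if (mode == "extended_ga") return(extended_ga_filter(hits, thresholds, delta, rules))
  if (is.null(network)) abort("network required for codd/ncodd", class = "dpucr_usage")
  if (is.null(positive_pairs)) positive_pairs <- positive_pair_set(network)
  pool <- dplyr::filter(hits, .data$evalue <= evalue_cutoff)
  if (nrow(pool) == 0) return(dplyr::mutate(pool, method = character(0)))
  pool |>
    dplyr::group_split(.data$protein) |>
    purrr::map(function(h) {
      G <- standard_filter(h, thresholds, rules)
      G <- dplyr::select(G, -dplyr::any_of(c("normalized", "method")))
      if (mode == "codd") {
        codd_filter(G, h, positive_pairs, rules)
      } else {
        ncodd_filter(G, h, positive_pairs, network, thresholds, rules)
      }
    }) |>
    purrr::list_rbind()
}
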