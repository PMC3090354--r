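# Per-protein exact maximization of the context-adjusted total score over
# subsets of candidate domains.
#
# No ILP solver is used: the search space per protein is small, so an exact
# include-first branch-and-bound (with an optimistic context bound and
# overlap/threshold pruning) finds the maximizer directly. A vectorised
# brute-force enumerator serves as the independent oracle in the test suite.

# internal problem matrices for one protein's candidate hits
.prep_problem <- function(hits, thresholds, rules, network,
                          objective_mode = c("edge_once", "edge_twice")) {
  objective_mode <- match.arg(objective_mode)
  m <- nrow(hits)
  node <- if (m > 0) normalized_score(hits, thresholds) else numeric(0)
  ov <- .overlap_matrix(hits)
  allowed <- .allowed_matrix(hits, rules)
  disallowed <- ov & !allowed
  if (m > 0 && !is.null(network)) {
    C <- matrix(context_lookup(
      network,
      rep(hits$family, times = m),
      rep(hits$family, each = m)
    ), m, m)
  } else {
    C <- matrix(0, m, m)
  }
  # context edges exist only between non-overlapping selected pairs:
  # allowed-nested overlapping pairs coexist but contribute no context term
  C[ov] <- 0
  diag(C) <- 0
  list(hits = hits, node = node, ov = ov, disallowed = disallowed,
       C = C, w = if (objective_mode == "edge_once") 1 else 2,
       objective_mode = objective_mode)
}

# S_{i,D} for every member of a selected set (vector)
selection_score_all <- function(selected, thresholds, rules, network) {
  p <- .prep_problem(selected, thresholds, rules, network)
  if (nrow(selected) == 0) return(numeric(0))
  p$node + rowSums(p$C)
}

#' Context-adjusted score of each selected domain
#'
#' For domain `i` in a selected set `D`,
#' `S_{i,D} = (H_i - T_i) + sum over non-overlapping partners j in D of
#' C_ij`. With no partners (or an all-zero network) this reduces to the
#' plain normalized score, i.e. the standard per-family threshold test.
#' Distinct hits of the same family contribute the family's self-pair
#' context to each other.
#'
#' @param selected Hit table of the selected set (one protein).
#' @param thresholds Threshold table.
#' @param rules Nesting rules.
#' @param network Context network, or NULL for no context.
#' @return The input tibble with a `selection_score` column added.
#' @export
selection_score <- function(selected, thresholds, rules = nesting_rules(),
                            network = NULL) {
  selected <- domain_hits(selected)
  selected$selection_score <-
    selection_score_all(selected, thresholds, rules, network)
  selected
}

#' Total score of a selected set
#'
#' Sum of node weights `H_i - T_i` plus context edge weights over unordered
#' non-overlapping pairs in the set. `edge_once` counts each pair edge once
#' (the graph objective); `edge_twice` counts it in both endpoints' scores,
#' i.e. totals the per-domain `S_{i,D}` values.
#'
#' @inheritParams selection_score
#' @param objective_mode `"edge_once"` (default) or `"edge_twice"`.
#' @return Numeric scalar (bits); 0 for an empty set.
#' @export
total_score <- function(selected, thresholds, rules = nesting_rules(),
                        network = NULL,
                        objective_mode = c("edge_once", "edge_twice")) {
  objective_mode <- match.arg(objective_mode)
  if (nrow(selected) == 0) return(0)
  selected <- domain_hits(selected)
  p <- .prep_problem(selected, thresholds, rules, network, objective_mode)
  sum(p$node) + p$w * sum(p$C[upper.tri(p$C)])
}

# selection result container ------------------------------------------------

.new_selection <- function(protein, candidates, chosen_idx, prep,
                           thresholds, status) {
  sel <- candidates[chosen_idx, , drop = FALSE]
  if (nrow(sel) > 0) {
    s_partial <- rowSums(prep$C[chosen_idx, chosen_idx, drop = FALSE])
    sel$normalized <- prep$node[chosen_idx]
    sel$context <- s_partial
    sel$selection_score <- sel$normalized + sel$context
  } else {
    sel$normalized <- numeric(0)
    sel$context <- numeric(0)
    sel$selection_score <- numeric(0)
  }
  total <- sum(prep$node[chosen_idx]) +
    prep$w * sum(prep$C[chosen_idx, chosen_idx]) / 2
  structure(list(
    protein = protein,
    candidates = candidates,
    selected = sel,
    total_score = total,
    objective_mode = prep$objective_mode,
    status = status
  ), class = "dpuc_selection")
}

#' @export
print.dpuc_selection <- function(x, ...) {
  cat(sprintf("<dpuc_selection> %s: %d of %d candidates, total score %.4g bits (%s, %s)\n",
              x$protein, nrow(x$selected), nrow(x$candidates),
              x$total_score, x$objective_mode, x$status))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dpuc_selection <- function(x, ...) {
  x$selected
}

#' @exportS3Method generics::glance
glance.dpuc_selection <- function(x, ...) {
  tibble::tibble(
    protein = x$protein,
    n_candidates = nrow(x$candidates),
    n_selected = nrow(x$selected),
    total_score = x$total_score,
    objective_mode = x$objective_mode,
    status = x$status
  )
}

# ---------------------------------------------------------------------------

#' Remove candidates that can never satisfy the selection threshold
#'
#' A candidate whose normalized score plus the sum of all positive context it
#' could possibly collect from non-overlapping candidates is still negative
#' can never reach `S_{i,D} >= 0` in any feasible set, so dropping it cannot
#' change the optimum. Applied to a fixed point (removals shrink other
#' candidates' best cases).
#'
#' @param hits Candidate hit table for one protein.
#' @param thresholds,rules,network As elsewhere.
#' @return The surviving candidate hit table.
#' @export
eliminate_candidates <- function(hits, thresholds, rules = nesting_rules(),
                                 network = NULL) {
  hits <- domain_hits(hits)
  m <- nrow(hits)
  if (m == 0) return(hits)
  p <- .prep_problem(hits, thresholds, rules, network)
  posC <- pmax(p$C, 0)
  keep <- rep(TRUE, m)
  repeat {
    # own column is zero on the diagonal, so no self term to subtract
    ub <- p$node + rowSums(posC[, keep, drop = FALSE])
    drop_now <- keep & (ub < -.dpucr_tol)
    if (!any(drop_now)) break
    keep[drop_now] <- FALSE
  }
  hits[keep, , drop = FALSE]
}

#' Exhaustive enumeration oracle for the selection problem
#'
#' Enumerates every subset of the candidates (vectorised over bitmask
#' chunks), keeps the feasible ones (no disallowed overlaps; every member's
#' `S_{i,D} >= 0`), and returns the maximizer of the total score. Ties are
#' broken by preferring inclusion of earlier hits in canonical `hit_id`
#' order. Intended as the independent correctness check for [solve_exact()];
#' capped at 25 candidates.
#'
#' @inheritParams total_score
#' @param hits Candidate hit table for a single protein.
#' @return A `dpuc_selection`.
#' @export
brute_force_oracle <- function(hits, thresholds, rules = nesting_rules(),
                               network = NULL,
                               objective_mode = c("edge_once", "edge_twice")) {
  objective_mode <- match.arg(objective_mode)
  hits <- domain_hits(hits)
  m <- nrow(hits)
  if (m > 25) {
    abort("brute_force_oracle is capped at 25 candidates", class = "dpucr_too_large")
  }
  protein <- if (m > 0) hits$protein[1] else NA_character_
  if (m > 0 && length(unique(hits$protein)) > 1) {
    abort("candidates must be on a single protein", class = "dpucr_usage")
  }
  p <- .prep_problem(hits, thresholds, rules, network, objective_mode)
  if (m == 0) {
    return(.new_selection(protein, hits, integer(0), p, thresholds, "optimal"))
  }
  node <- p$node
  Ceff <- p$C
  B <- p$disallowed * 1
  lexw <- 2^(-(seq_len(m))) # earlier hits dominate the tie-break
  best_total <- -Inf
  best_lex <- -Inf
  best_mask <- 0
  n_masks <- 2^m
  chunk <- 2^min(m, 16)
  for (base in seq(0, n_masks - 1, by = chunk)) {
    masks <- base + seq_len(min(chunk, n_masks - base)) - 1
    M <- vapply(seq_len(m), function(i) bitwAnd(masks %/% 2^(i - 1), 1L) == 1L,
                logical(length(masks)))
    if (is.null(dim(M))) M <- matrix(M, nrow = 1)
    storage.mode(M) <- "double"
    MC <- M %*% Ceff                       # MC[s, i] = sum_j in s of C_ij
    node_tot <- as.vector(M %*% node)
    edge_tot <- rowSums(M * MC) / 2
    total <- node_tot + p$w * edge_tot
    illegal <- rowSums(M * (M %*% B)) > 0
    S <- matrix(node, nrow(M), m, byrow = TRUE) + MC
    infeasible <- rowSums(M * (S < -.dpucr_tol)) > 0
    ok <- !illegal & !infeasible
    if (!any(ok)) next
    total[!ok] <- -Inf
    lex <- as.vector(M %*% lexw)
    better <- total > best_total + .dpucr_tol |
      (abs(total - best_total) <= .dpucr_tol & lex > best_lex)
    if (any(better)) {
      cand <- which(better)
      # among this chunk's improvers pick max total then max lex
      o <- cand[order(-total[cand], -lex[cand])][1]
      if (total[o] > best_total + .dpucr_tol ||
          (abs(total[o] - best_total) <= .dpucr_tol && lex[o] > best_lex)) {
        best_total <- total[o]
        best_lex <- lex[o]
        best_mask <- masks[o]
      }
    }
  }
  chosen <- which(bitwAnd(best_mask %/% 2^(seq_len(m) - 1), 1L) == 1L)
  .new_selection(protein, hits, chosen, p, thresholds, "optimal")
}

#' Exact solver for the per-protein domain selection problem
#'
#' Finds the subset `D` of the candidates maximizing the total score subject
#' to (a) all pairwise overlaps being allowed and (b) every selected domain's
#' context-adjusted score `S_{i,D}` being non-negative. The search is an
#' exact depth-first branch-and-bound over candidates in canonical order:
#' the include branch is explored first (so the first incumbent at a given
#' score is the preferred tie-break), branches whose optimistic total cannot
#' beat the incumbent are cut, and a member whose score cannot be rescued by
#' any remaining positive context prunes its branch. Candidates that provably
#' cannot satisfy the threshold in any set are eliminated up front.
#'
#' An optional per-family sequence-level threshold can be layered on top of
#' the per-domain gathering thresholds: after selection, any family whose
#' selected hits sum to less than its sequence threshold (in bits) is
#' removed from the candidate pool and the problem re-solved, to a fixed
#' point. Disabled by default.
#'
#' @inheritParams brute_force_oracle
#' @param eliminate Run [eliminate_candidates()] first? (default TRUE)
#' @param seq_thresholds Optional tibble (`family`, `seq_threshold`)
#'   activating the per-family sequence-level score gate; NULL (default)
#'   disables it.
#' @return A `dpuc_selection` (status `"optimal"`).
#' @export
solve_exact <- function(hits, thresholds, rules = nesting_rules(),
                        network = NULL,
                        objective_mode = c("edge_once", "edge_twice"),
                        eliminate = TRUE, seq_thresholds = NULL) {
  if (!is.null(seq_thresholds)) {
    repeat {
      sel <- solve_exact(hits, thresholds, rules, network, objective_mode,
                         eliminate, seq_thresholds = NULL)
      fam_sum <- tapply(sel$selected$score, sel$selected$family, sum)
      idx <- match(names(fam_sum), seq_thresholds$family)
      weak <- names(fam_sum)[!is.na(idx) &
                               fam_sum < seq_thresholds$seq_threshold[idx]]
      if (length(weak) == 0) return(sel)
      hits <- hits[!hits$family %in% weak, , drop = FALSE]
    }
  }
  objective_mode <- match.arg(objective_mode)
  hits <- domain_hits(hits)
  if (nrow(hits) > 0 && length(unique(hits$protein)) > 1) {
    abort("candidates must be on a single protein", class = "dpucr_usage")
  }
  protein <- if (nrow(hits) > 0) hits$protein[1] else NA_character_
  full <- hits
  if (eliminate) hits <- eliminate_candidates(hits, thresholds, rules, network)
  p <- .prep_problem(hits, thresholds, rules, network, objective_mode)
  m <- nrow(hits)
  if (m == 0) {
    p_full <- .prep_problem(full, thresholds, rules, network, objective_mode)
    return(.new_selection(protein, full, integer(0), p_full, thresholds, "optimal"))
  }
  node <- p$node
  Ceff <- p$C
  posC <- pmax(Ceff, 0)
  disallowed <- p$disallowed
  w <- p$w
  # pos_suffix[i, k] = sum over j >= k of max(0, C_ij)
  pos_suffix <- cbind(t(apply(posC, 1, function(r) rev(cumsum(rev(r))))), 0)

  env <- new.env(parent = emptyenv())
  env$best_total <- -Inf
  env$best <- integer(0)
  env$found <- FALSE
  s_partial <- numeric(m)   # sum over chosen j of C_ij, for all i
  chosen <- logical(m)

  dfs <- function(k, cur_total) {
    if (k > m) {
      idx <- which(chosen)
      if (all(node[idx] + s_partial[idx] >= -.dpucr_tol)) {
        if (cur_total > env$best_total + .dpucr_tol || !env$found) {
          env$best_total <- cur_total
          env$best <- idx
          env$found <- TRUE
        }
      }
      return(invisible())
    }
    idx <- which(chosen)
    # optimistic rescue bound: a chosen member that cannot reach 0 even with
    # all remaining positive context kills the branch
    if (length(idx) > 0 &&
        any(node[idx] + s_partial[idx] + pos_suffix[idx, k] < -.dpucr_tol)) {
      return(invisible())
    }
    # optimistic total: every undecided candidate contributes its best case
    und <- k:m
    # forced edges to chosen members (s_partial) plus every positive edge to
    # the remaining undecided candidates; edges among undecided are counted
    # in both endpoints' gains, which only raises the bound
    gain <- node[und] + w * (s_partial[und] + pos_suffix[und, k])
    ub <- cur_total + sum(pmax(0, gain))
    if (env$found && ub < env$best_total - .dpucr_tol) return(invisible())

    # include k first (preferred tie-break), unless it clashes with chosen
    if (!any(disallowed[k, chosen])) {
      add <- node[k] + w * s_partial[k]
      chosen[k] <<- TRUE
      s_partial <<- s_partial + Ceff[, k]
      dfs(k + 1, cur_total + add)
      s_partial <<- s_partial - Ceff[, k]
      chosen[k] <<- FALSE
    }
    dfs(k + 1, cur_total)
  }
  dfs(1, 0)

  chosen_ids <- hits$hit_id[env$best]
  p_full <- .prep_problem(full, thresholds, rules, network, objective_mode)
  .new_selection(protein, full, match(chosen_ids, full$hit_id), p_full,
                 thresholds, "optimal")
}

#' Predict domains for every protein in a candidate hit table
#'
#' The end-to-end context-aware predictor: restrict to the permissive
#' candidate pool (`evalue <= evalue_cutoff`, default 1), then solve each
#' protein's selection problem exactly and independently.
#'
#' @param hits Candidate hit table (any number of proteins).
#' @param thresholds,rules,network,objective_mode As in [solve_exact()].
#' @param evalue_cutoff Permissive candidate E-value cutoff (default 1).
#' @return A tibble of selected hits across proteins with columns of
#'   [domain_hits()] plus `normalized`, `context`, `selection_score`,
#'   `total_score` and `method = "dpuc"`.
#' @export
predict_domains <- function(hits, thresholds, rules = nesting_rules(),
                            network = NULL, evalue_cutoff = 1,
                            objective_mode = c("edge_once", "edge_twice")) {
  objective_mode <- match.arg(objective_mode)
  hits <- domain_hits(hits)
  hits <- dplyr::filter(hits, .data$evalue <= evalue_cutoff)
  if (nrow(hits) == 0) {
    return(dplyr::mutate(hits, normalized = numeric(0), context = numeric(0),
                         selection_score = numeric(0), total_score = numeric(0),
                         method = character(0)))
  }
  hits |>
    dplyr::group_split(.data$protein) |>
    purrr::map(function(h) {
      sel <- solve_exact(h, thresholds, rules, network, objective_mode)
      out <- sel$selected
      out$total_score <- rep(sel$total_score, nrow(out))
      out
    }) |>
    purrr::list_rbind() |>
    dplyr::mutate(method = "dpuc")
}
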