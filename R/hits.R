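# Core data model: candidate domain hits, thresholds, nesting rules,
# overlap legality and selection validation.

#' Build a validated table of candidate domain hits
#'
#' A hit is one candidate occurrence of a domain family on a protein, with
#' envelope coordinates (1-based, inclusive), a bit score `H` and an E-value.
#' All downstream functions (context scoring, selection, baselines,
#' benchmarks) consume this table.
#'
#' Rows are sorted canonically by (protein, start, end, family, descending
#' score) and, if absent, a stable `hit_id` is assigned from that order.
#' `hit_id` is the deterministic tie-break used everywhere.
#'
#' @param x A data frame with columns `protein`, `family`, `start`, `end`,
#'   `score`, `evalue`, and optionally `hit_id`.
#' @return A tibble with the six canonical columns plus `hit_id`, sorted.
#' @examples
#' domain_hits(data.frame(
#'   protein = "P1", family = "PF1", start = 10, end = 60,
#'   score = 25.3, evalue = 1e-6
#' ))
#' @export
domain_hits <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("protein", "family", "start", "end", "score", "evalue")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("hit table lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "dpucr_bad_hits")
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$score <- as.double(x$score)
  x$evalue <- as.double(x$evalue)
  if (nrow(x) > 0) {
    if (any(is.na(x$start) | is.na(x$end) | x$start < 1L | x$end < x$start)) {
      abort("hit coordinates must satisfy 1 <= start <= end", class = "dpucr_bad_hits")
    }
    if (any(!is.finite(x$score))) {
      abort("hit scores must be finite", class = "dpucr_bad_hits")
    }
    if (any(is.na(x$evalue) | x$evalue < 0)) {
      abort("hit E-values must be non-negative", class = "dpucr_bad_hits")
    }
  }
  x <- dplyr::arrange(x, .data$protein, .data$start, .data$end,
                      .data$family, dplyr::desc(.data$score))
  if (!"hit_id" %in% names(x)) {
    x$hit_id <- if (nrow(x) > 0) {
      sprintf("%s:%04d", x$protein, stats::ave(seq_len(nrow(x)), x$protein, FUN = seq_along))
    } else {
      character(0)
    }
  } else {
    x$hit_id <- as.character(x$hit_id)
    dup <- duplicated(paste(x$protein, x$hit_id, sep = "\r"))
    if (any(dup)) {
      abort("hit_id values must be unique within each protein", class = "dpucr_bad_hits")
    }
  }
  dplyr::select(x, "protein", "family", "start", "end", "score", "evalue", "hit_id")
}

#' Build a per-family score threshold table
#'
#' Per-family bit-score cutoffs `T_i` (e.g. Pfam gathering thresholds).
#'
#' @param x Data frame with columns `family`, `threshold`.
#' @return A tibble; duplicate families are an error.
#' @export
threshold_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("family", "threshold") %in% names(x))) {
    abort("threshold table needs columns `family` and `threshold`", class = "dpucr_bad_thresholds")
  }
  if (anyDuplicated(x$family)) {
    abort("duplicate family in threshold table", class = "dpucr_bad_thresholds")
  }
  x$threshold <- as.double(x$threshold)
  if (any(!is.finite(x$threshold))) {
    abort("thresholds must be finite", class = "dpucr_bad_thresholds")
  }
  dplyr::select(x, "family", "threshold")
}

#' Build a nesting (allowed-overlap) rule table
#'
#' Unordered family pairs whose members may legitimately overlap in
#' coordinates (one domain inserted into the other). Pairs are stored
#' canonically (`family_a <= family_b`), so membership is symmetric.
#'
#' @param x Data frame with columns `family_a`, `family_b`, or NULL for no
#'   allowed overlaps.
#' @return A tibble with canonical unordered pairs, deduplicated.
#' @export
nesting_rules <- function(x = NULL) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(tibble::tibble(family_a = character(0), family_b = character(0)))
  }
  x <- tibble::as_tibble(x)
  if (!all(c("family_a", "family_b") %in% names(x))) {
    abort("nesting rules need columns `family_a` and `family_b`", class = "dpucr_bad_nesting")
  }
  a <- pmin(x$family_a, x$family_b)
  b <- pmax(x$family_a, x$family_b)
  dplyr::distinct(tibble::tibble(family_a = a, family_b = b))
}

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Normalized score of a hit: bit score minus its family threshold
#'
#' @param hits Hit table ([domain_hits()]).
#' @param thresholds Threshold table ([threshold_table()]).
#' @return Numeric vector `H - T`, one value per hit row.
#' @export
normalized_score <- function(hits, thresholds) {
  idx <- match(hits$family, thresholds$family)
  if (anyNA(idx) && nrow(hits) > 0) {
    bad <- unique(hits$family[is.na(idx)])
    abort(paste0("no threshold for family: ", paste(bad, collapse = ", ")),
          class = "dpucr_missing_threshold")
  }
  hits$score - thresholds$threshold[idx]
}

#' Do two coordinate intervals overlap?
#'
#' 1-based inclusive convention: `[10,20]` and `[20,30]` share residue 20 and
#' overlap; `[10,20]` and `[21,30]` are adjacent and do not.
#'
#' @param a,b Single-row hit tables (or lists with `protein`, `start`, `end`).
#' @return Logical scalar.
#' @export
intervals_overlap <- function(a, b) {
  if (!identical(as.character(a$protein), as.character(b$protein))) {
    abort("hits are on different proteins", class = "dpucr_usage")
  }
  max(a$start, b$start) <= min(a$end, b$end)
}

# vectorised m x m overlap matrix for one protein's hits
.overlap_matrix <- function(hits) {
  m <- nrow(hits)
  if (m == 0) return(matrix(FALSE, 0, 0))
  s <- hits$start
  e <- hits$end
  ov <- outer(s, s, pmax) <= outer(e, e, pmin)
  diag(ov) <- FALSE
  ov
}

# m x m matrix: TRUE where the family pair is in the nesting rules
.allowed_matrix <- function(hits, rules) {
  m <- nrow(hits)
  if (m == 0) return(matrix(FALSE, 0, 0))
  keys <- outer(hits$family, hits$family, .pair_key)
  matrix(keys %in% .pair_key(rules$family_a, rules$family_b), m, m)
}

#' May two hits coexist in a prediction set?
#'
#' TRUE if the hits do not overlap, or overlap and their family pair is an
#' allowed (nesting) overlap.
#'
#' @param a,b Single-row hit tables on the same protein.
#' @param rules Nesting rules ([nesting_rules()]).
#' @return Logical scalar.
#' @export
overlap_allowed <- function(a, b, rules) {
  if (!intervals_overlap(a, b)) return(TRUE)
  .pair_key(a$family, b$family) %in% .pair_key(rules$family_a, rules$family_b)
}

#' Validate a selected set of domains against the model's constraints
#'
#' A legal selection `D` contains no disallowed overlaps, and every selected
#' domain `i` has a non-negative context-adjusted score
#' `S_{i,D} = (H_i - T_i) + sum of context scores with its non-overlapping
#' partners in D`. Violations are returned as data, not raised.
#'
#' @param selected Hit table of the chosen domains (one protein).
#' @param thresholds Threshold table.
#' @param rules Nesting rules.
#' @param network Context network ([context_network()]), or NULL for no
#'   context (all `C_ij = 0`).
#' @return A tibble of violations (`type`, `hit_id`, `partner_id`, `detail`);
#'   zero rows means the selection is legal.
#' @export
validate_selection <- function(selected, thresholds, rules, network = NULL) {
  out <- tibble::tibble(type = character(0), hit_id = character(0),
                        partner_id = character(0), detail = character(0))
  m <- nrow(selected)
  if (m == 0) return(out)
  if (length(unique(selected$protein)) > 1) {
    abort("validate_selection expects hits on a single protein", class = "dpucr_usage")
  }
  ov <- .overlap_matrix(selected)
  allowed <- .allowed_matrix(selected, rules)
  bad <- which(ov & !allowed, arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      type = "overlap",
      hit_id = selected$hit_id[bad[, 1]],
      partner_id = selected$hit_id[bad[, 2]],
      detail = "disallowed coordinate overlap"
    ))
  }
  s <- selection_score_all(selected, thresholds, rules, network)
  low <- which(s < -.dpucr_tol)
  if (length(low) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      type = "threshold",
      hit_id = selected$hit_id[low],
      partner_id = NA_character_,
      detail = sprintf("context-adjusted score %.6g < 0", s[low])
    ))
  }
  out
}
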