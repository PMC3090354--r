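# Ortholog coherence benchmark: how often a predicted domain is matched by a
# same-family, alignment-overlapping prediction in the protein's orthologs.

#' Map residue coordinates onto alignment columns
#'
#' Translates a hit's 1-based residue interval on an ungapped protein into
#' column indices of that protein's row in a multiple alignment, skipping gap
#' characters.
#'
#' @param aligned_row Single aligned sequence (string, gaps `-` or `.`).
#' @param start,end 1-based inclusive residue interval on the ungapped
#'   sequence.
#' @return Integer vector `c(col_start, col_end)`.
#' @export
map_to_alignment <- function(aligned_row, start, end) {
  stopifnot(length(aligned_row) == 1, start >= 1, end >= start)
  chars <- strsplit(aligned_row, "", fixed = TRUE)[[1]]
  cols <- which(!chars %in% c("-", "."))
  if (end > length(cols)) {
    abort("hit extends past the end of the aligned sequence",
          class = "dpucr_bad_coordinates")
  }
  c(cols[start], cols[end])
}

# map all of a protein's predictions in a group to column intervals
.mapped_predictions <- function(preds, alignment) {
  purrr::map(names(alignment), function(id) {
    ph <- preds[preds$protein == id, , drop = FALSE]
    if (nrow(ph) == 0) {
      return(tibble::tibble(protein = character(0), family = character(0),
                            col_start = integer(0), col_end = integer(0)))
    }
    cols <- t(vapply(seq_len(nrow(ph)),
                     function(i) map_to_alignment(alignment[[id]], ph$start[i], ph$end[i]),
                     integer(2)))
    tibble::tibble(protein = ph$protein, family = ph$family,
                   col_start = cols[, 1], col_end = cols[, 2])
  }) |> purrr::list_rbind()
}

#' Ortholog coherence of one predicted domain
#'
#' The fraction of the protein's group partners (orthologs and in-paralogs
#' alike) that carry at least one prediction of the same family whose
#' alignment-column interval overlaps the domain's (>= 1 shared column).
#' The denominator is group size minus one.
#'
#' @param mapped One row of column-mapped predictions (`protein`, `family`,
#'   `col_start`, `col_end`).
#' @param group_mapped All column-mapped predictions of the group.
#' @param members Character vector of the group's protein ids.
#' @return Fraction in `[0, 1]`.
#' @export
domain_coherence <- function(mapped, group_mapped, members) {
  others <- setdiff(members, mapped$protein)
  if (length(others) == 0) {
    abort("coherence undefined for singleton groups", class = "dpucr_usage")
  }
  hit_in <- vapply(others, function(id) {
    cand <- group_mapped[group_mapped$protein == id &
                           group_mapped$family == mapped$family, , drop = FALSE]
    any(pmax(cand$col_start, mapped$col_start) <=
          pmin(cand$col_end, mapped$col_end))
  }, logical(1))
  sum(hit_in) / length(others)
}

#' Coherence of a prediction method over ortholog groups
#'
#' Scores every predicted domain of every protein in the groups by
#' [domain_coherence()] and averages over all domain instances (the method
#' score). Groups larger than `max_group_size` are excluded (large
#' paralogous families would bias the score); singleton groups are excluded
#' (coherence undefined).
#'
#' @param predictions Prediction hit table over all proteins.
#' @param groups Tibble with columns `group`, `protein`.
#' @param alignments Named list (by group id) of named character vectors of
#'   aligned rows (names = protein ids).
#' @param max_group_size Drop groups with more proteins than this
#'   (default 13).
#' @return A `coherence_experiment` object with per-domain scores, the mean
#'   method score, and domains per protein.
#' @export
method_coherence <- function(predictions, groups, alignments,
                             max_group_size = 13) {
  groups <- tibble::as_tibble(groups)
  keep <- groups |>
    dplyr::count(.data$group) |>
    dplyr::filter(.data$n >= 2, .data$n <= max_group_size)
  groups <- dplyr::semi_join(groups, keep, by = "group")
  if (nrow(groups) == 0) {
    abort("no usable ortholog groups", class = "dpucr_usage")
  }
  per_domain <- groups |>
    dplyr::group_split(.data$group) |>
    purrr::map(function(g) {
      gid <- g$group[1]
      aln <- alignments[[gid]]
      if (is.null(aln)) abort(paste0("no alignment for group ", gid),
                              class = "dpucr_usage")
      members <- g$protein
      preds <- predictions[predictions$protein %in% members, , drop = FALSE]
      mapped <- .mapped_predictions(preds, aln[members])
      if (nrow(mapped) == 0) return(NULL)
      mapped$coherence <- vapply(seq_len(nrow(mapped)), function(i)
        domain_coherence(mapped[i, , drop = FALSE], mapped, members), 0)
      mapped$group <- gid
      mapped
    }) |>
    purrr::list_rbind()
  n_proteins <- nrow(groups)
  if (nrow(per_domain) == 0) {
    abort("no predictions in any group: method coherence undefined",
          class = "dpucr_undefined_coherence")
  }
  structure(list(
    per_domain = per_domain,
    mean_coherence = mean(per_domain$coherence),
    domains_per_protein = nrow(per_domain) / n_proteins,
    n_proteins = n_proteins,
    n_domains = nrow(per_domain)
  ), class = "coherence_experiment")
}

#' @export
print.coherence_experiment <- function(x, ...) {
  cat(sprintf("<coherence_experiment> %d domains on %d proteins: mean coherence %.4g, %.3g domains/protein\n",
              x$n_domains, x$n_proteins, x$mean_coherence, x$domains_per_protein))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.coherence_experiment <- function(x, ...) x$per_domain

#' @exportS3Method generics::glance
glance.coherence_experiment <- function(x, ...) {
  tibble::tibble(
    n_proteins = x$n_proteins,
    n_domains = x$n_domains,
    signal = x$domains_per_protein,
    mean_coherence = x$mean_coherence
  )
}
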