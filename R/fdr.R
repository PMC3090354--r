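# Estimated-FDR benchmark: predictions on real sequences vs on shuffled
# sequences concatenated to the real ones (so context can reward noise).

#' Shuffle the residues of a protein sequence
#'
#' Uniform random permutation of the residues: amino-acid composition and
#' length are preserved, word structure is destroyed.
#'
#' @param seq Non-empty single character string.
#' @param seed Optional integer seed; with a seed the result is
#'   deterministic and the caller's RNG state is untouched.
#' @return Character string of the same length and composition.
#' @export
shuffle_sequence <- function(seq, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) {
    abort("cannot shuffle an empty sequence", class = "dpucr_usage")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  perm <- if (is.null(seed)) {
    sample.int(length(chars))
  } else {
    withr::with_seed(as.integer(seed), sample.int(length(chars)))
  }
  paste(chars[perm], collapse = "")
}

#' Concatenate a real sequence with its shuffled copy
#'
#' The context methods are run on the real sequence followed by its shuffled
#' copy as one protein, so random hits on the shuffled portion can be
#' rewarded by context with potentially real domains; only shuffled-portion
#' hits are counted as noise.
#'
#' @param real,shuffled Character strings of equal length.
#' @return List with `sequence` (the concatenation) and `boundary` (the last
#'   residue of the real portion).
#' @export
concatenate_and_split <- function(real, shuffled) {
  if (nchar(real) != nchar(shuffled)) {
    abort("shuffled sequence must have the same length as the real one",
          class = "dpucr_usage")
  }
  list(sequence = paste0(real, shuffled), boundary = nchar(real))
}

#' Attribute hits to the real or shuffled portion of a concatenated sequence
#'
#' Under the default `"majority"` rule a hit belongs to the shuffled portion
#' iff more than half of its envelope lies past the boundary; `"strict"`
#' requires the whole envelope past the boundary.
#'
#' @param hits Hit table on the concatenated sequence.
#' @param boundary Last residue index of the real portion.
#' @param rule `"majority"` (default) or `"strict"`.
#' @return Logical vector: TRUE where the hit counts as shuffled-portion.
#' @export
hits_on_shuffled <- function(hits, boundary, rule = c("majority", "strict")) {
  rule <- match.arg(rule)
  if (nrow(hits) == 0) return(logical(0))
  if (rule == "strict") return(hits$start > boundary)
  past <- pmax(0, hits$end - pmax(hits$start - 1, boundary))
  past / (hits$end - hits$start + 1) > 0.5
}

#' Per-protein FDR records from raw counts
#'
#' Builds the benchmark's per-protein record: `R` real-sequence prediction
#' counts and `A`, the mean shuffled-portion prediction count over the
#' shuffle replicates.
#'
#' @param protein Character vector of protein ids.
#' @param real_counts Integer vector: predictions on each real protein.
#' @param shuffled_counts List (one element per protein) of per-replicate
#'   shuffled-portion prediction counts, or a numeric vector of totals.
#' @param n_shuffles Number of shuffle replicates each total is averaged
#'   over (used when `shuffled_counts` are totals; default 20).
#' @return Tibble with columns `protein`, `R`, `A`, `n_shuffles`.
#' @export
fdr_records <- function(protein, real_counts, shuffled_counts, n_shuffles = 20) {
  stopifnot(n_shuffles >= 1)
  if (is.list(shuffled_counts)) {
    A <- vapply(shuffled_counts, mean, 0)
    n_shuffles <- lengths(shuffled_counts)
  } else {
    A <- shuffled_counts / n_shuffles
  }
  tibble::tibble(protein = protein, R = as.double(real_counts), A = A,
                 n_shuffles = n_shuffles)
}

#' Estimated false discovery rate from shuffling records
#'
#' `FDR = mean(A) / mean(R)`: the mean number of predictions per shuffled
#' protein over the mean number per real protein. Shuffled-sequence hits
#' arise by chance alone, so this ratio approximates the fraction of
#' real-sequence predictions that are noise.
#'
#' @param records Tibble from [fdr_records()] (columns `R`, `A`).
#' @return FDR as a proportion (not a percentage).
#' @export
estimate_fdr <- function(records) {
  if (nrow(records) == 0 || sum(records$R) <= 0) {
    abort("FDR undefined: no predictions on real sequences",
          class = "dpucr_undefined_fdr")
  }
  mean(records$A) / mean(records$R)
}

#' FDR of the newly added domains only
#'
#' For a context method, `A_n`/`R_n` are the shuffled/real prediction rates
#' with negative context only (no new domains added), and `A`/`R` the rates
#' at the permissive candidate threshold of interest. The difference is
#' almost entirely the novel domains, so their FDR is
#' `(A - A_n) / (R - R_n)`.
#'
#' @param A,R Shuffled and real prediction rates at the permissive threshold.
#' @param A_n,R_n Same with negative context only.
#' @return FDR of the novel domains, as a proportion.
#' @export
new_domain_fdr <- function(A, R, A_n, R_n) {
  if (R <= R_n) {
    abort("no novel domains: R must exceed R_n", class = "dpucr_no_novel")
  }
  (A - A_n) / (R - R_n)
}

#' Run the shuffled-sequence FDR experiment
#'
#' For each protein: the scanner produces candidate hits on the real
#' sequence and the method is applied to count `R`; then, for each of
#' `n_shuffles` replicates, the real sequence is concatenated to a fresh
#' shuffle of itself, scanned, the method applied to the concatenated
#' protein as a single problem, and predictions attributed to the shuffled
#' portion are counted. `A` is the per-protein mean over replicates.
#'
#' @param sequences Named character vector of protein sequences.
#' @param scanner Function `(protein_id, sequence, seed)` returning a
#'   candidate hit table; must be deterministic given `seed`.
#' @param method Function mapping a candidate hit table to a prediction hit
#'   table (e.g. a closure over [predict_domains()] or [standard_filter()]).
#' @param n_shuffles Shuffle replicates per protein (default 20).
#' @param seed Integer master seed; all per-protein and per-replicate seeds
#'   derive from it.
#' @param rule Attribution rule, see [hits_on_shuffled()].
#' @return An `fdr_experiment` object: list with `records`
#'   ([fdr_records()] tibble), `fdr`, `n_shuffles`, `seed`.
#' @export
run_fdr_experiment <- function(sequences, scanner, method, n_shuffles = 20,
                               seed, rule = c("majority", "strict")) {
  rule <- match.arg(rule)
  stopifnot(n_shuffles >= 1, length(sequences) > 0, !is.null(names(sequences)))
  seed <- as.integer(seed)
  ids <- names(sequences)
  recs <- purrr::imap(sequences, function(sq, id) {
    k <- match(id, ids)
    real_hits <- scanner(id, sq, seed = seed + 1009L * k)
    R <- nrow(method(real_hits))
    a_counts <- vapply(seq_len(n_shuffles), function(r) {
      rep_seed <- seed + 1009L * k + 31L * r
      shuf <- shuffle_sequence(sq, seed = rep_seed)
      cs <- concatenate_and_split(sq, shuf)
      hits <- scanner(id, cs$sequence, seed = rep_seed + 7L)
      pred <- method(hits)
      sum(hits_on_shuffled(pred, cs$boundary, rule))
    }, 0)
    tibble::tibble(protein = id, R = as.double(R), A = mean(a_counts),
                   n_shuffles = n_shuffles)
  }) |> purrr::list_rbind()
  structure(list(records = recs, fdr = estimate_fdr(recs),
                 n_shuffles = n_shuffles, seed = seed),
            class = "fdr_experiment")
}

#' @export
print.fdr_experiment <- function(x, ...) {
  cat(sprintf("<fdr_experiment> %d proteins, %d shuffles: FDR = %.4g (signal %.3g domains/protein)\n",
              nrow(x$records), x$n_shuffles[1], x$fdr, mean(x$records$R)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fdr_experiment <- function(x, ...) x$records

#' @exportS3Method generics::glance
glance.fdr_experiment <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$records),
    n_shuffles = x$n_shuffles[1],
    signal = mean(x$records$R),
    fdr = x$fdr
  )
}
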