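# Readers and writers. All bespoke formats are UTF-8, Unix-newline,
# TAB-separated; "." marks missing optional values; floats are written at
# full precision (17 significant digits) so write -> read round-trips.

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "." else sprintf("%.17g", v)
  }, "")
  # trim trailing zeros sprintf leaves on exact values
  sub("(\\.[0-9]*[1-9])0+$|\\.0+$", "\\1", out)
}

.read_tsv <- function(path, col_types) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "dpucr_io")
  }
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE, na = ".")
}

#' Read a candidate hit table
#'
#' Two layouts: the canonical 6-column TSV
#' (`protein family start end score evalue`, header required, `#` comments
#' tolerated) and the HMMER3 per-domain table (`domtblout`,
#' whitespace-delimited; family = target name, protein = query name,
#' envelope coordinates, domain bit score, independent E-value).
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"domtblout"`.
#' @return A [domain_hits()] table.
#' @export
read_hits <- function(path, format = c("tsv", "domtblout")) {
  format <- match.arg(format)
  if (format == "domtblout") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(domain_hits(tibble::tibble(
        protein = character(0), family = character(0), start = integer(0),
        end = integer(0), score = double(0), evalue = double(0)
      )))
    }
    fields <- strsplit(trimws(lines), "[ \t]+")
    short <- which(lengths(fields) < 22)
    if (length(short) > 0) {
      abort(paste0("malformed domtblout row at line ", short[1]),
            class = "dpucr_parse")
    }
    f <- function(k) vapply(fields, `[[`, "", k)
    return(domain_hits(tibble::tibble(
      protein = f(4), family = f(1),
      start = as.integer(f(20)), end = as.integer(f(21)),
      score = as.double(f(14)), evalue = as.double(f(13))
    )))
  }
  tab <- .read_tsv(path, readr::cols(
    protein = readr::col_character(), family = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    score = readr::col_double(), evalue = readr::col_double(),
    .default = readr::col_character()
  ))
  bad <- which(is.na(tab$start) | is.na(tab$end) | tab$end < tab$start |
                 is.na(tab$evalue) | tab$evalue < 0)
  if (length(bad) > 0) {
    abort(paste0("malformed hit row (data line ", bad[1],
                 "): need 1 <= start <= end and evalue >= 0"),
          class = "dpucr_parse")
  }
  domain_hits(tab)
}

#' Write a hit table
#' @param hits Hit table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  hits <- domain_hits(hits)
  lines <- c("protein\tfamily\tstart\tend\tscore\tevalue\thit_id",
             sprintf("%s\t%s\t%d\t%d\t%s\t%s\t%s",
                     hits$protein, hits$family, hits$start, hits$end,
                     .fmt_num(hits$score), .fmt_num(hits$evalue), hits$hit_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-family threshold table (TSV: `family threshold`)
#' @param path File path.
#' @return A [threshold_table()]; duplicate families are an error.
#' @export
read_thresholds <- function(path) {
  threshold_table(.read_tsv(path, readr::cols(
    family = readr::col_character(), threshold = readr::col_double()
  )))
}

#' Write a threshold table
#' @param thresholds Threshold table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  thresholds <- threshold_table(thresholds)
  writeLines(c("family\tthreshold",
               sprintf("%s\t%s", thresholds$family, .fmt_num(thresholds$threshold))),
             path)
  invisible(path)
}

#' Read nesting (allowed-overlap) rules (TSV: `family_a family_b`)
#' @param path File path.
#' @return A [nesting_rules()] table.
#' @export
read_nesting <- function(path) {
  nesting_rules(.read_tsv(path, readr::cols(
    family_a = readr::col_character(), family_b = readr::col_character()
  )))
}

#' Write nesting rules
#' @param rules Nesting rules.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nesting <- function(rules, path) {
  rules <- nesting_rules(rules)
  writeLines(c("family_a\tfamily_b",
               sprintf("%s\t%s", rules$family_a, rules$family_b)), path)
  invisible(path)
}

#' Read an architecture database
#'
#' TSV: `protein` TAB comma-separated ordered family list.
#'
#' @param path File path.
#' @return An [architecture_db()]; duplicate proteins are an error.
#' @export
read_architectures <- function(path) {
  tab <- .read_tsv(path, readr::cols(
    protein = readr::col_character(), architecture = readr::col_character()
  ))
  architecture_db(tab)
}

#' Write an architecture database
#' @param db Architecture database.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_architectures <- function(db, path) {
  db <- architecture_db(db)
  writeLines(c("protein\tarchitecture",
               sprintf("%s\t%s", db$protein,
                       vapply(db$architecture, paste, "", collapse = ","))),
             path)
  invisible(path)
}

#' Write a context network
#'
#' A `#` metadata line carries `n`, `c`, `alpha`, `b` and the shared
#' unobserved-pair penalty at full precision, followed by one row per
#' observed pair: `family_a family_b count score`.
#'
#' @param net A `context_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  meta <- sprintf("# n=%d c=%s alpha=%s b=%s unobserved_penalty=%s families=%s",
                  net$n, .fmt_num(net$c_total), .fmt_num(net$alpha),
                  .fmt_num(net$b), .fmt_num(net$unobserved_penalty),
                  paste(net$families, collapse = ","))
  sc <- net$scores
  writeLines(c(meta, "family_a\tfamily_b\tcount\tscore",
               sprintf("%s\t%s\t%s\t%s", sc$family_a, sc$family_b,
                       .fmt_num(sc$count), .fmt_num(sc$score))),
             path)
  invisible(path)
}

#' Read a context network written by [write_network()]
#' @param path File path.
#' @return A `context_network`.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  meta_line <- lines[startsWith(lines, "#")][1]
  if (is.na(meta_line)) {
    abort("network file lacks its # metadata line", class = "dpucr_parse")
  }
  kv <- strsplit(strsplit(sub("^#\\s*", "", meta_line), " ")[[1]], "=")
  meta <- setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
  # base strtod parsing: correctly rounded, so full-precision floats
  # round-trip bit-identically
  sc <- utils::read.delim(path, comment.char = "#", colClasses = c(
    family_a = "character", family_b = "character",
    count = "numeric", score = "numeric"
  ))
  sc <- tibble::as_tibble(sc)
  structure(list(
    scores = sc,
    unobserved_penalty = as.double(meta[["unobserved_penalty"]]),
    n = as.integer(meta[["n"]]), c_total = as.double(meta[["c"]]),
    alpha = as.double(meta[["alpha"]]), b = as.double(meta[["b"]]),
    families = strsplit(meta[["families"]], ",", fixed = TRUE)[[1]]
  ), class = "context_network")
}

#' Read ortholog groups (TSV: `group` TAB comma-separated protein ids)
#' @param path File path.
#' @return Tibble with columns `group`, `protein` (one row per member).
#' @export
read_groups <- function(path) {
  tab <- .read_tsv(path, readr::cols(
    group = readr::col_character(), proteins = readr::col_character()
  ))
  if (anyDuplicated(tab$group)) {
    abort("duplicate group id", class = "dpucr_parse")
  }
  tidyr::separate_rows(tab, "proteins", sep = ",") |>
    dplyr::rename(protein = "proteins")
}

#' Write ortholog groups
#' @param groups Tibble (`group`, `protein`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  agg <- groups |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(proteins = paste(.data$protein, collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(.data$group)
  writeLines(c("group\tproteins", sprintf("%s\t%s", agg$group, agg$proteins)),
             path)
  invisible(path)
}

#' Write predictions
#'
#' Canonical row order (protein, start, end, family) regardless of input
#' order, full-precision floats, so identical prediction sets serialize to
#' identical bytes.
#'
#' @param predictions Prediction table (hit columns, optionally
#'   `normalized`, `selection_score`, `method`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  p <- tibble::as_tibble(predictions)
  for (col in c("normalized", "selection_score")) {
    if (!col %in% names(p)) p[[col]] <- NA_real_
  }
  if (!"method" %in% names(p)) p$method <- "."
  p <- dplyr::arrange(p, .data$protein, .data$start, .data$end, .data$family)
  writeLines(c(
    "protein\tfamily\tstart\tend\tscore\tnormalized\tselection_score\tmethod",
    sprintf("%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
            p$protein, p$family, as.integer(p$start), as.integer(p$end),
            .fmt_num(p$score), .fmt_num(p$normalized),
            .fmt_num(p$selection_score), p$method)
  ), path)
  invisible(path)
}

#' Write benchmark results
#'
#' One row per method: `method params signal metric value` with
#' full-precision numbers and deterministic (method-sorted) order.
#'
#' @param results Tibble with columns `method`, `params`, `signal`,
#'   `metric`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bench <- function(results, path) {
  r <- dplyr::arrange(tibble::as_tibble(results), .data$method, .data$metric)
  writeLines(c("method\tparams\tsignal\tmetric\tvalue",
               sprintf("%s\t%s\t%s\t%s\t%s", r$method, r$params,
                       .fmt_num(r$signal), r$metric, .fmt_num(r$value))),
             path)
  invisible(path)
}

#' Read protein sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write protein sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Export predictions as GFF3 `protein_match` features
#'
#' 1-based inclusive coordinates on the protein as the landmark; the family
#' goes in `Name`, the selection score (when present) in `score`.
#'
#' @param predictions Prediction table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(predictions, path) {
  p <- dplyr::arrange(tibble::as_tibble(predictions),
                      .data$protein, .data$start, .data$end, .data$family)
  score <- if ("selection_score" %in% names(p)) .fmt_num(p$selection_score) else
    .fmt_num(p$score)
  writeLines(c("##gff-version 3",
               sprintf("%s\tdpucr\tprotein_match\t%d\t%d\t%s\t.\t.\tName=%s",
                       p$protein, as.integer(p$start), as.integer(p$end),
                       score, p$family)),
             path)
  invisible(path)
}
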