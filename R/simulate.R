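# Synthetic fixtures with known ground truth: architecture corpora with
# planted pair enrichments, candidate hit tables with sub-threshold true
# domains and decoys, random proteomes, and jittered ortholog groups.
#
# Scores are simulated directly in bit space relative to the family
# thresholds: the selection machinery consumes scores, not sequences, so no
# HMM emission model is needed. Sequence content only matters for the
# shuffling benchmark, where residues are drawn i.i.d.

#' Specification of a synthetic study
#'
#' Bundles every knob of the fixture generator. Defaults are sized so the
#' whole battery of tests runs in well under a minute while still exercising
#' context rescue: 50 families, 500 proteins, 10 planted pairs whose members
#' co-occur ten times more often than a uniform background.
#'
#' @param seed Integer seed (mandatory; every generator is deterministic
#'   given the spec).
#' @param n_families Number of domain families.
#' @param n_proteins Number of proteins in the architecture corpus.
#' @param n_planted_pairs Number of enriched family pairs planted in the
#'   corpus.
#' @param planted_weight Enrichment weight of each planted pair; 0 disables
#'   planting (uniform background).
#' @param arch_len_probs Probabilities of architecture lengths `1..K`.
#' @param repeat_prob Probability an architecture duplicates one family.
#' @param offset_mean,offset_sd Normal distribution of true-domain score
#'   offsets around the family threshold (bits); negative draws are the
#'   sub-threshold true domains context must rescue.
#' @param decoy_rate Decoy hits per residue.
#' @param decoy_evalue_range Uniform E-value range of decoys.
#' @param domain_length,linker_length Residue lengths used to lay out hits.
#' @param n_groups,group_size Ortholog group count and inclusive size range.
#' @param jitter Per-position deletion probability in ortholog group members
#'   (divergence of the alignment).
#' @param decoy_tolerance Allowed excess decoy-acceptance rate of the
#'   context predictor over the standard filter in recovery experiments.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(seed,
                     n_families = 50,
                     n_proteins = 500,
                     n_planted_pairs = 10,
                     planted_weight = 10,
                     arch_len_probs = c(0.25, 0.35, 0.25, 0.15),
                     repeat_prob = 0.05,
                     offset_mean = 3,
                     offset_sd = 3,
                     decoy_rate = 0.003,
                     decoy_evalue_range = c(0.01, 1),
                     domain_length = 60,
                     linker_length = 15,
                     n_groups = 12,
                     group_size = c(3, 5),
                     jitter = 0.05,
                     decoy_tolerance = 0.02) {
  stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1)
  stopifnot(repeat_prob >= 0, repeat_prob <= 1, jitter >= 0, jitter <= 1,
            decoy_rate >= 0, n_families >= 2, n_proteins >= 2)
  families <- sprintf("F%03d", seq_len(n_families))
  planted <- if (n_planted_pairs > 0 && planted_weight > 0) {
    withr::with_seed(as.integer(seed) + 11L, {
      idx <- t(replicate(n_planted_pairs, sample.int(n_families, 2)))
      tibble::tibble(family_a = pmin(families[idx[, 1]], families[idx[, 2]]),
                     family_b = pmax(families[idx[, 1]], families[idx[, 2]]),
                     weight = planted_weight) |> dplyr::distinct()
    })
  } else {
    tibble::tibble(family_a = character(0), family_b = character(0),
                   weight = double(0))
  }
  structure(list(
    seed = as.integer(seed), n_families = n_families, families = families,
    n_proteins = n_proteins, planted_pairs = planted,
    arch_len_probs = arch_len_probs / sum(arch_len_probs),
    repeat_prob = repeat_prob, offset_mean = offset_mean, offset_sd = offset_sd,
    decoy_rate = decoy_rate, decoy_evalue_range = decoy_evalue_range,
    domain_length = domain_length, linker_length = linker_length,
    n_groups = n_groups, group_size = group_size, jitter = jitter,
    decoy_tolerance = decoy_tolerance
  ), class = "sim_spec")
}

#' Simulated per-family gathering thresholds
#'
#' Uniform bit-score thresholds in `[15, 30]`, one per family, deterministic
#' per spec seed.
#'
#' @param spec A [sim_spec()].
#' @return A [threshold_table()].
#' @export
simulate_thresholds <- function(spec) {
  withr::with_seed(spec$seed + 23L, threshold_table(tibble::tibble(
    family = spec$families,
    threshold = round(runif(spec$n_families, 15, 30), 1)
  )))
}

#' Simulate an architecture corpus with planted pair enrichments
#'
#' Draws distinct architectures (ordered family lists) and assigns each to
#' at least two proteins, so the default corpus survives
#' [filter_architectures()] unchanged. An architecture contains a planted
#' pair with probability `W / (W + n_families)` where `W` is the total
#' planted weight, making planted pairs co-occur far above the uniform
#' background; zero weight gives a uniform corpus.
#'
#' @param spec A [sim_spec()].
#' @return An [architecture_db()].
#' @export
simulate_architectures <- function(spec) {
  withr::with_seed(spec$seed + 37L, {
    n_arch <- ceiling(spec$n_proteins / 2)
    W <- sum(spec$planted_pairs$weight)
    p_plant <- W / (W + spec$n_families)
    archs <- purrr::map(seq_len(n_arch), function(i) {
      k <- sample(seq_along(spec$arch_len_probs), 1, prob = spec$arch_len_probs)
      if (nrow(spec$planted_pairs) > 0 && runif(1) < p_plant) {
        pr <- spec$planted_pairs[sample.int(nrow(spec$planted_pairs), 1,
                                            prob = spec$planted_pairs$weight), ]
        extra <- if (k > 2) sample(spec$families, k - 2, replace = TRUE) else character(0)
        arch <- sample(c(pr$family_a, pr$family_b, extra))
      } else {
        arch <- sample(spec$families, max(1, k), replace = TRUE)
      }
      if (runif(1) < spec$repeat_prob) {
        arch <- append(arch, arch[sample.int(length(arch), 1)],
                       after = sample.int(length(arch), 1))
      }
      arch
    })
    copies <- rep(2L, n_arch)
    extra_n <- spec$n_proteins - sum(copies)
    if (extra_n > 0) {
      add <- sample.int(n_arch, extra_n, replace = TRUE)
      for (a in add) copies[a] <- copies[a] + 1L
    } else if (extra_n < 0) {
      copies[n_arch] <- copies[n_arch] + extra_n
    }
    db <- tibble::tibble(
      protein = sprintf("P%05d", seq_len(sum(copies))),
      architecture = rep(archs, times = copies)
    )
    architecture_db(db)
  })
}

#' Simulate candidate hit tables with truth labels
#'
#' True domains are laid out left to right along each protein with scores
#' `H = T + offset`, `offset ~ N(offset_mean, offset_sd)`; the negative tail
#' gives sub-threshold true domains that only context can rescue. Decoy hits
#' land at `decoy_rate` per residue with scores strictly below threshold and
#' permissive E-values. E-values are a monotone transform of the offset,
#' scaled so moderately sub-threshold true domains stay inside the
#' default `E <= 1` candidate pool.
#'
#' @param db An [architecture_db()] of true architectures.
#' @param thresholds Threshold table covering all families.
#' @param spec A [sim_spec()].
#' @return List with `hits` (candidate [domain_hits()]) and `truth` (tibble:
#'   `protein`, `hit_id`, `truth` = "true"/"decoy", `subthreshold`).
#' @export
simulate_candidates <- function(db, thresholds, spec) {
  dl <- spec$domain_length
  step <- dl + spec$linker_length
  thr <- setNames(thresholds$threshold, thresholds$family)
  withr::with_seed(spec$seed + 53L, {
    rows <- purrr::map(seq_len(nrow(db)), function(p) {
      arch <- db$architecture[[p]]
      id <- db$protein[p]
      e_p <- length(arch)
      plen <- e_p * step
      offs <- rnorm(e_p, spec$offset_mean, spec$offset_sd)
      true <- tibble::tibble(
        protein = id, family = arch,
        start = (seq_len(e_p) - 1L) * step + 1L,
        end = (seq_len(e_p) - 1L) * step + dl,
        score = unname(thr[arch]) + offs,
        evalue = pmin(100, 0.01 * 2^(-offs)),
        hit_id = sprintf("%s:T%02d", id, seq_len(e_p)),
        truth = "true", subthreshold = offs < 0
      )
      n_dec <- rpois(1, spec$decoy_rate * plen)
      if (n_dec > 0) {
        fam_d <- sample(spec$families, n_dec, replace = TRUE)
        st <- sample.int(max(1L, plen - dl), n_dec, replace = TRUE)
        dec <- tibble::tibble(
          protein = id, family = fam_d,
          start = st, end = st + dl - 1L,
          score = unname(thr[fam_d]) - runif(n_dec, 0.5, 8),
          evalue = runif(n_dec, spec$decoy_evalue_range[1],
                         spec$decoy_evalue_range[2]),
          hit_id = sprintf("%s:D%02d", id, seq_len(n_dec)),
          truth = "decoy", subthreshold = TRUE
        )
        true <- dplyr::bind_rows(true, dec)
      }
      true
    }) |> purrr::list_rbind()
  })
  list(
    hits = domain_hits(dplyr::select(rows, -"truth", -"subthreshold")),
    truth = dplyr::select(rows, "protein", "hit_id", "truth", "subthreshold")
  )
}

#' Simulate a random proteome
#'
#' I.i.d. residues from a fixed composition; used by the shuffling benchmark
#' (which only needs composition and length, not homology).
#'
#' @param n Number of proteins.
#' @param length_range Inclusive residue-length range.
#' @param seed Integer seed.
#' @param composition Named probability vector over residues (default
#'   uniform over the 20 standard amino acids).
#' @return Named character vector of sequences.
#' @export
simulate_proteome <- function(n, length_range = c(200, 600), seed,
                              composition = NULL) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(composition)) composition <- setNames(rep(1 / 20, 20), aa)
  withr::with_seed(as.integer(seed), {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(names(composition), L, replace = TRUE, prob = composition),
            collapse = ""), "")
    setNames(seqs, sprintf("Q%04d", seq_len(n)))
  })
}

#' Poisson noise scanner
#'
#' A scanner (for [run_fdr_experiment()]) that fires candidate hits at a
#' fixed per-residue rate regardless of sequence content — the pure-noise
#' predictor whose estimated FDR should be ~1.
#'
#' @param rate Expected hits per residue.
#' @param families Family universe to draw from.
#' @param hit_length Envelope length of each hit.
#' @return A function `(protein_id, sequence, seed)` returning a hit table.
#' @export
scanner_noise <- function(rate, families, hit_length = 50) {
  force(rate); force(families); force(hit_length)
  function(protein_id, sequence, seed) {
    L <- nchar(sequence)
    withr::with_seed(as.integer(seed), {
      n <- rpois(1, rate * L)
      if (n == 0 || L <= hit_length) {
        return(domain_hits(tibble::tibble(
          protein = character(0), family = character(0), start = integer(0),
          end = integer(0), score = double(0), evalue = double(0)
        )))
      }
      st <- sample.int(L - hit_length, n, replace = TRUE)
      domain_hits(tibble::tibble(
        protein = protein_id, family = sample(families, n, replace = TRUE),
        start = st, end = st + hit_length - 1L,
        score = rnorm(n, 10, 3), evalue = runif(n)
      ))
    })
  }
}

#' Simulate ortholog groups with alignments and predictions
#'
#' Each group shares one true architecture. Member rows of the group
#' alignment start from a common base layout; with probability `jitter` a
#' base position is deleted in a member (a gap), so member coordinates
#' diverge while the alignment stays consistent with them. Per-member
#' predictions are the true domains mapped through the member's gaps; with
#' zero jitter every member predicts identical columns and the coherence of
#' the truth is exactly 1.
#'
#' @param spec A [sim_spec()].
#' @param thresholds Optional threshold table (scores are set 2 bits above
#'   threshold when given, else at a constant 25 bits).
#' @return List with `groups` (tibble `group`, `protein`), `alignments`
#'   (named list of named character vectors) and `hits` (prediction table).
#' @export
simulate_ortholog_groups <- function(spec, thresholds = NULL) {
  dl <- spec$domain_length
  step <- dl + spec$linker_length
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  thr <- if (!is.null(thresholds)) setNames(thresholds$threshold, thresholds$family)
  withr::with_seed(spec$seed + 71L, {
    out <- purrr::map(seq_len(spec$n_groups), function(g) {
      size <- sample(spec$group_size[1]:spec$group_size[2], 1)
      k <- sample(seq_along(spec$arch_len_probs), 1, prob = spec$arch_len_probs)
      arch <- sample(spec$families, max(1, k), replace = TRUE)
      L <- length(arch) * step
      members <- sprintf("G%02dM%02d", g, seq_len(size))
      dom_cols <- tibble::tibble(
        family = arch,
        col_start = (seq_along(arch) - 1L) * step + 1L,
        col_end = (seq_along(arch) - 1L) * step + dl
      )
      rows <- list(); hits <- list()
      for (m in members) {
        present <- runif(L) >= spec$jitter
        chars <- ifelse(present, sample(aa, L, replace = TRUE), "-")
        rows[[m]] <- paste(chars, collapse = "")
        resid_no <- cumsum(present)
        mh <- purrr::map(seq_len(nrow(dom_cols)), function(d) {
          span <- dom_cols$col_start[d]:dom_cols$col_end[d]
          span <- span[present[span]]
          if (length(span) == 0) return(NULL)
          fam <- dom_cols$family[d]
          tibble::tibble(
            protein = m, family = fam,
            start = resid_no[span[1]], end = resid_no[span[length(span)]],
            score = if (is.null(thr)) 25 else unname(thr[fam]) + 2,
            evalue = 1e-5
          )
        }) |> purrr::list_rbind()
        hits[[m]] <- mh
      }
      list(
        groups = tibble::tibble(group = sprintf("OG%03d", g), protein = members),
        alignment = unlist(rows),
        hits = purrr::list_rbind(hits)
      )
    })
    alignments <- setNames(purrr::map(out, "alignment"),
                           sprintf("OG%03d", seq_len(spec$n_groups)))
    list(
      groups = purrr::list_rbind(purrr::map(out, "groups")),
      alignments = alignments,
      hits = domain_hits(purrr::list_rbind(purrr::map(out, "hits")))
    )
  })
}
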