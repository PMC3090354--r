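---
title: "Context-aware domain prediction: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware domain prediction: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpucr)
library(dplyr)
```

## The problem

Profile-HMM searches (HMMER against Pfam-style family libraries) score each
candidate domain in isolation: a hit is accepted when its bit score `H_i`
clears its family's curated gathering threshold `T_i`. That per-domain rule
ignores a strong biological signal — domain families co-occur on proteins in
highly non-random combinations. A kinase domain next to an SH2 domain is
expected; the same kinase next to a family never seen with it anywhere is
suspicious. `dpucr` turns that co-occurrence signal into pairwise "context"
scores and selects, per protein, the subset of candidate hits that maximizes
a joint score, so weak-but-expected domains can be rescued and
strong-but-implausible combinations rejected.

## The score model

From a corpus of domain architectures (each protein's ordered family list,
repeats included), architectures seen in only one sequence are discarded as
likely annotation errors. For a multidomain protein `p` with `e_ip` domains
of family `i` and `e_p` domains in total, normalized pair counts are

* `c_ij += e_ip * e_jp / (e_p - 1)` for `i != j`, and
* `c_ii += e_ip * (e_ip - 1) / (e_p - 1)` for repeats of one family.

Single-domain proteins contribute nothing (the denominator would be zero).
The `1/(e_p - 1)` normalization compensates for proteins with many domains:
each protein contributes exactly `e_p` counts over all ordered pairs, and a
domain never pairs with itself. Both properties are asserted in the unit
tests. Counts become probabilities with a pseudocount spread uniformly over
the `n^2` ordered family pairs,

```
p_ij = (c_ij + alpha / n^2) / (c + alpha),     c = sum over ordered pairs,
```

which sums to one by construction. Against the uniform null `q_ij = 1/n^2`
(random hits under permissive E-value cutoffs land roughly uniformly over
families), the context score is the log-odds `s_ij = log_b(p_ij / q_ij)`
with `b = 2`, so context and HMM scores share the bit scale. Two
regularizations follow from the formulas: every never-observed pair gets the
same closed-form penalty `-log_b(1 + c/alpha)`, and observed pairs whose raw
log-odds are negative are floored at zero — observed pairs are never
penalized. With the defaults `alpha = 1`, `b = 2`; `alpha` controls how harsh
the unobserved penalty is and is the single most influential tuning knob.

## Selection as exact combinatorial optimization

For one protein, let `P` be the candidate pool (every hit with domain
E-value at most 1, by default). For a subset `D` the context-adjusted score
of member `i` is

```
S_{i,D} = (H_i - T_i) + sum over j in D, j != i, non-overlapping with i, of C_ij
```

and the chosen `D` maximizes the total score subject to two constraints:
every overlapping pair in `D` must be a curated allowed (nesting) overlap,
and every member must satisfy `S_{i,D} >= 0` — the per-family threshold
test, generalized so context can make up a deficit. With all `C_ij = 0` the
whole machinery collapses to the standard gathering-threshold filter, a
reduction the test suite checks on a hundred simulated fixtures.

Two details deserve note:

* **Edge counting.** Summing `S_{i,D}` over members counts each context
  edge twice; the equivalent graph view (nodes weighted `H_i - T_i`, edges
  weighted `C_ij` between non-overlapping candidates) counts each edge
  once. The two objectives can disagree about the argmax. `dpucr` uses
  edge-once as the default (`objective_mode = "edge_once"`), matching the
  graph formulation; edge-twice is available as a mode. The per-domain
  feasibility test always uses the single-counted `S_{i,D}`.
* **Overlaps carry no context.** Context edges exist only between
  non-overlapping selected pairs; an allowed nested pair coexists but
  contributes no context term.

The maximization is solved exactly by a depth-first branch-and-bound over
candidates in canonical order: the include branch is explored first (which
makes the first incumbent at a given score the deterministic tie-break),
a branch is cut when its optimistic total — current score plus each
undecided candidate's best case of forced edges to chosen members and all
positive edges to remaining candidates — cannot beat the incumbent, and a
chosen member that cannot reach `S_{i,D} >= 0` even with every remaining
positive edge kills its branch. A preprocessor removes candidates whose
normalized score plus all positive context available to them is still
negative; they can never be feasible, so the optimum is unchanged. Candidate
pools per protein are small (rarely above a dozen), so exhaustive-quality
search is cheap; correctness is certified against an independent brute-force
enumerator on hundreds of randomized instances with mixed positive and
negative context, overlaps, and nesting. A per-domain slack of `1e-9` bits
absorbs floating-point noise in the threshold test.

## Baselines and context filters

For comparison curves the package ships the standard gathering-threshold
filter, the same filter with all thresholds shifted by a constant, a plain
E-value filter, and two CODD-style filters. CODD promotes a sub-threshold
candidate (in ascending E-value order) when it has positive context with a
trusted domain and no disallowed overlap with the growing prediction set —
so weak domains can never rescue each other, which is the behavioral gap the
optimizer closes. nCODD adds a negative pass, removing members that form
never-observed pairs with stronger members; the published rule is not
available in detail, so the implementation here documents its own variant
(iterative removal of the weakest offender among non-overlapping pairs,
which is where context is defined) and should not be treated as
byte-compatible with the original. The greedy overlap resolution inside the
standard filter (descending normalized score, then canonical hit order) is
likewise this package's documented choice; ascending E-value is available.

## The two benchmarks

**Estimated FDR.** Real sequences are shuffled residue-by-residue
(composition and length preserved) and each real sequence is concatenated to
its shuffled copy; context methods are run on the concatenation as one
protein, so real domains can wrongly reward noise. With `R` predictions per
real protein and `A` predictions per shuffled portion (averaged over 20
shuffle replicates before averaging over proteins), `FDR = mean(A)/mean(R)`.
A hit spanning the junction is attributed to the shuffled portion when more
than half of its envelope lies past it; this majority rule is the package's
documented, configurable choice (strict containment is the alternative). The FDR of only the newly added domains is
`(A - A_n)/(R - R_n)`, where the `_n` quantities come from a negative-only
run: the difference isolates the domains that positive context added.

**Ortholog coherence.** Predictions are mapped through each protein's row
of its ortholog group's multiple alignment (gap columns skipped); a domain's
score is the fraction of the other group members carrying a same-family
prediction overlapping it by at least one column, and a method's score is
the unweighted mean over all predicted domain instances. Groups larger than
13 members are excluded (large paralogous families would dominate);
in-paralogs count in the denominator like orthologs. No minimum overlap
fraction is imposed beyond one shared column.

## What the synthetic generator does and does not emulate

`sim_spec()` fixes the study conditions: 50 families, 500 corpus proteins,
10 planted family pairs co-occurring at weight 10 over a uniform background,
architecture lengths 1-4 (probabilities 0.25/0.35/0.25/0.15), a 5% repeat
rate, true-domain score offsets `N(3, 3)` bits around the family threshold
(so roughly a sixth of true domains are sub-threshold and need rescuing),
decoys at 0.003 per residue scoring 0.5-8 bits below threshold, and every
distinct architecture emitted at least twice so the corpus survives
architecture filtering. Scores are drawn directly in bit space relative to
the thresholds: the selection machinery consumes scores, not sequences, so
no HMM emission model is simulated. Sequence content appears only where the
benchmark needs it — i.i.d. residues for the shuffling test, jittered
alignment rows for the coherence test. Consequently, passing tests
demonstrate the algebra and the selection behavior under planted context;
they say nothing about HMMER score calibration, compositional bias, or real
evolutionary divergence, which only a live profile-HMM search against a real
proteome can exercise.

Test problem sizes are deliberately modest — the oracle-equivalence suite
runs 500 random instances of up to 15 candidates, the reduction check 100
fixtures of 40 proteins, the recovery experiment one default-sized corpus —
chosen so the whole battery stays fast while each property still has room to
fail.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive envelope coordinates throughout; any
  shared residue counts as overlap (no tolerance).
* Allowed overlaps are an unordered family-pair relation; no directionality
  (which family nests inside which) is modeled.
* Scores serialize at 17 significant digits and the network reader parses
  with strtod, so write/read round-trips are bit-exact.
* An empty candidate set, an empty corpus, a singleton ortholog group, and
  an FDR with zero real predictions all raise typed conditions rather than
  returning silent zeros.
* The optional per-family sequence-threshold hook in the selection problem
  defaults to off; per-domain gathering thresholds are the only score gate.

## Known limitations

* The context network is symmetric; domain order along the protein carries
  no information in this model.
* The nCODD variant and the junction-attribution rule are this package's
  documented choices where the original procedures are underspecified.
* The published CODD network (no self-pairs, hypergeometric-filtered) is
  approximated by flags on `positive_pair_set()`; the exact published
  p-value cutoff is unknown and left configurable.
* Genome-scale behavior (real Pfam/UniProt corpora, millions of hits) is out
  of scope here; the per-protein solver is exact but written in R, and very
  large candidate pools (hundreds of hits on one protein) would need the
  elimination preprocessor to bite before search is practical.
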