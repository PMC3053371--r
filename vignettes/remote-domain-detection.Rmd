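---
title: "Detecting remotely conserved protein domains: model, scoring and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting remotely conserved protein domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remotethread)
```

## The problem

Profile-based domain searches lose power in the twilight zone of sequence
similarity: a genuinely homologous domain can score with an E-value of 1
or 10 — far beyond any defensible significance cutoff — simply because its
sequence has drifted while its three-dimensional fold has not.
`remotethread` implements a two-stage strategy for recovering such
domains at proteome scale:

1. **Relaxed profile search.** Every protein is searched against a
   profile database with a deliberately permissive reporting ceiling
   (E ≤ 50). Hits below E = 1e-04 are accepted outright.
2. **Fold-recognition confirmation.** Every weaker hit whose domain
   family has at least one known structure is masked, excised and
   threaded against a structure library. The resulting Z-score ranking
   is scored with a combined statistic (below); only hits whose expected
   structures are significantly over-represented at the top of the
   ranking survive.
3. **Cross-species validation.** Hits above E = 0.1 are additionally
   re-detected (at E ≤ 100) and re-scored in orthologs from up to three
   related species, and their essential consensus residues are checked
   under BLOSUM62. Two confirming species is the default operating
   point; a 25% identity-plus-similarity fraction over flagged residues
   is required for the residue check.

## The combined fold-recognition statistic

For one query region threaded against a library of `N` structures, with
`m` structures mapped to the expected domain family, the top `n` ranked
structures (the *top window*, 0.5% of the library, an absolute 60 at the
full SCOP-1.71 scale of 12,430 domains) are inspected. With `k` expected
structures inside the window and `z*` the best of their Z-scores, the
score combines

- `p_cdf`: the upper-tail probability of `z*` under an empirical
  background CDF of Z-scores pooled from threading runs of random
  proteins, with the pseudocount convention
  `p(z) = (#background ≥ z + 1)/(n_bg + 1)` so that probabilities are
  never zero; and
- `p_hyper`: the exact hypergeometric tail `P(X ≥ k)` for
  `X ~ Hypergeometric(N, m, n)` — the probability of seeing that many
  expected structures in the window by chance given the family's
  representation in the library.

The default combination is the plain product
`p_combined = p_cdf × p_hyper` (Fisher's method is available as an
alternative strategy via `combine_pvalues()`); a domain is accepted when
`p_combined ≤ 0.001` and `k ≥ 1`. The product is the simplest rule
consistent with the method's published description; the original
combination formula is not stated in reproducible form, so the rule is
exposed as a configurable strategy rather than asserted as the original
implementation.

Two properties of this statistic are worth stating honestly:

- Under a uniform null (expected structures placed randomly in the
  ranking) the chance acceptance rate is approximately `m·n/N`, because
  once an expected structure lands in the window its Z-score is
  top-of-library by construction and the product clears 0.001. For a
  single mapped structure at full scale this is 60/12430 ≈ 0.48% — just
  inside the nominal 0.5% envelope, which is how the discrete window was
  chosen — and it scales linearly with `m`. The per-domain error is
  therefore controlled at roughly half a percent per mapped structure,
  not globally; the published pipeline accepts this and leans on
  cross-species validation to prune the survivors.
- The hypergeometric factor down-weights frequent folds (a family
  holding 30% of the library sitting at its chance share of the window
  has `p_hyper ≈ 0.5` and is rejected), but a frequent fold carried by a
  genuinely extreme Z-score can still pass through the product. The
  test suite probes the chance-level configuration.

## The decision table

Each reported hit is assigned exactly one tier:

| E-value band      | structure mapped | fold accepted | validation level | tier |
|-------------------|------------------|---------------|------------------|------|
| E < 1e-04         | (ignored)        | (not run)     | (not run)        | `significant` |
| E ≥ 1e-04         | no               | —             | —                | `rejected` |
| E ≥ 1e-04         | yes              | no            | —                | `rejected` |
| 1e-04 ≤ E < 0.1   | yes              | yes           | —                | `confirmed_weak` |
| E ≥ 0.1           | yes              | yes           | ≥ 2 (default)    | `remote_validated` |
| E ≥ 0.1           | yes              | yes           | < 2              | `remote_unvalidated` |

Proteins with no ortholog data are reported `remote_unvalidated` with a
`no-data` marker rather than dropped. Profiles shorter than 50 match
positions carry a short-domain flag, since very short domains are the
dominant source of false identifications.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `report_threshold` | 50 | E-value reporting ceiling of the relaxed search |
| `significant_threshold` | 1e-04 | accept without threading below this |
| `weak_threshold` | 0.1 | require cross-species validation at/above this |
| `ortholog_threshold` | 100 | E-value ceiling for the ortholog re-search |
| `alpha` | 0.001 | combined-p acceptance threshold |
| `window_fraction` / `window_floor` | 0.005 / 60 | top-window rule (`top_window()`) |
| `required_level` | 2 | species needed to call a weak hit validated |
| `overlap_mode` | `all_overlapping` | benchmark mode; `top_hit_only` is the genome mode |

All thresholds live in `search_config()` so a run is reproducible from
its configuration alone.

## Engines: what is surrogate and what is not

The package's contribution is the scoring and decision layer. Both
engines underneath it are deliberately simple, documented surrogates
behind pluggable contracts:

- **Profile search**: glocal dynamic programming (global in the
  profile, local in the sequence) over per-position log-odds scores with
  linear gap costs (2.5 bits), no insert-state emission priors. Bit
  scores are converted to E-values through a per-profile extreme-value
  (Gumbel) calibration fitted by moments on scores against random
  sequences: `E = D·exp(−λ(S−μ))`. The Monte-Carlo property
  `P(E ≤ e) ≈ e` for random queries against a single profile is part of
  the test suite.
- **Threading**: a gapped local alignment (BLOSUM62, affine gaps 11/1)
  of the query against each structure's reference sequence,
  length-normalized and standardized per query over the library. It
  stands in for a structure-based energy function; it reproduces the
  *statistical shape* of fold recognition (a total Z-ranking with rare
  extreme hits), not any particular program's numbers. A real threading
  program can replace it by supplying any function
  `(query, library) → raw scores`.

**Effective database size.** E-values scale with the number of profiles
searched, and the published thresholds are calibrated to a full domain
database of thousands of families. A compact synthetic database searched
"as is" would make E ≤ 50 trivially satisfiable by noise. Profile
databases therefore carry an `effective_size` attribute (the generators
set 10,000) used for E-value scaling, so the thresholds keep their
full-scale meaning. This is a deliberate modelling choice, stated here
because every synthetic E-value in the package depends on it.

## The synthetic study conditions

`fixture_spec()` defaults define the reference conditions every
system-level test runs under; they were fixed once, by design analysis,
before the tests were written:

- 10 domain families, consensus length 60–90, profiles built from
  near members (consensus plus three members at each divergence ≤ 0.1)
  with Dirichlet pseudocounts;
- 2 structures per family (near-consensus references at 5% divergence)
  in a 1000-structure library of random decoys — top window 5;
- 30 proteins, half carrying an exact (divergence 0) planted member,
  half an engineered remote member; random flanks of 40–80 residues;
- remote members tuned by bisection into the E-value band (0.2, 10)
  against the database they will be searched with — the band the
  published worked examples occupy (E ≈ 11 and 6.9) — and verified in
  their assembled protein context (envelope covering ≥ 60% of the
  plant), since at remote-band divergences the profile signal sits at
  noise level and an unverified envelope can land on a flank;
- substitutions are BLOSUM-conditioned (replacement probability
  ∝ exp(B62/2)), so remote members stay fold-detectable — the premise
  that structure outlasts sequence, encoded in the generator;
- orthologs: the whole protein re-diverged at rate 0.02 in three
  species. The rate is deliberately modest: an ortholog of a
  boundary-E remote domain must itself stay within the E ≤ 100
  re-search ceiling, and with the surrogate's Gumbel slope a 2%
  whole-protein drift multiplies a band-top E of 10 by roughly a
  factor of 5–10, keeping re-detection reliable — mirroring the close
  validation species the method was designed around;
- background Z model: standard normal, 1e5 draws (≥ 10,000 required by
  `build_cdf()`).

What the generator does *not* emulate: real secondary structure (the
PSIPred hook is a pass-through), indels (members are substitution-only),
compositional bias interacting with masking, clan structure in the
default bundle, and real threading energetics. Passing the end-to-end
tests therefore demonstrates the statistical machinery is correct under
the stated model, not that real-data performance matches the published
benchmark figures — those require the original profile releases,
structure libraries and proteomes.

## Numerical choices and degenerate inputs

- Hit ordering is total and deterministic: E-value, then accession,
  then envelope start. Threading ties break by structure id.
- Overlap resolution is greedy by ascending E-value; the default
  tolerance is zero shared residues.
- A constant raw-score vector across the library (e.g. an all-X query)
  standardizes to all-zero Z-scores rather than dividing by zero.
- `p_cdf` uses the best expected Z *inside* the window; when no
  expected structure reaches the window the score is 1 and the hit
  cannot be accepted (`k ≥ 1` is part of the acceptance rule).
- Calibration refuses degenerate (zero-variance) score distributions;
  length-1 profiles calibrate normally (their score distribution over
  random sequences is non-degenerate).
- Report coordinates are 1-based inclusive; internal coordinates are
  0-based half-open; both conventions are stated in file headers.
- The truth-set ratio rule reads "greater than or equal to 10-fold"
  (`strict = TRUE` gives the strictly-greater variant).
- Benchmark percentages round half-up to integers for parity with
  printed tables; undefined metrics (zero denominators) are `NA`,
  never 0.
- FNR is computed as FN/(TP+FN) and FPR as FP/(FP+TN); these are the
  only formulas that reproduce the published comparison table from its
  own counts.

## Scaled-down problem sizes

System-level checks run at desk scale by design: a 1000-structure
library (window 5) instead of 12,430 (window 60), 10 families instead of
thousands, 30 proteins instead of a proteome, and a 6-family benchmark
fixture. The chance-acceptance null is the exception — it runs at the
full 12,430/60 operating dimensions, because the 0.5% envelope is a
property of that discrete geometry. The published absolute benchmark
counts are *not* reproduced (they require the original Pfam releases,
SCOP/ASTRAL and the 2007 human RefSeq proteome); the metric layer is
instead verified against the printed counts directly, and the framework
against engineered fixtures with exactly known truth.

## A worked example

```{r example, eval = FALSE}
library(remotethread)

bundle <- gen_fixture_bundle(fixture_spec(seed = 1))
res <- run_proteome(
  bundle$proteome,
  pipeline_resources(bundle$profiles, bundle$library, bundle$map,
                     bundle$cdf, orthologs = bundle$orthologs,
                     ortholog_seqs = bundle$ortholog_seqs,
                     essentials = bundle$essentials))
res$summary
dplyr::count(res$calls, tier)
```

## Known limitations

- The surrogate threader is sequence-based; truly analogous folds with
  no sequence signal are invisible to it, unlike to a physical
  threading engine.
- The search engine reports one (best) match per sequence-profile pair;
  repeat proteins with multiple copies of one domain yield one call.
- The product combination is a documented default, not a claim about
  the original implementation's formula.
- Acceptance is not multiplicity-corrected across a proteome; the
  fixed 0.001 threshold is applied per domain, as published.
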