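---
title: "Noise management for MS/MS spectra and its effect on molecular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise management for MS/MS spectra and its effect on molecular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
```

```{r setup}
library(specdenoise)
```

## The problem

A tandem-MS fragmentation spectrum mixes two populations of ions: fragments
generated by the molecule, and background ions from electronic noise and
chemical interference. Similarity scoring — the basis of spectral-library
annotation and molecular networking — is surprisingly sensitive to the
background: the modified-cosine (GNPS) score normalizes each spectrum by its
full intensity vector, so every unmatched background ion inflates the
denominator and drags the score of two spectra of the *same* compound well
below 1. Conversely, random coincidences between background ions create weak
spurious similarities between unrelated compounds. Denoising must therefore
balance two failure modes: too little, and homologous spectra fail to match;
too much, and genuinely informative low-intensity fragments are destroyed
while distinct compounds collapse onto each other in the network.

`specdenoise` implements three denoising procedures, the GNPS-style score
that measures their effect, minimum-spanning-tree (MST) diagnostics that
quantify network structure, and a data-dependent workflow to choose a cutoff.

## The tailored robust-linear-model filter

The filter rests on a structural assumption: background intensities are
roughly uniformly distributed, so if the $N$ ions of one spectrum are sorted
by increasing intensity, the background forms an approximately straight ramp
against rank, while true fragments are more intense and veer away from the
line. `tailored_denoise()`:

1. sorts peaks by increasing intensity (intensity ties broken by ascending
   m/z, so the ordering is deterministic);
2. fits a robust linear model (Huber M-estimation, tuning constant 1.345,
   via `MASS::rlm`) of intensity against rank over the lowest 75 % of ranks
   (`ceiling(0.75 N)`);
3. takes the standard deviation of the fit residuals over the fitted subset;
4. draws the upper boundary 3 SD above the trend line;
5. finds the ions that exceed their boundary value. If none do, the spectrum
   is kept unchanged. Otherwise the intensity threshold is the *minimum*
   intensity among the exceeding ions, and every ion at or above it is kept.

Step 5 deserves a note. Phrased as a rule about "the last-ranked ion
exceeding the boundary", the literal last exceeding ion under an increasing
ordering would be the most intense one — a reading that would discard nearly
the entire spectrum. The only reading consistent with the purpose of the
filter (keep the high-intensity tail that breaks from the background ramp)
is to cut at the *least intense* boundary-exceeding ion, which is what the
default `cut_rule = "min_exceeding"` does; the alternative is kept behind
`cut_rule = "last_exceeding"` for comparison. Two further conventions are
config-exposed because the procedure leaves them open: the residual SD is
computed over the fitted 75 % subset (residuals of a robust fit are defined
where it was fitted; `sd_all = TRUE` uses all ranks), and the M-estimator
flavor defaults to Huber (`psi` sets the constant). If the robust fit fails
to converge — e.g. on degenerate, exactly-collinear data where the scale
estimate vanishes — the filter falls back to ordinary least squares with a
warning, which on such data gives the identical line.

The whole construction uses only ranks and intensity ratios, so the filter
is invariant to uniform intensity rescaling, and a spectrum whose ions all
share one intensity passes through untouched.

```{r tailored-example}
lib <- generate_library(synth_config(seed = 42))
r <- tailored_denoise(lib[[1]])
r
plot(r)
```

## Percentage cutoff and consensus

`percent_cutoff_denoise(s, pct)` removes every ion strictly below
`pct * base peak`; an ion exactly at the threshold survives, and `pct = 0`
is the identity. Keep-sets are nested as `pct` grows, which makes sweep
diagnostics monotone by construction where only unmatched ions are removed.

`consensus_spectrum()` merges at least three replicate scans of one
compound: peaks are pooled, grouped by single-linkage on sorted m/z with a
0.01 Da tolerance (the same tolerance the similarity score uses; the choice
is a convention, not an estimate), and groups present in at least 70 % of
the scans survive. Consensus m/z is the intensity-weighted group mean,
consensus intensity the plain mean over member peaks. The method needs
replicates — it cannot be applied to one-spectrum-per-compound libraries,
which is why the cutoff sweep below is the tool of choice there.

## GNPS similarity with neutral-loss matching

`gnps_score()` square-root transforms intensities, scales each spectrum's
transformed vector to unit Euclidean norm, and enumerates candidate peak
pairs of two kinds within a 0.01 Da tolerance: *direct* (`|mzA - mzB| <=
tol`) and *shifted* (`|(mzA - mzB) - (precA - precB)| <= tol`, i.e. the two
fragments differ by the same neutral loss as the precursors). A pair
qualifying both ways counts once. A one-to-one assignment is then chosen
greedily by descending pair weight (the product of the two scaled
intensities), ties broken by ascending m/z so the score is symmetric in its
arguments; the score is the clamped sum of assigned weights. The greedy
assignment mirrors the reference scoring implementations; an exact
branch-and-bound assignment is available via `assignment = "optimal"` and
the test suite verifies the greedy score never exceeds it and almost always
attains it. The square-root transform is likewise a convention of the
reference implementations and can be disabled (`transform = "raw"`).

Two consequences matter for everything downstream. First,
`score(s, s) = 1` exactly. Second, adding ions to one spectrum that match
nothing in the other *strictly* lowers the score, because they enter only
the normalization. That is the entire mechanism by which background ions
corrupt similarity, and `noise_injection_experiment()` measures it directly:
spectra with few fragments degrade fastest, since their score rests on fewer
matched peaks.

```{r injection}
clean <- spectrum(seq(80, 300, length.out = 12), rep(10, 12),
                  precursor_mz = 340, id = "clean12")
ni <- noise_injection_experiment(clean, noise_injection_config(seed = 1))
plot(ni)
```

## Networks, the MST and M(d_5%)

`similarity_matrix()` scores all pairs (one ionization mode at a time);
`network_edges()` applies zero-thresholding by default, keeping every
strictly positive similarity. For structure diagnostics, `mst()` converts
similarities to distances $d = 1 - s$ on the *complete* graph — the tree
must span all spectra, including zero-similarity pairs at distance 1 — and
runs Kruskal's algorithm with lexicographic tie-breaking on the id pair, so
results are reproducible under relabeling (the sorted distance multiset is
unique regardless of tie order; the test suite checks both this and
agreement with exhaustive spanning-tree enumeration).

The sorted MST distances summarize network shape. Their low end is the
sensitive part: as denoising tightens genuinely related spectra, low
distances shrink; when distinct compounds become indistinguishable
(similarity exactly 1) distances hit zero and topological information is
destroyed. `compute_m_d5()` condenses this into $M(d_{5\%})$: the median of
the `ceiling(0.05 (n-1))` smallest tree distances (midpoint convention for
even counts — the subset size and median convention are our conventions, as
is the `1e-12` tolerance for counting "exact" zeros, which absorbs
floating-point residue from scores clamped at 1). $M(d_{5\%})
\rightarrow 0$ means 5 % of the network has collapsed.

## The data-dependent cutoff workflow

`cutoff_sweep()` evaluates a grid of percentage cutoffs (default 0–10 % in
steps of 0.25 %, a 41-point grid; the grid resolution is our choice) and
records, per cutoff: the pooled fraction of structurally explained ions
removed (ion-weighted pooling over all spectra, not per-spectrum averaging),
$M(d_{5\%})$, and the zero-distance count. Explained-ion flags are an
input — typically exported from a fragmentation-tree tool — or ground truth
in simulation. `optimal_cutoff()` then normalizes $M(d_{5\%})$ by its value
at cutoff 0, so both curves live in $[0,1]$ (one falling from 1, one rising
from 0), and returns the grid point with the smallest absolute gap between
the curves — the nearest-to-intersection cutoff, ties to the smaller value.
The two quantities have no canonical common scale; normalizing by the
cutoff-0 value is one defensible choice and `normalize = "minmax"` is
provided as the alternative. The tailored filter is evaluated once alongside
the sweep, and its (explained-removed, $M(d_{5\%})$) operating point can be
compared with the fixed-cutoff curve directly.

```{r sweep, eval = FALSE}
lib1 <- generate_library(synth_config(n_compounds = 40, family_count = 8,
                                      replicate_count = 1, seed = 42))
sw <- cutoff_sweep(lib1)
plot(sw)
optimal_cutoff(sw)
```

(The sweep rebuilds a 40-spectrum similarity matrix 41 times and takes
around 15 s; it is not evaluated when the vignette is built.)

## What the synthetic generator emulates — and what it does not

`generate_library()` provides ground truth for every mechanism above. Its
model, with the reasoning behind each default:

* **Background**: each spectrum carries 40–90 background ions with
  intensities uniform on $(0, 0.015]$ of the base peak. Uniformity is the
  structural assumption of the tailored filter. The 1.5 % ceiling encodes a
  background one to two orders of magnitude below the base peak — on data
  whose optimal cutoff workflow lands in the 1–2 % range — and deliberately
  sits inside the 0–10 % sweep window so the sweep crosses the entire
  background band early. Background m/z avoids a 0.01 Da neighbourhood
  around true peaks by default, so "background never matches" is exact in
  tests (`noise_overlap = TRUE` relaxes this for realism).
* **Families and core ions**: compounds belong to families that share their
  *dominant* fragments — a family "core" with the base peak at relative
  intensity 1 and the rest uniform on $[0.2, 1]$ — the way structural
  analogues share major scaffold ions. Because core ions sit above the 10 %
  sweep ceiling, the matched signal between family members is essentially
  constant across the sweep while their unmatched minor content shrinks;
  network tightening under increasing cutoffs is then a structural property
  of the model rather than an accident of one seed.
* **Compound-specific ions**: minor fragments, log-normal with median 6 %
  of base (sdlog 0.55). They are real signal (flagged `explained = TRUE`)
  living inside the sweep range, which is exactly what makes aggressive
  cutoffs costly: about 40 % of explained ions are gone by a 10 % cutoff,
  and roughly half of that already at 5 %.
* **Replicates**: homologous scans of one compound share its fragment set
  with multiplicative log-normal intensity scatter (CV 15 %) and Gaussian
  m/z jitter (SD 0.002 Da) — invented instrumental-variability magnitudes,
  documented as such — plus freshly drawn background per scan, so consensus
  building and homologous-pair scoring behave realistically. Defaults are
  50 compounds in 10 families with 4 replicates (200 spectra).

What the generator does **not** emulate: physical fragmentation (no isotope
patterns, no bond-energy structure, no correlated fragment intensities
between family members' core ions beyond sharing the profile), m/z-dependent
noise density, detector saturation, or chimeric precursor contamination.
Background is strictly bounded at its ceiling, whereas real spectra have a
continuum of interference intensities. Passing tests on this benchmark
therefore demonstrate that the algorithms do what they claim *under the
model's assumptions* — uniform background below clearly separated fragments
— not that any particular instrument's spectra satisfy those assumptions;
the intensity-rank plot (`plot()` on a tailored result) is the practical
check to run per instrumental setup.

Benchmark problem sizes used by the test suite and acceptance script — 200
spectra for filter-recovery and homologous-pair statistics, a 40-compound
single-replicate library for the 41-point sweep, 100 noise-injection
simulations per step — keep every experiment deterministic under one seed
while exercising the full pipeline.

## Numerical conventions and degenerate inputs

* All curation bounds are strict, matching their phrasing: entropy "below
  3", "more than 20" / "fewer than 1000" ions, explained ratio "less than
  0.75". `spectral_entropy()` uses natural log on raw normalized
  intensities, the standard spectral-entropy definition.
* Duplicate m/z within one spectrum are merged on construction by summing
  intensity (logged), keeping "strictly increasing m/z" a hard invariant.
* Polarity on MGF import: an explicit ion-mode field wins, else the sign of
  `CHARGE`, else an error — dialects vary too much to guess.
* Spectra with fewer than 4 peaks skip the tailored filter (a robust line
  through 3 points is meaningless) and are returned unchanged with a
  warning.
* Empty spectra score 0 with a warning; `mst()` requires at least 2 nodes;
  `optimal_cutoff()` refuses a network already collapsed at cutoff 0.

## Limitations

The tailored filter assumes the intensity-rank ramp; spectra dominated by
chemical interference with structured intensity, or heavily pre-filtered
spectra, violate it. The greedy assignment can in principle fall below the
optimal matching (bounded above by it; equality in the overwhelming majority
of random cases). $M(d_{5\%})$ on small networks rests on very few tree
edges and is correspondingly grainy. The optimal-cutoff workflow needs
explained-ion annotations, which require external fragmentation-tree
processing of known or putatively annotated compounds; the tailored filter
is the single-spectrum alternative precisely because it needs no reference
material.
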