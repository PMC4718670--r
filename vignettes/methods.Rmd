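---
title: "Methods: peak detection, deisotoping and alignment in lcmsquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak detection, deisotoping and alignment in lcmsquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmsquant)
```

`lcmsquant` quantifies label-free LC-MS1 metabolomics data. This vignette
is the package's account of the algorithms it implements, the parameters
that matter, the design decisions taken where more than one reading was
defensible, and what the bundled simulator does and does not establish
about real data.

## Data model

A run is a tibble of centroided signal points (`scan_index`, `rt` in
minutes, `mz` in Th, `intensity` in counts) with per-scan metadata as
attributes. Scans are strictly ordered by retention time. All downstream
objects are tibbles too: peak lists carry one row per EIC with a `trace`
list-column of the integrated points; aligned features carry a
`constituents` list-column with one row per contributing replicate peak.
Retention time is minutes everywhere internally; readers convert the
seconds that mzML files store.

## Preprocessing

**Centroiding** (profile data only) splits each scan into contiguous
above-zero m/z regions, cuts regions that contain several local maxima at
their interior strict local minima (the minimum point opens the next
sub-region), and emits one signal per sub-region with the
intensity-weighted mean m/z. The centroid intensity is the region's
*maximum*, not its sum: chromatographic FWHM and peak-shape similarity
both operate on apex-height traces, and the maximum makes centroid-mode
and profile-mode runs of the same sample yield the same EIC heights.
Regions are additionally cut at m/z gaps wider than `mzWidth`, which
delimits profile islands in files that omit explicit zero-intensity
points. Files that declare centroid mode skip this step; when the
declaration is missing, a density heuristic calls a scan profile if it
carries runs of ≥ 5 contiguous above-zero points whose median spacing is
below `mzWidth`/4.

**Noise removal** divides each scan's m/z range into `n_segments` (default
10) equal-width windows, widens every window so that neighbours overlap by
20 % of their width, and uses the arithmetic mean intensity inside the
widened window as its noise level *N*. A signal survives if its intensity
reaches `snr_threshold` (default 3) times *N* in at least one window
containing it — a borderline signal sitting in two windows gets the
friendlier verdict, which is what the overlap is for. Two consequences are
worth knowing. First, the mean includes the candidate signal itself, so in
very sparse scans a lone intense signal is its own noise estimate and is
removed; the rule presumes realistically dense scans (hundreds of signals).
Second, a very tall peak raises the mean of its own window and can
suppress a faint co-window neighbour; this is intrinsic to the
segment-mean definition and is the reason the filter is applied once, not
iterated. Windows holding no signal impose no verdict. The filter is not
idempotent in general, and the pipeline applies it exactly once per scan.

## EIC construction with dynamic peak width

Detection iterates two stages until every signal is consumed:

1. **Clustering.** The globally most intense unclustered signal seeds a
   cluster; all unclustered signals within `mzWidth` of the seed join it,
   at most one per scan (the closest in m/z — an EIC has one intensity per
   time point). Clusters with fewer than 3 signals are consumed and
   discarded. Ties on intensity break by lowest scan index, then lowest
   m/z, making the whole procedure deterministic.
2. **Boundary determination.** With apex intensity *I* at time *t*, the
   FWHM *w* is the distance between the two RTs where the trace crosses
   *I*/2, linearly interpolated between bracketing points; a side that
   never falls below *I*/2 uses its outermost point (fallback). Boundaries
   start at *t* ± *w* and each side extends independently into
   (*t* + *w*, *t* + 1.5 *w*] (mirrored left): the first strict
   local-minimum member scanning outward becomes the boundary, else the
   farthest member in the zone — the valley is preferred because a valley
   between two compounds is the physically meaningful cut. An empty zone
   keeps the outermost member within *t* ± *w*. Abundance is the
   trapezoidal area of the trace inside the boundaries
   (counts · minutes).

Members outside the final boundaries are *released* back to the pool, so
two compounds sharing an m/z but eluting apart are recovered on later
iterations; discarding sub-minimum clusters (rather than releasing them)
guarantees termination. Degenerate clusters spanning fewer than two
distinct RTs, and boundary-trimmed traces with fewer than two points, are
consumed without producing a peak.

## Charge state and isotope ratio

Processing peaks by descending apex intensity, each candidate monoisotope
is grouped with its neighbours at larger m/z, apex RT within
`rt_cooccurrence_tol`, and strictly decreasing apex intensity. For charge
hypotheses *z* = 4 down to 1, the chain is viable when consecutive m/z
gaps equal 1/*z* within `iso_mz_tol`; the highest viable *z* wins, because
the smaller spacing is the stricter pattern and a genuine z = 2 envelope
would otherwise be stolen by a coincidental 1 Th neighbour. The gap test
needs a tolerance — printed spacings are exact only in theory — and
defaults to the `mzWidth` clustering tolerance (0.02 Th). When several
peaks match one gap the nearest to the expected m/z is taken; chains are
capped at 5 isotopes.

The envelope is confirmed by the normalized dot product of the mono and
second-isotope trace intensities over their co-occurring scans (≥ 2 scans
required; threshold 0.8). Only the mono/second pair is shape-tested —
higher isotopes are kept in the group but not separately validated.
Confirmed monoisotopes receive charge *z* and isotope ratio
abundance(second)/abundance(mono), and all grouped followers are removed
from the report. A failed similarity leaves *every* peak in place with
charge 0 and ratio 0: the followers may be genuine compounds and stay
available for later grouping. No averagine-style envelope model is used —
validation is purely the observed co-elution shape.

## Alignment

The replicate with most peaks is the reference (ties: first in input
order). Landmarks are one-to-one matches within `mzTol` and `rtTol`,
assigned greedily in descending reference intensity with nearest-|ΔRT|
preference (|Δm/z| breaks ties). LOESS of the landmark offsets
(ref − target RT) on target RT — span 0.20, degree 1, tricube weights, no
robustness iterations — yields the correction; fitting offsets rather
than the raw RT map is numerically more stable and equally expressive.
Outside the landmark RT range the offset is clamped to the nearest fitted
value. Two numerical guards: with fewer than 4 landmarks the mapping falls
back to identity, and with 4–9 landmarks the span widens to min(1, 4/n) so
each local window holds enough points for a degree-1 fit; at the landmark
counts the package is designed for (≥ 100) the span is always 0.20.

Matching then re-runs on corrected RTs. Peaks unmatched to any existing
feature open a new feature, so a compound absent from the reference but
present in two other replicates still merges. Feature representatives used
*during* matching live on the reference RT scale, but constituent rows
keep their raw RTs, and all reported medians (m/z, RT) are computed over
raw values — reported numbers therefore do not depend on which replicate
happened to be the reference, and permuting replicate or sample order
changes nothing but internal bookkeeping. Medians over an even count are
the mean of the two central values. The same machinery aligns
representative peaks across samples.

## Reporting

Per feature and sample, the abundance is the median over the replicates in
which the feature was detected; absent replicates are excluded from the
median rather than imputed as zero (zero-imputation would bias the sample
median downward), and are rendered as 0 only in the exported table. The
reported charge is the modal charge over constituents, ties broken toward
the higher charge with 0 losing any tie; the reported isotope ratio is the
median over the constituents whose charge equals the reported one. Filters
(RT window, m/z window, minimum samples detected, charge, isotope-ratio
range) subset the summary and are idempotent.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `mzWidth` | 0.02 | Th | m/z clustering tolerance in EIC construction |
| `mzTol` | 0.02 | Th | m/z matching tolerance in alignment |
| `rtTol` | 0.2 | min | RT matching tolerance in alignment and isotope co-occurrence |
| `n_segments` | 10 | — | noise windows per scan |
| `snr_threshold` | 3 | — | minimum S/N to keep a signal |
| `similarity_threshold` | 0.8 | — | envelope confirmation threshold |
| `iso_mz_tol` | = `mzWidth` | Th | tolerance on the 1/z spacing |
| `loess_span` | 0.20 | fraction | LOESS locality |

The three tolerances are the only parameters a user must think about; they
mirror the instrument's mass accuracy and the chromatography's
reproducibility. The 0.02 Th / 0.2 min defaults suit high-resolution
Orbitrap-class data; wider chromatography or Q-TOF data may want 0.03 Th /
0.16 min.

## The simulator, and what passing tests show

`simulate_run()`/`simulate_experiment()` emulate: Gaussian elution
profiles sampled at a fixed scan rate; isotope envelopes at 1/*z* spacing
with a known second/mono abundance ratio (isotopes beyond the second decay
geometrically — a convenience, and nothing beyond the second ratio is ever
asserted); smooth monotone RT drift between replicates
(*t* + *A* sin(π *t*/*T*), |*A*| ≤ 0.2 min); a uniform noise floor of
scattered low-intensity signals (default 300 per scan — the density of a
real ESI MS1 scan matters because the S/N filter estimates noise from
window means); per-compound sample amounts; and log-normal replicate
variation. Elution traces are rendered to ± 3 σ of the apex: real centroid
data does not report signals orders of magnitude below the noise floor,
and a detection-limit cutoff is what instruments actually produce.
Profile mode renders each signal as a narrow m/z Gaussian with explicit
zero-intensity edge points.

The simulator does **not** emulate chemical noise structure, detector
saturation, vendor-specific centroiding artifacts, adducts, in-source
fragments, or peak-shape asymmetry (fronting/tailing beyond what the
boundary-extension rule is designed for). Tests passing on these fixtures
therefore establish the correctness of the algorithms under their stated
assumptions — Gaussian-ish shapes, drift within `rtTol` — not performance
on pathological real-world chromatography.

Validation problem sizes (also used by `scripts/acceptance.R`): 1,000
random traces for the integration oracle; σ ∈ {0.05, 0.1, 0.2} min at scan
interval σ/10 for FWHM; 40 envelopes (10 per charge 1–4) for charge
recovery; 200-peak replicate pairs with 0.12 min sinusoidal drift for
alignment; and a 2-sample × 3-replicate mixture with designed ratios
{0.2, 0.33, 0.5, 1.0} for end-to-end recovery. These sizes are chosen so
the full suite runs in well under a minute while leaving no algorithmic
branch unexercised.

## Known limitations

- No gap-filling: a compound undetected in a replicate is reported absent
  there, never re-extracted from the raw trace.
- Isotope-ratio accuracy degrades when the second isotope sits near the
  noise floor, where the S/N filter truncates its trace asymmetrically;
  the ratio is reported as computed, not corrected.
- The greedy one-to-one matcher can mispair peaks closer than the
  tolerances to two candidates; landmark-rich runs make this rare.
- netCDF input is not supported; convert to mzML/mzXML first.
- MS2 spectra are skipped, not used.
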