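---
title: "Growing virtual granule cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing virtual granule cells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendropop)
library(dplyr)
```

dendropop amplifies a small set of reconstructed dentate granule cells into a
large population of virtual neurons whose morphology is statistically
indistinguishable from the originals, and lays out the structural scaffold of
a full-scale dentate gyrus network around them. This vignette describes the
models and algorithms, the parameters that matter, and the design choices
made where the design was genuinely open.

## The pipeline

1. **Read** SWC reconstructions, correcting for anisotropic tissue shrinkage
   (1.06x in the transverse plane, 1.96x in depth).
2. **Measure**: decompose each tree into branches and extract the *basic*
   parameters consumed by the growth algorithm and the *emergent* whole-cell
   summaries used only for validation and filtering.
3. **Fit** each basic parameter with one of four distribution families
   (gamma, normal, uniform, constant).
4. **Generate** virtual trees with a recursive stochastic growth algorithm
   driven by those distributions.
5. **Filter** the generated population to cells whose ten emergent parameters
   all fall within windows around the reference statistics.
6. **Match**: resample the filtered pool so that total dendritic length,
   surface area and bifurcation count follow target truncated-Gaussian /
   Poisson distributions.

Validation is closed-loop: the two-sample Kolmogorov–Smirnov test compares
the basic-parameter distributions extracted from the generated population
against those of the reference set, parameter by parameter; the pipeline is
considered self-consistent when every directly drawn parameter's median
p-value across seeded runs exceeds 0.05.

## Branch decomposition and morphometry

A *branch* runs from the soma or a bifurcation node to the next bifurcation
node or tip, merging in-line continuation nodes, so a polyline of many SWC
segments counts as one branch. The segment from the anchor to the branch's
first own node belongs to the branch; the branch's initial diameter is read
at that first own node (an anchor node's diameter belongs to the parent
branch). Per branch we record kind (internal/terminal), centrifugal order,
path length, initial and final diameter, and taper rate (diameter lost per
micrometre of path).

Per bifurcation we record the amplitude between daughter initial directions,
the daughter diameter ratio (larger/smaller), and the Rall power: the
exponent $n$ solving $d_p^n = d_1^n + d_2^n$, found by bisection on
$[0.5, 5]$ (60 iterations, well below measurement noise). Bifurcations with
no solution in the bracket — e.g. a daughter at least as thick as its parent
— are recorded as `NA` with a warning and excluded from fitted
distributions. Trifurcations are counted as two bifurcations for counting
purposes but contribute no per-bifurcation geometry.

The ten emergent parameters are total dendritic length, bifurcation count,
surface area (sum of inter-node frusta, $\pi (r_1+r_2)\sqrt{h^2+(r_1-r_2)^2}$;
the soma is excluded, and the segment that attaches a stem to the soma uses
the stem node's own radius at both ends so the soma radius never leaks into
dendritic area), average path and average/maximum Euclidean distance from the
soma centre to the tips, maximum branch order, partition asymmetry,
and the transverse (xy) and longitudinal (z) spreads of the tips.

Partition asymmetry uses the van Pelt per-bifurcation form
$|l-r|/(l+r-2)$ on the daughter-subtree tip counts, averaged over
bifurcations, with the $(1,1)$ case defined as 0. Note that under this
convention a mean of exactly 1 is unattainable: every finite binary tree's
deepest bifurcation is $(1,1)$. A five-tip "caterpillar" therefore scores
$3/4$, not 1.

## The growth algorithm

Growth is Hillman-style and recursive. A soma of drawn diameter sits at the
origin; a drawn number of stems leave it with directions drawn uniformly on
the spherical cap within `stem_elevation_cone` (default 35 degrees) of +y —
granule cells are unipolar, pointing into the molecular layer. Each branch:

* draws a terminal-diameter threshold; the branch is **terminal** if its
  initial diameter is at or below the draw, or its order has reached
  `max_branch_order` (default 12, a hard recursion guard);
* draws its **total path length** from the terminal or internal length
  distribution accordingly, and grows as a straight polyline in
  `segment_step` (default 5 um) increments with linear taper;
* if internal, ends in a bifurcation: daughter diameters satisfy the drawn
  Rall power and diameter ratio at the parent's measured end diameter; the
  daughters are separated by the drawn amplitude in a bifurcation plane of
  uniform azimuth, the thicker daughter deviating less (deviation split in
  proportion to diameter share, equal on ties).

The generator is built so that **measured equals drawn** for every directly
drawn parameter: the first node of a branch carries the drawn initial
diameter exactly, path lengths are realised exactly, the amplitude separates
the daughter initial directions exactly, and the Rall relation holds at the
measured parent end diameter to machine precision. Terminal branches draw
their total path length in one piece rather than as an interbifurcation
segment plus a terminal segment; the two-segment construction and the
merged measurement would otherwise disagree, and collapsing them makes the
measured terminal length match its input by construction.

Numerical guards: taper draws that would push a branch's diameter below
0.01 um are redrawn (logged); after 100 redraws the taper is clamped to the
largest physical value, which only ever fires on near-degenerate branches.
Branches shorter than one segment step become single-node branches (their
measured taper is 0; with length distributions truncated at 5 um this has
negligible mass). Cell growth that fails outright is retried from a derived
retry seed, at most 5 times, with warnings.

Every cell draws from its own random stream seeded by a stable hash of
`(base_seed, "cell<i>")`, so a population is reproducible and independent of
chunking. Tropism (curvature toward a layer target) and parameter covariance
are deliberately not modelled.

## Fitting, and the termination threshold

Normal fits use sample moments, gamma fits the method of moments
(shape $= m^2/v$, scale $= v/m$), uniform the sample range, constant the
mean. Method-of-moments is deliberate: the fitted distributions seed a
generator whose output is then *measured again*, so moment fidelity is the
property that matters; an ML gamma fit is a drop-in replacement if wanted.

The termination threshold is the one basic parameter with no direct
observable. A branch is terminal exactly when its initial diameter $d_0$
fell at or below the cell's threshold draw, so terminal/internal status
given $d_0$ is Bernoulli with probability $1 - G(d_0)$, where $G$ is the
threshold CDF. dendropop therefore extracts the initial diameters of both
terminal and internal branches and fits the gamma threshold by maximum
likelihood on those outcomes (`fit_termination_threshold()`). A naive
moment fit to terminal initial diameters — which are censored from above —
biases the threshold low and makes generated trees systematically deeper
and thinner than the reference; the outcome-likelihood fit removes that
bias (on synthetic reference sets it recovers the true threshold mean to
within a percent).

## Filtering and matching

Filter windows are `mean +/- width * sd` per emergent parameter, with mean
and SD taken from the *reference* set, width 2.0 by default and 1.65 for
surface area (the 2 SD surface-area window would admit areas inconsistent
with the admitted lengths). Bounds are inclusive: a cell exactly at the
edge is kept, so ties never silently drop cells. Under normality these
windows retain more than 95% and 90% of the population respectively.

Matching selects `n_out` cells from the filtered pool by weighted sampling
without replacement with weights
$w_i = \prod_k \text{target}_k(x_{ik}) / \widehat{\text{pool}}_k(x_{ik})$
over the three matched parameters, assuming independence (covariance is out
of scope). Pool marginals are estimated by Freedman–Diaconis histograms
(continuous) or the empirical pmf (`n_bifurcations`). The fixed-size draw
uses systematic (Madow) sampling with inclusion probabilities
$\pi_i = n_{\text{out}} w_i / \sum w$: the expected number of selected cells
in any value band is then exactly target-proportional, which is what makes
the selected marginals KS-indistinguishable from their targets. (Successive
weighted draws — `sample(prob = w)` — lack this property at non-trivial
sampling fractions and were rejected.) Probabilities capped at 1 are
redistributed; if more than 1% of the requested mass needs capping the pool
cannot fully supply the targets and a warning says so. Targets with no pool
support in some decile band raise an error naming the band. Any scheme
whose output marginals match the stated targets would satisfy the
contract; this one was chosen for its exactness and determinism.

## The synthetic reference archetype

The in-vivo reconstruction set the pipeline was designed around is not
redistributable, so the fixtures module generates a synthetic stand-in with
known ground truth: the `granule_archetype()`. Its defaults emulate rat
dentate granule cells — 1–4 stems (uniform), stem diameters gamma around
2.6 um, soma 10.5 um, internal branch lengths gamma (mean 75 um, SD 35),
terminal branch lengths gamma (mean 150 um, SD 60, both truncated at 5 um),
bifurcation amplitudes normal (40 ± 10 degrees), Rall powers normal
(1.5 ± 0.12), diameter ratios uniform on [1, 1.6], taper gamma (mean
0.0012 um/um), termination threshold gamma (mean 0.85 um, SD 0.15). Under
these settings a typical cell has ~15 bifurcations, ~3,700 um of dendrite
and tip diameters around 0.4 um, in the range reported for mature granule
cells.

What the synthetic reference does *not* emulate: dendritic curvature
(branches are straight), parameter covariance, spines, layer-specific
tropism, and reconstruction artefacts (truncated tips, shrinkage residuals
beyond the global correction). Passing the closed-loop KS checks therefore
demonstrates that the pipeline's estimators and generator are mutually
consistent at realistic parameter values and sample sizes — not that any
particular biological archive would be matched equally well.

## Network scaffold

The scaffold module lays out the four numerically dominant cell types at
full scale — 1,000,000 granule, 30,000 mossy, 10,000 basket and 12,000 HIPP
cells — or at a divisor scale (1:20, 1:2000, custom), evenly spaced at bin
midpoints $x_i = (i+0.5)L/N$ along a configurable septotemporal axis
(default 6 mm; the length affects no counts). Midpoint placement makes
lamellar selections exact: the middle lamella is the central 10% of the
axis, and stimulating its leading tenth at full scale selects exactly
10,000 granule and 100 basket cells, while the whole middle lamella at 1:20
scale selects 5,000 and 50 — both consistent with a 10% lamella, which is
why that default was chosen. Mossy stimulation counts are protocol-explicit
(20 at full scale, 10 at 1:20) because the published percentages are not
derivable from the cell counts; the cells nearest the axis midpoint are
taken.

Injury marks a seeded uniform random fraction (default 80%) of mossy and
HIPP cells dead and flags mossy-fibre sprouting at the same severity; the
spatial structure of hilar loss is not modelled. Scale rules report the
published compensations: 5x connection probability at 1:20 (undefined and
an error at other reduced scales), 0.5 nS sprouted granule-granule peak
conductance, and granule-to-interneuron conductances divided by 2.
Connectivity instantiation itself takes user-supplied probability tables
and is out of scope here, as are membrane dynamics and spike simulation.

## Problem sizes used in the checks

The packaged checks run the closed loop at the sizes the workflow itself
uses: 19-cell reference sets, 10,000-cell generated populations, 20 seeded
repetitions for the KS self-consistency summary, filtering and matching
10,000 -> 1,000, and single-parameter filter coverage on $10^6$ draws.
Brute-force oracle comparisons use random trees of at most 30 nodes, where
exhaustive path enumeration is exact and fast.

## Worked example

```{r example, eval = FALSE}
arch <- granule_archetype()
refs <- make_reference_set(arch, n = 19, seed = 2012)

basic <- extract_basic(refs)
fitted <- fit_growth_params(basic, arch$kinds)

pop <- generate_population(fitted, n = 10000, base_seed = 42)
em <- extract_emergent(pop)

crit <- filter_criteria(extract_emergent(refs))
accepted <- filter_emergent(em, crit) |> dplyr::filter(accepted)

final <- match_target_distributions(
  accepted, target_distributions(crit),
  n_out = 1000, seed = 7
)
```

## Known limitations

* Straight branches: tortuosity and tropism are not modelled, so path and
  Euclidean tip distances are closer to each other than in real neurons.
* Basic parameters are drawn independently; covariance between them (e.g.
  thicker stems bearing longer branches) is not reproduced.
* The threshold estimator assumes the gamma family and a per-branch
  independent threshold draw — the same assumptions the generator makes.
* KS p-values for integer-valued parameters (`n_stems`) are tie-dominated
  and excluded from the self-consistency summary by default.
* The scaffold records structure only; it does not instantiate synapses or
  dynamics.
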