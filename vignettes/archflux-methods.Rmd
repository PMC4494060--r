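---
title: "Methods and design notes: replichore architecture and gene flux"
author: "archflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes: replichore architecture and gene flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archflux)
```

archflux analyzes small circular bacterial genomes of the kind found in
host-restricted symbionts — the motivating system is the honeybee symbiont
*Lactobacillus kunkeei* species complex, a ~1.5 Mb genome with strong
reductive evolution and an unusual functional chromosome organization. The
package covers five analyses that are usually scattered across ad hoc
scripts: replichore architecture from GC skew, positional bias of gene
functional categories, ancestral gene-content flux by generalized parsimony,
gene-tree congruence tallies, and a permutation screen for recombination.
Every analysis can be exercised end to end on synthetic data with planted
truth; this vignette explains the models, the tunable parameters, and the
design decisions that were genuinely open.

## Replichore architecture from GC skew

A circular bacterial chromosome is replicated bidirectionally from the origin
(*ori*) to the terminus (*ter*); the two halves are the replichores. The
leading strand accumulates a G-over-C excess, so the window GC skew
(G − C)/(G + C) flips sign at *ori* and *ter*, and the cumulative skew has
its extrema there. `gc_skew_profile()` computes the windowed and cumulative
skew (default window 10 kb, step 1 kb: on a 1.5 Mb genome this resolves the
two shifts without letting single-window noise dominate; both are
configurable). `detect_ori_ter()` calls the extrema of the cumulative curve.
The polarity convention — leading strand G-rich, hence cumulative minimum at
*ori* — is the common empirical pattern but is configurable
(`polarity = "c_leading"`), because skew amplitude and sign vary across taxa.

**Flat-signal guard.** Without replichore structure the cumulative skew is
not flat: it is a random walk whose range grows with the number of windows,
so a naive "range versus a few standard deviations of the window skews" rule
cannot distinguish drift from signal (a detail worth spelling out: with a
10 kb window and 1 kb step, consecutive windows share 90% of their bases, so
the walk takes correlated steps and its range is inflated by the overlap
factor). The detector therefore compares the observed cumulative range with
the null scale of that correlated walk, `sigma * sqrt(n * window / step)`,
where `sigma` is the binomial sampling noise of a window's skew, estimated
from the window G+C counts as `mean(1/sqrt(G+C))`. This statistic is
scale-free under the null (it follows the Brownian-range law; simulated
null maxima sit near 3 over hundreds of genomes) while a genuine
two-replichore signal grows linearly with the number of windows, i.e. as
`amp * sqrt(L)` after normalization. The default threshold `tol_factor = 4`
puts the null exceedance probability near 1e-4. The practical detection
limit follows from the same formula: at a 10 kb window, a skew amplitude of
0.05 is comfortably detectable at L = 200 kb (statistic ≈ 6) but not at
L = 50 kb (statistic ≈ 2.5, inside the null range) — short, weakly skewed
replicons genuinely do not carry enough signal at this window size.

`find_dif_sites()` scans both strands circularly for an IUPAC motif with
mismatches; the *dif* consensus (the site where chromosome dimers are
resolved, an independent *ter* marker) differs between taxa, so no motif is
hard-coded — the user supplies the consensus relevant to their clade.

**Growth and the R value.** `estimate_doubling_time()` fits log(OD) against
time by ordinary least squares and returns log(2)/slope. When no window is
given, the exponential phase is chosen automatically as the contiguous run
of at least 4 points with positive slope maximizing the fit's R², breaking
ties toward the longer run; this matters for curves with lag and stationary
phases, where a blind full-series fit underestimates the rate.
`replication_ratio_R()` computes R = (L/2 ÷ fork speed) ÷ doubling time —
the fraction of a generation a fork spends replicating one replichore. R
above 0.5 implies overlapping replication rounds and ori-proximal gene
dosage; for a 1.5 Mb genome at 1,000 nt/s and a 55 min generation, R = 0.23.

## Positional bias of functional categories

`build_distance_table()` assigns every categorized gene its circular distance
to *ori* — `min(d, L − d)`, computed from the gene midpoint (symmetric for
both strands; wrap-around genes handled modulo L) — and
`kruskal_wallis_bias()` / `pairwise_mannwhitney()` test whether categories
sit at different distances. Choices:

* Categories with fewer than `min_group = 5` genes are excluded (rank tests
  below that size carry no information) and listed in the result.
* Distances are integers, so ties are certain: mean ranks with the standard
  tie correction for H; the pairwise tests enumerate the full permutation
  distribution of the rank sum when both groups have ≤ 8 members (exact
  under ties), and use the tie- and continuity-corrected normal
  approximation otherwise. The two agree to about 0.01 on average at the
  crossover size; the worst cases reach about 0.02, which is the intrinsic
  error of the normal approximation at n = 8, not a bug to tighten away.
* Bonferroni multiplies by the number of pairs actually tested after the
  eligibility filter, not by the nominal number of all category pairs.
* Tests run per genome by default; to pool genomes of different sizes,
  normalize `distance_bp` by L/2 first.

Calibration on synthetic tables (three categories, 100 genes each, uniform
distances) keeps the type-I error of the global test inside the binomial
95% interval of the nominal level over 1,000 tables, and a planted
ori-proximal category (triangular distance distribution peaked at 0 against
uniform backgrounds) is detected at p < 0.001 in ≥ 90% of runs. That power
figure is tight, not comfortable: the triangular-vs-uniform shift at 100
genes per category sits right at the edge of what a rank test resolves at
that stringency.

## Ancestral gene-content flux (generalized parsimony)

`sankoff_reconstruct()` reconstructs per-family ancestral copy numbers on a
rooted species tree by the Sankoff dynamic program over states
0..`max_copies` (default 8; observed counts above the cap are clipped — at
0.2 per copy step the states beyond 8 are cost-equivalent and only widen the
DP). The event costs (`cost_scheme()`) are: acquisition 10, loss 5, first
duplication 1, and 0.2 per additional copy step, applied symmetrically to
expansions and contractions. The cost of a composite change along one branch
is the cheapest consistent composition: appearing at b copies costs
gain + first_dup + (b−2)·0.2; expanding from a single copy always pays the
first duplication; a loss is flat regardless of the copy number lost. The
transition matrix is verified to admit no cheaper multi-edge decomposition,
so the DP over single-branch transitions attains the true minimum.

**Root convention.** Presence at the root is charged as an acquisition on a
root stem (cost c(0, root state)). Without that prior, any family would be
"free" at the root and gain-vs-loss asymmetry could not polarize histories;
with it, a family present in half the tree is reconstructed as a gain on
that half's stem (10) rather than root presence plus loss (15), which is the
intended economy of the cost scheme. Two consequences are worth knowing:

* Events on the two branches adjacent to the root cannot be polarized: a
  loss on one root child (root gain 10 + loss 5) is never cheaper than a
  gain on the other root child (10). This is an identifiability limit of
  parsimony at the root, not an implementation artifact; flux on
  root-adjacent branches should not be interpreted. The bundled species tree
  places the interesting (genome-reduction) branch away from the root for
  exactly this reason, mirroring how such studies root with nested
  outgroups.
* Repeated loss and regain of a family on one branch collapses to a single
  event, so inferred event counts slightly undercount the true event tally
  in high-rate regimes.

**Tie-breaking.** Among co-optimal states the back-pass prefers the parent's
state (no change on the branch) and otherwise the higher copy number; at the
root, the highest co-optimal copy number. The rule is fixed and
deterministic, so event logs are byte-stable; it plays the role of an
accelerated-transformation convention, whose exact semantics under
generalized costs differ between implementations and are therefore pinned
down here explicitly. Families are processed in lexicographic order.

A presence/absence mode collapses counts to 0/1 and ignores duplication
costs, since published family-flux figures do not always state whether copy
numbers entered the analysis; outputs are labeled with the mode.

`flux_summary()` reports per-branch gains, losses, family totals and
branch-length-normalized loss rates, plus the focal branch's loss rate as a
fold range against the other internal branches. On simulated gene-content
evolution (13 taxa, 500 families, loss rate 0.3 per unit branch length with
a ×3 multiplier on the focal stem), branch-wise Spearman correlation between
true and inferred loss counts exceeds 0.9 on the identifiable branches and
the focal branch always carries the largest inferred loss count.

## Gene-tree congruence

`supported_sister_pairs()` extracts two-leaf cherries whose subtending node
support strictly exceeds the threshold ("> 95" is strict; missing supports
fail). Larger clades do not create pairs — the tally asks which strains pair
as sisters, and an `any-bipartition` mode (a supported split isolating
exactly the pair) is available behind a flag for the looser reading.
`tally_sister_support()` counts supported cherries across a tree set against
a fixed denominator of all trees; pairs seen in fewer than `rare_fraction =
0.01` of trees are flagged as rare arrangements. `monophyly_support()`
checks that every group with ≥ 2 present members forms a supported clade
(singletons are vacuous). `host_congruence()` relabels the host tree through
the symbiont-to-host mapping, restricts to shared leaves and reports the
unrooted Robinson–Foulds distance normalized by its maximum 2(n − 3); random
10-leaf tree pairs sit near 1, which is the reference point for "no
congruence".

## Recombination screen (Phi)

The pairwise homoplasy statistic asks whether nearby polymorphic sites are
more compatible with a single tree than distant ones — the signature of
recombination. For a pair of parsimony-informative sites the refined
incompatibility is the number of extra (homoplastic) changes any tree must
spend on the pair beyond the (s − 1) changes each site needs alone; it is
computed exactly as the cycle rank of the partition intersection graph
(vertices: the states at the two sites; edges: observed joint patterns),
which reduces to the four-gamete test for binary sites and is validated in
the test suite against exhaustive enumeration of all unrooted topologies on
small instances. `phi_test()` averages the incompatibility over site pairs
at most `window_w` apart in informative-site rank (default 100) and compares
it with a null built by permuting informative-site positions:
p = (1 + #{permuted ≤ observed}) / (permutations + 1), one-sided because
recombination lowers nearby incompatibility. The add-one rule floors p at
1/(n+1); when the window covers every pair the permutation is a no-op and
p = 1 exactly. Gaps and N are missing data; a state counts only over
non-missing sequences and sites with fewer than 4 non-missing sequences are
excluded. Alignments with fewer than 2 informative sites are reported
`untestable` and never get a p-value. The raw-mean form of the statistic is
used (with the permutation null the variance normalization used by some
implementations cancels out of the rank comparison).

`recombination_screen()` applies the strict all-tests rule: a gene is
positive only if every provided p-value (Phi plus any external per-gene
screens supplied as a side table) is strictly below alpha (default 0.01).
Untestable genes leave the denominator. Fractions are rounded half away from
zero to one decimal (47 positives of 1,053 tested → 4.5%).

Calibration: on clonal simulations (single topology, 1,000 sites, 4 taxa)
the p-values are uniform (KS test, 200 replicates at 200 permutations each —
the p granularity of 1/201 is far below the KS resolution at that sample
size); on two-topology 500+500-site concatenations with a long internal
branch, p < 0.01 in well over 90% of replicates.

## Synthetic data: what it does and does not emulate

Every generator is a pure function of (parameters, seed): it seeds a private
RNG stream, restores the session state, and attaches the planted truth to
its output. The bundled "kunkeei-like" scenario (see `default_run_config()`)
emulates the study regime at desk scale: a 1.5 Mb circular genome with
planted skew amplitude 0.08, 1,300 genes over five categories with
ori-proximal metabolic/transport and ter-proximal translation/replication
biases, 500 families evolved on the fixed 13-taxon tree with a loss-heavy
ingroup stem, 790 gene trees drawn from a 3-topology mixture over the
A-microcluster, six clonal and two recombinant alignments, and a 55-min
growth curve.

The generators deliberately omit: rate heterogeneity across sites and
branches (the substitution model is single-parameter equal-rates — enough to
calibrate rank and permutation tests, not to mimic real saturation
patterns), indels, codon structure, coalescent gene-tree discordance
(topology mixtures are drawn i.i.d., not from a population process), gene
order and operon structure, and compositional heterogeneity beyond the
planted skew. Passing the recovery suite therefore shows the estimators are
correct and calibrated under their stated models; it does not show
robustness to model violations in real genomes.

## Numerical conventions and problem sizes

* Coordinates are 0-based half-open internally; GFF3/TSV input (1-based
  inclusive) is converted on read and back on write. Wrap-around genes keep
  `start > end` plus a flag; midpoints are computed modulo L.
* Supports live on the percent scale; inputs in [0,1] are rescaled with a
  warning; unlabeled nodes are missing, never 0.
* Missing branch lengths are absent, never 0: rate computations warn and
  omit rather than divide.
* Monte-Carlo p-values carry the add-one floor; screen fractions and the R
  value round half away from zero (plain rounding would turn 6.25% into
  6.2%).
* The test suite's problem sizes — 200 kb genomes for ori/ter recovery,
  1,000 null bias tables, 200 clonal and 100 recombinant Phi replicates at
  200 permutations, 200 random Sankoff instances against the brute-force
  oracle, two full pipeline runs for the determinism audit — were chosen so
  the whole suite runs in a couple of minutes while keeping every binomial
  margin quoted above meaningful.

## Known limitations

* Ori/ter detection is skew-only; gene-context refinement (e.g. the
  *rpmH–dnaA* intergenic region) would need annotations and is out of scope.
* Flux on root-adjacent branches is unidentifiable (above); fold-change
  summaries exclude them from the background by construction only when they
  carry no rate, so interpret those rows with care.
* The Phi screen does not localize breakpoints and does not implement the
  NSS or MaxChi statistics; external p-values can be merged to reproduce an
  all-three positivity rule.
* The pairwise identity and screen-fraction helpers reproduce printed
  percentages only under the same rounding convention stated above.
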