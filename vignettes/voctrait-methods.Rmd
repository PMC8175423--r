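---
title: "Methods: chemotyping fungal volatilomes and finding volatile biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemotyping fungal volatilomes and finding volatile biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voctrait)
```

# The problem

Fungi emit blends of volatile organic compounds (VOCs) that act in
inter-organismal signalling. Given emission profiles of many species measured
on two complementary platforms — an online PTR-ToF-MS instrument producing
mass features in normalised counts per second (ncps cm⁻² s⁻¹), and an
offline sorptive-extraction GC–MS producing annotated compounds in
pmol cm⁻² h⁻¹ — the questions this package addresses are:

1. How diverse and even is each species' volatilome (Pielou evenness)?
2. Which compounds co-vary across species (Spearman clustering)?
3. Can taxonomy and ecological guild (trophic mode, lifestyle, substrate,
   host) be read off the chemical profile (DAPC chemotyping)?
4. Are structurally related compounds emitted as integrated bouquets within
   guilds (phenotypic integration with a permutation null)?
5. Which individual compounds are reliable guild biomarkers (three-model
   consensus machine learning)?

All stages consume one container, the `emission_matrix`: samples × compounds,
nonnegative, zeros meaning "not detected". Zeros are a deliberate single
state — there is no separate missing code — because every downstream
statistic (correlations, evenness, tree ensembles) treats absence of
emission as biological signal, not as missingness.

# The synthetic volatilome generator

Real data of this kind live in external repositories; the package instead
ships a generator whose defaults emulate the structure of such a study, so
that every stage can be tested against planted ground truth. The default
design is 43 species × 3 replicates, 200 PTR mass features and 60 GC
compounds.

For compound $j$, species $s$, replicate $r$ the log emission is

$$x = \mu_0 + a_j + b_{g(s),j} + \lambda_{c(j)}\, f_{s,c(j)} + \varepsilon$$

* $a_j \sim N(0, 0.5)$ — a per-compound baseline offset (sd 0.5), which
  makes some compounds globally large and others trace-level;
* $b$ — the planted biomarker effect: $\delta\sigma_0$ when species $s$
  carries the label value targeted by a biomarker entry naming $j$;
* $f_{s,c} \sim N(0,1)$ — a per-species latent factor shared by all
  compounds of structural class $c$, active only for species of the
  covariation entry's trophic mode, with loading $\lambda \in [0,1]$;
* $\varepsilon \sim N(0, \sigma_0)$, $\sigma_0 = 1$ by default.

The emission is $\exp(x)$, masked to zero with probability $\pi = 0.4$ per
(species, compound) pair — at the *species* level, so a species either emits
a compound in every replicate or never, making replicate profiles true
species fingerprints. Two generator-level conventions are worth spelling
out:

* **Biomarkers are never masked in their target group.** A biomarker is
  defined by reliable presence plus elevated emission; random dropout of a
  planted marker in its own class would simulate a different (and less
  interpretable) ground truth.
* **GC dispersion.** The GC platform uses dispersion scaled by 0.6 on both
  $a_j$ and $\varepsilon$. Profiles whose log-scale spread is smaller are
  more even, so GC evenness systematically exceeds PTR evenness — the
  qualitative platform contrast such studies report. We apply the factor to
  both dispersion sources because evenness across compounds is driven by
  the compound-offset spread at least as much as by the residual.

Default planted structure: six PTR trophic-mode biomarkers
(2 saprotrophic / 2 mycorrhizal / 1 phytopathogenic / 1 mycoparasitic) at
$\delta = 3$, and one covariation block (saprotrophic × carboxylic acids,
$\lambda = 0.8$). Guild labels are balanced across their levels by default;
an unbalanced preset (mycoparasites as a two-species rare class) exercises
the upsampling path of the biomarker module. Within a planted block the
log-scale pairwise correlation has the one-factor closed form
$\lambda^2/(\lambda^2 + \sigma_0^2)$, which the tests verify by simulation.

What the generator does **not** emulate: real mass spectra and fragmentation
chemistry, compound identities, instrument drift, batch effects, or
phylogenetic signal in the label assignment (labels are assigned
independently of the simulated taxonomy strings). Passing tests therefore
show that the *chain of methods* behaves as designed on data with this
covariance structure — not that any particular biological conclusion holds
on real measurements.

# Preprocessing

The preprocessing operations mirror the standard feature-table chain of the
two platforms; peak picking, mass calibration and library annotation are out
of scope (the package starts at feature tables).

* **Reagent-ion normalisation** (PTR): `ncps = cps × 10⁶ / reagent_counts`.
* **Background subtraction** (PTR): a natural cubic spline through the
  averaged blank-cuvette signal, evaluated at sample timestamps and
  subtracted. Negative corrected values are clipped to zero — a choice the
  measurement itself does not dictate, made because evenness and
  correlation statistics downstream require nonnegative abundances. With
  fewer than four background points the spline is refused and a linear
  fallback offered explicitly.
* **Area/time normalisation**: signal / (mycelium area × accumulation time);
  70 min is the PTR accumulation default and 960 min (16 h) the GC
  collection default.
* **ncps → pmol**: linear map through per-compound calibration
  sensitivities; the flow/molar-volume constant is configurable because the
  exact instrument constants are setup-specific. Compounds without a
  sensitivity stay in ncps and are flagged rather than dropped.
* **Isotopologue removal** (PTR): features at +1.00336 Da (¹³C) or
  +2.00425 Da (¹⁸O) of a parent are flagged — but only when the intensity
  ratio sits inside a window (default 0.2–5×) around the natural-abundance
  expectation, to avoid deleting genuine compounds at coincidental mass
  spacing. The carbon count defaults to the heuristic
  $n_C = \mathrm{round}((m/z - 18)/14)$ (a protonated oxygenated
  C$_n$H$_{2n+1}$O skeleton) and can be overridden per compound. The ratio
  check can be disabled to reproduce a pure mass-rule behaviour.
* **Fragment grouping**: compounds with squared Pearson correlation > 0.9
  across samples are joined; connected components of that graph are the
  groups, so grouping is transitive by construction. Groups are annotated,
  not collapsed, by default — mass features remain the analysis unit — with
  an explicit collapse option that sums members.
* **Retention indices** (GC): the linear van den Dool–Kratz form
  $RI = 100\,(n + (rt - rt_n)/(rt_{n+1} - rt_n))$, appropriate for
  temperature-programmed chromatography (the isothermal logarithmic form
  would be wrong for a ramped oven). No extrapolation outside the C9–C25
  alkane span.

# Diversity and clustering

Pielou evenness is computed on the **replicate-mean** profile of each
species (one J per species, as such profiles are reported), using natural
logs: $J = H/\ln p$ over the positive entries. J is undefined below two
positive compounds and reported as `NA` with a warning. Compound clustering
uses $d = 1 - \rho$ with Spearman correlation across species-mean profiles,
average linkage (UPGMA), and a cut at $k = 17$ clusters lettered A… in
dendrogram leaf order. Average linkage is a package choice — only the
correlation basis is fixed by the method being reproduced — and complete
linkage is available. Constant compounds get $\rho := 0$ against everything
rather than propagating NAs.

# DAPC

`fit_dapc()` centers and scales columns to unit variance (equal weighting of
the two platforms in a merged table), reduces by SVD-based PCA to $m$
components, and fits an LDA on the scores. `xval_select_m()` chooses $m$ by
repeated stratified hold-out: per replicate, 90 % of samples train the
model, the rest are assigned, and the per-$m$ RMSE
$\sqrt{\mathrm{mean}((1-\mathrm{success})^2)}$ is minimised, ties going to
the smaller $m$. Assignment is to the nearest group centroid in
discriminant space; reported scores are a softmin of squared centroid
distances, documented as a heuristic posterior (the assignment is identical
to what Gaussian posteriors would give, and assignment is what the method's
claims rest on). Exact ties break to the first group in factor order and
are flagged.

The pipeline applies a `log1p` transform to emissions before DAPC
(configurable off). Emission rates are log-normally distributed over orders
of magnitude; LDA on raw values is dominated by a handful of huge-variance
features, while on the log scale classes are close to elliptical. This is
the package's standard analysis convention for skewed emission data; the
tree-based biomarker module is invariant to monotone transforms and
therefore runs on raw values.

The cross-validation replicate count (default 30; 10 in the pipeline's
scaled demo) and the $m$ grid (10 even values from $k$ to
$\min(n-k, \mathrm{rank})$) are package choices, as is everything else not
fixed by the contracts above.

# Phenotypic integration

The integration index of a set of $p$ compounds over $n$ samples is the
variance of the eigenvalues of their Pearson correlation matrix. Because
the mean eigenvalue of a correlation matrix is exactly 1, we use the
population variance $\sum_i(\lambda_i - 1)^2/p$, whose maximum is exactly
$p - 1$ (all compounds perfectly correlated); relative PI then tops out at
exactly 100 %. The sample-variance alternative (divide by $p-1$) is
available via the oracle identity but not the default, precisely so that
"divide by the attainable maximum" is exact.

The corrected index subtracts the random-covariation expectation
$(p-1)/n$, and the relative index is $100 \times \mathrm{corrected}/(p-1)$.
Two null models calibrate significance, because "randomly drawn from the
data set" admits two readings:

* `permute` (default): each compound's values are independently permuted
  across samples — exactly the hypothesis of random covariation, preserving
  every marginal;
* `subset`: random compound sets of size $p$ from the full pool over the
  same samples — the compound-resampling reading.

Each of the 10,000 default draws yields a relative PI; the observed value
is significant when it exceeds the empirical 95 % quantile, and the
reported p-value is $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n)$,
never zero. Inside the null loop the index is computed by the algebraic
identity $\mathrm{raw} = (\mathrm{tr}(R^2) - p)/p = \sum_{i\ne j} r_{ij}^2/p$,
which the tests pin to the eigenvalue route at 1e-12.

Samples are species replicates within the selected guild (n counts
replicate rows, not species): the paper-style "number of samples" is
ambiguous on this point, and replicates are what the correlation actually
sees. Cells at $n = 3$ are computable but flagged `low_n`; cells below
$p = 2$ or $n = 3$ are reported with an explicit reason instead of a value.

# Biomarker discovery

Per task (label column) and platform: a 75/25 stratified split; minority
classes of the **training** part upsampled with replacement to the majority
size (originals always kept; the test set untouched); then three models on
the balanced training data only:

1. `rf_rfe` — recursive feature elimination wrapped around a random forest;
2. `bagged_rfe` — RFE wrapped around bagged CART (a forest with
   `mtry = p`, i.e. every tree sees all features);
3. `rf_embedded` — a single random forest with `mtry` tuned on a 5-point
   grid by stratified 10-fold CV, ranked by impurity importance.

RFE walks the subset-size grid {5, 10, 15, 20, 30, 50, all} downward,
refitting and re-ranking at each size per CV fold; the optimal size
maximises mean CV accuracy (ties to the smaller size), and the final
ranking is the mean of per-fold ranks at that size, ties broken by first
appearance. Each model's top-15 predictors are refit on the balanced
training set and evaluated once on the untouched test set: accuracy,
per-class sensitivity, and a one-sided *exact* binomial p-value of the
accuracy against the no-information rate. Models below 80 % accuracy or
with $p \ge 0.05$ are excluded; the consensus is the intersection of the
survivors' top-15 sets ordered by mean rank, with Table-style aggregated
metrics as the arithmetic means over survivors. By construction, no test
sample ever reaches feature selection or tuning.

Tree counts (200 for selection, 500 for final fits), the subset grid and
the `mtry` grid are package choices; none is printed in the design being
followed. Single-split mode replicates that design; a repeated-holdout
wrapper is deliberately left to the caller (run the task over several
seeds and take medians), since a single 25 % test set of ~32 samples
carries binomial noise of several percentage points.

# Pipeline, seeds and problem sizes

`run_pipeline()` executes the stages in dependency order from a validated
JSON config (unknown keys rejected) and writes TSV/JSON artifacts plus a
manifest (package version, config echo, derived stage seeds — no
timestamps, so reruns are byte-identical). Per-stage seeds derive from the
single global seed by hashing the stage name into it, so a stage rerun in
isolation reproduces the pipeline's result. The shipped demo config runs a
scaled-down scenario (16 species, 60 + 24 compounds, 300 null draws,
150-tree forests) chosen so a complete demonstration stays interactive;
the test suite and acceptance checks use the same scaled designs it
documents in each check (e.g. 2,000 null draws × 500 replicates for type-I
calibration of the PI null, 10 seeds for planted-biomarker recovery).

# Numerical conventions and degenerate inputs

* Constant columns: dropped with a warning before correlation-based
  statistics; $\rho := 0$ in compound clustering; no fragment edges.
* Negative values after background subtraction: clipped to 0.
* Ties: mid-ranks in Spearman; smaller $m$/subset size/`mtry` on equal CV
  scores; first group order on equidistant centroids (flagged); first
  appearance on equal feature ranks.
* Matrix I/O serialises at 12 significant digits (`%.12g`), making
  read/write round trips byte-stable.
* Empirical p-values use the add-one form and cannot be zero.

# Known limitations

* The generator's labels are independent of its taxonomy strings; real
  guild labels correlate with phylogeny, so real-data chemotype accuracy
  questions (e.g. guild signal beyond phylogenetic signal) cannot be asked
  of these simulations.
* Pearson correlations on raw emissions are attenuated for heavy-tailed
  data; the integration module follows the method's definition on raw
  values, which costs power at small $n$ (documented in the tests by the
  panel's behaviour at 5 species per guild).
* The DAPC posterior scores are centroid-distance heuristics, not
  calibrated probabilities.
* No phylogenetically corrected integration and no cross-study
  normalisation.
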