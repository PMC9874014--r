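---
title: "Whole-cell energy budgets from proteomics-constrained FBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-cell energy budgets from proteomics-constrained FBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enerflow)
library(dplyr)
```

## The model in one page

`enerflow` treats cellular energetics as a supply-and-demand problem posed
on a proteome.

**Supply** is a flux balance problem: given a metabolic network with
stoichiometric matrix $S$, find the flux vector $v$ maximising the flux of
a generic ATP-hydrolysis sink subject to steady state, $S v = 0$, and
bounds $lb \le v \le ub$. Only the optimal objective value is unique;
alternate optimal flux vectors exist and the package reports fluxes as-is
for that reason (the sweep and calibration depend only on the objective
and the glucose exchange flux).

Protein abundances enter through the reaction bounds. Each
enzyme-associated reaction carries a boolean gene-reaction rule; the
*minsum* convention aggregates abundances over it (sum across isozymes,
minimum across complex subunits), reflecting that any isozyme can carry
flux while a complex is limited by its scarcest subunit. The effective
abundance $a$ then maps to a bound through a saturating transform

$$\hat s(a) = \frac{a\,(1+k)}{a + k\,a_{\max}},\qquad
  ub = b_{\max}\,\hat s(a),$$

with $lb = -ub$ for reversible reactions and $0$ otherwise. The
*compression* parameter $k > 0$ interpolates between a linear mapping
($k \to \infty$, $\hat s \to a/a_{\max}$) and full saturation ($k \to 0$,
every expressed enzyme near $b_{\max}$). Two properties motivated this
exact form: $\hat s(a_{\max}) = 1$ at every $k$, so the most abundant
reaction's bound stays pinned at $b_{\max}$ across a sweep (comparisons
across $k$ are then about *relative* constraint, not overall scale); and
$\hat s$ is strictly increasing in $a$, so ordering by abundance is
preserved. Published analyses of this kind quote a working compression
value of 0.016, but the transform there is described only qualitatively
(Michaelis–Menten-like, normalised to its maximum); a different internal
parameterisation of the same idea would relabel the $k$ axis. $k$ should
therefore be treated as a calibration axis, not a transferable constant.

**Exchange bounds** set what the medium supplies. In medium-proportional
mode every exchanged metabolite $m$ present in the medium gets an uptake
bound $lb_m = -r\,b_{\max}\,\mathrm{mM}_m/\mathrm{mM}_{glc}$ — glucose, at
its reference 25 mM, anchors the scale and $r \ge 0$ (the *availability
ratio*) sets how generous the environment is relative to the enzyme
bounds. In measured mode, per-condition measured exchange rates are first
rescaled so glucose matches the reference (preserving between-metabolite
molar ratios and signs), then converted to flux units by the same factor;
measured uptakes bound uptake, measured secretions put a floor under
efflux (a config switch makes them free instead, since a measured efflux
could equally be read as a ceiling or an equality — the floor is the
choice that forces the network to actually dispose of what the cell was
observed to secrete). Metabolites absent from the medium cannot be taken
up. Oxygen is treated as freely available unless listed.

Sweeping $k \times r$ and solving each cell yields the capacity
landscape; infeasible cells (possible in measured mode, where efflux
floors can exceed what compressed internal bounds sustain) are recorded as
such, status-driven rather than residual-driven. The molar ATP/glucose
ratio of a solution times a measured glucose uptake (pmol/ng protein/day)
converts capacity into measured units; the grid cell closest to a measured
total ATP-production rate is the calibration point, ties resolved toward
smaller $r$ then smaller $k$ (the more conservative parameterisation).

**Demand** distributes the calibrated capacity. Consumers are proteins
annotated to require ATP or GTP (one shared pool by default — published
budgets pool "ATP + GTP" — with a flag for separate pools). Each
consumer's weight is its complex-corrected abundance, compressed with the
*same* $k$ as the supply side, times its turnover number; missing kcats
are mean-imputed within the cofactor group. Class flux = capacity x
summed weight share. The expression-percentage column is relative to the
total corrected expression of *all* proteins, not only consumers — this
reconciles small per-class percentages with large flux shares.

**Protein synthesis** follows from tRNA charging: 2 ATP per amino acid,
110 Da mean residue mass, so the ligase-class ATP flux $f$ (pmol/ng/day)
gives an amino-acid flux $f/2$ and a total synthesis rate
$f/2 \times 110/1000$ per day (a mass fraction of the existing pool).
Subtracting an assumed mean turnover of 0.5/day gives the net rate. On
the published wild-type reference budget (ligase flux 12.51 pmol/ng/day)
this arithmetic yields 0.688/day total and 0.188/day net, which does
*not* equal the 0.135/day the source table lists for the same condition —
the residual presumably absorbs elongation GTP costs or additional
corrections that were not stated. The package reports both numbers and
the inputs; it does not attempt to absorb the gap into a fitted factor.

## Missing-value imputation

Label-free proteomics leaves a large minority of proteins unquantified.
The imputation stage assumes (i) proteins of one functional class sit at a
similar order of magnitude, and (ii) a tissue-general protein that went
undetected is nonetheless present. Each missing entry is filled per its
tissue-expression category: *Detected in all* takes the class **average**
of detected values, *Detected in many/some/single* and *#N/A* take the
class **minimum** (present, but plausibly at the low end), *Not detected*
becomes **zero** regardless of class. Three choices were genuinely open
and are made explicit:

* **Fallback order.** When the level-1 class has no detected member in a
  sample, the cascade falls to level-2, then the whole table — the
  nearest (most specific) class first, as the most informative. A class
  empty at every level yields 0 and a `fallback` flag in the report.
* **Per-sample statistics.** Class averages/minima are computed per
  replicate column, not pooled, preserving replicate independence for
  downstream statistics. (Whether pooling was intended in the original
  description is unstated; the choice is explicit here and the report
  records the source of every filled value.)
* **Minimum over detected, non-zero values.** Zeros written by the
  *Not detected* rule never become another protein's "minimum".

Imputation is idempotent, never touches observed entries, and only adds
non-negative mass to group sums — all property-tested.

## What the synthetic data emulates — and what it does not

The generator produces the full input bundle: a toy metabolic network and
a class-structured proteome.

The **toy network** lumps central carbon metabolism into glycolysis
(2 ATP/glucose), pyruvate oxidation (30 further ATP/glucose at 6 O2),
lactate+proton overflow, optional glutamine oxidation (deliberately less
ATP-per-O2 efficient than glucose, so oxygen allocation has a unique
greedy optimum), and optional ATP→GTP branch. Its maximum ATP flux has a
closed form recorded with the model, which is what makes the LP machinery
testable: shifting the oxygen bound walks the network from a 32
ATP/glucose oxidative optimum to the 2 ATP/glucose fermentative one, the
same qualitative glycolysis↔oxphos trade-off the sweep heatmaps show on
genome-scale models.

The **synthetic proteome** draws log-normal abundances around per-class
log-means (default 20 classes x 50 proteins x 3 replicates, log-means
spanning e^6–e^12, dispersion 0.5 — typical LFQ orders of magnitude), with
category-stratified masking at 20% for quantifiable categories. *Not
detected* proteins have true abundance 0 and are always masked: they are
genuinely absent, and the zero rule should recover them exactly. The
first class labels mirror energy-consuming classes (tRNA ligases,
transporting ATPases, Ras GTPases, ...) so the demand side runs end to
end.

What passing on synthetic data does **not** show: real LFQ missingness is
intensity-dependent (left-censored), not independent within category;
real class structure is far looser than a log-normal around a single
mean; and the toy network has none of the redundancy, compartment
structure, or cofactor coupling of a genome-scale reconstruction. The
synthetic results validate the machinery and its invariants, not the
biological accuracy of any particular budget.

## Numerical choices

* **LP solver.** A dense two-phase primal simplex with Bland's rule
  (guaranteed termination under the degeneracy these polytopes exhibit),
  with variables shifted to non-negative form and upper bounds as slack
  rows. Exactness is verified against brute-force vertex enumeration on
  random small networks to 1e-8, and optimal solutions are checked for
  mass balance to 1e-6·b_max. Infinite bounds are clamped to 1e6 before
  solving. This is adequate for desk-scale networks; genome-scale
  reconstructions would want an industrial solver behind the same
  `solve_fba()` surface.
* **Infeasibility** is taken from solver status, never from residual
  thresholds, so blank sweep cells are unambiguous.
* **Sweep axes** are log-spaced by default (7 x 7 plus the working point
  k = 0.016, r = 0.05 always included), matching the visual spacing of
  published heatmaps; problem sizes in the tests (8 x 8 toy sweeps,
  1000-protein proteomes) were chosen so a full test run completes in
  well under a minute per stage.
* **Ranking ties.** Group-rank comparisons accept an externally supplied
  significance matrix; by default conditions tie when their mean sums
  differ by under 5% relative (exact equality always ties). This replaces
  the inferential post-hoc machinery, which is out of scope, while
  keeping the averaged-rank semantics.
* **Degenerate inputs.** Zero glucose uptake flags the ATP/glucose ratio
  undefined rather than dividing by zero; an abundance of exactly 0
  blocks its reaction; `lb > ub` reports infeasible rather than erroring;
  single-group correlations are reported as undefined.

## Known limitations

* Only the LP objective value is identifiable; reported flux vectors are
  one optimal solution among possibly many (no FVA/pFBA).
* The compression parameterisation is one member of a family; calibrated
  $k$ values are not transferable across parameterisations.
* Eq.-style glucose ratios use the *realised* uptake flux at optimum (a
  switch exposes the bound instead); at optima where glucose is not
  limiting the two can differ.
* Demand-side complex definitions default to monomers unless a complex
  file is supplied; kcat mean-imputation flattens real orders-of-magnitude
  variation in turnover numbers.
* No thermodynamic feasibility, loop removal, or enzyme-capacity coupling
  — deliberately, matching the plain-FBA scope of the analysis this
  package operationalises.

## A complete run

```{r pipeline}
bundle <- make_toy_bundle(seed = 1)
cfg <- pipeline_config(measured_atp = bundle$measured_atp,
                       measured_glucose = bundle$measured_glucose,
                       seed = 1)
res <- run_pipeline(cfg, model = bundle$model, proteome = bundle$proteome,
                    annotation = bundle$annotation, medium = bundle$medium)
res
head(res$budget)
res$synthesis
```

```{r heatmap, fig.width = 6, fig.height = 4}
autoplot(res$sweep)
```

```{r imputation, fig.width = 5, fig.height = 4}
ann <- validate_annotation(bundle$annotation)
imp <- impute_completerot(bundle$proteome, ann)
cmp <- compare_prepost(bundle$proteome, imp$completed, ann)
cmp$correlation
plot_imputation_compare(cmp)
```
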