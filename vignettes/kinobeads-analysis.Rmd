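---
title: "Kinobeads competition-binding analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinobeads competition-binding analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinobeadr)
```

## The assay and its model

Kinobeads are sepharose beads carrying immobilized broad-spectrum kinase
inhibitors. Incubated with a native cell lysate they enrich kinases and
other purine-binding proteins; a free test compound spiked into the lysate
beforehand competes its targets away from the beads, so the loss of
bead-bound signal at increasing compound concentration quantifies binding.
Each 96-well plate carries compound wells at two doses (100 nM and 1 µM) or
a nine-point ladder (vehicle, 0.3–1,000 nM), six randomized DMSO vehicle
controls, three replicate wells of a promiscuous reference compound for
quality control, and a depletion pair — two consecutive pulldowns of the
same vehicle lysate.

Per protein and well, the measured intensity divided by the median of the
six DMSO controls gives the *relative residual binding*
$r \in [0, \infty)$: 1 means no competition, 0 complete competition. Under
the one-site competition model with hill slope one,

$$ r(c) = \frac{1}{1 + c/\mathrm{IC}_{50}}, $$

so a single dose $[I]$ with residual $r$ inverts exactly to

$$ \mathrm{IC}_{50} = [I]\,\frac{r}{1 - r}. $$

`estimate_ic50_two_dose()` applies this at the dose whose residual is
closest to 0.5 (ties to the lower dose, the smaller extrapolation), with
$r$ clamped to $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-3}$.
Note a wording subtlety: the percent-form of this equation,
$\mathrm{IC}_{50} = [I](100-\mathrm{inhibition})/\mathrm{inhibition}$, only
yields finite, positive affinities when "inhibition" is read as percent
inhibition $100(1-r)$; that reading is algebraically identical to the form
above and is the exact inverse of the slope-1 engagement model used for
selectivity scoring, which is why we adopt it.

The assay IC50 overestimates affinity for proteins the beads deplete from
the lysate. The *correction factor* $\mathrm{cf} \in [0, 1]$ is the
capture ratio of the two consecutive pulldowns (capped at one; median over
available pairs; global median as fallback for proteins without depletion
data), and

$$ K_d^{app} = \mathrm{IC}_{50} \times \mathrm{cf}, \qquad
   \mathrm{p}K_d^{app} = -\log_{10}\!\big(K_d^{app}\,[\mathrm{mol/l}]\big). $$

Concentrations are carried in nM throughout; the mol/l conversion happens
only in the pKd presentation.

### Reliability flags

Two-dose estimates are approximations and the pipeline is explicit about
their limits:

* `non_binder` — top-dose residual ≥ 0.7 (less than the 30% reduction the
  target definition requires): no affinity is reported.
* `above_assay_max` — top-dose residual in (0.5, 0.7): an affinity is
  reported but it extrapolates beyond the highest assayed dose and is
  excluded from selectivity denominators by default.
* `degenerate` — the top-dose intensity is missing (imputed $r = 0$) while
  the low dose shows little competition ($r_{low} \ge 0.75$). The one-site
  model makes this profile impossible for a genuine binder: $r_{low} = 0.75$
  already implies a top-dose residual of at least
  $r_{low}/(10 - 9\,r_{low}) \approx 0.23$, a signal that does not genuinely
  vanish. These are detection artifacts of low-abundance proteins and are
  excluded from the drug–target matrix (but kept, flagged, for audit).

Missing intensities in general: a zero in MaxQuant-style output means "not
quantified" and is represented as `NA`, never as numeric zero. A missing
compound-well intensity for a protein quantified in the vehicle controls is
interpreted as complete competition ($r = 0$) and flagged `imputed`,
because label-free dropout at strong competition is the dominant
missingness mode — but the flag travels into the classifier features and
the reliability logic above so the interpretation stays auditable.

## Target calling

A training set is annotated by rule: a pair is a *target* when the top-dose
residual is at most 0.7 (≥ 30% reduction), the reduction exceeds three
times the standard deviation of the relative DMSO intensities (the
conventional 3σ reading of "clearly above vehicle variability"; `k` is a
parameter), and the protein has at least two unique peptides. Pairs with
top-dose residual ≥ 0.9 are *non-targets*; the band in between is
*ambiguous* and excluded from training to avoid label noise. A random
forest (500 trees, √p feature subsampling, fixed seed) is trained on the
features: residual binding at both doses, DMSO variability, log10 DMSO
median intensity, maximum unique peptides, maximum MS/MS count, and the
imputation flag. Because a panel quantifies far more non-binders than
binders, the pipeline trains on all target-labeled pairs plus a seeded
subsample of non-targets capped at 20:1.

A pair is called a target when its forest probability is *strictly greater*
than 0.935. The cutoff is a parameter; `select_probability_cutoff()`
implements the underlying criterion (minimize false positives plus false
negatives on labeled data). Called targets are categorized as *direct*
binders when their annotation matches the keyword set (protein/lipid
kinases, nucleotide binders, helicases, ATPases, GTPases, FAD/heme
proteins) and as *indirect* (complex partners) otherwise.

## Selectivity (CATDS) and probe nomination

Target engagement at concentration $c$ assumes slope one, top one, bottom
zero: $e(c) = c/(c + K_d^{app})$. CATDS for a reference target (or
declared paralog group, e.g. the two CK2 catalytic subunits) at an
evaluation concentration $c^*$ is

$$ \mathrm{CATDS} = \frac{\sum_{\text{reference}} e(c^*)}
                         {\sum_{\text{all targets}} e(c^*)}, $$

with $c^*$ defaulting to the Kd of the reference's most potent member. The
compound-centric score `catds_most_potent()` evaluates at the best target's
own Kd, where its engagement is exactly one half; a single-target compound
scores exactly 1 and a compound with two equally potent targets exactly
0.5. The denominator includes every called target (direct and indirect)
with a reliable affinity; `above_assay_max` targets are excluded by default
(configurable) because their affinities extrapolate beyond the assayed
range. Ties on the minimum Kd break lexicographically by protein id.

A compound is nominated as a chemical-probe candidate when its best target
is submicromolar ($K_d^{app} < 1000$ nM, strict) and
$\mathrm{CATDS}_{most\,potent} > 0.5$ (strict) — so the boundary cases
(exactly 1 µM, exactly 0.5) fail.

## Assay QC

Replicate concordance compares each reference-compound replicate's calls
(classifier-positive pairs with a reliable reported affinity) against the
compound's assay-detectable target set within the assayed universe (all
proteins quantified in the plate's vehicle controls). Pooled
(micro-averaged) rates are primary — FNR = missed detections over
replicates × reference size, FPR = spurious calls over replicates ×
non-reference universe — with per-replicate rates reported alongside.
`affinity_concordance()` reports the Pearson correlation of paired pKd
estimates between two assays (e.g. two-dose vs full dose–response).

## Full dose–response fits

`fit_log_logistic()` fits the natural-log four-parameter log-logistic

$$ r(c) = b + \frac{t - b}{1 + e^{s(\log c - \log i)}} $$

by bounded Levenberg–Marquardt least squares ($b \in [0,1]$,
$t \in [0.5, 1.5]$, $s > 0$, $i$ within a tenfold margin of the assayed
range), with vehicle wells entering at $c = 0$ as the top asymptote and
three seeded restarts. With $b=0, t=1, s=1$ the curve is exactly the
one-site model, so $i$ is the assay IC50 and $i \times \mathrm{cf}$ the
apparent Kd. A three-parameter log10 variant with hill slope fixed at one
covers displacement-assay readouts. Flat profiles return a converged but
`degenerate` fit (inflection pinned at the upper bound) rather than an
error.

## TMT phosphoproteomics regulation

The phospho table holds reporter intensities for sites × channels (five
treatments + DMSO control) × four biological replicates, with the
±7-residue sequence window per site. Normalization is total-sum (each
channel scaled within its replicate so its summed intensity equals the
control channel's) followed by row-wise (each site divided by the
cross-replicate mean of its per-replicate means, so that mean equals one).
Both are idempotent and the conservation laws hold to numerical precision.

Regulation is tested per treatment against the control on log2 intensities
with a two-sample Student statistic whose standard-error term is augmented
by the SAM fudge factor $S_0$ (default 0.1 on the log2 scale):

$$ d = \frac{\bar{x}_{treat} - \bar{x}_{ctrl}}{se_{pooled} + S_0}. $$

$S_0$ damps the spuriously large statistics of low-variance sites; the
optional `estimate_s0()` percentile search picks the value that makes the
statistic's scale independent of the site's standard error. Sites must be
quantified (both channels) in at least three of four replicates.

Significance uses a null distribution of the same statistic pooled across
all tested sites and all *balanced* permutations of the channel labels
(pseudo-groups drawing half their members from each original group, so a
genuine location shift cancels instead of contaminating the null),
followed by Benjamini–Hochberg adjustment at 1% FDR. This pooled
permutation null is the essential ingredient: with four replicates the
per-site t distribution (3–6 degrees of freedom) simply cannot produce the
small p-values that surviving a 1% BH correction across a thousand sites
requires, regardless of effect size — the pooled null gives the statistic
the resolution of the whole experiment, which is precisely the mechanism
of the SAM family of tests. A plain t-distribution null is available
(`null = "t"`) for comparison. We test unpaired across replicate columns,
the convention of the spreadsheet-style two-sample tests this emulates;
with the balanced-permutation null the paired variant differs negligibly.

Down-regulation means a significant call with negative log2 fold change;
`intersect_conditions()` keeps sites significantly down in *every*
condition, and `motif_check()` tests the 15-residue window for a central
serine followed by phenylalanine.

## The synthetic-data generator

`simulate_truth()` / `simulate_plate()` / `simulate_phospho()` generate the
ground-truthed inputs every stage is validated against. The plate
generator emulates: log-normal baseline intensities (median 10^7, sdlog
1.5), Beta(4, 2) depletion correction factors, log-uniform Kds on
[1, 10,000] nM, long-tailed compound promiscuity (negative binomial + 1:
most compounds hit a handful of proteins, some dozens), a 76-target
reference compound, multiplicative log-normal intensity noise with 10% CV,
intensity-dependent dropout (logistic in log10 intensity, midpoint at 1%
of the median baseline, slope 8 per decade so the detection transition is
confined to about a quarter decade — label-free detection limits are
sharp, and a wider transition would make well-quantified proteins vanish
at rates no real pulldown shows), and Poisson-linked peptide/MS/MS counts.
The depletion pair is generated so that the second-to-first intensity
ratio equals the protein's true cf exactly, closing the correction loop.

Crucially the generator emits residual binding from the *same* slope-1
one-site model the estimator inverts, $r(c) = 1/(1 + c\,\mathrm{cf}/K_d)$,
so with noise off the whole pipeline recovers every in-range Kd exactly
(relative error at machine precision) — the core closed-loop guarantee the
test suite asserts on a 50-compound × 300-protein panel, and the reason
two-dose and full-dose estimates correlate with Pearson r = 1 there.

What the generator does *not* emulate: peptide-level quantification and
razor-peptide effects, retention-time or batch drift, correlated noise
across wells, binding curves with hill slopes away from one, covalent or
slow-binding kinetics, and compound-dependent depletion. Passing tests
therefore validate the pipeline's arithmetic and its statistical behavior
under the stated noise model, not its robustness to every failure mode of
real data.

The phospho generator draws site baselines on the log2 scale (mean 20,
sd 2) and adds independent Gaussian channel noise (sd 0.25 log2 units);
regulated sites are shifted in the designated treatment channels. TMT
reporter channels within a run are essentially complete, so there is no
channel-level missingness; an optional per-replicate dropout removes whole
site × replicate blocks to exercise the 3-of-4 rule.

### Study-condition sizes

The tests and the acceptance script use: a 50 × 300 noiseless panel for
the exact-recovery and cross-design checks, a 20-compound × 1,500-protein
noisy panel for the replicate QC (pulldowns quantify thousands of
proteins, and specificity denominators of that order are what make small
absolute false-positive counts visible as rates in the fraction-of-a-
percent regime), 1,000 random selectivity panels, and the 1,050-site
(50 regulated, −1 log2 shift) phospho simulation. All complete in seconds
to a few minutes on one core.

### A note on the phospho operating point

At the phospho simulation's stated conditions (4 replicates, channel noise
0.25, $S_0 = 0.1$, 1% BH FDR over 1,050 sites) the S0-statistic of a true
2-fold shift is about 3.6 ± 0.7 while the pooled-null BH threshold sits
near 3.5 — the test operates at the edge of the information available in
four replicates, and realized power fluctuates roughly between 0.68 and
0.85 across seeds with the false-discovery proportion tightly controlled
(usually zero). This is a property of the design, not of the
implementation: even an oracle that knew the true variance would need the
pooled null to clear the BH threshold, and any per-site t null is
hopeless there.

## Numerical choices

* Residual clamp $\varepsilon = 10^{-3}$ bounds two-dose IC50s to
  $[\,[I]/999,\ 999[I]\,]$; estimates at the clamp are saturated, not
  extrapolated.
* 4PL optimizer: bounded `nlsLM`, objective tolerance 10^-12, inflection
  fitted on the log scale, 3 seeded restarts; ties in restart RSS keep the
  first solution. Bottom/top are swapped into $b \le t$ after fitting.
* Permutation p-values use the add-one convention,
  $p = (\#\{|d_0| \ge |d|\} + 1)/(N + 1)$.
* All randomness is seed-threaded: truth, plates, classifier training,
  restarts, and phospho tables reproduce byte-identically under a fixed
  seed.
* Correction factors: ratio capped at 1; a zero first pulldown with signal
  in the second yields cf = 1 with a warning; proteins without depletion
  data inherit the global median.

## Known limitations

Two-dose affinities are rough for weak interactions (everything beyond the
top dose is flagged, and estimates saturate near the residual clamp for
very strong binders). The classifier is retrained per run on rule-labeled
data — the published workflow's manually curated training set is not
recoverable, so probabilities are comparable within a run, not across
laboratories. CATDS depends on the called target set: missed weak targets
inflate selectivity. The S0 default is a convention, not an estimate; use
`estimate_s0()` when the variance structure of the data is unknown.
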