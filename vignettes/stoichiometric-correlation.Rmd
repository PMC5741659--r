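---
title: "Stoichiometric correlation analysis: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric correlation analysis: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichcor)
```

## The model

A metabolic network over species concentrations $x$ evolves as
$\dot x = N v(x)$, with $N$ the stoichiometric matrix and $v$ the rate
vector. Under mass action, $v_j = k_j \prod_i x_i^{\alpha_{ij}}$ over the
substrate stoichiometries $\alpha_{ij}$, so

$$\log v_j = \log k_j + \sum_i \alpha_{ij} \log x_i .$$

Two reactions are *coupled* when their rate ratio is constant over the
states considered (for example, every steady state of a given network
topology). On the log scale, coupling of reactions $p$ and $q$ means the two
integer-weighted sums $\sum_i \alpha_{ip}\log x_i$ and
$\sum_i \alpha_{iq}\log x_i$ differ by a constant — their Pearson
correlation over a state ensemble is exactly 1.

The stoichiometric correlation inverts this observation: for two disjoint
metabolite sets $U_p, U_q$ of size at most two, it is the maximum of
$\mathrm{cor}\!\left(\sum \beta_i \log x_i, \sum \eta_j \log x_j\right)$
over integer weights $\beta_i, \eta_j \in \{1,\dots,I_{\max}\}$. High values
flag candidate substrate complexes of coupled reactions without knowing the
network. It is a constrained maximal correlation: the admissible transforms
are exactly those mass action can produce, which keeps the statistic
estimable from the few dozen samples typical of metabolomics studies (the
unconstrained version requires far more data and is out of scope here).

Key assumptions, stated plainly:

* concentrations are strictly positive and measured on a ratio scale (logs
  must exist; any proportional normalization only shifts the logs and leaves
  correlations unchanged);
* elementary reactions are mass action — Michaelis–Menten and other
  saturating kinetics violate the log-linear form, and the package's
  simulation modules exist precisely to explore what that does to the
  statistic;
* samples (time points, conditions, accessions) are treated as exchangeable
  draws of the state ensemble; the analytic p-value additionally assumes
  approximate bivariate normality of the combined log profiles.

## The search and its invariances

Pearson correlation is invariant to positive affine maps of either side.
Hence a singleton side needs only the weight $(1)$, and a two-metabolite
side only one representative per weight *ratio*: the coprime pairs $(a,b)$,
$1 \le a,b \le I_{\max}$. For $I_{\max}=4$ that is 11 tuples instead of 16,
and the search over a quadruple split shrinks from $16\times16$ to
$11\times11$ grid points with provably identical maxima (the equivalence is
tested against an exhaustive grid oracle). The default $I_{\max}=4$ reflects
the largest stoichiometric coefficients commonly observed in metabolic
reactions; raising it can only increase the maximized correlation
(monotonicity is asserted in the tests).

Every unordered triple contributes its 3 pair-vs-singleton partitions and
every quadruple its 3 pair-vs-pair partitions, each counted as a separate
hypothesis; with $n$ metabolites the family has
$\binom{n}{2} + 3\binom{n}{3} + 3\binom{n}{4}$ members. Counting partitions
(rather than unordered subsets) makes every reported number reproducible
from the formula and is recorded in the output provenance. Splits are
canonical — members ascending, the side holding the smallest column index
first — and the enumeration order is deterministic, so identical inputs give
byte-identical outputs regardless of parallel or serial execution.

Both sides are log-transformed, including singleton sides: the statistic is
defined on log profiles throughout, and the invariance argument above would
fail otherwise.

Numerical tie handling: correlations within a relative $10^{-12}$ of the
maximum are ties; among ties the weight vector minimizing
$\lVert(\beta,\eta)\rVert_2$ is chosen, with lexicographic order on the
concatenation as the final deterministic tie-break. The smallest-norm rule
returns the most parsimonious stoichiometry consistent with the data (e.g.
unit weights rather than an equivalent scaled pair).

## Significance

The default p-value is the analytic two-sided correlation test,
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom, applied to the
maximized $r$. This ignores selection over the weight grid, and is kept as
the default because the grid is small, highly correlated across tuples
(the same data enter every candidate), and the familywise correction
below dominates in practice. For users who want the selection accounted
for, `permutation_pvalue()` re-runs the full maximization after permuting
the sample order of side B only, so the null distribution carries the same
selection effect; $p = (1 + \#\{r_b \ge r_{\mathrm{obs}}\})/(B+1)$.
The method used is labelled in the output provenance.

Benjamini–Hochberg is applied across the union of all tested splits of one
run — pairs, triplet partitions and quadruple partitions form a single
family. That is the conservative choice (the family is as large as it can
be) and avoids an arbitrary per-category split of the error budget.
Threshold comparisons are inclusive ($r \ge \tau$, $p_{adj} \le \alpha$).

Splits with fewer than 5 usable samples are skipped and logged, never
silently computed: with $n<5$ the correlation test has essentially no
resolution and degenerate fits are common.

Nonpositive or missing abundances are a hard error by default; the
`drop_sample` policy analyses complete cases per split and `offset` adds a
recorded constant. Silent imputation is deliberately not offered.

## Kinetic simulation

`simulate_network()` integrates $\dot x = N v(x)$ with deSolve's lsoda
(stiff-capable), relative tolerance $10^{-8}$, absolute $10^{-10}$.
Negative excursions are clipped to zero for rate evaluation and logged when
below $-10^{-9}$. Steady-state search integrates over a horizon of 1280
minutes and accepts when
$\lVert N v(x)\rVert_\infty \le 10^{-9}(1+\lVert x\rVert_\infty)$, doubling
the horizon up to 5 times before excluding a draw. The default time-course
grid is $t = 0$ plus 20 log-spaced points on $[1, 1280]$ minutes — dense
early coverage where transients live, matching the common design of
time-resolved metabolomics experiments; it is fully configurable.

Enzyme-complex expansion replaces a reaction by binding, unbinding and
catalysis elementary steps with defaults $k_{on} = k_{off} = 100$,
$k_{cat} = 1$. These sit deep in the quasi-steady-state regime
($k_{on}, k_{off} \gg k_{cat}$), where the scheme's flux provably
approaches $V_{\max} s/(K_m + s)$ with $V_{\max} = k_{cat} E_{tot}$,
$K_m = (k_{off}+k_{cat})/k_{on}$ — the regression tested to within 2%.

Two fixtures are shipped. The four-species cycle
`S1 + S2 -> S3 -> S4 -> S1 + S2` is the worked example: the closing
reaction uses the mass-conserving product complex `S1 + S2`, because a
variant producing `2 S1 + S2` cannot balance the S1 and S2 equations
simultaneously at any positive steady state — the shipped closure is the
unique completion with a well-defined steady-state ensemble. On that
ensemble the split $\{S_1,S_2\}$ vs $\{S_4\}$ attains $r = 1$ with unit
weights, which is the package's primary acceptance check. (The proportional
relation between $x_1$ and $x_2$ holds only on the invariant set
$x_1 = x_2$, since $x_1 - x_2$ is conserved; it is not asserted.)
The 11-metabolite single-loop fixture exists in three kinetic variants over
the identical species set — irreversible mass action, the same loop with
every reaction expanded into enzyme-complex elementary steps, and
reversible Michaelis–Menten ($V_f$ equal to the mass-action constants,
$V_r = 0.2$, all $K_m = 1$) — so the effect of the kinetic law on the
number of detected couplings can be compared on equal footing. Its rate
constants (spread over 0.7–1.3) and initial ranges (0.05–5, enzymes
0.05–0.5, complexes $10^{-3}$–$10^{-2}$) are generic order-one choices; the
package makes no claim that they match any published parameterization, so
the mass-action-versus-Michaelis–Menten count ordering is reported rather
than asserted.

## The synthetic benchmark

`generate_planted()` draws background metabolites i.i.d. log-normal with
unit log-variance — the multiplicative noise structure mass action induces —
and constructs each planted coupling so that
$\eta\cdot\log x_B = \beta\cdot\log x_A + \varepsilon$ with Gaussian
log-scale noise (for a two-member side B the first member is free and the
second solves the relation; the dependent variable is always on side B).
The standard recovery exercise uses 5 planted quadruples over 12
metabolites, 50 samples and noise sd 0.01, scored over 20 seeds at
$\tau = 0.95$, $\alpha = 0.05$.

What passing these tests shows: the search, significance machinery and
scoring are correct, and the method recovers exact log-linear couplings
under small multiplicative noise. What it does not show: performance on
real data, where couplings are approximate, noise is heteroscedastic and
correlated, metabolites are missing not at random, and saturating kinetics
bend the log-linear relation. The three-kinetics workflow probes the last
point qualitatively, but fixture parameters are not fitted to any organism.

## Problem sizes used in validation

The shipped tests and the acceptance script use: 50-draw steady-state
ensembles of the toy cycle; 200 random 10-sample matrices for the
grid-search equivalence oracle; brute-force enumeration cross-checks up to
$n = 12$ metabolites (closed form beyond); 20-seed benchmark and null
batteries at 12 metabolites by 50 samples; and 10 repetitions by 21 time
points for the three-kinetics comparison. These sizes give stable
Monte-Carlo estimates for every asserted quantity while keeping a full run
in the minutes range on a single core; all are parameters, not limits.

## Known limitations

* Weight bound $I_{\max}=4$ and side cardinality 2 are fixed defaults;
  reactions with more than two substrates or larger stoichiometries are
  invisible to the default search (the bound is configurable, the
  cardinality is not).
* The analytic p-value does not correct for maximization over the weight
  grid; use the permutation method when calibrated per-split p-values
  matter.
* Maximization is of the signed correlation; strong negative couplings are
  retained in the table but never pass the positive thresholds, matching
  the method's focus on rate-ratio maintenance.
* The overlap comparison matches metabolites by name (case-folded,
  whitespace-stripped); no synonym or identifier resolution is attempted.
* No stochastic (Gillespie) simulation and no SBML import; model files use
  the package's own plain-text schema.
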