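---
title: "Methods: expression-constrained steady-state modelling of hepatic tryptophan metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-constrained steady-state modelling of hepatic tryptophan metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`trpflux` implements a complete in-silico analogue of a common wet/dry
hybrid experiment: expose hepatocytes to two oxygen conditions, measure
gene expression with replicates, push the expression into a kinetic model
of tryptophan (Trp) metabolism, and ask which steady-state fluxes and
metabolite pools change significantly. This vignette documents the model,
its parameters, the numerical machinery, and the design decisions — with
the reasoning — so that a maintainer can judge every choice.

## The network

Dynamic intracellular species: Trp, kynurenine (Kyn), kynurenic acid
(KynA), 3-hydroxykynurenine (3HKyn), 3-hydroxyanthranilic acid (3HAA),
anthranilic acid (AA), quinolinate (Quin), a lumped NaMN/NAD-precursor
sink pool, tryptamine, N-methyltryptamine, N,N-dimethyltryptamine (DMT),
5-hydroxytryptophan, serotonin, and indole-3-pyruvate. Extracellular Trp
and Kyn are boundary species with clamped concentrations; because Trp_ext
is clamped, the model makes no prediction for extracellular Trp, and no
expectation is placed on intracellular Trp either.

Two deliberate lumpings keep the network at the granularity of the
readouts: TDO2 absorbs the fast N-formylkynurenine formamidase step, and
HAAO absorbs the non-enzymatic cyclization of ACMS to quinolinate. Neither
intermediate appears among the modelled readouts. KATs are represented by
one reaction driven by *Kyat1*; the xanthurenic-acid branch is omitted.
IDO1/2 are omitted because hepatic KP entry is carried by constitutively
expressed TDO2. Terminal products (KynA, AA, the NaMN pool, serotonin,
indole-3-pyruvate, DMT, and tryptamine via monoamine oxidase) receive
first-order clearances; without sinks the end products would accumulate
without bound and no steady state would exist.

### Rate laws

* Irreversible Michaelis–Menten, $v = V_{max} S/(K_m+S)$, for all enzymes.
* Antiport exchange for LAT1/LAT2:
  $v = V_{max}\,(S_{out}C_{in} - b\,S_{in}C_{out})\,/\,
  ((K_{m,S}+S_{out}+S_{in})(K_{m,C}+C_{in}+C_{out}))$
  with $S$ = Trp, $C$ = Kyn and reversibility bias $b$ (`keq_bias`,
  default 1). Net inward Trp transport is positive.
* First-order clearance $v = k\,S$.
* Optionally, oxygen-dependent enzymes (TDO2, KMO, HAAO, TPH1, IL4I1 —
  DDC, KATs, KYNU, QPRT, INMT and the transporters are oxygen-independent)
  are multiplied by $O_2/(K_{m,O_2}+O_2)$ with a global dimensionless
  oxygen level in $[0,1]$. This term is **off by default**: the study
  condition is encoded purely through expression scaling, and the oxygen
  term exists as an extension for users who want to superimpose direct
  kinetic oxygen limitation. As $K_{m,O_2}\to 0$ at $O_2=1$ the rates
  reduce exactly to the plain laws (tested).

### The antiport coupling fraction

The one place where the network deviates from the obvious textbook wiring
is the stoichiometry of the transporters. Write $J$ for total net Trp
import, $T$ for TDO2 flux, $B$ for the summed branch fluxes (DDC, TPH1,
IL4I1), and $K$ for the enzymatic Kyn consumption. If each imported Trp
exported exactly one Kyn, the node balances at steady state would be
$J = T + B$ (Trp) and $T = K + J$ (Kyn); adding them gives $0 = B + K$,
i.e. every branch and every Kyn-consuming flux must vanish — the only
steady state of the fully coupled network is the empty one, regardless of
parameter values. Physiologically the escape is that LAT1/LAT2 exchange
Trp against the whole system-L amino-acid pool, of which Kyn is only the
explicitly modelled component. The model therefore gives the Kyn
counter-flux a stoichiometric coupling fraction $\varphi$ (`kyn_coupling`,
default 0.5, configurable in $(0,1]$): each unit of imported Trp exports
$\varphi$ units of Kyn, the remainder of the counter-flux being amino
acids outside the model. The rate law is unchanged.

A second, subtler consequence of exchange-only entry is that the empty
state is always a fixed point (no counter-substrate, no transport), and
for weak antiport gain it is locally **stable** — trajectories can fall
into it, silently predicting a dead cell. The shipped baseline was chosen,
by linearizing around the empty state, so that the empty state is unstable
under both the normoxic and the hypoxic capacity scalings: high antiport
affinity for intracellular Kyn ($K_{m,C} = 0.1$), a small clamped
extracellular Kyn (0.01 model-units — large values feed the reverse,
Trp-exporting term precisely when intracellular Kyn is low), and weak
branch drain near the origin (branch $K_m = 10$). The uniqueness probe in
the test suite (two different initial states, identical steady state) and
the randomized solver-agreement checks guard this property.

## Baseline parameters

Concentrations are in model units (labelled "mM-equivalent" by default —
the label is configurable and deliberately noncommittal, because the
literature value of 10 for extracellular Trp sits at the upper bound of
blood measurements and plausibly reads as µM; the package follows the
printed value and exposes it as `trp_ext` rather than silently
"correcting" it). Time is in hours.

The kinetic constants of the underlying published hepatocyte model are not
reproduced in the source the analysis follows, so the defaults in
`inst/extdata/trp_parameters_v1.yaml` are this package's own design,
constructed to satisfy five explicit constraints, in this order:

1. **Sub-saturation everywhere.** Every steady-state substrate sits within
   roughly an order of magnitude of its $K_m$ (normoxic baseline: Trp ≈ 2
   vs $K_m^{TDO2}=2$; Kyn ≈ 0.5 vs 1; 3HKyn, 3HAA, Quin ≈ 0.8 vs 1;
   tryptamine ≈ 0.06 vs 0.5). If an enzyme were saturated, scaling its
   substrate supply would not move its flux and the expression signal
   would be masked.
2. **KP dominance.** TDO2 carries ~95% of intracellular Trp consumption at
   baseline, as it does in liver.
3. **Feasible chain capacities.** Every downstream capacity exceeds its
   steady influx (KYNU_b, HAAO, QPRT at 6 vs influx ≈ 2.7), otherwise an
   intermediate diverges and no steady state exists.
4. **Empty-state instability** in both conditions, as above.
5. **Tryptamine accumulation.** Monoamine-oxidase clearance (2 h⁻¹)
   dominates INMT in tryptamine disposal; if INMT dominated, the hypoxic
   up-scaling of *Inmt* (×2.5) would outrun the doubled DDC production and
   tryptamine would *fall* despite increased synthesis.

These constraints were resolved by hand (two-node balance algebra plus
linear stability at the origin) before the end-to-end comparisons were
run; the resulting round numbers are frozen in the versioned parameter
file and are not adjusted afterwards.

## Expression integration

Scaling factors are per-gene ratios to the reference-condition mean, so
the reference mean maps to 1 by construction. The default transform is
linear ($V_{max} \propto$ expression ratio): capacity proportional to
enzyme amount, enzyme amount proportional to transcript on the linear
scale. A log-linear alternative (`transform = "log_linear"`) is exposed as
a hook. Scaling is per replicate — three expression replicates per
condition yield three parameterizations and three steady states per
condition — because the downstream statistics (mean ± SEM, n = 3, t-test)
need replicate-level modelled values, exactly as the bar plots they mirror.
Only `Vmax` is ever touched; $K_m$, clearance constants and boundary
concentrations are invariant under expression (tested field-wise). Gene
symbols are matched case-insensitively after trimming; genes with no
mapped reaction (e.g. the hypoxia marker *Ndrg1*) are reported and ignored,
and their presence provably never changes results (tested).

## Steady-state computation

`steady_state()` integrates $dC/dt = N v(C)$ with `deSolve::lsoda`
(automatic stiff/non-stiff switching; rtol 1e-10, atol 1e-12) over
geometrically growing time chunks (1, 10, 100, … up to `t_max`, default
1e6 h) until the COPASI-style relative rate criterion
$\max_i |dC_i/dt| \le tol\,\max(1,|C_i|)$ holds, with `tol` defaulting to
1e-9 per unit time. The integrator runs without non-negativity clipping;
inside the derivative callback rates are evaluated on the non-negative
cone (`pmax(y, 0)`), and the final state is validated against dips below
$-10\,\varepsilon_{machine}$ and clamped to zero with a logged notice.

The default method (`hybrid`) then polishes the relaxation solution with a
damped Newton iteration on $F(C) = N v(C)$: finite-difference Jacobian,
step halving on any step that would go negative or fail to reduce
$\|F\|_\infty$, a ridge-damped retry on a singular Jacobian, and an
explicit divergence flag if the state grows 1e6-fold beyond the guess.
Newton typically lands at residuals near machine precision, which is what
makes the per-replicate outputs byte-reproducible across runs. Two
guards matter:

* the hybrid **polishes, never rescues**: if relaxation did not converge,
  the non-converged relaxation result is returned. The relative criterion
  alone can be satisfied by a divergent system at absurdly large
  concentrations (bounded $|F|$, huge $|C|$), so Newton is only trusted
  near a genuine root;
* a non-converged replicate is excluded from the statistics with a
  warning, and fewer than two converged replicates per arm flags every
  quantity untestable (NA p-values) rather than producing fabricated
  significance.

Relaxation and Newton (started from an independently perturbed guess) are
required to agree to 1e-6 relative on concentrations and fluxes across
randomized parameterizations. Randomized draws jitter all kinetic
constants by 20% lognormal; a small fraction of such draws push a
downstream capacity below its steady influx, in which case no steady state
exists and the draw is resampled — agreement is a property of solutions,
not of infeasible networks.

## Differential statistics

Per quantity (22 fluxes, 14 concentrations): condition means, SEMs, fold
change hypoxia/normoxia on the linear scale (bar-plot semantics), an
unpaired two-tailed t-test, significance codes `ns`/`*`/`**`/`***`/`****`
at p ≤ 0.05/0.01/0.001/0.0001, and a direction call (`up`/`down` only when
significant, else `flat`). The source protocol says "unpaired two-tailed
Student's t-tests" without fixing the variance assumption; at n = 3 the
choice can matter, so **both** Welch and pooled-variance p-values are
carried in every output (`p_welch`, `p_student`) and `test=` selects which
drives the codes — Welch by default, as the safer assumption under
condition-dependent variance. No multiple-testing correction feeds the
codes (matching per-quantity stars); a Benjamini–Hochberg column is
emitted as supplementary output. Replicate-identical data (the cv = 0
synthetic limit) make `t.test` error on constant input; the package
substitutes the degenerate limit p = 0 when the means differ and p = 1
when they coincide, so noise-free runs are maximally significant rather
than broken.

`sign_pattern()` compares the direction calls against an expectation set.
The shipped default encodes the hypoxic rewiring: transporter and all KP
fluxes down, tryptamine-branch fluxes up, Kyn/3HAA/Quin down, tryptamine
up; TPH1 flux, KynA, indole-3-pyruvate and all remaining quantities are
deliberately unconstrained (TPH1 only trends, KynA lacks sufficient
enzymatic parameters for a defensible call, and the serotonin/I3P pools
are not read out).

## The synthetic generator

`generate_expression()` emulates the input the pipeline would receive from
a normoxia/hypoxia microarray experiment: for each gene, per-condition
replicate values $baseline \cdot fc \cdot \epsilon$, with mean-corrected
log-normal noise $\epsilon$ ($\sigma^2_{\log} = \log(1+cv^2)$, so
$E[\epsilon]=1$ and the sample mean converges to $baseline\cdot fc$ —
tested at n = 10⁴). Defaults: cv = 0.1, n = 3, baseline 100. The fold
changes (Tdo2 0.1, Kmo 0.4, Kynu 0.5, Kyat1 0.5, Slc7a5 0.5, Slc7a8 0.5,
Haao 0.6, Qprt 0.6, Ddc 2.0, Inmt 2.5, Tph1 1.3, Il4i1 1.0, Ndrg1 8.0) are
**fixture choices encoding only the published directions of regulation**;
the source figures are plots without printed values, so no magnitude here
is presented as ground truth, and all are configurable. Log-normal noise
was chosen for positivity and scale-invariance. The generator is
deterministic given its seed and restores the caller's RNG state.

What the generator does *not* emulate: probe-level microarray structure,
normalization artefacts, gene–gene correlation, and condition-dependent
variance. Passing tests therefore demonstrate that the pipeline correctly
propagates directional expression changes of this magnitude through the
kinetic model under realistic replicate noise — not that it reproduces any
particular laboratory's numeric fluxes.

`generate_metabolite_fixture()` produces the matching measurement-side
fixture: steady-state concentrations under multiplicative noise with
left-censoring below a detection limit ("nd" entries), for end-to-end
tests against measured-panel file formats.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; `run_pipeline()` writes its
fully resolved configuration, a log of machine-parsable notices (unmapped
genes, clamped negatives, excluded replicates), and a manifest with MD5
hashes of all outputs. Numeric files are written at 12 significant digits
for diffability. The shipped checks use the study-sized problem
throughout — the full 16-species/22-reaction model, n = 3 replicates per
condition, cv = 0.1, 20 randomized draws for solver agreement, a 100-fold
capacity sweep for monotonicity — sizes at which the whole suite completes
in well under a minute on one core.

## Known limitations

* The model is this package's own construction from the published enzyme
  and metabolite panel; equivalence with the previously published
  hepatocyte Trp model it is inspired by is not claimed, and absolute
  fluxes/concentrations are in arbitrary-but-consistent model units. The
  defensible output is the sign-and-significance pattern.
* No reversible thermodynamics beyond the antiport bias factor; no NAD
  salvage; no albumin-bound/free Trp equilibrium; no xanthurenic-acid
  branch; no multistability or metabolic control analysis.
* The t-tests treat the three scaled parameterizations as independent
  biological replicates, mirroring the study design; they inherit all
  small-n caveats of that design.
* With exchange-only Trp entry the empty state always exists as a fixed
  point; outside the designed parameter regime (e.g. extreme user
  parameter files) trajectories may legitimately converge to it, and the
  uniqueness of the reported steady state is probed numerically, not
  proven globally.
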