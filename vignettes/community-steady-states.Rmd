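---
title: "Finding all steady states of microbial community models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding all steady states of microbial community models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commsteady)
```

## The modelling problem

Constraint-based models describe each microbial species $i$ by a
stoichiometric matrix $S_i$ with intracellular steady state
$S_i \nu_i = 0$ and capacity constraints $A_i \nu_i \le b_i(C)$ on the
flux vector $\nu_i$, one component of which, $\nu_{\mu,i}$, is the
specific growth rate. A community couples the species through a shared
pool of extracellular compounds. `commsteady` finds **all** metabolically
stationary states of such a community without simulating transients,
under four combinations of assumptions:

* **Environment.** In a *chemostat* (modes `CA`, `CC`) a dilution rate
  $D$ supplies nutrients at inflow concentrations $C_{in}$ and washes
  out compounds and cells; stationarity requires
  $D (C_{in} - C) = \sum_i T_i \nu_i X_i$ for the extracellular
  concentrations $C$ and absolute abundances $X$, and *D-growth*
  $X_i (\nu_{\mu,i} - D) = 0$ for every species. In a *steady-state
  batch* (modes `BA`, `BC`) concentrations are non-limiting and
  unrepresented; instead, culture uptake bounds $u$ cap the total
  exchange $\sum_i T_i \nu_i x_i$, the relative abundances satisfy
  $\sum_i x_i = 1$, and all present species share one growth rate
  $\nu_\mu^\star$.
* **Decision making.** Under the *rational agent* assumption (`CA`,
  `BA`) every species independently maximises its own growth rate given
  the extracellular concentrations (through concentration-dependent
  uptake bounds $b_i(C)$, restricted to piecewise-linear concave
  functions). Under the *rational community* assumption (`CC`, `BC`) a
  hypothetical community-level optimiser chooses all fluxes — and, in
  the chemostat, the concentrations — to maximise a community
  objective: total biomass production $\sum_i \nu_{\mu,i} X_i$ by
  default, or the summed growth rate $\sum_i \nu_{\mu,i}$ of the
  present species (`objective = "sum_growth"`).

Because every inner optimisation problem is a linear program, its
Karush-Kuhn-Tucker (KKT) conditions are necessary *and sufficient*.
Substituting them for the `argmax` operators turns each model variant
into a system of polynomial equations and inequalities — stationarity
rows $A_i^\top \lambda_{1,i} + S_i^\top \lambda_{2,i} = e_{\mu,i}$ (per
species for the agent modes; one joint block over fluxes and
concentrations for `CC`), sign conditions, and multiplicative
complementary slackness $\lambda_1 \odot q = 0$, where $q$ stacks the
capacity slacks $A\nu - b(C)$ and, in `CC`, the concentration signs
$-C$. `assemble_system()` builds this system; `residual()` evaluates a
candidate exactly, with inequality violations entering as
$\max(0, \cdot)$ hinge terms.

## Two solution routes

### Active-set enumeration (small models)

Every steady state lies on a *branch*: each inequality/multiplier pair
is either active (constraint tight, multiplier free and non-negative)
or inactive (multiplier zero), and each species is either absent or
growing at the required rate. `enumerate_solutions()` traverses the
branch space depth-first and prunes a subtree only when a **linear
relaxation** of the branch prefix is infeasible as an LP. The
relaxation keeps every linear row, lifts the bilinear chemostat mass
balance with abundance-weighted fluxes $\varphi_i = X_i \nu_i$ (whose
cone constraints are inherited from $\nu_i$), and divides the `CC`/`BC`
stationarity rows of present species by their (positive) abundance so
that they become linear in scaled multipliers. Dropping or rescaling
rows only enlarges the feasible set, so pruning never discards a
feasible branch.

Two design choices keep the enumeration exact but economical:

* **Canonical labelling.** A pair assigned *inactive* must show a slack
  of at least $10^{-7}$ in the relaxation, so each steady state is
  enumerated under the branch matching its exact active set; a
  constraint that is tight with a zero multiplier is found on its
  active branch, where the multiplier is merely required to be
  non-negative. States in which a nominally inactive constraint has
  slack below $10^{-7}$ would be missed; all constraint scales used
  here are of order one.
* **Decoupled absent species.** A species with $X_i = 0$ contributes
  nothing to the mass balance, so its single-species KKT subsystem is
  solved separately (one LP for the optimal fluxes, one for
  multipliers) and attached afterwards; its pairs are never enumerated.

Surviving leaves are square polynomial systems, solved in stages:
fluxes and concentrations from the active linear rows, abundances from
the mass balance, multipliers from the stationarity rows (a linear
least-squares problem, or an LP when degenerate). When a stage is
rank-deficient the leaf holds a solution *continuum*; the abundance
stage is then resolved by singular value decomposition into the
minimum-norm point plus seeded null-space samples, and fully coupled
leaves fall back to a damped Levenberg-Marquardt multistart (one
deterministic start plus `n_starts` seeded random starts; the spirit of
a large multistart is retained, but the analytic Jacobian, a full-rank
test at the first root, and a cap on consecutive failures keep the
budget at a handful of runs per branch). Band representatives are
polished by repeatedly minimising the abundance norm along the tangent
space of the root manifold, which lands exactly on the symmetric member
of affine bands.

Every accepted state must pass `residual()` below $10^{-8}$ **and** an
independent certificate: `verify_inner_optimality()` re-solves the
inner linear program at the candidate's outer variables and requires an
optimality gap below $10^{-6}$, independently of the multipliers.

### Grid + refinement (larger chemostat models)

For models beyond the enumeration budget, the chemostat systems are
solved numerically in two stages, mirroring how such bilevel systems
are handled at genome scale:

1. **`map_grid()` / `solve_at_point()`.** The abundance vector is fixed
   to a linearly spaced grid. At fixed $X$ every equation is linear
   except complementary slackness, which is linearised with binary
   activation variables $\Delta$ and a big-M constant $\Omega$
   (`choose_omega()` uses ten times the largest of the inflow
   concentrations, the constant bound pieces, the dilution-scaled
   inflow, and one; any solution approaching $0.99\,\Omega$ triggers an
   automatic re-solve at $10\,\Omega$). The equalities that contain the
   fixed abundances — mass balance and D-growth — receive paired
   non-negative slacks, and a small branch-and-bound MILP minimises the
   L1 slack sum. Both the L1 optimum and the maximal violation are
   reported. Piecewise bounds are handled exactly by enumerating
   active-piece combinations, each with linear validity cuts, so every
   MILP stays linear. The default per-point time limit is 60 s;
   incumbents at the limit are kept and flagged.
2. **`refine()`.** Each grid candidate seeds a Levenberg-Marquardt
   minimisation of the sum of squared violations (equalities, hinge
   terms, and the multiplicative complementarity products) with the
   abundances released, so candidates migrate off the grid.
   `accept_solutions()` then keeps exactly the candidates with maximal
   violation below $10^{-8}$ and a certified inner optimum, and
   `dedupe_solutions()` merges states within $10^{-6}$ in
   abundance/concentration space — one hundred times the acceptance
   threshold, separating numerical duplicates without merging members
   of a discretised band.

All linear programming is done by a dense two-phase simplex written for
this package (no LP library is part of the declared tool chain); the
hot paths run in compiled code, and the test suite cross-checks optima
against the recommended `boot::simplex` routine on random programs.

## Worked example

The two-species crossfeeding community (`pd_network()`) pits individual
against community interests: each species can make both required
compounds but one of them only expensively, so mutual secretion raises
community yield while unilateral defection raises individual yield.

```{r pd, eval = FALSE}
m <- pd_network()
agent <- enumerate_solutions(m, environment_spec("CA", D = 0.5,
                                                 C_in = c(10, 0, 0)))
community <- enumerate_solutions(m, environment_spec("CC", D = 0.5,
                                                     C_in = c(10, 0, 0)))
```

Rational agents never crossfeed: the substrate settles at $C_S = 3D$
and the coexistence states form a continuum $X_1 + X_2 = (10 - 3D)/3$
(reported as isolated representatives including the symmetric one). The
rational community at low flow secretes both compounds — uptakes of
$0.5$ against secretions of $0.627$, the difference being washed out —
and abandons crossfeeding altogether when the flow rate rises to
$D = 1.2$.

## Synthetic data and what the tests show

The package generates all of its study systems in code:

* `pd_network()` and `coexistence_network()` implement the two
  published toy communities. The growth stoichiometries (2,1)/(1,2) of
  the coexistence pair are a package choice satisfying the published
  asymmetry description; its quantitative sweep curves are therefore
  validated against this package's own closed forms, not against
  published curve values.
* `random_community()` provides seeded random communities for property
  tests (uptake chains guarantee a non-trivial flux cone).
* `synthetic_syntrophic_pair()` is a deliberately minimal stand-in for
  an amino-acid-auxotroph pair: two strains consume glucose, each
  requires two "amino acids" and can synthesise exactly one of them
  from glucose. With glucose in excess and trace supplements
  (`synthetic_syntrophic_env()`: $D = 0.1$, inflow $(10, 0.2, 0.2)$,
  uptake caps equal to the concentrations, half-unit amino-acid demand
  per unit growth), growth is limited by the crossfed compounds, and
  the rational-agent model opens a *band* of coexistence states fed by
  wasteful glucose allocation while the community model selects
  isolated states — the qualitative mechanism of interest. It is not
  derived from any genome-scale network; passing tests on it say
  nothing about any particular organism, only about the solver and the
  mechanism. Genome-scale auxotroph pairs can be built from user-supplied
  SBML files with `syntrophic_pair()`, whose kinetic bound pieces,
  knockouts and medium are configuration, not built-in values.

Problem sizes in the test suite and the acceptance script are chosen to
exercise every code path on one CPU: enumeration on the toy fixtures,
grid maps of up to $3 \times 3$ points, and an 11-point inflow sweep.
The published 50-by-50 residual maps of the genome-scale case are
reproduced in mechanism (same two-stage scheme), not in size.

## Numerical choices and limitations

* Acceptance threshold $10^{-8}$ on the maximal violation; inner-LP
  gap $10^{-6}$; deduplication $10^{-6}$; strict-slack margin
  $10^{-7}$; support threshold $X_i > 10^{-9}$ for "present".
* At a kink of a piecewise-linear bound the `CC` stationarity rows are
  scored with every adjacent piece gradient and the best combination is
  used (subgradient selection).
* The sum-of-growth objective weight $\delta(X_i > 0)$ is fixed per
  branch to the declared support, which keeps each branch polynomial.
* The batch-agent variant `BA` is assembled for completeness; a
  community steady state under it requires unrelated species to share
  the exact same maximal growth rate, so in practice it only admits
  single-species or trivial states.
* Enumeration reports continua through representatives; completeness is
  up to root-finding coverage on the (rare) fully coupled degenerate
  branches, which the test suite cross-checks against closed forms.
* The grid stage inherits the usual grid-resolution caveat: a steady
  state far from every grid point can be missed if refinement stalls in
  a local minimum.
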