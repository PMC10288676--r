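# commsteady

Microbial communities modelled with constraint-based (flux balance)
metabolic networks can settle into **multiple** metabolically stationary
states, and which states exist depends on two modelling assumptions that
are usually made implicitly: the **cultivation environment** (chemostat
with dilution rate *D* and inflow concentrations *C<sub>in</sub>*, or a
steady-state batch with culture uptake bounds *u*) and the **decision
maker** (each species maximising its own growth — *rational agent* — or
a community-level optimiser maximising total biomass production or the
summed growth rate — *rational community*). `commsteady` implements the
four resulting model variants (`CA`, `CC`, `BA`, `BC`) and finds **all**
their steady states directly, without simulating transients.

## Models and method

Each species *i* carries a stoichiometric matrix with intracellular
steady state *S<sub>i</sub>ν<sub>i</sub> = 0*, capacity constraints
*A<sub>i</sub>ν<sub>i</sub> ≤ b<sub>i</sub>(C)* (piecewise-linear
concave in the extracellular concentrations *C*), a growth flux
*ν<sub>μ,i</sub>*, and an exchange map *T<sub>i</sub>* coupling it to
the shared compound pool. A chemostat steady state requires

- *D (C<sub>in</sub> − C) = Σ<sub>i</sub> T<sub>i</sub>ν<sub>i</sub>X<sub>i</sub>* (mass balance),
- *X<sub>i</sub>(ν<sub>μ,i</sub> − D) = 0* (D-growth), and
- inner optimality of the fluxes (agent: per species at given *C*;
  community: jointly over fluxes and concentrations at given abundances *X*).

Because every inner problem is a linear program, its KKT conditions are
sufficient, and substituting them yields one polynomial system per
variant whose zeros are exactly the steady states. The package solves
these systems two ways:

1. **Active-set enumeration** (`enumerate_solutions()`): complete
   depth-first enumeration of complementarity/support branches with
   sound LP-relaxation pruning; exact linear solves per branch, damped
   Levenberg–Marquardt on the few genuinely coupled branches, and
   independent certification of every accepted state by re-solving the
   inner LP (`verify_inner_optimality()`).
2. **Abundance-grid MILP + refinement** (`map_grid()`, `refine()`):
   the published two-stage numerical scheme — fix *X* to a grid,
   linearise complementary slackness with big-M binaries, minimise
   paired slacks on the abundance-coupled equalities per point, then
   release *X* and polish by least squares; accept at maximal
   violation < 10⁻⁸.

## Worked example

The built-in two-species crossfeeding community (`pd_network()`) is a
metabolic prisoner's dilemma: both species need compounds A and B, each
produces one of them at half the partner's yield, and transporters are
bidirectional, so mutual secretion raises community yield while
defection raises individual yield.

```r
library(commsteady)
m <- pd_network()

agent <- enumerate_solutions(
  m, environment_spec("CA", D = 0.5, C_in = c(10, 0, 0)))
community <- enumerate_solutions(
  m, environment_spec("CC", D = 0.5, C_in = c(10, 0, 0)))

symmetric <- function(sols)
  Filter(function(s) abs(s$X[1] - s$X[2]) < 1e-6 && sum(s$X) > 1, sols)[[1]]

symmetric(agent)       # the symmetric rational-agent representative
#> steady_state_solution
#>   abundances: 1.417 1.417
#>   C: 1.5 0 0
#>   residual_max: 0

symmetric(community)   # the symmetric community crossfeeding state
#> steady_state_solution
#>   abundances: 1.968 1.968
#>   C: 1.127 0.5 0.5
#>   residual_max: 2.220446e-16

round(symmetric(community)$nu$sp1, 3)
#>    t_S    t_A    t_B    r_A    r_B     mu
#>  1.127  0.500 -0.627  0.000  1.127  0.500
```

Rational agents refuse to crossfeed: the substrate settles at
*C<sub>S</sub> = 3D = 1.5* and the coexistence states form the segment
*X₁ + X₂ = 17/6* (reported as representatives, including the symmetric
one). The rational community secretes 0.627 units of each compound to
deliver 0.5 to the partner — the rest is flushed out — and abandons
crossfeeding altogether at *D = 1.2*. `net_exchange()` reports
per-species secretion/uptake scaled by abundance, and
`write_solutions()` serialises accepted sets to CSV or JSON.

A command-line front end over the same functions is installed at
`inst/cli/commsteady.R` (`enumerate`, `map-grid`, `sweep`; scenarios in
YAML/JSON via `read_scenario()`).

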