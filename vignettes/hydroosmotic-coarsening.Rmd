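---
title: "Hydro-osmotic coarsening of lumen chains: model and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydro-osmotic coarsening of lumen chains: model and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumenchain)
```

## The model

`lumenchain` simulates the collective dynamics of fluid-filled
intercellular cavities (lumens) arranged along a one-dimensional chain and
coupled through the thin intercellular space, as during blastocoel
formation in early embryos. Each lumen is a two-dimensional lens of
half-length $L_i$ under constant membrane tension $\gamma$, so its Laplace
overpressure is $\delta P_i = \gamma\sin\theta/L_i$ with contact angle
$\theta = \arccos(\gamma_c/2\gamma)$. The lens geometry ties area to
half-length, $L = \sqrt{\mu A}$ with
$\mu = \sin^2\theta/(2\theta - \sin 2\theta)$, and the membrane arc length
is $2\nu L$ with $\nu = \theta/\sin\theta$. Each lumen also carries $N_i$
moles of a single uncharged solute at homogeneous concentration
$C_i = N_i/A_i$. The surrounding cells act as a chemostat (concentration
$c_0$) and barostat (pressure $p_0$).

Two transport routes couple the lumens:

* **lateral membrane exchange** - osmotic water flux
  $\propto \lambda_v (RT\,\delta C_i - \delta P_i)$ and passive solute
  leakage $\propto \lambda_s$, optionally augmented by an active pumping
  rate $j^a$ (ATP-driven solute import);
* **longitudinal bridge fluxes** - 2-D Poiseuille flow
  ($q = -\kappa_v \partial_x \delta p$, $\kappa_v = e_0^3/12\eta$) and
  Fickian diffusion along the bridge of thickness $e_0$ connecting
  adjacent lumens.

Because bridge walls are themselves permeable membranes, longitudinal
gradients are screened over the lengths
$\xi_v = \sqrt{\kappa_v/2\lambda_v}$ and
$\xi_s = \sqrt{D e_0 c_0 / 2\lambda_s RT}$. The dimensionless screening
numbers $\chi_{v,s} = \xi_{v,s}/\ell_0$ (bridge lengths rescaled by their
initial mean $\ell_0$) are the model's principal control knobs: lumens
further apart than $\xi_v$ are hydraulically deaf to each other.

In dimensionless variables (half-lengths in units of the mean initial
lumen scale, times in units of the solvent equilibration time
$\tau_v = L_0/2\lambda_v \Pi_0$, moles in units of $N_0 = c_0 L_0^2$,
pumping in units of $\lambda_s RT$) the lumen dynamics reads

$$\frac{d\bar L_i}{d\bar t} = \mu\nu\Big[\frac{\mu \bar N_i}{\bar L_i^2}
  - 1 - \frac{\epsilon}{\bar L_i}\Big] - \frac{\mu}{2\bar L_i}\bar J_i^v,
  \qquad
  \frac{\tau_s}{\tau_v}\frac{d\bar N_i}{d\bar t} =
  2\nu \bar L_i\Big[1 - \frac{\mu \bar N_i}{\bar L_i^2} + \bar j^a_i\Big]
  - \bar J_i^s,$$

with $\epsilon = \gamma\sin\theta/L_0\Pi_0$ the tension-to-osmotic
pressure ratio ($\Pi_0 = RT c_0$; $\epsilon \lesssim 10^{-2}$ in embryos)
and $\tau_s = L_0 c_0/2\lambda_s RT$ the solute relaxation time. Lumen
centers are fixed; every bridge length is recomputed from the geometry at
each evaluation, which enforces conservation of the total chain length
identically, including across topological events.

A note on conventions: the package treats these printed dimensionless
equations as canonical. Nondimensionalizing the dimensional solute-balance
equation term by term yields a lateral prefactor $\nu \bar L_i$ rather
than $2\nu \bar L_i$ (a factor that amounts to counting one or both
membrane faces); since only the dimensionless system is ever integrated,
this affects nothing inside the package, but users converting their own
dimensional parameter sets should be aware the converter follows the
printed timescale definitions verbatim.

## The bridge solution

With $\delta C_i,\ \delta c \ll c_0$ the bridge equations linearize to

$$\bar\xi_s^2\, \delta\bar c'' = \delta\bar c - \bar j^a, \qquad
  \bar\xi_v^2\, \delta\bar p'' = \delta\bar p - \delta\bar c,$$

solved analytically on $[-\ell/2, \ell/2]$ with Dirichlet data taken from
the adjacent lumens (concentration first, then pressure with the
concentration as osmotic source). The boundary fluxes
$\bar J^v = -\bar\xi_v^2 \delta\bar p'$ and
$\bar J^s = -\bar\xi_s^2 \delta\bar c'$ close the lumen ODEs. Numerical
care:

* hyperbolic terms are evaluated through `tanh`/shifted exponentials so
  strongly screened bridges ($\ell \gg \xi$) cannot overflow;
* when $\xi_v$ and $\xi_s$ are within a relative $10^{-6}$ the particular
  solution degenerates and the secular form $x\sinh(x/\xi)$ is used; the
  switch is verified to be continuous;
* sealed chain borders are handled by the method of images (a wall bridge
  of length $\ell$ is the half of a symmetric bridge of length $2\ell$),
  so the zero-flux condition at the wall is exact.

The closed-form coefficients are certified against an independent
second-order finite-difference boundary-value solver
(`fd_oracle_bridge()`) to a relative $10^{-6}$ in the test suite.

## Event-driven integration

The chain ODEs are integrated with an adaptive Runge-Kutta-Fehlberg 4(5)
scheme (classic Fehlberg tableau, error-controlled steps, default
tolerances `rtol = 1e-6`, `atol = 1e-8`). After each accepted step two
thresholds are checked: collapse, $\bar L_i \le L_{\min}$, and collision,
$\bar\ell_{ij} \le \ell_{\min}$. A crossing is localized by bisection on
the step (relative time tolerance $10^{-6}$), the integration halts, the
chain is rewritten, and integration restarts:

* **collapse** - the lumen is deleted; its two bridges fuse into one of
  combined length $\ell_l + \ell_r + 2\bar L_i$ (automatic from the fixed
  geometry); the residual moles (bounded by the threshold scale) are
  discarded rather than donated to the quasi-static bridge;
* **coalescence** - instantaneous merge conserving area and moles
  ($A' = A_i + A_j$, $N' = N_i + N_j$, $L' = \sqrt{\mu A'}$), centered at
  the area-weighted centroid; neighboring bridges only lengthen under
  this rewrite, so no overlap can result;
* **wall contact** - under pumping an end lumen can grow into the sealed
  border, a situation the continuum model leaves undefined. The package
  slides the lumen center inward (a center translation exchanges length
  between the lumen's two bridges, so total length is conserved exactly)
  and falls back to merging with the neighbor when no interior slack
  remains. Wall contacts never change the lumen count.

The model itself provides no microscopic cutoffs; the defaults
$L_{\min} = 10^{-2}\langle \bar L(0)\rangle$ and
$\ell_{\min} = 10^{-2}\bar\ell_0$ are numerical knobs, and the test suite
checks that the coarsening exponent is insensitive to halving them.
Integration ends at `t_end`, or early once one lumen remains - its
endgame is decided by the isolated-lumen criterion (growth if
$\bar j^a \ge \epsilon/\bar L$, collapse otherwise) instead of being
integrated, which avoids spending steps on a foregone conclusion.

The stepping loop and right-hand side run in compiled code; an R
reference right-hand side assembled from the analytic bridge solver is
exported (`chain_rhs()`) and the two are required to agree to $10^{-12}$
in the tests. An independent cross-check integrates a two-lumen fixture
with `deSolve` between events.

## Scenarios and the synthetic chain generator

`generate_chain()` draws lumen areas from $\mathcal N(1, 0.2^2)$ and
bridge lengths from $\mathcal N(10, 2^2)$ (the study's stated initial
conditions), redrawing non-positive values so the distribution shape is
preserved, and places lumens sequentially from the left wall; every lumen
starts at osmotic equilibrium ($\bar C_i = 1$). The generator emulates the
*initial* disorder of a microlumen network; it does not model nucleation,
spatial correlations between neighboring lumen sizes, or mechanical
heterogeneity of the surrounding cells, so passing tests speak to the
coarsening dynamics given such an initial state, not to how real embryos
arrive at it.

Defaults chosen where the study conditions leave freedom, fixed once and
documented here:

* $\theta = \pi/3$ (adhesive tension equal to membrane tension), a
  generic value for adhered membranes; the scaling results do not depend
  on $\theta$;
* $\epsilon = 10^{-3}$: within the embryo-motivated range
  $\epsilon < 10^{-2}$, and the unique decade consistent with the
  published two-lumen fate quartet, whose collapse/rescue boundary is the
  isolated-lumen criterion $\bar j^a \lessgtr \epsilon/\bar L$ with
  pumping rates $3.2\times10^{-4}$ and $3.2\times10^{-3}$ on either side;
* two-lumen experiments use mean half-length 1 and all three bridges of
  length $\ell_0$ ($\bar\ell_0 = 1$, the value the study's illustrative
  two-lumen material also uses).

The two-lumen fate (`classify_fate()`) is the first qualitative outcome:
coalescence if a merge occurred, otherwise the signs of the area changes
over the three last steps decide collapse (both shrink) versus coarsening
(one grows; *reversed* if the initially smaller lumen wins). Because
adaptive steps become arbitrarily fine next to a collapse - where the
dying lumen's final discharge gives its partner a machine-scale,
physically irrelevant uptick - the "three last steps" are taken on a
stepper-independent checkpoint grid spanning the last 6% of the pre-event
dynamics. An indeterminate sign pattern raises an error rather than
guessing.

```{r fate-example}
ch <- two_lumen_state(size_ratio = 1.1, ja1 = 3.2e-3, chi_v = 0.68,
                      chi_s = 1)
classify_fate(integrate_chain(ch, 5e3, record_steps = TRUE))
```

## The instantaneous flow diagram

`net_two_lumen_flow()` maps relative asymmetries of concentration and
pressure, $\Delta_C = (C_2 - C_1)/(C_1 + C_2)$ and
$\Delta_P = (P_2 - P_1)/(P_1 + P_2)$, to the signed net solvent flow
between two lumens. The asymmetries act on the *absolute* pressures and
concentrations around the external references ($P_i = p_0(1 \mp \Delta_P)$,
$C_i = c_0(1 \mp \Delta_C)$, with $p_0 \sim \Pi_0$). This choice matters:
a pressure asymmetry drives the longitudinal Poiseuille flux directly,
whereas a concentration asymmetry acts only through the osmotic source of
the pressure profile, which is why reversing the flow demands a far
larger $\Delta_C$ than $\Delta_P$ - the mechanism behind the robustness
of pressure-driven coarsening to passive osmotic heterogeneity. (Tying
the asymmetries to Laplace-realizable states instead would scale the
pressure data by $\epsilon$ and invert this conclusion; we verified and
rejected that reading.)

## Mean-field hydraulic chain

In the limit $\chi_v \gg 1$, $\chi_s \ll 1$, $\tau_s \ll \tau_v$ solutes
relax instantly and the model collapses onto the thin-film dewetting
dynamics

$$\frac{d\bar L_i}{dt} = \frac{1}{T_h}\sum_{j\,\mathrm{adj}}
  \frac{1}{\bar\ell_{ij}\bar L_i}
  \Big(\frac{1}{\bar L_j} - \frac{1}{\bar L_i}\Big) + \frac{1}{T_p},$$

with $T_h = 2\tau_v \ell_0 L_0/(\mu\epsilon\xi_v^2)$ and
$T_p = \tau_v/(\mu\nu\bar j^a)$ (no pumping: $T_p = \infty$). The bridge
length enters as a flow *resistance* (dividing), the only reading under
which longer bridges couple more weakly, consistent with screening; the
per-lumen form is then exactly antisymmetric in area variables, so total
area is conserved without further adjustment. This dynamics is exposed as
`model = "hydraulic"` in `integrate_chain()` (same event handling) and as
`hydraulic_rhs()`/`pumped_hydraulic_rhs()`; it serves as the independent
reference the full model is checked against (a three-lumen fixture must
agree to within 2% of the initial half-lengths over the pre-event
window). For $t \gg T_p$ every lumen grows at $1/T_p$ and every bridge
shrinks at $2/T_p$, which makes the coalescence rate - and hence the
lumen count - scale as $(t/T_p)^{-1}$.

The self-similar rescaled area distribution of the long-time hydraulic
chain is provided as a *simulated* reference
(`self_similar_reference()`), pooled from an ensemble at a fixed
surviving fraction, rather than as a transcribed closed form; the full
model's distribution is compared to it with a Kolmogorov-Smirnov
distance in the tests.

## Observables

Adaptive stepping gives every realization its own time grid, so ensemble
lumen-count curves are averaged at log-spaced time points (default 60
geometric bins spanning the ensemble's event times); each realization
contributes its exact event-log step function, carried as a constant
outside its own range. `fit_power_law()` fits $\log N$ against $\log t$
over an explicit, recorded window - there is no automatic regime
detection, to keep fit windows out of the tuning surface. The window rule
used by the package's own checks (bins where the mean count has at least
halved while at least 5 lumens remain; for the pumped late regime, from
the point where coalescences dominate the event log) is stated alongside
each result. Size distributions are pooled across realizations at the
nearest recorded snapshot and rescaled by the pooled mean area;
multimodality statements use a fixed kernel bandwidth of 0.1 on the
$A/A^*$ scale. Final-lumen positions pool only realizations with exactly
one surviving lumen; all-collapse runs are excluded and counted.

## Pumping profiles and symmetry breaking

Spatially biased pumping uses
$\bar j^a(x) = \bar j^a_0 + \frac{\delta \bar j^a}{\sqrt{2\pi}\sigma}
\exp(-(x-\mu)^2/\sigma^2)$ (position as a fraction of chain length). The
$\sigma^2$ exponent scale - not $2\sigma^2$ - is deliberate: it makes a
$\pm 2\sigma$ window carry a fraction $\mathrm{erf}(2)$ of the bump, as
the closed-form positioning threshold requires. That threshold,

$$\bar j^* = \frac{\delta\bar j^a\,\sigma\sqrt{\pi}\,
  \mathrm{erf}(2)}{0.6 - 8\sigma},$$

separates perturbation-dominated from baseline-dominated positioning of
the final lumen and is certified numerically by the area comparison it
encodes: the un-normalized bump (peak $\delta\bar j^a$) integrated over
its $4\sigma$ window, equated with the baseline pumping over the far-side
quasi-uniform region of length $(1-\mu) - 8\sigma$ (with $\mu = 0.4$;
`pumping_threshold_numeric()`). It is defined for $\sigma < 0.075$, where
the denominator is positive.

```{r threshold}
pumping_threshold(delta_j = 1, sigma = 0.05)
```

The profile is sampled at lumen centers and bridge midpoints (it is
continuous, so the discretization choice is immaterial at the stated
widths) and re-evaluated after every topological rewrite.

## Problem sizes

The package's checks run ensembles of 20 chains of 100 initial lumens for
the scaling laws (hydraulic regime $\chi_v = 500$, $\chi_s = 5$; pumped
regime $\bar j^a = 1$, $\chi_v = 50$), 8-25 chains of 30-100 lumens for
robustness and distribution checks, and 12-15 chains of 50 lumens for
positioning; these desk-scale sizes reproduce the published exponents
well within their tolerances, and the full-scale protocols (1000-lumen
chains, $10^4$ positioning runs) are configuration changes, not code
changes.

## Limitations

One uncharged solute (no electrodiffusion or membrane potentials); fixed
lumen centers; no nucleation or hydraulic fracture; instantaneous
coalescence without interface resolution; quasi-static bridges with
advection of solutes neglected; 1-D chains only (the 2-D network
extrapolation with its steeper exponent is out of scope). Within the
linearized bridge description, concentration deviations are assumed small
against $c_0$; trapped-solute regimes ($\tau_s \gg \tau_v$,
$\chi_s \ll 1$) drive concentrations far above the chemostat right before
collapse, where the logarithmic chemical potential would deviate from its
linearization - the model is then a qualitative guide rather than a
quantitative one.
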