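---
title: "Self-organization of synaptic weights: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organization of synaptic weights: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`sorn` simulates a self-organizing recurrent network (SORN) of binary
threshold neurons: `n_exc` excitatory and `n_inh` inhibitory units (defaults
200 and 40, the usual 80/20 split) connected by three weight matrices, all
stored *incoming-major* — entry `[i, j]` is the strength of the connection
from unit `j` onto unit `i`, so that homeostatic rescaling of a unit's inputs
is a row operation.

* `w_ee` — excitatory→excitatory, sparse (initial connection probability
  0.1), plastic, and structurally dynamic: synapses are eliminated when STDP
  drives them to zero and created by structural plasticity.
* `w_ei` — inhibitory→excitatory, sparse (probability 0.2), plastic under
  inhibitory STDP.
* `w_ie` — excitatory→inhibitory, dense, fixed after initialization, each
  row normalized to sum 1.

The state at discrete time $t$ is a pair of binary vectors $x(t), y(t)$.
One update reads

$$x_i(t+1) = \Theta\Big(\sum_j W^{EE}_{ij} x_j(t) - \sum_k W^{EI}_{ik} y_k(t)
  - T^E_i + \xi^E_i\Big), \qquad
y_k(t+1) = \Theta\Big(\sum_j W^{IE}_{kj} x_j(t) - T^I_k + \xi^I_k\Big),$$

with $\Theta$ the Heaviside step under a *strict* inequality (a unit whose
drive exactly equals its threshold stays silent — ties are a measure-zero
event under Gaussian noise, but the convention is fixed and tested), and
$\xi$ independent Gaussian noise. One time step corresponds roughly to a
membrane time constant / STDP window (10–20 ms); the homeostatic mechanisms
are deliberately run much faster than their biological counterparts, which
is admissible because of the separation of time scales and keeps simulations
short.

Five plasticity rules act on this state, composed per step in a fixed order
(see *Update ordering* below):

1. **Additive STDP** on existing EE synapses:
   $\Delta W^{EE}_{ij} = \eta_{STDP}\,[x_i(t+1)x_j(t) - x_i(t)x_j(t+1)]$.
   A weight driven to zero or below is set to exactly 0 and the synapse is
   removed from the network.
2. **Synaptic normalization**: each unit's incoming EE weights are rescaled
   to sum to one. This preserves relative strengths, caps total drive, and
   creates competition among a unit's inputs.
3. **Inhibitory STDP** on existing EI synapses: if inhibitory unit $k$ fired
   at $t$, the weight onto excitatory $i$ is reduced by $\eta_{dep}$ when
   $i$ stayed silent at $t+1$ ("successful" inhibition) and increased by the
   larger $\eta_{pot}$ when $i$ fired anyway; depression clips at a small
   positive floor (0.001) instead of eliminating the synapse.
4. **Intrinsic plasticity**: thresholds move by
   $\eta_{IP}\,(x_i(t+1) - r^*_i)$ toward the target rate $r^*$. Thresholds
   are *not* clipped at zero; under weak drive homeostasis legitimately
   pushes them negative.
5. **Structural plasticity**: with probability $p_{struct}$ per step, one
   ordered, non-self, currently unconnected EE pair is drawn uniformly and
   created at weight $w_{new} = 0.001$ — activity-independent, like the
   generation of new dendritic spines.

## Default parameters

| parameter | default | meaning (per step) |
|---|---|---|
| `n_exc`, `n_inh` | 200, 40 | network size |
| `p_ee_init`, `p_ei_init` | 0.1, 0.2 | initial connection probabilities |
| `eta_stdp` | 0.004 | additive STDP step |
| `eta_istdp_pot`, `eta_istdp_dep` | 0.01, 0.001 | iSTDP steps |
| `eta_ip` | 0.01 | threshold step |
| `target_rate` | 0.1 | target firing probability |
| `sigma_noise_exc`, `sigma_noise_inh` | $\sqrt{0.05} \approx 0.224$ | noise sd |
| `p_struct` | 0.1 | structural attempt probability |
| `w_new`, `w_ei_floor` | 0.001 | newborn weight / EI floor |
| `t_exc_max`, `t_inh_max` | 0.5, 1.0 | threshold init intervals |
| `hist_exclusion` | $10^{-4}$ | small-synapse detection limit |

Two of these deserve comment, because they are the quantities a user is most
likely to mis-scale:

* **Noise.** The membrane noise is specified by its *variance* in the SORN
  model family, $\sigma^2 = 0.05$; the default standard deviation is
  therefore $\sqrt{0.05} \approx 0.224$. This is not a cosmetic choice: with
  an sd of 0.05 the noise almost never crosses a threshold on its own, the
  population repeatedly falls into long silent stretches (thousands of
  silent steps in a 10,000-step run), and the ISI coefficient of variation
  inflates to ~1.5. With the correct scale the network fires irregularly at
  the target rate, activity never dies out, and the mean CV sits near 0.95
  — the Poisson-like regime the model is built to produce.
* **iSTDP asymmetry.** At equilibrium the depression and potentiation
  fluxes balance, so the conditional firing probability of an excitatory
  unit given that it was inhibited settles at
  $\eta_{dep}/(\eta_{pot}+\eta_{dep})$. With $\eta_{pot} =
  \eta_{dep}/r^* = 0.01$ this equals $1/11 \approx r^*$: the inhibitory
  feedback is consistent with the intrinsic-plasticity target, which is the
  point of having both homeostatic controllers.

## Update ordering and RNG discipline

Within one step the engine applies: state update → STDP (on the $(t, t+1)$
activity pair) → iSTDP → synaptic normalization → intrinsic plasticity →
structural plasticity. Normalization follows STDP so the row-sum-to-one
invariant holds at every step boundary; structural birth comes last so a
newborn synapse enters the next step at exactly $w_{new}$. Whether
normalization also covers the EI weights each step is left open by the
model's verbal description; here it covers EE rows only, because iSTDP is
the dedicated controller of inhibitory weights (the EI rows *are*
row-normalized once at initialization so excitatory and inhibitory drive
start balanced).

All randomness flows through R's global RNG, seeded once per run, with a
fixed draw order per step (excitatory noise, inhibitory noise, structural
attempt), so a seed fully determines a run. The engine normalizes only the
EE rows touched since the previous step (untouched rows already sum to one),
which is algebraically the same operation to ~1e-15; a checkpoint (state
plus RNG position) resumes a run bit-exactly.

## What the analyses compute

* `isi_cv_stats()` — inter-spike intervals after a washout (default 3000
  steps, discarding the arbitrary initial transient), exponential ML rates,
  and CV = sd/mean per unit; units with fewer than 3 ISIs are excluded from
  summaries. A Bernoulli($p$) train has geometric ISIs with CV
  $\to \sqrt{1-p}$, so CV near 1 at $p = 0.1$ is the irregular-firing
  signature.
* `weight_histogram()` / `fit_lognormal()` — log-binned density (count per
  *linear* bin width) with weights $\le 10^{-4}$ excluded, mimicking the
  detection limit of spine imaging; ML lognormal fit on the log scale with a
  KS statistic, and `fit_exponential()` as the comparison family.
* `top_share()` — the minimal fraction of the strongest synapses holding a
  given share of total weight; cortex concentrates ~50% of synaptic weight
  in ~20% of synapses.
* `phase_classify()` — per-window linear slopes of the connection-fraction
  series labeled decay/growth/stable. The stable tolerance defaults to twice
  the sd of the tail-quarter window slopes — an artifact constant, exposed
  as an argument.
* `synapse_lifetimes()` / `fit_power_law()` — lifetimes of structurally
  created synapses that die; right-censored (still alive) synapses and the
  initial backbone are excluded. The exponent is estimated by discrete
  maximum likelihood (Hurwitz-zeta normalization) and, secondarily, by a
  least-squares slope on the log-binned density.
* `weight_change_stats()`, `fluctuation_vs_weight()`,
  `stdp_conditional_curves()` — snapshot-to-snapshot change populations
  (persisting / eliminated / newborn), mean |Δw| per starting-weight bin at
  the snapshot cadence (default 200 steps), and the per-weight-bin
  potentiation/depression fractions from the isolated STDP delta log.
* `gibrat_null()` — proportionate growth ($w \leftarrow w\,e^{\varepsilon}$)
  with optional per-step renormalization: without it the log-weight variance
  grows linearly at rate $\sigma^2_{growth}$ (unbounded, biologically
  implausible); with it the ensemble stays bounded and lognormal-like but
  does *not* reproduce the weight-dependent fluctuation pattern — which is
  why the mechanistic network model is needed.

## Fitting the lifetime power law honestly

Two practical effects contaminate a naive fit of the 3/2 first-passage law.
First, lifetimes are measured in *steps*, but the weight random walk only
moves on steps with an STDP event; at a firing rate of 0.1 the waiting time
between events is geometric with mean ~50 steps, so the short-lifetime head
of the distribution reflects waiting-time statistics, not the walk. Fitting
from `xmin = 2` (the shipped default) therefore underestimates the exponent
(~1.23 on a 50,000-step run). Second, a finite run right-truncates the tail:
ignoring that biases the exponent *upward* when the cutoff is pushed into
the tail. The package addresses both: `fit_power_law(x, xmin = "auto")`
selects the cutoff by KS minimization (the Clauset–Shalizi–Newman
procedure), and the `xmax` argument switches the likelihood to the
truncated normalization, paired with
`synapse_lifetimes(rec, truncate_at = T)`, which restricts the sample to
synapses with a uniform observation window. With both corrections the
estimate plateaus near 1.5 across a wide range of cutoffs on 50,000-step
runs.

## Problem sizes and what the checks do (and do not) show

The package's tests exercise the default 200E/40I network at 10,000 steps
(firing statistics, weight concentration, lognormal shape) and 50,000 steps
(lifetime exponent, connectivity phases, strong-synapse scale), with a
3000-step washout — the observation points at which the emergent statistics
are customarily reported, and small enough to run on a laptop. The full
connectivity trajectory unfolds over millions of steps, and this matters for
what a short run can show. After the initial decay the connection fraction
bottoms out and regrows only slowly (structural plasticity contributes at
most one synapse per step while elimination churns the newborns), so at the
50,000-step observation point the network is inside the post-decay dip: the
test suite's 100,000-step series confirms decay, a minimum, and net regrowth
past it, but not yet the asymptotic stable regime. A visible consequence is
that in the dip some units retain a single incoming synapse, which
normalization pins at weight 1.0 — so the mean of the ten largest weights at
50,000 steps sits far above the 0.2–0.3 scale that characterizes very strong
synapses once connectivity has recovered (the suite's strong-synapse-scale
check documents exactly this, and fails honestly at this horizon). The
direction of the approach, not the asymptote, is what a desk-scale run
establishes.

The synthetic fixtures (`make_fixture()`) cover the estimators rather than
the biology: lognormal and discrete power-law samples with known parameters
for recovery tests, and first-passage times of a symmetric ±1 random walk
for the 3/2 law. Passing them shows the *analysis* pipeline is correct;
passing the network checks shows the *model* reproduces its emergent
statistics under the stated conditions. None of this demonstrates anything
about experimental data beyond the model's scope: real spine-size
fluctuations involve mechanisms (e.g. activity-independent volume dynamics)
the binary model does not represent, and the comparison interfaces accept
user-supplied tables precisely so such data can be analyzed with the same
statistics.

## Degenerate inputs and numerical conventions

Rows with no incoming synapses are left untouched by normalization (no
0/0); a unit whose last incoming synapse dies can be re-wired by structural
plasticity later. Elimination is identified with weight ≤ 0 after an STDP
step, so "exists" is exactly "weight > 0". Histograms on degenerate support
(all retained weights identical) produce a single bin. Correlations of
constant spike trains are reported as `NA` and flagged rather than silently
dropped. The discrete power-law machinery uses a Hurwitz-zeta evaluation
with an Euler–Maclaurin tail (absolute accuracy far below the statistical
error at the shipped sample sizes).

## Known limitations

Binary threshold units have no membrane integration, refractoriness or
conduction delays; the leaky-integrate-and-fire extension of the model
family is out of scope here. Inhibitory→inhibitory connections are absent by
construction. The engine is single-threaded; a 50,000-step default-network
run takes on the order of a minute. Network-topology statistics (motifs,
clustering) are deliberately not provided.
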