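---
title: "Modeling karyotype evolution and missegregation-induced extinction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling karyotype evolution and missegregation-induced extinction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyomie)
```

## The model and its assumptions

`karyomie` describes a cell population structured by karyotype: the state of
a cell is the integer vector of its chromosome copy numbers, and the
population is a vector of abundances over all karyotypes inside a viability
box. The model is deterministic and linear — per-karyotype birth rates
$\lambda_i$, death rates $\mu_i$ and missegregation rates $\beta_i$ do not
depend on abundances (no carrying capacity or Allee effects), so conclusions
hold for large populations in which every viable karyotype can be realized.
Three structural assumptions do the work:

1. **Mechanism.** Before division each chromosome copy is replicated into a
   chromatid pair. With probability $\beta$ per copy the pair missegregates
   and lands wholly in one daughter (chosen with probability $1/2$);
   otherwise the chromatids split faithfully. Copies and chromosomes act
   independently. This yields the daughter shift law
   $P(t \mid i_k) = \sum_{z=|t|,\ z\equiv t\,(2)}^{i_k} \binom{i_k}{z}
   \beta^z (1-\beta)^{i_k-z} (1/2)^z \binom{z}{(z-t)/2}$,
   which is symmetric, sums to one, and never exceeds $1/2$ off zero. Copy
   number is conserved: the division event produces the mirror pair
   $(j,\ 2i-j)$, so the division-event tensor is $q_{ii} = \prod_k P(0|i_k)$
   and $q_{ij} = 2\,q^{(1)}_{ij}$ off the diagonal (using the symmetry of
   $P$ instead of two products).
2. **Viability.** A karyotype is viable iff every chromosome stays inside
   its interval $[k_c, K_c]$. Losing all copies (nullisomy) or exceeding the
   upper limit kills the cell: probability flux to nonviable daughters is
   dropped *without renormalization* — renormalizing would silently restore
   net growth that the extinction analysis is precisely about. States with a
   zero-copy chromosome that lie inside a declared box (e.g. a `[0, K]`
   interval) are kept as absorbing non-dividers: they never divide, which
   also avoids the $0^0$ ambiguity of the shift law.
3. **Linearity.** With rates independent of prevalence the dynamics are
   $dn/dt = Jn$ with $J_{ii} = \lambda_i(2q_{ii}-1)-\mu_i$ and
   $J_{ij} = \lambda_j q_{j\to i}$. We use the column convention throughout
   ($n$ a column vector); the row form is the transpose and has the same
   spectrum. $J$ is Metzler, so its spectral abscissa is a real eigenvalue:
   negative means missegregation-induced extinction (MIE), positive means
   exponential growth, and the critical curve is its zero set.

## Extinction analysis

**Critical curves.** For a homogeneous death rate the generator separates as
$J = A - \mu I$ with $A$ built at $\mu = 0$, so the critical turnover is one
spectral abscissa per grid point: $\mu_{crit}/\lambda = s(A) =
2\rho(\tilde Q) - 1$, with $\tilde Q$ the truncated single-daughter matrix.
Heterogeneous death kernels break the shift identity; there the boundary is
found by bisection on a global death-rate multiplier (`uniroot` to 1e-10,
bracket doubling up to 1e6), and a failed bracket is reported as a flagged
`NA` point, never interpolated.

**Many chromosomes.** The viable box is a product set and chromosomes
missegregate independently, so $\tilde Q$ is the Kronecker product of
per-chromosome matrices and its Perron root factorizes:
$\mu_{crit}/\lambda = 2\prod_c \rho(Q_c) - 1$. The 22-autosome boundary is
22 eigensolves of (at most) $8\times 8$ matrices; the explicit joint tensor
is only ever built in tests, as an oracle on 2-chromosome boxes.

**Ruling MIE out.** Gershgorin margins (diagonal minus off-diagonal row or
column sum) give sufficient conditions for a positive dominant eigenvalue.
Since a matrix and its transpose share a spectrum, either margin being
positive suffices; both are reported. Three closed-form scenario bounds are
provided, including $\beta_c = \tfrac14(1-\mu/\lambda)$ for the
nearest-neighbor model in which at most one chromosome missegregates per
division — there $\beta$ is a *per-division* probability, and
`per_division_rate()` converts from the per-copy scale
($1-(1-\beta)^{copies}$). In the scenario conditions that reference state
$i+1$, the inflow term vanishes at the top state (no state above exists);
dropping a nonnegative subtracted term can only weaken the sufficient
condition at that boundary state.

**Continuum picture.** Treating total DNA content as continuous gives a
diffusion equation with growth $(\lambda-\mu)$ and diffusivity
$\beta\lambda$; absorbing boundaries at the viability limits yield
$\mu_{crit}/\lambda = 1 - \beta\pi^2/(p_{max}-p_{min})^2$, and the timescale
heuristic ($T_p \ll T_r$) is reported with a configurable "much less" factor
(default 0.1). Absorbing boundary conditions are a modeling choice: the
population simply cannot persist outside the range.

## Simulation protocol

`simulate_to_qss()` integrates to a *quasi*-steady state: the karyotype
composition converges while the total may still grow or shrink. To stay
well-conditioned over $10^4$ days of exponential dynamics the integrator
(deSolve's `lsoda`, stiffness-switching, rtol 1e-8/atol 1e-10) works on the
normalized composition and the log total. Convergence is declared when the
L1 change in composition per day falls below 0.001 (0.1%/day) between
checkpoints spaced `dt_check = 10` days apart; the L1 aggregate was chosen
as the strictest simple norm, the criterion being stated only as a
percentage change per day. Classification is by the sign of
$d\log N/dt$ at QSS. Non-convergence by `t_max` is flagged, never silently
classified. The default initial condition is all mass on the diploid
karyotype (all copies 2, clamped into the box). Population summaries weight
by cell proportions: $\beta_{pop} = \sum_i p_i (1-(1-\beta_i)^{\|i\|_1})$
(the per-division missegregation fraction) and $\mu_{pop} = \sum_i p_i\mu_i$;
division-weighting coincides for homogeneous birth rates.

## Rate kernels

Intra-tumor heterogeneity is modeled by kernels mapping karyotype to rate:
constant, linear in one chromosome's copy number
($\beta = b_0 + \theta_1 (i_c - 2)$, clipped to $[10^{-4}, 1]$), sinusoidal
in aggregate ploidy ($\beta = b_0 + \theta_2 \cos(2\pi(p - p_{peak})/
\text{period})$), or tabulated per state. The cosine is anchored by its
maximum: the peak defaults to ploidy 66 (near-triploid over 22 autosomes,
where missegregation rates are empirically highest) with period 44, placing
the minimum — the *refuge* karyotype — at the diploid aggregate. No fitted
constants for these kernels are published, so all shape parameters are
user-visible with these defaults. Death kernels reuse the same families.
With heterogeneous $\beta$ and homogeneous death, the steady state
concentrates at the minimum-$\beta$ karyotype and the boundary is sandwiched
between the homogeneous curves at $\max_i\beta_i$ and $\min_i\beta_i$ —
sitting near the latter, which is why a low-missegregation refuge renders
MIE practically impossible unless turnover is extreme.

## Inference from expression summaries

`estimate_ploidy()` turns chromosome-level tumor/normal mean-expression
ratios into integer copy numbers under three assumptions: expression scales
with copy number, at least one chromosome is diploid, and SCNAs are clonal.
Chromosomes are sorted so the least differentially expressed come first
(those are the credible diploid anchors; the literal
most-significant-first reading is available as an option but makes the bias
estimate meaningless). For each split $x$ the first $x$ chromosomes are
assumed diploid, fixing a scale $s_x$ (their mean ratio; the reported bias
is $1 - s_x$); remaining chromosomes get $j_k = 2\,r_k/s_x$ and
$E_x$ is the mean squared distance of the $j_k$ to their nearest integers.
Rounding is half-away-from-zero, avoiding bankers'-rounding surprises on
exact .5 estimates.

The split is chosen by minimal $E_x$ with a *statistical* tie rule: the copy
scale is only identified up to rescalings that happen to land every
remaining estimate on an integer, and because the significance sort makes
the tail homogeneous, such degenerate splits (typically leaving only one or
two residual chromosomes) produce spuriously deep minima. All splits with
$E_x \le 30\,\min E + 10^{-9}$ are therefore treated as equivalent —
the spread between a 1–2-term minimum and a ~20-term mean at the same noise
level — and the smallest $x$ wins: the most parsimonious split is the one
consistent with the differential-expression ranking. On noiseless data every
correct split is exactly zero, so the rule reduces to the plain smallest-tie
choice.

The calibration layer is ordinary least squares. Turnover prediction is
affine in the pathway score; values above 1 (beyond homeostasis) are
permitted but flagged. Missegregation prediction inverts the calibrated
response — the log2 of the percentage of divisions with lagging
chromosomes — into a per-division probability $2^L/100$ and divides by
ploidy for the per-chromosome rate, the only reading that yields rates in
$(0,1)$; out-of-range values are clipped and reported.

## Synthetic data

The generators emulate exactly the inputs the estimators consume: normal
means drawn lognormal, tumor means $= \text{bias}\cdot(c_k/2)\cdot
\text{normal}_k\cdot e^{\varepsilon_k}$ with multiplicative lognormal noise
(positivity guaranteed, matching ratio behavior), and a deterministic
monotone p-value surrogate of $|c_k - 2|$ with seeded jitter — only the rank
order enters the estimator, so no actual test is simulated. Default study
conditions for the recovery experiments: random karyotypes uniform on
$[1,4]^{22}$ with at least one diploid anchor (the estimator's stated
assumption), bias uniform on $[0.5, 1.5]$, noise $\sigma = 0.02$. What the
generator does *not* emulate: per-gene counts, dropout, library-size
effects, cell-type composition, subclonal SCNA mixtures, or correlated
noise across chromosomes — passing recovery tests therefore demonstrates
correctness of the estimation logic on clonal chromosome-level summaries,
not robustness to raw scRNA-seq artifacts. The Monte-Carlo division sampler
draws the mechanism directly and satisfies copy-number conservation exactly
by construction; it serves as the independent oracle for the closed-form
shift law and the product-form daughter distribution.

## Numerical choices

* Sparse tensors drop entries below $10^{-12}$ *without renormalization*
  (renormalizing would alter net growth).
* Dominant eigenvalues: dense `eigen()` up to dimension 600 (all standard
  analyses are far smaller), else a shifted power iteration on the
  nonnegative matrix $J + cI$ with dense fallback on non-convergence —
  never a silent `NaN`.
* Steady-state proportions require a simple dominant eigenvalue (spectral
  gap $> 10^{-10}$ and real); degenerate cases are explicit errors.
* State order is lexicographic on the copy vector, so matrix layouts are
  reproducible across runs; spaces above $10^6$ states are refused with an
  explicit error rather than truncated (the Kronecker path exists for
  that).
* All stochastic helpers take integer seeds and restore the RNG state
  (`withr`), so fixed seeds give byte-identical outputs.

## Problem sizes

The test suite exercises single-chromosome spaces up to 8 states, aggregate
ploidy spaces up to 67 states, joint 2-chromosome boxes up to 64 states, a
22-factor Kronecker analysis, Monte-Carlo oracles at $2\times10^5$–$10^6$
divisions, 20 quasi-steady-state integrations straddling the critical curve
at ±5% in turnover, and 200-fixture recovery experiments — sizes at which
every closed form has an independently computed numerical counterpart.

## Known limitations

Deterministic ODE dynamics ignore demographic stochasticity, so extinction
here means decay of the expected abundance — small populations and
early-stage dynamics need a stochastic treatment. Whole-genome doubling,
missegregation-induced G1 apoptosis and micronuclei are not modeled.
Structural CIN (sub-chromosomal change) is outside the state space, and
chromosome-arm resolution is available only as a configuration choice. The
calibration layer inherits whatever biases exist in the upstream pathway
scores it consumes.
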