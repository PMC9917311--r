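# karyomie

Deterministic modeling of karyotype evolution under chromosome
missegregation, and analysis of **missegregation-induced extinction (MIE)**.

Chromosome missegregation — a mitotic error in which both sister chromatids
of a chromosome land in the same daughter cell — continually moves cancer
cells through karyotype space. Cells that lose every copy of a chromosome
(nullisomy) or exceed a tolerated maximum (commonly eight copies) die, so a
sufficiently high missegregation rate combined with a sufficiently high cell
turnover rate can drive an entire population extinct. `karyomie` implements
a linear compartment model of this process and everything needed to map the
extinction boundary, for tumor populations and for the near-homeostatic
normal tissues that sit close to it.

## The model

A karyotype is an integer vector **i** = (i₁, …, i_M) of copy numbers over M
chromosome types, confined to a viable box k_c ≤ i_c ≤ K_c. During a
division of a parent with i_k copies of chromosome k, each copy
missegregates independently with probability β; the net copy-number shift t
of the first daughter follows

P(t | i_k) = Σ_{z = |t|, z ≡ t (mod 2)}^{i_k} C(i_k, z) β^z (1−β)^{i_k−z} (½)^z C(z, (z−t)/2),

and chromosomes are independent, so the first daughter's karyotype
distribution is q⁽¹⁾(i→j) = Π_k P(i_k − j_k | i_k). Copy number is conserved
(the second daughter is the mirror 2i − j), giving the division-event tensor
q with q_ii = Π_k P(0|i_k) and q_ij = 2 q⁽¹⁾_ij off the diagonal. With
per-karyotype birth and death rates λ_i, μ_i, abundances n obey the linear
ODE dn/dt = J n with the Metzler generator

J_ii = λ_i (2 q_ii − 1) − μ_i,  J_ij = λ_j q_{j→i}  (i ≠ j),

where flux to daughters outside the viable box is dropped (those cells die).
The sign of the spectral abscissa of J classifies the population: growth if
positive, MIE if negative. The package computes:

* **critical curves** — the turnover rate μ/λ at which the dominant
  eigenvalue crosses zero, as a function of β (homogeneous rates) or of the
  shape parameters of copy-number-dependent missegregation/death kernels;
* **Gershgorin-type sufficient conditions** that rule MIE out, including the
  closed-form scenario bounds such as β_c = ¼(1 − μ/λ) for the
  nearest-neighbor model;
* a **Kronecker factorization** μ_crit/λ = 2 Π_c ρ(Q_c) − 1 that evaluates
  joint viability constraints on all 22 autosomes without enumerating 8²²
  states;
* **quasi-steady-state ODE simulation** (composition converging at
  < 0.1%/day) with growth/extinction classification and population-average
  missegregation and death rates;
* a **continuum (diffusion) model** of ploidy with its closed-form
  extinction threshold μ_crit/λ = 1 − βπ²/(p_max − p_min)²;
* **rate inference from chromosome-level expression summaries**: integer
  karyotype and tumor/normal bias estimation from expression ratios, and
  linear calibrations mapping pathway scores to turnover rates and
  interferon-gamma scores to per-chromosome missegregation rates;
* **seeded synthetic generators** for every inference input.

## Worked example

```r
library(karyomie)

# a dosage-sensitive chromosome viable at 1..5 copies
sp <- karyo_space(1, 1, 5)

# extinction boundary in the (beta, mu/lambda) plane
critical_curve(sp, "beta", c(0.05, 0.2, 0.35, 0.5))
#>   parameter critical_turnover converged
#> 1      0.05             0.969 TRUE
#> 2      0.2              0.880 TRUE
#> 3      0.35             0.792 TRUE
#> 4      0.5              0.707 TRUE

# a growing population below the curve
gen <- build_generator(sp, constant_rates(lam = 1, mu = 0.6, beta = 0.1))
dominant_eigenvalue(gen)
#> [1] 0.3390661
qss <- simulate_to_qss(gen)
glance(qss)
#>   classification growth_rate beta_pop mu_pop converged t_end log_total
#> 1 growth               0.339    0.199    0.6 TRUE         30      10.4

# all 22 autosomes jointly constrained to 1..8 copies, via the Kronecker
# factorization (no 8^22 state enumeration)
multichromosome_critical(c(1, 8), 0.005, n_chromosomes = 22)
#> [1] 0.9554844
```

At β = 0.05 a single constrained chromosome only permits extinction once
turnover exceeds 0.969 — MIE is impossible at low turnover — while
constraining all 22 autosomes pulls the boundary down to 0.955 even at
β = 0.005. The simulated population grows at 0.339/day and missegregates in
19.9% of divisions (`beta_pop` is the per-division population average of
1 − (1−β)^ploidy).

Karyotype inference from a synthetic expression summary (true karyotype
diploid except 3 copies of chr7 and 1 copy of chr10, tumor/normal bias 0.8,
2% multiplicative noise):

```r
k <- rep(2L, 22); k[7] <- 3L; k[10] <- 1L
fx <- generate_expression_fixture(k, bias = 0.8, noise_sigma = 0.02, seed = 42)
est <- estimate_ploidy(fx)
glance(est)
#>   x_star scale  bias min_error ploidy
#> 1      8 0.796 0.204 0.0000355     44
tidy(est)$copies  # recovers k exactly
```

Each result type has `tidy()`/`glance()` methods and an `autoplot()`;
`run_pipeline()` executes a YAML-configured analysis end to end (see
`?run_pipeline`), with a thin command-line wrapper in
`inst/scripts/karyomie.R`.

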