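test_that("spectral abscissa matches closed forms and the dense oracle", {
  sp1 <- karyo_space(1, 1, 1)
  gen1 <- build_generator(sp1, constant_rates(1, 0.5, 0.3))
  expect_equal(dominant_eigenvalue(gen1), 1 * (1 - 2 * 0.3) - 0.5)

  sp <- karyo_space(1, 1, 5)
  gen0 <- build_generator(sp, constant_rates(1.5, 0.4, 0))
  expect_equal(dominant_eigenvalue(gen0), 1.1)

  # iterative Perron path agrees with dense eigendecomposition
  for (seed in 1:5) {
    m <- random_metzler(30, seed)
    dense <- max(Re(eigen(m, only.values = TRUE)$values))
    expect_equal(dominant_eigenvalue(m, dense_cutoff = 0), dense,
                 tolerance = 1e-10)
  }
})

test_that("Gershgorin margins rule out MIE when discs stay positive", {
  sp <- karyo_space(1, 1, 5)
  gen <- build_generator(sp, constant_rates(1, 0.4, 0))
  gc <- gershgorin_conditions(gen)
  expect_equal(gc$row_margin, 0.6)
  expect_equal(gc$col_margin, 0.6)
  expect_true(gc$mie_ruled_out)

  # nearest-neighbor model: beta_div = 0.05 < 0.25 * (1 - 0.7)
  nn <- nearest_neighbor_generator(karyo_space(1, 1, 5), 1, 0.7, 0.05)
  expect_true(gershgorin_conditions(nn)$mie_ruled_out)
})

test_that("a positive Gershgorin verdict implies a positive dominant eigenvalue", {
  withr::with_seed(11, {
    hits <- 0
    for (rep in 1:40) {
      sp <- karyo_space(1, 1, sample(2:6, 1))
      rates <- constant_rates(1, stats::runif(1, 0, 1), stats::runif(1, 0, 0.3))
      gen <- build_generator(sp, rates)
      gc <- gershgorin_conditions(gen)
      if (gc$mie_ruled_out) {
        hits <- hits + 1
        expect_gt(dominant_eigenvalue(gen), 0)
      }
    }
    expect_gt(hits, 0)  # the sweep actually exercised positive verdicts
  })
})

test_that("scenario conditions evaluate exactly as printed", {
  sp <- karyo_space(1, 1, 5)
  # scenario 1: beta_c = (1 - mu/lambda) / 4
  s1 <- table2_condition(1, constant_rates(1, 0.6, 0.05), sp)
  expect_equal(s1$beta_c, 0.1)
  expect_true(s1$satisfied)
  s1b <- table2_condition(1, constant_rates(1, 1, 0.001), sp)
  expect_equal(s1b$beta_c, 0)           # homeostasis boundary
  expect_false(s1b$satisfied)

  # scenario 2: lambda_i (1 - 3 beta_i) - mu_i - lambda_{i+1} beta_{i+1} > 0
  s2 <- table2_condition(2, constant_rates(1, 0, 0.2), sp)
  expect_equal(s2$per_state_margins$margin[1], 1 - 3 * 0.2 - 0.2)
  expect_true(s2$satisfied)

  # scenario 3: beta < (1 - mu_i/lambda_i) / (3 + lambda_{i+1}/lambda_i)
  s3 <- table2_condition(3, constant_rates(1, 0.2, 0.1), sp)
  expect_equal(s3$beta_c, (1 - 0.2) / 4)
  expect_true(s3$satisfied)

  expect_error(table2_condition(1, rate_model(constant_kernel(1),
                                              constant_kernel(0),
                                              linear_beta_kernel(0.01, 0.02)),
                                sp),
               "homogeneous")
})

test_that("Table-2 verdicts are sufficient (never a false 'safe')", {
  withr::with_seed(23, {
    for (rep in 1:25) {
      sp <- karyo_space(1, 1, sample(3:6, 1))
      mu <- stats::runif(1, 0, 1); beta <- stats::runif(1, 0, 0.3)
      rates <- constant_rates(1, mu, beta)
      s2 <- table2_condition(2, rates, sp)
      s3 <- table2_condition(3, rates, sp)
      if (s2$satisfied || s3$satisfied) {
        expect_gt(dominant_eigenvalue(build_generator(sp, rates)), 0)
      }
      # scenario 1 is about the nearest-neighbor tensor
      s1 <- table2_condition(1, rates, sp)
      if (s1$satisfied) {
        nn <- nearest_neighbor_generator(sp, 1, mu, beta)
        expect_gt(dominant_eigenvalue(nn), 0)
      }
    }
  })
})

test_that("critical turnover follows the spectral shift identity", {
  expect_equal(critical_turnover(karyo_space(1, 1, 1), 0.1), 0.8)
  expect_equal(critical_turnover(karyo_space(1, 1, 5), 0), 1)
  # dense-eigensolver oracle on the 5x5 A(beta)
  sp <- karyo_space(1, 1, 5)
  A <- as.matrix(build_generator(sp, constant_rates(1, 0, 0.05))$J)
  expect_equal(critical_turnover(sp, 0.05),
               max(Re(eigen(A, only.values = TRUE)$values)),
               tolerance = 1e-12)
})

test_that("homogeneous critical curves behave like the MIE boundary", {
  sp_chr <- karyo_space(1, 1, 5)
  grid <- c(0, 0.05, 0.1, 0.2, 0.4, 0.7, 1)
  cc <- critical_curve(sp_chr, "beta", grid)
  expect_equal(cc$critical_turnover[cc$parameter == 0], 1)   # faithful division
  expect_true(all(cc$critical_turnover > 0))                 # MIE impossible at low turnover
  expect_true(all(cc$converged))
  expect_false(any(is.na(cc$critical_turnover)))

  # ploidy-interval space is more permissive than a single critical chromosome
  sp_agg <- karyo_space(1, 22, 88)
  cc_agg <- critical_curve(sp_agg, "beta", grid[grid > 0])
  cc_chr <- cc$critical_turnover[cc$parameter > 0]
  expect_true(all(cc_chr < cc_agg$critical_turnover))
})

test_that("curve points straddled in turnover classify growth vs extinction", {
  sp <- karyo_space(1, 1, 5)
  for (beta in c(0.05, 0.3)) {
    mu_c <- critical_turnover(sp, beta)
    for (side in c(0.95, 1.05)) {
      gen <- build_generator(sp, constant_rates(1, side * mu_c, beta))
      qss <- simulate_to_qss(gen, qss_tol = 1e-5)
      expect_equal(qss$classification,
                   if (side < 1) "growth" else "extinction")
    }
  }
})

test_that("Kronecker factorization matches the explicit joint generator", {
  # two chromosomes each [1,1]: closed form 2 (1 - beta)^2 - 1
  expect_equal(multichromosome_critical(list(c(1, 1), c(1, 1)), 0.1),
               2 * 0.9^2 - 1)
  # a single factor reduces to critical_turnover
  expect_equal(multichromosome_critical(c(1, 5), 0.07),
               critical_turnover(karyo_space(1, 1, 5), 0.07),
               tolerance = 1e-12)
  # explicit 64-state joint space oracle
  lam <- 1; mu <- 0.3; beta <- 0.01
  sp <- karyo_space(2, 1, 8)
  gen <- build_generator(sp, constant_rates(lam, mu, beta))
  mu_crit <- multichromosome_critical(c(1, 8), beta, n_chromosomes = 2)
  expect_equal(dominant_eigenvalue(gen),
               lam * mu_crit - mu,          # 2 lam rho^2 - (lam + mu)
               tolerance = 1e-10)
})

test_that("joint generator equals the Kronecker product entrywise", {
  beta <- 0.08; lam <- 1.1; mu <- 0.2
  for (iv in list(c(1, 3), c(1, 4))) {
    spj <- karyo_space(2, iv[1], iv[2])
    J <- as.matrix(build_generator(spj, constant_rates(lam, mu, beta))$J)
    Qc <- karyomie:::single_daughter_matrix(iv[1], iv[2], beta)
    Qjoint <- kronecker(Qc, Qc)
    expect_equal(J, 2 * lam * t(Qjoint) - (lam + mu) * diag(nrow(Qjoint)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("extra constrained chromosomes contract viability with diminishing cost", {
  beta <- 0.01
  crits <- vapply(1:22, function(m) {
    multichromosome_critical(c(1, 8), beta, n_chromosomes = m)
  }, numeric(1))
  expect_true(all(diff(crits) < 0))              # monotone contraction
  decrements <- -diff(crits)
  expect_true(all(diff(decrements) < 1e-12))     # shrinking decrements
})

test_that("steady-state proportions come from the dominant eigenvector", {
  sp1 <- karyo_space(1, 1, 1)
  gen1 <- build_generator(sp1, constant_rates(1, 0.2, 0.1))
  expect_equal(steady_state_proportions(gen1), 1)

  # diagonal case: indicator of the fastest-growing state
  mu_tab <- tabulated_kernel(data.frame(state = as.character(1:3),
                                        rate = c(0.5, 0.1, 0.3)))
  sp <- karyo_space(1, 1, 3)
  gen <- build_generator(sp, rate_model(constant_kernel(1), mu_tab,
                                        constant_kernel(0)))
  expect_equal(steady_state_proportions(gen), c(0, 1, 0))

  # degenerate dominant pair is an explicit error
  expect_error(steady_state_proportions(diag(c(1, 1))), "not simple")
})

test_that("low-missegregation karyotypes act as a stabilizing refuge", {
  sp <- karyo_space(1, 1, 5)
  kern <- linear_beta_kernel(0.05, 0.02)     # beta rises with copy number
  rates <- rate_model(constant_kernel(1), constant_kernel(0.3), kern)
  gen <- build_generator(sp, rates)
  p <- steady_state_proportions(gen)
  betas <- evaluate_rates(sp, rates)$beta
  # composition concentrates at the minimum-beta karyotype
  expect_equal(which.max(p), which.min(betas))
  expect_gte(sum(p * betas), min(betas))
  # refuge bound: dominant eigenvalue is at least the homogeneous model's at max beta
  gen_hi <- build_generator(sp, constant_rates(1, 0.3, max(betas)))
  expect_gte(dominant_eigenvalue(gen), dominant_eigenvalue(gen_hi) - 1e-12)
})

test_that("kernel-parameterized critical curves show the refuge effect", {
  sp <- karyo_space(1, 2, 6)
  grid <- c(0.005, 0.01, 0.02)
  cc <- critical_curve(sp, "theta2", grid, b0 = 0.05)
  expect_true(all(cc$converged))
  for (i in seq_along(grid)) {
    rates <- rate_model(constant_kernel(1), constant_kernel(0),
                        sinusoidal_beta_kernel(grid[i], 0.05, p_peak = 8,
                                               period = 4))
    cc_k <- critical_curve(sp, "theta2", grid[i],
                           rates_factory = function(th) rates)
    betas <- evaluate_rates(sp, rates)$beta
    # refuge effect: the heterogeneous boundary sits strictly above the
    # worst-case homogeneous curve (at max beta), sandwiched below the
    # best-case one (at min beta)
    expect_gt(cc_k$critical_turnover, critical_turnover(sp, max(betas)))
    expect_lte(cc_k$critical_turnover,
               critical_turnover(sp, min(betas)) + 1e-10)
  }
})

test_that("heterogeneous death kernels solve the boundary by bisection", {
  sp <- karyo_space(1, 1, 5)
  death <- linear_kernel(0.2, 1, c_ref = 1)   # mu grows with copy number
  factory <- function(b) rate_model(constant_kernel(1), death, constant_kernel(b))
  cc <- critical_curve(sp, "beta", c(0.05, 0.2), rates_factory = factory)
  expect_true(all(cc$converged))
  # at the reported multiplier the dominant eigenvalue is ~0
  for (i in seq_len(nrow(cc))) {
    rates <- factory(cc$parameter[i])
    mvals <- evaluate_rates(sp, rates)$mu * cc$critical_turnover[i]
    mu_tab <- tabulated_kernel(data.frame(state = as.character(1:5), rate = mvals))
    gen <- build_generator(sp, rate_model(constant_kernel(1), mu_tab,
                                          constant_kernel(cc$parameter[i])))
    expect_lt(abs(dominant_eigenvalue(gen)), 1e-8)
  }
})

test_that("continuum threshold matches separation of variables and the PDE oracle", {
  m <- continuum_model(1, 0, 0.1, 0, 2)
  out <- continuum_critical(m)
  expect_equal(out$critical_turnover, 1 - 0.1 * pi^2 / 4)
  expect_equal(continuum_critical(continuum_model(1, 0, 0, 0, 2))$critical_turnover, 1)

  # 200-node finite-difference eigenvalue flips sign at the threshold within 1%
  lam <- 1; beta <- 0.02; p_min <- 0; p_max <- 3
  mu_crit <- lam * (1 - beta * pi^2 / (p_max - p_min)^2)
  ev_lo <- continuum_fd_eigenvalue(lam, 0.99 * mu_crit, beta, p_min, p_max)
  ev_hi <- continuum_fd_eigenvalue(lam, 1.01 * mu_crit, beta, p_min, p_max)
  expect_gt(ev_lo, 0)
  expect_lt(ev_hi, 0)
  # timescale heuristic
  h <- continuum_critical(continuum_model(1, 0.99, 0.5, 0, 40, L_p = 1))
  expect_true(h$mie_heuristic)
  expect_false(continuum_critical(continuum_model(1, 0.2, 0.01, 0, 40))$mie_heuristic)
})
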