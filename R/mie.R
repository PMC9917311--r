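#' Spectral abscissa of the generator
#'
#' The largest real part among the eigenvalues of `J` decides the fate of the
#' linear system `dn/dt = J n`: positive means exponential growth of some
#' karyotype mixture, negative means missegregation-induced extinction (MIE).
#' For a Metzler matrix the spectral abscissa is itself a real eigenvalue
#' (the Perron root of the nonnegative shift `J + cI`, minus `c`), which is
#' how it is computed for large sparse generators; small matrices use a dense
#' eigendecomposition directly.
#'
#' @param J A [build_generator()] result or a square (sparse) matrix.
#' @param tol Convergence tolerance of the shifted power iteration.
#' @param dense_cutoff Matrices up to this dimension are solved densely;
#'   larger ones by the shifted power iteration (with dense fallback on
#'   non-convergence).
#' @return The spectral abscissa (a real number).
#' @export
dominant_eigenvalue <- function(J, tol = 1e-12, dense_cutoff = 600) {
  J <- as_generator_J(J)
  n <- nrow(J)
  if (any(!is.finite(J@x))) {
    rlang::abort("generator matrix contains non-finite entries")
  }
  if (n <= dense_cutoff) {
    return(max(Re(eigen(as.matrix(J), only.values = TRUE)$values)))
  }
  # shifted power iteration: B = J + cI is nonnegative for Metzler J
  d <- Matrix::diag(J)
  c_shift <- max(0, -min(d)) + 1
  B <- J + Matrix::Diagonal(n, c_shift)
  v <- rep(1 / sqrt(n), n)
  lam_old <- NA_real_
  for (it in seq_len(50000L)) {
    w <- as.numeric(B %*% v)
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) return(-c_shift)  # nilpotent shift: abscissa at -c
    v <- w / nrm
    lam <- sum(v * as.numeric(B %*% v))
    if (!is.na(lam_old) && abs(lam - lam_old) < tol * max(1, abs(lam))) {
      return(lam - c_shift)
    }
    lam_old <- lam
  }
  # dense fallback rather than a silently unconverged value
  max(Re(eigen(as.matrix(J), only.values = TRUE)$values))
}

as_generator_J <- function(J) {
  if (inherits(J, "generator_matrix")) J <- J$J
  if (is.matrix(J)) J <- Matrix::Matrix(J, sparse = TRUE)
  J <- methods::as(methods::as(J, "generalMatrix"), "CsparseMatrix")
  if (nrow(J) != ncol(J)) rlang::abort("`J` must be square")
  J
}

# Perron root (spectral radius) of a small nonnegative matrix.
spectral_radius <- function(Q) {
  max(Re(eigen(as.matrix(Q), only.values = TRUE)$values))
}

#' Gershgorin sufficient conditions ruling out MIE
#'
#' Every eigenvalue of `J` lies in a Gershgorin disc centered at a diagonal
#' entry with radius the off-diagonal absolute row (or column) sum. If all
#' discs sit in the positive half-plane the dominant eigenvalue is positive
#' and MIE is impossible. For the Metzler generator the margin of state `i`
#' is `J_ii - sum_{j != i} J_ij` (rows) or with `J_ji` (columns); since `J`
#' and its transpose share a spectrum, either margin being positive suffices.
#' Biologically: no karyotype may lose cells to missegregation and death
#' faster than it gains them.
#'
#' @param J A [build_generator()] result or Metzler matrix.
#' @return A one-row tibble with `row_margin`, `col_margin` (the minima over
#'   states) and `mie_ruled_out`.
#' @export
gershgorin_conditions <- function(J) {
  J <- as_generator_J(J)
  d <- Matrix::diag(J)
  row_margin <- min(2 * d - Matrix::rowSums(J))
  col_margin <- min(2 * d - Matrix::colSums(J))
  tibble::tibble(row_margin = row_margin, col_margin = col_margin,
                 mie_ruled_out = row_margin > 0 || col_margin > 0)
}

#' Closed-form sufficient conditions for three biological scenarios
#'
#' Evaluates the scenario-specific sufficient conditions to avoid MIE on the
#' aggregate (1-D) model:
#' * **Scenario 1** -- at most one chromosome missegregates per division
#'   (nearest-neighbor tensor, `beta` read as a *per-division* probability)
#'   and homogeneous rates: safe when `beta < beta_c = (1 - mu/lambda)/4`.
#' * **Scenario 2** -- karyotype-dependent birth, death and missegregation
#'   rates: safe when `lambda_i (1 - 3 beta_i) - mu_i - lambda_{i+1}
#'   beta_{i+1} > 0` for every state `i` (at the top state the inflow term
#'   vanishes).
#' * **Scenario 3** -- homogeneous missegregation rate only: safe when
#'   `beta < (1 - mu_i/lambda_i) / (3 + lambda_{i+1}/lambda_i)` for every `i`.
#'
#' Use [per_division_rate()] to convert a per-copy missegregation rate into
#' the per-division probability scenario 1 expects.
#'
#' @param scenario 1, 2 or 3.
#' @param rates A [rate_model()]; scenario 1 requires all-constant kernels,
#'   scenario 3 a constant missegregation kernel.
#' @param space A [karyo_space()] with `M = 1` (the aggregate model).
#' @return A list with `satisfied` plus `beta_c` (scenarios 1, 3) and/or a
#'   `per_state_margins` tibble (scenarios 2, 3).
#' @export
table2_condition <- function(scenario, rates, space) {
  if (!scenario %in% 1:3) rlang::abort("`scenario` must be 1, 2 or 3.")
  if (space$M != 1L) {
    rlang::abort("Table-2 conditions operate on the aggregate model (M = 1).")
  }
  tab <- evaluate_rates(space, rates)
  copies <- as.integer(space$states[, 1L])
  if (scenario == 1) {
    if (!all(rates$kinds == "constant")) {
      rlang::abort("scenario 1 requires homogeneous (constant) rates")
    }
    lam <- tab$lambda[1]; mu <- tab$mu[1]; beta <- tab$beta[1]
    beta_c <- 0.25 * (1 - mu / lam)
    return(list(satisfied = beta < beta_c, beta_c = beta_c))
  }
  # states are in ascending copy-number order; "i+1" is the next state up
  lam <- tab$lambda; mu <- tab$mu; beta <- tab$beta
  S <- space$n_states
  lam_up <- c(lam[-1L], 0)    # no state above the top: inflow term vanishes
  beta_up <- c(beta[-1L], 0)
  if (scenario == 2) {
    margins <- lam * (1 - 3 * beta) - mu - lam_up * beta_up
    per_state <- tibble::tibble(copies = copies, margin = margins)
    return(list(satisfied = all(margins > 0), per_state_margins = per_state))
  }
  if (rates$kinds[["misseg"]] != "constant") {
    rlang::abort("scenario 3 requires a homogeneous missegregation rate")
  }
  beta_c_i <- (1 - mu / lam) / (3 + lam_up / lam)
  per_state <- tibble::tibble(copies = copies, beta_c = beta_c_i)
  list(satisfied = beta[1] < min(beta_c_i), beta_c = min(beta_c_i),
       per_state_margins = per_state)
}

#' Nearest-neighbor missegregation generator
#'
#' The scenario-1 model: at most one chromosome missegregates per division,
#' so a division is faithful with probability `1 - beta_div` or yields the
#' daughter pair `(i - 1, i + 1)` with probability `beta_div` (`beta_div` is
#' per division). Flux to daughters outside the viable interval is dropped.
#'
#' @param space A [karyo_space()] with `M = 1`.
#' @param lam,mu Homogeneous birth and death rates.
#' @param beta_div Per-division missegregation probability in \[0, 1\].
#' @return A `generator_matrix`-like object holding the sparse `J`.
#' @export
nearest_neighbor_generator <- function(space, lam, mu, beta_div) {
  if (space$M != 1L) rlang::abort("nearest-neighbor model requires M = 1")
  if (beta_div < 0 || beta_div > 1) rlang::abort("`beta_div` must lie in [0, 1].")
  copies <- as.integer(space$states[, 1L])
  S <- space$n_states
  i_idx <- integer(0); j_idx <- integer(0); x <- numeric(0)
  for (s in seq_len(S)) {
    if (copies[s] < 1L) next  # absorbing
    # division-event form: q_ss = 1 - beta_div; q to s±1 = beta_div each
    add <- function(dst, q) {
      if (dst >= 1L && dst <= S && q > 0) {
        i_idx <<- c(i_idx, dst); j_idx <<- c(j_idx, s); x <<- c(x, lam * q)
      }
    }
    add(s - 1L, beta_div)
    add(s + 1L, beta_div)
  }
  diag_vals <- ifelse(copies >= 1L, lam * (2 * (1 - beta_div) - 1) - mu, -mu)
  J <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = x, dims = c(S, S)) +
    Matrix::Diagonal(S, diag_vals)
  structure(list(space = space, J = methods::as(J, "CsparseMatrix")),
            class = "generator_matrix")
}

#' Critical turnover rate for a homogeneous model
#'
#' With homogeneous rates the generator separates as `J = lambda A - mu I`
#' with `A = 2 Qt' - I` built at `lambda = 1`, `mu = 0`, so the turnover at
#' which the dominant eigenvalue crosses zero is simply the spectral abscissa
#' of `A`: `mu_crit / lambda = s(A) = 2 rho(Qt) - 1`, one eigensolve per
#' missegregation rate.
#'
#' @param space A [karyo_space()].
#' @param beta Homogeneous per-copy missegregation rate.
#' @return The critical turnover `mu_crit / lambda` (may be negative if even
#'   a non-dying population cannot outgrow its missegregation losses).
#' @export
critical_turnover <- function(space, beta) {
  gen <- build_generator(space, constant_rates(1, 0, beta))
  dominant_eigenvalue(gen)
}

#' Critical curves in the (parameter, turnover) plane
#'
#' Traces the MIE boundary: for each value of a swept parameter, the turnover
#' rate `mu/lambda` at which the dominant eigenvalue of the generator is zero.
#' Sweeping `beta` with constant rates reproduces the homogeneous critical
#' curves; sweeping a kernel shape parameter (`theta1` of the linear kernel,
#' `theta2` of the sinusoidal kernel) gives the heterogeneous-rate curves.
#' When the death kernel is homogeneous the critical turnover is read off the
#' shift identity (see [critical_turnover()]); a heterogeneous death kernel
#' falls back to bisection on a global death-rate multiplier, and the
#' reported value is the multiplier at which extinction begins.
#'
#' @param space A [karyo_space()].
#' @param parameter_name `"beta"`, `"theta1"` or `"theta2"` (a label; the
#'   sweep itself is defined by `rates_factory`).
#' @param grid Numeric vector of parameter values.
#' @param rates_factory Function mapping one parameter value to a
#'   [rate_model()] with birth rate 1. Defaults: constant rates for `"beta"`;
#'   [linear_beta_kernel()] / [sinusoidal_beta_kernel()] with baseline `b0`
#'   for the shape parameters.
#' @param b0 Baseline missegregation rate used by the default kernel
#'   factories.
#' @param mu_max Upper bracket for the bisection path.
#' @return A tibble of class `critical_curve` with columns `parameter`,
#'   `critical_turnover` and `converged`, plus attributes `parameter_name`
#'   and `assumptions` (`"homogeneous"` or `"kernel"`).
#' @export
critical_curve <- function(space, parameter_name = c("beta", "theta1", "theta2"),
                           grid, rates_factory = NULL, b0 = 0.05, mu_max = 4) {
  parameter_name <- rlang::arg_match(parameter_name)
  if (is.null(rates_factory)) {
    rates_factory <- switch(
      parameter_name,
      beta = function(b) constant_rates(1, 0, b),
      theta1 = function(th) rate_model(constant_kernel(1), constant_kernel(0),
                                       linear_beta_kernel(th, b0)),
      theta2 = function(th) {
        p_lo <- sum(space$viable_lo); p_hi <- sum(space$viable_hi)
        rate_model(constant_kernel(1), constant_kernel(0),
                   sinusoidal_beta_kernel(th, b0, p_peak = mean(c(p_lo, p_hi)),
                                          period = max(p_hi - p_lo, 2)))
      }
    )
  }
  pts <- purrr::map(grid, function(par) {
    rates <- rates_factory(par)
    res <- critical_point(space, rates, mu_max = mu_max)
    tibble::tibble(parameter = par, critical_turnover = res$value,
                   converged = res$converged)
  })
  out <- dplyr::bind_rows(pts)
  assumptions <- if (rates_factory(grid[[1]])$kinds[["misseg"]] == "constant")
    "homogeneous" else "kernel"
  structure(out, class = c("critical_curve", class(out)),
            parameter_name = parameter_name, assumptions = assumptions,
            space = space_to_config(space))
}

# One critical-turnover point. Homogeneous death: shift identity.
# Heterogeneous death kernel m_i: bisect on c in mu_i = c * m_i.
critical_point <- function(space, rates, mu_max = 4) {
  zero_mu <- rate_model(rates$birth, constant_kernel(0), rates$misseg)
  A <- build_generator(space, zero_mu)$J
  sA <- dominant_eigenvalue(A)
  if (rates$kinds[["death"]] == "constant") {
    return(list(value = sA, converged = TRUE))
  }
  m <- vapply(seq_len(space$n_states),
              function(i) rates$death(space$states[i, ]), numeric(1))
  f <- function(c) dominant_eigenvalue(A - c * Matrix::Diagonal(space$n_states, m))
  if (sA <= 0) return(list(value = 0, converged = TRUE))  # extinct already at mu = 0
  hi <- mu_max
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
  if (f(hi) > 0) return(list(value = NA_real_, converged = FALSE))
  root <- stats::uniroot(f, lower = 0, upper = hi, tol = 1e-10)
  list(value = root$root, converged = TRUE)
}

#' Critical turnover for many jointly constrained chromosomes
#'
#' When cell viability requires every chromosome `c` to stay inside its own
#' interval `[k_c, K_c]`, the joint truncated single-daughter matrix is the
#' Kronecker product of the per-chromosome matrices
#' `(Q_c)_{i -> j} = P(j - i | i)` (the viable box is a product set and
#' chromosomes missegregate independently), so its spectral radius factorizes
#' and \deqn{\mu_{crit}/\lambda = 2 \prod_c \rho(Q_c) - 1.}
#' This evaluates the 22-autosome critical turnover without enumerating
#' `8^22` joint states.
#'
#' @param per_chrom_intervals A list of `c(lo, hi)` intervals (or a single
#'   interval to be replicated).
#' @param beta Homogeneous per-copy missegregation rate.
#' @param n_chromosomes If supplied with a single interval, the number of
#'   identical chromosomes.
#' @return The critical turnover `mu_crit / lambda`.
#' @examples
#' multichromosome_critical(list(c(1, 1), c(1, 1)), 0.1)  # 2*(0.9)^2 - 1
#' multichromosome_critical(c(1, 8), 0.005, n_chromosomes = 22)
#' @export
multichromosome_critical <- function(per_chrom_intervals, beta,
                                     n_chromosomes = NULL) {
  if (!is.list(per_chrom_intervals)) {
    per_chrom_intervals <- list(per_chrom_intervals)
  }
  if (!is.null(n_chromosomes)) {
    if (length(per_chrom_intervals) != 1L) {
      rlang::abort("`n_chromosomes` applies to a single replicated interval")
    }
    per_chrom_intervals <- rep(per_chrom_intervals, n_chromosomes)
  }
  rhos <- vapply(per_chrom_intervals, function(iv) {
    spectral_radius(single_daughter_matrix(iv[1], iv[2], beta))
  }, numeric(1))
  2 * prod(rhos) - 1
}

# Truncated single-chromosome single-daughter matrix on [lo, hi].
single_daughter_matrix <- function(lo, hi, beta) {
  copies <- seq.int(lo, hi)
  S <- length(copies)
  Q <- matrix(0, S, S)
  for (a in seq_len(S)) {
    i_k <- copies[a]
    if (i_k < 1L) next
    pr <- shift_probs(i_k, beta)  # shifts -i_k..i_k
    for (b in seq_len(S)) {
      t <- copies[b] - i_k
      if (abs(t) <= i_k) Q[a, b] <- pr[t + i_k + 1L]
    }
  }
  Q
}

#' Quasi-steady-state karyotype proportions from the dominant eigenvector
#'
#' For a simple dominant eigenvalue the long-run karyotype composition is the
#' corresponding right eigenvector of `J`, sign-fixed nonnegative and
#' normalized to sum 1.
#'
#' @param J A [build_generator()] result or Metzler matrix.
#' @param gap_tol Minimum spectral gap below which the dominant pair is
#'   declared degenerate (an error, never a silent answer).
#' @return A proportion vector over the states.
#' @export
steady_state_proportions <- function(J, gap_tol = 1e-10) {
  J <- as_generator_J(J)
  ed <- eigen(as.matrix(J))
  re <- Re(ed$values)
  ord <- order(re, decreasing = TRUE)
  i1 <- ord[1]
  if (length(ord) > 1 && re[i1] - re[ord[2]] < gap_tol) {
    rlang::abort("dominant eigenvalue is not simple: steady-state proportions undefined")
  }
  if (abs(Im(ed$values[i1])) > 1e-8) {
    rlang::abort("dominant eigenvalue is complex: not a Metzler generator?")
  }
  v <- Re(ed$vectors[, i1])
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8 * max(abs(v)))) {
    rlang::abort("dominant eigenvector has mixed signs: degenerate dominant pair")
  }
  v <- pmax(v, 0)
  v / sum(v)
}

#' Continuum (diffusion) model of ploidy and its extinction threshold
#'
#' The coarse continuum picture treats total DNA content `p` as a continuous
#' variable obeying `dn/dt = (lambda - mu) n + beta lambda d2n/dp2` on the
#' viable interval `(p_min, p_max)` with absorbing boundaries. Separation of
#' variables gives the dominant growth rate
#' `(lambda - mu) - beta lambda (pi / L)^2` with `L = p_max - p_min`, hence
#' extinction exactly when `mu/lambda > 1 - beta pi^2 / L^2`. The companion
#' timescale heuristic says MIE is plausible when the missegregation
#' (diffusion) timescale `T_p = L_p^2 / (beta lambda)` is much shorter than
#' the net-growth timescale `T_r = 1/(lambda - mu)`.
#'
#' @param lam,mu Birth and death rates (`lam > mu` assumed for the heuristic).
#' @param beta Missegregation rate.
#' @param p_min,p_max Viable DNA-content bounds (`p_max > p_min`).
#' @param L_p Characteristic DNA-content shift per missegregation event
#'   (default 1: one chromosome).
#' @return An object of class `continuum_model`.
#' @export
continuum_model <- function(lam, mu, beta, p_min, p_max, L_p = 1) {
  if (p_max <= p_min) rlang::abort("`p_max` must exceed `p_min`.")
  if (lam <= 0) rlang::abort("`lam` must be > 0.")
  structure(list(lam = lam, mu = mu, beta = beta, p_min = p_min,
                 p_max = p_max, L_p = L_p, r = lam - mu),
            class = "continuum_model")
}

#' @describeIn continuum_model Closed-form extinction threshold and timescale
#'   heuristic. `much_less_factor` quantifies the "much shorter" in
#'   `T_p << T_r`.
#' @param model A [continuum_model()].
#' @param much_less_factor Factor defining the heuristic inequality
#'   `L_p^2 < factor * beta * lambda / (lambda - mu)`.
#' @return A one-row tibble: `critical_turnover` (`1 - beta pi^2 / L^2`),
#'   `beta_critical` (`(1 - mu/lam) L^2 / pi^2`), `mie_predicted` (is the
#'   supplied `(mu, beta)` beyond the threshold?), `mie_heuristic` (timescale
#'   argument), `T_p`, `T_r`.
#' @export
continuum_critical <- function(model, much_less_factor = 0.1) {
  L <- model$p_max - model$p_min
  crit_turnover <- 1 - model$beta * pi^2 / L^2
  beta_critical <- (1 - model$mu / model$lam) * L^2 / pi^2
  T_p <- if (model$beta > 0) model$L_p^2 / (model$beta * model$lam) else Inf
  T_r <- if (model$r > 0) 1 / model$r else Inf
  heur <- model$r > 0 &&
    model$L_p^2 < much_less_factor * model$beta * model$lam / model$r
  tibble::tibble(critical_turnover = crit_turnover,
                 beta_critical = beta_critical,
                 mie_predicted = model$mu / model$lam > crit_turnover,
                 mie_heuristic = heur, T_p = T_p, T_r = T_r)
}
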