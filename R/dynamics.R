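#' Linear generator of the karyotype birth-death model
#'
#' Assembles the sparse Jacobian `J` of the linear ODE `dn/dt = J n` (column
#' convention; `n` is the column vector of per-karyotype abundances) from the
#' truncated division tensor:
#' \deqn{J_{ii} = \lambda_i (2 q_{ii} - 1) - \mu_i, \qquad
#'       J_{ij} = \lambda_j q_{j \to i} \; (i \neq j),}
#' where `q` is the division-event tensor. Equivalently
#' `J = 2 Lambda Qt' - (Lambda + diag(mu))` with `Qt` the truncated
#' single-daughter matrix -- the form the spectral shortcuts exploit. `J` is
#' Metzler (nonnegative off-diagonal), so its spectral abscissa is a real
#' eigenvalue whose sign classifies extinction versus growth.
#'
#' States containing a zero-copy chromosome (when the declared box allows
#' them) are absorbing: they never divide and decay at their death rate.
#'
#' @param space A [karyo_space()].
#' @param rates A [rate_model()].
#' @param truncate Drop flux to nonviable daughters (the standard model).
#'   With `truncate = FALSE` the generator is assembled over the extended box
#'   `[0, 2*viable_hi]` with the out-of-box states absorbing non-dividers, so
#'   no probability flux is lost -- the bookkeeping form behind the
#'   conservation identity `sum(n(t)) = sum(n(0)) exp((lambda - mu) t)` for
#'   homogeneous rates (its rate kernels must therefore be defined on the
#'   extended box; constant kernels always are).
#' @return An object of class `generator_matrix` with the sparse matrix `J`,
#'   the per-state rate tibble, the tensor, and the space `J` is indexed by
#'   (the extended box when `truncate = FALSE`).
#' @export
build_generator <- function(space, rates, truncate = TRUE) {
  rate_tab <- validate_rates(space, rates)
  tensor <- division_tensor(space, rates, truncate = truncate)
  if (truncate) {
    Q1 <- tensor$daughter_form
    lam_eff <- ifelse(tensor$dividing, rate_tab$lambda, 0)
    mu <- rate_tab$mu
    J_space <- space
  } else {
    # embed: rows = extended box, parents only the original viable dividers
    ext <- tensor$target_space
    E <- ext$n_states
    map <- index_of(ext, space$states)
    Q1 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(E, E))
    Q1[map, ] <- tensor$daughter_form
    lam_eff <- numeric(E)
    lam_eff[map] <- ifelse(tensor$dividing, rate_tab$lambda, 0)
    mu <- vapply(seq_len(E), function(i) rates$death(ext$states[i, ]),
                 numeric(1))
    J_space <- ext
  }
  S <- J_space$n_states
  J <- 2 * Matrix::t(Q1) %*% Matrix::Diagonal(S, lam_eff) -
    Matrix::Diagonal(S, lam_eff + mu)
  structure(
    list(space = J_space, J = methods::as(J, "CsparseMatrix"), rates = rates,
         rate_table = rate_tab, tensor = tensor, truncated = truncate),
    class = "generator_matrix"
  )
}

#' @export
print.generator_matrix <- function(x, ...) {
  cat(sprintf("<generator_matrix> %d x %d, %d nonzeros\n",
              nrow(x$J), ncol(x$J), Matrix::nnzero(x$J)))
  invisible(x)
}

#' Simulate the karyotype ODE to quasi-steady state
#'
#' Integrates `dn/dt = J n` until the karyotype *composition*
#' `p = n / sum(n)` stops changing, which is the quasi-steady state: the
#' population total may still grow or shrink exponentially. To stay
#' well-conditioned over thousands of days of exponential dynamics the
#' integrator works on the bounded system for `p` and the log total,
#' `dp/dt = J p - (1' J p) p`, `d log N/dt = 1' J p`, with `lsoda`
#' (stiffness-switching). QSS is declared when the L1 change in composition
#' per day between successive checkpoints drops below `qss_tol`; the run is
#' then classified as `"growth"` if the total is increasing
#' (`d log N / dt > 0`) and `"extinction"` otherwise.
#'
#' @param gen A [build_generator()] result.
#' @param n0 Initial abundance vector over states (nonnegative, positive
#'   total), or an initial karyotype (length-`M` integer vector). Default: all
#'   mass on the diploid state (all copies 2, clamped into the box).
#' @param qss_tol Composition-change threshold, per day (default `0.001`,
#'   i.e. 0.1 percent per day).
#' @param t_max Integration horizon in days.
#' @param dt_check Days between convergence checkpoints.
#' @return An object of class `qss_result`: `composition` (proportions),
#'   `growth_rate` (d log N / dt at QSS, per day), `classification`
#'   (`"growth"`/`"extinction"`), `beta_pop`, `mu_pop`, `converged`, `t_end`,
#'   `log_total`, and the checkpoint `trajectory` tibble.
#' @export
simulate_to_qss <- function(gen, n0 = NULL, qss_tol = 0.001, t_max = 1e4,
                            dt_check = 10) {
  space <- gen$space
  S <- space$n_states
  if (is.null(n0)) {
    n0 <- diploid_start(space)
  } else if (length(n0) == space$M && S != space$M) {
    n0 <- diploid_start(space, copies = n0)
  }
  if (length(n0) != S || any(n0 < 0) || sum(n0) <= 0) {
    rlang::abort("`n0` must be a nonnegative abundance vector with positive total")
  }
  J <- gen$J
  p <- n0 / sum(n0)
  log_total <- log(sum(n0))
  deriv <- function(t, y, parms) {
    pp <- y[seq_len(S)]
    flux <- as.numeric(J %*% pp)
    s <- sum(flux)
    list(c(flux - s * pp, s))
  }
  times_traj <- list()
  t_now <- 0
  converged <- FALSE
  growth_rate <- sum(J %*% p)
  record <- function(t, p, log_total) {
    tibble::tibble(t = t, log_total = log_total,
                   state = seq_len(S), proportion = p)
  }
  times_traj[[1]] <- record(0, p, log_total)
  while (t_now < t_max) {
    t_next <- min(t_now + dt_check, t_max)
    sol <- deSolve::lsoda(y = c(p, log_total), times = c(t_now, t_next),
                          func = deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    y <- unname(sol[nrow(sol), -1L])
    p_new <- pmax(y[seq_len(S)], 0)
    p_new <- p_new / sum(p_new)
    log_total <- y[S + 1L]
    delta_per_day <- sum(abs(p_new - p)) / (t_next - t_now)
    p <- p_new
    t_now <- t_next
    times_traj[[length(times_traj) + 1L]] <- record(t_now, p, log_total)
    if (delta_per_day < qss_tol) {
      converged <- TRUE
      break
    }
  }
  growth_rate <- sum(as.numeric(J %*% p))
  summ <- population_summaries(p, gen$rates, space)
  structure(
    list(composition = p, growth_rate = growth_rate,
         classification = if (growth_rate > 0) "growth" else "extinction",
         beta_pop = summ$beta_pop, mu_pop = summ$mu_pop,
         converged = converged, t_end = t_now, log_total = log_total,
         final_state = list(t = t_now, log_total = log_total, p = p),
         trajectory = dplyr::bind_rows(times_traj), space = space),
    class = "qss_result"
  )
}

#' @export
print.qss_result <- function(x, ...) {
  cat(sprintf("<qss_result> %s (growth rate %.4g /day) at t = %g days%s\n",
              x$classification, x$growth_rate, x$t_end,
              if (x$converged) "" else " [NOT converged]"))
  cat(sprintf("  beta_pop = %.4g, mu_pop = %.4g\n", x$beta_pop, x$mu_pop))
  invisible(x)
}

#' @describeIn simulate_to_qss Checkpoint trajectory as a long tibble
#'   `(t, log_total, state, proportion)`.
#' @param x A `qss_result`.
#' @param ... Unused.
#' @export
tidy.qss_result <- function(x, ...) {
  x$trajectory
}

#' @describeIn simulate_to_qss One-row model-level summary.
#' @export
glance.qss_result <- function(x, ...) {
  tibble::tibble(classification = x$classification,
                 growth_rate = x$growth_rate, beta_pop = x$beta_pop,
                 mu_pop = x$mu_pop, converged = x$converged, t_end = x$t_end,
                 log_total = x$log_total)
}

#' Population-average missegregation and death rates
#'
#' The population-average missegregation rate `beta_pop` is the expected
#' fraction of divisions with at least one missegregation,
#' `sum_i p_i (1 - (1 - beta_i)^{ploidy_i})`, and `mu_pop` is the
#' abundance-weighted mean death rate; weights are cell proportions.
#'
#' @param n Abundance (or proportion) vector over the states of `space`, with
#'   positive total.
#' @param rates A [rate_model()].
#' @param space A [karyo_space()].
#' @return A one-row tibble with `beta_pop` and `mu_pop`.
#' @export
population_summaries <- function(n, rates, space) {
  if (length(n) != space$n_states) {
    rlang::abort("`n` must have one entry per state of `space`")
  }
  if (sum(n) <= 0) rlang::abort("empty population: sum(n) must be > 0")
  p <- n / sum(n)
  S <- space$n_states
  beta_i <- vapply(seq_len(S), function(i) rates$misseg(space$states[i, ]), numeric(1))
  mu_i <- vapply(seq_len(S), function(i) rates$death(space$states[i, ]), numeric(1))
  ploidy <- aggregate_ploidy(space$states)
  tibble::tibble(
    beta_pop = sum(p * per_division_rate(beta_i, ploidy)),
    mu_pop = sum(p * mu_i)
  )
}
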