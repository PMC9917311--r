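#' Rate models: birth, death and missegregation as functions of karyotype
#'
#' A `rate_model` bundles three per-karyotype rate functions: the birth rate
#' `lambda` (divisions/day, > 0), the death rate `mu` (deaths/day, >= 0) and
#' the missegregation rate `beta` (missegregations per chromosome copy per
#' division, in \[0, 1\]). Constant ("homogeneous") kernels give the classic
#' setting of the critical-curve analysis; karyotype-dependent kernels model
#' intra-tumor heterogeneity in these rates.
#'
#' @param birth,death,misseg Kernel functions taking a karyotype (integer
#'   vector) and returning a single rate, e.g. built with [constant_kernel()],
#'   [linear_kernel()], [sinusoidal_kernel()] or [tabulated_kernel()].
#' @return An object of class `rate_model` with elements `birth`, `death`,
#'   `misseg` and a `kinds` character vector recording each component's kernel
#'   family.
#' @seealso [constant_rates()] for the all-constant shortcut,
#'   [validate_rates()] to check a model over a whole space.
#' @export
rate_model <- function(birth, death, misseg) {
  comp <- list(birth = birth, death = death, misseg = misseg)
  for (nm in names(comp)) {
    if (!is.function(comp[[nm]])) {
      rlang::abort(sprintf("`%s` must be a kernel function (karyotype -> rate).", nm))
    }
  }
  kinds <- vapply(comp, function(f) attr(f, "kernel_kind") %||% "custom", character(1))
  structure(list(birth = birth, death = death, misseg = misseg, kinds = kinds),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model>\n")
  for (nm in c("birth", "death", "misseg")) {
    cat(sprintf("  %-7s %s\n", nm, x$kinds[[nm]]))
  }
  invisible(x)
}

#' Homogeneous (constant) rate model
#'
#' All three rates independent of karyotype. With `beta = 0` this is the
#' uncoupled deterministic birth-death process `dn_i/dt = (lambda - mu) n_i`.
#' Turnover `mu/lambda` above 1 is allowed (a shrinking population).
#'
#' @param lam Birth rate, divisions/day (> 0).
#' @param mu Death rate, deaths/day (>= 0).
#' @param beta Missegregation rate per chromosome copy per division, in \[0, 1\].
#' @return A [rate_model()].
#' @export
constant_rates <- function(lam, mu, beta) {
  if (!is.numeric(lam) || lam <= 0) rlang::abort("`lam` must be > 0.")
  if (!is.numeric(mu) || mu < 0) rlang::abort("`mu` must be >= 0.")
  if (!is.numeric(beta) || beta < 0 || beta > 1) {
    rlang::abort("`beta` must lie in [0, 1].")
  }
  rate_model(constant_kernel(lam), constant_kernel(mu), constant_kernel(beta))
}

#' Kernel families
#'
#' Kernels map a karyotype to a rate. `constant_kernel()` ignores the
#' karyotype. `linear_kernel()` is affine in the copy number of one chromosome:
#' `value = base + slope * (copies[chromosome] - c_ref)`, clipped to
#' `[floor, ceil]`. `sinusoidal_kernel()` depends on aggregate ploidy through a
#' phase-anchored cosine with its maximum at `p_peak`:
#' `value = base + amplitude * cos(2*pi*(ploidy - p_peak)/period)`, clipped.
#' `tabulated_kernel()` looks rates up in a table keyed by karyotype.
#'
#' The two missegregation wrappers [linear_beta_kernel()] and
#' [sinusoidal_beta_kernel()] fix the clipping bounds inside \[0, 1\]; death
#' kernels reuse the same families with a nonnegative floor.
#'
#' @param value Constant rate.
#' @param slope Change in rate per extra chromosome copy (theta1 of the linear
#'   missegregation kernel).
#' @param base Baseline rate at the reference copy number / at a quarter
#'   period from the peak.
#' @param c_ref Reference copy number at which the linear kernel equals `base`
#'   (default 2, the diploid copy count).
#' @param chromosome Which chromosome's copy number drives the linear kernel.
#' @param amplitude Cosine amplitude (theta2 of the sinusoidal missegregation
#'   kernel).
#' @param p_peak Aggregate ploidy at which the cosine attains its maximum.
#' @param period Ploidy distance after which the cosine repeats; the minimum
#'   ("refuge") sits at `p_peak + period/2`.
#' @param floor,ceil Clipping bounds applied to the kernel output.
#' @param values A data frame with columns `state` (comma-separated copy
#'   numbers, e.g. `"3"` or `"2,3"`) and `rate`, or a named numeric vector
#'   with the same keys.
#' @return A kernel function `karyotype -> rate`, tagged with its family.
#' @name kernels
NULL

tag_kernel <- function(f, kind, params = list()) {
  attr(f, "kernel_kind") <- kind
  attr(f, "kernel_params") <- params
  f
}

#' @rdname kernels
#' @export
constant_kernel <- function(value) {
  force(value)
  tag_kernel(function(k) value, "constant", list(value = value))
}

#' @rdname kernels
#' @export
linear_kernel <- function(slope, base, c_ref = 2, chromosome = 1,
                          floor = 0, ceil = Inf) {
  if (floor > ceil) rlang::abort("`floor` must not exceed `ceil`.")
  force(slope); force(base); force(c_ref); force(chromosome)
  tag_kernel(function(k) {
    min(max(base + slope * (k[[chromosome]] - c_ref), floor), ceil)
  }, "linear", list(slope = slope, base = base, c_ref = c_ref,
                    chromosome = chromosome, floor = floor, ceil = ceil))
}

#' @rdname kernels
#' @export
sinusoidal_kernel <- function(amplitude, base, p_peak = 66, period = 44,
                              floor = 0, ceil = Inf) {
  if (period <= 0) rlang::abort("`period` must be > 0.")
  if (floor > ceil) rlang::abort("`floor` must not exceed `ceil`.")
  force(amplitude); force(base); force(p_peak); force(period)
  tag_kernel(function(k) {
    p <- aggregate_ploidy(k)
    min(max(base + amplitude * cos(2 * pi * (p - p_peak) / period), floor), ceil)
  }, "sinusoidal", list(amplitude = amplitude, base = base, p_peak = p_peak,
                        period = period, floor = floor, ceil = ceil))
}

#' @rdname kernels
#' @param theta1 Slope of the linear missegregation kernel (per copy).
#' @param b0 Baseline missegregation rate.
#' @export
linear_beta_kernel <- function(theta1, b0, c_ref = 2, chromosome = 1,
                               floor = 1e-4, ceil = 1) {
  if (floor < 0 || ceil > 1) {
    rlang::abort("missegregation kernel bounds must lie inside [0, 1].")
  }
  linear_kernel(theta1, b0, c_ref = c_ref, chromosome = chromosome,
                floor = floor, ceil = ceil)
}

#' @rdname kernels
#' @param theta2 Amplitude of the sinusoidal missegregation kernel.
#' @export
sinusoidal_beta_kernel <- function(theta2, b0, p_peak = 66, period = 44,
                                   floor = 1e-4, ceil = 1) {
  if (floor < 0 || ceil > 1) {
    rlang::abort("missegregation kernel bounds must lie inside [0, 1].")
  }
  sinusoidal_kernel(theta2, b0, p_peak = p_peak, period = period,
                    floor = floor, ceil = ceil)
}

karyotype_key <- function(k) paste(as.integer(k), collapse = ",")

#' @rdname kernels
#' @export
tabulated_kernel <- function(values) {
  if (is.data.frame(values)) {
    if (!all(c("state", "rate") %in% names(values))) {
      rlang::abort("tabulated kernel table needs columns `state` and `rate`.")
    }
    tab <- stats::setNames(values$rate, as.character(values$state))
  } else if (is.numeric(values) && !is.null(names(values))) {
    tab <- values
  } else {
    rlang::abort("`values` must be a (state, rate) data frame or a named numeric vector.")
  }
  # normalize keys: strip whitespace
  names(tab) <- gsub("\\s+", "", names(tab))
  tag_kernel(function(k) {
    key <- karyotype_key(k)
    if (!key %in% names(tab)) {
      rlang::abort(sprintf("tabulated kernel has no entry for state (%s)", key))
    }
    unname(tab[[key]])
  }, "tabulated", list(table = tab))
}

#' Evaluate a rate model over every state of a space
#'
#' @param space A [karyo_space()].
#' @param rates A [rate_model()].
#' @return A tibble with one row per state: `index`, `lambda`, `mu`, `beta`.
#' @export
evaluate_rates <- function(space, rates) {
  S <- space$n_states
  lam <- numeric(S); mu <- numeric(S); beta <- numeric(S)
  for (i in seq_len(S)) {
    k <- space$states[i, ]
    lam[i] <- rates$birth(k)
    mu[i] <- rates$death(k)
    beta[i] <- rates$misseg(k)
  }
  tibble::tibble(index = seq_len(S), lambda = lam, mu = mu, beta = beta)
}

#' Validate a rate model over a whole space
#'
#' Checks `lambda > 0`, `mu >= 0` and `beta` in \[0, 1\] for every viable
#' state; for tabulated kernels this also surfaces missing states, listed in
#' the error.
#'
#' @inheritParams evaluate_rates
#' @return The evaluated rate tibble (invisibly useful downstream), or an
#'   error describing every violation.
#' @export
validate_rates <- function(space, rates) {
  tab <- tryCatch(evaluate_rates(space, rates), error = function(e) e)
  if (inherits(tab, "error")) {
    # find all missing states for a clearer message
    missing <- character(0)
    for (i in seq_len(space$n_states)) {
      ok <- tryCatch({
        rates$birth(space$states[i, ]); rates$death(space$states[i, ])
        rates$misseg(space$states[i, ]); TRUE
      }, error = function(e) FALSE)
      if (!ok) missing <- c(missing, karyotype_key(space$states[i, ]))
    }
    rlang::abort(paste0("rate model undefined for state(s): ",
                        paste0("(", missing, ")", collapse = ", ")))
  }
  bad <- character(0)
  if (any(tab$lambda <= 0)) bad <- c(bad, "birth rate must be > 0 for every state")
  if (any(tab$mu < 0)) bad <- c(bad, "death rate must be >= 0 for every state")
  if (any(tab$beta < 0 | tab$beta > 1)) {
    bad <- c(bad, "missegregation rate must lie in [0, 1] for every state")
  }
  if (length(bad)) rlang::abort(paste(bad, collapse = "; "))
  invisible(tab)
}

#' Per-division missegregation probability
#'
#' Converts the per-copy rate `beta` into the probability that at least one of
#' `copies` independently segregating chromosome copies missegregates in a
#' division: `1 - (1 - beta)^copies`. This is the scale on which
#' population-average missegregation rates are reported.
#'
#' @param beta Per-copy missegregation rate in \[0, 1\] (vectorized).
#' @param copies Number of chromosome copies being segregated (>= 0).
#' @return Per-division missegregation probability.
#' @examples
#' per_division_rate(0.001, 44)  # ~0.043 for a near-diploid genome
#' @export
per_division_rate <- function(beta, copies) {
  if (any(beta < 0 | beta > 1)) rlang::abort("`beta` must lie in [0, 1].")
  if (any(copies < 0)) rlang::abort("`copies` must be >= 0.")
  1 - (1 - beta)^copies
}
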