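#' Integer karyotype and tumor/normal bias from chromosome expression ratios
#'
#' Estimates per-chromosome integer copy numbers of a tumor cell population
#' from chromosome-level mean expression in tumor versus normal cells,
#' assuming (i) chromosome expression scales with copy number, (ii) at least
#' one chromosome is diploid in all tumor cells, and (iii) SCNAs are clonal.
#' Because tumor and normal cells differ systematically (cell type, library
#' quality), the tumor/normal ratio carries a global multiplicative bias that
#' must be estimated jointly with the copy numbers.
#'
#' Chromosomes are sorted by differential-expression p-value; under the
#' default `sort_mode` the *least* significant (largest p) come first, as
#' those are the best diploid candidates. For each split point `x` the first
#' `x` chromosomes are assumed diploid, giving a scale estimate
#' `s_x = mean(tumor/normal)` over them; the remaining chromosomes get
#' unrounded copy estimates `j_k = 2 (tumor_k/normal_k) / s_x`, and
#' `E_x` is the mean squared deviation of the `j_k` from their nearest
#' integers. The split `x*` minimizing `E_x` (ties: smallest `x`) fixes the
#' assumed-diploid set (copy number 2) and the rounded copies of the rest;
#' the reported bias is `1 - s_{x*}`. Rounding is half-away-from-zero.
#'
#' @param expr A data frame with columns `chromosome`, `tumor_mean`,
#'   `normal_mean` (strictly positive) and `de_pvalue` (in (0, 1\]).
#' @param sort_mode `"least_significant_first"` (default: largest p-values
#'   assumed diploid first) or `"most_significant_first"` (the literal
#'   descending-significance reading).
#' @param tie_factor,tie_abs Splits whose error is within
#'   `min(E) * tie_factor + tie_abs` of the best are treated as statistically
#'   tied, and the smallest such `x` wins. The copy scale is only identified
#'   up to rescalings that happen to land every estimate on an integer, and
#'   such degenerate splits produce spuriously deep minima with few residual
#'   chromosomes; among splits at the noise floor, the most parsimonious one
#'   (fewest chromosomes assumed diploid) is the one consistent with the
#'   differential-expression ranking.
#' @return An object of class `ploidy_estimate`: `x_star`, `scale`
#'   (`s_{x*}`), `bias` (`1 - s_{x*}`), `copies` (integer, original
#'   chromosome order), `raw_j` (unrounded estimates, `NA` for the
#'   assumed-diploid set), `error_profile` (tibble of `x`, `error`) and the
#'   per-chromosome `table`.
#' @export
estimate_ploidy <- function(expr,
                            sort_mode = c("least_significant_first",
                                          "most_significant_first"),
                            tie_factor = 30, tie_abs = 1e-9) {
  sort_mode <- rlang::arg_match(sort_mode)
  req <- c("chromosome", "tumor_mean", "normal_mean", "de_pvalue")
  missing <- setdiff(req, names(expr))
  if (length(missing)) {
    rlang::abort(paste0("`expr` is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (any(expr$tumor_mean <= 0) || any(expr$normal_mean <= 0)) {
    rlang::abort("tumor and normal mean expression must be strictly positive")
  }
  n <- nrow(expr)
  if (n < 2L) rlang::abort("need at least two chromosomes")
  ord <- if (sort_mode == "least_significant_first") {
    order(expr$de_pvalue, decreasing = TRUE)
  } else {
    order(expr$de_pvalue, decreasing = FALSE)
  }
  ratio <- (expr$tumor_mean / expr$normal_mean)[ord]
  xs <- seq_len(n - 1L)
  errs <- vapply(xs, function(x) {
    s_x <- mean(ratio[seq_len(x)])
    j <- 2 * ratio[(x + 1L):n] / s_x
    mean((j - round_half_away(j))^2)
  }, numeric(1))
  # ties go to the smallest x: with several splits at the noise floor --
  # a fully diploid tumor, or a degenerate rescaling that maps an aneuploid
  # block onto integers -- the most parsimonious split wins
  x_star <- xs[which(errs <= min(errs) * tie_factor + tie_abs)[1]]
  s <- mean(ratio[seq_len(x_star)])
  j <- 2 * ratio[(x_star + 1L):n] / s
  copies_sorted <- c(rep(2L, x_star), as.integer(round_half_away(j)))
  raw_sorted <- c(rep(NA_real_, x_star), j)
  copies <- integer(n); copies[ord] <- copies_sorted
  raw_j <- numeric(n); raw_j[ord] <- raw_sorted
  assumed <- logical(n); assumed[ord[seq_len(x_star)]] <- TRUE
  tab <- tibble::tibble(
    chromosome = expr$chromosome,
    tumor_mean = expr$tumor_mean, normal_mean = expr$normal_mean,
    de_pvalue = expr$de_pvalue, assumed_diploid = assumed,
    raw_copies = raw_j, copies = copies
  )
  structure(
    list(x_star = x_star, scale = s, bias = 1 - s, copies = copies,
         raw_j = raw_j,
         error_profile = tibble::tibble(x = xs, error = errs),
         table = tab, sort_mode = sort_mode),
    class = "ploidy_estimate"
  )
}

# round half away from zero (avoids bankers' rounding on exact .5 estimates)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.ploidy_estimate <- function(x, ...) {
  cat(sprintf("<ploidy_estimate> x* = %d assumed-diploid chromosomes, bias = %.4g\n",
              x$x_star, x$bias))
  cat(sprintf("  total copies: %d; min E_x = %.3g\n",
              sum(x$copies), min(x$error_profile$error)))
  invisible(x)
}

#' @describeIn estimate_ploidy Per-chromosome table with assumed-diploid
#'   flags, raw and rounded copy numbers.
#' @param x A `ploidy_estimate`.
#' @param ... Unused.
#' @export
tidy.ploidy_estimate <- function(x, ...) x$table

#' @describeIn estimate_ploidy One-row summary (`x_star`, `scale`, `bias`,
#'   `min_error`, total ploidy).
#' @export
glance.ploidy_estimate <- function(x, ...) {
  tibble::tibble(x_star = x$x_star, scale = x$scale, bias = x$bias,
                 min_error = min(x$error_profile$error),
                 ploidy = sum(x$copies))
}

#' Linear calibration between a transcriptomic score and a rate
#'
#' Ordinary least-squares fit of `y = a x + b`, the form used both for the
#' turnover calibration (pathway score vs literature turnover rate) and for
#' the missegregation calibration (interferon-gamma score vs log2 percent
#' lagging chromosomes).
#'
#' @param data A data frame holding the calibration points.
#' @param x,y Column names (strings) of predictor and response.
#' @param response_name What the response means: `"turnover"` or
#'   `"log2_pct_lagging"` (free text allowed).
#' @return An object of class `calibration_model` with `slope`, `intercept`,
#'   `adj_r_squared`, `n` and the underlying `lm` fit.
#' @export
fit_linear_calibration <- function(data, x = "x", y = "y",
                                   response_name = "response") {
  if (!all(c(x, y) %in% names(data))) {
    rlang::abort(sprintf("`data` must contain columns `%s` and `%s`", x, y))
  }
  xv <- data[[x]]; yv <- data[[y]]
  if (length(unique(xv)) < 2L) {
    rlang::abort("degenerate predictor: need at least 2 distinct x values")
  }
  fit <- stats::lm(yv ~ xv)
  s <- suppressWarnings(summary(fit))  # noiseless fixtures fit perfectly
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         adj_r_squared = s$adj.r.squared, n = length(xv),
         response_name = response_name, fit = fit),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s = %.4g * score + %.4g (adj R^2 = %.3g, n = %d)\n",
              x$response_name, x$slope, x$intercept, x$adj_r_squared, x$n))
  invisible(x)
}

#' @describeIn fit_linear_calibration Coefficient table (term, estimate).
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @describeIn fit_linear_calibration One-row fit summary.
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 adj_r_squared = x$adj_r_squared, n = x$n,
                 response = x$response_name)
}

#' Per-cell turnover rates from a fitted calibration
#'
#' Applies `tau = a * score + b` to per-cell pathway scores. Turnover above 1
#' (death exceeding birth, beyond homeostasis) is permitted but flagged.
#' Downstream modeling conventionally sets the birth rate to 1 and uses
#' `mu = tau` as the death rate.
#'
#' @param model A [fit_linear_calibration()] result (turnover response).
#' @param scores Numeric vector of per-cell pathway scores.
#' @return A tibble with `score`, `turnover` and `exceeds_homeostasis`.
#' @export
predict_turnover <- function(model, scores) {
  tau <- model$slope * scores + model$intercept
  out <- tibble::tibble(score = scores, turnover = tau,
                        exceeds_homeostasis = tau > 1)
  if (any(out$exceeds_homeostasis)) {
    rlang::inform(sprintf(
      "%d cell(s) have inferred turnover > 1 (beyond homeostasis); flagged.",
      sum(out$exceeds_homeostasis)))
  }
  out
}

#' Per-chromosome missegregation rates from an interferon-score calibration
#'
#' The calibration response is the log2 of the percentage of cells with
#' lagging chromosomes, so prediction inverts that transform:
#' `L = a * gamma + b`, per-division missegregation probability
#' `2^L / 100`, and per-chromosome rate `beta = per-division / ploidy`.
#' Values outside \[0, 1\] are clipped (and reported).
#'
#' @param model A [fit_linear_calibration()] result with a
#'   log2-percent-lagging response.
#' @param gamma Numeric vector of per-cell interferon-gamma signaling scores.
#' @param ploidy Per-cell total chromosome count (>= 1; recycled if scalar).
#' @return A tibble with `gamma`, `ploidy`, `log2_pct_lagging`,
#'   `per_division_rate`, `beta` and `clipped`.
#' @export
predict_missegregation <- function(model, gamma, ploidy) {
  if (length(ploidy) == 1L) ploidy <- rep(ploidy, length(gamma))
  if (length(ploidy) != length(gamma)) {
    rlang::abort("`gamma` and `ploidy` must have equal length (or scalar ploidy)")
  }
  if (any(ploidy < 1)) rlang::abort("`ploidy` must be >= 1")
  L <- model$slope * gamma + model$intercept
  per_div <- 2^L / 100
  beta_raw <- per_div / ploidy
  clipped <- beta_raw < 0 | beta_raw > 1
  if (any(clipped)) {
    rlang::inform(sprintf("%d beta value(s) clipped into [0, 1].", sum(clipped)))
  }
  tibble::tibble(gamma = gamma, ploidy = ploidy, log2_pct_lagging = L,
                 per_division_rate = per_div,
                 beta = pmin(pmax(beta_raw, 0), 1), clipped = clipped)
}
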