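#' Seeded synthetic fixtures for the rate-inference estimators
#'
#' `random_karyotype()` draws an integer karyotype with copies in
#' `[lo, hi]`; because the ploidy estimator assumes at least one diploid
#' chromosome, one randomly chosen chromosome is forced to 2 copies when the
#' draw contains none (`ensure_diploid = TRUE`).
#'
#' `generate_expression_fixture()` emulates the chromosome-level expression
#' summary the ploidy estimator consumes: per-chromosome normal-cell means are
#' drawn positive (lognormal), tumor means follow
#' `tumor_k = bias * (copy_k / 2) * normal_k * exp(e_k)` with
#' `e_k ~ N(0, noise_sigma^2)` (multiplicative lognormal noise keeps
#' expression positive), and differential-expression p-values are a
#' deterministic monotone surrogate of `|copy_k - 2|` with seeded jitter --
#' only their rank order matters to the estimator. Identical seeds give
#' byte-identical tables.
#'
#' @param n_chrom Number of chromosomes (22 autosomes by default).
#' @param lo,hi Copy-number range of the random karyotype.
#' @param ensure_diploid Force at least one diploid chromosome.
#' @param seed Integer seed (all randomness is local to the call).
#' @return `random_karyotype()`: an integer vector;
#'   `generate_expression_fixture()`: a tibble with columns `chromosome`,
#'   `tumor_mean`, `normal_mean`, `de_pvalue` and attribute `true_karyotype`.
#' @name synthetic_expression
NULL

#' @rdname synthetic_expression
#' @export
random_karyotype <- function(n_chrom = 22, lo = 1, hi = 4,
                             ensure_diploid = TRUE, seed = 1L) {
  withr::with_seed(seed, {
    k <- sample(lo:hi, n_chrom, replace = TRUE)
    if (ensure_diploid && !any(k == 2L)) {
      k[sample.int(n_chrom, 1L)] <- 2L
    }
    as.integer(k)
  })
}

#' @rdname synthetic_expression
#' @param karyotype True integer copy-number vector.
#' @param bias Global tumor/normal expression scale factor (> 0).
#' @param noise_sigma Lognormal noise sd on the tumor/normal ratio (>= 0).
#' @export
generate_expression_fixture <- function(karyotype, bias = 1, noise_sigma = 0,
                                        seed = 1L) {
  if (bias <= 0) rlang::abort("`bias` must be > 0")
  if (noise_sigma < 0) rlang::abort("`noise_sigma` must be >= 0")
  karyotype <- as.integer(karyotype)
  n <- length(karyotype)
  withr::with_seed(seed, {
    normal <- exp(stats::rnorm(n, mean = log(10), sd = 0.3))
    eps <- if (noise_sigma > 0) stats::rnorm(n, 0, noise_sigma) else numeric(n)
    tumor <- bias * (karyotype / 2) * normal * exp(eps)
    d <- abs(karyotype - 2L)
    jitter <- stats::runif(n)
    # monotone surrogate: diploid chromosomes get large p, SCNAs small p,
    # strictly separated by |copy - 2|
    pval <- ifelse(d == 0L, 0.5 + 0.49 * jitter,
                   exp(-3 * d) * (0.5 + 0.4 * jitter))
  })
  out <- tibble::tibble(
    chromosome = paste0("chr", seq_len(n)),
    tumor_mean = tumor, normal_mean = normal, de_pvalue = pval
  )
  attr(out, "true_karyotype") <- karyotype
  out
}

#' Synthetic linear calibration table
#'
#' `y = a * x + b + N(0, noise_sd^2)` over a fixed score grid; with zero
#' noise the downstream OLS fit recovers `(a, b)` exactly.
#'
#' @param a,b True slope and intercept.
#' @param x_grid Numeric vector of at least 2 score values.
#' @param noise_sd Gaussian response noise (>= 0).
#' @param seed Integer seed.
#' @return A tibble with columns `x` and `y`.
#' @export
generate_calibration_table <- function(a, b, x_grid, noise_sd = 0, seed = 1L) {
  if (length(x_grid) < 2L) rlang::abort("`x_grid` needs at least 2 points")
  if (noise_sd < 0) rlang::abort("`noise_sd` must be >= 0")
  y <- withr::with_seed(seed, {
    a * x_grid + b + if (noise_sd > 0) stats::rnorm(length(x_grid), 0, noise_sd)
    else 0
  })
  tibble::tibble(x = x_grid, y = y)
}

#' Monte-Carlo division sampling (mechanism-level oracle)
#'
#' Simulates `n` divisions of a parent karyotype: each chromosome copy
#' missegregates independently with probability `beta`, and each
#' missegregated chromatid pair lands wholly in daughter one or two with
#' probability 1/2. Every sampled pair satisfies copy-number conservation
#' `j1 + j2 = 2 * parent` exactly by construction; the empirical
#' single-daughter frequencies converge to the product-form daughter
#' distribution.
#'
#' @param parent Integer karyotype (all entries >= 1).
#' @param beta Per-copy missegregation rate in \[0, 1\].
#' @param n Number of divisions to sample.
#' @param seed Integer seed.
#' @return A tibble of daughter pairs with columns `daughter1`, `daughter2`
#'   (comma-separated copy-number keys), `count` and `freq`, with the parent
#'   karyotype as attribute `parent`.
#' @seealso [parse_karyotype_key()] to recover integer vectors from the keys.
#' @export
sample_divisions <- function(parent, beta, n, seed = 1L) {
  parent <- as.integer(parent)
  if (any(parent < 1L)) rlang::abort("parent copies must all be >= 1")
  if (beta < 0 || beta > 1) rlang::abort("`beta` must lie in [0, 1].")
  if (n < 1) rlang::abort("`n` must be >= 1")
  M <- length(parent)
  j1 <- withr::with_seed(seed, {
    m <- matrix(0L, nrow = n, ncol = M)
    for (k in seq_len(M)) {
      z <- stats::rbinom(n, parent[k], beta)
      g <- stats::rbinom(n, z, 0.5)
      m[, k] <- parent[k] + 2L * g - z
    }
    m
  })
  j2 <- sweep(-j1, 2L, 2L * parent, "+")
  key1 <- do.call(paste, c(as.data.frame(j1), sep = ","))
  key2 <- do.call(paste, c(as.data.frame(j2), sep = ","))
  out <- tibble::tibble(daughter1 = key1, daughter2 = key2) |>
    dplyr::count(.data$daughter1, .data$daughter2, name = "count") |>
    dplyr::mutate(freq = .data$count / n) |>
    dplyr::arrange(dplyr::desc(.data$count))
  attr(out, "parent") <- parent
  attr(out, "n") <- n
  out
}

#' @rdname sample_divisions
#' @param key Character vector of comma-separated copy-number keys.
#' @export
parse_karyotype_key <- function(key) {
  m <- do.call(rbind, lapply(strsplit(key, ","), as.integer))
  colnames(m) <- paste0("chr", seq_len(ncol(m)))
  m
}
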