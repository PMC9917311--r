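#' Per-chromosome shift distribution under missegregation
#'
#' During mitosis each of the parent's `i_k` copies of a chromosome replicates
#' into a chromatid pair; with probability `beta` per copy the pair
#' missegregates and both chromatids land in the same daughter (chosen with
#' probability 1/2 each). The net shift `t` in the first daughter's copy
#' number is then distributed as
#' \deqn{P(t \mid i_k) = \sum_{z = |t|,\; z \equiv t (2)}^{i_k}
#'   \binom{i_k}{z} \beta^z (1-\beta)^{i_k - z} (1/2)^z \binom{z}{(z-t)/2},}
#' summing over the number `z` of missegregated copies, of which `(z+t)/2`
#' went to daughter one. The distribution is symmetric in `t`, sums to 1 over
#' `t` in `[-i_k, i_k]`, and satisfies `P(t|i_k) <= 1/2` for every `t != 0`.
#'
#' @param i_k Parent copy number of the chromosome (>= 1).
#' @param beta Missegregation rate per chromosome copy per division, in \[0, 1\].
#' @return A tibble of class `shift_distribution` with columns `t` (shift,
#'   `-i_k .. i_k`) and `prob`, and attributes `parent_copies` and `beta`.
#' @examples
#' shift_distribution(2, 0.1)   # P(0) = 0.815, P(+-1) = 0.09, P(+-2) = 0.0025
#' @export
shift_distribution <- function(i_k, beta) {
  check_shift_args(i_k, beta)
  t <- seq.int(-i_k, i_k)
  out <- tibble::tibble(t = t, prob = shift_probs(i_k, beta))
  new_shift_distribution(out, i_k, beta, source = "exact")
}

check_shift_args <- function(i_k, beta) {
  if (!is.numeric(i_k) || length(i_k) != 1L || i_k < 1 || i_k != round(i_k)) {
    rlang::abort("`i_k` must be a single integer >= 1.")
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta > 1) {
    rlang::abort("`beta` must lie in [0, 1].")
  }
}

new_shift_distribution <- function(tbl, i_k, beta, source) {
  structure(tbl,
            class = c("shift_distribution", class(tbl)),
            parent_copies = as.integer(i_k), beta = beta, source = source)
}

# P(t | i_k) for t = -i_k..i_k as a plain numeric vector.
shift_probs <- function(i_k, beta) {
  z <- 0:i_k
  pz <- stats::dbinom(z, i_k, beta)          # C(i,z) beta^z (1-beta)^(i-z)
  vapply(seq.int(-i_k, i_k), function(tt) {
    zz <- z[z >= abs(tt) & ((z - tt) %% 2) == 0]
    sum(pz[zz + 1L] * 0.5^zz * choose(zz, (zz - tt) / 2))
  }, numeric(1))
}

#' Monte-Carlo oracle for the shift distribution
#'
#' Samples the division mechanism directly -- each copy missegregates
#' independently with probability `beta`, each missegregated chromatid pair
#' goes wholly to daughter one or two with probability 1/2 -- and tabulates
#' the empirical shift frequencies. Used to cross-validate the closed form of
#' [shift_distribution()], never as the implementation.
#'
#' @inheritParams shift_distribution
#' @param n_samples Number of simulated divisions (>= 1).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A `shift_distribution` tibble of empirical frequencies, with an
#'   `n_samples` attribute.
#' @export
shift_distribution_oracle <- function(i_k, beta, n_samples = 1e5, seed = 1L) {
  check_shift_args(i_k, beta)
  if (n_samples < 1) rlang::abort("`n_samples` must be >= 1.")
  freq <- withr::with_seed(seed, {
    z <- stats::rbinom(n_samples, i_k, beta)    # missegregated copies
    g <- stats::rbinom(n_samples, z, 0.5)       # of which gained by daughter 1
    t <- 2L * g - z
    tabulate(t + i_k + 1L, nbins = 2L * i_k + 1L) / n_samples
  })
  out <- tibble::tibble(t = seq.int(-i_k, i_k), prob = freq)
  out <- new_shift_distribution(out, i_k, beta, source = "monte_carlo")
  attr(out, "n_samples") <- n_samples
  out
}

#' First-daughter karyotype distribution for one parent
#'
#' Chromosomes missegregate independently, so the probability that the first
#' daughter has karyotype `j` is the product over chromosomes of the
#' per-chromosome shift probabilities,
#' `q1(i -> j) = prod_k P(i_k - j_k | i_k)`, supported on daughters with
#' `j_k` in `[0, 2 i_k]`. The distribution sums to 1 before any viability
#' truncation.
#'
#' @param parent Integer karyotype vector with every entry >= 1 (cells that
#'   have lost all copies of a chromosome never divide).
#' @param rates A [rate_model()], or a single numeric `beta` for the
#'   homogeneous case.
#' @return A tibble of class `daughter_distribution` with one column per
#'   chromosome (`chr1..chrM`, the daughter karyotype) and `prob`.
#' @examples
#' daughter_distribution(c(1, 1), 0.5)  # q1((1,1) -> (1,1)) = 0.25
#' @export
daughter_distribution <- function(parent, rates) {
  parent <- as.integer(parent)
  if (any(parent < 1)) {
    rlang::abort("every chromosome of a dividing parent must have >= 1 copy")
  }
  beta <- if (is.numeric(rates)) rates else rates$misseg(parent)
  if (beta < 0 || beta > 1) rlang::abort("`beta` must lie in [0, 1].")
  M <- length(parent)
  per_chr <- lapply(parent, function(i_k) shift_probs(i_k, beta))
  shift_ranges <- lapply(parent, function(i_k) seq.int(-i_k, i_k))
  grid <- expand.grid(rev(shift_ranges), KEEP.OUT.ATTRS = FALSE)
  grid <- as.matrix(grid[, rev(seq_len(M)), drop = FALSE])
  prob <- rep(1, nrow(grid))
  for (k in seq_len(M)) {
    prob <- prob * per_chr[[k]][grid[, k] + parent[k] + 1L]
  }
  daughters <- sweep(grid, 2L, parent, "+")
  colnames(daughters) <- paste0("chr", seq_len(M))
  out <- tibble::as_tibble(as.data.frame(daughters))
  out$prob <- prob
  structure(out, class = c("daughter_distribution", class(tibble::tibble())),
            parent = parent, beta = beta)
}

#' Division tensor over a karyotype space
#'
#' Assembles the sparse parent-to-daughter transition structure of the model
#' in both of its forms. The *single-daughter* form `q1` gives the karyotype
#' distribution of the first daughter (rows sum to 1 before truncation). The
#' *division-event* form `q` describes what a division produces as an
#' unordered pair: by copy-number conservation the second daughter mirrors the
#' first (`j2 = 2i - j1`), and the shift distribution is symmetric, so
#' `q_ii = q1_ii` and `q_ij = 2 q1_ij` off the diagonal; untruncated rows sum
#' to `2 - q_ii`.
#'
#' With `truncate = TRUE` (the form the generator uses) probability flux to
#' daughters outside the viable box is dropped -- those daughters die
#' immediately -- without renormalization, so net growth is correctly reduced.
#' Parents containing a zero-copy chromosome are absorbing and get no
#' division row.
#'
#' @param space A [karyo_space()].
#' @param rates A [rate_model()] (only the missegregation component is used),
#'   or a single numeric `beta`.
#' @param truncate Drop flux to nonviable daughters? If `FALSE`, daughters are
#'   indexed in the extended box `[0, 2*viable_hi]` so that row-sum and
#'   mirror identities can be verified exactly.
#' @param drop_tol Entries at or below this value are not stored (no
#'   renormalization).
#' @return An object of class `division_tensor` with sparse matrices
#'   `daughter_form` and `division_form` (rows: viable parents; columns:
#'   viable states, or extended-box states when `truncate = FALSE`), the
#'   per-state `beta`, a `dividing` flag per state, and the target space.
#' @export
division_tensor <- function(space, rates, truncate = TRUE, drop_tol = 1e-12) {
  if (is.numeric(rates)) rates <- constant_rates(1, 0, rates)
  S <- space$n_states
  beta_by_state <- vapply(seq_len(S),
                          function(i) rates$misseg(space$states[i, ]),
                          numeric(1))
  if (any(beta_by_state < 0 | beta_by_state > 1)) {
    rlang::abort("missegregation kernel returned a rate outside [0, 1]")
  }
  dividing <- apply(space$states >= 1L, 1L, all)
  if (truncate) {
    target <- space
  } else {
    target <- karyo_space(space$M, 0L, 2L * space$viable_hi)
  }
  tp <- integer(0); td <- integer(0); tq1 <- numeric(0)
  for (p in which(dividing)) {
    dd <- daughter_distribution(space$states[p, ], beta_by_state[p])
    dmat <- as.matrix(dd[, seq_len(space$M), drop = FALSE])
    idx <- index_of(target, dmat)
    keep <- !is.na(idx) & dd$prob > drop_tol
    tp <- c(tp, rep.int(p, sum(keep)))
    td <- c(td, idx[keep])
    tq1 <- c(tq1, dd$prob[keep])
  }
  daughter_form <- Matrix::sparseMatrix(i = tp, j = td, x = tq1,
                                        dims = c(S, target$n_states))
  # division-event form: diagonal (daughter == parent) kept, off-diagonal doubled
  parent_idx_in_target <- index_of(target, space$states)
  is_diag <- td == parent_idx_in_target[tp]
  qdiv <- ifelse(is_diag, tq1, 2 * tq1)
  keep2 <- qdiv > drop_tol
  division_form <- Matrix::sparseMatrix(i = tp[keep2], j = td[keep2],
                                        x = qdiv[keep2],
                                        dims = c(S, target$n_states))
  structure(
    list(space = space, target_space = target,
         daughter_form = daughter_form, division_form = division_form,
         beta_by_state = beta_by_state, dividing = dividing,
         truncated = truncate, drop_tol = drop_tol),
    class = "division_tensor"
  )
}

#' @export
print.division_tensor <- function(x, ...) {
  cat(sprintf("<division_tensor> %d parent states -> %d daughter states (%s)\n",
              nrow(x$division_form), ncol(x$division_form),
              if (x$truncated) "truncated to viable box" else "untruncated"))
  cat(sprintf("  %d stored division-event entries\n",
              Matrix::nnzero(x$division_form)))
  invisible(x)
}

#' @describeIn division_tensor Tidy the tensor into sparse triplets
#'   `(parent_index, daughter_index, probability)`; `form` selects the
#'   division-event or single-daughter probabilities.
#' @param x A `division_tensor`.
#' @param form Which form to tidy: `"division"` (default) or `"daughter"`.
#' @param ... Unused.
#' @export
tidy.division_tensor <- function(x, form = c("division", "daughter"), ...) {
  form <- rlang::arg_match(form)
  m <- if (form == "division") x$division_form else x$daughter_form
  tr <- Matrix::mat2triplet(m)
  tibble::tibble(parent_index = tr$i, daughter_index = tr$j,
                 probability = tr$x) |>
    dplyr::arrange(.data$parent_index, .data$daughter_index)
}

#' Sparse-triplet text export of a division tensor
#'
#' Writes/reads the 3-column `(parent_index, daughter_index, probability)`
#' CSV dialect used for debugging and external tooling; the round trip is
#' exact.
#'
#' @param tensor A [division_tensor()].
#' @param path File path.
#' @param form Which form to export (`"division"` or `"daughter"`).
#' @return `write_tensor_triplets()` returns `path` invisibly;
#'   `read_tensor_triplets()` returns the triplet tibble.
#' @export
write_tensor_triplets <- function(tensor, path, form = c("division", "daughter")) {
  trip <- tidy.division_tensor(tensor, form = form)
  utils::write.csv(trip, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tensor_triplets
#' @export
read_tensor_triplets <- function(path) {
  df <- utils::read.csv(path)
  expected <- c("parent_index", "daughter_index", "probability")
  if (!identical(names(df), expected)) {
    rlang::abort("triplet file must have columns parent_index, daughter_index, probability")
  }
  tibble::as_tibble(df)
}
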