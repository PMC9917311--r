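#' Karyotype state spaces
#'
#' A karyotype is an integer vector of chromosome copy numbers, one entry per
#' chromosome type. `karyo_space()` enumerates every karyotype inside a
#' per-chromosome viability box `[viable_lo[c], viable_hi[c]]` and fixes a
#' deterministic index bijection (lexicographic on the copy vector, first
#' chromosome most significant) so that sparse tensors and generator matrices
#' have a reproducible layout across runs.
#'
#' Cells whose copy number leaves the box are nonviable: losing every copy of
#' a chromosome (nullisomy) or exceeding the tolerated maximum (eight copies
#' is a common choice) kills the lineage. The box therefore defines both the
#' state space of the linear model and the absorbing "death" boundary that
#' missegregation flux can cross.
#'
#' @param M Number of chromosome types (1 for the aggregate/ploidy model,
#'   22 for whole autosomes).
#' @param viable_lo,viable_hi Integer vectors of length `M` (or length 1,
#'   recycled) giving the inclusive per-chromosome viability bounds,
#'   `0 <= viable_lo[c] <= viable_hi[c]`.
#' @param cap Maximum number of states that may be enumerated. Exceeding it is
#'   an error, not a truncation: full tensor spaces like `8^22` are
#'   intentionally unsupported -- use [multichromosome_critical()] for the
#'   factorized path.
#' @return An object of class `karyo_space` with fields `M`, `viable_lo`,
#'   `viable_hi`, `states` (an `n_states x M` integer matrix, one row per
#'   karyotype in lexicographic order) and `n_states`.
#' @examples
#' sp <- karyo_space(1, 1, 5)      # dosage-sensitive chromosome, 1..5 copies
#' sp$n_states                     # 5
#' karyo_space(2, c(1, 1), c(8, 8))$n_states  # 64
#' @export
karyo_space <- function(M, viable_lo, viable_hi, cap = 1e6) {
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != round(M)) {
    rlang::abort("`M` must be a single positive integer.")
  }
  M <- as.integer(M)
  viable_lo <- vctr_recycle(viable_lo, M, "viable_lo")
  viable_hi <- vctr_recycle(viable_hi, M, "viable_hi")
  if (any(viable_lo < 0)) {
    rlang::abort("`viable_lo` must be nonnegative.")
  }
  if (any(viable_hi < viable_lo)) {
    rlang::abort("`viable_hi` must satisfy viable_hi[c] >= viable_lo[c].")
  }
  sizes <- viable_hi - viable_lo + 1L
  n_states <- prod(sizes)
  if (n_states > cap) {
    rlang::abort(sprintf(
      "Requested space has %.4g states, above the cap of %.4g. Use the Kronecker-factorized analysis (multichromosome_critical) for large joint spaces.",
      n_states, cap
    ))
  }
  # lexicographic order, first chromosome most significant: last index varies fastest
  ranges <- lapply(seq_len(M), function(c) seq.int(viable_lo[c], viable_hi[c]))
  grid <- expand.grid(rev(ranges), KEEP.OUT.ATTRS = FALSE)
  states <- as.matrix(grid[, rev(seq_len(M)), drop = FALSE])
  dimnames(states) <- list(NULL, paste0("chr", seq_len(M)))
  storage.mode(states) <- "integer"
  structure(
    list(M = M, viable_lo = viable_lo, viable_hi = viable_hi,
         states = states, n_states = as.integer(n_states)),
    class = "karyo_space"
  )
}

vctr_recycle <- function(x, M, name) {
  if (length(x) == 1L) x <- rep(x, M)
  if (length(x) != M || any(x != round(x))) {
    rlang::abort(sprintf("`%s` must be an integer vector of length 1 or M.", name))
  }
  as.integer(x)
}

#' @export
print.karyo_space <- function(x, ...) {
  cat(sprintf("<karyo_space> M = %d, %d states\n", x$M, x$n_states))
  cat("  viable box: [", paste(x$viable_lo, collapse = ","), "] .. [",
      paste(x$viable_hi, collapse = ","), "]\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.karyo_space <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$states))
  dplyr::mutate(out, index = dplyr::row_number(), .before = 1)
}

#' Index bijection between karyotypes and dense state indices
#'
#' `index_of()` maps a karyotype (or matrix of karyotypes, one per row) to its
#' 1-based position in the lexicographic enumeration; `karyotype_of()` is the
#' inverse. Both are exact mixed-radix computations, so round trips hold for
#' every state.
#'
#' @param space A [karyo_space()].
#' @param k An integer vector of length `space$M`, or a matrix with `M` columns.
#' @param i Integer state index (vectorized), in `1..space$n_states`.
#' @return `index_of()`: integer indices (NA for karyotypes outside the box);
#'   `karyotype_of()`: an integer matrix with one karyotype per row.
#' @export
index_of <- function(space, k) {
  k <- as_karyotype_matrix(space, k)
  sizes <- space$viable_hi - space$viable_lo + 1L
  radix <- rev(cumprod(rev(c(sizes[-1L], 1L))))
  off <- sweep(k, 2L, space$viable_lo, "-")
  idx <- as.integer(off %*% radix) + 1L
  inside <- viability_mask(space, k)
  idx[!inside] <- NA_integer_
  idx
}

#' @rdname index_of
#' @export
karyotype_of <- function(space, i) {
  if (any(i < 1 | i > space$n_states)) {
    rlang::abort("state index out of range")
  }
  space$states[i, , drop = FALSE]
}

as_karyotype_matrix <- function(space, k) {
  if (is.null(dim(k))) k <- matrix(k, nrow = 1L)
  if (ncol(k) != space$M) {
    rlang::abort(sprintf("karyotype has %d entries; space expects M = %d",
                         ncol(k), space$M))
  }
  storage.mode(k) <- "integer"
  k
}

viability_mask <- function(space, k) {
  lo_ok <- sweep(k, 2L, space$viable_lo, ">=")
  hi_ok <- sweep(k, 2L, space$viable_hi, "<=")
  rowSums(lo_ok & hi_ok) == space$M
}

#' Is a karyotype inside the viable box?
#'
#' @inheritParams index_of
#' @return Logical, one entry per karyotype row.
#' @examples
#' sp <- karyo_space(2, 1, 8)
#' is_viable(sp, c(1, 8))  # TRUE: bounds are inclusive
#' is_viable(sp, c(0, 4))  # FALSE: nullisomy
#' @export
is_viable <- function(space, k) {
  k <- as_karyotype_matrix(space, k)
  unname(viability_mask(space, k))
}

#' Aggregate ploidy of a karyotype
#'
#' The 1-D aggregate model collapses a multi-chromosome karyotype to its total
#' copy number (the L1 norm of the copy vector). For a matrix input the sum is
#' taken per row.
#'
#' @param k Integer karyotype vector, or a matrix with one karyotype per row.
#' @return Integer ploidy (total chromosome copies), vectorized over rows.
#' @examples
#' aggregate_ploidy(c(2, 3, 1))      # 6
#' aggregate_ploidy(rep(2L, 22))     # 44, the diploid autosome total
#' @export
aggregate_ploidy <- function(k) {
  if (any(k < 0)) rlang::abort("copy numbers must be nonnegative")
  if (is.null(dim(k))) as.integer(sum(k)) else as.integer(rowSums(k))
}

#' Serialize / deserialize a space definition
#'
#' A space is fully described by the config block
#' `{M, viable_lo, viable_hi}`; these helpers convert to and from that plain
#' list form (the YAML/JSON dialect used by [run_pipeline()]).
#'
#' @param space A [karyo_space()].
#' @param config A list with entries `M`, `viable_lo`, `viable_hi`.
#' @return `space_to_config()`: a plain list; `space_from_config()`: a
#'   [karyo_space()].
#' @export
space_to_config <- function(space) {
  list(M = space$M, viable_lo = space$viable_lo, viable_hi = space$viable_hi)
}

#' @rdname space_to_config
#' @export
space_from_config <- function(config) {
  required <- c("M", "viable_lo", "viable_hi")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    rlang::abort(paste0("space config is missing field(s): ",
                        paste(missing, collapse = ", ")))
  }
  karyo_space(config$M, config$viable_lo, config$viable_hi)
}

#' Default diploid initial condition
#'
#' All mass on the all-2s karyotype, componentwise clamped into the viable box
#' (so a ploidy-aggregate space starts at the state closest to diploid).
#'
#' @param space A [karyo_space()].
#' @param copies Optional explicit karyotype to start from instead.
#' @return A nonnegative abundance vector over the states, summing to 1.
#' @export
diploid_start <- function(space, copies = NULL) {
  if (is.null(copies)) {
    copies <- pmin(pmax(rep(2L, space$M), space$viable_lo), space$viable_hi)
  }
  i <- index_of(space, copies)
  if (is.na(i)) rlang::abort("initial karyotype is outside the viable box")
  n0 <- numeric(space$n_states)
  n0[i] <- 1
  n0
}
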