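#' Define a permutation plan
#'
#' Fixes everything the null model needs to be reproducible: the number of
#' permuted matrices, the master seed, the chain schedule (burn-in and
#' thinning, in attempted checkerboard swaps per block) and the sampling
#' mode. Permutation `k` depends only on `(seed, k)`, so any single
#' permutation can be regenerated without sweeping the whole stream and
#' batched or serial evaluation give identical results.
#'
#' @param n_permutations number of permuted matrices (default 10000).
#' @param seed master integer seed.
#' @param burn_in attempted swaps per block before the first permutation;
#'   `NULL` (default) means 10 x the block's nonzero count.
#' @param thinning attempted swaps per block between consecutive
#'   permutations in `"sequential"` mode; `NULL` means the block's nonzero
#'   count.
#' @param mode `"sequential"` (one long chain, thinned; the default) or
#'   `"restart"` (each permutation is an independent chain of `burn_in`
#'   swaps from the observed matrix, giving independent draws).
#' @return an object of class `permutation_plan`.
#' @export
permutation_plan <- function(n_permutations = 10000, seed = 1,
                             burn_in = NULL, thinning = NULL,
                             mode = c("sequential", "restart")) {
  mode <- match.arg(mode)
  stopifnot(n_permutations >= 0, is.numeric(seed), length(seed) == 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed) %% 2147483647L,
                 burn_in = burn_in, thinning = thinning, mode = mode),
            class = "permutation_plan")
}

#' @export
print.permutation_plan <- function(x, ...) {
  cat("permutation_plan:", x$n_permutations, "permutations, seed", x$seed,
      ", mode", x$mode, "\n")
  cat("  burn-in:", if (is.null(x$burn_in)) "10 x block nnz" else x$burn_in,
      "| thinning:", if (is.null(x$thinning)) "block nnz" else x$thinning, "\n")
  invisible(x)
}

# Deterministic substream seed for segment/permutation k of a master seed.
# Arithmetic stays below 2^53 so the double computation is exact.
.substream_seed <- function(seed, k) {
  as.integer((seed %% 2147483647) * 48271 %% 2147483647 +
               (k * 69621) %% 2147483647) %% 2147483646L + 1L
}

# (cancer type x alteration class) block decomposition of the incidence.
.perm_blocks <- function(mat) {
  blocks <- list()
  for (ct in unique(mat$cancer_type)) {
    rows <- which(mat$cancer_type == ct)
    for (cl in unique(mat$alteration_class)) {
      cols <- which(mat$alteration_class == cl)
      nnz <- sum(mat$incidence[rows, cols])
      blocks[[length(blocks) + 1L]] <-
        list(rows = rows, cols = cols, nnz = nnz)
    }
  }
  blocks
}

.block_swaps <- function(blocks, setting, mult) {
  vapply(blocks, function(b) {
    if (is.null(setting)) mult * b$nnz else as.integer(setting)
  }, 0L)
}

#' Randomize one binary block by checkerboard swaps
#'
#' Applies `n_swaps` attempted 2x2 checkerboard swaps (two rows and two
#' columns are drawn; if the induced submatrix is `[[1,0],[0,1]]` or its
#' complement, it is flipped) using the current R random number stream.
#' Row and column sums are preserved exactly; the chain's stationary
#' distribution is uniform over all 0/1 matrices with those margins.
#'
#' @param block a 0/1 matrix.
#' @param n_swaps attempted swaps; default 10 x the number of ones.
#' @return a randomized 0/1 matrix with identical row and column sums.
#' @export
swap_randomize_block <- function(block, n_swaps = NULL) {
  block <- as.matrix(block)
  storage.mode(block) <- "integer"
  if (length(block) && !all(block %in% c(0L, 1L))) stop("block must be 0/1")
  if (is.null(n_swaps)) n_swaps <- 10L * sum(block)
  out <- block + 0L  # private copy; the C++ kernel works in place
  swap_chain_inplace(out, as.integer(n_swaps))
  out
}

#' Stratified fixed-margin randomization of an alteration matrix
#'
#' Independently swap-randomizes every (cancer type x alteration class)
#' block of the incidence, so per-sample-per-class alteration loads and
#' per-alteration-per-type recurrence counts are all preserved exactly —
#' the null model that controls for mutational heterogeneity within and
#' across tumors. Uses the current R random number stream; for
#' reproducible streams use [permutation_stream()].
#'
#' @param mat an `alteration_matrix`.
#' @param n_swaps attempted swaps per block (`NULL` = 10 x block nonzeros).
#' @return a permuted `alteration_matrix` with unchanged metadata.
#' @export
stratified_permute <- function(mat, n_swaps = NULL) {
  stopifnot(inherits(mat, "alteration_matrix"))
  blocks <- .perm_blocks(mat)
  inc <- mat$incidence + 0L
  for (b in blocks) {
    ns <- if (is.null(n_swaps)) 10L * b$nnz else as.integer(n_swaps)
    if (ns > 0 && length(b$rows) > 1 && length(b$cols) > 1) {
      sub <- inc[b$rows, b$cols, drop = FALSE]
      swap_chain_inplace(sub, ns)
      inc[b$rows, b$cols] <- sub
    }
  }
  out <- mat
  out$incidence <- inc
  out
}

#' Create a reproducible stream of permuted matrices
#'
#' Returns a stream object yielding `plan$n_permutations` stratified
#' fixed-margin randomizations of `mat`. In `"sequential"` mode the stream
#' is one thinned chain per block; in `"restart"` mode every permutation
#' is an independent chain from the observed matrix. In both modes
#' permutation `k` is a pure function of `(plan$seed, k)`.
#'
#' @param mat an `alteration_matrix`.
#' @param plan a [permutation_plan()].
#' @return an object of class `permuted_matrix_stream` with methods
#'   `$get(k)` (the k-th permuted incidence matrix, k in 1..N),
#'   `$reset()`, and fields `$plan`, `$blocks`.
#' @export
permutation_stream <- function(mat, plan) {
  stopifnot(inherits(mat, "alteration_matrix"),
            inherits(plan, "permutation_plan"))
  blocks <- .perm_blocks(mat)
  burn <- .block_swaps(blocks, plan$burn_in, 10L)
  thin <- .block_swaps(blocks, plan$thinning, 1L)
  original <- mat$incidence + 0L
  env <- new.env(parent = emptyenv())
  env$pos <- -1L  # index of last generated sequential state (-1 = cold)
  env$state <- NULL

  fresh_state <- function() {
    lapply(blocks, function(b) original[b$rows, b$cols, drop = FALSE] + 0L)
  }
  run_segment <- function(seg, swaps) {
    # one seeded segment: every block advanced by its swap budget
    set.seed(.substream_seed(plan$seed, seg))
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      if (swaps[i] > 0 && length(b$rows) > 1 && length(b$cols) > 1)
        swap_chain_inplace(env$state[[i]], swaps[i])
    }
  }
  assemble <- function() {
    out <- original + 0L
    for (i in seq_along(blocks))
      out[blocks[[i]]$rows, blocks[[i]]$cols] <- env$state[[i]]
    out
  }
  get <- function(k) {
    k <- as.integer(k)
    if (k < 1 || k > plan$n_permutations)
      stop("permutation index out of range: ", k)
    if (plan$mode == "restart") {
      env$state <- fresh_state()
      run_segment(k, burn)
      return(assemble())
    }
    if (env$pos < 0L || k <= env$pos) {
      env$state <- fresh_state()
      run_segment(0L, burn)
      env$pos <- 0L
    }
    while (env$pos < k) {
      run_segment(env$pos + 1L, thin)
      env$pos <- env$pos + 1L
    }
    assemble()
  }
  structure(list(
    get = get,
    reset = function() { env$pos <- -1L; env$state <- NULL; invisible(NULL) },
    plan = plan, blocks = blocks, matrix = mat
  ), class = "permuted_matrix_stream")
}

#' @export
print.permuted_matrix_stream <- function(x, ...) {
  cat("permuted_matrix_stream:", x$plan$n_permutations, "permutations over",
      length(x$blocks), "(cancer type x class) block(s), mode",
      x$plan$mode, "\n")
  invisible(x)
}
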