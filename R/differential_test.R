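#' 2x2 contingency table of a pair within one cancer type
#'
#' @param mat an `alteration_matrix`.
#' @param pair character vector of two alteration ids.
#' @param cancer_type a cancer-type label present in the matrix.
#' @return an object of class `stratum_table`: counts `co`, `a_only`,
#'   `b_only`, `neither` plus the `cancer_type` label; the counts sum to
#'   the type's sample count.
#' @export
contingency <- function(mat, pair, cancer_type) {
  stopifnot(inherits(mat, "alteration_matrix"), length(pair) == 2)
  rows <- which(mat$cancer_type == cancer_type)
  if (!length(rows) && !(cancer_type %in% mat$cancer_type))
    stop("unknown cancer type: ", cancer_type)
  ids <- colnames(mat$incidence)
  i <- match(pair[1], ids); j <- match(pair[2], ids)
  if (is.na(i) || is.na(j))
    stop("alteration not in matrix: ",
         paste(pair[is.na(c(i, j))], collapse = ", "))
  cells <- if (length(rows)) .pair_cells(mat$incidence, i, j, rows)
           else c(co = 0, a_only = 0, b_only = 0, neither = 0)
  structure(as.list(c(cells, list(cancer_type = cancer_type))),
            class = "stratum_table")
}

#' @export
print.stratum_table <- function(x, ...) {
  cat("2x2 table (", x$cancer_type, "): CO =", x$co, ", A only =", x$a_only,
      ", B only =", x$b_only, ", neither =", x$neither, "\n")
  invisible(x)
}

.table_counts <- function(table) {
  if (inherits(table, "stratum_table"))
    c(table$co, table$a_only, table$b_only, table$neither)
  else as.numeric(table[c("co", "a_only", "b_only", "neither")])
}

#' Continuity-corrected odds ratio of a 2x2 table
#'
#' `((co + 0.5)(neither + 0.5)) / ((a_only + 0.5)(b_only + 0.5))`: 0.5 is
#' added to every cell so the ratio is always finite and positive, and an
#' empty table yields exactly 1.
#'
#' @param table a `stratum_table`, or a numeric vector with named elements
#'   `co`, `a_only`, `b_only`, `neither`.
#' @return a positive number.
#' @export
corrected_odds_ratio <- function(table) {
  x <- .table_counts(table)
  if (anyNA(x) || any(x < 0)) stop("table cells must be non-negative counts")
  ((x[1] + 0.5) * (x[4] + 0.5)) / ((x[2] + 0.5) * (x[3] + 0.5))
}

# Breslow-Day heterogeneity statistic with Tarone's correction, vectorized
# over comparisons. Inputs are matrices with one row per comparison and one
# column per stratum: a = both-altered count, m1/m2 = the two alteration
# margins, n = stratum size. Cells may be non-integer (continuity-shifted).
.bd_tarone <- function(a, m1, m2, n) {
  b <- m1 - a; cc <- m2 - a; d <- n - m1 - m2 + a
  num <- rowSums(a * d / n)
  den <- rowSums(b * cc / n)
  or <- ifelse(den > 0, num / den, Inf)
  K <- ncol(a)
  ea <- va <- matrix(0, nrow(a), K)
  for (k in seq_len(K)) {
    ea[, k] <- .expected_cell(or, m1[, k], m2[, k], n[, k])
    va[, k] <- 1 / (1 / ea[, k] + 1 / (m1[, k] - ea[, k]) +
                    1 / (m2[, k] - ea[, k]) +
                    1 / (n[, k] - m1[, k] - m2[, k] + ea[, k]))
  }
  dev <- a - ea
  t_bd <- rowSums(dev^2 / va)
  t_stat <- t_bd - rowSums(dev)^2 / rowSums(va)
  # degenerate strata (zero margins) give NaN contributions; a table whose
  # margins admit a single configuration carries no heterogeneity signal
  t_stat[!is.finite(t_stat)] <- 0
  pmax(t_stat, 0)
}

# Expected both-altered cell under a common odds ratio with fixed margins:
# the root of (or-1)e^2 - [or(m1+m2) + n-m1-m2]e + or*m1*m2 = 0 inside
# [max(0, m1+m2-n), min(m1, m2)]. Vectorized; or may be Inf (degenerate).
.expected_cell <- function(or, m1, m2, n) {
  e <- ifelse(n > 0, m1 * m2 / pmax(n, 1), 0)  # or == 1 solution
  idx <- which(is.finite(or) & abs(or - 1) > 1e-12 & n > 0)
  if (length(idx)) {
    A <- or[idx] - 1
    B <- -(or[idx] * (m1[idx] + m2[idx]) + n[idx] - m1[idx] - m2[idx])
    C <- or[idx] * m1[idx] * m2[idx]
    disc <- sqrt(pmax(B^2 - 4 * A * C, 0))
    r1 <- (-B - disc) / (2 * A)
    r2 <- (-B + disc) / (2 * A)
    lo <- pmax(0, m1[idx] + m2[idx] - n[idx])
    hi <- pmin(m1[idx], m2[idx])
    tol <- 1e-9 * pmax(1, n[idx])
    use1 <- r1 >= lo - tol & r1 <= hi + tol
    e[idx] <- pmin(pmax(ifelse(use1, r1, r2), lo), hi)
  }
  ifelse(is.infinite(or), pmin(m1, m2), e)
}

#' Breslow-Day/Tarone test statistic for homogeneity of odds ratios
#'
#' Chi-square statistic testing whether stratum-specific odds ratios are
#' consistent with the Mantel-Haenszel common odds ratio: for each stratum
#' the expected both-altered count under the common OR (positive root of
#' the quadratic with margins fixed) and its asymptotic variance (inverse
#' sum of reciprocal expected cells) give a squared standardized deviation;
#' Tarone's correction subtracts `(sum of deviations)^2 / (sum of
#' variances)` so the statistic is asymptotically chi-square with K - 1
#' degrees of freedom.
#'
#' @param tables a list of `stratum_table`s (or of named count vectors), or
#'   a matrix/data.frame with columns `co`, `a_only`, `b_only`, `neither`
#'   and one row per stratum.
#' @param correct continuity handling: `"auto"` (default) adds 0.5 to every
#'   cell of every stratum only when some cell is zero; `"always"` /
#'   `"never"` force the choice.
#' @return a list with `statistic` (`T`, >= 0) and `df` (= K - 1; 0 for a
#'   single stratum, where `T` is 0 by construction).
#' @export
tarone_statistic <- function(tables, correct = c("auto", "always", "never")) {
  correct <- match.arg(correct)
  if (is.list(tables) && !is.data.frame(tables))
    m <- do.call(rbind, lapply(tables, .table_counts))
  else {
    m <- as.matrix(as.data.frame(tables)[, c("co", "a_only", "b_only", "neither")])
  }
  K <- nrow(m)
  if (K < 1) stop("need at least one stratum")
  if (K == 1) return(list(statistic = 0, df = 0L))
  if (correct == "always" || (correct == "auto" && any(m == 0)))
    m <- m + 0.5
  a <- rbind(m[, 1]); b <- rbind(m[, 2]); cc <- rbind(m[, 3]); d <- rbind(m[, 4])
  t_stat <- .bd_tarone(a, a + b, a + cc, a + b + cc + d)
  list(statistic = as.numeric(t_stat), df = K - 1L)
}

# Shared helper for the permutation loop: given per-comparison fixed
# margins for the two strata and vectors of permuted both-altered counts,
# return the Tarone statistic for every comparison. `correct` as above,
# applied per comparison per permutation.
.tarone_pair_stat <- function(co1, co2, m) {
  # m: data.frame with mA1, mB1, n1, mA2, mB2, n2, correct flag handling
  a <- cbind(co1, co2)
  mm1 <- cbind(m$mA1, m$mA2); mm2 <- cbind(m$mB1, m$mB2)
  nn <- cbind(m$n1, m$n2)
  if (m$correct[1] == "never") return(.bd_tarone(a, mm1, mm2, nn))
  b <- mm1 - a; cc <- mm2 - a; d <- nn - mm1 - mm2 + a
  zero <- rowSums(a == 0 | b == 0 | cc == 0 | d == 0) > 0
  shift <- if (m$correct[1] == "always") rep(TRUE, length(zero)) else zero
  add <- ifelse(shift, 0.5, 0)
  .bd_tarone(a + add, mm1 + 2 * add, mm2 + 2 * add, nn + 4 * add)
}

#' Differential-interaction test for one pair between two cancer types
#'
#' Tests whether the strength of a pair's interaction (its odds ratio of
#' co-occurrence) differs between `detected_type` and `compared_type`.
#' The observed Tarone heterogeneity statistic over the two 2x2 strata is
#' compared with its distribution across stratified fixed-margin
#' permutations of both types' blocks (the whole two-type matrix is
#' permuted, as in detection), which controls for the mutational
#' heterogeneity between cancer types. The empirical P-value is the
#' fraction of permutations with `T_random > T_obs` (strict), floored at
#' 1/N. The effect size is the change in log odds ratio.
#'
#' @param mat an `alteration_matrix` containing both types' samples.
#' @param pair character vector of two alteration ids.
#' @param detected_type,compared_type cancer-type labels.
#' @param plan a [permutation_plan()].
#' @param correct continuity handling for the Tarone statistic (see
#'   [tarone_statistic()]).
#' @return a one-row data.frame: per-type continuity-corrected odds ratios,
#'   `delta_log_or`, `t_obs`, `p_empirical`; `q` and `call` are filled in
#'   by [differential_screen()].
#' @export
differential_interaction_test <- function(mat, pair, detected_type,
                                          compared_type, plan,
                                          correct = "auto") {
  sub <- subset_matrix(mat, samples = mat$cancer_type %in%
                         c(detected_type, compared_type))
  res <- .differential_core(sub,
                            data.frame(a = pair[1], b = pair[2],
                                       detected_type = detected_type,
                                       compared_type = compared_type,
                                       stringsAsFactors = FALSE),
                            plan, correct)
  res$q <- NA_real_; res$call <- NA_character_
  res
}

# Core screen: one shared permutation stream over `mat` (whole-matrix
# stratified permutation); T recomputed for every comparison per
# permutation. Margins are permutation-invariant, so per-permutation
# tables need only the both-altered counts.
.differential_core <- function(mat, comparisons, plan, correct = "auto") {
  ids <- colnames(mat$incidence)
  i <- match(comparisons$a, ids); j <- match(comparisons$b, ids)
  types <- unique(c(comparisons$detected_type, comparisons$compared_type))
  rows_of <- lapply(stats::setNames(types, types),
                    function(t) which(mat$cancer_type == t))
  margins <- function(t, idx) colSums(mat$incidence[rows_of[[t]], idx, drop = FALSE])
  nC <- nrow(comparisons)
  mA1 <- mB1 <- n1 <- mA2 <- mB2 <- n2 <- co1 <- co2 <- numeric(nC)
  for (r in seq_len(nC)) {
    t1 <- comparisons$detected_type[r]; t2 <- comparisons$compared_type[r]
    mA1[r] <- margins(t1, i[r]); mB1[r] <- margins(t1, j[r])
    mA2[r] <- margins(t2, i[r]); mB2[r] <- margins(t2, j[r])
    n1[r] <- length(rows_of[[t1]]); n2[r] <- length(rows_of[[t2]])
    co1[r] <- sum(mat$incidence[rows_of[[t1]], i[r]] *
                  mat$incidence[rows_of[[t1]], j[r]])
    co2[r] <- sum(mat$incidence[rows_of[[t2]], i[r]] *
                  mat$incidence[rows_of[[t2]], j[r]])
  }
  minfo <- data.frame(mA1 = mA1, mB1 = mB1, n1 = n1,
                      mA2 = mA2, mB2 = mB2, n2 = n2,
                      correct = correct, stringsAsFactors = FALSE)
  t_obs <- .tarone_pair_stat(co1, co2, minfo)
  N <- plan$n_permutations
  exceed <- numeric(nC)
  stream <- permutation_stream(mat, plan)
  for (k in seq_len(N)) {
    X <- stream$get(k) * 1
    pc1 <- pc2 <- numeric(nC)
    for (t in types) {
      sel <- which(comparisons$detected_type == t)
      sel2 <- which(comparisons$compared_type == t)
      if (length(sel) || length(sel2)) {
        Xa <- X[rows_of[[t]], , drop = FALSE]
        cp <- crossprod(Xa)
        if (length(sel)) pc1[sel] <- cp[cbind(i[sel], j[sel])]
        if (length(sel2)) pc2[sel2] <- cp[cbind(i[sel2], j[sel2])]
      }
    }
    t_rand <- .tarone_pair_stat(pc1, pc2, minfo)
    exceed <- exceed + (t_rand > t_obs)
  }
  p <- pmax(exceed, 1) / N
  or1 <- ((co1 + 0.5) * (n1 - mA1 - mB1 + co1 + 0.5)) /
         ((mA1 - co1 + 0.5) * (mB1 - co1 + 0.5))
  or2 <- ((co2 + 0.5) * (n2 - mA2 - mB2 + co2 + 0.5)) /
         ((mA2 - co2 + 0.5) * (mB2 - co2 + 0.5))
  data.frame(a = comparisons$a, b = comparisons$b,
             detected_type = comparisons$detected_type,
             compared_type = comparisons$compared_type,
             or_detected = or1, or_compared = or2,
             delta_log_or = log(or1) - log(or2),
             t_obs = t_obs, p_empirical = p, stringsAsFactors = FALSE)
}

#' Differential-interaction screen across cancer types
#'
#' Re-tests every interaction detected in one cancer type against every
#' other cancer type in which both alterations are individually recurrent
#' (altered in at least `min_frequency` of that type's samples). One
#' permutation stream over the full matrix is shared by all comparisons;
#' BH adjustment is applied across the whole screen. A comparison is
#' called `higher_OR` / `lower_OR` when `q <= fdr`, by the sign of the
#' change in log odds ratio, and `not_differential` otherwise.
#'
#' @param detections named list (by cancer type) of `interaction_network`s
#'   from per-type [detect_interactions()] runs.
#' @param mat the `alteration_matrix` the detections came from (all types).
#' @param plan a [permutation_plan()].
#' @param fdr FDR threshold (default 0.1).
#' @param min_frequency recurrence eligibility in the compared type
#'   (default 0.02).
#' @param correct continuity handling (see [tarone_statistic()]).
#' @return a data.frame of class `differential_results`, one row per
#'   (pair, detected type, compared type) comparison, with attributes
#'   `n_comparisons` and `n_pairs` (non-redundant pairs re-tested).
#' @export
differential_screen <- function(detections, mat, plan, fdr = 0.1,
                                min_frequency = 0.02, correct = "auto") {
  stopifnot(inherits(mat, "alteration_matrix"), is.list(detections))
  types <- unique(mat$cancer_type)
  counts <- lapply(stats::setNames(types, types), function(t) {
    rows <- which(mat$cancer_type == t)
    list(n = length(rows),
         k = colSums(mat$incidence[rows, , drop = FALSE]))
  })
  comp <- list()
  for (t in names(detections)) {
    e <- detections[[t]]$edges
    if (is.null(e) || !nrow(e)) next
    for (r in seq_len(nrow(e))) {
      for (u in setdiff(types, t)) {
        cu <- counts[[u]]
        thr <- ceiling(min_frequency * cu$n)
        if (cu$k[e$a[r]] >= thr && cu$k[e$b[r]] >= thr)
          comp[[length(comp) + 1L]] <-
            data.frame(a = e$a[r], b = e$b[r], detected_type = t,
                       compared_type = u, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(comp)) {
    out <- data.frame(a = character(), b = character(),
                      detected_type = character(), compared_type = character(),
                      or_detected = double(), or_compared = double(),
                      delta_log_or = double(), t_obs = double(),
                      p_empirical = double(), q = double(),
                      call = character(), stringsAsFactors = FALSE)
    attr(out, "n_comparisons") <- 0L; attr(out, "n_pairs") <- 0L
    class(out) <- c("differential_results", "data.frame")
    return(out)
  }
  comparisons <- do.call(rbind, comp)
  res <- .differential_core(mat, comparisons, plan, correct)
  res$q <- p.adjust(res$p_empirical, method = "BH")
  res$call <- ifelse(res$q <= fdr,
                     ifelse(res$delta_log_or > 0, "higher_OR", "lower_OR"),
                     "not_differential")
  attr(res, "n_comparisons") <- nrow(res)
  attr(res, "n_pairs") <- nrow(unique(res[c("a", "b")]))
  class(res) <- c("differential_results", "data.frame")
  res
}

#' @export
print.differential_results <- function(x, ...) {
  cat("differential screen:", attr(x, "n_comparisons"), "comparisons over",
      attr(x, "n_pairs"), "pair(s);",
      sum(x$call != "not_differential"), "differential\n")
  NextMethod()
}
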