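# Independent oracles and shared fixtures, kept deliberately separate from
# the package's own code paths.

# Exhaustive enumeration of all 0/1 matrices with the given row and column
# sums (brute-force recursion over rows with feasibility pruning). The
# ground truth for the uniformity and empirical-P oracle tests.
enumerate_fixed_margin <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  out <- list()
  rec <- function(i, cs_left, acc) {
    if (i > nr) {
      if (all(cs_left == 0))
        out[[length(out) + 1L]] <<- do.call(rbind, acc)
      return(invisible(NULL))
    }
    if (row_sums[i] == 0) {
      if (all(cs_left <= nr - i))
        rec(i + 1L, cs_left, c(acc, list(rep(0L, nc))))
      return(invisible(NULL))
    }
    cols <- which(cs_left > 0)
    if (length(cols) < row_sums[i]) return(invisible(NULL))
    sets <- combn(cols, row_sums[i])
    for (k in seq_len(ncol(sets))) {
      v <- rep(0L, nc); v[sets[, k]] <- 1L
      left <- cs_left - v
      if (all(left <= nr - i)) rec(i + 1L, left, c(acc, list(v)))
    }
    invisible(NULL)
  }
  rec(1L, col_sums, list())
  out
}

state_key <- function(m) paste(m, collapse = "")

# Independent Breslow-Day/Tarone reference: Mantel-Haenszel common OR, the
# expected both-altered cell found numerically (uniroot, not the closed-form
# quadratic the package uses), Tarone-corrected chi-square.
ref_tarone <- function(tabs) {
  a <- tabs[, 1]; b <- tabs[, 2]; cc <- tabs[, 3]; d <- tabs[, 4]
  n <- a + b + cc + d
  or <- sum(a * d / n) / sum(b * cc / n)
  K <- nrow(tabs)
  ea <- va <- numeric(K)
  for (k in seq_len(K)) {
    m1 <- a[k] + b[k]; m2 <- a[k] + cc[k]; N <- n[k]
    f <- function(e) or * (m1 - e) * (m2 - e) - e * (N - m1 - m2 + e)
    lo <- max(0, m1 + m2 - N); hi <- min(m1, m2)
    ea[k] <- uniroot(f, c(lo + 1e-10, hi - 1e-10), tol = 1e-13)$root
    va[k] <- 1 / (1 / ea[k] + 1 / (m1 - ea[k]) + 1 / (m2 - ea[k]) +
                  1 / (N - m1 - m2 + ea[k]))
  }
  sum((a - ea)^2 / va) - sum(a - ea)^2 / sum(va)
}

# Unordered pair key matching eligible_pairs' lexicographic convention.
pkey <- function(a, b) paste(pmin(a, b), pmax(a, b))

# A tiny hand-checkable cohort: 5 samples x 3 alterations, one cancer type,
# one class, so the permutation null is a single block.
toy_matrix <- function() {
  inc <- rbind(c(1, 1, 1),
               c(1, 1, 0),
               c(1, 0, 0),
               c(0, 1, 0),
               c(0, 0, 1))
  dimnames(inc) <- list(paste0("s", 1:5), c("A", "B", "C"))
  alteration_matrix(inc, rep("T1", 5), rep("mutation", 3))
}

# Study-condition cohorts used by both the property and acceptance tests.
# Null calibration: two cohorts of 200, a 20-alteration panel of highly
# recurrent drivers (frequencies 0.3-0.5 keep the co-occurrence statistic
# dense enough for the envelope check to be informative), nothing planted.
null_calib_spec <- function(seed) {
  synthetic_spec(
    data.frame(label = c("T1", "T2"), n_samples = c(200, 200)),
    data.frame(id = paste0("A", 1:20),
               class = rep(c("mutation", "CNA_gain", "methylation"), c(10, 5, 5)),
               chromosome = c(rep(NA, 10), paste0("chr", 1:5), rep(NA, 5)),
               frequency = seq(0.3, 0.5, length.out = 20)),
    seed = seed)
}

# Recovery power: 6 cancer types x 300 samples, frequency 0.1, three pairs
# planted co-occurring (theta 8) and three mutually exclusive (theta 0.1)
# in every type.
power_spec <- function(seed) {
  cls <- rep(c("mutation", "CNA_gain", "CNA_loss", "methylation"), 5)
  synthetic_spec(
    data.frame(label = paste0("T", 1:6), n_samples = 300),
    data.frame(id = paste0("A", 1:20), class = cls,
               chromosome = ifelse(cls %in% c("CNA_gain", "CNA_loss"),
                                   paste0("chr", 1:20), NA),
               frequency = 0.1),
    planted = do.call(rbind, lapply(paste0("T", 1:6), function(t) data.frame(
      a = c("A1", "A3", "A5", "A2", "A4", "A6"),
      b = c("A9", "A11", "A13", "A10", "A12", "A14"),
      cancer_type = t, theta = rep(c(8, 0.1), each = 3)))),
    seed = seed)
}
power_co_pairs <- data.frame(a = c("A1", "A3", "A5"), b = c("A9", "A11", "A13"))
power_me_pairs <- data.frame(a = c("A2", "A4", "A6"), b = c("A10", "A12", "A14"))

# Differential recovery: two cohorts of 400; five pairs differential
# (theta 8 in T1, 1 in T2) and five conserved (theta 8 in both) at
# frequency 0.2, plus ten unplanted background alterations.
diff_spec <- function(seed) {
  synthetic_spec(
    data.frame(label = c("T1", "T2"), n_samples = 400),
    data.frame(id = paste0("A", 1:30), class = "mutation", chromosome = NA,
               frequency = rep(c(0.2, 0.1), c(20, 10))),
    planted = rbind(
      data.frame(a = paste0("A", 1:5), b = paste0("A", 11:15),
                 cancer_type = "T1", theta = 8),
      data.frame(a = paste0("A", 1:5), b = paste0("A", 11:15),
                 cancer_type = "T2", theta = 1),
      data.frame(a = paste0("A", 6:10), b = paste0("A", 16:20),
                 cancer_type = "T1", theta = 8),
      data.frame(a = paste0("A", 6:10), b = paste0("A", 16:20),
                 cancer_type = "T2", theta = 8)),
    seed = seed)
}
diff_differential_pairs <- data.frame(a = paste0("A", 1:5), b = paste0("A", 11:15))
diff_conserved_pairs <- data.frame(a = paste0("A", 6:10), b = paste0("A", 16:20))
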