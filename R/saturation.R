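#' Saturation (down-sampling) curves of interaction discovery
#'
#' How the number of detected interactions grows with cohort size.
#' `saturation_within_type()` subsamples one cancer type on a regular grid
#' (adding `step` samples at a time, final full size always included);
#' `saturation_pan_samples()` subsamples the pooled pan-cancer cohort
#' proportionally across types; `saturation_by_type()` adds whole cancer
#' types one at a time along random orderings. Recurrence filtering is
#' recomputed inside every subset ("samples under consideration"), and the
#' full-size point reuses the analysis seed so it reproduces the
#' non-subsampled run exactly. Within a replicate, subsets are nested
#' (each size extends the previous draw), which reduces the variance of
#' the curve.
#'
#' @param mat an `alteration_matrix`.
#' @param cancer_type the type to subsample (within-type mode).
#' @param plan a [permutation_plan()]; its seed also drives the subset
#'   draws (replicate r uses a substream of the seed).
#' @param step grid spacing in samples (10 within type, 100 pan).
#' @param reps random subsets per size (default 10).
#' @param cap largest pan-cancer subset size (default 3000; the full size
#'   is always added as the final point).
#' @param n_orderings number of random type orderings (default: number of
#'   cancer types).
#' @param fdr,min_frequency detection parameters (defaults 0.1, 0.02).
#' @return an object of class `saturation_curve`: a data.frame with
#'   columns `size` (samples, or types in by-type mode), `replicate`,
#'   `n_detected`, plus a `mode` attribute.
#' @name saturation
NULL

.detect_count <- function(mat, plan, scope, fdr, min_frequency) {
  net <- detect_interactions(mat, plan, scope = scope, fdr = fdr,
                             min_frequency = min_frequency)
  nrow(net$edges)
}

.curve <- function(df, mode) {
  structure(df, mode = mode, class = c("saturation_curve", "data.frame"))
}

#' @rdname saturation
#' @export
saturation_within_type <- function(mat, cancer_type, plan, step = 10,
                                   reps = 10, fdr = 0.1,
                                   min_frequency = 0.02) {
  stopifnot(inherits(mat, "alteration_matrix"))
  rows <- which(mat$cancer_type == cancer_type)
  n <- length(rows)
  if (n < step) stop("cancer type has fewer samples than one step")
  sizes <- unique(c(seq(step, n, by = step), n))
  out <- list()
  for (r in seq_len(reps)) {
    set.seed(.substream_seed(plan$seed, 1000000 + r))
    ord <- sample(rows)  # nested draws: prefixes of one shuffled order
    for (s in sizes) {
      sub <- subset_matrix(mat, samples = sort(ord[seq_len(s)]))
      out[[length(out) + 1L]] <- data.frame(
        size = s, replicate = r,
        n_detected = .detect_count(sub, plan, cancer_type, fdr, min_frequency))
    }
  }
  .curve(do.call(rbind, out), "within_type")
}

#' @rdname saturation
#' @export
saturation_pan_samples <- function(mat, plan, step = 100, reps = 10,
                                   cap = 3000, fdr = 0.1,
                                   min_frequency = 0.02) {
  stopifnot(inherits(mat, "alteration_matrix"))
  n <- nrow(mat$incidence)
  top <- min(n, cap)
  sizes <- unique(c(seq(min(step, top), top, by = step), n))
  out <- list()
  for (r in seq_len(reps)) {
    set.seed(.substream_seed(plan$seed, 2000000 + r))
    # proportional across types: random rank within type, interleave by
    # within-type quantile so every prefix is ~proportionally mixed
    frac <- stats::ave(runif(n), mat$cancer_type,
                       FUN = function(z) rank(z) / (length(z) + 1))
    ord <- order(frac)
    for (s in sizes) {
      sub <- subset_matrix(mat, samples = sort(ord[seq_len(s)]))
      out[[length(out) + 1L]] <- data.frame(
        size = s, replicate = r,
        n_detected = .detect_count(sub, plan, "PAN", fdr, min_frequency))
    }
  }
  .curve(do.call(rbind, out), "pan_samples")
}

#' @rdname saturation
#' @export
saturation_by_type <- function(mat, plan, n_orderings = NULL, fdr = 0.1,
                               min_frequency = 0.02) {
  stopifnot(inherits(mat, "alteration_matrix"))
  types <- unique(mat$cancer_type)
  if (length(types) < 2) stop("need at least two cancer types")
  if (is.null(n_orderings)) n_orderings <- length(types)
  out <- list()
  for (r in seq_len(n_orderings)) {
    set.seed(.substream_seed(plan$seed, 3000000 + r))
    ord <- sample(types)
    for (k in seq_along(ord)) {
      sub <- subset_matrix(mat, samples = mat$cancer_type %in% ord[seq_len(k)])
      out[[length(out) + 1L]] <- data.frame(
        size = k, replicate = r,
        n_detected = .detect_count(sub, plan, "PAN", fdr, min_frequency))
    }
  }
  .curve(do.call(rbind, out), "pan_types")
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat("saturation_curve (", attr(x, "mode"), "):", length(unique(x$size)),
      "sizes x", length(unique(x$replicate)), "replicate(s)\n")
  agg <- stats::aggregate(n_detected ~ size, data = as.data.frame(x), FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' @export
plot.saturation_curve <- function(x, ...) {
  df <- as.data.frame(x)
  agg <- stats::aggregate(n_detected ~ size, data = df, FUN = mean)
  plot(df$size, df$n_detected, pch = 16, col = "grey60",
       xlab = if (attr(x, "mode") == "pan_types") "cancer types" else "samples",
       ylab = "detected interactions", ...)
  graphics::lines(agg$size, agg$n_detected, col = "red", lwd = 2)
  invisible(x)
}
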