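#' Bivariate Bernoulli cell probabilities with fixed marginals and odds ratio
#'
#' Solves for the joint distribution of two binary events with marginals
#' `pA`, `pB` and odds ratio `theta`: `p11` is the root of
#' `(theta-1) p11^2 - [1 + (pA+pB)(theta-1)] p11 + theta pA pB = 0`
#' inside `[max(0, pA+pB-1), min(pA, pB)]` (taken directly as `pA*pB` when
#' `theta = 1`). This is the analytic construction behind every planted
#' interaction: the implied odds ratio is exact, not a sampling target.
#'
#' @param pA,pB marginal alteration probabilities, in (0, 1).
#' @param theta target odds ratio, > 0.
#' @return named numeric vector `c(p11, p10, p01, p00)` summing to 1.
#' @export
joint_bernoulli_with_or <- function(pA, pB, theta) {
  stopifnot(pA > 0, pA < 1, pB > 0, pB < 1, theta > 0)
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  if (abs(theta - 1) < 1e-12) {
    p11 <- pA * pB
  } else {
    A <- theta - 1
    B <- -(1 + (pA + pB) * (theta - 1))
    C <- theta * pA * pB
    disc <- B^2 - 4 * A * C
    if (disc < 0) stop("no real root for the requested (pA, pB, theta)")
    roots <- c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A))
    ok <- roots >= lo - 1e-12 & roots <= hi + 1e-12
    if (!any(ok)) stop("no valid cell probability for (", pA, ", ", pB, ", ",
                       theta, ")")
    p11 <- min(max(roots[ok][1], lo), hi)
  }
  c(p11 = p11, p10 = pA - p11, p01 = pB - p11, p00 = 1 - pA - pB + p11)
}

#' Specify a synthetic cohort
#'
#' Full generative description of a multi-cancer-type cohort: per-type
#' sample counts, an alteration panel (class, chromosome, member genes,
#' baseline frequency), planted pairwise interactions with per-type target
#' odds ratios, per-sample load heterogeneity, and a fraction of
#' hyper-altered outlier samples. Planted pairs are drawn jointly from
#' [joint_bernoulli_with_or()], so their ground-truth odds ratios are
#' analytically exact; load heterogeneity (logit-space sample effects) is
#' applied to non-planted alterations only, keeping that ground truth
#' interpretable while still giving the permutation null its reason to
#' exist.
#'
#' @param cancer_types data.frame with columns `label`, `n_samples`.
#' @param alterations data.frame with columns `id`, `class`, `chromosome`
#'   (`NA` for non-CNA), `genes` (semicolon-separated or a list column) and
#'   `frequency` (baseline altered fraction, in (0, 1)).
#' @param planted data.frame with columns `a`, `b`, `cancer_type`, `theta`
#'   (target odds ratio in that type; types not listed for a pair default
#'   to `theta = 1`). An alteration may belong to at most one planted pair.
#' @param sample_load_dispersion standard deviation of the per-sample
#'   logit-scale load effect (default 0.4; 0 disables heterogeneity).
#' @param hyper_fraction expected fraction of hyper-altered samples
#'   (default 0.02).
#' @param hyper_shift extra logit shift given to hyper-altered samples
#'   (default 6, inflating their event load far past the Q3 + 4.5 IQR
#'   exclusion threshold).
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(cancer_types, alterations, planted = NULL,
                           sample_load_dispersion = 0.4,
                           hyper_fraction = 0.02, hyper_shift = 6,
                           seed = 1) {
  stopifnot(all(c("label", "n_samples") %in% names(cancer_types)),
            all(c("id", "class", "frequency") %in% names(alterations)))
  if (anyDuplicated(alterations$id)) stop("duplicate alteration ids")
  .check_classes(alterations$class, nrow(alterations))
  if (any(alterations$frequency <= 0 | alterations$frequency >= 1))
    stop("baseline frequencies must lie in (0, 1)")
  if (!"chromosome" %in% names(alterations))
    alterations$chromosome <- NA_character_
  if (!"genes" %in% names(alterations))
    alterations$genes <- alterations$id
  if (is.null(planted))
    planted <- data.frame(a = character(), b = character(),
                          cancer_type = character(), theta = double(),
                          stringsAsFactors = FALSE)
  stopifnot(all(c("a", "b", "cancer_type", "theta") %in% names(planted)))
  if (nrow(planted)) {
    if (!all(c(planted$a, planted$b) %in% alterations$id))
      stop("planted pair references undeclared alteration")
    if (any(planted$theta <= 0)) stop("planted theta must be > 0")
    if (!all(planted$cancer_type %in% cancer_types$label))
      stop("planted pair references undeclared cancer type")
    members <- unique(planted[c("a", "b")])
    if (anyDuplicated(c(members$a, members$b)))
      stop("an alteration may belong to at most one planted pair")
    cls <- stats::setNames(alterations$class, alterations$id)
    chr <- stats::setNames(alterations$chromosome, alterations$id)
    both_cna <- cls[members$a] %in% c("CNA_gain", "CNA_loss") &
                cls[members$b] %in% c("CNA_gain", "CNA_loss")
    same_chr <- !is.na(chr[members$a]) & chr[members$a] == chr[members$b]
    if (any(both_cna & same_chr))
      warning("planted CNA-CNA pair on one chromosome is untestable downstream")
  }
  structure(list(cancer_types = cancer_types, alterations = alterations,
                 planted = planted,
                 sample_load_dispersion = sample_load_dispersion,
                 hyper_fraction = hyper_fraction, hyper_shift = hyper_shift,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec:", nrow(x$cancer_types), "cancer types,",
      sum(x$cancer_types$n_samples), "samples,",
      nrow(x$alterations), "alterations,",
      nrow(unique(x$planted[c("a", "b")])), "planted pair(s), seed",
      x$seed, "\n")
  invisible(x)
}

.spec_genes <- function(spec) {
  g <- spec$alterations$genes
  if (is.list(g)) lapply(g, as.character)
  else strsplit(as.character(g), ";", fixed = TRUE)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws the cohort described by a [synthetic_spec()]: per cancer type,
#' planted pairs are sampled jointly from their exact cell probabilities;
#' all other alterations are independent Bernoulli draws at a per-sample
#' logit-shifted frequency (the load-heterogeneity model), with
#' hyper-altered samples receiving an additional inflating shift.
#'
#' @param spec a `synthetic_spec`.
#' @return a list with `matrix` (an [alteration_matrix()]) and `manifest`,
#'   a `ground_truth_manifest`: exact per-type cell probabilities and
#'   implied odds ratio of every planted pair, the planted differential
#'   pairs (types with differing theta), realized per-type alteration
#'   frequencies, and the hyper-altered sample ids.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  al <- spec$alterations
  freq <- stats::setNames(al$frequency, al$id)
  pair_tab <- unique(spec$planted[c("a", "b")])
  planted_ids <- c(pair_tab$a, pair_tab$b)
  free_ids <- setdiff(al$id, planted_ids)
  theta_of <- function(a, b, type) {
    hit <- spec$planted$a == a & spec$planted$b == b &
           spec$planted$cancer_type == type
    if (any(hit)) spec$planted$theta[hit][1] else 1
  }
  inc_list <- list(); ct_list <- list(); hyper_all <- character()
  cells_rows <- list()
  for (t in seq_len(nrow(spec$cancer_types))) {
    type <- spec$cancer_types$label[t]
    n <- spec$cancer_types$n_samples[t]
    sid <- sprintf("%s_%04d", type, seq_len(n))
    inc <- matrix(0L, n, nrow(al), dimnames = list(sid, al$id))
    hyper <- runif(n) < spec$hyper_fraction
    u <- rnorm(n, 0, spec$sample_load_dispersion) +
         ifelse(hyper, spec$hyper_shift, 0)
    for (id in free_ids)
      inc[, id] <- as.integer(runif(n) < plogis(qlogis(freq[id]) + u))
    if (nrow(pair_tab)) for (r in seq_len(nrow(pair_tab))) {
      a <- pair_tab$a[r]; b <- pair_tab$b[r]
      th <- theta_of(a, b, type)
      cells <- joint_bernoulli_with_or(freq[a], freq[b], th)
      draw <- sample.int(4, n, replace = TRUE, prob = cells)
      inc[, a] <- as.integer(draw %in% c(1L, 2L))
      inc[, b] <- as.integer(draw %in% c(1L, 3L))
      cells_rows[[length(cells_rows) + 1L]] <- data.frame(
        a = a, b = b, cancer_type = type, theta = th,
        p11 = cells[1], p10 = cells[2], p01 = cells[3], p00 = cells[4],
        or_implied = (cells[1] * cells[4]) / (cells[2] * cells[3]),
        stringsAsFactors = FALSE)
    }
    inc_list[[type]] <- inc
    ct_list[[type]] <- rep(type, n)
    hyper_all <- c(hyper_all, sid[hyper])
  }
  inc <- do.call(rbind, inc_list)
  mat <- alteration_matrix(inc, unlist(ct_list, use.names = FALSE),
                           al$class, al$chromosome, .spec_genes(spec))
  cells_df <- if (length(cells_rows)) do.call(rbind, cells_rows) else
    data.frame(a = character(), b = character(), cancer_type = character(),
               theta = double(), p11 = double(), p10 = double(),
               p01 = double(), p00 = double(), or_implied = double(),
               stringsAsFactors = FALSE)
  diff_pairs <- if (nrow(cells_df)) {
    spread <- stats::aggregate(theta ~ a + b, data = cells_df,
                               FUN = function(z) diff(range(z)))
    spread[spread$theta > 1e-12, c("a", "b"), drop = FALSE]
  } else cells_df[0, c("a", "b")]
  realized <- do.call(rbind, lapply(names(inc_list), function(type) {
    data.frame(cancer_type = type, alteration_id = al$id,
               frequency = colMeans(inc_list[[type]]),
               stringsAsFactors = FALSE)
  }))
  manifest <- structure(list(planted_cells = cells_df,
                             differential_pairs = diff_pairs,
                             realized_frequencies = realized,
                             hyper_samples = hyper_all,
                             seed = spec$seed),
                        class = "ground_truth_manifest")
  list(matrix = mat, manifest = manifest)
}

#' @export
print.ground_truth_manifest <- function(x, ...) {
  cat("ground_truth_manifest:",
      nrow(unique(x$planted_cells[c("a", "b")])), "planted pair(s),",
      nrow(x$differential_pairs), "differential,",
      length(x$hyper_samples), "hyper-altered sample(s), seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic PPI network over the cohort's genes
#'
#' Erdos-Renyi background at the requested edge density over all genes the
#' alteration panel declares; optionally one guaranteed cross edge per
#' planted pair (first member gene of each side), so planted interactions
#' are PPI-supported by construction.
#'
#' @param spec a `synthetic_spec`.
#' @param background_density edge probability, in \code{[0, 1]}.
#' @param guarantee_planted add one cross edge per planted pair.
#' @param seed integer seed.
#' @return a [ppi_network()].
#' @export
generate_ppi <- function(spec, background_density = 0.01,
                         guarantee_planted = TRUE, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"),
            background_density >= 0, background_density <= 1)
  genes <- sort(unique(unlist(.spec_genes(spec))))
  set.seed(seed)
  ea <- character(); eb <- character()
  if (length(genes) >= 2 && background_density > 0) {
    cmb <- combn(genes, 2)
    keep <- runif(ncol(cmb)) < background_density
    ea <- cmb[1, keep]; eb <- cmb[2, keep]
  }
  if (guarantee_planted && nrow(spec$planted)) {
    gmap <- stats::setNames(.spec_genes(spec), spec$alterations$id)
    pt <- unique(spec$planted[c("a", "b")])
    ea <- c(ea, vapply(pt$a, function(x) gmap[[x]][1], ""))
    eb <- c(eb, vapply(pt$b, function(x) gmap[[x]][1], ""))
  }
  ppi_network(ea, eb, source_label = "synthetic")
}

#' Write a PPI network to the edge-list TSV dialect
#'
#' @param network a `ppi_network`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ppi <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  parts <- strsplit(network$edges, "\r", fixed = TRUE)
  df <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                   gene_b = vapply(parts, `[`, "", 2),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate synthetic log2 expression with copy-number-driven shifts
#'
#' Gaussian baseline expression for every gene the panel declares; samples
#' altered for a copy-number region have the specified per-gene log2 shift
#' added, emulating dosage-concordant expression.
#'
#' @param mat the cohort `alteration_matrix` (from [generate_cohort()]).
#' @param shifts data.frame with columns `region`, `gene`, `shift` (log2
#'   units added in altered samples).
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @param baseline_mean baseline log2 expression level (default 0).
#' @param seed integer seed.
#' @return a numeric samples x genes matrix.
#' @export
generate_expression <- function(mat, shifts = NULL, noise_sd = 1,
                                baseline_mean = 0, seed = 1) {
  stopifnot(inherits(mat, "alteration_matrix"))
  genes <- sort(unique(unlist(mat$genes)))
  set.seed(seed)
  n <- nrow(mat$incidence)
  expr <- matrix(rnorm(n * length(genes), baseline_mean, noise_sd), n,
                 dimnames = list(rownames(mat$incidence), genes))
  if (!is.null(shifts) && nrow(shifts)) {
    stopifnot(all(c("region", "gene", "shift") %in% names(shifts)))
    for (r in seq_len(nrow(shifts))) {
      reg <- shifts$region[r]
      if (!reg %in% colnames(mat$incidence))
        stop("shift references undeclared region: ", reg)
      altered <- mat$incidence[, reg] == 1L
      expr[altered, shifts$gene[r]] <- expr[altered, shifts$gene[r]] +
        shifts$shift[r]
    }
  }
  expr
}

#' Ready-made synthetic scenarios
#'
#' Three scales of the default study design: `"smoke"` (2 cancer types x
#' 100 samples), `"standard"` (4 x 300) and `"stress"` (10 x 500). All use
#' a 30-alteration panel (12 mutations, 5 copy-number gains, 5 losses —
#' one same-chromosome gain/loss pair to exercise the linkage exclusion —
#' and 8 methylation events) with baseline frequencies between 0.05 and
#' 0.2, and plant four pairs at frequency 0.1: two conserved co-occurring
#' (theta 8), one conserved mutually exclusive (theta 0.1), and one
#' differential pair (theta 8 in the first cancer type, 1 elsewhere).
#'
#' @param scale `"smoke"`, `"standard"` or `"stress"`.
#' @param seed integer seed.
#' @return a [synthetic_spec()].
#' @export
synthetic_scenario <- function(scale = c("smoke", "standard", "stress"),
                               seed = 1) {
  scale <- match.arg(scale)
  dims <- switch(scale,
                 smoke = c(types = 2, n = 100),
                 standard = c(types = 4, n = 300),
                 stress = c(types = 10, n = 500))
  types <- paste0("T", seq_len(dims["types"]))
  cancer_types <- data.frame(label = types, n_samples = unname(dims["n"]))
  alterations <- data.frame(
    id = c(paste0("MUT", 1:12), paste0("GAIN", 1:5), paste0("LOSS", 1:5),
           paste0("METH", 1:8)),
    class = rep(c("mutation", "CNA_gain", "CNA_loss", "methylation"),
                c(12, 5, 5, 8)),
    chromosome = c(paste0("chr", 1:12),         # mutations (location unused)
                   "chr9", "chr10", "chr11", "chr12", "chr13",  # gains
                   "chr9", "chr14", "chr15", "chr16", "chr17",  # losses (chr9 shared)
                   rep(NA, 8)),
    frequency = rep_len(c(0.10, 0.15, 0.20, 0.05, 0.12), 30),
    stringsAsFactors = FALSE)
  alterations$genes <- ifelse(
    grepl("^(GAIN|LOSS)", alterations$id),
    paste0(alterations$id, "_g1;", alterations$id, "_g2;", alterations$id, "_g3"),
    alterations$id)
  alterations$frequency[alterations$id %in%
    c("MUT1", "MUT2", "GAIN2", "LOSS2", "MUT5", "METH3", "MUT6", "GAIN4")] <- 0.1
  planted <- do.call(rbind, lapply(types, function(tt) data.frame(
    a = c("MUT1", "GAIN2", "MUT5", "MUT6"),
    b = c("MUT2", "LOSS2", "METH3", "GAIN4"),
    cancer_type = tt,
    theta = c(8, 8, 0.1, if (tt == types[1]) 8 else 1),
    stringsAsFactors = FALSE)))
  synthetic_spec(cancer_types, alterations, planted, seed = seed)
}
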