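#' Read a protein-protein interaction edge list
#'
#' TSV with columns `gene_a`, `gene_b` and an optional numeric `score`;
#' edges are stored as an unordered set (duplicates and orientation
#' collapse), self-edges dropped.
#'
#' @param path edge-list TSV path.
#' @param min_score optional score cutoff; rows with `score < min_score`
#'   are dropped (requires a `score` column).
#' @param source_label free-text label recorded on the network.
#' @return an object of class `ppi_network`.
#' @export
read_ppi <- function(path, min_score = NULL, source_label = basename(path)) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df)))
    stop("PPI file must have columns gene_a, gene_b")
  if (!is.null(min_score)) {
    if (!"score" %in% names(df)) stop("min_score given but no score column")
    df <- df[df$score >= min_score, , drop = FALSE]
  }
  ppi_network(df$gene_a, df$gene_b, source_label = source_label)
}

#' Build a PPI network from two gene vectors
#'
#' @param gene_a,gene_b parallel character vectors of interacting genes.
#' @param source_label free-text provenance label.
#' @return a `ppi_network`: a set of unordered gene pairs.
#' @export
ppi_network <- function(gene_a, gene_b, source_label = "user") {
  keep <- gene_a != gene_b
  a <- pmin(gene_a[keep], gene_b[keep])
  b <- pmax(gene_a[keep], gene_b[keep])
  structure(list(edges = unique(paste(a, b, sep = "\r")),
                 source_label = source_label),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network (", x$source_label, "):", length(x$edges), "edges\n")
  invisible(x)
}

#' Does any cross edge link two alterations' gene sets?
#'
#' An alteration pair is PPI-supported when at least one gene of the first
#' alteration interacts with at least one gene of the second (existential,
#' not counting) — the region-to-gene edge rule for copy-number regions
#' carrying many genes.
#'
#' @param genes_a,genes_b non-empty character vectors of gene symbols.
#' @param network a `ppi_network`.
#' @return `TRUE` or `FALSE`.
#' @export
pair_has_ppi <- function(genes_a, genes_b, network) {
  stopifnot(inherits(network, "ppi_network"))
  if (!length(genes_a) || !length(genes_b))
    stop("empty gene set")
  cross <- expand.grid(a = genes_a, b = genes_b, stringsAsFactors = FALSE)
  keys <- paste(pmin(cross$a, cross$b), pmax(cross$a, cross$b), sep = "\r")
  any(keys %in% network$edges)
}

#' PPI enrichment of detected interactions by resampling
#'
#' Counts how many detected pairs are PPI-supported (`n_obs_ppi`) and
#' compares with the same count for `n_resamples` random draws of equally
#' many distinct pairs from the eligible recurrent-alteration pool.
#' Fold enrichment is `n_obs_ppi / mean(n_random_ppi)`; the empirical
#' P-value uses the (+1)/(N+1) estimator.
#'
#' @param detected_pairs data.frame with columns `a`, `b` (alteration ids).
#' @param mat the recurrence-filtered `alteration_matrix` defining the
#'   pool; the pool is its [eligible_pairs()] set.
#' @param network a `ppi_network`.
#' @param n_resamples number of random draws (default 1000).
#' @param seed integer seed for the resampling stream.
#' @return an object of class `enrichment_result`: `n_obs_ppi`,
#'   `mean_random_ppi`, `fold`, `empirical_p`, `ci95` (2.5/97.5 percent
#'   quantiles of the random counts), `n_resamples`.
#' @export
enrichment_score <- function(detected_pairs, mat, network,
                             n_resamples = 1000, seed = 1) {
  stopifnot(inherits(mat, "alteration_matrix"),
            inherits(network, "ppi_network"))
  pool <- eligible_pairs(mat)
  n_det <- nrow(detected_pairs)
  if (nrow(pool) < n_det)
    stop("eligible pool (", nrow(pool), " pairs) smaller than detected set (",
         n_det, ")")
  genes <- mat$genes
  supported <- function(pairs) {
    if (!nrow(pairs)) return(0L)
    sum(vapply(seq_len(nrow(pairs)), function(r)
      pair_has_ppi(genes[[pairs$a[r]]], genes[[pairs$b[r]]], network),
      FALSE))
  }
  n_obs <- supported(detected_pairs)
  # precompute support of every pool pair once; resamples then index it
  pool_hit <- if (nrow(pool)) vapply(seq_len(nrow(pool)), function(r)
    pair_has_ppi(genes[[pool$a[r]]], genes[[pool$b[r]]], network), FALSE)
    else logical()
  set.seed(seed)
  rand <- vapply(seq_len(n_resamples), function(k)
    sum(pool_hit[sample.int(nrow(pool), n_det)]), 0L)
  mean_rand <- mean(rand)
  fold <- if (mean_rand > 0) n_obs / mean_rand
          else if (n_obs > 0) Inf else 1  # 0/0: no signal either way
  structure(list(
    n_obs_ppi = n_obs,
    mean_random_ppi = mean_rand,
    fold = fold,
    empirical_p = (sum(rand >= n_obs) + 1) / (n_resamples + 1),
    ci95 = unname(quantile(rand, c(0.025, 0.975))),
    n_resamples = n_resamples,
    n_detected = n_det
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("PPI enrichment:", x$n_obs_ppi, "of", x$n_detected,
      "detected pairs PPI-supported\n")
  cat(sprintf("  random mean %.2f (95%% interval %g-%g), fold %.2f, empirical P %.4g\n",
              x$mean_random_ppi, x$ci95[1], x$ci95[2], x$fold, x$empirical_p))
  invisible(x)
}
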