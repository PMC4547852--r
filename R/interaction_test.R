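#' Observed co-occurrence of a pair
#'
#' Number of samples in the scope altered in both members of the pair.
#' For `"PAN"` scope this equals the sum of within-type co-occurrences,
#' since every sample belongs to exactly one cancer type.
#'
#' @param mat an `alteration_matrix`.
#' @param pair character vector of two alteration ids.
#' @param scope `"PAN"` or a cancer-type label.
#' @return an integer count.
#' @export
cooccurrence_count <- function(mat, pair, scope = "PAN") {
  stopifnot(inherits(mat, "alteration_matrix"), length(pair) == 2)
  if (!all(pair %in% colnames(mat$incidence)))
    stop("alteration not in matrix: ",
         paste(setdiff(pair, colnames(mat$incidence)), collapse = ", "))
  si <- if (scope == "PAN") seq_len(nrow(mat$incidence)) else {
    w <- which(mat$cancer_type == scope)
    if (!length(w)) stop("unknown cancer type: ", scope)
    w
  }
  sum(mat$incidence[si, pair[1]] * mat$incidence[si, pair[2]])
}

# 2x2 cell counts (co, a_only, b_only, neither) for given sample rows.
.pair_cells <- function(inc, i, j, rows) {
  a <- inc[rows, i]; b <- inc[rows, j]
  co <- sum(a * b)
  c(co = co, a_only = sum(a) - co, b_only = sum(b) - co,
    neither = length(rows) - sum(a) - sum(b) + co)
}

#' Empirical co-occurrence / mutual-exclusivity test
#'
#' For each eligible pair, compares the observed co-occurrence count with
#' its distribution across fixed-margin stratified permutations of the
#' incidence. `P_co` is the fraction of permutations whose co-occurrence is
#' greater than or equal to the observed count, `P_me` the fraction less
#' than or equal to it (ties count toward both sides, the conservative
#' convention), both floored at 1/N since an empirical P-value cannot
#' resolve below that. All pairs in a scope share one permutation stream,
#' so pair statistics are comparable within a permutation.
#'
#' For a single cancer type the test restricts to that type's samples; for
#' `scope = "PAN"` the statistic is the within-type co-occurrence summed
#' across cancer types while permutation still acts within each type.
#'
#' @param mat a recurrence-filtered `alteration_matrix` (see
#'   [filter_recurrent()]).
#' @param pairs data.frame with columns `a`, `b` (from [eligible_pairs()]);
#'   `NULL` means all eligible pairs of `mat`.
#' @param plan a [permutation_plan()].
#' @param scope `"PAN"` or one cancer-type label.
#' @return a data.frame of class `interaction_results` with one row per
#'   pair: observed co-occurrence, `p_co`, `p_me`, `p_min`, a two-sided
#'   `p_two` (= min(1, 2 p_min)), the continuity-corrected odds ratio and
#'   its natural log, and the interaction direction.
#' @export
empirical_interaction_test <- function(mat, pairs = NULL, plan, scope = "PAN") {
  stopifnot(inherits(mat, "alteration_matrix"),
            inherits(plan, "permutation_plan"))
  if (scope != "PAN") mat <- subset_matrix(mat, samples = mat$cancer_type == scope)
  if (!nrow(mat$incidence)) stop("no samples in scope: ", scope)
  if (is.null(pairs)) pairs <- eligible_pairs(mat)
  res <- .empirical_test_core(mat, pairs, plan, scope)
  class(res) <- c("interaction_results", "data.frame")
  res
}

.empirical_test_core <- function(mat, pairs, plan, scope) {
  n_pairs <- nrow(pairs)
  empty <- data.frame(a = character(), b = character(), scope = character(),
                      co_observed = integer(), p_co = double(),
                      p_me = double(), p_min = double(), p_two = double(),
                      odds_ratio = double(), log_odds_ratio = double(),
                      direction = character(), stringsAsFactors = FALSE)
  if (!n_pairs) return(empty)
  ids <- colnames(mat$incidence)
  i <- match(pairs$a, ids); j <- match(pairs$b, ids)
  if (anyNA(i) || anyNA(j))
    stop("pair references alteration not in matrix: ",
         paste(unique(c(pairs$a[is.na(i)], pairs$b[is.na(j)])), collapse = ", "))
  X <- mat$incidence * 1
  obs <- crossprod(X)[cbind(i, j)]
  N <- plan$n_permutations
  ge <- le <- integer(n_pairs)
  stream <- permutation_stream(mat, plan)
  for (k in seq_len(N)) {
    cp <- crossprod(stream$get(k) * 1)[cbind(i, j)]
    ge <- ge + (cp >= obs)
    le <- le + (cp <= obs)
  }
  p_co <- pmax(ge, 1L) / N
  p_me <- pmax(le, 1L) / N
  p_min <- pmin(p_co, p_me)
  or <- vapply(seq_len(n_pairs), function(r) {
    corrected_odds_ratio(.pair_cells(mat$incidence, i[r], j[r],
                                     seq_len(nrow(mat$incidence))))
  }, 0)
  direction <- ifelse(p_co < p_me, "co_occurrence",
               ifelse(p_me < p_co, "mutual_exclusivity",
                      ifelse(or > 1, "co_occurrence", "mutual_exclusivity")))
  data.frame(a = pairs$a, b = pairs$b, scope = scope,
             co_observed = as.integer(obs), p_co = p_co, p_me = p_me,
             p_min = p_min, p_two = pmin(1, 2 * p_min),
             odds_ratio = or, log_odds_ratio = log(or),
             direction = direction, stringsAsFactors = FALSE)
}

#' Pan-cancer interaction test
#'
#' Convenience wrapper for [empirical_interaction_test()] with
#' `scope = "PAN"`: permutations are performed within each cancer type
#' separately and co-occurrences summed across types. With a single cancer
#' type it reduces exactly to the per-type test.
#'
#' @inheritParams empirical_interaction_test
#' @return an `interaction_results` data.frame.
#' @export
pan_cancer_test <- function(mat, pairs = NULL, plan) {
  empirical_interaction_test(mat, pairs, plan, scope = "PAN")
}

#' FDR control and interaction-network assembly
#'
#' Applies Benjamini-Hochberg adjustment to the minimal one-sided P-values
#' of all tested pairs in a scope and assembles the network of pairs with
#' `q <= fdr`. Edge direction comes from the smaller one-sided P (odds
#' ratio breaking ties); edge weight is the absolute log odds ratio.
#'
#' @param results an `interaction_results` data.frame (one scope).
#' @param mat optionally, the tested `alteration_matrix`, used to attach
#'   node frequencies and classes.
#' @param fdr FDR threshold for an edge (default 0.1).
#' @return an object of class `interaction_network`: a list with `results`
#'   (all pairs, with `q`), `edges` (pairs with `q <= fdr`), `nodes`, and
#'   `fdr`.
#' @export
fdr_and_classify <- function(results, mat = NULL, fdr = 0.1) {
  stopifnot(is.data.frame(results))
  if (nrow(results) && length(unique(results$scope)) > 1)
    stop("results must share one scope")
  results$q <- if (nrow(results)) p.adjust(results$p_min, method = "BH") else double()
  edges <- results[results$q <= fdr, , drop = FALSE]
  nodes <- NULL
  if (!is.null(mat)) {
    stopifnot(inherits(mat, "alteration_matrix"))
    sc <- if (nrow(results)) results$scope[1] else "PAN"
    si <- if (identical(sc, "PAN")) seq_len(nrow(mat$incidence)) else
      which(mat$cancer_type == sc)
    nodes <- data.frame(
      alteration = colnames(mat$incidence),
      class = unname(mat$alteration_class),
      frequency = if (length(si)) colSums(mat$incidence[si, , drop = FALSE]) / length(si)
                  else NA_real_,
      stringsAsFactors = FALSE)
  }
  structure(list(results = results, edges = edges, nodes = nodes, fdr = fdr),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", nrow(x$results), "pairs tested,",
      nrow(x$edges), "interactions at FDR", x$fdr, "\n")
  if (nrow(x$edges)) {
    tb <- table(x$edges$direction)
    cat("  ", paste0(names(tb), ": ", tb, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.interaction_network <- function(object, ...) {
  e <- object$edges
  out <- list(n_tested = nrow(object$results), n_edges = nrow(e),
              n_co = sum(e$direction == "co_occurrence"),
              n_me = sum(e$direction == "mutual_exclusivity"),
              fdr = object$fdr)
  class(out) <- "summary.interaction_network"
  out
}

#' @export
print.summary.interaction_network <- function(x, ...) {
  cat(x$n_edges, "interactions (", x$n_co, "co-occurring,", x$n_me,
      "mutually exclusive ) among", x$n_tested, "tested pairs at FDR",
      x$fdr, "\n")
  invisible(x)
}

#' Export an interaction network to SIF or GraphML
#'
#' SIF rows are `a <direction> b`; GraphML (written with igraph) carries
#' node attributes (class, frequency) and edge attributes (direction,
#' `abs_log_or`, `q`).
#'
#' @param network an `interaction_network`.
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return invisibly, `path`.
#' @export
export_network <- function(network, path, format = c("sif", "graphml")) {
  stopifnot(inherits(network, "interaction_network"))
  format <- match.arg(format)
  e <- network$edges
  if (format == "sif") {
    writeLines(if (nrow(e)) paste(e$a, e$direction, e$b) else character(), path)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(e)) data.frame(from = e$a, to = e$b, direction = e$direction,
                            abs_log_or = abs(e$log_odds_ratio), q = e$q)
    else data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = if (!is.null(network$nodes)) {
      v <- network$nodes
      v[v$alteration %in% c(e$a, e$b), , drop = FALSE]
    } else NULL)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' One-call interaction detection for a scope
#'
#' The standard per-scope pipeline stage: recurrence-filter the matrix
#' within the scope, enumerate eligible pairs, run the empirical
#' permutation test, and apply FDR classification.
#'
#' @param mat an `alteration_matrix` (hyper-altered samples already
#'   excluded if desired; see [filter_hypermutated()]).
#' @param plan a [permutation_plan()].
#' @param scope `"PAN"` or one cancer-type label.
#' @param fdr FDR threshold (default 0.1).
#' @param min_frequency recurrence threshold (default 0.02).
#' @return an `interaction_network`.
#' @export
detect_interactions <- function(mat, plan, scope = "PAN", fdr = 0.1,
                                min_frequency = 0.02) {
  fm <- filter_recurrent(mat, min_frequency = min_frequency, scope = scope)
  pairs <- eligible_pairs(fm)
  res <- .empirical_test_core(fm, pairs, plan, scope)
  class(res) <- c("interaction_results", "data.frame")
  fdr_and_classify(res, mat = fm, fdr = fdr)
}
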