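#' Read a log2 expression matrix
#'
#' TSV with a `sample_id` column and one column per gene (header row of
#' gene symbols), values already log2-transformed.
#'
#' @param path expression TSV path.
#' @return a numeric matrix, samples in rows (named), genes in columns.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("expression file needs a sample_id column")
  m <- as.matrix(df[setdiff(names(df), "sample_id")])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

#' Write a log2 expression matrix to TSV
#'
#' @param expr numeric matrix, samples in rows, genes in columns.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(sample_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rank candidate driver genes inside a copy-number region
#'
#' For every member gene of a copy-number region, tests whether its
#' expression differs between samples altered and not altered for the
#' region (two-sided Mann-Whitney rank-sum test; exact enumeration when
#' both groups have at most 8 samples and no ties, normal approximation
#' with tie correction otherwise), then ranks the genes by ascending BH
#' FDR q computed across the region's genes. Genes whose copy-number
#' status is concordant with expression rise to the top — the candidate
#' drivers of the region.
#'
#' @param mat an `alteration_matrix`.
#' @param region the alteration id of a CNA region.
#' @param expr a log2 expression matrix (samples x genes; see
#'   [read_expression()]).
#' @param cancer_type restrict to one cancer type, or `"PAN"`.
#' @return a data.frame (`gene`, `u_statistic`, `p`, `q`, `rank`) sorted by
#'   ascending `q`, or `NULL` (with a message) if either group is empty.
#' @export
rank_genes_in_region <- function(mat, region, expr, cancer_type = "PAN") {
  stopifnot(inherits(mat, "alteration_matrix"))
  if (!region %in% colnames(mat$incidence)) stop("unknown region: ", region)
  if (!mat$alteration_class[region] %in% c("CNA_gain", "CNA_loss"))
    stop("region is not a copy-number alteration: ", region)
  rows <- if (cancer_type == "PAN") rownames(mat$incidence) else
    rownames(mat$incidence)[mat$cancer_type == cancer_type]
  rows <- intersect(rows, rownames(expr))
  if (!length(rows)) stop("no samples shared between cohort and expression")
  status <- mat$incidence[rows, region]
  if (!any(status == 1) || !any(status == 0)) {
    message("region ", region, " skipped: altered or non-altered group empty")
    return(NULL)
  }
  genes <- intersect(mat$genes[[region]], colnames(expr))
  if (!length(genes)) stop("no member gene of ", region, " in expression matrix")
  alt <- rows[status == 1]; ref <- rows[status == 0]
  use_exact <- length(alt) <= 8 && length(ref) <= 8
  stats_df <- do.call(rbind, lapply(genes, function(g) {
    x <- expr[alt, g]; y <- expr[ref, g]
    if (length(unique(c(x, y))) == 1L) {
      # fully tied: zero rank-sum signal by definition
      u <- length(x) * length(y) / 2; p <- 1
    } else {
      exact <- use_exact && !anyDuplicated(c(x, y))
      wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                         exact = exact, correct = !exact))
      u <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(gene = g, u_statistic = u, p = p, stringsAsFactors = FALSE)
  }))
  stats_df$q <- p.adjust(stats_df$p, method = "BH")
  stats_df <- stats_df[order(stats_df$q, stats_df$p), , drop = FALSE]
  stats_df$rank <- seq_len(nrow(stats_df))
  rownames(stats_df) <- NULL
  stats_df
}
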