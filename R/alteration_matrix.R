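#' Build an alteration matrix
#'
#' The central container of the package: a binary sample x alteration
#' incidence matrix together with the two pieces of structure the
#' permutation null conditions on — each sample's cancer type and each
#' alteration's class (mutation, CNA gain/loss, methylation) — plus the
#' chromosome and member-gene metadata used by pair-eligibility filtering
#' and the downstream enrichment / gene-ranking stages.
#'
#' @param incidence binary matrix (samples in rows, alterations in columns);
#'   dimnames, if absent, are taken from `sample_id` / `alteration_id`.
#' @param cancer_type character vector, one cancer-type label per sample.
#' @param alteration_class character vector, one class per alteration; must
#'   be one of `"mutation"`, `"CNA_gain"`, `"CNA_loss"`, `"methylation"`.
#' @param chromosome chromosome label per alteration (`NA` allowed for
#'   non-CNA classes, required for CNAs).
#' @param genes list of character vectors: the gene symbol(s) each
#'   alteration covers (singleton for mutations/methylation, possibly many
#'   for a CNA region). Defaults to the alteration id itself.
#' @return an object of class `alteration_matrix`.
#' @export
alteration_matrix <- function(incidence, cancer_type, alteration_class,
                              chromosome = NULL, genes = NULL) {
  incidence <- as.matrix(incidence)
  storage.mode(incidence) <- "integer"
  if (length(incidence) && !all(incidence %in% c(0L, 1L)))
    stop("incidence entries must be 0 or 1")
  n <- nrow(incidence); p <- ncol(incidence)
  if (length(cancer_type) != n)
    stop("cancer_type length (", length(cancer_type), ") != number of samples (", n, ")")
  .check_classes(alteration_class, p)
  if (is.null(chromosome)) chromosome <- rep(NA_character_, p)
  chromosome <- as.character(chromosome)
  if (length(chromosome) != p) stop("chromosome must have one entry per alteration")
  if (is.null(rownames(incidence)))
    rownames(incidence) <- if (n) paste0("S", seq_len(n)) else character()
  if (is.null(colnames(incidence)))
    colnames(incidence) <- if (p) paste0("A", seq_len(p)) else character()
  if (is.null(genes)) genes <- as.list(colnames(incidence))
  if (length(genes) != p) stop("genes must have one entry per alteration")
  genes <- lapply(genes, as.character)
  if (p && any(vapply(genes, length, 0L) == 0L))
    stop("every alteration needs at least one member gene")
  structure(list(
    incidence  = incidence,
    cancer_type = stats::setNames(as.character(cancer_type), rownames(incidence)),
    alteration_class = stats::setNames(as.character(alteration_class), colnames(incidence)),
    chromosome = stats::setNames(chromosome, colnames(incidence)),
    genes      = stats::setNames(genes, colnames(incidence))
  ), class = "alteration_matrix")
}

.alteration_classes <- c("mutation", "CNA_gain", "CNA_loss", "methylation")

.check_classes <- function(cls, p) {
  if (length(cls) != p) stop("alteration_class must have one entry per alteration")
  bad <- setdiff(unique(cls), .alteration_classes)
  if (length(bad))
    stop("unknown alteration class(es): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat("alteration_matrix:", nrow(x$incidence), "samples x",
      ncol(x$incidence), "alterations\n")
  if (nrow(x$incidence)) {
    tt <- table(x$cancer_type)
    cat("  cancer types: ", paste0(names(tt), " (", tt, ")", collapse = ", "), "\n")
  }
  if (ncol(x$incidence)) {
    tc <- table(x$alteration_class)
    cat("  classes:      ", paste0(names(tc), " (", tc, ")", collapse = ", "), "\n")
  }
  cat("  events:       ", sum(x$incidence), "\n")
  invisible(x)
}

#' @export
dim.alteration_matrix <- function(x) dim(x$incidence)

#' Subset an alteration matrix by samples and/or alterations
#'
#' @param mat an `alteration_matrix`.
#' @param samples row (sample) selector: indices, names, or logical.
#' @param alterations column (alteration) selector.
#' @return the restricted `alteration_matrix`.
#' @export
subset_matrix <- function(mat, samples = NULL, alterations = NULL) {
  stopifnot(inherits(mat, "alteration_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(mat$incidence)) else samples
  ai <- if (is.null(alterations)) seq_len(ncol(mat$incidence)) else alterations
  alteration_matrix(mat$incidence[si, ai, drop = FALSE],
                    mat$cancer_type[si],
                    mat$alteration_class[ai],
                    mat$chromosome[ai],
                    mat$genes[ai])
}

#' Read an event table and alteration metadata into an alteration matrix
#'
#' Events are long-format TSV with columns `sample_id`, `alteration_id`,
#' `alteration_class`, `cancer_type`; metadata TSV has `alteration_id`,
#' `alteration_class`, `chromosome` (`.` = missing) and `genes`
#' (semicolon-separated symbols). Both files must have header rows.
#'
#' @param events_path path to the events TSV.
#' @param meta_path path to the metadata TSV.
#' @param keep_all_meta if `TRUE`, alterations present only in the metadata
#'   appear as all-zero columns; by default they are dropped.
#' @return an `alteration_matrix`.
#' @export
load_events <- function(events_path, meta_path, keep_all_meta = FALSE) {
  ev <- read.delim(events_path, sep = "\t", header = TRUE,
                   colClasses = "character", quote = "")
  need <- c("sample_id", "alteration_id", "alteration_class", "cancer_type")
  if (!all(need %in% names(ev)))
    stop("events file must have columns: ", paste(need, collapse = ", "))
  me <- read.delim(meta_path, sep = "\t", header = TRUE,
                   colClasses = "character", quote = "")
  needm <- c("alteration_id", "alteration_class", "chromosome", "genes")
  if (!all(needm %in% names(me)))
    stop("metadata file must have columns: ", paste(needm, collapse = ", "))
  if (anyDuplicated(me$alteration_id))
    stop("duplicate alteration_id in metadata: ",
         me$alteration_id[duplicated(me$alteration_id)][1])
  key <- paste(ev$sample_id, ev$alteration_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate event row: sample ", ev$sample_id[d],
         ", alteration ", ev$alteration_id[d])
  }
  miss <- setdiff(ev$alteration_id, me$alteration_id)
  if (length(miss))
    stop("event references alteration_id missing from metadata: ", miss[1])
  # one cancer type per sample
  st <- unique(ev[c("sample_id", "cancer_type")])
  if (anyDuplicated(st$sample_id))
    stop("sample mapped to more than one cancer_type: ",
         st$sample_id[duplicated(st$sample_id)][1])
  # class consistency between files
  evc <- unique(ev[c("alteration_id", "alteration_class")])
  mm <- merge(evc, me[c("alteration_id", "alteration_class")],
              by = "alteration_id", suffixes = c(".ev", ".meta"))
  bad <- mm$alteration_class.ev != mm$alteration_class.meta
  if (any(bad))
    stop("alteration_class mismatch between events and metadata for: ",
         mm$alteration_id[bad][1])
  if (!keep_all_meta) me <- me[me$alteration_id %in% ev$alteration_id, , drop = FALSE]
  samples <- sort(unique(ev$sample_id))
  alts <- me$alteration_id
  inc <- matrix(0L, length(samples), length(alts),
                dimnames = list(samples, alts))
  if (nrow(ev)) inc[cbind(match(ev$sample_id, samples),
                          match(ev$alteration_id, alts))] <- 1L
  ct <- st$cancer_type[match(samples, st$sample_id)]
  chrom <- ifelse(me$chromosome == "." | me$chromosome == "", NA_character_,
                  me$chromosome)
  genes <- strsplit(me$genes, ";", fixed = TRUE)
  if (length(alts)) .check_classes(me$alteration_class, length(alts))
  cna <- me$alteration_class %in% c("CNA_gain", "CNA_loss")
  if (any(cna & is.na(chrom)))
    stop("CNA alteration missing chromosome: ", alts[cna & is.na(chrom)][1])
  alteration_matrix(inc, ct, me$alteration_class, chrom, genes)
}

#' Write an alteration matrix back to the events/metadata TSV dialect
#'
#' Inverse of [load_events()]: `load_events(write_events(mat))` reproduces
#' the incidence, classes and chromosomes exactly.
#'
#' @param mat an `alteration_matrix`.
#' @param events_path,meta_path output paths.
#' @return invisibly, the two paths.
#' @export
write_events <- function(mat, events_path, meta_path) {
  stopifnot(inherits(mat, "alteration_matrix"))
  idx <- which(mat$incidence == 1L, arr.ind = TRUE)
  ev <- data.frame(
    sample_id = rownames(mat$incidence)[idx[, 1]],
    alteration_id = colnames(mat$incidence)[idx[, 2]],
    alteration_class = unname(mat$alteration_class[idx[, 2]]),
    cancer_type = unname(mat$cancer_type[idx[, 1]]),
    stringsAsFactors = FALSE)
  ev <- ev[order(ev$sample_id, ev$alteration_id), , drop = FALSE]
  write.table(ev, events_path, sep = "\t", quote = FALSE, row.names = FALSE)
  me <- data.frame(
    alteration_id = colnames(mat$incidence),
    alteration_class = unname(mat$alteration_class),
    chromosome = ifelse(is.na(mat$chromosome), ".", mat$chromosome),
    genes = vapply(mat$genes, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  write.table(me, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(events = events_path, meta = meta_path))
}

#' Exclude hyper-altered samples
#'
#' Removes samples whose total event count strictly exceeds
#' Q3 + multiplier x IQR of the per-sample counts (type-7 linear
#' interpolation quartiles), the standard outlier rule for tumors with
#' runaway alteration loads that would otherwise dominate the margins of
#' the permutation null.
#'
#' @param mat an `alteration_matrix`.
#' @param multiplier the IQR multiplier (default 4.5).
#' @param scope `"global"` (one threshold over all samples, the default) or
#'   `"per_cancer_type"` (a threshold within each type).
#' @return a list with `matrix` (the filtered `alteration_matrix`) and
#'   `report`, a `cohort_filter_report` listing the excluded samples, their
#'   counts and the threshold(s) used. Scopes with fewer than 4 samples are
#'   skipped with a warning. Thresholds are computed once on the input and
#'   not recomputed after exclusion.
#' @export
filter_hypermutated <- function(mat, multiplier = 4.5,
                                scope = c("global", "per_cancer_type")) {
  stopifnot(inherits(mat, "alteration_matrix"))
  scope <- match.arg(scope)
  counts <- rowSums(mat$incidence)
  groups <- if (scope == "global") rep("global", length(counts)) else mat$cancer_type
  excluded <- character(); thresholds <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 4) {
      warning("scope '", g, "' has fewer than 4 samples; hyper-altered ",
              "filtering skipped there")
      thresholds[[g]] <- NA_real_
      next
    }
    q <- quantile(counts[idx], c(0.25, 0.75), type = 7, names = FALSE)
    thr <- q[2] + multiplier * (q[2] - q[1])
    thresholds[[g]] <- thr
    excluded <- c(excluded, names(counts)[idx][counts[idx] > thr])
  }
  keep <- setdiff(rownames(mat$incidence), excluded)
  report <- structure(list(
    excluded_hyper_samples = data.frame(
      sample_id = excluded,
      event_count = unname(counts[excluded]),
      threshold = vapply(if (scope == "global") rep("global", length(excluded))
                         else mat$cancer_type[excluded],
                         function(g) thresholds[[g]], 0),
      stringsAsFactors = FALSE),
    thresholds = unlist(thresholds),
    multiplier = multiplier,
    scope = scope,
    quartile_method = "type 7 (linear interpolation)"
  ), class = "cohort_filter_report")
  list(matrix = subset_matrix(mat, samples = keep), report = report)
}

#' @export
print.cohort_filter_report <- function(x, ...) {
  cat("hyper-altered sample filter (Q3 +", x$multiplier, "x IQR,",
      x$scope, "scope,", x$quartile_method, ")\n")
  cat("  excluded:", nrow(x$excluded_hyper_samples), "sample(s)\n")
  if (nrow(x$excluded_hyper_samples)) print(x$excluded_hyper_samples)
  invisible(x)
}

#' Keep recurrently altered alterations within a scope
#'
#' Restricts the matrix to the samples of `scope` (one cancer type, or
#' `"PAN"` for all) and keeps alterations altered in at least
#' `ceiling(min_frequency * n_scope)` of those samples — the "at least 2%
#' of the samples under consideration" recurrence rule.
#'
#' @param mat an `alteration_matrix`.
#' @param min_frequency minimum altered-sample fraction, in (0, 1].
#' @param scope `"PAN"` or a cancer-type label present in the matrix.
#' @return the restricted `alteration_matrix`.
#' @export
filter_recurrent <- function(mat, min_frequency = 0.02, scope = "PAN") {
  stopifnot(inherits(mat, "alteration_matrix"))
  if (!is.numeric(min_frequency) || min_frequency <= 0 || min_frequency > 1)
    stop("min_frequency must lie in (0, 1]")
  if (scope == "PAN") {
    si <- seq_len(nrow(mat$incidence))
  } else {
    si <- which(mat$cancer_type == scope)
    if (!length(si)) stop("unknown cancer type: ", scope)
  }
  thr <- ceiling(min_frequency * length(si))
  keep <- colSums(mat$incidence[si, , drop = FALSE]) >= thr
  subset_matrix(mat, samples = si, alterations = which(keep))
}

#' Enumerate testable alteration pairs
#'
#' All unordered pairs of alterations except pairs in which both members
#' are copy-number alterations (gain or loss) on the same chromosome —
#' such pairs are confounded by linkage rather than selection. Mutation
#' and methylation events are never excluded by location.
#'
#' @param mat an `alteration_matrix`.
#' @return a data.frame with columns `a` and `b` (alteration ids,
#'   `a` < `b` lexicographically), deduplicated.
#' @export
eligible_pairs <- function(mat) {
  stopifnot(inherits(mat, "alteration_matrix"))
  ids <- colnames(mat$incidence)
  p <- length(ids)
  if (p < 2)
    return(data.frame(a = character(), b = character(), stringsAsFactors = FALSE))
  cna <- mat$alteration_class %in% c("CNA_gain", "CNA_loss")
  if (any(cna & is.na(mat$chromosome)))
    stop("CNA alteration missing chromosome: ",
         ids[cna & is.na(mat$chromosome)][1])
  cmb <- combn(p, 2)
  i <- cmb[1, ]; j <- cmb[2, ]
  drop <- cna[i] & cna[j] & mat$chromosome[i] == mat$chromosome[j]
  drop[is.na(drop)] <- FALSE
  a <- ids[i][!drop]; b <- ids[j][!drop]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}
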