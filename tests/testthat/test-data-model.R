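test_that("events/metadata TSV round-trips through load_events exactly", {
  spec <- synthetic_scenario("smoke", seed = 4)
  mat <- generate_cohort(spec)$matrix
  ev <- tempfile(fileext = ".tsv"); me <- tempfile(fileext = ".tsv")
  write_events(mat, ev, me)
  back <- load_events(ev, me)
  # the long format carries only samples with at least one event
  samp <- rownames(mat$incidence)[rowSums(mat$incidence) > 0]
  expect_identical(back$incidence[samp, colnames(mat$incidence)],
                   mat$incidence[samp, ])
  expect_identical(back$alteration_class[colnames(mat$incidence)],
                   mat$alteration_class)
  expect_identical(back$chromosome[colnames(mat$incidence)], mat$chromosome)
  expect_identical(back$cancer_type[samp], mat$cancer_type[samp])
  expect_identical(back$genes[colnames(mat$incidence)], mat$genes)
})

test_that("load_events validates its inputs", {
  ev <- tempfile(fileext = ".tsv"); me <- tempfile(fileext = ".tsv")
  writeLines(c("alteration_id\talteration_class\tchromosome\tgenes",
               "m1\tmutation\t.\tTP53"), me)
  # empty events file with a valid header -> empty matrix
  writeLines("sample_id\talteration_id\talteration_class\tcancer_type", ev)
  empty <- load_events(ev, me)
  expect_equal(dim(empty), c(0L, 0L))
  # duplicate event row
  writeLines(c("sample_id\talteration_id\talteration_class\tcancer_type",
               "s1\tm1\tmutation\tBRCA", "s1\tm1\tmutation\tBRCA"), ev)
  expect_error(load_events(ev, me), "duplicate event row.*m1")
  # event referencing an alteration missing from metadata
  writeLines(c("sample_id\talteration_id\talteration_class\tcancer_type",
               "s1\tm2\tmutation\tBRCA"), ev)
  expect_error(load_events(ev, me), "m2")
  # class mismatch between files
  writeLines(c("sample_id\talteration_id\talteration_class\tcancer_type",
               "s1\tm1\tCNA_gain\tBRCA"), ev)
  expect_error(load_events(ev, me), "mismatch.*m1")
  # one sample mapped to two cancer types
  writeLines(c("alteration_id\talteration_class\tchromosome\tgenes",
               "m1\tmutation\t.\tTP53", "m2\tmutation\t.\tKRAS"), me)
  writeLines(c("sample_id\talteration_id\talteration_class\tcancer_type",
               "s1\tm1\tmutation\tBRCA", "s1\tm2\tmutation\tLUAD"), ev)
  expect_error(load_events(ev, me), "more than one cancer_type")
})

test_that("hyper-altered exclusion applies the Q3 + k x IQR rule with type-7 quartiles", {
  # counts {2,3,4,5,100}: Q1 = 3, Q3 = 5, threshold 5 + 4.5 x 2 = 14
  inc <- matrix(0L, 5, 100)
  for (i in seq_len(5)) inc[i, seq_len(c(2, 3, 4, 5, 100)[i])] <- 1L
  mat <- alteration_matrix(inc, rep("T1", 5), rep("mutation", 100))
  out <- filter_hypermutated(mat)
  expect_equal(out$report$excluded_hyper_samples$sample_id, "S5")
  expect_equal(unname(out$report$thresholds), 14)
  expect_equal(nrow(out$matrix$incidence), 4)
  # degenerate spread: identical counts, IQR 0, nothing strictly exceeds
  inc2 <- matrix(0L, 4, 10); inc2[, 1:5] <- 1L
  mat2 <- alteration_matrix(inc2, rep("T1", 4), rep("mutation", 10))
  out2 <- filter_hypermutated(mat2)
  expect_equal(nrow(out2$report$excluded_hyper_samples), 0)
  expect_equal(nrow(out2$matrix$incidence), 4)
  # fewer than 4 samples in a scope: skipped with a warning
  mat3 <- subset_matrix(mat, samples = 1:3)
  expect_warning(out3 <- filter_hypermutated(mat3), "fewer than 4")
  expect_equal(nrow(out3$matrix$incidence), 3)
  # never removes a sample at the threshold (boundary is strict)
  inc4 <- matrix(0L, 5, 20)
  for (i in seq_len(5)) inc4[i, seq_len(c(2, 3, 4, 5, 14)[i])] <- 1L
  mat4 <- alteration_matrix(inc4, rep("T1", 5), rep("mutation", 20))
  expect_equal(nrow(filter_hypermutated(mat4)$report$excluded_hyper_samples), 0)
})

test_that("recurrence filter keeps alterations at the ceiling(2% x n) boundary", {
  # n = 200: threshold 4; altered in 3 dropped, in 4 kept
  inc <- matrix(0L, 200, 2, dimnames = list(NULL, c("lo", "hi")))
  inc[1:3, "lo"] <- 1L; inc[1:4, "hi"] <- 1L
  mat <- alteration_matrix(inc, rep("T1", 200), rep("mutation", 2))
  kept <- filter_recurrent(mat)
  expect_equal(colnames(kept$incidence), "hi")
  # n = 50: one altered sample is 2.0%, ceiling(1) = 1 -> kept
  inc2 <- matrix(0L, 50, 1, dimnames = list(NULL, "x"))
  inc2[1, 1] <- 1L
  mat2 <- alteration_matrix(inc2, rep("T1", 50), "mutation")
  expect_equal(ncol(filter_recurrent(mat2)$incidence), 1)
  # min_frequency 1: only alterations in every sample survive
  inc3 <- cbind(all = rep(1L, 10), most = c(rep(1L, 9), 0L))
  mat3 <- alteration_matrix(inc3, rep("T1", 10), rep("mutation", 2))
  expect_equal(colnames(filter_recurrent(mat3, min_frequency = 1)$incidence), "all")
  expect_error(filter_recurrent(mat, min_frequency = 0), "min_frequency")
  expect_error(filter_recurrent(mat, min_frequency = 1.5), "min_frequency")
})

test_that("pair eligibility excludes only same-chromosome CNA-CNA pairs", {
  inc <- matrix(0L, 4, 4,
                dimnames = list(NULL, c("loss9", "gain9", "tp53", "loss17")))
  mat <- alteration_matrix(inc, rep("T1", 4),
                           c("CNA_loss", "CNA_gain", "mutation", "CNA_loss"),
                           chromosome = c("chr9", "chr9", "chr17", "chr17"))
  pr <- eligible_pairs(mat)
  keys <- pkey(pr$a, pr$b)
  expect_false(pkey("loss9", "gain9") %in% keys)       # CNA pair, same chromosome
  expect_true(pkey("tp53", "loss17") %in% keys)        # mutation-CNA never excluded
  expect_equal(nrow(pr), 5)                            # C(4,2) minus one exclusion
  expect_equal(anyDuplicated(keys), 0L)
  # 4 alterations, no co-chromosomal CNAs -> all 6 pairs
  mat2 <- alteration_matrix(inc, rep("T1", 4),
                            c("CNA_loss", "CNA_gain", "mutation", "CNA_loss"),
                            chromosome = c("chr1", "chr9", "chr17", "chr17"))
  expect_equal(nrow(eligible_pairs(mat2)), 6)
  # CNA without chromosome is an error naming it
  mat3 <- alteration_matrix(inc, rep("T1", 4),
                            c("CNA_loss", "mutation", "mutation", "mutation"))
  expect_error(eligible_pairs(mat3), "loss9")
})
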