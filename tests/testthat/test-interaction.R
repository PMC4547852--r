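test_that("co-occurrence counting matches direct set arithmetic", {
  m <- toy_matrix()
  expect_equal(cooccurrence_count(m, c("A", "B")), 2)       # hand-drawn overlap
  expect_equal(cooccurrence_count(m, c("B", "C")), 1)
  inc <- cbind(x = c(1L, 1L, 0L), y = c(0L, 0L, 1L), z = c(1L, 1L, 0L))
  m2 <- alteration_matrix(inc, rep("T1", 3), rep("mutation", 3))
  expect_equal(cooccurrence_count(m2, c("x", "y")), 0)      # disjoint
  expect_equal(cooccurrence_count(m2, c("x", "z")), 2)      # identical columns
  expect_error(cooccurrence_count(m2, c("x", "missing")), "missing")
  expect_error(cooccurrence_count(m2, c("x", "y"), scope = "nope"), "unknown")
})

test_that("empirical P-values carry the tie-inclusive counting convention", {
  m <- toy_matrix()
  plan <- permutation_plan(400, seed = 21)
  res <- empirical_interaction_test(m, plan = plan, scope = "T1")
  expect_equal(nrow(res), 3)
  # both one-sided P-values include ties, so they sum to 1 + P(tie) >= 1
  expect_true(all(res$p_co + res$p_me >= 1))
  expect_true(all(res$p_co >= 1 / 400 & res$p_me >= 1 / 400))
  expect_equal(res$p_min, pmin(res$p_co, res$p_me))
  expect_equal(res$p_two, pmin(1, 2 * res$p_min))
  # margins of the toy force C's column: a pair with constant permuted
  # co-occurrence has P_co = P_me = 1
  const <- res$p_co == 1 & res$p_me == 1
  expect_true(any(res$p_co + res$p_me > 1))  # ties exist at this scale
  # direction agrees with the smaller one-sided P (OR used only for ties)
  smaller_co <- res$p_co < res$p_me
  expect_true(all(res$direction[smaller_co] == "co_occurrence"))
})

test_that("pan-cancer statistic sums within-type co-occurrence and reduces to the per-type test", {
  spec <- synthetic_scenario("smoke", seed = 6)
  mat <- generate_cohort(spec)$matrix
  fm <- filter_recurrent(mat, scope = "PAN")
  pairs <- head(eligible_pairs(fm), 5)
  plan <- permutation_plan(50, seed = 14)
  res <- pan_cancer_test(fm, pairs, plan)
  # observed pan statistic = sum of within-type co-occurrence
  for (r in seq_len(nrow(pairs))) {
    by_type <- sum(vapply(unique(fm$cancer_type), function(t)
      cooccurrence_count(fm, c(pairs$a[r], pairs$b[r]), scope = t), 0))
    expect_equal(res$co_observed[r], by_type)
  }
  # one cancer type only: identical to the per-type empirical test
  one <- subset_matrix(mat, samples = mat$cancer_type == "T1")
  fm1 <- filter_recurrent(one, scope = "T1")
  pairs1 <- head(eligible_pairs(fm1), 5)
  r_pan <- pan_cancer_test(fm1, pairs1, permutation_plan(100, seed = 31))
  r_typ <- empirical_interaction_test(fm1, pairs1,
                                      permutation_plan(100, seed = 31),
                                      scope = "T1")
  expect_equal(r_pan[c("a", "b", "co_observed", "p_co", "p_me")],
               r_typ[c("a", "b", "co_observed", "p_co", "p_me")])
})

test_that("BH adjustment and network assembly follow the hand computation", {
  res <- data.frame(a = paste0("g", 1:4), b = paste0("h", 1:4), scope = "PAN",
                    co_observed = 5L, p_co = c(0.01, 0.02, 0.03, 0.04),
                    p_me = 1, p_min = c(0.01, 0.02, 0.03, 0.04),
                    p_two = c(0.02, 0.04, 0.06, 0.08),
                    odds_ratio = 2, log_odds_ratio = log(2),
                    direction = "co_occurrence", stringsAsFactors = FALSE)
  net <- fdr_and_classify(res, fdr = 0.1)
  expect_equal(net$results$q, rep(0.04, 4))   # hand BH: all 4 x 0.01 x (4/rank) -> 0.04
  expect_equal(nrow(net$edges), 4)
  # all p = 1: no edges at any threshold below 1
  res$p_min <- 1
  expect_equal(nrow(fdr_and_classify(res, fdr = 0.99)$edges), 0)
  # single pair: q equals p
  expect_equal(fdr_and_classify(res[1, ], fdr = 0.1)$results$q, 1)
  one <- res[1, ]; one$p_min <- 0.005
  expect_equal(fdr_and_classify(one)$results$q, 0.005)
  # BH output is monotone in the sorted p-values and bounded by 1
  set.seed(3)
  rp <- sort(runif(50))
  res50 <- res[rep(1, 50), ]; res50$p_min <- rp
  q <- fdr_and_classify(res50)$results$q
  expect_true(all(diff(q[order(rp)]) >= -1e-12))
  expect_true(all(q <= 1))
})

test_that("network export writes SIF and GraphML", {
  res <- data.frame(a = c("g1", "g2", "g3"), b = c("g2", "g3", "g4"),
                    scope = "PAN", co_observed = c(9L, 1L, 7L),
                    p_co = c(0.001, 0.9, 0.002), p_me = c(1, 0.004, 1),
                    p_min = c(0.001, 0.004, 0.002),
                    p_two = c(0.002, 0.008, 0.004),
                    odds_ratio = c(4, 0.2, 3),
                    log_odds_ratio = log(c(4, 0.2, 3)),
                    direction = c("co_occurrence", "mutual_exclusivity",
                                  "co_occurrence"), stringsAsFactors = FALSE)
  net <- fdr_and_classify(res, fdr = 0.1)
  expect_equal(nrow(net$edges), 3)
  sif <- tempfile(fileext = ".sif"); gml <- tempfile(fileext = ".graphml")
  export_network(net, sif, "sif")
  expect_equal(length(readLines(sif)), 3)
  expect_match(readLines(sif)[1], "g1 co_occurrence g2")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 3)
  expect_true("abs_log_or" %in% igraph::edge_attr_names(g))
  expect_equal(sort(igraph::edge_attr(g, "abs_log_or")),
               sort(abs(res$log_odds_ratio)), tolerance = 1e-10)
  # empty network still exports cleanly
  net0 <- fdr_and_classify(res[0, ], fdr = 0.1)
  export_network(net0, sif, "sif")
  expect_equal(length(readLines(sif)), 0)
})

test_that("planted odds ratios drive detection monotonically", {
  # raising theta never raises the expected P_co (same seed, all else fixed)
  base <- function(theta, seed) {
    spec <- synthetic_spec(
      data.frame(label = "T1", n_samples = 250),
      data.frame(id = paste0("A", 1:6), class = "mutation", chromosome = NA,
                 frequency = 0.15),
      planted = data.frame(a = "A1", b = "A2", cancer_type = "T1", theta = theta),
      seed = seed)
    m <- generate_cohort(spec)$matrix
    res <- empirical_interaction_test(m, data.frame(a = "A1", b = "A2"),
                                      permutation_plan(200, seed = seed + 1),
                                      scope = "T1")
    res$p_co
  }
  p1 <- mean(vapply(1:6, function(s) base(1, s), 0))
  p8 <- mean(vapply(1:6, function(s) base(8, s), 0))
  expect_lt(p8, p1)
})
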