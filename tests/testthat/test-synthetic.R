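test_that("joint Bernoulli cells reproduce marginals and odds ratio exactly", {
  # independence
  expect_equal(unname(joint_bernoulli_with_or(0.5, 0.5, 1)["p11"]), 0.25)
  # hand-solved quadratic: (0.3, 0.2, 4) -> p11 ~ 0.1107
  cells <- joint_bernoulli_with_or(0.3, 0.2, 4)
  expect_equal(unname(cells["p11"]), 0.1107, tolerance = 1e-3)
  expect_equal(unname((cells["p11"] * cells["p00"]) /
                        (cells["p10"] * cells["p01"])), 4, tolerance = 1e-10)
  # exclusivity limit: p11 ~ sqrt(theta)/2 -> 0 as theta -> 0
  expect_lt(unname(joint_bernoulli_with_or(0.5, 0.5, 1e-6)["p11"]), 1e-3)
  # grid: marginals and OR recovered to 1e-10
  for (pA in c(0.05, 0.2, 0.5, 0.8)) for (pB in c(0.1, 0.4, 0.7))
    for (th in c(0.05, 0.5, 1, 2, 8, 50)) {
      cl <- joint_bernoulli_with_or(pA, pB, th)
      expect_equal(sum(cl), 1, tolerance = 1e-12)
      expect_true(all(cl >= -1e-12))
      expect_equal(unname(cl["p11"] + cl["p10"]), pA, tolerance = 1e-10)
      expect_equal(unname(cl["p11"] + cl["p01"]), pB, tolerance = 1e-10)
      expect_equal(unname((cl["p11"] * cl["p00"]) / (cl["p10"] * cl["p01"])),
                   th, tolerance = 1e-8)
    }
})

test_that("cohort generation is deterministic and manifest ORs are analytic", {
  spec <- synthetic_scenario("smoke", seed = 101)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$matrix$incidence, c2$matrix$incidence)
  expect_identical(c1$manifest$planted_cells, c2$manifest$planted_cells)
  # implied OR equals requested theta to numerical tolerance
  pc <- c1$manifest$planted_cells
  expect_equal(pc$or_implied, pc$theta, tolerance = 1e-10)
  expect_equal(pc$p11 + pc$p10 + pc$p01 + pc$p00, rep(1, nrow(pc)),
               tolerance = 1e-12)
  # the differential pair is flagged
  expect_equal(nrow(c1$manifest$differential_pairs), 1)
  # distinct seeds differ
  c3 <- generate_cohort(synthetic_scenario("smoke", seed = 102))
  expect_false(identical(c1$matrix$incidence, c3$matrix$incidence))
})

test_that("realized frequencies converge to baselines at large n", {
  spec <- synthetic_spec(
    data.frame(label = "T1", n_samples = 10000),
    data.frame(id = paste0("A", 1:5), class = "mutation", chromosome = NA,
               frequency = c(0.05, 0.1, 0.2, 0.3, 0.4)),
    sample_load_dispersion = 0, hyper_fraction = 0, seed = 55)
  ch <- generate_cohort(spec)
  f <- colMeans(ch$matrix$incidence)
  se <- sqrt(c(0.05, 0.1, 0.2, 0.3, 0.4) * (1 - c(0.05, 0.1, 0.2, 0.3, 0.4)) / 10000)
  expect_true(all(abs(f - c(0.05, 0.1, 0.2, 0.3, 0.4)) <= 3 * se))
})

test_that("load dispersion produces overdispersed per-sample counts", {
  base <- data.frame(id = paste0("A", 1:30), class = "mutation",
                     chromosome = NA, frequency = 0.15)
  types <- data.frame(label = "T1", n_samples = 2000)
  ch0 <- generate_cohort(synthetic_spec(types, base, sample_load_dispersion = 0,
                                        hyper_fraction = 0, seed = 9))
  ch1 <- generate_cohort(synthetic_spec(types, base, sample_load_dispersion = 0.8,
                                        hyper_fraction = 0, seed = 9))
  v0 <- var(rowSums(ch0$matrix$incidence))
  v1 <- var(rowSums(ch1$matrix$incidence))
  binom_var <- 30 * 0.15 * 0.85
  expect_lt(v0, 1.3 * binom_var)
  expect_gt(v1, 1.5 * binom_var)
})

test_that("null cohorts show no systematic pairwise association", {
  spec <- synthetic_spec(
    data.frame(label = "T1", n_samples = 1000),
    data.frame(id = paste0("A", 1:12), class = "mutation", chromosome = NA,
               frequency = 0.2),
    sample_load_dispersion = 0, hyper_fraction = 0, seed = 77)
  m <- generate_cohort(spec)$matrix
  prs <- eligible_pairs(m)
  ors <- vapply(seq_len(nrow(prs)), function(r) {
    i <- prs$a[r]; j <- prs$b[r]
    corrected_odds_ratio(c(co = sum(m$incidence[, i] * m$incidence[, j]),
                           a_only = sum(m$incidence[, i] * (1 - m$incidence[, j])),
                           b_only = sum((1 - m$incidence[, i]) * m$incidence[, j]),
                           neither = sum((1 - m$incidence[, i]) * (1 - m$incidence[, j]))))
  }, 0)
  expect_equal(median(log(ors)), 0, tolerance = 0.15)
})

test_that("generator warns on untestable planted pairs and rejects bad specs", {
  types <- data.frame(label = "T1", n_samples = 50)
  alts <- data.frame(id = c("g1", "g2"), class = "CNA_gain",
                     chromosome = "chr7", frequency = 0.2)
  expect_warning(synthetic_spec(types, alts,
                                planted = data.frame(a = "g1", b = "g2",
                                                     cancer_type = "T1",
                                                     theta = 4)),
                 "untestable")
  expect_error(synthetic_spec(types, alts,
                              planted = data.frame(a = "g1", b = "zz",
                                                   cancer_type = "T1", theta = 2)),
               "undeclared")
  expect_error(synthetic_spec(types,
                              data.frame(id = "a", class = "mutation",
                                         frequency = 1.2)),
               "frequencies")
  # one alteration in two planted pairs is rejected
  alts3 <- data.frame(id = c("x", "y", "z"), class = "mutation", frequency = 0.1)
  expect_error(synthetic_spec(types, alts3,
                              planted = data.frame(a = c("x", "x"), b = c("y", "z"),
                                                   cancer_type = "T1", theta = 2)),
               "at most one")
})

test_that("synthetic expression carries the planted dosage shift", {
  spec <- synthetic_spec(
    data.frame(label = "T1", n_samples = 400),
    data.frame(id = "GAIN1", class = "CNA_gain", chromosome = "chr1",
               genes = "g1;g2", frequency = 0.5),
    seed = 21)
  ch <- generate_cohort(spec)
  # zero shift, zero noise: constant matrix
  e0 <- generate_expression(ch$matrix, noise_sd = 0, baseline_mean = 3, seed = 1)
  expect_true(all(e0 == 3))
  e2 <- generate_expression(ch$matrix,
                            shifts = data.frame(region = "GAIN1", gene = "g1",
                                                shift = 2),
                            noise_sd = 1, seed = 2)
  alt <- ch$matrix$incidence[, "GAIN1"] == 1
  expect_equal(mean(e2[alt, "g1"]) - mean(e2[!alt, "g1"]), 2, tolerance = 0.35)
  expect_equal(mean(e2[alt, "g2"]) - mean(e2[!alt, "g2"]), 0, tolerance = 0.35)
})
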