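# Segregation classification, exact gamete probabilities and two-point MLE.

test_that("classify_segregation labels and validates dosages", {
  s <- classify_segregation(1, 0)
  expect_equal(s$label, "1x0")
  expect_true(s$informative)
  expect_false(classify_segregation(0, 0)$informative)
  expect_false(classify_segregation(4, 4)$informative)
  expect_true(classify_segregation(1, 1)$informative)
  expect_error(classify_segregation(5, 0), "0..4")
  expect_error(classify_segregation(1, -1), "0..4")
  expect_error(classify_segregation(1.5, 0), "0..4")
})

test_that("pair_phase enforces the overlap range and labels phases", {
  expect_equal(pair_phase(1, 1, 1)$label, "coupling")
  expect_equal(pair_phase(1, 1, 0)$label, "repulsion")
  expect_equal(pair_phase(2, 2, 1)$label, "mixed")
  expect_equal(pair_phase(3, 3, 2)$label, "repulsion")  # lo = 2, hi = 3
  expect_error(pair_phase(1, 1, 2), "impossible")
  expect_error(pair_phase(3, 3, 1), "impossible")
})

test_that("gamete distributions are proper and match the no-recombination limits", {
  ## property: tables sum to 1 within 1e-12 over all dosage/overlap configs
  for (d1 in 0:4) for (d2 in 0:4) {
    for (ov in seq.int(max(0, d1 + d2 - 4), min(d1, d2))) {
      for (r in c(0, 0.123, 0.5)) {
        P <- joint_gamete_distribution(pair_phase(d1, d2, ov), r)
        expect_lt(abs(sum(P) - 1), 1e-12)
        expect_true(all(P >= -1e-15))
      }
    }
  }
  ## coupling simplex pair, r = 0: no single-transmission classes
  P0 <- joint_gamete_distribution(pair_phase(1, 1, 1), 0)
  expect_equal(P0[2, 1], 0)
  expect_equal(P0[1, 2], 0)
  ## symmetry: P(first only) = P(second only) for same-dosage coupling
  for (r in c(0.05, 0.2, 0.35)) {
    P <- joint_gamete_distribution(pair_phase(1, 1, 1), r)
    expect_equal(sum(P[2:3, 1]), sum(P[1, 2:3]))
    P2 <- joint_gamete_distribution(pair_phase(2, 2, 2), r)
    expect_equal(sum(P2[2:3, 1]), sum(P2[1, 2:3]))
  }
  ## repulsion simplex pair, r = 0: both-transmitted class has mass
  ## (homologues can enter different bivalents)
  Pr <- joint_gamete_distribution(pair_phase(1, 1, 0), 0)
  expect_gt(Pr[2, 2], 0)
  expect_error(joint_gamete_distribution(pair_phase(1, 1, 1), 0.6), "0, 0.5")
})

test_that("enumeration agrees with an independent Monte-Carlo meiosis", {
  set.seed(77)
  cases <- list(c(1, 1, 0), c(1, 1, 1), c(2, 1, 1), c(2, 2, 0), c(3, 2, 2))
  for (cs in cases) {
    for (r in c(0, 0.15, 0.4)) {
      h <- phase_alleles(cs[1], cs[2], cs[3])
      mc <- mc_gametes(h, r, 2e5)
      P <- joint_gamete_distribution(pair_phase(cs[1], cs[2], cs[3]), r)
      for (a in 0:2) for (b in 0:2) {
        p_hat <- mean(mc[, 1] == a & mc[, 2] == b)
        se <- sqrt(max(P[a + 1, b + 1] * (1 - P[a + 1, b + 1]), 1e-6) / 2e5)
        expect_lt(abs(p_hat - P[a + 1, b + 1]), 4 * se + 1e-4)
      }
    }
  }
})

test_that("estimate_two_point reproduces closed-form and boundary cases", {
  s10 <- classify_segregation(1, 0)
  ## coupling-consistent counts 48/2/2/48: r_hat = (n10 + n01)/n = 0.04
  cc <- matrix(0, 5, 5)
  cc[1, 1] <- 48; cc[2, 2] <- 48; cc[2, 1] <- 2; cc[1, 2] <- 2
  tp <- estimate_two_point(cc, s10, s10)
  expect_equal(tp$r, 0.04, tolerance = 1e-4)
  expect_equal(tp$phase$maternal$label, "coupling")
  expect_equal(tp$n_used, 100)

  ## perfect coupling: r = 0 exactly, LOD > 0
  pc <- matrix(0, 5, 5); pc[1, 1] <- 50; pc[2, 2] <- 50
  tp0 <- estimate_two_point(pc, s10, s10)
  expect_identical(tp0$r, 0)
  expect_gt(tp0$LOD, 0)

  ## independence: r = 0.5, LOD = 0
  ind <- matrix(0, 5, 5); ind[1:2, 1:2] <- 25
  tp5 <- estimate_two_point(ind, s10, s10)
  expect_identical(tp5$r, 0.5)
  expect_equal(tp5$LOD, 0)

  ## errors
  expect_error(estimate_two_point(matrix(0, 5, 5), s10, s10), "no data")
  bad <- pc; bad[5, 5] <- 3   # dosage 4/4 impossible for 1x0 markers
  expect_error(estimate_two_point(bad, s10, s10), "inconsistent")
  expect_error(
    estimate_two_point(pc, s10, classify_segregation(0, 1)),
    "not estimable")
})

test_that("MLE is monotone in the recombinant fraction for coupling tables", {
  s10 <- classify_segregation(1, 0)
  r_prev <- -1
  for (k in seq(0, 40, by = 8)) {
    cc <- matrix(0, 5, 5)
    cc[1, 1] <- 50 - k / 2; cc[2, 2] <- 50 - k / 2
    cc[2, 1] <- k / 2; cc[1, 2] <- k / 2
    tp <- estimate_two_point(cc, s10, s10)
    expect_gte(tp$r, r_prev)
    r_prev <- tp$r
  }
})

test_that("batch estimator agrees with the single-pair optimiser", {
  z <- small_cross(seed = 61, n_chrom = 1, n_mark = 30, n_off = 150)
  x <- z$sim$dosage
  prs <- t(utils::combn(rownames(x), 2))
  set.seed(1)
  prs <- prs[sample(nrow(prs), 60), ]
  pw <- estimate_two_point_batch(x, prs)
  dm <- attr(x, "dosage_m"); dp <- attr(x, "dosage_p")
  for (k in seq_len(nrow(pw))) {
    if (is.na(pw$r[k])) next
    tp <- estimate_two_point(
      joint_counts(x, pw$marker1[k], pw$marker2[k]),
      classify_segregation(dm[pw$marker1[k]], dp[pw$marker1[k]]),
      classify_segregation(dm[pw$marker2[k]], dp[pw$marker2[k]]))
    expect_lt(abs(tp$r - pw$r[k]), 1e-5)
    expect_lt(abs(tp$LOD - pw$LOD[k]), 1e-3 * max(1, tp$LOD))
  }
  ## pairs with no doubly-informative parent are flagged inestimable
  x10 <- which(dm == 1L & dp == 0L)[1]
  x01 <- which(dm == 0L & dp == 1L)[1]
  pw2 <- estimate_two_point_batch(x, cbind(rownames(x)[x10],
                                           rownames(x)[x01]))
  expect_true(is.na(pw2$r))
  expect_equal(pw2$LOD, 0)
})

test_that("double-reduction estimator matches its binomial model", {
  s10 <- classify_segregation(1, 0)
  expect_equal(
    estimate_double_reduction(rep(c(0, 1), c(100, 100)), s10)$alpha_hat, 0)
  est <- estimate_double_reduction(rep(c(0, 1, 2), c(97, 98, 5)), s10)
  expect_equal(est$alpha_hat, 0.10)
  expect_equal(est$n, 200)
  expect_true(est$ci[1] <= 0.10 && 0.10 <= est$ci[2])
  expect_error(
    estimate_double_reduction(c(0, 1), classify_segregation(2, 0)),
    "simplex")
})

test_that("preferential-pairing test evaluates the chi-squared exactly", {
  u <- preferential_pairing_check(c(100, 100, 100))
  expect_equal(u$statistic, 0)
  expect_equal(u$p_value, 1)
  v <- preferential_pairing_check(c(200, 50, 50))
  expect_equal(v$statistic, 150)
  expect_lt(v$p_value, 1e-30)
  expect_warning(preferential_pairing_check(c(5, 5, 5)), "underpowered")
})

test_that("preferential-pairing type-I error is near nominal under randomness", {
  ## simdata bivalent pairing truth is uniform over the 3 configurations
  cfg <- sim_config(n_chromosomes = 1, n_markers_per_chrom = 2,
                    quadrivalent_rate = 0, double_reduction_rate = 0,
                    seed = 91)
  par <- simulate_parents(cfg)
  set.seed(92)
  rej <- 0L
  n_rep <- 400L
  for (i in seq_len(n_rep)) {
    g <- simulate_gametes(par$maternal, cfg, n = 120)[[1]]
    counts <- tabulate(g$pairing, 3L)
    if (preferential_pairing_check(counts)$p_value < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / n_rep - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})
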