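test_that("the neutral variance formula degenerates and averages correctly", {
  # F_ST = 0: no neutral among-population variance at all
  q0 <- simulate_neutral_qst(0, n_pop = 10, v_a = 1, v_wp = 1,
                             n_sim = 100, seed = 1)
  expect_true(all(q0 == 0))
  # E[r / (n_pop - 1)] = 1, so E[Vnp] = F_ST * 2 V_A / (1 - F_ST)
  set.seed(2)
  n <- 1e5; npop <- 8
  vnp_implied <- function(q, vwp) 2 * vwp * q / (1 - q)
  q <- simulate_neutral_qst(0.5, n_pop = npop, v_a = 1, v_wp = 1,
                            n_sim = n)
  vnp <- vnp_implied(q, 1)
  mc_se <- sd(vnp) / sqrt(n)
  expect_lt(abs(mean(vnp) - 2), 3 * mc_se)
  expect_error(simulate_neutral_qst(1, 5, 1, 1), "< 1")
  expect_warning(simulate_neutral_qst(-0.01, 5, 1, 1, n_sim = 10),
                 "clipped")
})

test_that("neutral Q_ST quantiles match an independent brute-force simulation", {
  # direct one-line re-simulation, kept deliberately separate from the
  # package code path
  set.seed(33)
  npop <- 5; f <- 0.66
  brute <- {
    r <- rchisq(1e6, npop - 1)
    v <- f * (2 * 1 / (1 - f)) * r / (npop - 1)
    v / (v + 2 * 1)
  }
  q <- simulate_neutral_qst(f, n_pop = npop, v_a = 1, v_wp = 1,
                            n_sim = 1e5, seed = 44)
  qq <- quantile(q, c(0.05, 0.5, 0.95))
  bb <- quantile(brute, c(0.05, 0.5, 0.95))
  expect_true(all(abs(qq - bb) < 0.01))
})

test_that("raising F_ST stochastically increases neutral Q_ST", {
  qlo <- simulate_neutral_qst(0.2, 10, 1, 1, n_sim = 1e5, seed = 5)
  qhi <- simulate_neutral_qst(0.6, 10, 1, 1, n_sim = 1e5, seed = 5)
  gr <- seq(0.01, 0.99, by = 0.01)
  # first-order stochastic dominance on empirical CDFs
  expect_true(all(ecdf(qhi)(gr) <= ecdf(qlo)(gr) + 1e-3))
})

test_that("the difference test applies the CI-excludes-zero rule", {
  x <- runif(1000)
  t0 <- qst_fst_test(x, x)
  expect_true(all(t0$differences == 0))
  expect_equal(t0$verdict, "neutral")
  t_up <- qst_fst_test(x + 0.5, x)
  expect_equal(t_up$verdict, "directional")
  t_dn <- qst_fst_test(x - 0.5, x)
  expect_equal(t_dn$verdict, "stabilizing")
  expect_error(qst_fst_test(x, x[-1]), "length")
})

test_that("strong selection is detected with high power", {
  # among-population variance 10x the neutral expectation
  set.seed(61)
  hits <- vapply(1:30, function(i) {
    f <- 0.5
    des <- sim_design(n_pop = 20, lineage_sizes = 20,
                      families_range = c(4, 4), treatments = "T0",
                      treatment_mask = matrix(TRUE, 20, 1),
                      treatment_effects = 0, v_fxt = 0,
                      v_ap = 10 * f * 2 / (1 - f), v_wp = 1,
                      seed = 7000 + i)
    d <- simulate_phenotypes(des)
    est <- estimate_qst(d, "y", mode = "per_treatment", treatment = "T0",
                        n_iter = 1300, burn_in = 300, thin = 5,
                        seed = 7100 + i)
    qn <- simulate_neutral_qst(f, n_pop = 20, v_a = est$v_wp,
                               v_wp = est$v_wp, seed = 7200 + i)
    qst_fst_test(est$draws, qn)$verdict == "directional"
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("the suite runner recomputes subset F_ST and excludes small lineages", {
  des <- sim_design(n_pop = 8, lineage_sizes = c(5, 3), n_genotyped = 8,
                    treatment_mask = matrix(TRUE, 8, 3), seed = 9)
  gt <- simulate_genotypes(des)
  d <- simulate_phenotypes(des)
  res <- run_qstfst_suite(d, gt, traits_to_test = "y",
                          modes = c("across", "per_lineage"),
                          n_sim = 100, seed = 3,
                          n_iter = 600, burn_in = 100, thin = 5)
  # across + Eff1 only (Eff2 has 3 < 4 populations)
  expect_setequal(unique(res$subset), c("across", "Eff1"))
  expect_equal(res$n_pop[res$subset == "Eff1"], 5)
  expect_true(all(res$verdict %in% c("directional", "stabilizing",
                                     "neutral")))
  # deterministic under a fixed seed
  res2 <- run_qstfst_suite(d, gt, traits_to_test = "y",
                           modes = c("across", "per_lineage"),
                           n_sim = 100, seed = 3,
                           n_iter = 600, burn_in = 100, thin = 5)
  expect_identical(res, res2)
})
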