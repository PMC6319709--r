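test_that("Gibbs posterior medians agree with method-of-moments ANOVA components", {
  set.seed(101)
  k <- 50; n0 <- 20
  g <- rep(sprintf("g%02d", 1:k), each = n0)
  y <- rnorm(k, 0, sqrt(2))[as.integer(factor(g))] + rnorm(k * n0)
  d <- data.frame(g = g, y = y)
  mom <- anova_components_oneway(y, g)
  fit <- fit_lmm_gibbs(d, "y", random = "g", n_iter = 2600, burn_in = 600,
                       thin = 10, seed = 1)
  med <- apply(fit$sigma2, 2, median)
  expect_lt(abs(med["g"] - mom["between"]) / mom["between"], 0.15)
  expect_lt(abs(med["residual"] - mom["within"]) / mom["within"], 0.15)
})

test_that("a null group structure concentrates the group variance near zero", {
  set.seed(5)
  d <- data.frame(g = rep(sprintf("g%02d", 1:40), each = 20))
  d$y <- 5 + rnorm(800, 0, 0.1)           # equal means, tiny residual noise
  fit <- fit_lmm_gibbs(d, "y", random = "g", n_iter = 2600, burn_in = 600,
                       thin = 10, seed = 2)
  med <- apply(fit$sigma2, 2, median)
  expect_lt(med["g"], 0.05 * med["residual"])
})

test_that("chains are bit-identical under a fixed seed", {
  d <- simulate_phenotypes(sim_design(n_pop = 6, lineage_sizes = 6,
                                      seed = 3))
  f1 <- fit_lmm_gibbs(d, "y", fixed = "treatment",
                      random = c("population_id", "seed_family_id"),
                      n_iter = 500, burn_in = 100, thin = 4, seed = 99)
  f2 <- fit_lmm_gibbs(d, "y", fixed = "treatment",
                      random = c("population_id", "seed_family_id"),
                      n_iter = 500, burn_in = 100, thin = 4, seed = 99)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_identical(f1$beta, f2$beta)
})

test_that("aliased fixed effects are reported by name", {
  d <- data.frame(g = rep(c("a", "b"), each = 10),
                  x1 = rep(c(0, 1), each = 10))
  d$x2 <- d$x1
  d$y <- rnorm(20)
  expect_error(fit_lmm_gibbs(d, "y", fixed = c("x1", "x2"), random = "g"),
               "aliased.*x2")
})

test_that("REML equals closed-form ANOVA components on balanced data", {
  set.seed(77)
  k <- 40; n0 <- 12
  g <- rep(sprintf("g%02d", 1:k), each = n0)
  y <- rnorm(k, 0, 2)[as.integer(factor(g))] + rnorm(k * n0)
  mom <- anova_components_oneway(y, g)
  fit <- fit_lmm_reml(data.frame(g = g, y = y), "y", random = "g")
  expect_equal(unname(fit$varcomp["g"]), unname(mom["between"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$varcomp["residual"]), unname(mom["within"]),
               tolerance = 1e-6)
  # a zero generating component pushes REML to the boundary
  d0 <- data.frame(g = g, y = rnorm(k * n0))
  fit0 <- fit_lmm_reml(d0, "y", random = "g")
  expect_lt(fit0$varcomp["g"], 0.02)
})

test_that("REML and Gibbs agree on average across simulated datasets", {
  set.seed(13)
  rel <- replicate(25, {
    d <- simulate_phenotypes(sim_design(n_pop = 12, lineage_sizes = 12,
                                        families_range = c(4, 4),
                                        treatments = "T0",
                                        treatment_mask = matrix(TRUE, 12, 1),
                                        treatment_effects = 0, v_fxt = 0,
                                        seed = sample.int(1e6, 1)))
    g <- fit_lmm_gibbs(d, "y", random = c("population_id",
                                          "seed_family_id"),
                       n_iter = 1300, burn_in = 300, thin = 5,
                       seed = sample.int(1e6, 1))
    r <- fit_lmm_reml(d, "y", random = c("population_id",
                                         "seed_family_id"))
    gm <- median(g$sigma2[, "residual"])
    abs(gm - r$varcomp[["residual"]]) / r$varcomp[["residual"]]
  })
  expect_lt(mean(rel), 0.10)
})

test_that("post-hoc contrasts cover both engines and the degenerate factor", {
  d <- simulate_phenotypes(sim_design(n_pop = 8, lineage_sizes = 8,
                                      treatment_effects = c(0, 3, 6),
                                      seed = 8))
  r <- fit_lmm_reml(d, "y", fixed = "treatment",
                    random = c("population_id", "seed_family_id"))
  ct <- posthoc_contrasts(r, "treatment")
  expect_equal(nrow(ct), 3L)                    # 3 levels -> 3 pairs
  expect_true(all(ct$p_value <= 1))
  expect_lt(ct$p_value[ct$contrast == "T0 - T150"], 0.01)
  g <- fit_lmm_gibbs(d, "y", fixed = "treatment",
                     random = c("population_id", "seed_family_id"),
                     n_iter = 1300, burn_in = 300, thin = 5, seed = 4)
  cg <- posthoc_contrasts(g, "treatment")
  expect_equal(nrow(cg), 3L)
  big <- cg[grepl("T150", cg$contrast) & grepl("reference", cg$contrast), ]
  expect_true(big$ci_lo > 0 || big$ci_hi < 0)   # 6-SD effect detected
  # single-level factor: empty table
  d0 <- d[d$treatment == "T0", ]
  r0 <- fit_lmm_reml(d0, "y", random = c("population_id",
                                         "seed_family_id"))
  expect_equal(nrow(posthoc_contrasts(r0, "treatment")), 0L)
})
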