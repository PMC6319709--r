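test_that("unbiased gene diversity matches hand calculations and limits", {
  # monomorphic: He = 0
  mono <- genotype_table(matrix(120L, 4, 4), paste0("i", 1:4),
                         rep("A", 4), loci = c("l1", "l2"))
  expect_equal(expected_heterozygosity(mono)$he$He, 0)
  # one locus, allele counts {A:6, B:2}, n = 4: (8/7) * (1 - 0.625)
  al <- rbind(c(1L, 1L), c(1L, 1L), c(1L, 1L), c(2L, 2L))
  gt <- genotype_table(al, paste0("i", 1:4), rep("A", 4), loci = "l1")
  expect_equal(expected_heterozygosity(gt)$he$He, 8 / 7 * (1 - 0.625),
               tolerance = 1e-12)
  # two equifrequent alleles, large n: He -> 0.5
  n <- 5000
  al2 <- cbind(rep(1:2, n / 2), rep(2:1, n / 2))
  big <- genotype_table(al2, paste0("i", 1:n), rep("A", n), loci = "l1")
  expect_equal(expected_heterozygosity(big)$he$He, 0.5, tolerance = 1e-3)
})

test_that("He excludes loci untyped in a population and warns when nothing is typed", {
  al <- rbind(c(1L, 2L, NA, NA),
              c(1L, 1L, NA, NA),
              c(1L, 2L, 3L, 4L),
              c(2L, 2L, 3L, 3L))
  gt <- genotype_table(al, paste0("i", 1:4), c("A", "A", "B", "B"),
                       loci = c("l1", "l2"))
  div <- expected_heterozygosity(gt)
  expect_equal(div$he$n_loci_used, c(1L, 2L))
  expect_false(is.na(div$he$He[1]))
})

test_that("theta has the textbook degenerate values", {
  # identical frequencies, large n: theta ~ 0
  set.seed(7)
  n <- 200
  draw <- function() cbind(sample(1:4, n, TRUE), sample(1:4, n, TRUE))
  al4 <- cbind(rbind(draw(), draw()), rbind(draw(), draw()),
               rbind(draw(), draw()), rbind(draw(), draw()))
  gt4 <- genotype_table(al4, paste0("i", 1:(2 * n)),
                        rep(c("A", "B"), each = n))
  expect_lt(abs(fst(gt4)$value), 0.02)
  # alternative fixation at every locus: theta = 1
  gtf <- genotype_table(cbind(rep(c(1L, 2L), each = 6),
                              rep(c(1L, 2L), each = 6),
                              rep(c(3L, 4L), each = 6),
                              rep(c(3L, 4L), each = 6)),
                        paste0("i", 1:12), rep(c("A", "B"), each = 6),
                        loci = c("l1", "l2"))
  expect_equal(fst(gtf)$value, 1)
})

test_that("theta equals the manual variance-component oracle on a biallelic toy", {
  # pop1: 8 AA + 2 AB; pop2: 2 AA + 8 BB -- two iid copies of the locus so
  # the >= 2 polymorphic loci requirement is met without changing theta
  one_pop <- function(geno) do.call(rbind, geno)
  p1 <- rbind(matrix(rep(c(1L, 1L), 8), ncol = 2, byrow = TRUE),
              matrix(rep(c(1L, 2L), 2), ncol = 2, byrow = TRUE))
  p2 <- rbind(matrix(rep(c(1L, 1L), 2), ncol = 2, byrow = TRUE),
              matrix(rep(c(2L, 2L), 8), ncol = 2, byrow = TRUE))
  al <- rbind(p1, p2)
  gt <- genotype_table(cbind(al, al), paste0("i", 1:20),
                       rep(c("A", "B"), each = 10), loci = c("l1", "l2"))
  # oracle: p(A) = 18/20 and 4/20; het proportions 0.2 and 0
  oracle <- wc_theta_biallelic_2pop(10, 10, 0.9, 0.2, 0.2, 0)
  expect_equal(fst(gt)$value, oracle, tolerance = 1e-12)
})

test_that("He and theta are invariant to individual order; pairwise matrix is symmetric", {
  gt <- simulate_genotypes(sim_design(n_pop = 4, lineage_sizes = 4,
                                      n_genotyped = 8, seed = 5))
  set.seed(9)
  perm <- sample(n_individuals(gt))
  gtp <- genotype_table(gt$alleles[perm, ], gt$individual_id[perm],
                        gt$population_id[perm], gt$loci)
  expect_equal(fst(gt)$value, fst(gtp)$value)
  he1 <- expected_heterozygosity(gt)$he
  he2 <- expected_heterozygosity(gtp)$he
  expect_equal(he1$He[order(he1$population_id)],
               he2$He[order(he2$population_id)])
  pw <- pairwise_fst(gt)
  expect_equal(pw, t(pw))
  expect_equal(unname(diag(pw)), rep(0, 4))
})

test_that("theta recovers the generating island-model differentiation", {
  set.seed(31)
  est <- vapply(1:30, function(i)
    fst(simulate_genotypes(sim_design(seed = 1000 + i)))$value, numeric(1))
  expect_lt(abs(mean(est) - 0.66), 0.03)
})

test_that("the Nei GST variant and hierarchical F_CT behave sensibly", {
  gt <- simulate_genotypes(sim_design(n_pop = 6, lineage_sizes = c(3, 3),
                                      seed = 12))
  g_gst <- fst(gt, method = "gst")$value
  g_th <- fst(gt)$value
  expect_gt(g_gst, 0.3); expect_gt(g_th, 0.3)   # both register structure
  lin <- rep(c("L1", "L2"), each = 3 * 10)
  h <- hierarchical_fst(gt, lin)
  expect_true(is.finite(h$f_ct))
  expect_true(h$f_sc > 0.3)   # strong within-lineage population structure
  # guards
  expect_error(fst(gt, group = rep("g", n_individuals(gt))), ">= 2 groups")
})
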