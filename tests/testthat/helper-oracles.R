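# Independent oracles used across the suite.  Each reimplements the target
# quantity by the most direct route available (method-of-moments ANOVA,
# textbook component formulas, brute-force enumeration) so that the package
# code path is never checked against itself.

# balanced one-way ANOVA variance components (method of moments)
anova_components_oneway <- function(y, group) {
  group <- factor(group)
  k <- nlevels(group)
  n0 <- length(y) / k
  gm <- tapply(y, group, mean)
  msb <- n0 * sum((gm - mean(y))^2) / (k - 1)
  msw <- sum((y - gm[group])^2) / (length(y) - k)
  c(between = (msb - msw) / n0, within = msw)
}

# balanced two-level nested ANOVA (populations / families / residual)
anova_components_nested <- function(y, pop, fam) {
  pop <- factor(pop); fam <- factor(fam)
  a <- nlevels(pop)
  b <- nlevels(fam) / a            # families per population
  n <- length(y) / nlevels(fam)    # obs per family
  pm <- tapply(y, pop, mean); fm <- tapply(y, fam, mean)
  fam_pop <- tapply(as.character(pop), fam, function(v) v[1])
  ss_pop <- b * n * sum((pm - mean(y))^2)
  ss_fam <- n * sum((fm - pm[fam_pop])^2)
  ss_res <- sum((y - fm[fam])^2)
  ms_pop <- ss_pop / (a - 1)
  ms_fam <- ss_fam / (a * (b - 1))
  ms_res <- ss_res / (length(y) - a * b)
  c(pop = (ms_pop - ms_fam) / (b * n),
    fam = (ms_fam - ms_res) / n,
    res = ms_res)
}

# Weir-Cockerham theta for one biallelic locus and two populations,
# written out term by term from the component definitions
wc_theta_biallelic_2pop <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  n_i <- c(n1, n2); p_i <- c(p1, p2); h_i <- c(h1, h2)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  theta_num <- 0; theta_den <- 0
  for (allele in 1:2) {
    pa <- if (allele == 1) p_i else 1 - p_i
    pbar <- sum(n_i * pa) / (r * nbar)
    s2 <- sum(n_i * (pa - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    theta_num <- theta_num + a
    theta_den <- theta_den + a + b + cc
  }
  theta_num / theta_den
}

# Procrustes residual after optimal rotation/reflection/translation
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  sum((Xc - Yc %*% R)^2)
}

# small genotype table built by hand
toy_genotypes <- function() {
  al <- rbind(c(120L, 120L, 200L, 204L),
              c(120L, 122L, 200L, 200L),
              c(122L, 122L, 204L, 204L),
              c(120L, 120L, 200L, 200L))
  genotype_table(al, paste0("i", 1:4), c("A", "A", "B", "B"),
                 loci = c("locA", "locB"))
}
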