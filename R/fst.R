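#' Multilocus F-statistics for codominant genotypes
#'
#' Weir-Cockerham theta by the ratio of summed variance components over
#' loci and alleles (never a mean of per-locus ratios), the estimator used
#' by FSTAT-style software.  A Nei/Chesser GST variant is available for
#' sensitivity analyses.  Loci monomorphic across the groups compared are
#' dropped (they contribute no variance components); negative per-locus
#' components are retained in the ratio of sums, and small negative
#' multilocus estimates are reported as computed.
#'
#' @param gt a [genotype_table()].
#' @param group grouping vector, one entry per individual; defaults to the
#'   table's population labels.  Pass a lineage label per individual to get
#'   a pooled between-lineage estimate.
#' @param method `"theta"` (Weir-Cockerham, default) or `"gst"`
#'   (Nei gene-diversity partition, unweighted mean frequencies).
#' @param scope free-text label stored with the result.
#' @return object of class `fst_estimate`: list with `value` (multilocus
#'   estimate), `method`, `scope`, `per_locus` (data frame of per-locus
#'   components and estimates), `sd` (SD of per-locus estimates), and
#'   `n_loci` used.
#' @examples
#' gt <- simulate_genotypes(sim_design(n_pop = 4, seed = 1))
#' fst(gt)
#' @export
fst <- function(gt, group = NULL, method = c("theta", "gst"),
                scope = "populations") {
  method <- match.arg(method)
  if (is.null(group)) group <- gt$population_id
  group <- as.character(group)
  stopifnot(length(group) == n_individuals(gt))
  tab <- table(group)
  if (length(tab) < 2L) stop("need >= 2 groups, got ", length(tab))
  if (any(tab < 2L))
    stop("groups with < 2 individuals: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  per <- lapply(gt$loci, function(l)
    locus_components(locus_alleles(gt, l), group, method))
  keep <- !vapply(per, is.null, logical(1))
  if (sum(keep) < 2L)
    stop("fewer than 2 polymorphic loci across the groups compared")
  pl <- do.call(rbind, per[keep])
  pl$locus <- gt$loci[keep]
  if (method == "theta") {
    value <- sum(pl$a) / sum(pl$a + pl$b + pl$c)
    pl$estimate <- pl$a / (pl$a + pl$b + pl$c)
  } else {
    value <- sum(pl$ht - pl$hs) / sum(pl$ht)
    pl$estimate <- (pl$ht - pl$hs) / pl$ht
  }
  structure(list(value = value, method = method, scope = scope,
                 per_locus = pl[c("locus", setdiff(names(pl), "locus"))],
                 sd = stats::sd(pl$estimate), n_loci = nrow(pl)),
            class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("F_ST (%s, %s): %.4f  (per-locus SD %.3f, %d loci)\n",
              x$method, x$scope, x$value, x$sd, x$n_loci))
  invisible(x)
}

# Weir-Cockerham a/b/c (or Nei/Chesser Ht/Hs) for one locus.
# A: n x 2 allele matrix; returns NULL for monomorphic/unusable loci.
locus_components <- function(A, group, method = "theta") {
  ok <- !is.na(A[, 1]) & !is.na(group)
  A <- A[ok, , drop = FALSE]
  g <- factor(group[ok])
  g <- droplevels(g)
  n_i <- as.vector(table(g))
  if (length(n_i) < 2L) return(NULL)
  alleles <- sort(unique(c(A[, 1], A[, 2])))
  if (length(alleles) < 2L) return(NULL)          # monomorphic
  af <- factor(c(A[, 1], A[, 2]), levels = alleles)
  counts <- table(rep(g, 2), af)                  # pop x allele copy counts
  r <- length(n_i)
  nbar <- mean(n_i)
  if (nbar <= 1) return(NULL)
  p <- counts / (2 * n_i)
  if (method == "gst") {
    # classic Nei gene-diversity partition with unweighted mean frequencies
    hs <- mean(1 - rowSums(p^2))
    pbar_u <- colMeans(p)
    ht <- 1 - sum(pbar_u^2)
    return(data.frame(ht = ht, hs = hs))
  }
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(counts) / (2 * r * nbar)
  s2 <- colSums(n_i * (sweep(p, 2, pbar))^2) / ((r - 1) * nbar)
  hets <- het_counts(A, g, alleles)               # pop x allele: single-copy
  hbar <- colSums(hets) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  data.frame(a = sum(a), b = sum(b), c = sum(cc))
}

# per-pop count of heterozygous individuals carrying each allele once
het_counts <- function(A, g, alleles) {
  hh <- A[, 1] != A[, 2]
  m <- matrix(0, nlevels(g), length(alleles),
              dimnames = list(levels(g), alleles))
  if (any(hh)) {
    t <- table(factor(rep(g[hh], 2), levels = levels(g)),
               factor(c(A[hh, 1], A[hh, 2]), levels = alleles))
    m <- m + unclass(t)
  }
  m
}

#' Pairwise population F_ST matrix
#'
#' Weir-Cockerham theta for every pair of populations.
#'
#' @inheritParams fst
#' @return symmetric zero-diagonal matrix of pairwise estimates.
#' @export
pairwise_fst <- function(gt, method = c("theta", "gst")) {
  method <- match.arg(method)
  pops <- populations(gt)
  n <- length(pops)
  m <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sub <- subset_populations(gt, pops[c(i, j)])
    est <- tryCatch(fst(sub, method = method,
                        scope = paste(pops[i], pops[j], sep = "-"))$value,
                    error = function(e) NA_real_)
    m[i, j] <- m[j, i] <- est
  }
  m
}

#' Hierarchical differentiation among groups of populations
#'
#' Nested analysis of variance of allele-copy indicators (groups /
#' populations within groups / copies within populations), summed over
#' alleles and loci.  Returns the among-group fixation index
#' `F_CT = s2_a / (s2_a + s2_b + s2_c)` alongside the raw components,
#' as the population-structure-aware alternative to pooling individuals
#' per group in [fst()].
#'
#' @param gt a [genotype_table()].
#' @param group group (e.g. lineage) label per individual.
#' @return list with `f_ct`, `f_sc`, and the summed variance components.
#' @export
hierarchical_fst <- function(gt, group) {
  group <- as.character(group)
  stopifnot(length(group) == n_individuals(gt))
  comp <- c(a = 0, b = 0, c = 0)
  for (l in gt$loci) {
    A <- locus_alleles(gt, l)
    ok <- !is.na(A[, 1])
    A <- A[ok, , drop = FALSE]
    gr <- factor(group[ok])
    pp <- factor(gt$population_id[ok])
    x <- c(A[, 1], A[, 2])
    grc <- rep(gr, 2); ppc <- rep(pp, 2)
    alleles <- sort(unique(x))
    if (length(alleles) < 2) next
    N <- length(x)
    Np <- as.vector(table(ppc)); names(Np) <- levels(ppc)
    Ng <- as.vector(table(grc)); names(Ng) <- levels(grc)
    pop_group <- tapply(as.character(grc), ppc, function(v) v[1])
    P <- length(Np); G <- length(Ng)
    if (G < 2 || P <= G) next
    sumNp2_by_g <- tapply(Np^2, pop_group, sum)[names(Ng)]
    n1 <- (N - sum(sumNp2_by_g / Ng)) / (P - G)
    n2 <- (sum(sumNp2_by_g / Ng) - sum(Np^2) / N) / (G - 1)
    n3 <- (N - sum(Ng^2) / N) / (G - 1)
    for (u in alleles) {
      ind <- as.numeric(x == u)
      pT <- mean(ind)
      pg <- tapply(ind, grc, mean)
      pp_m <- tapply(ind, ppc, mean)
      ss_wp <- sum(Np * pp_m * (1 - pp_m))
      ss_ap <- sum(Np * (pp_m - pg[pop_group[names(Np)]])^2)
      ss_ag <- sum(Ng * (pg - pT)^2)
      ms_wp <- ss_wp / (N - P)
      ms_ap <- ss_ap / (P - G)
      ms_ag <- ss_ag / (G - 1)
      s2c <- ms_wp
      s2b <- (ms_ap - s2c) / n1
      s2a <- (ms_ag - s2c - n2 * s2b) / n3
      comp <- comp + c(a = s2a, b = s2b, c = s2c)
    }
  }
  tot <- sum(comp)
  list(f_ct = comp[["a"]] / tot,
       f_sc = comp[["b"]] / (comp[["b"]] + comp[["c"]]),
       components = comp)
}
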