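#' Squared codominant genotypic distance between individuals
#'
#' Per-locus squared genotype distance in the Smouse-Peakall scheme
#' (0 identical genotypes; 1 one allele shared with a heterozygote; up to 4
#' for opposite homozygotes), summed over loci shared by each pair.
#' Writing a genotype as its allele-count vector `y` (entries sum to 2),
#' the per-locus value is `0.5 * sum((y1 - y2)^2)`, which reproduces the
#' full scheme table.
#'
#' @param gt a [genotype_table()].
#' @return symmetric zero-diagonal individual x individual matrix of summed
#'   squared distances.  Pairs sharing no genotyped locus get `NA` with a
#'   warning.
#' @export
genotypic_distance <- function(gt) {
  n <- n_individuals(gt)
  D <- matrix(0, n, n, dimnames = list(gt$individual_id, gt$individual_id))
  shared <- matrix(0L, n, n)
  for (l in gt$loci) {
    A <- locus_alleles(gt, l)
    ok <- !is.na(A[, 1])
    alleles <- sort(unique(c(A[ok, 1], A[ok, 2])))
    if (!length(alleles)) next
    Y <- matrix(0, n, length(alleles))
    Y[cbind(seq_len(n), match(A[, 1], alleles))] <- 1
    i2 <- match(A[, 2], alleles)
    Y[cbind(seq_len(n), i2)] <- Y[cbind(seq_len(n), i2)] + 1
    Y[!ok, ] <- NA
    # 0.5 * squared Euclidean distance between allele-count vectors
    G <- tcrossprod(Y)
    sq <- rowSums(Y^2)
    dl <- 0.5 * (outer(sq, sq, "+") - 2 * G)
    okm <- outer(ok, ok, "&")
    D[okm] <- D[okm] + dl[okm]
    shared <- shared + okm
  }
  none <- shared == 0L & row(D) != col(D)
  if (any(none)) {
    warning(sum(none) / 2, " individual pair(s) share no genotyped locus",
            call. = FALSE)
    D[none] <- NA_real_
  }
  diag(D) <- 0
  D
}

#' Principal coordinate analysis (metric multidimensional scaling)
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition.
#' Axes are ordered by eigenvalue; negative eigenvalues (possible for
#' non-Euclidean inputs) are reported, not dropped, and the percentage of
#' variance is taken over the positive eigenvalues.
#'
#' @param d symmetric zero-diagonal distance matrix.
#' @param squared set `TRUE` when `d` already holds squared distances
#'   (e.g. the output of [genotypic_distance()]).
#' @return list with `scores` (rows = objects, columns = axes scaled by
#'   `sqrt(eigenvalue)` for positive axes), `eigenvalues`, and
#'   `pct_variance` (percent of positive eigenvalue mass per axis).
#' @export
pcoa <- function(d, squared = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d)), na.rm = TRUE) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(is.na(d))) stop("distance matrix contains missing entries")
  n <- nrow(d)
  A <- -0.5 * (if (squared) d else d^2)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > .Machine$double.eps^0.5 * max(abs(e$values), 1)
  scores <- matrix(0, n, n, dimnames = list(rownames(d), NULL))
  if (any(pos))
    scores[, which(pos)] <- e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), sum(pos))
  keep <- seq_len(max(which(pos), 1L))
  pct <- ifelse(e$values > 0, 100 * e$values / sum(e$values[e$values > 0]), 0)
  list(scores = scores[, keep, drop = FALSE],
       eigenvalues = e$values,
       pct_variance = pct)
}
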