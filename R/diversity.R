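#' Expected heterozygosity (unbiased gene diversity) per population
#'
#' Per locus and population, the small-sample-corrected gene diversity
#' `(2n / (2n - 1)) * (1 - sum(p^2))`, where `n` is the number of genotyped
#' diploid individuals and `p` the sample allele frequencies.  A
#' population's He is the mean over loci with at least one genotyped
#' individual; loci missing in all individuals of a population are excluded
#' from that population's statistics.
#'
#' @param gt a [genotype_table()].
#' @return object of class `diversity_result`: list with
#'   `he` (data frame `population_id`, `He`, `n_loci_used`),
#'   `per_locus` (population x locus He matrix), and
#'   `n` (population x locus matrix of genotyped sample sizes).
#' @export
expected_heterozygosity <- function(gt) {
  pops <- populations(gt)
  L <- n_loci(gt)
  heM <- matrix(NA_real_, length(pops), L, dimnames = list(pops, gt$loci))
  nM <- matrix(0L, length(pops), L, dimnames = list(pops, gt$loci))
  for (l in seq_len(L)) {
    A <- locus_alleles(gt, gt$loci[l])
    ok <- !is.na(A[, 1])
    for (p in pops) {
      rows <- ok & gt$population_id == p
      n <- sum(rows)
      nM[p, l] <- n
      if (n == 0L) next
      cnt <- table(c(A[rows, 1], A[rows, 2]))
      pr <- cnt / (2 * n)
      heM[p, l] <- (2 * n) / (2 * n - 1) * (1 - sum(pr^2))
    }
  }
  he <- data.frame(population_id = pops,
                   He = rowMeans(heM, na.rm = TRUE),
                   n_loci_used = rowSums(!is.na(heM)),
                   row.names = NULL, stringsAsFactors = FALSE)
  none <- he$n_loci_used == 0L
  if (any(none)) {
    he$He[none] <- NA_real_
    warning("no genotyped loci for: ",
            paste(pops[none], collapse = ", "), call. = FALSE)
  }
  structure(list(he = he, per_locus = heM, n = nM),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("Gene diversity (unbiased He) for", nrow(x$he), "populations; mean He =",
      round(mean(x$he$He, na.rm = TRUE), 3), "\n")
  print(x$he, ...)
  invisible(x)
}
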