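#' Codominant multilocus genotype table
#'
#' Container for diploid codominant genotypes (e.g. microsatellite fragment
#' lengths) with population labels.  Alleles are stored as an integer matrix
#' with two columns per locus; missing allele calls are `NA`.
#'
#' @param alleles integer matrix, one row per individual and two columns per
#'   locus (columns `<locus>.1`, `<locus>.2`).  Missing calls are `NA`.
#' @param individual_id character vector of unique individual labels.
#' @param population_id character vector (or factor) of population labels,
#'   one per individual.
#' @param loci character vector of locus names; defaults to names recovered
#'   from the column names of `alleles`.
#'
#' @return An object of class `genotype_table`: a list with elements
#'   `alleles`, `individual_id`, `population_id`, `loci`.
#' @examples
#' al <- rbind(c(120L, 122L, 200L, 200L),
#'             c(120L, 120L, 200L, 204L))
#' gt <- genotype_table(al, c("i1", "i2"), c("P1", "P1"),
#'                      loci = c("locA", "locB"))
#' n_loci(gt)
#' @export
genotype_table <- function(alleles, individual_id, population_id, loci = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) %% 2L != 0L)
    stop("allele matrix must have an even number of columns (2 per locus)")
  nl <- ncol(alleles) / 2L
  if (is.null(loci)) {
    cn <- colnames(alleles)
    loci <- if (is.null(cn)) paste0("L", seq_len(nl)) else
      unique(sub("\\.[12]$", "", cn))
  }
  if (length(loci) != nl)
    stop("number of locus names (", length(loci),
         ") does not match allele columns / 2 (", nl, ")")
  individual_id <- as.character(individual_id)
  population_id <- as.character(population_id)
  if (length(individual_id) != nrow(alleles) ||
      length(population_id) != nrow(alleles))
    stop("individual_id and population_id must match the number of rows")
  if (anyDuplicated(individual_id))
    stop("duplicate individual ids: ",
         paste(unique(individual_id[duplicated(individual_id)]), collapse = ", "))
  colnames(alleles) <- paste(rep(loci, each = 2L), 1:2, sep = ".")
  rownames(alleles) <- individual_id
  # a slot with exactly one NA allele is ambiguous; treat the locus as missing
  for (l in seq_len(nl)) {
    cols <- c(2L * l - 1L, 2L * l)
    half <- xor(is.na(alleles[, cols[1]]), is.na(alleles[, cols[2]]))
    if (any(half)) alleles[half, cols] <- NA_integer_
  }
  structure(list(alleles = alleles, individual_id = individual_id,
                 population_id = population_id, loci = loci),
            class = "genotype_table")
}

#' @rdname genotype_table
#' @param x a `genotype_table`.
#' @export
n_loci <- function(x) length(x$loci)

#' @rdname genotype_table
#' @export
n_individuals <- function(x) nrow(x$alleles)

#' @rdname genotype_table
#' @export
populations <- function(x) unique(x$population_id)

#' Subset a genotype table by population
#'
#' @param x a `genotype_table`.
#' @param pops character vector of population ids to keep.
#' @return a `genotype_table` restricted to `pops`.
#' @export
subset_populations <- function(x, pops) {
  keep <- x$population_id %in% pops
  if (!any(keep)) stop("no individuals in requested populations")
  genotype_table(x$alleles[keep, , drop = FALSE], x$individual_id[keep],
                 x$population_id[keep], x$loci)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", n_individuals(x), "individuals,",
      n_loci(x), "loci,", length(populations(x)), "populations\n")
  miss <- mean(is.na(x$alleles))
  cat(sprintf("  missing allele calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

# allele matrix for one locus (n x 2)
locus_alleles <- function(x, locus) {
  l <- match(locus, x$loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  x$alleles[, c(2L * l - 1L, 2L * l), drop = FALSE]
}
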