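#' Read codominant genotypes from standard text formats
#'
#' Supports a GenAlEx-style CSV layout (three header rows, two columns per
#' locus) and the two-row-per-individual STRUCTURE text format.  Missing
#' allele codes `0` and `-9` are both accepted on input and normalised to
#' `NA` internally, since the two dialects disagree on the sentinel.
#'
#' @param path path to the genotype file.
#' @param format `"genalex"` or `"structure"`.
#' @param missing_codes integer allele codes to treat as missing.
#' @return a [genotype_table()].
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("genalex", "structure"),
                           missing_codes = c(0L, -9L)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         genalex = read_genalex(path, missing_codes),
         structure = read_structure(path, missing_codes))
}

#' Write codominant genotypes
#'
#' @param x a [genotype_table()].
#' @param path output file path.
#' @param format `"genalex"` or `"structure"`.
#' @param missing_code sentinel written for missing alleles (`0` for the
#'   GenAlEx dialect, `-9` for STRUCTURE, by convention).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, format = c("genalex", "structure"),
                            missing_code = NULL) {
  format <- match.arg(format)
  if (is.null(missing_code))
    missing_code <- if (format == "genalex") 0L else -9L
  switch(format,
         genalex = write_genalex(x, path, missing_code),
         structure = write_structure(x, path, missing_code))
  invisible(path)
}

read_genalex <- function(path, missing_codes) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", blank.lines.skip = FALSE)
  if (nrow(raw) < 4L) stop("GenAlEx file too short: ", path)
  nl <- as.integer(raw[1, 1]); ni <- as.integer(raw[1, 2])
  if (is.na(nl) || is.na(ni))
    stop("line 1: expected numeric locus and sample counts")
  loci <- as.character(raw[3, seq(3, by = 2, length.out = nl)])
  loci <- trimws(loci)
  body <- raw[seq(4, length.out = ni), , drop = FALSE]
  need <- 2L + 2L * nl
  if (ncol(body) < need)
    stop("data rows have ", ncol(body), " columns; expected >= ", need)
  extra <- body[, -seq_len(need), drop = FALSE]
  if (ncol(extra) && any(nzchar(trimws(unlist(extra)))))
    stop("unexpected trailing values beyond ", need, " columns")
  ind <- trimws(body[, 1]); pop <- trimws(body[, 2])
  al <- suppressWarnings(
    matrix(as.integer(as.matrix(body[, 2L + seq_len(2L * nl)])), nrow = ni))
  bad <- which(!nzchar(ind) | !nzchar(pop))
  if (length(bad))
    stop("line ", 3L + bad[1], ": empty individual or population id")
  al[al %in% missing_codes] <- NA_integer_
  genotype_table(al, ind, pop, loci)
}

write_genalex <- function(x, path, missing_code) {
  nl <- n_loci(x); ni <- n_individuals(x)
  pops <- populations(x)
  sizes <- as.integer(table(factor(x$population_id, levels = pops)))
  pad <- function(v, n) c(v, rep("", n - length(v)))
  w <- 2L + 2L * nl
  l1 <- pad(c(nl, ni, length(pops), sizes), w)
  l2 <- pad(c("qstkit genotype export", "", "", pops), w)
  l3 <- pad(c("Ind", "Pop", as.vector(rbind(x$loci, ""))), w)
  al <- x$alleles
  al[is.na(al)] <- missing_code
  body <- cbind(x$individual_id, x$population_id, al)
  m <- rbind(l1, l2, l3, body)
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

read_structure <- function(path, missing_codes) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  tok <- strsplit(trimws(lines), "[ \t]+")
  # optional header line of locus names (non-numeric beyond the first field)
  first <- tok[[1]]
  has_header <- all(is.na(suppressWarnings(as.integer(first[-1])))) ||
    length(first) < 3L
  loci <- NULL
  if (has_header) {
    loci <- first
    tok <- tok[-1]
  }
  if (length(tok) %% 2L != 0L)
    stop("odd number of data lines (", length(tok),
         "): two rows per individual expected")
  nfield <- lengths(tok)
  if (length(unique(nfield)) != 1L)
    stop("line ", which(nfield != nfield[1])[1] + has_header,
         ": ragged row length")
  nl <- nfield[1] - 2L
  if (nl < 1L) stop("no locus columns found")
  if (is.null(loci)) loci <- paste0("L", seq_len(nl))
  if (length(loci) == nl + 2L) loci <- loci[-(1:2)]  # "ind pop" prefix style
  if (length(loci) != nl)
    stop("locus header names ", length(loci), " loci but rows carry ", nl)
  m <- do.call(rbind, tok)
  odd <- seq(1, nrow(m), by = 2); even <- odd + 1L
  if (any(m[odd, 1] != m[even, 1]))
    stop("line ", 2 * which(m[odd, 1] != m[even, 1])[1] - 1 + has_header,
         ": the two rows of an individual carry different ids")
  ind <- m[odd, 1]; pop <- m[odd, 2]
  a1 <- suppressWarnings(matrix(as.integer(m[odd, -(1:2)]), ncol = nl))
  a2 <- suppressWarnings(matrix(as.integer(m[even, -(1:2)]), ncol = nl))
  al <- matrix(NA_integer_, nrow = length(ind), ncol = 2L * nl)
  al[, seq(1, 2L * nl, 2)] <- a1
  al[, seq(2, 2L * nl, 2)] <- a2
  al[al %in% missing_codes] <- NA_integer_
  genotype_table(al, ind, pop, loci)
}

write_structure <- function(x, path, missing_code) {
  nl <- n_loci(x)
  al <- x$alleles
  al[is.na(al)] <- missing_code
  a1 <- al[, seq(1, 2L * nl, 2), drop = FALSE]
  a2 <- al[, seq(2, 2L * nl, 2), drop = FALSE]
  rows <- character(2L * n_individuals(x))
  for (i in seq_len(n_individuals(x))) {
    pre <- c(x$individual_id[i], x$population_id[i])
    rows[2 * i - 1] <- paste(c(pre, a1[i, ]), collapse = "\t")
    rows[2 * i]     <- paste(c(pre, a2[i, ]), collapse = "\t")
  }
  writeLines(c(paste(c("ind", "pop", x$loci), collapse = "\t"), rows), path)
}
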