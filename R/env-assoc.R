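#' PCA of standardized soil variables
#'
#' Standardizes each soil variable to mean 0 / SD 1 (dropping constant
#' columns with a warning, since they cannot be standardized) and performs
#' a PCA, i.e. the eigendecomposition of the correlation matrix.
#'
#' @param soil data frame with `population_id` and numeric soil variable
#'   columns; rows with missing values are dropped (listwise).
#' @return object of class `soil_pca`: list with `scores` (populations x
#'   axes), `loadings`, `pct_variance` (sums to 100), `sdev`, and the
#'   variables used.
#' @export
soil_pca <- function(soil) {
  stopifnot("population_id" %in% names(soil))
  vars <- names(soil)[vapply(soil, is.numeric, logical(1))]
  vars <- setdiff(vars, c("latitude", "longitude", "n_points"))
  if (length(vars) < 2) stop("need >= 2 numeric soil variables")
  cc <- stats::complete.cases(soil[vars])
  d <- soil[cc, , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 populations after listwise deletion")
  sds <- vapply(d[vars], stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("dropping constant soil variable(s): ",
            paste(vars[sds == 0], collapse = ", "), call. = FALSE)
    vars <- vars[sds > 0]
    if (length(vars) < 2) stop("fewer than 2 variable remain")
  }
  pc <- stats::prcomp(d[vars], center = TRUE, scale. = TRUE)
  scores <- pc$x
  rownames(scores) <- d$population_id
  structure(list(scores = scores, loadings = pc$rotation,
                 pct_variance = 100 * pc$sdev^2 / sum(pc$sdev^2),
                 sdev = pc$sdev, variables = vars,
                 population_id = d$population_id),
            class = "soil_pca")
}

#' @export
print.soil_pca <- function(x, ...) {
  cat("Soil PCA:", length(x$variables), "variables,",
      nrow(x$scores), "populations\n")
  cat("  % variance:",
      paste(sprintf("PC%d %.1f", seq_len(min(4, length(x$pct_variance))),
                    x$pct_variance[seq_len(min(4, length(x$pct_variance)))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise environmental distance between populations
#'
#' Euclidean distances over standardized (z-scored) soil variables.
#' Missing values are handled pairwise-complete (scaled by the number of
#' shared variables) with a warning.
#'
#' @inheritParams soil_pca
#' @return symmetric zero-diagonal population x population matrix.
#' @export
environmental_distance <- function(soil) {
  stopifnot("population_id" %in% names(soil))
  vars <- names(soil)[vapply(soil, is.numeric, logical(1))]
  vars <- setdiff(vars, c("latitude", "longitude", "n_points"))
  z <- scale(as.matrix(soil[vars]))
  z <- z[, !apply(z, 2, function(c) all(is.na(c))), drop = FALSE]
  n <- nrow(z); V <- ncol(z)
  if (anyNA(z))
    warning("missing soil values: using pairwise-complete variables",
            call. = FALSE)
  m <- matrix(0, n, n,
              dimnames = list(soil$population_id, soil$population_id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d2 <- (z[i, ] - z[j, ])^2
    ok <- !is.na(d2)
    m[i, j] <- m[j, i] <-
      if (any(ok)) sqrt(sum(d2[ok]) * V / sum(ok)) else NA_real_
  }
  m
}

#' Correlation between population diversity and an environmental axis
#'
#' Pearson correlation with the usual two-sided t-test, e.g. expected
#' heterozygosity against soil PC1 scores.
#'
#' @param he numeric vector (e.g. per-population He).
#' @param pc numeric vector of the same length (e.g. PC1 scores).
#' @return list with `r`, `p_value`, `n`, and the `htest` object.
#' @export
he_env_correlation <- function(he, pc) {
  if (length(he) != length(pc)) stop("vectors differ in length")
  ok <- stats::complete.cases(he, pc)
  if (sum(ok) < 3) stop("need >= 3 complete pairs")
  if (stats::sd(he[ok]) == 0 || stats::sd(pc[ok]) == 0)
    stop("zero variance: correlation undefined")
  ht <- stats::cor.test(he[ok], pc[ok])
  list(r = unname(ht$estimate), p_value = ht$p.value, n = sum(ok),
       test = ht)
}

#' Trait-environment cline model
#'
#' Mixed model relating individual trait values to a population-level
#' environmental axis (soil PC score).  Default ("overall") form: PC score
#' and treatment fixed; lineage, population and seed family random.  The
#' per-treatment form uses PC score, lineage and their interaction as
#' fixed effects with population and seed family random, fitted to one
#' treatment's observations.
#'
#' @param traits trait table (long format, one row per individual).
#' @param trait trait column name.
#' @param scores named numeric vector of PC scores (names = population
#'   ids), e.g. one column of `soil_pca()$scores`.
#' @param form `"overall"` or `"per_treatment"`.
#' @param treatment treatment level when `form = "per_treatment"`.
#' @param seed_mass optional named numeric vector of population mean seed
#'   mass/volume used as a covariate.
#' @return list with `slope` (PC coefficient), `anova` (Wald tests,
#'   the PC-score row carrying the cline test), and the `lmm_reml` fit.
#' @export
trait_env_model <- function(traits, trait, scores,
                            form = c("overall", "per_treatment"),
                            treatment = NULL, seed_mass = NULL) {
  form <- match.arg(form)
  d <- traits[!is.na(traits[[trait]]), , drop = FALSE]
  d$pc_score <- unname(scores[as.character(d$population_id)])
  if (all(is.na(d$pc_score))) stop("no PC scores match the populations")
  d <- d[!is.na(d$pc_score), , drop = FALSE]
  if (stats::sd(d$pc_score) == 0)
    stop("all populations share one PC value: slope aliased")
  fixed <- "pc_score"
  random <- c("population_id", "seed_family_id")
  if (form == "overall") {
    fixed <- c("pc_score", "treatment")
    if ("lineage" %in% names(d) &&
        length(unique(stats::na.omit(d$lineage))) > 1)
      random <- c("lineage", random)
  } else {
    if (is.null(treatment)) stop("treatment level required")
    d <- d[d$treatment == treatment, , drop = FALSE]
    if (!nrow(d)) stop("no observations for treatment ", treatment)
    if ("lineage" %in% names(d) &&
        length(unique(stats::na.omit(d$lineage))) > 1)
      fixed <- c("pc_score", "lineage", "pc_score:lineage")
  }
  if (!is.null(seed_mass)) {
    d$seed_mass <- unname(seed_mass[as.character(d$population_id)])
    fixed <- c(fixed, "seed_mass")
  }
  fit <- fit_lmm_reml(d, trait, fixed = fixed, random = random)
  list(slope = unname(fit$fixef["pc_score"]), anova = fit$anova, fit = fit)
}
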