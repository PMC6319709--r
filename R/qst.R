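#' Quantitative trait differentiation from variance components
#'
#' `Q_ST = V_AP / (V_AP + 2 V_WP)`, with `V_AP` the among-population and
#' `V_WP` the within-population (seed-family) additive variance.  The
#' factor 2 reflects that the family variance captures only part of the
#' within-population additive variance.
#'
#' @param v_ap,v_wp non-negative variance components (vectorised).
#' @return Q_ST value(s) in `[0, 1]`; `NA` where both components are 0.
#' @examples
#' qst_from_components(2, 1)  # 0.5
#' @export
qst_from_components <- function(v_ap, v_wp) {
  if (any(v_ap < 0, na.rm = TRUE) || any(v_wp < 0, na.rm = TRUE))
    stop("variance components must be non-negative")
  out <- v_ap / (v_ap + 2 * v_wp)
  both0 <- !is.na(v_ap) & !is.na(v_wp) & v_ap + v_wp == 0
  if (any(both0)) {
    out[both0] <- NA_real_
    warning("Q_ST undefined where both components are zero", call. = FALSE)
  }
  out
}

#' Posterior Q_ST estimation for a trait
#'
#' Fits the mode-appropriate nested mixed model by Gibbs sampling and
#' transforms each retained draw of the population and seed-family
#' variances into a Q_ST draw.  Three modes:
#'
#' * `"across"` -- all data; treatment fixed; population, seed family
#'   (and, by default, family x treatment) random;
#' * `"per_treatment"` -- observations of one treatment; intercept-only
#'   fixed part; population and seed family random;
#' * `"per_lineage"` -- observations of one lineage (>= 4 populations
#'   required); treatment fixed; population and seed family random.
#'
#' `V_WP` is the seed-family component only; the family x treatment
#' variance, when modelled, is deliberately not counted (toggle with
#' `count_fxt_in_vwp`).
#'
#' @param traits data frame with columns `population_id`,
#'   `seed_family_id`, `treatment`, optionally `lineage`, and the trait.
#' @param trait name of the trait column.
#' @param mode one of `"across"`, `"per_treatment"`, `"per_lineage"`.
#' @param treatment treatment level for `mode = "per_treatment"`.
#' @param lineage lineage label for `mode = "per_lineage"`.
#' @param include_family_treatment model the family x treatment random
#'   term in across/per-lineage modes.
#' @param count_fxt_in_vwp add the family x treatment variance into V_WP.
#' @param min_lineage_pops minimum populations for a per-lineage fit.
#' @param ... chain settings passed to [fit_lmm_gibbs()] (`n_iter`,
#'   `burn_in`, `thin`, `seed`, ...).
#' @return object of class `qst_estimate`: list with `trait`, `mode`,
#'   `draws` (posterior Q_ST draws, all in `[0, 1]`), `median`, `ci`
#'   (equal-tailed 95%), `v_ap`, `v_wp` (component draws), `n_pop`,
#'   and the underlying `fit`.
#' @export
estimate_qst <- function(traits, trait,
                         mode = c("across", "per_treatment", "per_lineage"),
                         treatment = NULL, lineage = NULL,
                         include_family_treatment = TRUE,
                         count_fxt_in_vwp = FALSE,
                         min_lineage_pops = 4, ...) {
  mode <- match.arg(mode)
  stopifnot(trait %in% names(traits))
  d <- traits[!is.na(traits[[trait]]), , drop = FALSE]
  check_nesting(d)
  fixed <- NULL; random <- c("population_id", "seed_family_id")
  if (mode == "across") {
    fixed <- "treatment"
  } else if (mode == "per_treatment") {
    if (is.null(treatment)) stop("treatment level required")
    d <- d[d$treatment == treatment, , drop = FALSE]
    if (!nrow(d)) stop("no observations for treatment ", treatment)
  } else {
    if (is.null(lineage)) stop("lineage label required")
    if (!"lineage" %in% names(d)) stop("traits table has no lineage column")
    d <- d[!is.na(d$lineage) & d$lineage == lineage, , drop = FALSE]
    np <- length(unique(d$population_id))
    if (np < 2) stop("lineage ", lineage, " has < 2 populations")
    if (np < min_lineage_pops)
      stop("lineage ", lineage, " has only ", np,
           " populations (< ", min_lineage_pops, "); refusing Q_ST fit")
    fixed <- "treatment"
  }
  if (mode != "per_treatment" && include_family_treatment &&
      length(unique(d$treatment)) > 1L)
    random <- c(random, "seed_family_id:treatment")
  if (length(unique(d$population_id)) < 2)
    stop("need >= 2 populations with data")
  d$treatment <- droplevels(factor(d$treatment))
  fit <- fit_lmm_gibbs(d, trait, fixed = fixed, random = random, ...)
  v_ap <- fit$sigma2[, "population_id"]
  v_wp <- fit$sigma2[, "seed_family_id"]
  if (count_fxt_in_vwp && "seed_family_id:treatment" %in% colnames(fit$sigma2))
    v_wp <- v_wp + fit$sigma2[, "seed_family_id:treatment"]
  draws <- qst_from_components(v_ap, v_wp)
  structure(list(trait = trait, mode = mode, treatment = treatment,
                 lineage = lineage, draws = draws,
                 median = stats::median(draws),
                 ci = stats::quantile(draws, c(0.025, 0.975), names = FALSE),
                 v_ap = v_ap, v_wp = v_wp,
                 n_pop = length(unique(d$population_id)), fit = fit),
            class = "qst_estimate")
}

#' @export
print.qst_estimate <- function(x, ...) {
  lab <- switch(x$mode, across = "across treatments",
                per_treatment = paste("treatment", x$treatment),
                per_lineage = paste("lineage", x$lineage))
  cat(sprintf("Q_ST[%s, %s] = %.3f  (95%% CI %.3f-%.3f, %d draws, %d pops)\n",
              x$trait, lab, x$median, x$ci[1], x$ci[2],
              length(x$draws), x$n_pop))
  invisible(x)
}

# seed families must be nested within populations
check_nesting <- function(d) {
  req <- c("population_id", "seed_family_id", "treatment")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("traits table lacks column(s): ",
                         paste(miss, collapse = ", "))
  t <- table(d$seed_family_id, d$population_id) > 0
  bad <- rownames(t)[rowSums(t) > 1]
  if (length(bad))
    stop("seed families found in more than one population: ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(TRUE)
}
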