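#' Simulate the neutral Q_ST distribution from molecular differentiation
#'
#' For each simulation `i`, the neutral among-population variance is
#' `Vnp_i = F_ST * (2 * V_A_i / (1 - F_ST)) * r_i / (n_pop - 1)`, where
#' `r_i` is a chi-square draw with `n_pop - 1` degrees of freedom that
#' injects the sampling variance of an among-population variance estimated
#' from `n_pop` populations.  The neutral Q_ST is then
#' `Vnp_i / (Vnp_i + 2 * Vwp_i)` with the observed within-population
#' variance.  `V_A` is conventionally taken equal to the seed-family
#' variance draws (`v_a_multiplier = 1`); under strong selfing the
#' among-family variance can exceed half the additive variance, which the
#' multiplier exposes.
#'
#' @param f_st molecular differentiation of the population set analysed
#'   (scalar; must be `< 1`; negative estimates are clipped to 0 with a
#'   warning).
#' @param n_pop number of populations behind `f_st`.
#' @param v_a additive-variance source: vector of posterior draws or a
#'   scalar.
#' @param v_wp observed within-population variance: vector of posterior
#'   draws (paired with `v_a` by index) or a scalar.
#' @param n_sim number of simulations (default 1000; forced to the common
#'   length of draw vectors when those are supplied).
#' @param v_a_multiplier scale factor on `v_a` (default 1).
#' @param seed optional RNG seed.
#' @return numeric vector of `n_sim` neutral Q_ST draws.
#' @export
simulate_neutral_qst <- function(f_st, n_pop, v_a, v_wp, n_sim = 1000,
                                 v_a_multiplier = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (f_st >= 1) stop("F_ST must be < 1")
  if (f_st < 0) {
    warning("negative F_ST clipped to 0 for the neutral simulation",
            call. = FALSE)
    f_st <- 0
  }
  if (n_pop < 2) stop("n_pop must be >= 2")
  nv <- c(length(v_a), length(v_wp))
  if (any(nv > 1L)) {
    len <- unique(nv[nv > 1L])
    if (length(len) != 1L) stop("v_a and v_wp draw vectors differ in length")
    n_sim <- len
  }
  v_a_i <- if (length(v_a) == 1L) rep(v_a, n_sim) else v_a
  v_wp_i <- if (length(v_wp) == 1L) rep(v_wp, n_sim) else v_wp
  r <- stats::rchisq(n_sim, df = n_pop - 1)
  vnp <- f_st * (2 * v_a_multiplier * v_a_i / (1 - f_st)) * r / (n_pop - 1)
  vnp / (vnp + 2 * v_wp_i)
}

#' Q_ST vs neutral-Q_ST difference test
#'
#' Index-paired differences between posterior Q_ST draws and simulated
#' neutral Q_ST draws, summarised by the posterior median and an
#' equal-tailed 95% credible interval.  The verdict is `"directional"`
#' when the interval lies entirely above zero, `"stabilizing"` when
#' entirely below, otherwise `"neutral"`.
#'
#' @param qst_draws posterior Q_ST draws (e.g. from [estimate_qst()]).
#' @param qnst_draws neutral draws from [simulate_neutral_qst()]; must
#'   have the same length.
#' @param level credibility level (default 0.95).
#' @return object of class `qstfst_test`: list with `differences`,
#'   `median`, `ci`, `verdict`, `level`.
#' @export
qst_fst_test <- function(qst_draws, qnst_draws, level = 0.95) {
  if (length(qst_draws) != length(qnst_draws))
    stop("draw vectors differ in length (", length(qst_draws), " vs ",
         length(qnst_draws), ")")
  d <- qst_draws - qnst_draws
  alpha <- (1 - level) / 2
  ci <- stats::quantile(d, c(alpha, 1 - alpha), names = FALSE)
  verdict <- if (ci[1] > 0) "directional" else
    if (ci[2] < 0) "stabilizing" else "neutral"
  structure(list(differences = d, median = stats::median(d), ci = ci,
                 verdict = verdict, level = level),
            class = "qstfst_test")
}

#' @export
print.qstfst_test <- function(x, ...) {
  cat(sprintf("Q_ST - Q_ST^neutral: median %.3f, %d%% CI [%.3f, %.3f] -> %s\n",
              x$median, round(100 * x$level), x$ci[1], x$ci[2], x$verdict))
  invisible(x)
}

#' Run the Q_ST - F_ST test battery over traits and modes
#'
#' For every trait and requested mode, estimates posterior Q_ST, recomputes
#' F_ST on exactly the population subset entering that mode (per-treatment
#' subsets and lineages have their own differentiation), simulates the
#' neutral distribution, and applies [qst_fst_test()].
#'
#' @param traits trait table (see [estimate_qst()]).
#' @param gt a [genotype_table()] used to (re)compute subset F_ST values;
#'   alternatively pass precomputed values via `f_st_values`, a named list
#'   keyed by mode label (`"across"`, `"T0"`, ..., or lineage name).
#' @param traits_to_test character vector of trait column names.
#' @param modes subset of `c("across", "per_treatment", "per_lineage")`.
#' @param lineage_assignment optional data frame `population_id`,
#'   `lineage` (needed for per-lineage mode when `traits` lacks lineages).
#' @param n_sim simulations per test (default 1000; also the number of
#'   posterior draws requested from the sampler).
#' @param seed integer; seeds trait/mode-specific chains and simulations
#'   reproducibly.
#' @param ... further chain settings for [estimate_qst()].
#' @return data frame: one row per trait x mode combination with the
#'   median difference, CI bounds, verdict, F_ST used and subset size.
#' @export
run_qstfst_suite <- function(traits, gt = NULL, traits_to_test,
                             modes = "across", f_st_values = NULL,
                             lineage_assignment = NULL,
                             n_sim = 1000, seed = 1, ...) {
  if (is.null(gt) && is.null(f_st_values))
    stop("either a genotype table or precomputed F_ST values are required")
  if (!is.null(lineage_assignment) && !"lineage" %in% names(traits))
    traits$lineage <- lineage_assignment$lineage[
      match(traits$population_id, lineage_assignment$population_id)]
  fst_for <- function(label, pops) {
    if (!is.null(f_st_values)) {
      if (is.null(f_st_values[[label]]))
        stop("no F_ST value supplied for subset ", label)
      return(f_st_values[[label]])
    }
    sub <- subset_populations(gt, pops)
    fst(sub, scope = label)$value
  }
  jobs <- list()
  for (m in modes) {
    if (m == "across") jobs[[length(jobs) + 1L]] <-
        list(mode = "across", label = "across", treatment = NULL,
             lineage = NULL)
    if (m == "per_treatment")
      for (tr in sort(unique(as.character(traits$treatment))))
        jobs[[length(jobs) + 1L]] <-
          list(mode = "per_treatment", label = tr, treatment = tr,
               lineage = NULL)
    if (m == "per_lineage") {
      if (!"lineage" %in% names(traits))
        stop("per-lineage mode requires a lineage column or assignment")
      for (ln in sort(unique(stats::na.omit(traits$lineage)))) {
        np <- length(unique(traits$population_id[traits$lineage == ln]))
        if (np < 4) next      # small lineages are excluded, not errored
        jobs[[length(jobs) + 1L]] <-
          list(mode = "per_lineage", label = ln, treatment = NULL,
               lineage = ln)
      }
    }
  }
  out <- list()
  ji <- 0L
  for (job in jobs) {
    ji <- ji + 1L
    for (ti in seq_along(traits_to_test)) {
      tr_name <- traits_to_test[ti]
      sub <- traits[!is.na(traits[[tr_name]]), , drop = FALSE]
      if (job$mode == "per_treatment")
        sub <- sub[sub$treatment == job$treatment, , drop = FALSE]
      if (job$mode == "per_lineage")
        sub <- sub[!is.na(sub$lineage) & sub$lineage == job$lineage, ,
                   drop = FALSE]
      pops <- unique(sub$population_id)
      job_seed <- (seed + 7919L * ji + 104729L * ti) %% .Machine$integer.max
      est <- estimate_qst(traits, tr_name, mode = job$mode,
                          treatment = job$treatment, lineage = job$lineage,
                          seed = job_seed, ...)
      f <- fst_for(job$label, pops)
      qn <- simulate_neutral_qst(max(f, 0), n_pop = est$n_pop,
                                 v_a = est$v_wp, v_wp = est$v_wp,
                                 n_sim = length(est$draws))
      tst <- qst_fst_test(est$draws, qn)
      out[[length(out) + 1L]] <- data.frame(
        trait = tr_name, mode = job$mode, subset = job$label,
        qst_median = est$median, f_st = f, n_pop = est$n_pop,
        median_diff = tst$median, ci_lo = tst$ci[1], ci_hi = tst$ci[2],
        verdict = tst$verdict, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
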