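#' Pairwise trait differentiation matrix (Q_ST per population pair)
#'
#' For every pair of populations, fits the two-population nested model by
#' REML (population and seed family random; treatment fixed when more than
#' one treatment is present) and computes
#' `V_AP / (V_AP + 2 V_WP)` from the point estimates.  REML is used per
#' pair for tractability over the full set of pairs; components estimated
#' at the boundary are 0 and enter the ratio as such.
#'
#' @param traits trait table (see [estimate_qst()]).
#' @param trait trait column name.
#' @param treatment optional: restrict to one treatment before fitting.
#' @return symmetric zero-diagonal population x population matrix; pairs
#'   whose model cannot be fitted get `NA` with a warning.
#' @export
pairwise_qst <- function(traits, trait, treatment = NULL) {
  d <- traits[!is.na(traits[[trait]]), , drop = FALSE]
  if (!is.null(treatment)) d <- d[d$treatment == treatment, , drop = FALSE]
  check_nesting(d)
  fams <- tapply(d$seed_family_id, d$population_id,
                 function(f) length(unique(f)))
  pops <- names(fams)[fams >= 2]
  if (length(pops) < 2) stop("need >= 2 populations with >= 2 seed families")
  n <- length(pops)
  m <- matrix(0, n, n, dimnames = list(pops, pops))
  failed <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sub <- d[d$population_id %in% pops[c(i, j)], , drop = FALSE]
    fixed <- if (length(unique(sub$treatment)) > 1) "treatment" else NULL
    est <- tryCatch({
      fit <- fit_lmm_reml(sub, trait, fixed = fixed,
                          random = c("population_id", "seed_family_id"))
      v_ap <- max(fit$varcomp[["population_id"]], 0)
      v_wp <- max(fit$varcomp[["seed_family_id"]], 0)
      if (v_ap + v_wp == 0) 0 else v_ap / (v_ap + 2 * v_wp)
    }, error = function(e) NA_real_)
    if (is.na(est)) failed <- failed + 1L
    m[i, j] <- m[j, i] <- est
  }
  if (failed)
    warning(failed, " population pair(s) failed the model fit (NA entries)",
            call. = FALSE)
  m
}
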