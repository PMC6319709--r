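#' REML fit of the nested variance-component model
#'
#' Thin wrapper around [lme4::lmer()] building the model from term lists,
#' used for the trait-response analyses and as an independent cross-check
#' of the Gibbs sampler.  Variance components sit at the boundary (0) when
#' the data support none.
#'
#' @inheritParams fit_lmm_gibbs
#' @return object of class `lmm_reml`: list with `varcomp` (named vector
#'   of variance components incl. `"residual"`), `fixef`, `anova` (type-III
#'   style Wald tests from \pkg{lmerTest} when installed, otherwise
#'   \pkg{lme4}'s sequential table), and the underlying `fit`.
#' @export
fit_lmm_reml <- function(data, response, fixed = NULL, random) {
  rhs <- if (is.null(fixed) || !length(fixed)) "1" else
    paste(fixed, collapse = " + ")
  for (tm in random) {
    vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    miss <- setdiff(vars, names(data))
    if (length(miss)) stop("unknown model variable(s): ",
                           paste(miss, collapse = ", "))
  }
  rterms <- paste0("(1 | ", gsub(":", ":", random), ")")
  fml <- stats::as.formula(paste(response, "~", rhs, "+",
                                 paste(rterms, collapse = " + ")))
  use_lmertest <- requireNamespace("lmerTest", quietly = TRUE)
  fit <- if (use_lmertest)
    lmerTest::lmer(fml, data = data, REML = TRUE)
  else
    lme4::lmer(fml, data = data, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  names(varcomp)[names(varcomp) == "Residual"] <- "residual"
  # map lme4's grouping-factor names back onto the requested terms
  for (tm in random) {
    hit <- which(names(varcomp) == tm | names(varcomp) == gsub(":", ".", tm))
    if (length(hit) == 1L) names(varcomp)[hit] <- tm
  }
  an <- tryCatch({
    if (use_lmertest) stats::anova(fit, type = 3) else stats::anova(fit)
  }, error = function(e) NULL)
  structure(list(varcomp = varcomp,
                 fixef = lme4::fixef(fit),
                 anova = an, fit = fit,
                 terms = list(fixed = rhs, random = random)),
            class = "lmm_reml")
}

#' @export
print.lmm_reml <- function(x, ...) {
  cat("REML mixed model: ~", x$terms$fixed, "+ (",
      paste(x$terms$random, collapse = ") + ("), ")\n")
  cat("variance components:\n"); print(round(x$varcomp, 4))
  invisible(x)
}

#' Pairwise post-hoc contrasts of adjusted means
#'
#' All pairwise differences between levels of a fixed factor.  For REML
#' fits, adjusted means come from \pkg{emmeans} with Holm-adjusted
#' p-values; for Gibbs fits, differences of coefficient draws are
#' summarised by posterior medians and equal-tailed 95% credible
#' intervals.
#'
#' @param fit an `lmm_reml` or `lmm_gibbs` object.
#' @param factor name of the fixed factor to contrast.
#' @param ... unused.
#' @return data frame, one row per level pair.
#' @export
posthoc_contrasts <- function(fit, factor, ...) UseMethod("posthoc_contrasts")

#' @export
posthoc_contrasts.lmm_reml <- function(fit, factor, ...) {
  lv <- levels(droplevels(as.factor(
    stats::model.frame(fit$fit)[[factor]])))
  if (length(lv) < 2L)
    return(data.frame(contrast = character(), estimate = numeric(),
                      p_value = numeric()))
  em <- emmeans::emmeans(fit$fit, specs = factor)
  pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "holm"))
  data.frame(contrast = pr$contrast, estimate = pr$estimate,
             se = pr$SE, p_value = pr$p.value, stringsAsFactors = FALSE)
}

#' @export
posthoc_contrasts.lmm_gibbs <- function(fit, factor, ...) {
  cols <- colnames(fit$beta)
  hit <- grep(paste0("^", factor), cols, value = TRUE)
  lv <- c("(reference)", sub(paste0("^", factor), "", hit))
  if (length(hit) < 1L)
    return(data.frame(contrast = character(), estimate = numeric(),
                      ci_lo = numeric(), ci_hi = numeric()))
  # treatment contrasts: reference level has implicit coefficient 0
  draws <- cbind(0, fit$beta[, hit, drop = FALSE])
  colnames(draws) <- lv
  out <- list()
  for (i in seq_len(ncol(draws) - 1)) for (j in (i + 1):ncol(draws)) {
    d <- draws[, j] - draws[, i]
    q <- stats::quantile(d, c(0.5, 0.025, 0.975), names = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      contrast = paste(colnames(draws)[j], "-", colnames(draws)[i]),
      estimate = q[1], ci_lo = q[2], ci_hi = q[3],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
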