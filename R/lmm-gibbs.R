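#' Blocked Gibbs sampler for Gaussian mixed models with crossed/nested
#' random intercepts
#'
#' Samples the posterior of `y = X beta + sum_k Z_k u_k + e` with
#' `u_k ~ N(0, sigma2_k I)` and `e ~ N(0, sigma2_e I)`.  Location effects
#' get conjugate normal updates (the fixed-effect block jointly, each
#' random-effect block level-wise, which is exact because every
#' observation belongs to one level per block); variances get
#' scaled-inverse-chi-square (inverse-gamma) updates.  Priors are
#' weakly-informative inverse-gamma on every variance (default shape and
#' scale 0.001) and flat on fixed effects.
#'
#' @param data data frame holding the response and all model variables.
#' @param response name of the (numeric, finite) response column.
#' @param fixed character vector of fixed-effect terms (RHS pieces, e.g.
#'   `c("treatment")`); `NULL` for intercept only.
#' @param random character vector of random-intercept terms; an entry like
#'   `"population:treatment"` is expanded to the interaction factor of the
#'   named columns.
#' @param priors list with `shape` and `scale` of the inverse-gamma
#'   variance prior.
#' @param n_iter,burn_in,thin chain settings; defaults 13000 / 3000 / 10
#'   retain exactly 1000 draws.
#' @param seed integer seed; same data + same seed gives identical draws.
#' @param store_effects keep random-effect draws (memory-heavy) in the
#'   result.
#' @return object of class `lmm_gibbs`: list with `beta` (draws x
#'   coefficients), `sigma2` (draws x variances, columns named after the
#'   random terms plus `"residual"`), `terms`, `levels` (levels per random
#'   term), `chain` settings, and optionally `effects`.
#' @examples
#' d <- data.frame(g = rep(letters[1:5], each = 4))
#' d$y <- rnorm(5)[as.integer(factor(d$g))] + rnorm(20)
#' fit <- fit_lmm_gibbs(d, "y", random = "g",
#'                      n_iter = 600, burn_in = 100, thin = 5, seed = 1)
#' apply(fit$sigma2, 2, stats::median)
#' @export
fit_lmm_gibbs <- function(data, response, fixed = NULL, random,
                          priors = list(shape = 0.001, scale = 0.001),
                          n_iter = 13000, burn_in = 3000, thin = 10,
                          seed = NULL, store_effects = FALSE) {
  stopifnot(is.data.frame(data), response %in% names(data))
  y <- data[[response]]
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("response must be numeric and finite (drop NA rows first)")
  n <- length(y)
  rhs <- if (is.null(fixed) || !length(fixed)) "1" else
    paste(fixed, collapse = " + ")
  X <- stats::model.matrix(stats::reformulate(rhs), data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("aliased fixed effects: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "))
  p <- ncol(X)
  if (length(random) < 1L) stop("at least one random term required")
  fac <- lapply(random, function(tm) {
    vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    miss <- setdiff(vars, names(data))
    if (length(miss)) stop("unknown model variable(s): ",
                           paste(miss, collapse = ", "))
    droplevels(interaction(data[vars], drop = TRUE, sep = ":"))
  })
  names(fac) <- random
  idx <- lapply(fac, as.integer)
  nlev <- vapply(fac, nlevels, integer(1))
  cnt <- lapply(fac, tabulate)
  K <- length(random)

  if (!is.null(seed)) set.seed(seed)
  a0 <- priors$shape; b0 <- priors$scale
  # init: OLS fixed effects, zero random effects, equal variance split
  beta <- qr.coef(qrX, y)
  Xb <- drop(X %*% beta)
  u <- lapply(nlev, function(q) numeric(q))
  contrib <- lapply(idx, function(i) numeric(n))
  v <- rep(stats::var(y) / (K + 1), K + 1)   # K random + residual
  R <- chol(crossprod(X))
  XtXinvXt <- backsolve(R, backsolve(R, t(X), transpose = TRUE))

  n_keep <- (n_iter - burn_in) %/% thin
  if (n_keep < 1L) stop("chain settings retain no draws")
  beta_out <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  sig_out <- matrix(NA_real_, n_keep, K + 1,
                    dimnames = list(NULL, c(random, "residual")))
  eff_out <- if (store_effects)
    lapply(nlev, function(q) matrix(NA_real_, n_keep, q)) else NULL

  utot <- Reduce(`+`, contrib, numeric(n))
  kept <- 0L
  for (it in seq_len(n_iter)) {
    # fixed-effect block
    r <- y - utot
    bhat <- drop(XtXinvXt %*% r)
    beta <- bhat + sqrt(v[K + 1]) * backsolve(R, stats::rnorm(p))
    Xb <- drop(X %*% beta)
    # random-effect blocks, level-conditionals are independent given the rest
    for (k in seq_len(K)) {
      r <- y - Xb - (utot - contrib[[k]])
      s <- rowsum(r, idx[[k]], reorder = TRUE)   # level sums, sorted = 1..q
      prec <- cnt[[k]] / v[K + 1] + 1 / v[k]
      mu <- (s / v[K + 1]) / prec
      u[[k]] <- drop(mu) + stats::rnorm(nlev[k]) / sqrt(prec)
      new_contrib <- u[[k]][idx[[k]]]
      utot <- utot - contrib[[k]] + new_contrib
      contrib[[k]] <- new_contrib
      v[k] <- 1 / stats::rgamma(1, a0 + nlev[k] / 2,
                                rate = b0 + sum(u[[k]]^2) / 2)
    }
    e <- y - Xb - utot
    v[K + 1] <- 1 / stats::rgamma(1, a0 + n / 2, rate = b0 + sum(e^2) / 2)
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      beta_out[kept, ] <- beta
      sig_out[kept, ] <- v
      if (store_effects)
        for (k in seq_len(K)) eff_out[[k]][kept, ] <- u[[k]]
    }
  }
  structure(list(beta = beta_out, sigma2 = sig_out,
                 terms = list(fixed = rhs, random = random),
                 levels = lapply(fac, levels),
                 chain = list(n_iter = n_iter, burn_in = burn_in,
                              thin = thin, seed = seed, retained = n_keep),
                 effects = eff_out),
            class = "lmm_gibbs")
}

#' @export
print.lmm_gibbs <- function(x, ...) {
  cat("Gibbs-sampled Gaussian mixed model\n")
  cat("  fixed: ~", x$terms$fixed, "\n  random:",
      paste(x$terms$random, collapse = ", "), "\n")
  cat("  retained draws:", x$chain$retained, "\n")
  cat("posterior median variances:\n")
  print(round(apply(x$sigma2, 2, stats::median), 4))
  invisible(x)
}
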