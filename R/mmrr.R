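#' Multiple matrix regression with randomization (MMRR)
#'
#' Regresses the unfolded lower triangle of a dependent
#' distance/differentiation matrix on one or more predictor matrices by
#' ordinary least squares.  Significance of each coefficient (and of the
#' model R^2) comes from a Mantel-style permutation null: rows and columns
#' of the dependent matrix are permuted jointly `n_perm` times, preserving
#' the dependence structure within the matrix, and two-tailed p-values are
#' `(# |t_perm| >= |t_obs| + 1) / (n_perm + 1)` (the observed statistic
#' counts in both numerator and denominator).
#'
#' By default every matrix is standardized by z-scoring its off-diagonal
#' vector, making coefficients comparable across predictors.
#'
#' @param y dependent matrix (symmetric, numeric).
#' @param x a single predictor matrix or a named list of them, all with
#'   the same dimension and population order as `y`.
#' @param n_perm number of permutations (default 9999).
#' @param standardize z-score each unfolded matrix first (default TRUE).
#' @param seed optional RNG seed.
#' @return object of class `mmrr_result`: data frame `coefficients`
#'   (estimate, t, p per predictor), plus `r_squared`, `f_statistic`,
#'   `p_model`, `n_perm`, `n_pop`.
#' @export
mmrr <- function(y, x, n_perm = 9999, standardize = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(x)) x <- list(X1 = x)
  if (is.null(names(x)) || !all(nzchar(names(x))))
    names(x) <- paste0("X", seq_along(x))
  y <- as.matrix(y)
  n <- nrow(y)
  if (n < 4) stop("need >= 4 populations")
  for (m in x)
    if (!all(dim(m) == n)) stop("predictor dimensions differ from y")
  lt <- lower.tri(y)
  unfold <- function(m) m[lt]
  zs <- function(v) if (standardize) (v - mean(v)) / stats::sd(v) else v
  yv <- zs(unfold(y))
  Xv <- vapply(x, function(m) zs(unfold(m)), numeric(sum(lt)))
  X <- cbind(`(Intercept)` = 1, Xv)
  if (qr(X)$rank < ncol(X)) {
    cc <- stats::cor(Xv)
    diag(cc) <- 0
    bad <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop("singular predictor set (collinear pair: ",
         paste(colnames(Xv)[bad], collapse = ", "), ")")
  }
  fit_t <- function(yvec) {
    f <- stats::lm.fit(X, yvec)
    rss <- sum(f$residuals^2)
    df <- length(yvec) - ncol(X)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(diag(XtXinv) * rss / df)
    list(coef = f$coefficients, t = f$coefficients / se, rss = rss)
  }
  obs <- fit_t(yv)
  tss <- sum((yv - mean(yv))^2)
  r2 <- 1 - obs$rss / tss
  k <- ncol(X) - 1
  f_obs <- (r2 / k) / ((1 - r2) / (length(yv) - k - 1))
  ge_t <- rep(1L, ncol(X))       # observed included
  ge_f <- 1L
  for (b in seq_len(n_perm)) {
    pi <- sample.int(n)
    yp <- zs(unfold(y[pi, pi]))
    pf <- fit_t(yp)
    ge_t <- ge_t + (abs(pf$t) >= abs(obs$t))
    r2p <- 1 - pf$rss / sum((yp - mean(yp))^2)
    ge_f <- ge_f + (r2p >= r2)
  }
  p <- ge_t / (n_perm + 1)
  coefs <- data.frame(predictor = colnames(X), estimate = unname(obs$coef),
                      t = unname(obs$t), p_value = unname(p),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs[-1, , drop = FALSE],
                 intercept = obs$coef[1],
                 r_squared = r2, f_statistic = f_obs,
                 p_model = ge_f / (n_perm + 1),
                 n_perm = n_perm, n_pop = n),
            class = "mmrr_result")
}

#' @export
print.mmrr_result <- function(x, ...) {
  cat(sprintf("MMRR over %d populations (%d permutations): R2 = %.3f (p = %.4g)\n",
              x$n_pop, x$n_perm, x$r_squared, x$p_model))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}
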