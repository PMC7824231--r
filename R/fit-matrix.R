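# Regression engines shared by the screening and EWAS modules.
#
# The design X (subjects x p) is common to every CpG while the outcome
# differs per CpG: OLS is a single shared projection, and the Huber IRLS
# loops over CpGs in compiled code (src/huber_irls.cpp).

# Ordinary least squares of each column of Y on X. Returns the coefficient,
# standard error, t and two-sided p of the column `which` of X.
ols_matrix <- function(X, Y, which = 2L) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  XtXinv <- solve(XtX)
  B <- XtXinv %*% crossprod(X, Y)              # p x m
  res <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(res^2) / df
  var_b <- XtXinv[which, which] * sigma2
  se <- sqrt(var_b)
  tval <- B[which, ] / se
  pval <- 2 * pt(-abs(tval), df)
  list(coef = B[which, ], se = se, t = tval, p = pval, df = df,
       coef_all = B)
}

# Huber M-estimation by iteratively reweighted least squares over outcome
# columns. Tuning constant k = 1.345 (95% efficiency under normal errors),
# scale = MAD of the current residuals per column, p-values from the final
# weighted least-squares fit with df = n - p.
huber_matrix <- function(X, Y, which = 2L, k = 1.345, maxit = 15L,
                         tol = 1e-5) {
  n <- nrow(X); p <- ncol(X)
  fit <- huber_irls_cpp(X, Y, as.integer(which), k, as.integer(maxit), tol)
  coef <- fit[1, ]
  se <- fit[2, ]
  df <- n - p
  tval <- coef / se
  pval <- 2 * pt(-abs(tval), df)
  names(coef) <- names(se) <- names(tval) <- names(pval) <- colnames(Y)
  list(coef = coef, se = se, t = tval, p = pval, df = df)
}
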