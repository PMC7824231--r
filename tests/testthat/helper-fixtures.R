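# Shared fixtures: tiny sample sheets and cohorts built in code.

# Minimal valid sample sheet for `n` subjects. Factor covariates are
# balanced shuffles (every level present, no accidental collinearity);
# deterministic for a given seed.
tiny_sheet <- function(n, seed = 1, jitter_cells = FALSE) {
  set.seed(seed)
  shuffled <- function(levels) sample(rep(levels, length.out = n))
  base <- c(CD8T = 0.08, CD4T = 0.15, NK = 0.05, Bcell = 0.07,
            Mono = 0.08, Gran = 0.57)
  cells <- function() {
    m <- matrix(rep(base, each = n), nrow = n)
    if (jitter_cells) {
      m <- m * matrix(exp(rnorm(n * 6, 0, 0.2)), n, 6)
    }
    m / rowSums(m)
  }
  cb <- cells(); ca <- cells()
  colnames(cb) <- paste0(names(base), "_birth")
  colnames(ca) <- paste0(names(base), "_age10")
  modes <- rep(c("EBF", "EFF", "Mixed"), length.out = n)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    feeding_mode = modes,
    bf_weeks = ifelse(modes == "EBF", 16, ifelse(modes == "EFF", 0, 6)),
    formula_week = ifelse(modes == "EBF", 16, ifelse(modes == "EFF", 0, 6)),
    solids_week = ifelse(modes == "EFF", 15, 17),
    cb, ca,
    season_birth = shuffled(c("winter", "spring", "summer", "fall")),
    season_age10 = shuffled(c("winter", "spring", "summer", "fall")),
    sex = shuffled(c("male", "female")),
    maternal_smoking = shuffled(c("no", "no", "yes")),
    maternal_age = rnorm(n, 30, 4),
    birthweight = rnorm(n, 3.4, 0.5),
    birth_order = shuffled(c("1", "2", "3+")),
    ses = shuffled(c("medium", "high", "medium", "low")),
    caesarean = shuffled(c("no", "no", "no", "yes")),
    maternal_asthma = rep("no", n),
    stringsAsFactors = FALSE
  )
}

# CpG x sample matrix with names.
named_matrix <- function(values, n_cpg, n_sample, prefix = "cg") {
  matrix(values, n_cpg, n_sample,
         dimnames = list(sprintf("%s%05d", prefix, seq_len(n_cpg)),
                         sprintf("S%03d", seq_len(n_sample))))
}

# A delta matrix built directly (bypassing the generator) for
# screening/global-shift tests where the noise scale must be explicit.
direct_delta <- function(n_cpg, n_sub, sd = 1, seed = 1) {
  set.seed(seed)
  d <- named_matrix(rnorm(n_cpg * n_sub, 0, sd), n_cpg, n_sub)
  structure(d, class = c("delta_matrix", class(d)))
}

# Independent normal-equations OLS oracle: coefficient and two-sided p of
# the last column of X, computed only from solve() and pt().
normal_equations_oracle <- function(X, y) {
  XtXinv <- solve(t(X) %*% X)
  beta <- XtXinv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  j <- ncol(X)
  se <- sqrt(XtXinv[j, j] * sigma2)
  tval <- beta[j] / se
  list(coefficient = as.numeric(beta[j]), se = as.numeric(se),
       p_value = 2 * pt(-abs(tval), df))
}

# Literal Benjamini-Hochberg step-up oracle.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
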