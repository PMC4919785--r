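# Internal least-squares / logistic helpers shared by the weight regressions,
# trait scans and instrument-strength diagnostics. All fits go through
# stats::lm.fit / stats::glm.fit so that repeated scanning (94 traits x
# hundreds of permutations) stays fast without reimplementing any statistics.

# Design matrix: intercept, x, then study dummies (first level as reference).
.design <- function(x, study = NULL) {
  X <- cbind(`(Intercept)` = 1, x = x)
  if (!is.null(study)) {
    study <- droplevels(as.factor(study))
    if (nlevels(study) > 1L) {
      D <- stats::model.matrix(~study)[, -1L, drop = FALSE]
      X <- cbind(X, D)
    }
  }
  X
}

# Gaussian fit of y on x adjusting for study; returns the x coefficient.
# Implemented by within-study centring (Frisch-Waugh), which gives exactly
# the coefficient, SE and t-test of lm(y ~ x + study) at a fraction of the
# cost — the scans run this tens of thousands of times. Wald p from the t
# reference with residual df n - (number of study levels) - 1.
.lm_xy <- function(y, x, study = NULL) {
  ok <- is.finite(y) & is.finite(x)
  if (!is.null(study)) ok <- ok & !is.na(study)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3L) return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n))
  if (is.null(study)) {
    g <- rep(1L, n); S <- 1L
  } else {
    sg <- study[ok]
    # integer study codes are accepted as-is so callers scanning many traits
    # can convert the factor once
    g <- if (is.integer(sg)) sg else as.integer(factor(sg))
    S <- max(g)
  }
  cnt <- tabulate(g, S)
  if (any(cnt == 0L)) { # drop empty study levels after complete-case subset
    pres <- which(cnt > 0L)
    g <- match(g, pres)
    S <- length(pres)
    cnt <- cnt[pres]
  }
  xc <- x - (rowsum(x, g, reorder = TRUE) / cnt)[g]
  yc <- y - (rowsum(y, g, reorder = TRUE) / cnt)[g]
  sxx <- sum(xc^2)
  df <- n - S - 1L
  if (sxx < 1e-12 || df < 1L) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                degenerate = "zero-variance predictor"))
  }
  beta <- sum(xc * yc) / sxx
  rss <- sum((yc - beta * xc)^2)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       t = tval, df = df, n = n, sigma2 = sigma2)
}

# Logistic fit of binary y on x adjusting for study; Wald z p-value.
# Separation is flagged (huge coefficient or non-convergence) and p set NA.
.logit_xy <- function(y, x, study = NULL) {
  ok <- is.finite(y) & is.finite(x)
  if (!is.null(study)) ok <- ok & !is.na(study)
  y <- y[ok]; x <- x[ok]
  study <- if (is.null(study)) NULL else factor(study[ok])
  n <- length(y)
  if (n < 3L || stats::var(x) == 0 || length(unique(y)) < 2L) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                separation = FALSE))
  }
  X <- .design(x, study)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())
  )
  r <- fit$rank
  Qr <- fit$qr
  R <- Qr$qr[seq_len(r), seq_len(r), drop = FALSE]
  R[lower.tri(R)] <- 0
  v <- rep(NA_real_, ncol(X))
  v[Qr$pivot[seq_len(r)]] <- diag(chol2inv(R))
  beta <- fit$coefficients["x"]
  se <- sqrt(v[2L])
  sep <- !fit$converged || !is.finite(beta) || abs(beta) > 15 ||
    !is.finite(se) || se > 100
  if (sep) {
    return(list(beta = unname(beta), se = se, p = NA_real_, n = n,
                separation = TRUE))
  }
  z <- beta / se
  list(beta = unname(beta), se = se,
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       z = unname(z), n = n, separation = FALSE)
}

# Logistic regression of case status on allele count fitted from the
# aggregated 2 x 3 (case x genotype) table — equivalent to the subject-level
# fit (genotype takes only the values 0/1/2) and far faster for the
# per-SNP consortium fits. cases/totals are length-3 vectors over g = 0,1,2.
.logit_geno <- function(cases, totals) {
  keep <- totals > 0
  if (sum(keep) < 2L || sum(cases) == 0 || sum(cases) == sum(totals)) {
    return(list(beta = NA_real_, se = NA_real_))
  }
  X <- cbind(1, c(0, 1, 2))[keep, , drop = FALSE]
  fit <- suppressWarnings(
    stats::glm.fit(X, (cases / totals)[keep], weights = totals[keep],
                   family = stats::binomial())
  )
  r <- fit$rank
  if (r < 2L) return(list(beta = NA_real_, se = NA_real_))
  R <- fit$qr$qr[1:2, 1:2, drop = FALSE]
  R[lower.tri(R)] <- 0
  v <- diag(chol2inv(R))
  v[fit$qr$pivot] <- v
  list(beta = unname(fit$coefficients[2L]), se = sqrt(v[2L]))
}

# Two unique non-missing values => treated as binary in trait scans.
.is_binary <- function(x) {
  u <- unique(x[is.finite(x)])
  length(u) == 2L
}

# Recode a two-valued vector to 0/1 (larger value = 1).
.as01 <- function(x) {
  u <- sort(unique(x[is.finite(x)]))
  as.integer(x == u[2L])
}

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
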