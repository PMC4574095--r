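# Independent reference implementations used to cross-check the package.
# Each deliberately uses a different algorithmic route than the code under
# test.

# Minute-by-minute state-machine scanner for the non-wear rule; returns a
# logical mask of non-wear minutes. Quadratic-ish and simple on purpose.
nonwear_oracle_mask <- function(counts, min_window = 60L, max_int = 2L) {
  n <- length(counts)
  flags <- logical(n)
  i <- 1L
  while (i <= n) {
    if (counts[i] == 0L) {
      last_zero <- i
      run_nz <- 0L
      k <- i
      while (k <= n) {
        if (counts[k] == 0L) {
          run_nz <- 0L
          last_zero <- k
        } else {
          run_nz <- run_nz + 1L
          if (run_nz > max_int) break
        }
        k <- k + 1L
      }
      if (last_zero - i + 1L >= min_window) flags[i:last_zero] <- TRUE
      i <- last_zero + 1L
      while (i <= n && counts[i] != 0L) i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  flags
}

# Stata-convention CR1 cluster-robust SEs computed from the sandwich formula
# written out longhand.
cr1_se_oracle <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  e <- stats::resid(fit)
  k <- ncol(X)
  n <- nrow(X)
  G <- length(unique(cluster))
  meat <- matrix(0, k, k)
  for (g in unique(cluster)) {
    idx <- cluster == g
    s <- colSums(X[idx, , drop = FALSE] * e[idx])
    meat <- meat + tcrossprod(s)
  }
  bread <- solve(crossprod(X))
  adj <- G / (G - 1) * (n - 1) / (n - k)
  sqrt(diag(adj * bread %*% meat %*% bread))
}

# DerSimonian-Laird pooling written directly from the moment formulas.
dl_oracle <- function(est, se) {
  w <- 1 / se^2
  tf <- sum(w * est) / sum(w)
  Q <- sum(w * (est - tf)^2)
  df <- length(est) - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  list(Q = Q, tau2 = tau2,
       I2 = if (Q > 0) max(0, 100 * (Q - df) / Q) else 0,
       pooled = sum(wr * est) / sum(wr),
       pooled_se = sqrt(1 / sum(wr)),
       p = stats::pchisq(Q, df, lower.tail = FALSE))
}

# Groupwise population-SD z-scores via split/unsplit.
group_z_oracle <- function(x, key) {
  z <- unsplit(lapply(split(x, key), function(v) {
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }), key)
  z
}
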