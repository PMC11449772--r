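# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Analytic Rician mean/variance at noncentrality nu, channel sd sigma.
# Mean = sigma * sqrt(pi/2) * L_{1/2}(-nu^2 / (2 sigma^2)) with the
# half-order Laguerre polynomial written via Bessel I (scaled for
# stability); variance = 2 sigma^2 + nu^2 - mean^2.
rician_moments <- function(nu, sigma) {
  # expon.scaled Bessel absorbs the e^{-x/2} factor of L_{1/2}(-x)
  x <- nu^2 / (2 * sigma^2)
  lhalf <- (1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
           x * besselI(x / 2, 1, expon.scaled = TRUE)
  m <- sigma * sqrt(pi / 2) * lhalf
  list(mean = m, var = 2 * sigma^2 + nu^2 - m^2)
}

# Brute-force search for the mono-exponential least-squares fit. S0 is
# profiled out in closed form (for fixed T2* the model is linear in S0),
# leaving an exhaustive 1-D grid over T2*, refined to ~1e-5 relative.
grid_fit_oracle <- function(te, y, t2_range = NULL) {
  if (is.null(t2_range)) t2_range <- c(min(te) / 20, max(te) * 50)
  prof <- function(t2) {
    e <- exp(-te / t2)
    s0 <- max(sum(y * e) / sum(e * e), 1e-12)
    c(ss = sum((y - s0 * e)^2), s0 = s0)
  }
  best_t2 <- NA
  for (pass in 1:4) {
    t2g <- exp(seq(log(t2_range[1]), log(t2_range[2]), length.out = 2001))
    ss <- vapply(t2g, function(t) prof(t)["ss"], numeric(1))
    k <- which.min(ss)
    best_t2 <- t2g[k]
    lo <- t2g[max(1, k - 2)]; hi <- t2g[min(length(t2g), k + 2)]
    t2_range <- c(lo, hi)
  }
  list(s0 = unname(prof(best_t2)["s0"]), t2star = best_t2)
}

# Brute-force direct standardization on an explicit stratum table:
# counts[g, i] cases and correct[g, i] successes per subgroup g, layer i.
sdar_bruteforce <- function(counts, correct, renormalize = TRUE) {
  Ni <- colSums(counts)
  N <- sum(Ni)
  vapply(seq_len(nrow(counts)), function(g) {
    num <- 0; den <- 0
    for (i in seq_len(ncol(counts))) {
      if (counts[g, i] > 0) {
        p_gi <- correct[g, i] / counts[g, i]
        num <- num + (Ni[i] / N) * p_gi
        den <- den + Ni[i] / N
      }
    }
    if (den == 0) NA_real_ else if (renormalize) num / den else num
  }, numeric(1))
}

# Turn a (counts, correct) stratum table into a record-level data.frame
# the accordance functions accept: subgroup/layer as plain columns, the
# grade pair encodes correctness.
records_from_table <- function(counts, correct) {
  rows <- list()
  for (g in seq_len(nrow(counts))) for (i in seq_len(ncol(counts))) {
    n <- counts[g, i]
    if (n == 0) next
    k <- correct[g, i]
    rows[[length(rows) + 1L]] <- data.frame(
      sub = sprintf("g%02d", g), lay = sprintf("l%02d", i),
      grade_hat = c(rep("mild", k), rep("severe", n - k)),
      grade_ref = rep("mild", n), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Exact two-sided permutation p-value for Spearman's rho at tiny n.
spearman_perm_oracle <- function(x, y) {
  n <- length(x)
  perms <- gtools_perms(n)
  obs <- cor(x, y, method = "spearman")
  rhos <- apply(perms, 1, function(p) cor(x, y[p], method = "spearman"))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

gtools_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

default_te <- c(1.29, 2.35, 3.43, 4.60, 5.68, 6.85,
                7.93, 9.10, 10.18, 11.35, 12.43, 13.6)
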