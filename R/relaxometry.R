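#' Multi-echo magnitude train
#'
#' The fitting substrate: paired echo times (ms) and nonnegative ROI-mean
#' magnitudes. Input echoes are sorted by TE internally so echo order on
#' input never affects results.
#'
#' @param te echo times in ms, all distinct and > 0.
#' @param signal magnitudes, same length, nonnegative.
#' @return An object of class `echo_train`.
#' @export
echo_train <- function(te, signal) {
  stopifnot(is.numeric(te), is.numeric(signal),
            length(te) == length(signal), length(te) >= 1L,
            all(is.finite(te)), all(te > 0), all(is.finite(signal)),
            all(signal >= 0))
  if (anyDuplicated(te)) stop("echo times must be distinct", call. = FALSE)
  ord <- order(te)
  structure(list(te = as.numeric(te[ord]), signal = as.numeric(signal[ord])),
            class = "echo_train")
}

# Log-linear initializer: OLS of log(signal) on TE over positive signals.
# Returns c(log_s0, log_t2star); slope >= 0 (no apparent decay) falls back
# to a very long T2*.
loglin_start <- function(te, signal) {
  pos <- signal > 0
  if (sum(pos) >= 2L) {
    fit <- stats::lm.fit(cbind(1, te[pos]), log(signal[pos]))
    a <- fit$coefficients[1]
    slope <- fit$coefficients[2]
  } else {
    a <- log(max(signal, 1))
    slope <- -1 / max(te)
  }
  rate <- max(-slope, 1e-12)
  c(a, -log(rate))
}

#' Fit the mono-exponential decay model to an echo train
#'
#' Nonlinear least squares for \eqn{S(TE) = S_0 e^{-TE/T2*}} over
#' \eqn{S_0 > 0, T2* > 0}, minimized by BFGS on (log S0, log T2*) with an
#' analytic gradient, started from an ordinary least-squares line through
#' log(signal) vs TE (positive signals only; zero signals stay in the
#' nonlinear objective). One deterministic perturbed restart is attempted
#' on non-convergence. R^2 is the ordinary centered coefficient of
#' determination on the untransformed magnitudes of the echoes actually
#' used.
#'
#' @param train an [echo_train()] with >= 3 echoes, at least one positive.
#' @return A `fit_result` list: `s0_hat`, `t2star_hat`, `r_squared`,
#'   `n_echoes`, `removed_tes`, `valid`. Degenerate inputs (all-zero
#'   signal, optimizer failure after restart) return `valid = FALSE`
#'   rather than an error.
#' @export
fit_monoexponential <- function(train) {
  te <- train$te; y <- train$signal
  if (length(te) < 3L) stop("need at least 3 echoes", call. = FALSE)
  if (all(y == 0)) {
    return(fit_result(NA_real_, NA_real_, NA_real_, length(te),
                      numeric(0), valid = FALSE))
  }

  obj <- function(p) {
    m <- exp(p[1] - te * exp(-p[2]))
    sum((y - m)^2)
  }
  grad <- function(p) {
    m <- exp(p[1] - te * exp(-p[2]))
    r <- y - m
    c(-2 * sum(r * m), -2 * sum(r * m * te * exp(-p[2])))
  }

  start <- loglin_start(te, y)
  opt <- try(stats::optim(start, obj, grad, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14)),
             silent = TRUE)
  bad <- inherits(opt, "try-error") || opt$convergence != 0 ||
    !all(is.finite(opt$par))
  if (bad) {
    # deterministic restart: nudge the start, loosen the line search
    opt2 <- try(stats::optim(start + c(0.1, -0.2), obj, grad,
                             method = "BFGS",
                             control = list(maxit = 2000, reltol = 1e-12)),
                silent = TRUE)
    if (!inherits(opt2, "try-error") && all(is.finite(opt2$par)) &&
        (inherits(opt, "try-error") || opt2$value <= opt$value)) {
      opt <- opt2
      bad <- opt$convergence != 0
    }
  }
  if (inherits(opt, "try-error") || !all(is.finite(opt$par))) {
    return(fit_result(NA_real_, NA_real_, NA_real_, length(te),
                      numeric(0), valid = FALSE))
  }

  s0_hat <- exp(opt$par[1])
  t2_hat <- exp(opt$par[2])
  ss_res <- opt$value
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res <= 1e-12) 1 else -Inf
  fit_result(s0_hat, t2_hat, r2, length(te), numeric(0), valid = !bad)
}

fit_result <- function(s0_hat, t2star_hat, r_squared, n_echoes,
                       removed_tes, valid = TRUE) {
  structure(list(s0_hat = unname(s0_hat), t2star_hat = unname(t2star_hat),
                 r_squared = unname(r_squared), n_echoes = as.integer(n_echoes),
                 removed_tes = as.numeric(removed_tes), valid = valid),
            class = "fit_result")
}

#' Truncation scan: refit while dropping the longest echoes
#'
#' The truncation method for the magnitude noise floor: starting from the
#' full echo set, repeatedly drop the single longest-TE echo and refit,
#' down to `min_echoes`. Level k uses the first n - k echoes; each level
#' records the echo times it dropped. Echoes are only ever removed from
#' the long-TE end, never from the interior.
#'
#' @param train an [echo_train()].
#' @param min_echoes smallest echo count fitted; must be >= 3 (the
#'   smallest echo-count subgroup analyzed downstream).
#' @return A `truncation_trace`: list of `fit_result`s ordered from the
#'   full set down to `min_echoes`.
#' @export
truncation_scan <- function(train, min_echoes = 3L) {
  if (min_echoes < 3L) stop("min_echoes must be >= 3", call. = FALSE)
  n <- length(train$te)
  if (n < min_echoes) stop("train has fewer than min_echoes echoes",
                           call. = FALSE)
  levels <- vector("list", n - min_echoes + 1L)
  for (k in 0:(n - min_echoes)) {
    keep <- seq_len(n - k)
    sub <- echo_train(train$te[keep], train$signal[keep])
    fr <- fit_monoexponential(sub)
    fr$removed_tes <- if (k > 0) train$te[(n - k + 1L):n] else numeric(0)
    levels[[k + 1L]] <- fr
  }
  structure(levels, class = "truncation_trace")
}

#' Goodness-of-fit bin label for an R-squared value
#'
#' Five bins of width 0.01 from 0.95 up, the top bin closed at 1 so a
#' perfect fit is representable, plus an internal below-0.95 bin so every
#' fit gets a label (records in that bin are excluded before accordance
#' analysis).
#'
#' @param r_squared numeric vector.
#' @return factor with levels `<0.95`, `[0.95,0.96)`, ..., `[0.99,1.00]`.
#' @export
r2_bin <- function(r_squared) {
  labs <- c("<0.95", "[0.95,0.96)", "[0.96,0.97)", "[0.97,0.98)",
            "[0.98,0.99)", "[0.99,1.00]")
  idx <- findInterval(r_squared, c(0.95, 0.96, 0.97, 0.98, 0.99)) + 1L
  idx[is.na(r_squared)] <- NA_integer_
  factor(labs[idx], levels = labs, ordered = TRUE)
}

#' Select the final fit from a truncation trace
#'
#' Default policy `"binned"`: assign each level's R^2 to the 0.01-wide
#' bins of [r2_bin()]; among levels in the highest occupied bin keep the
#' one using the most echoes (within an R^2 bin, more echoes means a more
#' stable fit). Policy `"max_r2"` simply takes the global R^2 maximum,
#' breaking ties toward more echoes.
#'
#' @param trace a [truncation_scan()] result.
#' @param policy `"binned"` or `"max_r2"`.
#' @return The chosen `fit_result`.
#' @export
select_fit <- function(trace, policy = c("binned", "max_r2")) {
  policy <- match.arg(policy)
  valid <- vapply(trace, function(f) isTRUE(f$valid), logical(1))
  if (!any(valid)) stop("no valid truncation level to select", call. = FALSE)
  cand <- trace[valid]
  r2 <- vapply(cand, `[[`, numeric(1), "r_squared")
  ne <- vapply(cand, `[[`, integer(1), "n_echoes")
  pick <- if (policy == "binned") {
    bins <- as.integer(r2_bin(r2))
    in_top <- bins == max(bins)
    which(in_top)[which.max(ne[in_top])]
  } else {
    best <- r2 == max(r2)
    which(best)[which.max(ne[best])]
  }
  cand[[pick]]
}
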