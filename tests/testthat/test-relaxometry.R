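noiseless_train <- function(s0, t2, te = default_te) {
  echo_train(te, s0 * exp(-te / t2))
}

test_that("model-true data is fitted exactly at every truncation level", {
  for (t2 in c(1, 2, 5, 10, 20)) {
    tr <- noiseless_train(1000, t2)
    fit <- fit_monoexponential(tr)
    expect_equal(fit$t2star_hat, t2, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    trace <- truncation_scan(tr)
    for (lev in trace) {
      expect_equal(lev$t2star_hat, t2, tolerance = 1e-6)
      expect_equal(lev$r_squared, 1, tolerance = 1e-9)
    }
  }
})

test_that("decay rate is invariant to amplitude scaling and echo order", {
  set.seed(42)
  y <- 800 * exp(-default_te / 3.7) + rnorm(12, 0, 5)
  y <- pmax(y, 0)
  f1 <- fit_monoexponential(echo_train(default_te, y))
  f2 <- fit_monoexponential(echo_train(default_te, 3.5 * y))
  expect_equal(f1$t2star_hat, f2$t2star_hat, tolerance = 1e-6)

  perm <- sample(12)
  f3 <- fit_monoexponential(echo_train(default_te[perm], y[perm]))
  expect_identical(f1$t2star_hat, f3$t2star_hat)
  expect_identical(f1$r_squared, f3$r_squared)
})

test_that("nonlinear fit matches a brute-force grid oracle on short trains", {
  set.seed(9)
  for (i in 1:12) {
    ne <- sample(3:5, 1)
    te <- sort(sample(default_te, ne))
    t2 <- runif(1, 1, 15)
    s0 <- runif(1, 400, 1500)
    y <- pmax(s0 * exp(-te / t2) + rnorm(ne, 0, 0.02 * s0), 0)
    fit <- fit_monoexponential(echo_train(te, y))
    oracle <- grid_fit_oracle(te, y)
    expect_equal(fit$t2star_hat, oracle$t2star, tolerance = 1e-3)
  }
})

test_that("degenerate inputs flag invalid fits instead of erroring", {
  dead <- echo_train(default_te, rep(0, 12))
  fit <- fit_monoexponential(dead)
  expect_false(fit$valid)
  expect_true(is.na(fit$t2star_hat))
})

test_that("truncation scan produces one level per dropped echo", {
  tr <- noiseless_train(1000, 5)
  trace <- truncation_scan(tr, min_echoes = 3)
  expect_length(trace, 10)
  expect_identical(vapply(trace, `[[`, integer(1), "n_echoes"), 12:3)
  expect_identical(trace[[1]]$removed_tes, numeric(0))
  expect_equal(trace[[10]]$removed_tes, default_te[4:12])
  expect_error(truncation_scan(tr, min_echoes = 2), "min_echoes")
})

test_that("noise-floor corruption biases the full fit up; truncation reduces it", {
  set.seed(77)
  p <- acquisition_protocol()
  n <- 300
  t2_full <- err_max <- err_full <- numeric(n)
  for (r in seq_len(n)) {
    tr <- simulate_echo_train(1000, 1.5, p, noise_sigma = 15)
    trace <- truncation_scan(tr)
    t2_full[r] <- trace[[1]]$t2star_hat
    r2 <- vapply(trace, `[[`, numeric(1), "r_squared")
    best <- trace[[which.max(r2)]]
    err_max[r] <- abs(best$t2star_hat - 1.5)
    err_full[r] <- abs(trace[[1]]$t2star_hat - 1.5)
  }
  # positive bias of the full-echo fit under the Rician floor
  expect_gt(mean(t2_full), 1.5)
  # the max-R2 truncation level is more accurate on average
  expect_lt(mean(err_max), mean(err_full))
})

test_that("selection policy: highest R2 bin, then maximum echoes", {
  lev <- function(r2, ne) ironaccord:::fit_result(1000, 5, r2, ne,
                                                  numeric(12 - ne))
  # one level clearly above every other bin
  trace <- structure(list(lev(0.981, 12), lev(0.9931, 11), lev(0.985, 10)),
                     class = "truncation_trace")
  expect_identical(select_fit(trace)$r_squared, 0.9931)

  # identical R2 everywhere: the full-echo level wins the echo tie-break
  trace <- structure(lapply(12:3, function(ne) lev(0.97, ne)),
                     class = "truncation_trace")
  expect_identical(select_fit(trace)$n_echoes, 12L)

  # two levels share the top bin: more echoes wins even with lower R2
  trace <- structure(list(lev(0.93, 12), lev(0.969, 5), lev(0.962, 7)),
                     class = "truncation_trace")
  sel <- select_fit(trace)
  expect_identical(sel$n_echoes, 7L)

  # global-max policy ignores bins
  expect_identical(select_fit(trace, "max_r2")$n_echoes, 5L)

  # invalid levels are never selected; all-invalid is a selection failure
  bad <- ironaccord:::fit_result(NA, NA, NA, 12L, numeric(0), valid = FALSE)
  trace <- structure(list(bad, lev(0.96, 11)), class = "truncation_trace")
  expect_identical(select_fit(trace)$n_echoes, 11L)
  expect_error(select_fit(structure(list(bad), class = "truncation_trace")),
               "no valid")
})

test_that("selected R2 never falls below the full-echo R2", {
  set.seed(5)
  p <- acquisition_protocol()
  for (r in 1:50) {
    tr <- simulate_echo_train(1000, runif(1, 1, 30), p, noise_sigma = 20)
    trace <- truncation_scan(tr)
    if (!trace[[1]]$valid) next
    sel <- select_fit(trace)
    expect_gte(sel$r_squared, trace[[1]]$r_squared)
  }
})

test_that("R2 bins use 0.01 spacing with a closed top and an under-bin", {
  b <- r2_bin(c(0.9931, 1.0, 0.95, 0.9599999, 0.94, 0.99))
  expect_identical(as.character(b),
                   c("[0.99,1.00]", "[0.99,1.00]", "[0.95,0.96)",
                     "[0.95,0.96)", "<0.95", "[0.99,1.00]"))
})
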