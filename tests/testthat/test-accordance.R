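test_that("crude accordance rate counts exact grade matches", {
  expect_identical(dar(c("a", "b"), c("a", "b")), 1)
  expect_identical(dar(c("severe", "mild", "normal"),
                       c("severe", "moderate", "normal")), 2 / 3)
  expect_identical(dar(c("a", "a"), c("b", "b")), 0)
  expect_error(dar(character(0), character(0)), "empty")
  expect_error(dar("a", c("a", "b")), "length")
})

make_records <- function(n, seed = 1) {
  set.seed(seed)
  grades <- grade_scale()$labels
  data.frame(
    r_squared = runif(n, 0.9, 1.0),
    n_echoes = sample(3:12, n, replace = TRUE),
    grade_ref = sample(grades, n, replace = TRUE),
    grade_hat = sample(grades, n, replace = TRUE),
    valid = TRUE, stringsAsFactors = FALSE
  )
}

test_that("stratification bins records and logs exclusions", {
  rec <- make_records(400)
  s <- stratify(rec, "r2")
  expect_identical(attr(s, "n_input"), 400L)
  expect_identical(attr(s, "n_excluded") + nrow(s), 400L)
  expect_true(all(s$r_squared >= 0.95))
  expect_identical(as.character(s$stratum), as.character(r2_bin(s$r_squared)))

  # boundary placement
  one <- data.frame(r_squared = c(0.9931, 1.0), n_echoes = c(4L, 5L),
                    grade_ref = "mild", grade_hat = "mild", valid = TRUE)
  expect_identical(as.character(stratify(one, "r2")$stratum),
                   rep("[0.99,1.00]", 2))

  st <- stratify(rec, "te")
  expect_setequal(unique(as.integer(as.character(st$stratum))), 3:12)
  sl <- stratify(rec, "lic")
  expect_identical(levels(sl$stratum), grade_scale()$labels)

  # invalid fits are excluded even with high R2
  rec2 <- rec; rec2$valid[1:7] <- FALSE; rec2$r_squared[1:7] <- 0.99
  s2 <- stratify(rec2, "r2")
  expect_identical(attr(s2, "n_excluded"),
                   attr(s, "n_excluded") + sum(rec$r_squared[1:7] >= 0.95))
})

test_that("direct standardization matches the printed formula by hand", {
  # two layers, pooled N1=10, N2=30; one subgroup with p1=0.5, p2=0.9
  counts <- rbind(gA = c(4, 20), gB = c(6, 10))
  correct <- rbind(gA = c(2, 18), gB = c(3, 9))    # gA: p1=0.5, p2=0.9
  rec <- records_from_table(counts, correct)
  out <- sdar(rec, "sub", "lay")
  expect_equal(out$sdar[out$subgroup == "g01"], (10 * 0.5 + 30 * 0.9) / 40,
               tolerance = 1e-12)

  # equal within-layer rates in every subgroup: SDAR is that common rate
  counts <- rbind(gA = c(10, 10), gB = c(20, 5))
  correct <- rbind(gA = c(8, 8), gB = c(16, 4))    # all p = 0.8
  out <- sdar(records_from_table(counts, correct), "sub", "lay")
  expect_equal(out$sdar, c(0.8, 0.8), tolerance = 1e-12)

  # degenerate weights: subgroup with cases only in layer 1 gets p1 under
  # renormalization
  counts <- rbind(gA = c(10, 0), gB = c(5, 8))
  correct <- rbind(gA = c(6, 0), gB = c(5, 4))
  out <- sdar(records_from_table(counts, correct), "sub", "lay")
  expect_equal(out$sdar[1], 0.6, tolerance = 1e-12)
  expect_identical(out$n_layers_missing, c(1L, 0L))

  # the drop rule keeps the original weights instead
  out2 <- sdar(records_from_table(counts, correct), "sub", "lay",
               missing_layer = "drop")
  expect_equal(out2$sdar[1], (15 / 23) * 0.6, tolerance = 1e-12)
})

test_that("sdar equals a brute-force oracle on random stratum tables", {
  set.seed(2024)
  for (i in 1:300) {
    nl <- sample(2:5, 1); ng <- sample(2:4, 1)
    counts <- matrix(sample(0:8, nl * ng, replace = TRUE), ng, nl)
    # keep every layer pooled-nonempty
    counts[1, colSums(counts) == 0] <- 1
    correct <- matrix(0L, ng, nl)
    correct[counts > 0] <- vapply(counts[counts > 0],
                                  function(n) sample(0:n, 1), integer(1))
    rec <- records_from_table(counts, correct)
    for (rule in c("renormalize", "drop")) {
      got <- sdar(rec, "sub", "lay", missing_layer = rule)
      want <- sdar_bruteforce(counts, correct, rule == "renormalize")
      present <- rowSums(counts) > 0
      expect_equal(got$sdar, want[present], tolerance = 1e-12)
    }
  }
})

test_that("sdar is invariant to layer relabeling and bounded by layer rates", {
  counts <- rbind(gA = c(5, 9, 2), gB = c(7, 3, 6))
  correct <- rbind(gA = c(4, 5, 1), gB = c(6, 2, 3))
  rec <- records_from_table(counts, correct)
  out <- sdar(rec, "sub", "lay")

  # reorder layers: results unchanged
  rec2 <- rec
  rec2$lay <- chartr("123", "321", rec2$lay)
  out2 <- sdar(rec2, "sub", "lay")
  expect_equal(out$sdar, out2$sdar, tolerance = 1e-12)

  # bounded by min/max within-layer rate per subgroup
  for (g in 1:2) {
    p <- correct[g, ] / counts[g, ]
    expect_gte(out$sdar[g], min(p) - 1e-12)
    expect_lte(out$sdar[g], max(p) + 1e-12)
  }
})

test_that("double standardization reduces correctly in degenerate layouts", {
  # 2x2 toy layout enumerated by hand
  # layers: v1 in {x, y}; v2 in {u, v}
  rec <- data.frame(
    sub = rep(c("A", "B"), each = 8),
    v1  = rep(c("x", "x", "y", "y"), 4),
    v2  = rep(c("u", "v"), 8),
    stringsAsFactors = FALSE
  )
  set.seed(8)
  rec$grade_ref <- "mild"
  rec$grade_hat <- ifelse(runif(16) < 0.6, "mild", "severe")
  got <- double_standardize(rec, "sub", c("v1", "v2"))

  # hand evaluation: per v2 level, sdar over v1; then weight by pooled v2
  hand <- sapply(c("A", "B"), function(g) {
    lv <- sapply(c("u", "v"), function(z) {
      sub <- rec[rec$v2 == z, ]
      ni <- table(sub$v1)
      p <- sapply(names(ni), function(l) {
        sel <- sub$sub == g & sub$v1 == l
        if (!any(sel)) NA else mean(sub$grade_hat[sel] == sub$grade_ref[sel])
      })
      ok <- !is.na(p)
      sum((ni[ok] / sum(ni[ok])) * p[ok])
    })
    nz <- table(rec$v2)
    sum((nz / sum(nz)) * lv)
  })
  expect_equal(got$sdar, unname(hand), tolerance = 1e-12)

  # constant layers collapse to the crude rate
  rec$v1 <- "x"; rec$v2 <- "u"
  flat <- double_standardize(rec, "sub", c("v1", "v2"))
  expect_equal(flat$sdar, flat$dar, tolerance = 1e-12)

  # single-level second variable reduces to plain sdar over the first
  rec2 <- rec; rec2$v1 <- rep(c("x", "y"), 8)
  red <- double_standardize(rec2, "sub", c("v1", "v2"))
  ref <- sdar(rec2, "sub", "v1")
  expect_equal(red$sdar, ref$sdar, tolerance = 1e-12)
})
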