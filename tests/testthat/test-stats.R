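# Textbook Welch oracle, written independently of the implementation.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Exhaustive-permutation two-sided p-value for small samples.
perm_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pool), n)
  obs <- abs(mean(a) - mean(b))
  diffs <- apply(idx, 2, function(i) abs(mean(pool[i]) - mean(pool[-i])))
  mean(diffs >= obs - 1e-12)
}

test_that("sem is the sample standard deviation over sqrt(n)", {
  expect_equal(sem(c(1, 1, 1)), 0)
  expect_equal(sem(c(0, 2)), 1) # sd = sqrt(2); sqrt(2)/sqrt(2) = 1
  expect_true(is.na(sem(5)))
  expect_true(is.na(sem(numeric())))
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  expect_equal(sem(x), sd(x) / sqrt(8))
})

test_that("welch_t matches the textbook formula", {
  a <- c(1, 2, 3, 4)
  b <- c(3, 4, 5, 6)
  got <- welch_t(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  # a second, unbalanced case
  a2 <- c(10, 11, 14, 13, 12, 9)
  b2 <- c(15, 19, 16)
  got2 <- welch_t(a2, b2)
  want2 <- welch_oracle(a2, b2)
  expect_equal(got2$t, want2$t, tolerance = 1e-12)
  expect_equal(got2$df, want2$df, tolerance = 1e-12)
  expect_equal(got2$p, want2$p, tolerance = 1e-12)
})

test_that("welch_t agrees with an exhaustive permutation test on tiny n", {
  cases <- list(
    list(a = c(1, 2, 3, 4), b = c(3, 4, 5, 6)),
    list(a = c(0.1, 0.4, 0.2), b = c(0.6, 0.9, 0.7, 0.8)),
    list(a = c(5, 6, 7, 8), b = c(5.5, 6.5, 7.5))
  )
  for (cs in cases) {
    p_t <- welch_t(cs$a, cs$b)$p
    p_perm <- perm_p(cs$a, cs$b)
    # the permutation p is discrete on tiny n; ask for the same order of
    # magnitude of evidence, not numeric equality
    expect_lt(abs(p_t - p_perm), 0.12)
    expect_equal(p_t < 0.05, p_perm < 0.05)
  }
})

test_that("identical samples give t = 0, p = 1; shifts increase |t|", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  a <- c(1, 2, 3, 4)
  t1 <- abs(welch_t(a, a + 1)$t)
  t2 <- abs(welch_t(a, a + 2)$t)
  expect_gt(t2, t1)
  # antisymmetry
  b <- c(2, 5, 6, 9)
  expect_equal(welch_t(a, b)$t, -welch_t(b, a)$t)
  expect_equal(welch_t(a, b)$p, welch_t(b, a)$p)
  # degenerate sizes are an error
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("stars follow the p-value thresholds", {
  expect_equal(signif_stars(c(0.2, 0.049, 0.009, 0.0009, NA)),
    c("", "*", "**", "***", "")
  )
})

test_that("compare_groups populates means, SEMs, test and stars", {
  df <- tibble::tibble(
    group = rep(c("opposition", "control"), each = 4),
    pct = c(30, 32, 28, 31, 2, 1, 3, 2)
  )
  cmp <- compare_groups(df, statistic_name = "rule frequency (%)")
  expect_equal(cmp$summary$mean[cmp$summary$group == "opposition"], 30.25)
  expect_equal(cmp$summary$mean[cmp$summary$group == "control"], 2)
  o <- welch_oracle(df$pct[df$group == "control"], df$pct[df$group == "opposition"])
  expect_equal(cmp$t, o$t)
  expect_equal(cmp$p, o$p)
  expect_true(cmp$stars %in% c("*", "**", "***"))
  expect_equal(cmp$stars, signif_stars(o$p))

  # equal groups carry no stars
  eq <- compare_groups(tibble::tibble(
    group = rep(c("a", "b"), each = 3), pct = rep(c(1, 2, 3), 2)
  ))
  expect_equal(eq$stars, "")

  # not-two-labels is an error
  expect_error(
    compare_groups(tibble::tibble(group = "a", pct = 1:3)),
    "exactly 2"
  )
  # an undersized group still reports means but no test
  expect_warning(
    small <- compare_groups(tibble::tibble(
      group = c("a", "b", "b"), pct = c(1, 2, 3)
    )),
    "fewer than 2"
  )
  expect_true(is.na(small$p))
  expect_equal(nrow(small$summary), 2)
})

test_that("tidy, glance and autoplot work on comparisons", {
  df <- tibble::tibble(
    group = rep(c("a", "b"), each = 3),
    pct = c(1, 2, 3, 7, 8, 9)
  )
  cmp <- compare_groups(df)
  td <- tidy(cmp)
  expect_equal(nrow(td), 2)
  expect_true(all(c("group", "n", "mean", "sem", "p", "stars") %in% names(td)))
  gl <- glance(cmp)
  expect_equal(nrow(gl), 1)
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("Student's variant is available and differs under imbalance", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  b <- c(10, 30, 50)
  w <- welch_t(a, b)
  s <- welch_t(a, b, var_equal = TRUE)
  expect_false(isTRUE(all.equal(w$df, s$df)))
  expect_equal(s$df, length(a) + length(b) - 2)
})

test_that("Holm adjustment is available across a comparison family", {
  mk <- function(shift) {
    compare_groups(tibble::tibble(
      group = rep(c("a", "b"), each = 4),
      pct = c(1, 2, 3, 4, 1 + shift, 2 + shift, 3 + shift, 4 + shift)
    ), statistic_name = paste0("shift", shift))
  }
  fam <- list(mk(0.5), mk(3), mk(10))
  adj <- adjust_comparisons(fam)
  expect_true(all(adj$p_adj >= adj$p))
  expect_equal(adj$p_adj, p.adjust(adj$p, "holm"))
})
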