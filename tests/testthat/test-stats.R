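test_that("Mann-Whitney U matches hand-enumerated exact p-values", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)   # 2 / choose(6, 3)
  expect_true(r$exact)
  r2 <- mannWhitneyU(c(1, 2), c(3))
  expect_equal(r2$U, 0)
  expect_equal(r2$p_value, 2 / 3)
  # identical samples under the approximation: U = n^2/2, p = 1
  x <- c(1, 2, 3, 4)
  r3 <- mannWhitneyU(x, x)
  expect_equal(r3$U, length(x)^2 / 2)
  expect_equal(r3$p_value, 1)
  expect_false(r3$exact)
  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney agrees with brute-force enumeration on random data", {
  set.seed(31)
  for (i in 1:20) {
    x <- round(stats::rnorm(sample(3:6, 1)), 2)
    y <- round(stats::rnorm(sample(3:6, 1), mean = stats::runif(1, 0, 2)), 2)
    if (anyDuplicated(c(x, y))) next
    r <- mannWhitneyU(x, y)
    expect_equal(r$p_value, enumMannWhitneyP(x, y), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis matches the hand-rank formula", {
  r <- kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$H, 12 / (6 * 7) * 2 * (1.5^2 + 3.5^2 + 5.5^2) - 3 * 7,
               tolerance = 1e-12)
  expect_equal(r$H, handKruskalH(list(c(1, 2), c(3, 4), c(5, 6))),
               tolerance = 1e-12)
  expect_equal(r$df, 2)
  # identical groups: H = 0, p = 1
  g <- c(1, 2, 3)
  r2 <- kruskalWallis(list(g, g, g))
  expect_equal(r2$H, 0, tolerance = 1e-12)
  expect_equal(r2$p_value, 1)
  expect_error(kruskalWallis(list(1:3)), "two groups")
  # random data with ties against the independent transcription
  set.seed(37)
  for (i in 1:10) {
    samples <- lapply(1:3, function(j) sample(1:8, 10, replace = TRUE))
    expect_equal(kruskalWallis(samples)$H, handKruskalH(samples),
                 tolerance = 1e-10)
  }
})

test_that("two-group Kruskal-Wallis is consistent with Mann-Whitney", {
  set.seed(41)
  x <- stats::rnorm(200)
  y <- stats::rnorm(200, 0.15)
  pk <- kruskalWallis(list(x, y))$p_value
  pm <- mannWhitneyU(x, y)$p_value
  expect_lt(abs(pk - pm), 0.01)
})

test_that("Dunn's test matches the published rank formula with ties", {
  set.seed(43)
  for (i in 1:10) {
    samples <- list(a = sample(1:12, 9, replace = TRUE),
                    b = sample(1:12, 7, replace = TRUE) + 2,
                    c = sample(1:12, 11, replace = TRUE))
    d <- dunnBonferroni(samples)
    expect_equal(d$z[1], handDunnZ(samples, 1, 2), tolerance = 1e-10)
    expect_equal(d$z[2], handDunnZ(samples, 1, 3), tolerance = 1e-10)
    expect_equal(d$z[3], handDunnZ(samples, 2, 3), tolerance = 1e-10)
    # Bonferroni: three pairs, capped at 1
    expect_equal(d$p_adjusted, pmin(1, 3 * d$p_value))
  }
  # identical groups: adjusted p = 1
  g <- c(2, 2, 2, 2)
  di <- dunnBonferroni(list(x = g, y = g, z = g))
  expect_true(all(di$p_adjusted == 1))
  expect_error(dunnBonferroni(list(a = 1:3, b = 4:6), pairs = list(c("a", "q"))),
               "does not match")
})

test_that("Cohen's d uses the pooled n-1 standard deviation", {
  expect_equal(cohensD(c(0, 1), c(1, 2)), -1 / sqrt(0.5))
  expect_equal(cohensD(1:10, 1:10), 0)
  set.seed(47)
  x <- stats::rnorm(20); y <- stats::rnorm(25, 1)
  expect_equal(cohensD(x, y), -cohensD(y, x))
  sp <- sqrt((19 * stats::var(x) + 24 * stats::var(y)) / 43)
  expect_equal(cohensD(x, y), (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  expect_error(cohensD(c(1, 1), c(1, 1)), "undefined")
  expect_error(cohensD(1, c(1, 2)), "at least 2")
})

test_that("post hoc power is calibrated at the null and monotone", {
  expect_equal(posthocPower(0, 30, 30, alpha = 0.05), 0.05, tolerance = 1e-12)
  expect_equal(posthocPower(0, 10, 50, alpha = 0.10), 0.10, tolerance = 1e-12)
  # monotone in |d| and n
  ds <- seq(0, 1.5, by = 0.25)
  pw <- vapply(ds, posthocPower, numeric(1), n1 = 30, n2 = 30)
  expect_true(all(diff(pw) > 0))
  ns <- c(5, 10, 20, 40, 80)
  pwn <- vapply(ns, function(n) posthocPower(0.4, n, n), numeric(1))
  expect_true(all(diff(pwn) > 0))
  # the two-group clinical scenario: d = 0.35, n = 46 vs 55
  expect_equal(posthocPower(0.35, 46, 55), 0.4176, tolerance = 2e-3)
  # noncentral-t variant stays close to stats::power.t.test
  ref <- stats::power.t.test(n = 40, delta = 0.35, sd = 1,
                             sig.level = 0.05)$power
  expect_equal(posthocPower(0.35, 40, 40, method = "t"), ref,
               tolerance = 5e-3)
  expect_error(posthocPower(0.3, 30, 30, alpha = 1.2), "alpha")
})

test_that("rank tests are invariant to shifts and within-group order", {
  set.seed(53)
  x <- stats::rnorm(15); y <- stats::rnorm(12, 0.5); z <- stats::rnorm(18, 1)
  base <- kruskalWallis(list(x, y, z))
  shifted <- kruskalWallis(list(x + 100, y + 100, z + 100))
  expect_equal(base$H, shifted$H, tolerance = 1e-12)
  perm <- kruskalWallis(list(sample(x), sample(y), sample(z)))
  expect_equal(base$H, perm$H, tolerance = 1e-12)
  expect_equal(mannWhitneyU(x, y)$p_value,
               mannWhitneyU(x + 3, y + 3)$p_value, tolerance = 1e-12)
})

test_that("the comparison battery produces the full results table", {
  set.seed(59)
  n <- 30
  summ <- data.frame(group = rep(c("g1", "g2", "g3"), each = n))
  for (sp in c("htp5", "fc5ht", "v5ht", "e5ht", "hiaa5")) {
    shift <- ifelse(summ$group == "g1", 0.3, 0)
    summ[[paste0(sp, "_mean")]] <- stats::rnorm(3 * n) + shift
  }
  out <- compareGroups(summ)
  # per species: one omnibus row + three pairwise rows
  expect_equal(nrow(out), 5 * 4)
  expect_setequal(unique(out$test), c("kruskal_wallis", "dunn"))
  dunn <- out[out$test == "dunn", ]
  expect_true(all(dunn$p_adjusted >= dunn$p_value - 1e-15))
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  # two-group battery adds effect size and power
  two <- compareGroups(summ[summ$group != "g3", ])
  expect_setequal(unique(two$test), "mann_whitney")
  expect_true(all(is.finite(two$effect_size_d)))
  expect_true(all(two$power >= 0 & two$power <= 1))
})
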