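# Frozen pooled-count oracles: independent column sums of the packaged
# per-testis fixtures (recomputed by spreadsheet-style summation outside the
# package code path).
table7_pooled <- list(
  "Scrambled RNAi" = c(normal_bundle = 72, lagging_bundle = 18, kinked = 10,
                       knotted = 0, needle_eyed = 0, decondensed = 0),
  "AAGAG RNAi" = c(normal_bundle = 8, lagging_bundle = 32, kinked = 47,
                   knotted = 15, needle_eyed = 10, decondensed = 2),
  "AAGAG RNA (Rescue)" = c(normal_bundle = 97, lagging_bundle = 56,
                           kinked = 89, knotted = 6, needle_eyed = 2,
                           decondensed = 0))
table8_pooled <- list(
  "Scrambled RNAi" = c(normal_canoe = 32, abnormal_canoe = 9),
  "AAGAG RNAi" = c(normal_canoe = 12, abnormal_canoe = 32),
  "AAGAG RNA (Rescue)" = c(normal_canoe = 48, abnormal_canoe = 71))

test_that("pooled proportions reproduce the fixture column sums exactly", {
  for (fx in c("table7", "table8")) {
    tab <- defect_table_fixture(fx)
    pp <- pooled_proportions(tab)
    oracle <- if (fx == "table7") table7_pooled else table8_pooled
    for (g in names(oracle)) {
      got <- pp[pp$genotype == g, ]
      expect_equal(setNames(got$count, got$category), oracle[[g]],
                   ignore_attr = FALSE)
      expect_equal(unique(got$total), sum(oracle[[g]]))
      expect_equal(sum(got$percent), 100)
      expect_equal(got$percent, 100 * oracle[[g]] / sum(oracle[[g]]),
                   ignore_attr = TRUE)
    }
  }
  # headline control values: 72% normal post-canoe, 41 canoe bundles scored
  pp7 <- pooled_proportions(defect_table_fixture("table7"))
  expect_equal(pp7$percent[pp7$genotype == "Scrambled RNAi" &
                           pp7$category == "normal_bundle"], 72)
  pp8 <- pooled_proportions(defect_table_fixture("table8"))
  expect_equal(unique(pp8$total[pp8$genotype == "Scrambled RNAi"]), 41L)
})

test_that("pooling is invariant to row order and row splitting", {
  srt <- function(x) {
    x <- x[order(x$genotype, x$category), ]
    rownames(x) <- NULL
    x
  }
  tab <- defect_table_fixture("table7")
  pp <- srt(pooled_proportions(tab))
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(srt(pooled_proportions(perm)), pp)
  # split the first testis of each genotype into two half-rows
  splt <- tab
  first <- !duplicated(tab$genotype)
  cnt <- setdiff(names(tab), c("genotype", "testis"))
  half <- tab[first, ]
  half[cnt] <- lapply(half[cnt], function(x) x %/% 2)
  splt[first, cnt] <- tab[first, cnt] - half[cnt]
  half$testis <- half$testis + 100L
  expect_equal(srt(pooled_proportions(rbind(splt, half))), pp)
})

test_that("single-testis proportions and degenerate tables", {
  one <- data.frame(genotype = "g", testis = 1, a = 5, b = 1, c = 0, d = 0,
                    e = 0, f = 0)
  pp <- pooled_proportions(one)
  expect_equal(pp$percent, c(500 / 6, 100 / 6, 0, 0, 0, 0))
  zero <- one
  zero[3:8] <- 0
  expect_error(pooled_proportions(zero), "all-zero")
})

test_that("welch_t_test matches the reference implementation to 1e-10", {
  set.seed(60)
  for (i in 1:100) {
    n1 <- sample(3:40, 1)
    n2 <- sample(3:40, 1)
    x <- rnorm(n1, mean = runif(1, -5, 5), sd = runif(1, 0.2, 4))
    y <- rnorm(n2, mean = runif(1, -5, 5), sd = runif(1, 0.2, 4))
    mine <- welch_t_test(x, y)
    ref <- t.test(x, y, var.equal = FALSE)
    expect_lt(abs(unname(mine$statistic) - unname(ref$statistic)), 1e-10)
    expect_lt(abs(unname(mine$parameter) - unname(ref$parameter)), 1e-10)
    expect_lt(abs(mine$p.value - ref$p.value), 1e-10)
  }
})

test_that("welch_t_test limits and degenerate inputs", {
  x <- c(1, 2, 3, 4, 5)
  r <- welch_t_test(x, x)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
  # antisymmetry
  set.seed(61)
  y <- rnorm(8)
  z <- rnorm(8, 1)
  expect_equal(unname(welch_t_test(y, z)$statistic),
               -unname(welch_t_test(z, y)$statistic))
  expect_equal(welch_t_test(y, z)$p.value, welch_t_test(z, y)$p.value)
  # equal-variance limit: df = n1 + n2 - 2 when variances and sizes match
  a <- c(1, 2, 3, 4)
  b <- c(11, 12, 13, 14)
  expect_equal(unname(welch_t_test(a, b)$parameter), 6, tolerance = 1e-9)
  expect_error(welch_t_test(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("viability ratios exclude Tubby-free vials and compare groups", {
  # third vial dropped (no Tubby), warning raised
  expect_warning(viability_ratio(c(8, 0, 5), c(8, 10, 0)), "excluded")
  expect_equal(suppressWarnings(
    viability_ratio(c(8, 0, 5), c(8, 10, 0))$vials$ratio), c(1, 0))
  expect_error(viability_ratio(c(1, 2), c(0, 0)), "no valid vials")

  # power on simulated vials: true ratios 1.0 vs 0.5, 11 vials per group
  set.seed(62)
  n_rep <- 500
  rejected <- 0L
  for (r in seq_len(n_rep)) {
    tot <- rep(25L, 22)  # mid-range brood size per vial
    p <- rep(c(0.5, 1 / 3), each = 11)  # ratio r maps to p = r / (1 + r)
    rnai <- rbinom(22, tot, p)
    res <- suppressWarnings(
      viability_ratio(rnai, tot - rnai,
                      group = rep(c("g1", "g2"), each = 11)))
    if (!is.null(res$test) && res$test$p.value < 0.05)
      rejected <- rejected + 1L
  }
  expect_gte(rejected / n_rep, 0.90)
})

test_that("fertility summaries exclude invalid males and match hand values", {
  # one set, 12 valid males, 11 fertile
  o <- data.frame(set = "s1", fertile = c(rep(TRUE, 11), FALSE),
                  valid = TRUE)
  f <- fertility_summary(o)
  expect_equal(f$per_set$percent, 100 * 11 / 12)

  # a male that died early is excluded from the denominator
  o2 <- rbind(o, data.frame(set = "s1", fertile = FALSE, valid = FALSE))
  expect_equal(fertility_summary(o2)$per_set$n_valid, 12L)

  # sets with percents {94, 90, 97}: mean 93.67, sample sd 3.51
  mk <- function(set, pct) data.frame(
    set = set, fertile = c(rep(TRUE, pct), rep(FALSE, 100 - pct)),
    valid = TRUE)
  f3 <- fertility_summary(rbind(mk("a", 94), mk("b", 90), mk("c", 97)))
  expect_equal(round(f3$mean, 2), 93.67)
  expect_equal(round(f3$sd, 2), 3.51)

  expect_warning(
    fertility_summary(rbind(o, data.frame(set = "s2", fertile = TRUE,
                                          valid = FALSE))),
    "no valid males")
  expect_error(suppressWarnings(
    fertility_summary(data.frame(set = "x", fertile = TRUE,
                                 valid = FALSE))), "no parental")
})
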