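test_that("one-way ANOVA matches first-principles computation", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  res <- one_way_anova(g)
  expect_equal(res$f_stat, 3.0)
  expect_equal(res$f_stat, anova_f_oracle(g))
  # identical groups: no between-group variance
  expect_equal(one_way_anova(list(a = 1:3, b = 1:3))$f_stat, 0)
  # random designs against the oracle
  set.seed(3)
  for (i in 1:10) {
    g2 <- lapply(stats::setNames(2:4, c("x", "y", "z")),
                 function(n) rnorm(n + 2))
    expect_equal(one_way_anova(g2)$f_stat, anova_f_oracle(g2))
  }
  expect_error(one_way_anova(list(a = 1, b = 1:3)), "2 finite")
  expect_error(one_way_anova(list(a = 1:3)), "two groups")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(4 + i)
    y <- rnorm(6, mean = 0.5)
    f <- one_way_anova(list(x = x, y = y))$f_stat
    t2 <- stats::t.test(x, y, var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2))
  }
})

test_that("ANOVA F is location-invariant and scale-invariant", {
  set.seed(8)
  g <- list(a = rnorm(5), b = rnorm(5, 1), c = rnorm(4, 2))
  f0 <- one_way_anova(g)$f_stat
  expect_equal(one_way_anova(lapply(g, `+`, 100))$f_stat, f0)
  expect_equal(one_way_anova(lapply(g, `*`, 3.7))$f_stat, f0)
})

test_that("mean-centered Levene equals ANOVA on absolute deviations", {
  set.seed(13)
  for (i in 1:5) {
    g <- list(a = rnorm(5, sd = 1), b = rnorm(6, sd = 2 + i),
              c = rnorm(4, sd = 0.5))
    res <- levene_mean(g)
    dev <- lapply(g, function(x) abs(x - mean(x)))
    expect_equal(res$w_stat, one_way_anova(dev)$f_stat)
    # independent cross-check against the standard implementation
    df <- data.frame(value = unlist(g),
                     group = factor(rep(names(g), lengths(g))))
    ref <- car::leveneTest(value ~ group, data = df, center = mean)
    expect_equal(res$w_stat, ref[1, "F value"], tolerance = 1e-12)
    expect_equal(res$p_value, ref[1, "Pr(>F)"], tolerance = 1e-12)
  }
  # identical spread patterns give W = 0
  expect_equal(levene_mean(list(a = c(0, 1), b = c(10, 11)))$w_stat, 0)
  expect_error(levene_mean(list(a = c(1, 1), b = c(2, 2))), "undefined")
})

test_that("KS normality statistic equals the brute-force sup-distance", {
  set.seed(21)
  samples <- c(list(c(1, 2, 3, 4, 5)),
               replicate(5, rnorm(10 + rpois(1, 10)), simplify = FALSE))
  for (x in samples) {
    res <- ks_normality(x)
    d <- ks_d_oracle(x, function(q) pnorm(q, mean(x), sd(x)))
    expect_equal(res$d_stat, d, tolerance = 1e-12)
    expect_gte(res$d_stat, 0)
    expect_lte(res$d_stat, 1)
  }
  expect_error(ks_normality(c(-1, 1)), "3")
  expect_error(ks_normality(c(2, 2, 2)), "zero")
})

test_that("letter displays encode exactly the non-significant sharing", {
  # no significant pair: everyone shares "a"
  pw <- data.frame(group1 = c("a", "a", "b"), group2 = c("b", "c", "c"),
                   significant = FALSE)
  expect_equal(unname(compact_letters(pw, c("a", "b", "c"))),
               c("a", "a", "a"))
  # all pairs significant: distinct letters in supplied order
  pw$significant <- TRUE
  expect_equal(unname(compact_letters(pw, c("a", "b", "c"))),
               c("a", "b", "c"))
  # only the extremes differ: middle group bridges both letters
  pw$significant <- c(FALSE, TRUE, FALSE)
  expect_equal(compact_letters(pw, c("a", "b", "c")),
               c(a = "a", b = "ab", c = "b"))
  expect_error(compact_letters(pw[1:2, ], c("a", "b", "c")), "incomplete")
})

test_that("letter displays satisfy the sharing property on all patterns", {
  for (k in 3:4) {
    gs <- letters[seq_len(k)]
    pairs <- t(utils::combn(gs, 2))
    n_pairs <- nrow(pairs)
    for (code in 0:(2^n_pairs - 1)) {
      sig <- as.logical(bitwAnd(code, 2^(seq_len(n_pairs) - 1)) > 0)
      pw <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                       significant = sig)
      m <- matrix(FALSE, k, k, dimnames = list(gs, gs))
      m[cbind(pw$group1, pw$group2)] <- sig
      m[cbind(pw$group2, pw$group1)] <- sig
      lt <- compact_letters(pw, gs)
      expect_true(cld_property_holds(lt, m),
                  info = paste("k =", k, "pattern", code))
    }
  }
})

test_that("group comparison letters groups by descending mean", {
  g <- list(low = c(1.0, 1.1, 0.9), mid = c(1.05, 1.15, 0.95),
            high = c(9.0, 9.2, 8.8))
  cmp <- group_compare(g)
  expect_lt(cmp$anova$p_value, 0.05)
  # the clearly separated group shares no letter with the others
  expect_false(grepl(cmp$letters[["high"]], cmp$letters[["low"]]))
  expect_equal(cmp$letters[["high"]], "a")  # highest mean lettered first
  expect_equal(cmp$letters[["low"]], cmp$letters[["mid"]])
  expect_equal(nrow(cmp$summary), 3)
  # unadjusted pairwise-t alternative agrees on significance and is less
  # conservative away from the deep tail (where the studentized-range
  # tail itself loses numerical accuracy)
  cmp_t <- group_compare(g, method = "t")
  expect_equal(cmp_t$pairwise$p_value < 0.05, cmp$pairwise$p_value < 0.05)
  mild <- cmp$pairwise$p_value > 1e-6
  expect_true(all(cmp_t$pairwise$p_value[mild] <=
                    cmp$pairwise$p_value[mild] + 1e-12))
})
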