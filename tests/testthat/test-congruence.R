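test_that("dominant grouping handles unanimity, majorities and ties", {
  asg <- setNames(c("Blue", "Blue", "Blue"), format_quote_id(c(23, 49, 54)))
  dg <- dominant_grouping(c(23, 49, 54), asg)
  expect_identical(dg$dominant, "Blue")
  expect_equal(dg$percentage, 100)

  # 9-of-11 majority: 81.82% unrounded, "82%" under the integer policy
  labs <- c(rep("Blue", 9), "Green", "Pink")
  asg11 <- setNames(labs, format_quote_id(1:11))
  dg11 <- dominant_grouping(1:11, asg11)
  expect_equal(dg11$percentage, 900 / 11)
  expect_identical(render_percentage(dg11$percentage, "integer"), "82%")

  # 6-of-7 majority renders "85.7%" under the one-decimal policy
  asg7 <- setNames(c(rep("Pink", 6), "Red"), format_quote_id(1:7))
  dg7 <- dominant_grouping(1:7, asg7)
  expect_identical(render_percentage(dg7$percentage, "one_decimal"), "85.7%")

  # 4/4/3 tie: no dominant grouping, breakdown ordered by count then label
  labs_tie <- c(rep("green", 4), rep("pink", 4), rep("blue", 3))
  asg_tie <- setNames(sample(labs_tie), format_quote_id(1:11))
  dg_tie <- dominant_grouping(1:11, asg_tie)
  expect_true(is.na(dg_tie$dominant))
  expect_true(is.na(dg_tie$percentage))
  expect_identical(pte:::breakdown_string(dg_tie$counts),
                   "4 green; 4 pink; 3 blue")
})

test_that("percentages are invariant to quote order and relabelling", {
  set.seed(67)
  asg <- setNames(sample(c("a", "b"), 10, replace = TRUE, prob = c(.7, .3)),
                  format_quote_id(1:10))
  q <- 1:10
  p1 <- dominant_grouping(q, asg)$percentage
  p2 <- dominant_grouping(sample(q), asg)$percentage
  relab <- setNames(c(a = "Z", b = "Y")[asg], names(asg))
  p3 <- dominant_grouping(q, relab)$percentage
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("a missing theme quote is reported by id", {
  asg <- setNames("blue", "ID01")
  expect_error(dominant_grouping(c(1, 2), asg), "ID02",
               class = "pte_coverage_error")
})

test_that("congruence tables preserve theme order and recount correctly", {
  set.seed(71)
  asg <- setNames(sample(c("red", "blue", "green"), 30, replace = TRUE),
                  format_quote_id(1:30))
  themes <- theme_collection(
    paste("theme", 1:5),
    lapply(1:5, function(i) sample(1:30, sample(3:8, 1))))
  tab <- theme_congruence_table(themes, asg, rounding = "full")
  expect_identical(tab$theme, paste("theme", 1:5))
  for (i in 1:5) {
    labs <- asg[format_quote_id(themes$quotes[[i]])]
    counts <- sort(table(labs), decreasing = TRUE)
    if (sum(counts == counts[1]) > 1) {
      expect_true(is.na(tab$pct[i]))
      expect_identical(tab$percentage[i], "N/A")
      expect_match(tab$dominant[i], "^No dominant grouping")
    } else {
      expect_equal(tab$pct[i], 100 * counts[[1]] / length(labs))
    }
  }
})

test_that("rounding policies render like the published tables", {
  expect_identical(render_percentage(100, "integer"), "100%")
  expect_identical(render_percentage(100, "one_decimal"), "100%")
  expect_identical(render_percentage(81.8181818, "integer"), "82%")
  expect_identical(render_percentage(85.7142857, "one_decimal"), "85.7%")
  expect_identical(render_percentage(NA_real_), "N/A")
})

test_that("adjusted Rand index matches first-principles pair counting", {
  expect_equal(adjusted_rand_index(setNames(c(1, 1, 2), format_quote_id(1:3)),
                                   setNames(c(1, 1, 2), format_quote_id(1:3))),
               1)
  # label-invariance
  a <- setNames(c(1, 1, 2, 2, 3), format_quote_id(1:5))
  b <- setNames(c("x", "x", "y", "y", "z"), format_quote_id(1:5))
  expect_equal(adjusted_rand_index(a, b), 1)
  # against the trivial one-community grouping of a non-trivial partition
  ones <- setNames(rep(1, 5), format_quote_id(1:5))
  expect_equal(adjusted_rand_index(a, ones), 0)

  set.seed(73)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    x <- setNames(sample.int(4, n, replace = TRUE), format_quote_id(1:n))
    y <- setNames(sample.int(3, n, replace = TRUE), format_quote_id(1:n))
    expect_equal(adjusted_rand_index(x, y), naive_ari(x, y),
                 tolerance = 1e-12)
    expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
  }
})

test_that("adjusted Rand index agrees with mclust on random pairs", {
  skip_if_not_installed("mclust")
  set.seed(79)
  for (rep in 1:10) {
    n <- sample(6:30, 1)
    x <- setNames(sample.int(5, n, replace = TRUE), format_quote_id(1:n))
    y <- setNames(sample.int(4, n, replace = TRUE), format_quote_id(1:n))
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(unname(x), unname(y)),
                 tolerance = 1e-12)
  }
})

test_that("mismatched quote sets are rejected with the difference listed", {
  a <- setNames(c(1, 2), format_quote_id(1:2))
  b <- setNames(c(1, 2), format_quote_id(2:3))
  expect_error(adjusted_rand_index(a, b), "ID01",
               class = "pte_coverage_error")
  expect_error(adjusted_rand_index(a, b), "ID03",
               class = "pte_coverage_error")
})

test_that("theme matching pairs the published social themes at 6/9", {
  co <- theme_collection("Social element/group dynamic",
                         list(c(14, 4, 2, 40, 49, 12, 80, 89)))
  ac <- theme_collection("A social environment",
                         list(c(2, 4, 12, 14, 80, 89, 10)))
  m <- match_theme_sets(co, ac)
  expect_equal(m$jaccard[1, 1], 6 / 9, tolerance = 1e-12)
  expect_identical(m$matches$n_shared, 6L)
  expect_identical(m$matches$shared,
                   paste(format_quote_id(c(2, 4, 12, 14, 80, 89)),
                         collapse = ", "))
})

test_that("theme matching is identity on equal sets, empty on disjoint", {
  th <- theme_collection(c("A", "B"), list(1:4, 5:8))
  m <- match_theme_sets(th, th)
  expect_equal(diag(m$jaccard), c(A = 1, B = 1))
  expect_identical(m$matches$theme_a, m$matches$theme_b)

  other <- theme_collection(c("C", "D"), list(9:12, 13:16))
  m2 <- match_theme_sets(th, other)
  expect_true(all(m2$jaccard == 0))
  expect_identical(nrow(m2$matches), 0L)
})

test_that("greedy matching is stable under theme permutation", {
  set.seed(83)
  a <- theme_collection(paste0("a", 1:4),
                        lapply(1:4, function(i) sample(1:40, 8)))
  b <- theme_collection(paste0("b", 1:4),
                        lapply(1:4, function(i) sample(1:40, 8)))
  m1 <- match_theme_sets(a, b)
  perm <- c(3, 1, 4, 2)
  b_perm <- theme_collection(b$labels[perm], b$quotes[perm])
  m2 <- match_theme_sets(a, b_perm)
  pairs <- function(m) {
    p <- paste(m$matches$theme_a, m$matches$theme_b)
    sort(p)
  }
  expect_true(all(m1$jaccard >= 0 & m1$jaccard <= 1))
  expect_identical(pairs(m1), pairs(m2))
})
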