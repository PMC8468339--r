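make_rows <- function(items_by_row, phase = "post", group = "control") {
  n <- nrow(items_by_row)
  response_table(sprintf("p%03d", seq_len(n)), rep(phase, n), rep(group, n),
                 items_by_row)
}

test_that("hits and null-expectation ratings score the stated examples", {
  part5 <- part_def("P", c(11, 12, 13, 17, 20))
  full <- matrix("dontknow", 3, 20)
  full[1, c(11, 12, 13, 17, 20)] <- "hit"                     # all five hit
  full[2, ] <- "dontknow"                                     # knows nothing
  full[3, c(11, 12, 13)] <- "hit"                             # 3 hit
  full[3, 17] <- "error"                                      # 1 error
  rt <- make_rows(full)
  expect_equal(score_hits(rt, part5), c(5, 0, 3))
  expect_equal(score_null_expectation(rt, part5), c(5, 0, 3 - 1 / 3),
               tolerance = 1e-12)
  all_err <- matrix("dontknow", 1, 20)
  all_err[1, c(11, 12, 13, 17, 20)] <- "error"
  expect_equal(score_null_expectation(make_rows(all_err), part5), -5 / 3,
               tolerance = 1e-12)
})

test_that("uniform guessing over four options has zero expected NE score", {
  set.seed(10)
  n <- 1e5
  guesses <- matrix(sample(c("hit", "error"), n * 5, TRUE,
                           prob = c(1 / 4, 3 / 4)), n, 5)
  rt <- make_rows(cbind(guesses, matrix("dontknow", n, 15)))
  sc <- score_null_expectation(rt, part_def("g", 1:5))
  expect_lt(abs(mean(sc)), 3 * sd(sc) / sqrt(n))
})

test_that("KR-20 and Cronbach's alpha reproduce the worked example", {
  m <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0), c(0, 0, 0))
  # oracle: direct formula evaluation under the stated conventions
  p <- colMeans(m); vtot <- var(rowSums(m))
  expect_equal(kr20(m), (3 / 2) * (1 - sum(p * (1 - p)) / vtot),
               tolerance = 1e-12)
  expect_equal(kr20(m), 0.9375, tolerance = 1e-12)
  expect_equal(cronbach_alpha(m),
               (3 / 2) * (1 - sum(apply(m, 2, var)) / vtot),
               tolerance = 1e-12)
  expect_equal(cronbach_alpha(m), 0.75, tolerance = 1e-12)
})

test_that("alpha is 1 for duplicated columns and ~0 for independent ones", {
  set.seed(11)
  x <- rbinom(50, 1, 0.5)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)
  set.seed(12)
  indep <- matrix(rnorm(1e4 * 4), ncol = 4)
  expect_lt(abs(cronbach_alpha(indep)), 0.05)
})

test_that("constant items contribute nothing to the KR-20 item-variance sum", {
  set.seed(19)
  m <- cbind(rbinom(30, 1, 0.5), rbinom(30, 1, 0.5), 1)
  p <- colMeans(m)
  expect_equal(p[3] * (1 - p[3]), 0)
  m2 <- m[, 1:2]
  k3 <- 3 / 2 * (1 - sum(p * (1 - p)) / var(rowSums(m)))
  expect_equal(kr20(m), k3, tolerance = 1e-12)
})

test_that("degenerate total variance raises an undefined-reliability error", {
  m <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_error(kr20(m), class = "mrisim_reliability_error")
  expect_error(cronbach_alpha(m), class = "mrisim_reliability_error")
})

test_that("KR-20 equals alpha on binary matrices up to variance convention", {
  set.seed(13)
  for (r in 1:25) {
    m <- random_binary_matrix(n = sample(8:20, 1), k = sample(3:6, 1))
    n <- nrow(m)
    # alpha uses n-1 item variances; KR-20 uses p*q = (n-1)/n * var
    p <- colMeans(m)
    alpha_nvar <- (ncol(m) / (ncol(m) - 1)) *
      (1 - sum(p * (1 - p)) / var(rowSums(m)))
    expect_equal(kr20(m), alpha_nvar, tolerance = 1e-12)
    expect_equal(cronbach_alpha(m),
                 (ncol(m) / (ncol(m) - 1)) *
                   (1 - (n / (n - 1)) * sum(p * (1 - p)) / var(rowSums(m))),
                 tolerance = 1e-12)
  }
})

test_that("greedy selection drops an anti-correlated item first (oracle)", {
  set.seed(14)
  core <- rbinom(40, 1, 0.5)
  noise <- function(p) ifelse(runif(40) < p, 1 - core, core)
  m <- cbind(noise(0.1), noise(0.15), noise(0.1), 1 - core, noise(0.12))
  part <- part_def("T", 1:5)
  picked <- select_items(m, part, 4)
  expect_false(4 %in% picked$items)
  # oracle: exhaustive search over all 4-item subsets
  combos <- utils::combn(5, 4)
  rels <- apply(combos, 2, function(cols) kr20(m[, cols]))
  expect_setequal(picked$items, combos[, which.max(rels)])
})

test_that("selection is the identity at full size and breaks ties by index", {
  set.seed(15)
  m <- random_binary_matrix(n = 15, k = 4)
  part <- part_def("T", c(2, 4, 6, 8))
  expect_identical(select_items(m, part, 4)$items, part$items)
  # exchangeable bad items: an exactly duplicated anti-correlated pair ties
  # both on reliability-after-removal and on item-total correlation, so the
  # lower index is dropped first
  core <- rbinom(60, 1, 0.5)
  noisy <- function(p) ifelse(runif(60) < p, 1 - core, core)
  bad <- 1 - core
  dup <- cbind(bad, bad, noisy(0.1), noisy(0.15), noisy(0.12))
  picked <- select_items(dup, part_def("T", 1:5), 4)
  expect_identical(picked$items, 2:5)
})

test_that("gains subtract matched pre from post and log exclusions", {
  post <- c(a = 5, b = 4, c = 3)
  pre <- c(a = 3, b = 4)
  expect_message(g <- gain(post, pre), "excluded 1")
  expect_equal(g, c(a = 2, b = 0))
  expect_equal(gain(post, post), c(a = 0, b = 0, c = 0))
  expect_equal(gain(post + 2, post), c(a = 2, b = 2, c = 2))
  expect_error(gain(c(x = 1), c(y = 2)), "no participants")
})

test_that("Cohen's d uses the pooled standard deviation", {
  expect_equal(cohen_d_from_stats(2.53, 1.36, 30, 1.63, 1.27, 30),
               0.9 / sqrt((1.36^2 + 1.27^2) / 2), tolerance = 1e-12)
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  expect_equal(cohen_d(x, y),
               (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2),
               tolerance = 1e-12)
})

test_that("the normality gate picks the t path for normal data", {
  set.seed(16)
  eg <- rnorm(30, 1); cg <- rnorm(30, 0)
  cmp <- compare_groups(eg, cg)
  expect_equal(cmp$test_used, "t")
  expect_equal(cmp$p_value, t.test(eg, cg, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  # discrete low-range scores fail normality -> rank path
  set.seed(17)
  eg2 <- rbinom(30, 5, 0.4); cg2 <- rbinom(30, 5, 0.4)
  cmp2 <- compare_groups(eg2, cg2)
  expect_equal(cmp2$test_used, "rank")
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("identical samples compare as indistinguishable", {
  set.seed(18)
  x <- rnorm(20)
  cmp <- compare_groups(x, x)
  expect_equal(cmp$effect_size_d, 0)
  expect_gt(cmp$p_value, 0.99)
  expect_equal(unname(cmp$n), c(20L, 20L))
})

test_that("response generation is deterministic and honours dontknow = 1", {
  a <- generate_responses(10, seed = 21)
  b <- generate_responses(10, seed = 21)
  expect_identical(a, b)
  expect_false(identical(a, generate_responses(10, seed = 22)))
  allna <- generate_responses(5, dontknow = 1, seed = 1)
  expect_true(all(score_hits(allna) == 0))
  expect_true(all(score_null_expectation(allna) == 0))
})

test_that("a null generator recovers a near-zero effect at large n", {
  rt <- generate_responses(2000, effect_d = 0, seed = 23)
  st <- score_table(rt, part_def("P", 11:20), "hits")
  post <- st[st$phase == "post", ]
  d <- cohen_d(post$score[post$group == "experimental"],
               post$score[post$group == "control"])
  expect_lt(abs(d), 0.1)
})

test_that("response files round-trip and malformed files are itemized", {
  rt <- generate_responses(8, seed = 30)
  f <- withr::local_tempfile(fileext = ".csv")
  write_responses(rt, f)
  rt2 <- read_responses(f)
  expect_identical(as.data.frame(rt), as.data.frame(rt2))

  # decimal -1/3 renderings parse as errors
  tab <- utils::read.csv(f, colClasses = "character")
  expect_true(any(tab[, 4:23] == "-0.3333333"))

  # 22 columns: format error naming the expected count
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(utils::read.csv(f)[, -23], f2, row.names = FALSE)
  expect_error(read_responses(f2), "23", class = "mrisim_format_error")

  # unknown cell values are located precisely
  tab$Q5[3] <- "maybe"
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, f3, row.names = FALSE, quote = FALSE)
  expect_error(read_responses(f3), "row 3, item column 5",
               class = "mrisim_parse_error")
})
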