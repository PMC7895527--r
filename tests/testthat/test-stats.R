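test_that("superplot summaries aggregate replicates correctly", {
  rows <- tibble::tibble(value = c(1, 2, 3), cell_id = 1:3,
                         replicate = "r1", condition = "ctrl")
  sp <- superplot_summarize(rows)
  expect_equal(sp$replicates$mean, 2)
  expect_equal(sp$replicates$n_cells, 3)
  # permuting row order changes nothing
  sp2 <- superplot_summarize(rows[c(3, 1, 2), ])
  expect_equal(sp$replicates, sp2$replicates)
  expect_error(superplot_summarize(rows[0, ]), "empty")
})

test_that("replicate means concentrate around their population means", {
  set.seed(11)
  mus <- c(r1 = 1, r2 = 3, r3 = 5)
  rows <- dplyr::bind_rows(lapply(names(mus), function(r) {
    tibble::tibble(value = rnorm(10, mus[[r]], 1), cell_id = 1:10,
                   replicate = r, condition = "c")
  }))
  sp <- superplot_summarize(rows)
  for (r in names(mus)) {
    m <- sp$replicates$mean[sp$replicates$replicate == r]
    expect_lt(abs(m - mus[[r]]), 3 / sqrt(10))
  }
})

test_that("Dunnett with one treatment reduces to the pooled t-test", {
  set.seed(1)
  x <- rnorm(4)
  y <- rnorm(5) + 1
  d <- dunnett_test(tibble::tibble(condition = rep(c("ctrl", "t"), c(4, 5)),
                                   value = c(x, y)), control = "ctrl")
  tt <- stats::t.test(y, x, var.equal = TRUE)
  expect_equal(d$p_adjusted, tt$p.value, tolerance = 1e-3)
  expect_equal(d$p_unadjusted, tt$p.value, tolerance = 1e-12)
  expect_equal(d$estimate, mean(y) - mean(x), tolerance = 1e-12)
})

test_that("Dunnett agrees with the multcomp reference implementation", {
  skip_if_not_installed("multcomp")
  set.seed(3)
  df <- data.frame(condition = factor(rep(c("ctrl", "a", "b"), each = 4),
                                      levels = c("ctrl", "a", "b")),
                   value = rnorm(12) + rep(c(0, 0.8, 1.6), each = 4))
  d <- dunnett_test(df, "ctrl")
  fit <- stats::aov(value ~ condition, data = df)
  mc <- summary(multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett")))
  expect_equal(sort(d$p_adjusted), sort(as.numeric(mc$test$pvalues)),
               tolerance = 1e-4)
  # unbalanced groups too
  df2 <- data.frame(condition = factor(rep(c("ctrl", "a", "b"), c(5, 3, 4)),
                                       levels = c("ctrl", "a", "b")),
                    value = rnorm(12, rep(c(0, 1, 0.4), c(5, 3, 4))))
  d2 <- dunnett_test(df2, "ctrl")
  fit2 <- stats::aov(value ~ condition, data = df2)
  mc2 <- summary(multcomp::glht(fit2, linfct = multcomp::mcp(condition = "Dunnett")))
  expect_equal(sort(d2$p_adjusted), sort(as.numeric(mc2$test$pvalues)),
               tolerance = 1e-4)
})

test_that("Dunnett guards: adjusted >= raw, monotone in added null groups, errors", {
  set.seed(5)
  base <- tibble::tibble(condition = rep(c("ctrl", "t1"), each = 4),
                         value = rnorm(8) + rep(c(0, 1), each = 4))
  d1 <- dunnett_test(base, "ctrl")
  expect_gte(d1$p_adjusted, d1$p_unadjusted)
  more <- dplyr::bind_rows(base,
                           tibble::tibble(condition = "t2", value = rnorm(4)))
  d2 <- dunnett_test(more, "ctrl")
  # same comparison, extra comparison family member: adjusted p grows
  expect_gte(d2$p_adjusted[d2$condition == "t1"] + 1e-9,
             d1$p_adjusted[d1$condition == "t1"])
  expect_error(dunnett_test(tibble::tibble(condition = c("ctrl", "ctrl", "t"),
                                           value = 1:3), "ctrl"),
               ">= 2 units")
  # a huge shift is detected
  sep <- tibble::tibble(condition = rep(c("ctrl", "t1", "t2"), each = 3),
                        value = c(rnorm(3), rnorm(3), rnorm(3) + 50))
  expect_lt(dunnett_test(sep, "ctrl")$p_adjusted[2], 0.01)
})

test_that("superplot input uses replicate means, not pooled cells", {
  set.seed(8)
  rows <- dplyr::bind_rows(lapply(c("ctrl", "treat"), function(cond) {
    dplyr::bind_rows(lapply(1:3, function(r) {
      tibble::tibble(value = rnorm(20, ifelse(cond == "treat", 0.3, 0)),
                     cell_id = 1:20,
                     replicate = paste0(cond, r), condition = cond)
    }))
  }))
  sp <- superplot_summarize(rows)
  d <- dunnett_test(sp, "ctrl")
  expect_equal(unique(d$df), 4) # 6 replicate means - 2 groups
  expect_warning(dunnett_test(sp, "ctrl", unit = "cell"), "pseudoreplication")
})

test_that("exact Mann-Whitney matches brute-force enumeration", {
  r <- mannwhitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  expect_match(r$method, "exact")
  # identical multisets: p = 1 (ties force the normal route, z = 0)
  expect_equal(mannwhitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # randomized small samples vs the value-level enumeration oracle
  set.seed(13)
  for (i in 1:30) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- sample(seq(0, 1000, 7), nx) + runif(nx, 0, 0.001) # tie-free
    y <- sample(seq(3, 997, 11), ny) + runif(ny, 0, 0.001)
    r <- mannwhitney_u(x, y)
    expect_equal(r$p_value, oracle_mw_exact(x, y), tolerance = 1e-12)
    # U identity and symmetry
    rs <- mannwhitney_u(y, x)
    expect_equal(r$U + rs$U, nx * ny)
    expect_equal(r$p_value, rs$p_value, tolerance = 1e-12)
    # cross-check against the standard implementation
    w <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(r$U, unname(w$statistic)) # both count x > y pairs
    expect_equal(r$p_value, w$p.value, tolerance = 1e-9)
  }
})

test_that("the tie-corrected normal approximation tracks wilcox.test", {
  set.seed(21)
  x <- round(rnorm(15, 0, 2), 1)
  y <- round(rnorm(18, 0.8, 2), 1)
  r <- mannwhitney_u(x, y)
  expect_match(r$method, "normal")
  w <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$p_value, w$p.value, tolerance = 1e-9)
  expect_error(mannwhitney_u(numeric(0), 1:3), "non-empty")
})
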