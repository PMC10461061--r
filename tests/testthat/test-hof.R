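test_that("hof curves match their closed forms", {
  x <- seq(0, 1, length.out = 11)
  expect_equal(hof_curve(x, "I", c(M = 1, a = 0)), rep(0.5, 11))
  # IV with a = c: maximum at (c - a)/(2b) = 0 with value M/(1+e^a)^2
  y4 <- hof_curve(x, "IV", c(M = 2, a = 1, b = 10, c = 1))
  expect_equal(y4[1], 2 / (1 + exp(1))^2, tolerance = 1e-12)
  expect_true(all(diff(y4) < 0))
  # II with b > 0 strictly decreasing, b < 0 strictly increasing
  expect_true(all(diff(hof_curve(x, "II", c(M = 1, a = 0, b = 4))) < 0))
  expect_true(all(diff(hof_curve(x, "II", c(M = 1, a = 0, b = -4))) > 0))
  # VI reduces to IV when the second peak has height fraction ~ 0
  p6 <- c(M = 1, a = -4, b = 12, c = 3, d2 = 0.4, h = 1e-12)
  expect_equal(hof_curve(x, "VI", p6),
               hof_curve(x, "IV", c(M = 1, a = -4, b = 12, c = 3)),
               tolerance = 1e-9)
  expect_error(hof_curve(x, "IV", c(M = 1, a = 0)), "exactly parameters")
  expect_error(hof_curve(x, "VIII", c(M = 1)), "arg")
})

test_that("types I-V have at most one interior maximum", {
  withr::with_seed(42, {
    x <- seq(0, 1, length.out = 501)
    for (i in 1:40) {
      type <- sample(c("II", "III", "IV", "V"), 1)
      nm <- soilniche:::hof_param_names(type)
      params <- setNames(c(1, runif(length(nm) - 1, -20, 20)), nm)
      y <- hof_curve(x, type, params)
      dy <- diff(y)
      # strict rises followed by strict falls (tolerance kills flat-plateau
      # float noise)
      n_max <- sum(dy[-length(dy)] > 1e-12 & dy[-1] < -1e-12)
      expect_lte(n_max, 1)
    }
  })
})

test_that("self-consistency: noise-free type II data is fit to ~zero RSS", {
  g <- generate_hof_gradient("II", c(M = 1, a = 2, b = -8), 120, noise_sd = 0)
  fits <- fit_hof_all(g$gradient, g$abundance, seed = 1)
  expect_lt(fits$rss[fits$type == "II"], 1e-10)
})

test_that("occurrence filter skips sparse taxa with a reason", {
  x <- seq(0, 1, length.out = 50)
  y <- c(rep(0, 41), rep(1, 9))           # 9 positive observations
  fits <- fit_hof_all(x, y, min_occ = 10)
  expect_equal(nrow(fits), 0)
  expect_match(attr(fits, "skip_reason"), "minimum occurrence")
  f <- fit_hof(tibble::tibble(g = x, a = y), g, a, min_occ = 10)
  expect_match(f$skip_reason, "minimum occurrence")
  expect_true(is.na(glance(f)$type))
})

test_that("flat data selects type I and monotone data type II", {
  x <- seq(0, 1, length.out = 80)
  f_flat <- fit_hof(tibble::tibble(g = x, a = rep(0.4, 80)), g, a, seed = 2)
  expect_identical(f_flat$chosen_type, "I")
  expect_true(is.na(f_flat$niche$optimum))
  expect_identical(f_flat$niche$flags, "flat_no_optimum")
  y2 <- hof_curve(x, "II", c(M = 1, a = 3, b = -9)) +
    withr::with_seed(5, rnorm(80, 0, 0.01))
  f2 <- fit_hof(tibble::tibble(g = x, a = pmax(y2, 0)), g, a, seed = 3)
  expect_true(f2$chosen_type %in% c("II", "III"))
  expect_true(is.na(f2$niche$optimum))
})

test_that("model selection is deterministic given a seed", {
  g <- generate_hof_gradient("IV", c(M = 4, a = -2, b = 6, c = 1.6), 150,
                             noise_sd = 0.05, seed = 21)
  f1 <- fit_hof(g, gradient, abundance, seed = 7)
  f2 <- fit_hof(g, gradient, abundance, seed = 7)
  expect_identical(f1$bootstrap_types, f2$bootstrap_types)
  expect_identical(f1$chosen_type, f2$chosen_type)
})

test_that("niche metrics find the analytic type-IV optimum and edges", {
  params <- c(M = 1, a = -4, b = 12, c = 2)     # optimum at 0.25
  nm <- niche_metrics("IV", params, x_range = c(0, 1))
  expect_equal(nm$optimum, (2 + 4) / (2 * 12), tolerance = 1e-3)
  expect_lt(nm$low_edge, nm$optimum)
  expect_gt(nm$high_edge, nm$optimum)
  expect_identical(nm$flags, "ok")
  # gradient range mapping
  nm2 <- niche_metrics("IV", params, x_range = c(4, 10))
  expect_equal(nm2$optimum, 4 + 0.25 * 6, tolerance = 1e-2)
})

test_that("bimodal fits with both optima at the range edges report no optimum", {
  # peaks at ~0.01 and ~0.99
  params <- c(M = 1, a = -0.4, b = 40, c = 0.4, d2 = 0.98, h = 0.9)
  nm <- niche_metrics("VI", params, x_range = c(4, 10))
  expect_true(is.na(nm$optimum))
  expect_identical(nm$flags, "optima_at_range_edges")
  # the same shape away from the edges keeps its optima
  params2 <- c(M = 1, a = -8, b = 20, c = 12, d2 = 0.4, h = 0.8)
  nm2 <- niche_metrics("VI", params2, x_range = c(0, 1))
  expect_false(is.na(nm2$optimum))
  expect_gte(length(nm2$optima), 2)
})

test_that("AICc ordering is invariant to rescaling the abundances", {
  g <- generate_hof_gradient("IV", c(M = 4, a = -2, b = 6, c = 1.6), 120,
                             noise_sd = 0.05, seed = 13)
  f1 <- fit_hof_all(g$gradient, g$abundance, seed = 4)
  f2 <- fit_hof_all(g$gradient, g$abundance * 37.5, seed = 4)
  # the selection is the invariant; individual AICc values of non-winning
  # types can wobble with the optimizer's floating-point path
  expect_identical(f1$type[which.min(f1$aicc)], f2$type[which.min(f2$aicc)])
  expect_equal(f1$aicc, f2$aicc, tolerance = 1e-2)
})

test_that("batch niche fitting returns one record per taxon", {
  n <- 120
  x <- seq(4, 9, length.out = n)     # a pH-like gradient
  xs <- (x - 4) / 5
  y1 <- hof_curve(xs, "IV", c(M = 4, a = -2, b = 6, c = 1.6)) +
    withr::with_seed(2, rnorm(n, 0, 0.02))
  y2 <- rep(0, n); y2[1:5] <- 1      # too sparse: skipped
  m <- rbind(peaked = pmax(y1, 0), sparse = y2)
  colnames(m) <- sprintf("s%03d", 1:n)
  ab <- abundance_table(m, "values")
  env <- env_table(tibble::tibble(sample_id = colnames(m), pH = x),
                   require = "pH")
  res <- fit_niche_all(ab, env, "pH", seed = 5)
  expect_equal(nrow(res), 2)
  expect_true(res$type[res$taxon_id == "peaked"] %in% c("IV", "V", "VI", "VII"))
  opt <- res$optimum[res$taxon_id == "peaked"]
  expect_lt(abs(opt - (4 + 0.3 * 5)), 0.2)   # optimum on the pH scale
  expect_match(res$flags[res$taxon_id == "sparse"], "minimum occurrence")
  p <- autoplot(res$fit[[1]])
  expect_s3_class(p, "ggplot")
})
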