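test_that("paired t matches the textbook formula and handles degenerate input", {
  r <- paired_t(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  x <- c(1, 2, 3)
  same <- paired_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_t(1, 1), "insufficient data")
  expect_error(paired_t(1:3, 1:4), "pairing error")
})

test_that("paired t agrees with stats::t.test on random datasets", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- paired_t(x, y)
    ref <- stats::t.test(x, y, paired = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
    expect_equal(mine$df, unname(ref$parameter))
  }
})

test_that("Pearson r test matches cor.test and the covariance formula", {
  x <- c(1, 2, 3, 5)
  r <- pearson_r_test(x, x)
  expect_equal(r$effect_size, 1)
  expect_equal(pearson_r_test(x, -x)$effect_size, -1)
  set.seed(202)
  for (i in 1:100) {
    n <- sample(4:15, 1)
    a <- rnorm(n); b <- rnorm(n)
    mine <- pearson_r_test(a, b)
    ref <- stats::cor.test(a, b)
    expect_equal(mine$effect_size, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
    expect_equal(mine$df, n - 2)
  }
  expect_error(pearson_r_test(1:2, 2:3), "insufficient data")
  expect_error(pearson_r_test(rep(1, 5), rnorm(5)), "undefined correlation")
})

test_that("repeated-measures ANOVA matches aov and is location invariant", {
  set.seed(303)
  for (i in 1:20) {
    n <- sample(3:8, 1); k <- sample(3:5, 1)
    m <- matrix(rnorm(n * k), n, k)
    mine <- rm_anova_slopes(m)
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(n), k)),
                     cond = factor(rep(seq_len(k), each = n)))
    ref <- summary(stats::aov(y ~ cond + Error(subj / cond), data = df))
    tab <- ref[["Error: subj:cond"]][[1]]
    expect_equal(mine$statistic, tab["cond", "F value"], tolerance = 1e-8)
    expect_equal(mine$p_value, tab["cond", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(mine$df, c(k - 1, (k - 1) * (n - 1)))
    shifted <- rm_anova_slopes(m + 5)
    expect_equal(shifted$statistic, mine$statistic, tolerance = 1e-8)
  }
  flat_same <- matrix(rep(c(1, 2, 3, 4), times = 3), nrow = 4)
  expect_equal(rm_anova_slopes(flat_same)$statistic, 0)
  expect_error(rm_anova_slopes(matrix(c(1, NA, 2, 3), 2)), "incomplete design")
})

test_that("eta squared is the condition share of within-subject variance", {
  m <- matrix(c(1, 2, 3,
                2, 3, 4,
                1, 3, 5), nrow = 3, byrow = TRUE)
  mine <- rm_anova_slopes(m)
  grand <- mean(m)
  ss_cond <- 3 * sum((colMeans(m) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_cond - ss_subj
  expect_equal(mine$effect_size, ss_cond / (ss_cond + ss_err),
               tolerance = 1e-10)
})

test_that("method comparison reports ratio 1 and t 0 for identical thresholds", {
  fits_cs <- data.frame(observer_id = 1:5, threshold_deg = c(3, 4, 5, 4, 3))
  adj <- data.frame(observer_id = 1:5, overall_threshold = c(3, 4, 5, 4, 3))
  rep0 <- compare_methods(fits_cs, adj)
  expect_equal(rep0$uncorrected$ratio, 1)
  expect_equal(rep0$uncorrected$t$statistic, 0)
  expect_null(rep0$corrected)
})

test_that("identity triadic gain leaves the corrected block equal to the uncorrected", {
  fits_cs <- data.frame(observer_id = 1:4, threshold_deg = c(2.5, 3.3, 4.1, 5))
  adj <- data.frame(observer_id = 1:4, overall_threshold = c(4, 5.2, 6, 7.5))
  segs <- do.call(rbind, lapply(1:4, function(id) {
    data.frame(observer_id = id, segment = 1:4,
               lower = c(0, 0.9, 2.2, 5.4), upper = c(0.9, 2.2, 5.4, 13.9),
               slope = 1, intercept = 0)
  }))
  rep1 <- compare_methods(fits_cs, adj, segs)
  expect_equal(rep1$corrected$mean_cs, rep1$uncorrected$mean_cs)
  expect_equal(rep1$corrected$mean_adj, rep1$uncorrected$mean_adj)
  expect_equal(rep1$corrected$ratio, rep1$uncorrected$ratio)
  expect_equal(rep1$per_observer$bias_cs, rep(1, 4))
})

test_that("method comparison is invariant to observer ordering and checks ids", {
  fits_cs <- data.frame(observer_id = 1:6, threshold_deg = seq(2, 4.5, by = 0.5))
  adj <- data.frame(observer_id = 1:6, overall_threshold = seq(4, 6.5, by = 0.5))
  a <- compare_methods(fits_cs, adj)
  b <- compare_methods(fits_cs[sample(6), ], adj[sample(6), ])
  expect_equal(a$uncorrected$ratio, b$uncorrected$ratio)
  expect_equal(a$uncorrected$t$statistic, b$uncorrected$t$statistic)
  expect_equal(a$per_observer, b$per_observer)
  adj_bad <- adj; adj_bad$observer_id[1] <- 99
  expect_error(compare_methods(fits_cs, adj_bad), "join error")
})

test_that("trial readers validate schemas and report offending lines", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "adj.csv")
  writeLines(c("observer_id,trial,series,side,stop_deg",
               "1,1,ascending,right,5.2",
               "1,2,descending,right,oops"), path)
  expect_error(read_trials(path, "adjustment"), "line 3")
  writeLines(c("observer_id,trial,series,side,stop_deg",
               "1,1,sideways,right,5.2"), path)
  expect_error(read_trials(path, "adjustment"), "sideways")
  writeLines(c("observer_id,trial,series,side,stop_deg"), path)
  empty <- read_trials(path, "adjustment")
  expect_equal(nrow(empty), 0)
  writeLines(c("observer_id,trial,gaze_deg,response,extra",
               "1,1,0,1,9"), path)
  expect_error(read_trials(path, "dyadic"), "unknown column")
  writeLines(c("observer_id,trial,gaze_deg,response",
               "1,1,0,1", "1,1,0.9,0"), path)
  expect_error(read_trials(path, "dyadic"), "duplicate")
})

test_that("comparison reports serialize to CSV and JSON faithfully", {
  fits_cs <- data.frame(observer_id = 1:4, threshold_deg = c(2.5, 3.3, 4.1, 5))
  adj <- data.frame(observer_id = 1:4, overall_threshold = c(4, 5.2, 6, 7.5))
  rep1 <- compare_methods(fits_cs, adj)
  dir <- withr::local_tempdir()
  paths <- write_report(rep1, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(js$uncorrected$ratio, rep1$uncorrected$ratio)
  expect_equal(js$uncorrected$t$statistic, rep1$uncorrected$t$statistic)
  per <- utils::read.csv(paths[["csv"]])
  expect_equal(per$threshold_cs, round(rep1$per_observer$threshold_cs, 2))
})
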