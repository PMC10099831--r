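test_that("count tables are read and validated with row-level diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_counts(path)
  tab <- read_counts(path)
  expect_s3_class(tab, "count_table")
  expect_equal(nrow(tab), 3L)
  # a BONCAT count exceeding its DAPI count names the offending row
  bad <- data.frame(sample_id = "S1", habitat = "ice",
                    incubation = "in_situ", incubation_time_days = 1,
                    replicate = "r1", field_of_view = 1:2,
                    dapi_count = c(10L, 30L), boncat_count = c(12L, 5L))
  write_fixture_counts(path, bad)
  expect_error(read_counts(path), "row\\(s\\): 1")
  # unknown extra columns pass with a notice
  ok <- cbind(bad, notes = c("a", "b"))
  ok$boncat_count <- c(5L, 5L)
  write_fixture_counts(path, ok)
  expect_message(tab2 <- read_counts(path), "unrecognized column")
  expect_true("notes" %in% names(tab2))
  # missing columns and empty files are parse errors
  writeLines("dapi_count,boncat_count\n5,3", path)
  expect_error(read_counts(path), "missing column")
  writeLines(paste(names(bad), collapse = ","), path)
  expect_error(read_counts(path), "empty")
})

test_that("per-field active fractions are boncat over dapi", {
  expect_equal(fov_active_fraction(100, 50), 0.5)
  expect_equal(fov_active_fraction(20, 17), 0.85)
  expect_equal(fov_active_fraction(40, 0), 0)        # killed-control-like
  expect_true(is.na(fov_active_fraction(0, 0)))      # undefined field
  expect_error(fov_active_fraction(10, 12), "exceed")
  expect_error(fov_active_fraction(-1, 0), "non-negative")
})

test_that("group summaries report sample mean, SD and field counts", {
  tab <- validate_counts(data.frame(
    sample_id = "S1", habitat = "snow", incubation = "in_situ",
    incubation_time_days = 1, replicate = "r1", field_of_view = 1:3,
    dapi_count = c(10L, 10L, 10L), boncat_count = c(4L, 5L, 6L)))
  s <- summarize_groups(tab, "sample_id")
  expect_equal(s$mean_active_fraction, 0.5)
  expect_equal(s$sd_active_fraction, 0.1)  # hand-computed sample SD
  expect_equal(s$n_fov, 3L)
  expect_true(s$low_n)                      # fewer than 20 fields flagged
  # identical fractions give zero SD; single field gives NA SD
  tab$boncat_count <- c(5L, 5L, 5L)
  expect_equal(summarize_groups(tab, "sample_id")$sd_active_fraction, 0)
  one <- tab[1, ]
  expect_true(is.na(summarize_groups(one, "sample_id")$sd_active_fraction))
  # zero-DAPI fields are excluded with a message
  tab2 <- tab
  tab2$dapi_count[2] <- 0L; tab2$boncat_count[2] <- 0L
  expect_message(s2 <- summarize_groups(tab2, "sample_id"), "excluded")
  expect_equal(s2$n_fov, 2L)
  expect_error(summarize_groups(tab, character(0)), "at least one")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # groups (1,2,3) and (2,3,4): SSB = 1.5, SSW = 4, F = 1.5 on (1, 4) df
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$F, 1.5, tolerance = 1e-12)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  expect_equal(res$p_value, stats::pf(1.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # three unbalanced groups against a from-scratch SSB/SSW evaluation
  g <- list(c(0.4, 0.5, 0.45, 0.6), c(0.55, 0.52, 0.61), c(0.3, 0.42))
  all_v <- unlist(g); gm <- mean(all_v)
  ssb <- sum(lengths(g) * (vapply(g, mean, numeric(1)) - gm)^2)
  ssw <- sum(unlist(lapply(g, function(x) (x - mean(x))^2)))
  k <- 3; N <- length(all_v)
  f_hand <- (ssb / (k - 1)) / (ssw / (N - k))
  res2 <- one_way_anova(g)
  expect_equal(res2$F, f_hand, tolerance = 1e-10)
  expect_equal(res2$df_within, N - k)
})

test_that("degenerate ANOVA inputs are handled explicitly", {
  same <- one_way_anova(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)
  expect_warning(sep <- one_way_anova(list(c(1, 1), c(2, 2))), "p = 0")
  expect_equal(sep$p_value, 0)
  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), "at least 2 observations")
  # equal means with unequal variances: no between-group signal
  set.seed(7)
  calm <- one_way_anova(list(rnorm(50, 0, 0.01), rnorm(50, 0, 1)))
  expect_gt(calm$p_value, 0.01)
})

test_that("synthetic count tables are reproducible and honor the truth", {
  a <- simulate_counts(0.52, 100, 80, overdispersion = 0.1, seed = 11)
  b <- simulate_counts(0.52, 100, 80, overdispersion = 0.1, seed = 11)
  expect_identical(a, b)
  c2 <- simulate_counts(0.52, 100, 80, overdispersion = 0.1, seed = 12)
  expect_false(identical(a, c2))
  # a fully inactive (killed-control) population never lights up
  k <- simulate_counts(0, 200, 50, overdispersion = 0.3, seed = 3)
  expect_true(all(k$boncat_count == 0))
  expect_equal(summarize_groups(k, "sample_id")$mean_active_fraction, 0)
  # binomial limit: pooled fraction within 3 SE of the truth
  big <- simulate_counts(0.52, 1e4, 100, overdispersion = 0, seed = 5)
  pooled <- sum(big$boncat_count) / sum(big$dapi_count)
  se <- sqrt(0.52 * 0.48 / sum(big$dapi_count))
  expect_lt(abs(pooled - 0.52), 3 * se)
  expect_error(simulate_counts(1.2, 10, 10, seed = 1), "\\[0, 1\\]")
  expect_error(simulate_counts(0.5, 10, 10, 0.1), "seed")
})

test_that("the mean-fraction estimator recovers the truth at modest n", {
  tab <- simulate_counts(0.5, n_fov = 1000, mean_cells_per_fov = 100,
                         overdispersion = 0, seed = 21)
  frac <- fov_active_fraction(tab$dapi_count, tab$boncat_count)
  expect_lt(abs(mean(frac) - 0.5), 0.01)
  # overdispersion widens the field-to-field spread but not the mean
  od <- simulate_counts(0.5, n_fov = 1000, mean_cells_per_fov = 100,
                        overdispersion = 0.2, seed = 22)
  fo <- fov_active_fraction(od$dapi_count, od$boncat_count)
  expect_lt(abs(mean(fo) - 0.5), 0.03)
  expect_gt(stats::sd(fo), stats::sd(frac))
})
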