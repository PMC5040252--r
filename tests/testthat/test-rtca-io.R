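test_that("table reading parses the export layout and drops bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_h,ci_mean,ci_sd",
               "0,0.10,0.01",
               "0.25,0.15,0.02",
               "comment row,,",
               "0.5,0.21,0.02"), path)
  expect_message(tb <- read_rtca_table(path), "dropped 1")
  expect_s3_class(tb, "rtca_table")
  expect_equal(tb$data$time_h, c(0, 0.25, 0.5))
  expect_true(tb$has_sd)
  # two columns only: SD flagged absent
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_h,ci_mean", "0,0.1", "1,0.2"), path2)
  expect_false(read_rtca_table(path2)$has_sd)
  # nothing numeric at all
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "x,y", "u,v"), path3)
  expect_error(read_rtca_table(path3), "no numeric rows")
})

test_that("write/read round-trip preserves values at double precision", {
  tb <- make_rtca_table(seq(0, 12, by = 0.25),
                        sin(seq(0, 12, by = 0.25)) / 3 + 0.5,
                        ci_sd = rep(pi * 1e-2, 49))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rtca_table(tb, path)
  back <- read_rtca_table(path)
  expect_equal(back$data$time_h, tb$data$time_h, tolerance = 1e-12)
  expect_equal(back$data$ci_mean, tb$data$ci_mean, tolerance = 1e-12)
  expect_equal(back$data$ci_sd, tb$data$ci_sd, tolerance = 1e-12)
})

test_that("xlsx sheets are readable through the same entry point", {
  xl <- readxl::readxl_example("datasets.xlsx")
  tb <- read_rtca_table(xl, sheet = 1)
  expect_s3_class(tb, "rtca_table")
  expect_true(nrow(tb$data) > 10)
  expect_true(all(is.finite(tb$data$ci_mean)))
})

test_that("replicate averaging is a pointwise mean with propagated SD", {
  t <- seq(0, 10, by = 0.5)
  a <- make_rtca_table(t, rep(1, length(t)))
  b <- make_rtca_table(t, rep(3, length(t)))
  avg <- average_replicates(list(a, b))
  expect_equal(avg$value, rep(2, length(t)))
  expect_equal(avg$sd, rep(stats::sd(c(1, 3)), length(t)))
  # identical tables average to themselves
  same <- average_replicates(list(a, a, a))
  expect_equal(same$value, a$data$ci_mean)
  expect_equal(same$sd, rep(0, length(t)))
  # three replicates with known means, against a hand computation
  vals <- list(0.2 + 0.05 * t, 0.25 + 0.04 * t, 0.15 + 0.06 * t)
  tabs <- lapply(vals, function(v) make_rtca_table(t, v))
  avg3 <- average_replicates(tabs)
  expect_equal(avg3$value, (vals[[1]] + vals[[2]] + vals[[3]]) / 3)
  # permutation invariance on a shared grid
  avg3p <- average_replicates(tabs[c(3, 1, 2)])
  expect_equal(avg3p$value, avg3$value)
  expect_error(average_replicates(list(a, make_rtca_table(20:25, 1:6))),
               "disjoint")
})

test_that("synthetic exports reproduce the noiseless curve when asked", {
  g <- fast_geometry()
  tabs <- synthesize_experiment(sarc, g,
                                preset_initial_conditions(2e4, "basal"),
                                fast_basal_settings(),
                                map = cell_index_map(2e-4),
                                noise_sd = 0, n_replicates = 4,
                                n_experiments = 2, seed = 3)
  expect_length(tabs, 2L)
  expect_equal(tabs[[1]]$data$ci_sd, rep(0, nrow(tabs[[1]]$data)))
  expect_equal(tabs[[1]]$data$ci_mean, tabs[[2]]$data$ci_mean)
  r <- simulate_assay(sarc, g, preset_initial_conditions(2e4, "basal"),
                      fast_basal_settings())
  ci <- 2e-4 * stats::approx(r$times, r$n_lower,
                             xout = tabs[[1]]$data$time_h)$y
  expect_equal(tabs[[1]]$data$ci_mean, ci, tolerance = 1e-12)
})

test_that("synthetic exports are deterministic and carry the noise level", {
  g <- fast_geometry()
  args <- list(sarc, g, preset_initial_conditions(2e4, "basal"),
               fast_basal_settings(), map = cell_index_map(2e-4),
               noise_sd = 0.05, n_replicates = 4, n_experiments = 2,
               seed = 17)
  t1 <- do.call(synthesize_experiment, args)
  t2 <- do.call(synthesize_experiment, args)
  expect_identical(t1, t2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_rtca_table(t1[[1]], f1)
  write_rtca_table(t2[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
  # the per-point SD across many samples estimates noise_sd
  big <- synthesize_experiment(sarc, g,
                               preset_initial_conditions(2e4, "basal"),
                               fast_basal_settings(),
                               map = cell_index_map(2e-4),
                               noise_sd = 0.05, n_replicates = 4,
                               n_experiments = 10, seed = 23,
                               cadence = 0.05)
  sds <- unlist(lapply(big, function(tb) tb$data$ci_sd))
  # mean of per-point SDs estimates the generating SD (chi-distributed,
  # E[s] = sd * sqrt(2/3) * gamma(2)/gamma(1.5) for n = 4)
  c4 <- sqrt(2 / 3) * gamma(2) / gamma(1.5)
  expect_lt(abs(mean(sds) / (0.05 * c4) - 1), 0.05)
})

test_that("synthetic tables satisfy the container invariants across seeds", {
  g <- fast_geometry()
  for (seed in c(1, 7, 19)) {
    tabs <- synthesize_experiment(sarc, g,
                                  preset_initial_conditions(2e4, "basal"),
                                  fast_basal_settings(),
                                  noise_sd = 0.03, n_replicates = 4,
                                  n_experiments = 2, seed = seed)
    for (tb in tabs) {
      expect_true(all(diff(tb$data$time_h) > 0))
      expect_true(all(tb$data$ci_sd >= 0))
      expect_equal(nrow(tb$data), length(seq(0, 12, by = 0.25)))
      curve <- as_ci_curve(tb)
      expect_s3_class(curve, "ci_curve")
    }
  }
})
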