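test_that("uniform noise is bounded, clamped at zero and seed-stable", {
  v <- matrix(c(0, 0.5, 2, 10, 25, 100), 2, 3,
              dimnames = list(c("a", "b"), NULL))
  expect_identical(add_noise(v, 0, seed = 1), v)
  expect_error(add_noise(v, -1), ">= 0")

  n1 <- add_noise(v, 2, seed = 7)
  n2 <- add_noise(v, 2, seed = 7)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0))
  big <- v[v >= 2]
  expect_true(all(abs(add_noise(v, 2, seed = 3)[v >= 2] - big) < 2))

  # clamping: zero input with large noise never goes negative
  z <- matrix(0, 5, 5, dimnames = list(paste0("t", 1:5), NULL))
  expect_true(all(add_noise(z, 10, seed = 1) >= 0))
})

test_that("polynomial-spline smoothing reproduces low-degree signals", {
  t <- seq(0, 30, 3)
  expect_equal(smooth_series(rep(7, 11), t, 4), rep(7, 11),
               tolerance = 1e-8)
  quartic <- 2 + 0.5 * t - 0.1 * t^2 + 0.01 * t^3 - 1e-4 * t^4
  expect_equal(smooth_series(quartic, t, 4), quartic, tolerance = 1e-8)
  expect_error(smooth_series(1:4, 1:4, 4), "degree")

  # smoothing a noisy sinusoid moves it towards the clean signal
  set.seed(11)
  clean <- 10 + 5 * sin(2 * pi * t / 24)
  noisy <- clean + runif(11, -2, 2)
  sm <- smooth_series(noisy, t, 4)
  expect_lt(sum((sm - clean)^2), sum((noisy - clean)^2))
})

test_that("crossings are sign changes with interpolated switch times", {
  cr <- find_crossings(c(1, 3), c(3, 1), c(0, 3))
  expect_equal(cr$time, 1.5)
  expect_equal(cr$before[[1]], 1L)
  expect_equal(cr$after[[1]], 2L)

  expect_equal(nrow(find_crossings(c(5, 6, 7), c(1, 2, 3), c(0, 1, 2))), 0)

  # touching zero with equal signs on both sides is not a crossing
  expect_equal(nrow(find_crossings(c(2, 1, 2), c(1, 1, 1), c(0, 1, 2))), 0)

  # zero at a sample with a genuine sign change roots at that sample
  cr2 <- find_crossings(c(2, 1, 0), c(1, 1, 1), c(0, 1, 2))
  expect_equal(cr2$time, 1)

  # consecutive crossings partition the samples
  t <- 0:5
  cr3 <- find_crossings(c(3, 1, 3, 1, 3, 1), c(2, 2, 2, 2, 2, 2), t)
  expect_equal(nrow(cr3), 5)
  expect_equal(cr3$before[[3]], 3L)
  expect_equal(cr3$after[[3]], 4L)

  expect_error(find_crossings(1:3, 1:2, 1:3), "length mismatch")
})

test_that("interval difference and S2 follow the defining sums", {
  expect_equal(interval_mean_difference(c(5, 7), c(1, 3), 1:2), 4)
  expect_equal(interval_mean_difference(c(2, 2), c(2, 2), 1:2), 0)
  expect_equal(interval_mean_difference(c(1, 5), c(3, 3), 1:2), 2)
  expect_error(interval_mean_difference(1, 1, integer(0)), "empty")

  si <- c(5, 7, 1, 3); sj <- c(1, 3, 5, 7)
  expect_equal(switch_magnitude(si, sj, 1:2, 3:4), 8)
  expect_equal(switch_magnitude(si, si, 1:2, 3:4), 0)
  expect_equal(switch_magnitude(2 * si - si[1], 2 * sj - si[1], 1:2, 3:4),
               2 * switch_magnitude(si, sj, 1:2, 3:4))
})

test_that("switch magnitude equals the naive per-sample oracle", {
  naive_s2 <- function(si, sj, i1, i2) {
    tot <- 0
    for (idx in list(i1, i2)) {
      acc <- 0
      for (m in idx) acc <- acc + abs(si[m] - sj[m])
      tot <- tot + acc / length(idx)
    }
    tot
  }
  set.seed(99)
  for (rep in 1:300) {
    n <- sample(4:12, 1)
    si <- runif(n, 0, 50); sj <- runif(n, 0, 50)
    cut <- sample(2:(n - 2), 1)
    i1 <- 1:cut; i2 <- (cut + 1):n
    expect_equal(switch_magnitude(si, sj, i1, i2),
                 naive_s2(si, sj, i1, i2), tolerance = 1e-12)
  }
})

test_that("switch probability counts consistent samples, ties against", {
  expect_equal(switch_probability(c(5, 5, 1, 1), c(1, 1, 5, 5), 1:2, 3:4), 1)
  expect_equal(switch_probability(c(5, 1, 1, 1), c(1, 5, 5, 5), 1:2, 3:4),
               0.75)
  expect_equal(switch_probability(c(1, 1, 5, 5), c(5, 5, 1, 1), 1:2, 3:4), 0)
  # tie counts as inconsistent
  expect_equal(switch_probability(c(5, 3, 1, 1), c(1, 3, 5, 5), 1:2, 3:4),
               0.75)
})

test_that("switch p-value is the max of two within-interval t-tests", {
  # closed form: diffs [3,4,5] -> t = 4/(1/sqrt(3)), df = 2
  si <- c(13, 14, 15, 13, 14, 15); sj <- c(10, 10, 10, 10, 10, 10)
  p <- switch_pvalue(si, sj, 1:3, 4:6)
  expect_equal(p, 2 * pt(-4 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_lt(abs(p - 0.0202), 1e-4)

  # mean-zero differences give p = 1
  expect_equal(switch_pvalue(c(0, 1, 2), c(1, 1, 1), 1:3, 1:3), 1)

  # max rule: weaker interval dominates
  si2 <- c(13, 14, 15, 10.2, 9.9, 10.4)
  p1 <- switch_pvalue(si2, sj, 1:3, 1:3)
  p2 <- switch_pvalue(si2, sj, 4:6, 4:6)
  expect_equal(switch_pvalue(si2, sj, 1:3, 4:6), max(p1, p2))

  # zero variance, non-zero mean
  expect_equal(switch_pvalue(c(5, 5, 1, 1), c(1, 1, 5, 5), 1:2, 3:4), 0)
  expect_error(switch_pvalue(si, sj, 1, 2:3), "undefined")
})

test_that("series correlation handles constants and orthogonal phases", {
  expect_equal(series_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(series_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(series_correlation(c(1, 0, -1, 0), c(0, 1, 0, -1)), 0)
  expect_equal(series_correlation(c(2, 2, 2), c(1, 5, 9)), 0)
})

test_that("score_gene enumerates pairs and orients events", {
  t <- seq(0, 30, 3)
  v <- rbind(solo = 10 + 0 * t)
  x1 <- toy_matrix(v, t, "G1")
  expect_equal(nrow(score_gene(x1, "G1")), 0)
  expect_error(score_gene(x1, "nope"), "unknown gene")

  # clean antiphase sinusoids (phase chosen so no sample sits on a zero):
  # every event fully consistent
  s <- sin(2 * pi * t / 24 + 0.7)
  v2 <- rbind(i1 = 10 + 5 * s, i2 = 10 - 5 * s)
  x2 <- toy_matrix(v2, t, c("G1", "G1"))
  ev <- score_gene(x2, "G1", use_smoothing = FALSE)
  expect_true(all(ev$prob == 1))
  expect_true(all(abs(ev$cor + 1) < 1e-12))
  # orientation: the isoform above before the switch is iso_before
  first <- ev[which.min(ev$switch_time), ]
  up_before <- v2[, max(first$idx_before[[1]])]
  expect_gt(up_before[first$iso_before], up_before[first$iso_after])

  # three isoforms -> three scored pairs
  v3 <- rbind(a = 10 + 5 * s, b = 10 - 5 * s, c = 10 + 4 * cos(2 * pi * t / 24))
  x3 <- toy_matrix(v3, t, rep("G1", 3))
  ev3 <- score_gene(x3, "G1", use_smoothing = FALSE)
  expect_equal(length(unique(paste(ev3$iso_before, ev3$iso_after))) >= 3,
               TRUE)
  expect_setequal(
    unique(apply(cbind(ev3$iso_before, ev3$iso_after), 1,
                 function(r) paste(sort(r), collapse = "-"))),
    c("a-b", "a-c", "b-c"))
})

test_that("metric antisymmetry under isoform swap", {
  set.seed(5)
  for (rep in 1:50) {
    n <- 10
    si <- runif(n, 0, 20); sj <- runif(n, 0, 20)
    i1 <- 1:4; i2 <- 6:10
    expect_equal(switch_magnitude(si, sj, i1, i2),
                 switch_magnitude(sj, si, i1, i2))
    expect_equal(switch_pvalue(si, sj, i1, i2),
                 switch_pvalue(sj, si, i1, i2))
    expect_equal(abs(series_correlation(si, sj)),
                 abs(series_correlation(sj, si)))
    expect_equal(switch_probability(si, sj, i1, i2),
                 1 - switch_probability(sj, si, i1, i2))
  }
})

test_that("conjunctive filter applies every cutoff and stays monotone", {
  expect_equal(nrow(filter_switches(detect_switches(
    toy_matrix(rbind(a = rep(1, 11), b = rep(2, 11)), seq(0, 30, 3),
               c("G1", "G1"))))), 0)

  ev <- data.frame(
    gene_id = "G1", iso_before = "a", iso_after = "b",
    switch_time = c(15, 15, 35, 15), prob = c(1, 1, 1, 1),
    diff = c(5, 0.9, 5, 5), pval = c(1e-5, 1e-5, 1e-5, NA),
    cor = c(-0.9, -0.9, -0.9, -0.9), min_points = c(4, 4, 4, 4),
    n_before = 4, n_after = 4)
  kept <- filter_switches(ev, switch_thresholds())
  expect_equal(nrow(kept), 1)          # diff 0.9, out-of-window and NA p fail
  expect_equal(kept$diff, 5)

  # anticorrelated events survive the default cutoff of 0
  expect_equal(nrow(filter_switches(ev[1, ],
                                    switch_thresholds(cor_min = 0.5))), 1)

  # tightening any single threshold yields a subset
  set.seed(21)
  pool <- data.frame(
    gene_id = "G", iso_before = "a", iso_after = "b",
    switch_time = runif(200, -5, 40), prob = runif(200),
    diff = runif(200, 0, 5), pval = runif(200, 0, 0.01),
    cor = runif(200, -1, 1), min_points = sample(1:5, 200, TRUE),
    n_before = 4, n_after = 4)
  base <- switch_thresholds()
  for (rep in 1:30) {
    field <- sample(names(unclass(base))[1:5], 1)
    tighter <- base
    tighter[[field]] <- if (field == "pval_max") base[[field]] / 2
                        else base[[field]] + runif(1, 0, 1)
    a <- filter_switches(pool, base); b <- filter_switches(pool, tighter)
    expect_lte(nrow(b), nrow(a))
    expect_true(all(rownames(b) %in% rownames(a)))
  }
})

test_that("planted sinusoid switch times are recovered on noisy data", {
  # with the p-value filter disabled (it cannot certify smoothly varying
  # differences at these sample sizes; see the vignette), identifiable
  # planted crossings are recovered to within half a sampling interval
  th <- switch_thresholds(pval_max = 1)
  total <- 0; recovered <- 0
  for (seed in 1:40) {
    cfg <- simulation_config(n_genes = 5, isoforms_per_gene = c(2, 2),
                             fraction_switching = 1, seed = seed)
    sim <- simulate_profiles(cfg)
    ev <- filter_switches(detect_switches(sim$matrix), th)
    truth <- sim$truth[sim$truth$identifiable &
                         sim$truth$crossing_time >= 0 &
                         sim$truth$crossing_time <= 30, ]
    for (i in seq_len(nrow(truth))) {
      total <- total + 1
      hit <- any(ev$gene_id == truth$gene_id[i] &
                   abs(ev$switch_time - truth$crossing_time[i]) <= 1.5)
      recovered <- recovered + hit
    }
  }
  expect_gt(total, 100)
  expect_gte(recovered / total, 0.95)
})

test_that("noise-free recovery is exact to half a sampling interval", {
  cfg <- simulation_config(n_genes = 8, isoforms_per_gene = c(2, 2),
                           fraction_switching = 1, noise_amount = 0,
                           seed = 31)
  sim <- simulate_profiles(cfg)
  ev <- detect_switches(sim$matrix, use_smoothing = FALSE)
  truth <- sim$truth[sim$truth$identifiable, ]
  for (i in seq_len(nrow(truth))) {
    d <- abs(ev$switch_time[ev$gene_id == truth$gene_id[i]] -
               truth$crossing_time[i])
    expect_lte(min(d), 1.5)
  }
})

test_that("proportional isoform pairs yield no filtered events at zero noise", {
  cfg <- simulation_config(n_genes = 20, fraction_switching = 0,
                           noise_amount = 0, seed = 13)
  sim <- simulate_profiles(cfg)
  ev <- filter_switches(detect_switches(sim$matrix), switch_thresholds())
  expect_equal(nrow(ev), 0)
})

test_that("detection is a pure function of matrix, options and seed", {
  cfg <- simulation_config(n_genes = 6, seed = 17)
  a <- simulate_profiles(cfg); b <- simulate_profiles(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(detect_switches(a$matrix), detect_switches(b$matrix))
})
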