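test_that("abundance filter is a strict fraction threshold", {
  counts <- c(a = 25, b = 20, c = 120000 - 45)  # total 120000
  cfg <- qc_config()
  # a: 25/120000 = 1/4800 > 1/5000 kept; b: 20/120000 = 1/6000 removed
  expect_setequal(abundance_filter(counts, cfg), c("a", "c"))
  counts2 <- c(a = 24, b = 120000 - 24)  # exactly 1/5000: removed
  expect_equal(abundance_filter(counts2, cfg), "b")
  expect_error(abundance_filter(c(a = 0, b = 0), cfg), "no -spectinomycin")
})

test_that("abundance threshold arithmetic matches the CFU reasoning", {
  expect_equal(abundance_to_cfu(1e8), 20)
  expect_equal(abundance_to_cfu(1e9), 200)
})

test_that("outgrowth gate passes proportional counts and fails distortions", {
  pos <- paste0("p", 1:6)
  base <- c(5, 10, 20, 40, 80, 160) * 100
  cfg <- qc_config()
  # perfectly proportional fractions: slope 1, r2 1
  og <- suppressWarnings(
    outgrowth_fit(setNames(base * 3, pos), setNames(base, pos), pos, cfg))
  expect_equal(og$slope, 1, tolerance = 1e-9)
  expect_true(og$pass)
  # constructed slope 0.3: y fractions compress toward the mean
  x <- base / sum(base)
  y <- 0.3 * x + (1 - 0.3) * mean(x)   # sums to 1, exact slope 0.3
  og2 <- suppressWarnings(outgrowth_fit(setNames(y * 1e5, pos),
                                        setNames(base, pos), pos, cfg))
  expect_equal(og2$slope, 0.3, tolerance = 1e-9)
  expect_false(og2$pass)
  # noisy scatter with low r2
  set.seed(31)
  repeat {
    y3 <- x * exp(rnorm(6, 0, 1.5)); y3 <- y3 / sum(y3)
    r2 <- summary(lm(y3 ~ x))$r.squared
    if (r2 < 0.5) break
  }
  og3 <- outgrowth_fit(setNames(y3 * 1e5, pos), setNames(base, pos), pos, cfg)
  expect_false(og3$pass)
  # fewer than 3 usable positives fails with a reason
  og4 <- outgrowth_fit(c(p1 = 10, p2 = 10), c(p1 = 10, p2 = 10),
                       c("p1", "p2"), cfg)
  expect_false(og4$pass)
  expect_match(og4$reason, "fewer than 3")
})

test_that("fold-change gate uses geometric means and a strict threshold", {
  cfg <- qc_config()
  fc <- fold_change_check(rep(1, 4), rep(0.01, 3), cfg)
  expect_equal(fc$fc, 100)
  expect_true(fc$pass)
  fc2 <- fold_change_check(rep(1, 4), rep(0.1, 3), cfg)  # fc 10
  expect_false(fc2$pass)
  # zero ORs are excluded from the geometric mean
  fc3 <- fold_change_check(c(1, 1), c(0, 0.01), cfg)
  expect_equal(fc3$fc, 100)
  # nothing usable: fail with the insufficiency reason
  fc4 <- fold_change_check(c(1, 1), c(0, 0), cfg)
  expect_false(fc4$pass)
  expect_match(fc4$reason, "[Ii]nsufficient")
})

test_that("QC gates are monotone under threshold tightening", {
  set.seed(32)
  for (rep in 1:20) {
    pos <- paste0("p", 1:8)
    cm <- setNames(rlnorm(8, 7, 1), pos)
    cp <- setNames(cm * rlnorm(8, 0, runif(1, 0, 0.8)), pos)
    loose <- qc_config(min_r2 = 0.4, slope_range = c(0.3, 3))
    tight <- qc_config(min_r2 = 0.7, slope_range = c(0.7, 1.5))
    og_loose <- suppressWarnings(outgrowth_fit(cp, cm, pos, loose))
    og_tight <- suppressWarnings(outgrowth_fit(cp, cm, pos, tight))
    if (og_tight$pass) expect_true(og_loose$pass)

    pos_or <- rlnorm(5, 0, 0.3)
    neg_or <- rlnorm(3, runif(1, -6, -1), 0.5)
    fc_lo <- fold_change_check(pos_or, neg_or, qc_config(min_fold_change = 10))
    fc_hi <- fold_change_check(pos_or, neg_or, qc_config(min_fold_change = 100))
    if (fc_hi$pass) expect_true(fc_lo$pass)
  }
})

test_that("abundance filter agrees with a brute-force fraction computation", {
  set.seed(33)
  cfg <- qc_config()
  for (rep in 1:20) {
    counts <- setNames(rpois(50, rlnorm(50, 3, 2)), paste0("b", 1:50))
    if (sum(counts) == 0) next
    brute <- names(counts)[vapply(seq_along(counts), function(i)
      counts[i] / sum(counts) > 1 / 5000, logical(1))]
    expect_setequal(abundance_filter(counts, cfg), brute)
  }
})

test_that("outgrowth-gate failure rate rises with lag-phase variance", {
  set.seed(34)
  cfg0 <- sim_config(n_sensors = 15, seed = 34, read_depth = 5e4)
  fail_rate <- vapply(c(0, 0.8), function(sd) {
    fails <- 0L
    for (r in 1:15) {
      cfg <- cfg0; cfg$lag_sd <- sd; cfg$seed <- 340L + r
      tr <- generate_library(cfg)
      s <- simulate_screen_counts(tr, "induced")
      res <- try(suppressWarnings(
        quantify_sample(s, truth_map(tr), truth_norm_set(tr))), silent = TRUE)
      if (inherits(res, "try-error") || !res$qc$outgrowth$pass) fails <- fails + 1L
    }
    fails / 15
  }, numeric(1))
  expect_lt(fail_rate[1], 0.2)
  expect_gt(fail_rate[2], fail_rate[1])
})

test_that("recovered fractions count detected barcodes and sensors", {
  map <- data.frame(barcode_id = paste0("b", 1:6),
                    sensor_id = rep(c("s1", "s2"), each = 3),
                    status = "assigned", stringsAsFactors = FALSE)
  cm <- c(b1 = 50, b2 = 5, b3 = 0, b4 = 100, b5 = 0, b6 = 0)
  rf <- recovered_fraction(cm, map)
  expect_equal(unname(rf["barcode_fraction"]), 3 / 6)
  expect_equal(unname(rf["sensor_fraction"]), 1.0)
  # at detection threshold 10 a 5-read barcode counts as absent
  rf10 <- recovered_fraction(cm, map, qc_config(detection_threshold = 10))
  expect_equal(unname(rf10["barcode_fraction"]), 2 / 6)
  # all detected
  rf_all <- recovered_fraction(setNames(rep(3, 6), names(cm)), map)
  expect_equal(unname(rf_all), c(1, 1))
})
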