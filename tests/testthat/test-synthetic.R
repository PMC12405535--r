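test_that("library generation is seeded and bit-reproducible", {
  cfg <- sim_config(n_sensors = 8, seed = 71, read_depth = 1e4)
  t1 <- generate_library(cfg)
  t2 <- generate_library(cfg)
  expect_identical(t1$barcodes, t2$barcodes)
  expect_identical(t1$sensors, t2$sensors)
  expect_identical(t1$f, t2$f)
  # and the downstream reads reproduce byte for byte
  s1 <- simulate_screen_counts(t1, "induced")
  r1 <- simulate_reads(t1, s1)
  s2 <- simulate_screen_counts(generate_library(cfg), "induced")
  r2 <- simulate_reads(t2, s2)
  expect_identical(r1, r2)
})

test_that("barcodes respect the mutual-identity cap and abundances sum to 1", {
  cfg <- sim_config(n_sensors = 5, seed = 72)
  tr <- generate_library(cfg)
  expect_equal(sum(tr$barcodes$abundance), 1, tolerance = 1e-12)
  expect_true(all(nchar(tr$barcodes$sequence) == 106))
  seqs <- tr$barcodes$sequence
  n <- length(seqs)
  worst <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      worst <- max(worst, pairwise_identity(seqs[i], seqs[j]))
    }
  }
  expect_lt(worst, 0.80)
})

test_that("screen counts implement the bacteriostatic growth model", {
  cfg <- sim_config(n_sensors = 4, seed = 73, outgrowth_fold_change = 50)
  tr <- generate_library(cfg, f_fun = function(n, k) matrix(c(0, 1, 0.5, 0.2), n, k))
  s <- simulate_screen_counts(tr, "induced", noiseless = TRUE)
  # -spect composition equals the library composition
  expect_equal(unname(s$counts_minus / sum(s$counts_minus)),
               tr$barcodes$abundance, tolerance = 1e-12)
  # +spect follows a * (f G + 1 - f)
  f <- tr$f[tr$barcodes$sensor_id, "induced"]
  w <- tr$barcodes$abundance * (f * 50 + (1 - f))
  expect_equal(unname(s$counts_plus / sum(s$counts_plus)),
               unname(w / sum(w)), tolerance = 1e-12)
  # multinomial sampling conserves the read depth
  s2 <- simulate_screen_counts(tr, "induced")
  expect_equal(sum(s2$counts_plus), cfg$read_depth)
  expect_equal(sum(s2$counts_minus), cfg$read_depth)
})

test_that("read simulation respects error rates and multiplicities", {
  cfg <- sim_config(n_sensors = 4, seed = 74, read_depth = 2000,
                    short_read_error_rate = 0, long_read_error_rate = 0,
                    long_reads_per_barcode = 3)
  tr <- generate_library(cfg)
  s <- simulate_screen_counts(tr, "induced")
  rd <- simulate_reads(tr, s)
  # zero error: every short read equals its barcode exactly
  bc_of <- setNames(tr$barcodes$sequence, tr$barcodes$barcode_id)
  ids <- sub("_r\\d+$", "", names(rd$short_minus))
  expect_identical(unname(rd$short_minus), unname(bc_of[ids]))
  expect_equal(length(rd$short_minus), sum(s$counts_minus))
  expect_equal(length(rd$short_plus), cfg$read_depth)
  # zero-error long reads are exact adapter+sensor+barcode+adapter
  refs <- setNames(tr$sensors$reference_sequence, tr$sensors$sensor_id)
  first <- rd$long[[1]]
  b1 <- tr$barcodes[1, ]
  expect_identical(first, paste0(cfg$adapter, refs[[b1$sensor_id]],
                                 b1$sequence, cfg$adapter))
  expect_equal(length(rd$long), nrow(tr$barcodes) * 3L)
  # each noisy long read's prefix stays close to its sensor reference
  cfg2 <- sim_config(n_sensors = 4, seed = 75, read_depth = 500,
                     long_read_error_rate = 0.06, long_reads_per_barcode = 2)
  tr2 <- generate_library(cfg2)
  s2 <- simulate_screen_counts(tr2, "induced")
  rd2 <- simulate_reads(tr2, s2)
  refs2 <- tr2$sensors$reference_sequence
  names(refs2) <- tr2$sensors$sensor_id
  idx <- sample(length(rd2$long), 20)
  for (i in idx) {
    bid <- sub("_L\\d+$", "", names(rd2$long)[i])
    sid <- tr2$barcodes$sensor_id[tr2$barcodes$barcode_id == bid]
    st <- sensorscreen:::cpp_fit_stats(refs2[[sid]], rd2$long[[i]])
    expect_gt(st[["matches"]] / st[["cols"]], 1 - 2 * 0.06)
  }
})

test_that("bottleneck survivors behave at the extremes and monotonically", {
  cfg <- sim_config(n_sensors = 6, seed = 76)
  tr <- generate_library(cfg)
  set.seed(1)
  expect_equal(length(simulate_bottleneck(tr, 1)), 1L)
  # n_cells far above 1/min(abundance): everything survives
  huge <- ceiling(50 / min(tr$barcodes$abundance))
  expect_equal(length(simulate_bottleneck(tr, huge)), nrow(tr$barcodes))
  # expected surviving fraction decreases as n_cells shrinks
  set.seed(2)
  small <- mean(replicate(10, length(simulate_bottleneck(tr, 100))))
  mid <- mean(replicate(10, length(simulate_bottleneck(tr, 2000))))
  expect_lt(small, mid)
})

test_that("simulate_screen writes FASTQ and count tables", {
  td <- withr::local_tempdir()
  cfg <- sim_config(n_sensors = 4, seed = 77, read_depth = 1000,
                    long_reads_per_barcode = 2)
  out <- simulate_screen(cfg, conditions = c("gavage", "induced"),
                         reads = TRUE, out_dir = td)
  expect_true(file.exists(file.path(td, "counts.tsv")))
  expect_true(file.exists(file.path(td, "truth_barcodes.tsv")))
  fq <- file.path(td, "induced", "short_minus.fastq")
  expect_true(file.exists(fq))
  rd <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_equal(length(rd), sum(out$samples$induced_s1$counts_minus))
})
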