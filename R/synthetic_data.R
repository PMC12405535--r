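#' Synthetic screening experiments
#'
#' Generates fully specified synthetic screens with known ground truth:
#' library composition (barcoded replicate strains with log-normal
#' abundance), per-sensor true switching fractions, bacteriostatic
#' spectinomycin selection, multinomial read sampling, error-bearing short
#' and long reads, and colonisation bottlenecks. Every stage downstream of
#' the simulator can be validated against the generated truth.
#'
#' The growth model is relative-abundance algebra: uniform growth preserves
#' composition in the -spectinomycin culture, while in the +spectinomycin
#' culture ON cells (fraction `f` per sensor) grow by the outgrowth fold
#' change `G` and OFF cells persist unreplicated (spectinomycin is
#' bacteriostatic). The +spectinomycin relative abundance of barcode `i` is
#' therefore proportional to `a_i * (f_i * G + (1 - f_i))`, which yields the
#' closed forms `E[OR] = f + (1 - f) / G` and `E[FOR] = f`.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults reflect the screening conditions the pipeline targets: ~60
#' library sensors with a log-normal number of barcoded replicates (median
#' 5, as in a small sensor library; a large promoter library would use
#' median 52), log-normal strain abundances, a 1:1000 outgrowth (fold change
#' `G = 1000`; in-vivo samples typically use 1:100), 2e5 reads per culture,
#' low short-read and high long-read per-base error.
#'
#' @param n_sensors Library sensors (excluding controls); default 60.
#' @param barcodes_per_sensor_median Median barcoded replicates per sensor
#'   (log-normal); default 5.
#' @param barcodes_per_sensor_sdlog sdlog of the replicate distribution; 0
#'   gives exactly the median. Default 1.
#' @param max_barcodes_per_sensor Upper clip, default 1000.
#' @param abundance_sdlog sdlog of per-barcode abundance; default 1.
#' @param outgrowth_fold_change `G` (> 1); default 1000.
#' @param read_depth Reads per culture; default 2e5.
#' @param short_read_error_rate Per-base substitution rate of barcode
#'   amplicon reads; default 0.001.
#' @param long_read_error_rate Total per-base error of long reads; default
#'   0.07, split 75% substitutions / 25% indels with geometric indel length
#'   (continuation 0.3).
#' @param long_reads_per_barcode Long reads covering each barcode; default
#'   10.
#' @param sensor_ref_length Length of simulated sensor reference sequences;
#'   default 500 bp (real sensor regions are kb-scale; scaled down for desk
#'   runtime, which only shortens alignments).
#' @param barcode_length Barcode length; default 106.
#' @param max_barcode_identity Rejection-sampling cap on mutual barcode
#'   identity; default 0.80.
#' @param n_positive_sensors,n_positive_barcodes Constitutively ON
#'   normalisation sensors and their total barcodes; defaults 3 and 14.
#' @param n_negative_barcodes Barcodes of the internal negative (always
#'   OFF) sensor; default 6.
#' @param bottleneck_size Cells surviving a colonisation bottleneck;
#'   default 1e5.
#' @param lag_sd sdlog of optional per-barcode, per-culture outgrowth (lag
#'   phase) multipliers; 0 disables the distortion. Default 0.
#' @param adapter Long-read adapter appended to both ends.
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_sensors = 60L, barcodes_per_sensor_median = 5,
                       barcodes_per_sensor_sdlog = 1,
                       max_barcodes_per_sensor = 1000L,
                       abundance_sdlog = 1, outgrowth_fold_change = 1000,
                       read_depth = 2e5, short_read_error_rate = 0.001,
                       long_read_error_rate = 0.07,
                       long_reads_per_barcode = 10L,
                       sensor_ref_length = 500L, barcode_length = 106L,
                       max_barcode_identity = 0.80,
                       n_positive_sensors = 3L, n_positive_barcodes = 14L,
                       n_negative_barcodes = 6L, bottleneck_size = 1e5,
                       lag_sd = 0, adapter = DEFAULT_ADAPTER, seed = 1L) {
  stopifnot(outgrowth_fold_change > 1, read_depth >= 1,
            short_read_error_rate >= 0, short_read_error_rate <= 1,
            long_read_error_rate >= 0, long_read_error_rate <= 1,
            n_sensors >= 1, barcode_length > 10)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic barcoded sensor library
#'
#' Draws sensor reference sequences, barcode sequences (rejection-sampled so
#' every pair is below `max_barcode_identity` global identity), the
#' barcode-to-sensor map, per-barcode abundances (log-normal, normalised to
#' sum 1) and per-sensor true ON-fractions `f` per condition. Positive
#' control sensors have `f = 1` and the negative control `f = 0` in every
#' condition.
#'
#' @param config A [sim_config()].
#' @param conditions Character vector of condition labels; default
#'   `"induced"`.
#' @param f_fun Function `(n_sensors, n_conditions)` returning the library
#'   sensors' ON-fraction matrix. The default draws, per sensor and
#'   condition, `f = 0` with probability 0.4, `f = 1` with probability 0.3
#'   (constitutively ON promoters) and `f ~ U(0, 1)` otherwise.
#' @return Object of class `sim_truth`: list with `sensors` (data frame
#'   `sensor_id`, `reference_sequence`, `role`), `barcodes` (data frame
#'   `barcode_id`, `sequence`, `sensor_id`, `abundance`), `f` (matrix
#'   sensors x conditions), `config`.
#' @export
generate_library <- function(config = sim_config(), conditions = "induced",
                             f_fun = NULL) {
  set.seed(config$seed)
  n_lib <- config$n_sensors
  sensor_id <- sprintf("sensor%03d", seq_len(n_lib))
  roles <- rep("library", n_lib)
  # normalisation controls on top of the library sensors
  pos_id <- sprintf("posctrl%02d", seq_len(config$n_positive_sensors))
  neg_id <- "negctrl01"
  all_ids <- c(sensor_id, pos_id, neg_id)
  roles <- c(roles, rep("positive", length(pos_id)), "negative")
  refs <- random_dna(length(all_ids), config$sensor_ref_length)
  sensors <- data.frame(sensor_id = all_ids, reference_sequence = refs,
                        role = roles, stringsAsFactors = FALSE)

  nb <- pmin(pmax(1L, as.integer(round(rlnorm(
    n_lib, log(config$barcodes_per_sensor_median),
    config$barcodes_per_sensor_sdlog)))), config$max_barcodes_per_sensor)
  # split the positive barcodes roughly evenly over the positive sensors
  pos_nb <- diff(round(seq(0, config$n_positive_barcodes,
                           length.out = config$n_positive_sensors + 1)))
  nb <- c(nb, pos_nb, config$n_negative_barcodes)
  total_bc <- sum(nb)

  seqs <- character(total_bc)
  for (i in seq_len(total_bc)) {
    repeat_guard <- 0L
    repeat {
      cand <- random_dna(1, config$barcode_length)
      if (i == 1L ||
          !cpp_any_identity_ge(cand, seqs[seq_len(i - 1L)],
                               config$max_barcode_identity)) break
      repeat_guard <- repeat_guard + 1L
      if (repeat_guard > 1000L) {
        stop("barcode rejection sampling failed after 1000 attempts")
      }
    }
    seqs[i] <- cand
  }
  abundance <- rlnorm(total_bc, 0, config$abundance_sdlog)
  abundance <- abundance / sum(abundance)
  barcodes <- data.frame(
    barcode_id = sprintf("bc%04d", seq_len(total_bc)),
    sequence = seqs,
    sensor_id = rep(all_ids, nb),
    abundance = abundance, stringsAsFactors = FALSE)

  if (is.null(f_fun)) {
    f_fun <- function(n, k) {
      m <- matrix(runif(n * k), n, k)
      kind <- matrix(runif(n * k), n, k)
      m[kind < 0.4] <- 0
      m[kind >= 0.7] <- 1
      m
    }
  }
  f <- f_fun(n_lib, length(conditions))
  f <- rbind(matrix(f, n_lib, length(conditions)),
             matrix(1, length(pos_id), length(conditions)),
             matrix(0, 1, length(conditions)))
  dimnames(f) <- list(all_ids, conditions)

  structure(list(sensors = sensors, barcodes = barcodes, f = f,
                 config = config), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Synthetic library:", nrow(x$sensors), "sensors (",
      sum(x$sensors$role == "library"), "library +",
      sum(x$sensors$role == "positive"), "positive +",
      sum(x$sensors$role == "negative"), "negative ),",
      nrow(x$barcodes), "barcodes;",
      ncol(x$f), "condition(s)\n")
  invisible(x)
}

#' Normalisation set implied by a synthetic library
#'
#' @param truth A `sim_truth`.
#' @return A [norm_set()] listing the positive-control barcodes and the
#'   negative sensor.
#' @export
truth_norm_set <- function(truth) {
  pos_sensors <- truth$sensors$sensor_id[truth$sensors$role == "positive"]
  neg_sensor <- truth$sensors$sensor_id[truth$sensors$role == "negative"]
  norm_set(truth$barcodes$barcode_id[truth$barcodes$sensor_id %in% pos_sensors],
           neg_sensor)
}

#' Ground-truth barcode-sensor map
#'
#' @param truth A `sim_truth`.
#' @return Data frame usable wherever a `barcode_sensor_map` is expected.
#' @export
truth_map <- function(truth) {
  data.frame(barcode_id = truth$barcodes$barcode_id,
             sensor_id = truth$barcodes$sensor_id,
             n_reads = NA_integer_, status = "assigned",
             stringsAsFactors = FALSE)
}

#' Simulate paired-culture read counts for one condition
#'
#' -spectinomycin relative abundance equals the library composition
#' (uniform growth); +spectinomycin relative abundance is proportional to
#' `a_i * (f_i * G + (1 - f_i))`. Counts are drawn multinomially at
#' `read_depth` per culture, or returned as exact expected (possibly
#' non-integer) counts in noiseless mode. Optional log-normal lag-phase
#' multipliers (independent per culture) emulate variable strain outgrowth.
#'
#' @param truth A `sim_truth` from [generate_library()].
#' @param condition Condition label (a column of `truth$f`).
#' @param noiseless If `TRUE`, emit expected counts instead of sampling.
#' @param sample_id Sample identifier; default derived from the condition.
#' @param barcode_subset Optional barcode ids to restrict the library to
#'   (e.g. bottleneck survivors).
#' @return A [screen_sample()].
#' @export
simulate_screen_counts <- function(truth, condition, noiseless = FALSE,
                                   sample_id = paste0(condition, "_s1"),
                                   barcode_subset = NULL) {
  config <- truth$config
  bc <- truth$barcodes
  if (!is.null(barcode_subset)) {
    bc <- bc[bc$barcode_id %in% barcode_subset, , drop = FALSE]
  }
  if (!condition %in% colnames(truth$f)) {
    stop("condition has no defined ON-fractions: ", condition)
  }
  f <- truth$f[bc$sensor_id, condition]
  G <- config$outgrowth_fold_change
  w_minus <- bc$abundance
  w_plus <- bc$abundance * (f * G + (1 - f))
  if (config$lag_sd > 0 && !noiseless) {
    w_minus <- w_minus * rlnorm(nrow(bc), 0, config$lag_sd)
    w_plus <- w_plus * rlnorm(nrow(bc), 0, config$lag_sd)
  }
  p_minus <- w_minus / sum(w_minus)
  p_plus <- w_plus / sum(w_plus)
  if (noiseless) {
    cm <- config$read_depth * p_minus
    cp <- config$read_depth * p_plus
  } else {
    cm <- as.numeric(rmultinom(1, config$read_depth, p_minus))
    cp <- as.numeric(rmultinom(1, config$read_depth, p_plus))
  }
  screen_sample(sample_id, condition,
                setNames(cp, bc$barcode_id), setNames(cm, bc$barcode_id))
}

#' Simulate sequencing reads for a sample
#'
#' Short reads are the barcode sequences with i.i.d. substitutions at the
#' short-read error rate, with multiplicities given by the sample's counts
#' (total per culture equals the sampled depth). Long reads are
#' adapter + sensor reference + barcode + adapter concatenations carrying
#' substitutions and geometric-length indels at the long-read error rate,
#' `long_reads_per_barcode` per barcode.
#'
#' @param truth A `sim_truth`.
#' @param sample A [screen_sample()] from [simulate_screen_counts()]
#'   (counts are rounded if noiseless).
#' @param out_dir If non-`NULL`, write `short_plus.fastq`,
#'   `short_minus.fastq` and `long.fastq` there and return the paths.
#' @return List with character vectors `short_plus`, `short_minus`, `long`
#'   (named by read id; names encode the true barcode for validation), or
#'   file paths when `out_dir` is given.
#' @export
simulate_reads <- function(truth, sample, out_dir = NULL) {
  config <- truth$config
  bc <- truth$barcodes[truth$barcodes$barcode_id %in% names(sample$counts_minus), ,
                       drop = FALSE]
  make_short <- function(counts) {
    counts <- round(counts[bc$barcode_id])
    tmpl <- rep(bc$sequence, counts)
    ids <- paste0(rep(bc$barcode_id, counts), "_r", sequence(counts))
    out <- cpp_mutate_reads(tmpl, config$short_read_error_rate, 0, 0)
    setNames(as.character(out), ids)
  }
  short_plus <- make_short(sample$counts_plus)
  short_minus <- make_short(sample$counts_minus)

  refs <- setNames(truth$sensors$reference_sequence, truth$sensors$sensor_id)
  n_long <- config$long_reads_per_barcode
  tmpl <- paste0(config$adapter, refs[bc$sensor_id], bc$sequence, config$adapter)
  tmpl <- rep(tmpl, each = n_long)
  ids <- paste0(rep(bc$barcode_id, each = n_long), "_L", seq_len(n_long))
  sub_rate <- 0.75 * config$long_read_error_rate
  indel_rate <- 0.25 * config$long_read_error_rate
  long <- cpp_mutate_reads(tmpl, sub_rate, indel_rate, 0.3)
  long <- setNames(as.character(long), ids)

  if (is.null(out_dir)) {
    return(list(short_plus = short_plus, short_minus = short_minus,
                long = long))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in c("short_plus", "short_minus", "long")) {
    x <- get(nm)
    p <- file.path(out_dir, paste0(nm, ".fastq"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), p,
                                format = "fastq")
    paths[[nm]] <- p
  }
  paths
}

#' Simulate a colonisation bottleneck
#'
#' Draws `n_cells` cells multinomially over the library's barcode
#' abundances; survivors are the barcodes receiving at least one cell.
#'
#' @param truth A `sim_truth`.
#' @param n_cells Bottleneck size (>= 1); defaults to the configured
#'   `bottleneck_size`.
#' @return Character vector of surviving barcode ids.
#' @export
simulate_bottleneck <- function(truth, n_cells = truth$config$bottleneck_size) {
  stopifnot(n_cells >= 1)
  cells <- as.numeric(rmultinom(1, n_cells, truth$barcodes$abundance))
  truth$barcodes$barcode_id[cells >= 1]
}

#' Simulate a complete screening experiment
#'
#' Convenience driver: generates a library, simulates paired-culture counts
#' for every condition (optionally several replicate samples each) and,
#' when requested, sequencing reads for the first sample of each condition.
#'
#' @param config A [sim_config()].
#' @param conditions Condition labels; default `c("gavage", "induced")`.
#' @param replicates Samples per condition; default 1.
#' @param noiseless Passed to [simulate_screen_counts()].
#' @param reads If `TRUE`, also simulate reads for each condition's first
#'   sample.
#' @param out_dir Optional directory for FASTQ/TSV output.
#' @param f_fun Passed to [generate_library()].
#' @return List with `truth`, `samples` (list of [screen_sample()]),
#'   `norm` (a [norm_set()]), `map` (ground-truth map) and optionally
#'   `reads`.
#' @export
simulate_screen <- function(config = sim_config(),
                            conditions = c("gavage", "induced"),
                            replicates = 1L, noiseless = FALSE,
                            reads = FALSE, out_dir = NULL, f_fun = NULL) {
  truth <- generate_library(config, conditions = conditions, f_fun = f_fun)
  samples <- list()
  for (cond in conditions) {
    for (r in seq_len(replicates)) {
      sid <- paste0(cond, "_s", r)
      samples[[sid]] <- simulate_screen_counts(truth, cond, noiseless,
                                               sample_id = sid)
    }
  }
  out <- list(truth = truth, samples = samples, norm = truth_norm_set(truth),
              map = truth_map(truth))
  if (reads) {
    out$reads <- lapply(conditions, function(cond) {
      simulate_reads(truth, samples[[paste0(cond, "_s1")]],
                     out_dir = if (is.null(out_dir)) NULL
                               else file.path(out_dir, cond))
    })
    names(out$reads) <- conditions
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(truth$barcodes, file.path(out_dir, "truth_barcodes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- do.call(rbind, lapply(samples, function(s) {
      data.frame(barcode_id = names(s$counts_plus), sample_id = s$sample_id,
                 culture = rep(c("plus", "minus"),
                               each = length(s$counts_plus)),
                 reads = c(unname(s$counts_plus), unname(s$counts_minus)),
                 stringsAsFactors = FALSE)
    }))
    write.table(counts, file.path(out_dir, "counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}
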