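#' Fractional odds ratio quantification
#'
#' Memory-ON cells express the aadA resistance cassette and therefore grow
#' under spectinomycin; OFF cells persist (spectinomycin is bacteriostatic)
#' at a level set by the culture's outgrowth fold change. Activation of each
#' barcode is quantified by comparing its read counts between paired
#' +spectinomycin and -spectinomycin cultures:
#'
#' \deqn{OR = \frac{BC_{+S} / \mathrm{mean}(PNB_{+S})}{BC_{-S} /
#'   \mathrm{mean}(PNB_{-S})}}
#'
#' where PNB are counts of positive normalisation barcodes (constitutively
#' ON strains). The fractional odds ratio rescales OR between the mean OR of
#' negative (~0, fully OFF) and positive (~1, fully ON) control strains:
#'
#' \deqn{FOR = \frac{OR - OR_{neg}}{OR_{pos} - OR_{neg}}}
#'
#' and is interpretable as the switched-ON fraction of the population.
#'
#' @name for_quant
NULL

#' Construct a screen sample
#'
#' @param sample_id Sample identifier.
#' @param condition Free-text condition label (e.g. `gavage`,
#'   `control-day2`).
#' @param counts_plus,counts_minus Named numeric vectors of per-barcode read
#'   counts in the +spectinomycin and -spectinomycin cultures. The two
#'   vectors are aligned onto the union of their barcode names (missing
#'   entries become 0).
#' @return Object of class `screen_sample`.
#' @export
screen_sample <- function(sample_id, condition, counts_plus, counts_minus) {
  if (any(counts_plus < 0) || any(counts_minus < 0)) {
    stop("read counts must be non-negative")
  }
  universe <- union(names(counts_plus), names(counts_minus))
  cp <- setNames(rep(0, length(universe)), universe)
  cm <- cp
  cp[names(counts_plus)] <- counts_plus
  cm[names(counts_minus)] <- counts_minus
  structure(list(sample_id = sample_id, condition = condition,
                 counts_plus = cp, counts_minus = cm),
            class = "screen_sample")
}

#' @export
print.screen_sample <- function(x, ...) {
  cat("Screen sample", x$sample_id, "(", x$condition, "):",
      length(x$counts_plus), "barcodes;",
      sum(x$counts_plus), "+SPECT /", sum(x$counts_minus), "-SPECT reads\n")
  invisible(x)
}

#' Normalisation set
#'
#' Positive normalisation barcodes (constitutively ON strains inside the
#' library) and the internal negative-control sensor.
#'
#' @param positive_barcodes Character vector of barcode ids (at least 2).
#' @param negative_sensor Single sensor id.
#' @return Object of class `norm_set`.
#' @export
norm_set <- function(positive_barcodes, negative_sensor) {
  stopifnot(length(positive_barcodes) >= 2, length(negative_sensor) == 1)
  structure(list(positive_barcodes = positive_barcodes,
                 negative_sensor = negative_sensor), class = "norm_set")
}

#' Per-barcode odds ratio
#'
#' `OR = (bc_plus / mean(pnb_plus)) / (bc_minus / mean(pnb_minus))`.
#' Undefined (`NA`) when `bc_minus` is zero; such barcodes are expected to
#' be removed by the abundance QC. No pseudocounts are applied, keeping the
#' statistic exactly as defined.
#'
#' @param bc_plus,bc_minus Read counts for the barcode (vectorised).
#' @param pnb_plus,pnb_minus Numeric vectors of positive-normalisation
#'   barcode counts in each culture (non-empty, positive mean).
#' @return Numeric vector of odds ratios (`NA` where undefined).
#' @export
compute_odds_ratio <- function(bc_plus, bc_minus, pnb_plus, pnb_minus) {
  if (!length(pnb_plus) || !length(pnb_minus) ||
      mean(pnb_plus) <= 0 || mean(pnb_minus) <= 0) {
    stop("positive normalisation counts have zero mean; sample cannot be normalised")
  }
  or <- (bc_plus / mean(pnb_plus)) / (bc_minus / mean(pnb_minus))
  or[bc_minus == 0] <- NA_real_
  or
}

#' Fractional odds ratio
#'
#' Linear rescaling of an odds ratio between the negative (0) and positive
#' (1) control anchors. Values are deliberately not clipped to `[0, 1]`.
#'
#' @param or_sensor Odds ratio(s) to rescale.
#' @param or_pos Mean odds ratio of the positive control strains.
#' @param or_neg Mean odds ratio of the negative control strain's barcodes.
#' @return Numeric vector of FOR values.
#' @export
compute_for <- function(or_sensor, or_pos, or_neg) {
  if (or_pos <= or_neg) {
    stop("or_pos must exceed or_neg (sample would fail fold-change QC)")
  }
  (or_sensor - or_neg) / (or_pos - or_neg)
}

#' Activation call from a FOR value
#'
#' A sensor is considered potentially activated when its FOR is strictly
#' greater than the threshold (default 0.01, roughly 1% of the population
#' switched ON).
#'
#' @param for_value Numeric vector of FOR values (finite).
#' @param threshold Default 0.01.
#' @return Character vector, `"activated"` or `"not_activated"`.
#' @export
classify_activation <- function(for_value, threshold = 0.01) {
  ifelse(for_value > threshold, "activated", "not_activated")
}

#' Aggregate barcode-level FOR values to sensor level
#'
#' Median mode takes the median FOR over a sensor's QC-passing barcodes.
#' Pooled mode (used for high-barcode-count libraries) sums the sensor's
#' barcode counts in each culture and recomputes OR and FOR on the pooled
#' counts.
#'
#' @param barcode_table Data frame with columns `barcode_id`, `sensor_id`,
#'   `bc_plus`, `bc_minus`, `odds_ratio`, `fractional_odds_ratio`,
#'   `qc_pass`.
#' @param mode `"median"` or `"pooled"`.
#' @param pnb_plus,pnb_minus Positive-normalisation counts (pooled mode
#'   only).
#' @param or_pos,or_neg Control anchors (pooled mode only).
#' @return Data frame: `sensor_id`, `n_barcodes`, `odds_ratio` (pooled mode),
#'   `fractional_odds_ratio`, `insufficient_data`.
#' @export
aggregate_sensor_for <- function(barcode_table, mode = c("median", "pooled"),
                                 pnb_plus = NULL, pnb_minus = NULL,
                                 or_pos = NULL, or_neg = NULL) {
  mode <- match.arg(mode)
  sensors <- unique(barcode_table$sensor_id)
  rows <- lapply(sensors, function(s) {
    sub <- barcode_table[barcode_table$sensor_id == s, , drop = FALSE]
    if (mode == "median") {
      ok <- sub[sub$qc_pass & !is.na(sub$fractional_odds_ratio), , drop = FALSE]
      if (!nrow(ok)) {
        return(data.frame(sensor_id = s, n_barcodes = 0L, odds_ratio = NA_real_,
                          fractional_odds_ratio = NA_real_,
                          insufficient_data = TRUE, stringsAsFactors = FALSE))
      }
      data.frame(sensor_id = s, n_barcodes = nrow(ok),
                 odds_ratio = median(ok$odds_ratio),
                 fractional_odds_ratio = median(ok$fractional_odds_ratio),
                 insufficient_data = FALSE, stringsAsFactors = FALSE)
    } else {
      bp <- sum(sub$bc_plus); bm <- sum(sub$bc_minus)
      if (bm == 0) {
        return(data.frame(sensor_id = s, n_barcodes = nrow(sub),
                          odds_ratio = NA_real_,
                          fractional_odds_ratio = NA_real_,
                          insufficient_data = TRUE, stringsAsFactors = FALSE))
      }
      or <- compute_odds_ratio(bp, bm, pnb_plus, pnb_minus)
      data.frame(sensor_id = s, n_barcodes = nrow(sub), odds_ratio = or,
                 fractional_odds_ratio = compute_for(or, or_pos, or_neg),
                 insufficient_data = FALSE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Quantify a screen sample
#'
#' Full per-sample quantification with the QC gates applied in order:
#' low-count positive-barcode exclusion, outgrowth-variability gate,
#' abundance filter, OR/FOR computation, fold-change gate. In pooled mode
#' all counts (including the normalisation controls) are first pooled by
#' sensor, and the pooled sensors take the place of barcodes throughout.
#'
#' @param sample A [screen_sample()].
#' @param map A `barcode_sensor_map` (or data frame with `barcode_id`,
#'   `sensor_id`, `status`).
#' @param norm A [norm_set()].
#' @param mode `"median"` (barcode-level FOR, sensor = median) or
#'   `"pooled"` (counts pooled by sensor first).
#' @param config A [qc_config()].
#' @return Object of class `for_result`: list with `barcode_table`,
#'   `sensor_table`, `qc` (a `qc_report`), `or_pos`, `or_neg`,
#'   `sample_id`, `condition`, `mode`.
#' @export
quantify_sample <- function(sample, map, norm, mode = c("median", "pooled"),
                            config = qc_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "screen_sample"), inherits(norm, "norm_set"))
  assigned <- map[map$status == "assigned", , drop = FALSE]
  sensor_of <- setNames(assigned$sensor_id, assigned$barcode_id)

  cp <- sample$counts_plus
  cm <- sample$counts_minus
  known <- intersect(names(cp), names(sensor_of))
  cp <- cp[known]; cm <- cm[known]

  if (mode == "pooled") {
    # pool reads by sensor before OR, FOR and QC
    sens <- sensor_of[known]
    cp <- tapply(cp, sens, sum)
    cm <- tapply(cm, sens, sum)
    cp <- setNames(as.numeric(cp), names(cp))
    cm <- setNames(as.numeric(cm), names(cm))
    units_sensor <- setNames(names(cp), names(cp))
    pos_units <- unique(sensor_of[intersect(norm$positive_barcodes,
                                            names(sensor_of))])
  } else {
    units_sensor <- sensor_of[known]
    pos_units <- intersect(norm$positive_barcodes, known)
  }
  neg_units <- names(units_sensor)[units_sensor == norm$negative_sensor]

  # 1. positive-control low-count exclusion (< min_positive_reads in either
  #    culture)
  usable_pos <- pos_units[cp[pos_units] >= config$min_positive_reads &
                          cm[pos_units] >= config$min_positive_reads]
  excluded_pos <- setdiff(pos_units, usable_pos)
  if (!length(usable_pos)) {
    stop("no usable positive normalisation barcodes in sample ",
         sample$sample_id,
         " (all fell below the ", config$min_positive_reads, "-read exclusion)")
  }

  # 2. outgrowth-variability gate
  og <- outgrowth_fit(cp, cm, usable_pos, config)

  # 3. abundance filter (on the -spectinomycin culture)
  kept <- abundance_filter(cm, config)

  # 4. OR / FOR
  pnb_plus <- cp[usable_pos]; pnb_minus <- cm[usable_pos]
  or_all <- compute_odds_ratio(cp, cm, pnb_plus, pnb_minus)
  pos_or <- or_all[usable_pos]
  neg_usable <- intersect(neg_units, kept)
  neg_or <- or_all[neg_usable]
  neg_or <- neg_or[!is.na(neg_or)]
  if (!length(neg_or)) {
    stop("no usable negative-control barcodes in sample ", sample$sample_id)
  }
  or_pos <- mean(pos_or, na.rm = TRUE)
  or_neg <- mean(neg_or)
  for_all <- compute_for(or_all, or_pos, or_neg)

  # 5. fold-change gate (geometric means of control ORs)
  fc <- fold_change_check(pos_or, neg_or, config)

  unit_table <- data.frame(
    barcode_id = names(units_sensor), sensor_id = unname(units_sensor),
    bc_plus = unname(cp[names(units_sensor)]),
    bc_minus = unname(cm[names(units_sensor)]),
    odds_ratio = unname(or_all[names(units_sensor)]),
    fractional_odds_ratio = unname(for_all[names(units_sensor)]),
    qc_pass = names(units_sensor) %in% kept &
      !is.na(or_all[names(units_sensor)]),
    stringsAsFactors = FALSE)

  if (mode == "median") {
    sensor_table <- aggregate_sensor_for(unit_table, mode = "median")
  } else {
    sensor_table <- unit_table[, c("sensor_id", "odds_ratio",
                                   "fractional_odds_ratio")]
    sensor_table$n_barcodes <- as.integer(table(sensor_of[known])[sensor_table$sensor_id])
    sensor_table$insufficient_data <- !unit_table$qc_pass
    sensor_table <- sensor_table[, c("sensor_id", "n_barcodes", "odds_ratio",
                                     "fractional_odds_ratio",
                                     "insufficient_data")]
  }
  sensor_table$activation <- classify_activation(
    ifelse(is.na(sensor_table$fractional_odds_ratio), -Inf,
           sensor_table$fractional_odds_ratio))

  qc <- structure(list(
    sample_id = sample$sample_id,
    outgrowth = og,
    abundance_summary = c(kept = length(kept), total = length(cp)),
    fold_change = fc,
    excluded_positive_barcodes = excluded_pos,
    sample_pass = isTRUE(og$pass) && isTRUE(fc$pass)
  ), class = "qc_report")

  structure(list(barcode_table = unit_table, sensor_table = sensor_table,
                 qc = qc, or_pos = or_pos, or_neg = or_neg,
                 sample_id = sample$sample_id, condition = sample$condition,
                 mode = mode),
            class = "for_result")
}

#' @export
print.for_result <- function(x, ...) {
  cat("FOR result for sample", x$sample_id, "(", x$condition, "), mode:",
      x$mode, "\n  OR_pos =", signif(x$or_pos, 4),
      "; OR_neg =", signif(x$or_neg, 4),
      "; sample QC:", if (x$qc$sample_pass) "PASS" else "FAIL", "\n  ",
      nrow(x$sensor_table), "sensors,",
      sum(x$sensor_table$activation == "activated", na.rm = TRUE),
      "called activated (FOR > 0.01)\n")
  invisible(x)
}
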