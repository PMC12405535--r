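#' Sample and barcode quality control
#'
#' Three gates guard each screen sample: (i) an outgrowth-variability gate
#' based on a linear fit across the positive normalisation barcodes, (ii) a
#' per-barcode abundance filter in the unselected (-spectinomycin) culture,
#' and (iii) a fold-change gate requiring clear separation between the
#' positive and negative control strains. A sample passes overall iff the
#' outgrowth and fold-change gates pass.
#'
#' @name qc
NULL

#' QC configuration
#'
#' @param min_r2 Outgrowth fit must achieve R-squared above this (default
#'   0.6).
#' @param slope_range Outgrowth fit slope must lie strictly inside this
#'   interval (default `c(0.5, 2)`).
#' @param min_abundance_fraction Barcodes must exceed this fraction of
#'   -spectinomycin reads (default 1/5000).
#' @param min_positive_reads Positive-control barcodes below this read count
#'   in either culture are excluded (default 100).
#' @param min_fold_change Geometric-mean positive/negative OR fold change
#'   must exceed this (default 30).
#' @param detection_threshold Reads needed to count a barcode as recovered
#'   (default 1).
#' @return Object of class `qc_config`.
#' @export
qc_config <- function(min_r2 = 0.6, slope_range = c(0.5, 2),
                      min_abundance_fraction = 1 / 5000,
                      min_positive_reads = 100L, min_fold_change = 30,
                      detection_threshold = 1L) {
  stopifnot(min_r2 > 0, min_abundance_fraction > 0, min_positive_reads > 0,
            min_fold_change > 0, slope_range[1] < slope_range[2])
  structure(list(min_r2 = min_r2, slope_range = slope_range,
                 min_abundance_fraction = min_abundance_fraction,
                 min_positive_reads = min_positive_reads,
                 min_fold_change = min_fold_change,
                 detection_threshold = detection_threshold),
            class = "qc_config")
}

#' Barcode abundance filter
#'
#' Keeps barcodes whose read fraction in the -spectinomycin culture is
#' strictly greater than `min_abundance_fraction`. The unselected culture is
#' used because it reflects total library composition; a fraction of 1/5000
#' of a stationary culture corresponds to only tens to hundreds of cells
#' after the 1:1000 split into the paired cultures (see
#' [abundance_to_cfu()]).
#'
#' @param counts_minus Named numeric vector of -spectinomycin counts, or a
#'   [screen_sample()].
#' @param config A [qc_config()].
#' @return Character vector of kept barcode ids.
#' @export
abundance_filter <- function(counts_minus, config = qc_config()) {
  if (inherits(counts_minus, "screen_sample")) {
    counts_minus <- counts_minus$counts_minus
  }
  total <- sum(counts_minus)
  if (!length(counts_minus) || total <= 0) {
    stop("abundance_filter(): sample has no -spectinomycin reads")
  }
  names(counts_minus)[counts_minus / total > config$min_abundance_fraction]
}

#' Expected cell density of a barcode at an abundance fraction
#'
#' Back-of-envelope arithmetic behind the abundance threshold: a barcode at
#' `fraction` of a culture at `culture_cfu_per_ml` CFU/mL, diluted by
#' `dilution`, is present at `culture_cfu_per_ml * fraction / dilution`
#' CFU/mL.
#'
#' @param culture_cfu_per_ml Stationary-phase density (e.g. `1e8`-`1e9`).
#' @param fraction Abundance fraction (default 1/5000).
#' @param dilution Dilution factor into the split cultures (default 1000).
#' @return CFU/mL after dilution.
#' @export
abundance_to_cfu <- function(culture_cfu_per_ml, fraction = 1 / 5000,
                             dilution = 1000) {
  culture_cfu_per_ml * fraction / dilution
}

#' Outgrowth-variability gate
#'
#' Ordinary least-squares fit, across the usable positive-control barcodes,
#' of the +spectinomycin read fraction against the -spectinomycin read
#' fraction (each normalised within the positive-control set, so a sample
#' with uniform outgrowth gives slope 1, R-squared 1). High scatter or a
#' slope far from 1 indicates variable strain outgrowth (e.g. differential
#' lag phases) that would distort odds ratios. Pass requires
#' `r2 > min_r2` and `slope` strictly inside `slope_range`.
#'
#' @param counts_plus,counts_minus Named numeric count vectors for the
#'   sample.
#' @param positive_ids Usable positive-control barcode ids (after the
#'   low-count exclusion); at least 3 required.
#' @param config A [qc_config()].
#' @return List: `slope`, `r2`, `pass`, `n`, `reason`.
#' @export
outgrowth_fit <- function(counts_plus, counts_minus, positive_ids,
                          config = qc_config()) {
  positive_ids <- intersect(positive_ids, names(counts_plus))
  if (length(positive_ids) < 3L) {
    return(list(slope = NA_real_, r2 = NA_real_, pass = FALSE,
                n = length(positive_ids),
                reason = "fewer than 3 usable positive-control barcodes"))
  }
  yp <- counts_plus[positive_ids]
  xm <- counts_minus[positive_ids]
  if (sum(yp) <= 0 || sum(xm) <= 0) {
    return(list(slope = NA_real_, r2 = NA_real_, pass = FALSE,
                n = length(positive_ids),
                reason = "positive-control barcodes have no reads"))
  }
  y <- yp / sum(yp)
  x <- xm / sum(xm)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  pass <- is.finite(slope) && is.finite(r2) && r2 > config$min_r2 &&
    slope > config$slope_range[1] && slope < config$slope_range[2]
  list(slope = slope, r2 = r2, pass = pass, n = length(positive_ids),
       reason = if (pass) NA_character_ else "outgrowth variability")
}

#' Fold-change gate
#'
#' Fold change between the geometric-mean OR of the positive and negative
#' control strains; insufficient separation means the library outgrowth was
#' too weak to distinguish ON from OFF sensors. Zero or undefined ORs are
#' excluded from the geometric means. Pass requires `fc > min_fold_change`.
#'
#' @param pos_or,neg_or Numeric vectors of control odds ratios.
#' @param config A [qc_config()].
#' @return List: `fc`, `pass`, `reason`.
#' @export
fold_change_check <- function(pos_or, neg_or, config = qc_config()) {
  pos_or <- pos_or[!is.na(pos_or) & pos_or > 0]
  neg_or <- neg_or[!is.na(neg_or) & neg_or > 0]
  if (!length(pos_or) || !length(neg_or)) {
    return(list(fc = NA_real_, pass = FALSE,
                reason = "insufficient difference between positive and negative strains"))
  }
  fc <- geometric_mean(pos_or) / geometric_mean(neg_or)
  list(fc = fc, pass = fc > config$min_fold_change,
       reason = if (fc > config$min_fold_change) NA_character_
                else "fold change below threshold")
}

#' Library recovery fractions
#'
#' Fraction of assigned barcodes (and of sensors with at least one detected
#' barcode) observed with at least `detection_threshold` reads in the
#' -spectinomycin culture of a sample.
#'
#' @param sample A [screen_sample()] or named -spectinomycin count vector.
#' @param map A `barcode_sensor_map` (assigned rows are used).
#' @param config A [qc_config()] (supplies `detection_threshold`).
#' @return Named numeric vector `c(barcode_fraction, sensor_fraction)`.
#' @export
recovered_fraction <- function(sample, map, config = qc_config()) {
  cm <- if (inherits(sample, "screen_sample")) sample$counts_minus else sample
  assigned <- map[map$status == "assigned", , drop = FALSE]
  if (!nrow(assigned)) stop("recovered_fraction(): map has no assigned barcodes")
  detected <- names(cm)[cm >= config$detection_threshold]
  bc_frac <- mean(assigned$barcode_id %in% detected)
  sensors <- unique(assigned$sensor_id)
  sensor_detected <- vapply(sensors, function(s) {
    any(assigned$barcode_id[assigned$sensor_id == s] %in% detected)
  }, logical(1))
  c(barcode_fraction = bc_frac, sensor_fraction = mean(sensor_detected))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report for sample", x$sample_id, "\n",
      " outgrowth: slope =", signif(x$outgrowth$slope, 3),
      ", r2 =", signif(x$outgrowth$r2, 3),
      if (isTRUE(x$outgrowth$pass)) "(pass)" else "(FAIL)", "\n",
      " abundance: kept", x$abundance_summary[["kept"]], "/",
      x$abundance_summary[["total"]], "barcodes\n",
      " fold change:", signif(x$fold_change$fc, 4),
      if (isTRUE(x$fold_change$pass)) "(pass)" else "(FAIL)", "\n",
      " overall:", if (isTRUE(x$sample_pass)) "PASS" else "FAIL", "\n")
  invisible(x)
}
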