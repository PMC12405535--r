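#' Sensor ranking
#'
#' Ranks sensors for in-vivo responsiveness or condition (e.g. inflammation)
#' specificity. Sensors are first required to be OFF in the gavage (input
#' inoculum) sample, `gavage FOR < 0.25`; the score is then a difference of
#' mean FOR values across sample groups.
#'
#' @name ranker
NULL

#' Rank sensors from sensor-level FOR values
#'
#' In `in_vivo` mode the score is `mean(faecal FOR) - gavage FOR` over all
#' QC-passing non-gavage samples. In `condition` mode it is
#' `mean(treatment FOR) - mean(control FOR)` over the named groups. Means
#' across samples are unweighted; samples failing QC and sensor/sample
#' combinations with missing FOR are dropped before averaging (`n_samples`
#' records how many contributed). Ties are broken by `sensor_id`.
#'
#' @param for_table Data frame with columns `sensor_id`, `sample_id`,
#'   `fractional_odds_ratio` and optionally `qc_pass` (defaults to `TRUE`).
#' @param design Data frame mapping `sample_id` to `group`. The gavage
#'   sample(s) must carry the group label `gavage_label`.
#' @param mode `"in_vivo"` or `"condition"`.
#' @param treatment,control Group labels used in `condition` mode.
#' @param gavage_label Group label of the gavage sample (default
#'   `"gavage"`).
#' @param max_gavage_for Sensors at or above this gavage FOR are excluded
#'   (default 0.25; the filter is strict: `gavage FOR < 0.25`).
#' @return Data frame of class `ranked_sensors`: `sensor_id`, `gavage_for`,
#'   group means, `score`, `n_samples`, `rank` (1 = top), sorted by rank.
#'   Sensors excluded by the gavage filter or missing data are attached as
#'   attribute `excluded`.
#' @export
rank_sensors <- function(for_table, design, mode = c("in_vivo", "condition"),
                         treatment = "treatment", control = "control",
                         gavage_label = "gavage", max_gavage_for = 0.25) {
  mode <- match.arg(mode)
  stopifnot(all(c("sensor_id", "sample_id", "fractional_odds_ratio") %in%
                  names(for_table)),
            all(c("sample_id", "group") %in% names(design)))
  if (!"qc_pass" %in% names(for_table)) for_table$qc_pass <- TRUE
  for_table$group <- design$group[match(for_table$sample_id, design$sample_id)]
  gavage_samples <- design$sample_id[design$group == gavage_label]
  if (!length(gavage_samples)) stop("no gavage sample in the design")

  ft <- for_table[for_table$qc_pass & !is.na(for_table$fractional_odds_ratio), ,
                  drop = FALSE]
  sensors <- sort(unique(for_table$sensor_id))
  rows <- list(); excluded <- list()
  for (s in sensors) {
    sub <- ft[ft$sensor_id == s, , drop = FALSE]
    gav <- sub$fractional_odds_ratio[sub$sample_id %in% gavage_samples]
    if (!length(gav)) {
      excluded[[s]] <- "no gavage FOR"
      next
    }
    gavage_for <- mean(gav)
    if (!(gavage_for < max_gavage_for)) {
      excluded[[s]] <- "gavage FOR >= 0.25"
      next
    }
    if (mode == "in_vivo") {
      faecal <- sub$fractional_odds_ratio[!(sub$sample_id %in% gavage_samples)]
      if (!length(faecal)) {
        excluded[[s]] <- "no passing faecal samples"
        next
      }
      score <- mean(faecal) - gavage_for
      rows[[s]] <- data.frame(sensor_id = s, gavage_for = gavage_for,
                              mean_faecal_for = mean(faecal), score = score,
                              n_samples = length(faecal),
                              stringsAsFactors = FALSE)
    } else {
      trt <- sub$fractional_odds_ratio[sub$group == treatment]
      ctl <- sub$fractional_odds_ratio[sub$group == control]
      if (!length(trt) || !length(ctl)) {
        excluded[[s]] <- "missing treatment or control samples"
        next
      }
      score <- mean(trt) - mean(ctl)
      rows[[s]] <- data.frame(sensor_id = s, gavage_for = gavage_for,
                              mean_treatment_for = mean(trt),
                              mean_control_for = mean(ctl), score = score,
                              n_samples = length(trt) + length(ctl),
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no sensors eligible for ranking")
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$sensor_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "excluded") <- unlist(excluded)
  class(out) <- c("ranked_sensors", class(out))
  out
}

#' @export
print.ranked_sensors <- function(x, ...) {
  cat("Sensor ranking (", nrow(x), "sensors;",
      length(attr(x, "excluded")), "excluded)\n")
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
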