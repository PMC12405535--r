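#' Barcode-to-sensor linkage from long reads
#'
#' Long reads spanning the sensor-barcode junction link each reference
#' barcode to its sensor. Reads are adapter-trimmed and length-filtered,
#' aligned to sensor reference sequences (the part extending past the
#' reference is the candidate barcode tail), and tails are matched to
#' reference barcodes. Barcodes are then assigned under a dual-criterion
#' rule: the winning sensor must hold both the highest read count for that
#' barcode and the highest count normalised by the sensor's total long
#' reads, with at least `min_reads` supporting reads.
#'
#' @name assigner
NULL

# Default Oxford Nanopore ligation adapter used for trimming.
DEFAULT_ADAPTER <- "CCTGTACTTCGTTCAGTTACGTATTGCT"

#' Adapter-trim and length-filter long reads
#'
#' Removes one leading and one trailing adapter occurrence per read, allowing
#' up to `max_mismatch` substitutions with at least `min_match` bases of the
#' adapter present (occurrences may overhang the read ends). Reads whose
#' remaining length is not strictly greater than `min_length` are discarded.
#'
#' @param reads Named character vector (or `DNAStringSet`) of long reads.
#' @param adapter Adapter sequence (length >= 10).
#' @param max_mismatch Allowed substitutions within the matched adapter
#'   region; default 5.
#' @param min_match Minimum adapter bases that must overlap the read;
#'   default 10.
#' @param min_length Reads must exceed this length after trimming
#'   (default 400 bp).
#' @return List with `kept` (named character vector of trimmed reads) and
#'   `discarded` (data frame `read_id`, `reason`).
#' @export
preprocess_long_reads <- function(reads, adapter = DEFAULT_ADAPTER,
                                  max_mismatch = 5L, min_match = 10L,
                                  min_length = 400L) {
  if (nchar(adapter) < 10L) stop("adapter must be at least 10 bp")
  reads <- setNames(as.character(reads), names(reads))
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  trimmed <- cpp_trim_adapter(reads, adapter, max_mismatch, min_match, 40L)
  names(trimmed) <- names(reads)
  keep <- nchar(trimmed) > min_length
  list(kept = trimmed[keep],
       discarded = data.frame(read_id = names(trimmed)[!keep],
                              reason = rep("too_short", sum(!keep)),
                              stringsAsFactors = FALSE))
}

#' Align long reads to sensor references and extract barcode tails
#'
#' Each read is aligned against all sensor references with an end-gap-free
#' (overlap) alignment; candidate references are pre-selected by shared
#' k-mers. A read is attributed to the best-scoring sensor when the identity
#' over the aligned span is at least `min_identity`; score ties between
#' references leave the read unaligned. The read suffix extending past the
#' reference 3' end is returned as the barcode-containing tail (empty when
#' the read is contained within the reference).
#'
#' @param reads Named character vector of trimmed long reads.
#' @param sensor_refs Named character vector of sensor reference sequences
#'   (barcode regions excluded).
#' @param min_identity Minimum alignment identity; default 0.75 (long-read
#'   error rates).
#' @param seed_k k-mer size for candidate pre-selection (default 11).
#' @param top_n Candidates aligned per read (default 3).
#' @return Data frame: `read_id`, `sensor_id` (`NA` if unaligned),
#'   `identity`, `tail`.
#' @export
align_long_reads <- function(reads, sensor_refs, min_identity = 0.75,
                             seed_k = 11L, top_n = 3L) {
  stopifnot(length(sensor_refs) > 0, !is.null(names(sensor_refs)))
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  if (!length(reads)) {
    return(data.frame(read_id = character(), sensor_id = character(),
                      identity = numeric(), tail = character(),
                      stringsAsFactors = FALSE))
  }
  hits <- cpp_seed_fit_align(unname(reads), unname(sensor_refs),
                             as.integer(seed_k), as.integer(top_n))
  ok <- hits$ref_idx > 0 & !hits$tie & !is.na(hits$identity) &
    hits$identity >= min_identity
  sensor_id <- ifelse(ok, names(sensor_refs)[hits$ref_idx], NA_character_)
  tail <- character(length(reads))
  for (i in seq_along(reads)) {
    if (ok[i] && hits$end[i] < nchar(reads[i])) {
      tail[i] <- substr(reads[i], hits$end[i] + 1L, nchar(reads[i]))
    }
  }
  data.frame(read_id = names(reads), sensor_id = sensor_id,
             identity = ifelse(ok, hits$identity, NA_real_), tail = tail,
             stringsAsFactors = FALSE)
}

#' Match barcode tails against reference barcodes
#'
#' The tail extracted by [align_long_reads()] is compared against all
#' reference barcodes with the same overlap alignment; the best-scoring
#' match counts as evidence when its identity over the barcode span is at
#' least `min_identity`. Ties contribute nothing.
#'
#' @param tails Character vector of tails.
#' @param barcodes Named character vector of reference barcode sequences.
#' @param min_identity Default 0.80.
#' @param seed_k,top_n Seeding parameters as in [align_long_reads()].
#' @return Character vector of barcode ids (`NA` where unmatched).
#' @export
match_tails_to_barcodes <- function(tails, barcodes, min_identity = 0.80,
                                    seed_k = 9L, top_n = 3L) {
  stopifnot(length(barcodes) > 0, !is.null(names(barcodes)))
  out <- rep(NA_character_, length(tails))
  nonempty <- which(nchar(tails) > 0)
  if (!length(nonempty)) return(out)
  hits <- cpp_seed_fit_align(tails[nonempty], unname(barcodes),
                             as.integer(seed_k), as.integer(top_n))
  ok <- hits$ref_idx > 0 & !hits$tie & !is.na(hits$identity) &
    hits$identity >= min_identity
  out[nonempty[ok]] <- names(barcodes)[hits$ref_idx[ok]]
  out
}

#' Dual-criterion barcode-to-sensor assignment
#'
#' Given the long-read evidence for one barcode, the barcode is assigned to
#' sensor `s` if and only if `s` is the unique maximiser of both the read
#' count and the count normalised by the sensor's total long reads, and its
#' count is at least `min_reads`. Any tie, or disagreement between the two
#' criteria, discards the barcode as ambiguous.
#'
#' @param counts Named numeric vector: trimmed long reads supporting this
#'   barcode, by sensor.
#' @param totals Named numeric vector: all trimmed long reads aligned to each
#'   sensor (must cover `names(counts)`).
#' @param min_reads Minimum supporting reads for assignment; default 5.
#' @return List with `sensor_id` (`NA` unless assigned) and `status` (one of
#'   `assigned`, `ambiguous`, `insufficient_reads`, `no_alignment`).
#' @export
assign_barcode_to_sensor <- function(counts, totals, min_reads = 5L) {
  counts <- counts[counts > 0]
  if (!length(counts)) {
    return(list(sensor_id = NA_character_, status = "no_alignment"))
  }
  if (any(!names(counts) %in% names(totals)) ||
      any(totals[names(counts)] <= 0)) {
    stop("data inconsistency: barcode evidence for a sensor with zero total reads")
  }
  if (any(counts > totals[names(counts)])) {
    stop("data inconsistency: per-sensor count exceeds the sensor total")
  }
  frac <- counts / totals[names(counts)]
  cmax <- which(counts == max(counts))
  fmax <- which(frac == max(frac))
  if (length(cmax) != 1L || length(fmax) != 1L ||
      names(counts)[cmax] != names(counts)[fmax]) {
    return(list(sensor_id = NA_character_, status = "ambiguous"))
  }
  if (counts[cmax] < min_reads) {
    return(list(sensor_id = NA_character_, status = "insufficient_reads"))
  }
  list(sensor_id = names(counts)[cmax], status = "assigned")
}

#' Link barcodes to sensors from long reads
#'
#' Full linkage driver: preprocess reads, align to sensor references,
#' match tails to barcodes, accumulate evidence and apply
#' [assign_barcode_to_sensor()] to every reference barcode. Every input
#' barcode appears exactly once in the result, either assigned or discarded
#' with a reason.
#'
#' @param long_reads Character vector (or path to FASTQ/FASTA) of long reads.
#' @param sensor_refs Named character vector or FASTA path of sensor
#'   references.
#' @param barcodes Named character vector or FASTA path of reference
#'   barcodes.
#' @param min_reads Minimum long reads for assignment (default 5).
#' @param adapter,min_length,min_identity,barcode_min_identity Tuning
#'   parameters, see the stage functions.
#' @param out_file Optional TSV path for the map.
#' @return Object of class `barcode_sensor_map`: data frame `barcode_id`,
#'   `sensor_id`, `n_reads`, `status`, with the evidence matrices attached as
#'   attributes `counts` (barcode x sensor) and `totals`.
#' @export
link_barcodes <- function(long_reads, sensor_refs, barcodes, min_reads = 5L,
                          adapter = DEFAULT_ADAPTER, min_length = 400L,
                          min_identity = 0.75, barcode_min_identity = 0.80,
                          out_file = NULL) {
  read_seqs <- function(x, label) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", x, ignore.case = TRUE))
        "fastq" else "fasta"
      s <- Biostrings::readDNAStringSet(x, format = fmt)
      setNames(as.character(s), names(s))
    } else x
  }
  long_reads <- read_seqs(long_reads)
  sensor_refs <- read_seqs(sensor_refs)
  barcodes <- read_seqs(barcodes)
  pre <- preprocess_long_reads(long_reads, adapter = adapter,
                               min_length = min_length)
  aln <- align_long_reads(pre$kept, sensor_refs, min_identity = min_identity)
  aln <- aln[!is.na(aln$sensor_id), , drop = FALSE]
  totals <- table(factor(aln$sensor_id, levels = names(sensor_refs)))
  totals <- setNames(as.numeric(totals), names(sensor_refs))
  aln$barcode_id <- match_tails_to_barcodes(aln$tail, barcodes,
                                            min_identity = barcode_min_identity)
  ev <- aln[!is.na(aln$barcode_id), , drop = FALSE]
  counts <- table(factor(ev$barcode_id, levels = names(barcodes)),
                  factor(ev$sensor_id, levels = names(sensor_refs)))
  counts <- matrix(as.numeric(counts), nrow = length(barcodes),
                   dimnames = list(names(barcodes), names(sensor_refs)))
  rows <- lapply(names(barcodes), function(b) {
    a <- assign_barcode_to_sensor(counts[b, ], totals, min_reads = min_reads)
    data.frame(barcode_id = b, sensor_id = a$sensor_id,
               n_reads = if (is.na(a$sensor_id)) sum(counts[b, ])
                         else counts[b, a$sensor_id],
               status = a$status, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  attr(map, "counts") <- counts
  attr(map, "totals") <- totals
  class(map) <- c("barcode_sensor_map", class(map))
  if (!is.null(out_file)) {
    write.table(map, out_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  map
}

#' @export
print.barcode_sensor_map <- function(x, ...) {
  cat("Barcode-sensor map:", nrow(x), "barcodes;",
      sum(x$status == "assigned"), "assigned\n")
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
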