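#' Reference barcode calling from short-read amplicon data
#'
#' The library tags every clone with a 106-bp hypervariable DNA barcode read
#' out by short-read sequencing. Reference barcodes are derived by
#' dereplicating reads, filtering to the expected barcode length, clustering
#' at 95% global identity and aggregating read counts onto each cluster's
#' highest-count representative.
#'
#' @name barcode_caller
NULL

#' Dereplicate and length-filter barcode reads
#'
#' Collapses reads to unique sequences with multiplicities, keeping only
#' sequences of exactly `expected_length`. Output is sorted by descending
#' count then lexicographically, the processing order required by
#' [cluster_barcodes()].
#'
#' @param reads Character vector (or `DNAStringSet`) of read sequences.
#' @param expected_length Barcode length; default 106 bp.
#' @param min_count Drop unique sequences below this count (default 1, i.e.
#'   keep everything; 2 drops singletons).
#' @return Data frame with columns `sequence` and `count`.
#' @export
dereplicate_reads <- function(reads, expected_length = 106L, min_count = 1L) {
  reads <- as.character(reads)
  reads <- reads[nchar(reads) == expected_length]
  if (!length(reads)) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(reads)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[df$count >= min_count, , drop = FALSE]
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Greedy centroid clustering of unique barcodes
#'
#' Processes unique sequences in descending-count order (ties broken
#' lexicographically). Each sequence joins the first existing centroid whose
#' global identity (see [pairwise_identity()]) is at least `threshold`,
#' otherwise it founds a new cluster. Because of the processing order, each
#' cluster's reference is its highest-count member; member counts are summed
#' into `total_count`.
#'
#' @param uniques Data frame from [dereplicate_reads()] (columns `sequence`,
#'   `count`), already sorted by descending count then sequence.
#' @param threshold Identity threshold, default 0.95.
#' @return Data frame of clusters: `barcode_id`, `reference_sequence`,
#'   `total_count`, `n_members`, plus a list column `members` holding each
#'   cluster's member data frame.
#' @export
cluster_barcodes <- function(uniques, threshold = 0.95) {
  if (!nrow(uniques)) {
    out <- data.frame(barcode_id = character(), reference_sequence = character(),
                      total_count = integer(), n_members = integer(),
                      stringsAsFactors = FALSE)
    out$members <- list()
    return(out)
  }
  ord <- order(-uniques$count, uniques$sequence)
  uniques <- uniques[ord, , drop = FALSE]
  cl <- cpp_greedy_cluster(uniques$sequence, threshold)
  centroid_idx <- sort(unique(cl))
  res <- lapply(centroid_idx, function(ci) {
    members <- uniques[cl == ci, , drop = FALSE]
    data.frame(reference_sequence = uniques$sequence[ci],
               total_count = sum(members$count),
               n_members = nrow(members), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(barcode_id = sprintf("bc%04d", seq_len(nrow(out))), out)
  out <- out[order(-out$total_count, out$reference_sequence), , drop = FALSE]
  out$barcode_id <- sprintf("bc%04d", seq_len(nrow(out)))
  out$members <- lapply(match(out$reference_sequence, uniques$sequence),
                        function(ci) uniques[cl == ci, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Call reference barcodes from a FASTQ/FASTA file
#'
#' Driver combining [dereplicate_reads()] and [cluster_barcodes()]. Base
#' qualities are ignored (quality-aware denoising is out of scope; the 95%
#' clustering absorbs sequencing-error structure).
#'
#' @param reads Path to a FASTQ or FASTA file, or a character vector of
#'   sequences.
#' @param expected_length,min_count,threshold See [dereplicate_reads()] and
#'   [cluster_barcodes()].
#' @param out_prefix If non-`NULL`, writes `<prefix>.barcodes.tsv` and
#'   `<prefix>.barcodes.fasta`.
#' @return The cluster data frame from [cluster_barcodes()].
#' @export
call_barcodes <- function(reads, expected_length = 106L, min_count = 1L,
                          threshold = 0.95, out_prefix = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  uniques <- dereplicate_reads(reads, expected_length, min_count)
  clusters <- cluster_barcodes(uniques, threshold)
  if (!is.null(out_prefix) && nrow(clusters)) {
    write.table(clusters[, c("barcode_id", "reference_sequence",
                             "total_count", "n_members")],
                paste0(out_prefix, ".barcodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    seqs <- Biostrings::DNAStringSet(setNames(clusters$reference_sequence,
                                              clusters$barcode_id))
    Biostrings::writeXStringSet(seqs, paste0(out_prefix, ".barcodes.fasta"))
  }
  clusters
}
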