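#' Grouped two-component system mining
#'
#' Bacterial two-component systems (TCSs) pair a histidine kinase (HK) with a
#' response regulator (RR). When the HK-RR pair sits head-to-head with a
#' divergently transcribed neighbour gene, the shared intergenic region
#' plausibly carries the promoter the pair regulates; such "grouped" TCSs can
#' be cloned as a single PCR product (pair + intergenic promoter). These
#' functions find grouped TCSs in an annotated genome, extract the sensor
#' region and check Golden Gate (Type IIS) cloning compatibility.
#'
#' @name tcs_miner
NULL

# Validate a gene table (gene_id, contig, start, end, strand, role).
validate_genes <- function(genes) {
  req <- c("gene_id", "contig", "start", "end", "strand", "role")
  missing <- setdiff(req, names(genes))
  if (length(missing)) {
    stop("gene table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("gene_id values must be unique within an annotation set")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  bad <- !is.finite(genes$start) | !is.finite(genes$end) | genes$start > genes$end |
    genes$start < 1
  if (any(bad)) {
    stop("malformed coordinates (need 1 <= start <= end) for: ",
         paste(genes$gene_id[bad], collapse = ", "))
  }
  genes
}

#' Identify HK-RR pairs by proximity
#'
#' Finds every histidine kinase / response regulator pair located on the same
#' contig and DNA strand with an inter-gene gap below `max_gap`. The gap is
#' `downstream$start - upstream$end - 1` in 1-based inclusive coordinates;
#' overlapping genes get gap 0 and are flagged. Either genomic order (HK then
#' RR, or RR then HK) is accepted.
#'
#' @param genes Data frame with columns `gene_id`, `contig`, `start`, `end`
#'   (1-based inclusive), `strand` (`+`/`-`) and `role` (`HK`, `RR` or
#'   `other`).
#' @param max_gap Pairs with gap strictly below this value (default 200 bp)
#'   are kept.
#' @return Data frame with one row per pair: `hk_id`, `rr_id`, `contig`,
#'   `strand`, `start`, `end` (span of the pair), `gap`, `overlapping` and
#'   `first_gene` (which member comes first in genomic order).
#' @export
identify_hk_rr_pairs <- function(genes, max_gap = 200L) {
  genes <- validate_genes(genes)
  hk <- genes[genes$role == "HK", , drop = FALSE]
  rr <- genes[genes$role == "RR", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(hk))) {
    h <- hk[i, ]
    cand <- rr[rr$contig == h$contig & rr$strand == h$strand, , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      r <- cand[j, ]
      up <- if (h$start <= r$start) h else r
      dn <- if (h$start <= r$start) r else h
      gap <- dn$start - up$end - 1L
      overlapping <- gap < 0L
      if (overlapping) {
        message("overlapping HK/RR genes ", h$gene_id, "/", r$gene_id,
                "; gap treated as 0")
        gap <- 0L
      }
      if (gap < max_gap) {
        out[[length(out) + 1L]] <- data.frame(
          hk_id = h$gene_id, rr_id = r$gene_id, contig = h$contig,
          strand = h$strand, start = min(h$start, r$start),
          end = max(h$end, r$end), gap = gap, overlapping = overlapping,
          first_gene = up$gene_id, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(hk_id = character(), rr_id = character(),
                      contig = character(), strand = character(),
                      start = integer(), end = integer(), gap = integer(),
                      overlapping = logical(), first_gene = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start, res$hk_id), , drop = FALSE]
}

#' Classify an HK-RR pair as a grouped TCS
#'
#' A pair is "grouped" when the nearest annotated gene upstream of its
#' transcriptional 5' end lies head-to-head on the opposite strand, so both
#' units transcribe away from the shared intergenic region. The search is
#' capped at `max_search` bp and the intergenic span must not overlap any
#' gene body.
#'
#' @param pair One row from [identify_hk_rr_pairs()].
#' @param genes Full annotation table (as for [identify_hk_rr_pairs()]).
#' @param max_search Maximum distance (bp) to the divergent gene; default
#'   5000.
#' @return A one-row data frame describing the grouped TCS (pair columns plus
#'   `divergent_id`, `intergenic_start`, `intergenic_end`, `region_start`,
#'   `region_end`), or `NULL` when the pair is not grouped.
#' @export
classify_grouped_tcs <- function(pair, genes, max_search = 5000L) {
  genes <- validate_genes(genes)
  own <- c(pair$hk_id, pair$rr_id)
  others <- genes[genes$contig == pair$contig & !(genes$gene_id %in% own), ,
                  drop = FALSE]
  if (pair$strand == "+") {
    cand <- others[others$end < pair$start, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    g <- cand[which.max(cand$end), ]
    if (pair$start - g$end - 1L > max_search) return(NULL)
    if (g$strand != "-") return(NULL)  # tandem, not divergent
    ig_start <- g$end + 1L
    ig_end <- pair$start - 1L
  } else {
    cand <- others[others$start > pair$end, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    g <- cand[which.min(cand$start), ]
    if (g$start - pair$end - 1L > max_search) return(NULL)
    if (g$strand != "+") return(NULL)
    ig_start <- pair$end + 1L
    ig_end <- g$start - 1L
  }
  if (ig_end < ig_start) return(NULL)  # no intergenic promoter region
  overlaps <- others$start <= ig_end & others$end >= ig_start
  if (any(overlaps)) return(NULL)
  region_start <- if (pair$strand == "+") ig_start else pair$start
  region_end <- if (pair$strand == "+") pair$end else ig_end
  cbind(pair,
        data.frame(divergent_id = g$gene_id, intergenic_start = ig_start,
                   intergenic_end = ig_end, region_start = region_start,
                   region_end = region_end, stringsAsFactors = FALSE))
}

#' Extract the sensor region of a grouped TCS
#'
#' Returns the contiguous genomic sequence from the boundary nearest the
#' divergent gene's start codon (the codon itself excluded) through the far
#' end of the HK-RR pair, reverse-complemented when the pair is on the minus
#' strand so that the pair always reads 5' to 3'.
#'
#' @param grouped A row from [classify_grouped_tcs()].
#' @param genome Named `DNAStringSet` (or named character vector) of contigs.
#' @return A single DNA string.
#' @export
extract_sensor_region <- function(grouped, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!grouped$contig %in% names(genome)) {
    stop("contig not found in genome: ", grouped$contig)
  }
  contig <- genome[[grouped$contig]]
  if (grouped$region_start < 1L || grouped$region_end > length(contig)) {
    stop("region coordinates out of bounds on contig ", grouped$contig)
  }
  s <- Biostrings::subseq(contig, grouped$region_start, grouped$region_end)
  if (grouped$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Scan a sensor region for Type IIS recognition sites
#'
#' Golden Gate assembly uses Type IIS enzymes that cut outside their
#' recognition sites; an internal recognition site anywhere in the cloned
#' region (on either strand) makes the part incompatible. SapI recognises
#' GCTCTTC, BsaI recognises GGTCTC. `N` bases never match.
#'
#' @param region DNA string over `A`, `C`, `G`, `T`, `N`.
#' @param enzymes Named character vector of recognition sequences.
#' @return An object of class `enzyme_compatibility`: a list with
#'   `sites` (data frame `enzyme`, `position`, `strand`),
#'   `sapi_compatible` and `bsai_compatible`.
#' @export
scan_typeIIS_sites <- function(region,
                               enzymes = c(SapI = "GCTCTTC", BsaI = "GGTCTC")) {
  subj <- Biostrings::DNAString(region)
  rows <- list()
  for (enz in names(enzymes)) {
    for (strand in c("+", "-")) {
      pat <- enzymes[[enz]]
      if (strand == "-") pat <- revcomp(pat)
      m <- Biostrings::matchPattern(pat, subj, fixed = TRUE)
      if (length(m)) {
        rows[[length(rows) + 1L]] <- data.frame(
          enzyme = enz, position = BiocGenerics::start(m), strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(enzyme = character(), position = integer(),
               strand = character(), stringsAsFactors = FALSE)
  structure(list(
    sites = sites,
    sapi_compatible = !any(sites$enzyme == "SapI"),
    bsai_compatible = !any(sites$enzyme == "BsaI")
  ), class = "enzyme_compatibility")
}

#' @export
print.enzyme_compatibility <- function(x, ...) {
  cat("Type IIS compatibility: SapI",
      if (x$sapi_compatible) "compatible" else "INCOMPATIBLE",
      "| BsaI", if (x$bsai_compatible) "compatible" else "INCOMPATIBLE", "\n")
  if (nrow(x$sites)) print(x$sites)
  invisible(x)
}

#' Mine grouped TCSs from genome files
#'
#' End-to-end driver: reads a genome FASTA, a GFF3 annotation (gene features,
#' 1-based inclusive) and an HK/RR classification table, finds grouped TCSs
#' and reports coordinates, gaps and Type IIS compatibility. Optionally
#' writes a TSV summary and a multi-FASTA of sensor regions.
#'
#' @param fasta Path to genome FASTA (or a named `DNAStringSet`).
#' @param gff Path to GFF3 annotation (or a prepared gene data frame).
#' @param roles Path to a TSV with columns `gene_id`, `role`
#'   (`HK`/`RR`/`other`), or an equivalent data frame.
#' @param max_gap,max_search See [identify_hk_rr_pairs()] and
#'   [classify_grouped_tcs()].
#' @param out_prefix If non-`NULL`, writes `<prefix>.grouped_tcs.tsv` and
#'   `<prefix>.sensor_regions.fasta`.
#' @return Invisibly, a list with `table` (grouped TCS data frame including
#'   `sapi_compatible`/`bsai_compatible`) and `regions` (named character
#'   vector of sensor sequences).
#' @export
mine_grouped_tcs <- function(fasta, gff, roles, max_gap = 200L,
                             max_search = 5000L, out_prefix = NULL) {
  genome <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    Biostrings::readDNAStringSet(fasta) else Biostrings::DNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- if (is.data.frame(gff)) gff else read_gene_annotation(gff)
  role_tab <- if (is.data.frame(roles)) roles else
    read.delim(roles, stringsAsFactors = FALSE)
  genes$role <- role_tab$role[match(genes$gene_id, role_tab$gene_id)]
  genes$role[is.na(genes$role)] <- "other"
  pairs <- identify_hk_rr_pairs(genes, max_gap = max_gap)
  grouped <- list()
  for (i in seq_len(nrow(pairs))) {
    g <- classify_grouped_tcs(pairs[i, ], genes, max_search = max_search)
    if (!is.null(g)) grouped[[length(grouped) + 1L]] <- g
  }
  if (!length(grouped)) {
    return(invisible(list(table = data.frame(), regions = character())))
  }
  tab <- do.call(rbind, grouped)
  tcs_id <- paste0("TCS", sprintf("%03d", seq_len(nrow(tab))))
  regions <- vapply(seq_len(nrow(tab)), function(i) {
    extract_sensor_region(tab[i, ], genome)
  }, character(1))
  names(regions) <- tcs_id
  compat <- lapply(regions, scan_typeIIS_sites)
  tab <- cbind(tcs_id = tcs_id, tab,
               sapi_compatible = vapply(compat, `[[`, logical(1), "sapi_compatible"),
               bsai_compatible = vapply(compat, `[[`, logical(1), "bsai_compatible"))
  rownames(tab) <- NULL
  if (!is.null(out_prefix)) {
    write.table(tab, paste0(out_prefix, ".grouped_tcs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(regions),
                                paste0(out_prefix, ".sensor_regions.fasta"))
  }
  invisible(list(table = tab, regions = regions))
}

# Read gene features from a GFF3 file into the gene-table layout.
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df <- df[df$type == "gene", , drop = FALSE]
  id <- if ("ID" %in% names(df)) df$ID else df$gene_id
  data.frame(gene_id = as.character(id), contig = as.character(df$seqnames),
             start = df$start, end = df$end, strand = as.character(df$strand),
             role = "other", stringsAsFactors = FALSE)
}
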