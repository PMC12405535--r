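mk_genes <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], contig = r[[2]], start = r[[3]], end = r[[4]],
               strand = r[[5]], role = r[[6]], stringsAsFactors = FALSE)
  }))
}

test_that("HK-RR pairing follows the gap and strand rules", {
  g <- mk_genes(list("h", "c1", 100L, 1300L, "+", "HK"),
                list("r", "c1", 1400L, 2100L, "+", "RR"))
  p <- identify_hk_rr_pairs(g)
  expect_equal(nrow(p), 1L)
  expect_equal(p$gap, 99L)

  g$start[2] <- 1551L  # gap 250 exceeds the threshold
  expect_equal(nrow(identify_hk_rr_pairs(g)), 0L)

  g$start[2] <- 1400L; g$strand[2] <- "-"  # opposite strands never pair
  expect_equal(nrow(identify_hk_rr_pairs(g)), 0L)
})

test_that("gap boundary is strict and overlaps are flagged as gap 0", {
  g <- mk_genes(list("h", "c1", 100L, 1300L, "+", "HK"),
                list("r", "c1", 1501L, 2100L, "+", "RR"))  # gap exactly 200
  expect_equal(nrow(identify_hk_rr_pairs(g)), 0L)
  g$start[2] <- 1500L  # gap 199
  expect_equal(nrow(identify_hk_rr_pairs(g)), 1L)
  g$start[2] <- 1200L  # overlapping genes
  expect_message(p <- identify_hk_rr_pairs(g), "overlap")
  expect_equal(p$gap, 0L)
  expect_true(p$overlapping)
})

test_that("malformed coordinates are rejected with a message", {
  g <- mk_genes(list("h", "c1", 1300L, 100L, "+", "HK"),
                list("r", "c1", 1400L, 2100L, "+", "RR"))
  expect_error(identify_hk_rr_pairs(g), "malformed")
})

test_that("grouped classification applies the divergence rule", {
  base <- mk_genes(list("d", "c1", 200L, 800L, "-", "other"),
                   list("h", "c1", 1000L, 1900L, "+", "HK"),
                   list("r", "c1", 2000L, 3000L, "+", "RR"))
  pair <- identify_hk_rr_pairs(base)
  g <- classify_grouped_tcs(pair, base)
  expect_equal(g$divergent_id, "d")
  expect_equal(c(g$intergenic_start, g$intergenic_end), c(801L, 999L))

  tandem <- base; tandem$strand[1] <- "+"  # upstream gene in tandem
  expect_null(classify_grouped_tcs(identify_hk_rr_pairs(tandem), tandem))

  lonely <- base[-1, ]  # no annotated gene upstream
  expect_null(classify_grouped_tcs(identify_hk_rr_pairs(lonely), lonely))
})

test_that("sensor region extraction spans intergenic through pair, 5'->3'", {
  genes <- mk_genes(list("d", "c1", 200L, 800L, "-", "other"),
                    list("h", "c1", 1000L, 1900L, "+", "HK"),
                    list("r", "c1", 2000L, 3000L, "+", "RR"))
  set.seed(8)
  contig <- random_seq(4000)
  genome <- Biostrings::DNAStringSet(setNames(contig, "c1"))
  g <- classify_grouped_tcs(identify_hk_rr_pairs(genes), genes)
  region <- extract_sensor_region(g, genome)
  expect_equal(nchar(region), 2200L)  # span [801, 3000]
  expect_equal(region, substr(contig, 801, 3000))
  # length = intergenic + pair span
  expect_equal(nchar(region),
               (g$intergenic_end - g$intergenic_start + 1L) +
                 (g$end - g$start + 1L))

  # minus-strand pair: reverse complement of the plus-strand span
  genes2 <- mk_genes(list("r", "c1", 200L, 800L, "-", "RR"),
                     list("h", "c1", 900L, 1900L, "-", "HK"),
                     list("d", "c1", 2100L, 2800L, "+", "other"))
  g2 <- classify_grouped_tcs(identify_hk_rr_pairs(genes2), genes2)
  region2 <- extract_sensor_region(g2, genome)
  expect_equal(region2,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(contig, 200, 2099)))))

  g_bad <- g; g_bad$region_end <- 5000L
  expect_error(extract_sensor_region(g_bad, genome), "c1")
})

test_that("Type IIS scanning reports sites on both strands", {
  left <- "ATATATATAT"; right <- "CGCGCGCGCG"
  r1 <- scan_typeIIS_sites(paste0(left, "GCTCTTC", right))
  expect_false(r1$sapi_compatible)
  expect_true(r1$bsai_compatible)
  expect_equal(r1$sites$position, 11L)
  # reverse-strand SapI site only
  r2 <- scan_typeIIS_sites(paste0(left, "GAAGAGC", right))
  expect_false(r2$sapi_compatible)
  expect_equal(r2$sites$strand, "-")
  # neither motif in either orientation
  r3 <- scan_typeIIS_sites(paste0(left, right))
  expect_true(r3$sapi_compatible && r3$bsai_compatible)
  # BsaI, and N never matches
  expect_false(scan_typeIIS_sites(paste0(left, "GGTCTC"))$bsai_compatible)
  expect_true(scan_typeIIS_sites(paste0(left, "GCTCTNC"))$sapi_compatible)
})

run_miner <- function(genes, max_gap = 200L, max_search = 5000L) {
  pairs <- identify_hk_rr_pairs(genes, max_gap)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    g <- classify_grouped_tcs(pairs[i, ], genes, max_search)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$hk_id, res$rr_id), , drop = FALSE]
}

test_that("miner recovers exactly the planted grouped TCSs", {
  set.seed(21)
  for (rep in 1:8) {
    pg <- planted_genome(n_grouped = sample(1:4, 1), n_decoys = sample(2:5, 1))
    res <- run_miner(pg$genes)
    expect_equal(nrow(res), nrow(pg$planted))
    expect_setequal(paste(res$hk_id, res$rr_id),
                    paste(pg$planted$hk_id, pg$planted$rr_id))
    # and the brute-force oracle agrees
    orc <- oracle_grouped_tcs(pg$genes)
    expect_equal(paste(res$hk_id, res$rr_id, res$divergent_id),
                 paste(orc$hk_id, orc$rr_id, orc$divergent_id))
    expect_equal(res$intergenic_start, orc$intergenic_start)
    expect_equal(res$intergenic_end, orc$intergenic_end)
  }
})

test_that("pair count is invariant to gene order", {
  set.seed(33)
  pg <- planted_genome(3, 4)
  shuffled <- pg$genes[sample(nrow(pg$genes)), , drop = FALSE]
  r1 <- run_miner(pg$genes)
  r2 <- run_miner(shuffled)
  expect_equal(paste(r1$hk_id, r1$rr_id), paste(r2$hk_id, r2$rr_id))
})

test_that("mining is invariant under genome reverse complement", {
  set.seed(44)
  pg <- planted_genome(3, 3)
  contig <- random_seq(pg$genome_len)
  genome <- Biostrings::DNAStringSet(setNames(contig, "chr"))
  L <- pg$genome_len
  flipped <- pg$genes
  flipped$start <- L - pg$genes$end + 1L
  flipped$end <- L - pg$genes$start + 1L
  flipped$strand <- ifelse(pg$genes$strand == "+", "-", "+")
  genome_rc <- Biostrings::DNAStringSet(setNames(
    as.character(Biostrings::reverseComplement(genome[[1]])), "chr"))
  r1 <- run_miner(pg$genes)
  r2 <- run_miner(flipped)
  expect_setequal(paste(r1$hk_id, r1$rr_id), paste(r2$hk_id, r2$rr_id))
  s1 <- sort(vapply(seq_len(nrow(r1)), function(i)
    extract_sensor_region(r1[i, ], genome), character(1)))
  s2 <- sort(vapply(seq_len(nrow(r2)), function(i)
    extract_sensor_region(r2[i, ], genome_rc), character(1)))
  expect_equal(s1, s2)
})

test_that("mine_grouped_tcs reads FASTA/GFF3/roles files end to end", {
  set.seed(55)
  pg <- planted_genome(2, 2)
  td <- withr::local_tempdir()
  contig <- random_seq(pg$genome_len)
  fa <- file.path(td, "g.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(contig, "chr")), fa)
  gff <- file.path(td, "g.gff3")
  writeLines(c("##gff-version 3", sprintf(
    "chr\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
    pg$genes$start, pg$genes$end, pg$genes$strand, pg$genes$gene_id)), gff)
  roles <- file.path(td, "roles.tsv")
  write.table(pg$genes[, c("gene_id", "role")], roles, sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- mine_grouped_tcs(fa, gff, roles, out_prefix = file.path(td, "out"))
  expect_equal(nrow(out$table), nrow(pg$planted))
  expect_true(file.exists(file.path(td, "out.grouped_tcs.tsv")))
  expect_true(file.exists(file.path(td, "out.sensor_regions.fasta")))
  written <- Biostrings::readDNAStringSet(file.path(td, "out.sensor_regions.fasta"))
  expect_equal(sort(unname(as.character(written))), sort(unname(out$regions)))
})
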