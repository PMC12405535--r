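# Independent oracles used by the unit and acceptance tests. These
# deliberately take naive routes (full enumeration, brute force) so they
# share no code with the implementation they check.

# Enumerate every global alignment of a and b; returns a matrix with one row
# per alignment: score (unit scoring), matches, cols. Exponential -- only for
# tiny strings.
oracle_alignments <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  rec <- function(i, j) {
    if (i > na && j > nb) return(list(c(0, 0, 0)))
    out <- list()
    if (i <= na && j <= nb) {
      m <- substr(a, i, i) == substr(b, j, j)
      for (r in rec(i + 1L, j + 1L)) {
        out[[length(out) + 1L]] <- r + c(if (m) 1 else -1, if (m) 1 else 0, 1)
      }
    }
    if (i <= na) {
      for (r in rec(i + 1L, j)) out[[length(out) + 1L]] <- r + c(-1, 0, 1)
    }
    if (j <= nb) {
      for (r in rec(i, j + 1L)) out[[length(out) + 1L]] <- r + c(-1, 0, 1)
    }
    out
  }
  do.call(rbind, rec(1L, 1L))
}

# Identities (matches/cols) achieved by the optimal-score global alignments.
oracle_identity_set <- function(a, b) {
  al <- oracle_alignments(a, b)
  opt <- al[al[, 1] == max(al[, 1]), , drop = FALSE]
  unique(opt[, 2] / opt[, 3])
}

# Brute-force grouped-TCS enumeration: tries every (HK, RR, divergent gene)
# triple directly against the definition.
oracle_grouped_tcs <- function(genes, max_gap = 200L, max_search = 5000L) {
  hk <- genes[genes$role == "HK", , drop = FALSE]
  rr <- genes[genes$role == "RR", , drop = FALSE]
  found <- list()
  for (i in seq_len(nrow(hk))) {
    for (j in seq_len(nrow(rr))) {
      h <- hk[i, ]; r <- rr[j, ]
      if (h$contig != r$contig || h$strand != r$strand) next
      up <- if (h$start <= r$start) h else r
      dn <- if (h$start <= r$start) r else h
      gap <- max(0L, dn$start - up$end - 1L)
      if (gap >= max_gap) next
      ps <- min(h$start, r$start); pe <- max(h$end, r$end)
      others <- genes[genes$contig == h$contig &
                        !(genes$gene_id %in% c(h$gene_id, r$gene_id)), ,
                      drop = FALSE]
      for (g in seq_len(nrow(others))) {
        d <- others[g, ]
        rest <- others[-g, , drop = FALSE]
        if (h$strand == "+") {
          if (d$end >= ps) next
          if (d$strand != "-") next
          if (ps - d$end - 1L > max_search) next
          ig <- c(d$end + 1L, ps - 1L)
        } else {
          if (d$start <= pe) next
          if (d$strand != "+") next
          if (d$start - pe - 1L > max_search) next
          ig <- c(pe + 1L, d$start - 1L)
        }
        if (ig[2] < ig[1]) next
        # d must be the nearest gene: nothing else may intrude on the span
        if (any(rest$start <= ig[2] & rest$end >= ig[1])) next
        # nor may any same-strand gene sit closer than d on the promoter side
        if (h$strand == "+") {
          if (any(rest$end < ps & rest$end > d$end)) next
        } else {
          if (any(rest$start > pe & rest$start < d$start)) next
        }
        found[[length(found) + 1L]] <- data.frame(
          hk_id = h$gene_id, rr_id = r$gene_id, divergent_id = d$gene_id,
          intergenic_start = ig[1], intergenic_end = ig[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(found)) {
    return(data.frame(hk_id = character(), rr_id = character(),
                      divergent_id = character(), intergenic_start = integer(),
                      intergenic_end = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, found)
  out[order(out$hk_id, out$rr_id), , drop = FALSE]
}

# Brute-force dual-argmax assignment rule.
oracle_assign <- function(counts, totals, min_reads = 5L) {
  counts <- counts[counts > 0]
  if (!length(counts)) return("no_alignment")
  best_count <- names(counts)[counts == max(counts)]
  frac <- counts / totals[names(counts)]
  best_frac <- names(counts)[frac == max(frac)]
  if (length(best_count) != 1L || length(best_frac) != 1L ||
      best_count != best_frac) return("ambiguous")
  if (counts[best_count] < min_reads) return("insufficient_reads")
  best_count
}

# Plant exactly d substitutions into a sequence (positions and replacement
# bases drawn from the current RNG, replacements guaranteed to differ).
plant_subs <- function(seq, d) {
  if (d == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), d)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random non-overlapping gene layout on one contig: genes laid left to right
# with random gaps, strands and roles. Used to compare miner vs oracle.
random_annotation <- function(n_genes = 12, contig = "c1") {
  pos <- 1L
  rows <- list()
  for (i in seq_len(n_genes)) {
    gap <- sample(c(sample(10:180, 1), sample(250:1500, 1),
                    sample(4000:7000, 1)), 1, prob = c(0.6, 0.25, 0.15))
    start <- pos + gap
    len <- sample(300:1500, 1)
    rows[[i]] <- data.frame(
      gene_id = sprintf("g%02d", i), contig = contig, start = start,
      end = start + len, strand = sample(c("+", "-"), 1),
      role = sample(c("HK", "RR", "other"), 1, prob = c(0.3, 0.3, 0.4)),
      stringsAsFactors = FALSE)
    pos <- start + len
  }
  do.call(rbind, rows)
}

# Planted genome: grouped TCS instances plus decoys, with >6 kb spacing so
# blocks cannot interact. Returns the annotation, the genome sequence and the
# planted (hk, rr) id pairs.
planted_genome <- function(n_grouped = 3, n_decoys = 4, contig = "chr") {
  pos <- 1000L
  rows <- list(); planted <- list()
  gid <- 0L
  add_gene <- function(start, end, strand, role) {
    gid <<- gid + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = sprintf("G%03d", gid), contig = contig, start = start,
      end = end, strand = strand, role = role, stringsAsFactors = FALSE)
    sprintf("G%03d", gid)
  }
  blocks <- sample(c(rep("grouped", n_grouped),
                     sample(c("tandem", "distant", "opposite", "lonely"),
                            n_decoys, replace = TRUE)))
  for (b in blocks) {
    flip <- sample(c(TRUE, FALSE), 1)   # mirror the block on the minus strand
    div_len <- sample(300:900, 1)
    ig <- sample(50:400, 1)
    hk_len <- sample(800:1400, 1)
    gap <- sample(5:150, 1)
    rr_len <- sample(500:900, 1)
    if (b == "grouped") {
      if (!flip) {
        d <- add_gene(pos, pos + div_len, "-", "other")
        h <- add_gene(pos + div_len + ig + 1L, pos + div_len + ig + hk_len, "+", "HK")
        r <- add_gene(pos + div_len + ig + hk_len + gap + 1L,
                      pos + div_len + ig + hk_len + gap + rr_len, "+", "RR")
      } else {
        r <- add_gene(pos, pos + rr_len, "-", "RR")
        h <- add_gene(pos + rr_len + gap + 1L, pos + rr_len + gap + hk_len, "-", "HK")
        d <- add_gene(pos + rr_len + gap + hk_len + ig + 1L,
                      pos + rr_len + gap + hk_len + ig + div_len, "+", "other")
      }
      planted[[length(planted) + 1L]] <- c(hk = h, rr = r)
      pos <- pos + div_len + ig + hk_len + gap + rr_len + 7000L
    } else if (b == "tandem") {
      add_gene(pos, pos + div_len, "+", "other")
      add_gene(pos + div_len + ig + 1L, pos + div_len + ig + hk_len, "+", "HK")
      add_gene(pos + div_len + ig + hk_len + gap + 1L,
               pos + div_len + ig + hk_len + gap + rr_len, "+", "RR")
      pos <- pos + div_len + ig + hk_len + gap + rr_len + 7000L
    } else if (b == "distant") {
      big_gap <- sample(220:800, 1)
      add_gene(pos, pos + div_len, "-", "other")
      add_gene(pos + div_len + ig + 1L, pos + div_len + ig + hk_len, "+", "HK")
      add_gene(pos + div_len + ig + hk_len + big_gap + 1L,
               pos + div_len + ig + hk_len + big_gap + rr_len, "+", "RR")
      pos <- pos + div_len + ig + hk_len + big_gap + rr_len + 7000L
    } else if (b == "opposite") {
      add_gene(pos, pos + div_len, "-", "other")
      add_gene(pos + div_len + ig + 1L, pos + div_len + ig + hk_len, "+", "HK")
      add_gene(pos + div_len + ig + hk_len + gap + 1L,
               pos + div_len + ig + hk_len + gap + rr_len, "-", "RR")
      pos <- pos + div_len + ig + hk_len + gap + rr_len + 7000L
    } else {  # lonely: HK-RR pair with no gene within the search window
      h <- add_gene(pos + 6000L, pos + 6000L + hk_len, "+", "HK")
      add_gene(pos + 6000L + hk_len + gap + 1L,
               pos + 6000L + hk_len + gap + rr_len, "+", "RR")
      pos <- pos + 6000L + hk_len + gap + rr_len + 7000L
    }
  }
  genes <- do.call(rbind, rows)
  genome_len <- pos + 2000L
  list(genes = genes, genome_len = genome_len,
       planted = do.call(rbind, lapply(planted, function(x)
         data.frame(hk_id = x[["hk"]], rr_id = x[["rr"]],
                    stringsAsFactors = FALSE))))
}
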