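test_that("k-mer index reports true positions, absences and palindromes", {
  g <- list(genome_record("chr", "ACGTACGTAAGGCCTTACGCGT"))
  expect_error(build_index(g, k = 20), "odd")
  ix <- build_index(g, k = 11)
  hit <- lookup_kmer(ix, substr(g[[1]]$sequence, 3, 13))[[1]]
  expect_equal(hit$pos, 2L)
  expect_true("+" %in% hit$strand)
  expect_equal(nrow(lookup_kmer(ix, strrep("T", 11))[[1]]), 0L)
  # reverse-complement queries report the same locus on the minus strand
  rev_hit <- lookup_kmer(ix, revcomp(substr(g[[1]]$sequence, 3, 13)))[[1]]
  expect_equal(rev_hit$pos, 2L)
  expect_equal(rev_hit$strand, "-")
  # note: with k restricted to odd values a k-mer can never equal its own
  # reverse complement, so the palindrome case cannot arise; lookup_kmer
  # still defines the "both" orientation for completeness
  expect_error(build_index(random_genome(10), k = 21), "shorter than k")
})

test_that("error-free reads map exactly; divergent reads stay unmapped", {
  set.seed(5)
  g <- random_genome(6000)
  p0 <- 1500L
  read <- substr(g[[1]]$sequence, p0 + 1L, p0 + 100L)
  reads <- data.frame(read_id = "r1", sequence = read, quality = strrep("I", 100),
                      mate = "single", stringsAsFactors = FALSE)
  mp <- map_reads(reads, g)
  expect_true(mp$mapped[1])
  expect_equal(mp$pos[1], p0)
  expect_equal(mp$identity[1], 1.0)
  expect_equal(mp$cigar[1], "100M")

  # 30 planted mismatches: best attainable identity 0.70 < 0.80 threshold
  v <- strsplit(read, "")[[1]]
  at <- round(seq(2, 99, length.out = 30))
  for (i in at) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  reads$sequence <- paste(v, collapse = "")
  mp2 <- map_reads(reads, g)
  expect_false(mp2$mapped[1])
})

test_that("a divergent mate is rescued within the insert window", {
  set.seed(6)
  g <- random_genome(20000)
  sim <- simulate_reads(g, coverage = 4, per_base_error = 0, seed = 2)
  reads <- sim$reads
  # corrupt one second mate to 25% divergence: unmappable alone, rescuable
  victim <- which(reads$mate == "second")[10]
  v <- strsplit(reads$sequence[victim], "")[[1]]
  at <- round(seq(2, 99, length.out = 25))
  for (i in at) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  reads$sequence[victim] <- paste(v, collapse = "")
  mp <- map_reads(reads, g)
  row <- mp[mp$read == victim & mp$primary, ]
  expect_true(row$mapped)
  expect_true(row$rescued)
  expect_true(row$proper)
  expect_lt(row$identity, 0.8) # below the reporting threshold: rescue path
  # rescue window arithmetic: placement within mean + 4 sd of the anchor
  anchor <- mp[mp$read == victim - 1L & mp$primary, ]
  tlen <- abs((row$pos + row$rlen) - anchor$pos)
  expect_lt(tlen, attr(mp, "insert_mean") + 4 * attr(mp, "insert_sd") + 1)
})

test_that("on error-free reads >=99% of primary placements hit the true origin", {
  set.seed(7)
  g <- random_genome(30000)
  sim <- simulate_reads(g, coverage = 10, per_base_error = 0, seed = 3)
  mp <- map_reads(sim$reads, g)
  prim <- mp[mp$primary, ]
  prim <- prim[order(prim$read), ]
  truth <- sim$truth[match(sim$reads$pair_id, sim$truth$pair_id), ]
  expected_pos <- ifelse(sim$reads$mate == "first", truth$frag_start,
                         truth$frag_start + truth$insert - 100L)
  ok <- prim$mapped & prim$pos == expected_pos & prim$identity == 1
  expect_gte(mean(ok), 0.99)
})

test_that("partitioning is exhaustive, inclusive at 1 bp, and repeat-aware", {
  rf <- repeat_fixture()
  mp <- map_reads(rf$sim$reads, rf$fix$genome)
  parts <- partition_reads(mp, rf$sim$reads, rf$clusters)
  expect_length(parts, 3L)
  # exhaustive: every in-region mapping's read appears in that partition
  for (i in seq_along(parts)) {
    cl <- rf$clusters[[i]]
    sel <- mp$mapped & mp$record_id == cl$record_id &
      mp$pos < cl$region_end & (mp$pos + mp$rlen) > cl$region_start
    expect_true(all(mp$read[sel] %in% parts[[i]]$read_idx))
  }
  # reads are unique within a partition and carry their mates
  for (p in parts) {
    expect_false(anyDuplicated(p$read_idx) > 0)
    pid <- rf$sim$reads$pair_id[p$read_idx]
    expect_true(all(table(pid) == 2L))
  }
  # repeat-internal reads belong to all three partitions
  common <- Reduce(intersect, lapply(parts, `[[`, "read_idx"))
  expect_gt(length(common), 100L)
  # flank-anchored reads are cluster-specific
  expect_gt(parts[[1]]$n_reads, length(common))
})

test_that("a read overlapping a region boundary by 1 bp joins the partition", {
  set.seed(8)
  g <- random_genome(12000)
  cl <- list(list(cluster_id = 1L, record_id = "g", span_start = 5000L,
                  span_end = 6000L, flank = 0L,
                  region_start = 5000L, region_end = 6000L))
  # read ends exactly 1 bp inside the region: positions 4901..5001 (0-based 4900)
  reads <- data.frame(
    read_id = c("in1", "out1"),
    sequence = c(substr(g[[1]]$sequence, 4902, 5001),
                 substr(g[[1]]$sequence, 4901, 5000)),
    quality = strrep("I", 100), mate = "single", stringsAsFactors = FALSE)
  mp <- map_reads(reads, g)
  parts <- partition_reads(mp, reads, cl)
  expect_true(1L %in% parts[[1]]$read_idx)   # overlaps by exactly 1 bp
  expect_false(2L %in% parts[[1]]$read_idx)  # ends exactly at the boundary
})

test_that("overlapping cluster regions give multi-membership", {
  set.seed(9)
  g <- random_genome(12000)
  cls <- list(list(cluster_id = 1L, record_id = "g", span_start = 4000L,
                   span_end = 5000L, flank = 1000L,
                   region_start = 3000L, region_end = 6000L),
              list(cluster_id = 2L, record_id = "g", span_start = 5500L,
                   span_end = 6500L, flank = 1000L,
                   region_start = 4500L, region_end = 7500L))
  reads <- data.frame(read_id = "r", sequence = substr(g[[1]]$sequence, 5001, 5100),
                      quality = strrep("I", 100), mate = "single",
                      stringsAsFactors = FALSE)
  mp <- map_reads(reads, g)
  parts <- partition_reads(mp, reads, cls)
  expect_true(1L %in% parts[[1]]$read_idx)
  expect_true(1L %in% parts[[2]]$read_idx)
})
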