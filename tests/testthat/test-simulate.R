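test_that("generators are seed-deterministic", {
  a <- synth_operon_genome(3, seed = 9)
  b <- synth_operon_genome(3, seed = 9)
  expect_identical(a, b)
  ra <- simulate_reads(a$genome, coverage = 2, seed = 4)
  rb <- simulate_reads(b$genome, coverage = 2, seed = 4)
  expect_identical(ra, rb)
  ma <- mutate_genome(a$genome, 0.01, seed = 3)
  mb <- mutate_genome(a$genome, 0.01, seed = 3)
  expect_identical(ma, mb)
  rc <- simulate_reads(a$genome, coverage = 2, seed = 5)
  expect_false(identical(ra$reads$sequence, rc$reads$sequence))
})

test_that("synthetic operon genomes satisfy their stated structure", {
  fix <- synth_operon_genome(3, seed = 13)
  g <- fix$genome[[1]]$sequence
  ops <- substring(g, fix$truth$op_start + 1L, fix$truth$op_end)
  expect_length(unique(ops), 1L) # identical copies
  expect_equal(nrow(fix$features), 9L) # 3 features per operon
  # pairwise flank identity < 60%
  flanks <- c(substring(g, fix$truth$region_start + 1L, fix$truth$op_start),
              substring(g, fix$truth$op_end + 1L, fix$truth$region_end))
  for (i in seq_along(flanks)) for (j in seq_along(flanks)) {
    if (i >= j) next
    a <- strsplit(flanks[i], "")[[1]]; b <- strsplit(flanks[j], "")[[1]]
    expect_lt(mean(a == b), 0.6)
  }
  # features sit inside their operons
  for (i in 1:3) {
    f <- fix$features[(3 * i - 2):(3 * i), ]
    expect_true(all(f$start >= fix$truth$op_start[i]))
    expect_true(all(f$end <= fix$truth$op_end[i]))
  }
  expect_error(synth_operon_genome(5, genome_length = 10000),
               "infeasible packing")
})

test_that("a single-operon genome assembles de novo without help", {
  fix <- synth_operon_genome(1, seed = 14)
  reads <- tile_reads(fix$genome[[1]]$sequence)
  asm <- debruijn_assemble(reads, k = 55, min_kmer_count = 1)
  expect_length(asm$contigs, 1L)
  s <- fix$genome[[1]]$sequence
  expect_true(asm$contigs[[1]] == s || asm$contigs[[1]] == revcomp(s))
})

test_that("mutate_genome follows its models", {
  fix <- synth_operon_genome(2, seed = 15)
  m0 <- mutate_genome(fix$genome, 0, seed = 1)
  expect_identical(m0$genome[[1]]$sequence, fix$genome[[1]]$sequence)
  expect_equal(nrow(m0$log), 0L)

  m <- mutate_genome(fix$genome, 0.01, seed = 2)
  expect_true(all(diff(m$log$position) > 0))
  v0 <- strsplit(fix$genome[[1]]$sequence, "")[[1]]
  v1 <- strsplit(m$genome[[1]]$sequence, "")[[1]]
  diffs <- which(v0 != v1) - 1L
  expect_equal(diffs, m$log$position)
  expect_true(all(m$log$ref_base != m$log$alt_base))

  spans <- data.frame(record_id = "synth_chr", start = fix$truth$op_start,
                      end = fix$truth$op_end)
  mf <- mutate_genome(fix$genome, 0.05, "flanking_only", rdna_spans = spans,
                      seed = 3)
  for (i in seq_len(nrow(spans)))
    expect_identical(
      substr(mf$genome[[1]]$sequence, spans$start[i] + 1L, spans$end[i]),
      substr(fix$genome[[1]]$sequence, spans$start[i] + 1L, spans$end[i]))
  expect_true(all(mf$log$position < spans$start[1] |
                    mf$log$position >= spans$end[1]))
  expect_gt(nrow(mf$log), 0L)
})

test_that("simulated reads obey the stated distributions", {
  set.seed(16)
  g <- random_genome(100000)
  sim <- simulate_reads(g, read_length = 100, coverage = 30,
                        per_base_error = 0, seed = 17)
  expect_equal(nrow(sim$truth), 15000L) # round(30 * 1e5 / 200)
  expect_equal(nrow(sim$reads), 30000L)
  # error 0: every read is an exact substring of the genome or its rc
  idx <- sample.int(nrow(sim$reads), 300)
  seqs <- sim$reads$sequence[idx]
  fwd <- vapply(seqs, grepl, logical(1), x = g[[1]]$sequence, fixed = TRUE)
  rev <- vapply(revcomp(seqs), grepl, logical(1), x = g[[1]]$sequence,
                fixed = TRUE)
  expect_true(all(fwd | rev))
  # mates reconstruct their fragment
  tr <- sim$truth[1:50, ]
  m1 <- sim$reads$sequence[sim$reads$mate == "first"][1:50]
  expect_equal(m1, substring(g[[1]]$sequence, tr$frag_start + 1L,
                             tr$frag_start + 100L))
  # CLT bound on the mean insert
  n <- nrow(sim$truth)
  expect_lt(abs(mean(sim$truth$insert) - 300), 3 * 10 / sqrt(n))
  expect_equal(sd(sim$truth$insert), 10, tolerance = 0.05)
  # mean per-base coverage within 5% of the configured fold
  expect_equal(nrow(sim$reads) * 100 / 1e5, 30, tolerance = 0.05)
})

test_that("read errors appear at the configured rate with matching quality", {
  set.seed(18)
  g <- random_genome(60000)
  sim <- simulate_reads(g, coverage = 10, per_base_error = 0.01, seed = 19)
  tr <- sim$truth
  m1 <- sim$reads$sequence[sim$reads$mate == "first"]
  truth_seq <- substring(g[[1]]$sequence, tr$frag_start + 1L,
                         tr$frag_start + 100L)
  mism <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                 m1[1:500], truth_seq[1:500])
  rate <- sum(mism) / (500 * 100)
  expect_equal(rate, 0.01, tolerance = 0.35)
  expect_equal(unique(sim$reads$quality), strrep(intToUtf8(20 + 33), 100))
})

test_that("artificial chromosomes concatenate regions with an invertible truth table", {
  fix <- synth_operon_genome(7, operon_length = 4500, flank_length = 5200,
                             seed = 20)
  cl <- select_operons(fix$features, fix$genome, flank = 1000)
  art <- build_artificial_chromosome(fix$genome, cl, flank = 5000)
  expect_equal(nrow(art$truth), 7L)
  # ~100 kb from 7 regions of span + 2x5 kb
  expect_equal(nchar(art$chromosome$sequence),
               sum(art$truth$end - art$truth$start))
  expect_gt(nchar(art$chromosome$sequence), 90000L)
  expect_lt(nchar(art$chromosome$sequence), 110000L)
  g <- fix$genome[[1]]$sequence
  for (i in seq_len(nrow(art$truth))) {
    tt <- art$truth[i, ]
    expect_identical(substr(art$chromosome$sequence, tt$chrom_start + 1L,
                            tt$chrom_end),
                     substr(g, tt$start + 1L, tt$end))
  }
  # single cluster: chromosome equals that region
  cl1 <- select_operons(fix$features[1:3, ], fix$genome, flank = 1000)
  art1 <- build_artificial_chromosome(fix$genome, cl1, flank = 5000)
  tt <- art1$truth[1, ]
  expect_identical(art1$chromosome$sequence, substr(g, tt$start + 1L, tt$end))
})
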