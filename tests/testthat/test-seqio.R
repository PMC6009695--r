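test_that("FASTA reading normalises case and alphabet, enforces contracts", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x some description", "acgt"), p)
  g <- read_fasta(p)
  expect_equal(g$x$sequence, "ACGT")
  expect_equal(g$x$description, "some description")

  writeLines(c(">x", "ACRT"), p)
  expect_message(g <- read_fasta(p), "1 non-ACGTN")
  expect_equal(g$x$sequence, "ACNT")
  expect_equal(g$x$n_normalised, 1L)

  writeLines(c(">x", "ACGT", ">x", "GGGG"), p)
  expect_error(read_fasta(p), "duplicate record id")
  writeLines(c(">x", "ACGT", ">", "GGGG"), p)
  expect_error(read_fasta(p), "line 3")
  writeLines(c(">x", "", ">y", "GGGG"), p)
  expect_error(read_fasta(p), "line 1.*empty sequence")
})

test_that("FASTA round trip is identity on id, sequence and description", {
  p <- withr::local_tempfile(fileext = ".fasta")
  set.seed(1)
  recs <- list(genome_record("a", random_dna(150), description = "first"),
               genome_record("b", random_dna(37)))
  write_fasta(recs, p, line_width = 70)
  lines <- readLines(p)
  expect_equal(sum(!startsWith(lines, ">")), 3 + 1) # 150 bp at 70 -> 3 lines
  back <- read_fasta(p)
  expect_equal(back$a$sequence, recs[[1]]$sequence)
  expect_equal(back$b$sequence, recs[[2]]$sequence)
  expect_equal(back$a$description, "first")
  expect_error(write_fasta(list(), p), "no records")
})

test_that("FASTQ round trip preserves ids, sequences and qualities exactly", {
  rf <- repeat_fixture()
  reads <- utils::head(rf$sim$reads, 20)
  p <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, p)
  back <- read_fastq(p)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$quality, reads$quality)
  expect_equal(back$mate, reads$mate)
  expect_equal(lengths(quality_scores(back$quality)), nchar(back$sequence))
})

test_that("GFF3 round trip obeys the coordinate conventions", {
  feats <- data.frame(record_id = "chr", start = 0L, end = 10L, strand = "+",
                      kind = "rRNA_16S", source_label = "16S ribosomal RNA",
                      stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, p)
  raw <- read.delim(p, header = FALSE, comment.char = "#")
  expect_equal(raw$V4[1], 1) # GFF3 is 1-based inclusive
  expect_equal(raw$V5[1], 10)
  back <- read_features(p, "gff3")
  expect_equal(back$start, 0L) # internal is 0-based half-open
  expect_equal(back$end, 10L)
  expect_equal(back$kind, "rRNA_16S")
})

test_that("rRNA product text classification follows the substring rule", {
  expect_equal(classify_rrna_kind("16S ribosomal RNA"), "rRNA_16S")
  expect_equal(classify_rrna_kind("23s rRNA"), "rRNA_23S")
  expect_equal(classify_rrna_kind("5S ribosomal RNA"), "rRNA_5S")
  expect_equal(classify_rrna_kind("ribosomal RNA"), "other")
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr", "test", "rRNA", "5", "50", ".", "+", ".",
                     "ID=r1;product=ribosomal RNA", sep = "\t")), p)
  expect_warning(f <- read_features(p, "gff3"), "could not be classified")
  expect_equal(f$kind, "other")
})

test_that("feature bounds are validated against the genome", {
  g <- random_genome(100)
  feats <- data.frame(record_id = "g", start = 50L, end = 120L, strand = "+",
                      kind = "rRNA_5S", source_label = "", stringsAsFactors = FALSE)
  expect_error(validate_features(feats, g), "beyond sequence bounds")
})

test_that("GenBank features are parsed with product and strand", {
  p <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       testrec    200 bp    DNA    linear",
    "FEATURES             Location/Qualifiers",
    "     source          1..200",
    "     rRNA            11..40",
    '                     /product="16S ribosomal RNA"',
    "     rRNA            complement(101..150)",
    '                     /product="5S ribosomal RNA"',
    "ORIGIN",
    "//"), p)
  f <- read_features(p, "genbank")
  expect_equal(nrow(f), 2L)
  expect_equal(f$start, c(10L, 100L))
  expect_equal(f$end, c(40L, 150L))
  expect_equal(f$strand, c("+", "-"))
  expect_equal(f$kind, c("rRNA_16S", "rRNA_5S"))
})

test_that("SAM round trip: stored identity is recomputable from the CIGAR", {
  set.seed(3)
  g <- random_genome(3000)
  starts <- seq(1, 2900, by = 53)
  reads <- data.frame(read_id = sprintf("r%03d", seq_along(starts)),
                      sequence = substring(g[[1]]$sequence, starts, starts + 99),
                      quality = strrep("I", 100), mate = "single",
                      stringsAsFactors = FALSE)
  # plant a couple of mismatches so identity is not trivially 1
  substr(reads$sequence[3], 10, 10) <- "N"
  mp <- map_reads(reads, g)
  p <- withr::local_tempfile(fileext = ".sam")
  write_sam(mp, reads, g, p)
  back <- read_sam(p, g, reads)
  m <- merge(mp[mp$primary & mp$mapped, c("read_id", "pos", "identity")],
             back[back$mapped, c("read_id", "pos", "identity")],
             by = "read_id")
  expect_equal(m$pos.x, m$pos.y)
  expect_equal(m$identity.x, m$identity.y, tolerance = 1e-9)
})

test_that("BED export is 0-based half-open on disk via the BED convention", {
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(data.frame(record_id = "chr", start = 5L, end = 25L,
                       name = "ivl"), p)
  raw <- read.delim(p, header = FALSE)
  expect_equal(raw$V2[1], 5)
  expect_equal(raw$V3[1], 25)
})
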