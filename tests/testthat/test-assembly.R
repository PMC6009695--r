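test_that("degenerate and small assemblies behave as specified", {
  read <- "ACGGTTCACGGAGGCTTACCATGCAGGCATTACGGATCCGGCTTAACGGATGCATTACGAA"
  asm <- debruijn_assemble(read, k = 31, min_kmer_count = 1)
  expect_length(asm$contigs, 1L)
  expect_true(asm$contigs[[1]] == read || asm$contigs[[1]] == revcomp(read))
  expect_warning(
    empty <- debruijn_assemble(read, k = 31, min_kmer_count = 5),
    "no k-mers")
  expect_length(empty$contigs, 0L)
  expect_error(debruijn_assemble(read, k = 30), "odd")
})

test_that("error-free tiled reads reconstruct a repeat-free sequence exactly", {
  set.seed(31)
  s <- random_dna(10000)
  asm <- debruijn_assemble(tile_reads(s), k = 31, min_kmer_count = 1)
  expect_length(asm$contigs, 1L)
  expect_true(asm$contigs[[1]] == s || asm$contigs[[1]] == revcomp(s))
})

test_that("reconstruction holds across 50 random 5-20 kb sequences", {
  set.seed(32)
  for (rep in 1:50) {
    L <- sample(5000:20000, 1)
    s <- random_dna(L)
    asm <- debruijn_assemble(tile_reads(s), k = 55, min_kmer_count = 1)
    expect_length(asm$contigs, 1L)
    expect_true(asm$contigs[[1]] == s || asm$contigs[[1]] == revcomp(s),
                label = sprintf("rep %d (L=%d) reconstructs", rep, L))
  }
})

test_that("an exact internal repeat longer than k breaks the assembly", {
  set.seed(33)
  rep500 <- random_dna(500)
  s <- paste0(random_dna(2000), rep500, random_dna(2000), rep500,
              random_dna(2000))
  asm <- debruijn_assemble(tile_reads(s), k = 55, min_kmer_count = 1)
  expect_gte(length(asm$contigs), 3L)
  expect_false(any(vapply(asm$contigs, function(ctg)
    grepl(rep500, ctg, fixed = TRUE) &&
      nchar(ctg) > 500 + 2 * 54 + 200, logical(1))))
})

test_that("emitted contigs are spelled paths over the read k-mer set", {
  rp <- repeat_pipeline()
  rf <- repeat_fixture()
  k <- 55
  km_sample <- function(ctg) {
    L <- nchar(ctg) - k + 1
    at <- unique(round(seq(1, L, length.out = min(50, L))))
    substring(ctg, at, at + k - 1)
  }
  haystack <- paste(c(rf$sim$reads$sequence, revcomp(rf$sim$reads$sequence)),
                    collapse = "|")
  for (ctg in rp$assemblies$de_novo$contigs) {
    kms <- km_sample(ctg$sequence)
    found <- vapply(kms, function(km)
      grepl(km, haystack, fixed = TRUE) ||
        grepl(revcomp(km), haystack, fixed = TRUE), logical(1))
    expect_true(all(found))
  }
})

test_that("pseudocontig QC follows the length rules", {
  set.seed(34)
  s5k <- random_dna(5000)
  part <- list(cluster_id = 1L, read_idx = seq_along(tile_reads(s5k)),
               n_reads = 0L, mapped_fraction = 1, mean_identity = 1)
  reads <- data.frame(sequence = tile_reads(s5k), stringsAsFactors = FALSE)
  part$n_reads <- nrow(reads)
  expect_warning(
    pc <- subassemble_cluster(part, reads, s5k, k = 55, expected_length = 7000),
    "too_short")
  expect_equal(pc$qc_status, "too_short") # 5000 < 6000
  expect_equal(pc$trust, "trusted")

  # same contig judged against a small expected length: too long (> 3x)
  expect_warning(
    pc2 <- subassemble_cluster(part, reads, s5k, k = 55,
                               expected_length = 1500, min_length = 1000),
    "too_long")
  expect_equal(pc2$qc_status, "too_long")

  # empty partition: zero-length pseudocontig, too_short
  empty <- list(cluster_id = 2L, read_idx = integer(0), n_reads = 0L,
                mapped_fraction = 0, mean_identity = NA_real_)
  expect_warning(pc3 <- subassemble_cluster(empty, reads, s5k, k = 55,
                                            expected_length = 7000))
  expect_equal(pc3$qc_status, "too_short")
  expect_equal(nchar(pc3$sequence), 0L)
  expect_equal(pc3$trust, "untrusted")
})

test_that("pseudogenome concatenation is exact and invertible", {
  pcs <- list(
    structure(list(cluster_id = 1, sequence = random_dna(7000),
                   qc_status = "accepted"), class = "pseudocontig"),
    structure(list(cluster_id = 2, sequence = random_dna(8000),
                   qc_status = "accepted"), class = "pseudocontig"))
  pg <- build_pseudogenome(pcs, spacer_length = 1000)
  expect_equal(nchar(pg$sequence$sequence), 16000L)
  expect_equal(pg$layout$start, c(0L, 8000L))
  for (i in 1:2)
    expect_equal(substr(pg$sequence$sequence, pg$layout$start[i] + 1L,
                        pg$layout$end[i]), pcs[[i]]$sequence)
  # exactly spacer_length Ns between pseudocontigs, none inside
  expect_equal(substr(pg$sequence$sequence, 7001, 8000), strrep("N", 1000))
  expect_false(grepl("N", pcs[[1]]$sequence))
  pg1 <- build_pseudogenome(pcs[1])
  expect_equal(pg1$sequence$sequence, pcs[[1]]$sequence)
  expect_error(build_pseudogenome(list()), "no accepted")
})

test_that("seed_iterate logs depth, converges in content, honours iterations=1", {
  rf <- repeat_fixture()
  rp <- repeat_pipeline()
  seeded <- rp$seeded
  # depth reported for every (cluster, iteration) pair
  expect_equal(nrow(seeded$depth), 3L * 3L)
  expect_true(all(seeded$depth$depth > 10))
  # content stability: every iteration's pseudocontig contains the reference
  # region of its cluster, and later iterations contain the earlier core
  for (cl in rf$clusters) {
    region <- substr(rf$fix$genome[[1]]$sequence, cl$region_start + 1L,
                     cl$region_end)
    for (it in 1:3) {
      pc <- seeded$history[[it]][[as.character(cl$cluster_id)]]
      expect_true(grepl(region, pc$sequence, fixed = TRUE) ||
                    grepl(region, revcomp(pc$sequence), fixed = TRUE),
                  label = sprintf("cluster %d iter %d contains its region",
                                  cl$cluster_id, it))
    }
  }
  single <- seed_iterate(rf$sim$reads, rf$fix$genome, rf$clusters,
                         iterations = 1)
  for (cid in names(single$pseudocontigs)) {
    expect_equal(single$pseudocontigs[[cid]]$sequence,
                 seeded$history[[1]][[cid]]$sequence)
  }
})

test_that("trusted threading records pairings and spans all repeat copies", {
  rf <- repeat_fixture()
  rp <- repeat_pipeline()
  dfn <- rp$assemblies$de_fere_novo
  pairings <- dfn$pairings
  expect_gt(nrow(pairings), 0L)
  expect_true(all(pairings$accepted[pairings$trusted]))
  # each pseudocontig's region is contained in some de fere novo contig
  for (cl in rf$clusters) {
    region <- substr(rf$fix$genome[[1]]$sequence, cl$region_start + 1L,
                     cl$region_end)
    hit <- vapply(dfn$contigs, function(ctg)
      grepl(region, ctg$sequence, fixed = TRUE) ||
        grepl(region, revcomp(ctg$sequence), fixed = TRUE), logical(1))
    expect_true(any(hit))
  }
  # the de novo control spans no repeat copy
  for (cl in rf$clusters) {
    region <- substr(rf$fix$genome[[1]]$sequence, cl$region_start + 1L,
                     cl$region_end)
    hit <- vapply(rp$assemblies$de_novo$contigs, function(ctg)
      grepl(region, ctg$sequence, fixed = TRUE) ||
        grepl(region, revcomp(ctg$sequence), fixed = TRUE), logical(1))
    expect_false(any(hit))
  }
})

test_that("a guide identical to an existing unitig is a no-op", {
  set.seed(35)
  s <- random_dna(6000)
  reads <- tile_reads(s)
  plain <- debruijn_assemble(reads, k = 55, min_kmer_count = 1)
  guided <- thread_trusted(reads, 55, plain$contigs[[1]], "trusted",
                           min_kmer_count = 1)
  expect_equal(sort(nchar(guided$contigs)), sort(nchar(plain$contigs)))
  expect_equal(unname(sort(unlist(guided$contigs))),
               unname(sort(unlist(plain$contigs))))
})

test_that("a chimeric untrusted guide cannot force a misjoin", {
  set.seed(36)
  X <- random_dna(400) # shared segment, longer than k
  A <- random_dna(1500); B <- random_dna(1500)
  C <- random_dna(1500); D <- random_dna(1500)
  reads <- c(tile_reads(paste0(A, X, B)), tile_reads(paste0(C, X, D)))
  plain <- debruijn_assemble(reads, k = 55, min_kmer_count = 1)
  chimera <- paste0(A, D) # joins A directly to D, contradicting all reads
  guided <- thread_trusted(reads, 55, chimera, "untrusted",
                           min_kmer_count = 1)
  fusion <- paste0(substring(A, nchar(A) - 60), substring(D, 1, 60))
  has <- function(ctg, piece) grepl(piece, ctg, fixed = TRUE) ||
    grepl(piece, revcomp(ctg), fixed = TRUE)
  expect_false(any(vapply(guided$contigs, has, logical(1), piece = fusion)))
  # no contig carries material from both sides of the claimed chimeric join
  expect_false(any(vapply(guided$contigs, function(ctg)
    has(ctg, substring(A, 700, 800)) && has(ctg, substring(D, 700, 800)),
    logical(1))))
  # and nothing is lost: every true segment survives somewhere
  for (piece in list(A, B, C, D, X))
    expect_true(any(vapply(guided$contigs, has, logical(1),
                           piece = substring(piece, 100, 300))))
})

test_that("final_assembly: degenerate equality, N50 gain, determinism", {
  rf <- repeat_fixture()
  rp <- repeat_pipeline()
  none <- final_assembly(rf$sim$reads, list())
  expect_equal(vapply(none$de_fere_novo$contigs, function(g) g$sequence,
                      character(1)),
               vapply(none$de_novo$contigs, function(g) g$sequence,
                      character(1)))
  expect_gt(assembly_n50(rp$assemblies$de_fere_novo),
            assembly_n50(rp$assemblies$de_novo))
  again <- final_assembly(rf$sim$reads, rp$seeded$pseudocontigs)
  expect_identical(
    vapply(again$de_fere_novo$contigs, function(g) g$sequence, character(1)),
    vapply(rp$assemblies$de_fere_novo$contigs, function(g) g$sequence,
           character(1)))
  # contigs sorted by descending length with stable ids
  lens <- vapply(rp$assemblies$de_fere_novo$contigs, function(g)
    nchar(g$sequence), integer(1))
  expect_true(all(diff(lens) <= 0))
  expect_equal(names(lens), paste0("contig_", seq_along(lens)))
})

test_that("swap replaces a bad contig with syntenic de novo contigs", {
  set.seed(37)
  a <- random_dna(4000); b <- random_dna(4000)
  dn <- list(genome_record("dn_1", a), genome_record("dn_2", b),
             genome_record("dn_3", random_dna(2000)))
  bad <- genome_record("contig_2", paste0(a, b)) # concatenation of dn_1+dn_2
  dfc <- list(genome_record("contig_1", random_dna(3000)), bad)
  out <- swap_contigs(dfc, dn, "contig_2")
  ids <- vapply(out, function(g) g$record_id, character(1))
  expect_false("contig_2" %in% ids)
  expect_true(all(c("dn_1", "dn_2") %in% ids))
  expect_false("dn_3" %in% ids)
  repl <- attr(out, "replacements")
  expect_equal(sort(repl$inserted), c("dn_1", "dn_2"))
  expect_true(all(c("target_start", "target_end", "identity") %in% names(repl)))
  expect_error(swap_contigs(dfc, dn, "nope"), "not found")
  expect_error(swap_contigs(dfc, list(genome_record("x", random_dna(500))),
                            "contig_2"), "no syntenic")
})

test_that("auto_k follows the read-length rule", {
  expect_equal(auto_k(100), 55L)
  expect_equal(auto_k(250), 127L)
  expect_true(auto_k(80) %% 2L == 1L)
})
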