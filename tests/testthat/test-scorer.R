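test_that("self-scoring a genome against its own clusters is 100% correct", {
  rf <- repeat_fixture()
  sc <- score_assembly(rf$fix$genome, rf$clusters, rf$fix$genome)
  expect_equal(unname(sc$summary), c(3L, 0L, 0L, 0L))
  m <- sc$matches
  per <- table(m$cluster_id, m$side)
  expect_true(all(per == 1L)) # each flank matches exactly once
  expect_true(all(m$identity == 1))
  expect_true(all(m$coverage == 1))
})

test_that("match_flanks keeps multiplicity and skips short flanks", {
  rf <- repeat_fixture()
  g <- rf$fix$genome[[1]]$sequence
  cl1 <- rf$clusters[[1]]
  up <- substr(g, cl1$region_start + 1L, cl1$span_start)
  # plant the upstream flank twice in an unrelated contig
  set.seed(41)
  asm <- list(genome_record("ctg", paste0(random_dna(500), up, random_dna(800),
                                          up, random_dna(500))))
  m <- match_flanks(rf$fix$genome, rf$clusters[1], asm)
  expect_equal(sum(m$side == "upstream"), 2L)
  expect_equal(sum(m$side == "downstream"), 0L) # absent flank: no match
  # flank shorter than 100 bp is skipped with a warning
  tiny <- rf$clusters[1]
  tiny[[1]]$region_start <- tiny[[1]]$span_start - 50L
  expect_warning(match_flanks(rf$fix$genome, tiny, asm), "shorter than 100")
})

test_that("midpoint-split assemblies are unassembled; empty assembly too", {
  rf <- repeat_fixture()
  g <- rf$fix$genome[[1]]$sequence
  halves <- list()
  for (cl in rf$clusters) {
    mid <- (cl$span_start + cl$span_end) %/% 2L
    halves[[length(halves) + 1L]] <-
      genome_record(paste0("L", cl$cluster_id),
                    substr(g, cl$region_start + 1L, mid))
    halves[[length(halves) + 1L]] <-
      genome_record(paste0("R", cl$cluster_id),
                    substr(g, mid + 1L, cl$region_end))
  }
  sc <- score_assembly(rf$fix$genome, rf$clusters, halves)
  expect_equal(unname(sc$summary), c(0L, 3L, 0L, 0L))

  sc_empty <- score_assembly(rf$fix$genome, rf$clusters, list())
  expect_equal(unname(sc_empty$summary), c(0L, 3L, 0L, 0L))
})

test_that("a cross-cluster fusion is called incorrect", {
  rf <- repeat_fixture()
  g <- rf$fix$genome[[1]]$sequence
  cl1 <- rf$clusters[[1]]; cl2 <- rf$clusters[[2]]
  rdna <- substr(g, cl1$span_start + 1L, cl1$span_end)
  up1 <- substr(g, cl1$region_start + 1L, cl1$span_start)
  down2 <- substr(g, cl2$span_end + 1L, cl2$region_end)
  fused <- list(genome_record("fused", paste0(up1, rdna, down2)))
  call1 <- classify_junction(cl1, match_flanks(rf$fix$genome, rf$clusters, fused))
  expect_equal(call1$category, "incorrect")
})

test_that("summary counts always sum to the number of clusters", {
  rf <- repeat_fixture()
  rp <- repeat_pipeline()
  for (sc in rp$scores) expect_equal(sum(sc$summary), length(rf$clusters))
})

test_that("the repeat fixture scores (3,0,0,0) de fere novo and (0,3,0,0) de novo", {
  rp <- repeat_pipeline()
  expect_equal(unname(rp$scores$de_fere_novo$summary), c(3L, 0L, 0L, 0L))
  expect_equal(unname(rp$scores$de_novo$summary), c(0L, 3L, 0L, 0L))
})

test_that("classify_junction is total over randomized evidence", {
  rf <- repeat_fixture()
  cl <- rf$clusters[[1]]
  set.seed(43)
  for (rep in 1:60) {
    n <- sample(0:6, 1)
    m <- data.frame(
      cluster_id = sample(c(1, 2), n, replace = TRUE),
      side = sample(c("upstream", "downstream"), n, replace = TRUE),
      contig_id = sample(c("c1", "c2"), n, replace = TRUE),
      contig_start = sample.int(20000, n),
      contig_end = integer(n), strand = sample(c("+", "-"), n, replace = TRUE),
      identity = runif(n, 0.95, 1), coverage = runif(n, 0.5, 1),
      stringsAsFactors = FALSE)
    m$contig_end <- m$contig_start + sample.int(1000, n)
    attr(m, "contig_lengths") <- c(c1 = 50000L, c2 = 50000L)
    out <- classify_junction(cl, m)
    expect_true(out$category %in%
                  c("correct", "unassembled", "incorrect", "ambiguous"))
  }
})

test_that("count_region_snps recovers planted substitutions exactly", {
  rf <- repeat_fixture()
  expect_equal(count_region_snps(rf$fix$genome, rf$fix$genome,
                                 rf$clusters)$total, 0L)

  # one known substitution inside cluster 1's region
  g <- rf$fix$genome[[1]]$sequence
  cl1 <- rf$clusters[[1]]
  at <- cl1$span_start + 500L # 0-based
  old <- substr(g, at + 1L, at + 1L)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  g2 <- g
  substr(g2, at + 1L, at + 1L) <- new
  b <- list(genome_record("alt", g2))
  res <- count_region_snps(rf$fix$genome, b, rf$clusters)
  expect_equal(res$total, 1L)
  expect_equal(res$snps$position, at)
  expect_equal(res$snps$base_a, old)
  expect_equal(res$snps$base_b, new)
  expect_equal(res$regions$n_snps[res$regions$cluster_id == 1], 1L)
})

test_that("multiple planted substitutions split correctly per region and are symmetric", {
  rf <- repeat_fixture()
  g <- rf$fix$genome[[1]]$sequence
  set.seed(44)
  plant <- data.frame(
    cluster = c(rep(1L, 4), rep(2L, 6)),
    pos = c(rf$clusters[[1]]$span_start + sort(sample(200:4000, 4)),
            rf$clusters[[2]]$span_start + sort(sample(200:4000, 6))))
  g2 <- g
  for (i in seq_len(nrow(plant))) {
    at <- plant$pos[i]
    old <- substr(g2, at + 1L, at + 1L)
    substr(g2, at + 1L, at + 1L) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  b <- list(synth_chr = genome_record("synth_chr", g2))
  res <- count_region_snps(rf$fix$genome, b, rf$clusters)
  expect_equal(res$total, 10L)
  expect_equal(res$regions$n_snps[order(res$regions$cluster_id)], c(4L, 6L, 0L))
  expect_equal(sort(res$snps$position), sort(plant$pos))
  # substitution-only symmetry: clusters recomputed on the mutated copy
  cl_b <- select_operons(rf$fix$features, b, flank = 1000)
  res_rev <- count_region_snps(b, rf$fix$genome, cl_b)
  expect_equal(res_rev$total, res$total)
})

test_that("unalignable regions are excluded with a warning", {
  rf <- repeat_fixture()
  set.seed(45)
  b <- list(genome_record("junk", random_dna(20000)))
  ws <- capture_warnings(res <- count_region_snps(rf$fix$genome, b, rf$clusters))
  expect_true(all(grepl("unalignable", ws)))
  expect_length(ws, 3L)
  expect_true(all(!res$regions$alignable))
  expect_equal(res$total, 0L)
})
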