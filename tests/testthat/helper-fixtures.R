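# Shared fixtures, memoised so expensive end-to-end objects are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The canonical repeat fixture: 3 identical 5 kb operons with unique 1.5 kb
# flanks in a 30 kb genome, 30x error-free 100 bp pairs, perfect reference.
repeat_fixture <- function() {
  memo("repeat_fixture", function() {
    fix <- synth_operon_genome(3, seed = 42)
    clusters <- select_operons(fix$features, fix$genome, flank = 1000)
    sim <- simulate_reads(fix$genome, coverage = 30, per_base_error = 0,
                          seed = 7)
    list(fix = fix, clusters = clusters, sim = sim)
  })
}

# Full pipeline products on the repeat fixture (seed iterations + final
# assemblies + junction scores).
repeat_pipeline <- function() {
  memo("repeat_pipeline", function() {
    rf <- repeat_fixture()
    seeded <- seed_iterate(rf$sim$reads, rf$fix$genome, rf$clusters,
                           iterations = 3)
    assemblies <- final_assembly(rf$sim$reads, seeded$pseudocontigs)
    scores <- list(
      de_fere_novo = score_assembly(rf$fix$genome, rf$clusters,
                                    assemblies$de_fere_novo),
      de_novo = score_assembly(rf$fix$genome, rf$clusters,
                               assemblies$de_novo))
    list(seeded = seeded, assemblies = assemblies, scores = scores)
  })
}

# deterministic error-free tiling reads covering a sequence end to end
tile_reads <- function(seq, read_length = 100, stride = 3) {
  L <- nchar(seq)
  starts <- unique(c(seq(1L, L - read_length + 1L, by = stride),
                     L - read_length + 1L))
  substring(seq, starts, starts + read_length - 1L)
}

# brute-force Jenks oracle: minimal within-class SS over all contiguous
# partitions of sorted values into n classes
jenks_oracle <- function(values, n_classes) {
  v <- sort(values)
  n <- length(v)
  ss <- function(x) sum((x - mean(x))^2)
  best <- Inf
  best_groups <- NULL
  splits <- utils::combn(n - 1L, n_classes - 1L)
  if (n_classes == 1L) splits <- matrix(integer(0), nrow = 0, ncol = 1)
  for (ci in seq_len(ncol(splits))) {
    b <- c(0L, splits[, ci], n)
    groups <- lapply(seq_len(n_classes), function(m) v[(b[m] + 1L):b[m + 1L]])
    total <- sum(vapply(groups, ss, numeric(1)))
    if (total < best - 1e-12) { best <- total; best_groups <- groups }
  }
  list(ss = best, groups = best_groups)
}

random_genome <- function(n, id = "g") {
  list(genome_record(id, random_dna(n)))
}
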