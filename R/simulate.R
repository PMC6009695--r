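# Generative machinery for validation: synthetic multi-operon genomes,
# artificial chromosomes, the two reference-mutation models, and a simple
# paired-end read simulator. All generators are seed-deterministic.

#' Random DNA string
#'
#' @param n Length in bases.
#' @return A single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Synthetic multi-operon test genome
#'
#' Builds the canonical repeat fixture: a random background chromosome in
#' which `n_operons` byte-identical copies of one rRNA operon are planted at
#' well-separated positions. Because the background is random, the flanking
#' sequence of every copy is unique within the genome (pairwise identity of
#' random DNA is ~25%), which is exactly the property the repeat-resolution
#' method relies on. Each operon carries 16S/23S/5S sub-features (sized in
#' proportion to a 1550/2900/120 bp operon at the default length).
#'
#' @param n_operons Number of identical operon copies.
#' @param operon_length Length of the operon in bp (>= 2000).
#' @param flank_length Length of the unique flank reserved on each side.
#' @param genome_length Total genome length; default leaves
#'   `1500 * (n_operons + 1)` bp of extra background between/around regions.
#' @param divergence_between_flanks If non-NULL, flanks are derived from a
#'   shared template mutated at this per-base rate instead of being
#'   independent random sequence (used to probe flank confusability).
#' @param seed Integer seed; same seed gives byte-identical output.
#' @return List with `genome` (list of one [genome_record()]), `features`
#'   (rRNA feature data.frame), and `truth` (operon coordinates).
#' @export
synth_operon_genome <- function(n_operons, operon_length = 5000,
                                flank_length = 1500, genome_length = NULL,
                                divergence_between_flanks = NULL, seed = 1) {
  stopifnot(n_operons >= 1, operon_length >= 2000, flank_length >= 0)
  unit <- operon_length + 2L * flank_length
  if (is.null(genome_length))
    genome_length <- n_operons * unit + 1500L * (n_operons + 1L)
  if (n_operons * unit > genome_length)
    stop("infeasible packing: ", n_operons, " x ", unit, " bp regions do not ",
         "fit in a ", genome_length, " bp genome")
  set.seed(seed)
  gap <- (genome_length - n_operons * unit) / (n_operons + 1L)
  bg <- strsplit(random_dna(genome_length), "")[[1]]
  operon <- random_dna(operon_length)

  if (!is.null(divergence_between_flanks)) {
    up_t <- random_dna(flank_length)
    dn_t <- random_dna(flank_length)
  }

  # operon sub-feature layout, proportional to the default architecture
  L <- operon_length
  o16 <- round(0.008 * L); l16 <- round(0.31 * L)
  g1 <- round(0.030 * L);  l23 <- round(0.58 * L)
  g2 <- round(0.016 * L);  l5 <- round(0.024 * L)

  feats <- list(); truth <- list()
  for (i in seq_len(n_operons)) {
    region_start <- round(i * gap + (i - 1L) * unit)
    op_start <- region_start + flank_length
    bg[(op_start + 1L):(op_start + operon_length)] <- strsplit(operon, "")[[1]]
    if (!is.null(divergence_between_flanks)) {
      up <- mutate_string(up_t, divergence_between_flanks)
      dn <- mutate_string(dn_t, divergence_between_flanks)
      if (flank_length > 0) {
        bg[(op_start - flank_length + 1L):op_start] <- strsplit(up, "")[[1]]
        bg[(op_start + operon_length + 1L):
             (op_start + operon_length + flank_length)] <- strsplit(dn, "")[[1]]
      }
    }
    s16 <- op_start + o16
    s23 <- s16 + l16 + g1
    s5 <- s23 + l23 + g2
    feats[[i]] <- data.frame(
      record_id = "synth_chr",
      start = c(s16, s23, s5), end = c(s16 + l16, s23 + l23, s5 + l5),
      strand = "+", kind = c("rRNA_16S", "rRNA_23S", "rRNA_5S"),
      source_label = c("16S ribosomal RNA", "23S ribosomal RNA",
                       "5S ribosomal RNA"),
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(operon = i, op_start = op_start,
                             op_end = op_start + operon_length,
                             region_start = op_start - flank_length,
                             region_end = op_start + operon_length + flank_length)
  }
  genome <- list(synth_chr = genome_record("synth_chr",
                                           paste(bg, collapse = ""),
                                           description = "synthetic operon fixture"))
  list(genome = genome, features = do.call(rbind, feats),
       truth = do.call(rbind, truth))
}

# substitute bases of a string at i.i.d. per-base rate (uses current RNG state)
mutate_string <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

#' Concatenate rDNA regions into an artificial test chromosome
#'
#' Extracts each cluster's span plus `flank` bp on either side (clamped at
#' sequence bounds) and concatenates the regions directly, recording a truth
#' table that maps every region back to its source coordinates. Overlapping
#' regions are merged with a warning. The chromosome is linear.
#'
#' @param genome Source genome (list of [genome_record()]).
#' @param clusters Operon clusters from [select_operons()].
#' @param flank Flank size in bp (default 5000).
#' @return List with `chromosome` (a [genome_record()]) and `truth`
#'   (data.frame mapping chromosome intervals to source intervals).
#' @export
build_artificial_chromosome <- function(genome, clusters, flank = 5000) {
  ids <- genome_ids(genome)
  regs <- lapply(clusters, function(cl) {
    len <- nchar(genome[[match(cl$record_id, ids)]]$sequence)
    data.frame(cluster_id = cl$cluster_id, record_id = cl$record_id,
               start = max(0L, cl$span_start - flank),
               end = min(len, cl$span_end + flank), stringsAsFactors = FALSE)
  })
  regs <- do.call(rbind, regs)
  regs <- regs[order(regs$record_id, regs$start), ]
  # merge overlaps
  merged <- regs[0, ]
  for (i in seq_len(nrow(regs))) {
    n <- nrow(merged)
    if (n > 0 && merged$record_id[n] == regs$record_id[i] &&
        regs$start[i] < merged$end[n]) {
      warning("overlapping extracted regions merged (clusters ",
              merged$cluster_id[n], " and ", regs$cluster_id[i], ")")
      merged$end[n] <- max(merged$end[n], regs$end[i])
    } else merged <- rbind(merged, regs[i, ])
  }
  pieces <- character(nrow(merged))
  truth <- merged
  truth$chrom_start <- NA_integer_
  truth$chrom_end <- NA_integer_
  at <- 0L
  for (i in seq_len(nrow(merged))) {
    seq <- substr(genome[[match(merged$record_id[i], ids)]]$sequence,
                  merged$start[i] + 1L, merged$end[i])
    pieces[i] <- seq
    truth$chrom_start[i] <- at
    truth$chrom_end[i] <- at + nchar(seq)
    at <- at + nchar(seq)
  }
  chrom <- genome_record("artificial_chromosome", paste(pieces, collapse = ""),
                         description = "concatenated rDNA regions")
  list(chromosome = chrom, truth = truth)
}

#' Mutate a genome under one of two substitution models
#'
#' Substitution positions advance by geometrically distributed gaps with
#' success probability `frequency` (equivalent to i.i.d. Bernoulli per base).
#' Under the `"flanking_only"` model positions that fall inside any rDNA span
#' are skipped, so rDNA bases are never altered. The substituted base is drawn
#' uniformly from the three alternatives.
#'
#' @param genome Genome (list of [genome_record()]).
#' @param frequency Substitutions per base, in `[0, 0.3]`.
#' @param model `"uniform"` or `"flanking_only"`.
#' @param rdna_spans data.frame with `record_id`, `start`, `end` (0-based
#'   half-open) of rDNA spans; required for the flanking-only model.
#' @param seed Integer seed.
#' @return List with `genome` (mutated copy) and `log` (data.frame of
#'   `record_id`, `position` (0-based), `ref_base`, `alt_base`), plus the
#'   model and frequency as attributes of the log.
#' @export
mutate_genome <- function(genome, frequency, model = c("uniform", "flanking_only"),
                          rdna_spans = NULL, seed = 1) {
  model <- match.arg(model)
  stopifnot(frequency >= 0, frequency <= 0.3)
  if (model == "flanking_only" && is.null(rdna_spans))
    stop("flanking_only model requires rdna_spans")
  set.seed(seed)
  out <- genome
  logs <- list()
  for (gi in seq_along(genome)) {
    rec <- genome[[gi]]
    L <- nchar(rec$sequence)
    if (frequency == 0) next
    # geometric inter-substitution gaps; over-draw then truncate
    n_draw <- ceiling(L * frequency + 10 * sqrt(L * frequency) + 10)
    pos <- cumsum(rgeom(n_draw, frequency) + 1L)
    while (length(pos) && pos[length(pos)] <= L) {
      extra <- cumsum(rgeom(n_draw, frequency) + 1L) + pos[length(pos)]
      pos <- c(pos, extra)
    }
    pos <- pos[pos <= L] # 1-based positions
    if (model == "flanking_only") {
      sp <- rdna_spans[rdna_spans$record_id == rec$record_id, , drop = FALSE]
      keep <- rep(TRUE, length(pos))
      for (i in seq_len(nrow(sp)))
        keep <- keep & !(pos > sp$start[i] & pos <= sp$end[i])
      pos <- pos[keep]
    }
    if (length(pos) == 0L) next
    v <- strsplit(rec$sequence, "")[[1]]
    ref <- v[pos]
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  character(1), USE.NAMES = FALSE)
    v[pos] <- alt
    out[[gi]]$sequence <- paste(v, collapse = "")
    logs[[length(logs) + 1L]] <- data.frame(
      record_id = rec$record_id, position = pos - 1L, ref_base = ref,
      alt_base = alt, stringsAsFactors = FALSE)
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(record_id = character(), position = integer(),
               ref_base = character(), alt_base = character(),
               stringsAsFactors = FALSE)
  rownames(log) <- NULL
  attr(log, "model") <- model
  attr(log, "frequency") <- frequency
  list(genome = out, log = log)
}

#' Simulate paired-end short reads
#'
#' Fragment starts are uniform, insert sizes are Normal(`insert_mean`,
#' `insert_sd`) rounded and clamped at `read_length`; mate 1 is the forward
#' strand at the fragment start and mate 2 the reverse complement at the
#' fragment end. Each base is substituted independently with probability
#' `per_base_error`; qualities are constant at the Phred score implied by the
#' error rate. Truth placements are recorded for mapper validation.
#'
#' @param genome Genome (list of [genome_record()]); reads are drawn from
#'   records in proportion to length.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Insert size distribution.
#' @param coverage Fold coverage.
#' @param per_base_error Per-base substitution error rate.
#' @param seed Integer seed.
#' @return List with `reads` (data.frame `read_id`, `sequence`, `quality`,
#'   `mate`, `pair_id`) and `truth` (fragment placements).
#' @export
simulate_reads <- function(genome, read_length = 100, insert_mean = 300,
                           insert_sd = 10, coverage = 30,
                           per_base_error = 0.001, seed = 1) {
  stopifnot(read_length < insert_mean, coverage > 0)
  set.seed(seed)
  all_reads <- list(); all_truth <- list()
  pair_off <- 0L
  for (rec in genome) {
    L <- nchar(rec$sequence)
    if (L <= insert_mean + 4 * insert_sd)
      stop("record ", rec$record_id, " too short for the insert distribution")
    n_pairs <- round(coverage * L / (2 * read_length))
    ins <- pmax(read_length, pmin(L, round(rnorm(n_pairs, insert_mean, insert_sd))))
    start <- floor(runif(n_pairs) * (L - ins + 1)) # 0-based fragment start
    m1 <- substring(rec$sequence, start + 1L, start + read_length)
    m2 <- revcomp(substring(rec$sequence, start + ins - read_length + 1L,
                            start + ins))
    if (per_base_error > 0) {
      m1 <- add_read_errors(m1, per_base_error)
      m2 <- add_read_errors(m2, per_base_error)
    }
    q <- if (per_base_error > 0)
      max(2L, min(40L, round(-10 * log10(per_base_error)))) else 40L
    qual <- strrep(intToUtf8(q + 33L), read_length)
    pid <- pair_off + seq_len(n_pairs)
    ids <- sprintf("sim_%06d", pid)
    all_reads[[length(all_reads) + 1L]] <- data.frame(
      read_id = rep(ids, each = 2L),
      sequence = as.vector(rbind(m1, m2)),
      quality = qual,
      mate = rep(c("first", "second"), n_pairs),
      pair_id = rep(pid, each = 2L),
      stringsAsFactors = FALSE)
    all_truth[[length(all_truth) + 1L]] <- data.frame(
      pair_id = pid, read_id = ids, record_id = rec$record_id,
      frag_start = start, insert = ins, stringsAsFactors = FALSE)
    pair_off <- pair_off + n_pairs
  }
  list(reads = do.call(rbind, all_reads), truth = do.call(rbind, all_truth))
}

# vectorised per-base substitution errors over a vector of equal-length reads
add_read_errors <- function(reads, rate) {
  n <- length(reads)
  rl <- nchar(reads[1])
  n_err <- stats::rbinom(n, rl, rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    v <- strsplit(reads[i], "")[[1]]
    at <- sample.int(rl, n_err[i])
    for (p in at) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
    reads[i] <- paste(v, collapse = "")
  }
  reads
}
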