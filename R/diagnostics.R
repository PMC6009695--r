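# The snag and stack diagnostics: per-column Shannon entropy with consensus
# depth over aligned rDNA regions, and rDNA-vs-background coverage comparison
# to flag references with collapsed (under-annotated) rDNA repeats.

#' Shannon entropy and consensus depth of one alignment column
#'
#' Entropy is computed in bits over the A/C/G/T distribution of the column;
#' gaps and Ns are excluded from both the distribution and the consensus
#' depth, so entropy is bounded by 2 bits. An all-gap column returns (0, 0).
#'
#' @param column Character vector of alignment column characters
#'   (`A,C,G,T,-,N`).
#' @return Numeric vector `c(entropy_bits, consensus_depth)`.
#' @export
column_entropy <- function(column) {
  counts <- table(factor(column, levels = c("A", "C", "G", "T")))
  depth <- sum(counts)
  if (depth == 0L) return(c(entropy_bits = 0, consensus_depth = 0))
  p <- counts[counts > 0] / depth
  c(entropy_bits = -sum(p * log2(p)), consensus_depth = depth)
}

# centered moving average; window shrinks symmetrically at the edges
moving_average <- function(x, window) {
  half <- (window - 1L) %/% 2L
  L <- length(x)
  vapply(seq_len(L), function(i) {
    h <- min(half, i - 1L, L - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

#' Entropy profile of aligned rDNA regions (snag)
#'
#' Computes per-column Shannon entropy and consensus depth over a multiple
#' alignment of extracted cluster sequences, smoothed with a centered moving
#' average (default window 351 bp; edges shrink symmetrically). Sequences of
#' unequal length are first aligned with the built-in center-star aligner
#' (suitable for <= 10 sequences of <= 20 kb); pre-aligned input (equal
#' lengths, with `-` gaps) is used as is.
#'
#' @param sequences List of [genome_record()]s or character vector of
#'   (aligned or unaligned) sequences.
#' @param window Odd smoothing window in bp.
#' @param out Optional TSV output path.
#' @return `entropy_profile` object: data.frame `position`, `entropy_bits`,
#'   `entropy_smoothed`, `consensus_depth` with the window and alignment as
#'   attributes.
#' @export
snag_entropy <- function(sequences, window = 351, out = NULL) {
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  seqs <- if (is.character(sequences)) sequences
          else vapply(sequences, function(g) g$sequence, character(1))
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(seqs))) > 1L) {
    if (length(seqs) > 10L || max(nchar(seqs)) > 20000L)
      stop("built-in center-star aligner is limited to <= 10 sequences of ",
           "<= 20 kb; supply a pre-aligned FASTA")
    seqs <- center_star_align(seqs)
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  prof <- apply(mat, 2L, column_entropy)
  df <- data.frame(position = seq_len(ncol(mat)) - 1L,
                   entropy_bits = prof[1, ],
                   entropy_smoothed = moving_average(prof[1, ], window),
                   consensus_depth = as.integer(prof[2, ]))
  if (!is.null(out))
    utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  structure(df, class = c("entropy_profile", "data.frame"),
            smoothing_window = window, alignment = seqs)
}

#' Center-star multiple alignment
#'
#' Aligns every sequence globally against the longest ("center") sequence
#' and merges the pairwise gap structures. Adequate for the near-identical
#' rDNA regions this diagnostic targets; not a general MSA.
#'
#' @param seqs Character vector of sequences.
#' @return Character vector of aligned rows (equal lengths, `-` gaps).
#' @export
center_star_align <- function(seqs) {
  ci <- which.max(nchar(seqs))
  center <- seqs[ci]
  n <- length(seqs)
  # pairwise alignments: per sequence, gap patterns relative to the center
  aln <- vector("list", n)
  ins_len <- integer(nchar(center) + 1L) # max insertion before center pos i
  for (i in seq_len(n)) {
    if (i == ci) next
    band <- abs(nchar(seqs[i]) - nchar(center)) + 200L
    a <- align_pair_cpp(seqs[i], center, "global", band = band)
    if (!a$ok) stop("center-star alignment failed for sequence ", i)
    aln[[i]] <- a
    # record insertions (query-only columns) by center position
    ops <- cigar_ops(a$cigar)
    rpos <- 0L
    for (j in seq_along(ops$op)) {
      if (ops$op[j] == "I") {
        ins_len[rpos + 1L] <- max(ins_len[rpos + 1L], ops$len[j])
      } else if (ops$op[j] %in% c("M", "D")) rpos <- rpos + ops$len[j]
    }
  }
  # build rows on the merged column layout
  build_row <- function(qseq, ops) {
    outp <- character(0)
    qi <- 1L; rpos <- 0L
    pending_ins <- 0L
    flush_ins <- function(used) {
      strrep("-", ins_len[rpos + 1L] - used)
    }
    j <- 1L
    while (j <= length(ops$op)) {
      op <- ops$op[j]; L <- ops$len[j]
      if (op == "I") {
        outp <- c(outp, substr(qseq, qi, qi + L - 1L))
        qi <- qi + L
        pending_ins <- L
      } else {
        # pad out any unused insertion room before this center position
        outp <- c(outp, strrep("-", ins_len[rpos + 1L] - pending_ins))
        pending_ins <- 0L
        for (s in seq_len(L)) {
          if (op == "M") {
            outp <- c(outp, substr(qseq, qi, qi))
            qi <- qi + 1L
          } else outp <- c(outp, "-")
          rpos <- rpos + 1L
          if (s < L) outp <- c(outp, strrep("-", ins_len[rpos + 1L]))
        }
      }
      j <- j + 1L
      if (j <= length(ops$op) && ops$op[j] != "I" && pending_ins == 0L) {
        # insertion room between ops handled at next non-I op
      }
    }
    outp <- c(outp, strrep("-", ins_len[rpos + 1L] - pending_ins))
    paste(outp, collapse = "")
  }
  out <- character(n)
  center_ops <- list(op = "M", len = nchar(center))
  out[ci] <- build_row(center, center_ops)
  for (i in seq_len(n)) {
    if (i == ci) next
    out[i] <- build_row(seqs[i], cigar_ops(aln[[i]]$cigar))
  }
  if (length(unique(nchar(out))) != 1L)
    stop("internal error: center-star rows have unequal lengths")
  out
}

#' Extract cluster region sequences from a genome
#'
#' @param genome Genome (list of [genome_record()]).
#' @param clusters `operon_clusters`.
#' @return Named character vector of region sequences.
#' @export
cluster_region_seqs <- function(genome, clusters) {
  ids <- genome_ids(genome)
  out <- vapply(clusters, function(cl)
    substr(genome[[match(cl$record_id, ids)]]$sequence,
           cl$region_start + 1L, cl$region_end), character(1))
  names(out) <- paste0("cluster_", vapply(clusters, function(cl)
    cl$cluster_id, numeric(1)))
  out
}

#' Compare rDNA coverage to the genomic background (stack)
#'
#' Computes the mean read depth over all cluster regions and over
#' `n_samples` randomly placed background intervals (each as long as the
#' mean cluster region, never overlapping an rDNA region). A ratio of about
#' 1 means the annotated rDNA count matches the sequenced isolate; a ratio
#' at or above `flag_ratio` suggests the reference has fewer rDNA copies
#' than the isolate (collapsed repeats).
#'
#' @param clusters `operon_clusters` on the reference.
#' @param genome Reference genome.
#' @param mappings Mapping data.frame from [map_reads()]; alternatively
#'   supply `depth` directly.
#' @param depth Optional named list of per-base depth vectors (as from
#'   [depth_from_mappings()]).
#' @param n_samples Number of background intervals.
#' @param flag_ratio Ratio at which the collapsed-repeat flag is raised.
#' @param seed Integer seed for background sampling.
#' @param out_bed Optional BED export of the sampled background intervals.
#' @return `coverage_comparison` object with fields `rdna_mean_depth`,
#'   `background_mean_depth`, `ratio`, `n_background_samples`, `flag`,
#'   `background_intervals`.
#' @export
stack_coverage <- function(clusters, genome, mappings = NULL, depth = NULL,
                           n_samples = 10, flag_ratio = 1.5, seed = 1,
                           out_bed = NULL) {
  if (is.null(depth)) {
    if (is.null(mappings)) stop("supply mappings or a depth table")
    depth <- depth_from_mappings(mappings, genome)
  }
  set.seed(seed)
  # depth over the rDNA spans themselves; flanks are excluded because a
  # collapsed reference still carries unique 1x flanks, which would dilute
  # the copy-number signal
  rdna_bases <- numeric(0)
  lens <- integer(0)
  for (cl in clusters) {
    d <- depth[[cl$record_id]]
    rdna_bases <- c(rdna_bases, d[(cl$span_start + 1L):cl$span_end])
    lens <- c(lens, cl$region_end - cl$region_start)
  }
  ivl_len <- as.integer(round(mean(lens)))
  # allowed background start positions: interval must avoid all rDNA regions
  intervals <- list()
  for (rid in names(depth)) {
    L <- length(depth[[rid]])
    ok <- rep(TRUE, max(0L, L - ivl_len + 1L))
    for (cl in clusters) {
      if (cl$record_id != rid) next
      lo <- max(1L, cl$region_start - ivl_len + 2L)
      hi <- min(length(ok), cl$region_end)
      if (lo <= hi) ok[lo:hi] <- FALSE
    }
    intervals[[rid]] <- which(ok)
  }
  avail <- sum(lengths(intervals))
  n_use <- n_samples
  if (avail == 0L) stop("genome too small to place background intervals")
  if (avail < n_samples) {
    n_use <- avail
    warning("only ", avail, " background start position(s) available; ",
            "reduced n_samples")
  }
  pool <- do.call(rbind, lapply(names(intervals), function(rid)
    if (length(intervals[[rid]]))
      data.frame(record_id = rid, start = intervals[[rid]] - 1L,
                 stringsAsFactors = FALSE)))
  picks <- pool[sample.int(nrow(pool), n_use), , drop = FALSE]
  picks$end <- picks$start + ivl_len
  bg_bases <- unlist(lapply(seq_len(nrow(picks)), function(i)
    depth[[picks$record_id[i]]][(picks$start[i] + 1L):picks$end[i]]))
  bg_mean <- mean(bg_bases)
  if (bg_mean == 0) stop("zero depth in background samples")
  rd_mean <- mean(rdna_bases)
  if (!is.null(out_bed)) {
    picks$name <- paste0("background_", seq_len(nrow(picks)))
    write_bed(picks, out_bed)
  }
  structure(list(rdna_mean_depth = rd_mean, background_mean_depth = bg_mean,
                 ratio = rd_mean / bg_mean,
                 n_background_samples = n_use,
                 flag = rd_mean / bg_mean >= flag_ratio,
                 background_intervals = picks),
            class = "coverage_comparison")
}

#' @export
print.coverage_comparison <- function(x, ...) {
  cat(sprintf(paste0("<coverage_comparison> rDNA %.1fx vs background %.1fx ",
                     "(ratio %.2f, %d samples)%s\n"),
              x$rdna_mean_depth, x$background_mean_depth, x$ratio,
              x$n_background_samples,
              if (x$flag) " FLAG: reference may have collapsed rDNAs" else ""))
  invisible(x)
}
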