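# Built-in seed-and-extend read mapper used for read baiting, plus the
# per-cluster read partitioning. External aligners can be substituted via
# read_sam().

#' Build an exact-match k-mer index over a genome
#'
#' The index is positional and strand-aware: queries report forward and
#' reverse-complement placements (palindromic queries are reported once with
#' orientation `"both"`).
#'
#' @param genome Genome (list of [genome_record()]).
#' @param k Odd k-mer size in `[11, 31]`.
#' @return `kmer_index` object; query with [lookup_kmer()].
#' @export
build_index <- function(genome, k = 21) {
  if (k %% 2L == 0L || k < 11L || k > 31L)
    stop("k must be odd and within [11, 31]")
  if (any(genome_lengths(genome) < k))
    stop("genome record shorter than k")
  structure(list(genome = genome, k = as.integer(k)), class = "kmer_index")
}

#' Query a k-mer index
#'
#' @param index `kmer_index` from [build_index()].
#' @param queries Character vector of length-k queries.
#' @return List of data.frames (`record`, `pos`, `strand`), one per query.
#' @export
lookup_kmer <- function(index, queries) {
  seqs <- vapply(index$genome, function(g) g$sequence, character(1))
  res <- kmer_lookup_cpp(unname(seqs), index$k, queries)
  ids <- genome_ids(index$genome)
  lapply(res, function(df) {
    df$record_id <- ids[df$record]
    df
  })
}

#' Map reads to a genome
#'
#' Seed-and-extend: k-mer seeds vote for candidate diagonals, candidates are
#' extended by banded affine-gap alignment (match +1, mismatch -1, gap open
#' -3, gap extend -1, band 15) and the best placement is reported when its
#' identity (matches / aligned columns) reaches `min_identity`. Score ties
#' are all retained (needed for repeat-aware partitioning) with the leftmost
#' placement marked primary. When one mate of a pair is unmapped it is
#' rescued by alignment within the insert window (mean + 4 sd).
#'
#' @param reads Read data.frame (`read_id`, `sequence`, `mate`, optionally
#'   `pair_id`).
#' @param genome Genome (list of [genome_record()]) or a `kmer_index`.
#' @param min_identity Minimum identity to report a placement.
#' @param max_seed_hits Seeds occurring more often than this are skipped.
#' @param k Seed k-mer size.
#' @return Mapping data.frame, one row per placement (multi-placements share
#'   a `read` index; `primary` marks the reported one). Insert-size estimates
#'   are attached as attributes `insert_mean` / `insert_sd`.
#' @export
map_reads <- function(reads, genome, min_identity = 0.8, max_seed_hits = 50,
                      k = 21) {
  if (inherits(genome, "kmer_index")) {
    k <- genome$k
    genome <- genome$genome
  }
  pair_id <- if (!is.null(reads$pair_id)) as.integer(reads$pair_id)
  else ifelse(reads$mate == "single", NA_integer_,
              match(reads$read_id, unique(reads$read_id)))
  seqs <- vapply(genome, function(g) g$sequence, character(1))
  res <- map_reads_cpp(unname(seqs), reads$sequence, pair_id,
                       as.integer(factor(reads$mate)), k = k,
                       min_identity = min_identity,
                       max_seed_hits = max_seed_hits)
  mp <- res$placements
  ids <- genome_ids(genome)
  mp$record_id <- ifelse(is.na(mp$record), NA_character_, ids[mp$record])
  mp$read_id <- reads$read_id[mp$read]
  mp$mate <- reads$mate[mp$read]
  attr(mp, "insert_mean") <- res$insert_mean
  attr(mp, "insert_sd") <- res$insert_sd
  mp
}

#' Partition reads by operon cluster region
#'
#' A read (and its mate) joins the partition of every cluster whose region
#' its alignment interval overlaps by at least 1 bp, considering all tied
#' best placements; repeat-internal reads therefore join all clusters they
#' could belong to, while flank-anchored reads are cluster-specific.
#'
#' @param mappings Mapping data.frame from [map_reads()].
#' @param reads Read data.frame the mappings refer to.
#' @param clusters `operon_clusters` (or any list with `cluster_id`,
#'   `record_id`, `region_start`, `region_end`).
#' @param min_identity Identity threshold used for the partition's
#'   `mapped_fraction` statistic.
#' @return List of partitions: `cluster_id`, `read_idx` (row indices into
#'   `reads`), `n_reads`, `mapped_fraction`, `mean_identity`, `depth`.
#' @export
partition_reads <- function(mappings, reads, clusters, min_identity = 0.8) {
  mp <- mappings[mappings$mapped, , drop = FALSE]
  prim <- mappings[mappings$primary, , drop = FALSE]
  prim <- prim[order(prim$read), , drop = FALSE]
  # mate lookup: rows of `reads` grouped by pair
  pair_key <- if (!is.null(reads$pair_id)) reads$pair_id else reads$read_id
  pair_key <- ifelse(is.na(pair_key), paste0("solo_", seq_along(pair_key)),
                     as.character(pair_key))
  lapply(clusters, function(cl) {
    sel <- !is.na(mp$record_id) & mp$record_id == cl$record_id &
      mp$pos < cl$region_end & (mp$pos + mp$rlen) > cl$region_start
    ridx <- unique(mp$read[sel])
    # include mates
    ridx <- which(pair_key %in% pair_key[ridx])
    ridx <- sort(unique(ridx))
    n <- length(ridx)
    pm <- prim[ridx, , drop = FALSE]
    mapped_ok <- !is.na(pm$identity) & pm$mapped & pm$identity >= min_identity
    region_len <- cl$region_end - cl$region_start
    ov <- pmin(mp$pos[sel] + mp$rlen[sel], cl$region_end) -
      pmax(mp$pos[sel], cl$region_start)
    list(cluster_id = cl$cluster_id,
         read_idx = ridx,
         n_reads = n,
         mapped_fraction = if (n > 0) mean(mapped_ok) else 0,
         mean_identity = if (any(mapped_ok)) mean(pm$identity[mapped_ok],
                                                  na.rm = TRUE) else NA_real_,
         depth = if (region_len > 0) sum(ov) / region_len else 0)
  })
}

#' Per-base read depth along a genome
#'
#' @param mappings Mapping data.frame (primary placements are used).
#' @param genome Genome the mappings refer to.
#' @return Named list of integer depth vectors, one per record.
#' @export
depth_from_mappings <- function(mappings, genome) {
  mp <- mappings[mappings$primary & mappings$mapped, , drop = FALSE]
  out <- list()
  for (rec in genome) {
    L <- nchar(rec$sequence)
    delta <- integer(L + 1L)
    sel <- mp$record_id == rec$record_id
    if (any(sel)) {
      st <- pmax(0L, mp$pos[sel]) + 1L
      en <- pmin(L, mp$pos[sel] + mp$rlen[sel]) + 1L
      for (i in seq_along(st)) {
        delta[st[i]] <- delta[st[i]] + 1L
        delta[en[i]] <- delta[en[i]] - 1L
      }
    }
    out[[rec$record_id]] <- cumsum(delta[seq_len(L)])
  }
  out
}
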