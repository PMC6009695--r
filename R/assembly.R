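# The seed step's computational core: a single-k de Bruijn assembler,
# per-cluster iterative subassembly into pseudocontigs, pseudogenome
# construction, trusted-contig threading for the final de fere novo
# assembly, and the swap repair operation.

#' Default assembly k-mer size for a read length
#'
#' `min(127, floor(0.55 * read_length))`, rounded down to odd (55 for 100 bp
#' reads).
#'
#' @param read_length Read length in bp.
#' @return Odd integer k.
#' @export
auto_k <- function(read_length) {
  k <- min(127L, as.integer(floor(0.55 * read_length)))
  if (k %% 2L == 0L) k <- k - 1L
  max(k, 21L)
}

#' Single-k de Bruijn assembly
#'
#' Builds the de Bruijn graph of read k-mers (canonical counting, both
#' orientations materialised), drops k-mers below `min_kmer_count`, clips
#' tips shorter than `tip_length`, pops bubbles whose branches align at
#' `bubble_identity` or better (keeping the higher-coverage branch) and emits
#' maximal non-branching paths (unitigs). Optionally, guide contigs are
#' threaded through the graph: at each branching node on a guide's k-mer walk
#' the supported (in-edge, out-edge) pairing is recorded; trusted guides may
#' additionally patch gaps of up to 2 missing k-mers from their own sequence,
#' while untrusted guides only contribute pairings that spanning reads do not
#' contradict. Accepted pairings resolve repeats: each guide's walk is
#' extended through uniquely-paired junctions and re-emitted as a single
#' contig, and unitigs wholly covered by these guided contigs are dropped.
#'
#' @param reads Character vector of read sequences, or a read data.frame.
#' @param k Odd k-mer size smaller than the read length.
#' @param min_kmer_count Minimum k-mer multiplicity.
#' @param tip_length Maximum tip length in bp (default `2k`).
#' @param bubble_identity Minimum branch identity for bubble popping.
#' @param trusted,untrusted Character vectors of guide contig sequences.
#' @param untrusted_min_support Read-pair support an alternative junction
#'   needs before an unsupported untrusted pairing is rejected.
#' @return List with `contigs` (named character vector, descending length),
#'   `coverage`, `kind` (`"guided"`/`"unitig"`), `pairings` (junction pairing
#'   report), `stats` and `warnings`.
#' @export
debruijn_assemble <- function(reads, k, min_kmer_count = 2,
                              tip_length = 2 * k, bubble_identity = 0.9,
                              trusted = NULL, untrusted = NULL,
                              untrusted_min_support = 5) {
  if (is.data.frame(reads)) reads <- reads$sequence
  if (k %% 2L == 0L) stop("k must be odd")
  res <- assemble_cpp(reads, as.integer(k), as.integer(min_kmer_count),
                      as.integer(tip_length), bubble_identity,
                      trusted = as.character(trusted %||% character(0)),
                      untrusted = as.character(untrusted %||% character(0)),
                      untrusted_min_support = as.integer(untrusted_min_support))
  for (w in res$warnings) warning(w, call. = FALSE)
  if (length(res$contigs))
    names(res$contigs) <- paste0("contig_", seq_along(res$contigs))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subassemble one cluster's read partition into a pseudocontig
#'
#' The partition's reads are assembled with [debruijn_assemble()]; when the
#' partition's mean mapping identity reaches `trust_threshold` the reference
#' region is threaded through the graph as a trusted contig, otherwise the
#' reads are assembled alone. The longest contig becomes the pseudocontig,
#' which is then length-checked: shorter than `min_length` (a conservative
#' minimum for a 16S-23S-5S operon) is `too_short`, longer than
#' `max_factor` times the expected length is `too_long`; either excludes the
#' cluster from later iterations with a warning.
#'
#' @param partition One partition from [partition_reads()].
#' @param reads Read data.frame.
#' @param reference_region Reference sequence of the cluster region.
#' @param k Assembly k-mer size.
#' @param expected_length Expected pseudocontig length (cluster span +
#'   2 x flank).
#' @param trust_threshold Mean-identity threshold for trusting the reference
#'   region (and later the pseudocontig itself).
#' @param min_length Minimum accepted pseudocontig length.
#' @param max_factor Maximum accepted length as a multiple of
#'   `expected_length`.
#' @param iteration Iteration index recorded on the pseudocontig.
#' @return A `pseudocontig` object.
#' @export
subassemble_cluster <- function(partition, reads, reference_region, k,
                                expected_length,
                                trust_threshold = 0.8, min_length = 6000,
                                max_factor = 3, iteration = 1L) {
  trusted <- !is.na(partition$mean_identity) &&
    partition$mean_identity >= trust_threshold
  seqs <- reads$sequence[partition$read_idx]
  contig <- ""
  if (length(seqs) > 0L) {
    asm <- debruijn_assemble(seqs, k,
                             trusted = if (trusted) reference_region else NULL)
    if (length(asm$contigs)) contig <- unname(asm$contigs[1])
  }
  len <- nchar(contig)
  qc <- if (len < min_length) "too_short"
        else if (len > max_factor * expected_length) "too_long"
        else "accepted"
  if (qc != "accepted")
    warning(sprintf("cluster %d pseudocontig failed QC (%s: %d bp, expected ~%d)",
                    partition$cluster_id, qc, len, expected_length),
            call. = FALSE)
  structure(list(cluster_id = partition$cluster_id, iteration = iteration,
                 sequence = contig, expected_length = expected_length,
                 qc_status = qc,
                 trust = if (trusted) "trusted" else "untrusted",
                 mean_identity = partition$mean_identity,
                 n_reads = partition$n_reads),
            class = "pseudocontig")
}

#' @export
print.pseudocontig <- function(x, ...) {
  cat(sprintf("<pseudocontig> cluster %d iter %d: %d bp [%s, %s]\n",
              x$cluster_id, x$iteration, nchar(x$sequence), x$qc_status,
              x$trust))
  invisible(x)
}

#' Concatenate accepted pseudocontigs into a pseudogenome
#'
#' Pseudocontigs are joined in ascending cluster order, separated by runs of
#' exactly `spacer_length` Ns (long enough that no read pair spans a spacer).
#' The layout table inverts the concatenation exactly.
#'
#' @param pseudocontigs List of accepted `pseudocontig` objects.
#' @param spacer_length Spacer run length in bp.
#' @return `pseudogenome` object: `sequence` ([genome_record()]),
#'   `spacer_length`, `layout` (data.frame `cluster_id`, `start`, `end`).
#' @export
build_pseudogenome <- function(pseudocontigs, spacer_length = 1000) {
  pcs <- Filter(function(p) p$qc_status == "accepted", pseudocontigs)
  if (length(pcs) == 0L) stop("no accepted pseudocontigs")
  pcs <- pcs[order(vapply(pcs, function(p) p$cluster_id, numeric(1)))]
  seqs <- vapply(pcs, function(p) p$sequence, character(1))
  lens <- nchar(seqs)
  starts <- cumsum(c(0L, utils::head(lens, -1) + spacer_length))
  layout <- data.frame(cluster_id = vapply(pcs, function(p) p$cluster_id,
                                           numeric(1)),
                       start = starts, end = starts + lens)
  sequence <- paste(seqs, collapse = strrep("N", spacer_length))
  structure(list(sequence = genome_record("pseudogenome", sequence),
                 spacer_length = spacer_length, layout = layout),
            class = "pseudogenome")
}

#' Iterative per-cluster subassembly (the seed step)
#'
#' Iteration 1 maps reads against the reference genome and partitions them by
#' cluster region; each partition is subassembled into a pseudocontig.
#' Subsequent iterations map against the previous round's pseudogenome (one
#' region per pseudocontig, no additional flank growth) and reassemble.
#' Clusters whose pseudocontig fails QC are frozen at their last accepted
#' version and not reseeded. Mapping depth per cluster and iteration is
#' recorded.
#'
#' @param reads Read data.frame.
#' @param reference Reference genome (list of [genome_record()]).
#' @param clusters `operon_clusters` from [select_operons()].
#' @param iterations Number of map/subassemble iterations.
#' @param k Assembly k-mer size or `"auto"`.
#' @param min_identity Mapping identity threshold for baiting.
#' @param trust_threshold,min_length,max_factor Pseudocontig QC and trust
#'   parameters (see [subassemble_cluster()]).
#' @param spacer_length Pseudogenome spacer length.
#' @return List with `pseudocontigs` (final accepted/frozen per cluster),
#'   `pseudogenome`, `depth` (per cluster x iteration), `history`.
#' @export
seed_iterate <- function(reads, reference, clusters, iterations = 3,
                         k = "auto", min_identity = 0.8,
                         trust_threshold = 0.8, min_length = 6000,
                         max_factor = 3, spacer_length = 1000) {
  stopifnot(length(clusters) >= 1L, iterations >= 1L)
  if (identical(k, "auto")) k <- auto_k(nchar(reads$sequence[1]))
  expected <- stats::setNames(
    vapply(clusters, function(cl)
      (cl$span_end - cl$span_start) + 2L * cl$flank, numeric(1)),
    vapply(clusters, function(cl) cl$cluster_id, numeric(1)))
  current <- list()    # cluster_id -> last accepted pseudocontig
  active <- vapply(clusters, function(cl) cl$cluster_id, numeric(1))
  depth_log <- list()
  history <- list()
  ref_ids <- genome_ids(reference)

  for (it in seq_len(iterations)) {
    if (it == 1L) {
      target <- reference
      part_clusters <- clusters
      region_seq <- function(cl) {
        substr(reference[[match(cl$record_id, ref_ids)]]$sequence,
               cl$region_start + 1L, cl$region_end)
      }
    } else {
      pg <- build_pseudogenome(current, spacer_length)
      target <- list(pseudogenome = pg$sequence)
      part_clusters <- lapply(seq_len(nrow(pg$layout)), function(i) {
        list(cluster_id = pg$layout$cluster_id[i], record_id = "pseudogenome",
             region_start = pg$layout$start[i], region_end = pg$layout$end[i],
             span_start = pg$layout$start[i], span_end = pg$layout$end[i],
             flank = 0L)
      })
      region_seq <- function(cl) current[[as.character(cl$cluster_id)]]$sequence
    }
    part_clusters <- Filter(function(cl) cl$cluster_id %in% active,
                            part_clusters)
    if (length(part_clusters) == 0L) break
    mp <- map_reads(reads, target, min_identity = min_identity)
    parts <- partition_reads(mp, reads, part_clusters,
                             min_identity = min_identity)
    iter_pcs <- list()
    for (pi in seq_along(parts)) {
      part <- parts[[pi]]
      cl <- part_clusters[[pi]]
      cid <- as.character(part$cluster_id)
      depth_log[[length(depth_log) + 1L]] <- data.frame(
        cluster_id = part$cluster_id, iteration = it, depth = part$depth,
        n_reads = part$n_reads, mapped_fraction = part$mapped_fraction,
        mean_identity = part$mean_identity)
      pc <- subassemble_cluster(part, reads, region_seq(cl), k,
                                expected_length = expected[[cid]],
                                trust_threshold = trust_threshold,
                                min_length = min_length,
                                max_factor = max_factor, iteration = it)
      iter_pcs[[cid]] <- pc
      if (pc$qc_status == "accepted") {
        current[[cid]] <- pc
      } else {
        active <- setdiff(active, part$cluster_id) # freeze at last accepted
      }
    }
    history[[it]] <- iter_pcs
    if (length(current) == 0L)
      stop("all clusters failed pseudocontig QC at iteration ", it,
           "; check k-mer size, flank length and reference choice")
  }
  list(pseudocontigs = current[order(as.numeric(names(current)))],
       pseudogenome = build_pseudogenome(current, spacer_length),
       depth = do.call(rbind, depth_log),
       history = history, k = k)
}

#' Thread a guide contig through the read de Bruijn graph
#'
#' Convenience wrapper exposing the junction-pairing machinery of
#' [debruijn_assemble()] for a single guide contig: returns the recorded
#' (in-edge, out-edge) pairings at branching nodes along the contig's k-mer
#' walk, and the resulting contigs.
#'
#' @param reads Read sequences (vector or data.frame).
#' @param k Assembly k-mer size.
#' @param contig_sequence Guide contig sequence.
#' @param trust `"trusted"` or `"untrusted"`.
#' @param ... Passed to [debruijn_assemble()].
#' @return List with `pairings` and `contigs`.
#' @export
thread_trusted <- function(reads, k, contig_sequence,
                           trust = c("trusted", "untrusted"), ...) {
  trust <- match.arg(trust)
  asm <- debruijn_assemble(reads, k,
                           trusted = if (trust == "trusted") contig_sequence,
                           untrusted = if (trust == "untrusted") contig_sequence,
                           ...)
  list(pairings = asm$pairings, contigs = asm$contigs)
}

#' Final de fere novo assembly (plus de novo control)
#'
#' Assembles all reads de novo, and again with the pseudocontigs threaded
#' through the graph as trusted (or untrusted) contigs. Both assemblies use
#' identical parameters apart from the pseudocontig injection.
#'
#' @param reads Read data.frame or sequence vector.
#' @param pseudocontigs Pseudocontigs from [seed_iterate()] (accepted ones
#'   are used; trust status controls threading mode).
#' @param k Assembly k-mer size or `"auto"`.
#' @param min_kmer_count Minimum k-mer multiplicity.
#' @return List with `de_fere_novo` and `de_novo`, each an `assembly_result`
#'   (contigs as [genome_record()]s sorted by descending length, plus mode
#'   and provenance).
#' @export
final_assembly <- function(reads, pseudocontigs, k = "auto",
                           min_kmer_count = 2) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  if (identical(k, "auto")) k <- auto_k(nchar(seqs[1]))
  pcs <- Filter(function(p) p$qc_status == "accepted", pseudocontigs)
  trusted <- vapply(Filter(function(p) p$trust == "trusted", pcs),
                    function(p) p$sequence, character(1))
  untrusted <- vapply(Filter(function(p) p$trust == "untrusted", pcs),
                      function(p) p$sequence, character(1))
  dn <- debruijn_assemble(seqs, k, min_kmer_count = min_kmer_count)
  df <- if (length(trusted) + length(untrusted) > 0) {
    debruijn_assemble(seqs, k, min_kmer_count = min_kmer_count,
                      trusted = trusted, untrusted = untrusted)
  } else dn
  prov <- list(k = k, min_kmer_count = min_kmer_count,
               n_trusted = length(trusted), n_untrusted = length(untrusted))
  list(de_fere_novo = as_assembly_result(df, "de_fere_novo", prov),
       de_novo = as_assembly_result(dn, "de_novo", prov))
}

as_assembly_result <- function(asm, mode, provenance) {
  contigs <- lapply(seq_along(asm$contigs), function(i)
    genome_record(paste0("contig_", i), asm$contigs[[i]]))
  names(contigs) <- vapply(contigs, function(x) x$record_id, character(1))
  structure(list(contigs = contigs, mode = mode, provenance = provenance,
                 kind = asm$kind, pairings = asm$pairings, stats = asm$stats),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  lens <- vapply(x$contigs, function(g) nchar(g$sequence), integer(1))
  cat(sprintf("<assembly_result> %s: %d contig(s), %d bp total, longest %d\n",
              x$mode, length(lens), sum(lens), if (length(lens)) max(lens) else 0L))
  invisible(x)
}

#' Assembly N50
#'
#' @param assembly `assembly_result` or list of [genome_record()]s.
#' @return N50 in bp.
#' @export
assembly_n50 <- function(assembly) {
  contigs <- if (inherits(assembly, "assembly_result")) assembly$contigs
             else assembly
  lens <- sort(vapply(contigs, function(g) nchar(g$sequence), integer(1)),
               decreasing = TRUE)
  if (length(lens) == 0L) return(0L)
  lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
}

#' Replace a suspect de fere novo contig with syntenic de novo contigs
#'
#' The named contig is removed and every de novo contig with a local
#' alignment to it at `min_identity` identity over at least `min_coverage`
#' of the de novo contig's length is inserted in its place. The replacement
#' map is attached as attribute `"replacements"`.
#'
#' @param de_fere_contigs,de_novo_contigs Contig lists
#'   ([genome_record()]s) or `assembly_result`s.
#' @param bad_contig_id Id of the contig to replace.
#' @param min_identity,min_coverage Synteny thresholds.
#' @return Edited contig list.
#' @export
swap_contigs <- function(de_fere_contigs, de_novo_contigs, bad_contig_id,
                         min_identity = 0.95, min_coverage = 0.5) {
  if (inherits(de_fere_contigs, "assembly_result"))
    de_fere_contigs <- de_fere_contigs$contigs
  if (inherits(de_novo_contigs, "assembly_result"))
    de_novo_contigs <- de_novo_contigs$contigs
  ids <- vapply(de_fere_contigs, function(g) g$record_id, character(1))
  at <- match(bad_contig_id, ids)
  if (is.na(at)) stop("contig not found: ", bad_contig_id)
  bad_seq <- de_fere_contigs[[at]]$sequence
  repl <- list(); map <- list()
  for (dn in de_novo_contigs) {
    res <- local_hits_cpp(dn$sequence, bad_seq, k = 21L,
                          min_identity = min_identity,
                          min_coverage = min_coverage)
    if (nrow(res$hits) > 0L) {
      h <- res$hits[which.max(res$hits$score), ]
      repl[[length(repl) + 1L]] <- dn
      map[[length(map) + 1L]] <- data.frame(
        inserted = dn$record_id, replaced = bad_contig_id,
        target_start = h$r_start, target_end = h$r_end,
        identity = h$identity, coverage = h$coverage,
        stringsAsFactors = FALSE)
    }
  }
  if (length(repl) == 0L)
    stop("no syntenic de novo contig found for ", bad_contig_id,
         "; assembly left unedited")
  out <- append(de_fere_contigs[-at], repl, after = at - 1L)
  attr(out, "replacements") <- do.call(rbind, map)
  out
}
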