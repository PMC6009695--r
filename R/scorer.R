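# The score step: classify each reference rDNA region in an assembly as
# correct / unassembled / incorrect / ambiguous by matching the reference
# flanking sequences into the assembly, plus region SNP counting between two
# assemblies.

JUNCTION_CATEGORIES <- c("correct", "unassembled", "incorrect", "ambiguous")

#' Match reference flanks into an assembly
#'
#' For every cluster and side, the reference flank sequence (the `flank` bp
#' immediately up/downstream of the rDNA span, as fixed at clustering time)
#' is locally aligned against every assembly contig on both strands with
#' BLAST-like thresholds. All qualifying hits are retained; multiplicity
#' matters for the ambiguity call. Flanks shorter than 100 bp after clamping
#' are skipped with a warning.
#'
#' @param reference Reference genome (list of [genome_record()]).
#' @param clusters `operon_clusters`.
#' @param assembly Contig list ([genome_record()]s) or `assembly_result`.
#' @param min_identity Minimum alignment identity.
#' @param min_coverage Minimum fraction of the flank aligned.
#' @return FlankMatch data.frame: `cluster_id`, `side`, `contig_id`,
#'   `contig_start`, `contig_end`, `strand`, `identity`, `coverage`.
#'   Contig lengths are attached as attribute `"contig_lengths"`.
#' @export
match_flanks <- function(reference, clusters, assembly, min_identity = 0.95,
                         min_coverage = 0.5) {
  if (inherits(assembly, "assembly_result")) assembly <- assembly$contigs
  contig_seqs <- vapply(assembly, function(g) g$sequence, character(1))
  contig_ids <- vapply(assembly, function(g) g$record_id, character(1))
  ref_ids <- genome_ids(reference)
  rows <- list()
  for (cl in clusters) {
    ref_seq <- reference[[match(cl$record_id, ref_ids)]]$sequence
    for (side in c("upstream", "downstream")) {
      fl <- if (side == "upstream")
        c(cl$region_start, cl$span_start) else c(cl$span_end, cl$region_end)
      if (fl[2] - fl[1] < 100L) {
        warning("cluster ", cl$cluster_id, " ", side,
                " flank shorter than 100 bp after clamping; side skipped")
        next
      }
      flank_seq <- substr(ref_seq, fl[1] + 1L, fl[2])
      if (length(contig_seqs) == 0L) next
      res <- local_hits_cpp(flank_seq, unname(contig_seqs), k = 21L,
                            min_identity = min_identity,
                            min_coverage = min_coverage)
      h <- res$hits
      if (nrow(h) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cl$cluster_id, side = side,
        contig_id = contig_ids[h$record],
        contig_start = h$r_start, contig_end = h$r_end,
        strand = h$strand, identity = h$identity, coverage = h$coverage,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = numeric(), side = character(),
               contig_id = character(), contig_start = integer(),
               contig_end = integer(), strand = character(),
               identity = numeric(), coverage = numeric(),
               stringsAsFactors = FALSE)
  attr(out, "contig_lengths") <- stats::setNames(nchar(contig_seqs), contig_ids)
  out
}

# enumerate (upstream, downstream) pairs on one contig satisfying the
# correct-junction geometry
valid_junction_pairs <- function(cm, rdna_span_length, min_extension, span_tol) {
  pairs <- list()
  ups <- cm[cm$side == "upstream" & cm$coverage >= min_extension, , drop = FALSE]
  downs <- cm[cm$side == "downstream" & cm$coverage >= min_extension, , drop = FALSE]
  lo <- rdna_span_length * (1 - span_tol)
  hi <- rdna_span_length * (1 + span_tol)
  for (i in seq_len(nrow(ups))) for (j in seq_len(nrow(downs))) {
    u <- ups[i, ]; d <- downs[j, ]
    if (u$contig_id != d$contig_id || u$strand != d$strand) next
    sep <- if (u$strand == "+") d$contig_start - u$contig_end
           else u$contig_start - d$contig_end
    if (sep >= lo && sep <= hi)
      pairs[[length(pairs) + 1L]] <- cbind(u, data.frame(
        partner_start = d$contig_start, partner_end = d$contig_end, sep = sep))
  }
  pairs
}

#' Classify one rDNA junction
#'
#' Pure function of the flank-match evidence. A cluster is `correct` when
#' its upstream and downstream flanks match the same contig, on the same
#' strand, in reference order, separated by approximately the rDNA span
#' (within `span_tol`), each covering at least `min_extension` of the flank.
#' It is `incorrect` when a flank is fused, at junction distance, to a flank
#' that contradicts the reference (wrong partner cluster, side or
#' orientation). It is `unassembled` when a contig end falls within the rDNA
#' or flanking region (truncated evidence, or a flank whose rDNA-side
#' continuation is shorter than the span). Anything conflicting or multiple
#' — including several co-best correct configurations — is `ambiguous`.
#'
#' @param cluster One `operon_cluster`.
#' @param matches Flank matches from [match_flanks()] (all clusters; evidence
#'   for other clusters is needed to detect cross-cluster fusions).
#' @param rdna_span_length rDNA span length in bp (defaults to the cluster's).
#' @param flank_length Flank length in bp (defaults to the cluster's).
#' @param min_extension Minimum fraction of the flank an assembled contig
#'   must cover.
#' @param span_tol Relative tolerance on the flank separation.
#' @return List with `cluster_id`, `category`, `evidence`, `note`.
#' @export
classify_junction <- function(cluster, matches,
                              rdna_span_length = NULL, flank_length = NULL,
                              min_extension = 0.9, span_tol = 0.2) {
  cid <- cluster$cluster_id
  if (is.null(rdna_span_length))
    rdna_span_length <- cluster$span_end - cluster$span_start
  if (is.null(flank_length)) flank_length <- cluster$flank
  clens <- attr(matches, "contig_lengths")
  cm <- matches[matches$cluster_id == cid, , drop = FALSE]
  call <- function(category, note = "") {
    list(cluster_id = cid, category = category, evidence = cm, note = note)
  }
  if (nrow(cm) == 0L)
    return(call("unassembled", "no flank matches in assembly"))

  pairs <- valid_junction_pairs(cm, rdna_span_length, min_extension, span_tol)
  if (length(pairs) == 1L)
    return(call("correct", sprintf("junction on %s, separation %d bp",
                                   pairs[[1]]$contig_id, round(pairs[[1]]$sep))))
  if (length(pairs) > 1L)
    return(call("ambiguous", sprintf("%d co-best junction configurations",
                                     length(pairs))))

  # cross-cluster fusion: one of this cluster's flanks sits at junction
  # distance from a partner flank that contradicts the reference
  lo <- rdna_span_length * (1 - span_tol)
  hi <- rdna_span_length * (1 + span_tol)
  om <- matches[matches$coverage >= min_extension, , drop = FALSE]
  for (i in which(cm$coverage >= min_extension)) {
    m <- cm[i, ]
    for (j in seq_len(nrow(om))) {
      o <- om[j, ]
      if (o$contig_id != m$contig_id) next
      if (o$cluster_id == cid && o$side != m$side) next # handled above
      same <- o$cluster_id == cid & o$side == m$side
      if (same) next
      sep <- if (m$side == "upstream")
        (if (m$strand == "+") o$contig_start - m$contig_end
         else m$contig_start - o$contig_end)
      else
        (if (m$strand == "+") m$contig_start - o$contig_end
         else o$contig_start - m$contig_end)
      if (!is.na(sep) && sep >= lo && sep <= hi)
        return(call("incorrect",
                    sprintf("%s flank of cluster %d fused to %s flank of cluster %d on %s",
                            m$side, cid, o$side, o$cluster_id, m$contig_id)))
    }
  }

  # truncation: contig terminates inside the rDNA or flanking region
  # (a valid junction needs span + far flank of room beyond the near flank)
  for (i in seq_len(nrow(cm))) {
    m <- cm[i, ]
    clen <- unname(clens[m$contig_id])
    rdna_side_space <- if ((m$side == "upstream") == (m$strand == "+"))
      clen - m$contig_end else m$contig_start
    if (m$coverage < 1 - 1e-9 ||
        rdna_side_space < rdna_span_length + flank_length)
      return(call("unassembled",
                  sprintf("contig %s ends within the rDNA region of cluster %d",
                          m$contig_id, cid)))
  }
  call("ambiguous", "flank evidence present but no consistent junction")
}

#' Score an assembly's rDNA junctions against the reference
#'
#' Runs [match_flanks()] and [classify_junction()] for every cluster and
#' tabulates the summary counts.
#'
#' @param reference Reference genome.
#' @param clusters `operon_clusters`.
#' @param assembly Contig list or `assembly_result`.
#' @param min_identity,min_coverage Flank-match thresholds.
#' @param min_extension,span_tol Junction-call thresholds.
#' @param out Optional TSV path for the per-cluster report.
#' @return `junction_scores` object: `calls` (per-cluster data.frame),
#'   `summary` (named counts), `matches`.
#' @export
score_assembly <- function(reference, clusters, assembly,
                           min_identity = 0.95, min_coverage = 0.5,
                           min_extension = 0.9, span_tol = 0.2, out = NULL) {
  matches <- match_flanks(reference, clusters, assembly,
                          min_identity = min_identity,
                          min_coverage = min_coverage)
  calls <- lapply(clusters, classify_junction, matches = matches,
                  min_extension = min_extension, span_tol = span_tol)
  df <- do.call(rbind, lapply(calls, function(cl) {
    ev <- cl$evidence
    data.frame(cluster_id = cl$cluster_id, category = cl$category,
               contigs = paste(unique(ev$contig_id), collapse = ";"),
               identities = paste(sprintf("%.3f", ev$identity), collapse = ";"),
               extensions = paste(sprintf("%.2f", ev$coverage), collapse = ";"),
               note = cl$note, stringsAsFactors = FALSE)
  }))
  summary <- vapply(JUNCTION_CATEGORIES,
                    function(cat) sum(df$category == cat), integer(1))
  if (!is.null(out))
    utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(calls = df, summary = summary, matches = matches),
            class = "junction_scores")
}

#' @export
print.junction_scores <- function(x, ...) {
  cat("<junction_scores> ",
      paste(sprintf("%s=%d", names(x$summary), x$summary), collapse = " "),
      "\n", sep = "")
  print(x$calls[, c("cluster_id", "category", "contigs", "note")],
        row.names = FALSE)
  invisible(x)
}

#' Count substitutions between two assemblies over the rDNA regions
#'
#' For every cluster's rDNA span plus `flank` bp on either side in
#' `assembly_a` (the coordinate-bearing assembly the clusters refer to), the
#' best local alignment in `assembly_b` is found and substitution columns are
#' enumerated; indels are reported separately and not counted as SNPs.
#' Regions with no alignment at >= 0.8 identity are marked unalignable and
#' excluded from the total, with a warning.
#'
#' @param assembly_a Genome/assembly carrying the cluster coordinates.
#' @param assembly_b Assembly to compare against.
#' @param clusters `operon_clusters` defined on `assembly_a`.
#' @param flank Flank size in bp.
#' @return List with `regions` (per-region table), `snps` (one row per
#'   substitution: `cluster_id`, `position` in `assembly_a` coordinates,
#'   `base_a`, `base_b`), and `total`.
#' @export
count_region_snps <- function(assembly_a, assembly_b, clusters, flank = 1000) {
  if (inherits(assembly_a, "assembly_result")) assembly_a <- assembly_a$contigs
  if (inherits(assembly_b, "assembly_result")) assembly_b <- assembly_b$contigs
  a_ids <- genome_ids(assembly_a)
  b_seqs <- vapply(assembly_b, function(g) g$sequence, character(1))
  regions <- list(); snps <- list()
  for (cl in clusters) {
    rec <- assembly_a[[match(cl$record_id, a_ids)]]
    start <- max(0L, cl$span_start - flank)
    end <- min(nchar(rec$sequence), cl$span_end + flank)
    query <- substr(rec$sequence, start + 1L, end)
    res <- local_hits_cpp(query, unname(b_seqs), k = 21L, min_identity = 0.8,
                          min_coverage = 0.5, band = 150L)
    h <- res$hits
    if (nrow(h) == 0L) {
      warning("cluster ", cl$cluster_id,
              " region unalignable (identity < 0.8); excluded from SNP total")
      regions[[length(regions) + 1L]] <- data.frame(
        cluster_id = cl$cluster_id, start = start, end = end,
        n_snps = NA_integer_, n_indels = NA_integer_, alignable = FALSE)
      next
    }
    best <- which.max(h$score)
    sub <- res$subs[[best]]
    if (nrow(sub) > 0L) {
      base_a <- substring(query, sub$q_pos + 1L, sub$q_pos + 1L)
      base_b <- substring(b_seqs[h$record[best]], sub$r_pos + 1L,
                          sub$r_pos + 1L)
      if (h$strand[best] == "-") base_b <- revcomp(base_b)
      snps[[length(snps) + 1L]] <- data.frame(
        cluster_id = cl$cluster_id, position = start + sub$q_pos,
        base_a = base_a, base_b = base_b, stringsAsFactors = FALSE)
    }
    regions[[length(regions) + 1L]] <- data.frame(
      cluster_id = cl$cluster_id, start = start, end = end,
      n_snps = nrow(sub), n_indels = h$n_ins[best] + h$n_del[best],
      alignable = TRUE)
  }
  regions <- do.call(rbind, regions)
  snps <- if (length(snps)) do.call(rbind, snps) else
    data.frame(cluster_id = numeric(), position = integer(),
               base_a = character(), base_b = character(),
               stringsAsFactors = FALSE)
  list(regions = regions, snps = snps,
       total = sum(regions$n_snps, na.rm = TRUE))
}
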