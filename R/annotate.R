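# The scan step: obtain and normalise rRNA annotations on the reference,
# either from a supplied feature table (the documented path for real genomes,
# e.g. a Barrnap GFF) or via a built-in exemplar k-mer detector suited to
# synthetic genomes and desk-scale tests.

#' Scan a reference for rRNA features
#'
#' If `features` are supplied they are filtered to the 16S/23S/5S kinds and
#' normalised (this path is idempotent). Otherwise rRNAs are detected by
#' exemplar k-mer matching: reference intervals whose shared-k-mer density
#' with an exemplar subunit sequence exceeds `min_density` are merged, and
#' intervals covering at least `min_len_frac` of the exemplar length are
#' reported, with strand taken from the k-mer orientation majority.
#'
#' @param genome Reference genome (list of [genome_record()]).
#' @param features Optional feature data.frame (see [read_features()]).
#' @param exemplars Optional list of [genome_record()]s holding exemplar rRNA
#'   subunit sequences; kind is classified from the record id/description.
#' @param k K-mer size for detection.
#' @param min_density Minimum shared-k-mer density within an interval.
#' @param min_len_frac Minimum merged interval length as a fraction of the
#'   exemplar length.
#' @return rRNA-only feature data.frame.
#' @export
scan_rrnas <- function(genome, features = NULL, exemplars = NULL, k = 31,
                       min_density = 0.5, min_len_frac = 0.8) {
  if (is.null(features) && is.null(exemplars))
    stop("supply rRNA feature annotations or exemplar sequences")
  if (!is.null(features)) {
    out <- validate_features(features, genome)
    out <- out[out$kind %in% c("rRNA_16S", "rRNA_23S", "rRNA_5S"), ,
               drop = FALSE]
  } else {
    out <- detect_by_exemplars(genome, exemplars, k, min_density, min_len_frac)
  }
  if (nrow(out) == 0L)
    stop("no rRNA features found; supply annotations (e.g. a Barrnap GFF) ",
         "for this reference")
  out <- merge_same_kind_overlaps(out)
  rownames(out) <- NULL
  out[order(out$record_id, out$start), , drop = FALSE]
}

detect_by_exemplars <- function(genome, exemplars, k, min_density,
                                min_len_frac) {
  if (inherits(exemplars, "genome_record")) exemplars <- list(exemplars)
  hits <- list()
  for (ex in exemplars) {
    kind <- classify_rrna_kind(paste(ex$record_id, ex$description))
    exlen <- nchar(ex$sequence)
    if (exlen < k) next
    exk <- substring(ex$sequence, seq_len(exlen - k + 1L),
                     seq_len(exlen - k + 1L) + k - 1L)
    fwd <- unique(exk)
    rev <- unique(revcomp(exk))
    for (rec in genome) {
      L <- nchar(rec$sequence)
      if (L < k) next
      refk <- substring(rec$sequence, seq_len(L - k + 1L),
                        seq_len(L - k + 1L) + k - 1L)
      is_f <- refk %in% fwd
      is_r <- refk %in% rev
      pos <- which(is_f | is_r) # 1-based k-mer starts
      if (length(pos) == 0L) next
      # split matched positions into runs with gaps <= 2k
      grp <- cumsum(c(1L, diff(pos) > 2L * k))
      for (g in split(seq_along(pos), grp)) {
        p <- pos[g]
        start0 <- p[1] - 1L
        end0 <- p[length(p)] + k - 1L
        dens <- length(p) / max(1L, (p[length(p)] - p[1] + 1L))
        if (dens < min_density) next
        if ((end0 - start0) < min_len_frac * exlen) next
        n_r <- sum(is_r[p])
        hits[[length(hits) + 1L]] <- data.frame(
          record_id = rec$record_id, start = start0, end = end0,
          strand = if (n_r > length(p) / 2) "-" else "+",
          kind = kind,
          source_label = paste0("exemplar:", ex$record_id),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) return(empty_features())
  do.call(rbind, hits)
}

# merge overlapping detections of the same kind on the same record
merge_same_kind_overlaps <- function(features) {
  if (nrow(features) < 2L) return(features)
  features <- features[order(features$record_id, features$kind,
                             features$start), ]
  keep <- features[1, , drop = FALSE]
  for (i in 2:nrow(features)) {
    n <- nrow(keep)
    f <- features[i, ]
    if (keep$record_id[n] == f$record_id && keep$kind[n] == f$kind &&
        f$start < keep$end[n]) {
      keep$end[n] <- max(keep$end[n], f$end)
    } else keep <- rbind(keep, f)
  }
  keep
}
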