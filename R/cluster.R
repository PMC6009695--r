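# The select step: group rRNA annotations into rDNA operon clusters with
# exact Fisher-Jenks natural breaks, the class count set by the number of 16S
# features, and a hand-editable plain-text cluster file.

#' Jenks natural breaks (exact Fisher-Jenks dynamic program)
#'
#' Partitions sorted numeric values into `n_classes` contiguous groups
#' minimising the total within-class sum of squared deviations from the class
#' means. Ties are broken towards the lexicographically smallest break
#' positions. Complexity O(n_classes * n^2), exact for any input.
#'
#' @param values Numeric vector (sorted internally).
#' @param n_classes Number of classes, `1 <= n_classes <= length(unique(values))`.
#' @return List of numeric vectors, one per class, in ascending order; the
#'   within-class sum of squares is attached as attribute `"ss"`.
#' @export
jenks_breaks <- function(values, n_classes) {
  n <- length(values)
  if (n_classes > n) stop("n_classes (", n_classes, ") exceeds number of values (", n, ")")
  if (n_classes < 1L) stop("n_classes must be >= 1")
  if (n_classes > length(unique(values)))
    stop("n_classes exceeds the number of distinct values")
  v <- sort(values)
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  ss <- function(i, j) { # within-class SS of v[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # D[m, j]: optimal cost of partitioning v[1..j] into m classes
  D <- matrix(Inf, n_classes, n)
  B <- matrix(0L, n_classes, n) # start index of the last class
  for (j in seq_len(n)) { D[1, j] <- ss(1, j); B[1, j] <- 1L }
  if (n_classes > 1) {
    for (m in 2:n_classes) {
      for (j in m:n) {
        for (i in m:j) { # last class = v[i..j]
          cost <- D[m - 1, i - 1] + ss(i, j)
          if (cost < D[m, j] - 1e-12) { D[m, j] <- cost; B[m, j] <- i }
        }
      }
    }
  }
  bounds <- integer(n_classes + 1L)
  bounds[n_classes + 1L] <- n
  j <- n
  for (m in n_classes:1) {
    bounds[m] <- B[m, j]
    j <- B[m, j] - 1L
  }
  groups <- lapply(seq_len(n_classes), function(m) {
    to <- if (m == n_classes) n else bounds[m + 1L] - 1L
    v[bounds[m]:to]
  })
  attr(groups, "ss") <- D[n_classes, n]
  groups
}

new_operon_cluster <- function(cluster_id, record_id, members, flank, seq_len) {
  span_start <- min(members$start)
  span_end <- max(members$end)
  structure(list(
    cluster_id = cluster_id, record_id = record_id, members = members,
    span_start = span_start, span_end = span_end, flank = flank,
    region_start = max(0L, span_start - flank),
    region_end = if (is.finite(seq_len)) min(seq_len, span_end + flank)
                 else span_end + flank),
    class = "operon_cluster")
}

#' @export
print.operon_cluster <- function(x, ...) {
  cat(sprintf("<operon_cluster %d> %s span [%d,%d) region [%d,%d) members: %s\n",
              x$cluster_id, x$record_id, x$span_start, x$span_end,
              x$region_start, x$region_end,
              paste(x$members$kind, collapse = ",")))
  invisible(x)
}

#' Group rRNA features into rDNA operon clusters
#'
#' Per record, rRNA feature midpoints are clustered with [jenks_breaks()]
#' using the number of 16S annotations on that record as the class count
#' (falling back to the 23S count, with a warning, if no 16S is present).
#' Each class becomes one operon cluster; clusters are numbered by ascending
#' span start. Clustering uses midpoints rather than starts so that it is
#' robust to gene order on either strand.
#'
#' @param features rRNA feature data.frame (from [scan_rrnas()]).
#' @param genome Optional genome used to clamp cluster regions at sequence
#'   bounds.
#' @param flank Flank length in bp added on both sides of each cluster span.
#' @return List of `operon_cluster` objects (class `operon_clusters`).
#' @export
select_operons <- function(features, genome = NULL, flank = 1000) {
  stopifnot(nrow(features) >= 1L)
  seq_lens <- if (!is.null(genome))
    stats::setNames(genome_lengths(genome), genome_ids(genome)) else NULL
  clusters <- list()
  cid <- 0L
  for (rid in unique(features$record_id)) {
    f <- features[features$record_id == rid, , drop = FALSE]
    n16 <- sum(f$kind == "rRNA_16S")
    ncl <- n16
    if (ncl == 0L) {
      ncl <- max(sum(f$kind == "rRNA_23S"), 1L)
      warning("record ", rid, " has rRNA features but no 16S; using ",
              ncl, " cluster(s) from the 23S count")
    }
    mid <- (f$start + f$end) / 2
    ord <- order(mid)
    f <- f[ord, , drop = FALSE]
    mid <- mid[ord]
    ncl <- min(ncl, length(unique(mid)))
    groups <- jenks_breaks(mid, ncl)
    # map each feature to its group by position in the sorted midpoints
    sizes <- lengths(groups)
    gidx <- rep(seq_along(groups), sizes)
    slen <- if (!is.null(seq_lens)) seq_lens[[rid]] else Inf
    rec_clusters <- lapply(seq_along(groups), function(g) {
      members <- f[gidx == g, , drop = FALSE]
      new_operon_cluster(0L, rid, members, flank, slen)
    })
    rec_clusters <- rec_clusters[order(vapply(rec_clusters,
                                              function(cl) cl$span_start,
                                              numeric(1)))]
    rec_clusters <- merge_overlapping_clusters(rec_clusters, flank, slen)
    for (cl in rec_clusters) {
      cid <- cid + 1L
      cl$cluster_id <- cid
      clusters[[cid]] <- cl
    }
  }
  structure(clusters, class = "operon_clusters")
}

merge_overlapping_clusters <- function(clusters, flank, seq_len) {
  if (length(clusters) < 2L) return(clusters)
  out <- list(clusters[[1]])
  for (i in 2:length(clusters)) {
    n <- length(out)
    if (clusters[[i]]$span_start < out[[n]]$span_end) {
      warning("spatially overlapping cluster spans merged")
      members <- rbind(out[[n]]$members, clusters[[i]]$members)
      out[[n]] <- new_operon_cluster(out[[n]]$cluster_id, out[[n]]$record_id,
                                     members, flank, seq_len)
    } else out[[n + 1L]] <- clusters[[i]]
  }
  out
}

#' @export
print.operon_clusters <- function(x, ...) {
  cat(sprintf("<operon_clusters> %d cluster(s)\n", length(x)))
  for (cl in x) print(cl)
  invisible(x)
}

#' @export
as.data.frame.operon_clusters <- function(x, ...) {
  do.call(rbind, lapply(x, function(cl) data.frame(
    cluster_id = cl$cluster_id, record_id = cl$record_id,
    span_start = cl$span_start, span_end = cl$span_end,
    region_start = cl$region_start, region_end = cl$region_end,
    n_members = nrow(cl$members), stringsAsFactors = FALSE)))
}

feature_descriptor <- function(members) {
  paste(sprintf("%s:%d-%d:%s", members$kind, members$start, members$end,
                members$strand), collapse = ",")
}

#' Write a hand-editable cluster file
#'
#' One cluster per line: `record_id<TAB>cluster_id<TAB>descriptors`, where
#' each descriptor is `kind:start-end:strand`. The file can be edited (e.g.
#' clusters merged) and loaded back with [load_cluster_file()].
#'
#' @param clusters `operon_clusters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_file <- function(clusters, path) {
  lines <- vapply(clusters, function(cl)
    paste(cl$record_id, cl$cluster_id, feature_descriptor(cl$members),
          sep = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load a cluster file
#'
#' Rebuilds clusters exactly as the file specifies, bypassing Jenks
#' clustering. Every descriptor must match a supplied feature; a feature
#' claimed by two clusters is an error.
#'
#' @param path Cluster file path.
#' @param features rRNA feature data.frame the descriptors refer to. When
#'   omitted, features are reconstructed from the descriptors themselves
#'   (they carry kind, interval and strand in full).
#' @param genome Optional genome for region clamping.
#' @param flank Flank length in bp.
#' @return `operon_clusters` object.
#' @export
load_cluster_file <- function(path, features = NULL, genome = NULL,
                              flank = 1000) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(features)) features <- features_from_cluster_lines(lines)
  seq_lens <- if (!is.null(genome))
    stats::setNames(genome_lengths(genome), genome_ids(genome)) else NULL
  key <- sprintf("%s|%s:%d-%d:%s", features$record_id, features$kind,
                 features$start, features$end, features$strand)
  claimed <- integer(0)
  clusters <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) != 3L) stop("malformed cluster line: ", ln)
    rid <- f[1]
    cid <- as.integer(f[2])
    descs <- strsplit(f[3], ",")[[1]]
    idx <- match(paste0(rid, "|", descs), key)
    if (anyNA(idx))
      stop("cluster file cites unknown feature(s): ",
           paste(descs[is.na(idx)], collapse = ", "))
    dup <- intersect(idx, claimed)
    if (length(dup))
      stop("feature claimed by two clusters: ", key[dup[1]])
    claimed <- c(claimed, idx)
    members <- features[idx, , drop = FALSE]
    slen <- if (!is.null(seq_lens)) seq_lens[[rid]] else Inf
    clusters[[length(clusters) + 1L]] <-
      new_operon_cluster(cid, rid, members, flank, slen)
  }
  clusters <- clusters[order(vapply(clusters, function(cl) cl$cluster_id,
                                    numeric(1)))]
  structure(clusters, class = "operon_clusters")
}

# rebuild a feature table from cluster-file descriptors (kind:start-end:strand)
features_from_cluster_lines <- function(lines) {
  rows <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) != 3L) stop("malformed cluster line: ", ln)
    for (d in strsplit(f[3], ",")[[1]]) {
      m <- regmatches(d, regexec("^([^:]+):([0-9]+)-([0-9]+):([+-])$", d))[[1]]
      if (length(m) != 5L) stop("malformed feature descriptor: ", d)
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = f[1], start = as.integer(m[3]), end = as.integer(m[4]),
        strand = m[5], kind = m[2], source_label = "",
        stringsAsFactors = FALSE)
    }
  }
  unique(do.call(rbind, rows))
}
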