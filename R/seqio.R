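# Sequence and feature I/O. All internal coordinates are 0-based half-open;
# conversion to/from the 1-based inclusive conventions of GFF3/GenBank/SAM
# happens only here, at the I/O boundary.

RRNA_KINDS <- c("rRNA_16S", "rRNA_23S", "rRNA_5S", "other")

#' Construct a genome record
#'
#' A genome record holds one replicon: an uppercase DNA sequence over
#' `{A,C,G,T,N}` plus its identifier and topology. Characters outside the
#' alphabet (IUPAC ambiguity codes and anything else) are normalised to `N`
#' and the number of normalised positions is reported.
#'
#' @param record_id Sequence identifier (non-empty, no whitespace).
#' @param sequence DNA sequence as a single string.
#' @param topology `"linear"` or `"circular"`.
#' @param description Free-text description.
#' @return An object of class `genome_record` with fields `record_id`,
#'   `sequence`, `topology`, `description`.
#' @export
genome_record <- function(record_id, sequence, topology = c("linear", "circular"),
                          description = "") {
  topology <- match.arg(topology)
  if (!is.character(record_id) || length(record_id) != 1L || !nzchar(record_id))
    stop("record_id must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  sequence <- toupper(sequence)
  n_norm <- 0L
  if (grepl("[^ACGTN]", sequence)) {
    n_norm <- nchar(gsub("[ACGTN]", "", sequence))
    sequence <- gsub("[^ACGTN]", "N", sequence)
    message(sprintf("record '%s': %d non-ACGTN character(s) normalised to N",
                    record_id, n_norm))
  }
  structure(list(record_id = record_id, sequence = sequence,
                 topology = topology, description = description,
                 n_normalised = n_norm),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s, %d bp)\n", x$record_id, x$topology,
              nchar(x$sequence)))
  invisible(x)
}

genome_lengths <- function(genome) {
  vapply(genome, function(g) nchar(g$sequence), integer(1),
         USE.NAMES = FALSE)
}

genome_ids <- function(genome) {
  vapply(genome, function(g) g$record_id, character(1), USE.NAMES = FALSE)
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) rc_cpp(toupper(x))

#' Read a FASTA file
#'
#' Sequences are uppercased and characters outside `{A,C,G,T,N}` are
#' normalised to `N` (the count is reported per record). Record ids must be
#' unique; malformed headers and empty sequences are errors naming the
#' offending line.
#'
#' @param path Path to a FASTA file.
#' @param topology Topology assigned to every record.
#' @return Named list of [genome_record()] objects.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA header found in ", path)
  if (hdr[1] != 1L && any(nzchar(trimws(lines[seq_len(hdr[1] - 1)]))))
    stop("FASTA parse error at line 1: sequence before first header")
  ends <- c(hdr[-1] - 1L, length(lines))
  recs <- vector("list", length(hdr))
  ids <- character(length(hdr))
  for (i in seq_along(hdr)) {
    h <- sub("^>", "", lines[hdr[i]])
    id <- sub("\\s.*$", "", h)
    if (!nzchar(id))
      stop(sprintf("FASTA parse error at line %d: empty record id", hdr[i]))
    desc <- trimws(sub("^\\S*\\s*", "", h))
    body <- lines[seq(hdr[i] + 1L, length.out = max(0L, ends[i] - hdr[i]))]
    seq <- gsub("\\s", "", paste(body, collapse = ""))
    if (!nzchar(seq))
      stop(sprintf("FASTA parse error at line %d: record '%s' has empty sequence",
                   hdr[i], id))
    ids[i] <- id
    recs[[i]] <- genome_record(id, seq, topology, desc)
  }
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(recs) <- ids
  recs
}

#' Write genome records to FASTA
#'
#' @param records A list of [genome_record()]s (or a single record).
#' @param path Output path.
#' @param line_width Sequence line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 70) {
  if (inherits(records, "genome_record")) records <- list(records)
  if (length(records) == 0L) stop("no records to write")
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$record_id, r$description)
           else r$record_id
    writeLines(paste0(">", hdr), con)
    s <- r$sequence
    starts <- seq(1L, nchar(s), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (Sanger Phred+33)
#'
#' @param path Path to an uncompressed FASTQ file with 4-line records.
#' @param mate Mate label for every read: `"single"`, `"first"` or `"second"`.
#'   `"auto"` derives it from a trailing `/1` or `/2` on the read id.
#' @return A data.frame with columns `read_id`, `sequence`, `quality`, `mate`.
#' @export
read_fastq <- function(path, mate = "auto") {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ parse error: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  n <- length(lines) %/% 4L
  at <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  qu <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(at, "@"))
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: header does not start with @",
                 (bad[1] - 1L) * 4L + 1L))
  bad <- which(nchar(sq) != nchar(qu))
  if (length(bad))
    stop(sprintf("FASTQ parse error: read %d sequence/quality length mismatch",
                 bad[1]))
  id <- sub("\\s.*$", "", sub("^@", "", at))
  m <- if (identical(mate, "auto")) {
    ifelse(grepl("/1$", id), "first", ifelse(grepl("/2$", id), "second", "single"))
  } else rep(mate, n)
  data.frame(read_id = sub("/[12]$", "", id), sequence = sq, quality = qu,
             mate = m, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads Read data.frame as returned by [read_fastq()] or
#'   [simulate_reads()].
#' @param path Output path; mate suffixes (`/1`, `/2`) are appended for paired
#'   reads.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  suf <- c(single = "", first = "/1", second = "/2")[reads$mate]
  out <- rbind(paste0("@", reads$read_id, suf), reads$sequence, "+",
               reads$quality)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Phred qualities as integer scores
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @return List of integer vectors.
#' @export
quality_scores <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

classify_rrna_kind <- function(label) {
  lab <- toupper(label)
  kind <- rep("other", length(lab))
  kind[grepl("16S", lab)] <- "rRNA_16S"
  kind[grepl("23S", lab)] <- "rRNA_23S"
  kind[grepl("5S", lab) & !grepl("16S|23S", lab)] <- "rRNA_5S"
  kind
}

empty_features <- function() {
  data.frame(record_id = character(), start = integer(), end = integer(),
             strand = character(), kind = character(),
             source_label = character(), stringsAsFactors = FALSE)
}

validate_features <- function(features, genome = NULL) {
  stopifnot(all(c("record_id", "start", "end", "strand", "kind") %in%
                  names(features)))
  if (nrow(features) == 0L) return(features)
  if (any(features$start < 0L) || any(features$start >= features$end))
    stop("invalid feature interval: require 0 <= start < end")
  if (!all(features$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'")
  if (!is.null(genome)) {
    len <- stats::setNames(genome_lengths(genome), genome_ids(genome))
    unknown <- setdiff(features$record_id, names(len))
    if (length(unknown))
      stop("features reference unknown record(s): ",
           paste(unknown, collapse = ", "))
    if (any(features$end > len[features$record_id]))
      stop("feature extends beyond sequence bounds on record ",
           features$record_id[which(features$end > len[features$record_id])[1]])
  }
  features
}

#' Read rRNA feature annotations
#'
#' Parses GFF3 (via rtracklayer) or GenBank flat files and returns features in
#' the package's internal convention: 0-based half-open coordinates. rRNA
#' features are classified into 16S/23S/5S by case-insensitive substring match
#' on the product/name text; rRNA features that cannot be classified get
#' `kind = "other"` with a warning.
#'
#' @param path Path to the feature file.
#' @param dialect `"gff3"` or `"genbank"`.
#' @param genome Optional genome (list of [genome_record()]) used to validate
#'   feature bounds.
#' @return Feature data.frame with columns `record_id`, `start`, `end`,
#'   `strand`, `kind`, `source_label`.
#' @export
read_features <- function(path, dialect = c("gff3", "genbank"), genome = NULL) {
  dialect <- match.arg(dialect)
  feats <- if (dialect == "gff3") read_features_gff3(path)
           else read_features_genbank(path)
  if (any(feats$kind == "other" & grepl("ribosomal|rRNA", feats$source_label,
                                        ignore.case = TRUE)))
    warning("some rRNA feature(s) could not be classified into 16S/23S/5S; ",
            "kept with kind 'other'")
  validate_features(feats, genome)
}

read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_features())
  mc <- S4Vectors::mcols(gr)
  label <- rep("", length(gr))
  for (col in c("product", "Name", "gene", "ID")) {
    if (col %in% names(mc)) {
      v <- as.character(mc[[col]])
      label <- ifelse(nzchar(label) | is.na(v), label, v)
    }
  }
  type <- if ("type" %in% names(mc)) as.character(mc$type) else
    rep("rRNA", length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  data.frame(record_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,  # 1-based -> 0-based
             end = GenomicRanges::end(gr),
             strand = strand,
             kind = ifelse(toupper(type) %in% c("RRNA", "GENE"),
                           classify_rrna_kind(label), "other"),
             source_label = ifelse(nzchar(label), label, type),
             stringsAsFactors = FALSE)
}

# Minimal GenBank flat-file feature reader: rRNA features and their /product
# qualifiers only. `join` locations are collapsed to their min..max extent.
read_features_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank file (no LOCUS line): ", path)
  record_id <- strsplit(trimws(locus[1]), "\\s+")[[1]][2]
  in_feat <- FALSE
  out <- list()
  cur <- NULL
  flush <- function(cur, out) {
    if (is.null(cur)) return(out)
    out[[length(out) + 1L]] <- cur
    out
  }
  for (ln in lines) {
    if (grepl("^FEATURES", ln)) { in_feat <- TRUE; next }
    if (grepl("^(ORIGIN|CONTIG|//)", ln)) { in_feat <- FALSE; next }
    if (!in_feat) next
    if (grepl("^ {5}\\S", ln)) { # new feature
      out <- flush(cur, out)
      cur <- NULL
      key <- sub("^ {5}(\\S+).*$", "\\1", ln)
      loc <- trimws(sub("^ {5}\\S+\\s+", "", ln))
      if (key == "rRNA") cur <- list(loc = loc, product = "")
    } else if (!is.null(cur)) {
      q <- trimws(ln)
      if (grepl("^/product=", q)) {
        cur$product <- gsub('"', "", sub("^/product=", "", q))
      } else if (!grepl("^/", q) && !grepl("=", q) && cur$product == "") {
        cur$loc <- paste0(cur$loc, q) # continued location line
      }
    }
  }
  out <- flush(cur, out)
  if (length(out) == 0L) return(empty_features())
  rows <- lapply(out, function(f) {
    strand <- if (grepl("complement", f$loc)) "-" else "+"
    nums <- as.integer(regmatches(f$loc, gregexpr("[0-9]+", f$loc))[[1]])
    if (length(nums) < 2L) stop("unparseable GenBank location: ", f$loc)
    data.frame(record_id = record_id, start = min(nums) - 1L, end = max(nums),
               strand = strand, kind = classify_rrna_kind(f$product),
               source_label = f$product, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write features as GFF3
#'
#' Internal 0-based half-open coordinates are converted to GFF3's 1-based
#' inclusive convention.
#'
#' @param features Feature data.frame (see [read_features()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  if (nrow(features) == 0L) stop("no features to write")
  gr <- GenomicRanges::GRanges(
    seqnames = features$record_id,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- "rRNA"
  S4Vectors::mcols(gr)$source <- "ribostitch"
  S4Vectors::mcols(gr)$product <- ifelse(
    nzchar(features$source_label), features$source_label,
    sub("rRNA_", "", paste0(features$kind, " ribosomal RNA")))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write regions as BED
#'
#' BED is already 0-based half-open, matching the internal convention.
#'
#' @param regions data.frame with `record_id`, `start`, `end` and optionally
#'   `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$record_id,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  if (!is.null(regions$name)) names(gr) <- regions$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(NULL)
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  if (length(len) != length(op)) stop("unparseable CIGAR: ", cigar)
  list(op = op, len = len)
}

# walk a CIGAR against query and reference, returning match/column counts
cigar_stats <- function(cigar, qseq, rseq) {
  ops <- cigar_ops(cigar)
  qi <- 1L; ri <- 1L; matches <- 0L; columns <- 0L
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]; L <- ops$len[i]
    if (op == "M") {
      q <- substr(qseq, qi, qi + L - 1L)
      r <- substr(rseq, ri, ri + L - 1L)
      matches <- matches + sum(strsplit(q, "")[[1]] == strsplit(r, "")[[1]])
      qi <- qi + L; ri <- ri + L; columns <- columns + L
    } else if (op == "I") { qi <- qi + L; columns <- columns + L }
    else if (op == "D") { ri <- ri + L; columns <- columns + L }
    else if (op == "S") { qi <- qi + L }
  }
  list(matches = matches, columns = columns, qlen_used = qi - 1L,
       rlen_used = ri - 1L)
}

#' Write mappings as SAM
#'
#' Minimal SAM dialect: QNAME/FLAG/RNAME/POS/MAPQ/CIGAR with M/I/D/S
#' operations, SEQ and QUAL. Only primary placements are emitted.
#'
#' @param mappings Mapping data.frame from [map_reads()].
#' @param reads Read data.frame the mappings were computed from.
#' @param genome Reference genome (list of [genome_record()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(mappings, reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  ids <- genome_ids(genome)
  lens <- genome_lengths(genome)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ids, lens), con)
  mp <- mappings[mappings$primary, , drop = FALSE]
  for (i in seq_len(nrow(mp))) {
    m <- mp[i, ]
    rd <- reads[m$read, ]
    flag <- 0L
    if (rd$mate != "single") {
      flag <- flag + 1L
      if (m$proper) flag <- flag + 2L
      flag <- flag + if (rd$mate == "first") 64L else 128L
    }
    seq <- rd$sequence
    qual <- rd$quality
    if (!m$mapped) {
      writeLines(paste(rd$read_id, flag + 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                       seq, qual, sep = "\t"), con)
      next
    }
    if (m$strand == "-") {
      flag <- flag + 16L
      seq <- revcomp(seq)
      qual <- paste(rev(strsplit(qual, "")[[1]]), collapse = "")
    }
    writeLines(paste(rd$read_id, flag, ids[m$record], m$pos + 1L, 60L, m$cigar,
                     "*", 0L, 0L, seq, qual, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal SAM file into a mapping table
#'
#' Supports ingesting alignments from an external mapper. Identity is
#' recomputed from the CIGAR against the supplied reference.
#'
#' @param path SAM path.
#' @param genome Reference genome used to recompute identity.
#' @param reads Read data.frame; rows are matched by read id and mate.
#' @return Mapping data.frame in the layout of [map_reads()].
#' @export
read_sam <- function(path, genome, reads) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  ids <- genome_ids(genome)
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    flag <- as.integer(f[2])
    mate <- if (bitwAnd(flag, 1L)) {
      if (bitwAnd(flag, 64L)) "first" else "second"
    } else "single"
    mapped <- !bitwAnd(flag, 4L)
    data.frame(read_id = f[1], mate = mate, mapped = mapped,
               record = if (mapped) match(f[3], ids) else NA_integer_,
               pos = if (mapped) as.integer(f[4]) - 1L else NA_integer_,
               strand = if (!mapped) "*" else
                 if (bitwAnd(flag, 16L)) "-" else "+",
               cigar = f[6], stringsAsFactors = FALSE)
  })
  mp <- do.call(rbind, rows)
  key_reads <- paste(reads$read_id, reads$mate)
  mp$read <- match(paste(mp$read_id, mp$mate), key_reads)
  mp$identity <- NA_real_
  mp$rlen <- NA_integer_
  for (i in which(mp$mapped & !is.na(mp$read))) {
    rd <- reads$sequence[mp$read[i]]
    if (mp$strand[i] == "-") rd <- revcomp(rd)
    st <- cigar_stats(mp$cigar[i], rd,
                      substr(genome[[mp$record[i]]]$sequence, mp$pos[i] + 1L,
                             nchar(genome[[mp$record[i]]]$sequence)))
    mp$identity[i] <- st$matches / st$columns
    mp$rlen[i] <- st$rlen_used
  }
  mp$primary <- TRUE
  mp$proper <- FALSE
  mp$rescued <- FALSE
  mp$score <- NA_integer_
  mp
}
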