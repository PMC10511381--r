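# Internal coordinate convention: 0-based, half-open [start, end), the BED
# convention. A breakend "pos" is the first base NOT retained on the retained
# side, so a junction between pos p on A and q on B fuses A[0, p) to B[q, ...).

#' Construct a set of genomic intervals
#'
#' Intervals use 0-based half-open coordinates (BED convention).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `0 <= start < end`.
#' @param chrom_sizes optional `chrom_sizes` object; when supplied, intervals
#'   are checked against chromosome bounds.
#' @return a `data.frame` with columns `chrom`, `start`, `end`.
#' @export
genome_intervals <- function(chrom, start, end, chrom_sizes = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval coordinates must be non-missing numbers")
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("invalid interval (need 0 <= start < end): %s:%s-%s",
                 chrom[bad[1]], format(start[bad[1]], scientific = FALSE),
                 format(end[bad[1]], scientific = FALSE)))
  }
  if (!is.null(chrom_sizes)) {
    len <- unname(chrom_sizes[chrom])
    if (any(is.na(len))) {
      stop("interval on chromosome absent from chrom_sizes: ",
           chrom[which(is.na(len))[1]])
    }
    if (any(end > len)) {
      stop("interval extends beyond chromosome end: ",
           chrom[which(end > len)[1]])
    }
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Construct a peak set
#'
#' A labelled collection of genomic intervals, e.g. peaks from one assay.
#'
#' @param intervals `data.frame` as returned by [genome_intervals()].
#' @param label assay label, e.g. `"sperm_ATAC"`.
#' @return an object of class `peak_set`.
#' @export
peak_set <- function(intervals, label = "peaks") {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  intervals <- intervals[order(intervals$chrom, intervals$start,
                               intervals$end), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(label = label, intervals = intervals), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d intervals, %s bp on %d chromosome(s)\n",
              x$label, nrow(x$intervals),
              format(total_bp(x), big.mark = ","),
              length(unique(x$intervals$chrom))))
  invisible(x)
}

#' Total covered base pairs of a peak set
#'
#' Counts each base once even if intervals overlap.
#'
#' @param peaks a `peak_set` or interval `data.frame`.
#' @return numeric, total distinct bp covered.
#' @export
total_bp <- function(peaks) {
  iv <- if (inherits(peaks, "peak_set")) peaks$intervals else peaks
  if (nrow(iv) == 0) return(0)
  tot <- 0
  for (ch in unique(iv$chrom)) {
    sel <- iv$chrom == ch
    r <- IRanges::reduce(IRanges::IRanges(start = iv$start[sel] + 1L,
                                          end = iv$end[sel]))
    tot <- tot + sum(IRanges::width(r))
  }
  tot
}

#' Read a chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named numeric vector of class `chrom_sizes`.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  chrom_sizes(stats::setNames(df$length, df$chrom))
}

#' Construct a chrom.sizes mapping
#'
#' @param sizes named numeric vector, chromosome name -> length in bp.
#' @return named numeric vector of class `chrom_sizes`.
#' @export
chrom_sizes <- function(sizes) {
  if (is.null(names(sizes)) || any(names(sizes) == "")) {
    stop("chrom_sizes must be a named vector")
  }
  if (anyDuplicated(names(sizes))) stop("duplicate chromosome names")
  if (any(sizes <= 0)) stop("chromosome lengths must be > 0")
  structure(as.numeric(stats::setNames(sizes, names(sizes))),
            class = "chrom_sizes", names = names(sizes))
}

#' Write a chrom.sizes file
#' @param sizes `chrom_sizes` object.
#' @param path output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(
    data.frame(chrom = names(sizes),
               length = format(as.numeric(sizes), scientific = FALSE,
                               trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3 or narrowPeak file into a peak set
#'
#' Coordinates are kept 0-based half-open exactly as in the file. Input need
#' not be sorted; output is. narrowPeak (ENCODE 10-column) lines must have at
#' least 10 columns; columns beyond chrom/start/end are ignored.
#'
#' @param path file path.
#' @param dialect `"bed3"` (>= 3 columns) or `"narrowPeak"` (>= 10 columns).
#' @param label assay label for the resulting peak set; defaults to the
#'   file name without extension.
#' @return a `peak_set`.
#' @export
read_bed <- function(path, dialect = c("bed3", "narrowPeak"), label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(peak_set(genome_intervals(character(), numeric(), numeric()),
                    label = label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (dialect == "narrowPeak") 10L else 3L
  nf <- lengths(fields)
  if (any(nf < need)) {
    i <- which(nf < need)[1]
    stop(sprintf("malformed %s line %d in %s: expected >= %d columns, got %d",
                 dialect, lineno[i], path, need, nf[i]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("malformed %s line %d in %s: non-numeric coordinates",
                 dialect, lineno[i], path))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop(sprintf("validation error at line %d in %s: start >= end (%s:%s-%s)",
                 lineno[bad[1]], path, chrom[bad[1]],
                 format(start[bad[1]], scientific = FALSE),
                 format(end[bad[1]], scientific = FALSE)))
  }
  peak_set(genome_intervals(chrom, start, end), label = label)
}

#' Write a peak set as BED3
#' @param peaks a `peak_set` or interval `data.frame`.
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  iv <- if (inherits(peaks, "peak_set")) peaks$intervals else peaks
  df <- data.frame(iv$chrom,
                   format(iv$start, scientific = FALSE, trim = TRUE),
                   format(iv$end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge peak sets (bedtools-merge semantics)
#'
#' Takes the set-theoretic union of the intervals of one or more peak sets and
#' coalesces overlapping or bookended (gap = 0) intervals, matching the
#' defaults of `bedtools merge`. Idempotent.
#'
#' @param ... one or more `peak_set` objects (or interval data frames).
#' @param label label for the merged set; defaults to the labels joined
#'   with `"+"`.
#' @return a merged `peak_set` whose intervals are sorted and disjoint with
#'   no bookended pairs.
#' @export
merge_peaks <- function(..., label = NULL) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "peak_set") && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  if (length(sets) == 0) stop("no peak sets given")
  ivs <- lapply(sets, function(s) {
    if (inherits(s, "peak_set")) s$intervals else s
  })
  if (is.null(label)) {
    labs <- vapply(sets, function(s) {
      if (inherits(s, "peak_set")) s$label else "intervals"
    }, "")
    label <- paste(unique(labs), collapse = "+")
  }
  iv <- do.call(rbind, ivs)
  if (nrow(iv) == 0) {
    return(peak_set(genome_intervals(character(), numeric(), numeric()),
                    label = label))
  }
  out <- lapply(split(iv, iv$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end),
                         min.gapwidth = 1L)
    data.frame(chrom = d$chrom[1], start = IRanges::start(r) - 1,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, out)
  rownames(merged) <- NULL
  peak_set(merged, label = label)
}

# ---- junctions (BEDPE) -----------------------------------------------------

#' Construct a junction set
#'
#' Each row is one breakpoint junction: an ordered pair of breakends plus an
#' optional observed junction sequence. `side1`/`side2` give the retained
#' flank of each breakend: `"left_retained"` (sequence below `pos` retained;
#' BEDPE strand `+`) or `"right_retained"` (sequence at/above `pos` retained;
#' BEDPE strand `-`). A breakend position is the first base not retained.
#'
#' @param chrom1,pos1,side1 first breakend.
#' @param chrom2,pos2,side2 second breakend.
#' @param name junction identifiers (default `J1`, `J2`, ...).
#' @param seq optional junction sequences (NA when unobserved).
#' @return `data.frame` of class `junction_set`.
#' @export
junction_set <- function(chrom1, pos1, side1, chrom2, pos2, side2,
                         name = NULL, seq = NA_character_) {
  n <- length(chrom1)
  if (is.null(name)) name <- if (n) paste0("J", seq_len(n)) else character()
  ok_side <- function(s) all(is.na(s) | s %in% c("left_retained",
                                                 "right_retained"))
  if (!ok_side(side1) || !ok_side(side2)) {
    stop("sides must be 'left_retained' or 'right_retained' (or NA)")
  }
  df <- data.frame(chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
                   side1 = as.character(side1),
                   chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
                   side2 = as.character(side2),
                   name = as.character(name), seq = as.character(seq),
                   stringsAsFactors = FALSE)
  selfj <- df$chrom1 == df$chrom2 & df$pos1 == df$pos2 &
    (is.na(df$side1) | is.na(df$side2) | df$side1 == df$side2)
  if (any(selfj)) {
    stop("self-junction: record with identical breakends (",
         df$name[which(selfj)[1]], ")")
  }
  class(df) <- c("junction_set", "data.frame")
  df
}

.strand_to_side <- function(strand) {
  out <- rep(NA_character_, length(strand))
  out[strand == "+"] <- "left_retained"
  out[strand == "-"] <- "right_retained"
  out
}

.side_to_strand <- function(side) {
  out <- rep(".", length(side))
  out[!is.na(side) & side == "left_retained"] <- "+"
  out[!is.na(side) & side == "right_retained"] <- "-"
  out
}

#' Read breakpoint junctions from a BEDPE file
#'
#' Requires >= 6 columns (chrom1, start1, end1, chrom2, start2, end2);
#' columns 7-10 are name, score, strand1, strand2; an optional column 11
#' carries the observed junction sequence. The breakend position is taken
#' from the `end` column of each mate (BEDPE records a breakend as the
#' 1-bp interval `[end-1, end)`). Strands map to retained sides:
#' `+` = left flank retained, `-` = right flank retained. Records with
#' missing strands are read with `NA` sides; orientation-dependent
#' operations then raise an explicit error rather than assuming a default.
#'
#' @param path file path.
#' @return a `junction_set`.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(junction_set(character(), numeric(), character(),
                        character(), numeric(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    i <- which(nf < 6)[1]
    stop(sprintf("malformed BEDPE line %d in %s: expected >= 6 columns, got %d",
                 lineno[i], path, nf[i]))
  }
  col <- function(k, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= k) f[[k]] else default, "")
  }
  num <- function(k) {
    v <- suppressWarnings(as.numeric(col(k)))
    if (anyNA(v)) {
      stop(sprintf("malformed BEDPE line %d in %s: non-numeric coordinate",
                   lineno[which(is.na(v))[1]], path))
    }
    v
  }
  s1 <- num(2); e1 <- num(3); s2 <- num(5); e2 <- num(6)
  bad <- which(s1 >= e1 | s2 >= e2 | s1 < 0 | s2 < 0)
  if (length(bad)) {
    stop(sprintf("validation error at BEDPE line %d in %s: start >= end",
                 lineno[bad[1]], path))
  }
  name <- col(7)
  name[is.na(name) | name == "."] <- NA
  if (anyNA(name)) {
    name[is.na(name)] <- paste0("J", which(is.na(name)))
  }
  strand1 <- col(9); strand2 <- col(10)
  sq <- col(11)
  sq[!is.na(sq) & (sq == "." | sq == "")] <- NA
  junction_set(col(1), e1, .strand_to_side(strand1),
               col(4), e2, .strand_to_side(strand2),
               name = name, seq = sq)
}

#' Write a junction set as BEDPE
#'
#' Inverse of [read_bedpe()]: breakends become 1-bp intervals `[pos-1, pos)`,
#' sides become strands, junction sequences go to column 11 (`.` when absent).
#'
#' @param junctions a `junction_set`.
#' @param path output path.
#' @export
write_bedpe <- function(junctions, path) {
  j <- junctions
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  df <- data.frame(j$chrom1, fmt(j$pos1 - 1), fmt(j$pos1),
                   j$chrom2, fmt(j$pos2 - 1), fmt(j$pos2),
                   j$name, 0L,
                   .side_to_strand(j$side1), .side_to_strand(j$side2),
                   ifelse(is.na(j$seq), ".", j$seq))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an analysis results table as TSV
#'
#' Tab-separated with a header row and deterministic column order;
#' round-trips through [read_results_table()].
#'
#' @param rows a `data.frame`.
#' @param path output path.
#' @export
write_results_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_results_table()]
#' @param path file path.
#' @return a `data.frame`.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a FASTA file as a named character vector
#' @param path file path.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write a named character vector of sequences as FASTA
#' @param genome named character vector.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}
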