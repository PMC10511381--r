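# Junction signature calling: blunt / microhomology / microinsertion.
#
# Microhomology length is defined as (number of valid split positions - 1):
# the junction sequence is aligned exactly to the reference context of each
# partner locus, letting the break position shift within the shared tract;
# the overlap of the two alignments on the junction is the ambiguity interval.
# 0 = blunt, > 0 = microhomology, < 0 = microinsertion of that length.

#' Reverse complement of a nucleotide string
#' @param x character vector of sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

#' Reference context around one breakend
#'
#' A context is a reference sequence oriented in junction reading direction
#' with a marked break offset: `break_at` bases precede the break. For the
#' first (A) partner the retained flank is `substr(seq, 1, break_at)`; for
#' the second (B) partner it is `substr(seq, break_at + 1, nchar(seq))`.
#'
#' @param seq nucleotide string.
#' @param break_at integer, number of bases before the break (0-based offset
#'   of the break within `seq`).
#' @return object of class `junction_context`.
#' @export
junction_context <- function(seq, break_at) {
  seq <- toupper(seq)
  stopifnot(is.character(seq), length(seq) == 1,
            break_at >= 0, break_at <= nchar(seq))
  structure(list(seq = seq, break_at = as.integer(break_at)),
            class = "junction_context")
}

# longest common prefix length of j (int codes) and s[o+1..] (int codes)
.lcp <- function(j, s, o) {
  k <- min(length(j), length(s) - o)
  if (k <= 0) return(0L)
  neq <- which(j[seq_len(k)] != s[o + seq_len(k)])
  if (length(neq)) neq[1] - 1L else k
}

# longest common suffix length of j and s[..e]
.lcs <- function(j, s, e) {
  k <- min(length(j), e)
  if (k <= 0) return(0L)
  neq <- which(j[length(j) + 1L - seq_len(k)] != s[e + 1L - seq_len(k)])
  if (length(neq)) neq[1] - 1L else k
}

.chars <- function(x) utf8ToInt(toupper(x))

#' Call the nucleotide-resolution signature of one junction
#'
#' Aligns the junction sequence exactly (no mismatches) to the two reference
#' contexts. The prefix of the junction is matched against context A ending
#' at (or shifted across) A's break; the suffix against context B starting at
#' (or shifted across) B's break. If the two alignments meet or overlap, the
#' overlap length is the microhomology (`signed_len >= 0`; the number of
#' valid split positions is `signed_len + 1`). If they leave a gap, the
#' uncovered middle of the junction is a microinsertion
#' (`signed_len = -length`).
#'
#' @param junction_seq observed sequence across the fusion; must carry at
#'   least `min_anchor` matching bases on each side.
#' @param context_a,context_b [junction_context()] objects oriented in
#'   junction reading direction (A's retained flank ends at its break, B's
#'   retained flank starts at its break).
#' @param min_anchor minimum exact anchor match per side (bp).
#' @return list of class `junction_signature` with `signed_len`,
#'   `insertion_seq` (empty unless `signed_len < 0`), `insertion_class`
#'   (`"not_applicable"` here; see [classify_insertion()]) and `n_splits`.
#' @export
call_signature <- function(junction_seq, context_a, context_b,
                           min_anchor = 10L) {
  stopifnot(inherits(context_a, "junction_context"),
            inherits(context_b, "junction_context"))
  j <- .chars(junction_seq)
  L <- length(j)
  sa <- .chars(context_a$seq); ba <- context_a$break_at
  sb <- .chars(context_b$seq); bb <- context_b$break_at
  # A: best alignment of a junction prefix starting at context offset o
  # (0-based), required to reach A's break (o + match >= ba, o <= ba).
  m_a <- 0L
  for (o in 0:ba) {
    m <- .lcp(j, sa, o)
    if (o + m >= ba && m > m_a) m_a <- m
  }
  anchor_a <- min(min_anchor, ba)
  if (m_a < anchor_a || m_a == 0L) {
    stop("unmappable junction: prefix does not anchor in context A")
  }
  # B: best alignment of a junction suffix ending at context offset e,
  # required to reach back to B's break (e - match <= bb, e >= bb).
  m_b <- 0L
  nb <- length(sb)
  for (e in bb:nb) {
    m <- .lcs(j, sb, e)
    if (e - m <= bb && m > m_b) m_b <- m
  }
  anchor_b <- min(min_anchor, nb - bb)
  if (m_b < anchor_b || m_b == 0L) {
    stop("unmappable junction: suffix does not anchor in context B")
  }
  if (m_a >= L && m_b >= L) {
    stop("ambiguous junction: both contexts cover the whole junction sequence")
  }
  h <- m_a + m_b - L
  if (h >= 0) {
    sig <- list(signed_len = as.integer(h), insertion_seq = "",
                insertion_class = "not_applicable",
                n_splits = as.integer(h + 1L))
  } else {
    ins <- substr(toupper(junction_seq), m_a + 1L, L - m_b)
    sig <- list(signed_len = -as.integer(nchar(ins)), insertion_seq = ins,
                insertion_class = "unknown_origin", n_splits = 0L)
  }
  class(sig) <- "junction_signature"
  sig
}

#' Classify the origin of a junction microinsertion
#'
#' Looks for an exact full-length copy of the insertion within
#' `search_radius` bp of either break: on the same strand (tandem repeat,
#' suggesting backward slippage) or as a reverse complement (inverted
#' repeat). Matches shorter than the full insertion do not count. When no
#' adjacent copy exists the origin is reported unknown; genome-wide origin
#' assignment of long insertions conventionally requires an alignment of at
#' least `min_genome_hit` bp (default 20) and is out of scope here.
#'
#' @param insertion_seq non-empty nucleotide string.
#' @param context_a,context_b [junction_context()] objects (junction
#'   orientation, as passed to [call_signature()]).
#' @param search_radius bp searched on each side of each break.
#' @param min_genome_hit documented threshold (bp) below which genome-wide
#'   hits would be disregarded; kept configurable for that extension.
#' @return one of `"tandem_repeat"`, `"inverted_repeat"`, `"unknown_origin"`.
#' @export
classify_insertion <- function(insertion_seq, context_a, context_b,
                               search_radius = 50L, min_genome_hit = 20L) {
  stopifnot(nchar(insertion_seq) > 0)
  ins <- toupper(insertion_seq)
  window <- function(ctx) {
    lo <- max(1L, ctx$break_at - search_radius + 1L)
    hi <- min(nchar(ctx$seq), ctx$break_at + search_radius)
    substr(ctx$seq, lo, hi)
  }
  wins <- c(window(context_a), window(context_b))
  if (any(vapply(wins, function(w) grepl(ins, w, fixed = TRUE), TRUE))) {
    return("tandem_repeat")
  }
  rc <- revcomp(ins)
  if (any(vapply(wins, function(w) grepl(rc, w, fixed = TRUE), TRUE))) {
    return("inverted_repeat")
  }
  "unknown_origin"
}

#' Extract junction-oriented reference contexts for a junction set
#'
#' For each junction, pulls `flank_len` bp either side of each breakend from
#' the genome and orients both contexts in junction reading direction (A's
#' retained flank ends at the break, B's starts at it), reverse-complementing
#' where the retained side requires it.
#'
#' @param junctions a `junction_set` with non-NA sides.
#' @param genome named character vector of chromosome sequences.
#' @param flank_len half-width of the extracted context (bp).
#' @return list with one element per junction: `list(a = , b = )` of
#'   [junction_context()] objects.
#' @export
extract_contexts <- function(junctions, genome, flank_len = 150L) {
  if (any(is.na(junctions$side1)) || any(is.na(junctions$side2))) {
    stop("junction strands/sides are missing; orientation-dependent context ",
         "extraction requires explicit sides (no silent default)")
  }
  one <- function(chrom, pos, side, role) {
    if (!chrom %in% names(genome)) {
      stop("breakend on chromosome absent from genome: ", chrom)
    }
    s <- genome[[chrom]]
    n <- nchar(s)
    lo <- max(0, pos - flank_len)
    hi <- min(n, pos + flank_len)
    seg <- substr(s, lo + 1, hi)       # covers [lo, hi), break at pos
    off <- pos - lo                    # bases before break within seg
    fwd <- (role == "a" && side == "left_retained") ||
      (role == "b" && side == "right_retained")
    if (fwd) {
      junction_context(seg, off)
    } else {
      junction_context(revcomp(seg), nchar(seg) - off)
    }
  }
  lapply(seq_len(nrow(junctions)), function(i) {
    list(a = one(junctions$chrom1[i], junctions$pos1[i],
                 junctions$side1[i], "a"),
         b = one(junctions$chrom2[i], junctions$pos2[i],
                 junctions$side2[i], "b"))
  })
}

#' Call signatures for a whole junction set
#'
#' @param junctions a `junction_set` with junction sequences in `$seq`.
#' @param genome named character vector (reference); used to extract contexts
#'   unless `contexts` is given.
#' @param contexts optional precomputed list as from [extract_contexts()].
#' @param flank_len context half-width (bp).
#' @param search_radius templated-insertion search radius (bp).
#' @param min_anchor minimum anchor match per side (bp).
#' @return `data.frame` with columns `name`, `signed_len`, `insertion_seq`,
#'   `insertion_class`, `n_splits`.
#' @export
call_signatures <- function(junctions, genome = NULL, contexts = NULL,
                            flank_len = 150L, search_radius = 50L,
                            min_anchor = 10L) {
  if (is.null(contexts)) {
    if (is.null(genome)) stop("either genome or contexts must be supplied")
    contexts <- extract_contexts(junctions, genome, flank_len = flank_len)
  }
  if (any(is.na(junctions$seq))) {
    stop("junction sequences missing for: ",
         paste(junctions$name[is.na(junctions$seq)], collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(junctions)), function(i) {
    sig <- call_signature(junctions$seq[i], contexts[[i]]$a,
                          contexts[[i]]$b, min_anchor = min_anchor)
    cls <- if (sig$signed_len < 0) {
      classify_insertion(sig$insertion_seq, contexts[[i]]$a, contexts[[i]]$b,
                         search_radius = search_radius)
    } else "not_applicable"
    data.frame(name = junctions$name[i], signed_len = sig$signed_len,
               insertion_seq = sig$insertion_seq, insertion_class = cls,
               n_splits = sig$n_splits, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Histogram of junction signatures
#'
#' Tabulates signed signature lengths (negative = microinsertion, 0 = blunt,
#' positive = microhomology); the table mirrors a junction-signature
#' histogram with counts summing to the number of inputs.
#'
#' @param signed_len integer vector (or data.frame with a `signed_len`
#'   column) of signatures.
#' @return `data.frame` with columns `signed_len` and `count`, sorted by
#'   `signed_len`.
#' @export
signature_histogram <- function(signed_len) {
  if (is.data.frame(signed_len)) signed_len <- signed_len$signed_len
  if (length(signed_len) == 0) {
    return(data.frame(signed_len = integer(), count = integer()))
  }
  tab <- table(signed_len)
  out <- data.frame(signed_len = as.integer(names(tab)),
                    count = as.integer(tab))
  out[order(out$signed_len), , drop = FALSE]
}

#' Classify junctions as intra- or inter-chromosomal rejoining
#'
#' Chromosome names are compared exactly; pairs that differ only by case are
#' still inter-chromosomal but trigger a warning, since that usually signals
#' inconsistent naming rather than a true translocation.
#'
#' @param junctions a `junction_set`.
#' @return character vector, `"intra_chromosomal"` or `"inter_chromosomal"`.
#' @export
classify_rejoining <- function(junctions) {
  same <- junctions$chrom1 == junctions$chrom2
  case_only <- !same & tolower(junctions$chrom1) == tolower(junctions$chrom2)
  if (any(case_only)) {
    warning("chromosome names differ only by case for junction(s): ",
            paste(junctions$name[case_only], collapse = ", "),
            "; treated as inter-chromosomal (exact matching)")
  }
  ifelse(same, "intra_chromosomal", "inter_chromosomal")
}

#' Breakends of a junction set in long format
#' @param junctions a `junction_set`.
#' @return `data.frame` with columns `chrom`, `pos`, `side`.
#' @export
breakends_of <- function(junctions) {
  data.frame(chrom = c(junctions$chrom1, junctions$chrom2),
             pos = c(junctions$pos1, junctions$pos2),
             side = c(junctions$side1, junctions$side2),
             stringsAsFactors = FALSE)
}

#' Breakpoint interval statistics
#'
#' Per chromosome, sorts the unique breakpoint positions and takes successive
#' differences (fragment sizes between DNA breaks); intervals are pooled
#' across chromosomes. Duplicate positions are collapsed with a warning.
#'
#' @param breakends `data.frame` with `chrom` and `pos` columns (e.g. from
#'   [breakends_of()]), or a `junction_set`.
#' @return list of class `interval_stats` with `intervals`, `median`,
#'   `quartiles` (25/75%), `n`.
#' @export
interval_stats <- function(breakends) {
  if (inherits(breakends, "junction_set")) {
    breakends <- breakends_of(breakends)
  }
  ndup <- 0L
  ints <- numeric()
  for (ch in unique(breakends$chrom)) {
    p <- breakends$pos[breakends$chrom == ch]
    ndup <- ndup + length(p) - length(unique(p))
    p <- sort(unique(p))
    if (length(p) >= 2) ints <- c(ints, diff(p))
  }
  if (ndup > 0) {
    warning(ndup, " duplicate breakend position(s) collapsed for interval ",
            "statistics")
  }
  if (length(ints) == 0) {
    out <- list(intervals = numeric(), median = NA_real_,
                quartiles = c(`25%` = NA_real_, `75%` = NA_real_), n = 0L)
  } else {
    out <- list(intervals = ints, median = stats::median(ints),
                quartiles = stats::quantile(ints, c(0.25, 0.75)),
                n = length(ints))
  }
  class(out) <- "interval_stats"
  out
}

#' @export
print.interval_stats <- function(x, ...) {
  if (x$n == 0) {
    cat("interval_stats: no intervals (fewer than 2 breakpoints per",
        "chromosome)\n")
  } else {
    cat(sprintf(
      "interval_stats: %d intervals, median %s bp (IQR %s-%s bp)\n",
      x$n, format(x$median, big.mark = ","),
      format(x$quartiles[[1]], big.mark = ","),
      format(x$quartiles[[2]], big.mark = ",")))
  }
  invisible(x)
}
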