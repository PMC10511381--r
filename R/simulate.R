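# Ground-truthed synthetic data: genomes, peak sets, chromothripsis-like
# rearrangements with a planted in-peak breakpoint enrichment, junction
# sequences with planted signatures, and paternal-origin trios.
#
# One pseudo-random stream per run: every stage reseeds deterministically
# from cfg$seed, so each emitted artifact is bit-reproducible.

.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage * 101) %% 2147483647)
}

.BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults describe a desk-scale analogue of a constitutional CCR study:
#' three 1-Mb chromosomes (three-way translocations involve three
#' chromosomes; real chromosomes are ~100x longer), ATAC-like peaks covering
#' 3% of the genome with mean width 600 bp, 20 breakpoints (observed cases
#' carry 4-40), a true in-peak risk ratio of 8 (the 1-kb window estimate in
#' sperm ATAC data is ~7.8), a 10% per-fragment deletion probability (only a
#' minority of fragments are lost), and a junction-signature distribution
#' with its mode at blunt joins and a tail of microinsertions.
#'
#' @param seed integer RNG seed (< 2^31).
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length (bp).
#' @param peak_fraction target genome fraction covered by peaks.
#' @param peak_len_mean mean peak length (bp).
#' @param true_rr planted risk ratio (>= 1) for breakpoints in peaks.
#' @param n_breaks number of breakpoints.
#' @param deletion_prob per-interstitial-fragment probability of loss.
#' @param signature_dist named probability vector over signed signature
#'   lengths (names are integers; negative = microinsertion length).
#' @param insertion_class_dist named probability vector over
#'   `tandem_repeat` / `inverted_repeat` / `unknown_origin` for insertions
#'   of length >= 5 (shorter insertions are always planted as adjacent
#'   tandem copies: an origin cannot be planted unambiguously below that).
#' @param genotype_error per-site probability that the derivative allele is
#'   replaced by a random other base.
#' @param n_sites_per_junction trio sites simulated near each breakend.
#' @param flank_len reference-context half-width used downstream (bp).
#' @param junction_flank bp of true flank carried on each side of emitted
#'   junction sequences (must be < `flank_len`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 3L,
                       chrom_len = 1e6,
                       peak_fraction = 0.03,
                       peak_len_mean = 600,
                       true_rr = 8,
                       n_breaks = 20L,
                       deletion_prob = 0.1,
                       signature_dist = NULL,
                       insertion_class_dist = c(tandem_repeat = 0.3,
                                                inverted_repeat = 0.2,
                                                unknown_origin = 0.5),
                       genotype_error = 0,
                       n_sites_per_junction = 3L,
                       flank_len = 150L,
                       junction_flank = 80L) {
  if (is.null(signature_dist)) {
    signature_dist <- c(`0` = 0.30, `1` = 0.20, `2` = 0.15, `3` = 0.10,
                        stats::setNames(rep(0.025, 10), as.character(-1:-10)))
  }
  stopifnot(seed == as.integer(seed), n_chroms >= 1, chrom_len > 1000,
            peak_fraction >= 0, peak_fraction < 1, peak_len_mean > 0,
            true_rr >= 1, n_breaks >= 0,
            deletion_prob >= 0, deletion_prob <= 1,
            genotype_error >= 0, genotype_error <= 1,
            junction_flank < flank_len, junction_flank >= 20)
  if (abs(sum(signature_dist) - 1) > 1e-8) {
    stop("signature_dist must sum to 1")
  }
  if (abs(sum(insertion_class_dist) - 1) > 1e-8) {
    stop("insertion_class_dist must sum to 1")
  }
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_len = chrom_len, peak_fraction = peak_fraction,
                 peak_len_mean = peak_len_mean, true_rr = true_rr,
                 n_breaks = as.integer(n_breaks),
                 deletion_prob = deletion_prob,
                 signature_dist = signature_dist,
                 insertion_class_dist = insertion_class_dist,
                 genotype_error = genotype_error,
                 n_sites_per_junction = as.integer(n_sites_per_junction),
                 flank_len = as.integer(flank_len),
                 junction_flank = as.integer(junction_flank)),
            class = "sim_config")
}

.sim_chrom_sizes <- function(cfg) {
  chrom_sizes(stats::setNames(rep(cfg$chrom_len, cfg$n_chroms),
                              paste0("chr", seq_len(cfg$n_chroms))))
}

#' Simulate a random genome
#'
#' I.i.d. uniform nucleotides; deterministic under the configured seed.
#'
#' @param cfg a `sim_config`.
#' @return list with `genome` (named character vector) and `chrom_sizes`.
#' @export
simulate_genome <- function(cfg) {
  set.seed(.stage_seed(cfg$seed, 1L))
  sizes <- .sim_chrom_sizes(cfg)
  genome <- vapply(names(sizes), function(ch) {
    paste(sample(.BASES, sizes[[ch]], replace = TRUE), collapse = "")
  }, "")
  list(genome = genome, chrom_sizes = sizes)
}

#' Simulate a peak set of controllable genome fraction
#'
#' Walks each chromosome alternating exponential gaps and exponential peak
#' lengths; the gap mean is set so the expected covered fraction equals
#' `peak_fraction`. Peaks are non-overlapping and non-bookended by
#' construction.
#'
#' @param cfg a `sim_config`.
#' @param chrom_sizes optional `chrom_sizes` (defaults to the configured
#'   genome).
#' @param label peak-set label.
#' @return a `peak_set`.
#' @export
simulate_peaks <- function(cfg, chrom_sizes = NULL, label = "sim_peaks") {
  set.seed(.stage_seed(cfg$seed, 2L))
  if (is.null(chrom_sizes)) chrom_sizes <- .sim_chrom_sizes(cfg)
  f <- cfg$peak_fraction
  if (f == 0) {
    return(peak_set(genome_intervals(character(), numeric(), numeric()),
                    label = label))
  }
  gap_mean <- cfg$peak_len_mean * (1 - f) / f
  rows <- list()
  for (ch in names(chrom_sizes)) {
    len <- unname(chrom_sizes[[ch]])
    pos <- 0
    repeat {
      pos <- pos + max(1, ceiling(stats::rexp(1, 1 / gap_mean)))
      plen <- max(20, ceiling(stats::rexp(1, 1 / cfg$peak_len_mean)))
      if (pos + plen >= len) break
      rows[[length(rows) + 1L]] <- data.frame(chrom = ch, start = pos,
                                              end = pos + plen,
                                              stringsAsFactors = FALSE)
      pos <- pos + plen
    }
  }
  iv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  peak_set(iv, label = label)
}

# complement of a peak set within chromosomes
.complement_intervals <- function(peaks, chrom_sizes) {
  iv <- merge_peaks(peaks)$intervals
  rows <- lapply(names(chrom_sizes), function(ch) {
    len <- unname(chrom_sizes[[ch]])
    d <- iv[iv$chrom == ch, , drop = FALSE]
    bounds <- c(0, as.vector(rbind(d$start, d$end)), len)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- starts < ends
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# uniform draw of n positions within a set of intervals (0-based, in [start,end))
.sample_in_intervals <- function(iv, n) {
  if (n == 0 || nrow(iv) == 0) {
    return(data.frame(chrom = character(), pos = numeric()))
  }
  w <- iv$end - iv$start
  pick <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
  off <- floor(stats::runif(n) * w[pick])
  data.frame(chrom = iv$chrom[pick], pos = iv$start[pick] + off,
             stringsAsFactors = FALSE)
}

#' Simulate breakpoints with a planted in-peak enrichment
#'
#' Positions follow a two-rate density proportional to `true_rr` inside
#' peaks and 1 outside, so with covered fraction f the expected in-peak
#' fraction is `true_rr * f / (true_rr * f + (1 - f))`. Positions are
#' distinct and strictly inside chromosomes.
#'
#' @param cfg a `sim_config`.
#' @param peaks a `peak_set` (e.g. from [simulate_peaks()]).
#' @param chrom_sizes optional `chrom_sizes`.
#' @return `data.frame` with `chrom`, `pos` and an `in_peak` attribute
#'   (logical vector).
#' @export
simulate_breakpoints <- function(cfg, peaks, chrom_sizes = NULL) {
  set.seed(.stage_seed(cfg$seed, 3L))
  if (is.null(chrom_sizes)) chrom_sizes <- .sim_chrom_sizes(cfg)
  n <- cfg$n_breaks
  if (n == 0) {
    out <- data.frame(chrom = character(), pos = numeric())
    attr(out, "in_peak") <- logical()
    return(out)
  }
  merged <- merge_peaks(peaks)
  covered <- total_bp(merged)
  total <- sum(as.numeric(chrom_sizes))
  p_in <- if (covered == 0) 0 else {
    cfg$true_rr * covered / (cfg$true_rr * covered + (total - covered))
  }
  comp <- .complement_intervals(merged, chrom_sizes)
  draw <- function(k) {
    flags <- stats::runif(k) < p_in
    pin <- .sample_in_intervals(merged$intervals, sum(flags))
    pout <- .sample_in_intervals(comp, sum(!flags))
    pin$in_peak <- rep(TRUE, nrow(pin))
    pout$in_peak <- rep(FALSE, nrow(pout))
    df <- rbind(pin, pout)
    df[df$pos > 0 & df$pos < chrom_sizes[df$chrom], , drop = FALSE]
  }
  out <- draw(n)
  out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
  while (nrow(out) < n) {
    out <- rbind(out, draw(n - nrow(out)))
    out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  flags <- out$in_peak
  out$in_peak <- NULL
  attr(out, "in_peak") <- flags
  out
}

# is the junction between oriented fragments x and y a religation (the two
# flanks are the same locus, which would make the junction signature
# degenerate)?
.is_religation <- function(x, y) {
  x$chrom == y$chrom &&
    ((x$orientation == "forward" && y$orientation == "forward" &&
        x$end == y$start) ||
       (x$orientation == "inverted" && y$orientation == "inverted" &&
          y$end == x$start))
}

#' Simulate a chromothripsis-like rearrangement
#'
#' Fragments every chromosome carrying a breakpoint, drops each interstitial
#' fragment with `deletion_prob`, and reassembles the remainder into
#' telomere-to-telomere derivative chromosomes: each involved chromosome
#' contributes its p-terminal fragment to one derivative (forward), the
#' q-terminal fragments are permuted across derivatives, and surviving
#' interstitial fragments are shuffled in between with random orientation.
#' No fragment is ever duplicated, so the process cannot create copy-number
#' gains. Junctions are emitted consistent with the derivative order;
#' religation joins (which would be invisible at the sequence level) are
#' avoided by resampling the arrangement.
#'
#' @param cfg a `sim_config`.
#' @param breakends `data.frame` with `chrom`, `pos` (e.g. from
#'   [simulate_breakpoints()]).
#' @param chrom_sizes optional `chrom_sizes`.
#' @return list of class `sim_truth`: `derivatives` (as in a
#'   `derivative_set`), `junctions` (a `junction_set`, without sequences
#'   yet), `deleted` (fragment data.frame), `fragments` (all fragments of
#'   involved chromosomes), `involved` (chromosome names).
#' @export
simulate_rearrangement <- function(cfg, breakends, chrom_sizes = NULL) {
  set.seed(.stage_seed(cfg$seed, 4L))
  if (is.null(chrom_sizes)) chrom_sizes <- .sim_chrom_sizes(cfg)
  involved <- sort(unique(breakends$chrom))
  if (length(involved) == 0) {
    return(structure(list(derivatives = list(),
                          junctions = junction_set(character(), numeric(),
                                                   character(), character(),
                                                   numeric(), character()),
                          deleted = NULL, fragments = NULL,
                          involved = character()),
                     class = "sim_truth"))
  }
  if (length(involved) == 1 &&
      length(unique(breakends$pos[breakends$chrom == involved])) < 2) {
    stop("a rearrangement of a single chromosome needs at least 2 breakpoints")
  }
  sub_sizes <- chrom_sizes(stats::setNames(
    as.numeric(chrom_sizes[involved]), involved))
  fragments <- fragment_genome(sub_sizes, breakends)
  k <- length(involved)
  p_idx <- vapply(involved, function(ch) {
    which(fragments$chrom == ch & fragments$start == 0)
  }, 0L)
  q_idx <- vapply(involved, function(ch) {
    which(fragments$chrom == ch &
            fragments$end == sub_sizes[[ch]])
  }, 0L)
  inter_idx <- setdiff(seq_len(nrow(fragments)), c(p_idx, q_idx))
  dropped <- inter_idx[stats::runif(length(inter_idx)) < cfg$deletion_prob]
  surviving <- setdiff(inter_idx, dropped)
  build <- function() {
    qp <- sample.int(k)
    mid <- surviving[sample.int(length(surviving))]
    assign_to <- if (length(mid)) sample.int(k, length(mid), replace = TRUE)
    else integer()
    lapply(seq_len(k), function(i) {
      ids <- c(p_idx[i], mid[assign_to == i], q_idx[qp[i]])
      orient <- c("forward",
                  sample(c("forward", "inverted"),
                         sum(assign_to == i), replace = TRUE),
                  "forward")
      d <- fragments[ids, , drop = FALSE]
      d$orientation <- orient
      rownames(d) <- NULL
      d
    })
  }
  ok <- FALSE
  for (try in 1:1000) {
    ders <- build()
    bad <- any(vapply(ders, function(d) {
      nrow(d) > 1 && any(vapply(seq_len(nrow(d) - 1), function(r) {
        .is_religation(d[r, ], d[r + 1, ])
      }, TRUE))
    }, TRUE))
    if (!bad) { ok <- TRUE; break }
  }
  if (!ok) stop("could not arrange fragments without a religation join")
  names(ders) <- paste0("der(", involved, ")")
  # junctions between consecutive oriented fragments
  jrows <- list()
  for (d in ders) {
    if (nrow(d) < 2) next
    for (r in seq_len(nrow(d) - 1)) {
      x <- d[r, ]; y <- d[r + 1, ]
      if (x$orientation == "forward") {
        b1 <- list(chrom = x$chrom, pos = x$end, side = "left_retained")
      } else {
        b1 <- list(chrom = x$chrom, pos = x$start, side = "right_retained")
      }
      if (y$orientation == "forward") {
        b2 <- list(chrom = y$chrom, pos = y$start, side = "right_retained")
      } else {
        b2 <- list(chrom = y$chrom, pos = y$end, side = "left_retained")
      }
      jrows[[length(jrows) + 1L]] <- data.frame(
        chrom1 = b1$chrom, pos1 = b1$pos, side1 = b1$side,
        chrom2 = b2$chrom, pos2 = b2$pos, side2 = b2$side,
        stringsAsFactors = FALSE)
    }
  }
  jdf <- do.call(rbind, jrows)
  junctions <- if (is.null(jdf)) {
    junction_set(character(), numeric(), character(),
                 character(), numeric(), character())
  } else {
    junction_set(jdf$chrom1, jdf$pos1, jdf$side1,
                 jdf$chrom2, jdf$pos2, jdf$side2)
  }
  deleted <- fragments[dropped, , drop = FALSE]
  rownames(deleted) <- NULL
  structure(list(derivatives = ders, junctions = junctions,
                 deleted = deleted, fragments = fragments,
                 involved = involved),
            class = "sim_truth")
}

# ---- junction-sequence planting -------------------------------------------

# helpers translating between junction-oriented flank indices and genome
# coordinates (1-based string positions). A-part index runs 1..fa with fa
# adjacent to the break; B-part index runs 1..fb with 1 adjacent to the break.
.get_A_part <- function(g, p, side, fa) {
  if (side == "left_retained") substr(g, p - fa + 1, p)
  else revcomp(substr(g, p + 1, p + fa))
}
.get_B_part <- function(g, p, side, fb) {
  if (side == "right_retained") substr(g, p + 1, p + fb)
  else revcomp(substr(g, p - fb + 1, p))
}
.set_A_char <- function(g, p, side, fa, i, v) {
  if (side == "left_retained") substr(g, p - fa + i, p - fa + i) <- v
  else substr(g, p + fa + 1 - i, p + fa + 1 - i) <- revcomp(v)
  g
}
.set_B_char <- function(g, p, side, i, v) {
  if (side == "right_retained") substr(g, p + i, p + i) <- v
  else substr(g, p - i + 1, p - i + 1) <- revcomp(v)
  g
}
.cont_after_A <- function(g, p, side) {
  if (side == "left_retained") substr(g, p + 1, p + 1)
  else revcomp(substr(g, p, p))
}
.cont_before_B <- function(g, p, side) {
  if (side == "right_retained") substr(g, p, p)
  else revcomp(substr(g, p + 1, p + 1))
}
.other_base <- function(...) {
  avoid <- toupper(unlist(list(...)))
  sample(setdiff(.BASES, avoid), 1)
}

# the two classify_insertion search windows (junction-oriented, +/- radius
# around each break) as they would be seen at analysis time
.analysis_windows <- function(genome, c1, p1, s1, c2, p2, s2, radius) {
  win <- function(ch, p, fwd) {
    g <- genome[[ch]]
    seg <- substr(g, max(1, p - radius + 1), min(nchar(g), p + radius))
    if (fwd) seg else revcomp(seg)
  }
  c(win(c1, p1, s1 == "left_retained"),
    win(c2, p2, s2 == "right_retained"))
}

#' Realize junction sequences with planted signatures
#'
#' For each junction, draws a signed signature length from the configured
#' distribution and locally edits the genome so that the realized signature
#' is exactly the planted one: for microhomology h, the first h retained
#' bases of partner B are overwritten with the last h retained bases of
#' partner A; for microinsertions, the inserted bases are an adjacent tandem
#' copy (partner B's retained start), an adjacent inverted copy (written
#' into partner A's retained flank), or a random sequence verified absent
#' near both breaks (unknown origin). Because junction flanks meet across
#' shared break positions, the single-base guards that stop the alignment
#' ambiguity from extending past the planted tract are iterated to a fixed
#' point over all junctions before the sequences are emitted. Insertions
#' shorter than 5 bp are always planted as tandem copies (an origin cannot
#' be planted unambiguously below that).
#'
#' @param truth a `sim_truth` from [simulate_rearrangement()].
#' @param genome named character vector (will be edited and returned).
#' @param cfg a `sim_config`.
#' @return list: `junctions` (the truth junctions with a `seq` column),
#'   `signatures` (truth data.frame: `name`, `signed_len`, `insertion_seq`,
#'   `insertion_class`), `genome` (edited).
#' @export
realize_junction_sequences <- function(truth, genome, cfg) {
  set.seed(.stage_seed(cfg$seed, 5L))
  jn <- truth$junctions
  empty_sig <- data.frame(name = character(), signed_len = integer(),
                          insertion_seq = character(),
                          insertion_class = character())
  if (nrow(jn) == 0) {
    return(list(junctions = jn, signatures = empty_sig, genome = genome))
  }
  all_pos <- breakends_of(jn)
  jw <- cfg$junction_flank
  radius <- 50L
  sig_vals <- as.integer(names(cfg$signature_dist))
  gap <- function(ch, p) {
    # clip flanks so edits cannot collide with another junction's flanks
    others <- all_pos$pos[all_pos$chrom == ch & all_pos$pos != p]
    lim <- min(c(abs(others - p), p,
                 unname(nchar(genome[[ch]])) - p)) - 1
    max(20L, min(jw, lim))
  }
  rand_ins <- function(m) {
    paste(sample(.BASES, m, replace = TRUE), collapse = "")
  }
  # phase 1: draw signatures, plant homology tracts and inverted templates
  plan <- vector("list", nrow(jn))
  for (i in seq_len(nrow(jn))) {
    c1 <- jn$chrom1[i]; p1 <- jn$pos1[i]; s1 <- jn$side1[i]
    c2 <- jn$chrom2[i]; p2 <- jn$pos2[i]; s2 <- jn$side2[i]
    fa <- gap(c1, p1); fb <- gap(c2, p2)
    planted <- sample(sig_vals, 1, prob = cfg$signature_dist)
    if (planted >= 0) {
      h <- planted
      if (h >= fa || h + 1 > fb) h <- 0L  # no room; degrade to blunt
      if (h > 0) {
        H <- strsplit(substr(.get_A_part(genome[[c1]], p1, s1, fa),
                             fa - h + 1, fa), "")[[1]]
        for (t in seq_len(h)) {
          genome[[c2]] <- .set_B_char(genome[[c2]], p2, s2, t, H[t])
        }
      }
      plan[[i]] <- list(type = "hom", h = h, fa = fa, fb = fb)
    } else {
      m <- min(-planted, fa - 1L, fb - 1L)
      cls <- if (m < 5) "tandem_repeat" else {
        sample(names(cfg$insertion_class_dist), 1,
               prob = cfg$insertion_class_dist)
      }
      if (cls == "inverted_repeat") {
        # write an inverted copy of the (future) insertion into A's flank
        cand <- rand_ins(m)
        rc <- strsplit(revcomp(cand), "")[[1]]
        for (t in seq_len(m)) {
          genome[[c1]] <- .set_A_char(genome[[c1]], p1, s1, fa,
                                      fa - m + t, rc[t])
        }
      }
      ins <- if (cls == "unknown_origin") rand_ins(m) else NULL
      plan[[i]] <- list(type = "ins", cls = cls, m = m, fa = fa, fb = fb,
                        ins = ins)
    }
  }
  # phase 2: single-base guards, iterated to a fixed point (edits near one
  # break can invalidate guards of the junction sharing that position)
  for (pass in 1:12) {
    changed <- FALSE
    for (i in seq_len(nrow(jn))) {
      c1 <- jn$chrom1[i]; p1 <- jn$pos1[i]; s1 <- jn$side1[i]
      c2 <- jn$chrom2[i]; p2 <- jn$pos2[i]; s2 <- jn$side2[i]
      pl <- plan[[i]]
      fa <- pl$fa; fb <- pl$fb
      caN <- .cont_after_A(genome[[c1]], p1, s1)
      cbP <- .cont_before_B(genome[[c2]], p2, s2)
      if (pl$type == "hom") {
        h <- pl$h
        bpart <- .get_B_part(genome[[c2]], p2, s2, fb)
        if (substr(bpart, h + 1, h + 1) == caN) {
          genome[[c2]] <- .set_B_char(genome[[c2]], p2, s2, h + 1L,
                                      .other_base(caN))
          changed <- TRUE
        }
        apart <- .get_A_part(genome[[c1]], p1, s1, fa)
        if (substr(apart, fa - h, fa - h) == cbP) {
          genome[[c1]] <- .set_A_char(genome[[c1]], p1, s1, fa, fa - h,
                                      .other_base(cbP))
          changed <- TRUE
        }
      } else if (pl$cls == "tandem_repeat") {
        m <- pl$m
        bpart <- .get_B_part(genome[[c2]], p2, s2, fb)
        b1_bad <- if (m == 1) substr(bpart, 1, 1) %in% c(caN, cbP)
        else substr(bpart, 1, 1) == caN
        if (b1_bad) {
          genome[[c2]] <- .set_B_char(
            genome[[c2]], p2, s2, 1L,
            if (m == 1) .other_base(caN, cbP) else .other_base(caN))
          changed <- TRUE
        }
        bpart <- .get_B_part(genome[[c2]], p2, s2, fb)
        if (m > 1 && substr(bpart, m, m) == cbP) {
          genome[[c2]] <- .set_B_char(genome[[c2]], p2, s2, m,
                                      .other_base(cbP))
          changed <- TRUE
        }
      } else if (pl$cls == "inverted_repeat") {
        m <- pl$m
        apart <- .get_A_part(genome[[c1]], p1, s1, fa)
        ins <- revcomp(substr(apart, fa - m + 1, fa))
        if (substr(ins, 1, 1) == caN) {  # ins[1] = complement(apart[fa])
          genome[[c1]] <- .set_A_char(genome[[c1]], p1, s1, fa, fa,
                                      .other_base(revcomp(caN)))
          changed <- TRUE
        }
        apart <- .get_A_part(genome[[c1]], p1, s1, fa)
        ins <- revcomp(substr(apart, fa - m + 1, fa))
        if (substr(ins, m, m) == cbP) {
          genome[[c1]] <- .set_A_char(genome[[c1]], p1, s1, fa, fa - m + 1,
                                      .other_base(revcomp(cbP)))
          changed <- TRUE
        }
        # a chance same-strand copy nearby would reclassify it as tandem
        ins <- revcomp(substr(.get_A_part(genome[[c1]], p1, s1, fa),
                              fa - m + 1, fa))
        wins <- .analysis_windows(genome, c1, p1, s1, c2, p2, s2, radius)
        if (any(grepl(ins, wins, fixed = TRUE)) ||
            ins == revcomp(ins)) {
          rc <- strsplit(revcomp(rand_ins(m)), "")[[1]]
          for (t in seq_len(m)) {
            genome[[c1]] <- .set_A_char(genome[[c1]], p1, s1, fa,
                                        fa - m + t, rc[t])
          }
          changed <- TRUE
        }
      } else {  # unknown_origin
        m <- pl$m
        ins <- plan[[i]]$ins
        wins <- .analysis_windows(genome, c1, p1, s1, c2, p2, s2, radius)
        bad <- substr(ins, 1, 1) == caN ||
          (m > 1 && substr(ins, m, m) == cbP) ||
          any(grepl(ins, wins, fixed = TRUE)) ||
          any(grepl(revcomp(ins), wins, fixed = TRUE))
        if (bad) {
          plan[[i]]$ins <- rand_ins(m)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # phase 3: emit sequences and truth from the final genome
  seqs <- character(nrow(jn))
  sigs <- vector("list", nrow(jn))
  for (i in seq_len(nrow(jn))) {
    c1 <- jn$chrom1[i]; p1 <- jn$pos1[i]; s1 <- jn$side1[i]
    c2 <- jn$chrom2[i]; p2 <- jn$pos2[i]; s2 <- jn$side2[i]
    pl <- plan[[i]]
    apart <- .get_A_part(genome[[c1]], p1, s1, pl$fa)
    bpart <- .get_B_part(genome[[c2]], p2, s2, pl$fb)
    if (pl$type == "hom") {
      seqs[i] <- paste0(apart, substr(bpart, pl$h + 1, pl$fb))
      sigs[[i]] <- data.frame(name = jn$name[i],
                              signed_len = as.integer(pl$h),
                              insertion_seq = "",
                              insertion_class = "not_applicable",
                              stringsAsFactors = FALSE)
    } else {
      ins <- switch(pl$cls,
                    tandem_repeat = substr(bpart, 1, pl$m),
                    inverted_repeat = revcomp(substr(apart,
                                                     pl$fa - pl$m + 1,
                                                     pl$fa)),
                    unknown_origin = pl$ins)
      seqs[i] <- paste0(apart, ins, bpart)
      sigs[[i]] <- data.frame(name = jn$name[i],
                              signed_len = -as.integer(pl$m),
                              insertion_seq = ins,
                              insertion_class = pl$cls,
                              stringsAsFactors = FALSE)
    }
  }
  jn$seq <- seqs
  list(junctions = jn, signatures = do.call(rbind, sigs), genome = genome)
}

#' Simulate trio genotypes with planted paternal origin
#'
#' Generates SNV-like sites near each junction breakend; the derivative
#' haplotype always carries a paternal allele, and with probability
#' `genotype_error` the observed derivative allele is replaced by a random
#' other base.
#'
#' @param truth a `sim_truth`.
#' @param cfg a `sim_config`.
#' @return list: `sites` (data.frame `chrom`, `pos`, `der_allele`,
#'   `father_gt`, `mother_gt`), `flipped` (logical truth vector).
#' @export
simulate_trio <- function(truth, cfg) {
  set.seed(.stage_seed(cfg$seed, 6L))
  be <- breakends_of(truth$junctions)
  if (nrow(be) == 0) {
    return(list(sites = data.frame(chrom = character(), pos = numeric(),
                                   der_allele = character(),
                                   father_gt = character(),
                                   mother_gt = character()),
                flipped = logical()))
  }
  rows <- list()
  flipped <- logical()
  for (i in seq_len(nrow(be))) {
    offs <- sample.int(500, cfg$n_sites_per_junction)
    pos <- if (be$side[i] == "left_retained") be$pos[i] - offs
    else be$pos[i] + offs
    for (p in pos) {
      f <- sample(.BASES, 2, replace = TRUE)
      m <- sample(.BASES, 2, replace = TRUE)
      der <- sample(f, 1)
      flip <- stats::runif(1) < cfg$genotype_error
      if (flip) der <- sample(setdiff(.BASES, der), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = be$chrom[i], pos = p, der_allele = der,
        father_gt = paste(f, collapse = "/"),
        mother_gt = paste(m, collapse = "/"), stringsAsFactors = FALSE)
      flipped <- c(flipped, flip)
    }
  }
  sites <- do.call(rbind, rows)
  ord <- order(sites$chrom, sites$pos)
  list(sites = sites[ord, , drop = FALSE], flipped = flipped[ord])
}

#' Run the full synthetic-data generator
#'
#' Chains genome, peaks, breakpoints, rearrangement, junction-sequence
#' planting and trio simulation; everything is reproducible from
#' `cfg$seed`.
#'
#' @param cfg a `sim_config`.
#' @return list of class `ccr_simulation`: `config`, `genome`,
#'   `chrom_sizes`, `peaks`, `breakends` (with `in_peak` attribute),
#'   `junctions` (with sequences), `truth` (derivatives, deleted fragments,
#'   fragments, signatures, trio flips, realized in-peak count), `trio`
#'   (site table).
#' @export
simulate_ccr <- function(cfg) {
  g <- simulate_genome(cfg)
  peaks <- simulate_peaks(cfg, g$chrom_sizes)
  breakends <- simulate_breakpoints(cfg, peaks, g$chrom_sizes)
  rearr <- simulate_rearrangement(cfg, breakends, g$chrom_sizes)
  real <- realize_junction_sequences(rearr, g$genome, cfg)
  trio <- simulate_trio(rearr, cfg)
  structure(list(
    config = cfg, genome = real$genome, chrom_sizes = g$chrom_sizes,
    peaks = peaks, breakends = breakends, junctions = real$junctions,
    truth = list(derivatives = rearr$derivatives, deleted = rearr$deleted,
                 fragments = rearr$fragments, involved = rearr$involved,
                 signatures = real$signatures, trio_flipped = trio$flipped,
                 n_in_peak = sum(attr(breakends, "in_peak"))),
    trio = trio$sites), class = "ccr_simulation")
}

#' Write a simulation to disk
#'
#' Emits `genome.fa`, `genome.chrom.sizes`, `peaks.bed`,
#' `junctions.bedpe` (sequence in column 11), `trio.tsv` and `truth.json`;
#' all files re-parse with the package readers into objects equal to the
#' in-memory simulation.
#'
#' @param sim a `ccr_simulation`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    peaks = file.path(dir, "peaks.bed"),
    junctions = file.path(dir, "junctions.bedpe"),
    trio = file.path(dir, "trio.tsv"),
    truth = file.path(dir, "truth.json"))
  write_fasta(sim$genome, paths[["genome"]])
  write_chrom_sizes(sim$chrom_sizes, paths[["chrom_sizes"]])
  write_bed(sim$peaks, paths[["peaks"]])
  write_bedpe(sim$junctions, paths[["junctions"]])
  write_results_table(sim$trio, paths[["trio"]])
  truth <- list(
    seed = sim$config$seed,
    signatures = sim$truth$signatures,
    derivatives = lapply(sim$truth$derivatives, function(d) {
      d[, c("chrom", "start", "end", "orientation")]
    }),
    deleted = sim$truth$deleted,
    involved = sim$truth$involved,
    n_in_peak = sim$truth$n_in_peak,
    breakends = sim$breakends)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
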