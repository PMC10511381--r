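# Derivative-chromosome reconstruction from a junction set.
#
# Model: nodes are fragment ends (L = genomic start boundary, R = genomic end
# boundary). Each fragment contributes an internal edge between its two ends;
# each junction pairs two ends according to the retained-side flags. A
# derivative is a maximal telomere-to-telomere walk alternating fragment and
# junction edges, using each fragment at most once. Because one end can carry
# at most one junction, walks are deterministic.

#' Fragment chromosomes at breakend positions
#'
#' Each chromosome with k distinct break positions yields k+1 fragments that
#' tile `[0, length)` exactly. Duplicate positions are deduplicated.
#'
#' @param chrom_sizes a `chrom_sizes` object.
#' @param breakends `data.frame` with `chrom`, `pos` columns, or a
#'   `junction_set`.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `id`
#'   (`chrom:start-end`).
#' @export
fragment_genome <- function(chrom_sizes, breakends) {
  if (inherits(breakends, "junction_set")) {
    breakends <- breakends_of(breakends)
  }
  unknown <- setdiff(unique(breakends$chrom), names(chrom_sizes))
  if (length(unknown)) {
    stop("breakend on unknown chromosome: ", paste(unknown, collapse = ", "))
  }
  rows <- lapply(names(chrom_sizes), function(ch) {
    len <- unname(chrom_sizes[[ch]])
    p <- sort(unique(breakends$pos[breakends$chrom == ch]))
    if (any(p <= 0 | p >= len)) {
      stop(sprintf("breakend position not strictly inside chromosome %s", ch))
    }
    bounds <- c(0, p, len)
    data.frame(chrom = ch, start = bounds[-length(bounds)], end = bounds[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$id <- sprintf("%s:%s-%s", out$chrom,
                    format(out$start, scientific = FALSE, trim = TRUE),
                    format(out$end, scientific = FALSE, trim = TRUE))
  rownames(out) <- NULL
  out
}

# map one breakend to a fragment-end node; returns list(idx, end)
.breakend_node <- function(fragments, chrom, pos, side, tol = 0) {
  if (side == "left_retained") {
    hit <- which(fragments$chrom == chrom & abs(fragments$end - pos) <= tol)
    end <- "R"
  } else {
    hit <- which(fragments$chrom == chrom & abs(fragments$start - pos) <= tol)
    end <- "L"
  }
  if (length(hit) != 1) {
    stop(sprintf("junction breakend %s:%s (%s) not resolvable to a fragment boundary",
                 chrom, format(pos, scientific = FALSE), side))
  }
  list(idx = hit, end = end)
}

#' Assemble derivative chromosomes from fragments and junctions
#'
#' Walks the fragment-end graph from telomeric free ends. Every walk starts
#' and should end at a telomere; fragments on no walk are unplaced (deleted).
#' The output is canonical: derivatives are discovered from p-telomeres in
#' chromosome order first, then remaining q-telomeres, and named after the
#' chromosome of their first (terminal) fragment, mirroring der() usage.
#'
#' `ambiguous` is set when the decomposition is under-determined: some
#' junction was never used (a junction cycle with no telomere) or a walk
#' ended at a non-telomeric free end.
#'
#' @param fragments from [fragment_genome()].
#' @param junctions a `junction_set` with non-NA sides whose breakends
#'   coincide with fragment boundaries (within `tol` bp).
#' @param chrom_sizes a `chrom_sizes` object.
#' @param tol snap tolerance in bp (default 0: exact, since junctions and
#'   fragments normally derive from the same call set).
#' @return list of class `derivative_set`: `derivatives` (named list of
#'   data.frames with `chrom`, `start`, `end`, `id`, `orientation`),
#'   `unplaced` (fragment data.frame), `ambiguous` (flag),
#'   `junctions_used` (count).
#' @export
assemble_derivatives <- function(fragments, junctions, chrom_sizes, tol = 0) {
  nfrag <- nrow(fragments)
  if (nrow(junctions) > 0 &&
      (any(is.na(junctions$side1)) || any(is.na(junctions$side2)))) {
    stop("junction sides are missing; assembly requires explicit ",
         "retained-side flags (no silent default)")
  }
  # junction edges: partner[node] and junction index per node
  partner <- new.env(parent = emptyenv())
  node_key <- function(n) paste0(n$idx, ".", n$end)
  for (i in seq_len(nrow(junctions))) {
    n1 <- .breakend_node(fragments, junctions$chrom1[i], junctions$pos1[i],
                         junctions$side1[i], tol)
    n2 <- .breakend_node(fragments, junctions$chrom2[i], junctions$pos2[i],
                         junctions$side2[i], tol)
    for (k in c(node_key(n1), node_key(n2))) {
      if (!is.null(partner[[k]])) {
        stop("conflicting junction: breakend side ", k,
             " used by more than one junction (", junctions$name[i], ")")
      }
    }
    partner[[node_key(n1)]] <- list(node = n2, junction = i)
    partner[[node_key(n2)]] <- list(node = n1, junction = i)
  }
  chrom_len <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  is_telomeric <- function(idx, end) {
    if (end == "L") fragments$start[idx] == 0
    else fragments$end[idx] == chrom_len[[fragments$chrom[idx]]]
  }
  used_frag <- logical(nfrag)
  used_junc <- logical(nrow(junctions))
  ambiguous <- FALSE
  walk <- function(start_idx, start_end) {
    parts <- list()
    idx <- start_idx; entry <- start_end
    repeat {
      if (used_frag[idx]) stop("internal error: fragment reused")
      used_frag[idx] <<- TRUE
      orient <- if (entry == "L") "forward" else "inverted"
      parts[[length(parts) + 1L]] <-
        cbind(fragments[idx, , drop = FALSE],
              data.frame(orientation = orient, stringsAsFactors = FALSE))
      exit <- if (entry == "L") "R" else "L"
      link <- partner[[paste0(idx, ".", exit)]]
      if (is.null(link) || used_junc[link$junction]) {
        if (!is_telomeric(idx, exit)) ambiguous <<- TRUE
        break
      }
      used_junc[link$junction] <<- TRUE
      idx <- link$node$idx; entry <- link$node$end
    }
    df <- do.call(rbind, parts)
    rownames(df) <- NULL
    df
  }
  # telomeric free ends, p-arms first, chromosome order
  starts_p <- which(fragments$start == 0)
  starts_p <- starts_p[order(fragments$chrom[starts_p])]
  starts_q <- which(fragments$end == chrom_len[fragments$chrom])
  starts_q <- starts_q[order(fragments$chrom[starts_q])]
  derivatives <- list()
  start_nodes <- c(lapply(starts_p, function(i) list(idx = i, end = "L")),
                   lapply(starts_q, function(i) list(idx = i, end = "R")))
  for (sn in start_nodes) {
    idx <- sn$idx; end <- sn$end
    if (used_frag[idx]) next
    if (!is.null(partner[[paste0(idx, ".", end)]])) next  # not a free end
    d <- walk(idx, end)
    nm <- paste0("der(", d$chrom[1], ")")
    if (nm %in% names(derivatives)) {
      nm <- paste0(nm, ".", sum(startsWith(names(derivatives), nm)) + 1L)
    }
    derivatives[[nm]] <- d
  }
  if (any(!used_junc)) ambiguous <- TRUE
  derivatives <- derivatives[order(names(derivatives))]
  unplaced <- fragments[!used_frag, , drop = FALSE]
  rownames(unplaced) <- NULL
  structure(list(derivatives = derivatives, unplaced = unplaced,
                 ambiguous = ambiguous, junctions_used = sum(used_junc)),
            class = "derivative_set")
}

#' @export
print.derivative_set <- function(x, ...) {
  cat(sprintf("derivative_set: %d derivative(s), %d unplaced fragment(s)%s\n",
              length(x$derivatives), nrow(x$unplaced),
              if (x$ambiguous) ", AMBIGUOUS" else ""))
  for (nm in names(x$derivatives)) {
    d <- x$derivatives[[nm]]
    cat(" ", nm, ": ",
        paste0(d$id, ifelse(d$orientation == "inverted", "'", ""),
               collapse = " - "), "\n", sep = "")
  }
  invisible(x)
}

#' Flatten a derivative set to a structure table
#'
#' @param x a `derivative_set`.
#' @param ... unused.
#' @return `data.frame` with columns `derivative`, `order`, `chrom`,
#'   `start`, `end`, `orientation`.
#' @export
as.data.frame.derivative_set <- function(x, ...) {
  rows <- lapply(names(x$derivatives), function(nm) {
    d <- x$derivatives[[nm]]
    data.frame(derivative = nm, order = seq_len(nrow(d)), chrom = d$chrom,
               start = d$start, end = d$end, orientation = d$orientation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(derivative = character(), order = integer(),
                      chrom = character(), start = numeric(),
                      end = numeric(), orientation = character())
  }
  rownames(out) <- NULL
  out
}

#' Copy-number accounting over an assembly
#'
#' Tallies how often each fragment was placed across all derivatives.
#' Fragments with count 0 are losses, count >= 2 gains; only events of at
#' least `min_report_len` bp are reported (the conventional microarray
#' reporting threshold is 50 kb), but the full accounting is returned too.
#'
#' @param assembly a `derivative_set`.
#' @param fragments the fragment table given to [assemble_derivatives()].
#' @param min_report_len minimum reported event length (bp).
#' @return list of class `copy_number_report`: `counts` (per-fragment
#'   data.frame with `copy_number`), `deleted`, `gained` (reported events),
#'   `min_report_len`.
#' @export
copy_number_report <- function(assembly, fragments, min_report_len = 50000) {
  placed <- do.call(rbind, c(assembly$derivatives,
                             list(fragments[0, , drop = FALSE])))
  counts <- fragments
  counts$copy_number <- as.integer(
    vapply(fragments$id, function(id) sum(placed$id == id), 0))
  big <- (counts$end - counts$start) >= min_report_len
  deleted <- counts[counts$copy_number == 0 & big, , drop = FALSE]
  gained <- counts[counts$copy_number >= 2 & big, , drop = FALSE]
  rownames(counts) <- rownames(deleted) <- rownames(gained) <- NULL
  structure(list(counts = counts, deleted = deleted, gained = gained,
                 min_report_len = min_report_len),
            class = "copy_number_report")
}

#' @export
print.copy_number_report <- function(x, ...) {
  cat(sprintf(
    "copy_number_report (>= %s bp): %d loss(es), %d gain(s); %d fragment(s) tallied\n",
    format(x$min_report_len, big.mark = ","), nrow(x$deleted),
    nrow(x$gained), nrow(x$counts)))
  invisible(x)
}

#' Arc table for circos-style plotting
#'
#' One arc per junction, classified as intra- or inter-chromosomal; rendering
#' is left to the plotting layer.
#'
#' @param junctions a `junction_set`.
#' @return `data.frame` with columns `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `class`.
#' @export
circos_table <- function(junctions) {
  if (nrow(junctions) == 0) {
    return(data.frame(chrom1 = character(), pos1 = numeric(),
                      chrom2 = character(), pos2 = numeric(),
                      class = character()))
  }
  data.frame(chrom1 = junctions$chrom1, pos1 = junctions$pos1,
             chrom2 = junctions$chrom2, pos2 = junctions$pos2,
             class = classify_rejoining(junctions),
             stringsAsFactors = FALSE)
}
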