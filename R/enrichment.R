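# Windowed Poisson-regression enrichment of breakpoints in peak sets.
#
# The genome is tiled with fixed-size windows; per window we record the
# fraction covered by (merged) peaks and the breakpoint count, then fit
#   log E[breaks_i] = alpha + beta * coverage_i
# by Poisson ML. exp(beta) is the risk ratio of a fully covered versus an
# uncovered window; inference is Wald (normal approximation on beta).

#' Tile chromosomes with fixed-size windows
#'
#' Per chromosome of length L there are `ceiling(L / window_size)` windows;
#' the last is truncated at the chromosome end.
#'
#' @param chrom_sizes a `chrom_sizes` object.
#' @param window_size window size in bp (> 0).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `index`
#'   (global ordinal).
#' @export
make_windows <- function(chrom_sizes, window_size) {
  if (!is.numeric(window_size) || length(window_size) != 1 ||
      window_size <= 0) {
    stop("window_size must be a positive number")
  }
  rows <- lapply(names(chrom_sizes), function(ch) {
    len <- unname(chrom_sizes[[ch]])
    starts <- seq(0, len - 1, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Fraction of each window covered by peaks
#'
#' Coverage is overlapped bp divided by the actual window length (truncated
#' windows use their true length). Windows on chromosomes absent from the
#' peak set get coverage 0 (they are not dropped).
#'
#' @param windows from [make_windows()].
#' @param peaks a `peak_set`; merged first (idempotent if already merged).
#' @return numeric vector of per-window coverage fractions in `[0, 1]`,
#'   aligned with `windows`.
#' @export
coverage_fractions <- function(windows, peaks) {
  peaks <- merge_peaks(peaks)
  cov <- numeric(nrow(windows))
  iv <- peaks$intervals
  for (ch in intersect(unique(windows$chrom), unique(iv$chrom))) {
    wi <- which(windows$chrom == ch)
    w <- IRanges::IRanges(start = windows$start[wi] + 1L,
                          end = windows$end[wi])
    sel <- iv$chrom == ch
    p <- IRanges::IRanges(start = iv$start[sel] + 1L, end = iv$end[sel])
    hits <- IRanges::findOverlaps(w, p)
    if (length(hits) == 0) next
    ov <- IRanges::width(IRanges::pintersect(
      w[S4Vectors::queryHits(hits)], p[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    cov[wi[as.integer(names(agg))]] <- as.numeric(agg)
  }
  cov / (windows$end - windows$start)
}

#' Count breakpoints per window
#'
#' A breakend at position p belongs to the unique window with
#' `start <= p < end` (half-open convention). Breakends on chromosomes
#' outside the window tiling, or beyond the chromosome end, are errors.
#'
#' @param windows from [make_windows()].
#' @param breakends `data.frame` with `chrom`, `pos` columns, or a
#'   `junction_set`.
#' @return integer vector of per-window counts aligned with `windows`;
#'   counts sum to the number of breakends.
#' @export
count_breaks <- function(windows, breakends) {
  if (inherits(breakends, "junction_set")) {
    breakends <- breakends_of(breakends)
  }
  counts <- integer(nrow(windows))
  for (ch in unique(breakends$chrom)) {
    wi <- which(windows$chrom == ch)
    if (length(wi) == 0) {
      stop("breakend on chromosome absent from the window tiling: ", ch)
    }
    p <- breakends$pos[breakends$chrom == ch]
    if (any(p < 0) || any(p >= max(windows$end[wi]))) {
      stop("breakend position beyond chromosome end on ", ch)
    }
    idx <- findInterval(p, windows$start[wi])
    tab <- table(idx)
    counts[wi[as.integer(names(tab))]] <-
      counts[wi[as.integer(names(tab))]] + as.integer(tab)
  }
  counts
}

#' Fit the univariate Poisson enrichment model
#'
#' Maximizes the Poisson likelihood for `log E[y] = alpha + beta * x` with
#' `x` = per-window peak-coverage fraction and `y` = per-window breakpoint
#' count (or presence/absence under `response = "binary"`), via IRLS
#' (relative deviance change < 1e-10, at most 100 iterations). The risk
#' ratio is `exp(beta)` with a Wald `exp(beta +/- z * se)` confidence
#' interval and a Wald p-value.
#'
#' @param records `data.frame` with columns `coverage` and `breaks` (a
#'   per-window table), e.g. built from [coverage_fractions()] and
#'   [count_breaks()].
#' @param response `"count"` (default) or `"binary"` (1{count > 0}).
#' @param covariate_scale `"fraction"` (default; rr compares a fully covered
#'   to an uncovered window) or `"percent"` (rr per percentage point).
#' @param z normal quantile for the CI (1.96 = 95%).
#' @return list of class `enrichment_result` with `alpha`, `beta`, `se`,
#'   `rr`, `ci_low`, `ci_high`, `p`, `n_windows`, `n_breaks`, `converged`,
#'   and NA `assay` / `window_size` fields (filled by
#'   [run_enrichment_matrix()]).
#' @export
fit_poisson_enrichment <- function(records,
                                   response = c("count", "binary"),
                                   covariate_scale = c("fraction", "percent"),
                                   z = 1.96) {
  response <- match.arg(response)
  covariate_scale <- match.arg(covariate_scale)
  stopifnot(is.data.frame(records),
            all(c("coverage", "breaks") %in% names(records)))
  x <- records$coverage
  if (covariate_scale == "percent") x <- x * 100
  y <- records$breaks
  if (response == "binary") y <- as.integer(y > 0)
  if (length(x) < 2) stop("need at least 2 windows")
  if (length(unique(x)) < 2) {
    stop("non-identifiable: coverage is constant across windows")
  }
  n_breaks <- sum(records$breaks)
  if (sum(y) == 0) stop("zero total breakpoints: nothing to model")
  fit <- suppressWarnings(stats::glm(
    y ~ x, family = stats::poisson(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- unname(stats::coef(fit)[2])
  alpha <- unname(stats::coef(fit)[1])
  se <- unname(sqrt(diag(stats::vcov(fit)))[2])
  # complete separation (all breaks at one extreme of x) drives |beta| off to
  # +/- Inf; report converged = FALSE rather than silently clipping
  diverged <- !is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 1e3
  converged <- isTRUE(fit$converged) && !diverged
  wald <- beta / se
  res <- list(assay = NA_character_, window_size = NA_real_,
              alpha = alpha, beta = beta, se = se,
              rr = exp(beta),
              ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
              p = 2 * stats::pnorm(-abs(wald)),
              n_windows = length(y), n_breaks = n_breaks,
              converged = converged)
  if (diverged) {
    res$diagnostic <- "diverging beta: complete or quasi-complete separation"
  }
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Poisson enrichment%s%s: RR %.3g (95%% CI %.3g-%.3g), p = %.3g\n  beta = %.4g (se %.4g), %d windows, %d breakpoints%s\n",
    if (!is.na(x$assay)) paste0(" [", x$assay, "]") else "",
    if (!is.na(x$window_size)) sprintf(" @ %g bp windows", x$window_size)
    else "",
    x$rr, x$ci_low, x$ci_high, x$p, x$beta, x$se, x$n_windows, x$n_breaks,
    if (!x$converged) " (NOT CONVERGED)" else ""))
  invisible(x)
}

#' Build a per-window record table for one assay and window size
#'
#' @param breakends `data.frame` with `chrom`, `pos`, or a `junction_set`.
#' @param peaks a `peak_set`.
#' @param chrom_sizes a `chrom_sizes` object.
#' @param window_size bp.
#' @return `data.frame` with `chrom`, `start`, `end`, `coverage`, `breaks`.
#' @export
window_table <- function(breakends, peaks, chrom_sizes, window_size) {
  w <- make_windows(chrom_sizes, window_size)
  w$coverage <- coverage_fractions(w, peaks)
  w$breaks <- count_breaks(w, breakends)
  w
}

#' Enrichment across assays and window sizes
#'
#' One Poisson fit per assay and window size, in deterministic order (assays
#' in the order given, window sizes ascending). The `significant` flag uses
#' the Wald p-value at `alpha_level` (conventionally 0.05).
#'
#' @param breakends `data.frame` with `chrom`, `pos`, or a `junction_set`.
#' @param assays list of `peak_set` objects (names override labels).
#' @param chrom_sizes a `chrom_sizes` object.
#' @param window_sizes bp vector (default 1, 5 and 10 kb).
#' @param response,covariate_scale,z passed to [fit_poisson_enrichment()].
#' @param alpha_level significance threshold for the flag column.
#' @return `data.frame` with one row per assay x window size: `assay`,
#'   `window_size`, `rr`, `ci_low`, `ci_high`, `p`, `beta`, `se`,
#'   `n_windows`, `n_breaks`, `converged`, `significant`.
#' @export
run_enrichment_matrix <- function(breakends, assays, chrom_sizes,
                                  window_sizes = c(1000, 5000, 10000),
                                  response = "count",
                                  covariate_scale = "fraction",
                                  z = 1.96, alpha_level = 0.05) {
  if (inherits(assays, "peak_set")) assays <- list(assays)
  labels <- names(assays)
  if (is.null(labels)) {
    labels <- vapply(assays, function(a) a$label, "")
  }
  window_sizes <- sort(window_sizes)
  rows <- list()
  for (ai in seq_along(assays)) {
    merged <- merge_peaks(assays[[ai]])
    for (ws in window_sizes) {
      tab <- window_table(breakends, merged, chrom_sizes, ws)
      r <- fit_poisson_enrichment(tab, response = response,
                                  covariate_scale = covariate_scale, z = z)
      rows[[length(rows) + 1L]] <- data.frame(
        assay = labels[ai], window_size = ws, rr = r$rr,
        ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
        beta = r$beta, se = r$se, n_windows = r$n_windows,
        n_breaks = r$n_breaks, converged = r$converged,
        significant = r$converged & r$p < alpha_level,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
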