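# Independent oracles and fixture builders, kept free of the package's own
# implementation paths.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force junction-signature oracle: enumerate every split position s of
# the junction; a split is valid iff the prefix occurs contiguously in
# context A and the suffix occurs contiguously in context B (the break may
# sit anywhere inside a shared homology tract, so no anchoring to the
# reported break position). `anchor` excludes trivial short matches, exactly
# as the caller's precondition demands junction sequences that span the
# fusion with enough matching bases each side. Number of valid splits
# n >= 1 gives signed_len = n - 1; otherwise the maximal prefix/suffix
# matches bracket the microinsertion.
oracle_signature <- function(junction_seq, ctx_a, ctx_b, anchor = 10L) {
  J <- toupper(junction_seq)
  L <- nchar(J)
  sa <- toupper(ctx_a$seq)
  sb <- toupper(ctx_b$seq)
  matchA <- function(s) {
    s > 0 && grepl(substr(J, 1, s), sa, fixed = TRUE)
  }
  matchB <- function(s) {
    s < L && grepl(substr(J, s + 1, L), sb, fixed = TRUE)
  }
  a_ok <- vapply(0:L, matchA, TRUE)
  b_ok <- vapply(0:L, matchB, TRUE)
  valid <- a_ok & b_ok & (0:L) >= anchor & (L - (0:L)) >= anchor
  n <- sum(valid)
  if (n >= 1) {
    return(list(signed_len = n - 1L, insertion_seq = ""))
  }
  s_a <- max(which(a_ok & (0:L) >= anchor)) - 1L
  s_b <- L - (min(which(b_ok & (L - (0:L)) >= anchor)) - 1L)
  ins <- substr(J, s_a + 1, L - s_b)
  list(signed_len = -nchar(ins), insertion_seq = ins)
}

# Construct a random junction with a planted signature that is unambiguous by
# construction (single-base guards at both ends of the planted tract).
# planted >= 0: microhomology of that length; planted < 0: microinsertion.
make_planted_junction <- function(planted, W = 40L, fa = 25L, fb = 25L) {
  other <- function(...) sample(setdiff(c("A", "C", "G", "T"),
                                        toupper(unlist(list(...)))), 1)
  sa <- rand_seq(2 * W)
  sb <- rand_seq(2 * W)
  setc <- function(s, i, v) { substr(s, i, i) <- v; s }
  if (planted >= 0) {
    h <- planted
    if (h > 0) {
      substr(sb, W + 1, W + h) <- substr(sa, W - h + 1, W)
    }
    # guards: stop the ambiguity interval at exactly h
    if (substr(sb, W + h + 1, W + h + 1) == substr(sa, W + 1, W + 1)) {
      sb <- setc(sb, W + h + 1, other(substr(sa, W + 1, W + 1)))
    }
    if (substr(sa, W - h, W - h) == substr(sb, W, W)) {
      sa <- setc(sa, W - h, other(substr(sb, W, W)))
    }
    junction <- paste0(substr(sa, W - fa + 1, W),
                       substr(sb, W + h + 1, W + fb))
  } else {
    m <- -planted
    caN <- substr(sa, W + 1, W + 1)
    cbP <- substr(sb, W, W)
    ins <- vapply(seq_len(m), function(i) sample(c("A","C","G","T"), 1), "")
    ins[1] <- other(caN, if (m == 1) cbP)
    if (m > 1) ins[m] <- other(cbP)
    ins <- paste(ins, collapse = "")
    junction <- paste0(substr(sa, W - fa + 1, W), ins,
                       substr(sb, W + 1, W + fb))
  }
  list(junction = junction,
       ctx_a = junction_context(sa, W),
       ctx_b = junction_context(sb, W),
       planted = as.integer(planted))
}

# Independent Poisson-likelihood maximizer: BFGS on the analytic negative
# log-likelihood, polished by full Newton steps. No IRLS, no stats::glm.
oracle_poisson_fit <- function(x, y) {
  nll <- function(p) sum(exp(p[1] + p[2] * x)) - sum(y * (p[1] + p[2] * x))
  grd <- function(p) {
    mu <- exp(p[1] + p[2] * x)
    c(sum(mu) - sum(y), sum(mu * x) - sum(y * x))
  }
  st <- c(log(mean(y) + 1e-8), 0)
  op <- stats::optim(st, nll, grd, method = "BFGS",
                     control = list(maxit = 5000, reltol = 1e-14))
  p <- op$par
  for (i in 1:50) {
    mu <- exp(p[1] + p[2] * x)
    g <- c(sum(mu) - sum(y), sum(mu * x) - sum(y * x))
    H <- matrix(c(sum(mu), sum(mu * x), sum(mu * x), sum(mu * x^2)), 2)
    step <- solve(H, g)
    p <- p - step
    if (max(abs(step)) < 1e-12) break
  }
  list(alpha = p[1], beta = p[2])
}

# Common scaled-down enrichment world: one 10-Mb chromosome tiled at 1 kb
# (10,000 windows), peaks long relative to windows so per-window coverage is
# essentially binary and exp(beta) estimates the planted rate ratio without
# appreciable model-misspecification bias.
enrichment_world <- function(seed = 42L, peak_len_mean = 1e5,
                             peak_fraction = 0.1, window_size = 1000) {
  cfg <- sim_config(seed = seed, n_chroms = 1L, chrom_len = 1e7,
                    peak_fraction = peak_fraction,
                    peak_len_mean = peak_len_mean, n_breaks = 193L)
  sizes <- chrom_sizes(c(chr1 = 1e7))
  peaks <- simulate_peaks(cfg, sizes)
  w <- make_windows(sizes, window_size)
  list(cfg = cfg, sizes = sizes, peaks = peaks, windows = w,
       coverage = coverage_fractions(w, peaks))
}
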