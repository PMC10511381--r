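test_that("simulate_genome is deterministic, sized and seed-sensitive", {
  cfg <- sim_config(seed = 12, n_chroms = 3, chrom_len = 5e4)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_equal(length(g1$genome), 3)
  expect_true(all(nchar(g1$genome) == 5e4))
  expect_equal(unname(as.numeric(g1$chrom_sizes)), rep(5e4, 3))
  g3 <- simulate_genome(sim_config(seed = 13, n_chroms = 3, chrom_len = 5e4))
  expect_false(identical(g1$genome, g3$genome))
})

test_that("simulate_peaks hits the target fraction with clean intervals", {
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_len = 1e7,
                    peak_fraction = 0.1, peak_len_mean = 600)
  pk <- simulate_peaks(cfg)
  f <- total_bp(pk) / 1e7
  expect_gt(f, 0.09)
  expect_lt(f, 0.11)
  iv <- pk$intervals
  expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))  # disjoint, unbookended
  expect_identical(simulate_peaks(cfg)$intervals, iv)
  none <- simulate_peaks(sim_config(seed = 5, peak_fraction = 0))
  expect_equal(nrow(none$intervals), 0)
})

test_that("simulate_breakpoints plants the two-rate enrichment", {
  base <- sim_config(seed = 6, n_chroms = 1, chrom_len = 1e7,
                     peak_fraction = 0.1, peak_len_mean = 600,
                     n_breaks = 2000L)
  pk <- simulate_peaks(base)
  sz <- chrom_sizes(c(chr1 = 1e7))
  f <- total_bp(pk) / 1e7

  cfg1 <- base; cfg1$true_rr <- 1
  be1 <- simulate_breakpoints(cfg1, pk, sz)
  frac1 <- mean(attr(be1, "in_peak"))
  expect_lt(abs(frac1 - f), 3 * sqrt(f * (1 - f) / 2000))

  cfg10 <- base; cfg10$true_rr <- 10
  be10 <- simulate_breakpoints(cfg10, pk, sz)
  p_exp <- 10 * f / (10 * f + (1 - f))
  expect_lt(abs(mean(attr(be10, "in_peak")) - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / 2000))
  # the in_peak flags agree with a direct overlap tally
  w <- pk$intervals
  inside <- vapply(seq_len(nrow(be10)), function(i) {
    any(w$chrom == be10$chrom[i] & w$start <= be10$pos[i] &
          be10$pos[i] < w$end)
  }, TRUE)
  expect_equal(inside, attr(be10, "in_peak"))

  cfg0 <- base; cfg0$n_breaks <- 0L
  expect_equal(nrow(simulate_breakpoints(cfg0, pk, sz)), 0)
  expect_equal(anyDuplicated(paste(be1$chrom, be1$pos)), 0)
})

test_that("simulate_rearrangement conserves sequence and never duplicates", {
  for (s in c(31, 32, 33)) {
    cfg <- sim_config(seed = s, n_breaks = 25L, deletion_prob = 0.2)
    sz <- chrom_sizes(setNames(rep(cfg$chrom_len, 3), paste0("chr", 1:3)))
    be <- simulate_breakpoints(cfg, simulate_peaks(cfg, sz), sz)
    tr <- simulate_rearrangement(cfg, be, sz)
    placed <- do.call(rbind, tr$derivatives)
    expect_equal(anyDuplicated(placed$id), 0)
    expect_equal(sum(placed$end - placed$start) +
                   sum(tr$deleted$end - tr$deleted$start),
                 sum(as.numeric(sz[tr$involved])))
    # each derivative is telomere-bounded
    for (d in tr$derivatives) {
      expect_equal(d$start[1], 0)
      expect_equal(d$orientation[1], "forward")
      expect_equal(d$end[nrow(d)], unname(cfg$chrom_len))
    }
    expect_equal(nrow(tr$junctions),
                 sum(vapply(tr$derivatives, nrow, 0L)) -
                   length(tr$derivatives))
  }
  cfg0 <- sim_config(seed = 31, n_breaks = 25L, deletion_prob = 0)
  sz <- chrom_sizes(setNames(rep(cfg0$chrom_len, 3), paste0("chr", 1:3)))
  be <- simulate_breakpoints(cfg0, simulate_peaks(cfg0, sz), sz)
  tr0 <- simulate_rearrangement(cfg0, be, sz)
  expect_equal(nrow(tr0$deleted), 0)
})

test_that("planted junction signatures are recovered by the caller", {
  sim <- simulate_ccr(sim_config(seed = 23, n_breaks = 24L))
  sigs <- call_signatures(sim$junctions, sim$genome)
  expect_equal(sigs$signed_len, sim$truth$signatures$signed_len)
  ins <- sim$truth$signatures$signed_len < 0
  expect_equal(sigs$insertion_class[ins],
               sim$truth$signatures$insertion_class[ins])
  expect_equal(sigs$insertion_seq[ins],
               sim$truth$signatures$insertion_seq[ins])
})

test_that("trio simulation plants paternal origin with the error knob", {
  cfg <- sim_config(seed = 41, genotype_error = 0)
  sim <- simulate_ccr(cfg)
  calls <- classify_site(sim$trio$der_allele, sim$trio$father_gt,
                         sim$trio$mother_gt)
  expect_true(all(calls %in% c("paternal", "uninformative")))
  expect_false(any(sim$truth$trio_flipped))
  # deterministic under seed
  sim2 <- simulate_ccr(cfg)
  expect_identical(sim$trio, sim2$trio)
})

test_that("emitted files re-parse into the simulation objects", {
  sim <- simulate_ccr(sim_config(seed = 29, n_breaks = 12L))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_identical(read_fasta(paths[["genome"]]), sim$genome)
  expect_equal(read_chrom_sizes(paths[["chrom_sizes"]]), sim$chrom_sizes,
               ignore_attr = TRUE)
  expect_equal(read_bed(paths[["peaks"]])$intervals, sim$peaks$intervals,
               ignore_attr = TRUE)
  expect_equal(read_bedpe(paths[["junctions"]]), sim$junctions,
               ignore_attr = TRUE)
  expect_equal(read_trio_sites(paths[["trio"]])$der_allele,
               sim$trio$der_allele)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$signatures$signed_len, sim$truth$signatures$signed_len)
  expect_equal(truth$n_in_peak, sim$truth$n_in_peak)
})
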