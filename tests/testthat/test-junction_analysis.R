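test_that("call_signature handles blunt, microhomology and microinsertion", {
  # blunt: no shared flanking base
  blunt <- call_signature("TTACGGGT",
                          junction_context("CCCTTAC", 7),
                          junction_context("GGGTAAA", 0),
                          min_anchor = 4)
  expect_equal(blunt$signed_len, 0)
  expect_equal(blunt$n_splits, 1)

  # "CG" flanks both breaks: 3 valid splits, homology 2
  hom <- call_signature("AAAACGTTTT",
                        junction_context("TTAAAACG", 8),
                        junction_context("AGCGTTTT", 2),
                        min_anchor = 4)
  expect_equal(hom$signed_len, 2)
  expect_equal(hom$n_splits, 3)

  # "TT" in neither context: microinsertion of 2
  ins <- call_signature("AAAATTGGGG",
                        junction_context("CCAAAA", 6),
                        junction_context("GGGGCC", 0),
                        min_anchor = 4)
  expect_equal(ins$signed_len, -2)
  expect_equal(ins$insertion_seq, "TT")
})

test_that("call_signature raises the contracted errors", {
  expect_error(
    call_signature("TTTTTTTT", junction_context("AAAAAAA", 7),
                   junction_context("CCCCCCC", 0), min_anchor = 4),
    "unmappable")
  # both contexts covering the whole junction is ambiguous
  expect_error(
    call_signature("ACGTACGT", junction_context("ACGTACGT", 8),
                   junction_context("ACGTACGT", 0), min_anchor = 4),
    "ambiguous")
})

test_that("call_signature agrees with the split-enumeration oracle", {
  set.seed(202)
  planted_vals <- c(0:10, -(1:15))
  for (rep in 1:200) {
    planted <- sample(planted_vals, 1)
    jc <- make_planted_junction(planted)
    sig <- call_signature(jc$junction, jc$ctx_a, jc$ctx_b)
    orc <- oracle_signature(jc$junction, jc$ctx_a, jc$ctx_b)
    expect_equal(sig$signed_len, orc$signed_len)
    expect_equal(sig$signed_len, jc$planted)
    if (planted < 0) expect_equal(sig$insertion_seq, orc$insertion_seq)
  }
})

test_that("signature is invariant under partner swap with reverse complement", {
  set.seed(303)
  for (rep in 1:50) {
    jc <- make_planted_junction(sample(c(0:6, -(1:8)), 1))
    fwd <- call_signature(jc$junction, jc$ctx_a, jc$ctx_b)
    swapped_a <- junction_context(revcomp(jc$ctx_b$seq),
                                  nchar(jc$ctx_b$seq) - jc$ctx_b$break_at)
    swapped_b <- junction_context(revcomp(jc$ctx_a$seq),
                                  nchar(jc$ctx_a$seq) - jc$ctx_a$break_at)
    rev <- call_signature(revcomp(jc$junction), swapped_a, swapped_b)
    expect_equal(rev$signed_len, fwd$signed_len)
  }
})

test_that("classify_insertion finds tandem, inverted and unknown origins", {
  ctx_a <- junction_context("CCCCGGATAT", 10)
  ctx_b <- junction_context("CTCTCTCTCT", 0)
  expect_equal(classify_insertion("ATAT", ctx_a, ctx_b, search_radius = 10),
               "tandem_repeat")
  # adjacent "CCTT" on the other side of a break: "AAGG" is its revcomp
  ctx_b2 <- junction_context("CCTTGGGGGG", 0)
  expect_equal(classify_insertion("AAGG", junction_context("GACGAC", 6),
                                  ctx_b2, search_radius = 10),
               "inverted_repeat")
  expect_equal(classify_insertion("TTTTT", junction_context("GACGACGAC", 9),
                                  junction_context("CAGCAGCAG", 0),
                                  search_radius = 10),
               "unknown_origin")
  # matches shorter than the full insertion do not count
  expect_equal(classify_insertion("ATATGC", ctx_a, ctx_b,
                                  search_radius = 10),
               "unknown_origin")
})

test_that("classify_rejoining is exact on chromosome names", {
  j <- junction_set(c("chr1", "chr1", "chrX"), c(10, 10, 10),
                    "left_retained",
                    c("chr1", "chr2", "chrx"), c(99, 99, 99),
                    "right_retained")
  expect_warning(cls <- classify_rejoining(j), "case")
  expect_equal(cls, c("intra_chromosomal", "inter_chromosomal",
                      "inter_chromosomal"))
})

test_that("interval_stats pools per-chromosome gaps between breaks", {
  one <- interval_stats(data.frame(chrom = "chr1",
                                   pos = c(100, 500, 2000)))
  expect_equal(sort(one$intervals), c(400, 1500))
  expect_equal(one$median, 950)

  two <- interval_stats(data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                                   pos = c(0, 10, 0, 30)))
  expect_equal(sort(two$intervals), c(10, 30))
  expect_equal(two$median, 20)

  expect_warning(
    dup <- interval_stats(data.frame(chrom = "chr1", pos = c(100, 100, 200))),
    "duplicate")
  expect_equal(dup$intervals, 100)

  empty <- interval_stats(data.frame(chrom = c("chr1", "chr2"), pos = c(1, 2)))
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$median))

  # n unique positions on one chromosome yield exactly n - 1 intervals
  set.seed(44)
  for (rep in 1:10) {
    p <- unique(sample.int(1e6, sample(2:50, 1)))
    st <- interval_stats(data.frame(chrom = "chr9", pos = p))
    expect_equal(st$n, length(p) - 1)
    expect_equal(sum(st$intervals), max(p) - min(p))
  }
})

test_that("signature_histogram tabulates signed lengths", {
  h <- signature_histogram(c(0L, 2L, -2L))
  expect_equal(h$signed_len, c(-2L, 0L, 2L))
  expect_equal(h$count, c(1L, 1L, 1L))
  expect_equal(sum(h$count), 3)
  expect_equal(nrow(signature_histogram(integer())), 0)
  # matches the sampled truth of a simulated run exactly
  sim <- simulate_ccr(sim_config(seed = 5))
  h2 <- signature_histogram(sim$truth$signatures)
  expect_equal(sum(h2$count), nrow(sim$truth$signatures))
  expect_equal(h2, signature_histogram(sim$truth$signatures$signed_len))
})

test_that("extract_contexts orients retained flanks into the junction", {
  genome <- c(chrA = "AAAACCCCGGGGTTTT", chrB = "ACGTACGTACGTACGT")
  j <- junction_set("chrA", 8, "left_retained", "chrB", 4, "right_retained")
  ctx <- extract_contexts(j, genome, flank_len = 4)[[1]]
  expect_equal(ctx$a$seq, "CCCCGGGG")   # covers [4, 12), break at 8
  expect_equal(ctx$a$break_at, 4)
  expect_equal(ctx$b$seq, "ACGTACGT")   # covers [0, 8), break at 4
  expect_equal(ctx$b$break_at, 4)
  # opposite retained sides read reverse complement into the junction
  j2 <- junction_set("chrA", 8, "right_retained", "chrB", 4,
                     "left_retained")
  ctx2 <- extract_contexts(j2, genome, flank_len = 4)[[1]]
  expect_equal(ctx2$a$seq, revcomp("CCCCGGGG"))
  expect_equal(ctx2$a$break_at, 4)
  expect_equal(ctx2$b$seq, revcomp("ACGTACGT"))
  expect_equal(ctx2$b$break_at, 4)
})
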