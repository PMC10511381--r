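sizes2 <- chrom_sizes(c(chrA = 1000, chrB = 2000))

test_that("fragment_genome tiles chromosomes at break positions", {
  fr <- fragment_genome(chrom_sizes(c(chrA = 1000)),
                        data.frame(chrom = "chrA", pos = 400))
  expect_equal(fr$start, c(0, 400))
  expect_equal(fr$end, c(400, 1000))

  none <- fragment_genome(chrom_sizes(c(chrA = 1000)),
                          data.frame(chrom = character(), pos = numeric()))
  expect_equal(nrow(none), 1)
  expect_equal(none$end, 1000)

  dup <- fragment_genome(chrom_sizes(c(chrA = 1000)),
                         data.frame(chrom = "chrA", pos = c(400, 400)))
  expect_equal(nrow(dup), 2)

  expect_error(fragment_genome(chrom_sizes(c(chrA = 1000)),
                               data.frame(chrom = "chrZ", pos = 5)),
               "unknown chromosome")
  expect_error(fragment_genome(chrom_sizes(c(chrA = 1000)),
                               data.frame(chrom = "chrA", pos = 1000)),
               "strictly inside")
})

test_that("assemble_derivatives recovers a reciprocal translocation", {
  # t1: A1-right <-> B2-left; t2: B1-right <-> A2-left
  jn <- junction_set(c("chrA", "chrB"), c(400, 700), "left_retained",
                     c("chrB", "chrA"), c(700, 400), "right_retained",
                     name = c("t1", "t2"))
  fr <- fragment_genome(sizes2, jn)
  asm <- assemble_derivatives(fr, jn, sizes2)
  expect_false(asm$ambiguous)
  expect_equal(nrow(asm$unplaced), 0)
  expect_equal(asm$derivatives[["der(chrA)"]]$id,
               c("chrA:0-400", "chrB:700-2000"))
  expect_equal(asm$derivatives[["der(chrB)"]]$id,
               c("chrB:0-700", "chrA:400-1000"))
  expect_true(all(unlist(lapply(asm$derivatives, `[[`, "orientation")) ==
                    "forward"))
})

test_that("assemble_derivatives recovers a forced three-way translocation", {
  sz <- chrom_sizes(c(chrA = 100, chrB = 200, chrC = 300))
  jn <- junction_set(c("chrA", "chrB", "chrC"), c(40, 60, 80),
                     "left_retained",
                     c("chrB", "chrC", "chrA"), c(60, 80, 40),
                     "right_retained")
  fr <- fragment_genome(sz, jn)
  asm <- assemble_derivatives(fr, jn, sz)
  expect_false(asm$ambiguous)
  expect_equal(length(asm$derivatives), 3)
  expect_equal(asm$derivatives[["der(chrA)"]]$id,
               c("chrA:0-40", "chrB:60-200"))
  expect_equal(asm$derivatives[["der(chrB)"]]$id,
               c("chrB:0-60", "chrC:80-300"))
  expect_equal(asm$derivatives[["der(chrC)"]]$id,
               c("chrC:0-80", "chrA:40-100"))
})

test_that("fragments skipped by all junctions are unplaced (deleted)", {
  sz <- chrom_sizes(c(chrA = 1000, chrB = 1000))
  # A2 = chrA:400-600 is bridged over: A1 joins B2, B1 joins A3
  jn <- junction_set(c("chrA", "chrB"), c(400, 500),
                     "left_retained",
                     c("chrB", "chrA"), c(500, 600),
                     "right_retained")
  fr <- fragment_genome(sz, jn)
  asm <- assemble_derivatives(fr, jn, sz)
  expect_false(asm$ambiguous)
  expect_equal(asm$unplaced$id, "chrA:400-600")
})

test_that("assembly errors are explicit", {
  sz <- chrom_sizes(c(chrA = 1000, chrB = 1000, chrC = 1000))
  jn <- junction_set(c("chrA", "chrA"), c(400, 400),
                     "left_retained",
                     c("chrB", "chrC"), c(500, 500),
                     "right_retained")
  fr <- fragment_genome(sz, jn)
  expect_error(assemble_derivatives(fr, jn, sz), "conflicting junction")

  jn2 <- junction_set("chrA", 123, "left_retained",
                      "chrB", 500, "right_retained")
  fr2 <- fragment_genome(sz, junction_set("chrA", 400, "left_retained",
                                          "chrB", 500, "right_retained"))
  expect_error(assemble_derivatives(fr2, jn2, sz), "not resolvable")

  jn3 <- junction_set("chrA", 400, NA_character_, "chrB", 500,
                      "right_retained")
  expect_error(assemble_derivatives(fr, jn3, sz), "sides are missing")
})

test_that("copy_number_report applies the reporting length threshold", {
  sz <- chrom_sizes(c(chrA = 200000, chrB = 100000))
  # 60-kb fragment chrA:60000-120000 deleted; 10-kb chrB:40000-50000 deleted
  jn <- junction_set(c("chrA", "chrB"), c(60000, 40000), "left_retained",
                     c("chrB", "chrA"), c(50000, 120000), "right_retained")
  fr <- fragment_genome(sz, data.frame(chrom = c("chrA", "chrA", "chrB",
                                                 "chrB"),
                                       pos = c(60000, 120000, 40000, 50000)))
  asm <- assemble_derivatives(fr, jn, sz)
  expect_equal(sort(asm$unplaced$id),
               sort(c("chrA:60000-120000", "chrB:40000-50000")))
  cn <- copy_number_report(asm, fr, min_report_len = 50000)
  expect_equal(cn$deleted$id, "chrA:60000-120000")  # 10-kb loss not reported
  expect_equal(nrow(cn$gained), 0)
  # full accounting still lists everything
  expect_equal(sum(cn$counts$copy_number == 0), 2)
  # balanced assembly reports nothing
  bal <- copy_number_report(asm, fr, min_report_len = 1e9)
  expect_equal(nrow(bal$deleted), 0)
})

test_that("circos_table has one classified arc per junction", {
  jn <- junction_set(c("chr1", "chr1", "chr2"), c(10, 20, 30),
                     "left_retained",
                     c("chr1", "chr2", "chr3"), c(99, 98, 97),
                     "right_retained")
  arcs <- circos_table(jn)
  expect_equal(nrow(arcs), 3)
  expect_equal(arcs$class, c("intra_chromosomal", "inter_chromosomal",
                             "inter_chromosomal"))
  empty <- circos_table(jn[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
  # arcs equal the simulator's junction list
  sim <- simulate_ccr(sim_config(seed = 3))
  arcs2 <- circos_table(sim$junctions)
  expect_equal(arcs2$pos1, sim$junctions$pos1)
  expect_equal(arcs2$pos2, sim$junctions$pos2)
})

test_that("simulated rearrangements round-trip through assembly", {
  # small cohort here; the acceptance suite runs 200
  for (s in 101:120) {
    cfg <- sim_config(seed = s, n_breaks = 4 + (s %% 30),
                      deletion_prob = ifelse(s %% 2, 0, 0.25))
    sizes <- chrom_sizes(setNames(rep(cfg$chrom_len, cfg$n_chroms),
                                  paste0("chr", 1:cfg$n_chroms)))
    peaks <- simulate_peaks(cfg, sizes)
    be <- simulate_breakpoints(cfg, peaks, sizes)
    truth <- simulate_rearrangement(cfg, be, sizes)
    sub <- chrom_sizes(setNames(as.numeric(sizes[truth$involved]),
                                truth$involved))
    asm <- assemble_derivatives(truth$fragments, truth$junctions, sub)
    expect_false(asm$ambiguous)
    for (nm in names(truth$derivatives)) {
      expect_equal(asm$derivatives[[nm]]$id, truth$derivatives[[nm]]$id)
      expect_equal(asm$derivatives[[nm]]$orientation,
                   truth$derivatives[[nm]]$orientation)
    }
    expect_setequal(asm$unplaced$id, truth$deleted$id)
    # conservation of sequence
    placed <- do.call(rbind, asm$derivatives)
    expect_equal(sum(placed$end - placed$start) +
                   sum(asm$unplaced$end - asm$unplaced$start),
                 sum(as.numeric(sub)))
    # the non-duplicating process can never create a gain
    cn <- copy_number_report(asm, truth$fragments, min_report_len = 0)
    expect_true(all(cn$counts$copy_number <= 1))
  }
})
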