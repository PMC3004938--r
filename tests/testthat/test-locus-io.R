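spec <- element_spec()

test_that("simulator output round-trips through the FASTA reader", {
  sim <- simulate_locus(sim_config(n_strains = 8, seed = 3), spec)
  dir <- tempfile()
  paths <- write_sim(sim, dir)
  # sidecar supplies reference strain and element interval
  aln <- read_locus_alignment(paths[["fasta"]])
  expect_identical(aln$strains, sim$alignment)
  expect_identical(aln$reference_strain, sim$reference_strain)
  expect_identical(aln$element_interval, sim$element_interval)
  expect_identical(aln$locus_id, sim$locus_id)
})

test_that("malformed alignment input is rejected", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGT", ">b", "ACGT"), f)
  expect_error(read_locus_alignment(f, "a", c(3, 6)), "ragged")

  writeLines(character(0), f)
  expect_error(read_locus_alignment(f, "a", c(3, 6)), "format error")

  writeLines(c(">a", "ACGTACGT", ">a", "ACGTACGT"), f)
  expect_error(read_locus_alignment(f, "a", c(3, 6)), "duplicate")

  writeLines(c(">a", "ACGTACGT", ">b", "ACGTACGT"), f)
  expect_error(read_locus_alignment(f, "zz", c(3, 6)), "lookup error")
  # element interval must leave flanks on both sides
  expect_error(read_locus_alignment(f, "a", c(1, 8)), "strictly inside")
})

test_that("ungapped extraction produces an exact two-way coordinate map", {
  aln <- read_locus_alignment(c(ref = "A-C-G", alt = "AACTG"),
                              reference_strain = "ref",
                              element_interval = c(3, 3))
  got <- extract_ungapped(aln, "ref", c(1, 5))
  expect_identical(got$seq, "ACG")
  expect_identical(got$map$column, c(1L, 3L, 5L))
  expect_identical(got$map$position, c(1L, 2L, 3L))
  # gap-free row: identity map
  got2 <- extract_ungapped(aln, "alt", c(1, 5))
  expect_identical(got2$seq, "AACTG")
  expect_identical(got2$map$column, got2$map$position)
  expect_error(extract_ungapped(aln, "nope", c(1, 5)), "lookup error")
  expect_error(extract_ungapped(aln, "ref", c(0, 5)), "outside")
})

test_that("extracted element coordinates agree with simulator truth", {
  sim <- simulate_locus(sim_config(n_strains = 8, seed = 6,
                                   mutation_rate = 0), spec)
  aln <- read_locus_alignment(sim$alignment,
                              reference_strain = sim$reference_strain,
                              element_interval = sim$element_interval)
  tr <- sim$truth[sim$truth$strain == sim$reference_strain, ]
  got <- extract_ungapped(aln, sim$reference_strain, sim$element_interval)
  expect_identical(got$seq, sim$element)
  expect_identical(range(got$map$position),
                   c(tr$element_start, tr$element_end))
  # alignment consistency: degapping any row reproduces its sequence
  for (s in names(aln$strains)) {
    expect_identical(extract_ungapped(aln, s)$seq,
                     gsub("-", "", aln$strains[[s]], fixed = TRUE))
  }
})

test_that("presence/orientation calls match truth for every scenario", {
  for (sc in c("full_ab", "internal_c", "conversion_left_d",
               "conversion_right_e", "excision", "none")) {
    sim <- simulate_locus(sim_config(n_strains = 10, scenario = sc,
                                     mutation_rate = 0, seed = 17), spec)
    aln <- read_locus_alignment(sim$alignment,
                                reference_strain = sim$reference_strain,
                                element_interval = sim$element_interval)
    calls <- call_presence_orientation(aln)
    m <- merge(calls, sim$truth, by = "strain")
    expect_identical(m$state.x, m$state.y)
    # reference strain is canonical on the plus strand
    ref <- calls[calls$strain == sim$reference_strain, ]
    expect_identical(ref$state, "canonical")
    expect_identical(ref$orf_strand, "+")
    # absent strains have no ORF strand by definition
    expect_true(all(calls$orf_strand[calls$state == "absent"] == "none"))
  }
})

test_that("degenerate rows fall into absent or ambiguous, never error", {
  sim <- simulate_locus(sim_config(n_strains = 6, seed = 8,
                                   mutation_rate = 0), spec)
  width <- nchar(sim$alignment[[1]])
  ei <- sim$element_interval
  aln_rows <- c(sim$alignment, GAPPY = strrep("-", width))
  # half-deleted element: ambiguous presence
  half <- sim$alignment[[sim$reference_strain]]
  cut_from <- ei[1] + floor(diff(ei) * 0.3)
  substr(half, cut_from, ei[2]) <- strrep("-", ei[2] - cut_from + 1)
  aln_rows <- c(aln_rows, HALF = half)
  aln <- read_locus_alignment(aln_rows,
                              reference_strain = sim$reference_strain,
                              element_interval = ei)
  calls <- call_presence_orientation(aln)
  expect_identical(calls$state[calls$strain == "GAPPY"], "absent")
  expect_identical(calls$non_gap_fraction[calls$strain == "GAPPY"], 0)
  expect_identical(calls$state[calls$strain == "HALF"], "ambiguous")
})

test_that("calls are invariant under reverse-complementing the alignment", {
  for (sc in c("conversion_left_d", "internal_c")) {
    sim <- simulate_locus(sim_config(n_strains = 10, scenario = sc,
                                     mutation_rate = 0, seed = 29), spec)
    aln <- read_locus_alignment(sim$alignment,
                                reference_strain = sim$reference_strain,
                                element_interval = sim$element_interval)
    calls <- call_presence_orientation(aln)

    width <- nchar(sim$alignment[[1]])
    flipped <- vapply(sim$alignment, rc, character(1))
    ei <- c(width - sim$element_interval[2] + 1,
            width - sim$element_interval[1] + 1)
    aln_rc <- read_locus_alignment(flipped,
                                   reference_strain = sim$reference_strain,
                                   element_interval = ei)
    calls_rc <- call_presence_orientation(aln_rc)
    expect_identical(calls_rc$state, calls$state)
    expect_identical(calls_rc$non_gap_fraction, calls$non_gap_fraction)
  }
})
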