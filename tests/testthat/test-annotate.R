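spec <- element_spec()

test_that("TIR detector recovers the asymmetric terminal repeats", {
  for (seed in c(1, 7, 19)) {
    el <- build_canonical_element(spec, seed = seed)
    tp <- detect_tirs(el)
    expect_true(tp$found)
    expect_identical(tp$length, 23L)
    expect_identical(tp$mismatch_positions, 17L)
    expect_identical(tp$left_inward, spec$left_tir_inward)
    expect_identical(tp$right_inward, spec$right_tir_inward)
  }
})

test_that("perfect terminal inverted repeats yield an empty mismatch list", {
  withr::with_seed(5, {
    tir <- rand_dna(23)
    # three non-pairing positions on each side of the interior stop the
    # repeat from extending into the filler under the default d_max = 2
    el <- paste0(tir, "AAA", rand_dna(148), "AAA", rc(tir))
    tp <- detect_tirs(el)
    expect_identical(tp$length, 23L)
    expect_identical(tp$mismatch_positions, integer(0))
    expect_identical(tp$right_inward, tp$left_inward)
  })
})

test_that("absence of a repeat is reported as a result, not an error", {
  tp <- detect_tirs(strrep("A", 100))
  expect_false(tp$found)
  expect_error(detect_tirs("ACGTACGTACGT"), "malformed")
})

test_that("exact-repeat detection agrees with a brute-force scan of all k", {
  withr::with_seed(11, {
    for (i in 1:60) {
      n <- sample(40:200, 1)
      el <- rand_dna(n)
      if (i %% 3 == 0) {
        # plant an exact terminal inverted repeat of known length
        k <- sample(10:18, 1)
        el <- paste0(substr(el, 1, k), substr(el, k + 1, n - k),
                     rc(substr(el, 1, k)))
      }
      tp <- detect_tirs(el, d_max = 0)
      got <- if (tp$found) tp$length else 0L
      expect_identical(got, brute_tir_exact(el))
    }
  })
})

test_that("TIR detection is symmetric under reverse complement", {
  for (sc in c("full_ab", "internal_c", "conversion_left_d",
               "conversion_right_e")) {
    el <- apply_inversion_operator(build_canonical_element(spec, 4), spec, sc)
    a <- detect_tirs(el)
    b <- detect_tirs(rc(el))
    expect_identical(a$length, b$length)
    expect_identical(b$left_inward, a$right_inward)
    expect_identical(b$right_inward, a$left_inward)
    expect_identical(a$mismatch_positions, b$mismatch_positions)
  }
})

test_that("transposase ORF finder locates the designed gene", {
  el <- build_canonical_element(spec, seed = 1)
  orf <- find_transposase_orf(el)
  expect_identical(orf$interval, c(34L, 891L))
  expect_identical(orf$length, spec$orf_length)
  expect_identical(orf$strand, "+")

  # strand symmetry: the reverse complement carries it on the minus strand
  orf_rc <- find_transposase_orf(rc(el))
  expect_identical(orf_rc$length, spec$orf_length)
  expect_identical(orf_rc$strand, "-")
  expect_identical(orf_rc$interval, c(916L - 891L + 1L, 916L - 34L + 1L))

  expect_null(find_transposase_orf(strrep("A", 400)))
})

test_that("ORF finder agrees with exhaustive start/stop enumeration", {
  withr::with_seed(21, {
    for (i in 1:40) {
      el <- rand_dna(sample(90:260, 1))
      got <- find_transposase_orf(el, min_len = 30)
      want <- brute_longest_orf(el, min_len = 30)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(as.numeric(got$interval),
                     as.numeric(c(want$start, want$end)))
        expect_identical(got$strand, as.character(want$strand))
      }
    }
  })
})

test_that("target-site duplication detection follows the T(T/A)A rule", {
  expect_identical(detect_tsd("GCGATTA", "TTACGGC")$sequence, "TTA")
  expect_true(detect_tsd("GCGATTA", "TTACGGC")$target_site_match)
  expect_identical(detect_tsd("GCGATAA", "TAACGGC")$sequence, "TAA")
  # longer direct repeats are reported but are not the target-site motif
  got <- detect_tsd("GCGGTTA", "GTTACGG")
  expect_identical(got$sequence, "GTTA")
  expect_false(got$target_site_match)
  expect_null(detect_tsd("AAAAACC", "GGTTTTT"))
  expect_error(detect_tsd("A", "TTACGG"), "malformed")
})

test_that("simulated flanks carry the configured target-site duplication", {
  sim <- simulate_locus(sim_config(n_strains = 8, mutation_rate = 0,
                                   seed = 14), spec)
  aln <- read_locus_alignment(sim$alignment,
                              reference_strain = sim$reference_strain,
                              element_interval = sim$element_interval)
  left <- extract_ungapped(aln, sim$reference_strain, c(1, 303))$seq
  right <- extract_ungapped(aln, sim$reference_strain, c(1220, 1522))$seq
  tsd <- detect_tsd(left, right)
  expect_identical(tsd$sequence, sim$config$target_site)
  expect_true(tsd$target_site_match)
})

test_that("promoter scan ranks the -35/-10 pair with 17-bp spacing first", {
  for (seed in c(1, 8, 23)) {
    el <- build_canonical_element(spec, seed = seed)
    hits <- scan_promoters(el)
    expect_gt(nrow(hits), 0)
    top <- hits[1, ]
    expect_identical(top$minus35_start, 5L)
    expect_identical(top$minus35_seq, "TTGTCC")
    expect_identical(top$minus10_start, 28L)
    expect_identical(top$minus10_seq, "TATAAT")
    expect_identical(top$spacer, 17L)
    expect_identical(top$score, 10L)
    # spacer identity holds for every reported hit
    expect_true(all(hits$spacer ==
                      hits$minus10_start - hits$minus35_end - 1))
  }
  expect_identical(nrow(scan_promoters(strrep("C", 100))), 0L)
})

test_that("promoter scan equals the exhaustive pair enumeration", {
  withr::with_seed(42, {
    for (i in 1:200) {
      el <- rand_dna(200)
      got <- scan_promoters(el)
      want <- brute_promoters(el)
      if (is.null(want)) {
        expect_identical(nrow(got), 0L)
      } else {
        got$score <- as.numeric(got$score)
        rownames(got) <- NULL
        expect_equal(got, want, ignore_attr = TRUE)
      }
    }
  })
})

test_that("all four annotators recover the generator truth", {
  for (seed in 101:200) {
    el <- build_canonical_element(spec, seed = seed)
    ann <- annotate_element(el, left_flank = "GCGTTA", right_flank = "TTAGCC")
    expect_identical(ann$tirs$length, 23L)
    expect_identical(ann$tirs$mismatch_positions, 17L)
    expect_identical(ann$orf$interval, c(34L, 891L))
    expect_identical(ann$orf$strand, "+")
    expect_identical(ann$tsd$sequence, "TTA")
    top <- ann$promoters[1, ]
    expect_identical(c(top$minus35_start, top$minus10_start, top$spacer),
                     c(5L, 28L, 17L))
  }
})

test_that("annotation exports valid GFF3", {
  el <- build_canonical_element(spec, seed = 1)
  ann <- annotate_element(el, left_flank = "GCGTTA", right_flank = "TTAGCC",
                          strain_id = "wRef", element_interval = c(307, 1222))
  f <- tempfile(fileext = ".gff3")
  write_annotation_gff3(ann, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_true(any(grepl("terminal_inverted_repeat", body)))
  expect_true(any(grepl("CDS", body)))
  # features are in ungapped strain coordinates
  cds <- body[grepl("\tCDS\t", body)]
  expect_identical(as.integer(strsplit(cds, "\t")[[1]][4]), 307L + 33L)
})
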