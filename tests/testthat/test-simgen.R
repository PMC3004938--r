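spec <- element_spec()

test_that("canonical element honours every anatomical constraint", {
  for (seed in 1:5) {
    el <- build_canonical_element(spec, seed = seed)
    expect_identical(nchar(el), 916L)
    # starts with the left TIR, ends with the reverse complement of the
    # right inward read
    expect_identical(substr(el, 1, 23), spec$left_tir_inward)
    expect_identical(substr(el, 916 - 22, 916), rc(spec$right_tir_inward))
    # the two inward reads differ only at np 17 (A on the left, T right)
    left <- substr(el, 1, 23)
    right <- rc(substr(el, 916 - 22, 916))
    d <- which(strsplit(left, "")[[1]] != strsplit(right, "")[[1]])
    expect_identical(d, 17L)
    expect_identical(substr(left, 17, 17), "A")
    expect_identical(substr(right, 17, 17), "T")
    # promoter boxes at their np intervals with the 17-bp spacer
    expect_identical(substr(el, 5, 10), "TTGTCC")
    expect_identical(substr(el, 28, 33), "TATAAT")
    # ORF: start codon, in-frame stop only at the end
    orf <- substr(el, 34, 891)
    expect_identical(substr(orf, 1, 3), "ATG")
    cods <- substring(orf, seq(1, 856, 3), seq(3, 858, 3))
    expect_identical(which(cods %in% c("TAA", "TAG", "TGA")), 286L)
  }
})

test_that("seeds vary the filler but never the constrained positions", {
  e1 <- strsplit(build_canonical_element(spec, seed = 1), "")[[1]]
  e2 <- strsplit(build_canonical_element(spec, seed = 2), "")[[1]]
  constrained <- c(1:23, 25:36, 889:891, 894:916)
  expect_identical(e1[constrained], e2[constrained])
  expect_true(any(e1 != e2))
})

test_that("contradictory element specifications are rejected", {
  # identical TIRs: no diagnostic asymmetry
  expect_error(
    element_spec(right_tir_inward = element_spec()$left_tir_inward),
    "differ exactly")
  # mismatch position outside the TIR
  expect_error(element_spec(mismatch_np = 30), "within the TIR")
  # ORF too long for the element
  expect_error(element_spec(orf_length = 900), "too large")
  # -35 interval inconsistent with the TIR carrying it
  expect_error(element_spec(minus35_seq = "TTGACA"), "does not carry")
})

test_that("inversion operators produce the predicted sequences", {
  el <- build_canonical_element(spec, seed = 3)
  L <- spec$left_tir_inward
  R <- spec$right_tir_inward

  # whole-element inversion swaps the inward reads and is an involution
  ab <- apply_inversion_operator(el, spec, "full_ab")
  expect_identical(ab, rc(el))
  expect_identical(substr(ab, 1, 23), R)
  expect_identical(rc(substr(ab, 894, 916)), L)
  expect_identical(apply_inversion_operator(ab, spec, "full_ab"), el)

  # internal inversion: termini untouched, interior reverse-complemented
  ic <- apply_inversion_operator(el, spec, "internal_c")
  expect_identical(substr(ic, 1, 23), substr(el, 1, 23))
  expect_identical(substr(ic, 894, 916), substr(el, 894, 916))
  expect_identical(substr(ic, 18, 899), rc(substr(el, 18, 899)))

  # conversion outcomes homogenise the TIRs toward the template
  d <- apply_inversion_operator(el, spec, "conversion_left_d")
  expect_identical(substr(d, 1, 23), L)
  expect_identical(rc(substr(d, 894, 916)), L)
  e <- apply_inversion_operator(el, spec, "conversion_right_e")
  expect_identical(substr(e, 1, 23), R)
  expect_identical(rc(substr(e, 894, 916)), R)
  # interiors of all internal-breakpoint scenarios agree
  expect_identical(substr(d, 24, 893), substr(ic, 24, 893))

  expect_identical(apply_inversion_operator(el, spec, "excision"), "")
  expect_error(apply_inversion_operator("ACGTACGT", spec, "full_ab"),
               "malformed")
})

test_that("simulated locus realises the configured history exactly", {
  nwk <- paste0("(((((A:1,B:1):1,C:1):1,(D:1,E:1):1):1,(F:1,G:1):1):1,",
                "((H:1,I:1):1,J:1):1);")
  cfg <- sim_config(tree = nwk,
                    insertion_clade = c("A", "B", "C", "D", "E"),
                    inversion_clade = c("A", "B"),
                    scenario = "conversion_left_d",
                    mutation_rate = 0, seed = 9)
  sim <- simulate_locus(cfg, spec)

  tab <- table(sim$truth$state)
  expect_identical(as.integer(tab[c("absent", "canonical", "inverted")]),
                   c(5L, 3L, 2L))
  # absence is one contiguous gap block spanning element + second TSD copy
  gap_rows <- sim$alignment[c("F", "G", "H", "I", "J")]
  for (row in gap_rows) {
    expect_identical(substr(row, 304, 1222), strrep("-", 919))
    expect_false(grepl("-", paste0(substr(row, 1, 303),
                                   substr(row, 1223, 1522))))
  }
  # with no point mutations all uninserted strains are identical
  expect_identical(length(unique(gap_rows)), 1L)
  # carriers are gap-free; TSD copies flank the element
  for (s in c("A", "B", "C", "D", "E")) {
    row <- sim$alignment[[s]]
    expect_false(grepl("-", row))
    expect_identical(substr(row, 301, 303), "TTA")
    expect_identical(substr(row, 1220, 1222), "TTA")
  }
  # inverted strains carry the conversion-d element, canonical strains the
  # canonical one
  expect_identical(substr(sim$alignment[["A"]], 304, 1219),
                   apply_inversion_operator(sim$element, spec,
                                            "conversion_left_d"))
  expect_identical(substr(sim$alignment[["C"]], 304, 1219), sim$element)
  # events sit on the branches to the two clade ancestors
  expect_identical(sort(sim$events$type), c("insertion", "inversion"))
})

test_that("precise excision restores the uninserted haplotype", {
  nwk <- paste0("(((((A:1,B:1):1,C:1):1,(D:1,E:1):1):1,(F:1,G:1):1):1,",
                "((H:1,I:1):1,J:1):1);")
  cfg <- sim_config(tree = nwk,
                    insertion_clade = c("A", "B", "C", "D", "E"),
                    inversion_clade = c("A", "B"),
                    scenario = "excision",
                    mutation_rate = 0, seed = 9)
  sim <- simulate_locus(cfg, spec)
  # excised strains are byte-identical to never-inserted strains: flanks
  # joined at a single target-site copy
  expect_identical(sim$alignment[["A"]], sim$alignment[["J"]])
  expect_identical(sim$truth$state[sim$truth$strain == "A"], "absent")
})

test_that("the same seed reproduces the simulation byte for byte", {
  cfg <- sim_config(n_strains = 12, seed = 77)
  s1 <- simulate_locus(cfg, spec)
  s2 <- simulate_locus(cfg, spec)
  expect_identical(s1$alignment, s2$alignment)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$events, s2$events)

  d1 <- tempfile()
  d2 <- tempfile()
  p1 <- write_sim(s1, d1)
  p2 <- write_sim(s2, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
})

test_that("invalid clade configurations are rejected", {
  nwk <- "((A:1,B:1):1,(C:1,D:1):1);"
  expect_error(
    simulate_locus(sim_config(tree = nwk,
                              insertion_clade = c("A", "B"),
                              inversion_clade = c("C", "D"), seed = 1)),
    "strict subset")
  expect_error(
    simulate_locus(sim_config(tree = nwk,
                              insertion_clade = c("A", "B", "C", "D"),
                              inversion_clade = c("A", "B"), seed = 1)),
    "exclude at least one")
  expect_error(
    simulate_locus(sim_config(tree = "((A:1,C:1):1,(B:1,D:1):1);",
                              insertion_clade = c("A", "B"),
                              inversion_clade = "A", seed = 1)),
    "not monophyletic")
})

test_that("branch mutation counts follow the binomial expectation", {
  cfg <- sim_config(n_strains = 20, mutation_rate = 0.01,
                    protect_features = FALSE, scenario = "none", seed = 123)
  sim <- simulate_locus(cfg, spec)
  b <- sim$branches
  p <- pmin(0.01 * b$length, 0.75)
  mu <- sum(b$n_sites * p)
  sdv <- sqrt(sum(b$n_sites * p * (1 - p)))
  obs <- sum(b$n_mutations)
  expect_gt(obs, mu - 4 * sdv)
  expect_lt(obs, mu + 4 * sdv)
})

test_that("feature protection keeps diagnostic windows mutation-free", {
  cfg <- sim_config(n_strains = 10, mutation_rate = 0.05,
                    protect_features = TRUE, scenario = "none", seed = 31)
  sim <- simulate_locus(cfg, spec)
  for (s in sim$insertion_clade) {
    row <- sim$alignment[[s]]
    expect_identical(substr(row, 301, 303), "TTA")
    expect_identical(substr(row, 304, 304 + 59), substr(sim$element, 1, 60))
    expect_identical(substr(row, 1219 - 59, 1219),
                     substr(sim$element, 857, 916))
  }
})
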