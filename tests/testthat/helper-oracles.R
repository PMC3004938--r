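# Independent oracles and fixture builders. All oracles here are written
# from scratch (naive enumeration / direct string manipulation) so that
# they share no code path with the package implementation they check.

# reverse complement without Biostrings
rc <- function(s) {
  if (!nzchar(s)) return("")
  paste(rev(strsplit(chartr("ACGTN-", "TGCAN-", s), "")[[1]]),
        collapse = "")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# largest k whose prefix equals the reverse complement of the suffix
# exactly (the d_max = 0 case), by scanning every k
brute_tir_exact <- function(el, k_min = 10, k_max = 50) {
  n <- nchar(el)
  best <- 0L
  for (k in seq(k_min, min(k_max, n %/% 2))) {
    if (substr(el, 1, k) == rc(substr(el, n - k + 1, n))) best <- k
  }
  best
}

# exhaustive (start, stop) pairing over both strands; same ORF definition
# as the package but built by double loop over codon positions
brute_longest_orf <- function(el, min_len) {
  starts <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  scan <- function(s) {
    n <- nchar(s)
    hits <- list()
    for (frame in 0:2) {
      pos <- seq(frame + 1, n - 2, by = 3)
      cods <- substring(s, pos, pos + 2)
      last_stop <- 0
      i_start <- NA
      for (i in seq_along(cods)) {
        if (is.na(i_start) && cods[i] %in% starts) i_start <- i
        if (cods[i] %in% stops) {
          if (!is.na(i_start)) {
            hits[[length(hits) + 1]] <- c(pos[i_start], pos[i] + 2)
          }
          i_start <- NA
        }
      }
    }
    hits
  }
  n <- nchar(el)
  all <- list()
  for (h in scan(el)) {
    all[[length(all) + 1]] <- list(start = h[1], end = h[2],
                                   len = h[2] - h[1] + 1, strand = "+")
  }
  for (h in scan(rc(el))) {
    all[[length(all) + 1]] <- list(start = n - h[2] + 1, end = n - h[1] + 1,
                                   len = h[2] - h[1] + 1, strand = "-")
  }
  all <- Filter(function(o) o$len >= min_len, all)
  if (!length(all)) return(NULL)
  df <- do.call(rbind, lapply(all, as.data.frame))
  df <- df[order(-df$len, df$strand != "+", df$start), ]
  df[1, ]
}

# exhaustive double loop over all (-35, -10) hexamer pairs
brute_promoters <- function(el, window = 60, spacers = 15:19,
                            max_soft = 2) {
  win <- substr(el, 1, window)
  score_hex <- function(hex, cons, conserved) {
    h <- strsplit(hex, "")[[1]]
    cs <- strsplit(cons, "")[[1]]
    if (any(h[conserved] != cs[conserved])) return(NA)
    soft <- setdiff(1:6, conserved)
    mm <- sum(h[soft] != cs[soft])
    if (mm > max_soft) return(NA)
    6 - mm
  }
  rows <- list()
  for (s1 in 1:(window - 5)) {
    sc35 <- score_hex(substr(win, s1, s1 + 5), "TTGACA", c(1, 2, 3))
    if (is.na(sc35)) next
    for (s2 in 1:(window - 5)) {
      spacer <- s2 - (s1 + 5) - 1
      if (!(spacer %in% spacers)) next
      sc10 <- score_hex(substr(win, s2, s2 + 5), "TATAAT", c(1, 2, 6))
      if (is.na(sc10)) next
      rows[[length(rows) + 1]] <- data.frame(
        minus35_start = s1, minus35_end = s1 + 5,
        minus35_seq = substr(win, s1, s1 + 5),
        minus10_start = s2, minus10_end = s2 + 5,
        minus10_seq = substr(win, s2, s2 + 5),
        spacer = spacer, score = sc35 + sc10)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, abs(out$spacer - 17),
                   out$minus35_start, out$minus10_start), ]
  rownames(out) <- NULL
  out
}

# exhaustive minimum-cost reconstruction: enumerate every assignment of
# states to internal nodes (and every admissible leaf choice)
brute_reconstruction <- function(tree, leaf_allowed, C,
                                 root_state = 1L) {
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  root <- ntip + 1L
  choices <- vector("list", ntot)
  for (i in seq_len(ntip)) choices[[i]] <- leaf_allowed[[tree$tip.label[i]]]
  for (i in (ntip + 1L):ntot) choices[[i]] <- 1:3
  if (!is.null(root_state)) choices[[root]] <- root_state
  grid <- do.call(expand.grid, choices)
  costs <- apply(grid, 1, function(a) {
    sum(C[cbind(a[tree$edge[, 1]], a[tree$edge[, 2]])])
  })
  m <- min(costs)
  list(cost = m, n_opt = sum(costs == m))
}

# ten-leaf tree shaped like the published nested-clade history: a 5-leaf
# monophyletic insertion clade containing a 2-leaf inverted subclade
fig2_tree <- function() {
  read_tree(paste0("(((((A:1,B:1):1,C:1):1,(D:1,E:1):1):1,",
                   "(F:1,G:1):1):1,((H:1,I:1):1,J:1):1);"))
}

fig2_states <- function() {
  c(A = "inverted", B = "inverted", C = "canonical", D = "canonical",
    E = "canonical", F = "absent", G = "absent", H = "absent",
    I = "absent", J = "absent")
}

# expected mechanism class per simulator scenario
scenario_class <- c(
  full_ab = "full_inversion_ab",
  internal_c = "internal_inversion_c",
  conversion_left_d = "conversion_left_d",
  conversion_right_e = "conversion_right_e"
)

# run the per-locus analysis through the public API and return calls plus
# mechanism classes joined with the simulator truth
analyse_sim <- function(sim) {
  aln <- read_locus_alignment(sim$alignment,
                              reference_strain = sim$reference_strain,
                              element_interval = sim$element_interval,
                              locus_id = sim$locus_id)
  canon <- annotate_element(
    extract_ungapped(aln, aln$reference_strain, aln$element_interval)$seq,
    strain_id = aln$reference_strain)
  calls <- call_presence_orientation(aln, canonical = canon)
  classes <- vapply(seq_len(nrow(calls)), function(i) {
    sid <- calls$strain[i]
    st <- calls$state[i]
    obs <- tirinv:::new_tir_pair(0L, "", "", found = FALSE)
    if (st %in% c("canonical", "inverted")) {
      el <- extract_ungapped(aln, sid, aln$element_interval)$seq
      if (nchar(el) >= 20) obs <- detect_tirs(el)
    }
    classify_mechanism(obs, canon$tirs,
                       orientation = if (st %in% c("canonical", "inverted",
                                                   "absent")) st
                       else "ambiguous",
                       strain_id = sid)$class
  }, character(1))
  out <- data.frame(strain = calls$strain, state = calls$state,
                    class = classes)
  merge(out, sim$truth, by = "strain", suffixes = c("", ".truth"))
}

# TRUE when every strain of a simulated locus is called and classified
# in agreement with the simulator truth
sim_recovered <- function(sim) {
  # an analysis failure (e.g. mutations wrecked the reference ORF anchor)
  # counts as an unrecovered replicate
  res <- tryCatch(analyse_sim(sim), error = function(e) NULL)
  if (is.null(res)) return(FALSE)
  if (!all(res$state == res$state.truth)) return(FALSE)
  inv <- res[res$state.truth == "inverted", , drop = FALSE]
  if (nrow(inv) == 0) return(TRUE)   # excision / insertion-only histories
  all(inv$class == scenario_class[[sim$config$scenario]])
}
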