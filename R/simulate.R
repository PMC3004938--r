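# --- tree helpers (ape phylo objects) ---------------------------------------

clade_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    out <- c(out, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  tree$tip.label[sort(out)]
}

descendant_nodes <- function(tree, node) {
  n <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > n])
  }
  sort(out)
}

# node whose clade is exactly `tips`; errors when the set is not monophyletic
find_clade_node <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  node <- ape::getMRCA(tree, tips)
  if (!setequal(clade_tips(tree, node), tips)) {
    stop("leaf set {", paste(tips, collapse = ","),
         "} is not monophyletic on the tree")
  }
  node
}

node_label <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  lab <- tree$node.label[node - n]
  if (is.null(tree$node.label) || is.na(lab) || !nzchar(lab)) {
    lab <- paste0("node", node)
  }
  lab
}

# --- simulation configuration ------------------------------------------------

#' Configuration for the locus simulator
#'
#' Gathers the parameters of one simulated locus history: a strain
#' phylogeny, a monophyletic insertion clade carrying the element, a nested
#' clade in which one inversion-process outcome is applied, the target
#' site, flank length and a per-branch point-mutation rate.
#'
#' Defaults emulate the kind of data the pipeline is designed for: about
#' 20 strains, a single canonical insertion in a monophyletic subset
#' flanked by T(T/A)A target-site duplications, an inversion arising once
#' in a nested subclade, 300 bp of anchoring flank per side and a low
#' neutral substitution rate.
#'
#' @param n_strains Number of strains (tips) when `tree = "random"`.
#' @param tree `"random"` (a birth-only tree is drawn), an `ape::phylo`
#'   object, or a newick string.
#' @param birth_rate Speciation rate of the random tree.
#' @param insertion_clade `"random"` or a character vector of strain names
#'   (must be monophyletic and exclude at least one strain).
#' @param inversion_clade `"random"` or a character vector of strain names
#'   (must be a strict, monophyletic subset of the insertion clade).
#' @param scenario Inversion-process operator applied in the inversion
#'   clade: one of `"full_ab"`, `"internal_c"`, `"conversion_left_d"`,
#'   `"conversion_right_e"`, `"excision"`, or `"none"` for a locus with a
#'   canonical insertion only.
#' @param target_site Insertion target 3-mer; T(T/A)A for this family.
#' @param flank_length Genomic anchor length per side (bp).
#' @param mutation_rate Substitutions per site per unit branch length
#'   (Jukes-Cantor; no indels beyond the event-level ones).
#' @param protect_features When `TRUE`, mutations never hit the diagnostic
#'   feature windows (target-site copies and the first/last 60 bp of the
#'   element, which contain the TIRs, promoter boxes, boundary breakers and
#'   ORF start/stop in either orientation).
#' @param seed Integer seed; fully determines the simulated output.
#' @param locus_id Label carried into outputs.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_locus()]
#' @export
sim_config <- function(n_strains = 20L,
                       tree = "random",
                       birth_rate = 1,
                       insertion_clade = "random",
                       inversion_clade = "random",
                       scenario = c("conversion_left_d", "full_ab",
                                    "internal_c", "conversion_right_e",
                                    "excision", "none"),
                       target_site = "TTA",
                       flank_length = 300L,
                       mutation_rate = 0.005,
                       protect_features = TRUE,
                       seed = 1L,
                       locus_id = "locus01") {
  scenario <- match.arg(scenario)
  if (!grepl("^T[TA]A$", target_site)) {
    stop("`target_site` must match the T(T/A)A motif")
  }
  if (flank_length < 10L) stop("`flank_length` must be at least 10 bp")
  if (mutation_rate < 0) stop("`mutation_rate` must be non-negative")
  structure(
    list(
      n_strains = as.integer(n_strains),
      tree = tree,
      birth_rate = birth_rate,
      insertion_clade = insertion_clade,
      inversion_clade = inversion_clade,
      scenario = scenario,
      target_site = toupper(target_site),
      flank_length = as.integer(flank_length),
      mutation_rate = mutation_rate,
      protect_features = isTRUE(protect_features),
      seed = as.integer(seed),
      locus_id = locus_id
    ),
    class = "sim_config"
  )
}

resolve_tree <- function(config) {
  tr <- config$tree
  if (inherits(tr, "phylo")) return(tr)
  if (identical(tr, "random")) {
    tree <- ape::rphylo(config$n_strains, birth = config$birth_rate,
                        death = 0)
    tree$tip.label <- sprintf("S%02d", seq_len(config$n_strains))
    return(tree)
  }
  if (is.character(tr) && length(tr) == 1L) {
    return(if (file.exists(tr)) ape::read.tree(tr)
           else ape::read.tree(text = tr))
  }
  stop("`tree` must be \"random\", a phylo object, or newick text/path")
}

# --- forward simulation ------------------------------------------------------

#' Forward-simulate one locus alignment with ground truth
#'
#' Simulates the evolutionary history of one IS insertion locus on a strain
#' phylogeny and returns the resulting multi-strain alignment together
#' with complete ground truth. The ancestral locus is random flanking
#' sequence joined at a single target-site copy. On the branch leading to
#' the insertion clade's ancestor the element is inserted, duplicating the
#' target site; on the branch leading to the nested inversion clade's
#' ancestor the configured scenario operator is applied
#' ([apply_inversion_operator()]). Point mutations accumulate on every
#' branch (probability `mutation_rate * branch_length` per eligible site,
#' Jukes-Cantor). Because the only length changes are the event-level ones,
#' the alignment is exact by construction: strains lacking the element
#' carry one contiguous gap block spanning the element plus the second
#' target-site copy.
#'
#' @param config A [sim_config()].
#' @param spec An [element_spec()] describing the canonical element.
#' @return An object of class `locus_sim` with fields:
#'   `locus_id`; `alignment` (named character vector of equal-length
#'   aligned rows); `tree` (`phylo`); `element` (canonical top strand);
#'   `element_interval` (1-based alignment-column interval of the
#'   element); `reference_strain` (a canonical-state strain);
#'   `truth` (data frame: strain, state in absent/canonical/inverted,
#'   scenario, element start/end in ungapped strain coordinates);
#'   `events` (data frame: branch, type, scenario); `branches` (per-branch
#'   mutation bookkeeping: child label, branch length, eligible sites,
#'   mutations placed); `insertion_clade`, `inversion_clade`; `spec`;
#'   `config`.
#' @examples
#' sim <- simulate_locus(sim_config(n_strains = 8, seed = 42))
#' sim
#' @export
simulate_locus <- function(config = sim_config(), spec = element_spec()) {
  stopifnot(inherits(config, "sim_config"))
  validate_element_spec(spec)

  withr::with_seed(config$seed, {
    tree <- resolve_tree(config)
    n <- length(tree$tip.label)
    if (n < 4L) stop("at least 4 strains are required")
    root <- n + 1L

    # --- event clades ---
    sizes <- vapply((n + 1L):(n + tree$Nnode), function(nd)
      length(clade_tips(tree, nd)), integer(1))
    if (identical(config$insertion_clade, "random")) {
      cand <- ((n + 1L):(n + tree$Nnode))[sizes >= 3L & sizes <= n - 2L]
      cand <- setdiff(cand, root)
      if (!length(cand)) stop("tree admits no suitable insertion clade")
      ins_node <- if (length(cand) == 1L) cand else sample(cand, 1L)
    } else {
      ins_node <- find_clade_node(tree, config$insertion_clade)
      if (ins_node == root) {
        stop("configuration error: the insertion clade must exclude at ",
             "least one strain (the flank anchors need an uninserted state)")
      }
    }
    ins_tips <- clade_tips(tree, ins_node)

    inv_node <- NA_integer_
    inv_tips <- character(0)
    if (config$scenario != "none") {
      if (identical(config$inversion_clade, "random")) {
        cand <- descendant_nodes(tree, ins_node)
        # keep a canonical-state strain around to serve as reference
        cand <- cand[vapply(cand, function(nd)
          length(clade_tips(tree, nd)), integer(1)) <= length(ins_tips) - 1L]
        inv_node <- if (length(cand) == 1L) cand else sample(cand, 1L)
      } else {
        if (!all(config$inversion_clade %in% ins_tips) ||
            setequal(config$inversion_clade, ins_tips)) {
          stop("configuration error: the inversion clade must be a strict ",
               "subset of the insertion clade")
        }
        inv_node <- find_clade_node(tree, config$inversion_clade)
      }
      inv_tips <- clade_tips(tree, inv_node)
    }

    # --- canonical element and locus geometry ---
    element <- build_canonical_element(
      spec, seed = sample.int(.Machine$integer.max, 1L))
    fl <- config$flank_length
    L <- spec$total_length
    ts <- chars(config$target_site)
    tlen <- length(ts)
    ncol_aln <- 2L * fl + 2L * tlen + L
    tsd1_cols <- (fl + 1L):(fl + tlen)
    el_cols <- (fl + tlen + 1L):(fl + tlen + L)
    tsd2_cols <- (fl + tlen + L + 1L):(fl + 2L * tlen + L)
    block_cols <- c(el_cols, tsd2_cols)

    protected <- integer(0)
    if (config$protect_features) {
      w <- min(60L, L %/% 2L)
      protected <- c(tsd1_cols, tsd2_cols,
                     el_cols[c(seq_len(w), (L - w + 1L):L)])
    }

    root_seq <- rep(NA_character_, ncol_aln)
    root_seq[tsd1_cols] <- ts
    root_seq[block_cols] <- "-"
    flank_pos <- which(is.na(root_seq))
    root_seq[flank_pos] <- sample(DNA_BASES, length(flank_pos),
                                  replace = TRUE)

    # --- evolve along the tree (parents before children) ---
    tree_cw <- ape::reorder.phylo(tree, "cladewise")
    seqs <- vector("list", n + tree$Nnode)
    seqs[[root]] <- root_seq
    events <- list()
    branches <- list()

    for (i in seq_len(nrow(tree_cw$edge))) {
      parent <- tree_cw$edge[i, 1L]
      child <- tree_cw$edge[i, 2L]
      bl <- tree_cw$edge.length[i]
      s <- seqs[[parent]]

      if (!is.na(ins_node) && child == ins_node) {
        s[el_cols] <- chars(element)
        s[tsd2_cols] <- s[tsd1_cols]
        events[[length(events) + 1L]] <- data.frame(
          branch = node_label(tree, child), type = "insertion",
          scenario = "canonical")
      }
      if (!is.na(inv_node) && child == inv_node) {
        cur <- paste(s[el_cols], collapse = "")
        new_el <- apply_inversion_operator(cur, spec, config$scenario)
        if (config$scenario == "excision") {
          s[block_cols] <- "-"
          events[[length(events) + 1L]] <- data.frame(
            branch = node_label(tree, child), type = "excision",
            scenario = config$scenario)
        } else {
          s[el_cols] <- chars(new_el)
          events[[length(events) + 1L]] <- data.frame(
            branch = node_label(tree, child), type = "inversion",
            scenario = config$scenario)
        }
      }

      sites <- which(s != "-")
      if (length(protected)) sites <- setdiff(sites, protected)
      p <- min(config$mutation_rate * bl, 0.75)
      n_mut <- 0L
      if (p > 0 && length(sites)) {
        hit <- sites[stats::runif(length(sites)) < p]
        n_mut <- length(hit)
        for (h in hit) {
          s[h] <- sample(setdiff(DNA_BASES, s[h]), 1L)
        }
      }
      branches[[length(branches) + 1L]] <- data.frame(
        branch = node_label(tree, child), length = bl,
        n_sites = length(sites), n_mutations = n_mut)
      seqs[[child]] <- s
    }

    alignment <- vapply(seq_len(n), function(i)
      paste(seqs[[i]], collapse = ""), character(1))
    names(alignment) <- tree$tip.label

    # --- ground truth ---
    state <- ifelse(
      tree$tip.label %in% inv_tips,
      if (config$scenario == "excision") "absent" else "inverted",
      ifelse(tree$tip.label %in% ins_tips, "canonical", "absent"))
    scen <- ifelse(tree$tip.label %in% inv_tips, config$scenario, "none")
    carrier <- state != "absent"
    truth <- data.frame(
      strain = tree$tip.label,
      state = state,
      scenario = scen,
      element_start = ifelse(carrier, fl + tlen + 1L, NA_integer_),
      element_end = ifelse(carrier, fl + tlen + L, NA_integer_)
    )

    ref_cand <- tree$tip.label[tree$tip.label %in% setdiff(ins_tips,
                                                           inv_tips)]
    if (!length(ref_cand)) stop("no canonical-state strain left to serve ",
                                "as reference")

    structure(
      list(
        locus_id = config$locus_id,
        alignment = alignment,
        tree = tree,
        element = element,
        element_interval = c(el_cols[1L], el_cols[L]),
        reference_strain = ref_cand[1L],
        truth = truth,
        events = if (length(events)) do.call(rbind, events) else
          data.frame(branch = character(0), type = character(0),
                     scenario = character(0)),
        branches = do.call(rbind, branches),
        insertion_clade = ins_tips,
        inversion_clade = inv_tips,
        spec = spec,
        config = config
      ),
      class = "locus_sim"
    )
  })
}

#' @export
print.locus_sim <- function(x, ...) {
  tab <- table(factor(x$truth$state,
                      levels = c("absent", "canonical", "inverted")))
  cat(sprintf("Simulated locus '%s': %d strains, %d alignment columns\n",
              x$locus_id, length(x$alignment), nchar(x$alignment[[1L]])))
  cat(sprintf("  states   : %d absent, %d canonical, %d inverted\n",
              tab[["absent"]], tab[["canonical"]], tab[["inverted"]]))
  cat(sprintf("  scenario : %s\n", x$config$scenario))
  cat(sprintf("  events   : %s\n",
              if (nrow(x$events)) paste(x$events$type, "on", x$events$branch,
                                        collapse = "; ") else "none"))
  cat(sprintf("  reference: %s\n", x$reference_strain))
  invisible(x)
}

#' Simulate a batch of loci on a shared strain phylogeny
#'
#' Draws one strain tree, then simulates `n_loci` independent insertion
#' loci on it. The first `inverted_loci` loci receive an inversion event
#' (scenario from `config`); the remainder carry a canonical insertion
#' only. Insertion/inversion clades are drawn independently per locus.
#'
#' @param config Template [sim_config()]; its `seed` seeds the batch and
#'   per-locus seeds are derived from it.
#' @param spec An [element_spec()].
#' @param n_loci Number of loci.
#' @param inverted_loci Number of loci (taken first) that receive an
#'   inversion event.
#' @return A list with `tree` and `loci` (list of `locus_sim`).
#' @examples
#' batch <- simulate_batch(sim_config(n_strains = 8, seed = 7),
#'                         n_loci = 3, inverted_loci = 1)
#' length(batch$loci)
#' @export
simulate_batch <- function(config = sim_config(), spec = element_spec(),
                           n_loci = 22L, inverted_loci = 2L) {
  stopifnot(inherits(config, "sim_config"))
  n_loci <- as.integer(n_loci)
  inverted_loci <- as.integer(inverted_loci)
  stopifnot(n_loci >= 0L, inverted_loci >= 0L, inverted_loci <= n_loci)
  out <- withr::with_seed(config$seed, {
    tree <- resolve_tree(config)
    locus_seeds <- sample.int(.Machine$integer.max, max(n_loci, 1L))
    list(tree = tree, locus_seeds = locus_seeds)
  })
  loci <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    cfg_i <- config
    cfg_i$tree <- out$tree
    cfg_i$insertion_clade <- "random"
    cfg_i$inversion_clade <- "random"
    cfg_i$scenario <- if (i <= inverted_loci) config$scenario else "none"
    cfg_i$seed <- out$locus_seeds[i]
    cfg_i$locus_id <- sprintf("locus%02d", i)
    loci[[i]] <- simulate_locus(cfg_i, spec)
  }
  list(tree = out$tree, loci = loci)
}

#' Write a simulated locus to disk
#'
#' Emits the aligned FASTA, the strain tree (newick), the truth table
#' (TSV), the event log (JSON) and a metadata sidecar (JSON: locus id,
#' reference strain, element column interval) that
#' [read_locus_alignment()] can consume.
#'
#' @param sim A [simulate_locus()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "locus_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, sim$locus_id)
  paths <- c(
    fasta = paste0(base, ".fasta"),
    tree = paste0(base, ".nwk"),
    truth = paste0(base, ".truth.tsv"),
    events = paste0(base, ".events.json"),
    meta = paste0(base, ".meta.json")
  )
  write_fasta(sim$alignment, paths[["fasta"]])
  ape::write.tree(sim$tree, file = paths[["tree"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(locus_id = sim$locus_id, events = sim$events),
    paths[["events"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(locus_id = sim$locus_id,
         reference_strain = sim$reference_strain,
         element_interval = sim$element_interval),
    paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
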