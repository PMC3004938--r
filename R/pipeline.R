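# orientation-call states -> leaf states for the event reconstruction
calls_to_leaf_states <- function(calls, present_min = 0.50) {
  st <- ifelse(
    calls$state == "ambiguous" & calls$non_gap_fraction >= present_min,
    "ambiguous_orientation",
    ifelse(calls$state == "ambiguous", "unknown", calls$state))
  stats::setNames(as.list(st), calls$strain)
}

# annotate + classify every strain of one locus alignment
process_locus <- function(aln, tree = NULL, orf_min_len = 300L) {
  ref <- extract_ungapped(aln, aln$reference_strain, aln$element_interval)
  ref_flanks <- list(
    left = extract_ungapped(aln, aln$reference_strain,
                            c(1L, aln$element_interval[1L] - 1L))$seq,
    right = extract_ungapped(aln, aln$reference_strain,
                             c(aln$element_interval[2L] + 1L,
                               nchar(aln$strains[[1L]])))$seq)
  canonical <- annotate_element(ref$seq, left_flank = ref_flanks$left,
                                right_flank = ref_flanks$right,
                                strain_id = aln$reference_strain,
                                orf_min_len = orf_min_len)
  calls <- call_presence_orientation(aln, canonical = canonical,
                                     orf_min_len = orf_min_len)

  mech <- lapply(seq_len(nrow(calls)), function(i) {
    sid <- calls$strain[i]
    state <- calls$state[i]
    obs <- new_tir_pair(0L, "", "", found = FALSE)
    if (state %in% c("canonical", "inverted")) {
      el <- extract_ungapped(aln, sid, aln$element_interval)$seq
      if (nchar(el) >= 2L * 10L) obs <- detect_tirs(el)
    }
    mc <- classify_mechanism(obs, canonical$tirs,
                             orientation = if (state %in%
                                               c("canonical", "inverted",
                                                 "absent")) state else
                               "ambiguous",
                             strain_id = sid)
    data.frame(locus = aln$locus_id, strain = sid, class = mc$class,
               left_match = mc$left_match, right_match = mc$right_match)
  })
  mechanisms <- do.call(rbind, mech)

  reconstruction <- NULL
  if (!is.null(tree)) {
    reconstruction <- reconstruct_events(tree, calls_to_leaf_states(calls))
  }

  list(locus_id = aln$locus_id, calls = calls, canonical = canonical,
       mechanisms = mechanisms, reconstruction = reconstruction)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) - presence/orientation calling -
#' element annotation - mechanism classification - event reconstruction
#' over a batch of loci, and assembles a consolidated report. Two input
#' modes:
#'
#' * **simulate**: `config$simulate` describes a synthetic batch
#'   ([simulate_batch()] parameters); alignments and the shared tree come
#'   from the simulator and ground truth is carried into the report.
#' * **manifest**: `config$loci` lists alignments on disk (fields `path`
#'   plus optionally `locus_id`, `reference_strain`, `element_start`,
#'   `element_end`; sidecar metadata fills the gaps) and `config$tree`
#'   names the strain phylogeny.
#'
#' The summary counts loci screened and loci with at least one strain
#' called inverted; their ratio is the reported inverted-locus fraction.
#'
#' @param config A list, or a path to a YAML/JSON file with the fields
#'   above plus optional `seed` and `out_dir`.
#' @param out_dir Output directory; when set (or named in the config),
#'   `summary.tsv`, `calls.tsv`, `mechanisms.tsv`, `events.tsv` and
#'   `report.json` are written there.
#' @param seed Integer seed; a value in the config wins over this argument
#'   (with a warning) so that configs stay self-contained.
#' @return An object of class `pipeline_report`.
#' @examples
#' cfg <- list(seed = 11,
#'             simulate = list(n_loci = 3, inverted_loci = 1,
#'                             n_strains = 8, mutation_rate = 0))
#' rep <- run_pipeline(cfg)
#' rep$summary$fraction_inverted
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  if (!is.null(config$seed) && !is.null(seed) &&
      as.integer(config$seed) != as.integer(seed)) {
    warning("both the config and the `seed` argument set a seed; ",
            "the config value (", config$seed, ") wins")
  }
  seed <- as.integer(config$seed %||% seed %||% 1L)
  out_dir <- config$out_dir %||% out_dir

  tree <- NULL
  truth <- NULL
  alns <- list()

  if (!is.null(config$simulate)) {
    sb <- config$simulate
    cfg <- sim_config(
      n_strains = sb$n_strains %||% 20L,
      tree = sb$tree %||% "random",
      birth_rate = sb$birth_rate %||% 1,
      scenario = sb$scenario %||% "conversion_left_d",
      target_site = sb$target_site %||% "TTA",
      flank_length = sb$flank_length %||% 300L,
      mutation_rate = sb$mutation_rate %||% 0.005,
      protect_features = sb$protect_features %||% TRUE,
      seed = seed
    )
    batch <- simulate_batch(cfg, spec = element_spec(),
                            n_loci = sb$n_loci %||% 22L,
                            inverted_loci = sb$inverted_loci %||% 2L)
    tree <- batch$tree
    truth <- do.call(rbind, lapply(batch$loci, function(s)
      cbind(locus = s$locus_id, s$truth)))
    alns <- lapply(batch$loci, function(s) {
      read_locus_alignment(s$alignment,
                           reference_strain = s$reference_strain,
                           element_interval = s$element_interval,
                           locus_id = s$locus_id)
    })
  } else if (!is.null(config$loci)) {
    manifest <- as.data.frame(config$loci)
    if (!"path" %in% names(manifest)) {
      stop("manifest mode needs a `loci` table with a `path` column")
    }
    if (!is.null(config$tree)) tree <- read_tree(config$tree)
    alns <- lapply(seq_len(nrow(manifest)), function(i) {
      row <- manifest[i, , drop = FALSE]
      ei <- NULL
      if (all(c("element_start", "element_end") %in% names(row)) &&
          !is.na(row$element_start)) {
        ei <- c(row$element_start, row$element_end)
      }
      read_locus_alignment(
        row$path,
        reference_strain = if ("reference_strain" %in% names(row))
          row$reference_strain else NULL,
        element_interval = ei,
        locus_id = if ("locus_id" %in% names(row)) row$locus_id else NULL)
    })
  }

  results <- lapply(alns, process_locus, tree = tree)

  locus_rows <- lapply(results, function(r) {
    inv <- sum(r$calls$state == "inverted")
    data.frame(
      locus = r$locus_id,
      n_strains = nrow(r$calls),
      n_present = sum(r$calls$state %in% c("canonical", "inverted")),
      n_inverted = inv,
      has_inversion = inv > 0L,
      parsimony_cost = if (!is.null(r$reconstruction))
        r$reconstruction$total_cost else NA_real_
    )
  })
  locus_summary <- if (length(locus_rows)) do.call(rbind, locus_rows) else
    data.frame(locus = character(0), n_strains = integer(0),
               n_present = integer(0), n_inverted = integer(0),
               has_inversion = logical(0), parsimony_cost = numeric(0))

  n_loci <- nrow(locus_summary)
  n_inverted_loci <- sum(locus_summary$has_inversion)
  report <- structure(
    list(
      summary = list(
        n_loci = n_loci,
        n_inverted_loci = n_inverted_loci,
        fraction_inverted = if (n_loci > 0L) n_inverted_loci / n_loci else
          NA_real_
      ),
      locus_summary = locus_summary,
      loci = results,
      tree = tree,
      truth = truth,
      seed = seed
    ),
    class = "pipeline_report"
  )
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' Write the pipeline report files
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    summary = file.path(out_dir, "summary.tsv"),
    calls = file.path(out_dir, "calls.tsv"),
    mechanisms = file.path(out_dir, "mechanisms.tsv"),
    events = file.path(out_dir, "events.tsv"),
    report = file.path(out_dir, "report.json")
  )
  utils::write.table(report$locus_summary, paths[["summary"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  calls <- do.call(rbind, lapply(report$loci, function(r)
    cbind(locus = r$locus_id, r$calls)))
  utils::write.table(calls, paths[["calls"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mech <- do.call(rbind, lapply(report$loci, function(r) r$mechanisms))
  utils::write.table(mech, paths[["mechanisms"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ev <- do.call(rbind, lapply(report$loci, function(r) {
    if (is.null(r$reconstruction) || !nrow(r$reconstruction$events)) {
      return(NULL)
    }
    cbind(locus = r$locus_id, r$reconstruction$events)
  }))
  if (is.null(ev)) {
    ev <- data.frame(locus = character(0), branch = character(0),
                     from = character(0), to = character(0),
                     type = character(0))
  }
  utils::write.table(ev, paths[["events"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(
      summary = report$summary,
      loci = lapply(report$loci, function(r) list(
        locus_id = r$locus_id,
        n_inverted = sum(r$calls$state == "inverted"),
        classes = stats::setNames(as.list(r$mechanisms$class),
                                  r$mechanisms$strain),
        parsimony_cost = if (!is.null(r$reconstruction))
          r$reconstruction$total_cost else NULL,
        events = if (!is.null(r$reconstruction)) r$reconstruction$events
          else NULL
      )),
      seed = report$seed
    ),
    paths[["report"]], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("IS inversion pipeline report\n")
  cat(sprintf("  loci screened          : %d\n", s$n_loci))
  cat(sprintf("  loci with >=1 inverted : %d\n", s$n_inverted_loci))
  if (s$n_loci > 0L) {
    cat(sprintf("  inverted-locus fraction: %d/%d = %.1f%%\n",
                s$n_inverted_loci, s$n_loci, 100 * s$fraction_inverted))
  }
  inv <- x$locus_summary[x$locus_summary$has_inversion, , drop = FALSE]
  if (nrow(inv)) {
    cat("  inverted loci:\n")
    for (i in seq_len(nrow(inv))) {
      cat(sprintf("    %s (%d inverted strain%s)\n", inv$locus[i],
                  inv$n_inverted[i], if (inv$n_inverted[i] == 1) "" else "s"))
    }
  }
  invisible(x)
}

#' @export
summary.pipeline_report <- function(object, ...) {
  print(object)
  invisible(object$summary)
}
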