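EVENT_STATES <- c("absent", "canonical", "inverted")

#' Transition-cost model for locus states
#'
#' States are `absent` (no element), `canonical` (element in reference
#' orientation) and `inverted`. The default costs charge 1 for an
#' insertion (absent to canonical), 1 for an inversion in either
#' direction, 1 for a deletion from either carrier state, and 2 for a
#' direct absent-to-inverted gain (equal to insertion plus inversion, so
#' the two routes tie and the tie-break resolves them reproducibly).
#' The diagonal is zero.
#'
#' @param cost Optional 3x3 numeric matrix (rows = parent state, columns =
#'   child state, order absent/canonical/inverted) overriding the default.
#'   Must be non-negative with a zero diagonal; `Inf` entries forbid a
#'   transition.
#' @return An object of class `event_model`.
#' @examples
#' event_model()
#' @export
event_model <- function(cost = NULL) {
  if (is.null(cost)) {
    cost <- matrix(c(
      0, 1, 2,
      1, 0, 1,
      1, 1, 0
    ), nrow = 3L, byrow = TRUE)
  }
  cost <- as.matrix(cost)
  dimnames(cost) <- list(EVENT_STATES, EVENT_STATES)
  if (!all(dim(cost) == c(3L, 3L))) stop("`cost` must be 3x3")
  if (any(cost < 0, na.rm = TRUE)) stop("`cost` must be non-negative")
  if (any(diag(cost) != 0)) stop("`cost` must have a zero diagonal")
  structure(list(states = EVENT_STATES, cost = cost), class = "event_model")
}

#' Read and root a strain phylogeny
#'
#' Thin wrapper over `ape` newick parsing with the validation the event
#' reconstruction needs: unique leaf labels and a rooted tree. Unrooted
#' input is rooted at `outgroup` when given, otherwise midpoint-rooted
#' (with a message, since the rooting then carries an assumption).
#'
#' @param x Newick text, a file path, or an `ape::phylo` object.
#' @param outgroup Optional tip label (or vector) to root on.
#' @return A rooted `phylo` object.
#' @examples
#' tr <- read_tree("((A,B),C);")
#' ape::Ntip(tr)
#' @export
read_tree <- function(x, outgroup = NULL) {
  if (inherits(x, "phylo")) {
    tree <- x
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    tree <- tryCatch(
      if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x),
      error = function(e) NULL)
    if (is.null(tree)) stop("newick parse failure")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else if (!ape::is.rooted(tree)) {
    if (!requireNamespace("phangorn", quietly = TRUE)) {
      stop("unrooted input: supply `outgroup` or install phangorn for ",
           "midpoint rooting")
    }
    message("unrooted input tree: midpoint-rooted")
    tree <- phangorn::midpoint(tree)
  }
  tree
}

# normalise leaf states to a logical allowed-matrix (tips x 3)
leaf_state_matrix <- function(tree, leaf_states) {
  tips <- tree$tip.label
  allowed <- matrix(FALSE, nrow = length(tips), ncol = 3L,
                    dimnames = list(tips, EVENT_STATES))
  expand <- function(v) {
    if (is.numeric(v)) v <- EVENT_STATES[v + 1L]
    v <- as.character(v)
    out <- unique(unlist(lapply(v, function(s) {
      switch(s,
             absent = "absent",
             canonical = "canonical",
             inverted = "inverted",
             # present element, orientation undetermined
             ambiguous_orientation = c("canonical", "inverted"),
             # presence itself undetermined
             ambiguous = ,
             unknown = EVENT_STATES,
             stop("unknown leaf state '", s, "'"))
    })))
    out
  }
  if (is.data.frame(leaf_states)) {
    stopifnot(all(c("strain", "state") %in% names(leaf_states)))
    ls <- stats::setNames(as.list(leaf_states$state), leaf_states$strain)
  } else if (is.list(leaf_states)) {
    ls <- leaf_states
  } else {
    ls <- as.list(leaf_states)
  }
  missing <- setdiff(tips, names(ls))
  extra <- setdiff(names(ls), tips)
  if (length(missing) || length(extra)) {
    stop("reconciliation error: ",
         if (length(missing)) paste0("leaves without a state: {",
                                     paste(missing, collapse = ","), "} "),
         if (length(extra)) paste0("states without a leaf: {",
                                   paste(extra, collapse = ","), "}"))
  }
  for (tip in tips) allowed[tip, expand(ls[[tip]])] <- TRUE
  allowed
}

#' Reconstruct insertion/inversion/deletion events by weighted parsimony
#'
#' Sankoff dynamic programming over a rooted tree: for every node and
#' state, the minimal total transition cost of the subtree is computed
#' from the tips up; one minimal ancestral-state assignment is then
#' recovered by a deterministic backtrace (ties resolved toward the
#' lower state index: absent < canonical < inverted), and the number of
#' co-optimal assignments is counted so the ambiguity is quantified rather
#' than hidden. Events are the per-branch state transitions of the chosen
#' assignment.
#'
#' The root state is fixed to `absent` by default: element gain is treated
#' as the derived condition, matching the outgroup pattern at loci where
#' strains outside the insertion clade lack the element. Set
#' `root_state = NULL` to minimise over root states instead.
#'
#' @param tree A rooted `phylo` object (see [read_tree()]).
#' @param leaf_states Named character vector, named list (for state sets),
#'   or a data frame with `strain`/`state` columns (e.g.
#'   [call_presence_orientation()] output). Values: `absent`, `canonical`,
#'   `inverted`, `ambiguous_orientation` (= {canonical, inverted}),
#'   `ambiguous`/`unknown` (= any state).
#' @param model An [event_model()].
#' @param root_state State the root is constrained to, or `NULL` for free.
#' @return An object of class `event_reconstruction`: `total_cost`,
#'   `node_states` (named by tip/node label), `events` (data frame:
#'   `branch` = child label, `from`, `to`, `type`), `n_co_optimal`,
#'   `tree`, `model`.
#' @examples
#' tr <- read_tree("((A:1,B:1):1,(C:1,D:1):1);")
#' reconstruct_events(tr, c(A = "canonical", B = "canonical",
#'                          C = "absent", D = "absent"))
#' @export
reconstruct_events <- function(tree, leaf_states, model = event_model(),
                               root_state = "absent") {
  stopifnot(inherits(tree, "phylo"), inherits(model, "event_model"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted; see read_tree()")
  C <- model$cost
  allowed <- leaf_state_matrix(tree, leaf_states)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ntot <- ntip + nnode
  root <- ntip + 1L

  S <- matrix(Inf, nrow = ntot, ncol = 3L)      # subtree cost per state
  N <- matrix(0, nrow = ntot, ncol = 3L)        # co-optimal count per state
  S[seq_len(ntip), ] <- ifelse(allowed[tree$tip.label, , drop = FALSE],
                               0, Inf)
  N[seq_len(ntip), ] <- ifelse(allowed[tree$tip.label, , drop = FALSE],
                               1, 0)
  for (nd in (ntip + 1L):ntot) S[nd, ] <- 0
  N[(ntip + 1L):ntot, ] <- 1

  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    parent <- po$edge[i, 1L]
    child <- po$edge[i, 2L]
    for (s in 1:3) {
      v <- C[s, ] + S[child, ]
      m <- min(v)
      S[parent, s] <- S[parent, s] + m
      N[parent, s] <- N[parent, s] *
        (if (is.finite(m)) sum(N[child, is.finite(v) & v == m]) else 0)
    }
  }

  if (!is.null(root_state)) {
    rs <- match(root_state, EVENT_STATES)
    if (is.na(rs)) stop("`root_state` must be one of ",
                        paste(EVENT_STATES, collapse = "/"))
    total <- S[root, rs]
    n_opt <- N[root, rs]
    root_choice <- rs
  } else {
    total <- min(S[root, ])
    opt <- which(S[root, ] == total)
    n_opt <- sum(N[root, opt])
    root_choice <- opt[1L]
  }
  if (!is.finite(total)) {
    stop("no admissible assignment: leaf states conflict with the cost ",
         "model/root constraint")
  }

  # deterministic backtrace, parents before children
  assign_state <- integer(ntot)
  assign_state[root] <- root_choice
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(cw$edge))) {
    parent <- cw$edge[i, 1L]
    child <- cw$edge[i, 2L]
    v <- C[assign_state[parent], ] + S[child, ]
    assign_state[child] <- which(v == min(v))[1L]
  }

  labels <- vapply(seq_len(ntot), function(nd) node_label(tree, nd),
                   character(1))
  node_states <- stats::setNames(EVENT_STATES[assign_state], labels)

  ev <- list()
  for (i in seq_len(nrow(cw$edge))) {
    ps <- assign_state[cw$edge[i, 1L]]
    cs <- assign_state[cw$edge[i, 2L]]
    if (ps != cs) {
      ev[[length(ev) + 1L]] <- data.frame(
        branch = labels[cw$edge[i, 2L]],
        from = EVENT_STATES[ps], to = EVENT_STATES[cs],
        type = transition_type(ps, cs))
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(branch = character(0), from = character(0),
               to = character(0), type = character(0))

  structure(
    list(total_cost = total, node_states = node_states, events = events,
         n_co_optimal = n_opt, tree = tree, model = model,
         root_state = if (is.null(root_state)) NULL else
           EVENT_STATES[root_choice]),
    class = "event_reconstruction"
  )
}

transition_type <- function(from, to) {
  key <- paste(from, to, sep = ">")
  switch(key,
         "1>2" = "insertion",
         "1>3" = "insertion+inversion",
         "2>3" = ,
         "3>2" = "inversion",
         "2>1" = ,
         "3>1" = "deletion",
         "other")
}

#' @export
print.event_reconstruction <- function(x, ...) {
  cat(sprintf(
    "Event reconstruction: total cost %g, %g co-optimal assignment%s\n",
    x$total_cost, x$n_co_optimal, if (x$n_co_optimal == 1) "" else "s"))
  if (nrow(x$events)) {
    for (i in seq_len(nrow(x$events))) {
      e <- x$events[i, ]
      cat(sprintf("  %s on branch to %s (%s -> %s)\n",
                  e$type, e$branch, e$from, e$to))
    }
  } else {
    cat("  no events\n")
  }
  invisible(x)
}

#' Write an event reconstruction to disk
#'
#' Emits the per-branch event table as TSV and the tree with ancestral
#' states as node labels (newick).
#'
#' @param rec A [reconstruct_events()] result.
#' @param events_path TSV output path.
#' @param tree_path Optional newick output path.
#' @return Invisibly, the paths written.
#' @export
write_events <- function(rec, events_path, tree_path = NULL) {
  stopifnot(inherits(rec, "event_reconstruction"))
  utils::write.table(rec$events, events_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- events_path
  if (!is.null(tree_path)) {
    tr <- rec$tree
    ntip <- length(tr$tip.label)
    tr$node.label <- unname(rec$node_states[(ntip + 1L):length(
      rec$node_states)])
    ape::write.tree(tr, file = tree_path)
    paths <- c(paths, tree_path)
  }
  invisible(paths)
}
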