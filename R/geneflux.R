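## Ancestral gene-content reconstruction by generalized (Sankoff) parsimony
## over copy-number states, with an event-cost scheme distinguishing
## acquisition, loss, first duplication and further copy-number steps.

#' Event-cost scheme for gene-content parsimony
#'
#' Costs of the elementary events along one branch: acquisition of a family
#' (gain), complete loss, the first duplication (1 -> 2 copies), and each
#' further copy-number step (expansion or contraction, treated
#' symmetrically). The dynamic program runs over copy-number states
#' 0..`max_copies`; larger observed counts are clipped.
#'
#' @param gain,loss,first_dup,copy_step non-negative event costs.
#' @param max_copies state cap (>= 1).
#' @return object of class `cost_scheme`.
#' @export
cost_scheme <- function(gain = 10, loss = 5, first_dup = 1, copy_step = 0.2,
                        max_copies = 8L) {
  if (any(c(gain, loss, first_dup, copy_step) < 0))
    stop_arch("costs must be non-negative")
  if (max_copies < 1L) stop_arch("max_copies must be >= 1")
  structure(list(gain = gain, loss = loss, first_dup = first_dup,
                 copy_step = copy_step, max_copies = as.integer(max_copies)),
            class = "cost_scheme")
}

#' Cost of a copy-number transition along one branch
#'
#' The composite cost of changing from `a` to `b` copies on a single branch:
#' zero if unchanged; a flat loss if the family disappears; a gain plus the
#' expansion from one copy if it appears at `b` copies (gain + first_dup +
#' (b-2) * copy_step for b >= 2); first_dup + (b-2) * copy_step for an
#' expansion from a single copy; and |a-b| * copy_step for every other
#' copy-number variation.
#'
#' @param a,b integer copy numbers (vectors recycled), in 0..`max_copies`.
#' @param costs a [cost_scheme()].
#' @return numeric vector of costs.
#' @export
transition_cost <- function(a, b, costs = cost_scheme()) {
  if (any(a < 0) || any(b < 0) || any(a > costs$max_copies) ||
      any(b > costs$max_copies))
    stop_arch("states must lie in 0..max_copies")
  n <- max(length(a), length(b))
  a <- rep_len(as.integer(a), n); b <- rep_len(as.integer(b), n)
  stepup1 <- function(bb) ifelse(bb >= 2L,
                                 costs$first_dup + (bb - 2L) * costs$copy_step,
                                 0)
  out <- numeric(n)
  same <- a == b
  gain <- a == 0L & b >= 1L
  lost <- a >= 1L & b == 0L
  dup1 <- a == 1L & b >= 2L
  other <- !(same | gain | lost | dup1)
  out[gain] <- costs$gain + stepup1(b[gain])
  out[lost] <- costs$loss
  out[dup1] <- stepup1(b[dup1])
  out[other] <- abs(a[other] - b[other]) * costs$copy_step
  out
}

## Full (max_copies+1)^2 transition-cost matrix; rows = parent state a,
## cols = child state b, both 0-based.
.cost_matrix <- function(costs, mode = "copy_number") {
  S <- if (mode == "presence_absence") 2L else costs$max_copies + 1L
  outer(0:(S - 1L), 0:(S - 1L), function(a, b) {
    if (mode == "presence_absence") {
      ifelse(a == b, 0, ifelse(a == 0, costs$gain, costs$loss))
    } else transition_cost(a, b, costs)
  })
}

## colMins for a small-row matrix.
.colmins <- function(m) do.call(pmin, lapply(seq_len(nrow(m)), function(i) m[i, ]))

#' Ancestral gene-content reconstruction (generalized parsimony)
#'
#' Per-family Sankoff dynamic program over copy-number states on a rooted
#' species tree, under the event costs of a [cost_scheme()]. Presence of a
#' family at the root is itself charged as an acquisition on the root stem,
#' so every family's history starts from absence; families may be gained,
#' lost and regained on any branch. Among co-optimal states the back-pass
#' prefers the parent's state (no change on the branch) and breaks remaining
#' ties toward the higher copy number; at the root, the highest co-optimal
#' copy number is chosen. The rule is deterministic, so event logs are
#' byte-stable.
#'
#' @param mat an [ortholog_matrix()] whose taxa are all tree leaves.
#' @param tree rooted `phylo` species tree.
#' @param costs a [cost_scheme()].
#' @param mode `"copy_number"` (default) or `"presence_absence"` (counts
#'   collapsed to 0/1 and duplication costs ignored).
#' @return object of class `gene_flux`: `states` (nodes x families integer
#'   matrix, ancestral copy numbers), `events` (per-branch event log),
#'   `branch_totals` (gains/losses/expansions/contractions per branch),
#'   `families_per_node`, `total_cost`, plus the inputs. Branches are named
#'   by their child node ("root" for the origination stem).
#' @export
sankoff_reconstruct <- function(mat, tree, costs = cost_scheme(),
                                mode = c("copy_number", "presence_absence")) {
  mode <- match.arg(mode)
  if (!inherits(tree, "phylo")) stop_arch("tree must be a phylo object")
  if (!ape::is.rooted(tree)) stop_arch("tree must be rooted")
  missing_taxa <- setdiff(colnames(mat), tree$tip.label)
  if (length(missing_taxa))
    stop_arch("matrix taxa absent from tree: ",
              paste(missing_taxa, collapse = ", "))
  uncovered <- setdiff(tree$tip.label, colnames(mat))
  if (length(uncovered)) {
    message("pruning ", length(uncovered), " tree leaves without matrix data")
    tree <- ape::drop.tip(tree, uncovered)
    if (is.null(tree) || length(tree$tip.label) < 2L)
      stop_arch("fewer than 2 tree leaves covered by the matrix")
  }
  counts <- unclass(mat)[, tree$tip.label, drop = FALSE]
  if (mode == "presence_absence") {
    counts <- (counts > 0L) + 0L
    S <- 2L
  } else {
    S <- costs$max_copies + 1L
    if (any(counts > costs$max_copies)) {
      warning("copy counts above max_copies (", costs$max_copies,
              ") clipped", call. = FALSE)
      counts[counts > costs$max_copies] <- costs$max_copies
    }
  }
  ## deterministic family order
  fam_order <- order(rownames(mat))
  counts <- counts[fam_order, , drop = FALSE]
  fams <- rownames(counts)
  Fm <- nrow(counts)
  C <- .cost_matrix(costs, mode)
  eps <- 1e-9

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge

  tip_counts <- t(counts)  # taxa x families, ordered as tree$tip.label subset
  ## D[[v]]: S x F matrix of minimal subtree costs given state at v
  D <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) {
    m <- matrix(Inf, nrow = S, ncol = Fm)
    obs <- counts[, match(tree$tip.label[i], colnames(counts))]
    m[cbind(obs + 1L, seq_len(Fm))] <- 0
    D[[i]] <- m
  }
  for (v in unique(edge[, 1])) D[[v]] <- matrix(0, nrow = S, ncol = Fm)
  ## postorder guarantees children done before parents
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    Dc <- D[[ch]]
    contrib <- matrix(0, nrow = S, ncol = Fm)
    for (s in seq_len(S)) contrib[s, ] <- .colmins(Dc + C[s, ])
    D[[par]] <- D[[par]] + contrib
  }

  ## root origination: charge c(0, s) on top of the root subtree cost
  W0 <- D[[root]] + C[1L, ]             # S x F (C[1,] recycles over rows)
  per_family_cost <- .colmins(W0)
  total_cost <- sum(per_family_cost)
  opt0 <- sweep(W0, 2, per_family_cost, `-`) <= eps  # S x F logical
  root_state <- apply(opt0, 2, function(z) max(which(z))) - 1L

  ## top-down back-pass in preorder
  states <- matrix(NA_integer_, nrow = ntip + nnode, ncol = Fm)
  states[root, ] <- root_state
  for (k in rev(seq_len(nrow(edge)))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    ps <- states[par, ]
    W <- C[ps + 1L, , drop = FALSE] + t(D[[ch]])    # F x S
    wmin <- do.call(pmin, lapply(seq_len(S), function(j) W[, j]))
    opt <- W <= wmin + eps
    pick <- max.col(opt, ties.method = "last")       # highest co-optimal
    keep <- opt[cbind(seq_len(Fm), ps + 1L)]         # parent state co-optimal?
    pick[keep] <- ps[keep] + 1L
    states[ch, ] <- pick - 1L
  }

  lab_ok <- !is.null(tree$node.label) && all(nzchar(tree$node.label)) &&
    !anyDuplicated(tree$node.label) &&
    all(is.na(suppressWarnings(as.numeric(tree$node.label))))
  node_names <- c(tree$tip.label,
                  if (lab_ok) tree$node.label
                  else paste0("node", seq_len(nnode) + ntip))
  branch_of <- function(node) node_names[node]

  ## event log
  ev_fam <- character(0); ev_branch <- character(0); ev_type <- character(0)
  ev_from <- integer(0); ev_to <- integer(0)
  classify <- function(p, c) {
    ifelse(p == 0L & c > 0L, "gain",
           ifelse(p > 0L & c == 0L, "loss",
                  ifelse(c > p, "expansion", "contraction")))
  }
  add_events <- function(p_states, c_states, branch) {
    idx <- which(p_states != c_states)
    if (!length(idx)) return(NULL)
    list(fam = fams[idx], branch = rep(branch, length(idx)),
         type = classify(p_states[idx], c_states[idx]),
         from = p_states[idx], to = c_states[idx])
  }
  pieces <- vector("list", nrow(edge) + 1L)
  pieces[[1]] <- add_events(rep(0L, Fm), states[root, ], "root")
  for (k in seq_len(nrow(edge)))
    pieces[[k + 1L]] <- add_events(states[edge[k, 1], ], states[edge[k, 2], ],
                                   branch_of(edge[k, 2]))
  pieces <- Filter(Negate(is.null), pieces)
  events <- if (length(pieces)) {
    data.frame(family = unlist(lapply(pieces, `[[`, "fam")),
               branch = unlist(lapply(pieces, `[[`, "branch")),
               type = unlist(lapply(pieces, `[[`, "type")),
               from = unlist(lapply(pieces, `[[`, "from")),
               to = unlist(lapply(pieces, `[[`, "to")),
               stringsAsFactors = FALSE)
  } else {
    data.frame(family = character(0), branch = character(0),
               type = character(0), from = integer(0), to = integer(0))
  }
  events <- events[order(events$branch, events$family), , drop = FALSE]
  rownames(events) <- NULL

  all_branches <- c("root", branch_of(edge[, 2]))
  tot <- t(vapply(all_branches, function(b) {
    e <- events[events$branch == b, ]
    c(gains = sum(e$type == "gain"), losses = sum(e$type == "loss"),
      expansions = sum(e$type == "expansion"),
      contractions = sum(e$type == "contraction"))
  }, numeric(4)))

  rownames(states) <- node_names
  colnames(states) <- fams
  structure(list(tree = tree, states = states, events = events,
                 branch_totals = tot,
                 families_per_node = rowSums(states >= 1L),
                 per_family_cost = setNames(per_family_cost, fams),
                 total_cost = total_cost, costs = costs, mode = mode),
            class = "gene_flux")
}

#' @export
print.gene_flux <- function(x, ...) {
  cat("Ancestral gene-content reconstruction (generalized parsimony, mode: ",
      x$mode, ")\n", sep = "")
  cat("  ", ncol(x$states), " families on ", length(x$tree$tip.label),
      " taxa; total cost ", format(x$total_cost, digits = 8), "\n", sep = "")
  cat("  events: ", nrow(x$events), " (",
      sum(x$events$type == "gain"), " gains, ",
      sum(x$events$type == "loss"), " losses, ",
      sum(x$events$type == "expansion"), " expansions, ",
      sum(x$events$type == "contraction"), " contractions)\n", sep = "")
  invisible(x)
}

#' @export
summary.gene_flux <- function(object, ...) flux_summary(object, ...)

#' Per-branch gene-flux summary
#'
#' Gains, losses and family totals per branch, plus branch-length-normalized
#' loss rates. For a designated focal branch the loss rate is compared with
#' the other internal branches, reported as a fold range (focal rate divided
#' by the maximum and minimum background rates).
#'
#' @param recon a [sankoff_reconstruct()] result.
#' @param focal_branch optional branch id (child-node name) whose loss rate
#'   is compared against the other internal branches.
#' @return data.frame of class `flux_summary` with one row per branch:
#'   `branch`, `gains`, `losses`, `families_at_child`, `branch_length`,
#'   `loss_rate`; attribute `fold_vs_background` (length-2 numeric, min and
#'   max fold) when a focal branch is given and rates are available.
#' @export
flux_summary <- function(recon, focal_branch = NULL) {
  tree <- recon$tree
  ntip <- length(tree$tip.label)
  node_names <- rownames(recon$states)
  branches <- rownames(recon$branch_totals)
  child_node <- match(branches, node_names)        # NA for "root"
  blen <- rep(NA_real_, length(branches))
  if (!is.null(tree$edge.length)) {
    m <- match(child_node, tree$edge[, 2])
    blen <- tree$edge.length[m]
  } else {
    warning("tree has no branch lengths; loss rates omitted", call. = FALSE)
  }
  losses <- recon$branch_totals[, "losses"]
  loss_rate <- ifelse(!is.na(blen) & blen > 0, losses / blen, NA_real_)
  out <- data.frame(branch = branches,
                    gains = recon$branch_totals[, "gains"],
                    losses = losses,
                    families_at_child = recon$families_per_node[
                      ifelse(is.na(child_node), ntip + 1L, child_node)],
                    branch_length = blen, loss_rate = loss_rate,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(focal_branch)) {
    if (!focal_branch %in% branches)
      stop_arch("unknown focal branch '", focal_branch, "'")
    internal <- !is.na(child_node) & child_node > ntip
    focal_rate <- out$loss_rate[out$branch == focal_branch]
    bg <- out$loss_rate[internal & out$branch != focal_branch]
    bg <- bg[!is.na(bg) & bg > 0]
    fold <- if (is.na(focal_rate) || !length(bg)) c(NA_real_, NA_real_)
            else sort(focal_rate / range(bg))
    attr(out, "fold_vs_background") <- fold
    attr(out, "focal_branch") <- focal_branch
  }
  class(out) <- c("flux_summary", "data.frame")
  out
}

#' Families unique to a clade
#'
#' @param mat an [ortholog_matrix()].
#' @param clade character vector of taxa (subset of the matrix taxa).
#' @param mode `"strict"`: present (count >= 1) in every clade member and
#'   absent outside; `"relaxed"`: present in at least one clade member and
#'   absent outside.
#' @return character vector of family ids.
#' @export
clade_unique_families <- function(mat, clade, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  if (!length(clade)) stop_arch("empty clade")
  bad <- setdiff(clade, colnames(mat))
  if (length(bad))
    stop_arch("clade taxa not in matrix: ", paste(bad, collapse = ", "))
  inside <- unclass(mat)[, clade, drop = FALSE]
  outside <- unclass(mat)[, setdiff(colnames(mat), clade), drop = FALSE]
  none_outside <- if (ncol(outside)) rowSums(outside) == 0 else TRUE
  keep <- if (mode == "strict") {
    rowSums(inside >= 1L) == length(clade) & none_outside
  } else {
    rowSums(inside >= 1L) >= 1L & none_outside
  }
  rownames(mat)[keep]
}
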