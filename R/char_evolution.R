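INF <- 1e9

# unit-cost Sankoff tables for one character on a (possibly multifurcating)
# tree; returns down/up cost matrices (nodes x states), children lists, L
mpr_tables <- function(tree, cellmasks, states) {
  nt <- length(tree$tip.label)
  nn <- max(tree$edge)
  k <- length(states)
  kids <- vector("list", nn)
  par <- integer(nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    kids[[p]] <- c(kids[[p]], v)
    par[v] <- p
  }
  root <- nt + 1L
  # postorder of internal nodes: reverse of preorder
  pre <- integer(0); stack <- root
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    pre <- c(pre, v); stack <- c(stack, kids[[v]])
  }
  internal_post <- rev(pre[pre > nt])

  down <- matrix(INF, nn, k)
  for (i in seq_len(nt)) {
    sm <- cellmasks[i]
    if (sm == 0L) down[i, ] <- 0
    else down[i, bitwAnd(bitwShiftR(sm, states), 1L) == 1L] <- 0
  }
  for (v in internal_post) {
    acc <- numeric(k)
    for (c in kids[[v]]) {
      mc <- min(down[c, ])
      acc <- acc + pmin(down[c, ], mc + 1)
    }
    down[v, ] <- acc
  }
  L <- min(down[root, ])

  up <- matrix(INF, nn, k)
  up[root, ] <- 0
  for (v in pre[pre != root]) {
    p <- par[v]
    # cost at p excluding v's subtree, per state of p
    excl <- up[p, ]
    for (b in kids[[p]]) {
      if (b == v) next
      mb <- min(down[b, ])
      excl <- excl + pmin(down[b, ], mb + 1)
    }
    me <- min(excl)
    up[v, ] <- pmin(excl, me + 1)
  }
  list(down = down, up = up, kids = kids, par = par, root = root, L = L,
       states = states, excl_cache = NULL)
}

# per-node MPR state sets (logical matrix nodes x states)
mpr_node_sets <- function(tab) {
  total <- tab$down + tab$up
  total <= tab$L + 1e-9
}

# optimal (parent_state, child_state) pairs for every edge of the tree;
# returns list indexed by edge row: integer matrix with columns from/to
mpr_edge_pairs <- function(tree, tab) {
  k <- length(tab$states)
  lapply(seq_len(nrow(tree$edge)), function(i) {
    p <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    excl <- tab$up[p, ]
    for (b in tab$kids[[p]]) {
      if (b == v) next
      mb <- min(tab$down[b, ])
      excl <- excl + pmin(tab$down[b, ], mb + 1)
    }
    pairs <- matrix(0L, 0, 2)
    for (t in seq_len(k)) for (s in seq_len(k)) {
      tot <- excl[t] + (t != s) + tab$down[v, s]
      if (tot <= tab$L + 1e-9)
        pairs <- rbind(pairs, c(tab$states[t], tab$states[s]))
    }
    colnames(pairs) <- c("from", "to")
    pairs
  })
}

#' Most-parsimonious ancestral state sets
#'
#' Exact MPR state sets for every node of a (rooted) tree under unordered
#' unit-cost parsimony: the set of states a node takes in at least one
#' most-parsimonious reconstruction. Missing/inapplicable/polymorphic cells
#' resolve freely within their allowed sets. Polytomies are scored exactly.
#'
#' @param tree a `phylo`; node numbering follows the tree (root = first
#'   internal node).
#' @param m a [char_matrix].
#' @param chars character indices (default: all active).
#' @return list (one element per character) of lists of integer state
#'   vectors, indexed by node id; `attr(,"lengths")` gives per-character
#'   steps (matching [fitch_steps]).
#' @export
mpr_sets <- function(tree, m, chars = NULL) {
  cols <- active_cols(m, chars)
  masks <- masks_for_tree(tree, m, cols)
  lens <- numeric(length(cols))
  out <- vector("list", length(cols))
  for (j in seq_along(cols)) {
    states <- mask_to_states(Reduce(bitwOr, masks[, j], 0L))
    if (length(states) == 0) states <- 0L
    tab <- mpr_tables(tree, masks[, j], states)
    sets <- mpr_node_sets(tab)
    lens[j] <- tab$L
    out[[j]] <- lapply(seq_len(nrow(sets)), function(v) states[sets[v, ]])
  }
  names(out) <- paste0("char", cols)
  attr(out, "lengths") <- lens
  attr(out, "chars") <- cols
  out
}

#' Unambiguous character changes on a tree
#'
#' For every edge and character, the set of optimal (ancestral, derived)
#' state pairs over all most-parsimonious reconstructions. A change is
#' unambiguous on an edge when every optimal pair is the same single pair
#' `(a, b)` with `a != b`: all MPRs place exactly that change there.
#'
#' @inheritParams mpr_sets
#' @return data.frame with columns `edge` (row index into `tree$edge`),
#'   `parent`, `child`, `char`, `from`, `to`, `unambiguous` (logical). Rows
#'   appear for every edge/character where a change occurs in at least one
#'   MPR (one row per optimal changing pair).
#' @export
unambiguous_changes <- function(tree, m, chars = NULL) {
  cols <- active_cols(m, chars)
  masks <- masks_for_tree(tree, m, cols)
  rows <- list()
  for (j in seq_along(cols)) {
    states <- mask_to_states(Reduce(bitwOr, masks[, j], 0L))
    if (length(states) < 2) next
    tab <- mpr_tables(tree, masks[, j], states)
    if (tab$L < 1e-9) next
    ep <- mpr_edge_pairs(tree, tab)
    for (i in seq_along(ep)) {
      pr <- unique(ep[[i]])
      chg <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
      if (nrow(chg) == 0) next
      unamb <- nrow(pr) == 1
      rows[[length(rows) + 1]] <- data.frame(
        edge = i, parent = tree$edge[i, 1], child = tree$edge[i, 2],
        char = cols[j], from = chg[, 1], to = chg[, 2],
        unambiguous = unamb)
    }
  }
  if (length(rows) == 0)
    return(data.frame(edge = integer(0), parent = integer(0),
                      child = integer(0), char = integer(0),
                      from = integer(0), to = integer(0),
                      unambiguous = logical(0)))
  do.call(rbind, rows)
}

# is a change into `to` for char tables `tab` necessary/possible per edge?
origin_edges <- function(tree, tab, to) {
  ep <- mpr_edge_pairs(tree, tab)
  possible <- logical(length(ep)); necessary <- logical(length(ep))
  for (i in seq_along(ep)) {
    pr <- unique(ep[[i]])
    gain <- pr[, 1] != pr[, 2] & pr[, 2] == to
    possible[i] <- any(gain)
    necessary[i] <- all(gain) && nrow(pr) > 0
  }
  list(possible = which(possible), necessary = which(necessary))
}

#' Synapomorphies supporting the clades of a tree
#'
#' Maps unambiguous state changes onto internal branches across one or more
#' equally parsimonious trees. A change supports a clade when it occurs
#' unambiguously on the branch subtending that clade; it is a *unique*
#' synapomorphy for its derived state when that state originates on exactly
#' that one branch in every most-parsimonious reconstruction of every input
#' tree (no parallel origin anywhere, under any optimization).
#'
#' @param trees a `phylo`, `multiPhylo`, or list of equally parsimonious
#'   trees over the same taxa (rooted consistently).
#' @param m a [char_matrix].
#' @param chars character indices (default: all active).
#' @return data.frame with columns `clade` (sorted taxon block, `+`-joined),
#'   `char`, `from`, `to`, `unique` (logical). Only changes unambiguous on
#'   the same clade's branch in all trees are listed.
#' @export
synapomorphies <- function(trees, m, chars = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  cols <- active_cols(m, chars)
  per_tree <- vector("list", length(trees))
  uniq_tabs <- vector("list", length(trees))
  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]
    sets <- edge_tip_sets(tree)
    clade_of <- vapply(sets, function(s) paste(sort(s), collapse = "+"), "")
    uc <- unambiguous_changes(tree, m, cols)
    uc <- uc[uc$unambiguous, , drop = FALSE]
    uc$clade <- clade_of[uc$edge]
    per_tree[[ti]] <- uc
    # per character: tables for uniqueness analysis
    masks <- masks_for_tree(tree, m, cols)
    uniq_tabs[[ti]] <- lapply(seq_along(cols), function(j) {
      states <- mask_to_states(Reduce(bitwOr, masks[, j], 0L))
      if (length(states) < 2) return(NULL)
      mpr_tables(tree, masks[, j], states)
    })
  }
  # keep (clade, char, from, to) present unambiguously in every tree
  key <- function(df) paste(df$clade, df$char, df$from, df$to)
  common <- Reduce(intersect, lapply(per_tree, key))
  out <- per_tree[[1]][key(per_tree[[1]]) %in% common,
                       c("clade", "char", "from", "to"), drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    out$unique <- logical(0)
    return(out)
  }
  out$unique <- vapply(seq_len(nrow(out)), function(r) {
    j <- match(out$char[r], cols)
    all(vapply(seq_along(trees), function(ti) {
      tab <- uniq_tabs[[ti]][[j]]
      if (is.null(tab)) return(FALSE)
      oe <- origin_edges(trees[[ti]], tab, out$to[r])
      length(oe$possible) == 1 && identical(oe$possible, oe$necessary)
    }, TRUE))
  }, TRUE)
  out
}

#' Trace a single character on a tree
#'
#' Human-readable summary of one character's evolution: per-node MPR state
#' sets and all optimal changes per edge.
#'
#' @param tree a `phylo`.
#' @param m a [char_matrix].
#' @param char one character index.
#' @return list with `states` (per-node MPR sets), `changes` (data.frame as
#'   in [unambiguous_changes]), `steps` (character length on the tree).
#' @export
trace_character <- function(tree, m, char) {
  stopifnot(length(char) == 1)
  sets <- mpr_sets(tree, m, chars = char)
  chg <- unambiguous_changes(tree, m, chars = char)
  list(states = sets[[1]], changes = chg,
       steps = attr(sets, "lengths")[1])
}
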