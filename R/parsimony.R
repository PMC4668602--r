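# ---- internal plumbing ------------------------------------------------------

# masks of the active characters, rows reordered to a tree's tip labels
masks_for_tree <- function(tree, m, chars = NULL) {
  idx <- match(normalize_label(tree$tip.label), m$taxa)
  if (anyNA(idx))
    stopf("leaf without a matrix row: %s",
          tree$tip.label[is.na(idx)][1])
  cols <- chars %||% which(m$active_chars)
  m$masks[idx, cols, drop = FALSE]
}

active_cols <- function(m, chars = NULL) chars %||% which(m$active_chars)

# ---- user-facing operations -------------------------------------------------

#' Minimum character changes (Fitch steps) on a tree
#'
#' Exact minimum number of state changes for unordered characters on a given
#' tree, by dynamic programming over state sets. Missing and inapplicable
#' cells carry the full observed state set; polymorphic cells may resolve to
#' any member state. Polytomies are treated as hard and scored exactly. The
#' result does not depend on where the tree is rooted.
#'
#' @param tree a `phylo`; every leaf must match a matrix taxon.
#' @param m a [char_matrix].
#' @param chars optional character indices (default: all active characters).
#' @return integer vector of per-character steps.
#' @export
fitch_steps <- function(tree, m, chars = NULL) {
  masks <- masks_for_tree(tree, m, chars)
  storage.mode(tree$edge) <- "integer"
  cpp_steps(tree$edge, length(tree$tip.label), masks)
}

#' Weighted tree length
#'
#' Sum of weighted Fitch steps over active characters; invariant under
#' rooting.
#'
#' @inheritParams fitch_steps
#' @return a single number.
#' @export
tree_length <- function(tree, m) {
  cols <- active_cols(m)
  if (length(cols) == 0) return(0)
  sum(m$weights[cols] * fitch_steps(tree, m, cols))
}

#' Minimum conceivable steps per character over all trees
#'
#' For an unordered character this is the minimum number of states needed to
#' intersect every scored cell (polymorphic cells may be "covered" by any
#' member state), minus one. Computed exactly by subset enumeration over the
#' observed alphabet. Missing/inapplicable cells never force a state.
#'
#' @param m a [char_matrix].
#' @param chars optional character indices (default: all).
#' @return integer vector `m_c`.
#' @export
char_min_steps <- function(m, chars = NULL) {
  cols <- chars %||% seq_len(ncol(m$masks))
  vapply(cols, function(j) {
    cellmasks <- m$masks[m$active_taxa & m$special[, j] == 0L, j]
    cellmasks <- cellmasks[cellmasks > 0L]
    if (length(cellmasks) == 0) return(0L)
    states <- mask_to_states(Reduce(bitwOr, cellmasks, 0L))
    for (size in seq_along(states)) {
      subs <- utils::combn(states, size, simplify = FALSE)
      for (s in subs) {
        sm <- states_to_mask(s)
        if (all(bitwAnd(cellmasks, sm) > 0L)) return(size - 1L)
      }
    }
    length(states) - 1L
  }, 0L)
}

#' Maximum conceivable steps per character over all trees
#'
#' The star-tree (worst-case) length of an unordered character: number of
#' scored cells minus the best attainable coverage of a single state (a
#' polymorphic cell counts as carrying a state if its set contains it).
#'
#' @inheritParams char_min_steps
#' @return integer vector `g_c`.
#' @export
char_max_steps <- function(m, chars = NULL) {
  cols <- chars %||% seq_len(ncol(m$masks))
  vapply(cols, function(j) {
    cellmasks <- m$masks[m$active_taxa & m$special[, j] == 0L, j]
    cellmasks <- cellmasks[cellmasks > 0L]
    if (length(cellmasks) == 0) return(0L)
    counts <- vapply(0:9, function(s)
      sum(bitwAnd(cellmasks, bitwShiftL(1L, s)) > 0L), 0L)
    as.integer(length(cellmasks) - max(counts))
  }, 0L)
}

#' Parsimony-informative characters
#'
#' A character is uninformative when its observed steps equal its minimum on
#' every tree, i.e. when `m_c == g_c`.
#'
#' @inheritParams char_min_steps
#' @return logical vector.
#' @export
informative_chars <- function(m, chars = NULL) {
  char_min_steps(m, chars) < char_max_steps(m, chars)
}

#' Ensemble consistency and retention indices
#'
#' For a set of equally parsimonious trees, computes per-character observed
#' steps `s_c`, the tree-independent bounds `m_c` and `g_c`, the ensemble
#' length `L = sum(w_c s_c)`, the consistency index `CI = sum(m) / sum(s)`
#' and the retention index `RI = (sum(g) - sum(s)) / (sum(g) - sum(m))`.
#' Both conventions regarding parsimony-uninformative characters are
#' reported: indices over all active characters and over informative
#' characters only.
#'
#' @param trees a `phylo`, `multiPhylo` or list of trees of equal length.
#' @param m a [char_matrix].
#' @return an object of class `parsimony_score`.
#' @export
ensemble_indices <- function(trees, m) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  cols <- active_cols(m)
  w <- m$weights[cols]
  s <- fitch_steps(trees[[1]], m, cols)
  lens <- vapply(trees, function(t) sum(w * fitch_steps(t, m, cols)), 0)
  if (max(lens) - min(lens) > 1e-9)
    stopf("trees are not all of equal length (range %g..%g)",
          min(lens), max(lens))
  mc <- char_min_steps(m, cols)
  gc_ <- char_max_steps(m, cols)
  info <- mc < gc_

  if (sum(w * s) == 0)
    warning("zero observed steps; CI reported as 1 by convention",
            call. = FALSE)
  ci_of <- function(keep) {
    S <- sum(w[keep] * s[keep]); M <- sum(w[keep] * mc[keep])
    if (S == 0) return(1)
    M / S
  }
  ri_of <- function(keep) {
    S <- sum(w[keep] * s[keep]); M <- sum(w[keep] * mc[keep])
    G <- sum(w[keep] * gc_[keep])
    if (G - M == 0) return(NA_real_)
    (G - S) / (G - M)
  }

  structure(list(
    per_char = data.frame(char = cols, steps = s, min_steps = mc,
                          max_steps = gc_, informative = info),
    length = lens[[1]],
    ci = ci_of(rep(TRUE, length(cols))), ri = ri_of(rep(TRUE, length(cols))),
    ci_informative = ci_of(info), ri_informative = ri_of(info),
    n_trees = length(trees)), class = "parsimony_score")
}

#' @export
print.parsimony_score <- function(x, ...) {
  cat(sprintf("parsimony score over %d tree(s)\n", x$n_trees))
  cat(sprintf("  length: %g\n", x$length))
  cat(sprintf("  CI: %.3f (all chars) / %.3f (informative only)\n",
              x$ci, x$ci_informative))
  cat(sprintf("  RI: %.3f (all chars) / %.3f (informative only)\n",
              x$ri, x$ri_informative))
  invisible(x)
}

#' Minimum attainable length of each internal branch
#'
#' For every internal edge of an unrooted binary tree, the minimum total
#' number of changes assigned to that edge over all most-parsimonious
#' reconstructions. Edges with value zero are those collapsed by the
#' "minimum length zero" rule.
#'
#' @inheritParams fitch_steps
#' @return data.frame with edge endpoints and `min_length`.
#' @export
min_branch_lengths <- function(tree, m) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  masks <- masks_for_tree(tree, m)
  w <- m$weights[active_cols(m)]
  storage.mode(tree$edge) <- "integer"
  internal <- tree$edge[tree$edge[, 1] > nt & tree$edge[, 2] > nt, , drop = FALSE]
  vals <- cpp_min_branch_lengths(tree$edge, nt, masks, w, internal)
  data.frame(parent = internal[, 1], child = internal[, 2], min_length = vals)
}

#' Collapse branches of minimum length zero
#'
#' Applies the "minimum length zero" collapse rule: internal branches whose
#' minimum attainable length over all most-parsimonious reconstructions is
#' zero are contracted into polytomies.
#'
#' @inheritParams fitch_steps
#' @return a `phylo`, possibly with polytomies.
#' @export
collapse_zero_branches <- function(tree, m) {
  tree <- ape::unroot(tree)
  mb <- min_branch_lengths(tree, m)
  drop <- mb[mb$min_length <= 1e-9, , drop = FALSE]
  if (nrow(drop) == 0) return(tree)
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  for (i in seq_len(nrow(drop))) {
    hit <- which(t2$edge[, 1] == drop$parent[i] & t2$edge[, 2] == drop$child[i])
    t2$edge.length[hit] <- 0
  }
  out <- ape::di2multi(t2, tol = 0.5)
  out$edge.length <- NULL
  out
}
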