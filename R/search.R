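#' Search configuration
#'
#' @param n_replicates number of random-addition-sequence + TBR replicates.
#' @param hold_per_replicate trees held per replicate.
#' @param final_pool_swap apply TBR to the pooled retained trees.
#' @param seed integer seed recorded in all outputs; `NULL` leaves the RNG
#'   state untouched.
#' @param collapse collapse rule applied before deduplication:
#'   `"min_length_zero"` contracts branches whose minimum attainable length
#'   is zero; `"no_collapse"` keeps binary topologies.
#' @param max_trees cap on trees retained during the final pooled swap.
#' @param tbr_max_rounds safety cap on TBR scan rounds per climb.
#' @return a `search_config` list.
#' @export
search_config <- function(n_replicates = 1000, hold_per_replicate = 10,
                          final_pool_swap = TRUE, seed = NULL,
                          collapse = c("min_length_zero", "no_collapse"),
                          max_trees = 500, tbr_max_rounds = 5000) {
  stopifnot(n_replicates >= 1, hold_per_replicate >= 1, max_trees >= 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 hold_per_replicate = as.integer(hold_per_replicate),
                 final_pool_swap = isTRUE(final_pool_swap),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 collapse = match.arg(collapse),
                 max_trees = as.integer(max_trees),
                 tbr_max_rounds = as.integer(tbr_max_rounds)),
            class = "search_config")
}

#' Monophyly constraint
#'
#' A positive constraint is a set of (nested) taxon groups, each of which
#' must be monophyletic relative to `scope` (all taxa by default; taxa
#' outside the scope float freely). A converse constraint is one or more
#' groups that must NOT be monophyletic. "Force X as sister of group Y" is
#' the positive constraint with groups `Y` and `c(X, Y)`.
#'
#' @param groups a character vector (single group) or list of character
#'   vectors of taxon labels.
#' @param scope taxa relative to which monophyly is judged (default: all
#'   taxa of the matrix/tree at evaluation time).
#' @param converse logical; if `TRUE` the groups are forbidden clades.
#' @return a `monophyly_constraint`.
#' @export
monophyly_constraint <- function(groups, scope = NULL, converse = FALSE) {
  if (!is.list(groups)) groups <- list(groups)
  groups <- lapply(groups, normalize_label)
  if (!is.null(scope)) scope <- normalize_label(scope)
  if (isTRUE(converse)) {
    structure(list(pos = list(), conv = groups, scope = scope),
              class = "monophyly_constraint")
  } else {
    structure(list(pos = groups, conv = list(), scope = scope),
              class = "monophyly_constraint")
  }
}

# resolve a constraint to 0-based tip indices for a given taxon ordering
constraint_indices <- function(constraint, taxa) {
  if (is.null(constraint))
    return(list(pos = list(), scope = integer(0), conv = list()))
  to_idx <- function(g) {
    i <- match(g, taxa)
    if (anyNA(i)) stopf("constraint taxon not found: %s", g[is.na(i)][1])
    as.integer(i - 1L)
  }
  list(pos = lapply(constraint$pos, to_idx),
       scope = if (is.null(constraint$scope)) integer(0)
               else to_idx(constraint$scope),
       conv = lapply(constraint$conv, to_idx))
}

#' Does a tree satisfy a monophyly constraint?
#'
#' @param tree a binary unrooted `phylo`.
#' @param constraint a [monophyly_constraint] (or `NULL`, always satisfied).
#' @return logical.
#' @export
satisfies_constraint <- function(tree, constraint) {
  if (is.null(constraint)) return(TRUE)
  tree <- ape::unroot(tree)
  labs <- normalize_label(tree$tip.label)
  ci <- constraint_indices(constraint, labs)
  storage.mode(tree$edge) <- "integer"
  cpp_satisfies(tree$edge, length(labs), ci$pos, ci$scope, ci$conv)
}

# build a phylo from a c++ edge matrix and tip labels
phylo_from_edge <- function(edge, taxa) {
  structure(list(edge = edge, tip.label = taxa,
                 Nnode = max(edge) - length(taxa)),
            class = "phylo", order = "cladewise")
}

#' Stepwise addition of taxa
#'
#' Builds an unrooted binary tree by inserting taxa in the given order, each
#' at the attachment edge that minimizes the incremental Fitch length (exact
#' incremental rescoring via directional state sets). Ties among equal-cost
#' feasible edges are broken by the current RNG stream; placements violating
#' a positive constraint are skipped.
#'
#' @param m a [char_matrix].
#' @param order taxon labels or indices in addition order (default: random
#'   permutation of active taxa).
#' @param constraint optional [monophyly_constraint] (positive groups only
#'   are enforced during addition).
#' @return a `phylo`.
#' @export
stepwise_addition <- function(m, order = NULL, constraint = NULL) {
  taxa <- m$taxa[m$active_taxa]
  if (length(taxa) < 3) stopf("need at least 3 active taxa")
  if (is.null(order)) order <- sample(taxa)
  if (is.numeric(order)) order <- taxa[order]
  order <- normalize_label(order)
  if (!setequal(order, taxa)) stopf("`order` must be a permutation of the active taxa")
  masks <- m$masks[match(taxa, m$taxa), which(m$active_chars), drop = FALSE]
  w <- m$weights[m$active_chars]
  ci <- constraint_indices(constraint, taxa)
  res <- cpp_stepwise(masks, w, as.integer(match(order, taxa) - 1L),
                      ci$pos, ci$scope)
  tr <- phylo_from_edge(res$edge, taxa)
  attr(tr, "length") <- res$length
  tr
}

# swap one constrained-group member with an outside tip to break an
# unwanted clade (converse repair); returns a satisfying tree or errors
repair_converse <- function(tree, m, constraint) {
  if (satisfies_constraint(tree, constraint)) return(tree)
  labs <- tree$tip.label
  for (g in constraint$conv) {
    inside <- intersect(labs, g)
    outside <- setdiff(labs, g)
    for (a in inside) for (b in outside) {
      t2 <- tree
      ia <- which(t2$tip.label == a); ib <- which(t2$tip.label == b)
      t2$tip.label[ia] <- b; t2$tip.label[ib] <- a
      if (satisfies_constraint(t2, constraint)) return(t2)
    }
  }
  stopf("could not repair start tree to satisfy the converse constraint")
}

#' TBR branch swapping from a start tree
#'
#' Hill-climbs through the full tree bisection-reconnection neighborhood
#' (every edge bisected; every pair of fragment edges reconnected), accepting
#' strictly shorter trees immediately and collecting equal-length trees up to
#' `hold`. Reconnection costs are computed incrementally from cached
#' directional state sets, so each candidate is scored exactly without a full
#' rescore. All returned trees satisfy the constraint.
#'
#' @param tree start `phylo` (unrooted binary, must satisfy the constraint).
#' @param m a [char_matrix].
#' @param hold maximum number of equal-length trees retained.
#' @param constraint optional [monophyly_constraint].
#' @param max_rounds safety cap on scan rounds.
#' @return a `tree_buffer`: list with `trees` (multiPhylo), `best_length`.
#' @export
tbr_search <- function(tree, m, hold = 10, constraint = NULL,
                       max_rounds = 5000) {
  tree <- ape::unroot(tree)
  labs <- normalize_label(tree$tip.label)
  masks <- m$masks[match(labs, m$taxa), which(m$active_chars), drop = FALSE]
  if (anyNA(match(labs, m$taxa))) stopf("leaf without a matrix row")
  w <- m$weights[m$active_chars]
  ci <- constraint_indices(constraint, labs)
  storage.mode(tree$edge) <- "integer"
  res <- cpp_tbr(tree$edge, length(labs), masks, w, as.integer(hold),
                 ci$pos, ci$scope, ci$conv, as.integer(max_rounds))
  trees <- lapply(res$edges, phylo_from_edge, taxa = labs)
  class(trees) <- "multiPhylo"
  new_tree_buffer(trees, res$best_length)
}

new_tree_buffer <- function(trees, best_length, config = NULL, seed = NULL,
                            replicate_best = NULL, collapsed = NULL) {
  structure(list(trees = trees, best_length = best_length, config = config,
                 seed = seed, replicate_best = replicate_best,
                 collapsed_trees = collapsed),
            class = "tree_buffer")
}

#' @export
print.tree_buffer <- function(x, ...) {
  cat(sprintf("tree_buffer: %d tree(s) of length %g\n",
              length(x$trees), x$best_length))
  if (!is.null(x$collapsed_trees))
    cat(sprintf("  after collapse rule: %d distinct tree(s)\n",
                length(x$collapsed_trees)))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# canonical topology key: fast C++ bitset key for unrooted binary trees
# (requires identical tip orderings), string split-set otherwise
tree_key <- function(tree) {
  nt <- length(tree$tip.label)
  if (nrow(tree$edge) == 2 * nt - 3) {
    storage.mode(tree$edge) <- "integer"
    cpp_topology_key(tree$edge, nt)
  } else topology_id(tree)
}

# deduplicate a list of phylo by topology (assumes identical tip orderings,
# which holds for all trees derived from one matrix's active taxa)
dedup_trees <- function(trees) {
  ids <- vapply(trees, tree_key, "")
  keep <- !duplicated(ids)
  out <- trees[keep]
  class(out) <- "multiPhylo"
  out
}

#' Heuristic maximum-parsimony search
#'
#' The full search protocol: `n_replicates` random addition sequences, each
#' followed by TBR swapping holding `hold_per_replicate` trees; the retained
#' trees are pooled and (optionally) swapped again with a larger buffer; the
#' resulting most-parsimonious trees are deduplicated, and the collapse rule
#' applied. With a seed the whole run is deterministic.
#'
#' @param m a [char_matrix].
#' @param config a [search_config].
#' @param constraint optional [monophyly_constraint]; all visited trees
#'   satisfy it.
#' @return a `tree_buffer` with fields `trees` (binary MPTs), `best_length`,
#'   `collapsed_trees` (distinct topologies after the collapse rule),
#'   `replicate_best` (per-replicate best lengths), `config`, `seed`.
#' @export
mp_search <- function(m, config = search_config(), constraint = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  taxa <- m$taxa[m$active_taxa]
  pool <- list()
  pool_ids <- character(0)
  best <- Inf
  rep_best <- numeric(config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    start <- stepwise_addition(m, constraint = constraint)
    if (length(constraint$conv %||% list()) > 0)
      start <- repair_converse(start, m, constraint)
    buf <- tbr_search(start, m, hold = config$hold_per_replicate,
                      constraint = constraint,
                      max_rounds = config$tbr_max_rounds)
    rep_best[r] <- buf$best_length
    if (buf$best_length < best - 1e-9) {
      best <- buf$best_length
      pool <- list(); pool_ids <- character(0)
    }
    if (buf$best_length < best + 1e-9) {
      for (t in buf$trees) {
        id <- tree_key(t)
        if (!id %in% pool_ids) { pool <- c(pool, list(t)); pool_ids <- c(pool_ids, id) }
      }
    }
  }
  # final TBR on everything retained in memory
  if (config$final_pool_swap) {
    repeat {
      improved <- FALSE
      merged <- list(); merged_ids <- character(0)
      for (t in pool) {
        # a start tree already in the merged buffer was reached by an
        # earlier swap and its neighborhood explored; don't swap it again
        if (tree_key(t) %in% merged_ids) next
        if (length(merged) >= config$max_trees) break
        buf <- tbr_search(t, m, hold = config$max_trees,
                          constraint = constraint,
                          max_rounds = config$tbr_max_rounds)
        if (buf$best_length < best - 1e-9) {
          best <- buf$best_length
          pool <- buf$trees
          improved <- TRUE
          break
        }
        for (t2 in buf$trees) {
          id <- tree_key(t2)
          if (!id %in% merged_ids) {
            merged <- c(merged, list(t2)); merged_ids <- c(merged_ids, id)
          }
          if (length(merged) >= config$max_trees) break
        }
      }
      if (!improved) { pool <- merged; break }
    }
  }
  pool <- dedup_trees(pool)
  collapsed <- if (config$collapse == "min_length_zero") {
    dedup_trees(lapply(pool, collapse_zero_branches, m = m))
  } else pool
  new_tree_buffer(pool, best, config = config, seed = config$seed,
                  replicate_best = rep_best, collapsed = collapsed)
}

#' Constrained maximum-parsimony search
#'
#' [mp_search] restricted to trees satisfying a positive or converse
#' monophyly constraint. The constrained best length is never smaller than
#' the unconstrained one.
#'
#' @inheritParams mp_search
#' @param constraint a [monophyly_constraint] (required).
#' @return a `tree_buffer`.
#' @export
constrained_search <- function(m, config = search_config(), constraint) {
  stopifnot(inherits(constraint, "monophyly_constraint"))
  mp_search(m, config, constraint)
}

# ---- exhaustive enumeration (oracle-scale machinery) ------------------------

#' All unrooted binary topologies on a set of labels
#'
#' Recursive edge-insertion enumeration: 3 labels give 1 topology, each
#' added label multiplies the count by the number of edges (1, 3, 15, 105,
#' 945, 10395, ... trees). Guarded to 9 labels.
#'
#' @param labels character vector of >= 3 tip labels.
#' @return list of `phylo` objects.
#' @export
all_topologies <- function(labels) {
  n <- length(labels)
  if (n < 3) stopf("need >= 3 labels")
  if (n > 9) stopf("refusing to enumerate > 9 taxa (%s trees)",
                   format(prod(seq(3, 2 * n - 5, by = 2)), big.mark = ","))
  # edges over ids: tips 1..n, internals n+1..2n-2
  grow <- function(edges, k, next_internal) {
    if (k > n) return(list(edges))
    out <- list()
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      e2 <- rbind(edges[-i, , drop = FALSE],
                  c(a, next_internal), c(next_internal, b),
                  c(next_internal, k))
      out <- c(out, grow(e2, k + 1, next_internal + 1))
    }
    out
  }
  base <- cbind(c(n + 1, n + 1, n + 1), c(1, 2, 3))
  all_edges <- grow(base, 4, n + 2)
  lapply(all_edges, function(e) {
    storage.mode(e) <- "integer"
    phylo_from_edge(cpp_canonical_edge(e, n), labels)
  })
}

#' Exhaustive parsimony search
#'
#' Scores every unrooted binary topology (optionally filtered by a
#' constraint) and returns all shortest trees. Exact; intended as the
#' small-problem oracle against which the heuristic search is validated.
#'
#' @inheritParams mp_search
#' @return a `tree_buffer` (no collapse applied; `collapsed_trees` holds the
#'   min-length-zero deduplication for convenience).
#' @export
exhaustive_search <- function(m, constraint = NULL) {
  taxa <- m$taxa[m$active_taxa]
  topos <- all_topologies(taxa)
  if (!is.null(constraint))
    topos <- Filter(function(t) satisfies_constraint(t, constraint), topos)
  if (length(topos) == 0) stopf("constraint unsatisfiable")
  lens <- vapply(topos, tree_length, 0, m = m)
  best <- min(lens)
  trees <- topos[lens < best + 1e-9]
  class(trees) <- "multiPhylo"
  collapsed <- dedup_trees(lapply(trees, collapse_zero_branches, m = m))
  new_tree_buffer(trees, best, collapsed = collapsed)
}
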