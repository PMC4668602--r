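# build a phylo over `taxa` from a set of mutually compatible taxon blocks
tree_from_blocks <- function(blocks, taxa) {
  taxa <- sort(taxa)
  n <- length(taxa)
  # sort blocks small-to-large so parents are attached after children
  blocks <- blocks[order(lengths(blocks))]
  node_of_tip <- seq_len(n)
  # start from the star tree: every tip hangs off the root
  children <- list()            # children[[internal id]] = vector of node ids
  root <- n + 1L
  children[[root]] <- seq_len(n)
  parent <- integer(0)          # parent[node id] = internal id
  parent[seq_len(n)] <- root
  parent[root] <- 0L
  next_id <- root + 1L
  for (b in blocks) {
    tip_ids <- match(sort(b), taxa)
    # nodes to regroup: maximal current nodes whose tip set lies inside b
    covered <- function(v) {
      tips <- tips_below(v, children, n)
      all(taxa[tips] %in% b)
    }
    # host: parent of the maximal current node that contains tip 1 of the
    # block and lies inside it (climb past already-built nested blocks)
    v <- tip_ids[1]
    while (parent[v] != 0L && covered(parent[v])) v <- parent[v]
    host <- parent[v]
    if (host == 0L) next  # block covers everything: no split to add
    grp <- children[[host]][vapply(children[[host]], covered, TRUE)]
    if (length(grp) < 2 ||
        (length(grp) == length(children[[host]]) && host != root))
      next  # block already implied by an equal clade
    new <- next_id; next_id <- next_id + 1L
    children[[host]] <- c(setdiff(children[[host]], grp), new)
    children[[new]] <- grp
    parent[new] <- host
    for (g in grp) parent[g] <- new
  }
  # flatten to an edge matrix
  edges <- matrix(0L, 0, 2)
  walk <- function(v) {
    for (c in children[[v]]) {
      edges <<- rbind(edges, c(v, c))
      if (c > n) walk(c)
    }
  }
  walk(root)
  # compact internal ids to n+1 .. n+Nnode in preorder
  ids <- unique(as.vector(t(edges)))
  internal <- ids[ids > n]
  remap <- integer(max(ids)); remap[seq_len(n)] <- seq_len(n)
  remap[internal] <- n + seq_along(internal)
  edges[] <- remap[edges]
  structure(list(edge = edges, tip.label = taxa,
                 Nnode = length(internal)),
            class = "phylo", order = "cladewise")
}

tips_below <- function(v, children, n) {
  if (v <= n) return(v)
  unlist(lapply(children[[v]], tips_below, children = children, n = n))
}

#' Strict consensus tree
#'
#' The tree whose internal branches are exactly the bipartitions shared by
#' every input tree. Idempotent; order-independent; the consensus of a set
#' plus its own consensus is unchanged.
#'
#' @param trees a `multiPhylo` or list of `phylo` over the same taxa.
#' @return a `phylo`, generally with polytomies.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) stopf("no trees")
  taxa <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!setequal(t$tip.label, taxa)) stopf("trees are not over the same taxa")
  keys <- Reduce(intersect, lapply(trees, function(t) as.character(bipartitions(t))))
  bp1 <- bipartitions(trees[[1]])
  blocks <- attr(bp1, "blocks")[keys]
  tree_from_blocks(blocks, taxa)
}

#' Maximum agreement subtree (greedy heuristic)
#'
#' Finds a large set of taxa on which all input trees induce the same
#' topology, by iteratively deleting the taxon involved in the most
#' conflicting bipartitions (ties broken alphabetically), then attempting to
#' re-add deleted taxa. The result is verified: restricted to the returned
#' taxa, all trees are identical. Exact maximality is not guaranteed (the
#' problem is hard); the result is maximal under single re-additions.
#'
#' @param trees a `multiPhylo` or list of `phylo` over the same taxa.
#' @return a `phylo` on the retained taxa, with `attr(,"dropped")` listing
#'   the deleted taxa.
#' @export
agreement_subtree <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) stopf("no trees")
  taxa <- sort(trees[[1]]$tip.label)
  restrict <- function(t, keep) {
    if (length(keep) == length(t$tip.label)) return(t)
    ape::keep.tip(t, keep)
  }
  agree <- function(keep) {
    if (length(keep) <= 3) return(TRUE)
    sub <- lapply(trees, restrict, keep = keep)
    ids <- vapply(sub, topology_id, "")
    all(ids == ids[1])
  }
  # how close to agreement a taxon set is: splits shared by all trees minus
  # splits present in some but not all (so full agreement scores highest)
  agreement_score <- function(keep) {
    keysets <- lapply(trees, function(t)
      as.character(bipartitions(restrict(t, keep))))
    shared <- Reduce(intersect, keysets)
    2 * length(shared) - length(unique(unlist(keysets)))
  }
  keep <- taxa
  while (!agree(keep) && length(keep) > 3) {
    # delete the taxon whose removal best restores agreement
    # (candidates in sorted order, so ties break alphabetically)
    scores <- vapply(keep, function(x)
      agreement_score(setdiff(keep, x)), 0)
    keep <- setdiff(keep, keep[which.max(scores)])
  }
  # polish: try to re-add dropped taxa one at a time (alphabetical order)
  repeat {
    added <- FALSE
    for (d in setdiff(taxa, keep)) {
      if (agree(sort(c(keep, d)))) { keep <- sort(c(keep, d)); added <- TRUE }
    }
    if (!added) break
  }
  out <- restrict(trees[[1]], keep)
  attr(out, "dropped") <- setdiff(taxa, keep)
  out
}
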