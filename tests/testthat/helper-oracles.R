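# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain enumeration over ancestral assignments and
# topologies, used to validate the optimized engines.

# minimum changes of one character on a tree by enumerating every assignment
# of observed states to internal nodes (tips range over their allowed sets)
oracle_char_steps <- function(tree, m, char) {
  idx <- match(tree$tip.label, m$taxa)
  cellmask <- m$masks[idx, char]
  tip_sets <- lapply(cellmask, function(mk) {
    s <- which(bitwAnd(bitwShiftR(as.integer(mk), 0:9), 1L) == 1L) - 1L
    if (length(s) == 0) 0:9 else s
  })
  alphabet <- sort(unique(unlist(tip_sets)))
  nt <- length(tree$tip.label)
  internals <- sort(unique(as.vector(tree$edge[tree$edge > nt])))
  grids <- rep(list(alphabet), length(internals))
  best <- Inf
  assign_states <- function(k, st) {
    if (k > length(internals)) {
      # minimize over tip resolutions greedily: each tip independently picks
      # the state in its set matching its neighbor if possible
      cost <- 0
      for (i in seq_len(nrow(tree$edge))) {
        a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
        sa <- if (a <= nt) tip_sets[[a]] else st[match(a, internals)]
        sb <- if (b <= nt) tip_sets[[b]] else st[match(b, internals)]
        if (length(intersect(sa, sb)) == 0) cost <- cost + 1
        if (cost >= best) return(invisible())
      }
      best <<- min(best, cost)
      return(invisible())
    }
    for (s in alphabet) assign_states(k + 1, c(st, s))
    invisible()
  }
  assign_states(1, integer(0))
  best
}

oracle_tree_length <- function(tree, m) {
  cols <- which(m$active_chars)
  sum(m$weights[cols] *
        vapply(cols, function(j) oracle_char_steps(tree, m, j), 0))
}

# random cell-token matrix exercising every cell kind
rand_cells <- function(n_taxa, n_char, n_states = 2,
                       p_missing = 0.1, p_inapp = 0.05, p_poly = 0.05) {
  draw <- function() {
    u <- runif(1)
    if (u < p_missing) return("?")
    if (u < p_missing + p_inapp) return("-")
    if (u < p_missing + p_inapp + p_poly && n_states > 1)
      return(paste(sort(sample(0:(n_states - 1), 2)), collapse = ""))
    as.character(sample(0:(n_states - 1), 1))
  }
  cells <- matrix(vapply(seq_len(n_taxa * n_char), function(i) draw(), ""),
                  n_taxa, n_char)
  rownames(cells) <- paste0("t", seq_len(n_taxa))
  cells
}

rand_matrix <- function(n_taxa, n_char, ...) char_matrix(rand_cells(n_taxa, n_char, ...))

# path of the deposited study matrix; empty string when not packaged.
# Dropping the published 61-taxon x 178-character TNT file in
# inst/extdata/luisiella_p2197.tnt activates the dataset-dependent
# acceptance criteria.
deposited_matrix_path <- function() {
  system.file("extdata", "luisiella_p2197.tnt", package = "fitchsearch")
}
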