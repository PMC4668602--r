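# random unrooted binary topology by random sequential edge insertion
random_topology <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3)
  edges <- cbind(rep(n + 1L, 3), 1:3)
  next_internal <- n + 2L
  for (k in seq_len(n)[-(1:3)]) {
    i <- sample.int(nrow(edges), 1)
    a <- edges[i, 1]; b <- edges[i, 2]
    edges <- rbind(edges[-i, , drop = FALSE],
                   c(a, next_internal), c(next_internal, b),
                   c(next_internal, k))
    next_internal <- next_internal + 1L
  }
  storage.mode(edges) <- "integer"
  phylo_from_edge(cpp_canonical_edge(edges, n), labels)
}

#' Simulate a discrete morphological matrix on a random tree
#'
#' Generates a random unrooted binary topology, evolves unordered characters
#' along it under a symmetric Markov-style model (a fixed per-branch change
#' probability; on change, a uniformly drawn different state), then degrades
#' the matrix with missing, inapplicable, and polymorphic cells. The defaults
#' reproduce the conditions of a typical large morphological analysis:
#' 61 taxa, 178 characters, mostly binary with some three-state characters,
#' enough per-branch change probability that most informative characters are
#' homoplastic, and a realistic fraction of missing data. Every generated
#' true change is logged, so recovery of the generating topology and of
#' individual synapomorphies can be checked exactly.
#'
#' @param n_taxa,n_char dimensions.
#' @param state_counts pool of per-character state counts, sampled uniformly
#'   (default: 3 binary for every three-state character).
#' @param change_prob per-branch probability that the character changes.
#' @param missing_fraction,inapplicable_fraction,polymorphic_fraction
#'   independent per-cell degradation probabilities (applied in this order;
#'   a cell gets at most one kind).
#' @param seed integer seed; the full output is a pure function of the
#'   arguments when given.
#' @param taxa optional taxon labels (default `t01`, `t02`, ...).
#' @return list with `matrix` (a [char_matrix]), `tree` (the generating
#'   `phylo`), `changes` (data.frame of true changes: `char`, `parent`,
#'   `child`, `from`, `to`), and `params`.
#' @export
simulate_matrix <- function(n_taxa = 61, n_char = 178,
                            state_counts = c(2, 2, 2, 3),
                            change_prob = 0.05,
                            missing_fraction = 0.25,
                            inapplicable_fraction = 0.02,
                            polymorphic_fraction = 0.01,
                            seed = NULL, taxa = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- taxa %||% sprintf("t%02d", seq_len(n_taxa))
  stopifnot(length(taxa) == n_taxa, n_taxa >= 4, n_char >= 1)
  tree <- random_topology(taxa)
  nt <- n_taxa
  edge <- tree$edge
  # cladewise edge order lists each parent before its children, so states
  # can be propagated in one pass from the basal node
  cells <- matrix("", nt, n_char)
  changes <- list()
  nn <- max(edge)
  for (j in seq_len(n_char)) {
    k <- sample(state_counts, 1)
    state <- integer(nn)
    state[nt + 1L] <- sample.int(k, 1) - 1L
    for (i in seq_len(nrow(edge))) {
      p <- edge[i, 1]; v <- edge[i, 2]
      s <- state[p]
      if (stats::runif(1) < change_prob) {
        s2 <- sample(setdiff(0:(k - 1), s), 1)
        changes[[length(changes) + 1]] <-
          data.frame(char = j, parent = p, child = v, from = s, to = s2)
        s <- s2
      }
      state[v] <- s
    }
    cells[, j] <- as.character(state[seq_len(nt)])
    # polymorphism: add one extra state to a few scored cells
    if (k > 1 && polymorphic_fraction > 0) {
      hit <- which(stats::runif(nt) < polymorphic_fraction)
      for (i in hit) {
        s <- as.integer(cells[i, j])
        extra <- sample(setdiff(0:(k - 1), s), 1)
        cells[i, j] <- paste(sort(c(s, extra)), collapse = "")
      }
    }
  }
  # missing / inapplicable overwrite whole cells
  u <- matrix(stats::runif(nt * n_char), nt, n_char)
  cells[u < missing_fraction] <- "?"
  cells[u >= missing_fraction &
        u < missing_fraction + inapplicable_fraction] <- "-"
  m <- char_matrix(cells, taxa = taxa)
  list(matrix = m, tree = tree,
       changes = if (length(changes)) do.call(rbind, changes)
                 else data.frame(char = integer(0), parent = integer(0),
                                 child = integer(0), from = integer(0),
                                 to = integer(0)),
       params = list(n_taxa = n_taxa, n_char = n_char,
                     state_counts = state_counts, change_prob = change_prob,
                     missing_fraction = missing_fraction,
                     inapplicable_fraction = inapplicable_fraction,
                     polymorphic_fraction = polymorphic_fraction,
                     seed = seed))
}

#' Built-in miniature fixtures with known exact answers
#'
#' Deterministic hand-written matrices small enough for exhaustive analysis:
#' \describe{
#'   \item{`clean6`}{6 taxa, 5 compatible binary characters; a single MPT
#'     with zero homoplasy (CI = RI = 1).}
#'   \item{`homoplasy7`}{7 taxa with deliberately conflicting characters;
#'     multiple MPTs and CI < 1.}
#'   \item{`rogue6`}{`clean6` plus a seventh, mostly-missing taxon that
#'     attaches in several places, creating multiple MPTs whose strict
#'     consensus is partly unresolved.}
#' }
#'
#' @param name fixture name.
#' @return a [char_matrix].
#' @export
make_fixture <- function(name = c("clean6", "homoplasy7", "rogue6")) {
  name <- match.arg(name)
  rows <- switch(name,
    clean6 = c(A = "00000", B = "10000", C = "11000",
               D = "11100", E = "11110", F = "11111"),
    homoplasy7 = c(A = "000000", B = "110100", C = "111010",
                   D = "101001", E = "011110", F = "010101", G = "001011"),
    rogue6 = c(A = "000000", B = "100001", C = "110001",
               D = "111001", E = "111101", F = "111111", R = "1?????"))
  cells <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(cells) <- names(rows)
  char_matrix(cells)
}
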