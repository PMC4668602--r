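test_that("Fitch steps: textbook examples", {
  tr <- parse_newick("((A,B),(C,D));")
  m <- char_matrix(matrix(c("0", "0", "1", "1",   # clean split: 1 step
                            "0", "1", "0", "1",   # conflicting: 2 steps
                            "0", "0", "0", "0"),  # constant: 0 steps
                          nrow = 4,
                          dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_equal(fitch_steps(tr, m), c(1L, 2L, 0L))
  expect_equal(tree_length(tr, m), 3)
})

test_that("missing/inapplicable never add steps; polymorphism resolves freely", {
  tr <- parse_newick("((A,B),(C,D));")
  m <- char_matrix(matrix(c("0", "?", "1", "1",
                            "0", "-", "1", "1",
                            "01", "0", "1", "1"),
                          nrow = 4,
                          dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_equal(fitch_steps(tr, m), c(1L, 1L, 1L))
})

test_that("Fitch equals brute-force oracle on random data (binary trees)", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    m <- rand_matrix(n, 6, n_states = 3)
    tr <- fitchsearch:::random_topology(m$taxa)
    expect_equal(tree_length(tr, m), oracle_tree_length(tr, m),
                 info = sprintf("rep %d", rep))
  }
})

test_that("polytomies are scored exactly (hard polytomy oracle)", {
  set.seed(12)
  # star tree plus one resolved pair: compare against assignment enumeration
  tr <- parse_newick("((A,B),C,D,E);")
  for (rep in 1:10) {
    m <- rand_matrix(5, 5, n_states = 3)
    tr2 <- tr
    tr2$tip.label <- m$taxa  # map A..E onto t1..t5
    expect_equal(tree_length(tr2, m), oracle_tree_length(tr2, m))
  }
})

test_that("Fitch agrees with phangorn on independent random instances", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    m <- rand_matrix(n, 20, n_states = 3)
    tr <- fitchsearch:::random_topology(m$taxa)
    cells <- fitchsearch:::cells_of(m)
    # build a phyDat with explicit contrasts for ?, -, and polymorphic cells
    lv <- c("0", "1", "2")
    toks <- sort(unique(as.vector(cells)))
    contrast <- t(vapply(toks, function(tk) {
      if (tk %in% c("?", "-")) rep(1, 3)
      else as.numeric(lv %in% strsplit(tk, "")[[1]])
    }, numeric(3)))
    dimnames(contrast) <- list(toks, lv)
    pd <- phangorn::phyDat(cells, type = "USER", contrast = contrast)
    expect_equal(tree_length(tr, m),
                 phangorn::parsimony(tr, pd, method = "sankoff"),
                 info = sprintf("rep %d", rep))
  }
})

test_that("char_min_steps / char_max_steps and informativeness", {
  cells <- matrix(c("0", "0", "1", "1", "2",   # 3 states: m=2, g=5-2=3
                    "0", "0", "0", "0", "1",   # autapomorphy: m=1, g=1
                    "0", "0", "0", "0", "0",   # constant: m=0, g=0
                    "?", "?", "0", "1", "1",   # m=1, g=3-2=1 -> uninformative
                    "01", "1", "0", "0", "0"), # polymorphic covers: m=0? no:
                   nrow = 5,                   # {01},1,0,0,0 -> state 0 hits 4,
                   dimnames = list(paste0("t", 1:5), NULL))  # state1 misses 3
  m <- char_matrix(cells)
  expect_equal(char_min_steps(m), c(2L, 1L, 0L, 1L, 1L))
  expect_equal(char_max_steps(m), c(3L, 1L, 0L, 1L, 1L))
  expect_equal(informative_chars(m), c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("min <= observed <= max steps on every tree (property)", {
  set.seed(14)
  for (rep in 1:10) {
    m <- rand_matrix(7, 10, n_states = 3)
    tr <- fitchsearch:::random_topology(m$taxa)
    s <- fitch_steps(tr, m)
    expect_true(all(char_min_steps(m) <= s))
    expect_true(all(s <= char_max_steps(m)))
  }
})

test_that("ensemble indices: CI/RI formulas and conventions", {
  m <- make_fixture("clean6")
  ex <- exhaustive_search(m)
  sc <- ensemble_indices(ex$trees, m)
  expect_equal(sc$ci, 1)
  expect_equal(sc$ri, 1)
  m2 <- make_fixture("homoplasy7")
  ex2 <- exhaustive_search(m2)
  sc2 <- ensemble_indices(ex2$trees, m2)
  pc <- sc2$per_char
  expect_equal(sc2$ci, sum(pc$min_steps) / sum(pc$steps))
  expect_equal(sc2$ri, (sum(pc$max_steps) - sum(pc$steps)) /
                       (sum(pc$max_steps) - sum(pc$min_steps)))
  expect_lt(sc2$ci, 1)
  # informative-only convention drops uninformative characters
  keep <- pc$informative
  expect_equal(sc2$ci_informative,
               sum(pc$min_steps[keep]) / sum(pc$steps[keep]))
})

test_that("unequal-length tree sets are rejected; zero-step CI convention", {
  m <- make_fixture("clean6")
  ex <- exhaustive_search(m)
  other <- all_topologies(m$taxa)[[5]]
  if (tree_length(other, m) != ex$best_length)
    expect_error(ensemble_indices(list(ex$trees[[1]], other), m), "equal length")
  mc <- char_matrix(matrix(rep("0", 8), 4, 2,
                           dimnames = list(LETTERS[1:4], NULL)))
  tr <- parse_newick("((A,B),(C,D));")
  expect_warning(sc <- ensemble_indices(tr, mc), "convention")
  expect_equal(sc$ci, 1)
})

test_that("character weights scale lengths and indices", {
  tr <- parse_newick("((A,B),(C,D));")
  cells <- matrix(c("0", "0", "1", "1", "0", "1", "0", "1"), nrow = 4,
                  dimnames = list(c("A", "B", "C", "D"), NULL))
  m1 <- char_matrix(cells)
  m2 <- char_matrix(cells, weights = c(2, 3))
  expect_equal(tree_length(tr, m1), 1 + 2)
  expect_equal(tree_length(tr, m2), 2 * 1 + 3 * 2)
})

test_that("min branch lengths and the collapse rule", {
  # char support for {C,D}: one character; the other internal split unsupported
  cells <- matrix(c("0", "0", "1", "1", "0",
                    "0", "0", "1", "1", "0"), nrow = 5,
                  dimnames = list(c("A", "B", "C", "D", "E"), NULL))
  m <- char_matrix(cells)
  tr <- parse_newick("((A,B),(E,(C,D)));")
  mb <- min_branch_lengths(tr, m)
  expect_true(any(mb$min_length == 0))   # the A,B edge has no possible change
  expect_true(any(mb$min_length == 2))   # the C,D edge carries both changes
  coll <- collapse_zero_branches(tr, m)
  expect_lt(coll$Nnode, tr$Nnode)
  # collapse does not change tree length
  expect_equal(tree_length(coll, m), tree_length(tr, m))
})
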