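tnt_example <- "xread
'example matrix'
5 4
Taxon_A  01[01]?-
Taxon_B  10010
Taxon_C  1101?
Taxon_D  0?2-1
;
"

nexus_example <- "#NEXUS
BEGIN DATA;
DIMENSIONS NTAX=4 NCHAR=5;
FORMAT SYMBOLS=\"0 1 2\" MISSING=? GAP=-;
MATRIX
Taxon_A  01(01)?-
Taxon_B  10010
Taxon_C  1101?
Taxon_D  0?2-1
;
END;
"

test_that("TNT parsing: states, polymorphism, missing, inapplicable", {
  m <- read_char_matrix(text = tnt_example)
  expect_s3_class(m, "char_matrix")
  expect_equal(dim(m), c(4, 5))
  expect_equal(m$taxa, c("Taxon_A", "Taxon_B", "Taxon_C", "Taxon_D"))
  cells <- fitchsearch:::cells_of(m)
  expect_equal(unname(cells["Taxon_A", ]), c("0", "1", "01", "?", "-"))
  expect_equal(unname(cells["Taxon_D", ]), c("0", "?", "2", "-", "1"))
  # missing and inapplicable are stored distinctly
  expect_equal(m$special[1, 4], 1L)
  expect_equal(m$special[1, 5], 2L)
  # but both carry the full observed state set of the character
  expect_equal(m$masks[1, 4], Reduce(bitwOr, m$masks[-1, 4]))
})

test_that("whitespace in labels normalizes to underscore; exact matching", {
  nex <- "#NEXUS\nBEGIN DATA;\nDIMENSIONS NTAX=2 NCHAR=2;\nMATRIX\n'Taxon  B' 01\nC 10\n;\nEND;"
  m <- read_char_matrix(text = nex)
  expect_true("Taxon_B" %in% m$taxa)      # was quoted 'Taxon  B'
  cm <- char_matrix(matrix(c("0", "1"), 1, 2), taxa = "A  strange \t name")
  expect_equal(cm$taxa, "A_strange_name")
})

test_that("NEXUS parsing agrees with TNT parsing cell-for-cell", {
  a <- read_char_matrix(text = tnt_example)
  b <- read_char_matrix(text = nexus_example)
  expect_identical(fitchsearch:::cells_of(a), fitchsearch:::cells_of(b))
})

test_that("auto-detection picks the right dialect", {
  expect_equal(dim(read_char_matrix(text = tnt_example, format = "auto")),
               c(4, 5))
  expect_equal(dim(read_char_matrix(text = nexus_example, format = "auto")),
               c(4, 5))
  expect_error(read_char_matrix(text = "no format here"), "auto-detect")
})

test_that("dimension mismatches and undeclared symbols are explicit errors", {
  bad_dim <- "xread\n3 2\nA 010\nB 01\n;"
  expect_error(read_char_matrix(text = bad_dim), "dimension mismatch")
  bad_ntax <- "xread\n3 3\nA 010\nB 011\n;"
  expect_error(read_char_matrix(text = bad_ntax), "dimension mismatch")
  bad_sym <- "xread\n3 2\nA 0X0\nB 010\n;"
  expect_error(read_char_matrix(text = bad_sym), "undeclared state symbol")
  dup <- "xread\n2 2\nA 01\nA 10\n;"
  expect_error(read_char_matrix(text = dup), "duplicate taxon")
})

test_that("round trip: write then read is cell-identical, both dialects", {
  set.seed(7)
  m <- char_matrix(rand_cells(8, 12, n_states = 3))
  for (fmt in c("tnt", "nexus")) {
    txt <- write_char_matrix(m, format = fmt)
    m2 <- read_char_matrix(text = txt)
    expect_identical(fitchsearch:::cells_of(m2), fitchsearch:::cells_of(m),
                     info = fmt)
  }
})

test_that("writing is deterministic (byte-identical on identical input)", {
  m <- read_char_matrix(text = tnt_example)
  expect_identical(write_char_matrix(m, format = "tnt"),
                   write_char_matrix(m, format = "tnt"))
})

test_that("polymorphic groups need >= 2 digits; unterminated groups error", {
  expect_error(read_char_matrix(text = "xread\n2 2\nA [0]1\nB 01\n;"),
               ">= 2 state digits")
  expect_error(read_char_matrix(text = "xread\n2 2\nA [01\nB 01\n;"),
               "unterminated")
})

test_that("file-based IO works", {
  f <- tempfile(fileext = ".tnt")
  writeLines(tnt_example, f)
  m <- read_char_matrix(file = f)
  expect_equal(dim(m), c(4, 5))
  f2 <- tempfile(fileext = ".nex")
  write_char_matrix(m, file = f2, format = "nexus")
  expect_identical(fitchsearch:::cells_of(read_char_matrix(file = f2)),
                   fitchsearch:::cells_of(m))
})
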