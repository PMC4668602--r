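`%||%` <- function(a, b) if (is.null(a)) b else a

# Taxon labels are matched exactly after collapsing runs of whitespace and
# underscores to a single underscore (no fuzzy matching).
normalize_label <- function(x) {
  x <- gsub("^[ _\t]+|[ _\t]+$", "", x)
  gsub("[ \t_]+", "_", x)
}

# bitmask helpers: bit k (0-based) of an integer mask = state k allowed
states_to_mask <- function(states) {
  as.integer(sum(bitwShiftL(1L, unique(as.integer(states)))))
}

mask_to_states <- function(mask) {
  which(bitwAnd(bitwShiftR(as.integer(mask), 0:9), 1L) == 1L) - 1L
}

mask_popcount <- function(mask) {
  sum(bitwAnd(bitwShiftR(as.integer(mask), 0:9), 1L))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
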