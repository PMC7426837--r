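#' @keywords internal
"_PACKAGE"

# Condition helper: every contract violation raises a classed error so callers
# (and tests) can catch specific failure modes rather than matching messages.
dg_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "digenomeR_error")))
}

dg_assert <- function(ok, msg, class) {
  if (!isTRUE(ok)) dg_stop(msg, class)
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

is_dna <- function(x, extra = "") {
  grepl(paste0("^[ACGT", extra, "]+$"), x)
}

# deterministic sub-seed derivation; keeps values inside 32-bit range
dg_subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k) %% 2147483647)
}
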