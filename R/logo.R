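#' Build a position frequency matrix
#'
#' Column-wise base counts over a set of equal-length sequences
#' (A/C/G/T/N; N is excluded from counts and tracked per column).
#'
#' @param sequences Character vector of equal-length sequences.
#' @return An object of class \code{"pfm"}: list with \code{counts}
#'   (L x 4 integer matrix, columns A/C/G/T), \code{n_sequences} and
#'   \code{n_counted} (per-position non-N count).
#' @export
build_pfm <- function(sequences) {
  dg_assert(length(sequences) > 0L, "no sequences supplied",
            "digenomeR_empty_sequences")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  dg_assert(length(unique(lens)) == 1L,
            "sequences must all have the same length",
            "digenomeR_ragged_lengths")
  dg_assert(all(grepl("^[ACGTN]+$", sequences)),
            "sequences must be over A/C/G/T/N",
            "digenomeR_bad_alphabet")
  L <- lens[1L]
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, bases))
  for (p in seq_len(L)) {
    bp <- substr(sequences, p, p)
    counts[p, ] <- as.integer(table(factor(bp, levels = bases)))
  }
  structure(list(counts = counts, n_sequences = length(sequences),
                 n_counted = rowSums(counts)),
            class = "pfm")
}

#' Information content profile of a PFM
#'
#' Per-position information \code{R = 2 - (H + e(n))} bits, where \code{H} is
#' the Shannon entropy of the column's base frequencies and \code{e(n) =
#' 3 / (2 ln(2) n)} is the small-sample correction (on by default, the
#' WebLogo convention); negative corrected values are clamped to 0. Per-base
#' letter heights are \code{frequency x R}.
#'
#' @param pfm A [build_pfm()] result.
#' @param small_sample_correction Apply \code{e(n)} (default \code{TRUE}).
#' @return A list with \code{bits} (per-position numeric) and \code{heights}
#'   (L x 4 matrix; each row sums to its position's bits).
#' @export
information_content <- function(pfm, small_sample_correction = TRUE) {
  n <- pfm$n_counted
  freq <- pfm$counts / pmax(n, 1L)
  h <- apply(freq, 1L, function(f) {
    f <- f[f > 0]
    if (!length(f)) return(2)   # empty column carries no information
    -sum(f * log2(f))
  })
  e <- if (small_sample_correction) 3 / (2 * log(2) * pmax(n, 1L)) else 0
  bits <- pmax(0, 2 - (h + e))
  bits[n == 0L] <- 0
  heights <- freq * bits
  list(bits = bits, heights = heights)
}

#' Write a PFM with information content as TSV
#' @param pfm A [build_pfm()] result.
#' @param path Output path.
#' @param small_sample_correction Passed to [information_content()].
#' @export
write_pfm_tsv <- function(pfm, path, small_sample_correction = TRUE) {
  ic <- information_content(pfm, small_sample_correction)
  df <- data.frame(position = seq_len(nrow(pfm$counts)), pfm$counts,
                   bits = ic$bits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract logo input sequences from captured sites
#'
#' Returns the PAM tetramer followed by the site protospacer (padded /
#' truncated to 23 nt for bulged sites so all rows align), PAM-first, the
#' orientation used for captured-site logos.
#'
#' @param sites A \code{"candidate_sites"} data frame with \code{pam} and
#'   \code{protospacer} columns.
#' @return Character vector of 27-nt sequences.
#' @export
site_logo_sequences <- function(sites) {
  proto <- sites$protospacer
  pad <- function(x) {
    x <- substr(x, 1L, 23L)
    paste0(x, strrep("N", 23L - nchar(x)))
  }
  paste0(sites$pam, vapply(proto, pad, character(1), USE.NAMES = FALSE))
}
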