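#' Amplicon specification for targeted deep-sequencing quantification
#'
#' @param name Site name.
#' @param reference Reference amplicon sequence (A/C/G/T).
#' @param protospacer_start 1-based offset of protospacer position 1 within
#'   the amplicon.
#' @param strand Strand of the protospacer relative to the amplicon
#'   (\code{"+"} or \code{"-"}).
#' @param window Protospacer position range summarised as the site editing
#'   frequency (default \code{c(8, 13)}, the deamination window).
#' @param protospacer_length Protospacer length in nt (default 23).
#' @return A list of class \code{"amplicon_spec"}.
#' @export
amplicon_spec <- function(name, reference, protospacer_start,
                          strand = c("+", "-"), window = c(8L, 13L),
                          protospacer_length = 23L) {
  strand <- match.arg(strand)
  reference <- toupper(reference)
  dg_assert(is_dna(reference), "amplicon must be over A/C/G/T",
            "digenomeR_bad_alphabet")
  dg_assert(protospacer_start >= 1L &&
              protospacer_start + protospacer_length - 1L <= nchar(reference),
            "protospacer interval outside amplicon",
            "digenomeR_bad_config")
  structure(list(name = name, reference = reference,
                 protospacer_start = as.integer(protospacer_start),
                 strand = strand, window = as.integer(window),
                 protospacer_length = as.integer(protospacer_length)),
            class = "amplicon_spec")
}

# amplicon coordinate of protospacer position k
proto_to_amplicon <- function(spec, k) {
  if (spec$strand == "+") spec$protospacer_start + k - 1L
  else spec$protospacer_start + spec$protospacer_length - k
}

# locate a length-changing event by longest common prefix/suffix against the
# reference; returns the 1-based reference interval the event touches
locate_indel <- function(read, ref) {
  rn <- nchar(read); fn <- nchar(ref)
  rc <- seq_chars(read); fc <- seq_chars(ref)
  m <- min(rn, fn)
  pre <- 0L
  while (pre < m && rc[pre + 1L] == fc[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < m - pre && rc[rn - suf] == fc[fn - suf]) suf <- suf + 1L
  c(start = pre + 1L, end = max(pre + 1L, fn - suf))
}

#' Per-position editing profile of an amplicon
#'
#' Compares each read with the reference amplicon. Reads whose length equals
#' the reference are treated as indel-free and contribute per-position base
#' counts; reads of different length carry an indel, located by an
#' end-anchored comparison, and count toward \code{reads_with_indel} when the
#' event overlaps the protospacer extended by \code{indel_flank} bp. Indel
#' reads are excluded from substitution fractions (a frameshift would corrupt
#' downstream base calls). The site editing frequency is the maximum C-to-T
#' fraction (on the protospacer strand) over reference C positions inside the
#' summary window.
#'
#' @param reads Character vector of merged read sequences spanning the
#'   amplicon.
#' @param spec An [amplicon_spec()].
#' @param indel_flank Bp added on each side of the protospacer for indel
#'   counting (default 10).
#' @param min_reads_warn Warn when fewer reads than this are supplied
#'   (default 100).
#' @return An object of class \code{"editing_profile"}: a list with a
#'   per-position data frame (\code{position}, \code{ref}, counts of
#'   A/C/G/T/other, \code{sub_fraction}), \code{reads_total},
#'   \code{reads_with_indel}, \code{indel_frequency} and
#'   \code{site_editing_frequency}.
#' @export
profile_amplicon <- function(reads, spec, indel_flank = 10L,
                             min_reads_warn = 100L) {
  dg_assert(length(reads) > 0L, "no reads supplied",
            "digenomeR_empty_reads")
  if (length(reads) < min_reads_warn) {
    warning(sprintf("only %d reads for amplicon %s (< %d)",
                    length(reads), spec$name, min_reads_warn))
  }
  reads <- toupper(reads)
  ref <- spec$reference
  L <- nchar(ref)
  same_len <- nchar(reads) == L

  # indel reads: event located by end-anchored comparison
  proto_lo <- spec$protospacer_start - indel_flank
  proto_hi <- spec$protospacer_start + spec$protospacer_length - 1L +
    indel_flank
  n_indel <- 0L
  for (rd in reads[!same_len]) {
    iv <- locate_indel(rd, ref)
    if (iv["end"] >= proto_lo && iv["start"] <= proto_hi) {
      n_indel <- n_indel + 1L
    }
  }

  clean <- reads[same_len]
  refc <- seq_chars(ref)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = L, ncol = 5L,
                   dimnames = list(NULL, c(bases, "other")))
  if (length(clean)) {
    for (p in seq_len(L)) {
      bp <- substr(clean, p, p)
      tb <- table(factor(ifelse(bp %in% bases, bp, "other"),
                         levels = c(bases, "other")))
      counts[p, ] <- as.integer(tb)
    }
  }
  n_clean <- length(clean)
  sub_fraction <- if (n_clean) {
    (n_clean - counts[cbind(seq_len(L), match(refc, bases))]) / n_clean
  } else rep(0, L)

  # C->T fraction on the protospacer strand at window positions
  win <- spec$window[1L]:spec$window[2L]
  edited_base <- if (spec$strand == "+") c(ref = "C", alt = "T") else
    c(ref = "G", alt = "A")
  freqs <- vapply(win, function(k) {
    p <- proto_to_amplicon(spec, k)
    if (refc[p] != edited_base["ref"] || n_clean == 0L) return(NA_real_)
    counts[p, edited_base["alt"]] / n_clean
  }, numeric(1))
  site_freq <- if (all(is.na(freqs))) 0 else max(freqs, na.rm = TRUE)

  structure(list(
    profile = data.frame(position = seq_len(L), ref = refc,
                         counts, sub_fraction = sub_fraction,
                         stringsAsFactors = FALSE),
    reads_total = length(reads),
    reads_no_indel = n_clean,
    reads_with_indel = n_indel,
    indel_frequency = n_indel / length(reads),
    site_editing_frequency = site_freq,
    spec = spec), class = "editing_profile")
}

#' @export
print.editing_profile <- function(x, ...) {
  cat(sprintf(
    "editing_profile '%s': %d reads, editing frequency %.4f, indel frequency %.4f\n",
    x$spec$name, x$reads_total, x$site_editing_frequency,
    x$indel_frequency))
  invisible(x)
}

#' Relative activity of a mismatched guide
#'
#' Editing frequency obtained with the mismatched crRNA divided by that with
#' the matched crRNA, expressed in percent; a measure of mismatch tolerance.
#'
#' @param freq_mismatched,freq_matched Editing frequencies (fractions).
#' @return Percent (100 = equal activity).
#' @export
relative_activity <- function(freq_mismatched, freq_matched) {
  dg_assert(freq_matched > 0,
            "matched-guide frequency is 0: relative activity undefined",
            "digenomeR_undefined_activity")
  100 * freq_mismatched / freq_matched
}

#' OTI index (off-target effect)
#'
#' Ratio of the sum of mutation frequencies at validated off-target sites to
#' the mutation frequency at the on-target site.
#'
#' @param on_freq On-target frequency (fraction, > 0).
#' @param off_freqs Numeric vector of off-target frequencies (possibly
#'   empty).
#' @return A ratio (0 when there are no off-target sites).
#' @export
oti_index <- function(on_freq, off_freqs = numeric()) {
  dg_assert(on_freq > 0, "on-target frequency is 0: OTI undefined",
            "digenomeR_undefined_index")
  sum(off_freqs) / on_freq
}

#' Specificity ratio of a base-editor variant
#'
#' (variant on-target / variant off-target) divided by
#' (wild-type on-target / wild-type off-target); values above 1 mean the
#' variant discriminates the off-target site better than the wild type.
#'
#' @param variant_on,variant_off,wt_on,wt_off Editing frequencies
#'   (fractions).
#' @return A ratio.
#' @export
specificity_ratio <- function(variant_on, variant_off, wt_on, wt_off) {
  for (nm in c("variant_off", "wt_on", "wt_off")) {
    v <- get(nm)
    dg_assert(v > 0, sprintf("%s is 0: specificity ratio undefined", nm),
              "digenomeR_undefined_ratio")
  }
  (variant_on / variant_off) / (wt_on / wt_off)
}

#' Write an editing profile as TSV
#' @param profile An [profile_amplicon()] result.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile$profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
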