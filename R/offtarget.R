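#' crRNA target specification
#'
#' A 23-nt protospacer, numbered 1-23 in the 5'-to-3' direction with position
#' 1 adjacent to the PAM (Cas12a places its PAM 5' of the protospacer).
#' Mismatches are only ever counted over positions 1-20: mismatches at
#' positions 21-23 have little effect on editing and are ignored by the
#' capture rule.
#'
#' @param name Target name (e.g. the locus the crRNA targets).
#' @param protospacer 23-nt string over A/C/G/T.
#' @param pam_pattern PAM used for candidate capture; the canonical motif is
#'   TTTV but the capture rule scans TTTN (default).
#' @return A list of class \code{"target_spec"}.
#' @export
target_spec <- function(name, protospacer, pam_pattern = "TTTN") {
  protospacer <- toupper(protospacer)
  dg_assert(nchar(protospacer) == 23L && is_dna(protospacer),
            "protospacer must be 23 nt over A/C/G/T",
            "digenomeR_bad_protospacer")
  structure(list(name = name, protospacer = protospacer,
                 pam_pattern = pam_pattern),
            class = "target_spec")
}

#' Classify a PAM tetramer
#'
#' Canonical Cas12a capture PAM is 5'-TTTN-3'; the PAM-like classes are
#' NTTN, TNTN and TTNN (one fixed T relaxed). A tetramer matching TTTN is
#' always canonical, never PAM-like. N bases in the genome never match the
#' fixed T positions.
#'
#' @param tetramer Character vector of 4-nt strings (A/C/G/T; N tolerated in
#'   genomic input and never matches a fixed position).
#' @return Character vector: \code{"canonical"}, \code{"pam_like"} or
#'   \code{"none"}.
#' @examples
#' classify_pam(c("TTTA", "ATTC", "GCGA"))
#' @export
classify_pam <- function(tetramer) {
  dg_assert(all(nchar(tetramer) == 4L),
            "PAM tetramer must be 4 nt", "digenomeR_bad_pam")
  dg_assert(all(grepl("^[ACGTN]{4}$", tetramer)),
            "PAM tetramer must be over A/C/G/T (N tolerated)",
            "digenomeR_bad_pam")
  b1 <- substr(tetramer, 1L, 1L) == "T"
  b2 <- substr(tetramer, 2L, 2L) == "T"
  b3 <- substr(tetramer, 3L, 3L) == "T"
  canonical <- b1 & b2 & b3
  pam_like <- !canonical & ((b2 & b3) | (b1 & b3) | (b1 & b2))
  ifelse(canonical, "canonical", ifelse(pam_like, "pam_like", "none"))
}

# mismatch positions over protospacer positions 1-20; N never matches
mism20 <- function(tchars, cchars) {
  which(tchars[1:20] != cchars[1:20])
}

new_site_alignment <- function(window = NA_character_, pam = NA_character_,
                               pam_class = NA_character_, protospacer,
                               mismatch_positions, bulge = "none",
                               bulge_pos = NA_integer_, aln = NA_character_,
                               bulge_penalty = 2L) {
  mm <- length(mismatch_positions)
  structure(list(
    window_sequence = window, pam_tetramer = pam, pam_class = pam_class,
    protospacer = protospacer,
    mismatch_positions = as.integer(mismatch_positions),
    mismatch_count = mm, bulge = bulge, bulge_pos = bulge_pos,
    score = mm + if (bulge == "none") 0L else as.integer(bulge_penalty),
    aln = aln), class = "site_alignment")
}

#' @export
print.site_alignment <- function(x, ...) {
  cat(sprintf("site_alignment: PAM %s (%s), %d mismatch(es)%s, score %d\n",
              x$pam_tetramer, x$pam_class, x$mismatch_count,
              if (x$bulge == "none") "" else
                sprintf(", %s bulge at %d", x$bulge, x$bulge_pos),
              x$score))
  if (!is.na(x$aln)) cat(" ", x$aln, "\n")
  invisible(x)
}

#' Count protospacer mismatches (ungapped)
#'
#' Compares a candidate 23-mer with the target protospacer position by
#' position. Only positions 1-20 contribute mismatches; positions 21-23 are
#' carried but never counted.
#'
#' @param target A [target_spec()].
#' @param candidate 23-nt string (A/C/G/T/N; N counts as a mismatch).
#' @return A \code{"site_alignment"} object with \code{bulge = "none"}.
#' @export
count_mismatches <- function(target, candidate) {
  candidate <- toupper(candidate)
  dg_assert(nchar(candidate) == 23L,
            "candidate protospacer must be 23 nt",
            "digenomeR_length_mismatch")
  tch <- seq_chars(target$protospacer)
  cch <- seq_chars(candidate)
  mmp <- mism20(tch, cch)
  aln <- cch
  aln[mmp] <- tolower(aln[mmp])
  new_site_alignment(protospacer = candidate, mismatch_positions = mmp,
                     aln = paste(aln, collapse = ""))
}

#' Best gapped or ungapped alignment of the target to a genomic window
#'
#' Evaluates the ungapped placement plus every single-nucleotide RNA bulge
#' (the genomic site lacks one base relative to the protospacer, leaving a
#' guide base unpaired) and DNA bulge (the genomic site carries one extra
#' base). A bulge costs \code{bulge_penalty} mismatch-equivalents; the
#' alignment with the lowest effective score wins, with deterministic
#' tie-breaking: ungapped before bulged, RNA bulge before DNA bulge, then the
#' smallest bulge position.
#'
#' @param target A [target_spec()].
#' @param genomic_window String of at least 28 nt on the protospacer strand:
#'   4-nt PAM followed by at least 24 nt.
#' @param bulge_penalty Mismatch-equivalents charged for a 1-nt bulge
#'   (default 2).
#' @return A \code{"site_alignment"}; its \code{score} is never worse than
#'   the ungapped alignment's.
#' @export
align_with_bulge <- function(target, genomic_window, bulge_penalty = 2L) {
  w <- toupper(genomic_window)
  dg_assert(nchar(w) >= 28L,
            "window must hold PAM + 23 nt + 1 (>= 28 nt)",
            "digenomeR_window_too_short")
  pam <- substr(w, 1L, 4L)
  pc <- classify_pam(pam)
  tch <- seq_chars(target$protospacer)
  wch <- seq_chars(w)
  finish <- function(sa) {
    sa$window_sequence <- w
    sa$pam_tetramer <- pam
    sa$pam_class <- pc
    sa
  }

  # ungapped
  g23 <- wch[5:27]
  mmp <- mism20(tch, g23)
  aln <- g23; aln[mmp] <- tolower(aln[mmp])
  best <- new_site_alignment(protospacer = paste(g23, collapse = ""),
                             mismatch_positions = mmp,
                             aln = paste(aln, collapse = ""),
                             bulge_penalty = bulge_penalty)
  cand <- list(best)

  # RNA bulge: guide position k unpaired; genomic site is 22 nt
  g22 <- wch[5:26]
  for (k in 1:23) {
    aligned <- c(if (k > 1L) g22[seq_len(k - 1L)], "-",
                 if (k < 23L) g22[seq(k, 22L)])
    mmp <- setdiff(mism20(tch, aligned), k)
    disp <- aligned
    disp[mmp] <- tolower(disp[mmp])
    cand[[length(cand) + 1L]] <- new_site_alignment(
      protospacer = paste(g22, collapse = ""), mismatch_positions = mmp,
      bulge = "rna_bulge", bulge_pos = k,
      aln = paste(disp, collapse = ""), bulge_penalty = bulge_penalty)
  }

  # DNA bulge: extra genomic base after protospacer position k; site is 24 nt
  g24 <- wch[5:28]
  for (k in 1:22) {
    aligned <- g24[-(k + 1L)]
    mmp <- mism20(tch, aligned)
    disp <- aligned
    disp[mmp] <- tolower(disp[mmp])
    disp <- c(disp[seq_len(k)], tolower(g24[k + 1L]),
              disp[seq(k + 1L, 23L)])
    cand[[length(cand) + 1L]] <- new_site_alignment(
      protospacer = paste(g24, collapse = ""), mismatch_positions = mmp,
      bulge = "dna_bulge", bulge_pos = k,
      aln = paste(disp, collapse = ""), bulge_penalty = bulge_penalty)
  }

  score <- vapply(cand, `[[`, numeric(1), "score")
  brank <- vapply(cand, function(x)
    match(x$bulge, c("none", "rna_bulge", "dna_bulge")), numeric(1))
  bpos <- vapply(cand, function(x)
    ifelse(is.na(x$bulge_pos), 0L, x$bulge_pos), numeric(1))
  finish(cand[[order(score, brank, bpos)[1L]]])
}

#' Candidate capture rule
#'
#' A site passes when it has a canonical TTTN PAM and an effective score of
#' at most 8, or a PAM-like tetramer (NTTN/TNTN/TTNN) and an effective score
#' of at most 7. The effective score is the 20-nt mismatch count plus the
#' bulge penalty for bulged alignments. Sites without a PAM never pass.
#'
#' @param alignment A \code{"site_alignment"} with \code{pam_class} set.
#' @param max_mm_canonical Cutoff for canonical PAM sites (default 8).
#' @param max_mm_pamlike Cutoff for PAM-like sites (default 7).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
match_rule <- function(alignment, max_mm_canonical = 8L, max_mm_pamlike = 7L) {
  switch(alignment$pam_class,
         canonical = alignment$score <= max_mm_canonical,
         pam_like = alignment$score <= max_mm_pamlike,
         FALSE)
}

empty_candidate_sites <- function() {
  df <- data.frame(contig = character(), start = integer(),
                   strand = character(), pam = character(),
                   pam_class = character(), protospacer = character(),
                   aln = character(), mismatch_count = integer(),
                   bulge = character(), bulge_pos = integer(),
                   score = integer(), nick_position = integer(),
                   nick_offset = numeric(), source = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("candidate_sites", "data.frame")
  df
}

candidate_row <- function(contig, start, strand, sa, nick_position = NA_integer_,
                          nick_offset = NA_real_, source = "genome-scan") {
  data.frame(contig = contig, start = as.integer(start), strand = strand,
             pam = sa$pam_tetramer, pam_class = sa$pam_class,
             protospacer = sa$protospacer, aln = sa$aln,
             mismatch_count = sa$mismatch_count, bulge = sa$bulge,
             bulge_pos = ifelse(is.na(sa$bulge_pos), NA_integer_, sa$bulge_pos),
             score = sa$score, nick_position = nick_position,
             nick_offset = nick_offset, source = source,
             stringsAsFactors = FALSE)
}

#' Explain an SSB candidate by target homology near the break
#'
#' Scans both genome strands around a called nick for protospacer placements
#' whose PAM tetramer (immediately 5' of the protospacer on the protospacer
#' strand) passes [classify_pam()] and whose alignment passes [match_rule()],
#' requiring the nick to fall within the protospacer interval extended by
#' \code{nick_slack} bp. Among passing placements the best is chosen by:
#' lowest effective score, ungapped over bulged, canonical over PAM-like
#' PAM, nick closest to protospacer position 10, then leftmost coordinate.
#'
#' @param genome Reference genome (\code{DNAStringSet}).
#' @param ssb One SSB candidate: a list or one-row data frame with
#'   \code{contig} and \code{position} (1-based).
#' @param target A [target_spec()].
#' @param search_radius Maximum distance in bp between the nick and the
#'   protospacer start considered (default 30).
#' @param nick_slack The nick must lie within the protospacer extended by
#'   this many bp on each side (default 5); the editing window spans
#'   protospacer positions 8-13, the slack absorbs end-repair resection.
#' @param bulges Also search 1-nt bulged alignments (default \code{TRUE}).
#' @param bulge_penalty See [align_with_bulge()].
#' @param max_mm_canonical,max_mm_pamlike See [match_rule()].
#' @return A one-row data frame of class \code{"candidate_sites"} (column
#'   \code{start} is the leftmost genomic base of the protospacer), or
#'   \code{NULL} when no placement passes.
#' @export
find_site_near_break <- function(genome, ssb, target, search_radius = 30L,
                                 nick_slack = 5L, bulges = TRUE,
                                 bulge_penalty = 2L, max_mm_canonical = 8L,
                                 max_mm_pamlike = 7L) {
  contig <- as.character(ssb$contig[1L])
  nick <- as.integer(ssb$position[1L])
  dg_assert(contig %in% names(genome), "unknown contig",
            "digenomeR_unknown_contig")
  gs <- as.character(genome[[contig]])
  L <- nchar(gs)
  dg_assert(nick >= 1L && nick <= L, "nick outside contig",
            "digenomeR_position_out_of_bounds")
  hits <- list()

  eval_placement <- function(pam, window, start, strand, nick_pp) {
    pc <- classify_pam(pam)
    if (pc == "none") return(NULL)
    sa <- if (bulges && nchar(window) >= 28L) {
      align_with_bulge(target, window, bulge_penalty = bulge_penalty)
    } else if (nchar(window) >= 27L) {
      sa0 <- count_mismatches(target, substr(window, 5L, 27L))
      sa0$window_sequence <- window
      sa0$pam_tetramer <- pam
      sa0$pam_class <- pc
      sa0
    } else return(NULL)
    if (!match_rule(sa, max_mm_canonical, max_mm_pamlike)) return(NULL)
    candidate_row(contig, start, strand, sa, nick_position = nick,
                  nick_offset = nick_pp, source = "ssb")
  }

  # forward-strand placements: protospacer [s, s+22], PAM [s-4, s-1]
  s_lo <- max(5L, nick - search_radius, nick - 22L - nick_slack)
  s_hi <- min(L - 22L, nick + search_radius, nick + nick_slack)
  if (s_lo <= s_hi) for (s in s_lo:s_hi) {
    w <- substr(gs, s - 4L, min(s + 23L, L))
    hits[[length(hits) + 1L]] <- eval_placement(
      substr(gs, s - 4L, s - 1L), w, s, "+", nick - s + 1L)
  }
  # reverse-strand placements: protospacer [s, s+22] with position 1 at s+22;
  # PAM genomic [s+23, s+26]; window read on the minus strand
  s_lo <- max(1L, nick - search_radius, nick - nick_slack - 22L)
  s_hi <- min(L - 26L, nick + search_radius, nick + nick_slack)
  if (s_lo <= s_hi) for (s in s_lo:s_hi) {
    w <- revcomp(substr(gs, max(1L, s - 1L), s + 26L))
    hits[[length(hits) + 1L]] <- eval_placement(
      substr(w, 1L, 4L), w, s, "-", (s + 22L) - nick + 1L)
  }
  hits <- Filter(Negate(is.null), hits)
  if (!length(hits)) return(NULL)
  df <- do.call(rbind, hits)
  ord <- order(df$score,
               df$bulge != "none",
               df$pam_class != "canonical",
               abs(df$nick_offset - 10),
               df$start,
               df$strand)
  res <- df[ord[1L], , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("candidate_sites", "data.frame")
  res
}

#' Enumerate genome-wide candidate off-target sites
#'
#' Exhaustively scans both strands for PAM placements followed by a 23-nt
#' protospacer with at most \code{max_mm_canonical} mismatches over positions
#' 1-20 (ungapped). By default only the canonical TTTN PAM is scanned, the
#' definition used for the genome-wide potential off-target count; PAM-like
#' classes can be included with their own cutoff.
#'
#' @param genome Reference genome (\code{DNAStringSet}).
#' @param target A [target_spec()].
#' @param max_mm_canonical Mismatch cutoff for TTTN sites (default 8).
#' @param include_pam_like Also scan NTTN/TNTN/TTNN placements (default
#'   \code{FALSE}).
#' @param max_mm_pamlike Cutoff for PAM-like sites (default 7).
#' @return A data frame of class \code{"candidate_sites"}; \code{start} is
#'   the leftmost genomic base of the protospacer.
#' @export
enumerate_genome_candidates <- function(genome, target, max_mm_canonical = 8L,
                                        include_pam_like = FALSE,
                                        max_mm_pamlike = 7L) {
  tch <- seq_chars(target$protospacer)
  out <- list()
  scan_one <- function(cv, L) {
    # PAM leftmost index i; protospacer at i+4 .. i+26
    n <- L - 26L
    if (n < 1L) return(NULL)
    i <- seq_len(n)
    b1 <- cv[i] == "T"; b2 <- cv[i + 1L] == "T"; b3 <- cv[i + 2L] == "T"
    canonical <- b1 & b2 & b3
    sel <- canonical
    if (include_pam_like) sel <- sel | (b2 & b3) | (b1 & b3) | (b1 & b2)
    idx <- which(sel)
    if (!length(idx)) return(NULL)
    mm <- integer(length(idx))
    for (j in 1:20) mm <- mm + (cv[idx + 3L + j] != tch[j])
    cano <- canonical[idx]
    pass <- (cano & mm <= max_mm_canonical) |
      (!cano & include_pam_like & mm <= max_mm_pamlike)
    list(pam_i = idx[pass], mm = mm[pass], canonical = cano[pass])
  }
  for (ctg in names(genome)) {
    gs <- as.character(genome[[ctg]])
    L <- nchar(gs)
    cv <- seq_chars(gs)
    fw <- scan_one(cv, L)
    if (!is.null(fw) && length(fw$pam_i)) {
      sp <- fw$pam_i + 4L
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = sp, strand = "+",
        pam = substring(gs, fw$pam_i, fw$pam_i + 3L),
        pam_class = ifelse(fw$canonical, "canonical", "pam_like"),
        protospacer = substring(gs, sp, sp + 22L),
        mismatch_count = fw$mm, stringsAsFactors = FALSE)
    }
    rcs <- revcomp(gs)
    rv <- scan_one(seq_chars(rcs), L)
    if (!is.null(rv) && length(rv$pam_i)) {
      sp_rc <- rv$pam_i + 4L
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = L - sp_rc - 21L, strand = "-",
        pam = substring(rcs, rv$pam_i, rv$pam_i + 3L),
        pam_class = ifelse(rv$canonical, "canonical", "pam_like"),
        protospacer = substring(rcs, sp_rc, sp_rc + 22L),
        mismatch_count = rv$mm, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), start = integer(), strand = character(),
               pam = character(), pam_class = character(),
               protospacer = character(), mismatch_count = integer(),
               stringsAsFactors = FALSE)
  res$bulge <- if (nrow(res)) "none" else character(0)
  res$score <- res$mismatch_count
  res$source <- if (nrow(res)) "genome-scan" else character(0)
  res <- res[order(res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("candidate_sites", "data.frame")
  res
}

#' Partition two site sets (Venn comparison)
#'
#' Two sites are the same iff they share contig and protospacer strand and
#' their protospacer starts differ by at most \code{tolerance} bp. Matching
#' is one-to-one and greedy by increasing positional distance.
#'
#' @param a,b Data frames with columns \code{contig}, \code{strand},
#'   \code{start} (e.g. \code{"candidate_sites"}).
#' @param tolerance Maximum start difference in bp (default 10).
#' @return A list with counts \code{a_only}, \code{shared}, \code{b_only}
#'   and a data frame \code{pairs} of matched row indices.
#' @export
compare_site_sets <- function(a, b, tolerance = 10L) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(list(a_only = nrow(a), shared = 0L, b_only = nrow(b),
                pairs = data.frame(a = integer(), b = integer())))
  }
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    j <- which(b$contig == a$contig[i] & b$strand == a$strand[i] &
                 abs(b$start - a$start[i]) <= tolerance)
    if (length(j)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        a = i, b = j, d = abs(b$start[j] - a$start[i]))
    }
  }
  if (!length(pairs)) {
    return(list(a_only = nrow(a), shared = 0L, b_only = nrow(b),
                pairs = data.frame(a = integer(), b = integer())))
  }
  pd <- do.call(rbind, pairs)
  pd <- pd[order(pd$d, pd$a, pd$b), , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(pd))
  for (k in seq_len(nrow(pd))) {
    if (!used_a[pd$a[k]] && !used_b[pd$b[k]]) {
      keep[k] <- TRUE
      used_a[pd$a[k]] <- TRUE
      used_b[pd$b[k]] <- TRUE
    }
  }
  matched <- pd[keep, c("a", "b"), drop = FALSE]
  list(a_only = nrow(a) - nrow(matched), shared = nrow(matched),
       b_only = nrow(b) - nrow(matched), pairs = matched)
}

#' Write candidate sites as TSV (1-based starts)
#' @param sites A \code{"candidate_sites"} data frame.
#' @param path Output path.
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write candidate sites as BED6 (0-based half-open; score = mismatch count)
#' @inheritParams write_sites_tsv
#' @export
write_sites_bed <- function(sites, path) {
  df <- as.data.frame(sites)
  end0 <- df$start - 1L + nchar(df$protospacer)
  lines <- sprintf("%s\t%d\t%d\tsite\t%d\t%s", df$contig, df$start - 1L,
                   end0, df$mismatch_count, df$strand)
  writeLines(lines, path)
  invisible(path)
}
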