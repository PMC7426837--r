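#' Load a reference genome from FASTA
#'
#' Reads all records of a FASTA file into a \code{DNAStringSet}. Sequences are
#' uppercased (soft-masked lowercase input is accepted), contig names are
#' truncated at the first whitespace, and basic invariants are enforced: at
#' least one record, unique contig names, non-empty sequences over
#' \code{A/C/G/T/N}.
#'
#' @param path Path to a FASTA file.
#' @return A \code{Biostrings::DNAStringSet}, one element per contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT", ">b", "NN"), fa)
#' genome <- load_reference(fa)
#' width(genome)
#' @export
load_reference <- function(path) {
  dg_assert(is.character(path) && length(path) == 1L && file.exists(path),
            sprintf("reference FASTA not found: %s", path),
            "digenomeR_missing_file")
  seqs <- Biostrings::readDNAStringSet(path)
  dg_assert(length(seqs) > 0L, "FASTA contains no records",
            "digenomeR_empty_fasta")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dg_assert(!anyDuplicated(names(seqs)),
            "duplicate contig names in FASTA",
            "digenomeR_duplicate_contig")
  dg_assert(all(Biostrings::width(seqs) > 0L),
            "FASTA contains an empty sequence",
            "digenomeR_empty_sequence")
  # DNAStringSet already uppercases; reject alphabet outside ACGTN
  alph <- Biostrings::alphabetFrequency(seqs, baseOnly = FALSE)
  bad <- colnames(alph)[!colnames(alph) %in% c("A", "C", "G", "T", "N")]
  dg_assert(sum(alph[, bad, drop = FALSE]) == 0,
            "sequence contains characters outside A/C/G/T/N",
            "digenomeR_bad_alphabet")
  seqs
}

#' Alignment filter settings
#'
#' @param min_mapq Minimum mapping quality retained (default 0, i.e. no
#'   MAPQ filtering).
#' @param keep_duplicates Keep records flagged as PCR/optical duplicates
#'   (default \code{TRUE}: Digenome signal comes from independent in vitro
#'   fragments, and the original analysis applied no deduplication).
#' @param primary_only Drop secondary and supplementary alignments
#'   (default \code{TRUE}) so each fragment end is counted once.
#' @return A list of class \code{"alignment_filter"}.
#' @export
alignment_filter <- function(min_mapq = 0L, keep_duplicates = TRUE,
                             primary_only = TRUE) {
  dg_assert(min_mapq >= 0L, "min_mapq must be >= 0", "digenomeR_bad_config")
  structure(list(min_mapq = as.integer(min_mapq),
                 keep_duplicates = isTRUE(keep_duplicates),
                 primary_only = isTRUE(primary_only)),
            class = "alignment_filter")
}

#' Read aligned reads from SAM/BAM
#'
#' Loads mapped records from a coordinate-sorted SAM or BAM file and returns
#' them as a data frame of aligned intervals (1-based, closed; the aligned
#' span only, soft clips excluded). Strand is taken from the
#' reverse-complement flag. Unmapped records are always dropped; secondary /
#' supplementary records are dropped when \code{filter$primary_only}.
#'
#' @param path Path to a SAM or BAM file with a header naming the contigs.
#' @param filter An [alignment_filter()].
#' @param genome Optional reference genome (\code{DNAStringSet}); when given,
#'   records on contigs absent from the genome raise an error.
#' @param check_sorted Verify that records are coordinate-sorted within each
#'   contig (default \code{TRUE}).
#' @return A data frame with columns \code{contig}, \code{strand}
#'   (\code{"+"}/\code{"-"}), \code{start}, \code{end} (1-based closed),
#'   \code{mapq}, \code{is_primary}.
#' @export
read_alignments <- function(path, filter = alignment_filter(), genome = NULL,
                            check_sorted = TRUE) {
  dg_assert(is.character(path) && length(path) == 1L && file.exists(path),
            sprintf("alignment file not found: %s", path),
            "digenomeR_missing_file")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  flag <- S4Vectors::mcols(ga)$flag
  mapq <- S4Vectors::mcols(ga)$mapq
  mapq[is.na(mapq)] <- 0L
  is_primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  is_dup <- bitwAnd(flag, 0x400L) != 0L
  keep <- mapq >= filter$min_mapq
  if (filter$primary_only) keep <- keep & is_primary
  if (!filter$keep_duplicates) keep <- keep & !is_dup
  gdf <- as.data.frame(ga)
  reads <- data.frame(
    contig = as.character(gdf$seqnames),
    strand = as.character(gdf$strand),
    start = gdf$start,
    end = gdf$end,
    mapq = mapq,
    is_primary = is_primary,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(reads) <- NULL
  if (check_sorted && nrow(reads) > 1L) {
    by_contig <- split(reads$start, reads$contig)
    dg_assert(all(vapply(by_contig, function(s) !is.unsorted(s), logical(1))),
              "alignment records are not coordinate-sorted",
              "digenomeR_unsorted_input")
  }
  if (!is.null(genome)) {
    dg_assert(all(reads$contig %in% names(genome)),
              "alignment contig absent from reference genome",
              "digenomeR_unknown_contig")
  }
  reads
}

#' Build strand-separated 5'-end pileups
#'
#' The core container of the method. Reads are split by orientation; for a
#' forward read the 5' end is its leftmost aligned base, for a reverse read
#' its rightmost aligned base (the base sequenced first after
#' reverse-complement mapping). Per contig and strand the pileup stores the
#' number of reads whose 5' end falls at each position and the read depth at
#' each position.
#'
#' @param reads Data frame of aligned reads (columns \code{contig},
#'   \code{strand}, \code{start}, \code{end}; 1-based closed), as returned by
#'   [read_alignments()] or [simulate_digested_reads()].
#' @param genome Reference genome (\code{DNAStringSet}) giving contig lengths.
#' @return An object of class \code{"strand_pileup"}: per contig a list of
#'   integer vectors \code{fwd_start}, \code{rev_start}, \code{fwd_depth},
#'   \code{rev_depth}, each of contig length.
#' @export
build_strand_pileup <- function(reads, genome) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  dg_assert(all(reads$contig %in% names(lens)),
            "read on contig absent from reference genome",
            "digenomeR_unknown_contig")
  ok <- reads$start >= 1L & reads$end <= lens[reads$contig] &
    reads$start <= reads$end
  dg_assert(all(ok), "read outside contig bounds",
            "digenomeR_read_out_of_bounds")
  pl <- lapply(names(lens), function(ctg) {
    L <- lens[[ctg]]
    r <- reads[reads$contig == ctg, , drop = FALSE]
    fwd <- r[r$strand == "+", , drop = FALSE]
    rev <- r[r$strand == "-", , drop = FALSE]
    list(
      fwd_start = tabulate(fwd$start, nbins = L),
      rev_start = tabulate(rev$end, nbins = L),
      fwd_depth = interval_depth(fwd$start, fwd$end, L),
      rev_depth = interval_depth(rev$start, rev$end, L)
    )
  })
  names(pl) <- names(lens)
  structure(pl, class = "strand_pileup", contig_lengths = lens)
}

# depth[p] = number of intervals [start, end] covering p, via cumulative sums
interval_depth <- function(starts, ends, L) {
  if (length(starts) == 0L) return(integer(L))
  opens <- cumsum(tabulate(starts, nbins = L))
  closes <- cumsum(tabulate(ends, nbins = L))
  as.integer(opens - c(0L, closes[-L]))
}

#' @export
print.strand_pileup <- function(x, ...) {
  lens <- attr(x, "contig_lengths")
  cat("strand_pileup over", length(x), "contig(s)\n")
  for (ctg in names(x)) {
    cat(sprintf("  %s (%d bp): %d fwd / %d rev read 5' ends\n", ctg,
                lens[[ctg]], sum(x[[ctg]]$fwd_start), sum(x[[ctg]]$rev_start)))
  }
  invisible(x)
}

#' Export pileup tracks as bedGraph
#'
#' Writes one bedGraph track (0-based half-open intervals, run-length
#' compressed) for a chosen strand and count type.
#'
#' @param pileup A [build_strand_pileup()] result.
#' @param path Output file path.
#' @param strand \code{"+"} or \code{"-"}.
#' @param what \code{"start"} (5'-end counts) or \code{"depth"}.
#' @return Invisibly, the output path.
#' @export
write_bedgraph <- function(pileup, path, strand = c("+", "-"),
                           what = c("start", "depth")) {
  strand <- match.arg(strand)
  what <- match.arg(what)
  field <- paste0(if (strand == "+") "fwd" else "rev", "_", what)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s strand %s\"",
                     what, strand), con)
  for (ctg in names(pileup)) {
    v <- pileup[[ctg]][[field]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts0 <- ends - r$lengths          # 0-based half-open
    nz <- r$values != 0L
    if (any(nz)) {
      writeLines(sprintf("%s\t%d\t%d\t%d", ctg, starts0[nz], ends[nz],
                         r$values[nz]), con)
    }
  }
  invisible(path)
}
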