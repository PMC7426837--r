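#' SSB caller configuration
#'
#' Thresholds for calling single-strand-break positions from a strand pileup.
#' Defaults reproduce the published capture rule: a position is called when
#' the count of reads sharing that 5' end is strictly greater than 5 and at
#' least 20\% of the reads at the position show the straight alignment.
#'
#' @param min_start_count Exclusive lower bound on the 5'-end start count
#'   (default 5: a count must be \code{> 5} to be called).
#' @param min_ratio Inclusive lower bound on the straight-alignment ratio
#'   (default 0.20).
#' @param merge_window Candidates on the same contig and strand within this
#'   many bp are collapsed (default 10; nicks at adjacent edited cytosines
#'   within the position 8-13 editing window cluster tighter than this).
#' @param denominator Depth used for the ratio: \code{"same"} strand (default;
#'   the intact strand's coverage is unrelated to the nick) or \code{"both"}.
#' @param require_opposite_staggered When \code{TRUE}, additionally require
#'   that the opposite strand does NOT show a straight edge (its ratio below
#'   \code{min_ratio}) at the position. Off by default: the chemistry nicks
#'   exactly one strand, and single-strand evidence suffices.
#' @return A list of class \code{"caller_config"}.
#' @export
caller_config <- function(min_start_count = 5L, min_ratio = 0.20,
                          merge_window = 10L,
                          denominator = c("same", "both"),
                          require_opposite_staggered = FALSE) {
  denominator <- match.arg(denominator)
  dg_assert(min_start_count >= 0L, "min_start_count must be >= 0",
            "digenomeR_bad_config")
  dg_assert(min_ratio > 0 && min_ratio <= 1, "min_ratio must be in (0, 1]",
            "digenomeR_bad_config")
  dg_assert(merge_window >= 0L, "merge_window must be >= 0",
            "digenomeR_bad_config")
  structure(list(min_start_count = as.integer(min_start_count),
                 min_ratio = min_ratio,
                 merge_window = as.integer(merge_window),
                 denominator = denominator,
                 require_opposite_staggered = isTRUE(require_opposite_staggered)),
            class = "caller_config")
}

#' Straight-alignment ratio at a position
#'
#' Fraction of same-strand reads at a position whose 5' end falls exactly
#' there. Returns 0 when the depth is 0.
#'
#' @param pileup A [build_strand_pileup()] result.
#' @param contig Contig name.
#' @param position 1-based position.
#' @param strand \code{"+"} or \code{"-"}.
#' @return A fraction in \code{[0, 1]}.
#' @export
straight_ratio <- function(pileup, contig, position, strand = c("+", "-")) {
  strand <- match.arg(strand)
  dg_assert(contig %in% names(pileup), "unknown contig",
            "digenomeR_unknown_contig")
  L <- attr(pileup, "contig_lengths")[[contig]]
  dg_assert(position >= 1L && position <= L, "position outside contig",
            "digenomeR_position_out_of_bounds")
  p <- pileup[[contig]]
  if (strand == "+") {
    if (p$fwd_depth[position] == 0L) return(0)
    p$fwd_start[position] / p$fwd_depth[position]
  } else {
    if (p$rev_depth[position] == 0L) return(0)
    p$rev_start[position] / p$rev_depth[position]
  }
}

#' Call candidate SSB positions from a strand pileup
#'
#' Scans both strands independently (a nick cuts only one strand) and emits
#' every position whose 5'-end start count exceeds
#' \code{config$min_start_count} (strict) and whose straight-alignment ratio
#' is at least \code{config$min_ratio} (inclusive).
#'
#' @param pileup A [build_strand_pileup()] result.
#' @param config A [caller_config()].
#' @return A data frame of class \code{"ssb_candidates"} with columns
#'   \code{contig}, \code{position} (1-based), \code{strand},
#'   \code{start_count}, \code{depth}, \code{ratio}, sorted by contig then
#'   position.
#' @export
call_ssb_sites <- function(pileup, config = caller_config()) {
  out <- list()
  for (ctg in names(pileup)) {
    p <- pileup[[ctg]]
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") p$fwd_start else p$rev_start
      dp <- if (strand == "+") p$fwd_depth else p$rev_depth
      denom <- if (config$denominator == "both") {
        p$fwd_depth + p$rev_depth
      } else dp
      hit <- sc > config$min_start_count & denom > 0L &
        sc / pmax(denom, 1L) >= config$min_ratio
      if (config$require_opposite_staggered) {
        osc <- if (strand == "+") p$rev_start else p$fwd_start
        odp <- if (strand == "+") p$rev_depth else p$fwd_depth
        oratio <- ifelse(odp > 0L, osc / pmax(odp, 1L), 0)
        hit <- hit & oratio < config$min_ratio
      }
      idx <- which(hit)
      if (length(idx)) {
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, position = idx, strand = strand,
          start_count = sc[idx], depth = denom[idx],
          ratio = sc[idx] / denom[idx], stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), position = integer(),
               strand = character(), start_count = integer(),
               depth = integer(), ratio = numeric(),
               stringsAsFactors = FALSE)
  res <- res[order(res$contig, res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ssb_candidates", "data.frame")
  res
}

#' Collapse clustered SSB candidates
#'
#' Single-linkage clustering per contig and strand: consecutive candidates
#' within \code{window} bp join the same cluster, and each cluster is
#' represented by the candidate with the highest start count (ties broken by
#' the leftmost position). The number of positions merged into each
#' representative is recorded in column \code{n_merged}.
#'
#' @param candidates An [call_ssb_sites()] result (sorted).
#' @param window Maximum gap in bp joining two candidates (default 10).
#' @return A data frame like the input with an added \code{n_merged} column.
#' @export
merge_ssb_candidates <- function(candidates, window = 10L) {
  dg_assert(window >= 0L, "window must be >= 0", "digenomeR_bad_config")
  if (nrow(candidates) == 0L) {
    candidates$n_merged <- integer(0)
    return(candidates)
  }
  key <- paste(candidates$contig, candidates$strand)
  parts <- split(seq_len(nrow(candidates)), key)
  keep <- lapply(parts, function(idx) {
    idx <- idx[order(candidates$position[idx])]
    pos <- candidates$position[idx]
    cl <- cumsum(c(1L, as.integer(diff(pos) > window)))
    vapply(split(idx, cl), function(ii) {
      best <- ii[candidates$start_count[ii] == max(candidates$start_count[ii])]
      rep_i <- best[which.min(candidates$position[best])]
      c(rep_i, length(ii))
    }, integer(2))
  })
  mat <- do.call(cbind, keep)
  res <- candidates[mat[1L, ], , drop = FALSE]
  res$n_merged <- mat[2L, ]
  res <- res[order(res$contig, res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ssb_candidates", "data.frame")
  res
}

#' Write SSB candidates as TSV (1-based positions)
#' @param candidates An [call_ssb_sites()] result.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_ssb_tsv <- function(candidates, path) {
  utils::write.table(as.data.frame(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write SSB candidates as BED6 (0-based half-open; score = start count)
#' @inheritParams write_ssb_tsv
#' @export
write_ssb_bed <- function(candidates, path) {
  df <- as.data.frame(candidates)
  lines <- sprintf("%s\t%d\t%d\tssb\t%d\t%s", df$contig, df$position - 1L,
                   df$position, df$start_count, df$strand)
  writeLines(lines, path)
  invisible(path)
}
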