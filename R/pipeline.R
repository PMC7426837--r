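#' Run the full SSB off-target pipeline
#'
#' Executes pileup, SSB calling, candidate merging and target-homology
#' matching, and optionally writes TSV/BED reports plus a JSON run manifest.
#'
#' @param reference Path to a FASTA file or a \code{DNAStringSet}.
#' @param alignments Path to a SAM/BAM file or a data frame of aligned reads
#'   (as from [read_alignments()] / [simulate_digested_reads()]).
#' @param target A [target_spec()] or a 23-nt protospacer string.
#' @param caller A [caller_config()].
#' @param filter An [alignment_filter()] applied when \code{alignments} is a
#'   file path.
#' @param search_radius,nick_slack,bulges,bulge_penalty Passed to
#'   [find_site_near_break()].
#' @param outdir Optional output directory for reports.
#' @return A list of class \code{"digenome_report"}: \code{ssb} (merged SSB
#'   candidates), \code{sites} (matched candidate sites, deduplicated by
#'   locus), \code{n_unexplained} (SSB calls with no passing homology), and
#'   the parameters used.
#' @export
run_pipeline <- function(reference, alignments, target,
                         caller = caller_config(),
                         filter = alignment_filter(),
                         search_radius = 30L, nick_slack = 5L,
                         bulges = TRUE, bulge_penalty = 2L,
                         outdir = NULL) {
  # validate configuration before any compute
  if (is.character(reference)) {
    dg_assert(file.exists(reference),
              sprintf("reference FASTA not found: %s", reference),
              "digenomeR_missing_file")
  }
  if (is.character(alignments)) {
    dg_assert(file.exists(alignments),
              sprintf("alignment file not found: %s", alignments),
              "digenomeR_missing_file")
  }
  if (is.character(target)) target <- target_spec("target", target)

  genome <- if (is.character(reference)) load_reference(reference) else
    reference
  reads <- if (is.character(alignments)) {
    read_alignments(alignments, filter = filter, genome = genome)
  } else alignments
  if (nrow(reads) == 0L) {
    warning("no aligned reads: empty report")
  }

  pileup <- build_strand_pileup(reads, genome)
  calls <- call_ssb_sites(pileup, caller)
  merged <- merge_ssb_candidates(calls, caller$merge_window)

  sites <- empty_candidate_sites()
  n_unexplained <- 0L
  if (nrow(merged)) {
    found <- lapply(seq_len(nrow(merged)), function(i) {
      find_site_near_break(genome, merged[i, ], target,
                           search_radius = search_radius,
                           nick_slack = nick_slack, bulges = bulges,
                           bulge_penalty = bulge_penalty)
    })
    n_unexplained <- sum(vapply(found, is.null, logical(1)))
    found <- Filter(Negate(is.null), found)
    if (length(found)) {
      sites <- do.call(rbind, found)
      # one locus can explain several clustered nicks: deduplicate
      key <- paste(sites$contig, sites$start, sites$strand)
      sites <- sites[!duplicated(key), , drop = FALSE]
      sites <- sites[order(sites$contig, sites$start), , drop = FALSE]
      rownames(sites) <- NULL
      class(sites) <- c("candidate_sites", "data.frame")
    }
  }

  report <- structure(list(
    ssb = merged, sites = sites, n_unexplained = n_unexplained,
    params = list(caller = unclass(caller), search_radius = search_radius,
                  nick_slack = nick_slack, bulges = bulges,
                  bulge_penalty = bulge_penalty,
                  target = unclass(target))),
    class = "digenome_report")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_ssb_tsv(merged, file.path(outdir, "ssb_sites.tsv"))
    write_ssb_bed(merged, file.path(outdir, "ssb_sites.bed"))
    write_sites_tsv(sites, file.path(outdir, "candidate_sites.tsv"))
    write_sites_bed(sites, file.path(outdir, "candidate_sites.bed"))
    manifest <- list(
      package = "digenomeR",
      version = as.character(utils::packageVersion("digenomeR")),
      parameters = report$params,
      inputs = list(
        reference = if (is.character(reference)) list(
          path = reference,
          md5 = unname(tools::md5sum(reference))) else "in-memory",
        alignments = if (is.character(alignments)) list(
          path = alignments,
          md5 = unname(tools::md5sum(alignments))) else "in-memory"),
      n_ssb = nrow(merged), n_sites = nrow(sites),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.digenome_report <- function(x, ...) {
  cat(sprintf(
    "digenome_report: %d SSB position(s), %d candidate site(s), %d unexplained\n",
    nrow(x$ssb), nrow(x$sites), x$n_unexplained))
  if (nrow(x$sites)) {
    cols <- c("contig", "start", "strand", "pam", "pam_class",
              "mismatch_count", "bulge", "aln")
    print(as.data.frame(x$sites)[, cols])
  }
  invisible(x)
}
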