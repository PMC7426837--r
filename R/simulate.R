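#' Planted target site for simulation
#'
#' Describes one on-/off-target site to embed in a synthetic genome: its
#' divergence from the crRNA target (mismatch positions, optional 1-nt
#' bulge), the protospacer position of the edited cytosine, and the fraction
#' of overlapping fragments nicked there (the in vitro deamination + USER
#' digestion efficiency).
#'
#' @param name Site label.
#' @param strand Genome strand carrying the protospacer (\code{"+"} /
#'   \code{"-"}).
#' @param mismatch_positions Protospacer positions (1-23) to mutate relative
#'   to the target.
#' @param bulge \code{"none"}, \code{"rna"} (site lacks one protospacer base)
#'   or \code{"dna"} (site carries one extra base).
#' @param bulge_pos Protospacer position of the RNA bulge, or the position
#'   after which the DNA-bulge base is inserted.
#' @param nick_offset Protospacer position of the edited C (default 10,
#'   inside the position 8-13 editing window).
#' @param nick_fraction Fraction of fragments overlapping the nick that are
#'   cut (default 0.9).
#' @param position Optional fixed genomic start (leftmost base) for the
#'   inserted site block; random placement when \code{NA}.
#' @return A list of class \code{"planted_site"}.
#' @export
planted_site <- function(name = "site", strand = c("+", "-"),
                         mismatch_positions = integer(),
                         bulge = c("none", "rna", "dna"),
                         bulge_pos = NA_integer_, nick_offset = 10L,
                         nick_fraction = 0.9, position = NA_integer_) {
  strand <- match.arg(strand)
  bulge <- match.arg(bulge)
  dg_assert(all(mismatch_positions %in% 1:23),
            "mismatch positions must lie in 1..23", "digenomeR_bad_config")
  dg_assert(nick_offset %in% 1:23, "nick_offset must lie in 1..23",
            "digenomeR_bad_config")
  dg_assert(nick_fraction >= 0 && nick_fraction <= 1,
            "nick_fraction must lie in [0, 1]", "digenomeR_bad_config")
  if (bulge != "none") {
    dg_assert(!is.na(bulge_pos) && bulge_pos %in% 1:22,
              "bulge_pos must lie in 1..22", "digenomeR_bad_config")
    dg_assert(bulge != "rna" || bulge_pos != nick_offset,
              "RNA bulge cannot delete the edited C", "digenomeR_bad_config")
  }
  dg_assert(!nick_offset %in% mismatch_positions,
            "the edited C cannot be a mismatch position",
            "digenomeR_bad_config")
  structure(list(name = name, strand = strand,
                 mismatch_positions = as.integer(mismatch_positions),
                 bulge = bulge, bulge_pos = as.integer(bulge_pos),
                 nick_offset = as.integer(nick_offset),
                 nick_fraction = nick_fraction,
                 position = as.integer(position)),
            class = "planted_site")
}

#' Simulation configuration
#'
#' Defaults follow the study conditions the simulator emulates: fragments of
#' 450 +/- 50 bp (sonication to 400-500 bp), 150-bp reads, 30x depth.
#'
#' @param genome_length Synthetic contig length in bp.
#' @param gc_fraction GC content of the random background (default 0.41,
#'   human-like).
#' @param seed Mandatory integer seed; every simulator output is
#'   deterministic given the config.
#' @param depth Mean sequencing depth (default 30).
#' @param fragment_mean,fragment_sd Fragment length distribution (default
#'   450 +/- 50 bp).
#' @param read_length Single-end read length (default 150).
#' @param planted_sites List of [planted_site()] objects.
#' @param contig_name Name of the synthetic contig.
#' @param min_site_separation Minimum distance between planted site blocks
#'   (default 1000 bp, larger than any fragment, so a fragment never spans
#'   two nicks).
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(genome_length = 100000L, gc_fraction = 0.41, seed,
                       depth = 30, fragment_mean = 450, fragment_sd = 50,
                       read_length = 150L, planted_sites = list(),
                       contig_name = "chrS", min_site_separation = 1000L) {
  dg_assert(!missing(seed) && is.finite(seed), "seed is mandatory",
            "digenomeR_bad_config")
  dg_assert(depth > 0, "depth must be > 0", "digenomeR_bad_config")
  dg_assert(read_length <= fragment_mean,
            "read_length must not exceed the mean fragment length",
            "digenomeR_bad_config")
  structure(list(genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, seed = as.integer(seed),
                 depth = depth, fragment_mean = fragment_mean,
                 fragment_sd = fragment_sd,
                 read_length = as.integer(read_length),
                 planted_sites = planted_sites,
                 contig_name = contig_name,
                 min_site_separation = as.integer(min_site_separation)),
            class = "sim_config")
}

# build the genomic site block (PAM + possibly bulged protospacer, on the
# protospacer strand) and the index of the edited C within the protospacer
build_site_sequence <- function(site, target) {
  proto <- seq_chars(target$protospacer)
  for (i in site$mismatch_positions) {
    proto[i] <- sample(setdiff(c("A", "C", "G", "T"), proto[i]), 1L)
  }
  idx <- site$nick_offset
  if (site$bulge == "rna") {
    proto <- proto[-site$bulge_pos]
    if (site$nick_offset > site$bulge_pos) idx <- idx - 1L
  } else if (site$bulge == "dna") {
    ins <- sample(c("A", "C", "G", "T"), 1L)
    proto <- append(proto, ins, after = site$bulge_pos)
    if (site$nick_offset > site$bulge_pos) idx <- idx + 1L
  }
  dg_assert(proto[idx] == "C",
            sprintf("site '%s' has no C at the nick offset", site$name),
            "digenomeR_no_editable_c")
  pam <- paste0("TTT", sample(c("A", "C", "G"), 1L))  # TTTV
  list(pam = pam, proto = paste(proto, collapse = ""), nick_idx = idx)
}

#' Generate a synthetic genome with planted target sites
#'
#' Draws a random background at the configured GC content and overwrites it
#' with each planted site block: a TTTV PAM followed by the target
#' protospacer carrying the site's mismatches and bulge, reverse-complemented
#' for minus-strand sites. Deterministic under \code{config$seed}.
#'
#' @param config A [sim_config()].
#' @param target A [target_spec()].
#' @return A list: \code{genome} (\code{DNAStringSet}) and \code{sites}, a
#'   data frame of realized coordinates (protospacer start = leftmost genomic
#'   base of the protospacer; \code{nick_pos} = genomic position of the
#'   edited C).
#' @export
simulate_genome <- function(config, target) {
  set.seed(config$seed)
  L <- config$genome_length
  gc <- config$gc_fraction
  gv <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  sites <- config$planted_sites
  placed <- integer(0)
  rows <- list()
  margin <- 200L
  for (site in sites) {
    blk <- build_site_sequence(site, target)
    plen <- nchar(blk$proto)
    blen <- plen + 4L
    dg_assert(blen + 2L * margin <= L, "planted site longer than genome",
              "digenomeR_site_too_long")
    if (!is.na(site$position)) {
      g0 <- site$position
      dg_assert(g0 >= 1L && g0 + blen - 1L <= L,
                "planted site outside genome", "digenomeR_site_too_long")
      dg_assert(all(abs(g0 - placed) >= blen + 4L),
                "planted sites overlap", "digenomeR_site_overlap")
    } else {
      for (try in 1:1000) {
        g0 <- sample.int(L - blen - 2L * margin, 1L) + margin
        if (all(abs(g0 - placed) >= config$min_site_separation)) break
        g0 <- NA_integer_
      }
      dg_assert(!is.na(g0), "could not place site without overlap",
                "digenomeR_site_overlap")
    }
    placed <- c(placed, g0)
    block <- paste0(blk$pam, blk$proto)
    if (site$strand == "+") {
      gv[g0:(g0 + blen - 1L)] <- seq_chars(block)
      proto_start <- g0 + 4L
      nick_pos <- proto_start + blk$nick_idx - 1L
    } else {
      gv[g0:(g0 + blen - 1L)] <- seq_chars(revcomp(block))
      proto_start <- g0            # leftmost genomic base of protospacer
      nick_pos <- g0 + plen - blk$nick_idx
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = site$name, contig = config$contig_name,
      protospacer_start = proto_start, strand = site$strand,
      n_mismatches = length(site$mismatch_positions),
      bulge = site$bulge,
      bulge_pos = site$bulge_pos,
      nick_pos = nick_pos, nick_offset = site$nick_offset,
      nick_fraction = site$nick_fraction,
      pam = blk$pam, protospacer = blk$proto,
      stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(paste(gv, collapse = ""))
  names(genome) <- config$contig_name
  sites_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), contig = character(),
               protospacer_start = integer(), strand = character(),
               n_mismatches = integer(), bulge = character(),
               bulge_pos = integer(), nick_pos = integer(),
               nick_offset = integer(), nick_fraction = numeric(),
               pam = character(), protospacer = character(),
               stringsAsFactors = FALSE)
  list(genome = genome, sites = sites_df, config = config)
}

#' Simulate in vitro digestion and WGS read alignments
#'
#' Shears the genome into fragments at the configured depth and length
#' distribution, nicks fragments overlapping planted sites (on the
#' protospacer strand, with the site's \code{nick_fraction}), and emits
#' single-end reads from both fragment ends. A nick splits the nicked strand
#' into two pieces with a 1-nt gap (the excised base); the downstream piece's
#' 5' end sits exactly at nick position + 1 on that strand, producing the
#' straight-alignment pile the caller detects, while the intact strand stays
#' staggered.
#'
#' @param sim A [simulate_genome()] result (or a list with \code{genome},
#'   \code{sites}, \code{config}).
#' @param keep_fragments Attach the fragment/piece table as attribute
#'   \code{"fragments"} (default \code{FALSE}).
#' @param min_piece Minimum piece length sequenced (default 20 bp).
#' @return A coordinate-sorted data frame of aligned reads (columns
#'   \code{contig}, \code{strand}, \code{start}, \code{end}, \code{mapq},
#'   \code{is_primary}) directly consumable by [build_strand_pileup()].
#' @export
simulate_digested_reads <- function(sim, keep_fragments = FALSE,
                                    min_piece = 20L) {
  config <- sim$config
  set.seed(dg_subseed(config$seed, 1L))
  L <- config$genome_length
  rl <- config$read_length
  n_frags <- max(1L, as.integer(round(config$depth * L / (2 * rl))))
  fs <- sample.int(L, n_frags, replace = TRUE)
  flen <- pmax(as.integer(round(stats::rnorm(n_frags, config$fragment_mean,
                                             config$fragment_sd))),
               2L * min_piece)
  fe <- fs + flen - 1L
  # fragments running past the contig are discarded, not clipped: clipping
  # would stack artificial 5' ends on the terminal base
  inb <- fe <= L
  fs <- fs[inb]; fe <- fe[inb]
  n_frags <- length(fs)

  nick_site <- rep(NA_integer_, n_frags)
  sites <- sim$sites
  if (nrow(sites)) {
    for (i in seq_len(nrow(sites))) {
      if (sites$nick_fraction[i] <= 0) next
      np <- sites$nick_pos[i]
      ov <- which(fs < np & fe > np & is.na(nick_site))
      if (length(ov)) {
        cut <- ov[stats::runif(length(ov)) < sites$nick_fraction[i]]
        nick_site[cut] <- i
      }
    }
  }

  reads <- list()
  add <- function(strand, start, end) {
    keep <- end - start + 1L >= min_piece
    if (any(keep)) {
      reads[[length(reads) + 1L]] <<- data.frame(
        contig = config$contig_name, strand = strand,
        start = as.integer(start[keep]), end = as.integer(end[keep]),
        stringsAsFactors = FALSE)
    }
  }

  plain <- is.na(nick_site)
  nick_strand <- rep(NA_character_, n_frags)
  nick_pos <- rep(NA_integer_, n_frags)
  if (nrow(sites)) {
    nick_strand[!plain] <- sites$strand[nick_site[!plain]]
    nick_pos[!plain] <- sites$nick_pos[nick_site[!plain]]
  }

  # intact forward strand reads (all fragments except those nicked on "+")
  fwd_ok <- plain | nick_strand != "+"
  add("+", fs[fwd_ok], pmin(fs[fwd_ok] + rl - 1L, fe[fwd_ok]))
  # intact reverse strand reads
  rev_ok <- plain | nick_strand != "-"
  add("-", pmax(fs[rev_ok], fe[rev_ok] - rl + 1L), fe[rev_ok])

  # nicked forward strand: pieces [fs, nick-1] and [nick+1, fe]
  nf <- which(!plain & nick_strand == "+")
  if (length(nf)) {
    add("+", fs[nf], pmin(fs[nf] + rl - 1L, nick_pos[nf] - 1L))
    add("+", nick_pos[nf] + 1L, pmin(nick_pos[nf] + rl, fe[nf]))
  }
  # nicked reverse strand: 5' ends at nick-1 (left piece) and fe (right piece)
  nr <- which(!plain & nick_strand == "-")
  if (length(nr)) {
    add("-", pmax(fs[nr], nick_pos[nr] - rl), nick_pos[nr] - 1L)
    add("-", pmax(nick_pos[nr] + 1L, fe[nr] - rl + 1L), fe[nr])
  }

  out <- do.call(rbind, reads)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  out$mapq <- 60L
  out$is_primary <- TRUE
  rownames(out) <- NULL
  if (keep_fragments) {
    attr(out, "fragments") <- data.frame(
      start = fs, end = fe, nick_pos = nick_pos,
      nick_strand = nick_strand, stringsAsFactors = FALSE)
  }
  out
}

#' Simulate merged amplicon reads with planted edits
#'
#' Each read starts as the reference amplicon; at every protospacer position
#' with a nonzero rate and an editable C (on the protospacer strand) the base
#' is converted independently with that probability. With probability
#' \code{indel_rate} a read instead of/additionally carries a 1-bp deletion
#' at a random position inside the protospacer.
#'
#' @param spec An [amplicon_spec()].
#' @param edit_rates Numeric vector of per-protospacer-position C-to-T rates:
#'   either length 23 or named by protospacer position.
#' @param indel_rate Per-read 1-bp deletion probability (default 0).
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @return Character vector of read sequences.
#' @export
simulate_amplicon_reads <- function(spec, edit_rates, indel_rate = 0,
                                    n_reads, seed) {
  set.seed(dg_subseed(seed, 2L))
  rates <- numeric(spec$protospacer_length)
  if (!is.null(names(edit_rates))) {
    rates[as.integer(names(edit_rates))] <- edit_rates
  } else {
    rates[seq_along(edit_rates)] <- edit_rates
  }
  dg_assert(all(rates >= 0 & rates <= 1) && indel_rate >= 0 && indel_rate <= 1,
            "rates must lie in [0, 1]", "digenomeR_bad_config")
  refc <- seq_chars(spec$reference)
  from <- if (spec$strand == "+") "C" else "G"
  to <- if (spec$strand == "+") "T" else "A"
  mat <- matrix(rep(refc, n_reads), nrow = n_reads, byrow = TRUE)
  for (k in which(rates > 0)) {
    p <- proto_to_amplicon(spec, k)
    if (refc[p] != from) next
    hit <- stats::runif(n_reads) < rates[k]
    mat[hit, p] <- to
  }
  reads <- apply(mat, 1L, paste, collapse = "")
  if (indel_rate > 0) {
    del <- stats::runif(n_reads) < indel_rate
    if (any(del)) {
      lo <- spec$protospacer_start
      hi <- spec$protospacer_start + spec$protospacer_length - 1L
      pos <- sample(lo:hi, sum(del), replace = TRUE)
      reads[del] <- paste0(substr(reads[del], 1L, pos - 1L),
                           substring(reads[del], pos + 1L))
    }
  }
  reads
}

#' Write simulated reads as a coordinate-sorted SAM file
#'
#' @param reads Data frame from [simulate_digested_reads()].
#' @param genome Reference genome (\code{DNAStringSet}) supplying read
#'   sequences.
#' @param path Output path (\code{.sam}).
#' @return Invisibly, the path.
#' @export
write_sam <- function(reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ctg in names(genome)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ctg,
                       Biostrings::width(genome)[names(genome) == ctg]), con)
  }
  ord <- order(match(reads$contig, names(genome)), reads$start)
  r <- reads[ord, , drop = FALSE]
  seqs <- character(nrow(r))
  for (ctg in unique(r$contig)) {
    ii <- which(r$contig == ctg)
    gs <- as.character(genome[[ctg]])
    seqs[ii] <- substring(gs, r$start[ii], r$end[ii])
  }
  minus <- r$strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  }
  len <- r$end - r$start + 1L
  lines <- sprintf("r%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                   seq_len(nrow(r)), ifelse(minus, 16L, 0L), r$contig,
                   r$start, if (is.null(r$mapq)) 60L else r$mapq, len, seqs,
                   strrep("I", len))
  writeLines(lines, con)
  invisible(path)
}
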