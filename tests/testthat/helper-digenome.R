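# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops over character vectors, independent of the package's
# vectorised code paths.

# 23-nt protospacer with an editable C at position 10 (inside the 8-13
# editing window); positions 10-13 are a C run, 8 is C too.
TEST_PROTO <- "GATTGAACTCCCCAGCACCGGTT"

make_target <- function() target_spec("t1", TEST_PROTO)

make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}

# brute-force strand pileup tally: scan the read list position by position
oracle_pileup <- function(reads, L) {
  fwd_start <- integer(L); rev_start <- integer(L)
  fwd_depth <- integer(L); rev_depth <- integer(L)
  for (i in seq_len(nrow(reads))) {
    s <- reads$start[i]; e <- reads$end[i]
    if (reads$strand[i] == "+") {
      fwd_start[s] <- fwd_start[s] + 1L
      fwd_depth[s:e] <- fwd_depth[s:e] + 1L
    } else {
      rev_start[e] <- rev_start[e] + 1L
      rev_depth[s:e] <- rev_depth[s:e] + 1L
    }
  }
  list(fwd_start = fwd_start, rev_start = rev_start,
       fwd_depth = fwd_depth, rev_depth = rev_depth)
}

# per-position mismatch count over protospacer positions 1-20
oracle_mismatches <- function(target_proto, cand) {
  tc <- strsplit(target_proto, "")[[1L]]
  cc <- strsplit(cand, "")[[1L]]
  n <- 0L
  for (i in 1:20) if (tc[i] != cc[i]) n <- n + 1L
  n
}

# exhaustive enumeration of all gap placements for a PAM+24nt window;
# returns the minimal effective score over ungapped / RNA-bulge / DNA-bulge
oracle_best_bulge_score <- function(target_proto, window, penalty = 2L) {
  tc <- strsplit(target_proto, "")[[1L]]
  wc <- strsplit(window, "")[[1L]]
  mm20 <- function(cand) {
    n <- 0L
    for (i in 1:20) if (tc[i] != cand[i]) n <- n + 1L
    n
  }
  best <- mm20(wc[5:27])                       # ungapped
  g22 <- wc[5:26]
  for (k in 1:23) {                            # RNA bulge: gap in genome
    cand <- append(g22, "-", after = k - 1L)
    sc <- penalty
    for (i in 1:20) if (i != k && tc[i] != cand[i]) sc <- sc + 1L
    best <- min(best, sc)
  }
  g24 <- wc[5:28]
  for (k in 1:22) {                            # DNA bulge: drop genome base
    cand <- g24[-(k + 1L)]
    best <- min(best, mm20(cand) + penalty)
  }
  best
}

# position-by-position genome scan for TTTN (+ optionally PAM-like) sites
oracle_enumerate <- function(genome_string, target_proto, max_mm = 8L,
                             pam_like = FALSE, max_mm_pl = 7L) {
  scan <- function(gs, strand, L) {
    res <- list()
    for (i in seq_len(nchar(gs) - 26L)) {
      pam <- substr(gs, i, i + 3L)
      cano <- substr(pam, 1, 3) == "TTT"
      pl <- !cano && pam_like &&
        (substr(pam, 2, 3) == "TT" ||
           (substr(pam, 1, 1) == "T" && substr(pam, 3, 3) == "T") ||
           substr(pam, 1, 2) == "TT")
      if (!cano && !pl) next
      mm <- oracle_mismatches(target_proto, substr(gs, i + 4L, i + 26L))
      if ((cano && mm <= max_mm) || (pl && mm <= max_mm_pl)) {
        start <- if (strand == "+") i + 4L else L - (i + 4L) - 21L
        res[[length(res) + 1L]] <- data.frame(
          start = start, strand = strand, mm = mm,
          stringsAsFactors = FALSE)
      }
    }
    if (length(res)) do.call(rbind, res) else NULL
  }
  L <- nchar(genome_string)
  out <- rbind(scan(genome_string, "+", L),
               scan(oracle_revcomp(genome_string), "-", L))
  if (is.null(out)) return(data.frame(start = integer(), strand = character(),
                                      mm = integer()))
  out[order(out$start, out$strand), , drop = FALSE]
}

# exhaustive placement scan around a nick: minimal passing effective score
# over every protospacer placement on either strand whose PAM classifies and
# that satisfies the nick-within-protospacer(+slack) constraint
oracle_best_near_break <- function(gs, nick, target_proto, radius = 30L,
                                   slack = 5L, penalty = 2L) {
  L <- nchar(gs)
  classify <- function(pam) {
    b <- strsplit(pam, "")[[1L]] == "T"
    if (b[1] && b[2] && b[3]) "canonical"
    else if ((b[2] && b[3]) || (b[1] && b[3]) || (b[1] && b[2])) "pam_like"
    else "none"
  }
  best <- Inf
  for (s in max(5L, nick - radius):min(L - 27L, nick + radius)) {
    if (nick < s - slack || nick > s + 22L + slack) next
    w <- substr(gs, s - 4L, s + 23L)
    pc <- classify(substr(w, 1L, 4L))
    if (pc == "none") next
    sc <- oracle_best_bulge_score(target_proto, w, penalty)
    if ((pc == "canonical" && sc <= 8L) || (pc == "pam_like" && sc <= 7L)) {
      best <- min(best, sc)
    }
  }
  rcs <- oracle_revcomp(gs)
  rnick <- L - nick + 1L
  for (s in max(5L, rnick - radius):min(L - 27L, rnick + radius)) {
    if (rnick < s - slack || rnick > s + 22L + slack) next
    w <- substr(rcs, s - 4L, s + 23L)
    pc <- classify(substr(w, 1L, 4L))
    if (pc == "none") next
    sc <- oracle_best_bulge_score(target_proto, w, penalty)
    if ((pc == "canonical" && sc <= 8L) || (pc == "pam_like" && sc <= 7L)) {
      best <- min(best, sc)
    }
  }
  best
}

# O(n^2) single-linkage clustering of candidate positions
oracle_merge <- function(cand, window) {
  if (nrow(cand) == 0L) return(cand)
  keep <- list()
  for (key in unique(paste(cand$contig, cand$strand))) {
    sub <- cand[paste(cand$contig, cand$strand) == key, , drop = FALSE]
    n <- nrow(sub)
    # transitive closure of the "within window" relation
    grp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (abs(sub$position[i] - sub$position[j]) <= window &&
            grp[i] != grp[j]) {
          grp[grp == max(grp[i], grp[j])] <- min(grp[i], grp[j])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (g in unique(grp)) {
      s2 <- sub[grp == g, , drop = FALSE]
      best <- s2[s2$start_count == max(s2$start_count), , drop = FALSE]
      keep[[length(keep) + 1L]] <-
        best[which.min(best$position), , drop = FALSE]
    }
  }
  out <- do.call(rbind, keep)
  out[order(out$contig, out$position, out$strand), , drop = FALSE]
}

# hand-built pileup object for threshold tests
make_pileup <- function(L, fwd_start = integer(L), rev_start = integer(L),
                        fwd_depth = integer(L), rev_depth = integer(L),
                        contig = "chrS") {
  pl <- list(list(fwd_start = fwd_start, rev_start = rev_start,
                  fwd_depth = fwd_depth, rev_depth = rev_depth))
  names(pl) <- contig
  structure(pl, class = "strand_pileup",
            contig_lengths = stats::setNames(L, contig))
}

# standard 6-site scenario: exact on-target plus five off-targets covering
# 2-8 mismatches and both bulge types (mismatches within positions 1-20)
six_site_config <- function(seed, genome_length = 1000000L, depth = 30,
                            nick_fraction = 0.7) {
  sim_config(
    genome_length = genome_length, seed = seed, depth = depth,
    planted_sites = list(
      planted_site("on", nick_fraction = nick_fraction),
      planted_site("off1", strand = "-", mismatch_positions = c(2, 15),
                   nick_fraction = nick_fraction),
      planted_site("off2", mismatch_positions = c(1, 5, 12, 18, 19),
                   nick_fraction = nick_fraction),
      planted_site("off3",
                   mismatch_positions = c(3, 6, 14, 15, 16, 17, 19, 20),
                   nick_fraction = nick_fraction),
      planted_site("off4", mismatch_positions = c(4, 15, 19),
                   bulge = "rna", bulge_pos = 6,
                   nick_fraction = nick_fraction),
      planted_site("off5", strand = "-",
                   mismatch_positions = c(2, 16, 18, 20),
                   bulge = "dna", bulge_pos = 15,
                   nick_fraction = nick_fraction)))
}

truth_sites <- function(sim) {
  data.frame(contig = sim$sites$contig, strand = sim$sites$strand,
             start = sim$sites$protospacer_start,
             stringsAsFactors = FALSE)
}
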