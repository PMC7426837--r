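test_that("PAM tetramers are classified as canonical, PAM-like or none", {
  expect_equal(classify_pam("TTTA"), "canonical")
  expect_equal(classify_pam("TTTT"), "canonical")
  expect_equal(classify_pam("ATTC"), "pam_like")   # NTTN
  expect_equal(classify_pam("TATA"), "pam_like")   # TNTN
  expect_equal(classify_pam("TTGA"), "pam_like")   # TTNN
  expect_equal(classify_pam("GCGA"), "none")
  expect_equal(classify_pam("NTTT"), "pam_like")   # wildcard position tolerates N
  expect_equal(classify_pam("TNTT"), "pam_like")   # N never matches a fixed T
  expect_error(classify_pam("TTT"), class = "digenomeR_bad_pam")
  expect_error(classify_pam("TTTX"), class = "digenomeR_bad_pam")
})

test_that("mismatches are counted over positions 1-20 only", {
  tg <- make_target()
  expect_equal(count_mismatches(tg, TEST_PROTO)$mismatch_count, 0L)
  # change only positions 21-23
  cand <- paste0(substr(TEST_PROTO, 1, 20), "AAA")
  expect_equal(count_mismatches(tg, cand)$mismatch_count, 0L)
  cand2 <- paste0("T", substr(TEST_PROTO, 2, 23))   # position 1 (G -> T)
  sa <- count_mismatches(tg, cand2)
  expect_equal(sa$mismatch_count, 1L)
  expect_equal(sa$mismatch_positions, 1L)
  expect_error(count_mismatches(tg, "ACGT"),
               class = "digenomeR_length_mismatch")
})

test_that("mismatch counting agrees with a per-position loop on 1000 random 23-mers", {
  tg <- make_target()
  set.seed(41)
  for (i in 1:1000) {
    cand <- random_dna(23L)
    expect_equal(count_mismatches(tg, cand)$mismatch_count,
                 oracle_mismatches(TEST_PROTO, cand))
  }
})

test_that("20-nt mismatch distance is a metric on positions 1-20", {
  tg <- make_target()
  set.seed(42)
  for (i in 1:50) {
    a <- random_dna(23L)
    ta <- target_spec("a", a)
    b <- random_dna(23L)
    expect_equal(count_mismatches(ta, b)$mismatch_count,
                 count_mismatches(target_spec("b", b), a)$mismatch_count)
  }
  same20 <- paste0(substr(TEST_PROTO, 1, 20), "GGG")
  expect_equal(count_mismatches(tg, same20)$mismatch_count, 0L)
})

test_that("bulge alignment recovers planted deletions and insertions", {
  tg <- make_target()
  pam <- "TTTA"
  tail2 <- "GT"   # filler beyond the protospacer
  # identity window: ungapped, 0 mismatches
  sa <- align_with_bulge(tg, paste0(pam, TEST_PROTO, tail2))
  expect_equal(sa$bulge, "none")
  expect_equal(sa$mismatch_count, 0L)
  expect_equal(sa$score, 0L)
  # genomic window lacking target position 10 (an RNA bulge)
  del10 <- paste0(substr(TEST_PROTO, 1, 9), substr(TEST_PROTO, 11, 23))
  sa <- align_with_bulge(tg, paste0(pam, del10, tail2))
  expect_equal(sa$bulge, "rna_bulge")
  expect_equal(sa$mismatch_count, 0L)
  expect_equal(sa$bulge_pos, 10L)
  expect_equal(sa$score, 2L)
  expect_match(sa$aln, "-")
  # extra G inserted after target position 12 (a DNA bulge)
  ins12 <- paste0(substr(TEST_PROTO, 1, 12), "G", substr(TEST_PROTO, 13, 23))
  sa <- align_with_bulge(tg, paste0(pam, ins12, "T"))
  expect_equal(sa$bulge, "dna_bulge")
  expect_equal(sa$mismatch_count, 0L)
  expect_equal(sa$bulge_pos, 12L)
  expect_error(align_with_bulge(tg, paste0(pam, substr(TEST_PROTO, 1, 23))),
               class = "digenomeR_window_too_short")
})

test_that("bulge alignment matches exhaustive gap-placement enumeration", {
  tg <- make_target()
  set.seed(43)
  for (i in 1:100) {
    w <- paste0(random_dna(4L), random_dna(24L))
    sa <- align_with_bulge(tg, w)
    expect_equal(sa$score, oracle_best_bulge_score(TEST_PROTO, w))
    # never worse than the ungapped alignment
    ungapped <- count_mismatches(tg, substr(w, 5L, 27L))
    expect_lte(sa$score, ungapped$mismatch_count)
  }
})

test_that("capture rule enforces <= 8 (canonical) and <= 7 (PAM-like)", {
  mk <- function(pam_class, score) {
    structure(list(pam_class = pam_class, score = score,
                   mismatch_count = score, bulge = "none"),
              class = "site_alignment")
  }
  expect_true(match_rule(mk("canonical", 8L)))
  expect_false(match_rule(mk("canonical", 9L)))
  expect_true(match_rule(mk("pam_like", 7L)))
  expect_false(match_rule(mk("pam_like", 8L)))
  expect_false(match_rule(mk("none", 0L)))
  # monotone: removing a mismatch never flips pass into fail
  for (pc in c("canonical", "pam_like")) for (s in 1:9) {
    if (match_rule(mk(pc, s))) expect_true(match_rule(mk(pc, s - 1L)))
  }
})

test_that("a bulge consumes two mismatch-equivalents of the budget", {
  tg <- make_target()
  set.seed(44)
  # site with 7 real mismatches (positions 5, 6, 10, 12, 13, 17, 20) plus
  # a 1-nt deletion at position 8: the best alignment is an RNA bulge with
  # 7 mismatches, score 7 + 2 = 9, which must fail the <= 8 cutoff.  This
  # mutation set was chosen so that no gapless or alternative gapped
  # alignment reaches a score below 9.
  mutated <- "GATTACACTACGAAGCCCCCGTT"
  expect_equal(oracle_mismatches(TEST_PROTO, mutated), 7L)
  del8 <- paste(strsplit(mutated, "")[[1L]][-8], collapse = "")
  sa <- align_with_bulge(tg, paste0("TTTA", del8, "GTA"))
  expect_equal(sa$bulge, "rna_bulge")
  expect_equal(sa$mismatch_count, 7L)
  expect_equal(sa$score, 9L)
  expect_false(match_rule(sa))
})

test_that("sites are found near planted breaks and not beyond the window", {
  tg <- make_target()
  set.seed(45)
  left <- random_dna(300L)
  right <- random_dna(300L)
  gs <- paste0(left, "TTTA", TEST_PROTO, right)
  g <- make_genome(c(chrS = gs))
  nick <- 300L + 4L + 10L     # protospacer position 10
  hit <- find_site_near_break(g, list(contig = "chrS", position = nick), tg)
  expect_false(is.null(hit))
  expect_equal(hit$start, 305L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$mismatch_count, 0L)
  expect_equal(hit$pam, "TTTA")
  # a nick 50 bp from the protospacer is outside the capture window
  far <- find_site_near_break(g, list(contig = "chrS", position = 305L + 22L + 50L), tg)
  expect_null(far)
})

test_that("a minus-strand site is found from its nick", {
  tg <- make_target()
  set.seed(46)
  block <- oracle_revcomp(paste0("TTTG", TEST_PROTO))
  gs <- paste0(random_dna(200L), block, random_dna(200L))
  g <- make_genome(c(chrS = gs))
  proto_left <- 201L                # revcomp(proto) occupies [201, 223]
  nick <- proto_left + 23L - 10L    # protospacer position 10 on minus strand
  hit <- find_site_near_break(g, list(contig = "chrS", position = nick), tg)
  expect_false(is.null(hit))
  expect_equal(hit$strand, "-")
  expect_equal(hit$start, proto_left)
  expect_equal(hit$mismatch_count, 0L)
  expect_equal(hit$pam, "TTTG")
})

test_that("genome-wide enumeration matches the loop oracle on a random genome", {
  tg <- make_target()
  set.seed(47)
  gs <- random_dna(20000L)
  g <- make_genome(c(chrS = gs))
  got <- enumerate_genome_candidates(g, tg, max_mm_canonical = 12L)
  want <- oracle_enumerate(gs, TEST_PROTO, max_mm = 12L)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$start, want$start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$mismatch_count, want$mm)
  # with PAM-like classes included
  got_pl <- enumerate_genome_candidates(g, tg, max_mm_canonical = 10L,
                                        include_pam_like = TRUE,
                                        max_mm_pamlike = 9L)
  want_pl <- oracle_enumerate(gs, TEST_PROTO, max_mm = 10L, pam_like = TRUE,
                              max_mm_pl = 9L)
  expect_equal(nrow(got_pl), nrow(want_pl))
  expect_equal(got_pl$start, want_pl$start)
})

test_that("enumeration is strand-symmetric under reverse complement", {
  tg <- make_target()
  set.seed(48)
  gs <- random_dna(10000L)
  a <- enumerate_genome_candidates(make_genome(c(chrS = gs)), tg)
  b <- enumerate_genome_candidates(make_genome(c(chrS = oracle_revcomp(gs))),
                                   tg)
  expect_equal(nrow(a), nrow(b))
  L <- nchar(gs)
  mirrored <- sort(L - (a$start + 22L) + 1L)
  expect_equal(sort(b$start), mirrored)
  expect_equal(sum(a$strand == "+"), sum(b$strand == "-"))
})

test_that("a single planted site is the only enumeration hit on a clean genome", {
  tg <- make_target()
  set.seed(49)
  repeat {   # background free of homologous placements at <= 8 mismatches
    gs <- random_dna(3000L)
    if (nrow(enumerate_genome_candidates(make_genome(c(chrS = gs)), tg)) == 0L)
      break
  }
  gs2 <- paste0(substr(gs, 1, 1000), "TTTA", TEST_PROTO,
                substring(gs, 1028))
  got <- enumerate_genome_candidates(make_genome(c(chrS = gs2)), tg)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 1005L)
  expect_equal(got$mismatch_count, 0L)
})

test_that("the site chosen near a break has the oracle-minimal score", {
  tg <- make_target()
  set.seed(53)
  proto <- strsplit(TEST_PROTO, "")[[1L]]
  for (rep in 1:20) {
    # decoy with 4-9 mismatches planted mid-genome, nick inside its window
    nmm <- sample(4:9, 1L)
    mut <- sample(setdiff(1:20, 10L), nmm)
    dec <- proto
    for (i in mut) dec[i] <- sample(setdiff(c("A", "C", "G", "T"), dec[i]), 1L)
    block <- paste0("TTT", sample(c("A", "C", "G"), 1L),
                    paste(dec, collapse = ""))
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") block <- oracle_revcomp(block)
    gs <- paste0(random_dna(150L), block, random_dna(150L))
    nick <- if (strand == "+") 150L + 4L + 10L else 150L + 23L - 10L + 1L
    got <- find_site_near_break(make_genome(c(chrS = gs)),
                                list(contig = "chrS", position = nick), tg)
    want <- oracle_best_near_break(gs, nick, TEST_PROTO)
    if (is.infinite(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$score, want)
    }
  }
})

test_that("break-anchored hits are a subset of the genome-wide enumeration", {
  tg <- make_target()
  set.seed(50)
  cfg <- six_site_config(seed = 51L, genome_length = 100000L, depth = 30,
                         nick_fraction = 0.8)
  sim <- simulate_genome(cfg, tg)
  reads <- simulate_digested_reads(sim)
  calls <- merge_ssb_candidates(
    call_ssb_sites(build_strand_pileup(reads, sim$genome)), 10L)
  hits <- lapply(seq_len(nrow(calls)), function(i) {
    find_site_near_break(sim$genome, calls[i, ], tg, bulges = FALSE)
  })
  hits <- do.call(rbind, Filter(Negate(is.null), hits))
  all_sites <- enumerate_genome_candidates(sim$genome, tg,
                                           include_pam_like = TRUE)
  key <- function(d) paste(d$contig, d$start, d$strand)
  expect_true(all(key(hits) %in% key(all_sites)))
})

test_that("site-set comparison partitions match an all-pairs oracle", {
  idset <- data.frame(contig = "c1", strand = "+",
                      start = c(100L, 200L, 300L))
  v <- compare_site_sets(idset, idset)
  expect_equal(c(v$a_only, v$shared, v$b_only), c(0L, 3L, 0L))
  other <- data.frame(contig = "c2", strand = "+", start = c(100L, 200L))
  v2 <- compare_site_sets(idset, other)
  expect_equal(c(v2$a_only, v2$shared, v2$b_only), c(3L, 0L, 2L))
  set.seed(52)
  for (rep in 1:10) {
    a <- data.frame(contig = sample(c("c1", "c2"), 15, TRUE),
                    strand = sample(c("+", "-"), 15, TRUE),
                    start = sample(1:500, 15))
    b <- data.frame(contig = sample(c("c1", "c2"), 12, TRUE),
                    strand = sample(c("+", "-"), 12, TRUE),
                    start = sample(1:500, 12))
    v <- compare_site_sets(a, b, tolerance = 20L)
    # oracle: maximum bipartite matching via greedy distance order equals
    # the shared count; verify partition arithmetic and match validity
    expect_equal(v$a_only + v$shared, nrow(a))
    expect_equal(v$b_only + v$shared, nrow(b))
    if (nrow(v$pairs)) {
      for (k in seq_len(nrow(v$pairs))) {
        i <- v$pairs$a[k]; j <- v$pairs$b[k]
        expect_equal(a$contig[i], b$contig[j])
        expect_equal(a$strand[i], b$strand[j])
        expect_lte(abs(a$start[i] - b$start[j]), 20L)
      }
      expect_false(anyDuplicated(v$pairs$a) > 0)
      expect_false(anyDuplicated(v$pairs$b) > 0)
    }
  }
})
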