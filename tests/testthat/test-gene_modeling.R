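# Reference-gene choice, HSP-pair classification, seeds, start/stop
# extension.

test_that("reference-gene preference: same-group intron-bearing, then
          same-group, then intron-bearing, then best hit", {
  p <- pillar("P", list(
    ref_gene("post_plain", "postA", "post-WGD", strrep("K", 99)),
    ref_gene("post_intron", "postB", "post-WGD", strrep("K", 99),
             exon_count = 2),
    ref_gene("non_plain", "nonA", "non-WGD", strrep("K", 99)),
    ref_gene("non_intron", "nonB", "non-WGD", strrep("K", 99),
             exon_count = 2)))
  rank_all <- data.frame(
    gene_id = c("post_plain", "post_intron", "non_plain", "non_intron"),
    evalue = c(1e-90, 1e-70, 1e-95, 1e-80), bitscore = c(1, 1, 1, 1))
  # intron-bearing post-WGD member wins for a post-WGD target even though
  # other members hit better
  expect_equal(select_reference_gene(p, "post-WGD", rank_all)$gene_id,
               "post_intron")
  expect_equal(select_reference_gene(p, "non-WGD", rank_all)$gene_id,
               "non_intron")
  # no same-group member hit: intron-bearing member from the other group
  rank_non <- rank_all[rank_all$gene_id %in% c("non_plain", "non_intron"), ]
  expect_equal(select_reference_gene(p, "post-WGD", rank_non)$gene_id,
               "non_intron")
  # intronless pillar, only other-group hits: overall best hit
  p2 <- pillar("P2", list(
    ref_gene("nA", "nonA", "non-WGD", "MKLMKL"),
    ref_gene("nB", "nonB", "non-WGD", "MKLMKL")))
  r2 <- data.frame(gene_id = c("nA", "nB"), evalue = c(1e-50, 1e-60),
                   bitscore = c(1, 1))
  expect_equal(select_reference_gene(p2, "post-WGD", r2)$gene_id, "nB")
  # equal zero E-values: higher bit score wins
  r3 <- data.frame(gene_id = c("nA", "nB"), evalue = c(0, 0),
                   bitscore = c(700, 900))
  expect_equal(select_reference_gene(p2, "non-WGD", r3)$gene_id, "nB")
  expect_error(select_reference_gene(p2, "non-WGD",
                                     r3[integer(0), ]), "no member")
})

test_that("mean group lengths average per species group and mark absent
          groups as undefined", {
  p <- pillar("P", list(
    ref_gene("a", "postA", "post-WGD", strrep("A", 100)),
    ref_gene("b", "postB", "post-WGD", strrep("A", 200))))
  expect_equal(unname(mean_group_lengths(p)["post-WGD"]), 150)
  expect_true(is.na(mean_group_lengths(p)["non-WGD"]))
  w <- build_reference_world(fixture_spec(seed = 3, n_pillars = 3))
  pl <- w$db$pillars[[1]]
  lens <- vapply(pl$members, function(m) nchar(m$protein), numeric(1))
  grp <- vapply(pl$members, `[[`, character(1), "species_group")
  expect_equal(unname(mean_group_lengths(pl)["non-WGD"]),
               mean(lens[grp == "non-WGD"]))
})

# Independent brute-force transcription of the four-way decision ladder:
# (i) frameshift: different frames, similar query/subject distance;
# (ii) low similarity: same frame, similar distance, no stop between;
# (iii) intron: dissimilar distances (small query gap, large subject gap),
#       only when the species group has an intron-bearing member;
# (iv) otherwise duplication (including heavy query overlap).
oracle_classify <- function(qgap_aa, ds, stop_between, intron_allowed,
                            gap_tol = 30, overlap_tol = 15,
                            min_intron = 40) {
  overlap <- max(0, -qgap_aa)
  if (overlap > overlap_tol) return("duplication")
  dq <- 3 * qgap_aa
  frames_same <- (ds - dq) %% 3 == 0
  similar <- abs(dq - ds) <= gap_tol
  if (!frames_same && similar) return("frameshift")
  if (frames_same && similar && !stop_between) return("low-similarity")
  if (!similar && intron_allowed && dq <= gap_tol && ds >= min_intron)
    return("intron")
  "duplication"
}

test_that("classifier matches the brute-force decision ladder on an
          exhaustive grid of >10000 cases", {
  qgaps <- -20:25                       # aa; negative = query overlap
  dss <- seq(-45, 620, by = 11)         # nt subject gaps
  n_cases <- 0L
  mismatch <- character(0)
  for (qgap in qgaps) {
    h1 <- hsp_row(qstart = 1L, qend = 50L, sstart = 1000, send = 1150)
    for (ds in dss) {
      h2 <- hsp_row(qstart = 51L + qgap, qend = 90L + qgap,
                    sstart = 1150 + ds, send = 1270 + ds)
      for (stop_between in c(FALSE, TRUE))
        for (intron_allowed in c(FALSE, TRUE)) {
          got <- classify_hsp_pair(h1, h2, intron_allowed,
                                   stop_between = stop_between)$kind
          want <- oracle_classify(qgap, ds, stop_between, intron_allowed)
          if (!identical(got, want))
            mismatch <- c(mismatch, sprintf(
              "qgap=%d ds=%d stop=%d intr=%d: %s != %s", qgap, ds,
              stop_between, intron_allowed, got, want))
          n_cases <- n_cases + 1L
        }
    }
  }
  expect_gte(n_cases, 10000L)
  expect_identical(mismatch, character(0))
})

test_that("worked classifier cases: frameshift, stop-broken merge, intron
          window", {
  h1 <- hsp_row(qstart = 1, qend = 50, sstart = 300, send = 450, frame = 0)
  # different frames, similar distances: frameshift with a site estimate
  h2 <- hsp_row(qstart = 62, qend = 100, sstart = 481, send = 595,
                frame = 1)
  cl <- classify_hsp_pair(h1, h2, FALSE, stop_between = FALSE)
  expect_equal(cl$kind, "frameshift")
  expect_equal(cl$details$site, floor((450 + 481) / 2))
  # same frame, similar distance, but an in-frame stop between: never
  # low-similarity (falls through to duplication)
  h3 <- hsp_row(qstart = 62, qend = 100, sstart = 480, send = 594)
  expect_equal(classify_hsp_pair(h1, h3, TRUE, stop_between = TRUE)$kind,
               "duplication")
  # query gap 0, subject gap 300: intron (when allowed)
  h4 <- hsp_row(qstart = 51, qend = 100, sstart = 750, send = 900)
  expect_equal(classify_hsp_pair(h1, h4, TRUE, stop_between = FALSE)$kind,
               "intron")
  expect_equal(classify_hsp_pair(h1, h4, FALSE, stop_between = FALSE)$kind,
               "duplication")
})

test_that("stop_between is computed from the genome when not supplied", {
  # two same-frame HSPs with a TAA vs a clean spacer between them
  set.seed(5)
  aa <- random_aa(40)
  cds <- syntann:::back_translate(aa)
  clean_gap <- strrep("GCT", 10)
  stop_gap <- paste0(strrep("GCT", 4), "TAA", strrep("GCT", 5))
  for (gap in list(clean_gap, stop_gap)) {
    g <- genome(c(s1 = paste0(cds, gap, cds)))
    h1 <- hsp_row(qstart = 1, qend = 40, sstart = 0, send = nchar(cds))
    h2 <- hsp_row(qstart = 51, qend = 90, sstart = nchar(cds) + 30,
                  send = 2 * nchar(cds) + 30)
    kind <- classify_hsp_pair(h1, h2, FALSE, genome = g)$kind
    expect_equal(kind, if (grepl("TAA", gap)) "duplication"
                 else "low-similarity")
  }
})

test_that("seed derivation merges through non-duplication calls and splits
          at duplications, for every call sequence over 3 HSPs", {
  hsps <- rbind(hsp_row(sstart = 0, send = 300),
                hsp_row(sstart = 400, send = 700),
                hsp_row(sstart = 800, send = 1100))
  fake_call <- function(kind) structure(list(kind = kind,
                                             pair = NULL, details = NULL),
                                        class = "syn_paircall")
  kinds <- c("frameshift", "low-similarity", "intron", "duplication")
  for (k1 in kinds) for (k2 in kinds) {
    groups <- seed_coordinates(hsps, list(fake_call(k1), fake_call(k2)))
    # independent expectation: split exactly at duplication calls
    want <- split(1:3, cumsum(c(0, c(k1, k2) == "duplication")))
    expect_length(groups, length(want))
    for (i in seq_along(want)) {
      expect_equal(groups[[i]]$hsp_idx, unname(want[[i]]))
      expect_equal(groups[[i]]$start, hsps$sstart[want[[i]][1]])
      expect_equal(groups[[i]]$end, hsps$send[tail(want[[i]], 1)])
    }
  }
  # single-HSP locus: seed is the HSP extent
  g1 <- seed_coordinates(hsps[1, ], list())
  expect_equal(c(g1[[1]]$start, g1[[1]]$end), c(0, 300))
})

# Naive start/stop oracle: enumerate every in-frame codon position with
# vectorized set logic instead of walking.
naive_extend <- function(cseq, cs, ce, window = 45L) {
  L <- nchar(cseq)
  frame <- cs %% 3
  pos <- seq.int(frame, L - 3L, by = 3L)
  cods <- substring(cseq, pos + 1L, pos + 3L)
  is_stop <- cods %in% c("TAA", "TAG", "TGA")
  is_atg <- cods == "ATG"
  tags <- character(0)
  if (cods[match(cs, pos)] == "ATG") {
    start <- cs
  } else {
    up_stops <- pos[is_stop & pos < cs]
    barrier <- if (length(up_stops)) max(up_stops) else frame - 3L
    up_atgs <- pos[is_atg & pos < cs & pos > barrier]
    if (length(up_atgs)) {
      start <- min(up_atgs)
    } else {
      inside <- pos[is_atg & pos >= cs & pos < cs + window]
      if (length(inside)) start <- inside[1]
      else { start <- cs; tags <- "manual-check" }
    }
  }
  down_stops <- pos[is_stop & pos >= start]
  if (length(down_stops)) end <- down_stops[1] + 3L
  else { end <- ce; tags <- c(tags, "manual-check") }
  list(start = start, end = end, tags = unique(tags))
}

test_that("start/stop extension agrees with the naive full-scan oracle on
          1000 random in-frame seeds (both strands)", {
  set.seed(77)
  for (i in 1:1000) {
    L <- 600L
    seq <- syntann:::random_dna(L)
    strand <- if (i %% 2 == 0) "-" else "+"
    cs <- 3L * sample(60:120, 1L)
    ce <- cs + 3L * sample(20:60, 1L)
    cseq <- if (strand == "-") revcomp(seq) else seq
    want <- naive_extend(cseq, cs, ce)
    seed_f <- if (strand == "-") c(L - ce, L - cs) else c(cs, ce)
    got <- extend_to_start_stop(seed_f[1], seed_f[2], seq, strand)
    got_c <- if (strand == "-") list(start = L - got$end,
                                     end = L - got$start)
             else got
    expect_equal(got_c$start, want$start, info = paste("case", i))
    expect_equal(got_c$end, want$end, info = paste("case", i))
    expect_setequal(got$tags, want$tags)
  }
})

test_that("worked extension cases: furthest ATG, 45-nt inside scan, manual
          tag, internal stop trim, N-run", {
  seed_block <- strrep("GCT", 20)
  # upstream TAA then two ATGs: the furthest ATG (after the stop) is taken
  seq <- paste0("TAA", "ATG", "ATG", seed_block, "TGA", "CC")
  got <- extend_to_start_stop(9, 9 + 60, seq, "+")
  expect_equal(got$start, 3)
  expect_equal(got$end, 9 + 60 + 3)
  expect_length(got$tags, 0L)
  # stop immediately upstream, ATG at seed offset +9: start inside the seed
  seq2 <- paste0("TAA", strrep("GCT", 3), "ATG", seed_block, "TGA")
  got2 <- extend_to_start_stop(3, 3 + 9 + 3 + 60, seq2, "+")
  expect_equal(got2$start, 12)
  # stop upstream, no ATG within the first 45 nt: seed kept, manual-check
  seq3 <- paste0("TAA", seed_block, "TGA")
  got3 <- extend_to_start_stop(3, 63, seq3, "+")
  expect_equal(got3$start, 3)
  expect_true("manual-check" %in% got3$tags)
  # a stop inside the seed trims the model
  seq4 <- paste0("TAA", "ATG", strrep("GCT", 5), "TAA", strrep("GCT", 10))
  got4 <- extend_to_start_stop(3, nchar(seq4), seq4, "+")
  expect_equal(got4$end, 3 + 3 + 15 + 3)
  # upstream N-run: runs-into-N tag
  seq5 <- paste0("NNNNNN", seed_block, "TGA")
  got5 <- extend_to_start_stop(6, 66, seq5, "+")
  expect_true("runs-into-N" %in% got5$tags)
  expect_error(extend_to_start_stop(0, 2, "ACGTACGT", "+"), "codon")
})

test_that("upstream extension respects the mean-length cap", {
  # a distant ATG beyond the cap is ignored
  seq <- paste0("ATG", strrep("GCT", 40), strrep("CCA", 20), "TGA")
  cs <- 3 + 120
  got_capped <- syntann:::extend_start_coding(seq, cs, max_extend_nt = 60)
  expect_true("manual-check" %in% got_capped$tags)
  got_free <- syntann:::extend_start_coding(seq, cs, max_extend_nt = Inf)
  expect_equal(got_free$start, 0)
})
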