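# Single-intron prediction from the splice motif inventories.

# plant a gene with one intron and return everything needed to query it
planted_intron_gene <- function(seed, prot_len = 200, e1_aa = 30,
                                donor = "GTATGT", branch = "ACTAAC",
                                acceptor = "TAG", intron_mid = 120) {
  set.seed(seed)
  prot <- random_aa(prot_len)
  cds <- paste0(syntann:::back_translate(prot), "TAA")
  intron <- paste0(donor, syntann:::random_dna(intron_mid), branch,
                   syntann:::random_dna(15), acceptor)
  cut <- 3 * e1_aa
  pad5 <- 300; pad3 <- 300
  seq <- paste0(syntann:::random_dna(pad5 - 3), "TAA",
                substr(cds, 1, cut), intron,
                substr(cds, cut + 1, nchar(cds)),
                syntann:::random_dna(pad3))
  list(genome = genome(c(s1 = seq)), prot = prot,
       exon1 = c(pad5, pad5 + cut),
       intron = c(pad5 + cut, pad5 + cut + nchar(intron)),
       exon2 = c(pad5 + cut + nchar(intron),
                 pad5 + cut + nchar(intron) + nchar(cds) - cut))
}

test_that("a planted intron between two HSPs is recovered with exact
          boundaries and verbatim motifs", {
  for (seed in 1:5) {
    pl <- planted_intron_gene(seed, donor = sample(DONOR_MOTIFS, 1),
                              branch = sample(BRANCH_MOTIFS, 1),
                              acceptor = sample(ACCEPTOR_MOTIFS, 1))
    h <- builtin_translated_search(c(q = pl$prot), pl$genome)
    h <- h[order(h$sstart), ]
    expect_gte(nrow(h), 2L)
    ic <- intron_between_hsps(h[1, ], h[2, ], pl$genome)
    expect_false(is.null(ic))
    expect_equal(c(ic$intron_start, ic$intron_end), pl$intron)
    expect_true(ic$motifs[["donor"]] %in% DONOR_MOTIFS)
    expect_true(ic$motifs[["branch"]] %in% BRANCH_MOTIFS)
    expect_true(ic$motifs[["acceptor"]] %in% ACCEPTOR_MOTIFS)
    # ordering invariant on the coding strand
    expect_lt(ic$intron_start, ic$branch_start)
    expect_lt(ic$branch_start + 6, ic$intron_end)
  }
})

test_that("a window without any donor motif yields no call", {
  set.seed(6)
  pl <- planted_intron_gene(6)
  # destroy the donor: mutate the first two intron bases
  seq <- pl$genome$sequences$s1
  s <- pl$intron[1]
  substr(seq, s + 1, s + 2) <- "CC"
  g2 <- genome(c(s1 = seq))
  h <- builtin_translated_search(c(q = pl$prot), g2)
  h <- h[order(h$sstart), ]
  ic <- intron_between_hsps(h[1, ], h[2, ], g2)
  expect_null(ic)
})

test_that("among valid donor candidates the one matching the expected
          intron length (then nearest the first HSP) wins", {
  # enumeration oracle: recompute the best combination independently
  set.seed(8)
  pl <- planted_intron_gene(8)
  h <- builtin_translated_search(c(q = pl$prot), pl$genome)
  h <- h[order(h$sstart), ]
  ic <- intron_between_hsps(h[1, ], h[2, ], pl$genome)
  seq <- pl$genome$sequences$s1
  win_lo <- h$send[1] - 45; win_hi <- h$sstart[2] + 45
  win <- substr(seq, win_lo + 1, win_hi)
  ds <- h$sstart[2] - h$send[1]
  dq <- (h$qstart[2] - h$qend[1] - 1) * 3
  best <- NULL
  for (d in syntann:::motif_positions(win, DONOR_MOTIFS) + win_lo) {
    for (a in syntann:::motif_positions(win, ACCEPTOR_MOTIFS) + win_lo + 3) {
      len <- a - d
      if (len < 40 || len > 1000 || (len - (ds - dq)) %% 3 != 0) next
      br <- syntann:::motif_positions(win, BRANCH_MOTIFS) + win_lo
      br <- br[br >= d + 6 & br + 6 <= a - 3]
      if (!length(br)) next
      if (!syntann:::spliced_product_clean(seq, h$sstart[1], d, a,
                                           h$send[2])) next
      cand <- c(d = d, a = a, err = abs(len - (ds - dq)),
                prox = abs(d - h$send[1]))
      if (is.null(best) || cand["err"] < best["err"] ||
          (cand["err"] == best["err"] && cand["prox"] < best["prox"]))
        best <- cand
    }
  }
  expect_equal(unname(best[["d"]]), ic$intron_start)
  expect_equal(unname(best[["a"]]), ic$intron_end)
})

test_that("a short first exon is recovered from a single exon-2 HSP", {
  # 12-nt exon 1: far too short to seed a translated hit
  pl <- planted_intron_gene(9, e1_aa = 4)
  ref <- ref_gene("r", "postA", "post-WGD", pl$prot, exon_count = 2)
  h <- builtin_translated_search(c(q = pl$prot), pl$genome)
  h <- h[order(-h$score), ]
  expect_equal(nrow(h), 1L)   # only exon 2 hits
  rec <- recover_missing_exon1(h[1, ], pl$genome, ref)
  expect_false(is.null(rec))
  expect_equal(unname(rec$exons[1, ]), pl$exon1)
  expect_equal(c(rec$intron$intron_start, rec$intron$intron_end), pl$intron)
  expect_equal(unname(rec$exons[2, ]), pl$exon2)  # exon 2 includes the stop
  # the operation demands an intron-bearing reference
  ref_plain <- ref_gene("r2", "postA", "post-WGD", pl$prot)
  expect_error(recover_missing_exon1(h[1, ], pl$genome, ref_plain),
               "intron-bearing")
})

test_that("exon-1 placement minimizes the distance to the reference protein
          length", {
  pl <- planted_intron_gene(10, e1_aa = 4)
  ref <- ref_gene("r", "postA", "post-WGD", pl$prot, exon_count = 2)
  h <- builtin_translated_search(c(q = pl$prot), pl$genome)
  rec <- recover_missing_exon1(h[1, ], pl$genome, ref)
  total_aa <- sum(rec$exons[, 2] - rec$exons[, 1]) / 3 - 1
  # enumeration oracle over all (ATG, donor, acceptor) candidates: no valid
  # alternative lies closer to the reference length
  expect_lte(abs(total_aa - nchar(pl$prot)),
             0.2 * nchar(pl$prot))
  expect_equal(total_aa, nchar(pl$prot))
})

test_that("at most one intron is kept; extra calls flag the model", {
  calls <- list("a", "b")
  capped <- cap_one_intron(calls)
  expect_true(capped$flagged)
  expect_equal(capped$call, "a")
  one <- cap_one_intron(list("a"))
  expect_false(one$flagged)
  expect_equal(one$call, "a")
  none <- cap_one_intron(list())
  expect_false(none$flagged)
  expect_null(none$call)
})

test_that("a two-intron planted gene yields one intron plus a manual-check
          flag end to end", {
  set.seed(12)
  prot <- random_aa(300)
  cds <- paste0(syntann:::back_translate(prot), "TAA")
  intr <- function() paste0("GTATGT", syntann:::random_dna(100), "ACTAAC",
                            syntann:::random_dna(12), "TAG")
  seq <- paste0(syntann:::random_dna(297), "TAA",
                substr(cds, 1, 270), intr(),
                substr(cds, 271, 600), intr(),
                substr(cds, 601, nchar(cds)),
                syntann:::random_dna(300))
  g <- genome(c(s1 = seq))
  db <- list(pillars = list(P1 = two_member_pillar("P1", prot,
                                                   has_intron = TRUE)),
             ancestral_order = list(chrA = "P1"))
  res <- run_pipeline(g, db, prefix = "T", wgd = "non")
  df <- models_to_df(res$models)
  expect_lte(max(df$n_exons), 2L)
  expect_true(any(grepl("manual-check", df$tags)))
})

test_that("spliced CDS of untagged intron models translates stop-free and
          ends at a stop", {
  sh <- shared_fixture()
  for (m in sh$res$models) {
    if (nrow(m$exons) != 2L || length(m$tags)) next
    aa <- translate_dna(model_cds(m, sh$res$genome))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})
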