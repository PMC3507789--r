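# Translated search, tabular parsing, and the hit-retention rules.

test_that("tabular hits normalize orientation, drop weak rows, and error on
          malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  row <- function(...) paste(..., sep = "\t")
  writeLines(c(
    row("q1", "s1", 95.0, 50, 2, 1, 50, 101, 250, 1, "1e-40", 120.5),
    row("q1", "s1", 90.0, 50, 5, 1, 50, 250, 101, 2, "1e-60", 150.0),
    row("q2", "s1", 80.0, 40, 8, 5, 44, 11, 130, 0, "1e-4", 35.0)), f)
  h <- parse_search_tabular(f, max_evalue = 1e-5)
  expect_equal(nrow(h), 2L)             # the 1e-4 row is below the cutoff
  expect_equal(h$strand, c("+", "-"))
  expect_equal(h$sstart, c(100, 100))   # both normalized to forward strand
  expect_equal(h$send, c(250, 250))

  writeLines("q1\ts1\tbroken", f)
  expect_error(parse_search_tabular(f), "line 1")
  writeLines(row("q1", "s1", 95, 50, 2, 60, 50, 101, 250, 1, "1e-40", 120),
             f)
  expect_error(parse_search_tabular(f), "line 1")
  writeLines(character(0), f)
  expect_equal(nrow(parse_search_tabular(f)), 0L)
})

test_that("parse -> serialize -> parse is lossless for retained fields", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("q1", "s1", 95.0, 50, 2, 1, 50, 101, 250, 1, "1e-40", 120.5,
          sep = "\t"),
    paste("q1", "s2", 90.0, 50, 5, 3, 52, 250, 101, 2, "1e-60", 150.25,
          sep = "\t")), f)
  h1 <- parse_search_tabular(f)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_search_tabular(h1, f2)
  h2 <- parse_search_tabular(f2)
  keep <- c("query_id", "scaffold", "qstart", "qend", "sstart", "send",
            "strand", "frame", "evalue", "bitscore")
  expect_equal(h2[keep], h1[keep])
})

test_that("built-in search finds an embedded protein at its true locus on
          either strand and stays silent on absent proteins", {
  set.seed(9)
  prot <- random_aa(150)
  cds <- syntann:::back_translate(prot)
  pad5 <- syntann:::random_dna(400)
  g <- genome(c(s1 = paste0(pad5, cds, syntann:::random_dna(350))))
  h <- builtin_translated_search(c(q = prot), g)
  expect_gte(nrow(h), 1L)
  top <- h[1, ]
  expect_equal(top$strand, "+")
  expect_gte((top$qend - top$qstart + 1) / nchar(prot), 0.95)
  expect_equal(top$sstart, 400)
  expect_equal(top$send, 400 + nchar(cds))

  g2 <- genome(c(s1 = revcomp(g$sequences$s1)))
  h2 <- builtin_translated_search(c(q = prot), g2)
  expect_equal(h2$strand[1], "-")
  expect_equal(h2$send[1] - h2$sstart[1], nchar(cds))
  expect_equal(translate_dna(revcomp(
    syntann:::subseq0(g2$sequences$s1, h2$sstart[1], h2$send[1]))), prot)

  absent <- random_aa(150)
  h3 <- builtin_translated_search(c(q = absent),
                                  genome(c(s1 = syntann:::random_dna(20000))))
  expect_equal(nrow(h3), 0L)
})

test_that("self-hit ranks the true locus first among paralogous copies", {
  set.seed(10)
  prot <- random_aa(120)
  near <- syntann:::mutate_protein(prot, 0.25)
  g <- genome(c(s1 = paste0(
    syntann:::random_dna(200), syntann:::back_translate(prot),
    syntann:::random_dna(500), syntann:::back_translate(near),
    syntann:::random_dna(200))))
  h <- builtin_translated_search(c(q = prot), g)
  expect_gte(nrow(h), 2L)
  expect_equal(h$sstart[1], 200)   # sorted by E-value: exact copy first
})

test_that("best query per pillar follows E-value, then bit score, then
          gene id, and reports pillars without hits", {
  p <- pillar("P1", list(
    ref_gene("gA", "postA", "post-WGD", "MKLV"),
    ref_gene("gB", "postB", "post-WGD", "MKLV"),
    ref_gene("gC", "nonA", "non-WGD", "MKLV")))
  h <- rbind(hsp_row("gA", evalue = 1e-80, bitscore = 300),
             hsp_row("gB", evalue = 1e-60, bitscore = 500))
  expect_equal(best_query_for_pillar(p, h)$query_id, "gA")

  h2 <- rbind(hsp_row("gA", evalue = 0, bitscore = 700),
              hsp_row("gB", evalue = 0, bitscore = 900))
  expect_equal(best_query_for_pillar(p, h2)$query_id, "gB")

  h3 <- rbind(hsp_row("gB", evalue = 0, bitscore = 900),
              hsp_row("gA", evalue = 0, bitscore = 900))
  expect_equal(best_query_for_pillar(p, h3)$query_id, "gA")

  none <- best_query_for_pillar(p, hsp_row("other"))
  expect_true(is.na(none$query_id))
})

test_that("the exponent-halving retention rule reproduces the worked
          example and an exhaustive truth table", {
  # strongest hit 1e-100: secondaries retained iff E < 1e-50
  expect_true(secondary_retained(1e-51, 1e-100))
  expect_false(secondary_retained(1e-49, 1e-100))
  # independent truth-table evaluation over the exponent grid (normal
  # double range; exact zero is covered separately)
  for (be in c(-20L, -40L, -60L, -100L, -200L, -300L)) {
    for (se in seq(-300L, -1L, by = 7L)) {
      expected <- (se < -30) && (se < be / 2)
      expect_equal(unname(secondary_retained(10^se, 10^be)), expected,
                   info = sprintf("sec=1e%d best=1e%d", se, be))
    }
  }
  # E = 0.0 maps to exponent -324 and always passes the halved-exponent gate
  expect_equal(exponent10(0), -324L)
  expect_true(secondary_retained(0, 1e-100))
  expect_equal(exponent10(c(1e-50, 3e-7, 0.5)), c(-50L, -7L, -1L))
})

test_that("retention is monotone: lowering a secondary E-value never flips
          kept to dropped", {
  set.seed(11)
  for (i in 1:200) {
    be <- -sample(10:324, 1)
    se <- -sample(1:324, 1)
    kept <- secondary_retained(10^se, 10^be)
    stronger <- secondary_retained(10^(se - sample(1:40, 1)), 10^be)
    if (kept) expect_true(stronger)
  }
})

test_that("locus clustering joins HSPs within the gap and separates tandem
          spacings beyond it", {
  h <- rbind(hsp_row(sstart = 1000, send = 1300, evalue = 1e-40),
             hsp_row(sstart = 1500, send = 1800, evalue = 1e-60),
             hsp_row(sstart = 60000, send = 60300, evalue = 1e-20))
  loci <- cluster_hsps_to_loci(h, max_gap_nt = 5000)
  expect_length(loci, 2L)
  expect_equal(loci[[1]]$evalue, 1e-60)   # locus E is the member minimum
  expect_equal(loci[[1]]$start, 1000)
  expect_equal(loci[[1]]$end, 1800)

  # sweep: two HSPs merge iff their spacing is at most the gap
  for (gap in c(100, 4999, 5000, 5001, 20000)) {
    h2 <- rbind(hsp_row(sstart = 0, send = 300),
                hsp_row(sstart = 300 + gap, send = 600 + gap))
    expect_length(cluster_hsps_to_loci(h2, max_gap_nt = 5000),
                  if (gap <= 5000) 1L else 2L)
  }
  # opposite strands never share a locus
  h3 <- rbind(hsp_row(sstart = 0, send = 300, strand = "+"),
              hsp_row(sstart = 350, send = 650, strand = "-"))
  expect_length(cluster_hsps_to_loci(h3), 2L)
})

test_that("retain_secondary_loci always keeps the strongest locus", {
  loci <- list(list(evalue = 1e-20), list(evalue = 1e-25),
               list(evalue = 1e-22))
  kept <- retain_secondary_loci(loci, 1e-25)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$evalue, 1e-25)
})
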