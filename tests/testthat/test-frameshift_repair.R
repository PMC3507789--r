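# Frameshift window extraction, indel voting, ORF-tested application, and
# N-placeholder patching.

test_that("the frameshift window spans 50 bp around the inter-HSP gap and
          clamps at scaffold bounds", {
  g <- genome(c(s1 = strrep("A", 1000)))
  h1 <- hsp_row(sstart = 40, send = 100)
  h2 <- hsp_row(sstart = 130, send = 200)
  w <- extract_fs_window(h1, h2, g)
  expect_equal(c(w$start, w$end), c(50, 180))
  expect_equal(w$end - w$start, (130 - 100) + 100)
  # genomic order is established internally
  w2 <- extract_fs_window(h2, h1, g)
  expect_equal(c(w2$start, w2$end), c(50, 180))
  # clamping at the scaffold start
  h0 <- hsp_row(sstart = 0, send = 30)
  w3 <- extract_fs_window(h0, h2, g)
  expect_equal(w3$start, 0)
})

test_that("indel votes count supporting reads, require two of them, and
          sort by support then offset", {
  set.seed(20)
  true_seq <- syntann:::random_dna(400)
  # assembly window deletes one base at offset 170 relative to the truth
  window <- paste0(substr(true_seq, 101, 270), substr(true_seq, 272, 300))
  reads <- setNames(
    c(replicate(5, substr(true_seq, 81, 320)),    # support the insertion
      substr(true_seq, 81, 250)),                 # clean read, not over indel
    c(sprintf("r%d/1", 1:5), "clean/1"))
  v <- vote_indels(window, reads)
  expect_gte(nrow(v), 1L)
  expect_equal(v$op[1], "insert")
  expect_equal(v$support[1], 5L)
  ins_base <- substr(true_seq, 271, 271)
  expect_equal(v$bases[1], ins_base)
  # the reverse-complemented read set votes identically
  rc_reads <- setNames(vapply(reads[1:5], revcomp, character(1)),
                       names(reads)[1:5])
  v2 <- vote_indels(window, rc_reads)
  expect_equal(v2[1, c("offset", "op", "bases", "support")],
               v[1, c("offset", "op", "bases", "support")])
  # a single supporting read is excluded
  v3 <- vote_indels(window, reads[1])
  expect_equal(nrow(v3), 0L)
  # no qualifying reads at all
  expect_equal(nrow(vote_indels(window, character(0))), 0L)
})

test_that("indel positions are normalized to the leftmost placement in a
          homopolymer run", {
  seqv <- "ACGTTTTTACG"
  expect_equal(normalize_indel_pos(seqv, 7, "insert", "T"), 3)
  expect_equal(normalize_indel_pos(seqv, 7, "delete", "T"), 3)
  expect_equal(normalize_indel_pos(seqv, 1, "insert", "G"), 1)
  expect_equal(normalize_indel_pos(seqv, 0, "delete", "A"), 0)
})

test_that("the first vote creating an intact ORF is applied; failures fall
          through to the next vote or to no correction", {
  set.seed(21)
  prot <- random_aa(120)
  cds <- syntann:::back_translate(prot)
  pre <- paste0(syntann:::random_dna(197), "TAA")
  # delete one base mid-gene to break the frame
  broken <- paste0(pre, substr(cds, 1, 180), substr(cds, 182, nchar(cds)),
                   "TAA", syntann:::random_dna(200))
  g <- genome(c(s1 = broken))
  h <- builtin_translated_search(c(q = prot), g)
  h <- h[order(h$sstart), ]
  expect_equal(nrow(h), 2L)
  cl <- classify_hsp_pair(h[1, ], h[2, ], FALSE, genome = g)
  expect_equal(cl$kind, "frameshift")
  win <- extract_fs_window(h[1, ], h[2, ], g)
  ctx <- list(genome = g, window = win, h1 = h[1, ], h2 = h[2, ])
  deleted <- substr(cds, 181, 181)
  good_off <- 200 + 180 - win$start
  cands <- data.frame(
    offset = c(10, good_off), op = c("delete", "insert"),
    bases = c(substr(win$seq, 11, 11), deleted), support = c(9L, 5L),
    stringsAsFactors = FALSE)
  co <- apply_first_fixing_indel(cands, ctx)
  expect_false(is.null(co))
  expect_equal(co$op, "insert")          # the top vote fails the ORF test
  expect_equal(co$read_support, 5L)
  fixed <- write_corrected_scaffolds(g, list(co))
  h2 <- builtin_translated_search(c(q = prot), fixed)
  expect_equal(nrow(h2), 1L)             # frame restored: one clean HSP
  # all candidates failing: no correction
  expect_null(apply_first_fixing_indel(cands[1, ], ctx))
  expect_null(apply_first_fixing_indel(cands[integer(0), ], ctx))
})

test_that("N-placeholder insertion restores the frame for every offset
          (modular-arithmetic oracle)", {
  g <- genome(c(s1 = strrep("ACGT", 300)))
  for (ds in c(91, 92, 94, 95, 151, 203)) {
    h1 <- hsp_row(sstart = 102, send = 300)
    h2 <- hsp_row(sstart = 300 + ds, send = 600 + ds)
    d <- ds %% 3
    if (d == 0) {
      expect_error(insert_placeholder_Ns(h1, h2, g), "not frame-shifted")
      next
    }
    co <- insert_placeholder_Ns(h1, h2, g)
    expect_equal(nchar(co$bases), (3 - d) %% 3)
    expect_true(grepl("^N+$", co$bases))
    expect_true(co$applied)
    expect_gte(co$position, h1$send)
    expect_lte(co$position, h2$sstart)
    # oracle: the new gap is a codon multiple
    expect_equal((ds + nchar(co$bases)) %% 3, 0)
    # the insertion site is codon-aligned with the upstream HSP frame
    expect_equal((co$position - h1$sstart) %% 3, 0)
  }
})

test_that("read-voting repair reverses planted indels exactly and re-running
          detection on the fixed assembly finds nothing", {
  spec <- fixture_spec(seed = 23, n_pillars = 15, frameshift_count = 6,
                       read_coverage = 20)
  fix <- make_fixture(spec)
  res <- run_pipeline(fix$genome, fix$db, prefix = "FS", wgd = "non",
                      fix_frameshifts = "reads", reads = fix$reads)
  key <- function(d) paste(d$scaffold, d$position, d$op, d$bases)
  co <- do.call(rbind, lapply(res$corrections, function(c)
    data.frame(scaffold = c$scaffold_id, position = c$position, op = c$op,
               bases = c$bases, stringsAsFactors = FALSE)))
  expect_gte(sum(key(fix$truth_edits) %in% key(co)),
             nrow(fix$truth_edits) - 1L)
  # re-annotation of the corrected assembly is part of run_pipeline: its
  # final models carry corrected tags and no uncorrected ones
  df <- models_to_df(res$models)
  expect_equal(sum(grepl("frameshift-uncorrected", df$tags)), 0L)
  expect_gte(sum(grepl("frameshift-corrected", df$tags)), 5L)
  # corrected CDS translate cleanly
  for (m in res$models[grepl("frameshift-corrected",
                             models_to_df(res$models)$tags)]) {
    aa <- translate_dna(model_cds(m, res$genome))
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("disabling correction yields the same detections but tags instead
          of edits", {
  spec <- fixture_spec(seed = 24, n_pillars = 12, frameshift_count = 4,
                       read_coverage = 20)
  fix <- make_fixture(spec)
  on <- run_pipeline(fix$genome, fix$db, prefix = "A", wgd = "non",
                     fix_frameshifts = "reads", reads = fix$reads)
  off <- run_pipeline(fix$genome, fix$db, prefix = "A", wgd = "non",
                      fix_frameshifts = "off", reads = fix$reads)
  expect_length(off$corrections, 0L)
  expect_equal(length(off$detected_frameshifts),
               length(on$detected_frameshifts))
  dfo <- models_to_df(off$models)
  expect_equal(sum(grepl("frameshift-uncorrected", dfo$tags)),
               length(off$detected_frameshifts))
})
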