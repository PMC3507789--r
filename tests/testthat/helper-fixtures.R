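# Shared helpers for the test suite. Fixtures are generated in code under
# fixed seeds; nothing is read from disk.

# exon-structure key for exact-coordinate comparison of model lists
structure_keys <- function(models) {
  vapply(models, function(m)
    paste(m$scaffold_id, m$strand, paste(t(m$exons), collapse = ","),
          sep = "|"),
    character(1))
}

# a one-row HSP data.frame with sensible defaults
hsp_row <- function(query_id = "q", scaffold = "s1", qstart = 1L,
                    qend = 50L, sstart = 0, send = 150, strand = "+",
                    frame = 0L, evalue = 1e-50, bitscore = 100,
                    score = 200) {
  data.frame(query_id = query_id, scaffold = scaffold, qstart = qstart,
             qend = qend, sstart = sstart, send = send, strand = strand,
             frame = frame, evalue = evalue, bitscore = bitscore,
             score = score, stringsAsFactors = FALSE)
}

# small pillar with one member per species group
two_member_pillar <- function(pid, prot, has_intron = FALSE) {
  ec <- if (has_intron) 2L else 1L
  pillar(pid, list(
    ref_gene(paste0("postA_", pid), "postA", "post-WGD", prot,
             exon_count = ec),
    ref_gene(paste0("nonA_", pid), "nonA", "non-WGD", prot,
             exon_count = ec)),
    ancestral_locus = pid)
}

random_aa <- function(n) {
  paste0("M", paste(sample(syntann:::AA20, n - 1L, replace = TRUE),
                    collapse = ""))
}

# one mid-size annotated fixture shared by several test files (computed once
# per test run)
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(seed = 101, n_pillars = 30, divergence = 0.1,
                           intron_fraction = 0.1)
      fix <- make_fixture(spec)
      res <- run_pipeline(fix$genome, fix$db, prefix = "SHR", wgd = "non")
      cache <<- list(fix = fix, res = res)
    }
    cache
  }
})
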