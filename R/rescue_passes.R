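# Post-annotation rescue passes: a thresholdless search for divergent genes
# in syntenic gaps, a sweep for unannotated large ORFs, and propagation of
# retrotransposon (Ty) flags. These passes only add tagged models (or tags);
# they never delete previously accepted models.

#' Find maximal ORFs in a genome
#'
#' Maximal ATG-to-stop open reading frames in all six frames. ORF length is
#' counted in amino acids excluding the stop codon; ORFs running off a
#' scaffold end without a stop are not reported.
#'
#' @param genome a [genome()]
#' @param min_len_aa minimum length (aa, stop excluded)
#' @return data.frame(scaffold, strand, start, end) with 0-based half-open
#'   forward-strand coords (end includes the stop codon)
#' @export
find_orfs <- function(genome, min_len_aa = 150L) {
  rows <- list()
  for (sc in names(genome$sequences)) {
    fwd <- genome$sequences[[sc]]
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      cseq <- if (strand == "+") fwd else revcomp(fwd)
      for (f in 0:2) {
        starts <- seq.int(f, L - 3L, by = 3L)
        if (length(starts) == 0L) next
        cods <- substring(cseq, starts + 1L, starts + 3L)
        stop_i <- which(cods %in% STOP_CODONS)
        atg_i <- which(cods == "ATG")
        prev <- 0L
        for (s in stop_i) {
          a <- atg_i[atg_i > prev & atg_i < s]
          if (length(a)) {
            a <- a[1]
            if (s - a >= min_len_aa) {
              cs <- starts[a]; ce <- starts[s] + 3L
              if (strand == "+")
                rows[[length(rows) + 1L]] <- data.frame(
                  scaffold = sc, strand = strand, start = cs, end = ce,
                  stringsAsFactors = FALSE)
              else
                rows[[length(rows) + 1L]] <- data.frame(
                  scaffold = sc, strand = strand, start = L - ce,
                  end = L - cs, stringsAsFactors = FALSE)
            }
          }
          prev <- s
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(scaffold = character(0), strand = character(0),
                      start = numeric(0), end = numeric(0)))
  do.call(rbind, rows)
}

# strand-agnostic interval overlap against a feature table
overlaps_features <- function(scaffold, start, end, features) {
  if (is.null(features) || nrow(features) == 0L) return(FALSE)
  any(features$scaffold == scaffold & features$start < end &
      features$end > start)
}

#' Sweep for large unannotated ORFs
#'
#' Emits every maximal ORF of at least `min_len_aa` amino acids that does
#' not overlap any existing feature on either strand, as a singleton model
#' tagged `large-orf`.
#'
#' @param genome a [genome()]
#' @param existing_features data.frame(scaffold, start, end) of occupied
#'   intervals (gene models and tRNAs, both strands pooled)
#' @param min_len_aa length threshold (aa, stop codon excluded)
#' @param prefix model-id prefix
#' @return list of [gene_model()] tagged `large-orf`
#' @export
find_large_orfs <- function(genome, existing_features, min_len_aa = 150L,
                            prefix = "ORF") {
  orfs <- find_orfs(genome, min_len_aa)
  out <- list()
  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i, ]
    if (overlaps_features(o$scaffold, o$start, o$end, existing_features))
      next
    out[[length(out) + 1L]] <- gene_model(
      sprintf("%s%03d", prefix, length(out) + 1L), o$scaffold, o$strand,
      matrix(c(o$start, o$end), ncol = 2), tags = "large-orf",
      evidence = "unresolved-singleton")
  }
  out
}

#' Thresholdless rescue of divergent genes in syntenic gaps
#'
#' For every ancestral locus whose two nearest ancestral neighbors are both
#' mapped to the same scaffold but which itself is unannotated, the pillar's
#' intronless member proteins are aligned against the intergenic gap alone,
#' with no E-value threshold. The best hit is extended to an ATG-to-stop
#' ORF; it is emitted (tagged `searchdogs`, assigned to the pillar) when it
#' reaches `min_codons` and covers at least `min_coverage` of the shortest
#' member protein, and does not overlap a tRNA or existing model.
#' Intron-bearing pillar candidates are skipped.
#'
#' @param assignments assignment data.frame from [assign_loci_to_pillars()]
#' @param db pillar database from [read_pillar_db()]
#' @param genome a [genome()]
#' @param existing_features data.frame(scaffold, start, end) of occupied
#'   intervals (models plus tRNA track)
#' @param min_codons minimum rescued ORF length (codons)
#' @param min_coverage minimum query coverage of the shortest member
#' @param max_gap_nt ignore gaps wider than this
#' @param prefix model-id prefix
#' @return list(models, assignments) -- rescued [gene_model()]s (tagged
#'   `searchdogs`) and their assignment rows
#' @export
syntenic_gap_search <- function(assignments, db, genome, existing_features,
                                min_codons = 30L, min_coverage = 0.5,
                                max_gap_nt = 20000L, prefix = "SDG") {
  assigned_pillars <- assignments$pillar_id[!is.na(assignments$pillar_id)]
  models <- list()
  new_rows <- list()
  for (chr in names(db$ancestral_order)) {
    ord <- db$ancestral_order[[chr]]
    for (i in seq_along(ord)) {
      pid <- ord[i]
      if (pid %in% assigned_pillars) next
      if (i == 1L || i == length(ord)) next
      left <- assignments[!is.na(assignments$pillar_id) &
                          assignments$pillar_id == ord[i - 1L], ,
                          drop = FALSE]
      right <- assignments[!is.na(assignments$pillar_id) &
                           assignments$pillar_id == ord[i + 1L], ,
                           drop = FALSE]
      if (nrow(left) == 0L || nrow(right) == 0L) next
      found <- NULL
      for (a in seq_len(nrow(left))) for (b in seq_len(nrow(right))) {
        if (left$scaffold[a] != right$scaffold[b]) next
        lo <- min(left$end[a], right$end[b])
        hi <- max(left$start[a], right$start[b])
        if (hi - lo <= 0 || hi - lo > max_gap_nt) next
        found <- list(scaffold = left$scaffold[a], lo = lo, hi = hi)
        break
      }
      if (is.null(found)) next
      p <- db$pillars[[pid]]
      if (is.null(p)) next
      cands <- Filter(function(m) !m$has_intron, p$members)
      if (!length(cands)) next
      prots <- setNames(vapply(cands, `[[`, character(1), "protein"),
                        vapply(cands, `[[`, character(1), "gene_id"))
      gap_seq <- subseq0(genome$sequences[[found$scaffold]], found$lo,
                         found$hi)
      if (nchar(gap_seq) < 3L * min_codons) next
      h <- best_local_protein_hit(prots, gap_seq)
      if (is.null(h)) next
      shortest <- min(nchar(prots))
      if ((h$qend - h$qstart + 1L) < min_coverage * shortest) next
      ext <- tryCatch(
        extend_to_start_stop(h$sstart, h$send, gap_seq, h$strand),
        error = function(e) NULL)
      if (is.null(ext) || length(ext$tags)) next
      if ((ext$end - ext$start) / 3 - 1L < min_codons) next
      g_start <- found$lo + ext$start
      g_end <- found$lo + ext$end
      if (overlaps_features(found$scaffold, g_start, g_end,
                            existing_features))
        next
      mid <- sprintf("%s%03d", prefix, length(models) + 1L)
      models[[length(models) + 1L]] <- gene_model(
        mid, found$scaffold, h$strand,
        matrix(c(g_start, g_end), ncol = 2), pillar_id = pid,
        tags = "searchdogs", source_ref_gene = h$query_id,
        evidence = "synteny-resolved", evalue = h$evalue)
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        locus_id = mid, scaffold = found$scaffold, strand = h$strand,
        start = g_start, end = g_end, pillar_id = pid,
        query_id = h$query_id, evalue = h$evalue,
        evidence = "synteny-resolved", stringsAsFactors = FALSE)
      assigned_pillars <- c(assigned_pillars, pid)
      existing_features <- rbind(existing_features,
                                 data.frame(scaffold = found$scaffold,
                                            start = g_start, end = g_end))
    }
  }
  list(models = models,
       assignments = if (length(new_rows)) do.call(rbind, new_rows)
                     else NULL)
}

# Exhaustive (thresholdless) local alignment of protein queries against a
# short DNA segment: Smith-Waterman on all six frame translations. Returns
# the best hit as a one-row HSP-like data.frame in segment coordinates, or
# NULL when nothing aligns with a positive score. Used only for the
# syntenic-gap pass, where the search space is one intergenic gap and
# seed-based heuristics would miss highly diverged genes.
best_local_protein_hit <- function(prots, segment) {
  tr <- six_frame_translate(genome(c(gap = segment)))
  best <- NULL
  for (qi in seq_along(prots)) {
    q <- Biostrings::AAString(prots[[qi]])
    for (s in seq_along(tr$aa)) {
      if (nchar(tr$aa[s]) < 5L) next
      aln <- Biostrings::pairwiseAlignment(
        q, Biostrings::AAString(tr$aa[s]), type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(aln)
      if (sc <= 0) next
      if (is.null(best) || sc > best$score) {
        meta <- tr$meta[s, ]
        nt <- frame_aa_to_nt(
          Biostrings::start(Biostrings::subject(aln)) - 1L,
          Biostrings::end(Biostrings::subject(aln)),
          meta$strand, meta$frame, meta$scaffold_length)
        best <- data.frame(
          query_id = names(prots)[qi], scaffold = "gap",
          qstart = Biostrings::start(Biostrings::pattern(aln)),
          qend = Biostrings::end(Biostrings::pattern(aln)),
          sstart = nt[1], send = nt[2], strand = meta$strand,
          frame = meta$frame, evalue = karlin_altschul_evalue(
            raw_to_bitscore(sc), nchar(prots[[qi]]), sum(nchar(tr$aa))),
          bitscore = raw_to_bitscore(sc), score = sc,
          stringsAsFactors = FALSE)
      }
    }
  }
  best
}

#' Propagate retrotransposon flags onto models
#'
#' Any model whose span is hit by a Ty-labelled reference gene at
#' `E < max_evalue` is tagged `ty` and detached from the pillar system (left
#' as a singleton), mirroring how reference databases keep retrotransposon
#' genes out of ortholog pillars. No attempt is made to resolve the detailed
#' structure of the elements.
#'
#' @param models list of [gene_model()]
#' @param ty_hits HSP data.frame of Ty-labelled reference queries
#' @param max_evalue flagging threshold
#' @return models with `ty` tags applied
#' @export
propagate_ty_flags <- function(models, ty_hits, max_evalue = 1e-5) {
  if (is.null(ty_hits) || nrow(ty_hits) == 0L) return(models)
  strong <- ty_hits[ty_hits$evalue < max_evalue, , drop = FALSE]
  lapply(models, function(m) {
    sp <- model_span(m)
    hit <- any(strong$scaffold == m$scaffold_id &
               strong$sstart < sp[2] & strong$send > sp[1])
    if (hit) {
      m$tags <- unique(c(m$tags, "ty"))
      m$pillar_id <- NA_character_
      m$evidence <- "unresolved-singleton"
    }
    m
  })
}
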