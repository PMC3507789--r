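# Pipeline orchestration: homology search, pillar mapping, gene modeling
# with intron prediction, frameshift detection/repair with one re-annotation
# round, rescue passes, and output writing.

#' Default pipeline options
#'
#' @param max_evalue initial translated-search cutoff
#' @param max_gap_nt locus clustering gap
#' @param gap_tol,overlap_tol,min_intron HSP-pair classifier tolerances
#' @param radius synteny neighbor scan radius
#' @param cap_start_extension bound upstream start extension at three times
#'   the mean group protein length (switchable interpretation)
#' @param len_tol relative protein-length tolerance for exon-1 recovery
#' @param min_orf_aa large-ORF sweep threshold
#' @param rescue run the syntenic-gap and large-ORF rescue passes
#' @return list of options
#' @export
pipeline_options <- function(max_evalue = 1e-5, max_gap_nt = 5000,
                             gap_tol = 30, overlap_tol = 15,
                             min_intron = 40, radius = 10L,
                             cap_start_extension = TRUE, len_tol = 0.2,
                             min_orf_aa = 150L, rescue = TRUE) {
  as.list(environment())
}

# gene-id -> pillar-id lookup
member_pillar_map <- function(db) {
  out <- character(0)
  for (p in db$pillars)
    out[vapply(p$members, `[[`, character(1), "gene_id")] <- p$pillar_id
  out
}

all_member_proteins <- function(db, ty = FALSE) {
  prots <- character(0)
  for (p in db$pillars) for (m in p$members) {
    if (m$is_ty == ty) prots[m$gene_id] <- m$protein
  }
  prots
}

#' Per-pillar candidate loci from the HSP table
#'
#' For each non-Ty pillar: identify the member (Q) whose best hit is
#' strongest, cluster Q's hits into loci, and keep the strongest locus plus
#' the secondaries passing the halved-exponent retention rule.
#'
#' @param db pillar database
#' @param hsps HSP data.frame
#' @param opts [pipeline_options()]
#' @return candidate data.frame (scaffold, strand, start, end, pillar_id,
#'   query_id, evalue)
#' @export
pillar_candidate_loci <- function(db, hsps, opts = pipeline_options()) {
  rows <- list()
  for (p in db$pillars) {
    if (any(vapply(p$members, `[[`, logical(1), "is_ty"))) next
    bq <- best_query_for_pillar(p, hsps)
    if (is.na(bq$query_id)) next
    qh <- hsps[hsps$query_id == bq$query_id, , drop = FALSE]
    loci <- cluster_hsps_to_loci(qh, max_gap_nt = opts$max_gap_nt)
    loci <- retain_secondary_loci(loci, bq$evalue)
    for (lc in loci)
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = lc$scaffold, strand = lc$strand, start = lc$start,
        end = lc$end, pillar_id = p$pillar_id, query_id = bq$query_id,
        evalue = lc$evalue, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(scaffold = character(0), strand = character(0),
                  start = numeric(0), end = numeric(0),
                  pillar_id = character(0), query_id = character(0),
                  evalue = numeric(0), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Per-locus model construction

# coding-strand coordinate helpers
to_coding <- function(x, L, strand) if (strand == "+") x else L - x

build_models_for_locus <- function(arow, db, gene2pillar, hsps, genome,
                                   wgd_group, opts) {
  pid <- arow$pillar_id
  base_pid <- if (!is.na(pid)) sub("\\.tandem\\d+$", "", pid) else
    unname(gene2pillar[arow$query_id])
  pil <- db$pillars[[base_pid]]
  if (is.null(pil)) return(NULL)
  member_ids <- vapply(pil$members, `[[`, character(1), "gene_id")
  at_locus <- hsps[hsps$query_id %in% member_ids &
                   hsps$scaffold == arow$scaffold &
                   hsps$strand == arow$strand &
                   hsps$sstart < arow$end & hsps$send > arow$start, ,
                   drop = FALSE]
  if (nrow(at_locus) == 0L) return(NULL)
  o <- order(at_locus$evalue, -at_locus$bitscore)
  ranking <- at_locus[o, , drop = FALSE]
  ranking <- ranking[!duplicated(ranking$query_id), c("query_id", "evalue",
                                                      "bitscore")]
  names(ranking)[1] <- "gene_id"
  R <- select_reference_gene(pil, wgd_group, ranking)
  rh <- at_locus[at_locus$query_id == R$gene_id, , drop = FALSE]
  if (nrow(rh) == 0L) {   # reference never hit this locus: use best member
    R <- pil$members[[match(ranking$gene_id[1], member_ids)]]
    rh <- at_locus[at_locus$query_id == R$gene_id, , drop = FALSE]
  }
  minus <- arow$strand == "-"
  rh <- rh[order(if (minus) -rh$sstart else rh$sstart), , drop = FALSE]
  rh <- drop_contained_hsps(rh)

  grp_members <- Filter(function(m) m$species_group == wgd_group,
                        pil$members)
  intron_allowed <- any(vapply(grp_members, `[[`, logical(1), "has_intron"))
  calls <- list()
  if (nrow(rh) > 1L) {
    for (i in seq_len(nrow(rh) - 1L))
      calls[[i]] <- classify_hsp_pair(rh[i, ], rh[i + 1L, ], intron_allowed,
                                      genome, gap_tol = opts$gap_tol,
                                      overlap_tol = opts$overlap_tol,
                                      min_intron = opts$min_intron)
  }
  groups <- seed_coordinates(rh, calls)
  lens <- mean_group_lengths(pil)
  cap <- if (opts$cap_start_extension) {
    ml <- lens[[wgd_group]]
    if (is.na(ml)) ml <- mean(lens, na.rm = TRUE)
    3 * 3 * ml
  } else Inf
  out <- list()
  for (g in groups) {
    m <- build_group_model(g, rh, pil, R, arow, genome, cap, opts)
    if (!is.null(m)) out[[length(out) + 1L]] <- m
  }
  out
}

# remove HSPs whose query interval is contained in another HSP's (weaker
# shadow alignments in other frames)
drop_contained_hsps <- function(rh) {
  if (nrow(rh) < 2L) return(rh)
  keep <- rep(TRUE, nrow(rh))
  for (i in seq_len(nrow(rh))) {
    for (j in seq_len(nrow(rh))) {
      if (i == j || !keep[j]) next
      if (rh$sstart[i] >= rh$sstart[j] && rh$send[i] <= rh$send[j] &&
          rh$score[i] <= rh$score[j] && keep[i] && i != j) {
        if (!(rh$sstart[i] == rh$sstart[j] && rh$send[i] == rh$send[j] &&
              i < j))
          keep[i] <- FALSE
      }
    }
  }
  rh[keep, , drop = FALSE]
}

build_group_model <- function(group, rh, pil, R, arow, genome, cap, opts) {
  seq <- genome$sequences[[arow$scaffold]]
  L <- nchar(seq)
  strand <- arow$strand
  minus <- strand == "-"
  cseq <- if (minus) revcomp(seq) else seq
  seed_cs <- to_coding(if (minus) group$end else group$start, L, strand)
  seed_ce <- to_coding(if (minus) group$start else group$end, L, strand)
  kinds <- vapply(group$calls, `[[`, character(1), "kind")
  fs_idx <- which(kinds == "frameshift")
  intr_idx <- which(kinds == "intron")
  tags <- character(0)
  fs_calls <- list()
  exons_c <- NULL    # coding-strand exon matrix

  if (length(fs_idx)) {
    # frame is broken: keep the seed span, extend only the start in the
    # frame of the 5' coding HSP; translation invariants are waived by tag
    st <- extend_start_coding(cseq, seed_cs, cap)
    exons_c <- matrix(c(st$start, seed_ce), ncol = 2)
    tags <- unique(c(tags, st$tags, "frameshift-uncorrected"))
    if (length(fs_idx) > 1L || length(intr_idx))
      tags <- unique(c(tags, "manual-check"))
    for (i in fs_idx) {
      pr <- group$calls[[i]]$pair
      fs_calls[[length(fs_calls) + 1L]] <- list(h1 = pr$h1, h2 = pr$h2)
    }
  } else if (length(intr_idx)) {
    capres <- cap_one_intron(lapply(intr_idx,
                                    function(i) group$calls[[i]]))
    if (capres$flagged) tags <- c(tags, "manual-check")
    icall <- capres$call
    ic <- intron_between_hsps(icall$pair$h1, icall$pair$h2, genome,
                              intron_min = opts$min_intron)
    if (is.null(ic)) {
      st <- extend_start_coding(cseq, seed_cs, cap)
      exons_c <- matrix(c(st$start, seed_ce), ncol = 2)
      tags <- unique(c(tags, st$tags, "manual-check"))
    } else {
      fin <- finalize_intron_model(cseq, seed_cs, seed_ce, ic, L, strand,
                                   cap)
      exons_c <- fin$exons_c
      tags <- unique(c(tags, fin$tags))
      if (is.null(exons_c)) {
        st <- extend_start_coding(cseq, seed_cs, cap)
        exons_c <- matrix(c(st$start, seed_ce), ncol = 2)
        tags <- unique(c(tags, "manual-check"))
      }
    }
  } else {
    ext <- extend_to_start_stop(group$start, group$end, seq, strand,
                                max_extend_nt = cap)
    tags <- unique(c(tags, ext$tags))
    exons_f <- matrix(c(ext$start, ext$end), ncol = 2)
    # single HSP against an intron-bearing reference: the first exon may be
    # too short to seed a hit; try to recover it and keep whichever
    # interpretation better matches the reference protein length
    ref_len <- nchar(R$protein)
    pred_len <- (ext$end - ext$start) / 3 - 1
    bad_single <- "manual-check" %in% tags ||
      abs(pred_len - ref_len) > opts$len_tol * ref_len
    if (length(group$hsp_idx) == 1L && R$has_intron &&
        (bad_single || rh$qstart[group$hsp_idx] > 1L)) {
      rec <- recover_missing_exon1(rh[group$hsp_idx, ], genome, R,
                                   intron_min = opts$min_intron,
                                   len_tol = opts$len_tol)
      if (!is.null(rec)) {
        rec_len <- (sum(rec$exons[, 2] - rec$exons[, 1])) / 3 - 1
        if (bad_single || abs(rec_len - ref_len) < abs(pred_len - ref_len))
          return(finish_model(rec$exons, strand, arow, R, setdiff(
            tags, "manual-check"), fs_calls, intron = rec$intron))
      } else if (bad_single) tags <- unique(c(tags, "manual-check"))
    }
    return(finish_model(exons_f, strand, arow, R, tags, fs_calls))
  }
  # map coding exons back to forward coordinates
  exons_f <- if (minus)
    matrix(c(L - exons_c[, 2], L - exons_c[, 1]), ncol = 2)
  else exons_c
  finish_model(exons_f, strand, arow, R, tags, fs_calls)
}

finish_model <- function(exons_f, strand, arow, R, tags, fs_calls,
                         intron = NULL) {
  m <- gene_model(arow$locus_id, arow$scaffold, strand, exons_f,
                  pillar_id = arow$pillar_id, tags = tags,
                  source_ref_gene = R$gene_id, evidence = arow$evidence,
                  evalue = arow$evalue)
  m$fs_calls <- fs_calls
  m$intron <- intron
  m
}

# build the two exons of an intron model and extend start/stop through the
# spliced frame
finalize_intron_model <- function(cseq, seed_cs, seed_ce, ic, L, strand,
                                  cap) {
  d_c <- to_coding(if (strand == "+") ic$intron_start else ic$intron_end,
                   L, strand)
  a_c <- to_coding(if (strand == "+") ic$intron_end else ic$intron_start,
                   L, strand)
  if (d_c <= seed_cs || a_c >= seed_ce)
    return(list(exons_c = NULL, tags = "manual-check"))
  st <- extend_start_coding(cseq, seed_cs, cap)
  tags <- st$tags
  m <- st$start
  e1len <- d_c - m
  # walk spliced codons to the first stop
  sp <- extend_stop_spliced(cseq, m, d_c, a_c)
  tags <- unique(c(tags, sp$tags))
  e2end <- if (is.na(sp$end)) seed_ce else sp$end
  if (e2end <= a_c) return(list(exons_c = NULL, tags = "manual-check"))
  list(exons_c = matrix(c(m, d_c, a_c, e2end), ncol = 2, byrow = TRUE),
       tags = tags)
}

extend_stop_spliced <- function(cseq, m, d_c, a_c) {
  L <- nchar(cseq)
  spliced <- paste0(subseq0(cseq, m, d_c), subseq0(cseq, a_c, L))
  e1len <- d_c - m
  t <- 0L
  while (t + 3L <= nchar(spliced)) {
    cod <- substr(spliced, t + 1L, t + 3L)
    if (grepl("N", cod))
      return(list(end = NA_integer_, tags = "runs-into-N"))
    if (is_stop_codon(cod)) {
      end_spliced <- t + 3L
      return(list(end = a_c + (end_spliced - e1len), tags = character(0)))
    }
    t <- t + 3L
  }
  list(end = NA_integer_, tags = "manual-check")
}

# ---------------------------------------------------------------------------
# One annotation round

#' Annotate a genome once (no frameshift editing)
#'
#' Runs the homology search (unless `hits` are supplied), maps pillars to
#' loci, builds gene models with intron prediction, applies the rescue
#' passes and Ty flags, and removes protein models overlapping tRNA
#' features.
#'
#' @param genome a [genome()]
#' @param db pillar database from [read_pillar_db()]
#' @param wgd_mode `"post"` or `"non"`
#' @param trna optional tRNA track data.frame (see [read_trna_track()])
#' @param hits optional precomputed HSP data.frame (bypasses the built-in
#'   search)
#' @param opts [pipeline_options()]
#' @return list(models, assignments, fs_calls, hsps, counts)
#' @export
annotate_once <- function(genome, db, wgd_mode = c("post", "non"),
                          trna = NULL, hits = NULL,
                          opts = pipeline_options()) {
  wgd_mode <- match.arg(wgd_mode)
  wgd_group <- if (wgd_mode == "post") "post-WGD" else "non-WGD"
  prots <- all_member_proteins(db, ty = FALSE)
  ty_prots <- all_member_proteins(db, ty = TRUE)
  hsps <- if (!is.null(hits)) hits
    else builtin_translated_search(prots, genome,
                                   max_evalue = opts$max_evalue)
  ty_hits <- if (length(ty_prots))
    builtin_translated_search(ty_prots, genome,
                              max_evalue = opts$max_evalue)
    else NULL

  candidates <- pillar_candidate_loci(db, hsps, opts)
  assignments <- assign_loci_to_pillars(candidates, db$ancestral_order,
                                        wgd_mode, radius = opts$radius)
  gene2pillar <- member_pillar_map(db)
  models <- list()
  for (i in seq_len(nrow(assignments))) {
    ms <- build_models_for_locus(assignments[i, ], db, gene2pillar, hsps,
                                 genome, wgd_group, opts)
    for (k in seq_along(ms)) {
      m <- ms[[k]]
      if (length(ms) > 1L) m$model_id <- sprintf("%s.%d", m$model_id, k)
      models[[length(models) + 1L]] <- m
    }
  }
  # model-level assignment table; duplication splits may have created
  # adjacent same-pillar models that the tandem rule must separate
  mt <- model_table(models)
  mt <- handle_tandem_duplicates(mt, ancestral_index(db$ancestral_order),
                                 radius = opts$radius)
  for (i in seq_along(models)) {
    models[[i]]$pillar_id <- mt$pillar_id[i]
    models[[i]]$evidence <- mt$evidence[i]
  }
  # no protein-coding gene may overlap a tRNA gene
  if (!is.null(trna) && nrow(trna)) {
    keep <- vapply(models, function(m) {
      sp <- model_span(m)
      !overlaps_features(m$scaffold_id, sp[1], sp[2], trna)
    }, logical(1))
    models <- models[keep]
    mt <- mt[keep, , drop = FALSE]
  }
  if (opts$rescue) {
    feats <- feature_table(models, trna)
    sg <- syntenic_gap_search(mt, db, genome, feats,
                              min_codons = 30L)
    models <- c(models, sg$models)
    if (!is.null(sg$assignments)) mt <- rbind(mt, sg$assignments)
    feats <- feature_table(models, trna)
    lo <- find_large_orfs(genome, feats, min_len_aa = opts$min_orf_aa)
    models <- c(models, lo)
  }
  models <- propagate_ty_flags(models, ty_hits)
  fs_calls <- unlist(lapply(models, function(m) m$fs_calls),
                     recursive = FALSE)
  counts <- c(hsps = nrow(hsps), candidate_loci = nrow(candidates),
              assigned = sum(!is.na(mt$pillar_id)),
              singletons = sum(vapply(models, function(m)
                is.na(m$pillar_id), logical(1))),
              models = length(models),
              frameshift_sites = length(fs_calls))
  list(models = models, assignments = mt, fs_calls = fs_calls,
       hsps = hsps, counts = counts)
}

model_table <- function(models) {
  if (!length(models))
    return(data.frame(locus_id = character(0), scaffold = character(0),
                      strand = character(0), start = numeric(0),
                      end = numeric(0), pillar_id = character(0),
                      query_id = character(0), evalue = numeric(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(models, function(m) {
    sp <- model_span(m)
    data.frame(locus_id = m$model_id, scaffold = m$scaffold_id,
               strand = m$strand, start = sp[1], end = sp[2],
               pillar_id = m$pillar_id, query_id = m$source_ref_gene,
               evalue = m$evalue, evidence = m$evidence,
               stringsAsFactors = FALSE)
  }))
}

feature_table <- function(models, trna = NULL) {
  ft <- if (length(models)) {
    do.call(rbind, lapply(models, function(m) {
      sp <- model_span(m)
      data.frame(scaffold = m$scaffold_id, start = sp[1], end = sp[2],
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(scaffold = character(0), start = numeric(0),
                    end = numeric(0))
  if (!is.null(trna) && nrow(trna))
    ft <- rbind(ft, trna[, c("scaffold", "start", "end")])
  ft
}

#' Gene names: prefix plus scaffold index plus a zero-padded ordinal
#' @keywords internal
rename_models <- function(models, genome, prefix) {
  scafs <- names(genome$sequences)
  by_sc <- split(seq_along(models),
                 vapply(models, `[[`, character(1), "scaffold_id"))
  for (sc in names(by_sc)) {
    idx <- by_sc[[sc]]
    starts <- vapply(models[idx], function(m) model_span(m)[1], numeric(1))
    idx <- idx[order(starts)]
    si <- match(sc, scafs)
    for (k in seq_along(idx))
      models[[idx[k]]]$model_id <- sprintf("%s%d_%04d", prefix, si, k)
  }
  models
}

# ---------------------------------------------------------------------------
# Full pipeline

#' Run the full annotation pipeline
#'
#' Stage order: tRNA track ingest, homology search, pillar mapping, gene
#' modeling with intron prediction, frameshift detection and repair
#' (according to `fix_frameshifts`), one re-annotation round if edits were
#' applied, rescue passes, and writers.
#'
#' @param scaffolds path to the scaffolds FASTA, or a [genome()]
#' @param pillars path to the pillar DB JSON, or a parsed database
#' @param prefix gene-name prefix
#' @param wgd `"post"` or `"non"`
#' @param fix_frameshifts `"reads"` (vote indels from primary reads),
#'   `"n-insert"` (patch with N placeholders), or `"off"` (report only)
#' @param reads optional reads FASTA path or named vector (required for
#'   `fix_frameshifts = "reads"`)
#' @param contigs optional contigs FASTA path or named vector (enables the
#'   scaffold-integrity check when reads are also given)
#' @param trna_track optional tRNA feature TSV path or data.frame
#' @param hits optional tabular hit file path or HSP data.frame
#' @param out output directory, or NULL to skip writing
#' @param opts [pipeline_options()]
#' @return list(models, assignments, corrections, genome, counts, qc,
#'   detected_frameshifts)
#' @export
run_pipeline <- function(scaffolds, pillars, prefix = "GEN",
                         wgd = c("post", "non"),
                         fix_frameshifts = c("off", "reads", "n-insert"),
                         reads = NULL, contigs = NULL, trna_track = NULL,
                         hits = NULL, out = NULL,
                         opts = pipeline_options()) {
  wgd <- match.arg(wgd)
  fix_frameshifts <- match.arg(fix_frameshifts)
  g <- if (inherits(scaffolds, "syn_genome")) scaffolds
    else read_genome(scaffolds)
  db <- if (is.character(pillars)) read_pillar_db(pillars) else pillars
  is_path <- function(x) is.character(x) && length(x) == 1L &&
    is.null(names(x)) && file.exists(x)
  if (is_path(reads)) reads <- read_fasta(reads)
  if (is_path(contigs)) contigs <- read_fasta(contigs)
  if (fix_frameshifts == "reads" && is.null(reads))
    stop("fix_frameshifts = 'reads' requires a reads file")
  trna <- if (is.character(trna_track)) read_trna_track(trna_track)
    else trna_track
  if (is.character(hits)) hits <- parse_search_tabular(hits,
                                                       opts$max_evalue)

  qc <- NULL
  if (!is.null(reads) && !is.null(contigs))
    qc <- check_scaffold_integrity(reads, contigs, g)

  ann <- annotate_once(g, db, wgd, trna = trna, hits = hits, opts = opts)
  detected <- ann$fs_calls
  corrections <- list()
  final_genome <- g
  if (fix_frameshifts != "off" && length(ann$fs_calls)) {
    rep <- repair_frameshifts(ann$fs_calls, g, reads, fix_frameshifts)
    corrections <- rep$corrections
    if (length(corrections)) {
      final_genome <- write_corrected_scaffolds(g, corrections)
      # re-annotate the edited assembly once (edits are batched)
      ann <- annotate_once(final_genome, db, wgd, trna = trna,
                           hits = NULL, opts = opts)
      ann$models <- mark_corrected_models(ann$models, corrections)
    }
  }
  ann$models <- rename_models(ann$models, final_genome, prefix)
  ann$assignments <- model_table(ann$models)

  res <- list(models = ann$models, assignments = ann$assignments,
              corrections = corrections, genome = final_genome,
              counts = ann$counts, qc = qc,
              detected_frameshifts = detected)
  if (!is.null(out)) write_pipeline_outputs(res, trna, out)
  res
}

# map correction positions into edited-genome coordinates and tag the
# models that span them
mark_corrected_models <- function(models, corrections) {
  if (!length(corrections)) return(models)
  df <- do.call(rbind, lapply(corrections, function(co)
    data.frame(scaffold = co$scaffold_id, pos = co$position,
               delta = if (co$op == "insert") nchar(co$bases)
                       else -nchar(co$bases), stringsAsFactors = FALSE)))
  df <- df[order(df$scaffold, df$pos), ]
  df$edited_pos <- df$pos
  for (sc in unique(df$scaffold)) {
    i <- which(df$scaffold == sc)
    if (length(i) > 1L)
      df$edited_pos[i] <- df$pos[i] + c(0, cumsum(df$delta[i]))[
        seq_along(i)]
  }
  lapply(models, function(m) {
    sp <- model_span(m)
    hit <- any(df$scaffold == m$scaffold_id & df$edited_pos >= sp[1] &
               df$edited_pos < sp[2])
    if (hit) m$tags <- unique(c(m$tags, "frameshift-corrected"))
    m
  })
}

#' Write all pipeline outputs to a directory
#'
#' Emits annotation GFF3, the locus-assignment table, per-tag gene lists,
#' the singleton list, predicted protein FASTA, the corrections report and
#' corrected scaffolds (when edits were applied), the contig-link matrix
#' (when computed), and a per-stage count log.
#'
#' @param res result of [run_pipeline()]
#' @param trna tRNA track used (echoed into the GFF3)
#' @param out output directory
#' @export
write_pipeline_outputs <- function(res, trna, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_gff3(res$models, trna, file.path(out, "annotation.gff3"),
             res$genome)
  write_assignment_table(res$assignments, file.path(out, "assignments.tsv"))
  write_tag_lists(res$models, file.path(out, "tags"))
  singles <- vapply(Filter(function(m) is.na(m$pillar_id), res$models),
                    `[[`, character(1), "model_id")
  writeLines(singles, file.path(out, "singletons.txt"))
  prots <- vapply(res$models, function(m) {
    aa <- translate_dna(model_cds(m, res$genome))
    sub("\\*$", "", aa)
  }, character(1))
  names(prots) <- vapply(res$models, `[[`, character(1), "model_id")
  write_fasta(prots, file.path(out, "proteins.fasta"))
  if (length(res$corrections))
    write_fasta(unlist(res$genome$sequences),
                file.path(out, "scaffolds.corrected.fasta"))
  # the corrections report reflects the edits applied to reach res$genome
  rep_path <- file.path(out, "corrections.tsv")
  reportable <- res$corrections
  rep <- if (length(reportable)) do.call(rbind, lapply(reportable,
    function(co) data.frame(scaffold = co$scaffold_id,
                            position = co$position, op = co$op,
                            bases = co$bases, support = co$read_support,
                            applied = co$applied, stringsAsFactors = FALSE)))
    else data.frame(scaffold = character(0), position = numeric(0),
                    op = character(0), bases = character(0),
                    support = integer(0), applied = logical(0))
  write.table(rep, rep_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$qc))
    write_link_matrix(res$qc, file.path(out, "contig_links.tsv"),
                      file.path(out, "flagged_joins.tsv"))
  log <- c(sprintf("%s\t%s", names(res$counts), res$counts),
           sprintf("corrections_applied\t%d", length(res$corrections)))
  writeLines(log, file.path(out, "log.txt"))
  invisible(out)
}
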