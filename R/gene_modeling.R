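# From retained loci to gene models: reference-gene choice, classification of
# consecutive HSP pairs, seed derivation and start/stop extension.
#
# All pair logic runs on the coding strand: `h1` is the 5' HSP in coding
# orientation. Stored coordinates always refer to the forward strand;
# reverse-complement views are taken locally where needed.

#' Choose the reference gene for a locus
#'
#' Preference order for a post-WGD target genome: (1) post-WGD
#' intron-containing member with the best hit; (2) post-WGD member with the
#' best hit; (3) intron-containing member with the best hit; (4) member with
#' the best hit. Symmetric for non-WGD targets. "Best hit" is the lowest
#' E-value, ties broken by higher bit score, then lexically by gene id.
#'
#' @param pillar a [pillar()]
#' @param species_group `"post-WGD"` or `"non-WGD"` (the target genome)
#' @param hit_ranking data.frame(gene_id, evalue, bitscore): each member's
#'   best hit at the locus (members without hits absent)
#' @return the chosen [ref_gene()]
#' @export
select_reference_gene <- function(pillar, species_group, hit_ranking) {
  if (nrow(hit_ranking) == 0L)
    stop("no member of pillar ", pillar$pillar_id, " hits the locus")
  members <- pillar$members
  names(members) <- vapply(members, `[[`, character(1), "gene_id")
  hit_ranking <- hit_ranking[hit_ranking$gene_id %in% names(members), ,
                             drop = FALSE]
  if (nrow(hit_ranking) == 0L)
    stop("hit ranking names no member of pillar ", pillar$pillar_id)
  grp <- vapply(members[hit_ranking$gene_id], `[[`, character(1),
                "species_group")
  intr <- vapply(members[hit_ranking$gene_id], `[[`, logical(1), "has_intron")
  tiers <- list(grp == species_group & intr,
                grp == species_group,
                intr,
                rep(TRUE, nrow(hit_ranking)))
  for (sel in tiers) {
    if (!any(sel)) next
    sub <- hit_ranking[sel, , drop = FALSE]
    o <- order(sub$evalue, -sub$bitscore, sub$gene_id)
    return(members[[sub$gene_id[o[1]]]])
  }
}

#' Mean protein lengths of a pillar's species groups
#' @param pillar a [pillar()]
#' @return named numeric c(`non-WGD`, `post-WGD`); NA for an absent group
#' @export
mean_group_lengths <- function(pillar) {
  grp <- vapply(pillar$members, `[[`, character(1), "species_group")
  len <- vapply(pillar$members, function(m) nchar(m$protein), numeric(1))
  c("non-WGD" = if (any(grp == "non-WGD")) mean(len[grp == "non-WGD"])
      else NA_real_,
    "post-WGD" = if (any(grp == "post-WGD")) mean(len[grp == "post-WGD"])
      else NA_real_)
}

#' Classify a pair of consecutive HSPs
#'
#' `h1` must be 5' of `h2` on the coding strand. With `dq` the query gap in
#' nucleotide equivalents (3x the amino-acid gap) and `ds` the subject gap
#' on the coding strand, the four outcomes are: *frameshift* (reading frames
#' differ, `|dq - ds| <= gap_tol`); *low-similarity* (same frame,
#' `|dq - ds| <= gap_tol`, no in-frame stop codon between the HSPs);
#' *intron* (`|dq - ds| > gap_tol`, a small query gap against a large
#' subject gap, and only when the pillar's species group has an
#' intron-bearing member); otherwise *duplication*. HSPs overlapping on the
#' query by more than `overlap_tol` amino acids are called duplications
#' directly.
#'
#' @param h1,h2 one-row HSP data.frames (same scaffold and strand)
#' @param intron_allowed logical
#' @param genome a [genome()], used to test for stops between same-frame
#'   HSPs; may be NULL when `stop_between` is supplied
#' @param gap_tol "similar distance" tolerance in nt (default 30: tolerant
#'   of small indels, below the ~50 nt minimum of real yeast introns)
#' @param overlap_tol query-overlap tolerance in aa
#' @param min_intron smallest subject gap accepted as an intron (nt)
#' @param stop_between optional logical overriding the stop-codon test
#' @return object of class `syn_paircall`: list(kind, pair, details) where
#'   `details` holds the frameshift site/phase, the intron search window, or
#'   the duplication split
#' @export
classify_hsp_pair <- function(h1, h2, intron_allowed, genome = NULL,
                              gap_tol = 30, overlap_tol = 15,
                              min_intron = 40, stop_between = NULL) {
  stopifnot(h1$scaffold == h2$scaffold, h1$strand == h2$strand)
  minus <- h1$strand == "-"
  if (minus && h1$sstart < h2$sstart)
    stop("h1 must be 5' of h2 on the coding strand")
  overlap_q <- max(0L, h1$qend - h2$qstart + 1L)
  dq <- (h2$qstart - h1$qend - 1L) * 3L
  ds <- if (minus) h1$sstart - h2$send else h2$sstart - h1$send
  phase <- ((ds - dq) %% 3 + 3) %% 3
  call <- function(kind, details = list())
    structure(list(kind = kind, pair = list(h1 = h1, h2 = h2),
                   details = c(details, list(dq = dq, ds = ds,
                                             phase = phase))),
              class = "syn_paircall")

  if (overlap_q > overlap_tol) return(call("duplication"))
  similar <- abs(dq - ds) <= gap_tol
  if (phase != 0 && similar) {
    site <- if (minus) floor((h2$send + h1$sstart) / 2)
            else floor((h1$send + h2$sstart) / 2)
    return(call("frameshift", list(site = site)))
  }
  if (phase == 0 && similar) {
    sb <- stop_between
    if (is.null(sb)) {
      if (is.null(genome))
        stop("need a genome (or stop_between) for same-frame pairs")
      sb <- stop_between_hsps(h1, h2, genome)
    }
    if (!sb) return(call("low-similarity"))
  }
  if (!similar && intron_allowed && dq <= gap_tol && ds >= min_intron) {
    win <- if (minus) c(h2$send, h1$sstart) else c(h1$send, h2$sstart)
    return(call("intron", list(window = win)))
  }
  call("duplication")
}

#' In-frame stop test between two same-frame HSPs (coding strand)
#' @keywords internal
stop_between_hsps <- function(h1, h2, genome) {
  seq <- genome$sequences[[h1$scaffold]]
  if (h1$strand == "-") {
    L <- nchar(seq)
    cseq <- revcomp(seq)
    a <- L - h1$sstart   # coding-strand position just after h1
    b <- L - h2$send     # coding-strand position of h2 start
  } else {
    cseq <- seq
    a <- h1$send
    b <- h2$sstart
  }
  gap <- b - a
  gap_aligned <- gap - gap %% 3
  has_inframe_stop(cseq, a, a + gap_aligned)
}

#' Derive seed intervals from a chain of classified HSP pairs
#'
#' Pairs are evaluated 5' to 3' on the coding strand, merging greedily:
#' frameshift, low-similarity and intron calls extend the current group to
#' the outer edges of both HSPs; a duplication call closes the current group
#' and opens a new one (two separate models). A single-HSP locus seeds
#' directly from that HSP's extent.
#'
#' @param hsps HSP data.frame of one locus, one query; rows sorted 5' to 3'
#'   on the coding strand
#' @param calls list of `syn_paircall` for consecutive rows
#'   (`length(calls) == nrow(hsps) - 1`)
#' @return list of groups; each group is a list(start, end, hsp_idx, calls)
#'   with forward-strand 0-based half-open seed coordinates and the calls
#'   internal to the group
#' @export
seed_coordinates <- function(hsps, calls) {
  stopifnot(length(calls) == max(nrow(hsps) - 1L, 0L))
  groups <- list()
  cur <- list(idx = 1L, calls = list())
  for (i in seq_along(calls)) {
    if (calls[[i]]$kind == "duplication") {
      groups[[length(groups) + 1L]] <- cur
      cur <- list(idx = i + 1L, calls = list())
    } else {
      cur$idx <- c(cur$idx, i + 1L)
      cur$calls <- c(cur$calls, list(calls[[i]]))
    }
  }
  groups[[length(groups) + 1L]] <- cur
  lapply(groups, function(g) {
    part <- hsps[g$idx, , drop = FALSE]
    list(start = min(part$sstart), end = max(part$send),
         hsp_idx = g$idx, calls = g$calls)
  })
}

#' Extend a seed interval to a start and stop codon
#'
#' Start rule: if the seed begins with ATG it is kept; otherwise the frame
#' is walked upstream to the furthest ATG reachable without crossing an
#' in-frame stop (bounded by `max_extend_nt`); if a stop intervenes before
#' any ATG, the first 45 nt inside the seed are scanned for a leading ATG;
#' failing that the seed start is kept and the model tagged `manual-check`.
#' Stop rule: the frame is walked downstream from the chosen start to the
#' first in-frame stop, which trims into the seed when the stop lies inside
#' it. Walking into an N run tags the model `runs-into-N`; walking off the
#' scaffold end without a stop tags `manual-check`.
#'
#' @param seed_start,seed_end 0-based half-open forward-strand interval;
#'   must be in frame with the gene (a codon boundary at the 5' coding edge)
#' @param scaffold_seq forward-strand scaffold sequence
#' @param strand `"+"` or `"-"`
#' @param max_extend_nt cap on upstream extension (nt); defaults to
#'   unbounded
#' @param start_window nt scanned inside the seed for a fallback start
#' @return list(start, end, tags): forward-strand coordinates of the final
#'   model (end includes the stop codon when one was found)
#' @export
extend_to_start_stop <- function(seed_start, seed_end, scaffold_seq, strand,
                                 max_extend_nt = Inf, start_window = 45L) {
  L <- nchar(scaffold_seq)
  if (seed_end - seed_start < 3L) stop("seed shorter than one codon")
  if (strand == "-") {
    cseq <- revcomp(scaffold_seq)
    cs <- L - seed_end
    ce <- L - seed_start
  } else {
    cseq <- scaffold_seq
    cs <- seed_start
    ce <- seed_end
  }
  st <- extend_start_coding(cseq, cs, max_extend_nt, start_window)
  en <- extend_stop_coding(cseq, st$start, ce)
  tags <- unique(c(st$tags, en$tags))
  if (strand == "-")
    list(start = L - en$end, end = L - st$start, tags = tags)
  else
    list(start = st$start, end = en$end, tags = tags)
}

# Start-codon search on the coding strand; `cs` is a codon boundary.
extend_start_coding <- function(cseq, cs, max_extend_nt = Inf,
                                start_window = 45L) {
  if (codon_at(cseq, cs) == "ATG")
    return(list(start = cs, tags = character(0)))
  atgs <- integer(0)
  tags <- character(0)
  p <- cs - 3L
  stopped <- FALSE
  while (p >= 0L && (cs - p) <= max_extend_nt) {
    cod <- codon_at(cseq, p)
    if (grepl("N", cod)) { tags <- c(tags, "runs-into-N"); break }
    if (is_stop_codon(cod)) { stopped <- TRUE; break }
    if (cod == "ATG") atgs <- c(atgs, p)
    p <- p - 3L
  }
  if (length(atgs))
    return(list(start = min(atgs), tags = tags))
  # no upstream ATG: look for a leading ATG within the first 45 nt of seed
  for (q in seq(cs, cs + start_window - 3L, by = 3L)) {
    if (q + 3L > nchar(cseq)) break
    if (codon_at(cseq, q) == "ATG")
      return(list(start = q, tags = tags))
  }
  list(start = cs, tags = unique(c(tags, "manual-check")))
}

# Stop-codon search downstream of `start` (coding strand, codon-aligned).
extend_stop_coding <- function(cseq, start, seed_end) {
  L <- nchar(cseq)
  p <- start
  while (p + 3L <= L) {
    cod <- codon_at(cseq, p)
    if (grepl("N", cod))
      return(list(end = max(seed_end, p), tags = "runs-into-N"))
    if (is_stop_codon(cod))
      return(list(end = p + 3L, tags = character(0)))
    p <- p + 3L
  }
  list(end = seed_end, tags = "manual-check")
}
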