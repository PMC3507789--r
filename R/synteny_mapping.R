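# Assignment of candidate genomic loci to pillars. Paralogous ambiguity is
# resolved by the neighboring-pillar interval test against the ancestral
# gene order; copy-number limits are 2 loci per pillar for post-WGD genomes
# and 1 for non-WGD genomes; tandem duplicates split off into their own
# pillar.
#
# Assignments are rows of a data.frame:
#   locus_id, scaffold, strand, start, end, pillar_id (NA = singleton),
#   query_id, evalue, evidence
# evidence is one of unique-hit, synteny-resolved, unresolved-singleton,
# tandem-copy.

#' Ancestral-order index of every pillar
#' @param ancestral_order named list of ordered pillar-id vectors (one per
#'   ancestral chromosome)
#' @return data.frame(pillar_id, chr, idx)
#' @export
ancestral_index <- function(ancestral_order) {
  if (length(ancestral_order) == 0L)
    return(data.frame(pillar_id = character(0), chr = character(0),
                      idx = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(names(ancestral_order), function(chr) {
    ids <- ancestral_order[[chr]]
    data.frame(pillar_id = ids, chr = chr, idx = seq_along(ids),
               stringsAsFactors = FALSE)
  }))
}

#' Resolve a multi-candidate locus by the neighboring-pillar interval test
#'
#' Scans outward from the locus for the nearest unambiguously assigned
#' neighbors on the same scaffold (at most `radius` assigned loci to each
#' side). A candidate pillar wins iff it lies strictly between the left and
#' right neighbors in the ancestral order -- on the same ancestral
#' chromosome -- and no other candidate does. At a scaffold end, where only
#' one flanking neighbor exists, a candidate wins iff it lies within
#' `radius` ancestral positions of that single neighbor. The decision is
#' made purely on synteny, ignoring E-values.
#'
#' @param locus list or one-row data.frame with scaffold, start, end
#' @param candidates character vector of candidate pillar ids
#' @param flanking_assignments assignment data.frame of unambiguous
#'   placements (used as anchors)
#' @param ancestral data.frame from [ancestral_index()]
#' @param radius neighbor scan radius (assigned loci per side) and the
#'   single-flank ancestral distance bound
#' @return the winning pillar id, or NA if the test is inconclusive
#' @export
resolve_by_synteny <- function(locus, candidates, flanking_assignments,
                               ancestral, radius = 10L) {
  fl <- flanking_assignments
  fl <- fl[fl$scaffold == locus$scaffold & !is.na(fl$pillar_id), ,
           drop = FALSE]
  fl <- merge(fl, ancestral, by = "pillar_id")
  if (nrow(fl) == 0L) return(NA_character_)
  lefts <- fl[fl$end <= locus$start, , drop = FALSE]
  rights <- fl[fl$start >= locus$end, , drop = FALSE]
  lefts <- head(lefts[order(-lefts$end), , drop = FALSE], radius)
  rights <- head(rights[order(rights$start), , drop = FALSE], radius)
  pl <- if (nrow(lefts)) lefts[1, ] else NULL    # nearest anchors
  pr <- if (nrow(rights)) rights[1, ] else NULL
  cand <- merge(data.frame(pillar_id = candidates,
                           stringsAsFactors = FALSE),
                ancestral, by = "pillar_id")
  if (nrow(cand) == 0L) return(NA_character_)

  in_interval <- function(ci) {
    if (!is.null(pl) && !is.null(pr)) {
      if (pl$chr != pr$chr || cand$chr[ci] != pl$chr) return(FALSE)
      lo <- min(pl$idx, pr$idx); hi <- max(pl$idx, pr$idx)
      cand$idx[ci] > lo && cand$idx[ci] < hi
    } else {
      anchor <- if (!is.null(pl)) pl else pr
      cand$chr[ci] == anchor$chr && cand$idx[ci] != anchor$idx &&
        abs(cand$idx[ci] - anchor$idx) <= radius
    }
  }
  ok <- vapply(seq_len(nrow(cand)), in_interval, logical(1))
  if (sum(ok) == 1L) cand$pillar_id[ok] else NA_character_
}

#' Demote loci exceeding the WGD-aware copy-number cap
#'
#' Post-WGD genomes may assign two loci to one pillar (the retained ohnolog
#' pair); non-WGD genomes only one. Excess loci are kept in order of
#' evidence strength (unique-hit, then synteny-resolved), then lowest
#' E-value; the rest are demoted to singletons.
#'
#' @param assignments assignment data.frame
#' @param wgd_mode `"post"` or `"non"`
#' @return assignment data.frame with caps enforced
#' @export
enforce_copy_number <- function(assignments, wgd_mode = c("post", "non")) {
  wgd_mode <- match.arg(wgd_mode)
  cap <- if (wgd_mode == "post") 2L else 1L
  ev_rank <- c("unique-hit" = 1L, "synteny-resolved" = 2L)
  for (pid in unique(assignments$pillar_id[!is.na(assignments$pillar_id)])) {
    rows <- which(assignments$pillar_id == pid)
    if (length(rows) <= cap) next
    o <- order(ev_rank[assignments$evidence[rows]],
               assignments$evalue[rows])
    demote <- rows[o][-seq_len(cap)]
    assignments$pillar_id[demote] <- NA_character_
    assignments$evidence[demote] <- "unresolved-singleton"
  }
  assignments
}

#' Split tandem duplicates off into their own pillar
#'
#' When two adjacent loci (no unrelated assigned locus between them, same
#' scaffold, strand-agnostic) are assigned to one pillar, only one keeps the
#' pillar: the copy whose flanking assignments match the pillar's ancestral
#' neighborhood, with ties going to the 5'-most copy. The other copy moves
#' to a derived tandem-copy pillar (`<pillar>.tandem<k>`).
#'
#' @param assignments assignment data.frame
#' @param ancestral data.frame from [ancestral_index()]
#' @param radius ancestral distance bound for the flank-match score
#' @return assignment data.frame
#' @export
handle_tandem_duplicates <- function(assignments, ancestral, radius = 10L) {
  anc_pos <- setNames(ancestral$idx, ancestral$pillar_id)
  anc_chr <- setNames(ancestral$chr, ancestral$pillar_id)
  for (pid in unique(assignments$pillar_id[!is.na(assignments$pillar_id)])) {
    rows <- which(assignments$pillar_id == pid)
    if (length(rows) < 2L) next
    for (sc in unique(assignments$scaffold[rows])) {
      srows <- rows[assignments$scaffold[rows] == sc]
      if (length(srows) < 2L) next
      srows <- srows[order(assignments$start[srows])]
      # adjacency: no other assigned locus between consecutive copies
      scaf_rows <- which(assignments$scaffold == sc &
                         !is.na(assignments$pillar_id))
      adj <- logical(length(srows) - 1L)
      for (i in seq_len(length(srows) - 1L)) {
        lo <- assignments$end[srows[i]]
        hi <- assignments$start[srows[i + 1L]]
        between <- scaf_rows[assignments$start[scaf_rows] >= lo &
                             assignments$end[scaf_rows] <= hi &
                             !scaf_rows %in% srows]
        adj[i] <- length(between) == 0L
      }
      if (!any(adj)) next
      # flank-match score per copy: assigned neighbors whose ancestral
      # position is within `radius` of this pillar's
      score <- vapply(srows, function(r) {
        nb <- scaf_rows[scaf_rows != r & !scaf_rows %in% srows]
        if (!length(nb) || is.na(anc_pos[pid])) return(0L)
        nb <- nb[order(abs(assignments$start[nb] - assignments$start[r]))]
        nb <- head(nb, 2L)
        sum(vapply(nb, function(n) {
          np <- assignments$pillar_id[n]
          isTRUE(anc_chr[np] == anc_chr[pid]) &&
            isTRUE(abs(anc_pos[np] - anc_pos[pid]) <= radius)
        }, logical(1)))
      }, integer(1))
      keep <- srows[order(-score, assignments$start[srows])][1]
      extras <- setdiff(srows, keep)
      for (k in seq_along(extras)) {
        assignments$pillar_id[extras[k]] <- sprintf("%s.tandem%d", pid, k)
        assignments$evidence[extras[k]] <- "tandem-copy"
      }
    }
  }
  assignments
}

#' Emit an unresolved multi-candidate locus as a singleton
#'
#' @param locus list or one-row data.frame (scaffold, strand, start, end,
#'   query_id, evalue, locus_id)
#' @param candidates candidate pillar ids (recorded but not assigned)
#' @return one-row assignment data.frame with evidence
#'   `unresolved-singleton`
#' @export
annotate_unplaced <- function(locus, candidates = character(0)) {
  data.frame(locus_id = locus$locus_id, scaffold = locus$scaffold,
             strand = locus$strand, start = locus$start, end = locus$end,
             pillar_id = NA_character_,
             query_id = locus$query_id, evalue = locus$evalue,
             evidence = "unresolved-singleton", stringsAsFactors = FALSE)
}

#' Assign candidate loci to pillars
#'
#' Takes the per-pillar candidate loci (best query per pillar, strongest
#' locus plus retained secondaries), groups candidates hitting overlapping
#' genomic regions, resolves multi-pillar loci by synteny (iterating so that
#' newly resolved loci can anchor later decisions), demotes the remainder to
#' singletons, and enforces copy-number caps.
#'
#' @param candidates data.frame with one row per (pillar, locus): scaffold,
#'   strand, start, end, pillar_id, query_id, evalue
#' @param ancestral_order named list of ordered pillar-id vectors
#' @param wgd_mode `"post"` or `"non"`
#' @param radius synteny scan radius
#' @return assignment data.frame (see module header)
#' @export
assign_loci_to_pillars <- function(candidates, ancestral_order,
                                   wgd_mode = c("post", "non"),
                                   radius = 10L) {
  wgd_mode <- match.arg(wgd_mode)
  anc <- ancestral_index(ancestral_order)
  if (nrow(candidates) == 0L)
    return(data.frame(locus_id = character(0), scaffold = character(0),
                      strand = character(0), start = numeric(0),
                      end = numeric(0), pillar_id = character(0),
                      query_id = character(0), evalue = numeric(0),
                      evidence = character(0), stringsAsFactors = FALSE))

  # group candidate rows whose genomic intervals overlap (strand-agnostic)
  candidates$group <- NA_integer_
  gid <- 0L
  for (sc in unique(candidates$scaffold)) {
    rows <- which(candidates$scaffold == sc)
    ir <- IRanges::IRanges(start = candidates$start[rows] + 1L,
                           end = candidates$end[rows])
    comp <- IRanges::reduce(ir, min.gapwidth = 1L)
    ov <- IRanges::findOverlaps(ir, comp)
    candidates$group[rows] <- gid + S4Vectors::subjectHits(ov)
    gid <- gid + length(comp)
  }

  out <- list()
  pending <- list()
  for (g in unique(candidates$group)) {
    sub <- candidates[candidates$group == g, , drop = FALSE]
    sub <- sub[order(sub$evalue), , drop = FALSE]
    locus <- data.frame(locus_id = sprintf("L%04d", g),
                        scaffold = sub$scaffold[1], strand = sub$strand[1],
                        start = min(sub$start), end = max(sub$end),
                        query_id = sub$query_id[1], evalue = sub$evalue[1],
                        stringsAsFactors = FALSE)
    cand_pillars <- unique(sub$pillar_id)
    if (length(cand_pillars) == 1L) {
      locus$pillar_id <- cand_pillars
      locus$evidence <- "unique-hit"
      out[[length(out) + 1L]] <- locus
    } else {
      pending[[length(pending) + 1L]] <-
        list(locus = locus, candidates = cand_pillars)
    }
  }
  assigned <- do.call(rbind, out)

  # iterate: resolved loci become anchors for later rounds
  repeat {
    progress <- FALSE
    still <- list()
    for (p in pending) {
      win <- resolve_by_synteny(p$locus, p$candidates, assigned, anc,
                                radius = radius)
      if (!is.na(win)) {
        row <- p$locus
        row$pillar_id <- win
        row$evidence <- "synteny-resolved"
        assigned <- rbind(assigned, row)
        progress <- TRUE
      } else {
        still[[length(still) + 1L]] <- p
      }
    }
    pending <- still
    if (!progress || length(pending) == 0L) break
  }
  for (p in pending)
    assigned <- rbind(assigned,
                      cbind(annotate_unplaced(p$locus, p$candidates)))
  assigned <- assigned[order(assigned$scaffold, assigned$start), ,
                       drop = FALSE]
  rownames(assigned) <- NULL
  assigned <- enforce_copy_number(assigned, wgd_mode)
  handle_tandem_duplicates(assigned, anc, radius = radius)
}
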