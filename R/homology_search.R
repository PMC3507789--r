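# Translated homology search and hit-retention rules.
#
# HSPs live in a plain data.frame with one row per high-scoring pair:
#   query_id, scaffold, qstart, qend   (1-based inclusive amino acids)
#   sstart, send                       (0-based half-open forward-strand nt)
#   strand, frame, evalue, bitscore, score (raw)

# Karlin-Altschul parameters for ungapped BLOSUM62
KA_LAMBDA <- 0.3176
KA_K <- 0.134

#' Convert a raw alignment score to a bit score (ungapped BLOSUM62 statistics)
#' @param raw raw alignment score
#' @return bit score
#' @export
raw_to_bitscore <- function(raw) (KA_LAMBDA * raw - log(KA_K)) / log(2)

#' Karlin-Altschul E-value from a bit score and the search-space size
#' @param bitscore bit score
#' @param m query length (aa)
#' @param n subject search-space size (aa summed over frames)
#' @return expected number of chance hits
#' @export
karlin_altschul_evalue <- function(bitscore, m, n) m * n * 2^(-bitscore)

empty_hsps <- function() {
  data.frame(query_id = character(0), scaffold = character(0),
             qstart = integer(0), qend = integer(0),
             sstart = numeric(0), send = numeric(0),
             strand = character(0), frame = integer(0),
             evalue = numeric(0), bitscore = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Parse a tabular translated-search hit file
#'
#' Twelve tab-separated columns, no header: query id, subject id, percent
#' identity, alignment length, mismatches, query start, query end, subject
#' start, subject end, frame (0-2), E-value, bit score. Subject coordinates
#' are 1-based inclusive; `sstart > send` marks a minus-strand hit. On
#' reading, subject coordinates are normalized to 0-based half-open
#' forward-strand intervals with an explicit strand field, and rows at or
#' above the initial E-value cutoff are dropped.
#'
#' @param path file path
#' @param max_evalue initial cutoff; hits with `E >= max_evalue` are dropped
#' @return HSP data.frame
#' @export
parse_search_tabular <- function(path, max_evalue = 1e-5) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(empty_hsps())
  rows <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 12L)
      stop("malformed hit row at line ", i, ": expected >= 12 columns, got ",
           length(f))
    num <- suppressWarnings(as.numeric(f[c(6:12)]))
    if (anyNA(num))
      stop("malformed hit row at line ", i, ": non-numeric field")
    qstart <- num[1]; qend <- num[2]
    s1 <- num[3]; s2 <- num[4]
    frame <- as.integer(num[5]); ev <- num[6]; bit <- num[7]
    if (qstart > qend || ev < 0 || !frame %in% 0:2)
      stop("malformed hit row at line ", i, ": bad coordinates or frame")
    if (s1 <= s2) {
      strand <- "+"; sstart <- s1 - 1; send <- s2
    } else {
      strand <- "-"; sstart <- s2 - 1; send <- s1
    }
    out[[i]] <- data.frame(query_id = f[1], scaffold = f[2],
                           qstart = as.integer(qstart),
                           qend = as.integer(qend),
                           sstart = sstart, send = send, strand = strand,
                           frame = frame, evalue = ev, bitscore = bit,
                           score = NA_real_, stringsAsFactors = FALSE)
  }
  hsps <- do.call(rbind, out)
  hsps[hsps$evalue < max_evalue, , drop = FALSE]
}

#' Serialize HSPs back to the tabular dialect read by [parse_search_tabular()]
#' @param hsps HSP data.frame
#' @param path output path
#' @export
write_search_tabular <- function(hsps, path) {
  lines <- character(nrow(hsps))
  for (i in seq_len(nrow(hsps))) {
    h <- hsps[i, ]
    if (h$strand == "+") { s1 <- h$sstart + 1; s2 <- h$send }
    else { s1 <- h$send; s2 <- h$sstart + 1 }
    lines[i] <- paste(h$query_id, h$scaffold, "100.0",
                      h$qend - h$qstart + 1L, 0L, h$qstart, h$qend,
                      s1, s2, h$frame,
                      format(h$evalue, digits = 17),
                      format(h$bitscore, digits = 17), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Translated search of protein queries against a genome
#'
#' Six-frame translation of the genome followed by exact 4-mer seeding and
#' ungapped X-drop extension with BLOSUM62 scoring. E-values follow the
#' Karlin-Altschul form from the bit score and the search-space size.
#' Deterministic for fixed input. Indels and introns deliberately break
#' alignments into separate HSPs, which downstream stages classify.
#'
#' @param proteins named character vector of amino-acid queries
#' @param genome a [genome()]
#' @param max_evalue retain hits with `E < max_evalue` (set `Inf` for the
#'   thresholdless syntenic-gap pass)
#' @param word seed word size
#' @param xdrop X-drop for the ungapped extension (raw score units)
#' @param min_raw_score floor on reported raw scores
#' @return HSP data.frame sorted by query then E-value
#' @export
builtin_translated_search <- function(proteins, genome, max_evalue = 1e-5,
                                      word = 4L, xdrop = 40L,
                                      min_raw_score = 40L) {
  stopifnot(length(proteins) > 0L, !is.null(names(proteins)))
  tr <- six_frame_translate(genome)
  raw <- .seed_extend_cpp(unname(proteins), tr$aa, word = word,
                          xdrop = xdrop, min_score = min_raw_score)
  if (nrow(raw) == 0L) return(empty_hsps())
  meta <- tr$meta[raw$subject, ]
  nt <- t(mapply(frame_aa_to_nt, raw$sstart, raw$send,
                 meta$strand, meta$frame, meta$scaffold_length))
  m <- nchar(proteins)[raw$query]
  n_space <- sum(nchar(tr$aa))
  bit <- raw_to_bitscore(raw$score)
  ev <- karlin_altschul_evalue(bit, m, n_space)
  hsps <- data.frame(query_id = names(proteins)[raw$query],
                     scaffold = meta$scaffold,
                     qstart = raw$qstart, qend = raw$qend,
                     sstart = nt[, 1], send = nt[, 2],
                     strand = meta$strand, frame = meta$frame,
                     evalue = ev, bitscore = bit, score = raw$score,
                     stringsAsFactors = FALSE)
  hsps <- hsps[hsps$evalue < max_evalue, , drop = FALSE]
  hsps <- hsps[order(hsps$query_id, hsps$evalue, -hsps$bitscore), ,
               drop = FALSE]
  rownames(hsps) <- NULL
  hsps
}

#' Decimal exponent of an E-value
#'
#' `floor(log10(e))` for positive `e`; an exact 0.0 maps to -324, matching
#' double-precision underflow, so that zero E-values always pass the
#' halved-exponent retention gate.
#'
#' @param e numeric vector of E-values
#' @return integer vector of exponents
#' @export
exponent10 <- function(e) {
  out <- ifelse(e == 0, -324, floor(log10(e)))
  as.integer(out)
}

#' Secondary-locus retention rule
#'
#' A weaker locus for the best query of a pillar is kept iff the decimal
#' exponent of its E-value is lower than -30 AND lower than half the
#' exponent of the strongest locus's E-value. With a strongest hit at
#' 1e-100, secondaries are retained iff their E-value is below 1e-50.
#'
#' @param evalue numeric vector of secondary-locus E-values
#' @param e_best E-value of the strongest locus
#' @return logical vector
#' @export
secondary_retained <- function(evalue, e_best) {
  ex <- exponent10(evalue)
  ex < -30 & ex < exponent10(e_best) / 2
}

#' Filter a list of candidate loci by the secondary-retention rule
#'
#' The strongest locus itself is always kept; the others are kept iff they
#' pass [secondary_retained()].
#'
#' @param loci list of locus objects (see [cluster_hsps_to_loci()])
#' @param e_best E-value of the strongest locus
#' @return filtered list
#' @export
retain_secondary_loci <- function(loci, e_best) {
  if (length(loci) == 0L) return(loci)
  ev <- vapply(loci, `[[`, numeric(1), "evalue")
  best <- which.min(ev)
  keep <- secondary_retained(ev, e_best)
  keep[best] <- TRUE
  loci[keep]
}

#' Group the HSPs of one query into candidate genomic loci
#'
#' Single-linkage clustering per scaffold and strand: consecutive HSPs whose
#' genomic gap is at most `max_gap_nt` join one locus. A locus's E-value is
#' the minimum over its member HSPs.
#'
#' @param hsps HSP data.frame for a single query
#' @param max_gap_nt linkage gap (default 5000, above the span of yeast
#'   introns and assembly indels but below typical gene spacing at which
#'   tandem paralogs separate)
#' @return list of loci; each is a list(scaffold, strand, start, end,
#'   evalue, hsps)
#' @export
cluster_hsps_to_loci <- function(hsps, max_gap_nt = 5000) {
  if (nrow(hsps) == 0L) return(list())
  loci <- list()
  for (key in unique(paste(hsps$scaffold, hsps$strand))) {
    sub <- hsps[paste(hsps$scaffold, hsps$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$sstart), , drop = FALSE]
    grp <- integer(nrow(sub))
    g <- 1L
    max_end <- sub$send[1]
    grp[1] <- g
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$sstart[i] - max_end > max_gap_nt) g <- g + 1L
      grp[i] <- g
      max_end <- max(max_end, sub$send[i])
    }
    for (gi in unique(grp)) {
      part <- sub[grp == gi, , drop = FALSE]
      loci[[length(loci) + 1L]] <- list(
        scaffold = part$scaffold[1], strand = part$strand[1],
        start = min(part$sstart), end = max(part$send),
        evalue = min(part$evalue), hsps = part)
    }
  }
  loci
}

#' Pick the pillar member whose best hit against the genome is strongest
#'
#' Returns the query protein with the minimal E-value over all its hits;
#' ties are broken by higher bit score, then lexically by gene id. Pillars
#' with no hits yield a distinguished no-hit result (`query_id = NA`).
#'
#' @param pillar a [pillar()]
#' @param hsps HSP data.frame covering (at least) this pillar's members
#' @return list(query_id, evalue, bitscore, best_hit) where `best_hit` is a
#'   one-row HSP data.frame, or `query_id = NA` if no member has a hit
#' @export
best_query_for_pillar <- function(pillar, hsps) {
  ids <- vapply(pillar$members, `[[`, character(1), "gene_id")
  sub <- hsps[hsps$query_id %in% ids, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(list(query_id = NA_character_, evalue = NA_real_,
                bitscore = NA_real_, best_hit = NULL))
  o <- order(sub$evalue, -sub$bitscore, sub$query_id)
  best <- sub[o[1], , drop = FALSE]
  list(query_id = best$query_id, evalue = best$evalue,
       bitscore = best$bitscore, best_hit = best)
}
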