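# Single-intron prediction from splice-site, branchpoint and 3' acceptor
# motif inventories. At most one intron is ever predicted per gene; evidence
# for a second intron flags the model for manual curation.

#' Construct an intron call
#'
#' @param intron_start,intron_end forward-strand 0-based half-open interval
#'   of the intron
#' @param strand coding strand
#' @param branch_start forward-strand coord of the branchpoint hexamer start
#' @param motifs named character c(donor, branch, acceptor)
#' @return object of class `syn_introncall`
#' @export
intron_call <- function(intron_start, intron_end, strand, branch_start,
                        motifs) {
  stopifnot(motifs[["donor"]] %in% DONOR_MOTIFS,
            motifs[["branch"]] %in% BRANCH_MOTIFS,
            motifs[["acceptor"]] %in% ACCEPTOR_MOTIFS)
  structure(list(intron_start = intron_start, intron_end = intron_end,
                 strand = strand, branch_start = branch_start,
                 motifs = motifs),
            class = "syn_introncall")
}

# positions (0-based) at which any of `motifs` occurs in `seq`; a zero-width
# lookahead reports overlapping occurrences too
motif_positions <- function(seq, motifs) {
  sort(unique(unlist(lapply(motifs, function(m) {
    hits <- gregexpr(paste0("(?=", m, ")"), seq, perl = TRUE)[[1]]
    if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
  }))))
}

#' Locate an intron between two HSPs
#'
#' Enumerates donor/branchpoint/acceptor motif combinations in the window
#' spanning the inter-HSP gap (plus `slack` nt into each HSP) and keeps
#' combinations for which the spliced product is in frame and stop-free with
#' donor < branchpoint < acceptor. Candidates are ranked by agreement
#' between the intron length and the subject-minus-query gap difference,
#' then by donor proximity to the end of the first HSP. Returns NULL when no
#' valid combination exists (the caller tags the model `manual-check`).
#'
#' @param h1,h2 one-row HSP data.frames, `h1` 5' on the coding strand, both
#'   from a pair classified as intron
#' @param genome a [genome()]
#' @param intron_min,intron_max accepted intron length bounds (nt)
#' @param slack nt searched inside each HSP end
#' @return a [intron_call()] or NULL
#' @export
intron_between_hsps <- function(h1, h2, genome, intron_min = 40L,
                                intron_max = 1000L, slack = 45L) {
  seq <- genome$sequences[[h1$scaffold]]
  L <- nchar(seq)
  minus <- h1$strand == "-"
  cseq <- if (minus) revcomp(seq) else seq
  # coding-strand coordinates of the HSP chain
  if (minus) {
    c1s <- L - h1$send; c1e <- L - h1$sstart
    c2s <- L - h2$send; c2e <- L - h2$sstart
  } else {
    c1s <- h1$sstart; c1e <- h1$send
    c2s <- h2$sstart; c2e <- h2$send
  }
  dq <- (h2$qstart - h1$qend - 1L) * 3L
  ds <- c2s - c1e
  expected_len <- ds - dq

  win_lo <- max(0L, c1e - slack)
  win_hi <- min(nchar(cseq), c2s + slack)
  win <- subseq0(cseq, win_lo, win_hi)
  donors <- motif_positions(win, DONOR_MOTIFS) + win_lo
  acc_ends <- motif_positions(win, ACCEPTOR_MOTIFS) + win_lo + 3L
  branches <- motif_positions(win, BRANCH_MOTIFS) + win_lo
  if (!length(donors) || !length(acc_ends) || !length(branches))
    return(NULL)

  best <- NULL
  for (d in donors) {
    for (a in acc_ends) {
      len <- a - d
      if (len < intron_min || len > intron_max) next
      if ((len - expected_len) %% 3 != 0) next
      br <- branches[branches >= d + 6L & branches + 6L <= a - 3L]
      if (!length(br)) next
      if (!spliced_product_clean(cseq, c1s, d, a, c2e)) next
      cand <- list(d = d, a = a, br = br[length(br)],
                   len_err = abs(len - expected_len),
                   donor_prox = abs(d - c1e))
      if (is.null(best) ||
          cand$len_err < best$len_err ||
          (cand$len_err == best$len_err && cand$donor_prox < best$donor_prox))
        best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  motifs <- c(donor = subseq0(cseq, best$d, best$d + 6L),
              branch = subseq0(cseq, best$br, best$br + 6L),
              acceptor = subseq0(cseq, best$a - 3L, best$a))
  if (minus)
    intron_call(L - best$a, L - best$d, "-", L - best$br - 6L, motifs)
  else
    intron_call(best$d, best$a, "+", best$br, motifs)
}

# in-frame, stop-free test for the spliced product [cs, d) + [a, ce)
spliced_product_clean <- function(cseq, cs, d, a, ce) {
  if (d <= cs || a >= ce) return(FALSE)
  spliced <- paste0(subseq0(cseq, cs, d), subseq0(cseq, a, ce))
  n <- nchar(spliced) - nchar(spliced) %% 3
  if (n < 3L) return(FALSE)
  aa <- translate_dna(substr(spliced, 1L, n))
  !grepl("\\*", aa)
}

#' Recover a missed first exon upstream of a single-HSP model
#'
#' When only exon 2 produced an HSP (the first exon being too short to seed
#' a translated hit), scan upstream for an acceptor, branchpoint and donor
#' in reverse order, then for an ATG-initiated exon 1 upstream of the donor,
#' such that the total protein length approximates the reference protein's.
#' Only invoked when the reference gene itself carries an intron.
#'
#' @param hsp one-row HSP data.frame (the exon-2 hit)
#' @param genome a [genome()]
#' @param reference_gene the chosen [ref_gene()] (must have an intron)
#' @param scan_window nt scanned upstream of the HSP for exon 1
#' @param intron_min,intron_max intron length bounds (nt)
#' @param len_tol relative tolerance on the reference protein length
#' @return list(exons, intron, start, end) with forward-strand coordinates
#'   (exons is a 2x2 matrix ordered 5' to 3' on the coding strand), or NULL
#' @export
recover_missing_exon1 <- function(hsp, genome, reference_gene,
                                  scan_window = 600L, intron_min = 40L,
                                  intron_max = 1000L, len_tol = 0.2) {
  if (!reference_gene$has_intron)
    stop("exon-1 recovery requires an intron-bearing reference gene")
  seq <- genome$sequences[[hsp$scaffold]]
  L <- nchar(seq)
  minus <- hsp$strand == "-"
  cseq <- if (minus) revcomp(seq) else seq
  c1 <- if (minus) L - hsp$send else hsp$sstart   # coding coord of HSP start
  ref_len <- nchar(reference_gene$protein)

  # the HSP may start a little inside the intron (extension overshoot) or a
  # little inside exon 2, so the acceptor is searched around the HSP start
  missing_prefix <- 3L * (hsp$qstart - 1L)
  a_lo <- max(0L, c1 - missing_prefix - 15L)
  a_hi <- min(nchar(cseq), c1 + 45L)
  win_lo <- max(0L, a_lo - intron_max - scan_window)
  win <- subseq0(cseq, win_lo, a_hi)
  acc_ends <- motif_positions(win, ACCEPTOR_MOTIFS) + win_lo + 3L
  acc_ends <- acc_ends[acc_ends >= a_lo & acc_ends <= a_hi]
  donors <- motif_positions(win, DONOR_MOTIFS) + win_lo
  branches <- motif_positions(win, BRANCH_MOTIFS) + win_lo
  atgs <- motif_positions(win, "ATG") + win_lo
  if (!length(acc_ends) || !length(donors) || !length(atgs)) return(NULL)

  best <- NULL
  for (a in acc_ends) {
    # exon 2 runs from this acceptor to the downstream stop; the codon scan
    # is anchored at the first codon boundary past the acceptor in the
    # HSP's frame (the HSP start itself may lie inside the intron)
    s0 <- a + (((c1 - a) %% 3) + 3L) %% 3L
    en <- extend_stop_coding(cseq, s0, s0 + 3L)
    if (length(en$tags)) next
    ce <- en$end
    for (d in donors[donors < a & a - donors >= intron_min &
                     a - donors <= intron_max]) {
      br <- branches[branches >= d + 6L & branches + 6L <= a - 3L]
      if (!length(br)) next
      for (m in atgs[atgs < d & d - atgs <= scan_window]) {
        e1 <- d - m
        if ((e1 + (ce - a)) %% 3 != 0) next
        total_aa <- (e1 + (ce - a)) / 3 - 1L   # exclude the stop codon
        if (abs(total_aa - ref_len) > len_tol * ref_len) next
        if (!spliced_start_clean(cseq, m, d, a, ce)) next
        cand <- list(m = m, d = d, a = a, br = br[length(br)],
                     len_err = abs(total_aa - ref_len))
        if (is.null(best) || cand$len_err < best$len_err ||
            (cand$len_err == best$len_err &&
             (cand$m > best$m || (cand$m == best$m && cand$d > best$d))))
          best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  motifs <- c(donor = subseq0(cseq, best$d, best$d + 6L),
              branch = subseq0(cseq, best$br, best$br + 6L),
              acceptor = subseq0(cseq, best$a - 3L, best$a))
  if (minus) {
    exons <- rbind(c(L - best$d, L - best$m),   # exon 1 (5' on coding strand)
                   c(L - ce, L - best$a))
    ic <- intron_call(L - best$a, L - best$d, "-", L - best$br - 6L, motifs)
    list(exons = exons, intron = ic, start = L - ce, end = L - best$m)
  } else {
    exons <- rbind(c(best$m, best$d), c(best$a, ce))
    ic <- intron_call(best$d, best$a, "+", best$br, motifs)
    list(exons = exons, intron = ic, start = best$m, end = ce)
  }
}

# spliced CDS must begin ATG, end at its stop, and be internally stop-free
spliced_start_clean <- function(cseq, m, d, a, ce) {
  spliced <- paste0(subseq0(cseq, m, d), subseq0(cseq, a, ce))
  if (nchar(spliced) %% 3 != 0) return(FALSE)
  if (substr(spliced, 1, 3) != "ATG") return(FALSE)
  aa <- translate_dna(spliced)
  n <- nchar(aa)
  substr(aa, n, n) == "*" && !grepl("\\*", substr(aa, 1, n - 1L))
}

#' Cap a model at one intron
#'
#' The intron search deliberately stops at a single intron per gene; when
#' the HSP chain implies two or more introns only the 5'-most call is kept
#' and the model is flagged for manual curation.
#'
#' @param calls list of [intron_call()] (possibly empty), ordered 5' to 3'
#'   on the coding strand
#' @return list(call = the retained call or NULL, flagged = logical)
#' @export
cap_one_intron <- function(calls) {
  if (length(calls) <= 1L)
    return(list(call = if (length(calls)) calls[[1]] else NULL,
                flagged = FALSE))
  list(call = calls[[1]], flagged = TRUE)
}
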