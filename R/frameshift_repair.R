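# Repair of frameshift sequencing errors. Given a frameshift-classified HSP
# pair, the assembly is either corrected with the indel most supported by
# primary reads (tested for creation of an intact ORF), or patched with one
# or two N placeholders that restore the downstream reading frame.

# BLASTN-like statistics for match +1 / mismatch -2 scoring
NT_LAMBDA <- 1.33
NT_K <- 0.621

#' Extract the genomic window around a putative frameshift
#'
#' The window runs from 50 bp upstream of the end of the first HSP to 50 bp
#' downstream of the start of the second HSP (HSPs in genomic order),
#' clamped to the scaffold bounds. When the two HSPs overlap on the subject
#' (both alignments extending a little past the indel), the window spans the
#' overlap region with the same 50 bp pads on each side.
#'
#' @param h1,h2 one-row HSP data.frames on one scaffold
#' @param genome a [genome()]
#' @param pad flank size in bp
#' @return list(scaffold, start, end, seq) with 0-based half-open coords
#' @export
extract_fs_window <- function(h1, h2, genome, pad = 50L) {
  if (h1$sstart > h2$sstart) { tmp <- h1; h1 <- h2; h2 <- tmp }
  L <- genome$lengths[[h1$scaffold]]
  start <- max(0L, min(h1$send, h2$sstart) - pad)
  end <- min(L, max(h1$send, h2$sstart) + pad)
  list(scaffold = h1$scaffold, start = start, end = end,
       seq = subseq0(genome$sequences[[h1$scaffold]], start, end))
}

#' Count indel votes from primary reads over a window
#'
#' Reads sharing a 20-mer with the window (either orientation) are aligned
#' locally; alignments whose E-value (Karlin-Altschul on the +1/-2
#' nucleotide score) is below `max_evalue` contribute their indels. Indels
#' are keyed by exact (window offset, op, bases) after normalizing the
#' position to the leftmost equivalent placement within a homopolymer run,
#' counted across reads, sorted by support then offset, and candidates seen
#' in fewer than `min_reads` reads are dropped.
#'
#' @param window_seq window DNA string
#' @param reads named character vector of read sequences
#' @param max_evalue read-hit threshold
#' @param min_reads minimum supporting reads
#' @return data.frame(offset, op, bases, support) sorted by decreasing
#'   support, then offset; zero rows when no qualifying read exists
#' @export
vote_indels <- function(window_seq, reads, max_evalue = 1e-30,
                        min_reads = 2L) {
  empty <- data.frame(offset = integer(0), op = character(0),
                      bases = character(0), support = integer(0),
                      stringsAsFactors = FALSE)
  if (length(reads) == 0L || nchar(window_seq) < 20L) return(empty)
  rset <- Biostrings::DNAStringSet(reads)
  n_space <- sum(nchar(reads))
  kpos <- seq(1L, nchar(window_seq) - 19L, by = 15L)
  hits_fwd <- rep(FALSE, length(reads))
  hits_rev <- rep(FALSE, length(reads))
  for (kp in kpos) {
    kmer <- substr(window_seq, kp, kp + 19L)
    if (grepl("N", kmer)) next
    hits_fwd <- hits_fwd | Biostrings::vcountPattern(kmer, rset) > 0L
    hits_rev <- hits_rev |
      Biostrings::vcountPattern(revcomp(kmer), rset) > 0L
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  votes <- list()
  for (i in which(hits_fwd | hits_rev)) {
    rd <- if (hits_fwd[i]) reads[[i]] else revcomp(reads[[i]])
    if (grepl("[^ACGT]", rd) || grepl("[^ACGT]", window_seq)) next
    aln <- Biostrings::pairwiseAlignment(
      pattern = window_seq, subject = rd, type = "local",
      substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
    bit <- (NT_LAMBDA * Biostrings::score(aln) - log(NT_K)) / log(2)
    ev <- karlin_altschul_evalue(bit, nchar(window_seq), n_space)
    if (ev >= max_evalue) next
    idl <- alignment_indels(aln, window_seq)
    for (v in idl)
      votes[[length(votes) + 1L]] <- c(v, read = names(reads)[i])
  }
  if (length(votes) == 0L) return(empty)
  df <- do.call(rbind, lapply(votes, function(v)
    data.frame(offset = as.integer(v[["offset"]]), op = v[["op"]],
               bases = v[["bases"]], read = v[["read"]],
               stringsAsFactors = FALSE)))
  df <- unique(df)   # one vote per read per indel
  agg <- stats::aggregate(read ~ offset + op + bases, df, length)
  names(agg)[names(agg) == "read"] <- "support"
  agg <- agg[agg$support >= min_reads, , drop = FALSE]
  agg <- agg[order(-agg$support, agg$offset), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# Extract indels of a local alignment relative to the pattern (the window),
# normalizing each indel to its leftmost equivalent position.
alignment_indels <- function(aln, window_seq) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  off <- Biostrings::start(Biostrings::pattern(aln)) - 1L  # 0-based
  out <- list()
  i <- 1L
  while (i <= length(p)) {
    if (p[i] == "-") {                    # read carries extra bases: insert
      j <- i
      while (j <= length(p) && p[j] == "-") j <- j + 1L
      bases <- paste(s[i:(j - 1L)], collapse = "")
      out[[length(out) + 1L]] <-
        c(offset = normalize_indel_pos(window_seq, off, "insert", bases),
          op = "insert", bases = bases)
      i <- j
    } else if (s[i] == "-") {             # window carries extra bases: delete
      j <- i
      while (j <= length(p) && s[j] == "-") j <- j + 1L
      bases <- paste(p[i:(j - 1L)], collapse = "")
      out[[length(out) + 1L]] <-
        c(offset = normalize_indel_pos(window_seq, off, "delete", bases),
          op = "delete", bases = bases)
      off <- off + (j - i)
      i <- j
    } else {
      off <- off + 1L
      i <- i + 1L
    }
  }
  out
}

#' Leftmost equivalent placement of an indel within a homopolymer run
#'
#' Distinct reads can report the same physical indel at different offsets of
#' a homopolymer; normalizing to the leftmost equivalent position makes the
#' (offset, op, bases) vote key exact.
#'
#' @param seq the reference string the offset refers to
#' @param offset 0-based indel position
#' @param op `"insert"` or `"delete"`
#' @param bases indel bases
#' @return normalized 0-based offset
#' @export
normalize_indel_pos <- function(seq, offset, op, bases) {
  offset <- as.integer(offset)
  if (op == "insert") {
    b <- substr(bases, nchar(bases), nchar(bases))
    if (length(unique(strsplit(bases, "")[[1]])) == 1L) {
      while (offset > 0L && substr(seq, offset, offset) == b)
        offset <- offset - 1L
    }
  } else {
    k <- nchar(bases)
    while (offset > 0L &&
           substr(seq, offset, offset + k - 1L) ==
           subseq0(seq, offset, offset + k))
      offset <- offset - 1L
  }
  offset
}

#' Apply the first vote that creates an intact ORF
#'
#' Candidates are tried in vote order; the first whose application yields a
#' stop-free, in-frame open reading frame spanning both HSPs is turned into
#' an applied [correction()]. If all candidates fail (or none exist) the
#' gene keeps its `frameshift-uncorrected` tag and NULL is returned.
#'
#' @param candidates data.frame from [vote_indels()]
#' @param ctx list(genome, window, h1, h2) where `window` comes from
#'   [extract_fs_window()] and `h1`/`h2` are the frameshifted pair in
#'   genomic order
#' @return an applied [correction()] or NULL
#' @export
apply_first_fixing_indel <- function(candidates, ctx) {
  if (nrow(candidates) == 0L) return(NULL)
  h1 <- ctx$h1; h2 <- ctx$h2
  if (h1$sstart > h2$sstart) { tmp <- h1; h1 <- h2; h2 <- tmp }
  seq <- ctx$genome$sequences[[h1$scaffold]]
  region_start <- h1$sstart
  region <- subseq0(seq, region_start, h2$send)
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    pos_in_region <- ctx$window$start + cand$offset - region_start
    if (pos_in_region <= 0L || pos_in_region >= nchar(region)) next
    edited <- if (cand$op == "insert")
      paste0(substr(region, 1L, pos_in_region), cand$bases,
             substr(region, pos_in_region + 1L, nchar(region)))
    else
      paste0(substr(region, 1L, pos_in_region),
             substr(region, pos_in_region + nchar(cand$bases) + 1L,
                    nchar(region)))
    if (orf_intact(edited, h1$strand)) {
      return(correction(h1$scaffold, ctx$window$start + cand$offset,
                        cand$op, cand$bases, read_support = cand$support,
                        applied = TRUE))
    }
  }
  NULL
}

# stop-free translation of the (possibly edited) inter-HSP region on the
# coding strand, anchored at the 5' coding HSP's codon boundary
orf_intact <- function(region, strand) {
  cseq <- if (strand == "-") revcomp(region) else region
  n <- nchar(cseq) - nchar(cseq) %% 3
  if (n < 3L) return(FALSE)
  !grepl("\\*", translate_dna(substr(cseq, 1L, n)))
}

#' Patch a frameshift with placeholder N bases
#'
#' With no reads available, the frame offset `d` between the two HSPs
#' determines the insertion: `(3 - d) mod 3` (one or two) N bases restore
#' the downstream frame. The estimated site is the midpoint of the
#' inter-HSP gap, aligned to the codon boundaries of the upstream coding
#' frame so the junction translates as an X residue.
#'
#' @param h1,h2 one-row HSP data.frames of the frameshifted pair
#' @param genome a [genome()]
#' @return an applied [correction()] inserting 1-2 N bases
#' @export
insert_placeholder_Ns <- function(h1, h2, genome) {
  if (h1$sstart > h2$sstart) { tmp <- h1; h1 <- h2; h2 <- tmp }
  # query gaps are whole codons, so the phase offset is the genomic gap mod 3
  d <- ((h2$sstart - h1$send) %% 3 + 3) %% 3
  if (d == 0) stop("HSP pair is not frame-shifted")
  n <- (3 - d) %% 3
  mid <- floor((h1$send + h2$sstart) / 2)
  if (h1$strand == "+") {
    pos <- h1$sstart + 3 * round((mid - h1$sstart) / 3)
  } else {
    pos <- h2$send - 3 * round((h2$send - mid) / 3)
  }
  pos <- min(max(pos, h1$send), h2$sstart)
  correction(h1$scaffold, pos, "insert", strrep("N", n),
             read_support = 0L, applied = TRUE)
}

#' Resolve detected frameshifts into corrections
#'
#' @param fs_calls list of frameshift contexts, each a list(h1, h2) in
#'   genomic order (as produced by the annotation driver)
#' @param genome a [genome()]
#' @param reads named character vector of primary reads (reads mode)
#' @param mode `"reads"`, `"n-insert"` or `"off"`
#' @return list(corrections = list of [correction()], fixed = logical per
#'   call)
#' @export
repair_frameshifts <- function(fs_calls, genome, reads = NULL,
                               mode = c("reads", "n-insert", "off")) {
  mode <- match.arg(mode)
  if (mode == "reads" && is.null(reads))
    stop("reads mode requested but no reads supplied")
  corrections <- list()
  fixed <- logical(length(fs_calls))
  if (mode == "off")
    return(list(corrections = corrections, fixed = fixed))
  seen_pos <- character(0)
  for (i in seq_along(fs_calls)) {
    fc <- fs_calls[[i]]
    win <- extract_fs_window(fc$h1, fc$h2, genome)
    co <- if (mode == "reads") {
      votes <- vote_indels(win$seq, reads)
      apply_first_fixing_indel(votes, list(genome = genome, window = win,
                                           h1 = fc$h1, h2 = fc$h2))
    } else {
      insert_placeholder_Ns(fc$h1, fc$h2, genome)
    }
    if (!is.null(co)) {
      key <- paste(co$scaffold_id, co$position, co$op, co$bases)
      if (!key %in% seen_pos) {
        corrections[[length(corrections) + 1L]] <- co
        seen_pos <- c(seen_pos, key)
      }
      fixed[i] <- TRUE
    }
  }
  list(corrections = corrections, fixed = fixed)
}
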