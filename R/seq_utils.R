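# Small sequence helpers shared across modules. All internal coordinates are
# 0-based half-open on the forward strand; conversion to the 1-based
# inclusive convention happens only in the GFF3/tabular writers and readers.

#' Extract a subsequence by 0-based half-open coordinates
#' @param seq character scalar (DNA or protein)
#' @param start,end 0-based half-open interval
#' @keywords internal
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

#' Reverse-complement a DNA string
#' @param seq character scalar, alphabet ACGTN
#' @return character scalar
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a DNA string (standard nuclear code)
#'
#' Trailing bases that do not fill a codon are dropped. Codons containing N
#' translate to `X`; stop codons translate to `*`.
#'
#' @param seq character scalar DNA
#' @return character scalar protein (may contain `*` and `X`)
#' @export
translate_dna <- function(seq) {
  n <- nchar(seq)
  n <- n - n %% 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1L, n)),
                                     if.fuzzy.codon = "X"))
}

#' Six-frame translation of a genome
#'
#' Returns one amino-acid string per (scaffold, strand, frame) combination
#' together with the metadata needed to map amino-acid coordinates back to
#' forward-strand nucleotide coordinates.
#'
#' @param genome a [genome()] object
#' @return list with `aa` (character vector of translations) and `meta`
#'   (data.frame: scaffold, strand, frame, scaffold_length)
#' @export
six_frame_translate <- function(genome) {
  ids <- names(genome$sequences)
  aa <- character(0)
  meta <- list()
  for (id in ids) {
    fwd <- genome$sequences[[id]]
    rev <- revcomp(fwd)
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      for (f in 0:2) {
        aa <- c(aa, translate_dna(substr(s, f + 1L, L)))
        meta[[length(meta) + 1L]] <- data.frame(
          scaffold = id, strand = strand, frame = f, scaffold_length = L,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(aa = aa, meta = do.call(rbind, meta))
}

#' Map amino-acid coordinates in a translation frame to forward-strand nt
#'
#' @param aa_start,aa_end 0-based half-open amino-acid coords within the frame
#' @param strand,frame,scaffold_length frame metadata
#' @return numeric c(start, end), 0-based half-open forward-strand nt
#' @keywords internal
frame_aa_to_nt <- function(aa_start, aa_end, strand, frame, scaffold_length) {
  p1 <- frame + 3L * aa_start     # coords on the translated strand
  p2 <- frame + 3L * aa_end
  if (strand == "+") c(p1, p2) else c(scaffold_length - p2, scaffold_length - p1)
}

#' Codon starting at a 0-based position of a coding-strand string
#' @keywords internal
codon_at <- function(seq, pos) {
  substr(seq, pos + 1L, pos + 3L)
}

is_stop_codon <- function(codon) codon %in% STOP_CODONS

#' Check whether an in-frame interval of a coding-strand string contains a
#' stop codon. `start`/`end` are 0-based half-open and must be codon-aligned
#' relative to each other.
#' @keywords internal
has_inframe_stop <- function(seq, start, end) {
  if (end - start < 3L) return(FALSE)
  p <- seq(start, end - 3L, by = 3L)
  any(vapply(p, function(i) is_stop_codon(codon_at(seq, i)), logical(1)))
}

#' Random DNA of a given length (uses the current RNG stream)
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Back-translate a protein using uniformly sampled synonymous codons
#' @keywords internal
back_translate <- function(protein) {
  tbl <- codon_table_by_aa()
  aas <- strsplit(protein, "")[[1]]
  paste(vapply(aas, function(a) {
    cods <- tbl[[a]]
    if (is.null(cods)) stop("cannot back-translate residue: ", a)
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

codon_table_by_aa <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- Biostrings::GENETIC_CODE
    cache <<- split(names(gc), unname(gc))
    cache
  }
})

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
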