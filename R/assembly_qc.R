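# Scaffold integrity checking: map paired reads onto contigs, build the
# contig-connection support matrix in scaffold order, and report joins whose
# read-pair support is weak compared to the rest.

#' Parse read pairing from read ids
#'
#' Accepts `/1` `/2` suffixes and 454-style `.f` `.r` suffixes, or a custom
#' regex with two capture groups (pair name, mate label).
#'
#' @param ids character vector of read ids
#' @param pair_regex regex with two capture groups
#' @return data.frame(id, pair, mate) with mate in {1,2}; ids that do not
#'   match have NA pair
#' @export
parse_pair_names <- function(ids,
                             pair_regex = "^(.*)(?:/([12])|\\.([fr]))$") {
  m <- regmatches(ids, regexec(pair_regex, ids))
  pair <- vapply(m, function(x) if (length(x)) x[2] else NA_character_,
                 character(1))
  mate_raw <- vapply(m, function(x) {
    if (!length(x)) return(NA_character_)
    lab <- x[-(1:2)]
    lab <- lab[nzchar(lab)]
    if (length(lab)) lab[1] else NA_character_
  }, character(1))
  mate <- ifelse(mate_raw %in% c("1", "f"), 1L,
                 ifelse(mate_raw %in% c("2", "r"), 2L, NA_integer_))
  pair[is.na(mate)] <- NA_character_
  data.frame(id = ids, pair = pair, mate = mate, stringsAsFactors = FALSE)
}

#' Layout of contigs within scaffolds
#'
#' Locates every contig in the scaffolds by exact sequence match (forward or
#' reverse-complement) and returns its placement ordered along the
#' scaffolds.
#'
#' @param contigs named character vector of contig sequences
#' @param genome the scaffolds [genome()]
#' @return data.frame(contig, scaffold, start, end, orient) ordered by
#'   scaffold then position (0-based half-open coords)
#' @export
contig_layout <- function(contigs, genome) {
  rows <- list()
  for (cid in names(contigs)) {
    found <- FALSE
    for (sc in names(genome$sequences)) {
      for (orient in c("+", "-")) {
        pat <- if (orient == "+") contigs[[cid]] else revcomp(contigs[[cid]])
        hit <- regexpr(pat, genome$sequences[[sc]], fixed = TRUE)
        if (hit[1] != -1) {
          rows[[length(rows) + 1L]] <- data.frame(
            contig = cid, scaffold = sc, start = as.integer(hit[1]) - 1L,
            end = as.integer(hit[1]) - 1L + nchar(pat), orient = orient,
            stringsAsFactors = FALSE)
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  df <- do.call(rbind, rows)
  df[order(df$scaffold, df$start), , drop = FALSE]
}

#' Map paired reads onto contigs via unique scaffold placement
#'
#' Each read is placed in the scaffolds by exact full-length match (both
#' orientations); reads with anything but exactly one placement are
#' discarded, and retained reads are assigned the contig containing their
#' placement. Reads without a parseable mate label are counted and ignored.
#'
#' @param reads named character vector (pairing encoded in the names)
#' @param contigs named character vector of contig sequences
#' @param genome the scaffolds [genome()]
#' @param pair_regex passed to [parse_pair_names()]
#' @return list(placements, layout, counts) where `placements` is a
#'   data.frame(pair, mate, contig, scaffold, start) of uniquely placed
#'   reads and `counts` tallies total/placed/nonunique/unmapped/unpaired
#' @export
map_read_pairs <- function(reads, contigs, genome,
                           pair_regex = "^(.*)(?:/([12])|\\.([fr]))$") {
  pr <- parse_pair_names(names(reads), pair_regex)
  if (all(is.na(pr$pair)))
    stop("no read id matches the pairing convention; offending ids: ",
         paste(head(pr$id, 3), collapse = ", "))
  layout <- contig_layout(contigs, genome)
  paired <- which(!is.na(pr$pair))
  widths <- nchar(reads[paired])
  placements <- list()
  n_nonunique <- 0L; n_unmapped <- 0L
  scaffolds <- Biostrings::DNAStringSet(unlist(genome$sequences))
  # exact full-length placement per read, counted over both strands
  for (w in unique(widths)) {
    idx <- paired[widths == w]
    pd_f <- Biostrings::PDict(Biostrings::DNAStringSet(reads[idx]))
    pd_r <- Biostrings::PDict(Biostrings::DNAStringSet(
      vapply(reads[idx], revcomp, character(1))))
    counts <- matrix(0L, nrow = length(idx), ncol = length(scaffolds))
    firstpos <- matrix(NA_integer_, nrow = length(idx),
                       ncol = length(scaffolds))
    for (s in seq_along(scaffolds)) {
      mf <- Biostrings::matchPDict(pd_f, scaffolds[[s]])
      mr <- Biostrings::matchPDict(pd_r, scaffolds[[s]])
      nf <- S4Vectors::elementNROWS(mf)
      nr <- S4Vectors::elementNROWS(mr)
      counts[, s] <- nf + nr
      st <- ifelse(nf > 0,
                   vapply(seq_along(idx), function(k)
                     if (nf[k] > 0) Biostrings::start(mf[[k]])[1] else
                       NA_integer_, integer(1)),
                   vapply(seq_along(idx), function(k)
                     if (nr[k] > 0) Biostrings::start(mr[[k]])[1] else
                       NA_integer_, integer(1)))
      firstpos[, s] <- st
    }
    tot <- rowSums(counts)
    for (k in seq_along(idx)) {
      if (tot[k] == 1L) {
        s <- which(counts[k, ] > 0L)
        pos <- firstpos[k, s] - 1L
        sc <- names(genome$sequences)[s]
        lay <- layout[layout$scaffold == sc &
                      layout$start <= pos &
                      layout$end >= pos + w, , drop = FALSE]
        if (nrow(lay) == 1L) {
          placements[[length(placements) + 1L]] <- data.frame(
            pair = pr$pair[idx[k]], mate = pr$mate[idx[k]],
            contig = lay$contig, scaffold = sc, start = pos,
            stringsAsFactors = FALSE)
        } else n_unmapped <- n_unmapped + 1L   # in a gap / across contigs
      } else if (tot[k] > 1L) n_nonunique <- n_nonunique + 1L
      else n_unmapped <- n_unmapped + 1L
    }
  }
  placements <- if (length(placements)) do.call(rbind, placements)
    else data.frame(pair = character(0), mate = integer(0),
                    contig = character(0), scaffold = character(0),
                    start = integer(0), stringsAsFactors = FALSE)
  counts <- c(total = length(reads), paired = length(paired),
              unpaired = sum(is.na(pr$pair)),
              placed = nrow(placements), nonunique = n_nonunique,
              unmapped = n_unmapped)
  list(placements = placements, layout = layout, counts = counts)
}

#' Contig-connection support matrix and weak-join report
#'
#' Builds the symmetric matrix of read-pair counts linking any two contigs,
#' with rows and columns ordered as the contigs occur in the scaffolds.
#' Cells for contigs adjacent in a scaffold form the expected band; adjacent
#' joins with support below a fraction of the median band support are
#' flagged, and off-band cells at or above `alt_threshold` are reported as
#' possible alternative joins. The decision to break a weak join is left to
#' the user; this function only reports.
#'
#' @param placements placement data.frame from [map_read_pairs()]
#' @param layout contig layout from [map_read_pairs()] / [contig_layout()]
#' @param weak_fraction adjacent joins with support below
#'   `weak_fraction * median(band support)` (and at least below 2) are
#'   flagged
#' @param alt_threshold minimum support for reporting an off-band link
#' @return list(matrix, band, flagged_joins, alternatives)
#' @export
contig_link_matrix <- function(placements, layout, weak_fraction = 0.25,
                               alt_threshold = 3L) {
  ids <- layout$contig
  n <- length(ids)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(placements)) {
    for (pname in unique(placements$pair)) {
      mates <- placements[placements$pair == pname, , drop = FALSE]
      if (nrow(mates) != 2L || length(unique(mates$mate)) != 2L) next
      a <- match(mates$contig[1], ids)
      b <- match(mates$contig[2], ids)
      if (is.na(a) || is.na(b) || a == b) next
      m[a, b] <- m[a, b] + 1L
      m[b, a] <- m[b, a] + 1L
    }
  }
  band <- list()
  for (sc in unique(layout$scaffold)) {
    cs <- layout$contig[layout$scaffold == sc]
    if (length(cs) < 2L) next
    for (i in seq_len(length(cs) - 1L))
      band[[length(band) + 1L]] <- data.frame(
        scaffold = sc, contig1 = cs[i], contig2 = cs[i + 1L],
        support = m[cs[i], cs[i + 1L]], stringsAsFactors = FALSE)
  }
  band <- if (length(band)) do.call(rbind, band)
    else data.frame(scaffold = character(0), contig1 = character(0),
                    contig2 = character(0), support = integer(0))
  thr <- if (nrow(band)) max(2, weak_fraction * median(band$support)) else 0
  flagged <- band[band$support < thr, , drop = FALSE]
  alt <- list()
  band_key <- paste(pmin(band$contig1, band$contig2),
                    pmax(band$contig1, band$contig2))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || m[i, j] < alt_threshold) next
    if (paste(pmin(ids[i], ids[j]), pmax(ids[i], ids[j])) %in% band_key)
      next
    alt[[length(alt) + 1L]] <- data.frame(
      contig1 = ids[i], contig2 = ids[j], support = m[i, j],
      stringsAsFactors = FALSE)
  }
  alt <- if (length(alt)) do.call(rbind, alt)
    else data.frame(contig1 = character(0), contig2 = character(0),
                    support = integer(0))
  list(matrix = m, band = band, flagged_joins = flagged,
       alternatives = alt)
}

#' Full scaffold-integrity check
#'
#' @param reads,contigs named character vectors
#' @param genome the scaffolds [genome()]
#' @param ... passed to [contig_link_matrix()]
#' @return list(matrix, band, flagged_joins, alternatives, counts)
#' @export
check_scaffold_integrity <- function(reads, contigs, genome, ...) {
  mp <- map_read_pairs(reads, contigs, genome)
  res <- contig_link_matrix(mp$placements, mp$layout, ...)
  res$counts <- mp$counts
  res
}

#' Write the contig link matrix and weak-join report as TSV
#' @param qc result of [check_scaffold_integrity()]
#' @param matrix_path,joins_path output paths
#' @export
write_link_matrix <- function(qc, matrix_path, joins_path) {
  write.table(qc$matrix, matrix_path, sep = "\t", quote = FALSE,
              col.names = NA)
  write.table(qc$flagged_joins, joins_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}
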