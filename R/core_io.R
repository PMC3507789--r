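# Domain types and on-disk formats.
#
# Containers are plain S3 lists / data.frames. Coordinates are 0-based
# half-open on the forward strand everywhere inside the package; the GFF3
# writer and the tabular-hit reader are the only places that convert to and
# from the 1-based inclusive convention.

#' Construct a genome object
#'
#' @param sequences named character vector or list of uppercase DNA strings
#'   (alphabet ACGTN), one per scaffold.
#' @return object of class `syn_genome` with elements `sequences` (named list)
#'   and `lengths` (named integer vector)
#' @export
genome <- function(sequences) {
  sequences <- as.list(sequences)
  if (length(sequences) == 0L) stop("genome has no scaffolds")
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("all scaffolds must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate scaffold id: ",
         names(sequences)[duplicated(names(sequences))][1])
  sequences <- lapply(sequences, toupper)
  bad <- vapply(sequences, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad))
    stop("scaffold contains characters outside ACGTN: ",
         names(sequences)[bad][1])
  structure(list(sequences = sequences,
                 lengths = vapply(sequences, nchar, integer(1))),
            class = "syn_genome")
}

#' @export
print.syn_genome <- function(x, ...) {
  cat("genome:", length(x$sequences), "scaffold(s),",
      sum(x$lengths), "bp total\n")
  invisible(x)
}

#' Construct a reference gene record
#'
#' @param gene_id,species character scalars
#' @param species_group `"post-WGD"` or `"non-WGD"`
#' @param protein amino-acid string (no stop)
#' @param exon_count integer >= 1
#' @param is_ty logical, TRUE for retrotransposon-derived genes
#' @return object of class `syn_refgene`
#' @export
ref_gene <- function(gene_id, species, species_group, protein,
                     exon_count = 1L, is_ty = FALSE) {
  if (!species_group %in% c("post-WGD", "non-WGD"))
    stop("unknown species group: ", species_group)
  if (!nzchar(protein)) stop("protein must be non-empty for ", gene_id)
  if (grepl(sprintf("[^%s]", paste(AA20, collapse = "")), protein))
    stop("invalid amino-acid alphabet in protein of ", gene_id)
  structure(list(gene_id = gene_id, species = species,
                 species_group = species_group, protein = protein,
                 exon_count = as.integer(exon_count),
                 has_intron = exon_count > 1L, is_ty = isTRUE(is_ty)),
            class = "syn_refgene")
}

#' Construct a homology pillar
#'
#' A pillar is a curated column of orthologous (and WGD-paralogous) genes
#' across the reference species. Retrotransposon (Ty) genes live in pillars
#' of their own and never share a pillar with non-Ty genes.
#'
#' @param pillar_id character scalar
#' @param members list of [ref_gene()] records
#' @param ancestral_locus optional id of the pillar's ancestral-order locus
#' @return object of class `syn_pillar`
#' @export
pillar <- function(pillar_id, members, ancestral_locus = NULL) {
  if (length(members) < 1L) stop("pillar ", pillar_id, " has no members")
  ids <- vapply(members, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids))
    stop("duplicate gene id in pillar ", pillar_id, ": ",
         ids[duplicated(ids)][1])
  ty <- vapply(members, `[[`, logical(1), "is_ty")
  if (any(ty) && !all(ty))
    stop("pillar ", pillar_id, " mixes Ty and non-Ty genes")
  structure(list(pillar_id = pillar_id, members = members,
                 ancestral_locus = ancestral_locus),
            class = "syn_pillar")
}

#' Read a FASTA file into a named character vector
#'
#' Record ids are the first whitespace-delimited token of the header;
#' sequences are uppercased. Works for DNA and protein files.
#'
#' @param path file path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line-wrap width
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a genome from a scaffolds FASTA
#' @param path FASTA path
#' @return [genome()] object
#' @export
read_genome <- function(path) genome(read_fasta(path))

# ---------------------------------------------------------------------------
# Pillar database JSON
#
# Self-describing dialect:
#   { "pillars": [ { "pillar_id": ..., "ancestral_locus": ...,
#                    "members": [ { "gene_id": ..., "species": ...,
#                                   "species_group": "post-WGD"|"non-WGD",
#                                   "protein": ..., "exon_count": n,
#                                   "is_ty": bool } ] } ],
#     "ancestral_order": { "<chr>": [ pillar ids in order ] } }

#' Read a pillar database (pillars + ancestral gene order) from JSON
#'
#' @param path JSON file path
#' @return list with `pillars` (named list of [pillar()]) and
#'   `ancestral_order` (named list of character vectors, one per ancestral
#'   chromosome; each pillar id appears at most once)
#' @export
read_pillar_db <- function(path) {
  raw <- jsonlite::read_json(path)
  if (is.null(raw$pillars)) stop("pillar DB lacks a 'pillars' field")
  seen_genes <- character(0)
  pillars <- list()
  for (p in raw$pillars) {
    members <- lapply(p$members, function(m) {
      ref_gene(m$gene_id, m$species, m$species_group, m$protein,
               exon_count = if (is.null(m$exon_count)) 1L else m$exon_count,
               is_ty = isTRUE(m$is_ty))
    })
    ids <- vapply(members, `[[`, character(1), "gene_id")
    dup <- intersect(ids, seen_genes)
    if (length(dup))
      stop("gene listed in two pillars: ", dup[1])
    seen_genes <- c(seen_genes, ids)
    pl <- pillar(p$pillar_id, members,
                 ancestral_locus = p$ancestral_locus)
    pillars[[pl$pillar_id]] <- pl
  }
  anc <- lapply(raw$ancestral_order, function(x) unlist(x, use.names = FALSE))
  all_loci <- unlist(anc, use.names = FALSE)
  if (anyDuplicated(all_loci))
    stop("pillar id repeated in ancestral order: ",
         all_loci[duplicated(all_loci)][1])
  list(pillars = pillars, ancestral_order = anc)
}

#' Write a pillar database to JSON
#' @param db list as returned by [read_pillar_db()]
#' @param path output path
#' @export
write_pillar_db <- function(db, path) {
  out <- list(
    pillars = lapply(unname(db$pillars), function(p) {
      list(pillar_id = p$pillar_id,
           ancestral_locus = p$ancestral_locus,
           members = lapply(p$members, function(m) {
             list(gene_id = m$gene_id, species = m$species,
                  species_group = m$species_group, protein = m$protein,
                  exon_count = m$exon_count, is_ty = m$is_ty)
           }))
    }),
    ancestral_order = db$ancestral_order)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models

#' Construct a gene model
#'
#' @param model_id character scalar
#' @param scaffold_id scaffold the model lives on
#' @param strand `"+"` or `"-"`
#' @param exons integer matrix with columns start,end (0-based half-open,
#'   forward strand), rows ordered 5' to 3' on the coding strand (at most 2)
#' @param pillar_id assigned pillar or NA for singletons
#' @param tags character vector drawn from the recognized tag set
#' @param source_ref_gene id of the reference gene the model was built from
#' @param evidence assignment evidence class
#' @param evalue best supporting E-value
#' @return object of class `syn_model`
#' @export
gene_model <- function(model_id, scaffold_id, strand, exons,
                       pillar_id = NA_character_, tags = character(0),
                       source_ref_gene = NA_character_,
                       evidence = NA_character_, evalue = NA_real_) {
  known <- c("manual-check", "ty", "frameshift-corrected",
             "frameshift-uncorrected", "searchdogs", "large-orf",
             "runs-into-N")
  if (length(setdiff(tags, known)))
    stop("unknown tag: ", setdiff(tags, known)[1])
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) > 2L) stop("more than two exons in ", model_id)
  structure(list(model_id = model_id, scaffold_id = scaffold_id,
                 strand = strand, exons = exons, pillar_id = pillar_id,
                 tags = unique(tags), source_ref_gene = source_ref_gene,
                 evidence = evidence, evalue = evalue),
            class = "syn_model")
}

#' Genomic extent of a model (0-based half-open)
#' @keywords internal
model_span <- function(model) {
  c(min(model$exons[, "start"]), max(model$exons[, "end"]))
}

#' Spliced coding sequence of a model on the coding strand
#' @param model a [gene_model()]
#' @param genome a [genome()]
#' @return character scalar DNA
#' @export
model_cds <- function(model, genome) {
  seq <- genome$sequences[[model$scaffold_id]]
  ex <- model$exons
  ex <- ex[order(ex[, "start"]), , drop = FALSE]   # genomic order
  parts <- vapply(seq_len(nrow(ex)), function(i)
    subseq0(seq, ex[i, "start"], ex[i, "end"]), character(1))
  cds <- paste(parts, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  cds
}

#' Validate a gene model against its invariants
#'
#' Exons must be non-overlapping and ordered; untagged models must have a
#' coding length divisible by three, start with ATG, end at a stop codon and
#' translate without an internal stop.
#'
#' @param model a [gene_model()]
#' @param genome a [genome()]
#' @return TRUE invisibly, or an error
#' @export
validate_model <- function(model, genome) {
  ex <- model$exons[order(model$exons[, "start"]), , drop = FALSE]
  if (any(ex[, "end"] <= ex[, "start"])) stop("empty exon in ", model$model_id)
  if (nrow(ex) == 2L && ex[1, "end"] > ex[2, "start"])
    stop("overlapping exons in ", model$model_id)
  L <- genome$lengths[[model$scaffold_id]]
  if (is.null(L)) stop("unknown scaffold in ", model$model_id)
  if (min(ex[, "start"]) < 0 || max(ex[, "end"]) > L)
    stop("exon outside scaffold bounds in ", model$model_id)
  lax <- any(model$tags %in% c("manual-check", "frameshift-uncorrected",
                               "runs-into-N"))
  cds <- model_cds(model, genome)
  if (!lax) {
    if (nchar(cds) %% 3L != 0L)
      stop("coding length not divisible by 3 in ", model$model_id)
    aa <- translate_dna(cds)
    if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
      stop("internal stop codon in ", model$model_id)
  }
  invisible(TRUE)
}

#' Flatten a list of models to a data.frame (one row per model)
#' @param models list of [gene_model()]
#' @return data.frame
#' @export
models_to_df <- function(models) {
  if (length(models) == 0L)
    return(data.frame(model_id = character(0), scaffold = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), n_exons = integer(0),
                      pillar_id = character(0), tags = character(0),
                      evidence = character(0), evalue = numeric(0)))
  do.call(rbind, lapply(models, function(m) {
    sp <- model_span(m)
    data.frame(model_id = m$model_id, scaffold = m$scaffold_id,
               start = sp[1], end = sp[2], strand = m$strand,
               n_exons = nrow(m$exons), pillar_id = m$pillar_id,
               tags = paste(m$tags, collapse = ","),
               evidence = m$evidence, evalue = m$evalue,
               stringsAsFactors = FALSE)
  }))
}

# ---------------------------------------------------------------------------
# GFF3

#' Write gene models (and an optional tRNA track) as GFF3
#'
#' Coordinates are converted from the internal 0-based half-open convention
#' to 1-based inclusive. Each model is emitted as gene/mRNA/CDS records;
#' two-exon models produce two CDS parts sharing a Parent. Tags are carried
#' in the attribute column (`tags=`), the pillar assignment in `pillar=`.
#'
#' @param models list of [gene_model()]
#' @param trna_features optional data.frame (scaffold,start,end,strand,id)
#'   with 0-based half-open coords
#' @param path output path
#' @param genome a [genome()] used for bounds checking
#' @export
write_gff3 <- function(models, trna_features = NULL, path, genome) {
  lines <- "##gff-version 3"
  for (id in names(genome$sequences))
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", id,
                              genome$lengths[[id]]))
  esc <- function(x) gsub("[;=,\t]", "_", x)
  for (m in models) {
    ex <- m$exons[order(m$exons[, "start"]), , drop = FALSE]
    L <- genome$lengths[[m$scaffold_id]]
    if (is.null(L)) stop("unknown scaffold ", m$scaffold_id)
    if (min(ex[, "start"]) < 0 || max(ex[, "end"]) > L)
      stop("exon outside scaffold bounds in ", m$model_id)
    sp <- model_span(m)
    attrs <- sprintf("ID=%s", esc(m$model_id))
    if (!is.na(m$pillar_id))
      attrs <- paste0(attrs, ";pillar=", esc(m$pillar_id))
    if (length(m$tags))
      attrs <- paste0(attrs, ";tags=", paste(esc(m$tags), collapse = ","))
    if ("manual-check" %in% m$tags)
      attrs <- paste0(attrs, ";note=requires manual curation")
    gl <- sprintf("%s\tsyntann\tgene\t%d\t%d\t.\t%s\t.\t%s",
                  m$scaffold_id, sp[1] + 1L, sp[2], m$strand, attrs)
    ml <- sprintf("%s\tsyntann\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                  m$scaffold_id, sp[1] + 1L, sp[2], m$strand,
                  esc(m$model_id), esc(m$model_id))
    # CDS phase: first coding exon (5' on coding strand) has phase 0
    ex_coding <- if (m$strand == "+") ex else ex[rev(seq_len(nrow(ex))), ,
                                                drop = FALSE]
    phase <- 0L
    cls <- character(0)
    for (i in seq_len(nrow(ex_coding))) {
      cls <- c(cls, sprintf(
        "%s\tsyntann\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s.t1",
        m$scaffold_id, ex_coding[i, "start"] + 1L, ex_coding[i, "end"],
        m$strand, phase, esc(m$model_id), esc(m$model_id)))
      len <- ex_coding[i, "end"] - ex_coding[i, "start"]
      phase <- as.integer((3L - (len - phase) %% 3L) %% 3L)
    }
    if (m$strand == "-") cls <- rev(cls)  # keep file in genomic order
    lines <- c(lines, gl, ml, cls)
  }
  if (!is.null(trna_features) && nrow(trna_features)) {
    for (i in seq_len(nrow(trna_features))) {
      tr <- trna_features[i, ]
      lines <- c(lines, sprintf(
        "%s\tsyntann\ttRNA\t%d\t%d\t.\t%s\t.\tID=%s",
        tr$scaffold, tr$start + 1L, tr$end, tr$strand, esc(tr$id)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a tRNA feature track
#'
#' Accepts a TSV with columns scaffold, start, end, strand, id where start
#' and end are 1-based inclusive (as written by tRNA predictors); converts
#' to the internal 0-based half-open convention.
#'
#' @param path TSV path
#' @return data.frame(scaffold, start, end, strand, id)
#' @export
read_trna_track <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("scaffold", "start", "end", "strand", "id")
  if (!all(need %in% names(df)))
    stop("tRNA track must have columns: ", paste(need, collapse = ", "))
  df$start <- df$start - 1L
  df
}

# ---------------------------------------------------------------------------
# Corrections

#' Construct a proposed assembly correction
#'
#' @param scaffold_id scaffold to edit
#' @param position 0-based position; insertions go before this base,
#'   deletions remove `nchar(bases)` bases starting here
#' @param op `"insert"` or `"delete"`
#' @param bases bases inserted or deleted
#' @param read_support number of reads supporting the edit (0 for N-patches)
#' @param applied whether the edit was applied to the output scaffolds
#' @return object of class `syn_correction`
#' @export
correction <- function(scaffold_id, position, op, bases, read_support = 0L,
                       applied = FALSE) {
  if (!op %in% c("insert", "delete")) stop("bad op: ", op)
  if (op == "insert" && read_support == 0L && !nchar(bases) %in% 1:2)
    stop("placeholder insertions must add 1 or 2 bases")
  if (read_support > 0L && read_support < 2L)
    stop("read-derived corrections need support from at least 2 reads")
  structure(list(scaffold_id = scaffold_id, position = as.numeric(position),
                 op = op, bases = bases,
                 read_support = as.integer(read_support),
                 applied = isTRUE(applied)),
            class = "syn_correction")
}

#' Apply corrections and write the edited scaffolds plus a report
#'
#' Corrections are applied right-to-left within each scaffold so that the
#' positions of earlier (more 5') edits remain valid. Overlapping
#' corrections are an error.
#'
#' @param genome a [genome()]
#' @param corrections list of [correction()] (only `applied` ones are made)
#' @param path output FASTA path, or NULL to skip writing sequence
#' @param report_path output TSV path for the edit report, or NULL
#' @return the edited [genome()]
#' @export
write_corrected_scaffolds <- function(genome, corrections, path = NULL,
                                      report_path = NULL) {
  todo <- Filter(function(co) co$applied, corrections)
  seqs <- genome$sequences
  by_scaf <- split(todo, vapply(todo, `[[`, character(1), "scaffold_id"))
  for (sc in names(by_scaf)) {
    cos <- by_scaf[[sc]]
    pos <- vapply(cos, `[[`, numeric(1), "position")
    width <- vapply(cos, function(co)
      if (co$op == "delete") nchar(co$bases) else 0L, numeric(1))
    o <- order(pos)
    if (any(pos[o][-1] < (pos + width)[o][-length(o)]))
      stop("overlapping corrections on ", sc)
    for (i in order(pos, decreasing = TRUE)) {
      co <- cos[[i]]
      s <- seqs[[sc]]
      if (co$op == "insert") {
        seqs[[sc]] <- paste0(substr(s, 1L, co$position), co$bases,
                             substr(s, co$position + 1L, nchar(s)))
      } else {
        k <- nchar(co$bases)
        found <- substr(s, co$position + 1L, co$position + k)
        if (found != co$bases)
          stop("deletion mismatch on ", sc, " at ", co$position,
               ": expected ", co$bases, ", found ", found)
        seqs[[sc]] <- paste0(substr(s, 1L, co$position),
                             substr(s, co$position + k + 1L, nchar(s)))
      }
    }
  }
  out <- genome(seqs)
  if (!is.null(path)) write_fasta(unlist(out$sequences), path)
  if (!is.null(report_path)) {
    rep <- if (length(corrections)) do.call(rbind, lapply(corrections,
      function(co) data.frame(scaffold = co$scaffold_id,
                              position = co$position, op = co$op,
                              bases = co$bases, support = co$read_support,
                              applied = co$applied,
                              stringsAsFactors = FALSE)))
      else data.frame(scaffold = character(0), position = numeric(0),
                      op = character(0), bases = character(0),
                      support = integer(0), applied = logical(0))
    write.table(rep, report_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  out
}

#' Write one gene-id list per tag
#'
#' Mirrors the "one list per tag" output style: each recognized tag found on
#' any model produces `<dir>/<tag>.txt` with one gene id per line.
#'
#' @param models list of [gene_model()]
#' @param dir output directory (created if needed)
#' @return named character vector of files written
#' @export
write_tag_lists <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tags <- unique(unlist(lapply(models, `[[`, "tags")))
  out <- character(0)
  for (tg in tags) {
    ids <- vapply(Filter(function(m) tg %in% m$tags, models),
                  `[[`, character(1), "model_id")
    f <- file.path(dir, paste0(tg, ".txt"))
    writeLines(ids, f)
    out[tg] <- f
  }
  out
}

#' Write the locus-assignment table
#' @param assignments assignment data.frame (see [assign_loci_to_pillars()])
#' @param path TSV path
#' @export
write_assignment_table <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
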