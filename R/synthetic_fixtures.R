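# Ground-truthed synthetic test worlds: a pillar database with an ancestral
# order, a derived target genome (optionally post-WGD) with planted genes,
# introns, tandem and Ty duplications, injected frameshifts, and simulated
# paired reads. Every generator output is fully determined by the fixture
# seed.

#' Specification of a synthetic fixture
#'
#' @param seed integer; fully determines every generator output
#' @param n_pillars number of homology pillars
#' @param wgd derive a post-WGD target (two ohnolog scaffolds)?
#' @param intron_fraction fraction of pillars carrying a single intron
#'   (default 0.04, the approximate fraction of intron-bearing yeast genes)
#' @param frameshift_count 1-bp indels injected into coding regions
#' @param tandem_count pillars receiving a tandem duplicate in the target
#' @param ty_copies copies of a Ty-like cassette scattered in the target
#' @param divergence amino-acid substitution rate between the ancestral
#'   protein and the target genome's protein
#' @param read_coverage mean depth of simulated paired reads (0 = none)
#' @param read_length read length (bp)
#' @param insert_size outer distance between paired reads (bp)
#' @param n_paralog_pairs pillar pairs given identical proteins, so that
#'   their loci can only be separated by synteny
#' @param wgd_retention fraction of pillars retained in duplicate after WGD
#' @param member_divergence substitution rate between the ancestral protein
#'   and each reference-species member
#' @param mean_protein_len mean protein length (codons, lognormal)
#' @param inversion_prob probability a gene is placed on the minus strand
#' @param shuffle_prob probability of swapping two adjacent genes
#' @return object of class `syn_fixture_spec`
#' @export
fixture_spec <- function(seed, n_pillars, wgd = FALSE,
                         intron_fraction = 0.04, frameshift_count = 0L,
                         tandem_count = 0L, ty_copies = 0L, divergence = 0,
                         read_coverage = 0, read_length = 300L,
                         insert_size = 900L, n_paralog_pairs = 0L,
                         wgd_retention = 0.2, member_divergence = 0.02,
                         mean_protein_len = 450, inversion_prob = 0.2,
                         shuffle_prob = 0.02) {
  stopifnot(intron_fraction >= 0, intron_fraction <= 1,
            divergence >= 0, divergence <= 1,
            wgd_retention >= 0, wgd_retention <= 1,
            frameshift_count >= 0, tandem_count >= 0, ty_copies >= 0,
            n_pillars >= 1)
  structure(as.list(environment()), class = "syn_fixture_spec")
}

# run expr under a derived RNG stream, restoring the caller's RNG state
with_fixture_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(
      rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed + offset)
  expr
}

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1L, replace = TRUE), collapse = ""))
}

mutate_protein <- function(protein, rate) {
  if (rate == 0) return(protein)
  aas <- strsplit(protein, "")[[1]]
  hit <- which(stats::runif(length(aas)) < rate)
  hit <- hit[hit > 1L]   # keep the initiator methionine
  for (i in hit) aas[i] <- sample(setdiff(AA20, aas[i]), 1L)
  paste(aas, collapse = "")
}

random_intron <- function(min_len = 60L, max_len = 400L) {
  donor <- sample(DONOR_MOTIFS, 1L)
  branch <- sample(BRANCH_MOTIFS, 1L)
  acceptor <- sample(ACCEPTOR_MOTIFS, 1L)
  tail_len <- sample(8:30, 1L)
  mid_len <- sample(min_len:max_len, 1L) - 6L - 6L - tail_len - 3L
  mid_len <- max(mid_len, 5L)
  paste0(donor, random_dna(mid_len), branch, random_dna(tail_len), acceptor)
}

#' Build the reference world: pillars, ancestral order, and truth metadata
#'
#' Each pillar gets an ancestral protein (uniform amino-acid model, length
#' lognormal around `mean_protein_len` codons) and four reference members
#' (two post-WGD and two non-WGD species), each a lightly mutated copy of
#' the ancestral protein. A fraction of pillars carries a single intron
#' (members flagged intron-bearing). Paralog-pair pillars share identical
#' ancestral proteins; Ty cassettes live in a separate Ty-only pillar
#' outside the ancestral order.
#'
#' @param spec a [fixture_spec()]
#' @return list(db = pillar database, truth = per-pillar data.frame)
#' @export
build_reference_world <- function(spec) {
  with_fixture_seed(spec$seed, 0L, {
    n <- spec$n_pillars
    sdlog <- 0.25
    lens <- pmax(50L, round(stats::rlnorm(
      n, log(spec$mean_protein_len) - sdlog^2 / 2, sdlog)))
    prots <- vapply(lens, random_protein, character(1))
    if (spec$n_paralog_pairs > 0) {
      half <- floor(n / 2)
      for (j in seq_len(spec$n_paralog_pairs)) {
        if (j + half > n) break
        prots[j + half] <- prots[j]   # identical family members
      }
    }
    has_intron <- stats::runif(n) < spec$intron_fraction
    species <- list(`post-WGD` = c("postA", "postB"),
                    `non-WGD` = c("nonA", "nonB"))
    pillars <- list()
    for (i in seq_len(n)) {
      pid <- sprintf("P%04d", i)
      members <- list()
      for (grp in names(species)) for (sp in species[[grp]]) {
        members[[length(members) + 1L]] <- ref_gene(
          sprintf("%s_%s", sp, pid), sp, grp,
          mutate_protein(prots[i], spec$member_divergence),
          exon_count = if (has_intron[i]) 2L else 1L)
      }
      pillars[[pid]] <- pillar(pid, members, ancestral_locus = pid)
    }
    if (spec$ty_copies > 0) {
      ty_prot <- random_protein(300L)
      pillars[["TY0001"]] <- pillar("TY0001", list(
        ref_gene("postA_TY0001", "postA", "post-WGD", ty_prot, is_ty = TRUE),
        ref_gene("nonA_TY0001", "nonA", "non-WGD",
                 mutate_protein(ty_prot, spec$member_divergence),
                 is_ty = TRUE)))
    }
    db <- list(pillars = pillars,
               ancestral_order = list(chrA = sprintf("P%04d", seq_len(n))))
    truth <- data.frame(pillar_id = sprintf("P%04d", seq_len(n)),
                        ancestral_protein = prots, has_intron = has_intron,
                        stringsAsFactors = FALSE)
    list(db = db, truth = truth)
  })
}

# one gene cassette on the coding strand; the in-frame TAA guard directly
# upstream of the ATG pins the start-codon extension to the true start
build_gene_block <- function(target_protein, intron_seq = NULL,
                             exon1_aa = NULL) {
  cds <- paste0(back_translate(target_protein), sample(STOP_CODONS, 1L))
  if (is.null(intron_seq)) {
    block <- paste0("TAA", cds)
    exons <- matrix(c(3L, 3L + nchar(cds)), ncol = 2)
  } else {
    cut <- 3L * exon1_aa
    block <- paste0("TAA", substr(cds, 1L, cut), intron_seq,
                    substr(cds, cut + 1L, nchar(cds)))
    exons <- matrix(c(3L, 3L + cut,
                      3L + cut + nchar(intron_seq), 3L + nchar(block) - 3L),
                    ncol = 2, byrow = TRUE)
    exons[2, 2] <- nchar(block)
  }
  list(seq = block, exons = exons)
}

#' Derive the target genome from the reference world
#'
#' Genes are placed in ancestral order with occasional adjacent swaps and
#' strand inversions, separated by random intergenic spacers. In WGD mode
#' the whole gene complement is duplicated onto two scaffolds and one copy
#' of each non-retained pillar is deleted at random (a 2:1 syntenic
#' relationship to the ancestral order). Target coding sequences are
#' back-translations of the ancestral protein after applying the divergence
#' substitution rate; intron-bearing pillars receive one motif-compliant
#' intron. The truth is returned as exact gene models.
#'
#' @param world result of [build_reference_world()]
#' @param spec the [fixture_spec()]
#' @return list(genome, truth_models = list of [gene_model()],
#'   truth = data.frame with per-gene metadata)
#' @export
derive_target_genome <- function(world, spec) {
  with_fixture_seed(spec$seed, 1L, {
    n <- spec$n_pillars
    order_ids <- world$db$ancestral_order$chrA
    # adjacent swaps
    for (i in seq_len(max(n - 1L, 0L))) {
      if (stats::runif(1) < spec$shuffle_prob) {
        tmp <- order_ids[i]
        order_ids[i] <- order_ids[i + 1L]
        order_ids[i + 1L] <- tmp
      }
    }
    scaffold_sets <- if (spec$wgd) {
      retained <- stats::runif(n) < spec$wgd_retention
      names(retained) <- world$db$ancestral_order$chrA
      pick <- stats::runif(n) < 0.5
      names(pick) <- names(retained)
      list(scf1 = order_ids[retained[order_ids] | pick[order_ids]],
           scf2 = order_ids[retained[order_ids] | !pick[order_ids]])
    } else list(scf1 = order_ids)

    tandem_ids <- character(0)
    if (spec$tandem_count > 0) {
      elig <- order_ids[!world$truth$has_intron[match(order_ids,
                                                      world$truth$pillar_id)]]
      tandem_ids <- head(elig, spec$tandem_count)
    }

    seqs <- list()
    truth_models <- list()
    truth_rows <- list()
    gi <- 0L
    for (sc in names(scaffold_sets)) {
      parts <- character(0)
      pos <- 0L
      emit_gene <- function(pid, type) {
        tr <- world$truth[world$truth$pillar_id == pid, ]
        target <- mutate_protein(tr$ancestral_protein, spec$divergence)
        if (tr$has_intron) {
          e1 <- sample(4:40, 1L)
          blk <- build_gene_block(target, random_intron(), e1)
        } else blk <- build_gene_block(target)
        strand <- if (stats::runif(1) < spec$inversion_prob) "-" else "+"
        seq <- blk$seq
        exons <- blk$exons
        if (strand == "-") {
          seq <- revcomp(seq)
          bl <- nchar(seq)
          exons <- matrix(c(bl - exons[, 2], bl - exons[, 1]), ncol = 2)
          if (nrow(exons) == 2L) exons <- exons[2:1, , drop = FALSE]
          # keep rows 5'->3' on the coding strand: exon1 first
          exons <- exons[nrow(exons):1, , drop = FALSE]
        }
        spacer <- random_dna(sample(300:800, 1L))
        parts <<- c(parts, spacer, seq)
        gstart <- pos + nchar(spacer)
        pos <<- gstart + nchar(seq)
        gi <<- gi + 1L
        id <- sprintf("G%04d", gi)
        truth_models[[length(truth_models) + 1L]] <<- gene_model(
          id, sc, strand, exons + gstart,
          pillar_id = if (type == "ty") NA_character_ else pid)
        truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
          gene_id = id, pillar_id = pid, scaffold = sc, strand = strand,
          type = type, has_intron = tr$has_intron,
          start = gstart + min(exons[, 1]), end = gstart + max(exons[, 2]),
          stringsAsFactors = FALSE)
        invisible(NULL)
      }
      for (pid in scaffold_sets[[sc]]) {
        emit_gene(pid, "normal")
        if (pid %in% tandem_ids && sc == "scf1")
          emit_gene(pid, "tandem")
      }
      parts <- c(parts, random_dna(sample(300:800, 1L)))
      seqs[[sc]] <- paste(parts, collapse = "")
    }

    if (spec$ty_copies > 0) {
      ty_prot <- world$db$pillars[["TY0001"]]$members[[1]]$protein
      for (k in seq_len(spec$ty_copies)) {
        sc <- sample(names(seqs), 1L)
        blk <- build_gene_block(ty_prot)
        gstart <- nchar(seqs[[sc]]) + sample(100:200, 1L)
        pad <- random_dna(gstart - nchar(seqs[[sc]]))
        seqs[[sc]] <- paste0(seqs[[sc]], pad, blk$seq)
        gi <- gi + 1L
        id <- sprintf("G%04d", gi)
        truth_models[[length(truth_models) + 1L]] <- gene_model(
          id, sc, "+", blk$exons + gstart, tags = "ty")
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          gene_id = id, pillar_id = "TY0001", scaffold = sc, strand = "+",
          type = "ty", has_intron = FALSE,
          start = gstart + blk$exons[1, 1], end = gstart + blk$exons[1, 2],
          stringsAsFactors = FALSE)
      }
      for (sc in names(seqs))
        seqs[[sc]] <- paste0(seqs[[sc]], random_dna(300L))
    }
    list(genome = genome(seqs),
         truth_models = truth_models,
         truth = do.call(rbind, truth_rows))
  })
}

#' Inject frameshift errors and simulate paired reads
#'
#' Reads are simulated error-free from the true (pre-edit) genome at the
#' requested coverage; 1-bp indels (deletions three times as often as
#' insertions, matching the dominance of base additions among real
#' corrections of pyrosequencing assemblies) are then placed inside coding
#' regions, biased to homopolymer runs, so that the reads out-vote the
#' assembly error. Truth edits record the reverse (fixing) edit in edited-
#' genome coordinates, normalized to the leftmost position of the
#' homopolymer run.
#'
#' @param derived result of [derive_target_genome()]
#' @param spec the [fixture_spec()]
#' @return list(genome = edited genome, reads = named character vector,
#'   truth_edits = data.frame(scaffold, position, op, bases), n_injected)
#' @export
inject_frameshifts_and_reads <- function(derived, spec) {
  with_fixture_seed(spec$seed, 2L, {
    g <- derived$genome
    reads <- character(0)
    if (spec$read_coverage > 0) {
      rl <- spec$read_length
      ins <- spec$insert_size
      ri <- 0L
      for (sc in names(g$sequences)) {
        L <- g$lengths[[sc]]
        n_pairs <- ceiling(spec$read_coverage * L / (2 * rl))
        starts <- sample.int(max(L - ins, 1L), n_pairs, replace = TRUE) - 1L
        for (st in starts) {
          frag <- subseq0(g$sequences[[sc]], st, min(st + ins, L))
          ri <- ri + 1L
          reads[[sprintf("rd%06d/1", ri)]] <- substr(frag, 1L, rl)
          reads[[sprintf("rd%06d/2", ri)]] <-
            revcomp(substr(frag, nchar(frag) - rl + 1L, nchar(frag)))
        }
      }
    }
    edits <- list()
    if (spec$frameshift_count > 0) {
      elig <- derived$truth[derived$truth$type == "normal" &
                            !derived$truth$has_intron, , drop = FALSE]
      elig <- elig[sample.int(nrow(elig)), , drop = FALSE]
      taken <- 0L
      for (i in seq_len(nrow(elig))) {
        if (taken >= spec$frameshift_count) break
        tr <- elig[i, ]
        seq <- g$sequences[[tr$scaffold]]
        # keep >= 35 codons on each side so both broken fragments remain
        # long enough to produce their own translated hit
        core <- subseq0(seq, tr$start + 105L, tr$end - 105L)
        hit <- regexpr("(A{3,}|C{3,}|G{3,}|T{3,})", core)
        if (hit[1] == -1) next
        pos <- tr$start + 60L + as.integer(hit[1]) - 1L   # run start, 0-based
        base <- substr(seq, pos + 1L, pos + 1L)
        op <- if (stats::runif(1) < 0.75) "delete" else "insert"
        edits[[length(edits) + 1L]] <- list(scaffold = tr$scaffold,
                                            pos = pos, op = op, base = base)
        taken <- taken + 1L
      }
    }
    # apply edits right-to-left; record fixing edits in edited coordinates
    seqs <- g$sequences
    truth_rows <- list()
    by_sc <- split(edits, vapply(edits, `[[`, character(1), "scaffold"))
    for (sc in names(by_sc)) {
      es <- by_sc[[sc]]
      pos <- vapply(es, `[[`, numeric(1), "pos")
      o <- order(pos)
      shift <- 0L
      for (k in o) {
        e <- es[[k]]
        s <- seqs[[sc]]
        p <- e$pos + shift
        if (e$op == "delete") {
          seqs[[sc]] <- paste0(substr(s, 1L, p), substr(s, p + 2L, nchar(s)))
          shift <- shift - 1L
          fix_op <- "insert"
        } else {
          seqs[[sc]] <- paste0(substr(s, 1L, p), e$base,
                               substr(s, p + 1L, nchar(s)))
          shift <- shift + 1L
          fix_op <- "delete"
        }
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          scaffold = sc, position = p, op = fix_op, bases = e$base,
          stringsAsFactors = FALSE)
      }
    }
    edited <- genome(seqs)
    truth_edits <- if (length(truth_rows)) do.call(rbind, truth_rows)
      else data.frame(scaffold = character(0), position = numeric(0),
                      op = character(0), bases = character(0))
    # canonicalize positions to the leftmost equivalent placement
    if (nrow(truth_edits)) {
      truth_edits$position <- vapply(seq_len(nrow(truth_edits)), function(i)
        normalize_indel_pos(edited$sequences[[truth_edits$scaffold[i]]],
                            truth_edits$position[i], truth_edits$op[i],
                            truth_edits$bases[i]), integer(1))
    }
    list(genome = edited, reads = reads, truth_edits = truth_edits,
         n_injected = length(edits))
  })
}

#' Materialize a complete fixture
#'
#' @param spec a [fixture_spec()]
#' @return list(spec, db, world_truth, genome (edited), true_genome,
#'   truth_models, truth, reads, truth_edits)
#' @export
make_fixture <- function(spec) {
  world <- build_reference_world(spec)
  derived <- derive_target_genome(world, spec)
  inj <- inject_frameshifts_and_reads(derived, spec)
  list(spec = spec, db = world$db, world_truth = world$truth,
       genome = inj$genome, true_genome = derived$genome,
       truth_models = derived$truth_models, truth = derived$truth,
       reads = inj$reads, truth_edits = inj$truth_edits)
}

#' Write a fixture to a directory of standard files
#'
#' Emits scaffolds FASTA, pillar DB JSON, reads FASTA (if any) and the
#' ground-truth GFF3.
#'
#' @param fix result of [make_fixture()]
#' @param dir output directory
#' @return dir invisibly
#' @export
write_fixture_dir <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(unlist(fix$genome$sequences),
              file.path(dir, "scaffolds.fasta"))
  write_pillar_db(fix$db, file.path(dir, "pillars.json"))
  if (length(fix$reads))
    write_fasta(fix$reads, file.path(dir, "reads.fasta"))
  write_gff3(fix$truth_models, NULL, file.path(dir, "truth.gff3"),
             fix$genome)
  invisible(dir)
}

#' Scaffold-integrity fixture: contigs, scaffolds and spanning read pairs
#'
#' One true chromosome (contigs A-B-C-D) generates the paired reads. The
#' scaffold joins the contigs with N gaps either in the true order, or
#' (with `misjoin = TRUE`) as A-B-D-C, which plants exactly one chimeric
#' join (B-D) with no spanning read pairs while every other declared join is
#' a true junction.
#'
#' @param seed RNG seed
#' @param contig_len contig length (bp)
#' @param coverage read-pair coverage of the true chromosome
#' @param read_length read length (bp)
#' @param insert_size pair outer distance (bp)
#' @param misjoin plant the chimeric join?
#' @return list(contigs, reads, genome, true_joins, planted_misjoins)
#' @export
make_qc_fixture <- function(seed, contig_len = 4000L, coverage = 15,
                            read_length = 300L, insert_size = 900L,
                            misjoin = FALSE) {
  with_fixture_seed(seed, 3L, {
    contigs <- setNames(
      vapply(1:4, function(i) random_dna(contig_len), character(1)),
      c("ctgA", "ctgB", "ctgC", "ctgD"))
    chr <- paste(contigs, collapse = "")
    gap <- strrep("N", 20L)
    if (misjoin) {
      scafs <- c(scaf1 = paste(c(contigs[c("ctgA", "ctgB", "ctgD",
                                           "ctgC")]), collapse = gap))
      planted <- data.frame(contig1 = "ctgB", contig2 = "ctgD",
                            stringsAsFactors = FALSE)
    } else {
      scafs <- c(scaf1 = paste(contigs, collapse = gap))
      planted <- data.frame(contig1 = character(0), contig2 = character(0))
    }
    reads <- character(0)
    ri <- 0L
    L <- nchar(chr)
    n_pairs <- ceiling(coverage * L / (2 * read_length))
    starts <- sample.int(L - insert_size, n_pairs, replace = TRUE) - 1L
    for (st in starts) {
      frag <- subseq0(chr, st, st + insert_size)
      ri <- ri + 1L
      reads[[sprintf("qc%05d/1", ri)]] <- substr(frag, 1L, read_length)
      reads[[sprintf("qc%05d/2", ri)]] <-
        revcomp(substr(frag, insert_size - read_length + 1L, insert_size))
    }
    list(contigs = contigs, reads = reads, genome = genome(scafs),
         true_joins = data.frame(contig1 = c("ctgA", "ctgB", "ctgC"),
                                 contig2 = c("ctgB", "ctgC", "ctgD"),
                                 stringsAsFactors = FALSE),
         planted_misjoins = planted)
  })
}
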