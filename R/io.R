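# Cohort serialization: FASTA (Biostrings), GFF3 (1-based inclusive,
# rtracklayer for reading), dot-bracket structure db, truth TSV, Newick trees.

write_structure_db <- function(structures, sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(structures)) {
    writeLines(c(paste0(">", id), sequences[[id]], structures[[id]]), con)
  }
  invisible(path)
}

#' Read a dot-bracket structure database
#'
#' Format: per record an id line (`>id`), a sequence line and a structure
#' line.
#'
#' @param path File path.
#' @return data.frame with `id`, `sequence`, `structure`.
#' @export
read_structure_db <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3L != 0L) stop("malformed structure db: ", path, call. = FALSE)
  idx <- seq(1L, length(lines), by = 3L)
  ids <- sub("^>", "", lines[idx])
  data.frame(id = ids, sequence = dna_to_rna(lines[idx + 1L]),
             structure = lines[idx + 2L], stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk
#'
#' Emits `genomes.fasta`, `genes.gff3` (1-based inclusive, `gene`, `exon` and
#' `intron` features), `introns.fasta`, `ref_genes.fasta`, `structures.db`,
#' `truth.tsv`, `manifest.tsv`, `tree.nwk` and (when present)
#' `family_tree.nwk`.
#'
#' @param cohort An `intron_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
emit_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "intron_cohort"))
  if (!NROW(cohort$introns)) stop("cohort has no introns", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)

  gseq <- Biostrings::DNAStringSet(vapply(cohort$genomes, `[[`, character(1L), "sequence"))
  names(gseq) <- vapply(cohort$genomes, `[[`, character(1L), "id")
  Biostrings::writeXStringSet(gseq, file.path(out_dir, "genomes.fasta"), width = 80L)

  iseq <- Biostrings::DNAStringSet(rna_to_dna(cohort$introns$sequence))
  names(iseq) <- cohort$introns$key
  Biostrings::writeXStringSet(iseq, file.path(out_dir, "introns.fasta"), width = 80L)

  rseq <- Biostrings::DNAStringSet(rna_to_dna(unlist(cohort$reference_genes)))
  names(rseq) <- names(cohort$reference_genes)
  Biostrings::writeXStringSet(rseq, file.path(out_dir, "ref_genes.fasta"), width = 80L)

  gff <- NULL
  for (g in cohort$genomes) {
    gm <- g$gene_models
    attrs <- character(nrow(gm))
    for (i in seq_len(nrow(gm))) {
      if (gm$type[i] == "intron") {
        attrs[i] <- paste0("ID=", gm$genome_id[i], ":", gm$family[i],
                           ";Name=", gm$family[i], ";gene=", gm$gene[i],
                           ";site=", gm$site[i])
      } else {
        attrs[i] <- paste0("ID=", gm$genome_id[i], ":", gm$gene[i], ":",
                           gm$type[i], ":", gm$start[i], ";gene=", gm$gene[i])
      }
    }
    gff <- rbind(gff, data.frame(
      seqid = gm$genome_id, source = "intronscape", type = gm$type,
      start = gm$start, end = gm$end, score = ".", strand = gm$strand,
      phase = ".", attributes = attrs, stringsAsFactors = FALSE
    ))
  }
  gff_path <- file.path(out_dir, "genes.gff3")
  writeLines("##gff-version 3", gff_path)
  suppressWarnings(write.table(gff, gff_path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE, append = TRUE))

  seqs <- setNames(as.list(rna_to_dna(cohort$introns$sequence)), cohort$introns$key)
  write_structure_db(as.list(cohort$structures[cohort$introns$key]), seqs,
                     file.path(out_dir, "structures.db"))

  write.table(cohort$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- data.frame(
    genome_id = vapply(cohort$genomes, `[[`, character(1L), "id"),
    organelle = vapply(cohort$genomes, `[[`, character(1L), "organelle"),
    species = vapply(cohort$genomes, `[[`, character(1L), "species"),
    stringsAsFactors = FALSE
  )
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ape::write.tree(cohort$species_tree, file.path(out_dir, "tree.nwk"))
  if (!is.null(cohort$family_tree)) {
    ape::write.tree(cohort$family_tree, file.path(out_dir, "family_tree.nwk"))
  }
  invisible(out_dir)
}

#' Load a cohort from disk into intron records
#'
#' Reads genomes (FASTA), gene models (GFF3, 1-based inclusive) and the
#' structure db, and builds one intron record per GFF3 `intron` feature:
#' sequence extracted from the genome (reverse-complemented on the `-`
#' strand, then converted to the RNA alphabet), with upstream/downstream exon
#' flanks of up to 20 nt taken from the annotated neighbouring exons (a
#' shorter exon yields a short flank and a warning).
#'
#' @param dir Cohort directory as written by [emit_cohort()], or a list of
#'   paths with elements `genomes`, `gff3`, `structures` (optional),
#'   `ref_genes` (optional), `truth` (optional), `tree` (optional).
#' @param flank_len Maximum exon flank length (default 20).
#' @return List with `introns` (data.frame of intron records), `genomes`
#'   (named DNA sequences), `reference_genes`, `truth`, `species_tree`.
#' @export
load_cohort <- function(dir, flank_len = 20L) {
  paths <- if (is.list(dir)) dir else list(
    genomes = file.path(dir, "genomes.fasta"),
    gff3 = file.path(dir, "genes.gff3"),
    structures = file.path(dir, "structures.db"),
    ref_genes = file.path(dir, "ref_genes.fasta"),
    truth = file.path(dir, "truth.tsv"),
    tree = file.path(dir, "tree.nwk")
  )
  gset <- Biostrings::readDNAStringSet(paths$genomes)
  genomes <- setNames(as.character(gset), names(gset))
  gr <- rtracklayer::import(paths$gff3)
  feat <- as.data.frame(gr)
  feat$seqnames <- as.character(feat$seqnames)
  feat$type <- as.character(feat$type)
  feat$strand <- as.character(feat$strand)

  structures <- NULL
  if (!is.null(paths$structures) && file.exists(paths$structures)) {
    sdb <- read_structure_db(paths$structures)
    structures <- setNames(sdb$structure, sdb$id)
  }

  introns <- feat[feat$type == "intron", , drop = FALSE]
  missing <- setdiff(unique(introns$seqnames), names(genomes))
  if (length(missing)) {
    stop("GFF3 records reference missing genomes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  exons <- feat[feat$type == "exon", , drop = FALSE]
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

  rows <- list()
  for (i in seq_len(nrow(introns))) {
    it <- introns[i, ]
    gseq <- genomes[[it$seqnames]]
    iseq <- substr(gseq, it$start, it$end)
    minus <- identical(it$strand, "-")
    if (minus) iseq <- rc(iseq)
    gene <- if (!is.null(it$gene)) it$gene else NA_character_
    ex <- exons[exons$seqnames == it$seqnames & exons$gene %in% gene, , drop = FALSE]
    # transcript-orientation upstream/downstream exons
    if (!minus) {
      up <- ex[ex$end == it$start - 1L, , drop = FALSE]
      dn <- ex[ex$start == it$end + 1L, , drop = FALSE]
    } else {
      up <- ex[ex$start == it$end + 1L, , drop = FALSE]
      dn <- ex[ex$end == it$start - 1L, , drop = FALSE]
    }
    take_flank <- function(exrow, side) {
      if (!nrow(exrow)) return(NA_character_)
      s <- substr(gseq, exrow$start[1L], exrow$end[1L])
      if (minus) s <- rc(s)
      w <- nchar(s)
      if (w < flank_len) {
        warning("short exon flank (", w, " nt) for intron ", it$ID)
      }
      if (side == "up") substr(s, max(1L, w - flank_len + 1L), w)
      else substr(s, 1L, min(flank_len, w))
    }
    key <- as.character(it$ID)
    site <- if (!is.null(it$site)) as.integer(it$site) else NA_integer_
    rows[[i]] <- data.frame(
      key = key,
      intron_id = as.character(it$Name), genome_id = it$seqnames,
      host_gene = gene, site = site,
      sequence = dna_to_rna(iseq),
      structure = if (!is.null(structures) && key %in% names(structures)) {
        structures[[key]]
      } else NA_character_,
      upstream_flank = dna_to_rna(take_flank(up, "up")),
      downstream_flank = dna_to_rna(take_flank(dn, "down")),
      strand = it$strand, start = it$start, end = it$end,
      stringsAsFactors = FALSE
    )
  }
  intron_df <- do.call(rbind, rows)
  rownames(intron_df) <- NULL

  ref_genes <- NULL
  if (!is.null(paths$ref_genes) && file.exists(paths$ref_genes)) {
    rset <- Biostrings::readDNAStringSet(paths$ref_genes)
    ref_genes <- setNames(dna_to_rna(as.character(rset)), names(rset))
  }
  truth <- if (!is.null(paths$truth) && file.exists(paths$truth)) {
    read.delim(paths$truth, stringsAsFactors = FALSE)
  } else NULL
  tree <- if (!is.null(paths$tree) && file.exists(paths$tree)) {
    ape::read.tree(paths$tree)
  } else NULL
  list(introns = intron_df, genomes = genomes, reference_genes = ref_genes,
       truth = truth, species_tree = tree)
}
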