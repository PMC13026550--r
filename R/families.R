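# Intron family definition: insertion-site mapping onto reference genes,
# site+homology clustering, seed-and-extend member search, and occurrence
# frequency across genome cohorts.

local_sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3, baseOnly = TRUE)
}

#' Map an intron's insertion site onto a reference host gene
#'
#' The upstream exon flank is locally aligned to the reference gene (match +2,
#' mismatch -3, gap open -5, gap extend -2); the insertion site is the
#' reference coordinate of the last aligned base of the flank (the intron lies
#' between `site` and `site + 1`).
#'
#' @param intron An intron record (list/row with `upstream_flank`) or the
#'   upstream flank string itself (>= 10 nt).
#' @param reference_gene Reference gene nucleotide sequence.
#' @return List with `site`, `score` and `identity` (percent).
#' @export
map_insertion_site <- function(intron, reference_gene) {
  flank <- if (is.character(intron)) intron else intron$upstream_flank
  stopifnot(is.character(flank), length(flank) == 1L)
  if (nchar(flank) < 10L) stop("upstream flank shorter than 10 nt", call. = FALSE)
  p <- Biostrings::DNAString(rna_to_dna(flank))
  s <- Biostrings::DNAString(rna_to_dna(reference_gene))
  aln <- Biostrings::pairwiseAlignment(
    p, s, type = "local", substitutionMatrix = local_sub_matrix(),
    gapOpening = 5, gapExtension = 2
  )
  # identity relative to the full flank: a short perfect local match on an
  # unrelated reference (e.g. a poly-A run) must not count as mappable
  identity <- 100 * Biostrings::nmatch(aln) / nchar(flank)
  if (identity < 60) {
    stop("unmappable insertion site: best local alignment identity ",
         round(identity, 1), "% < 60%", call. = FALSE)
  }
  list(site = Biostrings::end(Biostrings::subject(aln)),
       score = Biostrings::score(aln), identity = identity)
}

# Global percent identity between two sequences relative to the shorter one;
# equal-length pairs take a fast gap-free path (the generator introduces no
# indels, so this is the common case).
pairwise_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    va <- seq_chars(toupper(a)); vb <- seq_chars(toupper(b))
    return(sum(va == vb) / length(va))
  }
  pa <- Biostrings::DNAString(rna_to_dna(a))
  pb <- Biostrings::DNAString(rna_to_dna(b))
  aln <- Biostrings::pairwiseAlignment(
    pa, pb, type = "global", substitutionMatrix = local_sub_matrix(),
    gapOpening = 5, gapExtension = 2
  )
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Group introns into families by shared insertion site and sequence homology
#'
#' Each intron's upstream flank is mapped onto the reference copy of its host
#' gene; introns sharing (gene, mapped site) AND clustering by single linkage
#' at `identity_threshold` global identity (relative to the shorter sequence)
#' form one family, named `gene-site`. Co-sited but non-homologous clusters
#' get suffixed ids (`gene-site.2`, ...) in decreasing cluster size.
#' Unmappable introns are returned in an `unassigned` bin.
#'
#' @param introns data.frame with columns `key` (unique id), `host_gene`,
#'   `sequence`, `upstream_flank`.
#' @param reference_genes Named character vector of reference gene sequences,
#'   keyed by gene name.
#' @param identity_threshold Homology threshold (default 0.6).
#' @return List with `assignments` (data.frame: key, family, gene, site) and
#'   `unassigned` (keys with the mapping failure message).
#' @export
assign_families <- function(introns, reference_genes, identity_threshold = 0.6) {
  stopifnot(all(c("key", "host_gene", "sequence", "upstream_flank") %in% names(introns)))
  n <- nrow(introns)
  site <- rep(NA_integer_, n)
  fail <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    g <- introns$host_gene[i]
    if (!g %in% names(reference_genes)) {
      fail[i] <- paste0("no reference gene '", g, "'")
      next
    }
    res <- tryCatch(
      map_insertion_site(introns$upstream_flank[i], reference_genes[[g]]),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) fail[i] <- res else site[i] <- res$site
  }
  ok <- which(is.na(fail))
  assignments <- NULL
  groups <- split(ok, paste(introns$host_gene[ok], site[ok], sep = "\r"))
  for (idx in groups) {
    gene <- introns$host_gene[idx[1L]]
    s <- site[idx[1L]]
    # single-linkage clustering on pairwise identity
    parent <- seq_along(idx)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (length(idx) > 1L) {
      for (a in seq_len(length(idx) - 1L)) {
        for (b in (a + 1L):length(idx)) {
          if (find(a) == find(b)) next
          id <- pairwise_identity(introns$sequence[idx[a]], introns$sequence[idx[b]])
          if (id >= identity_threshold) parent[find(b)] <- find(a)
        }
      }
    }
    roots <- vapply(seq_along(idx), find, integer(1L))
    clusters <- split(seq_along(idx), roots)
    # order clusters by size desc, then by smallest member key for determinism
    sizes <- vapply(clusters, length, integer(1L))
    firsts <- vapply(clusters, function(m) min(introns$key[idx[m]]), character(1L))
    ord <- order(-sizes, firsts)
    base <- name_intron(gene, s)
    for (ci in seq_along(ord)) {
      fam <- if (ci == 1L) base else paste0(base, ".", ci)
      members <- idx[clusters[[ord[ci]]]]
      assignments <- rbind(assignments, data.frame(
        key = introns$key[members], family = fam, gene = gene, site = s,
        stringsAsFactors = FALSE
      ))
    }
  }
  unassigned <- data.frame(key = introns$key[!is.na(fail)],
                           reason = fail[!is.na(fail)], stringsAsFactors = FALSE)
  list(assignments = assignments, unassigned = unassigned)
}

# Karlin-Altschul-style E-value for an ungapped nucleotide scoring system
# (+2/-3 defaults); parity with any particular BLAST build is not promised --
# the cutoff semantics are what matter.
ka_evalue <- function(score, m, n, lambda = 0.625, K = 0.41) {
  K * m * n * exp(-lambda * score)
}

#' Seed-and-extend homology search of a family probe against a genome
#'
#' BLASTN-style search: exact word seeds (default word size 11) are located on
#' shared diagonals, seed clusters are extended by gapped local alignment
#' (match +2, mismatch -3, gap open -5, gap extend -2), and hits are assigned
#' a Karlin-Altschul-style E-value. Hits are filtered by `E <= evalue_cutoff`
#' and query coverage `>= min_coverage`, and sorted by E then identity.
#'
#' @param probe Probe nucleotide sequence (>= 50 nt and >= word size).
#' @param genome Genome sequence string, or a list with `$sequence` and `$id`.
#' @param evalue_cutoff Maximum E-value (default 1e-5).
#' @param min_coverage Minimum query coverage fraction (default 0.3).
#' @param word_size Seed word size (default 11).
#' @return data.frame of hits: `subject_id`, `start`, `end`, `pident`,
#'   `length`, `evalue`, `coverage`, `score`.
#' @export
search_family_members <- function(probe, genome, evalue_cutoff = 1e-5,
                                  min_coverage = 0.3, word_size = 11L) {
  subject_id <- if (is.list(genome)) genome$id else NA_character_
  gseq <- toupper(rna_to_dna(if (is.list(genome)) genome$sequence else genome))
  pseq <- toupper(rna_to_dna(probe))
  if (nchar(pseq) < word_size) stop("probe shorter than word size", call. = FALSE)
  if (nchar(pseq) < 50L) stop("probe shorter than 50 nt", call. = FALSE)
  m <- nchar(pseq); n <- nchar(gseq)

  gwords <- substring(gseq, seq_len(n - word_size + 1L),
                      seq_len(n - word_size + 1L) + word_size - 1L)
  gindex <- split(seq_along(gwords), gwords)
  pwords <- substring(pseq, seq_len(m - word_size + 1L),
                      seq_len(m - word_size + 1L) + word_size - 1L)
  seeds <- NULL
  for (p in seq_along(pwords)) {
    gpos <- gindex[[pwords[p]]]
    if (!is.null(gpos)) seeds <- rbind(seeds, cbind(p = p, g = gpos))
  }
  empty <- data.frame(subject_id = character(0), start = integer(0),
                      end = integer(0), pident = numeric(0), length = integer(0),
                      evalue = numeric(0), coverage = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(seeds)) return(empty)

  # Cluster seeds into candidate regions: same neighbourhood of diagonals.
  diag <- seeds[, "g"] - seeds[, "p"]
  ord <- order(diag, seeds[, "g"])
  seeds <- seeds[ord, , drop = FALSE]
  diag <- diag[ord]
  grp <- cumsum(c(1L, diff(diag) > 100L))
  hits <- empty
  sub_mat <- local_sub_matrix()
  for (g_id in unique(grp)) {
    s <- seeds[grp == g_id, , drop = FALSE]
    w0 <- max(1L, min(s[, "g"]) - min(s[, "p"]) - 20L)
    w1 <- min(n, max(s[, "g"]) + (m - max(s[, "p"])) + 20L)
    window <- substr(gseq, w0, w1)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(pseq), Biostrings::DNAString(window),
      type = "local", substitutionMatrix = sub_mat,
      gapOpening = 5, gapExtension = 2
    )
    score <- Biostrings::score(aln)
    ev <- ka_evalue(score, m, n)
    qw <- Biostrings::width(Biostrings::pattern(aln))
    cov <- qw / m
    if (ev <= evalue_cutoff && cov >= min_coverage) {
      hits <- rbind(hits, data.frame(
        subject_id = subject_id,
        start = w0 + Biostrings::start(Biostrings::subject(aln)) - 1L,
        end = w0 + Biostrings::end(Biostrings::subject(aln)) - 1L,
        pident = Biostrings::pid(aln, type = "PID1"),
        length = Biostrings::nchar(aln),
        evalue = ev, coverage = cov, score = score,
        stringsAsFactors = FALSE
      ))
    }
  }
  if (nrow(hits)) {
    hits <- hits[!duplicated(hits[, c("start", "end")]), , drop = FALSE]
    hits <- hits[order(hits$evalue, -hits$pident), , drop = FALSE]
  }
  hits
}

#' Build a family x genome presence/absence matrix
#'
#' @param assignments Assignment data.frame (from [assign_families()] or the
#'   cohort truth) with columns `family` and `genome_id`.
#' @param genome_ids All genome ids of the compartment (matrix columns);
#'   defaults to those seen in `assignments`.
#' @return Logical matrix, rows = families, columns = genomes.
#' @export
build_presence_matrix <- function(assignments, genome_ids = NULL) {
  stopifnot(all(c("family", "genome_id") %in% names(assignments)))
  if (is.null(genome_ids)) genome_ids <- sort(unique(assignments$genome_id))
  fams <- sort(unique(assignments$family))
  mat <- matrix(FALSE, length(fams), length(genome_ids),
                dimnames = list(fams, genome_ids))
  for (r in seq_len(nrow(assignments))) {
    mat[assignments$family[r], assignments$genome_id[r]] <- TRUE
  }
  mat
}

#' Occurrence frequency and distribution breadth of intron families
#'
#' Frequency = genomes containing the family / genomes sampled, reported as a
#' percent rounded to one decimal. Families present in more than 40% of
#' genomes are classed `broad`, below 15% `narrow`, otherwise `intermediate`.
#' Compartments (mt/cp) should be summarised separately so their denominators
#' stay distinct.
#'
#' @param presence Logical (or 0/1) matrix, rows = families, columns = genomes.
#' @return data.frame: family, count, denominator, percent, class.
#' @export
occurrence_frequency <- function(presence) {
  if (is.null(dim(presence)) || ncol(presence) < 1L || nrow(presence) < 1L) {
    stop("presence matrix must have at least one family and one genome", call. = FALSE)
  }
  counts <- rowSums(presence != 0)
  n <- ncol(presence)
  freq <- 100 * counts / n
  cls <- ifelse(freq > 40, "broad", ifelse(freq < 15, "narrow", "intermediate"))
  data.frame(
    family = rownames(presence), count = as.integer(counts), denominator = n,
    percent = round(freq, 1), class = cls,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
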