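#' Gene annotation
#'
#' A gene model whose exon list is in *transcription order*, not genomic
#' order. This is what lets a single data structure carry both cis-spliced
#' genes (contiguous, ordered exons) and the trans-spliced genes that are a
#' hallmark of rearranged conifer mitogenomes: exons of one mRNA scattered
#' across the circle, possibly on different strands.
#'
#' @param gene_id gene identifier.
#' @param biotype one of `"CDS"`, `"tRNA"`, `"rRNA"`, `"ORF"`.
#' @param exons list of [segment_interval]s in transcription order.
#' @param codon_start 0-2 offset trimmed from the spliced transcript before
#'   translation (GFF3 phase convention).
#' @return a `gene_annotation` object.
#' @export
gene_annotation <- function(gene_id, biotype = c("CDS", "tRNA", "rRNA", "ORF"),
                            exons, codon_start = 0L) {
  biotype <- match.arg(biotype)
  stopifnot(length(exons) >= 1L, codon_start %in% 0:2)
  if (!all(vapply(exons, inherits, logical(1L), "segment_interval")))
    stop("exons must be segment_interval objects")
  structure(list(gene_id = gene_id, biotype = biotype, exons = exons,
                 codon_start = as.integer(codon_start)),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %s (%s), %d exon(s), codon_start %d\n",
              x$gene_id, x$biotype, length(x$exons), x$codon_start))
  invisible(x)
}

spliced_length <- function(gene, genome_length) {
  sum(vapply(gene$exons, seg_length, integer(1L), genome_length))
}

#' Extract the spliced coding sequence of a gene
#'
#' Exons are extracted in transcription order; minus-strand exons are
#' reverse-complemented; segments may wrap the origin of a circular genome.
#' The `codon_start` offset is trimmed so the result begins at codon 1.
#'
#' @param genome a [genome_record].
#' @param gene a [gene_annotation] with `biotype == "CDS"` (or `"ORF"`).
#' @return the spliced CDS as a DNA string.
#' @export
extract_spliced_cds <- function(genome, gene) {
  if (!gene$biotype %in% c("CDS", "ORF"))
    stop("extract_spliced_cds requires a CDS/ORF gene, got ", gene$biotype)
  parts <- vapply(gene$exons, function(ex) {
    s <- extract_segment(genome, ex)
    if (ex$strand == "-") revcomp(s) else s
  }, character(1L))
  cds <- paste(parts, collapse = "")
  if (gene$codon_start > 0L) cds <- substr(cds, gene$codon_start + 1L, nchar(cds))
  if (gene$biotype == "CDS" && nchar(cds) < 3L)
    stop("spliced CDS of '", gene$gene_id, "' shorter than one codon")
  cds
}

# 0-based genomic position of each spliced-CDS position (coding-strand walk,
# codon_start already trimmed). Used by the editing pileup to map CDS
# coordinates back onto the genome.
cds_genomic_positions <- function(genome, gene) {
  pos <- unlist(lapply(gene$exons, function(ex) {
    p <- seg_positions(ex, genome$length)
    if (ex$strand == "-") rev(p) else p
  }), use.names = FALSE)
  strands <- unlist(lapply(gene$exons, function(ex) {
    rep(ex$strand, seg_length(ex, genome$length))
  }), use.names = FALSE)
  if (gene$codon_start > 0L) {
    keep <- -seq_len(gene$codon_start)
    pos <- pos[keep]; strands <- strands[keep]
  }
  data.frame(cds_pos = seq_along(pos) - 1L, genome_pos = pos, strand = strands)
}

# --- GFF3 I/O --------------------------------------------------------------

#' Write gene annotations to GFF3
#'
#' One `gene` feature plus ordered `exon` children per annotation. The
#' `exon_number` attribute encodes transcription order (which for
#' trans-spliced genes differs from coordinate order). Internal 0-based
#' half-open coordinates are converted to GFF3's 1-based inclusive; an
#' origin-wrapping exon is written as `start > end`-free by using
#' `end = start + len - 1` beyond the sequence length (the reader folds it
#' back), a convention some organelle annotation tools also use.
#'
#' @param annotations list of [gene_annotation]s.
#' @param genome the [genome_record] they annotate.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotations, genome, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$id, genome$length))
  for (g in annotations) {
    L <- genome$length
    spans <- vapply(g$exons, function(ex) {
      if (ex$wraps_origin) c(ex$start + 1L, L + ex$end)
      else c(ex$start + 1L, ex$end)
    }, integer(2L))
    gene_start <- min(spans[1L, ]); gene_end <- max(spans[2L, ])
    strand0 <- g$exons[[1L]]$strand
    lines <- c(lines, paste(
      genome$id, "orgkit", "gene", gene_start, gene_end, ".", strand0, ".",
      sprintf("ID=%s;biotype=%s", g$gene_id, g$biotype), sep = "\t"))
    for (i in seq_along(g$exons)) {
      ex <- g$exons[[i]]
      phase <- if (i == 1L) g$codon_start else "."
      lines <- c(lines, paste(
        genome$id, "orgkit", "exon", spans[1L, i], spans[2L, i], ".",
        ex$strand, as.character(phase),
        sprintf("ID=%s.exon%d;Parent=%s;exon_number=%d", g$gene_id, i, g$gene_id, i),
        sep = "\t"))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Parses with `rtracklayer`, then rebuilds [gene_annotation]s from `exon`
#' features grouped by `Parent` and ordered by their `exon_number` attribute.
#' Exon ends beyond the sequence length are folded back as origin-wrapping
#' segments (circular genomes only).
#'
#' @param path GFF3 path.
#' @param genome the [genome_record] the file annotates.
#' @return named list of [gene_annotation]s, in file order.
#' @export
read_gff3 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  genes <- df[df$type == "gene", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  if (nrow(genes) == 0L) return(list())
  bad <- setdiff(unique(df$seqnames), genome$id)
  if (length(bad))
    stop("GFF3 sequence id(s) ", paste(bad, collapse = ", "),
         " do not match genome '", genome$id, "'")
  parents <- vapply(exons$Parent, function(p) p[[1L]], character(1L))
  out <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    ex <- exons[parents == gid, , drop = FALSE]
    if (nrow(ex) == 0L) stop("gene '", gid, "' has no exon children")
    ord <- order(as.integer(ex$exon_number))
    ex <- ex[ord, , drop = FALSE]
    segs <- lapply(seq_len(nrow(ex)), function(j) {
      s <- ex$start[j] - 1L; e <- ex$end[j] # to 0-based half-open
      if (e > genome$length) {
        segment_interval(s, e - genome$length, ex$strand[j], wraps_origin = TRUE)
      } else segment_interval(s, e, ex$strand[j])
    })
    phase <- suppressWarnings(as.integer(ex$phase[1L]))
    if (is.na(phase)) phase <- 0L
    biotype <- genes$biotype[i]
    if (is.null(biotype) || is.na(biotype)) biotype <- "CDS"
    gene_annotation(gid, biotype, segs, phase)
  })
  names(out) <- genes$ID
  out
}
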