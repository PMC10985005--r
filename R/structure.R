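# Structural evolution scoring: ancestral gene-cluster retention and
# cis/trans intron classification. Rearrangement-heavy mitogenomes break
# ancestral syntenic blocks and convert cis-spliced group II introns to
# trans-spliced ones; both signals are read directly off gene models.

#' Load a gene-cluster catalog
#'
#' A catalog is a list of named, ordered gene lists. The packaged default
#' (14 ancestral angiosperm mitochondrial clusters) is a documented,
#' replaceable stand-in: three clusters are those named in the conifer
#' synteny literature, the rest are assembled from commonly reported
#' conserved angiosperm syntenies (see the file header).
#'
#' @param path TSV path (`name<TAB>gene1,gene2,...`); default: packaged
#'   catalog.
#' @return named list of character vectors.
#' @export
load_cluster_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ancestral_clusters.synthetic.tsv",
                        package = "orgkit", mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  cl <- lapply(parts, function(p) strsplit(p[2L], ",", fixed = TRUE)[[1L]])
  names(cl) <- vapply(parts, `[[`, character(1L), 1L)
  cl
}

# representative genomic anchor of a gene: start of its first exon, plus the
# strand of that exon (trans-spliced catalog genes are anchored by exon 1)
gene_anchor <- function(g, L) {
  ex <- g$exons[[1L]]
  list(start = ex$start, end = if (ex$wraps_origin) ex$start + seg_length(ex, L)
       else ex$end, strand = ex$strand)
}

#' Score retention of ancestral gene clusters
#'
#' A cluster is retained iff its genes appear consecutively on the circle
#' (no other catalog gene intervening), in catalog order or exactly
#' reversed, all on one strand, with inter-gene gaps of at most `max_gap`.
#' A cluster with any gene absent from the annotations is `unevaluable`,
#' not lost. Gene names are matched case-insensitively.
#'
#' @param annotations list of [gene_annotation]s.
#' @param genome the annotated [genome_record].
#' @param catalog named list of ordered gene vectors
#'   (default [load_cluster_catalog]).
#' @param max_gap maximum allowed inter-gene gap (bp).
#' @return data.frame: `cluster`, `status` (`retained`/`lost`/`unevaluable`),
#'   `reason`, `breakpoint_genes`.
#' @export
check_cluster_retention <- function(annotations, genome,
                                    catalog = load_cluster_catalog(),
                                    max_gap = 5000L) {
  L <- genome$length
  ann_names <- tolower(vapply(annotations, `[[`, character(1L), "gene_id"))
  anchors <- lapply(annotations, gene_anchor, L = L)
  all_catalog_genes <- tolower(unique(unlist(catalog)))
  res <- lapply(names(catalog), function(cname) {
    genes <- tolower(catalog[[cname]])
    idx <- match(genes, ann_names)
    if (anyNA(idx)) {
      return(data.frame(cluster = cname, status = "unevaluable",
                        reason = paste0("absent: ",
                                        paste(genes[is.na(idx)], collapse = ",")),
                        breakpoint_genes = "", stringsAsFactors = FALSE))
    }
    anc <- anchors[idx]
    strands <- vapply(anc, `[[`, character(1L), "strand")
    if (length(unique(strands)) > 1L) {
      bp <- genes[which(strands != strands[1L])]
      return(cluster_row(cname, "lost", "strand_switch", bp))
    }
    # order along the circle: walk from the first gene forward
    starts <- vapply(anc, function(a) a$start, integer(1L))
    ends <- vapply(anc, function(a) a$end, integer(1L))
    ok_fwd <- check_walk(starts, ends, order = seq_along(genes), L, max_gap)
    ok_rev <- check_walk(starts, ends, order = rev(seq_along(genes)), L, max_gap)
    walk <- if (!is.null(ok_fwd$fail)) ok_rev else ok_fwd
    if (!is.null(ok_fwd$fail) && !is.null(ok_rev$fail)) {
      better <- if (ok_fwd$n_ok >= ok_rev$n_ok) ok_fwd else ok_rev
      return(cluster_row(cname, "lost", better$fail,
                         genes[better$fail_at]))
    }
    # no intervening catalog gene inside the cluster arc
    arc_from <- min(starts); arc_span <- walk$span
    others <- setdiff(which(ann_names %in% all_catalog_genes), idx)
    for (oi in others) {
      d <- circ_fwd_dist(walk$arc_start, anchors[[oi]]$start, L)
      if (d < walk$span)
        return(cluster_row(cname, "lost", "intervening_gene",
                           vapply(annotations[oi], `[[`, character(1L), "gene_id")))
    }
    cluster_row(cname, "retained", "", character(0))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

cluster_row <- function(cname, status, reason, bp) {
  data.frame(cluster = cname, status = status, reason = reason,
             breakpoint_genes = paste(bp, collapse = ","),
             stringsAsFactors = FALSE)
}

# walk the genes in the given order along the circle, requiring each next
# gene to start within max_gap after the previous gene's end
check_walk <- function(starts, ends, order, L, max_gap) {
  s <- starts[order]; e <- ends[order]
  n <- length(s)
  if (n == 1L) return(list(arc_start = s[1L], span = e[1L] - s[1L], n_ok = 1L))
  for (i in seq_len(n - 1L)) {
    gap <- circ_fwd_dist(e[i] %% L, s[i + 1L], L)
    if (gap > max_gap) {
      fail <- if (gap > L / 2) "order_violation" else "distance_exceeded"
      return(list(fail = fail, fail_at = order[i + 1L], n_ok = i))
    }
  }
  span <- circ_fwd_dist(s[1L], e[n] %% L, L)
  if (span == 0L) span <- L
  list(arc_start = s[1L], span = span, n_ok = n)
}

#' Classify the introns of a gene as cis- or trans-spliced
#'
#' For each adjacent exon pair in transcription order: cis iff both exons
#' are on the same strand, the genomic step follows the strand's reading
#' direction, and the intron span is at most `max_intron_span` (shorter-arc
#' distances on circular genomes). Otherwise trans, with the triggering
#' evidence code (`strand_switch` > `order_violation` > `distance_exceeded`).
#'
#' @param gene a [gene_annotation] (transcription-ordered exons).
#' @param genome the [genome_record].
#' @param max_intron_span maximum cis intron length (bp).
#' @return data.frame with one row per intron: `gene_id`, `intron_index`,
#'   `mode` (`cis`/`trans`), `evidence`. Single-exon genes give zero rows.
#' @export
classify_intron_splicing <- function(gene, genome, max_intron_span = 50000L) {
  L <- genome$length
  n <- length(gene$exons)
  if (n < 2L)
    return(data.frame(gene_id = character(), intron_index = integer(),
                      mode = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(n - 1L), function(i) {
    e1 <- gene$exons[[i]]; e2 <- gene$exons[[i + 1L]]
    if (e1$strand != e2$strand) {
      mode <- "trans"; evid <- "strand_switch"
    } else {
      if (e1$strand == "+") {
        gap <- if (genome$topology == "circular")
          circ_fwd_dist(seg_end_pos(e1, L), e2$start, L)
        else e2$start - seg_end_pos(e1, L)
      } else {
        gap <- if (genome$topology == "circular")
          circ_fwd_dist(seg_end_pos(e2, L), e1$start, L)
        else e1$start - seg_end_pos(e2, L)
      }
      if (gap < 0L || (genome$topology == "circular" && gap > L / 2)) {
        mode <- "trans"; evid <- "order_violation"
      } else if (gap > max_intron_span) {
        mode <- "trans"; evid <- "distance_exceeded"
      } else {
        mode <- "cis"; evid <- "adjacent_same_strand"
      }
    }
    data.frame(gene_id = gene$gene_id, intron_index = i, mode = mode,
               evidence = evid, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# 0-based exclusive genomic end position of a segment, modulo L
seg_end_pos <- function(seg, L) {
  if (seg$wraps_origin) seg$end else seg$end %% L
}

#' Classify introns across a gene set
#'
#' @param annotations list of [gene_annotation]s (CDS genes are scanned).
#' @param genome the [genome_record].
#' @param max_intron_span see [classify_intron_splicing].
#' @return combined data.frame over all multi-exon CDS genes.
#' @export
classify_all_introns <- function(annotations, genome, max_intron_span = 50000L) {
  rows <- lapply(annotations, function(g) {
    if (g$biotype != "CDS") return(NULL)
    classify_intron_splicing(g, genome, max_intron_span)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), intron_index = integer(),
                      mode = character(), evidence = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
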