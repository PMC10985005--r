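# Empirical C-to-U RNA-editing detection.
#
# Plant mitochondrial transcripts are post-transcriptionally edited at
# hundreds of cytidines; on RNA-seq evidence an edit shows up as T reads over
# a genomic C on the coding strand. The caller consumes read pileups (BAM via
# Rsamtools, or a pre-tabulated TSV), transforms everything to coding-strand
# sense per gene, and classifies each called site's codon consequence.

AA_LEVELS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y", "*")

#' Pile up RNA-seq coverage over spliced gene models
#'
#' One row per spliced-CDS position with coverage, base counts transformed to
#' coding-strand sense (minus-strand genes complemented). From BAM, reads
#' with mapping quality `< min_mapq` and bases `< min_baseq` are excluded;
#' SAM input is converted on the fly. A pre-tabulated pileup (TSV or
#' data.frame with `gene_id`, `cds_pos`, `ref`, `A`, `C`, `G`, `T` and
#' optionally `N`) is accepted as-is, already in coding sense.
#'
#' @param alignments BAM/SAM path, pileup TSV path, or pileup data.frame.
#' @param genome a [genome_record].
#' @param gene_annotations list of [gene_annotation]s with CDS models.
#' @param min_mapq,min_baseq quality filters for BAM input.
#' @return data.frame: `gene_id`, `cds_pos` (0-based), `genome_pos`,
#'   `strand`, `ref_base` (coding sense), `depth`, `A`, `C`, `G`, `T`, `N`.
#' @export
pileup_genes <- function(alignments, genome, gene_annotations,
                         min_mapq = 20L, min_baseq = 20L) {
  if (is.data.frame(alignments)) return(pileup_from_table(alignments, genome,
                                                          gene_annotations))
  stopifnot(is.character(alignments), length(alignments) == 1L)
  ext <- tolower(tools::file_ext(alignments))
  if (ext %in% c("tsv", "txt")) {
    tab <- utils::read.table(alignments, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    return(pileup_from_table(tab, genome, gene_annotations))
  }
  bam <- alignments
  if (ext == "sam") {
    bam <- Rsamtools::asBam(alignments, tempfile("orgkit"), overwrite = TRUE,
                            indexDestination = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!genome$id %in% names(hdr))
    stop("alignment reference(s) [", paste(names(hdr), collapse = ", "),
         "] do not include genome '", genome$id, "'")
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(mapqFilter = min_mapq),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 100000L, min_base_quality = as.integer(min_baseq),
      min_mapq = as.integer(min_mapq), min_nucleotide_depth = 1L,
      distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
      include_deletions = FALSE, include_insertions = FALSE))
  p <- p[as.character(p$seqnames) == genome$id, , drop = FALSE]
  # per genomic position counts of A/C/G/T/N on the reference strand
  counts <- matrix(0L, nrow = genome$length, ncol = 5L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  nuc <- as.character(p$nucleotide)
  keep <- nuc %in% colnames(counts)
  idx <- cbind(p$pos[keep], match(nuc[keep], colnames(counts)))
  cnt_keep <- p$count[keep]
  for (r in seq_len(nrow(idx)))
    counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + cnt_keep[r]
  rows <- lapply(gene_annotations, function(g) {
    if (!g$biotype %in% c("CDS", "ORF")) return(NULL)
    map <- cds_genomic_positions(genome, g)
    cnt <- counts[map$genome_pos + 1L, , drop = FALSE]
    minus <- map$strand == "-"
    if (any(minus)) { # complement counts to coding sense
      cnt[minus, ] <- cnt[minus, c("T", "G", "C", "A", "N"), drop = FALSE]
    }
    depth <- rowSums(cnt)
    sel <- depth > 0L
    if (!any(sel)) return(NULL)
    cds <- extract_spliced_cds(genome, g)
    ref <- strsplit(cds, "", fixed = TRUE)[[1L]]
    data.frame(gene_id = g$gene_id, cds_pos = map$cds_pos[sel],
               genome_pos = map$genome_pos[sel], strand = map$strand[sel],
               ref_base = ref[map$cds_pos[sel] + 1L], depth = depth[sel],
               A = cnt[sel, "A"], C = cnt[sel, "C"], G = cnt[sel, "G"],
               T = cnt[sel, "T"], N = cnt[sel, "N"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_pileup_df()
  rownames(out) <- NULL
  out
}

pileup_from_table <- function(tab, genome, gene_annotations) {
  need <- c("gene_id", "cds_pos", "ref", "A", "C", "G", "T")
  if (!all(need %in% names(tab)))
    stop("pileup table must have columns: ", paste(need, collapse = ", "))
  if (is.null(tab$N)) tab$N <- 0L
  genes <- stats::setNames(gene_annotations,
                           vapply(gene_annotations, `[[`, character(1L), "gene_id"))
  rows <- lapply(split(tab, tab$gene_id), function(tg) {
    g <- genes[[tg$gene_id[1L]]]
    if (is.null(g)) stop("pileup references unknown gene '", tg$gene_id[1L], "'")
    map <- cds_genomic_positions(genome, g)
    m <- match(tg$cds_pos, map$cds_pos)
    if (anyNA(m)) stop("pileup cds_pos outside CDS of '", g$gene_id, "'")
    data.frame(gene_id = tg$gene_id, cds_pos = tg$cds_pos,
               genome_pos = map$genome_pos[m], strand = map$strand[m],
               ref_base = tg$ref, depth = tg$A + tg$C + tg$G + tg$T + tg$N,
               A = tg$A, C = tg$C, G = tg$G, T = tg$T, N = tg$N,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_pileup_df <- function() {
  data.frame(gene_id = character(), cds_pos = integer(), genome_pos = integer(),
             strand = character(), ref_base = character(), depth = integer(),
             A = integer(), C = integer(), G = integer(), T = integer(),
             N = integer(), stringsAsFactors = FALSE)
}

#' Call C-to-U editing sites from a pileup
#'
#' A site is called iff its coding-sense reference base is `C`, depth is at
#' least `min_depth`, and the T fraction among non-N bases is at least
#' `min_fraction`. No other mismatch class is ever called. The thresholds are
#' empirical-calling decisions (published organelle studies rarely state
#' any) and are exposed as parameters.
#'
#' @param sites pileup data.frame from [pileup_genes].
#' @param min_depth minimum read depth.
#' @param min_fraction minimum edited-read fraction.
#' @return subset of `sites` with an `edit_fraction` column.
#' @export
call_c_to_u <- function(sites, min_depth = 10L, min_fraction = 0.10) {
  eff <- sites$depth - sites$N
  frac <- ifelse(eff > 0, sites$T / eff, 0)
  called <- sites$ref_base == "C" & sites$depth >= min_depth & frac >= min_fraction
  out <- sites[called, , drop = FALSE]
  out$edit_fraction <- frac[called]
  rownames(out) <- NULL
  out
}

#' Classify the codon consequence of one editing site
#'
#' Builds the codon before/after the C-to-T change and classifies it:
#' `silent` (amino acid preserved, including edits that keep the annotated
#' stop a stop), `missense`, `stop_gain` (internal codon becomes a stop),
#' `start_gain` (first codon becomes ATG), `start_codon_edit` (first codon
#' edited but not to ATG, e.g. GCG to GTG), or `stop_codon_edit` (annotated
#' stop codon loses its stop).
#'
#' @param genome a [genome_record].
#' @param gene the [gene_annotation] containing the site.
#' @param cds_pos 0-based position in the spliced CDS (must be a `C`).
#' @param cds optional pre-extracted spliced CDS (performance).
#' @return list with `consequence` and the [codon_change].
#' @export
classify_consequence <- function(genome, gene, cds_pos, cds = NULL) {
  if (is.null(cds)) cds <- extract_spliced_cds(genome, gene)
  n <- nchar(cds)
  if (cds_pos < 0L || cds_pos >= n)
    stop("cds_pos ", cds_pos, " outside CDS of '", gene$gene_id,
         "' (length ", n, "); sites must be pre-filtered to coding positions")
  codon_idx <- cds_pos %/% 3L
  if (codon_idx >= n %/% 3L)
    stop("cds_pos ", cds_pos, " falls in a trailing incomplete codon")
  pos_in_codon <- cds_pos %% 3L + 1L
  codon <- substr(cds, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
  cc <- codon_change(codon, pos_in_codon)
  conseq <-
    if (codon_idx == 0L) {
      if (cc$codon_after == "ATG") "start_gain" else "start_codon_edit"
    } else if (cc$aa_before == "*") {
      if (cc$aa_after == "*") "silent" else "stop_codon_edit"
    } else if (cc$aa_after == "*") {
      "stop_gain"
    } else if (cc$aa_before == cc$aa_after) {
      "silent"
    } else "missense"
  list(consequence = conseq, codon_change = cc, codon_index = codon_idx)
}

#' Classify all called sites of a gene set
#'
#' Vectorized driver over [classify_consequence].
#'
#' @param genome a [genome_record].
#' @param gene_annotations list of [gene_annotation]s.
#' @param called data.frame from [call_c_to_u].
#' @return `called` with `consequence`, `codon_index`, `codon_before`,
#'   `codon_after`, `aa_before`, `aa_after`, `codon_position_edited` columns.
#' @export
classify_sites <- function(genome, gene_annotations, called) {
  genes <- stats::setNames(gene_annotations,
                           vapply(gene_annotations, `[[`, character(1L), "gene_id"))
  cds_cache <- new.env(parent = emptyenv())
  res <- lapply(seq_len(nrow(called)), function(i) {
    gid <- called$gene_id[i]
    g <- genes[[gid]]
    if (is.null(g)) stop("called site references unknown gene '", gid, "'")
    if (is.null(cds_cache[[gid]])) cds_cache[[gid]] <- extract_spliced_cds(genome, g)
    cl <- classify_consequence(genome, g, called$cds_pos[i], cds_cache[[gid]])
    cc <- cl$codon_change
    data.frame(consequence = cl$consequence, codon_index = cl$codon_index,
               codon_before = cc$codon_before, codon_after = cc$codon_after,
               aa_before = cc$aa_before, aa_after = cc$aa_after,
               codon_position_edited = cc$codon_position_edited,
               stringsAsFactors = FALSE)
  })
  cbind(called, do.call(rbind, res))
}

#' Summarize editing across genes
#'
#' Per-gene site counts, codon-change counts (distinct codons hit by at
#' least one edit -- two edits in one codon are one codon change), CDS
#' length and editing density; a 21x21 amino-acid conversion matrix over
#' nonsilent sites; codon-position counts; start/stop-gain site lists.
#'
#' @param sites classified sites from [classify_sites].
#' @param genome a [genome_record].
#' @param gene_annotations list of [gene_annotation]s (defines the gene set,
#'   including genes with zero sites).
#' @return list: `per_gene` data.frame, `aa_conversion_matrix`,
#'   `codon_position_counts`, `start_gains`, `stop_gains`, `n_sites`,
#'   `n_silent`, `n_nonsilent`.
#' @export
summarize_editing <- function(sites, genome, gene_annotations) {
  gids <- vapply(gene_annotations, `[[`, character(1L), "gene_id")
  cds_len <- vapply(gene_annotations, function(g) {
    if (!g$biotype %in% c("CDS", "ORF")) return(NA_integer_)
    nchar(extract_spliced_cds(genome, g))
  }, integer(1L))
  per_gene <- data.frame(gene_id = gids, cds_length = cds_len,
                         n_sites = 0L, n_codon_changes = 0L, density = 0,
                         stringsAsFactors = FALSE)
  mat <- matrix(0L, nrow = length(AA_LEVELS), ncol = length(AA_LEVELS),
                dimnames = list(before = AA_LEVELS, after = AA_LEVELS))
  pos_counts <- c(`1` = 0L, `2` = 0L, `3` = 0L)
  if (nrow(sites) > 0L) {
    ns <- table(sites$gene_id)
    ncc <- tapply(sites$codon_index, sites$gene_id,
                  function(x) length(unique(x)))
    m <- match(names(ns), per_gene$gene_id)
    per_gene$n_sites[m] <- as.integer(ns)
    per_gene$n_codon_changes[m] <- as.integer(ncc[names(ns)])
    per_gene$density <- ifelse(per_gene$cds_length > 0,
                               per_gene$n_sites / per_gene$cds_length, 0)
    nonsil <- sites[sites$consequence != "silent", , drop = FALSE]
    if (nrow(nonsil) > 0L) {
      tb <- table(factor(nonsil$aa_before, AA_LEVELS),
                  factor(nonsil$aa_after, AA_LEVELS))
      mat <- mat + unclass(tb)
    }
    pc <- table(factor(sites$codon_position_edited, levels = 1:3))
    pos_counts <- stats::setNames(as.integer(pc), c("1", "2", "3"))
  }
  list(per_gene = per_gene,
       aa_conversion_matrix = mat,
       codon_position_counts = pos_counts,
       start_gains = sites[sites$consequence == "start_gain", , drop = FALSE],
       stop_gains = sites[sites$consequence == "stop_gain", , drop = FALSE],
       n_sites = nrow(sites),
       n_silent = sum(sites$consequence == "silent"),
       n_nonsilent = sum(sites$consequence != "silent"))
}

#' Compare called sites against an external prediction list
#'
#' Exact `(gene_id, cds_pos)` set algebra between empirically called sites
#' and a prediction table (e.g. parsed from a phylogenetic editing
#' predictor's output). Duplicate predictions are collapsed with a warning.
#'
#' @param called data.frame with `gene_id`, `cds_pos`.
#' @param predicted data.frame with `gene_id`, `cds_pos`.
#' @return list of data.frames `confirmed`, `called_only`, `predicted_only`.
#' @export
compare_with_predictions <- function(called, predicted) {
  key <- function(df) paste(df$gene_id, df$cds_pos, sep = ":")
  pk <- key(predicted)
  if (anyDuplicated(pk)) {
    warning("collapsing ", sum(duplicated(pk)), " duplicate prediction(s)")
    predicted <- predicted[!duplicated(pk), , drop = FALSE]
    pk <- key(predicted)
  }
  ck <- key(called)
  list(confirmed = called[ck %in% pk, c("gene_id", "cds_pos"), drop = FALSE],
       called_only = called[!ck %in% pk, c("gene_id", "cds_pos"), drop = FALSE],
       predicted_only = predicted[!pk %in% ck, c("gene_id", "cds_pos"), drop = FALSE])
}
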