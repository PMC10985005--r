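# Plastid-to-mitochondrion transfer scanning.
#
# Local similarity search is delegated to the NCBI BLAST+ command-line suite
# (task=blastn: exact 11-mer seeds, gapped extension, Karlin-Altschul
# E-values), which is the engine family organelle studies use for this scan;
# orgkit owns the thresholds, circular handling, deduplication and merging.

blast_available <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

require_blast <- function() {
  if (!blast_available())
    stop("NCBI BLAST+ (blastn/makeblastdb) not found on PATH; ",
         "required for similarity scanning")
}

# Run blastn query-vs-subject, return outfmt-6 data.frame (possibly empty).
run_blastn <- function(query_fa, subject_fa, evalue = 10, word_size = 11L,
                       task = "blastn") {
  require_blast()
  db <- tempfile("orgkitdb")
  out <- tempfile("orgkitblast", fileext = ".tsv")
  on.exit(unlink(c(out, paste0(db, c("", ".nhr", ".nin", ".nsq", ".ndb",
                                     ".not", ".ntf", ".nto")))), add = TRUE)
  st <- system2("makeblastdb",
                c("-in", shQuote(subject_fa), "-dbtype", "nucl", "-out", shQuote(db)),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("makeblastdb failed on ", subject_fa)
  st <- system2("blastn", c(
    "-query", shQuote(query_fa), "-db", shQuote(db), "-task", task,
    "-word_size", word_size, "-evalue", format(evalue, scientific = TRUE),
    "-dust", "no", "-soft_masking", "false",
    "-outfmt", shQuote("6 qseqid sseqid pident length mismatch gapopen qstart qend sstart send evalue bitscore"),
    "-out", shQuote(out)), stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("blastn failed")
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!file.exists(out) || file.info(out)$size == 0L) {
    df <- as.data.frame(stats::setNames(replicate(12, numeric(0), simplify = FALSE), cols))
    df$qseqid <- character(0); df$sseqid <- character(0)
    return(df)
  }
  utils::read.table(out, sep = "\t", col.names = cols,
                    colClasses = c("character", "character", rep("numeric", 10)),
                    quote = "", comment.char = "")
}

#' Scan a mitogenome for plastid-derived fragments (MIPTs)
#'
#' Local BLASTN search of the plastome against the mitogenome (both strands),
#' filtered at the conventional MIPT thresholds: alignment length
#' `>= min_len`, identity `>= min_identity`, E-value `<= max_evalue`.
#' Circular subjects are searched on a doubled-sequence view and hits
#' deduplicated modulo length. A degenerate self-search (same record id)
#' suppresses the trivial full-length self-hit.
#'
#' @param mitogenome subject [genome_record] (where insertions are sought).
#' @param plastome query [genome_record] (the donor).
#' @param min_len minimum alignment length (bp).
#' @param min_identity minimum identity fraction.
#' @param max_evalue maximum E-value.
#' @param word_size BLASTN seed size; 7 by default because a 50 bp fragment
#'   at the 80% identity floor can lack any clean 11-mer.
#' @return data.frame of hits sorted by mitogenome coordinate: `q_start`,
#'   `q_end` (plastome, 0-based half-open, forward-strand), `s_start`,
#'   `s_end` (mitogenome), `s_strand`, `length`, `identity`, `evalue`.
#' @export
find_mipts <- function(mitogenome, plastome, min_len = 50L,
                       min_identity = 0.80, max_evalue = 1e-10,
                       word_size = 7L) {
  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, sf)), add = TRUE)
  write_genome_fasta(plastome, qf)
  Lm <- mitogenome$length
  subj <- if (mitogenome$topology == "circular") {
    genome_record(mitogenome$id,
                  paste0(mitogenome$sequence, mitogenome$sequence), "linear")
  } else mitogenome
  write_genome_fasta(subj, sf)
  hits <- run_blastn(qf, sf, evalue = max(max_evalue, 1e-3),
                     word_size = word_size)
  hits <- hits[hits$length >= min_len &
                 hits$pident / 100 >= min_identity &
                 hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_mipt_df())
  s_strand <- ifelse(hits$send >= hits$sstart, "+", "-")
  s_lo <- pmin(hits$sstart, hits$send) - 1L   # 0-based
  s_hi <- pmax(hits$sstart, hits$send)
  df <- data.frame(
    q_start = hits$qstart - 1L, q_end = hits$qend,
    s_start = s_lo %% Lm, s_end = s_lo %% Lm + (s_hi - s_lo),
    s_strand = s_strand, length = as.integer(hits$length),
    identity = hits$pident / 100, evalue = hits$evalue,
    stringsAsFactors = FALSE)
  # doubled-view duplicates: same alignment shifted by Lm
  key <- paste(df$q_start, df$q_end, df$s_start, df$s_end, df$s_strand)
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[df$s_end - df$s_start <= Lm, , drop = FALSE]
  # degenerate self-search: drop the identity hit
  if (mitogenome$id == plastome$id) {
    self <- df$identity == 1 & df$s_end - df$s_start >= min(Lm, plastome$length) &
      df$s_strand == "+"
    df <- df[!self, , drop = FALSE]
  }
  df <- df[order(df$s_start, df$s_end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_mipt_df <- function() {
  data.frame(q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), s_strand = character(), length = integer(),
             identity = numeric(), evalue = numeric(), stringsAsFactors = FALSE)
}

#' Merge MIPT hits into fragments and total transferred bp
#'
#' Hits whose mitogenome loci overlap by at least 1 bp are merged into one
#' fragment; the summary counts merged fragments and the union of their
#' lengths, which is how fragment totals are conventionally reported.
#'
#' @param hits output of [find_mipts].
#' @param genome_length mitogenome length (for circular wrap-around safety).
#' @return list with `n_fragments`, `total_bp` and a `fragments` data.frame
#'   (`start`, `end` 0-based half-open on the mitogenome).
#' @export
summarize_mipts <- function(hits, genome_length = NULL) {
  if (nrow(hits) == 0L)
    return(list(n_fragments = 0L, total_bp = 0L,
                fragments = data.frame(start = integer(), end = integer())))
  o <- order(hits$s_start, hits$s_end)
  s <- hits$s_start[o]; e <- hits$s_end[o]
  fs <- s[1L]; fe <- e[1L]; res_s <- integer(0); res_e <- integer(0)
  for (i in seq_along(s)[-1L]) {
    if (s[i] < fe) fe <- max(fe, e[i])  # >= 1 bp overlap
    else { res_s <- c(res_s, fs); res_e <- c(res_e, fe); fs <- s[i]; fe <- e[i] }
  }
  res_s <- c(res_s, fs); res_e <- c(res_e, fe)
  list(n_fragments = length(res_s), total_bp = sum(res_e - res_s),
       fragments = data.frame(start = res_s, end = res_e))
}

# --- ORFs ------------------------------------------------------------------

#' Find open reading frames
#'
#' All six reading frames (three per strand), ATG start, stop-terminated,
#' longest-per-stop (nested ATGs inside a reported ORF are not reported
#' separately). On circular genomes the scan honors origin wrap. ORF length
#' counts the stop codon.
#'
#' @param genome a [genome_record].
#' @param min_len minimum ORF length in bp (start through stop, inclusive).
#' @return data.frame: `start`, `end` (0-based half-open on the forward
#'   strand; `end` may exceed the genome length for wrapping ORFs), `strand`,
#'   `length`, `protein` (without the trailing stop), `partial`.
#' @export
find_orfs <- function(genome, min_len = 150L) {
  L <- genome$length
  circ <- genome$topology == "circular"
  scan_one <- function(seqstr, strand) {
    n <- nchar(seqstr)
    res <- list()
    for (frame in 0:2) {
      nc <- ((n - frame) %/% 3L) * 3L
      if (nc < 3L) next
      starts <- seq(frame + 1L, frame + nc, by = 3L)
      codons <- substring(seqstr, starts, starts + 2L)
      aa <- unname(.GENETIC_CODE_1[codons]); aa[is.na(aa)] <- "X"
      stop_idx <- which(aa == "*")
      seg_begin <- 1L
      bounds <- c(stop_idx, length(aa) + 1L)
      for (bi in seq_along(bounds)) {
        send <- bounds[bi]
        if (seg_begin > send - 1L) { seg_begin <- send + 1L; next }
        seg <- seq.int(seg_begin, send - 1L)
        seg_begin <- send + 1L
        m <- seg[which(aa[seg] == "M")[1L]]
        if (is.na(m)) next
        has_stop <- send <= length(aa)
        last <- if (has_stop) send else length(aa)
        orf_nt_start <- starts[m]                    # 1-based in seqstr
        orf_nt_end <- starts[last] + 2L
        len <- orf_nt_end - orf_nt_start + 1L
        prot <- paste(aa[seq.int(m, last - if (has_stop) 1L else 0L)], collapse = "")
        res[[length(res) + 1L]] <- list(
          s = orf_nt_start, e = orf_nt_end, len = len, prot = prot,
          partial = !has_stop, strand = strand)
      }
    }
    res
  }
  fw <- if (circ) paste0(genome$sequence, genome$sequence) else genome$sequence
  rv <- revcomp(fw)
  n_scan <- nchar(fw)
  cand <- c(scan_one(fw, "+"), scan_one(rv, "-"))
  if (!length(cand)) return(empty_orf_df())
  rows <- lapply(cand, function(x) {
    if (x$strand == "+") { g0 <- x$s - 1L } else { g0 <- n_scan - x$e }
    data.frame(start = g0, end = g0 + x$len, strand = x$strand,
               length = x$len, protein = x$prot, partial = x$partial,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (circ) {
    # on the doubled view every ORF not crossing the seam appears twice;
    # canonicalize start into [0, L) and drop over-long artifacts
    df <- df[df$length <= L, , drop = FALSE]
    df$end <- df$end - df$start %/% L * L
    df$start <- df$start %% L
    df <- df[!x_dup_orf(df), , drop = FALSE]
    df <- df[!df$partial, , drop = FALSE]  # a circle has no sequence ends
  }
  df <- df[df$length >= min_len, , drop = FALSE]
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

x_dup_orf <- function(df) duplicated(paste(df$start, df$end, df$strand))

empty_orf_df <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             length = integer(), protein = character(), partial = logical(),
             stringsAsFactors = FALSE)
}

#' Flag chimeric ORFs containing fragments of annotated genes
#'
#' Each ORF is searched (BLASTN) against the exon sequences of the annotated
#' genes; fragments of at least `min_frag` bp at `>= min_identity` identity
#' become chimera evidence. An ORF genomically overlapping a gene's own locus
#' is never reported as evidence for that gene (it *is* the gene).
#'
#' @param orfs data.frame from [find_orfs].
#' @param gene_annotations list of [gene_annotation]s.
#' @param genome the [genome_record] both live on.
#' @param min_frag minimum evidence fragment length (bp).
#' @param min_identity minimum identity fraction.
#' @param max_evalue maximum E-value for evidence fragments.
#' @return `orfs` with a list-column `chimera_evidence`; each element is a
#'   data.frame (`gene_id`, `orf_start`, `orf_end`, `length`, `identity`).
#' @export
flag_chimeric_orfs <- function(orfs, gene_annotations, genome,
                               min_frag = 30L, min_identity = 0.90,
                               max_evalue = 1e-3) {
  if (nrow(orfs) == 0L) {
    orfs$chimera_evidence <- list()
    return(orfs)
  }
  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, sf)), add = TRUE)
  orf_ids <- sprintf("orf_%d", seq_len(nrow(orfs)))
  orf_seqs <- lapply(seq_len(nrow(orfs)), function(i) {
    s <- extract_span(genome, orfs$start[i], orfs$length[i])
    if (orfs$strand[i] == "-") s <- revcomp(s)
    genome_record(orf_ids[i], s, "linear")
  })
  write_genome_fasta(orf_seqs, qf)
  exon_recs <- list(); exon_meta <- list()
  for (g in gene_annotations) {
    for (j in seq_along(g$exons)) {
      ex <- g$exons[[j]]
      id <- sprintf("%s|exon%d", g$gene_id, j)
      exon_recs[[id]] <- genome_record(id, extract_segment(genome, ex), "linear")
      exon_meta[[id]] <- list(gene = g$gene_id, seg = ex)
    }
  }
  if (!length(exon_recs)) {
    orfs$chimera_evidence <- replicate(nrow(orfs), empty_evidence_df(),
                                       simplify = FALSE)
    return(orfs)
  }
  write_genome_fasta(exon_recs, sf)
  hits <- run_blastn(qf, sf, evalue = max_evalue, word_size = 7L)
  hits <- hits[hits$length >= min_frag & hits$pident / 100 >= min_identity &
                 hits$evalue <= max_evalue, , drop = FALSE]
  L <- genome$length
  ev <- lapply(seq_len(nrow(orfs)), function(i) {
    h <- hits[hits$qseqid == orf_ids[i], , drop = FALSE]
    if (nrow(h) == 0L) return(empty_evidence_df())
    keep <- vapply(seq_len(nrow(h)), function(r) {
      meta <- exon_meta[[h$sseqid[r]]]
      !orf_overlaps_seg(orfs$start[i], orfs$end[i], meta$seg, L)
    }, logical(1L))
    h <- h[keep, , drop = FALSE]
    if (nrow(h) == 0L) return(empty_evidence_df())
    data.frame(
      gene_id = vapply(h$sseqid, function(s) exon_meta[[s]]$gene, character(1L)),
      orf_start = as.integer(h$qstart - 1L), orf_end = as.integer(h$qend),
      length = as.integer(h$length), identity = h$pident / 100,
      row.names = NULL, stringsAsFactors = FALSE)
  })
  orfs$chimera_evidence <- ev
  orfs
}

empty_evidence_df <- function() {
  data.frame(gene_id = character(), orf_start = integer(), orf_end = integer(),
             length = integer(), identity = numeric(), stringsAsFactors = FALSE)
}

orf_overlaps_seg <- function(orf_start, orf_end, seg, L) {
  opos <- (seq.int(orf_start, orf_end - 1L) %% L)
  spos <- seg_positions(seg, L)
  length(intersect(opos, spos)) > 0L
}
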