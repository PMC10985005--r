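# Seeded synthetic-data generators with ground truth.
#
# Every generator is a pure function of (seed, parameters): identical calls
# give byte-identical output (R's default integer RNG stream only, no
# hash-order dependence). Backgrounds are screened so that planted features
# are the *only* features: a random background containing an accidental
# 30 bp duplicate would make repeat-recall tests ill-posed.

DNA <- c("A", "C", "G", "T")

# random DNA with a target GC fraction
random_dna <- function(n, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA, n, replace = TRUE, prob = p), collapse = "")
}

# TRUE if s contains a duplicated k-mer or shares a k-mer with its own
# reverse complement (i.e., any direct or inverted repeat >= k)
has_repeat_kmer <- function(s, k = 30L) {
  n <- nchar(s)
  if (n < k) return(FALSE)
  km <- substring(s, 1:(n - k + 1L), k:n)
  if (anyDuplicated(km)) return(TRUE)
  rkm <- substring(revcomp(s), 1:(n - k + 1L), k:n)
  any(km %in% rkm)
}

# screened background: no direct/inverted repeat >= screen_len
screened_dna <- function(n, gc = 0.45, screen_len = 30L, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(n, gc)
    if (!has_repeat_kmer(s, screen_len)) return(s)
  }
  stop("could not generate a repeat-free background of ", n, " bp")
}

# ---------------------------------------------------------------------------
# annotated genome with planted genes / repeats / MIPT fragments

#' Simulate an annotated organelle genome with known ground truth
#'
#' Generates a screened background (no unplanned direct/inverted repeat of
#' 30 bp or more), plants protein-coding genes (single- and multi-exon;
#' optionally trans-spliced), dispersed repeats, and plastid-derived
#' fragments copied from a donor genome, and records exact coordinates of
#' everything planted.
#'
#' @param seed RNG seed.
#' @param genome_length genome size (bp).
#' @param gc background GC fraction.
#' @param topology `"circular"` or `"linear"`.
#' @param n_genes number of CDS genes.
#' @param n_trans_introns number of genes given one trans-spliced intron.
#' @param n_trna,n_rrna numbers of tRNA (75 bp) and rRNA (1500 bp) genes.
#' @param repeat_plan data.frame with `unit_length`, `orientation`
#'   (`direct`/`inverted`), `n_copies` (currently 2).
#' @param mipt_plan data.frame with `length`, `identity`.
#' @param donor donor [genome_record] for MIPT fragments (generated when
#'   `mipt_plan` is given but `donor` is `NULL`).
#' @param pad minimum spacing between planted features (bp).
#' @return list: `genome`, `annotations` (list of [gene_annotation]),
#'   `donor`, `truth` (planted repeats, mipts, gene mRNAs, intron modes,
#'   biotype bp).
#' @export
sim_genome <- function(seed, genome_length = 50000L, gc = 0.45,
                       topology = "circular", n_genes = 4L,
                       n_trans_introns = 0L, n_trna = 0L, n_rrna = 0L,
                       repeat_plan = NULL, mipt_plan = NULL, donor = NULL,
                       pad = 60L) {
  set.seed(seed)
  L <- as.integer(genome_length)
  planted_bp <- n_genes * 1200L + n_trna * 75L + n_rrna * 1500L +
    (if (is.null(repeat_plan)) 0L else sum(repeat_plan$unit_length * repeat_plan$n_copies)) +
    (if (is.null(mipt_plan)) 0L else sum(mipt_plan$length))
  if (planted_bp > 0.6 * L)
    stop("infeasible packing: planted features (", planted_bp,
         " bp) exceed 60% of genome length ", L)
  seqc <- strsplit(screened_dna(L, gc), "", fixed = TRUE)[[1L]]
  occupied <- matrix(integer(0), ncol = 2L)  # [start, end) 0-based, padded

  alloc <- function(len) {
    for (try in seq_len(2000L)) {
      s <- sample.int(L - len, 1L) - 1L  # avoid origin wrap for simplicity
      a <- s - pad; b <- s + len + pad
      if (nrow(occupied) == 0L ||
          all(b <= occupied[, 1L] | a >= occupied[, 2L])) {
        occupied <<- rbind(occupied, c(s, s + len))
        return(s)
      }
    }
    stop("infeasible packing: could not place a ", len, " bp feature")
  }
  write_seq <- function(s0, str) {
    seqc[(s0 + 1L):(s0 + nchar(str))] <<- strsplit(str, "", fixed = TRUE)[[1L]]
  }

  annotations <- list()
  truth <- list(genes = list(), introns = NULL, repeats = NULL, mipts = NULL)

  ## genes -------------------------------------------------------------
  non_stop <- setdiff(names(.GENETIC_CODE_1), c("TAA", "TAG", "TGA"))
  make_cds <- function(n_codons) {
    paste0("ATG",
           paste(sample(non_stop, n_codons - 2L, replace = TRUE), collapse = ""),
           sample(c("TAA", "TAG", "TGA"), 1L))
  }
  trans_genes <- if (n_genes > 0L) sample.int(n_genes, min(n_trans_introns, n_genes)) else integer(0)
  intron_rows <- list()
  for (gi in seq_len(n_genes)) {
    gid <- sprintf("gene%02d", gi)
    n_codons <- sample(150:400, 1L)
    cds <- make_cds(n_codons)
    n_ex <- if (gi %in% trans_genes) 2L else sample(1:3, 1L)
    cuts <- if (n_ex == 1L) integer(0) else
      sort(sample(seq(60L, nchar(cds) - 60L, by = 3L), n_ex - 1L))
    bounds <- c(0L, cuts, nchar(cds))
    pieces <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
    strand0 <- sample(c("+", "-"), 1L)
    modes <- character(0)
    if (gi %in% trans_genes) {
      # two exons, trans: opposite strands, or order-violating placement
      # (exon 2 genomically just *behind* exon 1, against reading direction)
      style <- sample(c("strand_switch", "order_violation"), 1L)
      l1 <- nchar(pieces[1L]); l2 <- nchar(pieces[2L])
      if (style == "strand_switch") {
        s1 <- alloc(l1); s2 <- alloc(l2)
        strands <- c(strand0, setdiff(c("+", "-"), strand0))
      } else {
        gap0 <- 100L
        s0 <- alloc(l1 + gap0 + l2)
        if (strand0 == "+") { s1 <- s0 + l2 + gap0; s2 <- s0 }
        else { s1 <- s0; s2 <- s0 + l1 + gap0 }
        strands <- c(strand0, strand0)
      }
      starts <- c(s1, s2)
      modes <- "trans"
    } else {
      # cis gene: contiguous span, introns 80-400 bp, one strand
      intron_lens <- if (n_ex > 1L) sample(80:400, n_ex - 1L, replace = TRUE) else integer(0)
      span <- sum(nchar(pieces)) + sum(intron_lens)
      s0 <- alloc(span)
      offs <- cumsum(c(0L, utils::head(nchar(pieces), -1L) + intron_lens))
      starts <- if (strand0 == "+") s0 + offs
      else s0 + span - (offs + nchar(pieces))  # transcription walks leftward
      strands <- rep(strand0, n_ex)
      modes <- rep("cis", max(0L, n_ex - 1L))
    }
    segs <- list()
    for (j in seq_along(pieces)) {
      pc <- pieces[j]
      gseq <- if (strands[j] == "-") revcomp(pc) else pc
      write_seq(starts[j], gseq)
      segs[[j]] <- segment_interval(starts[j], starts[j] + nchar(pc), strands[j])
    }
    annotations[[gid]] <- gene_annotation(gid, "CDS", segs)
    truth$genes[[gid]] <- cds
    if (length(modes))
      intron_rows[[gid]] <- data.frame(gene_id = gid,
                                       intron_index = seq_along(modes),
                                       mode = modes, stringsAsFactors = FALSE)
  }
  truth$introns <- if (length(intron_rows)) do.call(rbind, intron_rows) else
    data.frame(gene_id = character(), intron_index = integer(),
               mode = character(), stringsAsFactors = FALSE)
  rownames(truth$introns) <- NULL

  ## tRNA / rRNA genes --------------------------------------------------
  for (i in seq_len(n_trna)) {
    s0 <- alloc(75L)
    gid <- sprintf("trna%02d", i)
    annotations[[gid]] <- gene_annotation(gid, "tRNA",
                                          list(segment_interval(s0, s0 + 75L, "+")))
  }
  for (i in seq_len(n_rrna)) {
    s0 <- alloc(1500L)
    gid <- sprintf("rrna%02d", i)
    annotations[[gid]] <- gene_annotation(gid, "rRNA",
                                          list(segment_interval(s0, s0 + 1500L, "+")))
  }

  ## dispersed repeats ---------------------------------------------------
  if (!is.null(repeat_plan)) {
    rrows <- list()
    for (r in seq_len(nrow(repeat_plan))) {
      len <- as.integer(repeat_plan$unit_length[r])
      ori <- repeat_plan$orientation[r]
      nc <- as.integer(repeat_plan$n_copies[r])
      stopifnot(ori %in% c("direct", "inverted"), nc == 2L)
      unit <- random_dna(len, gc)
      genome_now <- paste(seqc, collapse = "")
      while (shares_kmer(unit, genome_now, 30L)) unit <- random_dna(len, gc)
      s1 <- alloc(len); s2 <- alloc(len)
      copy2 <- if (ori == "inverted") revcomp(unit) else unit
      write_seq(s1, unit)
      write_seq(s2, copy2)
      block_extension(seqc, s1, s2, len, ori, L) -> seqc
      rrows[[r]] <- data.frame(unit_length = len, orientation = ori,
                               start_a = min(s1, s2), start_b = max(s1, s2),
                               stringsAsFactors = FALSE)
    }
    truth$repeats <- do.call(rbind, rrows)
  }

  ## MIPT fragments -------------------------------------------------------
  if (!is.null(mipt_plan)) {
    if (is.null(donor)) {
      donor <- genome_record("donor_plastome", screened_dna(20000L, 0.383),
                             "circular")
    }
    mrows <- list()
    for (r in seq_len(nrow(mipt_plan))) {
      len <- as.integer(mipt_plan$length[r])
      ident <- mipt_plan$identity[r]
      ds <- sample.int(donor$length - len, 1L) - 1L
      frag <- substr(donor$sequence, ds + 1L, ds + len)
      n_mut <- round((1 - ident) * len)
      if (n_mut > 0L) {
        at <- sample.int(len, n_mut)
        fc <- strsplit(frag, "", fixed = TRUE)[[1L]]
        fc[at] <- vapply(fc[at], function(b) sample(setdiff(DNA, b), 1L),
                         character(1L))
        frag <- paste(fc, collapse = "")
      }
      s0 <- alloc(len)
      write_seq(s0, frag)
      # force mismatches in the 6 bp flanks so local alignment cannot creep
      # past the planted fragment into chance-matching background
      for (off in c(-6L:-1L, len:(len + 5L))) {
        mi <- s0 + off + 1L          # 1-based mito index
        di <- ds + off + 1L          # 1-based donor index
        if (mi >= 1L && mi <= L && di >= 1L && di <= donor$length) {
          db <- substr(donor$sequence, di, di)
          if (seqc[mi] == db) seqc[mi] <- sample(setdiff(DNA, db), 1L)
        }
      }
      mrows[[r]] <- data.frame(donor_start = ds, mito_start = s0,
                               length = len, identity = 1 - n_mut / len,
                               stringsAsFactors = FALSE)
    }
    truth$mipts <- do.call(rbind, mrows)
  }

  genome <- genome_record(sprintf("sim_genome_seed%d", seed),
                          paste(seqc, collapse = ""), topology)
  truth$biotype_bp <- biotype_bp_truth(annotations, L)
  list(genome = genome, annotations = annotations, donor = donor, truth = truth)
}

# TRUE if `unit` (either strand) shares a k-mer with `genome_str`, or
# repeats/palindromes internally
shares_kmer <- function(unit, genome_str, k = 30L) {
  n <- nchar(unit)
  if (n < k) return(FALSE)
  km_u <- substring(unit, 1:(n - k + 1L), k:n)
  km_ur <- substring(revcomp(unit), 1:(n - k + 1L), k:n)
  if (anyDuplicated(km_u) || any(km_u %in% km_ur)) return(TRUE)
  ng <- nchar(genome_str)
  km_g <- substring(genome_str, 1:(ng - k + 1L), k:ng)
  any(km_u %in% km_g) || any(km_ur %in% km_g)
}

# force a mismatch immediately outside each planted copy so chance
# single-base extensions cannot lengthen the planted unit
block_extension <- function(seqc, s1, s2, len, ori, L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  at <- function(i) if (i >= 1L && i <= L) seqc[i] else NA_character_
  fix <- function(i, forbidden) {
    if (is.na(forbidden) || i < 1L || i > L) return()
    if (identical(seqc[i], forbidden))
      seqc[i] <<- sample(setdiff(DNA, forbidden), 1L)
  }
  if (ori == "direct") {
    # left flanks must differ; right flanks must differ
    fix(s2, at(s1))
    fix(s2 + len + 1L, at(s1 + len + 1L))
  } else {
    # inverted: left flank of one copy pairs with right flank of the other
    r <- at(s1); fix(s2 + len + 1L, if (is.na(r)) NA_character_ else comp[[r]])
    r <- at(s1 + len + 1L); fix(s2, if (is.na(r)) NA_character_ else comp[[r]])
  }
  seqc
}

biotype_bp_truth <- function(annotations, L) {
  bp <- c(CDS = 0L, rRNA = 0L, tRNA = 0L)
  for (g in annotations) {
    if (!g$biotype %in% names(bp)) next
    bp[g$biotype] <- bp[g$biotype] +
      sum(vapply(g$exons, seg_length, integer(1L), L))
  }
  bp
}

# ---------------------------------------------------------------------------
# plastome with a single planted inverted-repeat pair (LSC + IR + SSC + IR')

#' Simulate a plastome with one inverted-repeat pair
#'
#' Constructs `LSC + IR + SSC + revcomp(IR)` over a screened background, so
#' the planted IR is the genome's only repeat of 30 bp or more. Boundary
#' bases are adjusted so chance extension cannot lengthen the IR.
#'
#' @param seed RNG seed.
#' @param lsc_len,ir_len,ssc_len segment lengths (bp).
#' @param gc GC fraction.
#' @return list: `genome` (circular [genome_record]), `truth` (planted
#'   coordinates: `ir_len`, `lsc`, `ssc`, copy starts).
#' @export
sim_plastome <- function(seed, lsc_len = 10000L, ir_len = 1000L,
                         ssc_len = 4000L, gc = 0.383) {
  set.seed(seed)
  base <- screened_dna(lsc_len + ir_len + ssc_len, gc)
  lsc <- substr(base, 1L, lsc_len)
  ir <- substr(base, lsc_len + 1L, lsc_len + ir_len)
  ssc <- substr(base, lsc_len + ir_len + 1L, lsc_len + ir_len + ssc_len)
  s <- paste0(lsc, ir, ssc, revcomp(ir))
  seqc <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(seqc)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # copy1 = [lsc_len, lsc_len+ir_len); copy2 = [lsc_len+ir_len+ssc_len, L)
  # prevent left/right chance extension of the planted pair (circular!)
  if (seqc[lsc_len] == comp[[seqc[1L]]])          # s[a-1] vs comp(s[(b+l) mod L])
    seqc[lsc_len] <- sample(setdiff(DNA, comp[[seqc[1L]]]), 1L)
  i_after <- lsc_len + ir_len + 1L                # s[a+l]
  i_b_before <- lsc_len + ir_len + ssc_len        # s[b-1]
  if (seqc[i_after] == comp[[seqc[i_b_before]]])
    seqc[i_after] <- sample(setdiff(DNA, comp[[seqc[i_b_before]]]), 1L)
  genome <- genome_record(sprintf("sim_plastome_seed%d", seed),
                          paste(seqc, collapse = ""), "circular")
  list(genome = genome,
       truth = list(ir_len = ir_len, lsc_len = lsc_len, ssc_len = ssc_len,
                    copy1_start = lsc_len, copy2_start = lsc_len + ir_len + ssc_len))
}

# ---------------------------------------------------------------------------
# editing pileups

#' Simulate an RNA-seq pileup with planted C-to-U editing sites
#'
#' Every covered spliced-CDS position of the given genes gets a row; at
#' `n_sites` randomly chosen C positions the T fraction is `fraction`
#' (binomial sampling at fixed `depth`), and uniform sequencing error at
#' `error_rate` is applied to all reads at all sites.
#'
#' @param genome a [genome_record].
#' @param annotations list of [gene_annotation]s (CDS genes are used).
#' @param seed RNG seed.
#' @param n_sites number of edited C positions to plant.
#' @param fraction editing fraction at planted sites.
#' @param depth read depth per site.
#' @param error_rate per-base sequencing error probability.
#' @return list: `pileup` (data.frame `gene_id`, `cds_pos`, `ref`, `A`,
#'   `C`, `G`, `T`, `N`), `truth` (data.frame of planted sites).
#' @export
sim_editing_pileup <- function(genome, annotations, seed, n_sites = 100L,
                               fraction = 0.9, depth = 100L,
                               error_rate = 0.005) {
  set.seed(seed)
  cds_tab <- list()
  for (g in annotations) {
    if (g$biotype != "CDS") next
    cds <- extract_spliced_cds(genome, g)
    ref <- strsplit(cds, "", fixed = TRUE)[[1L]]
    cds_tab[[g$gene_id]] <- data.frame(gene_id = g$gene_id,
                                       cds_pos = seq_along(ref) - 1L,
                                       ref = ref, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, cds_tab)
  rownames(tab) <- NULL
  c_idx <- which(tab$ref == "C")
  if (length(c_idx) < n_sites)
    stop("edit plan requests ", n_sites, " sites but only ", length(c_idx),
         " C positions are available")
  planted <- sort(sample(c_idx, n_sites))
  tab$edited <- FALSE
  tab$edited[planted] <- TRUE
  counts <- matrix(0L, nrow = nrow(tab), ncol = 4L,
                   dimnames = list(NULL, DNA))
  err_profile <- function(true_base, n) {
    # each read shows the true base, or with prob error_rate a uniform other
    p <- rep(error_rate / 3, 4L); names(p) <- DNA
    p[true_base] <- 1 - error_rate
    stats::rmultinom(1L, n, p)[, 1L]
  }
  for (i in seq_len(nrow(tab))) {
    if (tab$edited[i]) {
      n_ed <- stats::rbinom(1L, depth, fraction)
      counts[i, ] <- err_profile("T", n_ed) + err_profile(tab$ref[i], depth - n_ed)
    } else {
      counts[i, ] <- err_profile(tab$ref[i], depth)
    }
  }
  pile <- data.frame(gene_id = tab$gene_id, cds_pos = tab$cds_pos,
                     ref = tab$ref, A = counts[, "A"], C = counts[, "C"],
                     G = counts[, "G"], T = counts[, "T"], N = 0L,
                     stringsAsFactors = FALSE)
  truth <- tab[tab$edited, c("gene_id", "cds_pos"), drop = FALSE]
  truth$fraction <- fraction
  rownames(truth) <- NULL
  list(pileup = pile, truth = truth)
}

# ---------------------------------------------------------------------------
# long reads from a two-isoform mixture

#' Simulate long reads from a two-conformation plastome mixture
#'
#' Read start positions are uniform on the chosen circular form, lengths
#' log-normal around `read_len_mean`, strands random, and per-base errors
#' (60% substitutions, 40% indels split evenly) applied at `error_rate`.
#'
#' @param model an `isoform_model` from [build_alternative_form].
#' @param seed RNG seed.
#' @param n_reads number of reads.
#' @param ratio_a probability a read originates from form A.
#' @param read_len_mean mean read length (bp).
#' @param read_len_sdlog log-normal sdlog.
#' @param error_rate per-base error probability.
#' @return list: `reads` (named character vector), `truth` (data.frame
#'   `read_id`, `source_form`, `start`, `length`, `strand`).
#' @export
sim_long_reads <- function(model, seed, n_reads = 500L, ratio_a = 0.7,
                           read_len_mean = 3000, read_len_sdlog = 0.35,
                           error_rate = 0.05) {
  set.seed(seed)
  forms <- list(A = model$form_a, B = model$form_b)
  src <- ifelse(stats::runif(n_reads) < ratio_a, "A", "B")
  meanlog <- log(read_len_mean) - read_len_sdlog^2 / 2
  lens <- pmax(100L, pmin(
    as.integer(round(stats::rlnorm(n_reads, meanlog, read_len_sdlog))),
    2L * model$form_a$length))
  starts <- integer(n_reads); strands <- character(n_reads)
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    g <- forms[[src[i]]]
    s0 <- sample.int(g$length, 1L) - 1L
    frag <- extract_span(g, s0, min(lens[i], g$length))
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") frag <- revcomp(frag)
    reads[i] <- apply_read_errors(frag, error_rate)
    starts[i] <- s0; strands[i] <- strand
  }
  ids <- sprintf("read_%04d", seq_len(n_reads))
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read_id = ids, source_form = src, start = starts,
                          length = lens, strand = strands,
                          stringsAsFactors = FALSE))
}

apply_read_errors <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (!length(hit)) return(s)
  kinds <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                  prob = c(0.6, 0.2, 0.2))
  out <- ch
  sub_i <- hit[kinds == "sub"]
  if (length(sub_i)) {
    # a uniformly chosen *different* base: rotate the code by 1-3
    code <- match(ch[sub_i], DNA)
    out[sub_i] <- DNA[(code - 1L + sample.int(3L, length(sub_i), replace = TRUE)) %% 4L + 1L]
  }
  ins_i <- hit[kinds == "ins"]
  if (length(ins_i))
    out[ins_i] <- paste0(sample(DNA, length(ins_i), replace = TRUE), ch[ins_i])
  out[hit[kinds == "del"]] <- ""
  paste(out, collapse = "")
}

#' Write reads to FASTQ
#'
#' @param reads named character vector.
#' @param path output path.
#' @param qual quality character used for all bases.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", names(reads)[i]), reads[[i]], "+",
                 strrep(qual, nchar(reads[[i]]))), con, sep = "\n")
  }
  invisible(path)
}

#' Read sequences from FASTA/FASTQ
#'
#' @param path FASTQ or FASTA path.
#' @return named character vector of sequences.
#' @export
read_reads <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "@")) {
    lines <- readLines(path)
    ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
    stats::setNames(lines[seq(2L, length(lines), by = 4L)], ids)
  } else {
    set <- Biostrings::readBStringSet(path)
    stats::setNames(as.character(set),
                    vapply(strsplit(names(set), "[ \t]"), `[[`, character(1L), 1L))
  }
}

# ---------------------------------------------------------------------------
# alignments evolved down trees (recombination-free or block-wise)

# Jukes-Cantor site evolution down a tree (ape phylo with branch lengths)
jc_simulate <- function(tree, n_sites) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- vector("list", ntip + nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample.int(4L, n_sites, replace = TRUE)
  ord <- rev(ape::postorder(tree))  # parents before children
  for (e in ord) {
    p <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    t <- tree$edge.length[e]
    pch <- 3 / 4 * (1 - exp(-4 * t / 3))
    s <- seqs[[p]]
    mut <- which(stats::runif(n_sites) < pch)
    if (length(mut)) {
      # uniform among the three other states
      s[mut] <- (s[mut] - 1L + sample.int(3L, length(mut), replace = TRUE)) %% 4L + 1L
    }
    seqs[[child]] <- s
  }
  out <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(out) <- tree$tip.label
  matrix(DNA[out], nrow = ntip, dimnames = list(tree$tip.label, NULL))
}

#' Simulate a (possibly recombinant) multi-block alignment
#'
#' Each block evolves down its own topology under Jukes-Cantor; a
#' single-block plan gives a recombination-free null, discordant block
#' topologies give a known recombinant with breakpoints at block joins.
#'
#' @param seed RNG seed.
#' @param n_taxa number of taxa (random topologies; ignored for explicit
#'   trees).
#' @param block_lens integer vector of block lengths (sites).
#' @param trees optional list of `phylo` trees, one per block; random
#'   topologies (same taxa, independent shapes) are drawn when `NULL`.
#' @param branch_scale mean branch length after rescaling.
#' @return list: `alignment` (named character vector), `truth`
#'   (`breakpoints`, `trees`).
#' @export
sim_alignment <- function(seed, n_taxa = 8L, block_lens = 500L, trees = NULL,
                          branch_scale = 0.08) {
  set.seed(seed)
  nb <- length(block_lens)
  if (is.null(trees)) {
    trees <- lapply(seq_len(nb), function(i) {
      tr <- ape::rtree(n_taxa)
      tr$edge.length <- tr$edge.length / mean(tr$edge.length) * branch_scale
      tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
      tr
    })
  }
  stopifnot(length(trees) == nb)
  blocks <- lapply(seq_len(nb), function(i) jc_simulate(trees[[i]], block_lens[i]))
  taxa <- rownames(blocks[[1L]])
  rows <- vapply(taxa, function(t) {
    paste(unlist(lapply(blocks, function(b) b[t, ])), collapse = "")
  }, character(1L))
  breakpoints <- if (nb > 1L) cumsum(block_lens)[-nb] else integer(0)
  list(alignment = rows,
       truth = list(breakpoints = breakpoints, trees = trees))
}

# ---------------------------------------------------------------------------
# gene layouts for cluster-retention scoring

#' Simulate a gene layout with a known set of retained clusters
#'
#' Places the genes of `retained` clusters consecutively, in catalog order,
#' on one strand with small gaps; genes of the remaining clusters are either
#' scattered far apart, strand-broken, or (for `omit` clusters) partially
#' left out, so their planted status is `lost` or `unevaluable`.
#'
#' @param seed RNG seed.
#' @param catalog named list of ordered gene vectors
#'   (default [load_cluster_catalog]).
#' @param retained character vector of cluster names to keep intact.
#' @param omit cluster names to make unevaluable (first gene dropped).
#' @param genome_length circle size (bp).
#' @return list: `genome` (random circular [genome_record]), `annotations`,
#'   `truth` (data.frame `cluster`, `status`).
#' @export
sim_cluster_annotations <- function(seed, catalog = load_cluster_catalog(),
                                    retained = names(catalog)[1:3],
                                    omit = character(0),
                                    genome_length = 450000L) {
  set.seed(seed)
  L <- as.integer(genome_length)
  gene_len <- 300L
  annotations <- list()
  cursor <- 0L
  place_gene <- function(gid, start, strand) {
    annotations[[gid]] <<- gene_annotation(
      gid, "CDS", list(segment_interval(start, start + gene_len, strand)))
  }
  status <- character(0)
  for (cname in names(catalog)) {
    genes <- catalog[[cname]]
    if (cname %in% retained) {
      strand <- sample(c("+", "-"), 1L)
      ordered <- if (strand == "-") rev(genes) else genes
      for (g in ordered) {
        place_gene(g, cursor, strand)
        cursor <- cursor + gene_len + sample(100:800, 1L)
      }
      cursor <- cursor + 10000L
      status[cname] <- "retained"
    } else if (cname %in% omit) {
      for (g in genes[-1L]) {
        place_gene(g, cursor, "+")
        cursor <- cursor + gene_len + 15000L
      }
      status[cname] <- "unevaluable"
    } else {
      # broken: same order but huge gaps (or strand flip for pairs)
      style <- sample(c("gap", "strand"), 1L)
      for (i in seq_along(genes)) {
        strand <- if (style == "strand" && i == length(genes)) "-" else "+"
        place_gene(genes[i], cursor, strand)
        cursor <- cursor + gene_len +
          if (style == "gap") 15000L else sample(100:800, 1L)
      }
      cursor <- cursor + 10000L
      status[cname] <- "lost"
    }
  }
  if (cursor >= L)
    stop("genome_length too small for catalog layout (need > ", cursor, ")")
  genome <- genome_record(sprintf("sim_clusters_seed%d", seed),
                          random_dna(L, 0.45), "circular")
  list(genome = genome, annotations = annotations,
       truth = data.frame(cluster = names(catalog),
                          status = unname(status[names(catalog)]),
                          stringsAsFactors = FALSE))
}
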