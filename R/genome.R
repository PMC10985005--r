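#' Genome records
#'
#' A `genome_record` is the universal substrate of every scan in orgkit: an
#' uppercase DNA sequence over `{A,C,G,T,N}` plus an explicit topology.
#' Topology is never inferred from the sequence; circular molecules (the
#' normal state of plant organelle genomes) unlock origin-wrapping features
#' and doubled-sequence window scans.
#'
#' @param id sequence identifier.
#' @param sequence DNA string; lowercase is folded to uppercase.
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `genome_record` with fields `id`, `sequence`,
#'   `topology` and `length`.
#' @export
genome_record <- function(id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence for record '", id, "'")
  bad <- gregexpr("[^ACGTN]", sequence)[[1L]]
  if (bad[1L] != -1L) {
    stop(sprintf(
      "non-IUPAC character '%s' in record '%s' at offset %d",
      substr(sequence, bad[1L], bad[1L]), id, bad[1L]
    ))
  }
  structure(
    list(id = id, sequence = sequence, topology = topology,
         length = nchar(sequence)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s\n",
              x$id, format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

#' @export
length.genome_record <- function(x) x$length

#' Load genomes from a FASTA file
#'
#' Reads a single- or multi-record FASTA into a list of [genome_record]s.
#' `N` is allowed; anything outside `{A,C,G,T,N}` (after case folding) is
#' rejected with the offending offset.
#'
#' @param fasta_path path to a FASTA file.
#' @param topology topology assigned to every record (FASTA cannot express it).
#' @return A named list of `genome_record`s (single record: still a list).
#' @export
load_genome <- function(fasta_path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path)
  set <- tryCatch(Biostrings::readBStringSet(fasta_path),
                  error = function(e) stop("failed to parse FASTA '",
                                           fasta_path, "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA: ", fasta_path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1L), 1L)
  recs <- lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]), topology)
  })
  names(recs) <- ids
  recs
}

#' Write genome records to FASTA
#'
#' Sequences are wrapped at 60 columns; output is byte-deterministic so that
#' generator outputs round-trip bit-identically.
#'
#' @param genomes a `genome_record` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (g in genomes) {
    starts <- seq(1L, g$length, by = 60L)
    lines <- substring(g$sequence, starts, pmin(starts + 59L, g$length))
    writeLines(c(paste0(">", g$id), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Plain-string utility used throughout; `N` maps to `N`.
#' @param s DNA string.
#' @return the reverse complement string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' GC content of a genome
#'
#' `(G + C) / (A + C + G + T)`; `N` is excluded from the denominator.
#'
#' @param genome a [genome_record].
#' @return fraction in `[0, 1]` at full precision.
#' @export
gc_content <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  counts <- base_counts(genome$sequence)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L) stop("GC content undefined: sequence is all N")
  (counts[["G"]] + counts[["C"]]) / denom
}

base_counts <- function(s) {
  tab <- table(factor(strsplit(s, "", fixed = TRUE)[[1L]],
                      levels = c("A", "C", "G", "T", "N")))
  stats::setNames(as.integer(tab), names(tab))
}

# --- circular coordinate arithmetic (0-based half-open internally) ---------

#' Segment interval
#'
#' Internal coordinates are 0-based half-open `[start, end)`. A segment on a
#' circular genome may wrap the origin, in which case `end <= start` and the
#' segment covers `[start, L) + [0, end)`.
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param strand `"+"` or `"-"`.
#' @param wraps_origin does the segment cross the origin?
#' @return a `segment_interval` list.
#' @export
segment_interval <- function(start, end, strand = "+", wraps_origin = FALSE) {
  stopifnot(strand %in% c("+", "-"), start >= 0, end >= 0)
  if (!wraps_origin && start >= end) stop("empty/inverted interval [", start, ",", end, ")")
  structure(list(start = as.integer(start), end = as.integer(end),
                 strand = strand, wraps_origin = isTRUE(wraps_origin)),
            class = "segment_interval")
}

seg_length <- function(seg, genome_length) {
  if (seg$wraps_origin) genome_length - seg$start + seg$end else seg$end - seg$start
}

# Extract [start, end) honoring circular wrap. 0-based half-open.
extract_segment <- function(genome, seg) {
  L <- genome$length
  if (seg$wraps_origin) {
    if (genome$topology != "circular")
      stop("origin-wrapping segment on linear genome '", genome$id, "'")
    paste0(substr(genome$sequence, seg$start + 1L, L),
           substr(genome$sequence, 1L, seg$end))
  } else {
    if (seg$end > L)
      stop("segment [", seg$start, ",", seg$end, ") outside genome '",
           genome$id, "' of length ", L)
    substr(genome$sequence, seg$start + 1L, seg$end)
  }
}

# Forward (clockwise) distance from position a to b on a circle of length L.
circ_fwd_dist <- function(a, b, L) ((b - a) %% L + L) %% L

# Rotate a circular genome so that old position `offset` (0-based) becomes 0.
rotate_genome <- function(genome, offset) {
  stopifnot(genome$topology == "circular")
  offset <- offset %% genome$length
  if (offset == 0L) return(genome)
  s <- genome$sequence
  genome_record(genome$id,
                paste0(substr(s, offset + 1L, genome$length),
                       substr(s, 1L, offset)),
                "circular")
}

#' Genome composition by biotype
#'
#' Fraction of genome length covered by each annotation biotype (exonic bp).
#' A bp overlapped by several biotypes is counted once, for the
#' highest-priority category: `CDS > rRNA > tRNA > noncoding` (so the four
#' fractions sum to 1).
#'
#' @param genome a [genome_record].
#' @param annotations a list of [gene_annotation]s on this genome.
#' @return named numeric vector `protein_coding`, `rRNA`, `tRNA`, `noncoding`.
#' @export
composition_summary <- function(genome, annotations) {
  L <- genome$length
  prio <- c(CDS = 3L, ORF = 3L, rRNA = 2L, tRNA = 1L)
  cov <- integer(L) # 0 = noncoding
  for (g in annotations) {
    p <- prio[[g$biotype]]
    for (ex in g$exons) {
      idx <- seg_positions(ex, L) + 1L
      cov[idx] <- pmax(cov[idx], p)
    }
  }
  n <- tabulate(cov + 1L, nbins = 4L)
  c(protein_coding = n[4L] / L, rRNA = n[3L] / L,
    tRNA = n[2L] / L, noncoding = n[1L] / L)
}

# 0-based genomic positions covered by a segment, in forward genomic order
# from its start (wrapping handled).
seg_positions <- function(seg, L) {
  if (seg$wraps_origin) c(seq.int(seg$start, L - 1L), seq.int(0L, seg$end - 1L))
  else seq.int(seg$start, seg$end - 1L)
}
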