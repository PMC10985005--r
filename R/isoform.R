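# Plastome isomer (form A / form B) modelling.
#
# Conifer plastomes carry a highly reduced inverted repeat; intramolecular
# recombination across the two IR copies flips the single-copy region
# between them, producing two coexisting conformations of one genome.
# Because the IR itself is identical in both forms, the only informative
# evidence in a long read is *which unique single-copy flanks it connects
# across the IR*. Classification therefore uses unique-anchor k-mer matching
# rather than whole-genome alignment.

#' Build the alternative plastome conformation
#'
#' Form B is form A with the arc between the two IR copies (canonically the
#' SSC) reverse-complemented. A junction catalog of `min_anchor`-bp
#' single-copy flanks is built for both forms; these anchors are what
#' [classify_isoform_reads] matches against.
#'
#' @param plastome a circular [genome_record] (form A).
#' @param ir an `ir_pair` from [find_inverted_repeat_pair].
#' @param min_anchor anchor length (bp) for the junction catalog.
#' @return an `isoform_model` list: `form_a`, `form_b` ([genome_record]s),
#'   `ir`, `anchors` (named DNA strings), `junctions` (per-form anchor
#'   pairings with expected spacing).
#' @export
build_alternative_form <- function(plastome, ir, min_anchor = 200L) {
  stopifnot(inherits(ir, "ir_pair"), plastome$topology == "circular")
  L <- plastome$length
  a <- ir$copy_1$start; b <- ir$copy_2$start; len <- ir$ir_length
  if (circ_fwd_dist(a + len, b, L) + circ_fwd_dist((b + len) %% L, a, L) +
      2L * len != L)
    stop("IR copies overlap; cannot build the alternative form")
  # arc strictly between copy_1 and copy_2 (the flipped arc)
  mid_start <- (a + len) %% L
  mid_len <- circ_fwd_dist(a + len, b, L)
  if (mid_len < 2L * min_anchor)
    stop("arc between IR copies shorter than two anchors")
  out_len <- L - mid_len - 2L * len
  if (out_len < 2L * min_anchor)
    stop("arc outside IR copies shorter than two anchors")
  # the simple splice below requires the flipped arc not to wrap the origin;
  # if it does, rotate the genome so copy_1 starts at 0 (coordinates on a
  # circle are a representation choice, not information)
  if (mid_start + mid_len > L) {
    rot <- rotate_genome(plastome, a)
    return(build_alternative_form(rot, shift_ir(ir, a, L), min_anchor))
  }
  mid <- extract_span(plastome, mid_start, mid_len)
  prefix <- if (mid_start > 0L) extract_span(plastome, 0L, mid_start) else ""
  suf_len <- L - mid_start - mid_len
  suffix <- if (suf_len > 0L) extract_span(plastome, mid_start + mid_len, suf_len) else ""
  form_b <- genome_record(paste0(plastome$id, "_formB"),
                          paste0(prefix, revcomp(mid), suffix), "circular")

  # unique single-copy anchors: (1) outer arc end abutting copy_1,
  # (2) flipped arc start, (3) flipped arc end, (4) outer arc start after copy_2
  anch <- c(
    A1 = extract_span(plastome, (a - min_anchor) %% L, min_anchor),
    A2 = extract_span(plastome, mid_start, min_anchor),
    A3 = extract_span(plastome, (mid_start + mid_len - min_anchor) %% L, min_anchor),
    A4 = extract_span(plastome, (b + len) %% L, min_anchor))
  # expected offset between anchor starts across the IR
  spacing <- min_anchor + len
  junctions <- list(
    form_A = list(
      list(up = "A1", up_rc = FALSE, down = "A2", down_rc = FALSE, spacing = spacing),
      list(up = "A3", up_rc = FALSE, down = "A4", down_rc = FALSE, spacing = spacing)),
    form_B = list(
      list(up = "A1", up_rc = FALSE, down = "A3", down_rc = TRUE, spacing = spacing),
      list(up = "A2", up_rc = TRUE, down = "A4", down_rc = FALSE, spacing = spacing)))
  structure(list(form_a = plastome, form_b = form_b, ir = ir,
                 min_anchor = as.integer(min_anchor), anchors = anch,
                 junctions = junctions),
            class = "isoform_model")
}

shift_ir <- function(ir, offset, L) {
  sh <- function(seg) {
    s <- circ_fwd_dist(offset, seg$start, L)
    len <- seg_length(seg, L)
    wraps <- s + len > L
    segment_interval(s, if (wraps) (s + len) %% L else s + len, seg$strand,
                     wraps_origin = wraps)
  }
  structure(list(copy_1 = sh(ir$copy_1), copy_2 = sh(ir$copy_2),
                 ir_length = ir$ir_length,
                 lsc = if (is.null(ir$lsc)) NULL else sh(ir$lsc),
                 ssc = if (is.null(ir$ssc)) NULL else sh(ir$ssc),
                 identity = ir$identity), class = "ir_pair")
}

# k-mer index of the model anchors: parallel vectors (kmer, oriented-anchor
# code 1..8, offset). k-mer collisions across anchors are essentially
# impossible on screened backgrounds; the first occurrence wins.
anchor_kmer_index <- function(model, k) {
  kmer <- character(0); code <- integer(0); off <- integer(0)
  ci <- 0L
  for (nm in names(model$anchors)) {
    for (rc in c(FALSE, TRUE)) {
      ci <- ci + 1L
      s <- model$anchors[[nm]]
      if (rc) s <- revcomp(s)
      n <- nchar(s)
      if (n < k) next
      km <- substring(s, 1:(n - k + 1L), k:n)
      kmer <- c(kmer, km)
      code <- c(code, rep(ci, length(km)))
      off <- c(off, seq_along(km) - 1L)
    }
  }
  keep <- !duplicated(kmer)
  # oriented-anchor code ci: (anchor index - 1) * 2 + rc + 1, anchors in
  # names(model$anchors) order
  list(kmer = kmer[keep], code = code[keep], off = off[keep],
       anchor = rep(names(model$anchors), each = 2L),
       rc = rep(c(FALSE, TRUE), length(model$anchors)))
}

#' Classify long reads by plastome conformation
#'
#' Each read (both orientations) is matched against the junction-anchor
#' k-mer catalog. A read is labelled `form_A` or `form_B` if it spans at
#' least one IR junction whose unique flanks pair the way exactly one form
#' predicts (with `min_anchor_kmers` clean k-mers on each side and
#' consistent spacing); `chimeric` if different junctions in the same read
#' support different forms (the signature of within-molecule recombination);
#' `ambiguous` if it spans no junction. Reads shorter than a junction span
#' are ambiguous by construction, never an error.
#'
#' @param reads character vector of read sequences (or named vector).
#' @param model an `isoform_model` from [build_alternative_form].
#' @param k k-mer size for anchor matching.
#' @param min_anchor_kmers minimum matching k-mers per anchor side.
#' @param spacing_tol_frac,spacing_tol_abs spacing tolerance: the observed
#'   anchor-to-anchor offset may deviate from the expected IR span by
#'   `frac * expected + abs` (indel slack for noisy long reads).
#' @return data.frame: `read_id`, `label`, `junctions_spanned`,
#'   `n_support_a`, `n_support_b`.
#' @export
classify_isoform_reads <- function(reads, model, k = 15L,
                                   min_anchor_kmers = 3L,
                                   spacing_tol_frac = 0.25,
                                   spacing_tol_abs = 100) {
  idx <- anchor_kmer_index(model, k)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  res <- lapply(seq_along(reads), function(i) {
    counts <- junction_support(reads[[i]], model, idx, k,
                               min_anchor_kmers, spacing_tol_frac,
                               spacing_tol_abs)
    na <- counts["A"]; nb <- counts["B"]
    label <- if (na > 0L && nb > 0L) "chimeric"
    else if (na > 0L) "form_A"
    else if (nb > 0L) "form_B"
    else "ambiguous"
    data.frame(read_id = ids[i], label = label,
               junctions_spanned = na + nb,
               n_support_a = na, n_support_b = nb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# count junctions supported per form within one read (either orientation)
junction_support <- function(read, model, idx, k, min_kmers,
                             tol_frac, tol_abs) {
  support <- c(A = 0L, B = 0L)
  anchor_names <- names(model$anchors)
  n <- nchar(read)
  if (n < k) return(support)
  km <- substring(read, 1:(n - k + 1L), k:n)
  m <- match(km, idx$kmer)
  hit <- which(!is.na(m))
  if (length(hit) < 2L * min_kmers) return(support)
  code <- idx$code[m[hit]]
  diag <- hit - idx$off[m[hit]]  # read start offset of the anchor
  # an anchor is "present" at read offset d if >= min_kmers hits agree on
  # a tight diagonal band (+-20 bp for indel noise)
  pres_anchor <- character(0); pres_rc <- logical(0); pres_at <- numeric(0)
  for (ci in unique(code)) {
    d <- sort(diag[code == ci])
    grp <- cumsum(c(1L, diff(d) > 20L))
    for (g in unique(grp)) {
      dd <- d[grp == g]
      if (length(dd) >= min_kmers) {
        pres_anchor <- c(pres_anchor, anchor_names[(ci - 1L) %/% 2L + 1L])
        pres_rc <- c(pres_rc, (ci - 1L) %% 2L == 1L)
        pres_at <- c(pres_at, stats::median(dd))
      }
    }
  }
  if (length(pres_anchor) < 2L) return(support)
  pair_within <- function(a1, rc1, a2, rc2, spacing) {
    # anchor (a1, rc1) followed by (a2, rc2) at ~spacing downstream
    i1 <- which(pres_anchor == a1 & pres_rc == rc1)
    i2 <- which(pres_anchor == a2 & pres_rc == rc2)
    if (!length(i1) || !length(i2)) return(FALSE)
    tol <- tol_frac * spacing + tol_abs
    gaps <- outer(pres_at[i2], pres_at[i1], `-`)
    any(gaps > 0 & abs(gaps - spacing) <= tol)
  }
  for (form in c("A", "B")) {
    for (j in model$junctions[[paste0("form_", form)]]) {
      # forward-strand pattern, or its mirror image (reverse-strand read):
      # rc(down) followed by rc(up) at the same spacing
      if (pair_within(j$up, j$up_rc, j$down, j$down_rc, j$spacing) ||
          pair_within(j$down, !j$down_rc, j$up, !j$up_rc, j$spacing))
        support[form] <- support[form] + 1L
    }
  }
  support
}

#' Estimate the isomer mixing ratio from read calls
#'
#' `p = A / (A + B)` over informative reads with a Wilson 95% confidence
#' interval; ambiguous and chimeric reads are excluded from the denominator
#' but reported.
#'
#' @param calls data.frame from [classify_isoform_reads].
#' @return list: `p_form_a`, `ci_95` (length-2), `n_a`, `n_b`,
#'   `n_ambiguous`, `n_chimeric`; `p_form_a` is `NA` with a zero-width
#'   undefined interval when no informative reads exist.
#' @export
estimate_isoform_ratio <- function(calls) {
  n_a <- sum(calls$label == "form_A")
  n_b <- sum(calls$label == "form_B")
  n <- n_a + n_b
  if (n == 0L) {
    return(list(p_form_a = NA_real_, ci_95 = c(NA_real_, NA_real_),
                n_a = n_a, n_b = n_b,
                n_ambiguous = sum(calls$label == "ambiguous"),
                n_chimeric = sum(calls$label == "chimeric")))
  }
  p <- n_a / n
  z <- stats::qnorm(0.975)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(p_form_a = p, ci_95 = c(max(0, center - half), min(1, center + half)),
       n_a = n_a, n_b = n_b,
       n_ambiguous = sum(calls$label == "ambiguous"),
       n_chimeric = sum(calls$label == "chimeric"))
}
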