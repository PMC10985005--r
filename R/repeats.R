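# Dispersed repeat discovery.
#
# Strategy: exact k-mer seeding (k = 20) of the genome against itself and
# against its reverse complement, seeds merged per (anti)diagonal and
# extended to maximal exact matches; matches on a shared (anti)diagonal are
# then chained across short mismatch gaps and re-scored so diverged repeat
# copies (point mutations) come out as single units with an identity
# fraction. Circular genomes are scanned on a doubled-sequence view and hits
# deduplicated modulo L, which makes the scan invariant to the (arbitrary)
# choice of origin.

# All maximal exact matches >= min_len. Returns 0-based starts modulo L.
# orientation "direct": seq[a,a+len) == seq[b,b+len)
# orientation "inverted": seq[a,a+len) == revcomp(seq[b,b+len))
maximal_exact_matches <- function(genome, min_len = 30L, k = 20L) {
  stopifnot(inherits(genome, "genome_record"))
  if (min_len < k) stop("min_len (", min_len, ") must be >= seed size ", k)
  L <- genome$length
  S2 <- if (genome$topology == "circular")
    paste0(genome$sequence, genome$sequence) else genome$sequence
  n2 <- nchar(S2)
  if (n2 < k) return(empty_match_df())
  ch_s <- strsplit(S2, "", fixed = TRUE)[[1L]]
  R2 <- revcomp(S2)
  ch_r <- strsplit(R2, "", fixed = TRUE)[[1L]]

  starts <- seq_len(n2 - k + 1L)
  km_s <- substring(S2, starts, starts + k - 1L)
  km_r <- substring(R2, starts, starts + k - 1L)

  out <- list(
    direct_matches(km_s, ch_s, k, L, n2),
    inverted_matches(km_s, km_r, ch_s, ch_r, k, L, n2)
  )
  m <- do.call(rbind, out)
  m <- m[m$length >= min_len & m$length <= L, , drop = FALSE]
  if (nrow(m) == 0L) return(empty_match_df())
  dedup_matches(m)
}

empty_match_df <- function() {
  data.frame(start_a = integer(), start_b = integer(), length = integer(),
             orientation = character(), stringsAsFactors = FALSE)
}

# seed pairs -> per-diagonal runs -> extended maximal matches (direct)
direct_matches <- function(km, ch, k, L, n2) {
  grp <- split(seq_along(km), km)
  grp <- grp[lengths(grp) >= 2L]
  if (!length(grp)) return(empty_match_df())
  too_big <- lengths(grp) > 2000L
  if (any(too_big))
    stop("low-complexity sequence: a ", k, "-mer occurs ",
         max(lengths(grp)), " times; cannot enumerate repeat seeds")
  ii <- integer(0); dd <- integer(0)
  for (pos in grp) {
    pr <- utils::combn(sort(pos), 2L)
    d <- pr[2L, ] - pr[1L, ]
    keep <- d %% L != 0L  # same circle position in the doubled view
    ii <- c(ii, pr[1L, keep]); dd <- c(dd, d[keep])
  }
  if (!length(ii)) return(empty_match_df())
  res <- list()
  for (d in unique(dd)) {
    is <- sort(ii[dd == d])
    runs <- split(is, cumsum(c(1L, diff(is) != 1L)))
    for (r in runs) {
      a <- r[1L]; len <- r[length(r)] - a + k
      b <- a + d
      # extend left
      while (a > 1L && b > 1L && ch[a - 1L] == ch[b - 1L]) {
        a <- a - 1L; b <- b - 1L; len <- len + 1L
      }
      # extend right
      while (a + len <= n2 && b + len <= n2 && ch[a + len] == ch[b + len])
        len <- len + 1L
      res[[length(res) + 1L]] <- c(a, b, len)
    }
  }
  mat <- do.call(rbind, res)
  data.frame(start_a = (mat[, 1L] - 1L) %% L, start_b = (mat[, 2L] - 1L) %% L,
             length = mat[, 3L], orientation = "direct",
             stringsAsFactors = FALSE)
}

# matches between S2 and revcomp(S2), mapped back to genome coordinates
inverted_matches <- function(km_s, km_r, ch_s, ch_r, k, L, n2) {
  shared <- intersect(unique(km_s), unique(km_r))
  if (!length(shared)) return(empty_match_df())
  pos_s <- split(seq_along(km_s), km_s)[shared]
  pos_r <- split(seq_along(km_r), km_r)[shared]
  ii <- integer(0); pp <- integer(0)
  for (w in seq_along(shared)) {
    cross <- expand.grid(i = pos_s[[w]], p = pos_r[[w]])
    if (nrow(cross) > 4e5)
      stop("low-complexity sequence: inverted seed explosion")
    ii <- c(ii, cross$i); pp <- c(pp, cross$p)
  }
  dd <- pp - ii
  res <- list()
  for (d in unique(dd)) {
    is <- sort(ii[dd == d])
    runs <- split(is, cumsum(c(1L, diff(is) != 1L)))
    for (r in runs) {
      a <- r[1L]; len <- r[length(r)] - a + k
      p <- a + d
      while (a > 1L && p > 1L && ch_s[a - 1L] == ch_r[p - 1L]) {
        a <- a - 1L; p <- p - 1L; len <- len + 1L
      }
      while (a + len <= n2 && p + len <= n2 && ch_s[a + len] == ch_r[p + len])
        len <- len + 1L
      # R2[p, p+len) is revcomp of S2[n2-p-len+2, n2-p+1] (1-based)
      b1 <- n2 - p - len + 2L
      res[[length(res) + 1L]] <- c(a, b1, len)
    }
  }
  if (!length(res)) return(empty_match_df())
  mat <- do.call(rbind, res)
  df <- data.frame(start_a = (mat[, 1L] - 1L) %% L, start_b = (mat[, 2L] - 1L) %% L,
                   length = mat[, 3L], orientation = "inverted",
                   stringsAsFactors = FALSE)
  # a perfect palindrome matches itself at the same locus; the pair-list
  # invariant requires two distinct loci
  df[df$start_a != df$start_b, , drop = FALSE]
}

# canonicalize (unordered locus pair) and drop doubled-view duplicates,
# keeping the longest representative of each pair
dedup_matches <- function(m) {
  a <- pmin(m$start_a, m$start_b); b <- pmax(m$start_a, m$start_b)
  m$start_a <- a; m$start_b <- b
  key <- paste(m$start_a, m$start_b, m$orientation, sep = ":")
  m <- m[order(key, -m$length), , drop = FALSE]
  m <- m[!duplicated(paste(m$start_a, m$start_b, m$orientation, sep = ":")), ,
         drop = FALSE]
  m <- m[order(m$start_a, -m$length, m$start_b), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Find dispersed direct and inverted repeats
#'
#' Reports every repeated unit of at least `min_len` bp at identity
#' `>= min_identity` as a pair of loci. Exact maximal matches are found by
#' k-mer seeding and extension; collinear exact blocks separated by short
#' mismatch gaps (diverged copies) are chained and re-scored. Output order is
#' deterministic: by `start_a`, then unit length descending.
#'
#' @param genome a [genome_record].
#' @param min_len minimum repeat unit length (bp, `>= 20`).
#' @param min_identity minimum identity fraction for chained (diverged) units.
#' @return data.frame with columns `unit_length`, `start_a`, `end_a`,
#'   `start_b`, `end_b` (0-based half-open; `end` may exceed the genome
#'   length for origin-wrapping loci on circular genomes), `orientation`
#'   (`direct`/`inverted`) and `identity`.
#' @export
find_dispersed_repeats <- function(genome, min_len = 30L, min_identity = 0.90) {
  if (min_len < 20L)
    stop("min_len < 20 is refused: the exact-seed scheme is unreliable below the seed size")
  m <- maximal_exact_matches(genome, min_len = 20L, k = 20L)
  if (nrow(m) == 0L) return(empty_repeat_df())
  ch <- chain_matches(m, genome, min_len, min_identity)
  ch <- ch[ch$unit_length >= min_len & ch$identity >= min_identity, , drop = FALSE]
  ch <- canonical_repeat_order(ch)
  ch
}

empty_repeat_df <- function() {
  data.frame(unit_length = integer(), start_a = integer(), end_a = integer(),
             start_b = integer(), end_b = integer(), orientation = character(),
             identity = numeric(), stringsAsFactors = FALSE)
}

canonical_repeat_order <- function(df) {
  if (nrow(df) == 0L) return(df)
  swap <- df$start_a > df$start_b
  tmp_s <- df$start_a[swap]; tmp_e <- df$end_a[swap]
  df$start_a[swap] <- df$start_b[swap]; df$end_a[swap] <- df$end_b[swap]
  df$start_b[swap] <- tmp_s; df$end_b[swap] <- tmp_e
  df <- df[order(df$start_a, -df$unit_length, df$start_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# chain exact blocks that share an (anti)diagonal across small gaps; rescore
# identity by direct comparison of the chained spans
chain_matches <- function(m, genome, min_len, min_identity, max_chain_gap = 100L) {
  L <- genome$length
  diag_key <- ifelse(m$orientation == "direct",
                     (m$start_b - m$start_a) %% L,
                     (m$start_a + m$start_b + m$length) %% L)
  out <- list()
  for (key in unique(paste(m$orientation, diag_key))) {
    sel <- m[paste(m$orientation, diag_key) == key, , drop = FALSE]
    sel <- sel[order(sel$start_a), , drop = FALSE]
    ori <- sel$orientation[1L]
    chain_id <- cumsum(c(
      1L,
      (sel$start_a[-1L] - (sel$start_a[-nrow(sel)] + sel$length[-nrow(sel)])) >
        max_chain_gap))
    for (cid in unique(chain_id)) {
      blk <- sel[chain_id == cid, , drop = FALSE]
      a0 <- min(blk$start_a); a1 <- max(blk$start_a + blk$length)
      span <- a1 - a0
      if (ori == "direct") {
        b0 <- (a0 + (blk$start_b[1L] - blk$start_a[1L])) %% L
      } else {
        # anti-diagonal: a + b + len constant
        cst <- blk$start_a[1L] + blk$start_b[1L] + blk$length[1L]
        b0 <- (cst - a1) %% L
      }
      sa <- extract_span(genome, a0, span)
      sb <- extract_span(genome, b0, span)
      if (ori == "inverted") sb <- revcomp(sb)
      ident <- span_identity(sa, sb)
      out[[length(out) + 1L]] <- data.frame(
        unit_length = span, start_a = a0, end_a = a0 + span,
        start_b = b0, end_b = b0 + span, orientation = ori,
        identity = ident, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

extract_span <- function(genome, start0, len) {
  L <- genome$length
  if (start0 + len <= L) {
    substr(genome$sequence, start0 + 1L, start0 + len)
  } else {
    if (genome$topology != "circular")
      stop("span beyond end of linear genome")
    paste0(substr(genome$sequence, start0 + 1L, L),
           substr(genome$sequence, 1L, start0 + len - L))
  }
}

span_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(ca == cb)
}

#' Summarize repeats by size class
#'
#' Units (distinct repeated sequences, not locus pairs) are counted per size
#' class: large `> 1000` bp, intermediate `100-1000` bp (inclusive), small
#' `< 100` bp. Pairs whose loci coincide (reciprocal overlap `>= 0.9`,
#' single linkage) collapse into one unit. `total_repeat_bp` is the union of
#' all repeat loci -- overlapping loci are never double-counted.
#'
#' @param pairs output of [find_dispersed_repeats].
#' @param genome the scanned [genome_record].
#' @return list with `total_repeat_bp`, `counts` (named: large,
#'   intermediate, small), `n_units`, `min_len_observed`, `max_len_observed`.
#' @export
summarize_repeats <- function(pairs, genome) {
  L <- genome$length
  if (nrow(pairs) == 0L) {
    return(list(total_repeat_bp = 0L,
                counts = c(large = 0L, intermediate = 0L, small = 0L),
                n_units = 0L, min_len_observed = NA_integer_,
                max_len_observed = NA_integer_))
  }
  # coverage union
  cov <- logical(L)
  loci <- rbind(
    data.frame(start = pairs$start_a, len = pairs$unit_length, pair = seq_len(nrow(pairs))),
    data.frame(start = pairs$start_b, len = pairs$unit_length, pair = seq_len(nrow(pairs))))
  for (i in seq_len(nrow(loci)))
    cov[(seq.int(loci$start[i], length.out = loci$len[i]) %% L) + 1L] <- TRUE

  # single-linkage unit clustering on >= 90% reciprocal locus overlap
  n <- nrow(loci)
  parent <- seq_len(nrow(pairs))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(x, y) {
    rx <- find(x); ry <- find(y); if (rx != ry) parent[ry] <<- rx
  }
  ov <- function(s1, l1, s2, l2) {
    # circular-safe overlap via linear intervals in [0, 2L)
    o <- max(0L, min(s1 + l1, s2 + l2) - max(s1, s2))
    o2 <- max(0L, min(s1 + L + l1, s2 + l2) - max(s1 + L, s2))
    o3 <- max(0L, min(s1 + l1, s2 + L + l2) - max(s1, s2 + L))
    max(o, o2, o3)
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (loci$pair[i] == loci$pair[j]) next
      o <- ov(loci$start[i], loci$len[i], loci$start[j], loci$len[j])
      if (o >= 0.9 * loci$len[i] && o >= 0.9 * loci$len[j])
        union_(loci$pair[i], loci$pair[j])
    }
  }
  roots <- vapply(seq_len(nrow(pairs)), find, integer(1L))
  unit_len <- vapply(split(pairs$unit_length, roots), max, numeric(1L))
  counts <- c(large = sum(unit_len > 1000),
              intermediate = sum(unit_len >= 100 & unit_len <= 1000),
              small = sum(unit_len < 100))
  list(total_repeat_bp = sum(cov), counts = counts,
       n_units = length(unit_len),
       min_len_observed = min(pairs$unit_length),
       max_len_observed = max(pairs$unit_length))
}

#' Locate the plastome inverted-repeat pair
#'
#' Returns the longest inverted repeat pair that partitions the circle into
#' two single-copy arcs, with the large (LSC) and small (SSC) single-copy
#' regions assigned by arc length. Conifer plastomes carry a highly reduced
#' IR (around 1.2 kb), so the default `min_len` is 100 bp.
#'
#' @param genome a circular [genome_record].
#' @param min_len minimum IR length to consider.
#' @return an `ir_pair` list (`copy_1`, `copy_2` as [segment_interval]s,
#'   `ir_length`, `lsc`, `ssc`), or `NULL` if the genome has no inverted
#'   repeat of at least `min_len` bp (an explicit absence result).
#' @export
find_inverted_repeat_pair <- function(genome, min_len = 100L) {
  stopifnot(genome$topology == "circular")
  reps <- find_dispersed_repeats(genome, min_len = max(20L, min(min_len, 30L)))
  inv <- reps[reps$orientation == "inverted", , drop = FALSE]
  inv <- inv[inv$unit_length >= min_len, , drop = FALSE]
  if (nrow(inv) == 0L) return(NULL)
  L <- genome$length
  # longest pair with non-overlapping loci
  inv <- inv[order(-inv$unit_length), , drop = FALSE]
  for (i in seq_len(nrow(inv))) {
    a <- inv$start_a[i]; b <- inv$start_b[i]; len <- inv$unit_length[i]
    gap_ab <- circ_fwd_dist(a + len, b, L)
    gap_ba <- circ_fwd_dist((b + len) %% L, a, L)
    if (2L * len + gap_ab + gap_ba != L) next  # overlapping copies
    arcs <- list(
      list(start = (a + len) %% L, len = gap_ab),
      list(start = (b + len) %% L, len = gap_ba))
    ord <- order(-c(arcs[[1L]]$len, arcs[[2L]]$len))
    mk_seg <- function(arc) {
      if (arc$len == 0L) return(NULL)
      e <- (arc$start + arc$len) %% L
      wraps <- arc$start + arc$len > L
      segment_interval(arc$start, if (wraps) e else arc$start + arc$len,
                       "+", wraps_origin = wraps)
    }
    mk_copy <- function(s) {
      wraps <- s + len > L
      segment_interval(s, if (wraps) (s + len) %% L else s + len, "+",
                       wraps_origin = wraps)
    }
    return(structure(list(
      copy_1 = mk_copy(a), copy_2 = mk_copy(b), ir_length = len,
      lsc = mk_seg(arcs[[ord[1L]]]), ssc = mk_seg(arcs[[ord[2L]]]),
      identity = inv$identity[i]), class = "ir_pair"))
  }
  NULL
}

#' @export
print.ir_pair <- function(x, ...) {
  cat(sprintf("<ir_pair> IR %d bp at %d and %d; identity %.3f\n",
              x$ir_length, x$copy_1$start, x$copy_2$start, x$identity))
  invisible(x)
}

#' Write repeat pairs as BED6
#'
#' One line per locus; `name` is the unit id shared by the two loci of a
#' pair, strand encodes orientation (`+` direct, `-` inverted second copy).
#'
#' @param pairs output of [find_dispersed_repeats].
#' @param genome the scanned genome.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeats_bed <- function(pairs, genome, path) {
  lines <- character(0)
  L <- genome$length
  for (i in seq_len(nrow(pairs))) {
    nm <- sprintf("repeat_%04d", i)
    for (side in c("a", "b")) {
      s <- pairs[[paste0("start_", side)]][i]
      e <- pairs[[paste0("end_", side)]][i]
      strand <- if (side == "b" && pairs$orientation[i] == "inverted") "-" else "+"
      lines <- c(lines, paste(genome$id, s, min(e, L), nm, 0, strand, sep = "\t"))
    }
  }
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
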