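# Independent brute-force oracles. These deliberately avoid the package's
# seeding/extension machinery: repeats by exhaustive shift comparison, ORFs
# by regex over Biostrings translations, editing consequences by full
# protein rebuild-and-diff, bipartitions via ape::prop.part.

# --- repeats: O(L^2) shift-comparison oracle -------------------------------

# all maximal exact matches >= min_len as canonical tuples
# "start_a:start_b:len:orientation" (0-based, modulo L, unordered pair)
oracle_repeat_set <- function(genome, min_len = 30L) {
  L <- genome$length
  s2 <- if (genome$topology == "circular")
    paste0(genome$sequence, genome$sequence) else genome$sequence
  n2 <- nchar(s2)
  ch <- strsplit(s2, "", fixed = TRUE)[[1L]]
  rch <- strsplit(orgkit::revcomp(s2), "", fixed = TRUE)[[1L]]
  res <- new.env(parent = emptyenv())
  put <- function(a, b, len, ori) {
    a0 <- (a - 1L) %% L; b0 <- (b - 1L) %% L
    if (len > L) len <- L
    key <- paste(min(a0, b0), max(a0, b0), ori, sep = ":")
    old <- res[[key]]
    if (is.null(old) || old < len) res[[key]] <- len
  }
  # match runs from mismatch indices (cheaper than rle at this scale)
  runs_of <- function(eq) {
    mm <- c(0L, which(!eq), length(eq) + 1L)
    lens <- diff(mm) - 1L
    keep <- lens >= min_len
    cbind(mm[-length(mm)][keep] + 1L, lens[keep])
  }
  for (d in seq_len(n2 - min_len)) {
    if (d %% L == 0L) next
    eq <- ch[seq_len(n2 - d)] == ch[seq_len(n2 - d) + d]
    m <- runs_of(eq)
    if (nrow(m)) for (r in seq_len(nrow(m)))
      put(m[r, 1L], m[r, 1L] + d, m[r, 2L], "direct")
  }
  for (dd in seq.int(-(n2 - min_len), n2 - min_len)) {
    i0 <- max(1L, 1L - dd); i1 <- min(n2, n2 - dd)
    if (i1 - i0 + 1L < min_len) next
    eq <- ch[i0:i1] == rch[(i0 + dd):(i1 + dd)]
    m <- runs_of(eq)
    if (nrow(m)) for (r in seq_len(nrow(m))) {
      a <- i0 + m[r, 1L] - 1L; len <- m[r, 2L]; p <- a + dd
      b <- n2 - p - len + 2L  # map reverse-strand coords back
      a0 <- (a - 1L) %% L; b0 <- (b - 1L) %% L
      if (a0 == b0) next  # self-palindrome
      put(a, b, len, "inverted")
    }
  }
  keys <- ls(res)
  if (!length(keys)) return(character(0))
  sort(paste0(keys, ":", vapply(keys, function(k) res[[k]], numeric(1L))))
}

match_df_to_set <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(pmin(df$start_a, df$start_b), pmax(df$start_a, df$start_b),
             df$orientation, df$length, sep = ":"))
}

# --- ORFs: regex oracle over Biostrings translations -----------------------

oracle_orf_set <- function(genome, min_len) {
  stopifnot(genome$topology == "linear")
  s <- genome$sequence
  n <- nchar(s)
  out <- character(0)
  for (strand in c("+", "-")) {
    str <- if (strand == "+") s else orgkit::revcomp(s)
    for (frame in 0:2) {
      nc <- ((n - frame) %/% 3L) * 3L
      if (nc < 3L) next
      prot <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(substr(str, frame + 1L, frame + nc)),
        if.fuzzy.codon = "X")))
      mm <- gregexpr("M[^*]*\\*", prot)[[1L]]
      if (mm[1L] == -1L) next
      for (j in seq_along(mm)) {
        aa_start <- mm[j]; aa_len <- attr(mm, "match.length")[j]
        nt_start <- frame + (aa_start - 1L) * 3L + 1L  # 1-based in str
        nt_len <- aa_len * 3L
        if (nt_len < min_len) next
        g0 <- if (strand == "+") nt_start - 1L else n - (nt_start - 1L) - nt_len
        out <- c(out, paste(g0, g0 + nt_len, strand, sep = ":"))
      }
    }
  }
  sort(out)
}

# --- editing consequence: rebuild-and-diff oracle --------------------------

# batch form: rebuilds the full protein of every edited variant with one
# vectorized Biostrings::translate call and diffs against the original
oracle_consequence_batch <- function(cds, positions) {
  stopifnot(all(substring(cds, positions + 1L, positions + 1L) == "C"))
  nc <- (nchar(cds) %/% 3L) * 3L
  variants <- vapply(positions, function(p) {
    x <- cds; substr(x, p + 1L, p + 1L) <- "T"; substr(x, 1L, nc)
  }, character(1L))
  prots <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAStringSet(c(substr(cds, 1L, nc), variants)),
    no.init.codon = TRUE)))
  p1 <- prots[1L]; p2 <- prots[-1L]
  vapply(seq_along(positions), function(i) {
    codon_idx <- positions[i] %/% 3L
    if (codon_idx == 0L) {
      codon_after <- substr(variants[i], 1L, 3L)
      return(if (codon_after == "ATG") "start_gain" else "start_codon_edit")
    }
    if (p1 == p2[i]) return("silent")
    aa1 <- substr(p1, codon_idx + 1L, codon_idx + 1L)
    aa2 <- substr(p2[i], codon_idx + 1L, codon_idx + 1L)
    if (aa1 == "*") return("stop_codon_edit")
    if (aa2 == "*") return("stop_gain")
    "missense"
  }, character(1L))
}

oracle_consequence <- function(cds, cds_pos) {
  stopifnot(substr(cds, cds_pos + 1L, cds_pos + 1L) == "C")
  edited <- cds
  substr(edited, cds_pos + 1L, cds_pos + 1L) <- "T"
  codon_idx <- cds_pos %/% 3L
  if (codon_idx == 0L) {
    codon_after <- substr(edited, 1L, 3L)
    return(if (codon_after == "ATG") "start_gain" else "start_codon_edit")
  }
  tr <- function(x) as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(x), no.init.codon = TRUE)))
  nc <- (nchar(cds) %/% 3L) * 3L
  p1 <- tr(substr(cds, 1L, nc)); p2 <- tr(substr(edited, 1L, nc))
  if (p1 == p2) return("silent")
  aa1 <- substr(p1, codon_idx + 1L, codon_idx + 1L)
  aa2 <- substr(p2, codon_idx + 1L, codon_idx + 1L)
  if (aa1 == "*") return("stop_codon_edit")
  if (aa2 == "*") return("stop_gain")
  "missense"
}

# --- bipartitions: ape::prop.part oracle -----------------------------------

oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  nt <- length(labs)
  ref <- sort(labs)[1L]
  keys <- character(0)
  for (p in pp) {
    side <- labs[p]
    if (length(side) <= 1L || length(side) >= nt - 1L) next
    if (ref %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1); b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# shared helper: key sites by (gene, position)
site_key <- function(df) paste(df$gene_id, df$cds_pos, sep = ":")
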