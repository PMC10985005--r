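# Supermatrix bookkeeping, topology conflict and the PHI recombination test.

#' Read a FASTA multiple alignment
#'
#' @param path FASTA path.
#' @return named character vector of equal-length aligned sequences.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- stats::setNames(toupper(as.character(set)),
                         vapply(strsplit(names(set), "[ \t]"), `[[`,
                                character(1L), 1L))
  if (length(unique(nchar(out))) > 1L)
    stop("ragged alignment in '", path, "': rows ",
         paste(sprintf("%s(%d)", names(out), nchar(out)), collapse = ", "))
  out
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Partitions are laid out in input order as 1-based inclusive column
#' ranges; a taxon absent from a source gene is padded with `?` across that
#' partition. Taxon names may be reconciled through `taxon_map`
#' (`old name -> canonical name`).
#'
#' @param alignments named list: gene id -> FASTA path or named character
#'   vector (one aligned sequence per taxon).
#' @param taxon_map optional named character vector renaming taxa.
#' @return a `supermatrix` list: `taxa`, `columns`, `partitions`
#'   (data.frame `gene_id`, `start`, `end`), `matrix` (named character
#'   vector of concatenated rows).
#' @export
concatenate_alignments <- function(alignments, taxon_map = NULL) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  aln <- lapply(names(alignments), function(g) {
    x <- alignments[[g]]
    if (is.character(x) && length(x) == 1L && file.exists(x))
      x <- read_alignment_fasta(x)
    if (is.null(names(x))) stop("alignment '", g, "' has unnamed rows")
    if (length(unique(nchar(x))) > 1L)
      stop("ragged alignment '", g, "': rows ",
           paste(sprintf("%s(%d)", names(x), nchar(x)), collapse = ", "))
    if (!is.null(taxon_map)) {
      hit <- names(x) %in% names(taxon_map)
      names(x)[hit] <- taxon_map[names(x)[hit]]
    }
    x
  })
  names(aln) <- names(alignments)
  taxa <- sort(unique(unlist(lapply(aln, names))))
  widths <- vapply(aln, function(x) nchar(x[[1L]]), integer(1L))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  for (i in seq_along(aln)) {
    x <- aln[[i]]
    pad <- strrep("?", widths[i])
    add <- ifelse(taxa %in% names(x), x[taxa], pad)
    rows <- paste0(rows, add)
  }
  names(rows) <- taxa
  sm <- structure(list(
    taxa = taxa, columns = unname(ends[length(ends)]),
    partitions = data.frame(gene_id = names(aln), start = unname(starts),
                            end = unname(ends), stringsAsFactors = FALSE),
    matrix = rows), class = "supermatrix")
  stopifnot(sm$columns == sum(sm$partitions$end - sm$partitions$start + 1L))
  sm
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d partitions\n",
              length(x$taxa), x$columns, nrow(x$partitions)))
  invisible(x)
}

#' Write a supermatrix (FASTA + RAxML-style partition file)
#'
#' @param sm a `supermatrix`.
#' @param fasta_path alignment output path.
#' @param partition_path partition table output path (`DNA, gene = start-end`).
#' @return `fasta_path`, invisibly.
#' @export
write_supermatrix <- function(sm, fasta_path, partition_path) {
  con <- file(fasta_path, "wb")
  for (t in sm$taxa) {
    s <- sm$matrix[[t]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(c(paste0(">", t),
                 substring(s, starts, pmin(starts + 59L, nchar(s)))), con)
  }
  close(con)
  con <- file(partition_path, "wb")
  writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$gene_id,
                     sm$partitions$start, sm$partitions$end), con)
  close(con)
  invisible(fasta_path)
}

#' Read a supermatrix written by [write_supermatrix]
#'
#' @param fasta_path alignment path.
#' @param partition_path partition table path.
#' @return a `supermatrix`.
#' @export
read_supermatrix <- function(fasta_path, partition_path) {
  rows <- read_alignment_fasta(fasta_path)
  pl <- readLines(partition_path)
  m <- regmatches(pl, regexec("^DNA, *(\\S+) *= *(\\d+)-(\\d+)$", pl))
  parts <- data.frame(
    gene_id = vapply(m, `[[`, character(1L), 2L),
    start = as.integer(vapply(m, `[[`, character(1L), 3L)),
    end = as.integer(vapply(m, `[[`, character(1L), 4L)),
    stringsAsFactors = FALSE)
  structure(list(taxa = names(rows), columns = nchar(rows[[1L]]),
                 partitions = parts, matrix = rows), class = "supermatrix")
}

# --- topology conflict -----------------------------------------------------

# nontrivial bipartitions of an unrooted tree as canonical keys; optionally
# with support (internal node labels)
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {  # children settled before parents
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  ref <- sort(tree$tip.label)[1L]
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= nt) next  # trivial (single tip)
    side <- desc[[child]]
    if (length(side) >= nt - 1L) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    supp <- if (!is.null(tree$node.label)) tree$node.label[child - nt] else NA
    out[[key]] <- supp
  }
  out
}

#' Compare two tree topologies
#'
#' Prunes both trees to their shared leaf set, extracts nontrivial
#' bipartitions (unrooted), and reports shared splits, splits unique to each
#' tree (with support values when the Newick carries node labels), and the
#' Robinson-Foulds distance (count of splits unique to either tree).
#'
#' @param tree_a,tree_b `phylo` objects, Newick strings, or file paths.
#' @param labels length-2 character vector naming the trees in the report.
#' @return a `conflict_report` list: `tree_pair`, `shared_bipartitions`,
#'   `conflicting_bipartitions` (data.frame `split`, `tree`, `support`),
#'   `rf_distance`.
#' @export
compare_topologies <- function(tree_a, tree_b, labels = c("A", "B")) {
  ta <- as_phylo(tree_a); tb <- as_phylo(tree_b)
  shared <- intersect(ta$tip.label, tb$tip.label)
  if (length(shared) < 4L)
    stop("fewer than 4 shared leaves; symmetric difference: ",
         paste(c(setdiff(ta$tip.label, tb$tip.label),
                 setdiff(tb$tip.label, ta$tip.label)), collapse = ", "))
  ta <- ape::keep.tip(ta, shared); tb <- ape::keep.tip(tb, shared)
  ba <- tree_bipartitions(ta); bb <- tree_bipartitions(tb)
  ka <- names(ba); kb <- names(bb)
  only_a <- setdiff(ka, kb); only_b <- setdiff(kb, ka)
  confl <- rbind(
    if (length(only_a)) data.frame(split = only_a, tree = labels[1L],
                                   support = unlist(ba[only_a], use.names = FALSE),
                                   stringsAsFactors = FALSE),
    if (length(only_b)) data.frame(split = only_b, tree = labels[2L],
                                   support = unlist(bb[only_b], use.names = FALSE),
                                   stringsAsFactors = FALSE))
  if (is.null(confl))
    confl <- data.frame(split = character(), tree = character(),
                        support = character(), stringsAsFactors = FALSE)
  structure(list(tree_pair = labels,
                 shared_bipartitions = length(intersect(ka, kb)),
                 conflicting_bipartitions = confl,
                 rf_distance = length(only_a) + length(only_b)),
            class = "conflict_report")
}

as_phylo <- function(x) {
  if (inherits(x, "phylo")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
}

#' @export
print.conflict_report <- function(x, ...) {
  cat(sprintf("<conflict_report> %s vs %s: RF = %d (%d shared, %d conflicting)\n",
              x$tree_pair[1L], x$tree_pair[2L], x$rf_distance,
              x$shared_bipartitions, nrow(x$conflicting_bipartitions)))
  invisible(x)
}

# --- PHI recombination test ------------------------------------------------

# refined incompatibility of two site-state vectors (integer codes, 0 =
# missing): minimum extra steps to make the pair compatible = e - v + c of
# the bipartite state graph (0 for any tree-compatible pair; 1 for the
# binary four-gamete configuration)
refined_incompatibility <- function(a, b) {
  ok <- a > 0L & b > 0L
  if (!any(ok)) return(0L)
  a <- a[ok]; b <- b[ok]
  joint <- unique(a * 8L + b)
  ja <- joint %/% 8L; jb <- joint %% 8L
  ua <- unique(ja); ub <- unique(jb)
  v <- length(ua) + length(ub)
  e <- length(joint)
  # connected components of the bipartite graph (nodes: states, edges: joint)
  comp <- seq_len(v)
  ia <- match(ja, ua); ib <- length(ua) + match(jb, ub)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (i in seq_along(joint)) {
    ra <- find(ia[i]); rb <- find(ib[i])
    if (ra != rb) comp[rb] <- ra
  }
  c_n <- length(unique(vapply(seq_len(v), find, integer(1L))))
  as.integer(e - v + c_n)
}

# parsimony-informative site filter; returns integer-coded states and
# original positions
informative_sites <- function(mat) {
  # mat: taxa x columns integer matrix, 0 missing, 1..4 = ACGT
  informative <- apply(mat, 2L, function(col) {
    tab <- tabulate(col[col > 0L], nbins = 4L)
    sum(tab >= 2L) >= 2L
  })
  which(informative)
}

encode_alignment <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment))
    alignment <- read_alignment_fasta(alignment)
  if (is.matrix(alignment)) {
    chars <- alignment
  } else {
    chars <- do.call(rbind, strsplit(toupper(unlist(alignment)), "", fixed = TRUE))
    rownames(chars) <- names(alignment)
  }
  m <- matrix(match(chars, c("A", "C", "G", "T"), nomatch = 0L),
              nrow = nrow(chars), dimnames = dimnames(chars))
  m
}

#' Pairwise homoplasy index (PHI) test for recombination
#'
#' For every pair of parsimony-informative sites within `window_w` alignment
#' positions of each other, computes the refined incompatibility score (the
#' minimum number of extra mutations needed to fit both sites on one tree;
#' 0 for compatible pairs). The observed statistic is the mean score over
#' nearby pairs. Under recombination, nearby sites share genealogies and are
#' more compatible than distant ones, so small observed values are the
#' signal; significance is assessed against permutations of the
#' informative-site order, both analytically (exact permutation moments of
#' the Mantel-type statistic, normal approximation, lower tail) and by Monte
#' Carlo permutation.
#'
#' @param alignment FASTA path, named character vector, or character matrix.
#' @param window_w window in alignment positions.
#' @param n_perm number of permutations (0 skips the Monte Carlo p).
#' @param seed RNG seed for the permutations.
#' @return a `phi_result` list: `phi_observed`, `p_analytic`,
#'   `p_permutation`, `informative_sites`, `informative_pairs`, `window_w`.
#'   If fewer than 2 informative sites (or no pair within the window), the
#'   result has `uninformative = TRUE` and `NA` statistics.
#' @export
phi_test <- function(alignment, window_w = 100L, n_perm = 1000L, seed = NULL) {
  m <- encode_alignment(alignment)
  if (nrow(m) < 4L) stop("PHI test requires at least 4 taxa")
  pos <- informative_sites(m)
  n <- length(pos)
  uninformative <- function(msg) {
    structure(list(phi_observed = NA_real_, p_analytic = NA_real_,
                   p_permutation = NA_real_, informative_sites = n,
                   informative_pairs = 0L, window_w = window_w,
                   uninformative = TRUE, note = msg), class = "phi_result")
  }
  if (n < 2L) return(uninformative("fewer than 2 parsimony-informative sites"))
  sub <- m[, pos, drop = FALSE]
  # collapse duplicate site patterns for the O(n^2) score matrix
  pat_key <- apply(sub, 2L, paste, collapse = ",")
  upat <- !duplicated(pat_key)
  pidx <- match(pat_key, pat_key[upat])
  usub <- sub[, upat, drop = FALSE]
  nu <- ncol(usub)
  Bu <- matrix(0, nu, nu)
  if (nu > 1L) {
    for (i in seq_len(nu - 1L)) for (j in seq.int(i + 1L, nu)) {
      Bu[i, j] <- Bu[j, i] <- refined_incompatibility(usub[, i], usub[, j])
    }
  }
  B <- Bu[pidx, pidx, drop = FALSE]
  # nearby pairs by original alignment position
  pr <- which(outer(pos, pos, function(x, y) y - x) > 0 &
                outer(pos, pos, function(x, y) abs(y - x)) <= window_w,
              arr.ind = TRUE)
  if (nrow(pr) == 0L) return(uninformative("no informative pair within window"))
  pi_ <- pr[, 1L]; pj <- pr[, 2L]
  phi_obs <- mean(B[cbind(pi_, pj)])

  # exact permutation moments of the Mantel-type statistic
  mom <- mantel_moments(pi_, pj, n, B)
  p_analytic <- if (mom$sd < 1e-12) 1 else
    stats::pnorm((phi_obs - mom$mean) / mom$sd)

  p_perm <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    leq <- 0L
    for (r in seq_len(n_perm)) {
      sg <- sample.int(n)
      t_r <- mean(B[cbind(sg[pi_], sg[pj])])
      if (t_r <= phi_obs + 1e-12) leq <- leq + 1L
    }
    p_perm <- (1L + leq) / (n_perm + 1L)
  }
  structure(list(phi_observed = phi_obs, p_analytic = p_analytic,
                 p_permutation = p_perm, informative_sites = n,
                 informative_pairs = nrow(pr), window_w = window_w,
                 uninformative = FALSE,
                 perm_mean = mom$mean, perm_sd = mom$sd),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  if (isTRUE(x$uninformative)) {
    cat("<phi_result> uninformative:", x$note, "\n")
  } else {
    cat(sprintf(
      "<phi_result> PHI = %.4g over %d pairs (%d informative sites, w = %d)\n  p (analytic) = %.4g; p (permutation) = %s\n",
      x$phi_observed, x$informative_pairs, x$informative_sites, x$window_w,
      x$p_analytic,
      if (is.na(x$p_permutation)) "not run" else format(x$p_permutation)))
  }
  invisible(x)
}

# exact mean/sd of mean(B[sigma(i), sigma(j)]) over uniform permutations
# sigma, for a fixed pair set {(i,j)}; classical Mantel-statistic moments
# via the 2/3/4-distinct-index decomposition
mantel_moments <- function(pi_, pj, n, B) {
  npair <- length(pi_)
  # ordered-pair adjacency sums for A (0/1, symmetric)
  S1A <- 2 * npair
  S2A <- S1A
  degA <- tabulate(c(pi_, pj), nbins = n)
  PA <- sum(degA^2) - S2A
  QA <- S1A^2 - 2 * S2A - 4 * PA
  rB <- rowSums(B)
  S1B <- sum(rB)
  S2B <- sum(B^2)
  PB <- sum(rB^2) - S2B
  QB <- S1B^2 - 2 * S2B - 4 * PB
  n2 <- n * (n - 1); n3 <- n2 * (n - 2); n4 <- n3 * (n - 3)
  EG <- S1A * S1B / n2
  EG2 <- 2 * S2A * S2B / n2 + 4 * PA * PB / n3 + QA * QB / n4
  v <- EG2 - EG^2
  list(mean = EG / S1A, sd = sqrt(max(v, 0)) / S1A)
}
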