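test_that("planted plastid fragments are found; short ones excluded", {
  mp <- data.frame(length = c(80L, 100L, 120L, 49L), identity = 1)
  sim <- sim_genome(seed = 201, genome_length = 40000L, n_genes = 2,
                    mipt_plan = mp)
  hits <- find_mipts(sim$genome, sim$donor)
  s <- summarize_mipts(hits)
  expect_equal(s$n_fragments, 3L)
  expect_equal(s$total_bp, 300L)
  expect_setequal(hits$s_start, sim$truth$mipts$mito_start[sim$truth$mipts$length >= 50])
  expect_true(all(hits$evalue <= 1e-10))
  expect_true(all(hits$identity >= 0.80))
})

test_that("find_mipts is symmetric on synthetic pairs", {
  mp <- data.frame(length = c(90L, 130L), identity = 1)
  sim <- sim_genome(seed = 202, genome_length = 30000L, topology = "linear",
                    n_genes = 0, mipt_plan = mp)
  ab <- find_mipts(sim$genome, sim$donor)
  ba <- find_mipts(sim$donor, sim$genome)
  expect_equal(nrow(ab), nrow(ba))
  # coordinate mirror: subject loci of one direction are query loci of the other
  expect_setequal(paste(ab$s_start, ab$s_end), paste(ba$q_start, ba$q_end))
  expect_setequal(paste(ab$q_start, ab$q_end), paste(ba$s_start, ba$s_end))
})

test_that("degenerate self-search suppresses the trivial self-hit", {
  sim <- sim_genome(seed = 203, genome_length = 10000L, topology = "linear",
                    n_genes = 0)
  hits <- find_mipts(sim$genome, sim$genome)
  expect_equal(nrow(hits), 0L)
})

test_that("planted-fragment recovery across lengths and identities", {
  # detection-machinery recall for plantings >= 50 bp at >= 0.85 identity.
  # Thresholds are relaxed for the recovery scan (min_len 30, E 1e-3):
  # local alignment trims mutated fragment ends below 50 bp, and a 50 bp
  # 85%-identity hit is beyond 1e-10 by Karlin-Altschul arithmetic, so the
  # default filters cannot see every such planting even in principle.
  # Sub-50-bp plantings contribute zero at the default thresholds (below).
  set.seed(42)
  lens <- c(50L, 55L, 60L, 80L, 120L, 200L, 49L, 40L)
  ids <- c(0.86, 0.9, 1, 0.95, 0.88, 0.92, 1, 1)
  mp <- data.frame(length = lens, identity = ids)
  sim <- sim_genome(seed = 204, genome_length = 60000L, n_genes = 0,
                    mipt_plan = mp)
  hits <- find_mipts(sim$genome, sim$donor, min_len = 30, max_evalue = 1e-3)
  planted <- sim$truth$mipts
  long <- planted[planted$length >= 50, ]
  found <- vapply(seq_len(nrow(long)), function(i) {
    any(hits$s_start < long$mito_start[i] + long$length[i] &
          hits$s_end > long$mito_start[i])
  }, logical(1))
  expect_true(all(found))
  # at the default thresholds, the sub-50-bp plantings contribute nothing
  hits_def <- find_mipts(sim$genome, sim$donor)
  short <- planted[planted$length < 50, ]
  over_short <- vapply(seq_len(nrow(short)), function(i) {
    any(hits_def$s_start < short$mito_start[i] + short$length[i] &
          hits_def$s_end > short$mito_start[i])
  }, logical(1))
  expect_false(any(over_short))
})

test_that("find_orfs basic contracts and oracle equivalence", {
  g <- genome_record("t", paste0(strrep("C", 30), "ATGAAATAA", strrep("C", 30)),
                     "linear")
  orfs <- find_orfs(g, min_len = 9)
  plus <- orfs[orfs$strand == "+" & !orfs$partial, ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$protein, "MK")
  expect_equal(plus$length, 9L)

  # boundary: an ORF below min_len is excluded
  expect_equal(nrow(find_orfs(g, min_len = 12)[
    find_orfs(g, min_len = 12)$strand == "+", ]), 0L)

  # oracle equivalence on a random linear genome (complete ORFs)
  sim <- sim_genome(seed = 205, genome_length = 30000L, topology = "linear",
                    n_genes = 3)
  orfs <- find_orfs(sim$genome, min_len = 90)
  orfs <- orfs[!orfs$partial, ]
  got <- sort(paste(orfs$start, orfs$end, orfs$strand, sep = ":"))
  expect_identical(got, oracle_orf_set(sim$genome, 90L))

  # every protein starts with M and has no internal stop
  expect_true(all(substr(orfs$protein, 1, 1) == "M"))
  expect_false(any(grepl("*", orfs$protein, fixed = TRUE)))
  # lengths are multiples of 3 including the stop
  expect_true(all(orfs$length %% 3 == 0))
})

test_that("circular ORFs wrap the origin and are reported once", {
  # plant, across the origin, an in-frame stop wall followed by ATG...TAA;
  # the wall guarantees the planted ATG is the longest-per-stop start
  sim <- sim_genome(seed = 206, genome_length = 5000L, n_genes = 0)
  s <- sim$genome$sequence
  core <- paste0("ATG", strrep("GAC", 40), "TAA")          # 126 bp
  plant <- paste0("TAATAATAA", core)                        # stop wall + ORF
  head_len <- 69L  # wall (9) + first 60 bp of the ORF sit at the genome end
  tail_part <- substr(plant, head_len + 1L, nchar(plant))
  s2 <- paste0(tail_part,
               substr(s, nchar(plant) + 1L, nchar(s) - head_len),
               substr(plant, 1L, head_len))
  g <- genome_record("wrap", s2, "circular")
  orfs <- find_orfs(g, min_len = 120)
  hit <- orfs[orfs$start == g$length - 60L & orfs$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$length, nchar(core))
  expect_true(hit$end > g$length)  # wraps the origin
})

test_that("chimeric ORFs are flagged with gene evidence", {
  sim <- sim_genome(seed = 207, genome_length = 40000L, n_genes = 4)
  g <- sim$genome
  # a position clear of every annotated exon
  exon_iv <- do.call(rbind, lapply(sim$annotations, function(a) {
    t(vapply(a$exons, function(e) c(e$start, e$end), integer(2)))
  }))
  free_pos <- function(len) {
    for (p in seq(1000L, g$length - len - 100L, by = 997L)) {
      if (all(p + len + 50L <= exon_iv[, 1] | p - 50L >= exon_iv[, 2])) return(p)
    }
    stop("no free slot")
  }
  # chimeric ORF: 60 bp of gene01 CDS + novel non-stop filler
  donor_cds <- extract_spliced_cds(g, sim$annotations[["gene01"]])
  frag <- substr(donor_cds, 31, 90)  # in-frame 60 bp fragment
  set.seed(1)
  filler <- paste(sample(setdiff(names(orgkit:::.GENETIC_CODE_1),
                                 c("TAA", "TAG", "TGA")), 40, replace = TRUE),
                  collapse = "")
  orf_seq <- paste0("ATG", frag, filler, "TAA")
  pos <- free_pos(nchar(orf_seq))
  ch <- strsplit(g$sequence, "", fixed = TRUE)[[1]]
  ch[(pos + 1):(pos + nchar(orf_seq))] <- strsplit(orf_seq, "", fixed = TRUE)[[1]]
  g2 <- genome_record(g$id, paste(ch, collapse = ""), "circular")
  orfs <- find_orfs(g2, min_len = 150)
  flagged <- flag_chimeric_orfs(orfs, sim$annotations, g2)
  target <- which(flagged$start <= pos & flagged$end >= pos + nchar(orf_seq) - 1)
  expect_true(length(target) >= 1)
  ev <- flagged$chimera_evidence[[target[1]]]
  expect_true("gene01" %in% ev$gene_id)
  expect_true(all(ev$length >= 30))
  expect_true(all(ev$identity >= 0.90))
})

test_that("sub-30-bp shared fragments never become chimera evidence", {
  # fully synthetic construction with mismatch guards on both sides of a
  # 29 bp shared core, so local alignment cannot stretch it to 30
  set.seed(2)
  bg <- orgkit:::screened_dna(3000L, 0.45)
  gene_seq <- orgkit:::random_dna(300L, 0.45)
  guard <- function(template) {
    vapply(strsplit(template, "")[[1]],
           function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  }
  core <- substr(gene_seq, 100, 128)                       # 29 bp
  pre <- paste(guard(substr(gene_seq, 94, 99)), collapse = "")
  post <- paste(guard(substr(gene_seq, 129, 134)), collapse = "")
  non_stop <- setdiff(names(orgkit:::.GENETIC_CODE_1), c("TAA", "TAG", "TGA"))
  filler <- paste(sample(non_stop, 36, replace = TRUE), collapse = "")
  orf_seq <- paste0("ATG", pre, core, post, filler, "TAA")
  ch <- strsplit(bg, "", fixed = TRUE)[[1]]
  ch[501:(500 + 300)] <- strsplit(gene_seq, "", fixed = TRUE)[[1]]
  ch[1501:(1500 + nchar(orf_seq))] <- strsplit(orf_seq, "", fixed = TRUE)[[1]]
  g <- genome_record("syn", paste(ch, collapse = ""), "linear")
  ann <- list(gene_annotation("geneX", "CDS",
                              list(segment_interval(500, 800, "+"))))
  orfs <- data.frame(start = 1500L, end = 1500L + nchar(orf_seq),
                     strand = "+", length = nchar(orf_seq),
                     protein = "", partial = FALSE, stringsAsFactors = FALSE)
  flagged <- flag_chimeric_orfs(orfs, ann, g)
  expect_equal(nrow(flagged$chimera_evidence[[1]]), 0L)
})
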