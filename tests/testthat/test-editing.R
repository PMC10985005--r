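test_that("pileup table path maps counts and strands to coding sense", {
  # plus-strand gene: T reads over a genomic C
  g <- genome_record("g", paste0("ATGCCCAAATAA", strrep("G", 20)), "linear")
  gene <- gene_annotation("p", "CDS", list(segment_interval(0, 12, "+")))
  tab <- data.frame(gene_id = "p", cds_pos = 3L, ref = "C",
                    A = 0L, C = 0L, G = 0L, T = 10L)
  sites <- pileup_genes(tab, g, list(gene))
  expect_equal(sites$T, 10L)
  expect_equal(sites$ref_base, "C")
  expect_equal(sites$genome_pos, 3L)

  # the same gene on the minus strand of the reverse-complemented genome
  grc <- genome_record("g", revcomp(g$sequence), "linear")
  L <- grc$length
  gene_m <- gene_annotation("p", "CDS",
                            list(segment_interval(L - 12, L, "-")))
  sites_m <- pileup_genes(tab, grc, list(gene_m))
  expect_equal(sites_m$T, 10L)
  expect_equal(sites_m$ref_base, "C")
  expect_equal(sites_m$strand, "-")
})

test_that("BAM pileup honors quality filters and strand transform", {
  sim <- sim_genome(seed = 301, genome_length = 3000L, n_genes = 1)
  g <- sim$genome
  gene <- sim$annotations[[1]]
  map <- orgkit:::cds_genomic_positions(g, gene)
  # 12 reads of 40 bp over the first exon, 2 with low MAPQ (filtered)
  ex1 <- gene$exons[[1]]
  rs <- ex1$start + 1L  # 1-based genomic read start
  rseq <- orgkit:::extract_span(g, ex1$start, 40L)
  sam <- withr::local_tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", g$id, g$length))
  mk <- function(id, mapq) sprintf("%s\t0\t%s\t%d\t%d\t40M\t*\t0\t0\t%s\t%s",
                                   id, g$id, rs, mapq, rseq, strrep("I", 40))
  writeLines(c(hdr, vapply(1:10, function(i) mk(paste0("r", i), 60L), ""),
               mk("low1", 5L), mk("low2", 5L)), sam)
  sites <- pileup_genes(sam, g, list(gene))
  expect_true(nrow(sites) > 0)
  expect_true(all(sites$depth == 10L))  # low-MAPQ reads excluded
  # counts are coding-sense: every covered site is 10x the reference base
  ref <- sites$ref_base
  for (b in c("A", "C", "G", "T")) {
    expect_true(all(sites[[b]][ref == b] == 10L))
    expect_true(all(sites[[b]][ref != b] == 0L))
  }
  # mismatching reference name errors with names listed
  g_other <- genome_record("other_id", g$sequence, g$topology)
  expect_error(pileup_genes(sam, g_other, list(gene)), "other_id")
})

test_that("call_c_to_u thresholds", {
  base <- data.frame(gene_id = "g", cds_pos = 0:3,
                     genome_pos = 0:3, strand = "+",
                     ref_base = c("C", "C", "C", "A"),
                     depth = c(50L, 50L, 5L, 50L),
                     A = c(0L, 0L, 0L, 10L), C = c(10L, 46L, 1L, 0L),
                     G = 0L, T = c(40L, 4L, 4L, 40L), N = 0L)
  called <- call_c_to_u(base)
  # site 1: frac 0.8 called; site 2: frac 0.08 below threshold;
  # site 3: depth 5 below min_depth; site 4: ref A never called
  expect_equal(called$cds_pos, 0L)
  expect_equal(called$edit_fraction, 0.8)
})

test_that("consequence classification matches canonical codon cases", {
  # CAA -> TAA stop gain at codon position 1
  g <- genome_record("g", paste0("ATG", "CAA", "ACG", "TAC", "CTT", "TAA"),
                     "linear")
  gene <- gene_annotation("x", "CDS", list(segment_interval(0, 18, "+")))
  cl <- classify_consequence(g, gene, 3L)
  expect_equal(cl$consequence, "stop_gain")
  expect_equal(cl$codon_change$codon_after, "TAA")
  # TAC -> TAT silent at codon position 3
  expect_equal(classify_consequence(g, gene, 11L)$consequence, "silent")
  # CTT -> TTT missense L -> F
  cl2 <- classify_consequence(g, gene, 12L)
  expect_equal(cl2$consequence, "missense")
  expect_equal(cl2$codon_change$aa_before, "L")
  expect_equal(cl2$codon_change$aa_after, "F")

  # ACG start codon edited to ATG: start gain
  g2 <- genome_record("g", paste0("ACG", "AAA", "TAA"), "linear")
  gene2 <- gene_annotation("y", "CDS", list(segment_interval(0, 9, "+")))
  cl3 <- classify_consequence(g2, gene2, 1L)
  expect_equal(cl3$consequence, "start_gain")
  # GCG start codon edited to GTG: start_codon_edit
  g3 <- genome_record("g", paste0("GCG", "AAA", "TAA"), "linear")
  cl4 <- classify_consequence(g3, gene2, 1L)
  expect_equal(cl4$consequence, "start_codon_edit")
  expect_equal(cl4$codon_change$codon_after, "GTG")

  # outside the CDS errors
  expect_error(classify_consequence(g2, gene2, 9L), "outside")
})

test_that("summarize_editing counting rules", {
  sim <- sim_genome(seed = 302, genome_length = 20000L, n_genes = 2)
  g <- sim$genome
  gene <- sim$annotations[[1]]
  cds <- extract_spliced_cds(g, gene)
  cpos <- which(strsplit(cds, "")[[1]] == "C") - 1L
  # pick two edits in one codon and one in another
  by_codon <- split(cpos, cpos %/% 3)
  two <- by_codon[lengths(by_codon) >= 2][[1]][1:2]
  other <- setdiff(cpos, two)
  one <- other[other %/% 3 != two[1] %/% 3][1]
  called <- data.frame(gene_id = gene$gene_id, cds_pos = c(two, one),
                       depth = 50L, edit_fraction = 0.9,
                       stringsAsFactors = FALSE)
  cl <- classify_sites(g, sim$annotations, called)
  su <- summarize_editing(cl, g, sim$annotations)
  pg <- su$per_gene[su$per_gene$gene_id == gene$gene_id, ]
  expect_equal(pg$n_sites, 3L)
  expect_equal(pg$n_codon_changes, 2L)
  expect_equal(pg$density, 3 / nchar(cds))
  expect_equal(su$n_sites, 3L)
  expect_equal(su$n_silent + su$n_nonsilent, 3L)
  expect_equal(sum(su$aa_conversion_matrix), su$n_nonsilent)
  expect_equal(sum(su$codon_position_counts), 3L)

  # empty site list gives a zero summary
  su0 <- summarize_editing(cl[0, ], g, sim$annotations)
  expect_equal(su0$n_sites, 0L)
  expect_true(all(su0$aa_conversion_matrix == 0))
})

test_that("strand symmetry: minus-strand gene equals plus-strand mirror", {
  sim <- sim_genome(seed = 303, genome_length = 10000L, n_genes = 1)
  g <- sim$genome
  gene <- sim$annotations[[1]]
  ep <- sim_editing_pileup(g, sim$annotations, seed = 5, n_sites = 20,
                           depth = 80, error_rate = 0)
  # mirror genome: reverse complement, flip all exon coordinates/strands
  L <- g$length
  grc <- genome_record(g$id, revcomp(g$sequence), g$topology)
  flip <- function(seg) segment_interval(
    L - seg$end, L - seg$start, if (seg$strand == "+") "-" else "+")
  gene_rc <- gene_annotation(gene$gene_id, gene$biotype,
                             lapply(gene$exons, flip), gene$codon_start)
  s1 <- call_c_to_u(pileup_genes(ep$pileup, g, list(gene)))
  s2 <- call_c_to_u(pileup_genes(ep$pileup, grc, list(gene_rc)))
  expect_equal(s1$cds_pos, s2$cds_pos)
  expect_equal(s1$edit_fraction, s2$edit_fraction)
  cl1 <- classify_sites(g, list(gene), s1)
  cl2 <- classify_sites(grc, list(gene_rc), s2)
  expect_equal(cl1$consequence, cl2$consequence)
})

test_that("compare_with_predictions set algebra and duplicate handling", {
  called <- data.frame(gene_id = c("a", "a"), cds_pos = c(1L, 5L))
  predicted <- data.frame(gene_id = c("a", "b"), cds_pos = c(5L, 2L))
  cmp <- compare_with_predictions(called, predicted)
  expect_equal(site_key(cmp$confirmed), "a:5")
  expect_equal(site_key(cmp$called_only), "a:1")
  expect_equal(site_key(cmp$predicted_only), "b:2")

  cmp2 <- compare_with_predictions(called, called)
  expect_equal(nrow(cmp2$called_only), 0L)
  expect_equal(nrow(cmp2$predicted_only), 0L)

  expect_warning(compare_with_predictions(called, rbind(predicted, predicted)),
                 "duplicate")

  # generator truth vs deliberately corrupted prediction list
  sim <- sim_genome(seed = 304, genome_length = 15000L, n_genes = 2)
  ep <- sim_editing_pileup(sim$genome, sim$annotations, seed = 6, n_sites = 50)
  truth <- ep$truth[, c("gene_id", "cds_pos")]
  corrupted <- truth
  corrupted$cds_pos[1:5] <- corrupted$cds_pos[1:5] + 100000L  # 5 wrong
  extra <- data.frame(gene_id = "ghost", cds_pos = 1:3)
  cmp3 <- compare_with_predictions(truth, rbind(corrupted, extra))
  expect_equal(nrow(cmp3$confirmed), 45L)
  expect_equal(nrow(cmp3$called_only), 5L)
  expect_equal(nrow(cmp3$predicted_only), 8L)
})

test_that("planted edit fractions are recovered within binomial CI", {
  sim <- sim_genome(seed = 305, genome_length = 15000L, n_genes = 2)
  ep <- sim_editing_pileup(sim$genome, sim$annotations, seed = 7,
                           n_sites = 60, fraction = 0.6, depth = 100,
                           error_rate = 0)
  called <- call_c_to_u(pileup_genes(ep$pileup, sim$genome, sim$annotations))
  hit <- called[site_key(called) %in% site_key(ep$truth), ]
  ci <- stats::qbinom(c(0.0005, 0.9995), 100, 0.6) / 100  # per-site 99.9% CI
  inside <- mean(hit$edit_fraction >= ci[1] & hit$edit_fraction <= ci[2])
  expect_gte(inside, 0.95)
})
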