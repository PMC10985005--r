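test_that("load_genome folds case, validates characters, round-trips", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt"), fa)
  g <- load_genome(fa, "linear")[[1]]
  expect_equal(g$sequence, "ACGT")
  expect_equal(g$length, 4L)
  expect_equal(g$topology, "linear")

  writeLines(c(">x", "ACG1T"), fa)
  expect_error(load_genome(fa, "linear"), "offset 4")

  writeLines(character(0), fa)
  expect_error(load_genome(fa, "linear"))

  # write -> load round trip is bit-identical
  sim <- sim_genome(seed = 3, genome_length = 1000L, n_genes = 0)
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(sim$genome, p1)
  g2 <- load_genome(p1, "circular")[[1]]
  expect_identical(g2$sequence, sim$genome$sequence)
  write_genome_fasta(g2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("extract_spliced_cds handles strands, wrap, trans-splicing", {
  g <- genome_record("t", "ATGAAATTTCCC", "circular")
  plus <- gene_annotation("a", "CDS", list(segment_interval(0, 6, "+")))
  expect_equal(extract_spliced_cds(g, plus), "ATGAAA")
  minus <- gene_annotation("b", "ORF", list(segment_interval(0, 3, "-")))
  expect_equal(extract_spliced_cds(g, minus), "CAT")

  # origin wrap: [9,12) + [0,3) as one exon list
  wrap <- gene_annotation("c", "CDS", list(
    segment_interval(9, 3, "+", wraps_origin = TRUE)))
  expect_equal(extract_spliced_cds(g, wrap), "CCCATG")

  lin <- genome_record("t2", "ATGAAATTTCCC", "linear")
  expect_error(extract_spliced_cds(lin, wrap), "linear")
  out <- gene_annotation("d", "CDS", list(segment_interval(6, 30, "+")))
  expect_error(extract_spliced_cds(g, out), "outside")

  # generator-planted genes (incl. trans-spliced) equal the planted mRNA
  sim <- sim_genome(seed = 9, genome_length = 30000L, n_genes = 5,
                    n_trans_introns = 2)
  for (gid in names(sim$annotations)) {
    expect_identical(extract_spliced_cds(sim$genome, sim$annotations[[gid]]),
                     sim$truth$genes[[gid]], label = gid)
  }
})

test_that("translate_cds follows the standard code and editing-relevant codons", {
  expect_equal(translate_cds("ATGTTTTAA"), "MF*")
  expect_equal(translate_cds("CAA"), "Q")
  expect_equal(translate_cds("TAA"), "*")
  expect_equal(translate_cds("CGA"), "R")
  expect_equal(translate_cds("TGA"), "*")
  expect_equal(translate_cds("ATGNNNAAA"), "MXK")
  expect_warning(out <- translate_cds("ATGTT"), "incomplete")
  expect_equal(out, "M")
  expect_error(translate_cds("AT"))
  # does not stop at internal stops
  expect_equal(translate_cds("ATGTAAATG"), "M*M")

  # all 64 codons against an independent table-lookup oracle
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  for (cd in codons) {
    expect_equal(translate_cds(cd),
                 as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                                    no.init.codon = TRUE)),
                 label = cd)
  }
})

test_that("gc_content and composition_summary", {
  expect_equal(gc_content(genome_record("x", "ATGC", "linear")), 0.5)
  expect_equal(gc_content(genome_record("x", "AAAA", "linear")), 0)
  # N excluded from denominator
  expect_equal(gc_content(genome_record("x", "GGNN", "linear")), 1)
  expect_error(gc_content(genome_record("x", "NNN", "linear")), "all N")
  # invariant under reverse complement
  sim <- sim_genome(seed = 12, genome_length = 2000L, n_genes = 0)
  rc <- genome_record("rc", revcomp(sim$genome$sequence), "circular")
  expect_equal(gc_content(sim$genome), gc_content(rc))

  g <- genome_record("g", strrep("A", 1000), "circular")
  ann <- list(gene_annotation("c1", "CDS", list(segment_interval(100, 200, "+"))))
  cs <- composition_summary(g, ann)
  expect_equal(unname(cs["protein_coding"]), 0.10)
  expect_equal(unname(cs["noncoding"]), 0.90)
  expect_equal(unname(composition_summary(g, list())["noncoding"]), 1.0)
  # CDS takes priority over overlapping tRNA
  ann2 <- c(ann, list(gene_annotation("t1", "tRNA",
                                      list(segment_interval(150, 250, "+")))))
  cs2 <- composition_summary(g, ann2)
  expect_equal(unname(cs2["protein_coding"]), 0.10)
  expect_equal(unname(cs2["tRNA"]), 0.05)
  expect_equal(sum(cs2), 1.0)

  # generator bookkeeping matches exactly
  sim2 <- sim_genome(seed = 8, genome_length = 40000L, n_genes = 4,
                     n_trna = 2, n_rrna = 1)
  cs3 <- composition_summary(sim2$genome, sim2$annotations)
  bp <- sim2$truth$biotype_bp
  L <- sim2$genome$length
  expect_equal(unname(cs3["protein_coding"]), unname(bp["CDS"]) / L)
  expect_equal(unname(cs3["tRNA"]), unname(bp["tRNA"]) / L)
  expect_equal(unname(cs3["rRNA"]), unname(bp["rRNA"]) / L)
})

test_that("revcomp is an involution on random sequences", {
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 50, replace = TRUE),
               collapse = "")
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("GFF3 writer/reader round-trips gene models", {
  sim <- sim_genome(seed = 14, genome_length = 20000L, n_genes = 4,
                    n_trans_introns = 1, n_trna = 1)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$annotations, sim$genome, gff)
  back <- read_gff3(gff, sim$genome)
  expect_setequal(names(back), names(sim$annotations))
  for (gid in names(back)) {
    a <- sim$annotations[[gid]]; b <- back[[gid]]
    expect_equal(b$biotype, a$biotype, label = gid)
    expect_equal(length(b$exons), length(a$exons), label = gid)
    for (j in seq_along(a$exons)) {
      expect_equal(b$exons[[j]]$start, a$exons[[j]]$start)
      expect_equal(b$exons[[j]]$end, a$exons[[j]]$end)
      expect_equal(b$exons[[j]]$strand, a$exons[[j]]$strand)
    }
    # spliced CDS identical through the round trip
    if (a$biotype == "CDS")
      expect_identical(extract_spliced_cds(sim$genome, b),
                       extract_spliced_cds(sim$genome, a))
  }
})
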