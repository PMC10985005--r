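test_that("concatenation lays out partitions and pads missing taxa", {
  a1 <- c(t1 = "ACGT", t2 = "ACGA", t3 = "ACCT")
  a2 <- c(t1 = "GGGGGG", t2 = "GGGGGT")
  sm <- concatenate_alignments(list(g1 = a1, g2 = a2))
  expect_equal(sm$columns, 10L)
  expect_equal(sm$partitions$start, c(1L, 5L))
  expect_equal(sm$partitions$end, c(4L, 10L))
  expect_equal(unname(sm$matrix["t3"]), "ACCT??????")

  # ragged input errors naming the gene
  bad <- list(g1 = c(t1 = "ACGT", t2 = "ACG"))
  expect_error(concatenate_alignments(bad), "ragged")

  # taxon_map reconciliation
  sm2 <- concatenate_alignments(list(g1 = c(x1 = "AC"), g2 = c(t1 = "GG")),
                                taxon_map = c(x1 = "t1"))
  expect_equal(sm2$taxa, "t1")
  expect_equal(unname(sm2$matrix["t1"]), "ACGG")
})

test_that("supermatrix round-trips through FASTA + partition files", {
  set.seed(601)
  genes <- lapply(1:8, function(i) {
    w <- sample(10:60, 1)
    stats::setNames(
      vapply(1:5, function(j) paste(sample(c("A", "C", "G", "T", "-"), w,
                                           replace = TRUE), collapse = ""),
             ""),
      paste0("t", 1:5))
  })
  names(genes) <- paste0("g", 1:8)
  sm <- concatenate_alignments(genes)
  expect_equal(sm$columns, sum(sm$partitions$end - sm$partitions$start + 1L))
  fa <- withr::local_tempfile(fileext = ".fa")
  pt <- withr::local_tempfile(fileext = ".txt")
  write_supermatrix(sm, fa, pt)
  back <- read_supermatrix(fa, pt)
  expect_equal(back$matrix, sm$matrix)
  expect_equal(back$partitions, sm$partitions)
})

test_that("compare_topologies: identical, conflicting, and pruned trees", {
  t5 <- "((a,b),(c,d),e);"
  same <- compare_topologies(t5, t5)
  expect_equal(same$rf_distance, 0L)
  expect_equal(nrow(same$conflicting_bipartitions), 0L)

  # fully conflicting quartets on 5 taxa: every tree has 2 nontrivial
  # splits, none shared
  cr <- compare_topologies("((a,b),(c,d),e);", "((a,c),(b,d),e);")
  expect_equal(cr$rf_distance, 4L)
  expect_equal(cr$shared_bipartitions, 0L)

  # leaf mismatch below 4 shared tips errors with the symmetric difference
  expect_error(compare_topologies("((a,b),(c,x),y);", "((a,b),(c,q),p);"),
               "symmetric difference")
})

test_that("RF distance equals brute-force bipartition diff on random trees", {
  set.seed(602)
  for (i in 1:20) {
    t1 <- ape::rtree(8); t2 <- ape::rtree(8)
    t2$tip.label <- sample(t1$tip.label)
    cr <- compare_topologies(t1, t2)
    expect_equal(cr$rf_distance, oracle_rf(t1, t2))
    expect_equal(cr$rf_distance, compare_topologies(t2, t1)$rf_distance)
    if (requireNamespace("phangorn", quietly = TRUE))
      expect_equal(cr$rf_distance, phangorn::RF.dist(ape::unroot(t1),
                                                     ape::unroot(t2)))
  }
  # leaf-swap case: distance from itself with two tips exchanged
  t <- ape::rtree(8)
  swp <- t
  i <- which(swp$tip.label == "t1"); j <- which(swp$tip.label == "t2")
  swp$tip.label[c(i, j)] <- swp$tip.label[c(j, i)]
  expect_equal(compare_topologies(t, swp)$rf_distance, oracle_rf(t, swp))
  # metric properties: zero iff same splits; triangle inequality spot-check
  t3 <- ape::rtree(8)
  d <- function(x, y) compare_topologies(x, y)$rf_distance
  expect_lte(d(t, t3), d(t, swp) + d(swp, t3))
})

test_that("refined incompatibility scores the four-gamete configuration", {
  # 4 taxa, 2 binary sites showing all four gametes
  aln <- c(s1 = "AA", s2 = "AC", s3 = "CA", s4 = "CC")
  m <- orgkit:::encode_alignment(aln)
  expect_equal(orgkit:::refined_incompatibility(m[, 1], m[, 2]), 1L)
  # compatible pair: three gametes only
  aln2 <- c(s1 = "AA", s2 = "AC", s3 = "CA", s4 = "AA")
  m2 <- orgkit:::encode_alignment(aln2)
  expect_equal(orgkit:::refined_incompatibility(m2[, 1], m2[, 2]), 0L)
  # missing data is excluded from pair scoring
  aln3 <- c(s1 = "AA", s2 = "AC", s3 = "CA", s4 = "C-")
  m3 <- orgkit:::encode_alignment(aln3)
  expect_equal(orgkit:::refined_incompatibility(m3[, 1], m3[, 2]), 0L)
})

test_that("phi_test degenerate and uninformative inputs", {
  # every informative site pair mutually compatible: phi 0, p ~ 1
  aln <- c(a = "AAAACCCC", b = "AAAACCCC", c = "CCCCAAAA", d = "CCCCAAAA")
  r <- phi_test(aln, n_perm = 50, seed = 1)
  expect_equal(r$phi_observed, 0)
  expect_gte(r$p_permutation, 0.99)
  expect_gte(r$p_analytic, 0.5)

  # fewer than 2 informative sites: explicit uninformative result
  r0 <- phi_test(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  expect_true(r0$uninformative)
  expect_true(is.na(r0$phi_observed))
  expect_error(phi_test(c(a = "ACGT", b = "ACGT", c = "ACGT")), "4 taxa")
})

test_that("phi_test is invariant to taxon order; permutation p reproducible", {
  al <- sim_alignment(seed = 603, n_taxa = 8, block_lens = c(300, 300))
  r1 <- phi_test(al$alignment, n_perm = 99, seed = 7)
  r2 <- phi_test(al$alignment[sample(length(al$alignment))], n_perm = 99,
                 seed = 7)
  expect_equal(r1$phi_observed, r2$phi_observed)
  expect_equal(r1$p_analytic, r2$p_analytic)
  expect_identical(r1$p_permutation,
                   phi_test(al$alignment, n_perm = 99, seed = 7)$p_permutation)
})

test_that("analytic permutation moments match Monte Carlo", {
  set.seed(604)
  n <- 25L
  B <- matrix(0, n, n)
  B[upper.tri(B)] <- rpois(n * (n - 1) / 2, 0.7)
  B <- B + t(B)
  pos <- sort(sample(200, n))
  pr <- which(outer(pos, pos, function(x, y) y - x) > 0 &
                abs(outer(pos, pos, `-`)) <= 40, arr.ind = TRUE)
  mom <- orgkit:::mantel_moments(pr[, 1], pr[, 2], n, B)
  sims <- replicate(4000, {
    sg <- sample.int(n)
    mean(B[cbind(sg[pr[, 1]], sg[pr[, 2]])])
  })
  expect_equal(mom$mean, mean(sims), tolerance = 0.02)
  expect_equal(mom$sd, sd(sims), tolerance = 0.05)
})
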