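test_that("jaccard index matches direct counting", {
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_message(z <- jaccard(character(0), character(0)), "empty")
  expect_equal(z, 0)
})

test_that("jaccard is symmetric, bounded, and 1 iff equal nonempty sets", {
  set.seed(4)
  pool <- sprintf("G%02d", 1:30)
  for (i in 1:50) {
    a <- sample(pool, sample(1:20, 1)); b <- sample(pool, sample(1:20, 1))
    j <- jaccard(a, b)
    expect_equal(j, jaccard(b, a))
    expect_gte(j, 0); expect_lte(j, 1)
    expect_equal(j == 1, setequal(a, b))
  }
})

test_that("similarity matrix is symmetric with unit diagonal", {
  sets <- list(disease_gene_set("A", c("X", "Y", "Z")),
               disease_gene_set("B", c("Y", "Z", "W")),
               disease_gene_set("C", c("P", "Q")))
  m <- similarity_matrix(sets)
  expect_equal(diag(m), setNames(rep(1, 3), c("A", "B", "C")))
  expect_equal(m, t(m))
  expect_equal(m["A", "B"], 0.5)
  expect_equal(m["A", "C"], 0)
})

test_that("identical gene sets land in the same cluster", {
  sets <- list(disease_gene_set("A", c("X", "Y")),
               disease_gene_set("B", c("X", "Y")))
  cl <- cluster_diseases(similarity_matrix(sets), 1)
  expect_equal(cl[["A"]], cl[["B"]])
  expect_error(cluster_diseases(similarity_matrix(sets), 0), "at least 1")
  expect_error(cluster_diseases(similarity_matrix(sets), 5), "exceeds")
})

make_block_panel <- function(seed = 5, n_blocks = 4, per_block = 4) {
  # planted blocks: high within-block overlap, low between-block
  set.seed(seed)
  pool <- sprintf("G%04d", 1:4000)
  cores <- split(sample(pool, n_blocks * 150),
                 rep(1:n_blocks, each = 150))
  sets <- list(); truth <- integer(0)
  for (b in seq_len(n_blocks)) for (i in seq_len(per_block)) {
    id <- sprintf("B%d_%d", b, i)
    genes <- c(sample(cores[[b]], 100), sample(pool, 30))
    sets[[id]] <- disease_gene_set(id, genes)
    truth[id] <- b
  }
  list(sets = sets, truth = truth)
}

test_that("planted 4-block similarity structure is recovered exactly", {
  skip_if_not_installed("mclust")
  panel <- make_block_panel(seed = 5)
  sim <- similarity_matrix(panel$sets)
  cl <- cluster_diseases(sim, 4)
  ari <- mclust::adjustedRandIndex(cl[names(panel$truth)], panel$truth)
  expect_equal(ari, 1.0)
})

test_that("clustering is invariant to input order", {
  panel <- make_block_panel(seed = 6)
  sim <- similarity_matrix(panel$sets)
  cl1 <- cluster_diseases(sim, 4)
  perm <- sample(seq_len(nrow(sim)))
  cl2 <- cluster_diseases(sim[perm, perm], 4)
  ids <- names(cl1)
  # same partition (cluster ids may be relabelled)
  expect_equal(outer(cl1[ids], cl1[ids], "=="),
               outer(cl2[ids], cl2[ids], "=="))
})

test_that("consensus signature averages signs with support counts", {
  ann <- pn_annotation(c("U1", "U2", "A1"), c("UPS", "UPS", "ALP"))
  one <- disease_gene_set("D1", c("U1", "X"), sign_of = c(U1 = 1))
  sv <- consensus_signature(list(one), ann, "UPS")
  expect_equal(sv$value, 1)
  expect_equal(sv$support, 1L)

  d2 <- disease_gene_set("D2", "U1", sign_of = c(U1 = 1))
  d3 <- disease_gene_set("D3", "U1", sign_of = c(U1 = -1))
  sv3 <- consensus_signature(list(one, d2, d3), ann, "UPS")
  expect_equal(sv3$value, 1 / 3)
  expect_equal(sv3$support, 3L)

  expect_error(consensus_signature(list(disease_gene_set("D", "U1")),
                                   ann, "UPS"), "signed")
  expect_error(consensus_signature(list(one), ann, "NOPE"), "unknown pathway")
})

test_that("clusters planted with opposite signs anti-correlate", {
  spec <- synthetic_spec(seed = 9)
  u <- make_universe(spec)
  base <- make_base_signature(spec, u$universe, "cancer")
  anti <- -base
  mk <- function(ids, b) lapply(ids, function(id)
    make_disease_set(spec, id, "II", u$universe, u$annotation,
                     base_signature = b))
  cancer <- mk(c("C1", "C2", "C3"), base)
  neuro <- mk(c("N1", "N2", "N3"), anti)
  sc <- consensus_signature(cancer, u$annotation, "UPS")
  sn <- consensus_signature(neuro, u$annotation, "UPS")
  shared <- intersect(sc$gene, sn$gene)
  expect_gt(length(shared), 20)
  r <- cor(sc$value[match(shared, sc$gene)],
           sn$value[match(shared, sn$gene)])
  expect_lt(r, -0.5)
})

test_that("directional similarity counts agreeing overlap signs", {
  a <- c(G1 = 1, G2 = 1, G3 = -1)
  b <- c(G2 = 1, G3 = 1, G4 = -1)
  res <- directional_similarity(a, b)
  expect_equal(res$ds, 0.5)
  expect_equal(res$overlap, 2L)
  expect_equal(directional_similarity(a, a)$ds, 1)
  expect_equal(directional_similarity(a, -a)$ds, 0)
  expect_true(is.na(directional_similarity(a, c(G9 = 1))$ds))
  expect_error(directional_similarity(c(G1 = 0), b), "uncalled")
})

test_that("directional similarity of independent random signs is near 0.5", {
  set.seed(31)
  genes <- sprintf("G%04d", 1:1000)
  # average over replicates so the check sits several SDs from the bound
  ds <- replicate(5, {
    a <- setNames(sample(c(-1, 1), 1000, TRUE), genes)
    b <- setNames(sample(c(-1, 1), 1000, TRUE), genes)
    res <- directional_similarity(a, b)
    expect_equal(res$overlap, 1000L)
    res$ds
  })
  expect_lt(abs(mean(ds) - 0.5), 0.03)
})
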