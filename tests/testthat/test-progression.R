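net_from_edges <- function(...) {
  e <- do.call(rbind, list(...))
  interaction_network(edges = e)
}

test_that("centrality closed forms hold on path, star and cycle", {
  path <- net_from_edges(c("A", "B"), c("B", "C"))
  cen <- centrality(path)
  expect_equal(cen$betweenness[cen$node == "B"], 1)
  expect_equal(cen$betweenness[cen$node %in% c("A", "C")], c(0, 0))

  star <- net_from_edges(c("HUB", "L1"), c("HUB", "L2"), c("HUB", "L3"))
  cen2 <- centrality(star)
  expect_equal(cen2$degree[cen2$node == "HUB"], 3L)
  expect_equal(cen2$betweenness[cen2$node == "HUB"], 3)

  cyc <- net_from_edges(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A"))
  cen3 <- centrality(cyc)
  expect_equal(cen3$betweenness, rep(0.5, 4))
})

test_that("centrality matches exhaustive path enumeration on random graphs", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(3:7, 1)
    nodes <- LETTERS[1:n]
    adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
    for (a in 1:(n - 1)) for (b in (a + 1):n)
      if (runif(1) < 0.4) adj[a, b] <- adj[b, a] <- 1
    pairs <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    net <- interaction_network(
      nodes = nodes,
      edges = if (nrow(pairs)) cbind(nodes[pairs[, 1]], nodes[pairs[, 2]]))
    cen <- centrality(net)
    expect_equal(setNames(cen$degree, cen$node),
                 setNames(as.integer(rowSums(adj)), nodes))
    oracle <- betweenness_oracle(adj)
    expect_equal(setNames(cen$betweenness, cen$node), oracle,
                 tolerance = 1e-9)
    # conservation: total betweenness equals total internal-vertex credit
    expect_equal(sum(cen$betweenness), sum(oracle), tolerance = 1e-9)
  }
})

staged_result <- function(seed, schedule, affected_frac = 1) {
  spec <- synthetic_spec(seed = seed, n_genes = 4000, pn_size = 500,
                         pathway_sizes = c(ALP = 160, UPS = 140,
                                           EXTRACELLULAR = 100,
                                           PROTEOSTASIS_REGULATION = 100),
                         group_sizes = c(KINASE = 120, TF = 240,
                                         ION_CHANNEL = 60), k = 100)
  u <- make_universe(spec)
  aff <- u$annotation$pathway_genes$ALP
  aff <- aff[seq_len(round(affected_frac * length(aff)))]
  st <- make_staged_expression(spec, aff, u$universe, schedule)
  list(res = stagewise_de(st, paste0("STAGE_", 1:3), "CONTROL"),
       affected = aff, ann = u$annotation)
}

test_that("onset is the earliest significant stage", {
  # constructed study: one gene shifts only at the last stage
  set.seed(2)
  G <- 200
  m <- matrix(rnorm(G * 16, mean = 8, sd = 0.3), nrow = G)
  dimnames(m) <- list(sprintf("G%03d", 1:G), sprintf("S%02d", 1:16))
  cond <- rep(c("CONTROL", "ST1", "ST2", "ST3"), each = 4)
  m[1, cond == "ST3"] <- m[1, cond == "ST3"] + 3
  st <- expression_study(m, setNames(cond, colnames(m)))
  res <- stagewise_de(st, c("ST1", "ST2", "ST3"), "CONTROL")
  expect_identical(unname(res$onset["G001"]), "ST3")
  expect_true(all(is.na(res$onset[paste0("G", sprintf("%03d", 100:150))])))
  expect_error(stagewise_de(st, c("ST1", "ST9"), "CONTROL"), "ST9")
})

test_that("early schedule concentrates onsets in stage 1", {
  out <- staged_result(13, "early")
  props <- stage_proportions(out$res, out$affected)
  expect_equal(sum(props), 1)
  expect_gte(props[["STAGE_1"]], 0.6)
})

test_that("progressive schedule shifts onsets to later stages", {
  out <- staged_result(17, "progressive")
  props <- stage_proportions(out$res, out$affected)
  expect_equal(sum(props), 1)
  expect_gt(props[["STAGE_3"]], props[["STAGE_1"]])
})

test_that("stage proportions partition affected genes and handle degeneracy", {
  res <- structure(list(
    stages = c("S1", "S2", "S3"),
    tables = NULL,
    onset = c(A = "S1", B = "S1", C = "S2", D = "S3", E = NA),
    alpha = 0.05), class = "stage_result")
  p <- stage_proportions(res, c("A", "B", "C", "D", "E"))
  expect_equal(unname(p), c(2, 1, 1) / 4)
  expect_equal(sum(p), 1)
  p1 <- stage_proportions(res, c("A", "B"))
  expect_equal(unname(p1), c(1, 0, 0))
  expect_warning(p0 <- stage_proportions(res, "E"), "missing")
  expect_true(all(is.na(p0)))
  expect_error(stage_proportions(res, character(0)), "empty")
})

test_that("stage centrality summary gives quartiles and rank-sum tests", {
  net <- net_from_edges(c("A", "B"), c("B", "C"), c("C", "D"))
  net$stage_of <- c(A = "early", B = "mid", C = "mid", D = "late")
  s <- stage_centrality_summary(net, stages = c("early", "mid", "late"))
  one <- s$summary[s$summary$stage == "early" & s$summary$metric == "degree", ]
  expect_equal(one$median, 1)   # single node per stage: median is its value
  expect_equal(one$n, 1)
  # identical stage groups: exchangeable, rank-sum p of 1
  net2 <- net_from_edges(c("A", "B"), c("C", "D"))
  net2$stage_of <- c(A = "x", B = "y", C = "x", D = "y")
  s2 <- stage_centrality_summary(net2, stages = c("x", "y"))
  expect_true(all(s2$tests$p > 0.9))
  expect_warning(stage_centrality_summary(net2, stages = c("x", "y", "zz")),
                 "omitted")
  expect_error(stage_centrality_summary(net_from_edges(c("A", "B"))),
               "no stage labels")
})

test_that("planted hub stage is most central in the generated network", {
  spec <- synthetic_spec(seed = 19)
  stages <- setNames(rep(c("early", "mid", "late"), each = 40),
                     sprintf("N%03d", 1:120))
  net <- make_hub_network(spec, stages, m_base = 2, m_hub = 8)
  s <- stage_centrality_summary(net, stages = c("early", "mid", "late"))
  deg <- s$summary[s$summary$metric == "degree", ]
  med <- setNames(deg$median, deg$stage)
  expect_gt(med[["mid"]], med[["early"]])
  expect_gt(med[["mid"]], med[["late"]])
})
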