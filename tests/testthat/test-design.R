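# Candidate generation, ranking, selection rules, blacklist filtering, and
# end-to-end oracle equivalence of the selection on tiny families.

toyGenes <- function(cds, family = "FAM1", class = "CP") {
  geneSet(Biostrings::DNAStringSet(cds),
          data.frame(gene_id = names(cds), family_id = family,
                     class_label = class, stringsAsFactors = FALSE))
}

fakeCand <- function(mature, score, n_targets = 2L, node = 1L,
                     phase = "node_phase") {
  data.frame(mature = mature, origin_node = as.integer(node), phase = phase,
             n_targets = as.integer(n_targets), score = score,
             off_target_count = 0L,
             targets = I(list(setNames(rep(1, n_targets),
                                       paste0("g", seq_len(n_targets))))),
             stringsAsFactors = FALSE)
}

test_that("identical paralogs yield candidates with both genes at fraction 1", {
  set.seed(51)
  cds <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  gs <- toyGenes(c(gA = cds, gB = cds))
  tr <- familyTree(ape::read.tree(text = "(gA,gB);"))
  cands <- suppressWarnings(generateCandidates(tr, gs, 1L))
  expect_gt(nrow(cands), 0)
  expect_true(all(cands$n_targets == 2L))
  # windows whose mature needed no 5' edit keep fraction 1 on both genes
  fr <- unlist(cands$targets)
  expect_true(any(fr == 1))
  expect_true(all(fr >= 0.75))
})

test_that("subfamilies above the size cap are skipped with a log entry", {
  sim <- simulateFamily(n_genes = 12, cds_length = 120,
                        per_branch_sub_prob = 0, seed = 52,
                        class_label = "PA", family_id = "BIG")
  expect_message(
    out <- suppressWarnings(generateCandidates(sim$tree, sim$genes,
                                               rootNode(sim$tree))),
    "skipped")
  expect_null(out)
})

test_that("ranking is by target count, then score, then mature sequence", {
  cands <- rbind(fakeCand("CCCCCCCCCCCCCCCCCCCCC", 5, 2L),
                 fakeCand("GGGGGGGGGGGGGGGGGGGGG", 1, 3L),
                 fakeCand("AAAAAAAAAAAAAAAAAAAAA", 2, 2L))
  r <- rankCandidates(cands)
  expect_identical(r$n_targets, c(3L, 2L, 2L))
  expect_identical(r$score[2:3], c(5, 2))
  tie <- rbind(fakeCand("CCCCCCCCCCCCCCCCCCCCC", 1, 2L),
               fakeCand("AAAAAAAAAAAAAAAAAAAAA", 1, 2L))
  expect_identical(rankCandidates(tie)$mature[1], "AAAAAAAAAAAAAAAAAAAAA")
  # random lists equal an independent stable-sort oracle
  set.seed(53)
  rand <- do.call(rbind, lapply(1:30, function(i)
    fakeCand(paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                   collapse = ""),
             sample(1:5, 1), sample(2:4, 1))))
  ord <- order(-rand$n_targets, -rand$score, rand$mature)
  expect_identical(rankCandidates(rand)$mature, rand$mature[ord])
})

test_that("scores are monotone in mean fraction and off-target count, and hand-computable", {
  cfg <- designConfig()
  a <- fakeCand("TACGTACGTACGTACGTACGT", 0, 2L)
  a$targets <- I(list(c(g1 = 0.9, g2 = 0.8)))
  b <- a; b$targets <- I(list(c(g1 = 1.0, g2 = 0.95)))
  sc <- scoreCandidates(rbind(a, b), cfg)
  expect_gt(sc[2], sc[1])
  c2 <- a; c2$off_target_count <- 1L
  expect_gt(scoreCandidates(a, cfg), scoreCandidates(c2, cfg))
  # hand computation: mean fraction - |GC - 0.5| (off = 0)
  gc <- mean(strsplit(a$mature, "")[[1]] %in% c("G", "C"))
  expect_equal(sc[1], mean(c(0.9, 0.8)) - abs(gc - 0.5))
})

test_that("node budget caps admissions at x", {
  tr <- familyTree(ape::read.tree(text = "(A,B);"))
  set.seed(54)
  cands <- do.call(rbind, lapply(1:10, function(i)
    fakeCand(paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                   collapse = ""), i)))
  st <- selectNodePhase(tr, list("1" = cands), designConfig())
  expect_identical(nrow(st@chosen[["1"]]), 8L)
  st2 <- selectNodePhase(tr, list("1" = cands),
                         designConfig(node_budget_x = 3))
  expect_identical(nrow(st2@chosen[["1"]]), 3L)
})

test_that("similarity rules (a) and (b) govern admission along the lineage", {
  tr <- familyTree(ape::read.tree(text = "((A,B),(C,D));"))
  root <- rootNode(tr)
  m1 <- paste(rep("A", 21), collapse = "")
  m2 <- sub("^A", "C", m1)   # Hamming 1 from m1
  m3 <- paste(c(rep("G", 10), rep("A", 11)), collapse = "")  # far from both
  node_ab <- mrcaNode(tr, c("A", "B"))
  cfg <- designConfig(node_budget_x = 8)
  # lower-scoring similar candidate at a child is rejected
  cands <- setNames(list(fakeCand(m1, 5, node = root),
                         rbind(fakeCand(m2, 1, node = node_ab),
                               fakeCand(m3, 1, node = node_ab))),
                    c(as.character(root), as.character(node_ab)))
  st <- selectNodePhase(tr, cands, cfg)
  expect_identical(st@chosen[[as.character(node_ab)]]$mature, m3)
  # similar but strictly better scoring candidate is admitted by rule (b)
  cands2 <- setNames(list(fakeCand(m1, 5, node = root),
                          fakeCand(m2, 9, node = node_ab)),
                     c(as.character(root), as.character(node_ab)))
  st2 <- selectNodePhase(tr, cands2, cfg)
  expect_identical(st2@chosen[[as.character(node_ab)]]$mature, m2)
  # with rule (b) disabled it is rejected
  st3 <- selectNodePhase(tr, cands2, designConfig(rule_b = FALSE))
  expect_null(st3@chosen[[as.character(node_ab)]])
  # replace interpretation: the similar ancestor pick is dropped
  st4 <- selectNodePhase(tr, cands2, designConfig(replace_similar = TRUE))
  expect_identical(st4@chosen[[as.character(node_ab)]]$mature, m2)
  expect_identical(nrow(st4@chosen[[as.character(root)]]), 0L)
})

test_that("with rule (b) disabled all lineage pairs differ by at least m bases", {
  sim <- simulateFamily(n_genes = 6, cds_length = 300,
                        per_branch_sub_prob = 0.02, seed = 55,
                        class_label = "DMT", family_id = "FAMB")
  lib <- suppressWarnings(suppressMessages(
    runDesign(sim$genes, list(FAMB = sim$tree),
              designConfig(rule_b = FALSE))))
  e <- libraryEntries(lib)
  expect_gt(nrow(e), 0)
  tr <- sim$tree
  for (node in internalNodes(tr)) {
    here <- e$mature[e$origin_node == node]
    anc <- phyloAmiR:::ancestorNodes(tr, node)
    up <- e$mature[e$origin_node %in% anc]
    for (m in here) {
      others <- c(setdiff(here, m), up)
      if (length(others))
        expect_gte(min(vapply(others, function(y) hammingDist(m, y),
                              integer(1))), 2L)
    }
  }
})

test_that("blacklisted matures are removed and wrong-length entries warned about", {
  cands <- rbind(fakeCand("AAAAAAAAAAAAAAAAAAAAA", 1),
                 fakeCand("CCCCCCCCCCCCCCCCCCCCC", 2),
                 fakeCand("GGGGGGGGGGGGGGGGGGGGG", 3))
  expect_identical(nrow(suppressMessages(applyBlacklist(cands, character(0)))),
                   3L)
  out <- suppressMessages(
    applyBlacklist(cands, c("CCCCCCCCCCCCCCCCCCCCC")))
  expect_identical(nrow(out), 2L)
  expect_false("CCCCCCCCCCCCCCCCCCCCC" %in% out$mature)
  expect_warning(suppressMessages(applyBlacklist(cands, "ACGT")),
                 "wrong length")
  bl <- tempfile()
  writeLines(c("AAAAAAAAAAAAAAAAAAAAA", "GGGGGGGGGGGGGGGGGGGGG"), bl)
  expect_identical(suppressMessages(applyBlacklist(cands, bl))$mature,
                   "CCCCCCCCCCCCCCCCCCCCC")
})

test_that("node-phase effective targets are subsets of the origin subfamily and steps hold end to end", {
  sim <- simulateFamily(n_genes = 6, cds_length = 240,
                        per_branch_sub_prob = 0.02, seed = 56,
                        class_label = "MATE", family_id = "FAMC")
  cfg <- designConfig()
  lib <- suppressWarnings(suppressMessages(
    runDesign(sim$genes, list(FAMC = sim$tree), cfg)))
  e <- libraryEntries(lib)
  expect_gt(nrow(e), 0)
  expect_true(all(e$n_targets >= 2))
  fr <- lapply(strsplit(e$target_fractions, ";"), as.numeric)
  expect_true(all(unlist(fr) >= cfg@omega))
  for (i in seq_len(nrow(e))) {
    if (e$phase[i] == "node_phase") {
      tg <- strsplit(e$target_genes[i], ";")[[1]]
      expect_true(all(tg %in% subfamily(sim$tree, e$origin_node[i])))
    }
  }
  expect_lte(max(table(e$origin_node)), cfg@node_budget_x)
})

test_that("selection equals the exhaustive independent oracle on tiny families", {
  set.seed(57)
  for (rep in 1:3) {
    sim <- simulateFamily(n_genes = 3, cds_length = 150,
                          per_branch_sub_prob = 0.03, seed = 570 + rep,
                          class_label = "CP", family_id = "FAMO")
    cfg <- designConfig()
    sel <- suppressWarnings(suppressMessages(
      designFamily(sim$genes, sim$tree, cfg)))
    phy <- sim$tree@phylo
    orc <- oracleDesign(cdsSeqs(sim$genes), phy, "CP")
    key_pkg <- selectionKey(
      sel$mature, sel$phase,
      lapply(sel$targets, names),
      vapply(sel$origin_node, function(n)
        paste(subfamily(sim$tree, n), collapse = ","), character(1)))
    key_orc <- selectionKey(orc$mature, orc$phase,
                            orc$targets, orc$origin_leaves)
    expect_identical(key_pkg, key_orc)
    expect_gt(nrow(sel), 0)
  }
})

test_that("MRCA-phase candidates obey the cluster-distance cap", {
  # caterpillar: A and E are far apart; a guide hitting only {A, E} has two
  # singleton clusters at distance 4 and must be rejected
  phy <- ape::read.tree(text = "(A,(B,(C,(D,E))));")
  tr <- familyTree(phy)
  expect_identical(leafDistance(tr, "A", "E"), 4L)
  set.seed(58)
  base <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                collapse = "")
  scramble <- function() paste(sample(c("A", "C", "G", "T"), 150,
                                      replace = TRUE), collapse = "")
  # A and E share the base sequence; B, C, D are unrelated
  cds <- c(A = base, B = scramble(), C = scramble(), D = scramble(),
           E = base)
  gs <- toyGenes(cds, family = "FAMD", class = "UF")
  # cap subfamilies at 4 so the root is node-phase-skipped and {A, E} can
  # only be co-targeted through the MRCA phase, where the cluster rule bites
  cfg <- designConfig(max_subfamily_n = 4)
  sel <- suppressWarnings(suppressMessages(designFamily(gs, tr, cfg)))
  if (nrow(sel)) {
    for (i in seq_len(nrow(sel))) {
      expect_false(setequal(names(sel$targets[[i]]), c("A", "E")))
    }
  }
  # the same targets pass on a balanced tree where {A, E} is monophyletic
  phy2 <- ape::read.tree(text = "((A,E),(B,(C,D)));")
  tr2 <- familyTree(phy2)
  sel2 <- suppressWarnings(suppressMessages(designFamily(gs, tr2, cfg)))
  expect_true(any(vapply(sel2$targets, function(t)
    setequal(names(t), c("A", "E")), logical(1))))
})

test_that("off-target hits in a background transcriptome exclude candidates", {
  set.seed(59)
  cds <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
               collapse = "")
  gs <- toyGenes(c(gA = cds, gB = cds), family = "FAME", class = "ABC")
  tr <- familyTree(ape::read.tree(text = "(gA,gB);"))
  # background containing the family sequence itself: every candidate has a
  # perfect off-target hit and is excluded
  bg <- Biostrings::DNAStringSet(c(off1 = cds))
  sel_bg <- suppressMessages(designFamily(gs, tr, designConfig(),
                                          background = bg))
  expect_identical(nrow(sel_bg), 0L)
  # an unrelated background excludes nothing
  bg2 <- Biostrings::DNAStringSet(c(off1 = paste(
    sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")))
  sel_free <- suppressMessages(designFamily(gs, tr, designConfig(),
                                            background = bg2))
  expect_gt(nrow(sel_free), 0L)
  # no background at all warns prominently
  expect_warning(designFamily(gs, tr, designConfig()), "off-target")
})

test_that("design output is deterministic and independent of the config seed slot", {
  sim <- simulateFamily(n_genes = 5, cds_length = 210,
                        per_branch_sub_prob = 0.02, seed = 60,
                        class_label = "APC", family_id = "FAMF")
  l1 <- suppressWarnings(suppressMessages(
    runDesign(sim$genes, list(FAMF = sim$tree), designConfig(rng_seed = 1))))
  l2 <- suppressWarnings(suppressMessages(
    runDesign(sim$genes, list(FAMF = sim$tree), designConfig(rng_seed = 999))))
  expect_identical(libraryEntries(l1), libraryEntries(l2))
})
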