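# Tree computations: subfamilies, MRCA, internal-node distances,
# monophyletic partitions, cluster distances — including brute-force oracle
# equivalence on exhaustively enumerated topologies.

balanced4 <- function() familyTree(ape::read.tree(text = "((A,B),(C,D));"))
caterpillar <- function(txt = "(A,(B,(C,(D,E))));")
  familyTree(ape::read.tree(text = txt))

test_that("subfamilies are the leaf sets of subtrees", {
  tr <- balanced4()
  expect_identical(subfamily(tr, mrcaNode(tr, c("A", "B"))), c("A", "B"))
  expect_identical(subfamily(tr, rootNode(tr)), c("A", "B", "C", "D"))
  t2 <- familyTree(ape::read.tree(text = "(A,(B,(C,D)));"))
  expect_identical(subfamily(t2, mrcaNode(t2, c("B", "D"))),
                   c("B", "C", "D"))
  expect_error(subfamily(tr, 99), "internal node")
})

test_that("MRCA returns the deepest covering node", {
  tr <- balanced4()
  expect_identical(subfamily(tr, mrcaNode(tr, c("A", "B"))), c("A", "B"))
  expect_identical(mrcaNode(tr, c("A", "C")), rootNode(tr))
  expect_error(mrcaNode(tr, c("A", "Z")), "Z")
})

test_that("leaf distance counts internal nodes on the path, MRCA included", {
  tr <- balanced4()
  expect_identical(leafDistance(tr, "A", "B"), 1L)
  expect_identical(leafDistance(tr, "A", "C"), 3L)
  expect_identical(leafDistance(tr, "A", "A"), 0L)
  cat5 <- caterpillar()
  expect_identical(leafDistance(cat5, "A", "E"), 4L)
})

test_that("monophyletic partition returns maximal blocks, deterministically ordered", {
  tr <- balanced4()
  expect_identical(monophyleticPartition(tr, c("A", "B", "C")),
                   list(c("A", "B"), "C"))
  expect_identical(monophyleticPartition(tr, c("A", "B", "C", "D")),
                   list(c("A", "B", "C", "D")))
  t2 <- familyTree(ape::read.tree(text = "(A,(B,(C,D)));"))
  expect_identical(monophyleticPartition(t2, c("A", "C")),
                   list("A", "C"))
  expect_error(monophyleticPartition(tr, character(0)), "non-empty")
})

test_that("cluster distance is the minimum cross-pair leaf distance", {
  tr <- balanced4()
  expect_identical(clusterDistance(tr, c("A", "B"), "C"), 3L)
  expect_identical(clusterDistance(tr, "A", "B"), 1L)
  t2 <- familyTree(ape::read.tree(text = "(A,(B,(C,D)));"))
  expect_identical(clusterDistance(t2, "A", c("C", "D")),
                   min(leafDistance(t2, "A", "C"), leafDistance(t2, "A", "D")))
  expect_error(clusterDistance(tr, c("A", "B"), c("B", "C")), "overlap")
})

test_that("distances are symmetric and satisfy the triangle inequality", {
  set.seed(11)
  for (rep in 1:5) {
    phy <- randomOracleTree(LETTERS[1:7])
    tr <- familyTree(phy)
    tips <- leafLabels(tr)
    for (k in 1:10) {
      ijk <- sample(tips, 3)
      dij <- leafDistance(tr, ijk[1], ijk[2])
      expect_identical(dij, leafDistance(tr, ijk[2], ijk[1]))
      expect_lte(dij, leafDistance(tr, ijk[1], ijk[3]) +
                   leafDistance(tr, ijk[3], ijk[2]))
    }
  }
})

test_that("partitions cover the targets exactly and disjointly; mrca/subfamily laws hold", {
  set.seed(12)
  for (rep in 1:10) {
    phy <- randomOracleTree(paste0("g", 1:8))
    tr <- familyTree(phy)
    tips <- leafLabels(tr)
    targets <- sample(tips, sample(2:6, 1))
    p <- monophyleticPartition(tr, targets)
    expect_setequal(unlist(p), targets)
    expect_identical(anyDuplicated(unlist(p)), 0L)
    expect_identical(mrcaNode(tr, tips), rootNode(tr))
    S <- sample(tips, 3)
    expect_true(all(S %in% subfamily(tr, mrcaNode(tr, S))))
  }
})

test_that("tree operations match ape/brute-force oracles on all 5-leaf topologies", {
  skip_if_not_installed("phangorn")
  trees <- phangorn::allTrees(5, rooted = TRUE, tip.label = LETTERS[1:5])
  expect_length(trees, 105L)
  set.seed(21)
  for (ti in seq_along(trees)) {
    phy <- trees[[ti]]  # [[ expands the compressed multiPhylo tip labels
    tr <- familyTree(phy)
    tips <- phy$tip.label
    # distances vs ape::nodepath
    prs <- utils::combn(tips, 2)
    for (k in seq_len(ncol(prs))) {
      expect_identical(leafDistance(tr, prs[1, k], prs[2, k]),
                       oracleLeafDistance(phy, prs[1, k], prs[2, k]))
    }
    # MRCA vs ape::getMRCA (mapped through stable IDs)
    S <- sample(tips, 3)
    expect_identical(tr@apeNode[mrcaNode(tr, S)], ape::getMRCA(phy, S))
    # partition vs exhaustive set-partition enumeration
    targets <- sample(tips, sample(2:5, 1))
    expect_identical(canonicalPartition(monophyleticPartition(tr, targets)),
                     canonicalPartition(oraclePartition(phy, targets)))
  }
})

test_that("tree operations match oracles on random 6-8 leaf trees", {
  set.seed(31)
  for (n in 6:8) {
    for (rep in 1:8) {
      phy <- randomOracleTree(paste0("t", seq_len(n)))
      tr <- familyTree(phy)
      tips <- phy$tip.label
      pr <- sample(tips, 2)
      expect_identical(leafDistance(tr, pr[1], pr[2]),
                       oracleLeafDistance(phy, pr[1], pr[2]))
      targets <- sample(tips, sample(2:5, 1))
      expect_identical(canonicalPartition(monophyleticPartition(tr, targets)),
                       canonicalPartition(oraclePartition(phy, targets)))
      expect_identical(tr@apeNode[mrcaNode(tr, targets)],
                       ape::getMRCA(phy, targets))
    }
  }
})

test_that("multifurcating nodes induce one subfamily and partial child groups are not monophyletic", {
  tr <- familyTree(ape::read.tree(text = "((A,B,C),(D,E));"))
  n_abc <- mrcaNode(tr, c("A", "B"))
  expect_identical(subfamily(tr, n_abc), c("A", "B", "C"))
  # {A,B} is not the full leaf set of any subtree under the trifurcation
  expect_identical(monophyleticPartition(tr, c("A", "B")), list("A", "B"))
})
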