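#' Rooted gene-family tree with stable internal-node numbering
#'
#' Wraps an \code{ape} \code{phylo} object and assigns every internal node a
#' stable integer ID by deterministic post-order traversal, with children
#' visited in order of the lexicographically smallest leaf label in their
#' subtree. The numbering is therefore a pure function of topology and leaf
#' labels: rotating clades in the Newick string does not change IDs. Branch
#' lengths, if present, are ignored; all distances are internal-node counts.
#'
#' @slot phylo the underlying \code{ape::phylo} tree
#' @slot apeNode integer; apeNode[id] is the ape node number of stable ID id
#' @slot cladeList list; sorted leaf labels of the subtree under each ID
#' @slot parentId integer; parent stable ID per ID (NA at the root)
#' @slot leafPath named list; for each leaf label, the stable IDs of its
#'   ancestors ordered parent first, root last
#' @exportClass FamilyTree
setClass("FamilyTree", representation(phylo = "ANY",
                                      apeNode = "integer",
                                      cladeList = "list",
                                      parentId = "integer",
                                      leafPath = "list"))

setValidity("FamilyTree", function(object) {
  msg <- character(0)
  phy <- object@phylo
  if (!inherits(phy, "phylo")) return("phylo slot must be an ape phylo tree")
  if (anyDuplicated(phy$tip.label)) msg <- c(msg, "duplicate leaf labels")
  if (sum(is.na(object@parentId)) != 1L)
    msg <- c(msg, "exactly one root expected")
  K <- length(object@apeNode)
  if (!setequal(object@cladeList[[K]], phy$tip.label))
    msg <- c(msg, "root subfamily must equal the full leaf set")
  if (length(msg)) msg else TRUE
})

#' Build a FamilyTree from an ape phylo object
#'
#' @param phy rooted \code{phylo} (an unrooted basal trifurcation is accepted
#'   and its basal node treated as the root); multifurcations allowed
#' @param expected_leaf_ids optional character vector; if given, the leaf
#'   label set must equal it exactly
#' @return a \code{FamilyTree}
#' @export
familyTree <- function(phy, expected_leaf_ids = NULL) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape phylo object")
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  }
  if (!is.null(expected_leaf_ids)) {
    missing_ <- setdiff(expected_leaf_ids, phy$tip.label)
    extra <- setdiff(phy$tip.label, expected_leaf_ids)
    if (length(missing_) || length(extra)) {
      stop(sprintf(
        "leaf/gene mismatch; absent from tree: {%s}; absent from genes: {%s}",
        paste(missing_, collapse = ", "), paste(extra, collapse = ", ")))
    }
  }
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  children <- vector("list", ntip + nnode)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]
    children[[p]] <- c(children[[p]], phy$edge[e, 2])
  }
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]

  clade <- vector("list", ntip + nnode)  # sorted leaf labels per ape node
  minleaf <- character(ntip + nnode)
  fill <- function(v) {
    if (v <= ntip) {
      clade[[v]] <<- phy$tip.label[v]
      minleaf[v] <<- phy$tip.label[v]
      return(invisible(NULL))
    }
    for (ch in children[[v]]) fill(ch)
    clade[[v]] <<- sort(unique(unlist(clade[children[[v]]])))
    minleaf[v] <<- min(minleaf[children[[v]]])
    invisible(NULL)
  }
  fill(root)

  ape_order <- integer(0)  # internal ape nodes in canonical post-order
  walk <- function(v) {
    if (v <= ntip) return(invisible(NULL))
    for (ch in children[[v]][order(minleaf[children[[v]]])]) walk(ch)
    ape_order <<- c(ape_order, v)
    invisible(NULL)
  }
  walk(root)

  id_of <- integer(ntip + nnode)
  id_of[ape_order] <- seq_along(ape_order)
  parent_of <- integer(ntip + nnode)  # ape parent per ape node
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  parentId <- vapply(ape_order, function(v) {
    if (v == root) NA_integer_ else id_of[parent_of[v]]
  }, integer(1))

  leafPath <- vector("list", ntip)
  names(leafPath) <- phy$tip.label
  for (tip in seq_len(ntip)) {
    path <- integer(0)
    v <- parent_of[tip]
    repeat {
      path <- c(path, id_of[v])
      if (v == root) break
      v <- parent_of[v]
    }
    leafPath[[phy$tip.label[tip]]] <- path
  }

  new("FamilyTree", phylo = phy, apeNode = ape_order,
      cladeList = clade[ape_order], parentId = parentId,
      leafPath = leafPath)
}

#' Read a gene tree from a Newick file
#'
#' @param newick_path path to a Newick file (single tree)
#' @param expected_leaf_ids gene IDs the leaf labels must equal exactly
#' @return a \code{FamilyTree}
#' @export
readFamilyTree <- function(newick_path, expected_leaf_ids = NULL) {
  phy <- ape::read.tree(newick_path)
  if (is.null(phy)) stop("failed to parse Newick file: ", newick_path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  familyTree(phy, expected_leaf_ids)
}

#' @describeIn familyTree leaf labels of the whole tree
#' @param x a FamilyTree
#' @export
leafLabels <- function(x) x@phylo$tip.label

#' @describeIn familyTree stable IDs of all internal nodes (1..K, root = K)
#' @export
internalNodes <- function(x) seq_along(x@apeNode)

#' @describeIn familyTree stable ID of the root
#' @export
rootNode <- function(x) length(x@apeNode)

#' @describeIn familyTree parent stable ID (NA at the root)
#' @param node internal node stable ID
#' @export
parentNode <- function(x, node) x@parentId[node]

checkNode <- function(x, node) {
  if (!(is.numeric(node) && length(node) == 1L && node >= 1 &&
        node <= length(x@apeNode)))
    stop("not an internal node of this tree: ", node)
  as.integer(node)
}

#' Subfamily induced by an internal node
#'
#' The leaf labels (gene IDs) of the subtree rooted at \code{node}. Nodes
#' further from the root induce smaller subfamilies of more closely related
#' genes.
#'
#' @param tree a \code{FamilyTree}
#' @param node internal node stable ID
#' @return character vector of gene IDs (always length >= 2)
#' @export
subfamily <- function(tree, node) {
  node <- checkNode(tree, node)
  tree@cladeList[[node]]
}

#' Most recent common ancestor of a set of genes
#'
#' @param tree a \code{FamilyTree}
#' @param genes character vector of at least two leaf labels
#' @return stable ID of the deepest internal node whose subfamily contains
#'   all of \code{genes}
#' @export
mrcaNode <- function(tree, genes) {
  genes <- unique(genes)
  unknown <- setdiff(genes, leafLabels(tree))
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  if (length(genes) < 2L) stop("mrcaNode needs at least two genes")
  for (id in tree@leafPath[[genes[1]]]) {
    if (all(genes %in% tree@cladeList[[id]])) return(id)
  }
  rootNode(tree)
}

#' Leaf-to-leaf distance in internal nodes
#'
#' Counts every internal node on the unique path between two leaves,
#' including the MRCA and excluding the leaves themselves; siblings are at
#' distance 1. By documented convention the distance of a leaf to itself
#' is 0.
#'
#' @param tree a \code{FamilyTree}
#' @param i,j leaf labels
#' @return non-negative integer
#' @export
leafDistance <- function(tree, i, j) {
  if (identical(i, j)) return(0L)
  pi_ <- tree@leafPath[[i]]
  pj <- tree@leafPath[[j]]
  if (is.null(pi_)) stop("unknown gene: ", i)
  if (is.null(pj)) stop("unknown gene: ", j)
  common <- intersect(pi_, pj)
  m <- common[1]  # paths are ordered towards the root; first shared = MRCA
  (match(m, pi_) - 1L) + (match(m, pj) - 1L) + 1L
}

#' Partition target genes into maximal monophyletic clusters
#'
#' Splits \code{targets} into the minimum number of blocks such that each
#' block is exactly the leaf set of some subtree (a single leaf counts as a
#' subtree). Under a multifurcation a block must cover the full leaf set of
#' a child subtree; partial groups of children are not monophyletic.
#' Clusters are ordered by their smallest member gene ID.
#'
#' @param tree a \code{FamilyTree}
#' @param targets non-empty character vector of leaf labels
#' @return list of character vectors partitioning \code{targets}
#' @export
monophyleticPartition <- function(tree, targets) {
  targets <- unique(targets)
  if (length(targets) == 0L) stop("targets must be non-empty")
  unknown <- setdiff(targets, leafLabels(tree))
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  K <- length(tree@apeNode)
  inT <- vapply(seq_len(K), function(id)
    all(tree@cladeList[[id]] %in% targets), logical(1))
  maximal <- which(inT & vapply(seq_len(K), function(id) {
    p <- tree@parentId[id]
    is.na(p) || !inT[p]
  }, logical(1)))
  clusters <- tree@cladeList[maximal]
  covered <- unlist(clusters)
  singles <- setdiff(targets, covered)
  # a lone leaf is maximal unless some qualifying internal clade covers it
  singles <- singles[vapply(singles, function(l) {
    p <- tree@leafPath[[l]][1]
    !inT[p]
  }, logical(1))]
  clusters <- c(clusters, as.list(singles))
  clusters[order(vapply(clusters, min, character(1)))]
}

#' Distance between two monophyletic clusters
#'
#' Minimum leaf-to-leaf internal-node distance over all cross-cluster pairs.
#'
#' @param tree a \code{FamilyTree}
#' @param A,B disjoint non-empty character vectors of leaf labels
#' @return integer
#' @export
clusterDistance <- function(tree, A, B) {
  if (length(A) == 0L || length(B) == 0L) stop("clusters must be non-empty")
  if (length(intersect(A, B))) stop("clusters overlap")
  min(vapply(A, function(i)
    min(vapply(B, function(j) leafDistance(tree, i, j), integer(1))),
    integer(1)))
}

#' Node numbering table (debug dump)
#'
#' @param tree a \code{FamilyTree}
#' @return data.frame with node_id, parent_id, n_leaves, leaves
#' @export
nodeTable <- function(tree) {
  data.frame(
    node_id = internalNodes(tree),
    parent_id = tree@parentId,
    n_leaves = vapply(tree@cladeList, length, integer(1)),
    leaves = vapply(tree@cladeList, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
}

setMethod("show", "FamilyTree", function(object) {
  cat(sprintf("FamilyTree: %d leaves, %d internal nodes (root = node %d)\n",
              length(object@phylo$tip.label), length(object@apeNode),
              rootNode(object)))
})
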