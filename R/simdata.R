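#' @include GeneSet.R FamilyTree.R
NULL

# run expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# random rooted binary tree over labels, by recursive random bifurcation of
# the leaf set (uses the current RNG stream)
randomBifurcationNewick <- function(labels) {
  split_set <- function(lab) {
    if (length(lab) == 1L) return(lab)
    k <- sample(seq_len(length(lab) - 1L), 1L)
    left <- sample(lab, k)
    right <- setdiff(lab, left)
    paste0("(", split_set(left), ",", split_set(right), ")")
  }
  paste0(split_set(labels), ";")
}

mutateSeq <- function(chars, p) {
  idx <- which(stats::runif(length(chars)) < p)
  if (length(idx)) {
    b <- c("A", "C", "G", "T")
    cur <- match(chars[idx], b)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    chars[idx] <- b[((cur - 1L + shift) %% 4L) + 1L]
  }
  chars
}

#' Simulate a gene family of paralogs along a known tree
#'
#' Draws a root CDS uniformly over the 61 sense codons and evolves it down
#' the tree with independent per-site substitutions (probability
#' \code{per_branch_sub_prob} per site per branch, uniform over the three
#' alternative bases, no indels). Closely related leaves therefore share
#' conserved 21-nt windows, the raw material of multi-target guide design.
#' Pure function of its arguments and \code{seed}.
#'
#' @param n_genes number of paralogs (>= 2); ignored when \code{tree} is given
#' @param cds_length CDS length in nt (multiple of 3, default 600)
#' @param tree \code{"random"} (recursive random bifurcation), a Newick
#'   string, or a \code{phylo} object whose tip labels become the gene IDs
#' @param per_branch_sub_prob substitution probability per site per branch,
#'   in [0, 0.3]; a warning is issued if the expected number of shared
#'   21-nt windows between siblings falls below 1
#' @param seed integer seed
#' @param class_label functional class for every gene (8-class vocabulary)
#' @param family_id family identifier
#' @return list with \code{genes} (a \code{GeneSet}), \code{tree} (a
#'   \code{FamilyTree}) and \code{newick} (the tree string)
#' @export
simulateFamily <- function(n_genes = 8L, cds_length = 600L, tree = "random",
                           per_branch_sub_prob = 0.01, seed = 1L,
                           class_label = "UF", family_id = "FAM1") {
  if (cds_length %% 3L != 0L || cds_length < 21L)
    stop("cds_length must be a multiple of 3 and >= 21")
  if (per_branch_sub_prob < 0 || per_branch_sub_prob > 0.3)
    stop("per_branch_sub_prob must be in [0, 0.3]")
  if (!class_label %in% CLASS_VOCAB)
    stop("class_label outside the 8-class vocabulary")
  exp_shared <- (cds_length - 20) * (1 - per_branch_sub_prob)^42
  if (exp_shared < 1)
    warning("substitution rate so high that siblings are not expected to share any 21-nt window",
            call. = FALSE)
  withSeed(seed, {
    if (identical(tree, "random")) {
      if (n_genes < 2L) stop("n_genes must be >= 2")
      labels <- sprintf("%s_g%02d", family_id, seq_len(n_genes))
      newick <- randomBifurcationNewick(labels)
      phy <- ape::read.tree(text = newick)
    } else if (inherits(tree, "phylo")) {
      phy <- tree
      newick <- ape::write.tree(phy)
    } else {
      phy <- ape::read.tree(text = tree)
      newick <- tree
    }
    labels <- phy$tip.label
    ntip <- length(labels)
    root_cds <- strsplit(paste(sample(SENSE_CODONS, cds_length / 3L,
                                      replace = TRUE), collapse = ""),
                         "", fixed = TRUE)[[1]]
    nnode_total <- ntip + phy$Nnode
    seqs <- vector("list", nnode_total)
    root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
    seqs[[root]] <- root_cds
    kids <- split(phy$edge[, 2], phy$edge[, 1])
    evolve <- function(v) {
      for (ch in kids[[as.character(v)]]) {
        seqs[[ch]] <<- mutateSeq(seqs[[v]], per_branch_sub_prob)
        if (ch > ntip) evolve(ch)
      }
    }
    evolve(root)
    cds <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    anno <- data.frame(gene_id = labels, family_id = family_id,
                       class_label = class_label, stringsAsFactors = FALSE)
    genes <- geneSet(setNames(cds, labels), anno)
    list(genes = genes, tree = familyTree(phy, labels), newick = newick)
  })
}

#' Simulate a panel of gene families
#'
#' Convenience wrapper around \code{\link{simulateFamily}}: one family per
#' entry of \code{n_genes} (defaults span small to large families, 8 to 16
#' paralogs), with per-family seeds \code{seed, seed+1, ...} and functional
#' classes cycling through the 8-class vocabulary.
#'
#' @param n_genes integer vector of family sizes
#' @param cds_length,per_branch_sub_prob as in \code{\link{simulateFamily}}
#' @param seed base seed
#' @param class_labels classes per family (recycled); default cycles the
#'   vocabulary
#' @return list with \code{genes} (one combined \code{GeneSet}) and
#'   \code{trees} (named list of \code{FamilyTree})
#' @export
simulateFamilySet <- function(n_genes = c(8L, 10L, 12L, 14L, 16L),
                              cds_length = 600L,
                              per_branch_sub_prob = 0.01,
                              seed = 42L,
                              class_labels = NULL) {
  k <- length(n_genes)
  if (is.null(class_labels))
    class_labels <- rep_len(CLASS_VOCAB, k)
  class_labels <- rep_len(class_labels, k)
  sims <- lapply(seq_len(k), function(i)
    simulateFamily(n_genes = n_genes[i], cds_length = cds_length,
                   per_branch_sub_prob = per_branch_sub_prob,
                   seed = seed + i - 1L, class_label = class_labels[i],
                   family_id = sprintf("FAM%02d", i)))
  seqs <- do.call(c, lapply(sims, function(s) s$genes@seqs))
  anno <- do.call(rbind, lapply(sims, function(s) s$genes@anno))
  trees <- setNames(lapply(sims, `[[`, "tree"),
                    vapply(sims, function(s) unique(s$genes@anno$family_id),
                           character(1)))
  list(genes = geneSet(seqs, anno), trees = trees)
}

#' @describeIn simulateReads exactly \code{k} reads per member
#' @param k reads per member
#' @export
depthUniform <- function(k) list(type = "uniform", k = as.integer(k))

#' @describeIn simulateReads lognormal per-member depths (rounded, minimum 0)
#' @param meanlog,sdlog lognormal parameters
#' @export
depthLognormal <- function(meanlog = log(50), sdlog = 0.5) {
  list(type = "lognormal", meanlog = meanlog, sdlog = sdlog)
}

#' @describeIn simulateReads explicit per-member depth vector
#' @param counts integer vector, one depth per library member (in entry order)
#' @export
depthCustom <- function(counts) list(type = "custom",
                                     counts = as.integer(counts))

#' Simulate an amplicon read pool over a designed library
#'
#' Emits reads containing each member's amplicon region (the full oligo, so
#' every read carries the member's identifying antisense arm). Uniform
#' depth yields exactly \code{k} reads per member; lognormal draws
#' per-member depths. Deterministic given \code{seed}.
#'
#' @param library an \code{AmiRLibrary} or entries data.frame
#' @param depth_spec \code{depthUniform(k)}, \code{depthLognormal(...)} or
#'   \code{depthCustom(counts)}
#' @param seed integer seed (used by stochastic depth specs)
#' @return a \code{DNAStringSet} of reads named \code{<amirna_id>/<i>}
#' @export
simulateReads <- function(library, depth_spec = depthUniform(5L), seed = 1L) {
  entries <- if (is(library, "AmiRLibrary")) library@entries else library
  if (nrow(entries) == 0L) stop("library is empty")
  n <- nrow(entries)
  depths <- withSeed(seed, switch(
    depth_spec$type,
    uniform = rep(depth_spec$k, n),
    lognormal = pmax(0L, as.integer(round(
      rlnorm(n, depth_spec$meanlog, depth_spec$sdlog)))),
    custom = {
      if (length(depth_spec$counts) != n)
        stop("custom depth vector length must equal the library size")
      depth_spec$counts
    },
    stop("unknown depth spec type")))
  reads <- rep(entries$oligo, depths)
  ids <- paste0(rep(entries$amirna_id, depths), "/",
                unlist(lapply(depths, seq_len), use.names = FALSE))
  Biostrings::DNAStringSet(setNames(reads, ids))
}

#' Write simulated reads to FASTA or FASTQ
#'
#' @param reads a \code{DNAStringSet}
#' @param path output path
#' @param format \code{"fasta"} or \code{"fastq"} (constant quality)
#' @return invisibly, \code{path}
#' @export
writeReads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fastq") {
    q <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(w)
      paste(rep("I", w), collapse = ""), character(1)))
    Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  } else {
    Biostrings::writeXStringSet(reads, path)
  }
  invisible(path)
}

#' Write a simulated family to FASTA + annotation TSV + Newick
#'
#' @param sim result of \code{\link{simulateFamily}}
#' @param out_prefix output path prefix
#' @return invisibly, the three file paths
#' @export
writeFamily <- function(sim, out_prefix) {
  fa <- paste0(out_prefix, ".fasta")
  tsv <- paste0(out_prefix, "_annotation.tsv")
  nwk <- paste0(out_prefix, ".nwk")
  Biostrings::writeXStringSet(sim$genes@seqs, fa)
  write.table(sim$genes@anno, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(sim$newick, nwk)
  invisible(c(fasta = fa, annotation = tsv, newick = nwk))
}
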