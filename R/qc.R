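#' @include assembly.R
NULL

#' Per-member amplicon read counts
#'
#' @slot counts named integer; reads assigned to each library member
#' @slot total_reads integer; all reads seen
#' @slot unassigned integer; reads matching zero or two-plus members
#' @exportClass ReadCountTable
setClass("ReadCountTable", representation(counts = "integer",
                                          total_reads = "integer",
                                          unassigned = "integer"))

setValidity("ReadCountTable", function(object) {
  if (sum(object@counts) + object@unassigned != object@total_reads)
    return("counts + unassigned must equal total_reads")
  TRUE
})

setMethod("show", "ReadCountTable", function(object) {
  cat(sprintf(
    "ReadCountTable: %d reads, %d assigned over %d members, %d unassigned\n",
    object@total_reads, sum(object@counts), length(object@counts),
    object@unassigned))
})

#' @describeIn countReads named integer vector of per-member counts
#' @param x a \code{ReadCountTable}
#' @export
readCounts <- function(x) x@counts

#' Count amplicon reads per library member
#'
#' A read is assigned to a member iff it contains that member's identifying
#' 21-mer exactly, in forward or reverse-complement orientation. Reads
#' matching zero members or two or more members are tallied as unassigned.
#' Matching is exact (the identifying 21-mer is designed unique); a
#' Hamming-distance-1 rescue for otherwise-unmatched reads is available
#' behind \code{hamming1}.
#'
#' @param reads a \code{DNAStringSet}, or a path to a FASTA/FASTQ file
#'   (quality values are ignored)
#' @param library an \code{AmiRLibrary} or entries data.frame
#' @param match_region which part of the oligo identifies a member:
#'   \code{"mature"} (the 21-nt antisense arm, default) or \code{"star"}
#' @param hamming1 also accept a single mismatch for reads with no exact hit
#' @return a \code{ReadCountTable}
#' @export
countReads <- function(reads, library, match_region = c("mature", "star"),
                       hamming1 = FALSE) {
  match_region <- match.arg(match_region)
  entries <- if (is(library, "AmiRLibrary")) library@entries else library
  if (nrow(entries) == 0L) stop("library is empty")
  if (is.character(reads)) {
    fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  ids <- entries$amirna_id
  key <- entries[[match_region]]
  if (length(reads) == 0L) {
    warning("empty read set: all-zero count table", call. = FALSE)
    return(new("ReadCountTable", counts = setNames(integer(length(ids)), ids),
               total_reads = 0L, unassigned = 0L))
  }
  pd_f <- Biostrings::PDict(key)
  pd_r <- Biostrings::PDict(revcompDna(key))
  hit <- Biostrings::vcountPDict(pd_f, reads) > 0L |
    Biostrings::vcountPDict(pd_r, reads) > 0L   # members x reads
  n_per_read <- colSums(hit)
  if (hamming1 && any(n_per_read == 0L)) {
    for (r in which(n_per_read == 0L)) {
      hits1 <- vapply(key, function(k) {
        length(Biostrings::matchPattern(k, reads[[r]],
                                        max.mismatch = 1)) > 0L ||
          length(Biostrings::matchPattern(revcompDna(k), reads[[r]],
                                          max.mismatch = 1)) > 0L
      }, logical(1))
      hit[, r] <- hits1
      n_per_read[r] <- sum(hits1)
    }
  }
  assigned <- n_per_read == 1L
  counts <- setNames(integer(length(ids)), ids)
  if (any(assigned)) {
    member <- apply(hit[, assigned, drop = FALSE], 2, which.max)
    tab <- table(member)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  new("ReadCountTable", counts = counts,
      total_reads = length(reads),
      unassigned = as.integer(sum(!assigned)))
}

#' Library coverage from a read-count table
#'
#' Percentage of library members detected with at least one read relative
#' to the number of members theoretically synthesized.
#'
#' @param table a \code{ReadCountTable} computed against \code{library}
#' @param library an \code{AmiRLibrary} or entries data.frame
#' @return percentage in [0, 100]
#' @export
libraryCoverage <- function(table, library) {
  entries <- if (is(library, "AmiRLibrary")) library@entries else library
  if (nrow(entries) == 0L) stop("library is empty")
  100 * sum(table@counts[entries$amirna_id] >= 1L, na.rm = TRUE) /
    nrow(entries)
}

#' Skew of the read distribution across members
#'
#' Adjusted Fisher-Pearson sample skewness of per-member read fractions
#' (count / total assigned). Zero for a perfectly uniform table, positive
#' when a few members soak up a disproportionate share of reads; invariant
#' under member relabeling.
#'
#' @param table a \code{ReadCountTable} over at least 3 members
#' @return numeric skewness
#' @export
librarySkew <- function(table) {
  if (length(table@counts) < 3L) stop("skew needs at least 3 members")
  total <- sum(table@counts)
  if (total == 0L) stop("no assigned reads: skew undefined")
  frac <- table@counts / total
  if (max(frac) == min(frac)) return(0)  # degenerate symmetric distribution
  e1071::skewness(frac, type = 2)
}

#' Design-summary statistics
#'
#' Histograms of (i) effective targets per amiRNA, (ii) amiRNAs per
#' internal node (zero-count nodes included when trees are supplied),
#' (iii) amiRNAs per gene, and per-class totals.
#'
#' @param library an \code{AmiRLibrary} or entries data.frame
#' @param trees optional named list of \code{FamilyTree} objects (to include
#'   internal nodes with zero amiRNAs)
#' @param out_prefix optional path prefix; when given, each table is written
#'   to \code{<out_prefix>_<name>.tsv}
#' @return named list of data.frames: targets_per_amirna, amirnas_per_node,
#'   amirnas_per_gene, per_class
#' @export
summaryStats <- function(library, trees = NULL, out_prefix = NULL) {
  entries <- if (is(library, "AmiRLibrary")) library@entries else library
  tpa <- as.data.frame(table(n_targets = entries$n_targets),
                       stringsAsFactors = FALSE)
  names(tpa) <- c("n_targets", "n_amirnas")
  tpa$n_targets <- as.integer(tpa$n_targets)

  node_key <- paste(entries$family_id, entries$origin_node, sep = ":")
  per_node <- table(node_key)
  if (!is.null(trees)) {
    all_nodes <- unlist(lapply(names(trees), function(f)
      paste(f, internalNodes(trees[[f]]), sep = ":")))
    full <- setNames(integer(length(all_nodes)), all_nodes)
    full[names(per_node)] <- as.integer(per_node)
    per_node <- full
  }
  apn <- data.frame(family_node = names(per_node),
                    n_amirnas = as.integer(per_node),
                    stringsAsFactors = FALSE)

  genes <- unlist(strsplit(entries$target_genes, ";", fixed = TRUE))
  apg <- as.data.frame(table(gene_id = genes), stringsAsFactors = FALSE)
  names(apg) <- c("gene_id", "n_amirnas")

  pc <- as.data.frame(table(class_label = entries$class_label),
                      stringsAsFactors = FALSE)
  names(pc) <- c("class_label", "n_amirnas")

  out <- list(targets_per_amirna = tpa, amirnas_per_node = apn,
              amirnas_per_gene = apg, per_class = pc)
  if (!is.null(out_prefix)) {
    for (nm in names(out)) {
      write.table(out[[nm]], paste0(out_prefix, "_", nm, ".tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
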