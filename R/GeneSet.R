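#' Annotated gene set
#'
#' Coding sequences plus per-gene annotation (family and functional class).
#' Sequences are held as a \code{\link[Biostrings]{DNAStringSet}} named by
#' gene ID; annotation rows are parallel to the sequences.
#'
#' @slot seqs DNAStringSet of coding sequences (uppercase, no ambiguity codes)
#' @slot anno data.frame with columns gene_id, family_id, class_label
#' @exportClass GeneSet
setClass("GeneSet", representation(seqs = "DNAStringSet",
                                   anno = "data.frame"))

setValidity("GeneSet", function(object) {
  msg <- character(0)
  anno <- object@anno
  if (!all(c("gene_id", "family_id", "class_label") %in% names(anno)))
    return("annotation needs gene_id, family_id, class_label columns")
  if (length(object@seqs) != nrow(anno))
    msg <- c(msg, "sequence and annotation counts differ")
  if (anyDuplicated(anno$gene_id))
    msg <- c(msg, "duplicated gene_id")
  if (!identical(names(object@seqs), anno$gene_id))
    msg <- c(msg, "sequence names must equal annotation gene_id, in order")
  if (!all(anno$class_label %in% CLASS_VOCAB))
    msg <- c(msg, sprintf("class_label outside {%s}",
                          paste(CLASS_VOCAB, collapse = ", ")))
  s <- as.character(object@seqs)
  bad <- grepl("[^ACGT]", s)
  if (any(bad))
    msg <- c(msg, sprintf("ambiguity codes or lowercase in CDS of gene %s",
                          anno$gene_id[which(bad)[1]]))
  if (length(object@seqs) && any(Biostrings::width(object@seqs) < 21L))
    msg <- c(msg, "every CDS must be at least 21 nt")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSet from sequences and annotation
#' @param seqs DNAStringSet (or named character vector) of CDSs
#' @param anno data.frame with gene_id, family_id, class_label
#' @return a validated \code{GeneSet}
#' @export
geneSet <- function(seqs, anno) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  anno <- anno[match(names(seqs), anno$gene_id), , drop = FALSE]
  rownames(anno) <- NULL
  new("GeneSet", seqs = seqs, anno = anno)
}

#' @describeIn geneSet gene identifiers
#' @param x a GeneSet
#' @export
geneIds <- function(x) x@anno$gene_id

#' @describeIn geneSet family identifier per gene
#' @export
familyIds <- function(x) setNames(x@anno$family_id, x@anno$gene_id)

#' @describeIn geneSet functional class per gene
#' @export
classLabels <- function(x) setNames(x@anno$class_label, x@anno$gene_id)

#' @describeIn geneSet coding sequences as a named character vector
#' @export
cdsSeqs <- function(x) setNames(as.character(x@seqs), names(x@seqs))

#' @describeIn geneSet subset to one family
#' @param family family identifier
#' @export
familySubset <- function(x, family) {
  keep <- x@anno$family_id == family
  geneSet(x@seqs[keep], x@anno[keep, , drop = FALSE])
}

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet: %d genes, %d families, classes: %s\n",
              length(object@seqs), length(unique(object@anno$family_id)),
              paste(sort(unique(object@anno$class_label)), collapse = ", ")))
})

#' Read a gene set from FASTA plus an annotation table
#'
#' FASTA record names must match the \code{gene_id} column of the TSV.
#' Genes present in the FASTA but lacking annotation are reported to stderr
#' and dropped; an empty intersection is fatal. Any CDS containing ambiguity
#' codes triggers a validation error naming the gene.
#'
#' @param fasta_path FASTA of coding sequences (DNA)
#' @param annotation_tsv_path TSV with columns gene_id, family_id, class_label
#' @return a \code{GeneSet}
#' @export
readGeneSet <- function(fasta_path, annotation_tsv_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  anno <- read.delim(annotation_tsv_path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "family_id", "class_label") %in% names(anno)))
    stop("annotation table needs gene_id, family_id, class_label columns")
  common <- intersect(names(seqs), anno$gene_id)
  if (length(common) == 0L)
    stop("no gene is present in both the FASTA and the annotation table")
  dropped <- setdiff(names(seqs), common)
  if (length(dropped)) {
    logStage("dropping %d unannotated gene(s): %s", length(dropped),
             paste(head(dropped, 10), collapse = ", "))
  }
  seqs <- seqs[common]
  anno <- anno[match(common, anno$gene_id), , drop = FALSE]
  gs <- geneSet(seqs, anno)
  logStage("read %d annotated genes in %d families", length(common),
           length(unique(anno$family_id)))
  gs
}
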