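#' @include design.R
NULL

#' Assembled amiRNA library
#'
#' One row per library member: the selected candidate, its star strand,
#' precursor (backbone with both arms inserted) and full oligo
#' (class adaptors + precursor), plus design provenance. Column order of
#' \code{entries} is fixed: amirna_id, family_id, class_label, mature,
#' mature_rna, star, origin_node, phase, rank, n_targets, target_genes,
#' target_fractions, score, off_target_count, precursor, fwd_adaptor,
#' rev_adaptor, oligo.
#'
#' @slot entries data.frame of library members
#' @slot config the \code{DesignConfig} the library was built under
#' @slot skipped_nodes named list of node-phase-skipped node IDs per family
#' @exportClass AmiRLibrary
setClass("AmiRLibrary", representation(entries = "data.frame",
                                       config = "DesignConfig",
                                       skipped_nodes = "list"))

setValidity("AmiRLibrary", function(object) {
  e <- object@entries
  if (nrow(e) == 0L) return(TRUE)
  msg <- character(0)
  if (anyDuplicated(e$amirna_id)) msg <- c(msg, "amirna_id must be unique")
  if (!all(e$class_label %in% CLASS_VOCAB))
    msg <- c(msg, "class labels outside the 8-class vocabulary")
  one <- mapply(function(o, m)
    length(gregexpr(m, o, fixed = TRUE)[[1]]) == 1L &&
      gregexpr(m, o, fixed = TRUE)[[1]][1] != -1L, e$oligo, e$mature)
  if (!all(one))
    msg <- c(msg, "every oligo must contain its mature exactly once")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AmiRLibrary", function(object) {
  e <- object@entries
  cat(sprintf("AmiRLibrary: %d amiRNAs, %d families, %d target genes\n",
              nrow(e), length(unique(e$family_id)),
              length(unique(unlist(strsplit(e$target_genes, ";"))))))
  if (nrow(e)) {
    tab <- table(e$class_label)
    cat("  per class:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
})

#' @describeIn assembleLibrary entries data.frame of a library
#' @param x an \code{AmiRLibrary}
#' @export
libraryEntries <- function(x) x@entries

#' Star (sense/passenger) strand of a mature guide
#'
#' By default the plain 21-nt reverse complement; positions listed in
#' \code{mismatch_positions} (1-based on the star) are substituted by their
#' complement base, emulating backbone-specified star mismatches. Pure
#' function; with no substitutions it is an involution.
#'
#' @param mature 21-nt guide (DNA)
#' @param mismatch_positions integer positions to substitute (default none)
#' @return 21-nt star sequence
#' @export
makeStar <- function(mature, mismatch_positions = integer(0)) {
  assertDna(mature, "mature")
  star <- revcompDna(mature)
  for (p in mismatch_positions) {
    substr(star, p, p) <- chartr("ACGT", "TGCA", substr(star, p, p))
  }
  star
}

#' Insert mature and star arms into the backbone template
#'
#' @param mature,star 21-nt arm sequences
#' @param backbone_template template containing exactly one \code{{MATURE}}
#'   and one \code{{STAR}} placeholder
#' @return precursor DNA string
#' @export
assemblePrecursor <- function(mature, star,
                              backbone_template = defaultBackboneTemplate()) {
  for (ph in c("\\{MATURE\\}", "\\{STAR\\}")) {
    n <- lengths(regmatches(backbone_template,
                            gregexpr(ph, backbone_template)))
    if (n != 1L)
      stop(sprintf("backbone template must contain exactly one %s placeholder",
                   gsub("\\\\", "", ph)))
  }
  out <- sub("{MATURE}", mature, backbone_template, fixed = TRUE)
  sub("{STAR}", star, out, fixed = TRUE)
}

#' Attach class-specific adaptors to a precursor
#'
#' @param precursor precursor DNA string
#' @param class_label one of the 8 functional classes
#' @param adaptor_table data.frame(class_label, fwd, rev); validated so that
#'   no adaptor is a substring of another class's adaptor or of the backbone
#' @param backbone_template used only for the load-time uniqueness check
#' @return full oligo: fwd adaptor + precursor + rev adaptor
#' @export
attachAdaptors <- function(precursor, class_label,
                           adaptor_table = defaultAdaptorTable(),
                           backbone_template = defaultBackboneTemplate()) {
  validateAdaptors(adaptor_table, backbone_template)
  i <- match(class_label, adaptor_table$class_label)
  if (is.na(i)) stop("unknown class: ", class_label)
  paste0(adaptor_table$fwd[i], precursor, adaptor_table$rev[i])
}

#' Remove entries whose oligo contains a forbidden restriction motif
#'
#' The full concatenated oligo (adaptors + backbone + both arms) is scanned
#' in forward orientation; reverse complements are expected to be present
#' in the motif list already (the configuration adds them automatically).
#' Removals are logged with motif and position. The matures of removed
#' entries are attached as attribute \code{removed_matures}.
#'
#' @param entries library entry data.frame with an \code{oligo} column
#' @param forbidden_sites character vector of DNA motifs
#' @return the filtered data.frame
#' @export
filterRestrictionSites <- function(entries,
                                   forbidden_sites = c("GGTCTC", "GAGACC")) {
  if (nrow(entries) == 0L) return(entries)
  drop <- logical(nrow(entries))
  for (motif in forbidden_sites) {
    pos <- regexpr(motif, entries$oligo, fixed = TRUE)
    hit <- pos != -1L
    for (i in which(hit & !drop)) {
      logStage("entry %s removed: motif %s at oligo position %d",
               entries$amirna_id[i], motif, pos[i])
    }
    drop <- drop | hit
  }
  out <- entries[!drop, , drop = FALSE]
  attr(out, "removed_matures") <- entries$mature[drop]
  out
}

#' Assemble selected candidates into an oligo library
#'
#' Derives the star strand, inserts both arms into the backbone, attaches
#' the functional-class adaptors of each candidate's family, assigns
#' deterministic entry IDs (family, origin node, per-node rank), and
#' applies the restriction-site filter.
#'
#' @param selected candidate data.frame from \code{\link{designFamily}} or
#'   \code{\link{runDesign}} (columns mature, origin_node, phase, rank,
#'   family_id, targets, ...)
#' @param genes the \code{GeneSet} (for class labels)
#' @param config a \code{DesignConfig}
#' @return an \code{AmiRLibrary}
#' @export
assembleLibrary <- function(selected, genes, config = designConfig()) {
  if (is.null(selected) || nrow(selected) == 0L) {
    return(new("AmiRLibrary", entries = emptyEntries(), config = config,
               skipped_nodes = list()))
  }
  validateAdaptors(config@adaptor_table, config@backbone_template)
  cls <- classLabels(genes)
  fam_of <- familyIds(genes)
  ent <- lapply(seq_len(nrow(selected)), function(i) {
    row <- selected[i, , drop = FALSE]
    tg <- row$targets[[1]]
    fam_cls <- unique(cls[names(tg)])
    if (length(fam_cls) != 1L)
      stop("effective targets of one amiRNA span multiple classes")
    if (!all(fam_of[names(tg)] == row$family_id))
      stop("effective targets outside the candidate's family")
    star <- makeStar(row$mature, config@star_mismatch_positions)
    prec <- assemblePrecursor(row$mature, star, config@backbone_template)
    ai <- match(fam_cls, config@adaptor_table$class_label)
    if (is.na(ai)) stop("unknown class: ", fam_cls)
    oligo <- paste0(config@adaptor_table$fwd[ai], prec,
                    config@adaptor_table$rev[ai])
    data.frame(
      amirna_id = sprintf("%s_n%03d_r%02d", row$family_id, row$origin_node,
                          row$rank),
      family_id = row$family_id, class_label = fam_cls,
      mature = row$mature, mature_rna = dnaToRna(row$mature), star = star,
      origin_node = row$origin_node, phase = row$phase, rank = row$rank,
      n_targets = row$n_targets,
      target_genes = paste(names(tg), collapse = ";"),
      target_fractions = paste(sprintf("%.10g", tg), collapse = ";"),
      score = row$score, off_target_count = row$off_target_count,
      precursor = prec, fwd_adaptor = config@adaptor_table$fwd[ai],
      rev_adaptor = config@adaptor_table$rev[ai], oligo = oligo,
      stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, ent)
  n0 <- nrow(entries)
  entries <- filterRestrictionSites(entries, config@forbidden_sites)
  logStage("assembly: %d entries, %d removed by restriction-site filter",
           n0, n0 - nrow(entries))
  removed <- attr(entries, "removed_matures")
  rownames(entries) <- NULL
  attr(entries, "removed_matures") <- removed
  new("AmiRLibrary", entries = entries, config = config,
      skipped_nodes = list())
}

emptyEntries <- function() {
  data.frame(amirna_id = character(0), family_id = character(0),
             class_label = character(0), mature = character(0),
             mature_rna = character(0), star = character(0),
             origin_node = integer(0), phase = character(0),
             rank = integer(0), n_targets = integer(0),
             target_genes = character(0), target_fractions = character(0),
             score = numeric(0), off_target_count = integer(0),
             precursor = character(0), fwd_adaptor = character(0),
             rev_adaptor = character(0), oligo = character(0),
             stringsAsFactors = FALSE)
}

libraryColumns <- function() names(emptyEntries())

#' Write a library to TSV + oligo FASTA
#'
#' Writes \code{<out_prefix>.tsv} (fixed, documented column order; see
#' \code{\linkS4class{AmiRLibrary}}) and \code{<out_prefix>_oligos.fasta}.
#'
#' @param library an \code{AmiRLibrary} or its entries data.frame
#' @param out_prefix output path prefix
#' @return invisibly, the two file paths
#' @export
writeLibrary <- function(library, out_prefix) {
  entries <- if (is(library, "AmiRLibrary")) library@entries else library
  if (nrow(entries) == 0L) stop("refusing to write an empty library")
  tsv <- paste0(out_prefix, ".tsv")
  fa <- paste0(out_prefix, "_oligos.fasta")
  write.table(entries[, libraryColumns()], tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  oligos <- Biostrings::DNAStringSet(setNames(entries$oligo,
                                              entries$amirna_id))
  Biostrings::writeXStringSet(oligos, fa)
  invisible(c(tsv = tsv, fasta = fa))
}

#' Read a library table written by \code{\link{writeLibrary}}
#'
#' @param tsv_path path to the library TSV
#' @return entries data.frame (lossless round-trip of all fields)
#' @export
readLibraryTable <- function(tsv_path) {
  e <- read.delim(tsv_path, stringsAsFactors = FALSE,
                  colClasses = setNames(
                    c("character", "character", "character", "character",
                      "character", "character", "integer", "character",
                      "integer", "integer", "character", "character",
                      "numeric", "integer", "character", "character",
                      "character", "character"),
                    libraryColumns()))
  e
}

#' Export the guide-to-gene bipartite network
#'
#' SIF-compatible TSV: one row \code{amirna_id TAB targets TAB gene_id} per
#' (amiRNA, effective target) pair.
#'
#' @param library an \code{AmiRLibrary} or entries data.frame
#' @param out_path output file path
#' @return invisibly, the edge data.frame
#' @export
exportNetwork <- function(library, out_path) {
  entries <- if (is(library, "AmiRLibrary")) library@entries else library
  if (nrow(entries) == 0L) stop("empty library")
  tg <- strsplit(entries$target_genes, ";", fixed = TRUE)
  edges <- data.frame(amirna_id = rep(entries$amirna_id, lengths(tg)),
                      interaction = "targets",
                      gene_id = unlist(tg), stringsAsFactors = FALSE)
  write.table(edges, out_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(edges)
}
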