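#' Design configuration
#'
#' Holds every tunable parameter of the design pipeline. Defaults follow the
#' published study conditions: energy-fraction threshold \code{omega} = 0.75,
#' per-node budget \code{node_budget_x} = 8, minimum sequence difference
#' \code{min_diff_m} = 2 bases, node-phase subfamily size cap
#' \code{max_subfamily_n} = 11, monophyletic cluster distance cap
#' \code{cluster_dist_max} = 3 internal nodes, mature length 21 nt, and the
#' BsaI recognition site (GGTCTC) plus its reverse complement as forbidden
#' motifs. \code{max_targets} = 8 caps the number of effective targets per
#' amiRNA (the upper end of the two-to-eight targets design cut-off).
#'
#' @slot omega numeric in (0,1]; minimum energy fraction for an effective target
#' @slot node_budget_x integer >= 1; max amiRNAs ascribed to one internal node
#' @slot min_diff_m integer >= 1; minimum Hamming distance to lineage picks
#' @slot max_subfamily_n integer >= 1; node-phase subfamily size cap
#' @slot cluster_dist_max integer >= 0; max pairwise monophyletic-cluster distance
#' @slot mature_length integer; guide length in nt
#' @slot max_targets integer >= 2; cap on effective targets per amiRNA
#' @slot forbidden_sites character; DNA motifs purged from assembled oligos
#'   (reverse complements added automatically)
#' @slot blacklist_path optional path to a file of banned 21-mers
#' @slot backbone_template character; precursor template containing
#'   \code{{MATURE}} and \code{{STAR}} placeholders
#' @slot adaptor_table data.frame with columns class_label, fwd, rev
#' @slot star_mismatch_positions integer; mature positions substituted in the
#'   star strand (empty = plain reverse complement)
#' @slot score_weights named numeric (frac, off, comp)
#' @slot admissibility named list of mismatch-pattern rule parameters
#' @slot gc_range numeric length-2; admissible mature GC fraction
#' @slot max_homopolymer integer; matures with a run this long are excluded
#' @slot mismatch_penalty,gu_penalty,init_energy numeric; duplex model overrides
#' @slot rule_b logical; allow similar-but-better admissions (rule b)
#' @slot replace_similar logical; rule (b) replaces the similar picks instead
#'   of adding alongside them
#' @slot unique_matures logical; enforce global mature uniqueness
#' @slot backfill logical; re-open selection after restriction-site removals
#' @slot rng_seed integer; seed recorded for provenance
#' @exportClass DesignConfig
setClass("DesignConfig", representation(
  omega = "numeric",
  node_budget_x = "integer",
  min_diff_m = "integer",
  max_subfamily_n = "integer",
  cluster_dist_max = "integer",
  mature_length = "integer",
  max_targets = "integer",
  forbidden_sites = "character",
  blacklist_path = "character",
  backbone_template = "character",
  adaptor_table = "data.frame",
  star_mismatch_positions = "integer",
  score_weights = "numeric",
  admissibility = "list",
  gc_range = "numeric",
  max_homopolymer = "integer",
  mismatch_penalty = "numeric",
  gu_penalty = "numeric",
  init_energy = "numeric",
  rule_b = "logical",
  replace_similar = "logical",
  unique_matures = "logical",
  backfill = "logical",
  rng_seed = "integer"
))

setValidity("DesignConfig", function(object) {
  msg <- character(0)
  if (!(object@omega > 0 && object@omega <= 1))
    msg <- c(msg, "omega must be in (0, 1]")
  for (s in c("node_budget_x", "min_diff_m", "max_subfamily_n",
              "mature_length")) {
    if (slot(object, s) < 1L) msg <- c(msg, paste(s, "must be >= 1"))
  }
  if (object@cluster_dist_max < 0L)
    msg <- c(msg, "cluster_dist_max must be >= 0")
  if (object@max_targets < 2L) msg <- c(msg, "max_targets must be >= 2")
  if (any(grepl("[^ACGT]", object@forbidden_sites)))
    msg <- c(msg, "forbidden_sites must be DNA motifs over {A,C,G,T}")
  if (length(object@gc_range) != 2L || object@gc_range[1] > object@gc_range[2])
    msg <- c(msg, "gc_range must be an increasing length-2 numeric")
  need <- c("frac", "off", "comp")
  if (!all(need %in% names(object@score_weights)))
    msg <- c(msg, "score_weights must name frac, off and comp")
  at <- object@adaptor_table
  if (nrow(at)) {
    if (!all(c("class_label", "fwd", "rev") %in% names(at)))
      msg <- c(msg, "adaptor_table needs class_label, fwd, rev columns")
    else {
      if (!all(at$class_label %in% CLASS_VOCAB))
        msg <- c(msg, "adaptor_table class labels outside the 8-class vocabulary")
      err <- tryCatch({
        validateAdaptors(at, object@backbone_template)
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(err)) msg <- c(msg, err)
    }
  }
  if (length(msg)) msg else TRUE
})

# no adaptor may be a substring of another class's adaptor or of the backbone
validateAdaptors <- function(tab, backbone_template = "") {
  seqs <- c(tab$fwd, tab$rev)
  assertDna(seqs, "adaptor")
  who <- c(paste0(tab$class_label, ":fwd"), paste0(tab$class_label, ":rev"))
  bb <- gsub("\\{MATURE\\}|\\{STAR\\}", " ", backbone_template)
  for (i in seq_along(seqs)) {
    others <- seqs[-i]
    hit <- vapply(others, function(o) grepl(seqs[i], o, fixed = TRUE),
                  logical(1))
    if (any(hit)) {
      stop(sprintf("adaptor %s is a substring of %s", who[i],
                   who[-i][which(hit)[1]]))
    }
    if (grepl(seqs[i], bb, fixed = TRUE))
      stop(sprintf("adaptor %s is a substring of the backbone", who[i]))
  }
  invisible(tab)
}

defaultBackboneTemplate <- function() {
  # synthetic stand-in for the miR159a precursor scaffold (the true arm
  # positions and loop live in vendor/supplementary data); placeholders mark
  # where the antisense (mature) and sense (star) arms are inserted
  paste0("GGATGCAGAGGAGCTTACTTGTTCA{MATURE}",
         "TCTCTCTTTTGTATTCCAATTTTCT{STAR}ATGATGATCACATTCGTTATCTATT")
}

defaultAdaptorTable <- function() {
  path <- system.file("extdata", "adaptors.tsv", package = "phyloAmiR")
  read.delim(path, stringsAsFactors = FALSE)
}

defaultAdmissibilityRules <- function() {
  list(seed_lo = 2L, seed_hi = 9L, seed_max_mm = 1L,
       central_lo = 10L, central_hi = 11L,
       tail_lo = 12L, tail_hi = 21L, tail_max_mm = 3L,
       total_max = 4L, gu_weight = 0.5)
}

addReverseComplements <- function(motifs) {
  rc <- revcompDna(motifs)
  unique(c(motifs, rc))
}

#' Build a design configuration
#'
#' @param omega energy-fraction threshold in (0,1]
#' @param node_budget_x max amiRNAs per internal node
#' @param min_diff_m minimum Hamming distance (bases) to lineage-chosen guides
#' @param max_subfamily_n node-phase subfamily size cap
#' @param cluster_dist_max max distance (internal nodes) between monophyletic
#'   clusters of an MRCA-phase candidate's targets
#' @param mature_length guide length (nt)
#' @param max_targets cap on effective targets per amiRNA
#' @param forbidden_sites DNA motifs screened out of assembled oligos; reverse
#'   complements are appended automatically
#' @param blacklist_path optional path to a file of banned matures (one per line)
#' @param backbone_template precursor template with \code{{MATURE}}/\code{{STAR}}
#' @param adaptor_table data.frame(class_label, fwd, rev); defaults to the
#'   packaged 8-class table
#' @param star_mismatch_positions mature positions substituted when deriving
#'   the star strand (default none: plain reverse complement)
#' @param score_weights named numeric weights (frac, off, comp)
#' @param admissibility mismatch-pattern rule parameters (see
#'   \code{\link{admissibleHybrid}})
#' @param gc_range admissible GC fraction range for matures
#' @param max_homopolymer matures carrying a homopolymer run of at least this
#'   length are excluded
#' @param mismatch_penalty,gu_penalty,init_energy duplex-model energy terms
#'   (kcal/mol)
#' @param rule_b enable the similar-but-better admission rule
#' @param replace_similar rule (b) replaces similar lineage picks rather than
#'   adding alongside them
#' @param unique_matures enforce a single occurrence of each mature across the
#'   whole library
#' @param backfill re-open selection for nodes whose entries were removed by
#'   the restriction-site filter
#' @param rng_seed integer seed recorded with the run
#' @return a validated \code{DesignConfig}
#' @export
designConfig <- function(omega = 0.75,
                         node_budget_x = 8L,
                         min_diff_m = 2L,
                         max_subfamily_n = 11L,
                         cluster_dist_max = 3L,
                         mature_length = 21L,
                         max_targets = 8L,
                         forbidden_sites = c("GGTCTC", "GAGACC"),
                         blacklist_path = character(0),
                         backbone_template = defaultBackboneTemplate(),
                         adaptor_table = defaultAdaptorTable(),
                         star_mismatch_positions = integer(0),
                         score_weights = c(frac = 1, off = 1, comp = 1),
                         admissibility = defaultAdmissibilityRules(),
                         gc_range = c(0.3, 0.7),
                         max_homopolymer = 6L,
                         mismatch_penalty = 0.25,
                         gu_penalty = 0.10,
                         init_energy = NA_real_,
                         rule_b = TRUE,
                         replace_similar = FALSE,
                         unique_matures = TRUE,
                         backfill = FALSE,
                         rng_seed = 1L) {
  new("DesignConfig",
      omega = as.numeric(omega),
      node_budget_x = as.integer(node_budget_x),
      min_diff_m = as.integer(min_diff_m),
      max_subfamily_n = as.integer(max_subfamily_n),
      cluster_dist_max = as.integer(cluster_dist_max),
      mature_length = as.integer(mature_length),
      max_targets = as.integer(max_targets),
      forbidden_sites = addReverseComplements(toupper(forbidden_sites)),
      blacklist_path = as.character(blacklist_path),
      backbone_template = backbone_template,
      adaptor_table = adaptor_table,
      star_mismatch_positions = as.integer(star_mismatch_positions),
      score_weights = score_weights,
      admissibility = admissibility,
      gc_range = as.numeric(gc_range),
      max_homopolymer = as.integer(max_homopolymer),
      mismatch_penalty = as.numeric(mismatch_penalty),
      gu_penalty = as.numeric(gu_penalty),
      init_energy = as.numeric(init_energy),
      rule_b = isTRUE(rule_b),
      replace_similar = isTRUE(replace_similar),
      unique_matures = isTRUE(unique_matures),
      backfill = isTRUE(backfill),
      rng_seed = as.integer(rng_seed))
}

#' Read a design configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{designConfig}}; unspecified keys
#' keep their defaults. \code{adaptor_table} may be given as a path to a TSV.
#'
#' @param path YAML file path
#' @return a \code{DesignConfig}
#' @export
readDesignConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$adaptor_table) && is.character(vals$adaptor_table)) {
    vals$adaptor_table <- read.delim(vals$adaptor_table,
                                     stringsAsFactors = FALSE)
  }
  if (!is.null(vals$score_weights)) {
    vals$score_weights <- unlist(vals$score_weights)
  }
  do.call(designConfig, vals)
}

setMethod("show", "DesignConfig", function(object) {
  cat("DesignConfig\n")
  cat(sprintf("  omega: %.3g  node budget x: %d  min diff m: %d\n",
              object@omega, object@node_budget_x, object@min_diff_m))
  cat(sprintf("  subfamily cap n: %d  cluster dist max: %d  max targets: %d\n",
              object@max_subfamily_n, object@cluster_dist_max,
              object@max_targets))
  cat(sprintf("  mature length: %d nt  forbidden sites: %s\n",
              object@mature_length,
              paste(object@forbidden_sites, collapse = ", ")))
  cat(sprintf("  rule b: %s  unique matures: %s  backfill: %s\n",
              object@rule_b, object@unique_matures, object@backfill))
})
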