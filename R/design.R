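#' @include config.R FamilyTree.R GeneSet.R thermo.R
NULL

#' Selection state: amiRNAs chosen per internal node
#'
#' @slot chosen named list (by node stable ID) of candidate data.frames in
#'   admission order; no node ever holds more than the per-node budget
#' @exportClass SelectionState
setClass("SelectionState", representation(chosen = "list"))

setMethod("show", "SelectionState", function(object) {
  n <- sum(vapply(object@chosen, nrow, integer(1)))
  cat(sprintf("SelectionState: %d amiRNAs across %d internal nodes\n",
              n, sum(vapply(object@chosen, nrow, integer(1)) > 0)))
})

#' @describeIn selectNodePhase all candidates chosen at a node or any of its
#'   ancestors
#' @param state a \code{SelectionState}
#' @export
lineageChosen <- function(state, tree, node) {
  ids <- c(node, ancestorNodes(tree, node))
  dfs <- state@chosen[as.character(ids)]
  dfs <- dfs[!vapply(dfs, is.null, logical(1))]
  if (length(dfs) == 0L) return(emptyCandidates())
  do.call(rbind, dfs)
}

ancestorNodes <- function(tree, node) {
  out <- integer(0)
  p <- tree@parentId[node]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree@parentId[p]
  }
  out
}

preorderNodes <- function(tree) {
  kids <- split(seq_along(tree@parentId), tree@parentId)
  out <- integer(0)
  visit <- function(v) {
    out <<- c(out, v)
    for (ch in sort(kids[[as.character(v)]])) visit(ch)
  }
  visit(rootNode(tree))
  out
}

emptyCandidates <- function() {
  data.frame(mature = character(0), origin_node = integer(0),
              phase = character(0), n_targets = integer(0),
              score = numeric(0), off_target_count = integer(0),
              targets = I(list()), stringsAsFactors = FALSE)
}

# mature derivation: reverse complement of a sense-strand window, then the
# 5'-terminal base forced to T (the canonical 5'U of plant miRNAs); when the
# window does not already end in A this is an engineered mismatch at
# position 1.
matureFromWindow <- function(windows) {
  m <- revcompDna(windows)
  substr(m, 1L, 1L) <- "T"
  m
}

# every mature derivable from any CDS window of the family, deduplicated,
# with the set of genes whose windows produced it
familyMaturePool <- function(cds, mature_length) {
  per_gene <- lapply(cds, function(s) {
    n <- nchar(s) - mature_length + 1L
    if (n < 1L) return(character(0))
    matureFromWindow(substring(s, seq_len(n), seq_len(n) + mature_length - 1L))
  })
  all_m <- unlist(per_gene, use.names = FALSE)
  genes <- rep(names(cds), lengths(per_gene))
  origin <- split(genes, all_m)
  origin <- lapply(origin, unique)
  list(matures = names(origin), origin = origin)
}

compositionOk <- function(matures, config) {
  gc <- gcFraction(matures)
  gc >= config@gc_range[1] & gc <= config@gc_range[2] &
    maxHomopolymer(matures) < config@max_homopolymer
}

compositionPenalty <- function(matures) abs(gcFraction(matures) - 0.5)

# number of background transcripts with an admissible best site at or above
# omega; family members must not be part of the background
offTargetCounts <- function(matures, background, model, config) {
  if (is.null(background) || length(background) == 0L) {
    warning("no background transcriptome supplied: off-target screening skipped",
            call. = FALSE)
    return(integer(length(matures)))
  }
  if (is(background, "DNAStringSet")) {
    background <- setNames(as.character(background), names(background))
  }
  ht <- hybridTable(matures, background, model, config@admissibility)
  as.integer(rowSums(ht$admissible & ht$fraction >= config@omega))
}

# Precomputed per-family evaluation shared by both selection phases.
familyContext <- function(genes, tree, config, background = NULL,
                          model = NULL) {
  if (is.null(model)) model <- modelFromConfig(config)
  cds <- cdsSeqs(genes)
  pool <- familyMaturePool(cds, config@mature_length)
  ok <- compositionOk(pool$matures, config)
  matures <- pool$matures[ok]
  origin <- pool$origin[ok]
  off <- offTargetCounts(matures, background, model, config)
  keep <- off == 0L
  matures <- matures[keep]
  origin <- origin[keep]
  ht <- hybridTable(matures, cds, model, config@admissibility)
  list(genes = genes, tree = tree, model = model, cds = cds,
       matures = matures, origin = origin,
       fraction = ht$fraction, admissible = ht$admissible,
       comp_penalty = compositionPenalty(matures),
       off = off[keep])
}

candidateRows <- function(ctx, matures, target_genes_per_mature, node, phase,
                          config) {
  if (length(matures) == 0L) return(emptyCandidates())
  w <- config@score_weights
  mi <- match(matures, ctx$matures)
  fr_list <- lapply(seq_along(matures), function(i) {
    tg <- target_genes_per_mature[[i]]
    fr <- ctx$fraction[mi[i], tg]
    names(fr) <- tg
    fr
  })
  mean_fr <- vapply(fr_list, mean, numeric(1))
  score <- unname(w["frac"] * mean_fr - w["off"] * ctx$off[mi] -
                    w["comp"] * ctx$comp_penalty[mi])
  data.frame(mature = matures, origin_node = as.integer(node), phase = phase,
             n_targets = lengths(fr_list), score = score,
             off_target_count = ctx$off[mi], targets = I(fr_list),
             stringsAsFactors = FALSE)
}

nodeCandidatesFromCtx <- function(ctx, node, config) {
  sub <- subfamily(ctx$tree, node)
  if (length(sub) > config@max_subfamily_n) {
    logStage("node %d skipped: subfamily size %d exceeds cap %d", node,
             length(sub), config@max_subfamily_n)
    return(NULL)
  }
  if (length(sub) < 2L) return(emptyCandidates())
  from_sub <- vapply(ctx$origin, function(g) any(g %in% sub), logical(1))
  matures <- ctx$matures[from_sub]
  if (length(matures) == 0L) return(emptyCandidates())
  eff <- ctx$admissible[matures, sub, drop = FALSE] &
    ctx$fraction[matures, sub, drop = FALSE] >= config@omega
  tg <- lapply(seq_along(matures), function(i) sub[eff[i, ]])
  n <- lengths(tg)
  keep <- n >= 2L & n <= config@max_targets
  candidateRows(ctx, matures[keep], tg[keep], node, "node_phase", config)
}

#' Generate candidate amiRNAs for one internal node
#'
#' Candidates are derived from every 21-nt window of every subfamily
#' member's CDS: the window is reverse-complemented, the 5'-terminal base is
#' forced to T (recorded implicitly as an engineered mismatch at position
#' 1), and duplicates are removed. Each candidate is evaluated by
#' \code{\link{bestSite}} against every family gene (effective targets are
#' the subfamily genes with an admissible hybrid at fraction >= omega) and
#' against every background transcript (any admissible background hit at or
#' above omega excludes the candidate). Candidates with GC fraction outside
#' the configured range, a homopolymer run at or above the cap, fewer than
#' two or more than \code{max_targets} effective targets are excluded.
#' Nodes whose subfamily exceeds \code{max_subfamily_n} are skipped with a
#' log entry (returns \code{NULL}).
#'
#' @param tree a \code{FamilyTree} for the family
#' @param genes a \code{GeneSet} restricted to the family
#' @param node internal node stable ID
#' @param config a \code{DesignConfig}
#' @param background optional DNAStringSet (or named character) of off-target
#'   transcripts
#' @return data.frame of candidates (mature, origin_node, phase, n_targets,
#'   score, off_target_count, targets), or \code{NULL} when skipped
#' @export
generateCandidates <- function(tree, genes, node, config = designConfig(),
                               background = NULL) {
  node <- checkNode(tree, node)
  ctx <- familyContext(genes, tree, config, background)
  nodeCandidatesFromCtx(ctx, node, config)
}

#' Score candidates
#'
#' score = w_frac * mean(effective fractions) - w_off * off_target_count -
#' w_comp * |GC - 0.5|; higher is better. Weights come from
#' \code{config@score_weights}.
#'
#' @param candidates candidate data.frame
#' @param config a \code{DesignConfig}
#' @return numeric vector of scores
#' @export
scoreCandidates <- function(candidates, config = designConfig()) {
  w <- config@score_weights
  mean_fr <- vapply(candidates$targets, mean, numeric(1))
  unname(w["frac"] * mean_fr - w["off"] * candidates$off_target_count -
           w["comp"] * compositionPenalty(candidates$mature))
}

#' Rank candidates
#'
#' Primary key: number of effective targets, descending. Secondary: score,
#' descending. Final tie-break: mature sequence, lexicographically
#' ascending, so the ordering is fully deterministic.
#'
#' @param candidates candidate data.frame
#' @return the data.frame reordered
#' @export
rankCandidates <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  ord <- order(-candidates$n_targets, -candidates$score, candidates$mature,
               method = "radix")
  candidates[ord, , drop = FALSE]
}

# oligo constructor for one family's class: mature -> full oligo under the
# configured backbone and adaptors
oligoBuilder <- function(config, class_label) {
  validateAdaptors(config@adaptor_table, config@backbone_template)
  i <- match(class_label, config@adaptor_table$class_label)
  if (is.na(i)) stop("unknown class: ", class_label)
  fwd <- config@adaptor_table$fwd[i]
  rev_ <- config@adaptor_table$rev[i]
  template <- config@backbone_template
  star_pos <- config@star_mismatch_positions
  function(m) {
    paste0(fwd, assemblePrecursor(m, makeStar(m, star_pos), template), rev_)
  }
}

# library-identifiability clash: the candidate's 21-mer (either orientation)
# occurs in an already-chosen member's oligo, or a chosen 21-mer occurs in
# the candidate's oligo. Such members could not be told apart in amplicon
# sequencing.
identifiabilityClash <- function(m, oligo_c, stenv) {
  if (length(stenv$oligos)) {
    if (any(grepl(m, stenv$oligos, fixed = TRUE))) return(TRUE)
    if (any(grepl(revcompDna(m), stenv$oligos, fixed = TRUE))) return(TRUE)
  }
  for (mo in stenv$matures) {
    if (grepl(mo, oligo_c, fixed = TRUE)) return(TRUE)
    if (grepl(revcompDna(mo), oligo_c, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

# admission under the similarity rules; state is an environment with
# $chosen (named list), $global (character vector of all chosen matures),
# and optionally $builder/$oligos/$matures for the identifiability check
admitCandidates <- function(stenv, tree, node, cands, config) {
  x <- config@node_budget_x
  key <- as.character(node)
  count <- if (is.null(stenv$chosen[[key]])) 0L else nrow(stenv$chosen[[key]])
  if (count >= x || nrow(cands) == 0L) return(invisible(NULL))
  ranked <- rankCandidates(cands)
  for (i in seq_len(nrow(ranked))) {
    if (count >= x) break
    row <- ranked[i, , drop = FALSE]
    m <- row$mature
    if (config@unique_matures && m %in% stenv$global) next
    lin_ids <- c(node, ancestorNodes(tree, node))
    lin <- stenv$chosen[as.character(lin_ids)]
    lin <- lin[!vapply(lin, is.null, logical(1))]
    lin <- if (length(lin)) do.call(rbind, lin) else emptyCandidates()
    admit <- FALSE
    sim_idx <- integer(0)
    if (nrow(lin) == 0L) {
      admit <- TRUE
    } else {
      d <- vapply(lin$mature, function(y) hammingDist(m, y), integer(1))
      sim_idx <- which(d < config@min_diff_m)
      if (length(sim_idx) == 0L) {
        admit <- TRUE                                   # rule (a)
      } else if (config@rule_b &&
                 row$score > max(lin$score[sim_idx])) {
        admit <- TRUE                                   # rule (b)
        if (config@replace_similar) {
          drop_m <- lin$mature[sim_idx]
          for (k in names(stenv$chosen)) {
            df <- stenv$chosen[[k]]
            if (!is.null(df) && any(df$mature %in% drop_m)) {
              stenv$chosen[[k]] <- df[!df$mature %in% drop_m, , drop = FALSE]
            }
          }
          stenv$global <- setdiff(stenv$global, drop_m)
          stenv$matures <- setdiff(stenv$matures, drop_m)
          if (!is.null(names(stenv$oligos)))
            stenv$oligos <- stenv$oligos[!(names(stenv$oligos) %in% drop_m)]
          count <- if (is.null(stenv$chosen[[key]])) 0L else
            nrow(stenv$chosen[[key]])
        }
      }
    }
    if (admit && !is.null(stenv$builder)) {
      oligo_c <- stenv$builder(m)
      if (identifiabilityClash(m, oligo_c, stenv)) {
        admit <- FALSE
      } else if (admit) {
        stenv$oligos <- c(stenv$oligos, setNames(oligo_c, m))
        stenv$matures <- c(stenv$matures, m)
      }
    }
    if (admit) {
      stenv$chosen[[key]] <- rbind(stenv$chosen[[key]], row)
      stenv$global <- c(stenv$global, m)
      count <- count + 1L
    }
  }
  invisible(NULL)
}

newStateEnv <- function(exclude = character(0), builder = NULL,
                        exclude_oligos = character(0)) {
  e <- new.env(parent = emptyenv())
  e$chosen <- list()
  e$global <- exclude
  e$builder <- builder
  e$oligos <- exclude_oligos
  e$matures <- character(0)
  e
}

stateFromEnv <- function(e) new("SelectionState", chosen = e$chosen)

envFromState <- function(state, exclude = character(0), builder = NULL,
                         exclude_oligos = character(0)) {
  e <- newStateEnv(exclude, builder, exclude_oligos)
  e$chosen <- state@chosen
  e$matures <- unique(unlist(lapply(state@chosen, function(d) d$mature)))
  if (is.null(e$matures)) e$matures <- character(0)
  e$global <- unique(c(exclude, e$matures))
  if (!is.null(builder) && length(e$matures))
    e$oligos <- c(exclude_oligos, vapply(e$matures, builder, character(1)))
  e
}

#' Top-down node-phase selection
#'
#' Internal nodes are visited root to leaves (pre-order, children in stable
#' node-ID order). At each node, its ranked candidates are admitted while
#' fewer than \code{node_budget_x} amiRNAs are ascribed to it. A candidate
#' is admitted iff (a) its mature differs by at least \code{min_diff_m}
#' substitutions from every candidate already chosen at this node or any of
#' its ancestors, or (b) rule (a) fails but its score strictly exceeds the
#' scores of all such similar lineage picks (rule (b) can be disabled via
#' \code{config@rule_b}; \code{config@replace_similar} makes it replace the
#' similar picks instead of adding alongside them).
#'
#' @param tree a \code{FamilyTree}
#' @param candidates_by_node named list (by node stable ID) of candidate
#'   data.frames, e.g. from \code{\link{generateCandidates}}
#' In addition to the similarity rules, when an \code{oligo_builder} is
#' supplied (as the design drivers do) a candidate is rejected if its mature
#' 21-mer, in either orientation, would occur inside an already-chosen
#' member's assembled oligo, or an already-chosen mature inside the
#' candidate's oligo: such members could not be distinguished by their
#' identifying 21-mer in amplicon sequencing.
#'
#' @param config a \code{DesignConfig}
#' @param exclude matures that may not be chosen (already used elsewhere)
#' @param oligo_builder optional function mature -> assembled oligo enabling
#'   the library-identifiability check (see Details)
#' @param exclude_oligos oligos of members already chosen elsewhere
#' @return a \code{SelectionState}
#' @export
selectNodePhase <- function(tree, candidates_by_node,
                            config = designConfig(),
                            exclude = character(0),
                            oligo_builder = NULL,
                            exclude_oligos = character(0)) {
  e <- newStateEnv(exclude, oligo_builder, exclude_oligos)
  for (node in preorderNodes(tree)) {
    cands <- candidates_by_node[[as.character(node)]]
    if (is.null(cands) || nrow(cands) == 0L) next
    admitCandidates(e, tree, node, cands, config)
  }
  stateFromEnv(e)
}

mrcaCandidatesFromCtx <- function(ctx, config) {
  tree <- ctx$tree
  fam <- colnames(ctx$fraction)
  eff <- ctx$admissible & ctx$fraction >= config@omega
  tg <- lapply(seq_along(ctx$matures), function(i) fam[eff[i, ]])
  n <- lengths(tg)
  keep <- which(n >= 2L & n <= config@max_targets)
  if (length(keep) == 0L) return(list())
  nodes <- vapply(keep, function(i) mrcaNode(tree, tg[[i]]), integer(1))
  ok <- vapply(seq_along(keep), function(k) {
    clusters <- monophyleticPartition(tree, tg[[keep[k]]])
    if (length(clusters) < 2L) return(TRUE)
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in seq(a + 1L, length(clusters))) {
        if (clusterDistance(tree, clusters[[a]], clusters[[b]]) >
            config@cluster_dist_max) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  keep <- keep[ok]
  nodes <- nodes[ok]
  by_node <- split(keep, nodes)
  lapply(by_node, function(idx) {
    candidateRows(ctx, ctx$matures[idx], tg[idx],
                  nodes[match(idx[1], keep)], "mrca_phase", config)
  })
}

#' MRCA-phase selection (fill under-budget nodes)
#'
#' Candidates are regenerated over the whole family (no subfamily
#' restriction, minimum two effective targets) and each is ascribed to the
#' MRCA of its effective targets. Only nodes still under the per-node
#' budget are considered. A candidate is eligible only if the monophyletic
#' clusters of its effective targets are pairwise within
#' \code{cluster_dist_max} internal nodes of each other; eligible candidates
#' are then ranked and admitted under the same similarity rules as the node
#' phase until each node holds \code{node_budget_x} amiRNAs.
#'
#' @param tree a \code{FamilyTree}
#' @param family_genes a \code{GeneSet} restricted to the family
#' @param background optional off-target transcripts
#' @param state \code{SelectionState} from \code{\link{selectNodePhase}}
#' @param config a \code{DesignConfig}
#' @param exclude matures that may not be chosen
#' @return the updated \code{SelectionState}
#' @export
selectMrcaPhase <- function(tree, family_genes, background = NULL,
                            state = new("SelectionState", chosen = list()),
                            config = designConfig(),
                            exclude = character(0),
                            oligo_builder = NULL,
                            exclude_oligos = character(0)) {
  ctx <- familyContext(family_genes, tree, config, background)
  selectMrcaPhaseCtx(ctx, state, config, exclude, oligo_builder,
                     exclude_oligos)
}

selectMrcaPhaseCtx <- function(ctx, state, config, exclude = character(0),
                               oligo_builder = NULL,
                               exclude_oligos = character(0)) {
  e <- envFromState(state, exclude, oligo_builder, exclude_oligos)
  by_node <- mrcaCandidatesFromCtx(ctx, config)
  for (node in preorderNodes(ctx$tree)) {
    key <- as.character(node)
    cands <- by_node[[key]]
    if (is.null(cands) || nrow(cands) == 0L) next
    count <- if (is.null(e$chosen[[key]])) 0L else nrow(e$chosen[[key]])
    if (count >= config@node_budget_x) next
    admitCandidates(e, ctx$tree, node, cands, config)
  }
  stateFromEnv(e)
}

#' Remove blacklisted matures
#'
#' Drops candidates whose mature exactly matches a blacklist entry; the
#' removal count is logged. Entries whose length differs from the mature
#' length are ignored with a warning.
#'
#' @param candidates candidate (or library-entry) data.frame with a
#'   \code{mature} column
#' @param blacklist character vector of banned matures, or a path to a file
#'   with one per line
#' @param mature_length expected entry length
#' @return the filtered data.frame
#' @export
applyBlacklist <- function(candidates, blacklist, mature_length = 21L) {
  if (is.null(blacklist) || length(blacklist) == 0L) return(candidates)
  if (length(blacklist) == 1L && file.exists(blacklist)) {
    blacklist <- readLines(blacklist)
  }
  blacklist <- toupper(trimws(blacklist))
  blacklist <- blacklist[nzchar(blacklist)]
  bad_len <- nchar(blacklist) != mature_length
  if (any(bad_len)) {
    warning(sprintf("%d blacklist entries of wrong length ignored",
                    sum(bad_len)), call. = FALSE)
    blacklist <- blacklist[!bad_len]
  }
  hit <- candidates$mature %in% blacklist
  logStage("blacklist removed %d of %d candidates", sum(hit), nrow(candidates))
  candidates[!hit, , drop = FALSE]
}

#' Design amiRNAs for one gene family
#'
#' Runs candidate generation and both selection phases for a single family,
#' then applies the blacklist. Returns the selected candidates with a
#' per-node admission rank, family metadata, and the node-phase-skipped
#' nodes (subfamily size above \code{max_subfamily_n}) as attribute
#' \code{skipped_nodes}.
#'
#' @param genes a \code{GeneSet} restricted to one family
#' @param tree the family's \code{FamilyTree}
#' @param config a \code{DesignConfig}
#' @param background optional off-target transcripts
#' @param blacklist optional banned matures (vector or path)
#' @param exclude matures that may not be chosen (used across families)
#' @param exclude_oligos oligos of members chosen in other families, for the
#'   cross-family identifiability check
#' @return data.frame of selected candidates
#' @export
designFamily <- function(genes, tree, config = designConfig(),
                         background = NULL, blacklist = NULL,
                         exclude = character(0),
                         exclude_oligos = character(0)) {
  fam <- unique(familyIds(genes))
  if (length(fam) != 1L) stop("designFamily expects genes of one family")
  cls <- unique(classLabels(genes))
  if (length(cls) != 1L) stop("a family must map to a single class")
  builder <- oligoBuilder(config, cls)
  ctx <- familyContext(genes, tree, config, background)
  skipped <- integer(0)
  by_node <- list()
  for (node in internalNodes(tree)) {
    sub_n <- length(subfamily(tree, node))
    if (sub_n > config@max_subfamily_n) {
      skipped <- c(skipped, node)
      next
    }
    cands <- nodeCandidatesFromCtx(ctx, node, config)
    if (!is.null(cands) && nrow(cands)) by_node[[as.character(node)]] <- cands
  }
  state <- selectNodePhase(tree, by_node, config, exclude, builder,
                           exclude_oligos)
  n_node_phase <- sum(vapply(state@chosen, nrow, integer(1)))
  state <- selectMrcaPhaseCtx(ctx, state, config, exclude, builder,
                              exclude_oligos)
  sel <- do.call(rbind, c(list(emptyCandidates()),
                          unname(state@chosen[order(as.integer(names(state@chosen)))])))
  if (nrow(sel)) {
    sel$rank <- unlist(lapply(state@chosen[order(as.integer(names(state@chosen)))],
                              function(d) seq_len(nrow(d))), use.names = FALSE)
    sel$family_id <- fam
  } else {
    sel$rank <- integer(0)
    sel$family_id <- character(0)
  }
  sel <- applyBlacklist(sel, blacklist %||%
                          (if (length(config@blacklist_path))
                            config@blacklist_path else NULL),
                        config@mature_length)
  rownames(sel) <- NULL
  logStage("family %s: %d node-phase + %d mrca-phase amiRNAs selected",
           fam, n_node_phase, nrow(sel) - min(n_node_phase, nrow(sel)))
  attr(sel, "skipped_nodes") <- skipped
  sel
}

#' Run the full design pipeline over all families
#'
#' Families are processed in sorted family-ID order; with
#' \code{unique_matures} every mature appears at most once across the whole
#' run. Selected candidates are assembled into backbone+adaptor oligos and
#' screened for forbidden restriction sites; with \code{config@backfill}
#' selection is re-opened for nodes whose entries were removed.
#'
#' @param genes a \code{GeneSet} covering one or more families
#' @param trees named list of \code{FamilyTree} objects, names = family IDs
#' @param config a \code{DesignConfig}
#' @param background optional off-target transcripts
#' @param blacklist optional banned matures (vector or path)
#' @return an \code{\link{AmiRLibrary}}
#' @export
runDesign <- function(genes, trees, config = designConfig(),
                      background = NULL, blacklist = NULL) {
  fams <- sort(unique(familyIds(genes)))
  missing_ <- setdiff(fams, names(trees))
  if (length(missing_))
    stop("no tree supplied for family: ", paste(missing_, collapse = ", "))
  exclude <- character(0)
  exclude_oligos <- character(0)
  selected <- list()
  skipped <- list()
  for (fam in fams) {
    gs <- familySubset(genes, fam)
    sel <- designFamily(gs, trees[[fam]], config, background, blacklist,
                        exclude, exclude_oligos)
    exclude <- c(exclude, sel$mature)
    if (nrow(sel)) {
      builder <- oligoBuilder(config, unique(classLabels(gs)))
      exclude_oligos <- c(exclude_oligos,
                          vapply(sel$mature, builder, character(1)))
    }
    selected[[fam]] <- sel
    skipped[[fam]] <- attr(sel, "skipped_nodes")
  }
  lib <- assembleLibrary(do.call(rbind, unname(selected)), genes, config)
  if (config@backfill) {
    lib <- backfillLibrary(lib, genes, trees, config, background, blacklist,
                           selected)
  }
  lib@skipped_nodes <- skipped
  lib
}

# one re-selection pass per family that lost entries to the restriction
# filter, excluding the removed matures
backfillLibrary <- function(lib, genes, trees, config, background, blacklist,
                            selected) {
  removed <- attr(lib@entries, "removed_matures") %||% character(0)
  if (length(removed) == 0L) return(lib)
  kept <- lib@entries$mature
  redo <- list()
  for (fam in names(selected)) {
    if (!any(removed %in% selected[[fam]]$mature)) {
      redo[[fam]] <- selected[[fam]]
      next
    }
    gs <- familySubset(genes, fam)
    exclude <- c(removed, setdiff(kept, selected[[fam]]$mature))
    redo[[fam]] <- designFamily(gs, trees[[fam]], config, background,
                                blacklist, exclude)
  }
  assembleLibrary(do.call(rbind, unname(redo)), genes, config)
}
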