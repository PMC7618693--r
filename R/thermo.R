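#' Nearest-neighbor duplex energy model
#'
#' A simplified guide:target RNA duplex model: stacking free energies for
#' the 16 Watson-Crick dinucleotide stacks (read 5'->3' along the guide, DNA
#' spelling with T for U), a duplex initiation term, and flat positive
#' penalties per internal mismatch and per G:U wobble. A stack contributes
#' only when both of its positions are Watson-Crick paired. The packaged
#' table carries published RNA/RNA nearest-neighbor values (37 degrees C,
#' kcal/mol); all terms are user-overridable.
#'
#' @slot stacks named numeric(16), stacking free energies (kcal/mol, < 0)
#' @slot mismatch_penalty numeric > 0 (kcal/mol) per internal mismatch
#' @slot gu_penalty numeric > 0, < mismatch_penalty, per G:U wobble
#' @slot init_energy numeric, duplex initiation term (kcal/mol)
#' @exportClass DuplexModel
setClass("DuplexModel", representation(stacks = "numeric",
                                       mismatch_penalty = "numeric",
                                       gu_penalty = "numeric",
                                       init_energy = "numeric"))

setValidity("DuplexModel", function(object) {
  msg <- character(0)
  keys <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          paste0))
  if (!setequal(names(object@stacks), keys))
    msg <- c(msg, "stacks must name all 16 dinucleotides")
  if (any(object@stacks >= 0))
    msg <- c(msg, "every Watson-Crick stack value must be negative")
  if (object@mismatch_penalty <= 0 || object@gu_penalty <= 0)
    msg <- c(msg, "penalties must be positive")
  if (object@gu_penalty >= object@mismatch_penalty)
    msg <- c(msg, "gu_penalty must be smaller than mismatch_penalty")
  if (length(msg)) msg else TRUE
})

#' Load the duplex energy model
#'
#' @param path TSV with columns \code{stack} and \code{dg}; rows for the 16
#'   dinucleotide stacks plus an \code{INIT} row. Defaults to the packaged
#'   table.
#' @param mismatch_penalty,gu_penalty flat penalties (kcal/mol); defaults
#'   make a single internal mismatch cost roughly 10\% of a typical
#'   perfect-match duplex energy, so an energy-fraction threshold of 0.75
#'   tolerates about two mismatches
#' @param init_energy override for the initiation term (default: INIT row)
#' @return a \code{DuplexModel}
#' @export
duplexModel <- function(path = NULL, mismatch_penalty = 0.25,
                        gu_penalty = 0.10, init_energy = NA_real_) {
  if (is.null(path))
    path <- system.file("extdata", "nn_stacks.tsv", package = "phyloAmiR")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  init <- tab$dg[tab$stack == "INIT"]
  tab <- tab[tab$stack != "INIT", , drop = FALSE]
  if (!is.na(init_energy)) init <- init_energy
  new("DuplexModel", stacks = setNames(tab$dg, tab$stack),
      mismatch_penalty = mismatch_penalty, gu_penalty = gu_penalty,
      init_energy = init)
}

# model derived from a DesignConfig (penalty/init overrides)
modelFromConfig <- function(config) {
  duplexModel(mismatch_penalty = config@mismatch_penalty,
              gu_penalty = config@gu_penalty,
              init_energy = config@init_energy)
}

# stacks in the fixed order the C++ kernel indexes (4*first + second,
# A=0 C=1 G=2 T=3)
stacksVector <- function(model) {
  keys <- as.vector(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0)))
  unname(model@stacks[keys])
}

rulesVector <- function(rules) {
  as.integer(c(rules$seed_lo, rules$seed_hi, rules$seed_max_mm,
               rules$central_lo, rules$central_hi,
               rules$tail_lo, rules$tail_hi, rules$tail_max_mm,
               rules$total_max))
}

#' Guide:site hybrid evaluation
#'
#' @slot delta_g duplex free energy (kcal/mol)
#' @slot delta_g_perfect free energy of the perfect-complement duplex
#' @slot fraction delta_g / delta_g_perfect, clipped to [0, 1]; exactly 1
#'   for a perfect reverse complement
#' @slot mismatch_positions integer, 1-based from the mature 5' end
#' @slot gu_positions integer, G:U wobble positions
#' @slot admissible logical, mismatch pattern passes the admissibility rules
#' @exportClass HybridEvaluation
setClass("HybridEvaluation", representation(delta_g = "numeric",
                                            delta_g_perfect = "numeric",
                                            fraction = "numeric",
                                            mismatch_positions = "integer",
                                            gu_positions = "integer",
                                            admissible = "logical"))

setMethod("show", "HybridEvaluation", function(object) {
  cat(sprintf(
    "HybridEvaluation: dG = %.2f kcal/mol (perfect %.2f), fraction = %.3f\n",
    object@delta_g, object@delta_g_perfect, object@fraction))
  cat(sprintf("  mismatches at [%s], G:U at [%s], admissible: %s\n",
              paste(object@mismatch_positions, collapse = ","),
              paste(object@gu_positions, collapse = ","),
              object@admissible))
})

checkDuplexArgs <- function(mature, site) {
  assertDna(mature, "mature")
  assertDna(site, "site")
  if (nchar(mature) != nchar(site))
    stop("mature and site must have equal length")
}

#' Duplex free energy of a guide against a sense-strand site
#'
#' The guide (mature) is antisense: its 5' end pairs with the 3' end of the
#' site. dG = initiation + stacking over consecutive Watson-Crick paired
#' positions + penalties per mismatch and G:U wobble. Pure function of the
#' two sequences and the model.
#'
#' @param model a \code{DuplexModel}
#' @param mature guide sequence (DNA spelling)
#' @param site equal-length sense-strand target site
#' @return free energy in kcal/mol
#' @export
duplexEnergy <- function(model, mature, site) {
  checkDuplexArgs(mature, site)
  r <- cpp_evaluate(mature, site, stacksVector(model),
                    model@mismatch_penalty, model@gu_penalty,
                    model@init_energy)
  r$dg
}

#' Energy fraction of a hybrid relative to the perfect match
#'
#' fraction = dG(mature, site) / dG(mature, revcomp(mature)), clipped to
#' [0, 1] (clip events are logged to stderr). Mismatch and G:U positions are
#' recorded 1-based from the mature 5' end, and the admissibility flag is
#' set from \code{rules}.
#'
#' @inheritParams duplexEnergy
#' @param rules admissibility rule parameters
#'   (\code{\link{admissibleHybrid}}); defaults to the standard rule block
#' @return a \code{HybridEvaluation}
#' @export
energyFraction <- function(model, mature, site,
                           rules = defaultAdmissibilityRules()) {
  checkDuplexArgs(mature, site)
  r <- cpp_evaluate(mature, site, stacksVector(model),
                    model@mismatch_penalty, model@gu_penalty,
                    model@init_energy)
  if (r$dg / r$dg_perfect < 0 || r$dg / r$dg_perfect > 1)
    logStage("energy fraction clipped for mature %s", mature)
  ev <- new("HybridEvaluation", delta_g = r$dg,
            delta_g_perfect = r$dg_perfect, fraction = r$fraction,
            mismatch_positions = as.integer(r$mm_pos),
            gu_positions = as.integer(r$gu_pos), admissible = NA)
  ev@admissible <- admissibleHybrid(ev, rules)
  ev
}

#' Mismatch-pattern admissibility of a hybrid
#'
#' A hybrid is admissible iff, with positions counted 1-based from the
#' mature 5' end: no mismatch or G:U wobble falls in the central cleavage
#' region (positions 10-11); at most one mismatch falls in the 5' pairing
#' region (positions 2-9); at most three mismatches fall in the 3' region
#' (positions 12-21); and the weighted mismatch total (a G:U counts 0.5,
#' summed and rounded up) is at most 4. All bounds live in \code{rules},
#' not in code.
#'
#' @param evaluation a \code{HybridEvaluation}
#' @param rules named list: seed_lo, seed_hi, seed_max_mm, central_lo,
#'   central_hi, tail_lo, tail_hi, tail_max_mm, total_max, gu_weight
#' @return logical
#' @export
admissibleHybrid <- function(evaluation, rules = defaultAdmissibilityRules()) {
  mm <- evaluation@mismatch_positions
  gu <- evaluation@gu_positions
  if (any(mm >= rules$central_lo & mm <= rules$central_hi)) return(FALSE)
  if (any(gu >= rules$central_lo & gu <= rules$central_hi)) return(FALSE)
  if (sum(mm >= rules$seed_lo & mm <= rules$seed_hi) > rules$seed_max_mm)
    return(FALSE)
  if (sum(mm >= rules$tail_lo & mm <= rules$tail_hi) > rules$tail_max_mm)
    return(FALSE)
  total <- ceiling(length(mm) + rules$gu_weight * length(gu) - 1e-9)
  total <= rules$total_max
}

#' Best target site of a guide on a transcript
#'
#' Evaluates every window of the sense strand (0-based half-open
#' coordinates, step 1) and returns the window with maximal energy
#' fraction; ties are broken by the smallest start coordinate.
#'
#' @inheritParams energyFraction
#' @param transcript sense-strand transcript sequence, length >=
#'   \code{nchar(mature)}
#' @return list with \code{evaluation} (a \code{HybridEvaluation}),
#'   \code{start} and \code{end} (0-based half-open window coordinates)
#' @export
bestSite <- function(model, mature, transcript,
                     rules = defaultAdmissibilityRules()) {
  assertDna(mature, "mature")
  assertDna(transcript, "transcript")
  if (nchar(transcript) < nchar(mature))
    stop("transcript shorter than the mature sequence")
  r <- cpp_best_site(mature, transcript, stacksVector(model),
                     model@mismatch_penalty, model@gu_penalty,
                     model@init_energy)
  ev <- new("HybridEvaluation", delta_g = r$dg,
            delta_g_perfect = r$dg_perfect, fraction = r$fraction,
            mismatch_positions = as.integer(r$mm_pos),
            gu_positions = as.integer(r$gu_pos), admissible = NA)
  ev@admissible <- admissibleHybrid(ev, rules)
  list(evaluation = ev, start = r$start, end = r$end)
}

# Batch scan: best-site fraction and admissibility of many matures against
# each transcript of a named character vector. Returns matrices
# [mature, transcript].
hybridTable <- function(matures, transcripts, model,
                        rules = defaultAdmissibilityRules()) {
  sv <- stacksVector(model)
  rv <- rulesVector(rules)
  M <- length(matures)
  frac <- matrix(0, M, length(transcripts),
                 dimnames = list(matures, names(transcripts)))
  adm <- matrix(FALSE, M, length(transcripts),
                dimnames = list(matures, names(transcripts)))
  for (g in seq_along(transcripts)) {
    r <- cpp_scan_table(matures, transcripts[[g]], sv,
                        model@mismatch_penalty, model@gu_penalty,
                        model@init_energy, rv, rules$gu_weight)
    frac[, g] <- r$fraction
    adm[, g] <- r$admissible
  }
  list(fraction = frac, admissible = adm)
}
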