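# Independent oracles used to cross-check the implementation. These
# deliberately avoid the package's internal code paths: energies are
# re-summed from the packaged table in plain R, tree quantities come from
# ape, and the selection oracle is a direct, exhaustive re-implementation
# of the published filtering steps.

oracleModelParams <- function() {
  tab <- read.delim(system.file("extdata", "nn_stacks.tsv",
                                package = "phyloAmiR"),
                    stringsAsFactors = FALSE)
  list(stacks = setNames(tab$dg[tab$stack != "INIT"],
                         tab$stack[tab$stack != "INIT"]),
       init = tab$dg[tab$stack == "INIT"],
       mm = 0.25, gu = 0.10)
}

COMP <- c(A = "T", C = "G", G = "C", T = "A")

# position-by-position re-summation of the duplex energy
oracleEnergy <- function(mature, site, par = oracleModelParams()) {
  m <- strsplit(mature, "")[[1]]
  s <- rev(strsplit(site, "")[[1]])  # s[k] faces mature position k
  L <- length(m)
  status <- integer(L)  # 2 WC, 1 GU, 0 mismatch
  for (k in seq_len(L)) {
    if (s[k] == COMP[m[k]]) status[k] <- 2L
    else if ((m[k] == "G" && s[k] == "T") || (m[k] == "T" && s[k] == "G"))
      status[k] <- 1L
  }
  dg <- par$init
  dgp <- par$init
  for (k in seq_len(L - 1)) {
    st <- par$stacks[paste0(m[k], m[k + 1])]
    dgp <- dgp + st
    if (status[k] == 2L && status[k + 1] == 2L) dg <- dg + st
  }
  dg <- dg + par$mm * sum(status == 0L) + par$gu * sum(status == 1L)
  frac <- min(1, max(0, dg / dgp))
  list(dg = unname(dg), dg_perfect = unname(dgp), fraction = unname(frac),
       mm_pos = which(status == 0L), gu_pos = which(status == 1L))
}

oracleAdmissible <- function(mm_pos, gu_pos) {
  if (any(mm_pos %in% 10:11) || any(gu_pos %in% 10:11)) return(FALSE)
  if (sum(mm_pos %in% 2:9) > 1) return(FALSE)
  if (sum(mm_pos %in% 12:21) > 3) return(FALSE)
  ceiling(length(mm_pos) + 0.5 * length(gu_pos) - 1e-9) <= 4
}

# exhaustive per-window scan
oracleBestSite <- function(mature, transcript, par = oracleModelParams()) {
  L <- nchar(mature)
  n <- nchar(transcript) - L + 1
  best <- NULL
  for (w in seq_len(n)) {
    ev <- oracleEnergy(mature, substr(transcript, w, w + L - 1), par)
    if (is.null(best) || ev$fraction > best$fraction) {
      best <- ev
      best$start <- w - 1L  # 0-based
    }
  }
  best
}

revcompChr <- function(x) {
  vapply(x, function(s)
    paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# all clade leaf-label sets of an ape tree (internal nodes via prop.part,
# plus singletons)
oracleClades <- function(phy) {
  pp <- ape::prop.part(phy)
  clades <- lapply(pp, function(idx) sort(phy$tip.label[idx]))
  c(clades, as.list(sort(phy$tip.label)))
}

# every partition of a set (Bell-number enumeration)
allSetPartitions <- function(items) {
  if (length(items) == 1L) return(list(list(items)))
  rest <- allSetPartitions(items[-1])
  out <- list()
  for (p in rest) {
    for (j in seq_along(p)) {
      q <- p
      q[[j]] <- c(items[1], q[[j]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(items[1]), p)
  }
  out
}

# minimum-size partition of targets into clade leaf sets, by brute force
oraclePartition <- function(phy, targets) {
  clades <- oracleClades(phy)
  is_clade <- function(block) any(vapply(clades, function(cl)
    setequal(cl, block), logical(1)))
  parts <- allSetPartitions(sort(targets))
  valid <- Filter(function(p) all(vapply(p, is_clade, logical(1))), parts)
  sizes <- vapply(valid, length, integer(1))
  best <- valid[sizes == min(sizes)]
  stopifnot(length(best) == 1L)  # the coarsest monophyletic partition is unique
  lapply(best[[1]], sort)
}

oracleLeafDistance <- function(phy, i, j) {
  if (i == j) return(0L)
  path <- ape::nodepath(phy, which(phy$tip.label == i),
                        which(phy$tip.label == j))
  length(path) - 2L
}

canonicalPartition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, min, character(1)))]
}

# random rooted binary tree with given labels, independent of the package's
# generator
randomOracleTree <- function(labels) {
  phy <- ape::rtree(length(labels), rooted = TRUE, br = NULL)
  phy$tip.label <- sample(labels)
  phy
}
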