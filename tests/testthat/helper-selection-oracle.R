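# Exhaustive, independent re-implementation of the published selection
# procedure (candidate generation, node-phase and MRCA-phase filtering) for
# tiny families. Tree quantities come from ape; energies from the plain-R
# oracle. Used to verify the package's selected sets end to end.

oracleDesign <- function(cds, phy, class_label,
                         adaptors = read.delim(
                           system.file("extdata", "adaptors.tsv",
                                       package = "phyloAmiR"),
                           stringsAsFactors = FALSE),
                         template = paste0(
                           "GGATGCAGAGGAGCTTACTTGTTCA{MATURE}",
                           "TCTCTCTTTTGTATTCCAATTTTCT{STAR}",
                           "ATGATGATCACATTCGTTATCTATT"),
                         omega = 0.75, x = 8, m_min = 2, max_sub = 11,
                         clust_max = 3, max_targets = 8, rule_b = TRUE,
                         par = oracleModelParams()) {
  genes <- names(cds)
  L <- 21L

  # candidate matures from every window of every gene, 5' base forced to T
  origin <- list()
  for (g in genes) {
    s <- cds[[g]]
    for (w in seq_len(nchar(s) - L + 1)) {
      mat <- revcompChr(substr(s, w, w + L - 1))
      substr(mat, 1, 1) <- "T"
      origin[[mat]] <- unique(c(origin[[mat]], g))
    }
  }
  matures <- names(origin)
  gc <- vapply(strsplit(matures, ""), function(ch)
    mean(ch %in% c("G", "C")), numeric(1))
  homop <- vapply(strsplit(matures, ""), function(ch)
    max(rle(ch)$lengths), numeric(1))
  keep <- gc >= 0.3 & gc <= 0.7 & homop < 6
  matures <- matures[keep]
  gc <- gc[keep]
  origin <- origin[matures]

  frac <- matrix(0, length(matures), length(genes),
                 dimnames = list(matures, genes))
  adm <- frac > 1
  for (i in seq_along(matures)) {
    for (g in genes) {
      b <- oracleBestSite(matures[i], cds[[g]], par)
      frac[i, g] <- b$fraction
      adm[i, g] <- oracleAdmissible(b$mm_pos, b$gu_pos)
    }
  }
  score_of <- function(i, eff) mean(frac[i, eff]) - abs(gc[i] - 0.5)

  # ape tree scaffolding: clades, parents, preorder with children ordered by
  # smallest leaf label (the stable-ID traversal order)
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  clade <- function(v) {
    if (v <= ntip) return(phy$tip.label[v])
    sort(unlist(lapply(kids[[as.character(v)]], clade)))
  }
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  ancestors <- function(v) {
    out <- integer(0)
    while (v != root) {
      v <- parent[v]
      out <- c(out, v)
    }
    out
  }
  pre <- integer(0)
  walk <- function(v) {
    if (v <= ntip) return(invisible(NULL))
    pre <<- c(pre, v)
    ch <- kids[[as.character(v)]]
    for (c2 in ch[order(vapply(ch, function(z) min(clade(z)), character(1)))])
      walk(c2)
    invisible(NULL)
  }
  walk(root)

  fwd <- adaptors$fwd[adaptors$class_label == class_label]
  rev_ <- adaptors$rev[adaptors$class_label == class_label]
  oligo_of <- function(mat) {
    prec <- sub("{STAR}", revcompChr(mat),
                sub("{MATURE}", mat, template, fixed = TRUE), fixed = TRUE)
    paste0(fwd, prec, rev_)
  }
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

  chosen <- list()     # ape node (char) -> data.frame(mature, score, ...)
  chosen_m <- character(0)
  chosen_o <- character(0)

  admit_at <- function(v, cand) {
    # cand: data.frame(mature, n, score, targets=I(list))
    cnt <- if (is.null(chosen[[as.character(v)]])) 0L else
      nrow(chosen[[as.character(v)]])
    ord <- order(-cand$n, -cand$score, cand$mature, method = "radix")
    cand <- cand[ord, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      if (cnt >= x) break
      mat <- cand$mature[i]
      if (mat %in% chosen_m) next
      lin <- do.call(rbind, chosen[as.character(c(v, ancestors(v)))])
      ok <- FALSE
      if (is.null(lin) || nrow(lin) == 0L) ok <- TRUE
      else {
        d <- vapply(lin$mature, function(y) ham(mat, y), numeric(1))
        sims <- which(d < m_min)
        if (length(sims) == 0L) ok <- TRUE
        else if (rule_b && cand$score[i] > max(lin$score[sims])) ok <- TRUE
      }
      if (ok) {
        ol <- oligo_of(mat)
        clash <- any(vapply(chosen_o, function(o)
          grepl(mat, o, fixed = TRUE) ||
            grepl(revcompChr(mat), o, fixed = TRUE), logical(1))) ||
          any(vapply(chosen_m, function(mo)
            grepl(mo, ol, fixed = TRUE) ||
              grepl(revcompChr(mo), ol, fixed = TRUE), logical(1)))
        if (clash) next
        chosen[[as.character(v)]] <<- rbind(
          chosen[[as.character(v)]],
          data.frame(mature = mat, n = cand$n[i], score = cand$score[i],
                     targets = I(cand$targets[i]), phase = cand$phase[i],
                     stringsAsFactors = FALSE))
        chosen_m <<- c(chosen_m, mat)
        chosen_o <<- c(chosen_o, ol)
        cnt <- cnt + 1L
      }
    }
  }

  # node phase
  for (v in pre) {
    sub <- clade(v)
    if (length(sub) > max_sub || length(sub) < 2L) next
    cand_m <- matures[vapply(origin, function(g) any(g %in% sub), logical(1))]
    if (length(cand_m) == 0L) next
    rows <- list()
    for (mat in cand_m) {
      eff <- sub[adm[mat, sub] & frac[mat, sub] >= omega]
      if (length(eff) < 2L || length(eff) > max_targets) next
      rows[[length(rows) + 1L]] <- data.frame(
        mature = mat, n = length(eff),
        score = score_of(match(mat, matures), eff),
        targets = I(list(sort(eff))), phase = "node_phase",
        stringsAsFactors = FALSE)
    }
    if (length(rows)) admit_at(v, do.call(rbind, rows))
  }

  # MRCA phase
  by_node <- list()
  for (mat in matures) {
    eff <- genes[adm[mat, genes] & frac[mat, genes] >= omega]
    if (length(eff) < 2L || length(eff) > max_targets) next
    clusters <- oraclePartition(phy, eff)
    ok <- TRUE
    if (length(clusters) > 1L) {
      for (a in seq_len(length(clusters) - 1L)) {
        for (b in seq(a + 1L, length(clusters))) {
          dmin <- min(outer(clusters[[a]], clusters[[b]],
                            Vectorize(function(i, j)
                              oracleLeafDistance(phy, i, j))))
          if (dmin > clust_max) ok <- FALSE
        }
      }
    }
    if (!ok) next
    v <- ape::getMRCA(phy, eff)
    by_node[[as.character(v)]] <- rbind(
      by_node[[as.character(v)]],
      data.frame(mature = mat, n = length(eff),
                 score = score_of(match(mat, matures), sort(eff)),
                 targets = I(list(sort(eff))), phase = "mrca_phase",
                 stringsAsFactors = FALSE))
  }
  for (v in pre) {
    cnt <- if (is.null(chosen[[as.character(v)]])) 0L else
      nrow(chosen[[as.character(v)]])
    if (cnt >= x) next
    cand <- by_node[[as.character(v)]]
    if (!is.null(cand) && nrow(cand)) admit_at(v, cand)
  }

  out <- do.call(rbind, c(list(data.frame(mature = character(0),
                                          n = integer(0), score = numeric(0),
                                          targets = I(list()),
                                          phase = character(0))),
                          lapply(names(chosen), function(v) {
                            d <- chosen[[v]]
                            if (is.null(d) || nrow(d) == 0L) return(NULL)
                            d$origin_leaves <- paste(clade(as.integer(v)),
                                                     collapse = ",")
                            d
                          })))
  rownames(out) <- NULL
  out
}

# comparison key shared by oracle and package output
selectionKey <- function(mature, phase, targets, origin_leaves) {
  sort(paste(mature, phase,
             vapply(targets, function(t) paste(sort(t), collapse = ","),
                    character(1)),
             origin_leaves, sep = "|"))
}
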