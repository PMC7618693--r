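# Duplex energies, energy fractions, admissibility rules and best-site
# scanning, cross-checked against a plain-R re-summation of the packaged
# nearest-neighbor table.

randSeq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = "")

test_that("a perfect complement has fraction exactly 1 and the definitionally perfect energy", {
  model <- duplexModel()
  set.seed(41)
  for (rep in 1:20) {
    m <- randSeq(21)
    site <- revcompChr(m)
    ev <- energyFraction(model, m, site)
    expect_identical(ev@fraction, 1)
    expect_equal(ev@delta_g, ev@delta_g_perfect)
    expect_length(ev@mismatch_positions, 0)
    expect_lt(ev@delta_g_perfect, 0)
  }
})

test_that("duplex energies equal the independent position-by-position oracle", {
  model <- duplexModel()
  par <- oracleModelParams()
  set.seed(42)
  for (rep in 1:50) {
    m <- randSeq(21)
    site <- randSeq(21)
    expect_equal(duplexEnergy(model, m, site), oracleEnergy(m, site, par)$dg,
                 tolerance = 1e-12)
  }
  # and on near-complement sites with few mismatches
  for (rep in 1:30) {
    m <- randSeq(21)
    site <- revcompChr(m)
    pos <- sample(21, sample(1:3, 1))
    for (p in pos) {
      substr(site, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(site, p, p)), 1)
    }
    ev <- energyFraction(model, m, site)
    o <- oracleEnergy(m, site, par)
    expect_equal(ev@delta_g, o$dg, tolerance = 1e-12)
    expect_equal(ev@fraction, o$fraction, tolerance = 1e-12)
    expect_identical(ev@mismatch_positions, o$mm_pos)
    expect_identical(ev@gu_positions, o$gu_pos)
  }
})

test_that("a mismatch destabilizes and a G:U wobble sits strictly between", {
  model <- duplexModel()
  m <- "TACGATCGATCGATCGATCGA"
  site <- revcompChr(m)
  perfect <- energyFraction(model, m, site)
  # position 4 of the mature is G (pairs C); site C -> T makes a G:U wobble
  p <- 4L
  stopifnot(substr(m, p, p) == "G")
  sp <- 22 - p
  site_gu <- site; substr(site_gu, sp, sp) <- "T"
  site_mm <- site; substr(site_mm, sp, sp) <- "A"
  gu <- energyFraction(model, m, site_gu)
  mm <- energyFraction(model, m, site_mm)
  expect_gt(mm@delta_g, perfect@delta_g)
  expect_lt(gu@fraction, perfect@fraction)
  expect_gt(gu@fraction, mm@fraction)
  expect_identical(gu@gu_positions, p)
  expect_identical(mm@mismatch_positions, p)
})

test_that("adding a mismatch never increases the fraction (monotonicity)", {
  model <- duplexModel()
  set.seed(43)
  for (rep in 1:20) {
    m <- randSeq(21)
    site <- revcompChr(m)
    frac_prev <- energyFraction(model, m, site)@fraction
    for (p in sample(21, 5)) {
      cur <- substr(site, p, p)
      substr(site, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      frac_new <- energyFraction(model, m, site)@fraction
      expect_lte(frac_new, frac_prev + 1e-12)
      frac_prev <- frac_new
    }
  }
})

test_that("an all-mismatch site clips at fraction 0", {
  model <- duplexModel()
  m <- paste(rep("TTACG", 5), collapse = "")
  m <- substr(paste0(m, m), 1, 21)
  site <- chartr("ACGT", "CAAC", revcompChr(m))  # break every pair
  ev <- suppressMessages(energyFraction(model, m, site))
  expect_identical(ev@fraction, 0)
})

test_that("admissibility rules reject central, seed-heavy and overloaded patterns", {
  mk <- function(mm = integer(0), gu = integer(0))
    new("HybridEvaluation", delta_g = -30, delta_g_perfect = -40,
        fraction = 0.75, mismatch_positions = as.integer(mm),
        gu_positions = as.integer(gu), admissible = NA)
  expect_true(admissibleHybrid(mk()))
  expect_false(admissibleHybrid(mk(mm = 10)))
  expect_false(admissibleHybrid(mk(gu = 11)))
  expect_false(admissibleHybrid(mk(mm = c(2, 5))))
  expect_true(admissibleHybrid(mk(mm = c(2, 14))))
  expect_false(admissibleHybrid(mk(mm = c(12, 14, 16, 18))))
  expect_true(admissibleHybrid(mk(mm = c(1, 14, 16, 18))))
  expect_false(admissibleHybrid(mk(mm = c(1, 14, 16, 18), gu = 3)))  # 4.5 -> 5
  expect_true(admissibleHybrid(mk(mm = c(14, 16, 18), gu = c(3, 5))))  # 4
  # rule parameters live in config, not code
  loose <- defaultAdmissibilityRules()
  loose$seed_max_mm <- 2L
  expect_true(admissibleHybrid(mk(mm = c(2, 5)), loose))
})

test_that("bestSite equals the exhaustive per-window oracle on long transcripts", {
  model <- duplexModel()
  set.seed(44)
  for (rep in 1:4) {
    tx <- randSeq(500)
    w <- sample(480, 1)
    m <- revcompChr(substr(tx, w, w + 20))
    substr(m, 1, 1) <- "T"  # window-derived guide with the 5' edit
    b <- bestSite(model, m, tx)
    o <- oracleBestSite(m, tx)
    expect_equal(b$evaluation@fraction, o$fraction, tolerance = 1e-12)
    expect_identical(b$start, o$start)
    # and for an unrelated random guide
    m2 <- randSeq(21)
    b2 <- bestSite(model, m2, tx)
    o2 <- oracleBestSite(m2, tx)
    expect_equal(b2$evaluation@fraction, o2$fraction, tolerance = 1e-12)
    expect_identical(b2$start, o2$start)
  }
})

test_that("bestSite finds exact sites at fraction 1 and breaks ties by smallest start", {
  model <- duplexModel()
  set.seed(45)
  m <- randSeq(21)
  site <- revcompChr(m)
  tx <- paste0(randSeq(40), site, randSeq(30), site, randSeq(20))
  b <- bestSite(model, m, tx)
  expect_identical(b$evaluation@fraction, 1)
  expect_identical(b$start, 40L)
  expect_identical(b$end, 61L)
  expect_error(bestSite(model, m, "ACGT"), "shorter")
})

test_that("the batch scan table agrees with single-guide bestSite", {
  model <- duplexModel()
  set.seed(46)
  tx <- setNames(c(randSeq(200), randSeq(150)), c("g1", "g2"))
  matures <- vapply(1:10, function(i) randSeq(21), character(1))
  ht <- phyloAmiR:::hybridTable(matures, tx, model)
  for (i in seq_along(matures)) {
    for (g in names(tx)) {
      b <- bestSite(model, matures[i], tx[[g]])
      expect_equal(ht$fraction[i, g], b$evaluation@fraction,
                   tolerance = 1e-12)
      expect_identical(ht$admissible[i, g], b$evaluation@admissible)
    }
  }
})
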