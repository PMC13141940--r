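# shared synthetic assembly fixtures: a two-chain "dimer" of parallel
# helices and a terminal-dimer "template" whose partner chain is a pure
# translation of the anchor chain, so every propagation step is a known
# rigid motion.
makeTestDimer <- function(n = 28) {
  a <- makeHelix(n, chainId = "A")
  b <- atoms(a); b$chain <- "B"; b$y <- b$y + 12
  combineModels(a, StructureModel(b), identifier = "test-dimer")
}
makeTranslationTemplate <- function(n = 28, shift = c(0, 0, 30)) {
  a <- makeHelix(n, chainId = "A")
  g <- atoms(a); g$chain <- "G"
  g$x <- g$x + shift[1]; g$y <- g$y + shift[2]; g$z <- g$z + shift[3]
  combineModels(a, StructureModel(g), identifier = "test-template")
}

test_that("splicing two copies of the same donor reproduces the donor", {
  h <- makeHelix(58)
  res <- spliceChimera(h, "A", h, "A")
  expect_equal(res$fitRmsd, 0, tolerance = 1e-9)
  a <- atoms(res$model)
  expect_equal(sort(unique(a$resno)), 2:58)       # 57 residues, forced span
  donor <- atoms(selectAtoms(h, residues = c(2, 58)))
  expect_lt(max(abs(a[, c("x", "y", "z")] - donor[, c("x", "y", "z")])), 1e-9)
  expect_false(res$junctionFlagged)
})

test_that("splice preserves donor-fragment internal geometry exactly", {
  nDonor <- perturbModel(makeHelix(58), RigidTransform(randomRotation(), c(9, 8, 7)),
                         coordinateSigma = 0.2, seed = 31)
  cDonor <- makeHelix(58)
  res <- spliceChimera(nDonor, "A", cDonor, "A")
  chym <- atoms(res$model)
  for (part in list(c(2, 32), c(33, 58))) {
    src <- if (part[1] == 2) nDonor else cDonor
    a0 <- atoms(selectAtoms(src, residues = part))
    a1 <- chym[chym$resno >= part[1] & chym$resno <= part[2], ]
    d0 <- dist(cbind(a0$x, a0$y, a0$z))
    d1 <- dist(cbind(a1$x, a1$y, a1$z))
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
  expect_true(is.finite(res$junctionDistance))
})

test_that("splice rejects non-contiguous or overlapping ranges", {
  h <- makeHelix(58)
  expect_error(spliceChimera(h, "A", h, "A", nRange = c(2, 32), cRange = c(34, 58)),
               "contiguous")
  expect_error(spliceChimera(h, "A", h, "A", nRange = c(2, 33), cRange = c(33, 58)),
               "disjoint")
})

test_that("central dimer inherits placement and rejects duplicated chains", {
  h <- makeHelix(58)
  c1 <- spliceChimera(h, "A", h, "A")$model
  shifted <- applyTransform(h, RigidTransform(translation = c(0, 11, 0)))
  c2 <- spliceChimera(shifted, "A", shifted, "A")$model
  d <- buildCentralDimer(c1, c2)
  expect_equal(sort(chainIds(d)), c("A", "B"))
  for (ch in c("A", "B"))
    expect_equal(sort(unique(atoms(selectAtoms(d, ch))$resno)), 2:58)
  ## chain 2 must sit exactly where its c-donor frame put it
  expect_lt(max(abs(coords(selectAtoms(d, "B")) -
                    coords(selectAtoms(d, "A")) - rep(c(0, 11, 0), each = nAtoms(c1)))), 1e-9)
  expect_error(buildCentralDimer(c1, c1), "duplication")
})

test_that("filament of one dimer is the dimer itself", {
  dimer <- makeTestDimer()
  fil <- propagateFilament(dimer, makeTranslationTemplate(),
                           templatePairs = list(c("A", "G")), nDimers = 1)
  expect_equal(nDimers(fil), 1L)
  expect_identical(atoms(assembledStructure(fil)), atoms(dimer))
  expect_equal(nrow(junctionReport(fil)), 0L)
})

test_that("translation-template filament is periodic with known spacing", {
  shift <- c(0, 0, 30)
  dimer <- makeTestDimer()
  fil <- propagateFilament(dimer, makeTranslationTemplate(shift = shift),
                           templatePairs = list(c("A", "G")),
                           fitRange = c(2, 27), nDimers = 4)
  s <- assembledStructure(fil)
  expect_equal(length(chainIds(s)), 8L)
  expect_equal(nAtoms(s), 4L * nAtoms(dimer))      # linear scaling
  cents <- vapply(1:4, function(k)
    colMeans(coords(selectAtoms(s, chains = fil@provenance$outChain[fil@provenance$copy == k]))),
    numeric(3))
  gaps <- diff(t(cents))
  spacing <- sqrt(rowSums(gaps^2))
  expect_equal(spacing, rep(sqrt(sum(shift^2)), 3), tolerance = 1e-6)
  ## constant junction transform: consecutive displacement vectors identical
  expect_lt(max(abs(sweep(gaps, 2, gaps[1, ]))), 1e-6)
  ## junction fit rmsd self-consistency: exact template -> exact fits
  expect_lt(max(junctionReport(fil)$fitRmsd), 1e-9)
})

test_that("template pairs alternate cyclically along the filament", {
  dimer <- makeTestDimer()
  tmpl <- makeTranslationTemplate(shift = c(0, 0, 30))   # chains A, G
  p <- atoms(selectAtoms(tmpl, "A")); p$chain <- "P"
  q <- atoms(selectAtoms(tmpl, "A")); q$chain <- "Q"
  q$x <- q$x + 5; q$z <- q$z + 25
  tmpl2 <- combineModels(tmpl, StructureModel(p), StructureModel(q))
  fil <- propagateFilament(dimer, tmpl2,
                           templatePairs = list(c("A", "G"), c("P", "Q")),
                           fitRange = c(2, 27), nDimers = 3)
  jr <- junctionReport(fil)
  expect_equal(jr$templatePair, c("A-G", "P-Q"))
  s <- assembledStructure(fil)
  cents <- vapply(1:3, function(k)
    colMeans(coords(selectAtoms(s, chains = fil@provenance$outChain[fil@provenance$copy == k]))),
    numeric(3))
  ## junction 1 steps by the A->G shift; junction 2 by the P->Q shift
  ## corrected for the dimer-internal chain offset (0, 12, 0)
  expect_equal(unname(cents[, 2] - cents[, 1]), c(0, 0, 30), tolerance = 1e-6)
  expect_equal(unname(cents[, 3] - cents[, 2]), c(5, 0, 25), tolerance = 1e-6)
})

test_that("invalid propagation requests fail loudly or partially", {
  dimer <- makeTestDimer()
  tmpl <- makeTranslationTemplate()
  expect_error(propagateFilament(dimer, tmpl, nDimers = 0), "nDimers")
  ## a template whose chains share no residues with the fit range stops
  ## propagation with a partial result
  badTmpl <- tmpl
  ba <- atoms(badTmpl); ba$resno <- ba$resno + 500L
  expect_warning(
    fil <- propagateFilament(dimer, StructureModel(ba),
                             templatePairs = list(c("A", "G")), nDimers = 3),
    "propagation stopped")
  expect_lt(nDimers(fil), 3L)
})

test_that("junction reports serialize as JSON lines", {
  dimer <- makeTestDimer()
  fil <- propagateFilament(dimer, makeTranslationTemplate(),
                           templatePairs = list(c("A", "G")), nDimers = 3)
  f <- tempfile(fileext = ".jsonl")
  writeJunctionReport(fil, f)
  lines <- readLines(f)
  expect_equal(length(lines), 2L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("junction", "templatePair", "fitRmsd", "clashCount") %in%
                  names(rec)))
})
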