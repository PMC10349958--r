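test_that("build_toy_complex is reproducible and forms a real interface", {
  a <- build_toy_complex(seed = 71)
  b <- build_toy_complex(seed = 71)
  expect_identical(a$reference$atoms, b$reference$atoms)
  c <- build_toy_complex(seed = 72)
  expect_false(identical(a$reference$atoms, c$reference$atoms))
  # written files are bit-identical for the same seed
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(a$reference, p1)
  write_structure(b$reference, p2)
  expect_identical(readLines(p1), readLines(p2))
  # >= 5 native contacts at 5 A, confirmed by brute-force enumeration
  expect_gte(length(oracle_contacts(a$reference, a$partition, 5)), 5)
  # numbering populates all three CDR ranges
  expect_setequal(unique(a$numbering$region), c("FR", "CDR1", "CDR2", "CDR3"))
})

test_that("decoys carry exact planted truth", {
  cplx <- build_toy_complex(seed = 73)
  mags <- c(0, 2, 6, 15, 40)
  decoys <- make_decoys(cplx, decoy_config(translations = mags, seed = 5))
  m <- map_chains(cplx$reference, cplx$reference, cplx$partition)
  scores <- lapply(decoys, function(d)
    score_model(d$structure, cplx$reference, cplx$partition, mapping = m))
  # zero-magnitude decoy is the reference: DockQ 1, class High
  expect_equal(scores[[1]]$dockq, 1.0, tolerance = 1e-9)
  expect_equal(scores[[1]]$capri_class, "High")
  # measured L-RMSD equals the planted magnitude exactly
  for (i in seq_along(mags))
    expect_equal(scores[[i]]$l_rmsd, mags[i], tolerance = 1e-6)
  # DockQ non-increasing along the magnitude sweep
  dq <- vapply(scores, `[[`, numeric(1), "dockq")
  expect_true(all(diff(dq) <= 1e-12))
  # planted pLDDT decreases with planted error on average
  ipl <- vapply(decoys, function(d)
    interface_plddt(d$structure, cplx$partition), numeric(1))
  expect_lt(ipl[5], ipl[1])
  expect_gt(suppressWarnings(
    cor(ipl, -vapply(decoys, function(d) d$planted$error, numeric(1)),
        method = "spearman")), 0.9)
})

test_that("decoy pLDDT-accuracy association survives as rank correlation", {
  # mirrors the score-vs-accuracy recovery property: planted pLDDT falls
  # with error, so I-pLDDT correlates positively with DockQ across decoys
  cplx <- build_toy_complex(seed = 74)
  m <- map_chains(cplx$reference, cplx$reference, cplx$partition)
  decoys <- make_decoys(cplx, decoy_config(
    translations = c(0, 1, 2, 3, 5, 8, 12, 20, 30, 40), seed = 9))
  dq <- vapply(decoys, function(d)
    score_model(d$structure, cplx$reference, cplx$partition, mapping = m)$dockq,
    numeric(1))
  ipl <- vapply(decoys, function(d)
    interface_plddt(d$structure, cplx$partition), numeric(1))
  expect_gt(suppressWarnings(cor(ipl, dq, method = "spearman")), 0)
})

test_that("make_msa plants recoverable cluster structure", {
  m1 <- make_msa(1, 6, length = 80, seed = 1)
  expect_equal(neff(m1)$neff, 1)
  m5 <- make_msa(5, 1, between_identity = 0.3, length = 50, seed = 2)
  expect_equal(neff(m5)$neff, 5)
  expect_identical(make_msa(3, 4, seed = 9), make_msa(3, 4, seed = 9))
  expect_error(make_msa(2, 3, within_identity = 0.5, between_identity = 0.9),
               "infeasible")
  expect_error(make_msa(2, 3, within_identity = 0.9, between_identity = 0.85,
                        length = 5), "infeasible")
})

test_that("attach_glycan places hetero residues at the requested distance", {
  cplx <- build_toy_complex(seed = 75)
  for (d in c(2.5, 4.0, 5.0)) {
    g <- attach_glycan(cplx$reference, cplx$partition, "NAG", d)
    het <- g$atoms[g$atoms$het, ]
    ab <- g$atoms[g$atoms$chain %in% "H" & !g$atoms$het, ]
    dm <- sqrt(outer(rowSums(as.matrix(het[, c("x", "y", "z")])^2),
                     rowSums(as.matrix(ab[, c("x", "y", "z")])^2), `+`) -
                 2 * as.matrix(het[, c("x", "y", "z")]) %*%
                 t(as.matrix(ab[, c("x", "y", "z")])))
    expect_equal(min(dm), d, tolerance = 0.05)
  }
  expect_error(attach_glycan(cplx$reference, cplx$partition, "NAG", -1),
               "positive")
})

test_that("make_cohort produces a ranked, reproducible manifest", {
  coh <- make_cohort(n_complexes = 4, decoys_per_complex = 6, seed = 3)
  man <- coh$manifest
  expect_equal(nrow(man), 24)
  expect_equal(as.integer(table(man$complex_id)), rep(6L, 4))
  # ranks are unique 1..n within each complex
  for (cid in unique(man$complex_id))
    expect_setequal(man$rank[man$complex_id == cid], 1:6)
  # Ab/Nano mix and glycan flags present
  expect_setequal(unique(man$antibody_type), c("Ab", "Nano"))
  # deterministic given the seed
  coh2 <- make_cohort(n_complexes = 4, decoys_per_complex = 6, seed = 3)
  expect_identical(man, coh2$manifest)
  # planted class distribution spans multiple CAPRI levels
  expect_gte(length(unique(man$capri_class)), 3)
  # measured class always matches the threshold table on its own scores
  expect_equal(man$capri_class,
               as.character(capri_class(man$fnat, man$i_rmsd, man$l_rmsd)))
})

test_that("cohort files land on disk when out_dir is given", {
  dir <- withr::local_tempdir()
  make_cohort(n_complexes = 1, decoys_per_complex = 2, seed = 4, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  cdir <- file.path(dir, "complex_001")
  expect_true(file.exists(file.path(cdir, "reference.pdb")))
  expect_true(file.exists(file.path(cdir, "numbering.tsv")))
  expect_true(file.exists(file.path(cdir, "decoy_001.pdb")))
  expect_true(file.exists(file.path(cdir, "decoy_001_scores.txt")))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)
})
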