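test_that("find_contacts matches brute-force enumeration and boundary rule", {
  s <- mini_complex(n = 6, gap = 4)
  p <- partition_complex(s, "H", NULL, "A")
  # facing CA pairs are exactly 4 A apart; diagonals sqrt(16 + 16) > 5
  ct <- find_contacts(s, p, cutoff = 5)
  expect_equal(nrow(ct), 6)
  expect_equal(ct$min_dist, rep(4, 6))
  # inclusive boundary: cutoff exactly at the minimum distance keeps the pair
  expect_equal(nrow(find_contacts(s, p, cutoff = 4)), 6)
  expect_equal(nrow(find_contacts(s, p, cutoff = 3.999)), 0)
  # far-separated chains give an empty set
  far <- translate_chain(s, "H", c(0, 0, 100))
  expect_equal(nrow(find_contacts(far, p, cutoff = 5)), 0)
  expect_error(find_contacts(s, p, cutoff = 0), "positive")
  # agreement with the all-pairs oracle on an irregular complex
  cplx <- build_toy_complex(seed = 21)
  ct2 <- find_contacts(cplx$reference, cplx$partition, 5)
  keys <- paste(paste(ct2$ab_chain, ct2$ab_resno, ct2$ab_insert, sep = ":"),
                paste(ct2$ag_chain, ct2$ag_resno, ct2$ag_insert, sep = ":"),
                sep = "|")
  expect_setequal(keys, oracle_contacts(cplx$reference, cplx$partition, 5))
})

test_that("fnat recovers planted preserved-contact fractions", {
  cplx <- build_toy_complex(seed = 22)
  ref <- cplx$reference; p <- cplx$partition
  m <- map_chains(ref, ref, p)
  expect_equal(as.numeric(fnat(ref, ref, m, p)), 1.0)
  far <- translate_chain(ref, "H", c(0, 0, 100))
  expect_equal(as.numeric(fnat(far, ref, m, p)), 0.0)
  # partial decoy agrees with the oracle numerator/denominator exactly
  part <- translate_chain(ref, "H", c(6, 0, 0))
  fn <- fnat(part, ref, m, p)
  orc <- oracle_fnat(part, ref, p)
  expect_identical(attr(fn, "n_native"), orc$n_native)
  expect_identical(attr(fn, "n_preserved"), orc$n_preserved)
  expect_equal(as.numeric(fn), orc$fnat)
  # no native interface is an error
  apart <- translate_chain(ref, "A", c(0, 0, -100))
  expect_error(fnat(ref, apart, m, p), "no native interface")
})

test_that("i_rmsd and l_rmsd have the right trivial and planted values", {
  cplx <- build_toy_complex(seed = 23)
  ref <- cplx$reference; p <- cplx$partition
  m <- map_chains(ref, ref, p)
  expect_equal(i_rmsd(ref, ref, m, p), 0, tolerance = 1e-9)
  expect_equal(l_rmsd(ref, ref, m, p), 0, tolerance = 1e-9)
  # global rigid transform of the whole model complex changes nothing
  set.seed(9)
  moved <- apply_transform(ref, random_transform())
  expect_equal(i_rmsd(moved, ref, m, p), 0, tolerance = 1e-8)
  expect_equal(l_rmsd(moved, ref, m, p), 0, tolerance = 1e-8)
  expect_equal(as.numeric(fnat(moved, ref, m, p)), 1.0)
  # pure 6 A antibody translation: L-RMSD is exactly 6
  dec <- translate_chain(ref, "H", 6 * c(1, 2, 2) / 3)
  expect_equal(l_rmsd(dec, ref, m, p), 6.0, tolerance = 1e-9)
  # two-path equivalence: rotated-antibody decoy vs explicit-interface oracle
  rot <- abagqc:::rotation_about_axis(c(0, 1, 0), 10)
  abi <- ref$atoms$chain == "H"
  ctr <- colMeans(ref$atoms[abi, c("x", "y", "z")])
  dec2 <- ref
  dec2$atoms[abi, c("x", "y", "z")] <-
    sweep(sweep(as.matrix(ref$atoms[abi, c("x", "y", "z")]), 2, ctr) %*% t(rot),
          2, ctr, `+`)
  expect_equal(i_rmsd(dec2, ref, m, p), oracle_irmsd(dec2, ref, p),
               tolerance = 1e-6)
  expect_equal(l_rmsd(dec2, ref, m, p), oracle_lrmsd(dec2, ref, p),
               tolerance = 1e-6)
})

test_that("dockq_score follows the composite formula and its monotonicities", {
  expect_equal(dockq_score(1, 0, 0), 1.0)
  expect_equal(dockq_score(0.5, 1.5, 8.5), 0.5)
  v <- dockq_score(0, 100, 100)
  expect_lt(v, 0.01)
  expect_equal(v, (0 + 1 / (1 + (100 / 1.5)^2) + 1 / (1 + (100 / 8.5)^2)) / 3)
  expect_error(dockq_score(1.2, 0, 0))
  irs <- seq(0, 10, by = 0.5)
  expect_true(all(diff(dockq_score(0.5, irs, 3)) < 0))
  expect_true(all(diff(dockq_score(0.5, 3, irs)) < 0))
  fns <- seq(0, 1, by = 0.1)
  expect_true(all(diff(dockq_score(fns, 3, 3)) > 0))
})

test_that("capri_class applies the threshold table", {
  expect_equal(as.character(capri_class(0, 50, 80)), "Incorrect")
  expect_equal(as.character(capri_class(0.6, 0.68, 2.0)), "High")
  expect_equal(as.character(capri_class(0.35, 1.8, 6.0)), "Medium")
  # sweeping fnat across the 0.1 / 0.3 / 0.5 boundaries at small RMSDs
  cls <- capri_class(c(0.05, 0.1, 0.29, 0.3, 0.49, 0.5), 0.9, 0.9)
  expect_equal(as.character(cls),
               c("Incorrect", "Acceptable", "Acceptable", "Medium", "Medium", "High"))
  # levels are ordered for threshold comparisons
  expect_true(capri_class(1, 0, 0) > capri_class(0, 50, 50))
})

test_that("score_model composes a consistent record", {
  cplx <- build_toy_complex(seed = 24, config = list(light = TRUE))
  ref <- cplx$reference; p <- cplx$partition
  self <- score_model(ref, ref, p)
  expect_equal(self$fnat, 1.0)
  expect_equal(self$i_rmsd, 0, tolerance = 1e-9)
  expect_equal(self$l_rmsd, 0, tolerance = 1e-9)
  expect_equal(self$dockq, 1.0, tolerance = 1e-9)
  expect_equal(self$capri_class, "High")
  # destroyed interface is Incorrect
  wreck <- translate_chain(ref, c("H", "L"), c(0, 0, 120))
  expect_equal(score_model(wreck, ref, p)$capri_class, "Incorrect")
  # class always recomputable from the three component scores
  dec <- translate_chain(ref, c("H", "L"), c(4, 0, 0))
  sc <- score_model(dec, ref, p)
  expect_equal(sc$capri_class,
               as.character(capri_class(sc$fnat, sc$i_rmsd, sc$l_rmsd)))
})
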