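AG1 <- strrep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", 3)
AG2 <- strrep("GGSGGSGGSGGSGGSGGSGGSGGSGGSGGSGGS", 3)
AG3 <- strrep("KELNDARKELNDARKELNDARKELNDARKELND", 3)
HV1 <- "QVQLVESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVS"
HV2 <- "EIVLTQSPATLSLSPGERATLSCRASQSVSSYLAWYQQKPGQAPRLLIY"

entry <- function(id, date = "2019-06-01", res = 2.5, heavy = HV1,
                  light = NULL, ag = AG1, ...) {
  benchmark_entry(id, date, res, heavy, light_seq = light,
                  antigen_seqs = ag, ...)
}

test_that("sequence_redundant needs similar antibody AND an antigen match", {
  e <- entry("a")
  expect_true(as.logical(sequence_redundant(e, entry("b"))))
  # ~95% heavy identity with a shared antigen: redundant
  h95 <- HV1; substr(h95, 3, 4) <- "WW"
  expect_true(as.logical(sequence_redundant(entry("c", heavy = h95), e)))
  # both identities below 90%: nonredundant even with identical antigens
  h85 <- HV1
  for (i in seq(2, 16, by = 2)) substr(h85, i, i) <- "W"
  expect_lt(abagqc:::align_identity(h85, HV1), 0.9)
  expect_false(as.logical(sequence_redundant(entry("d", heavy = h85), e)))
  # identical antibody but unrelated antigens: nonredundant
  expect_false(as.logical(sequence_redundant(entry("e", ag = AG2), e)))
  expect_error(sequence_redundant(entry("f", heavy = ""), e), "empty")
})

test_that("length_filters applies both difference rules", {
  keep <- entry("a", seqres_lengths = 100, resolved_lengths = 100)
  expect_equal(length_filters(keep)$verdict, "keep")
  hard <- entry("b", seqres_lengths = 1000, resolved_lengths = 250)
  d <- length_filters(hard)
  expect_equal(d$verdict, "remove")
  expect_match(d$rule_fired, "length_difference")
  soft <- entry("c", seqres_lengths = 900, resolved_lengths = 540)
  d2 <- length_filters(soft)
  expect_equal(d2$verdict, "remove")
  expect_match(d2$rule_fired, "large_antigen")
  # 40% missing but small antigen passes
  ok <- entry("d", seqres_lengths = 400, resolved_lengths = 240)
  expect_equal(length_filters(ok)$verdict, "keep")
  expect_error(length_filters(entry("e", seqres_lengths = 0,
                                    resolved_lengths = 0)), "SEQRES")
})

test_that("basic_filters enforces resolution and release date", {
  expect_equal(basic_filters(entry("a", "2019-01-01", 2.5))$verdict, "keep")
  d <- basic_filters(entry("b", "2019-01-01", 3.2))
  expect_equal(d$verdict, "remove")
  expect_equal(d$rule_fired, "resolution")
  # boundary: exactly 3.0 A is kept (inclusive)
  expect_equal(basic_filters(entry("c", "2019-01-01", 3.0))$verdict, "keep")
  # date cutoff is strict: same-day release is removed
  d2 <- basic_filters(entry("d", "2018-04-30", 2.0))
  expect_equal(d2$rule_fired, "release_date")
  e <- entry("e"); e$release_date <- as.Date(NA)
  expect_error(basic_filters(e), "release date")
})

test_that("structural_redundant requires both proximity and identity", {
  c1 <- build_toy_complex(seed = 61)
  same <- entry("a", structure = c1$reference, partition = c1$partition)
  same2 <- entry("b", structure = c1$reference, partition = c1$partition)
  expect_true(as.logical(structural_redundant(same, same2)))
  # same antibody displaced 20 A on the antigen: RMSD breaks the rule
  moved <- translate_chain(c1$reference, "H", c(20, 0, 0))
  disp <- entry("c", structure = moved, partition = c1$partition)
  st <- structural_redundant(disp, same)
  expect_false(as.logical(st))
  # close pose but all identities at/below 70%: not redundant
  lowid <- entry("d", heavy = HV2, structure = c1$reference,
                 partition = c1$partition)
  expect_lt(abagqc:::align_identity(HV2, HV1), 0.7)
  expect_false(as.logical(structural_redundant(lowid, same)))
  expect_error(structural_redundant(entry("e"), same), "structures")
})

test_that("curate removes exactly the planted duplicates, deterministically", {
  h_alt <- HV2
  originals <- list(entry("1aaa", "2019-01-10"),
                    entry("2bbb", "2019-02-10", heavy = h_alt, ag = AG2),
                    # same heavy domain as 2bbb but an unrelated antigen:
                    # clause 2 (no antigen match) keeps it
                    entry("3ccc", "2019-03-10", heavy = h_alt, ag = AG3))
  dups <- list(entry("4ddd", "2019-04-10"),                  # dup of 1aaa
               entry("5eee", "2019-05-10", heavy = h_alt, ag = AG2))  # dup of 2bbb
  out <- curate(c(originals, dups))
  removed <- out$decisions[out$decisions$verdict == "remove", ]
  expect_equal(sort(removed$entry), c("4ddd", "5eee"))
  expect_true(all(removed$rule_fired == "sequence_redundant"))
  expect_true(all(nzchar(removed$rule_fired)))
  expect_equal(vapply(out$survivors, function(e) e$id, character(1)),
               c("1aaa", "2bbb", "3ccc"))
  # idempotence: curating the survivors removes nothing
  again <- curate(out$survivors)
  expect_true(all(again$decisions$verdict == "keep"))
  # input order does not matter
  set.seed(1)
  shuffled <- curate(sample(c(originals, dups)))
  expect_equal(sort(vapply(shuffled$survivors, function(e) e$id, character(1))),
               c("1aaa", "2bbb", "3ccc"))
  # rule-based filters fire before redundancy screening
  late <- entry("6fff", "2017-01-01")
  mixed <- curate(list(entry("1aaa", "2019-01-10"), late))
  expect_equal(mixed$decisions$rule_fired[mixed$decisions$entry == "6fff"],
               "release_date")
  # manual exclusion list
  excl <- curate(originals, config = list(exclude = "2bbb"))
  expect_equal(excl$decisions$rule_fired[excl$decisions$entry == "2bbb"],
               "manual_exclusion")
})
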