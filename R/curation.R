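# Benchmark curation: the non-redundancy and quality rules used to assemble
# an antibody-antigen evaluation set, as a deterministic rule engine.
# Candidates are screened against previously released ("prior") entries and
# against earlier-accepted candidates.

#' Construct a benchmark entry
#'
#' @param id entry identifier (e.g. a PDB id).
#' @param release_date release date (`Date` or parseable string).
#' @param resolution structure resolution in Angstroms.
#' @param heavy_seq heavy-chain variable-domain sequence.
#' @param light_seq light-chain variable-domain sequence or `NULL`.
#' @param antigen_seqs character vector of antigen chain sequences.
#' @param seqres_lengths,resolved_lengths per-antigen-chain SEQRES and
#'   resolved residue counts (same order as `antigen_seqs`); default to the
#'   antigen sequence lengths.
#' @param cdr_seq concatenated CDR loop sequence (optional).
#' @param structure optional `abag_structure` for structural checks.
#' @param partition optional `abag_partition` for `structure`.
#' @return An `abag_entry` list.
#' @export
benchmark_entry <- function(id, release_date, resolution, heavy_seq,
                            light_seq = NULL, antigen_seqs,
                            seqres_lengths = nchar(antigen_seqs),
                            resolved_lengths = nchar(antigen_seqs),
                            cdr_seq = NULL, structure = NULL, partition = NULL) {
  if (resolution <= 0) stop("resolution must be positive")
  if (any(resolved_lengths > seqres_lengths))
    stop("resolved length exceeds SEQRES length")
  structure(list(id = id, release_date = as.Date(release_date),
                 resolution = resolution, heavy_seq = heavy_seq,
                 light_seq = light_seq, antigen_seqs = antigen_seqs,
                 seqres_lengths = seqres_lengths,
                 resolved_lengths = resolved_lengths,
                 cdr_seq = cdr_seq, structure = structure,
                 partition = partition),
            class = "abag_entry")
}

full_variable_seq <- function(entry)
  paste0(entry$heavy_seq, entry$light_seq %||% "")

#' Sequence-level redundancy between two entries
#'
#' Redundant iff (heavy-chain variable identity >= 90% OR full variable
#' identity >= 90%) AND the antigens match. "Antigen match" is a local
#' alignment of length >= 30 at >= 30% identity between any candidate/prior
#' antigen chain pair.
#'
#' @param candidate,prior `abag_entry` objects.
#' @param id_cutoff variable-domain identity threshold (fraction).
#' @param antigen_min_len,antigen_min_identity local-match thresholds.
#' @return logical with a `details` attribute.
#' @export
sequence_redundant <- function(candidate, prior, id_cutoff = 0.90,
                               antigen_min_len = 30, antigen_min_identity = 0.30) {
  if (!nzchar(candidate$heavy_seq) || !nzchar(prior$heavy_seq))
    stop("empty heavy-chain sequence")
  heavy_id <- align_identity(candidate$heavy_seq, prior$heavy_seq)
  full_id <- align_identity(full_variable_seq(candidate), full_variable_seq(prior))
  ab_similar <- heavy_id >= id_cutoff || full_id >= id_cutoff
  ag_match <- FALSE
  if (ab_similar) {
    for (a in candidate$antigen_seqs) for (b in prior$antigen_seqs) {
      if (local_match(a, b, antigen_min_len, antigen_min_identity)) {
        ag_match <- TRUE; break
      }
    }
  }
  out <- ab_similar && ag_match
  attr(out, "details") <- sprintf("heavy_id=%.3f full_id=%.3f antigen_match=%s",
                                  heavy_id, full_id, ag_match)
  out
}

#' Structure-level redundancy between two entries
#'
#' Redundant iff the heavy-chain CA RMSD after superposing the antigens is
#' below 5 A AND any of heavy variable, light variable, or concatenated CDR
#' sequence identity exceeds 70%. When no antigen correspondence can be
#' built the candidate is kept (redundancy cannot be proven) with a warning.
#'
#' @param candidate,prior `abag_entry` objects carrying structures.
#' @param rmsd_cutoff heavy-chain CA RMSD threshold, default 5 A.
#' @param id_cutoff identity threshold, default 0.70 (exclusive).
#' @return logical with a `details` attribute.
#' @export
structural_redundant <- function(candidate, prior, rmsd_cutoff = 5,
                                 id_cutoff = 0.70) {
  if (is.null(candidate$structure) || is.null(prior$structure))
    stop("both entries need structures for the structural check")
  ids <- c(heavy = align_identity(candidate$heavy_seq, prior$heavy_seq),
           light = if (!is.null(candidate$light_seq) && !is.null(prior$light_seq))
             align_identity(candidate$light_seq, prior$light_seq) else 0,
           cdr = if (!is.null(candidate$cdr_seq) && !is.null(prior$cdr_seq))
             align_identity(candidate$cdr_seq, prior$cdr_seq) else 0)
  any_id <- any(ids > id_cutoff)
  ca_rmsd <- tryCatch({
    mapping <- map_chains(candidate$structure, prior$structure,
                          candidate$partition, prior$partition)
    ag <- mapping[mapping$role == "antigen", , drop = FALSE]
    ca_c <- atom_subset(candidate$structure, polymer = TRUE, elety = "CA")
    ca_p <- atom_subset(prior$structure, polymer = TRUE, elety = "CA")
    ic <- match(res_key(ag$model_chain, ag$model_resno, ag$model_insert),
                res_key(ca_c$chain, ca_c$resno, ca_c$insert))
    ip <- match(res_key(ag$ref_chain, ag$ref_resno, ag$ref_insert),
                res_key(ca_p$chain, ca_p$resno, ca_p$insert))
    ok <- !is.na(ic) & !is.na(ip)
    fit <- kabsch_superpose(as.matrix(ca_c[ic[ok], c("x", "y", "z")]),
                            as.matrix(ca_p[ip[ok], c("x", "y", "z")]))
    hv <- mapping[mapping$role == "heavy", , drop = FALSE]
    ihc <- match(res_key(hv$model_chain, hv$model_resno, hv$model_insert),
                 res_key(ca_c$chain, ca_c$resno, ca_c$insert))
    ihp <- match(res_key(hv$ref_chain, hv$ref_resno, hv$ref_insert),
                 res_key(ca_p$chain, ca_p$resno, ca_p$insert))
    okh <- !is.na(ihc) & !is.na(ihp)
    rmsd(apply_transform(as.matrix(ca_c[ihc[okh], c("x", "y", "z")]),
                         fit$transform),
         as.matrix(ca_p[ihp[okh], c("x", "y", "z")]))
  }, error = function(e) {
    warning("antigen correspondence unbuildable (", conditionMessage(e),
            "); keeping candidate")
    NA_real_
  })
  out <- !is.na(ca_rmsd) && ca_rmsd < rmsd_cutoff && any_id
  attr(out, "details") <- sprintf(
    "heavy_ca_rmsd=%s ids(heavy/light/cdr)=%.2f/%.2f/%.2f",
    ifelse(is.na(ca_rmsd), "NA", sprintf("%.2f", ca_rmsd)),
    ids["heavy"], ids["light"], ids["cdr"])
  out
}

decision_row <- function(entry_id, verdict, rule = "", details = "") {
  data.frame(entry = entry_id, verdict = verdict, rule_fired = rule,
             details = details, stringsAsFactors = FALSE)
}

#' Antigen length/completeness filter
#'
#' Removes entries whose antigen SEQRES-vs-resolved length difference
#' fraction exceeds 70%, or exceeds 35% with a resolved antigen longer than
#' 500 residues; the difference fraction is `(seqres - resolved) / seqres`.
#'
#' @param entry an `abag_entry`.
#' @return a one-row decision data.frame (`entry`, `verdict`, `rule_fired`,
#'   `details`).
#' @export
length_filters <- function(entry) {
  if (any(entry$seqres_lengths <= 0)) stop("zero SEQRES length")
  frac <- (entry$seqres_lengths - entry$resolved_lengths) / entry$seqres_lengths
  hard <- frac > 0.70
  soft <- frac > 0.35 & entry$resolved_lengths > 500
  if (any(hard))
    decision_row(entry$id, "remove", "length_difference",
                 sprintf("difference fraction %.2f > 0.70", max(frac[hard])))
  else if (any(soft))
    decision_row(entry$id, "remove", "length_difference_large_antigen",
                 sprintf("difference fraction %.2f > 0.35 and resolved %d > 500",
                         max(frac[soft]), max(entry$resolved_lengths[soft])))
  else decision_row(entry$id, "keep")
}

#' Resolution and release-date filter
#'
#' Keep iff resolution <= `resolution_cutoff` (inclusive) and release date
#' strictly after `date_cutoff`.
#'
#' @param entry an `abag_entry`.
#' @param resolution_cutoff Angstroms, default 3.0.
#' @param date_cutoff a `Date` or parseable string.
#' @return a one-row decision data.frame.
#' @export
basic_filters <- function(entry, resolution_cutoff = 3.0,
                          date_cutoff = "2018-04-30") {
  if (is.null(entry$release_date) || is.na(entry$release_date))
    stop("entry ", entry$id, " has no release date")
  if (entry$resolution > resolution_cutoff)
    decision_row(entry$id, "remove", "resolution",
                 sprintf("%.2f A > %.2f A", entry$resolution, resolution_cutoff))
  else if (entry$release_date <= as.Date(date_cutoff))
    decision_row(entry$id, "remove", "release_date",
                 sprintf("%s <= %s", entry$release_date, as.Date(date_cutoff)))
  else decision_row(entry$id, "keep")
}

#' Curate a candidate benchmark set
#'
#' Applies, in order: manual exclusions, resolution/date filter, antigen
#' length filters, then sequence and (when structures are present)
#' structural redundancy against all priors and all earlier-accepted
#' candidates. Candidates are processed in release-date then id order, so
#' the surviving set is independent of input order.
#'
#' @param candidates list of `abag_entry` objects.
#' @param priors list of `abag_entry` objects already in circulation.
#' @param config optional list: `resolution_cutoff`, `date_cutoff`,
#'   `exclude` (ids removed by manual inspection), `structural` (logical,
#'   attempt structural checks when structures exist; default TRUE).
#' @return list with `decisions` (data.frame, one row per candidate) and
#'   `survivors` (list of accepted entries, in processing order).
#' @export
curate <- function(candidates, priors = list(), config = list()) {
  cfg <- modifyList(list(resolution_cutoff = 3.0, date_cutoff = "2018-04-30",
                         exclude = character(), structural = TRUE), config)
  ord <- order(as.Date(vapply(candidates, function(e) as.character(e$release_date),
                              character(1))),
               vapply(candidates, function(e) e$id, character(1)))
  candidates <- candidates[ord]
  decisions <- list()
  survivors <- list()
  for (cand in candidates) {
    dec <- NULL
    if (cand$id %in% cfg$exclude) {
      dec <- decision_row(cand$id, "remove", "manual_exclusion", "exclusion list")
    }
    if (is.null(dec)) {
      d <- basic_filters(cand, cfg$resolution_cutoff, cfg$date_cutoff)
      if (d$verdict == "remove") dec <- d
    }
    if (is.null(dec)) {
      d <- length_filters(cand)
      if (d$verdict == "remove") dec <- d
    }
    if (is.null(dec)) {
      screen <- c(priors, survivors)
      for (prev in screen) {
        sr <- sequence_redundant(cand, prev)
        if (isTRUE(as.logical(sr))) {
          dec <- decision_row(cand$id, "remove", "sequence_redundant",
                              paste0("vs ", prev$id, ": ", attr(sr, "details")))
          break
        }
        if (cfg$structural && !is.null(cand$structure) && !is.null(prev$structure)) {
          st <- structural_redundant(cand, prev)
          if (isTRUE(as.logical(st))) {
            dec <- decision_row(cand$id, "remove", "structural_redundant",
                                paste0("vs ", prev$id, ": ", attr(st, "details")))
            break
          }
        }
      }
    }
    if (is.null(dec)) {
      dec <- decision_row(cand$id, "keep")
      survivors[[length(survivors) + 1L]] <- cand
    }
    decisions[[length(decisions) + 1L]] <- dec
  }
  list(decisions = do.call(rbind, decisions), survivors = survivors)
}
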