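# Predicted-model confidence: interface pLDDT, model confidence
# (pTM/ipTM combination), and within-complex ranking.

#' Interface pLDDT (I-pLDDT)
#'
#' Mean per-residue pLDDT over the union of antibody and antigen interface
#' residues, where an interface residue has any non-hydrogen atom within
#' `cutoff` (default 4.0 A) of the binding partner. When no interface
#' residues exist the fixed floor of 30 is returned, so a fully dissociated
#' prediction still gets a (minimal) score.
#'
#' @param model an `abag_structure` with pLDDT in the temperature factors.
#' @param partition an `abag_partition`.
#' @param cutoff interface distance cutoff in Angstroms.
#' @param floor value returned when the interface is empty.
#' @return I-pLDDT in \[0, 100\].
#' @export
interface_plddt <- function(model, partition, cutoff = 4.0, floor = 30) {
  contacts <- find_contacts(model, partition, cutoff)
  if (nrow(contacts) == 0) return(floor)
  keys <- unique(c(res_key(contacts$ab_chain, contacts$ab_resno, contacts$ab_insert),
                   res_key(contacts$ag_chain, contacts$ag_resno, contacts$ag_insert)))
  pl <- extract_plddt(model)
  plk <- res_key(pl$chain, pl$resno, pl$insert)
  mean(pl$plddt[match(keys, plk)])
}

#' Model confidence from pTM and ipTM
#'
#' The fixed linear combination `0.8 * iptm + 0.2 * ptm` used to rank
#' multimer predictions.
#'
#' @param ptm,iptm predicted TM-score confidences in \[0, 1\].
#' @return model confidence in \[0, 1\].
#' @export
model_confidence <- function(ptm, iptm) {
  if (any(ptm < 0 | ptm > 1 | iptm < 0 | iptm > 1))
    stop("ptm and iptm must be in [0, 1]")
  0.8 * iptm + 0.2 * ptm
}

#' Rank the models of one complex by confidence
#'
#' Orders records by descending `model_confidence` (falling back to `iplddt`
#' for records without one); ties are broken by model label so the ranking
#' is reproducible. Rank 1 is the most confident model.
#'
#' @param records data.frame with a `model` label column and a
#'   `model_confidence` (or `iplddt`) column.
#' @return the records sorted by rank, with a `rank` column added and a
#'   `ranked_by` attribute.
#' @export
rank_models <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no records to rank")
  key <- "model_confidence"
  if (is.null(records[[key]]) || all(is.na(records[[key]]))) key <- "iplddt"
  if (is.null(records[[key]])) stop("records carry neither model_confidence nor iplddt")
  ord <- order(-records[[key]], as.character(records$model))
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "ranked_by") <- key
  out
}

#' Read a per-model confidence record from a key-value text file
#'
#' Accepts `key value`, `key: value` or `key=value` lines (one per metric,
#' e.g. `ptm 0.81`, `iptm 0.74`); unknown keys are kept verbatim.
#'
#' @param path file path.
#' @return named list of numeric values, with `model_confidence` added when
#'   both `ptm` and `iptm` are present.
#' @export
read_confidence_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[=:[:space:]]+")[[1]]
    if (length(parts) >= 2)
      out[[parts[1]]] <- suppressWarnings(as.numeric(parts[2]))
  }
  if (!is.null(out$ptm) && !is.null(out$iptm) &&
      is.finite(out$ptm) && is.finite(out$iptm))
    out$model_confidence <- model_confidence(out$ptm, out$iptm)
  out
}

#' Write a per-model confidence record
#' @param record named list of numeric values.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_confidence_record <- function(record, path) {
  writeLines(paste(names(record), vapply(record, format, character(1))), path)
  invisible(path)
}
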