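# CDR / framework partition from AHo scheme numbering and per-loop backbone
# RMSD after framework superposition. The numbering itself (an HMM-based
# assignment) is consumed as an input table, not recomputed.

AHO_CDR_RANGES <- list(CDR1 = c(24L, 42L), CDR2 = c(57L, 76L), CDR3 = c(107L, 138L))

#' Assign CDR/framework regions from AHo scheme positions
#'
#' AHo positions run 1-149 per variable domain; CDR1 = 24-42, CDR2 = 57-76,
#' CDR3 = 107-138, everything else framework.
#'
#' @param numbering data.frame with columns `chain`, `resno`, `insert`
#'   (optional, default empty), `scheme_position` (integer 1-149) and `role`
#'   (`"heavy"` or `"light"`).
#' @return the table with a `region` column (`FR`, `CDR1`, `CDR2`, `CDR3`),
#'   class `abag_numbering`.
#' @export
assign_regions <- function(numbering) {
  req <- c("chain", "resno", "scheme_position", "role")
  if (!all(req %in% names(numbering)))
    stop("numbering table needs columns: ", paste(req, collapse = ", "))
  if (is.null(numbering$insert)) numbering$insert <- ""
  sp <- as.integer(numbering$scheme_position)
  if (any(is.na(sp) | sp < 1 | sp > 149))
    stop("scheme positions must be integers in 1..149")
  for (ch in unique(numbering$chain)) {
    s <- sp[numbering$chain == ch]
    if (anyDuplicated(s)) stop("duplicate scheme position in chain ", ch)
  }
  region <- rep("FR", length(sp))
  for (nm in names(AHO_CDR_RANGES)) {
    r <- AHO_CDR_RANGES[[nm]]
    region[sp >= r[1] & sp <= r[2]] <- nm
  }
  numbering$scheme_position <- sp
  numbering$region <- region
  class(numbering) <- c("abag_numbering", "data.frame")
  numbering
}

#' Read a numbering table (TSV: chain, resno, insert, scheme_position, role)
#' @param path file path.
#' @return an `abag_numbering` table with regions assigned.
#' @export
read_numbering <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = NA)
  if (!is.null(tab$insert)) tab$insert[is.na(tab$insert)] <- ""
  assign_regions(tab)
}

# Loop label: H1/H2/H3 or L1/L2/L3.
loop_label <- function(role, region) {
  paste0(ifelse(role == "heavy", "H", "L"), substr(region, 4, 4))
}

#' CDR loop backbone RMSD after framework superposition
#'
#' Superposes the model antibody onto the reference using the backbone
#' (N, CA, C, O) of all framework residues -- heavy and light jointly, as a
#' single rigid body -- then reports each CDR loop's backbone RMSD without
#' further superposition.
#'
#' @param model,reference `abag_structure` objects.
#' @param mapping an `abag_mapping` from [map_chains()] covering the antibody
#'   chains; numbering keys refer to the model antibody.
#' @param numbering an `abag_numbering` table (see [assign_regions()]).
#' @param loops loops to report; default all present.
#' @return An `abag_cdr_rmsd` list: named per-loop RMSDs (`H1`..`L3` as
#'   applicable) and `framework_rmsd`, all in Angstroms.
#' @export
cdr_rmsd <- function(model, reference, mapping, numbering, loops = NULL) {
  if (!inherits(numbering, "abag_numbering")) numbering <- assign_regions(numbering)
  ab <- mapping[mapping$role %in% c("heavy", "light"), , drop = FALSE]
  if (nrow(ab) == 0) stop("mapping has no antibody residues")
  nk <- res_key(numbering$chain, numbering$resno, numbering$insert)
  mk <- res_key(ab$model_chain, ab$model_resno, ab$model_insert)
  idx <- match(mk, nk)
  ab$region <- numbering$region[idx]
  ab$loop <- loop_label(numbering$role[idx], numbering$region[idx])
  ab <- ab[!is.na(ab$region), , drop = FALSE]

  fr <- ab[ab$region == "FR", , drop = FALSE]
  if (nrow(fr) < 3) stop("fewer than 3 mapped framework residues")
  frbb <- matched_backbone(model, reference, fr)
  if (nrow(frbb$model) < 3) stop("framework backbone too small for superposition")
  fit <- kabsch_superpose(frbb$model, frbb$ref)

  present <- sort(unique(ab$loop[ab$region != "FR"]))
  if (is.null(loops)) loops <- present
  missing <- setdiff(loops, present)
  if (length(missing))
    stop("loop(s) not resolved on both sides: ", paste(missing, collapse = ", "))
  out <- list()
  for (lp in loops) {
    sub <- ab[ab$region != "FR" & ab$loop == lp, , drop = FALSE]
    bb <- matched_backbone(model, reference, sub)
    if (nrow(bb$model) == 0) stop("loop ", lp, " has no matched backbone atoms")
    out[[lp]] <- rmsd(apply_transform(bb$model, fit$transform), bb$ref)
  }
  out$framework_rmsd <- fit$rmsd
  class(out) <- "abag_cdr_rmsd"
  out
}

#' @export
print.abag_cdr_rmsd <- function(x, ...) {
  v <- unlist(x)
  cat("CDR backbone RMSD (A):",
      paste(sprintf("%s=%.3f", names(v), v), collapse = "  "), "\n")
  invisible(x)
}

#' Antibody type of a partition
#'
#' @param partition an `abag_partition`.
#' @return `"Ab"` (heavy + light) or `"Nano"` (heavy-domain only, VHH).
#' @export
antibody_type <- function(partition) {
  stopifnot(inherits(partition, "abag_partition"))
  if (is.null(partition$light)) "Nano" else "Ab"
}
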