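# Model-vs-reference complex accuracy: native contacts, interface and ligand
# RMSDs, the DockQ composite, and CAPRI accuracy classes.
#
# Conventions (DockQ/CAPRI): fnat contacts at 5 A between heavy atoms;
# interface residues at 10 A for I-RMSD; backbone = N, CA, C, O; the antigen
# is the receptor and the antibody (heavy [+ light], pooled) is the ligand.

BACKBONE <- c("N", "CA", "C", "O")

#' Cross-partition residue contacts
#'
#' All antibody-antigen residue pairs with any non-hydrogen atom pair within
#' `cutoff` (inclusive).
#'
#' @param x an `abag_structure`.
#' @param partition an `abag_partition`.
#' @param cutoff distance cutoff in Angstroms (> 0).
#' @param backbone_only restrict to backbone atoms (used by tests; scoring
#'   uses all heavy atoms).
#' @return data.frame with the antibody residue key (`ab_chain`, `ab_resno`,
#'   `ab_insert`), antigen residue key (`ag_*`), and `min_dist`.
#' @export
find_contacts <- function(x, partition, cutoff = 5, backbone_only = FALSE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  ab <- atom_subset(x, chains = antibody_chains(partition), polymer = TRUE,
                    elety = if (backbone_only) BACKBONE else NULL)
  ag <- atom_subset(x, chains = partition$antigen, polymer = TRUE,
                    elety = if (backbone_only) BACKBONE else NULL)
  empty <- data.frame(ab_chain = character(), ab_resno = integer(),
                      ab_insert = character(), ag_chain = character(),
                      ag_resno = integer(), ag_insert = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE)
  if (nrow(ab) == 0 || nrow(ag) == 0) return(empty)
  hits <- atom_pairs_within(as.matrix(ab[, c("x", "y", "z")]),
                            as.matrix(ag[, c("x", "y", "z")]), cutoff)
  if (nrow(hits) == 0) return(empty)
  abk <- res_key(ab$chain, ab$resno, ab$insert)[hits$i]
  agk <- res_key(ag$chain, ag$resno, ag$insert)[hits$j]
  pk <- paste(abk, agk, sep = "|")
  md <- tapply(hits$d, pk, min)
  first <- match(names(md), pk)
  out <- data.frame(ab_chain = ab$chain[hits$i][first],
                    ab_resno = ab$resno[hits$i][first],
                    ab_insert = ab$insert[hits$i][first],
                    ag_chain = ag$chain[hits$j][first],
                    ag_resno = ag$resno[hits$j][first],
                    ag_insert = ag$insert[hits$j][first],
                    min_dist = as.numeric(md), stringsAsFactors = FALSE)
  out[order(out$ab_chain, out$ab_resno, out$ab_insert,
            out$ag_chain, out$ag_resno, out$ag_insert), , drop = FALSE]
}

# Atom pairs within cutoff, blocked to bound memory on large chains.
atom_pairs_within <- function(a, b, cutoff, block = 3000L) {
  res <- list()
  for (i0 in seq(1, nrow(a), by = block)) {
    ii <- i0:min(i0 + block - 1L, nrow(a))
    d2 <- outer(rowSums(a[ii, , drop = FALSE]^2), rowSums(b^2), `+`) -
      2 * (a[ii, , drop = FALSE] %*% t(b))
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit))
      res[[length(res) + 1L]] <- data.frame(
        i = ii[hit[, 1]], j = hit[, 2],
        d = sqrt(pmax(d2[hit], 0)))
  }
  if (!length(res)) data.frame(i = integer(), j = integer(), d = numeric())
  else do.call(rbind, res)
}

# Translate reference residue keys to model keys through a mapping (or back).
mapping_lookup <- function(mapping, from = c("ref", "model")) {
  from <- match.arg(from)
  if (from == "ref")
    setNames(res_key(mapping$model_chain, mapping$model_resno, mapping$model_insert),
             res_key(mapping$ref_chain, mapping$ref_resno, mapping$ref_insert))
  else
    setNames(res_key(mapping$ref_chain, mapping$ref_resno, mapping$ref_insert),
             res_key(mapping$model_chain, mapping$model_resno, mapping$model_insert))
}

#' Fraction of native contacts (fnat)
#'
#' Native contacts are reference antibody-antigen residue pairs at 5 A
#' (heavy atoms); fnat is the fraction of them whose mapped model residue
#' pair is also in contact in the model.
#'
#' @param model,reference `abag_structure` objects.
#' @param mapping an `abag_mapping` from [map_chains()].
#' @param partition model partition.
#' @param partition_ref reference partition (default: same chain ids).
#' @param cutoff contact cutoff, default 5 A.
#' @return fnat in \[0, 1\] with attributes `n_native` and `n_preserved`.
#' @export
fnat <- function(model, reference, mapping, partition,
                 partition_ref = partition, cutoff = 5) {
  native <- find_contacts(reference, partition_ref, cutoff)
  if (nrow(native) == 0) stop("no native interface: reference has zero contacts")
  modc <- find_contacts(model, partition, cutoff)
  lut <- mapping_lookup(mapping, "ref")
  nat_ab <- lut[res_key(native$ab_chain, native$ab_resno, native$ab_insert)]
  nat_ag <- lut[res_key(native$ag_chain, native$ag_resno, native$ag_insert)]
  nat_in_model <- paste(nat_ab, nat_ag, sep = "|")
  model_pairs <- paste(res_key(modc$ab_chain, modc$ab_resno, modc$ab_insert),
                       res_key(modc$ag_chain, modc$ag_resno, modc$ag_insert),
                       sep = "|")
  preserved <- sum(!is.na(nat_ab) & !is.na(nat_ag) & nat_in_model %in% model_pairs)
  out <- preserved / nrow(native)
  attr(out, "n_native") <- nrow(native)
  attr(out, "n_preserved") <- preserved
  out
}

# Matched backbone coordinate pairs for a set of reference residue keys.
# Atoms are matched by name within each mapped residue pair.
matched_backbone <- function(model, reference, mapping, ref_keys = NULL,
                             roles = NULL) {
  map <- mapping
  if (!is.null(roles)) map <- map[map$role %in% roles, , drop = FALSE]
  rk <- res_key(map$ref_chain, map$ref_resno, map$ref_insert)
  if (!is.null(ref_keys)) map <- map[rk %in% ref_keys, , drop = FALSE]
  am <- atom_subset(model, polymer = TRUE, elety = BACKBONE)
  ar <- atom_subset(reference, polymer = TRUE, elety = BACKBONE)
  amk <- paste(res_key(am$chain, am$resno, am$insert), trimws(am$elety))
  ark <- paste(res_key(ar$chain, ar$resno, ar$insert), trimws(ar$elety))
  mk <- res_key(map$model_chain, map$model_resno, map$model_insert)
  rk <- res_key(map$ref_chain, map$ref_resno, map$ref_insert)
  want_m <- paste(rep(mk, each = 4), BACKBONE)
  want_r <- paste(rep(rk, each = 4), BACKBONE)
  im <- match(want_m, amk); ir <- match(want_r, ark)
  ok <- !is.na(im) & !is.na(ir)
  list(model = as.matrix(am[im[ok], c("x", "y", "z")]),
       ref = as.matrix(ar[ir[ok], c("x", "y", "z")]),
       n_res = length(mk))
}

# Reference-defined interface residue keys (both sides) at `cutoff`.
reference_interface <- function(reference, partition_ref, cutoff = 10) {
  ic <- find_contacts(reference, partition_ref, cutoff)
  list(ab = unique(res_key(ic$ab_chain, ic$ab_resno, ic$ab_insert)),
       ag = unique(res_key(ic$ag_chain, ic$ag_resno, ic$ag_insert)))
}

#' Interface backbone RMSD (I-RMSD)
#'
#' Backbone RMSD over reference-defined interface residues (any heavy atom
#' within 10 A of the partner), after superposing the model onto the
#' reference using those same interface backbone atoms.
#'
#' @inheritParams fnat
#' @param interface_cutoff interface definition cutoff, default 10 A.
#' @return I-RMSD in Angstroms.
#' @export
i_rmsd <- function(model, reference, mapping, partition,
                   partition_ref = partition, interface_cutoff = 10) {
  iface <- reference_interface(reference, partition_ref, interface_cutoff)
  if (length(iface$ab) < 3 || length(iface$ag) < 3)
    stop("interface too small for superposition (need >= 3 residues per side)")
  bb <- matched_backbone(model, reference, mapping,
                         ref_keys = c(iface$ab, iface$ag))
  if (nrow(bb$model) < 3) stop("interface too small for superposition")
  kabsch_superpose(bb$model, bb$ref)$rmsd
}

#' Ligand backbone RMSD (L-RMSD)
#'
#' Superposes the model onto the reference by the receptor (antigen) backbone
#' and reports the backbone RMSD of the ligand (antibody) body.
#'
#' @inheritParams fnat
#' @return L-RMSD in Angstroms.
#' @export
l_rmsd <- function(model, reference, mapping, partition,
                   partition_ref = partition) {
  rec <- matched_backbone(model, reference, mapping, roles = "antigen")
  if (nrow(rec$model) < 3) stop("receptor backbone too small for superposition")
  fit <- kabsch_superpose(rec$model, rec$ref)
  lig <- matched_backbone(model, reference, mapping, roles = c("heavy", "light"))
  if (nrow(lig$model) < 1) stop("no mapped antibody backbone atoms")
  rmsd(apply_transform(lig$model, fit$transform), lig$ref)
}

#' DockQ score
#'
#' `(fnat + 1/(1+(i_rmsd/1.5)^2) + 1/(1+(l_rmsd/8.5)^2)) / 3`.
#'
#' @param fnat fraction of native contacts in \[0, 1\].
#' @param i_rmsd,l_rmsd RMSDs in Angstroms (>= 0).
#' @return DockQ in \[0, 1\].
#' @export
dockq_score <- function(fnat, i_rmsd, l_rmsd) {
  stopifnot(all(fnat >= 0 & fnat <= 1), all(i_rmsd >= 0), all(l_rmsd >= 0))
  (fnat + 1 / (1 + (i_rmsd / 1.5)^2) + 1 / (1 + (l_rmsd / 8.5)^2)) / 3
}

CAPRI_LEVELS <- c("Incorrect", "Acceptable", "Medium", "High")

#' CAPRI accuracy class
#'
#' High: fnat >= 0.5 and (I-RMSD <= 1.0 or L-RMSD <= 1.0); Medium:
#' fnat >= 0.3 and (I-RMSD <= 2.0 or L-RMSD <= 5.0); Acceptable:
#' fnat >= 0.1 and (I-RMSD <= 4.0 or L-RMSD <= 10.0); otherwise Incorrect.
#'
#' @inheritParams dockq_score
#' @return ordered factor with levels Incorrect < Acceptable < Medium < High.
#' @export
capri_class <- function(fnat, i_rmsd, l_rmsd) {
  n <- max(length(fnat), length(i_rmsd), length(l_rmsd))
  fnat <- rep_len(fnat, n); i_rmsd <- rep_len(i_rmsd, n); l_rmsd <- rep_len(l_rmsd, n)
  cls <- ifelse(fnat >= 0.5 & (i_rmsd <= 1.0 | l_rmsd <= 1.0), "High",
         ifelse(fnat >= 0.3 & (i_rmsd <= 2.0 | l_rmsd <= 5.0), "Medium",
         ifelse(fnat >= 0.1 & (i_rmsd <= 4.0 | l_rmsd <= 10.0), "Acceptable",
                "Incorrect")))
  factor(cls, levels = CAPRI_LEVELS, ordered = TRUE)
}

#' Score one model against its reference complex
#'
#' Composes [fnat()], [i_rmsd()], [l_rmsd()], [dockq_score()] and
#' [capri_class()] into a single `abag_dockscores` record.
#'
#' @inheritParams fnat
#' @param mapping optional precomputed mapping; built with [map_chains()]
#'   when `NULL`.
#' @return An `abag_dockscores` list: `fnat`, `i_rmsd`, `l_rmsd`, `dockq`,
#'   `capri_class`, plus native-contact bookkeeping.
#' @export
score_model <- function(model, reference, partition, partition_ref = partition,
                        mapping = NULL) {
  if (is.null(mapping))
    mapping <- map_chains(model, reference, partition, partition_ref)
  fn <- fnat(model, reference, mapping, partition, partition_ref)
  ir <- i_rmsd(model, reference, mapping, partition, partition_ref)
  lr <- l_rmsd(model, reference, mapping, partition, partition_ref)
  structure(list(fnat = as.numeric(fn), i_rmsd = ir, l_rmsd = lr,
                 dockq = dockq_score(as.numeric(fn), ir, lr),
                 capri_class = as.character(capri_class(as.numeric(fn), ir, lr)),
                 n_native = attr(fn, "n_native"),
                 n_preserved = attr(fn, "n_preserved")),
            class = "abag_dockscores")
}

#' @export
print.abag_dockscores <- function(x, ...) {
  cat(sprintf("DockQ %.3f  fnat %.3f (%d/%d)  I-RMSD %.2f A  L-RMSD %.2f A  [%s]\n",
              x$dockq, x$fnat, x$n_preserved, x$n_native,
              x$i_rmsd, x$l_rmsd, x$capri_class))
  invisible(x)
}
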