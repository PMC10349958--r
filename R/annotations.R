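# Per-complex annotations: interface glycan detection, antigen TM-score,
# and effective MSA depth (Neff) by greedy identity clustering.

#' Default saccharide component codes
#'
#' Common glycan residues seen in antibody-antigen structures. The set is an
#' argument everywhere it is used, so it can be extended to the full
#' chemical-component-dictionary saccharide class if needed.
#' @export
abag_saccharide_codes <- c("NAG", "NDG", "BMA", "MAN", "FUC", "GAL",
                           "GLC", "SIA", "XYS", "BGC")

#' Detect glycans at the antibody-antigen interface
#'
#' A HETATM residue is a hit when its component code is in the saccharide set
#' and any of its atoms lies within `cutoff` (default 4.5 A) of any antibody
#' non-hydrogen atom. Proximity to the antigen alone does not count.
#'
#' @param x the (experimentally determined) `abag_structure`, HETATMs retained.
#' @param partition an `abag_partition`.
#' @param cutoff distance cutoff in Angstroms.
#' @param saccharide_codes 3-letter component codes treated as saccharides.
#' @return list with `has_interface_glycan` (logical) and `hits` (data.frame:
#'   `chain`, `resno`, `insert`, `code`, `min_dist`).
#' @export
interface_glycans <- function(x, partition, cutoff = 4.5,
                              saccharide_codes = abag_saccharide_codes) {
  het <- atom_subset(x, polymer = FALSE, heavy_only = TRUE)
  het <- het[het$resid %in% saccharide_codes, , drop = FALSE]
  hits <- data.frame(chain = character(), resno = integer(),
                     insert = character(), code = character(),
                     min_dist = numeric(), stringsAsFactors = FALSE)
  ab <- atom_subset(x, chains = antibody_chains(partition), polymer = TRUE)
  if (nrow(het) > 0 && nrow(ab) > 0) {
    abxyz <- as.matrix(ab[, c("x", "y", "z")])
    key <- res_key(het$chain, het$resno, het$insert)
    for (k in unique(key)) {
      g <- het[key == k, , drop = FALSE]
      d2 <- outer(rowSums(as.matrix(g[, c("x", "y", "z")])^2),
                  rowSums(abxyz^2), `+`) -
        2 * as.matrix(g[, c("x", "y", "z")]) %*% t(abxyz)
      md <- sqrt(max(0, min(d2)))
      if (md <= cutoff)
        hits <- rbind(hits, data.frame(chain = g$chain[1], resno = g$resno[1],
                                       insert = g$insert[1], code = g$resid[1],
                                       min_dist = md, stringsAsFactors = FALSE))
    }
  }
  list(has_interface_glycan = nrow(hits) > 0, hits = hits)
}

#' TM-score between a modelled and a reference antigen
#'
#' `TM = max over superpositions of (1/L_target) * sum 1/(1 + (d_i/d0)^2)`
#' with `d0 = 1.24 (L_target - 15)^(1/3) - 1.8`, floored at 0.5 A, and
#' `L_target` the reference residue count. The maximisation seeds an
#' iterative refinement from the full-length Kabsch superposition and from
#' sliding windows of lengths 4, L/2 and L; each seed re-superposes on the
#' residues with `d_i < d0` until the selected set stabilises (at most 20
#' rounds), and the best score over all seeds and rounds is kept.
#'
#' @param model,reference `abag_structure` objects (antigen chains), or n x 3
#'   CA coordinate matrices.
#' @param mapping an `abag_mapping` restricted to the antigen role; ignored
#'   for coordinate-matrix input.
#' @return list with `tm`, `d0`, `n_aligned`, `normalizing_length`.
#' @export
tm_score <- function(model, reference, mapping = NULL) {
  if (inherits(model, "abag_structure")) {
    if (is.null(mapping)) stop("mapping required for structure input")
    map <- mapping[mapping$role == "antigen", , drop = FALSE]
    ca_m <- atom_subset(model, chains = unique(map$model_chain),
                        polymer = TRUE, elety = "CA")
    ca_r <- atom_subset(reference, chains = unique(map$ref_chain),
                        polymer = TRUE, elety = "CA")
    im <- match(res_key(map$model_chain, map$model_resno, map$model_insert),
                res_key(ca_m$chain, ca_m$resno, ca_m$insert))
    ir <- match(res_key(map$ref_chain, map$ref_resno, map$ref_insert),
                res_key(ca_r$chain, ca_r$resno, ca_r$insert))
    ok <- !is.na(im) & !is.na(ir)
    xm <- as.matrix(ca_m[im[ok], c("x", "y", "z")])
    xr <- as.matrix(ca_r[ir[ok], c("x", "y", "z")])
    l_target <- nrow(ca_r)
  } else {
    xm <- as_coord_matrix(model); xr <- as_coord_matrix(reference)
    l_target <- nrow(xr)
  }
  n <- nrow(xm)
  if (n < 5) stop("too few mapped residue pairs for TM-score (need >= 5)")
  d0 <- max(0.5, 1.24 * max(l_target - 15, 0)^(1/3) - 1.8)

  score_of <- function(tr) {
    d <- sqrt(rowSums((apply_transform(xm, tr) - xr)^2))
    sum(1 / (1 + (d / d0)^2)) / l_target
  }
  refine <- function(tr) {
    best <- score_of(tr)
    sel_prev <- NULL
    for (it in 1:20) {
      d <- sqrt(rowSums((apply_transform(xm, tr) - xr)^2))
      sel <- which(d < d0)
      if (length(sel) < 3) break
      if (!is.null(sel_prev) && identical(sel, sel_prev)) break
      sel_prev <- sel
      tr <- kabsch_superpose(xm[sel, , drop = FALSE], xr[sel, , drop = FALSE])$transform
      best <- max(best, score_of(tr))
    }
    best
  }
  best <- refine(kabsch_superpose(xm, xr)$transform)
  for (len in unique(pmin(n, c(4L, max(4L, n %/% 2L), n)))) {
    for (start in seq(1L, n - len + 1L)) {
      idx <- start:(start + len - 1L)
      tr <- tryCatch(
        kabsch_superpose(xm[idx, , drop = FALSE], xr[idx, , drop = FALSE])$transform,
        error = function(e) NULL)
      if (!is.null(tr)) best <- max(best, refine(tr))
    }
  }
  list(tm = min(1, best), d0 = d0, n_aligned = n, normalizing_length = l_target)
}

#' Read a multiple sequence alignment (FASTA or A3M)
#'
#' A3M insertion columns (lowercase letters) are removed on read, leaving an
#' equal-width alignment.
#'
#' @param path file path.
#' @param format `"auto"`, `"fasta"` or `"a3m"`.
#' @return named character vector of aligned rows.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "a3m")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "a3m") "a3m" else "fasta"
  ss <- Biostrings::readBStringSet(path)
  rows <- as.character(ss)
  if (format == "a3m") rows <- gsub("[a-z]", "", rows)
  rows
}

#' Effective number of sequences (Neff) by greedy identity clustering
#'
#' Gap characters are first replaced by `"U"`; rows are then clustered
#' greedily in order of decreasing ungapped length, each row joining the
#' first cluster whose representative (founder) it matches at or above the
#' identity cutoff, else founding a new cluster. Identity is the fraction of
#' matching positions over the full alignment width. Neff is the cluster
#' count at the 80% cutoff, following the CD-HIT-style depth measure.
#'
#' @param msa named character vector of equal-length aligned rows (or an
#'   `XStringSet`).
#' @param identity_cutoff clustering identity threshold, default 0.80.
#' @return An `abag_neff` list: `n_sequences`, `neff`, `identity_cutoff`,
#'   `cluster` (assignment per input row), `representatives` (row indices).
#' @export
neff <- function(msa, identity_cutoff = 0.80) {
  if (methods::is(msa, "XStringSet")) msa <- as.character(msa)
  msa <- as.character(msa)
  if (length(msa) == 0) stop("empty alignment")
  if (length(unique(nchar(msa))) != 1)
    stop("ragged alignment: rows differ in length")
  rows <- gsub("[-.]", "U", msa)
  width <- nchar(rows[1])
  chars <- do.call(rbind, strsplit(rows, ""))
  ungapped <- width - rowSums(chars == "U")
  ord <- order(-ungapped)  # stable: ties keep input order
  reps <- integer(0)
  cluster <- integer(length(rows))
  for (i in ord) {
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      ident <- sum(chars[i, ] == chars[reps[ci], ]) / width
      if (ident >= identity_cutoff) {
        cluster[i] <- ci; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  structure(list(n_sequences = length(rows), neff = length(reps),
                 identity_cutoff = identity_cutoff, cluster = cluster,
                 representatives = reps),
            class = "abag_neff")
}

#' @export
print.abag_neff <- function(x, ...) {
  cat("Neff:", x$neff, "clusters over", x$n_sequences,
      "sequences at", x$identity_cutoff * 100, "% identity\n")
  invisible(x)
}
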