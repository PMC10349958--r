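# Atom table columns shared by every structure object. Coordinates are
# double-precision Angstroms; `b` carries per-atom pLDDT for predicted models.
ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "eleno",
               "element", "x", "y", "z", "o", "b", "alt", "het")

new_structure <- function(atoms, source_format = "pdb", label = "") {
  stopifnot(is.data.frame(atoms), all(ATOM_COLS %in% names(atoms)))
  structure(list(atoms = atoms[, ATOM_COLS],
                 source_format = source_format,
                 label = label),
            class = "abag_structure")
}

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses ATOM/HETATM records into a flat atom table wrapped in an
#' `abag_structure` object. Hydrogens are retained but flagged by element;
#' alternate locations are reduced to the highest-occupancy conformer
#' (ties broken by first occurrence). The temperature-factor column is kept
#' as-is: predicted models carry per-residue pLDDT there.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param label free-text label attached to the object.
#' @return An `abag_structure`: list with `atoms` (data.frame), `source_format`,
#'   `label`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("could not parse ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: ", path)
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert) | at$insert == " ", "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    eleno = as.integer(at$eleno),
    element = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             substr(trimws(at$elety), 1, 1), trimws(at$elesy))),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    o = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    b = ifelse(is.na(at$b), 0, as.numeric(at$b)),
    alt = ifelse(is.na(at$alt) | at$alt == " ", "", as.character(at$alt)),
    het = as.character(at$type) == "HETATM",
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- ""
  atoms <- collapse_altloc(atoms)
  if (!any(!atoms$het)) stop("no polymer residues in ", path)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  new_structure(atoms, source_format = if (format == "cif") "mmcif" else "pdb",
                label = label)
}

# Keep one conformer per (residue, atom name): highest occupancy, tie -> first.
collapse_altloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), factor(key, levels = unique(key))),
                        function(i) i[which.max(atoms$o[i])]), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Write a structure in PDB format
#'
#' @param x an `abag_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "abag_structure"))
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = ifelse(a$chain == "", " ", a$chain),
                   insert = ifelse(a$insert == "", "", a$insert),
                   o = a$o, b = a$b, elesy = a$element)
  invisible(path)
}

#' @export
print.abag_structure <- function(x, ...) {
  a <- x$atoms
  pol <- a[!a$het, ]
  cat("abag_structure", if (nzchar(x$label)) paste0("'", x$label, "'"), "\n")
  cat("  chains:", paste(unique(a$chain), collapse = ", "), "\n")
  cat("  polymer residues:", nrow(unique(pol[, c("chain", "resno", "insert")])),
      " hetero residues:",
      nrow(unique(a[a$het, c("chain", "resno", "insert")])), "\n")
  cat("  atoms:", nrow(a), "\n")
  invisible(x)
}

structure_chains <- function(x) unique(x$atoms$chain)

# Residue table (one row per residue) for selected chains.
residue_table <- function(x, chains = NULL, polymer_only = TRUE) {
  a <- x$atoms
  if (polymer_only) a <- a[!a$het, , drop = FALSE]
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  unique(a[, c("chain", "resno", "insert", "resid")])
}

res_key <- function(chain, resno, insert) paste(chain, resno, insert, sep = ":")

# Atom subset helper; excludes hydrogens/deuterium by element unless asked.
atom_subset <- function(x, chains = NULL, polymer = NULL, heavy_only = TRUE,
                        elety = NULL) {
  a <- x$atoms
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  if (!is.null(polymer)) a <- a[a$het != polymer, , drop = FALSE]
  if (heavy_only) a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  if (!is.null(elety)) a <- a[trimws(a$elety) %in% elety, , drop = FALSE]
  a
}

#' Partition a complex into antibody and antigen chains
#'
#' Antibody-antigen complexes carry either a heavy+light antibody (Ab) or a
#' single heavy-domain nanobody/VHH (Nano). The partition records which chains
#' play which role and validates disjointness.
#'
#' @param x an `abag_structure`.
#' @param heavy heavy-chain id.
#' @param light light-chain id, or `NULL` for a nanobody.
#' @param antigens character vector of antigen chain ids (non-empty).
#' @return An `abag_partition`: list with `heavy`, `light`, `antigen`.
#' @export
partition_complex <- function(x, heavy, light = NULL, antigens) {
  stopifnot(inherits(x, "abag_structure"))
  if (length(light) == 0) light <- NULL
  if (length(antigens) < 1) stop("at least one antigen chain required")
  if (is.null(heavy) && !is.null(light))
    stop("light chain present without a heavy chain")
  ab <- c(heavy, light)
  chains <- structure_chains(x)
  missing <- setdiff(c(ab, antigens), chains)
  if (length(missing))
    stop("chains not in structure: ", paste(missing, collapse = ", "))
  if (length(intersect(ab, antigens)))
    stop("antibody and antigen chain sets overlap: ",
         paste(intersect(ab, antigens), collapse = ", "))
  structure(list(heavy = heavy, light = light, antigen = antigens),
            class = "abag_partition")
}

antibody_chains <- function(partition) c(partition$heavy, partition$light)

#' @export
print.abag_partition <- function(x, ...) {
  cat("abag_partition: heavy =", x$heavy %||% "-",
      " light =", x$light %||% "-",
      " antigen =", paste(x$antigen, collapse = ","),
      " [", antibody_type(x), "]\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-letter sequence plus residue keys for a chain's polymer residues.
chain_sequence <- function(x, chain) {
  rt <- residue_table(x, chains = chain)
  if (nrow(rt) == 0) return(list(seq = "", res = rt))
  one <- bio3d::aa321(rt$resid)
  one[is.na(one) | one == "X" | nchar(one) != 1] <- "X"
  list(seq = paste(one, collapse = ""), res = rt)
}

#' Build model-to-reference residue correspondences
#'
#' Aligns the one-letter sequence of each role-matched chain pair (heavy,
#' light, each antigen chain) with a global alignment (match +1, mismatch 0,
#' gap -1) and returns the aligned residue-key pairs. Multi-copy antigens are
#' resolved by best-identity assignment. Residues absent from either structure
#' (for instance not experimentally resolved in the reference) simply cannot
#' appear in the mapping.
#'
#' @param model,reference `abag_structure` objects.
#' @param partition partition of the model.
#' @param partition_ref partition of the reference; defaults to `partition`.
#' @param min_identity identity floor below which a chain pair is rejected as
#'   probably mis-assigned.
#' @return An `abag_mapping` data.frame with one row per residue pair and
#'   columns `role`, `model_chain`, `model_resno`, `model_insert`,
#'   `ref_chain`, `ref_resno`, `ref_insert`.
#' @export
map_chains <- function(model, reference, partition, partition_ref = partition,
                       min_identity = 0.6) {
  pairs <- list()
  add_role <- function(role, mc, rc) {
    pairs[[length(pairs) + 1L]] <<- list(role = role, model = mc, ref = rc)
  }
  if (!is.null(partition$heavy)) add_role("heavy", partition$heavy, partition_ref$heavy)
  if (!is.null(partition$light)) add_role("light", partition$light, partition_ref$light)
  # antigen copies: best-identity greedy assignment
  mag <- partition$antigen; rag <- partition_ref$antigen
  if (length(mag) == 1 && length(rag) == 1) {
    add_role("antigen", mag, rag)
  } else {
    idm <- matrix(NA_real_, length(mag), length(rag))
    for (i in seq_along(mag)) for (j in seq_along(rag)) {
      idm[i, j] <- align_identity(chain_sequence(model, mag[i])$seq,
                                  chain_sequence(reference, rag[j])$seq)
    }
    while (any(!is.na(idm))) {
      ij <- which(idm == max(idm, na.rm = TRUE), arr.ind = TRUE)[1, ]
      add_role("antigen", mag[ij[1]], rag[ij[2]])
      idm[ij[1], ] <- NA; idm[, ij[2]] <- NA
    }
  }
  out <- list()
  for (p in pairs) {
    sm <- chain_sequence(model, p$model)
    sr <- chain_sequence(reference, p$ref)
    al <- align_pair(sm$seq, sr$seq)
    if (al$identity < min_identity)
      stop("chain mapping ", p$model, " -> ", p$ref, " (", p$role,
           ") has identity ", round(al$identity, 3), " below floor ",
           min_identity, "; probable chain mis-assignment")
    if (nrow(al$pairs) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      role = p$role,
      model_chain = p$model,
      model_resno = sm$res$resno[al$pairs$i],
      model_insert = sm$res$insert[al$pairs$i],
      ref_chain = p$ref,
      ref_resno = sr$res$resno[al$pairs$j],
      ref_insert = sr$res$insert[al$pairs$j],
      stringsAsFactors = FALSE)
  }
  m <- do.call(rbind, out)
  class(m) <- c("abag_mapping", "data.frame")
  m
}

#' Extract per-residue pLDDT from a predicted model
#'
#' Predictors write a uniform per-residue pLDDT into the temperature-factor
#' column, so the CA atom is taken as the residue representative; residues
#' lacking a CA fall back to the mean over their non-hydrogen atoms.
#'
#' @param x an `abag_structure` holding a predicted model.
#' @return data.frame with `chain`, `resno`, `insert`, `plddt` (one row per
#'   polymer residue, values in \[0, 100\]).
#' @export
extract_plddt <- function(x) {
  stopifnot(inherits(x, "abag_structure"))
  a <- atom_subset(x, polymer = TRUE, heavy_only = TRUE)
  if (nrow(a) == 0) stop("no polymer residues")
  key <- res_key(a$chain, a$resno, a$insert)
  uk <- unique(key)
  plddt <- vapply(uk, function(k) {
    rows <- a[key == k, , drop = FALSE]
    ca <- rows[trimws(rows$elety) == "CA", , drop = FALSE]
    if (nrow(ca) >= 1) ca$b[1] else mean(rows$b)
  }, numeric(1))
  if (all(plddt == 0))
    warning("all temperature factors are zero; pLDDT may be absent")
  first <- match(uk, key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], plddt = unname(plddt),
             stringsAsFactors = FALSE)
}
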