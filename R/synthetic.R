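# Synthetic complex / decoy / MSA generators with planted ground truth.
#
# The toy complex is an idealized backbone-only (N, CA, C, O) antibody-like
# fold: serpentine strands in a plane standing in for the framework sheet,
# with AHo-numbered segments covering all three CDR ranges, and an antigen
# slab placed 4.4 A beneath it so a genuine 4-5 A contact interface exists.
# Decoys move the antibody as a rigid body, so a pure translation of
# magnitude m has L-RMSD exactly m -- the planted truth every scoring test
# checks against.

# AHo scheme segments populated by the toy heavy/light chains
TOY_SEGMENTS <- list(FR1 = 10:23, CDR1 = 27:38, FR2 = 45:56, CDR2 = 60:71,
                     FR3 = 80:100, CDR3 = 110:130, FR4 = 140:149)

# Serpentine CA grid: rows of `per_row` residues, 3.8 A along, 4.8 A across.
serpentine_ca <- function(n, per_row = 15, origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1L
  row <- i %/% per_row
  col <- i %% per_row
  col <- ifelse(row %% 2 == 1, per_row - 1 - col, col)  # snake back
  cbind(origin[1] + 3.8 * col, origin[2] + 4.8 * row, origin[3] + 0 * i)
}

# Expand CA positions to backbone atoms with fixed offsets (slightly
# out-of-plane so point sets are never exactly planar/collinear).
backbone_atoms <- function(ca, chain, resno, resid, b = 90, het = FALSE) {
  offs <- list(N = c(-1.2, 0.5, 0.3), CA = c(0, 0, 0),
               C = c(1.2, 0.5, -0.3), O = c(1.4, 1.6, -0.5))
  rows <- lapply(seq_len(nrow(ca)), function(i) {
    do.call(rbind, lapply(names(offs), function(nm) {
      p <- ca[i, ] + offs[[nm]]
      data.frame(chain = chain, resno = resno[i], insert = "",
                 resid = resid[i], elety = nm, eleno = 0L,
                 element = substr(nm, 1, 1), x = p[1], y = p[2], z = p[3],
                 o = 1, b = b, alt = "", het = het, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

random_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

#' Build a synthetic antibody-antigen complex with known geometry
#'
#' @param seed RNG seed; the build is bit-reproducible given (config, seed).
#' @param config list overriding defaults: `light` (logical, add a light
#'   chain -> Ab instead of Nano), `antigen_len` (residues, default 40),
#'   `jitter` (uniform coordinate jitter half-width in Angstroms, default
#'   0.15), `gap` (antibody-antigen plane separation, default 4.4 A),
#'   `plddt` (reference temperature-factor fill, default 90).
#' @return An `abag_synthetic_complex`: `reference` (`abag_structure`),
#'   `partition`, `numbering` (AHo table with all three CDR ranges
#'   populated), `seed`, `config`.
#' @export
build_toy_complex <- function(seed = 1, config = list()) {
  cfg <- utils::modifyList(list(light = FALSE, antigen_len = 40L,
                                jitter = 0.15, gap = 4.4, plddt = 90),
                           config)
  set.seed(seed)
  scheme <- unlist(TOY_SEGMENTS, use.names = FALSE)
  region_of <- rep(names(TOY_SEGMENTS), lengths(TOY_SEGMENTS))
  n_fr <- sum(startsWith(region_of, "FR"))
  if (n_fr < 3) stop("config produces fewer than 3 framework residues")
  nh <- length(scheme)
  heavy_seq <- strsplit(random_sequence(nh), "")[[1]]
  heavy <- backbone_atoms(serpentine_ca(nh), "H", seq_len(nh),
                          bio3d::aa123(heavy_seq), b = cfg$plddt)
  numbering <- data.frame(chain = "H", resno = seq_len(nh), insert = "",
                          scheme_position = scheme, role = "heavy",
                          stringsAsFactors = FALSE)
  atoms <- heavy
  light_id <- NULL
  if (isTRUE(cfg$light)) {
    nl <- length(scheme)
    light_seq <- strsplit(random_sequence(nl), "")[[1]]
    light <- backbone_atoms(serpentine_ca(nl, origin = c(2, 1, 7.5)), "L",
                            seq_len(nl), bio3d::aa123(light_seq), b = cfg$plddt)
    atoms <- rbind(atoms, light)
    numbering <- rbind(numbering,
                       data.frame(chain = "L", resno = seq_len(nl), insert = "",
                                  scheme_position = scheme, role = "light",
                                  stringsAsFactors = FALSE))
    light_id <- "L"
  }
  na <- as.integer(cfg$antigen_len)
  ag_seq <- strsplit(random_sequence(na), "")[[1]]
  # center the antigen slab under the heavy chain, one gap-width below
  hx <- atoms[atoms$chain == "H", c("x", "y")]
  ag_ca <- serpentine_ca(na, per_row = 10)
  ag_ca <- sweep(ag_ca, 2, c(colMeans(ag_ca[, 1:2]) - colMeans(hx), cfg$gap))
  antigen <- backbone_atoms(ag_ca, "A", seq_len(na), bio3d::aa123(ag_seq),
                            b = cfg$plddt)
  atoms <- rbind(atoms, antigen)
  atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
    matrix(runif(3 * nrow(atoms), -cfg$jitter, cfg$jitter), ncol = 3)
  atoms$eleno <- seq_len(nrow(atoms))
  ref <- new_structure(atoms, source_format = "pdb",
                       label = sprintf("toy_complex_seed%d", seed))
  part <- partition_complex(ref, heavy = "H", light = light_id, antigens = "A")
  structure(list(reference = ref, partition = part,
                 numbering = assign_regions(numbering),
                 seed = seed, config = cfg),
            class = "abag_synthetic_complex")
}

#' Decoy generation settings
#'
#' @param translations translation magnitudes in Angstroms (one decoy each).
#' @param rotations rotation magnitudes in degrees (one decoy each).
#' @param direction unit translation direction (normalised internally).
#' @param rotation_axis axis for rotation decoys, through the antibody
#'   centroid.
#' @param loop_noise_sd Gaussian noise SD added to CDR loop atoms (A).
#' @param plddt planted pLDDT model: `base - slope * planted_error + noise`,
#'   clipped to \[0, 100\].
#' @param confidence planted pTM/ipTM model (same linear-with-noise form).
#' @param seed RNG seed for the noise terms.
#' @return list of class `abag_decoy_config`.
#' @export
decoy_config <- function(translations = c(0, 2, 6, 15, 40),
                         rotations = numeric(0),
                         direction = c(1, 0, 0),
                         rotation_axis = c(0, 0, 1),
                         loop_noise_sd = 0,
                         plddt = list(base = 95, slope = 1.5, noise_sd = 2),
                         confidence = list(base_iptm = 0.85, slope = 0.018,
                                           noise_sd = 0.02, ptm_offset = 0.05),
                         seed = 1) {
  stopifnot(all(translations >= 0), all(rotations >= 0), loop_noise_sd >= 0,
            plddt$noise_sd >= 0)
  structure(list(translations = translations, rotations = rotations,
                 direction = direction / sqrt(sum(direction^2)),
                 rotation_axis = rotation_axis, loop_noise_sd = loop_noise_sd,
                 plddt = plddt, confidence = confidence, seed = seed),
            class = "abag_decoy_config")
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate rigid-body decoys with planted ground truth
#'
#' Each decoy is the reference with the antibody moved rigidly (translation
#' or rotation about its centroid), optional Gaussian noise on CDR loop
#' atoms, and pLDDT written into the temperature factors following the
#' planted linear-with-noise accuracy model. For noise-free pure
#' translations the planted L-RMSD equals the translation magnitude exactly.
#'
#' @param cplx an `abag_synthetic_complex`.
#' @param config an `abag_decoy_config`.
#' @return An `abag_decoy_set`: list of decoys, each with `structure`,
#'   `label`, `planted` (kind, magnitude, expected_l_rmsd, error) and
#'   `confidence` (ptm, iptm, model_confidence).
#' @export
make_decoys <- function(cplx, config = decoy_config()) {
  stopifnot(inherits(cplx, "abag_synthetic_complex"))
  set.seed(config$seed)
  ref <- cplx$reference
  ab_chains <- antibody_chains(cplx$partition)
  ab_idx <- which(ref$atoms$chain %in% ab_chains & !ref$atoms$het)
  ab_xyz <- as.matrix(ref$atoms[ab_idx, c("x", "y", "z")])
  centroid <- colMeans(ab_xyz)
  specs <- c(lapply(config$translations, function(m) list(kind = "translation", mag = m)),
             lapply(config$rotations, function(m) list(kind = "rotation", mag = m)))
  nk <- res_key(cplx$numbering$chain, cplx$numbering$resno, cplx$numbering$insert)
  loop_keys <- nk[cplx$numbering$region != "FR"]
  decoys <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    dec <- ref
    if (sp$kind == "translation") {
      shift <- sp$mag * config$direction
      new_xyz <- sweep(ab_xyz, 2, shift, `+`)
    } else {
      rot <- rotation_about_axis(config$rotation_axis, sp$mag)
      new_xyz <- sweep(sweep(ab_xyz, 2, centroid) %*% t(rot), 2, centroid, `+`)
    }
    dec$atoms[ab_idx, c("x", "y", "z")] <- new_xyz
    noisy <- config$loop_noise_sd > 0
    if (noisy) {
      li <- which(res_key(dec$atoms$chain, dec$atoms$resno, dec$atoms$insert)
                  %in% loop_keys)
      dec$atoms[li, c("x", "y", "z")] <- dec$atoms[li, c("x", "y", "z")] +
        matrix(rnorm(3 * length(li), 0, config$loop_noise_sd), ncol = 3)
    }
    # planted error drives the pLDDT/confidence models
    err <- if (sp$kind == "translation") sp$mag else {
      ca <- which(trimws(ref$atoms$elety[ab_idx]) == "CA")
      sqrt(mean(rowSums((new_xyz[ca, , drop = FALSE] -
                           ab_xyz[ca, , drop = FALSE])^2)))
    }
    pl <- config$plddt
    rt <- residue_table(dec)
    res_plddt <- clip(pl$base - pl$slope * err +
                        rnorm(nrow(rt), 0, pl$noise_sd), 0, 100)
    dec$atoms$b <- res_plddt[match(
      res_key(dec$atoms$chain, dec$atoms$resno, dec$atoms$insert),
      res_key(rt$chain, rt$resno, rt$insert))]
    dec$atoms$b[is.na(dec$atoms$b)] <- 50
    cf <- config$confidence
    iptm <- clip(cf$base_iptm - cf$slope * err + rnorm(1, 0, cf$noise_sd), 0, 1)
    ptm <- clip(iptm + cf$ptm_offset, 0, 1)
    dec$label <- sprintf("decoy_%03d", i)
    decoys[[i]] <- list(
      structure = dec, label = dec$label,
      planted = list(kind = sp$kind, magnitude = sp$mag,
                     expected_l_rmsd = if (sp$kind == "translation" && !noisy)
                       sp$mag else NA_real_,
                     error = err),
      confidence = list(ptm = ptm, iptm = iptm,
                        model_confidence = model_confidence(ptm, iptm)))
  }
  structure(decoys, class = "abag_decoy_set")
}

#' Generate an MSA with planted cluster structure
#'
#' Cluster founders share a common background and differ from each other on
#' a fixed block of positions overwritten with a cluster-specific letter, so
#' every between-cluster identity is exactly `between_identity`; members
#' mutate a subset of that block, giving identity exactly `within_identity`
#' to their founder. The planted cluster count is therefore recoverable by
#' any clustering at a cutoff strictly between the two identities.
#'
#' @param n_clusters number of planted clusters (<= 10).
#' @param members_per_cluster rows per cluster (founder included).
#' @param within_identity member-to-founder identity (fraction).
#' @param between_identity founder-to-founder identity (fraction).
#' @param length alignment width.
#' @param seed RNG seed.
#' @return named character vector of rows, founders first in each cluster.
#' @export
make_msa <- function(n_clusters, members_per_cluster, within_identity = 0.9,
                     between_identity = 0.5, length = 100, seed = 1) {
  set.seed(seed)
  if (within_identity <= between_identity)
    stop("infeasible identity targets: within must exceed between")
  n_between <- round((1 - between_identity) * length)
  n_within <- round((1 - within_identity) * length)
  if (n_clusters > 1 && n_between == 0)
    stop("infeasible identity targets: between-cluster block is empty at this length")
  if (n_within > n_between)
    stop("infeasible identity targets at this length")
  # targets must be representable at this alignment width
  if (abs((1 - n_within / length) - within_identity) > 0.05 ||
      abs((1 - n_between / length) - between_identity) > 0.05)
    stop("infeasible identity targets: not representable at length ", length)
  cluster_letters <- strsplit("LMNPQRSTVW", "")[[1]]
  if (n_clusters > length(cluster_letters)) stop("too many clusters (max 10)")
  background <- sample(strsplit("ACDEFGHIK", "")[[1]], length, replace = TRUE)
  block <- seq_len(n_between)
  rows <- character(0)
  for (k in seq_len(n_clusters)) {
    founder <- background
    founder[block] <- cluster_letters[k]
    rows <- c(rows, setNames(paste(founder, collapse = ""),
                             sprintf("c%d_founder", k)))
    for (j in seq_len(max(0, members_per_cluster - 1))) {
      member <- founder
      if (n_within > 0)
        member[sample(block, n_within)] <- "Y"
      rows <- c(rows, setNames(paste(member, collapse = ""),
                               sprintf("c%d_m%d", k, j)))
    }
  }
  rows
}

#' Attach a hetero (glycan) residue at a controlled distance from the antibody
#'
#' Places a compact saccharide-like atom cluster along the +x direction from
#' the antibody's extreme atom, so the closest glycan atom sits within
#' 0.05 A of `target_distance` from the nearest antibody non-hydrogen atom.
#'
#' @param x an `abag_structure`.
#' @param partition an `abag_partition` for `x`.
#' @param code 3-letter component code (e.g. `"NAG"`).
#' @param target_distance desired minimum distance in Angstroms (> 0).
#' @param seed RNG seed (reserved; placement is deterministic).
#' @return the structure with the hetero residue appended (chain `"X"`).
#' @export
attach_glycan <- function(x, partition, code = "NAG", target_distance = 4.0,
                          seed = 1) {
  if (target_distance <= 0) stop("target_distance must be positive")
  ab <- atom_subset(x, chains = antibody_chains(partition), polymer = TRUE)
  anchor <- unlist(ab[which.max(ab$x), c("x", "y", "z")])
  offs <- rbind(c(0, 0, 0), c(0.8, 1.2, 0), c(1.9, 1.5, 0.4), c(2.6, 0.6, 0),
                c(2.0, -0.8, -0.3), c(0.9, -1.0, 0.2))
  abxyz <- as.matrix(ab[, c("x", "y", "z")])
  place <- function(dist) sweep(offs, 2, anchor + c(dist, 0, 0), `+`)
  d <- target_distance
  for (it in 1:10) {
    g <- place(d)
    md <- sqrt(min(outer(rowSums(g^2), rowSums(abxyz^2), `+`) - 2 * g %*% t(abxyz)))
    if (abs(md - target_distance) <= 0.05) break
    d <- d + (target_distance - md)
  }
  if (abs(md - target_distance) > 0.05)
    stop("could not place glycan at ", target_distance, " A")
  gat <- data.frame(chain = "X", resno = 1L, insert = "", resid = code,
                    elety = c("C1", "C2", "C3", "C4", "C5", "O5"), eleno = 0L,
                    element = c(rep("C", 5), "O"),
                    x = g[, 1], y = g[, 2], z = g[, 3], o = 1, b = 0,
                    alt = "", het = TRUE, stringsAsFactors = FALSE)
  x$atoms <- rbind(x$atoms, gat)
  x$atoms$eleno <- seq_len(nrow(x$atoms))
  x
}

#' Generate a full evaluation cohort with planted truth
#'
#' Builds `n_complexes` toy complexes (alternating Ab and Nano, every fifth
#' carrying an interface glycan), generates `decoys_per_complex` decoys each
#' with translation magnitudes drawn from a pool spanning all CAPRI classes,
#' scores every decoy against its reference, computes I-pLDDT and model
#' confidence, and ranks models within each complex.
#'
#' @param n_complexes number of complexes (>= 1).
#' @param decoys_per_complex models per complex.
#' @param config overrides passed to [decoy_config()] (per-complex seeds are
#'   derived from `seed`).
#' @param seed master seed.
#' @param out_dir when non-NULL, writes references/decoys (PDB), numbering
#'   (TSV), confidence records and `manifest.csv` under this directory.
#' @return An `abag_cohort`: list with `manifest` (one row per model) and
#'   `seed`.
#' @export
make_cohort <- function(n_complexes = 10, decoys_per_complex = 25,
                        config = list(), seed = 1, out_dir = NULL) {
  stopifnot(n_complexes >= 1, decoys_per_complex >= 1)
  pool <- c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 15, 20, 30, 40)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(n_complexes)) {
    cseed <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
    cplx <- build_toy_complex(seed = cseed,
                              config = list(light = i %% 2 == 0))
    if (i %% 5 == 0)
      cplx$reference <- attach_glycan(cplx$reference, cplx$partition,
                                      target_distance = 4.0)
    glyc <- interface_glycans(cplx$reference, cplx$partition)
    set.seed(cseed + 1L)
    mags <- sample(pool, decoys_per_complex, replace = TRUE)
    dcfg <- do.call(decoy_config,
                    utils::modifyList(list(translations = mags,
                                           seed = cseed + 2L), config))
    decoys <- make_decoys(cplx, dcfg)
    mapping <- map_chains(cplx$reference, cplx$reference, cplx$partition)
    cid <- sprintf("complex_%03d", i)
    crow <- lapply(decoys, function(d) {
      sc <- score_model(d$structure, cplx$reference, cplx$partition,
                        mapping = mapping)
      data.frame(complex_id = cid, model = d$label,
                 fnat = sc$fnat, i_rmsd = sc$i_rmsd, l_rmsd = sc$l_rmsd,
                 dockq = sc$dockq, capri_class = sc$capri_class,
                 iplddt = interface_plddt(d$structure, cplx$partition),
                 ptm = d$confidence$ptm, iptm = d$confidence$iptm,
                 model_confidence = d$confidence$model_confidence,
                 has_interface_glycan = glyc$has_interface_glycan,
                 antibody_type = antibody_type(cplx$partition),
                 planted_kind = d$planted$kind,
                 planted_magnitude = d$planted$magnitude,
                 seed = cseed,
                 stringsAsFactors = FALSE)
    })
    ranked <- rank_models(do.call(rbind, crow))
    rows[[i]] <- ranked
    if (!is.null(out_dir)) {
      cdir <- file.path(out_dir, cid)
      dir.create(cdir, showWarnings = FALSE)
      write_structure(cplx$reference, file.path(cdir, "reference.pdb"))
      utils::write.table(cplx$numbering, file.path(cdir, "numbering.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      for (d in decoys) {
        write_structure(d$structure, file.path(cdir, paste0(d$label, ".pdb")))
        write_confidence_record(d$confidence,
                                file.path(cdir, paste0(d$label, "_scores.txt")))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  structure(list(manifest = manifest, seed = seed), class = "abag_cohort")
}
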