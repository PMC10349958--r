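# Independent brute-force oracles. These deliberately avoid the package's
# scoring code paths: contacts by direct atom-pair enumeration, superposition
# through bio3d's quaternion-based fit, AUC by pair enumeration, clustering
# by pairwise-identity connected components.

oracle_atoms <- function(x, chains) {
  a <- x$atoms
  a <- a[a$chain %in% chains & !a$het & !(a$element %in% c("H", "D")), ]
  a
}

# All cross-partition residue pairs with any heavy-atom pair <= cutoff.
oracle_contacts <- function(x, partition, cutoff) {
  ab <- oracle_atoms(x, c(partition$heavy, partition$light))
  ag <- oracle_atoms(x, partition$antigen)
  ab_res <- unique(ab[, c("chain", "resno", "insert")])
  out <- character(0)
  for (i in seq_len(nrow(ab_res))) {
    sel <- ab$chain == ab_res$chain[i] & ab$resno == ab_res$resno[i] &
      ab$insert == ab_res$insert[i]
    axyz <- as.matrix(ab[sel, c("x", "y", "z")])
    d <- sqrt(outer(rowSums(axyz^2), rowSums(as.matrix(ag[, c("x", "y", "z")])^2), `+`) -
                2 * axyz %*% t(as.matrix(ag[, c("x", "y", "z")])))
    mind <- apply(d, 2, min)
    agk <- paste(ag$chain, ag$resno, ag$insert, sep = ":")
    hit <- tapply(mind, agk, min)
    hit <- hit[hit <= cutoff + 1e-12]
    if (length(hit))
      out <- c(out, paste(paste(ab_res$chain[i], ab_res$resno[i],
                                ab_res$insert[i], sep = ":"),
                          names(hit), sep = "|"))
  }
  sort(unique(out))
}

oracle_fnat <- function(model, reference, partition, cutoff = 5) {
  native <- oracle_contacts(reference, partition, cutoff)
  modelc <- oracle_contacts(model, partition, cutoff)
  # toy decoys share residue numbering, so keys map one-to-one
  list(n_native = length(native), n_preserved = sum(native %in% modelc),
       fnat = sum(native %in% modelc) / length(native))
}

# Backbone coordinate matrix for a set of residue keys (N, CA, C, O order).
oracle_backbone <- function(x, chains, keys = NULL) {
  a <- oracle_atoms(x, chains)
  a <- a[trimws(a$elety) %in% c("N", "CA", "C", "O"), ]
  a$key <- paste(a$chain, a$resno, a$insert, sep = ":")
  if (!is.null(keys)) a <- a[a$key %in% keys, ]
  a <- a[order(a$key, match(trimws(a$elety), c("N", "CA", "C", "O"))), ]
  list(xyz = as.matrix(a[, c("x", "y", "z")]),
       id = paste(a$key, trimws(a$elety)))
}

# Optimal-superposition RMSD through bio3d (independent of the package's
# Kabsch implementation).
oracle_super_rmsd <- function(mobile, target) {
  moved <- bio3d::fit.xyz(as.numeric(t(target)), as.numeric(t(mobile)),
                          fixed.inds = seq_len(3 * nrow(target)),
                          mobile.inds = seq_len(3 * nrow(mobile)))
  mm <- matrix(moved, ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums((mm - target)^2)))
}

oracle_irmsd <- function(model, reference, partition, cutoff = 10) {
  iface <- oracle_contacts(reference, partition, cutoff)
  keys <- unique(unlist(strsplit(iface, "|", fixed = TRUE)))
  chains <- c(partition$heavy, partition$light, partition$antigen)
  rb <- oracle_backbone(reference, chains, keys)
  mb <- oracle_backbone(model, chains, keys)
  shared <- intersect(rb$id, mb$id)
  oracle_super_rmsd(mb$xyz[match(shared, mb$id), ],
                    rb$xyz[match(shared, rb$id), ])
}

oracle_lrmsd <- function(model, reference, partition) {
  chains <- c(partition$heavy, partition$light, partition$antigen)
  rb <- oracle_backbone(reference, chains)
  mb <- oracle_backbone(model, chains)
  shared <- intersect(rb$id, mb$id)
  rxyz <- rb$xyz[match(shared, rb$id), ]
  mxyz <- mb$xyz[match(shared, mb$id), ]
  is_ag <- sub(":.*", "", shared) %in% partition$antigen
  moved <- bio3d::fit.xyz(as.numeric(t(rxyz)), as.numeric(t(mxyz)),
                          fixed.inds = which(rep(is_ag, each = 3)),
                          mobile.inds = which(rep(is_ag, each = 3)))
  mm <- matrix(moved, ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums((mm[!is_ag, ] - rxyz[!is_ag, ])^2)))
}

# AUC by explicit positive-negative pair enumeration.
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Cluster count as connected components of the pairwise-identity graph.
oracle_neff_components <- function(rows, cutoff = 0.8) {
  rows <- gsub("[-.]", "U", rows)
  ch <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(ch)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- mean(ch[i, ] == ch[j, ]) >= cutoff
  comp <- rep(0L, n); k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  k
}

# Random proper rigid transform (for invariance properties).
random_transform <- function() {
  axis <- rnorm(3)
  tr <- list(rotation = abagqc:::rotation_about_axis(axis, runif(1, 0, 360)),
             translation = rnorm(3, 0, 20))
  class(tr) <- "abag_transform"
  tr
}
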