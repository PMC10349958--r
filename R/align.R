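# Pairwise sequence alignment helpers (Biostrings-backed).
#
# Global alignment scoring is deliberately simple -- match +1, mismatch 0,
# gap -1 -- because it is only used to build residue correspondences and
# percent identities between near-identical chains, not homology detection.

sub_matrix <- function(seqs, match = 1, mismatch = 0) {
  alpha <- sort(unique(c(strsplit(paste(seqs, collapse = ""), "")[[1]],
                         strsplit("ACDEFGHIKLMNPQRSTVWYXU", "")[[1]])))
  m <- matrix(mismatch, length(alpha), length(alpha),
              dimnames = list(alpha, alpha))
  diag(m) <- match
  m
}

# Global alignment; returns aligned index pairs and identity
# (matches / aligned residue pairs).
align_pair <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = sub_matrix(c(seq_a, seq_b)),
    gapOpening = 0, gapExtension = 1)
  ga <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- cumsum(ga != "-"); ib <- cumsum(gb != "-")
  both <- ga != "-" & gb != "-"
  pairs <- data.frame(i = ia[both], j = ib[both])
  nmatch <- sum(ga[both] == gb[both])
  identity <- if (nrow(pairs) == 0) 0 else nmatch / nrow(pairs)
  list(pairs = pairs, identity = identity, n_match = nmatch,
       n_aligned = nrow(pairs))
}

align_identity <- function(seq_a, seq_b) align_pair(seq_a, seq_b)$identity

# Local alignment probe standing in for a default-parameter BLAST hit:
# TRUE when some local alignment of length >= min_len reaches >= min_identity.
local_match <- function(seq_a, seq_b, min_len = 30, min_identity = 0.3) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "local",
    substitutionMatrix = sub_matrix(c(seq_a, seq_b), match = 2, mismatch = -1),
    gapOpening = 2, gapExtension = 1)
  ga <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  both <- ga != "-" & gb != "-"
  n <- sum(both)
  n >= min_len && n > 0 && sum(ga[both] == gb[both]) / n >= min_identity
}
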