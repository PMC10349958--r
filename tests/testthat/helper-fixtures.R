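# Programmatic fixtures: tiny structures assembled directly from atom rows.

atom_row <- function(chain, resno, elety, x, y, z, resid = "ALA", b = 0,
                     o = 1, het = FALSE, element = substr(trimws(elety), 1, 1),
                     insert = "", alt = "") {
  data.frame(chain = chain, resno = as.integer(resno), insert = insert,
             resid = resid, elety = elety, eleno = 0L, element = element,
             x = x, y = y, z = z, o = o, b = b, alt = alt, het = het,
             stringsAsFactors = FALSE)
}

mini_structure <- function(rows, label = "mini") {
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  abagqc:::new_structure(atoms, source_format = "pdb", label = label)
}

# Two-chain mini complex: n-residue CA-only chains facing each other at
# z-separation `gap`; residue i of each chain sits at x = 4 * i.
mini_complex <- function(n = 6, gap = 4, b_ab = 80, b_ag = 80) {
  rows <- c(
    lapply(seq_len(n), function(i)
      atom_row("H", i, "CA", 4 * i, 0, 0, b = b_ab)),
    lapply(seq_len(n), function(i)
      atom_row("A", i, "CA", 4 * i, 0, -gap, b = b_ag)))
  mini_structure(rows)
}

translate_chain <- function(x, chain, shift) {
  sel <- x$atoms$chain %in% chain
  x$atoms[sel, c("x", "y", "z")] <-
    sweep(x$atoms[sel, c("x", "y", "z")], 2, shift, `+`)
  x
}

drop_residues <- function(x, chain, resnos) {
  keep <- !(x$atoms$chain == chain & x$atoms$resno %in% resnos)
  x$atoms <- x$atoms[keep, , drop = FALSE]
  x
}

expect_transform_close <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$rotation - b$rotation)), tol)
  expect_lt(max(abs(a$translation - b$translation)), tol)
}
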