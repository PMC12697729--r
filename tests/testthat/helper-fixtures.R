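# Shared fixture builders; everything is generated in code.

# Backbone anchors (N, CA, C, O) of the middle residue of a short helix.
helper_backbone <- function() {
  s <- make_ideal_helix(4)
  a <- s$atoms[s$atoms$res_index == 2, ]
  as.matrix(a[match(c("N", "CA", "C", "O"), a$atom_name), c("x", "y", "z")])
}

# A protein chain whose residues are all 14-slot designed blocks encoding
# the given residue types on ideal-helix backbones.
helper_design_chain <- function(types, chain_id = "A") {
  src <- make_ideal_helix(max(4, length(types)))
  rows <- lapply(seq_along(types), function(i) {
    a <- src$atoms[src$atoms$res_index == i, ]
    bb <- as.matrix(a[match(c("N", "CA", "C", "O"), a$atom_name), c("x", "y", "z")])
    blk <- encode_residue(types[i], bb)
    data.frame(chain = chain_id, res_index = i, res_name = "DSN",
               atom_name = blk$atom_names, element = "X",
               x = blk$coords[, 1], y = blk$coords[, 2], z = blk$coords[, 3],
               is_virtual = blk$is_virtual, is_design = TRUE,
               stringsAsFactors = FALSE)
  })
  bk_structure(do.call(rbind, rows))
}

# Straight CA-only pseudo-chain (an idealised extended strand).
helper_strand <- function(n, spacing = 3.5) {
  bk_structure(data.frame(
    chain = "A", res_index = seq_len(n), res_name = "ALA",
    atom_name = "CA", element = "C",
    x = spacing * seq_len(n), y = 0, z = 0, stringsAsFactors = FALSE))
}

# Fixed-width PDB text: single-chain 3-residue poly-ALA with CB atoms
# (15 atoms in total).
helper_polyala_pdb <- function() {
  h <- make_ideal_helix(4)
  a <- h$atoms[h$atoms$res_index <= 3, ]
  lines <- character(0)
  serial <- 0L
  for (i in 1:3) {
    res <- a[a$res_index == i, ]
    ca <- unlist(res[res$atom_name == "CA", c("x", "y", "z")])
    res <- rbind(res, within(res[res$atom_name == "CA", ], {
      atom_name <- "CB"; element <- "C"; x <- ca[1] + 1.1; y <- ca[2] + 1.1
    }))
    for (j in seq_len(nrow(res))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, res$atom_name[j], "ALA", "A", i,
        res$x[j], res$y[j], res$z[j], 1, 0, res$element[j]))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

# 7-atom HETATM ligand with a small CONECT bond set.
helper_ligand_pdb <- function() {
  xyz <- cbind(seq_len(7) * 1.5, 0, 0)
  lines <- sprintf(
    "HETATM%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    1:7, paste0("C", 1:7), "LIG", "L", 1, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, "C")
  conect <- sprintf("CONECT%5d%5d", 1:6, 2:7)
  paste(c(lines, conect, "END"), collapse = "\n")
}

helper_rotate <- function(structure, seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- binderkit:::quat_to_rot(q)
  s <- structure
  xyz <- coords(s) %*% R
  s$atoms$x <- xyz[, 1] + 5; s$atoms$y <- xyz[, 2] - 2; s$atoms$z <- xyz[, 3] + 1
  s
}
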