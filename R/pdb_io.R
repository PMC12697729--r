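# Fixed-width PDB reading and writing. A purpose-built parser is used so that
# the codec and design-spec layers get string-level I/O, CONECT bond
# round-tripping, and parse errors that name the offending line.

#' Read a structure from PDB-format text
#'
#' Parses ATOM/HETATM/TER/CONECT records. Chains are split on the chain
#' identifier; HETATM groups become ligand entities with a single
#' pseudo-residue; CONECT records become covalent bonds. Hydrogens are
#' dropped (heavy-atom model) and for alternate locations only the
#' highest-occupancy conformer is kept.
#'
#' @param text a single PDB-format string, or a character vector of lines.
#' @return a [bk_structure()].
#' @examples
#' s <- make_ideal_helix(5)
#' s2 <- read_pdb(write_pdb(s))
#' n_atoms(s2) == n_atoms(s)
#' @export
read_pdb <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else as.character(text)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("read_pdb: no atoms")

  idx <- which(is_atom)
  ln <- lines[idx]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(ln, from, to)))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("read_pdb: malformed %s field at line %d", what, idx[bad[1]]))
    v
  }
  atoms <- data.frame(
    record = trimws(substr(ln, 1, 6)),
    serial = as.integer(num(7, 11, "serial")),
    atom_name = trimws(substr(ln, 13, 16)),
    alt_loc = substr(ln, 17, 17),
    res_name = trimws(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    res_index = as.integer(num(23, 26, "residue number")),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occupancy = suppressWarnings(as.numeric(substr(ln, 55, 60))),
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  el <- trimws(substr(ln, 77, 78))
  atoms$element <- ifelse(el == "", .element_of(atoms$atom_name), toupper(el))

  # heavy-atom model
  atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
  if (!nrow(atoms)) stop("read_pdb: no atoms")

  # alternate locations: keep the highest-occupancy conformer
  if (any(atoms$alt_loc != " ")) {
    key <- paste(atoms$chain, atoms$res_index, atoms$atom_name)
    ord <- order(key, -atoms$occupancy)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$res_index, atoms$atom_name)), , drop = FALSE]
    atoms <- atoms[order(atoms$chain, atoms$res_index, atoms$serial), , drop = FALSE]
  }

  is_het <- atoms$record == "HETATM" & !atoms$res_name %in% c(.AA3, "UNK", .DESIGN_RESNAME)
  atoms$is_design <- atoms$res_name == .DESIGN_RESNAME
  atoms$is_virtual <- atoms$atom_name == "VRT"
  atoms$charge <- 0L

  chains <- unique(atoms$chain)
  chain_tab <- data.frame(
    chain_id = chains,
    polymer_class = vapply(chains, function(id) {
      sel <- atoms$chain == id
      if (all(is_het[sel])) "ligand" else infer_polymer_class(atoms$res_name[sel])
    }, character(1)),
    stringsAsFactors = FALSE
  )
  # ligand entities: single pseudo-residue holding all atoms
  for (id in chain_tab$chain_id[chain_tab$polymer_class == "ligand"])
    atoms$res_index[atoms$chain == id] <- 1L

  # CONECT records -> bonds (serials mapped to row indices)
  bonds <- data.frame(a1 = integer(0), a2 = integer(0))
  cidx <- which(rec == "CONECT")
  if (length(cidx)) {
    pairs <- list()
    for (k in cidx) {
      flds <- suppressWarnings(as.integer(
        substring(lines[k], seq(7, 27, by = 5), seq(11, 31, by = 5))))
      flds <- flds[!is.na(flds)]
      if (length(flds) < 2)
        stop(sprintf("read_pdb: malformed CONECT record at line %d", k))
      a1 <- match(flds[1], atoms$serial)
      for (s2 in flds[-1]) {
        a2 <- match(s2, atoms$serial)
        if (is.na(a1) || is.na(a2))
          stop(sprintf("read_pdb: CONECT references unknown serial at line %d", k))
        pairs[[length(pairs) + 1L]] <- c(a1, a2)
      }
    }
    m <- do.call(rbind, pairs)
    bonds <- data.frame(a1 = m[, 1], a2 = m[, 2])
  }
  atoms$record <- NULL; atoms$alt_loc <- NULL; atoms$occupancy <- NULL
  bk_structure(atoms, chain_tab, bonds)
}

#' Write a structure as PDB-format text
#'
#' Emits fixed-width ATOM/HETATM records (TER after each polymer chain) and
#' symmetric CONECT records for the bond list. Virtual atoms of designed
#' residues are excluded unless `include_virtual = TRUE`.
#'
#' @param structure a [bk_structure()].
#' @param include_virtual serialize virtual placeholder atoms too (debug).
#' @return a single PDB-format string.
#' @export
write_pdb <- function(structure, include_virtual = FALSE) {
  a <- structure$atoms
  keep <- if (include_virtual) rep(TRUE, nrow(a)) else !a$is_virtual
  a <- a[keep, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (any(abs(xyz) >= 10000) || any(xyz <= -1000))
    stop("write_pdb: coordinates exceed PDB field width")
  serial <- seq_len(nrow(a))
  old_row <- which(keep)           # original row -> for bond remapping
  remap <- match(seq_len(nrow(structure$atoms)), old_row)

  lig <- structure$chains$chain_id[structure$chains$polymer_class == "ligand"]
  out <- character(0)
  for (ci in seq_len(nrow(structure$chains))) {
    id <- structure$chains$chain_id[ci]
    sel <- which(a$chain == id)
    if (!length(sel)) next
    rec <- if (id %in% lig) "HETATM" else "ATOM"
    for (j in sel) {
      nm <- a$atom_name[j]
      nm_fmt <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      out <- c(out, sprintf(
        "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, serial[j], nm_fmt, a$res_name[j], id, a$res_index[j],
        a$x[j], a$y[j], a$z[j], 1, 0, a$element[j]
      ))
    }
    if (!(id %in% lig)) {
      jlast <- sel[length(sel)]
      out <- c(out, sprintf("TER   %5d      %-3s %1s%4d",
                            serial[jlast] + 1L, a$res_name[jlast], id, a$res_index[jlast]))
    }
  }
  b <- structure$bonds
  if (nrow(b)) {
    b1 <- remap[b$a1]; b2 <- remap[b$a2]
    ok <- !is.na(b1) & !is.na(b2)
    for (k in which(ok)) {
      out <- c(out,
               sprintf("CONECT%5d%5d", serial[b1[k]], serial[b2[k]]),
               sprintf("CONECT%5d%5d", serial[b2[k]], serial[b1[k]]))
    }
  }
  paste0(paste(c(out, "END"), collapse = "\n"), "\n")
}
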