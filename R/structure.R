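# All-atom structure model. A structure is stored bio3d-style as a flat atom
# table plus a chain table and a bond list; entities, residues and tokens are
# views over that table.

#' Construct an all-atom structure
#'
#' The core container shared by every other component. Atoms live in a single
#' data frame; chains (entities) carry a polymer class; covalent bonds are
#' pairs of atom row indices. Ligand entities hold all their atoms in one
#' pseudo-residue.
#'
#' @param atoms data.frame with columns `chain`, `res_index`, `res_name`,
#'   `atom_name`, `element`, `x`, `y`, `z` and optionally `charge`,
#'   `is_virtual`, `is_design`, `serial`.
#' @param chains data.frame with columns `chain_id`, `polymer_class`
#'   (`"protein"`, `"dna"`, `"rna"` or `"ligand"`). Inferred from residue
#'   names when omitted.
#' @param bonds data.frame with integer columns `a1`, `a2` (atom row indices),
#'   or NULL.
#' @return object of class `bk_structure`.
#' @export
bk_structure <- function(atoms, chains = NULL, bonds = NULL) {
  req <- c("chain", "res_index", "res_name", "atom_name", "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  atoms$chain <- as.character(atoms$chain)
  atoms$res_index <- as.integer(atoms$res_index)
  n <- nrow(atoms)
  if (is.null(atoms$charge)) atoms$charge <- rep(0L, n)
  if (is.null(atoms$is_virtual)) atoms$is_virtual <- rep(FALSE, n)
  if (is.null(atoms$is_design)) atoms$is_design <- rep(FALSE, n)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  if (is.null(chains)) {
    ids <- unique(atoms$chain)
    chains <- data.frame(
      chain_id = ids,
      polymer_class = vapply(ids, function(id) {
        infer_polymer_class(atoms$res_name[atoms$chain == id])
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(chains$chain_id)) stop("chain_ids must be unique")
  if (!all(atoms$chain %in% chains$chain_id)) stop("atom references unknown chain")
  if (is.null(bonds)) bonds <- data.frame(a1 = integer(0), a2 = integer(0))
  if (nrow(bonds)) {
    bad <- bonds$a1 < 1 | bonds$a1 > nrow(atoms) | bonds$a2 < 1 | bonds$a2 > nrow(atoms)
    if (any(bad)) stop("bond endpoints must resolve to existing atoms")
    # store each bond once, a1 < a2
    swap <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[swap]; bonds$a1[swap] <- bonds$a2[swap]; bonds$a2[swap] <- tmp
    bonds <- unique(bonds[bonds$a1 != bonds$a2, , drop = FALSE])
  }
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, chains = chains, bonds = bonds),
    class = "bk_structure"
  )
}

infer_polymer_class <- function(res_names) {
  u <- unique(res_names)
  if (all(u %in% c(.AA3, "UNK", .DESIGN_RESNAME))) return("protein")
  if (all(u %in% .NUC_DNA)) return("dna")
  if (all(u %in% .NUC_RNA)) return("rna")
  "ligand"
}

#' @export
print.bk_structure <- function(x, ...) {
  cat(sprintf(
    "bk_structure: %d chain(s), %d residue(s), %d atom(s), %d bond(s)\n",
    nrow(x$chains), n_residues(x), nrow(x$atoms), nrow(x$bonds)
  ))
  for (i in seq_len(nrow(x$chains))) {
    id <- x$chains$chain_id[i]
    sel <- x$atoms$chain == id
    cat(sprintf("  chain %s [%s]: %d residues, %d atoms\n", id,
                x$chains$polymer_class[i],
                length(unique(x$atoms$res_index[sel])), sum(sel)))
  }
  invisible(x)
}

#' Number of atoms / residues in a structure
#' @param structure a `bk_structure`.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' @rdname n_atoms
#' @export
n_residues <- function(structure) {
  nrow(unique(structure$atoms[, c("chain", "res_index")]))
}

#' Atom coordinates as a matrix
#' @param structure a `bk_structure`.
#' @param sel optional logical or integer row selection.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(structure, sel = NULL) {
  a <- structure$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

`coords<-` <- function(structure, value) {
  value <- as_coord_matrix(value)
  stopifnot(nrow(value) == nrow(structure$atoms))
  structure$atoms$x <- value[, 1]
  structure$atoms$y <- value[, 2]
  structure$atoms$z <- value[, 3]
  structure
}

#' Extract a single chain as a new structure
#' @param structure a `bk_structure`.
#' @param chain_id chain identifier.
#' @export
get_chain <- function(structure, chain_id) {
  if (!chain_id %in% structure$chains$chain_id)
    stop("unknown chain: ", chain_id)
  keep <- which(structure$atoms$chain == chain_id)
  remap <- match(seq_len(nrow(structure$atoms)), keep)
  b <- structure$bonds
  b <- b[b$a1 %in% keep & b$a2 %in% keep, , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  bk_structure(structure$atoms[keep, , drop = FALSE],
               structure$chains[structure$chains$chain_id == chain_id, , drop = FALSE],
               b)
}

#' One-letter amino-acid sequence of a protein chain
#' @param structure a `bk_structure`.
#' @param chain_id chain identifier; default first protein chain.
#' @export
chain_sequence <- function(structure, chain_id = NULL) {
  if (is.null(chain_id)) {
    chain_id <- structure$chains$chain_id[structure$chains$polymer_class == "protein"][1]
    if (is.na(chain_id)) stop("no protein chain in structure")
  }
  a <- structure$atoms[structure$atoms$chain == chain_id, ]
  rn <- a$res_name[!duplicated(a$res_index)]
  one <- .AA3_TO_1[rn]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Tokenize a structure
#'
#' Proteins and nucleic acids are tokenized one token per residue; small
#' molecules one token per atom. Token indices are consecutive from 0 and the
#' tokens partition the atom set.
#'
#' @param structure a `bk_structure`.
#' @return list with `tokens` (data.frame: `token_index`, `chain`,
#'   `res_index`, `kind`, `is_design`, `n_atoms`) and `atom_token`
#'   (per-atom token index, 0-based).
#' @examples
#' s <- make_ideal_helix(10)
#' length(tokenize(s)$tokens$token_index)  # 10
#' @export
tokenize <- function(structure) {
  a <- structure$atoms
  atom_token <- integer(nrow(a))
  rows <- list()
  idx <- 0L
  for (i in seq_len(nrow(structure$chains))) {
    id <- structure$chains$chain_id[i]
    cls <- structure$chains$polymer_class[i]
    sel <- which(a$chain == id)
    if (cls == "ligand") {
      for (j in sel) {
        atom_token[j] <- idx
        rows[[length(rows) + 1L]] <- data.frame(
          token_index = idx, chain = id, res_index = a$res_index[j],
          kind = "atom-token", is_design = a$is_design[j], n_atoms = 1L,
          stringsAsFactors = FALSE
        )
        idx <- idx + 1L
      }
    } else {
      for (ri in unique(a$res_index[sel])) {
        j <- sel[a$res_index[sel] == ri]
        atom_token[j] <- idx
        rows[[length(rows) + 1L]] <- data.frame(
          token_index = idx, chain = id, res_index = ri,
          kind = "residue-token", is_design = any(a$is_design[j]),
          n_atoms = length(j), stringsAsFactors = FALSE
        )
        idx <- idx + 1L
      }
    }
  }
  tokens <- if (length(rows)) do.call(rbind, rows) else
    data.frame(token_index = integer(0), chain = character(0),
               res_index = integer(0), kind = character(0),
               is_design = logical(0), n_atoms = integer(0))
  list(tokens = tokens, atom_token = atom_token)
}
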