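# Physics-based design/target metrics used by the filtering stage.
# All criteria operate on heavy atoms only; every threshold is an argument.

# Donor/acceptor/charged atom annotation for one structure's atom table.
annotate_polar <- function(atoms, his_positive = FALSE) {
  key <- paste0(atoms$res_name, ":", atoms$atom_name)
  is_bb_n <- atoms$atom_name == "N" & atoms$res_name != "PRO"
  donor_key <- ifelse(is_bb_n, "*:N", ifelse(key %in% names(.HB_DONORS), key, NA))
  acceptor <- (atoms$atom_name == "O") | key %in% setdiff(.HB_ACCEPTORS, "*:O")
  neg <- key %in% .NEG_ATOMS
  pos <- key %in% c(.POS_ATOMS, if (his_positive) .POS_ATOMS_HIS)
  list(donor_key = donor_key, acceptor = acceptor, neg = neg, pos = pos)
}

# Antecedent coordinates for donors (needed for the donor angle); NA rows
# for donors whose antecedent atom is absent.
donor_antecedents <- function(atoms, donor_rows, donor_key) {
  t(vapply(donor_rows, function(i) {
    ante <- .HB_DONORS[[donor_key[i]]]
    j <- which(atoms$chain == atoms$chain[i] &
                 atoms$res_index == atoms$res_index[i] &
                 atoms$atom_name == ante)
    if (length(j) != 1L) return(c(NA_real_, NA_real_, NA_real_))
    unlist(atoms[j, c("x", "y", "z")], use.names = FALSE)
  }, numeric(3)))
}

#' Count interface hydrogen bonds
#'
#' Counts unique donor-acceptor heavy-atom pairs between two chains that
#' satisfy the geometric criterion: N/O donor (with an available proton) to
#' N/O acceptor distance at most `cutoff`, and
#' antecedent-donor-acceptor angle at least `min_angle` degrees. A pair is
#' counted once even if it qualifies in both directions.
#'
#' @param structure a [bk_structure()] containing both chains.
#' @param design_chain,target_chain chain identifiers.
#' @param cutoff donor-acceptor distance cutoff in Angstrom.
#' @param min_angle minimum antecedent-donor-acceptor angle in degrees.
#' @return integer count.
#' @export
hydrogen_bonds <- function(structure, design_chain = "A", target_chain = NULL,
                           cutoff = 3.5, min_angle = 120) {
  ab <- split_interface(structure, design_chain, target_chain)
  keys <- c(qualifying_hbond_pairs(ab$a, ab$b, cutoff, min_angle),
            qualifying_hbond_pairs(ab$b, ab$a, cutoff, min_angle))
  length(unique(keys))
}

# Canonical atom-pair keys of qualifying donor(da) -> acceptor(db) bonds.
qualifying_hbond_pairs <- function(da, db, cutoff, min_angle) {
  pa <- annotate_polar(da); pb <- annotate_polar(db)
  don <- which(!is.na(pa$donor_key))
  acc <- which(pb$acceptor)
  if (!length(don) || !length(acc)) return(character(0))
  ante <- donor_antecedents(da, don, pa$donor_key)
  dxyz <- as.matrix(da[don, c("x", "y", "z")])
  axyz <- as.matrix(db[acc, c("x", "y", "z")])
  atom_id <- function(tab, rows) paste(tab$chain[rows], tab$res_index[rows],
                                       tab$atom_name[rows], sep = ":")
  keys <- character(0)
  for (i in seq_along(don)) {
    if (anyNA(ante[i, ])) next
    dd <- sqrt(colSums((t(axyz) - dxyz[i, ])^2))
    for (j in which(dd <= cutoff)) {
      v1 <- ante[i, ] - dxyz[i, ]
      v2 <- axyz[j, ] - dxyz[i, ]
      ang <- acos(pmin(pmax(sum(v1 * v2) / (vnorm(v1) * vnorm(v2)), -1), 1)) * 180 / pi
      if (ang < min_angle) next
      pair <- sort(c(atom_id(da, don[i]), atom_id(db, acc[j])))
      keys <- c(keys, paste(pair, collapse = "|"))
    }
  }
  keys
}

split_interface <- function(structure, design_chain, target_chain) {
  a <- structure$atoms[!structure$atoms$is_virtual, , drop = FALSE]
  if (is.null(target_chain)) {
    ta <- a[a$chain != design_chain, , drop = FALSE]
  } else {
    ta <- a[a$chain %in% target_chain, , drop = FALSE]
  }
  da <- a[a$chain == design_chain, , drop = FALSE]
  if (!nrow(da)) stop("unknown or empty design chain: ", design_chain)
  list(a = da, b = ta)
}

#' Count interface salt bridges
#'
#' Counts opposite-charge residue-group pairs across the interface:
#' carboxylate oxygens (ASP OD1/OD2, GLU OE1/OE2) against lysine NZ or
#' arginine NE/NH guanidinium nitrogens (histidine ring nitrogens only when
#' `his_positive = TRUE`), with any charged-atom pair within `cutoff`.
#' Each (negative residue, positive residue) pair counts once.
#'
#' @inheritParams hydrogen_bonds
#' @param cutoff charged-atom distance cutoff in Angstrom.
#' @param his_positive treat histidine as protonated.
#' @return integer count.
#' @export
salt_bridges <- function(structure, design_chain = "A", target_chain = NULL,
                         cutoff = 4.0, his_positive = FALSE) {
  ab <- split_interface(structure, design_chain, target_chain)
  n <- 0L
  for (dir in 1:2) {
    da <- if (dir == 1) ab$a else ab$b
    db <- if (dir == 1) ab$b else ab$a
    pa <- annotate_polar(da, his_positive)
    pb <- annotate_polar(db, his_positive)
    neg <- which(pa$neg); pos <- which(pb$pos)
    if (!length(neg) || !length(pos)) next
    nx <- as.matrix(da[neg, c("x", "y", "z")])
    px <- as.matrix(db[pos, c("x", "y", "z")])
    pairs <- expand.grid(i = seq_along(neg), j = seq_along(pos))
    d <- sqrt(rowSums((nx[pairs$i, , drop = FALSE] - px[pairs$j, , drop = FALSE])^2))
    hit <- pairs[d <= cutoff, , drop = FALSE]
    if (nrow(hit)) {
      grp <- unique(data.frame(
        rn = paste(da$chain[neg[hit$i]], da$res_index[neg[hit$i]]),
        rp = paste(db$chain[pos[hit$j]], db$res_index[pos[hit$j]])
      ))
      n <- n + nrow(grp)
    }
  }
  n
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical rolling-probe SASA: each heavy atom is covered with a
#' deterministic Fibonacci lattice of test points on its solvent-expanded
#' sphere; points not buried inside any neighbour contribute area.
#'
#' @param structure a [bk_structure()] (virtual atoms ignored).
#' @param probe_radius solvent probe radius in Angstrom.
#' @param n_points sphere points per atom.
#' @param per_atom return the per-atom area vector instead of the total.
#' @return total SASA in square Angstrom (or per-atom vector).
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960,
                 per_atom = FALSE) {
  a <- structure$atoms[!structure$atoms$is_virtual, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- .VDW_RADII[a$element]
  rad[is.na(rad)] <- .VDW_RADII[["X"]]
  r <- rad + probe_radius
  n <- nrow(xyz)
  sp <- sphere_points(n_points)
  areas <- numeric(n)
  # neighbour lists via cutoff on the maximal contact distance
  maxr <- max(r)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (r[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < r[i] + r[nb]]
    pts <- sweep(sp * r[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj <- colSums((t(pts) - xyz[j, ])^2)
        free <- free & dj >= r[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    areas[i] <- 4 * pi * r[i]^2 * frac
  }
  if (per_atom) areas else sum(areas)
}

#' Buried surface area of an interface
#'
#' `BSA = SASA(design) + SASA(target) - SASA(complex)`, symmetric in the two
#' sides.
#'
#' @inheritParams hydrogen_bonds
#' @param probe_radius,n_points passed to [sasa()].
#' @return buried area in square Angstrom.
#' @export
buried_surface_area <- function(structure, design_chain = "A",
                                target_chain = NULL, probe_radius = 1.4,
                                n_points = 960) {
  ab <- split_interface(structure, design_chain, target_chain)
  sa <- sasa(bk_structure(ab$a), probe_radius, n_points)
  sb <- sasa(bk_structure(ab$b), probe_radius, n_points)
  sab <- sasa(bk_structure(rbind(ab$a, ab$b)), probe_radius, n_points)
  sa + sb - sab
}

#' Area of the largest hydrophobic surface patch
#'
#' Builds the solvent-exposed atom set of a chain, keeps nonpolar (C/S)
#' atoms of hydrophobic residues (ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO),
#' connects exposed atoms whose centres lie within the adjacency distance,
#' and returns the summed exposed area of the largest connected component.
#'
#' @param structure a [bk_structure()].
#' @param chain_id chain to analyse (default: whole structure).
#' @param exposure_min minimum per-atom exposed area (square Angstrom) to
#'   count as surface.
#' @param adjacency patch-graph connection distance in Angstrom.
#' @param probe_radius,n_points passed to [sasa()].
#' @return largest patch area in square Angstrom (0 if none).
#' @export
largest_hydrophobic_patch <- function(structure, chain_id = NULL,
                                      exposure_min = 5, adjacency = 6,
                                      probe_radius = 1.4, n_points = 960) {
  s <- if (is.null(chain_id)) structure else get_chain(structure, chain_id)
  a <- s$atoms[!s$atoms$is_virtual, , drop = FALSE]
  ar <- sasa(bk_structure(a), probe_radius, n_points, per_atom = TRUE)
  sel <- which(a$res_name %in% .HYDROPHOBIC_RES &
                 a$element %in% c("C", "S") & ar >= exposure_min)
  if (!length(sel)) return(0)
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  m <- length(sel)
  # union-find over the adjacency graph
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(m - 1)) {
    d <- sqrt(colSums((t(xyz[(i + 1):m, , drop = FALSE]) - xyz[i, ])^2))
    for (j in which(d <= adjacency)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(m), find, integer(1))
  max(tapply(ar[sel], comp, sum))
}

#' Sequence-based solubility score
#'
#' Deterministic, length-normalised composite in which higher values signal
#' better solubility:
#' `0.5 * (1 - normalised GRAVY) + 0.5 * |net charge| / length`, where GRAVY
#' is the Kyte-Doolittle mean hydropathy rescaled to `[0, 1]` and net charge
#' counts Asp/Glu as -1 and Lys/Arg as +1. A documented stand-in for an
#' external solubility predictor.
#'
#' @param sequence one-letter amino-acid string.
#' @return unitless score in `[0, 1]`.
#' @export
solubility_score <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  if (!length(s)) stop("empty sequence")
  unknown <- setdiff(s, names(.KD_HYDROPATHY))
  if (length(unknown)) stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  gravy <- mean(.KD_HYDROPATHY[s])
  gravy01 <- (gravy + 4.5) / 9
  charge <- sum(.AA_CHARGE[s])
  0.5 * (1 - gravy01) + 0.5 * min(abs(charge) / length(s), 1)
}

#' Interface residues of two chains
#'
#' Residues of each chain with any heavy atom within `cutoff` (closed
#' interval) of the other chain.
#'
#' @param structure a [bk_structure()].
#' @param chain_a,chain_b chain identifiers.
#' @param cutoff distance cutoff in Angstrom.
#' @return list with residue-index vectors `a` and `b`.
#' @export
interface_residues <- function(structure, chain_a, chain_b, cutoff = 4.0) {
  for (id in c(chain_a, chain_b))
    if (!id %in% structure$chains$chain_id) stop("missing chain: ", id)
  aa <- structure$atoms[structure$atoms$chain == chain_a & !structure$atoms$is_virtual, ]
  bb <- structure$atoms[structure$atoms$chain == chain_b & !structure$atoms$is_virtual, ]
  xa <- as.matrix(aa[, c("x", "y", "z")])
  xb <- as.matrix(bb[, c("x", "y", "z")])
  hit_a <- logical(nrow(aa)); hit_b <- logical(nrow(bb))
  for (i in seq_len(nrow(aa))) {
    d <- sqrt(colSums((t(xb) - xa[i, ])^2))
    cl <- d <= cutoff
    if (any(cl)) { hit_a[i] <- TRUE; hit_b <- hit_b | cl }
  }
  list(a = sort(unique(aa$res_index[hit_a])),
       b = sort(unique(bb$res_index[hit_b])))
}

#' CA RMSD between a designed and a refolded structure
#'
#' Rigidly aligns the refolded CA trace onto the designed one over the
#' requested scope and returns the RMSD; used for the refolding
#' self-consistency filter.
#'
#' @param designed,refolded [bk_structure()]s with matching residue
#'   correspondence over the scope.
#' @param scope `"complex"` (all chains) or `"binder_only"`.
#' @param binder_chain chain id of the binder for `scope = "binder_only"`.
#' @return RMSD in Angstrom.
#' @export
refold_rmsd <- function(designed, refolded, scope = c("complex", "binder_only"),
                        binder_chain = "A") {
  scope <- match.arg(scope)
  pick <- function(s) {
    a <- s$atoms[s$atoms$atom_name == "CA" & !s$atoms$is_virtual, ]
    if (scope == "binder_only") a <- a[a$chain == binder_chain, ]
    a <- a[order(a$chain, a$res_index), ]
    as.matrix(a[, c("x", "y", "z")])
  }
  xa <- pick(designed); xb <- pick(refolded)
  if (nrow(xa) != nrow(xb))
    stop(sprintf("refold_rmsd: CA length mismatch (%d vs %d)", nrow(xa), nrow(xb)))
  coord_rmsd(xa, xb, align = TRUE)
}

#' Full interaction report for a design/target complex
#'
#' Bundles all physics-based metrics into one named list with stable names
#' usable as ranking columns.
#'
#' @inheritParams hydrogen_bonds
#' @param n_points SASA sphere points.
#' @return list of class `bk_interaction_report`.
#' @export
interaction_report <- function(structure, design_chain = "A",
                               target_chain = NULL, n_points = 240) {
  target <- if (is.null(target_chain))
    setdiff(structure$chains$chain_id, design_chain) else target_chain
  seq_d <- chain_sequence(structure, design_chain)
  rep <- list(
    n_hbonds = hydrogen_bonds(structure, design_chain, target),
    n_salt_bridges = salt_bridges(structure, design_chain, target),
    buried_sasa = buried_surface_area(structure, design_chain, target,
                                      n_points = n_points),
    largest_hydrophobic_patch = largest_hydrophobic_patch(structure,
                                                          design_chain,
                                                          n_points = n_points),
    solubility_score = solubility_score(seq_d),
    interface_residues = interface_residues(structure, design_chain, target[1])
  )
  class(rep) <- "bk_interaction_report"
  rep
}
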