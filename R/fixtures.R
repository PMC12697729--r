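# Synthetic-structure generators and analytic oracles: ideal helices, toy
# two-chain complexes with planted interface interactions, random metric
# tables, and coordinate perturbation. Everything is deterministic given its
# seed so the whole package is testable without downloads.

#' Build an ideal alpha-helix
#'
#' Generates a backbone (N, CA, C, O per residue) with ideal helical
#' dihedrals (phi = -57, psi = -47, omega = 180 degrees) and standard
#' covalent geometry, giving the canonical ~1.5 Angstrom rise per residue
#' and ~3.8 Angstrom consecutive CA spacing.
#'
#' @param n_res number of residues (>= 4).
#' @param sequence optional one-letter sequence of length `n_res` (residue
#'   names only; no side-chain atoms are built). Default poly-alanine.
#' @param chain_id chain identifier.
#' @return a [bk_structure()] with one protein chain.
#' @examples
#' h <- make_ideal_helix(10)
#' n_residues(h)  # 10
#' @export
make_ideal_helix <- function(n_res, sequence = NULL, chain_id = "A") {
  if (n_res < 4) stop("make_ideal_helix: n_res must be >= 4")
  res_names <- if (is.null(sequence)) rep("ALA", n_res) else {
    s <- strsplit(toupper(sequence), "")[[1]]
    if (length(s) != n_res) stop("sequence length must equal n_res")
    unname(.AA1_TO_3[s])
  }
  if (anyNA(res_names)) stop("sequence contains unknown residue letters")

  g <- .BB_GEOM
  phi <- -57; psi <- -47; omega <- 180
  # seed frame for residue 1
  N <- list(); CA <- list(); C <- list(); O <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[[1]] <- CA[[1]] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                           g$b_c_n, g$a_ca_c_n, psi)
      CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                            g$b_n_ca, g$a_c_n_ca, omega)
      C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                           g$b_ca_c, g$a_n_ca_c, phi)
    }
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                         g$b_c_o, g$a_ca_c_o, psi + 180)
  }
  xyz <- do.call(rbind, lapply(seq_len(n_res), function(i)
    rbind(N[[i]], CA[[i]], C[[i]], O[[i]])))
  atoms <- data.frame(
    chain = chain_id,
    res_index = rep(seq_len(n_res), each = 4),
    res_name = rep(res_names, each = 4),
    atom_name = rep(c("N", "CA", "C", "O"), n_res),
    element = rep(c("N", "C", "C", "O"), n_res),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  bk_structure(atoms, data.frame(chain_id = chain_id, polymer_class = "protein",
                                 stringsAsFactors = FALSE))
}

#' Build a toy two-chain complex with planted interface interactions
#'
#' Poses two ideal helices side by side and plants exactly the requested
#' numbers of hydrogen bonds and salt bridges across the interface by adding
#' bridging side-chain atoms: each hydrogen bond is a LYS NZ donor on chain A
#' meeting a GLN OE1 acceptor on chain B at 2.9 Angstrom (neutral acceptor,
#' so it is never also a salt bridge); each salt bridge is a LYS NZ / ASP
#' OD1 pair at 3.8 Angstrom (outside the 3.5 Angstrom hydrogen-bond cutoff).
#' The planted counts are verified against [hydrogen_bonds()] and
#' [salt_bridges()] at build time, and the whole complex is given a random
#' rigid motion drawn from the seed.
#'
#' @param seed RNG seed for the rigid motion.
#' @param n_hbonds,n_salt_bridges requested interaction counts (>= 0).
#' @param n_res residues per helix.
#' @param separation axis-to-axis chain separation in Angstrom.
#' @return a [bk_structure()] with chains `"A"` (design) and `"B"` (target);
#'   attribute `ground_truth` records the planted counts.
#' @export
make_toy_complex <- function(seed = 1, n_hbonds = 1, n_salt_bridges = 1,
                             n_res = 12, separation = 12) {
  if (n_hbonds < 0 || n_salt_bridges < 0) stop("interaction counts must be >= 0")
  n_plant <- n_hbonds + n_salt_bridges
  sites <- seq(2, n_res - 1, by = 3)
  if (n_plant > length(sites))
    stop(sprintf("make_toy_complex: %d interactions do not fit on %d residues",
                 n_plant, n_res))

  A <- make_ideal_helix(n_res, chain_id = "A")
  B <- make_ideal_helix(n_res, chain_id = "B")
  ca <- coords(A, A$atoms$atom_name == "CA")
  axis <- svd(scale(ca, scale = FALSE))$v[, 1]
  perp <- unit(pracma_cross(axis, c(0, 0, 1)))
  if (!all(is.finite(perp))) perp <- unit(pracma_cross(axis, c(0, 1, 0)))
  coords(B) <- sweep(coords(B), 2, perp * separation, "+")

  atoms <- rbind(A$atoms, B$atoms)
  extra <- list()
  plant <- function(res_a, res_b, kind) {
    pa <- unlist(atoms[atoms$chain == "A" & atoms$res_index == res_a &
                         atoms$atom_name == "CA", c("x", "y", "z")])
    pb <- unlist(atoms[atoms$chain == "B" & atoms$res_index == res_b &
                         atoms$atom_name == "CA", c("x", "y", "z")])
    v <- unit(pb - pa)
    gap <- if (kind == "hbond") 2.9 else 3.8
    q <- (vnorm(pb - pa) - gap) / 2
    nz <- pa + q * v
    ce <- pa + (q - 1.5) * v
    acc <- nz + gap * v
    acc_name <- if (kind == "hbond") "OE1" else "OD1"
    acc_res <- if (kind == "hbond") "GLN" else "ASP"
    list(
      data.frame(chain = "A", res_index = res_a, res_name = "LYS",
                 atom_name = c("CE", "NZ"), element = c("C", "N"),
                 x = c(ce[1], nz[1]), y = c(ce[2], nz[2]), z = c(ce[3], nz[3]),
                 stringsAsFactors = FALSE),
      data.frame(chain = "B", res_index = res_b, res_name = acc_res,
                 atom_name = acc_name, element = "O",
                 x = acc[1], y = acc[2], z = acc[3], stringsAsFactors = FALSE)
    )
  }
  kinds <- c(rep("hbond", n_hbonds), rep("salt", n_salt_bridges))
  for (k in seq_along(kinds)) {
    res <- sites[k]
    pl <- plant(res, res, kinds[k])
    atoms$res_name[atoms$chain == "A" & atoms$res_index == res] <- "LYS"
    atoms$res_name[atoms$chain == "B" & atoms$res_index == res] <-
      pl[[2]]$res_name[1]
    extra <- c(extra, pl)
  }
  if (length(extra)) {
    extra <- do.call(rbind, extra)
    extra$charge <- 0L; extra$is_virtual <- FALSE; extra$is_design <- FALSE
    extra$serial <- NA_integer_
    atoms <- rbind(atoms, extra)
    atoms$serial <- seq_len(nrow(atoms))
  }
  atoms <- atoms[order(atoms$chain, atoms$res_index), , drop = FALSE]
  s <- bk_structure(atoms)
  # random rigid motion from the seed
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  s <- apply_random_rigid_motion(s)

  got_hb <- hydrogen_bonds(s, "A", "B")
  got_sb <- salt_bridges(s, "A", "B")
  if (got_hb != n_hbonds || got_sb != n_salt_bridges)
    stop(sprintf(paste0("make_toy_complex: planted interactions not realised ",
                        "(requested %d hbonds / %d bridges, measured %d / %d)"),
                 n_hbonds, n_salt_bridges, got_hb, got_sb))
  attr(s, "ground_truth") <- list(n_hbonds = n_hbonds,
                                  n_salt_bridges = n_salt_bridges)
  s
}

apply_random_rigid_motion <- function(structure) {
  q <- stats::rnorm(4); q <- q / vnorm(q)
  R <- quat_to_rot(q)
  shift <- stats::runif(3, -10, 10)
  coords(structure) <- sweep(coords(structure) %*% R, 2, shift, "+")
  structure
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Generate a reproducible random metric table
#'
#' Gaussian metric columns with configurable pairwise correlation; used to
#' exercise ranking and quality-diversity selection. Optionally one design
#' can be made dominant (best value in every metric).
#'
#' @param n_designs,n_metrics table dimensions (>= 1).
#' @param seed RNG seed.
#' @param correlation common correlation between metric columns.
#' @param dominant_design optional design index forced to dominate.
#' @return a [metric_table()] (all metrics oriented lower-is-better with
#'   unit weights).
#' @export
make_metric_table <- function(n_designs, n_metrics, seed = 1,
                              correlation = 0, dominant_design = NULL) {
  if (n_designs < 1 || n_metrics < 1) stop("table dimensions must be >= 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z0 <- stats::rnorm(n_designs)
  vals <- vapply(seq_len(n_metrics), function(m)
    sqrt(correlation) * z0 + sqrt(1 - correlation) * stats::rnorm(n_designs),
    numeric(n_designs))
  vals <- matrix(vals, n_designs, n_metrics)
  if (!is.null(dominant_design))
    vals[dominant_design, ] <- apply(vals, 2, min) - 1
  df <- data.frame(id = sprintf("design_%03d", seq_len(n_designs)), vals,
                   stringsAsFactors = FALSE)
  names(df)[-1] <- sprintf("metric_%02d", seq_len(n_metrics))
  metric_table(df, higher_better = rep(FALSE, n_metrics))
}

#' Perturb all atom coordinates with isotropic Gaussian noise
#'
#' @param structure a [bk_structure()].
#' @param noise_sd per-coordinate standard deviation in Angstrom (>= 0).
#' @param seed RNG seed.
#' @return perturbed copy of the structure.
#' @export
perturb_structure <- function(structure, noise_sd, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xyz <- coords(structure)
  coords(structure) <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd),
                                    nrow(xyz), 3)
  structure
}
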