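# Minimal two-chain structure with one backbone N-H...O=C geometry at a
# controllable donor-acceptor distance (linear arrangement CA-N...O).
helper_nh_o_pair <- function(d) {
  atoms <- data.frame(
    chain = c("A", "A", "A", "A", "B", "B", "B", "B"),
    res_index = c(1, 1, 1, 1, 1, 1, 1, 1),
    res_name = "GLY",
    atom_name = c("N", "CA", "C", "O", "N", "CA", "C", "O"),
    element = c("N", "C", "C", "O", "N", "C", "C", "O"),
    x = c(0, -1.46, -2.0, -2.0, 40, 41, 42, d),
    y = c(0, 0, 1.2, 2.4, 40, 40, 41, 0),
    z = 0,
    stringsAsFactors = FALSE
  )
  # acceptor O of chain B sits on the +x axis at distance d from the donor N
  atoms$y[atoms$chain == "B" & atoms$atom_name == "O"] <- 0
  bk_structure(atoms)
}

test_that("hydrogen bonds require the distance and donor-angle criterion", {
  expect_equal(hydrogen_bonds(helper_nh_o_pair(2.9), "A", "B"), 1L)
  expect_equal(hydrogen_bonds(helper_nh_o_pair(5.0), "A", "B"), 0L)
  # far-apart chains
  far <- make_toy_complex(seed = 1, n_hbonds = 0, n_salt_bridges = 0,
                          separation = 100)
  expect_equal(hydrogen_bonds(far, "A", "B"), 0L)
  # angle rule: put the acceptor on the same side as the antecedent CA
  bad <- helper_nh_o_pair(2.9)
  o <- bad$atoms$chain == "B" & bad$atoms$atom_name == "O"
  bad$atoms$x[o] <- -2.2; bad$atoms$y[o] <- 0.8   # ~2.4 A but angle << 120 deg
  expect_equal(hydrogen_bonds(bad, "A", "B"), 0L)
})

test_that("salt bridges pair opposite charges only", {
  mk <- function(neg_res, neg_atom, d) {
    atoms <- data.frame(
      chain = c(rep("A", 5), rep("B", 5)),
      res_index = 1,
      res_name = c(rep("LYS", 5), rep(neg_res, 5)),
      atom_name = c("N", "CA", "C", "O", "NZ", "N", "CA", "C", "O", neg_atom),
      element = c("N", "C", "C", "O", "N", "N", "C", "C", "O",
                  substr(neg_atom, 1, 1)),
      x = c(-8, -7, -6, -6, 0, 30, 31, 32, 33, d),
      y = c(0, 0, 1, 2, 0, 9, 9, 8, 7, 0),
      z = 0, stringsAsFactors = FALSE)
    bk_structure(atoms)
  }
  expect_equal(salt_bridges(mk("ASP", "OD1", 3.2), "A", "B"), 1L)
  expect_equal(salt_bridges(mk("ASP", "OD1", 4.5), "A", "B"), 0L)
  # like charges at contact distance do not count
  expect_equal(salt_bridges(mk("LYS", "NZ", 3.2), "A", "B"), 0L)
  far <- make_toy_complex(seed = 1, n_hbonds = 0, n_salt_bridges = 0,
                          separation = 100)
  expect_equal(salt_bridges(far, "A", "B"), 0L)
})

test_that("buried surface area vanishes without contact and is symmetric", {
  far <- make_toy_complex(seed = 1, n_hbonds = 0, n_salt_bridges = 0,
                          separation = 100)
  expect_equal(buried_surface_area(far, "A", "B", n_points = 240), 0,
               tolerance = 1e-6)
  tc <- make_toy_complex(seed = 3, n_hbonds = 1, n_salt_bridges = 1)
  ab <- buried_surface_area(tc, "A", "B", n_points = 240)
  ba <- buried_surface_area(tc, "B", "A", n_points = 240)
  expect_gt(ab, 10)
  expect_equal(ab, ba, tolerance = 1e-9)
})

test_that("BSA converges under sphere-point refinement", {
  tc <- make_toy_complex(seed = 3, n_hbonds = 1, n_salt_bridges = 1,
                         separation = 9)
  coarse <- buried_surface_area(tc, "A", "B", n_points = 240)
  fine <- buried_surface_area(tc, "A", "B", n_points = 2400)
  expect_lt(abs(coarse - fine) / fine, 0.05)
})

test_that("hydrophobic patches cover nonpolar surfaces and vanish on polar ones", {
  leu <- make_ideal_helix(12, sequence = strrep("L", 12))
  ser <- make_ideal_helix(12, sequence = strrep("S", 12))
  expect_equal(largest_hydrophobic_patch(ser, n_points = 240), 0)
  patch <- largest_hydrophobic_patch(leu, n_points = 240)
  expect_gt(patch, 100)
  expect_lte(patch, sasa(leu, n_points = 240))
  # a single connected component: patch equals the total exposed nonpolar area
  a <- leu$atoms
  ar <- sasa(leu, n_points = 240, per_atom = TRUE)
  sel <- a$res_name %in% c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO") &
    a$element %in% c("C", "S") & ar >= 5
  expect_equal(patch, sum(ar[sel]))
})

test_that("solubility scoring orders charged above hydrophobic sequences", {
  expect_gt(solubility_score(strrep("K", 20)), solubility_score(strrep("I", 20)))
  expect_equal(solubility_score("KDIR"), solubility_score(strrep("KDIR", 5)))
  expect_identical(solubility_score("ACDEFG"), solubility_score("ACDEFG"))
  expect_error(solubility_score("ACDEZ"), "unknown residue")
})

test_that("interface residues use a closed cutoff and grow monotonically", {
  far <- make_toy_complex(seed = 1, n_hbonds = 0, n_salt_bridges = 0,
                          separation = 100)
  ir <- interface_residues(far, "A", "B")
  expect_length(ir$a, 0L)
  expect_length(ir$b, 0L)
  # two CA atoms at exactly the cutoff are included
  s <- bk_structure(data.frame(
    chain = c("A", "B"), res_index = 1, res_name = "GLY",
    atom_name = "CA", element = "C", x = c(0, 4), y = 0, z = 0))
  expect_equal(interface_residues(s, "A", "B", cutoff = 4.0)$a, 1L)
  expect_error(interface_residues(s, "A", "Q"), "missing chain")
  tc <- make_toy_complex(seed = 4, n_hbonds = 2, n_salt_bridges = 1)
  i4 <- interface_residues(tc, "A", "B", 4)
  i5 <- interface_residues(tc, "A", "B", 5)
  expect_true(all(i4$a %in% i5$a))
  expect_true(all(i4$b %in% i5$b))
})

test_that("interface residues match a brute-force all-pairs scan", {
  tc <- make_toy_complex(seed = 7, n_hbonds = 1, n_salt_bridges = 1)
  a <- tc$atoms[tc$atoms$chain == "A", ]
  b <- tc$atoms[tc$atoms$chain == "B", ]
  brute_a <- sort(unique(unlist(lapply(seq_len(nrow(a)), function(i) {
    d <- sqrt((b$x - a$x[i])^2 + (b$y - a$y[i])^2 + (b$z - a$z[i])^2)
    if (any(d <= 4)) a$res_index[i] else NULL
  }))))
  expect_equal(interface_residues(tc, "A", "B", 4)$a, brute_a)
})

test_that("refold RMSD is alignment-invariant and matches the direct formula", {
  tc <- make_toy_complex(seed = 8, n_hbonds = 1, n_salt_bridges = 0)
  expect_equal(refold_rmsd(tc, tc), 0, tolerance = 1e-12)
  expect_lt(refold_rmsd(tc, helper_rotate(tc, seed = 3)), 1e-9)
  # one CA displaced by 1 A in a 100-residue chain: RMSD ~ sqrt(1/100)
  h <- make_ideal_helix(100)
  moved <- h
  i <- which(moved$atoms$atom_name == "CA" & moved$atoms$res_index == 50)
  moved$atoms$x[i] <- moved$atoms$x[i] + 1
  r <- refold_rmsd(h, moved)
  expect_lt(abs(r - 0.1), 0.01)
  short <- make_ideal_helix(50)
  expect_error(refold_rmsd(h, short), "length mismatch")
  # binder-only scope ignores the target chain
  shifted <- tc
  bsel <- shifted$atoms$chain == "B"
  shifted$atoms$x[bsel] <- shifted$atoms$x[bsel] + 5
  expect_lt(refold_rmsd(tc, shifted, scope = "binder_only"), 1e-9)
  expect_gt(refold_rmsd(tc, shifted, scope = "complex"), 1)
})

test_that("interaction metrics are invariant under global rigid motion", {
  tc <- make_toy_complex(seed = 9, n_hbonds = 2, n_salt_bridges = 1)
  rot <- helper_rotate(tc, seed = 5)
  expect_equal(hydrogen_bonds(rot, "A", "B"), hydrogen_bonds(tc, "A", "B"))
  expect_equal(salt_bridges(rot, "A", "B"), salt_bridges(tc, "A", "B"))
  b1 <- buried_surface_area(tc, "A", "B", n_points = 960)
  b2 <- buried_surface_area(rot, "A", "B", n_points = 960)
  expect_lt(abs(b1 - b2) / max(b1, 1), 0.03)  # sphere-lattice discretisation
  expect_equal(interface_residues(rot, "A", "B"), interface_residues(tc, "A", "B"))
})

test_that("the bundled interaction report exposes stable metric names", {
  tc <- make_toy_complex(seed = 10, n_hbonds = 1, n_salt_bridges = 1)
  rep <- interaction_report(tc, "A", "B", n_points = 120)
  expect_named(rep, c("n_hbonds", "n_salt_bridges", "buried_sasa",
                      "largest_hydrophobic_patch", "solubility_score",
                      "interface_residues"))
  expect_equal(rep$n_hbonds, 1L)
  expect_equal(rep$n_salt_bridges, 1L)
  expect_gte(rep$buried_sasa, 0)
})
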