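# SASA, interface detection, contacts and interface composition.

make_cx <- function(...) {
  cxg <- make_synthetic_complex(...)
  list(gen = cxg, cx = build_complex(parse_structure(cxg$pdb), "A", "B"))
}

test_that("a lone sphere matches the closed-form SASA", {
  atoms <- data.frame(name = "CA", element = "C", x = 0, y = 0, z = 0,
                      chain_id = "A", res_seq = 1, i_code = "",
                      res_name = "ALA", alt_loc = "", occupancy = 1)
  s <- compute_sasa(atoms, n_points = 960)
  r <- vdw_radii()[["C"]] + 1.4
  expect_equal(s$total, 4 * pi * r^2, tolerance = 1e-6)
})

test_that("a fully enclosed atom has zero SASA", {
  # Central atom caged by a 3x3x3 grid of neighbours 2 A apart.
  grid <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2))
  atoms <- data.frame(name = "CA", element = "C", x = grid$x, y = grid$y,
                      z = grid$z, chain_id = "A", res_seq = seq_len(27),
                      i_code = "", res_name = "ALA", alt_loc = "",
                      occupancy = 1)
  s <- compute_sasa(atoms, n_points = 480)
  central <- s$total[s$key == "A:14:"]
  expect_equal(central, 0)
})

test_that("default quadrature agrees with a 10x finer self-oracle within 2%", {
  lines <- c(residue_lines(1, "ALA", "A", 1, 0),
             residue_lines(6, "LEU", "A", 2, 3.8), "END")
  atoms <- parse_structure(lines)
  coarse <- compute_sasa(atoms, n_points = 960)
  fine <- compute_sasa(atoms, n_points = 9600)
  expect_equal(coarse$total, fine$total, tolerance = 0.02)
})

test_that("monomer SASA is never below complex SASA", {
  p <- sasa_profile(make_cx(n_res = 8, seed = 2)$cx, n_points = 240)
  expect_true(all(p$mon - p$comp > -0.5))
})

test_that("distant chains have no interface; touching chains do", {
  far <- make_cx(n_res = 6, separation = 30, seed = 3)
  expect_error(interface_residues(far$cx, profile = sasa_profile(far$cx, n_points = 240)),
               class = "hs_no_interface")
  near <- make_cx(n_res = 8, separation = 5.5, patch_size = 5, seed = 3)
  prof <- sasa_profile(near$cx, n_points = 240)
  iface <- interface_residues(near$cx, profile = prof)
  # Definitionally: exactly the residues with positive SASA burial.
  expect_setequal(iface, prof$key[prof$mon - prof$comp > 1e-6])
  # Geometrically: every residue the generator placed in contact range.
  expect_true(all(near$gen$contact_residues %in% iface))
})

test_that("interface and per-residue features are group-swap symmetric", {
  cxg <- make_synthetic_complex(n_res = 8, patch_size = 5, seed = 4)
  atoms <- parse_structure(cxg$pdb)
  ab <- build_complex(atoms, "A", "B")
  ba <- build_complex(atoms, "B", "A")
  p_ab <- sasa_profile(ab, n_points = 240)
  p_ba <- sasa_profile(ba, n_points = 240)
  expect_setequal(interface_residues(ab, profile = p_ab),
                  interface_residues(ba, profile = p_ba))
  expect_equal(p_ab$mon[match(p_ba$key, p_ab$key)], p_ba$mon)
  expect_equal(contact_counts(ab, 4.0), contact_counts(ba, 4.0)[names(contact_counts(ab, 4.0))])
  expect_equal(interface_composition(ab, interface = interface_residues(ab, profile = p_ab)),
               interface_composition(ba, interface = interface_residues(ba, profile = p_ba)))
})

test_that("SASA feature vector has documented degenerate behaviour", {
  cx <- make_cx(n_res = 8, patch_size = 5, seed = 6)$cx
  prof <- sasa_profile(cx, n_points = 240)
  v <- sasa_feature_vector(prof$key[1], prof)
  expect_length(v, 12)
  expect_equal(unname(v["sasa_delta"]), unname(v["sasa_mon"] - v["sasa_comp"]))
  expect_equal(unname(v["rel_delta"]),
               unname(v["sasa_delta"]) / max_sasa_reference()[["ALA"]])

  # Hand-crafted profile rows: unburied residue and fully buried residue.
  fake <- data.frame(key = c("A:1:", "A:2:"), resname = c("ALA", "LEU"),
                     group = "A", comp = c(50, 0), mon = c(50, 80),
                     comp_sc = c(20, 0), mon_sc = c(20, 30))
  v1 <- sasa_feature_vector("A:1:", fake)
  expect_equal(unname(v1[c("sasa_delta", "rel_delta", "sc_delta", "frac_buried")]),
               c(0, 0, 0, 0))
  v2 <- sasa_feature_vector("A:2:", fake)
  expect_equal(unname(v2["frac_buried"]), 1)
  expect_error(sasa_feature_vector("A:1:",
                                   transform(fake, resname = c("XXX", "LEU"))),
               class = "hs_validation_error")
})

test_that("contact counts honour cutoffs and match the brute-force oracle", {
  # Two single-atom residues across the groups at distance 2.4.
  lines <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
             pdb_line(2, "CA", "ALA", "B", 1, 2.4, 0, 0), "END")
  cx <- build_complex(parse_structure(lines), "A", "B")
  expect_equal(sum(contact_counts(cx, 2.5)), 2)  # one pair, counted on each side

  lines3 <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
              pdb_line(2, "CA", "ALA", "B", 1, 3.0, 0, 0), "END")
  cx3 <- build_complex(parse_structure(lines3), "A", "B")
  expect_equal(sum(contact_counts(cx3, 2.5)), 0)
  expect_equal(sum(contact_counts(cx3, 4.0)), 2)

  gen <- make_cx(n_res = 10, patch_size = 6, seed = 8)
  for (cutoff in c(2.5, 4.0)) {
    got <- contact_counts(gen$cx, cutoff)
    want <- oracle_contact_counts(gen$cx$atoms, gen$cx$group_a, cutoff)
    expect_equal(got[names(want)], want)
  }
})

test_that("contact counts are monotone in cutoff and conserved across groups", {
  gen <- make_cx(n_res = 10, patch_size = 6, seed = 9)
  c25 <- contact_counts(gen$cx, 2.5)
  c40 <- contact_counts(gen$cx, 4.0)
  expect_true(all(c25 <= c40))
  res <- hotspotr:::residue_table(gen$cx)
  in_a <- res$group[match(names(c40), res$key)] == "A"
  expect_equal(sum(c40[in_a]), sum(c40[!in_a]))
})

test_that("hydrophobic contacts require apolar residues and C-C pairs", {
  leu_leu <- c(pdb_line(1, "CB", "LEU", "A", 1, 0, 0, 0, element = "C"),
               pdb_line(2, "CB", "LEU", "B", 1, 4.0, 0, 0, element = "C"),
               "END")
  cx <- build_complex(parse_structure(leu_leu), "A", "B")
  expect_equal(sum(hydrophobic_contacts(cx)), 2)

  ser_leu <- c(pdb_line(1, "CB", "SER", "A", 1, 0, 0, 0, element = "C"),
               pdb_line(2, "CB", "LEU", "B", 1, 4.0, 0, 0, element = "C"),
               "END")
  cx2 <- build_complex(parse_structure(ser_leu), "A", "B")
  expect_equal(sum(hydrophobic_contacts(cx2)), 0)

  # Nitrogen-nitrogen pairs never count even between apolar residues.
  n_n <- c(pdb_line(1, "N", "LEU", "A", 1, 0, 0, 0, element = "N"),
           pdb_line(2, "N", "LEU", "B", 1, 4.0, 0, 0, element = "N"),
           "END")
  cx3 <- build_complex(parse_structure(n_n), "A", "B")
  expect_equal(sum(hydrophobic_contacts(cx3)), 0)
})

test_that("interface composition counts types and conserves the total", {
  gen <- make_cx(n_res = 10, patch_size = 6,
                 sequence = c("ALA", "LEU", "SER"), seed = 10)
  prof <- sasa_profile(gen$cx, n_points = 240)
  iface <- interface_residues(gen$cx, profile = prof)
  comp <- interface_composition(gen$cx, interface = iface)
  expect_length(comp, 20)
  expect_equal(sum(comp), length(iface))
  res <- hotspotr:::residue_table(gen$cx)
  expect_equal(unname(comp[["ALA"]]),
               sum(res$resname[match(iface, res$key)] == "ALA"))
})

test_that("features are invariant under rigid-body motion", {
  gen <- make_cx(n_res = 8, patch_size = 5, seed = 11)
  atoms <- gen$cx$atoms
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  moved <- atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  moved[, c("x", "y", "z")] <- sweep(xyz, 2, c(11, -7, 3), "+")
  cx2 <- build_complex(moved, "A", "B")
  expect_equal(contact_counts(cx2, 4.0), contact_counts(gen$cx, 4.0))
  expect_equal(hydrophobic_contacts(cx2), hydrophobic_contacts(gen$cx))
  p1 <- sasa_profile(gen$cx, n_points = 960)
  p2 <- sasa_profile(cx2, n_points = 960)
  expect_equal(p2$comp, p1$comp, tolerance = 0.02)
})
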