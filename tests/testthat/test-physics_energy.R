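ljtab <- load_lj_table()

test_that("Lorentz-Berthelot combining follows the stated rule", {
  ab <- combine_lj(lj_params(3.4, 0.1), lj_params(3.0, 0.4))
  expect_equal(ab$sigma, 3.2)
  expect_equal(ab$epsilon_well, 0.2)
  same <- combine_lj(lj_params(3.4, 0.1), lj_params(3.4, 0.1))
  expect_equal(same$sigma, 3.4)
  expect_equal(same$epsilon_well, 0.1)
  expect_equal(combine_lj(lj_params(3, 0), lj_params(3, 0.5))$epsilon_well, 0)
})

test_that("the switching function is exact at the window edges and C1", {
  cfg <- nonbonded_config()
  expect_equal(switching_factor(6, cfg), 1)
  expect_equal(switching_factor(8, cfg), 0)
  s7 <- switching_factor(7, cfg)
  expect_gt(s7, 0); expect_lt(s7, 1)
  # independent numeric evaluation of the documented polynomial at r = 7
  ref <- (64 - 49)^2 * (64 + 2 * 49 - 3 * 36) / (64 - 36)^3
  expect_equal(s7, ref, tolerance = 1e-12)
  # zero derivative at both edges by central finite differences
  h <- 1e-5
  for (r0 in c(6, 8)) {
    fd <- (switching_factor(r0 + h, cfg) - switching_factor(r0 - h, cfg)) / (2 * h)
    expect_lt(abs(fd), 1e-4)
  }
  # monotone decreasing inside the window
  rs <- seq(6, 8, by = 0.01)
  expect_true(all(diff(switching_factor(rs, cfg)) <= 0))
})

test_that("single-pair Coulomb energy matches the closed form", {
  cfg <- nonbonded_config()
  pp <- charged_particles(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, -1), c("C", "C"))
  expect_equal(coulomb_energy(pp, config = cfg), -332.0636 / 4,
               tolerance = 1e-12)
  # all charges zero
  p0 <- charged_particles(rbind(c(0, 0, 0), c(2, 0, 0)), c(0, 0), c("C", "C"))
  expect_equal(coulomb_energy(p0, config = cfg), 0)
  # beyond the cutoff
  pfar <- charged_particles(rbind(c(0, 0, 0), c(9, 0, 0)), c(1, -1), c("C", "C"))
  expect_equal(coulomb_energy(pfar, config = cfg), 0)
  # clash guard
  pclash <- charged_particles(rbind(c(0, 0, 0), c(0.3, 0, 0)), c(1, -1),
                              c("C", "C"))
  expect_error(coulomb_energy(pclash, config = cfg), "clash")
})

test_that("LJ energy has its textbook zero and minimum", {
  cfg <- nonbonded_config()
  sig <- ljtab$C$sigma; eps <- ljtab$C$epsilon_well
  at <- function(r) charged_particles(rbind(c(0, 0, 0), c(r, 0, 0)),
                                      c(0, 0), c("C", "C"))
  expect_equal(lj_energy(at(sig), config = cfg, table = ljtab), 0,
               tolerance = 1e-12)
  rmin <- 2^(1 / 6) * sig
  expect_equal(lj_energy(at(rmin), config = cfg, table = ljtab), -eps,
               tolerance = 1e-12)
  expect_error(lj_energy(charged_particles(rbind(0, 3) %*% t(c(1, 0, 0)),
                                           c(0, 0), c("C", "Zz")),
                         config = cfg, table = ljtab), "Zz")
})

brute_force_energies <- function(pp, cfg, tab) {
  n <- nrow(pp$positions)
  ec <- 0; el <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((pp$positions[i, ] - pp$positions[j, ])^2))
    s <- if (r <= cfg$r_on) 1 else if (r >= cfg$r_off) 0 else
      (cfg$r_off^2 - r^2)^2 * (cfg$r_off^2 + 2 * r^2 - 3 * cfg$r_on^2) /
        (cfg$r_off^2 - cfg$r_on^2)^3
    ec <- ec + cfg$coulomb_constant * pp$charges[i] * pp$charges[j] /
      (cfg$dielectric * r) * s
    mix <- combine_lj(tab[[pp$lj_types[i]]], tab[[pp$lj_types[j]]])
    el <- el + 4 * mix$epsilon_well *
      ((mix$sigma / r)^12 - (mix$sigma / r)^6) * s
  }
  c(coul = ec, lj = el)
}

test_that("vectorized energies equal a naive double loop", {
  cfg <- nonbonded_config()
  for (seed in 1:5) {
    pp <- make_toy_particles(sample(5:20, 1), seed = seed)
    ref <- brute_force_energies(pp, cfg, ljtab)
    expect_equal(coulomb_energy(pp, config = cfg), unname(ref["coul"]),
                 tolerance = 1e-10)
    expect_equal(lj_energy(pp, config = cfg, table = ljtab),
                 unname(ref["lj"]), tolerance = 1e-10)
  }
})

test_that("energies are invariant under rigid motions", {
  cfg <- nonbonded_config()
  pp <- make_toy_particles(12, seed = 4)
  e0 <- c(coulomb_energy(pp, config = cfg),
          lj_energy(pp, config = cfg, table = ljtab))
  set.seed(9)
  for (k in 1:5) {
    th <- stats::runif(3, 0, 2 * pi)
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0), c(sin(th[1]), cos(th[1]), 0),
                c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[2]), -sin(th[2])),
                c(0, sin(th[2]), cos(th[2])))
    shift <- matrix(stats::runif(3, -20, 20), nrow(pp$positions), 3,
                    byrow = TRUE)
    moved <- pp
    moved$positions <- pp$positions %*% (Rz %*% Rx) + shift
    e1 <- c(coulomb_energy(moved, config = cfg),
            lj_energy(moved, config = cfg, table = ljtab))
    expect_lt(max(abs(e1 - e0)), 1e-8)
  }
})

test_that("the energy vanishes continuously at the cutoff", {
  cfg <- nonbonded_config()
  for (delta in c(1e-2, 1e-4)) {
    pp <- charged_particles(rbind(c(0, 0, 0), c(cfg$r_off - delta, 0, 0)),
                            c(1, -1), c("C", "C"))
    expect_lt(abs(coulomb_energy(pp, config = cfg)), 0.05 * delta / 1e-2)
    expect_lt(abs(lj_energy(pp, config = cfg, table = ljtab)), 1e-4)
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- nonbonded_config()
  # isolated pair at 3 A and a pair inside the switching window
  for (r in c(3, 7)) {
    pp <- charged_particles(rbind(c(0, 0, 0), c(r, 0, 0)), c(0.6, -0.4),
                            c("C", "O"))
    expect_lt(gradient_check("coulomb", pp, cfg, ljtab), 1e-4)
    expect_lt(gradient_check("lj", pp, cfg, ljtab), 1e-4)
    # Newton's third law on the symmetric pair
    g <- energy_position_gradient("coulomb", pp, cfg, ljtab)
    expect_lt(max(abs(g[1, ] + g[2, ])), 1e-8)
  }
  pp <- make_toy_particles(8, seed = 2)
  expect_lt(gradient_check("coulomb", pp, cfg, ljtab), 1e-4)
  expect_lt(gradient_check("lj", pp, cfg, ljtab), 1e-4)
})

test_that("total physical energy composes its parts under exclusions", {
  g <- featurize_atoms_bonds(embed_conformer(ethanol_graph(), seed = 0))
  eb <- total_physical_energy(g)
  expect_s3_class(eb, "energy_breakdown")
  expect_identical(eb$e_phys, eb$e_coul + eb$e_lj)
  # ethanol heavy-atom graph: all 3 pairs are 1-2 or 1-3 -> nothing summed
  expect_equal(eb$n_pairs_evaluated, 0L)
  expect_equal(eb$e_phys, 0)

  # 4-atom toy ligand with printed coordinates: brute force over included pairs
  g4 <- featurize_atoms_bonds(embed_conformer(assign_gasteiger_charges(
    parse_smiles(ligand_record("butane", "CCCC"))), seed = 0))
  eb4 <- total_physical_energy(g4)
  # only the 1-4 pair (atoms 1 and 4) survives bonded12_13
  expect_equal(eb4$n_pairs_evaluated, 1L)
  cfg <- nonbonded_config()
  r14 <- sqrt(sum((g4$coords[1, ] - g4$coords[4, ])^2))
  q <- g4$atoms$partial_charge
  ref_c <- cfg$coulomb_constant * q[1] * q[4] / (cfg$dielectric * r14)
  mix <- ljtab$C
  ref_l <- 4 * mix$epsilon_well * ((mix$sigma / r14)^12 - (mix$sigma / r14)^6)
  expect_equal(eb4$e_coul, ref_c, tolerance = 1e-10)
  expect_equal(eb4$e_lj, ref_l, tolerance = 1e-10)

  # no-exclusion mode evaluates every pair
  eb_all <- total_physical_energy(g4, config = nonbonded_config(
    exclusion_policy = "none"))
  expect_equal(eb_all$n_pairs_evaluated, 6L)

  # zero charges and zero well depths give an exactly zero breakdown
  gz <- g4
  gz$atoms$partial_charge <- 0
  tab0 <- lapply(ljtab, function(x) lj_params(x$sigma, 0))
  ebz <- total_physical_energy(gz, table = tab0)
  expect_equal(c(ebz$e_coul, ebz$e_lj, ebz$e_phys), c(0, 0, 0))
})

test_that("min-max scaling maps, clips, and rejects degenerate fits", {
  sc <- fit_minmax(c(-10.8, -6.9))
  expect_equal(apply_minmax(sc, -10.8), 0)
  expect_equal(apply_minmax(sc, -6.9), 1)
  expect_equal(apply_minmax(sc, (-10.8 - 6.9) / 2), 0.5)
  expect_equal(apply_minmax(sc, -12), 0)
  expect_equal(apply_minmax(sc, 0), 1)
  expect_error(fit_minmax(c(2, 2, 2)), "degenerate")
  set.seed(5)
  vals <- stats::rnorm(100)
  sc2 <- fit_minmax(vals[1:50])
  out <- apply_minmax(sc2, vals)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("cross terms with a protein context add onto the intra-ligand sums", {
  g <- featurize_atoms_bonds(embed_conformer(assign_gasteiger_charges(
    parse_smiles(ligand_record("mol", "CC(=O)O"))), seed = 0))
  rec <- protein_record("p", "KDGA")
  # residues placed a few Angstrom from the ligand so pairs are in range
  coords <- rbind(c(4, 0, 0), c(0, 4, 0), c(0, 0, 4), c(4, 4, 4))
  ctx <- protein_particles(rec, coords)
  expect_equal(ctx$charges, c(1, -1, 0, 0))
  expect_true(all(ctx$lj_types == "RES"))
  eb_intra <- total_physical_energy(g)
  eb_cross <- total_physical_energy(g, protein_context = ctx)
  expect_equal(eb_cross$n_pairs_evaluated,
               eb_intra$n_pairs_evaluated + nrow(g$atoms) * 4L)
  expect_equal(eb_cross$e_phys, eb_cross$e_coul + eb_cross$e_lj)
  # the cross contribution equals the explicit two-set evaluation
  lig <- ligand_particles(g)
  cfg <- nonbonded_config()
  expect_equal(eb_cross$e_coul - eb_intra$e_coul,
               coulomb_energy(lig, ctx, cfg), tolerance = 1e-12)
  expect_equal(eb_cross$e_lj - eb_intra$e_lj,
               lj_energy(lig, ctx, cfg, ljtab), tolerance = 1e-12)
  expect_error(protein_particles(rec, coords[1:3, ]), "4 residues")
})
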