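# Analytical non-bonded energies: Coulomb electrostatics under a uniform
# relative permittivity and the 12-6 Lennard-Jones potential, both evaluated
# pairwise with a C1 switching window so the energy (and its gradient) goes
# smoothly to zero at the cutoff.  All energies are kcal/mol, distances
# Angstrom, charges elementary charge units.

#' Non-bonded configuration
#'
#' @param dielectric Relative permittivity `eps_r` dividing Coulomb terms
#'   (default 4, the usual implicit-solvent approximation for a protein
#'   interior).
#' @param coulomb_constant Conversion factor folding in `1/(4 pi eps_0)`,
#'   332.0636 kcal mol^-1 A e^-2.
#' @param r_on Switching onset in Angstrom (default 6).
#' @param r_off Cutoff in Angstrom (default 8); pairs beyond it contribute
#'   nothing.
#' @param exclusion_policy `"bonded12_13"` (default) drops 1-2 and 1-3
#'   bonded pairs from intra-molecular sums (1-4 pairs are kept, unscaled);
#'   `"none"` keeps every pair.
#' @return A `nonbonded_config` list.
#' @export
nonbonded_config <- function(dielectric = 4, coulomb_constant = 332.0636,
                             r_on = 6, r_off = 8,
                             exclusion_policy = c("bonded12_13", "none")) {
  exclusion_policy <- match.arg(exclusion_policy)
  stopifnot(dielectric > 0, r_on > 0, r_off > r_on, coulomb_constant > 0)
  structure(list(dielectric = dielectric,
                 coulomb_constant = coulomb_constant,
                 r_on = r_on, r_off = r_off,
                 exclusion_policy = exclusion_policy),
            class = "nonbonded_config")
}

#' Lennard-Jones type parameters
#' @param sigma Collision diameter, Angstrom (> 0).
#' @param epsilon_well Well depth, kcal/mol (>= 0).
#' @return An `lj_params` list.
#' @export
lj_params <- function(sigma, epsilon_well) {
  stopifnot(sigma > 0, epsilon_well >= 0)
  structure(list(sigma = sigma, epsilon_well = epsilon_well),
            class = "lj_params")
}

#' Lorentz-Berthelot combining rule
#'
#' Arithmetic mean of sigma, geometric mean of the well depth.
#' @param a,b `lj_params` objects.
#' @return Combined `lj_params`.
#' @export
combine_lj <- function(a, b) {
  lj_params((a$sigma + b$sigma) / 2, sqrt(a$epsilon_well * b$epsilon_well))
}

#' Load a Lennard-Jones parameter table
#'
#' Plain-text format: one `type sigma epsilon` row per atom type, `#`
#' comments.  The packaged table (`inst/extdata/lj_params.txt`) carries
#' GAFF-like values for common organic elements plus a generic residue bead.
#'
#' @param path File path; default is the packaged table.
#' @return Named list of `lj_params`, keyed by type.
#' @export
load_lj_table <- function(path = system.file("extdata", "lj_params.txt",
                                             package = "physdualgcn")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  tab <- list()
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) != 3L) stop("malformed LJ table row: ", ln, call. = FALSE)
    tab[[f[1]]] <- lj_params(as.numeric(f[2]), as.numeric(f[3]))
  }
  tab
}

#' Smooth switching factor
#'
#' Multiplies each pair energy: 1 up to `r_on`, 0 from `r_off`, and the
#' classical C1 polynomial
#' `(r_off^2 - r^2)^2 (r_off^2 + 2 r^2 - 3 r_on^2) / (r_off^2 - r_on^2)^3`
#' in between; continuous with zero derivative at both window edges.
#'
#' @param r Distance(s), Angstrom (vectorized).
#' @param config A [nonbonded_config()].
#' @return Values in `[0, 1]`.
#' @export
switching_factor <- function(r, config = nonbonded_config()) {
  stopifnot(all(r >= 0))
  ron2 <- config$r_on^2; roff2 <- config$r_off^2
  u <- r^2
  s <- (roff2 - u)^2 * (roff2 + 2 * u - 3 * ron2) / (roff2 - ron2)^3
  ifelse(r <= config$r_on, 1, ifelse(r >= config$r_off, 0, s))
}

# dS/dr of the switching polynomial (0 outside the window).
switching_derivative <- function(r, config) {
  ron2 <- config$r_on^2; roff2 <- config$r_off^2
  u <- r^2
  ds <- 12 * r * (roff2 - u) * (ron2 - u) / (roff2 - ron2)^3
  ifelse(r <= config$r_on | r >= config$r_off, 0, ds)
}

#' Build a set of charged particles
#'
#' @param positions N x 3 matrix, Angstrom.
#' @param charges Length-N numeric, elementary charges.
#' @param lj_types Length-N character of LJ type keys.
#' @return A `charged_particles` object.
#' @export
charged_particles <- function(positions, charges, lj_types) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, nrow(positions) == length(charges),
            length(lj_types) == length(charges),
            all(is.finite(positions)), all(is.finite(charges)))
  structure(list(positions = positions, charges = as.numeric(charges),
                 lj_types = as.character(lj_types)),
            class = "charged_particles")
}

# Enumerate interaction pairs.  Self mode (b NULL): i < j minus exclusions
# (two-column 1-based matrix).  Cross mode: full a x b product.  Returns
# ia, ib (indices into the concatenated particle list), and r.
enumerate_pairs <- function(a, b = NULL, exclude = NULL) {
  if (is.null(b)) {
    n <- nrow(a$positions)
    if (n < 2L) return(list(ia = integer(0), ib = integer(0), r = numeric(0),
                            pos = a$positions))
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ia <- idx[, 1]; ib <- idx[, 2]
    if (!is.null(exclude) && nrow(exclude)) {
      key <- paste(pmin(exclude[, 1], exclude[, 2]),
                   pmax(exclude[, 1], exclude[, 2]))
      keep <- !(paste(ia, ib) %in% key)
      ia <- ia[keep]; ib <- ib[keep]
    }
    pos <- a$positions
  } else {
    na <- nrow(a$positions); nb <- nrow(b$positions)
    ia <- rep(seq_len(na), times = nb)
    ib <- na + rep(seq_len(nb), each = na)
    pos <- rbind(a$positions, b$positions)
  }
  d <- pos[ia, , drop = FALSE] - pos[ib, , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  if (any(r < 0.5)) {
    stop(sprintf("clash: %d particle pair(s) closer than 0.5 Angstrom (min %.3f); geometry looks broken",
                 sum(r < 0.5), min(r)), call. = FALSE)
  }
  list(ia = ia, ib = ib, r = r, pos = pos)
}

pair_charges <- function(a, b) {
  if (is.null(b)) a$charges else c(a$charges, b$charges)
}

pair_types <- function(a, b) {
  if (is.null(b)) a$lj_types else c(a$lj_types, b$lj_types)
}

#' Coulomb interaction energy
#'
#' Sum over in-range pairs of
#' `k q_i q_j / (eps_r r_ij)` times the switching factor, `k` the
#' electrostatic conversion constant, in kcal/mol.  With one particle set,
#' pairs are enumerated once (i < j) minus `exclude`; with two sets, all
#' cross pairs are summed.
#'
#' @param particles_a,particles_b [charged_particles()]; `particles_b`
#'   `NULL` for an intra-set sum.
#' @param config A [nonbonded_config()].
#' @param exclude Optional two-column matrix of 1-based excluded pairs
#'   (self mode only).
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(particles_a, particles_b = NULL,
                           config = nonbonded_config(), exclude = NULL) {
  p <- enumerate_pairs(particles_a, particles_b, exclude)
  if (!length(p$r)) return(0)
  q <- pair_charges(particles_a, particles_b)
  s <- switching_factor(p$r, config)
  sum(config$coulomb_constant * q[p$ia] * q[p$ib] /
        (config$dielectric * p$r) * s)
}

#' Lennard-Jones 12-6 interaction energy
#'
#' Sum over in-range pairs of
#' `4 eps_ij ((sigma_ij / r)^12 - (sigma_ij / r)^6)` times the switching
#' factor, with cross parameters from [combine_lj()].
#'
#' @inheritParams coulomb_energy
#' @param table Named list of [lj_params()] keyed by type (see
#'   [load_lj_table()]).
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(particles_a, particles_b = NULL,
                      config = nonbonded_config(),
                      table = load_lj_table(), exclude = NULL) {
  types <- pair_types(particles_a, particles_b)
  missing <- setdiff(unique(types), names(table))
  if (length(missing)) {
    stop("LJ parameter table is missing type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- enumerate_pairs(particles_a, particles_b, exclude)
  if (!length(p$r)) return(0)
  sig <- vapply(table, `[[`, numeric(1), "sigma")
  eps <- vapply(table, `[[`, numeric(1), "epsilon_well")
  ti <- match(types[p$ia], names(table)); tj <- match(types[p$ib], names(table))
  sij <- (sig[ti] + sig[tj]) / 2
  eij <- sqrt(eps[ti] * eps[tj])
  x6 <- (sij / p$r)^6
  s <- switching_factor(p$r, config)
  sum(4 * eij * (x6^2 - x6) * s)
}

# 1-2 and 1-3 bonded pairs of a ligand graph, 1-based two-column matrix.
bonded_exclusions <- function(graph) {
  b <- graph$bonds
  if (!nrow(b)) return(matrix(integer(0), 0L, 2L))
  e12 <- cbind(b$i, b$j) + 1L
  adj <- split(c(e12[, 2], e12[, 1]), c(e12[, 1], e12[, 2]))
  e13 <- list()
  for (mid in names(adj)) {
    nb <- unique(adj[[mid]])
    if (length(nb) >= 2L) {
      cmb <- t(utils::combn(sort(nb), 2L))
      e13[[mid]] <- cmb
    }
  }
  ex <- rbind(e12, do.call(rbind, e13))
  ex <- unique(cbind(pmin(ex[, 1], ex[, 2]), pmax(ex[, 1], ex[, 2])))
  ex
}

# Ligand graph -> particle set (heavy atoms; element symbols as LJ types,
# hydrogen contributions folded into the heavy-atom charges upstream).
#' Convert an embedded, charged ligand graph to particles
#' @param graph A `ligand_graph` with coordinates and charges.
#' @return A [charged_particles()] object.
#' @export
ligand_particles <- function(graph) {
  stopifnot(inherits(graph, "ligand_graph"))
  if (is.null(graph$coords)) stop("ligand has no coordinates; run embed_conformer()",
                                  call. = FALSE)
  if (anyNA(graph$atoms$partial_charge)) {
    stop("ligand has no partial charges; run assign_gasteiger_charges()",
         call. = FALSE)
  }
  charged_particles(graph$coords, graph$atoms$partial_charge,
                    graph$atoms$element)
}

#' Build a residue-level protein context for cross-term energies
#'
#' Places one particle per residue at its representative (C-alpha)
#' coordinate, with the residue's net side-chain charge at physiological pH
#' (+1 for K/R, -1 for D/E, 0 otherwise -- a coarse per-residue template)
#' and a generic residue LJ bead type.  Intended for the optional
#' ligand-protein cross terms of [total_physical_energy()]; it is far
#' coarser than a per-atom force-field assignment and documented as such.
#'
#' @param record A [protein_record()].
#' @param coords N x 3 matrix of representative-atom coordinates, Angstrom
#'   (e.g. from [read_pdb_coords()]).
#' @param lj_type Bead type key present in the LJ table (default `"RES"`).
#' @return A [charged_particles()] set with one particle per residue.
#' @export
protein_particles <- function(record, coords, lj_type = "RES") {
  stopifnot(inherits(record, "protein_record"))
  coords <- as.matrix(coords)
  aa <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  if (nrow(coords) != length(aa)) {
    stop(sprintf("protein '%s': %d coordinate rows for %d residues",
                 record$id, nrow(coords), length(aa)), call. = FALSE)
  }
  chg <- unname(.aa_charge_class[aa])
  chg[is.na(chg)] <- 0
  charged_particles(coords, chg, rep(lj_type, length(aa)))
}

#' Total physical interaction energy of a ligand
#'
#' `E_phys = E_Coul + E_LJ`.  With no `protein_context` the sums are the
#' intra-ligand non-bonded terms (computable from the SMILES alone once a
#' conformer is embedded), under the configured exclusion policy.  With a
#' `protein_context` ([charged_particles()] for the receptor), the
#' ligand-protein cross terms are added.
#'
#' @param ligand A `ligand_graph` with coordinates and charges.
#' @param protein_context Optional [charged_particles()] for the protein.
#' @param config A [nonbonded_config()].
#' @param table LJ parameter table.
#' @return An `energy_breakdown`: list with `e_coul`, `e_lj`, `e_phys`
#'   (kcal/mol) and `n_pairs_evaluated`.
#' @export
total_physical_energy <- function(ligand, protein_context = NULL,
                                  config = nonbonded_config(),
                                  table = load_lj_table()) {
  particles <- ligand_particles(ligand)
  exclude <- if (config$exclusion_policy == "bonded12_13")
    bonded_exclusions(ligand) else NULL
  e_coul <- coulomb_energy(particles, config = config, exclude = exclude)
  e_lj <- lj_energy(particles, config = config, table = table,
                    exclude = exclude)
  n_pairs <- length(enumerate_pairs(particles, exclude = exclude)$r)
  if (!is.null(protein_context)) {
    e_coul <- e_coul + coulomb_energy(particles, protein_context, config)
    e_lj <- e_lj + lj_energy(particles, protein_context, config, table)
    n_pairs <- n_pairs +
      nrow(particles$positions) * nrow(protein_context$positions)
  }
  structure(list(e_coul = e_coul, e_lj = e_lj, e_phys = e_coul + e_lj,
                 n_pairs_evaluated = n_pairs),
            class = "energy_breakdown")
}

#' @exportS3Method base::print
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> E_Coul = %.4f, E_LJ = %.4f, E_phys = %.4f kcal/mol (%d pairs)\n",
              x$e_coul, x$e_lj, x$e_phys, x$n_pairs_evaluated))
  invisible(x)
}

#' Analytic position gradient of a non-bonded energy
#'
#' Exact derivative of the switched Coulomb or Lennard-Jones sum with
#' respect to every particle position, for a single particle set.
#'
#' @param kind `"coulomb"` or `"lj"`.
#' @param particles A [charged_particles()] set.
#' @param config A [nonbonded_config()].
#' @param table LJ table (needed for `kind = "lj"`).
#' @param exclude Optional excluded pairs.
#' @return N x 3 matrix of dE/dposition, kcal mol^-1 A^-1.
#' @export
energy_position_gradient <- function(kind = c("coulomb", "lj"), particles,
                                     config = nonbonded_config(),
                                     table = load_lj_table(),
                                     exclude = NULL) {
  kind <- match.arg(kind)
  p <- enumerate_pairs(particles, exclude = exclude)
  n <- nrow(particles$positions)
  grad <- matrix(0, n, 3L)
  if (!length(p$r)) return(grad)
  s <- switching_factor(p$r, config)
  ds <- switching_derivative(p$r, config)
  if (kind == "coulomb") {
    q <- particles$charges
    v <- config$coulomb_constant * q[p$ia] * q[p$ib] /
      (config$dielectric * p$r)
    dv <- -v / p$r
  } else {
    sig <- vapply(table, `[[`, numeric(1), "sigma")
    eps <- vapply(table, `[[`, numeric(1), "epsilon_well")
    ti <- match(particles$lj_types[p$ia], names(table))
    tj <- match(particles$lj_types[p$ib], names(table))
    if (anyNA(ti) || anyNA(tj)) {
      stop("LJ parameter table is missing a particle type", call. = FALSE)
    }
    sij <- (sig[ti] + sig[tj]) / 2
    eij <- sqrt(eps[ti] * eps[tj])
    x6 <- (sij / p$r)^6
    v <- 4 * eij * (x6^2 - x6)
    dv <- 4 * eij * (-12 * x6^2 + 6 * x6) / p$r
  }
  dEdr <- dv * s + v * ds
  diff <- particles$positions[p$ia, , drop = FALSE] -
    particles$positions[p$ib, , drop = FALSE]
  unit <- diff / p$r
  contrib <- unit * dEdr
  for (k in 1:3) {
    grad[, k] <- grad[, k] +
      as.numeric(tapply(contrib[, k], factor(p$ia, levels = 1:n), sum,
                        default = 0)) -
      as.numeric(tapply(contrib[, k], factor(p$ib, levels = 1:n), sum,
                        default = 0))
  }
  grad
}

#' Compare analytic energy gradients with finite differences
#'
#' Central finite differences (step 1e-4 Angstrom) of the switched energy
#' versus [energy_position_gradient()], as a differentiability check of the
#' physics terms.
#'
#' @inheritParams energy_position_gradient
#' @param step Finite-difference step, Angstrom.
#' @return Maximum relative deviation (absolute deviation where the
#'   reference magnitude is below 1).
#' @export
gradient_check <- function(kind = c("coulomb", "lj"), particles,
                           config = nonbonded_config(),
                           table = load_lj_table(), exclude = NULL,
                           step = 1e-4) {
  kind <- match.arg(kind)
  efun <- function(pp) {
    if (kind == "coulomb") coulomb_energy(pp, config = config,
                                          exclude = exclude)
    else lj_energy(pp, config = config, table = table, exclude = exclude)
  }
  ana <- energy_position_gradient(kind, particles, config, table, exclude)
  num <- matrix(0, nrow(particles$positions), 3L)
  for (i in seq_len(nrow(particles$positions))) {
    for (k in 1:3) {
      up <- particles; up$positions[i, k] <- up$positions[i, k] + step
      dn <- particles; dn$positions[i, k] <- dn$positions[i, k] - step
      num[i, k] <- (efun(up) - efun(dn)) / (2 * step)
    }
  }
  denom <- pmax(abs(num), 1)
  max(abs(ana - num) / denom)
}

#' Fit a min-max scaler
#'
#' Linear map taking the observed minimum to 0 and maximum to 1, used to
#' normalize the physics energies before fusion with learned embeddings.
#' Bounds are fitted on training data only and frozen with the model.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return A `minmax_scaler` with `lower` and `upper`.
#' @export
fit_minmax <- function(values) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L) {
    stop("min-max fit needs at least two distinct values (degenerate range)",
         call. = FALSE)
  }
  structure(list(lower = min(values), upper = max(values)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Values outside the fitted range are clipped to `[0, 1]` so downstream
#' features always honor the normalization contract.
#'
#' @param scaler A [fit_minmax()] result.
#' @param value Numeric vector.
#' @return Values in `[0, 1]`.
#' @export
apply_minmax <- function(scaler, value) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  pmin(1, pmax(0, (value - scaler$lower) / (scaler$upper - scaler$lower)))
}
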