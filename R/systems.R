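# Built-in model systems. Each system is a light S3 object holding particle
# count, dimension, masses and the parameters of a named analytic surface; the
# energy/gradient kernels live in compiled code and are shared with the engine.

#' Construct a built-in model system
#'
#' Systems are selectable by name: `double_well_1d`, `double_well_2d`,
#' `muller_brown`, `torsion_surface`, `bead_chain`. Coordinates are in nm
#' (radians for `torsion_surface`), energies in kJ/mol, masses in amu.
#'
#' * `double_well_1d` / `double_well_2d`: per-coordinate quartic double well
#'   `V(x) = a ((x/b)^2 - 1)^2` with minima at `x = +-b` and barrier `a`.
#' * `muller_brown`: the conventional two-dimensional Mueller-Brown surface
#'   (coefficients read in kJ/mol and nm).
#' * `torsion_surface`: a separable periodic surface on two angles,
#'   `V = A1/2 (1 + cos 3 phi) + A2/2 (1 + cos 2 psi)`, a three-by-two-basin
#'   surrogate for a backbone dihedral landscape; period `2*pi` in both
#'   coordinates.
#' * `bead_chain`: see [make_bead_chain()].
#'
#' @param name system name (see above).
#' @param ... parameters overriding the defaults of the chosen surface:
#'   `a`, `b` (double wells), `A1`, `A2` (torsion surface), `mass`.
#' @return An object of class `pathmd_system`.
#' @export
toy_system <- function(name = c("double_well_1d", "double_well_2d",
                                "muller_brown", "torsion_surface"), ...) {
  name <- match.arg(name)
  dots <- list(...)
  grab <- function(key, default) if (!is.null(dots[[key]])) dots[[key]] else default
  mass <- grab("mass", 1)
  sys <- switch(name,
    double_well_1d = list(name = name, n_particles = 1L, dimension = 1L,
                          parameters = list(a = grab("a", 5), b = grab("b", 0.5)),
                          periodic = FALSE,
                          q0 = -grab("b", 0.5)),
    double_well_2d = list(name = name, n_particles = 1L, dimension = 2L,
                          parameters = list(a = grab("a", 5), b = grab("b", 0.5)),
                          periodic = FALSE,
                          q0 = c(-grab("b", 0.5), -grab("b", 0.5))),
    muller_brown = list(name = name, n_particles = 1L, dimension = 2L,
                        parameters = list(), periodic = FALSE,
                        q0 = c(-0.558, 1.442)),
    torsion_surface = list(name = name, n_particles = 1L, dimension = 2L,
                           parameters = list(A1 = grab("A1", 10), A2 = grab("A2", 8)),
                           periodic = TRUE,
                           q0 = c(pi / 3, pi / 2)))
  sys$masses <- rep(as.numeric(mass), sys$n_particles)
  stopifnot(all(sys$masses > 0))
  class(sys) <- "pathmd_system"
  sys
}

#' @export
print.pathmd_system <- function(x, ...) {
  cat(sprintf("<pathmd_system '%s': %d particle(s), dimension %d>\n",
              x$name, x$n_particles, x$dimension))
  if (length(x$parameters))
    cat("  parameters:",
        paste(names(x$parameters),
              vapply(x$parameters, format, ""), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Potential energy and gradient of a system
#'
#' @param system a `pathmd_system`.
#' @param q flat coordinate vector of length `n_particles * dimension` (nm, or
#'   radians for periodic surfaces).
#' @return `system_potential` returns `list(energy, gradient)`;
#'   `system_energy` and `system_gradient` return the parts.
#' @export
system_potential <- function(system, q) {
  stopifnot(inherits(system, "pathmd_system"))
  if (!all(is.finite(q))) stop("non-finite coordinates")
  .cpp_potential(unclass(system), as.numeric(q))
}

#' @rdname system_potential
#' @export
system_energy <- function(system, q) system_potential(system, q)$energy

#' @rdname system_potential
#' @export
system_gradient <- function(system, q) system_potential(system, q)$gradient

#' Quartic double-well potential
#'
#' `V(x) = sum_j a ((x_j/b)^2 - 1)^2` with analytic gradient
#' `4 a x (x^2 - b^2) / b^4` per coordinate. Minima at `+-b` (V = 0),
#' barrier top at 0 (V = a per coordinate).
#'
#' @param q coordinate vector (nm).
#' @param a barrier height per coordinate (kJ/mol), > 0.
#' @param b well position (nm), > 0.
#' @return `list(energy, gradient)`.
#' @export
double_well_potential <- function(q, a = 5, b = 0.5) {
  stopifnot(a > 0, b > 0)
  if (!all(is.finite(q))) stop("non-finite coordinates")
  r <- q^2 / b^2 - 1
  list(energy = sum(a * r^2),
       gradient = 4 * a * q * (q^2 - b^2) / b^4)
}

#' Periodic torsion surface
#'
#' Separable two-angle surface `V = A1/2 (1 + cos 3 phi) + A2/2 (1 + cos 2 psi)`
#' with period `2*pi` in both coordinates; 3 x 2 basins at
#' `phi in {pi/3, pi, 5 pi/3}`, `psi in {pi/2, 3 pi/2}`.
#'
#' @param angles length-2 vector `c(phi, psi)` in radians.
#' @param params named vector/list with `A1`, `A2` (kJ/mol).
#' @return `list(energy, gradient)`.
#' @export
torsion_surface_potential <- function(angles, params = c(A1 = 10, A2 = 8)) {
  if (!all(is.finite(angles)) || length(angles) != 2)
    stop("angles must be two finite values")
  A1 <- unname(params[["A1"]]); A2 <- unname(params[["A2"]])
  list(energy = 0.5 * A1 * (1 + cos(3 * angles[1])) +
                0.5 * A2 * (1 + cos(2 * angles[2])),
       gradient = c(-1.5 * A1 * sin(3 * angles[1]),
                    -A2 * sin(2 * angles[2])))
}

#' Mueller-Brown surface
#'
#' @param q length-2 coordinate vector.
#' @return `list(energy, gradient)`.
#' @export
muller_brown_potential <- function(q) {
  sys <- toy_system("muller_brown")
  system_potential(sys, q)
}

#' Construct a restrainable bead chain
#'
#' A 3D chain of `n` beads joined by harmonic bonds plus a purely repulsive
#' truncated-and-shifted Lennard-Jones (WCA) term between non-bonded beads, so
#' that compaction is driven only by restraints or bias. The initial
#' conformation is a straight chain along x at bond length `bond_r0`.
#'
#' @param n number of beads (>= 2).
#' @param bond_k harmonic spring constant (kJ/mol/nm^2).
#' @param bond_r0 equilibrium bond length (nm); default 0.38 nm, a typical
#'   coarse-grained Calpha-Calpha spacing.
#' @param repulsion_eps,repulsion_sigma WCA energy (kJ/mol) and size (nm).
#' @param mass bead mass (amu).
#' @return A `pathmd_system` of name `bead_chain`.
#' @export
make_bead_chain <- function(n, bond_k = 1000, bond_r0 = 0.38,
                            repulsion_eps = 1, repulsion_sigma = 0.47,
                            mass = 100) {
  if (n < 2) stop("a bead chain needs at least 2 beads")
  stopifnot(bond_k > 0, bond_r0 > 0, repulsion_eps >= 0, repulsion_sigma > 0)
  q0 <- as.numeric(rbind((seq_len(n) - 1) * bond_r0, 0, 0))
  sys <- list(name = "bead_chain", n_particles = as.integer(n), dimension = 3L,
              masses = rep(as.numeric(mass), n),
              parameters = list(bond_k = bond_k, bond_r0 = bond_r0,
                                repulsion_eps = repulsion_eps,
                                repulsion_sigma = repulsion_sigma),
              periodic = FALSE, q0 = q0)
  class(sys) <- "pathmd_system"
  sys
}

#' Generate a synthetic distance-restraint fixture
#'
#' Emulates the shape of experimental restraint sets (crosslink-style records:
#' a group of candidate atoms for the first residue and exactly one atom for
#' the second) on a bead chain or other system. Pairs are drawn among beads
#' separated by at least 3 bonds; deterministic for a fixed seed.
#'
#' @param system a `pathmd_system` (sequence separation is the index distance).
#' @param n_restraints number of records (>= 1).
#' @param d0 target distance in nm (> 0).
#' @param group1_size number of atoms in the first group.
#' @param seed integer seed.
#' @param kind restraint kind label, `"xlink"` or `"noe"`.
#' @return A data-frame-like list of restraint records (see
#'   [restraint_record()]), with attributes `seed` and `system`.
#' @export
generate_restraint_fixture <- function(system, n_restraints, d0 = 0.75,
                                       group1_size = 1, seed = 1,
                                       kind = "xlink") {
  stopifnot(inherits(system, "pathmd_system"), n_restraints >= 1, d0 > 0,
            group1_size >= 1)
  n <- system$n_particles
  pairs <- which(outer(seq_len(n), seq_len(n),
                       function(i, j) (j - i) >= 3), arr.ind = TRUE)
  if (nrow(pairs) < n_restraints)
    stop("more restraints requested than admissible pairs (separation >= 3)")
  u <- .cpp_rng_draw(.cpp_make_rng(seed, 4L), n_restraints + n_restraints * group1_size,
                     FALSE)
  sel <- integer(0)
  avail <- seq_len(nrow(pairs))
  for (r in seq_len(n_restraints)) {
    pick <- avail[floor(u[r] * length(avail)) + 1]
    sel <- c(sel, pick)
    avail <- setdiff(avail, pick)
  }
  recs <- vector("list", n_restraints)
  ui <- n_restraints
  for (r in seq_len(n_restraints)) {
    i <- pairs[sel[r], 1]; j <- pairs[sel[r], 2]
    g1 <- i
    if (group1_size > 1) {
      # widen group1 with neighbours of i that stay >= 3 bonds from j
      cand <- setdiff(seq_len(n)[abs(seq_len(n) - i) <= group1_size],
                      c(i, j))
      cand <- cand[abs(cand - j) >= 3]
      while (length(g1) < group1_size && length(cand) > 0) {
        ui <- ui + 1
        pick <- cand[floor(u[ui] * length(cand)) + 1]
        g1 <- c(g1, pick)
        cand <- setdiff(cand, pick)
      }
    }
    recs[[r]] <- restraint_record(id = r, group1 = sort(g1) - 1L,
                                  group2 = j - 1L, d0 = d0, kind = kind)
  }
  structure(recs, class = "pathmd_restraints", seed = seed,
            system = system$name)
}
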