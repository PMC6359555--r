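# Bundled reference inputs and fixture writers.

#' Reference dialanine transition-time tables
#'
#' The published mean transition times of the dialanine backbone Phi angle at
#' four temperatures, for plain MD, the multi-path-biased simulations, and the
#' biased simulations propagated along principal components. These tables are
#' inputs for the Arrhenius analysis (activation energies of about 21.05,
#' 18.77, and 9.2 kJ/mol respectively).
#'
#' @return data frame with columns `series` (`"md"`, `"path"`, `"pc"`),
#'   `temperature_K`, `tau_ps`.
#' @export
dialanine_transition_times <- function() {
  data.frame(
    series = rep(c("md", "path", "pc"), each = 4),
    temperature_K = rep(c(300, 350, 400, 450), 3),
    tau_ps = c(42696, 15759, 5877, 2550,
               7228, 614, 634, 522,
               3873, 1325, 1236, 1083))
}

#' Write fixture files
#'
#' Deterministic per seed. Kinds:
#' * `"arrhenius-tables"`: the bundled dialanine (T, tau) tables as three
#'   two-column tab-separated files (`md.tsv`, `path.tsv`, `pc.tsv`).
#' * `"restraints"`: a synthetic restraint table for a bead chain
#'   (see [generate_restraint_fixture()]).
#' * `"trajectory"`: a short unbiased double-well trajectory CSV.
#'
#' @param kind fixture kind.
#' @param out output directory (created if needed).
#' @param seed integer seed.
#' @param n number of restraints (restraints kind) or steps (trajectory kind).
#' @param d0 restraint target distance (nm).
#' @param n_beads chain length for the restraints kind.
#' @return character vector of written paths, invisibly.
#' @export
write_fixtures <- function(kind = c("arrhenius-tables", "restraints",
                                    "trajectory"),
                           out = ".", seed = 1, n = NULL, d0 = 0.75,
                           n_beads = 30) {
  kind <- match.arg(kind)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (kind == "arrhenius-tables") {
    tab <- dialanine_transition_times()
    for (s in unique(tab$series)) {
      p <- file.path(out, paste0(s, ".tsv"))
      write.table(tab[tab$series == s, c("temperature_K", "tau_ps")], p,
                  sep = "\t", row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
  } else if (kind == "restraints") {
    if (is.null(n)) n <- 11
    sys <- make_bead_chain(n_beads)
    fix <- generate_restraint_fixture(sys, n, d0 = d0, seed = seed)
    p <- file.path(out, "restraints.tsv")
    write_restraint_table(fix, p)
    paths <- p
  } else {
    if (is.null(n)) n <- 5000
    sys <- toy_system("double_well_1d")
    traj <- run_trajectory(sys, integrator_config(seed = seed), n_steps = n)
    p <- file.path(out, "trajectory.csv")
    write_trajectory_csv(traj, p)
    paths <- p
  }
  invisible(paths)
}
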