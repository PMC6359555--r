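# Run configuration: a YAML document with sections [system], [integrator],
# [bias], [restraints], [output]. Every run writes the fully resolved config
# next to its outputs so that config + seed + package version reproduce it.

#' Default run configuration
#'
#' @return nested list with sections `system`, `integrator`, `bias`,
#'   `restraints`, `output`, and `n_steps`.
#' @export
default_config <- function() {
  list(
    system = list(name = "double_well_1d", a = 5, b = 0.5, mass = 1,
                  n_beads = 12, bond_k = 1000, bond_r0 = 0.38,
                  repulsion_eps = 1, repulsion_sigma = 0.47),
    integrator = list(dt = 0.002, temperature = 300, friction = 2, seed = 1),
    bias = list(enabled = FALSE, n_r = 5, tau1_ps = 1, tau2_ps = 2.5,
                beta_md = 1e-4, beta_prime = 1e-4, eta_md = 1, eta_prime = 1,
                gamma_pp = 1e-4, hill_w = 0.1, hill_dsigma = 0,
                delta_e = 1000, well_tempered = FALSE, use_pca = FALSE,
                pca_window_ps = 5),
    restraints = list(file = NULL),
    output = list(dir = "pathmd_run", stride = 10, xyz = FALSE),
    n_steps = 10000)
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.validate_config <- function(cfg) {
  ok_sys <- c("double_well_1d", "double_well_2d", "muller_brown",
              "torsion_surface", "bead_chain")
  if (!cfg$system$name %in% ok_sys)
    stop("config error at system.name: must be one of ",
         paste(ok_sys, collapse = ", "))
  if (!is.numeric(cfg$integrator$dt) || cfg$integrator$dt <= 0)
    stop("config error at integrator.dt: must be > 0")
  if (cfg$integrator$temperature < 0)
    stop("config error at integrator.temperature: must be >= 0")
  if (cfg$integrator$friction < 0)
    stop("config error at integrator.friction: must be >= 0")
  if (cfg$n_steps < 0) stop("config error at n_steps: must be >= 0")
  if (isTRUE(cfg$bias$enabled)) {
    if (cfg$bias$n_r < 1) stop("config error at bias.n_r: must be >= 1")
    if (cfg$bias$tau1_ps < cfg$integrator$dt ||
        cfg$bias$tau2_ps < cfg$integrator$dt)
      stop("config error at bias.tau1_ps/tau2_ps: must be >= dt")
  }
  invisible(cfg)
}

#' Read a run configuration
#'
#' @param path YAML file; missing keys fall back to [default_config()].
#' @return validated config list.
#' @export
read_config <- function(path) {
  cfg <- .merge_config(default_config(), yaml::read_yaml(path))
  .validate_config(cfg)
}

#' @rdname read_config
#' @param cfg a config list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.config_system <- function(cfg) {
  s <- cfg$system
  if (s$name == "bead_chain")
    make_bead_chain(s$n_beads, s$bond_k, s$bond_r0, s$repulsion_eps,
                    s$repulsion_sigma)
  else toy_system(s$name, a = s$a, b = s$b, mass = s$mass)
}

.config_bias <- function(cfg) {
  b <- cfg$bias
  if (!isTRUE(b$enabled)) return(NULL)
  bias_params(n_r = b$n_r, tau1 = b$tau1_ps, tau2 = b$tau2_ps,
              beta_md = b$beta_md, beta_prime = b$beta_prime,
              eta_md = b$eta_md, eta_prime = b$eta_prime,
              gamma_pp = b$gamma_pp, hill_w = b$hill_w,
              hill_dsigma = b$hill_dsigma, delta_e = b$delta_e,
              well_tempered = b$well_tempered, use_pca = b$use_pca,
              pca_window = b$pca_window_ps)
}

#' Execute a configured run
#'
#' Runs the configured trajectory and writes the trajectory CSV, hill log,
#' restraint-fulfillment report (when restraints are given), optional XYZ, and
#' the fully resolved config snapshot into the output directory.
#'
#' @param cfg config list (from [read_config()] or [default_config()]) or a
#'   path to a YAML config.
#' @param overrides optional named list merged over the config.
#' @return the `pathmd_trajectory`, invisibly, with attribute `files`.
#' @export
run_config <- function(cfg, overrides = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  else cfg <- .merge_config(default_config(), cfg)
  if (!is.null(overrides)) cfg <- .merge_config(cfg, overrides)
  .validate_config(cfg)
  sys <- .config_system(cfg)
  bias <- .config_bias(cfg)
  restraints <- NULL
  if (!is.null(cfg$restraints$file))
    restraints <- parse_restraint_table(cfg$restraints$file)
  ic <- integrator_config(cfg$integrator$dt, cfg$integrator$temperature,
                          cfg$integrator$friction, cfg$integrator$seed)
  traj <- run_trajectory(sys, ic, n_steps = cfg$n_steps, bias = bias,
                         restraints = restraints,
                         stride = cfg$output$stride)
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(trajectory = file.path(cfg$output$dir, "trajectory.csv"),
             config = file.path(cfg$output$dir, "config.yaml"))
  write_trajectory_csv(traj, files[["trajectory"]])
  write_config(cfg, files[["config"]])
  if (nrow(traj$hills) > 0) {
    files["hills"] <- file.path(cfg$output$dir, "hills.csv")
    write_hill_log(traj, files[["hills"]])
  }
  if (!is.null(restraints)) {
    rep <- fulfillment_report(traj, restraints)
    files["fulfillment_csv"] <- file.path(cfg$output$dir, "fulfillment.csv")
    files["fulfillment_json"] <- file.path(cfg$output$dir, "fulfillment.json")
    write_fulfillment(rep, files[["fulfillment_csv"]],
                      files[["fulfillment_json"]])
  }
  if (isTRUE(cfg$output$xyz) && sys$dimension == 3) {
    files["xyz"] <- file.path(cfg$output$dir, "trajectory.xyz")
    write_xyz(traj, files[["xyz"]])
  }
  attr(traj, "files") <- files
  invisible(traj)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `exec/pathmd` script. Subcommands:
#' `run [config.yaml] [--key value ...]`, `analyze kinetics <tsv>`,
#' `analyze fel <csv> <column>`, `analyze restraints <traj.csv> <restr.tsv>`,
#' `analyze relaxation <csv> [M]`, `fixtures <kind> [out]`, `print-config`.
#' Exit codes: 0 success, 2 config error, 3 numeric failure, 4 analysis-input
#' error.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: pathmd <run|analyze|fixtures|print-config> ...\n")
    invisible(2L)
  }
  if (length(args) < 1) return(usage())
  cmd <- args[1]
  rest <- args[-1]
  status <- tryCatch({
    if (cmd == "print-config") {
      cat(yaml::as.yaml(default_config()))
      0L
    } else if (cmd == "run") {
      cfgpath <- if (length(rest) >= 1 && !startsWith(rest[1], "--"))
        rest[1] else NULL
      cfg <- if (is.null(cfgpath)) default_config() else read_config(cfgpath)
      # --section.key value overrides
      opts <- rest[if (is.null(cfgpath)) TRUE else -1]
      i <- 1
      while (i < length(opts)) {
        if (startsWith(opts[i], "--")) {
          keys <- strsplit(sub("^--", "", opts[i]), ".", fixed = TRUE)[[1]]
          val <- utils::type.convert(opts[i + 1], as.is = TRUE)
          cfg <- .assign_path(cfg, keys, val)
          i <- i + 2
        } else i <- i + 1
      }
      run_config(cfg)
      0L
    } else if (cmd == "fixtures") {
      kind <- if (length(rest) >= 1) rest[1] else "arrhenius-tables"
      out <- if (length(rest) >= 2) rest[2] else "."
      write_fixtures(kind, out)
      0L
    } else if (cmd == "analyze") {
      .cli_analyze(rest)
    } else usage()
  },
  error = function(e) {
    msg <- conditionMessage(e)
    cat("error:", msg, "\n", file = stderr())
    if (grepl("config error", msg)) 2L
    else if (grepl("non-finite", msg)) 3L
    else 4L
  })
  invisible(status)
}

.assign_path <- function(cfg, keys, val) {
  if (length(keys) == 1) {
    cfg[[keys]] <- val
  } else {
    cfg[[keys[1]]] <- .assign_path(cfg[[keys[1]]], keys[-1], val)
  }
  cfg
}

.cli_analyze <- function(rest) {
  if (length(rest) < 1) stop("analysis-input error: missing analyze subcommand")
  sub <- rest[1]
  if (sub == "kinetics") {
    tab <- read.table(rest[2], header = TRUE, sep = "\t")
    fit <- arrhenius_fit(tab[[1]], tab[[2]])
    cat(jsonlite::toJSON(list(Ea_kJmol = fit$Ea, lnA = fit$lnA,
                              r_squared = fit$r_squared),
                         auto_unbox = TRUE, digits = NA), "\n")
  } else if (sub == "fel") {
    tab <- utils::read.csv(rest[2])
    col <- if (length(rest) >= 3) rest[3] else "q_1"
    fel <- free_energy_landscape(tab[[col]])
    out <- data.frame(mid = fel$mids, count = as.numeric(fel$counts),
                      delta_F_kBT = as.numeric(fel$delta_F))
    utils::write.csv(out, stdout(), row.names = FALSE)
  } else if (sub == "restraints") {
    tab <- utils::read.csv(rest[2])
    restr <- parse_restraint_table(rest[3])
    qcols <- grep("^q_", names(tab))
    dim <- if (length(rest) >= 4) as.integer(rest[4]) else 3L
    rep <- fulfillment_report(as.matrix(tab[, qcols]), restr, dimension = dim,
                              times = tab$t)
    print(rep)
  } else if (sub == "relaxation") {
    tab <- utils::read.csv(rest[2])
    M <- if (length(rest) >= 3) as.integer(rest[3]) else 1L
    print(fit_multiexponential(tab[[1]], tab[[2]], M = M))
  } else stop("analysis-input error: unknown analyze subcommand ", sub)
  0L
}
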