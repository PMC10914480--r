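# End-to-end orchestration: load a region, generate (or read) its ensemble,
# compute observables, salt bridges and secondary structure where defined,
# apply the convergence rule, and write deterministic delimited-text outputs.

#' Pipeline run configuration
#'
#' Defaults mirror the simulated study conditions: a 275-500 K ladder with
#' target exchange probability 0.4, five independent copies, one-sixth
#' burn-in discard, 150 mM ionic strength, 4.0 Angstrom salt-bridge cutoff
#' with residue-separation threshold 5, convergence threshold 5%, analysis
#' temperature 298 K.
#'
#' @param region_name Name of a packaged region (e.g. `"P2phosNterm"`), or
#'   `NULL` when `ensemble_path` is given.
#' @param ensemble_path Optional path to a multi-model PDB ensemble to
#'   analyse instead of generating one.
#' @param n_frames Frames recorded per copy (default 600).
#' @param n_copies Independent copies (default 5).
#' @param n_replicas Ladder rungs (default 8; a geometric 275-500 K ladder
#'   with 8 rungs places a rung at 299.5 K, close to the 298 K analysis
#'   temperature).
#' @param burn_in Burn-in fraction discarded (default 1/6).
#' @param seed Master seed (default 1).
#' @param t_min,t_max Ladder endpoints in K (defaults 275, 500).
#' @param target_exchange Target exchange probability diagnostic (0.4).
#' @param ionic_strength mol/L (default 0.150).
#' @param cutoff Salt-bridge cutoff, Angstrom (default 4.0).
#' @param range_threshold Long-range separation threshold (default 5).
#' @param convergence_threshold Relative-SEM threshold (default 0.05).
#' @param analysis_temperature K (default 298).
#' @return List of class `run_config`.
#' @export
run_config <- function(region_name = NULL, ensemble_path = NULL,
                       n_frames = 600, n_copies = 5, n_replicas = 8,
                       burn_in = 1 / 6, seed = 1, t_min = 275, t_max = 500,
                       target_exchange = 0.4, ionic_strength = 0.150,
                       cutoff = 4.0, range_threshold = 5,
                       convergence_threshold = 0.05,
                       analysis_temperature = 298) {
  if (is.null(region_name) && is.null(ensemble_path)) {
    stop("config needs a region_name or an ensemble_path", call. = FALSE)
  }
  cfg <- list(region_name = region_name, ensemble_path = ensemble_path,
              n_frames = n_frames, n_copies = n_copies,
              n_replicas = n_replicas, burn_in = burn_in, seed = seed,
              t_min = t_min, t_max = t_max,
              target_exchange = target_exchange,
              ionic_strength = ionic_strength, cutoff = cutoff,
              range_threshold = range_threshold,
              convergence_threshold = convergence_threshold,
              analysis_temperature = analysis_temperature)
  class(cfg) <- "run_config"
  cfg
}

config_text <- function(cfg) {
  vals <- cfg[!vapply(cfg, is.null, logical(1))]
  paste0(names(vals), " = ", vapply(vals, format, character(1)))
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(config_text(cfg), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline for one configuration
#'
#' Stages, in order: load the region (when named), generate the
#' coarse-grained replica set (or read the ensemble file), compute
#' per-frame Rg/Ree series and cross-replica statistics, compute salt-bridge
#' occupancy and secondary structure where the topology supports them
#' (all-atom backbone required for secondary structure; charge-site atoms
#' for salt bridges), and evaluate the convergence rule last. All outputs
#' are delimited text under `out_dir`, each carrying the config hash in a
#' header line; a fixed seed makes the run byte-reproducible.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage logging (default FALSE).
#' @return List of class `run_report`: region, stats, convergence, paths of
#'   written files, exchange-rate diagnostic, config and its hash.
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("idrflex_run_"),
                         quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  log_stage <- function(...) if (!quiet) message("[idrflex] ", ...)
  paths <- character(0)
  write_table <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    writeLines(paste0("# config_hash ", hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    paths[[name]] <<- p
    p
  }

  reg <- NULL
  net_q <- NA_integer_
  if (!is.null(cfg$region_name)) {
    regions <- load_region_tables()
    if (!cfg$region_name %in% names(regions)) {
      stop("stage load_region: unknown region '", cfg$region_name, "'",
           call. = FALSE)
    }
    reg <- regions[[cfg$region_name]]
    net_q <- net_charge(reg)
    log_stage("region ", reg$name, ": ", nchar(reg$sequence), " residues, ",
              nrow(reg$phosphosites), " phosphosites, net charge ", net_q, "e")
  }

  if (!is.null(cfg$ensemble_path)) {
    log_stage("reading ensemble from ", cfg$ensemble_path)
    ens <- read_multimodel_pdb(cfg$ensemble_path)
    copies <- list(ens)
    replica <- NULL
    log_stage("ensemble: ", n_frames(ens), " frames, ",
              nrow(ens$topology), " atoms")
  } else {
    ladder <- build_temperature_ladder(cfg$n_replicas, cfg$t_min, cfg$t_max,
                                       cfg$target_exchange)
    model <- cg_chain_model(reg, ionic_strength = cfg$ionic_strength)
    log_stage("sampling ", cfg$n_copies, " copies x ", cfg$n_frames,
              " frames on a ", cfg$n_replicas, "-rung ladder ", cfg$t_min,
              "-", cfg$t_max, " K (seed ", cfg$seed, ")")
    replica <- sample_ensemble(model, cfg$n_frames, cfg$seed, ladder,
                               n_copies = cfg$n_copies,
                               burn_in = cfg$burn_in,
                               analysis_temperature = cfg$analysis_temperature)
    copies <- replica$ensembles
    log_stage("mean exchange acceptance ",
              sprintf("%.3f", exchange_rate(replica)),
              " (target diagnostic ", cfg$target_exchange, ")")
  }

  series <- observable_series(if (is.null(replica)) copies[[1]] else replica)
  write_table(series, "observables.tsv")
  stats <- NULL
  conv <- NULL
  if (length(copies) >= 2) {
    stats <- replica_stats(series)
    if (!is.na(net_q)) {
      stats <- rbind(stats, data.frame(name = "net_charge",
                                       grand_mean = net_q, sem = 0,
                                       n_copies = length(copies)))
      class(stats) <- c("ensemble_stat", "data.frame")
    }
    write_table(stats[, c("name", "grand_mean", "sem", "n_copies")],
                "stats.tsv")
  }

  sb <- NULL
  top <- copies[[1]]$topology
  if (any(top$charge_site)) {
    log_stage("salt-bridge occupancy (cutoff ", cfg$cutoff, " A)")
    config <- salt_bridge_config(cfg$cutoff, cfg$range_threshold)
    sb <- occupancy(copies[[1]], config)
    for (cp in seq_along(copies)[-1]) {
      sb$occupancy <- sb$occupancy +
        occupancy(copies[[cp]], config)$occupancy
    }
    sb$occupancy <- sb$occupancy / length(copies)
    write_table(sb, "salt_bridges.tsv")
  } else {
    log_stage("no charge-site atoms; salt-bridge stage skipped")
  }

  ss <- NULL
  if (has_backbone(top)) {
    log_stage("secondary-structure assignment")
    ss <- ss_fractions(lapply(copies, assign_secondary_structure))
    ss_df <- data.frame(residue = rep(rownames(ss), ncol(ss)),
                        class = rep(colnames(ss), each = nrow(ss)),
                        fraction = as.vector(ss))
    write_table(ss_df, "ss_profile.tsv")
  } else {
    log_stage("no backbone atoms; secondary-structure stage skipped")
  }

  if (!is.null(stats)) {
    conv <- check_convergence(stats, cfg$convergence_threshold)
    p <- file.path(out_dir, "convergence.txt")
    writeLines(c(paste0("# config_hash ", hash),
                 paste0("converged = ", conv$converged),
                 sprintf("%s_ratio = %.6f", conv$report$name,
                         conv$report$ratio)), p)
    paths[["convergence.txt"]] <- p
    log_stage("convergence: ", conv$converged)
  }

  structure(
    list(region = reg, net_charge = net_q, stats = stats,
         convergence = conv, salt_bridges = sb, ss_profile = ss,
         exchange_rate = if (!is.null(replica)) exchange_rate(replica) else NA,
         paths = paths, seeds = if (!is.null(replica)) replica$seeds else NULL,
         config = cfg, config_hash = hash, out_dir = out_dir),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report ", if (!is.null(x$region)) x$region$name else "file input",
      ", hash ", substr(x$config_hash, 1, 8), ">\n", sep = "")
  if (!is.null(x$stats)) print(as.data.frame(
    x$stats[, c("name", "grand_mean", "sem")]))
  invisible(x)
}

#' Compare two pipeline reports (e.g. phosphorylated vs unphosphorylated)
#'
#' Per-observable differences `a - b` with SEMs propagated in quadrature,
#' plus the secondary-structure difference profile when both reports carry
#' one. The two runs must cover the same region span.
#'
#' @param report_a,report_b `run_report` objects with statistics.
#' @return List with `deltas` (data.frame: name, delta, sem) and
#'   `ss_difference` (or NULL).
#' @export
compare_regions <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "run_report"), inherits(report_b, "run_report"))
  if (!is.null(report_a$region) && !is.null(report_b$region)) {
    span <- function(r) c(r$first_residue, r$first_residue + nchar(r$sequence))
    if (!identical(span(report_a$region), span(report_b$region))) {
      stop("reports cover different region spans", call. = FALSE)
    }
  }
  a <- report_a$stats
  b <- report_b$stats
  if (is.null(a) || is.null(b)) stop("both reports need statistics",
                                     call. = FALSE)
  common <- intersect(a$name, b$name)
  ia <- match(common, a$name); ib <- match(common, b$name)
  deltas <- data.frame(
    name = common,
    delta = a$grand_mean[ia] - b$grand_mean[ib],
    sem = sqrt(a$sem[ia]^2 + b$sem[ib]^2))
  ssd <- NULL
  if (!is.null(report_a$ss_profile) && !is.null(report_b$ss_profile)) {
    ssd <- ss_difference(report_a$ss_profile, report_b$ss_profile)
  }
  list(deltas = deltas, ss_difference = ssd)
}
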