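#' Default simulation configuration
#'
#' Nested list of every stage's parameters with the model's standard
#' defaults: eps_m = -1.5, J_int = -3.92, l_c = 15 bp, l0 = 45 bp, lp = 50
#' nm, lt = 100 nm, L1 = 0.332 nm, 10.5 bp per helical turn, 147 bp wrap,
#' R = 4.19 nm, V0 = 1 kBT, minimum cluster size 4. Ensemble defaults: 1D
#' observables from 20 replicates of 1,000-nucleosome arrays; 3D fibers 200
#' nucleosomes long.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    marks = list(M_1d = 1000L, M_3d = 200L, rho_target = 0.11,
                 rho_band = NULL, corr_length_nuc = 10),
    binding = list(eps_m = -1.5, J_int = -3.92, mu_hp1 = -9.7, l_c = 15L),
    linkers = list(l0 = 45, n_sweeps = 500L, burn_in = 250L),
    growth = list(lp = 50, lt = 100, L1 = 0.332, bp_per_turn = 10.5,
                  wrap_bp = 147L, radius = 4.19, turns = 1.7, pitch = 2.39),
    sterics = list(V0 = 1.0, R = 4.19, n_steps = 100000L,
                   stretch_scale = 90, seg_max = 20L,
                   amp_crank = 0.6, amp_pivot = 0.4,
                   amp_single_t = 0.4, amp_single_r = 0.3,
                   run_relax = TRUE),
    clusters = list(min_size = 4L, bin_width = 5, normalized = FALSE),
    ensemble = list(n_replicates = 20L),
    seed = 1L,
    output = list(dir = NULL, write_pdb = FALSE)
  )
}

check_no_unknown_keys <- function(config, template, path = "") {
  extra <- setdiff(names(config), names(template))
  if (length(extra) > 0) {
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste0(path, extra, collapse = ", ")), call. = FALSE)
  }
  for (k in names(config)) {
    if (is.list(template[[k]]) && !is.null(config[[k]])) {
      if (!is.list(config[[k]])) {
        stop(sprintf("configuration key '%s%s' must be a section", path, k),
             call. = FALSE)
      }
      check_no_unknown_keys(config[[k]], template[[k]], paste0(path, k, "$"))
    }
  }
  invisible(config)
}

#' Validate and complete a simulation configuration
#'
#' Fills missing keys from [default_config()], rejects unknown keys, and
#' checks value constraints before any computation starts.
#'
#' @param config partial or full configuration list.
#' @return completed configuration.
#' @export
validate_config <- function(config = list()) {
  template <- default_config()
  check_no_unknown_keys(config, template)
  merged <- template
  for (k in names(config)) {
    if (is.list(template[[k]]) && !is.null(config[[k]])) {
      for (kk in names(config[[k]])) merged[[k]][[kk]] <- config[[k]][[kk]]
    } else {
      merged[[k]] <- config[[k]]
    }
  }
  m <- merged
  if (m$linkers$l0 <= 1) stop("linkers$l0 must exceed 1 bp", call. = FALSE)
  if (m$binding$l_c < 1) stop("binding$l_c must be at least 1 bp",
                              call. = FALSE)
  if (!is.null(m$marks$rho_band)) {
    rb <- m$marks$rho_band
    if (length(rb) != 2 || any(rb < 0 | rb > 1) || rb[1] > rb[2]) {
      stop("marks$rho_band must be an increasing pair within [0, 1]",
           call. = FALSE)
    }
  } else if (m$marks$rho_target < 0 || m$marks$rho_target > 1) {
    stop("marks$rho_target must lie in [0, 1]", call. = FALSE)
  }
  if (m$marks$corr_length_nuc <= 0) {
    stop("marks$corr_length_nuc must be positive", call. = FALSE)
  }
  if (m$marks$M_3d > m$marks$M_1d) {
    stop("marks$M_3d cannot exceed marks$M_1d", call. = FALSE)
  }
  for (key in c("lp", "lt", "L1", "bp_per_turn", "radius")) {
    if (m$growth[[key]] <= 0) {
      stop(sprintf("growth$%s must be positive", key), call. = FALSE)
    }
  }
  if (m$sterics$V0 <= 0 || m$sterics$R <= 0) {
    stop("sterics$V0 and sterics$R must be positive", call. = FALSE)
  }
  merged
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns a validated configuration.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_objects <- function(config) {
  g <- config$growth
  list(
    binding = binding_params(config$binding$eps_m, config$binding$J_int,
                             config$binding$mu_hp1, config$binding$l_c),
    link = linker_params(config$linkers$l0, config$binding$l_c),
    mech = dna_mechanics(g$lp, g$lt, g$L1, 2 * pi / g$bp_per_turn),
    geom = nucleosome_geometry(g$wrap_bp, g$radius, g$turns, g$pitch, g$L1),
    elastic = elastic_model(g$lp, g$lt, g$L1, 2 * pi / g$bp_per_turn,
                            config$sterics$stretch_scale),
    steric = steric_params(config$sterics$V0, config$sterics$R),
    mp = move_params(amp_crank = config$sterics$amp_crank,
                     amp_pivot = config$sterics$amp_pivot,
                     amp_single_t = config$sterics$amp_single_t,
                     amp_single_r = config$sterics$amp_single_r,
                     seg_max = config$sterics$seg_max)
  )
}

#' Simulate one replicate of the full model
#'
#' Runs marks -> binding -> linker sampling on a `M_1d`-nucleosome array,
#' then grows and (optionally) sterically relaxes a 3D fiber from the first
#' `M_3d` nucleosomes, and extracts cluster statistics. When `rho_band` is
#' set, the replicate's marked fraction is drawn uniformly within the band
#' (mark-abundance conditions are reported as ranges, not points).
#'
#' @param config validated configuration (see [validate_config()]).
#' @param seed replicate seed; spawns independent per-stage streams.
#' @param record_bp keep per-bp frames of the grown fiber.
#' @return list with `pattern`, `state` (linker_state), `occupancy`
#'   (binding_summary), `config3d` (relaxed `chain_config`, NULL when
#'   `M_3d < 2`), `clusters` (cluster table), `short_linker_fraction`,
#'   `rho_effective`, and `acceptance`.
#' @export
simulate_replicate <- function(config = validate_config(), seed = 1,
                               record_bp = FALSE) {
  obj <- config_objects(config)
  seeds <- derive_seeds(seed, 5)
  rho <- if (!is.null(config$marks$rho_band)) {
    with_seed(seeds[1], runif(1, config$marks$rho_band[1],
                              config$marks$rho_band[2]))
  } else config$marks$rho_target

  pattern <- generate_marks(config$marks$M_1d, rho,
                            config$marks$corr_length_nuc, seed = seeds[2],
                            check_size = FALSE)
  state <- run_sampler(pattern, obj$binding, obj$link,
                       n_sweeps = config$linkers$n_sweeps, seed = seeds[3])
  occ <- evaluate_ensemble(pattern, state$gamma, obj$binding)
  # time-average the short-linker fraction over post-burn-in sweeps; the
  # collective cluster formation makes the instantaneous fraction fluctuate
  burn <- min(config$linkers$burn_in, config$linkers$n_sweeps - 1L)
  slf <- mean(state$trace[(burn + 1L):config$linkers$n_sweeps])

  config3d <- NULL
  clusters <- NULL
  acceptance <- NULL
  M3 <- config$marks$M_3d
  if (M3 >= 2) {
    lens3d <- state$lengths[seq_len(M3 - 1)]
    grown <- grow_chain(lens3d, obj$geom, obj$mech, seed = seeds[4],
                        record_bp = record_bp)
    if (isTRUE(config$sterics$run_relax)) {
      rel <- relax(grown, obj$elastic, obj$steric,
                   n_steps = config$sterics$n_steps, seed = seeds[5],
                   mp = obj$mp, trace_every = 0)
      config3d <- rel$config
      acceptance <- rel$acceptance
    } else {
      config3d <- grown
    }
    clusters <- cluster_table(config3d, l_c = obj$binding$l_c,
                              min_size = config$clusters$min_size,
                              normalized = config$clusters$normalized)
  }
  list(pattern = pattern, state = state, occupancy = occ,
       config3d = config3d, clusters = clusters,
       short_linker_fraction = slf,
       rho_effective = rho, acceptance = acceptance)
}

#' Run the full simulation pipeline
#'
#' Executes the stages marks -> binding -> linkers -> growth -> sterics ->
#' clusters for `n_replicates` replicates, writes intermediate tables and a
#' machine-readable summary to the output directory (when one is set), and
#' returns the summary. Any stage failure halts with a diagnostic naming the
#' stage.
#'
#' @param config configuration list (validated with [validate_config()]
#'   before any computation).
#' @param quiet suppress progress messages.
#' @return invisible list with `short_linker_fraction` (ensemble mean),
#'   `mean_cluster_size` (nm, NA when no clusters), `histogram`,
#'   `distribution`, `replicates`, and `config`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  config <- validate_config(config)
  n_rep <- config$ensemble$n_replicates
  rep_seeds <- derive_seeds(config$seed, n_rep)

  reps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    if (!quiet) message(sprintf("replicate %d/%d", r, n_rep))
    reps[[r]] <- tryCatch(
      simulate_replicate(config, seed = rep_seeds[r]),
      error = function(e) {
        stop(sprintf("pipeline replicate %d failed: %s", r,
                     conditionMessage(e)), call. = FALSE)
      })
  }

  slf <- mean(vapply(reps, `[[`, numeric(1), "short_linker_fraction"))
  configs3d <- Filter(Negate(is.null), lapply(reps, `[[`, "config3d"))
  dist <- if (length(configs3d) > 0) {
    ensemble_distribution(configs3d, l_c = config$binding$l_c,
                          min_size = config$clusters$min_size,
                          bin_width = config$clusters$bin_width,
                          normalized = config$clusters$normalized)
  } else NULL

  summary <- list(
    short_linker_fraction = slf,
    mean_cluster_size = if (is.null(dist)) NA_real_ else dist$mean_size,
    n_clusters_pooled = if (is.null(dist)) 0L else length(dist$sizes),
    histogram = if (is.null(dist)) NULL else dist$histogram,
    distribution = dist,
    replicates = reps,
    config = config
  )

  dir <- config$output$dir
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    first <- reps[[1]]
    write_pattern(first$pattern, file.path(dir, "pattern.csv"))
    write_occupancy(first$occupancy, file.path(dir, "occupancy.csv"))
    write_linker_state(first$state, file.path(dir, "linkers.csv"),
                       pattern = first$pattern)
    write.csv(data.frame(sweep = seq_along(first$state$trace),
                         short_linker_fraction = first$state$trace),
              file.path(dir, "convergence.csv"), row.names = FALSE)
    if (!is.null(first$config3d)) {
      write_chain(first$config3d, file.path(dir, "chain.csv"))
      if (isTRUE(config$output$write_pdb)) {
        write_pdb(first$config3d, file.path(dir, "chain.pdb"))
      }
    }
    all_clusters <- do.call(rbind, lapply(seq_along(reps), function(r) {
      cl <- reps[[r]]$clusters
      if (is.null(cl) || nrow(cl) == 0) return(NULL)
      cbind(replicate = r, cl)
    }))
    if (!is.null(all_clusters)) {
      write.csv(all_clusters, file.path(dir, "clusters.csv"),
                row.names = FALSE)
    }
    if (!is.null(dist)) {
      write_histogram(dist, file.path(dir, "histogram.csv"))
    }
    yaml::write_yaml(
      list(short_linker_fraction = slf,
           mean_cluster_size = summary$mean_cluster_size,
           n_clusters_pooled = summary$n_clusters_pooled,
           n_replicates = n_rep, seed = config$seed),
      file.path(dir, "summary.yaml"))
    write_config(config, file.path(dir, "config.yaml"))
  }
  invisible(summary)
}

#' Parameter-sweep experiment runner
#'
#' Runs the pipeline over a grid of mark-abundance conditions x HP1 chemical
#' potentials and reports per-cell ensemble observables. Mark abundance may
#' be given as point fractions or as bands (length-2 ranges, sampled
#' uniformly per replicate).
#'
#' @param config base configuration.
#' @param rho list of marked-tail fractions (scalars) and/or bands (length-2
#'   vectors).
#' @param mu vector of HP1 chemical potentials (kBT).
#' @param quiet suppress progress messages.
#' @return data.frame with one row per grid cell: `rho_lo`, `rho_hi`, `mu`,
#'   `short_linker_fraction`, `mean_cluster_size`, `n_clusters`, and the
#'   pooled mass of the first two histogram bins (`first_two_bin_fraction`).
#' @export
sweep_grid <- function(config = list(), rho = list(0.11), mu = -9.7,
                       quiet = TRUE) {
  config <- validate_config(config)
  if (!is.list(rho)) rho <- as.list(rho)
  grid <- expand.grid(ir = seq_along(rho), mu = mu)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    rr <- rho[[grid$ir[g]]]
    cfg <- config
    if (length(rr) == 2) {
      cfg$marks$rho_band <- rr
    } else {
      cfg$marks$rho_band <- NULL
      cfg$marks$rho_target <- rr
    }
    cfg$binding$mu_hp1 <- grid$mu[g]
    cfg$output$dir <- NULL
    res <- run_pipeline(cfg, quiet = quiet)
    hist <- res$histogram
    f2 <- if (!is.null(hist) && nrow(hist) >= 1) {
      sum(hist$fraction[seq_len(min(2, nrow(hist)))])
    } else NA_real_
    data.frame(rho_lo = min(rr), rho_hi = max(rr), mu = grid$mu[g],
               short_linker_fraction = res$short_linker_fraction,
               mean_cluster_size = res$mean_cluster_size,
               n_clusters = res$n_clusters_pooled,
               first_two_bin_fraction = f2)
  })
  out <- do.call(rbind, out)
  out[order(out$mu, out$rho_lo), , drop = FALSE]
}

#' Preset experiment grids
#'
#' Three standard sweeps: `"mark_abundance"` varies the marked-tail fraction
#' over the low/moderate/high euchromatin bands (0-2%, 8-10%, 14-16%) at a
#' fixed chemical potential of -9.7 kBT; `"hp1_potential"` varies the
#' chemical potential over \{-9.8, -9.7, -9.6\} kBT at 10-12% marked tails;
#' `"cluster_histogram"` fixes mu = -9.66 kBT and spans four abundance bands
#' for cluster-size histogram comparisons.
#'
#' @param name preset name.
#' @return list with `rho` (list of bands) and `mu` (vector), suitable for
#'   [sweep_grid()].
#' @export
preset_sweep <- function(name = c("mark_abundance", "hp1_potential",
                                  "cluster_histogram")) {
  name <- match.arg(name)
  switch(name,
    mark_abundance = list(rho = list(c(0, 0.02), c(0.08, 0.10),
                                     c(0.14, 0.16)),
                          mu = -9.7),
    hp1_potential = list(rho = list(c(0.10, 0.12)),
                         mu = c(-9.8, -9.7, -9.6)),
    cluster_histogram = list(rho = list(c(0, 0.02), c(0.04, 0.06),
                                        c(0.08, 0.10), c(0.14, 0.16)),
                             mu = -9.66)
  )
}
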