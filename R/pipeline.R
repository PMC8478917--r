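# End-to-end orchestration: simulate -> analyse -> summarise, with seed
# management, config echo and tidy per-cell result tables.

#' Default run configuration
#'
#' One parameter block per stage; any block set to NULL disables that stage.
#' Sizes default to a quick demonstration run. The master `seed` is split
#' deterministically per stage (hash of master seed and stage name) so that
#' adding a stage never reshuffles another stage's randomness.
#'
#' @param seed master seed
#' @param out_dir output directory
#' @param tracks list: n_cells, conditions (named list of [crw_params()]
#'   overrides), delta_t, TR, alpha_mode
#' @param edge list of [synth_edge_movie()] arguments
#' @param flow list of [flow_movie_params()] overrides
#' @param flim list of [tcspc_params()] overrides
#' @return list of class `run_config`
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("lamellikine_run_"),
                       tracks = list(n_cells = 20L,
                                     conditions = list(
                                       control = list(speed_mean = 0.4, kappa = 1),
                                       perturbed = list(speed_mean = 0.6, kappa = 4)),
                                     frame_interval = 5, n_frames = 48L,
                                     noise_sd = 0, delta_t = 15, TR = 4L,
                                     alpha_mode = "raw"),
                       edge = list(arc_protruding = 90, edge_speed = 1,
                                   retraction_speed = 0.5, radius_um = 15,
                                   shape = c(120L, 120L), pixel_size = 0.4,
                                   frame_interval = 5, n_frames = 8L),
                       flow = list(shape = c(96L, 96L), flow_speed = 1.5,
                                   protrusion_speed = 0.5, n_frames = 10L),
                       flim = list(shape = c(24L, 24L), fraction_quenched = 0.3,
                                   photons_per_pixel = 5000)) {
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(seed = as.integer(seed), out_dir = out_dir, tracks = tracks,
                 edge = edge, flow = flow, flim = flim),
            class = "run_config")
}

#' Execute a full pipeline run
#'
#' Runs the enabled stages in dependency order, writes per-cell CSV tables,
#' a MANIFEST, the config echo and a run log under `config$out_dir`, and
#' returns the combined per-cell result table. Identical configs and seeds
#' give byte-identical tables.
#'
#' @param config a [run_config()]
#' @return data.frame result table (one row per cell/metric with provenance)
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = logf, append = TRUE)
  cat("", file = logf)
  cfg_ser <- rapply(unclass(config), as.vector, how = "replace")
  jsonlite::write_json(cfg_ser, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  rows <- list()
  add_rows <- function(df) rows[[length(rows) + 1L]] <<- df
  prov <- function(n, condition, metric, value) {
    data.frame(cell_id = n, condition = condition, metric = metric,
               value = value, seed = config$seed,
               version = as.character(utils::packageVersion("lamellikine")))
  }
  t_start <- proc.time()[3]
  if (!is.null(config$tracks)) {
    tc <- config$tracks
    seed0 <- split_seed(config$seed, "tracks")
    log_line("stage tracks: seed %d", seed0)
    pp <- persistence_params(delta_t = tc$delta_t, TR = tc$TR,
                             alpha_mode = tc$alpha_mode)
    i <- 0L
    for (cond in names(tc$conditions)) {
      ov <- tc$conditions[[cond]]
      for (c_i in seq_len(tc$n_cells)) {
        i <- i + 1L
        cp <- do.call(crw_params, c(list(n_frames = tc$n_frames,
                                         frame_interval = tc$frame_interval,
                                         noise_sd = tc$noise_sd,
                                         seed = split_seed(seed0, paste0("cell", i))),
                                    ov))
        tr <- simulate_crw(cp, cell_id = sprintf("%s_%02d", cond, c_i))
        st <- track_stats(tr, pp)
        add_rows(prov(tr$cell_id, cond, "MTS", st$MTS))
        add_rows(prov(tr$cell_id, cond, "MTP", st$MTP))
      }
    }
  }
  if (!is.null(config$edge)) {
    seed0 <- split_seed(config$seed, "edge")
    log_line("stage edge: seed %d", seed0)
    em <- do.call(synth_edge_movie, c(config$edge, list(seed = seed0)))
    prof <- edge_velocity(em$mask)
    cs <- cone_speed(prof)
    run <- longest_uninterrupted_run(prof)
    add_rows(prov("edge_cell", "synthetic", "cone_speed", mean(cs$cone_speed)))
    add_rows(prov("edge_cell", "synthetic", "stability",
                  protrusion_stability(prof)))
    add_rows(prov("edge_cell", "synthetic", "longest_run", run$track_mean))
  }
  if (!is.null(config$flow)) {
    seed0 <- split_seed(config$seed, "flow")
    log_line("stage flow: seed %d", seed0)
    fp <- do.call(flow_movie_params, c(config$flow, list(seed = seed0)))
    fm <- synth_flow_movie(fp)
    layers <- piv_movie(fm$movie, fm$mask)
    dense <- interpolate_dense(layers, piv_params(), dim(fm$movie)[1:2],
                               pixel_size_of(fm$movie),
                               frame_interval_of(fm$movie))
    fl <- mean_flow_speed(dense, fm$mask)
    add_rows(prov("flow_cell", "synthetic", "mean_flow", fl$cell_mean))
    add_rows(prov("flow_cell", "synthetic", "assembly_rate",
                  assembly_rate(fl$cell_mean, fp$protrusion_speed)))
  }
  if (!is.null(config$flim)) {
    seed0 <- split_seed(config$seed, "flim")
    log_line("stage flim: seed %d", seed0)
    tp <- do.call(tcspc_params, c(config$flim, list(seed = seed0)))
    stack <- synth_tcspc(tp)
    li <- lifetime_image(stack)
    em2 <- efficiency_map(li, tau_donor_ref = tp$tau_donor)
    wm <- weighted_mean_efficiency(em2)
    add_rows(prov("flim_cell", "synthetic", "weighted_E", wm$weighted))
  }
  tab <- do.call(rbind, rows)
  out_csv <- file.path(config$out_dir, "results.csv")
  utils::write.csv(format(tab, digits = 10), out_csv, row.names = FALSE,
                   quote = FALSE)
  writeLines(c("lamellikine run manifest",
               sprintf("seed: %d", config$seed),
               sprintf("rows: %d", nrow(tab)),
               "files: config.json results.csv run.log"),
             file.path(config$out_dir, "MANIFEST"))
  log_line("completed in %.1f s", proc.time()[3] - t_start)
  tab
}

#' Group summaries of a result table
#'
#' Mean, SEM (sd over cells divided by sqrt of the number of cells) and n
#' per condition for one metric, plus control-normalised values (control
#' mean maps to 1).
#'
#' @param table result table from [run_pipeline()] (long format: cell_id,
#'   condition, metric, value)
#' @param metric metric name to summarise
#' @param control_label condition used as normalisation reference (optional)
#' @return data.frame (condition, mean, sem, n, norm_mean)
#' @export
compare_groups <- function(table, metric, control_label = NULL) {
  avail <- unique(table$metric)
  if (!metric %in% avail)
    stop_bad("unknown metric '%s'; available: %s", metric,
             paste(avail, collapse = ", "))
  sub <- table[table$metric == metric, ]
  out <- do.call(rbind, lapply(split(sub, sub$condition), function(g) {
    n <- nrow(g)
    data.frame(condition = g$condition[1],
               mean = mean(as.numeric(g$value)),
               sem = if (n > 1) stats::sd(as.numeric(g$value)) / sqrt(n) else 0,
               n = n)
  }))
  rownames(out) <- NULL
  if (!is.null(control_label)) {
    if (!control_label %in% out$condition)
      stop_bad("control group '%s' not present", control_label)
    out$norm_mean <- out$mean / out$mean[out$condition == control_label]
  }
  out
}
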