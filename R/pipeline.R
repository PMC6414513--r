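#' Run the full analysis pipeline from one configuration
#'
#' Executes the stages in order: simulate (when the config names a built-in
#' scenario and no `events` are supplied), bead normalization, debarcoding,
#' arcsinh transformation, gating, SPADE-style clustering with annotation,
#' population statistics, Friedman-Rafsky comparisons, and trajectory
#' reconstruction. Stages without the required inputs (no bead channels, no
#' barcode channels, no FR reference, no trajectory lineage) are skipped and
#' recorded as such. One config seed feeds a per-stage seed sequence hashed
#' from the stage name, so inserting a stage does not perturb the seeds
#' downstream.
#'
#' A raw-count mirror of the events is carried alongside the transformed
#' table because the IdU positivity rule and the median shifts are defined on
#' raw counts; both views are subset identically at every filtering stage, so
#' event-count conservation holds for each.
#'
#' @param config A `pipeline_config` from [load_config()] or
#'   [scenario_config()].
#' @param events Optional raw-count [event_table()] to analyse instead of
#'   simulating (the simulate stage is then skipped).
#' @param out_dir Optional directory; when given, the gated events (FCS), the
#'   manifest (JSON) and the stats tables (TSV) are written into it.
#' @param verbose Log one line per stage.
#' @return A `pipeline_result` list: `manifest` (a `run_manifest`), `events`
#'   (final transformed table), `raw_events`, `graph` (annotated
#'   `cluster_graph`), `population` (per event), `condition` (per event, when
#'   debarcoded), `stats`, `fr`, `trajectory`, `config`.
#' @export
run_pipeline <- function(config, events = NULL, out_dir = NULL,
                         verbose = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config else load_config(config)
  seed <- cfg$seed
  manifest <- list()
  t_total <- proc.time()[["elapsed"]]
  log_stage <- function(stage, n_in, n_out, status, t0) {
    row <- data.frame(stage = stage, status = status,
                      n_in = n_in, n_out = n_out,
                      seed = stage_seed(seed, stage),
                      elapsed = round(proc.time()[["elapsed"]] - t0, 3))
    manifest[[length(manifest) + 1L]] <<- row
    if (verbose)
      message(sprintf("[%s] %s: %d -> %d events (%.2fs)", stage, status,
                      n_in, n_out, row$elapsed))
  }

  # -- simulate ---------------------------------------------------------
  design <- NULL
  t0 <- proc.time()[["elapsed"]]
  if (is.null(events)) {
    if (is.null(cfg$scenario))
      stop("no events supplied and the config names no scenario")
    design <- make_scenario(cfg$scenario, seed = stage_seed(seed, "simulate"),
                            n_events = cfg$n_events %||% NULL)
    events <- simulate_events(design)
    log_stage("simulate", 0L, n_events(events), "run", t0)
  } else {
    stopifnot(inherits(events, "event_table"))
    log_stage("simulate", n_events(events), n_events(events), "skipped", t0)
  }

  # -- bead normalization ----------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  bead_ch <- events$channels$name[events$channels$kind == "bead"]
  norm_report <- NULL
  n_in <- n_events(events)
  if (length(bead_ch) &&
      any(rowSums(events$values[, match_channel(events, bead_ch),
                                drop = FALSE] > 100) == length(bead_ch))) {
    bn <- bead_normalize(events, bead_ch)
    norm_report <- bn$report
    events <- subset_events(bn$table, !bn$is_bead)
    log_stage("normalize", n_in, n_events(events), "run", t0)
  } else {
    log_stage("normalize", n_in, n_in, "skipped", t0)
  }

  # -- debarcode --------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  bc_ch <- cfg$barcode$channels %||%
    events$channels$name[events$channels$kind == "barcode"]
  condition <- NULL
  debarcode_report <- NULL
  n_in <- n_events(events)
  if (length(bc_ch)) {
    scheme <- barcode_scheme(bc_ch, k = cfg$barcode$k %||% 3L)
    db <- debarcode(events, scheme,
                    min_separation = cfg$barcode$min_separation %||% 0.3,
                    cofactor = cfg$cofactor)
    keep <- !is.na(db$sample_id)
    sample_names <- if (!is.null(design))
      vapply(design$samples, `[[`, character(1L), "name")
    else paste0("sample", seq_along(scheme$keys))
    sid <- db$sample_id[keep]
    condition <- ifelse(sid <= length(sample_names), sample_names[sid],
                        paste0("key", sid))
    debarcode_report <- data.frame(
      assigned = sum(keep), unassigned = sum(!keep),
      doublet_flagged = sum(db$doublet_flag))
    events <- subset_events(events, keep)
    log_stage("debarcode", n_in, n_events(events), "run", t0)
  } else {
    log_stage("debarcode", n_in, n_in, "skipped", t0)
  }

  # -- arcsinh ----------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  raw_events <- events
  events <- arcsinh_transform(events, cfg$cofactor)
  log_stage("arcsinh", n_events(events), n_events(events), "run", t0)

  # -- gate -------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  gate_report <- NULL
  n_in <- n_events(events)
  if (length(cfg$gates)) {
    g <- apply_gates(events, cfg$gates, cofactor = cfg$cofactor)
    gate_report <- g$report
    events <- subset_events(events, g$mask)
    raw_events <- subset_events(raw_events, g$mask)
    if (!is.null(condition)) condition <- condition[g$mask]
    log_stage("gate", n_in, n_events(events), "run", t0)
  } else {
    log_stage("gate", n_in, n_in, "skipped", t0)
  }

  # -- cluster ----------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  cl_ch <- cfg$clustering$channels %||%
    events$channels$name[events$channels$kind == "phenotype"]
  params <- spade_params(cl_ch,
                         downsample_target = cfg$clustering$downsample_target,
                         n_nodes = cfg$clustering$n_nodes,
                         density_k = cfg$clustering$density_k,
                         seed = stage_seed(seed, "cluster"))
  graph <- spade_cluster(events, params, cofactor = cfg$cofactor)
  population <- NULL
  if (!is.null(cfg$annotation)) {
    graph <- annotate_nodes(graph, cfg$annotation)
    population <- event_populations(graph)
  }
  log_stage("cluster", n_events(events), n_events(events), "run", t0)

  # -- stats ------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  sp <- stat_params(bootstrap_R = cfg$stats$bootstrap_R,
                    ci_level = cfg$stats$ci_level,
                    idu_threshold = cfg$stats$idu_threshold,
                    idu_report_min = cfg$stats$idu_report_min,
                    seed = stage_seed(seed, "stats"))
  stats_out <- pipeline_stats(raw_events, population, condition, cfg, sp)
  log_stage("stats", n_events(events), n_events(events), "run", t0)

  # -- frtest -----------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  fr <- NULL
  if (!is.null(cfg$fr$reference) && !is.null(population)) {
    fp <- fr_params(cfg$fr$channels, S = cfg$fr$S, N = cfg$fr$N,
                    seed = stage_seed(seed, "frtest"))
    ci <- match_channel(events, fp$channels)
    half <- fp$S %/% 2L
    pops <- split(seq_len(n_events(events)), population)
    pops <- pops[vapply(pops, length, integer(1L)) >= half &
                   names(pops) != "unassigned"]
    mats <- lapply(pops, function(idx) events$values[idx, ci, drop = FALSE])
    if (cfg$fr$reference %in% names(mats))
      fr <- fr_matrix(mats, cfg$fr$reference, params = fp)
    log_stage("frtest", n_events(events), n_events(events),
              if (is.null(fr)) "skipped" else "run", t0)
  } else {
    log_stage("frtest", n_events(events), n_events(events), "skipped", t0)
  }

  # -- trajectory -------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  trajectory <- NULL
  if (!is.null(cfg$trajectory$lineage) && !is.null(population)) {
    idx <- which(population == cfg$trajectory$lineage)
    if (length(idx) > cfg$trajectory$k) {
      sub <- subset_events(events, idx)
      tp <- trajectory_params(
        cfg$trajectory$channels, k = cfg$trajectory$k, l = cfg$trajectory$l,
        n_graphs = cfg$trajectory$n_graphs,
        n_waypoints = cfg$trajectory$n_waypoints,
        # root the ordering at the most progenitor-like (first-channel-high) cell
        start_rule = function(m) which.max(m[, 1L]),
        seed = stage_seed(seed, "trajectory"))
      pt <- pseudotime(sub, tp, cofactor = cfg$cofactor)
      trend_ch <- union(cfg$trajectory$channels,
                        events$channels$name[events$channels$kind ==
                                               "biosynthesis"])
      trajectory <- list(result = pt, events = idx,
                         trends = channel_trends(sub, pt, trend_ch))
    }
    log_stage("trajectory", n_events(events), n_events(events),
              if (is.null(trajectory)) "skipped" else "run", t0)
  } else {
    log_stage("trajectory", n_events(events), n_events(events), "skipped", t0)
  }

  manifest <- do.call(rbind, manifest)
  run <- structure(list(config_hash = config_hash(cfg), seed = seed,
                        stages = manifest,
                        elapsed = proc.time()[["elapsed"]] - t_total),
                   class = "run_manifest")
  out <- structure(list(manifest = run, events = events,
                        raw_events = raw_events, graph = graph,
                        population = population, condition = condition,
                        stats = stats_out, fr = fr, trajectory = trajectory,
                        norm_report = norm_report,
                        debarcode_report = debarcode_report,
                        gate_report = gate_report, config = cfg),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# Per-population summary tables on the raw-count mirror.
pipeline_stats <- function(raw_events, population, condition, cfg, sp) {
  out <- list()
  has_idu <- "IdU" %in% channel_names(raw_events)
  bio_ch <- intersect(
    raw_events$channels$name[raw_events$channels$kind == "biosynthesis"],
    channel_names(raw_events))
  if (!is.null(population)) {
    pops <- sort(unique(population))
    tab <- data.frame(population = pops,
                      n = as.integer(table(factor(population, pops))))
    if (has_idu) {
      tab$idu_fraction <- NA_real_
      for (i in seq_along(pops)) {
        sub <- subset_events(raw_events, population == pops[i])
        tab$idu_fraction[i] <- idu_fraction_report(sub, sp)$fraction
      }
    }
    for (ch in setdiff(bio_ch, "IdU")) {
      tab[[paste0(ch, "_median")]] <- vapply(pops, function(p)
        transformed_median(channel_values(raw_events, ch)[population == p],
                           cfg$cofactor), numeric(1L))
    }
    out$populations <- tab
  }
  if (!is.null(condition) && !is.null(population) &&
      !is.null(cfg$comparisons)) {
    sig_ch <- raw_events$channels$name[raw_events$channels$kind == "signaling"]
    channels <- cfg$comparisons$channels %||%
      intersect(c(setdiff(bio_ch, "IdU"), sig_ch, "CD69"),
                channel_names(raw_events))
    out$shifts <- shift_table(raw_events, population, condition, channels,
                              control = cfg$comparisons$control,
                              cofactor = cfg$cofactor)
  }
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_events(res$events, file.path(out_dir, "events.fcs"))
  jsonlite::write_json(
    list(config_hash = res$manifest$config_hash, seed = res$manifest$seed,
         stages = res$manifest$stages),
    file.path(out_dir, "manifest.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (nm in names(res$stats))
    utils::write.table(res$stats[[nm]],
                       file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$fr))
    utils::write.table(res$fr, file.path(out_dir, "fr_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest (config ", x$config_hash, ", seed ", x$seed, ", ",
      sprintf("%.1fs", x$elapsed), ")\n", sep = "")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$manifest)
  invisible(x)
}

#' Headline report of a built-in scenario
#'
#' Runs the scenario end-to-end with [run_pipeline()] and extracts its
#' headline tables:
#' \describe{
#'   \item{cellcycle}{per-phase transformed medians of the biosynthesis
#'     channels (phases from the simulation truth labels, which survive the
#'     pipeline).}
#'   \item{pbmc_timecourse}{the shift table of biosynthesis, signaling and
#'     activation channels per annotated population across the debarcoded
#'     stimulation times.}
#'   \item{marrow_hierarchy}{per annotated population: event count, IdU
#'     fraction, bootstrap confidence intervals of the nascent-RNA and
#'     nascent-protein medians, and the Friedman-Rafsky matrix against the
#'     reference population with stars.}
#' }
#'
#' @param name Scenario name (see [scenario_names()]).
#' @param seed Seed.
#' @param n_events Event count override (see [make_scenario()]).
#' @param verbose Log pipeline stages.
#' @return A `scenario_report` list: `scenario`, `tables` (named list of data
#'   frames), `result` (the full `pipeline_result`).
#' @export
scenario_report <- function(name, seed = 0L, n_events = NULL,
                            verbose = FALSE) {
  if (length(name) != 1L || !name %in% scenario_names())
    stop("unknown scenario '", paste(name, collapse = ", "),
         "'; valid scenarios: ", paste(scenario_names(), collapse = ", "))
  cfg <- scenario_config(name, seed = seed, n_events = n_events)
  res <- run_pipeline(cfg, verbose = verbose)
  tables <- switch(name,
    cellcycle = {
      phase <- res$raw_events$labels$phase
      keep <- phase %in% cell_cycle_phases()
      bio <- c("IdU", "BRU", "Puromycin")
      tab <- data.frame(phase = cell_cycle_phases())
      tab$n <- as.integer(table(factor(phase[keep], cell_cycle_phases())))
      for (ch in bio) {
        v <- channel_values(res$raw_events, ch)
        tab[[paste0(ch, "_median")]] <- vapply(
          cell_cycle_phases(), function(ph)
            transformed_median(v[keep & phase == ph], cfg$cofactor),
          numeric(1L))
      }
      list(phase_medians = tab, populations = res$stats$populations)
    },
    pbmc_timecourse = list(shifts = res$stats$shifts,
                           populations = res$stats$populations),
    marrow_hierarchy = {
      tab <- res$stats$populations
      sp <- stat_params(bootstrap_R = cfg$stats$bootstrap_R,
                        ci_level = cfg$stats$ci_level,
                        seed = stage_seed(seed, "stats"))
      for (ch in c("BRU", "Puromycin")) {
        lo <- hi <- rep(NA_real_, nrow(tab))
        v_all <- asinh(channel_values(res$raw_events, ch) / cfg$cofactor)
        for (i in seq_len(nrow(tab))) {
          v <- v_all[res$population == tab$population[i]]
          if (length(v)) {
            b <- bootstrap_median(v, sp)
            lo[i] <- b$ci_low
            hi[i] <- b$ci_high
          }
        }
        tab[[paste0(ch, "_ci_low")]] <- lo
        tab[[paste0(ch, "_ci_high")]] <- hi
      }
      list(populations = tab, fr_matrix = res$fr)
    })
  structure(list(scenario = name, tables = tables, result = res),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("scenario_report:", x$scenario, "\n")
  for (nm in names(x$tables)) {
    cat("--", nm, "--\n")
    print(utils::head(x$tables[[nm]], 20L), row.names = FALSE)
  }
  invisible(x)
}
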