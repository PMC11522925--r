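# End-to-end orchestration: run the analysis stages on a fixture bundle (or
# user-supplied files) under a single configuration, with a reproducible
# summary report.

#' Run the full analysis pipeline
#'
#' Executes the stages in order contacts -> energetics -> entry -> fes ->
#' pathways -> kinetics on synthetic fixtures generated under
#' `config$seed` (or on files named in the config). Any stage can be
#' skipped. A failed stage is recorded in the report and later stages that
#' depend on it are skipped; completed outputs are kept.
#'
#' @param config Nested list. Recognized entries:
#'   \describe{
#'     \item{seed}{integer seed for every generator (default 1).}
#'     \item{analysis}{arguments for [analysis_config()].}
#'     \item{synth}{`n_residues`, `n_units`, `n_events`, `noise`,
#'       `n_contact_frames` for the fixture generators.}
#'     \item{stages}{named logical flags: `contacts`, `energetics`,
#'       `entry`, `fes`, `pathways`, `kinetics` (default all `TRUE`).}
#'     \item{kinetics}{`km`, `vmax`, `n`, `noise`, `conversion`,
#'       `substrate_load` for the kinetic stage.}
#'     \item{out_dir}{optional output directory for stage tables; refuses
#'       to overwrite an existing directory unless `force = TRUE`.}
#'     \item{force}{allow overwriting `out_dir` (default `FALSE`).}
#'   }
#' @param quiet Suppress stage progress messages (default `TRUE`).
#' @return A list of class `run_report`: per-stage status, the resolved
#'   configuration, headline numbers and (when `out_dir` is set) output
#'   paths with their md5 hashes.
#' @export
run_all <- function(config = list(), quiet = TRUE) {
  cfg <- resolve_config(config)
  if (!is.null(cfg$out_dir)) {
    if (dir.exists(cfg$out_dir) &&
        length(list.files(cfg$out_dir)) && !isTRUE(cfg$force))
      stop("out_dir exists and is non-empty; use force = TRUE to overwrite")
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  say <- function(...) if (!quiet) message(...)
  report <- list(config = cfg, stages = list(), headline = list(),
                 outputs = list())
  ac <- do.call(analysis_config, c(cfg$analysis, list(seed = cfg$seed)))

  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) {
      report$stages[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    say("stage ", name, " ...")
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- paste("failed:", conditionMessage(res))
      NULL
    } else {
      report$stages[[name]] <<- "ok"
      res
    }
  }

  sys <- make_toy_system(n_residues = cfg$synth$n_residues,
                         n_units = cfg$synth$n_units, seed = cfg$seed)
  truth <- attr(sys, "truth")

  contacts_res <- run_stage("contacts", function() {
    traj <- make_contact_trajectory(sys, persistent = cfg$synth$persistent,
                                    n_frames = cfg$synth$n_contact_frames,
                                    seed = cfg$seed)
    cm <- contact_matrix(traj, sys, cutoff = ac$contact_cutoff)
    pers <- persistence_filter(cm, ac$persistence_fraction)
    split <- proximal_distal_split(cm, traj, sys, ac$proximal_radius)
    if (!is.null(cfg$out_dir))
      write_contact_table(cm, split, sys,
                          file.path(cfg$out_dir, "contacts.tsv"))
    list(map = cm, persistent = pers, split = split, traj = traj)
  })
  if (!is.null(contacts_res))
    report$headline$persistent_contacts <- length(contacts_res$persistent)

  entry_trajs <- lapply(seq_len(cfg$synth$n_events), function(i)
    simulate_entry(sys, corridor = (i - 1L) %% 3L + 1L,
                   seed = cfg$seed + i, noise = cfg$synth$noise))

  energetics_res <- run_stage("energetics", function() {
    ser <- residue_energy_series(entry_trajs[[1]], sys, ac)
    if (!is.null(cfg$out_dir))
      write_energy_table(ser, file.path(cfg$out_dir, "energies.tsv"))
    ser
  })

  entry_res <- run_stage("entry", function() {
    series <- lapply(entry_trajs, entry_series, system = sys, config = ac)
    events <- lapply(series, segment_entries, config = ac)
    tally <- tally_entries(unlist(events, recursive = FALSE), series)
    if (!is.null(cfg$out_dir))
      write_entry_events(unlist(events, recursive = FALSE),
                         file.path(cfg$out_dir, "events.json"))
    list(series = series, events = events, tally = tally)
  })
  if (!is.null(entry_res)) {
    report$headline$entry_tally <- entry_res$tally
  }

  fes_res <- run_stage("fes", function() {
    if (is.null(entry_res)) stop("entry stage unavailable")
    ser_c <- unlist(lapply(entry_res$series, `[[`, "ser_c"))
    eint <- if (!is.null(energetics_res)) {
      tot <- Reduce(`+`, lapply(energetics_res, `[[`, "total"))
      rep(tot, length.out = length(ser_c))
    } else stop("energetics stage unavailable")
    grid <- fes2d(ser_c, eint, temperature = ac$temperature)
    feats <- fes_features(grid, boundary = ac$productive_cutoff, axis = "x")
    if (!is.null(cfg$out_dir))
      write_fes_grid(grid, file.path(cfg$out_dir, "fes.tsv"))
    list(grid = grid, features = feats)
  })
  if (!is.null(fes_res))
    report$headline$fes_minima <-
      if (is.null(fes_res$features$minima)) 0L
      else nrow(fes_res$features$minima)

  pathways_res <- run_stage("pathways", function() {
    if (is.null(entry_res)) stop("entry stage unavailable")
    feats <- entry_feature_matrix(entry_res$events, entry_trajs, sys,
                                  radius = ac$pca_radius)
    model <- pca_fit(feats)
    proj <- project_and_fes(model, feats, temperature = ac$temperature)
    paths <- assign_pathways(proj$projections, feats$event,
                             weights = feats$weight,
                             k = min(3L, length(unique(feats$event))),
                             seed = cfg$seed)
    if (!is.null(cfg$out_dir))
      write_pc_model(model, file.path(cfg$out_dir, "pc_model.json"))
    list(model = model, pathways = paths)
  })
  if (!is.null(pathways_res))
    report$headline$pathway_counts <-
      table(pathways_res$pathways$pathway)

  kinetics_res <- run_stage("kinetics", function() {
    kc <- cfg$kinetics
    conv <- fit_mm(make_kinetic_data(kc$km, kc$vmax, mode = "conv",
                                     n = kc$n, noise = kc$noise,
                                     seed = cfg$seed))
    inv <- fit_mm(make_kinetic_data(kc$km_inv, kc$vmax_inv, mode = "inv",
                                    n = kc$n, noise = kc$noise,
                                    seed = cfg$seed + 1L))
    sp <- secondary_params(conv, inv, conversion = kc$conversion,
                           substrate_load = kc$substrate_load)
    list(conv = conv, inv = inv, secondary = sp)
  })
  if (!is.null(kinetics_res))
    report$headline$kinetics <- list(
      conv_km = kinetics_res$conv$K_m, inv_km = kinetics_res$inv$K_m,
      k_cat = kinetics_res$secondary$k_cat,
      molar_eta = kinetics_res$secondary$molar_eta)

  if (!is.null(cfg$out_dir)) {
    files <- list.files(cfg$out_dir, full.names = TRUE)
    report$outputs <- as.list(tools::md5sum(files))
    jsonlite::write_json(cfg, file.path(cfg$out_dir, "config.json"),
                         auto_unbox = TRUE, force = TRUE)
  }
  structure(report, class = "run_report")
}

#' @keywords internal
resolve_config <- function(config) {
  defaults <- list(
    seed = 1L,
    analysis = list(),
    synth = list(n_residues = 30, n_units = 5, n_events = 6, noise = 0.3,
                 n_contact_frames = 40, persistent = c(5L, 8L, 12L)),
    stages = list(contacts = TRUE, energetics = TRUE, entry = TRUE,
                  fes = TRUE, pathways = TRUE, kinetics = TRUE),
    kinetics = list(km = 0.3, vmax = 1.0, km_inv = 0.5, vmax_inv = 2.0,
                    n = 8, noise = 0.05, conversion = 1.66,
                    substrate_load = 1.5),
    out_dir = NULL, force = FALSE)
  cfg <- utils::modifyList(defaults, config)
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  cfg$seed <- as.integer(cfg$seed)
  bad <- setdiff(names(cfg$stages),
                 c("contacts", "energetics", "entry", "fes", "pathways",
                   "kinetics"))
  if (length(bad)) stop("unknown stage flag(s): ", paste(bad, collapse = ", "))
  cfg
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed ", x$config$seed, "\n", sep = "")
  for (s in names(x$stages))
    cat(sprintf("  %-10s %s\n", s, x$stages[[s]]))
  h <- x$headline
  if (!is.null(h$persistent_contacts))
    cat("  persistent contacts:", h$persistent_contacts, "\n")
  if (!is.null(h$entry_tally))
    cat("  entries:", h$entry_tally$n_events, "events,",
        h$entry_tally$n_productive, "productive (",
        h$entry_tally$n_si, "si /", h$entry_tally$n_re, "re )\n")
  if (!is.null(h$pathway_counts)) {
    cat("  pathway sizes:",
        paste(names(h$pathway_counts), as.integer(h$pathway_counts),
              sep = ":", collapse = " "), "\n")
  }
  if (!is.null(h$kinetics))
    cat("  kinetics: conv K_m", signif(h$kinetics$conv_km, 3),
        "g/L, inv K_m", signif(h$kinetics$inv_km, 3),
        "uM, molar eta", signif(h$kinetics$molar_eta, 3), "\n")
  invisible(x)
}
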