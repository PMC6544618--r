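# Workflow commands tying the stages together:
# simulate -> ROI/histogram/parameters -> group comparison, plus the
# analytic worked examples. Each command reads a validated config, logs the
# resolved settings to the message stream, and writes only files.

known_config_keys <- list(
  top = c("seed", "out", "entropy_base", "cohort", "phantom", "roi",
          "volumes_dir", "profiles_a", "profiles_b", "profiles"),
  group = c("label", "target_mean", "target_sigma", "target_skewness",
            "n_specimens", "outer_radius", "canal_radius", "n_slices",
            "voxel_size_um", "specimen_jitter_sd", "seed"),
  phantom = c("densities", "slope", "intercept", "noise_sigma",
              "insert_radius", "insert_length", "background_level",
              "voxel_size_um", "seed"),
  roi = c("length_mm", "center_fraction", "mask_threshold")
)

check_keys <- function(block, known, where) {
  unknown <- setdiff(names(block), known)
  if (length(unknown) > 0L) {
    abort_ctx(sprintf("unknown %s config key(s): %s", where,
                      paste(unknown, collapse = ", ")),
              "cortexture_config_error")
  }
}

#' Read and validate a run configuration
#'
#' YAML or JSON with optional blocks `cohort` (sub-blocks `control`,
#' `treated`), `phantom`, `roi`, plus scalar keys `seed`, `out`,
#' `entropy_base`, `volumes_dir`, `profiles_a`, `profiles_b`. Unknown keys
#' anywhere are rejected.
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- read_config_file(path)
  check_keys(cfg, known_config_keys$top, "top-level")
  if (!is.null(cfg$cohort)) {
    check_keys(cfg$cohort, c("control", "treated"), "cohort")
    for (arm in c("control", "treated")) {
      if (is.null(cfg$cohort[[arm]])) {
        abort_ctx(sprintf("cohort config must define '%s'", arm),
                  "cortexture_config_error")
      }
      check_keys(cfg$cohort[[arm]], known_config_keys$group,
                 paste0("cohort$", arm))
    }
  }
  if (!is.null(cfg$phantom)) {
    check_keys(cfg$phantom, known_config_keys$phantom, "phantom")
  }
  if (!is.null(cfg$roi)) check_keys(cfg$roi, known_config_keys$roi, "roi")
  if (!is.null(cfg$entropy_base) &&
      !cfg$entropy_base %in% c("natural", "log2")) {
    abort_ctx("entropy_base must be 'natural' or 'log2'",
              "cortexture_config_error")
  }
  cfg
}

log_info <- function(fmt, ...) {
  message(sprintf(paste0("INFO [cortexture] ", fmt), ...))
}

resolve_out <- function(config, out) {
  out <- out %||% config$out
  if (is.null(out)) {
    abort_ctx("no output directory given (config key 'out' or --out)",
              "cortexture_config_error")
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a synthetic cohort and/or BMD phantom
#'
#' Writes one TIFF volume per specimen plus `manifest.csv` for a cohort
#' block, and `phantom.tif`, `phantom_labels.tif` and `phantom_inserts.csv`
#' for a phantom block.
#'
#' @param config validated config list (see [read_run_config()]).
#' @param out output directory (overrides `config$out`).
#' @param seed base seed (overrides `config$seed`).
#' @return Invisible character vector of files written.
#' @export
run_simulate <- function(config, out = NULL, seed = NULL) {
  out <- resolve_out(config, out)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  written <- character(0)
  if (is.null(config$cohort) && is.null(config$phantom)) {
    abort_ctx("simulate needs a 'cohort' or 'phantom' config block",
              "cortexture_config_error")
  }
  if (!is.null(config$cohort)) {
    mk <- function(block, default_seed) {
      block$seed <- block$seed %||% default_seed
      do.call(group_spec, block)
    }
    control <- mk(config$cohort$control, seed)
    treated <- mk(config$cohort$treated, seed + 1L)
    log_info("simulate cohort: %s (n=%d) vs %s (n=%d), base seed %d",
             control$label, control$n_specimens,
             treated$label, treated$n_specimens, seed)
    cohort <- generate_cohort(control, treated)
    specs <- list(control = control, treated = treated)
    for (arm in c("control", "treated")) {
      vols <- cohort[[arm]]
      ids <- cohort$manifest$specimen_id[
        cohort$manifest$group == specs[[arm]]$label]
      for (i in seq_along(vols)) {
        f <- file.path(out, paste0(ids[i], ".tif"))
        write_volume(vols[[i]], f)
        written <- c(written, f)
      }
    }
    mf <- file.path(out, "manifest.csv")
    write_table(cohort$manifest, mf)
    written <- c(written, mf)
  }
  if (!is.null(config$phantom)) {
    block <- config$phantom
    block$seed <- block$seed %||% seed
    if (!is.null(block$densities)) block$densities <- unlist(block$densities)
    spec <- do.call(phantom_spec, block)
    log_info("simulate phantom: %d inserts, noise sigma %.3g, seed %d",
             length(spec$densities), spec$noise_sigma, spec$seed)
    ph <- generate_bmd_phantom(spec)
    f <- file.path(out, "phantom.tif")
    write_volume(ph$volume, f)
    fl <- file.path(out, "phantom_labels.tif")
    write_volume(voxel_volume(ph$labels, spec$voxel_size_um), fl)
    ft <- file.path(out, "phantom_inserts.csv")
    write_table(ph$insert_table, ft)
    written <- c(written, f, fl, ft)
  }
  invisible(written)
}

#' Analyze simulated or scanned volumes
#'
#' Reads the manifest in `config$volumes_dir`, extracts the ROI pixel
#' population of each specimen, and writes `profiles.csv` (one row per
#' specimen: id, group, the seven parameters and the quartile fraction)
#' plus one histogram CSV per specimen under `histograms/`. A specimen
#' whose ROI is empty is recorded as failed and the run continues; the
#' command fails only if every specimen fails.
#'
#' @inheritParams run_simulate
#' @return Invisible data frame of profiles.
#' @export
run_analyze <- function(config, out = NULL, seed = NULL) {
  out <- resolve_out(config, out)
  vdir <- config$volumes_dir
  if (is.null(vdir)) {
    abort_ctx("analyze needs config key 'volumes_dir'",
              "cortexture_config_error")
  }
  manifest <- read.csv(file.path(vdir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  spec <- do.call(roi_spec, config$roi %||% list())
  base <- config$entropy_base %||% "natural"
  log_info("analyze %d specimens: slab %.3g mm, threshold %d, entropy base %s",
           nrow(manifest), spec$length_mm, spec$mask_threshold, base)
  hist_dir <- file.path(out, "histograms")
  dir.create(hist_dir, showWarnings = FALSE)
  rows <- list()
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$specimen_id[i]
    res <- tryCatch({
      vol <- read_volume(file.path(vdir, paste0(id, ".tif")))
      px <- extract_roi_pixels(vol, spec)
      write_histogram(build_histogram(px),
                      file.path(hist_dir, paste0(id, ".csv")))
      cbind(data.frame(specimen_id = id, group = manifest$group[i],
                       stringsAsFactors = FALSE),
            as.data.frame(texture_profile(px, entropy_base = base)))
    }, cortexture_error = function(e) {
      log_info("specimen %s failed: %s", id, conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- c(failures, id) else rows[[id]] <- res
  }
  if (length(rows) == 0L) {
    abort_ctx("all specimens failed ROI analysis", "cortexture_runtime_error")
  }
  profiles <- do.call(rbind, rows)
  rownames(profiles) <- NULL
  write_table(profiles, file.path(out, "profiles.csv"))
  if (length(failures) > 0L) {
    write_table(data.frame(specimen_id = failures),
                file.path(out, "failures.csv"))
  }
  invisible(profiles)
}

#' Compare two groups of analyzed profiles
#'
#' Reads profiles either from one CSV with a `group` column
#' (`config$profiles`) or from two per-group CSVs (`config$profiles_a`,
#' `config$profiles_b`) and writes the seven-row comparison report
#' `comparison.csv`.
#'
#' @inheritParams run_simulate
#' @return Invisible comparison data frame.
#' @export
run_compare <- function(config, out = NULL, seed = NULL) {
  out <- resolve_out(config, out)
  if (!is.null(config$profiles)) {
    df <- read.csv(config$profiles, stringsAsFactors = FALSE)
    groups <- unique(df$group)
    if (length(groups) != 2L) {
      abort_ctx("profiles CSV must contain exactly 2 groups",
                "cortexture_config_error")
    }
    pa <- df[df$group == groups[1], ]
    pb <- df[df$group == groups[2], ]
    labels <- groups
  } else if (!is.null(config$profiles_a) && !is.null(config$profiles_b)) {
    pa <- read.csv(config$profiles_a, stringsAsFactors = FALSE)
    pb <- read.csv(config$profiles_b, stringsAsFactors = FALSE)
    labels <- c("groupA", "groupB")
  } else {
    abort_ctx("compare needs 'profiles' or 'profiles_a'/'profiles_b'",
              "cortexture_config_error")
  }
  log_info("compare %s (n=%d) vs %s (n=%d)", labels[1], nrow(pa),
           labels[2], nrow(pb))
  report <- compare_groups(pa, pb, label_a = labels[1], label_b = labels[2])
  write_table(report, file.path(out, "comparison.csv"))
  invisible(report)
}

#' Write the analytic worked examples and demo images
#'
#' Produces `worked_examples.csv` (three rows: family, entropy, quartile
#' percentage), `worked_examples_r2.csv` (their squared correlation) and
#' the two 16 x 16 demonstration volumes `demo_uniform.tif` /
#' `demo_shuffled.tif`.
#'
#' @inheritParams run_simulate
#' @return Invisible worked-example list.
#' @export
run_worked_examples <- function(config = list(), out = NULL, seed = NULL) {
  out <- resolve_out(config, out)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  log_info("worked examples: seed %d", seed)
  wx <- worked_example_table()
  write_table(wx$table, file.path(out, "worked_examples.csv"))
  write_table(data.frame(r_squared = wx$r_squared),
              file.path(out, "worked_examples_r2.csv"))
  demos <- demo_images(seed)
  write_volume(demos$uniform, file.path(out, "demo_uniform.tif"))
  write_volume(demos$shuffled, file.path(out, "demo_shuffled.tif"))
  invisible(wx)
}

parse_cli_args <- function(args) {
  if (length(args) == 0L) {
    abort_ctx("usage: cortexture <simulate|analyze|compare|worked-examples> [--config PATH] [--seed INT] [--out DIR] [--entropy-base natural|log2] [--threshold INT] [--length-mm FLOAT]",
              "cortexture_config_error")
  }
  cmd <- args[1]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--") || i == length(args)) {
      abort_ctx(sprintf("malformed argument '%s'", key),
                "cortexture_config_error")
    }
    opts[[substring(key, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  list(cmd = cmd, opts = opts)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `analyze`, `compare` and
#' `worked-examples` with flags `--config`, `--seed`, `--out`,
#' `--entropy-base`, `--threshold`, `--length-mm`. Flag values override the
#' config file. Intended to be called from a thin Rscript wrapper (see
#' `system.file("cli", "cortexture.R", package = "cortexture")`).
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status: 0 success, 1 runtime failure,
#'   2 configuration error.
#' @export
cortexture_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    parsed <- parse_cli_args(args)
    cfg <- if (!is.null(parsed$opts$config)) {
      read_run_config(parsed$opts$config)
    } else {
      list()
    }
    if (!is.null(parsed$opts$`entropy-base`)) {
      cfg$entropy_base <- parsed$opts$`entropy-base`
    }
    if (!is.null(parsed$opts$threshold) || !is.null(parsed$opts$`length-mm`)) {
      cfg$roi <- cfg$roi %||% list()
      if (!is.null(parsed$opts$threshold)) {
        cfg$roi$mask_threshold <- as.integer(parsed$opts$threshold)
      }
      if (!is.null(parsed$opts$`length-mm`)) {
        cfg$roi$length_mm <- as.numeric(parsed$opts$`length-mm`)
      }
    }
    seed <- if (!is.null(parsed$opts$seed)) as.integer(parsed$opts$seed)
    out <- parsed$opts$out
    switch(parsed$cmd,
      "simulate" = run_simulate(cfg, out = out, seed = seed),
      "analyze" = run_analyze(cfg, out = out, seed = seed),
      "compare" = run_compare(cfg, out = out, seed = seed),
      "worked-examples" = run_worked_examples(cfg, out = out, seed = seed),
      abort_ctx(sprintf("unknown command '%s'", parsed$cmd),
                "cortexture_config_error")
    )
    0L
  },
  cortexture_config_error = function(e) {
    message("ERROR [cortexture] ", conditionMessage(e))
    2L
  },
  cortexture_unattainable_skewness_error = function(e) {
    message("ERROR [cortexture] ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("ERROR [cortexture] ", conditionMessage(e))
    1L
  })
  status
}
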