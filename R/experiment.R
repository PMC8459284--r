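#' Define an experiment grid
#'
#' The reference grid crosses bottleneck sizes 200/512/715/1024 with 4 or 8
#' training epochs, 20 trials per cell: 160 runs per experiment.
#'
#' @param bottlenecks integer vector of bottleneck sizes.
#' @param epoch_settings integer vector of epoch counts.
#' @param trials runs per cell.
#' @param base a [chain_config()] supplying every remaining parameter
#'   (structure size, population, generations, seed base, ...).
#' @return A list of class `"experiment_grid"`.
#' @export
experiment_grid <- function(bottlenecks = c(200L, 512L, 715L, 1024L),
                            epoch_settings = c(4L, 8L),
                            trials = 20L,
                            base = chain_config()) {
  stopifnot(length(bottlenecks) >= 1, all(bottlenecks >= 1),
            length(epoch_settings) >= 1, all(epoch_settings >= 0),
            trials >= 1, inherits(base, "chain_config"))
  structure(list(
    bottlenecks = as.integer(bottlenecks),
    epoch_settings = as.integer(epoch_settings),
    trials = as.integer(trials),
    base = base
  ), class = "experiment_grid")
}

.config_as_record <- function(config) {
  rec <- unclass(config)
  rec$agent_config <- unclass(rec$agent_config)
  rec
}

#' Run a full experiment grid
#'
#' Executes every (bottleneck, epochs, trial) cell as one chain. The run
#' seed of cell k (in grid order) is `base$master_seed + k - 1`, so the
#' whole grid derives from one integer. Each run streams its snapshots to
#' `<output_dir>/<run_id>.jsonl` — one JSON object per agent per
#' generation, carrying the run id, the resolved configuration, the
#' quantifier bit-string and all measures — and the grid maintains
#' `<output_dir>/manifest.json`. Rerunning with an existing manifest skips
#' completed runs, making the grid resumable.
#'
#' @param grid an [experiment_grid()].
#' @param experiment 1 (plain transmission) or 2 (shuffling channel).
#' @param output_dir writable directory for JSONL files and the manifest.
#' @param quiet suppress progress messages.
#' @return The manifest as a tibble (invisibly), one row per run with
#'   `run_id`, `seed`, `bottleneck`, `epochs`, `trial`, `file`, `completed`.
#' @export
run_grid <- function(grid, experiment = 1L, output_dir, quiet = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  if (!experiment %in% c(1L, 2L)) {
    stop("experiment must be 1 or 2", call. = FALSE)
  }
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  if (file.access(output_dir, 2L) != 0L) {
    stop("output directory is not writable: ", output_dir, call. = FALSE)
  }
  manifest_path <- file.path(output_dir, "manifest.json")
  done <- character(0)
  if (file.exists(manifest_path)) {
    old <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
    done <- old$run_id[old$completed &
                         file.exists(file.path(output_dir, old$file))]
  }

  cells <- expand.grid(trial = seq_len(grid$trials),
                       epochs = grid$epoch_settings,
                       bottleneck = grid$bottlenecks)
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    cell <- cells[k, ]
    run_id <- sprintf("exp%d_b%d_e%d_t%02d", experiment, cell$bottleneck,
                      cell$epochs, cell$trial)
    seed <- grid$base$master_seed + k - 1L
    file_name <- paste0(run_id, ".jsonl")
    rows[[k]] <- tibble::tibble(
      run_id = run_id, seed = seed,
      bottleneck = as.integer(cell$bottleneck),
      epochs = as.integer(cell$epochs), trial = as.integer(cell$trial),
      file = file_name, completed = TRUE
    )
    if (run_id %in% done) next
    config <- chain_config(
      n = grid$base$n, population = grid$base$population,
      bottleneck = cell$bottleneck, epochs = cell$epochs,
      generations = grid$base$generations,
      shuffle = experiment == 2L, master_seed = seed,
      replace = grid$base$replace,
      keep_confidences = grid$base$keep_confidences
    )
    if (!quiet) message("running ", run_id, " (seed ", seed, ")")
    chain <- run_chain(config, quiet = quiet)
    .write_snapshots_jsonl(chain, run_id,
                           file.path(output_dir, file_name))
    if (!quiet) {
      last <- chain$snapshots[
        chain$snapshots$generation == config$generations - 1L, ]
      if (all(last$degeneracy == 1)) {
        warning("run ", run_id, ": final population fully degenerate",
                call. = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = FALSE,
                       digits = NA)
  invisible(manifest)
}

.write_snapshots_jsonl <- function(chain, run_id, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  cfg <- .config_as_record(chain$config)
  snaps <- chain$snapshots
  for (r in seq_len(nrow(snaps))) {
    rec <- list(
      run = run_id,
      config = cfg,
      generation = snaps$generation[r],
      agent = snaps$agent[r],
      parent = snaps$parent[r],
      quantifier = snaps$quantifier[r],
      upward = snaps$upward[r],
      downward = snaps$downward[r],
      monotonicity = snaps$monotonicity[r],
      quantity = snaps$quantity[r],
      degeneracy = snaps$degeneracy[r]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"), con)
  }
  invisible(path)
}

#' Read chain snapshots back from a JSONL results file
#'
#' @param path a file written by [run_grid()].
#' @return A snapshot tibble (with a `run` column) as consumed by
#'   [summarize_run()].
#' @export
read_snapshots_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    tibble::tibble(
      run = rec$run, generation = rec$generation, agent = rec$agent,
      parent = if (is.null(rec$parent)) NA_integer_ else rec$parent,
      quantifier = rec$quantifier, upward = rec$upward,
      downward = rec$downward, monotonicity = rec$monotonicity,
      quantity = rec$quantity, degeneracy = rec$degeneracy
    )
  })
  do.call(rbind, rows)
}

#' Batch-score quantifier bit-strings from a file
#'
#' Reads one '0'/'1' truth-table string per line, computes every measure,
#' and writes a CSV with columns `quantifier`, `upward`, `downward`,
#' `monotonicity`, `quantity`, `degeneracy`. All lines must be valid
#' bit-strings of one common power-of-two length; a malformed line is
#' reported with its line number.
#'
#' @param input_path text file of bit-strings (blank lines ignored).
#' @param output_path CSV destination.
#' @return The number of scored rows, invisibly.
#' @export
score_quantifiers <- function(input_path, output_path) {
  lines <- readLines(input_path)
  keep <- nzchar(trimws(lines))
  lines <- trimws(lines[keep])
  line_no <- which(keep)
  rows <- vector("list", length(lines))
  len0 <- NULL
  for (k in seq_along(lines)) {
    l <- lines[k]
    if (!grepl("^[01]+$", l)) {
      stop("line ", line_no[k], ": not a '0'/'1' bit-string", call. = FALSE)
    }
    if (is.null(len0)) len0 <- nchar(l)
    if (nchar(l) != len0) {
      stop("line ", line_no[k], ": length ", nchar(l),
           " differs from first line's ", len0, call. = FALSE)
    }
    q <- tryCatch(as_quantifier(l), error = function(e) {
      stop("line ", line_no[k], ": ", conditionMessage(e), call. = FALSE)
    })
    rows[[k]] <- quantifier_measures(q)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(quantifier = character(0), upward = numeric(0),
                   downward = numeric(0), monotonicity = numeric(0),
                   quantity = numeric(0), degeneracy = numeric(0))
  write.csv(out, output_path, row.names = FALSE)
  invisible(nrow(out))
}
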