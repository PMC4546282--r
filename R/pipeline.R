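# End-to-end orchestration: simulate -> haplogroups -> diversity ->
# structure -> skyline -> demography, with fail-fast validation, derived
# seeds and a checksummed run manifest.

PIPELINE_STAGES <- c("simulate", "haplogroups", "diversity", "structure",
                     "skyline", "demography")

#' Validate a pipeline configuration
#'
#' Fail-fast: every enabled stage's inputs must be resolvable before any
#' stage executes.
#'
#' @param config configuration list (see [run_pipeline()]) or path to a YAML
#'   file.
#' @return the normalised configuration list, invisibly on success.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$stages <- config$stages %||% PIPELINE_STAGES
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  config$seed <- config$seed %||% 1L
  if (is.null(config$out_dir)) stop("config needs out_dir", call. = FALSE)
  if ("simulate" %in% config$stages) {
    if (is.null(config$simulate$scenario)) {
      stop("simulate stage enabled but no scenario given", call. = FALSE)
    }
  } else if (length(setdiff(config$stages, "simulate"))) {
    for (f in c("fasta", "metadata")) {
      path <- config$input[[f]]
      if (is.null(path) || !file.exists(path)) {
        stop("missing input file for '", f, "': ",
             path %||% "<unset>", call. = FALSE)
      }
    }
  }
  for (f in c("motifs", "periods")) {
    if (!is.null(config[[f]]) && is.character(config[[f]]) &&
        !file.exists(config[[f]])) {
      stop("configured ", f, " file does not exist: ", config[[f]],
           call. = FALSE)
    }
  }
  invisible(config)
}

stage_dir <- function(out_dir, stage, overwrite) {
  d <- file.path(out_dir, stage)
  if (dir.exists(d) && length(list.files(d)) && !overwrite) {
    stop("stage directory already has outputs (write-once): ", d,
         call. = FALSE)
  }
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

log_event <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full demographic-history pipeline
#'
#' Executes the enabled stages in dependency order on either a simulated
#' scenario or user-supplied FASTA + metadata, writing per-stage outputs
#' under `out_dir` and a manifest (`manifest.json`) recording package
#' version, seeds and md5 checksums of every written file.
#'
#' @param config list (or YAML path) with elements:
#'   * `seed`: master seed (per-stage/per-population seeds are derived);
#'   * `out_dir`: output directory;
#'   * `stages`: subset of simulate, haplogroups, diversity, structure,
#'     skyline, demography;
#'   * `simulate$scenario`: scenario list for [make_study_fixture()];
#'   * `input$fasta`, `input$metadata`: paths when not simulating;
#'   * `motifs`: motif YAML path (default: [default_motif_table()]);
#'   * `periods`: period YAML path (default table otherwise);
#'   * `clock`: list with `mu`, `generation_years`;
#'   * `structure`: list with `n_perm` (default 200) and `group_by`
#'     (`"region"`, `"language"`, or a named population -> group list);
#'   * `skyline`: list with `m`, `iterations`, `thin`.
#' @param overwrite allow writing into non-empty stage directories.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, overwrite = FALSE) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  clock <- do.call(clock_config, as.list(config$clock %||% list()))
  periods <- if (is.null(config$periods)) period_table() else
    read_period_table(config$periods)
  motifs <- if (is.null(config$motifs)) default_motif_table() else
    read_motif_table(config$motifs)

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      failed <- file.path(out_dir, "failed")
      dir.create(failed, showWarnings = FALSE)
      writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
                 file.path(failed, paste0(stage, ".error")))
      stop(sprintf("pipeline aborted in stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  manifest <- list(package = "mesodemog",
                   version = as.character(utils::packageVersion("mesodemog")),
                   seed = seed, stages = config$stages, outputs = list())
  aln <- NULL
  meta <- NULL

  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      d <- stage_dir(out_dir, "simulate", overwrite)
      log_event("simulate", "generating study fixture")
      fx <- make_study_fixture(config$simulate$scenario,
                               seed = stable_seed(seed, "simulate"),
                               out_dir = d)
      aln <<- fx$alignment
      meta <<- fx$metadata
    })
  } else if (length(setdiff(config$stages, "simulate"))) {
    aln <- read_alignment(config$input$fasta)
    meta <- read_metadata(config$input$metadata)
    ds <- join_dataset(aln, meta)
    aln <- ds$alignment
    meta <- ds$metadata
  }

  needs_data <- length(setdiff(config$stages, "simulate")) > 0
  if (needs_data) {
    pops <- stats::setNames(meta$population, meta$sample)
    ref <- control_region_reference(ncol(aln))
    profiles <- profile_alignment(aln, ref)
  }

  if ("haplogroups" %in% config$stages) {
    run_stage("haplogroups", function() {
      d <- stage_dir(out_dir, "haplogroups", overwrite)
      log_event("haplogroups", "assigning haplogroups")
      calls <- call_haplogroups(profiles, motifs)
      ft <- frequency_table(calls, pops)
      utils::write.table(calls, file.path(d, "calls.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(cbind(haplogroup = rownames(ft$percent),
                               as.data.frame(ft$percent)),
                         file.path(d, "frequencies.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }

  if ("diversity" %in% config$stages) {
    run_stage("diversity", function() {
      d <- stage_dir(out_dir, "diversity", overwrite)
      log_event("diversity", "computing per-population diversity table")
      dt <- diversity_table(aln, pops, ref)
      utils::write.table(dt, file.path(d, "diversity.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }

  if ("structure" %in% config$stages) {
    run_stage("structure", function() {
      d <- stage_dir(out_dir, "structure", overwrite)
      n_perm <- config$structure$n_perm %||% 200
      log_event("structure", "pairwise Phi-st and MDS")
      pm <- phist_matrix(aln, pops, n_perm = n_perm,
                         seed = stable_seed(seed, "structure"))
      utils::write.table(round(pm$phist, 5), file.path(d, "phist.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(round(pm$p_value, 5), file.path(d, "phist_p.tsv"),
                         sep = "\t", quote = FALSE)
      if (nrow(pm$phist) >= 3) {
        mds <- mds_scaling(pm$phist)
        utils::write.table(cbind(population = rownames(mds$points),
                                 as.data.frame(mds$points)),
                           file.path(d, "mds.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      group_by <- config$structure$group_by %||% "region"
      grouping <- if (is.list(group_by)) {
        unlist(group_by)
      } else {
        g <- meta[[group_by]][match(unique(meta$population),
                                    meta$population)]
        stats::setNames(g, unique(meta$population))
      }
      if (length(unique(grouping)) >= 2 &&
          !any(table(grouping) == length(grouping))) {
        av <- amova(difference_matrix(aln), pops[rownames(aln)], grouping,
                    n_perm = n_perm, seed = stable_seed(seed, "amova"))
        utils::write.table(
          data.frame(index = c("F_CT", "F_SC", "F_ST"),
                     value = c(av$F_CT, av$F_SC, av$F_ST),
                     p = c(av$p_CT, av$p_SC, av$p_ST)),
          file.path(d, "amova.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
      }
    })
  }

  trajectories <- list()
  if ("skyline" %in% config$stages) {
    run_stage("skyline", function() {
      d <- stage_dir(out_dir, "skyline", overwrite)
      sk <- config$skyline %||% list()
      for (p in unique(pops)) {
        ids <- names(pops)[pops == p]
        if (length(ids) < 3) {
          warning("population ", p, " has fewer than 3 samples; ",
                  "skyline skipped")
          next
        }
        log_event("skyline", paste("reconstructing", p))
        tr <- estimate_genealogy(aln[ids, , drop = FALSE], clock)
        ints <- coalescent_intervals(tr)
        ch <- mcmc_skyline(ints, m = min(sk$m %||% 5, length(ids) - 1),
                           iterations = sk$iterations %||% 20000,
                           thin = sk$thin %||% 20,
                           seed = stable_seed(seed, paste0("skyline/", p)))
        # evaluate on the generation grid inside the chronology window so the
        # IGR series downstream has per-generation resolution
        root <- max(ch$event_times)
        top <- min(root, max(periods$start_ybp) / clock$generation_years)
        traj <- skyline_trajectory(ch, clock, grid = seq(0, floor(top)))
        trajectories[[p]] <<- traj
        utils::write.table(traj, file.path(d, paste0(p, "_trajectory.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }

  if ("demography" %in% config$stages) {
    run_stage("demography", function() {
      d <- stage_dir(out_dir, "demography", overwrite)
      if (!length(trajectories)) {
        stop("demography stage needs skyline trajectories", call. = FALSE)
      }
      log_event("demography", "IGR series, extrema and inversions")
      series <- lapply(trajectories, function(tr) {
        igr_series(resample_to_generations(tr, clock$generation_years),
                   periods)
      })
      regions <- stats::setNames(
        meta$region[match(names(series), meta$population)], names(series))
      rep <- report_tables(series, regions, periods)
      for (p in names(series)) {
        utils::write.table(series[[p]],
                           file.path(d, paste0(p, "_igr.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      utils::write.table(rep$table, file.path(d, "extrema.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(rep$scatter, file.path(d, "period_scatter.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest$outputs <- stats::setNames(as.list(unname(sums)), files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
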