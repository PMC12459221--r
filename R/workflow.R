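#' Validate a pipeline run configuration
#'
#' A run configuration is a list (or YAML/JSON file) with:
#'
#' * `seed`: integer seed echoed into the run log;
#' * `out_dir`: output directory (created if needed);
#' * `samples`: named blocks, each with `path` (peak table or snapshot
#'   file) and, for peak tables, a `meta` block of [sample_meta()]
#'   fields;
#' * `stages`: an ordered list of stage blocks, each with an `id`, a
#'   `type` (`"pre"`, `"delta_i"`, `"phi"`, `"delta_phi"`,
#'   `"significance"`, `"csp"`, `"distances"`), and references to sample
#'   names or upstream stage ids.
#'
#' All referenced paths are checked before any stage runs, and every
#' stage parameter is resolved to its effective value (no silent
#' defaults) so the run log records the full provenance.
#'
#' @param config A list or the path of a YAML/JSON config file.
#' @return The validated config (class `run_config`), with defaults
#'   resolved.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_config(sprintf("Config file not found: %s", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$out_dir)) abort_config("Config must set `out_dir`.")
  if (!is.list(config$samples) || is.null(names(config$samples))) {
    abort_config("Config must contain named `samples` blocks.")
  }
  for (nm in names(config$samples)) {
    s <- config$samples[[nm]]
    if (is.null(s$path) || !file.exists(s$path)) {
      abort_validation(sprintf("Sample '%s': path missing or not found (%s).",
                               nm, s$path %||% "<unset>"))
    }
  }
  if (!is.list(config$stages) || length(config$stages) == 0L) {
    abort_config("Config must contain a non-empty `stages` list.")
  }
  defaults <- list(
    pre = list(bleach_snr_threshold = 3),
    delta_i = list(),
    phi = list(bleach_snr_threshold = 3, convention = "minus_minus_plus"),
    delta_phi = list(),
    significance = list(ddphi_threshold = 0.4, sigma_fraction = 0.2),
    csp = list(c_scale = 0.133),
    distances = list(low = 5, high = 15, far_floor = 25,
                     loop_residue = 220L, site_residue = 197L)
  )
  config$stages <- lapply(config$stages, function(st) {
    if (is.null(st$id) || is.null(st$type)) {
      abort_config("Every stage needs an `id` and a `type`.")
    }
    if (!st$type %in% names(defaults)) {
      abort_config(sprintf("Stage '%s': unknown type '%s'.", st$id, st$type))
    }
    st <- utils::modifyList(defaults[[st$type]], st)
    st
  })
  ids <- vapply(config$stages, `[[`, character(1), "id")
  if (anyDuplicated(ids)) abort_config("Stage ids must be unique.")
  structure(config, class = c("run_config", "list"))
}

load_sample <- function(block) {
  if (grepl("\\.pdb$", block$path, ignore.case = TRUE) ||
      isTRUE(block$snapshots)) {
    read_snapshots(block$path)
  } else {
    meta <- do.call(sample_meta, block$meta %||%
                      abort_config(sprintf("Sample '%s' needs a meta block.", block$path)))
    read_peak_table(block$path, meta)
  }
}

stage_hash <- function(stage, config, input_hashes) {
  digestable <- list(stage = stage, seed = config$seed, inputs = input_hashes)
  # md5 over the canonical JSON encoding of the resolved stage
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(digestable, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order against the sample manifest,
#' writing one TSV per stage plus a JSON run log that echoes every
#' effective parameter, the seed, the package version, and content
#' hashes of all inputs and outputs.  Stages are pure functions over
#' files: rerunning with an unchanged config and inputs skips completed
#' stages (content-hash check) and leaves byte-identical outputs.
#' A failing stage aborts the run with the stage id named.
#'
#' @param config A list, path, or validated [read_run_config()] output.
#' @return Invisibly, a list of class `premap_run`: per-stage results,
#'   output paths, and the run log.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  samples <- lapply(config$samples, load_sample)
  sample_hashes <- vapply(config$samples, function(s) unname(tools::md5sum(s$path)),
                          character(1))
  manifest_path <- file.path(config$out_dir, "premap_manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list()

  results <- list()
  log_stages <- list()
  for (st in config$stages) {
    out_path <- file.path(config$out_dir, paste0(st$id, ".tsv"))
    input_of <- function(ref) {
      if (ref %in% names(samples)) return(samples[[ref]])
      if (ref %in% names(results)) return(results[[ref]])
      abort_config(sprintf("Stage '%s' references unknown input '%s'.", st$id, ref))
    }
    input_hash_of <- function(ref) {
      if (ref %in% names(sample_hashes)) return(unname(sample_hashes[[ref]]))
      unname(manifest[[ref]] %||% "")
    }
    refs <- intersect(
      names(st),
      c("dia", "para", "a", "b", "plus", "minus", "low_ph", "high_ph",
        "wt_low", "wt_high", "mut_low", "mut_high", "snapshots")
    )
    in_hashes <- setNames(lapply(unlist(st[refs]), input_hash_of), unlist(st[refs]))
    h <- stage_hash(st, config, in_hashes)

    cached <- identical(manifest[[st$id]], h) && file.exists(out_path)
    res <- tryCatch({
      result <- switch(
        st$type,
        pre = {
          p <- build_pre_profile(input_of(st$dia), input_of(st$para),
                                 bleach_snr_threshold = st$bleach_snr_threshold)
          if (!is.null(st$groups) || isTRUE(st$annotate_groups %||% TRUE)) {
            groups <- st$groups %||% pre_groups_default()
            groups <- lapply(groups, as.integer)
            p <- annotate_groups(p, groups)
          }
          p
        },
        delta_i = delta_intensity(input_of(st$a), input_of(st$b)),
        phi = build_phi_profile(input_of(st$dia), input_of(st$plus),
                                input_of(st$minus),
                                bleach_snr_threshold = st$bleach_snr_threshold,
                                convention = st$convention),
        delta_phi = delta_phi(input_of(st$low_ph), input_of(st$high_ph)),
        significance = significance_filter(
          input_of(st$wt_low), input_of(st$wt_high),
          input_of(st$mut_low), input_of(st$mut_high),
          ddphi_threshold = st$ddphi_threshold,
          sigma_fraction = st$sigma_fraction
        ),
        csp = csp_profile(input_of(st$a), input_of(st$b), c_scale = st$c_scale),
        distances = {
          census <- distance_series(
            input_of(st$snapshots),
            loop_sel = atom_selector(st$loop_residue,
                                     st$loop_atoms %||% loop_selector_default()$atom_names),
            site_sel = atom_selector(st$site_residue,
                                     st$site_atoms %||% site_selector_default()$atom_names)
          )
          census
        }
      )
      result
    }, premap_error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", st$id, conditionMessage(e)),
            class = c("premap_stage_error", "premap_error"), parent = e)
    })

    if (!cached) {
      readr::write_tsv(as_tibble(res), out_path, progress = FALSE)
      manifest[[st$id]] <- h
    }
    results[[st$id]] <- res
    log_stages[[st$id]] <- list(
      type = st$type,
      parameters = st[setdiff(names(st), c("id", "type"))],
      skipped = cached,
      output = out_path,
      output_md5 = unname(tools::md5sum(out_path)),
      stage_hash = h
    )
  }

  run_log <- list(
    package = "premap",
    version = as.character(utils::packageVersion("premap")),
    seed = config$seed,
    samples = lapply(names(config$samples), function(nm) {
      list(name = nm, path = config$samples[[nm]]$path,
           md5 = unname(sample_hashes[[nm]]))
    }),
    stages = log_stages
  )
  jsonlite::write_json(run_log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  message(sprintf("Pipeline complete: %d stage(s) -> %s",
                  length(config$stages), config$out_dir))
  invisible(structure(
    list(results = results, run_log = run_log, out_dir = config$out_dir),
    class = "premap_run"
  ))
}
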