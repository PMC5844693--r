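# File formats and the end-to-end pipeline.
#
# Patches and estimate cubes are stored as a flat little-endian float64
# binary alongside a JSON header describing shapes and metadata (an R tiff
# writer is not available in the supported dependency set, so a documented
# raw-float container is used instead; round-trips are bit-exact).
# Manifests and trial tables are plain CSV (comma, UTF-8, header row, '.'
# decimal) with a declared column schema.

manifest_required_cols <- c("stimulus_id", "tilt", "slant", "distance", "contrast")

patch_plane_names <- c("left", "right", "range_map", "occlusion_mask")

#' Write / read a stereo patch
#'
#' `write_patch()` stores the four image planes (left, right, range,
#' occlusion) as one float64 binary at `<stem>.bin` plus a JSON sidecar
#' `<stem>.json` holding dimensions, the scene spec and the viewing
#' geometry.  `read_patch()` reconstructs the patch bit-exactly.
#'
#' @param patch a `stereo_patch`.
#' @param stem file path without extension.
#' @return `write_patch()` returns `stem` invisibly; `read_patch()` returns
#'   the `stereo_patch`.
#' @export
write_patch <- function(patch, stem) {
  stopifnot(inherits(patch, "stereo_patch"))
  d <- dim(patch$left)
  header <- list(format = "tiltnorm-patch-v1", dim = d,
                 planes = patch_plane_names,
                 spec = unclass(patch$spec), geom = unclass(patch$geom))
  jsonlite::write_json(header, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(c(patch$left, patch$right, patch$range_map,
                        patch$occlusion_mask)),
           con, size = 8, endian = "little")
  invisible(stem)
}

#' @rdname write_patch
#' @export
read_patch <- function(stem) {
  hd <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(hd$format, "tiltnorm-patch-v1")) err("not a tiltnorm patch file")
  d <- as.integer(hd$dim)
  n <- prod(d)
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, numeric(), n = 4 * n, size = 8, endian = "little")
  if (length(raw) != 4 * n) err("patch binary truncated")
  planes <- lapply(0:3, function(i) matrix(raw[(i * n + 1):((i + 1) * n)], d[1], d[2]))
  spec <- do.call(scene_spec, hd$spec[c("tilt", "slant", "distance",
                                        "texture_kind", "contrast",
                                        "bump_amplitude", "bump_corr_length",
                                        "seed")])
  geom <- do.call(viewing_geometry, hd$geom)
  structure(list(left = planes[[1]], right = planes[[2]],
                 range_map = planes[[3]],
                 occlusion_mask = planes[[4]] != 0,
                 spec = spec, geom = geom),
            class = "stereo_patch")
}

#' Write / read a stimulus manifest
#'
#' CSV table with one row per stimulus.  Required columns: `stimulus_id`,
#' `tilt`, `slant`, `distance`, `contrast`; pipelines append groundtruth
#' and cue columns (`tilt_var`, `lum_cue`, `disp_cue`, `tex_cue`, flags).
#' Validation rejects missing columns and non-finite contrast values,
#' naming offending columns / rows.
#'
#' @param manifest data frame.
#' @param path CSV path.
#' @param required minimal column set enforced on read and write.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   the validated data frame.
#' @export
write_manifest <- function(manifest, path, required = manifest_required_cols) {
  validate_manifest(manifest, required)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path, required = manifest_required_cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df, required)
  df
}

validate_manifest <- function(df, required) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    err(paste("manifest missing columns:", paste(missing, collapse = ", ")),
        class = "tiltnorm_schema_error")
  }
  if ("contrast" %in% names(df)) {
    bad <- which(!is.finite(df$contrast))
    if (length(bad)) {
      err(sprintf("manifest has non-finite contrast at row(s): %s",
                  paste(utils::head(bad, 10), collapse = ", ")),
          class = "tiltnorm_schema_error")
    }
  }
  invisible(df)
}

#' Write / read an estimate cube
#'
#' Flat float64 binary (`<stem>.bin`: estimates, counts, doubled-angle
#' cosine and sine accumulators) plus a JSON header (`<stem>.json`) with
#' bins, prior mean and training metadata.  Round-trips bit-exactly.
#'
#' @param cube an `estimate_cube`.
#' @param stem file path without extension.
#' @return `write_cube()` returns `stem` invisibly; `read_cube()` the cube.
#' @export
write_cube <- function(cube, stem) {
  stopifnot(inherits(cube, "estimate_cube"))
  header <- list(format = "tiltnorm-cube-v1", bins_per_cue = cube$bins_per_cue,
                 min_count = cube$min_count, prior_mean = cube$prior_mean,
                 n_train = cube$n_train)
  jsonlite::write_json(header, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(c(cube$cell_estimate, cube$cell_count,
                        cube$cell_cos2, cube$cell_sin2)),
           con, size = 8, endian = "little")
  invisible(stem)
}

#' @rdname write_cube
#' @export
read_cube <- function(stem) {
  hd <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(hd$format, "tiltnorm-cube-v1")) err("not a tiltnorm cube file")
  n <- as.integer(hd$bins_per_cue)^3
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, numeric(), n = 4 * n, size = 8, endian = "little")
  if (length(raw) != 4 * n) err("cube binary truncated")
  structure(list(bins_per_cue = as.integer(hd$bins_per_cue),
                 min_count = as.integer(hd$min_count),
                 cell_estimate = raw[1:n],
                 cell_count = as.integer(raw[(n + 1):(2 * n)]),
                 cell_cos2 = raw[(2 * n + 1):(3 * n)],
                 cell_sin2 = raw[(3 * n + 1):(4 * n)],
                 prior_mean = hd$prior_mean, n_train = hd$n_train),
            class = "estimate_cube")
}

#' Pipeline run configuration
#'
#' Bundles every stage's configuration plus the global seed and output
#' directory.  Serializes losslessly to JSON via [write_run_config()].
#'
#' @param seed global integer seed; all stage randomness derives from it.
#' @param out output directory.
#' @param geometry a [viewing_geometry()].
#' @param constraints a [sampling_constraints()].
#' @param truth a [truth_config()].
#' @param cue a [cue_config()].
#' @param cube list with `bins_per_cue`, `min_count`, `n_train`, and the
#'   cue-simulator settings used to train the estimate cube.
#' @param observer a [synthetic_observer_spec()].
#' @param evaluation list with `n_bins`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1, out = tempfile("tiltnorm_run_"),
                       geometry = viewing_geometry(),
                       constraints = sampling_constraints(n_per_bin = 5L),
                       truth = truth_config(),
                       cue = cue_config(),
                       cube = list(bins_per_cue = 32L, min_count = 10L,
                                   n_train = 200000L,
                                   kappa_set = c(1, 4, 16)),
                       observer = synthetic_observer_spec(),
                       evaluation = list(n_bins = 24L)) {
  cfg <- list(seed = as.integer(seed), out = out, geometry = geometry,
              constraints = constraints, truth = truth, cue = cue,
              cube = cube, observer = observer, evaluation = evaluation)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  need <- c("seed", "out", "geometry", "constraints", "truth", "cue",
            "cube", "observer", "evaluation")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    err(paste("run config missing field(s):", paste(missing, collapse = ", ")),
        class = "tiltnorm_config_error")
  }
  for (f in c("bins_per_cue", "min_count", "n_train")) {
    if (is.null(cfg$cube[[f]])) {
      err(paste("run config missing field: cube$", f, sep = ""),
          class = "tiltnorm_config_error")
    }
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  strip <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) return(Filter(Negate(is.null), lapply(unclass(x), strip)))
    x
  }
  jsonlite::write_json(strip(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config(
    seed = raw$seed, out = raw$out,
    geometry = do.call(viewing_geometry, raw$geometry),
    constraints = do.call(sampling_constraints, raw$constraints),
    truth = do.call(truth_config, raw$truth),
    cue = do.call(cue_config, raw$cue),
    cube = raw$cube,
    observer = do.call(synthetic_observer_spec,
                       raw$observer[setdiff(names(raw$observer), "bias_fn")]),
    evaluation = raw$evaluation)
  cfg
}

#' Run the full pipeline
#'
#' Executes every stage in order: constrained stimulus sampling and
#' rendering, groundtruth and cue measurement (written to the manifest
#' CSV), estimate-cube training on simulated cue samples, tilt estimation
#' for the sampled stimuli (trials CSV), synthetic-observer responses, and
#' the evaluation report (JSON).  Idempotent: identical config and seed
#' give byte-identical outputs.  A stage failure aborts with the stage
#' named; outputs of completed stages are preserved.
#'
#' @param cfg a [run_config()].
#' @param write_patches also write every rendered patch to disk (off by
#'   default; patch files are large relative to the manifest).
#' @return list with the manifest, trials, evaluation report, cube, and
#'   output paths, invisibly.
#' @export
run_pipeline <- function(cfg, write_patches = FALSE) {
  validate_run_config(cfg)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "tiltnorm_pipeline_error")
    })
  }

  patches <- stage("synth", sample_stimuli(
    cfg$constraints, cfg$geometry, seed = sub_seed(cfg$seed, "synth"),
    cue_cfg = cfg$cue))

  manifest <- stage("truth+cues", {
    rows <- lapply(seq_along(patches), function(i) {
      p <- patches[[i]]
      tr <- patch_truth(p, cfg$truth)
      cu <- compute_cue_triplet(p, cfg$cue)
      if (write_patches) {
        write_patch(p, file.path(cfg$out, sprintf("patch_%04d", i)))
      }
      data.frame(stimulus_id = i, tilt = tr$tilt, signed_tilt = tr$signed_tilt,
                 slant = tr$slant, distance = p$spec$distance,
                 contrast = cu$contrast, tilt_var = tr$tilt_variance,
                 lum_cue = cu$lum, disp_cue = cu$disp, tex_cue = cu$tex,
                 lum_ok = cu$reliable[["lum"]], disp_ok = cu$reliable[["disp"]],
                 tex_ok = cu$reliable[["tex"]])
    })
    m <- do.call(rbind, rows)
    write_manifest(m, file.path(cfg$out, "manifest.csv"))
    m
  })

  cube <- stage("train", {
    train <- sample_cue_database(cfg$cube$n_train,
                                 kappa_set = cfg$cube$kappa_set %||% c(1, 4, 16),
                                 seed = sub_seed(cfg$seed, "train"))
    cb <- build_cube(train, cfg$cube$bins_per_cue, cfg$cube$min_count)
    write_cube(cb, file.path(cfg$out, "cube"))
    cb
  })

  trials <- stage("estimate", {
    cues <- data.frame(lum = manifest$lum_cue, disp = manifest$disp_cue,
                       tex = manifest$tex_cue)
    est <- estimate_tilt(cube, cues)
    resp <- synthetic_observer(est$estimate, cfg$observer,
                               seed = sub_seed(cfg$seed, "observer"))
    tr <- make_trials(truth = manifest$tilt, estimate = est$estimate,
                      stimulus_id = manifest$stimulus_id,
                      slant = manifest$slant, distance = manifest$distance,
                      contrast = manifest$contrast,
                      tilt_var = manifest$tilt_var, observer = "model")
    tr$response <- resp
    tr$fallback <- est$fallback
    utils::write.csv(tr, file.path(cfg$out, "trials.csv"), row.names = FALSE)
    tr
  })

  report <- stage("evaluate", {
    nb <- cfg$evaluation$n_bins %||% 24L
    summ <- summarize_by_tilt(trials, n_bins = nb)
    eff <- lapply(c("slant", "distance"), function(cv) {
      tryCatch(covariate_effect(trials, cv, "quantile",
                                min(5L, max(2L, nrow(trials) %/% 4L)))[c("slope", "bins")],
               error = function(e) NULL)
    })
    names(eff) <- c("slant", "distance")
    rep <- list(n_trials = nrow(trials), summary = summ,
                mean_abs_error = mean(abs(trials$error)),
                covariate_slopes = lapply(eff, function(x) x$slope %||% NA))
    jsonlite::write_json(rep, file.path(cfg$out, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    rep
  })

  invisible(list(manifest = manifest, cube = cube, trials = trials,
                 report = report, out = cfg$out))
}
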