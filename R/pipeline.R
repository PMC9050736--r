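# Configuration, I/O and the end-to-end pipeline -------------------------

#' Build a run configuration
#'
#' Flat configuration with one keyed section per stage, carrying the
#' pipeline defaults: 1 um/px resampling, 10000-px hole/debris threshold,
#' radius-5 opening, smoothing value 10000, 1 um profile step, 10/40 um
#' extrema prominence/separation, 2/0.391/0.391 um voxels and a 50-frame
#' detrending window. Physical quantities are micrometres and minutes;
#' pixel-denominated parameters are suffixed `_px`. Round-trips losslessly
#' through YAML via [write_config()] / [read_config()].
#'
#' @param input list describing the input (e.g. `list(type =
#'   "synthetic_somitoid", n_somites = 8)` or `list(type = "mask",
#'   path = "mask.tif", anchors = "anchors.csv")`).
#' @param out_dir output directory.
#' @param seed integer seed for all randomness in the run.
#' @param ... overrides of individual stage parameters.
#' @return object of class `somitometry_config` (a named list).
#' @export
somitometry_config <- function(input = list(type = "synthetic_somitoid"),
                               out_dir = tempfile("somitometry_run_"),
                               seed = 0, ...) {
  cfg <- list(
    input = input,
    out_dir = out_dir,
    seed = seed,
    segment = list(method = "auto", target_px = 1,
                   min_size_px = 10000, opening_radius_px = 5),
    morph = list(smoothing = 10000, step_um = 1,
                 min_prominence_um = 10, min_separation_um = 40),
    volumes = list(voxel_um = c(2, 0.391, 0.391),
                   channels = c("SOX2", "BRACHYURY", "UNCX4.1")),
    oscillation = list(detrend_window_frames = 50, frame_interval_min = 10,
                       half_width_um = 20, median_radius_px = 3),
    log_level = "info")
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "somitometry_config")
}

#' @rdname somitometry_config
#' @param config a `somitometry_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname somitometry_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "somitometry_config")
}

#' Read a TIFF image with physical metadata
#'
#' Reads single- or multi-page TIFF into an [image_grid]. Pixel sizes are
#' taken from the `pixel_size` override (micrometres); plain TIFF carries no
#' trustworthy physical metadata, so the override is required. Multi-page
#' files become movies when `frame_interval` is supplied, 3-D stacks
#' otherwise.
#'
#' @param path TIFF file.
#' @param pixel_size per-axis sizes in micrometres (`c(y, x)` or
#'   `c(z, y, x)`).
#' @param frame_interval minutes between pages, for movies.
#' @param channel_names optional channel labels.
#' @return an [image_grid].
#' @export
read_image_tiff <- function(path, pixel_size, frame_interval = NULL,
                            channel_names = NULL) {
  if (!file.exists(path)) stop("cannot read ", path)
  if (missing(pixel_size) || is.null(pixel_size)) {
    stop("pixel_size must be supplied (plain TIFF carries no physical metadata)")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    pmax(p, 0)  # guard against float round-off below zero
  })
  if (length(pages) == 1L) {
    return(image_grid(pages[[1L]], pixel_size, channel_names = channel_names))
  }
  arr <- array(0, c(length(pages), dim(pages[[1L]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  if (!is.null(frame_interval)) {
    image_grid(arr, pixel_size, frame_interval = frame_interval, kind = "movie")
  } else {
    image_grid(arr, pixel_size, channel_names = channel_names, kind = "stack3d")
  }
}

#' Write a binary mask as 8-bit TIFF with a provenance sidecar
#'
#' @param mask a [labeled_mask] (2-D).
#' @param path output TIFF path; the JSON sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "labeled_mask"))
  tiff::writeTIFF(mask$mask * 1, path, bits.per.sample = 8L)
  side <- sub("\\.tiff?$", "", path)
  jsonlite::write_json(
    list(pixel_size_um = unname(mask$pixel_size),
         provenance = mask$provenance),
    paste0(side, ".provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read anchor / segment annotations
#'
#' CSV with columns `role,x_um,y_um`; roles `posterior`, `anterior`,
#' `lr_start`, `lr_end`.
#'
#' @param path CSV file.
#' @return named list of `(x, y)` numeric vectors keyed by role.
#' @export
read_anchors_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("role", "x_um", "y_um") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i) c(df$x_um[i], df$y_um[i]))
  stats::setNames(out, df$role)
}

#' Write stage results and a checksummed manifest
#'
#' Serializes morphometry results (per-somite calls, width profile, midline)
#' as CSV, a JSON summary, and a manifest listing every artifact with its
#' MD5 checksum plus the parameters and seed of the run. Identical runs
#' produce byte-identical artifacts and hence identical manifests.
#'
#' @param results named list; recognized elements: `somites` (data.frame),
#'   `profile` (`width_profile`), `midline` (`midline_curve`), `volumes`
#'   (`lineage_volume_report`), `summary` (list), `config`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("unwritable output directory: ", out_dir)
  files <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  if (!is.null(results$somites)) put_csv(results$somites, "somites.csv")
  if (!is.null(results$profile)) {
    put_csv(data.frame(s_um = results$profile$s, w_um = results$profile$w),
            "width_profile.csv")
  }
  if (!is.null(results$midline)) {
    put_csv(data.frame(s_um = results$midline$arc_length,
                       x_um = results$midline$points[, 1L],
                       y_um = results$midline$points[, 2L]),
            "midline.csv")
  }
  if (!is.null(results$volumes)) {
    v <- results$volumes
    p <- file.path(out_dir, "volumes.json")
    jsonlite::write_json(list(total_um3 = v$total_volume,
                              domains_um3 = as.list(v$domain_volumes),
                              fractions = as.list(v$domain_fractions),
                              voxel_um = unname(v$voxel_size)),
                         p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
  }
  if (!is.null(results$summary)) {
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(results$summary, p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
  }
  manifest <- list(
    version = as.character(utils::packageVersion("somitometry")),
    seed = results$config$seed %||% NA,
    parameters = if (!is.null(results$config)) unclass(results$config) else NULL,
    artifacts = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the somitoid pipeline end to end
#'
#' Chains segmentation (resample, binarize, clean) and midline morphometry
#' (ridge points, ordering, spline, width profile, somite calls) for a
#' configured input, writes the artifacts and returns the manifest. Stage
#' failures abort with the stage name. With a synthetic input the generator
#' is seeded from the config so reruns are byte-identical.
#'
#' @param config a [somitometry_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "somitometry_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  inp <- config$input
  anchors <- NULL
  truth <- NULL
  img <- stage("input", {
    if (identical(inp$type, "synthetic_somitoid")) {
      spec_args <- inp[setdiff(names(inp), "type")]
      spec_args$seed <- spec_args$seed %||% config$seed
      gen <- generate_somitoid(do.call(somitoid_spec, spec_args))
      truth <- gen$truth
      anchors <- list(posterior = gen$truth$anchors$posterior,
                      anterior = gen$truth$anchors$anterior)
      gen$image
    } else if (identical(inp$type, "image") || identical(inp$type, "mask")) {
      if (is.null(inp$anchors)) stop("anchors CSV is required for morphometry")
      anchors <- read_anchors_csv(inp$anchors)
      read_image_tiff(inp$path, pixel_size = inp$pixel_size %||% c(1, 1))
    } else {
      stop("unknown input type: ", inp$type %||% "<missing>")
    }
  })
  seg <- config$segment
  mask <- stage("segment", {
    im1 <- resample_isotropic(img, seg$target_px)
    method <- seg$method
    if (identical(method, "auto")) method <- as.character(select_threshold_method(im1))
    clean_mask(binarize(im1, method),
               min_size = seg$min_size_px, opening_radius = seg$opening_radius_px)
  })
  mo <- config$morph
  res <- stage("morph", {
    pts <- midline_ridge_points(mask)
    ord <- order_midline_points(pts, anchors$posterior, anchors$anterior)
    mid <- fit_midline_spline(ord$points, smoothing = mo$smoothing)
    prof <- compute_width_profile(mask, mid, step = mo$step_um)
    ex <- find_profile_extrema(prof, mo$min_prominence_um, mo$min_separation_um)
    calls <- call_somites(prof, ex)
    list(midline = mid, profile = prof, calls = calls)
  })
  summary <- list(n_somites = count_somite_rows(res$calls),
                  midline_length_um = res$midline$total_length,
                  threshold = mask$provenance$threshold %||% NA)
  manifest <- write_results(list(somites = res$calls, profile = res$profile,
                                 midline = res$midline, summary = summary,
                                 config = config),
                            config$out_dir)
  invisible(manifest)
}
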