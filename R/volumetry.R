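# 3-D HCR volumetry ------------------------------------------------------

.stack_channels <- function(stack) {
  d <- dim(stack$data)
  if (length(d) == 3L) {
    ch <- stack$channel_names %||% "channel1"
    return(stats::setNames(list(stack$data), ch))
  }
  ch <- stack$channel_names %||% paste0("channel", seq_len(d[4L]))
  stats::setNames(lapply(seq_len(d[4L]), function(k) stack$data[, , , k]), ch)
}

#' Per-channel 3-D masks by global Otsu thresholding
#'
#' One global Otsu threshold per channel over the whole 3-D stack (not per
#' slice). A constant channel yields an empty mask flagged degenerate.
#' Manual mask overrides (e.g. hand-corrected segmentations) are accepted
#' per channel and used verbatim, recorded in provenance.
#'
#' @param stack an [image_grid] of kind `"stack3d"` with named channels.
#' @param overrides optional named list of logical arrays (or
#'   [labeled_mask]s) replacing the computed mask for those channels.
#' @return named list of [labeled_mask]s, one per channel.
#' @export
channel_masks_3d <- function(stack, overrides = NULL) {
  stopifnot(inherits(stack, "image_grid"))
  if (stack$kind != "stack3d") stop("channel_masks_3d expects a 3-D stack")
  chans <- .stack_channels(stack)
  out <- lapply(names(chans), function(nm) {
    if (!is.null(overrides) && nm %in% names(overrides)) {
      ov <- overrides[[nm]]
      m <- if (inherits(ov, "labeled_mask")) ov$mask else ov
      if (!identical(dim(m), dim(chans[[nm]]))) {
        stop("override for channel ", nm, " has mismatched geometry")
      }
      return(labeled_mask(m, stack$pixel_size,
                          provenance = list(method = "override", channel = nm)))
    }
    thr <- threshold_value(chans[[nm]], "otsu")
    if (is.na(thr)) {
      return(labeled_mask(array(FALSE, dim(chans[[nm]])), stack$pixel_size,
                          provenance = list(method = "otsu", channel = nm,
                                            threshold = NA_real_,
                                            degenerate = TRUE)))
    }
    labeled_mask(chans[[nm]] > thr, stack$pixel_size,
                 provenance = list(method = "otsu", channel = nm,
                                   threshold = thr, degenerate = FALSE))
  })
  stats::setNames(out, names(chans))
}

#' Total somitoid reference mask from the channel sum
#'
#' The lineage markers jointly tile the somitoid, so the voxelwise sum of
#' all fluorescence channels (an artificial sum channel, accumulated in
#' double precision so it cannot saturate) binarized with Otsu delineates
#' the whole structure.
#'
#' @param stack an [image_grid] stack with at least 2 channels.
#' @return a [labeled_mask] of the whole somitoid.
#' @export
total_reference_mask <- function(stack) {
  stopifnot(inherits(stack, "image_grid"))
  if (stack$kind != "stack3d") stop("total_reference_mask expects a 3-D stack")
  chans <- .stack_channels(stack)
  if (length(chans) < 2L) {
    stop("total_reference_mask needs >= 2 channels; ",
         "use channel_masks_3d for a single-channel stack")
  }
  total <- Reduce(`+`, lapply(chans, as.numeric))
  total <- array(total, dim(chans[[1L]]))
  thr <- threshold_value(total, "otsu")
  if (is.na(thr)) {
    warning("constant sum channel: returning empty mask (degenerate)")
    return(labeled_mask(array(FALSE, dim(total)), stack$pixel_size,
                        provenance = list(method = "otsu_sum",
                                          threshold = NA_real_,
                                          degenerate = TRUE)))
  }
  labeled_mask(total > thr, stack$pixel_size,
               provenance = list(method = "otsu_sum", threshold = thr,
                                 degenerate = FALSE))
}

#' Volume of a 3-D mask
#'
#' Count of positive voxels converted to micrometres cubed with the per-axis
#' voxel sizes (anisotropic voxels supported, e.g. Z = 2 um, XY = 0.391 um).
#'
#' @param mask a 3-D [labeled_mask] with per-axis voxel sizes.
#' @return volume in um^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (length(dim(mask$mask)) != 3L) stop("mask_volume expects a 3-D mask")
  if (length(mask$pixel_size) != 3L || any(is.na(mask$pixel_size))) {
    stop("missing per-axis voxel sizes")
  }
  sum(mask$mask) * prod(mask$pixel_size)
}

#' Lineage-domain volumes from marker masks
#'
#' Boolean voxel combinations of the SOX2, BRACHYURY and UNCX4.1 masks,
#' restricted to the total somitoid mask: Neural = SOX2+ & BRACHYURY-;
#' PSM = BRACHYURY+ & SOX2-; NMP = BRACHYURY+ & SOX2+; Somite = UNCX4.1+
#' (not made exclusive of the other markers, so domain fractions may sum
#' above 1). By construction Neural + NMP equals the SOX2-positive volume
#' and PSM + NMP the BRACHYURY-positive volume, exactly, in voxel counts.
#'
#' @param masks named list of [labeled_mask]s from [channel_masks_3d()].
#' @param total the [labeled_mask] from [total_reference_mask()].
#' @param channels named character vector mapping roles `sox2`, `brachyury`,
#'   `uncx` to channel names in `masks` (matched case-insensitively).
#' @return object of class `lineage_volume_report`: per-channel volumes,
#'   total volume, domain volumes and fractions of total, voxel size.
#' @export
lineage_domain_volumes <- function(masks, total,
                                   channels = c(sox2 = "SOX2",
                                                brachyury = "BRACHYURY",
                                                uncx = "UNCX4.1")) {
  stopifnot(inherits(total, "labeled_mask"))
  find_channel <- function(role) {
    nm <- channels[[role]]
    hit <- which(tolower(names(masks)) == tolower(nm))
    if (!length(hit)) stop("missing channel '", nm, "' (role ", role, ")")
    masks[[hit[1L]]]
  }
  sox <- find_channel("sox2")
  bra <- find_channel("brachyury")
  unc <- find_channel("uncx")
  for (m in list(sox, bra, unc)) {
    if (!identical(dim(m$mask), dim(total$mask))) {
      stop("mask geometry mismatch against the total mask")
    }
  }
  vs <- total$pixel_size
  vol <- function(arr) sum(arr) * prod(vs)
  S <- sox$mask & total$mask
  B <- bra$mask & total$mask
  U <- unc$mask & total$mask
  domains <- list(neural = S & !B, somite = U, psm = B & !S, nmp = S & B)
  total_vol <- vol(total$mask)
  dom_vol <- vapply(domains, vol, numeric(1L))
  structure(list(
    channel_volumes = c(SOX2 = vol(S), BRACHYURY = vol(B), UNCX = vol(U)),
    total_volume = total_vol,
    domain_volumes = dom_vol,
    domain_fractions = if (total_vol > 0) dom_vol / total_vol else dom_vol * NA,
    voxel_size = vs),
    class = "lineage_volume_report")
}

#' @export
print.lineage_volume_report <- function(x, ...) {
  cat("<lineage_volume_report> total:", format(round(x$total_volume), big.mark = ","),
      "um^3\n")
  for (nm in names(x$domain_volumes)) {
    cat(sprintf("  %-7s %12.0f um^3  (%.1f%%)\n", nm, x$domain_volumes[[nm]],
                100 * x$domain_fractions[[nm]]))
  }
  invisible(x)
}
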