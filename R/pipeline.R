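#' Run the full courtship-recognition pipeline
#'
#' Frame reading, arena detection (once, on the first frame), per-arena
#' cropping, background subtraction, identity tracking through overlaps,
#' wing/torso characterization, identity verification, behavior
#' recognition, temporal denoising, and courtship analytics.
#'
#' @param source Directory of numbered image frames, or an in-memory list of
#'   `flycourt_frame` objects (e.g. from [render_sequence()]).
#' @param config A [flycourt_config()].
#' @param out_dir Optional output directory; when given, per-arena CSVs
#'   (poses, track, behavior, proportions, transitions), a summary JSON and
#'   a run manifest are written.
#' @return List with one element per arena: `arena` (detection row),
#'   `track`, `poses`, `behavior`, `ethogram`, `proportions`,
#'   `transitions`, `summary`, `gaps`.
#' @export
run_pipeline <- function(source, config = flycourt_config(), out_dir = NULL) {
  if (!inherits(config, "flycourt_config")) stop("config must be a flycourt_config", call. = FALSE)
  frames <- if (is.character(source)) read_frames(source, fps = config$fps) else source
  if (length(frames) == 0) stop("no frames to process", call. = FALSE)

  if (isTRUE(config$arena$precropped)) {
    mmpp <- frames[[1]]$mm_per_px
    if (is.null(mmpp)) mmpp <- config$arena$mm_per_px
    arenas <- tibble::tibble(arena_id = 0L, row = NA_real_, col = NA_real_,
                             radius = NA_real_, mm_per_px = mmpp)
    crop_sets <- list(frames)
  } else {
    arenas <- detect_arenas(frames[[1]], expected_count = config$arena$count,
                            radius_range = config$arena$radius_range,
                            arena_diameter_mm = config$arena$diameter_mm)
    crop_sets <- lapply(seq_len(nrow(arenas)), function(i) {
      lapply(frames, crop_arena, region = arenas[i, ])
    })
  }

  results <- lapply(seq_along(crop_sets), function(i) {
    tr <- track_arena(crop_sets[[i]], config)
    beh <- classify_behaviors(tr, config)
    eth <- ethogram(beh$label, fps = tr$fps, window = config$window,
                    window_seconds = config$window_seconds)
    prop <- element_proportions(eth)
    tm <- transition_matrix(eth)
    summ <- courtship_pattern_summary(prop, tm)
    list(arena = arenas[i, ], track = tr$track, poses = tr$poses,
         behavior = beh, ethogram = eth, proportions = prop,
         transitions = tm, summary = summ, gaps = tr$gaps)
  })

  if (!is.null(out_dir)) write_pipeline_outputs(results, config, out_dir)
  results
}

write_pipeline_outputs <- function(results, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (res in results) {
    aid <- res$arena$arena_id
    pre <- file.path(out_dir, sprintf("arena%d", aid))
    utils::write.csv(res$poses, paste0(pre, "_poses.csv"), row.names = FALSE)
    utils::write.csv(res$track, paste0(pre, "_track.csv"), row.names = FALSE)
    utils::write.csv(res$behavior, paste0(pre, "_behavior.csv"), row.names = FALSE)
    utils::write.csv(res$proportions, paste0(pre, "_proportions.csv"), row.names = FALSE)
    utils::write.csv(tidy(res$transitions), paste0(pre, "_transitions.csv"), row.names = FALSE)
    write_summary_json(res$summary, paste0(pre, "_summary.json"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("flycourt")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_arenas = length(results),
    timebase_fps = config$fps
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Annotate arena crops with tracking and behavior overlays
#'
#' Paints identity markers (male red, female blue), a heading line from the
#' torso centroid to the head, head/tail dots, and a top-left banner
#' color-coded by the frame's certified behavior; writes one PNG per frame.
#'
#' @param crops List of single-arena `flycourt_frame` objects.
#' @param poses Pose tibble from [track_arena()].
#' @param behavior Behavior tibble from [classify_behaviors()]; may have
#'   zero rows, in which case tracks alone are overlaid.
#' @param out_dir Output directory for the annotated PNGs.
#' @return Invisibly, the vector of written paths.
#' @export
annotate_frames <- function(crops, poses, behavior, out_dir) {
  if (nrow(behavior) > 0 &&
      !all(behavior$frame %in% vapply(crops, function(f) f$index, numeric(1)))) {
    stop("behavior frames do not match the crop sequence", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  label_colors <- list(
    none = c(0.6, 0.6, 0.6), orientation = c(1, 0.8, 0.2), singing = c(0.2, 0.8, 0.2),
    tapping = c(0.9, 0.4, 0.1), attempted_copulation = c(0.8, 0.2, 0.8),
    copulation = c(0.8, 0.1, 0.1)
  )
  paths <- character(length(crops))
  for (i in seq_along(crops)) {
    fr <- crops[[i]]
    img <- fr$pixels / 255
    nr <- dim(img)[1]; nc <- dim(img)[2]
    paint <- function(mask, col) {
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- col[ch]
        img[, , ch] <<- plane
      }
    }
    pr <- poses[poses$frame == fr$index, ]
    for (j in seq_len(nrow(pr))) {
      p <- pr[j, ]
      col <- if (p$fly_id == "male") c(1, 0.1, 0.1) else c(0.1, 0.3, 1)
      paint(fill_disc(nr, nc, c(p$row, p$col), 2.2), col)
      paint(draw_segment(nr, nc, c(p$row, p$col), c(p$head_row, p$head_col)), col)
      paint(fill_disc(nr, nc, c(p$head_row, p$head_col), 1.4), c(1, 1, 1))
    }
    if (nrow(behavior) > 0) {
      lab <- behavior$label[behavior$frame == fr$index]
      if (length(lab) == 1 && lab %in% names(label_colors)) {
        banner <- blank_mask(nr, nc); banner[1:8, 1:24] <- TRUE
        paint(banner, label_colors[[lab]])
      }
    }
    paths[i] <- file.path(out_dir, sprintf("annot_%04d.png", fr$index))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}
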