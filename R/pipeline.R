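# Jet-style colormap for 8-bit map renderings (dark blue -> cyan -> yellow -> red).
jet_rgb <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  list(r = r, g = g, b = b)
}

write_map_png <- function(map, path, na_value = 0) {
  v <- map
  v[is.na(v)] <- na_value
  col <- jet_rgb(v)
  img <- array(0, c(dim(map), 3L))
  img[, , 1] <- col$r; img[, , 2] <- col$g; img[, , 3] <- col$b
  png::writePNG(img, path)
  invisible(path)
}

write_map_tiff <- function(map, path, scale = 1) {
  v <- map / scale
  v[is.na(v)] <- 0
  tiff::writeTIFF(pmin(pmax(v, 0), 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' Run the full scar characterization pipeline on one image
#'
#' Executes segmentation (CAS/FS/BS), collagen density, orientation and
#' directional variance on an input image (path or RGB array), optionally
#' cropped to an ROI, and writes all artifacts under `outdir`: the three
#' masks and a color overlay (PNG), density / orientation / variance maps
#' (32-bit float TIFF, orientation stored as theta/180, plus jet-colormap PNG
#' renderings and an orientation-validity PNG), a one-row metrics CSV and a
#' `manifest.txt` recording every parameter, seed and artifact. On any stage
#' failure the partial outputs are removed before the error propagates.
#'
#' @param input Path to a PNG/TIFF image, or an integer `H x W x 3` array.
#' @param outdir Output directory (created if missing).
#' @param roi Optional [roi_box()] to crop before analysis.
#' @param mask Optional path to (or logical matrix of) a binary scar mask on
#'   the same frame; its pixel area is measured and logged.
#' @param seed K-means seed. @param restarts K-means restarts.
#' @param kernel_radius Airy-disk kernel radius, px.
#' @param window_radius,n_angles Orientation probe parameters.
#' @param roi_id,group Identifiers for the metrics row.
#' @return Invisibly, a list with `metrics` (data.frame row), `files`
#'   (artifact paths) and `scar_area_px` (or `NA` without a mask).
#' @export
run_characterize <- function(input, outdir, roi = NULL, mask = NULL,
                             seed = 0L, restarts = 10L, kernel_radius = 16L,
                             window_radius = 8L, n_angles = 18L,
                             roi_id = "roi1", group = NA_character_) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  tryCatch({
    image <- if (is.character(input)) read_image(input) else check_rgb_image(input)
    if (!is.null(roi)) image <- crop_roi(image, roi)
    scar_area <- NA_integer_
    if (!is.null(mask)) {
      m <- if (is.character(mask)) read_mask(mask) else check_mask(mask)
      if (!same_frame(m, image))
        stop_fdv("scar mask (%d x %d) does not match the analyzed frame (%d x %d)",
                 nrow(m), ncol(m), dim(image)[1], dim(image)[2],
                 class = "fiberDV_dim_error")
      scar_area <- measure_area(m)
    }
    seg <- segment_tissue(image, seed = seed, restarts = restarts)
    kern <- airy_kernel(kernel_radius)
    dens <- collagen_density(seg$cas, kern)
    field <- estimate_orientation(seg$cas, window_radius = window_radius,
                                  n_angles = n_angles)
    vmap <- directional_variance(field, kern)
    metrics <- summarize_roi(seg, dens, vmap, roi_id = roi_id, group = group)

    emit("cas.png", function(p) write_mask(seg$cas, p))
    emit("fs.png", function(p) write_mask(seg$fs, p))
    emit("bs.png", function(p) write_mask(seg$bs, p))
    emit("overlay.png", function(p) write_image(segmentation_overlay(seg), p))
    emit("density.tif", function(p) write_map_tiff(dens, p))
    emit("density.png", function(p) write_map_png(dens, p))
    emit("orientation.tif", function(p) write_map_tiff(field$theta, p, scale = 180))
    emit("orientation_valid.png", function(p) write_mask(field$valid, p))
    emit("variance.tif", function(p) write_map_tiff(vmap$V, p))
    emit("variance.png", function(p) write_map_png(vmap$V, p))
    emit("metrics.csv", function(p) utils::write.csv(metrics, p, row.names = FALSE))
    emit("manifest.txt", function(p) {
      lines <- c(
        "fiberDV characterize manifest",
        sprintf("input: %s", if (is.character(input)) input else "<in-memory array>"),
        sprintf("frame: %d x %d", dim(image)[1], dim(image)[2]),
        if (!is.null(roi)) sprintf("roi: rows [%d,%d) cols [%d,%d)",
                                   roi$row0, roi$row1, roi$col0, roi$col1),
        sprintf("scar_area_px: %s", scar_area),
        sprintf("seed: %d | restarts: %d | kernel_radius: %d | window_radius: %d | n_angles: %d",
                seed, restarts, kernel_radius, window_radius, n_angles),
        "orientation.tif stores theta/180; density.tif and variance.tif store raw [0,1] values",
        "artifacts:", paste(" ", basename(written))
      )
      writeLines(lines, p)
    })
    invisible(list(metrics = metrics, files = written, scar_area_px = scar_area))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

#' Compare ROI metric tables across tissue groups
#'
#' Reads per-ROI metric tables (CSV paths or data frames with a `group`
#' column), runs [compare_regions()] for each requested metric -- pooled
#' Student's t for two groups, one-way ANOVA otherwise -- and writes
#' `comparison.csv` plus a human-readable `report.txt` with mean +/- SD per
#' group and p-values.
#'
#' @param metrics CSV paths or data frames of [summarize_roi()] rows; all are
#'   row-bound and grouped by their `group` column.
#' @param outdir Output directory.
#' @param metric_names Metrics to compare (default all four).
#' @return Invisibly, a list of `group_comparison` objects keyed by metric.
#' @export
run_compare <- function(metrics, outdir,
                        metric_names = c("fs_pct", "cas_pct", "cdm_pct", "dv_pct")) {
  if (!is.list(metrics) || is.data.frame(metrics)) metrics <- list(metrics)
  tabs <- lapply(metrics, function(m)
    if (is.character(m)) utils::read.csv(m, stringsAsFactors = FALSE) else m)
  all_rows <- do.call(rbind, tabs)
  groups <- unique(all_rows$group)
  if (length(groups) < 2L)
    stop_fdv("need metrics from >= 2 groups (got: %s)",
             paste(groups, collapse = ", "), class = "fiberDV_param_error")
  by_group <- split(all_rows, factor(all_rows$group, levels = groups))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  comparisons <- lapply(metric_names, function(mn) compare_regions(by_group, mn))
  names(comparisons) <- metric_names
  rows <- do.call(rbind, lapply(metric_names, function(mn) {
    cmp <- comparisons[[mn]]
    data.frame(metric = mn, test = cmp$test,
               groups = paste(cmp$group_names, collapse = "|"),
               means = paste(sprintf("%.4f", cmp$means), collapse = "|"),
               sds = paste(sprintf("%.4f", cmp$sds), collapse = "|"),
               statistic = cmp$statistic, p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, file.path(outdir, "comparison.csv"), row.names = FALSE)
  report <- c("fiberDV group comparison", sprintf("groups: %s (n = %s)",
              paste(groups, collapse = ", "),
              paste(vapply(by_group, nrow, integer(1)), collapse = ", ")), "")
  for (mn in metric_names) {
    cmp <- comparisons[[mn]]
    report <- c(report, sprintf("%s [%s]:", mn, cmp$test),
                sprintf("  %s: %.3f +/- %.3f", cmp$group_names, cmp$means, cmp$sds),
                sprintf("  statistic = %.4f, p = %.4g", cmp$statistic, cmp$p_value), "")
  }
  writeLines(report, file.path(outdir, "report.txt"))
  invisible(comparisons)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `generate`, `augment`, `split`, `characterize`
#' and `compare` (see `inst/cli/fiberdv`). Returns an exit status instead of
#' calling `quit()` so it is testable in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fiberdv <command> [options]",
    "commands:",
    "  generate     render a synthetic H&E preset image with ground truth",
    "  augment      rotation-augment a set of images (right angles)",
    "  split        train/validate/test split of n items",
    "  characterize run the full pipeline on one image",
    "  compare      compare metric CSVs across groups", sep = "\n")
  if (length(args) < 1L) { message(usage); return(1L) }
  cmd <- args[1L]
  rest <- args[-1L]
  if (!requireNamespace("optparse", quietly = TRUE)) {
    message("the 'optparse' package is required for the CLI")
    return(1L)
  }
  o <- optparse::make_option
  status <- tryCatch({
    switch(cmd,
      generate = {
        opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
          o("--preset", type = "character", default = "normal"),
          o("--height", type = "integer", default = 500L),
          o("--width", type = "integer", default = 500L),
          o("--seed", type = "integer", default = 0L),
          o("--outdir", type = "character", default = "fiberdv_out"))), args = rest)
        spec <- preset(opts$preset, seed = opts$seed,
                       height = opts$height, width = opts$width)
        gen <- generate_image(spec)
        dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)
        write_image(gen$image, file.path(opts$outdir, "image.png"))
        png::writePNG(gen$truth$class_map / 2, file.path(opts$outdir, "class_map.png"))
        write_map_tiff(gen$truth$theta_map, file.path(opts$outdir, "theta_map.tif"),
                       scale = 180)
        message(sprintf("wrote %s preset scene (%d x %d, seed %d) to %s",
                        opts$preset, opts$height, opts$width, opts$seed, opts$outdir))
        0L
      },
      augment = {
        opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
          o("--angles", type = "character", default = "0,90,180,270"),
          o("--outdir", type = "character", default = "fiberdv_out"))),
          args = rest, positional_arguments = TRUE)
        paths <- opts$args
        if (length(paths) == 0L) stop("augment: no input images given")
        angles <- as.numeric(strsplit(opts$options$angles, ",")[[1]])
        imgs <- lapply(paths, read_image)
        out <- rotate_augment(imgs, angles)
        dir.create(opts$options$outdir, recursive = TRUE, showWarnings = FALSE)
        for (i in seq_along(out))
          write_image(out[[i]],
                      file.path(opts$options$outdir, sprintf("aug_%04d.png", i)))
        message(sprintf("augmented %d images x %d angles -> %d outputs",
                        length(paths), length(angles), length(out)))
        0L
      },
      split = {
        opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
          o("--n", type = "integer"),
          o("--fractions", type = "character", default = "0.64,0.16,0.20"),
          o("--seed", type = "integer", default = 0L),
          o("--outdir", type = "character", default = "fiberdv_out"))), args = rest)
        fr <- as.numeric(strsplit(opts$fractions, ",")[[1]])
        sp <- split_dataset(opts$n, fr, seed = opts$seed)
        dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)
        for (part in names(sp))
          writeLines(as.character(sp[[part]]),
                     file.path(opts$outdir, paste0(part, ".txt")))
        message(sprintf("split %d items into %d/%d/%d (train/validate/test)",
                        opts$n, length(sp$train), length(sp$validate),
                        length(sp$test)))
        0L
      },
      characterize = {
        opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
          o("--input", type = "character"),
          o("--mask", type = "character", default = NULL),
          o("--box", type = "character", default = NULL,
            help = "ROI as row0,col0,row1,col1 (0-based, half-open)"),
          o("--seed", type = "integer", default = 0L),
          o("--kernel_radius", type = "integer", default = 16L),
          o("--window_radius", type = "integer", default = 8L),
          o("--n_angles", type = "integer", default = 18L),
          o("--restarts", type = "integer", default = 10L),
          o("--group", type = "character", default = NA_character_),
          o("--roi_id", type = "character", default = "roi1"),
          o("--outdir", type = "character", default = "fiberdv_out"))), args = rest)
        roi <- NULL
        if (!is.null(opts$box)) {
          v <- as.integer(strsplit(opts$box, ",")[[1]])
          roi <- roi_box(v[1], v[2], v[3], v[4])
        }
        res <- run_characterize(opts$input, opts$outdir, roi = roi,
                                mask = opts$mask, seed = opts$seed,
                                restarts = opts$restarts,
                                kernel_radius = opts$kernel_radius,
                                window_radius = opts$window_radius,
                                n_angles = opts$n_angles,
                                roi_id = opts$roi_id, group = opts$group)
        message(sprintf("characterized %s: CAS %.1f%%, FS %.1f%%, CDM %.1f%%, DV %.1f%%",
                        opts$input, res$metrics$cas_pct, res$metrics$fs_pct,
                        res$metrics$cdm_pct, res$metrics$dv_pct))
        0L
      },
      compare = {
        opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
          o("--outdir", type = "character", default = "fiberdv_out"))),
          args = rest, positional_arguments = TRUE)
        if (length(opts$args) < 1L) stop("compare: no metric CSVs given")
        cmps <- run_compare(as.list(opts$args), opts$options$outdir)
        for (mn in names(cmps))
          message(sprintf("%s [%s]: p = %.4g", mn, cmps[[mn]]$test,
                          cmps[[mn]]$p_value))
        0L
      },
      { message(usage); 1L }
    )
  }, error = function(e) {
    message(sprintf("fiberdv %s: error: %s", cmd, conditionMessage(e)))
    1L
  })
  status
}
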