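#' Image and artifact I/O, and the end-to-end pipeline
#'
#' Plain interoperable formats throughout: PNG images in, 8-bit 0/255 PNG
#' masks out, CSV sample tables, JSON models and reports. A thin
#' command-line wrapper over these functions ships in
#' `inst/cli/canopyn.R`.
#'
#' @name pipeline
NULL

#' Read an RGB image from a PNG file
#'
#' @param path PNG path (greyscale images are replicated to three
#'   channels; an alpha channel is dropped).
#' @return RGB array on the 8-bit scale.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  a * 255
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask)), path)
  invisible(path)
}

#' Read a mask PNG back to a 0/1 matrix
#' @param path PNG path.
#' @return 0/1 integer matrix.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  matrix(as.integer(a > 0.5), nrow(a))
}

report_meta <- function(seed, config = NULL) {
  list(tool = "canopyN",
       version = as.character(utils::packageVersion("canopyN")),
       seed = seed,
       config_hash = if (!is.null(config))
         sum(utf8ToInt(paste(deparse(config), collapse = ""))) else NULL)
}

#' Run the full analysis pipeline
#'
#' Segments every image, computes growth status and channel means, joins
#' the measured nitrogen values, fits the requested model on the modeling
#' subset, and evaluates it on the validation subset (or on the modeling
#' data when no split is given). Artifacts (samples.csv, model.json,
#' report.json, masks) are written when `out_dir` is given; every JSON
#' embeds the package version, a config hash and the seed.
#'
#' @param images list of RGB arrays, or a character vector of PNG paths.
#' @param total_N numeric vector of measured total nitrogen, one per
#'   image.
#' @param spec a [model_spec()].
#' @param method `"lsm"` or `"eiv"`.
#' @param validation optional logical/integer index selecting validation
#'   samples; the rest form the modeling set.
#' @param seg_cfg a [seg_config()].
#' @param control a [fit_control()].
#' @param sigma optional [eiv_sigma()] for `method = "eiv"`.
#' @param out_dir optional output directory.
#' @param seed seed recorded in artifacts and used for fitting restarts.
#' @return list with `samples` (tibble), `fit` (`"canopy_fit"`) and
#'   `report` (evaluation tibble).
#' @export
run_pipeline <- function(images, total_N, spec = model_spec("exponential", "Lab", "MCC"),
                         method = c("lsm", "eiv"), validation = NULL,
                         seg_cfg = seg_config(), control = NULL,
                         sigma = NULL, out_dir = NULL, seed = 1L) {
  method <- match.arg(method)
  if (is.character(images)) images <- lapply(images, read_rgb_image)
  if (length(images) != length(total_N))
    stop("`images` and `total_N` lengths differ", call. = FALSE)
  if (is.null(control)) control <- fit_control(seed = seed)

  samples <- purrr::imap_dfr(images, function(img, i) {
    rec <- extract_features(img, cfg = seg_cfg, id = as.character(i))
    rec$total_N <- total_N[[i]]
    rec
  })

  idx_val <- if (is.null(validation)) integer(0) else {
    if (is.logical(validation)) which(validation) else as.integer(validation)
  }
  modeling <- if (length(idx_val)) samples[-idx_val, ] else samples
  holdout <- if (length(idx_val)) samples[idx_val, ] else samples

  fit <- if (method == "lsm") fit_lsm(spec, modeling, control = control)
         else fit_eiv(spec, modeling, sigma = sigma, control = control)
  report <- evaluate_model(fit, holdout)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(samples, file.path(out_dir, "samples.csv"), row.names = FALSE)
    write_model(fit$model, file.path(out_dir, "model.json"))
    jsonlite::write_json(
      c(report_meta(seed, config = list(spec = unclass(spec), method = method)),
        as.list(report)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  list(samples = samples, fit = fit, report = report)
}
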