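#' Read a 3D volume from a NIfTI-1 file
#'
#' Integer-typed files load as label maps (integer storage), float-typed as
#' images. Header geometry (voxel spacing, affine) is surfaced alongside the
#' data; only 3D volumes are accepted.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return list with \code{data} (3D array), \code{spacing} (length-3 mm),
#'   \code{affine} (4x4 matrix) and \code{is_labels} (integer-typed on disk).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("corrupt or unreadable NIfTI header in ",
                                           path, ": ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D data in ", path,
         " (dimensionality error)")
  hdr <- RNifti::niftiHeader(img)
  int_codes <- c(2, 4, 8, 256, 512, 768)  # NIfTI integer datatype codes
  is_labels <- hdr$datatype %in% int_codes
  data <- array(as.vector(img), dim = d)
  if (is_labels) storage.mode(data) <- "integer"
  list(data = data, spacing = as.numeric(RNifti::pixdim(img))[1:3],
       affine = unclass(RNifti::xform(img)), is_labels = is_labels)
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' Label volumes are stored as unsigned 8-bit integers, images as 32-bit
#' floats; spacing goes into the header's pixdim.
#'
#' @param volume a \code{\link{label_volume}} or 3D numeric array.
#' @param path output path (.nii or .nii.gz).
#' @param spacing voxel size; for a \code{label_volume} its own spacing is
#'   used.
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path, spacing = c(1, 1, 1)) {
  if (inherits(volume, "label_volume")) {
    data <- volume$data
    spacing <- volume$spacing
    dt <- "uint8"
    if (volume$n_labels > 256L) dt <- "int16"
  } else {
    data <- volume
    dt <- "float"
  }
  im <- RNifti::asNifti(data)
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, path, datatype = dt)
  invisible(path)
}

run_config_defaults <- function() {
  list(
    data = list(dir = NULL, phantom = unclass(phantom_spec()), n_subjects = 25L),
    network = list(preset = "desk", n_labels = 4L),
    loss = list(omega = 1.0, lambda = 1.0, dn = 3L, dilation = 2L,
                eps = 1e-7, channel_mean = FALSE),
    train = unclass(train_config()),
    eval = list(include_background_in_mean = TRUE, pooled_hd95 = FALSE),
    output = list(dir = "msfseg-out"),
    seed = 1L)
}

check_known_keys <- function(x, defaults, path = "") {
  for (k in names(x)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(x[[k]]) && is.list(defaults[[k]]) &&
        !is.null(names(defaults[[k]])))
      check_known_keys(x[[k]], defaults[[k]], full)
  }
}

merge_config <- function(defaults, values) {
  for (k in names(values)) {
    if (is.list(values[[k]]) && is.list(defaults[[k]]))
      defaults[[k]] <- merge_config(defaults[[k]], values[[k]])
    else defaults[[k]] <- values[[k]]
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration with sections \code{data}, \code{network},
#' \code{loss}, \code{train}, \code{eval}, \code{output} and \code{seed},
#' fills every missing field with its validated default, rejects unknown
#' keys naming the offending path, and applies command-line style overrides
#' (named \code{section.key}) on top of the file values.
#'
#' @param path YAML file, or \code{NULL} for all defaults.
#' @param overrides named list, e.g. \code{list("loss.lambda" = 0.5)}.
#' @return list of class \code{run_config} with fully populated sections.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- run_config_defaults()
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  check_known_keys(vals, defaults)
  cfg <- merge_config(defaults, vals)
  for (k in names(overrides)) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      if (!parts %in% names(defaults)) stop("unknown configuration key: ", k)
      cfg[[parts]] <- overrides[[k]]
    } else if (length(parts) == 2L) {
      if (!parts[1] %in% names(defaults) ||
          !parts[2] %in% names(defaults[[parts[1]]]))
        stop("unknown configuration key: ", k)
      cfg[[parts[1]]][[parts[2]]] <- overrides[[k]]
    } else stop("override keys must be 'key' or 'section.key': ", k)
  }
  structure(cfg, class = "run_config")
}

# realise typed config objects from a run_config
config_objects <- function(cfg) {
  ph <- do.call(phantom_spec, cfg$data$phantom[names(cfg$data$phantom) %in%
                                                 names(formals(phantom_spec))])
  loss <- do.call(loss_config, cfg$loss)
  tr_fields <- names(formals(train_config))
  train <- do.call(train_config, cfg$train[names(cfg$train) %in% tr_fields])
  train$seed <- as.integer(cfg$seed)
  net <- network_preset(cfg$network$preset, n_labels = cfg$network$n_labels)
  list(phantom = ph, loss = loss, train = train, network = net)
}

#' Write run metadata for reproducibility
#'
#' Records the configuration, seed and package version next to a command's
#' outputs as \code{run-meta.json}.
#'
#' @param cfg a \code{run_config}.
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
write_run_meta <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(config = unclass(cfg), seed = cfg$seed,
               package_version = as.character(utils::packageVersion("msfseg")),
               r_version = as.character(getRversion()),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  path <- file.path(dir, "run-meta.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
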