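#' Read and write trial tables as tab-separated values
#'
#' Fixed-header TSV with one row per trial, the interchange format between
#' the generator and the analysis stages.
#'
#' @param trials a trial table.
#' @param path file path.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns a tibble.
#' @export
write_trial_table <- function(trials, path) {
  # doubles formatted %.17g so values survive the text round trip exactly
  out <- dplyr::mutate(trials, dplyr::across(
    dplyr::where(is.double),
    ~ ifelse(is.na(.x), NA_character_, sprintf("%.17g", .x))
  ))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  chr_cols <- c("cued_item", "condition", "response")
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      cued_item = readr::col_character(),
      condition = readr::col_character(),
      response = readr::col_character(),
      correct = readr::col_logical(),
      # parse numerics from text with base strtod, which rounds correctly
      # to the nearest double (exact round trip of %.17g output)
      .default = readr::col_character()
    )
  )
  dplyr::mutate(out, dplyr::across(
    -dplyr::any_of(c(chr_cols, "correct")), as.numeric
  ))
}

#' Export an epoch set as a plain-text container
#'
#' Writes the trials x channels x samples array as a text matrix (one row
#' per trial-channel pair, `%.17g` formatting so doubles round-trip
#' exactly) together with a JSON sidecar holding the dimensions, time axis,
#' sampling rate, channel labels and montage coordinates.
#'
#' @param epochs a `wm_epochs` object.
#' @param path base path; `<path>.dat` and `<path>.json` are written.
#' @return base path, invisibly.
#' @export
export_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "wm_epochs"))
  d <- dim(epochs$data)
  mat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[3])  # samp x (ch*tr)
  con <- file(paste0(path, ".dat"), open = "wb")
  on.exit(close(con))
  writeLines(apply(mat, 2, function(row) {
    paste(sprintf("%.17g", row), collapse = "\t")
  }), con)
  # axes and montage coordinates as %.17g strings: exact double round trip
  meta <- list(
    dims = d,
    times = sprintf("%.17g", epochs$times),
    sampling_rate = epochs$sampling_rate,
    channels = epochs$channels,
    positions = matrix(sprintf("%.17g", epochs$positions),
                       nrow = nrow(epochs$positions)),
    csd_applied = epochs$csd_applied
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_epochs
#' @export
import_epochs <- function(path) {
  json_path <- paste0(path, ".json")
  dat_path <- paste0(path, ".dat")
  if (!file.exists(json_path)) stop("missing sidecar: ", json_path)
  if (!file.exists(dat_path)) stop("missing data file: ", dat_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  req <- c("dims", "times", "sampling_rate", "channels", "positions")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0) {
    stop("epoch sidecar missing field(s): ", paste(miss, collapse = ", "))
  }
  d <- as.integer(meta$dims)
  lines <- readLines(dat_path)
  if (length(lines) != d[1] * d[2]) {
    stop("epoch data file truncated: expected ", d[1] * d[2],
         " rows (trials x channels), found ", length(lines))
  }
  vals <- as.numeric(unlist(strsplit(lines, "\t", fixed = TRUE)))
  if (length(vals) != prod(d)) {
    stop("epoch data file truncated: expected ", prod(d), " values, found ",
         length(vals))
  }
  pos <- meta$positions
  if (is.list(pos)) pos <- do.call(rbind, lapply(pos, as.numeric))
  pos <- matrix(as.numeric(pos), nrow = length(meta$channels))
  colnames(pos) <- c("x", "y", "z")
  rownames(pos) <- meta$channels
  structure(
    list(
      data = aperm(array(vals, dim = c(d[3], d[2], d[1])), c(3, 2, 1)),
      times = as.numeric(meta$times),
      sampling_rate = meta$sampling_rate,
      channels = meta$channels,
      positions = pos,
      csd_applied = isTRUE(meta$csd_applied)
    ),
    class = "wm_epochs"
  )
}

#' Export one participant's dataset (trials + epochs)
#'
#' @param trials trial table.
#' @param epochs matching `wm_epochs`.
#' @param dir output directory (created if needed).
#' @param id participant identifier used in file names.
#' @return `dir`, invisibly.
#' @export
export_dataset <- function(trials, epochs, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trial_table(trials, file.path(dir, sprintf("trials_%03d.tsv", id)))
  export_epochs(epochs, file.path(dir, sprintf("epochs_%03d", id)))
  invisible(dir)
}

#' @rdname export_dataset
#' @return `import_dataset()` returns `list(trials = , epochs = )`.
#' @export
import_dataset <- function(dir, id) {
  list(
    trials = read_trial_table(file.path(dir, sprintf("trials_%03d.tsv", id))),
    epochs = import_epochs(file.path(dir, sprintf("epochs_%03d", id)))
  )
}
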