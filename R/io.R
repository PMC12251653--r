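#' Write a spectra_set to delimited text
#'
#' Layout: a single header row naming the columns, then one row per sample.
#' The first column is `instrument_id`, followed by one column per target
#' (named by the target labels) and one column per wavelength (named by the
#' nm value). Comma separated, `.` decimal, UTF-8; numbers are written at
#' full double precision so the file round-trips losslessly.
#'
#' @param set a [spectra_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  validate_spectra_set(set)
  header <- c("instrument_id", set$target_names,
              format(set$wavelengths, digits = 17, trim = TRUE,
                     scientific = FALSE))
  lines <- paste(header, collapse = ",")
  n <- nrow(set$X)
  if (n > 0) {
    num <- cbind(set$Y, set$X)
    body <- vapply(seq_len(n), function(i)
      paste(c(set$instrument_id,
              format(num[i, ], digits = 17, trim = TRUE)), collapse = ","),
      character(1))
    lines <- c(lines, body)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a spectra_set from delimited text
#'
#' Reads the format produced by [write_spectra()]. Ragged rows and
#' non-numeric cells raise a format error naming the offending line; a
#' non-increasing wavelength header raises a validation error.
#'
#' @param path file path.
#' @return A [spectra_set()]. A header-only file yields a 0-sample set with
#'   `instrument_id = "unknown"`.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("format error: empty file ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (header[1] != "instrument_id")
    stop("format error in ", path, ": first header column must be 'instrument_id'")
  rest <- header[-1]
  wl_num <- suppressWarnings(as.numeric(rest))
  n_targets <- match(FALSE, is.na(wl_num), nomatch = length(rest) + 1L) - 1L
  target_names <- rest[seq_len(n_targets)]
  wl <- wl_num[-seq_len(n_targets)]
  if (length(wl) == 0) wl <- numeric(0)
  if (anyNA(wl))
    stop("format error in ", path, ": non-numeric wavelength in header")
  if (length(wl) > 1 && any(diff(wl) <= 0))
    stop("validation error in ", path, ": wavelengths must be strictly increasing")
  ncol_exp <- 1L + n_targets + length(wl)
  n <- length(lines) - 1L
  Y <- matrix(0, n, n_targets)
  X <- matrix(0, n, length(wl))
  inst <- "unknown"
  for (i in seq_len(n)) {
    cells <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    if (length(cells) != ncol_exp)
      stop("format error in ", path, " line ", i + 1L, ": expected ",
           ncol_exp, " fields, found ", length(cells))
    vals <- suppressWarnings(as.numeric(cells[-1]))
    if (anyNA(vals))
      stop("format error in ", path, " line ", i + 1L, ": non-numeric cell")
    inst <- cells[1]
    if (n_targets > 0) Y[i, ] <- vals[seq_len(n_targets)]
    X[i, ] <- vals[-seq_len(n_targets)]
  }
  spectra_set(X, wl, Y, target_names = target_names, instrument_id = inst)
}

#' Read the public eigenvector calibration-transfer MATLAB containers
#'
#' Optional ingestion of the two public benchmark files (MATLAB v5
#' containers) distributed by Eigenvector Research: the "corn" set (80
#' samples on instruments m5/mp5/mp6, 700 wavelength points, constituents
#' moisture/oil/protein/starch) and the IDRC-2002 "tablet" shoot-out set
#' (655 samples on instruments A1/A2, 650 points, constituents
#' weight/hardness/assay). Requires the suggested package \pkg{R.matlab}.
#'
#' Variable mapping (discovered from the published files, not guaranteed by
#' the distributors): corn uses `m5spec`, `mp5spec`, `mp6spec` and
#' `propvals` (each a MATLAB "dataset" struct whose `data` field holds the
#' matrix); tablet uses `calibrate_1/2`, `validate_1/2`, `test_1/2` and the
#' matching `*_Y` reference blocks, which are concatenated per instrument.
#'
#' @param path path to the `.mat` file.
#' @param layout `"corn"` or `"tablet"`.
#' @return A named list of [spectra_set()]s, one per instrument.
#' @export
read_eigenvector_mat <- function(path, layout = c("corn", "tablet")) {
  layout <- match.arg(layout)
  if (!requireNamespace("R.matlab", quietly = TRUE))
    stop("read_eigenvector_mat() needs the optional package 'R.matlab'; ",
         "install it or use the delimited-text reader instead")
  if (!file.exists(path)) stop("file not found: ", path)
  mat <- R.matlab::readMat(path)
  grab <- function(name) {
    v <- mat[[name]]
    if (is.null(v)) return(NULL)
    # eigenvector "dataset" objects arrive as nested lists; find the first
    # numeric matrix with > 1 column
    find_mat <- function(x) {
      if (is.numeric(x) && is.matrix(x) && ncol(x) > 1) return(x)
      if (is.list(x)) for (el in x) {
        m <- find_mat(el)
        if (!is.null(m)) return(m)
      }
      NULL
    }
    find_mat(v)
  }
  if (layout == "corn") {
    need <- c("m5spec", "mp5spec", "mp6spec", "propvals")
    key <- gsub("[._]", "", names(mat))
    lookup <- function(nm) {
      i <- match(nm, key)
      if (is.na(i)) NULL else names(mat)[i]
    }
    got <- lapply(need, function(nm) {
      real <- lookup(nm)
      if (is.null(real)) NULL else grab(real)
    })
    names(got) <- need
    if (any(vapply(got, is.null, logical(1))))
      stop("format error: expected variables ",
           paste(need, collapse = ", "), " in ", path)
    wl <- seq(1100, by = 2, length.out = ncol(got$m5spec))
    targets <- c("moisture", "oil", "protein", "starch")
    out <- lapply(c(m5 = "m5spec", mp5 = "mp5spec", mp6 = "mp6spec"),
                  function(nm) spectra_set(got[[nm]], wl, got$propvals,
                                           target_names = targets,
                                           instrument_id = sub("spec$", "", nm)))
    names(out) <- c("m5", "mp5", "mp6")
    out
  } else {
    key <- gsub("[._]", "", names(mat))
    lookup <- function(nm) {
      i <- match(nm, key)
      if (is.na(i)) stop("format error: expected variable ", nm, " in ", path)
      names(mat)[i]
    }
    blocks <- c("calibrate", "validate", "test")
    spec <- function(inst) do.call(rbind, lapply(blocks, function(b)
      grab(lookup(paste0(b, inst)))))
    yblk <- do.call(rbind, lapply(blocks, function(b)
      grab(lookup(paste0(b, "Y")))))
    X1 <- spec("1"); X2 <- spec("2")
    wl <- seq(600, by = 2, length.out = ncol(X1))
    targets <- c("weight", "hardness", "assay")[seq_len(ncol(yblk))]
    list(A1 = spectra_set(X1, wl, yblk, target_names = targets,
                          instrument_id = "A1"),
         A2 = spectra_set(X2, wl, yblk, target_names = targets,
                          instrument_id = "A2"))
  }
}
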