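#' @include AllClasses.R
NULL

#' Read a spectrum set from CSV
#'
#' The expected dialect is comma-separated with a header row, `"."` decimal
#' mark, and a wavenumber column named `wavenumber_cm-1`. With
#' `orientation = "columns"` (default) each remaining column is one sample's
#' absorbance spectrum; with `orientation = "rows"` the file is transposed:
#' the header holds the wavenumbers (first field `sample_id`) and each row
#' is a sample. Descending grids are reversed, together with the spectra,
#' to the canonical ascending orientation.
#'
#' @param path file to read
#' @param orientation `"columns"` (samples are columns) or `"rows"`
#' @param replicateOf optional parent-sample label per spectrum
#' @return a [SpectrumSet-class]
#' @seealso [writeSpectraCSV()]
#' @export
readSpectraCSV <- function(path, orientation = c("columns", "rows"),
                           replicateOf = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  if (orientation == "columns") {
    wncol <- which(names(raw) == "wavenumber_cm-1")
    if (!length(wncol))
      stop("no 'wavenumber_cm-1' column in ", path)
    grid <- .numericOrDie(raw[[wncol[1]]], path, "wavenumber_cm-1")
    ids <- names(raw)[-wncol[1]]
    a <- vapply(ids, function(id) .numericOrDie(raw[[id]], path, id),
                numeric(nrow(raw)))
    SpectrumSet(t(a), grid, sampleIds = ids, replicateOf = replicateOf)
  } else {
    grid <- .numericOrDie(names(raw)[-1], path, "header wavenumbers")
    ids <- raw[[1]]
    a <- matrix(NA_real_, nrow(raw), length(grid))
    for (j in seq_along(grid))
      a[, j] <- .numericOrDie(raw[[j + 1]], path,
                              sprintf("column %d", j + 1))
    SpectrumSet(a, grid, sampleIds = ids, replicateOf = replicateOf)
  }
}

.numericOrDie <- function(x, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in %s (%s, entry %d)",
                 x[bad[1]], path, what, bad[1]))
  if (anyNA(v))
    stop(sprintf("missing value in %s (%s)", path, what))
  v
}

#' Write a spectrum set to CSV
#'
#' Inverse of [readSpectraCSV()] with `orientation = "columns"`: a
#' `wavenumber_cm-1` column followed by one column per sample, full
#' precision (round-trips to better than 1e-12 relative error).
#'
#' @param object a [SpectrumSet-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeSpectraCSV <- function(object, path) {
  df <- data.frame(wn = object@wavenumbers,
                   t(object@absorbance), check.names = FALSE)
  names(df) <- c("wavenumber_cm-1", object@sampleIds)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one spectrum from a JCAMP-DX file
#'
#' Supports AFFN-encoded `##XYDATA=(X++(Y..Y))` and `##XYPOINTS=(XY..XY)`
#' records (the plain numeric forms instruments commonly export; SQZ/DIF
#' compression is not handled). `XFACTOR`/`YFACTOR` scaling is applied,
#' micrometre abscissae are converted to cm-1, and transmittance ordinates
#' are converted to absorbance as `-log10(T)`.
#'
#' @param path file to read
#' @param sampleId label for the spectrum; defaults to the file's `##TITLE`
#' @return a single-spectrum [SpectrumSet-class]
#' @export
readJCAMPDX <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ldr <- grepl("^##", lines)
  labels <- toupper(sub("=.*$", "", sub("^##", "", lines[ldr])))
  values <- sub("^##[^=]*=", "", lines[ldr])
  getLdr <- function(lbl, default = NULL) {
    i <- which(labels == lbl)
    if (length(i)) trimws(values[i[1]]) else default
  }
  xfactor <- as.numeric(getLdr("XFACTOR", "1"))
  yfactor <- as.numeric(getLdr("YFACTOR", "1"))
  npoints <- as.numeric(getLdr("NPOINTS", NA))
  xunits <- toupper(getLdr("XUNITS", "1/CM"))
  yunits <- toupper(getLdr("YUNITS", "ABSORBANCE"))
  if (is.null(sampleId)) sampleId <- getLdr("TITLE", "jcamp")

  start <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  mode <- "xydata"
  if (!length(start)) {
    start <- grep("^##XYPOINTS\\s*=", lines, ignore.case = TRUE)
    mode <- "xypoints"
  }
  if (!length(start))
    stop("not a JCAMP-DX data file: no ##XYDATA or ##XYPOINTS record in ",
         path)
  if (!any(grepl("^##END", lines, ignore.case = TRUE)))
    stop("truncated JCAMP-DX file (no ##END): ", path)
  start <- start[1]
  body <- lines[seq(start + 1L, length(lines))]
  end <- grep("^##", body)
  if (length(end)) body <- body[seq_len(end[1] - 1L)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty JCAMP-DX data block in ", path)

  if (mode == "xydata") {
    rows <- lapply(body, function(l)
      as.numeric(strsplit(trimws(l), "[,;[:space:]]+")[[1]]))
    if (any(vapply(rows, anyNA, TRUE)))
      stop("unparseable (possibly compressed) XYDATA line in ", path,
           "; only AFFN-encoded data are supported")
    y <- unlist(lapply(rows, function(r) {
      if (length(r) < 2L) stop("malformed XYDATA line in ", path)
      r[-1]
    }))
    ## abscissa from FIRSTX/LASTX (actual units) when present, else from
    ## the XFACTOR-scaled per-line start values and implied uniform spacing
    firstx <- as.numeric(getLdr("FIRSTX", rows[[1]][1] * xfactor))
    lastx <- as.numeric(getLdr("LASTX", NA))
    n <- length(y)
    if (!is.na(npoints) && n < npoints)
      stop(sprintf("truncated JCAMP-DX file: %d of %d points in %s",
                   n, npoints, path))
    if (is.na(lastx)) {
      starts <- vapply(rows, function(r) r[1], 0) * xfactor
      counts <- vapply(rows, function(r) length(r) - 1L, 0L)
      dx <- if (length(starts) > 1L) (starts[2] - starts[1]) / counts[1]
            else 1
      lastx <- firstx + dx * (n - 1)
    }
    x <- seq(firstx, lastx, length.out = n)
  } else {
    nums <- as.numeric(strsplit(paste(body, collapse = " "),
                                "[,;[:space:]]+")[[1]])
    nums <- nums[!is.na(nums)]
    if (length(nums) %% 2L)
      stop("odd number of values in XYPOINTS block of ", path)
    x <- nums[seq(1, length(nums), by = 2)] * xfactor
    y <- nums[seq(2, length(nums), by = 2)]
    if (!is.na(npoints) && length(x) < npoints)
      stop(sprintf("truncated JCAMP-DX file: %d of %d points in %s",
                   length(x), npoints, path))
  }
  y <- y * yfactor
  if (grepl("MICROMETER", xunits)) x <- 1e4 / x
  if (grepl("TRANSMIT", yunits)) {
    if (any(y <= 0))
      stop("non-positive transmittance cannot be converted to absorbance")
    y <- -log10(y)
  }
  ord <- order(x)
  SpectrumSet(matrix(y[ord], nrow = 1), x[ord], sampleIds = sampleId)
}

#' @rdname selectRegion
#' @export
setMethod("selectRegion", "SpectrumSet", function(object, low, high) {
  if (low >= high) stop("selectRegion: low must be < high")
  keep <- object@wavenumbers >= low & object@wavenumbers <= high
  if (!any(keep))
    stop(sprintf(
      "selectRegion: window %g-%g cm-1 does not intersect grid %g-%g cm-1",
      low, high, min(object@wavenumbers), max(object@wavenumbers)))
  initialize(object,
             wavenumbers = object@wavenumbers[keep],
             absorbance = object@absorbance[, keep, drop = FALSE])
})

#' @rdname averageReplicates
#' @export
setMethod("averageReplicates", "SpectrumSet", function(object) {
  rep <- object@replicateOf
  if (!length(rep))
    stop("averageReplicates: the set carries no replicate mapping")
  parents <- unique(rep)
  a <- matrix(NA_real_, length(parents), ncol(object@absorbance))
  for (i in seq_along(parents)) {
    rows <- object@absorbance[rep == parents[i], , drop = FALSE]
    a[i, ] <- colMeans(rows)
  }
  SpectrumSet(a, object@wavenumbers, sampleIds = parents)
})
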