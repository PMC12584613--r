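#' Read a spectrum from CSV
#'
#' Expects a two-column CSV with header `wavenumber,intensity`. If a JSON
#' sidecar `<path>.meta.json` exists it is read into the metadata record;
#' otherwise metadata is empty. Readers reject invariant violations
#' (non-monotone axis, non-numeric cells) rather than silently repairing.
#'
#' @param path Path to the CSV file.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!all(c("wavenumber", "intensity") %in% names(df))) {
    stop("spectrum CSV must have columns 'wavenumber,intensity'", call. = FALSE)
  }
  wn <- suppressWarnings(as.double(df$wavenumber))
  it <- suppressWarnings(as.double(df$intensity))
  bad <- which(is.na(wn) | is.na(it))
  if (length(bad)) {
    stop(sprintf("non-numeric cell at data line %d of %s", bad[1L], path),
         call. = FALSE)
  }
  meta <- list()
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  raman_spectrum(wn, it, meta = meta)
}

#' Write a spectrum to CSV
#'
#' Values are written at full double precision (17 significant digits) so a
#' write/read round trip reproduces the spectrum exactly. Non-empty metadata
#' goes to a JSON sidecar `<path>.meta.json`.
#'
#' @param spectrum A [raman_spectrum()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("wavenumber,intensity", con)
  writeLines(paste(format_full(spectrum$wavenumber),
                   format_full(spectrum$intensity), sep = ","), con)
  if (length(spectrum$meta)) {
    jsonlite::write_json(spectrum$meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# full-precision decimal rendering; round-trips doubles exactly
format_full <- function(x) sprintf("%.17g", x)

#' Read a spectral map from long-format CSV
#'
#' Expects columns `x,y,wavenumber,intensity`. The grid is inferred from the
#' unique sorted x and y values; every (x, y) node must carry the full shared
#' wavenumber axis, otherwise a format error lists the first missing node.
#'
#' @param path Path to the CSV file.
#' @return A [raman_map()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("x", "y", "wavenumber", "intensity")
  if (!all(need %in% names(df))) {
    stop("map CSV must have columns 'x,y,wavenumber,intensity'", call. = FALSE)
  }
  num <- lapply(df[need], function(v) suppressWarnings(as.double(v)))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad)) {
    stop(sprintf("non-numeric cell at data line %d of %s", bad[1L], path),
         call. = FALSE)
  }
  xs <- sort(unique(num$x)); ys <- sort(unique(num$y))
  wns <- sort(unique(num$wavenumber))
  nchan <- length(wns)
  counts <- table(factor(paste(num$y, num$x, sep = "/"),
                         levels = as.vector(outer(xs, ys,
                           function(a, b) paste(b, a, sep = "/")))))
  if (any(counts != nchan)) {
    key <- names(counts)[which(counts != nchan)[1L]]
    yx <- strsplit(key, "/", fixed = TRUE)[[1L]]
    stop(sprintf("incomplete map grid: node (x=%s, y=%s) has %d of %d channels",
                 yx[2L], yx[1L], counts[key], nchan), call. = FALSE)
  }
  ord <- order(match(num$y, ys), match(num$x, xs), match(num$wavenumber, wns))
  cube <- array(NA_real_, dim = c(length(ys), length(xs), nchan))
  # row-major by ascending y then x; within a node, ascending wavenumber
  cube[] <- aperm(array(num$intensity[ord], dim = c(nchan, length(xs), length(ys))),
                  c(3L, 2L, 1L))
  raman_map(xs, ys, wns, cube)
}

#' Write a spectral map to long-format CSV
#'
#' Rows are emitted row-major by ascending y then x, ascending wavenumber
#' within each node, at full precision, so round trips are exact.
#'
#' @param map A [raman_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "raman_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("x,y,wavenumber,intensity", con)
  for (iy in seq_along(map$ys)) {
    for (ix in seq_along(map$xs)) {
      writeLines(paste(format_full(rep(map$xs[ix], length(map$wavenumber))),
                       format_full(rep(map$ys[iy], length(map$wavenumber))),
                       format_full(map$wavenumber),
                       format_full(map$cube[iy, ix, ]), sep = ","), con)
    }
  }
  invisible(path)
}
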