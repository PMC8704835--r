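# Tabular spectrum I/O.  Canonical layout: column 1 is `wavenumber_cm-1`,
# remaining columns are intensities, header row names the spectra.

#' Read spectra from a CSV/TSV table
#'
#' The first column is the wavenumber axis (must be strictly increasing and
#' uniformly spaced); every remaining column becomes one spectrum, named by
#' its header.  All spectra returned share a single grid object.
#'
#' @param path file to read
#' @param dialect `"csv"` (comma) or `"tsv"` (tab)
#' @return a list of [raman_spectrum()] objects
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("spectrum table needs a wavenumber column plus at least one intensity column",
         call. = FALSE)
  # a numeric-looking first column name means the header row is missing
  if (grepl("^X?[-+]?[0-9.]+([eE][-+]?[0-9]+)?$", names(df)[1L]))
    stop("spectrum table appears to lack a header row", call. = FALSE)
  nu <- as.numeric(df[[1L]])
  if (anyNA(df))
    stop("spectrum table contains missing values", call. = FALSE)
  if (any(diff(nu) <= 0))
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  sp <- diff(nu)
  if (max(abs(sp - sp[1L])) > 1e-9 * abs(sp[1L]))
    stop("wavenumber axis must be uniformly spaced", call. = FALSE)
  grid <- make_grid(nu[1L], nu[length(nu)], length(nu))
  lapply(seq_len(ncol(df) - 1L), function(j) {
    raman_spectrum(grid, as.numeric(df[[j + 1L]]), label = names(df)[j + 1L])
  })
}

#' Write spectra to a CSV/TSV table
#'
#' Writes at full double precision (17 significant digits) so that
#' `read_spectra(write_spectra(x))` round-trips exactly.
#'
#' @param spectra a list of [raman_spectrum()] objects on one shared grid
#' @param path output file
#' @param dialect `"csv"` or `"tsv"`
#' @export
write_spectra <- function(spectra, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (inherits(spectra, "raman_spectrum")) spectra <- list(spectra)
  if (length(spectra) == 0L)
    stop("no spectra to write", call. = FALSE)
  grid <- spectra[[1L]]$grid
  for (s in spectra) check_grid(grid, s$grid, "spectrum in list")
  labs <- vapply(spectra, function(s) s$label, character(1L))
  labs[!nzchar(labs)] <- paste0("spectrum", which(!nzchar(labs)))
  mat <- cbind(grid$nu, do.call(cbind, lapply(spectra, function(s) s$values)))
  colnames(mat) <- c("wavenumber_cm-1", labs)
  chr <- apply(mat, 2L, function(col) format(col, digits = 17, trim = TRUE,
                                             scientific = FALSE))
  sep <- if (dialect == "csv") "," else "\t"
  utils::write.table(chr, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read a model matrix using the spectrum table convention
#'
#' Columns of the matrix (basis vectors or reference spectra) are written
#' exactly like intensity columns, so matrices can be inspected, pinned as
#' fixtures and re-imported with the same tooling.
#'
#' @param grid shared wavenumber axis
#' @param mat p x k matrix
#' @param path file
#' @inheritParams read_spectra
#' @return `read_matrix` returns `list(grid=, mat=)`
#' @keywords internal
#' @export
write_matrix <- function(grid, mat, path, dialect = c("csv", "tsv")) {
  mat <- as.matrix(mat)
  cols <- colnames(mat)
  if (is.null(cols)) cols <- paste0("v", seq_len(ncol(mat)))
  sp <- lapply(seq_len(ncol(mat)), function(j)
    raman_spectrum(grid, mat[, j], label = cols[j]))
  write_spectra(sp, path, dialect)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, dialect = c("csv", "tsv")) {
  sp <- read_spectra(path, dialect)
  list(grid = sp[[1L]]$grid,
       mat = do.call(cbind, lapply(sp, function(s) {
         v <- s$values
         v
       })))
}
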