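#' Write a time trace to the plain-text interchange format
#'
#' Format: `#key: value` header lines (`time_unit`, `freq_GHz`,
#' `g_value`, `tau_ns`, `label`), then whitespace-separated columns
#' `time real [imag]`.  Conversion from vendor binary formats is upstream
#' of this package.
#'
#' @param trace An [time_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "epr_trace"))
  hdr <- c(sprintf("#time_unit: %s", trace$unit))
  for (key in c("freq_GHz", "g_value", "tau_ns", "label")) {
    val <- trace$meta[[key]]
    if (!is.null(val)) {
      txt <- if (is.numeric(val)) sprintf("%.15g", val) else as.character(val)
      hdr <- c(hdr, sprintf("#%s: %s", key, txt))
    }
  }
  cols <- cbind(trace$t, trace$real)
  if (!is.null(trace$imag)) cols <- cbind(cols, trace$imag)
  body <- apply(cols, 1, function(row)
    paste(sprintf("%.15g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a time trace from the plain-text interchange format
#'
#' Accepts the two-column (time, real), three-column (time, real, imag)
#' and headered `#key: value` dialects written by [write_trace()].
#' Missing acquisition metadata is filled with X-band defaults (9.5 GHz,
#' g = 2.006) with a warning; NaN values and non-monotone axes are
#' rejected with the offending line numbers.
#'
#' @param path Input file path.
#' @param unit Time unit to assume when the header does not state one.
#' @return An [time_trace()].
#' @export
read_trace <- function(path, unit = c("us", "ns")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#", lines)
  meta <- list()
  for (h in lines[hdr_idx]) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[m[2]]] <- if (is.na(num)) val else num
    }
  }
  data_idx <- setdiff(which(nzchar(trimws(lines))), hdr_idx)
  if (!length(data_idx)) stop("no data rows in ", path, " (header only?)")
  rows <- lapply(data_idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals) || any(is.nan(vals)))
      stop(sprintf("non-numeric or NaN value at line %d of %s", i, path))
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1 || !(ncols[1] %in% c(2, 3)))
    stop("expected 2 or 3 numeric columns throughout ", path)
  mat <- do.call(rbind, rows)
  t <- mat[, 1]
  bad <- which(diff(t) <= 0)
  if (length(bad))
    stop(sprintf("time axis not strictly increasing at line %d of %s",
                 data_idx[bad[1] + 1], path))
  if (!is.null(meta$time_unit)) {
    unit <- match.arg(meta$time_unit, c("us", "ns"))
    meta$time_unit <- NULL
  }
  if (is.null(meta$freq_GHz)) {
    warning("no `freq_GHz` in header; assuming X-band 9.5 GHz")
    meta$freq_GHz <- 9.5
  }
  if (is.null(meta$g_value)) {
    warning("no `g_value` in header; assuming nitroxide g = 2.006")
    meta$g_value <- 2.006
  }
  time_trace(t, mat[, 2], imag = if (ncols[1] == 3) mat[, 3],
             unit = unit, meta = meta)
}

#' Write a distance distribution to a two-column text file
#'
#' Columns: `r_nm density`.  The density is normalized on write.
#'
#' @param pr A [distance_distribution()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(pr, path) {
  stopifnot(inherits(pr, "distance_distribution"))
  writeLines(c("#columns: r_nm density",
               sprintf("%.15g %.15g", pr$r, pr$density)), path)
  invisible(path)
}

#' Read a distance distribution from a two-column text file
#'
#' Negative densities are rejected; a normalization drift beyond 1e-3
#' triggers a warning and the density is renormalized.
#'
#' @param path Input file path.
#' @return A [distance_distribution()].
#' @export
read_distribution <- function(path) {
  if (!file.exists(path)) stop("distribution file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty distribution file: ", path)
  mat <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (anyNA(mat) || ncol(mat) != 2)
    stop("expected two numeric columns (r_nm, density) in ", path)
  if (any(mat[, 2] < 0)) stop("negative densities in ", path)
  drift <- abs(pracma::trapz(mat[, 1], mat[, 2]) - 1)
  if (drift > 1e-3)
    warning(sprintf("distribution integral off by %.3g; renormalizing",
                    drift))
  distance_distribution(mat[, 1], mat[, 2])
}
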