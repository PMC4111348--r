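#' Construct a Raman spectrum
#'
#' Container for one replicate scan: a strictly increasing wavenumber grid with
#' matching intensities. Descending input is reversed; duplicate wavenumbers
#' (within 1e-9 cm\eqn{^{-1}}) are merged by mean intensity so construction is
#' order-independent. A spectrum whose grid does not cover at least
#' 300-3060 cm\eqn{^{-1}} cannot support the organic-phosphate ratio and is
#' flagged `usable = FALSE` rather than rejected.
#'
#' @param wavenumbers numeric vector, cm^-1.
#' @param intensities numeric vector, detector counts (arbitrary units).
#' @param sample_id character scalar identifying the bone sample.
#' @param replicate integer replicate index (>= 1); triplicate scans on
#'   different regions of compact bone are the usual acquisition protocol.
#' @return An object of class `raman_spectrum`: a list with fields
#'   `sample_id`, `replicate`, `wavenumbers`, `intensities`, `usable`.
#' @export
raman_spectrum <- function(wavenumbers, intensities, sample_id = "", replicate = 1L) {
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length")
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least two points")
  if (anyNA(wavenumbers) || !all(is.finite(wavenumbers)))
    stop("wavenumbers must be finite")
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L) stop("replicate index must be >= 1")

  ord <- order(wavenumbers)
  w <- wavenumbers[ord]
  y <- intensities[ord]
  # merge duplicates within tolerance by mean intensity
  grp <- cumsum(c(TRUE, diff(w) > 1e-9))
  if (max(grp) < length(w)) {
    w <- as.numeric(tapply(w, grp, mean))
    y <- as.numeric(tapply(y, grp, mean))
  }
  if (any(diff(w) <= 0))
    stop("wavenumber grid is not strictly increasing after sort/merge")

  structure(
    list(sample_id = as.character(sample_id), replicate = replicate,
         wavenumbers = w, intensities = y,
         usable = w[1] <= 300 && w[length(w)] >= 3060),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s (replicate %d): %d points, %.0f-%.0f cm-1%s\n",
              if (nzchar(x$sample_id)) x$sample_id else "<unnamed>",
              x$replicate, length(x$wavenumbers),
              x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)],
              if (x$usable) "" else " [range too short for ratio analysis]"))
  invisible(x)
}

#' Read a Raman spectrum from disk
#'
#' Supports the two plain-text forms instruments commonly export: a two-column
#' wavenumber/intensity table (whitespace or comma delimited, `#` comments
#' allowed) and JCAMP-DX with uncompressed AFFN `##XYDATA=(X++(Y..Y))` or
#' `##XYPOINTS=(XY..XY)` blocks. Vendor binary formats are out of scope.
#'
#' Sample id and replicate index are taken from the JCAMP `##TITLE`, when
#' present, or from the file name (a trailing `_rep<k>` or `_<k>` sets the
#' replicate).
#'
#' @param path file path.
#' @param dialect `"auto"` (default; JCAMP is recognised by its `##TITLE=` /
#'   `##JCAMP-DX=` header), `"two_column"` or `"jcamp"`.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, dialect = c("auto", "two_column", "jcamp")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    dialect <- if (any(grepl("^\\s*##(TITLE|JCAMP-DX)\\s*=", head(lines, 5L))))
      "jcamp" else "two_column"
  }
  meta <- .filename_metadata(path)
  if (dialect == "two_column") {
    .read_two_column(lines, meta$sample_id, meta$replicate)
  } else {
    .read_jcamp(lines, meta$sample_id, meta$replicate)
  }
}

.filename_metadata <- function(path) {
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  rep_idx <- 1L
  m <- regmatches(base, regexec("^(.*)_(?:rep)?([0-9]+)$", base))[[1]]
  if (length(m) == 3L) {
    rep_idx <- as.integer(m[3])
    base <- m[2]
  }
  list(sample_id = base, replicate = rep_idx)
}

.read_two_column <- function(lines, sample_id, replicate) {
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no data rows found")
  w <- numeric(length(idx)); y <- numeric(length(idx))
  for (k in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[k]]), "[,;[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals[1:2]))
      stop(sprintf("malformed two-column data at line %d: '%s'",
                   idx[k], lines[idx[k]]))
    w[k] <- vals[1]; y[k] <- vals[2]
  }
  raman_spectrum(w, y, sample_id = sample_id, replicate = replicate)
}

.jcamp_field <- function(lines, name) {
  pat <- paste0("^\\s*##", name, "\\s*=\\s*")
  hit <- grep(pat, lines, ignore.case = TRUE, value = TRUE)
  if (!length(hit)) return(NA_character_)
  trimws(sub(pat, "", hit[1], ignore.case = TRUE))
}

.read_jcamp <- function(lines, sample_id, replicate) {
  title <- .jcamp_field(lines, "TITLE")
  if (!is.na(title) && nzchar(title)) sample_id <- title
  xfac <- suppressWarnings(as.numeric(.jcamp_field(lines, "XFACTOR")))
  yfac <- suppressWarnings(as.numeric(.jcamp_field(lines, "YFACTOR")))
  if (is.na(xfac)) xfac <- 1
  if (is.na(yfac)) yfac <- 1

  xy_start <- grep("^\\s*##XYDATA\\s*=", lines, ignore.case = TRUE)
  pts_start <- grep("^\\s*##XYPOINTS\\s*=", lines, ignore.case = TRUE)
  end_line <- grep("^\\s*##END\\s*=?", lines, ignore.case = TRUE)
  stop_at <- if (length(end_line)) end_line[1] else length(lines) + 1L

  if (length(xy_start)) {
    body <- lines[seq(xy_start[1] + 1L, stop_at - 1L)]
    body <- body[!grepl("^\\s*(##|\\$\\$|$)", body)]
    if (!length(body)) stop("empty XYDATA block")
    firstx <- suppressWarnings(as.numeric(.jcamp_field(lines, "FIRSTX")))
    lastx <- suppressWarnings(as.numeric(.jcamp_field(lines, "LASTX")))
    npts <- suppressWarnings(as.numeric(.jcamp_field(lines, "NPOINTS")))
    if (anyNA(c(firstx, lastx, npts)))
      stop("XYDATA requires FIRSTX, LASTX and NPOINTS headers")
    deltax <- if (npts > 1) (lastx - firstx) / (npts - 1) else 0
    w <- c(); y <- c()
    for (i in seq_along(body)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]),
                                                   "[,;[:space:]]+")[[1]]))
      if (length(vals) < 2L || anyNA(vals))
        stop(sprintf("malformed XYDATA line %d: '%s'", i, body[i]))
      x0 <- vals[1] * xfac
      ys <- vals[-1] * yfac
      w <- c(w, x0 + deltax * xfac * (seq_along(ys) - 1L))
      y <- c(y, ys)
    }
    if (length(y) != npts)
      stop(sprintf("XYDATA declares %d points but %d were read", npts, length(y)))
  } else if (length(pts_start)) {
    body <- lines[seq(pts_start[1] + 1L, stop_at - 1L)]
    body <- body[!grepl("^\\s*(##|\\$\\$|$)", body)]
    vals <- suppressWarnings(as.numeric(unlist(
      strsplit(trimws(body), "[,;[:space:]]+"))))
    if (anyNA(vals) || length(vals) %% 2L != 0L)
      stop("malformed XYPOINTS block: expected numeric x,y pairs")
    w <- vals[seq(1, length(vals), 2)] * xfac
    y <- vals[seq(2, length(vals), 2)] * yfac
  } else {
    stop("no XYDATA or XYPOINTS block found in JCAMP-DX file")
  }
  raman_spectrum(w, y, sample_id = sample_id, replicate = replicate)
}

#' Write a Raman spectrum to disk
#'
#' @param spectrum a [raman_spectrum()].
#' @param path output file path.
#' @param dialect `"two_column"` (default) or `"jcamp"` (XYPOINTS form).
#' @param digits significant digits for intensities.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, dialect = c("two_column", "jcamp"),
                           digits = 10) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  dialect <- match.arg(dialect)
  w <- formatC(spectrum$wavenumbers, format = "g", digits = 12, width = 1)
  y <- formatC(spectrum$intensities, format = "g", digits = digits, width = 1)
  if (dialect == "two_column") {
    hdr <- c(sprintf("# sample_id: %s", spectrum$sample_id),
             sprintf("# replicate: %d", spectrum$replicate))
    writeLines(c(hdr, paste(w, y)), path)
  } else {
    writeLines(c(
      sprintf("##TITLE=%s", spectrum$sample_id),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=RAMAN SPECTRUM",
      "##XUNITS=1/CM", "##YUNITS=ARBITRARY UNITS",
      "##XFACTOR=1", "##YFACTOR=1",
      sprintf("##NPOINTS=%d", length(w)),
      "##XYPOINTS=(XY..XY)",
      paste(w, y, sep = ", "),
      "##END="), path)
  }
  invisible(path)
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Linear interpolation; the target grid must lie inside the spectrum's range
#' (no extrapolation).
#'
#' @param spectrum a [raman_spectrum()].
#' @param grid numeric vector of target wavenumbers, cm^-1, increasing.
#' @return A [raman_spectrum()] on `grid`.
#' @export
resample_spectrum <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  rng <- range(spectrum$wavenumbers)
  if (min(grid) < rng[1] || max(grid) > rng[2])
    stop(sprintf("target grid [%g, %g] outside spectrum range [%g, %g]",
                 min(grid), max(grid), rng[1], rng[2]))
  y <- approx(spectrum$wavenumbers, spectrum$intensities, xout = grid,
              method = "linear", ties = "ordered")$y
  raman_spectrum(grid, y, sample_id = spectrum$sample_id,
                 replicate = spectrum$replicate)
}

.PAIRED_COLUMNS <- c("sample_id", "burial_no", "phase", "pct_n", "pct_c",
                     "cn_atomic", "pct_collagen", "raman_ratio")
.PHASES <- c("Neolithic", "Bronze", "Iron")

#' Load a paired Raman / wet-chemistry table
#'
#' Reads a delimited table joining the per-sample Raman organic-phosphate
#' ratio with the wet-chemistry yields (%N, %C w/w, atomic C:N, % collagen).
#' Missing cells (empty or `"-"`, the convention of the printed source tables)
#' become `NA`, never zeros. This is the shape consumed by the correlation and
#' screening stages.
#'
#' @param path CSV (or TSV, by `.tsv`/`.txt` extension) file with headers
#'   `sample_id, burial_no, phase, pct_n, pct_c, cn_atomic, pct_collagen,
#'   raman_ratio`.
#' @return A `data.frame` with class `paired_dataset` prepended.
#' @export
load_paired_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE, strip.white = TRUE,
                 na.strings = c("", "-", "NA"))
  missing_cols <- setdiff(.PAIRED_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, .PAIRED_COLUMNS]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad_phase <- !is.na(df$phase) & !(df$phase %in% .PHASES)
  if (any(bad_phase))
    stop("unknown phase labels: ", paste(unique(df$phase[bad_phase]), collapse = ", "))
  for (col in c("pct_n", "pct_c", "cn_atomic", "pct_collagen", "raman_ratio")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("negative values in column ", col)
  }
  if (any(df$pct_collagen == 0, na.rm = TRUE))
    stop("pct_collagen must be > 0 when present")
  class(df) <- c("paired_dataset", class(df))
  df
}

#' Packaged reference tables for the Ban Non Wat burial cohort
#'
#' The packaged fixtures reproduce the published wet-chemistry and Raman
#' results for 41 subadult bone samples from a prehistoric site in the
#' monsoonal tropics of Northeast Thailand: 31 samples with complete records
#' (`"table1"`) and 10 with nitrogen at or below the 7 ug analytical floor,
#' missing %N, %C or the Raman ratio (`"table2"`; two of these lost their
#' ratio to fluorescence).
#'
#' @param which `"table1"`, `"table2"` or `"combined"` (default; both tables
#'   stacked).
#' @return A `paired_dataset` data frame (see [load_paired_table()]).
#' @export
bnw_dataset <- function(which = c("combined", "table1", "table2")) {
  which <- match.arg(which)
  path1 <- system.file("extdata", "bnw_table1.csv", package = "ramanbone")
  path2 <- system.file("extdata", "bnw_table2.csv", package = "ramanbone")
  out <- switch(which,
    table1 = load_paired_table(path1),
    table2 = load_paired_table(path2),
    combined = {
      combined <- rbind(load_paired_table(path1), load_paired_table(path2))
      combined <- combined[order(as.integer(combined$sample_id)), ]
      rownames(combined) <- NULL
      combined
    })
  out
}

#' Complete-case subset of a paired dataset
#'
#' Keeps the records usable for the correlation analysis: Raman ratio, %N, %C
#' and % collagen all present.
#'
#' @param dataset a `paired_dataset` data frame.
#' @return The subset with complete records, row names reset.
#' @export
complete_cases <- function(dataset) {
  keep <- stats::complete.cases(
    dataset[, c("raman_ratio", "pct_n", "pct_c", "pct_collagen")])
  out <- dataset[keep, ]
  rownames(out) <- NULL
  out
}
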