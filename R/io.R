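#' Write a digitized profile to a contour file
#'
#' The contour dialect is two-column delimited text (`x`, `y`) with one
#' `x,y` header line, preceded by `#`-comment headers declaring units,
#' orientation and (when known) the mm-per-px scale. Numbers are written
#' with 17 significant digits so a write/read round trip is lossless.
#'
#' @param profile an [egg_profile].
#' @param path output file path.
#' @param delim `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_contour <- function(profile, path, delim = ",") {
  stopifnot(inherits(profile, "egg_profile"), delim %in% c(",", "\t"))
  hdr <- c(sprintf("# units: %s", profile$units),
           sprintf("# orientation: %s", profile$orientation))
  if (!is.null(profile$scale))
    hdr <- c(hdr, sprintf("# scale_mm_per_px: %s",
                          format(profile$scale, digits = 17)))
  num <- function(v) vapply(v, function(z) format(z, digits = 17),
                            character(1))
  lines <- c(hdr, paste("x", "y", sep = delim),
             paste(num(profile$x), num(profile$y), sep = delim))
  writeLines(lines, path)
  invisible(path)
}

#' Read a contour file into a digitized profile
#'
#' Parses the dialect written by [write_contour]: optional `#` headers
#' (units, orientation, scale), one header line naming the two columns,
#' then one `x`, `y` pair per line. The delimiter (comma or tab) is
#' auto-detected from the header line unless given. Outlines with signed
#' `y` or duplicated `x` are treated as closed and folded to a
#' half-profile.
#'
#' @param path input file path.
#' @param delim optional delimiter override (`","` or `"\t"`).
#' @return An [egg_profile], sorted by `x`.
#' @export
read_contour <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty contour file: ", path)
  is_hdr <- startsWith(trimws(lines), "#")
  meta <- trimws(sub("^\\s*#", "", lines[is_hdr]))
  units <- "px"; orientation <- "pointed_negative_x"; scale <- NULL
  for (m in meta) {
    kv <- strsplit(m, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = ":"))
    if (key == "units") units <- val
    else if (key == "orientation") orientation <- val
    else if (key == "scale_mm_per_px") scale <- as.numeric(val)
  }
  body <- lines[!is_hdr]
  body_lineno <- which(!is_hdr)
  if (is.null(delim))
    delim <- if (grepl("\t", body[1])) "\t" else ","
  split1 <- strsplit(body[1], delim, fixed = TRUE)[[1]]
  if (length(split1) < 2)
    stop(sprintf("line %d: expected two %s-separated columns",
                 body_lineno[1],
                 if (delim == ",") "comma" else "tab"))
  has_header <- any(is.na(suppressWarnings(as.numeric(split1[1:2]))))
  data_lines <- if (has_header) body[-1] else body
  data_nos <- if (has_header) body_lineno[-1] else body_lineno
  if (!length(data_lines)) stop("contour file has no data rows")
  parts <- strsplit(data_lines, delim, fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(sprintf("line %d: expected two columns, found %d",
                 data_nos[bad[1]], lengths(parts)[bad[1]]))
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  nn <- which(is.na(x) | is.na(y))
  if (length(nn))
    stop(sprintf("line %d: non-numeric cell", data_nos[nn[1]]))
  o <- order(x)
  x <- x[o]; y <- y[o]
  closed <- any(y < 0) || anyDuplicated(x) > 0
  egg_profile(x, y, units = units, scale = scale,
              orientation = orientation, closed = closed)
}
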