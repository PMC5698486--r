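#' Read a 1D spectrum from JCAMP-DX or two-column CSV
#'
#' JCAMP-DX support covers the XYDATA `(X++(Y..Y))` AFFN form with equally
#' spaced abscissa (FIRSTX/LASTX/NPOINTS, XFACTOR/YFACTOR); the CSV form is
#' two columns `ppm,intensity` with a header row and optional `# key: value`
#' metadata comments. Format is auto-detected from the extension
#' (`.jdx`/`.dx` vs `.csv`) or, failing that, from the leading `##` of
#' JCAMP files.
#'
#' @param path Input file.
#' @param format `"auto"`, `"jcamp_dx"` or `"csv"`.
#' @return An `nmr_spectrum` (descending ppm axis).
#' @export
read_spectrum <- function(path, format = c("auto", "jcamp_dx", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_spectrum: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jdx", "dx", "jcamp")) "jcamp_dx"
              else if (ext == "csv") "csv"
              else {
        first <- readLines(path, n = 1L, warn = FALSE)
        if (length(first) > 0 && startsWith(first, "##")) "jcamp_dx" else "csv"
      }
  }
  sp <- if (format == "jcamp_dx") read_jcamp(path) else read_spectrum_csv(path)
  if (is.unsorted(rev(sp$ppm), strictly = TRUE)) {
    if (!is.unsorted(sp$ppm, strictly = TRUE)) {
      sp$ppm <- rev(sp$ppm); sp$intensity <- rev(sp$intensity)
    } else {
      stop("read_spectrum: ppm axis is not strictly monotone")
    }
  }
  sp
}

read_spectrum_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("read_spectrum: parse error at line 1: empty file")
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  if (length(body) < 2) {
    stop("read_spectrum: parse error at line ", length(meta_lines) + 1L,
         ": no data rows")
  }
  df <- tryCatch(
    utils::read.csv(text = lines[body], check.names = FALSE),
    error = function(e) stop("read_spectrum: parse error: ",
                             conditionMessage(e)))
  if (ncol(df) < 2) stop("read_spectrum: need two columns (ppm, intensity)")
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3) {
      v <- suppressWarnings(as.numeric(m[3]))
      meta[[trimws(m[2])]] <- if (is.na(v)) m[3] else v
    }
  }
  meta$n_points <- nrow(df)
  new_spectrum(as.numeric(df[[1]]), as.numeric(df[[2]]), meta)
}

read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("read_spectrum: parse error at line 1: empty file")
  hdr <- list()
  i_data <- NA_integer_
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (startsWith(l, "##")) {
      kv <- regmatches(l, regexec("^##([^=]*)=\\s*(.*)$", l))[[1]]
      if (length(kv) != 3) {
        stop("read_spectrum: parse error at line ", i, ": malformed record")
      }
      key <- toupper(trimws(kv[2]))
      if (startsWith(key, "XYDATA")) { i_data <- i; break }
      hdr[[key]] <- trimws(kv[3])
    }
  }
  if (is.na(i_data)) stop("read_spectrum: no ##XYDATA record found")
  num <- function(key, default = NA_real_) {
    if (is.null(hdr[[key]])) default else as.numeric(hdr[[key]])
  }
  npoints <- as.integer(num("NPOINTS"))
  firstx <- num("FIRSTX"); lastx <- num("LASTX")
  xfac <- num("XFACTOR", 1); yfac <- num("YFACTOR", 1)
  if (is.na(npoints) || is.na(firstx) || is.na(lastx)) {
    stop("read_spectrum: parse error: NPOINTS/FIRSTX/LASTX missing")
  }
  ys <- numeric(0)
  for (i in (i_data + 1L):length(lines)) {
    l <- trimws(lines[i])
    if (startsWith(l, "##")) break
    if (nchar(l) == 0) next
    toks <- strsplit(l, "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      stop("read_spectrum: parse error at line ", i, ": non-numeric token")
    }
    ys <- c(ys, vals[-1])           # first token is the line's X value
  }
  if (length(ys) != npoints) {
    stop("read_spectrum: parse error: expected ", npoints,
         " ordinates, found ", length(ys))
  }
  ppm <- seq(firstx * xfac, lastx * xfac, length.out = npoints)
  meta <- list(n_points = npoints,
               field_mhz = num(".OBSERVE FREQUENCY"),
               spectral_width_hz = num("$SPECTRALWIDTHHZ"),
               linewidth_hz = num("$LINEWIDTHHZ"),
               temperature_K = num("TEMPERATURE"))
  new_spectrum(ppm, ys * yfac, meta)
}

#' Write a spectrum to JCAMP-DX or CSV
#'
#' @param spectrum An `nmr_spectrum`.
#' @param path Output file.
#' @param format `"jcamp_dx"` or `"csv"` (default by extension).
#' @param title JCAMP TITLE record.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path,
                           format = c("auto", "jcamp_dx", "csv"),
                           title = "shiftnav simulated spectrum") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "jcamp_dx"
  }
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in c("field_mhz", "spectral_width_hz", "linewidth_hz",
                "temperature_K", "noise_sigma")) {
      if (!is.null(spectrum$meta[[k]]) && !is.na(spectrum$meta[[k]])) {
        writeLines(sprintf("# %s: %.10g", k, spectrum$meta[[k]]), con)
      }
    }
    writeLines("ppm,intensity", con)
    writeLines(sprintf("%.8f,%.8g", spectrum$ppm, spectrum$intensity), con)
    return(invisible(path))
  }
  y <- spectrum$intensity
  yfac <- max(max(abs(y)) / 2^30, 1e-30)
  yi <- round(y / yfac)
  n <- length(y)
  per_line <- 8L
  idx <- seq(1, n, by = per_line)
  xvals <- seq(0, n - 1)
  body <- vapply(idx, function(i0) {
    j <- i0:min(i0 + per_line - 1L, n)
    paste(c(format(xvals[i0]), format(yi[j], scientific = FALSE)),
          collapse = " ")
  }, character(1))
  hdr <- c(
    paste0("##TITLE= ", title),
    "##JCAMP-DX= 5.01",
    "##DATA TYPE= NMR SPECTRUM",
    "##DATA CLASS= XYDATA",
    "##ORIGIN= shiftnav",
    "##OWNER= shiftnav",
    sprintf("##.OBSERVE FREQUENCY= %.10g", spectrum$meta$field_mhz %||% NA),
    "##.OBSERVE NUCLEUS= ^1H",
    "##XUNITS= PPM",
    "##YUNITS= ARBITRARY UNITS",
    sprintf("##$SPECTRALWIDTHHZ= %.10g",
            spectrum$meta$spectral_width_hz %||% NA),
    sprintf("##$LINEWIDTHHZ= %.10g", spectrum$meta$linewidth_hz %||% NA),
    sprintf("##TEMPERATURE= %.10g", spectrum$meta$temperature_K %||% NA),
    sprintf("##NPOINTS= %d", n),
    sprintf("##FIRSTX= %.10f", spectrum$ppm[1]),
    sprintf("##LASTX= %.10f", spectrum$ppm[n]),
    "##XFACTOR= 1",
    sprintf("##YFACTOR= %.12g", yfac),
    sprintf("##MINY= %.10g", min(y)),
    sprintf("##MAXY= %.10g", max(y)),
    "##XYDATA= (X++(Y..Y))")
  writeLines(c(hdr, body, "##END="), path)
  invisible(path)
}
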