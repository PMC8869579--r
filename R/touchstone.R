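#' Touchstone v1 two-port input/output
#'
#' Reads and writes two-port `.s2p` files in Touchstone version 1: an
#' optional-comment header, one option line `# <unit> S <format> R <z0>`
#' (frequency unit Hz/kHz/MHz/GHz; format RI, MA or DB; reference impedance),
#' then one row per frequency with `f S11 S21 S12 S22` as value pairs.
#' Reading and writing round-trip the complex data to near machine
#' precision in all three encodings.
#'
#' @param path File path.
#' @return `read_touchstone()` returns an `lw_spectrum` with columns
#'   `frequency`, `s11`, `s21`, `s12`, `s22`; `write_touchstone()` returns
#'   `path` invisibly.
#' @examples
#' sp <- two_port_spectrum(c(1e6, 2e6, 3e6), c(0.5 + 0i, 0 + 0.5i, -0.5 + 0i))
#' f <- tempfile(fileext = ".s2p")
#' write_touchstone(sp, f)
#' read_touchstone(f)
#' @export
read_touchstone <- function(path) {
  lines <- readLines(path, warn = FALSE)
  unit_scale <- c(hz = 1, khz = 1e3, mhz = 1e6, ghz = 1e9)
  scale <- 1e9; fmt <- "MA"; z0 <- 50
  data_tokens <- character(0)
  for (i in seq_along(lines)) {
    line <- sub("!.*$", "", lines[i])
    line <- trimws(line)
    if (line == "") next
    if (startsWith(line, "#")) {
      toks <- strsplit(toupper(sub("^#", "", line)), "\\s+")[[1]]
      toks <- toks[toks != ""]
      j <- 1
      while (j <= length(toks)) {
        tk <- toks[j]
        if (tolower(tk) %in% names(unit_scale)) {
          scale <- unit_scale[[tolower(tk)]]
        } else if (tk == "S") {
          # parameter type: only scattering parameters supported
        } else if (tk %in% c("RI", "MA", "DB")) {
          fmt <- tk
        } else if (tk == "R" && j < length(toks)) {
          j <- j + 1
          z0 <- as.numeric(toks[j])
          if (is.na(z0)) abort(sprintf("line %d: bad reference impedance", i))
        } else if (tk %in% c("Y", "Z", "H", "G")) {
          abort(sprintf("line %d: only S-parameters are supported", i))
        }
        j <- j + 1
      }
      next
    }
    data_tokens <- c(data_tokens, strsplit(line, "[[:space:],]+")[[1]])
  }
  vals <- suppressWarnings(as.numeric(data_tokens))
  if (length(vals) == 0) abort("no data rows found")
  if (anyNA(vals)) abort("non-numeric token in data section")
  if (length(vals) %% 9 != 0)
    abort(sprintf("expected 9 values per two-port row, got %d values total",
                  length(vals)))
  m <- matrix(vals, ncol = 9, byrow = TRUE)
  f <- m[, 1] * scale
  decode <- function(a, b) {
    switch(fmt,
      RI = complex(real = a, imaginary = b),
      MA = complex(modulus = a, argument = b * pi / 180),
      DB = complex(modulus = 10^(a / 20), argument = b * pi / 180))
  }
  if (is.unsorted(f, strictly = TRUE))
    abort("frequency column must be strictly increasing")
  two_port_spectrum(f,
                    s21 = decode(m[, 4], m[, 5]),
                    s11 = decode(m[, 2], m[, 3]),
                    s12 = decode(m[, 6], m[, 7]),
                    s22 = decode(m[, 8], m[, 9]),
                    z0 = z0)
}

#' @rdname read_touchstone
#' @param spectrum An `lw_spectrum` (or data frame with `frequency`, `s21`).
#'   Missing `s11`/`s22` are written as `fill_reflection`; missing `s12` is
#'   mirrored from `s21` (a reciprocal passive delay line).
#' @param format One of `"RI"`, `"MA"`, `"DB"`.
#' @param frequency_unit One of `"Hz"`, `"kHz"`, `"MHz"`, `"GHz"`.
#' @param fill_reflection Complex constant written for absent reflection
#'   coefficients.
#' @export
write_touchstone <- function(spectrum, path, format = c("RI", "MA", "DB"),
                             frequency_unit = "MHz",
                             fill_reflection = 0 + 0i) {
  spectrum <- as_spectrum(spectrum)
  format <- arg_match(format)
  unit_scale <- c(Hz = 1, kHz = 1e3, MHz = 1e6, GHz = 1e9)
  if (!frequency_unit %in% names(unit_scale)) abort("bad frequency unit")
  z0 <- attr(spectrum, "z0") %||% 50
  n <- nrow(spectrum)
  fill <- rep(as.complex(fill_reflection), n)
  s11 <- spectrum[["s11"]] %||% fill
  s22 <- spectrum[["s22"]] %||% fill
  s12 <- spectrum[["s12"]] %||% spectrum$s21
  encode <- function(s) {
    switch(format,
      RI = cbind(Re(s), Im(s)),
      MA = cbind(abs(s), Arg(s) * 180 / pi),
      DB = cbind(20 * log10(pmax(abs(s), 1e-300)), Arg(s) * 180 / pi))
  }
  m <- cbind(spectrum$frequency / unit_scale[[frequency_unit]],
             encode(s11), encode(spectrum$s21), encode(s12), encode(s22))
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(
    "! Touchstone v1 two-port, written by the lovewave package",
    sprintf("# %s S %s R %g", frequency_unit, format, z0),
    rows
  ), path)
  invisible(path)
}
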