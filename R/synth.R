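# Synthetic-acquisition generator: emulates the VNA protocol (a spectrum
# every 10 s, 10-50 MHz span) over a programmed liquid schedule, so the
# gating and sensorgram stages can be exercised without measurements.

#' Synthesize one delay-line spectrum
#'
#' Composes the full device model for one loading liquid and dresses it with
#' the acquisition artefacts of a real measurement: an optional
#' triple-transit echo, a constant electromagnetic feedthrough floor, and
#' complex Gaussian noise. Deterministic for a given seed.
#'
#' @param design A [delay_line_design()].
#' @param stack_template [layer_stack()] whose top half-space is replaced by
#'   `liquid`.
#' @param liquid Top medium: a [material()] (vacuum for the air baseline).
#' @param f_start,f_stop,n_points Frequency grid (default 10–50 MHz,
#'   2001 points; the instrument protocol used 20,000, which gating does not
#'   require).
#' @param noise_sigma Standard deviation of the complex Gaussian noise added
#'   per frequency point (linear units; 0 disables).
#' @param feedthrough_db Level of the constant feedthrough floor in dB
#'   (`-Inf` disables).
#' @param r_tt Triple-transit reflection coefficient (0 disables).
#' @param seed Integer seed (required when noise is on).
#' @param time_s Timestamp attached to the spectrum.
#' @return An `lw_spectrum`.
#' @export
synth_spectrum <- function(design, stack_template, liquid,
                           f_start = 10e6, f_stop = 50e6, n_points = 2001,
                           noise_sigma = 0, feedthrough_db = -Inf,
                           r_tt = 0, seed = 1, time_s = NULL) {
  if (n_points < 16) abort("n_points must be at least 16")
  st <- stack_template
  st$top <- liquid
  f_grid <- seq(f_start, f_stop, length.out = n_points)
  sp <- delay_line_s21(design, st, f_grid)
  sp <- triple_transit(sp, r_tt)
  if (is.finite(feedthrough_db))
    sp$s21 <- sp$s21 + undb20(feedthrough_db)
  if (noise_sigma > 0) {
    if (is.null(seed)) abort("a seed is required for noisy synthesis")
    withr_seed(seed, {
      sp$s21 <- sp$s21 + complex(real = rnorm(n_points, sd = noise_sigma),
                                 imaginary = rnorm(n_points, sd = noise_sigma))
    })
  }
  attr(sp, "time_s") <- time_s
  sp
}

# evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Liquid schedule for a synthetic experiment
#'
#' A schedule is a tibble with a `start_s` column and a `liquid` list-column
#' of [material()] objects. `liquid_schedule()` builds one from start times
#' plus liquid specifications (materials, `"air"`, or viscosities in cP with
#' densities).
#'
#' @param start_s Start times in seconds (monotone increasing).
#' @param liquids List whose elements are [material()] objects or the string
#'   `"air"`.
#' @return A tibble with `start_s` and `liquid`.
#' @export
liquid_schedule <- function(start_s, liquids) {
  if (length(start_s) != length(liquids))
    abort("start_s and liquids must have equal length")
  if (is.unsorted(start_s, strictly = TRUE))
    abort("schedule start times must be strictly increasing")
  liquids <- lapply(liquids, function(l) {
    if (identical(l, "air")) vacuum_medium("air") else l
  })
  ok <- vapply(liquids, is_material, logical(1))
  if (!all(ok)) abort("liquids must be materials or \"air\"")
  tibble(start_s = start_s, liquid = liquids)
}

#' Synthesize a time series of spectra over a liquid schedule
#'
#' Emulates a step experiment: the chamber holds each scheduled liquid in
#' turn, and a spectrum is recorded every `sample_interval` seconds. The
#' change-over between liquids is modelled as first-order exponential mixing
#' of the (viscosity, density) pair with time constant `tau_mix`, which
#' reproduces the smooth settling seen in real step responses. Deterministic
#' for a given seed.
#'
#' @inheritParams synth_spectrum
#' @param schedule A [liquid_schedule()].
#' @param duration Total duration in seconds (default: last step start plus
#'   five mixing time constants).
#' @param sample_interval Seconds between spectra (default 10).
#' @param tau_mix Mixing time constant in seconds (default 30; 0 for
#'   instantaneous steps).
#' @return A tibble with columns `time_s` and `spectrum` (list-column of
#'   `lw_spectrum`), suitable for [build_sensorgram()].
#' @export
synth_series <- function(design, stack_template, schedule,
                         duration = NULL, sample_interval = 10,
                         tau_mix = 30,
                         f_start = 10e6, f_stop = 50e6, n_points = 2001,
                         noise_sigma = 0, feedthrough_db = -Inf, r_tt = 0,
                         seed = 1) {
  stopifnot(is.data.frame(schedule),
            all(c("start_s", "liquid") %in% names(schedule)))
  duration <- duration %||% (max(schedule$start_s) + 5 * max(tau_mix, sample_interval))
  times <- seq(0, duration, by = sample_interval)
  props <- function(m) {
    if (m$kind == "vacuum") c(eta = 0, rho = 0)
    else c(eta = m$eta, rho = m$rho)
  }
  liquid_at <- function(t) {
    idx <- max(which(schedule$start_s <= t))
    cur <- props(schedule$liquid[[idx]])
    if (idx > 1 && tau_mix > 0) {
      prev <- props(schedule$liquid[[idx - 1]])
      wmix <- 1 - exp(-(t - schedule$start_s[idx]) / tau_mix)
      cur <- wmix * cur + (1 - wmix) * prev
    }
    if (cur[["eta"]] <= 0 || cur[["rho"]] <= 0) return(vacuum_medium("air"))
    newtonian_liquid(sprintf("mix(%.3g cP)", pas_to_cp(cur[["eta"]])),
                     density = cur[["rho"]], viscosity = cur[["eta"]])
  }
  # plateau samples share a liquid: cache the noiseless spectrum per liquid
  cache <- new.env(parent = emptyenv())
  noiseless <- function(liquid) {
    key <- if (liquid$kind == "vacuum") "air"
           else sprintf("%.12g_%.12g", liquid$eta, liquid$rho)
    if (is.null(cache[[key]]))
      cache[[key]] <- synth_spectrum(design, stack_template, liquid,
                                     f_start = f_start, f_stop = f_stop,
                                     n_points = n_points, noise_sigma = 0,
                                     feedthrough_db = feedthrough_db,
                                     r_tt = r_tt, seed = seed)
    cache[[key]]
  }
  rows <- map(seq_along(times), function(i) {
    sp <- noiseless(liquid_at(times[i]))
    if (noise_sigma > 0) {
      withr_seed(seed + i, {
        sp$s21 <- sp$s21 + complex(real = rnorm(n_points, sd = noise_sigma),
                                   imaginary = rnorm(n_points, sd = noise_sigma))
      })
    }
    attr(sp, "time_s") <- times[i]
    tibble(time_s = times[i], spectrum = list(sp))
  })
  out <- list_rbind(rows)
  attr(out, "schedule") <- schedule
  class(out) <- c("lw_series", class(out))
  out
}

#' Write a synthetic series as timestamped Touchstone files
#'
#' Produces the directory layout of a real acquisition: one `.s2p` per
#' spectrum plus a `manifest.csv` with the timestamps and file names.
#'
#' @param series Output of [synth_series()].
#' @param dir Output directory (created if needed).
#' @param format Touchstone encoding passed to [write_touchstone()].
#' @return The manifest tibble, invisibly.
#' @export
write_series <- function(series, dir, format = "RI") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("spectrum_%06.0fs.s2p", series$time_s)
  for (i in seq_len(nrow(series)))
    write_touchstone(series$spectrum[[i]], file.path(dir, files[i]),
                     format = format)
  manifest <- tibble(time_s = series$time_s, file = files)
  write.table(manifest, file.path(dir, "manifest.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a series directory back into a spectrum table
#'
#' @param dir Directory containing a `manifest.csv` and `.s2p` files as
#'   written by [write_series()].
#' @return A tibble with `time_s` and `spectrum`, as [synth_series()].
#' @export
read_series <- function(dir) {
  manifest <- read.table(file.path(dir, "manifest.csv"), sep = ",",
                         header = TRUE, stringsAsFactors = FALSE)
  rows <- map(seq_len(nrow(manifest)), function(i) {
    sp <- read_touchstone(file.path(dir, manifest$file[i]))
    attr(sp, "time_s") <- manifest$time_s[i]
    tibble(time_s = manifest$time_s[i], spectrum = list(sp))
  })
  out <- list_rbind(rows)
  class(out) <- c("lw_series", class(out))
  out
}
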