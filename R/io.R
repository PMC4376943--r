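#' Read and write fNIRS recordings as CSV
#'
#' The on-disk recording format is a plain comma-separated file with a
#' mandatory header row: a `time_s` column with uniform `1/fs` steps, then
#' `ch<k>_hbo2` and `ch<k>_hhb` columns (concentrations in \eqn{\mu}mol/L)
#' for each channel `k`. Files may carry either the full montage or only the
#' active channels; columns for excluded channels are dropped on read, and
#' channel order always follows the montage. Decimal separator is `.`;
#' native acquisition-software formats are not parsed.
#'
#' @param path file path.
#' @param montage a \linkS4class{ChannelMontage}; columns for all active
#'   channels must be present.
#' @param fs expected sampling rate in Hz; the time column is validated
#'   against uniform `1/fs` steps.
#'
#' @return `readRecording()`: a \linkS4class{FnirsRecording}.
#' @examples
#' rec <- fnirsRecording(matrix(rnorm(64), 16), matrix(rnorm(64), 16))
#' f <- tempfile(fileext = ".csv")
#' writeRecording(rec, f)
#' rec2 <- readRecording(f)
#' stopifnot(identical(hbo2(rec), hbo2(rec2)))
#' @export
readRecording <- function(path, montage = channelMontage(), fs = 2.0) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("missing 'time_s' column")
  tm <- df$time_s
  if (length(tm) < 1L) stop("recording is empty")
  if (length(tm) > 1L) {
    steps <- diff(tm)
    if (any(abs(steps - 1 / fs) > 1e-6)) {
      stop(sprintf("non-uniform sampling: expected %.6g s steps", 1 / fs))
    }
  }
  act <- activeChannels(montage)
  for (sp in c("hbo2", "hhb")) {
    cols <- sprintf("ch%02d_%s", act, sp)
    alt <- sprintf("ch%d_%s", act, sp)
    miss <- !(cols %in% names(df)) & !(alt %in% names(df))
    if (any(miss)) {
      stop("missing channel column(s): ", paste(cols[miss], collapse = ", "))
    }
  }
  getcol <- function(ch, sp) {
    nm <- sprintf("ch%02d_%s", ch, sp)
    if (!nm %in% names(df)) nm <- sprintf("ch%d_%s", ch, sp)
    v <- df[[nm]]
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-finite value in column %s at data row %d", nm, bad[1L]))
    }
    v
  }
  hbo2 <- t(vapply(act, getcol, numeric(nrow(df)), sp = "hbo2"))
  hhb <- t(vapply(act, getcol, numeric(nrow(df)), sp = "hhb"))
  if (nrow(df) == 1L) {
    hbo2 <- matrix(hbo2, nrow = length(act))
    hhb <- matrix(hhb, nrow = length(act))
  }
  fnirsRecording(hbo2, hhb, montage = montage, fs = fs, t0 = tm[1L])
}

#' @rdname readRecording
#' @param rec a \linkS4class{FnirsRecording}.
#' @return `writeRecording()`: `path`, invisibly.
#' @export
writeRecording <- function(rec, path) {
  act <- activeChannels(rec)
  df <- data.frame(time_s = fmtNum(timePoints(rec)), check.names = FALSE)
  h <- hbo2(rec); d <- hhb(rec)
  for (i in seq_along(act)) {
    df[[sprintf("ch%02d_hbo2", act[i])]] <- fmtNum(h[i, ])
    df[[sprintf("ch%02d_hhb", act[i])]] <- fmtNum(d[i, ])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# shortest decimal representation that round-trips the double exactly
fmtNum <- function(x) {
  out <- sprintf("%.15g", x)
  bad <- as.numeric(out) != x
  out[bad] <- sprintf("%.17g", x[bad])
  out
}

#' Read and write event schedules as CSV
#'
#' Events CSV columns: `onset_s`, `message_dur_s`, `response_dur_s`,
#' `load` (`low`/`high`), one row per trial.
#'
#' @param path file path.
#' @return `readEvents()`: an \linkS4class{EventSchedule}.
#' @examples
#' sched <- eventSchedule(c(20, 70), c("low", "high"))
#' f <- tempfile(fileext = ".csv")
#' writeEvents(sched, f)
#' identical(trials(readEvents(f)), trials(sched))
#' @export
readEvents <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    onset_s = "numeric", message_dur_s = "numeric",
    response_dur_s = "numeric", load = "character"
  ))
  bad <- setdiff(unique(df$load), c("low", "high"))
  if (length(bad)) {
    stop("unknown load label: ", paste(bad, collapse = ", "))
  }
  eventSchedule(df$onset_s, df$load, df$message_dur_s, df$response_dur_s)
}

#' @rdname readEvents
#' @param schedule an \linkS4class{EventSchedule}.
#' @return `writeEvents()`: `path`, invisibly.
#' @export
writeEvents <- function(schedule, path) {
  tr <- trials(schedule)
  for (col in c("onset_s", "message_dur_s", "response_dur_s")) {
    tr[[col]] <- fmtNum(tr[[col]])
  }
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a chronogram as a two-column CSV
#'
#' @param cg a \linkS4class{Chronogram}.
#' @param path file path.
#' @return `path`, invisibly. Columns: `time_s`, `state` (0/1).
#' @export
writeChronogram <- function(cg, path) {
  utils::write.csv(
    data.frame(time_s = timePoints(cg), state = as.integer(states(cg))),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Default hemoglobin extinction coefficients
#'
#' Molar extinction coefficients of oxygenated and deoxygenated hemoglobin
#' at 730 and 850 nm, in \eqn{mM^{-1} cm^{-1}}, from standard published
#' in-vitro tables. Rows are wavelengths, columns are species
#' (HbO2, hHb). These are documented, overridable defaults: device firmware
#' may use different constants.
#'
#' @return 2x2 numeric matrix with dimnames.
#' @export
defaultExtinction <- function() {
  matrix(c(0.390, 1.102,
           1.058, 0.691),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("730", "850"), c("HbO2", "hHb")))
}

#' Raw two-wavelength intensity recording
#'
#' Container for raw detected light intensities of a continuous-wave fNIRS
#' device, prior to conversion to concentration changes.
#'
#' @param intensities list of two numeric matrices (channels x samples),
#'   named by wavelength (`"730"`, `"850"`), of detected intensities.
#' @param baseline numeric matrix (channels x wavelengths) of baseline
#'   intensities \eqn{I_0}.
#' @param fs sampling rate in Hz.
#' @param wavelengths the two wavelengths in nm.
#' @param separation_cm source-detector separation in cm (2.5 for a 25 mm
#'   optode spacing).
#' @param dpf differential pathlength factor per wavelength (default 6.0 at
#'   both; overridable, the appropriate value is device- and age-dependent).
#' @param extinction 2x2 extinction-coefficient matrix, wavelengths x
#'   (HbO2, hHb), in \eqn{mM^{-1} cm^{-1}}.
#' @param montage a \linkS4class{ChannelMontage}.
#'
#' @return A list of class `"RawIntensityRecording"`.
#' @seealso [beerLambertConvert()]
#' @export
rawIntensityRecording <- function(intensities, baseline, fs = 2.0,
                                  wavelengths = c(730, 850),
                                  separation_cm = 2.5,
                                  dpf = c(6.0, 6.0),
                                  extinction = defaultExtinction(),
                                  montage = channelMontage()) {
  if (length(intensities) != 2L) stop("two wavelengths required")
  if (length(wavelengths) != 2L || length(dpf) != 2L) {
    stop("two wavelengths required")
  }
  for (m in intensities) {
    if (any(!is.finite(m)) || any(m <= 0)) {
      stop("intensities must be positive and finite")
    }
  }
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stop("baseline intensities must be positive and finite")
  }
  structure(
    list(intensities = intensities, baseline = as.matrix(baseline),
         fs = fs, wavelengths = wavelengths,
         separation_cm = separation_cm, dpf = dpf,
         extinction = as.matrix(extinction), montage = montage),
    class = "RawIntensityRecording"
  )
}

#' Modified Beer-Lambert conversion of raw intensities
#'
#' Converts raw two-wavelength intensities to oxygenated and deoxygenated
#' hemoglobin concentration changes via the modified Beer-Lambert law. Per
#' channel and sample, the optical-density change at each wavelength is
#' \deqn{\Delta OD_\lambda(t) = -\log_{10}(I_\lambda(t)/I_{\lambda,0}),}
#' and the 2x2 linear system
#' \deqn{\Delta OD_\lambda = (\epsilon_{HbO_2,\lambda}\,\Delta[HbO_2] +
#'   \epsilon_{hHb,\lambda}\,\Delta[hHb])\; d\; DPF_\lambda}
#' is solved for the two concentration changes (\eqn{d} = source-detector
#' separation, \eqn{DPF} = differential pathlength factor). Concentrations
#' are returned in \eqn{\mu}mol/L.
#'
#' @param raw a [rawIntensityRecording()].
#' @return A \linkS4class{FnirsRecording} (excluded channels dropped).
#' @examples
#' I0 <- matrix(100, nrow = 16, ncol = 2)
#' I <- list("730" = matrix(100, 16, 5), "850" = matrix(100, 16, 5))
#' raw <- rawIntensityRecording(I, I0)
#' rec <- beerLambertConvert(raw)
#' all(hbo2(rec) == 0)  # no intensity change, no concentration change
#' @export
beerLambertConvert <- function(raw) {
  stopifnot(inherits(raw, "RawIntensityRecording"))
  E <- raw$extinction
  A <- diag(raw$dpf) %*% E * raw$separation_cm
  if (abs(det(A)) < 1e-12) stop("singular extinction matrix")
  Ainv <- solve(A)
  nch <- nrow(raw$intensities[[1L]])
  ns <- ncol(raw$intensities[[1L]])
  hbo2 <- matrix(0, nch, ns)
  hhb <- matrix(0, nch, ns)
  for (ch in seq_len(nch)) {
    od <- rbind(
      -log10(raw$intensities[[1L]][ch, ] / raw$baseline[ch, 1L]),
      -log10(raw$intensities[[2L]][ch, ] / raw$baseline[ch, 2L])
    )
    conc <- Ainv %*% od  # mM, rows (HbO2, hHb)
    hbo2[ch, ] <- conc[1L, ] * 1000
    hhb[ch, ] <- conc[2L, ] * 1000
  }
  fnirsRecording(hbo2, hhb, montage = raw$montage, fs = raw$fs)
}

#' Read a flat key-value configuration file
#'
#' Configuration files are flat YAML mappings (key: value). Recognized keys
#' are any argument of [simulationConfig()] plus the IO constants
#' (`dpf`, `separation_cm`, `excluded_channels`). Unknown keys are kept and
#' passed through.
#'
#' @param path YAML file path.
#' @return named list of settings.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key-value mapping")
  cfg
}
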