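# Synthetic MRS layer: FID datasets, a canonical text format whose
# serialization is byte-stable (so identical data always hash identically),
# deterministic preprocessing operators and a transparent linear
# least-squares quantitation. These exist to exercise the tracker
# end-to-end; they are not scanner-format readers or a clinical fitter.

#' Construct a FID dataset
#'
#' A free induction decay: complex time-domain samples plus the minimal
#' acquisition metadata needed for frequency math.
#'
#' @param points Complex vector of samples (non-empty).
#' @param sampling_interval_ms Dwell time in milliseconds (> 0).
#' @param transmitter_frequency_mhz Transmitter frequency in MHz.
#' @param label Free-text label.
#' @return A `fid_dataset` object.
#' @export
fid_dataset <- function(points, sampling_interval_ms,
                        transmitter_frequency_mhz = 123.25,
                        label = "fid") {
  points <- as.complex(points)
  if (length(points) == 0L)
    st_validation("a FID must contain at least one point")
  if (!is.numeric(sampling_interval_ms) || sampling_interval_ms <= 0)
    st_validation("sampling_interval_ms must be positive")
  structure(
    list(points = points,
         sampling_interval_ms = as.numeric(sampling_interval_ms),
         transmitter_frequency_mhz = as.numeric(transmitter_frequency_mhz),
         label = as.character(label)[1]),
    class = "fid_dataset")
}

#' @export
print.fid_dataset <- function(x, ...) {
  cat(sprintf("<fid_dataset '%s': %d points, dwell %g ms, %g MHz>\n",
              x$label, length(x$points), x$sampling_interval_ms,
              x$transmitter_frequency_mhz))
  invisible(x)
}

# Time axis in seconds: t_k = k * dwell, k from 0.
fid_time_axis <- function(n_points, sampling_interval_ms) {
  (seq_len(n_points) - 1) * sampling_interval_ms / 1000
}

# Basis signal matrix: column m is exp((2i*pi*f_m - d_m) * t).
basis_matrix <- function(basis, t) {
  vapply(seq_len(nrow(basis)), function(m)
    exp((2i * pi * basis$frequency_hz[m] - basis$damping_hz[m]) * t),
    complex(length(t)))
}

#' Define a metabolite basis set
#'
#' Each basis entry is a damped complex exponential: a frequency offset
#' (Hz, relative to the carrier) and a Lorentzian damping rate (Hz).
#'
#' @param name Unique metabolite names.
#' @param frequency_hz Frequency offsets in Hz.
#' @param damping_hz Non-negative damping rates in Hz.
#' @return A data.frame with one row per metabolite.
#' @export
metabolite_basis <- function(name, frequency_hz, damping_hz) {
  if (anyDuplicated(name))
    st_validation("metabolite names must be unique")
  if (any(damping_hz < 0))
    st_validation("damping rates must be non-negative")
  data.frame(name = as.character(name),
             frequency_hz = as.numeric(frequency_hz),
             damping_hz = as.numeric(damping_hz))
}

#' Simulate a FID from a metabolite basis
#'
#' Samples `s(t_k) = sum_m a_m * exp((2i*pi*f_m - d_m) * t_k)` plus
#' independent complex Gaussian noise of standard deviation `noise_sd`
#' per component. With a fixed `seed` the result — and hence its
#' serialized bytes and content hash — is fully deterministic.
#'
#' @param basis A [metabolite_basis()] data.frame.
#' @param amplitudes Numeric vector, one amplitude per basis entry.
#' @param n_points Number of samples (>= 2).
#' @param sampling_interval_ms Dwell time in ms.
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed RNG seed; required when `noise_sd > 0`.
#' @param transmitter_frequency_mhz Carrier frequency in MHz.
#' @param label Dataset label.
#' @return A [fid_dataset()].
#' @export
generate_fid <- function(basis, amplitudes, n_points = 512,
                         sampling_interval_ms = 0.4, noise_sd = 0,
                         seed = NULL, transmitter_frequency_mhz = 123.25,
                         label = "synthetic") {
  if (length(amplitudes) != nrow(basis))
    st_validation("need exactly one amplitude per basis entry (%d vs %d)",
                  length(amplitudes), nrow(basis))
  if (n_points < 2L) st_validation("n_points must be at least 2")
  if (noise_sd < 0) st_validation("noise_sd must be non-negative")
  t <- fid_time_axis(n_points, sampling_interval_ms)
  s <- as.complex(basis_matrix(basis, t) %*% as.numeric(amplitudes))
  if (noise_sd > 0) {
    if (is.null(seed))
      st_validation("a seed is required for noisy simulation")
    noise <- withr::with_seed(as.integer(seed), {
      complex(real = stats::rnorm(n_points, sd = noise_sd),
              imaginary = stats::rnorm(n_points, sd = noise_sd))
    })
    s <- s + noise
  }
  fid_dataset(s, sampling_interval_ms, transmitter_frequency_mhz, label)
}

# Canonical number rendering: 17 significant digits, lowercase scientific
# notation — enough for exact double round-trip, and byte-stable across
# runs, which the content-addressing of data files relies on.
fmt_num <- function(x) sprintf("%.16e", x)

#' Write a FID dataset in the canonical text format
#'
#' Format: header `SpectraTrack FID v1`, the metadata lines
#' `PointsInDataset`, `SamplingInterval_ms`, `TransmitterFrequency_MHz`,
#' `Label`, then `Data:` followed by one `real<TAB>imag` line per point.
#' Numbers are written with 17 significant digits in scientific notation,
#' UTF-8, `"\n"` line endings — writing the same dataset twice yields
#' byte-identical files (and therefore identical SHA-256 hashes).
#'
#' @param dataset A [fid_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fid <- function(dataset, path) {
  if (!inherits(dataset, "fid_dataset"))
    st_validation("not a fid_dataset")
  lines <- c(
    "SpectraTrack FID v1",
    sprintf("PointsInDataset: %d", length(dataset$points)),
    sprintf("SamplingInterval_ms: %s", fmt_num(dataset$sampling_interval_ms)),
    sprintf("TransmitterFrequency_MHz: %s",
            fmt_num(dataset$transmitter_frequency_mhz)),
    sprintf("Label: %s", dataset$label),
    "Data:",
    sprintf("%s\t%s", fmt_num(Re(dataset$points)),
            fmt_num(Im(dataset$points))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

fid_header_field <- function(lines, k, key, path) {
  if (length(lines) < k || !startsWith(lines[k], paste0(key, ": ")))
    st_parse("%s: expected '%s:' header at line %d", path, key, k)
  sub(paste0("^", key, ": "), "", lines[k])
}

#' Read a FID dataset from the canonical text format
#'
#' @param path File to read.
#' @return A [fid_dataset()].
#' @export
read_fid <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    st_io("cannot read FID file '%s'", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L || lines[1] != "SpectraTrack FID v1")
    st_parse("%s: not a SpectraTrack FID file (bad header at line 1)", path)
  n <- suppressWarnings(
    as.integer(fid_header_field(lines, 2, "PointsInDataset", path)))
  dt <- suppressWarnings(
    as.numeric(fid_header_field(lines, 3, "SamplingInterval_ms", path)))
  tf <- suppressWarnings(
    as.numeric(fid_header_field(lines, 4, "TransmitterFrequency_MHz", path)))
  label <- fid_header_field(lines, 5, "Label", path)
  if (is.na(n) || is.na(dt) || is.na(tf))
    st_parse("%s: malformed numeric header field", path)
  if (length(lines) < 6L || lines[6] != "Data:")
    st_parse("%s: expected 'Data:' at line 6", path)
  data_lines <- lines[-(1:6)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (length(data_lines) != n)
    st_parse("%s: expected %d data lines, found %d (file truncated?)",
             path, n, length(data_lines))
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    st_parse("%s: malformed data line %d", path, 6L + bad[1])
  re <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  im <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  if (anyNA(re) || anyNA(im))
    st_parse("%s: non-numeric data at line %d",
             path, 6L + which(is.na(re) | is.na(im))[1])
  fid_dataset(complex(real = re, imaginary = im), dt, tf, label)
}

#' Write / read a metabolite basis file (.ml)
#'
#' One `name<TAB>frequency_Hz<TAB>damping_Hz` line per metabolite.
#'
#' @param basis A [metabolite_basis()] data.frame.
#' @param path File path.
#' @return `write_basis`: `path`, invisibly. `read_basis`: the basis
#'   data.frame.
#' @export
write_basis <- function(basis, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%s\t%s\t%s", basis$name, fmt_num(basis$frequency_hz),
                     fmt_num(basis$damping_hz)),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  if (!file.exists(path)) st_io("cannot read basis file '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    st_validation("basis file '%s' is empty", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    st_parse("%s: malformed basis line %d", path, bad[1])
  metabolite_basis(
    vapply(parts, `[`, "", 1),
    as.numeric(vapply(parts, `[`, "", 2)),
    as.numeric(vapply(parts, `[`, "", 3)))
}

#' Write / read a processing-options file (.op)
#'
#' Plain `key: value` lines. The quantitation recognizes
#' `ZeroOrderPhase_deg`, the zero-order phase (degrees) applied to the
#' data before fitting.
#'
#' @param options Named list of scalar options.
#' @param path File path.
#' @return `write_options`: `path`, invisibly. `read_options`: named list
#'   of character values.
#' @export
write_options <- function(options, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%s: %s", names(options),
                     vapply(options, as.character, "")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_options
#' @export
read_options <- function(path) {
  if (!file.exists(path)) st_io("cannot read options file '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  m <- regexpr(": ", lines, fixed = TRUE)
  if (any(m < 0))
    st_parse("%s: malformed option line %d", path, which(m < 0)[1])
  vals <- as.list(substr(lines, m + 2, nchar(lines)))
  names(vals) <- substr(lines, 1, m - 1)
  vals
}

#' Apply one tracked preprocessing operator to a FID
#'
#' The deterministic operator set: `ZERO_FILL` appends zeros up to a
#' target length; `APODIZE` multiplies by the exponential window
#' `exp(-pi * lb * t)` (line broadening `lb` in Hz); `PHASE0` multiplies
#' by `exp(i * phi)` (zero-order phase in degrees); `SCALE` multiplies by
#' a non-zero factor. Besides the transformed dataset, the operator emits
#' the [provenance_entry()] describing itself — one parameter per
#' signature slot, with units in the description — ready for
#' [record_action()].
#'
#' @param key One of `"ZERO_FILL"`, `"APODIZE"`, `"PHASE0"`, `"SCALE"`.
#' @param dataset A [fid_dataset()].
#' @param params List of parameter values, positional per the signature.
#' @return List with `dataset` (transformed) and `entry`
#'   (the provenance entry).
#' @export
apply_processing <- function(key, dataset, params) {
  if (!inherits(dataset, "fid_dataset"))
    st_validation("not a fid_dataset")
  if (!is.list(params)) params <- as.list(params)
  sig <- plugin_signature(key)   # validates the key
  if (length(params) != length(sig))
    st_validation("%s expects %d parameter(s), got %d",
                  key, length(sig), length(params))
  t <- fid_time_axis(length(dataset$points), dataset$sampling_interval_ms)
  v1 <- suppressWarnings(as.numeric(params[[1]]))
  if (is.na(v1)) st_validation("%s: parameter must be numeric", key)
  out <- switch(
    key,
    ZERO_FILL = {
      n_target <- as.integer(v1)
      if (n_target < length(dataset$points))
        st_validation("ZERO_FILL target %d is below current length %d",
                      n_target, length(dataset$points))
      fid_dataset(c(dataset$points,
                    complex(n_target - length(dataset$points))),
                  dataset$sampling_interval_ms,
                  dataset$transmitter_frequency_mhz, dataset$label)
    },
    APODIZE = {
      if (v1 < 0) st_validation("APODIZE line broadening must be >= 0 Hz")
      fid_dataset(dataset$points * exp(-pi * v1 * t),
                  dataset$sampling_interval_ms,
                  dataset$transmitter_frequency_mhz, dataset$label)
    },
    PHASE0 = {
      fid_dataset(dataset$points * exp(1i * v1 * pi / 180),
                  dataset$sampling_interval_ms,
                  dataset$transmitter_frequency_mhz, dataset$label)
    },
    SCALE = {
      if (v1 == 0) st_validation("SCALE factor must be non-zero")
      fid_dataset(dataset$points * v1,
                  dataset$sampling_interval_ms,
                  dataset$transmitter_frequency_mhz, dataset$label)
    })
  entry <- provenance_entry(
    key,
    params = list(param_spec(format(v1), sig[[1]]$description)))
  list(dataset = out, entry = entry)
}

#' Mock metabolite quantitation by linear least squares
#'
#' Fits the observed FID as a linear combination of the basis signals
#' `exp((2i*pi*f_m - d_m) * t)` after applying the zero-order phase given
#' in the options file, and reports the real parts of the complex
#' least-squares amplitudes. On a noiseless FID generated from the same
#' basis this recovers the generating amplitudes exactly (to numerical
#' precision). The result is written as `name<TAB>amplitude` lines; the
#' emitted provenance entry carries the two file parameters (basis set and
#' options) with the quantitation flag set.
#'
#' @param dataset A [fid_dataset()].
#' @param basis_file_path Path to a `.ml` basis file.
#' @param options_file_path Path to a `.op` options file.
#' @param out_path Where to write the result file; defaults to
#'   `<label>_QUANT.results` in the basis file's directory.
#' @return List with `result_path`, `entry` (quantitation
#'   [provenance_entry()]), `amplitudes` (named numeric) and
#'   `residual_norm`.
#' @export
mock_quantitation <- function(dataset, basis_file_path, options_file_path,
                              out_path = NULL) {
  if (!inherits(dataset, "fid_dataset"))
    st_validation("not a fid_dataset")
  basis <- read_basis(basis_file_path)
  opts <- read_options(options_file_path)
  phase_deg <- if (!is.null(opts$ZeroOrderPhase_deg))
    as.numeric(opts$ZeroOrderPhase_deg) else 0
  s <- dataset$points * exp(1i * phase_deg * pi / 180)
  t <- fid_time_axis(length(s), dataset$sampling_interval_ms)
  B <- basis_matrix(basis, t)
  sv <- svd(B, nu = 0, nv = 0)$d
  if (min(sv) < max(sv) * 1e-10)
    st_estimation("singular basis design (duplicate basis entries?)")
  a <- qr.solve(B, s)
  amplitudes <- stats::setNames(Re(a), basis$name)
  residual_norm <- sqrt(sum(Mod(s - B %*% a)^2))
  if (is.null(out_path))
    out_path <- file.path(dirname(basis_file_path),
                          paste0(dataset$label, "_QUANT.results"))
  con <- file(out_path, open = "wb")
  writeLines(sprintf("%s\t%s", basis$name, fmt_num(amplitudes)),
             con, sep = "\n", useBytes = TRUE)
  close(con)
  entry <- provenance_entry(
    "QUANTIFY_LLS",
    params = list(
      param_spec(basis_file_path, "Metabolite basis set file (.ml)",
                 is_file = TRUE),
      param_spec(options_file_path, "Processing options file (.op)",
                 is_file = TRUE)),
    is_quantitation = TRUE,
    result_path = out_path,
    result_description = "linear least-squares amplitude estimates")
  list(result_path = out_path, entry = entry,
       amplitudes = amplitudes, residual_norm = residual_norm)
}
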