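test_that("simulated FIDs follow the damped-exponential model", {
  # single component, no damping, no noise: constant unit signal
  b <- metabolite_basis("X", 0, 0)
  fid <- generate_fid(b, 1, n_points = 32, sampling_interval_ms = 1)
  expect_equal(fid$points, rep(complex(real = 1), 32))

  # damping makes the envelope strictly decreasing
  b2 <- metabolite_basis("X", 25, 10)
  fid2 <- generate_fid(b2, 1, n_points = 64, sampling_interval_ms = 1)
  expect_true(all(diff(Mod(fid2$points)) < 0))

  # spot-check the closed form at an arbitrary sample
  t5 <- 4 * 1e-3
  expect_equal(fid2$points[5], exp((2i * pi * 25 - 10) * t5))

  expect_error(generate_fid(b, c(1, 2), n_points = 8),
               class = "spectratrack_validation_error")
  expect_error(generate_fid(b, 1, n_points = 8, noise_sd = 0.1),
               class = "spectratrack_validation_error")  # noise needs a seed
})

test_that("the canonical FID format round-trips and hashes stably", {
  fid <- tiny_fid(noise_sd = 0.05, seed = 3)
  p1 <- withr::local_tempfile(fileext = ".fid")
  p2 <- withr::local_tempfile(fileext = ".fid")

  write_fid(fid, p1)
  back <- read_fid(p1)
  expect_equal(back$points, fid$points)
  expect_equal(back$sampling_interval_ms, fid$sampling_interval_ms)
  expect_equal(back$transmitter_frequency_mhz,
               fid$transmitter_frequency_mhz)
  expect_equal(back$label, fid$label)

  # write -> read -> write is byte-identical; same seed, same bytes
  write_fid(back, p2)
  expect_identical(compute_file_hash(p1), compute_file_hash(p2))
  p3 <- withr::local_tempfile(fileext = ".fid")
  write_fid(tiny_fid(noise_sd = 0.05, seed = 3), p3)
  expect_identical(compute_file_hash(p1), compute_file_hash(p3))

  # malformed inputs are rejected with a line reference
  lines <- readLines(p1)
  bad <- local_text_file(lines[1:10])  # truncated data section
  err <- expect_error(read_fid(bad), class = "spectratrack_parse_error")
  expect_match(conditionMessage(err), "truncated")
  bad2 <- local_text_file(c("wrong header", lines[-1]))
  expect_error(read_fid(bad2), class = "spectratrack_parse_error")
})

test_that("preprocessing operators implement their stated transforms", {
  fid <- tiny_fid(noise_sd = 0.02, seed = 9)
  t <- (seq_along(fid$points) - 1) * fid$sampling_interval_ms / 1000

  # PHASE0: 0 degrees is the identity; 180 twice recovers the input
  expect_equal(apply_processing("PHASE0", fid, list(0))$dataset$points,
               fid$points)
  twice <- apply_processing(
    "PHASE0", apply_processing("PHASE0", fid, list(180))$dataset, list(180))
  expect_equal(twice$dataset$points, fid$points)

  # ZERO_FILL: prefix untouched, tail exactly zero
  zf <- apply_processing("ZERO_FILL", fid, list(128))$dataset
  expect_length(zf$points, 128L)
  expect_identical(zf$points[seq_along(fid$points)], fid$points)
  expect_true(all(zf$points[-seq_along(fid$points)] == 0))

  # APODIZE: multiplies by exp(-pi * lb * t)
  ap <- apply_processing("APODIZE", fid, list(3))$dataset
  expect_equal(ap$points, fid$points * exp(-pi * 3 * t))

  # SCALE
  sc <- apply_processing("SCALE", fid, list(-2))$dataset
  expect_equal(sc$points, fid$points * -2)

  # every emitted entry matches its signature and carries descriptions
  for (key in c("ZERO_FILL", "APODIZE", "PHASE0", "SCALE")) {
    out <- apply_processing(key, fid, list(if (key == "ZERO_FILL") 128 else 1))
    expect_equal(out$entry$action, key)
    expect_length(out$entry$params, 1L)
    expect_true(nzchar(out$entry$params[[1]]$description))
  }

  expect_error(apply_processing("ZERO_FILL", fid, list(8)),
               class = "spectratrack_validation_error")
  expect_error(apply_processing("APODIZE", fid, list(-1)),
               class = "spectratrack_validation_error")
  expect_error(apply_processing("SCALE", fid, list(0)),
               class = "spectratrack_validation_error")
})

test_that("basis and options files round-trip through their text formats", {
  basis <- tiny_basis()
  ml <- withr::local_tempfile(fileext = ".ml")
  write_basis(basis, ml)
  expect_equal(read_basis(ml), basis)

  op <- withr::local_tempfile(fileext = ".op")
  write_options(list(ZeroOrderPhase_deg = -30), op)
  expect_equal(read_options(op), list(ZeroOrderPhase_deg = "-30"))

  expect_error(read_basis(local_text_file(character(0))),
               class = "spectratrack_validation_error")
})

test_that("noiseless quantitation recovers the generating amplitudes", {
  basis <- tiny_basis()
  truth <- c(2.0, 0.5)
  fid <- generate_fid(basis, truth, n_points = 512,
                      sampling_interval_ms = 1)
  ml <- withr::local_tempfile(fileext = ".ml")
  op <- withr::local_tempfile(fileext = ".op")
  write_basis(basis, ml)
  write_options(list(ZeroOrderPhase_deg = 0), op)

  q <- mock_quantitation(fid, ml, op,
                         out_path = withr::local_tempfile(fileext = ".results"))
  expect_lt(max(abs(q$amplitudes - truth) / truth), 1e-9)
  expect_lt(q$residual_norm, 1e-9)

  # the result file holds exactly one amplitude per basis entry
  lines <- readLines(q$result_path)
  expect_length(lines, nrow(basis))
  expect_equal(vapply(strsplit(lines, "\t"), `[`, "", 1), basis$name)

  # phase applied before fitting undoes a zero-order phase on the data
  phased <- apply_processing("PHASE0", fid, list(30))$dataset
  op2 <- withr::local_tempfile(fileext = ".op")
  write_options(list(ZeroOrderPhase_deg = -30), op2)
  q2 <- mock_quantitation(phased, ml, op2,
                          out_path = withr::local_tempfile(fileext = ".results"))
  expect_lt(max(abs(q2$amplitudes - truth) / truth), 1e-9)
})

test_that("noisy estimates agree with an independent normal-equations solve", {
  basis <- tiny_basis()
  truth <- c(2.0, 0.5)
  fid <- generate_fid(basis, truth, n_points = 512,
                      sampling_interval_ms = 1, noise_sd = 0.01, seed = 17)
  ml <- withr::local_tempfile(fileext = ".ml")
  op <- withr::local_tempfile(fileext = ".op")
  write_basis(basis, ml)
  write_options(list(ZeroOrderPhase_deg = 0), op)
  q <- mock_quantitation(fid, ml, op,
                         out_path = withr::local_tempfile(fileext = ".results"))

  # oracle: complex normal equations B^H B a = B^H s, solved directly
  t <- (seq_along(fid$points) - 1) * fid$sampling_interval_ms / 1000
  B <- vapply(seq_len(nrow(basis)), function(m)
    exp((2i * pi * basis$frequency_hz[m] - basis$damping_hz[m]) * t),
    complex(length(t)))
  a_oracle <- Re(solve(Conj(t(B)) %*% B, Conj(t(B)) %*% fid$points))
  expect_lt(max(abs(q$amplitudes - a_oracle)), 1e-9)

  # degenerate designs are refused
  dup <- metabolite_basis(c("A", "B"), c(10, 10), c(5, 5))
  ml2 <- withr::local_tempfile(fileext = ".ml")
  write_basis(dup, ml2)
  expect_error(mock_quantitation(fid, ml2, op),
               class = "spectratrack_estimation_error")
})

test_that("the demo session writes the expected provenance footprint", {
  demo <- local_demo(seed = 5)
  rc <- demo$row_counts
  expect_equal(unname(rc["FILES"]), 2L)          # original + saved child
  expect_equal(unname(rc["RESULTS"]), 1L)
  expect_equal(unname(rc["ACTIONS"]), 5L)        # load, 2 ops, quant, save
  expect_equal(unname(rc["MACRO_contents"]), 3L)
  expect_equal(file_record(demo$store, demo$id_file_saved)$child,
               demo$id_file_original)

  # same seed into fresh stores: all content files identical; the rendered
  # history matches up to the recorded wall-clock timestamps
  demo2 <- local_demo(seed = 5)
  not_batch <- demo$manifest$role != "batch"
  expect_identical(demo2$manifest$hash[not_batch],
                   demo$manifest$hash[not_batch])
  # ... i.e. identical once timestamps and run-local file paths are masked
  stable_fields <- function(demo) {
    txt <- render_batch(actions_for_file(demo$store, demo$id_file_original))
    lines <- strsplit(txt, "\n")[[1]]
    lines <- gsub("^(ACTION \\S+) .*$", "\\1", lines)
    gsub("= \\S+ (HASH [0-9a-f]{64})$", "= <path> \\1", lines)
  }
  expect_identical(stable_fields(demo2), stable_fields(demo))

  # different noise seed: different data, same schema footprint
  demo3 <- local_demo(seed = 6)
  expect_false(demo3$original_hash == demo$original_hash)
  expect_identical(demo3$row_counts, demo$row_counts)
})

test_that("the command-line interface drives a tracked session end to end", {
  dir <- withr::local_tempdir()
  store_dir <- file.path(dir, "store")

  expect_equal(spectratrack_cli(c("init", "--store", store_dir)), 0L)

  fid_path <- file.path(dir, "cli.fid")
  write_fid(tiny_fid(), fid_path)
  out <- capture.output(
    status <- spectratrack_cli(c("load", "--store", store_dir, fid_path)))
  expect_equal(status, 0L)
  expect_match(out[1], "^ID_file\t1$")

  out_path <- file.path(dir, "cli_proc.fid")
  status <- spectratrack_cli(c("run", "APODIZE", "--store", store_dir,
                               "--in", fid_path, "--out", out_path,
                               "--param", "2"))
  expect_equal(status, 0L)
  expect_true(file.exists(out_path))

  hist <- capture.output(
    spectratrack_cli(c("history", "--store", store_dir,
                       "--file", out_path, "--mode", "parents")))
  expect_match(hist, "ACTION APODIZE", all = FALSE)

  # errors exit non-zero instead of throwing
  expect_equal(suppressMessages(
    spectratrack_cli(c("history", "--store", store_dir,
                       "--file", "missing.fid"))), 1L)
})
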