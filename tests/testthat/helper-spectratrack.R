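# Shared fixtures: every store, registry and data file is built in code
# inside a temporary directory and cleaned up with the test.

local_store <- function(env = parent.frame(), ...) {
  dir <- withr::local_tempdir(.local_envir = env)
  store <- init_store(file.path(dir, "store"), ...)
  withr::defer(close_store(store), envir = env)
  store
}

local_text_file <- function(lines, ext = ".txt", env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = env)
  writeLines(lines, path)
  path
}

tiny_basis <- function() {
  metabolite_basis(name = c("A", "B"),
                   frequency_hz = c(-50, 40),
                   damping_hz = c(5, 3))
}

tiny_fid <- function(amplitudes = c(2, 0.5), noise_sd = 0, seed = NULL,
                     n_points = 64) {
  generate_fid(tiny_basis(), amplitudes, n_points = n_points,
               sampling_interval_ms = 1, noise_sd = noise_sd, seed = seed,
               label = "tiny")
}

last_action_id <- function(store) {
  as.integer(DBI::dbGetQuery(
    store$con, "SELECT MAX(ID_action) AS id FROM ACTIONS")$id)
}

# One recorded preprocessing action with a single numeric parameter.
record_simple_op <- function(store, registry, id_file, key = "APODIZE",
                             value = 2) {
  entry <- provenance_entry(
    key, params = list(param_spec(format(value), "Line broadening [Hz]")))
  record_action(store, registry, entry, id_file)
}

local_demo <- function(seed = 42, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  demo <- run_demo_session(file.path(dir, "store"), file.path(dir, "work"),
                           seed = seed)
  withr::defer(close_store(demo$store), envir = env)
  demo
}

unzip_bundle <- function(bundle_path, env = parent.frame()) {
  out <- withr::local_tempdir(.local_envir = env)
  utils::unzip(bundle_path, exdir = out)
  out
}
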