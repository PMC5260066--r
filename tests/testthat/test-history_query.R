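# Builds sessions step by step while keeping an independent ledger of what
# was inserted, then checks the query paths against that ledger.

test_that("per-file history lists load, ops and save in link order", {
  store <- local_store()
  reg <- open_files_registry()
  expected <- character(0)  # oracle: actions in insertion order

  p <- local_text_file("original")
  id <- register_loaded_file(store, reg, p)
  expected <- c(expected, "LOAD_FILE")
  record_simple_op(store, reg, id, "APODIZE", 2)
  expected <- c(expected, "APODIZE")
  record_simple_op(store, reg, id, "PHASE0", 45)
  expected <- c(expected, "PHASE0")
  p2 <- local_text_file("derived")
  id2 <- register_saved_file(store, reg, id, p2)
  expected <- c(expected, "SAVE")  # SAVE is linked to the new file

  items <- actions_for_file(store, id)
  expect_equal(vapply(items, `[[`, "", "action"), expected[1:3])
  items2 <- actions_for_file(store, id2)
  expect_equal(vapply(items2, `[[`, "", "action"), "SAVE")

  # an untouched registered file has only its load event
  q <- local_text_file("untouched")
  idq <- register_loaded_file(store, reg, q)
  expect_equal(vapply(actions_for_file(store, idq), `[[`, "", "action"),
               "LOAD_FILE")

  expect_error(actions_for_file(store, 99L),
               class = "spectratrack_validation_error")
})

test_that("lineage history concatenates ancestors root-first on chains 1-10", {
  store <- local_store()
  reg <- open_files_registry()
  # oracle: per-file expected action id sequences, built while inserting
  per_file <- list()

  p <- local_text_file("gen 0")
  id <- register_loaded_file(store, reg, p)
  per_file[[as.character(id)]] <- last_action_id(store)
  chain_ids <- id

  withr::with_seed(11, {
    for (depth in 1:10) {
      for (k in seq_len(sample(0:2, 1))) {
        record_simple_op(store, reg, id, "APODIZE", depth + k)
        per_file[[as.character(id)]] <-
          c(per_file[[as.character(id)]], last_action_id(store))
      }
      p <- local_text_file(sprintf("gen %d", depth))
      id <- register_saved_file(store, reg, id, p)
      per_file[[as.character(id)]] <- last_action_id(store)
      chain_ids <- c(chain_ids, id)

      # check at every depth: concatenation over ancestors, root first
      items <- history_with_parents(store, id)
      got <- vapply(items, `[[`, integer(1), "id_action")
      want <- unlist(per_file[as.character(chain_ids)], use.names = FALSE)
      expect_identical(got, want)

      # prefix and additivity properties
      root_items <- actions_for_file(store, chain_ids[1])
      expect_identical(got[seq_along(root_items)],
                       vapply(root_items, `[[`, integer(1), "id_action"))
      expect_length(items, sum(lengths(per_file[as.character(chain_ids)])))
    }
  })

  # base case: a root file's lineage history equals its own history
  root <- chain_ids[1]
  expect_identical(
    vapply(history_with_parents(store, root), `[[`, integer(1), "id_action"),
    vapply(actions_for_file(store, root), `[[`, integer(1), "id_action"))
})

test_that("session listing starts where the file last entered the registry", {
  store <- local_store()
  reg <- open_files_registry()
  p <- local_text_file("session data")
  id <- register_loaded_file(store, reg, p)
  record_simple_op(store, reg, id, "APODIZE", 1)
  record_simple_op(store, reg, id, "PHASE0", 10)
  record_simple_op(store, reg, id, "SCALE", 2)

  items <- session_actions(store, reg, id, mode = "data")
  expect_equal(vapply(items, `[[`, "", "action"),
               c("LOAD_FILE", "APODIZE", "PHASE0", "SCALE"))

  # close and reopen: only events from the reopening onward
  close_file(reg, id)
  register_loaded_file(store, reg, p)
  record_simple_op(store, reg, id, "SCALE", 3)
  items <- session_actions(store, reg, id, mode = "data")
  expect_equal(vapply(items, `[[`, "", "action"), c("LOAD_FILE", "SCALE"))

  # full history still remembers everything
  expect_length(actions_for_file(store, id), 6L)
  expect_error(session_actions(store, reg, id + 1L, mode = "data"),
               class = "spectratrack_state_error")
})

test_that("result-mode session ends at the quantitation that produced it", {
  demo <- local_demo()
  items <- session_actions(demo$store, result_hash = demo$result_hash,
                           mode = "result")
  keys <- vapply(items, `[[`, "", "action")
  expect_equal(keys, c("LOAD_FILE", "APODIZE", "PHASE0", "QUANTIFY_LLS"))
  expect_equal(items[[length(items)]]$id_action, demo$id_action_quant)

  expect_error(
    session_actions(demo$store, result_hash = strrep("a", 64),
                    mode = "result"),
    class = "spectratrack_validation_error")
})

test_that("batch text renders deterministically and parses back", {
  demo <- local_demo()
  items <- actions_for_file(demo$store, demo$id_file_original)

  txt <- render_batch(items)
  expect_identical(render_batch(items), txt)  # byte-identical
  expect_match(strsplit(txt, "\n")[[1]][1], "^# spectratrack batch v1$")

  parsed <- parse_batch(txt)
  expect_length(parsed, length(items))
  for (i in seq_along(items)) {
    expect_equal(parsed[[i]]$action, items[[i]]$action)
    expect_equal(parsed[[i]]$opertime, items[[i]]$opertime)
    expect_equal(parsed[[i]]$params$parameter, items[[i]]$params$parameter)
    expect_equal(parsed[[i]]$params$description,
                 items[[i]]$params$description)
    expect_equal(parsed[[i]]$params$hash, items[[i]]$params$hash)
  }
  # file params carry their hash; the quantitation line survives
  quant <- parsed[[length(parsed)]]  # the quantitation step
  expect_true(all(grepl("^[0-9a-f]{64}$", quant$params$hash)))
  expect_equal(nrow(quant$result), 1L)

  # re-render of the parsed structure reproduces the text exactly
  expect_identical(render_batch(parsed), txt)

  expect_error(render_batch(list()),
               class = "spectratrack_validation_error")
  expect_error(parse_batch("no header\n"),
               class = "spectratrack_parse_error")
})

test_that("a result bundle carries data, batch, parameters and result", {
  demo <- local_demo()
  expect_setequal(demo$manifest$role,
                  c("data", "batch", "parameter", "result"))
  expect_equal(sum(demo$manifest$role == "data"), 1L)
  expect_equal(sum(demo$manifest$role == "batch"), 1L)
  expect_equal(sum(demo$manifest$role == "parameter"), 2L)
  expect_equal(sum(demo$manifest$role == "result"), 1L)

  # every manifest hash matches the archived bytes
  extracted <- unzip_bundle(demo$paths$bundle)
  for (i in seq_len(nrow(demo$manifest))) {
    member <- file.path(extracted, demo$manifest$name[i])
    expect_true(file.exists(member))
    expect_identical(compute_file_hash(member), demo$manifest$hash[i])
  }
  expect_true(file.exists(file.path(extracted, "MANIFEST.txt")))
  # the archived batch covers the steps up to the quantitation
  batch <- parse_batch(paste0(paste(readLines(
    file.path(extracted, "processing.batch")), collapse = "\n"), "\n"))
  expect_equal(vapply(batch, `[[`, "", "action"),
               c("LOAD_FILE", "APODIZE", "PHASE0", "QUANTIFY_LLS"))

  # re-export is deterministic at the manifest level
  again <- file.path(withr::local_tempdir(), "again.zip")
  manifest2 <- export_result_bundle(demo$store, demo$result_hash, again)
  expect_identical(manifest2$hash, demo$manifest$hash)

  expect_error(export_result_bundle(demo$store, strrep("b", 64),
                                    tempfile(fileext = ".zip")),
               class = "spectratrack_validation_error")

  # a missing managed parameter file is an integrity error naming the hash
  param_hash <- demo$manifest$hash[demo$manifest$role == "parameter"][1]
  # remove both the managed copy and the original so no fallback exists
  orig <- DBI::dbGetQuery(
    demo$store$con, "SELECT parameter FROM PARAMS WHERE hash = ?",
    params = list(param_hash))$parameter[1]
  file.remove(file.path(demo$store$param_files_dir, param_hash), orig)
  expect_error(
    export_result_bundle(demo$store, demo$result_hash,
                         tempfile(fileext = ".zip")),
    regexp = param_hash, class = "spectratrack_integrity_error")
})

test_that("verification recomputes every managed hash and spots corruption", {
  empty <- local_store()
  rep0 <- verify_store(empty)
  expect_equal(rep0$checked, 0L)
  expect_equal(nrow(rep0$mismatched), 0L)

  demo <- local_demo()
  rep <- verify_store(demo$store)
  expect_gt(rep$checked, 0L)
  expect_equal(nrow(rep$mismatched), 0L)

  # flip one byte inside one managed parameter file
  victim <- list.files(demo$store$param_files_dir, full.names = TRUE)[1]
  bytes <- readBin(victim, "raw", file.size(victim))
  bytes[1] <- xor(bytes[1], as.raw(1))
  writeBin(bytes, victim)

  rep2 <- verify_store(demo$store)
  expect_equal(nrow(rep2$mismatched), 1L)
  expect_equal(rep2$mismatched$hash, basename(victim))
})
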