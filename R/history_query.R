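# History extraction: per-file listings, lineage traversal, batch text
# rendering and parsing, reproducibility-bundle export, store verification.

history_item <- function(store, id_action, id_file, link_id) {
  act <- DBI::dbGetQuery(
    store$con,
    "SELECT ID_action, opertime, action FROM ACTIONS WHERE ID_action = ?",
    params = list(id_action))
  params <- DBI::dbGetQuery(
    store$con,
    "SELECT parameter, description, hash FROM PARAMS
     WHERE ID_action = ? ORDER BY ID",
    params = list(id_action))
  result <- DBI::dbGetQuery(
    store$con,
    "SELECT parameter, description, hash FROM RESULTS
     WHERE ID_action = ? ORDER BY ID",
    params = list(id_action))
  structure(
    list(id_action = as.integer(id_action),
         opertime = act$opertime,
         action = act$action,
         params = params,
         result = result,
         comments = comments_for(store, id_action, "action"),
         approved = approval_status(store, id_action),
         id_file = as.integer(id_file),
         link_id = as.integer(link_id)),
    class = "history_item")
}

#' @export
print.history_item <- function(x, ...) {
  cat(sprintf("[%d] %s @ %s (file %d)\n", x$id_action, x$action,
              x$opertime, x$id_file))
  if (nrow(x$params))
    cat(sprintf("    %s = %s\n", x$params$description, x$params$parameter),
        sep = "")
  if (nrow(x$result))
    cat(sprintf("    -> %s\n", basename(x$result$parameter)), sep = "")
  invisible(x)
}

#' All actions recorded for one file
#'
#' Lists every processing step linked to `id_file` — including its
#' `LOAD_FILE` and `SAVE` events — in the order the links were written
#' (ascending `FILES_ACTIONS.ID`).
#'
#' @param store A `spectratrack_store`.
#' @param id_file A registered `ID_file`.
#' @return List of `history_item` objects.
#' @export
actions_for_file <- function(store, id_file) {
  check_store(store)
  id_file <- as.integer(id_file)
  file_record(store, id_file)  # validates existence
  links <- DBI::dbGetQuery(
    store$con,
    "SELECT ID, ID_action FROM FILES_ACTIONS WHERE ID_file = ? ORDER BY ID",
    params = list(id_file))
  lapply(seq_len(nrow(links)), function(i)
    history_item(store, links$ID_action[i], id_file, links$ID[i]))
}

#' History of a file including all its ancestors
#'
#' Walks the lineage from the root ancestor down to `id_file` and
#' concatenates each ancestor's [actions_for_file()] listing: everything
#' that was ever done to any file this file derives from, root first,
#' the file itself last.
#'
#' @param store A `spectratrack_store`.
#' @param id_file A registered `ID_file`.
#' @return List of `history_item` objects.
#' @export
history_with_parents <- function(store, id_file) {
  check_store(store)
  chain <- lineage(store, as.integer(id_file))
  do.call(c, lapply(chain, function(idf) actions_for_file(store, idf)))
}

#' Actions of the current session
#'
#' In `"data"` mode, lists the steps recorded for an open file since its
#' id last entered the open-files registry (the triggering `LOAD_FILE` or
#' `SAVE` event is included). In `"result"` mode, resolves a result hash
#' to the action that produced it and lists that file's history up to and
#' including the quantitation — the steps that led to the result.
#'
#' @param store A `spectratrack_store`.
#' @param registry An [open_files_registry()]; only used in data mode.
#' @param id_file Open file id (data mode).
#' @param result_hash Result content hash (result mode).
#' @param mode `"data"` or `"result"`.
#' @return List of `history_item` objects.
#' @export
session_actions <- function(store, registry = NULL, id_file = NULL,
                            result_hash = NULL,
                            mode = c("data", "result")) {
  check_store(store)
  mode <- match.arg(mode)
  if (mode == "data") {
    check_registry(registry)
    id_file <- as.integer(id_file)
    if (!(id_file %in% registry$ids))
      st_state("file id %d is not open", id_file)
    start <- registry$session_start[[as.character(id_file)]]
    items <- actions_for_file(store, id_file)
    Filter(function(it) it$link_id >= start, items)
  } else {
    h <- normalize_hash(result_hash)
    res <- DBI::dbGetQuery(
      store$con,
      "SELECT ID_action FROM RESULTS WHERE hash = ? ORDER BY ID LIMIT 1",
      params = list(h))
    if (nrow(res) == 0L)
      st_validation("no result with hash %s", h)
    id_action_q <- as.integer(res$ID_action)
    link <- DBI::dbGetQuery(
      store$con,
      "SELECT ID_file FROM FILES_ACTIONS WHERE ID_action = ?
       ORDER BY ID LIMIT 1",
      params = list(id_action_q))
    items <- actions_for_file(store, as.integer(link$ID_file))
    upto <- which(vapply(items, function(it) it$id_action, integer(1)) ==
                    id_action_q)[1]
    items[seq_len(upto)]
  }
}

#' Render history items as batch text
#'
#' The line-oriented batch dialect is the package's portable history
#' format: a header line, then per action an `ACTION <key> <time>` line,
#' one `PARAM <description> = <value>` line per parameter (file-valued
#' parameters carry a ` HASH <64-hex>` suffix), and for quantitation a
#' final `RESULT <basename> HASH <64-hex>` line. Rendering is
#' deterministic: identical items give byte-identical text.
#'
#' @param items Non-empty list of `history_item` objects (or the
#'   equivalent structure returned by [parse_batch()]).
#' @return A single string, `"\n"`-separated, trailing newline included.
#' @export
render_batch <- function(items) {
  if (length(items) == 0L)
    st_validation("cannot render an empty history")
  lines <- "# spectratrack batch v1"
  for (it in items) {
    lines <- c(lines, sprintf("ACTION %s %s", it$action, it$opertime))
    p <- it$params
    for (i in seq_len(NROW(p))) {
      ln <- sprintf("PARAM %s = %s", p$description[i], p$parameter[i])
      if (nzchar(p$hash[i])) ln <- paste0(ln, " HASH ", p$hash[i])
      lines <- c(lines, ln)
    }
    r <- it$result
    for (i in seq_len(NROW(r)))
      lines <- c(lines, sprintf("RESULT %s HASH %s",
                                basename(r$parameter[i]), r$hash[i]))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse batch text back into history items
#'
#' Inverse of [render_batch()] on the rendered fields (action key, time,
#' parameter descriptions/values/hashes, result basename/hash).
#'
#' @param text Batch text as produced by [render_batch()].
#' @return List of item structures with `action`, `opertime`, `params`
#'   and `result` fields.
#' @export
parse_batch <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L || lines[1] != "# spectratrack batch v1")
    st_parse("missing batch header line")
  items <- list()
  cur <- NULL
  flush <- function(items, cur) if (is.null(cur)) items else c(items, list(cur))
  for (k in seq_along(lines)[-1]) {
    ln <- lines[k]
    if (!nzchar(ln)) next
    if (startsWith(ln, "ACTION ")) {
      items <- flush(items, cur)
      body <- sub("^ACTION ", "", ln)
      sp <- regexpr(" ", body, fixed = TRUE)
      if (sp < 0) st_parse("malformed ACTION line %d", k)
      cur <- list(action = substr(body, 1, sp - 1),
                  opertime = substr(body, sp + 1, nchar(body)),
                  params = data.frame(parameter = character(0),
                                      description = character(0),
                                      hash = character(0)),
                  result = data.frame(parameter = character(0),
                                      hash = character(0)))
    } else if (startsWith(ln, "PARAM ")) {
      if (is.null(cur)) st_parse("PARAM before ACTION at line %d", k)
      body <- sub("^PARAM ", "", ln)
      hash <- ""
      m <- regmatches(body, regexpr(" HASH [0-9a-f]{64}$", body))
      if (length(m)) {
        hash <- sub("^ HASH ", "", m)
        body <- sub(" HASH [0-9a-f]{64}$", "", body)
      }
      sep <- regexpr(" = ", body, fixed = TRUE)
      if (sep < 0) st_parse("malformed PARAM line %d", k)
      cur$params <- rbind(cur$params, data.frame(
        parameter = substr(body, sep + 3, nchar(body)),
        description = substr(body, 1, sep - 1),
        hash = hash))
    } else if (startsWith(ln, "RESULT ")) {
      if (is.null(cur)) st_parse("RESULT before ACTION at line %d", k)
      body <- sub("^RESULT ", "", ln)
      m <- regexpr(" HASH [0-9a-f]{64}$", body)
      if (m < 0) st_parse("malformed RESULT line %d", k)
      cur$result <- rbind(cur$result, data.frame(
        parameter = substr(body, 1, m - 1),
        hash = sub("^ HASH ", "", regmatches(body, m))))
    } else {
      st_parse("unrecognized line %d: '%s'", k, ln)
    }
  }
  flush(items, cur)
}

# Appends the batch rendering of one action to "<path>.history.txt" next
# to the data file (optional per-file text history).
append_text_history <- function(store, id_file, id_action) {
  rec <- file_record(store, id_file)
  links <- DBI::dbGetQuery(
    store$con,
    "SELECT ID FROM FILES_ACTIONS WHERE ID_file = ? AND ID_action = ?
     ORDER BY ID LIMIT 1",
    params = list(as.integer(id_file), as.integer(id_action)))
  it <- history_item(store, id_action, id_file, links$ID[1])
  txt <- render_batch(list(it))
  txt <- sub("^# spectratrack batch v1\n", "", txt)
  hist_path <- paste0(rec$path, ".history.txt")
  cat(txt, file = hist_path, append = TRUE)
  invisible(hist_path)
}

bundle_member_name <- function(name, hash, taken) {
  # Resolve basename collisions with a short content-hash prefix.
  if (!(name %in% names(taken)) || taken[[name]] == hash) return(name)
  paste0(substr(hash, 1, 8), "_", name)
}

#' Export a reproducibility bundle for a quantitation result
#'
#' Packs everything needed to reproduce a quantitation into one zip file:
#' the originating data file (the root ancestor of the lineage), the
#' rendered processing history (`processing.batch`, the history with
#' parents truncated at the quantitation), every file-valued parameter of
#' those actions (taken from managed storage), the result file itself, and
#' a `MANIFEST.txt` mapping archive names to content hashes and roles
#' (`data`, `batch`, `parameter`, `result`).
#'
#' @param store A `spectratrack_store`.
#' @param result_hash Content hash of a recorded result.
#' @param out_path Path of the zip file to write.
#' @return The manifest, a data.frame with columns `name`, `hash`, `role`.
#' @export
export_result_bundle <- function(store, result_hash, out_path) {
  check_store(store)
  h <- normalize_hash(result_hash)
  res <- DBI::dbGetQuery(
    store$con,
    "SELECT ID_action, parameter, hash FROM RESULTS WHERE hash = ?
     ORDER BY ID LIMIT 1",
    params = list(h))
  if (nrow(res) == 0L)
    st_validation("no result with hash %s", h)
  id_action_q <- as.integer(res$ID_action)
  link <- DBI::dbGetQuery(
    store$con,
    "SELECT ID_file FROM FILES_ACTIONS WHERE ID_action = ?
     ORDER BY ID LIMIT 1",
    params = list(id_action_q))
  id_file <- as.integer(link$ID_file)

  items <- history_with_parents(store, id_file)
  upto <- which(vapply(items, function(it) it$id_action, integer(1)) ==
                  id_action_q)[1]
  items <- items[seq_len(upto)]

  root <- file_record(store, lineage(store, id_file)[1])
  if (!file.exists(root$path))
    st_integrity("original data file for hash %s is missing (%s)",
                 root$hash, root$path)
  if (compute_file_hash(root$path) != root$hash)
    st_integrity("original data file no longer matches recorded hash %s",
                 root$hash)

  staging <- tempfile("bundle")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  taken <- list()
  manifest <- data.frame(name = character(0), hash = character(0),
                         role = character(0))
  add_member <- function(src, name, hash, role, manifest, bytes = NULL) {
    name <- bundle_member_name(name, hash, taken)
    if (!(name %in% names(taken))) {
      if (is.null(bytes)) {
        file.copy(src, file.path(staging, name))
      } else {
        writeChar(bytes, file.path(staging, name), eos = NULL,
                  useBytes = TRUE)
      }
      taken[[name]] <<- hash
      manifest <- rbind(manifest,
                        data.frame(name = name, hash = hash, role = role))
    }
    manifest
  }

  manifest <- add_member(root$path, basename(root$path), root$hash,
                         "data", manifest)
  batch_txt <- render_batch(items)
  manifest <- add_member(NULL, "processing.batch",
                         compute_file_hash(charToRaw(batch_txt)),
                         "batch", manifest, bytes = batch_txt)
  for (it in items) {
    p <- it$params
    for (i in seq_len(NROW(p))) {
      if (!nzchar(p$hash[i])) next
      managed <- file.path(store$param_files_dir, p$hash[i])
      src <- if (file.exists(managed)) managed else p$parameter[i]
      if (!file.exists(src))
        st_integrity("managed parameter file %s is missing", p$hash[i])
      manifest <- add_member(src, basename(p$parameter[i]), p$hash[i],
                             "parameter", manifest)
    }
  }
  managed_res <- file.path(store$results_dir, res$hash)
  if (!file.exists(managed_res))
    st_integrity("managed result file %s is missing", res$hash)
  manifest <- add_member(managed_res, basename(res$parameter), res$hash,
                         "result", manifest)

  writeLines(sprintf("%s\t%s\t%s", manifest$name, manifest$hash,
                     manifest$role),
             file.path(staging, "MANIFEST.txt"))
  # zip() works relative to `root`; pin the destination to an absolute path
  out_path <- file.path(normalizePath(dirname(out_path), mustWork = TRUE),
                        basename(out_path))
  zip::zip(zipfile = out_path,
           files = c(manifest$name, "MANIFEST.txt"),
           root = staging, mode = "cherry-pick")
  manifest
}

#' Verify the integrity of managed storage
#'
#' Recomputes the SHA-256 hash of every file under `param_files/` and
#' `results/` (each must equal its own file name) and checks that every
#' hash referenced from `PARAMS` and `RESULTS` has a managed copy on disk.
#'
#' @param store A `spectratrack_store`.
#' @return List with `checked` (number of checks performed) and
#'   `mismatched` (data.frame of `hash`, `path`, `reason`; zero rows when
#'   the store is intact).
#' @export
verify_store <- function(store) {
  check_store(store)
  mism <- data.frame(hash = character(0), path = character(0),
                     reason = character(0))
  checked <- 0L
  for (dir in c(store$param_files_dir, store$results_dir)) {
    for (f in list.files(dir, full.names = TRUE)) {
      checked <- checked + 1L
      h <- compute_file_hash(f)
      if (h != basename(f))
        mism <- rbind(mism, data.frame(
          hash = basename(f), path = f,
          reason = "content does not match stored name"))
    }
  }
  refs <- data.frame(
    hash = c(DBI::dbGetQuery(
               store$con, "SELECT hash FROM PARAMS WHERE hash <> ''")$hash,
             DBI::dbGetQuery(store$con, "SELECT hash FROM RESULTS")$hash),
    dir = c(rep(store$param_files_dir, DBI::dbGetQuery(
              store$con,
              "SELECT COUNT(*) AS n FROM PARAMS WHERE hash <> ''")$n),
            rep(store$results_dir, st_count(store, "RESULTS"))))
  for (i in seq_len(nrow(refs))) {
    checked <- checked + 1L
    f <- file.path(refs$dir[i], refs$hash[i])
    if (!file.exists(f))
      mism <- rbind(mism, data.frame(
        hash = refs$hash[i], path = f,
        reason = "referenced managed file is missing"))
  }
  list(checked = checked, mismatched = mism)
}
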