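#' Compute the SHA-256 content hash of a file or raw vector
#'
#' File identity in the store is the SHA-256 digest of the file's bytes,
#' rendered as 64 lowercase hex characters. Two byte-identical files hash
#' equally regardless of their names or locations, which is what lets the
#' store recognize files that have been copied or moved.
#'
#' @param x A file path, or a raw vector of bytes.
#' @return A 64-character lowercase hex string.
#' @examples
#' compute_file_hash(raw(0))  # hash of the empty byte stream
#' @export
compute_file_hash <- function(x) {
  if (is.raw(x))
    return(digest::digest(x, algo = "sha256", serialize = FALSE))
  if (!is.character(x) || length(x) != 1L)
    st_validation("expected a single file path or a raw vector")
  if (!file.exists(x) || dir.exists(x))
    st_io("cannot read file '%s'", x)
  digest::digest(file = x, algo = "sha256")
}

is_valid_hash <- function(h) {
  is.character(h) && length(h) == 1L && grepl("^[0-9a-fA-F]{64}$", h)
}

normalize_hash <- function(h) {
  if (!is_valid_hash(h))
    st_validation("malformed content hash '%s'", as.character(h)[1])
  tolower(h)
}

#' Create an in-memory registry of open files
#'
#' The "OPEN FILES" registry tracks which registered files are currently
#' open in a processing session. It lives only in memory — it is never
#' written to disk — and holds, for each open `ID_file`, the link id at
#' which its current session began (used by [session_actions()]).
#'
#' @return An `open_files_registry` object.
#' @export
open_files_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$ids <- integer(0)            # open ID_file values, in open order
  reg$session_start <- integer(0)  # FILES_ACTIONS.ID at which session began
  class(reg) <- "open_files_registry"
  reg
}

#' @export
print.open_files_registry <- function(x, ...) {
  cat("<open files registry>", if (length(x$ids)) paste(x$ids, collapse = ", ")
      else "(empty)", "\n")
  invisible(x)
}

check_registry <- function(registry) {
  if (!inherits(registry, "open_files_registry"))
    st_validation("not an open-files registry")
  invisible(registry)
}

#' IDs currently open in a registry
#'
#' @param registry An [open_files_registry()].
#' @return Integer vector of open `ID_file` values, in open order.
#' @export
open_ids <- function(registry) {
  check_registry(registry)
  registry$ids
}

registry_add <- function(registry, id_file, link_id) {
  id_file <- as.integer(id_file)
  if (!(id_file %in% registry$ids))
    registry$ids <- c(registry$ids, id_file)
  registry$session_start[as.character(id_file)] <- as.integer(link_id)
  invisible(registry)
}

registry_remove <- function(registry, id_file) {
  id_file <- as.integer(id_file)
  registry$ids <- setdiff(registry$ids, id_file)
  registry$session_start <-
    registry$session_start[names(registry$session_start) !=
                             as.character(id_file)]
  invisible(registry)
}

# Insert an ACTIONS row plus one FILES_ACTIONS link per target file.
# Returns list(id_action, link_ids).
insert_action_rows <- function(store, action, id_files) {
  DBI::dbExecute(
    store$con,
    "INSERT INTO ACTIONS (opertime, action) VALUES (?, ?)",
    params = list(st_now(), action))
  id_action <- DBI::dbGetQuery(
    store$con, "SELECT last_insert_rowid() AS id")$id
  link_ids <- vapply(id_files, function(idf) {
    DBI::dbExecute(
      store$con,
      "INSERT INTO FILES_ACTIONS (ID_file, ID_action) VALUES (?, ?)",
      params = list(as.integer(idf), as.integer(id_action)))
    DBI::dbGetQuery(store$con, "SELECT last_insert_rowid() AS id")$id
  }, numeric(1))
  list(id_action = as.integer(id_action), link_ids = as.integer(link_ids))
}

#' Register a loaded data file
#'
#' Computes the file's content hash and looks it up in `FILES`. A known
#' hash returns the existing `ID_file` (the path on record is left as it
#' was — the hash, not the path, is the file's identity); an unknown hash
#' inserts a new row with lineage pointer `child = -1`. Either way a
#' `LOAD_FILE` action is appended and linked to the file, and the id is
#' placed in the open-files registry.
#'
#' @param store A `spectratrack_store`.
#' @param registry An [open_files_registry()].
#' @param path Path of the data file being loaded.
#' @return The `ID_file` (integer).
#' @export
register_loaded_file <- function(store, registry, path) {
  check_store(store); check_registry(registry)
  if (!file.exists(path) || dir.exists(path))
    st_io("cannot read data file '%s'", path)
  h <- compute_file_hash(path)
  rec <- find_file_by_hash(store, h)
  id_file <- DBI::dbWithTransaction(store$con, {
    if (is.null(rec)) {
      DBI::dbExecute(
        store$con,
        "INSERT INTO FILES (path, hash, child) VALUES (?, ?, -1)",
        params = list(normalizePath(path), h))
      idf <- as.integer(DBI::dbGetQuery(
        store$con, "SELECT last_insert_rowid() AS id")$id)
    } else {
      idf <- rec$id_file
    }
    ins <- insert_action_rows(store, "LOAD_FILE", idf)
    registry_add(registry, idf, ins$link_ids[1])
    if (store$text_history)
      append_text_history(store, idf, ins$id_action)
    idf
  })
  id_file
}

#' Register a saved (derived) data file
#'
#' The caller has already serialized the processed data to `new_path`;
#' this records the save. The original `ID_file` leaves the registry, a
#' new `FILES` row is written whose `child` column holds the id of the
#' originating ("parent") file, a `SAVE` action is appended and linked to
#' the new file, and the new id enters the registry. If the saved bytes
#' are already known to the store, the existing record is returned instead
#' of creating a duplicate.
#'
#' @param store A `spectratrack_store`.
#' @param registry An [open_files_registry()].
#' @param original_id `ID_file` of the open file the new one derives from.
#' @param new_path Path of the file just written.
#' @return The new `ID_file` (integer).
#' @export
register_saved_file <- function(store, registry, original_id, new_path) {
  check_store(store); check_registry(registry)
  original_id <- as.integer(original_id)
  if (!(original_id %in% registry$ids))
    st_state("file id %d is not open", original_id)
  if (!file.exists(new_path) || dir.exists(new_path))
    st_io("cannot read saved file '%s'", new_path)
  h <- compute_file_hash(new_path)
  rec <- find_file_by_hash(store, h)
  DBI::dbWithTransaction(store$con, {
    if (is.null(rec)) {
      DBI::dbExecute(
        store$con,
        "INSERT INTO FILES (path, hash, child) VALUES (?, ?, ?)",
        params = list(normalizePath(new_path), h, original_id))
      idf <- as.integer(DBI::dbGetQuery(
        store$con, "SELECT last_insert_rowid() AS id")$id)
    } else {
      idf <- rec$id_file
    }
    ins <- insert_action_rows(store, "SAVE", idf)
    registry_remove(registry, original_id)
    registry_add(registry, idf, ins$link_ids[1])
    if (store$text_history)
      append_text_history(store, idf, ins$id_action)
    idf
  })
}

#' Remove a file from the open-files registry
#'
#' Closing touches only the in-memory registry; no database rows are
#' written or removed.
#'
#' @param registry An [open_files_registry()].
#' @param id_file An open `ID_file`.
#' @return The registry, invisibly.
#' @export
close_file <- function(registry, id_file) {
  check_registry(registry)
  id_file <- as.integer(id_file)
  if (!(id_file %in% registry$ids))
    st_state("file id %d is not open", id_file)
  registry_remove(registry, id_file)
  invisible(registry)
}

#' Copy a parameter or result file into managed, hash-named storage
#'
#' The file is copied byte-for-byte into the store's `param_files/` or
#' `results/` subdirectory with its SHA-256 hash as the file name.
#' Re-ingesting identical content is a no-op returning the same stored
#' path.
#'
#' @param store A `spectratrack_store`.
#' @param path File to ingest.
#' @param kind `"parameter"` or `"result"`.
#' @return List with `stored_path` and `hash`.
#' @export
ingest_managed_file <- function(store, path, kind = c("parameter", "result")) {
  check_store(store)
  kind <- match.arg(kind)
  if (!file.exists(path) || dir.exists(path))
    st_io("cannot read file '%s'", path)
  h <- compute_file_hash(path)
  dir <- if (kind == "parameter") store$param_files_dir else store$results_dir
  dest <- file.path(dir, h)
  if (!file.exists(dest)) {
    if (!file.copy(path, dest, overwrite = FALSE))
      st_io("failed to copy '%s' into managed storage", path)
  }
  list(stored_path = dest, hash = h)
}

#' Look a file up by its content hash
#'
#' Finds the `FILES` record whose hash equals `hash` (case-insensitively;
#' hashes are stored lowercase). Because lookup is by content, a file that
#' has been moved or renamed since registration is still recognized.
#'
#' @param store A `spectratrack_store`.
#' @param hash 64-character hex string.
#' @return A list with `id_file`, `path`, `hash`, `child`, or `NULL` if
#'   the hash is unknown.
#' @export
find_file_by_hash <- function(store, hash) {
  check_store(store)
  h <- normalize_hash(hash)
  row <- DBI::dbGetQuery(
    store$con,
    "SELECT ID_file, path, hash, child FROM FILES WHERE hash = ?",
    params = list(h))
  if (nrow(row) == 0L) return(NULL)
  list(id_file = as.integer(row$ID_file), path = row$path,
       hash = row$hash, child = as.integer(row$child))
}

#' Fetch a file's registration record by id
#'
#' @param store A `spectratrack_store`.
#' @param id_file A registered `ID_file`.
#' @return List with `id_file`, `path`, `hash` and `child` (the lineage
#'   pointer: `-1`, or the id of the file this one was derived from).
#' @export
file_record <- function(store, id_file) {
  row <- DBI::dbGetQuery(
    store$con,
    "SELECT ID_file, path, hash, child FROM FILES WHERE ID_file = ?",
    params = list(as.integer(id_file)))
  if (nrow(row) == 0L)
    st_validation("unknown file id %d", as.integer(id_file))
  list(id_file = as.integer(row$ID_file), path = row$path,
       hash = row$hash, child = as.integer(row$child))
}

#' Derivation chain of a file
#'
#' Follows the `child` lineage pointers from `id_file` up to the root
#' ancestor (a file whose pointer is `-1`).
#'
#' @param store A `spectratrack_store`.
#' @param id_file A registered `ID_file`.
#' @return Integer vector of `ID_file` values, root ancestor first,
#'   `id_file` last.
#' @export
lineage <- function(store, id_file) {
  check_store(store)
  chain <- integer(0)
  cur <- as.integer(id_file)
  n_files <- st_count(store, "FILES")
  while (cur != -1L) {
    if (length(chain) > n_files)
      st_integrity("lineage cycle detected at file id %d", cur)
    rec <- file_record(store, cur)
    chain <- c(cur, chain)
    cur <- rec$child
  }
  chain
}
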