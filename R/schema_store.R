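#' @importFrom DBI dbConnect dbDisconnect dbExecute dbGetQuery dbWithTransaction
#'   dbListTables dbIsValid
NULL

# Canonical table order used throughout: history tables, comment tables,
# macro tables.
ST_TABLES <- c(
  "ACTIONS", "PARAMS", "RESULTS", "FILES", "FILES_ACTIONS",
  "ACTIONS_comment", "RESULTS_comment",
  "MACRO", "MACRO_contents"
)

ST_RESERVED_ACTIONS <- c("LOAD_FILE", "SAVE")

st_ddl <- function() {
  c(
    "CREATE TABLE ACTIONS (
       ID_action INTEGER PRIMARY KEY,
       opertime  TEXT    NOT NULL,
       action    TEXT    NOT NULL CHECK (length(action) BETWEEN 1 AND 64)
     )",
    "CREATE TABLE PARAMS (
       ID          INTEGER PRIMARY KEY,
       ID_action   INTEGER NOT NULL REFERENCES ACTIONS(ID_action),
       parameter   TEXT    NOT NULL,
       description TEXT    NOT NULL,
       hash        TEXT    NOT NULL DEFAULT ''
     )",
    "CREATE TABLE RESULTS (
       ID          INTEGER PRIMARY KEY,
       ID_action   INTEGER NOT NULL REFERENCES ACTIONS(ID_action),
       parameter   TEXT    NOT NULL,
       description TEXT    NOT NULL,
       hash        TEXT    NOT NULL CHECK (length(hash) = 64)
     )",
    "CREATE TABLE FILES (
       ID_file INTEGER PRIMARY KEY,
       path    TEXT    NOT NULL,
       hash    TEXT    NOT NULL UNIQUE,
       child   INTEGER NOT NULL DEFAULT -1
     )",
    "CREATE TABLE FILES_ACTIONS (
       ID        INTEGER PRIMARY KEY,
       ID_file   INTEGER NOT NULL REFERENCES FILES(ID_file),
       ID_action INTEGER NOT NULL REFERENCES ACTIONS(ID_action)
     )",
    "CREATE TABLE ACTIONS_comment (
       ID_action INTEGER NOT NULL REFERENCES ACTIONS(ID_action),
       comment   TEXT    NOT NULL DEFAULT '',
       approved  TEXT    NOT NULL DEFAULT 'unset'
                 CHECK (approved IN ('unset', 'approved', 'not-approved'))
     )",
    "CREATE TABLE RESULTS_comment (
       ID_action INTEGER NOT NULL REFERENCES ACTIONS(ID_action),
       comment   TEXT    NOT NULL DEFAULT '',
       approved  TEXT    NOT NULL DEFAULT 'unset'
                 CHECK (approved IN ('unset', 'approved', 'not-approved'))
     )",
    "CREATE TABLE MACRO (
       ID_macro INTEGER PRIMARY KEY,
       name     TEXT    NOT NULL UNIQUE CHECK (length(name) > 0),
       comment  TEXT    NOT NULL DEFAULT ''
     )",
    "CREATE TABLE MACRO_contents (
       ID_macro  INTEGER NOT NULL REFERENCES MACRO(ID_macro),
       ID_action INTEGER NOT NULL REFERENCES ACTIONS(ID_action),
       position  INTEGER NOT NULL,
       UNIQUE (ID_macro, position)
     )"
  )
}

#' Create or open a provenance store
#'
#' A store is a directory holding one SQLite database file
#' (`spectratrack.db`) and two managed subdirectories, `param_files/` and
#' `results/`, into which every parameter and quantitation-result file is
#' copied under its own SHA-256 content hash as file name. The database
#' holds nine tables: five history tables (`ACTIONS`, `PARAMS`, `RESULTS`,
#' `FILES`, `FILES_ACTIONS`), two comment tables (`ACTIONS_comment`,
#' `RESULTS_comment`) and two macro tables (`MACRO`, `MACRO_contents`).
#'
#' Calling `init_store()` on a directory that already contains a valid
#' store opens it without touching existing rows; a directory containing a
#' foreign or corrupt database raises a schema error. The store is
#' append-only: no public operation deletes or edits recorded history.
#'
#' @param root_dir Directory for the store; created if absent.
#' @param text_history If `TRUE`, every recorded action is also appended,
#'   in the batch text dialect, to a `<data file>.history.txt` file next to
#'   each data file it was applied to.
#' @return A `spectratrack_store` handle used by all other functions.
#' @examples
#' store <- init_store(file.path(tempdir(), "demo-store"))
#' names(introspect_schema(store))
#' close_store(store)
#' @export
init_store <- function(root_dir, text_history = FALSE) {
  if (file.exists(root_dir) && !dir.exists(root_dir))
    st_io("'%s' exists and is not a directory", root_dir)
  if (!dir.exists(root_dir) &&
      !dir.create(root_dir, recursive = TRUE, showWarnings = FALSE))
    st_io("cannot create store directory '%s'", root_dir)
  if (file.access(root_dir, mode = 2L) != 0L)
    st_io("store directory '%s' is not writable", root_dir)

  db_file <- file.path(root_dir, "spectratrack.db")
  fresh <- !file.exists(db_file)
  con <- DBI::dbConnect(RSQLite::SQLite(), db_file)
  ok <- FALSE
  on.exit(if (!ok) DBI::dbDisconnect(con))
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")

  if (fresh) {
    for (ddl in st_ddl()) DBI::dbExecute(con, ddl)
  } else {
    have <- setdiff(DBI::dbListTables(con), "sqlite_sequence")
    if (!setequal(have, ST_TABLES))
      st_schema(
        "'%s' is not a spectratrack store (tables found: %s)",
        db_file, paste(sort(have), collapse = ", "))
  }

  store <- structure(
    list(
      root_dir = normalizePath(root_dir),
      db_file = normalizePath(db_file),
      param_files_dir = file.path(normalizePath(root_dir), "param_files"),
      results_dir = file.path(normalizePath(root_dir), "results"),
      con = con,
      text_history = isTRUE(text_history)
    ),
    class = "spectratrack_store"
  )
  for (d in c(store$param_files_dir, store$results_dir))
    if (!dir.exists(d) && !dir.create(d)) st_io("cannot create '%s'", d)
  ok <- TRUE
  store
}

#' Close a provenance store
#'
#' Releases the database connection. The handle must not be used afterwards.
#'
#' @param store A `spectratrack_store`.
#' @return `NULL`, invisibly.
#' @export
close_store <- function(store) {
  check_store(store, open = FALSE)
  if (DBI::dbIsValid(store$con)) DBI::dbDisconnect(store$con)
  invisible(NULL)
}

check_store <- function(store, open = TRUE) {
  if (!inherits(store, "spectratrack_store"))
    st_validation("not a spectratrack store handle")
  if (open && !DBI::dbIsValid(store$con))
    st_state("store connection is closed")
  invisible(store)
}

#' List the tables and columns of a store
#'
#' Returns the schema actually present in the database, as a named list
#' mapping each table name to its column names in declaration order. The
#' order of tables and columns is stable across calls and across
#' close/reopen cycles.
#'
#' @param store A `spectratrack_store`.
#' @return Named list of character vectors.
#' @export
introspect_schema <- function(store) {
  check_store(store)
  have <- setdiff(DBI::dbListTables(store$con), "sqlite_sequence")
  if (!setequal(have, ST_TABLES))
    st_schema("store schema does not match the expected nine tables")
  out <- lapply(ST_TABLES, function(tb) {
    info <- DBI::dbGetQuery(
      store$con, sprintf("PRAGMA table_info(%s)", tb))
    info$name[order(info$cid)]
  })
  names(out) <- ST_TABLES
  out
}

st_now <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

st_count <- function(store, table) {
  DBI::dbGetQuery(
    store$con, sprintf("SELECT COUNT(*) AS n FROM %s", table))$n
}

#' Row counts of every table in a store
#'
#' @param store A `spectratrack_store`.
#' @return Named integer vector, one element per table.
#' @export
table_counts <- function(store) {
  check_store(store)
  vapply(ST_TABLES, function(tb) as.integer(st_count(store, tb)),
         integer(1))
}
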