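#' Describe one parameter of a processing action
#'
#' A parameter is recorded as text — a number rendered as text, free text,
#' or a full file name — together with a mandatory description carrying
#' units and/or meaning. File-valued parameters (`is_file = TRUE`) are
#' additionally ingested into managed storage and their content hash is
#' recorded, so the exact bytes used can always be retrieved.
#'
#' @param value The parameter value (number, text, or file path).
#' @param description Non-empty human-readable description, with units
#'   where applicable. Must not contain the literal separator `" = "`,
#'   which the batch text format reserves.
#' @param is_file Whether `value` names a file to be ingested.
#' @return A `param_spec` object.
#' @export
param_spec <- function(value, description, is_file = FALSE) {
  if (!is.character(description) || length(description) != 1L ||
      !nzchar(description))
    st_validation("a parameter description is always required")
  if (grepl(" = ", description, fixed = TRUE))
    st_validation("parameter descriptions must not contain ' = '")
  structure(
    list(value = as.character(value)[1], description = description,
         is_file = isTRUE(is_file)),
    class = "param_spec")
}

#' Describe one processing action for recording
#'
#' The in-flight description of an action that a processing routine hands
#' to the recorder: the action's macro key (its short routine name, at
#' most 64 characters), its ordered parameters, and — for quantitation
#' routines — the path of the result file it produced.
#'
#' @param action Macro-key string, 1–64 characters; the reserved keys
#'   `LOAD_FILE` and `SAVE` are refused.
#' @param params List of [param_spec()] objects, in signature order.
#' @param is_quantitation Whether the action produced a quantitation
#'   result file.
#' @param result_path Path of the result file; required iff
#'   `is_quantitation`.
#' @param result_description Description stored with the result record.
#' @return A `provenance_entry` object.
#' @export
provenance_entry <- function(action, params = list(),
                             is_quantitation = FALSE, result_path = NULL,
                             result_description = "quantitation result") {
  if (!is.character(action) || length(action) != 1L || !nzchar(action))
    st_validation("action key must be a non-empty string")
  if (nchar(action) > 64L)
    st_validation("action key exceeds 64 characters")
  if (action %in% ST_RESERVED_ACTIONS)
    st_validation("'%s' is a reserved action keyword", action)
  if (!all(vapply(params, inherits, logical(1), "param_spec")))
    st_validation("params must be a list of param_spec objects")
  if (isTRUE(is_quantitation)) {
    if (is.null(result_path))
      st_validation("a quantitation entry requires a result_path")
  } else if (!is.null(result_path)) {
    st_validation("result_path is only allowed for quantitation entries")
  }
  structure(
    list(action = action, params = params,
         is_quantitation = isTRUE(is_quantitation),
         result_path = result_path,
         result_description = result_description),
    class = "provenance_entry")
}

#' Record a processing action in the store
#'
#' The single write path for provenance: one call appends the action (key
#' and timestamp), its parameters in order (file parameters are ingested
#' into `param_files/` with their hash recorded), one `FILES_ACTIONS` link
#' per target file, and — for quantitation — the result file, ingested
#' into `results/` with its hash always recorded. The database write is
#' atomic: on any error no rows are added.
#'
#' @param store A `spectratrack_store`.
#' @param registry An [open_files_registry()].
#' @param entry A [provenance_entry()].
#' @param target_ids Non-empty subset of the registry's open ids — the
#'   files the action was applied to.
#' @return The new `ID_action` (integer).
#' @export
record_action <- function(store, registry, entry, target_ids) {
  check_store(store); check_registry(registry)
  if (!inherits(entry, "provenance_entry"))
    st_validation("entry must be a provenance_entry")
  target_ids <- as.integer(target_ids)
  if (length(target_ids) == 0L)
    st_validation("target_ids must name at least one open file")
  if (anyDuplicated(target_ids))
    st_validation("target_ids contains duplicates")
  not_open <- setdiff(target_ids, registry$ids)
  if (length(not_open))
    st_state("file id(s) %s are not open", paste(not_open, collapse = ", "))

  # Ingest managed copies before opening the transaction; ingestion is
  # idempotent and content-addressed, so copies from a failed recording
  # are harmless.
  param_rows <- lapply(entry$params, function(p) {
    if (p$is_file) {
      if (!file.exists(p$value) || dir.exists(p$value))
        st_io("parameter file '%s' is not readable", p$value)
      ing <- ingest_managed_file(store, p$value, "parameter")
      list(parameter = normalizePath(p$value),
           description = p$description, hash = ing$hash)
    } else {
      list(parameter = p$value, description = p$description, hash = "")
    }
  })
  result_row <- NULL
  if (entry$is_quantitation) {
    if (!file.exists(entry$result_path) || dir.exists(entry$result_path))
      st_io("result file '%s' is not readable", entry$result_path)
    ing <- ingest_managed_file(store, entry$result_path, "result")
    result_row <- list(parameter = normalizePath(entry$result_path),
                       description = entry$result_description,
                       hash = ing$hash)
  }

  DBI::dbWithTransaction(store$con, {
    ins <- insert_action_rows(store, entry$action, target_ids)
    for (pr in param_rows)
      DBI::dbExecute(
        store$con,
        "INSERT INTO PARAMS (ID_action, parameter, description, hash)
         VALUES (?, ?, ?, ?)",
        params = list(ins$id_action, pr$parameter, pr$description, pr$hash))
    if (!is.null(result_row))
      DBI::dbExecute(
        store$con,
        "INSERT INTO RESULTS (ID_action, parameter, description, hash)
         VALUES (?, ?, ?, ?)",
        params = list(ins$id_action, result_row$parameter,
                      result_row$description, result_row$hash))
    if (store$text_history)
      for (idf in target_ids) append_text_history(store, idf, ins$id_action)
    ins$id_action
  })
}

check_action_exists <- function(store, id_action) {
  n <- DBI::dbGetQuery(
    store$con, "SELECT COUNT(*) AS n FROM ACTIONS WHERE ID_action = ?",
    params = list(as.integer(id_action)))$n
  if (n == 0L) st_validation("unknown action id %d", as.integer(id_action))
  invisible(TRUE)
}

#' Comment an action or its result
#'
#' Comments on processing methods go to `ACTIONS_comment`; comments on
#' quantitation results go to `RESULTS_comment` (which requires that the
#' action actually produced a result). Comments are append-only.
#'
#' @param store A `spectratrack_store`.
#' @param id_action The action being commented.
#' @param text Non-empty comment text.
#' @param target `"action"` or `"result"`.
#' @return The new comment row, invisibly (list of `id_action`, `comment`,
#'   `approved`).
#' @export
add_comment <- function(store, id_action, text,
                        target = c("action", "result")) {
  check_store(store)
  target <- match.arg(target)
  id_action <- as.integer(id_action)
  check_action_exists(store, id_action)
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    st_validation("comment text must be a non-empty string")
  if (target == "result") {
    n <- DBI::dbGetQuery(
      store$con, "SELECT COUNT(*) AS n FROM RESULTS WHERE ID_action = ?",
      params = list(id_action))$n
    if (n == 0L)
      st_validation("action %d has no recorded result", id_action)
  }
  tb <- if (target == "action") "ACTIONS_comment" else "RESULTS_comment"
  DBI::dbExecute(
    store$con,
    sprintf("INSERT INTO %s (ID_action, comment, approved)
             VALUES (?, ?, 'unset')", tb),
    params = list(id_action, text))
  invisible(list(id_action = id_action, comment = text, approved = "unset"))
}

#' Set or clear the approval status of an action
#'
#' Approval is annotation, not history editing: each call appends a status
#' row (with empty comment text, which user comments can never carry) to
#' `ACTIONS_comment`, and the most recent status row wins. Fresh actions
#' are `"unset"`.
#'
#' @param store A `spectratrack_store`.
#' @param id_action The action.
#' @param status `"approved"`, `"not-approved"`, or `"unset"`.
#' @return The effective status, invisibly.
#' @export
set_approval <- function(store, id_action,
                         status = c("approved", "not-approved", "unset")) {
  check_store(store)
  status <- match.arg(status)
  id_action <- as.integer(id_action)
  check_action_exists(store, id_action)
  DBI::dbExecute(
    store$con,
    "INSERT INTO ACTIONS_comment (ID_action, comment, approved)
     VALUES (?, '', ?)",
    params = list(id_action, status))
  invisible(status)
}

#' Current approval status of an action
#'
#' @param store A `spectratrack_store`.
#' @param id_action The action.
#' @return `"approved"`, `"not-approved"`, or `"unset"`.
#' @export
approval_status <- function(store, id_action) {
  check_store(store)
  id_action <- as.integer(id_action)
  check_action_exists(store, id_action)
  row <- DBI::dbGetQuery(
    store$con,
    "SELECT approved FROM ACTIONS_comment
     WHERE ID_action = ? AND comment = ''
     ORDER BY rowid DESC LIMIT 1",
    params = list(id_action))
  if (nrow(row) == 0L) "unset" else row$approved
}

#' Filter recorded actions by approval status
#'
#' @param store A `spectratrack_store`.
#' @param approval `"all"`, `"approved"`, or `"not-approved"`.
#' @return Integer vector of matching `ID_action` values, ascending.
#' @export
filter_actions <- function(store,
                           approval = c("all", "approved", "not-approved")) {
  check_store(store)
  approval <- match.arg(approval)
  ids <- DBI::dbGetQuery(
    store$con, "SELECT ID_action FROM ACTIONS ORDER BY ID_action")$ID_action
  ids <- as.integer(ids)
  if (approval == "all") return(ids)
  keep <- vapply(ids, function(i) approval_status(store, i) == approval,
                 logical(1))
  ids[keep]
}

#' Comments recorded for an action
#'
#' @param store A `spectratrack_store`.
#' @param id_action The action.
#' @param target `"action"` or `"result"`.
#' @return Character vector of comment texts, oldest first.
#' @export
comments_for <- function(store, id_action, target = c("action", "result")) {
  check_store(store)
  target <- match.arg(target)
  id_action <- as.integer(id_action)
  check_action_exists(store, id_action)
  tb <- if (target == "action") "ACTIONS_comment" else "RESULTS_comment"
  DBI::dbGetQuery(
    store$con,
    sprintf("SELECT comment FROM %s
             WHERE ID_action = ? AND comment <> '' ORDER BY rowid", tb),
    params = list(id_action))$comment
}
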