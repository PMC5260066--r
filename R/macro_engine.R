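# Macros: named, ordered, replayable subsets of past actions. A macro
# stores references (ID_action) to history, never copies; replay
# re-executes the referenced actions through registered plugins and
# re-records them as new history, leaving the original rows untouched.

#' Describe a processing plugin
#'
#' A plugin implements one processing method: a unique macro key, a fixed
#' ordered parameter signature, and a function. Preprocessing plugins are
#' called as `fun(dataset, values)` and must return
#' `list(dataset =, entry =)`; quantitation plugins are called as
#' `fun(dataset, values, work_dir)` and must return
#' `list(result_path =, entry =)`.
#'
#' @param key Macro-key string (1–64 chars, not a reserved keyword).
#' @param signature List of `list(description =, kind =)` with kind one of
#'   `"number"`, `"text"`, `"file"`.
#' @param fun The plugin function.
#' @param is_quantitation Whether the plugin produces a result file.
#' @return A `plugin_spec` object.
#' @export
plugin_spec <- function(key, signature, fun, is_quantitation = FALSE) {
  if (!is.character(key) || length(key) != 1L || !nzchar(key) ||
      nchar(key) > 64L)
    st_validation("plugin key must be a 1-64 character string")
  if (key %in% ST_RESERVED_ACTIONS)
    st_validation("'%s' is a reserved action keyword", key)
  ok <- vapply(signature, function(s)
    is.list(s) && !is.null(s$description) && nzchar(s$description) &&
      s$kind %in% c("number", "text", "file"), logical(1))
  if (length(signature) && !all(ok))
    st_validation("malformed plugin signature for '%s'", key)
  if (!is.function(fun)) st_validation("plugin fun must be a function")
  structure(list(key = key, signature = signature, fun = fun,
                 is_quantitation = isTRUE(is_quantitation)),
            class = "plugin_spec")
}

#' Create an empty plugin registry
#'
#' @return A `plugin_registry` environment mapping keys to
#'   [plugin_spec()]s.
#' @export
plugin_registry <- function() {
  reg <- new.env(parent = emptyenv())
  class(reg) <- "plugin_registry"
  reg
}

#' Register a plugin under its macro key
#'
#' @param plugins A [plugin_registry()].
#' @param spec A [plugin_spec()].
#' @return The registry, invisibly.
#' @export
register_plugin <- function(plugins, spec) {
  if (!inherits(plugins, "plugin_registry"))
    st_validation("not a plugin registry")
  if (!inherits(spec, "plugin_spec"))
    st_validation("not a plugin_spec")
  if (exists(spec$key, envir = plugins, inherits = FALSE))
    st_validation("plugin key '%s' is already registered", spec$key)
  assign(spec$key, spec, envir = plugins)
  invisible(plugins)
}

resolve_plugin <- function(plugins, key) {
  if (!exists(key, envir = plugins, inherits = FALSE))
    st_resolution("no plugin registered for action key '%s'", key)
  get(key, envir = plugins, inherits = FALSE)
}

# Signatures of the built-in toy operators.
ST_BUILTIN_SIGNATURES <- list(
  ZERO_FILL = list(list(description = "Target number of points",
                        kind = "number")),
  APODIZE = list(list(description = "Exponential line broadening [Hz]",
                      kind = "number")),
  PHASE0 = list(list(description = "Zero-order phase [deg]",
                     kind = "number")),
  SCALE = list(list(description = "Scaling factor", kind = "number")),
  QUANTIFY_LLS = list(
    list(description = "Metabolite basis set file (.ml)", kind = "file"),
    list(description = "Processing options file (.op)", kind = "file"))
)

plugin_signature <- function(key) {
  sig <- ST_BUILTIN_SIGNATURES[[key]]
  if (is.null(sig)) st_validation("unknown processing key '%s'", key)
  sig
}

#' Plugin registry pre-loaded with the toy pipeline operators
#'
#' Registers `ZERO_FILL`, `APODIZE`, `PHASE0`, `SCALE` (preprocessing) and
#' `QUANTIFY_LLS` (quantitation), all backed by [apply_processing()] and
#' [mock_quantitation()].
#'
#' @return A [plugin_registry()].
#' @export
default_plugins <- function() {
  reg <- plugin_registry()
  for (key in c("ZERO_FILL", "APODIZE", "PHASE0", "SCALE"))
    register_plugin(reg, plugin_spec(
      key, ST_BUILTIN_SIGNATURES[[key]],
      local({
        k <- key
        function(dataset, values) apply_processing(k, dataset, values)
      })))
  register_plugin(reg, plugin_spec(
    "QUANTIFY_LLS", ST_BUILTIN_SIGNATURES$QUANTIFY_LLS,
    function(dataset, values, work_dir) {
      mock_quantitation(
        dataset, values[[1]], values[[2]],
        out_path = file.path(work_dir,
                             paste0(dataset$label, "_QUANT.results")))
    },
    is_quantitation = TRUE))
  reg
}

#' Save a named macro from past actions
#'
#' Writes one `MACRO` row and one `MACRO_contents` row per action, sharing
#' the newly generated `ID_macro`, with positions recording the order.
#' The bookkeeping actions `LOAD_FILE` and `SAVE` cannot be part of a
#' macro.
#'
#' @param store A `spectratrack_store`.
#' @param name Unique non-empty macro name.
#' @param comment Free-text comment.
#' @param action_ids Ordered, non-empty vector of existing `ID_action`s.
#' @return The new `ID_macro` (integer).
#' @export
create_macro <- function(store, name, comment = "", action_ids) {
  check_store(store)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    st_validation("macro name must be a non-empty string")
  if (length(action_ids) == 0L)
    st_validation("a macro needs at least one action")
  action_ids <- as.integer(action_ids)
  dup <- DBI::dbGetQuery(
    store$con, "SELECT COUNT(*) AS n FROM MACRO WHERE name = ?",
    params = list(name))$n
  if (dup > 0L) st_validation("macro name '%s' is already in use", name)
  for (ida in action_ids) {
    check_action_exists(store, ida)
    key <- DBI::dbGetQuery(
      store$con, "SELECT action FROM ACTIONS WHERE ID_action = ?",
      params = list(ida))$action
    if (key %in% ST_RESERVED_ACTIONS)
      st_validation("action %d (%s) cannot be part of a macro", ida, key)
  }
  DBI::dbWithTransaction(store$con, {
    DBI::dbExecute(store$con,
                   "INSERT INTO MACRO (name, comment) VALUES (?, ?)",
                   params = list(name, comment))
    id_macro <- as.integer(DBI::dbGetQuery(
      store$con, "SELECT last_insert_rowid() AS id")$id)
    for (pos in seq_along(action_ids))
      DBI::dbExecute(
        store$con,
        "INSERT INTO MACRO_contents (ID_macro, ID_action, position)
         VALUES (?, ?, ?)",
        params = list(id_macro, action_ids[pos], pos))
    id_macro
  })
}

#' List stored macros
#'
#' @param store A `spectratrack_store`.
#' @return data.frame with `ID_macro`, `name`, `comment`, `n_actions`.
#' @export
list_macros <- function(store) {
  check_store(store)
  DBI::dbGetQuery(
    store$con,
    "SELECT m.ID_macro, m.name, m.comment, COUNT(c.ID_action) AS n_actions
     FROM MACRO m LEFT JOIN MACRO_contents c ON m.ID_macro = c.ID_macro
     GROUP BY m.ID_macro ORDER BY m.ID_macro")
}

macro_action_ids <- function(store, id_macro) {
  id_macro <- as.integer(id_macro)
  n <- DBI::dbGetQuery(
    store$con, "SELECT COUNT(*) AS n FROM MACRO WHERE ID_macro = ?",
    params = list(id_macro))$n
  if (n == 0L) st_validation("unknown macro id %d", id_macro)
  as.integer(DBI::dbGetQuery(
    store$con,
    "SELECT ID_action FROM MACRO_contents WHERE ID_macro = ?
     ORDER BY position",
    params = list(id_macro))$ID_action)
}

#' Export a macro as batch text
#'
#' Renders the macro's actions, with their recorded parameters, in the
#' same batch dialect as `processing.batch` (see [render_batch()]).
#' Deterministic: exporting twice yields byte-identical text.
#'
#' @param store A `spectratrack_store`.
#' @param id_macro The macro.
#' @param out_path Optional file to write the text to.
#' @return The batch text (a single string); written to `out_path` too
#'   when given.
#' @export
export_macro_text <- function(store, id_macro, out_path = NULL) {
  check_store(store)
  ids <- macro_action_ids(store, id_macro)
  items <- lapply(ids, function(ida) {
    link <- DBI::dbGetQuery(
      store$con,
      "SELECT ID, ID_file FROM FILES_ACTIONS WHERE ID_action = ?
       ORDER BY ID LIMIT 1",
      params = list(ida))
    history_item(store, ida, link$ID_file[1], link$ID[1])
  })
  txt <- render_batch(items)
  if (!is.null(out_path)) {
    con <- file(out_path, open = "wb")
    writeChar(txt, con, eos = NULL)
    close(con)
  }
  txt
}

# Recorded parameter values of one action, in PARAMS ID order.
recorded_param_values <- function(store, id_action) {
  DBI::dbGetQuery(
    store$con,
    "SELECT parameter, hash FROM PARAMS WHERE ID_action = ? ORDER BY ID",
    params = list(as.integer(id_action)))
}

# A file parameter is replayed from its managed copy when present (the
# exact bytes used originally), falling back to the recorded path.
resolve_param_file <- function(store, parameter, hash) {
  managed <- file.path(store$param_files_dir, hash)
  if (nzchar(hash) && file.exists(managed)) managed else parameter
}

#' Replay a macro on a dataset
#'
#' Executes the macro's actions in stored order against `dataset`, using
#' each action's recorded parameter values except where `overrides`
#' substitutes new ones. Every executed step is re-recorded through
#' [record_action()] as new history against `id_file` (which must be
#' open); the original rows are never modified. For the deterministic toy
#' plugins, replaying on byte-identical input reproduces byte-identical
#' output.
#'
#' @param store A `spectratrack_store`.
#' @param registry An [open_files_registry()]; `id_file` must be open.
#' @param plugins A [plugin_registry()] resolving every macro key.
#' @param id_macro The macro to replay.
#' @param dataset The [fid_dataset()] to process.
#' @param id_file The open file id the replayed actions are recorded
#'   against.
#' @param overrides List of `list(position =, param =, value =)` — replace
#'   the `param`-th parameter of the `position`-th macro step.
#' @param work_dir Directory for result files written by quantitation
#'   steps.
#' @return A `replay_report`: data.frame `steps` (`position`,
#'   `original_id_action`, `new_id_action`, `overridden`), plus `dataset`
#'   (final state) and `result_paths`.
#' @export
replay_macro <- function(store, registry, plugins, id_macro, dataset,
                         id_file, overrides = list(),
                         work_dir = tempfile("replay")) {
  check_store(store); check_registry(registry)
  if (!inherits(plugins, "plugin_registry"))
    st_validation("not a plugin registry")
  id_file <- as.integer(id_file)
  if (!(id_file %in% registry$ids))
    st_state("file id %d is not open", id_file)
  ids <- macro_action_ids(store, id_macro)
  keys <- vapply(ids, function(ida) DBI::dbGetQuery(
    store$con, "SELECT action FROM ACTIONS WHERE ID_action = ?",
    params = list(ida))$action, "")
  specs <- lapply(keys, function(k) resolve_plugin(plugins, k))

  recorded <- lapply(ids, function(ida) recorded_param_values(store, ida))
  for (ov in overrides) {
    if (!is.list(ov) || is.null(ov$position) || is.null(ov$param) ||
        is.null(ov$value))
      st_validation("each override needs position, param and value")
    if (ov$position < 1L || ov$position > length(ids))
      st_validation("override position %d out of range", ov$position)
    if (ov$param < 1L || ov$param > nrow(recorded[[ov$position]]))
      st_validation("override parameter index %d out of range for step %d",
                    ov$param, ov$position)
  }

  if (!dir.exists(work_dir)) dir.create(work_dir, recursive = TRUE)
  steps <- data.frame(position = integer(0), original_id_action = integer(0),
                      new_id_action = integer(0), overridden = logical(0))
  result_paths <- character(0)
  for (pos in seq_along(ids)) {
    spec <- specs[[pos]]
    rec <- recorded[[pos]]
    values <- as.list(rec$parameter)
    overridden <- FALSE
    for (ov in overrides) {
      if (ov$position == pos) {
        values[[ov$param]] <- as.character(ov$value)
        rec$hash[ov$param] <- ""   # an override supersedes the stored file
        overridden <- TRUE
      }
    }
    for (j in seq_along(values)) {
      kind <- spec$signature[[j]]$kind
      if (kind == "file")
        values[[j]] <- resolve_param_file(store, values[[j]], rec$hash[j])
    }
    out <- if (spec$is_quantitation)
      spec$fun(dataset, values, work_dir)
    else
      spec$fun(dataset, values)
    if (!is.null(out$dataset)) dataset <- out$dataset
    if (!is.null(out$result_path))
      result_paths <- c(result_paths, out$result_path)
    new_id <- record_action(store, registry, out$entry, id_file)
    steps <- rbind(steps, data.frame(
      position = pos, original_id_action = ids[pos],
      new_id_action = new_id, overridden = overridden))
  }
  structure(list(steps = steps, dataset = dataset,
                 result_paths = result_paths),
            class = "replay_report")
}

#' @export
print.replay_report <- function(x, ...) {
  cat(sprintf("<replay report: %d step(s), %d result file(s)>\n",
              nrow(x$steps), length(x$result_paths)))
  print(x$steps)
  invisible(x)
}
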