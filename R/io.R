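# Readers and writers for the package's plain-text interchange formats:
# network definitions (JSON, with YAML accepted as an equivalent dialect on
# read), parameter sets (JSON), case files (CSV or JSON), panel ratings and
# agreement tables (CSV).

#' Write / read a network definition
#'
#' The document has three keys: `metadata`, `nodes` (list of objects with
#' `name`, `layer`, `display_name`, `description`, `provenance`, `states`)
#' and `edges` (`parent`, `child`, `elicited_strength`, `provenance`).
#' Writing then reading reproduces the structure element-wise.
#'
#' @param net an `ssp_network`.
#' @param path file path; `write_network` infers YAML from a
#'   `.yaml`/`.yml` extension, JSON otherwise.
#' @return `read_network` returns an `ssp_network`; `write_network` returns
#'   `path` invisibly.
#' @export
write_network <- function(net, path) {
  doc <- list(
    metadata = net$metadata,
    nodes = lapply(seq_len(nrow(net$nodes)), function(i) {
      n <- net$nodes[i, ]
      list(name = n$name, layer = n$layer, display_name = n$display_name,
           description = n$description, provenance = n$provenance,
           states = as.list(net$states[[n$name]]))
    }),
    edges = lapply(seq_len(nrow(net$edges)), function(i) {
      e <- net$edges[i, ]
      list(parent = e$parent, child = e$child,
           elicited_strength = if (is.na(e$elicited_strength)) NULL
           else e$elicited_strength,
           provenance = e$provenance)
    }))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                         pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path))
    stop("network file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (is.null(doc$nodes))
    stop("network file '", path, "' has no 'nodes' key", call. = FALSE)
  req <- function(x, field, what) {
    if (is.null(x[[field]]))
      stop("network file '", path, "': ", what, " is missing field '",
           field, "'", call. = FALSE)
    x[[field]]
  }
  nodes <- lapply(doc$nodes, function(nd) {
    nm <- req(nd, "name", "a node")
    ssp_node(nm,
             layer = req(nd, "layer", paste0("node '", nm, "'")),
             display_name = if (is.null(nd$display_name)) nm
             else nd$display_name,
             description = if (is.null(nd$description)) "" else nd$description,
             provenance = if (is.null(nd$provenance)) "placeholder"
             else nd$provenance,
             states = if (is.null(nd$states)) c("present", "absent")
             else unlist(nd$states))
  })
  edges <- lapply(doc$edges, function(ed) {
    ssp_edge(req(ed, "parent", "an edge"), req(ed, "child", "an edge"),
             elicited_strength = if (is.null(ed$elicited_strength))
               NA_integer_ else ed$elicited_strength,
             provenance = if (is.null(ed$provenance)) "placeholder"
             else ed$provenance)
  })
  metadata <- if (is.null(doc$metadata)) list() else doc$metadata
  network_definition(nodes, edges, metadata)
}

#' Write / read a parameter set
#'
#' JSON with a `priors` map and a `tables` map; each table is either
#' `{"type": "noisy_or", "leak": ..., "links": {...}}` or `{"type":
#' "table", "parents": [...], "rows": [...]}`. Probabilities are written
#' with 15 significant digits so a round trip preserves them to full double
#' precision.
#'
#' @param params an `ssp_params`.
#' @param path file path.
#' @param net optionally, the network; when supplied, all noisy-OR specs
#'   are expanded to explicit tables on export.
#' @return `read_params` returns an `ssp_params`; `write_params` returns
#'   `path` invisibly.
#' @export
write_params <- function(params, path, net = NULL) {
  tables <- lapply(params$tables, function(tb) {
    if (inherits(tb, "noisy_or_spec") && !is.null(net))
      tb <- noisy_or_table(tb, net)
    if (inherits(tb, "noisy_or_spec")) {
      list(type = "noisy_or", leak = tb$leak,
           links = as.list(tb$link_strength))
    } else {
      rows <- lapply(seq_len(nrow(tb$prob)), function(i) {
        list(parent_states = as.list(tb$combos[i, , drop = TRUE]),
             p = as.list(stats::setNames(as.numeric(tb$prob[i, ]),
                                         colnames(tb$prob))))
      })
      list(type = "table", parents = as.list(tb$parents),
           states = as.list(tb$states), rows = rows)
    }
  })
  doc <- list(priors = as.list(params$priors), tables = tables)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 15,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path))
    stop("parameter file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  priors <- unlist(doc$priors)
  tables <- lapply(names(doc$tables), function(child) {
    tb <- doc$tables[[child]]
    if (identical(tb$type, "noisy_or")) {
      noisy_or_spec(child, tb$leak, unlist(tb$links))
    } else if (identical(tb$type, "table")) {
      parents <- unlist(tb$parents)
      states <- unlist(tb$states)
      combos <- as.data.frame(
        do.call(rbind, lapply(tb$rows, function(r)
          unlist(r$parent_states)[parents])),
        stringsAsFactors = FALSE)
      names(combos) <- parents
      prob <- do.call(rbind, lapply(tb$rows, function(r)
        unlist(r$p)[states]))
      colnames(prob) <- states
      cond_table(child, parents, combos, prob, states)
    } else {
      stop("parameter file '", path, "': table for '", child,
           "' has unknown type", call. = FALSE)
    }
  })
  names(tables) <- names(doc$tables)
  parameter_set(priors, tables)
}

#' Write / read patient case files
#'
#' CSV dialect: columns `id`, `source`, one `ev_<node>` column per evidence
#' node with values `present`/`absent`/`unknown` (case-insensitive on read;
#' `unknown` rows are omitted from the evidence) and one `label_<condition>`
#' column per labeled condition with 0/1 values. A JSON dialect (list of
#' case objects) is accepted on read via the `.json` extension.
#'
#' @param cases list of `ssp_case` records.
#' @param path file path (`.csv` or `.json`).
#' @param net optional `ssp_network` used to check node names on read.
#' @return `read_cases` returns a list of `ssp_case`; `write_cases` returns
#'   `path` invisibly.
#' @export
write_cases <- function(cases, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- lapply(cases, function(cs)
      list(id = cs$id, source = cs$source,
           evidence = as.list(cs$evidence),
           labels = as.list(cs$labels)))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  ev_nodes <- sort(unique(as.character(unlist(lapply(cases, function(cs)
    names(cs$evidence))))))
  lab_conds <- sort(unique(as.character(unlist(lapply(cases, function(cs)
    names(cs$labels))))))
  prefix <- function(p, x) if (length(x)) paste0(p, x) else character(0)
  rows <- lapply(cases, function(cs) {
    ev <- vapply(ev_nodes, function(n)
      if (n %in% names(cs$evidence)) cs$evidence[[n]] else "unknown",
      character(1))
    lb <- vapply(lab_conds, function(cd)
      if (cd %in% names(cs$labels)) as.integer(cs$labels[[cd]])
      else NA_integer_, integer(1))
    c(list(id = cs$id, source = cs$source),
      as.list(stats::setNames(ev, prefix("ev_", ev_nodes))),
      as.list(stats::setNames(lb, prefix("label_", lab_conds))))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cases
#' @export
read_cases <- function(path, net = NULL) {
  if (!file.exists(path))
    stop("case file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    cases <- lapply(doc, function(cs)
      case_record(cs$id,
                  evidence = tolower(unlist(cs$evidence)),
                  labels = vapply(cs$labels, as.integer, integer(1)),
                  source = if (is.null(cs$source)) "unspecified"
                  else cs$source))
  } else {
    first <- readLines(path, n = 1L)
    if (!length(first) || !nzchar(first)) {
      warning("case file '", path, "' is empty", call. = FALSE)
      return(list())
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
    if (!nrow(df)) {
      warning("case file '", path, "' contains no cases", call. = FALSE)
      return(list())
    }
    ev_cols <- grep("^ev_", names(df), value = TRUE)
    lab_cols <- grep("^label_", names(df), value = TRUE)
    cases <- lapply(seq_len(nrow(df)), function(i) {
      ev <- character(0)
      for (col in ev_cols) {
        val <- tolower(as.character(df[i, col]))
        if (is.na(val) || val == "unknown" || !nzchar(val)) next
        if (!val %in% c("present", "absent"))
          stop("case file '", path, "', row ", i, ": illegal evidence ",
               "value '", df[i, col], "' in column ", col, call. = FALSE)
        ev[[sub("^ev_", "", col)]] <- val
      }
      lb <- integer(0)
      for (col in lab_cols) {
        val <- df[i, col]
        if (is.na(val)) next
        if (!val %in% c(0, 1))
          stop("case file '", path, "', row ", i, ": illegal label '",
               val, "' in column ", col, call. = FALSE)
        lb[[sub("^label_", "", col)]] <- as.integer(val)
      }
      id <- if ("id" %in% names(df)) df$id[i] else paste0("case_", i)
      src <- if ("source" %in% names(df)) df$source[i] else "unspecified"
      tryCatch(case_record(id, ev, lb, src),
               error = function(e)
                 stop("case file '", path, "', row ", i, ": ",
                      conditionMessage(e), call. = FALSE))
    })
  }
  if (!is.null(net)) {
    for (cs in cases) {
      unknown <- setdiff(names(cs$evidence), node_names(net))
      if (length(unknown))
        stop("case '", cs$id, "' names node(s) absent from the network: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  cases
}

#' Read a panel rating matrix from CSV
#'
#' Wide form: one row per participant, one column per item (plus an
#' optional leading `participant` column). Long form: columns
#' `participant`, `item`, `score`. The form is detected from the header.
#'
#' @param path CSV path.
#' @return integer matrix items x participants.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path))
    stop("ratings file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("participant", "item", "score") %in% names(df))) {
    items <- unique(df$item)
    parts <- unique(df$participant)
    m <- matrix(NA_integer_, nrow = length(items), ncol = length(parts),
                dimnames = list(items, parts))
    for (i in seq_len(nrow(df)))
      m[df$item[i], as.character(df$participant[i])] <-
        as.integer(df$score[i])
    return(m)
  }
  id_col <- intersect(c("participant", "rater"), names(df))
  parts <- if (length(id_col)) as.character(df[[id_col[1]]])
  else paste0("participant_", seq_len(nrow(df)))
  vals <- df[setdiff(names(df), id_col)]
  m <- t(as.matrix(vals))
  storage.mode(m) <- "integer"
  colnames(m) <- parts
  m
}

#' Read a categorical agreement table from CSV
#'
#' Long form with columns `item`, `rater`, `category`.
#'
#' @param path CSV path.
#' @return character matrix items x raters (`NA` for missing ratings).
#' @export
read_agreement_table <- function(path) {
  if (!file.exists(path))
    stop("agreement file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item", "rater", "category") %in% names(df)))
    stop("agreement file '", path,
         "' must have columns item, rater, category", call. = FALSE)
  items <- unique(df$item)
  raters <- unique(df$rater)
  m <- matrix(NA_character_, nrow = length(items), ncol = length(raters),
              dimnames = list(items, raters))
  for (i in seq_len(nrow(df)))
    m[as.character(df$item[i]), as.character(df$rater[i])] <-
      as.character(df$category[i])
  m
}
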