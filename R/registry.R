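# Unified S-haplotype nomenclature: alias loading, transitive unification,
# lookup, and registration of novel haplotypes.

S_TEAMS <- c("okamoto", "lim", "kim_d", "other")

# first integer embedded in a label ("S22" -> 22); Inf when none
.label_num <- function(label) {
  vapply(label, function(l) {
    m <- regmatches(l, regexpr("[0-9]+", l))
    if (length(m) == 0L) Inf else as.numeric(m)
  }, numeric(1), USE.NAMES = FALSE)
}

# split one table cell into alias entries: ";" separates independent
# aliases, a parenthesized token is a synonym label of the same team
.parse_cell <- function(cell, team, row) {
  cell <- trimws(cell)
  if (!nzchar(cell)) return(NULL)
  out <- list()
  for (entry in trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])) {
    if (!nzchar(entry)) next
    syn <- regmatches(entry, gregexpr("\\(([^)]*)\\)", entry))[[1L]]
    syn <- trimws(gsub("[()]", "", syn))
    primary <- trimws(gsub("\\([^)]*\\)", "", entry))
    if (!nzchar(primary)) stop("row ", row, ": alias cell '", cell,
                               "' has no primary label", call. = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      row = row, team = team,
      label = c(primary, syn[nzchar(syn)]),
      is_synonym = c(FALSE, rep(TRUE, sum(nzchar(syn)))),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Load a team alias cross-reference table
#'
#' Reads a TSV in which each row lists the names that different research
#' teams gave to one and the same S haplotype (columns `okamoto`, `lim`,
#' `kim_d`, `other`, plus optional `nau_name` and similarity annotation
#' columns). All non-empty cells of a row are declared mutually equivalent.
#' A parenthesized token inside a cell (e.g. `"S22 (S7)"`) is a synonym of
#' the same team's record; `";"` separates independent aliases in one cell.
#'
#' @param path path to the TSV file (UTF-8; empty cell = absent).
#' @return an object of class `alias_table`: a list with `records`
#'   (data frame `row`, `team`, `label`, `is_synonym`), `similarities`
#'   (annotation columns, when present) and `n_rows`.
#' @seealso [unify_haplotypes()]
#' @export
load_alias_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, na.strings = NULL,
                           quote = "", comment.char = "")
  missing_cols <- setdiff(S_TEAMS, names(tab))
  if (length(missing_cols))
    stop("alias table lacks team column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  recs <- list()
  for (i in seq_len(nrow(tab))) {
    row_recs <- do.call(rbind, lapply(S_TEAMS, function(tm)
      .parse_cell(tab[[tm]][i], tm, i)))
    if (is.null(row_recs))
      stop("row ", i, " is malformed: no non-empty team cell", call. = FALSE)
    recs[[i]] <- row_recs
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- data.frame(row = integer(), team = character(),
                          label = character(), is_synonym = logical())
  key <- paste(records$team, records$label, sep = "|")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    rows <- unique(records$row[key == d])
    stop("duplicate alias ", d, " appears in rows ",
         paste(rows, collapse = " and "), call. = FALSE)
  }
  sim_cols <- intersect(c("nau_name", "sim_okamoto_lim", "sim_lim_kimd"),
                        names(tab))
  structure(list(records = records,
                 similarities = tab[, sim_cols, drop = FALSE],
                 n_rows = nrow(tab)),
            class = "alias_table")
}

#' Unify alias records into a non-redundant S-haplotype registry
#'
#' Computes the connected components of the equivalence-link graph (row
#' membership links all aliases of a row; transitive closure via graph
#' components) and numbers each component `NAU-S1`, `NAU-S2`, ...
#'
#' Components are ordered deterministically: by the highest-priority team
#' present among the component's primary labels (okamoto < lim < kim_d <
#' other), then by the numeric part of the smallest primary label of that
#' team. This reproduces the published numbering for all entries anchored on
#' a team-specific serial number.
#'
#' @param table an `alias_table` from [load_alias_table()].
#' @return an object of class `s_registry`: list with `members` (data frame
#'   `nau_name`, `team`, `label`, `is_synonym`), `novel` (named character
#'   vector mapping registered novel query ids to names) and `n_classes`.
#' @export
unify_haplotypes <- function(table) {
  stopifnot(inherits(table, "alias_table"))
  rec <- table$records
  if (nrow(rec) == 0L)
    return(structure(list(members = data.frame(nau_name = character(),
                                               team = character(),
                                               label = character(),
                                               is_synonym = logical()),
                          novel = character(), n_classes = 0L),
                     class = "s_registry"))
  node <- paste(rec$team, rec$label, sep = "|")
  # chain-link all aliases within each row; components give the closure
  edges <- do.call(rbind, lapply(split(node, rec$row), function(v) {
    if (length(v) < 2L) return(NULL)
    data.frame(from = v[-length(v)], to = v[-1L], stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = unique(node)))
  comp <- igraph::components(g)$membership[node]
  # anchor of a component: highest-priority team among primary labels,
  # then smallest (numeric, lexicographic) primary label of that team
  anchors <- do.call(rbind, lapply(split(seq_len(nrow(rec)), comp), function(idx) {
    prim <- rec[idx, ][!rec$is_synonym[idx], , drop = FALSE]
    if (nrow(prim) == 0L) prim <- rec[idx, , drop = FALSE]
    pri <- min(match(prim$team, S_TEAMS))
    lab <- prim$label[prim$team == S_TEAMS[pri]]
    key <- order(.label_num(lab), lab)[1L]
    data.frame(comp = comp[idx][1L], team_pri = pri,
               num = .label_num(lab[key]), label = lab[key],
               stringsAsFactors = FALSE)
  }))
  anchors <- anchors[order(anchors$team_pri, anchors$num, anchors$label), ]
  nau <- stats::setNames(paste0("NAU-S", seq_len(nrow(anchors))), anchors$comp)
  members <- data.frame(nau_name = unname(nau[as.character(comp)]),
                        team = rec$team, label = rec$label,
                        is_synonym = rec$is_synonym,
                        stringsAsFactors = FALSE)
  members <- unique(members) # a label may be declared in several rows
  members <- members[order(.registry_index(members$nau_name)), ]
  rownames(members) <- NULL
  structure(list(members = members, novel = character(),
                 n_classes = nrow(anchors)),
            class = "s_registry")
}

.registry_index <- function(nau_name) as.integer(sub("^NAU-S", "", nau_name))

#' @export
print.s_registry <- function(x, ...) {
  cat("S-haplotype registry:", x$n_classes, "unified classes,",
      nrow(x$members), "alias members,",
      length(x$novel), "novel registrations\n")
  invisible(x)
}

#' Look up the unified name of a team-specific S-allele label
#'
#' @param registry an `s_registry`.
#' @param team one of `"okamoto"`, `"lim"`, `"kim_d"`, `"other"`.
#' @param label team-specific label (synonyms resolve too).
#' @return the `NAU-S` name, or `NA_character_` when the (team, label) pair
#'   is not registered (an unknown team is an error, not a miss).
#' @export
s_lookup <- function(registry, team, label) {
  stopifnot(inherits(registry, "s_registry"))
  team <- match.arg(team, S_TEAMS)
  hit <- registry$members$nau_name[registry$members$team == team &
                                     registry$members$label == label]
  if (length(hit) == 0L) NA_character_ else hit[1L]
}

#' Members of one unified haplotype (reverse lookup)
#'
#' @param registry an `s_registry`.
#' @param nau_name unified name, e.g. `"NAU-S16"`.
#' @return data frame of the (team, label) members of that class.
#' @export
registry_members <- function(registry, nau_name) {
  stopifnot(inherits(registry, "s_registry"))
  out <- registry$members[registry$members$nau_name == nau_name, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Register a novel S haplotype
#'
#' Assigns the next unused `NAU-S` serial number to a query flagged as novel
#' by the typing step. Registration is idempotent: re-registering the same
#' query id returns the previously assigned name.
#'
#' @param registry an `s_registry`.
#' @param query_id identifier of the novel query sequence.
#' @return list with `registry` (grown by one singleton class, unless the id
#'   was already registered) and `nau_name` (the assigned name).
#' @export
register_novel <- function(registry, query_id) {
  stopifnot(inherits(registry, "s_registry"), is.character(query_id),
            length(query_id) == 1L, nzchar(query_id))
  if (query_id %in% names(registry$novel))
    return(list(registry = registry, nau_name = registry$novel[[query_id]]))
  existing <- .registry_index(registry$members$nau_name)
  nxt <- if (length(existing) == 0L) 1L else max(existing) + 1L
  name <- paste0("NAU-S", nxt)
  registry$members <- rbind(registry$members,
                            data.frame(nau_name = name, team = "other",
                                       label = query_id, is_synonym = FALSE,
                                       stringsAsFactors = FALSE))
  registry$novel[[query_id]] <- name
  registry$n_classes <- registry$n_classes + 1L
  list(registry = registry, nau_name = name)
}
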