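# ---------------------------------------------------------------------------
# Navigation: single steps, scripted sessions, per-taxon path
# reconstruction, whole-key statistics, exhaustive path enumeration.
#
# A path's length is counted in decisions (edges taken), not couplets
# visited; its last step is the terminal lead itself.
# ---------------------------------------------------------------------------

find_lead <- function(key, couplet_id, lead_label) {
  cp <- get_couplet(key, couplet_id)
  for (ld in cp$leads) if (ld$label == lead_label) return(ld)
  stop("unknown lead '", lead_label, "' at couplet ", couplet_id,
       "; options: ",
       paste(vapply(cp$leads, function(l) l$label, character(1)),
             collapse = ", "),
       call. = FALSE)
}

lead_options <- function(cp) {
  data.frame(label = vapply(cp$leads, function(l) l$label, character(1)),
             statement = vapply(cp$leads, function(l) l$statement,
                                character(1)),
             stringsAsFactors = FALSE)
}

new_path <- function(couplets, labels, terminal) {
  structure(
    list(steps = data.frame(couplet = as.integer(couplets),
                            label = as.character(labels),
                            stringsAsFactors = FALSE),
         terminal = terminal),
    class = "key_path")
}

#' Take one step through a key
#'
#' Resolves a single lead choice.  Returns the lead's target unchanged: an
#' integer couplet reference (class `couplet_ref`) when the lead continues,
#' or the [taxon_terminal()] when it ends an identification.
#'
#' @param key An [identification_key()].
#' @param couplet_id Couplet to answer.
#' @param lead_label Letter of the chosen lead.
#' @return A `couplet_ref` integer or a `taxon_terminal`.  Unknown couplets
#'   or labels raise an error listing the valid options.
#' @export
#' @examples
#' key_step(load_builtin_key(), 1, "b")   # -> couplet 43
key_step <- function(key, couplet_id, lead_label) {
  ld <- find_lead(key, couplet_id, lead_label)
  if (!is.null(ld$next_id)) structure(ld$next_id, class = "couplet_ref")
  else ld$taxon
}

#' Run an identification session
#'
#' Applies an ordered vector of lead labels starting from the root.  A
#' session is a value, not hidden state: the answer list fully determines
#' the position, so any partial session can be resumed by re-running with
#' more answers appended.
#'
#' @param key An [identification_key()].
#' @param answers Character vector of lead labels, possibly empty.
#' @return An object of class `key_session`.  When a terminal is reached:
#'   `complete = TRUE`, `path` (a `key_path`) and `terminal`.  Otherwise:
#'   `complete = FALSE`, `at` (pending couplet id), `options` (data frame of
#'   label and statement) and `steps` so far.  An invalid answer raises an
#'   error reporting its position and the valid options; answers left over
#'   after a terminal are also an error.
#' @export
#' @examples
#' run_session(load_builtin_key(), c("a", "a", "b"))   # -> Heteropsammia
run_session <- function(key, answers = character()) {
  stopifnot(inherits(key, "identification_key"))
  answers <- as.character(answers)
  at <- key$root
  couplets <- integer(); labels <- character()
  for (k in seq_along(answers)) {
    ld <- tryCatch(
      find_lead(key, at, answers[k]),
      error = function(e)
        stop("invalid answer at position ", k, ": ", conditionMessage(e),
             call. = FALSE))
    couplets <- c(couplets, at); labels <- c(labels, ld$label)
    if (!is.null(ld$taxon)) {
      if (k < length(answers))
        stop("terminal reached at position ", k, " but ",
             length(answers) - k, " answer(s) remain", call. = FALSE)
      return(structure(
        list(complete = TRUE,
             path = new_path(couplets, labels, ld$taxon),
             terminal = ld$taxon),
        class = "key_session"))
    }
    at <- ld$next_id
  }
  cp <- get_couplet(key, at)
  structure(
    list(complete = FALSE, at = at, options = lead_options(cp),
         steps = data.frame(couplet = couplets, label = labels,
                            stringsAsFactors = FALSE)),
    class = "key_session")
}

#' @export
print.key_session <- function(x, ...) {
  if (x$complete) {
    cat("<key_session> complete in", nrow(x$path$steps), "decisions:",
        format_steps(x$path$steps), "\n")
    print(x$terminal)
  } else {
    cat("<key_session> pending at couplet ", x$at, "\n", sep = "")
    for (i in seq_len(nrow(x$options)))
      cat("  ", x$options$label[i], ": ", x$options$statement[i], "\n",
          sep = "")
  }
  invisible(x)
}

format_steps <- function(steps) {
  paste(paste0(steps$couplet, steps$label), collapse = " -> ")
}

#' @export
print.key_path <- function(x, ...) {
  cat(format_steps(x$steps), "->", format(x$terminal), "\n")
  invisible(x)
}

# parent map: for each couplet id, list of (parent id, label) pairs
parent_map <- function(key) {
  edges <- edge_table(key)
  split(edges[, c("from", "label")], as.character(edges$to))
}

# all root paths to a couplet, as lists of (couplet, label) step frames
paths_to_couplet <- function(key, id, parents, seen = integer()) {
  if (id %in% seen) stop("cycle at couplet ", id, call. = FALSE)
  if (id == key$root)
    return(list(data.frame(couplet = integer(), label = character(),
                           stringsAsFactors = FALSE)))
  up <- parents[[as.character(id)]]
  if (is.null(up) || !nrow(up)) return(list())   # unreachable
  out <- list()
  for (i in seq_len(nrow(up))) {
    for (pre in paths_to_couplet(key, up$from[i], parents, c(seen, id))) {
      out[[length(out) + 1L]] <-
        rbind(pre, data.frame(couplet = up$from[i], label = up$label[i],
                              stringsAsFactors = FALSE))
    }
  }
  out
}

#' All paths leading to a taxon
#'
#' Reconstructs, by walking parent links back to the root, every
#' identification path that ends at the given taxon — one per terminal for
#' tree-shaped keys, more when a terminal's couplet is reachable several
#' ways.  Variable taxa keyed "(in part)" at several terminals therefore
#' yield several paths.
#'
#' @param key An [identification_key()].
#' @param genus Genus name.
#' @param subgenus Optional subgenus name; `NULL` matches only terminals
#'   without a subgenus.
#' @return List of `key_path` objects, ordered by terminal position.
#' @export
#' @examples
#' length(paths_to_taxon(load_builtin_key(), "Caryophyllia", "Caryophyllia"))
paths_to_taxon <- function(key, genus, subgenus = NULL) {
  stopifnot(inherits(key, "identification_key"))
  terms <- terminal_table(key)
  taxa <- attr(terms, "taxa")
  want <- taxon_id(list(genus = genus, subgenus = subgenus))
  hit <- which(terms$taxon == want)
  if (!length(hit)) {
    known <- sort(unique(terms$taxon))
    stop("unknown taxon '", want, "'", call. = FALSE)
  }
  parents <- parent_map(key)
  out <- list()
  for (i in hit) {
    for (pre in paths_to_couplet(key, terms$couplet[i], parents)) {
      steps <- rbind(pre, data.frame(couplet = terms$couplet[i],
                                     label = terms$label[i],
                                     stringsAsFactors = FALSE))
      out[[length(out) + 1L]] <- new_path(steps$couplet, steps$label,
                                          taxa[[i]])
    }
  }
  out
}

#' Enumerate every identification path of a key
#'
#' Exhaustive depth-first enumeration of all root-to-terminal paths, in
#' document order of leads.  This is the single path oracle behind
#' [key_stats()], [derive_matrix()] and [filter_taxa()].
#'
#' @param key An [identification_key()]; must be acyclic.
#' @return List of `key_path` objects.
#' @export
enumerate_paths <- function(key) {
  stopifnot(inherits(key, "identification_key"))
  out <- list()
  walk <- function(id, couplets, labels, seen) {
    if (id %in% seen) stop("cycle at couplet ", id, call. = FALSE)
    cp <- get_couplet(key, id)
    for (ld in cp$leads) {
      if (!is.null(ld$taxon)) {
        out[[length(out) + 1L]] <<-
          new_path(c(couplets, id), c(labels, ld$label), ld$taxon)
      } else {
        walk(ld$next_id, c(couplets, id), c(labels, ld$label),
             c(seen, id))
      }
    }
  }
  walk(key$root, integer(), character(), integer())
  out
}

#' Key statistics
#'
#' Counts and path-length statistics computed over the exact enumeration of
#' all root-to-terminal paths (never sampled).
#'
#' @param key An [identification_key()]; should validate clean.
#' @return An object of class `key_stats`: `n_couplets`,
#'   `n_terminal_leads`, `n_paths`, `min_path_length`, `max_path_length`,
#'   `mean_path_length` (decisions per identification).
#' @export
#' @examples
#' key_stats(load_builtin_key())
key_stats <- function(key) {
  paths <- enumerate_paths(key)
  lens <- vapply(paths, function(p) nrow(p$steps), integer(1))
  n_term <- length(terminal_table(key)$couplet)
  structure(
    list(n_couplets = length(key$couplets),
         n_terminal_leads = n_term,
         n_paths = length(paths),
         min_path_length = min(lens),
         max_path_length = max(lens),
         mean_path_length = mean(lens)),
    class = "key_stats")
}

#' @export
print.key_stats <- function(x, ...) {
  cat("<key_stats>\n")
  cat("  couplets:       ", x$n_couplets, "\n")
  cat("  terminal leads: ", x$n_terminal_leads, "\n")
  cat("  paths:          ", x$n_paths, "\n")
  cat(sprintf("  path length:     min %d / mean %.2f / max %d decisions\n",
              x$min_path_length, x$mean_path_length, x$max_path_length))
  invisible(x)
}
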