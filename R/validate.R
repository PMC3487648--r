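# ---------------------------------------------------------------------------
# Structural and semantic validation.
#
# Problems are findings, not exceptions.  Error codes:
#   E1 unresolved reference (lead or root pointing to a missing couplet)
#   E2 cycle in the couplet graph
#   E3 couplet unreachable from the root
#   E4 couplet with fewer than two leads
#   E5 duplicate or non-alphabetical lead labels within a couplet
# Warnings:
#   W1 non-root couplet whose incoming lead count differs from one
#      (deviation from pure tree shape)
#   W2 taxon whose apozooxanthellate flag differs between its terminals
# Info:
#   I1 taxon keyed at more than one terminal
#   I2 region token not in the controlled vocabulary
# ---------------------------------------------------------------------------

finding <- function(code, severity, location, message) {
  data.frame(code = code, severity = severity, location = location,
             message = message, stringsAsFactors = FALSE)
}

#' Validate an identification key
#'
#' Runs the full battery of structural checks (resolution, acyclicity,
#' reachability, lead arity, label discipline) and semantic lints
#' (tree-shape deviations, inconsistent apozooxanthellate flags, multiply
#' keyed taxa, region tokens outside the controlled vocabulary).  A key is
#' *clean* when it has no error-severity findings; warnings and info never
#' make a key unclean.
#'
#' @param key An [identification_key()].
#' @param vocabulary Region vocabulary used for the I2 check, as returned
#'   by [region_vocabulary()]; pass `NULL` to skip the region lint.
#' @return An object of class `key_validation`: a list with `findings`
#'   (data frame of code, severity, location, message) and `clean`.
#' @export
#' @examples
#' validate_key(load_builtin_key())
validate_key <- function(key, vocabulary = region_vocabulary()) {
  stopifnot(inherits(key, "identification_key"))
  f <- list()
  add <- function(...) f[[length(f) + 1L]] <<- finding(...)

  ids <- couplet_ids(key)
  known <- as.character(ids)

  # E1: resolution (root and every couplet-targeting lead)
  if (!as.character(key$root) %in% known)
    add("E1", "error", "root", paste0("root couplet ", key$root, " missing"))
  for (cp in key$couplets) {
    for (ld in cp$leads) {
      if (!is.null(ld$next_id) && !as.character(ld$next_id) %in% known)
        add("E1", "error", sprintf("couplet %d lead %s", cp$id, ld$label),
            paste0("dangling reference to couplet ", ld$next_id))
    }
  }

  # E4 / E5: per-couplet lead discipline
  for (cp in key$couplets) {
    loc <- paste0("couplet ", cp$id)
    if (length(cp$leads) < 2L)
      add("E4", "error", loc,
          sprintf("only %d lead(s); a couplet offers at least two", length(cp$leads)))
    labels <- vapply(cp$leads, function(ld) ld$label, character(1))
    if (anyDuplicated(labels) ||
        !identical(labels, letters[seq_along(labels)]))
      add("E5", "error", loc,
          paste0("lead labels must be distinct letters a, b, c, ... in order; got ",
                 paste(labels, collapse = ", ")))
  }

  # E2 / E3 / W1: graph checks on resolvable couplet->couplet edges
  edges <- edge_table(key)
  edges <- edges[edges$to %in% ids, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to),
               stringsAsFactors = FALSE),
    directed = TRUE, vertices = known)
  if (!igraph::is_dag(g))
    add("E2", "error", "couplet graph", "cycle among couplets")
  if (as.character(key$root) %in% known) {
    reach <- names(igraph::subcomponent(g, as.character(key$root),
                                        mode = "out"))
    for (id in setdiff(known, reach))
      add("E3", "error", paste0("couplet ", id),
          "not reachable from the root")
  }
  incoming <- table(factor(as.character(edges$to), levels = known))
  for (id in known) {
    if (id == as.character(key$root)) next
    if (incoming[[id]] != 1L)
      add("W1", "warning", paste0("couplet ", id),
          sprintf("%d incoming leads (tree shape expects exactly 1)",
                  incoming[[id]]))
  }

  # W2 / I1: per-taxon checks over terminals
  terms <- terminal_table(key)
  if (!is.null(terms) && nrow(terms)) {
    taxa <- attr(terms, "taxa")
    flags <- split(vapply(taxa, function(tx) tx$apozooxanthellate, logical(1)),
                   terms$taxon)
    for (tid in names(flags)) {
      if (length(unique(flags[[tid]])) > 1L)
        add("W2", "warning", tid,
            "apozooxanthellate flag differs between terminals of one taxon")
    }
    counts <- table(terms$taxon)
    for (tid in names(counts)[counts > 1L]) {
      at <- terms[terms$taxon == tid, ]
      add("I1", "info", tid,
          sprintf("keyed at %d terminals: %s", counts[[tid]],
                  paste0(at$couplet, at$label, collapse = ", ")))
    }
    # I2: unmappable region tokens
    if (!is.null(vocabulary)) {
      for (i in seq_len(nrow(terms))) {
        unknown <- terms_unknown_regions(taxa[[i]]$regions, vocabulary)
        if (length(unknown))
          add("I2", "info",
              sprintf("couplet %d lead %s", terms$couplet[i], terms$label[i]),
              paste0("region token(s) outside vocabulary: ",
                     paste(unknown, collapse = ", ")))
      }
    }
  }

  findings <- if (length(f)) do.call(rbind, f) else
    finding(character(), character(), character(), character())[0, ]
  structure(
    list(findings = findings,
         clean = !any(findings$severity == "error")),
    class = "key_validation")
}

terms_unknown_regions <- function(regions, vocabulary) {
  regions[!regions %in% vocabulary$token]
}

#' @export
print.key_validation <- function(x, ...) {
  n <- table(factor(x$findings$severity,
                    levels = c("error", "warning", "info")))
  cat(sprintf("<key_validation> %d errors, %d warnings, %d info — %s\n",
              n[["error"]], n[["warning"]], n[["info"]],
              if (x$clean) "clean" else "NOT clean"))
  if (nrow(x$findings)) {
    for (i in seq_len(nrow(x$findings)))
      cat(sprintf("  [%s/%s] %s: %s\n", x$findings$code[i],
                  x$findings$severity[i], x$findings$location[i],
                  x$findings$message[i]))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Taxon census of a key
#'
#' Aggregate counts over the key's terminals.  `distinct_genera` counts
#' unique genus names; `named_subgenus_pairs` counts unique
#' (genus, subgenus) pairs with a subgenus set; `additional_subgenera` is
#' the sum over genera having named subgenera of (pairs - 1), i.e. the
#' number of subgenera beyond each genus's first — the convention under
#' which the builtin key counts 120 genera and 7 additional subgenera.
#' `multiply_keyed` maps each taxon keyed at more than one terminal to its
#' terminal count.
#'
#' @param key An [identification_key()]; should validate clean.
#' @return An object of class `taxon_census`: a list with
#'   `distinct_genera`, `named_subgenus_pairs`, `additional_subgenera`,
#'   `distinct_taxa`, `terminal_lead_count` and `multiply_keyed`.
#' @export
#' @examples
#' key_census(load_builtin_key())
key_census <- function(key) {
  stopifnot(inherits(key, "identification_key"))
  terms <- terminal_table(key)
  if (is.null(terms) || !nrow(terms))
    stop("key has no terminals", call. = FALSE)
  pairs <- unique(terms[!is.na(terms$subgenus), c("genus", "subgenus")])
  per_genus <- table(pairs$genus)
  counts <- table(terms$taxon)
  multiply <- counts[counts > 1L]
  structure(
    list(distinct_genera = length(unique(terms$genus)),
         named_subgenus_pairs = nrow(pairs),
         additional_subgenera = sum(pmax(0L, as.integer(per_genus) - 1L)),
         distinct_taxa = length(counts),
         terminal_lead_count = nrow(terms),
         multiply_keyed = stats::setNames(as.integer(multiply),
                                          names(multiply))),
    class = "taxon_census")
}

#' @export
print.taxon_census <- function(x, ...) {
  cat("<taxon_census>\n")
  cat("  distinct genera:      ", x$distinct_genera, "\n")
  cat("  subgenus pairs:       ", x$named_subgenus_pairs,
      " (", x$additional_subgenera, " additional subgenera)\n", sep = "")
  cat("  distinct taxa:        ", x$distinct_taxa, "\n")
  cat("  terminal leads:       ", x$terminal_lead_count, "\n")
  if (length(x$multiply_keyed)) {
    cat("  multiply keyed:\n")
    for (tid in names(x$multiply_keyed))
      cat("    ", tid, " x", x$multiply_keyed[[tid]], "\n", sep = "")
  }
  invisible(x)
}
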