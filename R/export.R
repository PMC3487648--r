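# ---------------------------------------------------------------------------
# Exports: Graphviz DOT and the flat taxon table.
# ---------------------------------------------------------------------------

dot_escape <- function(x) gsub('"', '\\\\"', x)

truncate40 <- function(x) {
  ifelse(nchar(x) > 40L, paste0(substr(x, 1L, 40L), "…"), x)
}

#' Export a key as Graphviz DOT
#'
#' One diamond node per couplet, one box per taxon terminal, one labelled
#' edge per lead (`"<label>: <statement truncated to 40 chars>"`, full
#' statement in the edge tooltip).  Node ordering is by couplet id and lead
#' position, so output is byte-identical across runs.
#'
#' @param key An [identification_key()].
#' @return DOT source as a single string.
#' @export
export_dot <- function(key) {
  stopifnot(inherits(key, "identification_key"))
  ids <- sort(couplet_ids(key))
  lines <- c("digraph key {",
             "  rankdir=TB;",
             "  node [fontname=\"Helvetica\"];")
  for (id in ids) {
    cp <- get_couplet(key, id)
    lab <- as.character(id)
    if (!is.null(cp$group_label))
      lab <- paste0(id, "\\n(", dot_escape(cp$group_label), ")")
    lines <- c(lines, sprintf("  c%d [shape=diamond, label=\"%s\"];", id, lab))
  }
  tn <- 0L
  edges <- character()
  for (id in ids) {
    cp <- get_couplet(key, id)
    for (ld in cp$leads) {
      elab <- sprintf("%s: %s", ld$label,
                      dot_escape(truncate40(ld$statement)))
      tip <- dot_escape(ld$statement)
      if (!is.null(ld$next_id)) {
        edges <- c(edges, sprintf(
          "  c%d -> c%d [label=\"%s\", tooltip=\"%s\"];",
          id, ld$next_id, elab, tip))
      } else {
        tn <- tn + 1L
        lines <- c(lines, sprintf(
          "  t%d [shape=box, label=\"%s\"];", tn,
          dot_escape(format(ld$taxon))))
        edges <- c(edges, sprintf(
          "  c%d -> t%d [label=\"%s\", tooltip=\"%s\"];",
          id, tn, elab, tip))
      }
    }
  }
  paste(c(lines, edges, "}"), collapse = "\n")
}

#' Flat taxon table
#'
#' One row per taxon (not per terminal): flags, the union of printed range
#' tokens, and the terminal positions and figure tags, in key order.
#'
#' @param key An [identification_key()].
#' @return A data frame with columns `genus`, `subgenus`,
#'   `apozooxanthellate`, `in_part`, `regions`, `terminals`, `figures`.
#' @export
taxon_table <- function(key) {
  stopifnot(inherits(key, "identification_key"))
  terms <- terminal_table(key)
  taxa <- attr(terms, "taxa")
  ids <- unique(terms$taxon)
  rows <- lapply(ids, function(tid) {
    i <- which(terms$taxon == tid)
    tx <- taxa[i]
    data.frame(
      genus = terms$genus[i[1]],
      subgenus = terms$subgenus[i[1]],
      apozooxanthellate = any(vapply(tx, `[[`, logical(1),
                                     "apozooxanthellate")),
      in_part = any(vapply(tx, `[[`, logical(1), "in_part")),
      regions = paste(unique(unlist(lapply(tx, `[[`, "regions"))),
                      collapse = "; "),
      terminals = paste0(terms$couplet[i], terms$label[i], collapse = "; "),
      figures = paste(unlist(lapply(tx, function(t)
        if (is.null(t$figure)) "" else t$figure)), collapse = "; "),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genus, out$subgenus, na.last = FALSE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
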