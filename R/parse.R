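# ---------------------------------------------------------------------------
# Key-document parsing and serialization.
#
# The on-disk format is a JSON dialect documented by the schema shipped at
# inst/extdata/key-document.schema.json.  Unknown fields are rejected; a
# lead carries exactly one of "next" (couplet id) or "taxon".  All I/O is
# UTF-8.  parse_key(serialize_key(k)) is structurally identical to k.
# ---------------------------------------------------------------------------

TOP_FIELDS     <- c("title", "source", "root", "couplets", "metadata")
COUPLET_FIELDS <- c("id", "group_label", "leads")
LEAD_FIELDS    <- c("label", "statement", "group", "next", "taxon")
TAXON_FIELDS   <- c("genus", "subgenus", "in_part", "apozooxanthellate",
                    "regions", "figure")

doc_error <- function(where, msg) {
  stop("key document error at ", where, ": ", msg, call. = FALSE)
}

check_fields <- function(x, allowed, required, where) {
  if (!is.list(x)) doc_error(where, "expected an object")
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    doc_error(where, paste0("unknown field(s): ",
                            paste(unknown, collapse = ", ")))
  missing <- setdiff(required, names(x))
  if (length(missing))
    doc_error(where, paste0("missing field(s): ",
                            paste(missing, collapse = ", ")))
  invisible(x)
}

scalar_chr <- function(x, where) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    doc_error(where, "expected a string")
  x
}

scalar_int <- function(x, where) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x))
    doc_error(where, "expected an integer")
  as.integer(x)
}

parse_taxon_block <- function(tx, where) {
  check_fields(tx, TAXON_FIELDS, c("genus", "regions"), where)
  regions <- tx$regions
  if (is.list(regions)) regions <- unlist(regions, use.names = FALSE)
  if (length(regions) && !is.character(regions))
    doc_error(where, "regions must be strings")
  taxon_terminal(
    genus = scalar_chr(tx$genus, where),
    subgenus = if (!is.null(tx$subgenus)) scalar_chr(tx$subgenus, where),
    in_part = isTRUE(tx$in_part),
    apozooxanthellate = isTRUE(tx$apozooxanthellate),
    regions = as.character(regions),
    figure = if (!is.null(tx$figure)) scalar_chr(tx$figure, where))
}

parse_lead_block <- function(ld, where) {
  check_fields(ld, LEAD_FIELDS, c("label", "statement"), where)
  has_next <- !is.null(ld[["next"]])
  has_taxon <- !is.null(ld$taxon)
  if (has_next == has_taxon)
    doc_error(where, "lead must have exactly one of 'next' or 'taxon'")
  key_lead(
    label = scalar_chr(ld$label, where),
    statement = scalar_chr(ld$statement, where),
    next_id = if (has_next) scalar_int(ld[["next"]], where),
    taxon = if (has_taxon) parse_taxon_block(ld$taxon, where),
    group = if (!is.null(ld$group)) scalar_chr(ld$group, where))
}

#' Parse a key document
#'
#' Reads the JSON key-document dialect into an [identification_key()].
#' Structural rules of the shipped schema are enforced: unknown fields,
#' duplicate couplet ids, duplicate lead labels, couplets with fewer than
#' two leads, and targets that are neither an integer couplet id nor a
#' taxon block are all rejected.  With `strict = TRUE` (the default) a lead
#' pointing to a couplet id absent from the document is a dangling-reference
#' error; `strict = FALSE` defers that to [validate_key()], which is how the
#' command line loads deliberately broken documents for inspection.
#'
#' Group annotations printed on a lead (e.g. a family name) are also echoed
#' onto the target couplet as its `group_label`.
#'
#' @param text Key document as a single JSON string, or a character vector
#'   of lines.
#' @param strict Reject dangling couplet references at parse time?
#' @return An [identification_key()].
#' @seealso [read_key()] to parse from a file, [serialize_key()] for the
#'   inverse operation.
#' @export
parse_key <- function(text, strict = TRUE) {
  text <- paste(text, collapse = "\n")
  doc <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) doc_error("top level", paste("malformed JSON:",
                                                     conditionMessage(e))))
  check_fields(doc, TOP_FIELDS, c("title", "source", "root", "couplets"),
               "top level")
  if (!is.list(doc$couplets) || !length(doc$couplets))
    doc_error("couplets", "expected a non-empty array")

  couplets <- vector("list", length(doc$couplets))
  for (i in seq_along(doc$couplets)) {
    cb <- doc$couplets[[i]]
    where <- paste0("couplet #", i)
    check_fields(cb, COUPLET_FIELDS, c("id", "leads"), where)
    id <- scalar_int(cb$id, where)
    where <- paste0("couplet ", id)
    if (!is.list(cb$leads) || length(cb$leads) < 2L)
      doc_error(where, "a couplet needs at least 2 leads")
    if (length(cb$leads) > 26L)
      doc_error(where, "more than 26 leads (labels are a-z)")
    leads <- lapply(seq_along(cb$leads), function(j)
      parse_lead_block(cb$leads[[j]], paste0(where, ", lead #", j)))
    labels <- vapply(leads, function(ld) ld$label, character(1))
    if (anyDuplicated(labels))
      doc_error(where, paste0("duplicate lead label '",
                              labels[duplicated(labels)][1], "'"))
    if (!identical(labels, letters[seq_along(labels)]))
      doc_error(where, paste0("lead labels must run a, b, c, ... in order; got ",
                              paste(labels, collapse = ", ")))
    couplets[[i]] <- key_couplet(
      id, leads,
      group_label = if (!is.null(cb$group_label))
        scalar_chr(cb$group_label, where))
  }

  ids <- vapply(couplets, function(cp) cp$id, integer(1))
  if (anyDuplicated(ids))
    doc_error("top level",
              paste0("duplicate couplet id ", ids[duplicated(ids)][1]))

  metadata <- NULL
  if (!is.null(doc$metadata)) {
    check_fields(doc$metadata, c("generator", "seed"), character(), "metadata")
    metadata <- doc$metadata
    if (!is.null(metadata$seed))
      metadata$seed <- scalar_int(metadata$seed, "metadata")
  }

  key <- identification_key(
    title = scalar_chr(doc$title, "top level"),
    source = scalar_chr(doc$source, "top level"),
    root = scalar_int(doc$root, "top level"),
    couplets = couplets, metadata = metadata)

  # echo lead group annotations onto their target couplets
  for (cp in key$couplets) {
    for (ld in cp$leads) {
      if (!is.null(ld$group) && !is.null(ld$next_id)) {
        tgt <- as.character(ld$next_id)
        if (!is.null(key$couplets[[tgt]]))
          key$couplets[[tgt]]$group_label <- ld$group
      }
    }
  }

  if (strict) {
    for (cp in key$couplets) {
      for (ld in cp$leads) {
        if (!is.null(ld$next_id) &&
            !as.character(ld$next_id) %in% names(key$couplets))
          doc_error(paste0("couplet ", cp$id, ", lead ", ld$label),
                    paste0("dangling reference to couplet ", ld$next_id))
      }
    }
  }
  key
}

#' Read a key document from a file
#'
#' @param path Path to a UTF-8 JSON key document.
#' @inheritParams parse_key
#' @return An [identification_key()].
#' @export
read_key <- function(path, strict = TRUE) {
  parse_key(readLines(path, encoding = "UTF-8", warn = FALSE), strict = strict)
}

# -- serialization ----------------------------------------------------------

taxon_to_list <- function(tx) {
  out <- list(genus = tx$genus)
  if (!is.null(tx$subgenus)) out$subgenus <- tx$subgenus
  if (tx$in_part) out$in_part <- TRUE
  if (tx$apozooxanthellate) out$apozooxanthellate <- TRUE
  out$regions <- as.list(tx$regions)
  if (!is.null(tx$figure)) out$figure <- tx$figure
  out
}

lead_to_list <- function(ld) {
  out <- list(label = ld$label, statement = ld$statement)
  if (!is.null(ld$group)) out$group <- ld$group
  if (!is.null(ld$next_id)) out[["next"]] <- ld$next_id
  if (!is.null(ld$taxon)) out$taxon <- taxon_to_list(ld$taxon)
  out
}

#' Serialize a key to document text
#'
#' Writes the canonical JSON form: fixed field order, couplets in document
#' order, two-space indentation.  Output is deterministic, so identical
#' keys serialize to byte-identical text.  `group_label`s that merely echo
#' an incoming lead's annotation are not written (the lead's `group` field
#' is authoritative and they are restored at parse time).
#'
#' @param key An [identification_key()].
#' @return A single string of JSON text.
#' @export
serialize_key <- function(key) {
  stopifnot(inherits(key, "identification_key"))
  echoed <- character()
  for (cp in key$couplets)
    for (ld in cp$leads)
      if (!is.null(ld$group) && !is.null(ld$next_id))
        echoed <- c(echoed, as.character(ld$next_id))
  doc <- list(title = key$title, source = key$source, root = key$root)
  if (!is.null(key$metadata)) doc$metadata <- key$metadata
  doc$couplets <- lapply(key$couplets, function(cp) {
    out <- list(id = cp$id)
    if (!is.null(cp$group_label) && !as.character(cp$id) %in% echoed)
      out$group_label <- cp$group_label
    out$leads <- lapply(cp$leads, lead_to_list)
    out
  })
  names(doc$couplets) <- NULL
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2,
                                digits = NA))
}

#' Write a key document to a file
#'
#' @param key An [identification_key()].
#' @param path Output path; written as UTF-8.
#' @return `path`, invisibly.
#' @export
write_key <- function(key, path) {
  writeLines(serialize_key(key), path, useBytes = TRUE)
  invisible(path)
}
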