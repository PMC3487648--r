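# ---------------------------------------------------------------------------
# Typed constructors for the key data model.
#
# An identification key is a rooted decision graph of numbered couplets.
# Every couplet offers >= 2 leads; every lead carries a verbatim character
# statement and points either onward to another couplet or to a taxon
# terminal.  Bracketed geographic ranges, asterisk flags, "(in part)"
# markers, figure tags and parenthetical family annotations are structured
# metadata, never part of the statement text.
# ---------------------------------------------------------------------------

#' Construct a taxon terminal
#'
#' A taxon terminal is the end point of an identification: a genus, an
#' optional subgenus, and the metadata the key prints alongside the name.
#' Taxon identity is the pair (genus, subgenus-or-NULL); a taxon keyed at
#' several terminals ("in part") is still one taxon.
#'
#' @param genus Capitalised Latin genus name.
#' @param subgenus Optional Latin subgenus name (`NULL` for none).
#'   Nominotypical subgenera (e.g. `Caryophyllia (Caryophyllia)`) are stored
#'   with `subgenus` set, exactly as the source key prints them.
#' @param in_part `TRUE` when the key marks this terminal "(in part)",
#'   i.e. the taxon is keyed at more than one terminal because of
#'   within-taxon variation.
#' @param apozooxanthellate `TRUE` for genera flagged (by an asterisk in the
#'   printed key) as having both azooxanthellate and zooxanthellate
#'   representatives.
#' @param regions Character vector of geographic range tokens (controlled
#'   vocabulary, see [region_vocabulary()]).  Informational only: ranges are
#'   never diagnostic characters.
#' @param figure Optional figure tag (e.g. `"F2"`) naming the plate that
#'   illustrates the taxon.
#' @return An object of class `taxon_terminal`.
#' @export
#' @examples
#' taxon_terminal("Lophelia", regions = "Cosmopolitan", figure = "F2")
taxon_terminal <- function(genus, subgenus = NULL, in_part = FALSE,
                           apozooxanthellate = FALSE, regions = character(),
                           figure = NULL) {
  stopifnot(is.character(genus), length(genus) == 1L, nzchar(genus))
  if (!grepl("^[A-Z]", genus))
    stop("genus must be capitalised: ", genus, call. = FALSE)
  if (!is.null(subgenus)) {
    stopifnot(is.character(subgenus), length(subgenus) == 1L, nzchar(subgenus))
  }
  if (!is.null(figure)) stopifnot(is.character(figure), length(figure) == 1L)
  structure(
    list(genus = genus, subgenus = subgenus,
         in_part = isTRUE(in_part),
         apozooxanthellate = isTRUE(apozooxanthellate),
         regions = as.character(regions), figure = figure),
    class = "taxon_terminal")
}

#' Construct a lead
#'
#' One alternative within a couplet: a single-letter label, the verbatim
#' character statement, and a target that is exactly one of a couplet id
#' (`next_id`) or a [taxon_terminal()].
#'
#' @param label Single lowercase letter.
#' @param statement Non-empty verbatim character text.
#' @param next_id Integer id of the couplet this lead continues to, or
#'   `NULL` for a terminal lead.
#' @param taxon A [taxon_terminal()], or `NULL` for an internal lead.
#' @param group Optional group annotation carried on the edge, e.g. a family
#'   name the key prints in parentheses at this lead ("Rhizangiidae").
#' @return An object of class `key_lead`.
#' @export
key_lead <- function(label, statement, next_id = NULL, taxon = NULL,
                     group = NULL) {
  stopifnot(is.character(label), length(label) == 1L,
            grepl("^[a-z]$", label))
  stopifnot(is.character(statement), length(statement) == 1L)
  if (!nzchar(statement)) stop("lead statement must be non-empty", call. = FALSE)
  if (is.null(next_id) == is.null(taxon))
    stop("a lead targets exactly one of a couplet or a taxon", call. = FALSE)
  if (!is.null(next_id)) {
    next_id <- as.integer(next_id)
    stopifnot(length(next_id) == 1L, !is.na(next_id), next_id >= 1L)
  }
  if (!is.null(taxon) && !inherits(taxon, "taxon_terminal"))
    stop("taxon must be a taxon_terminal", call. = FALSE)
  if (!is.null(group)) stopifnot(is.character(group), length(group) == 1L)
  structure(
    list(label = label, statement = statement, next_id = next_id,
         taxon = taxon, group = group),
    class = "key_lead")
}

#' Construct a couplet
#'
#' @param id Positive integer couplet number, as printed in the key.
#' @param leads List of [key_lead()] objects, length >= 2, in print order.
#'   Labels must be distinct lowercase letters in alphabetical order
#'   starting at "a"; up to 26 leads (a--z) are accepted.
#' @param group_label Optional group text attached to this couplet because
#'   an incoming lead prints a parenthetical group annotation.
#' @return An object of class `key_couplet`.
#' @export
key_couplet <- function(id, leads, group_label = NULL) {
  id <- as.integer(id)
  stopifnot(length(id) == 1L, !is.na(id), id >= 1L)
  stopifnot(is.list(leads))
  if (!all(vapply(leads, inherits, logical(1), "key_lead")))
    stop("leads must be key_lead objects", call. = FALSE)
  if (!is.null(group_label))
    stopifnot(is.character(group_label), length(group_label) == 1L)
  structure(
    list(id = id, group_label = group_label, leads = leads),
    class = "key_couplet")
}

#' Construct an identification key
#'
#' Assembles couplets into a key.  The constructor checks only local shape
#' (unique couplet ids, root present); graph-level soundness (resolving
#' targets, acyclicity, reachability, lead arity) is the job of
#' [validate_key()], which reports findings rather than failing.
#'
#' @param title Free-text title.
#' @param source Citation text for the key's origin.
#' @param root Integer id of the entry couplet.
#' @param couplets List of [key_couplet()] objects in document order.
#' @param metadata Optional named list (e.g. generator provenance for
#'   synthetic keys).
#' @return An object of class `identification_key`.
#' @export
identification_key <- function(title, source, root, couplets,
                               metadata = NULL) {
  stopifnot(is.character(title), length(title) == 1L)
  stopifnot(is.character(source), length(source) == 1L)
  root <- as.integer(root)
  stopifnot(length(root) == 1L, !is.na(root))
  stopifnot(is.list(couplets), length(couplets) >= 1L)
  if (!all(vapply(couplets, inherits, logical(1), "key_couplet")))
    stop("couplets must be key_couplet objects", call. = FALSE)
  ids <- vapply(couplets, function(cp) cp$id, integer(1))
  if (anyDuplicated(ids))
    stop("duplicate couplet id: ", ids[duplicated(ids)][1], call. = FALSE)
  names(couplets) <- as.character(ids)
  if (!as.character(root) %in% names(couplets))
    stop("root couplet ", root, " is not among the couplets", call. = FALSE)
  structure(
    list(title = title, source = source, root = root, couplets = couplets,
         metadata = metadata),
    class = "identification_key")
}

# internal accessors ---------------------------------------------------------

get_couplet <- function(key, id) {
  cp <- key$couplets[[as.character(id)]]
  if (is.null(cp))
    stop("unknown couplet: ", id, " (key has couplets ",
         paste(names(key$couplets), collapse = ", "), ")", call. = FALSE)
  cp
}

couplet_ids <- function(key) {
  vapply(key$couplets, function(cp) cp$id, integer(1), USE.NAMES = FALSE)
}

# Canonical taxon identity string: "Genus" or "Genus (Subgenus)".
taxon_id <- function(taxon) {
  if (is.null(taxon$subgenus)) taxon$genus
  else paste0(taxon$genus, " (", taxon$subgenus, ")")
}

# Data frame of every terminal lead: couplet, label, taxon id, plus the
# taxon objects as a parallel list.
terminal_table <- function(key) {
  rows <- list()
  taxa <- list()
  for (cp in key$couplets) {
    for (ld in cp$leads) {
      if (!is.null(ld$taxon)) {
        rows[[length(rows) + 1L]] <-
          data.frame(couplet = cp$id, label = ld$label,
                     taxon = taxon_id(ld$taxon),
                     genus = ld$taxon$genus,
                     subgenus = ifelse(is.null(ld$taxon$subgenus), NA_character_,
                                       ld$taxon$subgenus),
                     stringsAsFactors = FALSE)
        taxa[[length(taxa) + 1L]] <- ld$taxon
      }
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "taxa") <- taxa
  tab
}

# All internal edges (couplet -> couplet), with lead labels.
edge_table <- function(key) {
  from <- integer(); to <- integer(); label <- character()
  for (cp in key$couplets) {
    for (ld in cp$leads) {
      if (!is.null(ld$next_id)) {
        from <- c(from, cp$id); to <- c(to, ld$next_id)
        label <- c(label, ld$label)
      }
    }
  }
  data.frame(from = from, to = to, label = label, stringsAsFactors = FALSE)
}

#' @export
print.identification_key <- function(x, ...) {
  n_term <- sum(vapply(x$couplets, function(cp)
    sum(vapply(cp$leads, function(ld) !is.null(ld$taxon), logical(1))),
    integer(1)))
  cat("<identification_key> ", x$title, "\n", sep = "")
  cat("  source:   ", x$source, "\n", sep = "")
  cat("  couplets: ", length(x$couplets),
      " (root ", x$root, "), terminal leads: ", n_term, "\n", sep = "")
  invisible(x)
}

#' @export
print.taxon_terminal <- function(x, ...) {
  cat(taxon_id(x),
      if (x$apozooxanthellate) "*",
      if (x$in_part) " (in part)", "\n", sep = "")
  if (length(x$regions))
    cat("  regions: ", paste(x$regions, collapse = " + "), "\n", sep = "")
  if (!is.null(x$figure)) cat("  figure:  ", x$figure, "\n", sep = "")
  invisible(x)
}

#' @export
format.taxon_terminal <- function(x, ...) {
  paste0(taxon_id(x),
         if (x$apozooxanthellate) "*" else "",
         if (x$in_part) " (in part)" else "")
}
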