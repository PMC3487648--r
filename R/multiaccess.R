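# ---------------------------------------------------------------------------
# Multi-access (polyclave) identification.
#
# The printed key's characters exist only as lead contrasts, so a
# "character" here is a (couplet, lead) pair and an assertion is the claim
# that the specimen takes that lead wherever the couplet arises.  All
# semantics are defined over the exhaustive set of identification paths:
#   required (R)  every path of the taxon takes the lead
#   excluded (X)  every path passes the couplet via another lead
#   inapplicable  otherwise (some path never meets the couplet, or the
#                 taxon's variants disagree)
# ---------------------------------------------------------------------------

# per-path couplet -> chosen-lead lookup
path_choice_map <- function(p) {
  stats::setNames(p$steps$label, as.character(p$steps$couplet))
}

# paths grouped by taxon identity
paths_by_taxon <- function(key) {
  paths <- enumerate_paths(key)
  ids <- vapply(paths, function(p) taxon_id(p$terminal), character(1))
  split(paths, ids)
}

#' Derive the taxon-by-character matrix
#'
#' Projects the key onto a multi-access matrix: one row per taxon, one
#' column per (couplet, lead) pair, cells `"R"` (required), `"X"`
#' (excluded) or `"·"` (inapplicable) under exhaustive-path semantics
#' (see the package vignette).  Column metadata (couplet, label, statement)
#' is attached as attribute `columns`.
#'
#' @param key An [identification_key()]; should validate clean.
#' @return A character matrix of class `character_matrix` with taxon row
#'   names and `"<couplet><label>"` column names.
#' @export
#' @examples
#' m <- derive_matrix(load_builtin_key())
#' m["Lophelia", "1a"]   # "R": Lophelia always keys as colonial
derive_matrix <- function(key) {
  stopifnot(inherits(key, "identification_key"))
  cols <- list()
  for (cp in key$couplets)
    for (ld in cp$leads)
      cols[[length(cols) + 1L]] <-
        data.frame(couplet = cp$id, label = ld$label,
                   statement = ld$statement, stringsAsFactors = FALSE)
  cols <- do.call(rbind, cols)
  cols <- cols[order(cols$couplet, cols$label), , drop = FALSE]
  rownames(cols) <- NULL

  grouped <- paths_by_taxon(key)
  taxa <- sort(names(grouped))
  mat <- matrix("·", nrow = length(taxa), ncol = nrow(cols),
                dimnames = list(taxa, paste0(cols$couplet, cols$label)))
  for (t in taxa) {
    maps <- lapply(grouped[[t]], path_choice_map)
    # chosen lead per couplet per path (NA = couplet not on that path)
    chosen <- vapply(maps, function(m) m[as.character(cols$couplet)],
                     character(nrow(cols)))
    chosen <- matrix(chosen, nrow = nrow(cols))
    takes <- chosen == cols$label
    required <- apply(takes, 1L, function(r) all(!is.na(r) & r))
    visited_all <- apply(chosen, 1L, function(r) all(!is.na(r)))
    never_taken <- !apply(takes, 1L, function(r) any(r, na.rm = TRUE))
    excluded <- visited_all & never_taken
    mat[t, required] <- "R"
    mat[t, excluded & !required] <- "X"
  }
  structure(mat, columns = cols, class = c("character_matrix", "matrix"))
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("<character_matrix> ", nrow(x), " taxa × ", ncol(x),
      " (couplet, lead) characters\n", sep = "")
  cat("  cells: R required / X excluded / · inapplicable\n")
  invisible(x)
}

check_assertions <- function(key, assertions) {
  if (is.data.frame(assertions)) {
    stopifnot(all(c("couplet", "label") %in% names(assertions)))
    a <- stats::setNames(as.character(assertions$label),
                         as.character(assertions$couplet))
  } else if (length(assertions) == 0L) {
    return(stats::setNames(character(), character()))
  } else {
    stopifnot(is.character(assertions), !is.null(names(assertions)))
    a <- assertions
  }
  if (anyDuplicated(names(a))) {
    dup <- names(a)[duplicated(names(a))][1]
    stop("conflicting assertions: couplet ", dup,
         " asserted more than once", call. = FALSE)
  }
  for (i in seq_along(a))
    find_lead(key, as.integer(names(a)[i]), a[[i]])   # existence check
  a
}

#' Filter taxa by order-free assertions
#'
#' Multi-access identification: the user asserts lead choices for any
#' subset of couplets, in any order.  A path is compatible when every
#' asserted couplet that lies on it is taken via the asserted lead; a taxon
#' remains a candidate while at least one of its paths is compatible, so a
#' variable taxon survives as long as any of its keyed variants fits the
#' observations.  Adding assertions can only shrink the candidate set.
#'
#' @param key An [identification_key()]; should validate clean.
#' @param assertions Named character vector mapping couplet id to lead
#'   label (e.g. `c("1" = "b", "44" = "a")`), or a data frame with columns
#'   `couplet` and `label`.  At most one assertion per couplet; conflicting
#'   assertions are rejected.
#' @return A data frame of candidate taxa (`taxon`, `genus`, `subgenus`,
#'   `n_compatible_paths`), sorted by genus then subgenus.
#' @export
#' @examples
#' nrow(filter_taxa(load_builtin_key(), c("1" = "b")))
filter_taxa <- function(key, assertions = character()) {
  stopifnot(inherits(key, "identification_key"))
  a <- check_assertions(key, assertions)
  grouped <- paths_by_taxon(key)
  compatible <- function(p) {
    m <- path_choice_map(p)
    for (cid in names(a)) {
      got <- unname(m[cid])      # NA when the couplet is not on this path
      if (!is.na(got) && got != a[[cid]]) return(FALSE)
    }
    TRUE
  }
  rows <- lapply(names(grouped), function(t) {
    n_ok <- sum(vapply(grouped[[t]], compatible, logical(1)))
    if (n_ok == 0L) return(NULL)
    tx <- grouped[[t]][[1]]$terminal
    data.frame(taxon = t, genus = tx$genus,
               subgenus = ifelse(is.null(tx$subgenus), NA_character_,
                                 tx$subgenus),
               n_compatible_paths = n_ok, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(taxon = character(), genus = character(),
                      subgenus = character(),
                      n_compatible_paths = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$genus, out$subgenus, na.last = FALSE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Diagnostic contrast of a taxon
#'
#' For each terminal of the taxon, reports the final couplet — the last
#' decision that separates it — with the taxon's own lead statement and
#' every sibling lead it is contrasted against there.
#'
#' @inheritParams paths_to_taxon
#' @return A list of class `diagnostic_contrast`; one element per terminal,
#'   each with `couplet`, `label`, `statement` and `siblings` (data frame of
#'   label, statement, and the sibling's target).
#' @export
#' @examples
#' diagnostic_contrast(load_builtin_key(), "Desmophyllum")
diagnostic_contrast <- function(key, genus, subgenus = NULL) {
  stopifnot(inherits(key, "identification_key"))
  terms <- terminal_table(key)
  want <- taxon_id(list(genus = genus, subgenus = subgenus))
  hit <- which(terms$taxon == want)
  if (!length(hit)) stop("unknown taxon '", want, "'", call. = FALSE)
  out <- lapply(hit, function(i) {
    cp <- get_couplet(key, terms$couplet[i])
    own <- Filter(function(ld) ld$label == terms$label[i], cp$leads)[[1]]
    sib <- Filter(function(ld) ld$label != terms$label[i], cp$leads)
    list(couplet = cp$id, label = own$label, statement = own$statement,
         siblings = data.frame(
           label = vapply(sib, function(l) l$label, character(1)),
           statement = vapply(sib, function(l) l$statement, character(1)),
           target = vapply(sib, function(l)
             if (is.null(l$taxon)) paste0("couplet ", l$next_id)
             else format(l$taxon), character(1)),
           stringsAsFactors = FALSE))
  })
  structure(out, taxon = want, class = "diagnostic_contrast")
}

#' @export
print.diagnostic_contrast <- function(x, ...) {
  cat("<diagnostic_contrast> ", attr(x, "taxon"), "\n", sep = "")
  for (e in x) {
    cat("  at couplet ", e$couplet, ", lead ", e$label, ": ",
        e$statement, "\n", sep = "")
    for (i in seq_len(nrow(e$siblings)))
      cat("    vs ", e$siblings$label[i], ": ", e$siblings$statement[i],
          " -> ", e$siblings$target[i], "\n", sep = "")
  }
  invisible(x)
}
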