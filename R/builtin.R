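# ---------------------------------------------------------------------------
# Builtin dataset: the encoded genus-level key to the Recent azooxanthellate
# Scleractinia, the table of previously published species-level keys, and
# the controlled vocabulary of geographic range abbreviations.
# ---------------------------------------------------------------------------

builtin_path <- function(file) {
  path <- system.file("extdata", file, package = "coralkey")
  if (!nzchar(path)) stop("builtin data file missing: ", file, call. = FALSE)
  path
}

#' Load the builtin Scleractinia key
#'
#' The flagship dataset: a complete polytomous key to the 120 genera and 7
#' additional subgenera of the Recent azooxanthellate Scleractinia, encoded
#' couplet by couplet from its published form (111 couplets, 246 leads, 136
#' taxon terminals).  Statements are verbatim; bracketed geographic ranges,
#' asterisk (apozooxanthellate) flags, "(in part)" markers, figure tags and
#' parenthetical family annotations are carried as structured metadata.
#'
#' @return An [identification_key()] that validates clean.
#' @export
#' @examples
#' key <- load_builtin_key()
#' key_census(key)
load_builtin_key <- function() {
  key <- tryCatch(
    read_key(builtin_path("scleractinia_key.json")),
    error = function(e)
      stop("builtin key dataset is corrupt: ", conditionMessage(e),
           call. = FALSE))
  key
}

#' Region vocabulary
#'
#' The controlled vocabulary of geographic range tokens used in the builtin
#' key: ocean abbreviations (e.g. `IWP` = Indo-West Pacific), their
#' compass-prefixed forms, literal place names, and printed variants mapped
#' to their canonical token.  `Cosmopolitan` implying occurrence in all
#' three oceans plus the (Sub)Antarctic is recorded as vocabulary metadata,
#' never silently expanded when matching.
#'
#' @return A data frame with columns `token`, `expansion`, `source_note`.
#' @export
region_vocabulary <- function() {
  utils::read.csv(builtin_path("regions.csv"), stringsAsFactors = FALSE,
                  encoding = "UTF-8")
}

#' Normalize a region token
#'
#' Maps printed variants (`"I–P"`, `"Subant."`, `"IWP."`,
#' `"SW. Pac."`) to their canonical vocabulary token; canonical tokens pass
#' through; tokens outside the vocabulary are returned unchanged.
#'
#' @param token Character vector of region tokens.
#' @param vocabulary A [region_vocabulary()] data frame.
#' @return Character vector of the same length.
#' @export
normalize_region <- function(token, vocabulary = region_vocabulary()) {
  variants <- grepl("^variant of ", vocabulary$source_note)
  map <- stats::setNames(sub("^variant of ", "",
                             vocabulary$source_note[variants]),
                         vocabulary$token[variants])
  out <- trimws(token)
  hit <- out %in% names(map)
  out[hit] <- unname(map[out[hit]])
  out
}

#' Look up previously published species-level keys
#'
#' Case-insensitive substring search over the subjects of the builtin
#' bibliography of species-level keys (comprehensive keys to a whole taxon
#' and partial, faunistic keys of a region; tabular keys are flagged).
#' Records are returned in table order, comprehensive before faunistic.
#'
#' @param query Non-empty search text matched against the subject column
#'   (taxon name or fauna description).
#' @return A data frame with columns `subject`, `scope` (`"comprehensive"`
#'   or `"faunistic"`), `tabular` (logical) and `citation`; zero rows when
#'   nothing matches.
#' @export
#' @examples
#' species_key_lookup("Deltocyathus")
species_key_lookup <- function(query) {
  stopifnot(is.character(query), length(query) == 1L)
  if (!nzchar(query)) stop("query must be non-empty", call. = FALSE)
  bib <- load_bibliography()
  hit <- grepl(query, bib$subject, ignore.case = TRUE, fixed = FALSE)
  bib[hit, , drop = FALSE]
}

#' Load the bibliography of species-level keys
#'
#' @return The full bibliography data frame (see [species_key_lookup()]).
#' @export
load_bibliography <- function() {
  bib <- utils::read.csv(builtin_path("table1_bibliography.csv"),
                         stringsAsFactors = FALSE, encoding = "UTF-8")
  bib$tabular <- as.logical(bib$tabular)
  bib[order(match(bib$scope, c("comprehensive", "faunistic"))), ,
      drop = FALSE]
}

#' Taxa recorded from a region
#'
#' Lists the taxa having at least one terminal whose bracketed range
#' includes the given token (after variant normalization), deduplicated by
#' taxon identity.  Ranges are informational, not diagnostic: this is a
#' browsing aid, not an identification filter.
#'
#' @param key An [identification_key()].
#' @param region_token Non-empty region token, e.g. `"Cosmopolitan"` or
#'   `"S. Africa"`.
#' @param vocabulary A [region_vocabulary()] data frame.
#' @return A data frame with one row per taxon (`taxon`, `genus`,
#'   `subgenus`, `terminals`), sorted by genus then subgenus.  If the token
#'   is outside the vocabulary and absent from the data, the result carries
#'   attribute `unknown_token = TRUE` and a warning is raised.
#' @export
#' @examples
#' taxa_by_region(load_builtin_key(), "Cosmopolitan")
taxa_by_region <- function(key, region_token,
                           vocabulary = region_vocabulary()) {
  stopifnot(inherits(key, "identification_key"),
            is.character(region_token), length(region_token) == 1L)
  if (!nzchar(trimws(region_token)))
    stop("region token must be non-empty", call. = FALSE)
  token <- normalize_region(region_token, vocabulary)
  terms <- terminal_table(key)
  taxa <- attr(terms, "taxa")
  all_tokens <- unique(unlist(lapply(taxa, function(tx)
    normalize_region(tx$regions, vocabulary))))
  unknown <- !token %in% vocabulary$token && !token %in% all_tokens
  if (unknown)
    warning("region token not in vocabulary or data: ", region_token,
            call. = FALSE)
  hit <- vapply(taxa, function(tx)
    token %in% normalize_region(tx$regions, vocabulary), logical(1))
  sub <- terms[hit, , drop = FALSE]
  if (nrow(sub)) {
    agg <- stats::aggregate(
      list(terminals = paste0(sub$couplet, sub$label)),
      by = list(taxon = sub$taxon, genus = sub$genus,
                subgenus = ifelse(is.na(sub$subgenus), "", sub$subgenus)),
      FUN = function(x) paste(x, collapse = ", "))
    agg <- agg[order(agg$genus, agg$subgenus), , drop = FALSE]
    agg$subgenus[agg$subgenus == ""] <- NA_character_
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(taxon = character(), genus = character(),
                      subgenus = character(), terminals = character(),
                      stringsAsFactors = FALSE)
  }
  attr(agg, "unknown_token") <- unknown
  agg
}
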