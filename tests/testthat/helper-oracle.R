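# Independent oracles, deliberately written against the raw list structure
# of a key (never through enumerate_paths / filter_taxa) so that engine and
# oracle can disagree.

# Exhaustive iterative DFS over a key; returns a list of records
# list(steps = c("1a", "2b", ...), taxon = "Genus (Subgenus)").
oracle_paths <- function(key) {
  out <- list()
  # stack of (couplet id, prefix of "<id><label>" strings)
  stack <- list(list(id = key$root, prefix = character()))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    cp <- key$couplets[[as.character(top$id)]]
    # push in reverse so leads come out in document order
    for (ld in rev(cp$leads)) {
      step <- paste0(cp$id, ld$label)
      if (is.null(ld$next_id)) {
        tid <- if (is.null(ld$taxon$subgenus)) ld$taxon$genus else
          paste0(ld$taxon$genus, " (", ld$taxon$subgenus, ")")
        out[[length(out) + 1L]] <-
          list(steps = c(top$prefix, step), taxon = tid)
      } else {
        stack[[length(stack) + 1L]] <-
          list(id = ld$next_id, prefix = c(top$prefix, step))
      }
    }
  }
  out
}

# Candidate taxa under a single assertion "couplet=label", by brute force
# over oracle paths.
oracle_filter_single <- function(key, couplet, label) {
  paths <- oracle_paths(key)
  want <- paste0(couplet, label)
  other <- paste0(couplet, setdiff(letters, label))
  ok <- vapply(paths, function(p) {
    hits <- p$steps[sub("^([0-9]+).*$", "\\1", p$steps) ==
                      as.character(couplet)]
    !length(hits) || hits[1] == want
  }, logical(1))
  sort(unique(vapply(paths[ok], `[[`, character(1), "taxon")))
}

# Path-length stats by brute force.
oracle_stats <- function(key) {
  lens <- vapply(oracle_paths(key), function(p) length(p$steps), integer(1))
  list(n = length(lens), min = min(lens), max = max(lens),
       mean = mean(lens))
}
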