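# ---------------------------------------------------------------------------
# Seeded random keys and structural defect injection.
#
# Generated keys are trees (every non-root couplet entered by exactly one
# lead), mirroring the shape of the builtin key; the default branching
# weights are the builtin key's observed distribution of leads per couplet
# (mostly dichotomous, a few couplets with up to seven leads).  The RNG
# algorithm identifier is recorded in the document metadata so the same
# config always serializes to byte-identical text.
# ---------------------------------------------------------------------------

# observed leads-per-couplet frequencies of the builtin key (2..7 leads)
DEFAULT_BRANCHING <- c(`2` = 101, `3` = 3, `4` = 4, `5` = 0, `6` = 2,
                       `7` = 1) / 111

GEN_ALGORITHM <- "coralkey-testgen-1 (Mersenne-Twister)"

STATEMENT_WORDS <- c("corallum", "septa", "columella", "theca", "pali",
                     "costae", "coenosteum", "calice", "epitheca",
                     "smooth", "granular", "porous", "dentate", "costate",
                     "absent", "present", "colonial", "solitary",
                     "papillose", "fascicular", "lamellar", "styliform")

GEN_REGIONS <- c("Atl.", "Pac.", "IP", "IWP", "Ant.", "SubAnt",
                 "Cosmopolitan")

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Generate a random valid key
#'
#' Builds a seeded random tree-shaped key: couplet ids `1..n_couplets` with
#' branching drawn from `branching_weights`, terminals filled from a pool
#' of synthetic genus names, and a fraction of taxa deliberately keyed at
#' more than one terminal (marked "in part") to emulate variable taxa.
#' The same configuration always yields a byte-identical serialized
#' document.
#'
#' @param n_couplets Number of couplets (>= 1).
#' @param taxon_pool_size Number of distinct synthetic taxa available
#'   (>= 2).
#' @param multiplicity_rate Probability, per terminal after the first, of
#'   reusing an already-placed taxon instead of drawing a fresh one.
#' @param branching_weights Named numeric vector of weights over 2..7
#'   leads per couplet; defaults to the builtin key's observed
#'   distribution.
#' @param seed Integer seed.
#' @return An [identification_key()] that validates clean.
#' @export
#' @examples
#' k <- generate_key(n_couplets = 10, taxon_pool_size = 8, seed = 42)
#' validate_key(k)$clean
generate_key <- function(n_couplets, taxon_pool_size,
                         multiplicity_rate = 0,
                         branching_weights = DEFAULT_BRANCHING,
                         seed) {
  n_couplets <- as.integer(n_couplets)
  taxon_pool_size <- as.integer(taxon_pool_size)
  stopifnot(length(n_couplets) == 1L, n_couplets >= 1L,
            length(seed) == 1L, is.finite(seed))
  if (taxon_pool_size < 2L)
    stop("infeasible config: taxon_pool_size must be at least 2",
         call. = FALSE)
  stopifnot(is.numeric(branching_weights), all(branching_weights >= 0),
            sum(branching_weights) > 0)
  stopifnot(is.numeric(multiplicity_rate), multiplicity_rate >= 0,
            multiplicity_rate <= 1)
  sizes <- suppressWarnings(as.integer(names(branching_weights)))
  if (is.null(names(branching_weights)) || any(is.na(sizes)) ||
      any(sizes < 2L) || any(sizes > 26L))
    stop("branching_weights must be named with lead counts in 2..26",
         call. = FALSE)

  with_seed(seed, {
    n_leads <- sizes[sample.int(length(sizes), n_couplets, replace = TRUE,
                                prob = branching_weights)]
    # targets[[i]][j]: 0 = open slot, >0 = child couplet id
    targets <- lapply(n_leads, function(b) integer(b))
    open <- if (n_couplets > 1L)
      data.frame(couplet = rep(1L, n_leads[1]),
                 slot = seq_len(n_leads[1]))
    else NULL
    for (i in seq_len(n_couplets)[-1]) {
      pick <- if (nrow(open) == 1L) 1L else sample(nrow(open), 1L)
      at <- open[pick, ]
      targets[[at$couplet]][at$slot] <- i
      open <- rbind(open[-pick, , drop = FALSE],
                    data.frame(couplet = i, slot = seq_len(n_leads[i])))
    }

    # assign taxa to the remaining open slots, in couplet/slot order
    pool <- sprintf("Genus%03d", seq_len(taxon_pool_size))
    used <- character(); fresh <- 1L
    assignment <- list()
    for (i in seq_len(n_couplets)) {
      for (j in seq_len(n_leads[i])) {
        if (targets[[i]][j] != 0L) next
        reuse <- length(used) > 0L &&
          (fresh > taxon_pool_size || stats::runif(1) < multiplicity_rate)
        name <- if (reuse) {
          if (length(used) == 1L) used else sample(used, 1L)
        } else {
          nm <- pool[fresh]; fresh <- fresh + 1L; nm
        }
        used <- unique(c(used, name))
        assignment[[paste(i, j)]] <- name
      }
    }
    tallies <- table(unlist(assignment))

    fig <- 0L
    couplets <- lapply(seq_len(n_couplets), function(i) {
      leads <- lapply(seq_len(n_leads[i]), function(j) {
        statement <- paste(
          sample(STATEMENT_WORDS, 3L, replace = TRUE), collapse = " ")
        if (targets[[i]][j] != 0L) {
          key_lead(letters[j], statement, next_id = targets[[i]][j])
        } else {
          name <- assignment[[paste(i, j)]]
          fig <<- fig + 1L
          key_lead(letters[j], statement, taxon = taxon_terminal(
            genus = name,
            in_part = tallies[[name]] > 1L,
            regions = sample(GEN_REGIONS,
                             sample(1:2, 1L)),
            figure = sprintf("F%d", fig)))
        }
      })
      key_couplet(i, leads)
    })

    identification_key(
      title = sprintf("Synthetic key (seed %d)", as.integer(seed)),
      source = "coralkey testgen",
      root = 1L, couplets = couplets,
      metadata = list(generator = GEN_ALGORITHM, seed = as.integer(seed)))
  })
}

#' Inject a structural defect into a key
#'
#' Deliberately breaks a copy of a key so that [validate_key()] must report
#' the matching error code — and only that error code:
#' \describe{
#'   \item{cycle}{a terminal lead is redirected back onto its own couplet
#'     (E2)}
#'   \item{dangling_ref}{a terminal lead is redirected to a missing couplet
#'     id (E1)}
#'   \item{orphan_couplet}{a fresh couplet reachable from nothing is added
#'     (E3)}
#'   \item{single_lead}{a couplet whose leads are all terminal is cut down
#'     to one lead (E4)}
#'   \item{duplicate_label}{a couplet's second lead is relabelled "a" (E5)}
#' }
#'
#' @param key An [identification_key()], usually from [generate_key()].
#' @param defect One of `"cycle"`, `"dangling_ref"`, `"orphan_couplet"`,
#'   `"single_lead"`, `"duplicate_label"`.
#' @param seed Integer seed for the position choices.
#' @return The broken [identification_key()].
#' @export
inject_defect <- function(key, defect = c("cycle", "dangling_ref",
                                          "orphan_couplet", "single_lead",
                                          "duplicate_label"), seed = 1L) {
  stopifnot(inherits(key, "identification_key"))
  defect <- match.arg(defect)
  terms <- terminal_table(key)
  if ((is.null(terms) || !nrow(terms)) &&
      defect %in% c("cycle", "dangling_ref", "single_lead"))
    stop("defect not applicable: key has no terminal leads", call. = FALSE)

  pick1 <- function(n) if (n == 1L) 1L else sample(n, 1L)

  with_seed(seed, {
    switch(defect,
      cycle = {
        i <- pick1(nrow(terms))
        cid <- as.character(terms$couplet[i])
        for (j in seq_along(key$couplets[[cid]]$leads)) {
          ld <- key$couplets[[cid]]$leads[[j]]
          if (ld$label == terms$label[i]) {
            key$couplets[[cid]]$leads[[j]] <-
              key_lead(ld$label, ld$statement,
                       next_id = terms$couplet[i])
          }
        }
      },
      dangling_ref = {
        i <- pick1(nrow(terms))
        cid <- as.character(terms$couplet[i])
        ghost <- max(couplet_ids(key)) + 41L
        for (j in seq_along(key$couplets[[cid]]$leads)) {
          ld <- key$couplets[[cid]]$leads[[j]]
          if (ld$label == terms$label[i]) {
            key$couplets[[cid]]$leads[[j]] <-
              key_lead(ld$label, ld$statement, next_id = ghost)
          }
        }
      },
      orphan_couplet = {
        oid <- max(couplet_ids(key)) + 1L
        orphan <- key_couplet(oid, list(
          key_lead("a", "orphan state alpha",
                   taxon = taxon_terminal("Orphanus",
                                          regions = "Atl.",
                                          figure = "F999")),
          key_lead("b", "orphan state beta",
                   taxon = taxon_terminal("Derelictus",
                                          regions = "Pac.",
                                          figure = "F999"))))
        key$couplets[[as.character(oid)]] <- orphan
      },
      single_lead = {
        # a couplet all of whose leads are terminal always exists in a
        # finished key (take one at maximal depth)
        all_term <- Filter(function(cp)
          all(vapply(cp$leads, function(ld) !is.null(ld$taxon),
                     logical(1))),
          key$couplets)
        if (!length(all_term))
          stop("defect not applicable: no fully terminal couplet",
               call. = FALSE)
        cp <- all_term[[pick1(length(all_term))]]
        key$couplets[[as.character(cp$id)]]$leads <- cp$leads[1]
      },
      duplicate_label = {
        cands <- Filter(function(cp) length(cp$leads) >= 2L, key$couplets)
        cp <- cands[[pick1(length(cands))]]
        ld <- cp$leads[[2]]
        key$couplets[[as.character(cp$id)]]$leads[[2]] <-
          key_lead("a", ld$statement, next_id = ld$next_id,
                   taxon = ld$taxon, group = ld$group)
      })
    key
  })
}
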