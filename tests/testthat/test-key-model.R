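test_that("a minimal document parses into one couplet and two terminals", {
  key <- toy_two_taxon()
  expect_s3_class(key, "identification_key")
  expect_length(key$couplets, 1)
  expect_equal(key$root, 1L)
  leads <- key$couplets[["1"]]$leads
  expect_length(leads, 2)
  expect_identical(leads[[1]]$statement, "Corallum colonial")
  expect_identical(leads[[1]]$taxon$genus, "Alpha")
  expect_identical(leads[[2]]$taxon$genus, "Beta")
})

test_that("malformed documents are rejected with informative errors", {
  expect_error(parse_key("{not json"), "malformed JSON")
  expect_error(parse_key('{"title":"t","source":"s","root":1,"bogus":1,
    "couplets":[{"id":1,"leads":[
      {"label":"a","statement":"x","taxon":{"genus":"A","regions":[]}},
      {"label":"b","statement":"y","taxon":{"genus":"B","regions":[]}}]}]}'),
    "unknown field")
  # duplicate couplet id
  expect_error(parse_key('{"title":"t","source":"s","root":1,"couplets":[
    {"id":1,"leads":[{"label":"a","statement":"x","next":1},
                     {"label":"b","statement":"y","next":1}]},
    {"id":1,"leads":[{"label":"a","statement":"x","next":1},
                     {"label":"b","statement":"y","next":1}]}]}'),
    "duplicate couplet id")
  # duplicate lead label
  expect_error(parse_key('{"title":"t","source":"s","root":1,"couplets":[
    {"id":1,"leads":[{"label":"a","statement":"x","next":1},
                     {"label":"a","statement":"y","next":1}]}]}'),
    "duplicate lead label|labels must run")
  # a lead must target exactly one of couplet or taxon
  expect_error(parse_key('{"title":"t","source":"s","root":1,"couplets":[
    {"id":1,"leads":[{"label":"a","statement":"x"},
                     {"label":"b","statement":"y","next":1}]}]}'),
    "exactly one of")
  # dangling reference under strict parsing
  dangling <- '{"title":"t","source":"s","root":1,"couplets":[
    {"id":1,"leads":[{"label":"a","statement":"x","next":999},
      {"label":"b","statement":"y",
       "taxon":{"genus":"B","regions":["Atl."]}}]}]}'
  expect_error(parse_key(dangling), "dangling reference to couplet 999")
  # ... but lenient parsing defers it to the validator
  lenient <- parse_key(dangling, strict = FALSE)
  rep <- validate_key(lenient, vocabulary = NULL)
  expect_false(rep$clean)
  expect_true("E1" %in% rep$findings$code)
})

test_that("serialize/parse round trip is the identity and preserves titles", {
  for (key in list(toy_two_taxon(), toy_multi())) {
    expect_identical(parse_key(serialize_key(key)), key)
  }
  # empty title is preserved verbatim
  empty <- parse_key('{"title":"","source":"s","root":1,"couplets":[
    {"id":1,"leads":[
      {"label":"a","statement":"x","taxon":{"genus":"A","regions":["Atl."]}},
      {"label":"b","statement":"y","taxon":{"genus":"B","regions":["Pac."]}}]}]}')
  expect_identical(parse_key(serialize_key(empty))$title, "")
})

test_that("group annotations ride on the lead and echo onto the couplet", {
  doc <- '{"title":"t","source":"s","root":1,"couplets":[
    {"id":1,"leads":[
      {"label":"a","statement":"ridged","group":"Fammily", "next":2},
      {"label":"b","statement":"smooth",
       "taxon":{"genus":"A","regions":["Atl."]}}]},
    {"id":2,"leads":[
      {"label":"a","statement":"x","taxon":{"genus":"B","regions":["Pac."]}},
      {"label":"b","statement":"y","taxon":{"genus":"C","regions":["IP"]}}]}]}'
  key <- parse_key(doc)
  expect_identical(key$couplets[["1"]]$leads[[1]]$group, "Fammily")
  expect_identical(key$couplets[["2"]]$group_label, "Fammily")
  expect_identical(parse_key(serialize_key(key)), key)
})

test_that("validator reports cycles, unreachable couplets and arity faults", {
  # redirecting a lead to its own couplet creates a cycle
  key <- toy_multi()
  key$couplets[["3"]]$leads[[1]] <- key_lead("a", "Septa smooth", next_id = 3L)
  rep <- validate_key(key, vocabulary = NULL)
  expect_false(rep$clean)
  expect_true("E2" %in% rep$findings$code)

  # an unreferenced couplet is unreachable
  key <- toy_multi()
  key$couplets[["9"]] <- key_couplet(9L, list(
    key_lead("a", "x", taxon = taxon_terminal("Zeta", regions = "Atl.")),
    key_lead("b", "y", taxon = taxon_terminal("Eta", regions = "Pac."))))
  rep <- validate_key(key, vocabulary = NULL)
  expect_true("E3" %in% rep$findings$code)

  # single-lead couplet
  key <- toy_multi()
  key$couplets[["2"]]$leads <- key$couplets[["2"]]$leads[1]
  expect_true("E4" %in% validate_key(key, vocabulary = NULL)$findings$code)
})

test_that("tree-shape deviation is a warning, not an error", {
  # two leads of couplet 1 both target couplet 2
  doc <- '{"title":"t","source":"s","root":1,"couplets":[
    {"id":1,"leads":[{"label":"a","statement":"x","next":2},
                     {"label":"b","statement":"y","next":2}]},
    {"id":2,"leads":[
      {"label":"a","statement":"x","taxon":{"genus":"A","regions":["Atl."]}},
      {"label":"b","statement":"y","taxon":{"genus":"B","regions":["Pac."]}}]}]}'
  rep <- validate_key(parse_key(doc), vocabulary = NULL)
  expect_true(rep$clean)
  w1 <- rep$findings[rep$findings$code == "W1", ]
  expect_identical(w1$severity, "warning")
  expect_match(w1$location, "couplet 2")
})

test_that("inconsistent apozooxanthellate flags across one taxon warn (W2)", {
  key <- toy_multi()
  key$couplets[["2"]]$leads[[2]]$taxon$apozooxanthellate <- TRUE  # Gamma at 2b
  rep <- validate_key(key, vocabulary = NULL)
  expect_true(rep$clean)
  expect_true("W2" %in% rep$findings$code)
  expect_true("Gamma" %in% rep$findings$location[rep$findings$code == "W2"])
})

test_that("census counts genera, subgenus pairs and multiplicity", {
  cs <- key_census(toy_two_taxon())
  expect_equal(cs$distinct_genera, 2)
  expect_equal(cs$additional_subgenera, 0)
  expect_equal(cs$terminal_lead_count, 2)
  expect_length(cs$multiply_keyed, 0)

  cs <- key_census(toy_multi())
  expect_equal(cs$distinct_genera, 4)          # Alpha Beta Gamma Delta
  expect_equal(cs$named_subgenus_pairs, 1)     # Delta (Delta)
  expect_equal(cs$additional_subgenera, 0)     # first subgenus is not "additional"
  expect_equal(cs$distinct_taxa, 4)
  expect_equal(cs$multiply_keyed[["Gamma"]], 2)
})

test_that("tree keys satisfy the edge-count identity", {
  # in a W1-clean key, couplet-targeting leads number n_couplets - 1
  for (key in list(toy_two_taxon(), toy_multi(), load_builtin_key())) {
    rep <- validate_key(key, vocabulary = NULL)
    if (!any(rep$findings$code == "W1")) {
      n_internal <- sum(vapply(key$couplets, function(cp)
        sum(vapply(cp$leads, function(ld) !is.null(ld$next_id), logical(1))),
        integer(1)))
      expect_equal(n_internal, length(key$couplets) - 1L)
    }
  }
})

test_that("constructors enforce local invariants", {
  expect_error(taxon_terminal("lowercase"), "capitalised")
  expect_error(key_lead("a", ""), "non-empty")
  expect_error(key_lead("a", "x"), "exactly one")
  expect_error(key_lead("a", "x", next_id = 2,
                        taxon = taxon_terminal("A")), "exactly one")
  expect_error(identification_key("t", "s", 5, list(
    key_couplet(1, list(key_lead("a", "x", next_id = 1),
                        key_lead("b", "y", next_id = 1))))),
    "root couplet 5")
})
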