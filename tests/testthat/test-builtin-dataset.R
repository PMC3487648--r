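key <- load_builtin_key()

test_that("the shipped key loads, validates clean, and covers couplets 1-111", {
  expect_s3_class(key, "identification_key")
  rep <- validate_key(key)
  expect_true(rep$clean)
  expect_equal(sum(rep$findings$severity == "error"), 0)
  expect_setequal(couplet_ids <- as.integer(names(key$couplets)), 1:111)
  expect_equal(key$root, 1L)
  expect_identical(key$couplets[["1"]]$leads[[1]]$statement,
                   "Corallum colonial")
})

test_that("printed polychotomies and terminals are encoded as printed", {
  expect_length(key$couplets[["69"]]$leads, 6)
  expect_length(key$couplets[["102"]]$leads, 7)
  expect_identical(
    vapply(key$couplets[["102"]]$leads, function(l) l$label, character(1)),
    letters[1:7])
  sten <- key_step(key, 68, "f")
  expect_s3_class(sten, "taxon_terminal")
  expect_identical(sten$genus, "Stenocyathus")
  expect_setequal(sten$regions, c("Atl.", "IWP", "Ant."))
  # family annotations ride the printed leads
  expect_identical(key_step_group <- key$couplets[["33"]]$leads[[1]]$group,
                   "Rhizangiidae")
  expect_identical(key$couplets[["91"]]$leads[[1]]$group, "Micrabaciidae")
  expect_identical(key$couplets[["68"]]$leads[[4]]$group,
                   "Turbinoliidae, in part")
})

test_that("every terminal carries regions and an F-numbered figure tag", {
  terms <- coralkey:::terminal_table(key)
  taxa <- attr(terms, "taxa")
  expect_equal(nrow(terms), 136)
  for (tx in taxa) {
    expect_gt(length(tx$regions), 0)
    expect_match(tx$figure, "^F[0-9]+$")
  }
  # the printed duplicate figure label is preserved uncorrected
  expect_identical(key_step(key, 111, "b")$figure, "F21")
  expect_identical(key_step(key, 102, "f")$figure, "F21")
})

test_that("apozooxanthellate flags match the printed asterisks", {
  flagged <- taxon_table(key)
  flagged <- flagged$genus[flagged$apozooxanthellate]
  expect_setequal(flagged,
                  c("Heteropsammia", "Madracis", "Oculina", "Astrangia",
                    "Balanophyllia", "Heterocyathus"))
  # no taxon is flagged at one terminal but not another
  expect_false("W2" %in% validate_key(key)$findings$code)
})

test_that("multiply keyed taxa are listed as info, led by Caryophyllia", {
  rep <- validate_key(key)
  i1 <- rep$findings[rep$findings$code == "I1", ]
  expect_true("Caryophyllia (Caryophyllia)" %in% i1$location)
  expect_match(i1$message[i1$location == "Caryophyllia (Caryophyllia)"],
               "51a, 84b, 111a")
})

test_that("the bibliography reproduces the published table of keys", {
  bib <- load_bibliography()
  expect_setequal(unique(bib$scope), c("comprehensive", "faunistic"))
  expect_equal(sum(bib$scope == "comprehensive"), 18)
  expect_equal(sum(bib$scope == "faunistic"), 40)
  expect_true(all(nzchar(bib$citation)))
  # tabular keys are flagged
  expect_true(bib$tabular[bib$subject == "Anthemiphyllia, species"])
  expect_false(bib$tabular[bib$subject == "Aulocyathus, species"])
  # the compound-citation Turbinoliidae row is one record
  expect_equal(sum(grepl("^Turbinoliidae", bib$subject) &
                     bib$scope == "comprehensive"), 1)
})

test_that("species_key_lookup is a case-insensitive substring search", {
  d <- species_key_lookup("Deltocyathus")
  expect_equal(nrow(d), 3)
  expect_equal(sum(d$scope == "comprehensive"), 1)
  expect_equal(sum(d$scope == "faunistic"), 2)
  # comprehensive rows come first
  expect_identical(d$scope[1], "comprehensive")
  expect_identical(species_key_lookup("deltocyathus"), d)
  expect_equal(nrow(species_key_lookup("Zebrafish")), 0)
  nz <- species_key_lookup("New Zealand")
  expect_true(any(grepl("Caryophyllia", nz$subject)))
  expect_true(any(grepl("Flabellum", nz$subject)))
  expect_error(species_key_lookup(""), "non-empty")
})

test_that("taxa_by_region matches tokens after variant normalization", {
  cosmo <- taxa_by_region(key, "Cosmopolitan")
  expect_true(all(c("Desmophyllum", "Lophelia", "Solenosmilia", "Javania")
                  %in% cosmo$genus))
  sa <- taxa_by_region(key, "S. Africa")
  expect_identical(sa$taxon, "Pourtalopsammia")
  # printed variants reach their canonical token
  expect_identical(normalize_region(c("I–P", "Subant.", "IWP.", "SW. Pac.")),
                   c("IP", "SubAnt", "IWP", "SW Pac."))
  goni <- taxa_by_region(key, "I–P")   # printed at couplet 15a
  expect_true("Goniocorella" %in% goni$genus)
  expect_error(taxa_by_region(key, ""), "non-empty")
  expect_warning(res <- taxa_by_region(key, "Atlantis"), "not in vocabulary")
  expect_equal(nrow(res), 0)
})

test_that("the region vocabulary covers the published abbreviation list", {
  v <- region_vocabulary()
  expect_true(all(c("Ant.", "Atl.", "IP", "IWP", "Pac.", "SubAnt",
                    "Cosmopolitan") %in% v$token))
  expect_match(v$expansion[v$token == "Cosmopolitan"], "all three oceans",
               ignore.case = TRUE)
})

test_that("distinct genera are invariant to collapsing in-part duplicates", {
  cs <- key_census(key)
  one_row_per_taxon <- taxon_table(key)
  expect_equal(length(unique(one_row_per_taxon$genus)), cs$distinct_genera)
  expect_equal(nrow(one_row_per_taxon), cs$distinct_taxa)
})
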