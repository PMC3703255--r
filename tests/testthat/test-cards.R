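test_that("gene card reproduces the CTP synthase disagreement structure", {
  corpus <- paper_fixtures("ctps")
  card <- gene_card(corpus, "CTPS")
  rows <- tidy(card)
  counts <- dplyr::count(rows, source_db)
  expect_identical(setNames(counts$n, counts$source_db),
                   c(EHMN = 2L, HumanCyc = 1L, KEGG = 2L, Reactome = 1L,
                     Recon1 = 1L))
  # glutamine-dependent for Reactome/HumanCyc, ammonium-dependent for Recon1
  expect_identical(rows$reaction_id[rows$source_db == "Reactome"], "r_gln")
  expect_identical(rows$reaction_id[rows$source_db == "HumanCyc"], "r_gln")
  expect_identical(rows$reaction_id[rows$source_db == "Recon1"], "r_amm")
  # all five databases agree on the EC number
  expect_identical(unique(rows$ec), "6.3.4.2")
  # the glutamine-dependent reactions are mutually at 100 in the
  # all-pairs similarity table
  gln <- card$similarity %>%
    dplyr::filter(reaction1 == "r_gln", reaction2 == "r_gln")
  expect_identical(nrow(gln), (4L * 3L) %/% 2L)
  expect_true(all(gln$percent_display == 100L))
  # the protonation conflict keeps ammonia/ammonium reactions below 100
  amm <- card$similarity %>%
    dplyr::filter(reaction1 == "r_amm", reaction2 == "r_amm",
                  db1 == "Recon1" | db2 == "Recon1")
  expect_true(all(amm$percent_display < 100L))
})

test_that("gene queries resolve uniquely or fail informatively", {
  corpus <- paper_fixtures("ctps")
  expect_error(gene_card(corpus, "NO_SUCH_GENE"), class = "c2_not_found")
  one_db <- gene_card(corpus, "CTPS2")
  expect_identical(unique(tidy(one_db)$source_db), "Recon1")
})

test_that("EC card separates the consensus reaction from the alternative-substrate variant", {
  corpus <- paper_fixtures("succinate_coa_ligase")
  card <- ec_card(corpus, "6.2.1.4")
  rows <- tidy(card)
  gdp <- rows[rows$reaction_id == "r_gdp", ]
  idp <- rows[rows$reaction_id == "r_idp", ]
  expect_identical(sort(gdp$source_db),
                   sort(c("EHMN", "Recon1", "HumanCyc", "KEGG", "Reactome")))
  expect_identical(sort(idp$source_db), c("EHMN", "KEGG"))
  # complexes render parenthesized with 'and'; list dialect with commas
  expect_identical(gdp$genes[gdp$source_db == "Recon1"],
                   "(SUCLG1 and SUCLG2)")
  expect_identical(gdp$genes[gdp$source_db == "EHMN"], "SUCLG1, SUCLG2")
  # the database without a pathway annotation renders the missing marker
  expect_identical(gdp$pathway[gdp$source_db == "HumanCyc"], "—")
  # unknown direction renders |==|
  expect_match(gdp$reaction[gdp$source_db == "HumanCyc"], "|==|", fixed = TRUE)
  # absent EC: empty card with the focus echoed
  none <- ec_card(corpus, "9.9.9.9")
  expect_identical(nrow(none$rows), 0L)
  expect_identical(none$focus$key, "9.9.9.9")
  expect_error(ec_card(corpus, "bad.ec"), class = "c2_parse_error")
})

test_that("fourth-component wildcard widens the EC card", {
  corpus <- paper_fixtures("cmpk1_ec")
  strict <- ec_card(corpus, "2.7.4.14")
  expect_identical(sort(unique(tidy(strict)$source_db)), c("EHMN", "KEGG"))
  wide <- ec_card(corpus, "2.7.4.14", fourth_wildcard = TRUE)
  expect_identical(dplyr::n_distinct(tidy(wide)$source_db), 5L)
  # all five databases describe the same chemistry: all pairs at 100
  expect_true(all(wide$similarity$percent_display == 100L))
  # the per-EC reference panel travels with the card
  expect_setequal(wide$ec_panels$ec, c("2.7.4.4", "2.7.4.14", "2.7.4.22"))
})

test_that("reaction card reproduces the deoxyuridine EC/gene disagreement pattern", {
  corpus <- paper_fixtures("deoxyuridine")
  card <- reaction_card(
    corpus,
    "deoxyuridine + phosphate <==> 2-deoxy-d-ribose 1-phosphate + uracil")
  rows <- tidy(card)
  expect_identical(dplyr::n_distinct(rows$source_db), 5L)
  expect_true(all(rows$overlap == "100"))
  ec_by_db <- function(db) sort(unique(as.character(unlist(
    strsplit(rows$ec[rows$source_db == db & rows$ec != "—"], ", ")))))
  expect_identical(ec_by_db("EHMN"), c("2.4.2.1", "2.4.2.4"))
  expect_identical(ec_by_db("Recon1"), character(0))
  expect_identical(ec_by_db("HumanCyc"), "2.4.2.23")
  expect_identical(ec_by_db("KEGG"), c("2.4.2.1", "2.4.2.4"))
  expect_identical(ec_by_db("Reactome"), c("2.4.2.-", "2.4.2.3"))
  # the missing gene renders as the missing marker
  expect_identical(rows$genes[rows$source_db == "HumanCyc"], "—")
  expect_identical(rows$genes[rows$source_db == "Recon1"], "PNP or UPP2")
})

test_that("reaction card by key includes its own row at 100", {
  corpus <- paper_fixtures("aconitase_steps")
  card <- reaction_card(corpus, "Recon1:r_acn", allowed_mismatches = 0)
  rows <- tidy(card)
  self <- rows[rows$source_db == "Recon1" & rows$reaction_id == "r_acn", ]
  expect_identical(self$overlap, "100")
  # the two-step description does not exact-match the one-step reaction
  expect_false(any(rows$source_db == "HumanCyc"))
  # similarity annotations equal fresh overlap() computations
  cls <- metabolite_classes(corpus)
  excl <- default_exclusion_classes(corpus)
  focus <- make_signature(corpus, "Recon1", "r_acn", cls, excl)
  for (i in seq_len(nrow(card$similarity))) {
    s <- make_signature(corpus, card$similarity$source_db[i],
                        card$similarity$local_id[i], cls, excl)
    expect_equal(card$similarity$percent[i], overlap(focus, s)$percent)
  }
})

test_that("card row multiplicity follows pathway membership", {
  # a reaction in k pathways yields k rows
  st <- c2cards:::fx_new()
  st <- c2cards:::fx_db(st, "d")
  st <- c2cards:::fx_met(st, "d", "a", "metA", "C2H4O2", kegg = "C10000")
  st <- c2cards:::fx_met(st, "d", "b", "metB", "C2H4O3", kegg = "C10001")
  st <- c2cards:::fx_gene(st, "d", "g1", hgnc = "G1", entrez = "1")
  st <- c2cards:::fx_pathway(st, "d", "p1", "Path one")
  st <- c2cards:::fx_pathway(st, "d", "p2", "Path two")
  st <- c2cards:::fx_rxn(st, "d", "r1", "a", "b", ec = "1.1.1.1",
                         genes = "g1", pathways = c("p1", "p2"))
  st <- c2cards:::fx_rxn(st, "d", "r2", "b", "a", ec = "1.1.1.1",
                         genes = "g1")
  cor <- c2cards:::fx_build(st)
  card <- gene_card(cor, "G1")
  rows <- tidy(card)
  expect_identical(nrow(rows), 3L)  # r1 x 2 pathways + r2 x 1 (missing)
  expect_identical(sum(rows$reaction_id == "r1"), 2L)
  expect_identical(rows$pathway[rows$reaction_id == "r2"], "—")
})

test_that("perspective navigation closure: card entities resolve to cards", {
  corpus <- paper_fixtures("deoxyuridine")
  card <- reaction_card(
    corpus,
    "deoxyuridine + phosphate <==> 2-deoxy-d-ribose 1-phosphate + uracil")
  rows <- tidy(card)
  for (e in unique(unlist(strsplit(rows$ec[rows$ec != "—"], ", ")))) {
    expect_s3_class(ec_card(corpus, e), "c2_card")
  }
  for (g in c("PNP", "TYMP", "UPP1", "UPP2")) {
    expect_s3_class(gene_card(corpus, g), "c2_card")
  }
  for (i in seq_len(nrow(rows))) {
    expect_s3_class(
      reaction_card(corpus, paste0(rows$source_db[i], ":", rows$reaction_id[i])),
      "c2_card")
  }
})

test_that("TSV rendering uses the fixed column order; JSON round-trips", {
  corpus <- paper_fixtures("arginase")
  card <- reaction_card(corpus, "l-arginine + H2O -> ornithine + urea",
                        allowed_mismatches = 1)
  tsv <- render_card(card, "tsv")
  lines <- strsplit(tsv, "\n")[[1]]
  expect_identical(lines[1],
                   "Database\tReaction\tOverlap(%)\tEC number\tGene(s)\tPathway")
  reactome <- grep("^Reactome", lines, value = TRUE)
  expect_identical(length(reactome), 2L)
  expect_true(all(vapply(strsplit(reactome, "\t"), `[`, "", 3) == "66"))
  # empty card renders header-only TSV
  empty <- ec_card(corpus, "9.9.9.9")
  expect_identical(render_card(empty, "tsv"),
                   paste0(lines[1], "\n"))
  # JSON round-trip is stable
  js <- render_card(card, "json")
  back <- parse_card(js)
  expect_identical(render_card(back, "json"), js)
  expect_equal(as.data.frame(back$rows), as.data.frame(card$rows))
  expect_error(render_card(card, "xml"))
})

test_that("export_all writes one export set per database and perspective", {
  corpus <- paper_fixtures("arginase")
  d <- withr::local_tempdir()
  idx <- export_all(corpus, d)
  expect_identical(sort(unique(paste(idx$source_db, idx$perspective))),
                   sort(as.vector(outer(c("Reactome", "Recon1"),
                                        c("gene", "ec", "reaction"),
                                        paste))))
  # entity counts in the index line up with corpus content statistics
  stats <- corpus_stats(corpus)
  cnt <- dplyr::count(idx, source_db, perspective)
  for (db in c("Recon1", "Reactome")) {
    expect_identical(cnt$n[cnt$source_db == db & cnt$perspective == "reaction"],
                     stats$reactions[stats$source_db == db])
    expect_identical(cnt$n[cnt$source_db == db & cnt$perspective == "ec"],
                     stats$ec_numbers[stats$source_db == db])
  }
  # every exported file exists and starts with the card header
  for (f in idx$file) {
    expect_true(file.exists(f))
    expect_match(readLines(f, n = 1), "^Database\t")
  }
})

test_that("cards tidy, glance and autoplot cleanly", {
  corpus <- paper_fixtures("ctps")
  card <- gene_card(corpus, "CTPS")
  g <- glance(card)
  expect_identical(g$n_databases, 5L)
  expect_identical(g$n_rows, 7L)
  expect_s3_class(autoplot(card), "ggplot")
  rcard <- reaction_card(corpus, "Recon1:r_amm", allowed_mismatches = 1)
  expect_s3_class(autoplot(rcard), "ggplot")
  expect_s3_class(plot_corpus_stats(corpus), "ggplot")
  expect_identical(nrow(tidy(corpus)), 5L)
  expect_identical(glance(corpus)$n_reactions, nrow(corpus$reactions))
})
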