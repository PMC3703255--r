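chain_corpus <- function(direction = "forward") {
  st <- c2cards:::fx_new()
  st <- c2cards:::fx_db(st, "d")
  for (m in c("a", "b", "c")) {
    st <- c2cards:::fx_met(st, "d", m, paste0("met", m),
                           paste0("C", which(c("a", "b", "c") == m), "H4O2"),
                           kegg = paste0("C123", which(c("a", "b", "c") == m)))
  }
  st <- c2cards:::fx_rxn(st, "d", "r1", "a", "b", direction = direction)
  st <- c2cards:::fx_rxn(st, "d", "r2", "b", "c", direction = direction)
  c2cards:::fx_build(st)
}

test_that("dead-end status follows the production/consumption definition", {
  cor <- chain_corpus("forward")
  de <- dead_end_metabolites(cor, "d")
  st <- setNames(de$status, sub("^d:", "", de$class_id))
  expect_identical(st[["a"]], "consumed_only")
  expect_identical(st[["c"]], "produced_only")
  expect_false("b" %in% names(st))
  # a single reversible reaction has no dead-ends
  st2 <- c2cards:::fx_new()
  st2 <- c2cards:::fx_db(st2, "d")
  st2 <- c2cards:::fx_met(st2, "d", "a", "metA", "C2H4O2")
  st2 <- c2cards:::fx_met(st2, "d", "b", "metB", "C2H4O3")
  st2 <- c2cards:::fx_rxn(st2, "d", "r1", "a", "b", direction = "reversible")
  expect_identical(nrow(dead_end_metabolites(c2cards:::fx_build(st2), "d")), 0L)
  # unknown direction counts as both producing and consuming too
  expect_identical(nrow(dead_end_metabolites(chain_corpus("unknown"), "d")), 0L)
  expect_error(dead_end_metabolites(cor, "nope"), class = "c2_not_found")
})

test_that("dead-end reports equal brute-force recounts on random corpora", {
  for (seed in 1:12) {
    corpus <- rand_corpus(seed, n_databases = 2, n_reactions = 6,
                          protonation = 0.2, granularity_split = 0.2,
                          alt_substrate = 0.2)
    excl <- default_exclusion_classes(corpus)
    for (db in corpus$databases$source_db) {
      got <- dead_end_metabolites(corpus, db, exclusion = excl)
      want <- oracle_dead_ends(corpus, db, exclusion = excl)
      expect_identical(got$class_id, want$class_id,
                       label = paste("seed", seed, db))
      expect_identical(got$status, want$status)
    }
  }
})

test_that("dead-end reports are stable under reordering and excluded additions", {
  corpus <- paper_fixtures("ctps")
  base <- dead_end_metabolites(corpus, "EHMN")
  shuffled <- corpus
  set.seed(1)
  shuffled$participants <- shuffled$participants[
    sample.int(nrow(shuffled$participants)), ]
  shuffled$reactions <- shuffled$reactions[
    sample.int(nrow(shuffled$reactions)), ]
  shuffled <- c2cards:::corpus_rebuild(shuffled)
  expect_equal(as.data.frame(dead_end_metabolites(shuffled, "EHMN")),
               as.data.frame(base))
  # adding water participants to every EHMN reaction changes nothing
  watered <- corpus
  extra <- tibble::tibble(source_db = "EHMN",
                          reaction_id = c("r_gln", "r_amm"),
                          metabolite_id = "h2o", side = "right",
                          compartment = NA_character_,
                          stoichiometry = NA_real_)
  watered$participants <- dplyr::distinct(
    dplyr::bind_rows(watered$participants, extra))
  watered <- c2cards:::corpus_rebuild(watered)
  expect_equal(as.data.frame(dead_end_metabolites(watered, "EHMN")),
               as.data.frame(base))
  # with exclusion disabled, water (consumed-only in this database's
  # forward reactions) is reported as a dead-end
  with_w <- dead_end_metabolites(corpus, "EHMN", apply_exclusion = FALSE)
  expect_true(any(grepl("h2o", with_w$class_id)))
  expect_identical(with_w$status[grepl("h2o", with_w$class_id)],
                   "consumed_only")
})

test_that("metabolite fate lists per-database reactions and flags dead-ends", {
  corpus <- paper_fixtures("ctps")
  fate <- metabolite_fate(corpus, "UTP")
  # UTP participates in both reactions of EHMN/KEGG/Recon1, one elsewhere
  counts <- dplyr::count(fate, source_db)
  expect_identical(setNames(counts$n, counts$source_db),
                   c(EHMN = 2L, HumanCyc = 1L, KEGG = 2L, Reactome = 1L,
                     Recon1 = 2L))
  # UTP is consumed-only everywhere: flagged as dead-end in all databases
  expect_true(all(fate$dead_end))
  expect_identical(unique(fate$dead_end_status), "consumed_only")
  # flags agree with the dedicated report
  for (db in unique(fate$source_db)) {
    de <- dead_end_metabolites(corpus, db)
    utp_cls <- metabolite_classes(corpus)
    utp_cls <- utp_cls$class_id[utp_cls$local_id == "utp"][1]
    expect_identical(unique(fate$dead_end[fate$source_db == db]),
                     utp_cls %in% de$class_id)
  }
  # every listed reaction resolves to a card
  one <- fate[1, ]
  expect_s3_class(
    reaction_card(corpus, paste0(one$source_db, ":", one$local_id)),
    "c2_card")
  expect_error(metabolite_fate(corpus, "unobtainium"), class = "c2_not_found")
})

test_that("pathway membership tables join entities to pathways", {
  st <- c2cards:::fx_new()
  st <- c2cards:::fx_db(st, "d")
  for (m in c("a", "b", "c")) st <- c2cards:::fx_met(st, "d", m, paste0("M", m))
  st <- c2cards:::fx_gene(st, "d", "g1", hgnc = "G1", entrez = "1")
  st <- c2cards:::fx_gene(st, "d", "g2", hgnc = "G2", entrez = "2")
  st <- c2cards:::fx_pathway(st, "d", "p1", "Path one")
  st <- c2cards:::fx_rxn(st, "d", "r1", c("a", "b"), "c",
                         genes = "g1 or g2", pathways = "p1")
  st <- c2cards:::fx_rxn(st, "d", "r2", "c", "a")  # no pathway
  cor <- c2cards:::fx_build(st)
  tabs <- pathway_membership_tables(cor)
  expect_identical(nrow(tabs$genes), 2L)
  expect_identical(nrow(tabs$metabolites), 3L)
  expect_identical(unique(tabs$genes$pathway_name), "Path one")
  # fixture totals equal brute-force join counts on a generated corpus
  corpus <- rand_corpus(9, n_databases = 2, n_reactions = 8)
  tabs2 <- pathway_membership_tables(corpus)
  brute_met <- merge(as.data.frame(corpus$participants),
                     as.data.frame(corpus$reaction_pathways),
                     by = c("source_db", "reaction_id"))
  brute_met <- unique(brute_met[, c("source_db", "metabolite_id", "pathway_id")])
  expect_identical(nrow(tabs2$metabolites), nrow(brute_met))
})

test_that("content statistics count distinct entities per database", {
  corpus <- paper_fixtures("deoxyuridine")
  stats <- corpus_stats(corpus)
  expect_identical(names(stats),
                   c("source_db", "genes", "ec_numbers", "reactions",
                     "pathways"))
  expect_identical(stats$reactions[stats$source_db == "KEGG"], 2L)
  expect_identical(stats$ec_numbers[stats$source_db == "Recon1"], 0L)
  # duplicating an EC link leaves the distinct count unchanged
  dup <- corpus
  dup$reaction_ec <- dplyr::bind_rows(dup$reaction_ec, dup$reaction_ec[1, ])
  dup <- c2cards:::corpus_rebuild(dup)
  expect_identical(corpus_stats(dup)$ec_numbers, stats$ec_numbers)
  # record order never matters
  shuf <- corpus
  set.seed(2)
  for (tb in c("genes", "reactions", "pathways", "reaction_ec")) {
    shuf[[tb]] <- shuf[[tb]][sample.int(nrow(shuf[[tb]])), ]
  }
  shuf <- c2cards:::corpus_rebuild(shuf)
  expect_identical(as.data.frame(corpus_stats(shuf)), as.data.frame(stats))
  # an empty database reports zeros
  empty <- c2_corpus(databases = tibble::tibble(source_db = "void"))
  expect_identical(unlist(corpus_stats(empty)[, -1]),
                   c(genes = 0L, ec_numbers = 0L, reactions = 0L,
                     pathways = 0L))
})

test_that("presence overview keeps near-duplicates on separate rows", {
  corpus <- paper_fixtures("arginase")
  ov <- presence_overview(corpus)
  # the 66%-similar arginase reactions are different exact-match classes:
  # no reaction row spans both databases (the cytosolic/mitochondrial pair
  # within each database merges, since compartments never affect matching)
  rx <- ov$reaction
  expect_identical(nrow(rx), 2L)
  expect_true(all(rowSums(as.matrix(rx[, -1])) == 1))
  # genes are shared: ARG1/ARG2 rows span both databases
  gn <- ov$gene
  expect_identical(nrow(gn), 2L)
  expect_true(all(rowSums(as.matrix(gn[, -1])) == 2))
  # every row has at least one present cell; row sums equal a recount
  corpus2 <- paper_fixtures("succinate_coa_ligase")
  ov2 <- presence_overview(corpus2)
  for (kind in names(ov2)) {
    m <- as.matrix(ov2[[kind]][, -1])
    expect_true(all(rowSums(m) >= 1), label = kind)
  }
  rcls <- exact_reaction_classes(corpus2)
  recount <- table(vapply(split(rcls$source_db, rcls$class_id),
                          dplyr::n_distinct, integer(1)))
  expect_identical(sum(rowSums(as.matrix(ov2$reaction[, -1])) == 5), 1L)
  expect_identical(sum(rowSums(as.matrix(ov2$reaction[, -1])) == 2), 1L)
})
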