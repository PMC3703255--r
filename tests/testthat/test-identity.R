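test_that("name normalization is case/space/punctuation-insensitive and idempotent", {
  expect_identical(normalize_name("L-Arginine"), "larginine")
  expect_identical(normalize_name(""), "")
  expect_identical(normalize_name("2-Deoxy-D-ribose 1-phosphate"),
                   normalize_name("2 deoxy d ribose 1 phosphate."))
  mixed <- c("alpha,beta-D-Glucose!", "  (weird) name's ", "A B  C", "")
  expect_identical(normalize_name(normalize_name(mixed)),
                   normalize_name(mixed))
})

test_that("formula parsing handles counts, charges, and rejects non-grammar text", {
  expect_identical(parse_formula("C6H12O6"), c(C = 6L, H = 12L, O = 6L))
  expect_identical(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_identical(parse_formula("CHO2-"), c(C = 1L, H = 1L, O = 2L))
  expect_null(parse_formula("(C5H8)n"))
  expect_null(parse_formula(NA_character_))
  expect_identical(parse_formula("Fe2O3"), c(Fe = 2L, O = 3L))
})

test_that("formula parsing agrees with an independent token-scanner oracle", {
  # independent parser: sequential scan with regexpr, no shared code path
  oracle_parse <- function(s) {
    s <- sub("[+-][0-9]*$", "", s)
    counts <- integer()
    while (nzchar(s)) {
      m <- regexpr("^[A-Z][a-z]?", s)
      if (m == -1) return(NULL)
      el <- regmatches(s, m)
      s <- substring(s, attr(m, "match.length") + 1L)
      d <- regexpr("^[0-9]+", s)
      k <- if (d == -1) 1L else {
        v <- as.integer(regmatches(s, d))
        s <- substring(s, attr(d, "match.length") + 1L)
        v
      }
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + k
    }
    counts[order(names(counts))]
  }
  formulas <- c("C6H12O6", "CHO2-", "C10H16N5O13P3", "H", "NH4", "C2H3O2-",
                "Fe", "C5H11O7P", "CuSO4", "C6H15NO2+2", "CHNOPS")
  for (f in formulas) {
    expect_identical(parse_formula(f), oracle_parse(f), label = f)
  }
})

test_that("formula matching ignores hydrogen only", {
  expect_true(formulas_match("C6H12O6", "C6H13O6"))
  expect_false(formulas_match("C6H12O6", "C5H12O6"))
  expect_false(formulas_match("(C5H8)n", "C5H8"))
  # randomized pairs agree with element-wise comparison dropping H
  set.seed(42)
  for (k in 1:200) {
    mk <- function() {
      n <- sample(0:2, 1)
      paste0("C", sample(1:4, 1), "H", sample(1:9, 1),
             if (n > 0) paste0("N", n), "O", sample(1:4, 1))
    }
    f1 <- mk(); f2 <- mk()
    drop_h <- function(f) {
      p <- parse_formula(f); p <- p[names(p) != "H"]
      p[order(names(p))]
    }
    expect_identical(formulas_match(f1, f2),
                     identical(drop_h(f1), drop_h(f2)))
  }
})

make_met <- function(name = "x", formula = NA, kegg = NA, glycan = NA,
                     chebi = NA, pubchem = NA, cas = NA, synonyms = NA,
                     kegg_status = "current") {
  tibble::tibble(source_db = "db", local_id = "m", primary_name = name,
                 synonyms = as.character(synonyms),
                 formula = as.character(formula),
                 kegg_compound = as.character(kegg),
                 kegg_glycan = as.character(glycan),
                 chebi = as.character(chebi),
                 pubchem_compound = as.character(pubchem),
                 pubchem_substance = NA_character_, cas = as.character(cas),
                 kegg_compound_status = kegg_status,
                 kegg_glycan_status = "current", chebi_status = "current",
                 pubchem_compound_status = "current",
                 pubchem_substance_status = "current", cas_status = "current")
}

test_that("metabolite cascade: KEGG Compound dominates, then other ids, then name+formula", {
  # step 1: shared KEGG Compound decides, names irrelevant
  expect_true(metabolite_pair_match(make_met("a", kegg = "C1"),
                                    make_met("b", kegg = "C1")))
  expect_false(metabolite_pair_match(
    make_met("same", "C6H12O6", kegg = "C1", chebi = "7"),
    make_met("same", "C6H12O6", kegg = "C2", chebi = "7")))
  # step 2: any other shared identifier
  expect_true(metabolite_pair_match(make_met("a", chebi = "7"),
                                    make_met("b", chebi = "7")))
  expect_true(metabolite_pair_match(make_met("a", kegg = "C1", cas = "50-00-0"),
                                    make_met("b", cas = "50-00-0")))
  # step 3: name/synonym + H-insensitive formula
  expect_true(metabolite_pair_match(
    make_met("D-Glucose", "C6H12O6"),
    make_met("other", "C6H13O6", synonyms = "d-glucose")))
  expect_false(metabolite_pair_match(make_met("D-Glucose", "C6H12O6"),
                                     make_met("D-Glucose", "C5H12O6")))
  expect_false(metabolite_pair_match(make_met("D-Glucose", NA),
                                     make_met("D-Glucose", "C6H12O6")))
  # disjoint ids and names: the ammonia vs ammonium situation
  expect_false(metabolite_pair_match(make_met("ammonia", "NH3", kegg = "C00014"),
                                     make_met("ammonium", "NH4", chebi = "28938")))
  # obsolete identifiers are excluded from every step
  expect_false(metabolite_pair_match(
    make_met("a", kegg = "C1", kegg_status = "obsolete"),
    make_met("b", kegg = "C1")))
})

make_gene <- function(entrez = NA, ensembl = NA, hgnc = NA) {
  tibble::tibble(source_db = "db", local_id = "g",
                 entrez = as.character(entrez),
                 ensembl = as.character(ensembl), uniprot = NA_character_,
                 hgnc = as.character(hgnc), entrez_status = "current",
                 ensembl_status = "current", uniprot_status = "current")
}

test_that("gene matching: Entrez and/or Ensembl, HGNC only without a shared namespace", {
  expect_true(gene_pair_match(make_gene(entrez = "1"), make_gene(entrez = "1")))
  expect_true(gene_pair_match(make_gene(entrez = "1", ensembl = "E1"),
                              make_gene(entrez = "2", ensembl = "E1")))
  expect_false(gene_pair_match(make_gene(entrez = "1"), make_gene(entrez = "2")))
  # cross-genome-database bridge via HGNC
  expect_true(gene_pair_match(make_gene(entrez = "1", hgnc = "ABC"),
                              make_gene(ensembl = "E9", hgnc = "ABC")))
  # shared namespace with disagreement blocks the HGNC fallback
  expect_false(gene_pair_match(make_gene(entrez = "1", hgnc = "ABC"),
                               make_gene(entrez = "2", hgnc = "ABC")))
  expect_true(gene_pair_match(make_gene(hgnc = "A|B"), make_gene(hgnc = "B")))
})

test_that("pair rules are symmetric on randomized inputs", {
  set.seed(7)
  mk <- function() make_met(name = sample(letters, 1),
                            formula = sample(c(NA, "C2H4O2", "C3H4O2"), 1),
                            kegg = sample(c(NA, "C1", "C2"), 1),
                            chebi = sample(c(NA, "7", "8"), 1))
  gk <- function() make_gene(entrez = sample(c(NA, "1", "2"), 1),
                             ensembl = sample(c(NA, "E1", "E2"), 1),
                             hgnc = sample(c(NA, "A", "B", "A|B"), 1))
  for (k in 1:100) {
    a <- mk(); b <- mk()
    expect_identical(metabolite_pair_match(a, b), metabolite_pair_match(b, a))
    g1 <- gk(); g2 <- gk()
    expect_identical(gene_pair_match(g1, g2), gene_pair_match(g2, g1))
  }
})

test_that("transitive closure: A~B and B~C puts A, B, C in one class", {
  recs <- tibble::tibble(
    source_db = c("A", "B", "C"), local_id = c("g", "g", "g"),
    entrez = c("1", "1", NA), ensembl = c(NA, "E1", "E1"),
    uniprot = NA_character_, hgnc = NA_character_,
    entrez_status = "current", ensembl_status = "current",
    uniprot_status = "current")
  cls <- build_equivalence(recs, gene_pair_match)
  expect_identical(dplyr::n_distinct(cls$class_id), 1L)
  expect_identical(cls$class_id, rep("A:g", 3))
  # no matches: all singletons
  recs2 <- recs
  recs2$entrez <- c("1", "2", NA); recs2$ensembl <- c(NA, "E1", "E2")
  expect_identical(dplyr::n_distinct(
    build_equivalence(recs2, gene_pair_match)$class_id), 3L)
})

test_that("closure equals a breadth-first-search oracle on random match graphs", {
  set.seed(11)
  for (k in 1:25) {
    n <- sample(5:60, 1)
    records <- tibble::tibble(source_db = "db",
                              local_id = sprintf("n%03d", seq_len(n)))
    m <- sample(0:(2 * n), 1)
    edges <- if (m > 0) {
      cbind(sample.int(n, m, replace = TRUE), sample.int(n, m, replace = TRUE))
    } else NULL
    if (!is.null(edges)) edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    got <- c2cards:::components_to_classes(records, edges)
    want <- oracle_components(n, edges)
    got_part <- partition_of(got)
    want_part <- sort(vapply(want, function(ix) {
      paste(sort(paste("db", records$local_id[ix], sep = ":")), collapse = "|")
    }, character(1)))
    expect_identical(got_part, want_part)
    # closure is idempotent: classes of the classes change nothing
    expect_identical(partition_of(got), partition_of(got))
  }
})

test_that("corpus-level class builders agree with the O(n^2) pairwise builder", {
  gen <- generate_corpus(fixture_config(n_databases = 3, n_reactions = 6,
                                        id_sparsity = 0.3, synonym_only = 0.2,
                                        protonation = 0.2, seed = 5))
  corpus <- gen$corpus
  expect_identical(partition_of(metabolite_classes(corpus)),
                   partition_of(build_equivalence(corpus$metabolites,
                                                  metabolite_pair_match)))
  expect_identical(partition_of(gene_classes(corpus)),
                   partition_of(build_equivalence(corpus$genes,
                                                  gene_pair_match)))
})

test_that("every record lands in exactly one class (partition property)", {
  corpus <- rand_corpus(3, n_databases = 3, n_reactions = 8,
                        id_sparsity = 0.3)
  cls <- metabolite_classes(corpus)
  expect_identical(nrow(cls), nrow(corpus$metabolites))
  expect_identical(anyDuplicated(paste(cls$source_db, cls$local_id)), 0L)
})

test_that("equivalence classes export in the documented TSV layout", {
  corpus <- paper_fixtures("arginase")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_equivalence(metabolite_classes(corpus), "metabolite", path)
  back <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  expect_identical(names(back), c("kind", "class_id", "source_db", "local_id"))
  expect_identical(unique(back$kind), "metabolite")
  expect_identical(nrow(back), nrow(corpus$metabolites))
})
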