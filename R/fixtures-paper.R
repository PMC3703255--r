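# ---- hand-coded mini-corpora ------------------------------------------------
#
# Small multi-database corpora encoding well-characterized consensus/conflict
# scenarios from human central metabolism: CTP synthase (ammonia vs ammonium
# protonation conflict), CMPK1 (divergent EC assignment for one reaction),
# aconitase (one- vs two-step granularity), succinate-CoA ligase (IDP/ITP
# alternative-substrate variant), arginase (ornithine vs l-ornithine detail
# level), and deoxyuridine phosphorolysis (EC and gene disagreement with a
# missing gene). Database labels follow the five human pathway databases
# these scenarios are drawn from.

# tiny accumulator-style corpus builder used by the fixtures
fx_new <- function() {
  list(databases = list(), metabolites = list(), genes = list(),
       reactions = list(), participants = list(), reaction_genes = list(),
       reaction_ec = list(), reaction_pathways = list(), pathways = list())
}

fx_db <- function(st, db, version = "1") {
  st$databases <- c(st$databases, list(tibble(
    source_db = db, version = version,
    url_template = paste0("https://example.org/", db, "/{id}"))))
  st
}

fx_met <- function(st, db, id, name, formula = NA, kegg = NA, chebi = NA,
                   synonyms = NA, glycan = NA, pubchem = NA, sid = NA,
                   cas = NA) {
  st$metabolites <- c(st$metabolites, list(tibble(
    source_db = db, local_id = id, primary_name = name,
    synonyms = as.character(synonyms), formula = as.character(formula),
    kegg_compound = as.character(kegg), kegg_glycan = as.character(glycan),
    chebi = as.character(chebi), pubchem_compound = as.character(pubchem),
    pubchem_substance = as.character(sid), cas = as.character(cas))))
  st
}

fx_gene <- function(st, db, id, hgnc = NA, entrez = NA, ensembl = NA,
                    uniprot = NA) {
  st$genes <- c(st$genes, list(tibble(
    source_db = db, local_id = id, entrez = as.character(entrez),
    ensembl = as.character(ensembl), uniprot = as.character(uniprot),
    hgnc = as.character(hgnc))))
  st
}

fx_pathway <- function(st, db, id, name) {
  st$pathways <- c(st$pathways, list(tibble(
    source_db = db, pathway_id = id, name = name)))
  st
}

# left/right: metabolite ids, optionally suffixed "@<compartment>"
fx_rxn <- function(st, db, id, left, right, direction = "forward",
                   ec = NULL, genes = NULL, dialect = "boolean",
                   pathways = NULL) {
  st$reactions <- c(st$reactions, list(tibble(
    source_db = db, local_id = id, direction = direction)))
  part <- function(items, side) {
    m <- stringr::str_match(items, "^([^@]+)(?:@(.+))?$")
    tibble(source_db = db, reaction_id = id, metabolite_id = m[, 2],
           side = side, compartment = m[, 3], stoichiometry = NA_real_)
  }
  st$participants <- c(st$participants,
                       list(part(left, "left"), part(right, "right")))
  if (!is.null(ec)) {
    st$reaction_ec <- c(st$reaction_ec, list(tibble(
      source_db = db, reaction_id = id, ec = ec)))
  }
  if (!is.null(genes)) {
    st$reaction_genes <- c(st$reaction_genes, list(tibble(
      source_db = db, reaction_id = id, association_text = genes,
      dialect = dialect)))
  }
  if (!is.null(pathways)) {
    st$reaction_pathways <- c(st$reaction_pathways, list(tibble(
      source_db = db, reaction_id = id, pathway_id = pathways)))
  }
  st
}

fx_build <- function(st, ec_reference = NULL) {
  cat_tbl <- function(x) if (length(x)) bind_rows(x) else NULL
  c2_corpus(databases = cat_tbl(st$databases),
            metabolites = cat_tbl(st$metabolites),
            genes = cat_tbl(st$genes),
            reactions = cat_tbl(st$reactions),
            participants = cat_tbl(st$participants),
            reaction_genes = cat_tbl(st$reaction_genes),
            reaction_ec = cat_tbl(st$reaction_ec),
            reaction_pathways = cat_tbl(st$reaction_pathways),
            pathways = cat_tbl(st$pathways),
            ec_reference = ec_reference)
}

fixture_arginase <- function() {
  st <- fx_new()
  st <- fx_db(st, "Recon1"); st <- fx_db(st, "Reactome")
  for (db in c("Recon1", "Reactome")) {
    st <- fx_met(st, db, "arg", "l-arginine", "C6H14N4O2", kegg = "C00062")
    st <- fx_met(st, db, "h2o", "H2O", "H2O", kegg = "C00001",
                 synonyms = "water")
    st <- fx_met(st, db, "urea", "urea", "CH4N2O", kegg = "C00086")
    st <- fx_gene(st, db, "arg1", hgnc = "ARG1", entrez = "383")
    st <- fx_gene(st, db, "arg2", hgnc = "ARG2", entrez = "384")
  }
  # the two databases describe ornithine at different levels of detail,
  # with distinct KEGG Compound ids and non-matching names
  st <- fx_met(st, "Recon1", "orn", "ornithine", "C5H12N2O2", kegg = "C01602")
  st <- fx_met(st, "Reactome", "orn", "l-ornithine", "C5H12N2O2",
               kegg = "C00077")
  st <- fx_pathway(st, "Recon1", "pw1", "Urea cycle / amino group metabolism")
  st <- fx_pathway(st, "Reactome", "pw1", "Urea Cycle")
  for (db in c("Recon1", "Reactome")) {
    st <- fx_rxn(st, db, "r_arg_c",
                 left = c("arg@c", "h2o@c"), right = c("orn@c", "urea@c"),
                 ec = "3.5.3.1", genes = "arg1", pathways = "pw1")
    st <- fx_rxn(st, db, "r_arg_m",
                 left = c("arg@m", "h2o@m"), right = c("orn@m", "urea@m"),
                 ec = "3.5.3.1", genes = "arg2", pathways = "pw1")
  }
  fx_build(st)
}

fixture_ctps <- function() {
  dbs <- c("EHMN", "Recon1", "HumanCyc", "KEGG", "Reactome")
  st <- fx_new()
  for (db in dbs) st <- fx_db(st, db)
  shared <- list(
    gln = c("l-glutamine", "C5H10N2O3", "C00064"),
    atp = c("ATP", "C10H16N5O13P3", "C00002"),
    utp = c("UTP", "C9H15N2O15P3", "C00075"),
    h2o = c("H2O", "H2O", "C00001"),
    glu = c("l-glutamate", "C5H9NO4", "C00025"),
    adp = c("ADP", "C10H15N5O10P2", "C00008"),
    ctp = c("CTP", "C9H16N3O14P3", "C00063"),
    pi = c("orthophosphate", "H3PO4", "C00009"))
  for (db in dbs) {
    for (id in names(shared)) {
      s <- shared[[id]]
      st <- fx_met(st, db, id, s[1], s[2], kegg = s[3],
                   synonyms = if (id == "pi") "phosphate" else NA)
    }
    st <- fx_gene(st, db, "ctps", hgnc = "CTPS", entrez = "1503")
  }
  # the neutral-form databases state ammonia; the protonated-form database
  # states ammonium, with disjoint identifiers and names
  for (db in c("EHMN", "KEGG")) {
    st <- fx_met(st, db, "nh3", "ammonia", "NH3", kegg = "C00014")
  }
  st <- fx_met(st, "Recon1", "nh4", "ammonium", "NH4", chebi = "28938")
  st <- fx_met(st, "Recon1", "h", "H+", "H", kegg = "C00080")
  st <- fx_gene(st, "Recon1", "ctps2", hgnc = "CTPS2", entrez = "56474")
  pw <- c(EHMN = "Pyrimidine metabolism", Recon1 = "Nucleotides",
          HumanCyc = "pyrimidine ribonucleotides de novo biosynthesis",
          KEGG = "Pyrimidine metabolism", Reactome = "Nucleotide biosynthesis")
  for (db in dbs) st <- fx_pathway(st, db, "pw1", unname(pw[db]))
  gln_left <- c("gln", "atp", "utp", "h2o")
  gln_right <- c("glu", "adp", "ctp", "pi")
  dialect <- function(db) if (db %in% c("EHMN", "KEGG")) "list" else "boolean"
  for (db in c("EHMN", "KEGG", "HumanCyc", "Reactome")) {
    st <- fx_rxn(st, db, "r_gln", gln_left, gln_right, ec = "6.3.4.2",
                 genes = "ctps", dialect = dialect(db), pathways = "pw1")
  }
  # Recon1 carries the glutamine-dependent reaction but links it to CTPS2
  st <- fx_rxn(st, "Recon1", "r_gln", gln_left, gln_right, ec = "6.3.4.2",
               genes = "ctps2", pathways = "pw1")
  for (db in c("EHMN", "KEGG")) {
    st <- fx_rxn(st, db, "r_amm", c("nh3", "atp", "utp"),
                 c("adp", "ctp", "pi"), ec = "6.3.4.2", genes = "ctps",
                 dialect = dialect(db), pathways = "pw1")
  }
  st <- fx_rxn(st, "Recon1", "r_amm", c("nh4", "atp", "utp"),
               c("adp", "ctp", "pi", "h"), ec = "6.3.4.2", genes = "ctps",
               pathways = "pw1")
  fx_build(st)
}

fixture_cmpk1 <- function() {
  dbs <- c("EHMN", "Recon1", "HumanCyc", "KEGG", "Reactome")
  ecs <- c(EHMN = "2.7.4.14", Recon1 = "2.7.4.22", HumanCyc = "2.7.4.22",
           KEGG = "2.7.4.14", Reactome = "2.7.4.4")
  st <- fx_new()
  shared <- list(atp = c("ATP", "C10H16N5O13P3", "C00002"),
                 ump = c("UMP", "C9H13N2O9P", "C00105"),
                 adp = c("ADP", "C10H15N5O10P2", "C00008"),
                 udp = c("UDP", "C9H14N2O12P2", "C00015"))
  for (db in dbs) {
    st <- fx_db(st, db)
    for (id in names(shared)) {
      s <- shared[[id]]
      st <- fx_met(st, db, id, s[1], s[2], kegg = s[3])
    }
    st <- fx_gene(st, db, "cmpk1", hgnc = "CMPK1", entrez = "51727")
    st <- fx_pathway(st, db, "pw1", "Pyrimidine metabolism")
    st <- fx_rxn(st, db, "r_ump", c("atp", "ump"), c("adp", "udp"),
                 direction = "reversible", ec = unname(ecs[db]),
                 genes = "cmpk1",
                 dialect = if (db %in% c("EHMN", "KEGG")) "list" else "boolean",
                 pathways = "pw1")
  }
  ec_ref <- tibble(
    ec = c("2.7.4.4", "2.7.4.14", "2.7.4.22"),
    enzyme_name = c("Nucleoside-phosphate kinase", "UMP/CMP kinase",
                    "UMP kinase"),
    reference_reaction = c(
      "ATP + nucleoside phosphate = ADP + nucleoside diphosphate",
      "(1) ATP + (d)CMP = ADP + (d)CDP; (2) ATP + UMP = ADP + UDP",
      "ATP + UMP = ADP + UDP"))
  fx_build(st, ec_reference = ec_ref)
}

fixture_aconitase <- function() {
  st <- fx_new()
  st <- fx_db(st, "Recon1"); st <- fx_db(st, "HumanCyc")
  shared <- list(cit = c("citrate", "C6H8O7", "C00158"),
                 icit = c("isocitrate", "C6H8O7", "C00311"),
                 h2o = c("H2O", "H2O", "C00001"))
  for (db in c("Recon1", "HumanCyc")) {
    for (id in names(shared)) {
      s <- shared[[id]]
      st <- fx_met(st, db, id, s[1], s[2], kegg = s[3])
    }
    st <- fx_gene(st, db, "aco1", hgnc = "ACO1", entrez = "48")
    st <- fx_pathway(st, db, "pw1", "TCA cycle")
  }
  st <- fx_met(st, "HumanCyc", "acon", "cis-aconitate", "C6H6O6",
               kegg = "C00417")
  # one database describes the conversion in a single step ...
  st <- fx_rxn(st, "Recon1", "r_acn", "cit", "icit",
               direction = "reversible", ec = "4.2.1.3", genes = "aco1",
               pathways = "pw1")
  # ... the other in two steps via cis-aconitate; gene and EC agree
  st <- fx_rxn(st, "HumanCyc", "r_acn1", "cit", c("acon", "h2o"),
               direction = "reversible", ec = "4.2.1.3", genes = "aco1",
               pathways = "pw1")
  st <- fx_rxn(st, "HumanCyc", "r_acn2", c("acon", "h2o"), "icit",
               direction = "reversible", ec = "4.2.1.3", genes = "aco1",
               pathways = "pw1")
  fx_build(st)
}

fixture_succinate <- function() {
  dbs <- c("EHMN", "Recon1", "HumanCyc", "KEGG", "Reactome")
  st <- fx_new()
  shared <- list(suc = c("succinate", "C4H6O4", "C00042"),
                 coa = c("CoA", "C21H36N7O16P3S", "C00010"),
                 gtp = c("GTP", "C10H16N5O14P3", "C00044"),
                 gdp = c("GDP", "C10H15N5O11P2", "C00035"),
                 succoa = c("succinyl-CoA", "C25H40N7O19P3S", "C00091"),
                 pi = c("phosphate", "H3PO4", "C00009"))
  for (db in dbs) {
    st <- fx_db(st, db)
    for (id in names(shared)) {
      s <- shared[[id]]
      st <- fx_met(st, db, id, s[1], s[2], kegg = s[3])
    }
    st <- fx_gene(st, db, "suclg1", hgnc = "SUCLG1", entrez = "8802")
    st <- fx_gene(st, db, "suclg2", hgnc = "SUCLG2", entrez = "8801")
  }
  # considered part of the TCA cycle by all databases except one
  for (db in setdiff(dbs, "HumanCyc")) {
    st <- fx_pathway(st, db, "pw1", "Citric acid cycle (TCA cycle)")
  }
  dialect <- function(db) if (db %in% c("EHMN", "KEGG")) "list" else "boolean"
  genes_of <- function(db) {
    if (db %in% c("EHMN", "KEGG")) "suclg1, suclg2" else "(suclg1 and suclg2)"
  }
  for (db in dbs) {
    st <- fx_rxn(st, db, "r_gdp", c("gtp", "suc", "coa"),
                 c("gdp", "succoa", "pi"),
                 direction = if (db == "HumanCyc") "unknown" else "reversible",
                 ec = "6.2.1.4", genes = genes_of(db), dialect = dialect(db),
                 pathways = if (db == "HumanCyc") NULL else "pw1")
  }
  # the alternative-substrate variant (IDP/ITP) present in two databases only
  for (db in c("EHMN", "KEGG")) {
    st <- fx_met(st, db, "itp", "ITP", "C10H14N4O14P3", kegg = "C00081")
    st <- fx_met(st, db, "idp", "IDP", "C10H13N4O11P2", kegg = "C00104")
    st <- fx_rxn(st, db, "r_idp", c("itp", "suc", "coa"),
                 c("idp", "succoa", "pi"), direction = "reversible",
                 ec = "6.2.1.4", genes = genes_of(db), dialect = dialect(db),
                 pathways = "pw1")
  }
  fx_build(st)
}

fixture_deoxyuridine <- function() {
  dbs <- c("EHMN", "Recon1", "HumanCyc", "KEGG", "Reactome")
  st <- fx_new()
  shared <- list(duri = c("deoxyuridine", "C9H12N2O5", "C00526"),
                 pi = c("phosphate", "H3PO4", "C00009"),
                 drib = c("2-deoxy-d-ribose 1-phosphate", "C5H11O7P",
                          "C00672"),
                 ura = c("uracil", "C4H4N2O2", "C00106"))
  genes <- list(pnp = c("PNP", "4860"), tymp = c("TYMP", "1890"),
                upp1 = c("UPP1", "7378"), upp2 = c("UPP2", "151531"))
  for (db in dbs) {
    st <- fx_db(st, db)
    for (id in names(shared)) {
      s <- shared[[id]]
      st <- fx_met(st, db, id, s[1], s[2], kegg = s[3])
    }
    for (id in names(genes)) {
      g <- genes[[id]]
      st <- fx_gene(st, db, id, hgnc = g[1], entrez = g[2])
    }
  }
  left <- c("duri", "pi"); right <- c("drib", "ura")
  st <- fx_pathway(st, "EHMN", "pw1", "Pyrimidine metabolism")
  st <- fx_rxn(st, "EHMN", "r1", left, right, direction = "reversible",
               ec = c("2.4.2.1", "2.4.2.4"), genes = "pnp, tymp, upp1",
               dialect = "list", pathways = "pw1")
  st <- fx_pathway(st, "Recon1", "pw1", "Nucleotides")
  st <- fx_rxn(st, "Recon1", "r1", left, right, direction = "reversible",
               genes = "pnp or upp2", pathways = "pw1")
  # no gene linked to the reaction in this database
  st <- fx_pathway(st, "HumanCyc", "pw1",
                   "salvage pathways of pyrimidine deoxyribonucleotides")
  st <- fx_rxn(st, "HumanCyc", "r1", left, right, direction = "reversible",
               ec = "2.4.2.23", pathways = "pw1")
  st <- fx_pathway(st, "KEGG", "pw1", "Pyrimidine metabolism")
  st <- fx_rxn(st, "KEGG", "r1", left, right, direction = "reversible",
               ec = "2.4.2.1", genes = "pnp", dialect = "list",
               pathways = "pw1")
  st <- fx_rxn(st, "KEGG", "r2", left, right, direction = "reversible",
               ec = "2.4.2.4", genes = "tymp", dialect = "list",
               pathways = "pw1")
  st <- fx_pathway(st, "Reactome", "pw1",
                   "Pyrimidine catabolism and Pyrimidine salvage reactions")
  st <- fx_rxn(st, "Reactome", "r1", left, right, direction = "reversible",
               ec = "2.4.2.3", genes = "upp1 or upp2", pathways = "pw1")
  st <- fx_rxn(st, "Reactome", "r2", left, right, direction = "reversible",
               ec = "2.4.2.-", genes = "tymp", pathways = "pw1")
  fx_build(st)
}

#' Hand-coded multi-database mini-corpora
#'
#' Six small corpora encoding classic cross-database conflict scenarios:
#' \describe{
#'   \item{ctps}{CTP synthase: protonation conflict (ammonia vs ammonium)
#'     and a gene-assignment disagreement (CTPS vs CTPS2).}
#'   \item{cmpk1_ec}{One kinase reaction carrying three different EC numbers
#'     across databases; includes per-EC reference text.}
#'   \item{aconitase_steps}{Citrate to isocitrate in one step vs two steps
#'     via cis-aconitate, same gene and EC throughout.}
#'   \item{succinate_coa_ligase}{EC 6.2.1.4 with a GDP-forming reaction in
#'     all five databases and an IDP/ITP variant in two.}
#'   \item{arginase}{Ornithine vs l-ornithine described at different levels
#'     of detail; the canonical one-mismatch query example.}
#'   \item{deoxyuridine}{Deoxyuridine phosphorolysis with near-total EC and
#'     gene disagreement, including a database with no gene linked.}
#' }
#'
#' @param name Optional fixture name; when given, returns that corpus only.
#' @return A named list of `c2_corpus` objects, or one corpus.
#' @export
paper_fixtures <- function(name = NULL) {
  builders <- list(ctps = fixture_ctps,
                   cmpk1_ec = fixture_cmpk1,
                   aconitase_steps = fixture_aconitase,
                   succinate_coa_ligase = fixture_succinate,
                   arginase = fixture_arginase,
                   deoxyuridine = fixture_deoxyuridine)
  if (!is.null(name)) {
    if (!name %in% names(builders)) {
      abort(paste0("unknown fixture '", name, "'; available: ",
                   paste(names(builders), collapse = ", ")),
            class = "c2_not_found")
    }
    return(builders[[name]]())
  }
  lapply(builders, function(f) f())
}
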