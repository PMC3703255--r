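# ---- deterministic synthetic corpora ----------------------------------------
#
# A base metabolic network (a linear chain with cofactor branches, enough
# structure to create metabolite fates and dead-ends) is replicated across
# databases and perturbed per configurable conflict-class rates. Identifiers
# are assigned so the identity rules can — or, for identity-destroying
# perturbations, deliberately cannot — recover the construction ground truth,
# which is returned alongside the corpus.

#' Configuration for the synthetic-corpus generator
#'
#' Conflict rates are per-(database, reaction) or per-(database, metabolite)
#' Bernoulli probabilities in \[0, 1\]:
#' \describe{
#'   \item{granularity_split}{replace a reaction by two steps via a new
#'     database-private intermediate metabolite (same gene and EC).}
#'   \item{generic_specific}{replace one metabolite by a database-private
#'     "generic form" record with no shared identifiers.}
#'   \item{protonation}{replace one metabolite by a protonated variant
#'     (formula differs by one H, name and identifiers disjoint).}
#'   \item{alt_substrate}{add a variant reaction with one co-substrate
#'     swapped for a database-private alternative.}
#'   \item{missing_gene}{drop the reaction's gene association.}
#'   \item{gpr_divergence}{flip the Boolean operator (isozymes vs complex)
#'     of a two-gene association.}
#'   \item{id_sparsity}{drop a metabolite's KEGG Compound and ChEBI ids,
#'     leaving name + formula as the only match evidence.}
#'   \item{synonym_only}{drop all identifiers and swap the primary name for
#'     a synonym (the original name survives in the synonym list).}
#' }
#' The defaults describe a clean replication (all rates 0) of a 30-reaction
#' network across five databases.
#'
#' @param n_databases Number of databases (labels follow the five human
#'   pathway databases, then `db6`, `db7`, ...).
#' @param n_reactions Base-network reactions per database.
#' @param granularity_split,generic_specific,protonation,alt_substrate,
#'   missing_gene,gpr_divergence,id_sparsity,synonym_only Conflict rates.
#' @param seed Integer seed; same seed + config gives a byte-identical
#'   corpus.
#' @return A `c2_fixture_config` list.
#' @export
fixture_config <- function(n_databases = 5, n_reactions = 30,
                           granularity_split = 0, generic_specific = 0,
                           protonation = 0, alt_substrate = 0,
                           missing_gene = 0, gpr_divergence = 0,
                           id_sparsity = 0, synonym_only = 0, seed = 1) {
  rates <- c(granularity_split = granularity_split,
             generic_specific = generic_specific, protonation = protonation,
             alt_substrate = alt_substrate, missing_gene = missing_gene,
             gpr_divergence = gpr_divergence, id_sparsity = id_sparsity,
             synonym_only = synonym_only)
  if (any(rates < 0 | rates > 1)) {
    abort("conflict rates must lie in [0, 1]", class = "c2_config_error")
  }
  if (n_databases < 1 || n_reactions < 1) {
    abort("need at least one database and one reaction",
          class = "c2_config_error")
  }
  structure(c(list(n_databases = n_databases, n_reactions = n_reactions),
              as.list(rates), list(seed = as.integer(seed))),
            class = "c2_fixture_config")
}

fixture_db_labels <- function(n) {
  base <- c("EHMN", "Recon1", "HumanCyc", "KEGG", "Reactome")
  if (n <= 5) base[seq_len(n)] else c(base, paste0("db", 6:n))
}

#' Generate a synthetic multi-database corpus with ground truth
#'
#' @param config A [fixture_config()].
#' @return A list with `corpus` (a valid `c2_corpus`), and `truth`: tibbles
#'   `metabolites`, `genes`, `reactions` mapping every record to its true
#'   equivalence class, plus `conflicts` labelling each perturbation
#'   `(source_db, base_reaction, local_id, conflict)`.
#' @export
generate_corpus <- function(config = fixture_config()) {
  stopifnot(inherits(config, "c2_fixture_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  dbs <- fixture_db_labels(cfg$n_databases)
  nr <- cfg$n_reactions
  n_cof <- max(4L, nr %/% 4L)

  # ---- base network (shared blueprint) --------------------------------------
  chain_ids <- paste0("m", sprintf("%03d", seq_len(nr + 1L)))
  cof_ids <- paste0("c", sprintf("%02d", seq_len(n_cof)))
  met_ids <- c(chain_ids, cof_ids, "h2o")
  met_base <- tibble(
    base_id = met_ids,
    primary_name = c(paste0("Metabolite-", seq_len(nr + 1L)),
                     paste0("Cofactor-", seq_len(n_cof)), "H2O"),
    synonyms = c(paste0("compound ", seq_len(nr + 1L)),
                 paste0("cofactor ", seq_len(n_cof)), "water"),
    formula = c(sprintf("C%dH%dO%d", 2L + seq_len(nr + 1L) %% 9L,
                        3L + seq_len(nr + 1L) %% 11L,
                        1L + seq_len(nr + 1L) %% 5L),
                sprintf("C%dH%dN%dO%d", 8L + seq_len(n_cof) %% 5L,
                        10L + seq_len(n_cof) %% 7L,
                        1L + seq_len(n_cof) %% 4L,
                        5L + seq_len(n_cof) %% 6L),
                "H2O"),
    kegg_compound = c(sprintf("C%05d", 10000L + seq_len(nr + 1L)),
                      sprintf("C%05d", 20000L + seq_len(n_cof)), "C00001"),
    chebi = as.character(30000L + seq_along(met_ids)))

  n_genes <- max(2L, nr)
  gene_base <- tibble(
    base_id = paste0("g", sprintf("%03d", seq_len(n_genes))),
    hgnc = paste0("GENE", seq_len(n_genes)),
    entrez = as.character(5000L + seq_len(n_genes)),
    ensembl = sprintf("ENSG%011d", seq_len(n_genes)))

  # reaction i: chain[i] + cofactor -> chain[i+1] (+ cofactor'), some with
  # water; 1-2 genes; EC from a compact grid; pathway blocks of 5
  cof_in <- sample(n_cof, nr, replace = TRUE)
  cof_out <- sample(n_cof, nr, replace = TRUE)
  with_cof_out <- stats::runif(nr) < 0.6
  with_water <- stats::runif(nr) < 0.3
  directions <- sample(c("forward", "reversible", "unknown"), nr,
                       replace = TRUE, prob = c(0.6, 0.3, 0.1))
  gene1 <- sample(n_genes, nr, replace = TRUE)
  gene2 <- sample(n_genes, nr, replace = TRUE)
  two_genes <- stats::runif(nr) < 0.4
  gene_op <- sample(c("or", "and"), nr, replace = TRUE)
  ecs <- sprintf("%d.%d.%d.%d", 1L + seq_len(nr) %% 6L,
                 1L + seq_len(nr) %% 9L, 1L + seq_len(nr) %% 7L, seq_len(nr))
  pw_of <- paste0("pw", sprintf("%02d", 1L + (seq_len(nr) - 1L) %/% 5L))
  base_rxn <- tibble(
    base_id = paste0("r", sprintf("%03d", seq_len(nr))),
    direction = directions, ec = ecs, pathway = pw_of)
  base_left <- lapply(seq_len(nr), function(i) {
    c(chain_ids[i], cof_ids[cof_in[i]], if (with_water[i]) "h2o")
  })
  base_right <- lapply(seq_len(nr), function(i) {
    unique(c(chain_ids[i + 1L], if (with_cof_out[i]) cof_ids[cof_out[i]]))
  })
  base_genes <- lapply(seq_len(nr), function(i) {
    if (two_genes[i] && gene2[i] != gene1[i]) {
      gene_base$base_id[c(gene1[i], gene2[i])]
    } else gene_base$base_id[gene1[i]]
  })

  # ---- replicate and perturb ------------------------------------------------
  st <- fx_new()
  truth_met <- list(); truth_gene <- list(); truth_rxn <- list()
  conflicts <- list()
  bern <- function(p) stats::runif(1) < p

  for (db in dbs) {
    st <- fx_db(st, db, version = "synthetic")
    dialect <- if (db %in% c("EHMN", "KEGG")) "list" else "boolean"
    # metabolite records, with id-level perturbations
    met_db <- met_base
    for (j in seq_len(nrow(met_db))) {
      kind <- NULL
      if (bern(cfg$synonym_only)) kind <- "synonym_only"
      else if (bern(cfg$id_sparsity)) kind <- "id_sparsity"
      row <- met_db[j, ]
      if (identical(kind, "id_sparsity")) {
        row$kegg_compound <- NA_character_
        row$chebi <- NA_character_
      } else if (identical(kind, "synonym_only")) {
        row$kegg_compound <- NA_character_
        row$chebi <- NA_character_
        row$synonyms <- paste(row$primary_name, row$synonyms, sep = "|")
        row$primary_name <- paste0(toupper(substr(db, 1, 2)), " form of ",
                                   met_db$primary_name[j])
      }
      st <- fx_met(st, db, row$base_id, row$primary_name, row$formula,
                   kegg = row$kegg_compound, chebi = row$chebi,
                   synonyms = row$synonyms)
      truth_met[[length(truth_met) + 1L]] <-
        tibble(source_db = db, local_id = row$base_id,
               true_class = row$base_id)
      if (!is.null(kind)) {
        conflicts[[length(conflicts) + 1L]] <-
          tibble(source_db = db, base_reaction = NA_character_,
                 local_id = row$base_id, conflict = kind)
      }
    }
    for (j in seq_len(nrow(gene_base))) {
      st <- fx_gene(st, db, gene_base$base_id[j], hgnc = gene_base$hgnc[j],
                    entrez = gene_base$entrez[j],
                    ensembl = gene_base$ensembl[j])
      truth_gene[[length(truth_gene) + 1L]] <-
        tibble(source_db = db, local_id = gene_base$base_id[j],
               true_class = gene_base$base_id[j])
    }
    for (p in unique(base_rxn$pathway)) {
      st <- fx_pathway(st, db, p, paste0("Pathway ", sub("pw0*", "", p)))
    }

    add_private_met <- function(st, id, name, formula) {
      st <- fx_met(st, db, id, name, formula)
      truth_met[[length(truth_met) + 1L]] <<-
        tibble(source_db = db, local_id = id,
               true_class = rec_key(db, id))
      st
    }
    assoc_text <- function(gids, op) {
      if (length(gids) == 1L) return(gids)
      if (dialect == "list") return(paste(gids, collapse = ", "))
      if (op == "and") paste0("(", paste(gids, collapse = " and "), ")")
      else paste(gids, collapse = " or ")
    }

    for (i in seq_len(nr)) {
      rid <- base_rxn$base_id[i]
      left <- base_left[[i]]; right <- base_right[[i]]
      gids <- base_genes[[i]]; op <- gene_op[i]
      ec <- base_rxn$ec[i]; pw <- base_rxn$pathway[i]
      dir <- base_rxn$direction[i]
      perturbed <- FALSE

      if (bern(cfg$gpr_divergence) && length(gids) == 2L) {
        op <- if (op == "and") "or" else "and"
        conflicts[[length(conflicts) + 1L]] <-
          tibble(source_db = db, base_reaction = rid, local_id = rid,
                 conflict = "gpr_divergence")
      }
      drop_gene <- bern(cfg$missing_gene)
      if (drop_gene) {
        conflicts[[length(conflicts) + 1L]] <-
          tibble(source_db = db, base_reaction = rid, local_id = rid,
                 conflict = "missing_gene")
      }
      genes_txt <- if (drop_gene) NULL else assoc_text(gids, op)

      if (bern(cfg$granularity_split)) {
        # two steps via a database-private intermediate
        int_id <- paste0(rid, "_int")
        st <- add_private_met(st, int_id,
                              paste0("intermediate ", rid, " (", db, ")"),
                              "C7H9O3")
        for (part in c("a", "b")) {
          sub_id <- paste0(rid, part)
          st <- fx_rxn(st, db, sub_id,
                       left = if (part == "a") left else int_id,
                       right = if (part == "a") int_id else right,
                       direction = dir, ec = ec, genes = genes_txt,
                       dialect = dialect, pathways = pw)
          truth_rxn[[length(truth_rxn) + 1L]] <-
            tibble(source_db = db, local_id = sub_id,
                   true_class = rec_key(db, sub_id), base_reaction = rid)
        }
        conflicts[[length(conflicts) + 1L]] <-
          tibble(source_db = db, base_reaction = rid, local_id = rid,
                 conflict = "granularity_split")
        next
      }
      if (bern(cfg$protonation)) {
        target <- left[1]
        var_id <- paste0(target, "_prot")
        f <- parse_formula(met_base$formula[met_base$base_id == target])
        f["H"] <- (if ("H" %in% names(f)) f[["H"]] else 0L) + 1L
        st <- add_private_met(st, var_id,
                              paste0(met_base$primary_name[
                                met_base$base_id == target],
                                " (protonated, ", db, ")"),
                              paste0(names(f), ifelse(f > 1L, f, ""),
                                     collapse = ""))
        left[1] <- var_id
        perturbed <- TRUE
        conflicts[[length(conflicts) + 1L]] <-
          tibble(source_db = db, base_reaction = rid, local_id = rid,
                 conflict = "protonation")
      } else if (bern(cfg$generic_specific)) {
        target <- left[1]
        var_id <- paste0(target, "_gen")
        st <- add_private_met(st, var_id,
                              paste0("a generic ", met_base$primary_name[
                                met_base$base_id == target], " (", db, ")"),
                              met_base$formula[met_base$base_id == target])
        left[1] <- var_id
        perturbed <- TRUE
        conflicts[[length(conflicts) + 1L]] <-
          tibble(source_db = db, base_reaction = rid, local_id = rid,
                 conflict = "generic_specific")
      }
      st <- fx_rxn(st, db, rid, left, right, direction = dir, ec = ec,
                   genes = genes_txt, dialect = dialect, pathways = pw)
      truth_rxn[[length(truth_rxn) + 1L]] <-
        tibble(source_db = db, local_id = rid,
               true_class = if (perturbed) rec_key(db, rid) else rid,
               base_reaction = rid)

      if (bern(cfg$alt_substrate)) {
        alt_id <- paste0(rid, "_altmet")
        st <- add_private_met(st, alt_id,
                              paste0("alternative substrate ", rid,
                                     " (", db, ")"), "C9H11NO2")
        alt_left <- base_left[[i]]
        alt_left[min(2L, length(alt_left))] <- alt_id
        alt_rid <- paste0(rid, "x")
        st <- fx_rxn(st, db, alt_rid, alt_left, right, direction = dir,
                     ec = ec, genes = genes_txt, dialect = dialect,
                     pathways = pw)
        truth_rxn[[length(truth_rxn) + 1L]] <-
          tibble(source_db = db, local_id = alt_rid,
                 true_class = rec_key(db, alt_rid), base_reaction = rid)
        conflicts[[length(conflicts) + 1L]] <-
          tibble(source_db = db, base_reaction = rid, local_id = alt_rid,
                 conflict = "alt_substrate")
      }
    }
  }

  corpus <- fx_build(st)
  truth <- list(
    metabolites = bind_rows(truth_met) %>%
      arrange(.data$source_db, .data$local_id),
    genes = bind_rows(truth_gene) %>%
      arrange(.data$source_db, .data$local_id),
    reactions = bind_rows(truth_rxn) %>%
      arrange(.data$source_db, .data$local_id),
    conflicts = if (length(conflicts)) bind_rows(conflicts) else
      tibble(source_db = character(), base_reaction = character(),
             local_id = character(), conflict = character()))
  list(corpus = corpus, truth = truth)
}

#' Compare two class assignments as partitions
#'
#' Class labels are arbitrary; two assignments agree when they induce the
#' same partition of the records into groups.
#'
#' @param classes Tibble with `source_db`, `local_id` and a class column
#'   (`class_id` or `true_class`).
#' @param truth Second tibble in the same form.
#' @return `TRUE` iff the partitions coincide.
#' @export
same_partition <- function(classes, truth) {
  canon <- function(tbl) {
    col <- intersect(c("class_id", "true_class"), names(tbl))[1]
    tbl %>%
      mutate(key = rec_key(.data$source_db, .data$local_id)) %>%
      group_by(.data[[col]]) %>%
      summarise(members = paste(sort(.data$key), collapse = "|"),
                .groups = "drop") %>%
      pull("members") %>% sort()
  }
  identical(canon(classes), canon(truth))
}
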