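# Independent brute-force oracles used to cross-check the package's
# join-based implementations, plus small random-input generators.

# connected components by hand-rolled breadth-first search; returns the
# partition as a sorted list of sorted member-key vectors
oracle_components <- function(n, edges) {
  adj <- vector("list", n)
  if (!is.null(edges) && nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) {
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, function(x) x[1], integer(1)))]
}

# partition induced by a classes tibble, as sorted member-key strings
partition_of <- function(classes) {
  key <- paste(classes$source_db, classes$local_id, sep = ":")
  unname(sort(vapply(split(key, classes$class_id),
                     function(m) paste(sort(m), collapse = "|"),
                     character(1))))
}

# brute-force overlap on two side-sets, enumerating both orientations
oracle_overlap <- function(l1, r1, l2, r2) {
  isz <- function(a, b) length(intersect(a, b))
  par <- isz(l1, l2) + isz(r1, r2)
  anti <- isz(l1, r2) + isz(r1, l2)
  matches <- max(par, anti)
  denom <- max(length(l1) + length(r1), length(l2) + length(r2))
  list(matches = matches,
       percent = if (denom == 0) 0 else matches / denom * 100,
       mismatches = denom - matches)
}

rand_signature <- function(universe = 20, max_side = 4) {
  pool <- paste0("cls", seq_len(universe))
  pick <- function() sample(pool, sample(0:max_side, 1))
  c2cards:::new_signature("rnd", paste0("s", sample.int(1e6, 1)),
                          sort(pick()), sort(pick()))
}

# brute-force per-database dead-end recount over raw participant rows
oracle_dead_ends <- function(corpus, db, exclusion = character()) {
  classes <- metabolite_classes(corpus)
  cls_of <- setNames(classes$class_id,
                     paste(classes$source_db, classes$local_id, sep = ":"))
  pa <- corpus$participants[corpus$participants$source_db == db, ]
  rxn <- corpus$reactions
  produced <- list(); consumed <- list()
  for (k in seq_len(nrow(pa))) {
    cls <- cls_of[[paste(db, pa$metabolite_id[k], sep = ":")]]
    if (cls %in% exclusion) next
    dir <- rxn$direction[rxn$source_db == db & rxn$local_id == pa$reaction_id[k]]
    both <- dir %in% c("reversible", "unknown")
    if (both || pa$side[k] == "left") consumed[[cls]] <- TRUE
    if (both || pa$side[k] == "right") produced[[cls]] <- TRUE
  }
  all_cls <- union(names(produced), names(consumed))
  out <- lapply(all_cls, function(cl) {
    p <- isTRUE(produced[[cl]]); co <- isTRUE(consumed[[cl]])
    if (p && !co) data.frame(class_id = cl, status = "produced_only")
    else if (co && !p) data.frame(class_id = cl, status = "consumed_only")
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(class_id = character(), status = character())
  else out[order(out$class_id), , drop = FALSE]
}

# small random corpus via the generator, with mixed conflict rates
rand_corpus <- function(seed, n_databases = 2, n_reactions = 6, ...) {
  generate_corpus(fixture_config(n_databases = n_databases,
                                 n_reactions = n_reactions, seed = seed,
                                 ...))$corpus
}
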