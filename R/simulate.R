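# Synthetic two-species comparative functional-genomics data.
#
# The generator emulates the statistical structure of the real inputs: two
# species separated by a single speciation event, gene families shaped by a
# birth process of duplications before and after the split (with optional
# relocation of the new copy to another chromosome), codon sequences
# evolving by independent synonymous/nonsynonymous Poisson substitution,
# annotation term sets evolving by Poisson gain/loss, and cross-tissue
# expression profiles evolving by Brownian drift. A "species context shift"
# plants extra functional divergence across the speciation boundary: it has
# an organism-wide component (applied identically to every lineage entering
# a species, so that two same-species genes are not driven apart by it) and
# a per-lineage component. Interchromosomal duplicates can receive an extra
# divergence multiplier on the relocated branch. Everything is driven by a
# single seed and is byte-identical across runs with an equal configuration.

#' Simulation configuration
#'
#' Returns the default configuration, with any field overridable by name.
#' Times are in units of the species divergence time (the speciation is at
#' `t_speciation = 1` and leaves are sampled at `t_total = 2`, so one-to-one
#' orthologs have divergence time 2). Rates are per time unit.
#'
#' @param ... named overrides of the defaults.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_families = 600L,
    # family birth process
    t_speciation = 1, t_total = 2,
    dup_rate = 0.4, max_duplications = 8L,
    p_relocate = 0.35, n_chromosomes = 20L,
    # sequences
    n_codons = 150L, mu_nonsyn = 0.06, mu_syn = 0.30,
    # ontologies
    n_terms_bp = 400L, n_terms_mf = 250L,
    max_ontology_depth = 5L, p_extra_parent = 0.15, p_part_of = 0.3,
    # annotation evolution
    n_root_terms_bp = 10L, n_root_terms_mf = 8L,
    lambda_gain = 4, lambda_loss = 4, mf_rate_scale = 0.5,
    delta = 0.75, delta_shared_frac = 0.5,
    chrom_multiplier = 1.5,
    annotation_sparsity = 0.6,
    evidence_probs = c(IDA = 0.30, IMP = 0.20, IPI = 0.12, IGI = 0.10,
                       IEP = 0.05, TAS = 0.18, IC = 0.05),
    p_same_publication = 0.4, p_second_publication = 0.2,
    # expression
    n_tissues = 25L, sigma2_expr = 0.35, expr_scale = 0.8, expr_base = 6,
    measurement_sd = 0.05, n_duplicate_tissues = 3L,
    probes_per_set = 16L, probe_length = 25L, p_ambiguous_probeset = 0.05
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$n_tissues >= 3, cfg$t_speciation < cfg$t_total,
            cfg$dup_rate >= 0, cfg$delta >= 0, cfg$chrom_multiplier >= 0,
            cfg$annotation_sparsity >= 0, cfg$annotation_sparsity <= 1)
  structure(cfg, class = "sim_config")
}

# ---- ontology ----

#' Generate a random single-rooted ontology DAG
#'
#' Terms are attached under random parents (bounded depth); a fraction of
#' terms receive a second parent at a strictly smaller depth, creating
#' diamonds, via `is_a` or `part_of` relations. The output always passes
#' [load_obo()] validation.
#'
#' @param n_terms number of terms (>= 3).
#' @param namespace namespace string written into the OBO stanzas.
#' @param prefix term-id prefix.
#' @param max_depth,p_extra_parent,p_part_of shape parameters.
#' @return list with `terms` (data frame `id`, `name`, `namespace`),
#'   `edges` (data frame `child`, `parent`, `rel`), `root`, `leaves`.
#' @export
generate_ontology <- function(n_terms, namespace = "biological_process",
                              prefix = "BP", max_depth = 8,
                              p_extra_parent = 0.15, p_part_of = 0.3) {
  stopifnot(n_terms >= 3)
  ids <- sprintf("%s:%05d", prefix, seq_len(n_terms))
  depth <- integer(n_terms); depth[1] <- 0L
  child <- parent <- rel <- character(0)
  for (i in 2:n_terms) {
    cand <- which(depth[seq_len(i - 1L)] < max_depth)
    p <- cand[sample.int(length(cand), 1L)]
    depth[i] <- depth[p] + 1L
    child <- c(child, ids[i]); parent <- c(parent, ids[p]); rel <- c(rel, "is_a")
    if (stats::runif(1) < p_extra_parent) {
      cand2 <- which(depth[seq_len(i - 1L)] < depth[i])
      cand2 <- setdiff(cand2, p)
      if (length(cand2)) {
        p2 <- cand2[sample.int(length(cand2), 1L)]
        child <- c(child, ids[i]); parent <- c(parent, ids[p2])
        rel <- c(rel, if (stats::runif(1) < p_part_of) "part_of" else "is_a")
      }
    }
  }
  leaves <- setdiff(ids, parent)
  list(terms = data.frame(id = ids, name = paste0("term ", ids),
                          namespace = namespace, stringsAsFactors = FALSE),
       edges = data.frame(child = child, parent = parent, rel = rel,
                          stringsAsFactors = FALSE),
       root = ids[1], leaves = leaves)
}

#' Write ontologies to an OBO 1.2 file
#' @param ontologies list of objects from [generate_ontology()].
#' @param path output file.
#' @export
write_obo <- function(ontologies, path) {
  out <- c("format-version: 1.2", "")
  for (ont in ontologies) {
    for (i in seq_len(nrow(ont$terms))) {
      id <- ont$terms$id[i]
      out <- c(out, "[Term]",
               paste0("id: ", id),
               paste0("name: ", ont$terms$name[i]),
               paste0("namespace: ", ont$terms$namespace[i]))
      ee <- ont$edges[ont$edges$child == id, , drop = FALSE]
      for (j in seq_len(nrow(ee))) {
        out <- c(out, if (ee$rel[j] == "is_a") {
          paste0("is_a: ", ee$parent[j])
        } else {
          paste0("relationship: ", ee$rel[j], " ", ee$parent[j])
        })
      }
      out <- c(out, "")
    }
  }
  writeLines(out, path)
  invisible(path)
}

# ---- gene family birth process ----

#' Simulate one gene family
#'
#' A single ancestral lineage duplicates at rate `dup_rate`; every lineage
#' alive at `t_speciation` splits into one copy per species; duplications
#' continue independently within each species until `t_total`. Each
#' duplication relocates the new copy to a different chromosome with
#' probability `p_relocate`. Internal nodes carry their true event and age.
#'
#' @param config a `sim_config`.
#' @param family_id family identifier used in gene names.
#' @return list with `nodes` (data frame: `id`, `parent`, `time`, `event`,
#'   `species`, `chromosome`, `relocated`, `gene_id`), `genes` (gene
#'   metadata for the leaves), `newick` (NHX-tagged string).
#' @export
simulate_family <- function(config, family_id = "F0001") {
  env <- new.env()
  env$rows <- list()
  env$n_dup <- 0L
  chrom0 <- sprintf("chr%02d", sample.int(config$n_chromosomes, 1L))
  add <- function(parent, time, event, species, chrom, relocated) {
    id <- length(env$rows) + 1L
    env$rows[[id]] <- list(id = id, parent = parent, time = time, event = event,
                           species = species, chromosome = chrom,
                           relocated = relocated)
    id
  }
  grow <- function(parent, t0, species, chrom, relocated) {
    repeat {
      horizon <- if (species == "anc") config$t_speciation else config$t_total
      wait <- if (config$dup_rate > 0) stats::rexp(1, config$dup_rate) else Inf
      t_dup <- t0 + wait
      if (t_dup < horizon && env$n_dup < config$max_duplications) {
        env$n_dup <- env$n_dup + 1L
        me <- add(parent, t_dup, "duplication", species, chrom, relocated)
        grow(me, t_dup, species, chrom, relocated)
        reloc <- stats::runif(1) < config$p_relocate
        chrom2 <- if (reloc) {
          sprintf("chr%02d", sample.int(config$n_chromosomes, 1L))
        } else chrom
        # a relocated copy's whole descendant lineage keeps the flag: its
        # functional context stays foreign to the ancestral locus
        parent <- me; t0 <- t_dup; chrom <- chrom2
        relocated <- relocated || reloc
        # continue as the second (possibly relocated) copy
        next
      }
      if (species == "anc") {
        me <- add(parent, config$t_speciation, "speciation", species, chrom, relocated)
        grow(me, config$t_speciation, "A", chrom, FALSE)
        grow(me, config$t_speciation, "B", chrom, FALSE)
      } else {
        add(parent, config$t_total, "leaf", species, chrom, relocated)
      }
      return(invisible(NULL))
    }
  }
  grow(NA_integer_, 0, "anc", chrom0, FALSE)
  nodes <- do.call(rbind, lapply(env$rows, function(r) {
    data.frame(id = r$id, parent = r$parent, time = r$time, event = r$event,
               species = r$species, chromosome = r$chromosome,
               relocated = r$relocated, stringsAsFactors = FALSE)
  }))
  # assign gene ids to leaves, per species, in node order
  nodes$gene_id <- NA_character_
  for (sp in c("A", "B")) {
    sel <- which(nodes$event == "leaf" & nodes$species == sp)
    nodes$gene_id[sel] <- sprintf("%s%s%d", family_id, sp, seq_along(sel))
  }
  genes <- nodes[nodes$event == "leaf",
                 c("gene_id", "species", "chromosome"), drop = FALSE]
  rownames(genes) <- NULL
  list(nodes = nodes, genes = genes, newick = family_newick(nodes))
}

family_newick <- function(nodes) {
  children <- split(nodes$id, factor(nodes$parent, levels = nodes$id))
  fmt <- function(id) {
    nd <- nodes[id, ]
    kids <- children[[as.character(id)]]
    if (nd$event == "leaf") {
      lab <- nd$gene_id
    } else {
      tag <- if (nd$event == "duplication") "[&&NHX:D=Y]" else "[&&NHX:D=N]"
      lab <- paste0("(", paste(vapply(kids, fmt, character(1)), collapse = ","),
                    ")", tag)
    }
    if (is.na(nd$parent)) return(paste0(lab, ";"))
    bl <- nd$time - nodes$time[nd$parent]
    paste0(lab, ":", format(bl, digits = 10))
  }
  root <- nodes$id[is.na(nodes$parent)]
  fmt(root)
}

#' True homolog classes and divergence times of a simulated family
#'
#' Derived from the generator's own node ages (a duplication is an
#' inparalog-maker iff it postdates the speciation), independently of the
#' topology-based classifier, so the two can be cross-checked.
#'
#' @param family result of [simulate_family()].
#' @param config the `sim_config`.
#' @return data frame: `gene_a`, `gene_b`, `true_class`, `divergence_time`,
#'   `same_chromosome`, `family_id`.
#' @export
family_truth <- function(family, config) {
  nodes <- family$nodes
  leaves <- nodes[nodes$event == "leaf", , drop = FALSE]
  n <- nrow(leaves)
  if (n < 2) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      true_class = character(0), divergence_time = numeric(0),
                      same_chromosome = logical(0), family_id = character(0)))
  }
  lineage <- function(id) {
    path <- id
    while (!is.na(nodes$parent[path[length(path)]])) {
      path <- c(path, nodes$parent[path[length(path)]])
    }
    path
  }
  paths <- lapply(leaves$id, lineage)
  fam_id <- sub("[AB][0-9]+$", "", leaves$gene_id[1])
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      common <- intersect(paths[[i]], paths[[j]])
      lca <- common[which.max(nodes$time[common])]
      ev <- nodes$event[lca]
      same_sp <- leaves$species[i] == leaves$species[j]
      if (ev == "speciation") {
        below <- function(p) {
          seg <- p[seq_len(which(p == lca) - 1L)]
          any(nodes$event[seg] == "duplication")
        }
        cls <- if (below(paths[[i]]) || below(paths[[j]])) "ortholog_1toMany" else "ortholog_1to1"
      } else if (same_sp) {
        cls <- if (nodes$time[lca] > config$t_speciation) "inparalog"
               else "within_species_outparalog"
      } else {
        cls <- "between_species_outparalog"
      }
      a <- leaves$gene_id[i]; b <- leaves$gene_id[j]
      if (a > b) { tmp <- a; a <- b; b <- tmp }
      out[[length(out) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, true_class = cls,
        divergence_time = 2 * (config$t_total - nodes$time[lca]),
        same_chromosome = if (same_sp) {
          leaves$chromosome[i] == leaves$chromosome[j]
        } else NA,
        family_id = fam_id, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# ---- trait evolution along a family tree ----

# walk the family tree applying a branch-transition function; the species
# context shift has a shared component (identical for every lineage entering
# a species) and an independent per-lineage component.
walk_family <- function(family, config, root_state, transition,
                        shared_pulse_A, shared_pulse_B, lineage_pulse) {
  nodes <- family$nodes
  children <- split(nodes$id, factor(nodes$parent, levels = nodes$id))
  states <- vector("list", nrow(nodes))
  leaf_states <- list()
  recurse <- function(id, state) {
    nd <- nodes[id, ]
    if (!is.na(nd$parent)) {
      dt <- nd$time - nodes$time[nd$parent]
      if (nodes$event[nd$parent] == "speciation") {
        pulse <- if (nd$species == "A") shared_pulse_A else shared_pulse_B
        state <- pulse(state)
        state <- lineage_pulse(state)
      }
      dt_eff <- dt * if (nd$relocated) config$chrom_multiplier else 1
      state <- transition(state, dt_eff)
    }
    states[[id]] <<- state
    if (nd$event == "leaf") {
      leaf_states[[nd$gene_id]] <<- state
    } else {
      for (k in children[[as.character(id)]]) recurse(k, state)
    }
  }
  recurse(nodes$id[is.na(nodes$parent)], root_state)
  leaf_states
}

# ---- sequences ----

sim_codon_data <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  sense <- codons[gc != "*"]
  aa_of <- gc
  codons_by_aa <- split(names(gc), gc)
  codons_by_aa[["*"]] <- NULL
  list(sense = sense, aa_of = aa_of, codons_by_aa = codons_by_aa)
}

#' Evolve codon sequences along a simulated family
#'
#' The root is a random stop-free coding sequence. Along each branch,
#' nonsynonymous events arrive as Poisson(`mu_nonsyn` x codons x t) --- each
#' replaces the amino acid of a random codon with a uniformly drawn
#' different amino acid (random codon choice) --- and synonymous events as
#' Poisson(`mu_syn` x codons x t), each replacing a random codon with a
#' synonymous alternative. Sequence evolution ignores the context shift and
#' the relocation multiplier, which act on function only. Per amino-acid
#' site, the probability that two sequences separated by time tau agree is
#' `1/20 + (19/20) exp(-(20/19) 2 mu_nonsyn tau/2)` in the Jukes-Cantor-like
#' closed form used by the calibration tests.
#'
#' @param family result of [simulate_family()].
#' @param config a `sim_config`.
#' @return list with `cds` and `protein` (named character vectors, one per
#'   leaf gene).
#' @export
evolve_sequences <- function(family, config) {
  cd <- sim_codon_data()
  nc <- config$n_codons
  root <- cd$sense[sample.int(length(cd$sense), nc, replace = TRUE)]
  transition <- function(state, dt) {
    n_non <- stats::rpois(1, config$mu_nonsyn * nc * dt)
    for (k in seq_len(n_non)) {
      i <- sample.int(nc, 1L)
      cur_aa <- cd$aa_of[state[i]]
      new_aa <- sample(setdiff(names(cd$codons_by_aa), cur_aa), 1L)
      opts <- cd$codons_by_aa[[new_aa]]
      state[i] <- opts[sample.int(length(opts), 1L)]
    }
    n_syn <- stats::rpois(1, config$mu_syn * nc * dt)
    for (k in seq_len(n_syn)) {
      i <- sample.int(nc, 1L)
      opts <- setdiff(cd$codons_by_aa[[cd$aa_of[state[i]]]], state[i])
      if (length(opts)) state[i] <- opts[sample.int(length(opts), 1L)]
    }
    state
  }
  identity_pulse <- function(state) state
  leaf <- walk_family(family, config, root, transition,
                      identity_pulse, identity_pulse, identity_pulse)
  cds <- vapply(leaf, paste, character(1), collapse = "")
  prot <- vapply(cds, function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }, character(1))
  names(prot) <- names(cds)
  list(cds = cds, protein = prot)
}

# ---- annotations ----

#' Evolve annotation term sets along a simulated family
#'
#' Each root gene starts with a random set of ontology leaf terms; along a
#' branch of length t, terms are lost as Poisson(`lambda_loss` t) and gained
#' (uniform draws from the ontology leaves) as Poisson(`lambda_gain` t).
#' Crossing the speciation boundary applies the context shift `delta`:
#' a fraction `delta_shared_frac` of it as an organism-wide gain/loss
#' pattern shared by all lineages of a species, the rest as independent
#' per-lineage gain/loss. Branches of a lineage descending from a relocated
#' duplicate evolve with their time multiplied by `chrom_multiplier` (the
#' relocated copy's functional context remains foreign to the ancestral
#' locus).
#'
#' @param family result of [simulate_family()].
#' @param ontology result of [generate_ontology()].
#' @param config a `sim_config`.
#' @param rate_scale multiplies gain/loss rates and the root set size
#'   (used to give the second namespace slower functional turnover).
#' @param n_root_terms size of the root gene's term set.
#' @return named list gene id -> character vector of (leaf-level) terms.
#' @export
evolve_annotations <- function(family, ontology, config, rate_scale = 1,
                               n_root_terms = config$n_root_terms_bp) {
  leaves_pool <- ontology$leaves
  lg <- config$lambda_gain * rate_scale
  ll <- config$lambda_loss * rate_scale
  root <- sample(leaves_pool, min(n_root_terms, length(leaves_pool)))
  lose <- function(state, k) {
    k <- min(k, length(state))
    if (k > 0) state <- state[-sample.int(length(state), k)]
    state
  }
  gain <- function(state, k) {
    if (k > 0) state <- unique(c(state, sample(leaves_pool, min(k, length(leaves_pool)))))
    state
  }
  transition <- function(state, dt) {
    gain(lose(state, stats::rpois(1, ll * dt)), stats::rpois(1, lg * dt))
  }
  make_shared_pulse <- function() {
    loss_pattern <- sample(leaves_pool,
                           min(stats::rpois(1, ll * config$delta * config$delta_shared_frac),
                               length(leaves_pool)))
    gain_pattern <- sample(leaves_pool,
                           min(stats::rpois(1, lg * config$delta * config$delta_shared_frac),
                               length(leaves_pool)))
    function(state) unique(c(setdiff(state, loss_pattern), gain_pattern))
  }
  pulse_A <- make_shared_pulse()
  pulse_B <- make_shared_pulse()
  d_ind <- config$delta * (1 - config$delta_shared_frac)
  lineage_pulse <- function(state) {
    gain(lose(state, stats::rpois(1, ll * d_ind)), stats::rpois(1, lg * d_ind))
  }
  walk_family(family, config, root, transition, pulse_A, pulse_B, lineage_pulse)
}

# ---- expression ----

#' Evolve cross-tissue expression profiles along a simulated family
#'
#' The family's ancestral per-tissue profile is standard normal; profiles
#' drift as Brownian motion with variance `sigma2_expr` per time unit, with
#' the same shared/per-lineage decomposition of the species context shift
#' as the annotations and the same relocation multiplier.
#'
#' @inheritParams evolve_annotations
#' @return named list gene id -> numeric vector of length `n_tissues`.
#' @export
evolve_expression_profiles <- function(family, config) {
  nt <- config$n_tissues
  root <- stats::rnorm(nt)
  transition <- function(state, dt) {
    state + stats::rnorm(nt, 0, sqrt(config$sigma2_expr * dt))
  }
  make_shared_pulse <- function() {
    shift <- stats::rnorm(nt, 0, sqrt(config$sigma2_expr * config$delta *
                                        config$delta_shared_frac))
    function(state) state + shift
  }
  pulse_A <- make_shared_pulse()
  pulse_B <- make_shared_pulse()
  v_ind <- config$sigma2_expr * config$delta * (1 - config$delta_shared_frac)
  lineage_pulse <- function(state) state + stats::rnorm(nt, 0, sqrt(v_ind))
  walk_family(family, config, root, transition, pulse_A, pulse_B, lineage_pulse)
}

# ---- full dataset ----

#' Generate a complete synthetic dataset
#'
#' Runs the whole generator under `config$seed`: two ontologies (one per
#' namespace), `n_families` gene families with sequences, annotations
#' (subsampled to the configured sparsity, with evidence codes and
#' publication ids), expression profiles with probes and transcripts, and a
#' ground-truth pair table.
#'
#' @param config a `sim_config`.
#' @return object of class `synthetic_dataset`; see [write_dataset()] for
#'   the file representation.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  ont_bp <- generate_ontology(config$n_terms_bp, "biological_process", "BP",
                              config$max_ontology_depth, config$p_extra_parent,
                              config$p_part_of)
  ont_mf <- generate_ontology(config$n_terms_mf, "molecular_function", "MF",
                              config$max_ontology_depth, config$p_extra_parent,
                              config$p_part_of)
  genes <- list(); newicks <- character(config$n_families)
  cds <- prot <- character(0)
  ann_states <- list(BP = list(), MF = list())
  expr_profiles <- list()
  truth <- list()
  for (f in seq_len(config$n_families)) {
    fid <- sprintf("F%04d", f)
    fam <- simulate_family(config, fid)
    genes[[f]] <- fam$genes
    newicks[f] <- fam$newick
    seqs <- evolve_sequences(fam, config)
    cds <- c(cds, seqs$cds); prot <- c(prot, seqs$protein)
    ann_states$BP <- c(ann_states$BP,
                       evolve_annotations(fam, ont_bp, config, 1,
                                          config$n_root_terms_bp))
    ann_states$MF <- c(ann_states$MF,
                       evolve_annotations(fam, ont_mf, config,
                                          config$mf_rate_scale,
                                          config$n_root_terms_mf))
    expr_profiles <- c(expr_profiles, evolve_expression_profiles(fam, config))
    truth[[f]] <- family_truth(fam, config)
  }
  genes <- do.call(rbind, genes)
  genes$species <- ifelse(genes$species == "A", "speciesA", "speciesB")
  truth <- do.call(rbind, truth)
  annotations <- build_annotation_records(ann_states, genes, config)
  expr <- build_expression_data(expr_profiles, cds, config)
  structure(list(config = config,
                 ontologies = list(BP = ont_bp, MF = ont_mf),
                 genes = genes, newicks = newicks,
                 cds = cds, protein = prot,
                 annotations = annotations,
                 expression = expr, truth = truth),
            class = "synthetic_dataset")
}

build_annotation_records <- function(ann_states, genes, config) {
  sp <- stats::setNames(genes$species, genes$gene_id)
  rows <- list()
  for (ns in c("BP", "MF")) {
    states <- ann_states[[ns]]
    for (g in genes$gene_id) {
      terms <- states[[g]]
      if (is.null(terms) || length(terms) == 0L) next
      if (stats::runif(1) >= config$annotation_sparsity) next
      fam_pub <- paste0("PM", sub("([AB])[0-9]+$", "", g), ns)
      ev <- sample(names(config$evidence_probs), length(terms), replace = TRUE,
                   prob = config$evidence_probs)
      pubs <- vapply(seq_along(terms), function(i) {
        main <- if (stats::runif(1) < config$p_same_publication) {
          fam_pub
        } else {
          paste0("PM", g, "x", i)
        }
        if (stats::runif(1) < config$p_second_publication) {
          paste(main, paste0("PM", g, "y", i), sep = ";")
        } else main
      }, character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = g, species = unname(sp[g]), term_id = terms,
        evidence_code = ev, pubmed_ids = pubs, namespace = ns,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

build_expression_data <- function(profiles, cds, config) {
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  gene_ids <- names(profiles)
  # transcripts: one per gene, the coding sequence
  transcripts <- stats::setNames(cds[gene_ids],
                                 paste0(gene_ids, "|", gene_ids, ".t1"))
  # probes: probes_per_set exact substrings of the gene's transcript
  probes <- character(0)
  probeset_gene <- character(0)
  for (g in gene_ids) {
    L <- nchar(cds[[g]])
    starts <- sample.int(L - config$probe_length + 1L, config$probes_per_set,
                         replace = FALSE)
    pr <- substring(cds[[g]], starts, starts + config$probe_length - 1L)
    names(pr) <- paste0("PS", g, ":", seq_along(pr))
    probes <- c(probes, pr)
    probeset_gene <- c(probeset_gene, g)
  }
  # plant ambiguous probesets: first probe copied from another gene
  n_amb <- round(config$p_ambiguous_probeset * length(gene_ids))
  ambiguous <- character(0)
  if (n_amb > 0 && length(gene_ids) > 1) {
    amb_idx <- sample.int(length(gene_ids), n_amb)
    for (i in amb_idx) {
      g <- gene_ids[i]
      other <- sample(gene_ids[-i], 1L)
      probes[paste0("PS", g, ":1")] <- unname(probes[paste0("PS", other, ":2")])
      ambiguous <- c(ambiguous, paste0("PS", g))
    }
  }
  # raw intensities: exponentiated profiles plus measurement noise;
  # a few tissues are measured twice (duplicate columns)
  col_tissue <- c(tissues, tissues[seq_len(config$n_duplicate_tissues)])
  mat <- matrix(NA_real_, length(gene_ids), length(col_tissue),
                dimnames = list(paste0("PS", gene_ids), col_tissue))
  for (i in seq_along(gene_ids)) {
    z <- profiles[[gene_ids[i]]]
    for (j in seq_along(col_tissue)) {
      t_idx <- match(col_tissue[j], tissues)
      mat[i, j] <- exp(config$expr_base + config$expr_scale * z[t_idx] +
                         stats::rnorm(1, 0, config$measurement_sd))
    }
  }
  list(matrix = mat, probes = probes, transcripts = transcripts,
       tissues = tissues, ambiguous_probesets = ambiguous)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `ontology.obo`, `genes.tsv`, `trees.nwk` (one NHX-tagged Newick
#' per line, families in order), `proteins.fa`, `cds.fa`,
#' `annotations.tsv`, `expression.tsv` (probeset x tissue, duplicate tissue
#' columns allowed), `probes.fa`, `transcripts.fa`, `tissues.txt` and
#' `truth.tsv`. Output is byte-identical for equal configurations.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_obo(ds$ontologies, fp("ontology.obo"))
  utils::write.table(ds$genes, fp("genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(ds$newicks, fp("trees.nwk"))
  writeLines(paste0(">", names(ds$protein), "\n", ds$protein), fp("proteins.fa"))
  writeLines(paste0(">", names(ds$cds), "\n", ds$cds), fp("cds.fa"))
  utils::write.table(ds$annotations, fp("annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  em <- data.frame(probeset_id = rownames(ds$expression$matrix),
                   ds$expression$matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(em, fp("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(paste0(">", names(ds$expression$probes), "\n", ds$expression$probes),
             fp("probes.fa"))
  writeLines(paste0(">", names(ds$expression$transcripts), "\n",
                    ds$expression$transcripts), fp("transcripts.fa"))
  writeLines(ds$expression$tissues, fp("tissues.txt"))
  utils::write.table(ds$truth, fp("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d families, %d genes, %d annotation records, seed %s\n",
              x$config$n_families, nrow(x$genes), nrow(x$annotations),
              x$config$seed))
  invisible(x)
}
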