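# Synthetic corpus generator.
#
# Families of TFs evolve along a star tree from a family ancestor. Each
# member carries two latent divergence factors: one for the DNA-binding
# domain and one for the flanking regions (the rest of the protein), each
# drawn either from a short "ortholog" regime or an ordinary regime. Point
# substitutions are applied to the two regions at rate mu_s scaled by the
# respective factor; the ancestor PFM's columns are mixed with fresh
# Dirichlet draws at weight mu_p times the motif branch length. With
# probability `coupling`, the motif branch is the mean of the two sequence
# factors — so domain divergence and flank divergence each carry part of
# the signal and no single region predicts motif divergence alone, the
# structure under which combining many pairwise features pays off. Species
# come from a three-level toy taxonomy; each family's members are split
# 2:1 into references and queries. Everything is deterministic given the
# seed.

#' Parameters of the synthetic corpus
#'
#' @param n_families number of TF families.
#' @param members_per_family members per family (star tree leaves).
#' @param dbd_length DNA-binding-domain length (amino acids).
#' @param motif_length_range inclusive range of motif lengths.
#' @param flank_length length of the N- and C-terminal flanks embedding the
#'   DBD in the full protein.
#' @param mu_s per-site substitution probability per unit branch length.
#' @param mu_p per-column motif perturbation weight per unit branch length.
#' @param coupling probability that a member's motif branch length equals
#'   its sequence branch length (joint mutation).
#' @param ortholog_rate fraction of members on very short branches,
#'   emulating the close orthologs/isoforms that dominate real motif
#'   corpora; the rest sit on ordinary branches.
#' @param superclasses superclass labels recycled over families.
#' @param seed mandatory integer seed.
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(n_families = 24L, members_per_family = 6L,
                              dbd_length = 24L, motif_length_range = c(6L, 8L),
                              flank_length = 60L, mu_s = 0.2, mu_p = 0.1,
                              coupling = 0.9, ortholog_rate = 0.4,
                              superclasses = 1:5, seed) {
  if (missing(seed)) stopf("simulation seed is mandatory")
  for (r in c(mu_s, mu_p, coupling, ortholog_rate))
    if (r < 0 || r > 1) stopf("rates and coupling must lie in [0, 1]")
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 dbd_length = as.integer(dbd_length),
                 motif_length_range = as.integer(motif_length_range),
                 flank_length = as.integer(flank_length),
                 mu_s = mu_s, mu_p = mu_p, coupling = coupling,
                 ortholog_rate = ortholog_rate,
                 superclasses = as.integer(superclasses),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

random_aa <- function(n) paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")

mutate_aa <- function(seq, p_sub) {
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < p_sub
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(a)
      sample(setdiff(AA_ALPHABET20, a), 1L), character(1))
  paste(ch, collapse = "")
}

# region-wise mutation: DBD interval at rate p_dbd, the rest at p_flank
mutate_regions <- function(seq, dbd_from, dbd_to, p_dbd, p_flank) {
  n <- nchar(seq)
  paste0(mutate_aa(substr(seq, 1L, dbd_from - 1L), p_flank),
         mutate_aa(substr(seq, dbd_from, dbd_to), p_dbd),
         mutate_aa(substr(seq, dbd_to + 1L, n), p_flank))
}

rdirichlet1 <- function() {
  g <- rgamma(4L, 1)
  g / sum(g)
}

perturb_pfm <- function(m, w) {
  for (j in seq_len(ncol(m))) m[, j] <- (1 - w) * m[, j] + w * rdirichlet1()
  m
}

toy_taxonomy <- function() {
  kingdoms <- c("K1", "K2")
  genera <- c("G1", "G2", "G3", "G4")
  species <- sprintf("S%d", 1:8)
  taxonomy_from_edges(
    children = c(kingdoms, genera, species),
    parents = c(rep("root", 2), rep(kingdoms, each = 2), rep(genera, each = 2)))
}

#' Simulate a reference/query TF corpus
#'
#' @param params a [simulation_params()].
#' @return list with `refs` and `queries` (lists of `tf_record`, every
#'   record carrying a `pfm_id`), `pfms` (named list incl. the queries'
#'   held-out truths), `taxonomy`, and `params`.
#' @export
simulate_corpus <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  m <- params$members_per_family
  n_ref <- ceiling(2 / 3 * m)
  if (n_ref < 1L || n_ref >= m)
    stopf("members_per_family = %d does not admit a 2:1 reference/query split", m)
  set.seed(derive_seed(params$seed, "corpus"))
  taxonomy <- toy_taxonomy()
  species <- sprintf("S%d", 1:8)
  refs <- list()
  queries <- list()
  pfms <- list()
  sp_i <- 0L
  for (f in seq_len(params$n_families)) {
    superclass <- params$superclasses[(f - 1L) %% length(params$superclasses) + 1L]
    L <- sample(params$motif_length_range[1]:params$motif_length_range[2], 1L)
    anc_protein <- random_aa(params$flank_length * 2L + params$dbd_length)
    anc_pfm <- vapply(seq_len(L), function(j) rdirichlet1(), numeric(4))
    rbranch <- function() {
      if (runif(1) < params$ortholog_rate) runif(1, 0.02, 0.25)
      else runif(1, 0.2, 1.8)
    }
    dbd_from <- params$flank_length + 1L
    dbd_to <- params$flank_length + params$dbd_length
    for (k in seq_len(m)) {
      b_dbd <- rbranch()
      b_flank <- rbranch()
      b_mot <- if (runif(1) < params$coupling) (b_dbd + b_flank) / 2 else rbranch()
      protein <- mutate_regions(anc_protein, dbd_from, dbd_to,
                                min(1, params$mu_s * b_dbd),
                                min(1, params$mu_s * b_flank))
      motif <- perturb_pfm(anc_pfm, min(1, params$mu_p * b_mot))
      acc <- sprintf("TF_%03d_%02d", f, k)
      pid <- sprintf("PFM_%03d_%02d", f, k)
      sp_i <- sp_i + 1L
      tf <- tf_record(accession = acc,
                      taxon = species[(sp_i - 1L) %% length(species) + 1L],
                      superclass = superclass, sequence = protein,
                      dbd_intervals = c(params$flank_length + 1L,
                                        params$flank_length + params$dbd_length),
                      pfm_id = pid)
      pfms[[pid]] <- pfm(motif, id = pid)
      if (k <= n_ref) refs[[length(refs) + 1L]] <- tf
      else queries[[length(queries) + 1L]] <- tf
    }
  }
  list(refs = refs, queries = queries, pfms = pfms,
       taxonomy = taxonomy, params = params)
}

#' Simulate background DNA sequence
#'
#' @param bg a `background_model` (or length-4 probabilities).
#' @param length number of bases.
#' @param seed integer seed.
#' @return a DNA string (empty for `length = 0`).
#' @export
simulate_background_sequence <- function(bg, length, seed = 1L) {
  if (!inherits(bg, "background_model")) bg <- background_model(bg)
  length <- as.integer(length)
  if (length == 0L) return("")
  set.seed(derive_seed(seed, "bgseq"))
  v <- integer(length)
  v[1L] <- sample.int(4L, 1L, prob = bg$probs)
  if (length > 1L) {
    if (bg$order == 0L) {
      v[2:length] <- sample.int(4L, length - 1L, replace = TRUE, prob = bg$probs)
    } else {
      for (i in 2:length) {
        if (i <= bg$order) {
          v[i] <- sample.int(4L, 1L, prob = bg$probs)
        } else {
          ctx <- context_index(v[(i - bg$order):i], bg$order)
          v[i] <- sample.int(4L, 1L, prob = bg$trans[ctx, ])
        }
      }
    }
  }
  paste(DNA_BASES[v], collapse = "")
}
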