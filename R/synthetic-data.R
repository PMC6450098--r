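AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
TAX_CLASSES <- c("viral", "eukaryotic", "prokaryotic", "unclassified")

# Run code under a temporary RNG state so generators are pure functions
# of (config, seed) and do not disturb the caller's stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic universe generator
#'
#' Bundles and validates every knob of the synthetic-data module. The
#' defaults emulate the study design: a giant-virus proteome of a few
#' hundred ORFs against its amoeba host, a labelled background database
#' standing in for the reference protein universe, planted lateral gene
#' transfer (LGT) events of each direction class, negative-binomial
#' expression counts over 14 RNA-seq runs with a silencing effect on
#' virus-derived host genes, and a genome drawn at the observed G+C of
#' 61.7%.
#'
#' @param seed Integer RNG seed.
#' @param n_host_genes,n_virus_genes,n_background Set sizes.
#' @param n_planted_vtoa,n_planted_atov,n_planted_undetermined Numbers
#'   of planted LGT pairs per direction class.
#' @param mutation_rate Per-residue substitution probability in `[0, 1)`
#'   separating the two copies of a planted pair from their ancestor.
#' @param background_mix Named fractions over
#'   viral/eukaryotic/prokaryotic/unclassified, summing to 1.
#' @param mean_count,dispersion Negative-binomial mean and dispersion of
#'   per-run expression counts (`var = mu + dispersion * mu^2`).
#' @param silencing_multiplier Multiplier in `(0, 1]` applied to the
#'   expected count of silenced (virus-derived) host genes.
#' @param n_runs Number of expression runs (the study used 14 SRA runs).
#' @param genome_length,gc_target Synthetic genome length (bp) and
#'   target G+C fraction.
#' @param protein_length Length range (residues) for random proteins.
#' @param kmer_size Word size of the k-mer scoring used by
#'   [emit_homology_tables()].
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_host_genes = 80L,
                         n_virus_genes = 60L,
                         n_background = 200L,
                         n_planted_vtoa = 5L,
                         n_planted_atov = 3L,
                         n_planted_undetermined = 2L,
                         mutation_rate = 0.02,
                         background_mix = c(viral = 0.3, eukaryotic = 0.4,
                                            prokaryotic = 0.2,
                                            unclassified = 0.1),
                         mean_count = 200,
                         dispersion = 0.3,
                         silencing_multiplier = 0.1,
                         n_runs = 14L,
                         genome_length = 381277L,
                         gc_target = 0.617,
                         protein_length = c(150L, 400L),
                         kmer_size = 4L) {
  counts <- c(n_host_genes, n_virus_genes, n_background, n_planted_vtoa,
              n_planted_atov, n_planted_undetermined, n_runs)
  if (any(counts < 0)) rlang::abort("counts must be >= 0.")
  if (mutation_rate < 0 || mutation_rate >= 1) {
    rlang::abort("mutation_rate must be in [0, 1).")
  }
  if (!setequal(names(background_mix), TAX_CLASSES) ||
      abs(sum(background_mix) - 1) > 1e-9) {
    rlang::abort("background_mix must cover the four taxonomy classes and sum to 1.")
  }
  if (dispersion <= 0) rlang::abort("dispersion must be > 0.")
  if (silencing_multiplier <= 0 || silencing_multiplier > 1) {
    rlang::abort("silencing_multiplier must be in (0, 1].")
  }
  if (gc_target < 0 || gc_target > 1) rlang::abort("gc_target must be in [0, 1].")
  if (genome_length < 1) rlang::abort("genome_length must be positive.")
  n_planted <- n_planted_vtoa + n_planted_atov + n_planted_undetermined
  if (n_planted > min(n_host_genes, n_virus_genes)) {
    rlang::abort("planted pairs exceed the host or virus gene namespace.")
  }
  if (n_planted > n_background) {
    rlang::abort("planted pairs exceed the background namespace (one relative each).")
  }
  structure(list(
    seed = as.integer(seed),
    n_host_genes = as.integer(n_host_genes),
    n_virus_genes = as.integer(n_virus_genes),
    n_background = as.integer(n_background),
    n_planted_vtoa = as.integer(n_planted_vtoa),
    n_planted_atov = as.integer(n_planted_atov),
    n_planted_undetermined = as.integer(n_planted_undetermined),
    mutation_rate = mutation_rate,
    background_mix = background_mix[TAX_CLASSES],
    mean_count = mean_count,
    dispersion = dispersion,
    silencing_multiplier = silencing_multiplier,
    n_runs = as.integer(n_runs),
    genome_length = as.integer(genome_length),
    gc_target = gc_target,
    protein_length = as.integer(protein_length),
    kmer_size = as.integer(kmer_size)
  ), class = "synth_config")
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# Substitute each residue with probability `rate` by a different residue.
mutate_protein <- function(seq, rate) {
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic virus/host/background protein universe
#'
#' Builds the three protein sets the LGT pipeline consumes, with planted
#' reciprocal homolog pairs of known transfer direction. Each planted
#' pair descends from a random ancestor: the virus and host copies are
#' lightly mutated siblings, and a more heavily mutated third copy is
#' placed in the background database with the taxonomy that encodes the
#' direction (viral for virus-to-amoeba, eukaryotic for amoeba-to-virus,
#' prokaryotic/unclassified — or no relative at all — for undetermined
#' pairs; undetermined plantings alternate between the two variants).
#' All other proteins are independent random sequences, so planted
#' partners strictly outscore everything else at low mutation rates.
#'
#' @param config A [synth_config()].
#' @return A `synthetic_universe` list: `proteins` (tibble with `id`,
#'   `sequence`, `source`, `taxonomy`), `truth` (tibble with
#'   `virus_gene_id`, `host_gene_id`, `planted_direction`,
#'   `relative_id`, `relative_taxonomy`), and the `config`.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    lens <- function(n) sample(config$protein_length[1]:config$protein_length[2],
                               n, replace = TRUE)
    host_ids <- sprintf("hg%04d", seq_len(config$n_host_genes))
    virus_ids <- sprintf("vg%04d", seq_len(config$n_virus_genes))
    bg_ids <- sprintf("bg%05d", seq_len(config$n_background))
    host_seq <- vapply(lens(config$n_host_genes), random_protein, character(1))
    virus_seq <- vapply(lens(config$n_virus_genes), random_protein, character(1))
    bg_seq <- vapply(lens(config$n_background), random_protein, character(1))
    bg_tax <- if (config$n_background > 0) {
      sample(TAX_CLASSES, config$n_background, replace = TRUE,
             prob = config$background_mix)
    } else character(0)

    directions <- rep(c("VtoA", "AtoV", "undetermined"),
                      times = c(config$n_planted_vtoa, config$n_planted_atov,
                                config$n_planted_undetermined))
    # divergence of the background relative: strictly larger than the
    # copy-to-copy divergence so planted partners always win
    rel_rate <- min(0.45, 4 * config$mutation_rate + 0.08)
    truth <- tibble::tibble(
      virus_gene_id = character(0), host_gene_id = character(0),
      planted_direction = character(0), relative_id = character(0),
      relative_taxonomy = character(0)
    )
    n_und_seen <- 0L
    for (i in seq_along(directions)) {
      dir <- directions[i]
      anc <- random_protein(sample(config$protein_length[1]:config$protein_length[2], 1))
      vs <- mutate_protein(anc, config$mutation_rate)
      hs <- mutate_protein(anc, config$mutation_rate)
      virus_seq[i] <- vs
      host_seq[i] <- hs
      rel_tax <- switch(dir,
        VtoA = "viral",
        AtoV = "eukaryotic",
        undetermined = {
          n_und_seen <- n_und_seen + 1L
          if (n_und_seen %% 2L == 1L) "prokaryotic" else NA_character_
        }
      )
      rel_id <- NA_character_
      if (!is.na(rel_tax)) {
        bg_seq[i] <- mutate_protein(anc, rel_rate)
        bg_tax[i] <- rel_tax
        rel_id <- bg_ids[i]
      }
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        virus_gene_id = virus_ids[i], host_gene_id = host_ids[i],
        planted_direction = dir, relative_id = rel_id,
        relative_taxonomy = rel_tax
      ))
    }

    proteins <- dplyr::bind_rows(
      tibble::tibble(id = virus_ids, sequence = virus_seq, source = "virus",
                     taxonomy = "viral"),
      tibble::tibble(id = host_ids, sequence = host_seq, source = "host",
                     taxonomy = "eukaryotic"),
      tibble::tibble(id = bg_ids, sequence = bg_seq, source = "db",
                     taxonomy = bg_tax)
    )
    structure(list(proteins = proteins, truth = truth, config = config),
              class = "synthetic_universe")
  })
}

distinct_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

score_pairs <- function(queries, subjects, k, min_score) {
  q_kmers <- lapply(queries$sequence, distinct_kmers, k = k)
  s_kmers <- lapply(subjects$sequence, distinct_kmers, k = k)
  rows <- list()
  for (i in seq_len(nrow(queries))) {
    qk <- q_kmers[[i]]
    for (j in seq_len(nrow(subjects))) {
      score <- sum(s_kmers[[j]] %in% qk)
      if (score >= min_score) {
        qlen <- nchar(queries$sequence[i])
        slen <- nchar(subjects$sequence[j])
        alen <- min(qlen, slen)
        pid <- round(100 * score / max(1, alen - k + 1), 2)
        rows[[length(rows) + 1]] <- tibble::tibble(
          query_id = queries$id[i], subject_id = subjects$id[j],
          percent_identity = pid, alignment_length = alen,
          mismatches = as.integer(round(alen * (1 - pid / 100))),
          gap_openings = 0L, q_start = 1L, q_end = qlen,
          s_start = 1L, s_end = slen,
          evalue = 10^(-score), bitscore = as.numeric(score)
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(query_id = character(0), subject_id = character(0),
                          percent_identity = numeric(0),
                          alignment_length = integer(0),
                          mismatches = integer(0), gap_openings = integer(0),
                          q_start = integer(0), q_end = integer(0),
                          s_start = integer(0), s_end = integer(0),
                          evalue = numeric(0), bitscore = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Emit synthetic homology hit tables
#'
#' Deterministic stand-in for a bidirectional protein similarity search:
#' the score between two proteins is their number of shared distinct
#' k-mers (default k = 4), so identical sequences attain the maximal
#' score for a query and divergence decreases scores monotonically in
#' expectation. Two tables are produced, mirroring the study's search
#' design: virus queries against host + background, and host queries
#' against virus + background — each query's own genome is excluded.
#' Pairs sharing fewer than `min_score` k-mers (chance-level matches
#' between unrelated random proteins) are not reported; emitted rows
#' carry `evalue = 10^-score`, comfortably below the usual `1e-5`
#' retention threshold.
#'
#' @param universe A [generate_universe()] result.
#' @param min_score Minimum shared-k-mer count to report (default 10).
#' @return List with `virus_hits` and `host_hits`, each an annotated
#'   hit tibble (subject source/taxonomy attached).
#' @export
emit_homology_tables <- function(universe, min_score = 10) {
  stopifnot(inherits(universe, "synthetic_universe"))
  k <- universe$config$kmer_size
  p <- universe$proteins
  virus <- dplyr::filter(p, .data$source == "virus")
  host <- dplyr::filter(p, .data$source == "host")
  db <- dplyr::filter(p, .data$source == "db")
  virus_hits <- score_pairs(virus, dplyr::bind_rows(host, db), k, min_score)
  host_hits <- score_pairs(host, dplyr::bind_rows(virus, db), k, min_score)
  list(
    virus_hits = annotate_hits(virus_hits, p),
    host_hits = annotate_hits(host_hits, p)
  )
}

#' Simulate a negative-binomial count matrix by gene group
#'
#' Low-level count generator: every gene gets independent
#' negative-binomial counts per run (`var = mu + dispersion * mu^2`);
#' genes whose group is in `silenced_groups` have their expected mean
#' scaled by `silencing_multiplier`.
#'
#' @param groups Data frame with `gene_id`, `group` and optionally
#'   `length` (bp; default 1000).
#' @param mean_count,dispersion,silencing_multiplier,n_runs See
#'   [synth_config()].
#' @param silenced_groups Group labels subject to silencing. The default
#'   mirrors the study observation that virus-derived and
#'   undetermined-direction transferred genes are the low-activity
#'   classes.
#' @param seed RNG seed.
#' @return List: `counts` (tibble `gene_id`, `length`, one column per
#'   run) and `groups` (echo of the assignment).
#' @export
simulate_count_matrix <- function(groups, mean_count = 200, dispersion = 0.3,
                                  silencing_multiplier = 0.1, n_runs = 14,
                                  silenced_groups = c("VtoA", "undetermined"),
                                  seed = 1) {
  stopifnot(n_runs >= 1, all(c("gene_id", "group") %in% names(groups)))
  if (dispersion <= 0) rlang::abort("dispersion must be > 0.")
  with_seed(seed, {
    n_genes <- nrow(groups)
    len <- if ("length" %in% names(groups)) groups$length else rep(1000L, n_genes)
    mu <- ifelse(groups$group %in% silenced_groups,
                 mean_count * silencing_multiplier, mean_count)
    mat <- matrix(stats::rnbinom(n_genes * n_runs, mu = rep(mu, n_runs),
                                 size = 1 / dispersion),
                  nrow = n_genes, ncol = n_runs)
    colnames(mat) <- sprintf("run_%02d", seq_len(n_runs))
    counts <- dplyr::bind_cols(
      tibble::tibble(gene_id = groups$gene_id, length = as.integer(len)),
      tibble::as_tibble(mat)
    )
    list(counts = counts, groups = tibble::as_tibble(groups)[, c("gene_id", "group")])
  })
}

#' Simulate expression counts for a synthetic universe
#'
#' Assigns host genes to activity groups — planted LGT genes take their
#' planted direction as group label, all remaining host genes stand in
#' for the vertically inherited genes conserved among Amoebozoa
#' (`AC_conserved`) — and draws negative-binomial counts via
#' [simulate_count_matrix()]. Gene lengths are the coding lengths of the
#' host proteins (3 bp per residue plus stop).
#'
#' @param universe A [generate_universe()] result.
#' @param config Optional [synth_config()]; defaults to the universe's.
#' @return List with `counts` and `groups` tibbles.
#' @export
simulate_expression <- function(universe, config = universe$config) {
  stopifnot(inherits(universe, "synthetic_universe"))
  host <- dplyr::filter(universe$proteins, .data$source == "host")
  groups <- host |>
    dplyr::transmute(
      gene_id = .data$id,
      length = 3L * nchar(.data$sequence) + 3L
    ) |>
    dplyr::left_join(
      dplyr::select(universe$truth, gene_id = "host_gene_id",
                    group = "planted_direction"),
      by = "gene_id"
    ) |>
    dplyr::mutate(group = dplyr::coalesce(.data$group, "AC_conserved"))
  simulate_count_matrix(
    groups,
    mean_count = config$mean_count, dispersion = config$dispersion,
    silencing_multiplier = config$silencing_multiplier,
    n_runs = config$n_runs, seed = config$seed + 1L
  )
}

#' Generate a random genome at a target G+C
#'
#' I.i.d. residues with `P(G) = P(C) = gc_target / 2`.
#'
#' @param length Genome length in bp (> 0).
#' @param gc_target Target G+C fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return A single nucleotide string of the requested length.
#' @export
generate_genome <- function(length, gc_target, seed = 1) {
  stopifnot(length > 0)
  if (gc_target < 0 || gc_target > 1) rlang::abort("gc_target must be in [0, 1].")
  with_seed(seed, {
    p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
           G = gc_target / 2, T = (1 - gc_target) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Simulate peptide detection evidence
#'
#' For each protein, counts the in-silico observable tryptic peptides
#' and draws the number observed as
#' `Binomial(n_observable, detection_prob)`.
#'
#' @param proteome Tibble with `id` and `sequence`.
#' @param detection_prob Per-peptide detection probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param mass_range Observable mass window, see [observable_count()].
#' @return Tibble with `id`, `n_observable`, `n_observed`.
#' @export
simulate_peptides <- function(proteome, detection_prob, seed = 1,
                              mass_range = c(500, 5000)) {
  stopifnot(detection_prob >= 0, detection_prob <= 1)
  n_obs <- vapply(proteome$sequence, function(s) {
    observable_count(tryptic_peptides(s), mass_range)
  }, integer(1), USE.NAMES = FALSE)
  with_seed(seed, {
    tibble::tibble(
      id = proteome$id,
      n_observable = n_obs,
      n_observed = stats::rbinom(length(n_obs), n_obs, detection_prob)
    )
  })
}

#' Generate a synthetic gene-content membership matrix
#'
#' Emits a binary taxa-by-cluster presence/absence matrix with two
#' planted clades: a block of clusters shared within each clade, a block
#' shared by everyone, and per-taxon private clusters, plus optional
#' random noise. Used to exercise the gene-content cladistics stage
#' without running any orthology clustering.
#'
#' @param taxa_a,taxa_b Character vectors of taxon names per clade.
#' @param n_shared Clusters present in all taxa.
#' @param n_clade Clusters private to each clade (all members).
#' @param n_private Clusters private to each taxon.
#' @param noise_flip Probability of flipping a cell (default 0).
#' @param seed RNG seed.
#' @return Binary matrix, taxa as rownames, clusters as colnames.
#' @export
generate_membership <- function(taxa_a, taxa_b, n_shared = 10, n_clade = 10,
                                n_private = 3, noise_flip = 0, seed = 1) {
  taxa <- c(taxa_a, taxa_b)
  stopifnot(length(taxa) >= 3, !anyDuplicated(taxa))
  with_seed(seed, {
    n_taxa <- length(taxa)
    blocks <- list(
      shared = matrix(1, n_taxa, n_shared),
      clade_a = rbind(matrix(1, length(taxa_a), n_clade),
                      matrix(0, length(taxa_b), n_clade)),
      clade_b = rbind(matrix(0, length(taxa_a), n_clade),
                      matrix(1, length(taxa_b), n_clade)),
      private = diag(1, n_taxa) %x% matrix(1, 1, n_private)
    )
    m <- do.call(cbind, blocks)
    if (noise_flip > 0) {
      flip <- matrix(stats::runif(length(m)) < noise_flip, nrow = nrow(m))
      m[flip] <- 1 - m[flip]
      # membership invariant: no empty taxon
      empty <- rowSums(m) == 0
      m[empty, 1] <- 1
    }
    rownames(m) <- taxa
    colnames(m) <- sprintf("OG%04d", seq_len(ncol(m)))
    storage.mode(m) <- "integer"
    m
  })
}
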