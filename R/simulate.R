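# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth: one underlying community
# observed by four methods, two genome collections with their
# characteristic sampling biases, gene catalogs with core/flexible
# structure, KO annotations with planted module effects, contamination
# reports with planted chimeras, 16S assignments with planted conflicts,
# and read-recruitment summaries. Each generator is a pure function of
# (spec, seed): identical seeds give byte-identical outputs.

.lineage_labels <- function(n, rank = "order") {
  sprintf("%s%s%02d", RANK_PREFIX[[normalize_rank(rank)]], "Lineage", 1:n)
}

#' Specification of a synthetic community experiment
#'
#' Describes one underlying community observed by the four methods. The
#' default base concentration follows a power-law-ranked profile (a few
#' dominant lineages, a long rare tail), the shape typical of marine
#' prokaryoplankton surveys. Per-method multiplicative biases default to
#' 1 (no bias): the community seen by each method is
#' `renormalize(truth * bias)`.
#'
#' @param n_lineages number of lineages (default 40).
#' @param concentration base Dirichlet concentration vector (default
#'   `20 / rank^0.7`).
#' @param method_bias named list of per-method multiplicative bias
#'   vectors (strictly positive; defaults to all 1).
#' @param n_samples samples per method (default 20; recycled over
#'   methods if scalar).
#' @param mean_depth mean sequencing depth (counts per sample; default
#'   5e4). Depths are drawn log-normally with sdlog `depth_sdlog`.
#' @param depth_sdlog log-sd of the per-sample depth (default 0.2).
#' @param rank taxonomic rank of the lineage labels (default "order").
#' @return a list of class `"community_spec"`.
#' @export
community_spec <- function(n_lineages = 40, concentration = NULL,
                           method_bias = NULL, n_samples = 20,
                           mean_depth = 5e4, depth_sdlog = 0.2,
                           rank = "order") {
  if (is.null(concentration))
    concentration <- 20 / seq_len(n_lineages)^0.7
  stopifnot(length(concentration) == n_lineages, all(concentration > 0))
  bias <- setNames(rep(list(rep(1, n_lineages)), length(METHODS)), METHODS)
  if (!is.null(method_bias)) {
    stopifnot(all(names(method_bias) %in% METHODS))
    for (m in names(method_bias)) {
      stopifnot(length(method_bias[[m]]) == n_lineages,
                all(method_bias[[m]] > 0))
      bias[[m]] <- method_bias[[m]]
    }
  }
  n_samples <- setNames(rep_len(n_samples, length(METHODS)), METHODS)
  structure(list(n_lineages = n_lineages, concentration = concentration,
                 method_bias = bias, n_samples = n_samples,
                 mean_depth = mean_depth, depth_sdlog = depth_sdlog,
                 rank = normalize_rank(rank),
                 lineages = .lineage_labels(n_lineages, rank)),
            class = "community_spec")
}

#' Simulate per-sample lineage counts for four observation methods
#'
#' The true composition is drawn once from the base Dirichlet; each
#' method observes `renormalize(truth * bias)`; each sample's counts are
#' multinomial at a log-normally drawn depth.
#'
#' @param spec a [community_spec()].
#' @param seed integer seed.
#' @return list with `counts` (a `counts` table) and `truth` (a list
#'   with `true_proportions`, `method_proportions`, and `planted`: the
#'   lineages whose bias differs from 1, with their method and fold
#'   change).
#' @export
simulate_community_counts <- function(spec, seed) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(seed, {
    g <- rgamma(spec$n_lineages, shape = spec$concentration)
    truth <- g / sum(g)
    method_props <- lapply(spec$method_bias, function(b) {
      p <- truth * b; p / sum(p)
    })
    rows <- list()
    for (m in METHODS) {
      depths <- pmax(1, round(exp(rnorm(spec$n_samples[[m]],
                                        log(spec$mean_depth),
                                        spec$depth_sdlog))))
      cnt <- sapply(depths, function(d)
        rmultinom(1L, size = d, prob = method_props[[m]]))
      for (s in seq_len(spec$n_samples[[m]]))
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, sample_id = sprintf("%s_s%02d", m, s),
          lineage = spec$lineages, rank = spec$rank,
          count = as.integer(cnt[, s]), stringsAsFactors = FALSE)
    }
    counts <- validate_table(do.call(rbind, rows), "counts")
    planted <- do.call(rbind, lapply(METHODS, function(m) {
      b <- spec$method_bias[[m]]
      ix <- which(b != 1)
      if (!length(ix)) return(NULL)
      data.frame(method = m, lineage = spec$lineages[ix], fold = b[ix],
                 stringsAsFactors = FALSE)
    }))
    list(counts = counts,
         truth = list(true_proportions = setNames(truth, spec$lineages),
                      method_proportions = method_props,
                      planted = planted))
  })
}

.synthetic_taxonomy <- function(lineage_index, rank = "order",
                                per_group = 4L) {
  # nested synthetic labels: lineages grouped into classes/phyla
  o <- lineage_index
  cl <- (o - 1L) %/% per_group + 1L
  ph <- (cl - 1L) %/% per_group + 1L
  dom <- ifelse(ph %% 5L == 0L, "Archaea_X", "Bacteria_X")
  sprintf("d__%s;p__Phylum%02d;c__Class%02d;o__Lineage%02d;f__Family%02d;g__Genus%02d;s__",
          dom, ph, cl, o, o, o)
}

#' Simulate SAG, MAG and isolate genome collections
#'
#' Emulates the sampling characteristics of the two technologies: SAG
#' lineages are drawn proportional to true abundance (randomized cell
#' sorting), while MAG lineages are drawn proportional to
#' `abundance^tau` with `tau < 1`, which tempers the abundance gradient
#' and enriches rare lineages (abundance-correlation binning recovers
#' rare but distinct genomes). Completeness is drawn per collection
#' (defaults: mean 69% for SAGs, 71% for MAGs, sd 12, truncated to
#' [50, 100]); contamination is exponential, truncated to [0, 10].
#'
#' @param truth `true_proportions` from [simulate_community_counts()]
#'   (named numeric), or a `community_spec` truth list.
#' @param n_sag,n_mag,n_isolate collection sizes (defaults 400, 400, 0).
#' @param tau MAG tempering exponent in (0, 1] (default 0.3).
#' @param completeness_mean named means per collection.
#' @param seed integer seed.
#' @return a `genomes` table (isolates sample abundance-proportionally,
#'   like SAGs).
#' @export
simulate_genome_collections <- function(truth, n_sag = 400, n_mag = 400,
                                        n_isolate = 0, tau = 0.3,
                                        completeness_mean = c(SAG = 69,
                                                              MAG = 71,
                                                              ISOLATE = 90),
                                        seed = 1L) {
  if (is.list(truth)) truth <- truth$true_proportions
  stopifnot(!is.null(names(truth)), all(truth > 0))
  if (tau <= 0 || tau > 1) stop("tau must be in (0,1]", call. = FALSE)
  p_mag <- truth^tau / sum(truth^tau)
  with_seed(seed, {
    draw <- function(n, coll, prob) {
      if (n < 1L) return(NULL)
      li <- sample.int(length(truth), n, replace = TRUE, prob = prob)
      comp <- pmin(100, pmax(50, rnorm(n, completeness_mean[[coll]], 12)))
      data.frame(
        genome_id = sprintf("%s_%04d", coll, seq_len(n)),
        collection = coll,
        taxonomy = .synthetic_taxonomy(li),
        completeness = round(comp, 2),
        contamination = round(pmin(10, rexp(n, rate = 1)), 2),
        sample_id = sprintf("%s_s%02d", coll,
                            sample.int(20L, n, replace = TRUE)),
        depth_m = round(runif(n, 0, 100), 1),
        latitude_deg = round(runif(n, -40, 40), 2),
        region_flag = "open_ocean", stringsAsFactors = FALSE)
    }
    out <- rbind(draw(n_sag, "SAG", truth), draw(n_mag, "MAG", p_mag),
                 draw(n_isolate, "ISOLATE", truth))
    validate_table(out, "genomes")
  })
}

.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}

.mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    seq <- paste(ch, collapse = "")
  }
  seq
}

#' Simulate a gene catalog with core/flexible structure
#'
#' An ancestral pool of `n_core + n_flexible` gene families (random
#' nucleotide sequences, one KO per family, consecutive families grouped
#' into KEGG-style modules of `module_size` KOs, flexible families
#' last). Every genome carries each core family unless lost to the base
#' per-gene dropout; flexible families are additionally subject to the
#' collection-specific flexible dropout -- elevated for MAG-labeled
#' genomes, which is the planted "MAGs are depleted in flexible genes"
#' effect. Each genome's gene copies are point-mutated at
#' `mutation_rate` per site.
#'
#' @param genomes a `genomes` table ([simulate_genome_collections()]).
#' @param n_core,n_flexible family counts (defaults 30 and 60).
#' @param base_dropout per-gene loss probability for every genome
#'   (default 0.1, the incompleteness of real assemblies).
#' @param sag_flexible_dropout additional flexible-gene loss for SAGs
#'   (default 0.1).
#' @param mag_flexible_dropout flexible-gene loss for MAGs (default 0.6).
#' @param mutation_rate per-site substitution probability (default 0.02).
#' @param gene_length bp per gene (default 300).
#' @param module_size KOs per synthetic module (default 6).
#' @param seed integer seed.
#' @param emit_sequences generate mutated gene sequences (default TRUE);
#'   `FALSE` skips them for annotation-only studies.
#' @return list with `sequences` (sequence records, or `NULL`),
#'   `annotations` (`annotations` table), `modules` (`modules` table)
#'   and `truth` (family -> KO map, flexible flags, per-family module).
#' @export
simulate_gene_catalog <- function(genomes, n_core = 30, n_flexible = 60,
                                  base_dropout = 0.1,
                                  sag_flexible_dropout = 0.1,
                                  mag_flexible_dropout = 0.6,
                                  mutation_rate = 0.02, gene_length = 300,
                                  module_size = 6, seed = 1L,
                                  emit_sequences = TRUE) {
  genomes <- validate_table(genomes, "genomes")
  rates <- c(base_dropout, sag_flexible_dropout, mag_flexible_dropout,
             mutation_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]",
                                       call. = FALSE)
  n_fam <- n_core + n_flexible
  fam_ids <- sprintf("fam%04d", seq_len(n_fam))
  kos <- sprintf("K%05d", seq_len(n_fam))
  flexible <- c(rep(FALSE, n_core), rep(TRUE, n_flexible))
  module_of <- sprintf("M%04d", (seq_len(n_fam) - 1L) %/% module_size + 1L)
  with_seed(seed, {
    ancestral <- .random_dna(n_fam, gene_length)
    seqs <- list(); ann <- list()
    for (i in seq_len(nrow(genomes))) {
      g <- genomes$genome_id[i]
      coll <- genomes$collection[i]
      flex_rate <- switch(coll, SAG = sag_flexible_dropout,
                          MAG = mag_flexible_dropout, ISOLATE = 0)
      keep <- runif(n_fam) >= base_dropout
      keep[flexible] <- keep[flexible] & (runif(n_flexible) >= flex_rate)
      kept <- which(keep)
      gids <- paste0(g, ":", fam_ids[kept])
      if (length(kept)) {
        if (emit_sequences)
          seqs[[length(seqs) + 1L]] <- data.frame(
            seq_id = gids, genome_id = g, alphabet = "nucleotide",
            residues = vapply(ancestral[kept], .mutate_dna, "",
                              rate = mutation_rate, USE.NAMES = FALSE),
            stringsAsFactors = FALSE)
        ann[[length(ann) + 1L]] <- data.frame(
          genome_id = g, gene_id = gids, ko_id = kos[kept],
          stringsAsFactors = FALSE)
      }
    }
    sequences <- NULL
    if (emit_sequences) {
      sequences <- do.call(rbind, seqs)
      sequences <- sequence_records(sequences$seq_id, sequences$genome_id,
                                    sequences$alphabet, sequences$residues)
    }
    modules <- validate_table(
      data.frame(module_id = module_of, ko_id = kos,
                 stringsAsFactors = FALSE), "modules")
    list(sequences = sequences,
         annotations = validate_table(do.call(rbind, ann), "annotations"),
         modules = modules,
         truth = data.frame(family = fam_ids, ko_id = kos,
                            flexible = flexible, module_id = module_of,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate contamination reports and 16S assignments
#'
#' Planted chimeras receive, at one rank strictly above genus, a clade
#' separation score in `css_range`, a reference representation score in
#' `rrs_range`, and a second-estimator contamination fraction in
#' `mdm_range` -- jointly satisfying every consensus condition. Clean
#' genomes are given evidence failing at least one condition (low CSS
#' everywhere, low RRS, or low second-estimator contamination). Each
#' genome yields one or two 16S copies with probability
#' `rrna_recovery`; planted conflicts substitute a different-domain or
#' different-phylum taxonomy for one copy.
#'
#' @param genomes a `genomes` table.
#' @param chimera_fraction fraction of genomes planted as chimeras
#'   (default 0.04); applied to MAGs first (the collection where
#'   chimerism concentrates), spilling over to SAGs only if needed.
#' @param conflict_fraction fraction of 16S-bearing genomes with a
#'   planted conflicting copy (default 0.02).
#' @param css_range,rrs_range,mdm_range evidence ranges for planted
#'   chimeras (defaults `[0.85,1]`, `[0.5,1]`, `[0.10,0.5]`).
#' @param rrna_recovery probability a genome yields any 16S copy
#'   (default 0.6).
#' @param seed integer seed.
#' @return list with `gunc`, `mdm`, `rrna` tables and `truth`
#'   (`chimera_ids`, `conflicts`: data.frame genome_id, rank).
#' @export
simulate_quality_reports <- function(genomes, chimera_fraction = 0.04,
                                     conflict_fraction = 0.02,
                                     css_range = c(0.85, 1),
                                     rrs_range = c(0.5, 1),
                                     mdm_range = c(0.10, 0.5),
                                     rrna_recovery = 0.6, seed = 1L) {
  genomes <- validate_table(genomes, "genomes")
  stopifnot(chimera_fraction >= 0, chimera_fraction <= 1,
            conflict_fraction >= 0, conflict_fraction <= 1)
  n <- nrow(genomes)
  n_chim <- round(chimera_fraction * n)
  above_genus <- c("domain", "phylum", "class", "order", "family")
  with_seed(seed, {
    mags <- which(genomes$collection == "MAG")
    others <- setdiff(seq_len(n), mags)
    pool <- c(sample(mags), sample(others))
    chim_ix <- sort(pool[seq_len(n_chim)])
    is_chim <- seq_len(n) %in% chim_ix
    gunc <- list(); mdm_val <- numeric(n)
    for (i in seq_len(n)) {
      css <- runif(7L, 0, 0.3)
      rrs <- runif(7L, 0.5, 1)
      contam <- runif(7L, 0, 0.08)
      if (is_chim[i]) {
        ev_rank <- match(sample(above_genus, 1L), TAX_RANKS)
        css[ev_rank] <- runif(1L, css_range[1L], css_range[2L])
        rrs[ev_rank] <- runif(1L, rrs_range[1L], rrs_range[2L])
        contam[ev_rank] <- runif(1L, 0.1, 0.5)
        mdm_val[i] <- runif(1L, mdm_range[1L], mdm_range[2L])
      } else {
        # fail at least one consensus condition, sampled per genome
        mode <- sample(3L, 1L)
        if (mode == 1L) {                 # low CSS everywhere (the default)
          mdm_val[i] <- runif(1L, 0, 0.04)
        } else if (mode == 2L) {          # poorly represented: low RRS
          rrs <- runif(7L, 0, 0.4)
          css[sample(7L, 1L)] <- runif(1L, 0.5, 1)
          mdm_val[i] <- runif(1L, 0, 0.04)
        } else {                          # second estimator disagrees
          css[match(sample(above_genus, 1L), TAX_RANKS)] <-
            runif(1L, 0.85, 1)
          mdm_val[i] <- runif(1L, 0, 0.04)
        }
      }
      gunc[[i]] <- data.frame(genome_id = genomes$genome_id[i],
                              rank = TAX_RANKS, css = round(css, 4),
                              rrs = round(rrs, 4),
                              contamination_portion = round(contam, 4),
                              stringsAsFactors = FALSE)
    }
    gunc <- validate_table(do.call(rbind, gunc), "gunc")
    mdm <- validate_table(data.frame(genome_id = genomes$genome_id,
                                     contamination_fraction =
                                       round(mdm_val, 4),
                                     stringsAsFactors = FALSE), "mdm")
    # 16S assignments
    has_rrna <- runif(n) < rrna_recovery
    carriers <- which(has_rrna)
    n_confl <- round(conflict_fraction * length(carriers))
    confl_ix <- sort(sample(carriers, n_confl))
    gt <- parse_taxonomy(genomes$taxonomy)
    rrna <- list(); confl <- list()
    for (i in carriers) {
      copies <- sample(2L, 1L)
      tax <- genomes$taxonomy[i]
      for (cp in seq_len(copies)) {
        this_tax <- tax
        if (i %in% confl_ix && cp == copies) {
          alt <- gt[i, ]
          cr <- sample(c("domain", "phylum"), 1L)
          alt[cr] <- paste0(alt[cr], "_alt")
          if (cr == "domain") alt["phylum"] <- paste0(alt["phylum"], "_alt")
          this_tax <- format_taxonomy(alt)
          confl[[length(confl) + 1L]] <-
            data.frame(genome_id = genomes$genome_id[i], rank = cr,
                       stringsAsFactors = FALSE)
        }
        rrna[[length(rrna) + 1L]] <- data.frame(
          genome_id = genomes$genome_id[i],
          seq_id = sprintf("%s_16S_%d", genomes$genome_id[i], cp),
          taxonomy = this_tax, stringsAsFactors = FALSE)
      }
    }
    rrna <- validate_table(do.call(rbind, rrna), "rrna")
    list(gunc = gunc, mdm = mdm, rrna = rrna,
         truth = list(chimera_ids = genomes$genome_id[chim_ix],
                      conflicts = if (length(confl)) do.call(rbind, confl)
                      else data.frame(genome_id = character(0),
                                      rank = character(0))))
  })
}

#' Simulate fragment-recruitment summaries
#'
#' Per sample, reads are drawn from the community composition; a read is
#' recruitable by a reference set when its lineage happens to be covered
#' by that set in that sample (each lineage is covered independently
#' with probability `reference_coverage`, redrawn per sample to mimic
#' per-sample reference variability). Recruited reads get a best
#' identity of `1 - |N(0, identity_noise)|` and an alignment length
#' drawn around 150 bp with some mass below 100 bp, so the length filter
#' is exercised.
#'
#' @param truth named vector of true lineage proportions.
#' @param reference_coverage named per-set lineage coverage in `[0,1]`
#'   (default `c(SAG = 0.8, MAG = 0.8)`).
#' @param n_samples number of metagenome samples (default 24).
#' @param n_reads reads per sample (default 5000).
#' @param identity_noise sd of the identity shortfall (default 0.03).
#' @param aln_mean,aln_sd normal parameters of the alignment length in
#'   bp (defaults 150 and 30, leaving some mass below the 100 bp
#'   filter).
#' @param seed integer seed.
#' @return an `alignments` table.
#' @export
simulate_recruitment <- function(truth,
                                 reference_coverage = c(SAG = 0.8,
                                                        MAG = 0.8),
                                 n_samples = 24, n_reads = 5000,
                                 identity_noise = 0.03, aln_mean = 150,
                                 aln_sd = 30, seed = 1L) {
  if (is.list(truth)) truth <- truth$true_proportions
  stopifnot(all(reference_coverage >= 0), all(reference_coverage <= 1),
            all(c("SAG", "MAG") %in% names(reference_coverage)))
  L <- length(truth)
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_samples)) {
      sid <- sprintf("meta_s%02d", s)
      lin <- sample.int(L, n_reads, replace = TRUE, prob = truth)
      for (rs in c("SAG", "MAG")) {
        covered <- runif(L) < reference_coverage[[rs]]
        hit <- which(covered[lin])
        if (!length(hit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, reference_set = rs,
          read_id = sprintf("r%05d", hit),
          identity = round(pmax(0.7, 1 - abs(rnorm(length(hit), 0,
                                                   identity_noise))), 4),
          aln_length = pmax(30L, as.integer(round(rnorm(length(hit),
                                                        aln_mean,
                                                        aln_sd)))),
          sample_total_reads = as.integer(n_reads),
          stringsAsFactors = FALSE)
      }
    }
    validate_table(do.call(rbind, rows), "alignments")
  })
}
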