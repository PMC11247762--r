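# Subcommand front-end tying the stages into the two workflows
# (composition comparison; genome-quality comparison), with a run
# manifest for provenance. Each stage reads validated TSVs, writes its
# outputs with a manifest reference in a leading comment line, and logs
# row counts in and out.

.digest_files <- function(paths) {
  paths <- as.character(unlist(paths))
  if (!length(paths)) return(list())
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(list())
  # keyed by basename so the manifest id is independent of the directory
  setNames(as.list(unname(tools::md5sum(paths))), basename(paths))
}

.write_manifest <- function(outdir, subcommand, params, seed, inputs) {
  digests <- .digest_files(inputs)
  # canonical parameters: path-valued entries reduced to basenames so the
  # manifest id (hence the provenance headers) does not depend on where
  # the run directory lives
  params_key <- lapply(params, function(v)
    if (is.character(v) && length(v) == 1L && file.exists(v)) basename(v)
    else v)
  key <- jsonlite::toJSON(list(subcommand = subcommand, params = params_key,
                               seed = seed, inputs = digests),
                          auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(key, tmp)
  id <- unname(tools::md5sum(tmp)); unlink(tmp)
  manifest <- list(subcommand = subcommand, manifest_id = id,
                   params = params, inputs = digests, seed = seed,
                   tool_version = as.character(packageVersion("sagmag")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest,
                       file.path(outdir,
                                 paste0("manifest_", subcommand, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  id
}

.write_out <- function(df, path, manifest_id, log = TRUE) {
  out <- as.data.frame(df)
  for (cn in names(out))
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.15g", out[[cn]])
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# manifest: ", manifest_id), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  if (log) message("wrote ", nrow(df), " rows to ", basename(path))
  invisible(path)
}

.stage_outputs <- list(
  simulate = c("genomes.tsv", "counts.tsv", "annotations.tsv",
               "modules.tsv", "genes.fasta", "gunc.tsv", "mdm.tsv",
               "rrna.tsv", "alignments.tsv", "truth.json"),
  composition = c("profile.tsv", "diffabund.tsv"),
  richness = "richness.tsv",
  cluster = "clusters.tsv",
  pangenome = c("curve.tsv", "venn.tsv"),
  modules = c("categories.tsv", "standardized.tsv", "module_tests.tsv"),
  chimera = c("chimera_calls.tsv", "incongruence.tsv"),
  conflicts = "conflicts_16s.tsv",
  recruit = c("recruitment.tsv", "recruitment_tests.tsv"),
  report = "summary.tsv")

#' Run one pipeline stage
#'
#' File-level front-end over the package's functions. Each call
#' validates its inputs, runs one stage, writes the stage's output
#' tables into `outdir` (each carrying a `# manifest:` provenance
#' comment) plus a `manifest_<subcommand>.json` recording parameters,
#' input digests, seed and tool version. Reruns with identical inputs,
#' parameters and seed produce byte-identical output tables.
#'
#' Subcommands and their main parameters (supplied via `params`):
#' `simulate` (the full synthetic bundle; sizes and rates of the
#' generators), `composition` (`counts`, `rank`, `n_mc`, cutoffs),
#' `richness` (`genomes`), `cluster` (`fasta`, `alphabet`, `identity`,
#' `coverage`, `coverage_mode`), `pangenome` (`clusters`, `genomes`,
#' `subset`, `n_perm`), `modules` (`annotations`, `modules`, `genomes`),
#' `chimera` (`gunc`, `mdm`), `conflicts` (`genomes`, `rrna`),
#' `recruit` (`alignments`, `thresholds`, `min_aln_length`), and
#' `report` (aggregates whatever stage outputs exist in `outdir`).
#'
#' @param subcommand one of the stage names above.
#' @param outdir output directory (created if needed).
#' @param params named list of stage parameters; file parameters are
#'   paths.
#' @param seed integer seed for every stochastic stage.
#' @param log emit per-stage row-count messages (default TRUE).
#' @return named character vector of the files written, invisibly.
#' @export
run_stage <- function(subcommand, outdir, params = list(), seed = 1L,
                      log = TRUE) {
  subcommand <- match.arg(subcommand, names(.stage_outputs))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name, default = NULL) params[[name]] %||% default
  inputs <- unlist(params[vapply(params, function(v)
    is.character(v) && length(v) == 1L && file.exists(v), NA)])
  id <- .write_manifest(outdir, subcommand, params, seed, inputs)
  o <- function(f) file.path(outdir, f)
  emit <- function(df, f) .write_out(df, o(f), id, log)

  switch(subcommand,
    simulate = {
      spec <- community_spec(
        n_lineages = p("n_lineages", 40),
        n_samples = p("n_samples", 20),
        mean_depth = p("mean_depth", 5e4))
      cc <- simulate_community_counts(spec, seed = seed)
      genomes <- simulate_genome_collections(
        cc$truth, n_sag = p("n_sag", 400), n_mag = p("n_mag", 400),
        n_isolate = p("n_isolate", 20), tau = p("tau", 0.3),
        seed = derive_seed(seed, 1L))
      cat_genomes <- genomes[seq_len(min(nrow(genomes),
                                         p("n_catalog_genomes", 60))), ]
      catalog <- simulate_gene_catalog(
        cat_genomes, n_core = p("n_core", 30),
        n_flexible = p("n_flexible", 60),
        mag_flexible_dropout = p("mag_flexible_dropout", 0.6),
        seed = derive_seed(seed, 2L))
      qual <- simulate_quality_reports(
        genomes, chimera_fraction = p("chimera_fraction", 0.04),
        conflict_fraction = p("conflict_fraction", 0.02),
        seed = derive_seed(seed, 3L))
      aln <- simulate_recruitment(
        cc$truth,
        reference_coverage = c(SAG = p("sag_coverage", 0.8),
                               MAG = p("mag_coverage", 0.8)),
        seed = derive_seed(seed, 4L))
      hdr <- c(paste("manifest:", id), paste("seed:", seed))
      write_table(genomes, o("genomes.tsv"), "genomes", hdr)
      write_table(cc$counts, o("counts.tsv"), "counts", hdr)
      write_table(catalog$annotations, o("annotations.tsv"), "annotations",
                  hdr)
      write_table(catalog$modules, o("modules.tsv"), "modules", hdr)
      write_fasta(catalog$sequences, o("genes.fasta"))
      write_table(qual$gunc, o("gunc.tsv"), "gunc", hdr)
      write_table(qual$mdm, o("mdm.tsv"), "mdm", hdr)
      write_table(qual$rrna, o("rrna.tsv"), "rrna", hdr)
      write_table(aln, o("alignments.tsv"), "alignments", hdr)
      jsonlite::write_json(
        list(seed = seed,
             true_proportions = as.list(cc$truth$true_proportions),
             planted_lineages = cc$truth$planted,
             flexible_families =
               catalog$truth$family[catalog$truth$flexible],
             chimera_ids = qual$truth$chimera_ids,
             conflicts = qual$truth$conflicts),
        o("truth.json"), auto_unbox = TRUE, digits = NA)
      if (log) message("simulated bundle written to ", outdir)
    },
    composition = {
      counts <- read_table(p("counts", o("counts.tsv")), "counts")
      rank <- p("rank", "order")
      prof <- build_profile(counts, rank)
      emit(prof, "profile.tsv")
      da <- differential_abundance(
        counts, rank, n_mc = p("n_mc", 1000),
        prior_mass = p("prior_mass", 0.5),
        diff_cutoff = p("diff_cutoff", 2), p_cutoff = p("p_cutoff", 1e-3),
        seed = seed)
      emit(as.data.frame(da), "diffabund.tsv")
    },
    richness = {
      genomes <- read_table(p("genomes", o("genomes.tsv")), "genomes")
      sag <- genomes[genomes$collection == "SAG", ]
      mag <- genomes[genomes$collection == "MAG", ]
      rich <- do.call(rbind, lapply(
        c("phylum", "class", "order", "family"), function(r) {
          v <- richness_by_rank(sag, mag, r)
          data.frame(rank = r, shared = v[["shared"]],
                     sag_only = v[["sag_only"]],
                     mag_only = v[["mag_only"]])
        }))
      emit(rich, "richness.tsv")
    },
    cluster = {
      seqs <- read_fasta(p("fasta", o("genes.fasta")),
                         alphabet = p("alphabet", "nucleotide"))
      cl <- greedy_cluster(seqs, cluster_params(
        identity_threshold = p("identity", 0.95),
        coverage_threshold = p("coverage", 0.9),
        coverage_mode = p("coverage_mode", "shorter")))
      write_table(cl, o("clusters.tsv"), "clusters",
                  paste("manifest:", id))
      if (log) message(nrow(cl), " members in ",
                       sum(cl$is_representative), " clusters")
    },
    pangenome = {
      cl <- read_table(p("clusters", o("clusters.tsv")), "clusters")
      genomes <- read_table(p("genomes", o("genomes.tsv")), "genomes")
      genome_of <- setNames(sub(":.*$", "", cl$member_id), cl$member_id)
      inc <- incidence_matrix(cl, genomes, genome_of = genome_of)
      subsets <- if (!is.null(params$subset)) params$subset else
        c("SAG", "MAG")
      curves <- do.call(rbind, lapply(subsets, function(ss) {
        if (ss != "all" && !any(attr(inc, "collection") == ss))
          return(NULL)
        cv <- accumulation_curve_perm(inc, subset = ss,
                                      n_perm = p("n_perm", 1000),
                                      seed = seed)
        cbind(subset = ss, as.data.frame(cv))
      }))
      emit(curves, "curve.tsv")
      v <- venn_counts(cl, genomes, genome_of = genome_of)
      emit(data.frame(shared = v[["shared"]],
                      sag_exclusive = v[["sag_exclusive"]],
                      mag_exclusive = v[["mag_exclusive"]]), "venn.tsv")
    },
    modules = {
      ann <- read_table(p("annotations", o("annotations.tsv")),
                        "annotations")
      mods <- read_table(p("modules", o("modules.tsv")), "modules")
      genomes <- read_table(p("genomes", o("genomes.tsv")), "genomes")
      coll <- setNames(genomes$collection, genomes$genome_id)
      iso <- names(coll)[coll == "ISOLATE"]
      sm_ann <- ann[!ann$genome_id %in% iso, ]
      iso_ann <- ann[ann$genome_id %in% iso, ]
      pres <- presence_matrix(sm_ann, mods,
                              threshold = p("presence_threshold", 0.75))
      ref_pres <- if (length(iso))
        apply(presence_matrix(iso_ann, mods, genomes = iso), 2L, any)
      else setNames(rep(FALSE, length(module_definitions(mods))),
                    names(module_definitions(mods)))
      retained <- retain_modules(pres, ref_pres, coll,
                                 min_prevalence = p("prevalence", 0.05))
      defs <- module_definitions(mods)[retained]
      cats <- merge_overlapping(defs,
                                overlap_threshold = p("overlap_threshold",
                                                      0.65))
      emit(cats$map, "categories.tsv")
      std <- standardized_counts(sm_ann, cats, iso_ann,
                                 isolate_genomes = iso)
      emit(std, "standardized.tsv")
      tests <- compare_categories(std, coll,
                                  p_cutoff = p("p_cutoff", 1e-3))
      emit(tests, "module_tests.tsv")
    },
    chimera = {
      gunc <- read_table(p("gunc", o("gunc.tsv")), "gunc")
      mdm <- read_table(p("mdm", o("mdm.tsv")), "mdm")
      calls <- consensus_chimera_call(
        gunc, mdm, rrs_min = p("rrs_min", 0.5),
        css_min = p("css_min", 0.85), mdm_min = p("mdm_min", 0.10),
        css_default = p("css_default", 0.45))
      emit(as.data.frame(calls), "chimera_calls.tsv")
      inc <- contamination_incongruence(gunc, mdm)
      emit(inc$table, "incongruence.tsv")
    },
    conflicts = {
      genomes <- read_table(p("genomes", o("genomes.tsv")), "genomes")
      rrna <- read_table(p("rrna", o("rrna.tsv")), "rrna")
      cf <- conflict_16s(genomes, rrna)
      counts <- as.data.frame(as.table(cf$mismatch_counts),
                              stringsAsFactors = FALSE)
      names(counts) <- c("collection", "rank", "mismatches")
      rec <- data.frame(collection = names(cf$recovery_fraction),
                        rank = "any",
                        mismatches = NA_integer_,
                        recovery_fraction = unname(cf$recovery_fraction))
      counts$recovery_fraction <- NA_real_
      emit(rbind(counts, rec), "conflicts_16s.tsv")
    },
    recruit = {
      aln <- read_table(p("alignments", o("alignments.tsv")), "alignments")
      thr <- p("thresholds", DEFAULT_IDENTITY_THRESHOLDS)
      fr <- do.call(rbind, lapply(thr, function(t0)
        cbind(threshold = t0,
              recruitment_fraction(aln, t0,
                                   p("min_aln_length", 100L)))))
      emit(fr, "recruitment.tsv")
      emit(compare_recruitment(aln, thr, p("min_aln_length", 100L)),
           "recruitment_tests.tsv")
    },
    report = {
      pieces <- list()
      grab <- function(f) {
        path <- o(f)
        if (!file.exists(path)) return(NULL)
        read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
      }
      da <- grab("diffabund.tsv")
      if (!is.null(da))
        pieces$composition <- data.frame(
          section = "composition", item = "significant_lineage_pairs",
          value = sum(da$significant == "TRUE" | da$significant == TRUE))
      rich <- grab("richness.tsv")
      if (!is.null(rich))
        pieces$richness <- data.frame(
          section = "richness",
          item = paste0(rich$rank, c("_shared")),
          value = rich$shared)
      venn <- grab("venn.tsv")
      if (!is.null(venn))
        pieces$venn <- data.frame(
          section = "pangenome",
          item = c("shared_clusters", "sag_exclusive", "mag_exclusive"),
          value = c(venn$shared, venn$sag_exclusive, venn$mag_exclusive))
      mt <- grab("module_tests.tsv")
      if (!is.null(mt))
        pieces$modules <- data.frame(
          section = "modules", item = "significant_categories",
          value = sum(mt$significant == "TRUE" | mt$significant == TRUE))
      ch <- grab("chimera_calls.tsv")
      if (!is.null(ch))
        pieces$chimera <- data.frame(
          section = "chimera",
          item = c("default_calls", "consensus_calls"),
          value = c(sum(ch$default_call == "TRUE" | ch$default_call == TRUE),
                    sum(ch$consensus_call == "TRUE" |
                          ch$consensus_call == TRUE)))
      cf <- grab("conflicts_16s.tsv")
      if (!is.null(cf))
        pieces$conflicts <- data.frame(
          section = "conflicts_16s", item = "total_mismatches",
          value = sum(as.numeric(cf$mismatches), na.rm = TRUE))
      rt <- grab("recruitment_tests.tsv")
      if (!is.null(rt))
        pieces$recruit <- data.frame(
          section = "recruitment",
          item = paste0("p_at_", rt$threshold),
          value = as.numeric(rt$p_value))
      if (!length(pieces))
        stop("no stage outputs found in ", outdir, call. = FALSE)
      emit(do.call(rbind, unname(pieces)), "summary.tsv")
    })
  invisible(setNames(file.path(outdir, .stage_outputs[[subcommand]]),
                     .stage_outputs[[subcommand]]))
}
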