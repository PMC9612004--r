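# Pipeline orchestration: a single entry point chaining the stages
# (simulate, enumerate, dsa, splice-quant, ptc, architecture) over a
# file-based working directory, with a run manifest and one master seed
# governing every stochastic stage. Outputs are plain TSV and are
# byte-identical across runs with the same configuration and seed.

#' Pipeline configuration
#'
#' Every parameter has a field-standard default: the 15-40 nt enumeration
#' window with the 21-30 nt prevalent range, 500-gene/1000-replicate
#' bootstrap, ten CDS bins, a 10-read coverage minimum, 15 nt flank
#' windows and a 200 bp gene tail.
#'
#' @param genome_fasta,annotation_gff3,expression_tsv,junctions_tsv,counts_tsv
#'   Input paths. When `NULL`, the `simulate` stage outputs in `outdir` are
#'   used.
#' @param enumeration An [enumeration_params()] object.
#' @param bootstrap A [bootstrap_params()] object.
#' @param quant A [quant_params()] object.
#' @param analysis An [analysis_config()] object.
#' @param simulation A [simulation_params()] object (for the `simulate`
#'   stage).
#' @param depletion_delta Depletion planted by `simulate` (0 disables).
#' @param flank_width Flank window width (nt).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta = NULL, annotation_gff3 = NULL,
                            expression_tsv = NULL, junctions_tsv = NULL,
                            counts_tsv = NULL,
                            enumeration = enumeration_params(),
                            bootstrap = bootstrap_params(),
                            quant = quant_params(),
                            analysis = analysis_config(),
                            simulation = simulation_params(),
                            depletion_delta = 0,
                            flank_width = 15L,
                            seed = 1L) {
  structure(list(genome_fasta = genome_fasta,
                 annotation_gff3 = annotation_gff3,
                 expression_tsv = expression_tsv,
                 junctions_tsv = junctions_tsv,
                 counts_tsv = counts_tsv,
                 enumeration = enumeration, bootstrap = bootstrap,
                 quant = quant, analysis = analysis,
                 simulation = simulation,
                 depletion_delta = depletion_delta,
                 flank_width = as.integer(flank_width),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' Plain-text `key = value` lines; `#` starts a comment. Nested parameters
#' use dotted keys, e.g. `bootstrap.replicates = 1000`,
#' `simulation.n_genes = 2000`, `enumeration.min_len = 15`. Unknown keys
#' are an error.
#'
#' @param path Path to the config file.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- pipeline_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    val <- if (!is.na(num)) num else val
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      if (!parts %in% names(cfg)) stop("unknown config key: ", key)
      cfg[[parts]] <- val
    } else if (length(parts) == 2L) {
      if (!parts[1L] %in% names(cfg) ||
          !parts[2L] %in% names(cfg[[parts[1L]]]))
        stop("unknown config key: ", key)
      cfg[[parts[1L]]][[parts[2L]]] <- val
    } else stop("unknown config key: ", key)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

stage_outputs <- function(outdir) {
  list(genome = file.path(outdir, "genome.fasta"),
       annotation = file.path(outdir, "annotation.gff3"),
       expression = file.path(outdir, "expression.tsv"),
       junctions = file.path(outdir, "junctions.tsv"),
       counts = file.path(outdir, "locus_counts.tsv"),
       segments = file.path(outdir, "segments.tsv"),
       dsa_profile = file.path(outdir, "dsa_profile.tsv"),
       bootstrap_scores = file.path(outdir, "bootstrap_scores.tsv"),
       bootstrap_tests = file.path(outdir, "bootstrap_tests.tsv"),
       flank_dsa = file.path(outdir, "flank_dsa.tsv"),
       profiles = file.path(outdir, "splicing_profiles.tsv"),
       splicing_bins = file.path(outdir, "splicing_bins.tsv"),
       introns = file.path(outdir, "introns.tsv"),
       ptc = file.path(outdir, "ptc_enrichment.tsv"),
       metrics = file.path(outdir, "gene_metrics.tsv"),
       bin_occupancy = file.path(outdir, "bin_occupancy.tsv"),
       assoc_tests = file.path(outdir, "association_tests.tsv"),
       manifest = file.path(outdir, "manifest.tsv"))
}

require_stage_input <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing input '", basename(path), "': run stage '", produced_by,
         "' first (or point the config at existing inputs)")
  path
}

load_pipeline_inputs <- function(config, out) {
  genome_path <- config$genome_fasta %||% out$genome
  gff_path <- config$annotation_gff3 %||% out$annotation
  expr_path <- config$expression_tsv %||% out$expression
  require_stage_input(genome_path, "simulate")
  require_stage_input(gff_path, "simulate")
  expr <- if (file.exists(expr_path)) read_expression_table(expr_path)
    else NULL
  genome <- read_fasta(genome_path)
  genes <- read_gff3_gene_models(gff_path, expression = expr)
  list(genome = genome, genes = genes, expression = expr)
}

manifest_rows <- function(stage, params) {
  flat <- unlist(params)
  data.frame(stage = stage, key = names(flat),
             value = as.character(flat), stringsAsFactors = FALSE)
}

#' Run the analysis pipeline
#'
#' Subcommands: `simulate` (synthetic genome + junction tables),
#' `enumerate` (coding exons and GT|AG segments), `dsa` (per-size DSA
#' profiles, gene-bootstrap scores and tests, flank-motif DSA scans),
#' `splice-quant` (per-locus splicing profiles and level-class summary),
#' `ptc` (intron table and PTC enrichment), `architecture` (per-gene
#' metrics, CDS bin occupancy, association tests), and `all` (every stage
#' in dependency order). Each stage writes TSV tables into `outdir` and
#' appends its parameters to `manifest.tsv`. Missing stage inputs are an
#' error naming the stage that produces them. With a fixed config and seed
#' the outputs are byte-identical across runs.
#'
#' @param config A [pipeline_config()] object.
#' @param subcommand One of `"simulate"`, `"enumerate"`, `"dsa"`,
#'   `"splice-quant"`, `"ptc"`, `"architecture"`, `"all"`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the named list of output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), subcommand = "all",
                         outdir = "intronsig_out") {
  subcommand <- match.arg(subcommand,
                          c("all", "simulate", "enumerate", "dsa",
                            "splice-quant", "ptc", "architecture"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- stage_outputs(outdir)
  stages <- if (subcommand == "all")
    c("simulate", "enumerate", "dsa", "splice-quant", "ptc",
      "architecture") else subcommand
  manifest <- list(manifest_rows("run", list(seed = config$seed,
                                             version = pkg_version(),
                                             stages = paste(stages,
                                                            collapse = ","))))
  for (stage in stages) {
    manifest[[length(manifest) + 1L]] <- switch(
      stage,
      simulate = stage_simulate(config, out),
      enumerate = stage_enumerate(config, out),
      dsa = stage_dsa(config, out),
      `splice-quant` = stage_splice_quant(config, out),
      ptc = stage_ptc(config, out),
      architecture = stage_architecture(config, out))
  }
  write_tsv_file(bind_rows_list(manifest), out$manifest)
  invisible(out)
}

pkg_version <- function() {
  as.character(utils::packageVersion("intronsig"))
}

stage_simulate <- function(config, out) {
  sp <- config$simulation
  sp$seed <- derive_seed(config$seed, 1L)
  sim <- simulate_genome(sp)
  if (config$depletion_delta > 0)
    sim <- deplete_genome(sim, config$depletion_delta,
                          params = config$enumeration,
                          seed = derive_seed(config$seed, 2L))
  write_simulated_dataset(sim, dirname(out$genome))
  # junction/count tables for the annotated introns, at heterogeneous
  # planted levels
  introns <- derive_intron_records(sim$genes, sim$genome)
  set.seed(derive_seed(config$seed, 3L))
  ls <- stats::runif(nrow(introns), 0.3, 0.9)
  la <- stats::runif(nrow(introns), 0, 0.05)
  loci <- data.frame(locus_id = paste0(introns$gene_id, ".i",
                                       introns$intron_index),
                     chrom = introns$chrom, start = introns$start,
                     end = introns$end,
                     level_spliced = ls, level_retained = 1 - ls - la,
                     level_alt = la,
                     depth = stats::rpois(nrow(introns), 60) + 1L,
                     annotated = TRUE, stringsAsFactors = FALSE)
  jc <- simulate_junction_counts(loci, seed = derive_seed(config$seed, 4L))
  write_junction_table(jc$junctions, out$junctions)
  write_tsv_file(jc$counts, out$counts)
  write_tsv_file(loci, file.path(dirname(out$genome), "truth_levels.tsv"))
  manifest_rows("simulate",
                c(sp[c("n_genes", "mean_introns", "exon_at", "intron_at",
                       "gta_tag_intron_fraction", "seed")],
                  list(depletion_delta = config$depletion_delta)))
}

stage_enumerate <- function(config, out) {
  inp <- load_pipeline_inputs(config, out)
  exons <- extract_coding_exons(inp$genes, inp$genome)
  seg <- segment_table(exons, config$enumeration)
  write_tsv_file(seg[, setdiff(names(seg), "expression")], out$segments)
  manifest_rows("enumerate",
                list(min_len = config$enumeration$min_len,
                     max_len = config$enumeration$max_len,
                     n_exons = nrow(exons), n_segments = nrow(seg)))
}

stage_dsa <- function(config, out) {
  require_stage_input(out$segments, "enumerate")
  inp <- load_pipeline_inputs(config, out)
  seg <- read_tsv_file(out$segments)
  ep <- config$enumeration
  profiles <- lapply(c("GTA|TAG", "GTA|nAG", "GTn|TAG", "GTn|nAG"),
                     function(sig) {
    lapply(c("3n", "3n+1", "3n+2"), function(m3) {
      p <- dsa_size_profile(seg, ep, signal = sig, mod3 = m3)
      p$signal_class <- sig
      p$mod3_class <- m3
      p
    })
  })
  write_tsv_file(bind_rows_list(unlist(profiles, recursive = FALSE)),
                 out$dsa_profile)

  # bootstrap by exon position class and by expression extreme quartiles
  bp <- config$bootstrap
  bp$seed <- derive_seed(config$seed, 5L)
  all_ids <- vapply(inp$genes, `[[`, "", "gene_id")
  groups <- list(first = all_ids, internal = all_ids, last = all_ids)
  quart <- NULL
  if (!is.null(inp$expression)) {
    quart <- assign_expression_quartiles(inp$expression)
    groups$weak <- names(quart)[quart == "Q1"]
    groups$high <- names(quart)[quart == "Q4"]
  }
  positions <- list(first = "first", internal = "internal", last = "last",
                    weak = NULL, high = NULL)
  dists <- list()
  for (nm in names(groups)) {
    if (length(groups[[nm]]) < bp$genes_per_draw) next
    dists[[nm]] <- bootstrap_group_dsa(
      seg, groups[[nm]], bp, signal = "GTA|TAG", mod3 = "3n",
      position = positions[[nm]],
      size_range = ep$prevalent_range, group = nm)
  }
  if (length(dists) >= 2L) {
    write_tsv_file(as.data.frame(dists), out$bootstrap_scores)
    write_tsv_file(compare_bootstrap_groups(dists), out$bootstrap_tests)
  }

  # flank-motif DSA around annotated introns
  up <- character(0); down <- character(0)
  for (g in inp$genes) {
    n_int <- nrow(g$exons) - 1L
    if (n_int < 1L) next
    for (i in seq_len(n_int)) {
      w <- intron_flank_windows(g, i, inp$genome, config$flank_width)
      up <- c(up, w$upstream)
      down <- c(down, w$downstream)
    }
  }
  fl_up <- flank_motif_dsa(up, "GTA", "upstream", config$flank_width)
  fl_up$side <- "upstream"; fl_up$motif <- "GTA"
  fl_down <- flank_motif_dsa(down, "TAG", "downstream", config$flank_width)
  fl_down$side <- "downstream"; fl_down$motif <- "TAG"
  write_tsv_file(rbind(fl_up, fl_down), out$flank_dsa)
  manifest_rows("dsa", list(genes_per_draw = bp$genes_per_draw,
                            replicates = bp$replicates,
                            flank_width = config$flank_width,
                            bootstrap_groups = paste(names(dists),
                                                     collapse = ",")))
}

stage_splice_quant <- function(config, out) {
  junc_path <- config$junctions_tsv %||% out$junctions
  counts_path <- config$counts_tsv %||% out$counts
  require_stage_input(junc_path, "simulate")
  require_stage_input(counts_path, "simulate")
  inp <- load_pipeline_inputs(config, out)
  junctions <- read_junction_table(junc_path)
  counts <- read_tsv_file(counts_path)
  profiles <- profiles_from_counts(counts, config$quant)
  introns <- derive_intron_records(inp$genes, inp$genome)
  key <- paste0(introns$gene_id, ".i", introns$intron_index)
  idx <- match(profiles$locus_id, key)
  profiles$mod3_class <- introns$mod3_class[idx]
  profiles$at <- at_content(introns$sequence[idx])
  write_tsv_file(profiles, out$profiles)
  summ <- splicing_level_class_summary(profiles, config$analysis$n_bins)
  write_tsv_file(summ$bins, out$splicing_bins)
  manifest_rows("splice-quant",
                list(min_reads = config$quant$min_reads,
                     n_loci = nrow(profiles),
                     n_covered = sum(profiles$covered)))
}

stage_ptc <- function(config, out) {
  inp <- load_pipeline_inputs(config, out)
  introns <- derive_intron_records(inp$genes, inp$genome)
  write_tsv_file(introns[, setdiff(names(introns), "sequence")],
                 out$introns)
  enr <- ptc_enrichment(introns, by = "mod3_class")
  enr$fractions$comparison <- "mod3_class"
  enr$tests$comparison <- "mod3_class"
  pos <- introns[introns$position_class %in% c("first", "internal", "last"),
                 , drop = FALSE]
  enr_pos <- ptc_enrichment(pos, by = "position_class")
  enr_pos$fractions$comparison <- "position_class"
  enr_pos$tests$comparison <- "position_class"
  write_tsv_file(rbind(enr$fractions, enr_pos$fractions), out$ptc)
  write_tsv_file(rbind(enr$tests, enr_pos$tests),
                 file.path(dirname(out$ptc), "ptc_tests.tsv"))
  manifest_rows("ptc", list(n_introns = nrow(introns),
                            n_ptc = sum(introns$ptc)))
}

stage_architecture <- function(config, out) {
  require_stage_input(out$segments, "enumerate")
  inp <- load_pipeline_inputs(config, out)
  arch <- architecture_table(inp$genes)
  write_tsv_file(arch$genes, out$metrics)
  seg <- read_tsv_file(out$segments)
  sense <- seg[seg$strand == "sense" & !is.na(seg$cds_start), ,
               drop = FALSE]
  cds_len <- stats::setNames(arch$genes$cds_length, arch$genes$gene_id)
  bins <- bin_cds_position(sense$cds_start, cds_len[sense$gene_id],
                           config$analysis$n_bins)
  occ <- data.frame(bin = seq_len(config$analysis$n_bins),
                    count = as.integer(table(factor(bins,
                      levels = seq_len(config$analysis$n_bins)))))
  write_tsv_file(occ, out$bin_occupancy)
  reqs <- list(bin_uniformity = list(type = "chisq_uniform",
                                     counts = occ$count))
  ok <- !is.na(arch$genes$expression) & arch$genes$expression > 0
  if (sum(ok) >= 4L) {
    reqs$expression_vs_intron_density <- list(
      type = "pearson", x = log2(arch$genes$expression[ok]),
      y = arch$genes$intron_density[ok])
    reqs$expression_vs_cds_length <- list(
      type = "pearson", x = log2(arch$genes$expression[ok]),
      y = arch$genes$cds_length[ok])
  }
  write_tsv_file(association_tests(reqs), out$assoc_tests)
  manifest_rows("architecture",
                list(n_bins = config$analysis$n_bins,
                     tail_window = config$analysis$tail_window,
                     n_genes = nrow(arch$genes)))
}
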