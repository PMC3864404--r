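#' Validate pipeline input files
#'
#' Schema and sanity checks on the TSV inputs: required columns, coordinate
#' sanity (`end > start`, non-negative counts and copy numbers). Returns a
#' machine-readable issue table instead of stopping, so callers can report
#' all problems at once.
#'
#' @param paths Named list/vector with any of `counts`, `segments`.
#' @return data.frame `file`, `issue`, `fatal` (zero rows when all inputs
#'   are well-formed).
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  note <- function(file, issue, fatal = TRUE) {
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, issue = issue, fatal = fatal, stringsAsFactors = FALSE)
  }
  if (!is.null(paths$counts)) {
    if (!file.exists(paths$counts)) {
      note(paths$counts, "file not readable")
    } else {
      x <- tryCatch(read_amplicon_counts(paths$counts), error = function(e) e)
      if (inherits(x, "error")) {
        note(paths$counts, conditionMessage(x))
      } else {
        if (any(x$ref_count < 0 | x$var_count < 0))
          note(paths$counts, "negative read counts")
        if (anyDuplicated(x[c("mutation_id", "sample_id")]))
          note(paths$counts, "duplicated (mutation, sample) pairs")
        if (any(x$pos < 1)) note(paths$counts, "positions must be 1-based")
      }
    }
  }
  if (!is.null(paths$segments)) {
    if (!file.exists(paths$segments)) {
      note(paths$segments, "file not readable")
    } else {
      x <- tryCatch(read_segments(paths$segments), error = function(e) e)
      if (inherits(x, "error")) note(paths$segments, conditionMessage(x))
      else if (any(vapply(x, function(d) any(d$start < 0), logical(1))))
        note(paths$segments, "negative segment start")
    }
  }
  if (length(issues) == 0)
    return(data.frame(file = character(0), issue = character(0),
                      fatal = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Run the full clonal-architecture pipeline
#'
#' Executes the enabled stages in dependency order — simulate, presence,
#' phylo, cna, ctdna, diversity — writing each stage's outputs under
#' `outdir` and returning a manifest (parameters, output md5 hashes,
#' package version). With a fixed configuration the manifest hashes are
#' reproducible.
#'
#' @param config A list (or path to a YAML file) with elements `outdir`,
#'   `stages` (character vector of stage names; default all), `sim`
#'   (arguments for [sim_config()]), and optional per-stage parameter lists
#'   `presence` (error_rate, alpha, min_depth, min_var_reads), `ctdna`
#'   (error_rate, fdr, alpha) and `cna` (doubling_threshold).
#' @return The manifest (invisibly also written to `outdir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir
  if (is.null(outdir)) stop("config error: outdir required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("simulate", "presence", "phylo", "cna", "ctdna",
                  "diversity")
  stages <- if (is.null(config$stages)) all_stages
            else match.arg(config$stages, all_stages, several.ok = TRUE)
  need <- function(stage, dep) {
    if (!dep %in% stages)
      stop("dependency error: stage '", stage, "' requires stage '", dep,
           "'", call. = FALSE)
  }
  outputs <- character(0)
  emit <- function(name) outputs <<- c(outputs, file.path(outdir, name))

  cfg <- do.call(sim_config, as.list(config$sim))
  pcfg <- utils::modifyList(list(error_rate = 0.001, alpha = 0.01,
                                 min_depth = 50, min_var_reads = 5),
                            as.list(config$presence))
  ccfg <- utils::modifyList(list(error_rate = 0.001, fdr = 0.05,
                                 alpha = 0.05), as.list(config$ctdna))
  dcfg <- utils::modifyList(list(doubling_threshold = 0.5),
                            as.list(config$cna))

  sim <- NULL
  if ("simulate" %in% stages) {
    tree <- simulate_clone_tree(cfg)
    comp <- simulate_regions(tree, cfg)
    counts <- simulate_amplicon_counts(tree, comp, cfg)
    profiles <- simulate_cna_profiles(tree, comp, cfg)
    plasma <- simulate_ctdna(tree, cfg)
    write_amplicon_counts(counts, file.path(outdir, "counts.tsv"))
    write_amplicon_counts(plasma, file.path(outdir, "plasma.tsv"))
    write_segments(profiles, file.path(outdir, "segments.tsv"))
    write_truth(tree, comp, file.path(outdir, "truth.json"))
    for (f in c("counts.tsv", "plasma.tsv", "segments.tsv", "truth.json"))
      emit(f)
    sim <- list(tree = tree, comp = comp, counts = counts,
                profiles = profiles, plasma = plasma)
  }

  pm <- NULL
  if ("presence" %in% stages) {
    need("presence", "simulate")
    pm <- call_presence(sim$counts, error_rate = pcfg$error_rate,
                        alpha = pcfg$alpha, min_depth = pcfg$min_depth,
                        min_var_reads = pcfg$min_var_reads)
    grouping <- stats::setNames(rep("case", ncol(pm$call)),
                                colnames(pm$call))
    cons <- conservation_stats(pm, grouping)
    cats <- classify_mutations(pm, grouping)
    write_presence_matrix(pm, file.path(outdir, "presence.tsv"))
    jsonlite::write_json(cons, file.path(outdir, "conservation.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    utils::write.csv(cats, file.path(outdir, "mutation_categories.csv"),
                     row.names = FALSE)
    for (f in c("presence.tsv", "conservation.json",
                "mutation_categories.csv")) emit(f)
  }

  if ("phylo" %in% stages) {
    need("phylo", "presence")
    D <- profile_distance_matrix(pm, mode = "vaf")
    tree_snv <- neighbour_joining(D)
    writeLines(write_newick(tree_snv), file.path(outdir, "snv_tree.nwk"))
    utils::write.table(D, file.path(outdir, "snv_distances.tsv"),
                       sep = "\t", quote = FALSE)
    emit("snv_tree.nwk"); emit("snv_distances.tsv")
  }

  if ("cna" %in% stages) {
    need("cna", "simulate")
    profiles <- sim$profiles
    genes <- tile_genes(cfg$genome)
    gene_states <- lapply(profiles, project_to_genes, genes = genes)
    weights <- t(vapply(gene_states, function(g) as.numeric(g$weight),
                        numeric(nrow(genes))))
    fractions <- data.frame(
      sample_id = names(profiles),
      compound_fraction = vapply(profiles, compound_fraction,
                                 numeric(1), genome = cfg$genome),
      row.names = NULL, stringsAsFactors = FALSE)
    cn_tree <- cna_distance_tree(weights)
    writeLines(write_newick(cn_tree$tree), file.path(outdir, "cna_tree.nwk"))
    utils::write.csv(fractions, file.path(outdir, "compound_fractions.csv"),
                     row.names = FALSE)
    ref <- names(profiles)[1]
    doubling <- do.call(rbind, lapply(setdiff(names(profiles), ref),
      function(s) {
        dd <- detect_doubling(profiles[[ref]], profiles[[s]],
                              threshold = dcfg$doubling_threshold)
        data.frame(reference = ref, test = s, n_doubled = dd$n_doubled,
                   stringsAsFactors = FALSE)
      }))
    utils::write.csv(doubling, file.path(outdir, "doubling.csv"),
                     row.names = FALSE)
    for (f in c("cna_tree.nwk", "compound_fractions.csv", "doubling.csv"))
      emit(f)
  }

  if ("ctdna" %in% stages) {
    need("ctdna", "presence")
    grouping <- stats::setNames(rep("case", ncol(pm$call)),
                                colnames(pm$call))
    cats <- classify_mutations(pm, grouping)
    anc <- stats::setNames(cats$category == "ancestral", cats$mutation_id)
    det <- ctdna_detect(sim$plasma, ancestral = anc,
                        error_rate = ccfg$error_rate, fdr = ccfg$fdr,
                        alpha = ccfg$alpha)
    utils::write.csv(det$results, file.path(outdir, "ctdna_results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(det$summary, file.path(outdir, "ctdna_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    emit("ctdna_results.csv"); emit("ctdna_summary.json")
  }

  if ("diversity" %in% stages) {
    need("diversity", "presence")
    tc <- vapply(split(sim$comp$tumour_content, sim$comp$sample_id),
                 `[`, numeric(1), 1L)
    freqs <- estimate_cellular_frequencies(
      pm, sim$tree$mutations, sim$profiles, tc)
    div <- sample_diversity(freqs)
    utils::write.csv(freqs, file.path(outdir, "cellular_frequencies.csv"),
                     row.names = FALSE)
    utils::write.csv(div, file.path(outdir, "diversity.csv"),
                     row.names = FALSE)
    emit("cellular_frequencies.csv"); emit("diversity.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("clonescape")),
    stages = stages,
    parameters = list(sim = unclass(cfg)[setdiff(names(cfg), "genome")],
                      presence = pcfg, ctdna = ccfg, cna = dcfg),
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

#' Regular gene tiling of a genome
#'
#' A synthetic gene model: fixed-width genes tiled along each chromosome,
#' used to project segment states onto a shared gene universe when no real
#' gene annotation is in play.
#'
#' @param genome Genome data.frame (`chrom`, `length`).
#' @param width Gene width in bases.
#' @param spacing Distance between gene starts.
#' @return data.frame `gene`, `chrom`, `start`, `end`.
#' @export
tile_genes <- function(genome, width = 1e5, spacing = 2e6) {
  rows <- lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - width, by = spacing)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = starts + width, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(gene = sprintf("g%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  out
}
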