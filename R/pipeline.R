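## End-to-end orchestration: validate -> spore-pigment filter -> chemotype
## assignment -> similarity binning -> rarefaction -> three dissimilarity
## layers -> PD clustering tests -> distance-decay / driver statistics ->
## machine-readable summary. Every stage writes a checkpoint file; a rerun
## with the same configuration and seed is bit-identical.

#' Default pipeline configuration
#'
#' @param tree,alignment,refs,community,metadata input file paths (each may
#'   instead be passed as an in-memory object to [run_pipeline()]).
#' @param out_dir run directory for checkpointed outputs.
#' @param cutoff_pct percent-identity binning cutoff (default 90).
#' @param rarefaction_depth `"min"` (minimum sequence count across samples)
#'   or a fixed integer.
#' @param pigment_threshold spore-pigment exclusion threshold (default 0.5).
#' @param confidence confident-assignment threshold (default 0.75).
#' @param n_perm permutations for Mantel/ANOSIM/MRM (default 999).
#' @param pd_draws random draws for the PD clustering test (default 10000).
#' @param seed integer seed.
#' @param pigment_filter apply the spore-pigment exclusion?
#' @param bonferroni report Bonferroni-adjusted p-values?
#' @param exclude_clade optional character pair of tip ids: the clade below
#'   their MRCA is dropped before analysis (the "uncharacterized clade"
#'   exclusion analog).
#' @param identity_from `"alignment"` (pairwise identity of the alignment)
#'   or `"tree"` (monotone map of patristic distance).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(tree = NULL, alignment = NULL, refs = NULL,
                            community = NULL, metadata = NULL,
                            out_dir = tempfile("traitscape_run_"),
                            cutoff_pct = 90, rarefaction_depth = "min",
                            pigment_threshold = 0.5, confidence = 0.75,
                            n_perm = 999, pd_draws = 10000, seed = 1,
                            pigment_filter = TRUE, bonferroni = TRUE,
                            exclude_clade = NULL,
                            identity_from = c("alignment", "tree")) {
  structure(list(tree = tree, alignment = alignment, refs = refs,
                 community = community, metadata = metadata,
                 out_dir = out_dir, cutoff_pct = cutoff_pct,
                 rarefaction_depth = rarefaction_depth,
                 pigment_threshold = pigment_threshold,
                 confidence = confidence, n_perm = n_perm,
                 pd_draws = pd_draws, seed = seed,
                 pigment_filter = pigment_filter, bonferroni = bonferroni,
                 exclude_clade = exclude_clade,
                 identity_from = match.arg(identity_from)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.load_input <- function(x, reader) {
  if (is.null(x) || !is.character(x)) return(x)
  reader(x)
}

#' Run the full analysis pipeline
#'
#' @param cfg a [pipeline_config()]; path entries are read from disk, while
#'   in-memory objects (e.g. a [simulate_landscape()] bundle's components)
#'   are used directly.
#' @return a list with the staged results and the path of the JSON summary;
#'   checkpoints are written under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message(sprintf(...))
  stage <- function(name, expr) {
    log("stage: %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  tree <- .load_input(cfg$tree, read_tree)
  aln <- .load_input(cfg$alignment, read_alignment)
  refs <- .load_input(cfg$refs, read_reference_annotations)
  community <- .load_input(cfg$community, read_community_table)
  meta <- .load_input(cfg$metadata, read_sample_metadata)
  identity <- NULL
  if (inherits(cfg$alignment, "identity_matrix")) {
    identity <- cfg$alignment; aln <- NULL
  }

  stage("validate", validate_bundle(tree, aln, refs, community, meta))

  if (!is.null(cfg$exclude_clade)) {
    tree0 <- tree
    drop <- stage("exclude_clade", {
      mrca <- ape::getMRCA(tree, cfg$exclude_clade)
      tree$tip.label[ape::prop.part(tree)[[mrca - length(tree$tip.label)]]]
    })
    drop <- setdiff(drop, refs$id)
    tree <- ape::drop.tip(tree0, drop)
    community <- community[, setdiff(colnames(community), drop), drop = FALSE]
    community <- as_community_table(community, attr(community, "unit_kind") %||% "sequence")
  }

  queries <- setdiff(colnames(community), refs$id)

  excluded <- character(0)
  pigment <- NULL
  if (cfg$pigment_filter) {
    pigment <- stage("pigment_filter",
                     classify_spore_pigment(tree, refs, queries,
                                            threshold = cfg$pigment_threshold))
    excluded <- attr(pigment, "excluded")
    utils::write.table(as.data.frame(pigment),
                       file.path(cfg$out_dir, "pigment_probs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  retained <- setdiff(queries, excluded)
  if (!length(retained)) stop("pigment filter excluded every query")

  chemo <- stage("chemotype_assignment",
                 assign_chemotypes(tree, refs, retained,
                                   confidence = cfg$confidence))
  utils::write.table(as.data.frame(chemo),
                     file.path(cfg$out_dir, "chemotype_probs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  groups <- stage("binning", {
    if (is.null(identity))
      identity <- if (!is.null(aln) && cfg$identity_from == "alignment")
        pairwise_identity(aln)
      else {
        D <- ape::cophenetic.phylo(tree)
        id <- 100 * exp(-D / 2); diag(id) <- 100
        structure(id, class = c("identity_matrix", "matrix"))
      }
    bin_by_tree(tree, identity, cfg$cutoff_pct)
  })

  comm_seq <- community[, retained, drop = FALSE]
  comm_seq <- comm_seq[rowSums(comm_seq) > 0, , drop = FALSE]
  depth <- if (identical(cfg$rarefaction_depth, "min")) min(rowSums(comm_seq))
           else as.integer(cfg$rarefaction_depth)
  rare <- stage("rarefaction",
                rarefy(comm_seq, depth, seed = cfg$seed))
  write_community_table(rare, file.path(cfg$out_dir, "rarefied_community.tsv"))

  comm_group <- collapse_to_groups(rare, groups)
  comm_trait <- build_trait_matrix(rare, chemo)

  d_group <- stage("bray_curtis_groups", bray_curtis(comm_group))
  d_phylo <- stage("weighted_unifrac", weighted_unifrac(rare, tree))
  d_trait <- stage("bray_curtis_traits", bray_curtis(comm_trait))
  write_distance_matrix(d_group, file.path(cfg$out_dir, "dist_groups.tsv"))
  write_distance_matrix(d_phylo, file.path(cfg$out_dir, "dist_phylo.tsv"))
  write_distance_matrix(d_trait, file.path(cfg$out_dir, "dist_traits.tsv"))

  clust <- stage("pd_clustering", {
    reftree <- ape::keep.tip(tree, refs$id)
    anti <- refs[refs$category == "antibiotic", ]
    labs <- sort(unique(anti$chemotype))
    out <- lapply(labs, function(lab) {
      tips <- anti$id[anti$chemotype == lab]
      if (length(tips) < 2)
        return(data.frame(chemotype = lab, n = length(tips),
                          observed_pd = NA, quantile = NA))
      z <- trait_clustering_score(reftree, tips, n_draws = cfg$pd_draws,
                                  seed = cfg$seed)
      data.frame(chemotype = lab, n = length(tips),
                 observed_pd = z$observed_pd, quantile = z$quantile)
    })
    do.call(rbind, out)
  })
  utils::write.table(clust, file.path(cfg$out_dir, "pd_clustering.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stats_out <- NULL
  if (!is.null(meta)) {
    stats_out <- stage("spatial_statistics", {
      ids <- rownames(rare)
      sub <- function(m) m[ids, ids]
      geo <- sub(geo_distance(meta))
      grp <- meta$continent[ids]
      res <- list()
      for (layer in c("group", "phylo", "trait")) {
        dmat <- switch(layer, group = d_group, phylo = d_phylo, trait = d_trait)
        an <- if (length(unique(grp)) > 1 && all(table(grp) >= 2))
          anosim(dmat, grp, n_perm = cfg$n_perm, seed = cfg$seed) else NULL
        env_d <- if (ncol(meta$env)) {
          envf <- env_prefilter(meta$env[ids, , drop = FALSE])
          sc <- apply(envf, 2, function(v)
            if (diff(range(v)) > 0) (v - min(v)) / diff(range(v)) else v * 0)
          .as_dm(as.matrix(stats::dist(sc)), ids)
        } else NULL
        plant_d <- if (ncol(meta$plants))
          tryCatch(plant_distance(meta)[ids, ids], error = function(e) NULL)
        else NULL
        drv <- tryCatch(
          driver_analysis(dmat, geo, env_d, plant_d,
                          n_perm = cfg$n_perm, seed = cfg$seed),
          error = function(e) {
            warning(sprintf("driver analysis skipped for layer '%s': %s",
                            layer, conditionMessage(e)))
            NULL
          })
        res[[layer]] <- list(anosim = an, drivers = drv)
      }
      res
    })
  }

  summary <- list(
    n_sequences = ncol(community),
    n_references = nrow(refs),
    n_ref_spore_pigment = sum(refs$category == "spore_pigment"),
    n_ref_antibiotic = sum(refs$category == "antibiotic"),
    n_chemotypes = length(unique(stats::na.omit(refs$chemotype))),
    n_excluded_pigment = length(excluded),
    n_retained_sequences = length(retained),
    n_groups = length(unique(groups[retained])),
    rarefaction_depth = depth,
    n_samples_retained = nrow(rare),
    confident_fraction = mean(attr(chemo, "confident")),
    mean_dissimilarity = list(group = mean(.lower(d_group)),
                              phylo = mean(.lower(d_phylo)),
                              trait = mean(.lower(d_trait))),
    pd_clustering = clust,
    seed = cfg$seed)
  if (!is.null(stats_out)) {
    summary$anosim <- lapply(stats_out, function(x)
      if (is.null(x$anosim)) NULL else x$anosim)
    summary$decay_slope <- lapply(stats_out, function(x)
      if (is.null(x$drivers)) NA else x$drivers$decay$slope)
    summary$decay_p <- lapply(stats_out, function(x)
      if (is.null(x$drivers)) NA else x$drivers$decay$p)
  }
  json_path <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = 12,
                       dataframe = "columns")
  list(summary = summary, summary_path = json_path,
       trait_probs = chemo, pigment = pigment, groups = groups,
       rarefied = rare, distances = list(group = d_group, phylo = d_phylo,
                                         trait = d_trait),
       clustering = clust, spatial = stats_out, out_dir = cfg$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
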